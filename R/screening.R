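#' Screening configuration
#'
#' Defaults follow the protocol the package implements: only commercially
#' available solvents are considered, a strict environmental-index ceiling
#' of 2 is applied (a solvent with EI exactly 2 is excluded), predicted
#' solubilities are computed at 298.15 K, and candidates are compared
#' against methanol as the best conventional solvent.
#'
#' @param ei_max Strict upper bound on the environmental index.
#' @param temperature Kelvin, for the solubility predictions.
#' @param reference_solvent Name of the benchmark solvent; must be present
#'   in the screened catalog unless `reference_log_solubility` is given.
#' @param include_pcop Use the PCOP-included EI variant for the threshold?
#' @param reference_log_solubility Optional externally supplied
#'   `log10(x_sat)` of the reference, bypassing the in-catalog solve.
#' @return A list of class `screening_config`.
#' @export
screening_config <- function(ei_max = 2.0, temperature = 298.15,
                             reference_solvent = "methanol",
                             include_pcop = TRUE,
                             reference_log_solubility = NULL) {
  stopifnot(ei_max > 0, temperature > 0)
  structure(list(ei_max = ei_max, temperature = temperature,
                 reference_solvent = reference_solvent,
                 include_pcop = include_pcop,
                 reference_log_solubility = reference_log_solubility),
            class = "screening_config")
}

#' Screen a solvent catalog for green, efficient candidates
#'
#' The three-stage filter cascade:
#'
#' 1. **availability** — solvents not commercially available are dropped;
#' 2. **greenness** — survivors must have EI strictly below `ei_max`;
#' 3. **solubility** — the saturation solubility of the solute is
#'    predicted in each survivor and candidates are flagged
#'    `better_than_reference` when their predicted `log10(x_sat)` strictly
#'    exceeds the reference solvent's (miscible predictions count as
#'    "infinite" solubility and sort above every finite value).
#'
#' Solvents lacking both an EI block and an activity model are excluded
#' with a warning and counted separately; the reference solvent's
#' solubility is computed from its catalog record regardless of whether it
#' passes the filters (a benchmark need not be green).
#'
#' @param catalog A solvent catalog tibble ([read_solvent_catalog()] or
#'   [generate_solvent_catalog()]).
#' @param solute A solute (name, row or list; see [gibbs_fusion()]).
#' @param model_provider A function `(solvent_row) -> activity_model`
#'   giving the solute-in-solvent activity model for each catalog row.
#'   Defaults to [margules_provider()], which reads a `margules_a` column
#'   (ideal when absent).
#' @param config A [screening_config()].
#' @return An object of class `screening_report`: `counts` (stage
#'   tibble), `shortlist` (ranked tibble: `name`, `ei`, `log10_x_sat`,
#'   `miscible`, `better_than_reference`), `reference` (name and
#'   `log10_x_sat`), `excluded_no_model` (names).  [tidy()] returns the
#'   shortlist, [glance()] the stage counts in one row.
#' @export
screen_catalog <- function(catalog, solute,
                           model_provider = margules_provider(),
                           config = screening_config()) {
  validate_solvent_catalog(catalog)
  solute <- as_solute(solute)
  stopifnot(inherits(config, "screening_config"), is.function(model_provider))

  n_input <- nrow(catalog)
  if (n_input > 0) {
    catalog <- ei_total(catalog, include_pcop = config$include_pcop)
  } else {
    catalog$ei <- numeric(0)
  }

  # reference solubility, computed outside the cascade
  ref_log <- config$reference_log_solubility
  if (is.null(ref_log)) {
    ref_row <- catalog[catalog$name == config$reference_solvent, , drop = FALSE]
    if (nrow(ref_row) != 1) {
      if (n_input == 0) {
        ref_log <- NA_real_ # empty catalog: nothing to compare, empty report
      } else {
        abort(sprintf("reference solvent '%s' not in catalog and no reference_log_solubility given",
                      config$reference_solvent))
      }
    } else {
      ref_log <- predict_for_row(ref_row, solute, model_provider, config)
    }
  }

  stage_available <- catalog[catalog$available %in% TRUE, , drop = FALSE]
  stage_ei <- stage_available[!is.na(stage_available$ei) &
                                stage_available$ei < config$ei_max, , drop = FALSE]
  no_ei <- stage_available[is.na(stage_available$ei), , drop = FALSE]
  if (nrow(no_ei) > 0) {
    warn(sprintf("%d available solvent(s) lack EI components and were excluded: %s",
                 nrow(no_ei), paste(head(no_ei$name, 5), collapse = ", ")))
  }

  shortlist <- purrr::map(seq_len(nrow(stage_ei)), function(i) {
    row <- stage_ei[i, , drop = FALSE]
    lg <- predict_for_row(row, solute, model_provider, config)
    tibble(name = row$name, ei = row$ei, log10_x_sat = lg,
           miscible = is.infinite(lg) & lg > 0)
  }) |> dplyr::bind_rows()

  if (nrow(shortlist) > 0) {
    shortlist <- dplyr::mutate(
      shortlist,
      better_than_reference = !is.na(.data$log10_x_sat) & .data$log10_x_sat > ref_log
    )
    # miscible entries first, then descending predicted solubility; name
    # breaks ties so reports are byte-identical across runs
    shortlist <- shortlist[order(-shortlist$miscible,
                                 -xtfrm(shortlist$log10_x_sat),
                                 shortlist$name), , drop = FALSE]
  } else {
    shortlist <- tibble(name = character(), ei = numeric(),
                        log10_x_sat = numeric(), miscible = logical(),
                        better_than_reference = logical())
  }

  structure(
    list(
      counts = tibble(
        stage = c("input", "available", "ei_pass"),
        count = c(n_input, nrow(stage_available), nrow(stage_ei))
      ),
      shortlist = shortlist,
      reference = list(name = config$reference_solvent, log10_x_sat = ref_log),
      excluded_no_model = no_ei$name,
      solute = solute$name,
      config = config
    ),
    class = "screening_report"
  )
}

#' @export
print.screening_report <- function(x, ...) {
  cat(sprintf("<screening report: %s, reference %s (log10 x = %s)>\n",
              x$solute, x$reference$name, format(x$reference$log10_x_sat, digits = 4)))
  counts <- paste(sprintf("%s=%d", x$counts$stage, x$counts$count), collapse = " -> ")
  cat("  cascade: ", counts, "\n", sep = "")
  n_better <- sum(x$shortlist$better_than_reference)
  cat(sprintf("  shortlist: %d candidate(s), %d better than reference\n",
              nrow(x$shortlist), n_better))
  invisible(x)
}

#' @rdname screen_catalog
#' @param x A `screening_report`.
#' @param ... Unused.
#' @method tidy screening_report
#' @export
tidy.screening_report <- function(x, ...) x$shortlist

#' @rdname screen_catalog
#' @method glance screening_report
#' @export
glance.screening_report <- function(x, ...) {
  tibble(
    input = x$counts$count[1], available = x$counts$count[2],
    ei_pass = x$counts$count[3],
    better_than_reference = sum(x$shortlist$better_than_reference),
    reference_log10_x = x$reference$log10_x_sat
  )
}

#' Aqueous-binary follow-up for a shortlist
#'
#' For each shortlisted solvent, computes a water--organic solubility
#' profile over `grid` and couples every point with the mixture EI at the
#' same solute-free fraction, yielding the solubility-versus-greenness
#' trade-off table that drives binary-mixture recommendations.  Solvents
#' whose profile fails entirely are dropped with a warning.
#'
#' @param report A `screening_report`, or a character vector of solvent
#'   names to look up in `catalog`.
#' @param catalog The solvent catalog (needed for molar masses and EI).
#' @inheritParams screen_catalog
#' @param grid Solute-free organic fractions in `[0, 1]`.
#' @return A tibble: `name`, `organic_fraction`, `x_sat`, `miscible`,
#'   `ei`.
#' @export
shortlist_binary_grids <- function(report, catalog, solute,
                                   grid = c(0.2, 0.4, 0.6, 0.8, 1.0),
                                   model_provider = margules_provider(),
                                   config = screening_config()) {
  names_wanted <- if (inherits(report, "screening_report")) report$shortlist$name else report
  if (length(names_wanted) == 0 || length(grid) == 0) {
    return(tibble(name = character(), organic_fraction = numeric(),
                  x_sat = numeric(), miscible = logical(), ei = numeric()))
  }
  solute <- as_solute(solute)
  rows <- purrr::map(names_wanted, function(nm) {
    row <- catalog[catalog$name == nm, , drop = FALSE]
    if (nrow(row) != 1) {
      warn(sprintf("solvent '%s' not found in catalog; skipped", nm))
      return(NULL)
    }
    model <- aqueous_model_for_row(row, solute, model_provider)
    prof <- solubility_profile(solute, nm, grid, model,
                               temperature = config$temperature)
    eis <- ei_aqueous_mixture(row, grid, include_pcop = config$include_pcop)
    dplyr::left_join(
      dplyr::select(dplyr::mutate(prof, name = nm),
                    "name", "organic_fraction", "x_sat", "miscible"),
      dplyr::select(eis, "organic_fraction", "ei"),
      by = "organic_fraction"
    )
  })
  dplyr::bind_rows(rows)
}

#' Default per-solvent activity-model lookup
#'
#' Builds the `model_provider` used by [screen_catalog()]: for a catalog
#' row with a `margules_a` column the solute--solvent pair gets a binary
#' two-suffix Margules model with that interaction parameter (negative
#' values mean favourable solute--solvent interactions, hence
#' above-ideal solubility); rows without the column fall back to the
#' ideal model.  `a_water` supplies the solute--water and water--organic
#' parameters used when the model is extended to aqueous ternaries.
#'
#' @param a_water Interaction parameters for the aqueous extension:
#'   `c(solute_water, organic_water)`.
#' @return A function `(solvent_row) -> activity_model`.
#' @export
margules_provider <- function(a_water = c(3, 0)) {
  force(a_water)
  function(solvent_row) {
    row <- as.list(solvent_row)
    a <- if (!is.null(row$margules_a) && is.finite(row$margules_a)) row$margules_a else 0
    structure(
      list(a_organic = a, a_solute_water = a_water[1], a_organic_water = a_water[2],
           solvent_name = row$name),
      class = "margules_provider_entry"
    )
  }
}

# Resolve a provider result into a concrete binary (neat) model for the
# solute in one solvent.  Providers may return a ready activity_model or
# the lightweight margules entry produced by margules_provider().
neat_model_for_row <- function(row, solute, model_provider) {
  m <- model_provider(row)
  if (inherits(m, "activity_model")) return(m)
  if (inherits(m, "margules_provider_entry")) {
    return(activity_margules(m$a_organic, components = c(solute$name, row$name)))
  }
  abort("model_provider must return an activity_model")
}

aqueous_model_for_row <- function(row, solute, model_provider) {
  m <- model_provider(row)
  if (inherits(m, "activity_model")) return(m)
  if (inherits(m, "margules_provider_entry")) {
    comps <- c(solute$name, row$name, "water")
    A <- matrix(0, 3, 3)
    A[1, 2] <- A[2, 1] <- m$a_organic
    A[1, 3] <- A[3, 1] <- m$a_solute_water
    A[2, 3] <- A[3, 2] <- m$a_organic_water
    return(activity_margules(A, components = comps))
  }
  abort("model_provider must return an activity_model")
}

predict_for_row <- function(row, solute, model_provider, config) {
  model <- neat_model_for_row(row, solute, model_provider)
  predicted_log_solubility(solute, row$name, model,
                           temperature = config$temperature)
}
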