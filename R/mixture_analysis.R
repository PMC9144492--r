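#' Detect co-solvation synergy in a binary-solvent solubility profile
#'
#' A profile is synergistic when its maximum mean solubility sits at an
#' interior solute-free organic fraction and exceeds **both** endpoint
#' means by more than `rel_tol` relative — the signature of a
#' co-solvation effect, where the mixed solvent outperforms either neat
#' component.  Points are sorted by fraction internally, so input order
#' does not matter; the test is invariant to uniform rescaling of the
#' solubilities.
#'
#' @param profile A tibble with `organic_fraction` and a mean-solubility
#'   column (`x_mean` or `x_sat`); optionally `x_sd`.  At least three
#'   points spanning an interior fraction are required.
#' @param rel_tol Relative excess over the better endpoint required to
#'   call synergy (default 5%, a robust margin against triplicate
#'   shake-flask noise).
#' @return A one-row tibble of class `synergy_report`: `synergistic`,
#'   `argmax_fraction`, `max_solubility`, `endpoint_low`, `endpoint_high`
#'   (solubility at the lowest / highest fraction), `excess` (relative
#'   excess of the maximum over the better endpoint).
#' @export
#' @examples
#' prof <- read_measurements(system.file("extdata",
#'   "salicylamide_4fm_synthetic.csv", package = "greensolv"))
#' detect_synergy(prof)
detect_synergy <- function(profile, rel_tol = 0.05) {
  p <- normalize_profile(profile)
  if (nrow(p) < 3) abort("synergy detection needs at least 3 grid points")
  i_max <- which.max(p$x)
  interior <- i_max > 1 && i_max < nrow(p)
  best_endpoint <- max(p$x[1], p$x[nrow(p)])
  excess <- p$x[i_max] / best_endpoint - 1
  out <- tibble(
    synergistic = interior && excess > rel_tol,
    argmax_fraction = p$fraction[i_max],
    max_solubility = p$x[i_max],
    endpoint_low = p$x[1],
    endpoint_high = p$x[nrow(p)],
    excess = excess
  )
  class(out) <- c("synergy_report", class(out))
  out
}

#' Classify a binary-solvent profile's dilution behaviour
#'
#' Three regimes:
#' * `"water_antisolvent"` — mean solubility never decreases with the
#'   organic fraction (within one pooled replicate standard deviation,
#'   one-sided): adding water only hurts, so the pair works as an
#'   efficient solvent--antisolvent couple for crystallisation.
#' * `"synergistic"` — an interior maximum per [detect_synergy()].
#' * `"irregular"` — anything else (non-monotone beyond noise without an
#'   interior co-solvation maximum).
#'
#' @inheritParams detect_synergy
#' @return A single string, one of the three regime labels.
#' @export
antisolvent_classification <- function(profile, rel_tol = 0.05) {
  p <- normalize_profile(profile)
  if (nrow(p) < 3) abort("classification needs at least 3 grid points")
  if (detect_synergy(profile, rel_tol)$synergistic) return("synergistic")
  pooled_sd <- if (all(is.na(p$sd))) 0 else sqrt(mean(p$sd^2, na.rm = TRUE))
  drops <- diff(p$x)
  if (all(drops >= -pooled_sd)) "water_antisolvent" else "irregular"
}

#' Order neat solvents by solubilizing power, grouping near-ties
#'
#' Sorts solvents by descending mean solubility and merges consecutive
#' solvents into an approximately-equal group when their means differ by
#' less than `tie_rel_tol` relative, or when their one-standard-deviation
#' intervals overlap (if SDs are given).  The result renders orderings
#' such as `DMF > 4FM ~ DMSO` without inventing a formal significance
#' test.
#'
#' @param neat_values A tibble with `solvent` and `x_mean` columns,
#'   optionally `x_sd`; or a named numeric vector of means.
#' @param tie_rel_tol Relative difference under which two consecutive
#'   solvents tie (default 5%).
#' @return An object of class `solvent_ordering`: a tibble `solvent`,
#'   `x_mean`, `x_sd`, `group` (1 = strongest), with the rendered
#'   ordering string in attribute `"ordering"` (also shown by `print()`
#'   and returned by `format()`).
#' @export
#' @examples
#' order_solvent_power(c(DMF = 0.30, `4FM` = 0.21, DMSO = 0.20))
order_solvent_power <- function(neat_values, tie_rel_tol = 0.05) {
  if (is.numeric(neat_values) && !is.null(names(neat_values))) {
    neat_values <- tibble(solvent = names(neat_values), x_mean = unname(neat_values))
  }
  stopifnot(is.data.frame(neat_values),
            all(c("solvent", "x_mean") %in% names(neat_values)))
  if (nrow(neat_values) < 2) abort("ordering needs at least 2 solvents")
  sd <- if ("x_sd" %in% names(neat_values)) neat_values$x_sd else rep(NA_real_, nrow(neat_values))

  ord <- order(-neat_values$x_mean, neat_values$solvent)
  m <- neat_values$x_mean[ord]
  s <- sd[ord]
  group <- integer(length(m))
  group[1] <- 1L
  for (i in seq_along(m)[-1]) {
    rel <- abs(m[i - 1] - m[i]) / mean(c(m[i - 1], m[i]))
    overlap <- !is.na(s[i - 1]) && !is.na(s[i]) &&
      (m[i - 1] - s[i - 1]) <= (m[i] + s[i])
    group[i] <- if (rel < tie_rel_tol || overlap) group[i - 1] else group[i - 1] + 1L
  }
  out <- tibble(solvent = neat_values$solvent[ord], x_mean = m, x_sd = s,
                group = group)
  parts <- vapply(split(out$solvent, out$group),
                  paste, character(1), collapse = " ~ ")
  attr(out, "ordering") <- paste(parts, collapse = " > ")
  class(out) <- c("solvent_ordering", class(out))
  out
}

#' @export
format.solvent_ordering <- function(x, ...) attr(x, "ordering")

#' @export
print.solvent_ordering <- function(x, ...) {
  cat("<solvent ordering> ", attr(x, "ordering"), "\n", sep = "")
  NextMethod()
}

# Accept measurement tibbles (x_mean/x_sd), solver profiles (x_sat) or bare
# fraction/value tables; return sorted fraction/x/sd columns.
normalize_profile <- function(profile) {
  stopifnot(is.data.frame(profile))
  if (!"organic_fraction" %in% names(profile)) {
    abort("profile needs an 'organic_fraction' column")
  }
  xcol <- intersect(c("x_mean", "x_sat", "x"), names(profile))[1]
  if (is.na(xcol)) abort("profile needs a solubility column (x_mean, x_sat or x)")
  p <- tibble(
    fraction = profile$organic_fraction,
    x = profile[[xcol]],
    sd = if ("x_sd" %in% names(profile)) profile$x_sd else NA_real_
  )
  p <- p[!is.na(p$x), , drop = FALSE]
  if (any(p$fraction < 0 | p$fraction > 1)) abort("fractions must lie in [0, 1]")
  p <- p[order(p$fraction), , drop = FALSE]
  if (anyDuplicated(p$fraction)) abort("duplicate organic fractions in profile")
  p
}
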