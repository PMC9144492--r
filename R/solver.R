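#' Solver options for the saturation fixed point
#'
#' @param tol Convergence tolerance on \eqn{|\Delta \ln x|} between
#'   successive iterates.
#' @param max_iter Maximum number of fixed-point iterations.
#' @param damping Damping factor in `(0, 1]` applied to the log-space
#'   update; 1 is the undamped iteration.
#' @param miscibility_cutoff Solute mole fraction at which the iterate is
#'   declared to have run to the pure-liquid limit ("infinite" predicted
#'   solubility, i.e. the liquids are taken as fully miscible).
#' @return A list of class `solver_options`.
#' @export
solver_options <- function(tol = 1e-10, max_iter = 500, damping = 0.5,
                           miscibility_cutoff = 0.9999) {
  stopifnot(tol > 0, max_iter >= 1, damping > 0, damping <= 1,
            miscibility_cutoff > 0, miscibility_cutoff < 1)
  structure(list(tol = tol, max_iter = max_iter, damping = damping,
                 miscibility_cutoff = miscibility_cutoff),
            class = "solver_options")
}

#' Solve the saturation equation for a solute in a (mixed) solvent
#'
#' Finds the saturation mole fraction \eqn{x^{sat}} satisfying
#' \deqn{\ln(\gamma^{sat} x^{sat}) = -\max(0, \Delta_{fus}G)/RT}
#' by damped fixed-point iteration in \eqn{\ln x}:
#' \deqn{\ln x^{(k+1)} = (1-d)\ln x^{(k)} + d\,[\ln a^{sat} - \ln\gamma(x^{(k)})]}
#' where \eqn{a^{sat} = \exp(-\max(0,\Delta_{fus}G)/RT)} is the solid's
#' activity.  The solvent components keep their solute-free ratio and are
#' renormalised against the current solute fraction each step, so ternary
#' compositions always sum to 1.  Iteration starts from the ideal
#' solubility (which is already the fixed point when \eqn{\gamma \approx 1}).
#'
#' If the iterate reaches `miscibility_cutoff` the solute is flagged
#' miscible with the solvent (\eqn{x^{sat}} reported as 1.0) — the
#' "predicted solubility is infinite" outcome that screening ranks above
#' every finite value.  Non-convergence within `max_iter` is reported via
#' `converged = FALSE`, never as an error.
#'
#' @param solute A solute name, one-row solute tibble, or list with `tm`
#'   (K) and `hfus` (kJ/mol); see [gibbs_fusion()].
#' @param solvent_fractions Named numeric vector of solute-free solvent
#'   mole fractions (e.g. `c(water = 0.4, DMSO = 0.6)`), summing to 1.
#' @param model An [activity_model][activity_models] covering the solute
#'   and every solvent component (by name), or covering none (the ideal
#'   model needs no component list).
#' @param temperature Kelvin.
#' @param options A [solver_options()] list.
#' @return An object of class `saturation_fit`: fields `x_sat`,
#'   `gamma_sat`, `activity_target`, `iterations`, `converged`,
#'   `miscible`, plus the inputs for printing.  Use [tidy()] / [glance()]
#'   for tibble views.
#' @export
#' @examples
#' solve_saturation("benzamide", c(solvent = 1), activity_ideal(), 298.15)
solve_saturation <- function(solute, solvent_fractions, model,
                             temperature = 298.15,
                             options = solver_options()) {
  solute <- as_solute(solute)
  stopifnot(inherits(model, "activity_model"), temperature > 0)
  sf <- check_solvent_fractions(solvent_fractions)

  a_sat <- activity_target(solute, temperature)
  comp_names <- c(solute$name, names(sf))
  lng_solute <- make_lngamma_fn(model, solute$name, sf, comp_names)

  cutoff <- options$miscibility_cutoff
  ln_x <- log(min(a_sat, cutoff)) # ideal solubility start, capped below the cutoff
  converged <- FALSE
  miscible <- FALSE
  iter <- 0L
  if (a_sat >= cutoff) {
    # above (or at) the melting point: activity target 1, trivially miscible
    miscible <- TRUE
    converged <- TRUE
    ln_x <- 0
  } else {
    d <- options$damping
    for (iter in seq_len(options$max_iter)) {
      lng <- lng_solute(exp(ln_x), temperature)
      ln_x_new <- (1 - d) * ln_x + d * (log(a_sat) - lng)
      if (!is.finite(ln_x_new)) {
        abort("activity-coefficient evaluation returned a non-finite value")
      }
      if (exp(ln_x_new) >= cutoff) {
        miscible <- TRUE
        converged <- TRUE
        ln_x <- 0
        break
      }
      delta <- abs(ln_x_new - ln_x)
      ln_x <- ln_x_new
      if (delta < options$tol) {
        converged <- TRUE
        break
      }
    }
  }

  x_sat <- if (miscible) 1.0 else exp(ln_x)
  gamma_sat <- if (miscible) NA_real_ else exp(lng_solute(x_sat, temperature))
  structure(
    list(
      x_sat = x_sat, gamma_sat = gamma_sat, activity_target = a_sat,
      iterations = iter, converged = converged, miscible = miscible,
      solute = solute$name, temperature = temperature, model = model$name,
      solvent_fractions = sf
    ),
    class = "saturation_fit"
  )
}

#' @export
print.saturation_fit <- function(x, ...) {
  cat(sprintf("<saturation fit: %s in %s at %.2f K (%s model)>\n",
              x$solute, paste(names(x$solvent_fractions), collapse = "/"),
              x$temperature, x$model))
  if (x$miscible) {
    cat("  predicted miscible (x_sat -> 1); solubility unbounded\n")
  } else {
    cat(sprintf("  x_sat = %.6g  gamma_sat = %.6g  (a_sat = %.6g)\n",
                x$x_sat, x$gamma_sat, x$activity_target))
  }
  cat(sprintf("  %d iteration(s), converged = %s\n", x$iterations, x$converged))
  invisible(x)
}

#' @rdname solve_saturation
#' @param x A `saturation_fit`.
#' @param ... Unused.
#' @method tidy saturation_fit
#' @export
tidy.saturation_fit <- function(x, ...) {
  tibble(
    solute = x$solute,
    solvent = paste(names(x$solvent_fractions), collapse = "/"),
    temperature = x$temperature,
    x_sat = x$x_sat,
    gamma_sat = x$gamma_sat,
    log10_x_sat = if (x$miscible) Inf else log10(x$x_sat),
    miscible = x$miscible
  )
}

#' @rdname solve_saturation
#' @method glance saturation_fit
#' @export
glance.saturation_fit <- function(x, ...) {
  tibble(
    activity_target = x$activity_target,
    iterations = x$iterations,
    converged = x$converged,
    miscible = x$miscible,
    model = x$model
  )
}

#' Solubility profile across a water--organic composition grid
#'
#' Runs [solve_saturation()] at each solute-free organic fraction of a
#' water--organic binary solvent and collects the results in a tibble
#' (one row per grid point).  Per-point failures are recorded (`converged
#' = FALSE`, `x_sat = NA`), not raised, so a partially valid profile is
#' still returned.
#'
#' @inheritParams solve_saturation
#' @param organic The organic solvent: a name or a one-row solvent tibble
#'   (only the name is used here).
#' @param grid Solute-free organic mole fractions in `[0, 1]`.
#' @param water Name of the aqueous component as known to the model.
#' @return A `solubility_profile` tibble: `organic_fraction`, `x_sat`,
#'   `gamma_sat`, `miscible`, `converged`, `iterations`, `temperature`.
#' @export
solubility_profile <- function(solute, organic, grid, model,
                               temperature = 298.15,
                               options = solver_options(), water = "water") {
  organic_name <- if (is.character(organic)) organic else as.list(organic)$name
  stopifnot(is.numeric(grid), all(grid >= 0 & grid <= 1))
  rows <- purrr::map(grid, function(x2) {
    sf <- c(x2, 1 - x2)
    names(sf) <- c(organic_name, water)
    sf <- sf[sf > 0]
    fit <- tryCatch(
      solve_saturation(solute, sf, model, temperature, options),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      tibble(organic_fraction = x2, x_sat = NA_real_, gamma_sat = NA_real_,
             miscible = FALSE, converged = FALSE, iterations = NA_integer_)
    } else {
      tibble(organic_fraction = x2, x_sat = fit$x_sat, gamma_sat = fit$gamma_sat,
             miscible = fit$miscible, converged = fit$converged,
             iterations = fit$iterations)
    }
  })
  out <- dplyr::bind_rows(rows)
  out$temperature <- rep(temperature, nrow(out))
  class(out) <- c("solubility_profile", class(out))
  out
}

#' Predicted log10 solubility for ranking
#'
#' Thin wrapper over [solve_saturation()] that returns
#' \eqn{\log_{10} x^{sat}}, with `Inf` as the sentinel for a miscible
#' ("infinite solubility") prediction so that such solvents sort above
#' every finite value, and `NA` for a non-converged solve.
#'
#' @inheritParams solve_saturation
#' @param solvent Solvent name (neat solvent), or a named solute-free
#'   fraction vector for mixtures.
#' @return A single number: `log10(x_sat)`, `Inf` (miscible) or `NA`.
#' @export
predicted_log_solubility <- function(solute, solvent, model,
                                     temperature = 298.15,
                                     options = solver_options()) {
  sf <- if (is.character(solvent)) setNames(1, solvent) else solvent
  fit <- solve_saturation(solute, sf, model, temperature, options)
  if (fit$miscible) return(Inf)
  if (!fit$converged) return(NA_real_)
  log10(fit$x_sat)
}

# ---- internals --------------------------------------------------------------

check_solvent_fractions <- function(sf) {
  if (is.null(names(sf)) || any(names(sf) == "")) {
    abort("solvent_fractions must be a named numeric vector")
  }
  nm <- names(sf)
  sf <- as.double(sf)
  names(sf) <- nm
  if (any(sf < 0)) abort("solvent fractions must be non-negative")
  s <- sum(sf)
  if (s <= 0) abort("solvent fractions must not all be zero")
  if (abs(s - 1) > 1e-8) abort("solute-free solvent fractions must sum to 1")
  sf / s
}

# Build a function x_solute -> ln gamma_solute with the solvent held at its
# solute-free ratio.  The ideal model short-circuits (no component matching
# needed); otherwise components are matched by name.
make_lngamma_fn <- function(model, solute_name, sf, comp_names) {
  if (inherits(model, "activity_ideal")) {
    return(function(x, temperature) 0)
  }
  missing <- setdiff(comp_names, model$components)
  if (length(missing) > 0) {
    abort(sprintf("model '%s' does not cover component(s): %s",
                  model$name, paste(missing, collapse = ", ")))
  }
  function(x, temperature) {
    comp <- c(x, (1 - x) * sf)
    names(comp) <- comp_names
    full <- setNames(rep(0, model$n_components), model$components)
    full[names(comp)] <- comp
    unname(ln_gamma(model, full, temperature)[solute_name])
  }
}
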