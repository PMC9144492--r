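#' Generate a synthetic solvent catalog
#'
#' Emulates the structure of a large environmental-screening solvent
#' database: each solvent gets a molar mass, a commercial-availability
#' flag, eight log-normal environmental-impact component scores (totals
#' spanning well below and well above the usual EI ceiling of 2), and a
#' binary Margules interaction parameter `margules_a` describing the
#' solute--solvent pair for solubility prediction.
#'
#' `planted_good` solvents are constructed to pass the full screening
#' cascade: forced available, EI components rescaled so the composite
#' index falls in `[0.1, 1.5]`, and a favourable (negative) `margules_a`
#' in `[-3, -1]` so their predicted solubility strictly exceeds the
#' ideal-solution reference.  All other solvents get an unfavourable
#' `margules_a` in `[0.5, 3]`.  A reference row (`reference_name`, ideal
#' behaviour, `margules_a = 0`) is appended so the cascade's
#' better-than-reference comparison is self-contained.
#'
#' All randomness flows from `seed`; identical specs give identical
#' catalogs.
#'
#' @param n_solvents Number of candidate solvents (reference row excluded).
#' @param planted_good Number of planted cascade passers.
#' @param availability_prob Probability a non-planted solvent is available.
#' @param ei_meanlog,ei_sdlog Log-normal parameters for each raw EI
#'   component score.
#' @param reference_name Name of the appended reference solvent.
#' @param seed Integer seed.
#' @return A solvent catalog tibble with the extra columns `margules_a`
#'   and `planted` (logical).
#' @export
#' @examples
#' cat200 <- generate_solvent_catalog(n_solvents = 200, planted_good = 40, seed = 42)
#' sum(cat200$planted)
generate_solvent_catalog <- function(n_solvents, planted_good = 0,
                                     availability_prob = 0.7,
                                     ei_meanlog = -1.5, ei_sdlog = 1.5,
                                     reference_name = "methanol",
                                     seed = 1) {
  stopifnot(n_solvents >= 0, planted_good >= 0, planted_good <= n_solvents,
            availability_prob >= 0, availability_prob <= 1)
  local_seed(seed)

  comps <- matrix(stats::rlnorm(n_solvents * 8, ei_meanlog, ei_sdlog),
                  nrow = n_solvents, ncol = 8)
  colnames(comps) <- EI_COMPONENTS
  available <- stats::rbinom(n_solvents, 1, availability_prob) == 1
  margules_a <- stats::runif(n_solvents, 0.5, 3)
  planted <- rep(FALSE, n_solvents)
  if (planted_good > 0) {
    idx <- sample.int(n_solvents, planted_good)
    planted[idx] <- TRUE
    available[idx] <- TRUE
    target_ei <- stats::runif(planted_good, 0.1, 1.5)
    comps[idx, ] <- comps[idx, , drop = FALSE] *
      (target_ei / rowSums(comps[idx, , drop = FALSE]))
    margules_a[idx] <- stats::runif(planted_good, -3, -1)
  }

  out <- tibble(
    name = sprintf("solvent_%03d", seq_len(n_solvents)),
    cas = sprintf("0000-%03d-0", seq_len(n_solvents)),
    molar_mass = stats::runif(n_solvents, 18, 200),
    available = available
  )
  for (k in seq_along(EI_COMPONENTS)) out[[EI_COMPONENTS[k]]] <- comps[, k]
  out$margules_a <- margules_a
  out$planted <- planted

  ref <- tibble(name = reference_name, cas = "67-56-1", molar_mass = 32.04,
                available = TRUE)
  for (comp in EI_COMPONENTS) ref[[comp]] <- 0.1
  ref$margules_a <- 0
  ref$planted <- FALSE
  dplyr::bind_rows(out, ref)
}

#' Simulate triplicate shake-flask measurements from a known model
#'
#' Computes the true saturation solubility of `solute` in the
#' water--`organic` binary at each grid fraction and temperature using the
#' supplied activity model, then draws `replicates` noisy observations per
#' point with multiplicative log-normal noise,
#' \eqn{x_k = x_{true}\,e^{\varepsilon_k}}, \eqn{\varepsilon_k \sim N(0, cv^2)}
#' — solubilities span orders of magnitude and must stay positive, and
#' spectrophotometric assay error is relative, which additive noise would
#' misrepresent.  `cv = 0` reproduces the model exactly.  All randomness
#' flows from `seed`.
#'
#' @inheritParams solubility_profile
#' @param true_model The activity model generating the data.
#' @param temperatures Kelvin; one set of grid points is produced per
#'   temperature.
#' @param replicates Replicates per point (default 3).
#' @param cv Coefficient of variation of the multiplicative noise.
#' @param seed Integer seed.
#' @return A measurement tibble in the [read_measurements()] layout
#'   (`replicates` list column plus `x_mean` / `x_sd`).
#' @export
generate_measured_profiles <- function(solute, organic, grid, true_model,
                                       temperatures = 298.15,
                                       replicates = 3, cv = 0.03, seed = 1,
                                       options = solver_options()) {
  stopifnot(replicates >= 1, cv >= 0, all(grid >= 0 & grid <= 1))
  solute <- as_solute(solute)
  organic_name <- if (is.character(organic)) organic else as.list(organic)$name
  local_seed(seed)

  rows <- purrr::map(temperatures, function(tk) {
    prof <- solubility_profile(solute, organic_name, grid, true_model,
                               temperature = tk, options = options)
    reps <- purrr::map(prof$x_sat, function(x_true) {
      if (is.na(x_true)) return(numeric(0))
      eps <- if (cv > 0) stats::rnorm(replicates, 0, cv) else rep(0, replicates)
      pmin(x_true * exp(eps), 1 - 1e-9)
    })
    tibble(
      solute = solute$name,
      organic_solvent = organic_name,
      organic_fraction = prof$organic_fraction,
      temperature = tk,
      replicates = reps,
      x_mean = purrr::map_dbl(reps, function(r) if (length(r)) mean(r) else NA_real_),
      x_sd = purrr::map_dbl(reps, function(r) if (length(r) > 1) stats::sd(r) else NA_real_)
    )
  })
  dplyr::bind_rows(rows)
}

#' Recover a binary Margules parameter from measured profiles
#'
#' Inverts [generate_measured_profiles()]-style data by grid search:
#' for each candidate `A` the model solubilities are computed at the
#' measured temperatures/fractions and the candidate minimising the sum
#' of squared log-differences against the measured means is returned.
#' Mainly a self-consistency instrument for the synthetic-data pathway.
#'
#' @param measurements A measurement tibble (neat-solvent rows,
#'   `organic_fraction == 1`, are the informative ones for a binary
#'   model; other rows are ignored).
#' @param solute The solute the data refer to.
#' @param a_grid Candidate values of the Margules parameter.
#' @return The best-fitting `A` (a single number).
#' @export
recover_margules_a <- function(measurements, solute,
                               a_grid = seq(-3, 3, by = 0.01)) {
  solute <- as_solute(solute)
  neat <- measurements[measurements$organic_fraction == 1, , drop = FALSE]
  if (nrow(neat) == 0) abort("need neat-solvent (organic_fraction = 1) measurements")
  organic <- neat$organic_solvent[1]
  sse <- vapply(a_grid, function(a) {
    model <- activity_margules(a, components = c(solute$name, organic))
    pred <- vapply(neat$temperature, function(tk) {
      solve_saturation(solute, setNames(1, organic), model, tk)$x_sat
    }, numeric(1))
    sum((log(pred) - log(neat$x_mean))^2)
  }, numeric(1))
  a_grid[which.min(sse)]
}

# Seed the RNG locally and restore the caller's state on exit two frames up
# (the caller of the function that invoked us).
local_seed <- function(seed, env = parent.frame()) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed) %% .Machine$integer.max)
  withr::defer({
    if (has_old) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, envir = env)
  invisible(seed)
}
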