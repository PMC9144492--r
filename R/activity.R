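#' Activity-coefficient models
#'
#' The saturation solver is agnostic to how activity coefficients are
#' produced: anything implementing the [ln_gamma()] generic with a
#' `components` field plugs in.  Three engines ship with the package:
#'
#' * `activity_ideal()` — \eqn{\ln\gamma_i = 0} for every component; the
#'   reference limit in which the solver reproduces the closed-form ideal
#'   solubility.
#' * `activity_margules()` — the two-suffix (regular-solution) Margules
#'   model.  For a binary, \eqn{\ln\gamma_1 = A x_2^2}; the multicomponent
#'   generalisation derives from the excess Gibbs energy
#'   \eqn{G^E/RT = \sum_{j<k} A_{jk} x_j x_k}, so Gibbs–Duhem consistency
#'   holds by construction.
#' * `activity_nrtl()` — the standard multicomponent NRTL expression with
#'   user-supplied \eqn{\tau} and \eqn{\alpha} tables (no built-in
#'   temperature dependence: supply \eqn{\tau(T)} yourself).
#'
#' All engines use the pure-liquid reference state, so
#' \eqn{\ln\gamma_i \to 0} as \eqn{x_i \to 1}.
#'
#' @param components Character vector of component names (the solute plus
#'   the solvent components, in any order).
#' @param A For `activity_margules()`: a single interaction parameter
#'   (binary), or a symmetric matrix with zero diagonal, one row/column per
#'   component.
#' @param tau,alpha For `activity_nrtl()`: square matrices over the
#'   components; `tau` has zero diagonal, `alpha` is symmetric.
#' @return An object of class `activity_model`.
#' @name activity_models
#' @examples
#' m <- activity_margules(2, components = c("benzamide", "hexane"))
#' ln_gamma(m, c(benzamide = 0.5, hexane = 0.5), 298.15)
NULL

#' @rdname activity_models
#' @export
activity_ideal <- function(components = character()) {
  new_activity_model("ideal", components, list())
}

#' @rdname activity_models
#' @export
activity_margules <- function(A, components) {
  stopifnot(is.character(components), length(components) >= 2)
  n <- length(components)
  if (is.matrix(A)) {
    if (!all(dim(A) == n)) abort("Margules matrix A must be n_components x n_components")
    if (!isSymmetric(unname(A)) || any(diag(A) != 0)) {
      abort("Margules matrix A must be symmetric with zero diagonal")
    }
  } else {
    if (length(A) != 1 || n != 2) {
      abort("scalar A requires exactly two components; give a matrix otherwise")
    }
    A <- matrix(c(0, A, A, 0), 2, 2)
  }
  new_activity_model("margules", components, list(A = unname(A)))
}

#' @rdname activity_models
#' @export
activity_nrtl <- function(tau, alpha, components) {
  stopifnot(is.character(components), length(components) >= 2)
  n <- length(components)
  tau <- as.matrix(tau); alpha <- as.matrix(alpha)
  if (!all(dim(tau) == n) || !all(dim(alpha) == n)) {
    abort(sprintf("tau and alpha must be %d x %d to match the components", n, n))
  }
  if (any(diag(tau) != 0)) abort("NRTL requires tau_ii = 0")
  if (!isSymmetric(unname(alpha))) abort("NRTL requires a symmetric alpha")
  new_activity_model("nrtl", components, list(tau = unname(tau), alpha = unname(alpha)))
}

new_activity_model <- function(kind, components, parameters) {
  structure(
    list(name = kind, components = as.character(components),
         n_components = length(components), parameters = parameters),
    class = c(paste0("activity_", kind), "activity_model")
  )
}

#' @export
print.activity_model <- function(x, ...) {
  cat(sprintf("<activity model: %s | %d component(s): %s>\n",
              x$name, x$n_components, paste(x$components, collapse = ", ")))
  invisible(x)
}

#' Log activity coefficients at a composition
#'
#' @param model An `activity_model`.
#' @param composition Named (or positional, in model component order)
#'   numeric vector of mole fractions summing to 1.
#' @param temperature Kelvin; unused by the bundled parameter tables but
#'   part of the contract so temperature-dependent engines can plug in.
#' @return Named numeric vector of \eqn{\ln\gamma_i}, one per component.
#' @export
ln_gamma <- function(model, composition, temperature = 298.15) {
  UseMethod("ln_gamma")
}

#' @export
ln_gamma.activity_ideal <- function(model, composition, temperature = 298.15) {
  x <- check_composition(model, composition)
  setNames(rep(0, length(x)), names(x))
}

#' @export
ln_gamma.activity_margules <- function(model, composition, temperature = 298.15) {
  x <- check_composition(model, composition)
  A <- model$parameters$A
  # ln gamma_i = sum_j A_ij x_j - G^E/RT for the two-suffix form
  ge <- 0.5 * sum((A %*% x) * x)
  setNames(as.vector(A %*% x) - ge, names(x))
}

#' @export
ln_gamma.activity_nrtl <- function(model, composition, temperature = 298.15) {
  x <- check_composition(model, composition)
  tau <- model$parameters$tau
  G <- exp(-model$parameters$alpha * tau)
  n <- length(x)
  denom <- as.vector(t(G) %*% x)              # denom_j = sum_k G_kj x_k
  frac1 <- as.vector(t(tau * G) %*% x) / denom # sum_j tau_ji G_ji x_j / denom_i
  lng <- numeric(n)
  for (i in seq_len(n)) {
    term2 <- sum(vapply(seq_len(n), function(j) {
      (x[j] * G[i, j] / denom[j]) *
        (tau[i, j] - sum(x * tau[, j] * G[, j]) / denom[j])
    }, numeric(1)))
    lng[i] <- frac1[i] + term2
  }
  setNames(lng, names(x))
}

#' Read an activity model from a JSON parameter file
#'
#' The file declares `model` (`"ideal"`, `"margules"` or `"nrtl"`),
#' `components`, and the model's parameter tables (`A` for Margules;
#' `tau` and `alpha` for NRTL).
#'
#' @param path Path to a JSON file.
#' @return An `activity_model`.
#' @export
read_activity_model <- function(path) {
  spec <- jsonlite::fromJSON(path)
  if (is.null(spec$model)) abort("activity-model file must declare 'model'")
  comps <- as.character(spec$components)
  switch(spec$model,
    ideal = activity_ideal(comps),
    margules = activity_margules(as.matrix(spec$A), comps),
    nrtl = activity_nrtl(as.matrix(spec$tau), as.matrix(spec$alpha), comps),
    abort(sprintf("unknown activity model '%s'", spec$model))
  )
}

# Validate a composition against a model: right length, in [0,1], sums to 1.
# Positional input is accepted and named after the model's components.
check_composition <- function(model, composition) {
  x <- as.double(composition)
  if (length(model$components) > 0 && !is.null(names(composition))) {
    missing <- setdiff(model$components, names(composition))
    if (length(missing) > 0) {
      abort(sprintf("composition lacks component(s): %s", paste(missing, collapse = ", ")))
    }
    x <- as.double(composition[model$components])
    names(x) <- model$components
  } else {
    if (model$n_components > 0 && length(x) != model$n_components) {
      abort(sprintf("expected %d mole fractions, got %d", model$n_components, length(x)))
    }
    names(x) <- if (model$n_components > 0) model$components else names(composition)
  }
  if (any(x < -1e-12 | x > 1 + 1e-12)) abort("mole fractions must lie in [0, 1]")
  if (abs(sum(x) - 1) > 1e-8) abort("mole fractions must sum to 1")
  x
}
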