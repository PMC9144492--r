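# Shared fixtures: paper-style solutes and solvents, plus small builders
# used across test files.

benzamide <- list(name = "benzamide", tm = 401.0, hfus = 20.9)
salicylamide <- list(name = "salicylamide", tm = 412.3, hfus = 28.4)

# Printed composite EI values and ranks for the worked-example systems
# (three organic solvents across the five-point aqueous grid), default
# variant and PCOP-excluded variant.
printed_greenness <- tibble::tribble(
  ~solvent, ~organic_fraction, ~ei_default, ~ei_no_pcop, ~rank_default, ~rank_no_pcop,
  "DMSO", 0.2,  6.09, 0.15, 12,  2,
  "DMSO", 0.4,  8.69, 0.20, 13,  3,
  "DMSO", 0.6, 10.10, 0.23, 14,  4,
  "DMSO", 0.8, 11.00, 0.25, 15,  5,
  "DMSO", 1.0, 11.70, 0.26, 16,  6,
  "DMF",  0.2,  1.10, 1.10,  7, 12,
  "DMF",  0.4,  1.58, 1.58,  8, 13,
  "DMF",  0.6,  1.85, 1.85,  9, 14,
  "DMF",  0.8,  2.03, 2.03, 10, 15,
  "DMF",  1.0,  2.16, 2.16, 11, 16,
  "4FM",  0.2,  0.32, 0.32,  2,  7,
  "4FM",  0.4,  0.42, 0.41,  3,  8,
  "4FM",  0.6,  0.46, 0.46,  4,  9,
  "4FM",  0.8,  0.49, 0.49,  5, 10,
  "4FM",  1.0,  0.51, 0.51,  6, 11
)

# Independent oracle for binary saturation: root of gamma(x) * x = a on
# (0, 1) by interval bisection (uniroot), independent of the fixed-point
# iteration it checks.
bisect_saturation <- function(lng_fun, a, upper = 1 - 1e-9) {
  f <- function(x) log(x) + lng_fun(x) - log(a)
  stats::uniroot(f, lower = 1e-14, upper = upper, tol = 1e-14)$root
}

# ln gamma of component 1 in a binary Margules system at solute fraction x
margules_lng1 <- function(A) function(x) A * (1 - x)^2

# ln gamma of component 1 in a binary NRTL system at solute fraction x
nrtl_lng1 <- function(tau12, tau21, alpha) {
  model <- activity_nrtl(matrix(c(0, tau21, tau12, 0), 2, 2),
                         matrix(c(0, alpha, alpha, 0), 2, 2),
                         c("c1", "c2"))
  function(x) unname(ln_gamma(model, c(c1 = x, c2 = 1 - x))["c1"])
}

# A ternary Margules construction whose solute activity coefficient has an
# interior minimum along the water->organic axis, so the solubility profile
# peaks at an interior grid point (argmax 0.6 on the standard grid).
synergy_model <- function(solute_name = "salicylamide",
                          organic = "4FM", water = "water") {
  A <- matrix(0, 3, 3)
  A[1, 2] <- A[2, 1] <- 1   # solute-organic
  A[1, 3] <- A[3, 1] <- 3   # solute-water
  A[2, 3] <- A[3, 2] <- 6   # organic-water
  activity_margules(A, components = c(solute_name, organic, water))
}
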