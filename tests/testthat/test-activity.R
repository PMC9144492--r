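test_that("ideal model returns zeros for any composition", {
  m <- activity_ideal(c("a", "b", "c"))
  expect_equal(unname(ln_gamma(m, c(a = 1/3, b = 1/3, c = 1/3))), c(0, 0, 0))
  expect_equal(unname(ln_gamma(m, c(a = 1, b = 0, c = 0))), c(0, 0, 0))
})

test_that("binary Margules matches its closed form", {
  m <- activity_margules(1, c("c1", "c2"))
  expect_equal(unname(ln_gamma(m, c(c1 = 0, c2 = 1))), c(1, 0))
  m0 <- activity_margules(0, c("c1", "c2"))
  expect_equal(unname(ln_gamma(m0, c(c1 = 0.3, c2 = 0.7))), c(0, 0))
  m2 <- activity_margules(2, c("c1", "c2"))
  expect_equal(unname(ln_gamma(m2, c(c1 = 0.5, c2 = 0.5))), c(0.5, 0.5))
  # general composition, closed form A * x_other^2
  for (x1 in c(0.1, 0.42, 0.9)) {
    lg <- ln_gamma(m2, c(c1 = x1, c2 = 1 - x1))
    expect_equal(unname(lg), c(2 * (1 - x1)^2, 2 * x1^2))
  }
})

test_that("NRTL reduces to ideal at tau = 0 and hits the infinite-dilution identity", {
  tau0 <- matrix(0, 2, 2)
  alpha <- matrix(c(0, 0.3, 0.3, 0), 2, 2)
  m0 <- activity_nrtl(tau0, alpha, c("c1", "c2"))
  expect_equal(unname(ln_gamma(m0, c(c1 = 0.4, c2 = 0.6))), c(0, 0))

  # binary: ln gamma1_inf = tau21 + tau12 * exp(-alpha * tau12)
  tau <- matrix(c(0, 1, 1, 0), 2, 2)
  m <- activity_nrtl(tau, alpha, c("c1", "c2"))
  lg_inf <- unname(ln_gamma(m, c(c1 = 1e-13, c2 = 1 - 1e-13))["c1"])
  expect_equal(lg_inf, 1 + exp(-0.3), tolerance = 1e-10)
})

test_that("permuting component order permutes NRTL outputs identically", {
  tau <- matrix(c(0, 0.8, -0.4, 0,
                  1.2, 0, 0.5, 0,
                  0.3, -0.2, 0, 0,
                  0, 0, 0, 0), 4, 4)[1:3, 1:3]
  diag(tau) <- 0
  alpha <- matrix(0.3, 3, 3); diag(alpha) <- 0
  m <- activity_nrtl(tau, alpha, c("a", "b", "c"))
  x <- c(a = 0.2, b = 0.5, c = 0.3)
  perm <- c(3, 1, 2)
  m_perm <- activity_nrtl(tau[perm, perm], alpha[perm, perm],
                          c("a", "b", "c")[perm])
  expect_equal(ln_gamma(m, x)[c("c", "a", "b")],
               ln_gamma(m_perm, x[c("c", "a", "b")]))
})

test_that("pure-component limit gives ln gamma = 0 for every model", {
  nearly_pure <- c(c1 = 1 - 1e-10, c2 = 1e-10)
  models <- list(
    activity_ideal(c("c1", "c2")),
    activity_margules(1.7, c("c1", "c2")),
    activity_nrtl(matrix(c(0, 0.9, 0.4, 0), 2, 2),
                  matrix(c(0, 0.3, 0.3, 0), 2, 2), c("c1", "c2"))
  )
  for (m in models) {
    expect_equal(unname(ln_gamma(m, nearly_pure)["c1"]), 0, tolerance = 1e-8)
  }
})

test_that("binary models satisfy Gibbs-Duhem by central differences", {
  h <- 1e-6
  check_gd <- function(lng_pair) {
    for (x1 in seq(0.1, 0.9, by = 0.1)) {
      up <- lng_pair(x1 + h); dn <- lng_pair(x1 - h)
      d1 <- (up[1] - dn[1]) / (2 * h)
      d2 <- (up[2] - dn[2]) / (2 * h)
      expect_equal(x1 * d1 + (1 - x1) * d2, 0, tolerance = 1e-6)
    }
  }
  mm <- activity_margules(2.2, c("c1", "c2"))
  check_gd(function(x1) unname(ln_gamma(mm, c(c1 = x1, c2 = 1 - x1))))
  mn <- activity_nrtl(matrix(c(0, 1.1, 0.6, 0), 2, 2),
                      matrix(c(0, 0.3, 0.3, 0), 2, 2), c("c1", "c2"))
  check_gd(function(x1) unname(ln_gamma(mn, c(c1 = x1, c2 = 1 - x1))))
})

test_that("model constructors and compositions are validated", {
  expect_error(activity_margules(1, c("a", "b", "c")), "matrix")
  expect_error(activity_margules(matrix(1:9, 3), letters[1:3]), "symmetric")
  expect_error(activity_nrtl(matrix(1, 2, 2), matrix(0, 2, 2), c("a", "b")),
               "tau_ii")
  expect_error(activity_nrtl(matrix(0, 3, 3), matrix(0, 2, 2), c("a", "b")),
               "2 x 2")
  m <- activity_margules(1, c("a", "b"))
  expect_error(ln_gamma(m, c(a = 0.6, b = 0.6)), "sum to 1")
  expect_error(ln_gamma(m, c(a = 0.5)), "lacks component")
})

test_that("activity models round-trip through JSON parameter files", {
  tmp <- tempfile(fileext = ".json")
  jsonlite::write_json(
    list(model = "nrtl", components = c("solute", "solv"),
         tau = matrix(c(0, 1, 0.5, 0), 2, 2),
         alpha = matrix(c(0, 0.3, 0.3, 0), 2, 2)),
    tmp, auto_unbox = TRUE, digits = NA
  )
  m <- read_activity_model(tmp)
  expect_s3_class(m, "activity_nrtl")
  expect_equal(m$parameters$tau[2, 1], 1)
  jsonlite::write_json(list(model = "margules", components = c("x", "y"),
                            A = matrix(c(0, 2, 2, 0), 2, 2)),
                       tmp, auto_unbox = TRUE, digits = NA)
  m2 <- read_activity_model(tmp)
  expect_equal(unname(ln_gamma(m2, c(x = 0.5, y = 0.5))), c(0.5, 0.5))
})
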