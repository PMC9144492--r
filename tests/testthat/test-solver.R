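test_that("solver reproduces the closed-form ideal solubility", {
  fit <- solve_saturation(benzamide, c(solvent = 1), activity_ideal())
  expect_true(fit$converged)
  expect_equal(fit$x_sat, ideal_solubility(benzamide, 298.15), tolerance = 1e-10)
  expect_equal(fit$x_sat, 0.1150, tolerance = 1e-3)
  expect_equal(fit$gamma_sat, 1)
  # cross-module consistency over solutes and temperatures
  for (solute in list(benzamide, salicylamide)) {
    for (tk in c(288.15, 298.15, 313.15, 350)) {
      fit <- solve_saturation(solute, c(solvent = 1), activity_ideal(), tk)
      expect_equal(fit$x_sat, ideal_solubility(solute, tk), tolerance = 1e-9)
    }
  }
})

test_that("at or above the melting point the solute is flagged miscible", {
  for (tk in c(401.0, 420, 451)) {
    fit <- solve_saturation(benzamide, c(solvent = 1), activity_ideal(), tk)
    expect_true(fit$miscible)
    expect_equal(fit$x_sat, 1.0)
  }
})

test_that("Margules binary fixed point agrees with the hand-checked value", {
  m <- activity_margules(2, c("benzamide", "solv"))
  fit <- solve_saturation(benzamide, c(solv = 1), m)
  expect_true(fit$converged)
  expect_equal(fit$x_sat, 0.0166, tolerance = 2e-3)
  expect_equal(fit$gamma_sat * fit$x_sat, fit$activity_target, tolerance = 1e-8)
})

test_that("fixed point matches the bisection oracle over random binaries", {
  set.seed(101)
  for (rep in 1:50) {
    a <- runif(1, 0.005, 0.5)
    solute <- list(name = "s", tm = 400,
                   hfus = -log(a) * 8.31446 * 298.15 / (1 - 298.15 / 400) / 1000)
    if (rep %% 2 == 0) {
      A <- runif(1, -2, 3)
      model <- activity_margules(A, c("s", "solv"))
      lng1 <- margules_lng1(A)
    } else {
      tau12 <- runif(1, -1, 1.5); tau21 <- runif(1, -1, 1.5)
      model <- activity_nrtl(matrix(c(0, tau21, tau12, 0), 2, 2),
                             matrix(c(0, 0.3, 0.3, 0), 2, 2), c("s", "solv"))
      lng1 <- nrtl_lng1(tau12, tau21, 0.3)
    }
    fit <- solve_saturation(solute, c(solv = 1), model)
    if (fit$miscible) next # oracle undefined past the pure-liquid limit
    expect_true(fit$converged)
    oracle <- bisect_saturation(lng1, fit$activity_target)
    expect_equal(fit$x_sat, oracle, tolerance = 1e-8)
  }
})

test_that("results are independent of damping for convergent cases", {
  m <- activity_margules(1.5, c("benzamide", "solv"))
  fits <- lapply(c(0.25, 0.5, 1.0), function(d) {
    solve_saturation(benzamide, c(solv = 1), m,
                     options = solver_options(damping = d))
  })
  expect_true(all(vapply(fits, `[[`, logical(1), "converged")))
  xs <- vapply(fits, `[[`, numeric(1), "x_sat")
  expect_equal(xs[1], xs[2], tolerance = 1e-9)
  expect_equal(xs[2], xs[3], tolerance = 1e-9)
})

test_that("non-convergence is reported, not raised", {
  m <- activity_margules(2, c("benzamide", "solv"))
  fit <- solve_saturation(benzamide, c(solv = 1), m,
                          options = solver_options(max_iter = 2))
  expect_false(fit$converged)
})

test_that("profiles cover the composition grid and respect the ideal limit", {
  prof <- solubility_profile(benzamide, "DMSO", c(0, 1), activity_ideal())
  expect_equal(prof$x_sat, rep(ideal_solubility(benzamide, 298.15), 2),
               tolerance = 1e-9)

  empty <- solubility_profile(benzamide, "DMSO", numeric(0), activity_ideal())
  expect_equal(nrow(empty), 0)

  # stronger organic affinity -> monotone increasing profile, each point
  # agreeing with an independent per-point solve
  A <- matrix(0, 3, 3)
  A[1, 2] <- A[2, 1] <- -0.5 # favourable organic
  A[1, 3] <- A[3, 1] <- 2.5  # unfavourable water
  A[2, 3] <- A[3, 2] <- 0.5
  m <- activity_margules(A, c("benzamide", "org", "water"))
  grid <- seq(0, 1, by = 0.2)
  prof <- solubility_profile(benzamide, "org", grid, m)
  expect_true(all(prof$converged))
  expect_true(all(diff(prof$x_sat) > 0))
  for (i in seq_along(grid)) {
    sf <- c(org = grid[i], water = 1 - grid[i])
    sf <- sf[sf > 0]
    fit <- solve_saturation(benzamide, sf, m)
    expect_equal(prof$x_sat[i], fit$x_sat, tolerance = 1e-12)
  }
})

test_that("log-solubility wrapper maps miscibility to a first-sorting sentinel", {
  expect_equal(
    predicted_log_solubility(
      list(name = "s", tm = 400, hfus = 19.097), "solv", activity_ideal()),
    log10(ideal_solubility(list(name = "s", tm = 400, hfus = 19.097), 298.15))
  )
  lg <- predicted_log_solubility(benzamide, "solv", activity_ideal(),
                                 temperature = 450)
  expect_identical(lg, Inf)
  expect_true(all(Inf > c(-1, 0, 5)))
  # strongly favourable interactions drive the iterate to the cutoff
  m <- activity_margules(-8, c("benzamide", "solv"))
  expect_identical(predicted_log_solubility(benzamide, "solv", m), Inf)
})

test_that("tidy and glance expose the fit as tibbles", {
  fit <- solve_saturation(benzamide, c(water = 0.4, DMSO = 0.6), activity_ideal())
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$solvent, "water/DMSO")
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_equal(gl$model, "ideal")
})
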