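test_that("the bundled co-solvation profile is classified synergistic at 0.6", {
  prof <- read_measurements(system.file("extdata",
    "salicylamide_4fm_synthetic.csv", package = "greensolv"))
  rep <- detect_synergy(prof)
  expect_true(rep$synergistic)
  expect_equal(rep$argmax_fraction, 0.6)
  expect_equal(rep$max_solubility, 0.379)
  expect_equal(antisolvent_classification(prof), "synergistic")
})

test_that("monotone, flat and zig-zag profiles land in the right regimes", {
  mono <- tibble::tibble(organic_fraction = seq(0, 1, 0.2),
                         x_mean = c(0.002, 0.01, 0.05, 0.12, 0.2, 0.3))
  expect_false(detect_synergy(mono)$synergistic)
  expect_equal(detect_synergy(mono)$argmax_fraction, 1.0)
  expect_equal(antisolvent_classification(mono), "water_antisolvent")

  flat <- tibble::tibble(organic_fraction = c(0, 0.5, 1), x_mean = 0.1)
  expect_false(detect_synergy(flat)$synergistic)
  expect_equal(antisolvent_classification(flat), "water_antisolvent")

  # non-monotone beyond noise but maximal at an endpoint: irregular
  zig <- tibble::tibble(organic_fraction = seq(0, 1, 0.25),
                        x_mean = c(0.05, 0.2, 0.05, 0.2, 0.3),
                        x_sd = rep(0.005, 5))
  expect_equal(antisolvent_classification(zig), "irregular")

  # small dips within one pooled SD do not break the antisolvent call
  noisy_mono <- tibble::tibble(organic_fraction = seq(0, 1, 0.25),
                               x_mean = c(0.05, 0.1, 0.098, 0.2, 0.3),
                               x_sd = rep(0.01, 5))
  expect_equal(antisolvent_classification(noisy_mono), "water_antisolvent")

  expect_error(detect_synergy(flat[1:2, ]), "3 grid points")
})

test_that("synergy detection is scale-invariant and order-insensitive", {
  prof <- tibble::tibble(organic_fraction = seq(0, 1, 0.2),
                         x_mean = c(0.01, 0.1, 0.3, 0.38, 0.36, 0.35))
  base <- detect_synergy(prof)
  scaled <- detect_synergy(dplyr::mutate(prof, x_mean = x_mean * 1e-3))
  expect_equal(scaled$synergistic, base$synergistic)
  expect_equal(scaled$argmax_fraction, base$argmax_fraction)
  expect_equal(scaled$excess, base$excess)

  reversed <- detect_synergy(prof[rev(seq_len(nrow(prof))), ])
  expect_equal(reversed$argmax_fraction, base$argmax_fraction)
  expect_equal(antisolvent_classification(prof[sample(6), ]),
               antisolvent_classification(prof))
})

test_that("noise-free solver profiles with an interior gamma minimum peak where built", {
  grid <- seq(0, 1, by = 0.2)
  prof <- solubility_profile(salicylamide, "4FM", grid, synergy_model())
  rep <- detect_synergy(prof)
  expect_true(rep$synergistic)
  expect_equal(rep$argmax_fraction, 0.6)
})

test_that("solvent-power ordering groups near-ties", {
  ord <- order_solvent_power(c(A = 0.30, B = 0.21, C = 0.20))
  expect_equal(format(ord), "A > B ~ C")
  expect_equal(ord$group, c(1L, 2L, 2L))

  strict <- order_solvent_power(c(A = 0.3, B = 0.2, C = 0.1))
  expect_equal(format(strict), "A > B > C")

  equal2 <- order_solvent_power(c(X = 0.2, Y = 0.2))
  expect_equal(max(equal2$group), 1L)

  # the aprotic-power pattern: strongest clearly ahead, next two tied
  amide <- order_solvent_power(c(DMF = 0.37, `4FM` = 0.305, DMSO = 0.30))
  expect_equal(format(amide), "DMF > 4FM ~ DMSO")

  # overlapping +-1 SD intervals group even when means differ by >5%
  sdtie <- order_solvent_power(
    tibble::tibble(solvent = c("P", "Q"), x_mean = c(0.30, 0.27),
                   x_sd = c(0.02, 0.02)))
  expect_equal(max(sdtie$group), 1L)

  expect_error(order_solvent_power(c(A = 0.1)), "at least 2")
})
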