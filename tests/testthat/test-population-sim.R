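test_that("sample_gaussian_distances drops negatives without resampling", {
  p0 <- sample_gaussian_distances(5.4, 0, 1000, seed = 1)
  expect_true(all(p0$values == 5.4))
  expect_equal(p0$n_retained, 1000L)

  p1 <- sample_gaussian_distances(5.4, 0.054, 1e4, seed = 2)
  expect_equal(p1$n_retained, 10000L)  # 100 sigma from zero

  # truncation point at (0 - 5.4)/10.8 = -0.5: retained fraction ~ pnorm(0.5)
  p2 <- sample_gaussian_distances(5.4, 10.8, 1e5, seed = 3)
  frac <- p2$n_retained / p2$n_requested
  se <- sqrt(pnorm(0.5) * (1 - pnorm(0.5)) / 1e5)
  expect_lt(abs(frac - pnorm(0.5)), 4 * se)
  expect_true(all(p2$values > 0))
  expect_error(sample_gaussian_distances(5.4, -1, 10), "non-negative")
})

test_that("efficiency_distribution integrates to 1 and matches raw moments", {
  set.seed(4)
  E <- runif(5e4)
  d <- efficiency_distribution(E)
  expect_equal(sum(d$density * diff(d$bin_edges)), 1, tolerance = 1e-9)
  expect_true(all(d$density >= 0))
  # density-weighted bin-center mean within one bin width of the raw mean
  w <- d$density * diff(d$bin_edges)
  expect_lt(abs(sum(w * d$bin_centers) - d$mean_E), 0.01)
  # E = 1 lands in the final (right-closed) bin
  d1 <- efficiency_distribution(c(0, 0.5, 1))
  expect_equal(sum(d1$density * diff(d1$bin_edges)), 1, tolerance = 1e-12)
  expect_equal(d1$density[100] * 0.01, 1 / 3, tolerance = 1e-12)
  expect_error(efficiency_distribution(numeric(0)), "no efficiency")
  expect_error(efficiency_distribution(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("tight populations give a narrow efficiency peak at 0.5", {
  d <- simulate_distance_heterogeneity(5.4, 1, cv_system(), n = 1e5, seed = 5)
  expect_equal(d$mean_E, 0.5, tolerance = 0.01)
  expect_lt(d$sd_E, 0.02)
  expect_equal(which.max(d$density), 50L, tolerance = 1)  # bin [0.49, 0.50)
})

test_that("large separation variance produces bimodal efficiency distributions", {
  d25 <- simulate_distance_heterogeneity(5.4, 25, cv_system(), n = 1e5, seed = 6)
  expect_lt(abs(d25$mean_E - 0.5), 0.03)  # still near 0.5, though broadened
  expect_gt(d25$sd_E, 0.2)

  d200 <- simulate_distance_heterogeneity(5.4, 200, cv_system(), n = 1e5, seed = 7)
  dens <- d200$density
  # modes in the extreme bins, interior valley far below either peak
  expect_equal(sort(order(dens, decreasing = TRUE)[1:2]), c(1L, 100L))
  expect_lt(max(dens[40:60]), 0.2 * min(dens[c(1, 100)]))
})

test_that("dark-state masking zeros the expected fraction of rates", {
  rates <- rep(1 / 3, 2e4)
  expect_identical(apply_acceptor_dark_states(rates, 0, seed = 8), rates)
  expect_identical(apply_acceptor_dark_states(rates, 1, seed = 8),
                   rep(0, 2e4))
  masked <- apply_acceptor_dark_states(rates, 0.5, seed = 9)
  expect_lt(abs(mean(masked == 0) - 0.5), 3 * sqrt(0.25 / 2e4))
  expect_error(apply_acceptor_dark_states(rates, 1.5), "\\[0, 1\\]")
})

test_that("blinking law <E_B> = (1 - f) <E> holds across dark fractions", {
  sys <- cv_system()
  set.seed(10)
  pop <- sample_gaussian_distances(5.4, 0.054, 1e5)
  kT <- transfer_rate(pop$values, sys)
  E0 <- mean(efficiency_from_rate(kT, sys$tau0D))
  for (f in c(0.05, 0.15, 0.3, 0.5)) {
    EB <- efficiency_from_rate(apply_acceptor_dark_states(kT, f), sys$tau0D)
    se <- sd(EB) / sqrt(length(EB))
    expect_lt(abs(mean(EB) - (1 - f) * E0), 3 * se)
  }
})

test_that("dark states make the efficiency distribution bimodal at 0 and 0.5", {
  sys <- cv_system()
  set.seed(12)
  pop <- sample_gaussian_distances(5.4, 0.054, 1e5)
  kT <- apply_acceptor_dark_states(transfer_rate(pop$values, sys), 0.5)
  d <- efficiency_distribution(efficiency_from_rate(kT, sys$tau0D))
  expect_equal(d$mean_E, 0.25, tolerance = 0.01)
  peaks <- order(d$density, decreasing = TRUE)[1:2]
  expect_true(1L %in% peaks)            # E = 0 peak
  expect_true(any(peaks %in% 49:52))    # E = 0.5 peak
  # reciprocal weights: each peak region holds ~half the mass
  w <- d$density * diff(d$bin_edges)
  expect_equal(w[1], 0.5, tolerance = 0.01)
  expect_equal(sum(w[45:55]), 0.5, tolerance = 0.01)
})

test_that("static regime reproduces the broad bimodal distribution", {
  d <- simulate_static_regime(5.4, 1, cv_system(), n = 1e5, seed = 13)
  expect_lt(abs(d$mean_E - 0.38), 0.01)
  expect_lt(abs(d$sd_E - 0.25), 0.01)
  # sharply reached maximum in the lowest bin, secondary peak near 0.6
  expect_equal(which.max(d$density), 1L)
  interior <- d$density[20:90]
  expect_equal(20 + which.max(interior) - 1, 60, tolerance = 2)
  # kappa2 = 2/3 control recovers the narrow dynamic distribution
  dc <- simulate_static_regime(5.4, 1, cv_system(), n = 1e5, seed = 14,
                               kappa2 = 2 / 3)
  expect_lt(abs(dc$mean_E - 0.5), 0.01)
  expect_lt(dc$sd_E, 0.02)  # ~0.015: 1% separation SD maps to 1.5% in E
})

test_that("simulations are deterministic given a seed", {
  a <- simulate_static_regime(5.4, 1, cv_system(), n = 5000, seed = 99)
  b <- simulate_static_regime(5.4, 1, cv_system(), n = 5000, seed = 99)
  expect_identical(a$density, b$density)
  expect_identical(a$mean_E, b$mean_E)
})

test_that("sweep_mean_efficiency reproduces the qualitative curve orderings", {
  sys <- cv_system()
  grid <- c(2.7, 4, 5.4, 8, 10.8)
  sw <- sweep_mean_efficiency("distance_sd", grid, levels = c(1, 50), sys,
                              n = 2e4, seed = 15)
  tight <- sw[sw$level == 1, ]
  broad <- sw[sw$level == 50, ]
  # 1% curve indistinguishable from the fixed pair
  expect_equal(tight$mean_E, tight$E_fixed_pair, tolerance = 0.01)
  # broad heterogeneity: below fixed-pair curve inside R0, above outside
  expect_true(all(broad$mean_E[broad$R_DA < 5.4] <
                  broad$E_fixed_pair[broad$R_DA < 5.4]))
  expect_true(all(broad$mean_E[broad$R_DA > 5.4] >
                  broad$E_fixed_pair[broad$R_DA > 5.4]))

  swd <- sweep_mean_efficiency("dark_fraction", grid, levels = c(0.3), sys,
                               n = 2e4, seed = 16)
  expect_equal(swd$mean_E, 0.7 * swd$E_fixed_pair, tolerance = 0.02)

  swr <- sweep_mean_efficiency("regime", grid, system = sys, n = 2e4, seed = 17)
  dyn <- swr[swr$level == "dynamic", ]
  sta <- swr[swr$level == "static", ]
  expect_true(all(sta$mean_E < dyn$mean_E))
})

test_that("C5V scenario yields mean efficiency above the measured 0.43", {
  d <- c5v_scenario(n = 1e5, seed = 18)
  expect_gt(d$mean_E, 0.7)
  expect_gt(d$mean_E, 0.43)
  expect_true(all(attr(d, "distances")$values > 0))
})
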