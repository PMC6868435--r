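# Dudko-Szabo rate law, rupture-force distributions, sampling, and
# force-profile reconstruction.

test_that("rate law limits: zero force, exact Bell equivalence at nu = 1", {
  expect_equal(ds_rate(0, ds_na), 1 / 50)

  # nu = 1 collapses to the Bell rate exp(F dx / kBT)/tau0 for any dG
  bell <- ds_params(dx_dagger = 4.11, tau0 = 1, dG_dagger = 5, nu = 1)
  expect_equal(ds_rate(1, bell, kBT = 4.11), exp(1))
  set.seed(42)
  for (i in 1:10) {
    p <- ds_params(runif(1, 1, 8), exp(runif(1, 0, 6)), runif(1, 4, 15),
                   nu = 1)
    f <- runif(1, 0, 0.9 * critical_force(p))
    expect_equal(ds_rate(f, p), exp(f * p$dx_dagger / 4.11) / p$tau0,
                 tolerance = 1e-12)
  }
})

test_that("rate at 4 pN for the sodium-solution parameters matches the closed form", {
  # (1/50) z exp(6.5 (1 - z^2)) with z = 1 - 2*4.3/26.715, evaluated by hand
  expect_equal(ds_rate(4, ds_na), 0.4542127, tolerance = 1e-6)
})

test_that("forces at or beyond the critical force are rejected", {
  Fc <- critical_force(ds_na)
  expect_error(ds_rate(Fc, ds_na), "F_c")
  expect_error(ds_rate(Fc + 1, ds_na), "F_c")
  expect_silent(ds_rate(Fc - 1e-6, ds_na))
})

test_that("hazard is monotone below the turnover force for nu = 1/2", {
  # k'(F) changes sign where (1 - nu F dx/dG_E) = 1/sqrt(2 dG)
  p <- ds_na
  kBT <- 4.11
  z_star <- 1 / sqrt(2 * p$dG_dagger)
  F_star <- (1 - z_star) * p$dG_dagger * kBT / (p$nu * p$dx_dagger)
  grid_lo <- seq(0, F_star * 0.999, length.out = 200)
  k_lo <- ds_rate(grid_lo, p)
  expect_true(all(diff(k_lo) > 0))
  grid_hi <- seq(F_star * 1.001, critical_force(p) * 0.9999,
                 length.out = 200)
  expect_true(all(diff(ds_rate(grid_hi, p)) < 0))
})

test_that("rupture density conserves probability for randomized parameters", {
  set.seed(7)
  for (i in 1:10) {
    p <- ds_params(runif(1, 2, 8), exp(runif(1, 0, 8)), runif(1, 4, 14))
    rd <- rupture_density(p, default_sched)
    expect_equal(rd$total_mass + rd$survival, 1, tolerance = 1e-4)
  }
})

test_that("Bell-Evans mode under a constant ramp matches the closed form", {
  # nu = 1, dx = kBT, unit loading rate: mode = ln(rate * tau0 * dx / kBT)
  p <- ds_params(dx_dagger = 4.11, tau0 = 50, dG_dagger = 100, nu = 1)
  cs <- constant_schedule(rate = 1, F_max = 30)
  rd <- rupture_density(p, cs, n_grid = 4001)
  expect_equal(rd$mode, log(50), tolerance = 1e-3)
})

test_that("quadrature agrees with the brute-force Euler survival oracle", {
  for (p in list(ds_na, ds_strong)) {
    rd <- rupture_density(p, default_sched, n_grid = 3001)
    oracle <- euler_survival(p, default_sched)
    expect_equal(rd$survival, oracle$survival[length(oracle$survival)],
                 tolerance = 1e-3)
    # CDF agreement at interior forces (trapezoid cumulative of the density)
    cdf <- fretforce:::cumtrapz(rd$density$force, rd$density$density)
    for (fq in c(5, 10, 20)) {
      S_o <- approx(oracle$force, oracle$survival, xout = fq)$y
      i <- which.min(abs(rd$density$force - fq))
      expect_lt(abs((1 - cdf[i]) - S_o), 2e-3)
    }
  }
})

test_that("sampler is deterministic and agrees with the quadrature CDF", {
  s1 <- sample_ruptures(ds_na, default_sched, 200, seed = 5)
  s2 <- sample_ruptures(ds_na, default_sched, 200, seed = 5)
  expect_identical(s1, s2)

  set.seed(31)
  for (i in 1:10) {
    p <- ds_params(runif(1, 3, 7), exp(runif(1, 1, 6)), runif(1, 5, 13))
    s <- sample_ruptures(p, default_sched, 2000,
                         seed = sample.int(1e6, 1))
    rd <- rupture_density(p, default_sched, n_grid = 4001)
    dx <- diff(rd$density$force[1:2])
    cdf_grid <- cumsum(rd$density$density) * dx
    total <- cdf_grid[length(cdf_grid)] + rd$survival
    cdf_fun <- approxfun(rd$density$force, cdf_grid / total,
                         yleft = 0, yright = cdf_grid[length(cdf_grid)] / total)
    # censored draws sit in the upper tail mass; KS applies to uncensored
    f_unc <- s$force[!s$censored]
    ks <- suppressWarnings(
      ks.test(f_unc, function(q) cdf_fun(q) / (1 - rd$survival / total)))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("mixture sampling respects the weights", {
  mix <- ds_mixture(list(ds_na, ds_strong), weights = c(0.7, 0.3))
  s <- sample_ruptures(mix, default_sched, 2000, seed = 12)
  frac <- mean(s$component == 1)
  expect_lt(abs(frac - 0.7), 3 * sqrt(0.21 / 2000))
})

test_that("reconstructed profiles reproduce the printed force-cluster peaks", {
  # forward-model consistency: each printed parameter triple, evaluated at
  # the protocol's nominal loading rate, peaks at the printed cluster force
  prof_na <- reconstruct_profile(ds_na, default_sched)
  expect_equal(prof_na$modal_force, 8, tolerance = 0.2)
  prof_strong <- reconstruct_profile(ds_strong, default_sched)
  expect_equal(prof_strong$modal_force, 16, tolerance = 0.2)
  prof_weak <- reconstruct_profile(ds_weak, default_sched)
  expect_equal(prof_weak$modal_force, 8, tolerance = 0.2)
  # reconstruction is internally consistent with rupture_density
  expect_equal(prof_na$modal_force, prof_na$density$mode)
  expect_true(all(prof_na$rate_curve$force < prof_na$critical_force))
})

test_that("mixture objects validate weights and components", {
  expect_error(ds_mixture(list(ds_na), weights = c(0.5)), "sum to 1")
  expect_error(ds_mixture(list(ds_na, "x")), "ds_params")
  expect_error(ds_params(-1, 1, 1), "positive")
  expect_error(ds_params(1, 1, 1, nu = 0.4), "nu")
})
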