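# Generators: determinism, ground-truth consistency, and agreement between
# generated data and the declared generative model.

test_that("generators are deterministic given a seed", {
  comp <- fret_components(c(0.7, 0.85))
  comp$weight <- c(0.5, 0.5)
  a <- sim_fret_population(20, comp, seed = 4)
  b <- sim_fret_population(20, comp, seed = 4)
  expect_identical(a, b)

  p1 <- sim_pulling_ensemble(counts = c(type_I = 3), seed = 4)
  p2 <- sim_pulling_ensemble(counts = c(type_I = 3), seed = 4)
  expect_identical(p1$cycles, p2$cycles)

  v1 <- sim_vectorial_traces(10, seed = 4)
  v2 <- sim_vectorial_traces(10, seed = 4)
  expect_identical(v1, v2)
})

test_that("noise-free intensity traces return the component centre exactly", {
  comp <- fret_components(0.75, sigma = 1e-12)
  comp$weight <- 1
  sim <- sim_fret_population(5, comp, shot_noise = FALSE, seed = 1)
  eff <- fret_efficiency(sim$traces)
  expect_equal(eff$E, rep(0.75, nrow(eff)), tolerance = 1e-9)
})

test_that("embedded corrections are undone by the matching correction spec", {
  comp <- fret_components(0.6, sigma = 1e-12)
  comp$weight <- 1
  corr <- correction_spec(donor_background = 40, acceptor_background = 70,
                          crosstalk = 0.08)
  sim <- sim_fret_population(5, comp, correction = corr, shot_noise = FALSE,
                             seed = 2)
  eff <- fret_efficiency(sim$traces, corr)
  # crosstalk is added in rounded counts; recovery is exact to < 1 count
  expect_equal(eff$E, rep(0.6, nrow(eff)), tolerance = 2e-3)
})

test_that("photobleached frames fall to background and are flagged invalid", {
  comp <- fret_components(0.75, sigma = 1e-12)
  comp$weight <- 1
  sim <- sim_fret_population(40, comp, frames = 100, bleach_rate = 1,
                             frame_interval = 0.03, seed = 6)
  expect_true(any(sim$truth$bleach_frame <= 100, na.rm = TRUE))
  m <- sim$truth$molecule_id[which(sim$truth$bleach_frame <= 50)[1]]
  tr <- sim$traces[sim$traces$molecule_id == m, ]
  bf <- sim$truth$bleach_frame[sim$truth$molecule_id == m]
  expect_true(all(tr$donor[tr$frame >= bf] == 0))
  expect_true(all(tr$acceptor[tr$frame >= bf] == 0))
})

test_that("exact archetype counts are honoured and ultrastable never ruptures", {
  ens <- sim_pulling_ensemble(
    counts = c(complete = 7, type_I = 5, ultrastable = 4),
    cycles_per_molecule = 2, seed = 13)
  tab <- table(ens$truth$label)
  expect_equal(tab[["complete"]], 7L)
  expect_equal(tab[["type_I"]], 5L)
  expect_equal(tab[["ultrastable"]], 4L)
  ultra <- ens$truth[ens$truth$label == "ultrastable", ]
  expect_true(all(is.na(ultra$f_unfold)))
})

test_that("pre-noise pulling efficiencies lie on the archetype curve", {
  archs <- default_archetypes()
  ens <- sim_pulling_ensemble(archetypes = archs, counts = c(type_II = 3),
                              sigma_E = 0, seed = 19)
  eff <- fret_efficiency(ens$cycles)
  expected <- archs$type_II$E_of_force(eff$force_pN)
  # counts quantize E at 1/total_intensity
  expect_lt(max(abs(eff$E - expected)), 2.5e-3)
})

test_that("generated rupture forces follow the Dudko-Szabo distribution", {
  truth <- ds_params(6.6, 30, 7)
  archs <- default_archetypes(rupture = truth)
  ens <- sim_pulling_ensemble(archetypes = archs, counts = c(complete = 400),
                              cycles_per_molecule = 1, seed = 23)
  f_rup <- ens$truth$f_unfold[!is.na(ens$truth$f_unfold)]
  rd <- rupture_density(truth, default_sched, n_grid = 4001)
  dx <- diff(rd$density$force[1:2])
  cdf_grid <- cumsum(rd$density$density) * dx
  mass <- cdf_grid[length(cdf_grid)]
  cdf_fun <- approxfun(rd$density$force, cdf_grid / mass, yleft = 0,
                       yright = 1)
  ks <- suppressWarnings(ks.test(f_rup, cdf_fun))
  expect_gt(ks$p.value, 0.01)
})

test_that("refolding forces fall in the configured window", {
  ens <- sim_pulling_ensemble(counts = c(complete = 50),
                              cycles_per_molecule = 1, seed = 27)
  fr <- ens$truth$f_refold[!is.na(ens$truth$f_refold)]
  expect_gt(length(fr), 0)
  expect_true(all(fr >= 1 & fr <= 7))
})

test_that("vectorial generator handles n = 0 and emits matched truth", {
  empty <- sim_vectorial_traces(0)
  expect_equal(nrow(empty$traces), 0L)
  expect_equal(nrow(empty$truth), 0L)

  sim <- sim_vectorial_traces(25, seed = 3)
  expect_setequal(unique(sim$traces$molecule_id), sim$truth$molecule_id)
})
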