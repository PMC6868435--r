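# Pulling-cycle segmentation, rupture detection, class assignment,
# switching statistics and ensemble force-response curves.

test_that("cycles are segmented into alternating stretch/relax halves", {
  ens <- sim_pulling_ensemble(counts = c(type_I = 4),
                              cycles_per_molecule = 4, seed = 2)
  seg <- segment_cycles(fret_efficiency(ens$cycles))
  halves <- seg |>
    dplyr::distinct(.data$molecule_id, .data$cycle, .data$phase)
  expect_equal(nrow(halves), 8L)
  expect_setequal(unique(seg$phase), c("stretch", "relax"))
  # boundary agrees with the generator's direction flag within one sample
  mism <- sum(seg$phase != seg$direction)
  expect_lte(mism, 4L)
})

test_that("truncated final relax halves are flagged partial", {
  ens <- sim_pulling_ensemble(counts = c(type_I = 1), seed = 3)
  cyc <- ens$cycles
  n <- nrow(cyc)
  truncated <- cyc[1:(n - floor(n / 4)), ]
  seg <- segment_cycles(fret_efficiency(truncated))
  expect_true(all(seg$partial))
  full <- segment_cycles(fret_efficiency(cyc))
  expect_false(any(full$partial))
})

test_that("non-alternating stage motion is rejected", {
  bad <- tibble::tibble(
    molecule_id = "m", cycle = 1, t_s = seq(0, 0.18, by = 0.02),
    stage_nm = c(1, 2, 3, 2, 3, 4, 3, 2, 1, 0) * 100 + 14000,
    donor = 100, acceptor = 100)
  expect_error(segment_cycles(bad), "Non-alternating")
})

test_that("an abrupt drop yields one unfold event at the midpoint force", {
  drop_at <- function(f_rup, E_hi = 0.80, E_lo = 0.08) {
    function(f) ifelse(f < f_rup, E_hi, E_lo)
  }
  half <- make_stretch_half(drop_at(7))
  ev <- detect_ruptures(half)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$kind, "unfold")
  expect_equal(ev$force, 7, tolerance = 0.03)
  expect_lt(abs(ev$E_before - 0.80), 0.05)
  expect_lt(abs(ev$E_after - 0.08), 0.05)
})

test_that("gradual unraveling produces no abrupt events", {
  grad <- make_stretch_half(function(f) 0.75 - 0.5 * (f / 28))
  expect_equal(nrow(detect_ruptures(grad)), 0L)
})

test_that("two abrupt drops are both found; the larger drop sets f_unfold", {
  two_step <- make_stretch_half(function(f) {
    ifelse(f < 5, 0.9, ifelse(f < 15, 0.55, 0.05))
  })
  ev <- detect_ruptures(two_step)
  expect_equal(nrow(ev), 2L)
  expect_true(all(diff(ev$force) > 0))
  lab <- classify_cycles(two_step, events = ev)
  # second drop is larger (0.55 -> 0.05); it defines the cycle's f_unfold
  expect_equal(lab$f_unfold, 15, tolerance = 0.05)
  expect_equal(lab$n_events, 2L)
})

test_that("noiseless archetypes classify exactly (identity confusion)", {
  archs <- default_archetypes()
  ens <- sim_pulling_ensemble(
    archetypes = archs,
    counts = c(complete = 5, type_I = 5, type_II = 5, ultrastable = 5),
    cycles_per_molecule = 1, sigma_E = 0, seed = 6)
  seg <- segment_cycles(fret_efficiency(ens$cycles))
  lab <- classify_cycles(seg)
  merged <- dplyr::inner_join(lab, ens$truth, by = c("molecule_id", "cycle"))
  truth_as_class <- ifelse(merged$label.y == "ultrastable", "no_unfolding",
                           merged$label.y)
  expect_equal(merged$label.x, truth_as_class)
})

test_that("263 noisy cycles recover the printed class fractions", {
  ens <- sim_pulling_ensemble(
    counts = c(complete = 58, type_I = 150, type_II = 55),
    cycles_per_molecule = 263, sigma_E = 0.03, seed = 11)
  seg <- segment_cycles(fret_efficiency(ens$cycles))
  lab <- classify_cycles(seg)
  frac <- table(lab$label) / nrow(lab)
  expect_equal(nrow(lab), 263L)
  expect_lt(abs(frac[["complete"]] - 58 / 263), 0.02)
  expect_lt(abs(frac[["type_I"]] - 150 / 263), 0.02)
  expect_lt(abs(frac[["type_II"]] - 55 / 263), 0.02)
})

test_that("switching statistics count ordered consecutive pairs", {
  lab <- tibble::tibble(
    molecule_id = "m", cycle = 1:4,
    label = c("complete", "type_I", "type_I", "complete"))
  st <- switching_stats(lab)
  expect_equal(st$matrix["complete", "type_I"], 1L)
  expect_equal(st$matrix["type_I", "type_I"], 1L)
  expect_equal(st$matrix["type_I", "complete"], 1L)
  expect_equal(sum(st$matrix), 3L)

  same <- tibble::tibble(molecule_id = "m", cycle = 1:5, label = "type_I")
  st2 <- switching_stats(same)
  expect_equal(st2$conditional$switch_fraction, 0)
})

test_that("a generated switching matrix is recovered from labels", {
  M <- matrix(c(0.7, 0.3, 0.2, 0.8), 2, 2, byrow = TRUE,
              dimnames = list(c("complete", "type_I"),
                              c("complete", "type_I")))
  ens <- sim_pulling_ensemble(
    weights = c(complete = 0.5, type_I = 0.5), switching = M,
    cycles_per_molecule = 10, n_molecules = 40, sigma_E = 0.02, seed = 14)
  seg <- segment_cycles(fret_efficiency(ens$cycles))
  lab <- classify_cycles(seg)
  st <- switching_stats(lab)
  for (from in rownames(M)) {
    n_from <- st$conditional$n_pairs[st$conditional$from == from]
    p_hat <- st$conditional$switch_fraction[st$conditional$from == from]
    p_true <- 1 - M[from, from]
    expect_lt(abs(p_hat - p_true),
              2 * sqrt(p_true * (1 - p_true) / n_from) + 0.02)
  }
})

test_that("binned mean E follows the archetype and SE shrinks with n", {
  archs <- default_archetypes()
  ens <- sim_pulling_ensemble(archetypes = archs, counts = c(type_I = 10),
                              cycles_per_molecule = 1, sigma_E = 0,
                              seed = 9)
  seg <- segment_cycles(fret_efficiency(ens$cycles))
  lab <- classify_cycles(seg)
  curve <- mean_E_vs_force(seg, lab, bin_width = 1)
  arch_E <- archs$type_I$E_of_force(curve$force_bin)
  expect_lt(max(abs(curve$mean_E - arch_E)), 0.02)

  noisy_small <- sim_pulling_ensemble(archetypes = archs,
                                      counts = c(type_I = 5),
                                      cycles_per_molecule = 1,
                                      sigma_E = 0.05, seed = 10)
  noisy_big <- sim_pulling_ensemble(archetypes = archs,
                                    counts = c(type_I = 20),
                                    cycles_per_molecule = 1,
                                    sigma_E = 0.05, seed = 10)
  se_of <- function(ens) {
    seg <- segment_cycles(fret_efficiency(ens$cycles))
    lab <- classify_cycles(seg)
    curve <- mean_E_vs_force(seg, lab, bin_width = 2)
    median(curve$se, na.rm = TRUE)
  }
  # quadrupling the cycle count halves the standard error, roughly
  ratio <- se_of(noisy_small) / se_of(noisy_big)
  expect_gt(ratio, 1.4)
  expect_lt(ratio, 2.9)
})

test_that("rupture-force table carries censored ultrastable cycles", {
  lab <- tibble::tibble(
    molecule_id = "m", cycle = 1:6,
    label = c("complete", "complete", "no_unfolding", "no_unfolding",
              "no_unfolding", "type_I"),
    f_unfold = c(7.2, 16.5, NA, NA, NA, NA))
  tab <- rupture_force_table(lab, classes = "complete", F_max = 28)
  expect_equal(sum(!tab$censored), 2L)
  expect_equal(sum(tab$censored), 3L)
  expect_equal(tab$force[tab$censored], rep(28, 3))
})

test_that("end-to-end: simulated complete-class ruptures refit their kinetics", {
  truth <- ds_params(dx_dagger = 6.6, tau0 = 30, dG_dagger = 7)
  archs <- default_archetypes(rupture = truth)
  ens <- sim_pulling_ensemble(archetypes = archs,
                              counts = c(complete = 250),
                              cycles_per_molecule = 1, sigma_E = 0.03,
                              seed = 21)
  seg <- segment_cycles(fret_efficiency(ens$cycles))
  lab <- classify_cycles(seg)
  tab <- rupture_force_table(lab, classes = "complete", F_max = 28)
  # extracted forces agree with the generator's ground truth
  merged <- dplyr::inner_join(
    lab[!is.na(lab$f_unfold), c("molecule_id", "cycle", "f_unfold")],
    ens$truth, by = c("molecule_id", "cycle"))
  expect_lt(median(abs(merged$f_unfold.x - merged$f_unfold.y)), 0.15)
  fit <- fit_ds(tab, default_sched, n_components = 1, starts = 8, seed = 22)
  td <- tidy(fit)
  expect_lt(abs(td$estimate[td$term == "dx_dagger"] - 6.6) / 6.6, 0.15)
})
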