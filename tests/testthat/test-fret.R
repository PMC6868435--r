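# Zero-force smFRET pipeline: corrections, summaries, histograms, and the
# fixed-component mixture decomposition.

test_that("efficiency arithmetic: symmetry, zero-acceptor, corrections", {
  tr <- tibble::tibble(molecule_id = "m", frame = 1:3,
                       donor = c(50, 100, 320),
                       acceptor = c(50, 0, 700))
  raw <- fret_efficiency(tr)
  expect_equal(raw$E[1], 0.5)
  expect_equal(raw$E[2], 0)
  # corrected: I_D' = 300, I_A' = 700 - 50 - 0.1*300 = 620, E = 620/920
  corr <- fret_efficiency(tr, correction_spec(20, 50, 0.1))
  expect_equal(corr$E[3], 620 / 920)
  # with zero corrections the raw ratio is returned exactly
  expect_equal(raw$E, tr$acceptor / (tr$acceptor + tr$donor))
})

test_that("invalid frames are flagged and all-invalid traces error", {
  tr <- tibble::tibble(molecule_id = "m", frame = 1:2,
                       donor = c(10, 100), acceptor = c(5, 100))
  out <- fret_efficiency(tr, correction_spec(10, 5, 0))
  expect_false(out$valid[1])
  expect_true(out$valid[2])
  all_dead <- tibble::tibble(molecule_id = "m", frame = 1, donor = 2,
                             acceptor = 2)
  expect_error(fret_efficiency(all_dead, correction_spec(5, 5, 0)),
               "invalid")
  neg <- tibble::tibble(molecule_id = "m", frame = 1, donor = -1,
                        acceptor = 5)
  expect_error(fret_efficiency(neg), ">= 0")
})

test_that("molecule summaries use only the first ten valid frames", {
  tr <- tibble::tibble(
    molecule_id = "m", frame = 1:30,
    E = c(rep(0.8, 10), rep(0.1, 20)), valid = TRUE)
  s <- summarize_molecules(tr)
  expect_equal(s$E_mean, 0.8)
  expect_equal(s$n_frames_used, 10L)

  short <- tibble::tibble(molecule_id = "m", frame = 1:6, E = 0.6,
                          valid = TRUE)
  s2 <- summarize_molecules(short)
  expect_equal(s2$E_mean, 0.6)
  expect_equal(s2$n_frames_used, 6L)
})

test_that("donor-only exclusion removes the zero peak and nothing else", {
  s <- tibble::tibble(molecule_id = c("a", "b", "c"),
                      E_mean = c(0.02, 0.05, 0.75))
  out <- suppressMessages(exclude_donor_only(s))
  expect_equal(out$E_mean, 0.75)
  expect_equal(attr(out, "n_removed"), 2L)
  ident <- suppressMessages(exclude_donor_only(s, threshold = 0))
  expect_equal(nrow(ident), 3L)

  # binomial property: with a 20% donor-only fraction ~80% are retained
  comp <- fret_components(0.75, 0.05, "folded")
  comp$weight <- 0.8
  sim <- sim_fret_population(1000, comp, donor_only_fraction = 0.2,
                             seed = 21)
  summ <- summarize_molecules(fret_efficiency(sim$traces))
  kept <- suppressMessages(exclude_donor_only(summ))
  expect_lt(abs(nrow(kept) / 1000 - 0.8), 2 * sqrt(0.16 / 1000) + 0.01)
})

test_that("histogram counts are conserved and match direct binning", {
  comp <- fret_components(c(0.66, 0.75, 0.85))
  comp$weight <- c(0.2, 0.5, 0.3)
  sim <- sim_fret_population(300, comp, seed = 11)
  summ <- summarize_molecules(fret_efficiency(sim$traces))
  h <- build_histogram(summ)
  expect_equal(sum(h$count), nrow(summ))
  # independent binning oracle
  oracle <- table(cut(summ$E_mean, breaks = seq(-0.1, 1.2, by = 0.02),
                      right = FALSE))
  expect_equal(h$count, as.integer(oracle))
  # conservation holds for any bin width
  expect_equal(sum(build_histogram(summ, bin_width = 0.07)$count),
               nrow(summ))
})

test_that("variant calibration recovers the folded-peak centre and width", {
  comp <- fret_components(0.71, 0.05, "hTel28.1")
  comp$weight <- 1
  sim <- sim_fret_population(300, comp, seed = 8)
  summ <- summarize_molecules(fret_efficiency(sim$traces))
  summ$construct <- "hTel28.1"
  cal <- calibrate_components(summ)
  expect_equal(cal$center, 0.71, tolerance = 0.03)
  expect_equal(cal$sigma, 0.05, tolerance = 0.25)
  expect_equal(nrow(cal), 1L)

  two <- dplyr::bind_rows(summ, dplyr::mutate(summ, construct = "hTel28.5",
                                              E_mean = E_mean - 0.09))
  expect_equal(nrow(calibrate_components(two)), 2L)
  expect_error(calibrate_components(summ[1:5, ]), "Insufficient")
})

test_that("mixture decomposition: degenerate input, identifiability, anchors", {
  comp <- fret_components(c(0.66, 0.75, 0.85), 0.05)
  # all molecules from the middle component
  set.seed(2)
  pure <- tibble::tibble(molecule_id = as.character(1:150),
                         E_mean = rnorm(150, 0.75, 0.05))
  fit <- suppressWarnings(decompose_mixture(pure, comp))
  expect_gt(fit$weights[2], 0.9)
  dup <- comp
  dup$center <- c(0.7, 0.7, 0.85)
  expect_error(decompose_mixture(pure, dup), "distinct")
  expect_error(decompose_mixture(pure[0, ], comp), "empty")
})

test_that("three-subpopulation proportions are recovered within 2 SE", {
  comp <- fret_components(c(0.66, 0.75, 0.85), 0.05,
                          c("five_prime_GQ", "three_prime_GQ",
                            "long_loop_GQ"))
  comp$weight <- c(0.185, 0.64, 0.175)
  sim <- sim_fret_population(200, comp, seed = 3)
  summ <- summarize_molecules(fret_efficiency(sim$traces))
  fit <- decompose_mixture(summ, comp)
  td <- tidy(fit)
  expect_lt(abs(td$weight[2] - 0.64), 2 * td$std.error[2])
  expect_equal(sum(fit$hard_counts), 200L)
  # EM log-likelihood is monotone non-decreasing
  expect_true(all(diff(fit$logLik_trace) >= -1e-10))
})

test_that("transition detector separates steps from blinks", {
  set.seed(5)
  flat <- 0.75 + rnorm(300, 0, 0.05)
  expect_equal(nrow(detect_E_transitions(flat)), 0L)

  step <- c(rep(0.75, 99), rep(0.3, 101)) + rnorm(200, 0, 0.02)
  tr <- detect_E_transitions(step)
  expect_equal(nrow(tr), 1L)
  expect_lt(abs(tr$frame - 100), 4)

  blink <- rep(0.75, 200)
  blink[100:101] <- 0.1
  expect_equal(nrow(detect_E_transitions(blink)), 0L)
})
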