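# Synthetic-data generators. Each generator emulates the statistical
# structure of one assay (TIRF intensity traces at 30 ms/frame, stage-driven
# pulling cycles at 20 ms/sample, real-time vectorial folding traces) and
# emits machine-readable ground truth alongside the data, so that every
# analysis stage can be validated by round-trip at matched noise.

# Partition a total intensity into donor/acceptor counts given a true
# efficiency, with Poisson photon noise, constant backgrounds, and donor
# crosstalk into the acceptor channel.
emit_counts <- function(E_true, total_intensity, correction,
                        shot_noise = TRUE) {
  n <- length(E_true)
  if (shot_noise) {
    a_true <- rpois(n, total_intensity * pmin(pmax(E_true, 0), 1))
    d_true <- rpois(n, total_intensity * pmin(pmax(1 - E_true, 0), 1))
  } else {
    a_true <- total_intensity * pmin(pmax(E_true, 0), 1)
    d_true <- total_intensity * pmin(pmax(1 - E_true, 0), 1)
  }
  donor <- d_true + correction$donor_background
  acceptor <- a_true + correction$acceptor_background +
    round(correction$crosstalk * d_true)
  list(donor = donor, acceptor = acceptor)
}

#' Simulate zero-force TIRF intensity traces of a mixed population
#'
#' Each molecule draws a subpopulation by weight (or is donor-only), takes a
#' molecule-level true efficiency from the component's Gaussian, and emits
#' per-frame donor/acceptor photon counts with Poisson shot noise, constant
#' backgrounds, donor-to-acceptor crosstalk and an optional exponential
#' photobleaching time after which both channels fall to background.
#'
#' @param n_molecules Number of molecules.
#' @param components A [fret_components()] tibble with an additional `weight`
#'   column (weights plus `donor_only_fraction` must sum to 1).
#' @param donor_only_fraction Fraction of molecules with an inactive
#'   acceptor (E near 0).
#' @param frames Frames per trace.
#' @param frame_interval Frame time, s.
#' @param total_intensity Expected total photons per frame.
#' @param bleach_rate Photobleaching rate, 1/s (0 disables bleaching).
#' @param correction Embedded [correction_spec()] (backgrounds, crosstalk).
#' @param shot_noise When FALSE the intensity partition is deterministic
#'   (no Poisson noise), so the emitted efficiency is exactly the molecule's
#'   true value; useful for exact round-trip checks.
#' @param seed Optional integer seed.
#' @return A list with `traces` (tibble: `molecule_id`, `frame`, `donor`,
#'   `acceptor`), `truth` (tibble: `molecule_id`, `component`, `label`,
#'   `E_true`, `bleach_frame`), and the `correction` used.
#' @export
sim_fret_population <- function(n_molecules,
                                components = fret_components(
                                  center = c(0.66, 0.75, 0.85),
                                  sigma = 0.05,
                                  label = c("five_prime_GQ", "three_prime_GQ",
                                            "long_loop_GQ")),
                                donor_only_fraction = 0,
                                frames = 50,
                                frame_interval = 0.03,
                                total_intensity = 500,
                                bleach_rate = 0,
                                correction = correction_spec(),
                                shot_noise = TRUE,
                                seed = NULL) {
  if (!"weight" %in% names(components)) {
    components$weight <- rep((1 - donor_only_fraction) / nrow(components),
                             nrow(components))
  }
  if (abs(sum(components$weight) + donor_only_fraction - 1) > 1e-9) {
    abort("Component weights plus `donor_only_fraction` must sum to 1.")
  }
  with_seed(seed, {
    K <- nrow(components)
    comp <- sample.int(K + 1L, n_molecules, replace = TRUE,
                       prob = c(components$weight, donor_only_fraction))
    E_mol <- ifelse(
      comp <= K,
      rnorm(n_molecules, components$center[pmin(comp, K)],
            components$sigma[pmin(comp, K)]),
      rnorm(n_molecules, 0.02, 0.01)
    )
    E_mol <- pmin(pmax(E_mol, 0), 1)
    bleach_frame <- if (bleach_rate > 0) {
      pmax(1L, ceiling(rexp(n_molecules, bleach_rate) / frame_interval))
    } else {
      rep(NA_integer_, n_molecules)
    }
    ids <- sprintf("mol_%04d", seq_len(n_molecules))
    traces <- purrr::map_dfr(seq_len(n_molecules), function(i) {
      E_frames <- rep(E_mol[i], frames)
      if (!is.na(bleach_frame[i]) && bleach_frame[i] <= frames) {
        E_frames[bleach_frame[i]:frames] <- NA
      }
      live <- !is.na(E_frames)
      counts <- emit_counts(E_frames[live], total_intensity, correction,
                            shot_noise)
      donor <- rep(correction$donor_background, frames)
      acceptor <- rep(correction$acceptor_background, frames)
      donor[live] <- counts$donor
      acceptor[live] <- counts$acceptor
      tibble::tibble(molecule_id = ids[i], frame = seq_len(frames),
                     donor = donor, acceptor = acceptor)
    })
    truth <- tibble::tibble(
      molecule_id = ids,
      component = ifelse(comp <= K, comp, NA_integer_),
      label = ifelse(comp <= K, components$label[pmin(comp, K)], "donor_only"),
      E_true = E_mol,
      bleach_frame = bleach_frame
    )
    list(traces = traces, truth = truth, correction = correction)
  })
}

#' Archetype efficiency-versus-force curve
#'
#' The generative description of one mechanical class: monotone anchor points
#' interpolated by a monotone cubic spline, optionally an abrupt rupture
#' drawn from a Dudko-Szabo hazard (after which the trace follows a
#' post-rupture single-stranded baseline), and a flat pre-anchor level.
#'
#' @param label Class label.
#' @param anchors A tibble/data frame with `force` (pN, increasing) and `E`.
#' @param rupture A [ds_params()] for rupture-bearing archetypes, or NULL.
#' @param post_rupture_E Post-rupture baseline efficiency at the rupture
#'   force; it declines gently with further force.
#' @return An object of class `archetype_curve`.
#' @export
archetype_curve <- function(label, anchors, rupture = NULL,
                            post_rupture_E = 0.10) {
  anchors <- tibble::as_tibble(anchors)
  if (is.unsorted(anchors$force, strictly = TRUE)) {
    abort("Anchor forces must be strictly increasing.")
  }
  if (any(anchors$E < 0 | anchors$E > 1)) abort("Anchor E must lie in [0, 1].")
  if (!is.null(rupture) && !inherits(rupture, "ds_params")) {
    abort(sprintf("Archetype '%s': `rupture` must be a ds_params or NULL.",
                  label))
  }
  interp <- if (nrow(anchors) > 1) {
    splinefun(anchors$force, anchors$E, method = "monoH.FC")
  } else {
    function(f) rep_len(anchors$E[1], length(f))
  }
  structure(
    list(label = label, anchors = anchors, rupture = rupture,
         post_rupture_E = post_rupture_E,
         E_of_force = function(f) {
           interp(pmin(pmax(f, anchors$force[1]),
                       anchors$force[nrow(anchors)]))
         }),
    class = "archetype_curve"
  )
}

#' Default archetype set for five-repeat telomeric constructs
#'
#' Anchors follow the printed endpoint values of each mechanical class:
#' `complete` holds E ~ 0.80 until an abrupt Dudko-Szabo rupture to a
#' single-stranded baseline near 0.10; `type_I` declines gradually from 0.75
#' at 2 pN to 0.25 at 28 pN; `type_II` from 0.68 to 0.37; `ultrastable`
#' stays high throughout; `hTel28_1` declines from 0.72 at 2 pN to 0.25 at
#' 8 pN and stays flat.
#'
#' @param rupture [ds_params()] used by the `complete` archetype.
#' @return A named list of [archetype_curve()] objects.
#' @export
default_archetypes <- function(rupture = ds_params(4.3, 50, 6.5)) {
  list(
    complete = archetype_curve(
      "complete", tibble::tibble(force = c(0, 28), E = c(0.80, 0.80)),
      rupture = rupture),
    type_I = archetype_curve(
      "type_I", tibble::tibble(force = c(0, 2, 28), E = c(0.75, 0.75, 0.25))),
    type_II = archetype_curve(
      "type_II", tibble::tibble(force = c(0, 2, 28), E = c(0.68, 0.68, 0.37))),
    ultrastable = archetype_curve(
      "ultrastable", tibble::tibble(force = c(0, 28), E = c(0.75, 0.68))),
    hTel28_1 = archetype_curve(
      "hTel28_1",
      tibble::tibble(force = c(0, 2, 8, 28), E = c(0.72, 0.72, 0.25, 0.25)))
  )
}

#' Simulate an ensemble of pulling cycles
#'
#' Builds the force-versus-time trajectory from the tether model's loading
#' schedule (20 ms sampling), assigns each cycle an archetype either by exact
#' counts or by sampling weights (optionally evolved across a molecule's
#' consecutive cycles by a switching matrix), lays the archetype's
#' efficiency-force curve onto the ramp, draws rupture forces for
#' rupture-bearing archetypes from their Dudko-Szabo hazard under the
#' schedule, switches to the post-rupture single-stranded baseline at the
#' rupture, refolds on relaxation at a force drawn uniformly from
#' `refold_range`, adds Gaussian efficiency noise, and emits donor/acceptor
#' counts.
#'
#' @param archetypes Named list of [archetype_curve()]s.
#' @param counts Named integer vector of exact per-archetype cycle counts, or
#'   NULL to sample by `weights`.
#' @param weights Named sampling weights (used when `counts` is NULL).
#' @param switching Optional row-stochastic matrix over archetype names; when
#'   given, each molecule's first cycle draws from `weights` and later
#'   cycles follow the matrix.
#' @param cycles_per_molecule Pulling cycles per molecule.
#' @param n_molecules Number of molecules when sampling by `weights`
#'   (ignored when `counts` is given, where it follows from the pool size).
#' @param sigma_E Gaussian efficiency noise per sample.
#' @param model A [tether_model()].
#' @param stage_start,stage_end Stage ramp endpoints, nm.
#' @param sample_interval Sampling time, s.
#' @param total_intensity Expected total photons per sample.
#' @param refold_range Force window for abrupt refolding on relaxation, pN.
#' @param condition_on_rupture When TRUE (default), rupture-bearing
#'   archetypes draw their rupture force conditional on rupturing within the
#'   ramp, because a cycle carries such a label only when the rupture was
#'   observed; ultrastable cycles are represented by their own archetype.
#'   Set FALSE for unconditional draws (censored cycles then stay folded).
#' @param seed Optional integer seed.
#' @return A list with `cycles` (tibble: `molecule_id`, `cycle`, `t_s`,
#'   `stage_nm`, `force_pN`, `donor`, `acceptor`, `direction`), `truth`
#'   (tibble: per-cycle `label`, `f_unfold`, `f_refold`), and the `schedule`.
#' @export
sim_pulling_ensemble <- function(archetypes = default_archetypes(),
                                 counts = NULL,
                                 weights = NULL,
                                 switching = NULL,
                                 cycles_per_molecule = 1,
                                 n_molecules = 20,
                                 sigma_E = 0.03,
                                 model = tether_model(),
                                 stage_start = 14000,
                                 stage_end = 16960,
                                 sample_interval = 0.02,
                                 total_intensity = 500,
                                 refold_range = c(1, 7),
                                 condition_on_rupture = TRUE,
                                 seed = NULL) {
  sched <- loading_schedule(model, stage_start, stage_end)
  tt <- seq(0, sched$duration, by = sample_interval)
  stage_up <- stage_start + model$stage_speed * tt
  f_up <- sched$force_of_time(tt)
  n_up <- length(tt)
  # relax half retraces the ramp; drop the duplicated turnaround sample
  f_down <- rev(f_up)[-1]
  stage_down <- rev(stage_up)[-1]
  t_cycle <- c(tt, sched$duration + tt[-1])
  direction <- c(rep("stretch", n_up), rep("relax", n_up - 1L))

  names_arch <- names(archetypes)
  rupture_tabs <- lapply(archetypes, function(a) {
    if (is.null(a$rupture)) return(NULL)
    ds_hazard_table(a$rupture, sched, KBT_DEFAULT, 2001)
  })

  with_seed(seed, {
    if (!is.null(counts)) {
      if (is.null(names(counts)) || !all(names(counts) %in% names_arch)) {
        abort("`counts` must be named after archetypes.")
      }
      pool <- rep(names(counts), counts)
      label_pool <- pool[sample.int(length(pool))]
      n_molecules <- ceiling(length(label_pool) / cycles_per_molecule)
    } else {
      weights <- weights %||%
        stats::setNames(rep(1 / length(archetypes), length(archetypes)),
                        names_arch)
      label_pool <- NULL
    }

    assign_label <- local({
      k <- 0L
      function(prev) {
        if (!is.null(label_pool)) {
          k <<- k + 1L
          return(label_pool[min(k, length(label_pool))])
        }
        if (!is.null(switching) && !is.null(prev)) {
          return(sample(colnames(switching), 1,
                        prob = switching[prev, ]))
        }
        sample(names(weights), 1, prob = weights)
      }
    })

    rows <- list()
    truth <- list()
    cyc_global <- 0L
    for (m in seq_len(n_molecules)) {
      mol_id <- sprintf("mol_%04d", m)
      prev <- NULL
      for (cy in seq_len(cycles_per_molecule)) {
        cyc_global <- cyc_global + 1L
        if (!is.null(label_pool) && cyc_global > length(label_pool)) break
        lab <- assign_label(prev)
        prev <- lab
        arch <- archetypes[[lab]]
        E_up <- arch$E_of_force(f_up)
        E_down <- arch$E_of_force(f_down)
        f_unfold <- NA_real_
        f_refold <- NA_real_
        if (!is.null(arch$rupture)) {
          tab <- rupture_tabs[[lab]]
          # a cycle carrying a rupture-bearing label is one that showed the
          # rupture, so the draw is conditioned on rupture within the ramp
          # unless the caller asks for unconditional draws
          u <- if (condition_on_rupture) {
            runif(1, min = tab$S_end + 1e-12, max = 1)
          } else {
            runif(1)
          }
          surv <- exp(-tab$Lambda)
          if (u > tab$S_end) {
            f_unfold <- approx(rev(surv), rev(tab$grid), xout = u,
                               ties = "ordered")$y
            post <- pmax(0.02, arch$post_rupture_E -
                           0.002 * (f_up - f_unfold))
            E_up <- ifelse(f_up >= f_unfold, post, E_up)
            f_refold <- runif(1, refold_range[1], refold_range[2])
            post_d <- pmax(0.02, arch$post_rupture_E -
                             0.002 * (f_down - f_refold))
            E_down <- ifelse(f_down > f_refold, post_d, E_down)
          }
        }
        E_all <- pmin(pmax(c(E_up, E_down) + rnorm(2 * n_up - 1, 0, sigma_E),
                           0), 1)
        counts_dc <- list(
          donor = pmax(0, round(total_intensity * (1 - E_all))),
          acceptor = pmax(0, round(total_intensity * E_all))
        )
        rows[[cyc_global]] <- tibble::tibble(
          molecule_id = mol_id,
          cycle = cy,
          t_s = t_cycle,
          stage_nm = c(stage_up, stage_down),
          force_pN = c(f_up, f_down),
          donor = counts_dc$donor,
          acceptor = counts_dc$acceptor,
          direction = direction
        )
        truth[[cyc_global]] <- tibble::tibble(
          molecule_id = mol_id, cycle = cy, label = lab,
          f_unfold = f_unfold, f_refold = f_refold
        )
      }
    }
    list(cycles = dplyr::bind_rows(rows), truth = dplyr::bind_rows(truth),
         schedule = sched)
  })
}

#' Simulate real-time vectorial folding traces
#'
#' Each trace starts at the duplex baseline; after an exponential waiting
#' time the unwinding front releases the G-rich strand and the efficiency
#' rises monotonically to the class's terminal level. The drawn rise
#' duration parameterises the ramp so that the measurable rise time (first
#' departure from the baseline band to first entry into the terminal band)
#' equals the drawn value. `not_unwound` traces stay at baseline.
#'
#' @param n Number of molecules.
#' @param fractions Named class fractions over `direct_3prime`, `five_prime`,
#'   `unfolded_ssDNA`, `not_unwound` (must sum to 1). Names not present get 0.
#' @param baseline_E Duplex baseline efficiency.
#' @param terminal_E Named terminal efficiencies per class.
#' @param rise_mean,rise_sd Rise-duration distribution (s), truncated at
#'   0.2 s.
#' @param wait_mean Mean waiting time before unwinding starts, s.
#' @param sigma_E Gaussian efficiency noise per frame.
#' @param frames Frames per trace.
#' @param frame_interval Frame time, s.
#' @param total_intensity Expected total photons per frame.
#' @param correction Embedded [correction_spec()].
#' @param seed Optional integer seed.
#' @return A list with `traces` (counts tibble) and `truth` (per-molecule
#'   `label`, `rise_duration`, `terminal_E`).
#' @export
sim_vectorial_traces <- function(n,
                                 fractions = c(direct_3prime = 0.64,
                                               five_prime = 0.22,
                                               unfolded_ssDNA = 0.14),
                                 baseline_E = 0.07,
                                 terminal_E = c(direct_3prime = 0.73,
                                                five_prime = 0.62,
                                                unfolded_ssDNA = 0.35,
                                                not_unwound = NA),
                                 rise_mean = 0.7,
                                 rise_sd = 0.1,
                                 wait_mean = 2,
                                 sigma_E = 0.05,
                                 frames = 300,
                                 frame_interval = 0.03,
                                 total_intensity = 500,
                                 correction = correction_spec(),
                                 seed = NULL) {
  if (n == 0) {
    return(list(
      traces = tibble::tibble(molecule_id = character(0), frame = integer(0),
                              donor = numeric(0), acceptor = numeric(0)),
      truth = tibble::tibble(molecule_id = character(0), label = character(0),
                             rise_duration = numeric(0),
                             terminal_E = numeric(0))
    ))
  }
  if (abs(sum(fractions) - 1) > 1e-9) abort("`fractions` must sum to 1.")
  with_seed(seed, {
    labels <- sample(names(fractions), n, replace = TRUE, prob = fractions)
    ids <- sprintf("mol_%04d", seq_len(n))
    t_frames <- (seq_len(frames) - 1L) * frame_interval
    traces <- vector("list", n)
    rise_all <- numeric(n)
    for (i in seq_len(n)) {
      lab <- labels[i]
      if (lab == "not_unwound") {
        E_true <- rep(baseline_E, frames)
        rise_all[i] <- NA_real_
      } else {
        term <- terminal_E[[lab]]
        rise <- max(0.2, rnorm(1, rise_mean, rise_sd))
        rise_all[i] <- rise
        t0 <- rexp(1, 1 / wait_mean)
        # slope chosen so that (baseline+0.1) -> (terminal-0.05) takes `rise`
        slope <- ((term - 0.05) - (baseline_E + 0.1)) / rise
        E_true <- pmin(term, pmax(baseline_E, baseline_E + slope *
                                    (t_frames - t0)))
      }
      E_noisy <- pmin(pmax(E_true + rnorm(frames, 0, sigma_E), 0), 1)
      counts <- emit_counts(E_noisy, total_intensity, correction)
      traces[[i]] <- tibble::tibble(molecule_id = ids[i],
                                    frame = seq_len(frames),
                                    donor = counts$donor,
                                    acceptor = counts$acceptor)
    }
    truth <- tibble::tibble(
      molecule_id = ids, label = labels, rise_duration = rise_all,
      terminal_E = unname(unlist(terminal_E[labels]))
    )
    list(traces = dplyr::bind_rows(traces), truth = truth)
  })
}
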