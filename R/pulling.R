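# Force-ramp trajectory analysis: segmentation of stretch/relax cycles,
# abrupt-rupture detection with midpoint force extraction, lowest-E
# classification into unfolding classes, switching statistics, and binned
# E-versus-force curves.

#' Segment a pulling trace into stretch and relax halves
#'
#' Boundaries are placed at sign changes of the stage velocity; each half must
#' be monotone in stage position. If a `direction` column is present it is
#' validated against the recomputed phases. A final half that ends before the
#' stage returns to its start is flagged partial.
#'
#' @param cycles A tibble with columns `molecule_id`, `cycle`, `t_s`,
#'   `stage_nm`, `force_pN`, and efficiency data (`E` or `donor`/`acceptor`).
#' @return The input with added columns `phase` (`"stretch"`/`"relax"`) and
#'   `partial` (logical, TRUE on truncated final halves).
#' @export
segment_cycles <- function(cycles) {
  need <- c("molecule_id", "cycle", "t_s", "stage_nm")
  missing_cols <- setdiff(need, names(cycles))
  if (length(missing_cols) > 0) {
    abort(sprintf("Missing required column(s): %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  out <- cycles |>
    dplyr::group_by(.data$molecule_id, .data$cycle) |>
    dplyr::group_modify(function(df, key) {
      if (is.unsorted(df$t_s, strictly = TRUE)) {
        abort(sprintf("Time is not strictly increasing for molecule %s.",
                      key$molecule_id))
      }
      v <- diff(df$stage_nm)
      phase <- c(ifelse(v >= 0, "stretch", "relax"), NA)
      phase[length(phase)] <- phase[length(phase) - 1L]
      runs <- rle(phase)
      if (length(runs$values) > 2L) {
        abort(sprintf(
          "Non-alternating stage direction within cycle %s of molecule %s.",
          key$cycle, key$molecule_id))
      }
      if (!identical(runs$values[1], "stretch")) {
        abort(sprintf(
          "Cycle %s of molecule %s does not begin with a stretch half.",
          key$cycle, key$molecule_id))
      }
      if ("direction" %in% names(df)) {
        # the sample at the turnaround is ambiguous by one position
        disagree <- sum(as.character(df$direction) != phase)
        if (disagree > 2L) {
          abort(sprintf(
            "`direction` flags disagree with stage motion in cycle %s of %s.",
            key$cycle, key$molecule_id))
        }
      }
      partial <- length(runs$values) < 2L ||
        df$stage_nm[nrow(df)] > df$stage_nm[1] + abs(v[1])
      df$phase <- phase
      df$partial <- partial
      df
    }) |>
    dplyr::ungroup()
  out
}

# Locate abrupt level changes in one half-cycle. The change must be complete
# within `max_span` samples, exceed `delta` between the pre- and post-levels
# (5-sample medians), and persist for `min_persist` samples.
detect_rupture_half <- function(E, force, kind, delta = 0.3, max_span = 3,
                                min_persist = 5) {
  n <- length(E)
  if (n < 10) abort("A half-cycle needs >= 10 samples.")
  med <- running_median(E, 3)
  events <- list()
  i <- min_persist + 1L
  while (i + max_span + min_persist - 1L <= n) {
    jump <- med[i + max_span] - med[i]
    if (abs(jump) >= delta) {
      e_before <- median(E[max(1, i - min_persist + 1L):i])
      post_idx <- (i + max_span):min(n, i + max_span + min_persist - 1L)
      e_after <- median(E[post_idx])
      if (abs(e_after - e_before) >= delta &&
          all(abs(E[post_idx] - e_before) >= delta / 2)) {
        midpoint <- (e_before + e_after) / 2
        seg <- i:(i + max_span)
        crossing <- if (e_after < e_before) {
          seg[which(E[seg] <= midpoint)[1]]
        } else {
          seg[which(E[seg] >= midpoint)[1]]
        }
        if (is.na(crossing)) crossing <- i + max_span
        events[[length(events) + 1L]] <- tibble::tibble(
          kind = kind,
          force = force[crossing],
          E_before = e_before,
          E_after = e_after,
          sample = crossing
        )
        i <- i + max_span + min_persist
        next
      }
    }
    i <- i + 1L
  }
  if (length(events) == 0) {
    return(tibble::tibble(kind = character(0), force = numeric(0),
                          E_before = numeric(0), E_after = numeric(0),
                          sample = integer(0)))
  }
  dplyr::bind_rows(events) |> dplyr::arrange(.data$force)
}

#' Detect abrupt rupture and refolding events
#'
#' Scans every stretch and relax half for abrupt efficiency transitions: a
#' change of at least `delta` (default 0.3) in the 3-sample running median,
#' completed within `max_span` samples (60 ms at 20 ms sampling) and
#' persisting for at least `min_persist` samples. The event force is the
#' force at the sample where E crosses the midpoint of the transition.
#' Stretch-half events are unfolding, relax-half events refolding. Gradual
#' (non-cooperative) unraveling produces no events.
#'
#' @param segmented Output of [segment_cycles()], with an `E` column (add one
#'   with [fret_efficiency()] if the trace holds raw counts).
#' @param delta Minimum level change in E units.
#' @param max_span Maximum number of samples the transition may take.
#' @param min_persist Minimum persistence of the new level, samples.
#' @return A tibble of events: `molecule_id`, `cycle`, `phase`, `kind`
#'   (`"unfold"`/`"refold"`), `force`, `E_before`, `E_after`.
#' @export
detect_ruptures <- function(segmented, delta = 0.3, max_span = 3,
                            min_persist = 5) {
  if (!"E" %in% names(segmented)) {
    abort("`segmented` needs an `E` column; compute it with fret_efficiency().")
  }
  segmented |>
    dplyr::group_by(.data$molecule_id, .data$cycle, .data$phase) |>
    dplyr::group_modify(function(df, key) {
      kind <- if (key$phase == "stretch") "unfold" else "refold"
      detect_rupture_half(df$E, df$force_pN, kind, delta, max_span,
                          min_persist)
    }) |>
    dplyr::ungroup()
}

#' Classify pulling cycles by the lowest efficiency reached
#'
#' Each analyzable stretch half is assigned to one of four classes from the
#' minimum of its 5-sample running-median efficiency: `complete`
#' (lowest E < 0.15 together with an abrupt rupture event), `type_I`
#' (0.15 <= lowest E < 0.30, gradual unraveling), `type_II`
#' (0.30 <= lowest E < 0.45) and `no_unfolding` (lowest E >= 0.45,
#' mechanically ultrastable). Cycles whose stretch half does not reach
#' `min_force_frac * F_max` are excluded with a warning. A sub-0.15 minimum
#' without an abrupt event is treated as gradual (`type_I`).
#'
#' @param segmented Output of [segment_cycles()] with an `E` column.
#' @param events Optional pre-computed [detect_ruptures()] output.
#' @param F_max Nominal peak force of the protocol, pN.
#' @param min_force_frac Fraction of `F_max` a stretch half must reach.
#' @param ... Passed to [detect_ruptures()] when `events` is NULL.
#' @return A tibble with one row per analyzable cycle: `molecule_id`,
#'   `cycle`, `label`, `lowest_E`, `f_unfold` (largest-|dE| abrupt unfolding
#'   event force, NA when none), `f_refold`, `n_events`.
#' @export
classify_cycles <- function(segmented, events = NULL, F_max = 28,
                            min_force_frac = 0.9, ...) {
  events <- events %||% detect_ruptures(segmented, ...)
  stretch <- segmented |> dplyr::filter(.data$phase == "stretch")
  labels <- stretch |>
    dplyr::group_by(.data$molecule_id, .data$cycle) |>
    dplyr::summarise(
      lowest_E = min(running_median(.data$E, 5)),
      peak_force = max(.data$force_pN),
      .groups = "drop"
    )
  reached <- labels$peak_force >= min_force_frac * F_max
  if (any(!reached)) {
    warn(sprintf("%d cycle(s) excluded: stretch half below %.2g pN.",
                 sum(!reached), min_force_frac * F_max))
  }
  labels <- labels[reached, , drop = FALSE]
  ev_unfold <- events |>
    dplyr::filter(.data$kind == "unfold") |>
    dplyr::group_by(.data$molecule_id, .data$cycle) |>
    dplyr::summarise(
      f_unfold = if (dplyr::n() == 0) NA_real_ else {
        .data$force[which.max(abs(.data$E_after - .data$E_before))]
      },
      n_unfold = dplyr::n(),
      .groups = "drop"
    )
  ev_refold <- events |>
    dplyr::filter(.data$kind == "refold") |>
    dplyr::group_by(.data$molecule_id, .data$cycle) |>
    dplyr::summarise(
      f_refold = if (dplyr::n() == 0) NA_real_ else {
        .data$force[which.max(abs(.data$E_after - .data$E_before))]
      },
      n_refold = dplyr::n(),
      .groups = "drop"
    )
  labels |>
    dplyr::left_join(ev_unfold, by = c("molecule_id", "cycle")) |>
    dplyr::left_join(ev_refold, by = c("molecule_id", "cycle")) |>
    dplyr::mutate(
      n_events = dplyr::coalesce(.data$n_unfold, 0L) +
        dplyr::coalesce(.data$n_refold, 0L),
      label = dplyr::case_when(
        .data$lowest_E < 0.15 & !is.na(.data$f_unfold) ~ "complete",
        .data$lowest_E < 0.30 ~ "type_I",
        .data$lowest_E < 0.45 ~ "type_II",
        TRUE ~ "no_unfolding"
      )
    ) |>
    dplyr::select("molecule_id", "cycle", "label", "lowest_E", "f_unfold",
                  "f_refold", "n_events")
}

#' Cycle-to-cycle switching statistics
#'
#' Counts ordered pairs of labels in consecutive cycles of the same molecule
#' and the conditional probability of switching away from each class.
#'
#' @param labels Output of [classify_cycles()].
#' @return A list of class `switching_stats`: `$pairs` (tibble of
#'   `from`, `to`, `count`), `$matrix` (contingency matrix), and
#'   `$conditional` (per-label `n_pairs` and `switch_fraction`).
#' @export
switching_stats <- function(labels) {
  pairs <- labels |>
    dplyr::arrange(.data$molecule_id, .data$cycle) |>
    dplyr::group_by(.data$molecule_id) |>
    dplyr::reframe(
      from = head(.data$label, -1),
      to = tail(.data$label, -1),
      consecutive = diff(.data$cycle) == 1
    ) |>
    dplyr::filter(.data$consecutive)
  if (nrow(pairs) == 0) {
    abort("Need at least one molecule with two consecutive cycles.")
  }
  lvls <- sort(unique(c(pairs$from, pairs$to)))
  counts <- pairs |>
    dplyr::count(.data$from, .data$to, name = "count")
  m <- matrix(0L, length(lvls), length(lvls), dimnames = list(lvls, lvls))
  m[cbind(match(counts$from, lvls), match(counts$to, lvls))] <- counts$count
  conditional <- counts |>
    dplyr::group_by(.data$from) |>
    dplyr::summarise(
      n_pairs = sum(.data$count),
      switch_fraction = sum(.data$count[.data$to != .data$from]) /
        sum(.data$count),
      .groups = "drop"
    )
  structure(list(pairs = counts, matrix = m, conditional = conditional),
            class = "switching_stats")
}

#' @export
print.switching_stats <- function(x, ...) {
  cat("<switching_stats>\n")
  print(x$matrix)
  print(x$conditional)
  invisible(x)
}

#' Ensemble-averaged efficiency versus force, per class
#'
#' Pools stretch-half samples of all cycles of each class into force bins and
#' reports the mean efficiency and its standard error per bin. Empty bins are
#' omitted; bins with a single sample have undefined SE (NA).
#'
#' @param segmented Output of [segment_cycles()] with an `E` column.
#' @param labels Output of [classify_cycles()].
#' @param bin_width Force bin width, pN.
#' @return A tibble: `label`, `force_bin` (centre, pN), `mean_E`, `se`, `n`.
#' @export
mean_E_vs_force <- function(segmented, labels, bin_width = 1) {
  segmented |>
    dplyr::filter(.data$phase == "stretch") |>
    dplyr::inner_join(labels[, c("molecule_id", "cycle", "label")],
                      by = c("molecule_id", "cycle")) |>
    dplyr::mutate(
      force_bin = (floor(.data$force_pN / bin_width) + 0.5) * bin_width
    ) |>
    dplyr::group_by(.data$label, .data$force_bin) |>
    dplyr::summarise(
      mean_E = mean(.data$E),
      se = if (dplyr::n() > 1) sd(.data$E) / sqrt(dplyr::n()) else NA_real_,
      n = dplyr::n(),
      .groups = "drop"
    )
}

#' Rupture-force table for kinetic fitting
#'
#' Collects the unfolding forces of cycles in the requested class(es) and
#' counts the censored cycles (high-efficiency cycles that reached the end of
#' the ramp without an abrupt rupture, i.e. the `no_unfolding` class), in the
#' form [fit_ds()] consumes.
#'
#' @param labels Output of [classify_cycles()].
#' @param classes Classes whose `f_unfold` values enter the table.
#' @param F_max Censoring force, pN.
#' @return A tibble with `force` and `censored`; censored rows carry `F_max`.
#' @export
rupture_force_table <- function(labels, classes = "complete", F_max = 28) {
  unc <- labels |>
    dplyr::filter(.data$label %in% classes, !is.na(.data$f_unfold))
  n_cens <- sum(labels$label == "no_unfolding")
  dplyr::bind_rows(
    tibble::tibble(force = unc$f_unfold, censored = FALSE),
    tibble::tibble(force = rep(F_max, n_cens), censored = TRUE)
  )
}
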