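# Classification of real-time zero-force folding traces from the
# superhelicase unwinding assay: as the complementary strand is peeled away
# 5'->3', the released G-rich strand can fold into a quadruplex, seen as a
# rise in FRET efficiency from the duplex baseline (~0.07) to the folded
# level of the 3' quadruplex (~0.73) or the 5' quadruplex (~0.62).

#' Classify a single real-time folding trace
#'
#' The baseline is the median of the first 10 frames. A trace that never
#' leaves the baseline band (+/- 0.1) is `not_unwound`. Otherwise the
#' terminal state is the median of the last 20 frames: `direct_3prime` if the
#' terminal efficiency lies in \[0.68, 0.80\] and the rise shows no pause at
#' intermediate efficiency (a pause being >= `pause_frames` consecutive
#' frames inside a +/- 0.05 band between E = 0.2 and 0.55; a paused rise to
#' the high band is labelled `paused_rise`); `five_prime` if the terminal
#' lies in \[0.55, 0.68); `unfolded_ssDNA` in (0.15, 0.55). The
#' rise duration runs from the first departure out of the baseline band to
#' the first entry into the terminal band (terminal - 0.05).
#'
#' @param E Efficiency time series of one molecule.
#' @param frame_interval Frame time, s.
#' @param pause_frames Minimum length of an intermediate plateau, frames.
#' @return A one-row tibble: `label`, `rise_duration` (s, NA when not
#'   applicable), `final_E`, `baseline`.
#' @export
classify_folding_trace <- function(E, frame_interval = 0.03,
                                   pause_frames = 10) {
  if (length(E) * frame_interval < 5) {
    abort("Trace must span at least 5 s.")
  }
  baseline <- median(E[seq_len(min(10, length(E)))])
  in_base <- abs(E - baseline) <= 0.1
  if (all(in_base)) {
    return(tibble::tibble(label = "not_unwound", rise_duration = NA_real_,
                          final_E = baseline, baseline = baseline))
  }
  terminal <- median(E[max(1, length(E) - 19):length(E)])
  departure <- which(!in_base)[1]
  entry <- which(seq_along(E) >= departure & E >= terminal - 0.05)[1]
  rise_duration <- if (is.na(entry)) NA_real_ else {
    (entry - departure) * frame_interval
  }
  label <-
    if (terminal >= 0.68 && terminal <= 0.80) {
      if (has_intermediate_pause(E, departure, entry, pause_frames)) {
        "paused_rise"
      } else {
        "direct_3prime"
      }
    } else if (terminal >= 0.55 && terminal < 0.68) {
      "five_prime"
    } else if (terminal > 0.15 && terminal < 0.55) {
      "unfolded_ssDNA"
    } else {
      "not_unwound"
    }
  tibble::tibble(label = label, rise_duration = rise_duration,
                 final_E = terminal, baseline = baseline)
}

# A pause is >= `pause_frames` consecutive frames that stay inside a +/-0.05
# band around their running level, at intermediate efficiency (0.2-0.55),
# within the rise window.
has_intermediate_pause <- function(E, departure, entry, pause_frames = 10) {
  if (is.na(entry) || entry - departure < pause_frames) return(FALSE)
  window <- E[departure:entry]
  n <- length(window)
  for (i in seq_len(n - pause_frames + 1L)) {
    seg <- window[i:(i + pause_frames - 1L)]
    centre <- median(seg)
    # a plateau stays in a narrow band AND shows no net drift -- a steady
    # slow climb through the band is still a rise, not a pause
    drift <- median(tail(seg, 3)) - median(head(seg, 3))
    if (centre > 0.2 && centre < 0.55 && all(abs(seg - centre) <= 0.05) &&
        abs(drift) < 0.02) {
      return(TRUE)
    }
  }
  FALSE
}

#' Classify many folding traces
#'
#' @param traces A tibble with `molecule_id`, `frame` and `E` columns (e.g.
#'   [fret_efficiency()] output on [sim_vectorial_traces()] data).
#' @inheritParams classify_folding_trace
#' @return A tibble with one row per molecule: `molecule_id`, `label`,
#'   `rise_duration`, `final_E`, `baseline`.
#' @export
classify_folding_traces <- function(traces, frame_interval = 0.03,
                                    pause_frames = 10) {
  traces |>
    dplyr::arrange(.data$molecule_id, .data$frame) |>
    dplyr::group_by(.data$molecule_id) |>
    dplyr::group_modify(function(df, key) {
      classify_folding_trace(df$E, frame_interval, pause_frames)
    }) |>
    dplyr::ungroup()
}

#' Fraction of molecules folded into a quadruplex
#'
#' Fraction of molecule summaries whose mean efficiency falls inside the
#' folded band, with a Wilson binomial confidence interval. Run
#' [exclude_donor_only()] first.
#'
#' @param summaries Output of [summarize_molecules()].
#' @param band Efficiency band counted as folded.
#' @param conf Confidence level for the Wilson interval.
#' @param min_n Minimum number of molecules.
#' @return A one-row tibble: `n`, `n_folded`, `fraction`, `conf.low`,
#'   `conf.high`.
#' @export
folded_fraction <- function(summaries, band = c(0.6, 0.9), conf = 0.95,
                            min_n = 20) {
  n <- nrow(summaries)
  if (n < min_n) abort(sprintf("Need at least %d molecules.", min_n))
  folded <- summaries$E_mean >= band[1] & summaries$E_mean <= band[2]
  k <- sum(folded)
  if (k == 0 && all(summaries$E_mean > band[2] | summaries$E_mean < band[1])) {
    if (all(summaries$E_mean > band[2]) || all(summaries$E_mean < band[1])) {
      warn("Folded band excludes every molecule.")
    }
  }
  ci <- wilson_interval(k, n, conf)
  tibble::tibble(n = n, n_folded = k, fraction = k / n,
                 conf.low = ci[["lower"]], conf.high = ci[["upper"]])
}
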