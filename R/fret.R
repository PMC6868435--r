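#' Background and crosstalk correction constants
#'
#' @param donor_background,acceptor_background Constant per-frame background
#'   counts subtracted from each channel.
#' @param crosstalk Fraction of the corrected donor signal leaking into the
#'   acceptor channel (0 <= crosstalk < 1).
#' @return An object of class `correction_spec`.
#' @export
correction_spec <- function(donor_background = 0, acceptor_background = 0,
                            crosstalk = 0) {
  if (donor_background < 0 || acceptor_background < 0) {
    abort("Backgrounds must be >= 0.")
  }
  if (crosstalk < 0 || crosstalk >= 1) abort("`crosstalk` must lie in [0, 1).")
  structure(
    list(donor_background = donor_background,
         acceptor_background = acceptor_background,
         crosstalk = crosstalk),
    class = "correction_spec"
  )
}

#' FRET efficiency from two-channel intensity traces
#'
#' Applies background and crosstalk corrections
#' (`I_D' = I_D - bg_D`, `I_A' = I_A - bg_A - crosstalk * I_D'`) and computes
#' `E = I_A' / (I_A' + I_D')` per frame. Frames whose corrected total
#' intensity is not positive carry no signal and are flagged invalid.
#'
#' @param traces A tibble with columns `molecule_id`, `frame`, `donor`,
#'   `acceptor` (counts per frame).
#' @param correction A [correction_spec()].
#' @return The input tibble with added columns `E` (NA on invalid frames) and
#'   `valid`.
#' @examples
#' tr <- tibble::tibble(molecule_id = "m1", frame = 1:2,
#'                      donor = c(50, 320), acceptor = c(50, 700))
#' fret_efficiency(tr, correction_spec(20, 50, 0.1))
#' @export
fret_efficiency <- function(traces, correction = correction_spec()) {
  check_intensity_traces(traces)
  d <- traces$donor - correction$donor_background
  a <- traces$acceptor - correction$acceptor_background - correction$crosstalk * d
  total <- a + d
  valid <- is.finite(total) & total > 0
  if (!any(valid)) abort("All frames are invalid after correction.")
  E <- ifelse(valid, pmax(a, 0) / pmax(total, .Machine$double.eps), NA_real_)
  dplyr::mutate(traces, E = E, valid = valid)
}

check_intensity_traces <- function(traces) {
  need <- c("molecule_id", "donor", "acceptor")
  missing_cols <- setdiff(need, names(traces))
  if (length(missing_cols) > 0) {
    abort(sprintf("Missing required column(s): %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  if (any(traces$donor < 0, na.rm = TRUE) ||
      any(traces$acceptor < 0, na.rm = TRUE)) {
    abort("Intensity counts must be >= 0.")
  }
  invisible(traces)
}

#' Per-molecule FRET summaries from the start of each trace
#'
#' Averages the first `n_frames` valid frames of each molecule's efficiency
#' trace (fewer if the trace is shorter; the number used is recorded), the
#' convention used to build zero-force efficiency histograms.
#'
#' @param efficiencies Output of [fret_efficiency()] (needs `molecule_id`,
#'   `frame`, `E`, `valid`).
#' @param n_frames Number of initial valid frames to average.
#' @return A tibble with `molecule_id`, `E_mean`, `n_frames_used`.
#' @export
summarize_molecules <- function(efficiencies, n_frames = 10) {
  if (!all(c("molecule_id", "E") %in% names(efficiencies))) {
    abort("`efficiencies` must contain `molecule_id` and `E` columns.")
  }
  if (!"valid" %in% names(efficiencies)) {
    efficiencies$valid <- is.finite(efficiencies$E)
  }
  efficiencies |>
    dplyr::filter(.data$valid) |>
    dplyr::arrange(.data$molecule_id, .data$frame) |>
    dplyr::group_by(.data$molecule_id) |>
    dplyr::slice_head(n = n_frames) |>
    dplyr::summarise(E_mean = mean(.data$E),
                     n_frames_used = dplyr::n(),
                     .groups = "drop")
}

#' Remove donor-only molecules
#'
#' Molecules whose mean efficiency sits at the zero peak have a missing or
#' inactive acceptor and carry no conformational information; they are
#' excluded before histogramming or decomposition.
#'
#' @param summaries Output of [summarize_molecules()].
#' @param threshold Molecules with `E_mean < threshold` are removed.
#' @return The filtered tibble; the number removed is reported as a message
#'   and stored in the `n_removed` attribute.
#' @export
exclude_donor_only <- function(summaries, threshold = 0.1) {
  keep <- summaries$E_mean >= threshold
  out <- summaries[keep, , drop = FALSE]
  inform(sprintf("Excluded %d donor-only molecule(s) below E = %g.",
                 sum(!keep), threshold))
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Efficiency histogram over molecules
#'
#' @param summaries Output of [summarize_molecules()].
#' @param bin_width Histogram bin width in E units.
#' @param range Histogram range (left-closed bins).
#' @return A tibble with `bin_left`, `bin_mid`, `bin_right`, `count`.
#' @export
build_histogram <- function(summaries, bin_width = 0.02,
                            range = c(-0.1, 1.2)) {
  if (nrow(summaries) < 1) abort("Need at least one molecule summary.")
  breaks <- seq(range[1], range[2], by = bin_width)
  if (breaks[length(breaks)] < range[2]) breaks <- c(breaks, range[2])
  e <- pmin(pmax(summaries$E_mean, range[1]), range[2] - 1e-12)
  idx <- findInterval(e, breaks, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = length(breaks) - 1L)
  tibble::tibble(
    bin_left = breaks[-length(breaks)],
    bin_right = breaks[-1],
    bin_mid = (breaks[-length(breaks)] + breaks[-1]) / 2,
    count = counts
  )
}

#' Calibrate mixture components from single-construct variants
#'
#' Fits a single Gaussian (maximum likelihood: sample mean and
#' 1/n standard deviation) to each variant construct's folded peak after
#' donor-only exclusion. The labelled centres and widths are then used as
#' fixed components when decomposing the multi-position construct.
#'
#' @param variant_summaries A tibble with columns `construct` and `E_mean`
#'   (one row per molecule), already restricted to folded molecules.
#' @param min_n Minimum molecules per construct.
#' @return A tibble with `label`, `center`, `sigma`, `n`.
#' @export
calibrate_components <- function(variant_summaries, min_n = 30) {
  if (!all(c("construct", "E_mean") %in% names(variant_summaries))) {
    abort("`variant_summaries` must contain `construct` and `E_mean`.")
  }
  out <- variant_summaries |>
    dplyr::group_by(label = .data$construct) |>
    dplyr::summarise(
      center = mean(.data$E_mean),
      sigma = sqrt(mean((.data$E_mean - mean(.data$E_mean))^2)),
      n = dplyr::n(),
      .groups = "drop"
    )
  bad <- out$n < min_n
  if (any(bad)) {
    abort(sprintf("Insufficient molecules (< %d) for construct(s): %s.",
                  min_n, paste(out$label[bad], collapse = ", ")))
  }
  out
}

#' Fixed-component Gaussian mixture components
#'
#' @param center Component centres in E units (must be distinct).
#' @param sigma Component widths; recycled. Defaults to 0.05, a typical
#'   shot-noise-limited smFRET peak width at these intensities.
#' @param label Optional component labels.
#' @return A tibble of components suitable for [decompose_mixture()].
#' @export
fret_components <- function(center, sigma = 0.05, label = NULL) {
  if (any(center <= 0) || any(center >= 1.2)) {
    abort("`center` values must lie in (0, 1.2).")
  }
  if (anyDuplicated(center)) abort("Component centres must be distinct.")
  if (any(sigma <= 0)) abort("`sigma` must be > 0.")
  tibble::tibble(
    label = label %||% paste0("component_", seq_along(center)),
    center = center,
    sigma = rep_len(sigma, length(center))
  )
}

#' Decompose molecule efficiencies into fixed Gaussian subpopulations
#'
#' Expectation-maximisation over mixture weights only: component centres and
#' widths stay fixed (they are calibrated from single-position variant
#' constructs), so the only free parameters are the subpopulation
#' proportions. The log-likelihood is checked to be non-decreasing at every
#' iteration. Standard errors come from the observed information of the
#' weight simplex; hard maximum-posterior labels are also recorded so that
#' integer event counts per subpopulation can be reported.
#'
#' @param summaries Output of [summarize_molecules()] (or any tibble with an
#'   `E_mean` column), after donor-only exclusion.
#' @param components A components tibble from [fret_components()] or
#'   [calibrate_components()].
#' @param max_iter,tol EM iteration cap and log-likelihood convergence
#'   tolerance.
#' @return An object of class `fret_mixture_fit`; see [tidy.fret_mixture_fit()].
#' @export
decompose_mixture <- function(summaries, components, max_iter = 1000,
                              tol = 1e-8) {
  if (nrow(summaries) == 0) abort("`summaries` is empty.")
  if (nrow(components) < 2) abort("Need at least two components.")
  if (anyDuplicated(components$center)) {
    abort("Component centres must be distinct (identifiability).")
  }
  e <- summaries$E_mean
  n <- length(e)
  K <- nrow(components)
  dens <- vapply(seq_len(K), function(k) {
    dnorm(e, components$center[k], components$sigma[k])
  }, numeric(n))
  w <- rep(1 / K, K)
  ll_old <- -Inf
  ll_trace <- numeric(0)
  for (iter in seq_len(max_iter)) {
    num <- sweep(dens, 2, w, `*`)
    mix <- rowSums(num)
    ll <- sum(log(pmax(mix, 1e-300)))
    if (ll < ll_old - 1e-10) {
      abort("EM log-likelihood decreased; this should be impossible.")
    }
    ll_trace <- c(ll_trace, ll)
    resp <- num / pmax(mix, 1e-300)
    w_new <- colMeans(resp)
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
    w <- w_new
  }
  boundary <- w < 1e-8
  if (any(boundary)) {
    warn(sprintf("Weight(s) at the zero boundary: %s.",
                 paste(components$label[boundary], collapse = ", ")))
  }
  # observed information for the first K-1 weights (the last is 1 - sum)
  se <- mixture_weight_se(dens, w)
  hard <- apply(resp, 1, which.max)
  structure(
    list(
      components = components,
      weights = w,
      se = se,
      responsibilities = resp,
      hard_labels = components$label[hard],
      hard_counts = tabulate(hard, K),
      logLik = ll,
      logLik_trace = ll_trace,
      n = n,
      iterations = iter
    ),
    class = "fret_mixture_fit"
  )
}

# Standard errors of EM weight estimates from the observed information of
# the (K-1)-dimensional simplex parametrisation; the last weight's variance
# follows from the constraint.
mixture_weight_se <- function(dens, w) {
  K <- ncol(dens)
  mix <- as.vector(dens %*% w)
  d_rel <- sweep(dens[, -K, drop = FALSE], 1, dens[, K], `-`) /
    pmax(mix, 1e-300)
  info <- crossprod(d_rel)
  v <- tryCatch(solve(info), error = function(e) NULL)
  if (is.null(v)) return(rep(NA_real_, K))
  ones <- rep(1, K - 1)
  c(sqrt(pmax(diag(v), 0)), sqrt(max(as.numeric(t(ones) %*% v %*% ones), 0)))
}

#' @export
print.fret_mixture_fit <- function(x, ...) {
  cat(sprintf("<fret_mixture_fit> %d molecules, %d components, logLik = %.2f\n",
              x$n, nrow(x$components), x$logLik))
  print(tidy(x))
  invisible(x)
}

#' Tidy a fixed-component mixture decomposition
#'
#' @param x A `fret_mixture_fit` from [decompose_mixture()].
#' @param ... Unused.
#' @return A tibble with one row per component: `label`, `center`, `sigma`,
#'   `weight`, `std.error`, `n_hard` (maximum-posterior event count).
#' @method tidy fret_mixture_fit
#' @export
tidy.fret_mixture_fit <- function(x, ...) {
  tibble::tibble(
    label = x$components$label,
    center = x$components$center,
    sigma = x$components$sigma,
    weight = x$weights,
    std.error = x$se,
    n_hard = x$hard_counts
  )
}

#' @rdname tidy.fret_mixture_fit
#' @method glance fret_mixture_fit
#' @export
glance.fret_mixture_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$logLik,
    n = x$n,
    n_components = nrow(x$components),
    iterations = x$iterations
  )
}

#' Count abrupt efficiency transitions in a time trace
#'
#' A transition is an excursion in which the 3-frame running median moves by
#' more than `jump_threshold` from the current level and stays there for at
#' least `min_persist` frames; brief blinks fail the persistence rule and
#' are not counted.
#'
#' @param E Efficiency time series (numeric).
#' @param jump_threshold Minimum level change in E units.
#' @param min_persist Minimum number of frames the new level must persist.
#' @return A tibble with one row per transition: `frame` (index of the first
#'   frame at the new level), `from`, `to`.
#' @export
detect_E_transitions <- function(E, jump_threshold = 0.2, min_persist = 3) {
  if (length(E) < 2) abort("`E` must have length >= 2.")
  med <- running_median(E, 3)
  n <- length(med)
  level <- med[1]
  out <- list()
  i <- 2L
  while (i <= n - min_persist + 1L) {
    if (abs(med[i] - level) > jump_threshold) {
      window <- med[i:(i + min_persist - 1L)]
      if (all(abs(window - level) > jump_threshold)) {
        new_level <- median(window)
        out[[length(out) + 1L]] <-
          tibble::tibble(frame = i, from = level, to = new_level)
        level <- new_level
        i <- i + min_persist
        next
      }
    }
    i <- i + 1L
  }
  if (length(out) == 0) {
    return(tibble::tibble(frame = integer(0), from = numeric(0),
                          to = numeric(0)))
  }
  dplyr::bind_rows(out)
}
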