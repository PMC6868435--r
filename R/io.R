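# Tabular trace files and structured result documents.
#
# Traces travel as plain TSV with a one-line header so files are diff-able
# and language-neutral: intensity traces carry `molecule_id, frame, donor,
# acceptor`; pulling cycles carry `molecule_id, cycle, t_s, stage_nm,
# force_pN, donor, acceptor, direction`. Result documents are JSON with a
# fixed key order (units embedded in key names), so identical results give
# byte-identical files.

INTENSITY_COLS <- c("molecule_id", "frame", "donor", "acceptor")
PULLING_COLS <- c("molecule_id", "cycle", "t_s", "stage_nm", "force_pN",
                  "donor", "acceptor", "direction")

#' Read intensity or pulling traces from TSV
#'
#' @param path Path to a TSV written by [write_traces()] (or conforming to
#'   the same column dialect).
#' @param kind `"intensity"` or `"pulling"`.
#' @return A tibble with validated columns, sorted by molecule (and cycle,
#'   time for pulling data).
#' @export
read_traces <- function(path, kind = c("intensity", "pulling")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  need <- if (kind == "intensity") INTENSITY_COLS else PULLING_COLS
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    abort(sprintf("Missing required column(s) in %s: %s.", path,
                  paste(missing_cols, collapse = ", ")))
  }
  if (any(df$donor < 0) || any(df$acceptor < 0)) {
    abort("Intensity counts must be >= 0.")
  }
  if (kind == "pulling") {
    bad <- df |>
      dplyr::group_by(.data$molecule_id, .data$cycle) |>
      dplyr::summarise(ok = !is.unsorted(.data$t_s, strictly = TRUE),
                       .groups = "drop") |>
      dplyr::filter(!.data$ok)
    if (nrow(bad) > 0) {
      abort(sprintf("Non-monotone time for molecule(s): %s.",
                    paste(unique(bad$molecule_id), collapse = ", ")))
    }
    if (any(df$force_pN < 0)) abort("Forces must be >= 0.")
    df <- dplyr::arrange(df, .data$molecule_id, .data$cycle, .data$t_s)
  } else {
    df <- dplyr::arrange(df, .data$molecule_id, .data$frame)
  }
  df
}

#' Write traces to TSV
#'
#' @param traces A tibble with the intensity or pulling column dialect.
#' @param path Output path.
#' @param kind `"intensity"` or `"pulling"`.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path, kind = c("intensity", "pulling")) {
  kind <- match.arg(kind)
  need <- if (kind == "intensity") INTENSITY_COLS else PULLING_COLS
  missing_cols <- setdiff(need, names(traces))
  if (length(missing_cols) > 0) {
    abort(sprintf("Missing required column(s): %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  out <- traces[, need]
  # doubles are printed with 10 significant digits: far below any
  # instrument resolution, and stable under write-read-write, so a second
  # write is byte-identical to the first
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      out[[j]] <- sprintf("%.10g", out[[j]])
    }
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Structured result document
#'
#' A serialisable record of one pipeline stage: its name, parameter
#' estimates (a named list; embed units in the names, e.g. `dx_dagger_nm`),
#' and provenance (input files, seeds, configuration). Documents round-trip
#' losslessly through [write_results()] / [read_results()], and two writes of
#' the same document are byte-identical.
#'
#' @param stage Stage name.
#' @param estimates Named list of parameter estimates (numbers or vectors).
#' @param uncertainties Optional named list of standard errors.
#' @param provenance Optional named list (input files, config hash).
#' @param seed Optional integer seed used by the stage.
#' @return An object of class `result_document`.
#' @export
result_document <- function(stage, estimates, uncertainties = NULL,
                            provenance = NULL, seed = NULL) {
  if (!is.character(stage) || length(stage) != 1L) {
    abort("`stage` must be a single string.")
  }
  if (!is.list(estimates) || is.null(names(estimates))) {
    abort("`estimates` must be a named list.")
  }
  structure(
    list(stage = stage,
         estimates = estimates[order(names(estimates))],
         uncertainties = if (!is.null(uncertainties)) {
           uncertainties[order(names(uncertainties))]
         },
         provenance = provenance,
         seed = seed),
    class = "result_document"
  )
}

#' Write a result document as canonical JSON
#'
#' @param doc A [result_document()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(doc, path) {
  if (!inherits(doc, "result_document")) {
    abort("`doc` must be a `result_document`.")
  }
  json <- jsonlite::toJSON(unclass(doc), auto_unbox = TRUE, digits = NA,
                           null = "null", pretty = TRUE)
  ok <- try(writeLines(json, path), silent = TRUE)
  if (inherits(ok, "try-error")) {
    abort(sprintf("Cannot write to %s.", path))
  }
  invisible(path)
}

#' Read a result document written by [write_results()]
#'
#' @param path Path to the JSON document.
#' @return A `result_document`.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  result_document(stage = x$stage,
                  estimates = as.list(x$estimates),
                  uncertainties = if (!is.null(x$uncertainties)) {
                    as.list(x$uncertainties)
                  },
                  provenance = if (!is.null(x$provenance)) {
                    as.list(x$provenance)
                  },
                  seed = x$seed)
}

#' @export
print.result_document <- function(x, ...) {
  cat(sprintf("<result_document: %s>\n", x$stage))
  utils::str(x$estimates, give.attr = FALSE)
  invisible(x)
}
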