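#' Source-space recording container
#'
#' A `source_recording` bundles a sources-by-samples activity matrix with
#' its sampling rate, a per-source table (id, hemisphere, atlas label,
#' coordinates in mm), an analyzable-sample mask and optional event ground
#' truth. It is the common currency of every pipeline stage: simulation
#' renders one, preprocessing refines its mask, and detection consumes it.
#'
#' @param data numeric matrix, sources in rows, samples in columns. A bare
#'   vector is promoted to a one-source matrix.
#' @param fs sampling rate in Hz (> 0).
#' @param sources data frame with one row per source and at least columns
#'   `id`, `hemisphere` ("lh"/"rh") and `label`; coordinate columns
#'   `x`, `y`, `z` (mm) are optional. Defaults to a single left-hemisphere
#'   source per row of `data`.
#' @param subject subject identifier string.
#' @param mask logical vector, one entry per sample; `TRUE` means the
#'   sample is analyzable. Defaults to all-analyzable.
#' @param truth optional data frame of ground-truth events
#'   (`onset`, `duration`, `freq`, `amplitude`, `kind`) kept for detector
#'   scoring; never consumed by the analysis itself.
#' @param boundaries numeric vector of segment-boundary times in seconds
#'   (concatenation points detections must not span).
#' @param vertical_axis name of the mesh axis pointing superior ("z" by
#'   convention); consumed by the geometry helpers.
#'
#' @return an object of class `source_recording`.
#' @export
source_recording <- function(data, fs, sources = NULL, subject = "subj",
                             mask = NULL, truth = NULL,
                             boundaries = numeric(0), vertical_axis = "z") {
  if (is.null(dim(data))) data <- matrix(data, nrow = 1L)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a single positive number", call. = FALSE)
  n_src <- nrow(data)
  if (is.null(sources)) {
    sources <- data.frame(id = seq_len(n_src), hemisphere = "lh",
                          label = "roi", stringsAsFactors = FALSE)
  }
  if (nrow(sources) != n_src)
    stop("source table rows (", nrow(sources),
         ") do not match data rows (", n_src, ")", call. = FALSE)
  if (is.null(mask)) mask <- rep(TRUE, ncol(data))
  if (length(mask) != ncol(data))
    stop("mask length does not match sample count", call. = FALSE)
  structure(
    list(data = data, fs = fs, sources = sources, subject = subject,
         mask = as.logical(mask), truth = truth,
         boundaries = as.numeric(boundaries),
         vertical_axis = vertical_axis),
    class = "source_recording")
}

#' @export
print.source_recording <- function(x, ...) {
  cat(sprintf(
    "<source_recording> subject=%s  %d source(s) x %d samples @ %g Hz (%.1f s, %.1f s analyzable)\n",
    x$subject, nrow(x$data), ncol(x$data), x$fs,
    ncol(x$data) / x$fs, sum(x$mask) / x$fs))
  invisible(x)
}

#' Duration helpers for recordings
#'
#' `recording_duration()` is the raw record length; `analyzable_duration()`
#' is the masked (artifact/spike-free) time that downstream rate
#' denominators use exclusively.
#'
#' @param rec a `source_recording`.
#' @return duration in seconds.
#' @export
recording_duration <- function(rec) ncol(rec$data) / rec$fs

#' @rdname recording_duration
#' @export
analyzable_duration <- function(rec) sum(rec$mask) / rec$fs
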