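#' Aperiodic spectral slope of a short interval
#'
#' Least-squares slope of log10(power) versus log10(frequency) on the
#' Hann-tapered periodogram of the interval, restricted to the given
#' band. Clean EEG background follows a 1/f^alpha law, so the slope over
#' 30-95 Hz is strongly negative; broadband artifacts (muscle) flatten
#' it, which is the artifact criterion.
#'
#' @param x numeric signal interval (typically 1 s).
#' @param fs sampling rate in Hz; `fs/2` must exceed the band top.
#' @param band Hz pair, default c(30, 95).
#' @return slope in log10-power per log10-Hz.
#' @export
spectral_slope <- function(x, fs, band = c(30, 95)) {
  if (all(x == 0)) stop("zero signal: log-power undefined", call. = FALSE)
  if (fs / 2 <= band[2])
    stop("Nyquist must exceed the slope band", call. = FALSE)
  sp <- hann_periodogram(x, fs)
  sel <- sp$frequency >= band[1] & sp$frequency <= band[2] & sp$power > 0
  lf <- log10(sp$frequency[sel])
  lp <- log10(sp$power[sel])
  unname(stats::coef(stats::lm.fit(cbind(1, lf), lp))[2])
}

runs_from_logical <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

add_mask_runs <- function(rec, excl_idx_runs, reason) {
  if (nrow(excl_idx_runs) == 0) return(rec)
  new <- data.frame(onset = (excl_idx_runs$start - 1L) / rec$fs,
                    offset = excl_idx_runs$end / rec$fs,
                    reason = reason, stringsAsFactors = FALSE)
  rec$mask_runs <- rbind(rec$mask_runs, new)
  rec
}

#' Flag artifact windows by spectral slope
#'
#' Evaluates non-overlapping windows (1 s by default) aligned to the
#' recording start; any window whose slope exceeds `-slope_threshold`
#' (i.e. is not sufficiently negative) on any source is excluded from
#' the analyzable mask. The trailing partial window is always excluded.
#'
#' @param rec a [source_recording()].
#' @param slope_band Hz pair for the fit, default c(30, 95).
#' @param slope_threshold the exponent threshold alpha, default 1.5:
#'   windows with slope > -1.5 are artifacts.
#' @param window window length in seconds, default 1.
#' @return the recording with its mask (and `mask_runs` provenance)
#'   updated.
#' @export
flag_artifacts <- function(rec, slope_band = c(30, 95),
                           slope_threshold = 1.5, window = 1) {
  if (slope_threshold <= 0) stop("slope threshold must be > 0", call. = FALSE)
  w <- round(window * rec$fs)
  n <- ncol(rec$data)
  if (n <= w) stop("recording must exceed one window", call. = FALSE)
  nwin <- n %/% w
  bad <- rep(FALSE, n)
  for (k in seq_len(nwin)) {
    idx <- ((k - 1L) * w + 1L):(k * w)
    flagged <- any(vapply(seq_len(nrow(rec$data)), function(s) {
      seg <- rec$data[s, idx]
      if (all(seg == 0)) return(TRUE)
      spectral_slope(seg, rec$fs, slope_band) > -slope_threshold
    }, logical(1)))
    if (flagged) bad[idx] <- TRUE
  }
  if (nwin * w < n) bad[(nwin * w + 1L):n] <- TRUE
  rec <- add_mask_runs(rec, runs_from_logical(bad), "artifact")
  rec$mask <- rec$mask & !bad
  rec
}

#' Mask epochs around epileptic spikes
#'
#' For each spike time `t`, samples in `[t - pad/2, t + pad/2)` are
#' removed from the analyzable mask (a 200 ms window centred on the
#' detection by default, matching the amount of data removed around each
#' detected spike). Overlapping exclusions merge.
#'
#' @param rec a [source_recording()].
#' @param spike_times numeric vector of spike onsets in seconds.
#' @param pad total excluded span per spike in seconds, default 0.2.
#' @return the recording with its mask updated.
#' @export
mask_spikes <- function(rec, spike_times, pad = 0.2) {
  if (pad < 0) stop("pad must be non-negative", call. = FALSE)
  if (length(spike_times) == 0) return(rec)
  total <- recording_duration(rec)
  if (any(spike_times < 0 | spike_times > total))
    stop("spike times outside the recording", call. = FALSE)
  n <- ncol(rec$data)
  bad <- rep(FALSE, n)
  for (t in spike_times) {
    i0 <- max(1L, floor((t - pad / 2) * rec$fs) + 1L)
    i1 <- min(n, ceiling((t + pad / 2) * rec$fs))
    bad[i0:i1] <- TRUE
  }
  rec <- add_mask_runs(rec, runs_from_logical(bad), "spike")
  rec$mask <- rec$mask & !bad
  rec
}

#' Read spike times from a plain-text event list
#'
#' One onset in seconds per line; `#` comments and blank lines ignored.
#'
#' @param path file path.
#' @return numeric vector of onsets.
#' @export
read_spike_times <- function(path) {
  ln <- readLines(path)
  ln <- sub("#.*$", "", ln)
  ln <- trimws(ln)
  as.numeric(ln[nzchar(ln)])
}

#' Export excluded intervals
#'
#' Writes merged excluded runs as a tab-delimited table (onset, offset,
#' reason) in half-open, 0-based seconds.
#'
#' @param rec a [source_recording()] after masking.
#' @return data frame of excluded runs (invisibly written to `path` if
#'   given).
#' @param path optional output path.
#' @export
mask_intervals <- function(rec, path = NULL) {
  runs <- rec$mask_runs
  if (is.null(runs)) runs <- data.frame(onset = numeric(0),
                                        offset = numeric(0),
                                        reason = character(0))
  runs <- runs[order(runs$onset), , drop = FALSE]
  rownames(runs) <- NULL
  if (!is.null(path))
    utils::write.table(runs, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  runs
}

#' Decimate a recording to a lower sampling rate
#'
#' Anti-alias low-pass filtering followed by integer-stride selection
#' (60-tap linear-phase FIR low-pass at 0.8 of the target Nyquist via
#' `signal::decimate`), applied per source. The mask is carried over by
#' stride; ground truth and boundaries are in seconds and unchanged.
#'
#' @param rec a [source_recording()].
#' @param target_fs target rate in Hz; the original rate must be an
#'   integer multiple (2035 -> 407 Hz is the study's factor-5 case).
#' @return the decimated [source_recording()].
#' @export
decimate_recording <- function(rec, target_fs) {
  q <- rec$fs / target_fs
  if (abs(q - round(q)) > 1e-9)
    stop("sampling-rate ratio must be an integer", call. = FALSE)
  q <- as.integer(round(q))
  if (q == 1L) return(rec)
  newdata <- t(apply(rec$data, 1, function(x)
    signal::decimate(x, q, n = 60, ftype = "fir")))
  keep <- seq(1L, ncol(rec$data), by = q)
  source_recording(newdata, target_fs, sources = rec$sources,
                   subject = rec$subject, mask = rec$mask[keep],
                   truth = rec$truth, boundaries = rec$boundaries,
                   vertical_axis = rec$vertical_axis)
}

#' Concatenate sleep segments
#'
#' Joins recordings (same fs and source set) end to end, retaining the
#' junction positions as segment boundaries so that no spindle detection
#' may span a join. Masks, provenance runs and ground truth are shifted
#' accordingly.
#'
#' @param recs list of [source_recording()]s.
#' @return one [source_recording()] with `boundaries` set at interior
#'   junctions.
#' @export
concatenate_segments <- function(recs) {
  if (length(recs) == 1L) return(recs[[1]])
  fs <- recs[[1]]$fs
  ids <- recs[[1]]$sources$id
  for (r in recs) {
    if (r$fs != fs) stop("sampling rates differ", call. = FALSE)
    if (!identical(r$sources$id, ids))
      stop("source sets differ", call. = FALSE)
  }
  offsets <- cumsum(c(0, vapply(recs, recording_duration, numeric(1))))
  shift_truth <- function(r, off) {
    if (is.null(r$truth)) return(NULL)
    tr <- r$truth; tr$onset <- tr$onset + off; tr
  }
  shift_runs <- function(r, off) {
    if (is.null(r$mask_runs)) return(NULL)
    m <- r$mask_runs; m$onset <- m$onset + off; m$offset <- m$offset + off; m
  }
  out <- source_recording(
    do.call(cbind, lapply(recs, function(r) r$data)), fs,
    sources = recs[[1]]$sources, subject = recs[[1]]$subject,
    mask = do.call(c, lapply(recs, function(r) r$mask)),
    truth = do.call(rbind, Map(shift_truth, recs, offsets[-length(offsets)])),
    boundaries = offsets[c(-1, -length(offsets))],
    vertical_axis = recs[[1]]$vertical_axis)
  out$mask_runs <- do.call(rbind, Map(shift_runs, recs,
                                      offsets[-length(offsets)]))
  out
}
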