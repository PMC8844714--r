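#' Sigma-band power of one spindle segment
#'
#' Applies a Hann window to the spindle-interval signal, zero-pads to
#' 4 s (0.25 Hz grid) when the spindle is shorter than 4 s, and returns
#' the mean power over the bins between 10.25 and 14.75 Hz (closed
#' band). Callers average this over all spindles of a region per
#' subject.
#'
#' @param seg numeric signal over one spindle interval.
#' @param fs sampling rate in Hz.
#' @param band closed Hz pair, default c(10.25, 14.75).
#' @param pad_to zero-pad target in seconds, default 4.
#' @return mean band power (quadratic in the signal amplitude).
#' @export
spindle_sigma_power <- function(seg, fs, band = c(10.25, 14.75),
                                pad_to = 4) {
  n <- length(seg)
  if (n == 0) stop("empty spindle segment", call. = FALSE)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  xw <- seg * w
  npad <- max(n, round(pad_to * fs))
  xp <- c(xw, rep(0, npad - n))
  xf <- stats::fft(xp)
  nh <- floor(npad / 2) + 1L
  freq <- (seq_len(nh) - 1L) * fs / npad
  p <- (Mod(xf[seq_len(nh)])^2) / (fs * sum(w^2))
  p[2:(nh - 1L)] <- 2 * p[2:(nh - 1L)]
  sel <- freq >= band[1] & freq <= band[2]
  mean(p[sel])
}

#' Spindle indicator vector for a region
#'
#' Binary sample series equal to 1 when at least one source in the
#' region is inside a spindle detection; overlapping detections union.
#'
#' @param detections detection data frame (`onset`, `offset` in
#'   seconds, any number of sources).
#' @param n_samples length of the recording in samples.
#' @param fs sampling rate in Hz.
#' @return integer vector of 0/1 of length `n_samples`.
#' @export
indicator_vector <- function(detections, n_samples, fs) {
  ind <- integer(n_samples)
  if (is.null(detections) || nrow(detections) == 0) return(ind)
  if (any(detections$onset < 0) ||
      any(detections$offset > n_samples / fs + 1e-9))
    stop("detection outside the recording", call. = FALSE)
  for (i in seq_len(nrow(detections))) {
    i0 <- floor(detections$onset[i] * fs) + 1L
    i1 <- min(n_samples, ceiling(detections$offset[i] * fs))
    ind[i0:i1] <- 1L
  }
  ind
}

#' Spindle epochs from an indicator vector
#'
#' One 2-s epoch (+/- 1 s) around the centre of each maximal run of
#' ones. Epochs whose window would extend past either record edge are
#' dropped.
#'
#' @param indicator 0/1 vector.
#' @param fs sampling rate in Hz.
#' @return data frame with `center` (s), `start`, `end` (sample
#'   indices of the 2-s window), `run_start`, `run_end` (sample indices
#'   of the spindle run itself).
#' @export
spindle_epochs <- function(indicator, fs) {
  r <- runs_from_logical(indicator == 1L)
  if (nrow(r) == 0)
    return(data.frame(center = numeric(0), start = integer(0),
                      end = integer(0), run_start = integer(0),
                      run_end = integer(0)))
  half <- round(fs)          # 1 s in samples
  center <- (r$start + r$end) / 2 / fs
  start <- round(center * fs) - half + 1L
  end <- start + 2L * half - 1L
  keep <- start >= 1L & end <= length(indicator)
  data.frame(center = center, start = start, end = end,
             run_start = r$start, run_end = r$end)[keep, , drop = FALSE]
}

epoch_participants <- function(detections, epoch, fs) {
  # sources whose detection overlaps the 2-s epoch window
  a <- (epoch$start - 1L) / fs
  b <- epoch$end / fs
  unique(detections$source[detections$onset < b & detections$offset > a])
}

#' Intra-hemispheric sigma coherence during spindle epochs
#'
#' For each spindle epoch of a region, computes pairwise multitaper
#' coherence at `eval_freq` among the sources exhibiting spindles in
#' that epoch, averages over pairs, then over epochs. Epochs with fewer
#' than two participating sources are skipped; if no epoch qualifies
#' the value is missing (`NA`), not zero.
#'
#' @param rec a [source_recording()] restricted to the region's sources.
#' @param detections detection data frame with a `source` column
#'   matching `rec$sources$id`.
#' @param tapers a `taper_set` sized for the 2-s epoch.
#' @param eval_freq Hz, default 12.5.
#' @return mean coherence in [0, 1], or `NA` when undefined.
#' @export
intra_coherence <- function(rec, detections, tapers, eval_freq = 12.5) {
  n <- ncol(rec$data)
  ind <- indicator_vector(detections, n, rec$fs)
  ep <- spindle_epochs(ind, rec$fs)
  vals <- c()
  for (k in seq_len(nrow(ep))) {
    parts <- epoch_participants(detections, ep[k, ], rec$fs)
    rows <- which(rec$sources$id %in% parts)
    if (length(rows) < 2L) next
    idx <- ep$start[k]:ep$end[k]
    pr <- utils::combn(rows, 2L)
    cc <- vapply(seq_len(ncol(pr)), function(j) {
      multitaper_coherence(rec$data[pr[1, j], idx], rec$data[pr[2, j], idx],
                           tapers, rec$fs, eval_freq)
    }, numeric(1))
    vals <- c(vals, mean(cc))
  }
  if (length(vals) == 0) NA_real_ else mean(vals)
}

#' Inter-hemispheric sigma coherence during bilateral spindle epochs
#'
#' Epochs are taken where spindle runs occur in both hemispheres
#' simultaneously (joint indicator). Cross-hemisphere source pairs among
#' the participating sources contribute; averaged over pairs, then
#' epochs. `NA` when no bilateral epoch exists (the subject is then
#' excluded from that model).
#'
#' @param rec_left,rec_right [source_recording()]s of the two regions,
#'   time-aligned and equal length.
#' @param det_left,det_right detection data frames with `source`
#'   columns.
#' @param tapers a `taper_set` for the 2-s epoch.
#' @param eval_freq Hz, default 12.5.
#' @return mean coherence in [0, 1], or `NA`.
#' @export
inter_coherence <- function(rec_left, rec_right, det_left, det_right,
                            tapers, eval_freq = 12.5) {
  n <- ncol(rec_left$data)
  if (ncol(rec_right$data) != n)
    stop("hemisphere recordings differ in length", call. = FALSE)
  fs <- rec_left$fs
  il <- indicator_vector(det_left, n, fs)
  ir <- indicator_vector(det_right, n, fs)
  ep <- spindle_epochs(as.integer(il & ir), fs)
  vals <- c()
  for (k in seq_len(nrow(ep))) {
    rl <- which(rec_left$sources$id %in%
                  epoch_participants(det_left, ep[k, ], fs))
    rr <- which(rec_right$sources$id %in%
                  epoch_participants(det_right, ep[k, ], fs))
    if (length(rl) < 1L || length(rr) < 1L) next
    idx <- ep$start[k]:ep$end[k]
    cc <- c()
    for (a in rl) for (b in rr) {
      cc <- c(cc, multitaper_coherence(rec_left$data[a, idx],
                                       rec_right$data[b, idx],
                                       tapers, fs, eval_freq))
    }
    vals <- c(vals, mean(cc))
  }
  if (length(vals) == 0) NA_real_ else mean(vals)
}

#' Bilateral spindle synchrony
#'
#' Dot product of the left and right spindle indicator vectors divided
#' by the length of their union (samples where spindles occur in either
#' hemisphere). 1 when spindles fully co-occur, 0 when disjoint; defined
#' as 0 when the union is empty. Symmetric and invariant to all-zero
#' padding.
#'
#' @param ind_left,ind_right equal-length 0/1 vectors.
#' @return fraction in [0, 1].
#' @export
bilateral_synchrony <- function(ind_left, ind_right) {
  if (length(ind_left) != length(ind_right))
    stop("indicator vectors differ in length", call. = FALSE)
  u <- sum(ind_left | ind_right)
  if (u == 0) return(0)
  sum(ind_left * ind_right) / u
}

#' Per-subject spindle feature summary
#'
#' Convenience wrapper producing the per-subject feature table used by
#' the group models: spindle counts and rates per hemisphere, mean
#' duration, mean spindle sigma power, intra-/inter-hemispheric
#' coherence and bilateral synchrony.
#'
#' @param rec_left,rec_right [source_recording()]s of the left/right
#'   region.
#' @param det_left,det_right detection data frames with `source`.
#' @param tapers optional `taper_set` (built for 2 s at the recording's
#'   fs when `NULL`).
#' @return one-row data frame.
#' @export
spindle_feature_table <- function(rec_left, rec_right, det_left, det_right,
                                  tapers = NULL) {
  fs <- rec_left$fs
  if (is.null(tapers)) tapers <- dpss_tapers(2L * round(fs), 5)
  n <- ncol(rec_left$data)
  sp_power <- function(rec, det) {
    if (nrow(det) == 0) return(NA_real_)
    mean(vapply(seq_len(nrow(det)), function(i) {
      row <- which(rec$sources$id == det$source[i])
      i0 <- floor(det$onset[i] * fs) + 1L
      i1 <- min(ncol(rec$data), ceiling(det$offset[i] * fs))
      spindle_sigma_power(rec$data[row, i0:i1], fs)
    }, numeric(1)))
  }
  il <- indicator_vector(det_left, n, fs)
  ir <- indicator_vector(det_right, n, fs)
  data.frame(
    subject = rec_left$subject,
    n_spindles_lh = nrow(det_left), n_spindles_rh = nrow(det_right),
    rate_lh = spindle_rate(det_left, analyzable_duration(rec_left)),
    rate_rh = spindle_rate(det_right, analyzable_duration(rec_right)),
    mean_duration = {
      dur <- c(det_left$offset - det_left$onset,
               det_right$offset - det_right$onset)
      if (length(dur)) mean(dur) else NA_real_
    },
    sigma_power_lh = sp_power(rec_left, det_left),
    sigma_power_rh = sp_power(rec_right, det_right),
    intra_coh_lh = intra_coherence(rec_left, det_left, tapers),
    intra_coh_rh = intra_coherence(rec_right, det_right, tapers),
    inter_coh = inter_coherence(rec_left, rec_right, det_left, det_right,
                                tapers),
    synchrony = bilateral_synchrony(il, ir),
    stringsAsFactors = FALSE)
}
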