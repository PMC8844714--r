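band_power <- function(sp, band) {
  sum(sp$power[sp$frequency >= band[1] & sp$frequency <= band[2]])
}

extrema_intervals <- function(x) {
  d <- sign(diff(x))
  # collapse flat stretches so plateaus count once
  nz <- d != 0
  idx <- which(nz)
  dd <- d[idx]
  turn <- which(diff(dd) != 0)
  peaks <- idx[turn][dd[turn] > 0] + 1L
  troughs <- idx[turn][dd[turn] < 0] + 1L
  list(peaks = peaks, troughs = troughs)
}

#' Rhythmicity of a short signal window
#'
#' Consistency of the time intervals between subsequent peaks and
#' between subsequent troughs: `1 / (1 + cv)` where `cv` is the SD over
#' mean of the pooled inter-peak and inter-trough intervals. A pure
#' sinusoid has identical intervals (score near 1); irregular noise
#' scores low. Windows with fewer than three extrema of both kinds score
#' 0.
#'
#' @param x numeric window.
#' @return score in [0, 1].
#' @export
rhythmicity <- function(x) {
  ex <- extrema_intervals(x)
  iv <- c(diff(ex$peaks), diff(ex$troughs))
  if (length(iv) < 2L) return(0)
  cv <- stats::sd(iv) / mean(iv)
  1 / (1 + cv)
}

#' Sliding-window detector features
#'
#' For each sliding window, computes the three spindle-detector
#' features: theta band power (4-8 Hz), sigma band power (9-15 Hz; the
#' detector's wider sigma definition), and rhythmicity. Band powers are
#' Hann-periodogram band sums.
#'
#' @param x numeric signal (one source).
#' @param fs sampling rate in Hz.
#' @param window window length in seconds, default 0.5.
#' @param step hop in seconds, default 0.1.
#' @param theta_band,sigma_band Hz pairs.
#' @return a `feature_series` data frame with columns `time` (window
#'   centers, s), `theta`, `sigma`, `rhythmicity`, and attributes
#'   `window`, `step`.
#' @export
compute_features <- function(x, fs, window = 0.5, step = 0.1,
                             theta_band = c(4, 8), sigma_band = c(9, 15)) {
  n <- length(x)
  w <- round(window * fs)
  if (w > n) stop("window exceeds the signal", call. = FALSE)
  hop <- max(1L, round(step * fs))
  starts <- seq(1L, n - w + 1L, by = hop)
  out <- vapply(starts, function(i0) {
    seg <- x[i0:(i0 + w - 1L)]
    sp <- hann_periodogram(seg, fs)
    c(band_power(sp, theta_band), band_power(sp, sigma_band),
      rhythmicity(seg))
  }, numeric(3))
  fs_df <- data.frame(time = (starts - 1L + w / 2) / fs,
                      theta = out[1, ], sigma = out[2, ],
                      rhythmicity = out[3, ])
  attr(fs_df, "window") <- window
  attr(fs_df, "step") <- hop / fs
  class(fs_df) <- c("feature_series", "data.frame")
  fs_df
}

feature_matrix <- function(features, eps = 1e-12) {
  cbind(log(features$theta + eps), log(features$sigma + eps),
        features$rhythmicity)
}

gauss_logdens <- function(z, mean, cov) {
  p <- length(mean)
  ch <- chol(cov + diag(1e-9, p))
  d <- forwardsolve(t(ch), t(z) - mean)
  -0.5 * colSums(d^2) - sum(log(diag(ch))) - 0.5 * p * log(2 * pi)
}

#' Train the probabilistic spindle-state detector
#'
#' Class-conditional Gaussian (full covariance) model on the
#' log-transformed band powers plus rhythmicity, with the class prior
#' taken from the label frequencies. The posterior probability of the
#' spindle state given the three features drives detection.
#'
#' @param features a `feature_series` from [compute_features()].
#' @param labels logical per window: `TRUE` = spindle state.
#' @param threshold posterior probability threshold, default 0.95.
#' @param min_duration minimum spindle duration in seconds, default 0.5.
#' @param merge_gap supra-threshold runs closer than this merge, seconds,
#'   default 0.1.
#' @return a `detector_model`.
#' @export
train_detector <- function(features, labels, threshold = 0.95,
                           min_duration = 0.5, merge_gap = 0.1) {
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2L)
    stop("training needs both spindle and non-spindle windows",
         call. = FALSE)
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must be in (0, 1)", call. = FALSE)
  z <- feature_matrix(features)
  fit_class <- function(m) list(mean = colMeans(m), cov = stats::cov(m))
  structure(list(spindle = fit_class(z[labels, , drop = FALSE]),
                 nonspindle = fit_class(z[!labels, , drop = FALSE]),
                 prior = mean(labels), threshold = threshold,
                 min_duration = min_duration, merge_gap = merge_gap),
            class = "detector_model")
}

#' Posterior spindle-state probability per window
#'
#' Bayes rule over the two class-conditional Gaussians and the class
#' prior.
#'
#' @param features a `feature_series`.
#' @param model a `detector_model`.
#' @return numeric vector of probabilities in [0, 1].
#' @export
spindle_probability <- function(features, model) {
  z <- feature_matrix(features)
  l1 <- gauss_logdens(z, model$spindle$mean, model$spindle$cov) +
    log(model$prior)
  l0 <- gauss_logdens(z, model$nonspindle$mean, model$nonspindle$cov) +
    log(1 - model$prior)
  1 / (1 + exp(l0 - l1))
}

interval_intersect_runs <- function(onset, offset, runs) {
  # split [onset, offset) by excluded runs; return kept sub-intervals
  keep <- data.frame(onset = onset, offset = offset)
  if (is.null(runs) || nrow(runs) == 0) return(keep)
  for (j in seq_len(nrow(runs))) {
    nxt <- keep[0, ]
    for (i in seq_len(nrow(keep))) {
      a <- keep$onset[i]; b <- keep$offset[i]
      lo <- runs$onset[j]; hi <- runs$offset[j]
      if (hi <= a || lo >= b) { nxt <- rbind(nxt, keep[i, ]); next }
      if (lo > a) nxt <- rbind(nxt, data.frame(onset = a, offset = lo))
      if (hi < b) nxt <- rbind(nxt, data.frame(onset = hi, offset = b))
    }
    keep <- nxt
    if (nrow(keep) == 0) break
  }
  keep
}

#' Turn a probability series into spindle detections
#'
#' Supra-threshold runs of windows become half-open intervals spanning
#' the run's window extent; runs separated by less than `merge_gap`
#' merge; intervals are clipped at segment boundaries and at
#' excluded-mask runs; anything shorter than `min_duration` (0.5 s) is
#' discarded.
#'
#' @param prob probability series aligned with `features`.
#' @param features the `feature_series` the probabilities were computed
#'   on (provides window centers and step).
#' @param model a `detector_model` (threshold, min duration, merge gap).
#' @param mask optional logical sample mask (with `fs`) whose excluded
#'   runs detections must avoid.
#' @param fs sampling rate of `mask` in Hz.
#' @param boundaries segment-boundary times in seconds.
#' @return data frame with `onset`, `offset`, `duration` (seconds,
#'   half-open).
#' @export
detect_spindles <- function(prob, features, model, mask = NULL, fs = NULL,
                            boundaries = numeric(0)) {
  step <- attr(features, "step")
  half <- attr(features, "window") / 2
  above <- prob >= model$threshold
  out <- data.frame(onset = numeric(0), offset = numeric(0))
  if (any(above)) {
    r <- runs_from_logical(above)
    iv <- data.frame(onset = features$time[r$start] - half,
                     offset = features$time[r$end] + half)
    # merge runs separated by < merge_gap
    if (nrow(iv) > 1) {
      merged <- iv[1, ]
      for (i in 2:nrow(iv)) {
        if (iv$onset[i] - merged$offset[nrow(merged)] < model$merge_gap) {
          merged$offset[nrow(merged)] <- iv$offset[i]
        } else merged <- rbind(merged, iv[i, ])
      }
      iv <- merged
    }
    excl <- NULL
    if (!is.null(mask) && !all(mask)) {
      r0 <- runs_from_logical(!mask)
      excl <- data.frame(onset = (r0$start - 1L) / fs, offset = r0$end / fs)
    }
    if (length(boundaries) > 0)
      excl <- rbind(excl, data.frame(onset = boundaries,
                                     offset = boundaries))
    out <- do.call(rbind, lapply(seq_len(nrow(iv)), function(i) {
      interval_intersect_runs(iv$onset[i], iv$offset[i], excl)
    }))
    if (length(boundaries) > 0 && nrow(out) > 0) {
      # boundary points have zero width; split intervals crossing them
      for (b in boundaries) {
        cross <- out$onset < b & out$offset > b
        if (any(cross)) {
          pre <- out[cross, ]; post <- out[cross, ]
          pre$offset <- b; post$onset <- b
          out <- rbind(out[!cross, ], pre, post)
        }
      }
    }
  }
  out$duration <- out$offset - out$onset
  out <- out[out$duration >= model$min_duration, , drop = FALSE]
  out <- out[order(out$onset), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect spindles on every source of a recording
#'
#' Runs feature extraction, the posterior, and interval extraction per
#' source; detections respect the recording's mask and segment
#' boundaries.
#'
#' @param rec a [source_recording()].
#' @param model a `detector_model`.
#' @param window,step feature windowing in seconds.
#' @return data frame with `source`, `onset`, `offset`, `duration`.
#' @export
detect_recording <- function(rec, model, window = 0.5, step = 0.1) {
  out <- lapply(seq_len(nrow(rec$data)), function(s) {
    ft <- compute_features(rec$data[s, ], rec$fs, window, step)
    pp <- spindle_probability(ft, model)
    det <- detect_spindles(pp, ft, model, mask = rec$mask, fs = rec$fs,
                           boundaries = rec$boundaries)
    if (nrow(det) > 0) cbind(source = rec$sources$id[s], det)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(source = integer(0), onset = numeric(0),
                      offset = numeric(0), duration = numeric(0))
  out
}

#' Spindle rate
#'
#' Detections per minute of analyzable (artifact/spike-masked) time.
#'
#' @param detections detection data frame (or its row count).
#' @param analyzable_duration analyzable time in seconds (> 0).
#' @return spindles per minute.
#' @export
spindle_rate <- function(detections, analyzable_duration) {
  if (analyzable_duration <= 0)
    stop("analyzable duration must be positive", call. = FALSE)
  n <- if (is.data.frame(detections)) nrow(detections) else detections
  n / (analyzable_duration / 60)
}

#' Label feature windows from ground truth
#'
#' A window is a spindle-state window when its center lies inside a
#' ground-truth burst interval. Used to train the detector on synthetic
#' recordings.
#'
#' @param features a `feature_series`.
#' @param truth ground-truth event table (`onset`, `duration`,
#'   optionally `kind` == "spindle").
#' @return logical vector per window.
#' @export
label_windows <- function(features, truth) {
  if (!is.null(truth$kind)) truth <- truth[truth$kind == "spindle", ]
  lab <- rep(FALSE, nrow(features))
  for (i in seq_len(nrow(truth))) {
    lab <- lab | (features$time >= truth$onset[i] &
                    features$time < truth$onset[i] + truth$duration[i])
  }
  lab
}

#' Score detections against ground truth
#'
#' A detection and a true burst match when either midpoint falls inside
#' the other interval. Precision is the matched fraction of detections;
#' recall the matched fraction of true bursts.
#'
#' @param detections detection data frame (`onset`, `offset`).
#' @param truth ground-truth table (`onset`, `duration`).
#' @return list with `precision`, `recall`, `n_detected`, `n_true`.
#' @export
score_detections <- function(detections, truth) {
  if (!is.null(truth$kind)) truth <- truth[truth$kind == "spindle", ]
  t0 <- truth$onset; t1 <- truth$onset + truth$duration
  tmid <- (t0 + t1) / 2
  dmid <- (detections$onset + detections$offset) / 2
  det_hit <- vapply(seq_len(nrow(detections)), function(i) {
    any(dmid[i] >= t0 & dmid[i] < t1) ||
      any(tmid >= detections$onset[i] & tmid < detections$offset[i])
  }, logical(1))
  true_hit <- vapply(seq_len(nrow(truth)), function(j) {
    any(dmid >= t0[j] & dmid < t1[j]) ||
      any(tmid[j] >= detections$onset & tmid[j] < detections$offset)
  }, logical(1))
  list(precision = if (nrow(detections)) mean(det_hit) else NA_real_,
       recall = if (nrow(truth)) mean(true_hit) else NA_real_,
       n_detected = nrow(detections), n_true = nrow(truth))
}

#' Serialize / restore a detector model as plain text key-value pairs
#'
#' @param model a `detector_model`.
#' @param path file path.
#' @export
write_detector <- function(model, path) {
  fmt <- function(x) paste(format(x, digits = 17, trim = TRUE),
                           collapse = " ")
  writeLines(c(
    paste("spindle_mean", fmt(model$spindle$mean)),
    paste("spindle_cov", fmt(as.vector(model$spindle$cov))),
    paste("nonspindle_mean", fmt(model$nonspindle$mean)),
    paste("nonspindle_cov", fmt(as.vector(model$nonspindle$cov))),
    paste("prior", fmt(model$prior)),
    paste("threshold", fmt(model$threshold)),
    paste("min_duration", fmt(model$min_duration)),
    paste("merge_gap", fmt(model$merge_gap))), path)
  invisible(path)
}

#' @rdname write_detector
#' @export
read_detector <- function(path) {
  kv <- strsplit(readLines(path), " +")
  vals <- stats::setNames(lapply(kv, function(x) as.numeric(x[-1])),
                          vapply(kv, `[[`, "", 1))
  structure(list(
    spindle = list(mean = vals$spindle_mean,
                   cov = matrix(vals$spindle_cov, 3, 3)),
    nonspindle = list(mean = vals$nonspindle_mean,
                      cov = matrix(vals$nonspindle_cov, 3, 3)),
    prior = vals$prior, threshold = vals$threshold,
    min_duration = vals$min_duration, merge_gap = vals$merge_gap),
    class = "detector_model")
}
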