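#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so generators are pure functions of
#' their configuration (including the seed) without disturbing the
#' caller's RNG stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Simulation configuration for one synthetic source recording
#'
#' Holds the generative parameters of a single-source synthetic NREM
#' recording: a 1/f^alpha aperiodic background, Poisson-process sigma
#' bursts (the synthetic sleep spindles) and large biphasic spike
#' transients. Defaults encode the cohort's recording conditions: 407 Hz
#' source sampling rate, 10-15 Hz sigma carriers, 0.5-2 s burst
#' durations, and a mean concatenated NREM duration of 811.9 s.
#'
#' @param sampling_rate Hz, default 407.
#' @param duration seconds of signal to generate (> 0), default 811.9.
#' @param alpha aperiodic 1/f exponent of the background (power ~
#'   1/f^alpha), default 2 (typical of NREM sleep EEG; steeper than the
#'   1.5 artifact threshold so clean background is never flagged).
#' @param burst_rate sigma bursts per minute, default 1.84 (control-group
#'   mean spindle rate).
#' @param burst_freq_range Hz pair, carrier frequencies drawn uniformly,
#'   default c(10, 15).
#' @param burst_dur_range seconds pair, burst durations drawn uniformly,
#'   default c(0.5, 2).
#' @param burst_snr burst peak amplitude as a multiple of the background
#'   RMS, default 3.
#' @param spike_rate spike transients per minute, default 0.
#' @param spike_snr spike peak amplitude as a multiple of background RMS,
#'   default 10.
#' @param synchrony_target fraction in [0, 1] of spindle time shared
#'   across hemispheres for bilateral simulations, default 0.6.
#' @param seed integer RNG seed.
#'
#' @return a `sim_config` list.
#' @export
sim_config <- function(sampling_rate = 407, duration = 811.9, alpha = 2,
                       burst_rate = 1.84, burst_freq_range = c(10, 15),
                       burst_dur_range = c(0.5, 2), burst_snr = 3,
                       spike_rate = 0, spike_snr = 10,
                       synchrony_target = 0.6, seed = 1L) {
  if (duration <= 0) stop("duration must be positive", call. = FALSE)
  if (sampling_rate <= 0) stop("sampling_rate must be positive", call. = FALSE)
  if (synchrony_target < 0 || synchrony_target > 1)
    stop("synchrony_target must be in [0, 1]", call. = FALSE)
  if (burst_dur_range[1] <= 0 || burst_dur_range[2] > duration)
    stop("burst_dur_range must lie within (0, duration)", call. = FALSE)
  if (burst_rate < 0 || spike_rate < 0)
    stop("event rates must be non-negative", call. = FALSE)
  structure(list(sampling_rate = sampling_rate, duration = duration,
                 alpha = alpha, burst_rate = burst_rate,
                 burst_freq_range = burst_freq_range,
                 burst_dur_range = burst_dur_range, burst_snr = burst_snr,
                 spike_rate = spike_rate, spike_snr = spike_snr,
                 synchrony_target = synchrony_target, seed = seed),
            class = "sim_config")
}

#' Simulate 1/f^alpha background activity
#'
#' Generates a zero-mean Gaussian signal whose expected power spectrum
#' follows 1/f^alpha, by shaping the Fourier coefficients of white noise
#' with f^(-alpha/2) (DC removed). The output is standardized to unit
#' sample standard deviation, which leaves the spectral shape untouched.
#'
#' @param config a [sim_config()].
#' @return numeric vector of length `round(duration * sampling_rate)`.
#' @export
simulate_background <- function(config) {
  n <- round(config$duration * config$sampling_rate)
  if (n < 2) stop("need at least 2 samples of background", call. = FALSE)
  with_seed(config$seed, {
    w <- stats::rnorm(n)
    xf <- stats::fft(w)
    # two-sided frequency axis; bin k pairs with n - k
    f <- (seq_len(n) - 1) / n * config$sampling_rate
    f <- pmin(f, config$sampling_rate - f)
    shape <- ifelse(f > 0, f^(-config$alpha / 2), 0)
    x <- Re(stats::fft(xf * shape, inverse = TRUE)) / n
    x <- x - mean(x)
    x / stats::sd(x)
  })
}

#' Simulate a Poisson event train
#'
#' Event count is Poisson(rate * total); onsets are uniform; overlapping
#' draws are rejected and redrawn (up to 100 attempts per event) so that
#' accepted events are discrete and non-overlapping, as spindles are on a
#' single source. Durations are uniform in `dur_range`, carrier
#' frequencies uniform in `freq_range`.
#'
#' @param rate events per minute (>= 0).
#' @param total total duration in seconds.
#' @param dur_range seconds pair.
#' @param freq_range Hz pair.
#' @param amplitude amplitude attached to each event (multiple of
#'   background RMS at render time).
#' @param seed integer seed.
#'
#' @return an `event_train`: data frame with columns `onset`, `duration`,
#'   `freq`, `amplitude`, sorted by onset, plus attribute
#'   `total_duration`.
#' @export
simulate_event_train <- function(rate, total, dur_range = c(0.5, 2),
                                 freq_range = c(10, 15), amplitude = 1,
                                 seed = 1L) {
  if (rate < 0) stop("rate must be non-negative", call. = FALSE)
  if (dur_range[1] <= 0)
    stop("duration range lower bound must be positive", call. = FALSE)
  ev <- with_seed(seed, {
    n <- stats::rpois(1L, rate / 60 * total)
    acc <- data.frame(onset = numeric(0), duration = numeric(0),
                      freq = numeric(0), amplitude = numeric(0))
    for (i in seq_len(n)) {
      for (try in seq_len(100L)) {
        dur <- stats::runif(1L, dur_range[1], min(dur_range[2], total))
        ons <- stats::runif(1L, 0, total - dur)
        clash <- nrow(acc) > 0 &&
          any(ons < acc$onset + acc$duration & acc$onset < ons + dur)
        if (!clash) {
          acc <- rbind(acc, data.frame(
            onset = ons, duration = dur,
            freq = stats::runif(1L, freq_range[1], freq_range[2]),
            amplitude = amplitude))
          break
        }
      }
    }
    acc
  })
  ev <- ev[order(ev$onset), , drop = FALSE]
  rownames(ev) <- NULL
  attr(ev, "total_duration") <- total
  class(ev) <- c("event_train", "data.frame")
  ev
}

empty_event_train <- function(total) {
  ev <- data.frame(onset = numeric(0), duration = numeric(0),
                   freq = numeric(0), amplitude = numeric(0))
  attr(ev, "total_duration") <- total
  class(ev) <- c("event_train", "data.frame")
  ev
}

# 70 ms biphasic spike template: a sharp (few-ms) positive transient
# followed by a slower negative after-wave. The fast rise carries the
# broadband spectral content that flattens the 30-95 Hz slope, which is
# the only property downstream stages rely on.
spike_template <- function(fs, width = 0.07) {
  n <- max(3L, round(width * fs))
  t <- (seq_len(n) - 1) / fs
  tp <- 0.1 * width
  sharp <- exp(-abs(t - tp) / 0.002)
  after <- -0.45 * exp(-pmax(0, t - tp - 0.004) / 0.02) *
    (t > tp + 0.004)
  sharp + after
}

#' Render a single-source recording from background and event trains
#'
#' Sigma bursts are added as sine carriers under a Hann envelope with
#' peak amplitude `event amplitude x snr x background RMS`; spikes are
#' added as a fixed 70 ms biphasic template scaled by the spike train's
#' amplitude times the background RMS. Ground truth for every rendered
#' event is retained in the recording's `truth` table for detector
#' scoring.
#'
#' @param background numeric background signal (see
#'   [simulate_background()]).
#' @param events an `event_train` of sigma bursts (or `NULL`).
#' @param spikes an `event_train` of spike transients (or `NULL`);
#'   the `amplitude` column is the multiple of background RMS.
#' @param snr burst peak amplitude multiplier (times each event's own
#'   `amplitude`), in background-RMS units.
#' @param fs sampling rate in Hz.
#' @param subject,hemisphere,label metadata for the source table.
#' @return a [source_recording()] with `truth` listing all rendered events.
#' @export
render_recording <- function(background, events = NULL, spikes = NULL,
                             snr = 3, fs = 407, subject = "sim",
                             hemisphere = "lh", label = "inferiorRolandic") {
  n <- length(background)
  total <- n / fs
  check_train <- function(tr, what) {
    if (!is.null(tr) && nrow(tr) > 0) {
      if (abs(attr(tr, "total_duration") - total) > 1 / fs)
        stop(what, " train duration does not match background", call. = FALSE)
      if (any(tr$onset + tr$duration > total + 1e-9))
        stop(what, " event extends past the recording", call. = FALSE)
    }
  }
  check_train(events, "burst"); check_train(spikes, "spike")
  x <- background
  rms <- sqrt(mean(background^2))
  truth <- NULL
  if (!is.null(events) && nrow(events) > 0) {
    for (i in seq_len(nrow(events))) {
      i0 <- floor(events$onset[i] * fs) + 1L
      len <- max(2L, round(events$duration[i] * fs))
      i1 <- min(n, i0 + len - 1L)
      idx <- i0:i1
      tt <- (idx - i0) / fs
      env <- 0.5 - 0.5 * cos(2 * pi * (seq_along(idx) - 1) / (length(idx) - 1))
      x[idx] <- x[idx] + events$amplitude[i] * snr * rms *
        env * sin(2 * pi * events$freq[i] * tt)
    }
    truth <- data.frame(events, kind = "spindle")
  }
  if (!is.null(spikes) && nrow(spikes) > 0) {
    tpl <- spike_template(fs)
    for (i in seq_len(nrow(spikes))) {
      i0 <- floor(spikes$onset[i] * fs) + 1L
      idx <- i0:min(n, i0 + length(tpl) - 1L)
      x[idx] <- x[idx] + spikes$amplitude[i] * rms * tpl[seq_along(idx)]
    }
    truth <- rbind(truth, data.frame(spikes, kind = "spike"))
  }
  source_recording(
    matrix(x, nrow = 1L), fs = fs,
    sources = data.frame(id = 1L, hemisphere = hemisphere, label = label,
                         stringsAsFactors = FALSE),
    subject = subject, truth = truth)
}

#' Simulate one recording from a configuration
#'
#' Convenience wrapper: background, burst train and spike train drawn
#' from `config` (sub-seeds derived deterministically), rendered into a
#' single-source recording.
#'
#' @param config a [sim_config()].
#' @inheritParams render_recording
#' @return a [source_recording()].
#' @export
simulate_recording <- function(config, subject = "sim", hemisphere = "lh",
                               label = "inferiorRolandic") {
  bg <- simulate_background(config)
  ev <- simulate_event_train(config$burst_rate, config$duration,
                             config$burst_dur_range,
                             config$burst_freq_range,
                             seed = config$seed + 1000L)
  sp <- if (config$spike_rate > 0)
    simulate_event_train(config$spike_rate, config$duration,
                         dur_range = c(0.07, 0.071),
                         freq_range = c(0, 0),
                         amplitude = config$spike_snr,
                         seed = config$seed + 2000L)
  else NULL
  render_recording(bg, ev, sp, snr = config$burst_snr,
                   fs = config$sampling_rate, subject = subject,
                   hemisphere = hemisphere, label = label)
}

#' Simulate left/right spindle trains with controlled synchrony
#'
#' A fraction of spindle events is shared across hemispheres (duplicated
#' with onset jitter at most 0.1 s); the remainder occur independently in
#' each hemisphere. Rates are balanced so each hemisphere sees `rate`
#' events/min and the expected indicator overlap/union statistic equals
#' `synchrony_target`: shared events arrive at rate 2T/(1+T) x rate and
#' independent events at (1-T)/(1+T) x rate per hemisphere.
#'
#' @param rate per-hemisphere spindle rate, events/min.
#' @param synchrony_target fraction in [0, 1].
#' @param total duration in seconds.
#' @param dur_range,freq_range event parameter ranges.
#' @param seed integer seed.
#' @return list with `left` and `right` event trains.
#' @export
simulate_bilateral_trains <- function(rate, synchrony_target, total,
                                      dur_range = c(0.5, 2),
                                      freq_range = c(10, 15), seed = 1L) {
  if (synchrony_target < 0 || synchrony_target > 1)
    stop("synchrony_target must be in [0, 1]", call. = FALSE)
  tt <- synchrony_target
  shared_rate <- rate * 2 * tt / (1 + tt)
  indep_rate <- rate * (1 - tt) / (1 + tt)
  shared <- simulate_event_train(shared_rate, total, dur_range, freq_range,
                                 seed = seed)
  lo <- simulate_event_train(indep_rate, total, dur_range, freq_range,
                             seed = seed + 1L)
  ro <- simulate_event_train(indep_rate, total, dur_range, freq_range,
                             seed = seed + 2L)
  jit <- with_seed(seed + 3L, stats::runif(max(1L, nrow(shared)), -0.1, 0.1))
  rshared <- shared
  if (nrow(shared) > 0) {
    rshared$onset <- pmin(pmax(shared$onset + jit[seq_len(nrow(shared))], 0),
                          total - shared$duration)
  }
  finish <- function(a, b) {
    ev <- rbind(as.data.frame(a), as.data.frame(b))
    ev <- ev[order(ev$onset), , drop = FALSE]
    rownames(ev) <- NULL
    attr(ev, "total_duration") <- total
    class(ev) <- c("event_train", "data.frame")
    ev
  }
  list(left = finish(shared, lo), right = finish(rshared, ro))
}
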