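#' Single-taper Hann periodogram
#'
#' One-sided power spectral density of a short interval under a single
#' Hann taper, normalized so that the bin sum times the bin width equals
#' the signal variance (Parseval).
#'
#' @param x numeric signal.
#' @param fs sampling rate in Hz.
#' @return list with `frequency` (0..Nyquist grid, spacing fs/n) and
#'   `power`.
#' @export
hann_periodogram <- function(x, fs) {
  n <- length(x)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  xw <- (x - mean(x)) * w
  xf <- stats::fft(xw)
  nh <- floor(n / 2) + 1L
  p <- (Mod(xf[seq_len(nh)])^2) / (fs * sum(w^2))
  # fold the negative-frequency half into interior bins
  interior <- 2:(nh - 1L)
  if (n %% 2 == 0) interior <- 2:(nh - 1L) else interior <- 2:nh
  p[interior] <- 2 * p[interior]
  list(frequency = (seq_len(nh) - 1L) * fs / n, power = p)
}

power_spectrum <- function(frequency, power, window,
                          normalization = "absolute") {
  structure(list(frequency = frequency, power = power, window = window,
                 normalization = normalization),
            class = "power_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("<power_spectrum> %d bins, df=%.3g Hz, window=%g s, %s\n",
              length(x$frequency), x$frequency[2] - x$frequency[1],
              x$window, x$normalization))
  invisible(x)
}

#' Windowed average power spectrum
#'
#' Averages single-Hann-taper periodograms over non-overlapping windows
#' (1 s by default, giving a 1 Hz frequency resolution), using only
#' windows in which every sample is analyzable under the mask.
#'
#' @param x numeric signal (one source).
#' @param fs sampling rate in Hz.
#' @param mask logical analyzable-sample mask (default: all analyzable).
#' @param window window length in seconds.
#' @return a `power_spectrum` (absolute normalization).
#' @export
psd_windowed <- function(x, fs, mask = NULL, window = 1) {
  n <- length(x)
  w <- round(window * fs)
  if (is.null(mask)) mask <- rep(TRUE, n)
  nwin <- n %/% w
  acc <- NULL
  used <- 0L
  for (k in seq_len(nwin)) {
    idx <- ((k - 1L) * w + 1L):(k * w)
    if (!all(mask[idx])) next
    sp <- hann_periodogram(x[idx], fs)
    acc <- if (is.null(acc)) sp$power else acc + sp$power
    used <- used + 1L
    freq <- sp$frequency
  }
  if (used == 0L)
    stop("no fully analyzable window available", call. = FALSE)
  power_spectrum(freq, acc / used, window)
}

#' Average several spectra on a shared grid
#'
#' Used to pool all sources of a region into one label spectrum.
#'
#' @param spectra list of `power_spectrum` objects on identical grids.
#' @return a `power_spectrum`.
#' @export
average_spectra <- function(spectra) {
  p <- Reduce(`+`, lapply(spectra, function(s) s$power)) / length(spectra)
  power_spectrum(spectra[[1]]$frequency, p, spectra[[1]]$window,
                 spectra[[1]]$normalization)
}

#' Relative power spectrum
#'
#' Divides the spectrum by its summed power over 0-50 Hz, so the
#' relative power sums to one across that range. Idempotent; invariant
#' to signal scaling.
#'
#' @param spec a `power_spectrum`.
#' @param norm_band Hz pair defining the normalization range (closed),
#'   default c(0, 50).
#' @return a `power_spectrum` with normalization "relative".
#' @export
relative_power <- function(spec, norm_band = c(0, 50)) {
  sel <- spec$frequency >= norm_band[1] & spec$frequency <= norm_band[2]
  tot <- sum(spec$power[sel])
  if (tot <= 0) stop("total power in the normalization band is zero",
                     call. = FALSE)
  power_spectrum(spec$frequency, spec$power / tot, spec$window, "relative")
}

#' Sigma power of a spectrum
#'
#' Mean (relative) power over the closed sigma band, 10-15 Hz by
#' default.
#'
#' @param spec a `power_spectrum` (typically relative).
#' @param band closed Hz pair, default c(10, 15).
#' @return scalar mean power.
#' @export
sigma_power <- function(spec, band = c(10, 15)) {
  sel <- spec$frequency >= band[1] & spec$frequency <= band[2]
  if (!any(sel)) stop("spectrum does not cover the sigma band",
                      call. = FALSE)
  mean(spec$power[sel])
}

#' Sigma bump of a spectrum
#'
#' Approximates sigma-band activity above the aperiodic background: a
#' line is fit between the power at the bins nearest 10 and 15 Hz, the
#' line is subtracted, and positive residuals are summed over the band.
#' Exactly zero for any spectrum linear (or flat) across the band.
#'
#' @param spec a `power_spectrum`.
#' @param band closed Hz pair, default c(10, 15).
#' @return non-negative scalar.
#' @export
sigma_bump <- function(spec, band = c(10, 15)) {
  f <- spec$frequency
  sel <- f >= band[1] & f <= band[2]
  if (!any(sel)) stop("spectrum does not cover the sigma band",
                      call. = FALSE)
  i0 <- which.min(abs(f - band[1]))
  i1 <- which.min(abs(f - band[2]))
  slope <- (spec$power[i1] - spec$power[i0]) / (f[i1] - f[i0])
  chord <- spec$power[i0] + slope * (f[sel] - f[i0])
  resid <- spec$power[sel] - chord
  sum(resid[resid > 0])
}

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' First `K = 2*TW - 1` Slepian sequences for `N` samples at
#' time-half-bandwidth product `TW`, computed from the classical
#' symmetric tridiagonal eigenproblem and orthonormalized. With a 2 s
#' window and 2.5 Hz half-bandwidth, TW = 5 and K = 9 tapers.
#'
#' @param N samples per window (>= 2).
#' @param TW time-half-bandwidth product (>= 1).
#' @param K taper count, default `2*TW - 1` (must be <= `2*TW - 1`).
#' @return a `taper_set`: list with `tapers` (K x N, rows orthonormal),
#'   `TW`, `K`.
#' @export
dpss_tapers <- function(N, TW, K = 2 * TW - 1) {
  if (N < 2 || TW < 1) stop("need N >= 2 and TW >= 1", call. = FALSE)
  if (K > 2 * TW - 1) stop("K must be <= 2*TW - 1", call. = FALSE)
  if (2 * TW >= N) stop("TW too large for N", call. = FALSE)
  W <- TW / N
  t <- 0:(N - 1)
  diag_main <- ((N - 1 - 2 * t) / 2)^2 * cos(2 * pi * W)
  diag_off <- (1:(N - 1)) * (N - (1:(N - 1))) / 2
  A <- matrix(0, N, N)
  A[cbind(t + 1, t + 1)] <- diag_main
  A[cbind(1:(N - 1), 2:N)] <- diag_off
  A[cbind(2:N, 1:(N - 1))] <- diag_off
  eg <- eigen(A, symmetric = TRUE)
  tp <- t(eg$vectors[, seq_len(K), drop = FALSE])
  # sign convention: symmetric tapers have positive mean, antisymmetric
  # ones start on an up-slope
  for (k in seq_len(K)) {
    s <- sum(tp[k, ])
    if (abs(s) > 1e-10) {
      if (s < 0) tp[k, ] <- -tp[k, ]
    } else if (tp[k, 2] - tp[k, 1] < 0) tp[k, ] <- -tp[k, ]
  }
  structure(list(tapers = tp, TW = TW, K = K), class = "taper_set")
}

#' Multitaper magnitude-squared coherence at one frequency
#'
#' Tapers both signals with each Slepian sequence, averages cross- and
#' auto-spectra over tapers, and evaluates
#' `|Sxy|^2 / (Sxx * Syy)` at the frequency bin nearest `eval_freq`
#' (12.5 Hz covering 12.5 +/- 2.5 Hz in the sigma-coherence setting).
#'
#' @param x,y equal-length numeric signals.
#' @param tapers a `taper_set` from [dpss_tapers()] with N matching the
#'   signal length.
#' @param fs sampling rate in Hz.
#' @param eval_freq evaluation frequency in Hz, default 12.5.
#' @return coherence in [0, 1].
#' @export
multitaper_coherence <- function(x, y, tapers, fs, eval_freq = 12.5) {
  n <- length(x)
  if (length(y) != n) stop("signals must have equal length", call. = FALSE)
  if (ncol(tapers$tapers) != n)
    stop("taper length does not match the signals", call. = FALSE)
  bin <- which.min(abs((0:(n - 1)) * fs / n - eval_freq))
  xf <- stats::mvfft(t(tapers$tapers * rep(x, each = tapers$K)))[bin, ]
  yf <- stats::mvfft(t(tapers$tapers * rep(y, each = tapers$K)))[bin, ]
  sxx <- mean(Mod(xf)^2)
  syy <- mean(Mod(yf)^2)
  if (sxx <= 0 || syy <= 0)
    stop("zero-power signal: coherence undefined", call. = FALSE)
  sxy <- mean(xf * Conj(yf))
  min(1, Mod(sxy)^2 / (sxx * syy))
}

#' Export a spectrum as two-column delimited text
#'
#' @param spec a `power_spectrum`.
#' @param path output path.
#' @export
write_spectrum <- function(spec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# normalization: %s  window_s: %g",
                     spec$normalization, spec$window), con)
  utils::write.table(
    data.frame(frequency = spec$frequency, power = spec$power),
    con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
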