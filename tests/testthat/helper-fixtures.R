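# Shared fixtures, built in code at test time.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# 2-s Slepian taper set at 407 Hz (the sigma-coherence configuration);
# the eigendecomposition is costly, so share it across tests
tapers_2s <- function() cached("tapers814", dpss_tapers(814L, 5))

# a trained detector plus a held-out labelled recording, shared by the
# detector tests and the acceptance suite
detector_fixture <- function(snr = 2, seed = 101L) {
  cached(paste0("det", snr, "_", seed), {
    tr <- simulate_recording(sim_config(duration = 600, burst_rate = 3,
                                        burst_snr = snr, seed = seed))
    ft <- compute_features(tr$data[1, ], tr$fs)
    model <- train_detector(ft, label_windows(ft, tr$truth))
    te <- simulate_recording(sim_config(duration = 600, burst_rate = 2,
                                        burst_snr = snr, seed = seed + 1L))
    fte <- compute_features(te$data[1, ], te$fs)
    prob <- spindle_probability(fte, model)
    list(model = model, test_rec = te, test_features = fte, prob = prob,
         detections = detect_spindles(prob, fte, model))
  })
}

# least-squares log-log slope of an averaged periodogram; independent
# check used against the generators (not the package's spectral_slope)
oracle_loglog_slope <- function(x, fs, band = c(30, 95), win_s = 1) {
  w <- round(win_s * fs)
  nwin <- length(x) %/% w
  acc <- 0
  for (k in seq_len(nwin)) {
    seg <- x[((k - 1) * w + 1):(k * w)]
    seg <- seg - mean(seg)
    p <- Mod(stats::fft(seg))^2
    acc <- acc + p[1:(w %/% 2 + 1)]
  }
  f <- (0:(w %/% 2)) * fs / w
  sel <- f >= band[1] & f <= band[2]
  unname(coef(lm(log10(acc[sel]) ~ log10(f[sel])))[2])
}

# long cohort format used by the group models
cohort_long <- function(tab) {
  data.frame(subject = rep(tab$subject, 2), group = rep(tab$group, 2),
             age = rep(tab$age, 2),
             count = c(tab$count_lh, tab$count_rh),
             minutes = rep(tab$minutes, 2))
}

# null-world regional count table: every region shares one rate process
null_regional_data <- function(n_per_group = 20, regions = 31,
                               seed = 1L) {
  spec <- cohort_spec(
    n_per_group = c(active = n_per_group, resolved = n_per_group,
                    control = n_per_group),
    group_rate_means = c(active = 1.84, resolved = 1.84, control = 1.84),
    rate_dispersion = 2, seed = seed)
  do.call(rbind, lapply(seq_len(regions), function(r) {
    spec$seed <- seed + 1000L * r
    tab <- simulate_cohort(spec)$table
    cbind(region = sprintf("region%02d", r), cohort_long(tab))
  }))
}
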