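test_that("spindle sigma power matches an explicit DFT oracle", {
  fs <- 407
  expect_equal(spindle_sigma_power(rep(0, fs), fs), 0)

  seg <- sin(2 * pi * 12.5 * (0:(fs - 1)) / fs)
  got <- spindle_sigma_power(seg, fs)
  # oracle: direct DFT of the Hann-windowed, zero-padded segment
  n <- fs
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
  xp <- c(seg * w, rep(0, round(4 * fs) - n))
  np <- length(xp)
  freq <- (0:(np - 1)) * fs / np
  bins <- which(freq >= 10.25 & freq <= 14.75)
  pows <- vapply(bins, function(b) {
    k <- b - 1
    re <- sum(xp * cos(-2 * pi * k * (0:(np - 1)) / np))
    im <- sum(xp * sin(-2 * pi * k * (0:(np - 1)) / np))
    2 * (re^2 + im^2) / (fs * sum(w^2))
  }, numeric(1))
  expect_equal(length(bins), 19)  # 0.25 Hz grid across 10.25-14.75 Hz
  expect_equal(got, mean(pows), tolerance = 1e-10)

  expect_equal(spindle_sigma_power(2 * seg, fs), 4 * got,
               tolerance = 1e-12)
  expect_error(spindle_sigma_power(numeric(0), fs), "empty")
})

test_that("indicator vectors union detections sample-wise", {
  fs <- 100
  expect_equal(indicator_vector(NULL, 500, fs), integer(500))

  det <- data.frame(onset = c(1, 1.5), offset = c(2, 2.5))
  ind <- indicator_vector(det, 500, fs)
  on <- which(ind == 1)
  expect_equal(min(on), 101)
  expect_equal(max(on), 250)
  expect_equal(sum(ind), 150)
  # covered time equals the interval-union length
  expect_equal(sum(ind) / fs, 1.5)
  expect_error(indicator_vector(data.frame(onset = 4, offset = 9),
                                500, fs), "outside")
})

test_that("spindle epochs are 2 s around run midpoints, clipped at edges", {
  fs <- 100
  ind <- integer(30 * fs)
  ind[(10 * fs + 1):(11 * fs)] <- 1L   # run [10, 11) s
  ind[1:(0.4 * fs)] <- 1L              # run at the record start
  ind[(20 * fs + 1):(20.6 * fs)] <- 1L
  ep <- spindle_epochs(ind, fs)
  expect_equal(nrow(ep), 2)            # start run dropped by clipping
  expect_equal(ep$center[1], 10.5, tolerance = 0.02)
  expect_equal(ep$end - ep$start + 1L, rep(2L * fs, 2))
  expect_equal((ep$start[1] - 1) / fs, 9.5, tolerance = 0.02)
  # epoch count equals the maximal-run count away from edges
  r <- rle(ind)
  expect_equal(sum(ind == 1 & FALSE) + nrow(ep),
               sum(r$values == 1L) - 1L)
})

test_that("intra-hemispheric coherence averages participant pairs", {
  fs <- 407
  tp <- tapers_2s()
  n <- 20 * fs
  set.seed(61)
  shared <- sin(2 * pi * 12.5 * (1:n) / fs)
  dat <- rbind(shared, shared, rnorm(n))
  rec <- source_recording(dat, fs,
                          sources = data.frame(id = 1:3,
                                               hemisphere = "lh",
                                               label = "roi"))
  det <- data.frame(source = c(1L, 2L), onset = c(8, 8.1),
                    offset = c(9.2, 9.3))
  expect_equal(intra_coherence(rec, det, tp), 1, tolerance = 1e-6)

  # independent-noise participants: small-sample bias level ~ 1/K
  set.seed(62)
  vals <- vapply(1:15, function(i) {
    recn <- source_recording(matrix(rnorm(2 * n), 2), fs,
                             sources = data.frame(id = 1:2,
                                                  hemisphere = "lh",
                                                  label = "roi"))
    intra_coherence(recn, det, tp)
  }, numeric(1))
  expect_lt(mean(vals), 0.35)

  # single-participant epochs are skipped without error -> NA overall
  det1 <- data.frame(source = 1L, onset = 8, offset = 9.2)
  expect_true(is.na(intra_coherence(rec, det1, tp)))
})

test_that("inter-hemispheric coherence needs simultaneous spindles", {
  fs <- 407
  tp <- tapers_2s()
  n <- 20 * fs
  set.seed(63)
  x <- matrix(rnorm(n), 1)
  left <- source_recording(x, fs,
                           sources = data.frame(id = 1L,
                                                hemisphere = "lh",
                                                label = "roi"))
  right <- source_recording(x, fs,
                            sources = data.frame(id = 1L,
                                                 hemisphere = "rh",
                                                 label = "roi"))
  det <- data.frame(source = 1L, onset = 10, offset = 11)
  expect_equal(inter_coherence(left, right, det, det, tp), 1,
               tolerance = 1e-6)

  disjoint <- data.frame(source = 1L, onset = 15, offset = 16)
  expect_true(is.na(inter_coherence(left, right, det, disjoint, tp)))
})

test_that("bilateral synchrony is overlap over union of indicators", {
  expect_equal(bilateral_synchrony(c(0, 1, 1, 0), c(0, 1, 1, 0)), 1)
  expect_equal(bilateral_synchrony(c(1, 1, 0, 0), c(0, 0, 1, 1)), 0)
  expect_equal(bilateral_synchrony(integer(10), integer(10)), 0)

  # overlap 9 samples, union 11 samples -> 9/11
  l <- c(rep(1L, 10), 0L)
  r <- c(0L, rep(1L, 10))
  expect_equal(bilateral_synchrony(l, r), 9 / 11)
  expect_equal(bilateral_synchrony(r, l), 9 / 11)
  expect_equal(bilateral_synchrony(c(l, integer(50)), c(r, integer(50))),
               9 / 11)
  expect_error(bilateral_synchrony(l, r[-1]), "length")
})

test_that("the per-subject feature table assembles all statistics", {
  fs <- 407
  n <- 30 * fs
  set.seed(64)
  base <- sin(2 * pi * 12.5 * (1:n) / fs) + 0.3 * rnorm(n)
  left <- source_recording(rbind(base, base + 0.05 * rnorm(n)), fs,
                           sources = data.frame(id = 1:2,
                                                hemisphere = "lh",
                                                label = "roi"),
                           subject = "s1")
  right <- source_recording(matrix(base, 1), fs,
                            sources = data.frame(id = 1L,
                                                 hemisphere = "rh",
                                                 label = "roi"),
                            subject = "s1")
  dl <- data.frame(source = c(1L, 2L), onset = c(5, 5),
                   offset = c(6.2, 6.2))
  dr <- data.frame(source = 1L, onset = 5.1, offset = 6.1)
  ft <- spindle_feature_table(left, right, dl, dr, tapers_2s())
  expect_equal(ft$n_spindles_lh, 2)
  expect_equal(ft$rate_rh, 2)           # 1 spindle in 0.5 min
  expect_gt(ft$intra_coh_lh, 0.9)
  expect_gt(ft$inter_coh, 0.9)
  expect_gt(ft$synchrony, 0.7)
  expect_true(is.na(ft$intra_coh_rh))   # one source only
})
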