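test_that("features separate theta, sigma and rhythmic content", {
  fs <- 407
  t <- (0:(4 * fs - 1)) / fs
  f12 <- compute_features(sin(2 * pi * 12 * t), fs)
  expect_true(all(f12$sigma > 10 * f12$theta))
  expect_true(all(f12$rhythmicity > 0.9))

  f6 <- compute_features(sin(2 * pi * 6 * t), fs)
  expect_true(all(f6$theta > 10 * f6$sigma))

  set.seed(51)
  noise <- rnorm(4 * fs)
  fn <- compute_features(noise, fs)
  expect_lt(mean(fn$rhythmicity), min(f12$rhythmicity))

  # rhythmicity oracle: explicit extrema-interval CV on one window
  win <- noise[1:204]
  pk <- c(); tr <- c()
  for (i in 2:203) {
    if (win[i] > win[i - 1] && win[i] > win[i + 1]) pk <- c(pk, i)
    if (win[i] < win[i - 1] && win[i] < win[i + 1]) tr <- c(tr, i)
  }
  iv <- c(diff(pk), diff(tr))
  expect_equal(rhythmicity(win), 1 / (1 + sd(iv) / mean(iv)))
  expect_equal(rhythmicity(seq_len(50)), 0) # monotone: no extrema
})

test_that("posterior matches an explicit Bayes computation", {
  set.seed(52)
  n <- 400
  ft <- data.frame(time = seq_len(2 * n) / 10,
                   theta = exp(rnorm(2 * n)),
                   sigma = exp(c(rnorm(n, 0), rnorm(n, 3))),
                   rhythmicity = c(runif(n, 0.2, 0.6),
                                   runif(n, 0.6, 1)))
  attr(ft, "window") <- 0.5
  attr(ft, "step") <- 0.1
  lab <- rep(c(FALSE, TRUE), each = n)
  m <- train_detector(ft, lab)
  p <- spindle_probability(ft, m)
  expect_true(all(p >= 0 & p <= 1))

  # explicit Bayes rule on ten windows
  z <- cbind(log(ft$theta + 1e-12), log(ft$sigma + 1e-12),
             ft$rhythmicity)
  dens <- function(zi, cl) {
    S <- cl$cov + diag(1e-9, 3)
    exp(-0.5 * drop(t(zi - cl$mean) %*% solve(S) %*% (zi - cl$mean))) /
      sqrt((2 * pi)^3 * det(S))
  }
  for (i in seq(1, 2 * n, length.out = 10)) {
    num <- m$prior * dens(z[i, ], m$spindle)
    den <- num + (1 - m$prior) * dens(z[i, ], m$nonspindle)
    expect_equal(p[i], num / den, tolerance = 1e-8)
  }

  # identical class distributions: posterior hugs the prior
  ft0 <- ft
  ft0$sigma <- exp(rnorm(2 * n))
  ft0$rhythmicity <- runif(2 * n)
  m0 <- train_detector(ft0, lab)
  p0 <- spindle_probability(ft0, m0)
  expect_lt(abs(mean(p0) - m0$prior), 0.1)
  expect_error(train_detector(ft, rep(TRUE, 2 * n)), "both")
})

test_that("training on separable classes generalizes; permuted labels do not", {
  fx <- detector_fixture(snr = 2)
  held <- fx$test_features
  truth_lab <- label_windows(held, fx$test_rec$truth)
  pred <- spindle_probability(held, fx$model) > 0.5
  expect_gt(mean(pred == truth_lab), 0.95)

  tr <- simulate_recording(sim_config(duration = 300, burst_rate = 3,
                                      burst_snr = 2, seed = 53))
  ft <- compute_features(tr$data[1, ], tr$fs)
  lab <- label_windows(ft, tr$truth)
  set.seed(530)
  perm <- sample(lab)
  mp <- train_detector(ft, perm)
  # permuted training destroys the classes: spindle windows are no
  # longer recovered above the prior level
  sens <- mean(spindle_probability(ft, mp)[lab] > 0.5)
  expect_lt(sens, 0.3)
})

test_that("interval extraction respects duration, gaps, masks, boundaries", {
  mkft <- function(times) {
    ft <- data.frame(time = times, theta = 1, sigma = 1, rhythmicity = 0.5)
    attr(ft, "window") <- 0.5
    attr(ft, "step") <- 0.1
    ft
  }
  m <- structure(list(threshold = 0.95, min_duration = 0.5,
                      merge_gap = 0.1), class = "detector_model")
  times <- seq(0.25, 59.75, by = 0.1)
  ft <- mkft(times)

  expect_equal(nrow(detect_spindles(rep(0, length(times)), ft, m)), 0)

  # a 0.3-s supra-threshold stretch of window centers is too short
  p <- as.numeric(times >= 10 & times <= 10.3) * 0.2
  expect_equal(nrow(detect_spindles(p, ft, m)), 0)

  p <- as.numeric(times >= 10 & times <= 11.2)
  det <- detect_spindles(p, ft, m)
  expect_equal(nrow(det), 1)
  expect_gte(det$duration, 0.5)
  expect_lt(abs(det$onset - (10 - 0.25)), 0.11)
  expect_lt(abs(det$offset - (11.2 + 0.25)), 0.11)

  # monotonicity: on detector posteriors (well-separated bursts),
  # raising the threshold never adds detections
  fx <- detector_fixture(snr = 2)
  counts <- vapply(c(0.3, 0.5, 0.7, 0.9, 0.99), function(th) {
    mm <- fx$model; mm$threshold <- th
    nrow(detect_spindles(fx$prob, fx$test_features, mm))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))

  # detections are clipped at excluded-mask runs and boundaries
  fs <- 407
  mask <- rep(TRUE, 60 * fs)
  mask[(10.5 * fs):(10.7 * fs)] <- FALSE
  p <- as.numeric(times >= 9.5 & times <= 12)
  det2 <- detect_spindles(p, ft, m, mask = mask, fs = fs)
  for (i in seq_len(nrow(det2)))
    expect_true(det2$offset[i] <= 10.5 + 1e-6 ||
                  det2$onset[i] >= 10.7 - 2 / fs)
  det3 <- detect_spindles(p, ft, m, boundaries = 11)
  expect_true(all(det3$offset <= 11 | det3$onset >= 11))
  expect_equal(nrow(det3), 2)
})

test_that("detector meets recall and precision 0.8 at SNR 2", {
  fx <- detector_fixture(snr = 2)
  sc <- score_detections(fx$detections, fx$test_rec$truth)
  expect_gte(sc$precision, 0.8)
  expect_gte(sc$recall, 0.8)
  expect_true(all(fx$detections$duration >= 0.5))
})

test_that("spindle rate is count per analyzable minute", {
  det <- data.frame(onset = 1:10, offset = 1:10 + 0.6,
                    duration = rep(0.6, 10))
  expect_equal(spindle_rate(det, 300), 2)
  expect_equal(spindle_rate(det[0, ], 300), 0)
  expect_equal(spindle_rate(det, 150), 4)
  expect_error(spindle_rate(det, 0), "positive")
})

test_that("detector models survive a text round trip", {
  fx <- detector_fixture(snr = 2)
  p <- file.path(tempdir(), "model.txt")
  write_detector(fx$model, p)
  m2 <- read_detector(p)
  expect_equal(m2$spindle$mean, unname(fx$model$spindle$mean))
  expect_equal(m2$spindle$cov, unname(fx$model$spindle$cov),
               ignore_attr = TRUE)
  expect_equal(m2$threshold, fx$model$threshold)
  p1 <- spindle_probability(fx$test_features, fx$model)
  p2 <- spindle_probability(fx$test_features, m2)
  expect_equal(p1, p2, tolerance = 1e-12)
})
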