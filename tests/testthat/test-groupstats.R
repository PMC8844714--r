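test_that("PQL quasi-Poisson agrees with an independent PQL implementation", {
  skip_if_not_installed("MASS")
  skip_if_not_installed("nlme")
  spec <- cohort_spec(n_per_group = c(active = 40, resolved = 30,
                                      control = 40),
                      rate_dispersion = 2, seed = 71)
  long <- cohort_long(simulate_cohort(spec)$table)
  fit <- group_rate_model(long$count, long$group, long$age, long$subject,
                          long$minutes)
  long$active <- as.numeric(long$group == "active")
  long$resolved <- as.numeric(long$group == "resolved")
  ref <- suppressMessages(MASS::glmmPQL(
    count ~ active + resolved + age + offset(log(minutes)),
    random = ~ 1 | subject, family = stats::quasipoisson, data = long,
    verbose = FALSE))
  tt <- summary(ref)$tTable
  expect_equal(unname(fit$coefficients),
               unname(tt[c("(Intercept)", "active", "resolved", "age"),
                         "Value"]),
               tolerance = 1e-3)
  expect_equal(unname(fit$se),
               unname(tt[c("(Intercept)", "active", "resolved", "age"),
                         "Std.Error"]),
               tolerance = 0.02)
  expect_equal(fit$dispersion, ref$sigma^2, tolerance = 0.02)
})

test_that("quasi-Poisson mixed model recovers nulls, ratios and dispersion", {
  # identical groups: the active contrast is null
  null_spec <- cohort_spec(
    n_per_group = c(active = 150, resolved = 2, control = 150),
    group_rate_means = c(active = 1.84, resolved = 1.84, control = 1.84),
    rate_dispersion = 2, seed = 72)
  nl <- cohort_long(simulate_cohort(null_spec)$table)
  nf <- group_rate_model(nl$count, nl$group, nl$age, nl$subject,
                         nl$minutes)
  expect_lt(abs(nf$coefficients[["active"]]), 0.15)
  expect_gt(nf$p_values[["active"]], 0.01)

  # rate ratio 0.291 at dispersion 2
  spec <- cohort_spec(
    n_per_group = c(active = 200, resolved = 2, control = 200),
    group_rate_means = c(active = 1.84 * 0.291, resolved = 1.09,
                         control = 1.84),
    rate_dispersion = 2, seed = 73)
  long <- cohort_long(simulate_cohort(spec)$table)
  fit <- group_rate_model(long$count, long$group, long$age, long$subject,
                          long$minutes)
  est <- exp(fit$coefficients[["active"]])
  ci <- exp(fit$coefficients[["active"]] +
              c(-1.96, 1.96) * fit$se[["active"]])
  expect_true(ci[1] <= 0.291 && 0.291 <= ci[2])
  expect_lt(abs(est - 0.291), 0.05)

  # equidispersed counts, no subject mixing: phi near 1
  eq <- cohort_spec(n_per_group = c(active = 250, resolved = 2,
                                    control = 250),
                    rate_dispersion = 1, seed = 74)
  el <- cohort_long(simulate_cohort(eq)$table)
  ef <- group_rate_model(el$count, el$group, el$age, el$subject,
                         el$minutes)
  expect_lt(abs(ef$dispersion - 1), 0.15)
})

test_that("linear mixed fits recover exact and stochastic structure", {
  set.seed(75)
  n <- 60
  X <- data.frame(x = rnorm(n), age = runif(n, 9, 16))
  y <- 2 + 3 * X$x - 0.5 * X$age
  # noise-free responses: lme4 grumbles about the degenerate fit
  f <- suppressWarnings(fit_linear_mixed(y, X, subject = seq_len(n),
                                         random_intercept = FALSE))
  expect_equal(unname(f$coefficients), c(2, 3, -0.5), tolerance = 1e-10)
  expect_equal(unname(f$loglik),
               as.numeric(logLik(lm(y ~ x + age, data = X))))

  # variance components at subject SD 1, residual SD 0.5
  set.seed(76)
  ns <- 200
  subj <- rep(seq_len(ns), each = 2)
  b <- rnorm(ns, 0, 1)[subj]
  x <- rnorm(2 * ns)
  y2 <- 1 + 0.8 * x + b + rnorm(2 * ns, 0, 0.5)
  f2 <- fit_linear_mixed(y2, data.frame(x = x), subj)
  expect_lt(abs(f2$sigma_b - 1) / 1, 0.2)
  expect_lt(abs(f2$sigma - 0.5) / 0.5, 0.2)
  expect_lt(abs(f2$coefficients[["x"]] - 0.8), 0.1)

  f3 <- fit_linear_mixed(y2, data.frame(x = x), subj,
                         random_intercept = FALSE)
  ref <- lm(y2 ~ x)
  expect_equal(unname(f3$coefficients), unname(coef(ref)),
               tolerance = 1e-10)
})

test_that("likelihood ratio tests follow the chi-squared reference", {
  expect_equal(likelihood_ratio_test(-100, -100, 2),
               list(statistic = 0, p = 1))
  lrt <- likelihood_ratio_test(-100, -100 + 5.991 / 2, 2)
  expect_equal(lrt$p, 0.05, tolerance = 0.001)
  expect_error(likelihood_ratio_test(-100, -101, 2), "nested")
})

test_that("Lilliefors Monte-Carlo p-values are calibrated", {
  set.seed(77)
  expect_lt(lilliefors(rexp(100), nsim = 2000)$p, 0.01)

  rejections <- vapply(1:150, function(i) {
    lilliefors(rnorm(50), nsim = 400, seed = 1000 + i)$p < 0.05
  }, logical(1))
  # size 0.05 within binomial error at 150 draws
  expect_lt(abs(mean(rejections) - 0.05), 0.06)

  skip_if_not_installed("nortest")
  set.seed(78)
  x <- rnorm(200) + 0.5 * rexp(200)
  ours <- lilliefors(x, nsim = 5000)
  ref <- nortest::lillie.test(x)
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_lt(abs(ours$p - ref$p.value), 0.05)

  expect_error(lilliefors(rep(1, 10)), "constant")
  expect_error(lilliefors(rnorm(3)), "at least 4")
})

test_that("percent reduction and FDR behave as published procedures", {
  expect_equal(percent_reduction(0), 0)
  expect_equal(percent_reduction(log(0.5)), 50)
  expect_equal(percent_reduction(log(0.291)), 70.9)

  one <- fdr_bh(0.03)
  expect_equal(one$p_adjusted, 0.03)
  all31 <- fdr_bh(rep(0.001, 31))
  expect_true(all(all31$significant))

  adj <- fdr_bh(c(0.01, 0.02, 0.03, 0.5))
  expect_equal(adj$p_adjusted, c(0.04, 0.04, 0.04, 0.5))
  # monotone flags: everything below a flagged p is flagged
  set.seed(79)
  p <- runif(40)^2
  res <- fdr_bh(p)
  if (any(res$significant))
    expect_true(all(res$significant[p <= max(p[res$significant])]))
  expect_error(fdr_bh(c(0.5, 1.2)), "0, 1")
})

test_that("the regional screen flags simulated deficit regions", {
  deficit_regions <- sprintf("region%02d", 1:9)
  make_data <- function(seed) {
    do.call(rbind, lapply(1:31, function(r) {
      rg <- sprintf("region%02d", r)
      ratio <- if (rg %in% deficit_regions) 0.4 else 1
      spec <- cohort_spec(
        n_per_group = c(active = 100, resolved = 2, control = 100),
        group_rate_means = c(active = 1.84 * ratio, resolved = 1.84,
                             control = 1.84),
        rate_dispersion = 2, seed = seed + 1000L * r)
      cbind(region = rg, cohort_long(simulate_cohort(spec)$table))
    }))
  }
  hits <- vapply(1:5, function(s) {
    res <- regional_screen(make_data(s))
    flagged <- res$region[res$significant]
    setequal(flagged, deficit_regions)
  }, logical(1))
  expect_gte(mean(hits), 0.8)

  res <- regional_screen(make_data(1))
  expect_equal(nrow(res), 31)
  expect_true(all(res$p_adjusted >= res$p))
  expect_lt(mean(res$percent_reduction[res$region %in% deficit_regions]) -
              60, 15)
})
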