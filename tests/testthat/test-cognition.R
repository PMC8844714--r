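test_that("IHS transform has the closed-form properties", {
  expect_equal(ihs(0), 0)
  expect_equal(ihs(sinh(1)), 1)
  expect_equal(ihs(-2.5), -ihs(2.5))
  expect_equal(ihs(3), log(3 + sqrt(10)))
  x <- seq(-5, 5, by = 0.5)
  expect_true(all(diff(ihs(x)) > 0))
})

test_that("rate sets average the configured region groups", {
  rates <- data.frame(
    source = 1:6,
    region = rep(c("inferiorRolandic", "insula", "cuneus"), 2),
    hemisphere = rep(c("lh", "rh"), each = 3),
    rate = c(1, 2, 3, 4, 5, 6))
  rs <- build_rate_sets(rates, c("inferiorRolandic", "insula"))
  lh <- rs[rs$hemisphere == "lh", ]
  expect_equal(lh$focal, 1)
  expect_equal(lh$regional, 1.5)
  expect_equal(lh$nonfocal, 2)

  same <- rates
  same$rate <- 2
  rs2 <- build_rate_sets(same, c("inferiorRolandic", "insula", "cuneus"))
  expect_true(all(rs2$focal == 2 & rs2$regional == 2 & rs2$nonfocal == 2))

  deficit <- rates
  deficit$rate <- ifelse(deficit$region == "inferiorRolandic", 0.3, 2)
  rs3 <- build_rate_sets(deficit, c("inferiorRolandic", "insula"))
  expect_true(all(rs3$focal < rs3$nonfocal))
  expect_error(build_rate_sets(rates, c("insula")), "focal")
  expect_error(build_rate_sets(rates, c("inferiorRolandic", "zzz")),
               "without sources")
})

test_that("task models recover noise-free coefficients and pairing", {
  spec <- cohort_spec(
    n_per_group = c(active = 10, resolved = 10, control = 10),
    beta_cognition = list(motor = c(-1.2, 0.9, 0.05),
                          processing_speed = c(-1.2, 0.84, 0),
                          iq = c(-1.1, 0.76, 0),
                          phono = c(-1.1, 0.79, 0)),
    motor_re_sd = 0, noise_sd = 0, seed = 81)
  tab <- simulate_cohort(spec)$table
  # noise-free motor scores make the mixed fit degenerate; lme4 warns
  fm <- suppressWarnings(fit_task_model(tab, "motor"))
  expect_equal(fm$beta1, 0.9, tolerance = 1e-4)
  expect_true(fm$fit$age_included)
  expect_equal(fm$n_obs, 60)

  fp <- suppressWarnings(fit_task_model(tab, "processing_speed"))
  expect_equal(fp$beta1, 0.84, tolerance = 1e-6)
  expect_equal(suppressWarnings(fit_task_model(tab, "phono"))$beta1, 0.79,
               tolerance = 1e-6)

  # contralateral pairing: left-hand scores follow the right hemisphere
  tab2 <- tab
  tab2$motor_left <- -0.5 + 1.4 * ihs(tab2$rate_rh) + 0.05 * tab2$age
  tab2$motor_right <- -0.5 + 1.4 * ihs(tab2$rate_lh) + 0.05 * tab2$age
  fm2 <- suppressWarnings(fit_task_model(tab2, "motor"))
  expect_equal(fm2$beta1, 1.4, tolerance = 1e-4)
  # swapping hemispheres in the table breaks the exact fit
  tab3 <- tab2
  tab3$rate_lh <- tab2$rate_rh
  tab3$rate_rh <- tab2$rate_lh
  fm3 <- suppressWarnings(fit_task_model(tab3, "motor"))
  expect_gt(abs(fm3$beta1 - 1.4), 0.05)
})

test_that("null cohorts give calibrated beta1 inference", {
  covered <- vapply(1:25, function(s) {
    spec <- cohort_spec(
      n_per_group = c(active = 12, resolved = 12, control = 12),
      beta_cognition = list(motor = c(0, 0, 0),
                            processing_speed = c(0, 0, 0),
                            iq = c(0, 0, 0), phono = c(0, 0, 0)),
      noise_sd = 0.5, seed = 8100 + s)
    f <- fit_task_model(simulate_cohort(spec)$table, "processing_speed")
    f$ci[1] <= 0 && 0 <= f$ci[2]
  }, logical(1))
  expect_gte(mean(covered), 0.8)
})

test_that("the global model sums task likelihoods and detects signal", {
  spec <- cohort_spec(n_per_group = c(active = 20, resolved = 20,
                                      control = 20), seed = 82)
  tab <- simulate_cohort(spec)$table
  g <- global_model_test(tab)
  expect_equal(g$loglik,
               sum(vapply(g$fits, function(f) f$fit$loglik, numeric(1))))
  expect_lt(g$lrt$p, 0.05)
  expect_gte(g$lrt$statistic, 0)
})

test_that("focal-vs-regional comparison uses nested 1-df LRTs", {
  spec <- cohort_spec(n_per_group = c(active = 20, resolved = 20,
                                      control = 20), seed = 83)
  tab <- simulate_cohort(spec, rate_sets = TRUE)$table
  cmp <- compare_focal_vs_regional(tab)
  for (tk in names(cmp$per_task)) {
    expect_gte(cmp$per_task[[tk]]$full$loglik,
               cmp$per_task[[tk]]$null$loglik - 1e-6)
    expect_true(cmp$per_task[[tk]]$lrt$p >= 0 &&
                  cmp$per_task[[tk]]$lrt$p <= 1)
  }
  expect_equal(cmp$focal_loglik,
               sum(vapply(cmp$per_task, function(x) x$null$loglik,
                          numeric(1))))

  # non-focal drives the scores: the full model wins decisively
  spec2 <- cohort_spec(n_per_group = c(active = 35, resolved = 30,
                                       control = 35), seed = 84)
  tab2 <- simulate_cohort(spec2, rate_sets = TRUE,
                          cognition_driver = "nonfocal")$table
  cmp2 <- compare_focal_vs_regional(tab2)
  expect_lt(cmp2$per_task$motor$lrt$p, 0.05)
  expect_lt(cmp2$global$p, 0.05)
})

test_that("conditioning on IQ shrinks shared residual correlation", {
  set.seed(85)
  n <- 60
  spec <- cohort_spec(n_per_group = c(active = 20, resolved = 20,
                                      control = 20),
                      noise_sd = 0.3, seed = 86)
  tab <- simulate_cohort(spec)$table
  # inject a common IQ-driven component into every score
  common <- rnorm(n, 0, 1)
  tab$iq <- tab$iq + common
  tab$motor_left <- tab$motor_left + 0.8 * common
  tab$motor_right <- tab$motor_right + 0.8 * common
  tab$processing_speed <- tab$processing_speed + 0.8 * common
  tab$phono <- tab$phono + 0.8 * common
  res <- conditional_on_iq_variant(tab)
  rc <- res$residual_correlations
  expect_true(all(abs(rc$after) < abs(rc$before)))
  expect_gt(mean(abs(rc$before)), 0.3)
})
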