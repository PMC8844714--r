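#' Inverse hyperbolic sine transform
#'
#' `ln(x + sqrt(x^2 + 1))`: variance-stabilizing, odd, strictly
#' increasing, defined at zero; applied to spindle rates to reduce the
#' influence of extreme observations.
#'
#' @param x numeric.
#' @return transformed values.
#' @export
ihs <- function(x) asinh(x)

#' Focal / regional / non-focal spindle-rate sets
#'
#' Per hemisphere: the focal rate is the unweighted mean over sources in
#' the inferior Rolandic cortex; the regional rate the mean over all
#' sources in the significantly affected regions (which include the
#' focal region); the non-focal rate the mean over the same regions
#' excluding the focal one.
#'
#' @param rates data frame with columns `source`, `region`,
#'   `hemisphere`, `rate` (one row per source).
#' @param significant_regions character vector of affected region names;
#'   must include `focal_region`.
#' @param focal_region name of the focal label, default
#'   "inferiorRolandic".
#' @return data frame with one row per hemisphere: `hemisphere`,
#'   `focal`, `regional`, `nonfocal`.
#' @export
build_rate_sets <- function(rates, significant_regions,
                            focal_region = "inferiorRolandic") {
  if (!(focal_region %in% significant_regions))
    stop("significant region set must include the focal region",
         call. = FALSE)
  missing <- setdiff(significant_regions, unique(rates$region))
  if (length(missing))
    stop("regions without sources: ", paste(missing, collapse = ", "),
         call. = FALSE)
  out <- lapply(unique(rates$hemisphere), function(h) {
    d <- rates[rates$hemisphere == h, ]
    reg <- d$rate[d$region %in% significant_regions]
    nf <- d$rate[d$region %in% setdiff(significant_regions, focal_region)]
    data.frame(hemisphere = h,
               focal = mean(d$rate[d$region == focal_region]),
               regional = mean(reg),
               nonfocal = if (length(nf)) mean(nf) else NA_real_)
  })
  do.call(rbind, out)
}

#' Specification of one spindle-rate to cognition model
#'
#' Encodes the pairing rule between task score and hemisphere rate:
#' motor scores pair per hand with the contralateral hemisphere and get
#' a subject random intercept; processing speed and IQ use the mean of
#' hemispheres; phonological awareness the left hemisphere.
#'
#' @param task one of "motor", "processing_speed", "iq", "phono".
#' @return a `task_model_spec` list with `task`, `pairing`,
#'   `random_intercept`.
#' @export
task_model_spec <- function(task = c("motor", "processing_speed", "iq",
                                     "phono")) {
  task <- match.arg(task)
  switch(task,
    motor = list(task = "motor", pairing = "contralateral",
                 random_intercept = TRUE),
    processing_speed = list(task = "processing_speed",
                            pairing = "mean", random_intercept = FALSE),
    iq = list(task = "iq", pairing = "mean", random_intercept = FALSE),
    phono = list(task = "phono", pairing = "left",
                 random_intercept = FALSE))
}

# Assemble the observation table for one task from a cohort table with
# rate columns `<prefix>_lh` / `<prefix>_rh`. Motor yields two rows per
# subject (right hand <- left hemisphere, left hand <- right
# hemisphere); other tasks one row.
task_observations <- function(cohort, spec, rate_prefix = "rate") {
  lh <- cohort[[paste0(rate_prefix, "_lh")]]
  rh <- cohort[[paste0(rate_prefix, "_rh")]]
  if (spec$task == "motor") {
    d <- data.frame(
      subject = rep(cohort$subject, 2L),
      age = rep(cohort$age, 2L),
      score = c(cohort$motor_right, cohort$motor_left),
      rate = c(lh, rh),
      iq = rep(cohort$iq, 2L))
  } else {
    rate <- switch(spec$pairing, mean = (lh + rh) / 2, left = lh)
    d <- data.frame(subject = cohort$subject, age = cohort$age,
                    score = cohort[[spec$task]], rate = rate,
                    iq = cohort$iq)
  }
  d <- d[stats::complete.cases(d[c("score", "rate", "age")]), ]
  d$x <- ihs(d$rate)
  d
}

fit_score_model <- function(d, predictors, spec, age_screen = 0.1,
                            force_age = NULL) {
  # age enters the model only when its coefficient screens at P < 0.1
  with_age <- fit_linear_mixed(d$score, d[c(predictors, "age")],
                               d$subject, spec$random_intercept)
  use_age <- if (is.null(force_age)) {
    with_age$p_values[["age"]] < age_screen
  } else force_age
  fit <- if (use_age) with_age
         else fit_linear_mixed(d$score, d[, predictors, drop = FALSE],
                               d$subject, spec$random_intercept)
  fit$age_included <- use_age
  fit$n_obs <- nrow(d)
  fit
}

model_r_squared <- function(fit, d) {
  # ordinary R^2 for fixed-effects fits; marginal and conditional
  # (variance-partition) R^2 for mixed fits
  if (!is.null(fit$r_squared))
    return(list(marginal = fit$r_squared, conditional = fit$r_squared))
  vf <- stats::var(as.vector(
    stats::model.matrix(fit$model) %*% lme4::fixef(fit$model)))
  vb <- fit$sigma_b^2
  ve <- fit$sigma^2
  list(marginal = vf / (vf + vb + ve),
       conditional = (vf + vb) / (vf + vb + ve))
}

#' Fit one spindle-rate to cognition model
#'
#' ML fit of `score ~ IHS(rate)` with the task's pairing rule, an age
#' covariate screened in at P < 0.1, and a subject random intercept for
#' the motor task. Also fits the matching intercept-only null (same
#' observations, same age/random terms, no rate term) for likelihood
#' comparisons.
#'
#' @param cohort cohort table (see [simulate_cohort()]): columns
#'   `subject`, `age`, task scores, and `<rate_prefix>_lh/_rh`.
#' @param task task name (see [task_model_spec()]).
#' @param rate_prefix which rate columns to use ("rate" = focal rates in
#'   simulated tables; "regional", "nonfocal" when present).
#' @param age_screen inclusion threshold for the age covariate.
#' @return list with `fit`, `null` (both `model_fit`s), `spec`, `n_obs`,
#'   `beta1`, `ci` (95% Wald), `p`, `r_squared`.
#' @export
fit_task_model <- function(cohort, task, rate_prefix = "rate",
                           age_screen = 0.1) {
  spec <- task_model_spec(task)
  d <- task_observations(cohort, spec, rate_prefix)
  if (nrow(d) < 3L) stop("fewer than 3 complete observations",
                         call. = FALSE)
  fit <- fit_score_model(d, "x", spec, age_screen)
  null <- fit_score_model(d, character(0), spec,
                          force_age = fit$age_included)
  b <- fit$coefficients[["x"]]
  se <- fit$se[["x"]]
  list(fit = fit, null = null, spec = spec, n_obs = nrow(d),
       beta1 = b, ci = b + c(-1, 1) * stats::qnorm(0.975) * se,
       p = fit$p_values[["x"]], r_squared = model_r_squared(fit, d))
}

#' Global spindle-rate model of cognitive function
#'
#' Fits the four task models, sums their log-likelihoods (assuming
#' independence between cognitive functions after conditioning on
#' spindle rate) and compares against the summed intercept-only nulls
#' with a 4-degree-of-freedom likelihood ratio test.
#'
#' @param cohort cohort table.
#' @param rate_prefix rate columns to use.
#' @param tasks tasks included, default all four.
#' @return list with `fits` (per task), `loglik`, `null_loglik`, `lrt`.
#' @export
global_model_test <- function(cohort, rate_prefix = "rate",
                              tasks = c("motor", "processing_speed",
                                        "iq", "phono")) {
  fits <- lapply(tasks, function(tk)
    fit_task_model(cohort, tk, rate_prefix))
  names(fits) <- tasks
  ll <- sum(vapply(fits, function(f) f$fit$loglik, numeric(1)))
  ll0 <- sum(vapply(fits, function(f) f$null$loglik, numeric(1)))
  list(fits = fits, loglik = ll, null_loglik = ll0,
       lrt = likelihood_ratio_test(ll0, ll, df = length(tasks)))
}

#' Compare focal-only against focal + non-focal regional models
#'
#' Null: task score on the focal IHS spindle rate. Full: additionally
#' the non-focal component of the regional rate. Per-task 1-df LRTs and
#' a 4-df global LRT on the summed log-likelihoods. A conditioning
#' warning is attached when focal and non-focal rates are essentially
#' collinear (r > 0.999).
#'
#' @param cohort cohort table with `focal_lh/_rh` and `nonfocal_lh/_rh`
#'   rate columns (simulated tables name the focal pair `rate_lh/_rh`;
#'   pass `focal_prefix` accordingly).
#' @param focal_prefix,nonfocal_prefix rate column prefixes.
#' @param tasks tasks to compare.
#' @return list with per-task results (`lrt`, fits) and `global` (4-df
#'   LRT).
#' @export
compare_focal_vs_regional <- function(cohort, focal_prefix = "rate",
                                      nonfocal_prefix = "nonfocal",
                                      tasks = c("motor",
                                                "processing_speed",
                                                "iq", "phono")) {
  per_task <- lapply(tasks, function(tk) {
    spec <- task_model_spec(tk)
    d <- task_observations(cohort, spec, focal_prefix)
    dn <- task_observations(cohort, spec, nonfocal_prefix)
    d$x2 <- dn$x
    if (stats::cor(d$x, d$x2) > 0.999)
      warning("focal and non-focal rates are collinear for task ", tk)
    null <- fit_score_model(d, "x", spec)
    full <- fit_score_model(d[c("subject", "age", "score", "x", "x2")],
                            c("x", "x2"), spec,
                            force_age = null$age_included)
    list(task = tk, null = null, full = full,
         lrt = likelihood_ratio_test(null, full, df = 1))
  })
  names(per_task) <- tasks
  ll0 <- sum(vapply(per_task, function(x) x$null$loglik, numeric(1)))
  ll1 <- sum(vapply(per_task, function(x) x$full$loglik, numeric(1)))
  list(per_task = per_task,
       global = likelihood_ratio_test(ll0, ll1, df = length(tasks)),
       focal_loglik = ll0, regional_loglik = ll1)
}

#' Task models conditioned on IQ
#'
#' Refits the motor, processing-speed and phonological models with the
#' IQ z-score as an additional fixed covariate, and reports the Pearson
#' correlation between each task's model residuals and the IQ model's
#' residuals before and after conditioning, as a diagnostic of
#' cross-model dependence.
#'
#' @param cohort cohort table (IQ must be present).
#' @param rate_prefix rate columns to use.
#' @return list with `fits` (conditioned fits per task) and
#'   `residual_correlations` (`before`, `after` per task).
#' @export
conditional_on_iq_variant <- function(cohort, rate_prefix = "rate") {
  tasks <- c("motor", "processing_speed", "phono")
  iq_spec <- task_model_spec("iq")
  diq <- task_observations(cohort, iq_spec, rate_prefix)
  iq_fit <- fit_score_model(diq, "x", iq_spec)
  iq_res <- diq$score - iq_fit$fitted
  names(iq_res) <- diq$subject
  out <- lapply(tasks, function(tk) {
    spec <- task_model_spec(tk)
    d <- task_observations(cohort, spec, rate_prefix)
    base <- fit_score_model(d, "x", spec)
    cond <- fit_score_model(d, c("x", "iq"), spec,
                            force_age = base$age_included)
    res_b <- d$score - base$fitted
    res_c <- d$score - cond$fitted
    common <- intersect(unique(d$subject), names(iq_res))
    per_subj <- function(r) tapply(r, d$subject, mean)[common]
    list(task = tk, fit = cond,
         before = stats::cor(per_subj(res_b), iq_res[common]),
         after = stats::cor(per_subj(res_c), iq_res[common]))
  })
  names(out) <- tasks
  list(fits = lapply(out, `[[`, "fit"),
       residual_correlations = data.frame(
         task = tasks,
         before = vapply(out, `[[`, numeric(1), "before"),
         after = vapply(out, `[[`, numeric(1), "after")))
}
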