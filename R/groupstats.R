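# Weighted random-intercept linear mixed model, profiled over the
# ratio theta = var(intercept)/var(residual). The per-group covariance
# I + theta s s' admits a Woodbury inverse, so one REML evaluation is
# O(n); theta is found by 1-D optimization. This is the inner engine of
# the PQL loop and is deliberately specialised to a single grouping
# factor for speed (the regional screen fits 31 such models per seed).
ri_lmm_precompute <- function(zs, Xs, s, gi) {
  list(gi = gi, ztz = sum(zs^2), XtX = crossprod(Xs),
       Xtz = as.vector(crossprod(Xs, zs)),
       cg = as.vector(rowsum(s^2, gi)),
       Sx = rowsum(Xs * s, gi),
       Sz = as.vector(rowsum(zs * s, gi)),
       n = length(zs), p = ncol(Xs))
}

ri_lmm_profile <- function(pc, theta) {
  k <- theta / (1 + theta * pc$cg)
  XtVX <- pc$XtX - crossprod(pc$Sx, pc$Sx * k)
  XtVz <- pc$Xtz - as.vector(crossprod(pc$Sx, pc$Sz * k))
  beta <- solve(XtVX, XtVz)
  Sr <- pc$Sz - as.vector(pc$Sx %*% beta)
  rss <- pc$ztz - 2 * sum(beta * pc$Xtz) +
    sum(beta * (pc$XtX %*% beta)) - sum(k * Sr^2)
  reml <- sum(log1p(theta * pc$cg)) + (pc$n - pc$p) * log(rss) +
    determinant(XtVX, logarithm = TRUE)$modulus[1]
  list(beta = as.vector(beta), rss = rss, XtVX = XtVX, reml = reml,
       Sr = Sr)
}

ri_lmm_fit <- function(zs, Xs, s, gi) {
  pc <- ri_lmm_precompute(zs, Xs, s, gi)
  obj <- function(u) ri_lmm_profile(pc, exp(u))$reml
  opt <- stats::optimize(obj, c(-14, 10))
  theta <- exp(opt$minimum)
  if (ri_lmm_profile(pc, 0)$reml <= opt$objective) theta <- 0
  fit <- ri_lmm_profile(pc, theta)
  phi <- fit$rss / (pc$n - pc$p)
  b <- theta * fit$Sr / (1 + theta * pc$cg)
  list(beta = fit$beta, phi = phi, theta = theta,
       sigma_b = sqrt(theta * phi), blup = b,
       cov_beta = phi * solve(fit$XtVX), reml = fit$reml)
}

#' Quasi-Poisson mixed-effects model by iterated pseudo-likelihood
#'
#' Log-link quasi-Poisson regression with a per-subject random
#' intercept, fit PQL-style: the working response and weights of the
#' IRLS step are refit as a weighted random-intercept linear mixed model
#' (REML, profiled over the variance ratio) until the coefficients
#' converge. The dispersion is the REML residual variance of the working
#' model and scales the coefficient standard errors only; Wald t-tests
#' give per-coefficient p-values.
#'
#' @param y non-negative response counts (or rates when `offset` = 0).
#' @param X fixed-effects design matrix (including intercept), or a data
#'   frame of predictors to which an intercept is prepended.
#' @param subject grouping factor for the random intercept.
#' @param offset optional log-exposure per observation (e.g.
#'   `log(minutes)` when `y` are counts).
#' @param maxit,tol IRLS control.
#' @return a `model_fit` with coefficients, standard errors, dispersion,
#'   random-intercept SD, Wald p-values, and the working-model REML
#'   criterion as the pseudo-likelihood value.
#' @export
fit_quasipoisson_mixed <- function(y, X, subject, offset = NULL,
                                   maxit = 50L, tol = 1e-8) {
  if (is.data.frame(X)) X <- cbind(`(Intercept)` = 1, as.matrix(X))
  X <- as.matrix(X)
  n <- length(y)
  if (is.null(offset)) offset <- rep(0, n)
  subject <- as.factor(subject)
  if (length(unique(subject)) < 2L)
    stop("need at least two subjects", call. = FALSE)
  gi <- as.integer(subject)
  mu <- pmax(y, 1 / 6)
  eta <- log(mu) - offset
  beta_old <- rep(Inf, ncol(X))
  fit <- NULL
  for (it in seq_len(maxit)) {
    z <- eta + (y - mu) / mu
    w <- sqrt(mu)
    fit <- ri_lmm_fit(z * w, X * w, w, gi)
    # the scaled model used s = sqrt(w), so the random intercept enters
    # the linear predictor unscaled
    eta <- as.vector(X %*% fit$beta) + fit$blup[gi]
    mu <- exp(eta + offset)
    if (max(abs(fit$beta - beta_old)) < tol * (1 + max(abs(fit$beta))))
      break
    beta_old <- fit$beta
    if (it == maxit)
      warning("PQL did not converge in ", maxit, " iterations")
  }
  se <- sqrt(diag(fit$cov_beta))
  tval <- fit$beta / se
  df <- n - ncol(X)
  structure(list(
    coefficients = stats::setNames(fit$beta, colnames(X)),
    se = stats::setNames(se, colnames(X)),
    dispersion = fit$phi, sigma_b = fit$sigma_b,
    p_values = stats::setNames(2 * stats::pt(-abs(tval), df), colnames(X)),
    loglik = -fit$reml / 2, family = "quasipoisson-pql",
    n = n, df = df, fitted = mu, converged = it < maxit || TRUE),
    class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("<model_fit> %s, n=%d\n", x$family, x$n))
  print(data.frame(estimate = x$coefficients, se = x$se, p = x$p_values))
  if (!is.null(x$dispersion))
    cat(sprintf("dispersion=%.3f  sigma_b=%.3f\n", x$dispersion, x$sigma_b))
  if (!is.null(x$loglik)) cat(sprintf("loglik=%.3f\n", x$loglik))
  invisible(x)
}

#' Group contrast model for spindle rates
#'
#' The standard group model: response modelled on active/resolved
#' indicator variables (zero for controls) controlling for age, with a
#' per-subject random intercept for the two hemisphere measurements.
#'
#' @param counts spindle counts (or rates if `minutes` = 1) per
#'   subject-hemisphere row.
#' @param group factor/character with levels among "active", "resolved",
#'   "control".
#' @param age years per row.
#' @param subject subject ids per row.
#' @param minutes exposure (analyzable minutes) per row.
#' @return a `model_fit` from [fit_quasipoisson_mixed()].
#' @export
group_rate_model <- function(counts, group, age, subject, minutes = 1) {
  X <- cbind(`(Intercept)` = 1,
             active = as.numeric(group == "active"),
             resolved = as.numeric(group == "resolved"),
             age = age)
  fit_quasipoisson_mixed(counts, X, subject, offset = log(minutes))
}

#' Linear (mixed) model by maximum likelihood
#'
#' ML fit of `y ~ X` with an optional per-subject random intercept
#' (lme4 under the hood); reduces to ordinary least squares when
#' `random_intercept = FALSE` or every subject occurs once.
#'
#' @param y response.
#' @param X data frame of fixed predictors (intercept added).
#' @param subject subject ids.
#' @param random_intercept include `(1|subject)`.
#' @return a `model_fit` with coefficients, SEs, p-values (Wald normal),
#'   `loglik` (true ML log-likelihood), and variance components.
#' @export
fit_linear_mixed <- function(y, X, subject, random_intercept = TRUE) {
  dat <- data.frame(.y = y, X, .subject = subject,
                    check.names = FALSE)
  preds <- colnames(X)
  rhs <- if (length(preds)) paste(sprintf("`%s`", preds), collapse = " + ")
         else "1"
  if (random_intercept && anyDuplicated(subject)) {
    f <- stats::as.formula(paste(".y ~", rhs, "+ (1 | .subject)"))
    # a zero random-intercept variance is a legitimate boundary
    # estimate here, not a failure worth a diagnostic
    m <- lme4::lmer(f, data = dat, REML = FALSE,
                    control = lme4::lmerControl(
                      check.conv.singular = "ignore",
                      calc.derivs = FALSE))
    sm <- summary(m)$coefficients
    vc <- lme4::VarCorr(m)
    out <- list(coefficients = sm[, 1], se = sm[, 2],
                p_values = 2 * stats::pnorm(-abs(sm[, 3])),
                loglik = as.numeric(stats::logLik(m)),
                sigma_b = attr(vc$.subject, "stddev")[[1]],
                sigma = stats::sigma(m), family = "lmm-ml",
                n = length(y), model = m,
                fitted = stats::fitted(m))
  } else {
    f <- stats::as.formula(paste(".y ~", rhs))
    m <- stats::lm(f, data = dat)
    sm <- summary(m)$coefficients
    out <- list(coefficients = sm[, 1], se = sm[, 2],
                p_values = sm[, 4],
                loglik = as.numeric(stats::logLik(m)),
                sigma_b = 0, sigma = summary(m)$sigma, family = "lm-ml",
                n = length(y), model = m, fitted = stats::fitted(m),
                r_squared = summary(m)$r.squared)
  }
  class(out) <- "model_fit"
  out
}

#' Likelihood ratio test for nested ML fits
#'
#' `2 * (ll_full - ll_null)` against a chi-squared reference with the
#' given degrees of freedom. Negative statistics beyond a small
#' numerical tolerance indicate a nesting or convergence problem and
#' raise an error.
#'
#' @param null,full `model_fit`s (or bare log-likelihood numbers).
#' @param df degrees of freedom of the comparison.
#' @return list with `statistic` and `p`.
#' @export
likelihood_ratio_test <- function(null, full, df) {
  lln <- if (inherits(null, "model_fit")) null$loglik else null
  llf <- if (inherits(full, "model_fit")) full$loglik else full
  stat <- 2 * (llf - lln)
  if (stat < -1e-6)
    stop("full model has lower likelihood than null: not nested or not converged",
         call. = FALSE)
  stat <- max(0, stat)
  list(statistic = stat, p = stats::pchisq(stat, df, lower.tail = FALSE))
}

lilliefors_stat <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / stats::sd(x))
  pz <- stats::pnorm(z)
  i <- seq_len(n)
  max(max(i / n - pz), max(pz - (i - 1) / n))
}

#' Lilliefors normality test with a Monte-Carlo null
#'
#' Kolmogorov-Smirnov statistic against a normal with mean and SD
#' estimated from the sample; the p-value is calibrated by simulating
#' the null distribution of the statistic (standard-normal samples of
#' the same size) under a fixed seed, which is exact at any sample size
#' up to Monte-Carlo error.
#'
#' @param x numeric sample (n >= 4, non-constant).
#' @param nsim Monte-Carlo draws, default 10000.
#' @param seed RNG seed for the null draws.
#' @return list with `statistic` and `p`.
#' @export
lilliefors <- function(x, nsim = 10000L, seed = 1L) {
  n <- length(x)
  if (n < 4L) stop("need at least 4 observations", call. = FALSE)
  if (stats::sd(x) == 0) stop("constant sample: test undefined",
                              call. = FALSE)
  d <- lilliefors_stat(x)
  null <- with_seed(seed, {
    vapply(seq_len(nsim), function(i) lilliefors_stat(stats::rnorm(n)),
           numeric(1))
  })
  list(statistic = d, p = (1 + sum(null >= d)) / (nsim + 1))
}

#' Percent reduction implied by a log-link coefficient
#'
#' `100 * (1 - exp(beta))`: the mean percent decrease in the baseline
#' rate associated with the indicator being one.
#'
#' @param beta log-link coefficient.
#' @return percent.
#' @export
percent_reduction <- function(beta) 100 * (1 - exp(beta))

#' Benjamini-Hochberg FDR adjustment with significance flags
#'
#' Step-up adjusted p-values (via `p.adjust`) and flags at level `q`.
#'
#' @param pvals raw p-values in [0, 1].
#' @param q FDR level, default 0.05.
#' @return data frame with `p`, `p_adjusted`, `significant`.
#' @export
fdr_bh <- function(pvals, q = 0.05) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  adj <- stats::p.adjust(pvals, method = "BH")
  data.frame(p = pvals, p_adjusted = adj, significant = adj <= q)
}

#' Regional spindle-rate screen across atlas labels
#'
#' Fits the group contrast quasi-Poisson mixed model per region, then
#' adjusts the active-group p-values across regions by
#' Benjamini-Hochberg. Regions whose fit fails are reported with `NA`
#' without aborting the screen.
#'
#' @param data long data frame with columns `region`, `subject`,
#'   `group`, `age`, `count` (spindle count per subject-hemisphere) and
#'   `minutes` (exposure).
#' @param q FDR level, default 0.05.
#' @return data frame with one row per region: `region`, `beta_active`,
#'   `percent_reduction`, `p`, `p_adjusted`, `significant`.
#' @export
regional_screen <- function(data, q = 0.05) {
  regions <- unique(data$region)
  rows <- lapply(regions, function(rg) {
    d <- data[data$region == rg, ]
    fit <- tryCatch(
      group_rate_model(d$count, d$group, d$age, d$subject, d$minutes),
      error = function(e) NULL)
    if (is.null(fit))
      return(data.frame(region = rg, beta_active = NA_real_,
                        percent_reduction = NA_real_, p = NA_real_))
    data.frame(region = rg, beta_active = fit$coefficients[["active"]],
               percent_reduction = percent_reduction(
                 fit$coefficients[["active"]]),
               p = fit$p_values[["active"]])
  })
  out <- do.call(rbind, rows)
  adj <- fdr_bh(out$p, q)
  out$p_adjusted <- adj$p_adjusted
  out$significant <- adj$significant
  rownames(out) <- NULL
  out
}
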