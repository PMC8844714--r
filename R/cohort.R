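#' Cohort simulation specification
#'
#' Describes a synthetic cohort with active / resolved / control groups,
#' gamma-mixed Poisson (overdispersed) spindle counts per subject and
#' hemisphere, and neuropsychological z-scores generated as linear
#' functions of the IHS-transformed spindle rate. Defaults encode the
#' study conditions: group sizes 8/10/8, group mean spindle rates
#' 0.65 / 1.09 / 1.84 spindles/min, ages spanning 8.9-16.7 years, and
#' task slopes (on IHS spindle rate) of 0.9 (motor), 0.84 (processing
#' speed), 0.76 (IQ) and 0.79 (phonological awareness).
#'
#' @param n_per_group named counts for `active`, `resolved`, `control`.
#' @param group_rate_means spindles/min per group, same order.
#' @param rate_dispersion quasi-Poisson dispersion (variance/mean of
#'   spindle counts) >= 1; 1 gives pure Poisson counts.
#' @param minutes analyzable NREM minutes per hemisphere used as the
#'   count exposure, default 811.9/60.
#' @param age_range years, ages drawn uniformly.
#' @param beta_cognition list of per-task coefficient vectors
#'   `c(b0, b1, b2)`; `b2` (age) is used by the motor task only.
#' @param motor_re_sd SD of the per-subject random intercept added to the
#'   two motor (per-hand) scores, z-score units.
#' @param noise_sd residual SD of all task scores, z-score units.
#' @param synchrony_target bilateral synchrony used when rendering
#'   signals.
#' @param render_duration seconds of signal per hemisphere when
#'   `render = TRUE` in [simulate_cohort()].
#' @param seed integer seed.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n_per_group = c(active = 8, resolved = 10, control = 8),
                        group_rate_means = c(active = 0.65, resolved = 1.09,
                                             control = 1.84),
                        rate_dispersion = 2, minutes = 811.9 / 60,
                        age_range = c(8.9, 16.7),
                        beta_cognition = list(
                          motor = c(-1.2, 0.9, 0.05),
                          processing_speed = c(-1.2, 0.84, 0),
                          iq = c(-1.1, 0.76, 0),
                          phono = c(-1.1, 0.79, 0)),
                        motor_re_sd = 0.5, noise_sd = 0.5,
                        synchrony_target = 0.6, render_duration = 300,
                        seed = 1L) {
  if (any(group_rate_means < 0)) stop("rates must be >= 0", call. = FALSE)
  if (rate_dispersion < 1) stop("dispersion must be >= 1", call. = FALSE)
  if (any(n_per_group < 1)) stop("group sizes must be >= 1", call. = FALSE)
  structure(list(n_per_group = n_per_group,
                 group_rate_means = group_rate_means,
                 rate_dispersion = rate_dispersion, minutes = minutes,
                 age_range = age_range, beta_cognition = beta_cognition,
                 motor_re_sd = motor_re_sd, noise_sd = noise_sd,
                 synchrony_target = synchrony_target,
                 render_duration = render_duration, seed = seed),
            class = "cohort_spec")
}

#' Draw overdispersed per-hemisphere spindle counts
#'
#' Counts are gamma-mixed Poisson: each subject receives a gamma
#' multiplier (mean 1) shared by both hemispheres -- this shared
#' multiplier is the generative counterpart of the subject random
#' intercept -- with shape chosen so the marginal count variance equals
#' `dispersion x mean` at the given exposure.
#'
#' @param n subjects.
#' @param rate_mean group mean rate, spindles/min.
#' @param dispersion quasi-Poisson dispersion at exposure `minutes`.
#' @param minutes exposure per hemisphere.
#' @return data frame with `count_lh`, `count_rh`, `rate_lh`, `rate_rh`.
#' @keywords internal
draw_group_counts <- function(n, rate_mean, dispersion, minutes) {
  mu <- rate_mean * minutes
  g <- if (dispersion > 1) {
    k <- mu / (dispersion - 1)
    stats::rgamma(n, shape = k, scale = 1 / k)
  } else rep(1, n)
  cl <- stats::rpois(n, rate_mean * g * minutes)
  cr <- stats::rpois(n, rate_mean * g * minutes)
  data.frame(count_lh = cl, count_rh = cr,
             rate_lh = cl / minutes, rate_rh = cr / minutes)
}

#' Simulate a cohort table (and optionally rendered recordings)
#'
#' Produces one row per subject with group, age, sex, per-hemisphere
#' spindle counts/rates, and task z-scores generated as
#' `b0 + b1 * IHS(rate) (+ b2 * age for motor) + noise`, where motor
#' scores are produced per hand against the contralateral-hemisphere
#' rate plus a per-subject random intercept. With `render = TRUE`, a
#' pair of single-source recordings (left/right inferior Rolandic) is
#' rendered per subject whose burst trains realize the drawn counts'
#' rates with the configured bilateral synchrony.
#'
#' When `rate_sets = TRUE` the table additionally carries an
#' independently mixed non-focal rate pair (`nonfocal_lh/_rh`, same
#' group means) and their average with the focal rates
#' (`regional_lh/_rh`); `cognition_driver` selects whether task scores
#' are generated from the focal or the non-focal rates, which is what
#' the nested focal-versus-regional model comparison probes.
#'
#' @param spec a [cohort_spec()].
#' @param render render per-hemisphere source recordings (slow; used by
#'   end-to-end pipeline runs, not by the statistical simulations).
#' @param rate_sets also draw non-focal/regional rate columns.
#' @param cognition_driver "focal" (default) or "nonfocal": which rate
#'   set generates the task scores.
#' @return list with `table` (the cohort data frame) and `recordings`
#'   (`NULL` unless `render`; else a per-subject list of left/right
#'   [source_recording()]s).
#' @export
simulate_cohort <- function(spec, render = FALSE, rate_sets = FALSE,
                            cognition_driver = c("focal", "nonfocal")) {
  cognition_driver <- match.arg(cognition_driver)
  if (cognition_driver == "nonfocal" && !rate_sets)
    stop("cognition_driver = 'nonfocal' requires rate_sets = TRUE",
         call. = FALSE)
  groups <- rep(names(spec$n_per_group), spec$n_per_group)
  n <- length(groups)
  tab <- with_seed(spec$seed, {
    age <- stats::runif(n, spec$age_range[1], spec$age_range[2])
    sex <- sample(c("M", "F"), n, replace = TRUE)
    counts <- do.call(rbind, lapply(names(spec$n_per_group), function(g) {
      draw_group_counts(spec$n_per_group[[g]], spec$group_rate_means[[g]],
                        spec$rate_dispersion, spec$minutes)
    }))
    extra <- NULL
    if (rate_sets) {
      nf <- do.call(rbind, lapply(names(spec$n_per_group), function(g) {
        draw_group_counts(spec$n_per_group[[g]],
                          spec$group_rate_means[[g]],
                          spec$rate_dispersion, spec$minutes)
      }))
      extra <- data.frame(nonfocal_lh = nf$rate_lh,
                          nonfocal_rh = nf$rate_rh,
                          regional_lh = (counts$rate_lh + nf$rate_lh) / 2,
                          regional_rh = (counts$rate_rh + nf$rate_rh) / 2)
    }
    drv_lh <- if (cognition_driver == "focal") counts$rate_lh
              else extra$nonfocal_lh
    drv_rh <- if (cognition_driver == "focal") counts$rate_rh
              else extra$nonfocal_rh
    b <- spec$beta_cognition
    re <- stats::rnorm(n, 0, spec$motor_re_sd)
    noise <- function() stats::rnorm(n, 0, spec$noise_sd)
    mean_rate <- (drv_lh + drv_rh) / 2
    tab <- data.frame(
      subject = sprintf("s%03d", seq_len(n)), group = groups,
      age = age, sex = sex, counts, minutes = spec$minutes,
      # right hand is driven by the left hemisphere and vice versa
      motor_right = b$motor[1] + b$motor[2] * ihs(drv_lh) +
        b$motor[3] * age + re + noise(),
      motor_left = b$motor[1] + b$motor[2] * ihs(drv_rh) +
        b$motor[3] * age + re + noise(),
      processing_speed = b$processing_speed[1] +
        b$processing_speed[2] * ihs(mean_rate) + noise(),
      iq = b$iq[1] + b$iq[2] * ihs(mean_rate) + noise(),
      phono = b$phono[1] + b$phono[2] * ihs(drv_lh) + noise(),
      stringsAsFactors = FALSE)
    if (!is.null(extra)) tab <- cbind(tab, extra)
    tab
  })
  recs <- NULL
  if (render) {
    recs <- lapply(seq_len(n), function(i) {
      rate <- (tab$rate_lh[i] + tab$rate_rh[i]) / 2
      tr <- simulate_bilateral_trains(rate, spec$synchrony_target,
                                      spec$render_duration,
                                      seed = spec$seed + 10L * i)
      cfg <- function(off) sim_config(duration = spec$render_duration,
                                      seed = spec$seed + 10L * i + off)
      list(left = render_recording(simulate_background(cfg(1L)), tr$left,
                                   snr = 3, fs = 407,
                                   subject = tab$subject[i],
                                   hemisphere = "lh"),
           right = render_recording(simulate_background(cfg(2L)), tr$right,
                                    snr = 3, fs = 407,
                                    subject = tab$subject[i],
                                    hemisphere = "rh"))
    })
    names(recs) <- tab$subject
  }
  list(table = tab, recordings = recs)
}
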