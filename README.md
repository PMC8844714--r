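# spindlesource

Source-space sleep-spindle analysis for focal-epilepsy cohorts.

Children with Rolandic epilepsy — spikes arising from the inferior
Rolandic cortex in NREM sleep — show cognitive deficits that the spikes
alone do not explain. Sleep spindles (10–15 Hz sigma-band oscillations
of NREM sleep, 0.5–2 s long) are generated by the same thalamocortical
circuits, so a *spindle-rate deficit*, measured focally in the inferior
Rolandic cortex and regionally across cortical labels, is a candidate
biomarker for the encephalopathy and its cognitive burden.
`spindlesource` implements that analysis end to end for cortical
source-space recordings, together with a synthetic cohort generator that
makes every stage testable without clinical data.

## What the package computes

* **Synthetic data** — 1/f^α backgrounds, Poisson sigma-burst trains
  (non-overlapping, 0.5–2 s, 10–15 Hz), biphasic spike transients,
  bilateral trains with a controllable synchrony fraction, and cohorts
  with gamma-mixed (overdispersed) Poisson spindle counts and task
  z-scores linear in the IHS-transformed rate.
* **Geometry** — icosahedral source spaces (10·4ⁿ + 2 vertices),
  1 cm-disc patch averaging from 10,242 to 162 sources per hemisphere,
  and the inferior Rolandic ROI (sphere about the most inferior
  pre/post-central vertex, radius half the inferior–superior extent,
  intersected with the two gyral labels).
* **Preprocessing** — artifact flagging by the 30–95 Hz aperiodic slope
  (1 s Hann windows, threshold α = 1.5), 200 ms spike masking,
  anti-aliased decimation to 407 Hz, segment concatenation with
  boundary tracking.
* **Spectral estimation** — averaged 1 s Hann periodograms, relative
  power (0–50 Hz normalization), sigma power (10–15 Hz mean), the
  sigma "bump" (positive residuals above the 10↔15 Hz chord), Slepian
  tapers (2 s, TW = 5, K = 9) and multitaper coherence at 12.5 Hz.
* **Spindle detection** — a trainable three-feature probabilistic
  detector (theta power 4–8 Hz, sigma power 9–15 Hz, peak/trough
  rhythmicity → Gaussian-Bayes posterior of the spindle state),
  duration floor 0.5 s, and spindle rate per analyzable minute.
* **Spindle features** — per-spindle sigma power (zero-padded to 4 s,
  10.25–14.75 Hz), regional indicator vectors, ±1 s spindle epochs,
  intra-/inter-hemispheric coherence among spindle-exhibiting sources,
  and bilateral synchrony = indicator overlap / union.
* **Group statistics** — quasi-Poisson mixed models fit by iterated
  pseudo-likelihood (subject random intercept, Wald tests, percent
  reduction = 100(1 − e^β)), ML linear mixed models, likelihood-ratio
  tests, Monte-Carlo Lilliefors normality screening, Benjamini–Hochberg
  FDR, and a 31-label regional screen.
* **Cognition models** — IHS-transformed focal/regional/non-focal
  spindle rates predicting motor (contralateral pairing, subject random
  intercept), processing-speed, IQ and phonological scores; summed
  log-likelihood global tests (4 df) and nested focal-vs-regional
  comparisons (1 df per task).

## Worked example

```r
library(spindlesource)

## detect spindles on a synthetic 10-minute source recording
train <- simulate_recording(sim_config(duration = 600, burst_rate = 3, seed = 1))
ft    <- compute_features(train$data[1, ], train$fs)
model <- train_detector(ft, label_windows(ft, train$truth))

rec  <- simulate_recording(sim_config(duration = 600, burst_rate = 2, seed = 2))
ft2  <- compute_features(rec$data[1, ], rec$fs)
det  <- detect_spindles(spindle_probability(ft2, model), ft2, model)
head(det, 3)
#>      onset   offset duration
#> 1 11.88759 13.59644 1.708845
#> 2 30.32248 31.93059 1.608108
#> 3 50.06695 52.38022 2.313268
spindle_rate(det, analyzable_duration(rec))   # 1.9 spindles/min
score_detections(det, rec$truth)              # recall 1.00, precision 1.00

## group contrast on a simulated cohort (8 active / 10 resolved / 8 control)
tab  <- simulate_cohort(cohort_spec(seed = 3))$table
long <- data.frame(subject = rep(tab$subject, 2), group = rep(tab$group, 2),
                   age = rep(tab$age, 2),
                   count = c(tab$count_lh, tab$count_rh),
                   minutes = tab$minutes)
fit <- group_rate_model(long$count, long$group, long$age,
                        long$subject, long$minutes)
percent_reduction(fit$coefficients[["active"]])
#> 61.5        # % decrease in baseline spindle rate for the active group
fit$p_values[["active"]]
#> 1.6e-07

## spindle rate -> fine-motor performance (contralateral pairing)
cog <- fit_task_model(tab, "motor")
c(beta1 = cog$beta1, ci = cog$ci, p = cog$p)
#> beta1 0.90, 95% CI [0.30, 1.51], p = 0.003
```

The detected rate (1.9/min) reflects the configured burst rate of
2/min net of edge effects; the group coefficient is the log rate ratio
of the active group against controls after adjusting for age, here a
61.5% reduction on a cohort drawn at the default group means
(0.65/1.09/1.84 spindles/min); and `beta1` is the slope of the motor
z-score on the IHS-transformed contralateral spindle rate, recovering
the generator's 0.9.

`run_pipeline(pipeline_config(...), out_dir)` chains all stages —
simulate, preprocess, train, detect, feature extraction, group model,
cognition models — and writes tab-delimited tables stamped with the
configuration hash; identical seeds give byte-identical outputs.

## Layout

```
R/                  implementation (simulation, geometry, preprocess,
                    spectral, detection, features, group stats,
                    cognition, pipeline/container I/O)
tests/testthat/     unit, property and acceptance suites
scripts/acceptance.R   acceptance-quantity recomputation
vignettes/          methods vignette: models, parameters, design choices
```
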