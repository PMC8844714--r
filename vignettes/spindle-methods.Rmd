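---
title: "Source-space sleep-spindle analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Source-space sleep-spindle analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spindlesource)
```

## The scientific problem

Rolandic epilepsy is a self-limited childhood epilepsy whose spikes arise
from the inferior Rolandic (peri-central) cortex during NREM sleep, and
whose cognitive comorbidities — fine-motor, processing-speed, phonological
and global-IQ deficits — are poorly explained by the spikes themselves.
Sleep spindles (discrete 10–15 Hz thalamocortical oscillations of NREM
sleep, 0.5–2 s long) are a candidate mechanistic link: they are generated
by the same thalamocortical circuitry the disease disrupts and they
support sleep-dependent consolidation. `spindlesource` implements, as a
reusable and fully tested pipeline, an analysis that (i) quantifies
spindle rates in cortical source space, focally in the inferior Rolandic
cortex and regionally across atlas labels, (ii) compares rates between
active, resolved and control groups with overdispersion-robust mixed
models, and (iii) relates focal versus regional spindle-rate estimates to
neuropsychological task performance.

Because clinical source-space EEG of this kind is not publicly
deposited, the package carries a first-class synthetic-data module that
generates recordings and cohorts with the statistical structure the
analysis assumes. Every downstream stage is exercised against this
generator; what that does and does not demonstrate about real data is
discussed at the end.

## Synthetic recordings

A single-source recording is the sum of three components:

* **Aperiodic background.** Gaussian noise shaped in the frequency
  domain to a $1/f^\alpha$ power law (DC removed, unit variance). The
  default $\alpha = 2$ reflects the steep aperiodic slope of NREM sleep
  EEG and deliberately sits on the "clean" side of the artifact
  criterion below.
* **Sigma bursts** (synthetic spindles): homogeneous-Poisson event
  onsets, rejected-and-redrawn on overlap (up to 100 attempts) so bursts
  stay discrete, with durations uniform on 0.5–2 s and carrier
  frequencies uniform on 10–15 Hz. Each burst is a sine carrier under a
  Hann envelope with peak amplitude `burst_snr` times the background
  RMS. The amplitude distribution of real spindles is not constrained by
  the source material, so `burst_snr` is an explicit knob (default 3;
  detector guarantees are additionally tested at 2).
* **Spike transients**: a fixed 70 ms biphasic template — a few-ms sharp
  positive deflection followed by a slower negative after-wave — scaled
  to `spike_snr` (default 10) times background RMS. Only the
  large-amplitude, broadband character matters: spikes must flatten the
  30–95 Hz spectral slope so that removal procedures have something to
  remove.

Bilateral trains share a configurable fraction of events across
hemispheres. For a synchrony target $T$ the generator draws shared
events at rate $2T/(1+T)\times r$ and per-hemisphere independent events
at $(1-T)/(1+T)\times r$, which keeps each hemisphere at rate $r$ while
making the expected indicator overlap/union statistic equal $T$. Shared
events are duplicated with onset jitter at most 0.1 s, small enough to
stay inside the ±1 s epoch window used by the coherence analysis.

The cohort generator draws per-subject spindle counts from a
gamma-mixed Poisson: one gamma multiplier per subject (mean 1), shared
by both hemispheres, with shape chosen so that marginal count variance
equals `rate_dispersion` × mean at the configured exposure. The shared
multiplier is the generative counterpart of the subject random
intercept in the analysis models. Defaults encode the study conditions:
groups of 8/10/8 (active/resolved/control), group mean rates
0.65/1.09/1.84 spindles/min, dispersion 2, ages 8.9–16.7 years, and
811.9 s of analyzable NREM per hemisphere. Task z-scores are linear in
the IHS-transformed rate (slopes 0.9, 0.84, 0.76, 0.79 for motor,
processing speed, IQ and phonological awareness; intercepts chosen so
control-group scores centre near zero) plus Gaussian noise (SD 0.5) and,
for the per-hand motor scores, a subject random intercept (SD 0.5) and a
small age term (0.05/yr, a value chosen once as a plausible residual
age trend; the source material reports only that age screened into the
motor model).

## Geometry

Source spaces live on recursively subdivided icosahedra
($10\cdot4^n+2$ vertices: 162 at order 2, 10,242 at order 5, per
hemisphere). High→low-density reduction draws a disc of about 1 cm
diameter around each low-density point and averages the high-density
sources inside it. Membership uses Euclidean (chord) distance by
default: the published procedure defines the disc through a smoothing
kernel on the cortical surface, which is implementation-specific,
whereas chord distance is reproducible and testable against a
brute-force scan; a geodesic (edge-graph Dijkstra) mode is provided for
users who want surface distance.

The inferior Rolandic ROI is built from the pre- and post-central gyrus
labels: a sphere is centred on the most inferior vertex of their union
(minimal vertical coordinate, with the vertical axis declared in the
container header, since the published construction assumes an anatomical
frame it never names), with radius half the Euclidean distance between
the union's most inferior and most superior vertices; the ROI is the
**intersection** of that sphere with the union of the two labels. The
source text describes both a union and an overlap reading of this
construction; the intersection reading matches the depicted extent of
the ROI and is the one implemented.

## Preprocessing

* **Artifact criterion.** For each non-overlapping 1 s window, the
  least-squares slope of log-power versus log-frequency on a single
  Hann-taper periodogram, restricted to 30–95 Hz; windows with slope
  $> -1.5$ are excluded. One honest numerical property deserves
  emphasis: single-window slope estimates scatter with SD ≈ 0.6, so even
  a perfect $1/f^2$ background loses roughly a fifth of its windows at
  the 1.5 threshold. The tests assert the statistical behaviour (most
  windows survive at $\alpha=2$, almost none at $\alpha=1$, white-noise
  insertions are always caught) rather than a noise-free ideal.
* **Spike masking** removes 200 ms around each listed spike time,
  interpreted as a window centred on the detection (±100 ms) — the total
  matches the stated amount removed; the pad is configurable. Exclusions
  merge, masking is idempotent and order-independent, and all
  downstream rates use the masked (analyzable) duration as their
  denominator.
* **Decimation** to 407 Hz uses a 60-tap linear-phase FIR anti-alias
  low-pass at 0.8 of the target Nyquist followed by stride selection.
  The FIR was chosen over the classical order-8 Chebyshev IIR because
  its passband is flat to <0.5% (the Chebyshev ripple attenuates even a
  constant signal by ~1%), which keeps amplitudes testable to 1%.
* **Concatenation** of sleep segments records junction times; no
  detection may span a junction.

## Spectral estimation

Power spectra average single-Hann-taper periodograms over fully
analyzable, non-overlapping 1 s windows (1 Hz resolution), normalized so
bin sum × bin width equals variance. Relative power divides by the
summed power over 0–50 Hz. Sigma power is the mean relative power over
the closed 10–15 Hz band. The sigma bump fits a chord between the
spectrum's values at the bins nearest 10 and 15 Hz and sums the
*positive* residuals across the band — a bin-wise sum, not a trapezoid,
matching the stated procedure — so it is exactly zero for any spectrum
linear across the band and invariant to adding any linear function of
frequency. All band edges are closed.

Slepian (DPSS) tapers come from the classical symmetric tridiagonal
eigenproblem, orthonormalized, with $K = 2\,TW - 1$: a 2 s window at
2.5 Hz half-bandwidth gives $TW=5$ and 9 tapers. Coherence is the
taper-averaged magnitude-squared cross-spectrum over the geometric mean
of auto-spectra, evaluated at the bin nearest 12.5 Hz (covering
12.5 ± 2.5 Hz). Under independence, multitaper coherence has a
small-sample bias near $1/K$; the tests assert that level rather than
zero.

## Spindle detection

The detector estimates the probability of the spindle state from three
features per sliding window (0.5 s window, 0.1 s step — resolving the
0.5 s minimum event; the windowing is a package choice, as the original
state model's internals are not published): theta band power (4–8 Hz),
sigma band power (9–15 Hz; the detector's wider sigma definition is kept
distinct from the 10–15 Hz analysis band, as both appear in the source
procedure), and a rhythmicity score $1/(1+\mathrm{cv})$ where cv is the
SD/mean of pooled inter-peak and inter-trough intervals (windows with
fewer than three extrema of both kinds score 0).

The state model is a trainable stand-in with the same contract as the
original (which was trained on clinical scalp EEG and is not embedded
here): class-conditional full-covariance Gaussians on (log theta power,
log sigma power, rhythmicity) with the class prior from label
frequencies, giving a Bayes posterior per window. The default posterior
threshold is 0.95. Supra-threshold runs become intervals spanning the
run's window extent; runs separated by less than 0.1 s merge (step-level
dropouts should not split one event); intervals are clipped at segment
boundaries and excluded-mask runs; and anything shorter than 0.5 s is
discarded. Spindle rate is detections per analyzable minute. On
synthetic recordings at burst SNR 2 the detector holds recall and
precision above 0.8 (midpoint-containment matching), and it never
returns an event shorter than 0.5 s.

## Spindle features and synchrony

Per-spindle sigma power Hann-windows the detection, zero-pads to 4 s
(0.25 Hz grid) and averages power over the closed 10.25–14.75 Hz band
(19 bins). Indicator vectors are 1 whenever ≥1 source of a region is in
a spindle; each maximal run yields a 2 s epoch centred on the *run*
midpoint (the run is defined on the indicator, not on any single
constituent detection), with edge-clipped epochs dropped. Intra- and
inter-hemispheric coherence average pairwise multitaper coherence at
12.5 Hz among spindle-exhibiting sources only, over pairs first and
then epochs (the averaging order is not determined by the source
procedure; pair-then-epoch is fixed here for reproducibility). Subjects
with no qualifying epoch get a missing value, never a zero. Bilateral
synchrony is the dot product of the two hemispheres' indicators divided
by the size of their union (0 on an empty union): 1 for fully
co-occurring spindles, 0 for disjoint ones, 9/11 on the canonical
overlap-9/union-11 example.

## Group statistics

The group contrast is a log-link quasi-Poisson mixed model: response
spindle count (or rate with exposure offset) on active and resolved
indicators plus age, with a per-subject random intercept for the two
hemisphere measurements. It is fit by iterated pseudo-likelihood
(PQL-style): each IRLS step refits the working response as a weighted
random-intercept linear mixed model, solved by profiling the REML
criterion over the variance ratio with a Woodbury block inverse, which
makes one fit a few milliseconds — fast enough to screen 31 regions over
hundreds of simulated cohorts. The dispersion is the working model's
REML residual variance and scales the standard errors only; Wald
t-tests give per-coefficient p-values (quasi-families have no true
likelihood for single-coefficient LRTs). The implementation is checked
against an independent PQL implementation (`MASS::glmmPQL`) in the test
suite. A log-link coefficient $\beta$ for the active group converts to a
percent reduction $100(1-e^\beta)$; $\beta=\ln 0.291$ gives the 70.9%
benchmark.

Linear (mixed) models for approximately normal features are ML fits via
`lme4`, reducing to OLS with one measurement per subject. Nested ML
fits are compared by likelihood ratio against $\chi^2$ references (2 df
for the group contrast on spindle features, 4 df for the global
cognition models, 1 df per-task). Normality screening uses a Lilliefors
test whose p-value is calibrated by seeded Monte-Carlo simulation of the
null statistic (≥10,000 draws by default) — exact at any sample size up
to Monte-Carlo error, unlike table interpolation. The regional screen
fits the group model per atlas label (31 labels per hemisphere-averaged
set) and adjusts the active-group p-values by Benjamini–Hochberg at
q = 0.05; per-region failures are reported, not fatal. Under a complete
null the screen's probability of any flag is bounded by q, which the
acceptance suite verifies over 200 simulated cohorts.

## Cognition models

Spindle rates enter cognition models through the inverse hyperbolic
sine, $\mathrm{ihs}(x)=\ln(x+\sqrt{x^2+1})$, which tames extreme
observations while remaining defined at zero. Focal rates average
sources in the inferior Rolandic cortex; regional rates average all
sources in the significantly affected regions; non-focal rates exclude
the focal region from that set. The default affected-region list is the
nine-region set the regional screen identifies under the study
conditions (orbitofrontal ×2, rostral middle frontal, superior frontal,
triangularis, inferior Rolandic, superior parietal, insula, entorhinal),
and is configurable from any `regional_screen()` result so the pipeline
stays self-consistent end-to-end on synthetic data.

Per task: motor scores pair each hand with the contralateral-hemisphere
rate and carry a subject random intercept (two hands per subject);
processing speed and IQ use the mean of hemispheres; phonological
awareness uses the left hemisphere. Age is screened into each model at
P < 0.1 (it enters only the motor model under the default generator).
Missing task scores drop the subject from that task only, and each fit
reports its n — nothing is imputed. The global test sums the four task
log-likelihoods (assuming task independence conditional on spindle
rate) against the summed intercept-only nulls at 4 df. The
focal-versus-regional comparison nests the focal-only model inside
focal + non-focal and tests at 1 df per task and 4 df globally; a
collinearity warning is attached when focal and non-focal rates
correlate above 0.999. The IQ-conditioned variant refits motor,
processing-speed and phonological models with the IQ z-score as an
extra covariate and reports residual cross-model correlations before and
after — the stated purpose of the published supplementary variant —
without guessing at its unprinted functional form. For mixed-model fits
both marginal and conditional variance-partition R² are reported, since
the source material does not say which definition its R² values use.

## Numerical choices and degenerate inputs

* Frequency bands are closed at both edges throughout; chord endpoints
  for the sigma bump use the single nearest bin (exact on the 1 Hz
  grid).
* Zero signals raise errors where logs or ratios would be undefined
  (slope fitting, coherence, relative power); rhythmicity degrades to 0
  rather than erroring on extrema-poor windows.
* PQL iterations stop when coefficients move by less than $10^{-8}$
  (relative); the variance-ratio profile is optimized on a log grid
  with an explicit boundary check at zero.
* The Lilliefors Monte-Carlo null and every generator are seeded;
  identical configurations reproduce byte-identical pipeline outputs.
* Detection intervals are half-open, 0-based seconds everywhere.

## Problem sizes used in tests

The test and acceptance suites choose simulation sizes as a balance of
statistical resolution and runtime: 10-minute recordings for detector
guarantees; 200 subjects/group × 100 seeds for rate-ratio recovery;
20 subjects/group × 31 regions × 200 seeds for FDR calibration;
100 subjects × 150–200 seeds for cognition size/power; 6-subject
renders for end-to-end determinism. These are the package's own
choices and are stated here so they can be scaled up by users with more
patience.

## What passing tests do and do not show

The generator reproduces the *statistical* structure the analysis
assumes: 1/f backgrounds, discrete sigma-band events, overdispersed
group-specific rates, IHS-linear cognition scores. It does not emulate
volume conduction, inverse-solution spatial leakage, non-stationary
sleep architecture, movement artifact morphology beyond slope
flattening, or realistic spindle amplitude distributions. Passing the
suite therefore demonstrates that the pipeline measures what it claims
on data satisfying its assumptions — detector guarantees at a given
burst SNR, calibrated model inference, correct statistic definitions —
not that those assumptions hold in any particular clinical recording.

## Known limitations

* The detector is a Gaussian-Bayes stand-in trained per study; it does
  not reproduce the original published state model's exact decision
  boundary.
* The quasi-Poisson PQL shares PQL's known small-count bias; it matches
  `glmmPQL` rather than an exact integrated likelihood.
* Intra-regional coherence requires ≥2 spindle-exhibiting sources per
  epoch; single-source regions yield missing values by design.
* The artifact criterion's single-window slope scatter (SD ≈ 0.6)
  trades analyzable time for specificity; steeper backgrounds lose
  less.
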