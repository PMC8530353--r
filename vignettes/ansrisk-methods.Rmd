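---
title: "Methods: from heartbeats and telemetry to a collision-risk regression"
author: "ansrisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from heartbeats and telemetry to a collision-risk regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ansrisk)
```

## The analysis in one paragraph

Occupational drivers' autonomic state can be monitored continuously through
heart-rate variability (HRV), and their rear-end-collision risk can be
quantified continuously by learning, from vehicle behaviour alone, the
probability that a 20-s driving segment resembles a validated near-miss
situation.  This package implements the full chain: beat-to-beat R-R series
are turned into windowed autonomic indices; 1 Hz telemetry is classified into
speed-regime driving scenes; per-scene gradient-boosted classifiers convert
warning-event labels into a continuous risk index; the index is resampled to
2 min, joined with the autonomic windows and filtered into a regression
dataset; logistic quantile regression with hierarchical AIC selection
estimates how sympathetic and parasympathetic indices shift each quantile of
the bounded risk index; and shift-phase contrasts compare the resting and
driving autonomic states.  A synthetic cohort generator with known planted
effects makes every stage testable without fleet data.

## Autonomic indices from the tachogram

R-R series are cut into tumbling 120-s windows (a single leading 90-s span
for the resting pre/post measurements).  Windows are half-open and anchored
at shift start so that they align exactly with the 2-min analysis grid
downstream.

**Quality gate.** A window is excluded when misdetected or abnormal beats
exceed 10% of its beats — exactly 10% still passes — or when its average
heart rate leaves a physiological band (default 30–150 beats/min).
"Abnormal" means an interval outside 300–2000 ms or a successive relative
jump above 20%.  The gate only excludes windows; it never repairs beats,
so no interpolation artifacts can leak into the spectra.  The gate is
monotone: adding flagged beats can only hurt.

**Spectral estimation.** Frequency-domain HRV on 2-min records uses the
maximum entropy method: the unevenly spaced tachogram (unflagged beats only)
is interpolated onto an even 4 Hz grid with a cubic spline, linearly
detrended, and fit with a Burg autoregressive model.  The AR order is fixed
at 16 by default (an AIC-selected order capped at 30 is available); order 16
resolves the two HRV bands on 480-sample records without spurious peak
splitting.  The one-sided AR spectrum is rescaled so its trapezoidal
integral over [0, 2] Hz equals the detrended sample variance, keeping band
powers calibrated in ms².  LF is the integral over 0.04–0.15 Hz, HF over
0.15–0.40 Hz; LF/HF indexes sympatho-vagal balance.

**Deviation scores.** Because LF and HF depend on heart rate and age, the
analysis uses age-referenced deviation scores on a mean-50, SD-10 scale:

$$LF_{score} = 10\,\frac{\log(LF/RRI_{avg}) - \mu_{LF}(age)}{\sigma_{LF}(age)} + 50,
\qquad
HF_{score} = 10\,\frac{HF/RRI_{avg} - \mu_{HF}(age)}{\sigma_{HF}(age)} + 50.$$

The asymmetry is intentional and implemented as defined: the LF input is
log-transformed, the HF input is not (`log_hf = TRUE` switches a logged
variant on).  The normative means and SDs per age year come from reference
populations that are not publicly distributed, so the package ships a
clearly-labelled *synthetic* normative table — smooth curves with spectral
power declining in age — plus a CSV override (`read_normative_csv()`).
Scores are therefore relative to the supplied table; their differences and
regression coefficients are meaningful, their absolute level is not
clinically interpretable.

**Time-domain indices** are computed on unflagged beats: AVGHR =
60000/mean(RRI); SDNN with the n−1 denominator; NN50 as the count of
successive differences exceeding 50 ms (the standard reading of the looser
phrase "NN intervals greater than 50 ms"); RMSSD as the root mean square of
successive differences.

## Driving scenes from speed

Road type constrains speed, so speed rules proxy road type.  Four scene
rules are stated at minute or second resolution and are ambiguous in three
places; the package resolves them as follows and treats the choices as
fixed:

* **High-speed**: a minute qualifies when speed exceeds 70 km/h for *more
  than* 30 s (31 s is the threshold).  The carry-over rule — a minute after
  a high-speed minute stays high-speed — has no stated termination, and as
  written would never end; carry-over here stops at the first minute that
  independently qualifies low-speed, has a majority of stopped/extremely-low
  seconds, or never reaches 20 km/h.
* **Low-speed**: minutes with more than 45 s below 20 km/h, "continuing for
  over 4 min" read as runs of at least 5 consecutive qualifying minutes.
* **Extremely low**: seconds at (0, 3) km/h whose centered 5-s moving-average
  speed stays below 8 km/h at every second of the 10 s before and after;
  never at exactly 0 km/h.
* **Stopped** at 0 km/h; everything else moving is **medium**.

Minute labels are broadcast to seconds and resolved with precedence
STOPPED > XLOW > LOW > HIGH > MEDIUM.  A 20-s feature window takes the
majority label of its seconds, ties resolving toward the faster scene.

## The near-miss risk index

Each tumbling 20-s window carries 15 features (max/min/mean/SD of speed and
the two acceleration axes, the SD of speed around its centered 10-s moving
average, and the mean-speed differences to the previous and next windows)
and a 0/1 label: whether a validated warning sounded within the window
(half-open, so a warning at exactly the boundary belongs to the next
window).  Edge windows missing a neighbour get zeroed difference features,
are flagged incomplete, and are excluded from training.

One gradient-boosted tree classifier is fit per scene, for the high- and
medium-speed scenes only — low-speed driving produces no rear-end
near-misses, so the index is undefined there and reported as missing.
Hyperparameters come from a grid search (trees {100, 300} × depth {3, 5} ×
learning rate {0.05, 0.1} by default; the grid itself is a package
default) maximizing mean out-of-fold AUC under stratified, shuffled,
seeded 5-fold cross-validation.  No class re-weighting is applied, and folds
are not grouped by driver by default (a `group_by_driver` option keeps
each driver's windows together for across-driver validation); pooled
out-of-fold ROC points, AUC and gain-based importances (normalized to sum
to 1) are reported.  Multi-driver training tables must carry a `driver_id`
column so windows join their scenes driver-by-driver.  The risk index of a
window is its predicted class-1 probability.

## The regression dataset

The 20-s index is resampled to 2 min by averaging exactly six values; a
block with any missing value is dropped (conservative; a missing value means
the index was undefined during part of the block).  Records are kept when
the driver drove continuously (every second of the block at speed > 0), the
block mean speed is at least 20 km/h (the validated domain of the index; a
strict every-second variant is available by flag), the autonomic window
passed quality, and the risk block exists.  The count after each filter is
attached as a funnel.  Risk enters the regression in percent.

## Logistic quantile regression and model selection

The risk index is bounded in [0, 100] and heavily right-tailed, so
conditional quantiles of the logit-transformed response are modelled:

$$Q_y(\tau \mid X) = \frac{y_{max}\,e^{X\beta_\tau} + y_{min}}{1 + e^{X\beta_\tau}},
\qquad z = \log\frac{y - y_{min}}{y_{max} - y},$$

with $y_{min} = 0$, $y_{max} = 100$ and observations clamped into
$[\varepsilon, 100-\varepsilon]$, $\varepsilon = 0.1$ by default ($\varepsilon$ is
configurable and fitted quantiles always respect the bounds).  The
coefficients minimize the check loss
$\sum_i \rho_\tau(z_i - x_i\beta)$, $\rho_\tau(u) = u(\tau - 1\{u<0\})$.

**Solver.** The check loss is minimized by a Frisch–Newton interior-point
method (Mehrotra predictor–corrector on the bounded-dual linear program),
implemented in compiled code; an IRLS smoothing solver serves as fallback.
The duality-gap tolerance is $10^{-9}$ relative.  The solver is verified in
the test suite against brute-force lattice minimization on small instances
and against the quantile-coverage identity (the fraction of observations
below the fitted $\tau$-quantile matches $\tau$ to within 0.02 at
$n = 20000$).

**AIC.** Quantile fits are compared by AIC under the asymmetric-Laplace
working likelihood with scale set to the mean check loss
$\hat\sigma = n^{-1}\sum_i\rho_\tau(r_i)$:
$\hat\ell = n(\log(\tau(1-\tau)) - \log\hat\sigma - 1)$, AIC
$= 2k - 2\hat\ell$.  The same closed form is used for every model, so AIC
*differences* at fixed $\tau$ are meaningful; no cross-$\tau$ comparison is
made.  Under this definition a pure-noise covariate increases AIC in about
79% of replicates (the $\chi^2_1 < 2$ rule familiar from OLS-AIC).

**Inference.** Standard errors are bootstrap SDs over records resampled
i.i.d. with replacement (2000 by default; configurable),
with two-sided normal-approximation p-values at $\alpha = 0.05$.  No driver
clustering is applied; a clustered bootstrap would be a natural extension.  Collinearity is screened with VIF < 10.

**Hierarchical selection.** Step 1 fits the control-only baseline (AVGHR,
age, mean speed; sex is dropped when invariant, as in an all-male cohort).
Step 2 adds one sympathetic-reflecting variable (LF_score, LF/HF, SDNN) and
one parasympathetic-reflecting variable (HF_score, NN50, RMSSD) — all nine
pairs, no interactions — at each of $\tau \in \{0.25, 0.5, 0.75, 0.9,
0.95\}$ (upper quantiles because the risk distribution is right-tailed).
Models are ranked by AIC within each quantile (average ranks on ties);
among candidates whose two added coefficients are significant at every
quantile, the smallest average rank wins.  `aic_rank_table()` exposes the
rank arithmetic directly.  The "mean" column companion is OLS on the
transformed response (`fit_mean_model()`), with a quasi-likelihood
fractional-logit GLM available behind `method = "fractional"`; OLS on the
logit scale is the default because it reports the mean effect on exactly
the same scale as the quantile coefficients.

## Shift-phase comparisons

The driving-state representative of each index is its mean over
quality-passing 120-s windows starting within 30 min of driving onset;
pre/post representatives are the single resting 90-s windows.  For each
index, all three phase samples are gated through Shapiro–Wilk at
$\alpha = 0.05$ — all must pass (per-group gating; stricter than pooled and
standard practice) — choosing Tukey–Kramer (studentized range, unequal group
sizes honoured) or Steel–Dwass.  Steel–Dwass jointly ranks each pair with
mid-ranks and a tie-corrected variance; large samples are referred to the
studentized-range distribution with $k$ groups, while pairs with
$\min(n) \le 6$ use exhaustive enumeration of all assignments.  In that
exact small-sample regime the p-value is the pair's exact permutation tail
(no studentized-range family adjustment), which is what an enumeration
oracle can verify; at cohort-scale group sizes (about 20 drivers) the
large-sample path is the one exercised.

## The synthetic cohort: what it emulates, and what it does not

The generator reproduces naturalistic fleet-study conditions end to end:
drivers aged 35–63
(mean ≈ 49), shifts of 30 min pre-shift rest + 6 h driving/loading mix +
30 min post-shift rest (no shift schema is published; this template is the
package's choice), 1 Hz telemetry over high/medium/low/stopped regimes with
AR(1) speed noise, rare validated warnings, and beat series whose LF
(0.10 Hz) and HF (0.25 Hz) amplitude modulation follows a latent per-second
stress state — up for LF, down for HF — so stress raises LF/HF and lowers
NN50/RMSSD.  Amplitude-modulated sinusoids are used instead of a full
integral-pulse-frequency-modulation model: they place power exactly in the
two analysis bands and admit a simple periodogram oracle.

Three generator choices deserve emphasis:

* **Stress is a single scalar in [0, 1]** (baseline + slow drift + decaying
  events + noise, rate-limited per second).  "Acute stress-induced fatigue"
  has no single agreed operational definition; the generator owns this one
  and records it in the ground truth.
* **Warnings follow a logistic hazard per 20-s window** on speed SD, mean
  speed and mean stress, with a positive stress coefficient planting the
  headline association.  The intercept is calibrated so that the
  warning-positive fraction of driving windows lands in a realistic 1–20%
  band for validated fleet warnings (observed ≈ 9–17% high-speed,
  ≈ 5% medium-speed); warnings are timestamped uniformly among the window's
  moving seconds and never at speed 0.
* **Stress perturbs speed-keeping**: speed-noise innovations scale with
  (1 + 0.8 · stress).  Without some stress→behaviour channel the
  behaviour-only risk index is structurally independent of stress and no
  association between autonomic indices and the index could exist; the
  coupling mirrors the proposed mechanism (stress-induced fatigue degrades
  vehicle control).

Artifact injection emulates missed beats (two intervals merge, preserving
elapsed time) and ectopic detections (one interval splits 40/60), flagging
affected beats, at 1% / 0.5% by default.

What the generator does *not* emulate: road geometry and traffic
interaction, GPS or weather, circadian structure, driver-specific shift
schedules, device-specific artifact morphology, or any dependence of
warnings on actual inter-vehicle distance.  Passing tests on this cohort
show that the pipeline recovers *planted* effects of the stated form at the
stated sizes — not that real fleet data would yield the same coefficients,
AUCs or p-values.

## Numerical choices and problem sizes

Degenerate inputs: empty windows are carried (quality-failed) rather than
erroring; constant tachograms yield zero spectra; exact collinearity reports
an infinite, flagged VIF; a zero check loss makes AIC error rather than
return −∞; single-class training scenes raise an error naming the scene.
Ties: AIC ranks average; window-scene ties go to the faster scene; rank ties
in Steel–Dwass use mid-ranks with variance correction.

The test suite and acceptance checks run at sizes chosen for a single CPU:
selection-recovery uses 50 cohorts of 2000 records with 20 bootstrap
resamples; coverage and sign-recovery use 20000 records; the bootstrap
coverage study uses 200 replicates of 250 records with 100 resamples; the
risk-model check uses an 8-driver cohort with 3-h mid-shifts.  Function
defaults keep the full-scale values (2000 bootstrap resamples, 6-h
mid-shifts).

## Known limitations

The normative table is synthetic, so deviation-score levels are not
clinically anchored.  The HF score's missing log transform is implemented
as defined, which makes its scale sensitive to the normative SD.  The AIC
form for quantile fits is one of several defensible choices; only
within-quantile differences are used.  Mixed-effects or time-series
extensions, interaction terms, non-crossing constraints across quantiles
and causal interpretation are out of scope.
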