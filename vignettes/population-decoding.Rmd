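---
title: "Population decoding of pooled orientation signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population decoding of pooled orientation signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orientpool)
```

## The question the package addresses

When a texture contains hundreds of differently oriented lines, observers
nonetheless report a single global orientation. Which statistic of the local
orientations does that percept follow? If the distribution of orientations is
symmetric, every candidate — mean, median, mode — coincides and the question
cannot be answered. `orientpool` therefore builds *skewed* orientation
distributions whose mean, median and mode are pulled apart, simulates a
two-alternative forced-choice (2AFC) discrimination task against them, and
asks which population read-out of a bank of model neurons predicts the
resulting points of subjective equality (PSEs).

The model chain is:

1. a discrete orientation distribution relative to a reference
   (`orientation_distribution`);
2. a sampled texture stimulus — 500 lines in one 0.052 s frame (static,
   orientations distributed over space) or 25 frames of 0.052 s with one
   common orientation each (dynamic, distributed over time);
3. a bank of 180 orientation-tuned neurons at 1° spacing with Gaussian
   sensitivity profiles and independent Poisson spiking;
4. three read-outs of the spike counts: vector average (VA),
   winner-takes-all (WTA) and maximum likelihood (ML);
5. a simulated observer who compares the decoded orientations of two
   intervals, yielding psychometric data that are fitted with a logistic
   function.

## The encoding model

Neuron $i$, preferring orientation $\theta_i$, has sensitivity

$$S_i(\theta) = \exp\!\left[-\left(\frac{d(\theta,\theta_i)}{h}\right)^2
\ln 2\right],$$

where $d$ is the *axial* distance (wrapped to at most 90° on the
180°-periodic orientation circle) and $h = 22.5°$ is the half-height
half-width bandwidth, so sensitivity is exactly 0.5 one bandwidth away. The
expected spike count to a stimulus with orientation proportions
$\mathrm{pr}(\theta)$ over an interval of $t$ seconds is

$$R_i = R_{\max}\, t \sum_{\theta} S_i(\theta)\,\mathrm{pr}(\theta),
\qquad R_{\max} = 60\ \mathrm{spikes/s},$$

and the observed count is a Poisson draw with that mean. Defaults
(spacing 1°, $h$ = 22.5°, $R_{\max}$ = 60) give dense, even coverage of the
orientation space.

Three numerical choices deserve note:

* **Axial wrapping.** The tuning distance is wrapped
  ($d = \min(|\Delta|, 180 - |\Delta|)$): a linear difference would break
  neurons preferring orientations near the 0°/180° seam, and every decoder
  below is rotation-equivariant only because the encoding is.
* **Rate floor.** Mean counts are floored at `rate_floor` × t
  (default 0.01 spikes/s) so that log-likelihoods stay finite. At the default
  the floor contributes well under one spike per interval across the whole
  bank and has no measurable effect on any estimate.
* **Frame additivity.** Dynamic stimuli are encoded frame by frame with
  $t$ = 0.052 s and the per-frame mean counts summed; because sums of
  independent Poisson variables are Poisson, a single draw from the summed
  means is distributed identically, and that is what `encode_stimulus()`
  draws.

Contrast enters only through an optional gain hook `g(contrast)` in (0, 1]
multiplying $R_{\max}$. The model itself specifies no
contrast-to-firing-rate mechanism, so the default is the identity gain; the
hook exists so that contrast manipulations can be explored, not calibrated.

## The stimulus distributions

Three families reproduce the stimulus protocol:

* **Experiment 1** (`experiment_conditions(1)`): piecewise Gaussians sampled
  at 2.5° over ±45°, counter-clockwise SD 15–30° against clockwise SD 15–0°,
  halves weighted *in proportion to their SDs*. This density-matched
  weighting keeps the probability density continuous at the mode; in the
  extreme 30/0 condition it places all mass on one half, whose discrete
  truncated-half-Gaussian mean sits 18.27° from the mode.
* **Experiment 2** (`experiment_conditions(2)`): piecewise Gaussians with
  clockwise SDs 15–45° sampled at 0.5° and counter-clockwise SDs 6–18°
  sampled at 2.5°, truncated at ±90°, with *equal-mass* halves. Equal-mass
  weighting pins both the median and the mode to the junction while the mean
  moves with the heavy tail — the property these conditions exist for. The
  sampling intervals are treated purely as support spacings; they do not
  change the mass a half carries.
* **Experiment 3** (`experiment_conditions(3)`): skewed uniforms sampled at
  2.5°, counter-clockwise ranges 45–75° against clockwise ranges 45–15°,
  equal-mass halves, so the junction is the median by construction while the
  mean sits in the long tail.

Since a support point at −90° would duplicate +90° on the axial circle, the
builders drop it; for every condition above its weight is below $10^{-5}$ of
its half. For the same reason a distribution *containing* +90° has no exact
mirror image: +90° is its own reflection.

Sign convention, used everywhere: orientations live in [0°, 180°), signed
offsets in (−90°, 90°], positive offsets are clockwise. PSEs are reported
both signed and as magnitudes of rotation toward the distribution's long
tail.

## The decoders

**Vector average.** The printed textbook form — preferred orientations
averaged with response weights — is ill-defined on axial data at the seam.
`va_decode()` therefore computes the weighted *axial Fréchet mean*: the
orientation $m$ such that the count-weighted mean of the signed offsets of
all preferred orientations from $m$ (each wrapped to (−90°, 90°]) is zero,
found by fixed-point iteration started at the doubled-angle resultant. Away
from the seam this equals the plain weighted vector average; unlike the pure
doubled-angle resultant it does not shrink wide distributions toward their
axial centre, which matters for the ±90°-wide Experiment 2 and 3 stimuli.
Convolution with the symmetric tuning curve leaves the read-out's central
tendency at the stimulus mean for compact distributions; for stimuli whose
convolved response wraps past ±90° a residual pull toward the centre remains
(about 1.5° for the widest conditions) because mass at the orthogonal
orientation genuinely has no side.

**Winner-takes-all.** The preferred orientation of the most active neuron,
ties uniform at random. Its estimates track the *peak of the convolved
response*, which for strongly skewed distributions sits on the dense side of
the median, and they are much more variable than ML at short durations.

**Maximum likelihood.** `loglik_profile()` scores candidates by
$\log L(c) = \sum_i n_i \log R_i(c)$, dropping candidate-independent
constants. Two candidate families are provided:

* *Single orientations* (the default for raw calls): $R_i(c)$ is the point
  response $k\,S_i(c)$. Because $\log S$ is quadratic in distance, this
  likelihood is maximised close to the response-weighted mean — with a
  22.5° bandwidth on a 180° space it lands within a fraction of a degree of
  the vector average for every stimulus family above, so it cannot be
  distinguished from VA behaviourally.
* *Matched templates* (the default inside the simulated observer): the
  candidates are translated copies of the interval's own generating
  distribution, i.e. the likelihood family of an ideal observer who knows
  the stimulus up to rotation. Its estimate recovers the distribution's
  reference — the mode for the Gaussian experiments, the median junction for
  the uniforms — which is what makes ML behaviourally separable from the
  mean-tracking VA, and is how the task simulations in this package define
  the ML observer.

On the uniform wrap-around grid both candidate-response matrices are
circulant, so their column sums are candidate-independent and dropping the
$-\sum_i R_i(c)$ Poisson term changes nothing (the `include_rate_term`
argument exists to verify this). Exact likelihood ties are broken uniformly
at random; flat profiles, all-equal counts and zero resultants are flagged
degenerate, and the forced-choice layer resolves degenerate estimates with a
fair coin.

## The simulated observer

`simulate_2afc_trial()` draws a random standard orientation uniformly over
the 180° range, places the comparison's reference `level` degrees clockwise
of it, samples and encodes both intervals independently, decodes each with
the chosen read-out, and judges the comparison "more clockwise" by the sign
of the axial difference of the two estimates. The only noise source is
Poisson spiking — the simulated observer adds no internal noise.

`run_constant_stimuli()` places 9 levels symmetrically about the anticipated
PSE — the negative of the noiseless decoder prediction for the comparison —
spanning ±3 pilot thresholds, the pilot threshold coming from a 50-trial
pre-run (clamped to [0.75°, 12°] with a 4° fallback, so a pathological pilot
cannot collapse the level range). The session default is 80 trials per level
(720 trials). Levels are a design choice, not data: the protocol does not
print its level values, so anticipated-PSE-centred placement is the neutral
reconstruction.

`fit_logistic()` fits
$y = 100 / (1 + e^{-(x - \mathrm{PSE})/\theta})$
by binomial maximum likelihood via `stats::glm`, with the sign fixed so the
curve increases toward clockwise judgements; $\theta > 0$ is the
discrimination threshold. Binomial likelihood is well defined at small
per-level counts; a least-squares objective on the percentages is available
for strict replication of least-squares fits. `bootstrap_pse_ci()` takes
5000 nonparametric per-level binomial resamples and returns the percentile
95% interval; resampled fits run through an in-package vectorised
Newton–Raphson fitter (all resamples at once) whose agreement with `glm` is
enforced by the test suite. More than 5% non-converged resamples flags the
interval.

## The duration and contrast experiments

`simulate_vertical_judgement()` probes a single interval: is a static
texture oriented clockwise of implicit vertical? The diagnostic stimulus
(`diagnostic_distribution()`) is the 75°/15° equal-mass skewed uniform with
its median placed 7.5° *clockwise* of vertical — midway between the
median (which the template-ML observer recovers, +7.5° from vertical) and
the mean (which VA tracks, reaching about −6.8°). The two read-outs thus
fall on opposite sides of vertical with margins above 5°, which is exactly
the property that makes the stimulus diagnostic; with the median *at*
vertical no admissible skewed uniform separates them, since template-ML is
unbiased about the median. `run_duration_experiment()` verifies this
sign-divergence precondition from the noiseless predictions before running
and rejects non-diagnostic stimuli.

Durations follow the seven-point log-spaced grid from 0.05 to 3.33 s. As
duration grows, spike counts grow linearly and every estimate's variability
shrinks, so the ML observer's clockwise judgements become increasingly
consistent (saturating at 1) while the VA observer's counter-clockwise
judgements do the same — the model predicts each decoder's curve separately
and contains no mechanism for a transition between read-outs; the two curves
are what the human transition is compared against.
`run_contrast_experiment()` repeats the grid at contrasts 0.25/0.5/1 through
the gain hook; with the identity gain it reproduces the duration experiment
exactly at the same seed.

## What the synthetic stimuli do and do not emulate

The generator reproduces the stimulus *statistics*: discrete skewed
distributions, 500-line frames, 25-frame sequences at 0.052 s, sampling with
replacement over space or time. It does not render pixels — line positions,
Gaussian luminance envelopes, the 12° circular window and monitor
calibration are outside the model, and contrast has no calibrated effect on
firing. Passing tests therefore demonstrate properties of the decoding
model under Poisson noise, not of human vision: real observers bring
adaptation, surround interactions, correlated variability and internal noise
that this model deliberately omits.

## Problem sizes used by the tests

The test suite runs each key 2AFC condition at the full session scale
(9 levels × 80 trials plus a 50-trial pilot), bootstrap intervals at their
5000-resample default, decoder-oracle equivalence on 1000 random draws,
CI-coverage simulations at 200 repetitions × 1000 resamples, and the
duration grid at 300 trials per point; Monte-Carlo property checks use a few
hundred trials each. These sizes keep every Monte-Carlo standard error an
order of magnitude below the tolerances being asserted.

## Known limitations

* For distributions with substantial mass near ±90° the notion "mean
  orientation" is itself frame-dependent; the axial Fréchet mean is the
  principled resolution but still reads out 1–2° closer to the centre than
  the linear mean of the offsets for the widest conditions.
* The ML observer must be told its candidate family; the package's task
  simulations match it to the generating distribution (an ideal-observer
  assumption). With single-orientation candidates ML becomes behaviourally
  indistinguishable from VA.
* WTA estimates at 0.052 s rest on very few spikes per neuron and are
  dominated by tie-breaking among sparsely active neurons; their PSEs are
  unbiased for symmetric stimuli but their thresholds are far higher than
  ML's or VA's.
* No lapse or guess-rate parameters are fitted; the simulated observer never
  lapses, so the logistic asymptotes are exactly 0 and 100%.

## A worked session

```{r, eval = FALSE}
library(orientpool)

# the strongly skewed Gaussian: all mass counter-clockwise of the mode
cond <- experiment_conditions(1)[4, ]
res <- run_spatial_experiment(1, decoders = "va",
                              conditions = cond, seed = 7)
res[, c("condition", "decoder", "pse_deg", "threshold_deg",
        "ci_low", "ci_high", "dist_mean")]
```

The fitted PSE magnitude lands within a degree of 18.3° — the mean offset of
the comparison distribution — reproducing the central finding that perceived
global orientation follows the mean (vector-average read-out) of the
orientation signals, across both space (`run_spatial_experiment()`) and time
(`run_temporal_experiment()`).
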