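---
title: "confclust: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{confclust: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

confclust analyses single-trial EEG correlates of performance monitoring
(error-related negativity and confidence-related potentials) in designs
where two groups are matched on task performance by an adaptive
staircase, together with the behavioural metacognition of the same task.
This vignette explains the statistical machinery, the synthetic world the
package can generate, and the design decisions taken where the design was
genuinely open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The experimental world being modelled

A motion-discrimination trial: random-dot motion left or right, response
by reaching a screen target with the mouse (6 s deadline), then a
confidence rating on a 0-100 visual-analogue scale where 50 means "not
sure at all" and values below 50 signal a post-decisional change of mind.
Motion coherence is driven by a 1-up-2-down staircase, so every
participant in both groups (`control`, n = 19; `ssd`, n = 14 in the
reference design) performs near the rule's asymptote
p = sqrt(0.5) ~ 70.7% correct. EEG (64-channel 10-10, analysed at 128 Hz)
is time-locked to *movement onset* -- the first crossing of 20% of the
trial's peak mouse velocity, minus a fixed five-frame (~83 ms at 60 Hz)
offset -- rather than to the response click.

## Kinematics

`compute_velocity()` is the plain finite-difference speed at interval
midpoints. `detect_movement_onset()` applies a closed (>=) threshold at
20% of the trial's maximum speed, earliest sample on ties; sub-threshold
micro-movements can never produce the first crossing, which implements
the "non-decisional peaks are discarded" reading without a separate
rule. The five-frame offset may push an onset before 0; it is floored at
0 and flagged (`attr(..., "floored")`), a case the source design leaves
open. A change of mind before the response is a midline crossing
occurring after the cursor has covered 20% of the vertical distance to
the target's y-projection; confidence exactly 50 is *not* a
post-decisional change of mind (the rule is strictly "lower than 50").
Exclusion precedence is fixed: `no_movement > early (<100 ms) >
late (>6 s) > com_pre > com_post > none`. No smoothing is applied by
default; a 3-sample moving average is available for noisy real
recordings.

## EEG preprocessing

The pipeline order is fixed and test-enforced: band-pass filter (FIR,
zero-phase, 0.5-45 Hz) and resample to 128 Hz, epoch -1 to +2 s around
movement onset, common-average reference, artifact handling, baseline
correction, percentile trimming.

Numerical choices:

* Filtering uses Hamming windowed-sinc kernels applied by FFT convolution
  with exact group-delay compensation (symmetric kernels are zero-phase).
  Resampling is Fourier interpolation, which handles the non-integer
  1200 -> 128 Hz ratio exactly and without phase error.
* Baseline correction subtracts ONE scalar per participant and channel --
  the mean over -700 to -200 ms pooled across that participant's retained
  trials. Per-trial baselining would transfer pre-movement effects into
  the epoch; the cross-trial scalar preserves trial-to-trial baseline
  differences. The operation is idempotent. The source design does not
  say whether baselines precede trimming; the pipeline's stated operation
  order (baseline, then trim) is followed.
* Percentile trimming drops `ceil(n/100)` trials per tail of the
  per-participant max-|amplitude| distribution (rounding convention:
  ceiling; ties broken by trial index).
* Participant exclusion: per channel, a participant's variance is
  compared against the across-participant pool mean + 2 SD; strictly more
  than 10 flagged channels excludes the participant. The pooling axis
  (per-channel across participants) is our choice; the source leaves it
  open.
* ICA with automatic component classification and spherical-spline
  interpolation are deliberately out of scope. The documented surrogate
  rejects epochs with peak-to-peak amplitude above 150 uV or |EOG| above
  threshold (EOG derived as AF8-AF7 and FPz-AFz). Users with real data
  can plug an external ICA step in before `preprocess_epochs()`.

## The three-step statistical procedure

**Step 1 (electrode scan).** For every electrode and sample in 0-500 ms
(closed interval), the single-trial mixed model `amplitude ~ term * group
+ (1|participant)` is fitted and the term's p-values are FDR-corrected
jointly over the whole electrodes x samples family (the most conservative
reading of a per-sample, per-electrode scan). Electrodes with at least
one significant sample, intersected with the a-priori fronto-central ROI,
move on. The group covariate is centred (-0.5/+0.5) so the scanned term
is the main effect across groups rather than one group's simple effect.
Confidence is scanned on correct trials only, as in the reference
analysis; `z_`-covariates are standardized within participant.

**Step 2 (cluster regression).** The same fixed-effects model is fitted
per sample over the selected electrodes jointly, now with electrode
nested in participant (`(1|participant/electrode)`); FDR runs over
samples. Runs of significant adjacent samples strictly longer than 50 ms
(>= 7 samples at 128 Hz; a run of k samples spans k/fs) become clusters;
the peak is the largest |test statistic|. Step 2 scans -0.2 to 0.75 s by
default: unlike step 1's 0-500 ms window, reported confidence effects can
begin pre-movement, so the step-2 window extends earlier -- the asymmetry
is intentional and configurable.

Effect amplitudes average the condition contrast (correct - incorrect,
or top - bottom per-participant tertile for graded covariates) over the
cluster electrodes and a 50 ms window centred on the peak, computed
within participant and averaged across participants; the window shrinks
symmetrically at epoch edges and reports the half-width actually used.
Tertiles use `ceiling(3 * rank / n)` with minimum-rank ties (all-equal
values all land in the bottom bin); models always use the continuous
ratings -- tertiles are display/contrast conveniences.

**Mixed-model engine.** Scanning fits the same design to thousands of
voltage series, far beyond what a general LMM fitter can do in the time
budget. For random-intercept structures the covariance
`I + l1*Z1Z1' + l2*Z2Z2'` inverts analytically (Woodbury within
electrode cells, Sherman-Morrison across a participant's cells), so REML
reduces to a 1-D/2-D profile optimization with O(#cells) evaluations;
the scan path vectorizes the profile over responses on a log-lambda grid
with parabolic refinement. lme4 remains available as
`fit_lmm(engine = "lme4")` and is the independent oracle in the test
suite (the two engines agree on the REML criterion to ~1e-5). Wald
normal-approximation p-values are used throughout: Satterthwaite degrees
of freedom are not available in the supported dependency set, and at
single-trial sample sizes (hundreds to thousands of rows) the difference
is negligible. Degenerate fits (variance ratio at the boundary) are kept,
not errored.

**Step 3 (cluster-level Bayesian models).** On cluster-averaged
amplitudes (per trial and electrode), model 4 is
`amplitude ~ correctness * group` with random intercepts and correctness
slopes at participant and electrode-within-participant; model 5 is
`amplitude ~ z_confidence * group * z_movementRT` with the full
`z_confidence * z_movementRT` random structure at both levels. Priors
are the stated mildly informative Gaussians (correctness: mean 1, sd 1;
group: 0, 1; correctness x group: -1, 1; confidence: 0.5; movement
onset: -1; the onset x group and confidence x group interactions: 0.5;
unstated terms standard normal, intercept N(0, 10)).

Because no Stan-like sampler is available in the supported environment,
the posterior is simulated by a conjugate Gibbs sampler written for this
package: Gaussian fixed effects, Gaussian random effects with
independent per-term variances (no intercept-slope correlation),
inverse-gamma priors on variances (tau^2 ~ IG(1.5, 0.5), sigma^2 ~
IG(0.001, 0.001)) -- the package's own documented defaults, replacing
half-Student-t priors that would break conjugacy. Two mixing aids make
the output usable at the default 4 chains x 2000 iterations (1000
warmup): a collapsed fixed-effects update (random intercept integrated
out via Woodbury) for single-intercept models, and an
interweaving recentering move (a deterministic-proposal Metropolis shift
of each random-intercept block's mean into the fixed intercept)
otherwise. Split-half R-hat is computed per fixed term; any R-hat >=
1.05 flags the fit (`converged = FALSE`) rather than failing silently.

Every fixed term gets both a directional **evidence ratio** -- the count
of posterior draws in the hypothesized direction over the count against,
capped at the total draw count when unopposed -- and a Savage-Dickey
**BF01** (Gaussian-kernel posterior density at zero over the closed-form
prior density at zero, Silverman bandwidth, doubled with a flag when
fewer than 10 draws fall near zero). The source reports both without
stating when each applies, so both are always reported side by side. One
subtlety: the reference analysis set a *positive* prior on the
correctness effect yet reported a large evidence ratio together with a
*negative* measured contrast, so the hypothesized ER direction cannot be
read off the prior mean; `default_priors()` therefore carries an
explicit `direction` column (correctness: negative, matching the
error-related-negativity contrast), decoupled from the prior means.

Group descriptive comparisons use the Welch t statistic with the JZS
default Bayes factor (Cauchy scale sqrt(2)/2, numerical integration over
the mixing parameter; the test suite checks it against a Monte-Carlo
integration oracle to <1%).

## Behavioural metacognition

Type-1 sensitivity uses the standard d' with 1/(2N) extreme-rate
correction. meta-d' maximizes the type-2 likelihood of
confidence-conditional counts under an equal-variance SDT observer whose
type-1 criterion is carried over at the same relative position
(`meta_c = c * meta_d / d'`); confidence criteria are response-collapsed
(one symmetric offset set) -- the response-specific variant is noted as
an alternative but not implemented. Confidence is binned into 4
per-participant equal-quantile bins after excluding sub-50 ratings
(the change-of-mind rule), so bins span 50-100. Optimization is
Nelder-Mead over (meta-d', log criterion increments) from multiple
starts; the acceptance suite checks it against a brute-force grid-search
maximizer of the same likelihood to 0.01.

The hierarchical group model places `log M-ratio_i ~ N(mu_g, sigma_g^2)`
with `mu_g ~ N(0, 1)` and `sigma_g ~ halfN(0, 1)`; participant type-1
parameters are fixed at their corrected point estimates, and
(log M-ratio, criteria) are sampled by adaptive random-walk Metropolis
within Gibbs. Group summaries are posteriors of `exp(mu_g)`; the group
difference gets a Savage-Dickey BF on `mu_a - mu_b` (prior N(0,
sqrt(2)), induced by the independent group priors). `simulate_sdt_counts()`
draws counts directly from the meta-SDT conditionals, making generative
meta-d' exact -- the right ground truth for recovery tests (a
"corrupted-channel" generator, where confidence derives from a noisier
copy of the decision evidence, has no closed-form meta-d' and is not
used for truth).

The confidence ~ movement-onset model regresses confidence (0-1) on
`z_onset x correctness x group` with a participant random intercept via
the same Gibbs machinery, standard-normal slope priors, and reports
directional evidence ratios (onset main effect hypothesized negative,
onset x group positive).

## The synthetic world: what it emulates, and what it does not

`simulate_behavior()` runs an independent staircase per participant
(performance matching by construction; multiplicative 1.1 steps, SDT
observer with evidence `x ~ N(side * sens * coherence, 1)`, lapse 2%).
Movement onsets are lognormal (mean 1.3 s, sd 0.65 s) with mild error
slowing; 5% of trials are stamped early (<100 ms), 3% late (>6 s), 7%
pre-response changes of mind -- the excluded-trial classes at roughly
their reported rates. Confidence is the ideal-observer posterior
`plogis(2 d |x|)` compressed into [0.5, 0.92], plus coupling to the
standardized onset and Gaussian noise (sd 0.10), times 100.

Two calibrations deserve emphasis because they are easy to get silently
wrong:

* **Coupling semantics.** The sub-50 exclusion truncates the analysis
  sample from below and the rating ceiling compresses it from above;
  together they attenuate a latent confidence~onset slope by ~0.47 in
  the fitted retained-trial regression. The observer's
  `confidence_rt_coupling` is therefore defined as the slope *recovered
  on retained trials* (the quantity the reference analysis reports), and
  the generator inflates the latent slope by the inverse factor (2.1),
  calibrated once from this truncation geometry. Confidence couples to
  the standardized onset *before* the early/late artifact classes are
  stamped in, since their extreme values never enter any analysis.
* **Reference-free voltages.** Scalp EEG has no absolute reference, so
  `simulate_epochs()` emits average-referenced potentials directly:
  component topographies are dipolar (a Gaussian lobe at the centre
  channel plus a broader posterior-inferior counter-lobe balanced over
  the full 64-channel layout), projected onto the montage's zero-mean
  space and scaled to exactly 1 at the centre channel. The
  common-average reference is then a no-op on the signal, and the
  nominal gain (e.g. -0.34 uV correct-incorrect at Cz) equals the
  analyzed contrast. An all-positive topography would lose ~35-40% of
  its effect to the common average on a small montage.

Epochs are `intercept_p + sum_components gain * modulator * topography *
kernel + noise`: Gaussian temporal kernels at 266 ms (correctness),
102 ms (confidence), 133 ms (movement onset) plus a constant
motor-evoked wave; 1/f noise from spectrally shaped white noise plus
white noise, independent per trial and channel; per-participant DC
offsets; optional transient artifacts (with uneven spatial profiles --
perfectly common-mode artifacts would vanish under the common average)
and noisy channels. The default noise level (pink 2 uV + white 1 uV
single-trial in-band) is at the optimistic end of clean, heavily
filtered adult EEG; it was chosen once so that the mass-univariate scan
operates in the power regime the reference analysis exhibits
(FDR-significant samples spanning hundreds of milliseconds at these
cohort sizes). Real recordings are typically noisier; a green recovery
test therefore establishes correctness of the machinery at a realistic
but favourable SNR, not that any given real dataset has the power to
show the same effects. Epochs are generated directly at 128 Hz; the
1200 -> 128 Hz resampling path is exercised by its own fixtures, not by
default. The default montages are whole-head 8/16-channel subsets (in
the spirit of a 10-20 cap) so the common average behaves as on a full
cap; 64 channels are supported but memory-hungry.

What the generator does **not** emulate: spatially correlated noise
across channels, non-stationary artifacts, volume-conduction mixing
beyond the separable topographies, staircase non-convergence, response
biases, or serial dependencies (confidence history) -- the latter is
explicitly out of scope.

## Reproducibility and orchestration

One master seed fans out to per-stage seeds through a labelled FNV-1a
hash (`derive_seed(master, "epochs")` etc.), so any stage reruns in
isolation; every output table carries the configuration fingerprint.
`run_pipeline()` wires the stages in the fixed order and returns the
behavioural summary table, M-ratio posteriors, scan/cluster/effect
tables per term, optional step-3 summaries, and the per-participant
retention log. The `inst/cli/confclust.R` script exposes the verbs
`simulate`, `kinematics`, `scan`, `cluster`, `bayes`, `metacog`,
`report`, `all`.

## Known limitations

* EDF ingestion and HDF5 persistence are not provided (no R reader in
  the supported dependency set); continuous data enter as in-memory
  matrices or wide CSV.
* The Gibbs sampler omits intercept-slope correlations and uses
  inverse-gamma variance priors; posterior sds for variance components
  (not reported) would be sensitive to that choice, fixed-effect
  summaries much less so.
* meta-d' point estimates are noisy below ~200 retained trials per
  participant; the hierarchical model pools but does not fully remove
  small-sample variability.
* p-values from the closed-form engine are Wald/normal; with very few
  participants (< ~8) and between-participant covariates they are
  mildly anti-conservative.
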