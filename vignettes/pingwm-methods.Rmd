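---
title: "Models and methods behind pingwm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pingwm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pingwm)
```

# The scientific question

"Pinging" experiments probe working memory by flashing a task-irrelevant,
high-contrast impulse during a memory delay and asking whether the evoked
EEG response becomes *decodable* for the memorized stimulus. A rise in
decodability after the ping has been read as a memory being *reactivated*
from an activity-silent, synaptic trace. pingwm packages the analysis and
simulation machinery needed to scrutinize that inference:

1. a phenomenological generator of synthetic EEG trials in which the only
   impulse-locked event is a *drop in noise variability*, not a signal;
2. the time-resolved Mahalanobis representational-dissimilarity decoder with
   vector-strength summary and shuffle-null calibration;
3. the statistical-power toolkit (windowed one-sided tests, trial/session
   subsampling grids, bootstrap intervals, randomization tests, and a
   cross-validated median split of sessions);
4. across-trial variance analyses (percent change from baseline, variance
   differences between high- and low-decoding trials, outlier screening);
5. a spiking ring network of leaky integrate-and-fire (LIF) neurons run in
   two regimes — activity-silent (short-term plasticity) versus bump
   attractor — whose across-trial variability signatures after a nonspecific
   drive discriminate the two accounts.

# Synthetic EEG trials

Each trial's evoked response is a Gamma-density-shaped transient

$$f(t \mid a, b) = e^{a-1}\,[b(a-1)]^{-(a-1)}\, t^{a-1} e^{-t/b},$$

normalized so that its peak equals 1 at the mode $t = (a-1)b$. Per trial,
$a \sim \mathcal N(\mu_a, \sigma_a)$ and $b \sim \mathcal N(\mu_b,
\sigma_b)$, with rejection-redraw of invalid values ($a \le 1$, $b \le 0$)
rather than clipping, which would distort the distribution shape. The
two-condition defaults are $\mu_a = 2, \mu_b = 130$ ms (scale 0.5) versus
$\mu_a = 3, \mu_b = 80$ ms (scale 0.25), both with $\sigma_a = 0.2$,
$\sigma_b = 0.5$ ms and onset 0.1 s. Waveforms are assigned to two dipole
sources, projected to scalp channels through a lead field, and i.i.d.
Gaussian noise is added per channel and sample with s.d. 0.75 — except
inside the impulse window (1.3–1.5 s), where the s.d. is reduced by 30% to
0.525. "Variability reduction" is an s.d. (not variance) reduction:
$0.75 \times 0.7 = 0.525$.

The lead field is synthetic and documented (`make_leadfield()`): two
occipital sources with smooth Gaussian gains across a posterior channel row
plus a small floor so no channel is blind, or a random-orthonormal mixing.
A realistic boundary-element head model would only change the fixed,
full-rank mixing, to which the Mahalanobis decoder is invariant (see below),
so nothing downstream depends on head-model fidelity.

`simulate_oriented_trials()` generalizes the two-condition scheme for the
circular decoder: orientations are $\pi$-periodic, so tuning uses the
doubled angle, and each trial's two source amplitudes are
$g\,(\cos 2\theta, \sin 2\theta)$ — a two-channel circular code riding on
the same waveform-plus-noise machinery. With `tuning_gain = 0` the data are
exchangeable noise, which is what all null calibrations use.

# Preprocessing

* `apply_baseline()` subtracts each trial's mean over a window; it is
  idempotent, and deliberately dangerous when the window sits in the delay
  (see the baselining artifact below).
* `debaseline_stitch()` reverts per-epoch baselining by adding back the
  trial-by-trial junction offset between consecutive epochs. With a
  one-sample overlap the reconstruction is exact; with mere abutment it
  assumes continuity over one sample step.
* `detrend_linear()` removes a least-squares line. Inside the variance
  pipeline the slope-only (mean-preserving) variant is used: removing the
  full line would center the variance time course near zero and make the
  percent-change normalization $\Delta\text{var} = (v-b)/b \times 100$
  ill-defined.
* `smooth_gaussian()` convolves with a unit-area Gaussian kernel
  (truncated at $6\sigma$, reflection padding; $\sigma = 0$ is the
  identity). Two conventional uses: 32 ms on voltages *before* decoding (the
  power-improvement variant) and 10 ms on decoding strengths *after*.
* `alpha_power()` band-passes to 8–12 Hz with a zero-phase
  (forward–backward) FIR filter, then squares the magnitude of the Hilbert
  analytic signal. The filter half-width is attached as `edge_samples`;
  estimates inside that margin are transient-contaminated and excluded from
  assertions.

# Decoding

At each time point and session, `mahalanobis_rdf()` runs stratified k-fold
cross-validation (default 8 folds). Per fold it estimates class means and a
pooled within-class covariance from training trials only, shrunk toward
$\bar\lambda I$ with a Ledoit–Wolf analytic intensity (or a fixed value;
`shrinkage = 0` is allowed and errors only on an actually singular
covariance). Each held-out trial's Mahalanobis distances to all class means
are re-indexed by the circular label difference on the doubled circle and
mean-centered per trial, giving the representational dissimilarity function
(RDF). The decoding strength is the vector strength
$-\frac1K \sum_k \cos(\Delta\theta_k)\, \mathrm{RDF}(\Delta\theta_k)$:
positive when dissimilarity grows with angular difference; a planted
$-\cos$ profile gives exactly $+0.5$. With only two conditions the circular
summary degenerates and the strength is the two-class reduction,
cross-minus-within distance.

Because Mahalanobis distance is invariant under invertible affine maps of
the feature space, the decoder (as shrinkage $\to$ 0) does not depend on
the channel mixing — the package's justification for substituting a
synthetic lead field, and an acceptance-tested property.

`shuffle_null()` reruns the identical pipeline with orientation labels
permuted within session; all chance levels and randomization tests use this
empirical null rather than a theoretical one.

# Inference

* `window_test()`: one-sample, one-sided t test of window-mean strength
  against zero, across sessions or pooled trials. One-sided is conservative
  when the claim is a *lack* of decoding.
* `subsample_grid()`: power as a function of session and trial counts by
  repeated subsampling without repetition (default 5,000 resamples per
  cell; cell p is the median over resamples; the full-data corner
  reproduces the pooled test exactly; infeasible cells are NA).
* `bootstrap_ci()`: resample sessions with replacement; SEM = s.d. of
  bootstrap means; percentile intervals.
* `randomization_test()`: one-sided permutation p with the add-one rule,
  $(1 + \#\{\text{null} \ge \text{obs}\})/(1 + n)$, exact under
  exchangeability and never zero.
* `median_split_cv()`: the selection-without-circularity construction. Per
  split-fold, each session's single-trial strengths are randomly halved
  (stratified by orientation when labels are given); half 1 ranks sessions
  by mean strength in the early-delay window (default 0.25–0.45 s) and
  median-splits them (odd counts: the high group gets the extra session);
  half 2 supplies held-out group means. The shuffle predictor is the
  high-group held-out mean of label-shuffled decodings under the same
  procedure, averaged over shuffles and split-folds; a time point is
  significant when at least 95% of split-folds beat the predictor. On
  exchangeable data the construction is unbiased (the high-group held-out
  mean beats the predictor in about half the folds), which the tests
  assert.

# Across-trial variance

Variance is computed across trials per sensor and time point, *per
session*; each sensor's variance time course is slope-detrended
(mean-preserving), sensors are averaged, and only then are sessions
combined — the ordering matters when session means differ, and a fixture
test asserts it. $\Delta\text{var}$ is the percent change from a
pre-impulse baseline; both conventional baselines (the 0.2 s immediately
before the impulse, or the full 2 s preceding it) are arguments, not
constants. With waveform scale 0 and the 30% s.d. reduction the expected
impulse-window value is $(0.49 - 1)\times 100 = -51\%$.

Two geometric choices worth noting. First, the acceptance fixture uses a
2.8 s epoch with the impulse window centered, so the linear detrend is
orthogonal to the variance dip; an off-center dip tilts the fitted line and
biases $\Delta\text{var}$ by several percentage points. Second,
`exclude_outlier_sessions()` screens sessions at the impulse time with a
median + 5 MAD robust threshold — a screening rule chosen once, not tuned.

# The baselining artifact

When trials are baselined on a *delay* window, the baseline subtracts a
condition-dependent offset (the delay tail of the evoked waveforms differs
between conditions) plus per-trial noise. That injected separation is
constant in time — but the decoder sees it through the noise covariance, so
when across-trial variability drops during the impulse, the whitened
separation grows and decodability rises: a spurious reactivation, with no
stimulus signal anywhere near the impulse. `run_s3_demo()` quantifies the
reactivation as the impulse-window decoding increase over the immediately
preceding period, compares late (0.4–0.6 s, mid-delay) versus early
(pre-onset) baselines paired over seeds, and shows the difference vanishes
when `reduction_fraction = 0`. The *increase* is the right readout: the
injected separation itself is present under a late baseline regardless of
the variance drop, so raw impulse-window decoding would not vanish in the
control.

# The spiking ring network

`simulate_trial()` integrates (Euler, 0.1 ms steps) a ring of `n_exc`
excitatory and `n_inh` inhibitory LIF neurons (defaults 2,048/512; tests
and acceptance use 512/128, where all qualitative contrasts hold).
Excitatory-to-excitatory connections are all-to-all and spatially tuned — a
Gaussian kernel over angular distance normalized to ring-mean 1, so the
total recurrent strength is width-independent — while E→I, I→E and I→I are
untuned and all-to-all (implemented as scalar population traces).
Exponential current synapses, white-noise current per neuron, absolute
refractory period 2 ms, threshold 20 mV above rest.

Short-term plasticity follows the standard two-variable presynaptic scheme:
on each spike, facilitation first ($u \leftarrow u + U(1-u)$), release of
efficacy $u\,x$, then depression ($x \leftarrow x - ux$); between spikes
$u \to U$ with $\tau_f$ and $x \to 1$ with $\tau_d$. From rest with
$U = 0.2$ a single spike leaves $u = 0.36$. The simulator records the
mean $u x$ over cue-adjacent synapses and over the whole ring every 10 ms,
which is how the *silent trace* is observed while no neuron fires.

Since the source parameter table is not reproducible from the text, the two
presets were designed (and are documented in `ring_spec()`) to realize the
regimes the analyses require:

* **bump**: no plasticity; slow (NMDA-like, 80 ms) recurrent excitation
  stabilizes a persistent bump at moderate peak rates, parked close enough
  to the bifurcation that a nonspecific drive measurably deepens the
  attractor. Signatures: the cued angle is maintained for seconds with
  slowly growing diffusion; a sustained nonspecific drive *reduces* the
  Fano factor (variability quenching) and *increases* population-vector
  tuning in the final 0.5 s (the attractor boost).
* **silent**: strong but depressing/facilitating recurrence
  ($U = 0.2, \tau_f = 3$ s, $\tau_d = 0.25$ s, faster 30 ms synapses,
  narrower kernel) under strong untuned inhibition. The cue ignites a bump
  that collapses by depression; the delay is essentially silent
  (< 0.1 Hz) while $u x$ at cue-adjacent synapses stays elevated above the
  ring average — the activity-silent memory. A *weak, near-threshold*
  nonspecific drive reignites the bump at the cued location in some trials
  and not others; this all-or-none reactivation raises the across-trial
  Fano factor after the drive.

Drive strengths are therefore regime-specific (defaults: 1.5 silent, 8
bump, 5 for the boost comparison) with matched drive windows (2.5–3.0 s);
a single value cannot sit at the ignition threshold of one regime and be an
effective ping in the other.

The Fano factor is computed per neuron as var/mean of spike counts across
trials in sliding 100-ms windows (stepped by half a window), averaged over
neurons with nonzero mean; $\Delta FF$ subtracts the mean FF of the delay
baseline. Because FF is an across-trial statistic, its one-sided tests use
a bootstrap over trials (add-one p).

# Problem sizes, tolerances and degenerate inputs

The test-suite and acceptance problem sizes are the package's chosen study
conditions: 2,000 trials for the noise-s.d. check (±2%), 1,000 trials for
$\Delta\text{var}$ (±3 points around −51%), 1,000 independent null runs for
each test calibration (5% ± 2%), 100 seeds for the baselining artifact
(paired p < 0.01), 12 sessions × 64 trials with 2,000 split-folds and a
200-shuffle × 200-split-fold predictor for the median split, 100 trials per
spiking regime at 512E/128I, and 50 trials per condition for the tuning
boost. Sampling rates of 100–200 Hz are used for synthetic data (the
generator's default is 500 Hz); all such sizes are arguments.

Numerical choices: covariance factorization by Cholesky with an explicit
error advising shrinkage when singular; profiles and bins matched on values
rounded to 1e-6 degrees; smoothing kernels truncated at $6\sigma$ so a
delta input reproduces the sampled Gaussian to < 1e-6 L2 error; window
selection is inclusive with 1 ns slack; the all-zero t test returns the
null-neutral t = 0, p = 0.5; `delta_var` errors on non-positive baselines;
degenerate decoding splits (all strengths equal) and single-trial sessions
error rather than silently degrade.

# What the synthetic data do and do not show

The generator reproduces the statistical skeleton the analyses rely on —
condition-dependent evoked transients with trial-varying parameters, a
stable full-rank channel mixing, stationary Gaussian noise with an
impulse-locked variability drop, and circularly tuned multi-session data
with heterogeneous gains. It does not emulate real EEG artifacts (blinks,
line noise, electrode pops), 1/f spectra, spatially correlated noise, or
realistic head-volume conduction. Passing tests therefore certify the
*pipeline* — calibration of the tests, unbiasedness of the session
selection, the direction and mechanism of the baselining artifact, and the
model contrasts — not the reanalysis of any particular recording set, which
would require the original public datasets and is out of scope.
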