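---
title: "Time-varying information storage: model, estimator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-varying information storage: model, estimator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tvis)
```

## The measure

Information storage (IS) quantifies how much of a stochastic process's
present is predictable from its own past: the mutual information between
$Y_n$ and the history $Y_{n-1}, Y_{n-2}, \dots$. For a process that is
(conditionally) Gaussian and well described by an autoregressive model of
order $p$,

$$ S_{Y,n} \;=\; H(Y_n) - H(Y_n \mid W_n) \;=\; \tfrac12 \log
\frac{\sigma^2_{Y,n}}{\sigma^2_{U,n}}, \qquad
W_n = (Y_{n-1}, \dots, Y_{n-p}), $$

where $\sigma^2_{Y,n}$ is the process variance and $\sigma^2_{U,n}$ the
innovation (one-step prediction error) variance at time $n$. The measure
is reported in nats (natural logarithm; a bits option exists but is off by
default). For a stationary AR(1) with coefficient $a$ the closed form is
$S = -\tfrac12\log(1-a^2)$: 0.83 nats at $a = 0.9$, 0.05 nats at
$a = 0.3$, 0 for white noise, and divergent as $|a| \to 1$.

The point of this package is the *time-resolved* version: none of the
quantities above is assumed constant. The pipeline has three stages.

**1. Recursive identification.** The TV-AR model
$Y_n = \sum_k a_{k,n} Y_{n-k} + U_n$ is identified by recursive least
squares (RLS) minimising the exponentially weighted cost
$\sum_i (1-c)^{n-i} Z_i^2$, where $Z_i$ is the a-priori prediction error
and $c \in [0,1)$ the adaptation factor. The *forgetting factor* $1-c$
sets the memory of the estimator: an effective window of roughly
$1/c$ samples. The innovation variance is tracked by the convex recursion
$\sigma^2_{U,n} = \sigma^2_{U,n-1} + c\,(Z_n^2 - \sigma^2_{U,n-1})$, which
keeps it non-negative. `forgetting = 1` is the ordinary least-squares
limit and is the oracle used in tests, not an adaptive estimator.

**2. Instantaneous process variance.** At each $n$ the current
coefficients are frozen and embedded in the companion-form system; the
lag-0 autocovariance matrix solves the discrete Lyapunov equation
$\Gamma_0 = A\,\Gamma_0 A^\top + \Lambda$, whose (1,1) entry is
$\sigma^2_{Y,n}$ and whose first row holds the autocovariances at lags
$0..p-1$ (the time-varying Yule-Walker equations hold on this solution;
a test asserts the residuals vanish). For $p \le 20$ the $p^2 \times p^2$
vectorised linear solve is used directly, with symmetry enforced
post-solve; for $p = 1$ this reduces to $\sigma^2_U/(1-a^2)$, which the
implementation exploits as a fast path (a test pins the two routes
together to machine precision).

**3. The storage trajectory.** Applying the log-ratio per instant yields
$S_{Y,n}$. Because the frozen-coefficient model is only meaningful when
stable, each instant is screened by the companion spectral radius with
threshold $1 - 10^{-8}$; unstable instants produce missing values rather
than clamped coefficients — clamping would fabricate storage — and their
count is reported. Non-positive variances are floored at $10^{-12}$
relative to the median innovation variance (warn), or raise in strict
mode.

Note that for $p = 1$ the innovation variance cancels in the ratio:
$S_n = -\tfrac12\log(1-\hat a_{1,n}^2)$ exactly. The storage trajectory of
a first-order model is therefore purely a function of the estimated
coefficient, a fact worth keeping in mind when interpreting transition
speeds below.

## Estimator initialisation

The textbook initialisation sets the weighted correlation matrix
$\Phi_p = 0$, which leaves the gain $K_n = \Phi_n^{-1} W_n$ undefined
until $\Phi$ accumulates full rank (it is a sum of fewer than $p$ rank-one
terms before $n = 2p$). The default here regularises with
$\Phi_p = \delta I$, $\delta = 10^{-6}\,\mathrm{var}(y)$; scaling
$\delta$ with the signal variance makes the estimates invariant to
amplitude scaling (tested to $10^{-10}$), and estimates for $n \gg p$ are
insensitive to $\delta$. A literal zero start is available
(`init = "literal"`). The default update maintains $P = \Phi^{-1}$ by the
matrix-inversion lemma at $O(p^2)$ per step with explicit symmetrisation;
a direct $O(p^3)$ inversion mode is kept for validation, and the two are
required by tests to agree to $10^{-8}$. The innovation-variance start is
$\sigma^2_{U,p} = 0$; a warm start (variance of the first $p+10$ a-priori
errors) is available because the zero start biases the earliest storage
values downward. Estimates before index $p+1$ are flagged missing, never
zero-filled. The model has no intercept, so inputs must be de-meaned (the
command-line interface does this by default and logs the removed mean).

## The simulation benchmark

`sim_preset("square")` encodes the benchmark scenario: 500 Hz sampling,
10 s (5000 samples), an AR(1) coefficient alternating between 0.3 ("OFF",
theoretical IS 0.05 nats) and 0.9 ("ON", 0.83 nats) as a 0.3 Hz square
wave with 50% duty cycle, unit innovation variance. A sinusoidal preset
with the same bounds is included; its "theoretical" trajectory is the
quasi-stationary value obtained by freezing the instantaneous coefficient,
which is an approximation — the modulation is slow (0.3 Hz) relative to
the process dynamics, so the approximation is good, but it is not exact.
The square waveform starts on its high plateau and the sine at mid-level
ascending; both can be rephased. The first $p$ simulated samples are pure
innovations with no pre-history, so callers wanting fully burned-in
records should discard the first modulation cycle.

Performance is summarised per forgetting factor by:

* **BIAS** per plateau (mean estimate minus theoretical level, after
  excluding a guard fraction — default the first 25% of each plateau —
  so post-transition transients do not contaminate steady-state
  statistics; the guard exceeds the longest transition observed at
  forgetting 0.996);
* **VAR**, the mean squared deviation from the plateau mean (population
  formula); summary bias averages absolute per-plateau biases, summary
  variance is the simple mean;
* **rise/fall time**, the 10–90% threshold-crossing time after each
  transition, averaged over transitions and seeded realizations; their
  mean is the rise-fall time (RFT).

Two threshold conventions are implemented. `"range"` (default) places the
thresholds 10% and 90% of the way from the low to the high theoretical
level — the standard engineering 10–90% convention. `"literal"` places
them at $0.1\,S_{\mathrm{low}}$ and $0.9\,S_{\mathrm{high}}$; since
$0.1\,S_{\mathrm{low}} \approx 0.005$ nats lies *below* the low plateau
itself ($\approx 0.05$ nats), a noisy estimate essentially never crosses
it on the way down and downward transitions are then excluded — we
measured 0 of 60 falls completing at forgetting 0.996. The literal
convention is therefore not usable as a default and `"range"` is. Crossing
times use the first sample at/beyond each threshold after the transition,
searched within the half-cycle, with an inclusive sample count so that an
ideal instantaneous step measures exactly one sample period; transitions
whose thresholds are never crossed are excluded with a warning and count.

With 20 realizations per point the benchmark reproduces the expected
trade-off: variance decreases monotonically with the forgetting factor
while bias and RFT increase (the curves cross near 0.97–0.98), plateau
means at forgetting 0.97 sit within ±0.1 nats of 0.83/0.05 with a slight
underestimation of the high plateau, and the RFT at forgetting 0.98 is
about 0.19 s. One caveat this package's benchmark makes explicit: the
upward and downward transition speeds are asymmetric. At an upward
coefficient step the lag-vector power rises about five-fold, inflating
the RLS gain, so rises complete faster than falls (at forgetting 0.996,
roughly 0.75 s versus 1.15 s; RFT about 1.0 s). Transition-time figures
reported elsewhere for comparable settings are longer at high forgetting;
with the threshold wording unimplementable as written, the exact
convention behind them could not be reconstructed, and the numbers
computed here are the faithful output of the stated procedure.

The single root seed expands deterministically: realization $r$ of a
benchmark uses `seed + r - 1`; fixture channel $ch$ uses `seed + ch`.
Re-running any command or function with the same configuration reproduces
identical output.

## The heartbeat-locked pipeline

Each cardiac cycle (R-peak to next R-peak) is split into three half-open
intervals: **I1** from the R-peak to 80 ms after the T-wave peak, **I2**
from there to 40 ms before the next P-wave peak, and **I3** the remainder
up to the next R-peak, plus the global interval **G**. The split reflects
the cardiac field artifact, which contaminates the EEG most strongly
around the QRS complex and T wave (I1, I3) and least in I2. Boundaries
are computed in continuous time and converted to samples once, by
round-half-away-from-zero of $t \cdot f_s$, with half-open ranges so
adjacent intervals never double-count a sample; the three intervals
exactly partition the cycle (asserted in tests). Beats with degenerate
geometry (e.g., T + 80 ms reaching past P − 40 ms) are skipped, not
truncated, with a recorded reason.

Per beat and interval, the trajectory's mean and standard deviation are
computed over in-interval samples (missing samples excluded; population
SD), then averaged without weighting across the first `max_beats` beats
(default 300, the short-term heart-rate-variability convention). Weighting
beats equally — rather than samples equally — matches the convention of
averaging one value per cardiac cycle. Across subjects, each channel,
interval pair and metric (MEAN, STD) is compared by a paired Student's
t-test with Bonferroni correction (`n_comparisons` defaults to 62, one
per electrode of a full-scalp montage; configurable because fixtures have
fewer channels), and the effect size is Cohen's $d$ with pooled-variance
denominator. Normality is assumed, matching standard practice for these
group comparisons. Identical paired distributions yield $t = 0$,
corrected $p = 1$, $d = 0$; a constant non-zero paired difference has
undefined $p$ and is flagged.

## What the synthetic fixtures emulate — and what they do not

`cardiac_fixture()` produces multichannel TV-AR(1) signals whose lag-1
coefficient is stepped by channel-specific depths inside each of the
three within-beat windows, on a regular (optionally jittered) beat grid,
with ground-truth fiducials and interval labels returned. Defaults —
128 Hz sampling, 0.8 s beat period (75 bpm), T at 30% of the R-R interval
after R, P at 16% before the next R, baseline coefficient 0.5, unit
innovation variance — were chosen once as physiologically plausible
resting values. The fixture is a *statistical* stand-in: it has no
QRS/EEG waveshape morphology, no 1/f spectrum, no cardiac field artifact
and no volume conduction; the bundled impulse-train "ecg" trace exists
only so the convenience detector can be exercised and is labelled
synthetic. Passing the fixture tests therefore demonstrates that the
estimator and statistics recover interval-locked regularity changes of
known size under the model's own assumptions — not that they are robust
to real EEG artifacts, which the pipeline deliberately leaves to upstream
preprocessing (fiducial annotations are accepted as input; the built-in
detector is a convenience for synthetic traces, not a clinical QRS
detector).

Two lessons from the fixtures are worth recording. First, recovery of an
interval-locked coefficient step requires the estimator to adapt within
the interval: the adaptation time constant is roughly $1/(c f_s)$
seconds, and with 128 Hz data and intervals of 0.13–0.35 s a forgetting
factor of 0.9 (time constant ≈ 0.08 s) resolves all three intervals,
whereas 0.95–0.97 smears the modulated interval into the following one.
The fixture-recovery analyses therefore use forgetting 0.9, and the
general rule — choose $1/(c f_s)$ below the shortest structure of
interest — is the practical guidance this package offers. Second, the
within-beat *STD* of the adaptive trajectory carries systematic
window-length structure even with no modulation at all: longer windows
capture more of the estimator's slow wander, so STD(G) > STD(I1) >
STD(I3) on a completely null fixture. Group comparisons of STD across
intervals of unequal length are therefore confounded by construction,
and the package's false-positive guarantees are stated for the MEAN
metric, whose null genuinely holds on null fixtures (verified by Monte
Carlo: ≤ 5% family-wise flags under Bonferroni).

## Numerical choices and limitations

* Stability screening threshold $1 - 10^{-8}$ on the spectral radius;
  unstable instants are missing values, counted and logged.
* Variance floor $10^{-12}$ relative to the median innovation variance
  before the log; warn-and-floor by default, error in strict mode.
* Millisecond offsets (80/40 ms) are converted to samples once, by
  round-half-away-from-zero, in continuous time.
* The Lyapunov solve is exact (direct linear solve), not iterative; the
  fixed-point iteration appears only as an independent oracle in tests.
* Problem sizes in the test suite are desk-scale by design: 20
  realizations per benchmark point, 6–8 synthetic subjects, 4–6 channels,
  30 beats, 12 Monte-Carlo families for the false-positive check; the
  statistical conclusions they support are stated with matching modesty.
* Known limitations: no multivariate (VAR) extension, no Kalman-filter
  identification, no local (pointwise outcome-specific) storage, no
  frequency-domain measures, no EEG preprocessing, and single-channel
  identification only — channels are processed independently.

## A worked run

```{r benchmark, eval = FALSE}
cfg <- sim_preset("square", seed = 1)
sweep <- forgetting_sweep(cfg, c(0.95, 0.97, 0.99), n_realizations = 20,
                          seed = 1)
sweep[, c("forgetting", "bias", "var", "rft")]
```

The sweep table shows the bias/variance/RFT trade-off directly; the
README walks through the same run with its printed output.
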