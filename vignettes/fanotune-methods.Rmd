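---
title: "Methods: state-dependent variability tuning, gain models, and population decoding"
author: "fanotune"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: state-dependent variability tuning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`fanotune` analyses trial-resolved spike counts of direction-tuned visual
neurons recorded (or simulated) in different behavioural states, with five
stages: (1) per-direction response statistics and tuning indices, including
mean-matched comparisons; (2) a doubly-stochastic gain model of count
variance and four ways of fitting it; (3) spike-count autocorrelation and
its decay time constant; (4) mutual information between count and
direction with finite-sample bias correction; (5) linear
Fisher-information decoding of model populations with information-limiting
correlations. A seeded synthetic-data generator supplies data with exactly
the statistical structure the analyses assume, so every stage can be
validated end to end.

# The count model and its assumptions

A neuron's expected count per window follows a direction tuning curve
$f(\theta)$, either von Mises,
$f(\theta) = b + A\,\frac{e^{\kappa(\cos(\theta-\theta_p)+1)}-1}{e^{2\kappa}-1}$,
or Gaussian with width $\sigma$ in degrees. On each trial the rate is
scaled by a multiplicative gain $g$ drawn from the unique mean-1 Gamma
distribution with variance $\mathrm{var}(g)$ (shape $1/\mathrm{var}(g)$,
scale $\mathrm{var}(g)$); the count is then drawn from a normal law with
mean $\mu = f(\theta)g$ and variance $\mu^\alpha$. Integrating over the
gain,

$$\mathrm{var}(x\mid\theta) = f(\theta)^\alpha \langle g^\alpha\rangle
  + f(\theta)^2 \mathrm{var}(g), \qquad
  \langle g^\alpha\rangle = \mathrm{var}(g)^\alpha
  \frac{\Gamma(1/\mathrm{var}(g)+\alpha)}{\Gamma(1/\mathrm{var}(g))}.$$

Because the mean-1 Gamma has $\langle g^\alpha\rangle \approx 1$ for small
gain variance (0.993 at $\alpha = 0.74$, $\mathrm{var}(g) = 0.0732$), the
package uses the approximation
$\mathrm{var} \approx f^\alpha + f^2\mathrm{var}(g)$ for fitting and
exposes the exact Gamma-moment form (`predictVariance(..., exact = TRUE)`,
cross-checked against numerical integration in the tests). The Fano factor
is $FF(\theta) \approx f^{\alpha-1} + f\,\mathrm{var}(g)$: decreasing in
$f$ (U-shaped tuning, FFTI > 0) when the first term dominates and
$\alpha < 1$; increasing in $f$ (flat or inverted tuning, FFTI $\le$ 0)
when gain fluctuations dominate. The model assumes the gain is independent
across trials and neurons, stationary within the analysis epoch, and
stimulus-independent; none of these need hold exactly in cortex (gain
fluctuations are partly shared across neurons, and slow drifts violate
independence across trials), which is why the decoding stage imposes
correlations explicitly rather than deriving them from the count model.

# Key tunable parameters

* `alpha` (dimensionless, in [0, 2], default 1): exponent linking count
  variance to rate; 1 is Poisson-like.
* `var_g` (dimensionless, $\ge 0$, default 0): trial-gain variance; the
  state parameter. The bundled presets use the two state best-fit pairs
  (0.31, 0.0094) and (0.74, 0.0732).
* `window_ms` (default 250): counting window over which tuning values are
  expressed as expected counts.
* `bin_ms` (default 2) and `smooth_bins` (default 5): temporal resolution
  and running-average width of the autocorrelation analysis.
* `tau_gain_ms`: exponential correlation time of the within-trial gain in
  the temporal generator (presets 29 and 88 ms).
* `n_bins = 15` and `n_resamples` ($10^4$ by default, configurable) for
  mean matching. The resample count trades Monte-Carlo error of the
  matched-FFTI summary against runtime; $10^4$ puts that error well below
  the across-neuron spread at desk scale.
* Decoding: `c_max` (default 0.1) and `kappa` (1) of the correlation
  kernel; `epsilon` in squared degrees (default 4, i.e. a 2°
  information-limiting floor, the behavioural discrimination benchmark);
  FF-tuning `amplitude` (default 0.3, matching the scale of the observed
  alert-state FF modulation, peak-to-trough).

# The synthetic generator

`generateTrialCounts` draws counts exactly from the model above;
`generateTemporalTrains` produces binned trains whose per-bin rate is
$f(\theta)\,g_t\,(bin/window)$ with $g_t$ a stationary AR(1) process
(discretised Ornstein–Uhlenbeck) of mean 1, variance `var_g` and lag-$k$
correlation $e^{-k\,bin/\tau}$, initialised from its stationary law and
clipped at zero before use as a Poisson rate; response latency is a hard
rate onset. The AR(1) choice is the simplest process with the required
exponential autocorrelation; the trial-level and within-trial gains share
one variance parameter by default, a modelling convenience rather than an
empirical claim. `generatePopulationSample` draws multivariate-normal
population responses from the assembled covariance and returns the
generating covariance for oracle comparisons.

What the generator does **not** emulate: spike-history structure
(refractoriness, bursting), stimulus-locked transients beyond the onset
step, shared (correlated) gain across neurons in the single-neuron
analyses, non-Gamma gain laws, and count discreteness in the default
continuous mode (a `rounded` mode exists but biases Fano factors at low
rates). Passing tests therefore validate the estimators under the model's
assumptions; they do not certify behaviour under real-data violations of
those assumptions.

# Statistics and estimators

**Direction statistics.** Unbiased ($n-1$) variances throughout. The
orthogonal-direction statistic averages the two sampled directions nearest
±90° from preferred when both exist ("average" mode, default); a "pool"
mode concatenates their trials instead. Preferred direction comes from a
parametric tuning fit by default (less noisy than the raw argmax; argmax
and pre-aligned modes available). Neurons with no spikes at the orthogonal
directions have undefined FF_orth and are excluded from FFTI with a
recorded reason.

**Mean matching.** Neuron-level mean counts at each direction are binned
into 15 evenly spaced bins spanning the pooled range; the over-populated
state loses randomly chosen neurons per bin until counts match; the
population FFTI is recomputed from matched mean FFs, and the procedure is
repeated to average over random subsets. Degenerate inputs (no overlapping
bins at some direction) raise an error naming the direction. A 4-neuron
toy case is checked against exhaustive enumeration of all discard choices.

**Autocorrelation.** Residuals are taken about the per-time-bin
across-trial mean (removing stimulus-locked structure), smoothed with a
centred 5-bin running average, autocorrelated per trial via a zero-padded
FFT, averaged over trials then neurons (unweighted), and normalised so lag
0 is exactly 1. The exponential fit $a\,e^{-lag/\tau}$ excludes the
smoothing-dominated lags (start = `smooth_bins * bin_ms`) and ends at
300 ms; because a fixed 300 ms window leaves a fast decay mostly fitting
pure noise, the fit by default refines its window end once to five fitted
time constants. The optimiser bounds $\tau \in [1, 10^4]$ ms and flags
bound-hitting or zero-amplitude fits ill-defined. `fitDecayBagged`
additionally stabilises low signal-to-noise fits by bootstrap aggregation
over neurons (median of re-fits on resampled populations). Even so, the
time-constant estimate is intrinsically imprecise when the gain-induced
autocorrelation amplitude is a fraction of a percent of the total
variance, as it is for a weakly fluctuating gain at moderate rates over a
single stimulus condition: there the per-run estimate scatters by tens of
percent, and recovery experiments should pool residuals across all
stimulus conditions (as the multi-direction recovery test in the suite
does) whenever multi-condition data exist.

**Mutual information.** Plugin estimate of $I(k;\theta)$ in bits, uniform
prior over presented directions, raw integer counts as categories
(continuous counts rounded). Bias correction by quadratic extrapolation:
plugin MI on random subsamples at fractions 0.50–0.95 (50 subsamples per
fraction by default) plus the full-data point, regressed on the inverse
effective sample size $1/(fN)$ with a quadratic polynomial; the intercept
is the corrected estimate. The extrapolation variable is $1/N$ rather than
the fraction itself (equivalent up to scale; $1/N$ is the variable in
which the leading bias is linear). A residual-based diagnostic warns on
badly scattered subsample means.

**Gain-model fitting.** Four variants: (1) population grid search over
$(\alpha, \mathrm{var}(g))$ minimising the two-sample Kolmogorov–Smirnov
distance between simulated and observed FFTI distributions, with the same
seed at every grid point so the objective surface is smooth, and a
boundary warning when the optimum lies on a grid edge; (2, 3) two-state
fits with a shared $\alpha$ or shared $\mathrm{var}(g)$, minimising the
sum of squared per-state KS statistics; (4) per-neuron least squares on
$FF(\theta)$, where for fixed $\alpha$ the optimal $\mathrm{var}(g)$ is a
truncated linear-least-squares solution, so the search is a dense 1-D grid
over $\alpha$ (step 0.01 on [0, 1.5]) with local refinement — this avoids
multi-start failures of a 2-D nonlinear search entirely.

# Decoding model

Populations hold von Mises tuning curves with preferred directions evenly
tiling the circle (heterogeneous populations resample curves from a pool
with replacement and re-tile; uniform-random preferred directions are a
mode). Imposed FF tunings are von Mises-shaped modulations normalised to
peak-to-trough `amplitude`, centred so the grid-average FF is exactly 1;
positive and negative specs are exact mirror images about FF = 1.
Covariances: $\Sigma_0[i,i] = FF_i(\theta) f_i(\theta)$, off-diagonals
$c(d_{ij})\sqrt{v_i v_j}$ from the correlation kernel (applied to the
total variances including FF tuning), then
$\Sigma_\epsilon = \Sigma_0 + \epsilon f' f'^T$ with $f'$ analytic, in
counts per degree, so $J$ is in deg$^{-2}$ and the Cramér–Rao bound
$\sqrt{1/J_0 + \epsilon}$ is in degrees. The information-limited $J$ is
computed both by direct inversion and through
$J_\epsilon = J_0/(1+\epsilon J_0)$; the two must agree to $10^{-6}$
relative (exact for a rank-one update) or an error is raised. Covariance
derivatives are ignored in $J$, as is standard for this bound. Bounds are
averaged over a grid of evaluation directions (single-direction mode
available); threshold searches walk a doubling grid of population sizes
with bisection refinement, verify monotone non-increase, and report
thresholds below $\sqrt\epsilon$ as unreachable. The time-to-threshold
experiment uses a latency-plus-ramp surrogate for cumulative-count tuning
(expected count to time $T$ is rate $\times \max(0, T - \mathrm{latency})/1000$).

# Numerical choices

* Positive-semidefinite repair: symmetric eigenvalue clipping at
  $10^{-10}$ of the largest eigenvalue, with an error if the repair moves
  the matrix by more than $10^{-6}$ relative Frobenius norm; a Cholesky
  fast path skips the eigendecomposition for the (usual) already-definite
  case. Near-singular solves fall back to a logged $10^{-10}$ ridge.
* Tuning-curve fits: Levenberg–Marquardt with multi-start over width
  ({0.5, 1, 2, 4} for von Mises $\kappa$; {20, 40, 80}° for Gaussian
  $\sigma$), box constraints $b, A \ge 0$, and the preferred-direction
  start offset 1° from the argmax because the gradient with respect to the
  preferred direction vanishes at exactly symmetric starts. Flat inputs
  return amplitude 0 with an unconstrained (flagged) preferred direction.
* Latency: first time the PSTH exceeds baseline mean + 3 baseline SD for 5
  consecutive bins; both constants exposed. A never-met criterion returns
  NA with a `no_latency` attribute.
* Seeds: every stochastic entry point takes an explicit seed; sub-streams
  are derived with a fixed integer hash (kept below $2^{31}$), and the
  ambient RNG state is always restored.

# Problem sizes

The test suite validates moment convergence at $10^4$–$10^5$ draws,
parameter recovery at 20 neurons × 2000 trials/direction, time-constant
recovery at 25 neurons × 13 directions × 100 trials (20 seeds per state),
and decoding orderings at N = 200 with threshold searches up to N = 2048.
The acceptance script uses 50 neurons × 100 trials for the
autocorrelation recoveries and 20 neurons × 2000 trials/direction for the
gain-model recoveries. These sizes keep a full run in minutes on one core
while leaving the stochastic checks' sampling error well inside their
tolerances — except for the single-condition fast-time-constant recovery,
whose intrinsic imprecision is discussed above.

# Known limitations

* The count law is continuous (normal, clipped at zero); at very low rates
  clipping biases means slightly upward and variances downward, and the
  rounded mode trades that for discretisation bias.
* Mean matching operates on neuron-level mean counts, not trial-level
  count histograms, and therefore compares population-level (not
  cell-specific) tuning.
* The KS-based population fits inherit Monte-Carlo error from the model
  FFTI simulation; grid resolution limits precision, and per-neuron least
  squares fits poorly, by design of the variance law, for neurons with
  both large Fano factors and positive FFTI.
* Information-limiting $\epsilon$ is imposed, not estimated from data.
* The gain process is independent across neurons; analyses of shared
  variability would need a common-gain extension.
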