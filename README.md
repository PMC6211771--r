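# fanotune

Behavioural state changes the *variability* of cortical responses, not just
their rates. In motion-sensitive area MT, spike-count Fano factors (variance
divided by mean, FF) are tuned to motion direction in alert animals —
U-shaped, dipping at each neuron's preferred direction — while under light
opioid anesthesia FF tuning is flat and counts are supra-Poisson.
`fanotune` implements the analysis chain for studying this phenomenon and
its consequences for population decoding, together with a seeded
synthetic-data generator so the whole pipeline is testable without
recordings. It is aimed at systems neuroscientists analysing trial-resolved
spike counts across behavioural states.

## The model at the core

Each neuron's count in a window is doubly stochastic. With direction tuning
f(θ) and a trial gain g ~ Gamma(mean 1, variance var(g)), the trial rate is
μ = f(θ)·g and the count is drawn with mean μ and variance μ^α, giving

    var(x | θ) = f(θ)^α ⟨g^α⟩ + f(θ)² var(g)  ≈  f(θ)^α + f(θ)² var(g)

so the Fano factor is FF(θ) ≈ f(θ)^(α−1) + f(θ)·var(g). For α < 1 and small
var(g) the first term dominates and FF *dips* at the preferred direction
(FF tuning index FFTI = (FF_orth − FF_pref)/(FF_orth + FF_pref) > 0); as
var(g) grows the second term dominates and the tuning flattens or inverts.
A change in the gain variance alone therefore reverses FF tuning — the
mechanism the package's fitting procedures (population Kolmogorov–Smirnov
fits, shared-parameter variants, per-neuron least squares) quantify.

Downstream, model populations with imposed FF tunings (mean FF = 1),
distance-dependent pairwise correlations
c(d) = c_max·(e^{κ(cos d + 1)} − 1)/(e^{2κ} − 1), and information-limiting
correlations Σ_ε = Σ₀ + ε f′f′ᵀ are scored by linear Fisher information
J = f′ᵀΣ⁻¹f′ and the Cramér–Rao bound √(1/J₀ + ε) on direction
discrimination.

Also included: mean-matched FF comparisons between states, spike-count
autocorrelation with exponential time-constant fits, and spike-count/direction
mutual information with quadratic-extrapolation bias correction.

## Worked example

```r
library(fanotune)

## Simulate an anesthetized-like state: alpha = 0.74, var(g) = 0.0732,
## Gaussian tuning, 13 directions, 200 trials per direction
cfg <- SyntheticConfig(
    n_neurons = 4, n_trials = 200,
    direction_grid = seq(-90, 90, by = 15),
    gain_params = GainModelParams(alpha = 0.74, var_g = 0.0732),
    tuning = replicate(4, TuningCurveFit(4, 10, 40, shape = "gaussian")),
    seed = 42)
cm <- generateTrialCounts(cfg)

ti <- tuningIndices(cm, pref_method = "zero")
round(ti$FFTI, 3)
#> [1] -0.236 -0.136 -0.200 -0.273

st <- directionStats(cm)
fit <- fitNeuronLSQ(st$ff[st$neuron_id == "n1"], st$mean[st$neuron_id == "n1"])
round(c(fit$alpha, fit$var_g), 3)
#> [1] 0.568 0.093
```

The negative FFTI values show the gain-dominated regime (FF rises with
rate, so variability tuning follows rate tuning), and the per-neuron least
squares recovers the generating (α, var(g)) from 200 trials to within
sampling error.

```r
## Decoding: a 200-neuron population with U-shaped FF tuning needs a lower
## Cramer-Rao bound than its flat / inverted counterparts
pop <- function(sgn) homogeneousPopulation(
    200, TuningCurveFit(3, 30, 2), ff_spec = FFTuningSpec(sgn, 0.3),
    kernel = CorrelationKernel(0.1, 1), epsilon = 4,
    direction_grid = seq(-180, 135, 45))
sapply(c("positive", "flat", "negative"),
       function(s) mean(crBound(linearFisher(pop(s)))))
#> positive     flat negative
#> 3.060938 3.147570 3.220746
```

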