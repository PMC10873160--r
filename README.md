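# densitypinn

Cells respond to an extracellular signal through chains of unobserved
intermediate reactions.  A practical reduced description of such a pathway
is a **stochastic delayed birth–death process**: signal-initiation events
fire as a Poisson process at rate λ<sub>b</sub>, each initiated signal
produces one response molecule only after a random **transduction time**
τ ~ g(t), and response molecules decay (or dilute) at a first-order rate
λ<sub>d</sub>.  The shape of g(t) is biologically informative — its mean and
variance measure pathway speed and precision, and multimodality indicates
that several pathways with different timescales regulate the same response —
but g(t) is not directly observable.  Only time traces of the final response
y(t) (e.g. single-cell fluorescent-reporter trajectories) are measured.

`densitypinn` estimates g(t), λ<sub>b</sub> and λ<sub>d</sub> from response
traces alone.  The population mean trace obeys the delayed mean-field
equation

&nbsp;&nbsp;&nbsp;&nbsp; dy/dt = λ<sub>b</sub> ∫<sub>0</sub><sup>t</sup> g(s) ds − λ<sub>d</sub> y(t),

and the estimator is a **physics-informed variational autoencoder**
(a "Density-PINN"): an encoder maps each trace to a latent Gaussian
(k = 4); a decoder maps latent draws to (i) weights ω on the probability
simplex and (ii) scales s of a mixture of **shifted Rayleigh kernels**

&nbsp;&nbsp;&nbsp;&nbsp; g̃(t) = Σ<sub>j</sub> ω<sub>j</sub> K(t; c<sub>j</sub>, s<sub>j</sub>),&nbsp;&nbsp; K(t; c, s) = ((t−c)/s²)·exp(−(t−c)²/(2s²)) for t ≥ c,

plus (iii) positive rates; a small network maps ω to reconstruction weights
ω′, giving the reconstructed response ỹ(t) = Σ<sub>j</sub> ω′<sub>j</sub>
∫<sub>0</sub><sup>t</sup> K — all in closed form because the Rayleigh CDF is
analytic.  Training minimizes the unweighted sum of an L1 data loss, the L1
residual of the mean-field equation at collocation points (the physics
loss), a scale regularizer pulling each kernel width toward data-driven
targets, and the usual KL term of the variational autoencoder.  Because the
decay rate is only identified *from below* (faster decay can always be
absorbed into a reshaped delay distribution), the unknown-λ<sub>d</sub> mode
profiles the converged physics loss over a grid of fixed decay rates by
warm-started continuation and selects the slowest rate consistent with the
data; see the methods vignette (`vignettes/density-pinn-methods.Rmd`).

The package also ships an **exact simulator** of the delayed birth–death
process (molecule-wise superposition construction, distributionally
identical to the delayed stochastic simulation algorithm) with five
documented preset scenarios (unimodal, weakly/strongly bimodal, trimodal,
flat-peak delay), the deterministic mean-field solver, evaluation metrics
(grid KL divergence, an exact from-scratch implementation of **Hartigan's
dip statistic**, population CV at the final observation point), a
replicated parameter-recovery harness, and a command-line interface.

## Worked example

Simulate 50 traces from the unimodal preset (λ<sub>b</sub> = 20/h,
λ<sub>d</sub> = 0.5/h, gamma-distributed delay with mean 4 h, sampled every
0.5 h for 20 h), fit with the decay rate fixed at its known value — the
recommended mode when the dilution rate is measured, and also the fastest —
then summarize the posterior:

```r
library(densitypinn)

scen <- preset_scenarios(seed = 1)$unimodal
traces <- generate_dataset(scen)                    # time_trace_set + truth
fit <- train_dpinn(traces,
                   config = training_config(max_epochs = 6000, seed = 1),
                   fixed_lambda_d = 0.5)
post <- posterior_sample(fit, n = 1000, seed = 2)
summ <- prediction_interval(post, grid = traces$time)
summ
#> Posterior summary from 1000 draws
#>   lambda_b = 20 +/- 0.125 /h, lambda_d = 0.5 +/- 0 /h
#>   delay distribution: mean 4.04 h, sd 1.53 h, cv 0.379

summarize_pathway(summ, seed = 3)
#> Pathway characteristics: initiation 0.05 h, mu_g 4.04 h, sd 1.53 h, cv 0.379
#>   log response time -1.6; dip 0.003459 (threshold 0.007198) -> unimodal
```

The activation rate is recovered to 0.1% (truth 20/h), the delay mean to
1% (truth 4 h; its SD, truth 1.41 h, is somewhat inflated by the
scale-target smoothing — see the vignette), and the fitted delay
distribution is correctly called unimodal.  `kl_divergence()` and
`dip_statistic()` compare the estimate against the recorded ground truth;
`recovery_experiment()` repeats simulate → fit → infer over replicate
datasets and trace counts.

With `fixed_lambda_d` omitted, `train_dpinn()` runs the decay-rate profile
described above; expect roughly ±25% accuracy on the rates from 50 traces
of this scenario, and see the vignette for why that limit is intrinsic.

## Command line

```sh
exec/density-pinn simulate --preset strongly_bimodal --n 50 --seed 1 --out run/
exec/density-pinn fit --traces run/traces.csv --fixed-lambda-d 0.5 --seed 1 --out run/
exec/density-pinn infer --model run/model.json --seed 1 --out run/
exec/density-pinn evaluate --truth run/truth.json --estimate run/posterior.csv --out run/
```

Every command writes a `resolved_config.json` next to its outputs and is
bit-reproducible from its seed.  Time units are hours throughout.

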