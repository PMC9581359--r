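# idobs — stochastic index of difficulty for repetitive 3D movements

Classical indices of difficulty score a reaching task from its geometry
alone: Fitts' `ID = log2(2D/W)` and MacKenzie's `ID = log2(D/W + 1)` depend
only on target distance `D` and width `W`, and the trajectory
generalization `∫ ds / W_t(s)` on a prescribed width along the path. None of
them measures what a particular mover actually experiences. `idobs` is for
researchers in human motor control, ergonomics and rehabilitation who record
repeated 3D end-effector trajectories (e.g. a hand marker during a
pick-and-place cycle) and want a single difficulty number per
subject-condition that reflects the mover's own variability.

## The model

Given `n` repeated trial trajectories with average path `t̄`, at every arc
length `s` the trials are intersected with the plane `P(s)` orthogonal to
`t̄`. PCA of the `n` crossing points gives in-plane standard deviations
`σ_ε(s) ≥ σ_η(s)`; the standard-deviation ellipse is inflated to a
confidence ellipse at probability level `φ` by the squared scale

    c² = (n − 1)·ν₁ / (n·(n − ν₁)) · F(ν₁, n − ν₁, φ)      (Hotelling, small n)
    c² = χ²(ν₁, φ)                                          (population known)

with `ν₁ = 2` the in-plane dimensionality (for `n = 7`, `φ = 0.95`:
`F(2,5,0.95) = 5.786`, `c² = 1.984`; the population value is
`χ²(2,0.95) = 5.992`). The ellipse is converted to an equivalent circle via
the angular mean radius

    r_mean(s, φ) = (1/2π) ∫₀^{2π} √(c²σ_ε²cos²θ + c²σ_η²sin²θ) dθ,

the stochastic width is `W_obs(s, φ) = 2·r_mean(s, φ)`, and the stochastic
index of difficulty is the cumulative, dimensionless integral

    ID_obs(s*, φ) = ∫₀^{s*} ds / W_obs(s, φ),   s* ∈ [0, |t̄|].

Wide tubes of trials (high motor flexibility) accumulate difficulty slowly;
narrow, constrained passages accumulate it fast. The package also provides
speed profiles with per-phase peak extraction, a synthetic
reach–transport–return trial generator with prescribed dispersion, and
within-subject condition comparison (repeated-measures ANOVA with
Bonferroni-corrected paired post hocs).

## Worked example

```r
library(idobs)

spec <- generator_spec(n = 7, seed = 42)   # tabletop pick-and-place cycle
ens  <- simulate_trials(spec)              # 7 trials, palm-marker-like noise
fit  <- idobs(ens, phi = 0.95, M = 200)
fit
#> Stochastic Index of Difficulty fit
#>   subject 'sim', condition 'default', n = 7 trials
#>   mean path length 1367.5 mm over 200 planes; phi = 0.95 (hotelling regime)
#>   total ID_obs = 115.5
round(coef(fit), 3)
#>       total_ID path_length_mm      mean_W_mm            phi             c2
#>        115.515       1367.462         23.232          0.950          1.984
```

The fit walks a 200-plane grid along the 1367 mm average path; trial
crossings in each orthogonal plane give a mean stochastic width of 23.2 mm
at the 95% Hotelling scale `c² = 1.984`, and integrating `1/W_obs` along the
path accumulates a total difficulty of 115.5 (dimensionless). `plot(fit)`
shows the three per-phase width bells with minima at the grasp/release
events and the difficulty curve steepening there.

Comparing simulated object conditions across subjects:

```r
totals <- sapply(condition_presets(), function(sp) {
  sapply(1:6, function(s) { sp$seed <- 100 * s
                            idobs(simulate_trials(sp), M = 100)$total })
})
compare_conditions(totals)$anova
#> One-way repeated-measures ANOVA: F(4,20) = 2028.622, p = 8.86e-26
```

Conditions with tighter dispersion (the "bottle" presets) come out harder —
the model's core direction: less movement flexibility, more experienced
difficulty.

A thin command-line front end is installed as `exec/idobs`
(`idobs simulate|width|difficulty|velocity|compare --seed ... --out ...`).

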