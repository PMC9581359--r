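---
title: "The stochastic index of difficulty: model, estimation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The stochastic index of difficulty: model, estimation and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idobs)
```

## The problem and the model

Geometric indices of difficulty (Fitts, MacKenzie, and the trajectory
integral with a prescribed target width) are functions of the task alone.
When an agent repeats a 3D movement, however, the difficulty it experiences
also depends on how much freedom it has to vary the movement while still
succeeding. This package treats the natural trial-to-trial dispersion of the
end-effector as a measurement of that freedom ("motor flexibility") and
accumulates its reciprocal along the movement.

Given an ensemble of $n$ repeated trajectories with average path
$\bar{t}$ and arc-length coordinate $s \in [0, |\bar{t}|]$:

1. **Sections.** At each grid value of $s$, every trial is intersected with
   the plane $P(s)$ orthogonal to $\bar{t}$ at the point $p(s)$. A trial
   polyline crosses the plane wherever consecutive points have opposite
   signed distances; the crossing is located by linear interpolation.
2. **In-plane PCA.** The $n$ crossing points are expressed in an in-plane
   orthonormal basis and their $2 \times 2$ sample covariance
   (denominator $n-1$) is eigen-decomposed, giving standard deviations
   $\sigma_\epsilon(s) \ge \sigma_\eta(s)$ along the principal directions.
   The third direction, the path tangent, carries zero spread by
   construction.
3. **Confidence scaling.** Under a bivariate-normal dispersion model, the
   standard-deviation ellipse is inflated to a confidence ellipse at
   probability $\varphi$ by $c^2$: the Hotelling $T^2$ quantile
   $c^2 = \frac{(n-1)\nu_1}{n(n-\nu_1)} F_{\nu_1, n-\nu_1, \varphi}$ with
   $\nu_1 = 2$ when only a small sample is available, or the
   $\chi^2_{\nu_1,\varphi}$ quantile when the population is known.
4. **Width and difficulty.** The ellipse is summarized by its angular mean
   radius $r_{mean}(s,\varphi) = \frac{1}{2\pi}\int_0^{2\pi}
   \sqrt{c^2\sigma_\epsilon^2\cos^2\theta + c^2\sigma_\eta^2\sin^2\theta}
   \,d\theta$, the stochastic width is $W_{obs} = 2\,r_{mean}$, and
   $ID_{obs}(s^*,\varphi) = \int_0^{s^*} ds / W_{obs}(s,\varphi)$.

$ID_{obs}$ is dimensionless and invariant under uniform spatial scaling and
rigid motion of all trials; it is *not* logarithmic, unlike the classical
bit-valued indices — it is a cumulative ratio of length to width.

**Assumptions.** Trials realize one movement strategy (no multimodal
mixtures of qualitatively different paths); crossings in each section are
approximately bivariate normal; the ensemble is large enough
($n \ge \nu_1 + 1 = 3$) for the sample covariance and the $F$ quantile to
exist. The model reads larger dispersion as larger flexibility — appropriate
for repetitive, well-practised tasks on short time scales, not for tremor or
pathological variability.

## Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `phi` | 0.95 | — | probability level of the confidence ellipse; enters only through $c^2$, so it rescales $W$ globally (exactly so for fixed $n$) |
| `M` | 200 | planes | grid density along $\bar t$; the trapezoid error of the difficulty integral decays as $M^{-2}$ |
| `regime` | `"hotelling"` | — | small-sample $T^2$ scaling; `"chi2"` only when the caller asserts the population is known |
| `center` | `"centroid"` | — | PCA centering: centroid of the crossings (standard PCA practice) or the mean-path point $p(s)$ |
| `w_min` | $10^{-6}$ | mm | divergence guard: the fit aborts rather than integrate through a closed tube |
| `quadrature_points` | 256 | nodes | trapezoid order for $r_{mean}$ |

Two definitional choices deserve justification because the construction does
not force them:

* **Trial correspondence by normalized arc length.** The average path is the
  pointwise mean of trials resampled at equal fractions of their own arc
  length, not at equal times. This makes $\bar t$ — and everything downstream
  — independent of speed fluctuations, consistent with the purely spatial
  difficulty integral. Time-based averaging would let a slow trial drag the
  mean sideways at a fixed $s$.
* **Ellipse center.** The nominal center of the section ellipse is the
  mean-path point $p(s)$, but the crossings' centroid coincides with it only
  asymptotically. We center the PCA on the centroid by default (dispersion
  should be measured about the cloud's own mean; centering on $p(s)$ would
  leak mean-path estimation error into $\sigma$), and keep `center = "path"`
  as an option.

The two scaling regimes deliberately do not meet in the large-$n$ limit: the
$T^2$ quantile falls below $\chi^2_{2,\varphi}$ as $n$ grows. Both formulas
are implemented exactly as defined and the regime is never switched
silently.

## Numerical choices

* **Mean-radius quadrature.** The integrand is periodic and analytic
  whenever $\sigma_\eta > 0$, so the 256-node trapezoid rule is spectrally
  accurate (machine precision at axis ratios up to at least 10:1). The two
  non-smooth limits are special-cased to their closed forms: a circle gives
  $\sqrt{c^2}\sigma$ and a collapsed ellipse $(2/\pi)\sqrt{c^2}
  \sigma_\epsilon$.
* **Difficulty integral.** Cumulative trapezoid on the plane grid itself —
  the width is only known at plane locations, so no resampling happens
  inside the integral. The rule is exact for constant integrands and
  additive over sub-intervals to round-off.
* **Tangents.** Central differences on the resampled mean path, one-sided at
  the endpoints, normalized to unit length.
* **Multiple crossings.** A trial may cross $P(s)$ several times (e.g. a
  looping return phase). The crossing nearest $p(s)$ within the plane is
  kept, because the dispersion model describes the cloud around $p(s)$; ties
  go to the earliest crossing along the trial.
* **Invalid planes.** A plane with fewer than $\nu_1 + 1$ crossings, or zero
  dispersion, gets no width of its own; it is flagged and filled by linear
  interpolation from valid neighbours (constant extrapolation at the ends),
  keeping the integrand defined without fabricating dispersion. If more than
  half the planes are invalid the ensemble is rejected as degenerate.
* **Degenerate post hocs.** A paired comparison whose difference vector is
  identically zero reports $t = 0$, $p = 1$; a zero-variance difference with
  non-zero mean has no defined $t$ and is flagged with `p = NA`.
* **Ties in peak extraction.** Equal speed maxima report the earliest
  position.

## What the generator emulates — and what it does not

`generator_spec()` encodes a seated tabletop pick-and-place cycle: start at
the table edge, grasp at (250, 300, 0) mm, release at (−250, 300, 0) mm —
500 mm away, symmetric across the midline, both 300 mm into the table — and
return, with 60 mm lifted control points between events so the path is
genuinely three-dimensional. Natural cubic splines through these control
points give the mean path; the evaluation grid contains the control-point
parameters, so the path interpolates every waypoint exactly.

Dispersion follows the accuracy structure of such tasks: within each of the
three phases $\sigma_\epsilon$ rises from `sigma_min` (2 mm) at the events
to `sigma_max` (20 mm) at mid-phase as $\sin^2(\pi v)$, with
$\sigma_\eta = 0.6\,\sigma_\epsilon$. These magnitudes are plausible for a
palm marker in a practised adult reach (millimetre-level precision at grasp,
centimetre-level wander mid-flight); the anisotropy reflects that in-plane
variability is rarely isotropic. Trials are the mean path plus two
independent Gaussian processes along the normal frame, squared-exponential
correlation with length 10% of the path — uncorrelated noise would produce
jagged, non-physical trials and discontinuous plane crossings. Timing is
per-phase minimum-jerk with equal phase durations over a 3 s cycle, so
longer phases have proportionally higher speed peaks. `n = 7` trials per
ensemble is the default unit of analysis. Named condition presets rescale
only the dispersion amplitude, standing in for grasp types.

The generator emulates the *statistical structure* the estimator assumes —
smooth tube, per-phase bells, normal sections. It does not emulate marker
dropout, soft-tissue artefact, multimodal strategies, trial-length
imbalance, or any biomechanics of the arm; passing recovery tests on
simulated data therefore validates the estimation chain, not the model's
adequacy for any particular real dataset.

## Problem sizes in the test suite

The suite checks generator-truth recovery of $W_{obs}$ with $n = 200$
simulated trials on a 200-plane grid (mean absolute relative error on the
interior of the path), plus a companion check at the study-scale $n = 7$;
the shape analysis (three width bells, minima at events, difficulty slope
more than twice steeper at the minima) uses $n = 100$ trials for a stable
per-plane profile; the dispersion–difficulty ordering uses 100 paired-seed
simulations at $n = 7$ on a 100-plane grid; and the type-I error of the
repeated-measures ANOVA is calibrated on 2000 null simulations. These sizes
are the package's own accuracy/stability choices for each property.

## Known limitations

* Crossing-based sections degrade near the path endpoints, where trials may
  not reach the first/last planes; those planes are interpolated and
  flagged.
* Strongly self-intersecting mean paths can place distinct path regions in
  the same plane; the nearest-crossing rule resolves this locally but a
  figure-eight path with touching lobes would confuse the sections.
* The Hotelling/χ² regimes are not continuous in $n$; comparisons across
  ensembles of different sizes should fix the regime (and ideally $n$).
* No correction for non-sphericity is applied in the repeated-measures
  ANOVA; with $k > 2$ conditions and suspect covariance structure, apply an
  external Greenhouse–Geisser correction.
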