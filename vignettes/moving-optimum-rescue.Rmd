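---
title: "Moving-optimum evolutionary rescue with male indirect genetic effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Moving-optimum evolutionary rescue with male indirect genetic effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evorescue)
```

## The model

Avian lay-date is modelled as a normally distributed quantitative trait under
stabilizing selection around an optimum that advances linearly as springs
warm.  The package extends the classical sex-limited moving-optimum model in
two directions:

1. **Indirect genetic effects (IGEs).**  A male partner trait $z_m$
   (arrival date, courtship feeding, territory quality, ...) affects his
   mate's lay-date through a linear reaction norm with slope $\psi$ (social
   plasticity).  Because $z_m$ is heritable (variance $G_m$), male evolution
   feeds into female phenotypic change.
2. **Cross-sex genetic correlation.**  The breeding values of lay-date and
   the male trait may covary ($G_{fm}$; correlation
   $\rho = G_{fm}/\sqrt{G_f G_m}$, regression $\xi = G_{fm}/G_m$), so
   selection on either sex drags the other along.

Each sex has its own quadratic fitness function; under warming at $\eta$
°C/year the optima advance by $B_j\,\eta$ days per year ($j \in \{f, m\}$).
Per generation (one generation $= T$ years) the trait means respond to the
linearized gradients $\beta_j = -\gamma_j(\bar z_j - \theta_j)$ via the
two-sex Lande equation

$$\Delta\bar z_m = \tfrac12\,(G_m\beta_m + G_{fm}\beta_f), \qquad
  \Delta\bar z_f = \tfrac12\,(G_f\beta_f + G_{fm}\beta_m)
                 + \psi\,\Delta\bar z_m,$$

where the $\tfrac12$ reflects sex-specific selection.  Population growth is
governed by female adaptation alone (female demographic dominance):
per-generation log growth is $r_{max} T$ minus the lag load
$\tfrac{\gamma_f}{2}(\bar z_f - \theta_f)^2$.  Both traits eventually track
their optima with a constant lag; setting equilibrium log growth to zero
gives the **critical rate of environmental change**

$$\eta_c \;=\; \frac12 \sqrt{\frac{2\,\gamma_f\,r_{max}}{T}}\;
  \frac{G_f\,(1-\rho^2)}{\lvert B_f - (\psi + \xi)\,B_m \rvert},$$

implemented in `eta_critical_full()`, with `eta_critical_ige()`
($\rho = 0$) and `eta_critical_reference()` ($\rho = \psi = 0$) as exact
special cases.  The correlation acts twice: it erodes sex-independent
genetic variance in the numerator and adds indirect selection
$\xi B_m$ to the tracking denominator, exactly parallel to the plastic term
$\psi B_m$.

## Assumptions

Density-independent, panmictic population; constant additive (co)variances,
$\psi$, $\gamma_j$, $B_j$; no drift, dispersal, or (abiotic) phenotypic
plasticity; discrete non-overlapping generations; a constant rate of
temperature change; males affect females but not vice versa (the male trait
is expressed before lay-date); persistence decided purely by the sign of
equilibrium log growth.  The standing load from phenotypic variance around
the optimum is constant under these assumptions and treated as absorbed
into $r_{max}$.

## Parameters, units, defaults

| parameter | meaning | units | standard value |
|---|---|---|---|
| $G_f$, $G_m$, $G_{fm}$ | additive (co)variances | days² | species table |
| $\psi$ | social plasticity slope | days/day | $G_{fi}/G_i$ |
| $\gamma_f$ | stabilizing selection curvature | 1/days² | 0.005 |
| $B_f$, $B_m$ | optimum sensitivity to temperature | days/°C | $-5$ |
| $r_{max}$ | intrinsic growth rate | 1/year | species table |
| $T$ | generation time | years | species table |
| $\eta$ | rate of environmental change | °C/year | free |

The standard evaluation set ($r_{max} = 0.5$, $T = 2$, $\gamma = 0.005$,
$G_f = 6$, $B_f = -5$) gives the reference value $\eta_c = 0.03$ °C/year
used throughout the examples and tests.  $\gamma_m$ defaults to $\gamma_f$
(a single curvature is the standard evaluation choice).  Published species
estimates (`species_estimates_path()`) supply $r_{max}$, $T$ and the
variance components $G_f$, $G_i$, $G_{fi}$ from which $\psi = G_{fi}/G_i$ is
back-calculated under the single-male-trait simplification.

## Conventions and numerical choices

**Year/generation bookkeeping.**  One simulator step spans $T$ years: optima
advance $B_j \eta T$ days per step and log growth per step is
$r_{max} T$ minus the lag load.  This convention is what produces the
$\sqrt{2 r_{max} \gamma_f / T}$ prefactor, and the test suite pins it down
by a time-rescaling invariance: multiplying $T$ by $k$ while dividing
$\eta$ and $r_{max}$ by $k$ leaves the per-generation lag sequence
unchanged.

**Sign conventions.**  Lay-date is in days of year (earlier = smaller);
under warming both $B_f, B_m < 0$ in the focal scenario (opposing optima
are allowed and only trigger a constructor warning).  The lag is
$\bar z_f - \theta_f$, so positive means breeding later than optimal.  The
equilibrium lag is

$$\bar z_f - \theta_f \;=\;
  \frac{-2\,\eta\,T\,\bigl(B_f - (\psi+\xi) B_m\bigr)}
       {\gamma_f\,G_f\,(1-\rho^2)},$$

the fixed point of the recursion (`equilibrium_lag()`); the leading minus
sign makes the lag positive for $B_f < 0$ in the reference case.  At
$\eta = \eta_c$ its magnitude is exactly $\sqrt{2 r_{max} T / \gamma_f}$ —
the pivot identity of the derivation, asserted to machine precision in the
tests.

**Selection gradient.**  $\beta = -\gamma(\bar z - \theta)$, the linearized
gradient on the quadratic surface.  Phenotypic variance is constant by
assumption and not used to inflate the fitness-function width; $\gamma$
enters the equations directly.

**Adaptive range of plasticity.**  `psi_adaptive_range()` solves
$\lvert B_f - (\psi + \xi) B_m\rvert < (1-\rho^2)\lvert B_f\rvert$ for
$\psi$ from first principles rather than using any closed-form shorthand;
with $\rho = \xi = 0$ it reduces to the interval $(0,\, 2B_f/B_m)$.  A
dense-grid comparison (resolution $10^{-4}$) of the full-model curve against
the reference value across 100 randomized parameter sets confirms the
endpoints in the test suite.

**Degenerate denominators.**  At $\psi = \psi_{opt} = B_f/B_m - \xi$ the
tracking denominator vanishes and tolerance is unbounded; since this is an
interior point of every plotted grid, such values are returned as flagged
non-finite `critical_rate` objects (CSV sentinel `inf`) rather than raised
as errors, and Monte Carlo tables count them explicitly.  $|\rho| = 1$
leaves no sex-independent variance: the critical rate is zero, with a
warning.

**Simulator.**  `simulate_tracking()` iterates the deterministic mean
recursion (an infinite-population model: no demographic or genetic
stochasticity).  Equilibrium is declared when both sexes' lags change by
less than `equilibrium_tol` (default $10^{-9}$ days) in one generation;
non-convergence within `max_generations` is flagged, never truncated
silently.  `critical_rate_by_simulation()` bisects $\eta$ over the
persistence/extinction boundary to a $10^{-6}$ relative tolerance using a
storage-free recursion with a tighter equilibrium tolerance
($10^{-10}$ days) and a larger generation cap ($10^5$), since strongly
correlated architectures converge slowly.  The simulator never evaluates
the closed forms, which is what makes the bisection an independent check:
the suite requires agreement within 0.1% on the standard evaluation set and
within 1% on randomized parameter sets with $|\rho| \le 0.8$.

## Monte Carlo propagation

`sample_parameter_set()` draws each uncertain parameter independently from a
normal with the published mean and SE (parameters published without an SE
stay fixed), rejecting draws until $G_f, G_i > 10^{-6}$ and
$\lvert G_{fi}\rvert \le \sqrt{G_f G_i}$.  When $G_{fi}$ itself is fixed
(SE $= 0$, as for the song sparrow) the bound is enforced by resampling the
variance pair instead, since the covariance cannot move.  Independent
normals are the richest distribution the published SE columns support; no
covariance between estimates is modelled.

`eta_c_density()` crosses the draws with a `scenario_grid()` of imposed
correlation levels and sensitivity offsets $B_m - B_f$, identifying the
male-trait variance with the printed indirect variance ($G_m := G_i$), the
convention under which $\psi = G_{fi}/G_i$ closes.  The alternative
identification $G_m = G_i/\psi^2$ is exposed via
`gm_convention = "Gi_over_psi2"` for exploration.  $\rho$ is imposed per
scenario; $\xi$ is recomputed per draw from the sampled variances.  The
default is 50,000 draws per cell with fixed evaluation constants
$\gamma_f = 0.005$, $B_f = -5$; the tests exercise $10^2$–$1.6 \times 10^3$
draws, which is ample because every distributional property asserted
(point-mass collapse at zero SE, seeded bit-reproducibility,
admissibility of retained draws, $\sqrt n$ tightening of the median) is
scale-free.

A caution on summaries: $\eta_c$ is a reciprocal of the sampled mismatch
$B_f - \psi B_m$, so whenever draws of $\psi$ approach $B_f/B_m$ the density
acquires a heavy right tail and its *mean* may not converge with sample
size.  Medians and quantiles are stable and are what the CLI summary
reports; the test suite checks $\sqrt n$ tightening on the median for a
species whose denominator stays away from zero.

## What the synthetic data do and do not show

Randomized parameter sets in the property tests draw variances, curvatures,
sensitivities and demographic rates from ranges bracketing the species table
(e.g. $G_f \in [2, 12]$, $\gamma_f \in [0.003, 0.01]$,
$B_j \in [-8, -2]$, $|\rho| \le 0.8$).  They emulate the model's own world —
constant parameters, deterministic tracking, linear optimum shifts — so
passing tests establish internal consistency of the algebra, the recursion
and the sampling machinery, not realism: real populations experience
fluctuating selection, density dependence, evolving plasticity, measurement
error correlated across components, and finite population size, all outside
this model class.

## Known limitations

No evolution of $\psi$ itself, no assortative mating, no density- or
frequency-dependent selection, no drift or dispersal, one male trait only,
and sex-specific phenotypic variances enter only through the constant
standing load.  The critical-rate surface is exact only at equilibrium;
transient dynamics after an abrupt onset of warming are visible in
`simulate_tracking()` trajectories but do not enter $\eta_c$.
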