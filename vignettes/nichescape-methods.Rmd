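---
title: "Model and methods: niche and dispersal evolution on fractal landscapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: niche and dispersal evolution on fractal landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`nichescape` simulates guilds of annual, asexual organisms living on
toroidal grid landscapes whose environments vary in space and time, in
order to study how the *magnitude* of spatial environmental variation
(compositional heterogeneity) and its *arrangement* (spatial
autocorrelation) jointly shape the evolution of niche optima, niche
tolerances, dispersal frequency and dispersal distance. This vignette
is the package's own account of the model, its parameters, the
numerical choices made, and what the test suite does and does not
demonstrate.

## The landscape

A landscape is a `width x height` grid of habitat patches (default
20 x 20 = 400) carrying two attributes: a temperature-like attribute
*T* that fluctuates globally over time, and a static habitat attribute
*H* (think of a soil property). Both attribute surfaces are fractal
random fields generated by **Fourier spectral synthesis**: white
Gaussian noise is filtered in the frequency domain with amplitude
$f^{-(H_u + 1)}$ — power spectrum $S(f) \propto f^{-(2 H_u + 2)}$,
the fractional-Brownian-motion convention — where $H_u \in [0, 1]$ is
the Hurst index. The zero-frequency component is removed before the
inverse transform.

Spectral synthesis was chosen over midpoint displacement deliberately:
a field synthesized on the discrete Fourier basis is *inherently
periodic*, so opposite edges of the grid connect seamlessly and the
landscape is a torus with no edge effects; midpoint displacement is
not periodic and requires $2^n + 1$ grids, while synthesis supports
arbitrary dimensions directly. A Hurst index of 1 produces smooth,
completely autocorrelated fields; a Hurst index of 0 maps to spectral
exponent $\beta = 2$, which at the 20 x 20 scale is a largely random
arrangement (there is no special white-noise branch; autocorrelation
is simply monotone in the index, which the test suite checks through
Moran's I under rook adjacency on the torus).

Each field is standardized to mean 0 and standard deviation 1
(**population** SD, divisor $n$; at $n = 400$ the distinction from
the sample SD is immaterial, but it is fixed and documented so that
the G-scaling identity `sd(G * field) == G` is exact). Because every
field is standardized, the frequency distribution of patch values is
identical across spatial configurations, and a single multiplier *G*
(compositional heterogeneity) controls the magnitude of spatial
variation. *G* is stored unapplied and only enters at attribute
lookup, so one landscape file serves every *G* scenario.

The *T* attribute additionally receives a global temporal fluctuation
$\epsilon(t) \sim \mathcal{N}(0, 1)$, identical for all patches in a
step and pre-generated for the whole run at initialization:

$$T_{patch}(x, y, t) = G\,\hat T(x, y) + \epsilon(t), \qquad
  H_{patch}(x, y) = G\,\hat H(x, y).$$

Crucially, the temporal noise scale is fixed at 1 while the spatial
scale is *G*: small-*G* worlds are spatially homogeneous but exactly
as temporally variable as large-*G* worlds.

## Organisms and fertility

Organisms are clonal. A lineage is founded by a single immigrant whose
six traits are drawn once and inherited unchanged: temperature
optimum/tolerance ($T_{opt}, T_{tol}$), habitat optimum/tolerance
($H_{opt}, H_{tol}$), dispersal probability $P_{disp}$ and dispersal-
mode preference $P_{global}$. There is no mutation: all evolution is
differential survival and reproduction among immigrant-founded
lineages, with immigration continuously re-supplying variation.

Expected fecundity is a product of two Gaussian mismatch terms and two
tolerance trade-off terms:

$$E_{fert} = R_0
  \; e^{-\left(T_{patch} - T_{opt}\right)^2 / T_{tol}^2}
  \; e^{-\left(H_{patch} - H_{opt}\right)^2 / H_{tol}^2}
  \; e^{-T_{tol}^2 / 2\alpha^2}
  \; e^{-H_{tol}^2 / 2\alpha^2}$$

with $R_0 = 15$ and $\alpha = 3$ by default. The trade-off factors
cap the fecundity of generalists, preventing runaway tolerance
evolution; specialists pay instead through mismatch risk under the
global temperature fluctuations. The mismatch denominators are
written here as $T_{tol}^2$ with **no factor 2**, matching the form
in which the trade-off exponent carries an explicit 2 and the mismatch
exponent does not. Because the alternative convention ($2\,T_{tol}^2$)
is defensible, it is isolated behind a single switch
(`sim_params(niche_denominator_factor = 2)`), and every fertility
computation in both engines flows through the one formula.

## The annual cycle

Each time step runs four phases in fixed order:

1. **Reproduction.** Every adult produces
   $\mathrm{Poisson}(E_{fert})$ offspring with identical traits,
   evaluated at this step's realized patch attributes. Adults then die
   (complete generational replacement).
2. **Competition.** Offspring mature under Beverton–Holt density
   regulation: with $a = (R_0 - 1)/(K R_0)$ and patch offspring pool
   $L_0$, each offspring survives independently with probability
   $S_A = 1/(1 + a L_0)$. The patch survivor count is therefore
   $\mathrm{Binomial}(L_0, S_A)$ and survival is trait-blind. At
   $L_0 = R_0 K$ the expected survivor count is exactly $K$ (150 by
   default), the carrying capacity under perfect fitness; maladapted
   populations realize a lower effective capacity.
3. **Immigration.** Each patch receives
   $\mathrm{Poisson}(E_{immi})$ external immigrants
   ($E_{immi} = 2.5$), each founding a fresh lineage with traits drawn
   from: $T_{opt} \sim \mathcal{N}(T_{trend}, G)$,
   $H_{opt} \sim \mathcal{N}(0, G)$, tolerances log-normal with
   log-scale parameters $(0, 1)$ (median 1), dispersal traits uniform
   on $[0, 1]$. $T_{trend} = 0$ throughout: no directional
   environmental trend is simulated. Immigrants join the new
   generation before dispersal and so may disperse in their arrival
   step; realized immigration intensity is exactly $E_{immi}$
   regardless of local density. At capacity this is roughly
   $2.5/2250 \approx 0.11\%$ of a perfectly adapted patch's expected
   offspring production.
4. **Dispersal.** Each individual disperses at most once: a uniform
   draw against $P_{disp}$ decides whether to leave; a second draw
   against $P_{global}$ chooses random **global** dispersal (uniform
   over all non-natal patches) over **nearest-neighbour** dispersal
   (uniform over the 8-cell Moore ring, wrapping across the toroidal
   edges). Both modes redraw rather than settle the natal patch. The
   two modes approximate the peak and tail of a dispersal kernel at
   minimal computational cost.

Landscapes start empty and are colonized by immigration. Per-step
landscape summaries record the settled new generation after dispersal
(means and variances of all six traits, fecundity and
proportion-of-maximum fitness, evaluated at that step's realized
attributes). The final-step census records every individual with its
patch, lineage, traits, both the base ($G \hat T$) and
fluctuation-realized ($G \hat T + \epsilon(t_{max})$) temperature
attribute, and fitness metrics computed from the **base** attribute —
the time-invariant expectation of the patch environment, since
$\epsilon$ has mean zero; which convention the census uses matters
only marginally for mismatch summaries, and both columns are stored.

## Engines, determinism, performance

The cycle is implemented twice, by design:

* a pure-R reference (`step()`, plus the per-operation functions
  `reproduce()`, `compete()`, `decide_dispersal()`, ...), readable and
  used for fine-grained invariant tests; and
* a compiled engine (Rcpp) used by `run_replicate()`, which executes
  all `tmax` steps in C++. In the compiled engine the competition
  phase draws each parent's survivor count directly as
  $\mathrm{Binomial}(n_{off,i}, S_A)$ — distributionally identical to
  per-offspring Bernoulli thinning by the splitting property of the
  binomial, but several-fold faster because the full offspring pool is
  never materialized.

Both engines draw exclusively from R's global RNG stream, so a
replicate is a pure function of its seed. Replicate seeds derive from
`(base_seed, scenario_index, replicate_index)` via a fixed
multiply-and-add hash modulo $2^{31}-1$ (`replicate_seed()`), and
within a replicate the draw order is documented and fixed: landscape
*T* field, landscape *H* field, fluctuation series, then dynamics.
The two engines consume randomness in different orders, so they are
not bit-identical to each other; the suite instead checks exact
formula agreement (R vs compiled fertility) and demographic agreement
at equal parameters. Patch iteration is row-major and individual
iteration is storage-ordered, which fixes bit-level reproducibility
without affecting distributions.

## Experiment design and analysis pipeline

The full study design crosses
$G \in \{0.05, 0.1, 0.3, 0.7, 1, 1.3, 1.7\}$ with Hurst index
$\in \{0, 1\}$ — 14 scenarios, 30 replicates of 10,000 steps each —
and is the default of `run_experiment()` / the `run` subcommand. The
analysis pipeline (`analyze_census()`) mirrors how such censuses are
analysed:

* **Establishment filter**: keep individuals of lineages with at least
  50 members in their replicate's landscape at the final step,
  removing transient maladapted immigrants.
* **Sampling**: a seeded simple random sample of 10,000 individuals
  per scenario, pooled over that scenario's replicates; crashed
  scenarios contribute everything they have (high-*G* fluctuation
  crashes are expected behaviour, not errors — the engine tolerates
  empty patches and extinct landscapes).
* **Trait correlations**: pairwise squared Pearson correlations among
  the six traits, niche optima absolute-value transformed by default —
  on a standardized symmetric attribute axis the sign of an optimum is
  arbitrary, its magnitude is what measures extremeness. $R^2$ is the
  square of the Pearson coefficient, identical to the regression
  $R^2$ of a simple linear fit with intercept. Zero-variance pairs are
  reported as missing, never 0.
* **Adaptation/mismatch and scenario summaries**: per-individual
  optimum-minus-attribute differences with fitness metrics, and
  per-scenario medians/variances/quartiles. No statistical
  significance tests are computed anywhere in the pipeline: with a
  mechanistic generative model and $n = 10^4$ samples they would be
  both meaningless and trivially "significant".

## Problem sizes used in the checks

The packaged checks run a reduced design chosen to exercise the full
pipeline at desk scale: the four corner scenarios
$(G, H_u) \in \{0.05, 1\} \times \{0, 1\}$, three replicates each,
20 x 20 landscapes, 2,000 steps. Two thousand steps is past the point
where the qualitative trait contrasts stabilize (the dispersal
collapse with rising *G* is already visible within a few hundred
steps), while the full 10,000-step, 30-replicate grid remains
available through `run_experiment()` defaults. At this reduced scale
the suite asserts direction, not magnitude: higher median $P_{disp}$
at $G = 0.05$ than at $G = 1$ within each autocorrelation level;
higher median $H_{tol}$ at $G = 1$; lower median $P_{global}$ under
full autocorrelation at $G = 1$; and strong local adaptation (median
mismatch-only fitness proportion above 0.8) at $G = 1$.

## What the synthetic conditions do and do not show

Everything here is simulation: the generator *is* the study system.
Passing tests demonstrate that the implementation realizes the stated
stochastic processes (rates, distributions, fixed points, invariants)
and that the eco-evolutionary feedbacks those processes imply —
risk-avoidance versus bet-hedging — reproduce the expected qualitative
trait patterns. They say nothing about any real organism or landscape:
patch attributes are abstract standardized axes; generations are
discrete and non-overlapping; reproduction is clonal with no mutation,
so standing variation is bounded by the immigrant stream; dispersal is
uninformed and cost-free in itself (its cost is emergent, through
settling in mismatched habitat); temporal noise is white, global and
Gaussian. Known numerical edges: tolerances of exactly 0 are outside
the trait domain (the fertility mismatch term would be singular) and
are rejected; `Ttol = 1e-9` style values are fine because the
zero-mismatch limit is taken before the tolerance limit; constant
fields cannot be standardized and raise an error rather than
propagating NaNs; and a 1 x 1 landscape admits no global dispersal
target and is likewise an error.
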