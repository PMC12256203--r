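# nichescape

Spatially explicit, individual-based simulation of how landscape
structure shapes the joint evolution of environmental niches and
dispersal. `nichescape` is for theoretical ecologists and
evolutionary biologists who want to ask: when spatial environmental
variation gets stronger (compositional heterogeneity) or more
clumped (spatial autocorrelation), what happens to niche optima,
niche breadth, dispersal frequency and dispersal distance — and to
the correlations among them?

## The model in brief

Annual, asexual organisms live on a toroidal `20 x 20` grid of
patches. Each patch carries two standardized attributes: a
temperature-like axis *T* that fluctuates globally each step
(`T(x,y,t) = G·T̂(x,y) + ε(t)`, `ε ~ N(0,1)`) and a static habitat
axis *H* (`H(x,y) = G·Ĥ(x,y)`). The surfaces `T̂`, `Ĥ` are periodic
fractal fields generated by spectral synthesis with power spectrum
`S(f) ∝ f^-(2H_u+2)`; the Hurst index `H_u ∈ [0,1]` sets spatial
autocorrelation and the multiplier `G` sets the magnitude of spatial
heterogeneity.

Each individual carries six heritable traits — niche optima and
tolerances for both axes (`Topt`, `Ttol`, `Hopt`, `Htol`) and two
dispersal traits (`Pdisp`, `Pglobal`). Expected fecundity follows a
Gaussian niche with a tolerance/fecundity trade-off:

    Efert = R0 · exp(−(T−Topt)²/Ttol²) · exp(−(H−Hopt)²/Htol²)
               · exp(−Ttol²/2α²) · exp(−Htol²/2α²)

with `R0 = 15`, `α = 3`. The annual cycle is Poisson reproduction →
Beverton–Holt density-dependent survival (`SA = 1/(1 + a·L0)`,
`a = (R0−1)/(K·R0)`, `K = 150`) → external immigration (Poisson,
`Eimmi = 2.5` per patch-step; immigrants found fresh lineages with
randomized traits) → dispersal (stay with `1−Pdisp`; otherwise
nearest-neighbour on the Moore ring or global uniform, chosen by
`Pglobal`; torus wrap everywhere). There is no mutation: trait
evolution is lineage sorting under continuous immigrant supply.

The simulation loop is compiled (Rcpp); a 10,000-step replicate with
~60,000 individuals runs in minutes, and every run is a pure function
of its seed.

## Worked example

One replicate of the high-heterogeneity, fully autocorrelated
scenario (`G = 1`, Hurst 1), 500 steps:

```r
library(nichescape)
p   <- sim_params(tmax = 500, G = 1, hurst = 1)
res <- run_replicate(p, base_seed = 42)
res
#> Simulation replicate (G1_H1, replicate 1): 57382 individuals at tmax = 500

cen <- filter_established(res$census, 50)   # established lineages only
round(sapply(cen[, c("Pdisp", "Pglobal", "Ttol", "Htol")], median), 3)
#>   Pdisp Pglobal    Ttol    Htol
#>   0.078   0.373   2.188   0.857

trait_correlations(cen)
#> Trait R-squared matrix (n = 55926 individuals)
#>         |Topt|  Ttol |Hopt|  Htol Pdisp Pglobal
#> |Topt|   1.000 0.000  0.015 0.002 0.002   0.003
#> Ttol     0.000 1.000  0.000 0.006 0.003   0.079
#> |Hopt|   0.015 0.000  1.000 0.155 0.068   0.074
#> Htol     0.002 0.006  0.155 1.000 0.023   0.008
#> Pdisp    0.002 0.003  0.068 0.023 1.000   0.170
#> Pglobal  0.003 0.079  0.074 0.008 0.170   1.000

median(cen$prop_max_tradeoff)
#> [1] 0.924
```

Reading the output: under strong, clumped heterogeneity dispersal has
collapsed (median `Pdisp` ≈ 0.08 against an immigrant-pool median of
0.5) because emigrating usually means landing in mismatched habitat.
Temperature tolerance stays broad (median `Ttol` ≈ 2.2) — global
fluctuations cannot be escaped in space — while habitat tolerance
stays narrow (median `Htol` ≈ 0.86): purely spatial variation can be
avoided by *not moving*. Organisms in more extreme habitat patches
tend to be broader-tolerance dispersers (the positive
`|Hopt|`–`Htol`–`Pdisp` block of the R² matrix), and the population is
strongly locally adapted (median 92% of mismatch-free maximum
fecundity).

The full 14-scenario experiment
(`G ∈ {0.05, 0.1, 0.3, 0.7, 1, 1.3, 1.7} x Hurst ∈ {0, 1}`, 30
replicates of 10,000 steps) is the default of `run_experiment()`, and
a command-line front end lives in `inst/cli/`:

```sh
Rscript inst/cli/nichescape.R generate-landscape --width 20 --height 20 \
    --hurst 1 --seed 42 -o land.txt
Rscript inst/cli/nichescape.R run --config config.yaml
Rscript inst/cli/nichescape.R analyze out/*/census.csv --out-dir analysis
```

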