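# crossel

Stochastic simulation of multi-trait **genomic cross selection** in a
recurrent-selection breeding program, for breeders and quantitative
geneticists who want to compare cross-selection metrics and resource
allocations (numbers of parents, crosses, and progeny per cross) before
committing a real program to them.

## What it models

A selfing-crop pipeline — crossing block → F1 → doubled haploids (DH) →
nursery → preliminary yield trial (PYT) → advanced yield trial (AYT) — run
year by year, with the best PYT entries recycled as parents. Multi-trait
merit is the **rank summation index** (RSI): each genotype is ranked within
each trait (respecting that trait's goal: increase, decrease, or an optimum
target) and the ranks are summed,

> y<sub>IS,i</sub> = Σ<sub>j</sub> g<sub>ij</sub>,  lower = better.

The (negated) index is the derived phenotype of a whole-genome **Bayesian
ridge regression** fit by Gibbs sampling on SNP-chip dosages,

> y = μ + Xβ + ε,  β<sub>j</sub> ~ N(0, σ²<sub>β</sub>),

whose posterior feeds five ways of choosing which parent pairs to cross:

| metric | definition |
|---|---|
| MeanGEBV | ½(GEBV<sub>A</sub> + GEBV<sub>B</sub>), after a Rogers-distance prefilter |
| PMV | posterior mean-variance of progeny: (1/L) Σ<sub>l</sub> β⁽ˡ⁾′ Σ β⁽ˡ⁾, with Σ<sub>jk</sub> = 4 D<sub>jk</sub>(1 − 2c<sub>jk</sub>) from parental linkage phase and Haldane's c = ½(1 − e<sup>−2d</sup>) |
| UC | usefulness criterion μ + i·√PMV, i = φ(Φ⁻¹(1−p))/p |
| OHV | optimal haploid value 2 Σ<sub>segments</sub> max(H<sup>s</sup>β<sup>s</sup>) |
| RandPheno | random pairing of the same index-selected parents (baseline) |

Founder genomes (7 chromosomes, 500 QTN, a disjoint 3,500-SNP chip) are
generated internally with linkage disequilibrium that decays with map
distance; four correlated traits (grain yield, kernel weight, maturity,
height) are calibrated so founder genetic means and variances hit their
targets exactly. See the vignette (`vignettes/cross-selection-methods.Rmd`)
for the full model, parameter meanings, and design choices.

## Worked example

Score parent pairs for a crossing block:

```r
library(crossel)
set.seed(42)

g        <- build_genome(n_chrom = 7, chrom_lengths = 1, sites_per_chrom = 600)
founders <- generate_founders(g, n_founders = 100)
part     <- partition_sites(g)                    # 500 QTN + 3,500 chip SNPs
arch     <- calibrate(sample_effects(part, default_trait_specs(),
                                     default_correlations()), founders)

round(colMeans(genetic_values(founders, arch)), 2)
#>    YLD    TKW    DPM     PH
#>   5.78 433.00  81.00  67.00          # calibrated founder means, exact

pt  <- simulate_phenotypes(founders, arch,
         trial_design("PYT", n_locations = 2, n_reps = 2,
                      plot_h2 = c(0.3, 0.6, 0.7, 0.5),
                      gxe_variance_ratio = 0.2))
y   <- -rsi(entry_means(pt), arch$specs)          # merit: higher = better
fit <- fit_brr(y, dosage(founders, part$snp), seed = 1)
fit
#> Bayesian ridge regression fit
#>   n = 100  markers = 3500
#>   chain: 2000 iterations, 500 burn-in, thin 5 -> 300 retained draws
```

Given inbred (DH) candidate parents, every pair gets every metric and the
requested method picks the plan:

```r
plan <- select_crosses(dh_parents, fit, part$snp, method = "UC",
                       n_crosses = 5, progeny_per_cross = 300)
plan
#> cross plan ( UC ): 5 crosses selected from 45 candidate pairs, 1500 total progeny
#>   parent_a parent_b rogers_distance mean_gebv      pmv       uc       ohv
#> 1    DH1_2    DH2_1       0.3694286  65.16971 1278.491 147.8845  90.64121
#> 2    DH1_2    DH4_2       0.4014286  62.64836 1370.582 148.2904  88.06560
#> ...
```

`uc` here is the expected index merit of the top fraction of each cross's
progeny: mid-parent GEBV plus intensity times the predicted progeny SD
(√PMV). Whole programs run via `run_burn_in()` / `run_program()`, and
treatment grids (up to the full 60-treatment layout) via `run_grid()` with
the packaged `full-scale` or `desk-small` YAML profiles; `report()` writes
tidy CSVs and per-trait trajectory plots. A thin CLI wrapper lives at
`inst/cli/crossel`.

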