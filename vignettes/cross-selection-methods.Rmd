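---
title: "Multi-trait genomic cross selection in a simulated recurrent-selection program"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-trait genomic cross selection in a simulated recurrent-selection program}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossel)
```

## The problem

A selfing-crop breeding program advances material through a yearly pipeline:
crossing block → F1 → doubled haploids (DH) → nursery → preliminary yield
trial (PYT) → advanced yield trial (AYT), with the best PYT entries recycled
as parents. Two decisions dominate long-run genetic gain: *which genotypes
become parents* and *which parent pairs are actually crossed*. Truncation on
predicted merit gains quickly but erodes genetic variance; cross-selection
metrics that value the *variance a cross will segregate* trade a little
short-term gain for sustained long-term progress. `crossel` simulates this
pipeline stochastically so those trade-offs — and resource-allocation
questions (how many parents, crosses, progeny per cross) — can be studied
quantitatively.

Four pulse-crop traits are modelled by default: grain yield (YLD, improved
upward), thousand-kernel weight (TKW, upward), and days to maturity (DPM)
and plant height (PH), both driven toward optimum targets.

## The index and the derived phenotype

Multi-trait merit is summarised by the rank summation index: within each
trait individuals are ranked (rank 1 = best, respecting that trait's
direction: largest for "increase", smallest for "decrease", closest to
target for "optimum"; ties receive average ranks), and ranks are summed:

$$y_{IS,i} = \sum_{j=1}^{n} g_{ij},$$

where $g_{ij}$ is individual $i$'s rank on trait $j$. Lower sums are better.
The index needs no economic weights and is invariant to any monotone
transform of a trait's scale. Because it aggregates many polygenic traits,
$y_{IS}$ is itself treated as a quantitative trait: it becomes the response
of a whole-genome regression.

One convention matters: `crossel` fits the regression on the *negated* index
(a merit, higher = better). This is a pure sign change, but it lets every
downstream cross metric take its standard orientation — selection keeps the
*largest* GEBVs, the usefulness criterion *adds* its intensity term, and the
optimal haploid value takes segment *maxima*.

## Genomic prediction

The model is Bayesian ridge regression on SNP-chip dosages
($X_{ij} \in \{0,1,2\}$, QTN excluded from the chip):

$$y = \mu + X\beta + \varepsilon, \qquad
  \beta_j \sim N(0, \sigma_\beta^2), \qquad
  \varepsilon_i \sim N(0, \sigma_\varepsilon^2),$$

with scaled inverse-$\chi^2$ priors on both variances (df 5 by default;
scales solved so each prior mode explains half the phenotypic variance, the
convention of common whole-genome regression software). A single-site Gibbs
sampler (in C++) cycles the intercept, each effect, and the two variances;
the retained chain is thinned post burn-in. Experiment mode uses the
40,000 / 10,000 / 10 schedule; the package default (2,000 / 500 / 5) is a
short chain suitable for testing and reduced-scale study. The sampler's
correctness anchor is exact: with the variances held fixed its posterior
mean must converge to the closed-form ridge solution
$(X_c'X_c + \lambda I)^{-1} X_c' y_c$, $\lambda = \sigma_\varepsilon^2 /
\sigma_\beta^2$ — the test suite checks this to < 5% relative $L_2$ error.

GEBVs are $X\hat\beta$ with the intercept deliberately dropped: every
consumer (parent ranking, cross means) uses only differences.

## Cross-selection metrics

For every unordered pair of (inbred) candidate parents:

* **MeanGEBV** — the mid-parent value $\tfrac12(GEBV_A + GEBV_B)$, after a
  Rogers-distance prefilter (below).
* **PMV** — the posterior mean-variance, a prediction of the within-cross
  progeny variance of the index:
  $$PMV = \frac{1}{L}\sum_{l=1}^{L} \beta^{(l)\prime}\, \Sigma\, \beta^{(l)},
    \qquad \Sigma_{jk} = 4\,D_{jk}\,(1 - 2 c_{jk}),$$
  averaging over the $L$ retained posterior draws rather than plugging in a
  point estimate. $D_{jk}$ is the parental linkage-phase parameter (0 when
  either locus is monomorphic between the parents, otherwise $\pm 0.25$ by
  coupling/repulsion) and $c_{jk}$ the Haldane recombination fraction
  $c = \tfrac12(1 - e^{-2d})$ for map distance $d$ Morgans (0.5 across
  chromosomes, so $\Sigma$ is block diagonal).
* **UC** — the usefulness criterion $\mu + i\,\sqrt{PMV}$: the expected mean
  of the selected fraction $p$ of the cross's progeny, with
  $i = \phi(\Phi^{-1}(1-p))/p$. The progeny SD comes from the PMV; the
  selected proportion defaults to the pipeline's own advance rate
  (PYT capacity / DH budget, 400/15,000 at full scale).
* **OHV** — the optimal haploid value
  $2\sum_{s} \max(H^s \beta^s)$: per map segment, the best parental
  haplotype score, doubled — the value of the ideal DH recoverable from the
  cross. Segments default to 3 equal map-length pieces per chromosome; the
  segment count is deliberately not fine-tuned.
* **RandPheno** — the baseline: the same RSI-selected superior parents,
  paired at random.

Scoring is vectorised over all pairs: because
$\frac{1}{L}\sum_l \beta^{(l)\prime}\Sigma\beta^{(l)} =
\sum_{jk}\Sigma_{jk} M_{jk}$ with $M = \frac{1}{L}\sum_l
\beta^{(l)}\beta^{(l)\prime}$, the posterior second-moment blocks are formed
once per fit and each pair costs one quadratic form in its allele-difference
vector. The batched path is tested to agree with the per-cross definition to
numerical precision, and the PMV itself is validated against an independent
Monte-Carlo oracle: simulating 20,000 DH progeny through the meiosis engine
and taking the empirical GEBV variance agrees within 2%.

### The distance prefilter

The MeanGEBV method first filters pairs by Rogers' distance. The published
rule keeps pairs with distance *less than* 0.1; taken literally this crosses
near-identical parents, which sits oddly with the stated aim of limiting
coancestry. `crossel` implements the filter with a configurable direction
and follows the literal rule by default (`"lt"`), flagging `"gt"` as the
likely intent; when the filter leaves fewer pairs than crosses requested it
falls back to unfiltered ranking with a warning.

## The simulated genome and traits

Seven chromosomes of 1 Morgan each carry 600 evenly spaced sites: 500 QTN
(71 or 72 per chromosome) and a disjoint 3,500-SNP chip. (The source
material's "2,100 segregating sites" is arithmetically inconsistent with
500 + 3,500 disjoint sites; 600 sites/chromosome is the smallest round
figure accommodating both sets.) Chromosome lengths default to 1 Morgan
because the reference pea map is not reprinted; both are configurable.

Founders (200 non-inbred individuals) are built without an external
coalescent: K = 20 ancestral haplotypes receive i.i.d. Bernoulli(0.5)
alleles, and founders are recombinant mosaics produced by G = 50 random-
mating drift generations through the meiosis engine. Sites that fix are
repaired by redrawing the ancestral allele column (and, where every lineage
has coalesced to one ancestor, by grafting the ancestor-index column of the
nearest segregating site, which preserves the local mosaic). The emulated
features are: every site segregating, allele-frequency spread, and LD that
decays with map distance (tested: median pairwise $r^2$ is non-increasing
over distance bins). Not emulated: sequence-level mutation, demographic
history, selfing-specific long-range LD structure — so full-scale results
should be read as properties of *an* LD-structured founder pool, not of pea
specifically.

QTN effects are multivariate Gaussian across traits with a configurable
genetic correlation matrix, then calibrated: an affine per-trait rescaling
makes founder genetic means and variances hit their targets *exactly*
(YLD 5.78/3.59, TKW 433.0/50.10, DPM 81.0/12.24, PH 67.0/15.80). Because
the supplementary heritability/correlation table is not reprinted, defaults
are plausible values (plot-level h²: YLD 0.3, TKW 0.6, DPM 0.7, PH 0.5;
correlations |r| ≤ 0.3) and every configuration knob is exposed; checks that
depend on them are approximate by design. Dominance and epistasis are
omitted, as in the source design.

Phenotypes add a location effect (i.i.d. Gaussian per location × year,
variance a configurable fraction of the current genetic variance — a
non-heritable G×E-like term) and a plot residual with variance
$\sigma_g^2 (1 - h^2)/h^2$. Nursery evaluation uses h² = 0.1 (visual
selection); PYT uses 2 replicates × 2 locations; AYT 3 × 6 × 2 years.
Selection acts on entry means; AYT is terminal (variety evaluation only).

## The yearly cycle and its budgets

Each post-burn-in year: (1) the best `n_parents` PYT entries by RSI enter
the crossing block; (2) the regression is refit on the current PYT cohort
(training does not accumulate across cycles by default); (3) the treatment's
metric picks `n_crosses` pairs; (4) each cross contributes
`progeny_per_cross` DH lines (15,000 total at full scale; one F1 per cross
suffices once parents are inbred, since all F1s of an inbred pair are
identical); (5) nursery phenotypes at h² = 0.1, an optional 4,000-entry
pre-screen, and the top 400 advance; (6) PYT evaluation; (7) the top 40
enter the AYT; (8) per-trait genetic mean, variance and gains are logged
from the DH cohort's true genetic values. Burn-in (10 years at full scale)
runs the same pipeline under phenotypic RSI selection with random mating,
and its final state is shared by all treatments of a replicate, so methods
diverge only after year 0. Gains are reported both raw and in baseline-SD
units because the published gain scale is ambiguous.

## Reduced-scale study conditions

Full-scale results (50 replicates × 60 treatments × 40 years) are a cluster
workload. The packaged `desk-small` profile keeps the **full genome and
chip** and shrinks only the pipeline: 100 founders, 10 parents, 15 crosses
× 40 DH, PYT 60, AYT 10, 3 burn-in years, 8 logged years, MCMC
2,000/500/5. Stage capacities keep the full-scale ratios (PYT ≈ 1/10 of the
DH cohort; AYT ≈ 1/6 of the PYT). At this scale the package's directional
check compares PMV against RandPheno over 10 paired replicates on the
*index's genetic variance* — each component trait's final-year genetic
variance in year-0 units, summed over traits (the RSI itself is degenerate
as a cohort statistic: its mean is a constant of cohort size). What passing
shows: variance-aware cross selection retains more of the variance the
index selects on than random pairing of the same parents, without a
meaningful gain penalty on the headline trait. What it does not show:
magnitudes at full scale, method orderings among UC/PMV/OHV (too close at
this replication), or anything about real pea data.

## Numerical choices

* Haldane's map function is used as printed up to an evident sign typo
  (the published exponent $e^{+2d}$ gives negative fractions); no crossover
  interference, consistent with Haldane.
* Ties in ranks: average; ties in selection: broken by id in C-locale
  (radix) order, so runs are bit-reproducible across session locales.
* The Gibbs sampler centres marker columns (decoupling intercept and
  effects); monomorphic markers draw from their prior.
* PMV's batched quadratic forms can go microscopically negative through
  floating-point cancellation; they are clamped at zero.
* Random streams: every run seeds R's RNG from a pure function of
  (master seed, treatment index, replicate index); treatment index 0 is the
  replicate's shared burn-in stream. Results are independent of execution
  order.

## Limitations

Single-trait alternatives (Smith–Hazel weights, multi-trait covariance
machinery) are out of scope by design; the index is the point. The progeny
covariance assumes fully inbred parents (DH pipeline), one meiosis, and no
mutation. The optimum targets for PH (50 cm) and DPM (79 d) are defaults,
not published values. Treatment grids run sequentially in-process;
process-level parallelism can be layered on top because streams are pure.
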