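# pgnet — phenotype–genotype association network analysis

`pgnet` is an R package for building and characterizing bipartite
**phenotype–genotype networks**: graphs that link clinical disease subtypes
(phenotypes) to the molecular entities reported in association with them —
here non-coding RNAs (miRNA, lncRNA, circRNA) curated for cardiovascular
disease, but any curated disease–entity table with the same shape works. It
is aimed at systems-biology practitioners who want the full analysis chain
— network construction, scale-free topology testing, hub/leaf class
contrasts, sponge (ceRNA) network assembly, gene-set over-representation
and tissue-expression clustering — as plain, scriptable R functions with no
web services behind them.

## The models at the core

**Scale-free topology.** The genotype-side degree distribution is modelled
as a discrete power law (zeta distribution)

    P(k) = k^-γ / ζ(γ, x_min),   k = x_min, x_min+1, ...

with ζ the Hurwitz zeta function. `fit_power_law()` estimates γ by maximum
likelihood (bracketed search on the zeta log-likelihood), summarizes tail
fit by the Kolmogorov–Smirnov distance, optionally scans `x_min` to
minimize it, bootstraps a confidence interval (`bootstrap_ci()`), and runs
the standard semi-parametric KS surrogate test (`goodness_of_fit()`).
Scale-free association networks typically show 2 < γ < 3.

**Universal vs specific entities.** ncRNAs associated with ≥ 2 diseases
(degree ≥ 2) are *universal*; those with exactly one are *specific*.
`class_contrast()` compares the classes on biomarker annotation rates
(Fisher exact — matched against exhaustive hypergeometric enumeration in
the tests — plus chi-square and a label-permutation test), validated-target
coverage, and essential-gene ratios.

**Ternary sponge networks.** `build_ternary()` assembles
lncRNA/circRNA–miRNA–mRNA networks from curated triple tables (a published
17-row table ships as `pgnet_example("ternary_table.tsv")`), and
`ora()` / `cluster_expression()` cover the downstream gene-set
over-representation (hypergeometric upper tail, BH/Bonferroni) and
tissue-expression clustering (z-scored rows, correlation distance, average
linkage) analyses.

**Synthetic data.** `generate_study_data(synthetic_config(seed = ...))`
draws a complete synthetic study — associations, targets, essential genes,
GMT sets, expression — with the statistical structure these analyses
assume, plus a `truth` record of every latent parameter, so the entire
pipeline is testable offline and parameter recovery is measurable.

## Worked example

```r
library(pgnet)

sim <- generate_study_data(synthetic_config(seed = 1))
net <- build_bipartite(sim$associations, "miRNA")
net
#> Bipartite phenotype-genotype network: 23 phenotypes, 426 ncRNAs, 702 edges

fit <- bootstrap_ci(fit_power_law(degree_distribution(net, "genotype")),
                    n_boot = 500, seed = 1)
fit
#> Discrete power-law fit (mle): gamma = 2.558 (xmin = 1, n_tail = 426)
#>   KS = 0.0070, 95% bootstrap CI [2.416, 2.739]

class_contrast(net, sim$targets, sim$essential, n_perm = 999, seed = 1)
#> Universal vs specific miRNA contrast
#>   n = 103 universal, 323 specific
#>   biomarker rate: 86.4% vs 57.6%
#>   Fisher p = 3.21e-08, chi-square p = 1.92e-07, permutation p = 0.001, OR = 4.68
#>   targets: universal 7660 genes / 14545 interactions; specific 7738 / 14652
#>   essential-gene ratio: universal 55.2%, specific 55.2%

build_ternary(read_ternary_table())
#> Ternary sponge network: 14 lncRNA-miRNA and 3 circRNA-miRNA pairs, 34 edges
```

The generator planted γ = 2.5 degrees, biomarker rates of 0.903 (universal)
and 0.594 (specific) and a 55% essential-gene fraction; the fitted exponent,
the class rates (86.4%/57.6% is one seed's realization; rates concentrate on
the planted values across seeds) and the essential ratios recover them, and
the class difference is strongly significant under all three tests.
`run_pipeline()` chains all of the above (plus exports, over-representation
and clustering) from a single config and writes a reproducible bundle.

## Package layout

- `R/` — I/O and validation (`read_associations()`, `read_gmt()`, …),
  network construction/export, power-law fitting, class statistics,
  over-representation, clustering, synthetic data, pipeline.
- `inst/extdata/` — the published ternary table and a small synthetic
  tissue-expression fixture.
- `vignettes/phenotype-genotype-networks.Rmd` — the methods vignette:
  models, conventions, parameter defaults and limitations.
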