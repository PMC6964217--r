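---
title: "Methods: phenotype-genotype network construction and characterization"
author: "pgnet authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phenotype-genotype network construction and characterization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgnet)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the conventions adopted where curated
association data leave choices open, the parameters that matter and their
defaults, and the limits of what the synthetic-data tests demonstrate.

## 1. The phenotype-genotype network

The primary object is a bipartite graph linking clinical disease subtypes
(phenotypes) to the non-coding RNAs reported in association with them
(genotypes). `read_associations()` validates a curated association table
against a controlled disease vocabulary (`disease_catalog()`), unifies
miRNA names by rule (`normalize_mirna_name()`: strip the `hsa-` species
prefix, canonicalize the family token to `miR`/`let`, lower-case the rest;
the rules are idempotent and need no registry lookup), and collapses
duplicate (ncRNA, disease) reports. Two conventions are worth stating:

* **Biomarker flag on deduplication: logical OR.** An ncRNA counts as a
  biomarker if any supporting report concluded it to be a candidate or
  potential marker; one article suffices.
* **Conflicting expression directions collapse to `"mixed"`.** Curated
  literature does not resolve conflicting up/down reports; `mixed` records
  the conflict instead of silently preferring one side.

The shipped 23-label cardiovascular catalog is a *reconstruction*: curated
CVD resources cover 23 subtypes in the ICD-10 I05-I79 range plus a
generalized "Others" category, and the catalog applies the two standard
acuity merges (acute/chronic heart failure into heart failure; acute
myocardial infarction into myocardial infarction). Labels outside the
catalog fail loudly rather than being fuzzy-matched — wrong-but-plausible
merges are worse than an error naming the offending label. "Others"
participates as an ordinary phenotype node by default; `build_bipartite()`
takes `drop_others = TRUE` because whether published network figures
included such catch-all categories is generally not recoverable.

Degree on the genotype side counts **distinct diseases**, never supporting
articles, so a heavily re-reported single association still has degree 1.
Isolated nodes cannot occur (every node enters through an association).

## 2. Scale-free topology: the discrete power law

Degree distributions of association networks are heavy-tailed: a few hub
ncRNAs connect to a dozen diseases while most connect to one. The model is
the zeta (discrete power-law) distribution

$$P(k) = \frac{k^{-\gamma}}{\zeta(\gamma, x_{\min})}, \qquad k \ge x_{\min},$$

with $\zeta(\gamma, a)$ the Hurwitz zeta function, implemented in-package
by Euler-Maclaurin summation (25 direct terms plus integral and
Bernoulli-correction tail; absolute error far below the $10^{-12}$ the
tests require; cross-checked against an independent Riemann-zeta
implementation at $a = 1$).

**Estimation.** `fit_power_law()` maximizes the tail log-likelihood
$-\gamma \sum_i \log k_i - n \log \zeta(\gamma, x_{\min})$ by bracketed
scalar search on $\gamma \in (1.01, 10)$ (tolerance $10^{-8}$); a
grid-search oracle agrees to $10^{-3}$ in the tests. The default
$x_{\min} = 1$ fits the full distribution, which is the natural choice for
disease-association degrees that start at $k = 1$; `xmin = "scan"` instead
chooses the cutoff minimizing the Kolmogorov-Smirnov distance between the
empirical and fitted tail CDFs (ties break to the smallest cutoff, the
choice that keeps the most data). Published exponents for such networks
were obtained with unstated fitting procedures — often least squares on
$\log P(k)$ vs $\log k$ — so a `method = "loglog_ls"` fallback is provided
for comparison; it is exact on an exactly linear log-log pmf but is known
to be biased on sampled tails, and the MLE is the estimator of record.

**Guards.** All-equal degrees ("no tail variation"), fewer than 3 tail
observations, and networks whose maximum degree is below 3 (the pipeline's
small-tail guard — real lncRNA-disease networks can have max $k \approx 5$,
and an exponent fit to such a stub is numerology) refuse to fit.

**Uncertainty and fit quality.** `bootstrap_ci()` resamples the tail
nonparametrically (default 1000 replicates, 2.5/97.5 percentiles;
`n_boot = 0` returns a flagged degenerate interval). `goodness_of_fit()`
is the standard semi-parametric KS surrogate test: draw surrogates from
the fitted law at the same tail size via the package's exact inverse-CDF
sampler `rpower_law()` (tabulated CDF to $10^5$, zeta-CDF bisection
beyond, so the sampler is exact at all $k$), refit each, and report the
fraction of surrogate KS distances at or above the observed one. Refits
hold $x_{\min}$ at the fitted value — cheaper than re-scanning, and
calibration under the null is verified directly in the tests.

## 3. Universal vs specific classes and their contrasts

ncRNAs split at degree 2: *universal* ($k \ge 2$) vs *specific*
($k = 1$). `class_contrast()` reports three p-values for the biomarker
contrast side by side — Fisher exact, continuity-corrected chi-square, and
a label-permutation test — because published class contrasts of this kind
rarely name their test; reporting all three makes the choice auditable
rather than implicit. Conventions:

* Fisher's two-sided p sums hypergeometric point probabilities no larger
  than the observed one, with the conventional $1 + 10^{-7}$ relative tie
  slack. The implementation (base `dhyper`) is checked against exhaustive
  lgamma-based enumeration on *every* 2x2 table with total $\le 60$.
* The odds ratio is the sample estimate $ad/bc$ with the Haldane-Anscombe
  0.5 correction when any cell is zero — a descriptive companion to the
  exact p, not a conditional MLE.
* The permutation p is $(1 + \#\{|\Delta^*| \ge |\Delta|\})/(n_{perm}+1)$
  for the absolute rate difference, guaranteeing validity at any
  $n_{perm}$ (default 9999, seed 1234).

Target coverage counts distinct genes and (miRNA, gene) pairs per class
from a validated-interaction table; genes match by exact upper-cased
symbol, with no alias resolution — a documented limitation relative to
curated essential-gene mappings. `essential_ratio()` is plain set
arithmetic, $|G \cap E| / |G|$.

## 4. Ternary sponge networks

Sponge (ceRNA) tables list lncRNA/circRNA-miRNA-mRNA triples in two
sections keyed by sponge class. `read_ternary_table()` yields one triple
per printed row, keeping multi-gene mRNA cells (e.g. `BCL2/HSP60`) verbatim
and `NA` as the no-reported-target sentinel; `build_ternary()` then emits
one sponge-miRNA edge per triple and one miRNA-mRNA edge per
slash-separated gene. Splitting at network-build rather than read keeps the
row count of the printed table (17 in the packaged fixture: 14 lncRNA and
3 circRNA pairs) as the triple count while still typing every gene its own
node — and makes the edge-count identity
(edges = triples + per-split mRNA links) hold exactly.

The packaged expression fixture carries the 16 distinct miRNAs of the
ternary table. Published cluster analyses of this kind cite 13 clustered
miRNAs, a roster that cannot be reconstructed from the printed table; the
fixture therefore ships all 16 and the discrepancy is noted here rather
than resolved by guesswork. The fixture's values are synthetic (seeded,
two planted expression programs), as its name and header state.

## 5. Over-representation analysis

`ora()` is the statistical skeleton shared by pathway/GO tools: for each
gene set, the hypergeometric upper-tail probability of the observed
overlap between query and set within a universe. Conventions: the universe
defaults to the union of all collection members (commercial tools'
universes are proprietary; an explicit `universe` argument overrides);
query genes outside the universe are dropped with a warning; `ratio` is
overlap/set-size, our reading of the "ratio of enriched genes" column in
published pathway tables, which never define it. `adjust_pvalues()`
delegates to `stats::p.adjust` — "FDR" and "BH" name the same shipped
procedure — and `overlap_report()` counts sets enriched at `alpha`
(default 0.01, the conventional collection threshold) in two result lists
and their name-matched intersection. No GO-graph propagation, term
clustering, or proprietary pathway definitions are attempted.

## 6. Tissue-expression clustering

`cluster_expression()` z-scores each row (so profiles are compared by
shape, not magnitude) and clusters rows and columns hierarchically.
Defaults — 1 − Pearson correlation distance, average linkage, `k_rows = 2`
— reflect the common finding of two tissue-expression programs in such
panels; published figures of this kind rarely state their method, so both
distance (`euclidean`) and linkage (`complete`) are configurable and the
defaults are just that. Constant rows, whose z-score is undefined, are
excluded from the dendrogram, flagged, and assigned to the nearest
centroid afterwards. Average-linkage merge heights are checked
nondecreasing (no inversions), and label invariance under row/column
permutation is a tested property.

## 7. The synthetic-data generator

`generate_study_data()` draws a complete synthetic study. Its defaults
*are* the study conditions the rest of the package is tested under:

| parameter | default | rationale |
|---|---|---|
| `n_diseases` | 23 | size of the curated CVD phenotype vocabulary |
| `n_mirna` / `n_lncrna` / `n_circrna` | 426 / 99 / 24 | entry counts of a curated CVD-ncRNA database |
| `gamma_target` | 2.5 | mid-band scale-free exponent (2 < γ < 3) |
| `biomarker_rate_universal` / `_specific` | 0.903 / 0.594 | reported class-conditional biomarker rates |
| `mean_targets_universal` / `_specific` | 142 / 46 | reported interactions-per-miRNA (24937/175, 11444/251) |
| `essential_frac` | 0.55 | reported essential-gene overlap (~54-58%) |
| `gene_pool_size` | 10000 | order of a validated-target gene universe |
| `n_expr_mirna` x `n_tissues` | 16 x 9 | ternary-table miRNAs x common tissue panel |
| `cluster_sep`, `expr_noise_sd` | 1, 0.1 | clearly separated two-block structure |

Degrees are i.i.d. from the power law renormalized on $1..23$ — identical
in law to redrawing unbounded zeta samples until they fit, but exact and
cheap; the truncation is noted in the `truth` record. Disease popularity
is uniform: real catalogs are skewed (heart failure dominates miRNA
counts), but skew does not affect any statistic the pipeline estimates
from the genotype side, so the simpler model is the default. Biomarker
flags condition on the *realized* degree class — the generator encodes the
observed association between class and biomarker status, not a causal
mechanism. Targets, essential flags and GMT sets are independent draws, so
essential ratios concentrate on `essential_frac` for both classes and
over-representation is null unless a test plants an effect.

What passing tests therefore show: the estimators recover the parameters
of data generated under the model's own assumptions (exponent to within
0.1 at $n = 2000$; class rates to within 0.05 over replicate studies;
exact two-block recovery at tenfold signal-to-noise). What they do not
show: robustness to curation biases — disease-label skew, correlated
re-reporting, name synonymy, target-database redundancy — none of which
the generator emulates.

`published_count_fixture()` is a separate, internally seeded, fully
deterministic association table whose partition is exactly 175 universal
and 251 specific miRNAs (426 total), for tests and demonstrations that
need those published class sizes as fixed inputs.

## 8. Numerical and reproducibility choices

* Hurwitz zeta: Euler-Maclaurin with 25 direct terms and three correction
  terms; exponent search on $(1.01, 10)$, `optimize` tolerance $10^{-8}$.
* Exact sampler: CDF table to $10^5$ per (γ, $x_{\min}$), cached per
  session; bisection on the zeta CDF for the (rare) draws beyond it.
* Fisher/ORA tails: base `dhyper`/`phyper`; tie handling as in §3.
* All stochastic routines take explicit integer seeds (default 1234);
  `run_pipeline()` derives stage seeds from one root seed by fixed
  offsets, making a whole bundle a pure function of its config. The
  pipeline writes a manifest recording package version, seed and config.
* Test problem sizes (e.g. 200 seeds at $n = 2000$ for exponent recovery,
  50-100 replicate studies for rate recovery, full Fisher sweep to total
  60) were chosen as the smallest sizes at which the Monte-Carlo noise is
  comfortably below the tolerances being asserted.

## 9. Known limitations

* The exponent of a 23-phenotype network with a few hundred nodes is an
  estimate with wide uncertainty; the bootstrap interval, not the point
  estimate, is the honest summary at curated-database scale.
* Exponents published for real CVD-ncRNA networks (near 2.1 for miRNA,
  2.7 for lncRNA) were produced by unstated procedures on data that are
  not redistributable; this package does not claim to reproduce those
  numbers, only to provide estimators whose behavior is verified on data
  of known structure.
* Similarly, a published class-contrast p-value of 0.005332 is not
  reproducible from the published class sizes and rates (an exact test on
  the implied 2x2 table is orders of magnitude smaller); the package
  reports its own three tests and documents the discrepancy.
* Gene matching is by exact upper-cased symbol; no synonym resolution.
* The ORA universe default (union of collection members) understates the
  true assay universe when collections are small; supply `universe`
  explicitly for calibrated absolute p-values.
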