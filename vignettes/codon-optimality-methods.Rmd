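---
title: "Methods: codon optimality and mRNA kinetics association analysis"
author: "codonStability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: codon optimality and mRNA kinetics association analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonStability)
```

## The model

The package quantifies a population-level association: genes whose
coding sequences are enriched in *optimal* codons — codons decoded by
abundant tRNAs — tend to have longer mRNA half-lives and higher
synthesis rates. Three layers of machinery express this.

**Codon-level correlation vectors.** For sense codon $c$ and gene $g$,
let $x_{gc}$ be the frequency of $c$ among the gene's sense codons. The
CSC (codon occurrence to mRNA stability correlation coefficient) is the
Spearman correlation of $x_{\cdot c}$ with per-gene half-lives across
genes; the CPC replaces half-lives with synthesis rates (RNA polymerase
II occupancy is an accepted proxy when direct rates are unavailable).
Rank correlation is used because genome-wide kinetic measurements carry
heavy-tailed outliers; every statistic downstream is therefore
invariant to monotone rescalings of the kinetic data — an important
property given that absolute half-life scales differ several-fold
between laboratories while rank agreement is good.

**The sign-partition test.** The 61 sense codons are split on the sign
of the CSC/CPC (exactly zero, a measure-zero event, deterministically
joins the non-positive group) and cross-classified against a binary
optimality classification. Association is tested with a chi-square test
on the 2×2 table, 1 degree of freedom, Yates-corrected by default. The
summary is reported in the conventional layout: *Total* (number of
positive codons), *Observed* (optimal codons among them), and
*Expected* $= n_{\mathrm{opt}} \cdot \mathrm{Total}/61$. Codons with
undefined CSC (constant frequency across genes) are dropped and the
codon total adjusted.

**tAI weights.** The tRNA adaptation index assigns each codon an
absolute weight $W_c = \sum_j (1 - s_{\mathrm{class}(c,j)}) \,
\mathrm{tGCN}_j$ over the anticodons $j$ able to decode it: the
Watson–Crick anticodon plus one wobble decoder determined by the
codon's third base (G:U for codons ending in U, I:C and I:A for the
inosine-modified A34 anticodon, U:G for codons ending in G), with ATG
decoded only by its cognate anticodon and ATA special-cased by domain
(inosine in eukaryotes, the lysidine-modified CAT anticodon in
bacteria). Default penalties are the published constants of the
standard construction ($s_{G:U} = 0.41$, $s_{I:C} = 0.28$,
$s_{I:A} = 0.9999$, $s_{U:G} = 0.68$, $s_{L:A} = 0.89$); all are
overridable, and published weight tables can be loaded directly, which
is the preferred path when one exists. Weights are normalized to
maximum 1; codons with no decoding tRNA receive the geometric mean of
the nonzero weights. The gene-level score is the geometric mean with
multiplicity, $\mathrm{tAI}_g = \exp\!\big(\sum_c n_{gc}\log w_c /
\sum_c n_{gc}\big)$.

**Steady-state kinetics.** Under balanced synthesis and loss,
$\mu = m(\alpha + \lambda)$ with $\lambda = \ln 2 / hl$ and growth
dilution $\alpha = \ln 2 / \mathrm{ccl}$; units are minutes, molecules
per cell, and molecules per minute per cell. "log2" in the half-life
identity is the *natural logarithm of 2* — the only reading for which
$\lambda \cdot hl = \ln 2$ is dimensionally consistent. Datasets that
measured only a subset of (half-life, synthesis rate, abundance) are
completed through these identities; relative abundances are rescaled to
a per-cell total (60,000 molecules for budding yeast, 41,000 for
fission yeast in the bundled profiles). Transcription-shutoff datasets
use $\alpha = 0$ (growth is halted); the policy is stored per dataset,
never inferred. Missing inputs propagate to missing outputs — nothing
is imputed, matching the drop-don't-impute convention of the underlying
studies.

## Key analytical choices

**Stop codons and frames.** Frequency vectors cover the 61 sense codons
only; stop triplets — which arise at CDS ends and throughout
frameshifted readings — are counted but excluded, and the frequency
denominator is the number of sense triplets. This keeps frame-0 and
frameshift-control analyses on a common 61-codon support. The start
codon is counted like any other sense codon. Whether the frequency
denominator includes the terminal stop changes each gene's denominator
by at most one codon; the sense-only convention is used throughout and
documented here rather than resolved, since rank-based statistics are
essentially unaffected.

**Continuity correction.** Only "chi-square tests" is specified by
convention; this package defaults to the Yates-corrected 2×2 statistic
because that choice exactly reproduces the published p-values of the
reference contingency tables (e.g. cells (22, 4, 6, 29) give
p = 6.7e-07 corrected versus 1.7e-07 uncorrected). The uncorrected
statistic is available via `correct = FALSE`.

**Spearman p-values.** Both plain and partial rank correlations use
average ranks and the t approximation throughout (n − 2 and n − 3
degrees of freedom respectively), rather than switching to an exact
small-sample null for untied data. This keeps p-values comparable
across tied and untied datasets and matches the behaviour of standard
statistical environments on tied data. The first-order partial
correlation is computed from the rank-correlation triple,
$r_{xy\cdot z} = (r_{xy} - r_{xz} r_{yz}) / \sqrt{(1 - r_{xz}^2)(1 -
r_{yz}^2)}$, equivalent to correlating rank-regression residuals.

**Motif tests.** Motif instance tables are inputs (motif discovery is
out of scope). Sequence variants of the same element are pooled by
summing per-gene instance counts before testing; a gene "contains" a
motif when its significant-instance count is ≥ 1. Scores of
motif-bearing versus motif-lacking genes within an explicit background
set (genes with both half-life and synthesis-rate estimates) are
compared by one-sided Wilcoxon rank-sum tests (normal approximation,
tie and continuity corrections). The Bonferroni family size defaults to
the number of motif × direction tests per score metric and is
configurable, because the family is a reporting convention that cannot
be derived from the data.

**Cross-dataset comparison.** Pairwise Spearman matrices use
pairwise-complete genes (coverage differs per dataset). Hierarchical
clustering operates on Euclidean distances between correlation-matrix
rows — the displayed object — with complete linkage by default;
quartiles use linear interpolation (type 7). Both are configurable.

**nTE weights.** Published binary cTE/nTE classifications are the
primary interface for the association tests. `computeNte()` is a
clearly labelled convenience reconstruction: codon demand is the
abundance-weighted codon usage over genes (raw counts by default, a
within-gene-frequency variant is selectable, since the published
construction's exact normalization is not recoverable), scaled to
maximum 1, and the nTE weight is the tAI weight divided by demand,
renormalized.

## The synthetic-data generator

`simulateStudy()` generates the study conditions every test runs under.
Each gene receives a latent optimality score $u_g \sim U(0,1)$. Codons
are sampled with an exponential tilt *within synonymous families*,
$p_c \propto \exp(\beta_{\mathrm{tilt}} u_g w_c)$, with family
probabilities proportional to family size and shared by all genes — so
the coupling acts purely through synonymous codon choice, the quantity
the CSC logic isolates, and amino-acid composition is homogeneous by
construction. Kinetics follow the steady-state model generatively:
log half-life and log synthesis rate are linear in $u_g$ with
independent Gaussian noise, and abundance is derived exactly as
$m = \mu/(\alpha + \lambda)$ (log-normal noise because half-lives are
positive and right-skewed in every published dataset). An alternative
*abundance-mediated* regime routes the coupling through abundance
($u_g$ drives $\log m$; half-life tracks $\log m$ plus noise) so that
the pairwise optimality–half-life association exists but the partial
correlation given abundance collapses — the contrast that motivates the
partial-correlation analyses. Stabilizing motifs are assigned with
presence probability increasing in $u_g$ on the logit scale;
destabilizing 3'-UTR motifs are independent of it, mirroring the
typical null result for destabilizing elements.

Defaults, chosen once as a compact yeast-like study: 500 genes of
100–500 codons (runtime-scaled from genomic size while keeping per-gene
codon counts realistic), median half-life 20 min, synthesis ~0.1
molecules min⁻¹ cell⁻¹, noise SD 0.5 on the log scale (several-fold
spread, as observed between replicate datasets), tilt 2 and half-life
coupling 1.5 (a clear but not overwhelming association: CSC–weight
ρ ≈ 0.7–0.85 at 500 genes), 28 of 61 codons optimal (a fission-yeast-
like split). What the generator does *not* emulate: real codon-usage
phylogenetic structure, amino-acid composition variation between genes,
measurement-protocol biases (e.g. poly(A)-selection skew), or
correlated noise between half-life and synthesis estimates. Passing
tests therefore demonstrate correctness of the statistical machinery
and recoverability of a planted signal — not biological conclusions
about real genomes.

## Numerical and degenerate-input conventions

- Sequences failing validation (non-ACGT characters, shorter than one
  codon) are dropped with a warning in lenient mode and are errors in
  strict mode; strict mode additionally requires length divisible by 3
  and no internal frame-0 stop. Internal stops in lenient mode warn but
  retain the sequence, since dubious ORFs are handled by upstream gene
  filters.
- A codon with constant frequency across genes has no defined rank
  correlation: its CSC/CPC is `NA`, it is dropped from the sign
  partition, and the contingency total is adjusted and reported.
- Zero marginals (all codons one sign, or a single optimality class)
  make the chi-square test undefined and raise an error rather than
  returning a degenerate statistic.
- `halfLifeFrom()` returns `NA` with a warning when $\mu/m \le \alpha$,
  which is non-physical under steady state.
- Ties: average ranks everywhere; the hierarchical clustering
  tie-break is the deterministic input-order behaviour of `hclust()`.
- The null calibration of the sign-partition test deserves a note: the
  Yates-corrected p-value of a discrete 2×2 statistic is conservative
  by construction and can never be exactly uniform under the null; its
  *rejection tail* is calibrated (empirical size ≤ nominal at 0.01 and
  0.05 in the package's null simulations), while uniformity itself is
  a property of the uncorrected statistic. The test suite checks both,
  each against the regime in which it is meaningful. Decoupling the
  generator for these null checks means switching the codon-usage tilt
  off: with the tilt on, the 61 codon frequencies co-vary along the
  latent score even when kinetics are decoupled, the CSC values are
  then mutually dependent, and the chi-square (whose implicit unit of
  information is one codon) is anti-conservative — an instructive
  caveat that applies equally to real genomes, where codon usage
  co-varies with expression demand.

## Multiple testing

Chi-square p-values of the contingency analyses are reported raw, as is
conventional for these summary tables; Bonferroni correction is applied
only within the motif-test family, where it is part of the published
reporting convention.

## Problem sizes used by the test suite

Module tests run on toy inputs and genomes of 12–500 genes; the
acceptance suite uses 100 replicate studies of 500 genes for power
recovery, 200 replicates for null calibration, 1000+ random instances
per statistic for oracle equivalence, and 10⁵ records for the
steady-state round trip. These sizes give the calibration checks
stable, reproducible outcomes under their fixed seeds while completing
in minutes on a single CPU.

## Known limitations

- The package tests association, not causation; frameshift controls
  exclude nucleotide-composition confounding but not every shared
  selective pressure.
- Reproduction of the dataset-level published statistics (Total /
  Observed per kinetic dataset) requires the original external kinetic
  tables; the package ships only their printed contingency marginals,
  which fully determine the 2×2 tests but not the underlying CSC
  vectors.
- Labeling-kinetics model fitting (estimating half-lives from raw
  time-course data) is out of scope; inputs are per-gene kinetic
  tables.
- `relativeAdaptiveness()` covers the standard genetic code; organisms
  with non-standard codes or heavily edited tRNA pools need externally
  supplied weights.
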