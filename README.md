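# codonStability

Genome-wide association between codon optimality and mRNA kinetics in
yeasts, as a tested, reusable R package.

## The scientific problem

Synonymous codons are not used interchangeably: codons decoded by
abundant tRNAs ("optimal" codons) are translated faster, and in budding
and fission yeast genes enriched in optimal codons tend to produce more
stable, more highly synthesized mRNAs. Quantifying that association
from heterogeneous genome-wide kinetic datasets requires a small but
specific statistical toolkit, which this package implements:

- **CSC / CPC** — for each of the 61 sense codons, the Spearman
  correlation across genes between the codon's frequency within each
  coding sequence, `x_gc`, and the gene's mRNA half-life (codon
  occurrence to mRNA **stability** correlation coefficient, CSC) or
  synthesis rate (codon occurrence to mRNA **production** correlation
  coefficient, CPC). Codons enriched in stable (highly transcribed)
  mRNAs get positive values.
- **Sign-partition chi-square test** — codons are split on the sign of
  the CSC/CPC and cross-classified against a binary optimality
  classification (cTE or nTE); the 2×2 table is tested with a
  Yates-corrected chi-square (1 df). The summary mirrors the
  conventional table layout: Total (positive codons), Observed (optimal
  ∩ positive), Expected = `n_opt · Total / 61`.
- **tAI machinery** — per-codon relative adaptiveness weights `w_c`
  from tRNA gene copy numbers with wobble-pairing penalties
  (`W_c = Σ_j (1 − s_class) · tGCN_j`, normalized to max 1, geometric
  mean replacement for undecoded codons), the gene-level geometric mean
  `tAI_g = exp(Σ_c n_gc log w_c / Σ_c n_gc)`, percent-optimal-codon
  content, and a demand-normalized (nTE-style) variant.
- **Steady-state kinetics** — `λ = ln2 / hl`, `μ = m(α + λ)`,
  `α = ln2 / ccl`, with exact inversion `hl = ln2 / (μ/m − α)`, used to
  harmonize datasets that measured different subsets of (half-life,
  synthesis rate, abundance).
- **Partial Spearman correlations** controlling for mRNA abundance,
  **frameshift controls** (+1/+2 computational frameshifts must destroy
  a genuine codon-identity signal), **motif–optimality Wilcoxon tests**
  with Bonferroni correction, and cross-dataset comparison utilities
  (pairwise Spearman matrices, hierarchical clustering).
- A fully seeded **synthetic-data generator** that produces genomes and
  steady-state-consistent kinetic tables with tunable
  optimality–expression coupling, so every stage is testable without
  external downloads.

## Worked example

```r
library(codonStability)

sim  <- simulateStudy(simulationConfig(nGenes = 500, seed = 42))
freq <- codonFrequencyMatrix(sim$sequences)
hl   <- setNames(sim$kinetics$half_life_min, sim$kinetics$gene_id)

csc <- computeCsc(freq, hl)
csc
#> CSC vector (frame +0, 500 genes): 61/61 codons, 28 positive

chisqSignTest(csc, sim$classification)
#> Sign-by-optimality chi-square test (Yates-corrected)
#>   Total positive: 28   Observed optimal-positive: 24   Expected: 12.9
#>   n optimal: 28 / 61 codons
#>   X-squared = 30.14, p = 4.02e-08

frameshiftControl(sim$sequences, hl, sim$weights)
#>   shift     rho      p  n
#> 1     0  0.8498 0.0000 61
#> 2     1 -0.3767 0.0028 61
#> 3     2 -0.0685 0.6000 61
```

Reading: 28 of 61 codons correlate positively with half-life, and 24 of
them are optimal codons, far above the 12.9 expected under independence
(p ≈ 4e-08) — the generator's built-in coupling is recovered. The
CSC–weight correlation (ρ = 0.85 in frame 0) collapses when the reading
frame is shifted, confirming the signal is carried by codon identity
rather than nucleotide composition.

The same statistics can be applied directly to a published contingency
summary, with no sequence or kinetic data at all:

```r
contingencySummary(totalPos = 26, observed = 22, nOpt = 28)
#> Sign-by-optimality chi-square test (Yates-corrected)
#>   Total positive: 26   Observed optimal-positive: 22   Expected: 11.9
#>   n optimal: 28 / 61 codons
#>   X-squared = 24.7, p = 6.7e-07
```

A thin command-line front end is available at
`inst/scripts/codon-stability` (subcommands `chisq --counts a,b,c,d`,
`simulate`, `all`).

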