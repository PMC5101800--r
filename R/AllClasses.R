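#' @include AllGenerics.R codon-tables.R
NULL

## ---------------------------------------------------------------------------
## AdaptivenessWeights
## ---------------------------------------------------------------------------

#' Per-codon adaptiveness weights (tAI or nTE)
#'
#' Holds one relative adaptiveness weight per sense codon, in (0, 1],
#' as used by the tRNA adaptation index. Weights are either computed from
#' a tRNA gene copy-number table via [relativeAdaptiveness()]
#' (`provenance = "computed"`, maximum weight exactly 1) or loaded from a
#' published table via [readWeights()] (`provenance = "loaded"`).
#' Demand-normalized (nTE-style) weights built by [computeNte()] may
#' contain `NA` for codons with zero demand.
#'
#' @slot weights Named numeric vector over the 61 sense codons.
#' @slot provenance Either `"computed"` or `"loaded"`.
#' @seealso [relativeAdaptiveness()], [readWeights()], [taiG()]
#' @aliases AdaptivenessWeights
#' @exportClass AdaptivenessWeights
setClass("AdaptivenessWeights",
  slots = c(weights = "numeric", provenance = "character"))

setValidity("AdaptivenessWeights", function(object) {
  w <- object@weights
  if (!identical(names(w), senseCodons()))
    return("weights must be named by the 61 sense codons in canonical order")
  ok <- !is.na(w)
  if (!any(ok)) return("all weights are missing")
  if (any(w[ok] <= 0) || any(w[ok] > 1 + 1e-9))
    return("weights must lie in (0, 1]")
  if (length(object@provenance) != 1L ||
      !object@provenance %in% c("computed", "loaded"))
    return("provenance must be 'computed' or 'loaded'")
  if (object@provenance == "computed" && abs(max(w[ok]) - 1) > 1e-9)
    return("computed weights must have maximum 1")
  TRUE
})

#' @rdname accessors
#' @export
setMethod("adaptiveness", "AdaptivenessWeights", function(object)
  object@weights)

setMethod("show", "AdaptivenessWeights", function(object) {
  w <- object@weights
  cat("AdaptivenessWeights (", object@provenance, ") over ",
      sum(!is.na(w)), "/61 sense codons\n", sep = "")
  cat("  range: [", format(min(w, na.rm = TRUE), digits = 4), ", ",
      format(max(w, na.rm = TRUE), digits = 4), "]\n", sep = "")
})

AdaptivenessWeights <- function(weights, provenance = "computed") {
  new("AdaptivenessWeights", weights = weights[senseCodons()],
      provenance = provenance)
}

## ---------------------------------------------------------------------------
## OptimalityClassification
## ---------------------------------------------------------------------------

#' Binary codon-optimality classification
#'
#' A partition of the 61 sense codons into optimal and non-optimal under
#' one metric, typically classical translation efficiency (cTE, i.e.
#' tAI-based) or normalized translation efficiency (nTE, additionally
#' accounting for codon demand from mRNA abundance). Classifications are
#' inputs to the association tests, never derived internally from a
#' weight cutoff.
#'
#' @slot metric Metric label, e.g. `"cTE"` or `"nTE"`.
#' @slot optimal Named logical vector over the 61 sense codons.
#' @seealso [readClassifications()], [chisqSignTest()], [percentOptimal()]
#' @aliases OptimalityClassification
#' @exportClass OptimalityClassification
setClass("OptimalityClassification",
  slots = c(metric = "character", optimal = "logical"))

setValidity("OptimalityClassification", function(object) {
  o <- object@optimal
  if (!identical(names(o), senseCodons()))
    return("optimal must be named by the 61 sense codons in canonical order")
  if (anyNA(o)) return("optimal flags must not be missing")
  if (!any(o) || all(o))
    return("both the optimal and the non-optimal class must be non-empty")
  if (length(object@metric) != 1L || !nzchar(object@metric))
    return("metric must be a single non-empty string")
  TRUE
})

#' @rdname accessors
#' @export
setMethod("isOptimal", "OptimalityClassification", function(object)
  object@optimal)

setMethod("show", "OptimalityClassification", function(object) {
  cat("OptimalityClassification [", object@metric, "]: ",
      sum(object@optimal), " optimal / ",
      sum(!object@optimal), " non-optimal codons\n", sep = "")
})

#' Construct a codon-optimality classification
#'
#' @param optimal Named logical vector (or character vector of optimal
#'   codons) over the 61 sense codons.
#' @param metric Metric label, e.g. `"cTE"`.
#' @return An [OptimalityClassification-class] object.
#' @examples
#' cls <- optimalityClassification(head(senseCodons(), 25), "cTE")
#' sum(isOptimal(cls))
#' @export
optimalityClassification <- function(optimal, metric = "cTE") {
  if (is.character(optimal)) {
    bad <- setdiff(optimal, senseCodons())
    if (length(bad))
      stop("not sense codons: ", paste(bad, collapse = ", "))
    optimal <- setNames(senseCodons() %in% optimal, senseCodons())
  }
  new("OptimalityClassification", metric = metric,
      optimal = optimal[senseCodons()])
}

## ---------------------------------------------------------------------------
## CodonProfile
## ---------------------------------------------------------------------------

#' Per-gene codon usage profile
#'
#' Codon counts and sense-codon frequencies for one coding sequence read
#' in a given frame. Counts cover all 64 triplets (stop triplets arise at
#' sequence ends and in shifted frames); frequencies are defined over the
#' 61 sense codons only, with denominator equal to the number of sense
#' triplets counted, so that frame-0 and frameshifted readings share the
#' same 61-codon support.
#'
#' @slot geneId Gene identifier.
#' @slot counts Named integer vector over all 64 triplets.
#' @slot frequencies Named numeric vector over the 61 sense codons
#'   (all `NA` when no sense triplet was counted).
#' @slot nCounted Total number of triplets counted.
#' @slot nSense Number of sense triplets counted.
#' @slot frame Frame offset in \{0, 1, 2\} (nucleotides skipped 5').
#' @seealso [codonProfile()], [codonFrequencyMatrix()]
#' @aliases CodonProfile
#' @exportClass CodonProfile
setClass("CodonProfile",
  slots = c(geneId = "character", counts = "integer",
            frequencies = "numeric", nCounted = "integer",
            nSense = "integer", frame = "integer"))

setValidity("CodonProfile", function(object) {
  if (!identical(names(object@counts), allCodons()))
    return("counts must cover all 64 triplets in canonical order")
  if (any(object@counts < 0)) return("counts must be non-negative")
  if (sum(object@counts) != object@nCounted)
    return("counts are inconsistent with nCounted")
  if (sum(object@counts[senseCodons()]) != object@nSense)
    return("sense-codon counts are inconsistent with nSense")
  f <- object@frequencies
  if (!identical(names(f), senseCodons()))
    return("frequencies must cover the 61 sense codons")
  if (object@nSense > 0L) {
    if (abs(sum(f) - 1) > 1e-12)
      return("frequencies must sum to 1 over the sense codons")
  } else if (!all(is.na(f))) {
    return("frequencies must be all-NA when no sense codon was counted")
  }
  if (!object@frame %in% 0:2) return("frame must be 0, 1 or 2")
  TRUE
})

setMethod("show", "CodonProfile", function(object) {
  cat("CodonProfile for ", object@geneId, " (frame +", object@frame, "): ",
      object@nCounted, " triplets, ", object@nSense, " sense codons\n",
      sep = "")
})

## ---------------------------------------------------------------------------
## Correlation results
## ---------------------------------------------------------------------------

#' Spearman correlation result
#'
#' Rank correlation coefficient with a two-sided p-value from the
#' t approximation on `n - 2` degrees of freedom (average ranks for
#' ties). The subclass [PartialCorrelationResult-class] adds the name of
#' the variable controlled for and uses `n - 3` degrees of freedom.
#'
#' @slot rho Spearman correlation coefficient in \[-1, 1\] (`NA` when a
#'   variable is constant).
#' @slot p Two-sided p-value.
#' @slot n Number of complete observation pairs (triples) used.
#' @seealso [spearmanTest()], [partialSpearman()]
#' @aliases CorrelationResult
#' @exportClass CorrelationResult
setClass("CorrelationResult",
  slots = c(rho = "numeric", p = "numeric", n = "integer"))

setValidity("CorrelationResult", function(object) {
  if (!is.na(object@rho) && abs(object@rho) > 1 + 1e-12)
    return("|rho| must not exceed 1")
  if (!is.na(object@p) && (object@p < 0 || object@p > 1))
    return("p must lie in [0, 1]")
  TRUE
})

#' @rdname CorrelationResult-class
#' @slot controlled Name of the variable partialled out.
#' @aliases PartialCorrelationResult
#' @exportClass PartialCorrelationResult
setClass("PartialCorrelationResult", contains = "CorrelationResult",
  slots = c(controlled = "character"))

#' @rdname accessors
#' @export
setMethod("rho", "CorrelationResult", function(object) object@rho)

#' @rdname accessors
#' @export
setMethod("pValue", "CorrelationResult", function(object) object@p)

#' @rdname accessors
#' @export
setMethod("nObs", "CorrelationResult", function(object) object@n)

setMethod("show", "CorrelationResult", function(object) {
  cat("Spearman correlation: rho = ", format(object@rho, digits = 4),
      ", p = ", format(object@p, digits = 3), ", n = ", object@n, "\n",
      sep = "")
})

setMethod("show", "PartialCorrelationResult", function(object) {
  cat("Partial Spearman correlation (controlling for ", object@controlled,
      "): rho = ", format(object@rho, digits = 4),
      ", p = ", format(object@p, digits = 3), ", n = ", object@n, "\n",
      sep = "")
})

## ---------------------------------------------------------------------------
## CodonCorrelationVector
## ---------------------------------------------------------------------------

#' Per-codon correlation vector (CSC or CPC)
#'
#' For each of the 61 sense codons, the Spearman correlation across genes
#' between the codon's within-gene frequency and a per-gene kinetic
#' quantity: mRNA half-life (CSC, codon occurrence to mRNA stability
#' correlation coefficient) or mRNA synthesis rate (CPC, codon occurrence
#' to mRNA production correlation coefficient). Codons with constant
#' frequency across the analyzed genes carry `NA`.
#'
#' @slot kind `"CSC"` or `"CPC"`.
#' @slot values Named numeric vector of per-codon Spearman rho.
#' @slot ns Named integer vector of per-codon complete-pair counts.
#' @slot nGenes Number of genes with both a frequency row and a kinetic
#'   value.
#' @slot frame Reading-frame offset the frequencies were computed in.
#' @seealso [computeCsc()], [computeCpc()], [signPartition()],
#'   [chisqSignTest()]
#' @aliases CodonCorrelationVector
#' @exportClass CodonCorrelationVector
setClass("CodonCorrelationVector",
  slots = c(kind = "character", values = "numeric", ns = "integer",
            nGenes = "integer", frame = "integer"))

setValidity("CodonCorrelationVector", function(object) {
  if (!object@kind %in% c("CSC", "CPC"))
    return("kind must be 'CSC' or 'CPC'")
  if (!identical(names(object@values), senseCodons()))
    return("values must cover the 61 sense codons in canonical order")
  v <- object@values
  if (any(abs(v[!is.na(v)]) > 1 + 1e-12)) return("|rho| must not exceed 1")
  if (!object@frame %in% 0:2) return("frame must be 0, 1 or 2")
  TRUE
})

#' @rdname accessors
#' @export
setMethod("codonValues", "CodonCorrelationVector", function(object)
  object@values)

#' @rdname accessors
#' @export
setMethod("nObs", "CodonCorrelationVector", function(object) object@nGenes)

setMethod("show", "CodonCorrelationVector", function(object) {
  v <- object@values
  cat(object@kind, " vector (frame +", object@frame, ", ", object@nGenes,
      " genes): ", sum(!is.na(v)), "/61 codons, ",
      sum(v > 0, na.rm = TRUE), " positive\n", sep = "")
})

## ---------------------------------------------------------------------------
## ContingencySummary
## ---------------------------------------------------------------------------

#' Sign-by-optimality contingency test summary
#'
#' Summary of the 2x2 chi-square test of association between the sign of
#' a per-codon correlation vector (positive vs non-positive CSC/CPC) and
#' a binary codon-optimality classification, in the layout of the
#' published summary tables: `totalPos` is the number of codons with a
#' positive coefficient ("Total"), `observed` the number of optimal
#' codons among them ("Observed"), and `expected` the expected count
#' under independence, `nOpt * totalPos / nCodons`.
#'
#' @slot totalPos Codons with positive coefficient.
#' @slot observed Optimal codons with positive coefficient.
#' @slot expected Expected optimal-positive count under independence.
#' @slot nOpt Number of optimal codons among those tested.
#' @slot nCodons Number of codons tested (61 unless some were dropped).
#' @slot chi2 Chi-square statistic (1 degree of freedom).
#' @slot p P-value.
#' @slot corrected Whether the Yates continuity correction was applied.
#' @seealso [chisqSignTest()], [contingencySummary()]
#' @aliases ContingencySummary
#' @exportClass ContingencySummary
setClass("ContingencySummary",
  slots = c(totalPos = "integer", observed = "integer", expected = "numeric",
            nOpt = "integer", nCodons = "integer", chi2 = "numeric",
            p = "numeric", corrected = "logical"))

setValidity("ContingencySummary", function(object) {
  cells <- contingencyCells(object)
  if (any(cells < 0)) return("implied 2x2 cells must be non-negative")
  if (sum(cells) != object@nCodons)
    return("implied 2x2 cells must sum to nCodons")
  if (abs(object@expected -
          object@nOpt * object@totalPos / object@nCodons) > 1e-9)
    return("expected must equal nOpt * totalPos / nCodons")
  if (!is.na(object@chi2) && object@chi2 < 0)
    return("chi2 must be non-negative")
  if (!is.na(object@p) && (object@p < 0 || object@p > 1))
    return("p must lie in [0, 1]")
  TRUE
})

#' Reconstruct the 2x2 cells of a contingency summary
#'
#' Returns the implied 2x2 table (optimality by coefficient sign) of a
#' [ContingencySummary-class]: rows optimal/non-optimal, columns
#' positive/non-positive.
#'
#' @param object A [ContingencySummary-class] object.
#' @return A 2x2 integer matrix whose cells sum to `nCodons`.
#' @examples
#' s <- contingencySummary(totalPos = 26, observed = 22, nOpt = 28)
#' contingencyCells(s)
#' @export
contingencyCells <- function(object) {
  a <- object@observed                       # optimal, positive
  b <- object@nOpt - a                       # optimal, non-positive
  c_ <- object@totalPos - a                  # non-optimal, positive
  d <- object@nCodons - object@nOpt - c_     # non-optimal, non-positive
  matrix(c(a, c_, b, d), nrow = 2,
         dimnames = list(optimal = c("yes", "no"),
                         sign = c("positive", "nonPositive")))
}

#' @rdname accessors
#' @export
setMethod("pValue", "ContingencySummary", function(object) object@p)

setMethod("show", "ContingencySummary", function(object) {
  cat("Sign-by-optimality chi-square test (",
      if (object@corrected) "Yates-corrected" else "uncorrected", ")\n",
      "  Total positive: ", object@totalPos,
      "   Observed optimal-positive: ", object@observed,
      "   Expected: ", format(round(object@expected, 1), nsmall = 1), "\n",
      "  n optimal: ", object@nOpt, " / ", object@nCodons, " codons\n",
      "  X-squared = ", format(object@chi2, digits = 4),
      ", p = ", format(object@p, digits = 3), "\n", sep = "")
})

#' Motif association rank-sum test result
#'
#' One-sided Wilcoxon rank-sum comparison of a gene-level codon
#' optimality score (e.g. tAI_g or percent optimal codons) between genes
#' carrying a sequence motif and genes lacking it.
#'
#' @slot motifId Motif (or motif-group) identifier.
#' @slot direction Alternative hypothesis: `"greater"` (motif-bearing
#'   genes score higher) or `"less"`.
#' @slot statistic Rank-sum W statistic.
#' @slot pRaw Raw one-sided p-value.
#' @slot pBonferroni Bonferroni-corrected p-value (`NA` until corrected).
#' @slot nWith,nWithout Group sizes.
#' @seealso [motifWilcoxon()], [motifAssociationTable()]
#' @aliases MotifTestResult
#' @exportClass MotifTestResult
setClass("MotifTestResult",
  slots = c(motifId = "character", direction = "character",
            statistic = "numeric", pRaw = "numeric",
            pBonferroni = "numeric", nWith = "integer",
            nWithout = "integer"))

setValidity("MotifTestResult", function(object) {
  if (!object@direction %in% c("greater", "less"))
    return("direction must be 'greater' or 'less'")
  if (object@pRaw < 0 || object@pRaw > 1) return("pRaw must lie in [0, 1]")
  if (!is.na(object@pBonferroni) &&
      (object@pBonferroni < object@pRaw - 1e-12 || object@pBonferroni > 1))
    return("pBonferroni must lie in [pRaw, 1]")
  TRUE
})

#' @rdname accessors
#' @export
setMethod("pValue", "MotifTestResult", function(object)
  if (is.na(object@pBonferroni)) object@pRaw else object@pBonferroni)

setMethod("show", "MotifTestResult", function(object) {
  cat("Wilcoxon rank-sum (", object@direction, ") for motif ",
      object@motifId, ": W = ", object@statistic,
      ", p = ", format(object@pRaw, digits = 3),
      if (!is.na(object@pBonferroni))
        paste0(", Bonferroni p = ", format(object@pBonferroni, digits = 3)),
      " (n = ", object@nWith, " vs ", object@nWithout, ")\n", sep = "")
})
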