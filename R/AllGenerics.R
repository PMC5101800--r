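#' @include codonStability-package.R
NULL

#' Accessor generics
#'
#' Small accessor generics shared by the result classes of the package:
#' `rho()` returns a correlation coefficient, `pValue()` a p-value,
#' `nObs()` the number of observations a statistic was computed from,
#' `codonValues()` a named per-codon numeric vector, and
#' `adaptiveness()` the per-codon weight vector of an
#' [AdaptivenessWeights-class] object.
#'
#' @param object An object of one of the package's S4 result classes.
#' @return `rho()`, `pValue()` a numeric scalar; `nObs()` an integer;
#'   `codonValues()` and `adaptiveness()` a named numeric vector over the
#'   61 sense codons; `isOptimal()` a named logical vector.
#' @name accessors
#' @aliases rho pValue nObs codonValues adaptiveness isOptimal
#' @examples
#' r <- spearmanTest(1:10, (1:10)^2)
#' rho(r)
#' pValue(r)
#' nObs(r)
NULL

#' @rdname accessors
#' @export
setGeneric("rho", function(object) standardGeneric("rho"))

#' @rdname accessors
#' @export
setGeneric("pValue", function(object) standardGeneric("pValue"))

#' @rdname accessors
#' @export
setGeneric("nObs", function(object) standardGeneric("nObs"))

#' @rdname accessors
#' @export
setGeneric("codonValues", function(object) standardGeneric("codonValues"))

#' @rdname accessors
#' @export
setGeneric("adaptiveness", function(object) standardGeneric("adaptiveness"))

#' @rdname accessors
#' @export
setGeneric("isOptimal", function(object) standardGeneric("isOptimal"))

#' Gene-level codon-optimality score generics
#'
#' `taiG()` computes the gene-level tRNA adaptation index (geometric mean
#' of per-codon adaptiveness weights over a gene's codons);
#' `percentOptimal()` computes the percentage of a gene's sense codons
#' classified as optimal. Both have methods for a single
#' [CodonProfile-class] and for a gene-by-codon count matrix as produced
#' by [codonCountMatrix()].
#'
#' @param x A [CodonProfile-class] or a numeric gene-by-codon count matrix
#'   whose columns include the 61 sense codons.
#' @param weights An [AdaptivenessWeights-class] object (or named numeric
#'   vector over the sense codons).
#' @param classification An [OptimalityClassification-class] object.
#' @return A numeric scalar (profile method) or named numeric vector
#'   (matrix method); `NA` for genes with zero counted sense codons.
#' @seealso [relativeAdaptiveness()], [readClassifications()]
#' @name geneScores
NULL

#' @rdname geneScores
#' @export
setGeneric("taiG", function(x, weights) standardGeneric("taiG"))

#' @rdname geneScores
#' @export
setGeneric("percentOptimal", function(x, classification)
  standardGeneric("percentOptimal"))
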