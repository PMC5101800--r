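#' @include AllClasses.R
NULL

## ---------------------------------------------------------------------------
## Wobble pairing rules and relative adaptiveness (tAI weights)
## ---------------------------------------------------------------------------

.PAIRING_CLASSES <- c("watsonCrick", "GU", "IC", "IA", "UG", "LA")

#' Wobble-pairing selective penalties
#'
#' Constructs the penalty vector `s` used by the tRNA adaptation index:
#' the efficiency cost of each codon-anticodon pairing class, with 0 for
#' a perfect Watson-Crick pair and values in (0, 1\] for wobble pairs.
#' The defaults are the published penalties of the standard tAI
#' construction (G:U 0.41, I:C 0.28, I:A 0.9999, U:G 0.68, and L:A 0.89
#' for the bacterial lysidine-modified tRNA reading of ATA); all are
#' overridable. The contribution of an anticodon to a codon's absolute
#' weight is `(1 - s) * tGCN`.
#'
#' @param watsonCrick,GU,IC,IA,UG,LA Penalties in \[0, 1\] per pairing
#'   class (Watson-Crick must be 0).
#' @return Named numeric vector of penalties.
#' @seealso [relativeAdaptiveness()], [codonAnticodonPairs()]
#' @examples
#' wobblePenalties()
#' @export
wobblePenalties <- function(watsonCrick = 0, GU = 0.41, IC = 0.28,
                            IA = 0.9999, UG = 0.68, LA = 0.89) {
  s <- c(watsonCrick = watsonCrick, GU = GU, IC = IC, IA = IA, UG = UG,
         LA = LA)
  if (s[["watsonCrick"]] != 0)
    stop("the Watson-Crick penalty must be 0")
  if (any(s < 0 | s > 1)) stop("penalties must lie in [0, 1]")
  s
}

#' Codon-anticodon decoding rules
#'
#' The pairing table underlying [relativeAdaptiveness()]: for each sense
#' codon, the anticodons (written 5'->3', as in tRNA gene copy-number
#' tables) that can decode it and the pairing class of the wobble
#' position. Each codon is read by its Watson-Crick anticodon plus at
#' most one wobble decoder determined by the codon's third base:
#' codons ending in T are additionally read by the G34 anticodon of the
#' NNC codon (G:U pair); codons ending in C by the inosine-modified A34
#' anticodon (I:C); codons ending in A by the same inosine anticodon
#' (I:A); codons ending in G by the U34 anticodon of the NNA codon
#' (U:G). ATG (methionine) is decoded only by its Watson-Crick
#' anticodon. ATA is special-cased by domain: in eukaryotes it follows
#' the generic rule, in prokaryotes it is read by its Watson-Crick
#' anticodon plus the lysidine-modified CAT anticodon (L:A).
#'
#' @param domain `"eukaryote"` (default) or `"prokaryote"`.
#' @return A data frame with columns `codon`, `anticodon`, `class`.
#' @examples
#' subset(codonAnticodonPairs(), codon %in% c("TTT", "ATG", "ATA"))
#' @export
codonAnticodonPairs <- function(domain = c("eukaryote", "prokaryote")) {
  domain <- match.arg(domain)
  codons <- .SENSE_CODONS
  wc <- data.frame(codon = codons, anticodon = .revcomp(codons),
                   class = "watsonCrick")
  third <- substring(codons, 3L, 3L)
  stem <- substring(codons, 1L, 2L)
  wobble <- data.frame(
    codon = codons,
    anticodon = ifelse(third == "T", .revcomp(paste0(stem, "C")),
                ifelse(third == "C", .revcomp(paste0(stem, "T")),
                ifelse(third == "A", .revcomp(paste0(stem, "T")),
                                     .revcomp(paste0(stem, "A"))))),
    class = c(T = "GU", C = "IC", A = "IA", G = "UG")[third])
  pairs <- rbind(wc, wobble)
  ## methionine: no wobble decoding of ATG
  pairs <- pairs[!(pairs$codon == "ATG" & pairs$class != "watsonCrick"), ]
  if (domain == "prokaryote") {
    ## ATA read by lysidine-modified CAT instead of inosine
    pairs <- pairs[!(pairs$codon == "ATA" & pairs$class == "IA"), ]
    pairs <- rbind(pairs, data.frame(codon = "ATA", anticodon = "CAT",
                                     class = "LA"))
  }
  rownames(pairs) <- NULL
  pairs[order(match(pairs$codon, codons)), ]
}

#' Relative adaptiveness weights from tRNA gene copy numbers
#'
#' Computes the per-codon relative adaptiveness weights of the tRNA
#' adaptation index (tAI). For each sense codon `i`, the absolute weight
#' is `W_i = sum_j (1 - s_class(i,j)) * tGCN_j` over the cognate and
#' wobble anticodons `j` that can decode it (see
#' [codonAnticodonPairs()]); anticodons absent from the copy-number
#' table contribute 0. Weights are normalized by the maximum, and codons
#' with `W_i = 0` (no decoding tRNA) receive the geometric mean of the
#' nonzero normalized weights.
#'
#' @param tgcn Named non-negative integer vector of tRNA gene copy
#'   numbers, named by anticodon (5'->3' triplet), or a data frame with
#'   columns `anticodon` and `copies` (see [readTgcn()]).
#' @param penalties Penalty vector from [wobblePenalties()].
#' @param domain Passed to [codonAnticodonPairs()].
#' @return An [AdaptivenessWeights-class] with `provenance = "computed"`.
#' @examples
#' tgcn <- c(AAA = 10, GAA = 8, CAT = 6, TAT = 2)
#' relativeAdaptiveness(tgcn)
#' @export
relativeAdaptiveness <- function(tgcn, penalties = wobblePenalties(),
                                 domain = c("eukaryote", "prokaryote")) {
  domain <- match.arg(domain)
  if (is.data.frame(tgcn))
    tgcn <- stats::setNames(tgcn$copies, tgcn$anticodon)
  if (is.null(names(tgcn)) || !all(grepl("^[ACGT]{3}$", names(tgcn))))
    stop("tgcn must be named by anticodon triplets over {A,C,G,T}")
  if (anyNA(tgcn) || any(tgcn < 0))
    stop("copy numbers must be non-negative")
  if (!any(tgcn > 0)) stop("at least one copy number must be positive")
  if (anyDuplicated(names(tgcn)))
    stop("duplicate anticodon(s): ",
         paste(unique(names(tgcn)[duplicated(names(tgcn))]), collapse = ", "))
  pairs <- codonAnticodonPairs(domain)
  contrib <- (1 - penalties[pairs$class]) *
    ifelse(pairs$anticodon %in% names(tgcn), tgcn[pairs$anticodon], 0)
  W <- vapply(split(contrib, factor(pairs$codon, levels = .SENSE_CODONS)),
              sum, numeric(1L))
  if (all(W == 0)) stop("all absolute weights are zero")
  w <- W / max(W)
  zero <- w == 0
  if (any(zero)) w[zero] <- exp(mean(log(w[!zero])))
  AdaptivenessWeights(w, provenance = "computed")
}

## ---------------------------------------------------------------------------
## Table readers
## ---------------------------------------------------------------------------

#' Read tRNA gene copy numbers, adaptiveness weights, or classifications
#'
#' TSV readers for the three tabular inputs of the optimality module.
#' `readTgcn()` expects columns `anticodon` and `copies`;
#' `readWeights()` expects `codon` and `weight`, requires all 61 sense
#' codons with weights in (0, 1\], and returns an
#' [AdaptivenessWeights-class] with `provenance = "loaded"` (the
#' paper-faithful path of taking published weights as given);
#' `readClassifications()` expects `codon`, `metric` and `optimal`
#' (0/1) and returns a named list of
#' [OptimalityClassification-class] objects, one per metric.
#'
#' @param file Path to a tab-separated file with a header.
#' @return See details above.
#' @examples
#' tf <- tempfile()
#' write.table(data.frame(codon = senseCodons(), weight = 1),
#'             tf, sep = "\t", row.names = FALSE)
#' readWeights(tf)
#' @export
readTgcn <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  if (!all(c("anticodon", "copies") %in% names(df)))
    stop("tGCN table must have columns 'anticodon' and 'copies'")
  stats::setNames(as.numeric(df$copies), toupper(df$anticodon))
}

#' @rdname readTgcn
#' @export
readWeights <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  if (!all(c("codon", "weight") %in% names(df)))
    stop("weights table must have columns 'codon' and 'weight'")
  df$codon <- toupper(df$codon)
  missing <- setdiff(.SENSE_CODONS, df$codon)
  if (length(missing))
    stop("missing codon(s) in weights table: ",
         paste(missing, collapse = ", "))
  w <- stats::setNames(df$weight, df$codon)[.SENSE_CODONS]
  if (anyNA(w) || any(w <= 0) || any(w > 1))
    stop("weights must lie in (0, 1]")
  AdaptivenessWeights(w, provenance = "loaded")
}

#' @rdname readTgcn
#' @export
readClassifications <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  if (!all(c("codon", "metric", "optimal") %in% names(df)))
    stop("classification table must have columns 'codon', 'metric', 'optimal'")
  df$codon <- toupper(df$codon)
  out <- lapply(split(df, df$metric), function(d) {
    missing <- setdiff(.SENSE_CODONS, d$codon)
    if (length(missing))
      stop("metric '", d$metric[1L], "' is missing codon(s): ",
           paste(missing, collapse = ", "))
    flags <- stats::setNames(as.logical(as.integer(d$optimal)),
                             d$codon)[.SENSE_CODONS]
    optimalityClassification(flags, metric = d$metric[1L])
  })
  out
}

## ---------------------------------------------------------------------------
## Gene-level scores
## ---------------------------------------------------------------------------

.weightsVector <- function(weights) {
  if (methods::is(weights, "AdaptivenessWeights"))
    weights <- adaptiveness(weights)
  if (!identical(names(weights), .SENSE_CODONS))
    weights <- weights[.SENSE_CODONS]
  if (is.null(names(weights)) || anyNA(names(weights)))
    stop("weights must be named by the 61 sense codons")
  weights
}

## Gene-level geometric mean of weights with codon multiplicity. Codons
## whose weight is NA (possible for nTE-style weights) are excluded from
## both numerator and denominator.
.taiGFromCounts <- function(counts, w) {
  use <- !is.na(w)
  cs <- counts[, .SENSE_CODONS[use], drop = FALSE]
  n <- rowSums(cs)
  out <- exp(as.numeric(cs %*% log(w[use])) / n)
  out[n == 0] <- NA_real_
  stats::setNames(out, rownames(counts))
}

#' @rdname geneScores
#' @export
setMethod("taiG", "matrix", function(x, weights) {
  w <- .weightsVector(weights)
  .taiGFromCounts(x, w)
})

#' @rdname geneScores
#' @export
setMethod("taiG", "CodonProfile", function(x, weights) {
  w <- .weightsVector(weights)
  m <- matrix(x@counts[.SENSE_CODONS], nrow = 1L,
              dimnames = list(x@geneId, .SENSE_CODONS))
  unname(.taiGFromCounts(m, w))
})

#' @rdname geneScores
#' @export
setMethod("percentOptimal", "matrix", function(x, classification) {
  opt <- isOptimal(classification)
  sense <- x[, .SENSE_CODONS, drop = FALSE]
  n <- rowSums(sense)
  out <- 100 * rowSums(sense[, .SENSE_CODONS[opt], drop = FALSE]) / n
  out[n == 0] <- NA_real_
  stats::setNames(out, rownames(x))
})

#' @rdname geneScores
#' @export
setMethod("percentOptimal", "CodonProfile", function(x, classification) {
  m <- matrix(x@counts[.SENSE_CODONS], nrow = 1L,
              dimnames = list(x@geneId, .SENSE_CODONS))
  unname(percentOptimal(m, classification))
})

#' Demand-normalized adaptiveness weights (nTE-style)
#'
#' Normalizes adaptiveness weights by codon demand, following the
#' normalized translation efficiency construction: the demand for codon
#' `i` is `d_i = sum_g usage_{g,i} * m_g` over genes `g` with abundance
#' `m_g`, where usage is either the raw codon count (`variant =
#' "count"`) or the within-gene codon frequency (`variant =
#' "frequency"`); demand is scaled to maximum 1 and the returned weights
#' are `w_i / d_i`, renormalized to maximum 1. Codons with zero demand
#' get `NA` with a warning. Doubling all abundances leaves the result
#' unchanged. This is a convenience reconstruction: published binary
#' nTE classifications remain the primary interface for association
#' tests.
#'
#' @param weights An [AdaptivenessWeights-class] (tAI weights).
#' @param counts Gene-by-codon count matrix ([codonCountMatrix()]).
#' @param abundance Named positive abundance vector (molecules per
#'   cell), names matching `counts` row names.
#' @param variant `"count"` (abundance-weighted codon counts, default)
#'   or `"frequency"` (abundance-weighted within-gene frequencies).
#' @return An [AdaptivenessWeights-class] with `provenance = "computed"`.
#' @examples
#' seqs <- Biostrings::DNAStringSet(c(g1 = "ATGGCTAAA", g2 = "ATGGCTGCT"))
#' counts <- codonCountMatrix(seqs)
#' w <- relativeAdaptiveness(c(CAT = 4, AGC = 4, TTT = 2))
#' nte <- computeNte(w, counts, c(g1 = 100, g2 = 50))
#' @export
computeNte <- function(weights, counts, abundance,
                       variant = c("count", "frequency")) {
  variant <- match.arg(variant)
  w <- .weightsVector(weights)
  common <- intersect(rownames(counts), names(abundance))
  if (!length(common)) stop("no genes shared between counts and abundance")
  m <- abundance[common]
  if (anyNA(m) || any(m <= 0))
    stop("abundance must be positive for included genes")
  usage <- counts[common, .SENSE_CODONS, drop = FALSE]
  if (variant == "frequency") {
    nSense <- rowSums(usage)
    usage <- usage / ifelse(nSense == 0, NA_real_, nSense)
    usage[is.na(usage)] <- 0
  }
  d <- as.numeric(t(usage) %*% m)
  names(d) <- .SENSE_CODONS
  if (max(d) == 0) stop("all codon demands are zero")
  d <- d / max(d)
  nte <- w / d
  zero <- d == 0
  if (any(zero)) {
    warning("zero demand for codon(s): ",
            paste(.SENSE_CODONS[zero], collapse = ", "),
            "; nTE set to NA")
    nte[zero] <- NA_real_
  }
  nte <- nte / max(nte, na.rm = TRUE)
  AdaptivenessWeights(nte, provenance = "computed")
}

#' Gene-level optimality score table
#'
#' Combines [taiG()] and [percentOptimal()] over a set of genes into one
#' data frame, one row per gene and one percent-optimal column per
#' classification metric.
#'
#' @param counts Gene-by-codon count matrix ([codonCountMatrix()]).
#' @param weights An [AdaptivenessWeights-class].
#' @param classifications A list of [OptimalityClassification-class]
#'   objects (possibly empty).
#' @return A data frame with columns `gene_id`, `tai_g` and
#'   `pct_optimal_<metric>`.
#' @examples
#' seqs <- Biostrings::DNAStringSet(c(g1 = "ATGGCTAAA"))
#' w <- relativeAdaptiveness(c(CAT = 4, AGC = 4, TTT = 2))
#' geneOptimality(codonCountMatrix(seqs), w)
#' @export
geneOptimality <- function(counts, weights, classifications = list()) {
  out <- data.frame(gene_id = rownames(counts),
                    tai_g = unname(taiG(counts, weights)))
  for (cls in classifications)
    out[[paste0("pct_optimal_", cls@metric)]] <-
      unname(percentOptimal(counts, cls))
  out
}
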