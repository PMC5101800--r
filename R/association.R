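#' @include AllClasses.R
NULL

## ---------------------------------------------------------------------------
## Spearman machinery
## ---------------------------------------------------------------------------

## rho on average ranks + two-sided p from the t approximation. The t
## approximation is used for every n (including small, tied or untied
## samples) so that CSC/CPC p-values are computed under one consistent
## rule across datasets.
.spearmanRho <- function(rx, ry) {
  sx <- sum((rx - mean(rx))^2)
  sy <- sum((ry - mean(ry))^2)
  if (sx == 0 || sy == 0) return(NA_real_)
  sum((rx - mean(rx)) * (ry - mean(ry))) / sqrt(sx * sy)
}

.tPvalue <- function(r, df) {
  if (is.na(r) || df <= 0) return(NA_real_)
  if (abs(r) >= 1) return(0)
  tt <- r * sqrt(df / (1 - r^2))
  2 * stats::pt(-abs(tt), df)
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Computes the Spearman correlation between two vectors using average
#' ranks for ties and pairwise-complete deletion, with a two-sided
#' p-value from the t approximation on `n - 2` degrees of freedom. The
#' t approximation is applied uniformly (rather than switching to an
#' exact small-sample null), so p-values are comparable across tied and
#' untied data.
#'
#' @param x,y Numeric vectors of equal length.
#' @return A [CorrelationResult-class]; `rho` is `NA` with a warning
#'   when either variable is constant over the complete pairs.
#' @examples
#' spearmanTest(1:10, exp(1:10))     # rho = 1 (monotone invariance)
#' @export
spearmanTest <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- stats::complete.cases(x, y)
  n <- sum(ok)
  if (n < 3L) stop("need at least 3 complete observation pairs")
  rx <- rank(x[ok])
  ry <- rank(y[ok])
  r <- .spearmanRho(rx, ry)
  if (is.na(r)) warning("constant variable; rho undefined")
  new("CorrelationResult", rho = r, p = .tPvalue(r, n - 2L),
      n = as.integer(n))
}

#' Spearman partial correlation controlling for a third variable
#'
#' First-order partial rank correlation: all three variables are
#' average-rank transformed, the pairwise Pearson correlations of the
#' ranks are combined as
#' `r_xy.z = (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) (1 - r_yz^2))`,
#' and the two-sided p-value comes from the t statistic on `n - 3`
#' degrees of freedom. Used to ask whether codon optimality remains
#' associated with half-lives or synthesis rates once mRNA abundance is
#' controlled for.
#'
#' @param x,y Numeric vectors.
#' @param z Numeric vector to control for.
#' @param controlled Label for the controlled variable (for reporting).
#' @return A [PartialCorrelationResult-class].
#' @examples
#' set.seed(1)
#' z <- rnorm(50); x <- z + rnorm(50); y <- z + rnorm(50)
#' partialSpearman(x, y, z)
#' @export
partialSpearman <- function(x, y, z, controlled = "z") {
  if (length(x) != length(y) || length(x) != length(z))
    stop("x, y and z must have equal length")
  ok <- stats::complete.cases(x, y, z)
  n <- sum(ok)
  if (n < 4L) stop("need at least 4 complete observation triples")
  rx <- rank(x[ok]); ry <- rank(y[ok]); rz <- rank(z[ok])
  if (stats::var(rz) == 0) stop("control variable z is constant")
  rxy <- .spearmanRho(rx, ry)
  rxz <- .spearmanRho(rx, rz)
  ryz <- .spearmanRho(ry, rz)
  if (is.na(rxy) || is.na(rxz) || is.na(ryz))
    stop("constant variable; partial correlation undefined")
  if (abs(rxz) >= 1 || abs(ryz) >= 1)
    stop("x or y is perfectly rank-correlated with z; ",
         "partial correlation undefined")
  r <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  r <- max(-1, min(1, r))
  new("PartialCorrelationResult", rho = r, p = .tPvalue(r, n - 3L),
      n = as.integer(n), controlled = controlled)
}

## ---------------------------------------------------------------------------
## CSC / CPC
## ---------------------------------------------------------------------------

.codonCorrelation <- function(freq, values, kind, frame) {
  if (is.null(rownames(freq))) stop("frequency matrix must have gene rows")
  if (is.null(names(values))) stop("kinetic values must be named by gene")
  common <- intersect(rownames(freq), names(values))
  common <- common[!is.na(values[common])]
  freq <- freq[common, .SENSE_CODONS, drop = FALSE]
  v <- values[common]
  complete <- stats::complete.cases(freq)   # all-NA rows (no sense codons)
  freq <- freq[complete, , drop = FALSE]
  v <- v[complete]
  if (length(v) < 3L)
    stop("need at least 3 genes with both frequencies and kinetic values")
  rv <- rank(v)
  rfreq <- apply(freq, 2L, rank)
  rhos <- apply(rfreq, 2L, .spearmanRho, ry = rv)
  if (anyNA(rhos))
    warning(sum(is.na(rhos)), " codon(s) with constant frequency; ",
            kind, " set to NA")
  new("CodonCorrelationVector", kind = kind,
      values = stats::setNames(as.numeric(rhos), .SENSE_CODONS),
      ns = stats::setNames(rep(length(v), 61L), .SENSE_CODONS),
      nGenes = length(v), frame = as.integer(frame))
}

#' Codon occurrence to mRNA stability/production correlation (CSC/CPC)
#'
#' For each of the 61 sense codons, computes the Spearman correlation
#' across genes between the codon's within-gene frequency (a column of
#' [codonFrequencyMatrix()]) and a per-gene kinetic value: mRNA
#' half-life for the CSC, mRNA synthesis rate (or RNA polymerase II
#' occupancy as a proxy) for the CPC. Codons enriched in stable
#' (highly synthesized) mRNAs have positive values. Genes are matched
#' by name; pairs with a missing kinetic value or an all-missing
#' frequency row are dropped. Codons with constant frequency across the
#' analyzed genes get `NA` with a warning.
#'
#' @param freq Gene-by-codon frequency matrix.
#' @param halfLives,synthesisRates Named numeric vector per gene.
#' @param frame Frame offset the frequencies were computed in (metadata
#'   only; use [codonFrequencyMatrix()]'s `shift` to actually reread).
#' @return A [CodonCorrelationVector-class].
#' @seealso [signPartition()], [chisqSignTest()], [frameshiftControl()]
#' @examples
#' set.seed(1)
#' sim <- simulateStudy(simulationConfig(nGenes = 50, seed = 1))
#' freq <- codonFrequencyMatrix(sim$sequences)
#' hl <- setNames(sim$kinetics$half_life_min, sim$kinetics$gene_id)
#' csc <- computeCsc(freq, hl)
#' csc
#' @export
computeCsc <- function(freq, halfLives, frame = 0) {
  .codonCorrelation(freq, halfLives, "CSC", frame)
}

#' @rdname computeCsc
#' @export
computeCpc <- function(freq, synthesisRates, frame = 0) {
  .codonCorrelation(freq, synthesisRates, "CPC", frame)
}

## ---------------------------------------------------------------------------
## Sign partition and chi-square test
## ---------------------------------------------------------------------------

#' Partition codons on the sign of their CSC/CPC value
#'
#' Splits the sense codons into those with strictly positive
#' coefficient and the rest; a coefficient of exactly zero is assigned
#' to the non-positive group (a deterministic, measure-zero tie-break).
#' Codons with missing coefficients are dropped with a warning.
#'
#' @param vec A [CodonCorrelationVector-class] or named numeric vector
#'   over the sense codons.
#' @return A list with character vectors `positive`, `nonPositive`,
#'   `dropped`.
#' @examples
#' signPartition(c(AAA = 0.2, AAC = -0.1, AAG = 0))$positive
#' @export
signPartition <- function(vec) {
  v <- if (methods::is(vec, "CodonCorrelationVector")) codonValues(vec)
       else vec
  dropped <- names(v)[is.na(v)]
  if (length(dropped))
    warning(length(dropped), " codon(s) with missing coefficient dropped: ",
            paste(dropped, collapse = ", "))
  v <- v[!is.na(v)]
  list(positive = names(v)[v > 0], nonPositive = names(v)[v <= 0],
       dropped = dropped)
}

.chisq2x2 <- function(cells, correct) {
  suppressWarnings(stats::chisq.test(cells, correct = correct))
}

#' Chi-square test of CSC/CPC sign against codon optimality
#'
#' Tests whether codons with a positive correlation coefficient are
#' enriched for optimal codons: the sense codons are cross-classified
#' by coefficient sign ([signPartition()]) and binary optimality, and
#' the resulting 2x2 table is tested by a chi-square test with 1 degree
#' of freedom, Yates-corrected by default (`correct = FALSE` gives the
#' uncorrected statistic). Codons with missing coefficients are dropped
#' and `nCodons` adjusted accordingly. `contingencySummary()` is the
#' direct-entry form taking the marginal counts themselves, so
#' published summary tables can be re-tested without any sequence or
#' kinetic input.
#'
#' @param vec A [CodonCorrelationVector-class] (or named numeric vector).
#' @param classification An [OptimalityClassification-class].
#' @param correct Logical; apply the Yates continuity correction
#'   (default `TRUE`).
#' @param totalPos Number of codons with positive coefficient ("Total").
#' @param observed Number of optimal codons with positive coefficient
#'   ("Observed").
#' @param nOpt Number of optimal codons among those tested.
#' @param nCodons Number of codons tested (default 61).
#' @return A [ContingencySummary-class].
#' @examples
#' contingencySummary(totalPos = 26, observed = 22, nOpt = 28)
#' @export
chisqSignTest <- function(vec, classification, correct = TRUE) {
  part <- signPartition(vec)
  opt <- isOptimal(classification)
  opt <- opt[setdiff(names(opt), part$dropped)]
  if (!any(opt) || all(opt))
    stop("both optimality classes must be non-empty among tested codons")
  nCodons <- length(opt)
  totalPos <- length(part$positive)
  observed <- sum(opt[part$positive])
  contingencySummary(totalPos, observed, sum(opt), nCodons, correct)
}

#' @rdname chisqSignTest
#' @export
contingencySummary <- function(totalPos, observed, nOpt, nCodons = 61,
                               correct = TRUE) {
  obj <- new("ContingencySummary", totalPos = as.integer(totalPos),
             observed = as.integer(observed), nOpt = as.integer(nOpt),
             nCodons = as.integer(nCodons),
             expected = nOpt * totalPos / nCodons,
             chi2 = NA_real_, p = NA_real_, corrected = correct)
  cells <- contingencyCells(obj)
  if (any(rowSums(cells) == 0) || any(colSums(cells) == 0))
    stop("zero marginal: all codons in one sign or one optimality class; ",
         "test undefined")
  ht <- .chisq2x2(cells, correct)
  obj@chi2 <- unname(ht$statistic)
  obj@p <- ht$p.value
  obj
}

## ---------------------------------------------------------------------------
## Frameshift control
## ---------------------------------------------------------------------------

#' Frameshift control for codon-level correlations
#'
#' Recomputes the per-codon correlation vector (CSC or CPC) after
#' computationally shifting the reading frame by 0, +1 and +2
#' nucleotides, and correlates each vector with the per-codon
#' adaptiveness weights. A genuine codon-identity signal is positive in
#' frame 0 and collapses toward zero in the shifted frames; a signal
#' driven by nucleotide composition would survive the shifts.
#'
#' @param seqs Named `DNAStringSet` of coding sequences.
#' @param values Named per-gene kinetic vector (half-lives for CSC,
#'   synthesis rates for CPC).
#' @param weights An [AdaptivenessWeights-class] (or named numeric
#'   vector over the sense codons).
#' @param shifts Integer frame offsets to evaluate (default `0:2`).
#' @param kind `"CSC"` or `"CPC"`.
#' @return A data frame with one row per shift: `shift`, `rho`, `p`,
#'   `n` (codons correlated), plus the correlation vectors as the
#'   `"vectors"` attribute.
#' @examples
#' set.seed(1)
#' sim <- simulateStudy(simulationConfig(nGenes = 60, seed = 1))
#' hl <- setNames(sim$kinetics$half_life_min, sim$kinetics$gene_id)
#' frameshiftControl(sim$sequences, hl, sim$weights)
#' @export
frameshiftControl <- function(seqs, values, weights, shifts = 0:2,
                              kind = c("CSC", "CPC")) {
  kind <- match.arg(kind)
  w <- .weightsVector(weights)
  vecs <- list()
  rows <- lapply(shifts, function(sh) {
    freq <- codonFrequencyMatrix(seqs, shift = sh)
    vec <- .codonCorrelation(freq, values, kind, sh)
    vecs[[as.character(sh)]] <<- vec
    r <- spearmanTest(codonValues(vec), w)
    data.frame(shift = sh, rho = rho(r), p = pValue(r), n = nObs(r))
  })
  out <- do.call(rbind, rows)
  attr(out, "vectors") <- vecs
  out
}
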