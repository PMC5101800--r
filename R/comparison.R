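## Cross-dataset comparison of kinetic measurements: absolute half-life
## and synthesis-rate scales differ substantially between laboratories
## and protocols, but rank agreement is informative, so comparisons are
## rank-based and pairwise-complete.

#' Pairwise Spearman correlation matrix across datasets
#'
#' Correlates every pair of dataset columns of a gene-by-dataset value
#' matrix using Spearman correlation on pairwise-complete genes. Pairs
#' with fewer than 3 common genes get `NA` with a warning. The per-pair
#' sample sizes are returned alongside.
#'
#' @param mat Numeric matrix: genes (rows, named) by datasets (columns,
#'   uniquely named); `NA` for unmeasured genes.
#' @return A list with `rho` (symmetric correlation matrix, unit
#'   diagonal) and `n` (matrix of complete-pair counts).
#' @examples
#' m <- cbind(a = 1:6, b = c(2, 1, 4, 3, 6, 5), c = 6:1)
#' pairwiseSpearmanMatrix(m)$rho
#' @export
pairwiseSpearmanMatrix <- function(mat) {
  if (is.null(colnames(mat)) || anyDuplicated(colnames(mat)))
    stop("dataset columns must be uniquely named")
  k <- ncol(mat)
  rhoM <- diag(1, k)
  nM <- matrix(0L, k, k)
  dimnames(rhoM) <- dimnames(nM) <- list(colnames(mat), colnames(mat))
  diag(nM) <- colSums(!is.na(mat))
  for (i in seq_len(k - 1L)) for (j in seq((i + 1L), k)) {
    ok <- stats::complete.cases(mat[, i], mat[, j])
    nM[i, j] <- nM[j, i] <- sum(ok)
    if (sum(ok) < 3L) {
      warning("fewer than 3 common genes for pair ", colnames(mat)[i],
              " / ", colnames(mat)[j], "; correlation set to NA")
      rhoM[i, j] <- rhoM[j, i] <- NA_real_
    } else {
      rhoM[i, j] <- rhoM[j, i] <-
        .spearmanRho(rank(mat[ok, i]), rank(mat[ok, j]))
    }
  }
  list(rho = rhoM, n = nM)
}

#' Hierarchically cluster datasets by their correlation profiles
#'
#' Agglomerative clustering of the rows of a complete correlation
#' matrix using Euclidean distance between correlation-vector rows,
#' complete linkage by default (configurable). Ties are broken
#' deterministically by input order (the behaviour of [stats::hclust()]
#' on an ordered dissimilarity). The merge tree is also rendered as a
#' newick string.
#'
#' @param corrMat Complete (no `NA`) symmetric correlation matrix with
#'   named rows.
#' @param method Linkage passed to [stats::hclust()] (default
#'   `"complete"`).
#' @return A list with `order` (leaf labels in dendrogram order),
#'   `hclust` (the fitted tree) and `newick` (merge tree as a newick
#'   string).
#' @examples
#' m <- cbind(a = 1:6, b = c(2, 1, 4, 3, 6, 5), c = 6:1)
#' co <- clusterOrder(pairwiseSpearmanMatrix(m)$rho)
#' co$order
#' @export
clusterOrder <- function(corrMat, method = "complete") {
  if (anyNA(corrMat))
    stop("correlation matrix contains missing cells; subset to datasets ",
         "with sufficient overlap (or impute) before clustering")
  if (nrow(corrMat) < 2L) stop("need at least 2 datasets to cluster")
  hc <- stats::hclust(stats::dist(corrMat), method = method)
  list(order = hc$labels[hc$order], hclust = hc,
       newick = ape::write.tree(ape::as.phylo(hc)))
}

#' Per-dataset distribution summaries
#'
#' Five-number summaries (minimum, quartiles, median, maximum) plus
#' sample size per dataset column, with quartiles computed by linear
#' interpolation (quantile type 7, configurable). Datasets can then be
#' ordered by median; the sort is stable under ties.
#'
#' @param mat Gene-by-dataset value matrix.
#' @param type Quantile type passed to [stats::quantile()].
#' @param sortByMedian Logical; order rows by increasing median.
#' @return A data frame with columns `dataset`, `n`, `min`, `q1`,
#'   `median`, `q3`, `max` (all-`NA` columns yield `NA` summaries).
#' @examples
#' m <- cbind(a = 1:5, b = c(5, 5, 5, 5, 5))
#' datasetSummary(m)
#' @export
datasetSummary <- function(mat, type = 7, sortByMedian = FALSE) {
  rows <- lapply(colnames(mat), function(ds) {
    x <- mat[, ds]
    x <- x[!is.na(x)]
    if (!length(x))
      return(data.frame(dataset = ds, n = 0L, min = NA_real_,
                        q1 = NA_real_, median = NA_real_, q3 = NA_real_,
                        max = NA_real_))
    q <- stats::quantile(x, c(0, 0.25, 0.5, 0.75, 1), type = type,
                         names = FALSE)
    data.frame(dataset = ds, n = length(x), min = q[1], q1 = q[2],
               median = q[3], q3 = q[4], max = q[5])
  })
  out <- do.call(rbind, rows)
  if (sortByMedian) out <- out[order(out$median), , drop = FALSE]
  rownames(out) <- NULL
  out
}
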