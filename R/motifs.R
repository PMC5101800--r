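#' @include AllClasses.R
NULL

## Motif annotations are tidy data frames with columns
## motif_id, location ("promoter" / "5UTR" / "3UTR"), rate (the kinetic
## association the motif was discovered with, e.g. "long half-life"),
## gene_id, count (number of significant instances in that gene).

#' Read a gene-by-motif annotation table
#'
#' Reads a tab-separated motif instance table with columns `gene_id`,
#' `motif_id`, `location`, `count` and optionally `rate`. A gene
#' "contains" a motif when its significant-instance count is >= 1.
#'
#' @param file Path to the TSV file.
#' @return A data frame of motif annotations.
#' @seealso [groupMotifVariants()], [motifAssociationTable()]
#' @export
readMotifTable <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  need <- c("gene_id", "motif_id", "location", "count")
  if (!all(need %in% names(df)))
    stop("motif table must have columns ", paste(need, collapse = ", "))
  if (any(df$count < 0)) stop("motif instance counts must be >= 0")
  df
}

#' Default motif-variant groupings
#'
#' AU-rich 3' UTR motif variants that are conventionally pooled before
#' testing: TATTTAT/TATTTA/ATTTAT (reported as TATTTAT) and
#' TTAATGA/TTAATG/TAATGA (reported as TTAATGA).
#'
#' @return A named list of character vectors of member motif ids.
#' @export
defaultMotifGroups <- function() {
  list(TATTTAT = c("TATTTAT", "TATTTA", "ATTTAT"),
       TTAATGA = c("TTAATGA", "TTAATG", "TAATGA"))
}

#' Pool motif sequence variants into groups
#'
#' Replaces the member motifs of each group by a single grouped motif
#' whose per-gene instance counts are the element-wise sums of the
#' members' counts. Members of a group must share the same location
#' annotation. Motifs not named in any group pass through unchanged;
#' grouping a single motif is the identity.
#'
#' @param annotations Motif annotation data frame (see
#'   [readMotifTable()]).
#' @param groups Named list: group id -> character vector of member
#'   motif ids (default [defaultMotifGroups()]).
#' @return The annotation data frame with grouped motifs.
#' @examples
#' ann <- data.frame(gene_id = c("g1", "g1", "g2"),
#'                   motif_id = c("TATTTAT", "TATTTA", "TATTTA"),
#'                   location = "3UTR", count = c(1, 1, 2))
#' groupMotifVariants(ann)
#' @export
groupMotifVariants <- function(annotations, groups = defaultMotifGroups()) {
  for (gid in names(groups)) {
    members <- groups[[gid]]
    hit <- annotations$motif_id %in% members
    if (!any(hit)) next
    sub <- annotations[hit, , drop = FALSE]
    if (length(unique(sub$location)) > 1L)
      stop("members of group '", gid, "' have different locations: ",
           paste(unique(sub$location), collapse = ", "))
    agg <- stats::aggregate(count ~ gene_id, data = sub, FUN = sum)
    agg$motif_id <- gid
    agg$location <- sub$location[1L]
    if ("rate" %in% names(annotations))
      agg$rate <- sub$rate[1L]
    annotations <- rbind(annotations[!hit, , drop = FALSE],
                         agg[, names(annotations), drop = FALSE])
  }
  rownames(annotations) <- NULL
  annotations
}

#' One-sided rank-sum test of a motif against gene-level optimality
#'
#' Wilcoxon rank-sum test comparing a gene-level codon optimality score
#' (tAI_g or percent optimal codons) between background genes that
#' carry the motif (instance count >= 1) and background genes that lack
#' it, with the stated one-sided alternative (`"greater"`: motif-bearing
#' genes score higher). Average ranks are used for ties and the p-value
#' comes from the normal approximation with tie correction and
#' continuity correction.
#'
#' @param scores Named numeric vector of gene-level scores.
#' @param motifGenes Character vector of genes carrying the motif.
#' @param background Character vector: the background gene set (e.g.
#'   genes with both half-life and synthesis-rate estimates). Defaults
#'   to all score names.
#' @param direction `"greater"` or `"less"`.
#' @param motifId Motif label for error messages and the result.
#' @return A [MotifTestResult-class] (Bonferroni slot `NA`; see
#'   [bonferroni()] and [motifAssociationTable()]).
#' @examples
#' scores <- setNames(c(5, 6, 7, 8, 1, 2, 3, 4), paste0("g", 1:8))
#' motifWilcoxon(scores, paste0("g", 1:4), direction = "greater")
#' @export
motifWilcoxon <- function(scores, motifGenes, background = names(scores),
                          direction = c("greater", "less"),
                          motifId = "motif") {
  direction <- match.arg(direction)
  background <- intersect(background, names(scores)[!is.na(scores)])
  withM <- intersect(background, motifGenes)
  withoutM <- setdiff(background, motifGenes)
  if (!length(withM) || !length(withoutM))
    stop("empty gene group for motif '", motifId,
         "' (with: ", length(withM), ", without: ", length(withoutM), ")")
  ht <- suppressWarnings(stats::wilcox.test(
    scores[withM], scores[withoutM], alternative = direction,
    exact = FALSE, correct = TRUE))
  new("MotifTestResult", motifId = motifId, direction = direction,
      statistic = unname(ht$statistic), pRaw = ht$p.value,
      pBonferroni = NA_real_, nWith = length(withM),
      nWithout = length(withoutM))
}

#' Bonferroni correction
#'
#' Multiplies p-values by the family size `m` and caps at 1. `m` must
#' be at least the number of p-values in the family.
#'
#' @param p Numeric vector of raw p-values.
#' @param m Family size.
#' @return Corrected p-values, `pmin(1, m * p)`.
#' @examples
#' bonferroni(c(0.01, 0.2), m = 12)
#' @export
bonferroni <- function(p, m) {
  if (m < length(p))
    stop("family size m (", m, ") is smaller than the number of tests (",
         length(p), ")")
  pmin(1, p * m)
}

#' Motif-by-direction association table
#'
#' Runs [motifWilcoxon()] for every motif in an annotation table, in
#' both directions, for each supplied gene-level score metric, and
#' Bonferroni-corrects within each metric. The default family size is
#' the number of motif-direction tests per metric, configurable because
#' the exact published family is a reporting convention, not a derived
#' quantity.
#'
#' @param scoreList Named list of named numeric score vectors (e.g.
#'   `list(tai_g = ..., pct_optimal_cTE = ...)`).
#' @param annotations Motif annotation data frame (after
#'   [groupMotifVariants()] if variants should be pooled).
#' @param background Background gene set.
#' @param m Bonferroni family size per metric (default: number of
#'   motifs x 2 directions).
#' @return A data frame with one row per motif: `motif_id`, `location`,
#'   `rate` (if annotated), and `<metric>_greater` / `<metric>_less`
#'   Bonferroni-corrected p-value columns.
#' @examples
#' set.seed(1)
#' sim <- simulateStudy(simulationConfig(nGenes = 80, seed = 1))
#' counts <- codonCountMatrix(sim$sequences)
#' scores <- list(tai_g = taiG(counts, sim$weights))
#' motifAssociationTable(scores, sim$motifs, rownames(counts))
#' @export
motifAssociationTable <- function(scoreList, annotations, background,
                                  m = NULL) {
  ids <- unique(annotations$motif_id)
  if (is.null(m)) m <- 2L * length(ids)
  meta <- annotations[!duplicated(annotations$motif_id),
                      intersect(c("motif_id", "location", "rate"),
                                names(annotations)), drop = FALSE]
  out <- meta[match(ids, meta$motif_id), , drop = FALSE]
  for (metric in names(scoreList)) {
    scores <- scoreList[[metric]]
    for (dir in c("greater", "less")) {
      praw <- vapply(ids, function(id) {
        genes <- annotations$gene_id[annotations$motif_id == id &
                                       annotations$count >= 1]
        pValue(motifWilcoxon(scores, genes, background, dir, motifId = id))
      }, numeric(1L))
      out[[paste0(metric, "_", dir)]] <- bonferroni(praw, m)
    }
  }
  rownames(out) <- NULL
  out
}
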