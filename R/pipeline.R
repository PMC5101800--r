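#' @include simulate.R association.R motifs.R comparison.R kinetics.R
NULL

#' Published sign-by-optimality contingency marginals
#'
#' Loads the bundled table of published contingency marginals for the
#' codon optimality association in budding and fission yeast: for each
#' kinetic dataset, rate type (half-life based CSC or synthesis-rate
#' based CPC) and optimality metric (cTE/nTE), the number of codons
#' with a positive coefficient (`total_positive`), the number of
#' optimal codons among them (`observed_optimal`), and the number of
#' codons classified optimal (`n_optimal`), out of 61 sense codons.
#' These marginals fully determine the 2x2 tables, so the expected
#' counts and chi-square tests can be recomputed with
#' [contingencySummary()] without access to the underlying sequence or
#' kinetic data.
#'
#' @return A data frame with columns `organism`, `rate`, `dataset`,
#'   `metric`, `total_positive`, `observed_optimal`, `n_optimal`.
#' @examples
#' marg <- yeastContingencyMarginals()
#' row <- subset(marg, dataset == "Gagneur" & rate == "half_life" &
#'               metric == "cTE")
#' contingencySummary(row$total_positive, row$observed_optimal,
#'                    row$n_optimal)
#' @export
yeastContingencyMarginals <- function() {
  f <- system.file("extdata", "yeast_contingency_marginals.tsv",
                   package = "codonStability", mustWork = TRUE)
  utils::read.delim(f, stringsAsFactors = FALSE)
}

#' Recompute chi-square tests for a table of contingency marginals
#'
#' Applies [contingencySummary()] to every row of a marginals table
#' (see [yeastContingencyMarginals()]) and returns the expanded table
#' with the recomputed expected counts, chi-square statistics and
#' p-values.
#'
#' @param marginals Data frame with columns `total_positive`,
#'   `observed_optimal`, `n_optimal` (and any identifying columns).
#' @param nCodons Number of codons tested (default 61).
#' @param correct Apply the Yates continuity correction (default
#'   `TRUE`).
#' @return The input with columns `expected`, `chi2`, `p` appended.
#' @examples
#' head(contingencyTable(yeastContingencyMarginals()))
#' @export
contingencyTable <- function(marginals, nCodons = 61, correct = TRUE) {
  res <- lapply(seq_len(nrow(marginals)), function(i) {
    s <- contingencySummary(marginals$total_positive[i],
                            marginals$observed_optimal[i],
                            marginals$n_optimal[i], nCodons, correct)
    data.frame(expected = s@expected, chi2 = s@chi2, p = s@p)
  })
  cbind(marginals, do.call(rbind, res))
}

## ---------------------------------------------------------------------------
## End-to-end pipeline on synthetic (or user-supplied) data
## ---------------------------------------------------------------------------

#' Write the artifacts of a synthetic study
#'
#' Writes the FASTA, kinetic, motif and truth tables of a
#' [simulateStudy()] bundle in the same plain-text formats the analysis
#' functions read.
#'
#' @param sim A [simulateStudy()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths written.
#' @export
writeSyntheticStudy <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fasta = file.path(dir, "cds.fa"),
             kinetics = file.path(dir, "kinetics.tsv"),
             motifs = file.path(dir, "motifs.tsv"),
             truth = file.path(dir, "truth.tsv"),
             weights = file.path(dir, "weights.tsv"),
             classification = file.path(dir, "classification.tsv"))
  Biostrings::writeXStringSet(sim$sequences, paths["fasta"])
  wt <- function(df, p) utils::write.table(df, p, sep = "\t",
                                           quote = FALSE, row.names = FALSE)
  wt(sim$kinetics, paths["kinetics"])
  wt(sim$motifs, paths["motifs"])
  wt(sim$truth, paths["truth"])
  wt(data.frame(codon = senseCodons(),
                weight = unname(adaptiveness(sim$weights))),
     paths["weights"])
  wt(data.frame(codon = senseCodons(),
                metric = sim$classification@metric,
                optimal = as.integer(isOptimal(sim$classification))),
     paths["classification"])
  invisible(paths)
}

#' Run the full association pipeline
#'
#' Orchestrates every analysis stage on one study (by default a
#' synthetic one): codon counting, gene-level optimality scores,
#' CSC/CPC vectors, the sign-partition chi-square tests, partial
#' correlations controlling for abundance, frameshift controls and
#' motif association tests, writing each result as a TSV artifact plus
#' a machine-readable JSON run log (inputs, package version, seed,
#' configuration hash).
#'
#' @param config A [simulationConfig()]; its `seed` drives all
#'   randomness.
#' @param outDir Output directory for artifacts.
#' @param sim Optionally a pre-built [simulateStudy()] bundle (the
#'   config is then ignored for generation but still logged).
#' @return Invisibly, a list with every computed result and the paths
#'   of the written artifacts.
#' @examples
#' res <- runPipeline(simulationConfig(nGenes = 60, seed = 2),
#'                    outDir = tempfile())
#' res$contingency
#' @export
runPipeline <- function(config = simulationConfig(), outDir = "results",
                        sim = NULL) {
  if (is.null(sim)) sim <- simulateStudy(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    p <- file.path(outDir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }

  counts <- codonCountMatrix(sim$sequences)
  freq <- .frequenciesFromCounts(counts)
  hl <- stats::setNames(sim$kinetics$half_life_min, sim$kinetics$gene_id)
  mu <- stats::setNames(sim$kinetics$synthesis_rate, sim$kinetics$gene_id)
  m <- stats::setNames(sim$kinetics$abundance, sim$kinetics$gene_id)

  opt <- geneOptimality(counts, sim$weights, list(sim$classification))
  csc <- computeCsc(freq, hl)
  cpc <- computeCpc(freq, mu)
  chisq <- list(CSC = chisqSignTest(csc, sim$classification),
                CPC = chisqSignTest(cpc, sim$classification))
  tai <- stats::setNames(opt$tai_g, opt$gene_id)
  partial <- list(
    half_life = partialSpearman(tai[names(hl)], hl, m[names(hl)],
                                controlled = "abundance"),
    synthesis = partialSpearman(tai[names(mu)], mu, m[names(mu)],
                                controlled = "abundance"))
  fsCsc <- frameshiftControl(sim$sequences, hl, sim$weights, kind = "CSC")
  motifs <- motifAssociationTable(
    list(tai_g = tai,
         pct_optimal = stats::setNames(
           opt[[paste0("pct_optimal_", sim$classification@metric)]],
           opt$gene_id)),
    sim$motifs, background = opt$gene_id)

  paths <- character(0)
  paths["gene_optimality"] <- wt(opt, "gene_optimality.tsv")
  codonTab <- data.frame(codon = senseCodons(),
                         csc = unname(codonValues(csc)),
                         cpc = unname(codonValues(cpc)),
                         n = unname(csc@ns))
  paths["codon_correlations"] <- wt(codonTab, "codon_correlations.tsv")
  chisqTab <- data.frame(
    kind = names(chisq),
    total_positive = vapply(chisq, function(s) s@totalPos, integer(1L)),
    observed_optimal = vapply(chisq, function(s) s@observed, integer(1L)),
    expected = vapply(chisq, function(s) s@expected, numeric(1L)),
    p = vapply(chisq, pValue, numeric(1L)))
  paths["contingency"] <- wt(chisqTab, "contingency.tsv")
  partialTab <- data.frame(
    pair = paste0("tai_g~", names(partial)),
    rho = vapply(partial, rho, numeric(1L)),
    p = vapply(partial, pValue, numeric(1L)),
    n = vapply(partial, nObs, integer(1L)),
    controlled = "abundance")
  paths["partial_correlations"] <- wt(partialTab, "partial_correlations.tsv")
  paths["frameshift_control"] <- wt(fsCsc, "frameshift_control.tsv")
  paths["motif_tests"] <- wt(motifs, "motif_tests.tsv")

  log <- list(package = "codonStability",
              version = as.character(utils::packageVersion("codonStability")),
              seed = sim$config$seed,
              config = unclass(sim$config),
              config_hash = .configHash(sim$config),
              n_genes = nrow(opt),
              artifacts = as.list(paths))
  logPath <- file.path(outDir, "run_log.json")
  jsonlite::write_json(log, logPath, auto_unbox = TRUE, pretty = TRUE)
  paths["run_log"] <- logPath

  invisible(list(sim = sim, counts = counts, optimality = opt, csc = csc,
                 cpc = cpc, contingency = chisqTab, partial = partialTab,
                 frameshift = fsCsc, motifs = motifs, paths = paths))
}

## md5 of the deparsed configuration; identifies a run in the log.
.configHash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(deparse(unclass(config)), tf)
  unname(tools::md5sum(tf))
}
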