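#' @include optimality.R
NULL

## ---------------------------------------------------------------------------
## Simulation configuration
## ---------------------------------------------------------------------------

#' Configuration for the synthetic study generator
#'
#' Bundles the tunable parameters of the synthetic-data module, which
#' generates genomes and kinetic tables with a known, adjustable
#' coupling between codon optimality and mRNA kinetics under the
#' steady-state model. Defaults describe a compact yeast-like study:
#' 500 genes of 100-500 codons, half-lives around 20 min with
#' log-normal spread, synthesis rates around 0.1 molecules/min/cell,
#' and 28 of 61 codons classified optimal.
#'
#' @param nGenes Number of genes (>= 10).
#' @param geneLengthRange Range of body lengths in codons (>= 30); the
#'   emitted CDS adds a start codon and a stop codon.
#' @param tiltBeta Strength of the within-family exponential tilt of
#'   codon sampling toward high-weight codons for high-optimality
#'   genes; 0 decouples codon usage from everything downstream.
#' @param couplingBeta Slope of log half-life (or, in the
#'   abundance-mediated regime, log abundance) on the latent per-gene
#'   optimality score `u`.
#' @param synthesisCoupling Slope of log synthesis rate on `u` (direct
#'   regime only).
#' @param noiseSd Standard deviation of the log-normal noise on kinetic
#'   quantities (>= 0).
#' @param alpha Growth-dilution rate \[min^-1\].
#' @param couplingVia `"direct"` (optimality drives half-life and
#'   synthesis, abundance follows from steady state) or `"abundance"`
#'   (optimality drives abundance and half-life tracks abundance, so
#'   pairwise optimality-half-life association exists but vanishes when
#'   abundance is controlled for).
#' @param motifEffectDelta Logit-scale effect of `u` on the presence
#'   probability of stabilizing motifs; 0 gives null motifs.
#' @param nOpt Number of codons classified optimal (default 28, a
#'   fission-yeast-like split of the 61 sense codons).
#' @param baseHalfLife,baseSynthesis,baseAbundance Median scales:
#'   minutes, molecules/min/cell, molecules/cell.
#' @param nStabilizing,nDestabilizing Numbers of stabilizing
#'   (optimality-coupled) and destabilizing (null) motifs.
#' @param seed Integer seed used by [simulateStudy()].
#' @return A list of class `"simulationConfig"`.
#' @seealso [simulateStudy()]
#' @examples
#' simulationConfig(nGenes = 100, seed = 7)$nGenes
#' @export
simulationConfig <- function(nGenes = 500, geneLengthRange = c(100, 500),
                             tiltBeta = 2, couplingBeta = 1.5,
                             synthesisCoupling = 1, noiseSd = 0.5,
                             alpha = 0,
                             couplingVia = c("direct", "abundance"),
                             motifEffectDelta = 2, nOpt = 28,
                             baseHalfLife = 20, baseSynthesis = 0.1,
                             baseAbundance = 10, nStabilizing = 3,
                             nDestabilizing = 3, seed = 1) {
  couplingVia <- match.arg(couplingVia)
  if (nGenes < 10) stop("nGenes must be at least 10")
  if (length(geneLengthRange) != 2L || any(geneLengthRange < 30) ||
      geneLengthRange[1] > geneLengthRange[2])
    stop("geneLengthRange must be an increasing pair of lengths >= 30")
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  if (nOpt < 1 || nOpt > 60) stop("nOpt must leave both classes non-empty")
  structure(list(nGenes = as.integer(nGenes),
                 geneLengthRange = as.integer(geneLengthRange),
                 tiltBeta = tiltBeta, couplingBeta = couplingBeta,
                 synthesisCoupling = synthesisCoupling, noiseSd = noiseSd,
                 alpha = alpha, couplingVia = couplingVia,
                 motifEffectDelta = motifEffectDelta,
                 nOpt = as.integer(nOpt), baseHalfLife = baseHalfLife,
                 baseSynthesis = baseSynthesis,
                 baseAbundance = baseAbundance,
                 nStabilizing = as.integer(nStabilizing),
                 nDestabilizing = as.integer(nDestabilizing),
                 seed = as.integer(seed)),
            class = "simulationConfig")
}

## ---------------------------------------------------------------------------
## Component generators (consume the current RNG state; simulateStudy
## seeds once from config$seed)
## ---------------------------------------------------------------------------

#' Simulate adaptiveness weights and an optimality classification
#'
#' Draws per-codon adaptiveness weights from a right-skewed Beta(1.2,
#' 1.8) rescaled to maximum 1, and classifies the top `nOpt` codons by
#' weight as optimal (ties broken by canonical codon order).
#'
#' @param config A [simulationConfig()].
#' @return A list with `weights` ([AdaptivenessWeights-class]) and
#'   `classification` ([OptimalityClassification-class]).
#' @export
simulateWeights <- function(config) {
  raw <- stats::rbeta(61L, 1.2, 1.8)
  w <- stats::setNames(raw / max(raw), .SENSE_CODONS)
  top <- order(-w, .SENSE_CODONS)[seq_len(config$nOpt)]
  cls <- optimalityClassification(.SENSE_CODONS[top], metric = "cTE")
  list(weights = AdaptivenessWeights(w, "computed"), classification = cls)
}

#' Simulate a genome with optimality-tilted codon usage
#'
#' Draws a latent optimality score `u_g ~ Uniform(0, 1)` per gene and
#' samples each gene's codons with an exponential tilt toward
#' high-weight codons, `p_c` proportional to `exp(tiltBeta * u_g * w_c)`
#' within each synonymous family; amino-acid family probabilities are
#' proportional to family size and identical for all genes, so the tilt
#' changes only synonymous codon choice. Each CDS is emitted as a start
#' codon, the sampled body, and a TAA stop, so it passes strict parsing.
#'
#' @param config A [simulationConfig()].
#' @param weights An [AdaptivenessWeights-class] (e.g. from
#'   [simulateWeights()]).
#' @return A list with `sequences` (named `DNAStringSet`) and `truth`
#'   (data frame `gene_id`, `u`, `length_codons`).
#' @export
simulateGenome <- function(config, weights) {
  w <- .weightsVector(weights)
  n <- config$nGenes
  u <- stats::runif(n)
  aa <- codonAminoAcids()
  famSize <- table(aa)[aa]                  # per codon: its family size
  lens <- config$geneLengthRange[1] +
    sample.int(diff(config$geneLengthRange) + 1L, n, replace = TRUE) - 1L
  ids <- sprintf("g%04d", seq_len(n))
  seqs <- character(n)
  for (g in seq_len(n)) {
    tilt <- exp(config$tiltBeta * u[g] * w)
    famTot <- vapply(split(tilt, aa), sum, numeric(1L))[aa]
    p <- (as.numeric(famSize) / 61) * tilt / famTot
    body <- sample(.SENSE_CODONS, lens[g], replace = TRUE, prob = p)
    seqs[g] <- paste0("ATG", paste(body, collapse = ""), "TAA")
  }
  list(sequences = Biostrings::DNAStringSet(stats::setNames(seqs, ids)),
       truth = data.frame(gene_id = ids, u = u, length_codons = lens))
}

#' Simulate steady-state-consistent kinetic records
#'
#' Generates half-lives, synthesis rates and abundances coupled to the
#' latent optimality score. In the direct regime,
#' `log hl = log(baseHalfLife) + couplingBeta * (u - 1/2) + e` and
#' `log mu = log(baseSynthesis) + synthesisCoupling * (u - 1/2) + e'`
#' with independent Normal(0, noiseSd) noise, and abundance is derived
#' exactly as `m = mu / (alpha + ln(2)/hl)`. In the abundance-mediated
#' regime, `u` drives log abundance, half-life tracks log abundance
#' with unit elasticity plus noise, and the synthesis rate is derived
#' from the steady state; every emitted record satisfies
#' `mu = m * (alpha + lambda)` exactly.
#'
#' @param truth Data frame with `gene_id` and `u` (see
#'   [simulateGenome()]).
#' @param config A [simulationConfig()].
#' @return A data frame `gene_id`, `half_life_min`, `synthesis_rate`,
#'   `abundance`.
#' @export
simulateKinetics <- function(truth, config) {
  u <- truth$u
  n <- length(u)
  if (config$couplingVia == "direct") {
    hl <- exp(log(config$baseHalfLife) + config$couplingBeta * (u - 0.5) +
                stats::rnorm(n, 0, config$noiseSd))
    mu <- exp(log(config$baseSynthesis) +
                config$synthesisCoupling * (u - 0.5) +
                stats::rnorm(n, 0, config$noiseSd))
    m <- mu / (config$alpha + log(2) / hl)
  } else {
    lm_ <- log(config$baseAbundance) + config$couplingBeta * (u - 0.5) +
      stats::rnorm(n, 0, config$noiseSd)
    m <- exp(lm_)
    hl <- exp(log(config$baseHalfLife) + (lm_ - log(config$baseAbundance)) +
                stats::rnorm(n, 0, config$noiseSd))
    mu <- m * (config$alpha + log(2) / hl)
  }
  data.frame(gene_id = truth$gene_id, half_life_min = hl,
             synthesis_rate = mu, abundance = m)
}

#' Simulate motif annotations coupled to optimality
#'
#' Assigns stabilizing motifs (promoter/5' UTR, associated with long
#' half-life or fast synthesis) with presence probability increasing in
#' the latent optimality score on the logit scale by
#' `motifEffectDelta`, and destabilizing 3' UTR motifs independently of
#' it (null motifs). Instance counts for present motifs are
#' `1 + Poisson(0.5)`.
#'
#' @param truth Data frame with `gene_id` and `u`.
#' @param config A [simulationConfig()].
#' @return A motif annotation data frame (`gene_id`, `motif_id`,
#'   `location`, `rate`, `count`) listing genes with count >= 1.
#' @export
simulateMotifs <- function(truth, config) {
  u <- truth$u
  n <- length(u)
  base <- stats::qlogis(0.3)
  one <- function(id, location, rate, p) {
    present <- stats::rbinom(n, 1L, p) == 1L
    if (!any(present)) return(NULL)
    data.frame(gene_id = truth$gene_id[present], motif_id = id,
               location = location, rate = rate,
               count = 1L + stats::rpois(sum(present), 0.5))
  }
  rows <- list()
  for (i in seq_len(config$nStabilizing)) {
    p <- stats::plogis(base + config$motifEffectDelta * (u - 0.5))
    loc <- c("promoter", "5UTR")[1L + i %% 2L]
    rate <- c("long half-life", "fast synthesis")[1L + i %% 2L]
    rows[[length(rows) + 1L]] <-
      one(sprintf("stab_%s_%d", loc, i), loc, rate, p)
  }
  for (i in seq_len(config$nDestabilizing))
    rows[[length(rows) + 1L]] <-
      one(sprintf("destab_3UTR_%d", i), "3UTR", "short half-life",
          stats::plogis(base))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a complete synthetic study
#'
#' Seeds the RNG from `config$seed` and generates weights, a
#' classification, a genome, kinetics and motif annotations as one
#' reproducible bundle: identical configurations give identical output.
#'
#' @param config A [simulationConfig()].
#' @return A list with elements `config`, `weights`, `classification`,
#'   `sequences`, `truth` (latent scores joined with the realized
#'   gene-level tAI), `kinetics`, `motifs`.
#' @examples
#' sim <- simulateStudy(simulationConfig(nGenes = 50, seed = 3))
#' head(sim$truth)
#' @export
simulateStudy <- function(config = simulationConfig()) {
  set.seed(config$seed)
  wcls <- simulateWeights(config)
  genome <- simulateGenome(config, wcls$weights)
  kin <- simulateKinetics(genome$truth, config)
  motifs <- simulateMotifs(genome$truth, config)
  counts <- codonCountMatrix(genome$sequences)
  truth <- genome$truth
  truth$tai_g <- unname(taiG(counts, wcls$weights)[truth$gene_id])
  list(config = config, weights = wcls$weights,
       classification = wcls$classification,
       sequences = genome$sequences, truth = truth, kinetics = kin,
       motifs = motifs)
}
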