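## Steady-state mRNA kinetics. Under balanced synthesis and loss,
##   mu = m * (alpha + lambda),   lambda = ln(2) / hl,
## with mu the synthesis rate [molecules min^-1 cell^-1], m the abundance
## [molecules cell^-1], hl the half-life [min], and alpha the growth
## (dilution) rate [min^-1], alpha = ln(2) / cell-cycle-length. All
## conversions propagate missing values and never impute.

#' Steady-state kinetic conversions
#'
#' `decayRate()` converts half-lives to first-order decay rates,
#' `lambda = ln(2)/hl`; `growthRate()` converts a cell-cycle length to
#' the dilution rate `alpha = ln(2)/ccl`; `synthesisRate()` computes the
#' steady-state synthesis rate `mu = m * (alpha + lambda)`; and
#' `halfLifeFrom()` inverts it, `hl = ln(2)/(mu/m - alpha)`. All
#' functions are vectorized; non-positive or missing inputs yield `NA`
#' (with a warning from `halfLifeFrom()` when `mu/m <= alpha`, which is
#' non-physical under steady state).
#'
#' @param hl mRNA half-life in minutes (> 0).
#' @param ccl Cell-cycle length in minutes (> 0).
#' @param m mRNA abundance in molecules per cell (>= 0).
#' @param alpha Growth rate per minute (>= 0); 0 for transcription
#'   shutoff conditions where growth is halted.
#' @param mu mRNA synthesis rate in molecules per minute per cell.
#' @return A numeric vector in the units stated above.
#' @examples
#' decayRate(1)                      # ln 2
#' growthRate(150)                   # yeast-like cell cycle
#' synthesisRate(m = 100, hl = 10)   # ~6.93 molecules/min/cell
#' halfLifeFrom(mu = 6.931, m = 100) # ~10 min
#' @export
decayRate <- function(hl) {
  out <- log(2) / hl
  out[!is.na(hl) & hl <= 0] <- NA_real_
  out
}

#' @rdname decayRate
#' @export
growthRate <- function(ccl) {
  if (anyNA(ccl)) stop("cell-cycle length is missing")
  if (any(ccl <= 0)) stop("cell-cycle length must be positive")
  log(2) / ccl
}

#' @rdname decayRate
#' @export
synthesisRate <- function(m, hl, alpha = 0) {
  m * (alpha + decayRate(hl))
}

#' @rdname decayRate
#' @export
halfLifeFrom <- function(mu, m, alpha = 0) {
  perMolecule <- mu / m
  out <- log(2) / (perMolecule - alpha)
  bad <- !is.na(perMolecule) & perMolecule <= alpha
  if (any(bad)) {
    warning(sum(bad), " record(s) with mu/m <= alpha set to NA ",
            "(non-physical under steady state)")
    out[bad] <- NA_real_
  }
  out
}

#' Scale relative abundances to a per-cell total
#'
#' Rescales relative mRNA abundance measurements (e.g. microarray
#' intensities) so that they sum to a total number of mRNA molecules
#' per cell (60,000 for budding yeast, 41,000 for fission yeast in the
#' package's organism profiles), preserving proportions. Missing values
#' are excluded from the normalizing sum and propagated.
#'
#' @param x Non-negative numeric vector of relative abundances.
#' @param total Target total number of molecules per cell.
#' @return Numeric vector summing to `total` over non-missing entries.
#' @examples
#' scaleAbundance(c(1, 1, 2), 41000)
#' @export
scaleAbundance <- function(x, total) {
  if (any(x < 0, na.rm = TRUE)) stop("relative abundances must be >= 0")
  s <- sum(x, na.rm = TRUE)
  if (s == 0) stop("all relative abundances are zero or missing")
  x / s * total
}

#' Dataset metadata for kinetic harmonization
#'
#' Describes one RNA kinetic dataset: the organism, the measurement
#' method, how the growth-dilution rate `alpha` is obtained (`"zero"`
#' for transcription-shutoff conditions or datasets computed without
#' accounting for cell division, `"from_ccl"` to derive it from the
#' cell-cycle length), and the per-cell mRNA total used to scale
#' relative abundances.
#'
#' @param name Dataset label.
#' @param organism Organism label, e.g. `"S. cerevisiae"`.
#' @param method One of `"shutoff"`, `"labeling"`, `"chase"`, `"GRO"`,
#'   `"ChIP"`.
#' @param alphaPolicy `"zero"` or `"from_ccl"`.
#' @param ccl Cell-cycle length in minutes (required when
#'   `alphaPolicy = "from_ccl"`).
#' @param totalMrnaPerCell Total mRNA molecules per cell, or `NA`.
#' @return A list of class `"datasetMeta"`.
#' @seealso [harmonizeKinetics()]
#' @examples
#' datasetMeta("chase-example", "S. cerevisiae", "chase",
#'             alphaPolicy = "from_ccl", ccl = 150)
#' @export
datasetMeta <- function(name, organism = c("S. cerevisiae", "S. pombe"),
                        method = c("labeling", "shutoff", "chase", "GRO",
                                   "ChIP"),
                        alphaPolicy = c("zero", "from_ccl"), ccl = NA_real_,
                        totalMrnaPerCell = NA_real_) {
  organism <- match.arg(organism)
  method <- match.arg(method)
  alphaPolicy <- match.arg(alphaPolicy)
  if (alphaPolicy == "from_ccl" && (is.na(ccl) || ccl <= 0))
    stop("alphaPolicy 'from_ccl' requires a positive cell-cycle length")
  structure(list(name = name, organism = organism, method = method,
                 alphaPolicy = alphaPolicy, ccl = ccl,
                 totalMrnaPerCell = totalMrnaPerCell),
            class = "datasetMeta")
}

#' Read a per-gene kinetic table
#'
#' Reads a tab-separated kinetic table with a header and columns
#' `gene_id` plus any of `half_life_min`, `synthesis_rate`, `abundance`.
#'
#' @param file Path to the TSV file.
#' @return A data frame with the available columns.
#' @export
readKineticTable <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  if (!"gene_id" %in% names(df))
    stop("kinetic table must have a 'gene_id' column")
  known <- c("gene_id", "half_life_min", "synthesis_rate", "abundance")
  df[, intersect(known, names(df)), drop = FALSE]
}

#' Harmonize a kinetic dataset under the steady-state model
#'
#' Completes a per-gene kinetic table to the common unit system: decay
#' rates `lambda` from half-lives, the growth rate `alpha` from the
#' dataset's policy, synthesis rates from abundance and half-life when
#' absent, and half-lives from synthesis rate and abundance when those
#' are what was measured. Abundance is rescaled to the dataset's
#' per-cell total when one is given. Missing inputs yield missing
#' outputs; nothing is imputed.
#'
#' @param records Data frame with `gene_id` and any of `half_life_min`,
#'   `synthesis_rate`, `abundance`.
#' @param meta A [datasetMeta()] object.
#' @param rescaleAbundance Logical; rescale abundance to
#'   `meta$totalMrnaPerCell` when available (default `TRUE`).
#' @return The input with columns `lambda`, `alpha` added and
#'   `half_life_min`/`synthesis_rate` completed where derivable.
#' @examples
#' rec <- data.frame(gene_id = "g1", half_life_min = 10, abundance = 100)
#' harmonizeKinetics(rec, datasetMeta("x", "S. pombe", "labeling"))
#' @export
harmonizeKinetics <- function(records, meta, rescaleAbundance = TRUE) {
  stopifnot(inherits(meta, "datasetMeta"))
  alpha <- if (meta$alphaPolicy == "zero") 0 else growthRate(meta$ccl)
  if (rescaleAbundance && !is.na(meta$totalMrnaPerCell) &&
      "abundance" %in% names(records))
    records$abundance <- scaleAbundance(records$abundance,
                                        meta$totalMrnaPerCell)
  if (is.null(records$half_life_min)) records$half_life_min <- NA_real_
  if (is.null(records$synthesis_rate)) records$synthesis_rate <- NA_real_
  if (is.null(records$abundance)) records$abundance <- NA_real_
  records$alpha <- alpha
  needMu <- is.na(records$synthesis_rate)
  records$synthesis_rate[needMu] <- synthesisRate(
    records$abundance[needMu], records$half_life_min[needMu], alpha)
  needHl <- is.na(records$half_life_min)
  if (any(needHl))
    records$half_life_min[needHl] <- halfLifeFrom(
      records$synthesis_rate[needHl], records$abundance[needHl], alpha)
  records$lambda <- decayRate(records$half_life_min)
  records
}

#' Filter gene records by include/exclude lists
#'
#' Applies ordered gene filters (an include list, then an exclude list)
#' to a kinetic record table, mirroring the usual pre-analysis curation
#' (e.g. keeping verified ORFs, excluding dubious ORFs and
#' multicistronic transcript units — both expressible as lists). The
#' per-rule removal counts are recorded in the `"removals"` attribute
#' and reported via `message()`.
#'
#' @param records Data frame with a `gene_id` column.
#' @param include Optional character vector: genes to keep. An empty
#'   vector keeps nothing (with a warning); `NULL` disables the rule.
#' @param exclude Optional character vector: genes to drop.
#' @return The filtered data frame, with attribute `"removals"` (a named
#'   integer vector of per-rule removal counts).
#' @examples
#' df <- data.frame(gene_id = c("g1", "g2", "g3"))
#' applyFilters(df, exclude = "g2")
#' @export
applyFilters <- function(records, include = NULL, exclude = NULL) {
  stopifnot("gene_id" %in% names(records))
  removals <- integer(0)
  if (!is.null(include)) {
    keep <- records$gene_id %in% include
    removals["include"] <- sum(!keep)
    records <- records[keep, , drop = FALSE]
  }
  if (!is.null(exclude)) {
    keep <- !records$gene_id %in% exclude
    removals["exclude"] <- sum(!keep)
    records <- records[keep, , drop = FALSE]
  }
  if (length(removals))
    message("gene filters removed ",
            paste(names(removals), removals, sep = ": ", collapse = ", "),
            " (", nrow(records), " genes retained)")
  if (nrow(records) == 0L) warning("no genes remain after filtering")
  attr(records, "removals") <- removals
  records
}
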