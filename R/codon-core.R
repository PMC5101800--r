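#' @include AllClasses.R
NULL

## ---------------------------------------------------------------------------
## CDS parsing
## ---------------------------------------------------------------------------

#' Read coding sequences from a FASTA file
#'
#' Reads a (possibly multi-line, mixed-case) FASTA file of coding
#' sequences into a named [Biostrings::DNAStringSet]. Sequences are
#' uppercased; the gene identifier is the first whitespace-delimited
#' token of the header. Records are validated: duplicate identifiers are
#' an error, and records containing characters outside \{A, C, G, T\} or
#' shorter than one codon are dropped with a warning (an error in strict
#' mode). In strict mode the sequence length must additionally be a
#' multiple of 3 and the frame-0 reading must contain no internal stop
#' codon; in lenient mode an internal frame-0 stop only triggers a
#' warning (dubious ORFs are expected to be handled by upstream gene
#' filters) and trailing partial codons are tolerated (they are dropped
#' at counting time).
#'
#' @param file Path to a FASTA file.
#' @param strict Logical; apply strict CDS validation (default `FALSE`).
#' @return A named `DNAStringSet`, one element per retained record.
#' @seealso [codonCountMatrix()], [codonFrequencyMatrix()]
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">g1", "atggcttaa", ">g2", "ATGAAATAA"), tf)
#' parseCds(tf)
#' @export
parseCds <- function(file, strict = FALSE) {
  seqs <- Biostrings::readDNAStringSet(file)
  if (length(seqs) == 0L) {
    warning("FASTA file '", file, "' contains no records")
    return(seqs)
  }
  ids <- vapply(strsplit(names(seqs), "[ \t]+"), `[[`, character(1L), 1L)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate gene id(s) in FASTA: ", paste(dup, collapse = ", "))
  names(seqs) <- ids
  seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))

  af <- Biostrings::alphabetFrequency(seqs, baseOnly = TRUE)
  nonACGT <- af[, "other"] > 0
  tooShort <- Biostrings::width(seqs) < 3L
  drop <- nonACGT | tooShort
  if (any(drop)) {
    msg <- paste0(
      if (any(nonACGT)) paste0("non-ACGT characters in: ",
                               paste(ids[nonACGT], collapse = ", ")),
      if (any(nonACGT) && any(tooShort)) "; ",
      if (any(tooShort)) paste0("shorter than one codon: ",
                                paste(ids[tooShort], collapse = ", ")))
    if (strict) stop(msg)
    warning(msg, "; record(s) dropped")
    seqs <- seqs[!drop]
  }
  if (strict) {
    offFrame <- Biostrings::width(seqs) %% 3L != 0L
    if (any(offFrame))
      stop("CDS length not a multiple of 3: ",
           paste(names(seqs)[offFrame], collapse = ", "))
  }
  if (length(seqs)) {
    counts <- .codonCounts(seqs, 0L)
    body <- counts[, .STOP_CODONS, drop = FALSE]
    ends <- substring(as.character(seqs),
                      (Biostrings::width(seqs) %/% 3L) * 3L - 2L)
    terminalStop <- ends %in% .STOP_CODONS &
      Biostrings::width(seqs) %% 3L == 0L
    internal <- rowSums(body) > as.integer(terminalStop)
    if (any(internal)) {
      msg <- paste0("internal stop codon(s) in frame 0: ",
                    paste(names(seqs)[internal], collapse = ", "))
      if (strict) stop(msg) else warning(msg)
    }
  }
  seqs
}

## ---------------------------------------------------------------------------
## Codon counting
## ---------------------------------------------------------------------------

.checkShift <- function(shift) {
  if (length(shift) != 1L || is.na(shift) || !shift %in% 0:2)
    stop("frame shift must be 0, 1 or 2")
  as.integer(shift)
}

## genes x 64 integer count matrix; trailing partial triplets dropped.
.codonCounts <- function(seqs, shift) {
  if (any(Biostrings::width(seqs) - shift < 3L))
    stop("sequence(s) too short after frame shift +", shift, ": ",
         paste(names(seqs)[Biostrings::width(seqs) - shift < 3L],
               collapse = ", "))
  shifted <- if (shift > 0L) Biostrings::subseq(seqs, start = shift + 1L)
             else seqs
  m <- Biostrings::oligonucleotideFrequency(shifted, width = 3L, step = 3L)
  storage.mode(m) <- "integer"
  rownames(m) <- names(seqs)
  m[, .ALL_CODONS, drop = FALSE]
}

#' Count codons per gene in a chosen reading frame
#'
#' `codonCountMatrix()` reads triplets from position `shift` (0, 1 or 2
#' nucleotides skipped at the 5' end, the computational frameshift
#' control) in steps of 3, dropping any trailing partial triplet, and
#' returns a gene-by-64 integer count matrix. `codonFrequencyMatrix()`
#' converts counts to frequencies over the 61 sense codons only: the
#' denominator is the number of sense triplets counted, so stop triplets
#' (which arise in shifted frames and at CDS ends) are counted but never
#' enter the frequency vector, keeping all frames on the same 61-codon
#' support. Genes with no counted sense triplet yield an all-`NA` row.
#'
#' @param seqs A named `DNAStringSet` (see [parseCds()]) or named
#'   character vector of sequences.
#' @param shift Frame offset in \{0, 1, 2\}.
#' @return `codonCountMatrix()`: integer matrix genes x 64 triplets;
#'   `codonFrequencyMatrix()`: numeric matrix genes x 61 sense codons,
#'   rows ordered by gene id, each row summing to 1 (or all `NA`).
#' @examples
#' seqs <- Biostrings::DNAStringSet(c(g1 = "ATGATGTAA"))
#' codonCountMatrix(seqs)[, c("ATG", "TAA")]
#' codonCountMatrix(seqs, shift = 1)[, c("TGA", "TGT")]
#' codonFrequencyMatrix(seqs)[, "ATG"]
#' @export
codonCountMatrix <- function(seqs, shift = 0) {
  shift <- .checkShift(shift)
  seqs <- .asDNAStringSet(seqs)
  m <- .codonCounts(seqs, shift)
  m[order(rownames(m)), , drop = FALSE]
}

#' @rdname codonCountMatrix
#' @export
codonFrequencyMatrix <- function(seqs, shift = 0) {
  counts <- codonCountMatrix(seqs, shift)
  .frequenciesFromCounts(counts)
}

.frequenciesFromCounts <- function(counts) {
  sense <- counts[, .SENSE_CODONS, drop = FALSE]
  nSense <- rowSums(sense)
  freq <- sense / nSense
  freq[nSense == 0L, ] <- NA_real_
  storage.mode(freq) <- "double"
  attr(freq, "nSense") <- nSense
  freq
}

.asDNAStringSet <- function(seqs) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  if (!methods::is(seqs, "DNAStringSet"))
    stop("seqs must be a DNAStringSet or named character vector")
  if (is.null(names(seqs)) || anyNA(names(seqs)) || !all(nzchar(names(seqs))))
    stop("sequences must be named by gene id")
  seqs
}

#' Build a per-gene codon profile
#'
#' Convenience wrapper around the codon counting machinery for a single
#' sequence, returning a [CodonProfile-class] with both the 64-triplet
#' counts and the 61-sense-codon frequency vector.
#'
#' @param seq A single sequence (character, `DNAString` or length-1
#'   `DNAStringSet`).
#' @param geneId Gene identifier (defaults to the sequence name).
#' @param shift Frame offset in \{0, 1, 2\}.
#' @return A [CodonProfile-class] object.
#' @examples
#' p <- codonProfile("ATGATGTAA", geneId = "g1")
#' p
#' @export
codonProfile <- function(seq, geneId = NULL, shift = 0) {
  shift <- .checkShift(shift)
  if (methods::is(seq, "DNAString"))
    seq <- Biostrings::DNAStringSet(seq)
  if (is.character(seq) || methods::is(seq, "DNAStringSet")) {
    if (length(seq) != 1L) stop("seq must be a single sequence")
    if (is.null(geneId))
      geneId <- if (!is.null(names(seq))) names(seq) else "gene"
    seq <- stats::setNames(Biostrings::DNAStringSet(as.character(seq)),
                           geneId)
  } else stop("unsupported sequence type")
  counts <- .codonCounts(seq, shift)[1L, ]
  nSense <- sum(counts[.SENSE_CODONS])
  freq <- stats::setNames(rep(NA_real_, 61L), .SENSE_CODONS)
  if (nSense > 0L) freq[] <- counts[.SENSE_CODONS] / nSense
  new("CodonProfile", geneId = geneId, counts = counts,
      frequencies = freq,
      nCounted = as.integer(sum(counts)), nSense = as.integer(nSense),
      frame = shift)
}

#' Write a codon frequency matrix as TSV
#'
#' Writes a gene-by-codon frequency matrix (see
#' [codonFrequencyMatrix()]) as a tab-separated file with a `gene_id`
#' column followed by the 61 canonical sense-codon columns.
#'
#' @param mat A frequency matrix with genes as row names.
#' @param file Output path.
#' @return Invisibly, the path written.
#' @export
writeFrequencyMatrix <- function(mat, file) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
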