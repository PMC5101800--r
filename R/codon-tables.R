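## Canonical codon orderings and genetic-code helpers. All per-codon
## vectors and matrix columns in the package follow senseCodons() order
## (alphabetical among the 61 sense codons of the standard code).

.BASES <- c("A", "C", "G", "T")

.ALL_CODONS <- sort(apply(expand.grid(.BASES, .BASES, .BASES), 1L, paste,
                          collapse = ""))

.STOP_CODONS <- c("TAA", "TAG", "TGA")

.SENSE_CODONS <- setdiff(.ALL_CODONS, .STOP_CODONS)

#' Canonical codon orderings
#'
#' `allCodons()` returns the 64 nucleotide triplets and `senseCodons()`
#' the 61 sense codons of the standard genetic code, both in alphabetical
#' order; `stopCodons()` returns the three stop triplets. Every per-codon
#' vector and matrix column in the package follows `senseCodons()` order.
#'
#' @return A character vector of triplets.
#' @examples
#' length(senseCodons())
#' stopCodons()
#' @export
senseCodons <- function() .SENSE_CODONS

#' @rdname senseCodons
#' @export
allCodons <- function() .ALL_CODONS

#' @rdname senseCodons
#' @export
stopCodons <- function() .STOP_CODONS

#' Amino acid encoded by each sense codon
#'
#' One-letter amino acid for each of the 61 sense codons (standard
#' genetic code), in canonical order. Used to define synonymous-codon
#' families, e.g. by the synthetic genome generator.
#'
#' @return Named character vector over [senseCodons()].
#' @examples
#' table(codonAminoAcids())[c("L", "M", "W")]
#' @export
codonAminoAcids <- function() {
  gc <- Biostrings::GENETIC_CODE
  aa <- gc[.SENSE_CODONS]
  names(aa) <- .SENSE_CODONS
  aa
}

## Reverse complement for plain triplet strings (no Biostrings objects,
## cheap enough for the 64-codon tables).
.revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  vapply(strsplit(x, ""), function(b)
    paste(rev(unname(comp[b])), collapse = ""), character(1L))
}
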