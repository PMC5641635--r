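#' The 61 sense codons of the standard genetic code
#'
#' All codon accounting in this package is performed over the fixed universe
#' of the 61 non-stop triplets of the standard genetic code, in alphabetical
#' order. Stop codons (TAA, TAG, TGA) are never counted and their presence
#' inside a coding region is treated as a validation error.
#'
#' @return Character vector of 61 codons, alphabetically sorted.
#' @export
sense_codons <- function() .SENSE_CODONS

.GENETIC_CODE <- {
  gc <- Biostrings::GENETIC_CODE
  names(gc) <- chartr("U", "T", names(gc))
  gc
}

.STOP_CODONS <- sort(names(.GENETIC_CODE)[.GENETIC_CODE == "*"])
.SENSE_CODONS <- sort(names(.GENETIC_CODE)[.GENETIC_CODE != "*"])

#' Split a nucleotide sequence into codons
#'
#' @param nt_seq Single nucleotide string; length must be divisible by 3.
#' @return Character vector of triplets.
#' @keywords internal
split_codons <- function(nt_seq) {
  n <- nchar(nt_seq)
  if (n == 0L || n %% 3L != 0L) {
    stop("nucleotide sequence length (", n, ") is not a positive multiple of 3")
  }
  starts <- seq.int(1L, n, by = 3L)
  substring(nt_seq, starts, starts + 2L)
}

#' Translate an in-frame coding sequence
#'
#' Standard-genetic-code translation with strict validation: the sequence must
#' be a non-empty multiple of 3 and must not contain an internal stop codon.
#' A trailing stop codon is not allowed either; coding sequences handled by
#' this package are stop-stripped by convention so that amino-acid length is
#' exactly nucleotide length / 3.
#'
#' @param nt_seq Single in-frame nucleotide string (A/C/G/T).
#' @return Single amino-acid string of length `nchar(nt_seq) / 3`.
#' @examples
#' translate_cds("ATGAAAGCTAAG")  # "MKAK"
#' @export
translate_cds <- function(nt_seq) {
  stopifnot(is.character(nt_seq), length(nt_seq) == 1L, !is.na(nt_seq))
  codons <- split_codons(toupper(nt_seq))
  aa <- unname(.GENETIC_CODE[codons])
  if (anyNA(aa)) {
    bad <- which(is.na(aa))[1L]
    stop("unrecognized codon '", codons[bad], "' at codon position ", bad)
  }
  stops <- which(aa == "*")
  if (length(stops)) {
    stop("stop codon '", codons[stops[1L]], "' at codon position ", stops[1L])
  }
  paste(aa, collapse = "")
}

#' Translate a vector of codons (no stop allowed)
#' @keywords internal
translate_codons <- function(codons) {
  aa <- unname(.GENETIC_CODE[codons])
  if (anyNA(aa) || any(aa == "*")) {
    stop("codon list contains an unrecognized or stop codon")
  }
  paste(aa, collapse = "")
}
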