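#' Locate a peptide inside a protein sequence
#'
#' Exact-match search returning every occurrence as a 0-based start offset,
#' ascending. A peptide that does not occur at all raises a mapping error —
#' it indicates the peptide and protein databases are out of sync.
#'
#' @param peptide,protein_aa_seq Non-empty amino-acid strings.
#' @param peptide_id,protein_id Optional ids used in the error message.
#' @return Integer vector of 0-based offsets.
#' @export
locate_peptide <- function(peptide, protein_aa_seq,
                           peptide_id = peptide, protein_id = "?") {
  stopifnot(nchar(peptide) > 0L, nchar(protein_aa_seq) > 0L)
  hits <- gregexpr(peptide, protein_aa_seq, fixed = TRUE)[[1L]]
  if (hits[1L] == -1L) {
    stop("peptide '", peptide_id, "' not found in protein '", protein_id, "'")
  }
  as.integer(hits) - 1L
}

#' Extract the codons coding for a peptide from its CDS
#'
#' Slices `nt_seq[3*start_aa .. 3*(start_aa+length_aa))` into triplets and
#' verifies that their translation reproduces the expected residues, so a
#' CDS/protein database mismatch surfaces as an integrity error rather than
#' silently wrong counts.
#'
#' @param nt_seq In-frame nucleotide sequence of the whole protein.
#' @param start_aa 0-based start offset in the protein.
#' @param length_aa Peptide length in amino acids.
#' @param expect_peptide Optional peptide sequence to validate against.
#' @return Character vector of `length_aa` codons.
#' @export
extract_codons <- function(nt_seq, start_aa, length_aa,
                           expect_peptide = NULL) {
  n_aa <- nchar(nt_seq) / 3L
  if (start_aa < 0L || length_aa < 1L || start_aa + length_aa > n_aa) {
    stop("codon range [", start_aa, ", ", start_aa + length_aa,
         ") outside protein of length ", n_aa)
  }
  starts <- 3L * (start_aa + seq_len(length_aa) - 1L) + 1L
  codons <- substring(nt_seq, starts, starts + 2L)
  if (!is.null(expect_peptide)) {
    aa <- translate_codons(codons)
    if (!identical(aa, expect_peptide)) {
      stop("CDS/protein integrity error: codons translate to '", aa,
           "' but expected '", expect_peptide, "'")
    }
  }
  codons
}

#' Count codons over the fixed 61-sense-codon universe
#'
#' @param codons Character vector of sense codons (stop codons are an error).
#' @return Named integer vector over all 61 sense codons (absent = 0), with
#'   attribute `freq_percent` (per-codon percentage; all-NA and flagged via
#'   attribute `empty` when the input is empty).
#' @export
count_codons <- function(codons) {
  universe <- sense_codons()
  if (length(codons)) {
    bad <- setdiff(unique(codons), universe)
    if (length(bad)) {
      stop("non-sense codon(s) in input: ", paste(bad, collapse = ", "))
    }
  }
  counts <- table(factor(codons, levels = universe))
  counts <- stats::setNames(as.integer(counts), universe)
  if (length(codons)) {
    attr(counts, "freq_percent") <- 100 * counts / length(codons)
    attr(counts, "empty") <- FALSE
  } else {
    attr(counts, "freq_percent") <- stats::setNames(rep(NA_real_, 61), universe)
    attr(counts, "empty") <- TRUE
  }
  counts
}

#' Build per-peptide codon profiles for quantified peptides
#'
#' For every peptide, looks up its parsimony-assigned protein, locates the
#' peptide in that protein's translation (first occurrence when several;
#' multiplicity is recorded), extracts the corresponding codons from the CDS
#' with translation validation, and counts them over the 61 sense codons.
#'
#' @param peptides Character vector of peptide sequences.
#' @param assignment peptide -> protein data.frame from
#'   [assemble_parsimony()].
#' @param cds CDS table (id, nt_seq, aa_seq) from
#'   [generate_coding_sequences()] or [read_cds_fasta()].
#' @return data.frame: peptide, protein_id, start_aa, length, n_sites
#'   (occurrence multiplicity), then the 61 codon-count columns in fixed
#'   alphabetical order.
#' @export
peptide_codon_profiles <- function(peptides, assignment, cds) {
  peptides <- unique(peptides)
  prot <- assignment$protein_id[match(peptides, assignment$peptide)]
  if (anyNA(prot)) {
    stop("peptides without a protein assignment: ",
         paste(utils::head(peptides[is.na(prot)], 5), collapse = ", "))
  }
  ci <- match(prot, cds$id)
  if (anyNA(ci)) {
    stop("assigned proteins missing from the CDS database: ",
         paste(utils::head(unique(prot[is.na(ci)]), 5), collapse = ", "))
  }
  universe <- sense_codons()
  npep <- length(peptides)
  lens <- nchar(peptides)
  # split each needed CDS into codon indices once, with a whole-protein
  # integrity check (translation must reproduce the stored protein)
  need <- unique(ci)
  cache <- vector("list", length(need))
  for (jj in seq_along(need)) {
    i <- need[jj]
    cod <- split_codons(cds$nt_seq[i])
    idx <- match(cod, universe)
    if (anyNA(idx)) {
      stop("CDS/protein integrity error: protein '", cds$id[i],
           "' CDS contains a stop or invalid codon")
    }
    aa_chk <- paste(unname(.GENETIC_CODE[cod]), collapse = "")
    if (!identical(aa_chk, cds$aa_seq[i])) {
      stop("CDS/protein integrity error: CDS of '", cds$id[i],
           "' does not translate to its protein sequence")
    }
    cache[[jj]] <- idx
  }
  # first occurrence (0-based) and multiplicity of each peptide
  start_aa <- integer(npep)
  n_sites <- integer(npep)
  for (k in seq_len(npep)) {
    offs <- locate_peptide(peptides[k], cds$aa_seq[ci[k]],
                           peptides[k], cds$id[ci[k]])
    start_aa[k] <- offs[1L]
    n_sites[k] <- length(offs)
  }
  # flatten cached codon vectors and gather every peptide's codons at once
  offset <- cumsum(c(0L, lengths(cache)[-length(cache)]))
  g <- offset[match(ci, need)] + start_aa
  pos <- rep(g, lens) + sequence(lens)
  codon_idx <- unlist(cache, use.names = FALSE)[pos]
  pep_idx <- rep.int(seq_len(npep), lens)
  counts <- matrix(tabulate((pep_idx - 1L) * 61L + codon_idx,
                            nbins = npep * 61L),
                   nrow = npep, ncol = 61L, byrow = TRUE,
                   dimnames = list(NULL, universe))
  out <- data.frame(peptide = peptides, protein_id = prot,
                    start_aa = start_aa, length = lens,
                    n_sites = n_sites, stringsAsFactors = FALSE)
  cbind(out, as.data.frame(counts))
}
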