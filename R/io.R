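#' Write a coding-sequence or protein FASTA (60-column wrap)
#'
#' @param cds CDS table (id, nt_seq, aa_seq).
#' @param path Output path.
#' @export
write_cds_fasta <- function(cds, path) {
  x <- Biostrings::DNAStringSet(stats::setNames(cds$nt_seq, cds$id))
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' @rdname write_cds_fasta
#' @export
write_protein_fasta <- function(cds, path) {
  x <- Biostrings::AAStringSet(stats::setNames(cds$aa_seq, cds$id))
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' Read a coding-sequence FASTA and derive validated translations
#'
#' Every record must be an in-frame, stop-free coding sequence; the
#' translation is recomputed (a trailing stop codon, if present, is
#' stripped first).
#'
#' @param path CDS FASTA path.
#' @return data.frame (id, nt_seq, aa_seq).
#' @export
read_cds_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  nt <- as.character(x)
  ids <- sub("\\s.*$", "", names(x))
  aa <- character(length(nt))
  for (i in seq_along(nt)) {
    s <- nt[i]
    n <- nchar(s)
    if (n >= 3L && n %% 3L == 0L &&
        substring(s, n - 2L, n) %in% .STOP_CODONS) {
      s <- substring(s, 1L, n - 3L)
      nt[i] <- s
    }
    aa[i] <- tryCatch(translate_cds(s), error = function(e) {
      stop("record '", ids[i], "': ", conditionMessage(e))
    })
  }
  data.frame(id = unname(ids), nt_seq = unname(nt), aa_seq = aa,
             stringsAsFactors = FALSE)
}

# shared TSV writers: tab-separated, header, missing written as empty string
write_tsv <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", na = "", quote = FALSE, eol = "\n")
  invisible(path)
}

read_tsv <- function(path, ...) {
  as.data.frame(data.table::fread(path, sep = "\t", na.strings = "",
                                  header = TRUE, ...))
}

#' Write / read the PSM-level quantification table
#'
#' TSV with header psm_id, peptide, protein_ids (semicolon-joined),
#' start_aa, score, is_decoy (0/1), has_ms3 (0/1), then one `sn_<channel>`
#' column per reporter channel; missing reporter values are empty strings.
#'
#' @param psms PSM data.frame.
#' @param path File path.
#' @export
write_psm_table <- function(psms, path) {
  out <- psms
  out$is_decoy <- as.integer(out$is_decoy)
  out$has_ms3 <- as.integer(out$has_ms3)
  write_tsv(out, path)
}

#' @rdname write_psm_table
#' @export
read_psm_table <- function(path) {
  psms <- read_tsv(path)
  req <- c("psm_id", "peptide", "protein_ids", "start_aa", "score",
           "is_decoy", "has_ms3")
  if (!all(req %in% names(psms))) {
    stop("PSM table lacks required columns: ",
         paste(setdiff(req, names(psms)), collapse = ", "))
  }
  if (length(sn_columns(psms)) == 0L) stop("PSM table has no sn_ columns")
  psms$is_decoy <- as.logical(psms$is_decoy)
  psms$has_ms3 <- as.logical(psms$has_ms3)
  for (cc in sn_columns(psms)) psms[[cc]] <- as.numeric(psms[[cc]])
  psms
}

#' Write a units-by-samples quantification matrix as TSV
#' @param m Matrix from [quantify()].
#' @param path File path.
#' @param unit_col Name for the row-id column.
#' @export
write_quant_matrix <- function(m, path, unit_col = "unit_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- unit_col
  write_tsv(df, path)
}
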