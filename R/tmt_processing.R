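#' PSM quality-filter thresholds
#'
#' Defaults are the exclusion rules applied to MS3-quantified TMT reporter
#' data: PSMs with no MS3 spectrum, with more than eight of the ten reporter
#' channels missing, or with a summed reporter signal-to-noise below 100 are
#' excluded from quantification, and identifications are controlled at a 1%
#' FDR at both peptide and protein level.
#'
#' Boundary semantics are strict: "more than eight missing" excludes only 9+
#' missing channels, and "less than 100" excludes only sums strictly below
#' 100.
#'
#' @param max_missing_channels Maximum tolerated missing reporter channels.
#' @param min_summed_sn Minimum summed signal-to-noise over present channels.
#' @param require_ms3 Drop PSMs lacking an MS3 spectrum.
#' @param peptide_fdr,protein_fdr Target-decoy FDR levels, in (0, 1).
#' @return list of class `filter_thresholds`.
#' @export
filter_thresholds <- function(max_missing_channels = 8,
                              min_summed_sn = 100,
                              require_ms3 = TRUE,
                              peptide_fdr = 0.01,
                              protein_fdr = 0.01) {
  th <- list(max_missing_channels = as.integer(max_missing_channels),
             min_summed_sn = min_summed_sn,
             require_ms3 = isTRUE(require_ms3),
             peptide_fdr = peptide_fdr, protein_fdr = protein_fdr)
  if (th$peptide_fdr <= 0 || th$peptide_fdr >= 1 ||
      th$protein_fdr <= 0 || th$protein_fdr >= 1) {
    stop("FDR levels must lie in (0, 1)")
  }
  class(th) <- "filter_thresholds"
  th
}

sn_columns <- function(psms) grep("^sn_", names(psms), value = TRUE)

#' Apply PSM-level reporter-quality exclusion rules
#'
#' A PSM is retained iff it has an MS3 spectrum (when required), has at most
#' `max_missing_channels` missing reporter values, and its summed
#' signal-to-noise over present channels is at least `min_summed_sn`.
#' Exclusions are tallied by the first failing rule, in that order.
#'
#' @param psms PSM data.frame with `has_ms3` and `sn_*` reporter columns
#'   (NA = missing channel).
#' @param thresholds A [filter_thresholds()].
#' @param design Optional design table; if given, the reporter columns must
#'   match its channels exactly.
#' @return list with `retained` (filtered PSM data.frame) and `tally`
#'   (data.frame rule/excluded, rules: no_ms3, missing_channels, low_sn).
#' @export
filter_psms <- function(psms, thresholds = filter_thresholds(),
                        design = NULL) {
  sn_cols <- sn_columns(psms)
  if (length(sn_cols) == 0L) stop("no reporter (sn_) columns in PSM table")
  if (!is.null(design)) {
    expected <- paste0("sn_", design$channel_id)
    if (!identical(sort(sn_cols), sort(expected))) {
      stop("reporter columns do not match the design channels")
    }
    sn_cols <- expected
  }
  if (thresholds$max_missing_channels >= length(sn_cols)) {
    stop("max_missing_channels must be below the channel count")
  }
  sn <- as.matrix(psms[sn_cols])
  n_missing <- rowSums(is.na(sn))
  summed <- rowSums(sn, na.rm = TRUE)

  fail_ms3 <- thresholds$require_ms3 & !psms$has_ms3
  fail_missing <- !fail_ms3 & n_missing > thresholds$max_missing_channels
  fail_sn <- !fail_ms3 & !fail_missing & summed < thresholds$min_summed_sn
  keep <- !(fail_ms3 | fail_missing | fail_sn)

  tally <- data.frame(
    rule = c("no_ms3", "missing_channels", "low_sn"),
    excluded = c(sum(fail_ms3), sum(fail_missing), sum(fail_sn)))
  ret <- psms[keep, , drop = FALSE]
  rownames(ret) <- NULL
  list(retained = ret, tally = tally)
}

#' Target-decoy FDR collapse at peptide or protein level
#'
#' PSMs are collapsed to units (peptide sequences, or candidate protein
#' accessions) by best score per unit. Units are ranked by descending score;
#' the estimated FDR at threshold t is (#decoy units with score >= t) /
#' max(1, #target units with score >= t), smoothed into monotone q-values
#' (running minimum from the permissive end). All target units with q-value
#' at or below `level` are retained; decoys are never returned.
#'
#' With no decoy units present the estimator is undefined: a warning is
#' raised, every target is accepted, and the estimated FDR is reported as 0
#' (unreliable).
#'
#' @param psms data.frame with `score`, `is_decoy`, and `peptide` (for
#'   `unit = "peptide"`) or `protein_ids` (semicolon-joined candidates, for
#'   `unit = "protein"`).
#' @param level FDR level in (0, 1).
#' @param unit Collapse unit.
#' @return list with `retained` (character vector of accepted target unit
#'   ids), `threshold` (most permissive accepted score), `est_fdr`
#'   (estimated FDR at the threshold), and `units` (per-unit table with raw
#'   FDR and q-values, decoys included, for downstream staging).
#' @export
apply_fdr <- function(psms, level = 0.01, unit = c("peptide", "protein")) {
  unit <- match.arg(unit)
  if (level <= 0 || level >= 1) stop("FDR level must lie in (0, 1)")
  if (nrow(psms) == 0L) {
    return(list(retained = character(0), threshold = Inf, est_fdr = 0,
                units = data.frame(unit = character(0), score = numeric(0),
                                   is_decoy = logical(0), fdr = numeric(0),
                                   q = numeric(0))))
  }
  if (unit == "peptide") {
    id <- psms$peptide
    score <- psms$score
    dec <- psms$is_decoy
  } else {
    cand <- strsplit(psms$protein_ids, ";", fixed = TRUE)
    times <- lengths(cand)
    id <- unlist(cand, use.names = FALSE)
    score <- rep.int(psms$score, times)
    dec <- rep.int(psms$is_decoy, times)
  }
  # best score per unit
  o <- order(id, -score)
  first <- !duplicated(id[o])
  u <- data.frame(unit = id[o][first], score = score[o][first],
                  is_decoy = dec[o][first], stringsAsFactors = FALSE)
  u <- u[order(-u$score, u$unit), , drop = FALSE]

  if (!any(u$is_decoy)) {
    warning("no decoy units present; FDR estimate unreliable, accepting all")
    u$fdr <- 0
    u$q <- 0
    return(list(retained = u$unit[!u$is_decoy], threshold = min(u$score),
                est_fdr = 0, units = u))
  }
  n_dec <- cumsum(u$is_decoy)
  n_tar <- cumsum(!u$is_decoy)
  u$fdr <- n_dec / pmax(1L, n_tar)
  u$q <- rev(cummin(rev(u$fdr)))
  ok <- u$q <= level
  if (!any(ok)) {
    return(list(retained = character(0), threshold = Inf,
                est_fdr = NA_real_, units = u))
  }
  cut <- max(which(ok))
  retained <- u$unit[seq_len(cut)][!u$is_decoy[seq_len(cut)]]
  list(retained = retained, threshold = u$score[cut],
       est_fdr = u$fdr[cut], units = u)
}

#' Parsimony protein inference (greedy minimal set cover)
#'
#' Selects the smallest set of proteins necessary to account for all
#' observed peptides by greedy set cover: repeatedly pick the protein
#' covering the most still-uncovered peptides, breaking ties by larger total
#' peptide count and then by lexicographically smaller accession. Each
#' peptide is assigned to exactly one protein group — the earliest-selected
#' protein that contains it.
#'
#' @param pep2prot Named list: peptide sequence -> character vector of
#'   candidate protein accessions (each non-empty).
#' @return data.frame with columns peptide, protein_id (the representative
#'   the peptide is assigned to); attribute "groups" holds the selection
#'   order of representatives.
#' @export
assemble_parsimony <- function(pep2prot) {
  if (length(pep2prot) == 0L) {
    res <- data.frame(peptide = character(0), protein_id = character(0))
    attr(res, "groups") <- character(0)
    return(res)
  }
  if (any(lengths(pep2prot) == 0L)) {
    stop("every peptide needs at least one candidate protein")
  }
  peptides <- names(pep2prot)
  prot <- unlist(pep2prot, use.names = FALSE)
  pep_idx <- rep.int(seq_along(pep2prot), lengths(pep2prot))
  prot_ids <- sort(unique(prot))
  # per-protein list of peptide indices
  members <- split(pep_idx, factor(prot, levels = prot_ids))
  total <- lengths(members)

  uncovered <- rep(TRUE, length(peptides))
  assigned <- rep(NA_character_, length(peptides))
  order_sel <- character(0)
  while (any(uncovered)) {
    gain <- vapply(members, function(ix) sum(uncovered[ix]), integer(1))
    best <- which(gain == max(gain))
    if (length(best) > 1L) {
      best <- best[total[best] == max(total[best])]
      best <- best[order(prot_ids[best])][1L]  # lexicographic tie-break
    }
    sel <- prot_ids[best]
    newly <- members[[best]][uncovered[members[[best]]]]
    assigned[newly] <- sel
    uncovered[newly] <- FALSE
    order_sel <- c(order_sel, sel)
  }
  res <- data.frame(peptide = peptides, protein_id = assigned,
                    stringsAsFactors = FALSE)
  attr(res, "groups") <- order_sel
  res
}

#' Quantify peptides or proteins by reporter summation
#'
#' The cell for unit u and sample s is the sum over u's PSMs of the reporter
#' signal-to-noise in s's channel. Missing reporter values contribute 0 to
#' the sum (they are bounded in number by the upstream missingness filter)
#' but are never imputed. Columns follow the design's sample order.
#'
#' @param psms Retained PSM data.frame (`peptide`, `sn_*` columns).
#' @param assignment Either NULL (peptide-level: rows are peptide sequences)
#'   or the peptide -> protein assignment from [assemble_parsimony()]
#'   (protein-level: rows are representative accessions; unassigned peptides
#'   are dropped).
#' @param design Design table (channel_id, sample_id, group).
#' @param unit "peptide" or "protein".
#' @return Numeric matrix, units x samples.
#' @export
quantify <- function(psms, assignment = NULL, design,
                     unit = c("peptide", "protein")) {
  unit <- match.arg(unit)
  expected <- paste0("sn_", design$channel_id)
  if (!all(expected %in% names(psms))) {
    stop("PSM table lacks reporter columns for design channels: ",
         paste(setdiff(expected, names(psms)), collapse = ", "))
  }
  sn <- as.matrix(psms[expected])
  sn[is.na(sn)] <- 0
  if (unit == "peptide") {
    key <- psms$peptide
  } else {
    if (is.null(assignment)) stop("protein-level quantification needs a parsimony assignment")
    key <- assignment$protein_id[match(psms$peptide, assignment$peptide)]
    drop <- is.na(key)
    if (any(drop)) {
      sn <- sn[!drop, , drop = FALSE]
      key <- key[!drop]
    }
  }
  if (length(key) == 0L) stop("no quantifiable PSMs")
  m <- rowsum(sn, group = key, reorder = TRUE)
  colnames(m) <- design$sample_id
  m
}
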