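# Independent oracles and fixture builders shared across the suite.
# These deliberately re-derive results by brute force / enumeration and must
# never call the implementation paths they are used to check.

# ---- target-decoy FDR: exhaustive threshold scan --------------------------
# Collapses PSMs to best score per unit itself, then scans every candidate
# threshold and returns the largest retained target set whose raw decoy/target
# FDR estimate is at or below `level`.
fdr_brute_force <- function(psms, level) {
  agg <- stats::aggregate(score ~ peptide + is_decoy, data = psms, FUN = max)
  best <- NULL
  for (t in sort(unique(agg$score))) {
    nd <- sum(agg$is_decoy & agg$score >= t)
    nt <- sum(!agg$is_decoy & agg$score >= t)
    if (nd / max(1, nt) <= level) {
      if (is.null(best) || nt > best$n) {
        best <- list(n = nt,
                     retained = sort(agg$peptide[!agg$is_decoy &
                                                   agg$score >= t]))
      }
    }
  }
  if (is.null(best)) list(n = 0L, retained = character(0)) else best
}

random_fdr_instance <- function(n_units_max = 200) {
  n_t <- sample.int(floor(n_units_max * 0.7), 1)
  n_d <- sample.int(n_units_max - n_t, 1)
  units <- c(sprintf("t%03d", seq_len(n_t)), sprintf("d%03d", seq_len(n_d)))
  dec <- rep(c(FALSE, TRUE), c(n_t, n_d))
  # several PSMs per unit so the best-score collapse is exercised
  mult <- sample(1:3, length(units), replace = TRUE)
  idx <- rep(seq_along(units), mult)
  data.frame(peptide = units[idx],
             is_decoy = dec[idx],
             score = round(stats::rnorm(length(idx),
                                        mean = ifelse(dec[idx], 0, 1.5)), 2),
             stringsAsFactors = FALSE)
}

# ---- parsimony: exhaustive minimal set cover ------------------------------
min_cover_size <- function(pep2prot) {
  prots <- sort(unique(unlist(pep2prot)))
  P <- length(prots)
  npep <- length(pep2prot)
  full <- bitwShiftL(1L, npep) - 1L
  masks <- integer(P)
  for (j in seq_len(P)) {
    covered <- which(vapply(pep2prot, function(x) prots[j] %in% x, logical(1)))
    masks[j] <- Reduce(bitwOr, bitwShiftL(1L, covered - 1L), 0L)
  }
  for (size in seq_len(P)) {
    combos <- utils::combn(P, size)
    for (k in seq_len(ncol(combos))) {
      if (Reduce(bitwOr, masks[combos[, k]], 0L) == full) return(size)
    }
  }
  stop("no cover exists")  # unreachable: every peptide has a candidate
}

# Candidate multiplicity mirrors tryptic reality: most peptides are unique
# to one protein, a minority shared by two or three (share_probs). The
# adversarial uniform distribution c(1,1,1)/3 drops greedy optimality to
# ~93% and can be passed explicitly where that regime is of interest.
random_parsimony_instance <- function(max_proteins = 12, max_peptides = 20,
                                      share_probs = c(0.7, 0.2, 0.1)) {
  n_prot <- sample(2:max_proteins, 1)
  n_pep <- sample(3:max_peptides, 1)
  prots <- sprintf("P%02d", seq_len(n_prot))
  peps <- sprintf("pep%02d", seq_len(n_pep))
  k_max <- min(3, n_prot)
  stats::setNames(lapply(peps, function(p) {
    sort(sample(prots, sample(seq_len(k_max), 1, prob = share_probs[seq_len(k_max)])))
  }), peps)
}

# ---- small hand-built fixtures --------------------------------------------
# PSM row with explicit reporter values over 10 channels.
make_psm <- function(sn, has_ms3 = TRUE, score = 5, peptide = "ELVISLIVES",
                     protein_ids = "PROT00001", is_decoy = FALSE,
                     psm_id = "PSM000001") {
  stopifnot(length(sn) == 10L)
  row <- data.frame(psm_id = psm_id, peptide = peptide,
                    protein_ids = protein_ids, start_aa = 0L, score = score,
                    is_decoy = is_decoy, has_ms3 = has_ms3,
                    stringsAsFactors = FALSE)
  sn_df <- as.data.frame(as.list(sn))
  names(sn_df) <- sprintf("sn_ch%02d", 1:10)
  cbind(row, sn_df)
}

design10 <- function() sample_design(sim_config())

# tiny two-protein CDS fixture with known codons
tiny_cds <- function() {
  data.frame(
    id = c("PA", "PB"),
    nt_seq = c("ATGAAAGCTAAG",            # M  K  A  K
               "ATGAAAAAGCGTCCG"),        # M  K  K  R  P
    aa_seq = c("MKAK", "MKKRP"),
    stringsAsFactors = FALSE)
}
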