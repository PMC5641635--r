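#' Abundance-weighted per-sample codon totals
#'
#' For each sample, each peptide's codon counts are multiplied by that
#' peptide's abundance and summed: totals[s, c] = sum_p count_c(p) *
#' abundance(p, s). This is the abundance-corrected per-mouse codon
#' accounting used for the total-proteome group comparison.
#'
#' @param quant Peptide-level abundance matrix (peptides x samples) from
#'   [quantify()].
#' @param profiles Codon-profile table from [peptide_codon_profiles()].
#' @return Numeric matrix, samples x 61 codons.
#' @export
weighted_codon_totals <- function(quant, profiles) {
  missing <- setdiff(rownames(quant), profiles$peptide)
  if (length(missing)) {
    stop("quantified peptides without a codon profile: ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) sprintf(" (and %d more)", length(missing) - 5))
  }
  counts <- as.matrix(profiles[match(rownames(quant), profiles$peptide),
                               sense_codons(), drop = FALSE])
  t(quant) %*% counts  # samples x codons
}

#' Two-group comparison of per-sample codon totals
#'
#' Classical two-sided Student's t-test with pooled (equal) variance on the
#' per-sample abundance-weighted totals of each requested codon. When both
#' groups are constant and equal the statistic is defined as t = 0, p = 1.
#'
#' @param totals Matrix from [weighted_codon_totals()] (samples x codons).
#' @param design Design table; `sample_id` must match the rownames.
#' @param codons Codons to test (default Lys AAA).
#' @return data.frame: codon, mean_control, mean_ko, t_statistic, p_value.
#' @export
compare_codon_totals <- function(totals, design, codons = "AAA") {
  stopifnot(all(codons %in% sense_codons()))
  idx <- match(design$sample_id, rownames(totals))
  if (anyNA(idx)) stop("totals rows do not cover the design samples")
  ctrl <- totals[idx[design$group == "control"], , drop = FALSE]
  ko <- totals[idx[design$group == "ko"], , drop = FALSE]
  n1 <- nrow(ctrl); n2 <- nrow(ko)
  if (n1 < 2L || n2 < 2L) stop("need at least two samples per group")
  res <- lapply(codons, function(cc) {
    x <- ctrl[, cc]; y <- ko[, cc]
    sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    if (se == 0) {
      tt <- 0; p <- 1
    } else {
      # control minus knockout, the stats::t.test(ctrl, ko) convention
      tt <- (mean(x) - mean(y)) / se
      p <- 2 * stats::pt(-abs(tt), df = n1 + n2 - 2)
    }
    data.frame(codon = cc, mean_control = mean(x), mean_ko = mean(y),
               t_statistic = tt, p_value = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Knockout/control fold changes with a downregulation flag
#'
#' log2 fold change of group means with a small pseudocount added to both
#' means to avoid infinite ratios for units absent in one group. Units
#' absent in every sample are dropped (and reported via the "dropped"
#' attribute). A unit is flagged downregulated when its fold change is at or
#' below -log2(threshold_fold) (default: 2-fold, log2FC <= -1).
#'
#' @param quant Abundance matrix (units x samples) from [quantify()].
#' @param design Design table.
#' @param threshold_fold Fold-change threshold (default 2).
#' @param pseudocount Added to both group means before the ratio
#'   (default 0.5 signal-to-noise units).
#' @return data.frame: unit_id, mean_control, mean_ko, log2fc, is_down_2x.
#' @export
fold_changes <- function(quant, design, threshold_fold = 2,
                         pseudocount = 0.5) {
  idx <- match(design$sample_id, colnames(quant))
  if (anyNA(idx)) stop("quant columns do not cover the design samples")
  m_ctrl <- rowMeans(quant[, idx[design$group == "control"], drop = FALSE])
  m_ko <- rowMeans(quant[, idx[design$group == "ko"], drop = FALSE])
  absent <- m_ctrl == 0 & m_ko == 0
  res <- data.frame(unit_id = rownames(quant), mean_control = m_ctrl,
                    mean_ko = m_ko, stringsAsFactors = FALSE,
                    row.names = NULL)[!absent, , drop = FALSE]
  res$log2fc <- log2((res$mean_ko + pseudocount) /
                     (res$mean_control + pseudocount))
  res$is_down_2x <- res$log2fc <= -log2(threshold_fold)
  attr(res, "dropped") <- rownames(quant)[absent]
  res
}

#' Codon-frequency enrichment in downregulated peptides
#'
#' Computes, for each of the 61 sense codons, its percentage among all
#' codons of the total peptide set and of the downregulated subset
#' (unweighted: percentage of each codon in the peptide coding sequences),
#' the enrichment delta (down minus total), and the rank of that delta
#' (rank 1 = most enriched in the downregulated set; ties broken
#' alphabetically by codon).
#'
#' @param profiles Codon-profile table from [peptide_codon_profiles()].
#' @param down_set Peptides in the downregulated subset (must be a subset of
#'   `total_set`).
#' @param total_set Peptides forming the reference set; default all profiled
#'   peptides.
#' @return data.frame (one row per codon, alphabetical): codon,
#'   freq_total_percent, freq_down_percent, delta_percent, rank. With an
#'   empty `down_set` the down/delta/rank columns are NA and the attribute
#'   "empty_down" is TRUE.
#' @export
codon_enrichment <- function(profiles, down_set, total_set = NULL) {
  if (is.null(total_set)) total_set <- profiles$peptide
  if (length(total_set) == 0L) stop("total peptide set is empty")
  if (!all(total_set %in% profiles$peptide)) stop("total_set peptides lack profiles")
  if (!all(down_set %in% total_set)) {
    stop("down_set must be a subset of total_set")
  }
  universe <- sense_codons()
  cm <- as.matrix(profiles[sense_codons()])
  rownames(cm) <- profiles$peptide
  set_freq <- function(set) {
    counts <- colSums(cm[rownames(cm) %in% set, , drop = FALSE])
    100 * counts / sum(counts)
  }
  res <- data.frame(codon = universe,
                    freq_total_percent = unname(set_freq(total_set)),
                    stringsAsFactors = FALSE)
  if (length(down_set) == 0L) {
    res$freq_down_percent <- NA_real_
    res$delta_percent <- NA_real_
    res$rank <- NA_integer_
    attr(res, "empty_down") <- TRUE
    return(res)
  }
  res$freq_down_percent <- unname(set_freq(down_set))
  res$delta_percent <- res$freq_down_percent - res$freq_total_percent
  # rank 1 = largest delta; ties resolved alphabetically by codon
  res$rank <- order(order(-res$delta_percent, res$codon))
  attr(res, "empty_down") <- FALSE
  res
}

#' Codon-table heatmap layout of enrichment deltas
#'
#' Arranges the 61 enrichment deltas in the classical codon-table layout:
#' 16 rows (first base x second base, T/C/A/G order) by 4 columns (third
#' base), with the three stop-codon cells set to NA.
#'
#' @param enrichment Table from [codon_enrichment()].
#' @return 16 x 4 numeric matrix; rownames are the first two bases, colnames
#'   the third base.
#' @export
heatmap_layout <- function(enrichment) {
  bases <- c("T", "C", "A", "G")
  rows <- as.vector(t(outer(bases, bases, paste0)))  # TT,TC,TA,TG,CT,...
  m <- matrix(NA_real_, 16L, 4L, dimnames = list(rows, bases))
  for (r in rows) for (b in bases) {
    codon <- paste0(r, b)
    if (codon %in% .STOP_CODONS) next
    m[r, b] <- enrichment$delta_percent[enrichment$codon == codon]
  }
  m
}

#' Mixed-effects regression of peptide fold change on Lys(AAA) frequency
#'
#' Fits log2fc ~ percent_AAA with a random intercept per grouping unit
#' (default: the parsimony-assigned protein, since peptides of one protein
#' share a fold change by construction), by maximum likelihood. Reports the
#' fixed slope (change in log2 fold change per percentage point of Lys(AAA)
#' codons), its standard error and a Wald p-value. If the random-intercept
#' variance collapses (singular fit) or the fit fails, falls back to
#' ordinary least squares with `converged = FALSE`.
#'
#' @param fc Peptide-level table from [fold_changes()].
#' @param profiles Codon-profile table from [peptide_codon_profiles()].
#' @param grouping Column of `profiles` to use as the random-effect group
#'   (default "protein_id").
#' @param min_peptides,min_groups Precondition sizes.
#' @return list: slope, standard_error, p_value, grouping_variable,
#'   converged, n_peptides, n_groups.
#' @export
regress_fc_on_aaa <- function(fc, profiles, grouping = "protein_id",
                              min_peptides = 10, min_groups = 3) {
  i <- match(fc$unit_id, profiles$peptide)
  if (anyNA(i)) stop("fold-change units without codon profiles")
  d <- data.frame(
    log2fc = fc$log2fc,
    pct_aaa = 100 * profiles$AAA[i] / profiles$length[i],
    group = profiles[[grouping]][i])
  d <- d[is.finite(d$log2fc), , drop = FALSE]
  if (nrow(d) < min_peptides) stop("need at least ", min_peptides, " peptides")
  if (length(unique(d$group)) < min_groups) {
    stop("need at least ", min_groups, " grouping units")
  }
  if (stats::var(d$pct_aaa) == 0) {
    stop("degenerate design: percent AAA constant across peptides")
  }
  if (stats::var(d$log2fc) == 0) {
    return(list(slope = 0, standard_error = NA_real_, p_value = 1,
                grouping_variable = grouping, converged = FALSE,
                n_peptides = nrow(d), n_groups = length(unique(d$group))))
  }
  fit <- tryCatch(
    lme4::lmer(log2fc ~ pct_aaa + (1 | group), data = d, REML = FALSE),
    error = function(e) NULL)
  singular <- is.null(fit) || lme4::isSingular(fit, tol = 1e-5)
  if (!singular) {
    co <- summary(fit)$coefficients
    slope <- co["pct_aaa", "Estimate"]
    se <- co["pct_aaa", "Std. Error"]
    converged <- TRUE
  } else {
    ols <- stats::lm(log2fc ~ pct_aaa, data = d)
    co <- summary(ols)$coefficients
    slope <- co["pct_aaa", "Estimate"]
    se <- co["pct_aaa", "Std. Error"]
    converged <- FALSE
  }
  list(slope = slope, standard_error = se,
       p_value = 2 * stats::pnorm(-abs(slope / se)),
       grouping_variable = grouping, converged = converged,
       n_peptides = nrow(d), n_groups = length(unique(d$group)))
}
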