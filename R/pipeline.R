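#' Pipeline configuration
#'
#' Bundles the simulation parameters, PSM filter thresholds and analysis
#' switches of a full run. All quality-filter defaults are the values the
#' processing stage is built around (at most 8 missing reporter channels,
#' summed signal-to-noise of at least 100, 1% peptide- and protein-level
#' FDR, 2-fold downregulation threshold).
#'
#' @param sim A [sim_config()].
#' @param thresholds A [filter_thresholds()].
#' @param threshold_fold Downregulation fold threshold (default 2).
#' @param pseudocount Pseudocount on group means before ratios.
#' @param significance_gate Also require a per-peptide two-sample t-test
#'   p < `gate_alpha` for membership in the downregulated set (off by
#'   default; the plain >2-fold rule is the primary definition).
#' @param gate_alpha Alpha for the optional significance gate.
#' @param grouping Random-effect grouping for the regression.
#' @param seed Top-level seed (overrides `sim$seed` when given).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            thresholds = filter_thresholds(),
                            threshold_fold = 2,
                            pseudocount = 0.5,
                            significance_gate = FALSE,
                            gate_alpha = 0.05,
                            grouping = "protein_id",
                            seed = NULL) {
  if (!is.null(seed)) sim$seed <- as.integer(seed)
  cfg <- list(sim = sim, thresholds = thresholds,
              threshold_fold = threshold_fold, pseudocount = pseudocount,
              significance_gate = isTRUE(significance_gate),
              gate_alpha = gate_alpha, grouping = grouping)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a flat key: value configuration file
#'
#' One `key: value` pair per line; `#` comments and blank lines ignored.
#' Keys matching [sim_config()] arguments go to the simulation block, keys
#' matching [filter_thresholds()] to the filter block, the rest
#' ([pipeline_config()] arguments) to the top level. Unknown keys are an
#' error.
#'
#' @param path Config file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z_0-9]+)\\s*[:=]\\s*(.*)$", lines))
  if (any(lengths(kv) != 3L)) {
    stop("malformed config line: ", lines[which(lengths(kv) != 3L)[1L]])
  }
  keys <- vapply(kv, `[`, character(1), 2L)
  vals <- vapply(kv, `[`, character(1), 3L)
  coerce <- function(v) {
    if (v %in% c("true", "TRUE", "yes")) return(TRUE)
    if (v %in% c("false", "FALSE", "no")) return(FALSE)
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  }
  sim_args <- list()
  th_args <- list()
  top_args <- list()
  sim_names <- names(formals(sim_config))
  th_names <- names(formals(filter_thresholds))
  top_names <- setdiff(names(formals(pipeline_config)), c("sim", "thresholds"))
  for (i in seq_along(keys)) {
    k <- keys[i]; v <- coerce(vals[i])
    if (k %in% sim_names) sim_args[[k]] <- v
    else if (k %in% th_names) th_args[[k]] <- v
    else if (k %in% top_names) top_args[[k]] <- v
    else stop("unknown configuration key: ", k)
  }
  do.call(pipeline_config,
          c(list(sim = do.call(sim_config, sim_args),
                 thresholds = do.call(filter_thresholds, th_args)),
            top_args))
}

#' Validate an on-disk input set
#'
#' Checks FASTA well-formedness, CDS/protein translation consistency, the
#' PSM-table schema, and design-table coverage of the PSM reporter
#' channels. Fatal problems and warnings are reported separately; nothing
#' is thrown.
#'
#' @param cds_fasta,protein_fasta,psm_tsv,design_tsv Input paths
#'   (`protein_fasta` optional, NULL to skip the consistency check).
#' @return list with character vectors `errors` and `warnings`.
#' @export
validate_inputs <- function(cds_fasta, psm_tsv, design_tsv,
                            protein_fasta = NULL) {
  errors <- character(0)
  warnings <- character(0)
  cds <- NULL
  for (p in c(cds_fasta, psm_tsv, design_tsv, protein_fasta)) {
    if (!file.exists(p)) errors <- c(errors, paste0("missing file: ", p))
  }
  if (length(errors)) return(list(errors = errors, warnings = warnings))

  cds <- tryCatch(read_cds_fasta(cds_fasta), error = function(e) {
    errors <<- c(errors, paste0("CDS FASTA invalid: ", conditionMessage(e)))
    NULL
  })
  if (!is.null(cds) && !is.null(protein_fasta)) {
    aa <- tryCatch(Biostrings::readAAStringSet(protein_fasta),
                   error = function(e) NULL)
    if (is.null(aa)) {
      errors <- c(errors, "protein FASTA unreadable")
    } else {
      ids <- sub("\\s.*$", "", names(aa))
      common <- intersect(ids, cds$id)
      mism <- common[as.character(aa[match(common, ids)]) !=
                       cds$aa_seq[match(common, cds$id)]]
      if (length(mism)) {
        errors <- c(errors, paste0("CDS translation does not match protein ",
                                   "FASTA for: ",
                                   paste(utils::head(mism, 5), collapse = ", ")))
      }
      if (length(common) < length(cds$id)) {
        warnings <- c(warnings, "protein FASTA does not cover every CDS record")
      }
    }
  }
  psms <- tryCatch(read_psm_table(psm_tsv), error = function(e) {
    errors <<- c(errors, paste0("PSM table invalid: ", conditionMessage(e)))
    NULL
  })
  design <- tryCatch({
    d <- read_tsv(design_tsv)
    validate_design(d)
    d
  }, error = function(e) {
    errors <<- c(errors, paste0("design table invalid: ", conditionMessage(e)))
    NULL
  })
  if (!is.null(psms) && !is.null(design)) {
    expected <- paste0("sn_", design$channel_id)
    if (!identical(sort(sn_columns(psms)), sort(expected))) {
      errors <- c(errors, "design channels do not match PSM reporter columns")
    }
  }
  list(errors = errors, warnings = warnings)
}

stage_log <- function(quiet, ...) {
  if (!quiet) message(sprintf(...))
}

#' Run the full simulate/process/map/analyze pipeline
#'
#' Orchestrates all stages. With `out_dir` set, every interface table is
#' written as TSV (plus CDS/protein FASTA and a run manifest); reruns with
#' an identical configuration are byte-identical. With `out_dir = NULL`
#' nothing touches disk and all intermediate and final objects are
#' returned.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed), or NULL for an
#'   in-memory run.
#' @param mode "all" (default), "simulate" (fixtures and truth only), or
#'   "analyze" (everything).
#' @param inputs Optional list (cds, psms, design) to analyze instead of
#'   simulating; file paths (cds_fasta, psm_tsv, design_tsv) are also
#'   accepted.
#' @param quiet Suppress stage logging to stderr.
#' @return Invisible list with all stage outputs (cds, design, psms, truth,
#'   filtered, fdr, assignment, quant_peptide, quant_protein, profiles,
#'   totals, comparison, fc_peptide, fc_protein, enrichment, heatmap,
#'   regression, manifest).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         mode = c("all", "simulate", "analyze"),
                         inputs = NULL, quiet = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  emit <- function(x, name, writer = write_tsv) {
    if (!is.null(out_dir)) writer(x, file.path(out_dir, name))
  }
  counts <- list()

  # ---- stage: simulate (or load) -------------------------------------------
  if (is.null(inputs)) {
    stage_log(quiet, "[simulate] seed=%d proteins=%d",
              config$sim$seed, config$sim$n_proteins)
    ds <- simulate_dataset(config$sim)
  } else {
    if (is.character(inputs$cds_fasta %||% NULL)) {
      if (!file.exists(inputs$cds_fasta)) {
        stop("mapping stage input missing: ", inputs$cds_fasta)
      }
      ds <- list(cds = read_cds_fasta(inputs$cds_fasta),
                 psms = read_psm_table(inputs$psm_tsv),
                 design = read_tsv(inputs$design_tsv),
                 truth = NULL)
    } else {
      ds <- list(cds = inputs$cds, psms = inputs$psms,
                 design = inputs$design, truth = inputs$truth %||% NULL)
    }
    validate_design(ds$design)
  }
  counts$proteins <- nrow(ds$cds)
  counts$psms_in <- nrow(ds$psms)
  emit(ds$cds, "cds.fasta", write_cds_fasta)
  emit(ds$cds, "proteins.fasta", write_protein_fasta)
  emit(ds$design, "design.tsv")
  emit(ds$psms, "psms.tsv", write_psm_table)
  if (!is.null(ds$truth)) emit(ds$truth, "truth.tsv")
  if (mode == "simulate") {
    emit(manifest_lines(config, counts), "manifest.txt", writeLines)
    return(invisible(c(ds, list(manifest = counts))))
  }

  # ---- stage: process -------------------------------------------------------
  th <- config$thresholds
  flt <- filter_psms(ds$psms, th, ds$design)
  counts$psms_filtered <- nrow(flt$retained)
  stage_log(quiet, "[process] %d/%d PSMs pass quality filters",
            nrow(flt$retained), nrow(ds$psms))
  pep_fdr <- apply_fdr(flt$retained, th$peptide_fdr, unit = "peptide")
  pass_pep <- pep_fdr$units$unit[pep_fdr$units$score >= pep_fdr$threshold]
  psms_pep <- flt$retained[flt$retained$peptide %in% pass_pep, , drop = FALSE]
  prot_fdr <- apply_fdr(psms_pep, th$protein_fdr, unit = "protein")
  kept_prot <- prot_fdr$retained
  psms_q <- psms_pep[!psms_pep$is_decoy &
                       psms_pep$peptide %in% pep_fdr$retained, , drop = FALSE]
  cand <- strsplit(psms_q$protein_ids, ";", fixed = TRUE)
  cand <- lapply(cand, intersect, kept_prot)
  psms_q <- psms_q[lengths(cand) > 0L, , drop = FALSE]
  cand <- cand[lengths(cand) > 0L]
  counts$peptides <- length(unique(psms_q$peptide))
  counts$proteins_retained <- length(kept_prot)
  stage_log(quiet, "[process] %d peptides / %d proteins at %g%%/%g%% FDR",
            counts$peptides, counts$proteins_retained,
            100 * th$peptide_fdr, 100 * th$protein_fdr)
  if (nrow(psms_q) == 0L) stop("stage process: no PSMs survive FDR control")

  pep2prot <- lapply(split(cand, psms_q$peptide),
                     function(x) sort(unique(unlist(x))))
  assignment <- assemble_parsimony(pep2prot)
  counts$protein_groups <- length(attr(assignment, "groups"))
  quant_pep <- quantify(psms_q, NULL, ds$design, unit = "peptide")
  quant_prot <- quantify(psms_q, assignment, ds$design, unit = "protein")
  emit(flt$retained, "filtered_psms.tsv", write_psm_table)
  emit(flt$tally, "exclusion_tally.tsv")
  emit(assignment, "protein_groups.tsv")
  emit(quant_pep, "quant_peptide.tsv",
       function(x, p) write_quant_matrix(x, p, "peptide"))
  emit(quant_prot, "quant_protein.tsv",
       function(x, p) write_quant_matrix(x, p, "protein_id"))

  # ---- stage: map -----------------------------------------------------------
  profiles <- peptide_codon_profiles(rownames(quant_pep), assignment, ds$cds)
  counts$profiled_peptides <- nrow(profiles)
  stage_log(quiet, "[map] codon profiles for %d peptides", nrow(profiles))
  emit(profiles, "codon_profiles.tsv")

  # ---- stage: analyze -------------------------------------------------------
  totals <- weighted_codon_totals(quant_pep, profiles)
  comparison <- compare_codon_totals(totals, ds$design,
                                     codons = sense_codons())
  fc_pep <- fold_changes(quant_pep, ds$design, config$threshold_fold,
                         config$pseudocount)
  fc_prot <- fold_changes(quant_prot, ds$design, config$threshold_fold,
                          config$pseudocount)
  down <- fc_pep$unit_id[fc_pep$is_down_2x]
  if (config$significance_gate) {
    down <- intersect(down, gate_significant(quant_pep, ds$design,
                                             config$gate_alpha))
  }
  enrichment <- codon_enrichment(profiles, down_set = down)
  heat <- heatmap_layout(enrichment)
  regression <- tryCatch(
    regress_fc_on_aaa(fc_pep, profiles, grouping = config$grouping),
    error = function(e) {
      stage_log(quiet, "[analyze] regression unavailable: %s",
                conditionMessage(e))
      NULL
    })
  counts$down_peptides <- length(down)
  counts$down_proteins_2x <- sum(fc_prot$is_down_2x)
  stage_log(quiet,
            "[analyze] %d peptides >%g-fold down; Lys(AAA) delta rank %s",
            length(down), config$threshold_fold,
            enrichment$rank[enrichment$codon == "AAA"])

  emit(as.data.frame(cbind(sample_id = rownames(totals), totals)),
       "weighted_codon_totals.tsv")
  emit(comparison, "codon_group_comparison.tsv")
  emit(fc_pep, "fold_change_peptide.tsv")
  emit(fc_prot, "fold_change_protein.tsv")
  emit(enrichment, "codon_enrichment.tsv")
  emit(data.frame(first_two = rownames(heat), heat, check.names = FALSE),
       "codon_heatmap.tsv")
  scatter <- fc_prot[c("unit_id", "mean_control", "mean_ko", "is_down_2x")]
  emit(scatter, "protein_scatter.tsv")
  if (!is.null(regression)) {
    emit(data.frame(term = "pct_AAA", slope = regression$slope,
                    standard_error = regression$standard_error,
                    p_value = regression$p_value,
                    grouping = regression$grouping_variable,
                    converged = regression$converged),
         "regression_summary.tsv")
  }
  emit(manifest_lines(config, counts), "manifest.txt", writeLines)

  invisible(list(
    cds = ds$cds, design = ds$design, psms = ds$psms, truth = ds$truth,
    filtered = flt, peptide_fdr = pep_fdr, protein_fdr = prot_fdr,
    assignment = assignment, quant_peptide = quant_pep,
    quant_protein = quant_prot, profiles = profiles, totals = totals,
    comparison = comparison, fc_peptide = fc_pep, fc_protein = fc_prot,
    down_set = down, enrichment = enrichment, heatmap = heat,
    regression = regression, manifest = counts))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# peptides whose per-peptide equal-variance t-test rejects at alpha
gate_significant <- function(quant, design, alpha) {
  i_c <- match(design$sample_id[design$group == "control"], colnames(quant))
  i_k <- match(design$sample_id[design$group == "ko"], colnames(quant))
  p <- apply(quant, 1L, function(v) {
    x <- v[i_c]; y <- v[i_k]
    if (stats::sd(x) == 0 && stats::sd(y) == 0) return(1)
    stats::t.test(x, y, var.equal = TRUE)$p.value
  })
  rownames(quant)[p < alpha]
}

# deterministic manifest: config echo + record counts, no timestamps
manifest_lines <- function(config, counts) {
  flat <- function(x, prefix = "") {
    out <- character(0)
    for (nm in names(x)) {
      v <- x[[nm]]
      if (is.list(v) && !is.null(names(v))) {
        out <- c(out, flat(v, paste0(prefix, nm, ".")))
      } else if (!is.null(v) && !is.function(v)) {
        out <- c(out, sprintf("%s%s: %s", prefix, nm,
                              paste(format(v, digits = 15), collapse = ",")))
      }
    }
    out
  }
  c(sprintf("tmtcodon manifest (package version %s)",
            as.character(utils::packageVersion("tmtcodon"))),
    "# configuration", flat(unclass(config)),
    "# record counts", flat(counts))
}
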