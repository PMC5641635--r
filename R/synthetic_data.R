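#' Configuration for the synthetic TMT proteome generator
#'
#' Captures everything the simulator needs to emit a coding-sequence database
#' and a PSM-level 10-plex TMT quantification table with known ground truth.
#' Defaults describe the design being emulated: 10 reporter channels pooled
#' 1:1 and split 5 control vs 5 knockout, tryptic peptides drawn from
#' CDS-backed proteins, reporter signal-to-noise with multiplicative noise
#' and channel dropout, decoy PSMs from reversed sequences, and an optional
#' codon-dependent translational-deficit effect.
#'
#' @param n_proteins Number of target proteins to generate.
#' @param length_mean_aa,length_sd_aa Mean and SD of protein length in amino
#'   acids; lengths are drawn log-normally with these natural-scale moments.
#' @param codon_usage Named numeric vector of relative weights over exactly
#'   the 61 sense codons (see [sense_codons()]); default uniform.
#' @param usage_dispersion Dirichlet concentration controlling how much
#'   per-protein codon usage varies around `codon_usage`; smaller values give
#'   more between-protein spread in e.g. Lys(AAA) frequency.
#' @param n_control,n_ko Samples per group; their sum is the channel count.
#' @param effect_beta Slope of the injected translational-deficit effect:
#'   a protein with Lys(AAA) frequency f (in percent of codons) has true
#'   knockout/control log2 fold change `-effect_beta * f`. 0 = null world.
#' @param peptide_noise_sd SD (log2 units) of per-channel multiplicative
#'   measurement noise on reporter signal-to-noise.
#' @param peptide_response_sdlog SD (natural log) of the per-peptide
#'   ionization-efficiency factor shared by all channels of a peptide.
#' @param psm_per_peptide_mean Expected PSMs per digest peptide (Poisson).
#' @param channel_dropout_p Probability any one reporter channel of a PSM is
#'   missing (emitted as NA, never zero).
#' @param no_ms3_fraction Fraction of PSMs lacking an MS3 scan (these carry
#'   no reporter values and are removed by the quality filter).
#' @param decoy_fraction Fraction of all PSMs drawn from reversed (decoy)
#'   protein sequences.
#' @param base_sn_mean Signal-to-noise scale: expected per-channel S:N for a
#'   protein of unit abundance and a peptide of unit response.
#' @param abundance_sdlog SD (natural log) of true protein base abundances.
#' @param channel_scale Optional numeric vector (one entry per channel) of
#'   per-channel loading factors; default NULL = no channel imbalance.
#' @param max_missed_cleavages,min_peptide_len,max_peptide_len Tryptic
#'   digestion parameters (cut after K/R except before P).
#' @param seed Integer seed; all stochastic draws flow from one generator
#'   stream started at this seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_proteins = 300,
                       length_mean_aa = 400,
                       length_sd_aa = 250,
                       codon_usage = NULL,
                       usage_dispersion = 60,
                       n_control = 5,
                       n_ko = 5,
                       effect_beta = 0,
                       peptide_noise_sd = 1.0,
                       peptide_response_sdlog = 1.0,
                       psm_per_peptide_mean = 1.3,
                       channel_dropout_p = 0.05,
                       no_ms3_fraction = 0.02,
                       decoy_fraction = 0.10,
                       base_sn_mean = 50,
                       abundance_sdlog = 1.0,
                       channel_scale = NULL,
                       max_missed_cleavages = 2,
                       min_peptide_len = 6,
                       max_peptide_len = 40,
                       seed = 1L) {
  if (is.null(codon_usage)) {
    codon_usage <- stats::setNames(rep(1, 61), sense_codons())
  }
  cfg <- list(
    n_proteins = as.integer(n_proteins),
    length_mean_aa = length_mean_aa, length_sd_aa = length_sd_aa,
    codon_usage = codon_usage, usage_dispersion = usage_dispersion,
    n_control = as.integer(n_control), n_ko = as.integer(n_ko),
    effect_beta = effect_beta,
    peptide_noise_sd = peptide_noise_sd,
    peptide_response_sdlog = peptide_response_sdlog,
    psm_per_peptide_mean = psm_per_peptide_mean,
    channel_dropout_p = channel_dropout_p,
    no_ms3_fraction = no_ms3_fraction,
    decoy_fraction = decoy_fraction,
    base_sn_mean = base_sn_mean,
    abundance_sdlog = abundance_sdlog,
    channel_scale = channel_scale,
    max_missed_cleavages = as.integer(max_missed_cleavages),
    min_peptide_len = as.integer(min_peptide_len),
    max_peptide_len = as.integer(max_peptide_len),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic TMT proteome configuration\n")
  cat(sprintf("  proteins: %d (length ~ logN, mean %g aa, sd %g aa)\n",
              x$n_proteins, x$length_mean_aa, x$length_sd_aa))
  cat(sprintf("  design: %d control vs %d knockout channels\n",
              x$n_control, x$n_ko))
  cat(sprintf("  effect_beta: %g (log2FC per %% Lys(AAA))\n", x$effect_beta))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

validate_sim_config <- function(cfg) {
  if (cfg$n_proteins < 1L) stop("n_proteins must be positive")
  if (!(cfg$length_mean_aa > 0) || !(cfg$length_sd_aa >= 0)) {
    stop("degenerate protein length distribution")
  }
  u <- cfg$codon_usage
  if (!setequal(names(u), sense_codons()) || length(u) != 61L) {
    stop("codon_usage must be named by exactly the 61 sense codons")
  }
  if (any(u < 0) || all(u == 0)) stop("codon_usage weights must be non-negative with positive sum")
  for (p in c("channel_dropout_p", "no_ms3_fraction", "decoy_fraction")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop(p, " must be in [0, 1]")
  }
  if (cfg$n_control < 1L || cfg$n_ko < 1L) stop("both groups need at least one channel")
  if (!is.null(cfg$channel_scale) &&
      length(cfg$channel_scale) != cfg$n_control + cfg$n_ko) {
    stop("channel_scale must have one entry per channel")
  }
  if (cfg$min_peptide_len < 1L || cfg$max_peptide_len < cfg$min_peptide_len) {
    stop("invalid peptide length window")
  }
  invisible(cfg)
}

#' Build the channel-to-sample design table for a configuration
#'
#' Control channels come first, then knockout, mirroring a 10-plex pooled at
#' a 1:1 ratio across samples.
#'
#' @param config A [sim_config()].
#' @return data.frame with columns channel_id, sample_id, group.
#' @export
sample_design <- function(config) {
  n <- config$n_control + config$n_ko
  data.frame(
    channel_id = sprintf("ch%02d", seq_len(n)),
    sample_id = c(sprintf("ctrl_%d", seq_len(config$n_control)),
                  sprintf("ko_%d", seq_len(config$n_ko))),
    group = rep(c("control", "ko"), c(config$n_control, config$n_ko)),
    stringsAsFactors = FALSE
  )
}

validate_design <- function(design, config = NULL) {
  stopifnot(all(c("channel_id", "sample_id", "group") %in% names(design)))
  if (anyDuplicated(design$channel_id)) stop("duplicate channel ids in design")
  if (!all(design$group %in% c("control", "ko"))) {
    stop("design groups must be 'control' or 'ko'")
  }
  if (length(unique(design$group)) < 2L) stop("both groups must be non-empty")
  if (!is.null(config) &&
      nrow(design) != config$n_control + config$n_ko) {
    stop("design has ", nrow(design), " channels but config expects ",
         config$n_control + config$n_ko)
  }
  invisible(design)
}

# Solve log-normal meanlog/sdlog from natural-scale mean and sd.
lnorm_pars <- function(mean, sd) {
  sdlog <- sqrt(log1p((sd / mean)^2))
  c(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Generate an in-frame coding-sequence database
#'
#' Protein lengths are log-normal; codons after the fixed ATG start are drawn
#' from a per-protein codon-usage vector sampled from a Dirichlet
#' distribution centred on `config$codon_usage` with concentration
#' `usage_dispersion`, so codon frequencies (notably Lys AAA) vary between
#' proteins. No stop codons are ever emitted, so every sequence translates
#' cleanly and amino-acid length equals nucleotide length / 3.
#'
#' @param config A [sim_config()].
#' @param set_seed Seed the RNG from `config$seed` first (default TRUE; the
#'   pipeline passes FALSE to keep a single stream across stages).
#' @return data.frame with columns id, nt_seq, aa_seq.
#' @export
generate_coding_sequences <- function(config, set_seed = TRUE) {
  validate_sim_config(config)
  if (set_seed) set.seed(config$seed)
  n <- config$n_proteins
  lp <- lnorm_pars(config$length_mean_aa, config$length_sd_aa)
  len_aa <- pmax(30L, as.integer(round(
    stats::rlnorm(n, lp["meanlog"], lp["sdlog"]))))
  base_w <- config$codon_usage[sense_codons()]
  alpha <- config$usage_dispersion * base_w / sum(base_w)
  nt <- character(n)
  aa <- character(n)
  for (i in seq_len(n)) {
    # per-protein Dirichlet usage via normalized gammas; zero weight stays zero
    g <- stats::rgamma(61L, shape = alpha, rate = 1)
    if (all(g == 0)) g <- base_w
    idx <- sample.int(61L, len_aa[i] - 1L, replace = TRUE, prob = g)
    codons <- c("ATG", sense_codons()[idx])
    nt[i] <- paste(codons, collapse = "")
    aa[i] <- paste(c("M", unname(.GENETIC_CODE[codons[-1L]])), collapse = "")
  }
  data.frame(id = sprintf("PROT%05d", seq_len(n)),
             nt_seq = nt, aa_seq = aa, stringsAsFactors = FALSE)
}

#' In-silico tryptic digestion
#'
#' Cleaves after K or R except when the next residue is P. Emits every
#' product with at most `max_missed_cleavages` internal uncut sites whose
#' length falls inside `[min_len, max_len]`. Coordinates are 0-based,
#' half-open in the protein.
#'
#' @param aa_seq Single amino-acid string.
#' @param max_missed_cleavages Maximum internal missed cleavage sites.
#' @param min_len,max_len Peptide length window (amino acids).
#' @return data.frame with columns peptide, start (0-based), missed.
#' @examples
#' digest_protein("MKAKR", max_missed_cleavages = 0, min_len = 1, max_len = 50)
#' @export
digest_protein <- function(aa_seq, max_missed_cleavages = 2,
                           min_len = 6, max_len = 40) {
  stopifnot(is.character(aa_seq), length(aa_seq) == 1L, nchar(aa_seq) > 0L)
  if (max_missed_cleavages < 0) stop("max_missed_cleavages must be >= 0")
  n <- nchar(aa_seq)
  m <- gregexpr("[KR](?!P)", aa_seq, perl = TRUE)[[1L]]
  cut_after <- if (m[1L] == -1L) integer(0) else as.integer(m)
  bounds <- unique(c(0L, cut_after, n))  # fragment boundaries, 0-based
  k <- length(bounds) - 1L               # number of fully-cleaved fragments
  if (k < 1L) return(data.frame(peptide = character(0), start = integer(0),
                                missed = integer(0)))
  out <- vector("list", max_missed_cleavages + 1L)
  for (mc in 0:max_missed_cleavages) {
    if (k - mc < 1L) break
    i <- seq_len(k - mc)
    start <- bounds[i]
    end <- bounds[i + mc + 1L]
    len <- end - start
    keep <- len >= min_len & len <= max_len
    if (!any(keep)) next
    out[[mc + 1L]] <- data.frame(
      peptide = substring(aa_seq, start[keep] + 1L, end[keep]),
      start = start[keep], missed = rep.int(mc, sum(keep)),
      stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) {
    return(data.frame(peptide = character(0), start = integer(0),
                      missed = integer(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Digest every protein in a CDS table; returns one row per (protein, peptide
# occurrence) with protein_idx into cds. Vectorized across proteins but
# equivalent to digest_protein() applied per sequence (property-tested).
digest_all <- function(cds, config) {
  aa <- cds$aa_seq
  n <- nchar(aa)
  hits <- gregexpr("[KR](?!P)", aa, perl = TRUE)
  start_l <- list(); end_l <- list(); mc_l <- list(); prot_l <- list()
  j <- 0L
  for (i in seq_along(aa)) {
    m <- hits[[i]]
    cut_after <- if (m[1L] == -1L) integer(0) else as.integer(m)
    bounds <- unique(c(0L, cut_after, n[i]))
    k <- length(bounds) - 1L
    for (mc in 0:config$max_missed_cleavages) {
      if (k - mc < 1L) break
      ii <- seq_len(k - mc)
      s <- bounds[ii]; e <- bounds[ii + mc + 1L]
      keep <- (e - s) >= config$min_peptide_len &
              (e - s) <= config$max_peptide_len
      if (!any(keep)) next
      j <- j + 1L
      start_l[[j]] <- s[keep]; end_l[[j]] <- e[keep]
      mc_l[[j]] <- rep.int(mc, sum(keep)); prot_l[[j]] <- rep.int(i, sum(keep))
    }
  }
  if (j == 0L) stop("digestion produced no peptides")
  start <- unlist(start_l); end <- unlist(end_l)
  prot <- unlist(prot_l)
  data.frame(
    peptide = substring(aa[prot], start + 1L, end),
    start = start, missed = unlist(mc_l), protein_idx = prot,
    stringsAsFactors = FALSE)
}

# peptide -> semicolon-joined sorted unique candidate accessions; most
# peptides have one candidate, so only runs of length > 1 pay for paste()
candidate_map <- function(peptide, protein_id) {
  dtu <- unique(data.table::data.table(pep = peptide, prot = protein_id))
  data.table::setorder(dtu, pep, prot)
  r <- rle(dtu$pep)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ids <- dtu$prot[starts]
  multi <- which(r$lengths > 1L)
  for (i in multi) {
    ids[i] <- paste(dtu$prot[starts[i]:ends[i]], collapse = ";")
  }
  stats::setNames(ids, r$values)
}

#' Simulate a 10-plex TMT quantification experiment
#'
#' Digests every protein, draws a Poisson number of PSMs per digest peptide,
#' and emits per-channel reporter signal-to-noise values
#' `base_sn_mean * abundance * response * 2^(group effect) * 2^noise`,
#' where the group effect for knockout channels is the protein's true log2
#' fold change `-effect_beta * f_AAA_percent`. Channels are dropped out
#' (explicit NA) with probability `channel_dropout_p`; a small fraction of
#' PSMs lack MS3 scans and carry no reporter values. Decoy PSMs are drawn
#' from reversed protein sequences with a stochastically lower score
#' distribution; decoy peptides colliding with any target peptide are
#' resampled away.
#'
#' @param cds CDS table from [generate_coding_sequences()].
#' @param design Design table from [sample_design()].
#' @param config A [sim_config()].
#' @param set_seed Seed the RNG from `config$seed` first (default TRUE).
#' @return list with elements `psms` (PSM table: psm_id, peptide,
#'   protein_ids, start_aa, score, is_decoy, has_ms3, sn_ch01..) and `truth`
#'   (protein_id, true_base_abundance, true_log2fc, f_AAA_percent).
#' @export
simulate_quant_experiment <- function(cds, design, config, set_seed = TRUE) {
  validate_sim_config(config)
  validate_design(design, config)
  if (nrow(cds) == 0L) stop("empty CDS set")
  if (set_seed) set.seed(config$seed)
  n_ch <- nrow(design)
  ko_ch <- design$group == "ko"

  # ground truth per protein
  f_aaa <- vapply(cds$nt_seq, function(s) {
    cd <- split_codons(s); 100 * sum(cd == "AAA") / length(cd)
  }, numeric(1), USE.NAMES = FALSE)
  abund <- stats::rlnorm(nrow(cds), 0, config$abundance_sdlog)
  log2fc <- -config$effect_beta * f_aaa
  truth <- data.frame(protein_id = cds$id,
                      true_base_abundance = abund,
                      true_log2fc = log2fc,
                      f_AAA_percent = f_aaa,
                      stringsAsFactors = FALSE)

  # target peptide population and candidate-protein map
  dig <- digest_all(cds, config)
  cand <- candidate_map(dig$peptide, cds$id[dig$protein_idx])

  n_psm <- stats::rpois(nrow(dig), config$psm_per_peptide_mean)
  rep_idx <- rep.int(seq_len(nrow(dig)), n_psm)
  n_t <- length(rep_idx)
  if (n_t == 0L) stop("no PSMs generated; increase psm_per_peptide_mean")

  # per-peptide ionization response, shared across that peptide's PSMs
  response <- stats::rlnorm(nrow(dig), 0, config$peptide_response_sdlog)
  prot_of <- dig$protein_idx[rep_idx]
  mu <- config$base_sn_mean * abund[prot_of] * response[rep_idx]
  shift <- outer(log2fc[prot_of], as.numeric(ko_ch))  # log2 group effect
  noise <- matrix(stats::rnorm(n_t * n_ch, 0, config$peptide_noise_sd),
                  n_t, n_ch)
  sn <- mu * 2^(shift + noise)
  if (!is.null(config$channel_scale)) {
    sn <- sweep(sn, 2L, config$channel_scale, `*`)
  }
  if (config$channel_dropout_p > 0) {
    sn[matrix(stats::runif(n_t * n_ch) < config$channel_dropout_p,
              n_t, n_ch)] <- NA_real_
  }
  no_ms3 <- stats::runif(n_t) < config$no_ms3_fraction
  sn[no_ms3, ] <- NA_real_

  target <- data.frame(
    peptide = dig$peptide[rep_idx],
    protein_ids = unname(cand[dig$peptide[rep_idx]]),
    start_aa = dig$start[rep_idx],
    score = stats::rnorm(n_t, 4, 1),
    is_decoy = FALSE,
    has_ms3 = !no_ms3,
    stringsAsFactors = FALSE)
  target <- cbind(target, as.data.frame(sn))

  # decoys from reversed proteins; resample collisions with target peptides
  decoy <- NULL
  if (config$decoy_fraction > 0) {
    n_d <- round(n_t * config$decoy_fraction / (1 - config$decoy_fraction))
    rev_cds <- cds
    rev_cds$aa_seq <- vapply(strsplit(cds$aa_seq, ""), function(x)
      paste(rev(x), collapse = ""), character(1))
    rev_cds$id <- paste0("rev_", cds$id)
    ddig <- digest_all(rev_cds, config)
    ddig <- ddig[!(ddig$peptide %in% dig$peptide), , drop = FALSE]
    if (nrow(ddig) > 0L && n_d > 0L) {
      di <- sample.int(nrow(ddig), n_d, replace = TRUE)
      dmu <- config$base_sn_mean *
        stats::rlnorm(n_d, 0, config$abundance_sdlog) *
        stats::rlnorm(n_d, 0, config$peptide_response_sdlog)
      dsn <- dmu * 2^matrix(stats::rnorm(n_d * n_ch, 0,
                                         config$peptide_noise_sd), n_d, n_ch)
      if (!is.null(config$channel_scale)) {
        dsn <- sweep(dsn, 2L, config$channel_scale, `*`)
      }
      if (config$channel_dropout_p > 0) {
        dsn[matrix(stats::runif(n_d * n_ch) < config$channel_dropout_p,
                   n_d, n_ch)] <- NA_real_
      }
      d_no_ms3 <- stats::runif(n_d) < config$no_ms3_fraction
      dsn[d_no_ms3, ] <- NA_real_
      decoy <- data.frame(
        peptide = ddig$peptide[di],
        protein_ids = rev_cds$id[ddig$protein_idx[di]],
        start_aa = ddig$start[di],
        score = stats::rnorm(n_d, 1, 1),
        is_decoy = TRUE,
        has_ms3 = !d_no_ms3,
        stringsAsFactors = FALSE)
      decoy <- cbind(decoy, as.data.frame(dsn))
    }
  }

  psms <- rbind(target, decoy)
  names(psms)[grep("^V[0-9]+$", names(psms))] <-
    paste0("sn_", design$channel_id)
  psms$psm_id <- sprintf("PSM%06d", seq_len(nrow(psms)))
  psms <- psms[c("psm_id", setdiff(names(psms), "psm_id"))]
  rownames(psms) <- NULL
  list(psms = psms, truth = truth)
}

#' Generate a complete synthetic dataset in one seeded stream
#'
#' Convenience wrapper: seeds the RNG once from `config$seed`, then runs
#' [generate_coding_sequences()] and [simulate_quant_experiment()] in that
#' single stream.
#'
#' @param config A [sim_config()].
#' @return list with cds, design, psms, truth.
#' @export
simulate_dataset <- function(config) {
  set.seed(config$seed)
  cds <- generate_coding_sequences(config, set_seed = FALSE)
  design <- sample_design(config)
  sim <- simulate_quant_experiment(cds, design, config, set_seed = FALSE)
  list(cds = cds, design = design, psms = sim$psms, truth = sim$truth)
}
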