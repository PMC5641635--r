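test_that("translation follows the standard genetic code and validates input", {
  expect_identical(translate_cds("ATGAAAGCTAAG"), "MKAK")
  expect_identical(translate_cds("ATG"), "M")
  expect_error(translate_cds("ATGTAAAAA"), "codon position 2")
  expect_error(translate_cds("ATGA"), "multiple of 3")
  expect_error(translate_cds("ATGNNN"), "unrecognized codon")
})

test_that("generated coding sequences satisfy the CDS invariants", {
  cfg <- sim_config(n_proteins = 100, seed = 1)
  cds <- generate_coding_sequences(cfg)
  expect_equal(nrow(cds), 100)
  expect_true(all(nchar(cds$nt_seq) %% 3 == 0))
  expect_true(all(substr(cds$nt_seq, 1, 3) == "ATG"))
  # no internal stop and translation consistency, both via translate_cds
  retrans <- vapply(cds$nt_seq, translate_cds, character(1), USE.NAMES = FALSE)
  expect_identical(retrans, cds$aa_seq)
  expect_equal(nchar(cds$aa_seq), nchar(cds$nt_seq) / 3)
})

test_that("sequence generation is deterministic and byte-identical per seed", {
  cfg <- sim_config(n_proteins = 20, seed = 42)
  f1 <- tempfile(fileext = ".fasta"); f2 <- tempfile(fileext = ".fasta")
  write_cds_fasta(generate_coding_sequences(cfg), f1)
  write_cds_fasta(generate_coding_sequences(cfg), f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("zero AAA usage weight forces f_AAA = 0 in every protein", {
  usage <- stats::setNames(rep(1, 61), sense_codons())
  usage["AAA"] <- 0
  cfg <- sim_config(n_proteins = 30, codon_usage = usage, seed = 3)
  ds <- simulate_dataset(cfg)
  expect_true(all(ds$truth$f_AAA_percent == 0))
  expect_false(any(grepl("AAA", substring(ds$cds$nt_seq, 1, 3), fixed = TRUE)))
})

test_that("tryptic digestion applies cut-after-K/R-not-before-P exactly", {
  d0 <- digest_protein("MKAKR", max_missed_cleavages = 0, min_len = 1,
                       max_len = 50)
  expect_equal(d0$peptide, c("MK", "AK", "R"))
  expect_equal(d0$start, c(0L, 2L, 4L))
  expect_equal(d0$missed, c(0L, 0L, 0L))

  dp <- digest_protein("MKPR", max_missed_cleavages = 0, min_len = 1,
                       max_len = 50)
  expect_equal(dp$peptide, "MKPR")
  expect_equal(dp$start, 0L)

  d1 <- digest_protein("MKAKR", max_missed_cleavages = 1, min_len = 1,
                       max_len = 50)
  expect_true(all(c("MKAK", "AKR") %in% d1$peptide))
  expect_equal(d1[d1$peptide == "MKAK", c("start", "missed")],
               data.frame(start = 0L, missed = 1L),
               ignore_attr = TRUE)
  # length window is enforced
  dw <- digest_protein("MKAKR", max_missed_cleavages = 1, min_len = 3,
                       max_len = 3)
  expect_equal(dw$peptide, "AKR")
})

test_that("batch digestion agrees exactly with per-protein digestion", {
  set.seed(11)
  cfg <- sim_config(n_proteins = 40, length_mean_aa = 120, length_sd_aa = 60,
                    seed = 11)
  cds <- generate_coding_sequences(cfg)
  batch <- tmtcodon:::digest_all(cds, cfg)
  ref <- do.call(rbind, lapply(seq_len(nrow(cds)), function(i) {
    d <- digest_protein(cds$aa_seq[i], cfg$max_missed_cleavages,
                        cfg$min_peptide_len, cfg$max_peptide_len)
    if (nrow(d)) d$protein_idx <- i
    d
  }))
  ref <- ref[order(ref$protein_idx, ref$missed, ref$start), ]
  batch <- batch[order(batch$protein_idx, batch$missed, batch$start), ]
  expect_equal(unname(as.list(batch)), unname(as.list(ref)),
               ignore_attr = TRUE)
})

test_that("the injected effect model is exact in the truth table", {
  cfg0 <- sim_config(n_proteins = 25, effect_beta = 0, seed = 5)
  ds0 <- simulate_dataset(cfg0)
  expect_true(all(ds0$truth$true_log2fc == 0))

  cfg <- sim_config(n_proteins = 25, effect_beta = 0.2, seed = 5)
  ds <- simulate_dataset(cfg)
  expect_equal(ds$truth$true_log2fc, -0.2 * ds$truth$f_AAA_percent)
  # a protein with f_AAA = 10% would have true_log2fc exactly -2
  expect_equal(-0.2 * 10, -2)
})

test_that("channel dropout probability zero yields a complete reporter table", {
  cfg <- sim_config(n_proteins = 15, channel_dropout_p = 0,
                    no_ms3_fraction = 0, seed = 9)
  ds <- simulate_dataset(cfg)
  sn <- ds$psms[grep("^sn_", names(ds$psms))]
  expect_false(anyNA(sn))
  expect_true(all(ds$psms$has_ms3))
})

test_that("every target PSM peptide matches its protein at its coordinate", {
  cfg <- sim_config(n_proteins = 40, seed = 13)
  ds <- simulate_dataset(cfg)
  tgt <- ds$psms[!ds$psms$is_decoy, ]
  set.seed(99)
  take <- sample.int(nrow(tgt), 500)
  for (k in take) {
    prots <- strsplit(tgt$protein_ids[k], ";", fixed = TRUE)[[1]]
    aa <- ds$cds$aa_seq[match(prots, ds$cds$id)]
    hit <- any(vapply(aa, function(s) {
      substr(s, tgt$start_aa[k] + 1, tgt$start_aa[k] + nchar(tgt$peptide[k])) ==
        tgt$peptide[k]
    }, logical(1)))
    expect_true(hit)
  }
})

test_that("decoy peptides never collide with target peptides", {
  for (s in 1:5) {
    ds <- simulate_dataset(sim_config(n_proteins = 30, decoy_fraction = 0.2,
                                      seed = s))
    tgt <- unique(ds$psms$peptide[!ds$psms$is_decoy])
    dec <- unique(ds$psms$peptide[ds$psms$is_decoy])
    expect_length(intersect(tgt, dec), 0)
    # decoy scores sit stochastically below target scores
    expect_lt(mean(ds$psms$score[ds$psms$is_decoy]),
              mean(ds$psms$score[!ds$psms$is_decoy]))
  }
})

test_that("reporter means recover the true group ratio within MC error", {
  # many PSMs over few proteins: >= 1000 PSMs per protein
  cfg <- sim_config(n_proteins = 3, length_mean_aa = 500, length_sd_aa = 50,
                    effect_beta = 0.5, psm_per_peptide_mean = 15,
                    channel_dropout_p = 0, no_ms3_fraction = 0,
                    decoy_fraction = 0, seed = 21)
  ds <- simulate_dataset(cfg)
  ko_cols <- paste0("sn_", ds$design$channel_id[ds$design$group == "ko"])
  ct_cols <- paste0("sn_", ds$design$channel_id[ds$design$group == "control"])
  for (pid in ds$truth$protein_id) {
    rows <- vapply(strsplit(ds$psms$protein_ids, ";", fixed = TRUE),
                   function(x) pid %in% x, logical(1)) & !ds$psms$is_decoy
    expect_gt(sum(rows), 1000)
    obs <- log2(mean(as.matrix(ds$psms[rows, ko_cols])) /
                  mean(as.matrix(ds$psms[rows, ct_cols])))
    expect_equal(obs, ds$truth$true_log2fc[ds$truth$protein_id == pid],
                 tolerance = 0.12)
  }
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_proteins = 0), "positive")
  expect_error(sim_config(channel_dropout_p = 1.5), "\\[0, 1\\]")
  expect_error(sim_config(codon_usage = c(AAA = 1)), "61 sense codons")
  bad_usage <- stats::setNames(rep(1, 61), sense_codons())
  names(bad_usage)[1] <- "TAA"
  expect_error(sim_config(codon_usage = bad_usage), "61 sense codons")
  cfg <- sim_config(n_proteins = 5, seed = 1)
  wrong_design <- sample_design(sim_config(n_control = 4, n_ko = 4))
  cds <- generate_coding_sequences(cfg)
  expect_error(simulate_quant_experiment(cds, wrong_design, cfg), "channels")
})
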