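des <- design10()

# minimal profile table: counts over the 61 codons plus bookkeeping columns
mk_profiles <- function(peptides, protein, codon_lists) {
  counts <- t(vapply(codon_lists,
                     function(x) unname(count_codons(x))[seq_len(61)],
                     integer(61)))
  colnames(counts) <- sense_codons()
  cbind(data.frame(peptide = peptides, protein_id = protein,
                   start_aa = 0L, length = lengths(codon_lists),
                   n_sites = 1L, stringsAsFactors = FALSE),
        as.data.frame(counts))
}

test_that("abundance weighting of codon totals is exact", {
  prof <- mk_profiles(c("pepA", "pepB"), "PX",
                      list(c("AAA", "AAA", "GCT"), c("AAA", "TGG", "TGG")))
  quant <- matrix(c(10, 5, 2, 7), nrow = 2,
                  dimnames = list(c("pepA", "pepB"),
                                  c("ctrl_1", "ko_1")))
  tot <- weighted_codon_totals(quant, prof)
  expect_equal(unname(tot["ctrl_1", "AAA"]), 2 * 10 + 1 * 5)
  expect_equal(unname(tot["ko_1", "AAA"]), 2 * 2 + 1 * 7)
  expect_equal(unname(tot["ctrl_1", "TGG"]), 2 * 5)
  # annihilator and linearity
  expect_true(all(weighted_codon_totals(quant * 0, prof) == 0))
  expect_equal(weighted_codon_totals(quant * 4, prof), 4 * tot)
  expect_error(weighted_codon_totals(
    matrix(1, 1, 1, dimnames = list("ghost", "ctrl_1")), prof),
    "without a codon profile")
})

test_that("the group t-test matches stats::t.test and handles degeneracy", {
  tot <- matrix(0, nrow = 10, ncol = 61,
                dimnames = list(des$sample_id, sense_codons()))
  tot[, "AAA"] <- c(1, 2, 3, 2, 2, 4, 5, 6, 5, 5)
  cmp <- compare_codon_totals(tot, des, "AAA")
  oracle <- stats::t.test(tot[1:5, "AAA"], tot[6:10, "AAA"], var.equal = TRUE)
  expect_equal(cmp$t_statistic, unname(oracle$statistic))
  expect_equal(cmp$p_value, oracle$p.value)
  expect_equal(cmp$mean_control, 2)
  expect_equal(cmp$mean_ko, 5)

  # identical constant groups: defined as t = 0, p = 1
  tot[, "AAG"] <- 10
  cmp0 <- compare_codon_totals(tot, des, "AAG")
  expect_equal(cmp0$t_statistic, 0)
  expect_equal(cmp0$p_value, 1)

  # three-vs-three example: pooled-variance t with 4 df
  d3 <- data.frame(channel_id = sprintf("ch%02d", 1:6),
                   sample_id = sprintf("s%d", 1:6),
                   group = rep(c("control", "ko"), each = 3))
  t3 <- matrix(0, 6, 61, dimnames = list(d3$sample_id, sense_codons()))
  t3[, "AAA"] <- c(1, 2, 3, 4, 5, 6)
  cmp3 <- compare_codon_totals(t3, d3, "AAA")
  o3 <- stats::t.test(1:3, 4:6, var.equal = TRUE)
  expect_equal(cmp3$t_statistic, unname(o3$statistic))  # = -3.674 with 4 df
  expect_equal(cmp3$p_value, o3$p.value)                # = 0.02131
  expect_lt(cmp3$t_statistic, 0)

  one <- d3[c(1, 4), ]
  expect_error(compare_codon_totals(t3[c(1, 4), ], one, "AAA"),
               "two samples per group")
})

test_that("group statistics are invariant to relabeling within a group", {
  set.seed(19)
  tot <- matrix(rlnorm(10 * 61), nrow = 10,
                dimnames = list(des$sample_id, sense_codons()))
  perm <- des
  perm$sample_id <- des$sample_id[c(3, 1, 2, 5, 4, 8, 10, 6, 7, 9)]
  a <- compare_codon_totals(tot, des, c("AAA", "GGG"))
  b <- compare_codon_totals(tot, perm, c("AAA", "GGG"))
  expect_equal(a, b)
})

test_that("fold changes and the 2-fold flag follow the stated arithmetic", {
  q <- matrix(c(rep(100, 5), rep(25, 5),
                rep(100, 5), rep(51, 5),
                rep(40, 5), rep(40, 5),
                rep(0, 10)),
              nrow = 4, byrow = TRUE,
              dimnames = list(c("a", "b", "c", "absent"), des$sample_id))
  fc <- fold_changes(q, des, pseudocount = 0)
  expect_equal(fc$log2fc[fc$unit_id == "a"], -2)
  expect_true(fc$is_down_2x[fc$unit_id == "a"])
  expect_equal(fc$log2fc[fc$unit_id == "b"], log2(51 / 100))
  expect_false(fc$is_down_2x[fc$unit_id == "b"])
  expect_equal(fc$log2fc[fc$unit_id == "c"], 0)
  expect_false(fc$is_down_2x[fc$unit_id == "c"])
  # all-zero units are dropped and logged
  expect_false("absent" %in% fc$unit_id)
  expect_identical(attr(fc, "dropped"), "absent")
  # pseudocount bounds the ratio when one group is absent
  q2 <- matrix(c(rep(64, 5), rep(0, 5)), nrow = 1,
               dimnames = list("only_ctrl", des$sample_id))
  fc2 <- fold_changes(q2, des, pseudocount = 0.5)
  expect_equal(fc2$log2fc, log2(0.5 / 64.5))
  expect_true(is.finite(fc2$log2fc))
})

test_that("codon enrichment deltas and ranks match hand computation", {
  prof <- mk_profiles(c("down1", "other"), "PX",
                      list(c("GCT", "GCT"), c("AAA", "GCT")))
  enr <- codon_enrichment(prof, down_set = "down1")
  # totals: 4 codons, AAA 1 (25%), GCT 3 (75%); down: GCT 100%
  expect_equal(enr$freq_total_percent[enr$codon == "AAA"], 25)
  expect_equal(enr$freq_down_percent[enr$codon == "GCT"], 100)
  expect_equal(enr$delta_percent[enr$codon == "GCT"], 25)
  expect_equal(enr$delta_percent[enr$codon == "AAA"], -25)
  expect_equal(enr$rank[enr$codon == "GCT"], 1)
  expect_equal(enr$rank[enr$codon == "AAA"], 61)
  # frequency normalization invariant
  expect_equal(sum(enr$freq_total_percent), 100, tolerance = 1e-9)
  expect_equal(sum(enr$freq_down_percent), 100, tolerance = 1e-9)

  # down = total: all deltas zero, ranks are 1..61 in alphabetical order
  enr2 <- codon_enrichment(prof, down_set = c("down1", "other"))
  expect_true(all(enr2$delta_percent == 0))
  expect_identical(enr2$rank, seq_len(61))
  expect_identical(sort(enr2$rank), seq_len(61))

  # pure-AAA downregulated peptide takes rank 1
  prof3 <- mk_profiles(c("aaa", "mix"), "PX",
                       list(c("AAA", "AAA"), c("GCT", "TGG", "AAA")))
  enr3 <- codon_enrichment(prof3, down_set = "aaa")
  expect_equal(enr3$freq_down_percent[enr3$codon == "AAA"], 100)
  expect_equal(enr3$rank[enr3$codon == "AAA"], 1)

  # empty down set is flagged, not fabricated
  enr4 <- codon_enrichment(prof, down_set = character(0))
  expect_true(attr(enr4, "empty_down"))
  expect_true(all(is.na(enr4$delta_percent)))
  expect_error(codon_enrichment(prof, down_set = "ghost"), "subset")
})

test_that("heatmap layout places 61 deltas in the codon table with 3 stops", {
  prof <- mk_profiles("p", "PX", list(c("AAA", "GCT")))
  enr <- codon_enrichment(prof, down_set = "p")
  m <- heatmap_layout(enr)
  expect_equal(dim(m), c(16, 4))
  expect_equal(sum(is.na(m)), 3)
  expect_true(all(is.na(m[cbind(c("TA", "TA", "TG"), c("A", "G", "A"))])))
  expect_equal(rownames(m)[1:4], c("TT", "TC", "TA", "TG"))
  # every sense codon appears exactly once at its table position
  expect_equal(unname(m["AA", "A"]),
               enr$delta_percent[enr$codon == "AAA"])
  zero <- enr
  zero$delta_percent <- 0
  expect_true(all(heatmap_layout(zero) == 0, na.rm = TRUE))
})

test_that("the mixed-effects regression recovers sign and handles degeneracy", {
  set.seed(23)
  suppressMessages({
    ds <- run_pipeline(pipeline_config(
      sim = sim_config(n_proteins = 60, effect_beta = 0.3, seed = 23)),
      quiet = TRUE)
  })
  r <- ds$regression
  expect_lt(r$slope, 0)
  expect_true(r$standard_error > 0)
  expect_equal(r$grouping_variable, "protein_id")

  # constant predictor is a degenerate design
  prof <- mk_profiles(c("p1", "p2", "p3"), c("A", "B", "C"),
                      list(c("GCT", "GCT"), c("GCT", "GCT"), c("GCT", "GCT")))
  prof <- prof[rep(1:3, each = 4), ]
  prof$peptide <- sprintf("p%d", 1:12)
  prof$protein_id <- rep(c("A", "B", "C"), each = 4)
  fc <- data.frame(unit_id = prof$peptide, log2fc = rnorm(12))
  expect_error(regress_fc_on_aaa(fc, prof), "degenerate")

  # all-zero fold changes: slope 0, p 1, flagged unconverged
  prof$AAA <- rep(c(0L, 1L, 2L), 4)
  fc0 <- data.frame(unit_id = prof$peptide, log2fc = 0)
  r0 <- regress_fc_on_aaa(fc0, prof)
  expect_equal(r0$slope, 0)
  expect_equal(r0$p_value, 1)
  expect_false(r0$converged)
})
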