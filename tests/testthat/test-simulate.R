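test_that("sequence generation is byte-deterministic and manifest-complete", {
  pe <- data.frame(mirna = 1:2, lncrna = 1:2, offset = c(50L, 120L),
                   bulge_side = c("none", "lncrna"), bulge_length = c(0L, 1L),
                   n_mismatches = c(1L, 0L), n_wobbles = c(0L, 1L))
  cfg <- synth_config(seed = 42L, planted_etm = pe)
  s1 <- gen_sequences(cfg)
  s2 <- gen_sequences(cfg)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_fasta(s1$lncrnas, f1); write_fasta(s2$lncrnas, f2)
  expect_identical(readLines(f1), readLines(f2))
  # one manifest row per planted item: 2 positives + 3 negatives
  expect_equal(nrow(s1$manifest), 5L)
  expect_equal(sum(s1$manifest$label == "positive"), nrow(pe))
  expect_error(
    gen_sequences(synth_config(planted_etm = data.frame(
      mirna = 1, lncrna = 1, offset = 10000, bulge_side = "none",
      bulge_length = 0, n_mismatches = 0, n_wobbles = 0))),
    "exceeds")
  expect_error(synth_config(planted_etm = data.frame(
    mirna = 1, lncrna = 1, offset = 1, bulge_side = "none",
    bulge_length = 0, n_mismatches = 2, n_wobbles = 1)),
    "at most 2")
})

test_that("planted sites satisfy the rules; negatives violate exactly one", {
  pe <- data.frame(mirna = 1:3, lncrna = 1:3, offset = 100L,
                   bulge_side = c("none", "lncrna", "mirna"),
                   bulge_length = c(0L, 2L, 1L),
                   n_mismatches = c(1L, 0L, 1L), n_wobbles = c(1L, 1L, 0L))
  s <- gen_sequences(synth_config(seed = 7L, planted_etm = pe))
  for (k in which(s$manifest$label == "positive")) {
    m <- s$manifest[k, ]
    rep <- validate_etm_table(data.frame(
      mirna_id = m$mirna_id,
      mirna_seq = s$mirnas$residues[s$mirnas$id == m$mirna_id],
      lncrna_id = m$lncrna_id, etm_site_gapped = m$site_seq))
    expect_true(rep$verdict)
  }
  for (rule in c("rule1", "rule2", "rule3")) {
    m <- s$manifest[s$manifest$label == paste0("negative_", rule), ]
    rep <- validate_etm_table(data.frame(
      mirna_id = m$mirna_id, mirna_seq = s$mirnas$residues[1],
      lncrna_id = m$lncrna_id, etm_site_gapped = m$site_seq))
    expect_false(rep$verdict)
    expect_false(rep[[paste0(sub("rule", "rule", rule), "_ok")]])
    others <- setdiff(c("rule1_ok", "rule2_ok", "rule3_ok"),
                      paste0(rule, "_ok"))
    expect_true(all(unlist(rep[others])))
  }
})

test_that("expression generation is deterministic and hits planted targets", {
  cfg <- synth_config(
    seed = 9L, n_lncrnas = 20L, n_genes = 30L, noise_cv = 0.1,
    planted_tau = data.frame(feature_id = "lnc05", target_tissue = "stamen",
                             fold_over_background = 1000),
    trans_r = data.frame(lncrna_id = c("lnc01", "lnc02"),
                         gene_id = c("gene01", "gene02"),
                         target_r = c(0.99, -0.99)))
  e1 <- gen_expression(cfg)
  e2 <- gen_expression(cfg)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_expression(e1$lnc_gene_expr, f1)
  write_expression(e2$lnc_gene_expr, f2)
  expect_identical(readLines(f1), readLines(f2))

  # planted trans pairs achieve |r| within 0.02 of target at the sample level
  m <- unclass(e1$lnc_gene_expr)
  expect_equal(cor(m["lnc01", ], m["gene01", ]), 0.99, tolerance = 0.021)
  expect_equal(cor(m["lnc02", ], m["gene02", ]), -0.99, tolerance = 0.021)
  expect_equal(e1$manifest$trans$realised_r,
               c(cor(m["lnc01", ], m["gene01", ]),
                 cor(m["lnc02", ], m["gene02", ])))
  expect_error(synth_config(trans_r = data.frame(
    lncrna_id = "l", gene_id = "g", target_r = 1)), "target_r")
})

test_that("a 1000-fold planted tissue factor yields tau >= 0.95 across seeds", {
  taus_planted <- numeric(0)
  taus_background <- numeric(0)
  for (sd in 1:100) {
    cfg <- synth_config(
      seed = sd, n_lncrnas = 5L, n_genes = 5L, n_mirnas = 2L, noise_cv = 0.1,
      planted_tau = data.frame(feature_id = "lnc1", target_tissue = "petal",
                               fold_over_background = 1000))
    e <- gen_expression(cfg)
    tau <- compute_tau(aggregate_tissues(e$lnc_gene_expr))
    taus_planted <- c(taus_planted, tau$tau[tau$feature_id == "lnc1"])
    taus_background <- c(taus_background,
                         tau$tau[tau$feature_id != "lnc1"])
  }
  expect_true(all(taus_planted >= 0.95))
  # unplanted (fold 1) features stay concentrated well below 0.95
  expect_lt(mean(taus_background), 0.5)
  expect_lt(quantile(taus_background, 0.99), 0.95)
})

test_that("annotation generation realises requested cis distances", {
  cd <- data.frame(lncrna_id = c("lnc01", "lnc02", "lnc03"),
                   gene_id = c("gene01", "gene02", "gene03"),
                   signed_distance_bp = c(50000L, -99999L, 150000L))
  cfg <- synth_config(seed = 5L, n_lncrnas = 12L, n_genes = 20L,
                      cis_distances = cd)
  ann <- gen_annotation(cfg)
  cis <- predict_cis(ann$features[ann$features$feature_class == "lncRNA", ],
                     ann$features[ann$features$feature_class == "gene", ])
  expect_equal(cis$distance_bp[cis$gene_id == "gene01"], 50000L)
  expect_equal(cis$side[cis$gene_id == "gene01"], "downstream")
  expect_equal(cis$distance_bp[cis$gene_id == "gene02"], 99999L)
  expect_equal(cis$side[cis$gene_id == "gene02"], "upstream")
  # a 150 kb pair is beyond the window
  expect_false("gene03" %in% cis$gene_id)
  # distractors never fall inside any lncRNA window
  expect_true(all(cis$gene_id %in% cd$gene_id))

  empty <- gen_annotation(synth_config(seed = 5L))
  expect_equal(sum(empty$features$feature_class == "gene"),
               synth_config()$n_genes)
  expect_error(gen_annotation(synth_config(cis_distances = data.frame(
    lncrna_id = c("lnc01", "lnc02"), gene_id = "gene01",
    signed_distance_bp = c(1000L, 2000L)))), "at most one")
})

test_that("DE generation plants recoverable positives and boundary rows", {
  planted <- sprintf("gene%04d", 1:100)
  cfg <- synth_config(seed = 6L, n_genes = 1000L, planted_de = planted)
  de <- gen_de_table(cfg)
  expect_equal(nrow(de$de_table), 1000L)
  expect_equal(filter_de(de$de_table), sort(planted))
  # boundary rows exist and are dropped
  tab <- de$de_table
  expect_true(any(tab$padj == 0.05))
  expect_true(any(abs(tab$log2fc) == 1))
})
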