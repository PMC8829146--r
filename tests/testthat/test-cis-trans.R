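test_that("cis prediction applies the window, chromosome guard, and sides", {
  lnc <- genomic_features("lncA", "chr1", 1000000L, 1001000L, "+", "lncRNA")
  genes <- genomic_features(
    id = c("g_up", "g_boundary", "g_out", "g_chr2", "g_overlap", "g_adj"),
    chrom = c("chr1", "chr1", "chr1", "chr2", "chr1", "chr1"),
    start = c(948000L, 1101000L, 1101001L, 948000L, 1000500L, 1001000L),
    end = c(950000L, 1103000L, 1103001L, 950000L, 1000600L, 1003000L),
    strand = "+", feature_class = "gene")
  res <- predict_cis(lnc, genes)
  expect_setequal(res$gene_id, c("g_up", "g_boundary", "g_overlap", "g_adj"))
  expect_equal(res$distance_bp[res$gene_id == "g_up"], 50000L)
  expect_equal(res$side[res$gene_id == "g_up"], "upstream")
  # nearest-edge gap of exactly 100,000 is inside the window
  expect_equal(res$distance_bp[res$gene_id == "g_boundary"], 100000L)
  expect_equal(res$side[res$gene_id == "g_boundary"], "downstream")
  # 100,001 is outside; same coordinates on another chromosome are outside
  expect_false("g_out" %in% res$gene_id)
  expect_false("g_chr2" %in% res$gene_id)
  # contained and book-ended genes report distance 0 / overlap
  expect_equal(res$distance_bp[res$gene_id %in% c("g_overlap", "g_adj")],
               c(0L, 0L))
  expect_true(all(res$side[res$gene_id %in% c("g_overlap", "g_adj")] ==
                    "overlap"))
})

test_that("cis prediction equals the all-pairs interval oracle", {
  set.seed(20)
  for (rep in 1:5) {
    n_l <- sample(20:60, 1)
    n_g <- sample(100:300, 1)
    mk <- function(prefix, n) {
      start <- sample(0:2000000, n)
      genomic_features(paste0(prefix, seq_len(n)),
                       sample(c("chr1", "chr2", "chr3"), n, replace = TRUE),
                       start, start + sample(500:5000, n, replace = TRUE),
                       "+", if (prefix == "l") "lncRNA" else "gene")
    }
    lnc <- mk("l", n_l)
    genes <- mk("g", n_g)
    expect_equal(predict_cis(lnc, genes), oracle_cis(lnc, genes))
    # translation invariance: shifting every feature leaves output fixed
    shift <- 123456L
    lnc2 <- lnc; lnc2$start <- lnc2$start + shift; lnc2$end <- lnc2$end + shift
    g2 <- genes; g2$start <- g2$start + shift; g2$end <- g2$end + shift
    expect_equal(predict_cis(lnc2, g2), predict_cis(lnc, genes))
  }
})

tissue4 <- setNames(rep(c("leaf", "petal", "stamen", "pistil"), each = 3),
                    paste0("s", 1:12))

test_that("trans prediction reports strictly |r| > threshold pairs", {
  set.seed(21)
  base <- rlnorm(12, 2, 1)
  lnc <- expression_matrix(
    matrix(c(base, rlnorm(12)), 2, 12, byrow = TRUE,
           dimnames = list(c("l_prop", "l_anti"), names(tissue4))), tissue4)
  gene_vals <- rbind(2 * base,                 # r = 1
                     max(base) + 1 - base,     # r = -1
                     rlnorm(12))
  genes <- expression_matrix(
    matrix(gene_vals, 3, 12,
           dimnames = list(c("g_prop", "g_anti", "g_noise"), names(tissue4))),
    tissue4)
  res <- predict_trans(lnc, genes)
  expect_true(all(c("g_prop", "g_anti") %in%
                    res$gene_id[res$lncrna_id == "l_prop"]))
  expect_equal(res$r[res$lncrna_id == "l_prop" & res$gene_id == "g_anti"], -1)
  expect_true(all(abs(res$r) <= 1 + 1e-12))

  # strictness: a pair at exactly the threshold is not reported
  r_noise <- cor(unclass(lnc)["l_prop", ], unclass(genes)["g_noise", ])
  at <- predict_trans(lnc, genes, r_threshold = abs(r_noise))
  expect_false(any(at$lncrna_id == "l_prop" & at$gene_id == "g_noise"))
  below <- predict_trans(lnc, genes, r_threshold = abs(r_noise) - 1e-9)
  expect_true(any(below$lncrna_id == "l_prop" & below$gene_id == "g_noise"))
})

test_that("trans prediction is invariant to sample permutation and row scaling", {
  set.seed(22)
  lnc <- expression_matrix(
    matrix(rlnorm(5 * 12), 5, 12,
           dimnames = list(paste0("l", 1:5), names(tissue4))), tissue4)
  genes <- expression_matrix(
    matrix(rlnorm(8 * 12), 8, 12,
           dimnames = list(paste0("g", 1:8), names(tissue4))), tissue4)
  res <- predict_trans(lnc, genes, r_threshold = 0.5)
  perm <- sample(12)
  res_p <- predict_trans(expression_matrix(unclass(lnc)[, perm], tissue4),
                         expression_matrix(unclass(genes)[, perm], tissue4),
                         r_threshold = 0.5)
  expect_equal(res_p, res)
  scaled <- unclass(lnc) * rlnorm(5)
  res_s <- predict_trans(expression_matrix(scaled, tissue4), genes,
                         r_threshold = 0.5)
  expect_equal(res_s[, c("lncrna_id", "gene_id")],
               res[, c("lncrna_id", "gene_id")])

  expect_error(predict_trans(lnc, expression_matrix(
    unclass(genes)[, 1:6], tissue4)), "identical sample columns")
})

test_that("zero-variance rows are skipped with a message", {
  m <- matrix(rlnorm(24), 2, 12,
              dimnames = list(c("l1", "l2"), names(tissue4)))
  m["l1", ] <- 7
  lnc <- expression_matrix(m, tissue4)
  genes <- expression_matrix(
    matrix(m["l2", ] * 3, 1, 12, dimnames = list("g1", names(tissue4))),
    tissue4)
  expect_message(res <- predict_trans(lnc, genes), "zero-variance")
  expect_equal(res$lncrna_id, "l2")
  expect_equal(res$r, 1)
})
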