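test_that("base pairs classify as Watson-Crick, wobble, or mismatch", {
  expect_equal(pair_class("A", "U"), "watson_crick")
  expect_equal(pair_class("G", "U"), "wobble")
  expect_equal(pair_class("U", "G"), "wobble")
  expect_equal(pair_class("C", "U"), "mismatch")
  expect_equal(pair_class(c("A", "G"), c("U", "C")),
               c("watson_crick", "watson_crick"))
  expect_error(pair_class("A", "T"), "A, C, G, U")
})

mir156h <- "UGACAGAAGAAAGAGAGCAC"
site7374 <- "GUGCUCUCUAUCUUCUGUCA"

test_that("published miR156h site passes with one mismatch at position 11", {
  aln <- pairing_alignment(mir156h, site7374,
                           mirna_id = "lch-miR156h", lncrna_id = "lch-lnc7374")
  rep <- evaluate_alignment(aln)
  expect_true(rep$verdict)
  expect_equal(rep$n_mismatch, 1L)
  expect_equal(rep$mismatch_positions, 11L)
  expect_equal(rep$n_wobble, 0L)
  expect_equal(nrow(rep$bulges), 0L)
})

test_that("a perfect reverse-complement duplex satisfies all rules", {
  set.seed(10)
  mir <- oracle_random_rna(21)
  rep <- evaluate_alignment(pairing_alignment(mir, oracle_revcomp(mir)))
  expect_true(rep$verdict)
  expect_equal(rep$n_mismatch + rep$n_wobble + nrow(rep$bulges), 0L)
})

test_that("any seed-region mismatch flips rule 1 and the verdict", {
  # mutate the site base paired with each miRNA position 2-8 in turn
  schars <- strsplit(site7374, "")[[1]]
  mchars <- strsplit(mir156h, "")[[1]]
  # residue that neither Watson-Crick- nor wobble-pairs the given base
  mm_partner <- c(A = "A", C = "C", G = "A", U = "U")
  n <- length(schars)
  for (p in 2:8) {
    mutated <- schars
    col_target_idx <- n - p + 1L   # column p pairs site base n-p+1 (5'->3')
    mutated[col_target_idx] <- mm_partner[[mchars[p]]]
    aln <- pairing_alignment(mir156h, paste(mutated, collapse = ""))
    rep <- evaluate_alignment(aln)
    expect_false(rep$rule1_ok)
    expect_false(rep$verdict)
  }
  # position 1 is exempt from rule 1 but counts toward rule 3
  schars1 <- schars
  schars1[n] <- "U"                # opposite miRNA position 1 (U): mismatch
  rep1 <- evaluate_alignment(pairing_alignment(mir156h,
                                               paste(schars1, collapse = "")))
  expect_true(rep1$rule1_ok)
  expect_equal(sort(rep1$mismatch_positions), c(1L, 11L))
})

test_that("three combined mismatches and wobbles fail rule 3", {
  set.seed(11)
  mir <- "UGACAGAAGAAAGAGAGCAC"
  tch <- strsplit(oracle_revcomp(mir), "")[[1]]
  n <- length(tch)
  # 2 mismatches (G:A at 13, A:A at 14) + 1 wobble (G:U at 15)
  tch[n - 13 + 1] <- "A"
  tch[n - 14 + 1] <- "A"
  tch[n - 15 + 1] <- "U"
  rep <- evaluate_alignment(pairing_alignment(mir, paste(tch, collapse = "")))
  expect_equal(rep$n_mismatch, 2L)
  expect_equal(rep$n_wobble, 1L)
  expect_false(rep$rule3_ok)
  expect_false(rep$verdict)
})

test_that("terminal overhang columns are excluded from rule counting", {
  # published pair whose printed rendering ends in a dash
  aln <- pairing_alignment("GCUCUCUAGCCUUCUGUCAUC", "GAUGACAGAAGCAUAGAGAG-",
                           mirna_id = "lch-miR157a-3p",
                           lncrna_id = "lch-lnc4803")
  rep <- evaluate_alignment(aln)
  expect_true(rep$verdict)
  expect_equal(rep$n_mismatch, 2L)
  expect_equal(nrow(rep$bulges), 0L)   # the terminal dash is not a bulge
})

test_that("bulge placement decides rule 2", {
  mir <- "UGACAGAAGAAAGAGAGCAC"
  wc <- oracle_revcomp(mir)
  ins <- function(s, after_col_from_3prime, nt) {
    # insert on the site strand so the bulge lands after the given miRNA
    # position; site is 5'->3' so insertion index counts from the 3' end
    n <- nchar(s)
    i <- n - after_col_from_3prime
    paste0(substr(s, 1, i), nt, substr(s, i + 1, n))
  }
  gap_at <- function(a) paste0(substr(mir, 1, a), "-",
                               substr(mir, a + 1, nchar(mir)))
  ok <- evaluate_alignment(pairing_alignment(gap_at(10), ins(wc, 10, "A")))
  expect_true(ok$rule2_ok)
  expect_true(ok$verdict)
  expect_equal(ok$bulges$side, "lncrna")
  expect_equal(ok$bulges$anchor, 10L)
  bad <- evaluate_alignment(pairing_alignment(gap_at(14), ins(wc, 14, "A")))
  expect_false(bad$rule2_ok)
  expect_false(bad$verdict)
  # over-long bulge fails even at a legal anchor
  long <- evaluate_alignment(pairing_alignment(
    paste0(substr(mir, 1, 10), "----", substr(mir, 11, nchar(mir))),
    ins(wc, 10, "ACGU")))
  expect_false(long$rule2_ok)
})

test_that("scanner recovers a planted site exactly and rejects noise", {
  set.seed(12)
  lnc <- paste0(oracle_random_rna(240), site7374, oracle_random_rna(240))
  hits <- scan_lncrna(mir156h, lnc, "lch-miR156h", "lnc_t")
  expect_length(hits, 1L)
  expect_equal(hits[[1]]$alignment$site_start, 240L)
  expect_equal(hits[[1]]$alignment$site_end, 260L)
  expect_equal(hits[[1]]$alignment$site_seq, site7374)
  expect_true(hits[[1]]$report$verdict)

  # a poly-A transcript offers no complementarity to this miRNA
  expect_length(scan_lncrna(mir156h, strrep("A", 100)), 0L)
  expect_error(scan_lncrna("ACGT", strrep("A", 100)), "RNA")
  expect_error(scan_lncrna(mir156h, "ACGU"), "shorter")
})

test_that("scanner output equals the brute-force enumeration oracle", {
  set.seed(13)
  n_checked <- 0L
  for (i in 1:110) {
    m_len <- sample(18:24, 1)
    l_len <- sample(60:200, 1)
    mir <- oracle_random_rna(m_len)
    # half the instances carry a planted (possibly imperfect) site
    lnc <- if (i %% 2 == 0) {
      site <- strsplit(oracle_revcomp(mir), "")[[1]]
      k <- sample(0:2, 1)
      for (p in sample(setdiff(seq_len(m_len), 2:8), k)) {
        site[m_len - p + 1] <- sample(c("A", "C", "G", "U"), 1)
      }
      pos <- sample(0:(l_len - m_len), 1)
      paste0(oracle_random_rna(pos), paste(site, collapse = ""),
             oracle_random_rna(l_len - m_len - pos))
    } else {
      oracle_random_rna(l_len)
    }
    got <- scan_lncrna(mir, lnc)
    want <- oracle_scan(mir, lnc)
    got_tab <- data.frame(
      start = vapply(got, function(h) h$alignment$site_start, 0L),
      end = vapply(got, function(h) h$alignment$site_end, 0L))
    expect_equal(got_tab, want, ignore_attr = TRUE)
    n_checked <- n_checked + 1L
    # every reported hit satisfies the rule invariants
    for (h in got) {
      expect_lte(h$report$n_mismatch + h$report$n_wobble, 2L)
      if (nrow(h$report$bulges) > 0L) {
        expect_true(all(h$report$bulges$anchor >= 9L &
                          h$report$bulges$anchor <= 12L))
      }
    }
  }
  expect_gte(n_checked, 100L)
})

test_that("site strand reversal convention round-trips", {
  set.seed(14)
  mir <- oracle_random_rna(20)
  site <- oracle_revcomp(mir)
  aln <- pairing_alignment(mir, site)
  # non-gap target chars, read back in column order, are the reversed site
  expect_equal(paste(rev(aln$columns$target_char), collapse = ""), site)
  expect_equal(aln$site_seq, site)
  # miRNA positions strictly increase over non-gap columns
  pos <- aln$columns$mirna_pos[!is.na(aln$columns$mirna_pos)]
  expect_true(all(diff(pos) > 0))
})
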