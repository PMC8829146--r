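# Independent oracles, written without reference to the package internals.

RNA4 <- c("A", "C", "G", "U")

oracle_random_rna <- function(n) {
  paste(sample(RNA4, n, replace = TRUE), collapse = "")
}

# plain lookup-based pair classification
oracle_class <- function(a, b) {
  p <- paste0(a, b)
  if (p %in% c("AU", "UA", "GC", "CG")) return("wc")
  if (p %in% c("GU", "UG")) return("wobble")
  "mm"
}

# Evaluate one explicit candidate alignment: miRNA chars and target chars
# per column (target is the reversed site window, with NA marking a gap on
# that strand; NA in mir marks a gap on the miRNA strand). Independent
# re-statement of the three rules. Candidates here never have terminal
# overhangs.
oracle_eval <- function(mir_cols, tgt_cols, max_bulge) {
  n <- length(mir_cols)
  mir_pos <- cumsum(!is.na(mir_cols))
  mir_pos[is.na(mir_cols)] <- NA
  n_mm <- 0L; n_wob <- 0L
  rule1 <- TRUE; rule2 <- TRUE
  in_bulge <- FALSE; bulge_len <- 0L; bulge_anchor <- NA; bulge_side <- NA
  close_bulge <- function() {
    if (bulge_side == "mir") {
      if (!(bulge_anchor >= 9 && (bulge_anchor + bulge_len - 1) <= 12)) {
        rule2 <<- FALSE
      }
    } else {
      if (!(bulge_anchor >= 9 && bulge_anchor <= 11)) rule2 <<- FALSE
    }
    if (bulge_len > max_bulge) rule2 <<- FALSE
  }
  last_pos <- 0L
  for (i in seq_len(n)) {
    gap <- is.na(mir_cols[i]) || is.na(tgt_cols[i])
    if (gap) {
      side <- if (is.na(tgt_cols[i])) "mir" else "lnc"
      if (!in_bulge) {
        in_bulge <- TRUE; bulge_len <- 1L; bulge_side <- side
        bulge_anchor <- if (side == "mir") mir_pos[i] else last_pos
      } else {
        bulge_len <- bulge_len + 1L
      }
      if (!is.na(mir_pos[i]) && mir_pos[i] >= 2 && mir_pos[i] <= 8) {
        rule1 <- FALSE
      }
      if (side == "lnc" && last_pos >= 2 && last_pos < 8) rule1 <- FALSE
    } else {
      if (in_bulge) { close_bulge(); in_bulge <- FALSE }
      cl <- oracle_class(mir_cols[i], tgt_cols[i])
      p <- mir_pos[i]
      last_pos <- p
      if (p >= 2 && p <= 8 && cl != "wc") rule1 <- FALSE
      if (cl == "mm") n_mm <- n_mm + 1L
      if (cl == "wobble") n_wob <- n_wob + 1L
    }
  }
  if (in_bulge) close_bulge()
  list(verdict = rule1 && rule2 && (n_mm + n_wob) < 3L,
       score = n_mm + n_wob, n_wob = n_wob)
}

# Brute-force enumeration of every candidate duplex in the scanner's
# search space: gapless at every offset, plus one bulge of length
# 1..max_bulge on either strand at every legal anchor at every offset.
oracle_scan <- function(mirna, lnc, max_bulge = 3L) {
  mch <- strsplit(mirna, "")[[1]]
  lch <- strsplit(lnc, "")[[1]]
  m <- length(mch); L <- length(lch)
  cands <- list()
  add <- function(st0, e, mir_cols, tgt_cols, n_bulge) {
    ev <- oracle_eval(mir_cols, tgt_cols, max_bulge)
    if (ev$verdict) {
      cands[[length(cands) + 1L]] <<- c(start = st0, end = e,
                                        score = ev$score, nb = n_bulge,
                                        nw = ev$n_wob)
    }
  }
  for (e in m:L) {
    # gapless
    w <- m
    st <- e - w + 1L
    if (st >= 1L) {
      add(st - 1L, e, mch, lch[e:st], 0L)
    }
    if (m >= 13L) {
      # one bulge of extra lncRNA nucleotides after miRNA position a
      for (b in 1:max_bulge) {
        w <- m + b
        st <- e - w + 1L
        if (st < 1L) next
        tgt <- lch[e:st]
        for (a in 9:11) {
          mir_cols <- c(mch[1:a], rep(NA, b), mch[(a + 1):m])
          add(st - 1L, e, mir_cols, tgt, 1L)
        }
      }
      # one run of unpaired miRNA positions s..s+b-1
      for (b in 1:min(max_bulge, 4L)) {
        w <- m - b
        st <- e - w + 1L
        if (st < 1L) next
        tgt0 <- lch[e:st]
        for (s in 9:(13L - b)) {
          tgt <- append(tgt0, rep(NA, b), after = s - 1L)
          add(st - 1L, e, mch, tgt, 1L)
        }
      }
    }
  }
  if (length(cands) == 0L) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  tab <- as.data.frame(do.call(rbind, cands))
  tab <- tab[order(tab$score, tab$nb, tab$nw, tab$start, tab$end), ]
  kept <- tab[0, ]
  for (i in seq_len(nrow(tab))) {
    if (!any(tab$start[i] < kept$end & kept$start < tab$end[i])) {
      kept <- rbind(kept, tab[i, ])
    }
  }
  kept <- kept[order(kept$start, kept$score), c("start", "end")]
  rownames(kept) <- NULL
  kept
}

# All-pairs quadratic interval-distance oracle for cis prediction
# (0-based half-open intervals).
oracle_cis <- function(lncrnas, genes, window_bp = 100000L) {
  rows <- list()
  for (i in seq_len(nrow(lncrnas))) {
    for (j in seq_len(nrow(genes))) {
      if (lncrnas$chrom[i] != genes$chrom[j]) next
      if (lncrnas$id[i] == genes$id[j]) next
      gap <- max(genes$start[j] - lncrnas$end[i],
                 lncrnas$start[i] - genes$end[j], 0L)
      if (gap > window_bp) next
      side <- if (gap == 0L) "overlap" else
        if (genes$end[j] <= lncrnas$start[i]) "upstream" else "downstream"
      rows[[length(rows) + 1L]] <- data.frame(
        lncrna_id = lncrnas$id[i], gene_id = genes$id[j],
        distance_bp = gap, side = side, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(lncrna_id = character(0), gene_id = character(0),
                      distance_bp = integer(0), side = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$lncrna_id, out$distance_bp, out$gene_id), ]
  rownames(out) <- NULL
  out
}

# reverse complement used to build planted duplexes in tests
oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGU", "UGCA", s), "")[[1]]), collapse = "")
}
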