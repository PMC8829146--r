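# Candidate bulge layouts for a miRNA of length m under a bulge cap.
# side "none": gapless duplex. side "lncrna": extra lncRNA nucleotides
# (gap on the miRNA strand) inserted after miRNA position `anchor`
# (9..11). side "mirna": unpaired miRNA positions anchor..anchor+len-1,
# all within 9..12.
.bulge_configs <- function(m, max_bulge) {
  cfg <- list(list(side = "none", anchor = NA_integer_, len = 0L))
  if (m >= 13L) {
    for (b in seq_len(max_bulge)) {
      for (a in 9:11) {
        cfg[[length(cfg) + 1L]] <- list(side = "lncrna", anchor = a, len = b)
      }
    }
    for (b in seq_len(min(max_bulge, 4L))) {
      for (s in 9:(13L - b)) {
        cfg[[length(cfg) + 1L]] <- list(side = "mirna", anchor = s, len = b)
      }
    }
  }
  cfg
}

# Column vectors for one candidate site. site_chars are the lncRNA window
# 5'->3'; columns run along the miRNA 5'->3' so the target strand is the
# reversed window with gaps inserted per config.
.candidate_columns <- function(mirna_chars, site_chars, cfg) {
  m <- length(mirna_chars)
  rev_site <- rev(site_chars)
  if (cfg$side == "none") {
    list(m = mirna_chars, t = rev_site)
  } else if (cfg$side == "lncrna") {
    a <- cfg$anchor
    list(m = c(mirna_chars[1:a], rep(GAP, cfg$len), mirna_chars[(a + 1):m]),
         t = rev_site)
  } else {
    s <- cfg$anchor
    list(m = mirna_chars,
         t = append(rev_site, rep(GAP, cfg$len), after = s - 1L))
  }
}

# Watson-Crick complement used for the seed prefilter (rule 1 demands
# exact WC pairing at miRNA positions 2-8, so a site must contain the
# reverse complement of that seed verbatim).
.rna_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGU", "UGCA", s), "", fixed = TRUE)[[1]]),
        collapse = "")
}

#' Scan one lncRNA transcript for eTM sites of one miRNA
#'
#' Enumerates candidate antiparallel duplexes at every transcript offset --
#' gapless, plus every single bulge of length 1..`max_bulge` on either
#' strand anchored within miRNA positions 9-12 -- evaluates each with
#' [evaluate_alignment()]'s rule set, and returns the rule-satisfying
#' hits. A Watson-Crick seed prefilter (the reverse complement of miRNA
#' positions 2-8 must occur in the transcript) prunes offsets that cannot
#' satisfy rule 1. Overlapping hits are deduplicated best-score-first
#' (fewest mismatches+wobbles, then fewest bulges, then fewest wobbles,
#' then leftmost site); output is sorted by site start.
#'
#' @param mirna_seq,lncrna_seq RNA sequences 5'->3' (plain strings).
#' @param mirna_id,lncrna_id Identifiers carried into the results.
#' @param max_bulge Maximum bulge run length (default 3).
#' @return List of hits, each a list with `$alignment`
#'   ([pairing_alignment()]) and `$report` (`etm_report`).
#' @export
scan_lncrna <- function(mirna_seq, lncrna_seq, mirna_id = "miRNA",
                        lncrna_id = "lncRNA", max_bulge = 3L) {
  mirna_seq <- toupper(mirna_seq)
  lncrna_seq <- toupper(lncrna_seq)
  if (grepl("[^ACGU]", mirna_seq) || grepl("[^ACGU]", lncrna_seq)) {
    stop("scan_lncrna requires RNA sequences over A, C, G, U")
  }
  m <- nchar(mirna_seq)
  L <- nchar(lncrna_seq)
  if (L < m) stop("lncRNA shorter than miRNA")
  mchars <- strsplit(mirna_seq, "", fixed = TRUE)[[1]]
  lchars <- strsplit(lncrna_seq, "", fixed = TRUE)[[1]]

  # candidate site 3' ends: column i pairs lncRNA base (end - i + 1), so
  # positions 2-8 of the miRNA read the 7-mer ending one base short of the
  # site 3' end
  seed <- .rna_revcomp(substr(mirna_seq, 2L, 8L))
  hit_pos <- Biostrings::start(Biostrings::matchPattern(
    Biostrings::RNAString(seed), Biostrings::RNAString(lncrna_seq)))
  ends <- hit_pos + 7L                      # 1-based index of site 3' base
  ends <- ends[ends <= L]

  cfgs <- .bulge_configs(m, max_bulge)
  hits <- list()
  for (e in ends) {
    for (cfg in cfgs) {
      w <- m + switch(cfg$side, none = 0L, lncrna = cfg$len, mirna = -cfg$len)
      st <- e - w + 1L                      # 1-based site start
      if (st < 1L) next
      site_chars <- lchars[st:e]
      cols <- .candidate_columns(mchars, site_chars, cfg)
      ev <- .eval_columns(cols$m, cols$t, max_bulge = max_bulge)
      if (!ev$verdict) next
      hits[[length(hits) + 1L]] <- list(
        site_start = st - 1L, site_end = e,   # 0-based half-open
        score = ev$n_mismatch + ev$n_wobble,
        n_bulge = nrow(ev$bulges), n_wobble = ev$n_wobble,
        mcols = paste(cols$m, collapse = ""),
        site = paste(site_chars, collapse = ""),
        tcols = cols$t
      )
    }
  }
  if (length(hits) == 0L) return(list())

  # best-score-first deduplication of overlapping candidates
  ord <- order(vapply(hits, `[[`, 0, "score"),
               vapply(hits, `[[`, 0L, "n_bulge"),
               vapply(hits, `[[`, 0L, "n_wobble"),
               vapply(hits, `[[`, 0L, "site_start"),
               vapply(hits, `[[`, 0L, "site_end"))
  kept <- list()
  for (h in hits[ord]) {
    clash <- any(vapply(kept, function(k) {
      h$site_start < k$site_end && k$site_start < h$site_end
    }, logical(1)))
    if (!clash) kept[[length(kept) + 1L]] <- h
  }
  kept <- kept[order(vapply(kept, `[[`, 0L, "site_start"),
                     vapply(kept, `[[`, 0, "score"))]

  lapply(kept, function(h) {
    aln <- pairing_alignment(
      mirna_gapped = h$mcols,
      site_gapped = paste(rev(h$tcols), collapse = ""),
      mirna_id = mirna_id, lncrna_id = lncrna_id,
      site_start = h$site_start, site_end = h$site_end
    )
    list(alignment = aln, report = evaluate_alignment(aln))
  })
}

#' Scan all miRNA x lncRNA combinations for eTM sites
#'
#' @param mirnas,lncrnas Sequence records from [read_fasta()] (RNA).
#' @param max_bulge Maximum bulge run length.
#' @return A data.frame of hits with columns `mirna_id`, `lncrna_id`,
#'   `site_start`, `site_end`, `n_mismatch`, `n_wobble`, `bulge_desc`,
#'   `verdict`, `alignment` (gapped `miRNA&site` rendering); the full
#'   hit objects are attached as attribute `hits`.
#' @export
scan_etms <- function(mirnas, lncrnas, max_bulge = 3L) {
  all_hits <- list()
  rows <- list()
  for (i in seq_len(nrow(mirnas))) {
    for (j in seq_len(nrow(lncrnas))) {
      if (nchar(lncrnas$residues[j]) < nchar(mirnas$residues[i])) next
      hits <- scan_lncrna(mirnas$residues[i], lncrnas$residues[j],
                          mirna_id = mirnas$id[i],
                          lncrna_id = lncrnas$id[j], max_bulge = max_bulge)
      for (h in hits) {
        rep <- h$report
        bd <- if (nrow(rep$bulges) == 0L) "." else
          paste(sprintf("%s:%d+%d", rep$bulges$side, rep$bulges$anchor,
                        rep$bulges$length), collapse = ",")
        rows[[length(rows) + 1L]] <- data.frame(
          mirna_id = h$alignment$mirna_id,
          lncrna_id = h$alignment$lncrna_id,
          site_start = h$alignment$site_start,
          site_end = h$alignment$site_end,
          n_mismatch = rep$n_mismatch, n_wobble = rep$n_wobble,
          bulge_desc = bd, verdict = rep$verdict,
          alignment = paste0(
            paste(h$alignment$columns$mirna_char, collapse = ""), "&",
            h$alignment$site_seq),
          stringsAsFactors = FALSE
        )
        all_hits[[length(all_hits) + 1L]] <- h
      }
    }
  }
  out <- if (length(rows) == 0L) {
    data.frame(mirna_id = character(0), lncrna_id = character(0),
               site_start = integer(0), site_end = integer(0),
               n_mismatch = integer(0), n_wobble = integer(0),
               bulge_desc = character(0), verdict = logical(0),
               alignment = character(0), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, rows)
  }
  attr(out, "hits") <- all_hits
  out
}
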