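#' Published Liriodendron chinense miRNA-eTM pairing table
#'
#' A curated table of 23 printed miRNA / lncRNA eTM pairing renderings
#' from *L. chinense* (both strands 5'->3'; `-` marks a bulged position on
#' the opposite strand). Ships with the package as a plain-text fixture
#' and drives the worked examples and validation tallies.
#'
#' @return Data.frame with columns `mirna_id`, `mirna_seq`, `lncrna_id`,
#'   `etm_site_gapped`.
#' @export
etm_reference_pairs <- function() {
  path <- system.file("extdata", "lchinense_etm_pairs.tsv",
                      package = "etmnet", mustWork = TRUE)
  read.delim(path, sep = "\t", quote = "", stringsAsFactors = FALSE)
}

#' Evaluate a printed miRNA-eTM pairing table against the eTM rules
#'
#' Each row is rebuilt as an antiparallel [pairing_alignment()] and scored
#' with [evaluate_alignment()]. Rows whose strands have unequal column
#' counts (a bulge the rendering does not mark with gaps) are resolved by
#' enumerating every single-bulge placement and keeping the best-scoring
#' alignment (rule-satisfying first, then fewest mismatches+wobbles, then
#' leftmost anchor).
#'
#' @param pairs Data.frame as returned by [etm_reference_pairs()], or a
#'   path to such a TSV.
#' @param max_bulge Bulge cap passed to the rule engine.
#' @return Data.frame with one row per input pair (`row`, ids, per-rule
#'   booleans, counts, `verdict`), with tally list attached as attribute
#'   `tallies`: `n_rows`, `n_distinct_lncrnas`, `n_distinct_mirnas`,
#'   `rows_per_mirna`, `lncrnas_per_mirna`.
#' @export
validate_etm_table <- function(pairs = etm_reference_pairs(),
                               max_bulge = 3L) {
  if (is.character(pairs) && length(pairs) == 1L) {
    pairs <- read.delim(pairs, sep = "\t", quote = "",
                        stringsAsFactors = FALSE)
  }
  need <- c("mirna_id", "mirna_seq", "lncrna_id", "etm_site_gapped")
  if (!all(need %in% names(pairs))) {
    stop("pair table must have columns: ", paste(need, collapse = ", "))
  }
  rows <- vector("list", nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    res <- tryCatch(
      .align_printed_pair(pairs$mirna_seq[k], pairs$etm_site_gapped[k],
                          pairs$mirna_id[k], pairs$lncrna_id[k], max_bulge),
      error = function(e) stop("row ", k, ": ", conditionMessage(e),
                               call. = FALSE)
    )
    rep <- res$report
    rows[[k]] <- data.frame(
      row = k, mirna_id = pairs$mirna_id[k], lncrna_id = pairs$lncrna_id[k],
      rule1_ok = rep$rule1_ok, rule2_ok = rep$rule2_ok,
      rule3_ok = rep$rule3_ok, n_mismatch = rep$n_mismatch,
      n_wobble = rep$n_wobble, n_bulge = nrow(rep$bulges),
      verdict = rep$verdict, stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  tallies <- list(
    n_rows = nrow(pairs),
    n_distinct_lncrnas = length(unique(pairs$lncrna_id)),
    n_distinct_mirnas = length(unique(pairs$mirna_id)),
    rows_per_mirna = table(pairs$mirna_id),
    lncrnas_per_mirna = vapply(split(pairs$lncrna_id, pairs$mirna_id),
                               function(x) length(unique(x)), 0L)
  )
  attr(out, "tallies") <- tallies
  out
}

# Align one printed pair; resolves unequal column counts by enumerating
# single-bulge placements on the shorter strand.
.align_printed_pair <- function(mirna_seq, site_gapped, mirna_id, lncrna_id,
                                max_bulge = 3L) {
  mirna_seq <- toupper(mirna_seq)
  site_gapped <- toupper(site_gapped)
  nm <- nchar(mirna_seq)
  nc <- nchar(site_gapped)
  mk <- function(mir_gapped, site) {
    aln <- pairing_alignment(mir_gapped, site, mirna_id = mirna_id,
                             lncrna_id = lncrna_id)
    list(alignment = aln, report = evaluate_alignment(aln, max_bulge))
  }
  if (nc == nm) return(mk(mirna_seq, site_gapped))
  diff <- abs(nc - nm)
  cands <- list()
  if (nc > nm) {
    # extra lncRNA columns: gap run on the miRNA strand
    for (a in seq_len(nm - 1L)) {
      g <- paste0(substr(mirna_seq, 1L, a), strrep(GAP, diff),
                  substr(mirna_seq, a + 1L, nm))
      cands[[length(cands) + 1L]] <- mk(g, site_gapped)
    }
  } else {
    for (a in 0:nc) {
      g <- paste0(substr(site_gapped, 0L, a), strrep(GAP, diff),
                  substr(site_gapped, a + 1L, nc))
      cands[[length(cands) + 1L]] <- mk(mirna_seq, g)
    }
  }
  score <- vapply(cands, function(x)
    x$report$n_mismatch + x$report$n_wobble, 0)
  verdict <- vapply(cands, function(x) x$report$verdict, logical(1))
  cands[[order(-verdict, score)[1]]]
}
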