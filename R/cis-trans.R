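#' Predict cis-acting lncRNA target genes by genomic proximity
#'
#' A gene is a cis target of an lncRNA when both lie on the same chromosome
#' and the nearest-edge gap between their intervals is at most `window_bp`
#' (default 100 kb, inclusive). Overlapping or book-ended features have
#' distance 0 and side `overlap`; otherwise the side is `upstream`
#' (gene left of the lncRNA in genome orientation) or `downstream`,
#' strand-agnostic. Pairs sharing an id are skipped (an lncRNA is not its
#' own target).
#'
#' @param lncrnas,genes Feature data.frames from [genomic_features()] /
#'   [read_features()] (0-based half-open coordinates).
#' @param window_bp Window size in bp (default 100000).
#' @return Data.frame with columns `lncrna_id`, `gene_id`, `distance_bp`,
#'   `side`, sorted by (`lncrna_id`, `distance_bp`, `gene_id`).
#' @export
predict_cis <- function(lncrnas, genes, window_bp = 100000L) {
  gr_l <- GenomicRanges::GRanges(
    lncrnas$chrom, IRanges::IRanges(lncrnas$start + 1L, lncrnas$end))
  gr_g <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start + 1L, genes$end))
  hits <- GenomicRanges::findOverlaps(gr_l, gr_g, maxgap = window_bp,
                                      ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  keep <- lncrnas$id[qi] != genes$id[si]
  qi <- qi[keep]; si <- si[keep]
  if (length(qi) == 0L) {
    return(data.frame(lncrna_id = character(0), gene_id = character(0),
                      distance_bp = integer(0), side = character(0),
                      stringsAsFactors = FALSE))
  }
  d <- GenomicRanges::distance(gr_l[qi], gr_g[si], ignore.strand = TRUE)
  side <- ifelse(d == 0L, "overlap",
                 ifelse(genes$end[si] <= lncrnas$start[qi],
                        "upstream", "downstream"))
  out <- data.frame(lncrna_id = lncrnas$id[qi], gene_id = genes$id[si],
                    distance_bp = as.integer(d), side = side,
                    stringsAsFactors = FALSE)
  out <- out[out$distance_bp <= window_bp, , drop = FALSE]
  out <- out[order(out$lncrna_id, out$distance_bp, out$gene_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Predict trans-acting lncRNA target genes by expression correlation
#'
#' Computes the sample-level Pearson correlation between every lncRNA row
#' and every gene row across the shared sample columns (replicates, not
#' tissue means, unless `use_tissue_means = TRUE`) and reports pairs with
#' strictly `|r| > r_threshold`. Zero-variance rows are skipped with a
#' message.
#'
#' @param lnc_expr,gene_expr Matrices from [expression_matrix()] with
#'   identical sample columns.
#' @param r_threshold Strict absolute-correlation threshold (default 0.95).
#' @param use_tissue_means Correlate per-tissue means instead of replicate
#'   columns (default `FALSE`).
#' @return Data.frame with columns `lncrna_id`, `gene_id`, `r`,
#'   `n_samples`, sorted by (`lncrna_id`, `gene_id`).
#' @export
predict_trans <- function(lnc_expr, gene_expr, r_threshold = 0.95,
                          use_tissue_means = FALSE) {
  if (!identical(colnames(lnc_expr), colnames(gene_expr))) {
    stop("lncRNA and gene matrices must share identical sample columns")
  }
  if (use_tissue_means) {
    lnc <- aggregate_tissues(lnc_expr)
    gen <- aggregate_tissues(gene_expr)
  } else {
    lnc <- unclass(lnc_expr)
    gen <- unclass(gene_expr)
  }
  n <- ncol(lnc)
  if (n < 3L) stop("need at least 3 sample columns")
  sd_l <- apply(lnc, 1L, stats::sd)
  sd_g <- apply(gen, 1L, stats::sd)
  n_const <- sum(sd_l == 0) + sum(sd_g == 0)
  if (n_const > 0L) {
    message(n_const, " zero-variance row(s) skipped in trans prediction")
  }
  lnc <- lnc[sd_l > 0, , drop = FALSE]
  gen <- gen[sd_g > 0, , drop = FALSE]
  if (nrow(lnc) == 0L || nrow(gen) == 0L) {
    return(data.frame(lncrna_id = character(0), gene_id = character(0),
                      r = numeric(0), n_samples = integer(0),
                      stringsAsFactors = FALSE))
  }
  rmat <- stats::cor(t(lnc), t(gen))
  idx <- which(abs(rmat) > r_threshold, arr.ind = TRUE)
  out <- data.frame(
    lncrna_id = rownames(lnc)[idx[, 1]],
    gene_id = rownames(gen)[idx[, 2]],
    r = rmat[idx], n_samples = rep(n, nrow(idx)), stringsAsFactors = FALSE
  )
  out <- out[out$lncrna_id != out$gene_id, , drop = FALSE]
  out <- out[order(out$lncrna_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
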