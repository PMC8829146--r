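#' Aggregate replicate samples into per-tissue expression profiles
#'
#' Collapses an expression matrix to one value per tissue by taking the
#' arithmetic mean over that tissue's replicate columns, on the linear
#' FPKM/TPM scale the tau index is defined on.
#'
#' @param x Matrix from [expression_matrix()].
#' @param tissue_order Optional character vector fixing the tissue column
#'   order; defaults to first-appearance order of the sample map.
#' @return Numeric matrix, features x tissues.
#' @export
aggregate_tissues <- function(x, tissue_order = NULL) {
  tissue <- tissue_map(x)
  if (is.null(tissue)) stop("input must carry a sample-to-tissue map")
  tissues <- tissue_order %||% unique(unname(tissue))
  missing <- setdiff(tissues, tissue)
  if (length(missing) > 0L) {
    stop("tissue(s) with zero samples: ", paste(missing, collapse = ", "))
  }
  out <- vapply(tissues, function(tt) {
    rowMeans(x[, tissue == tt, drop = FALSE])
  }, numeric(nrow(x)))
  out <- matrix(out, nrow = nrow(x),
                dimnames = list(rownames(x), tissues))
  out
}

#' Compute the tau tissue-specificity index
#'
#' For a per-tissue profile `x_1..x_n`, tau = sum(1 - x_i / max(x)) / (n-1).
#' tau is 1 when expression is confined to a single tissue and 0 when it is
#' uniform; it is undefined (NA, `defined = FALSE`) for all-zero profiles.
#'
#' @param profiles Numeric matrix (features x tissues) from
#'   [aggregate_tissues()], or a single numeric vector of tissue values.
#' @return A data.frame with columns `feature_id`, `tau`, `peak_tissue`
#'   (tissue of the maximal value; first on ties), `defined`.
#' @export
compute_tau <- function(profiles) {
  if (is.null(dim(profiles))) {
    profiles <- matrix(profiles, nrow = 1,
                       dimnames = list("feature",
                                       names(profiles) %||%
                                         paste0("t", seq_along(profiles))))
  }
  n <- ncol(profiles)
  if (n < 2L) stop("tau requires at least 2 tissues")
  if (any(!is.finite(profiles)) || any(profiles < 0)) {
    stop("tissue values must be finite and non-negative")
  }
  mx <- apply(profiles, 1L, max)
  defined <- mx > 0
  tau <- rep(NA_real_, nrow(profiles))
  tau[defined] <- rowSums(1 - profiles[defined, , drop = FALSE] /
                            mx[defined]) / (n - 1)
  peak <- colnames(profiles)[apply(profiles, 1L, which.max)]
  peak[!defined] <- NA_character_
  data.frame(feature_id = rownames(profiles), tau = tau,
             peak_tissue = peak, defined = defined,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Select the most tissue-specific fraction of features
#'
#' Ranks defined tau values and returns the `floor(fraction * N_defined)`
#' feature ids with the highest tau. Ties at the selection boundary are
#' broken by higher maximal tissue value (when profiles are supplied), then
#' lexicographic id, so the output is a deterministic function of the input.
#'
#' @param tau_results Data.frame from [compute_tau()].
#' @param fraction Fraction to keep, in `(0, 1]`; default 0.05 (top 5%).
#' @param profiles Optional profile matrix used for the tie key.
#' @return Character vector of selected feature ids.
#' @export
select_top_fraction <- function(tau_results, fraction = 0.05,
                                profiles = NULL) {
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1) {
    stop("fraction must lie in (0, 1]")
  }
  res <- tau_results[tau_results$defined, , drop = FALSE]
  if (nrow(res) == 0L) stop("no defined tau values to rank")
  k <- floor(fraction * nrow(res))
  if (k == 0L) return(character(0))
  peak_val <- if (!is.null(profiles)) {
    apply(profiles[res$feature_id, , drop = FALSE], 1L, max)
  } else {
    rep(0, nrow(res))
  }
  ord <- order(-res$tau, -peak_val, res$feature_id)
  res$feature_id[ord[seq_len(k)]]
}

#' Filter a differential-expression table by strict thresholds
#'
#' Keeps records with `padj < padj_lt` and `|log2fc| > abs_lfc_gt`; both
#' comparisons are strict, so boundary rows (padj exactly 0.05, |log2fc|
#' exactly 1) are dropped.
#'
#' @param records Data.frame from [de_records()].
#' @param padj_lt Adjusted p-value threshold (default 0.05).
#' @param abs_lfc_gt Absolute log2 fold-change threshold (default 1).
#' @return Sorted character vector of unique qualifying feature ids.
#' @export
filter_de <- function(records, padj_lt = 0.05, abs_lfc_gt = 1) {
  key <- paste(records$feature_id, records$contrast, sep = "\r")
  if (anyDuplicated(key)) {
    d <- records[duplicated(key), c("feature_id", "contrast")][1, ]
    stop("duplicate (feature, contrast) row: ", d$feature_id, " / ",
         d$contrast)
  }
  keep <- records$padj < padj_lt & abs(records$log2fc) > abs_lfc_gt
  sort(unique(records$feature_id[keep]))
}

#' Relative expression by the 2^-ddCt method
#'
#' Computes `2^-((Ct_target_sample - Ct_ref_sample) -
#' (Ct_target_calibrator - Ct_ref_calibrator))` for RT-qPCR relative
#' quantification against a reference gene and a calibrator sample.
#'
#' @param ct_target_sample,ct_ref_sample Ct values in the sample of interest.
#' @param ct_target_calibrator,ct_ref_calibrator Ct values in the calibrator.
#' @return Positive numeric relative-expression value(s).
#' @export
delta_delta_ct <- function(ct_target_sample, ct_ref_sample,
                           ct_target_calibrator, ct_ref_calibrator) {
  vals <- c(ct_target_sample, ct_ref_sample, ct_target_calibrator,
            ct_ref_calibrator)
  if (any(!is.finite(vals))) stop("Ct values must be finite")
  ddct <- (ct_target_sample - ct_ref_sample) -
    (ct_target_calibrator - ct_ref_calibrator)
  2^(-ddct)
}

#' Sample Pearson correlation with explicit degeneracy handling
#'
#' Thin wrapper over [stats::cor()] that enforces equal lengths, n >= 3,
#' and returns `NA` (rather than an error) when either vector has zero
#' variance.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Correlation in `[-1, 1]`, or `NA` if undefined.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("inputs must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}
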