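#' Construct and validate an expression matrix
#'
#' The container for FPKM/TPM-scale values: a plain numeric matrix
#' (features x samples) carrying a sample-to-tissue map as the `tissue`
#' attribute.
#'
#' @param values Numeric matrix, feature ids as rownames, sample labels as
#'   colnames; all values finite and non-negative.
#' @param tissue_of_sample Named character vector mapping every sample
#'   label to a tissue name.
#' @return The validated matrix with attribute `tissue`.
#' @export
expression_matrix <- function(values, tissue_of_sample) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression matrix requires feature rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) stop("duplicate feature ids")
  if (anyDuplicated(colnames(values))) stop("duplicate sample labels")
  if (!is.numeric(values) || any(!is.finite(values))) {
    stop("expression values must be finite numbers (missing values rejected)")
  }
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative expression value at feature '%s', sample '%s'",
                 rownames(values)[bad[1]], colnames(values)[bad[2]]))
  }
  missing <- setdiff(colnames(values), names(tissue_of_sample))
  if (length(missing) > 0L) {
    stop("sample(s) absent from tissue map: ", paste(missing, collapse = ", "))
  }
  tissue <- vapply(tissue_of_sample[colnames(values)], as.character, "")
  names(tissue) <- colnames(values)
  if (length(unique(tissue)) < 1L) stop("at least one tissue required")
  attr(values, "tissue") <- tissue
  values
}

#' Sample-to-tissue map of an expression matrix
#' @param x Matrix from [expression_matrix()].
#' @return Named character vector (sample -> tissue).
#' @export
tissue_map <- function(x) attr(x, "tissue")

#' Read an expression matrix from TSV
#'
#' Expects a header row of sample labels and feature ids in the first
#' column. Values must be non-negative and complete; `.` or empty cells are
#' rejected.
#'
#' @param path TSV file path.
#' @param tissue_of_sample Named character vector mapping samples to tissues.
#' @return A validated matrix (see [expression_matrix()]).
#' @export
read_expression <- function(path, tissue_of_sample) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                   check.names = FALSE, na.strings = c("", "."),
                   stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop(sprintf("missing/non-numeric value at row '%s', column '%s'",
                 ids[bad[1]], colnames(vals)[bad[2]]))
  }
  storage.mode(vals) <- "double"
  rownames(vals) <- ids
  expression_matrix(vals, tissue_of_sample)
}

#' Write an expression matrix to TSV
#' @param x Matrix from [expression_matrix()].
#' @param path Output path.
#' @param id_column Header for the feature-id column.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, id_column = "feature_id") {
  df <- data.frame(rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_column
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
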