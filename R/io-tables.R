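PAIR_INTERACTIONS <- c("mirna_cleaves_mrna", "mirna_cleaves_lncrna")

#' Construct and validate miRNA target pairs
#'
#' The in-memory form of a degradome-style cleavage table: one row per
#' regulator/target pair with the interaction class and an optional 1-based
#' cleavage position on the target transcript.
#'
#' @param regulator_id,target_id Character vectors.
#' @param interaction One of `r paste(PAIR_INTERACTIONS, collapse=", ")`.
#' @param cleavage_position Optional integer vector (`NA` allowed), 1-based.
#' @return A data.frame with the four columns.
#' @export
target_pairs <- function(regulator_id, target_id, interaction,
                         cleavage_position = NA_integer_) {
  n <- length(regulator_id)
  out <- data.frame(
    regulator_id = as.character(regulator_id),
    target_id = as.character(target_id),
    interaction = rep_len(as.character(interaction), n),
    cleavage_position = rep_len(as.integer(cleavage_position), n),
    stringsAsFactors = FALSE
  )
  if (any(out$regulator_id == out$target_id)) {
    stop("regulator_id must differ from target_id")
  }
  bad <- setdiff(unique(out$interaction), PAIR_INTERACTIONS)
  if (length(bad) > 0L) {
    stop("unknown interaction token(s): ", paste(bad, collapse = ", "))
  }
  if (any(!is.na(out$cleavage_position) & out$cleavage_position < 1L)) {
    stop("cleavage_position must be >= 1")
  }
  out
}

#' Read a regulator/target pair table from TSV
#' @param path TSV with columns regulator_id, target_id, interaction,
#'   cleavage_position (empty or `.` allowed).
#' @return A data.frame (see [target_pairs()]).
#' @export
read_pair_table <- function(path) {
  if (!file.exists(path)) stop("pair table not found: ", path)
  df <- read.delim(path, sep = "\t", quote = "", check.names = FALSE,
                   na.strings = c("", "."), stringsAsFactors = FALSE,
                   colClasses = c("character", "character", "character",
                                  "integer"))
  if (nrow(df) == 0L) {
    return(target_pairs(character(0), character(0), character(0), integer(0)))
  }
  target_pairs(df$regulator_id, df$target_id, df$interaction,
               df$cleavage_position)
}

#' Write a regulator/target pair table to TSV
#' @param pairs Data.frame from [target_pairs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pair_table <- function(pairs, path) {
  out <- pairs
  out$cleavage_position <- ifelse(is.na(out$cleavage_position), "",
                                  as.character(out$cleavage_position))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct and validate differential-expression records
#'
#' @param feature_id,contrast Character vectors.
#' @param log2fc Finite numeric vector.
#' @param padj Numeric vector in `[0, 1]` (already multiplicity-corrected).
#' @return A data.frame with the four columns.
#' @export
de_records <- function(feature_id, contrast, log2fc, padj) {
  out <- data.frame(
    feature_id = as.character(feature_id),
    contrast = as.character(contrast),
    log2fc = as.numeric(log2fc),
    padj = as.numeric(padj),
    stringsAsFactors = FALSE
  )
  if (any(!is.finite(out$log2fc))) stop("log2fc must be finite")
  if (any(!is.finite(out$padj) | out$padj < 0 | out$padj > 1)) {
    stop("padj must lie in [0, 1]")
  }
  out
}

#' Read a differential-expression table from TSV
#' @param path TSV with columns feature_id, contrast, log2fc, padj.
#' @return A data.frame (see [de_records()]).
#' @export
read_de_table <- function(path) {
  if (!file.exists(path)) stop("DE table not found: ", path)
  df <- read.delim(path, sep = "\t", quote = "", check.names = FALSE,
                   stringsAsFactors = FALSE)
  de_records(df$feature_id, df$contrast, df$log2fc, df$padj)
}

#' Write a differential-expression table to TSV
#' @param records Data.frame from [de_records()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_de_table <- function(records, path) {
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
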