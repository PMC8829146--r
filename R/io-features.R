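#' Construct and validate genomic features
#'
#' Internal coordinates are 0-based half-open on every code path; GFF3's
#' 1-based inclusive convention is converted at the file boundary only.
#'
#' @param id,chrom Character vectors.
#' @param start,end Integer vectors, 0-based half-open.
#' @param strand Character vector over `+`, `-`, `*` (unknown).
#' @param feature_class Character vector over `gene`, `lncRNA`, `TF_gene`,
#'   `other`.
#' @return A data.frame with the columns above.
#' @export
genomic_features <- function(id, chrom, start, end, strand = "*",
                             feature_class = "other") {
  n <- length(id)
  out <- data.frame(
    id = as.character(id), chrom = as.character(chrom),
    start = as.integer(start), end = as.integer(end),
    strand = rep_len(as.character(strand), n),
    feature_class = rep_len(as.character(feature_class), n),
    stringsAsFactors = FALSE
  )
  if (any(!nzchar(out$chrom))) stop("empty chromosome name")
  bad <- which(!(out$start >= 0L & out$start < out$end))
  if (length(bad) > 0L) {
    stop("invalid interval for feature '", out$id[bad[1]],
         "': require 0 <= start < end, got [", out$start[bad[1]], ", ",
         out$end[bad[1]], ")")
  }
  if (!all(out$strand %in% c("+", "-", "*"))) stop("invalid strand value")
  if (!all(out$feature_class %in% c("gene", "lncRNA", "TF_gene", "other"))) {
    stop("invalid feature_class value")
  }
  dup <- out$id[duplicated(out$id)]
  if (length(dup) > 0L) {
    stop("duplicate feature id(s): ", paste(unique(dup), collapse = ", "))
  }
  out
}

# default mapping from GFF3 type column to internal feature class
.default_class_map <- c(
  gene = "gene", mRNA = "gene", lnc_RNA = "lncRNA", lncRNA = "lncRNA",
  ncRNA = "lncRNA", TF_gene = "TF_gene"
)

#' Read genomic features from GFF3 or BED
#'
#' GFF3 (1-based inclusive) and BED (0-based half-open) are parsed with
#' [rtracklayer::import()] and normalised to internal 0-based half-open
#' coordinates.
#'
#' @param path Annotation file path.
#' @param dialect `"GFF3"` or `"BED"`.
#' @param class_map Named character vector mapping GFF3 `type` values to
#'   feature classes; types not in the map become `"other"`. Ignored for
#'   BED, where every row gets `default_class`.
#' @param default_class Feature class for unmapped rows.
#' @return A data.frame of features (see [genomic_features()]).
#' @export
read_features <- function(path, dialect = c("GFF3", "BED"),
                          class_map = NULL, default_class = "other") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  cmap <- c(class_map, .default_class_map)
  cmap <- cmap[!duplicated(names(cmap))]
  gr <- rtracklayer::import(path, format = if (dialect == "GFF3") "gff3" else "bed")
  md <- S4Vectors::mcols(gr)
  if (dialect == "GFF3") {
    type <- as.character(md$type)
    id <- if ("ID" %in% names(md)) as.character(md$ID) else NA_character_
    if (anyNA(id) && "Name" %in% names(md)) {
      nm <- as.character(md$Name)
      id[is.na(id)] <- nm[is.na(id)]
    }
    if (anyNA(id)) {
      id[is.na(id)] <- paste0(type[is.na(id)], ":", which(is.na(id)))
    }
    cls <- unname(cmap[type])
    cls[is.na(cls)] <- default_class
  } else {
    id <- if ("name" %in% names(md)) as.character(md$name) else
      paste0("feat", seq_along(gr))
    cls <- default_class
  }
  # GRanges is 1-based inclusive regardless of source dialect
  genomic_features(
    id = id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = sub("\\*", "*", as.character(GenomicRanges::strand(gr))),
    feature_class = cls
  )
}

#' Write genomic features as GFF3
#'
#' Emits 1-based inclusive coordinates; reading the file back with
#' [read_features()] reproduces the input exactly.
#'
#' @param features Data.frame from [genomic_features()].
#' @param path Output path.
#' @param source Value for the GFF3 source column.
#' @return `path`, invisibly.
#' @export
write_features_gff3 <- function(features, path, source = "etmnet") {
  type <- c(gene = "gene", lncRNA = "lnc_RNA", TF_gene = "TF_gene",
            other = "sequence_feature")[features$feature_class]
  lines <- sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\tID=%s",
                   features$chrom, source, type,
                   features$start + 1L, features$end,
                   ifelse(features$strand == "*", ".", features$strand),
                   features$id)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}
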