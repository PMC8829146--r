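#' Read a FASTA file into a set of sequence records
#'
#' Parses FASTA with [Biostrings::readBStringSet()] and validates the
#' records against a declared alphabet. Residues are uppercased; for
#' `alphabet = "RNA"` any `T` is converted to `U` with a warning.
#' IUPAC ambiguity codes are rejected: downstream pairing rules are defined
#' only over the four unambiguous residues.
#'
#' @param path Path to a FASTA file (plain or gzip).
#' @param alphabet `"RNA"` or `"DNA"`.
#' @return A data.frame with columns `id` and `residues` (one row per
#'   record, file order), with attribute `alphabet`.
#' @export
read_fasta <- function(path, alphabet = c("RNA", "DNA")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  seqs <- toupper(as.character(ss))
  seq_records(ids, seqs, alphabet = alphabet)
}

#' Construct and validate sequence records
#'
#' @param id Character vector of unique identifiers.
#' @param residues Character vector of sequences (same length as `id`).
#' @param alphabet `"RNA"` or `"DNA"`.
#' @return A validated data.frame of records (see [read_fasta()]).
#' @export
seq_records <- function(id, residues, alphabet = c("RNA", "DNA")) {
  alphabet <- match.arg(alphabet)
  stopifnot(length(id) == length(residues))
  id <- as.character(id)
  residues <- toupper(as.character(residues))
  dup <- id[duplicated(id)]
  if (length(dup) > 0L) {
    stop("duplicate sequence id(s): ", paste(unique(dup), collapse = ", "))
  }
  if (any(!nzchar(residues))) {
    stop("empty sequence for record(s): ",
         paste(id[!nzchar(residues)], collapse = ", "))
  }
  if (alphabet == "RNA" && any(grepl("T", residues, fixed = TRUE))) {
    warning("T residues converted to U for RNA alphabet")
    residues <- gsub("T", "U", residues, fixed = TRUE)
  }
  valid <- if (alphabet == "RNA") RNA_RESIDUES else DNA_RESIDUES
  chars <- strsplit(residues, "", fixed = TRUE)
  for (i in seq_along(chars)) {
    bad <- which(!chars[[i]] %in% valid)
    if (length(bad) > 0L) {
      stop(sprintf("invalid %s residue '%s' in record '%s' at position %d",
                   alphabet, chars[[i]][bad[1]], id[i], bad[1]))
    }
  }
  out <- data.frame(id = id, residues = residues, stringsAsFactors = FALSE)
  attr(out, "alphabet") <- alphabet
  out
}

#' Write sequence records to FASTA
#'
#' One record per header, sequence on a single line, so that
#' write -> read -> write is byte-identical.
#'
#' @param records Data.frame from [read_fasta()] / [seq_records()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(is.data.frame(records), all(c("id", "residues") %in% names(records)))
  lines <- as.vector(rbind(paste0(">", records$id), records$residues))
  writeLines(lines, path)
  invisible(path)
}
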