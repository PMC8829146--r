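#' Classify an antiparallel RNA base pair
#'
#' A:U, U:A, G:C, C:G are Watson-Crick; G:U and U:G are wobble pairs
#' (counted separately from mismatches by the eTM rules); everything else
#' is a mismatch.
#'
#' @param a,b Single RNA residues (`A`, `C`, `G`, `U`), vectorised.
#' @return Character vector over `watson_crick`, `wobble`, `mismatch`.
#' @export
pair_class <- function(a, b) {
  if (any(!a %in% RNA_RESIDUES) || any(!b %in% RNA_RESIDUES)) {
    stop("residues must be one of A, C, G, U")
  }
  duplex <- paste0(a, b)
  out <- rep("mismatch", length(duplex))
  out[duplex %in% c("AU", "UA", "GC", "CG")] <- "watson_crick"
  out[duplex %in% c("GU", "UG")] <- "wobble"
  out
}

# Columnwise evaluation shared by evaluate_alignment() and the scanner.
# mchars / tchars are per-column characters, column order = miRNA 5'->3'
# (the target strand therefore reads 3'->5' across columns). "-" is a gap.
.eval_columns <- function(mchars, tchars, max_bulge = 3L) {
  n <- length(mchars)
  gap_m <- mchars == GAP
  gap_t <- tchars == GAP
  if (any(gap_m & gap_t)) stop("column with gaps on both strands")
  mirna_pos <- ifelse(gap_m, NA_integer_, cumsum(!gap_m))

  # terminal overhangs: gap-bearing columns at the extreme ends sit outside
  # the pairing region and count toward no rule
  is_gap <- gap_m | gap_t
  paired_idx <- which(!is_gap)
  if (length(paired_idx) == 0L) stop("alignment has no paired columns")
  region <- seq(min(paired_idx), max(paired_idx))

  cls <- rep(NA_character_, n)
  cls[gap_m] <- "target_bulge"   # extra lncRNA nucleotide
  cls[gap_t] <- "mirna_bulge"    # unpaired miRNA nucleotide
  pi <- which(!is_gap)
  cls[pi] <- pair_class(mchars[pi], tchars[pi])

  in_region <- seq_len(n) %in% region
  mm_idx <- which(in_region & cls == "mismatch")
  wob_idx <- which(in_region & cls == "wobble")
  n_mismatch <- length(mm_idx)
  n_wobble <- length(wob_idx)

  # maximal runs of gap columns inside the pairing region, split by strand
  bulges <- data.frame(anchor = integer(0), length = integer(0),
                       side = character(0), stringsAsFactors = FALSE)
  gap_in_region <- in_region & is_gap
  if (any(gap_in_region)) {
    r <- rle(ifelse(gap_in_region, cls, "pair"))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values != "pair")) {
      side <- if (r$values[k] == "mirna_bulge") "mirna" else "lncrna"
      anchor <- if (side == "mirna") {
        mirna_pos[starts[k]]            # first bulged miRNA position
      } else {
        # insertion point: miRNA position 5' of the run
        prev <- max(which(seq_len(n) < starts[k] & !gap_m))
        mirna_pos[prev]
      }
      bulges <- rbind(bulges, data.frame(anchor = anchor,
                                         length = r$lengths[k],
                                         side = side,
                                         stringsAsFactors = FALSE))
    }
  }

  # rule 1: perfect Watson-Crick pairing over miRNA positions 2-8
  seed_cols <- which(in_region & !is.na(mirna_pos) & mirna_pos >= 2L &
                       mirna_pos <= 8L)
  rule1_ok <- length(seed_cols) == 7L &&
    all(cls[seed_cols] == "watson_crick") &&
    !any(gap_in_region &
           seq_len(n) > min(seed_cols) & seq_len(n) < max(seed_cols))

  # rule 2: bulges only between miRNA positions 9 and 12, length-capped.
  # miRNA-side bulge columns must occupy positions 9..12; lncRNA-side
  # insertions must fall after positions 9..11 (strictly between nts 9-12).
  rule2_ok <- nrow(bulges) == 0L || all(
    bulges$length <= max_bulge &
      ifelse(bulges$side == "mirna",
             bulges$anchor >= 9L & (bulges$anchor + bulges$length - 1L) <= 12L,
             bulges$anchor >= 9L & bulges$anchor <= 11L)
  )

  # rule 3: fewer than three mismatches and G/U pairs in the pairing region
  rule3_ok <- (n_mismatch + n_wobble) < 3L

  list(rule1_ok = rule1_ok, rule2_ok = rule2_ok, rule3_ok = rule3_ok,
       n_mismatch = n_mismatch, n_wobble = n_wobble,
       mismatch_positions = as.integer(mirna_pos[mm_idx]),
       wobble_positions = as.integer(mirna_pos[wob_idx]),
       bulges = bulges,
       verdict = rule1_ok && rule2_ok && rule3_ok,
       classes = cls, mirna_pos = mirna_pos,
       region = c(min(region), max(region)))
}

#' Build a miRNA:site pairing alignment from gapped strands
#'
#' Both strands are given 5'->3' (as printed in eTM tables); the site is
#' reversed internally so that columns run along the miRNA 5'->3' with the
#' site antiparallel (miRNA 5' end opposite the site 3' end). `-` marks a
#' bulged (unpaired) position on the opposite strand.
#'
#' @param mirna_gapped miRNA strand 5'->3', possibly with `-`.
#' @param site_gapped lncRNA site strand 5'->3', possibly with `-`.
#' @param mirna_id,lncrna_id Identifiers carried on the object.
#' @param site_start,site_end Optional 0-based half-open site coordinates
#'   on the lncRNA transcript.
#' @return A `pairing_alignment` object: list with the ungapped sequences,
#'   coordinates, and a per-column data.frame (`mirna_char`, `target_char`,
#'   `mirna_pos`, `pair_class`).
#' @export
pairing_alignment <- function(mirna_gapped, site_gapped,
                              mirna_id = "miRNA", lncrna_id = "lncRNA",
                              site_start = NA_integer_,
                              site_end = NA_integer_) {
  mchars <- strsplit(toupper(mirna_gapped), "", fixed = TRUE)[[1]]
  schars <- strsplit(toupper(site_gapped), "", fixed = TRUE)[[1]]
  if (length(mchars) != length(schars)) {
    stop("gapped strands must have equal column counts (",
         length(mchars), " vs ", length(schars), ")")
  }
  ok <- c(RNA_RESIDUES, GAP)
  if (any(!mchars %in% ok) || any(!schars %in% ok)) {
    stop("strands must contain only A, C, G, U and '-'")
  }
  tchars <- rev(schars)
  ev <- .eval_columns(mchars, tchars)
  columns <- data.frame(
    mirna_char = mchars, target_char = tchars,
    mirna_pos = ev$mirna_pos, pair_class = ev$classes,
    stringsAsFactors = FALSE
  )
  structure(
    list(mirna_id = mirna_id, lncrna_id = lncrna_id,
         mirna_seq = paste(mchars[mchars != GAP], collapse = ""),
         site_seq = paste(schars[schars != GAP], collapse = ""),
         site_start = as.integer(site_start),
         site_end = as.integer(site_end),
         columns = columns),
    class = "pairing_alignment"
  )
}

#' Evaluate an alignment against the three eTM pairing rules
#'
#' Rule 1: perfect Watson-Crick pairing at miRNA positions 2-8 (a wobble
#' there is not "perfect"). Rule 2: bulges only between miRNA positions 9
#' and 12, each run at most `max_bulge` long. Rule 3: fewer than three
#' mismatches plus G:U wobbles over the pairing region. Terminal gap
#' columns at the alignment ends are overhangs and count toward no rule.
#'
#' @param aln A [pairing_alignment()] object.
#' @param max_bulge Maximum bulge run length (default 3).
#' @return An `etm_report` list: per-rule booleans, mismatch/wobble counts
#'   and miRNA positions, bulge table (`anchor`, `length`, `side`), and the
#'   overall `verdict` (conjunction of the three rules).
#' @export
evaluate_alignment <- function(aln, max_bulge = 3L) {
  stopifnot(inherits(aln, "pairing_alignment"))
  ev <- .eval_columns(aln$columns$mirna_char, aln$columns$target_char,
                      max_bulge = max_bulge)
  structure(ev[c("rule1_ok", "rule2_ok", "rule3_ok", "n_mismatch",
                 "n_wobble", "mismatch_positions", "wobble_positions",
                 "bulges", "verdict")],
            class = "etm_report")
}

#' @export
print.pairing_alignment <- function(x, ...) {
  cat(sprintf("%s : %s  (site %s..%s)\n", x$mirna_id, x$lncrna_id,
              x$site_start, x$site_end))
  marks <- c(watson_crick = "|", wobble = "o", mismatch = " ",
             mirna_bulge = " ", target_bulge = " ")
  cat("miRNA  5'-", paste(x$columns$mirna_char, collapse = ""), "-3'\n",
      "          ", paste(marks[x$columns$pair_class], collapse = ""), "\n",
      "lncRNA 3'-", paste(x$columns$target_char, collapse = ""), "-5'\n",
      sep = "")
  invisible(x)
}

#' @export
print.etm_report <- function(x, ...) {
  cat(sprintf(
    "eTM verdict: %s (rule1 %s, rule2 %s, rule3 %s; %d mismatch, %d wobble, %d bulge run)\n",
    x$verdict, x$rule1_ok, x$rule2_ok, x$rule3_ok,
    x$n_mismatch, x$n_wobble, nrow(x$bulges)))
  invisible(x)
}
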