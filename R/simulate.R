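#' Configuration for the synthetic-data generator
#'
#' Describes a complete synthetic study emulating a 4-tissue x 3-replicate
#' plant transcriptome with known planted structure: eTM sites obeying (or
#' deliberately violating) the pairing rules, tissue-specific expression
#' profiles, genomic cis distances, correlated trans pairs, and labelled
#' differential expression. Every generator is deterministic under the
#' configured seed.
#'
#' @param seed Integer seed driving all randomness.
#' @param n_tissues,n_replicates Study design (defaults 4 and 3: 12 samples).
#' @param tissue_names Tissue labels (length `n_tissues`).
#' @param n_mirnas,n_lncrnas,n_genes Feature counts.
#' @param mirna_length_range,lncrna_length_range Length ranges (nt).
#' @param planted_etm Data.frame with columns `mirna` (index), `lncrna`
#'   (index), `offset` (0-based site start), `bulge_side` (`none`,
#'   `lncrna`, `mirna`), `bulge_length` (0..`max_bulge`), `n_mismatches`,
#'   `n_wobbles` (sum <= 2).
#' @param plant_negatives Emit, per rule, one extra lncRNA carrying a site
#'   violating exactly that rule (default `TRUE`).
#' @param planted_tau Data.frame with columns `feature_id`,
#'   `target_tissue`, `fold_over_background`.
#' @param cis_distances Data.frame with columns `lncrna_id`, `gene_id`,
#'   `signed_distance_bp` (negative = gene upstream of the lncRNA).
#' @param trans_r Data.frame with columns `lncrna_id`, `gene_id`,
#'   `target_r` in (-1, 1).
#' @param planted_de Character vector of feature ids planted as
#'   differentially expressed.
#' @param noise_cv Replicate-level coefficient of variation of the
#'   log-normal expression noise (> 0 unless exactly 0 for the noise-free
#'   regime).
#' @param max_bulge Bulge cap used when planting sites.
#' @return A `synth_config` list.
#' @export
synth_config <- function(seed = 1L, n_tissues = 4L, n_replicates = 3L,
                         tissue_names = c("leaf", "petal", "stamen",
                                          "pistil")[seq_len(n_tissues)],
                         n_mirnas = 6L, n_lncrnas = 12L, n_genes = 60L,
                         mirna_length_range = c(20L, 24L),
                         lncrna_length_range = c(300L, 600L),
                         planted_etm = NULL, plant_negatives = TRUE,
                         planted_tau = NULL, cis_distances = NULL,
                         trans_r = NULL, planted_de = NULL,
                         noise_cv = 0.2, max_bulge = 3L) {
  if (length(tissue_names) != n_tissues) stop("need one name per tissue")
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  if (!is.null(planted_etm)) {
    stopifnot(all(planted_etm$mirna %in% seq_len(n_mirnas)),
              all(planted_etm$lncrna %in% seq_len(n_lncrnas)),
              all(planted_etm$bulge_length >= 0L),
              all(planted_etm$bulge_length <= max_bulge |
                    planted_etm$bulge_side == "none"))
    if (any(planted_etm$n_mismatches + planted_etm$n_wobbles > 2L)) {
      stop("planted sites allow at most 2 mismatches + wobbles")
    }
  }
  if (!is.null(trans_r) && any(abs(trans_r$target_r) >= 1)) {
    stop("target_r must lie in (-1, 1)")
  }
  structure(list(
    seed = as.integer(seed), n_tissues = as.integer(n_tissues),
    n_replicates = as.integer(n_replicates), tissue_names = tissue_names,
    n_mirnas = as.integer(n_mirnas), n_lncrnas = as.integer(n_lncrnas),
    n_genes = as.integer(n_genes),
    mirna_length_range = as.integer(mirna_length_range),
    lncrna_length_range = as.integer(lncrna_length_range),
    planted_etm = planted_etm, plant_negatives = isTRUE(plant_negatives),
    planted_tau = planted_tau, cis_distances = cis_distances,
    trans_r = trans_r, planted_de = planted_de,
    noise_cv = noise_cv, max_bulge = as.integer(max_bulge)
  ), class = "synth_config")
}

.id_pad <- function(prefix, i, n) sprintf("%s%0*d", prefix, nchar(n), i)

.random_rna <- function(len) {
  paste(sample(RNA_RESIDUES, len, replace = TRUE), collapse = "")
}

# A residue that neither Watson-Crick- nor wobble-pairs with `base`
.mismatch_partner <- function(base) {
  switch(base, A = "A", C = "C", G = "A", U = "U")
}

# Build one eTM site (5'->3' on the lncRNA) for `mirna_seq`, with the
# requested bulge and with mismatches/wobbles placed outside miRNA
# positions 2-8 and outside the bulge region 9-12.
.plant_site <- function(mirna_seq, bulge_side = "none", bulge_length = 0L,
                        n_mismatches = 0L, n_wobbles = 0L,
                        violate_rule = NULL, max_bulge = 3L) {
  mchars <- strsplit(mirna_seq, "", fixed = TRUE)[[1]]
  m <- length(mchars)
  # start from the perfect duplex: target chars in column order (3'->5'
  # along the site)
  wc <- c(A = "U", C = "G", G = "C", U = "A")
  tchars <- unname(wc[mchars])

  edit_positions <- setdiff(seq_len(m), 2:12)
  if (!is.null(violate_rule) && violate_rule == "rule1") {
    p <- 5L
    tchars[p] <- .mismatch_partner(mchars[p])
  }
  if (!is.null(violate_rule) && violate_rule == "rule3") {
    ps <- utils::head(edit_positions, 3L)
    for (p in ps) tchars[p] <- .mismatch_partner(mchars[p])
  }
  if (n_wobbles > 0L) {
    cand <- edit_positions[mchars[edit_positions] %in% c("G", "U")]
    if (length(cand) < n_wobbles) stop("cannot place requested wobbles")
    for (p in utils::head(cand, n_wobbles)) {
      tchars[p] <- if (mchars[p] == "G") "U" else "G"
      edit_positions <- setdiff(edit_positions, p)
    }
  }
  if (n_mismatches > 0L) {
    if (length(edit_positions) < n_mismatches) {
      stop("cannot place requested mismatches")
    }
    ps <- sample(edit_positions, n_mismatches)
    for (p in ps) tchars[p] <- .mismatch_partner(mchars[p])
  }

  if (!is.null(violate_rule) && violate_rule == "rule2") {
    # over-long bulge outside positions 9-12: no legal re-registration of
    # the site (bulge cap + anchor range) can absorb it
    bulge_side <- "lncrna"; bulge_length <- max_bulge + 1L
    anchor <- 14L
  } else {
    anchor <- if (bulge_side == "lncrna") 10L else 9L
  }
  if (bulge_side == "lncrna" && bulge_length > 0L) {
    tchars <- append(tchars, sample(RNA_RESIDUES, bulge_length,
                                    replace = TRUE), after = anchor)
  } else if (bulge_side == "mirna" && bulge_length > 0L) {
    tchars <- tchars[-(anchor:(anchor + bulge_length - 1L))]
  }
  # column order is site 3'->5'; the site sequence is the reverse
  paste(rev(tchars), collapse = "")
}

#' Generate miRNA and lncRNA sequences with planted eTM sites
#'
#' Backgrounds are uniform over A/C/G/U. Each `planted_etm` row excises a
#' rule-satisfying site into its lncRNA at the requested offset; when
#' `plant_negatives` is set, three extra lncRNAs each carry a site
#' violating exactly one rule (a seed mismatch at position 5; a 1-nt bulge
#' inserted after miRNA position 14; three mismatches outside the seed).
#'
#' @param config A [synth_config()].
#' @return List with `mirnas`, `lncrnas` (sequence records) and `manifest`
#'   (data.frame of planted sites: ids, offsets, site sequence, label).
#' @export
gen_sequences <- function(config) {
  set.seed(config$seed)
  mir_len <- sample(seq(config$mirna_length_range[1],
                        config$mirna_length_range[2]),
                    config$n_mirnas, replace = TRUE)
  mirnas <- seq_records(
    .id_pad("mir", seq_len(config$n_mirnas), config$n_mirnas),
    vapply(mir_len, .random_rna, ""), alphabet = "RNA")
  lnc_len <- sample(seq(config$lncrna_length_range[1],
                        config$lncrna_length_range[2]),
                    config$n_lncrnas, replace = TRUE)
  lnc_seq <- vapply(lnc_len, .random_rna, "")
  lnc_id <- .id_pad("lnc", seq_len(config$n_lncrnas), config$n_lncrnas)

  manifest <- data.frame(mirna_id = character(0), lncrna_id = character(0),
                         site_start = integer(0), site_end = integer(0),
                         site_seq = character(0), label = character(0),
                         stringsAsFactors = FALSE)
  pe <- config$planted_etm
  if (!is.null(pe)) {
    for (k in seq_len(nrow(pe))) {
      site <- .plant_site(mirnas$residues[pe$mirna[k]],
                          bulge_side = pe$bulge_side[k],
                          bulge_length = pe$bulge_length[k],
                          n_mismatches = pe$n_mismatches[k],
                          n_wobbles = pe$n_wobbles[k])
      j <- pe$lncrna[k]
      off <- pe$offset[k]
      if (off + nchar(site) > nchar(lnc_seq[j])) {
        stop("planted site exceeds lncRNA length for row ", k)
      }
      substr(lnc_seq[j], off + 1L, off + nchar(site)) <- site
      manifest <- rbind(manifest, data.frame(
        mirna_id = mirnas$id[pe$mirna[k]], lncrna_id = lnc_id[j],
        site_start = off, site_end = off + nchar(site), site_seq = site,
        label = "positive", stringsAsFactors = FALSE))
    }
  }
  if (config$plant_negatives && config$n_mirnas >= 1L) {
    for (rule in c("rule1", "rule2", "rule3")) {
      # a violating site can still admit a rule-satisfying alternative
      # registration (e.g. a bulge re-anchored across a homopolymer run),
      # so resample the random components until the transcript truly
      # carries no qualifying site
      ok <- FALSE
      for (attempt in seq_len(100L)) {
        site <- .plant_site(mirnas$residues[1], violate_rule = rule,
                            max_bulge = config$max_bulge)
        flank_len <- max(50L, config$lncrna_length_range[1] - nchar(site))
        left <- .random_rna(floor(flank_len / 2))
        right <- .random_rna(ceiling(flank_len / 2))
        seq <- paste0(left, site, right)
        if (length(scan_lncrna(mirnas$residues[1], seq,
                               max_bulge = config$max_bulge)) == 0L) {
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("could not plant a clean negative for ", rule)
      lnc_id <- c(lnc_id, paste0("lnc_neg_", rule))
      lnc_seq <- c(lnc_seq, seq)
      manifest <- rbind(manifest, data.frame(
        mirna_id = mirnas$id[1], lncrna_id = paste0("lnc_neg_", rule),
        site_start = nchar(left), site_end = nchar(left) + nchar(site),
        site_seq = site, label = paste0("negative_", rule),
        stringsAsFactors = FALSE))
    }
  }
  list(mirnas = mirnas,
       lncrnas = seq_records(lnc_id, lnc_seq, alphabet = "RNA"),
       manifest = manifest)
}

# multiplicative log-normal replicate noise with unit mean and the
# requested coefficient of variation
.lnorm_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate expression matrices with planted tissue-specific and
#' correlated features
#'
#' Background per-feature baselines are log-normal; replicate values are
#' baseline x log-normal noise with CV `noise_cv`. `planted_tau` features
#' get mean `fold_over_background` x baseline in the target tissue and
#' baseline elsewhere. `trans_r` pairs are built from a shared latent
#' signal plus independent noise and rejection-sampled until the realised
#' sample Pearson r lies within 0.02 of the target.
#'
#' @param config A [synth_config()].
#' @return List with `lnc_gene_expr`, `mirna_expr` (matrices from
#'   [expression_matrix()]) and `manifest` (list with `tau` and `trans`
#'   ground truth, the latter including the realised r).
#' @export
gen_expression <- function(config) {
  set.seed(config$seed + 1L)
  tissues <- config$tissue_names
  samples <- as.vector(t(outer(tissues, seq_len(config$n_replicates),
                               paste, sep = "_rep")))
  tmap <- setNames(rep(tissues, each = config$n_replicates), samples)
  n_samp <- length(samples)

  make_matrix <- function(ids) {
    base <- rlnorm(length(ids), meanlog = log(10), sdlog = 1)
    vals <- base * matrix(.lnorm_noise(length(ids) * n_samp, config$noise_cv),
                          nrow = length(ids))
    dimnames(vals) <- list(ids, samples)
    vals
  }
  lnc_ids <- .id_pad("lnc", seq_len(config$n_lncrnas), config$n_lncrnas)
  gene_ids <- .id_pad("gene", seq_len(config$n_genes), config$n_genes)
  mir_ids <- .id_pad("mir", seq_len(config$n_mirnas), config$n_mirnas)
  lg <- make_matrix(c(lnc_ids, gene_ids))
  mir <- make_matrix(mir_ids)

  tau_manifest <- NULL
  pt <- config$planted_tau
  if (!is.null(pt)) {
    for (k in seq_len(nrow(pt))) {
      fid <- pt$feature_id[k]
      target <- rownames(lg) == fid
      mat <- if (any(target)) "lg" else "mir"
      baseline <- 10
      mean_per_sample <- ifelse(tmap[samples] == pt$target_tissue[k],
                                baseline * pt$fold_over_background[k],
                                baseline)
      row <- mean_per_sample * .lnorm_noise(n_samp, config$noise_cv)
      if (mat == "lg") lg[fid, ] <- row else mir[fid, ] <- row
    }
    tau_manifest <- pt
  }

  trans_manifest <- NULL
  tr <- config$trans_r
  if (!is.null(tr)) {
    realised <- numeric(nrow(tr))
    for (k in seq_len(nrow(tr))) {
      target <- tr$target_r[k]
      rho <- abs(target)
      z <- rnorm(n_samp)
      for (attempt in seq_len(10000L)) {
        e <- rnorm(n_samp)
        y <- sign(target) * (rho * z + sqrt(1 - rho^2) * e)
        r <- stats::cor(z, y)
        if (abs(r - target) <= 0.02) break
      }
      if (abs(r - target) > 0.02) stop("could not hit target r within 0.02")
      # affine/positive-scale maps preserve Pearson r and keep values >= 0
      to_expr <- function(v) 50 * (1 + 0.9 * v / max(abs(v), 1e-9))
      lg[tr$lncrna_id[k], ] <- to_expr(z)
      lg[tr$gene_id[k], ] <- to_expr(y)
      realised[k] <- r
    }
    trans_manifest <- cbind(tr, realised_r = realised)
  }

  list(lnc_gene_expr = expression_matrix(lg, tmap),
       mirna_expr = expression_matrix(mir, tmap),
       manifest = list(tau = tau_manifest, trans = trans_manifest))
}

#' Generate genomic annotation with controlled lncRNA-gene distances
#'
#' lncRNAs are spaced 1 Mb apart on one chromosome; each `cis_distances`
#' row places its gene at exactly the requested signed nearest-edge
#' distance from its lncRNA (negative = upstream). Remaining genes are
#' distractors, placed either on a second chromosome or beyond 100 kb of
#' every lncRNA.
#'
#' @param config A [synth_config()].
#' @return List with `features` (data.frame from [genomic_features()]) and
#'   `manifest` (the realised cis table).
#' @export
gen_annotation <- function(config) {
  set.seed(config$seed + 2L)
  lnc_ids <- .id_pad("lnc", seq_len(config$n_lncrnas), config$n_lncrnas)
  gene_ids <- .id_pad("gene", seq_len(config$n_genes), config$n_genes)
  lnc_len <- 1000L
  gene_len <- 2000L
  lnc_start <- 10000000L + (seq_len(config$n_lncrnas) - 1L) * 1000000L
  feats <- genomic_features(
    id = lnc_ids, chrom = "chr1", start = lnc_start,
    end = lnc_start + lnc_len, strand = "+", feature_class = "lncRNA")

  cd <- config$cis_distances
  placed <- character(0)
  if (!is.null(cd)) {
    if (anyDuplicated(cd$gene_id)) {
      stop("each gene may appear in at most one cis placement")
    }
    if (any(abs(cd$signed_distance_bp) > 800000L)) {
      stop("requested cis distance would collide with a neighbouring lncRNA")
    }
    for (k in seq_len(nrow(cd))) {
      i <- match(cd$lncrna_id[k], lnc_ids)
      if (is.na(i)) stop("unknown lncRNA in cis spec: ", cd$lncrna_id[k])
      d <- cd$signed_distance_bp[k]
      if (d >= 0L) {
        gs <- lnc_start[i] + lnc_len + d
      } else {
        gs <- lnc_start[i] + d - gene_len
      }
      feats <- rbind(feats, genomic_features(
        id = cd$gene_id[k], chrom = "chr1", start = gs, end = gs + gene_len,
        strand = "+", feature_class = "gene"))
      placed <- c(placed, cd$gene_id[k])
    }
  }
  rest <- setdiff(gene_ids, placed)
  if (length(rest) > 0L) {
    half <- seq_along(rest) %% 2L == 0L
    gs2 <- 1000000L + (cumsum(half) - 1L) * 50000L
    gs1 <- max(lnc_start) + 2000000L + (cumsum(!half) - 1L) * 50000L
    feats <- rbind(feats, genomic_features(
      id = rest, chrom = ifelse(half, "chr2", "chr1"),
      start = ifelse(half, gs2, gs1),
      end = ifelse(half, gs2, gs1) + gene_len,
      strand = "+", feature_class = "gene"))
  }
  manifest <- if (is.null(cd)) NULL else cd
  list(features = feats, manifest = manifest)
}

#' Generate a differential-expression table with planted positives and
#' boundary rows
#'
#' Planted features receive `padj < 0.05` and `|log2fc| > 1`; background
#' rows straddle both thresholds and include exact-boundary rows
#' (`padj = 0.05`, `|log2fc| = 1`) that a strict filter must drop.
#'
#' @param config A [synth_config()].
#' @param contrast Contrast label for every row.
#' @return List with `de_table` (data.frame from [de_records()]) and
#'   `manifest` (planted feature ids).
#' @export
gen_de_table <- function(config, contrast = "petal_vs_leaf") {
  set.seed(config$seed + 3L)
  gene_ids <- .id_pad("gene", seq_len(config$n_genes), config$n_genes)
  planted <- config$planted_de %||% character(0)
  if (!all(planted %in% gene_ids)) stop("planted DE ids must be gene ids")
  rest <- setdiff(gene_ids, planted)
  n_p <- length(planted)
  n_b <- length(rest)
  lfc_p <- sample(c(-1, 1), n_p, replace = TRUE) * runif(n_p, 1.5, 5)
  padj_p <- runif(n_p, 0, 0.049)
  # background: alternate failure modes, with exact-boundary rows first
  lfc_b <- numeric(n_b)
  padj_b <- numeric(n_b)
  if (n_b >= 1L) { lfc_b[1] <- 3;  padj_b[1] <- 0.05 }   # padj boundary
  if (n_b >= 2L) { lfc_b[2] <- 1;  padj_b[2] <- 0.01 }   # lfc boundary
  if (n_b >= 3L) { lfc_b[3] <- -1; padj_b[3] <- 0.01 }
  if (n_b > 3L) {
    i <- 4:n_b
    fail_p <- i %% 2L == 0L
    lfc_b[i] <- ifelse(fail_p, runif(length(i), 1.5, 4),
                       runif(length(i), -0.9, 0.9))
    padj_b[i] <- ifelse(fail_p, runif(length(i), 0.06, 1),
                        runif(length(i), 0, 0.049))
  }
  de <- de_records(c(planted, rest), contrast, c(lfc_p, lfc_b),
                   c(padj_p, padj_b))
  list(de_table = de, manifest = planted)
}
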