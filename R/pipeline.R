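#' Generate a deterministic degradome-style pair table for a synthetic run
#'
#' Emulates cleavage output: miRNA `i` cleaves gene `i` and (for the first
#' few miRNAs) lncRNA `i`, with arbitrary but reproducible cleavage
#' positions.
#'
#' @param config A [synth_config()].
#' @return List with `mirna_mrna` and `mirna_lnc` pair tables.
#' @export
gen_target_pair_tables <- function(config) {
  set.seed(config$seed + 4L)
  n <- min(config$n_mirnas, config$n_genes)
  mir <- .id_pad("mir", seq_len(config$n_mirnas), config$n_mirnas)
  gene <- .id_pad("gene", seq_len(config$n_genes), config$n_genes)
  lnc <- .id_pad("lnc", seq_len(config$n_lncrnas), config$n_lncrnas)
  mm <- target_pairs(mir[seq_len(n)], gene[seq_len(n)],
                     "mirna_cleaves_mrna",
                     sample(200:1500, n, replace = TRUE))
  nl <- min(config$n_mirnas, config$n_lncrnas, 3L)
  ml <- target_pairs(mir[seq_len(nl)], lnc[seq_len(nl)],
                     "mirna_cleaves_lncrna",
                     sample(50:300, nl, replace = TRUE))
  list(mirna_mrna = mm, mirna_lnc = ml)
}

#' Run the full synthetic pipeline end to end
#'
#' simulate -> tau ranking -> eTM scan -> cis -> trans -> DE filter ->
#' network, writing every stage's table under `out_dir` together with a
#' YAML run manifest (configuration echo, package version, per-file MD5
#' checksums). Rerunning with an identical configuration reproduces
#' identical checksums.
#'
#' @param config A [synth_config()].
#' @param out_dir Output directory (created if needed).
#' @param fraction Top-tau fraction to select (default 0.05).
#' @param window_bp Cis window (default 100000).
#' @param r_threshold Trans correlation threshold (default 0.95).
#' @param padj_lt,abs_lfc_gt DE thresholds (defaults 0.05 and 1).
#' @param max_bulge eTM bulge cap (default 3).
#' @param quiet Suppress per-stage messages.
#' @return Invisibly, a list with the stage results (`manifest`, `tau_lnc`,
#'   `tau_mirna`, `selected_lnc`, `etm_hits`, `cis`, `trans`, `de_ids`,
#'   `network`, `summary`, `files`, `checksums`).
#' @export
run_pipeline <- function(config = synth_config(), out_dir = tempdir(),
                         fraction = 0.05, window_bp = 100000L,
                         r_threshold = 0.95, padj_lt = 0.05,
                         abs_lfc_gt = 1, max_bulge = 3L, quiet = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[etmnet] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  fp <- function(f) file.path(out_dir, f)

  seqs <- stage("simulate_sequences", gen_sequences(config))
  expr <- stage("simulate_expression", gen_expression(config))
  ann <- stage("simulate_annotation", gen_annotation(config))
  de <- stage("simulate_de", gen_de_table(config))
  pairs <- stage("simulate_pairs", gen_target_pair_tables(config))

  stage("write_inputs", {
    write_fasta(seqs$mirnas, fp("mirnas.fa"))
    write_fasta(seqs$lncrnas, fp("lncrnas.fa"))
    write_features_gff3(ann$features, fp("annotation.gff3"))
    write_expression(expr$lnc_gene_expr, fp("expr_lnc_gene.tsv"))
    write_expression(expr$mirna_expr, fp("expr_mirna.tsv"))
    write_de_table(de$de_table, fp("de_table.tsv"))
    write_pair_table(pairs$mirna_mrna, fp("pairs_mirna_mrna.tsv"))
    write_pair_table(pairs$mirna_lnc, fp("pairs_mirna_lnc.tsv"))
  })
  say("simulate: ", nrow(seqs$mirnas), " miRNAs, ", nrow(seqs$lncrnas),
      " lncRNAs, ", nrow(ann$features), " features")

  # stages consume the written files, exercising the same readers a real
  # run would use
  tmap <- tissue_map(expr$lnc_gene_expr)
  lg <- stage("read_expression", read_expression(fp("expr_lnc_gene.tsv"), tmap))
  mir_expr <- stage("read_expression", read_expression(fp("expr_mirna.tsv"), tmap))

  tau_lnc <- stage("tau", compute_tau(aggregate_tissues(lg)))
  tau_mir <- stage("tau", compute_tau(aggregate_tissues(mir_expr)))
  lnc_mask <- grepl("^lnc", tau_lnc$feature_id)
  selected <- stage("tau", select_top_fraction(
    tau_lnc[lnc_mask, , drop = FALSE], fraction,
    profiles = aggregate_tissues(lg)[lnc_mask, , drop = FALSE]))
  say("tau: selected ", length(selected), " of ", sum(lnc_mask),
      " lncRNAs at fraction ", fraction)

  mirnas <- stage("read_fasta", read_fasta(fp("mirnas.fa"), "RNA"))
  lncrnas <- stage("read_fasta", read_fasta(fp("lncrnas.fa"), "RNA"))
  etm_hits <- stage("etm_scan", scan_etms(mirnas, lncrnas, max_bulge))
  write.table(etm_hits, fp("etm_hits.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  say("etm-scan: ", nrow(etm_hits), " rule-satisfying sites")

  feats <- stage("read_features", read_features(fp("annotation.gff3"), "GFF3"))
  cis <- stage("cis", predict_cis(feats[feats$feature_class == "lncRNA", ],
                                  feats[feats$feature_class == "gene", ],
                                  window_bp))
  write.table(cis, fp("cis_targets.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  say("cis: ", nrow(cis), " pairs within ", window_bp, " bp")

  lnc_rows <- grepl("^lnc", rownames(lg))
  trans <- stage("trans", suppressMessages(predict_trans(
    expression_matrix(lg[lnc_rows, , drop = FALSE], tmap),
    expression_matrix(lg[!lnc_rows, , drop = FALSE], tmap),
    r_threshold)))
  write.table(trans, fp("trans_targets.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  say("trans: ", nrow(trans), " pairs with |r| > ", r_threshold)

  de_tab <- stage("read_de", read_de_table(fp("de_table.tsv")))
  de_ids <- stage("de_filter", filter_de(de_tab, padj_lt, abs_lfc_gt))
  writeLines(de_ids, fp("de_selected.txt"))
  say("de-filter: ", length(de_ids), " of ", nrow(de_tab), " records kept")

  net <- stage("network", build_network(
    mirna_mrna = read_pair_table(fp("pairs_mirna_mrna.tsv")),
    mirna_lnc = read_pair_table(fp("pairs_mirna_lnc.tsv")),
    cis = cis, trans = trans, etms = etm_hits))
  export_network(net, fp("network_edges.tsv"), "edges_tsv")
  export_network(net, fp("network.graphml"), "graphml")
  summ <- summarize_network(net)
  say("network: ", summ$n_nodes, " nodes, ", summ$n_edges, " edges, ",
      summ$n_components, " components")

  files <- c("mirnas.fa", "lncrnas.fa", "annotation.gff3",
             "expr_lnc_gene.tsv", "expr_mirna.tsv", "de_table.tsv",
             "pairs_mirna_mrna.tsv", "pairs_mirna_lnc.tsv", "etm_hits.tsv",
             "cis_targets.tsv", "trans_targets.tsv", "de_selected.txt",
             "network_edges.tsv")
  checksums <- tools::md5sum(file.path(out_dir, files))
  names(checksums) <- files
  manifest <- list(
    package_version = as.character(utils::packageVersion("etmnet")),
    config = config[setdiff(names(config),
                            c("planted_etm", "planted_tau", "cis_distances",
                              "trans_r", "planted_de"))],
    checksums = as.list(checksums)
  )
  yaml::write_yaml(manifest, fp("run_manifest.yaml"))

  invisible(list(
    manifest = list(etm = seqs$manifest, expression = expr$manifest,
                    cis = ann$manifest, de = de$manifest),
    tau_lnc = tau_lnc, tau_mirna = tau_mir, selected_lnc = selected,
    etm_hits = etm_hits, cis = cis, trans = trans, de_ids = de_ids,
    network = net, summary = summ,
    files = file.path(out_dir, files), checksums = checksums
  ))
}
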