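NODE_CLASSES <- c("miRNA", "lncRNA", "mRNA", "TF")
EDGE_CLASSES <- c("mirna_cleaves_mrna", "mirna_cleaves_lncrna",
                  "lncrna_cis_gene", "lncrna_trans_gene",
                  "lncrna_etm_mirna")

# endpoint classes implied by each edge class (target "mRNA" may be
# upgraded to TF by the node annotation)
.edge_endpoint_class <- list(
  mirna_cleaves_mrna = c("miRNA", "mRNA"),
  mirna_cleaves_lncrna = c("miRNA", "lncRNA"),
  lncrna_cis_gene = c("lncRNA", "mRNA"),
  lncrna_trans_gene = c("lncRNA", "mRNA"),
  lncrna_etm_mirna = c("lncRNA", "miRNA")
)

.new_network <- function(nodes, edges) {
  structure(list(nodes = nodes, edges = edges), class = "regulatory_network")
}

#' Assemble the tripartite miRNA-lncRNA-mRNA/TF regulatory network
#'
#' Nodes are created on demand from the edge tables; classes are inferred
#' from each table's role and may be upgraded from mRNA to TF by
#' `node_annot`. eTM edges run lncRNA -> miRNA (the mimic sequesters the
#' miRNA) and only rule-satisfying (verdict-true) hits are admitted. The
#' result is a pure function of the input sets: row order and duplicated
#' rows do not change it.
#'
#' @param mirna_mrna,mirna_lnc Pair tables from [target_pairs()] (cleavage
#'   edges; the second must target lncRNAs).
#' @param cis Data.frame from [predict_cis()].
#' @param trans Data.frame from [predict_trans()].
#' @param etms Data.frame from [scan_etms()] or [validate_etm_table()]
#'   (columns `mirna_id`, `lncrna_id`, `verdict`, optionally `n_mismatch`).
#' @param node_annot Optional data.frame with columns `id`, `class`
#'   (one of `r paste(NODE_CLASSES, collapse=", ")`) and optionally
#'   `family`, used to type TF genes.
#' @return A `regulatory_network`: list with `nodes` (id, node_class,
#'   family) and `edges` (source, target, edge_class, distance_bp, r,
#'   n_mismatch).
#' @export
build_network <- function(mirna_mrna = NULL, mirna_lnc = NULL, cis = NULL,
                          trans = NULL, etms = NULL, node_annot = NULL) {
  ed <- list()
  add_edges <- function(source, target, edge_class, distance_bp = NA_integer_,
                        r = NA_real_, n_mismatch = NA_integer_) {
    n <- length(source)
    if (n == 0L) return()
    ed[[length(ed) + 1L]] <<- data.frame(
      source = source, target = target, edge_class = edge_class,
      distance_bp = rep_len(distance_bp, n), r = rep_len(r, n),
      n_mismatch = rep_len(n_mismatch, n), stringsAsFactors = FALSE
    )
  }
  if (!is.null(mirna_mrna) && nrow(mirna_mrna) > 0L) {
    if (!all(mirna_mrna$interaction == "mirna_cleaves_mrna")) {
      stop("mirna_mrna table must contain only mirna_cleaves_mrna rows")
    }
    add_edges(mirna_mrna$regulator_id, mirna_mrna$target_id,
              "mirna_cleaves_mrna")
  }
  if (!is.null(mirna_lnc) && nrow(mirna_lnc) > 0L) {
    if (!all(mirna_lnc$interaction == "mirna_cleaves_lncrna")) {
      stop("mirna_lnc table must contain only mirna_cleaves_lncrna rows")
    }
    add_edges(mirna_lnc$regulator_id, mirna_lnc$target_id,
              "mirna_cleaves_lncrna")
  }
  if (!is.null(cis) && nrow(cis) > 0L) {
    add_edges(cis$lncrna_id, cis$gene_id, "lncrna_cis_gene",
              distance_bp = cis$distance_bp)
  }
  if (!is.null(trans) && nrow(trans) > 0L) {
    add_edges(trans$lncrna_id, trans$gene_id, "lncrna_trans_gene",
              r = trans$r)
  }
  if (!is.null(etms) && nrow(etms) > 0L) {
    keep <- if ("verdict" %in% names(etms)) etms$verdict else TRUE
    e <- etms[keep, , drop = FALSE]
    if (nrow(e) > 0L) {
      add_edges(e$lncrna_id, e$mirna_id, "lncrna_etm_mirna",
                n_mismatch = if ("n_mismatch" %in% names(e))
                  e$n_mismatch else NA_integer_)
    }
  }

  edges <- if (length(ed) == 0L) {
    data.frame(source = character(0), target = character(0),
               edge_class = character(0), distance_bp = integer(0),
               r = numeric(0), n_mismatch = integer(0),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, ed)
  }
  # same-class duplicates collapse; multi-edges of different classes stay
  edges <- edges[!duplicated(edges[, c("source", "target", "edge_class")]), ,
                 drop = FALSE]
  edges <- edges[order(edges$edge_class, edges$source, edges$target), ,
                 drop = FALSE]
  rownames(edges) <- NULL

  # node classes implied by the edges; conflicts are hard errors
  cls <- list()
  assign_class <- function(id, class) {
    for (i in seq_along(id)) {
      cur <- cls[[id[i]]]
      if (is.null(cur)) {
        cls[[id[i]]] <<- class[i]
      } else if (cur != class[i]) {
        stop("conflicting node class for '", id[i], "': ", cur, " vs ",
             class[i])
      }
    }
  }
  for (k in seq_len(nrow(edges))) {
    ec <- .edge_endpoint_class[[edges$edge_class[k]]]
    assign_class(edges$source[k], ec[1])
    assign_class(edges$target[k], ec[2])
  }
  nodes <- data.frame(id = names(cls) %||% character(0),
                      node_class = unlist(cls, use.names = FALSE) %||%
                        character(0),
                      family = rep(NA_character_, length(cls)),
                      stringsAsFactors = FALSE)
  if (!is.null(node_annot) && nrow(nodes) > 0L) {
    idx <- match(nodes$id, node_annot$id)
    ann_class <- node_annot$class[idx]
    # TF annotation takes precedence over the inferred mRNA class
    up <- !is.na(ann_class) & ann_class == "TF" & nodes$node_class == "mRNA"
    nodes$node_class[up] <- "TF"
    conflict <- !is.na(ann_class) & !up & ann_class != nodes$node_class
    if (any(conflict)) {
      stop("conflicting node class annotation for: ",
           paste(nodes$id[conflict], collapse = ", "))
    }
    if ("family" %in% names(node_annot)) {
      nodes$family <- node_annot$family[idx]
    }
  }
  nodes <- nodes[order(nodes$node_class, nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL
  .new_network(nodes, edges)
}

#' Convert a regulatory network to an igraph graph
#' @param net A `regulatory_network`.
#' @return An [igraph::igraph] directed graph with `node_class` and
#'   `edge_class` attributes.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "regulatory_network"))
  igraph::graph_from_data_frame(
    d = net$edges, directed = TRUE,
    vertices = data.frame(name = net$nodes$id,
                          node_class = net$nodes$node_class,
                          stringsAsFactors = FALSE)
  )
}

#' Summarize a regulatory network
#'
#' @param net A `regulatory_network`.
#' @param top_n Number of top-degree nodes reported per class.
#' @return List with `n_nodes`, `n_edges`, `nodes_by_class`,
#'   `edges_by_class`, `degree_by_class` (mean/max), `n_components`
#'   (weak), and `top_degree` per class.
#' @export
summarize_network <- function(net, top_n = 5L) {
  stopifnot(inherits(net, "regulatory_network"))
  nodes_by_class <- table(factor(net$nodes$node_class, levels = NODE_CLASSES))
  edges_by_class <- table(factor(net$edges$edge_class, levels = EDGE_CLASSES))
  deg <- table(factor(c(net$edges$source, net$edges$target),
                      levels = net$nodes$id))
  deg_by_class <- lapply(split(as.integer(deg[net$nodes$id]),
                               net$nodes$node_class), function(d) {
    c(mean = if (length(d)) mean(d) else 0, max = if (length(d)) max(d) else 0)
  })
  top <- lapply(split(net$nodes$id, net$nodes$node_class), function(ids) {
    d <- as.integer(deg[ids])
    ord <- order(-d, ids)
    setNames(d[ord], ids[ord])[seq_len(min(top_n, length(ids)))]
  })
  n_comp <- if (nrow(net$nodes) == 0L) 0L else
    igraph::count_components(as_igraph(net), mode = "weak")
  list(n_nodes = nrow(net$nodes), n_edges = nrow(net$edges),
       nodes_by_class = c(nodes_by_class), edges_by_class = c(edges_by_class),
       degree_by_class = deg_by_class, n_components = n_comp,
       top_degree = top)
}

#' Export a regulatory network
#'
#' `edges_tsv` writes one row per edge with non-missing attributes packed
#' as `key=value` pairs; `graphml` writes GraphML (via igraph) with
#' `node_class` and `edge_class` as typed attributes.
#'
#' @param net A `regulatory_network`.
#' @param path Output file path.
#' @param format `"edges_tsv"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("edges_tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(as_igraph(net), path, format = "graphml")
    return(invisible(path))
  }
  attrs <- vapply(seq_len(nrow(net$edges)), function(k) {
    kv <- character(0)
    if (!is.na(net$edges$distance_bp[k])) {
      kv <- c(kv, paste0("distance_bp=", net$edges$distance_bp[k]))
    }
    if (!is.na(net$edges$r[k])) {
      kv <- c(kv, paste0("r=", format(net$edges$r[k], digits = 15)))
    }
    if (!is.na(net$edges$n_mismatch[k])) {
      kv <- c(kv, paste0("n_mismatch=", net$edges$n_mismatch[k]))
    }
    if (length(kv) == 0L) "." else paste(kv, collapse = ";")
  }, "")
  df <- data.frame(source = net$edges$source, target = net$edges$target,
                   edge_class = net$edges$edge_class, attributes = attrs,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Re-import a network from an edges TSV
#'
#' Rebuilds nodes and typed edges from [export_network()]'s `edges_tsv`
#' output. Node classes are inferred from edge classes; TF status is
#' restored only when `node_annot` is supplied.
#'
#' @param path Edges TSV path.
#' @param node_annot Optional annotation (see [build_network()]).
#' @return A `regulatory_network`.
#' @export
import_edges_tsv <- function(path, node_annot = NULL) {
  df <- read.delim(path, sep = "\t", quote = "", stringsAsFactors = FALSE)
  bad <- setdiff(unique(df$edge_class), EDGE_CLASSES)
  if (length(bad) > 0L) stop("unknown edge class: ", paste(bad, collapse = ", "))
  parse_attr <- function(s, key) {
    m <- regmatches(s, regexpr(paste0(key, "=[^;]+"), s))
    if (length(m) == 0L) NA else sub(paste0(key, "="), "", m)
  }
  df$distance_bp <- vapply(df$attributes, function(s)
    as.integer(parse_attr(s, "distance_bp")), integer(1), USE.NAMES = FALSE)
  df$r <- vapply(df$attributes, function(s)
    as.numeric(parse_attr(s, "r")), numeric(1), USE.NAMES = FALSE)
  df$n_mismatch <- vapply(df$attributes, function(s)
    as.integer(parse_attr(s, "n_mismatch")), integer(1), USE.NAMES = FALSE)
  net <- build_network(
    mirna_mrna = if (any(df$edge_class == "mirna_cleaves_mrna")) {
      e <- df[df$edge_class == "mirna_cleaves_mrna", ]
      target_pairs(e$source, e$target, "mirna_cleaves_mrna")
    },
    mirna_lnc = if (any(df$edge_class == "mirna_cleaves_lncrna")) {
      e <- df[df$edge_class == "mirna_cleaves_lncrna", ]
      target_pairs(e$source, e$target, "mirna_cleaves_lncrna")
    },
    cis = if (any(df$edge_class == "lncrna_cis_gene")) {
      e <- df[df$edge_class == "lncrna_cis_gene", ]
      data.frame(lncrna_id = e$source, gene_id = e$target,
                 distance_bp = e$distance_bp, side = NA_character_,
                 stringsAsFactors = FALSE)
    },
    trans = if (any(df$edge_class == "lncrna_trans_gene")) {
      e <- df[df$edge_class == "lncrna_trans_gene", ]
      data.frame(lncrna_id = e$source, gene_id = e$target, r = e$r,
                 n_samples = NA_integer_, stringsAsFactors = FALSE)
    },
    etms = if (any(df$edge_class == "lncrna_etm_mirna")) {
      e <- df[df$edge_class == "lncrna_etm_mirna", ]
      data.frame(mirna_id = e$target, lncrna_id = e$source, verdict = TRUE,
                 n_mismatch = e$n_mismatch, stringsAsFactors = FALSE)
    },
    node_annot = node_annot
  )
  net
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat("regulatory_network:", nrow(x$nodes), "nodes,", nrow(x$edges),
      "edges\n")
  print(table(x$nodes$node_class))
  print(table(x$edges$edge_class))
  invisible(x)
}
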