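# Multi-evidence divergence network: TFs as nodes, with co-expression,
# target-overlap, motif-similarity and effector-preference edges, plus
# conditional-regulation edges linking TFs to the condition sets where
# they act.

#' Assemble the multi-evidence divergence network
#'
#' Builds an igraph network over the TF family. Edges are included only
#' when they pass their defining thresholds: co-expression `rho >= 0.5`
#' and `p <= 0.05`; target overlap Bonferroni-corrected `p <= 0.05` (over
#' all pairs in the overlap table) and percent overlap `>= 50`;
#' conditional regulation `bh_q <= 0.05` and `|median r| >= 0.4` (i.e. the
#' `called` rows of [call_regulons()] output); motif similarity is an
#' optional pass-through table with its own precomputed corrected q-values
#' (`q <= 0.05`). Effector-cluster membership adds a node per cluster
#' consensus and one edge per TF.
#'
#' @param tfs character vector of TF ids (always present as nodes).
#' @param coexpression output of [ffrp_coexpression()] (optional).
#' @param overlap data frame `tf_a`, `tf_b`, `k`, `percent_overlap`,
#'   `pvalue` (optional), e.g. built from [target_overlap()] over all
#'   pairs.
#' @param conditional a `regulon_calls` data frame (optional).
#' @param effector output of [effector_clusters()] (optional).
#' @param motif optional data frame `tf_a`, `tf_b`, `q`.
#' @param rho_min,p_max,percent_min,q_max,min_abs_r thresholds as above.
#' @return an [igraph::graph] with vertex attributes `name`, `kind` and
#'   typed, attribute-carrying edges (attribute `type` plus the defining
#'   statistic).
#' @export
assemble_network <- function(tfs, coexpression = NULL, overlap = NULL,
                             conditional = NULL, effector = NULL,
                             motif = NULL, rho_min = 0.5, p_max = 0.05,
                             percent_min = 50, q_max = 0.05,
                             min_abs_r = 0.4) {
  nodes <- data.frame(name = tfs, kind = "tf", stringsAsFactors = FALSE)
  edges <- list()
  add_edge <- function(from, to, type, stat, role = NA_character_) {
    data.frame(from = from, to = to, type = type, statistic = stat,
               role = role, stringsAsFactors = FALSE)
  }
  check_nodes <- function(ids) {
    bad <- setdiff(ids, nodes$name)
    if (length(bad)) {
      stop("edge references unknown node(s): ",
           paste(unique(bad), collapse = ", "), call. = FALSE)
    }
  }
  if (!is.null(coexpression)) {
    sig <- coexpression[!is.na(coexpression$rho) &
                          coexpression$rho >= rho_min &
                          coexpression$pvalue <= p_max, , drop = FALSE]
    check_nodes(c(sig$tf_a, sig$tf_b))
    if (nrow(sig)) {
      edges[[length(edges) + 1L]] <-
        add_edge(sig$tf_a, sig$tf_b, "coexpression", sig$rho)
    }
  }
  if (!is.null(overlap)) {
    ov <- overlap
    ov$bonferroni_p <- pmin(ov$pvalue * nrow(ov), 1)
    sig <- ov[ov$bonferroni_p <= p_max & ov$percent_overlap >= percent_min,
              , drop = FALSE]
    check_nodes(c(sig$tf_a, sig$tf_b))
    if (nrow(sig)) {
      edges[[length(edges) + 1L]] <-
        add_edge(sig$tf_a, sig$tf_b, "target_overlap", sig$percent_overlap)
    }
  }
  if (!is.null(motif)) {
    sig <- motif[motif$q <= q_max, , drop = FALSE]
    check_nodes(c(sig$tf_a, sig$tf_b))
    if (nrow(sig)) {
      edges[[length(edges) + 1L]] <-
        add_edge(sig$tf_a, sig$tf_b, "motif_similarity", sig$q)
    }
  }
  # conditional edges add condition-set nodes alongside the TF nodes
  g_nodes <- nodes
  if (!is.null(conditional) && nrow(conditional)) {
    sig <- if (!is.null(conditional$called)) {
      conditional[conditional$called, , drop = FALSE]
    } else {
      conditional[conditional$bh_q <= q_max &
                    abs(conditional$median_r) >= min_abs_r, , drop = FALSE]
    }
    if (nrow(sig)) {
      check_nodes(sig$tf)
      g_nodes <- rbind(g_nodes,
                       data.frame(name = unique(sig$condition_set),
                                  kind = "condition_set"))
      edges[[length(edges) + 1L]] <-
        add_edge(sig$tf, sig$condition_set, "conditional_regulation",
                 sig$bh_q, role = sig$role)
    }
  }
  if (!is.null(effector)) {
    cons <- attr(effector, "consensus")
    labels <- if (!is.null(cons)) {
      paste0("effector:", cons[as.character(effector$cluster)])
    } else {
      paste0("effector:", effector$cluster)
    }
    g_nodes <- rbind(g_nodes, data.frame(name = unique(labels),
                                         kind = "effector"))
    edges[[length(edges) + 1L]] <-
      add_edge(effector$tf, labels, "effector_preference", NA_real_)
  }
  ed <- if (length(edges)) do.call(rbind, edges) else
    data.frame(from = character(0), to = character(0), type = character(0),
               statistic = numeric(0), role = character(0))
  # deduplicate by (type, unordered endpoint pair)
  if (nrow(ed)) {
    a <- pmin(ed$from, ed$to); b <- pmax(ed$from, ed$to)
    ed <- ed[!duplicated(paste(ed$type, a, b)), , drop = FALSE]
  }
  g_nodes <- g_nodes[!duplicated(g_nodes$name), , drop = FALSE]
  igraph::graph_from_data_frame(ed, directed = FALSE, vertices = g_nodes)
}

#' Export / import an evidence network
#'
#' GraphML round-trips all node and edge attributes; SIF carries edge
#' types only (`node1 type node2` per line).
#'
#' @param network an igraph object from [assemble_network()].
#' @param path output file.
#' @param format `"graphml"` or `"sif"`.
#' @export
export_network <- function(network, path, format = c("graphml", "sif")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(network, path, format = "graphml")
  } else {
    ed <- igraph::as_data_frame(network, what = "edges")
    lines <- if (nrow(ed)) {
      sprintf("%s\t%s\t%s", ed$from, ed$type, ed$to)
    } else character(0)
    iso <- setdiff(igraph::V(network)$name, c(ed$from, ed$to))
    writeLines(c(lines, iso), path)
  }
  invisible(path)
}

#' @rdname export_network
#' @export
read_network <- function(path) {
  igraph::read_graph(path, format = "graphml")
}

#' Summarise all edges of an evidence network as a table
#'
#' @param network an igraph object from [assemble_network()].
#' @return data frame `from`, `to`, `type`, `statistic`, `role`.
#' @export
network_edge_table <- function(network) {
  igraph::as_data_frame(network, what = "edges")
}
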