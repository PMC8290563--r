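# Combined interaction network: scored protein-protein edges plus
# mRNA-lncRNA pairing edges, degree-centrality ranking, and the
# three-stage hub-pair shortlist.

#' Read STRING-style scored edges
#'
#' @param path TSV with columns `protein1`, `protein2`, `combined_score`
#'   (native STRING scores 0-1000 are rescaled to \[0, 1\]; scores already
#'   in \[0, 1\] are kept as-is).
#' @return data.frame `node_a`, `node_b`, `score`.
#' @export
read_string_edges <- function(path) {
  if (!file.exists(path)) stop("edge file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  nm <- names(df)
  if (all(c("protein1", "protein2", "combined_score") %in% nm))
    df <- data.frame(node_a = df$protein1, node_b = df$protein2,
                     score = df$combined_score, stringsAsFactors = FALSE)
  miss <- setdiff(c("node_a", "node_b", "score"), names(df))
  if (length(miss)) stop("edge file lacks columns: ",
                         paste(miss, collapse = ", "))
  if (any(df$score > 1)) df$score <- df$score / 1000
  if (any(df$score < 0 | df$score > 1))
    stop("edge scores must lie in [0, 1] (or 0-1000 native)")
  df
}

#' Build the combined interaction network
#'
#' Protein-protein edges at or above `score_threshold` are combined with
#' one unweighted `hml` edge per mRNA-lncRNA pair into a simple undirected
#' igraph graph. Self-loops in the input are dropped with a warning;
#' duplicate edges are collapsed (an edge supported by both sources keeps
#' kind `"hml"`, the predicted association).
#'
#' @param ppi_edges data.frame from [read_string_edges()] (may have zero
#'   rows).
#' @param pairs a [pair_by_proximity()] result (may have zero rows).
#' @param score_threshold minimum combined score for a ppi edge to be
#'   kept, in \[0, 1\] (default 0.4, STRING's "medium confidence").
#' @return an igraph object with edge attribute `kind` in
#'   `{"ppi", "hml"}`.
#' @export
build_network <- function(ppi_edges, pairs, score_threshold = 0.4) {
  if (score_threshold < 0 || score_threshold > 1)
    stop("score_threshold must lie in [0, 1]")
  ppi <- ppi_edges[ppi_edges$score >= score_threshold, , drop = FALSE]
  el <- rbind(
    if (nrow(ppi)) data.frame(a = ppi$node_a, b = ppi$node_b,
                              kind = "ppi", stringsAsFactors = FALSE),
    if (nrow(pairs)) data.frame(a = pairs$mrna_id, b = pairs$lncrna_id,
                                kind = "hml", stringsAsFactors = FALSE))
  if (is.null(el) || nrow(el) == 0L)
    return(igraph::make_empty_graph(0, directed = FALSE))
  loops <- el$a == el$b
  if (any(loops)) {
    warning(sum(loops), " self-loop edge(s) dropped")
    el <- el[!loops, , drop = FALSE]
  }
  # canonical endpoint order so duplicates collapse deterministically;
  # hml sorts before ppi, so an edge seen as both keeps kind "hml"
  key_a <- pmin(el$a, el$b)
  key_b <- pmax(el$a, el$b)
  o <- order(key_a, key_b, el$kind)
  el <- data.frame(a = key_a[o], b = key_b[o], kind = el$kind[o],
                   stringsAsFactors = FALSE)
  el <- el[!duplicated(el[c("a", "b")]), , drop = FALSE]
  g <- igraph::graph_from_data_frame(el[c("a", "b")], directed = FALSE)
  igraph::E(g)$kind <- el$kind
  g
}

#' Degree centrality
#'
#' degree / (n - 1) for every node, the hub-ranking score.
#'
#' @param graph an igraph object with at least 2 nodes.
#' @param kind optional edge kind (`"ppi"` or `"hml"`) to restrict the
#'   degree computation to one edge class; by default all edges count.
#' @return named numeric vector in \[0, 1\].
#' @export
degree_centrality <- function(graph, kind = NULL) {
  n <- igraph::vcount(graph)
  if (n < 2L) stop("degree centrality needs at least 2 nodes")
  if (!is.null(kind)) {
    keep <- igraph::E(graph)[igraph::E(graph)$kind == kind]
    graph <- igraph::subgraph.edges(graph, keep, delete.vertices = FALSE)
  }
  igraph::degree(graph) / (n - 1)
}

#' Shortlist hub mRNA-lncRNA pairs
#'
#' Applies the screening funnel to the mRNAs that carry at least one
#' proximity pair: (1) membership in the target pathway (insulin
#' resistance in the motivating study); (2) functional annotation in a
#' common metabolic cluster — by default both carbohydrate- and
#' lipid-metabolism category flags (`dual_rule = "both_categories"`), with
#' the alternative reading "involved in more than two pathways"
#' (`dual_rule = "multi_pathway"`, `n_pathways > 2`) also available;
#' (3) at least one paired lncRNA with a database annotation. Survivors
#' are ranked by degree centrality (descending), ties by `n_pathways`
#' then id, and truncated to `top_k`. Every filter's before/after count is
#' recorded in the `funnel` attribute; an empty shortlist is a valid
#' outcome.
#'
#' @param graph the [build_network()] graph.
#' @param gene_tags a [tag_categories()] data.frame for the candidate
#'   mRNAs.
#' @param pairs a [pair_by_proximity()] result.
#' @param lnc_annotated named logical vector: lncrna_id -> has a database
#'   annotation.
#' @param target_pathway character vector of gene ids in the target
#'   pathway.
#' @param top_k maximum shortlist size (default 10).
#' @param dual_rule `"both_categories"` (default) or `"multi_pathway"`.
#' @return data.frame of `HubCandidate` rows: `mrna_id`, `lncrna_ids`
#'   (comma-joined), `degree`, `degree_centrality`, `categories`,
#'   `in_target_pathway`, `n_pathways`, `annotated_lncrna`; attribute
#'   `funnel` holds the per-stage counts.
#' @export
select_hub_pairs <- function(graph, gene_tags, pairs, lnc_annotated,
                             target_pathway, top_k = 10L,
                             dual_rule = c("both_categories",
                                           "multi_pathway")) {
  dual_rule <- match.arg(dual_rule)
  if (top_k < 1L) stop("top_k must be >= 1")
  funnel <- data.frame(stage = character(0), n_in = integer(0),
                       n_out = integer(0), stringsAsFactors = FALSE)
  log_stage <- function(stage, n_in, n_out) {
    message(sprintf("select_hub_pairs: %-22s %d -> %d", stage, n_in, n_out))
    rbind(funnel, data.frame(stage = stage, n_in = n_in, n_out = n_out,
                             stringsAsFactors = FALSE))
  }
  cand <- sort(unique(pairs$mrna_id))
  in_target <- cand[cand %in% target_pathway]
  funnel <- log_stage("target_pathway", length(cand), length(in_target))
  tag_idx <- match(in_target, gene_tags$feature_id)
  dual_ok <- if (dual_rule == "both_categories") {
    !is.na(tag_idx) & gene_tags$both[tag_idx]
  } else {
    !is.na(tag_idx) & gene_tags$n_pathways[tag_idx] > 2L
  }
  dual <- in_target[dual_ok]
  funnel <- log_stage(paste0("dual_category(", dual_rule, ")"),
                      length(in_target), length(dual))
  has_annot <- vapply(dual, function(g) {
    lncs <- pairs$lncrna_id[pairs$mrna_id == g]
    any(lnc_annotated[lncs] %in% TRUE)
  }, logical(1))
  final <- dual[has_annot]
  funnel <- log_stage("annotated_lncrna", length(dual), length(final))
  if (!length(final)) {
    message("select_hub_pairs: empty shortlist")
    out <- data.frame(mrna_id = character(0), lncrna_ids = character(0),
                      degree = integer(0), degree_centrality = numeric(0),
                      categories = character(0),
                      in_target_pathway = logical(0),
                      n_pathways = integer(0),
                      annotated_lncrna = logical(0),
                      stringsAsFactors = FALSE)
    attr(out, "funnel") <- funnel
    return(out)
  }
  dc <- degree_centrality(graph)
  deg <- igraph::degree(graph)
  rows <- lapply(final, function(g) {
    lncs <- sort(unique(pairs$lncrna_id[pairs$mrna_id == g]))
    ti <- match(g, gene_tags$feature_id)
    data.frame(mrna_id = g,
               lncrna_ids = paste(lncs, collapse = ","),
               degree = if (g %in% names(deg)) unname(deg[g]) else 0L,
               degree_centrality = if (g %in% names(dc)) unname(dc[g]) else 0,
               categories = gene_tags$categories[ti],
               in_target_pathway = TRUE,
               n_pathways = gene_tags$n_pathways[ti],
               annotated_lncrna = TRUE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$degree_centrality, -out$n_pathways, out$mrna_id), ]
  n_ranked <- nrow(out)
  out <- utils::head(out, top_k)
  funnel <- log_stage("rank_truncate_top_k", n_ranked, nrow(out))
  rownames(out) <- NULL
  attr(out, "funnel") <- funnel
  out
}

#' Export the network for visualization tools
#'
#' Writes an edge-list TSV (`node_a`, `node_b`, `kind`) and a
#' node-attribute TSV (`node`, `degree`, `degree_centrality`).
#'
#' @param graph the [build_network()] graph.
#' @param edge_path,node_path output paths.
#' @return `edge_path`, invisibly.
#' @export
write_network <- function(graph, edge_path, node_path) {
  el <- igraph::as_data_frame(graph, what = "edges")
  names(el)[1:2] <- c("node_a", "node_b")
  utils::write.table(el, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  deg <- igraph::degree(graph)
  dc <- if (igraph::vcount(graph) >= 2) degree_centrality(graph)
        else stats::setNames(numeric(length(deg)), names(deg))
  nd <- data.frame(node = names(deg), degree = unname(deg),
                   degree_centrality = unname(dc[names(deg)]),
                   stringsAsFactors = FALSE)
  nd <- nd[order(nd$node), ]
  utils::write.table(nd, node_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(edge_path)
}
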