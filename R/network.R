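## miRNA-gene interaction network assembly.  Gene-gene edges come from an
## offline STRING-style combined-score table; miRNA-gene edges come from the
## seed-based target table.  The network is undirected; regulation
## directionality is a node-type attribute, not an edge direction.

normalize_scores <- function(score) {
  if (length(score) == 0) return(numeric(0))
  if (any(!is.finite(score)) || any(score < 0))
    stop("malformed interaction scores")
  ## STRING exports use either a 0-1000 integer scale or a 0-1 real scale;
  ## auto-detect by the column maximum
  if (max(score) > 1) score <- score / 1000
  if (any(score > 1)) stop("scores not normalizable to [0, 1]")
  score
}

#' Assemble the miRNA-gene interaction network
#'
#' Gene-gene edges are interaction-table rows with normalized combined score
#' at or above `score_min` (duplicate unordered pairs keep their maximal
#' score); miRNA-gene edges come from the target table.  When the
#' interaction table contributes at least one passing edge, target genes are
#' restricted to genes incident to a passing gene-gene edge; with an empty
#' (or fully filtered-out) interaction table all target genes are kept, so
#' the network then contains only miRNA-target edges.  Isolated nodes are
#' dropped and node ordering is deterministic.
#'
#' @param targets data.frame with columns `mirna_id`, `gene_id` (e.g. from
#'   [predict_targets()]).
#' @param interactions data.frame with columns `gene_a`, `gene_b`, `score`
#'   and optionally `evidence` (`validated` / `predicted`).
#' @param score_min minimum normalized combined score for a gene-gene edge
#'   (default 0.4, the conventional medium-confidence cut-off).
#' @param node_universe optional id set; nodes outside it are dropped first.
#' @return an [igraph::graph] with vertex attributes `name` and `type`
#'   (`"gene"` / `"miRNA"`) and edge attributes `score` and `evidence`.
#' @export
build_network <- function(targets, interactions, score_min = 0.4,
                          node_universe = NULL) {
  if (nrow(interactions) > 0) {
    if (any(interactions$gene_a == interactions$gene_b))
      stop("self-pairs are not allowed in the interaction table")
    interactions$score <- normalize_scores(interactions$score)
    if (is.null(interactions$evidence)) interactions$evidence <- "predicted"
    key <- apply(cbind(interactions$gene_a, interactions$gene_b), 1,
                 function(r) paste(sort(r), collapse = "|"))
    ord <- order(key, -interactions$score)
    interactions <- interactions[ord[!duplicated(key[ord])], , drop = FALSE]
    interactions <- interactions[interactions$score >= score_min, ,
                                 drop = FALSE]
  }
  if (!is.null(node_universe)) {
    targets <- targets[targets$gene_id %in% node_universe &
                         targets$mirna_id %in% node_universe, , drop = FALSE]
    if (nrow(interactions) > 0)
      interactions <- interactions[interactions$gene_a %in% node_universe &
                                     interactions$gene_b %in% node_universe, ,
                                   drop = FALSE]
  }
  retained_genes <- if (nrow(interactions) > 0)
    sort(unique(c(interactions$gene_a, interactions$gene_b)))
  else sort(unique(targets$gene_id))
  targets <- targets[targets$gene_id %in% retained_genes, , drop = FALSE]
  edges <- rbind(
    if (nrow(interactions) > 0)
      data.frame(from = interactions$gene_a, to = interactions$gene_b,
                 score = interactions$score,
                 evidence = interactions$evidence, stringsAsFactors = FALSE),
    if (nrow(targets) > 0)
      data.frame(from = targets$mirna_id, to = targets$gene_id,
                 score = NA_real_, evidence = "predicted",
                 stringsAsFactors = FALSE))
  if (is.null(edges) || nrow(edges) == 0)
    return(igraph::make_empty_graph(directed = FALSE))
  genes <- sort(unique(c(targets$gene_id,
                         if (nrow(interactions) > 0)
                           c(interactions$gene_a, interactions$gene_b))))
  mirnas <- sort(unique(targets$mirna_id))
  vertices <- data.frame(name = c(genes, mirnas),
                         type = c(rep("gene", length(genes)),
                                  rep("miRNA", length(mirnas))),
                         stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = vertices)
  igraph::delete_vertices(g, igraph::V(g)[igraph::degree(g) == 0])
}

#' Per-node degree table and hub ranking
#'
#' @param network an [igraph::graph] from [build_network()].
#' @param top_k number of hubs to flag.
#' @return data.frame `node`, `type`, `degree`, `is_hub`, ranked by
#'   descending degree with ties broken by id.
#' @export
node_stats <- function(network, top_k = 10) {
  if (igraph::vcount(network) == 0)
    return(data.frame(node = character(), type = character(),
                      degree = integer(), is_hub = logical()))
  deg <- igraph::degree(network)
  typ <- igraph::vertex_attr(network, "type")
  ord <- order(-deg, names(deg))
  out <- data.frame(node = names(deg)[ord], type = typ[ord],
                    degree = as.integer(deg[ord]),
                    stringsAsFactors = FALSE)
  out$is_hub <- seq_len(nrow(out)) <= top_k
  out
}

#' Export a network as a Cytoscape-loadable SIF edge list
#'
#' One line per edge: `source <TAB> interaction-type <TAB> target`, with the
#' type `gene-gene` or `miRNA-gene`.
#'
#' @param network an [igraph::graph] with `type` vertex attributes.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sif <- function(network, path) {
  el <- igraph::as_edgelist(network)
  typ <- igraph::vertex_attr(network, "type")
  names(typ) <- igraph::V(network)$name
  rel <- ifelse(typ[el[, 1]] == "miRNA" | typ[el[, 2]] == "miRNA",
                "miRNA-gene", "gene-gene")
  writeLines(paste(el[, 1], rel, el[, 2], sep = "\t"), path)
  invisible(path)
}

#' Export a network as GraphML (node types and scores preserved)
#'
#' @inheritParams write_sif
#' @export
write_graphml <- function(network, path) {
  igraph::write_graph(network, path, format = "graphml")
  invisible(path)
}
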