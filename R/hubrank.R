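#' Enumerate maximal cliques of an undirected graph
#'
#' Inclusion-maximal cliques via Bron-Kerbosch with pivoting
#' (igraph's implementation). Isolated vertices form their own maximal
#' clique of size 1. Self-loops and duplicate edges are dropped first.
#'
#' @param edges Two-column data frame of undirected edges (any column
#'   names), or an `igraph` object.
#' @param nodes Optional character vector of node ids, to include isolated
#'   nodes that appear in no edge.
#' @param max_nodes Guard against worst-case exponential blow-up: refuse
#'   graphs larger than this (default 5000).
#' @return List of character vectors, each a maximal clique (sorted ids);
#'   order of the list is unspecified.
#' @examples
#' enumerate_maximal_cliques(tibble::tibble(a = c("a", "b"), b = c("b", "c")))
#' @export
enumerate_maximal_cliques <- function(edges, nodes = NULL, max_nodes = 5000) {
  g <- as_simple_graph(edges, nodes)
  if (igraph::vcount(g) > max_nodes) {
    abort(sprintf(
      "graph has %d nodes (> max_nodes = %d); clique enumeration is worst-case exponential",
      igraph::vcount(g), max_nodes
    ))
  }
  cl <- igraph::max_cliques(g)
  purrr::map(cl, ~ sort(igraph::V(g)$name[.x]))
}

#' Degree and Maximal Clique Centrality hub scores
#'
#' `degree(v)` is the number of incident edges in the simple undirected
#' graph; `MCC(v)` is the sum over all maximal cliques `C` containing `v`
#' of `(|C| - 1)!`, so an isolated node scores `0! = 1` and, in a
#' triangle-free graph, MCC reduces to the degree for every non-isolated
#' node.
#'
#' @inheritParams enumerate_maximal_cliques
#' @return Tibble `node_id, degree, mcc, rank_degree, rank_mcc`, ranked by
#'   score descending with ties broken by node id ascending.
#' @examples
#' tri <- tibble::tibble(from = c("a", "b", "a"), to = c("b", "c", "c"))
#' hub_scores(tri) # every node: degree 2, mcc 2
#' @export
hub_scores <- function(edges, nodes = NULL, max_nodes = 5000) {
  g <- as_simple_graph(edges, nodes)
  ids <- igraph::V(g)$name
  deg <- setNames(as.integer(igraph::degree(g)), ids)
  mcc <- setNames(rep(0, length(ids)), ids)
  for (cl in enumerate_maximal_cliques(g, max_nodes = max_nodes)) {
    mcc[cl] <- mcc[cl] + factorial(length(cl) - 1)
  }
  out <- tibble::tibble(
    node_id = ids, degree = unname(deg), mcc = unname(mcc)
  )
  rank_by <- function(score) {
    ord <- order(-score, out$node_id)
    r <- integer(length(ord))
    r[ord] <- seq_along(ord)
    r
  }
  out |>
    dplyr::mutate(
      rank_degree = rank_by(.data$degree),
      rank_mcc = rank_by(.data$mcc)
    ) |>
    dplyr::arrange(.data$rank_mcc)
}

#' Degree-only hub scores
#'
#' @inheritParams enumerate_maximal_cliques
#' @return Tibble `node_id, degree`.
#' @export
degree_scores <- function(edges, nodes = NULL) {
  g <- as_simple_graph(edges, nodes)
  tibble::tibble(
    node_id = igraph::V(g)$name,
    degree = as.integer(igraph::degree(g))
  )
}

#' Top-K nodes by a hub-ranking method
#'
#' Deterministic selection: nodes sorted by the chosen score descending,
#' ties broken by node id ascending; if the graph has fewer than `k` nodes,
#' all of them are returned (a 45-node network asked for its top 50 yields
#' 45 nodes).
#'
#' @param scores Tibble from [hub_scores()] or [degree_scores()].
#' @param k Number of nodes requested (>= 1).
#' @param method `"degree"` or `"mcc"` — the score column to rank on.
#' @return Character vector of at most `k` node ids, best first.
#' @export
top_k <- function(scores, k, method = c("degree", "mcc")) {
  method <- match.arg(method)
  assert_scalar_number(k, "k", lower = 1)
  assert_columns(scores, c("node_id", method), "scores")
  ord <- order(-scores[[method]], scores$node_id)
  utils::head(scores$node_id[ord], k)
}

# Coerce an edge table (or igraph) to a simple undirected named graph.
as_simple_graph <- function(edges, nodes = NULL) {
  if (igraph::is_igraph(edges)) {
    g <- edges
    if (is.null(igraph::V(g)$name)) {
      igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
    }
  } else {
    edges <- as.data.frame(edges)[, 1:2, drop = FALSE]
    g <- igraph::graph_from_data_frame(
      data.frame(
        from = as.character(edges[[1]]), to = as.character(edges[[2]])
      ),
      directed = FALSE,
      vertices = if (is.null(nodes)) {
        NULL
      } else {
        unique(c(nodes, as.character(edges[[1]]), as.character(edges[[2]])))
      }
    )
  }
  igraph::simplify(igraph::as_undirected(g, mode = "collapse"))
}

#' Flatten a triplet network to an undirected edge table
#'
#' @param network A `triplet_network` from [extract_differential_network()].
#' @return Tibble `from, to` suitable for [hub_scores()].
#' @export
network_edges <- function(network) {
  stopifnot(inherits(network, "triplet_network"))
  tibble::tibble(from = network$edges$source, to = network$edges$target)
}
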