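# Correlation-filtered interaction networks for a candidate gene set and
# topological prioritization by the composite rank score
# RS = (rank_degree + rank_BC + rank_CC) / 3, smaller = more central.

#' Build the correlation-filtered candidate interaction network
#'
#' Edges are restricted to candidate-candidate pairs whose confidence score
#' is strictly greater than `score_min` and whose two-sided Pearson
#' correlation test (t distribution, n - 2 df) on the tissue-matched
#' expression has `p < corr_p`. Isolated nodes are dropped, so the node set
#' is exactly the endpoints of retained edges. Edges with a constant
#' expression profile on an endpoint are dropped with a warning (the
#' correlation is undefined).
#'
#' @param candidates Candidate gene set (character vector or
#'   `candidate_set`).
#' @param edges Edge data frame (`gene1`, `gene2`, `score`), as from
#'   [read_edge_list()] or [simulate_network()].
#' @param expr The tissue-matched [expression_matrix()].
#' @param score_min Confidence threshold, exclusive (default 0.4).
#' @param corr_p Pearson-test threshold (default 0.05).
#' @return Object of class `interaction_network`: list with `graph` (an
#'   igraph), `nodes`, and `edges` (retained edges with per-edge Pearson `r`
#'   and `p` provenance).
#' @export
build_filtered_network <- function(candidates, edges, expr, score_min = 0.4,
                                   corr_p = 0.05) {
  if (inherits(candidates, "candidate_set")) candidates <- candidates$genes
  m <- expr$values
  keep <- edges$gene1 %in% candidates & edges$gene2 %in% candidates &
    edges$gene1 %in% rownames(m) & edges$gene2 %in% rownames(m) &
    edges$score > score_min
  e <- edges[keep, , drop = FALSE]
  n <- ncol(m)
  if (nrow(e)) {
    x <- m[e$gene1, , drop = FALSE]
    y <- m[e$gene2, , drop = FALSE]
    const <- apply(x, 1L, stats::sd) == 0 | apply(y, 1L, stats::sd) == 0
    if (any(const)) {
      warning(sprintf("dropped %d edge(s) with constant expression",
                      sum(const)))
      e <- e[!const, , drop = FALSE]
      x <- x[!const, , drop = FALSE]
      y <- y[!const, , drop = FALSE]
    }
    xs <- x - rowMeans(x); ys <- y - rowMeans(y)
    r <- rowSums(xs * ys) / sqrt(rowSums(xs^2) * rowSums(ys^2))
    r <- pmin(1, pmax(-1, r))
    tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    e$pearson_r <- r
    e$pearson_p <- p
    e <- e[p < corr_p, , drop = FALSE]
  } else {
    e$pearson_r <- numeric(0)
    e$pearson_p <- numeric(0)
  }
  rownames(e) <- NULL
  g <- igraph::graph_from_data_frame(e[, c("gene1", "gene2")],
                                     directed = FALSE)
  structure(list(graph = g, nodes = sort(igraph::V(g)$name), edges = e),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("interaction network: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Node topology table: degree, betweenness, closeness
#'
#' Betweenness is Brandes betweenness normalized by `(n-1)(n-2)/2` with `n`
#' the network size. Closeness uses the within-component convention:
#' `(component size - 1) / sum of distances` to same-component nodes, and 0
#' for singleton components.
#'
#' @param net An `interaction_network` (or an igraph).
#' @return Data frame with columns `gene`, `degree`, `bc`, `cc`.
#' @export
node_topology <- function(net) {
  g <- if (inherits(net, "interaction_network")) net$graph else net
  n <- igraph::vcount(g)
  if (n == 0L) stop("empty network", call. = FALSE)
  deg <- igraph::degree(g)
  bc <- if (n > 2L) igraph::betweenness(g) / ((n - 1) * (n - 2) / 2)
        else rep(0, n)
  d <- igraph::distances(g)
  cc <- apply(d, 1L, function(row) {
    reach <- row[is.finite(row) & row > 0]
    if (length(reach) == 0L) 0 else length(reach) / sum(reach)
  })
  data.frame(gene = igraph::V(g)$name, degree = as.integer(deg),
             bc = unname(bc), cc = unname(cc), stringsAsFactors = FALSE)
}

#' Composite rank score (RS)
#'
#' Ranks nodes descending on each of degree, betweenness and closeness
#' (rank 1 = highest value; average ranks on ties) and sets
#' `rs = (rank_degree + rank_bc + rank_cc) / 3`. Lower RS = more central.
#'
#' @param topo A [node_topology()] table.
#' @return The table with added `rank_degree`, `rank_bc`, `rank_cc`, `rs`.
#' @export
rank_score <- function(topo) {
  desc_rank <- function(x) rank(-x, ties.method = "average")
  topo$rank_degree <- desc_rank(topo$degree)
  topo$rank_bc <- desc_rank(topo$bc)
  topo$rank_cc <- desc_rank(topo$cc)
  topo$rs <- (topo$rank_degree + topo$rank_bc + topo$rank_cc) / 3
  topo
}

#' Select the topological core (top nodes by RS)
#'
#' Takes the `ceiling(fraction * n)` nodes of smallest RS; nodes tied with
#' the boundary RS are all included, so the result is order-independent.
#'
#' @param topo A [rank_score()] table.
#' @param fraction Core fraction (default 0.05, the top 5%).
#' @return Character vector of core gene ids.
#' @export
select_core <- function(topo, fraction = 0.05) {
  if (nrow(topo) == 0L) stop("empty topology table", call. = FALSE)
  k <- ceiling(fraction * nrow(topo))
  cut <- sort(topo$rs)[k]
  sort(topo$gene[topo$rs <= cut])
}

#' Network summary statistics
#'
#' Density `2E / (N (N - 1))` and average neighbors `2E / N`, reported at
#' full precision with the conventional roundings (3 and 2 decimals).
#'
#' @param net An `interaction_network`.
#' @return List: `n_nodes`, `n_edges`, `density`, `avg_neighbors`,
#'   `density_rounded`, `avg_neighbors_rounded`. Density is `NA` for fewer
#'   than 2 nodes.
#' @export
network_summary <- function(net) {
  summarize_network_counts(length(net$nodes), nrow(net$edges))
}

#' @rdname network_summary
#' @param n_nodes,n_edges Node and edge counts of a simple undirected graph.
#' @export
summarize_network_counts <- function(n_nodes, n_edges) {
  density <- if (n_nodes < 2L) NA_real_ else
    2 * n_edges / (n_nodes * (n_nodes - 1))
  avg <- if (n_nodes < 1L) NA_real_ else 2 * n_edges / n_nodes
  list(n_nodes = n_nodes, n_edges = n_edges, density = density,
       avg_neighbors = avg,
       density_rounded = round(density, 3L),
       avg_neighbors_rounded = round(avg, 2L))
}
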