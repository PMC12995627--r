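check_graph <- function(g, min_nodes = 1L) {
  if (!igraph::is_igraph(g)) stop("expected an igraph object", call. = FALSE)
  if (igraph::vcount(g) < min_nodes) {
    stop("graph needs >= ", min_nodes, " node(s)", call. = FALSE)
  }
  if (!igraph::is_simple(g)) {
    stop("graph must be simple (no self-loops or duplicate edges)", call. = FALSE)
  }
  invisible(g)
}

#' Average node degree of an undirected graph
#'
#' `2 |E| / |N|`. For the nine-protein interaction network with 31 edges this
#' is 6.89 (2 d.p.).
#'
#' @param g An undirected simple [igraph::graph].
#' @return Average degree (numeric scalar).
#' @export
average_degree <- function(g) {
  check_graph(g, 1L)
  2 * igraph::ecount(g) / igraph::vcount(g)
}

#' Average local clustering coefficient
#'
#' Mean over all nodes of `C_i = 2 t_i / (k_i (k_i - 1))` where `t_i` counts
#' triangles through node i and `k_i` is its degree; nodes with degree < 2
#' contribute `C_i = 0` (one of the two standard conventions, stated
#' explicitly because it changes the average on sparse graphs).
#'
#' @param g An undirected simple [igraph::graph].
#' @return Value in \[0, 1\]; exactly 1 on complete graphs, 0 on stars.
#' @export
avg_local_clustering <- function(g) {
  check_graph(g, 1L)
  igraph::transitivity(g, type = "localaverage", isolates = "zero")
}

#' Edge density of an undirected graph
#'
#' `|E| / (|N| (|N| - 1) / 2)`, the fraction of possible edges present.
#'
#' @param g An undirected simple [igraph::graph] with >= 2 nodes.
#' @return Value in \[0, 1\].
#' @export
graph_density <- function(g) {
  check_graph(g, 2L)
  igraph::edge_density(g)
}

#' Summary metrics of an interaction graph
#'
#' @param g An undirected simple [igraph::graph].
#' @return One-row data.frame: `nodes`, `edges`, `average_degree`,
#'   `avg_local_clustering`, `density` (`NA` density below 2 nodes).
#' @export
#' @examples
#' g <- igraph::make_full_graph(3)
#' network_summary(g)
network_summary <- function(g) {
  check_graph(g, 1L)
  data.frame(
    nodes = igraph::vcount(g),
    edges = igraph::ecount(g),
    average_degree = average_degree(g),
    avg_local_clustering = avg_local_clustering(g),
    density = if (igraph::vcount(g) >= 2L) graph_density(g) else NA_real_
  )
}
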