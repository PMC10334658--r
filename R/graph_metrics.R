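# Coerce an edge table / network object to a simple undirected igraph
as_undirected_graph <- function(g) {
  if (inherits(g, "igraph")) {
    return(igraph::simplify(igraph::as_undirected(g)))
  }
  if (inherits(g, "differential_network")) {
    return(graph_from_pairs(g$edges$taxon_a, g$edges$taxon_b, g$nodes))
  }
  if (inherits(g, "cooccurrence_network")) {
    e <- g$edges[g$edges$significant, ]
    return(graph_from_pairs(e$taxon_a, e$taxon_b, g$nodes))
  }
  if (is.data.frame(g)) {
    return(graph_from_pairs(g[[1L]], g[[2L]], NULL))
  }
  abort("Cannot interpret `g` as an undirected graph.")
}

graph_from_pairs <- function(a, b, nodes) {
  nodes <- nodes %||% sort(unique(c(a, b)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = a, to = b),
    directed = FALSE,
    vertices = data.frame(name = nodes)
  )
  igraph::simplify(g)
}

#' Betweenness centrality (normalized, undirected)
#'
#' Brandes' algorithm over unweighted shortest paths, normalized by
#' `(n - 1)(n - 2) / 2` (the undirected convention used by Cytoscape).
#' Disconnected graphs are handled naturally: only within-component paths
#' contribute.
#'
#' @param g An igraph, a `differential_network`/`cooccurrence_network`, or
#'   a two-column edge data frame.
#' @return Named numeric vector in `[0, 1]`.
#' @export
betweenness_centrality <- function(g) {
  g <- as_undirected_graph(g)
  n <- igraph::vcount(g)
  b <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  if (n > 2) b / ((n - 1) * (n - 2) / 2) else b * 0
}

#' Closeness centrality (component-local, Cytoscape convention)
#'
#' For node `v` with reachable set `R(v)`:
#' `C(v) = |R(v)| / sum_{u in R(v)} d(v, u)` — the reciprocal of the mean
#' shortest-path distance within the component. Isolated nodes get 0.
#'
#' @inheritParams betweenness_centrality
#' @return Named numeric vector in `[0, 1]`.
#' @export
closeness_centrality <- function(g) {
  g <- as_undirected_graph(g)
  dm <- igraph::distances(g)
  vapply(seq_len(nrow(dm)), function(i) {
    d <- dm[i, -i]
    d <- d[is.finite(d)]
    if (!length(d)) 0 else length(d) / sum(d)
  }, numeric(1)) |>
    stats::setNames(igraph::V(g)$name)
}

#' Local clustering coefficient
#'
#' `C(v) = 2 * (edges among neighbors) / (k_v (k_v - 1))`; nodes of degree
#' below 2 get 0.
#'
#' @inheritParams betweenness_centrality
#' @return Named numeric vector in `[0, 1]`.
#' @export
local_clustering <- function(g) {
  g <- as_undirected_graph(g)
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  stats::setNames(cc, igraph::V(g)$name)
}

#' Neighborhood connectivity
#'
#' Mean degree over a node's neighbors; nodes of degree 0 get 0.
#'
#' @inheritParams betweenness_centrality
#' @return Named numeric vector (>= 0).
#' @export
neighborhood_connectivity <- function(g) {
  g <- as_undirected_graph(g)
  deg <- igraph::degree(g)
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  nc <- as.vector(A %*% deg)
  out <- ifelse(deg > 0, nc / deg, 0)
  stats::setNames(out, igraph::V(g)$name)
}

#' Node characteristics of a (differential) network
#'
#' Degree, betweenness, closeness, local clustering coefficient and
#' neighborhood connectivity for every node, computed on the rewired-edge
#' graph (all edge classes treated as plain undirected edges), sorted by
#' degree descending then node name. The same function accepts a
#' per-condition `cooccurrence_network` (its significant edges) or a raw
#' edge table.
#'
#' @inheritParams betweenness_centrality
#' @return A `microrewire_centrality` tibble: `node`, `degree`,
#'   `betweenness`, `closeness`, `clustering`, `neighborhood_connectivity`.
#' @export
centrality_table <- function(g) {
  ig <- as_undirected_graph(g)
  if (igraph::ecount(ig) == 0L) abort("The network has no edges.")
  out <- tibble(
    node = igraph::V(ig)$name,
    degree = as.integer(igraph::degree(ig)),
    betweenness = unname(betweenness_centrality(ig)),
    closeness = unname(closeness_centrality(ig)),
    clustering = unname(local_clustering(ig)),
    neighborhood_connectivity = unname(neighborhood_connectivity(ig))
  ) |>
    arrange(desc(.data$degree), .data$node)
  class(out) <- c("microrewire_centrality", class(out))
  out
}
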