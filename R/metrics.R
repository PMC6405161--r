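#' Nodal graph metrics of a weighted connectome
#'
#' Six per-region measures of segregation, integration and centrality:
#' \describe{
#'   \item{degree}{number of nonzero links (weights ignored).}
#'   \item{strength}{sum of incident weights.}
#'   \item{clustering}{fraction of triangles around the node, on the
#'     binarized (nonzero) adjacency; 0 for nodes with fewer than two
#'     neighbours. A weighted variant is available via `weighted_clustering`.}
#'   \item{efficiency}{mean inverse shortest-path distance to all other
#'     nodes; disconnected pairs contribute 0, so an isolated node has
#'     efficiency 0.}
#'   \item{betweenness}{fraction of all shortest paths in the network that
#'     pass through the node (fractional credit for degenerate equal-length
#'     paths).}
#'   \item{closeness}{inverse of the average shortest-path distance to the
#'     other nodes; unreachable pairs are excluded from the average
#'     (per-component convention), and isolated nodes score 0.}
#' }
#' Path-based measures use the distance mapping `d = 1/weight` over
#' positive-weight edges, so stronger connections are shorter.
#'
#' @param c a `connectome`.
#' @param weighted_clustering if `TRUE`, use the weighted local clustering
#'   coefficient (Barrat) instead of the binary triangle fraction.
#' @return data.frame with one row per region: `node`, `label`, `degree`,
#'   `strength`, `clustering`, `efficiency`, `betweenness`, `closeness`.
#' @examples
#' tri <- connectome(matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3, 3))
#' nodal_metrics(tri)  # clustering 1, degree 2, strength 2 everywhere
#' @export
nodal_metrics <- function(c, weighted_clustering = FALSE) {
  stopifnot(inherits(c, "connectome"))
  w <- c$weights
  n <- nrow(w)
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::E(g)$dist <- 1 / igraph::E(g)$weight

  degree <- as.integer(rowSums(w > 0))
  strength <- rowSums(w)

  gb <- igraph::graph_from_adjacency_matrix((w > 0) * 1, mode = "undirected",
                                            diag = FALSE)
  clustering <- if (weighted_clustering) {
    igraph::transitivity(g, type = "barrat", weights = igraph::E(g)$weight,
                         isolates = "zero")
  } else {
    igraph::transitivity(gb, type = "local", isolates = "zero")
  }
  clustering[is.na(clustering)] <- 0

  d <- igraph::distances(g, weights = igraph::E(g)$dist)
  inv <- 1 / d
  diag(inv) <- 0            # exclude self
  inv[is.infinite(d)] <- 0  # disconnected pairs contribute 0
  efficiency <- if (n > 1) rowSums(inv) / (n - 1) else rep(0, n)

  betweenness <- igraph::betweenness(g, weights = igraph::E(g)$dist,
                                     normalized = TRUE)

  closeness <- vapply(seq_len(n), function(i) {
    di <- d[i, -i]
    di <- di[is.finite(di)]
    if (length(di) == 0 || sum(di) == 0) 0 else length(di) / sum(di)
  }, 0.0)

  data.frame(node = seq_len(n), label = c$labels, degree = degree,
             strength = strength, clustering = clustering,
             efficiency = efficiency, betweenness = betweenness,
             closeness = closeness)
}
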