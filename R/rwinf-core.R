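#' Neighbourhood weighted influence (nwI)
#'
#' Sum of a node's incident edge weights — the total contact time it shares
#' with its direct neighbours.  Strong ties raise the chance that the node
#' passes an infection on, so nwI is the local (single-level) influence
#' building block of RWInf.
#'
#' @param graph an undirected weighted igraph graph.
#' @return named numeric vector, one score per node; isolated nodes score 0.
#' @export
neighborhood_weighted_influence <- function(graph) {
  stop_if_unweighted(graph)
  s <- igraph::strength(graph, weights = igraph::E(graph)$weight)
  stats::setNames(as.numeric(s), igraph::V(graph)$name)
}

#' Contact distances from one node
#'
#' Hop-count shortest-path distances ("levels") from `source` to every node.
#' Edge weights play no role here: the level separating two individuals is
#' the number of intermediate contacts, so unit edge lengths are used and
#' unreachable nodes carry `Inf`.
#'
#' @param graph an igraph graph.
#' @param source node name.
#' @return named numeric vector of hop counts (`Inf` if unreachable).
#' @export
contact_distances <- function(graph, source) {
  if (!source %in% igraph::V(graph)$name) {
    stop("unknown source node: ", source, call. = FALSE)
  }
  d <- igraph::distances(graph, v = source, weights = NA)[1L, ]
  stats::setNames(as.numeric(d), igraph::V(graph)$name)
}

#' Single-and-multiple-level influence from precomputed tables
#'
#' Evaluates smlI(v) = sum over u != v of nwI(u) / cd(v, u): each other
#' node's neighbourhood weighted influence, discounted by its contact
#' distance from v.  Unreachable nodes (infinite distance) contribute 0.
#' This table form exists so the score can be computed from published
#' nwI/distance values without the underlying graph.
#'
#' @param nwi named numeric vector of nwI values covering every node in
#'   `distances`.
#' @param distances named numeric vector of contact distances from the focal
#'   node (the focal node itself, at distance 0, is excluded automatically).
#' @return the smlI value (a scalar).
#' @export
smli_from_tables <- function(nwi, distances) {
  others <- names(distances)[distances > 0 & is.finite(distances)]
  missing <- setdiff(others, names(nwi))
  if (length(missing)) {
    stop("nwI table missing nodes: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  sum(nwi[others] / distances[others])
}

#' Single-and-multiple-level influence (smlI) for every node
#'
#' Combines local strength and global reach: nearby high-contact individuals
#' dominate, but every reachable node contributes with weight 1/level.
#'
#' @inheritParams neighborhood_weighted_influence
#' @param distance `"hop"` (default) uses unit edge lengths;
#'   `"weighted-inverse"` uses lengths 1/W so long-contact ties count as
#'   shorter paths (sensitivity analysis only).
#' @return named numeric vector of smlI scores.
#' @export
smli <- function(graph, distance = c("hop", "weighted-inverse")) {
  distance <- match.arg(distance)
  nwi <- neighborhood_weighted_influence(graph)
  d <- shortest_distance_matrix(graph, distance)
  inv <- ifelse(is.finite(d) & d > 0, 1 / d, 0)
  stats::setNames(as.numeric(inv %*% nwi), igraph::V(graph)$name)
}

shortest_distance_matrix <- function(graph, distance) {
  if (distance == "hop") {
    igraph::distances(graph, weights = NA)
  } else {
    stop_if_unweighted(graph)
    igraph::distances(graph, weights = 1 / igraph::E(graph)$weight)
  }
}

#' Per-node triangle counts
#'
#' Number of neighbour pairs of each node that are themselves connected,
#' on the unweighted skeleton of the graph.
#'
#' @param graph an igraph graph.
#' @return named integer vector.
#' @export
triangle_count <- function(graph) {
  stats::setNames(as.integer(igraph::count_triangles(graph)),
                  igraph::V(graph)$name)
}

#' Local density (ld)
#'
#' ld(v) = (triangles(v) + 1) * degree(v).  Degree counts the direct
#' contacts; the triangle term captures whether those contacts also meet
#' each other, which accelerates within-neighbourhood spread.  The +1 keeps
#' triangle-free nodes in play; isolated nodes score 0 via the degree
#' factor.
#'
#' @param graph an igraph graph.
#' @return named numeric vector.
#' @export
local_density <- function(graph) {
  k <- igraph::degree(graph)
  (triangle_count(graph) + 1) * as.numeric(k)
}

#' Real Weighted Influence (RWInf) score
#'
#' RWInf(v) = ld(v) * smlI(v): the product of a node's clustering-aware
#' local size and its distance-discounted global contact influence.  The
#' highest-scoring node is the predicted superspreader.
#'
#' @inheritParams smli
#' @return named numeric vector of RWInf scores.
#' @export
rwinf_scores <- function(graph, distance = c("hop", "weighted-inverse")) {
  local_density(graph) * smli(graph, distance = match.arg(distance))
}

#' Rank nodes by influence score
#'
#' Competition ranking: rank 1 is the largest score, tied scores share the
#' smaller rank, and ties are listed in node-identifier order so output is
#' deterministic.
#'
#' @param scores named numeric vector (node -> score).
#' @return data.frame with columns `node`, `score`, `rank`, sorted by
#'   decreasing score.
#' @export
rank_nodes <- function(scores) {
  if (length(scores) == 0L) stop("empty score table", call. = FALSE)
  if (any(!is.finite(scores))) stop("scores must be finite", call. = FALSE)
  ord <- order(-scores, names(scores))
  s <- scores[ord]
  rnk <- rank(-s, ties.method = "min")
  data.frame(node = names(s), score = as.numeric(s), rank = as.integer(rnk),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Top-k most influential nodes
#'
#' @param scores named numeric vector (node -> score).
#' @param k number of nodes to return, between 1 and the number of nodes.
#' @return character vector of the k top-ranked node names, best first.
#' @export
top_k <- function(scores, k) {
  if (k < 1 || k > length(scores)) {
    stop("k must be between 1 and the number of nodes", call. = FALSE)
  }
  rank_nodes(scores)$node[seq_len(k)]
}

stop_if_unweighted <- function(graph) {
  if (igraph::gsize(graph) > 0 && is.null(igraph::E(graph)$weight)) {
    stop("graph has no 'weight' edge attribute", call. = FALSE)
  }
  invisible(graph)
}
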