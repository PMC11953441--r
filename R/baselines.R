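#' k-shell decomposition with pruning rounds
#'
#' Iterative minimum-degree pruning on the unweighted skeleton.  Nodes are
#' removed in waves: all nodes whose residual degree is at most the current
#' shell value fall in one wave (one pruning round), and removals that drop
#' a neighbour's degree below the shell trigger further rounds at the same
#' shell.  Besides the shell index itself, the round at which each node is
#' removed and the total number of rounds are returned — the ingredients of
#' the k-shell iteration factor used by the HIC index.
#'
#' @param graph an igraph graph (edge weights ignored).
#' @return data.frame with columns `node`, `ks`, `removal_iteration`,
#'   `total_iterations`.
#' @export
kshell_decomposition <- function(graph) {
  peel_shells(as.numeric(igraph::degree(graph)), graph)
}

# Generalized peeling used by both the plain and the weighted k-shell:
# `metric` is a per-node degree-like quantity; `recompute`, if given, maps
# (residual degree, residual strength) -> metric after each removal wave.
peel_shells <- function(metric, graph, recompute = NULL) {
  n <- igraph::vcount(graph)
  nodes <- igraph::V(graph)$name
  if (is.null(nodes)) nodes <- as.character(seq_len(n))
  aw <- adj_with_weights(graph)
  adj <- aw$adj
  wadj <- aw$w
  deg <- as.numeric(igraph::degree(graph))
  str <- as.numeric(igraph::strength(graph))
  alive <- rep(TRUE, n)
  ks <- integer(n); removed_at <- integer(n)
  round_no <- 0L; shell <- 0L
  while (any(alive)) {
    shell <- max(shell, as.integer(min(metric[alive])))
    repeat {
      sel <- which(alive & metric <= shell)
      if (length(sel) == 0L) break
      round_no <- round_no + 1L
      ks[sel] <- shell
      removed_at[sel] <- round_no
      alive[sel] <- FALSE
      for (v in sel) {
        nb <- adj[[v]]
        live <- alive[nb]
        if (any(live)) {
          live_nb <- nb[live]
          deg[live_nb] <- deg[live_nb] - 1
          str[live_nb] <- str[live_nb] - wadj[[v]][live]
        }
      }
      if (!is.null(recompute)) metric[alive] <- recompute(deg, str)[alive]
      else metric <- deg
    }
  }
  data.frame(node = nodes, ks = ks, removal_iteration = removed_at,
             total_iterations = round_no, stringsAsFactors = FALSE)
}

# Neighbour indices and the matching incident edge weights, both built from
# the same edge-list pass so their positions stay aligned.
adj_with_weights <- function(graph) {
  n <- igraph::vcount(graph)
  adj <- replicate(n, integer(0), simplify = FALSE)
  wl <- replicate(n, numeric(0), simplify = FALSE)
  if (igraph::gsize(graph) > 0L) {
    el <- igraph::ends(graph, igraph::E(graph), names = FALSE)
    w <- igraph::E(graph)$weight
    if (is.null(w)) w <- rep(1, nrow(el))
    for (e in seq_len(nrow(el))) {
      a <- el[e, 1L]; b <- el[e, 2L]
      adj[[a]] <- c(adj[[a]], b); wl[[a]] <- c(wl[[a]], w[e])
      adj[[b]] <- c(adj[[b]], a); wl[[b]] <- c(wl[[b]], w[e])
    }
  }
  list(adj = adj, w = wl)
}

#' Weighted k-shell decomposition
#'
#' Assigns each node the degree-and-strength blend
#' k' = \[k^a1 * (sum of incident weights)^b1\]^(1/(a1+b1)) and peels shells
#' on k' exactly as the unweighted decomposition peels on degree, with k'
#' recomputed from the residual graph after every removal wave.  k' is
#' real-valued and is rounded half-up to an integer before comparison with
#' the shell counter; with all weights equal to 1 the index reduces to the
#' plain k-shell.
#'
#' @param graph an undirected weighted igraph graph.
#' @param alpha1,beta1 positive exponents of degree and strength (defaults
#'   1, 1).
#' @param rounding `"nearest"` (half-up, default), `"floor"` or `"ceiling"`.
#' @return named numeric vector of shell indices.
#' @export
weighted_kshell <- function(graph, alpha1 = 1, beta1 = 1,
                            rounding = c("nearest", "floor", "ceiling")) {
  stopifnot(alpha1 > 0, beta1 > 0)
  rounding <- match.arg(rounding)
  rnd <- switch(rounding,
                nearest = function(x) floor(x + 0.5),
                floor = floor,
                ceiling = ceiling)
  kprime <- function(deg, str) {
    x <- ifelse(deg > 0, (deg^alpha1 * str^beta1)^(1 / (alpha1 + beta1)), 0)
    rnd(x)
  }
  res <- peel_shells(
    kprime(as.numeric(igraph::degree(graph)),
           as.numeric(igraph::strength(graph))),
    graph, recompute = kprime)
  stats::setNames(as.numeric(res$ks), res$node)
}

#' Wks: degree-sum weighted degree
#'
#' Ignores any stored durations by construction: each edge is given the
#' synthetic weight k_u + k_v, and the node score blends own degree with the
#' summed synthetic weights of incident edges,
#' k^W(v) = a1 * k(v) + (1 - a1) * sum over neighbours u of (k(v) + k(u)).
#'
#' @param graph an igraph graph (topology only is used).
#' @param alpha1 mixing weight in \[0, 1\] (default 0.5).
#' @return named numeric vector.
#' @export
wks_scores <- function(graph, alpha1 = 0.5) {
  k <- as.numeric(igraph::degree(graph))
  nodes <- igraph::V(graph)$name
  adj <- lapply(igraph::as_adj_list(graph), as.integer)
  sw <- vapply(seq_along(adj), function(i) {
    nb <- adj[[i]]
    if (length(nb) == 0L) 0 else sum(k[i] + k[nb])
  }, numeric(1))
  stats::setNames(alpha1 * k + (1 - alpha1) * sw, nodes)
}

#' ksd^w: k-shell/degree product-weighted neighbourhood score
#'
#' Each edge gets the synthetic weight
#' (a1 * k_u + m1 * ks_u) * (a1 * k_v + m1 * ks_v); a node's score is the
#' sum of those weights over its incident edges.
#'
#' @param graph an igraph graph (topology only is used).
#' @param alpha1,mu1 tunables in \[0, 1\] (defaults 0.5, 0.5).
#' @return named numeric vector.
#' @export
ksd_w_scores <- function(graph, alpha1 = 0.5, mu1 = 0.5) {
  stopifnot(alpha1 >= 0, alpha1 <= 1, mu1 >= 0, mu1 <= 1)
  ks <- kshell_decomposition(graph)$ks
  k <- as.numeric(igraph::degree(graph))
  f <- alpha1 * k + mu1 * ks
  adj <- lapply(igraph::as_adj_list(graph), as.integer)
  sc <- vapply(seq_along(adj), function(i) {
    nb <- adj[[i]]
    if (length(nb) == 0L) 0 else sum(f[i] * f[nb])
  }, numeric(1))
  stats::setNames(sc, igraph::V(graph)$name)
}

#' ngsc: network global structure-based centrality
#'
#' ngsc(v) = sum over neighbours u of
#' (t1 * ks_v + t2 * k_v) + (t1 * ks_u + t2 * k_u).
#'
#' @param graph an igraph graph (topology only is used).
#' @param t1,t2 tunables in \[0, 1\] (defaults 0.5, 0.5).
#' @return named numeric vector.
#' @export
ngsc_scores <- function(graph, t1 = 0.5, t2 = 0.5) {
  stopifnot(t1 >= 0, t1 <= 1, t2 >= 0, t2 <= 1)
  ks <- kshell_decomposition(graph)$ks
  k <- as.numeric(igraph::degree(graph))
  f <- t1 * ks + t2 * k
  adj <- lapply(igraph::as_adj_list(graph), as.integer)
  sc <- vapply(seq_along(adj), function(i) {
    nb <- adj[[i]]
    if (length(nb) == 0L) 0 else sum(f[i] + f[nb])
  }, numeric(1))
  stats::setNames(sc, igraph::V(graph)$name)
}

#' Node H-index
#'
#' Largest h such that the node has at least h neighbours of degree at
#' least h.
#'
#' @param graph an igraph graph.
#' @return named integer vector.
#' @export
h_index <- function(graph) {
  k <- as.numeric(igraph::degree(graph))
  adj <- lapply(igraph::as_adj_list(graph), as.integer)
  h <- vapply(adj, function(nb) {
    if (length(nb) == 0L) return(0L)
    d <- sort(k[nb], decreasing = TRUE)
    as.integer(max(0L, which(d >= seq_along(d))))
  }, integer(1))
  stats::setNames(h, igraph::V(graph)$name)
}

# k-shell iteration factor: ks scaled by how late in the pruning the node
# survived, I_v = ks_v * (1 + n_v / m).  Kept as one small function so an
# alternative refinement is a one-line swap.
kshell_iteration_factor <- function(graph) {
  dec <- kshell_decomposition(graph)
  stats::setNames(dec$ks * (1 + dec$removal_iteration / dec$total_iterations),
                  dec$node)
}

#' HIC: H-index / iteration-factor / clustering composite
#'
#' Each edge gets the weight H_u I_u / (1 + C_u) + H_v I_v / (1 + C_v),
#' where H is the node H-index, I the k-shell iteration factor and C the
#' local clustering coefficient; a node's HIC score is the sum of its
#' incident edge weights.
#'
#' @param graph an igraph graph (topology only is used).
#' @return named numeric vector.
#' @export
hic_scores <- function(graph) {
  H <- as.numeric(h_index(graph))
  I <- as.numeric(kshell_iteration_factor(graph))
  C <- igraph::transitivity(graph, type = "local", isolates = "zero")
  C[is.nan(C)] <- 0
  term <- H * I / (1 + C)
  adj <- lapply(igraph::as_adj_list(graph), as.integer)
  sc <- vapply(seq_along(adj), function(i) {
    nb <- adj[[i]]
    if (length(nb) == 0L) 0 else sum(term[i] + term[nb])
  }, numeric(1))
  stats::setNames(sc, igraph::V(graph)$name)
}

#' Weighted degree centrality
#'
#' Total contact time a node shares with its neighbours — identical to
#' [neighborhood_weighted_influence()] but kept as a named baseline.
#'
#' @param graph an undirected weighted igraph graph.
#' @return named numeric vector.
#' @export
weighted_degree <- function(graph) {
  neighborhood_weighted_influence(graph)
}

weighted_path_lengths <- function(graph, distance_mode) {
  stop_if_unweighted(graph)
  w <- igraph::E(graph)$weight
  if (any(w <= 0)) stop("edge weights must be positive", call. = FALSE)
  switch(distance_mode, inverse_weight = 1 / w, raw_weight = w)
}

#' Weighted betweenness centrality
#'
#' Fraction of weighted shortest paths passing through each node (endpoints
#' excluded).  By default edge lengths are 1/W so that long-contact ties are
#' short paths; `raw_weight` treats durations as costs instead.
#'
#' @param graph an undirected weighted igraph graph.
#' @param distance_mode `"inverse_weight"` (default) or `"raw_weight"`.
#' @return named numeric vector.
#' @export
weighted_betweenness <- function(graph,
                                 distance_mode = c("inverse_weight",
                                                   "raw_weight")) {
  distance_mode <- match.arg(distance_mode)
  len <- weighted_path_lengths(graph, distance_mode)
  b <- igraph::betweenness(graph, weights = len, directed = FALSE)
  stats::setNames(as.numeric(b), igraph::V(graph)$name)
}

#' Weighted closeness centrality
#'
#' Reciprocal of the summed weighted shortest-path distances from a node to
#' every other node, with the same length convention as
#' [weighted_betweenness()].  On a disconnected graph the sum runs over the
#' reachable nodes only, with a warning; isolated nodes score 0.
#'
#' @inheritParams weighted_betweenness
#' @return named numeric vector.
#' @export
weighted_closeness <- function(graph,
                               distance_mode = c("inverse_weight",
                                                 "raw_weight")) {
  distance_mode <- match.arg(distance_mode)
  len <- weighted_path_lengths(graph, distance_mode)
  d <- igraph::distances(graph, weights = len)
  diag(d) <- NA
  if (any(is.infinite(d))) {
    warning("graph is disconnected; closeness computed over reachable nodes",
            call. = FALSE)
  }
  sums <- apply(d, 1L, function(row) sum(row[is.finite(row)]))
  stats::setNames(ifelse(sums > 0, 1 / sums, 0), igraph::V(graph)$name)
}

#' Compute any supported influence index by name
#'
#' Dispatcher used by the evaluation sweep and the command-line tool.
#'
#' @param graph an undirected weighted igraph graph.
#' @param index one of `"rwinf"`, `"wkshell"`, `"wks"`, `"ksdw"`, `"ngsc"`,
#'   `"hic"`, `"wdeg"`, `"wbet"`, `"wclo"`.
#' @param params optional named list of tunables forwarded to the index
#'   (e.g. `alpha1`, `mu1`, `t1`, `t2`, `distance_mode`).
#' @return named numeric vector of scores.
#' @export
compute_index <- function(graph, index, params = list()) {
  fn <- switch(index,
               rwinf = rwinf_scores,
               wkshell = weighted_kshell,
               wks = wks_scores,
               ksdw = ksd_w_scores,
               ngsc = ngsc_scores,
               hic = hic_scores,
               wdeg = weighted_degree,
               wbet = weighted_betweenness,
               wclo = weighted_closeness,
               stop("unknown index: ", index, call. = FALSE))
  args <- c(list(graph), params[intersect(names(params),
                                          names(formals(fn)))])
  do.call(fn, args)
}
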