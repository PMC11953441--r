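#' Epidemic threshold estimate
#'
#' Heterogeneous mean-field threshold beta_th = <k> / <k^2>, with moments
#' taken over the degree sequence of the unweighted skeleton.  Infection
#' probabilities above this value sustain spreading.
#'
#' @param graph an igraph graph with at least one edge.
#' @return the threshold (a scalar in (0, 1]).
#' @export
epidemic_threshold <- function(graph) {
  if (igraph::gsize(graph) == 0L) {
    stop("epidemic threshold is undefined on an edgeless graph", call. = FALSE)
  }
  k <- as.numeric(igraph::degree(graph))
  mean(k) / mean(k^2)
}

#' SIR configuration
#'
#' @param beta per-contact infection probability per step, in \[0, 1\].
#' @param lam recovery probability per step, in (0, 1\] (default 1: each
#'   node is infectious for exactly one step).
#' @param runs independent repetitions per seed node (default 1000).
#' @param seed root RNG seed; per-(source, run) substreams are derived from
#'   it so results are independent of evaluation order.
#' @param transmission `"unweighted"` (default): every infected-susceptible
#'   contact transmits with probability `beta`.  `"weighted"`: a contact of
#'   weight W transmits with probability 1 - (1 - beta)^(W / delta),
#'   treating the weight as W/delta independent exposure windows.
#' @param delta exposure-window length in seconds for the weighted mode
#'   (default 20).
#' @return a list of class `sir_config`.
#' @export
sir_config <- function(beta, lam = 1, runs = 1000, seed = 1L,
                       transmission = c("unweighted", "weighted"),
                       delta = 20) {
  stopifnot(beta >= 0, beta <= 1, lam > 0, lam <= 1, runs >= 1, delta > 0)
  structure(list(beta = beta, lam = lam, runs = as.integer(runs),
                 seed = as.integer(seed),
                 transmission = match.arg(transmission), delta = delta),
            class = "sir_config")
}

# Per-edge transmission probabilities under a config.
sir_edge_probs <- function(graph, config) {
  if (config$transmission == "unweighted") return(NULL)
  stop_if_unweighted(graph)
  w <- igraph::E(graph)$weight
  1 - (1 - config$beta)^(w / config$delta)
}

# One synchronous SIR trajectory on a precomputed adjacency structure.
# Infected nodes expose each susceptible neighbour once per step, then
# recover with probability lam; nodes infected this step transmit from the
# next step on.  Returns the final recovered count (source included).
sir_step_loop <- function(adj, padj, n, src, beta, lam) {
  state <- integer(n)          # 0 susceptible, 1 infected, 2 recovered
  state[src] <- 1L
  infected <- src
  while (length(infected)) {
    targets <- unlist(adj[infected], use.names = FALSE)
    if (is.null(padj)) {
      probs <- rep.int(beta, length(targets))
    } else {
      probs <- unlist(padj[infected], use.names = FALSE)
    }
    open <- state[targets] == 0L
    targets <- targets[open]
    newly <- integer(0)
    if (length(targets)) {
      hit <- targets[stats::runif(length(targets)) < probs[open]]
      newly <- unique(hit)
    }
    recovers <- stats::runif(length(infected)) < lam
    state[infected[recovers]] <- 2L
    state[newly] <- 1L
    infected <- c(infected[!recovers], newly)
  }
  sum(state == 2L)
}

# 32-bit-safe derived seed for the (beta index, source index) substream.
derive_seed <- function(seed, i, j = 0L) {
  (as.numeric(seed) + 104729 * i + 7919 * j) %% 2147483647
}

#' Single SIR run
#'
#' One synchronous susceptible-infected-recovered trajectory seeded at
#' `source`, using the current RNG state.  Ends when no infected nodes
#' remain; the final recovered count (which includes the source) is the
#' realized spread.
#'
#' @param graph an igraph graph.
#' @param source seed node name.
#' @param config a [sir_config()].
#' @return integer final recovered count, in \[1, |V|\].
#' @export
sir_run <- function(graph, source, config) {
  src <- match(source, igraph::V(graph)$name)
  if (is.na(src)) stop("unknown source node: ", source, call. = FALSE)
  aw <- adj_with_weights(graph)
  padj <- sir_prob_adj(graph, aw, config)
  sir_step_loop(aw$adj, padj, igraph::vcount(graph), src,
                config$beta, config$lam)
}

sir_prob_adj <- function(graph, aw, config) {
  if (config$transmission == "unweighted") return(NULL)
  lapply(aw$w, function(w) 1 - (1 - config$beta)^(w / config$delta))
}

#' Mean spreading capability of one seed node
#'
#' Averages the final recovered count over `config$runs` independent SIR
#' trajectories started at `source`.  The RNG substream is derived from
#' (config$seed, source), so the result does not depend on which other
#' nodes were simulated before.
#'
#' @inheritParams sir_run
#' @param keep_runs if TRUE, attach the per-run final counts.
#' @return list with `node`, `mean_spread` and optionally `per_run`.
#' @export
sir_influence <- function(graph, source, config, keep_runs = FALSE) {
  src <- match(source, igraph::V(graph)$name)
  if (is.na(src)) stop("unknown source node: ", source, call. = FALSE)
  aw <- adj_with_weights(graph)
  padj <- sir_prob_adj(graph, aw, config)
  counts <- sir_source_counts(aw$adj, padj, igraph::vcount(graph), src, config)
  out <- list(node = source, mean_spread = mean(counts))
  if (keep_runs) out$per_run <- counts
  out
}

sir_source_counts <- function(adj, padj, n, src, config) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(derive_seed(config$seed, src))
  vapply(seq_len(config$runs), function(r) {
    sir_step_loop(adj, padj, n, src, config$beta, config$lam)
  }, numeric(1))
}

#' SIR ground-truth score table
#'
#' Runs [sir_influence()] for every node and assembles the mean spreads into
#' a named score vector — the simulation ground truth that the structural
#' indices are evaluated against.
#'
#' @param graph an igraph graph.
#' @param config a [sir_config()].
#' @return named numeric vector of mean spreads.
#' @export
sir_ground_truth <- function(graph, config) {
  n <- igraph::vcount(graph)
  aw <- adj_with_weights(graph)
  padj <- sir_prob_adj(graph, aw, config)
  means <- vapply(seq_len(n), function(src) {
    mean(sir_source_counts(aw$adj, padj, n, src, config))
  }, numeric(1))
  stats::setNames(means, igraph::V(graph)$name)
}
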