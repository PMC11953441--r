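#' Generate a synthetic timestamped contact stream with ground truth
#'
#' Emulates a proximity-sensor deployment: for each pair of individuals,
#' interaction sessions arrive one after another with geometric inter-session
#' gaps and geometric session lengths (in units of the sampling tick
#' `interval`), and every active tick emits one contact record.  Session
#' starts sit on the tick grid and inter-session gaps are at least two
#' ticks, so sessionizing the emitted records with `max_gap = interval`
#' recovers the generated sessions exactly — the generator records those
#' sessions and the per-pair total durations as ground truth.
#'
#' @param n_individuals number of individuals (nodes).
#' @param t_horizon observation window in seconds (default 8 hours).
#' @param contact_rate expected number of new sessions per pair per hour
#'   (default 0.2).
#' @param mean_session_ticks mean session length in ticks (default 3, i.e.
#'   60 s at the default interval).
#' @param interval sampling tick in seconds (default 20).
#' @param seed RNG seed.
#' @return list with `events` (data.frame `u`, `v`, `t` in time order),
#'   `sessions` (data.frame `u`, `v`, `st`, `et`, `duration`) and `weights`
#'   (data.frame `u`, `v`, `weight` of total contact seconds per pair).
#' @export
generate_contact_stream <- function(n_individuals, t_horizon = 8 * 3600,
                                    contact_rate = 0.2,
                                    mean_session_ticks = 3,
                                    interval = 20, seed = 1L) {
  stopifnot(n_individuals >= 2, t_horizon > 0, contact_rate >= 0,
            mean_session_ticks >= 1, interval > 0)
  set.seed(seed)
  ids <- sprintf("n%03d", seq_len(n_individuals))
  max_tick <- floor(t_horizon / interval)
  # geometric gap calibrated so sessions arrive at ~contact_rate per hour
  mean_gap_ticks <- if (contact_rate > 0) {
    max(2, 3600 / (contact_rate * interval))
  } else Inf
  p_gap <- if (is.finite(mean_gap_ticks)) 1 / (mean_gap_ticks - 1) else 0
  p_len <- 1 / mean_session_ticks

  ev_u <- character(0); ev_v <- character(0); ev_t <- integer(0)
  se <- list()
  if (contact_rate > 0) {
    for (i in seq_len(n_individuals - 1L)) {
      for (j in seq((i + 1L), n_individuals)) {
        cur <- 0L  # tick index of the last emitted tick for this pair
        repeat {
          gap <- 2L + stats::rgeom(1L, p_gap)       # >= 2 ticks between sessions
          len <- 1L + stats::rgeom(1L, p_len)       # session length in ticks
          first <- cur + gap
          last <- first + len - 1L
          if (last > max_tick) break
          ticks <- seq.int(first, last) * interval
          ev_u <- c(ev_u, rep(ids[i], len))
          ev_v <- c(ev_v, rep(ids[j], len))
          ev_t <- c(ev_t, as.integer(ticks))
          se[[length(se) + 1L]] <- data.frame(
            u = ids[i], v = ids[j],
            st = (first - 1L) * interval, et = last * interval,
            stringsAsFactors = FALSE)
          cur <- last
        }
      }
    }
  }
  events <- data.frame(u = ev_u, v = ev_v, t = ev_t, stringsAsFactors = FALSE)
  events <- events[order(events$t, events$u, events$v), , drop = FALSE]
  rownames(events) <- NULL
  sessions <- if (length(se)) do.call(rbind, se) else {
    data.frame(u = character(), v = character(), st = numeric(),
               et = numeric(), stringsAsFactors = FALSE)
  }
  sessions$duration <- sessions$et - sessions$st
  weights <- if (nrow(sessions)) {
    agg <- stats::aggregate(duration ~ u + v, data = sessions, FUN = sum)
    names(agg)[3L] <- "weight"
    agg[order(agg$u, agg$v), , drop = FALSE]
  } else {
    data.frame(u = character(), v = character(), weight = numeric(),
               stringsAsFactors = FALSE)
  }
  rownames(weights) <- NULL
  list(events = events, sessions = sessions, weights = weights)
}

#' Format a contact stream as tij lines
#'
#' @param events data.frame with columns `u`, `v`, `t`.
#' @return character vector of `t i j` lines.
#' @export
format_tij <- function(events) {
  sprintf("%d %s %s", events$t, events$u, events$v)
}

#' Generate a random weighted graph
#'
#' Topology from a named random-graph model, edge weights drawn from a
#' heavy-tailed lognormal (mimicking empirical contact-duration
#' distributions) or fixed at 1.
#'
#' @param model `"erdos_renyi"`, `"barabasi_albert"` or `"ring"`.
#' @param n number of nodes (at least 2).
#' @param model_param edge probability for Erdos-Renyi (default 0.1), edges
#'   per new node for Barabasi-Albert (default 2); ignored for the ring.
#' @param weight_dist `"lognormal"` (meanlog 4, sdlog 1, seconds) or
#'   `"unit"`.
#' @param seed RNG seed.
#' @return an undirected weighted igraph graph with character node names.
#' @export
generate_weighted_graph <- function(model = c("erdos_renyi",
                                              "barabasi_albert", "ring"),
                                    n, model_param = NULL,
                                    weight_dist = c("lognormal", "unit"),
                                    seed = 1L) {
  model <- match.arg(model)
  weight_dist <- match.arg(weight_dist)
  stopifnot(n >= 2)
  set.seed(seed)
  g <- switch(model,
              erdos_renyi = igraph::sample_gnp(
                n, if (is.null(model_param)) 0.1 else model_param),
              barabasi_albert = igraph::sample_pa(
                n, m = if (is.null(model_param)) 2 else model_param,
                directed = FALSE),
              ring = igraph::make_ring(n))
  igraph::V(g)$name <- sprintf("n%03d", seq_len(n))
  m <- igraph::gsize(g)
  igraph::E(g)$weight <- switch(weight_dist,
                                lognormal = stats::rlnorm(m, 4, 1),
                                unit = rep(1, m))
  g
}

#' Worked-example fixture for the RWInf score
#'
#' The published toy computation: 26 nodes A..Z with stated neighbourhood
#' weighted influence values, the contact distances from node A, node A's
#' degree (5) and triangle count (5), and the expected smlI, ld and RWInf
#' values for A (expected values carry the source's 3-decimal rounding).
#'
#' @return list with `nwi`, `dist_from_A`, `k_A`, `tri_A`,
#'   `expected_smli_A`, `expected_ld_A`, `expected_rwinf_A`.
#' @export
worked_example_fixture <- function() {
  nwi <- c(A = 16, B = 20, C = 20, D = 35, E = 9, F = 11, G = 1, H = 2,
           I = 17, J = 5, K = 18, L = 7, M = 3, N = 15, O = 5, P = 5,
           Q = 5, R = 8, S = 4, T = 13, U = 6, V = 2, W = 13, X = 1,
           Y = 2, Z = 7)
  dist_from_A <- c(B = 1, C = 1, D = 1, E = 1, F = 1,
                   G = 2, H = 2, I = 2, K = 2, N = 2, Q = 2, R = 2,
                   V = 2, W = 2,
                   J = 3, L = 3, M = 3, O = 3, P = 3, S = 3, T = 3,
                   X = 3, Y = 3, Z = 3,
                   U = 4)
  list(nwi = nwi, dist_from_A = dist_from_A, k_A = 5, tri_A = 5,
       expected_smli_A = 154.333, expected_ld_A = 30,
       expected_rwinf_A = 4629.99)
}
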