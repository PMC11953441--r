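#' Kendall's tau-b between two score tables
#'
#' Tie-adjusted rank correlation between two per-node score vectors aligned
#' by node name.  Both SIR mean spreads and structural indices carry ties,
#' so the tau-b variant is used throughout.
#'
#' @param x,y named numeric vectors over identical node sets.
#' @return tau in \[-1, 1\] (NA if either vector is constant).
#' @export
kendall_tau <- function(x, y) {
  if (!setequal(names(x), names(y)) || length(x) != length(y)) {
    stop("score tables cover different node sets", call. = FALSE)
  }
  suppressWarnings(stats::cor(x, y[names(x)], method = "kendall"))
}

#' Beta sweep of Kendall's tau against SIR ground truth
#'
#' For each infection probability on the grid, simulates the SIR ground
#' truth and correlates it with every supplied index score table.  The
#' default grid follows the threshold-anchored rule
#' beta_i = beta_th + 0.01 * i, i = 1..iter; an absolute grid can be given
#' instead.  Grid values above 1 are dropped with a warning.  The summary
#' sigma(tau) is the per-index mean of tau over the grid.
#'
#' @param graph an undirected weighted igraph graph.
#' @param score_tables named list of score vectors (one per index); the
#'   index scores do not depend on beta, only the ground truth does.
#' @param iter number of grid points (default 15).
#' @param step grid increment in beta (default 0.01).
#' @param runs SIR repetitions per node per beta (default 1000).
#' @param lam recovery probability (default 1).
#' @param seed root seed; each beta gets a derived substream.
#' @param beta_grid optional explicit vector of beta values overriding the
#'   threshold-anchored rule.
#' @return list with `beta_grid`, `tau` (matrix, index x beta) and
#'   `sigma_tau` (named vector).
#' @export
sir_tau_sweep <- function(graph, score_tables, iter = 15, step = 0.01,
                          runs = 1000, lam = 1, seed = 1L, beta_grid = NULL) {
  stopifnot(iter >= 1)
  if (is.null(beta_grid)) {
    beta_grid <- epidemic_threshold(graph) + step * seq_len(iter)
  }
  if (any(beta_grid > 1)) {
    warning("dropping beta values above 1 from the sweep", call. = FALSE)
    beta_grid <- beta_grid[beta_grid <= 1]
  }
  tau <- matrix(NA_real_, nrow = length(score_tables),
                ncol = length(beta_grid),
                dimnames = list(names(score_tables), NULL))
  for (i in seq_along(beta_grid)) {
    cfg <- sir_config(beta = beta_grid[i], lam = lam, runs = runs,
                      seed = derive_seed(seed, 0L, i))
    truth <- sir_ground_truth(graph, cfg)
    for (nm in names(score_tables)) {
      tau[nm, i] <- kendall_tau(score_tables[[nm]], truth)
    }
  }
  list(beta_grid = beta_grid, tau = tau, sigma_tau = rowMeans(tau))
}

#' Monotonicity of a ranking
#'
#' M(I) = \[1 - sum_i V_i (V_i - 1) / (V (V - 1))\]^2 over tie-group sizes
#' V_i: 1 when every node gets a unique rank, 0 when all scores are tied.
#'
#' @param scores named numeric vector with at least two nodes.
#' @return M in \[0, 1\].
#' @export
monotonicity <- function(scores) {
  V <- length(scores)
  if (V < 2L) stop("monotonicity needs at least two nodes", call. = FALSE)
  sizes <- table(scores)
  (1 - sum(sizes * (sizes - 1)) / (V * (V - 1)))^2
}

#' Improvement percentage of a reference index over a comparator
#'
#' eta = (tau_ref - tau_cmp) / |tau_cmp| * 100, with eta = 0 when the
#' comparator's tau is exactly 0.  Positive eta means the reference index
#' tracks the SIR ground truth better than the comparator.
#'
#' @param tau_ref tau of the reference (proposed) index.
#' @param tau_cmp tau of the comparison index.
#' @return eta in percent (NA if either tau is NA, e.g. for a constant
#'   score vector whose tau-b is undefined).
#' @export
improvement_pct <- function(tau_ref, tau_cmp) {
  if (is.na(tau_ref) || is.na(tau_cmp)) return(NA_real_)
  stopifnot(abs(tau_ref) <= 1, abs(tau_cmp) <= 1)
  if (tau_cmp == 0) return(0)
  (tau_ref - tau_cmp) / abs(tau_cmp) * 100
}

#' Structural summary of a contact graph
#'
#' Node/edge counts, mean degree and the epidemic threshold on the full
#' graph; diameter, mean shortest-path length and mean local clustering on
#' the largest connected component (with a warning if the graph is
#' disconnected).
#'
#' @param graph an igraph graph.
#' @return list with `n_nodes`, `n_edges`, `mean_degree`, `diameter`,
#'   `mean_path`, `mean_clustering`, `beta_th`.
#' @export
graph_summary <- function(graph) {
  comp <- igraph::components(graph)
  g <- graph
  if (comp$no > 1L) {
    warning("graph is disconnected; path statistics use the largest component",
            call. = FALSE)
    g <- igraph::induced_subgraph(
      graph, which(comp$membership == which.max(comp$csize)))
  }
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  cc[is.nan(cc)] <- 0
  list(
    n_nodes = igraph::vcount(graph),
    n_edges = igraph::gsize(graph),
    mean_degree = mean(as.numeric(igraph::degree(graph))),
    diameter = igraph::diameter(g, weights = NA),
    mean_path = igraph::mean_distance(g, weights = NA),
    mean_clustering = mean(cc),
    beta_th = epidemic_threshold(graph)
  )
}

#' Full index-versus-SIR evaluation
#'
#' Computes every requested index on the graph, sweeps the SIR ground truth
#' over the beta grid, and reports per-beta tau, sigma(tau), ranking
#' monotonicity and the per-beta improvement percentage of the reference
#' index over every other index.
#'
#' @param graph an undirected weighted igraph graph.
#' @param indices character vector of index names understood by
#'   [compute_index()] (default: all nine).
#' @param reference index whose improvement is reported (default
#'   `"rwinf"`; must be in `indices`).
#' @param params named list of tunables forwarded to the indices.
#' @inheritParams sir_tau_sweep
#' @return list of class `rwinf_eval` with `beta_grid`, `tau`, `sigma_tau`,
#'   `monotonicity`, `improvement` (data.frame reference/comparator/beta/eta),
#'   `seed`.
#' @export
evaluate_all <- function(graph,
                         indices = c("rwinf", "wkshell", "wks", "ksdw",
                                     "ngsc", "hic", "wdeg", "wbet", "wclo"),
                         reference = "rwinf", params = list(),
                         iter = 15, step = 0.01, runs = 1000, lam = 1,
                         seed = 1L, beta_grid = NULL) {
  tables <- lapply(indices, function(ix) compute_index(graph, ix, params))
  names(tables) <- indices
  sweep <- sir_tau_sweep(graph, tables, iter = iter, step = step,
                         runs = runs, lam = lam, seed = seed,
                         beta_grid = beta_grid)
  mono <- vapply(tables, monotonicity, numeric(1))
  improvement <- NULL
  if (reference %in% indices && length(indices) > 1L) {
    comparators <- setdiff(indices, reference)
    improvement <- do.call(rbind, lapply(comparators, function(cmp) {
      data.frame(reference = reference, comparator = cmp,
                 beta = sweep$beta_grid,
                 eta = vapply(seq_along(sweep$beta_grid), function(i) {
                   improvement_pct(sweep$tau[reference, i],
                                   sweep$tau[cmp, i])
                 }, numeric(1)),
                 stringsAsFactors = FALSE)
    }))
  }
  structure(list(beta_grid = sweep$beta_grid, tau = sweep$tau,
                 sigma_tau = sweep$sigma_tau, monotonicity = mono,
                 improvement = improvement, seed = seed),
            class = "rwinf_eval")
}

#' Write an evaluation report as JSON
#'
#' @param report an `rwinf_eval` object from [evaluate_all()].
#' @param path output file path.
#' @export
write_eval_report <- function(report, path) {
  obj <- list(
    seed = report$seed,
    beta_grid = report$beta_grid,
    tau = as.data.frame(t(report$tau)),
    sigma_tau = as.list(report$sigma_tau),
    monotonicity = as.list(report$monotonicity),
    improvement = report$improvement
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
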