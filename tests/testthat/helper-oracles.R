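# Independent brute-force oracles used across the test files.  They work
# from the dense weighted adjacency matrix and plain loops, deliberately
# avoiding the package's code paths (and igraph where the package uses it).

adj_matrix <- function(g) {
  w <- if (igraph::gsize(g) > 0 && !is.null(igraph::E(g)$weight)) {
    igraph::E(g)$weight
  } else NULL
  m <- igraph::as_adjacency_matrix(g, attr = if (is.null(w)) NULL else "weight",
                                   sparse = FALSE)
  storage.mode(m) <- "double"
  m
}

random_test_graph <- function(n, p = 0.4, seed = 1, weights = TRUE) {
  set.seed(seed)
  m <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (stats::runif(1) < p) {
        m[i, j] <- m[j, i] <- if (weights) round(stats::runif(1, 1, 50)) else 1
      }
    }
  }
  rownames(m) <- colnames(m) <- sprintf("v%02d", seq_len(n))
  g <- igraph::graph_from_adjacency_matrix(m, mode = "undirected",
                                           weighted = TRUE)
  list(graph = g, m = m[igraph::V(g)$name, igraph::V(g)$name, drop = FALSE])
}

oracle_nwi <- function(m) rowSums(m)

# Floyd-Warshall over arbitrary edge lengths (0 entries mean no edge).
oracle_fw <- function(lengths) {
  n <- nrow(lengths)
  d <- matrix(Inf, n, n, dimnames = dimnames(lengths))
  diag(d) <- 0
  d[lengths > 0] <- lengths[lengths > 0]
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

oracle_hop_dist <- function(m) oracle_fw((m > 0) * 1)

oracle_smli <- function(m) {
  nwi <- oracle_nwi(m)
  d <- oracle_hop_dist(m)
  n <- nrow(m)
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (j in seq_len(n)) {
      if (i != j && is.finite(d[i, j])) acc <- acc + nwi[j] / d[i, j]
    }
    out[i] <- acc
  }
  names(out) <- rownames(m)
  out
}

oracle_triangles <- function(m) {
  a <- m > 0
  n <- nrow(m)
  tri <- integer(n)
  for (i in seq_len(n)) {
    cnt <- 0L
    nb <- which(a[i, ])
    if (length(nb) >= 2) {
      for (x in seq_len(length(nb) - 1)) {
        for (y in seq(x + 1, length(nb))) {
          if (a[nb[x], nb[y]]) cnt <- cnt + 1L
        }
      }
    }
    tri[i] <- cnt
  }
  names(tri) <- rownames(m)
  tri
}

oracle_hindex <- function(m) {
  a <- m > 0
  k <- rowSums(a)
  out <- integer(nrow(m))
  for (i in seq_len(nrow(m))) {
    nbdeg <- k[a[i, ]]
    h <- 0L
    for (cand in 0:length(nbdeg)) {
      if (sum(nbdeg >= cand) >= cand) h <- cand
    }
    out[i] <- h
  }
  names(out) <- rownames(m)
  out
}

oracle_kendall <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      a <- sign(x[i] - x[j]); b <- sign(y[i] - y[j])
      if (a == 0 && b == 0) next
      else if (a == 0) tx <- tx + 1
      else if (b == 0) ty <- ty + 1
      else if (a == b) conc <- conc + 1
      else disc <- disc + 1
    }
  }
  (conc - disc) / sqrt((conc + disc + tx) * (conc + disc + ty))
}

# All simple paths between s and t; returns list(len = min length,
# count = number of shortest paths, through = per-node counts of shortest
# paths passing through it as an interior node).
oracle_paths <- function(lengths, s, t) {
  n <- nrow(lengths)
  best <- Inf; count <- 0; through <- numeric(n)
  visit <- function(v, used, len, interior) {
    if (v == t) {
      if (len < best - 1e-12) {
        best <<- len; count <<- 1; through <<- numeric(n)
        through[interior] <<- 1
      } else if (abs(len - best) < 1e-12) {
        count <<- count + 1
        through[interior] <<- through[interior] + 1
      }
      return(invisible())
    }
    for (u in which(lengths[v, ] > 0)) {
      if (!used[u]) {
        used[u] <- TRUE
        visit(u, used, len + lengths[v, u],
              if (v == s) interior else c(interior, v))
        used[u] <- FALSE
      }
    }
  }
  used <- rep(FALSE, n); used[s] <- TRUE
  visit(s, used, 0, integer(0))
  list(len = best, count = count, through = through)
}

oracle_weighted_betweenness <- function(m) {
  lengths <- ifelse(m > 0, 1 / m, 0)
  n <- nrow(m)
  b <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in seq(s + 1, n)) {
      res <- oracle_paths(lengths, s, t)
      if (is.finite(res$len) && res$count > 0) {
        b <- b + res$through / res$count
      }
    }
  }
  names(b) <- rownames(m)
  b
}

oracle_weighted_closeness <- function(m) {
  d <- oracle_fw(ifelse(m > 0, 1 / m, 0))
  diag(d) <- NA
  sums <- apply(d, 1, function(r) sum(r[is.finite(r)]))
  out <- ifelse(sums > 0, 1 / sums, 0)
  names(out) <- rownames(m)
  out
}

expect_named_equal <- function(got, want, tol = 1e-9) {
  expect_equal(got[names(want)], want, tolerance = tol,
               ignore_attr = FALSE)
}
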