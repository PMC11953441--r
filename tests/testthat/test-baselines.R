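path3 <- function() {
  g <- igraph::make_graph(~ A-B, B-C)
  igraph::E(g)$weight <- 1
  g
}

test_that("k-shell decomposition matches known shells and coreness", {
  p <- path3()
  expect_equal(kshell_decomposition(p)$ks, c(1L, 1L, 1L))

  k4 <- igraph::make_full_graph(4)
  igraph::V(k4)$name <- LETTERS[1:4]
  dec <- kshell_decomposition(k4)
  expect_equal(dec$ks, rep(3L, 4))
  expect_equal(dec$removal_iteration, rep(1L, 4))
  expect_equal(dec$total_iterations, rep(1L, 4))

  for (seed in 1:20) {
    g <- random_test_graph(sample(5:12, 1), p = 0.35, seed = seed)$graph
    dec <- kshell_decomposition(g)
    expect_equal(dec$ks,
                 unname(igraph::coreness(g)[dec$node]))
    # shell never exceeds degree
    expect_true(all(dec$ks <= igraph::degree(g)[dec$node]))
  }
})

test_that("weighted k-shell blends degree and strength and reduces at W=1", {
  # closed form of the blended degree before peeling
  g <- igraph::make_star(5, mode = "undirected")
  igraph::V(g)$name <- LETTERS[1:5]
  igraph::E(g)$weight <- c(2, 2, 2, 3)   # center: k=4, sum W=9 -> k'=6
  kp <- (4^1 * 9^1)^(1 / 2)
  expect_equal(kp, 6)

  for (seed in 1:10) {
    g <- random_test_graph(sample(5:10, 1), seed = seed)$graph
    gu <- g
    igraph::E(gu)$weight <- 1
    expect_equal(weighted_kshell(gu),
                 setNames(as.numeric(igraph::coreness(gu)),
                          igraph::V(gu)$name))
  }
})

test_that("Wks expands degree-derived weights by hand", {
  p <- path3()
  s <- wks_scores(p)
  expect_equal(s[["B"]], 0.5 * 2 + 0.5 * ((2 + 1) + (2 + 1)))
  expect_equal(s[["A"]], 0.5 * 1 + 0.5 * (1 + 2))

  for (seed in 1:10) {
    tg <- random_test_graph(sample(4:9, 1), seed = seed + 100)
    m <- tg$m; g <- tg$graph
    k <- rowSums(m > 0)
    want <- vapply(seq_len(nrow(m)), function(i) {
      nb <- which(m[i, ] > 0)
      0.5 * k[i] + 0.5 * sum(k[i] + k[nb])
    }, numeric(1))
    expect_equal(unname(wks_scores(g)[rownames(m)]), want)
  }
})

test_that("ksd^w products match the hand expansion and an oracle", {
  p <- path3()
  s <- ksd_w_scores(p)
  expect_equal(s[["B"]], 3.0)
  expect_equal(s[["A"]], 1.5)

  for (seed in 1:10) {
    tg <- random_test_graph(sample(4:9, 1), seed = seed + 200)
    g <- tg$graph; m <- tg$m
    k <- rowSums(m > 0)
    ks <- igraph::coreness(g)[rownames(m)]
    f <- 0.5 * k + 0.5 * ks
    want <- vapply(seq_len(nrow(m)), function(i) {
      sum(f[i] * f[which(m[i, ] > 0)])
    }, numeric(1))
    expect_equal(unname(ksd_w_scores(g)[rownames(m)]), want)
  }
})

test_that("ngsc sums blended shell/degree terms over neighbours", {
  tri <- igraph::make_full_graph(3)
  igraph::V(tri)$name <- LETTERS[1:3]
  expect_equal(unname(ngsc_scores(tri)), rep(8, 3))

  iso <- igraph::add_vertices(tri, 1, name = "Z")
  expect_equal(ngsc_scores(iso)[["Z"]], 0)

  for (seed in 1:10) {
    tg <- random_test_graph(sample(4:9, 1), seed = seed + 300)
    g <- tg$graph; m <- tg$m
    k <- rowSums(m > 0)
    ks <- igraph::coreness(g)[rownames(m)]
    f <- 0.5 * ks + 0.5 * k
    want <- vapply(seq_len(nrow(m)), function(i) {
      nb <- which(m[i, ] > 0)
      if (!length(nb)) 0 else sum(f[i] + f[nb])
    }, numeric(1))
    expect_equal(unname(ngsc_scores(g)[rownames(m)]), want)
  }
})

test_that("H-index matches closed forms and a brute-force scan", {
  tri <- igraph::make_full_graph(3)
  igraph::V(tri)$name <- LETTERS[1:3]
  expect_equal(unname(h_index(tri)), rep(2L, 3))

  star <- igraph::make_star(5, mode = "undirected")
  igraph::V(star)$name <- LETTERS[1:5]
  expect_equal(h_index(star)[["A"]], 1L)

  for (seed in 1:15) {
    tg <- random_test_graph(sample(4:10, 1), seed = seed + 400)
    hx <- h_index(tg$graph)
    expect_equal(hx[rownames(tg$m)], oracle_hindex(tg$m),
                 ignore_attr = TRUE)
    expect_true(all(hx <= igraph::degree(tg$graph)[names(hx)]))
  }
})

test_that("HIC composes H-index, iteration factor and clustering", {
  tri <- igraph::make_full_graph(3)
  igraph::V(tri)$name <- LETTERS[1:3]
  # H = 2, C = 1, one pruning round so I = 2 * (1 + 1/1) = 4,
  # each edge weighs 8/2 + 8/2 = 8, two incident edges -> 16
  expect_equal(unname(hic_scores(tri)), rep(16, 3))

  for (seed in 1:10) {
    tg <- random_test_graph(sample(4:9, 1), seed = seed + 500)
    g <- tg$graph; m <- tg$m
    dec <- kshell_decomposition(g)
    I <- setNames(dec$ks * (1 + dec$removal_iteration / dec$total_iterations),
                  dec$node)[rownames(m)]
    H <- oracle_hindex(m)
    tri_cnt <- oracle_triangles(m)
    k <- rowSums(m > 0)
    C <- ifelse(k >= 2, 2 * tri_cnt / (k * (k - 1)), 0)
    term <- H * I / (1 + C)
    want <- vapply(seq_len(nrow(m)), function(i) {
      nb <- which(m[i, ] > 0)
      if (!length(nb)) 0 else sum(term[i] + term[nb])
    }, numeric(1))
    expect_equal(unname(hic_scores(g)[rownames(m)]), want)
  }
})

test_that("weighted degree equals nwI on the same graph", {
  star <- igraph::make_star(4, mode = "undirected")
  igraph::V(star)$name <- LETTERS[1:4]
  igraph::E(star)$weight <- c(2, 3, 4)
  wd <- weighted_degree(star)
  expect_equal(wd[["A"]], 9)
  expect_equal(wd[["B"]], 2)

  tg <- random_test_graph(10, seed = 600)
  expect_equal(weighted_degree(tg$graph),
               neighborhood_weighted_influence(tg$graph))
})

test_that("weighted betweenness uses 1/W lengths and matches path oracle", {
  p <- path3()
  igraph::E(p)$weight <- c(5, 2)
  expect_equal(unname(weighted_betweenness(p)), c(0, 1, 0))

  k4 <- igraph::make_full_graph(4)
  igraph::V(k4)$name <- LETTERS[1:4]
  igraph::E(k4)$weight <- 3
  expect_equal(unname(weighted_betweenness(k4)), rep(0, 4))

  for (seed in 1:12) {
    tg <- random_test_graph(sample(4:8, 1), seed = seed + 700)
    expect_equal(weighted_betweenness(tg$graph)[rownames(tg$m)],
                 oracle_weighted_betweenness(tg$m),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("weighted closeness inverts summed 1/W path lengths", {
  tri <- igraph::make_full_graph(3)
  igraph::V(tri)$name <- LETTERS[1:3]
  igraph::E(tri)$weight <- 2
  expect_equal(unname(weighted_closeness(tri)), rep(1, 3))

  p <- path3()
  expect_equal(weighted_closeness(p)[["B"]], 0.5)

  for (seed in 1:12) {
    tg <- random_test_graph(sample(4:8, 1), seed = seed + 800)
    got <- suppressWarnings(weighted_closeness(tg$graph))
    expect_equal(got[rownames(tg$m)], oracle_weighted_closeness(tg$m),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("structural indices ignore edge-weight rescaling", {
  tg <- random_test_graph(10, seed = 900)
  g <- tg$graph
  g2 <- g
  igraph::E(g2)$weight <- igraph::E(g)$weight * 37.5
  for (ix in c("wks", "ksdw", "ngsc", "hic")) {
    expect_equal(compute_index(g2, ix), compute_index(g, ix))
  }
  # duration-driven indices do move
  expect_equal(compute_index(g2, "wdeg"), 37.5 * compute_index(g, "wdeg"))
})

test_that("with unit weights the weighted centralities reduce to unweighted", {
  tg <- random_test_graph(9, seed = 950, weights = FALSE)
  g <- tg$graph
  expect_equal(unname(weighted_degree(g)),
               as.numeric(igraph::degree(g)))
  expect_equal(unname(weighted_betweenness(g)),
               as.numeric(igraph::betweenness(g, weights = NA)))
})

test_that("compute_index rejects unknown names and forwards params", {
  tg <- random_test_graph(6, seed = 999)
  expect_error(compute_index(tg$graph, "nosuch"), "unknown index")
  expect_equal(compute_index(tg$graph, "ksdw", list(alpha1 = 1, mu1 = 0)),
               ksd_w_scores(tg$graph, alpha1 = 1, mu1 = 0))
})
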