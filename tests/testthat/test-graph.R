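make_toy_graph <- function(M = 6, seed = 1, df_range = c(20, 120), q = 0.05) {
  set.seed(seed)
  R <- matrix(0, M, M)
  R[upper.tri(R)] <- runif(M * (M - 1) / 2, -0.6, 0.8)
  R <- R + t(R); diag(R) <- 1
  dfs <- runif(M, df_range[1], df_range[2])
  build_probabilistic_graph(R, edge_df_matrix(dfs), q = q, node_df = dfs)
}

test_that("zero correlations give an empty graph; input validation works", {
  R <- diag(4)
  g <- build_probabilistic_graph(R, 100)
  expect_equal(g$density, 0)
  expect_identical(sum(g$edges$significant), 0L)
  expect_true(all(g$edges$node_i < g$edges$node_j))  # no self-edges, undirected
  bad <- R; bad[1, 2] <- 0.5
  expect_error(build_probabilistic_graph(bad, 100), "symmetric")
})

test_that("the significant edge count equals the BH decision on edge P values", {
  # a toy where exactly three edges pass the FDR threshold
  R <- diag(4)
  R[1, 2] <- R[2, 1] <- 0.9
  R[1, 3] <- R[3, 1] <- 0.85
  R[2, 3] <- R[3, 2] <- 0.8
  R[3, 4] <- R[4, 3] <- 0.2
  g <- build_probabilistic_graph(R, 60, q = 0.05, cn_mode = "harmonic")
  ref <- brute_bh(g$edges$p, 0.05, harmonic = TRUE)
  expect_identical(sum(g$edges$significant), as.integer(ref$n_sig))
  expect_identical(sum(g$edges$significant), 3L)
  expect_equal(g$density, 3 / 6)
})

test_that("df heterogeneity reorders edges: top-P can differ from top-r", {
  R <- diag(4)
  R[1, 2] <- R[2, 1] <- 0.8   # strongest r, but low df
  R[3, 4] <- R[4, 3] <- 0.6
  dfs <- c(5, 100, 100, 100)
  g <- build_probabilistic_graph(R, edge_df_matrix(dfs))
  top_p <- g$edges[1, c("node_i", "node_j")]
  top_r <- g$edges[which.max(abs(g$edges$r)), c("node_i", "node_j")]
  expect_equal(unlist(top_p), c(node_i = 3, node_j = 4), ignore_attr = TRUE)
  expect_false(identical(top_p, top_r))
})

test_that("with constant df the P order equals the |r| order", {
  g <- make_toy_graph(8, seed = 2)
  R <- diag(8); R[upper.tri(R)] <- runif(28, -0.5, 0.9)
  R <- R + t(R) - diag(diag(R)); diag(R) <- 1
  gc <- build_probabilistic_graph(R, 80)
  expect_identical(order(gc$edges$p), order(-abs(gc$edges$r)))
})

test_that("edge order is non-decreasing in P and significant edges form a prefix", {
  g <- make_toy_graph(10, seed = 3, q = 0.3)
  expect_true(!is.unsorted(g$edges$p))
  sig <- g$edges$significant
  if (any(sig)) expect_true(all(which(sig) == seq_len(sum(sig))))
})

test_that("binary and weighted variants share topology and differ only in weight", {
  R <- diag(4); R[1, 2] <- R[2, 1] <- 0.9; R[3, 4] <- R[4, 3] <- -0.7
  gw <- build_probabilistic_graph(R, 50, weighting = "weighted")
  gb <- build_probabilistic_graph(R, 50, weighting = "binary")
  expect_identical(gw$edges$significant, gb$edges$significant)
  expect_identical(gw$edges[c("node_i", "node_j")], gb$edges[c("node_i", "node_j")])
  expect_equal(gw$edges$weight, gw$edges$r)
  expect_true(all(gb$edges$weight == 1))
  # negative correlations survive 2-tailed testing with negative weights
  expect_true(any(gw$edges$weight < 0 & gw$edges$significant))
  gp <- build_probabilistic_graph(R, 50, positive_only = TRUE)
  expect_true(all(gp$edges$r > 0))
})

test_that("incremental clustering curve matches the exhaustive triangle oracle", {
  g <- make_toy_graph(20, seed = 4)
  curve <- edges_by_p_curve(g, metric = "clustering")
  e <- g$edges[!is.na(g$edges$p), ]
  for (k in c(1, 5, 20, 60, nrow(e))) {
    ref <- brute_clustering(as.matrix(e[seq_len(k), c("node_i", "node_j")]), 20)
    expect_equal(curve$metric[k], ref, tolerance = 1e-12)
  }
  expect_true(!is.unsorted(curve$density))
  expect_true(!is.unsorted(curve$max_p))
})

test_that("triangle and star toys give clustering 1 and 0", {
  R3 <- diag(3); R3[upper.tri(R3)] <- 0.9; R3 <- R3 + t(R3) - diag(diag(R3)); diag(R3) <- 1
  g3 <- build_probabilistic_graph(R3, 100)
  cv3 <- edges_by_p_curve(g3)
  expect_equal(cv3$metric[3], 1)
  Rs <- diag(5); Rs[1, 2:5] <- Rs[2:5, 1] <- 0.9
  gs <- build_probabilistic_graph(Rs, 100)
  cvs <- edges_by_p_curve(gs)
  expect_true(all(cvs$metric[1:4] == 0))
})

test_that("maximum density at FDR counts exactly the BH-significant set", {
  g <- make_toy_graph(8, seed = 5, q = 0.05)
  expect_equal(max_density_at_fdr(g), g$density)
  d10 <- max_density_at_fdr(g, q = 0.2)
  ref <- brute_bh(g$edges$p, 0.2, harmonic = TRUE)
  expect_equal(d10, ref$n_sig / 28)
  # all significant -> density 1; none -> 0
  Rhi <- matrix(0.95, 3, 3); diag(Rhi) <- 1
  expect_equal(build_probabilistic_graph(Rhi, 200, cn_mode = "unit")$density, 1)
  expect_equal(build_probabilistic_graph(diag(3), 200)$density, 0)
})

test_that("subject matching uses the common comparison window", {
  g1 <- make_toy_graph(10, seed = 6)
  g2 <- make_toy_graph(10, seed = 7)
  c1 <- edges_by_p_curve(g1)
  c2 <- edges_by_p_curve(g2)
  m <- match_subjects(list(a = c1, b = c2), mode = "by_density")
  expect_equal(m$window, min(max(c1$density), max(c2$density)))
  expect_identical(dim(m$values), c(50L, 2L))
  # identical subjects give identical aligned curves
  mi <- match_subjects(list(a = c1, b = c1))
  expect_equal(mi$values[, 1], mi$values[, 2])
  mp <- match_subjects(list(a = c1, b = c2), mode = "by_p")
  expect_equal(mp$window, min(max(c1$max_p), max(c2$max_p)))
  # disjoint windows produce an explicit empty-overlap report
  c_lo <- c1[1:2, ]; class(c_lo) <- class(c1)
  c_hi <- c2[c2$density > max(c_lo$density), ]; class(c_hi) <- class(c2)
  me <- match_subjects(list(a = c_lo, b = c_hi))
  expect_true(is.na(me$window))
  expect_identical(nrow(me$values), 0L)
})

test_that("graphs export to GraphML with matching edge counts", {
  g <- make_toy_graph(8, seed = 8, q = 0.3)
  path <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(g, path)
  gg <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::ecount(gg), sum(g$edges$significant), ignore_attr = TRUE)
  expect_equal(igraph::vcount(gg), 8, ignore_attr = TRUE)
})
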