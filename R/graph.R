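# Probabilistically thresholded brain graphs: edges are ranked and added
# in order of increasing P value (df-corrected), the graph is cut at a
# BH-FDR-adjusted P threshold, and topology summaries are computed along
# the P-ordered addition curve.

#' Build a probabilistically thresholded graph
#'
#' Five steps: (1) edge connectivity `r`; (2) edge df (pairwise-minimum
#' nodal df, supplied as a matrix); (3) df-corrected Fisher r-to-Z; (4)
#' 2-tailed Normal P values; (5) BH-FDR thresholding at level `q` over all
#' `(M^2 - M)/2` candidate edges. All edges and their P values are
#' retained (sorted ascending by P) so that incremental addition curves
#' can be computed later. Ties in P break by larger `|r|`, then
#' lexicographic node-pair order.
#'
#' @param r_matrix Symmetric correlation matrix (unit diagonal ignored).
#' @param df_matrix Symmetric matrix of edge df (e.g. [edge_df_matrix()]
#'   of nodal df), or a single number used for every edge.
#' @param q FDR level (default 0.05).
#' @param cn_mode `"harmonic"` (default) or `"unit"`.
#' @param weighting `"weighted"` (default; edge weight = `r`) or
#'   `"binary"` (unit weights). Topology is identical.
#' @param tails 1 or 2 (default 2; negative correlations can then form
#'   negatively weighted edges).
#' @param positive_only Drop edges with `r <= 0` before testing (default
#'   `FALSE`).
#' @param node_df Optional vector of nodal df stored on the node table.
#' @return An object of class `brain_graph`: list with `edges` (data
#'   frame: `node_i`, `node_j`, `r`, `df`, `z`, `p`, `weight`,
#'   `significant`, sorted by P ascending), `n_nodes`, `density`
#'   (significant-edge density), `fdr`, `weighting`, `tie_break`
#'   description, `node_df`.
#' @export
build_probabilistic_graph <- function(r_matrix, df_matrix, q = 0.05,
                                      cn_mode = c("harmonic", "unit"),
                                      weighting = c("weighted", "binary"),
                                      tails = 2, positive_only = FALSE,
                                      node_df = NULL) {
  cn_mode <- match.arg(cn_mode)
  weighting <- match.arg(weighting)
  r_matrix <- as.matrix(r_matrix)
  M <- nrow(r_matrix)
  if (M < 2 || ncol(r_matrix) != M) stop("r_matrix must be square with M >= 2")
  if (max(abs(r_matrix - t(r_matrix)), na.rm = TRUE) > 1e-10)
    stop("r_matrix must be symmetric")
  if (length(df_matrix) == 1) df_matrix <- matrix(df_matrix, M, M)
  df_matrix <- as.matrix(df_matrix)
  if (!all(dim(df_matrix) == M))
    stop("df_matrix dimensions must match r_matrix")
  if (max(abs(df_matrix - t(df_matrix)), na.rm = TRUE) > 1e-10)
    stop("df_matrix must be symmetric")

  ut <- which(upper.tri(r_matrix), arr.ind = TRUE)
  edges <- data.frame(node_i = ut[, 1], node_j = ut[, 2],
                      r = r_matrix[ut], df = df_matrix[ut])
  if (positive_only) edges <- edges[!is.na(edges$r) & edges$r > 0, ]
  usable <- !is.na(edges$r) & abs(edges$r) < 1
  edges$z <- NA_real_
  edges$z[usable] <- fisher_z(edges$r[usable], edges$df[usable])
  edges$p <- NA_real_
  edges$p[usable] <- z_to_p(edges$z[usable], tails)
  edges$weight <- if (weighting == "weighted") edges$r else 1

  test <- !is.na(edges$p)
  fdr <- bh_fdr(edges$p[test], q = q, cn_mode = cn_mode)
  edges$significant <- FALSE
  edges$significant[test] <- fdr$significant

  ord <- order(edges$p, -abs(edges$r), edges$node_i, edges$node_j,
               na.last = TRUE)
  edges <- edges[ord, ]
  rownames(edges) <- NULL
  n_possible <- M * (M - 1) / 2
  structure(list(edges = edges, n_nodes = M,
                 density = sum(edges$significant) / n_possible,
                 fdr = fdr, weighting = weighting,
                 tie_break = "p asc, |r| desc, node pair lexicographic",
                 node_df = node_df),
            class = "brain_graph")
}

#' @export
print.brain_graph <- function(x, ...) {
  cat(sprintf("brain_graph: %d nodes, %d/%d significant edges (density %.4f, q = %g, c(N) %s)\n",
              x$n_nodes, sum(x$edges$significant), nrow(x$edges),
              x$density, x$fdr$q, x$fdr$cn_mode))
  invisible(x)
}

# mean local clustering coefficient; nodes of degree < 2 contribute 0
.clustering_coefficient <- function(edge_idx, M) {
  if (nrow(edge_idx) == 0) return(0)
  g <- igraph::graph_from_edgelist(as.matrix(edge_idx), directed = FALSE)
  if (igraph::vcount(g) < M) g <- igraph::add_vertices(g, M - igraph::vcount(g))
  lc <- igraph::transitivity(g, type = "local", isolates = "zero")
  mean(lc)
}

#' Incremental edge-addition curve
#'
#' Ranks all edges by P value and adds them one at a time, smallest P
#' first (ties broken as recorded in the graph), recording after each
#' addition the connection density, the maximum edge P so far, and a
#' topology metric: the mean local clustering coefficient (nodes of
#' degree < 2 contribute 0) or the density itself.
#'
#' @param graph A `brain_graph`.
#' @param metric `"clustering"` (default) or `"density"`.
#' @param max_edges Stop after this many additions (default all edges with
#'   defined P).
#' @return Data frame of class `edge_curve`: `step`, `density`, `max_p`,
#'   `metric` value per addition.
#' @export
edges_by_p_curve <- function(graph, metric = c("clustering", "density"),
                             max_edges = NULL) {
  metric <- match.arg(metric)
  stopifnot(inherits(graph, "brain_graph"))
  e <- graph$edges[!is.na(graph$edges$p), , drop = FALSE]
  if (nrow(e) == 0) stop("graph has no testable edges")
  if (!is.null(max_edges)) e <- e[seq_len(min(max_edges, nrow(e))), ]
  M <- graph$n_nodes
  n_possible <- M * (M - 1) / 2
  vals <- numeric(nrow(e))
  if (metric == "density") {
    vals <- seq_len(nrow(e)) / n_possible
  } else {
    adj <- matrix(FALSE, M, M)
    deg <- integer(M)
    tri <- numeric(M)   # triangles through each node
    for (k in seq_len(nrow(e))) {
      i <- e$node_i[k]; j <- e$node_j[k]
      common <- which(adj[i, ] & adj[j, ])
      tri[i] <- tri[i] + length(common)
      tri[j] <- tri[j] + length(common)
      tri[common] <- tri[common] + 1
      adj[i, j] <- adj[j, i] <- TRUE
      deg[i] <- deg[i] + 1L; deg[j] <- deg[j] + 1L
      denom <- deg * (deg - 1) / 2
      lc <- ifelse(deg >= 2, tri / denom, 0)
      vals[k] <- mean(lc)
    }
  }
  out <- data.frame(step = seq_len(nrow(e)),
                    density = seq_len(nrow(e)) / n_possible,
                    max_p = cummax(e$p),
                    metric = vals)
  attr(out, "metric_name") <- metric
  class(out) <- c("edge_curve", "data.frame")
  out
}

#' Maximum connection density at an FDR level
#'
#' The density reached after adding exactly the BH-significant edge set at
#' level `q`: the maximum interpretable density of the network.
#'
#' @param graph A `brain_graph`.
#' @param q FDR level; default the level the graph was built at (reuses
#'   the stored decision; any other level re-runs BH on the stored P
#'   values).
#' @return Density in `[0, 1]`.
#' @export
max_density_at_fdr <- function(graph, q = NULL) {
  stopifnot(inherits(graph, "brain_graph"))
  n_possible <- graph$n_nodes * (graph$n_nodes - 1) / 2
  if (is.null(q) || identical(q, graph$fdr$q)) return(graph$density)
  p <- graph$edges$p[!is.na(graph$edges$p)]
  if (length(p) == 0) return(0)
  bh_fdr(p, q = q, cn_mode = graph$fdr$cn_mode)$n_significant / n_possible
}

#' Align edge-addition curves across subjects
#'
#' For group comparison, subjects' metric-vs-density (or metric-vs-max-P)
#' curves are step functions; they are evaluated on a common grid bounded
#' by the smallest maximum density (or max P) across subjects — the
#' "comparison window" — using previous-step interpolation.
#'
#' @param curves Named list of `edge_curve` data frames (>= 2).
#' @param mode `"by_density"` (default) or `"by_p"`.
#' @param n_grid Number of grid points (default 50).
#' @return List of class `matched_curves`: `grid`, `values` (matrix,
#'   grid x subjects), `mode`, `window` (upper bound). If the comparison
#'   window is empty an explicit empty-overlap report is returned
#'   (`window = NA`, zero-row values).
#' @export
match_subjects <- function(curves, mode = c("by_density", "by_p"), n_grid = 50) {
  mode <- match.arg(mode)
  if (length(curves) < 2) stop("need >= 2 subjects")
  xcol <- if (mode == "by_density") "density" else "max_p"
  upper <- min(vapply(curves, function(cv) max(cv[[xcol]]), numeric(1)))
  lower <- max(vapply(curves, function(cv) min(cv[[xcol]]), numeric(1)))
  if (upper < lower) {
    return(structure(list(grid = numeric(0),
                          values = matrix(numeric(0), 0, length(curves),
                                          dimnames = list(NULL, names(curves))),
                          mode = mode, window = NA_real_),
                     class = "matched_curves"))
  }
  grid <- seq(lower, upper, length.out = n_grid)
  vals <- vapply(curves, function(cv) {
    stats::approx(cv[[xcol]], cv$metric, xout = grid, method = "constant",
                  f = 0, ties = list("ordered", max), rule = 2)$y
  }, numeric(n_grid))
  colnames(vals) <- names(curves)
  structure(list(grid = grid, values = vals, mode = mode, window = upper),
            class = "matched_curves")
}

#' Export a brain graph as GraphML
#'
#' Writes the significant edge set (weights included) via igraph.
#'
#' @param graph A `brain_graph`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(graph, path) {
  stopifnot(inherits(graph, "brain_graph"))
  e <- graph$edges[graph$edges$significant, , drop = FALSE]
  g <- igraph::make_empty_graph(n = graph$n_nodes, directed = FALSE)
  if (nrow(e) > 0) {
    g <- igraph::add_edges(g, rbind(e$node_i, e$node_j))
    igraph::E(g)$weight <- e$weight
    igraph::E(g)$p <- e$p
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
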