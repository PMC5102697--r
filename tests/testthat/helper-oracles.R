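# Independent brute-force oracles, deliberately written without reusing
# the package's pyramid code paths.

# Direct-convolution MODWT: explicit circular convolution with upsampled
# filters, following the closed-form filter cascade definition.
brute_modwt <- function(x, g, h, J) {
  N <- length(x)
  gt <- g / sqrt(2)
  ht <- h / sqrt(2)
  upsample <- function(f, j) {
    # insert 2^(j-1) - 1 zeros between taps
    if (j == 1) return(f)
    out <- rep(0, (length(f) - 1) * 2^(j - 1) + 1)
    out[seq(1, length(out), by = 2^(j - 1))] <- f
    out
  }
  circ_conv <- function(v, f) {
    sapply(seq_len(N) - 1, function(t) {
      s <- 0
      for (l in seq_along(f) - 1) s <- s + f[l + 1] * v[((t - l) %% N) + 1]
      s
    })
  }
  W <- matrix(0, N, J)
  V <- x
  for (j in seq_len(J)) {
    W[, j] <- circ_conv(V, upsample(ht, j))
    V <- circ_conv(V, upsample(gt, j))
  }
  list(W = W, V = V)
}

# Brute-force BH step-up: test every candidate threshold explicitly.
brute_bh <- function(p, q, harmonic) {
  n <- length(p)
  cN <- if (harmonic) sum(1 / seq_len(n)) else 1
  ps <- sort(p)
  passing <- which(sapply(seq_len(n), function(i) ps[i] <= i * q / (n * cN)))
  if (length(passing) == 0) return(list(threshold = NA_real_, n_sig = 0L))
  thr <- ps[max(passing)]
  list(threshold = thr, n_sig = sum(p <= thr))
}

# Exhaustive triangle-count clustering coefficient (degree < 2 -> 0).
brute_clustering <- function(edges, M) {
  adj <- matrix(FALSE, M, M)
  for (k in seq_len(nrow(edges))) {
    adj[edges[k, 1], edges[k, 2]] <- TRUE
    adj[edges[k, 2], edges[k, 1]] <- TRUE
  }
  lc <- sapply(seq_len(M), function(i) {
    nb <- which(adj[i, ])
    k <- length(nb)
    if (k < 2) return(0)
    tri <- 0
    for (a in seq_len(k - 1)) for (b in (a + 1):k)
      if (adj[nb[a], nb[b]]) tri <- tri + 1
    tri / (k * (k - 1) / 2)
  })
  mean(lc)
}

# small helper: a run with one planted network and an artifact slab
toy_run <- function(seed = 1, N = 128, grid = c(4, 4, 4), amplitude = 8) {
  spec <- synthetic_spec(
    grid = grid, N = N, seed = seed,
    networks = list(list(voxels = cbind(1:3, 1, 1), rho = 0.6)),
    artifacts = if (amplitude > 0)
      list(list(onset = round(N / 2), duration = 16, amplitude = amplitude,
                axis = 3, slope = 1)) else NULL)
  generate_run(spec)
}
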