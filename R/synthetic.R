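# Synthetic 4D runs with known ground truth: colored (AR(1)) baseline
# noise, planted inter-regional correlations via shared latent signals,
# transient ramped artifact bursts with a spatial amplitude gradient, and
# a co-timed motion trace. Everything is deterministic given the seed.

#' Specification for a synthetic run
#'
#' @param grid 3D grid dimensions (default `c(8, 8, 8)`).
#' @param N Time points (default 256).
#' @param TR Sampling interval in seconds (default 2).
#' @param ar_phi AR(1) coefficient of the baseline noise (default 0.4, an
#'   fMRI-like positive autocorrelation).
#' @param networks List of planted networks, each a list with `voxels`
#'   (matrix of 1-based voxel indices, one row per member) and `rho`
#'   (target pairwise correlation between members, `|rho| < 1`).
#' @param artifacts List of artifact events, each a list with `onset`
#'   (sample), `duration` (samples), `amplitude` (in baseline-sd units),
#'   `axis` (1-3, spatial gradient axis) and `slope` (0-1; 0 = spatially
#'   uniform, 1 = amplitude ramps from 0 at the low end of the axis to
#'   twice the nominal at the high end).
#' @param seed RNG seed.
#' @return List of class `synthetic_spec`.
#' @export
synthetic_spec <- function(grid = c(8, 8, 8), N = 256, TR = 2, ar_phi = 0.4,
                           networks = NULL, artifacts = NULL, seed = 1) {
  if (length(grid) != 3 || any(grid < 1)) stop("grid must be 3 positive dimensions")
  for (nw in networks) {
    if (is.null(nw$voxels) || is.null(nw$rho)) stop("each network needs voxels and rho")
    if (abs(nw$rho) >= 1) stop("network correlation targets must satisfy |rho| < 1")
  }
  for (ev in artifacts) {
    if (ev$onset < 1 || ev$onset + ev$duration - 1 > N)
      stop("artifact event outside the run")
  }
  structure(list(grid = grid, N = N, TR = TR, ar_phi = ar_phi,
                 networks = networks, artifacts = artifacts, seed = seed),
            class = "synthetic_spec")
}

# unit-variance AR(1) series, one column per draw
.ar1_matrix <- function(N, P, phi) {
  innov <- matrix(stats::rnorm(N * P, sd = sqrt(1 - phi^2)), N, P)
  innov[1, ] <- stats::rnorm(P)
  if (phi == 0) return(innov)
  apply(innov, 2, function(e) stats::filter(e, phi, method = "recursive"))
}

#' Generate a synthetic run
#'
#' Voxel series are unit-variance AR(1) baselines; members of a planted
#' network share a latent AR(1) signal mixed in as
#' `sqrt(rho) * latent + sqrt(1 - rho) * noise`, so any two members
#' correlate at `rho`. Artifact bursts are additive ramped (triangular
#' envelope) events spanning multiple frequencies, with amplitude scaled
#' along the stated spatial gradient and random polarity per voxel. The
#' motion trace is low-amplitude noise plus displacement steps co-timed
#' with the artifact onsets.
#'
#' @param spec A `synthetic_spec`.
#' @return List of class `synthetic_run`: `volume` (4D array), `clean`
#'   (artifact-free 4D array), `motion` (N x 6 matrix: mm, mm, mm,
#'   degrees x3), `ground_truth` (list: `networks`, `planted_edges` data
#'   frame of member voxel linear-index pairs, `artifact_cells` logical
#'   voxel x time matrix), `spec`.
#' @export
generate_run <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(spec$seed)

  dims <- spec$grid
  nvox <- prod(dims)
  N <- spec$N
  X <- .ar1_matrix(N, nvox, spec$ar_phi)   # time x voxels

  lin_of <- function(ijk) ijk[, 1] + (ijk[, 2] - 1) * dims[1] +
    (ijk[, 3] - 1) * dims[1] * dims[2]

  planted_edges <- NULL
  for (nw in spec$networks) {
    vox <- as.matrix(nw$voxels)
    lin <- lin_of(vox)
    latent <- .ar1_matrix(N, 1, spec$ar_phi)[, 1]
    X[, lin] <- sqrt(nw$rho) * latent +
      sqrt(1 - nw$rho) * X[, lin, drop = FALSE]
    if (length(lin) >= 2) {
      pairs <- t(utils::combn(sort(lin), 2))
      planted_edges <- rbind(planted_edges,
                             data.frame(voxel_a = pairs[, 1], voxel_b = pairs[, 2],
                                        rho = nw$rho))
    }
  }
  clean <- X

  coords <- arrayInd(seq_len(nvox), dims)
  artifact_cells <- matrix(FALSE, nvox, N)
  for (ev in spec$artifacts) {
    tt <- ev$onset:(ev$onset + ev$duration - 1)
    # ramped envelope with sample-to-sample jitter, so the burst carries
    # both low- and high-frequency non-stationary content
    env <- 1 - abs(seq(-1, 1, length.out = length(tt)))
    profile <- env * (1 + 0.5 * stats::rnorm(length(tt)))
    coord_norm <- if (dims[ev$axis] > 1) {
      (coords[, ev$axis] - 1) / (dims[ev$axis] - 1)
    } else rep(0.5, nvox)
    mult <- (1 - ev$slope) + ev$slope * 2 * coord_norm
    polarity <- sample(c(-1, 1), nvox, replace = TRUE)
    X[tt, ] <- X[tt, ] + outer(profile, ev$amplitude * mult * polarity)
    artifact_cells[mult > 0.05, tt] <- TRUE
  }

  # head position follows the burst envelope (displacement co-timed with
  # the artifact), on top of low-amplitude jitter
  motion <- matrix(stats::rnorm(N * 6, sd = c(rep(0.02, 3), rep(0.01, 3))[rep(1:6, each = N)]),
                   N, 6)
  for (ev in spec$artifacts) {
    tt <- ev$onset:(ev$onset + ev$duration - 1)
    env <- 1 - abs(seq(-1, 1, length.out = length(tt)))
    motion[tt, 1] <- motion[tt, 1] + 0.05 * ev$amplitude * env
    motion[tt, 5] <- motion[tt, 5] + 0.03 * ev$amplitude * env
  }

  structure(list(volume = array(t(X), c(dims, N)),
                 clean = array(t(clean), c(dims, N)),
                 motion = motion,
                 ground_truth = list(networks = spec$networks,
                                     planted_edges = planted_edges,
                                     artifact_cells = artifact_cells),
                 spec = spec),
            class = "synthetic_run")
}

#' Generate a balanced contiguous parcellation
#'
#' Partitions a 3D grid into `n_regions` contiguous integer-labelled
#' blocks with no region more than twice the size of any other. When
#' `n_regions` factorises into axis-aligned chunk counts the regions are
#' rectangular blocks (e.g. an 8x8x8 grid with 8 regions gives eight
#' 64-voxel cubes); otherwise contiguous runs of the flattened grid of
#' near-equal size are used.
#'
#' @param grid 3D grid dimensions.
#' @param n_regions Number of regions (<= number of voxels).
#' @return 3D integer array of region labels `1..n_regions`.
#' @export
generate_parcellation <- function(grid, n_regions) {
  if (length(grid) != 3) stop("grid must be 3 dimensions")
  nvox <- prod(grid)
  if (n_regions > nvox) stop("more regions than voxels: infeasible balance")
  if (n_regions < 1) stop("need >= 1 region")

  chunk_sizes <- function(len, k) {
    base <- len %/% k
    extra <- len %% k
    rep(c(base + 1L, base), c(extra, k - extra))
  }
  # try axis-aligned factorisations a*b*c = n_regions
  best <- NULL
  for (a in 1:n_regions) {
    if (n_regions %% a != 0 || a > grid[1]) next
    rem <- n_regions / a
    for (b in 1:rem) {
      if (rem %% b != 0 || b > grid[2]) next
      cc <- rem / b
      if (cc > grid[3]) next
      sz <- list(chunk_sizes(grid[1], a), chunk_sizes(grid[2], b),
                 chunk_sizes(grid[3], cc))
      region_sizes <- as.vector(outer(outer(sz[[1]], sz[[2]]), sz[[3]]))
      ratio <- max(region_sizes) / min(region_sizes)
      # prefer balanced sizes, then cube-like (low-aspect) blocks
      edges <- grid / c(a, b, cc)
      aspect <- max(edges) / min(edges)
      if (ratio <= 2 &&
          (is.null(best) || ratio < best$ratio - 1e-12 ||
           (abs(ratio - best$ratio) < 1e-12 && aspect < best$aspect - 1e-12))) {
        best <- list(counts = c(a, b, cc), sizes = sz, ratio = ratio,
                     aspect = aspect)
      }
    }
  }
  labels <- array(0L, grid)
  if (!is.null(best)) {
    bx <- rep(seq_along(best$sizes[[1]]), best$sizes[[1]])
    by <- rep(seq_along(best$sizes[[2]]), best$sizes[[2]])
    bz <- rep(seq_along(best$sizes[[3]]), best$sizes[[3]])
    coords <- arrayInd(seq_len(nvox), grid)
    labels[] <- bx[coords[, 1]] +
      (by[coords[, 2]] - 1L) * best$counts[1] +
      (bz[coords[, 3]] - 1L) * best$counts[1] * best$counts[2]
  } else {
    sizes <- chunk_sizes(nvox, n_regions)
    labels[] <- rep(seq_len(n_regions), sizes)
  }
  labels
}
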