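# Wavelet despiking: separate detail coefficients into disjoint "signal"
# and "noise" sets, reconstruct a denoised series from the signal set, and
# keep the binary mask for effective-df accounting.
#
# The noise detector shipped here is a documented stand-in: a robust
# (MAD-based) amplitude threshold per scale whose flags are extended along
# contiguous same-sign runs of coefficients ("chains") and optionally
# propagated to the next-coarser scale within the filter support.
# Externally produced binary noise masks are fully supported via
# coefficient_mask(), so all downstream df and inference machinery is
# independent of the detector.

#' Construct a coefficient mask
#'
#' A binary labelling of every MODWT detail coefficient: `TRUE` marks a
#' noise coefficient (member of the artifact set), `FALSE` a signal
#' coefficient. The two sets are disjoint and additive in the wavelet
#' domain: the sum of their reconstructions is the original series.
#'
#' @param mask Logical (or 0/1) matrix, effective coefficient count x `J`.
#' @param d The `modwt` decomposition the mask refers to (dimension check
#'   and metadata source).
#' @return An object of class `coef_mask` carrying the matrix plus
#'   `N`, `J`, `boundary` and `filter_name` attributes.
#' @export
coefficient_mask <- function(mask, d) {
  stopifnot(inherits(d, "modwt"))
  mask <- as.matrix(mask)
  if (!all(dim(mask) == dim(d$W)))
    stop("mask dimensions do not match the decomposition's coefficient matrix")
  storage.mode(mask) <- "logical"
  structure(mask, N = d$N, J = d$J, boundary = d$boundary,
            filter_name = d$filter$name, L = d$filter$L,
            class = c("coef_mask", "matrix"))
}

#' Per-scale noise-coefficient counts of a mask
#'
#' Counts flagged coefficients per scale restricted to the time-index
#' ranges used for df estimation: for the reflection boundary only the
#' first `N` indices (those aligned with the original series) are counted
#' (`N_phi_j`); for the periodic boundary only non-boundary indices
#' `t >= L_j - 1` are counted (`M_phi_j`), where
#' `L_j = (2^j - 1)(L - 1) + 1` is the level-`j` filter width.
#'
#' @param m A `coef_mask`.
#' @return Integer vector of length `J`.
#' @export
noise_counts <- function(m) {
  stopifnot(inherits(m, "coef_mask"))
  N <- attr(m, "N"); J <- attr(m, "J"); L <- attr(m, "L")
  if (attr(m, "boundary") == "reflection") {
    counts <- colSums(m[seq_len(N), , drop = FALSE])
  } else {
    counts <- vapply(seq_len(J), function(j) {
      Lj <- (2^j - 1) * (L - 1) + 1
      nb <- min(Lj - 1, N)      # boundary coefficients occupy t = 0..Lj-2
      if (nb >= N) 0L else sum(m[(nb + 1):N, j])
    }, numeric(1))
  }
  as.integer(counts)
}

# extend flagged indices to the full contiguous run of same-sign
# coefficients containing each flag
.extend_chains <- function(flag, w) {
  if (!any(flag)) return(flag)
  sgn <- sign(w)
  sgn[sgn == 0] <- 1
  run <- cumsum(c(1L, diff(sgn) != 0))   # id of each same-sign run
  flagged_runs <- unique(run[flag])
  run %in% flagged_runs
}

#' Detect noise coefficients
#'
#' Stand-in artifact detector: per scale, coefficients whose magnitude
#' exceeds `threshold_k` robust standard deviations (1.4826 x the median
#' absolute deviation of that scale's coefficients) are flagged, flags are
#' extended to the contiguous run of same-sign coefficients containing
#' them (maxima/minima "chains"), and, if `chain_across_scales`, a flag at
#' scale `j` propagates to scale `j + 1` coefficients within the
#' level-`(j+1)` filter support of the same time index. Deterministic for
#' fixed input. Approximation coefficients are never flagged.
#'
#' @param d A `modwt` decomposition.
#' @param threshold_k Positive threshold in robust-sd units (default 5).
#' @param chain_across_scales Propagate flags to the next-coarser scale
#'   (default `TRUE`)?
#' @return A `coef_mask`.
#' @export
detect_noise_coefficients <- function(d, threshold_k = 5, chain_across_scales = TRUE) {
  stopifnot(inherits(d, "modwt"))
  if (!is.numeric(threshold_k) || threshold_k <= 0)
    stop("threshold_k must be > 0")
  Neff <- nrow(d$W)
  mask <- matrix(FALSE, Neff, d$J)
  for (j in seq_len(d$J)) {
    w <- d$W[, j]
    sigma <- stats::mad(w)           # 1.4826 * MAD
    if (sigma > 0) {
      flag <- abs(w) > threshold_k * sigma
      mask[, j] <- .extend_chains(flag, w)
    }
  }
  if (chain_across_scales && d$J > 1) {
    L <- d$filter$L
    for (j in seq_len(d$J - 1)) {
      idx <- which(mask[, j])
      if (length(idx) == 0) next
      halfwidth <- 2^j * (L - 1)     # level-(j+1) filter support radius
      reach <- unique(unlist(lapply(idx, function(t0)
        ((t0 - 1 + 0:halfwidth) %% Neff) + 1L)))
      mask[reach, j + 1] <- TRUE
    }
  }
  coefficient_mask(mask, d)
}

#' Reconstruct a series from the signal (or noise) coefficients
#'
#' Zeroes the flagged (noise) detail coefficients and inverts the
#' decomposition, yielding the denoised series. The approximation is
#' always retained. Because the transform is linear, the signal and noise
#' reconstructions sum to the original series.
#'
#' @param d A `modwt` decomposition.
#' @param m A `coef_mask` with matching dimensions.
#' @param keep `"signal"` (default, zero the noise set) or `"noise"`
#'   (reconstruct only the flagged set, without the approximation).
#' @return An object of class `despike_result`: a list with `series` (the
#'   reconstruction), `mask` and `decomposition`.
#' @export
apply_coefficient_mask <- function(d, m, keep = c("signal", "noise")) {
  keep <- match.arg(keep)
  stopifnot(inherits(d, "modwt"), inherits(m, "coef_mask"))
  if (!all(dim(m) == dim(d$W)))
    stop("mask dimensions do not match decomposition")
  dd <- d
  if (keep == "signal") {
    dd$W[unclass(m)] <- 0
  } else {
    dd$W[!unclass(m)] <- 0
    dd$V <- rep(0, length(d$V))
  }
  structure(list(series = imodwt(dd), mask = m, decomposition = d),
            class = "despike_result")
}

#' Despike one time series
#'
#' Convenience wrapper: forward MODWT, noise detection (or an externally
#' supplied mask), and reconstruction from the signal coefficients.
#'
#' @param x Numeric series.
#' @param filter,J,boundary Passed to [modwt()].
#' @param threshold_k,chain_across_scales Passed to
#'   [detect_noise_coefficients()].
#' @param mask Optional externally produced `coef_mask` (logical matrix
#'   accepted); when supplied the internal detector is skipped.
#' @return A `despike_result`.
#' @export
wavelet_despike <- function(x, filter = "d8", J = NULL,
                            boundary = c("reflection", "periodic"),
                            threshold_k = 5, chain_across_scales = TRUE,
                            mask = NULL) {
  boundary <- match.arg(boundary)
  d <- modwt(x, filter = filter, J = J, boundary = boundary)
  m <- if (is.null(mask)) {
    detect_noise_coefficients(d, threshold_k, chain_across_scales)
  } else if (inherits(mask, "coef_mask")) mask else coefficient_mask(mask, d)
  apply_coefficient_mask(d, m)
}

#' Despike every voxel of a 4D volume
#'
#' Runs wavelet despiking independently on every in-mask voxel of a 4D
#' array (x, y, z, t). Out-of-mask voxels are passed through unchanged.
#' The per-voxel coefficient masks are retained for df estimation and
#' diagnostics.
#'
#' @param v 4D numeric array.
#' @param brain_mask Optional 3D logical array; default: voxels with
#'   nonzero temporal variance.
#' @param filter,J,boundary,threshold_k,chain_across_scales As in
#'   [wavelet_despike()].
#' @return A list of class `despiked_volume` with `volume` (denoised 4D
#'   array), `masks` (list of `coef_mask`, one per in-mask voxel),
#'   `voxels` (matrix of in-mask voxel indices, one row per mask),
#'   `brain_mask`, `N`, `J`, `boundary`, `filter`.
#' @export
despike_volume <- function(v, brain_mask = NULL, filter = "d8", J = NULL,
                           boundary = c("reflection", "periodic"),
                           threshold_k = 5, chain_across_scales = TRUE) {
  boundary <- match.arg(boundary)
  filter <- .as_filter(filter)
  if (length(dim(v)) != 4) stop("v must be a 4D array (x, y, z, t)")
  dims <- dim(v)
  N <- dims[4]
  vox_mat <- matrix(v, ncol = N)           # voxels x time
  if (is.null(brain_mask)) {
    vars <- apply(vox_mat, 1, stats::var)
    brain_mask <- array(vars > 0, dims[1:3])
  } else {
    if (!all(dim(brain_mask) == dims[1:3]))
      stop("brain_mask grid does not match volume grid")
    brain_mask <- array(as.logical(brain_mask), dims[1:3])
  }
  inmask <- which(brain_mask)
  if (length(inmask) == 0) stop("empty brain mask: no voxels to process")
  if (is.null(J)) J <- modwt_max_level(N, filter$L)

  # vectorised forward pyramid over all in-mask voxels
  X <- t(vox_mat[inmask, , drop = FALSE])  # time x voxels
  Xin <- if (boundary == "reflection") rbind(X, X[N:1, , drop = FALSE]) else X
  pyr <- .modwt_pyramid(Xin, filter, J)

  # per-voxel detection + masked inverse
  nvox <- length(inmask)
  masks <- vector("list", nvox)
  Wm <- pyr$W
  for (i in seq_len(nvox)) {
    d_i <- structure(list(
      W = vapply(Wm, function(M) M[, i], numeric(nrow(Xin))),
      V = pyr$V[, i], N = N, J = J, boundary = boundary, filter = filter),
      class = "modwt")
    m <- detect_noise_coefficients(d_i, threshold_k, chain_across_scales)
    masks[[i]] <- m
    for (j in seq_len(J)) Wm[[j]][unclass(m)[, j], i] <- 0
  }
  Xden <- .imodwt_pyramid(Wm, pyr$V, filter)[seq_len(N), , drop = FALSE]
  out <- vox_mat
  out[inmask, ] <- t(Xden)
  structure(list(volume = array(out, dims), masks = masks,
                 voxels = arrayInd(inmask, dims[1:3]),
                 brain_mask = brain_mask, N = N, J = J,
                 boundary = boundary, filter = filter),
            class = "despiked_volume")
}
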