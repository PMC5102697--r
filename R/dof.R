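# Effective degrees of freedom (df) estimation from despiked MODWT
# coefficients: per scale, per voxel, combined across scales, parcellated
# to regions, and reduced to pairwise/edge df.
#
# The estimator is the conservative band-pass counting one: scale j of the
# MODWT approximates the pass-band 1/2^(j+1) < |f| <= 1/2^j, so a clean
# length-N series carries about N/2^j independent observations at scale j.
# Noise coefficients removed during despiking are subtracted from the
# usable count; the periodic boundary additionally discounts the
# (2^j - 1)(L - 1) boundary coefficients. df never drops below 1.

#' Effective df of one scale
#'
#' * reflection boundary: `eta_j = max((N - n_noise) / 2^j, 1)`, where
#'   `n_noise` counts noise flags over the first `N` time indices only.
#' * periodic boundary: `M_j = N - min((2^j - 1)(L - 1), N)` non-boundary
#'   coefficients and `eta_j = max((M_j - n_noise) / 2^j, 1)`, where
#'   `n_noise` counts non-boundary noise flags.
#'
#' The result is a real number; no rounding is applied.
#'
#' @param N Series length (original time points).
#' @param j Scale index.
#' @param boundary `"reflection"` or `"periodic"`.
#' @param L Filter taps (needed for the periodic boundary count).
#' @param n_noise Number of noise coefficients counted at this scale
#'   (default 0). Vectorised over `n_noise`.
#' @return Effective df (real, >= 1).
#' @examples
#' df_per_scale(512, 1, "reflection")            # 256
#' df_per_scale(512, 3, "periodic", L = 8)       # 57.875
#' @export
df_per_scale <- function(N, j, boundary = c("reflection", "periodic"),
                         L = 8L, n_noise = 0) {
  boundary <- match.arg(boundary)
  if (any(n_noise < 0)) stop("n_noise must be >= 0")
  if (boundary == "reflection") {
    Mj <- N
  } else {
    Mj <- N - min((2^j - 1) * (L - 1), N)
  }
  if (any(n_noise > Mj))
    stop(sprintf("n_noise exceeds the admissible coefficient count (%g) at scale %d", Mj, j))
  pmax((Mj - n_noise) / 2^j, 1)
}

#' Per-scale effective df of one despiked series
#'
#' Applies [df_per_scale()] with the noise counts of a coefficient mask
#' (counted under the mask's boundary convention, see [noise_counts()]).
#'
#' @param m A `coef_mask`.
#' @return Named numeric vector of df, one per scale.
#' @export
df_from_mask <- function(m) {
  stopifnot(inherits(m, "coef_mask"))
  N <- attr(m, "N"); J <- attr(m, "J"); L <- attr(m, "L")
  boundary <- attr(m, "boundary")
  counts <- noise_counts(m)
  out <- vapply(seq_len(J), function(j)
    df_per_scale(N, j, boundary, L, counts[j]), numeric(1))
  names(out) <- paste0("j", seq_len(J))
  out
}

#' Combine df across scales
#'
#' Under approximate independence across scales, df add: the combined df
#' over a scale set is the arithmetic sum of the per-scale df. The total
#' over all scales is bounded by `N`.
#'
#' @param df_by_scale Numeric vector of per-scale df (names or positions
#'   index scales).
#' @param scales Integer vector of scales to combine.
#' @return Combined df (real).
#' @examples
#' combine_df_scales(c(66.5, 33.25, 16.625, 8.3125, 4.15625), 2:4)  # 58.1875
#' @export
combine_df_scales <- function(df_by_scale, scales) {
  scales <- as.integer(scales)
  if (length(scales) == 0) stop("empty scale set")
  if (any(scales < 1) || any(scales > length(df_by_scale)))
    stop("scales outside the available range")
  sum(df_by_scale[scales])
}

#' Voxel-wise df maps from despiking masks
#'
#' Applies the per-scale df formula to every voxel's coefficient mask,
#' yielding one spatial df volume per wavelet scale (and optionally a
#' combined volume over a scale set).
#'
#' @param dv A `despiked_volume` (from [despike_volume()]), or a list of
#'   `coef_mask` plus explicit geometry via `voxels` and `dim3`.
#' @param combine Optional integer vector of scales to sum into a combined
#'   map.
#' @param voxels,dim3 Only needed when `dv` is a bare list of masks: a
#'   matrix of voxel indices (rows aligned with the masks) and the 3D grid
#'   dimensions.
#' @return An object of class `df_map`: list with `scale_maps` (list of 3D
#'   arrays, `NA` outside the mask), `combined` (3D array or `NULL`),
#'   `combined_scales`, `N`, `J`, `boundary`.
#' @export
df_map_from_masks <- function(dv, combine = NULL, voxels = NULL, dim3 = NULL) {
  if (inherits(dv, "despiked_volume")) {
    masks <- dv$masks; voxels <- dv$voxels; dim3 <- dim(dv$brain_mask)
  } else {
    masks <- dv
    if (is.null(voxels) || is.null(dim3))
      stop("voxels and dim3 must be supplied with a bare mask list")
  }
  if (length(masks) == 0) stop("no masks supplied")
  J <- attr(masks[[1]], "J"); N <- attr(masks[[1]], "N")
  boundary <- attr(masks[[1]], "boundary")
  ok <- vapply(masks, function(m)
    attr(m, "J") == J && attr(m, "N") == N && attr(m, "boundary") == boundary,
    logical(1))
  if (!all(ok)) stop("masks have inconsistent dimensions or metadata")
  df_mat <- t(vapply(masks, df_from_mask, numeric(J)))  # voxels x scales
  lin <- voxels[, 1] + (voxels[, 2] - 1) * dim3[1] +
    (voxels[, 3] - 1) * dim3[1] * dim3[2]
  scale_maps <- lapply(seq_len(J), function(j) {
    a <- array(NA_real_, dim3)
    a[lin] <- df_mat[, j]
    a
  })
  names(scale_maps) <- paste0("j", seq_len(J))
  combined <- NULL
  if (!is.null(combine)) {
    combine <- as.integer(combine)
    if (any(combine < 1) || any(combine > J)) stop("combine scales outside 1..J")
    a <- array(NA_real_, dim3)
    a[lin] <- rowSums(df_mat[, combine, drop = FALSE])
    combined <- a
  }
  structure(list(scale_maps = scale_maps, combined = combined,
                 combined_scales = combine, N = N, J = J,
                 boundary = boundary),
            class = "df_map")
}

#' Parcellate a df map into regional nodes
#'
#' Per-region (optionally weighted) mean of the member voxels' df, per
#' scale, with region centroids as the (weighted) mean voxel coordinates.
#' The same averaging used for regional time series applies to df maps.
#'
#' @param df A `df_map`.
#' @param labels 3D integer array: positive region labels, 0 = background.
#' @param weights Optional 3D array of per-voxel weights (e.g. gray-matter
#'   probability).
#' @return A data frame of class `regional_df`: `region`, `n_voxels`,
#'   centroid `x`, `y`, `z` (0-based voxel coordinates), one `df_j<scale>`
#'   column per scale, and `df_combined` when the map has one. Regions
#'   with no in-mask voxels are flagged with `NA` df.
#' @export
parcellate_df <- function(df, labels, weights = NULL) {
  stopifnot(inherits(df, "df_map"))
  dim3 <- dim(df$scale_maps[[1]])
  if (!all(dim(labels) == dim3)) stop("label volume grid does not match df map grid")
  if (any(labels != round(labels)) || any(labels < 0))
    stop("labels must be non-negative integers")
  if (is.null(weights)) weights <- array(1, dim3)
  if (!all(dim(weights) == dim3)) stop("weights grid does not match df map grid")
  regions <- sort(unique(labels[labels > 0]))
  coords <- arrayInd(seq_len(prod(dim3)), dim3) - 1L   # 0-based
  inmask_vol <- !is.na(df$scale_maps[[1]])
  rows <- lapply(regions, function(rg) {
    sel <- which(labels == rg & inmask_vol)
    if (length(sel) == 0) {
      out <- c(rg, 0, NA, NA, NA, rep(NA_real_, df$J),
               if (!is.null(df$combined)) NA_real_)
      return(out)
    }
    w <- weights[sel]
    if (sum(w) <= 0) w <- rep(1, length(sel))
    w <- w / sum(w)
    cen <- colSums(coords[sel, , drop = FALSE] * w)
    dfs <- vapply(df$scale_maps, function(a) sum(a[sel] * w), numeric(1))
    c(rg, length(sel), cen, dfs,
      if (!is.null(df$combined)) sum(df$combined[sel] * w))
  })
  out <- as.data.frame(do.call(rbind, rows))
  nm <- c("region", "n_voxels", "x", "y", "z", paste0("df_j", seq_len(df$J)))
  if (!is.null(df$combined)) nm <- c(nm, "df_combined")
  names(out) <- nm
  class(out) <- c("regional_df", "data.frame")
  out
}

#' Pairwise (edge or seed-voxel) df
#'
#' The df assigned to a correlation between two series is the minimum of
#' the two series' df. Vectorised; applied to two df vectors with
#' `outer()` it yields a symmetric edge-df matrix.
#'
#' @param df_a,df_b Effective df values (each >= 1).
#' @return `pmin(df_a, df_b)`.
#' @export
pair_df <- function(df_a, df_b) {
  if (any(df_a < 1, na.rm = TRUE) || any(df_b < 1, na.rm = TRUE))
    stop("df values must be >= 1")
  pmin(df_a, df_b)
}

#' Edge-df matrix from nodal df
#'
#' @param df Numeric vector of nodal df.
#' @return Symmetric matrix `min(df_i, df_j)`.
#' @export
edge_df_matrix <- function(df) outer(df, df, pmin)
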