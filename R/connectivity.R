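# df-corrected inference on correlations: Fisher r-to-Z with effective df,
# Normal P values, Benjamini-Hochberg FDR with optional harmonic c(N)
# penalty, seed-correlation maps and per-scale wavelet-domain correlation
# matrices.

#' df-corrected Fisher r-to-Z transform
#'
#' `Z = 0.5 * log((1 + r)/(1 - r)) * sqrt(df - 3)`: the r-to-Z transformed
#' correlation divided by its standard error `1/sqrt(df - 3)`, with the
#' effective df of the pair in place of the nominal sample size.
#' Vectorised over `r` and `df`.
#'
#' @param r Pearson correlation(s), `|r| <= 1`.
#' @param df Effective df of the correlation (pairwise minimum upstream).
#' @param low_df `"pmax"` (default): correlations with `df <= 3` get
#'   `Z = 0`/`P = 1` downstream (such edges can never be significant);
#'   `"strict"`: error on `df <= 3`.
#' @return Z score(s); `Inf` with matching sign when `|r| = 1`, `NA` where
#'   `df <= 3` under the default policy.
#' @examples
#' fisher_z(0.5, 103)   # atanh(0.5) * 10 = 5.49306
#' @export
fisher_z <- function(r, df, low_df = c("pmax", "strict")) {
  low_df <- match.arg(low_df)
  if (any(abs(r) > 1, na.rm = TRUE)) stop("|r| must be <= 1")
  bad <- df <= 3
  if (any(bad, na.rm = TRUE) && low_df == "strict")
    stop("df <= 3: Z undefined (strict mode)")
  z <- atanh(r) * sqrt(pmax(df - 3, 0))
  z[which(bad)] <- NA_real_
  z
}

#' Convert Z scores to Normal-theory P values
#'
#' Two-tailed (default): `2 * (1 - Phi(|Z|))`; one-tailed: `1 - Phi(Z)`.
#' `NA` Z scores (the low-df sentinel of [fisher_z()]) map to `P = 1`,
#' infinite Z to `P = 0`.
#'
#' @param z Z score(s).
#' @param tails 1 or 2 (default 2).
#' @return P value(s) in `[0, 1]`.
#' @export
z_to_p <- function(z, tails = 2) {
  if (!tails %in% c(1, 2)) stop("tails must be 1 or 2")
  p <- if (tails == 2) 2 * stats::pnorm(-abs(z)) else stats::pnorm(z, lower.tail = FALSE)
  p[is.na(z)] <- 1
  pmin(p, 1)
}

#' Benjamini-Hochberg FDR thresholding with optional harmonic penalty
#'
#' Step-up rule: sort the `N` P values ascending and take as threshold the
#' largest `P_i` with `P_i <= i * q / (N * c(N))`, where `c(N)` is the
#' harmonic sum `1 + 1/2 + ... + 1/N` (`cn_mode = "harmonic"`, valid under
#' arbitrary dependence and strictly harsher) or 1 (`cn_mode = "unit"`,
#' the classical BH rule). The significant set is every test with
#' `P <=` threshold.
#'
#' @param p Numeric vector of P values in `[0, 1]`.
#' @param q FDR level in (0, 1).
#' @param cn_mode `"harmonic"` (default) or `"unit"`.
#' @return An object of class `fdr_result`: list with `threshold` (the
#'   chosen P cut-off, `NA` if nothing is significant), `significant`
#'   (logical vector in the original order), `n_significant`, `q`,
#'   `cn_mode`, `cN`.
#' @examples
#' bh_fdr(c(0.001, 0.02, 0.03, 0.04), q = 0.05, cn_mode = "unit")$n_significant  # 4
#' @export
bh_fdr <- function(p, q = 0.05, cn_mode = c("harmonic", "unit")) {
  cn_mode <- match.arg(cn_mode)
  if (length(p) == 0) stop("empty P value collection")
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("P values must lie in [0, 1]")
  if (q <= 0 || q >= 1) stop("q must lie in (0, 1)")
  n <- length(p)
  cN <- if (cn_mode == "harmonic") sum(1 / seq_len(n)) else 1
  ord <- order(p)
  ps <- p[ord]
  ok <- ps <= seq_len(n) * q / (n * cN)
  if (!any(ok, na.rm = TRUE)) {
    thr <- NA_real_
    sig <- rep(FALSE, n)
  } else {
    thr <- ps[max(which(ok))]
    sig <- p <= thr
    sig[is.na(sig)] <- FALSE
  }
  structure(list(threshold = thr, significant = sig,
                 n_significant = sum(sig), q = q, cn_mode = cn_mode, cN = cN),
            class = "fdr_result")
}

#' df-corrected seed correlation map
#'
#' Averages the voxel series in a seed block, band-passes seed and target
#' series over the requested wavelet scales, correlates in the time
#' domain, assigns each voxel the pairwise-minimum combined df, converts
#' to Z and P, and thresholds by BH-FDR over the in-mask search volume.
#'
#' @param dv A `despiked_volume` (denoised data plus per-voxel masks).
#' @param seed_box 2x3 matrix (or list of `lo`, `hi`) of 1-based inclusive
#'   voxel index ranges defining the seed block.
#' @param scales Wavelet scales retained for the band-pass and df
#'   combination.
#' @param q FDR level (default 0.01).
#' @param cn_mode `"harmonic"` (default) or `"unit"`.
#' @param tails 1 or 2 (default 2).
#' @param df_mode `"effective"` (default) uses the despiking df maps;
#'   `"nominal"` assumes `df = N` everywhere (the biased comparator).
#' @return List of class `seed_map`: 3D arrays `r`, `z`, `p`,
#'   `r_thresholded` (`r` where significant, `NA` elsewhere, seed voxels
#'   are a sentinel `r = 1` excluded from testing), the `fdr` result,
#'   `seed_df`, `stats` (data frame of per-voxel edge statistics), and the
#'   call parameters.
#' @export
seed_correlation_map <- function(dv, seed_box, scales, q = 0.01,
                                 cn_mode = c("harmonic", "unit"), tails = 2,
                                 df_mode = c("effective", "nominal")) {
  cn_mode <- match.arg(cn_mode)
  df_mode <- match.arg(df_mode)
  stopifnot(inherits(dv, "despiked_volume"))
  dims <- dim(dv$volume)
  if (is.list(seed_box)) seed_box <- rbind(seed_box$lo, seed_box$hi)
  seed_box <- as.matrix(seed_box)
  if (!all(dim(seed_box) == c(2, 3))) stop("seed_box must give lo/hi for 3 axes")
  if (any(seed_box[1, ] < 1) || any(seed_box[2, ] > dims[1:3]))
    stop("seed block outside volume grid")
  scales <- as.integer(scales)
  if (any(scales < 1) || any(scales > dv$J)) stop("scales outside 1..J")

  # per-voxel lookup of masks
  lin_of <- function(ijk) ijk[, 1] + (ijk[, 2] - 1) * dims[1] +
    (ijk[, 3] - 1) * dims[1] * dims[2]
  mask_index <- integer(prod(dims[1:3]))
  mask_index[lin_of(dv$voxels)] <- seq_along(dv$masks)

  seed_idx <- as.matrix(expand.grid(
    seed_box[1, 1]:seed_box[2, 1], seed_box[1, 2]:seed_box[2, 2],
    seed_box[1, 3]:seed_box[2, 3]))
  seed_lin <- lin_of(seed_idx)
  if (any(mask_index[seed_lin] == 0)) stop("seed block extends outside the brain mask")

  vox_mat <- matrix(dv$volume, ncol = dv$N)    # voxels x time
  seed_series <- colMeans(vox_mat[seed_lin, , drop = FALSE])

  # band-pass all in-mask voxels and the seed over the requested scales
  inmask_lin <- lin_of(dv$voxels)
  X <- t(vox_mat[inmask_lin, , drop = FALSE])  # time x voxels
  Xbp <- .bandpass_matrix(cbind(seed_series, X), dv$filter, max(dv$J, max(scales)),
                          dv$boundary, scales, dv$N)
  seed_bp <- Xbp[, 1]
  targ_bp <- Xbp[, -1, drop = FALSE]

  r <- suppressWarnings(as.vector(stats::cor(seed_bp, targ_bp)))
  r[!is.finite(r)] <- NA_real_

  if (df_mode == "effective") {
    df_vox <- vapply(dv$masks, function(m) combine_df_scales(df_from_mask(m), scales),
                     numeric(1))
    seed_df <- min(df_vox[mask_index[seed_lin]])
  } else {
    df_vox <- rep(dv$N, length(dv$masks))
    seed_df <- dv$N
  }
  edge_df <- pair_df(rep(seed_df, length(df_vox)), df_vox)

  is_seed <- inmask_lin %in% seed_lin
  selfcor <- !is.na(r) & abs(r) >= 1 - 1e-12
  testable <- !is_seed & !selfcor & !is.na(r)

  z <- rep(NA_real_, length(r))
  p <- rep(NA_real_, length(r))
  z[testable] <- fisher_z(r[testable], edge_df[testable])
  p[testable] <- z_to_p(z[testable], tails)
  fdr <- bh_fdr(p[testable], q = q, cn_mode = cn_mode)
  sig <- logical(length(r))
  sig[testable] <- fdr$significant

  to_vol <- function(vals) {
    a <- array(NA_real_, dims[1:3]); a[inmask_lin] <- vals; a
  }
  r_thr <- r
  r_thr[!sig] <- NA_real_
  stats_df <- data.frame(
    x = dv$voxels[, 1], y = dv$voxels[, 2], z = dv$voxels[, 3],
    r = r, df = edge_df, z_score = z, p = p,
    significant = sig, seed = is_seed)
  structure(list(r = to_vol(r), z = to_vol(z), p = to_vol(p),
                 r_thresholded = to_vol(r_thr), fdr = fdr,
                 seed_df = seed_df, stats = stats_df, scales = scales,
                 q = q, cn_mode = cn_mode, tails = tails, df_mode = df_mode),
            class = "seed_map")
}

# band-pass each column of a time x series matrix over `scales`
.bandpass_matrix <- function(X, filter, J, boundary, scales, N) {
  J <- min(J, modwt_max_level(if (boundary == "reflection") 2 * N else N, filter$L))
  Xin <- if (boundary == "reflection") rbind(X, X[N:1, , drop = FALSE]) else X
  pyr <- .modwt_pyramid(Xin, filter, J)
  zero <- matrix(0, nrow(Xin), ncol(X))
  W <- lapply(seq_len(J), function(j) if (j %in% scales) pyr$W[[j]] else zero)
  .imodwt_pyramid(W, zero, filter)[seq_len(N), , drop = FALSE]
}

#' Per-scale wavelet-domain correlation matrix
#'
#' Pearson correlation between the scale-`j` detail coefficient series of
#' each pair of regional time series. With the reflection boundary only
#' the first `N` coefficients (those aligned with the original series) are
#' used, matching the df counting convention.
#'
#' @param series Numeric matrix, time x regions (>= 2 columns).
#' @param j Wavelet scale.
#' @param filter,boundary As in [modwt()].
#' @return Symmetric correlation matrix with unit diagonal; pairs
#'   involving a zero-variance coefficient series are `NA`.
#' @export
wavelet_correlation_matrix <- function(series, j, filter = "d8",
                                       boundary = c("reflection", "periodic")) {
  boundary <- match.arg(boundary)
  filter <- .as_filter(filter)
  series <- as.matrix(series)
  if (ncol(series) < 2) stop("need at least 2 regional series")
  N <- nrow(series)
  Xin <- if (boundary == "reflection") rbind(series, series[N:1, , drop = FALSE]) else series
  pyr <- .modwt_pyramid(Xin, filter, j)
  Wj <- pyr$W[[j]][seq_len(N), , drop = FALSE]
  sds <- apply(Wj, 2, stats::sd)
  R <- suppressWarnings(stats::cor(Wj))
  R[sds == 0, ] <- NA_real_
  R[, sds == 0] <- NA_real_
  diag(R) <- 1
  R
}
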