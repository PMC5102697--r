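# Motion and artifact-burden diagnostics: framewise displacement from
# rigid-body realignment parameters, spike percentage from scale-1 noise
# flags, and FD-to-signal correlation maps.

#' Framewise displacement
#'
#' `FD_t` is the sum of the absolute first differences of the six
#' rigid-body parameters, with rotations converted to arc length on a
#' 50 mm sphere: `FD_t = sum_d |d_{t-1} - d_t| + (50 * pi/180) *
#' sum_r |r_{t-1} - r_t|` for rotations in degrees (factor 50 for
#' radians). `FD_0 = 0` so the trace has length `N`.
#'
#' @param params Numeric matrix or data frame with 6 columns: x, y, z
#'   translations (mm) then three rotations.
#' @param rotation_units `"degrees"` (default) or `"radians"`.
#' @return Numeric FD series (mm), length `nrow(params)`.
#' @examples
#' p <- matrix(0, 10, 6); p[5:10, 5] <- 1  # a single 1-degree pitch step
#' framewise_displacement(p)[5]            # 50 * pi / 180 = 0.8727
#' @export
framewise_displacement <- function(params, rotation_units = c("degrees", "radians")) {
  rotation_units <- match.arg(rotation_units)
  params <- as.matrix(params)
  if (ncol(params) != 6)
    stop("motion parameters must have 6 columns: x, y, z translations then 3 rotations")
  if (nrow(params) < 2) stop("need N >= 2 time points")
  rot_factor <- if (rotation_units == "degrees") 50 * pi / 180 else 50
  d <- abs(apply(params, 2, diff))
  if (nrow(params) == 2) d <- matrix(d, nrow = 1)
  fd <- rowSums(d[, 1:3, drop = FALSE]) + rot_factor * rowSums(d[, 4:6, drop = FALSE])
  c(0, fd)
}

#' Spike percentage
#'
#' `SP_t` is the percentage of voxels whose scale-1 detail coefficient at
#' time `t` is flagged as noise — a per-frame artifact-burden diagnostic.
#' Only the first `N` time indices of reflection-boundary masks are used.
#'
#' @param masks List of `coef_mask` (one per voxel) or a
#'   `despiked_volume`.
#' @return List of class `spike_trace`: `SP` (length-`N` percentage
#'   series) and `mean_SP`.
#' @export
spike_percentage <- function(masks) {
  if (inherits(masks, "despiked_volume")) masks <- masks$masks
  if (length(masks) == 0) stop("need >= 1 voxel mask")
  N <- attr(masks[[1]], "N")
  count <- rep(0, N)
  for (m in masks) count <- count + unclass(m)[seq_len(N), 1]
  sp <- 100 * count / length(masks)
  structure(list(SP = sp, mean_SP = mean(sp)), class = "spike_trace")
}

#' FD-to-signal correlation map
#'
#' Pearson correlation between the framewise displacement trace and every
#' voxel time series: high-magnitude regions mark spatially concentrated
#' motion artifact.
#'
#' @param v 4D numeric array (x, y, z, t).
#' @param fd FD series of length `dim(v)[4]`.
#' @return 3D array of correlations in `[-1, 1]`; zero-variance voxels are
#'   `NA`.
#' @export
motion_correlation_map <- function(v, fd) {
  if (length(dim(v)) != 4) stop("v must be a 4D array")
  N <- dim(v)[4]
  if (length(fd) != N) stop("FD length does not match volume time dimension")
  vox <- matrix(v, ncol = N)
  r <- suppressWarnings(as.vector(stats::cor(t(vox), fd)))
  r[!is.finite(r)] <- NA_real_
  array(r, dim(v)[1:3])
}
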