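# Signal-fraction-driven dynamic windows: window lengths grow where the
# signal fraction is low so that every window carries approximately equal
# effective df, keeping window-to-window df variation within 1.

#' Signal fraction trace
#'
#' `SF_t` is the fraction of (voxel, scale) cells whose detail coefficient
#' at time `t` is a signal (unflagged) coefficient:
#' `SF_t = (1/(nV*J)) * sum over voxels and scales of signal indicator`.
#' Only the first `N` time indices of reflection-boundary masks are used.
#'
#' @param masks List of `coef_mask` (one per voxel), or a
#'   `despiked_volume`.
#' @return Numeric vector of length `N`, values in `[0, 1]`.
#' @export
signal_fraction <- function(masks) {
  if (inherits(masks, "despiked_volume")) masks <- masks$masks
  if (length(masks) == 0) stop("need >= 1 voxel mask")
  N <- attr(masks[[1]], "N"); J <- attr(masks[[1]], "J")
  noise_t <- rep(0, N)
  for (m in masks) {
    noise_t <- noise_t + rowSums(unclass(m)[seq_len(N), , drop = FALSE])
  }
  1 - noise_t / (length(masks) * J)
}

#' Dynamic window lengths from a signal-fraction trace
#'
#' For a target "effective" window length `w`, the window starting at `t`
#' ends at the largest `T` in `{t+1, ..., N}` for which the summed signal
#' fraction `D_t = sum(SF[t..T])` lies in `[w - 1, w]`. Window lengths
#' therefore grow where SF is low; when `SF == 1` everywhere the rule
#' degenerates to fixed windows of exactly `w` samples. Starts advance by
#' `step`; trailing starts with no admissible end are dropped.
#'
#' @param SF Signal-fraction series in `[0, 1]`.
#' @param w Target effective window length in samples (>= 2). Seconds are
#'   accepted via `TR`: `w` in seconds is divided by `TR` when
#'   `units = "seconds"`.
#' @param step Start-index increment in samples (default 1).
#' @param units `"samples"` (default) or `"seconds"`.
#' @param TR Sampling interval, required when `units = "seconds"`.
#' @return Data frame of class `window_set`: `start`, `end` (1-based
#'   inclusive), `length`, `D` (summed signal fraction).
#' @export
dynamic_windows <- function(SF, w, step = 1L, units = c("samples", "seconds"),
                            TR = NULL) {
  units <- match.arg(units)
  if (units == "seconds") {
    if (is.null(TR)) stop("TR required when w is given in seconds")
    w <- w / TR
  }
  if (w < 2) stop("target effective window length w must be >= 2")
  if (any(SF < 0 | SF > 1)) stop("SF values must lie in [0, 1]")
  N <- length(SF)
  cs <- c(0, cumsum(SF))
  starts <- seq(1L, N, by = as.integer(step))
  rows <- lapply(starts, function(t) {
    # D_t(T) = cs[T + 1] - cs[t]; largest T in {t+1..N} with D in [w-1, w]
    D <- cs[(t + 1):(N + 1)] - cs[t]      # D for T = t..N
    ok <- which(D >= w - 1 & D <= w)
    ok <- ok[ok >= 2]                     # enforce T >= t + 1
    if (length(ok) == 0) return(NULL)
    Tend <- t + max(ok) - 1L
    c(start = t, end = Tend, length = Tend - t + 1L, D = D[max(ok)])
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0)
    stop("no admissible window: cumulative signal fraction never reaches w - 1")
  out <- as.data.frame(do.call(rbind, rows))
  attr(out, "w") <- w
  class(out) <- c("window_set", "data.frame")
  out
}

#' Per-window df maps
#'
#' Recomputes the voxel-wise df inside each window by restricting the
#' noise-coefficient counts to the window's time indices and using the
#' window length as `N` in the per-scale formula. Scales whose pass-band
#' the window cannot support (level bound of the window length) are
#' dropped.
#'
#' @param dv A `despiked_volume`.
#' @param windows A `window_set` (or data frame with `start`, `end`).
#' @param combine Optional scale set summed into a combined map per
#'   window.
#' @return List of `df_map`, one per window.
#' @export
windowed_df_maps <- function(dv, windows, combine = NULL) {
  stopifnot(inherits(dv, "despiked_volume"))
  L <- dv$filter$L
  lapply(seq_len(nrow(windows)), function(k) {
    t0 <- windows$start[k]; t1 <- windows$end[k]
    if (t1 > dv$N || t0 < 1) stop("window outside series length")
    n_win <- t1 - t0 + 1L
    if (n_win < L)
      stop(sprintf("window of %d samples is shorter than the filter support (L = %d)", n_win, L))
    Jw <- min(dv$J, modwt_max_level(n_win, L))
    df_mat <- t(vapply(dv$masks, function(m) {
      sub <- unclass(m)[t0:t1, seq_len(Jw), drop = FALSE]
      counts <- if (attr(m, "boundary") == "reflection") {
        colSums(sub)
      } else {
        vapply(seq_len(Jw), function(j) {
          Lj <- (2^j - 1) * (L - 1) + 1
          nb <- min(Lj - 1, n_win)
          if (nb >= n_win) 0 else sum(sub[(nb + 1):n_win, j])
        }, numeric(1))
      }
      vapply(seq_len(Jw), function(j)
        df_per_scale(n_win, j, attr(m, "boundary"), L, min(counts[j], n_win)),
        numeric(1))
    }, numeric(Jw)))
    dim3 <- dim(dv$brain_mask)
    lin <- dv$voxels[, 1] + (dv$voxels[, 2] - 1) * dim3[1] +
      (dv$voxels[, 3] - 1) * dim3[1] * dim3[2]
    scale_maps <- lapply(seq_len(Jw), function(j) {
      a <- array(NA_real_, dim3); a[lin] <- df_mat[, j]; a
    })
    names(scale_maps) <- paste0("j", seq_len(Jw))
    combined <- NULL
    cmb <- combine[combine <= Jw]
    if (!is.null(combine) && length(cmb) > 0) {
      a <- array(NA_real_, dim3)
      a[lin] <- rowSums(df_mat[, cmb, drop = FALSE])
      combined <- a
    }
    structure(list(scale_maps = scale_maps, combined = combined,
                   combined_scales = cmb, N = n_win, J = Jw,
                   boundary = dv$boundary, window = c(start = t0, end = t1)),
              class = "df_map")
  })
}

#' Window-to-window df variability
#'
#' Standard deviation of the successive differences of a per-window
#' summary (e.g. per-window mean df, or the summed signal fraction `D`).
#' Used to compare dynamic against fixed windowing: the dynamic rule keeps
#' consecutive `|change| <= 1` by construction.
#'
#' @param x A `window_set` (its `D` column is used) or a numeric vector of
#'   per-window values.
#' @return Standard deviation of successive differences.
#' @export
window_variability <- function(x) {
  v <- if (inherits(x, "window_set") || is.data.frame(x)) x$D else as.numeric(x)
  if (length(v) < 2) stop("need >= 2 windows")
  stats::sd(diff(v))
}

#' Fixed windows (comparator for the dynamic rule)
#'
#' Plain sliding windows of a fixed sample length, with the summed signal
#' fraction recorded per window so that variability can be compared
#' against [dynamic_windows()].
#'
#' @param SF Signal-fraction series.
#' @param length_samples Window length in samples.
#' @param step Start increment (default 1).
#' @return A `window_set` data frame.
#' @export
fixed_windows <- function(SF, length_samples, step = 1L) {
  N <- length(SF)
  if (length_samples < 2 || length_samples > N) stop("invalid window length")
  cs <- c(0, cumsum(SF))
  starts <- seq(1L, N - length_samples + 1L, by = as.integer(step))
  out <- data.frame(start = starts, end = starts + length_samples - 1L,
                    length = length_samples,
                    D = cs[starts + length_samples] - cs[starts])
  class(out) <- c("window_set", "data.frame")
  out
}
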