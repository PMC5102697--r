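# MODWT engine: forward/inverse maximal overlap discrete wavelet transform
# with reflection or periodic boundary, band-pass recomposition and
# scale <-> frequency bookkeeping.
#
# Internally all pyramid routines operate on a matrix whose columns are
# series, so that voxel-wise volume processing is vectorised.

#' Maximum MODWT decomposition level
#'
#' The largest number of scales `J` that a length-`N` series admits for a
#' filter with `L` taps, defined conservatively as the largest positive
#' integer with `J <= log2(N/(L-1) + 1)`.
#'
#' @param N Series length (time points).
#' @param L Filter length in taps (default 8, the fourth-order Daubechies
#'   filter).
#' @return Integer `J >= 1`.
#' @examples
#' modwt_max_level(512, 4)  # 7
#' modwt_max_level(133, 4)  # 5
#' @export
modwt_max_level <- function(N, L = 8L) {
  if (!is.numeric(N) || length(N) != 1 || N < 2)
    stop("N must be a single value >= 2")
  if (!is.numeric(L) || length(L) != 1 || L < 2)
    stop("L must be a single value >= 2")
  if (N < L)
    stop(sprintf("series too short to decompose: N = %d < filter length L = %d", N, L))
  J <- floor(log2(N / (L - 1) + 1))
  # guard against floating-point sitting just below an integer
  if (2^(J + 1) <= N / (L - 1) + 1) J <- J + 1
  max(1L, as.integer(J))
}

# circular row shift: result[t] = x[(t - s) mod N], 1-based rows
.rowshift <- function(x, s, N) {
  idx <- ((seq_len(N) - 1 - s) %% N) + 1L
  if (is.matrix(x)) x[idx, , drop = FALSE] else x[idx]
}

# forward pyramid on a matrix (columns = series), periodic convolution
.modwt_pyramid <- function(X, filter, J) {
  N <- nrow(X)
  gt <- filter$g / sqrt(2)
  ht <- filter$h / sqrt(2)
  L <- filter$L
  W <- vector("list", J)
  V <- X
  for (j in seq_len(J)) {
    step <- 2^(j - 1)
    Wj <- matrix(0, N, ncol(X))
    Vj <- matrix(0, N, ncol(X))
    for (l in seq_len(L)) {
      shifted <- .rowshift(V, step * (l - 1), N)
      Wj <- Wj + ht[l] * shifted
      Vj <- Vj + gt[l] * shifted
    }
    W[[j]] <- Wj
    V <- Vj
  }
  list(W = W, V = V)
}

# inverse pyramid on matrices
.imodwt_pyramid <- function(W, V, filter) {
  J <- length(W)
  N <- nrow(V)
  gt <- filter$g / sqrt(2)
  ht <- filter$h / sqrt(2)
  L <- filter$L
  for (j in rev(seq_len(J))) {
    step <- 2^(j - 1)
    Vprev <- matrix(0, N, ncol(V))
    for (l in seq_len(L)) {
      s <- -step * (l - 1)
      Vprev <- Vprev + ht[l] * .rowshift(W[[j]], s, N) +
        gt[l] * .rowshift(V, s, N)
    }
    V <- Vprev
  }
  V
}

#' Forward MODWT of a time series
#'
#' Decomposes a series into `J` scales of detail coefficients plus a final
#' approximation using Mallat's pyramid algorithm with circular convolution
#' of the level-rescaled (by `1/sqrt(2)`) filters. With the `"reflection"`
#' boundary the length-`2N` series `c(x, rev(x))` is transformed
#' periodically, so every scale holds `2N` coefficients; with the
#' `"periodic"` boundary every scale holds `N` coefficients.
#'
#' @param x Numeric series, all values finite.
#' @param filter A `wavelet_filter` or filter name (default `"d8"`).
#' @param J Number of scales; default is the maximum admissible level for
#'   the original series length (see [modwt_max_level()]).
#' @param boundary `"reflection"` (default) or `"periodic"`.
#' @return An object of class `modwt` with fields `W` (coefficient matrix,
#'   effective length x `J`, one column per scale), `V` (final
#'   approximation), `N` (original length), `J`, `boundary` and `filter`.
#' @examples
#' d <- modwt(sin(2 * pi * (1:128) / 16))
#' max(abs(imodwt(d) - sin(2 * pi * (1:128) / 16)))  # ~1e-15
#' @export
modwt <- function(x, filter = "d8", J = NULL, boundary = c("reflection", "periodic")) {
  boundary <- match.arg(boundary)
  filter <- .as_filter(filter)
  if (!is.numeric(x) || length(x) < 2) stop("x must be a numeric series")
  if (any(!is.finite(x))) stop("x contains non-finite values")
  N <- length(x)
  Jmax_orig <- modwt_max_level(N, filter$L)
  Neff_len <- if (boundary == "reflection") 2L * N else N
  Jmax_eff <- modwt_max_level(Neff_len, filter$L)
  if (is.null(J)) J <- Jmax_orig
  J <- as.integer(J)
  if (J < 1) stop("J must be >= 1")
  if (J > Jmax_eff)
    stop(sprintf(
      "J = %d exceeds the maximum level bound J <= log2(N/(L-1) + 1) = %d for N = %d, L = %d",
      J, Jmax_eff, Neff_len, filter$L))
  xin <- if (boundary == "reflection") c(x, rev(x)) else x
  pyr <- .modwt_pyramid(matrix(xin, ncol = 1), filter, J)
  W <- do.call(cbind, lapply(pyr$W, as.vector))
  colnames(W) <- paste0("j", seq_len(J))
  structure(list(W = W, V = as.vector(pyr$V), N = N, J = J,
                 boundary = boundary, filter = filter),
            class = "modwt")
}

#' @export
print.modwt <- function(x, ...) {
  cat(sprintf("MODWT: N = %d, J = %d scales, %s boundary, filter %s (%d coefficients/scale)\n",
              x$N, x$J, x$boundary, x$filter$name, nrow(x$W)))
  invisible(x)
}

#' Inverse MODWT
#'
#' Reconstructs the time series from a (possibly masked) decomposition via
#' the inverse pyramid algorithm. For a reflection-boundary decomposition
#' only the first `N` samples of the reconstructed `2N`-series are
#' returned.
#'
#' @param d A `modwt` object.
#' @return Numeric series of length `d$N`.
#' @export
imodwt <- function(d) {
  stopifnot(inherits(d, "modwt"))
  if (ncol(d$W) != d$J)
    stop("scale count of coefficient matrix does not match decomposition metadata")
  W <- lapply(seq_len(d$J), function(j) matrix(d$W[, j], ncol = 1))
  x <- as.vector(.imodwt_pyramid(W, matrix(d$V, ncol = 1), d$filter))
  x[seq_len(d$N)]
}

#' Band-pass recomposition from selected wavelet scales
#'
#' Inverse-transforms a decomposition with detail coefficients outside
#' `scales` zeroed (and the approximation zeroed unless
#' `keep_approximation`), yielding a frequency-filtered series. Scale `j`
#' approximates the pass-band `1/2^(j+1) < |f| <= 1/2^j` cycles/sample.
#'
#' @param d A `modwt` object.
#' @param scales Integer vector of scales to retain, subset of `1:J`. May
#'   be empty only if `keep_approximation = TRUE`.
#' @param keep_approximation Retain the final approximation (default
#'   `FALSE`)?
#' @return Numeric series of length `d$N`.
#' @examples
#' x <- rnorm(128)
#' d <- modwt(x)
#' lowfreq <- modwt_bandpass(d, scales = 3:d$J, keep_approximation = TRUE)
#' @export
modwt_bandpass <- function(d, scales, keep_approximation = FALSE) {
  stopifnot(inherits(d, "modwt"))
  scales <- as.integer(scales)
  if (length(scales) == 0 && !keep_approximation)
    stop("empty scale set: nothing to recompose")
  if (length(scales) > 0 && (any(scales < 1) || any(scales > d$J)))
    stop(sprintf("scales must lie in 1..%d", d$J))
  dd <- d
  drop <- setdiff(seq_len(d$J), scales)
  dd$W[, drop] <- 0
  if (!keep_approximation) dd$V <- rep(0, length(d$V))
  imodwt(dd)
}

#' Physical pass-band of a wavelet scale
#'
#' Scale `j` of the MODWT acts as an approximate band-pass filter with
#' pass-band `1/2^(j+1) < |f| <= 1/2^j` cycles per sample; dividing by the
#' sampling interval `TR` gives the band in Hz.
#'
#' @param j Scale index (>= 1).
#' @param TR Sampling interval in seconds (> 0).
#' @return Named numeric vector `c(f_low, f_high)` in Hz (the band is
#'   `(f_low, f_high]`).
#' @examples
#' scale_passband(1, TR = 2)  # (0.125, 0.25] Hz
#' scale_passband(4, TR = 2)  # (0.015625, 0.03125] Hz
#' @export
scale_passband <- function(j, TR = 1) {
  if (!is.numeric(j) || any(j < 1) || any(j != round(j)))
    stop("j must be a positive integer scale index")
  if (!is.numeric(TR) || TR <= 0) stop("TR must be > 0")
  c(f_low = 1 / 2^(j + 1), f_high = 1 / 2^j) / TR
}

# effective per-scale coefficient count of a decomposition
.n_coef <- function(d) nrow(d$W)
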