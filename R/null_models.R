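# Fourier phase-randomization surrogates and observed-vs-expected Type I
# error estimation. Surrogates preserve the amplitude spectrum (hence the
# sample autocorrelation) while destroying phase relations, so the true
# correlation between independently randomized series is zero.

#' Phase-randomized surrogate series
#'
#' Replaces the phases of all non-DC, non-Nyquist Fourier bins with
#' independent uniform(0, 2*pi) draws (Hermitian symmetry enforced), keeps
#' the DC and Nyquist amplitudes real, and inverse-transforms. The
#' amplitude spectrum — and therefore the autocorrelation — of the output
#' equals the input's.
#'
#' @param x Numeric series, length >= 4, finite.
#' @return Surrogate series of the same length and mean.
#' @export
phase_randomize <- function(x) {
  if (any(!is.finite(x))) stop("x contains non-finite values")
  N <- length(x)
  if (N < 4) stop("need N >= 4")
  X <- stats::fft(x)
  half <- if (N %% 2 == 0) N / 2 - 1 else (N - 1) / 2
  phi <- stats::runif(half, 0, 2 * pi)
  idx <- 2:(half + 1)
  X[idx] <- Mod(X[idx]) * exp(1i * phi)
  X[N + 2 - idx] <- Conj(X[idx])
  Re(stats::fft(X, inverse = TRUE)) / N
}

#' Observed Type I error under the phase-randomized null
#'
#' For each repetition, every series is independently phase-randomized,
#' all pairs (or seed-vs-others) are band-passed over the requested
#' scales, correlated in the time domain, converted to df-corrected Z and
#' P, and the fraction significant at each nominal P level is recorded.
#' The observed false positive rate `alpha(P)`, averaged over repetitions,
#' should not exceed the nominal `P` for the test to be valid. With
#' `df_mode = "nominal"` (`df = N`) on colored series the test is
#' anticonservative — the negative control.
#'
#' @param series Numeric matrix, time x series (>= 2 columns).
#' @param p_grid Nominal P levels (default `c(0.001, 0.005, 0.01, 0.05, 0.1)`).
#' @param reps Repetitions (default 100).
#' @param df_mode `"effective"` (default: despiking df combined over
#'   `scales`, pairwise minimum) or `"nominal"` (`df = N`).
#' @param scales Wavelet scales used for band-passing and df combination;
#'   `NULL` (default) skips band-passing and uses all scales' df.
#' @param filter,boundary MODWT configuration for the effective-df mode.
#' @param tails 1 or 2 (default 2).
#' @param pairing `"all"` (default: all series pairs) or `"seed"` (column
#'   1 against the rest).
#' @return Data frame of class `type1_curve`: `p_nominal`,
#'   `alpha_observed` (mean over reps), `alpha_sd`, `mc_se` plus
#'   attributes `reps` and `df_mode`. Monotone non-decreasing in
#'   `p_nominal`.
#' @export
type1_error_curve <- function(series, p_grid = c(0.001, 0.005, 0.01, 0.05, 0.1),
                              reps = 100, df_mode = c("effective", "nominal"),
                              scales = NULL, filter = "d8",
                              boundary = c("reflection", "periodic"),
                              tails = 2, pairing = c("all", "seed")) {
  df_mode <- match.arg(df_mode)
  boundary <- match.arg(boundary)
  pairing <- match.arg(pairing)
  filter <- .as_filter(filter)
  series <- as.matrix(series)
  N <- nrow(series)
  P <- ncol(series)
  if (P < 2) stop("need >= 2 series")
  if (reps < 1) stop("reps must be >= 1")
  p_grid <- sort(p_grid)
  J <- modwt_max_level(N, filter$L)
  if (is.null(scales)) scales_use <- seq_len(J) else scales_use <- as.integer(scales)

  alpha <- matrix(0, reps, length(p_grid))
  for (rep in seq_len(reps)) {
    S <- apply(series, 2, phase_randomize)
    if (!is.null(scales)) {
      Sc <- .bandpass_matrix(S, filter, J, boundary, scales_use, N)
    } else Sc <- S
    if (df_mode == "effective") {
      dfs <- vapply(seq_len(P), function(i) {
        d <- modwt(S[, i], filter = filter, J = J, boundary = boundary)
        m <- detect_noise_coefficients(d)
        combine_df_scales(df_from_mask(m), scales_use)
      }, numeric(1))
    } else {
      dfs <- rep(N, P)
    }
    if (pairing == "all") {
      R <- stats::cor(Sc)
      ut <- upper.tri(R)
      r <- R[ut]
      edf <- edge_df_matrix(dfs)[ut]
    } else {
      r <- as.vector(stats::cor(Sc[, 1], Sc[, -1, drop = FALSE]))
      edf <- pair_df(rep(dfs[1], P - 1), dfs[-1])
    }
    p <- z_to_p(fisher_z(r, edf), tails)
    alpha[rep, ] <- vapply(p_grid, function(pp) mean(p <= pp), numeric(1))
  }
  out <- data.frame(p_nominal = p_grid,
                    alpha_observed = colMeans(alpha),
                    alpha_sd = apply(alpha, 2, stats::sd),
                    mc_se = apply(alpha, 2, stats::sd) / sqrt(reps))
  attr(out, "reps") <- reps
  attr(out, "df_mode") <- df_mode
  class(out) <- c("type1_curve", "data.frame")
  out
}
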