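# Daubechies extremal-phase scaling filters, standard (Percival-Walden) tap
# order, normalised so that sum(g) = sqrt(2). L = taps, M = vanishing moments.
.db_scaling <- list(
  d4 = c(0.48296291314453416, 0.83651630373780794,
         0.22414386804201339, -0.12940952255126037),
  d8 = c(0.23037781330889651, 0.71484657055291567,
         0.63088076792985892, -0.027983769416859854,
         -0.18703481171909309, 0.030841381835560764,
         0.032883011666885197, -0.010597401785069032),
  d12 = c(0.11154074335010947, 0.49462389039845306,
          0.75113390802109536, 0.31525035170919763,
          -0.22626469396543983, -0.12976686756726194,
          0.097501605587323043, 0.027522865530305727,
          -0.03158203931748603, 0.00055384220116149613,
          0.0047772575109455108, -0.0010773010853084796),
  d16 = c(0.054415842243104008, 0.31287159091429995,
          0.67563073629728976, 0.58535468365420673,
          -0.015829105256349306, -0.28401554296154691,
          0.00047248457391328279, 0.12874742662047847,
          -0.017369301001807547, -0.044088253930794755,
          0.013981027917398282, 0.0087460940474057766,
          -0.0048703529934515741, -0.00039174037337694705,
          0.00067544940645056933, -0.00011747678412476953)
)

#' Construct a wavelet filter
#'
#' Returns the orthonormal Daubechies extremal-phase filter pair used by the
#' MODWT engine. The scaling filter `g` sums to `sqrt(2)`; the wavelet filter
#' `h` is its quadrature mirror, `h[l] = (-1)^l g[L - 1 - l]` (zero-based
#' `l`), and sums to 0. The MODWT rescales both by `1/sqrt(2)` at each level
#' so that the transform preserves energy.
#'
#' @param name Filter name: one of `"d4"`, `"d8"` (default), `"d12"`,
#'   `"d16"`, i.e. Daubechies filters with `L = 4, 8, 12, 16` taps
#'   (`M = L/2` vanishing moments). The default is the fourth-order
#'   Daubechies filter (`L = 8`), which decorrelates detail coefficients
#'   well while retaining compact support for artifact localisation.
#' @return An object of class `wavelet_filter` with fields `name`, `g`
#'   (scaling taps), `h` (wavelet taps), `L` (number of taps) and `M`
#'   (vanishing moments).
#' @examples
#' f <- wavelet_filter("d8")
#' sum(f$h)            # 0
#' sum(f$g) - sqrt(2)  # 0
#' @export
wavelet_filter <- function(name = "d8") {
  name <- match.arg(name, names(.db_scaling))
  g <- .db_scaling[[name]]
  L <- length(g)
  h <- rev(g) * (-1)^(seq_len(L) - 1)
  structure(list(name = name, g = g, h = h, L = L, M = L / 2L),
            class = "wavelet_filter")
}

#' @export
print.wavelet_filter <- function(x, ...) {
  cat(sprintf("Daubechies wavelet filter '%s': L = %d taps, M = %d vanishing moments\n",
              x$name, x$L, x$M))
  invisible(x)
}

#' Read a wavelet filter from a plain-text tap file
#'
#' Loads a scaling filter from a text file containing one tap value per
#' line (standard tap order, summing to `sqrt(2)`), and derives the
#' quadrature-mirror wavelet filter.
#'
#' @param path Path to the tap file.
#' @param name Label for the filter.
#' @return A `wavelet_filter` object.
#' @export
read_wavelet_filter <- function(path, name = basename(path)) {
  g <- scan(path, what = numeric(), quiet = TRUE, comment.char = "#")
  if (length(g) < 2 || length(g) %% 2 != 0)
    stop("filter must have an even number of taps >= 2")
  if (abs(sum(g) - sqrt(2)) > 1e-8)
    stop("scaling filter taps must sum to sqrt(2)")
  L <- length(g)
  h <- rev(g) * (-1)^(seq_len(L) - 1)
  structure(list(name = name, g = g, h = h, L = L, M = L / 2L),
            class = "wavelet_filter")
}

.as_filter <- function(filter) {
  if (inherits(filter, "wavelet_filter")) filter else wavelet_filter(filter)
}
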