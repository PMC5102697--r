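test_that("filter invariants hold for all shipped Daubechies filters", {
  for (nm in c("d4", "d8", "d12", "d16")) {
    f <- wavelet_filter(nm)
    expect_equal(sum(f$h), 0, tolerance = 1e-12)
    expect_equal(sum(f$g), sqrt(2), tolerance = 1e-12)
    # quadrature-mirror relation: h[l] = (-1)^l g[L-1-l]
    L <- f$L
    expect_equal(f$h, rev(f$g) * (-1)^(0:(L - 1)), tolerance = 1e-12)
    # orthonormality to even shifts
    expect_equal(sum(f$g^2), 1, tolerance = 1e-12)
    if (L > 2) expect_equal(sum(f$g[1:(L - 2)] * f$g[3:L]), 0, tolerance = 1e-12)
  }
})

test_that("maximum decomposition level follows the log2(N/(L-1)+1) bound", {
  expect_identical(modwt_max_level(512, 4), 7L)
  expect_identical(modwt_max_level(133, 4), 5L)
  expect_identical(modwt_max_level(4, 4), 1L)
  expect_error(modwt_max_level(4, 8), "too short")
  for (N in c(50, 64, 100, 133, 512)) {
    for (L in c(4, 8, 16)) {
      if (N < L) next
      J <- modwt_max_level(N, L)
      expect_lte(J, log2(N / (L - 1) + 1) + 1e-9)
      expect_gt(J + 1, log2(N / (L - 1) + 1))
      expect_lte(J, floor(log2(N)))
    }
  }
})

test_that("perfect reconstruction and energy conservation across lengths and boundaries", {
  set.seed(42)
  for (N in c(50, 64, 100, 133, 512)) {
    x <- rnorm(N)
    for (bd in c("reflection", "periodic")) {
      d <- modwt(x, boundary = bd)
      expect_lte(max(abs(imodwt(d) - x)), 1e-8)
      xin <- if (bd == "reflection") c(x, rev(x)) else x
      expect_identical(nrow(d$W), length(xin))
      energy <- sum(d$W^2) + sum(d$V^2)
      expect_lt(abs(energy - sum(xin^2)) / sum(xin^2), 1e-8)
    }
  }
})

test_that("reflection boundary yields 2N coefficients at every scale", {
  x <- rnorm(133)
  d <- modwt(x, boundary = "reflection")
  expect_identical(dim(d$W), c(266L, d$J))
})

test_that("constant series has zero details and constant approximation", {
  d <- modwt(rep(3.5, 64), J = 3)
  expect_lte(max(abs(d$W)), 1e-12)
  expect_equal(d$V, rep(3.5, 128), tolerance = 1e-12)
})

test_that("unit impulse produces exactly L nonzero scale-1 coefficients (periodic)", {
  x <- c(1, rep(0, 63))
  f <- wavelet_filter("d8")
  d <- modwt(x, filter = f, J = 1, boundary = "periodic")
  nz <- which(abs(d$W[, 1]) > 1e-14)
  expect_identical(nz, 1:f$L)
  expect_equal(d$W[1:f$L, 1], f$h / sqrt(2), tolerance = 1e-12)
})

test_that("pyramid output matches the direct circular-convolution oracle", {
  set.seed(7)
  f <- wavelet_filter("d4")
  for (N in c(32, 64)) {
    x <- rnorm(N)
    J <- modwt_max_level(N, f$L)
    d <- modwt(x, filter = f, J = J, boundary = "periodic")
    ref <- brute_modwt(x, f$g, f$h, J)
    expect_lt(max(abs(d$W - ref$W)), 1e-10)
    expect_lt(max(abs(d$V - ref$V)), 1e-10)
  }
})

test_that("MODWT commutes with circular shifts (periodic boundary)", {
  set.seed(8)
  x <- rnorm(64)
  d <- modwt(x, boundary = "periodic", J = 3)
  for (s in c(1, 13)) {
    xs <- c(x[(s + 1):64], x[1:s])
    ds <- modwt(xs, boundary = "periodic", J = 3)
    expect_equal(ds$W, d$W[c((s + 1):64, 1:s), ], tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("non-finite input and out-of-bound J are rejected", {
  expect_error(modwt(c(1, NA, 3, 4, 5, 6, 7, 8)), "non-finite")
  expect_error(modwt(rnorm(64), J = 20), "bound")
})

test_that("band-pass recomposition is complete and frequency-selective", {
  set.seed(9)
  x <- rnorm(128)
  d <- modwt(x)
  expect_equal(modwt_bandpass(d, 1:d$J, keep_approximation = TRUE), x,
               tolerance = 1e-8)
  expect_error(modwt_bandpass(d, integer(0)), "empty")
  # approximation only -> a smooth trend with less variance than x
  trend <- modwt_bandpass(d, integer(0), keep_approximation = TRUE)
  expect_lt(var(diff(trend)), var(diff(x)))

  # sinusoid at 0.09 cycles/sample sits in scale 3's band (1/16, 1/8];
  # the in-band scale dominates, far scales reject (bands are leaky at
  # the edges, so adjacent scales may carry some variance)
  N <- 256
  s <- sin(2 * pi * 0.09 * seq_len(N))
  ds <- modwt(s)
  retained <- sapply(1:5, function(j) var(modwt_bandpass(ds, j)) / var(s))
  expect_identical(which.max(retained), 3L)
  expect_gte(retained[3], 0.6)
  expect_lte(retained[1], 0.02)
  expect_lte(retained[5], 0.02)
  # the recomposed series is still (close to) a pure tone at 0.09: FFT
  # power oracle
  pw <- Mod(fft(modwt_bandpass(ds, 3)))^2
  peak_bin <- which.max(pw[2:(N / 2)]) + 1
  expect_equal((peak_bin - 1) / N, 0.09, tolerance = 1 / N)
  expect_gte(sum(pw[c(peak_bin, N + 2 - peak_bin)]) / sum(pw[-1]), 0.8)
})

test_that("sum of single-scale recompositions equals the original (linearity)", {
  set.seed(10)
  x <- rnorm(100)     # non-power-of-two length
  d <- modwt(x)
  parts <- sapply(1:d$J, function(j) modwt_bandpass(d, j))
  approx_part <- modwt_bandpass(d, integer(0), keep_approximation = TRUE)
  expect_equal(rowSums(parts) + approx_part, x, tolerance = 1e-8)
})

test_that("scale pass-bands tile (0, 1/2] and convert to Hz by 1/TR", {
  expect_equal(scale_passband(1, 2), c(f_low = 0.125, f_high = 0.25))
  expect_equal(scale_passband(4, 2), c(f_low = 0.015625, f_high = 0.03125))
  expect_equal(scale_passband(2, 1), c(f_low = 0.125, f_high = 0.25))
  bands <- t(sapply(1:6, scale_passband, TR = 1))
  expect_equal(unname(bands[1, 2]), 0.5)
  expect_equal(unname(bands[-6, 1]), unname(bands[-1, 2]))  # adjacent bands tile
  expect_error(scale_passband(0, 2), "positive")
  expect_error(scale_passband(1, -1), "TR")
})

test_that("filters round-trip through the plain-text tap format", {
  f <- wavelet_filter("d8")
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(format(f$g, digits = 17), path)
  f2 <- read_wavelet_filter(path)
  expect_equal(f2$g, f$g, tolerance = 1e-15)
  expect_equal(f2$h, f$h, tolerance = 1e-15)
})
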