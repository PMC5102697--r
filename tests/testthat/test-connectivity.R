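test_that("df-corrected Fisher Z matches the closed form and its symmetries", {
  expect_equal(fisher_z(0, 50), 0)
  expect_equal(fisher_z(0.5, 103), atanh(0.5) * 10, tolerance = 1e-12)
  expect_equal(fisher_z(0.5, 103), 5.49306, tolerance = 1e-5)
  expect_equal(fisher_z(-0.5, 103), -fisher_z(0.5, 103))
  expect_identical(fisher_z(1, 100), Inf)
  # monotone in r for fixed df, and in df for fixed positive r
  r <- seq(-0.9, 0.9, by = 0.1)
  expect_true(all(diff(fisher_z(r, 50)) > 0))
  dfs <- c(10, 50, 100, 500)
  expect_true(all(diff(fisher_z(0.4, dfs)) > 0))
  # low-df policy: NA sentinel by default, error in strict mode
  expect_true(is.na(fisher_z(0.9, 3)))
  expect_error(fisher_z(0.9, 3, low_df = "strict"), "df <= 3")
  expect_error(fisher_z(1.2, 100), "<= 1")
})

test_that("Z-to-P conversion follows the Normal distribution", {
  expect_equal(z_to_p(0, tails = 2), 1)
  expect_equal(z_to_p(qnorm(0.975), tails = 2), 0.05, tolerance = 1e-9)
  expect_equal(z_to_p(1.959964, tails = 2), 0.05, tolerance = 1e-6)
  expect_equal(z_to_p(qnorm(0.95), tails = 1), 0.05, tolerance = 1e-9)
  expect_equal(z_to_p(Inf), 0)
  expect_equal(z_to_p(NA_real_), 1)  # low-df sentinel can never be significant
  expect_error(z_to_p(1, tails = 3), "tails")
})

test_that("BH step-up matches hand-evaluated examples", {
  p <- c(0.001, 0.02, 0.03, 0.04)
  unit <- bh_fdr(p, q = 0.05, cn_mode = "unit")
  expect_identical(unit$n_significant, 4L)
  expect_equal(unit$threshold, 0.04)
  harm <- bh_fdr(p, q = 0.05, cn_mode = "harmonic")
  expect_equal(harm$cN, sum(1 / 1:4), tolerance = 1e-12)
  expect_identical(harm$n_significant, 1L)
  expect_equal(harm$threshold, 0.001)
  none <- bh_fdr(rep(1, 10), q = 0.05)
  expect_identical(none$n_significant, 0L)
  expect_true(is.na(none$threshold))
  expect_error(bh_fdr(numeric(0), 0.05), "empty")
  expect_error(bh_fdr(c(0.5, 1.2), 0.05), "0, 1")
})

test_that("BH step-up equals brute-force and p.adjust oracles on random P sets", {
  set.seed(30)
  for (rep in 1:200) {
    n <- sample(1:50, 1)
    p <- round(runif(n)^sample(1:3, 1), 4)
    q <- sample(c(0.01, 0.05, 0.1), 1)
    for (harmonic in c(TRUE, FALSE)) {
      mine <- bh_fdr(p, q, if (harmonic) "harmonic" else "unit")
      ref <- brute_bh(p, q, harmonic)
      expect_identical(mine$n_significant, as.integer(ref$n_sig))
      expect_equal(mine$threshold, ref$threshold)
      # p.adjust: BH is the unit rule, BY is the harmonic rule
      adj <- p.adjust(p, method = if (harmonic) "BY" else "BH")
      expect_identical(mine$significant, adj <= q)
    }
    # harmonic penalty never yields more discoveries
    expect_lte(bh_fdr(p, q, "harmonic")$n_significant,
               bh_fdr(p, q, "unit")$n_significant)
  }
})

test_that("wavelet-domain correlation matrices behave like Pearson correlation", {
  set.seed(31)
  N <- 512
  S <- matrix(rnorm(N * 5), N, 5)
  S[, 5] <- S[, 1]                      # duplicated region
  R <- wavelet_correlation_matrix(S, j = 1)
  expect_true(isSymmetric(R))
  expect_equal(diag(R), rep(1, 5))
  expect_equal(R[1, 5], 1, tolerance = 1e-12)
  # independent white-noise regions decorrelate
  S2 <- matrix(rnorm(N * 6), N, 6)
  R2 <- wavelet_correlation_matrix(S2, j = 1)
  expect_lt(mean(abs(R2[upper.tri(R2)])), 0.1)
  # matches a brute-force pairwise loop on the same coefficients
  f <- wavelet_filter("d8")
  ref <- brute_modwt(c(S2[, 1], rev(S2[, 1])), f$g, f$h, 1)
  ref2 <- brute_modwt(c(S2[, 2], rev(S2[, 2])), f$g, f$h, 1)
  expect_equal(R2[1, 2], cor(ref$W[1:N, 1], ref2$W[1:N, 1]), tolerance = 1e-10)
  # zero-variance series yield NA sentinels
  S3 <- cbind(S2[, 1:2], 0)
  R3 <- wavelet_correlation_matrix(S3, j = 1)
  expect_true(is.na(R3[1, 3]))
  expect_equal(R3[3, 3], 1)
  expect_error(wavelet_correlation_matrix(S2[, 1, drop = FALSE], 1), "2 regional")
})

test_that("seed correlation maps recover a planted network", {
  set.seed(32)
  spec <- synthetic_spec(
    grid = c(6, 6, 2), N = 256, ar_phi = 0.4,
    networks = list(list(voxels = rbind(c(1, 1, 1), c(1, 2, 1), c(2, 1, 1),
                                        c(2, 2, 1), c(5, 5, 2), c(6, 5, 2),
                                        c(5, 6, 2), c(6, 6, 2)), rho = 0.6)),
    seed = 32)
  run <- generate_run(spec)
  dv <- despike_volume(run$volume, array(TRUE, c(6, 6, 2)))
  sm <- seed_correlation_map(dv, rbind(c(1, 1, 1), c(2, 2, 1)),
                             scales = 2:4, q = 0.01)
  # seed voxels are excluded sentinels
  expect_true(all(sm$stats$seed[sm$stats$x <= 2 & sm$stats$y <= 2 & sm$stats$z == 1]))
  # the four planted voxels away from the seed should be found
  planted <- sm$stats$x >= 5 & sm$stats$y >= 5 & sm$stats$z == 2
  expect_gt(mean(sm$stats$significant[planted]), 0.5)
  ok <- !is.na(sm$z)
  expect_equal(sign(sm$z[ok]), sign(sm$r[ok]))
  expect_error(seed_correlation_map(dv, rbind(c(9, 1, 1), c(9, 2, 1)), 2:4),
               "outside")
})

test_that("seed maps under the phase-randomized null stay near the nominal rate", {
  set.seed(33)
  spec <- synthetic_spec(grid = c(4, 4, 2), N = 256, seed = 33)
  run <- generate_run(spec)
  v <- run$volume
  vox <- matrix(v, ncol = 256)
  for (k in seq_len(nrow(vox))) vox[k, ] <- phase_randomize(vox[k, ])
  vr <- array(vox, dim(v))
  dv <- despike_volume(vr, array(TRUE, c(4, 4, 2)))
  reps <- 20
  frac <- replicate(reps, {
    vox2 <- matrix(vr, ncol = 256)
    for (k in seq_len(nrow(vox2))) vox2[k, ] <- phase_randomize(vox2[k, ])
    dv$volume <- array(vox2, dim(v))
    sm <- seed_correlation_map(dv, rbind(c(1, 1, 1), c(2, 2, 1)),
                               scales = 2:4, q = 0.01, cn_mode = "unit")
    mean(sm$stats$significant[!sm$stats$seed])
  })
  expect_lte(mean(frac), 0.01 + 2 * sd(frac) / sqrt(reps) + 1e-9)
})
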