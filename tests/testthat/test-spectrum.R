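test_that("spectra sum to the directly computed statistics", {
  d <- pca_from_data(collinear_triple())
  s <- fstat_spectrum(d, "f2", c("end1", "end2"))
  expect_equal(s$contributions, c(1, 0), tolerance = 1e-10)
  expect_equal(s$total, 1, tolerance = 1e-10)

  fr <- rand_freqs(7, 90, seed = 31)
  d7 <- pca_from_data(fr, want_loadings = FALSE)
  s2 <- fstat_spectrum(d7, "f2", c("P1", "P4"))
  expect_true(all(s2$contributions >= 0))
  expect_equal(s2$total, f2(fr, "P1", "P4"), tolerance = 1e-10)
  s3 <- fstat_spectrum(d7, "f3", c("P2", "P1", "P3"))
  expect_equal(s3$total, f3(fr, "P2", "P1", "P3"), tolerance = 1e-10)
  s4 <- fstat_spectrum(d7, "f4", c("P1", "P2", "P3", "P4"))
  expect_equal(s4$total, f4(fr, "P1", "P2", "P3", "P4"), tolerance = 1e-10)
})

test_that("truncation splits a statistic into approx + error", {
  fr <- rand_freqs(6, 70, seed = 32)
  d <- pca_from_data(fr, want_loadings = FALSE)
  total <- f2(fr, "P1", "P2")

  t0 <- fstat_truncated(d, "f2", c("P1", "P2"), 0)
  expect_identical(t0$approx, 0)
  expect_equal(t0$error, total, tolerance = 1e-10)

  tmax <- fstat_truncated(d, "f2", c("P1", "P2"), d$K_max)
  expect_equal(tmax$approx, total, tolerance = 1e-10)
  expect_identical(tmax$error, 0)

  prev <- 0
  for (K in 0:d$K_max) {
    tr <- fstat_truncated(d, "f2", c("P1", "P2"), K)
    expect_equal(tr$approx + tr$error, tr$total, tolerance = 1e-10)
    expect_gte(tr$error, 0)
    expect_gte(tr$approx, prev - 1e-14)   # non-decreasing in K
    expect_lte(tr$approx, total + 1e-12)
    prev <- tr$approx
  }
  expect_error(fstat_truncated(d, "f2", c("P1", "P2"), d$K_max + 1L),
               class = "fp_error_parse")
  expect_error(fstat_truncated(d, "f2", c("P1", "P2"), -1L),
               class = "fp_error_parse")
})

test_that("Frobenius truncation error matches the pairwise loop and shrinks in K", {
  tri <- pairwise_f2(collinear_triple())
  expect_equal(f2_frobenius_error(tri, 1), 0, tolerance = 1e-10)

  fr <- rand_freqs(6, 60, seed = 33)
  m <- pairwise_f2(fr)
  d <- pca_from_f2(m)
  expect_equal(f2_frobenius_error(m, d$K_max, d = d), 0, tolerance = 1e-8)

  labs <- rownames(fr)
  prev <- Inf
  for (K in 0:d$K_max) {
    fro <- f2_frobenius_error(m, K, d = d)
    # loop oracle over all ordered pairs of per-pair truncation errors
    loop <- 0
    for (i in seq_along(labs)) {
      for (j in seq_along(labs)) {
        if (i != j) {
          loop <- loop +
            fstat_truncated(d, "f2", c(labs[i], labs[j]), K)$error^2
        }
      }
    }
    expect_equal(fro, sqrt(loop), tolerance = 1e-8)
    expect_lte(fro, prev + 1e-12)
    prev <- fro
  }
})

test_that("rank-K PC truncation beats random orthonormal projections", {
  fr <- rand_freqs(7, 80, seed = 34)
  m <- pairwise_f2(fr)
  d <- pca_from_f2(m)
  for (K in c(1L, 2L, 3L)) {
    best <- f2_frobenius_error(m, K, d = d)
    set.seed(100 + K)
    for (rep in 1:20) {
      Q <- qr.Q(qr(matrix(rnorm(d$K_max * K), d$K_max, K)))
      Pk <- d$coords %*% Q
      G <- tcrossprod(Pk)
      hat <- outer(diag(G), diag(G), `+`) - 2 * G
      diag(hat) <- 0
      expect_gte(sqrt(sum((unclass(m) - hat)^2)), best - 1e-10)
    }
  }
})

test_that("projection returns build populations exactly, with zero error", {
  fr <- rand_freqs(6, 50, seed = 35)
  d <- pca_from_data(fr, want_loadings = TRUE)
  for (i in c(1L, 4L)) {
    ps <- project_sample(d, fr[i, ])
    expect_equal(unname(ps$coords), unname(d$coords[i, ]),
                 tolerance = 1e-10)
    expect_lt(ps$projection_error_f2, 1e-10)
  }
  # the SNP-mean vector projects to the origin
  ps0 <- project_sample(d, center_freqs(fr)$snp_means)
  expect_lt(max(abs(ps0$coords)), 1e-10)
})

test_that("projection is linear: a 50/50 mixture lands at the midpoint", {
  fr <- rand_freqs(5, 40, seed = 36)
  d <- pca_from_data(fr)
  mix <- 0.5 * fr[1, ] + 0.5 * fr[2, ]
  ps <- project_sample(d, mix)
  expect_equal(unname(ps$coords),
               unname((d$coords[1, ] + d$coords[2, ]) / 2),
               tolerance = 1e-10)
  expect_lt(ps$projection_error_f2, 1e-10)
})

test_that("missing-data projection recovers in-span samples from partial loci", {
  fr <- rand_freqs(6, 100, seed = 37)
  d <- pca_from_data(fr)
  mask <- rep(TRUE, 100)
  set.seed(38)
  mask[sample(100, 20)] <- FALSE
  ps <- project_sample(d, fr[3, ], mask = mask)
  expect_equal(unname(ps$coords), unname(d$coords[3, ]), tolerance = 1e-8)
  expect_lt(ps$projection_error_f2, 1e-10)
  expect_identical(ps$observed_mask, mask)
  expect_error(project_sample(d, fr[3, ], mask = rep(FALSE, 100)),
               class = "fp_error_degenerate")
  d_nl <- pca_from_data(fr, want_loadings = FALSE)
  expect_error(project_sample(d_nl, fr[3, ]),
               class = "fp_error_capability")
})

test_that("three-part F2 decomposition sums to the directly computed F2", {
  fr <- rand_freqs(6, 60, seed = 39)
  d <- pca_from_data(fr)
  # the build population itself at K = K_max: (F2, 0, 0)
  ps_self <- project_sample(d, fr[2, ])
  dec_self <- f2_with_projected(d, "P1", ps_self, d$K_max)
  expect_equal(dec_self$truncated, f2(fr, "P1", "P2"), tolerance = 1e-10)
  expect_lt(dec_self$truncation_remainder, 1e-12)
  expect_lt(dec_self$projection_error, 1e-12)

  # a random off-span sample, every K
  set.seed(40)
  new_x <- pmin(pmax(fr[1, ] * 0.3 + runif(60) * 0.7, 0), 1)
  ps <- project_sample(d, new_x)
  fr_aug <- freq_matrix(rbind(unclass(fr), new = new_x))
  direct <- f2(fr_aug, "P3", "new")
  for (K in 0:d$K_max) {
    dec <- f2_with_projected(d, "P3", ps, K)
    expect_equal(dec$total, direct, tolerance = 1e-10)
  }
})

test_that("a residual orthogonal to all loadings appears only as projection error", {
  fr <- rand_freqs(4, 30, seed = 41)
  d <- pca_from_data(fr)
  set.seed(42)
  v <- rnorm(30)
  # remove the loading-span and the constant direction used by centring
  v <- v - as.numeric((v %*% t(d$loadings)) %*% d$loadings)
  base <- 0.5 + 0.4 * (fr[2, ] - 0.5)  # squeeze into [0.1, 0.9]
  eps <- 0.05
  new_x <- base + eps * v / sqrt(sum(v^2))
  stopifnot(all(new_x >= 0 & new_x <= 1))
  ps <- project_sample(d, new_x)
  y_new <- (new_x - d$snp_means) / sqrt(30)
  resid_f2 <- sum((y_new - as.numeric(ps$coords %*% d$loadings))^2)
  expect_equal(ps$projection_error_f2, resid_f2, tolerance = 1e-12)
  expect_gt(ps$projection_error_f2, 0)
  # coords unchanged from the base population up to the mean shift of v
  dec <- f2_with_projected(d, "P1", ps, d$K_max)
  fr_aug <- freq_matrix(rbind(unclass(fr), new = new_x))
  expect_equal(dec$total, f2(fr_aug, "P1", "new"), tolerance = 1e-10)
})
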