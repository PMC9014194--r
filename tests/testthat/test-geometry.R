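test_that("admixture_circle computes center, radii and the projection bound", {
  fr <- rand_freqs(6, 40, seed = 51)
  d <- pca_from_data(fr, want_loadings = FALSE)
  circ <- admixture_circle(d, "P1", "P2", c(1L, 2L))
  expect_equal(unname(circ$center),
               unname((d$coords["P1", 1:2] + d$coords["P2", 1:2]) / 2))
  expect_equal(circ$full_diameter_f2, f2(fr, "P1", "P2"),
               tolerance = 1e-10)
  # projection shrinks distances: subspace radius <= full-ball radius
  expect_lte(circ$radius, circ$radius_full_ball + 1e-12)
  same <- admixture_circle(d, "P1", "P1", c(1L, 2L))
  expect_identical(same$radius, 0)
  expect_error(admixture_circle(d, "P1", "P2", integer()),
               class = "fp_error_parse")
  expect_error(admixture_circle(d, "P1", "P2", c(1L, 99L)),
               class = "fp_error_parse")
})

test_that("classify_f3 matches sign and the Pythagorean boundary cases", {
  # drift-free midpoint mixture: inside the ball, F3 = -F2/4
  fm <- freq_matrix(rbind(a = c(1, 0, 0.4), b = c(0, 1, 0.8),
                          t = c(0.5, 0.5, 0.6), o = c(0.2, 0.9, 0.1)))
  d <- pca_from_data(fm)
  cl <- classify_f3(fm, d, "t", "a", "b", c(1L, 2L))
  expect_identical(cl$position, "inside_ball")
  expect_equal(cl$f3_value, -f2(fm, "a", "b") / 4, tolerance = 1e-12)
  expect_false(cl$outside_projected_circle)

  # right angle at the target: on the sphere
  ra <- freq_matrix(rbind(t = c(0, 0), a = c(1, 0), b = c(0, 1)))
  dra <- pca_from_data(ra)
  cl2 <- classify_f3(ra, dra, "t", "a", "b", 1L)
  expect_identical(cl2$position, "on_sphere")
})

test_that("sign(F3) equals the inside/on/outside ball classification", {
  set.seed(52)
  for (rep in 1:200) {
    fr <- rand_freqs(4, 25)
    d <- pca_from_data(fr, want_loadings = FALSE)
    cl <- classify_f3(fr, d, "P3", "P1", "P2", 1L)
    # independent ball test in frequency space
    mid <- (fr[1, ] + fr[2, ]) / 2
    d2_mid <- sum((fr[3, ] - mid)^2) / 25
    r2 <- f2(fr, "P1", "P2") / 4
    expected <- if (abs(d2_mid - r2) < 1e-12) "on_sphere"
                else if (d2_mid < r2) "inside_ball" else "outside_ball"
    expect_identical(cl$position, expected)
    if (cl$outside_projected_circle) expect_gt(cl$f3_value, 0)
  }
})

test_that("outside the projected full-ball circle guarantees F3 > 0 for any higher PCs", {
  set.seed(53)
  fr <- freq_matrix(0.5 + 0.3 * (matrix(runif(10 * 60), 10, 60) - 0.5),
                    pop_labels = paste0("P", 1:10))
  d <- pca_from_data(fr, want_loadings = TRUE)
  set.seed(54)
  n_outside <- 0L
  for (rep in 1:200) {
    # random completion: arbitrary coords in all PCs, mapped back into
    # frequency space through the loadings (rescaled into [0, 1]) so
    # classify sees a raw frequency vector
    t_coords <- rnorm(d$K_max, 0, 0.2)
    dev <- sqrt(d$n_snps) * as.numeric(t_coords %*% d$loadings)
    f <- min(1, 0.45 / max(abs(dev), 1e-12))
    x_t <- d$snp_means + f * dev
    cl <- classify_f3(fr, d, x_t, "P1", "P2", c(1L, 2L))
    if (cl$outside_projected_circle) {
      n_outside <- n_outside + 1L
      expect_gt(cl$f3_value, 0)
    }
  }
  expect_gt(n_outside, 10L)  # the guarantee was actually exercised
})

test_that("outgroup-F3 ranking equals a brute-force F3 sort", {
  fr <- rand_freqs(8, 50, seed = 55)
  rk <- outgroup_f3_rank(fr, "P1", "P2", paste0("P", 3:8))
  oracle <- sapply(paste0("P", 3:8), function(p) f3(fr, "P1", "P2", p))
  expect_identical(rk$population,
                   names(sort(oracle, decreasing = TRUE)))
  expect_true(all(diff(rk$f3) <= 0))
  # ordering by f3 equals ordering by projected length
  expect_identical(order(rk$f3), order(rk$projected_length))
  expect_equal(rk$projected_length, rk$f3 / sqrt(f2(fr, "P1", "P2")),
               tolerance = 1e-12)

  # the unknown itself tops the ranking with f3 = F2(O, U)
  rk2 <- outgroup_f3_rank(fr, "P1", "P2", c("P2", "P3", "P1"))
  expect_identical(rk2$population[1L], "P2")
  expect_equal(rk2$f3[1L], f2(fr, "P1", "P2"), tolerance = 1e-12)
  # a panel member equal to the outgroup scores zero
  expect_equal(rk2$f3[rk2$population == "P1"], 0, tolerance = 1e-15)

  expect_error(outgroup_f3_rank(fr, "P1", "P1", "P2"),
               class = "fp_error_degenerate")
  expect_error(outgroup_f3_rank(fr, "P1", "P2", character()),
               class = "fp_error_parse")
})

test_that("f4_angle recovers parallel, orthogonal and random geometries", {
  # (a-b) parallel to (c-d): shift both ends by the same vector
  base <- 0.5 + 0.4 * (unclass(rand_freqs(2, 30, seed = 56)) - 0.5)
  shift <- runif(30, -0.05, 0.05)
  fm <- freq_matrix(rbind(a = base[1, ], b = base[2, ],
                          c = base[1, ] + shift, d = base[2, ] + shift))
  ang <- f4_angle(fm, "a", "b", "c", "d")
  expect_equal(ang$cos_phi, 1, tolerance = 1e-12)
  expect_equal(ang$phi_degrees, 0, tolerance = 1e-5)

  # orthogonal construction on disjoint loci
  orth <- freq_matrix(rbind(a = c(1, 0, 0.5), b = c(0, 0, 0.5),
                            c = c(0.5, 1, 0.5), d = c(0.5, 0, 0.5)))
  ang0 <- f4_angle(orth, "a", "b", "c", "d")
  expect_equal(ang0$cos_phi, 0, tolerance = 1e-12)
  expect_equal(ang0$phi_degrees, 90)

  set.seed(57)
  for (rep in 1:20) {
    fr <- rand_freqs(4, 35)
    a <- f4_angle(fr, "P1", "P2", "P3", "P4")
    v1 <- fr[1, ] - fr[2, ]
    v2 <- fr[3, ] - fr[4, ]
    oracle <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
    expect_equal(a$cos_phi, oracle, tolerance = 1e-12)
    expect_lte(abs(a$cos_phi), 1 + 1e-12)
  }

  expect_error(f4_angle(fm, "a", "a", "c", "d"),
               class = "fp_error_degenerate")
})

test_that("truncated f4_angle at K_max equals the frequency-space angle", {
  fr <- rand_freqs(6, 45, seed = 58)
  d <- pca_from_data(fr, want_loadings = FALSE)
  full <- f4_angle(fr, "P1", "P2", "P3", "P4")
  at_kmax <- f4_angle(d, "P1", "P2", "P3", "P4", K = d$K_max)
  expect_equal(at_kmax$cos_phi, full$cos_phi, tolerance = 1e-10)
  expect_equal(at_kmax$f4_value, full$f4_value, tolerance = 1e-10)
  two_pc <- f4_angle(d, "P1", "P2", "P3", "P4", K = 2L)
  expect_identical(two_pc$K_used, 2L)
  expect_lte(abs(two_pc$cos_phi), 1 + 1e-12)
})

test_that("f4_ratio recovers drift-free mixture weights exactly", {
  set.seed(59)
  pops <- 0.5 + 0.4 * (unclass(rand_freqs(4, 100)) - 0.5)  # in [0.1, 0.9]
  for (w in c(0, 0.3, 1)) {
    xx <- (1 - w) * pops[3, ] + w * pops[4, ]
    fm <- freq_matrix(rbind(pops, XX = xx))
    r <- f4_ratio(fm, "P1", "P2", "XX", "P3", "P4")
    expect_equal(r$alpha, w, tolerance = 1e-10)
  }
  # a perturbation of XX orthogonal to R1 - R2 leaves alpha unchanged
  w <- 0.3
  xx <- (1 - w) * pops[3, ] + w * pops[4, ]
  v <- rnorm(100)
  axis <- pops[1, ] - pops[2, ]
  v <- v - axis * sum(v * axis) / sum(axis^2)
  xx_p <- xx + 0.02 * v / sqrt(sum(v^2))
  stopifnot(all(xx_p >= 0 & xx_p <= 1))
  fmp <- freq_matrix(rbind(pops, XX = xx_p))
  expect_equal(f4_ratio(fmp, "P1", "P2", "XX", "P3", "P4")$alpha, w,
               tolerance = 1e-8)

  # degenerate references: X2 - X1 orthogonal to R1 - R2
  orth <- freq_matrix(rbind(R1 = c(1, 0, 0.5, 0.5), R2 = c(0, 0, 0.5, 0.5),
                            X1 = c(0.5, 0, 0.5, 0.5),
                            X2 = c(0.5, 1, 0.5, 0.5),
                            XX = c(0.5, 0.5, 0.5, 0.5)))
  expect_error(f4_ratio(orth, "R1", "R2", "XX", "X1", "X2"),
               class = "fp_error_degenerate")
})

test_that("residual rotation aligns the reference axis and reproduces f4-ratios", {
  set.seed(60)
  base <- rand_freqs(6, 120)
  pops <- unclass(base)
  w <- 0.4
  xx <- (1 - w) * pops[3, ] + w * pops[4, ]
  fm <- freq_matrix(rbind(pops, XX = xx))
  d <- pca_from_data(fm, want_loadings = FALSE)
  rr <- residual_rotation(d, "P1", "P2")

  expect_equal(rr$axis_length, sqrt(f2(fm, "P1", "P2")), tolerance = 1e-10)
  expect_equal(unname(rr$axis_pos["P1"]), 0, tolerance = 1e-10)
  expect_equal(unname(rr$axis_pos["P2"]), rr$axis_length, tolerance = 1e-10)

  # axis-position differences reproduce the f4-ratio estimate
  alpha <- f4_ratio(fm, "P1", "P2", "XX", "P3", "P4")$alpha
  pos_ratio <- (rr$axis_pos["XX"] - rr$axis_pos["P3"]) /
    (rr$axis_pos["P4"] - rr$axis_pos["P3"])
  expect_equal(unname(pos_ratio), alpha, tolerance = 1e-10)
  expect_equal(unname(pos_ratio), w, tolerance = 1e-10)

  # drift-free mixture stays collinear with its sources in residual space
  seg <- rr$residual_pcs["P4", ] - rr$residual_pcs["P3", ]
  dev <- rr$residual_pcs["XX", ] - (rr$residual_pcs["P3", ] + w * seg)
  expect_lt(sqrt(sum(dev^2)), 1e-8)

  expect_error(residual_rotation(d, "P1", "P1"),
               class = "fp_error_degenerate")
})

test_that("orthogonality_test flags shared vs independent drift", {
  # shared-drift construction: a2, b2 displaced by the same vector
  base <- 0.5 + 0.4 * (unclass(rand_freqs(2, 40, seed = 61)) - 0.5)
  shift <- runif(40, -0.04, 0.04)
  fm <- freq_matrix(rbind(a = base[1, ], a2 = base[1, ] + shift,
                          b = base[2, ], b2 = base[2, ] + shift))
  res <- orthogonality_test(fm, "a", "a2", "b", "b2", tol = 0.1)
  expect_false(res$orthogonal)
  expect_equal(res$cos_phi, 1, tolerance = 1e-10)

  # identical labels: F4 exactly zero
  res0 <- orthogonality_test(fm, "a", "a", "b", "b2")
  expect_identical(res0$f4_value, 0)
  expect_true(res0$orthogonal)

  # independent drift on disjoint branches (large S simulation)
  g <- balanced_tree(tau_int = 0.02, tau_leaf = 0.02)
  sim <- sim_freqs(g, sim_config(S = 100000, seed = 62))
  res_ind <- orthogonality_test(sim$freqs, "L1", "L2", "L3", "L4",
                                tol = 0.1)
  expect_true(res_ind$orthogonal)
})
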