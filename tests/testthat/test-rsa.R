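test_that("theoretical RDM is the Euclidean goal-distance matrix", {
  r <- theoretical_rdm(rbind(c(0, 0), c(3, 4)))
  expect_equal(r[1, 2], 5)
  expect_equal(r[2, 1], 5)
  expect_equal(diag(r), c(0, 0), ignore_attr = TRUE)
  # duplicate goals
  r2 <- theoretical_rdm(rbind(c(1, 2), c(1, 2), c(4, 2)))
  expect_equal(r2[1, 2], 0)
  # 1D goals: |i - j| exhaustively
  g <- matrix(0:5, ncol = 1)
  r3 <- theoretical_rdm(g)
  expect_equal(r3, abs(outer(0:5, 0:5, "-")), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(theoretical_rdm(list(c(1, 2), c(1, 2, 3))), "dimensionalities")
})

test_that("neural RDM is 1 - Pearson r with guarded degenerate input", {
  set.seed(41)
  p <- matrix(rnorm(5 * 30), 5, 30)
  r <- neural_rdm(p)
  expect_equal(r, t(r))
  expect_equal(diag(r), rep(0, 5))
  expect_true(all(r >= 0 & r <= 2))
  # definitional oracle: 1 - cov / (sd * sd)
  for (i in 1:4) for (j in (i + 1):5) {
    expect_equal(r[i, j],
                 1 - cov(p[i, ], p[j, ]) / (sd(p[i, ]) * sd(p[j, ])),
                 tolerance = 1e-10)
  }
  p2 <- rbind(p[1, ], p[1, ], p[2, ])
  expect_equal(neural_rdm(p2)[1, 2], 0)
  p3 <- rbind(p[1, ], -p[1, ], p[2, ])
  expect_equal(neural_rdm(p3)[1, 2], 2)
  p4 <- p; p4[3, ] <- 7
  expect_error(neural_rdm(p4), "path\\(s\\): 3")
  expect_error(neural_rdm(p[1:2, ]), ">= 3 paths")
})

test_that("RDM rank correlation matches oracles and monotone invariance", {
  set.seed(42)
  th <- theoretical_rdm(rbind(c(0, 0), c(1, 3), c(4, 1), c(5, 5)))
  nr <- matrix(0, 4, 4)
  nr[lower.tri(nr)] <- runif(6)
  nr <- nr + t(nr)
  rho <- rdm_spearman(nr, th)
  expect_equal(rho, spearman_oracle(nr[lower.tri(nr)], th[lower.tri(th)]),
               tolerance = 1e-12)
  expect_equal(rho, cor(nr[lower.tri(nr)], th[lower.tri(th)],
                        method = "spearman"), tolerance = 1e-12)
  # monotone transforms leave rho unchanged; order reversal flips the sign
  expect_equal(rdm_spearman(2 * th, th), 1)
  expect_equal(rdm_spearman(max(th) + 1 - th, th), -1)
  for (i in 1:20) {
    a <- runif(1, 0.5, 3); b <- runif(1, 0, 2)
    expect_equal(rdm_spearman(exp(a * nr) + b, th), rho, tolerance = 1e-12)
  }
  # ties: constant triangle is undefined
  cst <- matrix(1, 4, 4); diag(cst) <- 0
  expect_warning(res <- rdm_spearman(cst, th), "constant")
  expect_true(is.na(res))
  expect_error(rdm_spearman(nr, th[1:3, 1:3]), "shapes")
})

test_that("Fisher transform is atanh with clipping", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5493, tolerance = 1e-4)
  expect_equal(fisher_z(-0.73), -fisher_z(0.73))
  expect_true(is.finite(fisher_z(1)) && is.finite(fisher_z(-1)))
  expect_equal(fisher_z(1), atanh(1 - 1e-7))
  expect_true(is.na(fisher_z(NA)))
})

test_that("searchlight center count matches the closed form for box masks", {
  sl <- abstractnav:::searchlight_centers(c(10L, 10L, 10L),
                                          array(TRUE, dim = c(10, 10, 10)),
                                          cube_side = 3L, stride = 1L)
  expect_equal(length(sl$centers_lin), 8^3)
  sl2 <- abstractnav:::searchlight_centers(c(10L, 10L, 10L),
                                           array(TRUE, dim = c(10, 10, 10)),
                                           cube_side = 3L, stride = 2L)
  expect_equal(length(sl2$centers_lin), 4^3)
  # masked corner removes exactly the centers whose cube touches it
  mask <- array(TRUE, dim = c(10, 10, 10))
  mask[1, 1, 1] <- FALSE
  sl3 <- abstractnav:::searchlight_centers(c(10L, 10L, 10L), mask, 3L, 1L)
  expect_equal(length(sl3$centers_lin), 8^3 - 1)
})

test_that("patterns with exact per-cube correlation structure give rho = 1", {
  # two 3-periodic spatial modes are zero-mean and orthogonal inside every
  # 3-cube, so pattern_i = cos(theta_i) a + sin(theta_i) b has pairwise
  # correlation cos(theta_i - theta_j) in every searchlight
  shape <- c(9L, 9L, 9L)
  idx <- arrayInd(seq_len(prod(shape)), shape)
  f3 <- c(1, 0, -1)
  a <- array(f3[(idx[, 1] - 1) %% 3 + 1], dim = shape)
  b <- array(f3[(idx[, 2] - 1) %% 3 + 1], dim = shape)
  goals <- c(0, 1, 3)  # distinct pairwise distances: no rank ties
  theta <- goals / 5 * (pi * 0.9)
  dat <- array(0, dim = c(shape, 3))
  for (i in 1:3) dat[, , , i] <- cos(theta[i]) * a + sin(theta[i]) * b
  pe <- manual_pe_set(dat, as.character(goals), "S1P", 1)
  sl <- searchlight_rsa(pe)
  rho <- sl$rho$exploitation
  expect_equal(sl$n_centers, 7^3)
  expect_equal(unname(rho[!is.na(rho)]), rep(1, 7^3), tolerance = 1e-12)
})

test_that("noise-only volumes give a grand-mean searchlight rho near zero", {
  goals <- rbind(c(5, 5), c(5, 3), c(0, 0), c(2, 5), c(1, 0), c(3, 1))
  set.seed(43)
  means <- vapply(1:50, function(i) {
    dat <- array(rnorm(8^3 * 6), dim = c(8, 8, 8, 6))
    pe <- manual_pe_set(dat, apply(goals, 1, paste, collapse = ";"), "S2C", 2)
    mean(searchlight_rsa(pe)$rho$exploitation, na.rm = TRUE)
  }, numeric(1))
  expect_lt(abs(mean(means)), 0.02)
})

test_that("stage contrast is a voxelwise paired t with missing-data exclusion", {
  shape <- c(6L, 6L, 6L)
  set.seed(44)
  zs <- lapply(1:5, function(i) array(rnorm(prod(shape)), dim = shape))
  same <- stage_contrast(zs, zs)
  expect_equal(unname(same$t_map[!is.na(same$t_map)]),
               rep(0, prod(shape)))
  zb <- lapply(zs, function(z) z + array(rnorm(prod(shape), 0.3), dim = shape))
  con <- stage_contrast(zb, zs)
  d <- sapply(1:5, function(i) zb[[i]][2, 2, 2] - zs[[i]][2, 2, 2])
  expect_equal(con$t_map[2, 2, 2], unname(t.test(d)$statistic))
  # a voxel missing in one subject is excluded everywhere
  zb2 <- zb; zb2[[3]][1, 1, 1] <- NA
  con2 <- stage_contrast(zb2, zs)
  expect_true(is.na(con2$t_map[1, 1, 1]))
  expect_false(anyNA(con2$t_map[2, , ]))
  expect_error(stage_contrast(zb[1], zs[1]), ">= 2 subjects")
})

test_that("paired t of a planted shift matches sampling theory", {
  set.seed(45)
  n <- 25; delta <- 0.3; sigma <- 0.5
  ts <- replicate(100, {
    zs0 <- lapply(1:n, function(i) array(0, dim = c(3, 3, 3)))
    zs1 <- lapply(1:n, function(i)
      array(delta + rnorm(27, 0, sigma), dim = c(3, 3, 3)))
    mean(stage_contrast(zs1, zs0)$t_map)
  })
  expected <- delta * sqrt(n) / sigma
  expect_lt(abs(mean(ts) - expected), 2 * sd(ts) / sqrt(100) + 0.25)
})

test_that("TFCE matches closed-form and decomposition oracles", {
  shape <- c(8L, 8L, 8L)
  z <- array(0, dim = shape)
  expect_equal(tfce(z), z)
  # single isolated voxel
  z1 <- z; z1[4, 4, 4] <- 2.5
  e1 <- tfce(z1)
  expect_equal(e1[4, 4, 4], single_voxel_tfce(2.5))
  expect_equal(sum(e1 != 0), 1)
  # dh -> 0 converges to h^3 / 3
  expect_equal(tfce(z1, dh = 0.001)[4, 4, 4], 2.5^3 / 3, tolerance = 1e-2)
  # negative values enhanced on the negated map
  zneg <- -z1
  expect_equal(tfce(zneg)[4, 4, 4], -single_voxel_tfce(2.5))
  # two disconnected clusters enhance independently
  z2 <- z
  z2[2:3, 2, 2] <- 1.8
  z2[6:7, 6, 6] <- c(1.2, 0.7)
  za <- z; za[2:3, 2, 2] <- 1.8
  zb <- z; zb[6:7, 6, 6] <- c(1.2, 0.7)
  expect_equal(tfce(z2), tfce(za) + tfce(zb))
  # 6- vs 26-connectivity: diagonal neighbours merge only under 26
  z3 <- z
  z3[2, 2, 2] <- 1; z3[3, 3, 3] <- 1
  e6 <- tfce(z3, connectivity = 6)
  e26 <- tfce(z3, connectivity = 26)
  expect_equal(e6[2, 2, 2], single_voxel_tfce(1))
  expect_gt(e26[2, 2, 2], e6[2, 2, 2])  # extent 2 at every threshold
  expect_equal(e26[2, 2, 2], sum(2^0.5 * (seq(0.1, 1, 0.1))^2 * 0.1))
})

test_that("sign-flip permutation inference is seeded, calibrated and exact when small", {
  shape <- c(6L, 6L, 6L)
  set.seed(46)
  diffs <- t(sapply(1:10, function(i) rnorm(prod(shape), 0, 0.3)))
  g1 <- permutation_fwe(diffs, shape = shape, n_perm = 200, seed = 3)
  g2 <- permutation_fwe(diffs, shape = shape, n_perm = 200, seed = 3)
  expect_identical(g1$p_map, g2$p_map)
  expect_gte(min(g1$p_map), 1 / 201)
  expect_true(all(g1$p_map <= 1))
  # exhaustive enumeration kicks in for tiny cohorts
  g3 <- permutation_fwe(diffs[1:4, ], shape = shape, n_perm = 500, seed = 3)
  expect_true(g3$exhaustive)
  expect_equal(g3$n_perm, 16L)
  expect_gte(min(g3$p_map), 1 / 16)
})

test_that("family-wise error is controlled on pure-noise differences", {
  shape <- c(6L, 6L, 6L)
  set.seed(47)
  any_sig <- vapply(1:120, function(i) {
    diffs <- t(sapply(1:8, function(j) rnorm(prod(shape), 0, 1)))
    g <- permutation_fwe(diffs, shape = shape, n_perm = 99, seed = i)
    any(g$p_map < 0.05)
  }, logical(1))
  expect_lte(mean(any_sig), 0.10)
})

test_that("a strong planted effect is detected with FWE correction", {
  shape <- c(8L, 8L, 8L)
  reg <- array(FALSE, dim = shape); reg[3:6, 3:6, 3:6] <- TRUE
  set.seed(48)
  diffs <- t(sapply(1:25, function(i) {
    d <- array(rnorm(prod(shape), 0, 0.2), dim = shape)
    d[reg] <- d[reg] + 0.6   # delta = 3 sigma
    as.numeric(d)
  }))
  g <- permutation_fwe(diffs, shape = shape, n_perm = 500, seed = 4)
  expect_gte(mean(g$p_map[reg] < 0.05), 0.9)
  expect_lte(mean(g$p_map[!reg] < 0.05), 0.05)
})
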