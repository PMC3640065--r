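test_that("forward signal follows the Stejskal-Tanner relation", {
  sc <- test_scheme()
  expect_equal(forward_signal(rep(0, 6), sc), rep(1, sc$J))
  # isotropic tensor: identical attenuation along every direction
  d <- 1e-3
  expect_equal(forward_signal(c(d, d, d, 0, 0, 0), sc),
               rep(exp(-700 * d), sc$J))
  # hand evaluation: D = diag(1.7, .2, .2)e-3, b = 700, g = x-axis
  gx <- gradient_scheme(700, rbind(c(1, 0, 0),
                                   gradient_table_repulsion(8, seed = 2)))
  S <- forward_signal(c(1.7e-3, 2e-4, 2e-4, 0, 0, 0), gx)
  expect_equal(S[1], exp(-1.19), tolerance = 1e-12)
})

test_that("noiseless signals invert to the generating tensor", {
  sc <- test_scheme()
  set.seed(1)
  for (i in 1:100) {
    d6 <- random_pd_tensor()
    d6_hat <- fit_tensor_lls(forward_signal(d6, sc), sc)
    expect_equal(d6_hat, d6, tolerance = 1e-10)
  }
  # S == 1 everywhere is the zero tensor
  d0 <- fit_tensor_lls(rep(1, sc$J), sc)
  expect_equal(d0, rep(0, 6), tolerance = 1e-12)
  expect_equal(md_from_eigenvalues(tensor_eigenvalues(d0)), 0,
               tolerance = 1e-12)
})

test_that("degenerate gradient tables are rejected with the condition number", {
  g <- matrix(rep(c(1, 0, 0), 8), ncol = 3, byrow = TRUE)
  sc <- gradient_scheme(700, g)
  expect_error(fit_tensor_lls(rep(0.5, 8), sc), "condition number")
})

test_that("closed-form eigenvalues agree with eigen()", {
  set.seed(2)
  for (i in 1:50) {
    d6 <- random_pd_tensor()
    ev <- tensor_eigenvalues(d6)
    ref <- eigen(matrix(c(d6[1], d6[4], d6[5],
                          d6[4], d6[2], d6[6],
                          d6[5], d6[6], d6[3]), 3), symmetric = TRUE,
                 only.values = TRUE)$values
    expect_equal(drop(ev), ref, tolerance = 1e-9)
    expect_true(all(diff(drop(ev)) <= 1e-12))  # descending order
  }
})

test_that("FA and MD match their eigenvalue definitions", {
  # anisotropic hand case: lambda = (1.7, 0.2, 0.2)e-3
  ev <- c(1.7e-3, 0.2e-3, 0.2e-3)
  expect_equal(fa_from_eigenvalues(ev), 0.870388, tolerance = 1e-6)
  expect_equal(md_from_eigenvalues(ev), 0.7e-3, tolerance = 1e-12)
  # limits
  expect_equal(fa_from_eigenvalues(c(1e-3, 1e-3, 1e-3)), 0)
  expect_equal(fa_from_eigenvalues(c(1e-3, 0, 0)), 1)
  expect_equal(fa_from_eigenvalues(c(0, 0, 0)), 0)
})

test_that("FA is rotation invariant and monotone in eigenvalue ratio", {
  set.seed(3)
  for (i in 1:20) {
    d6 <- random_pd_tensor()
    R <- random_rotation()
    D <- matrix(c(d6[1], d6[4], d6[5],
                  d6[4], d6[2], d6[6],
                  d6[5], d6[6], d6[3]), 3)
    Dr <- R %*% D %*% t(R)
    d6r <- c(Dr[1, 1], Dr[2, 2], Dr[3, 3], Dr[1, 2], Dr[1, 3], Dr[2, 3])
    expect_equal(fa_from_eigenvalues(tensor_eigenvalues(d6r)),
                 fa_from_eigenvalues(tensor_eigenvalues(d6)),
                 tolerance = 1e-10)
  }
  # increasing lambda1/lambda3 at fixed MD increases FA
  md <- 0.7e-3
  ratios <- c(1.5, 3, 6, 12, 24)
  fas <- vapply(ratios, function(r) {
    l3 <- 3 * md / (r + 2); l1 <- r * l3
    fa_from_eigenvalues(c(l1, l3, l3))
  }, numeric(1))
  expect_true(all(diff(fas) > 0))
})

test_that("normalization divides by b0 and drops non-positive b0 voxels", {
  ph <- test_phantom_clean()
  st <- ph$study
  # DWI == b0 everywhere gives S == 1
  st1 <- st
  for (j in seq_len(st$scheme$J)) st1$dwis[, , , j] <- st1$b0
  nz1 <- normalize_signals(st1)
  expect_true(all(abs(nz1$s_measured[st1$b0[nz1$idx] > 0, ] - 1) < 1e-12))
  # forward-model agreement on the clean phantom
  nz <- normalize_signals(st)
  lab <- st$labels[nz$idx]
  pred <- forward_signal(ph$truth$tensors, st$scheme)
  expect_equal(nz$s_measured, pred[lab, ], tolerance = 1e-10,
               ignore_attr = TRUE)
  # a zeroed b0 voxel is excluded and counted
  st2 <- st
  v <- which(st2$mask)[1]
  st2$b0[v] <- 0
  nz2 <- normalize_signals(st2)
  expect_equal(nz2$n_b0_dropped, 1L)
  expect_false(v %in% nz2$idx)
  # empty mask errors
  st3 <- st; st3$mask[] <- FALSE
  expect_error(normalize_signals(st3), "empty mask")
})

test_that("signal clamping makes non-positive signals fittable", {
  s <- c(0.5, 0.4, -0.1, 0, NA, 0.3, 0.2, 0.25)
  cl <- dtiqa:::clamp_signals(s)
  expect_true(all(cl > 0))
  expect_equal(cl[c(3, 4, 5)], rep(0.1, 3))  # half the smallest positive
  expect_equal(cl[-c(3, 4, 5)], s[-c(3, 4, 5)])
})

test_that("residual-outlier counts isolate a corrupted gradient", {
  clean_fit <- fit_study(test_phantom_clean()$study)
  expect_equal(outlier_voxels_per_dwi(clean_fit, noise_sigma = 10),
               rep(0L, clean_fit$scheme$J))
  # halve one gradient inside the brain; the unweighted refit smears some
  # misfit onto other gradients, but the corrupted DWI clearly dominates
  sp <- phantom_spec(grid_shape = c(24L, 24L, 24L), seed = 101L,
                     artifacts = list(list(type = "gradient_dropout",
                                           j = 5L, factor = 0.5)))
  fit <- fit_study(generate_phantom(sp)$study)
  cnt <- outlier_voxels_per_dwi(fit, noise_sigma = 25)
  expect_equal(which.max(cnt), 5L)
  expect_gt(cnt[5], 3 * max(cnt[-5]))
  # infinite threshold: no outliers anywhere
  expect_equal(outlier_voxels_per_dwi(fit, 25, threshold = Inf),
               rep(0L, fit$scheme$J))
  expect_error(outlier_voxels_per_dwi(fit, noise_sigma = 0), "positive")
})
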