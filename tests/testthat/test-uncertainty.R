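test_that("zero residuals give zero sigma_FA; results are seed-reproducible", {
  sc <- test_scheme()
  s <- forward_signal(dtiqa:::tensor_from_fa_md(0.5, 0.7e-3, c(1, 0, 0)), sc)
  bt <- wild_bootstrap_fa(s, sc, n_reps = 200L, seed = 1L)
  expect_equal(bt$sigma_fa, 0)
  set.seed(8)
  sm <- dtiqa:::rician(s * 1000, 50) / 1000
  a <- wild_bootstrap_fa(sm, sc, n_reps = 300L, seed = 4L)
  b <- wild_bootstrap_fa(sm, sc, n_reps = 300L, seed = 4L)
  c <- wild_bootstrap_fa(sm, sc, n_reps = 300L, seed = 5L)
  expect_identical(a$sigma_fa, b$sigma_fa)
  expect_false(identical(a$sigma_fa, c$sigma_fa))
  # doubling reps moves the estimate by less than its own Monte-Carlo scale
  d <- wild_bootstrap_fa(sm, sc, n_reps = 600L, seed = 4L)
  expect_lt(abs(d$sigma_fa - a$sigma_fa), 0.25 * a$sigma_fa)
})

test_that("sigma_FA decreases with more gradient directions at fixed SNR", {
  b0i <- 1000; sigma <- 100
  est <- vapply(c(15L, 60L), function(J) {
    sc <- gradient_scheme(700, gradient_table_repulsion(J, seed = 7))
    d6 <- dtiqa:::tensor_from_fa_md(0.4, 0.7e-3, c(1, 0, 0))
    s_true <- forward_signal(d6, sc)
    set.seed(J)
    mean(replicate(8, {
      acq <- acquire_voxel(s_true, b0i, sigma)
      wild_bootstrap_fa(acq$s_m, sc, n_reps = 400L,
                        seed = sample.int(1e6, 1))$sigma_fa
    }))
  }, numeric(1))
  expect_gt(est[1], est[2])
})

test_that("SIMEX geometry: flat trends extrapolate to themselves; sigma 0 short-circuits", {
  sc <- test_scheme()
  d6 <- dtiqa:::tensor_from_fa_md(0.3, 0.7e-3, c(1, 0, 0))
  dwi <- forward_signal(d6, sc) * 1000
  sx0 <- simex_bias_fa(dwi, 1000, sc, sigma_hat = 0, seed = 1L)
  expect_true(sx0$flagged)
  expect_equal(sx0$bias_fa, 0)
  # tiny noise: trend is nearly flat, bias near zero
  sx <- simex_bias_fa(dwi, 1000, sc, sigma_hat = 1,
                      reps = rep(200L, 4L), seed = 2L)
  expect_lt(abs(sx$bias_fa), 5e-3)
  a <- simex_bias_fa(dwi, 1000, sc, 50, reps = rep(100L, 4L), seed = 3L)
  b <- simex_bias_fa(dwi, 1000, sc, 50, reps = rep(100L, 4L), seed = 3L)
  expect_identical(a$bias_fa, b$bias_fa)
})

test_that("SIMEX recovers the empirical FA bias in its moderate-SNR domain", {
  # SNR 20: bias is the few-percent scale seen in vivo, where the
  # quadratic extrapolation is accurate
  sc <- test_scheme()
  b0i <- 1000; sigma <- 50
  d6 <- dtiqa:::tensor_from_fa_md(0.3, 0.7e-3, c(1, 0, 0))
  s_true <- forward_signal(d6, sc)
  set.seed(41)
  fa_emp <- replicate(1500, {
    acq <- acquire_voxel(s_true, b0i, sigma)
    dtiqa:::fa_from_tensor(fit_tensor_lls(acq$s_m, sc))
  })
  emp_bias <- mean(fa_emp) - 0.3
  set.seed(42)
  sx <- replicate(10, {
    acq <- acquire_voxel(s_true, b0i, sigma)
    simex_bias_fa(acq$dwi, acq$b0, sc, sigma_hat = sigma,
                  reps = rep(200L, 4L), seed = sample.int(1e6, 1))$bias_fa
  })
  expect_gt(emp_bias, 0.005)               # noise inflates anisotropy
  expect_lt(abs(mean(sx) - emp_bias), 0.01)
})

test_that("FA bias is positive for low-FA low-SNR voxels", {
  sc <- test_scheme()
  d6 <- dtiqa:::tensor_from_fa_md(0.2, 0.7e-3, c(0, 1, 0))
  s_true <- forward_signal(d6, sc)
  set.seed(43)
  sx <- replicate(8, {
    acq <- acquire_voxel(s_true, 1000, 100)
    simex_bias_fa(acq$dwi, acq$b0, sc, sigma_hat = 100,
                  reps = rep(150L, 4L), seed = sample.int(1e6, 1))$bias_fa
  })
  expect_gt(mean(sx), 0)
})

test_that("the per-voxel driver joins sample, bootstrap and SIMEX results", {
  ph <- test_phantom()
  fit <- test_fit()
  vs <- subsample_voxels(ph$study$labels, ph$study$mask,
                         target_fraction = 1e-6, min_per_region = 2L,
                         seed = 3L)
  unc <- estimate_uncertainty(ph$study, fit, vs,
                              sigma_hat = ph$truth$sigma,
                              n_boot = 60L, simex_reps = rep(60L, 4L),
                              seed = 4L)
  expect_equal(nrow(unc), length(vs$indices))
  expect_true(all(is.finite(unc$sigma_fa)))
  expect_true(all(is.finite(unc$bias_fa)))
  expect_true(all(unc$sigma_fa >= 0))
  # reproducible under the same master seed
  unc2 <- estimate_uncertainty(ph$study, fit, vs,
                               sigma_hat = ph$truth$sigma,
                               n_boot = 60L, simex_reps = rep(60L, 4L),
                               seed = 4L)
  expect_identical(unc$sigma_fa, unc2$sigma_fa)
})
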