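test_that("pixel chi-squared matches hand arithmetic and scales in residuals", {
  expect_equal(chi_pixel(c(0.5, 0.5), c(0.4, 0.6)), 0.08)
  expect_equal(chi_pixel(c(0.5, 0.5), c(0.5, 0.5)), 0)
  # doubling all residuals quadruples the statistic
  s_m <- c(0.5, 0.4, 0.3, 0.6)
  r <- c(0.02, -0.03, 0.01, -0.02)
  expect_equal(chi_pixel(s_m, s_m - 2 * r), 4 * chi_pixel(s_m, s_m - r))
  expect_true(is.na(chi_pixel(c(0, 0), c(0.1, 0.2))))
})

test_that("slice chi-squared applies the J/K compatibility factor", {
  # K = 2 in-mask voxels, J = 4; per-voxel normalized squared errors
  # 0.02 and 0.06 on one slice: (4/2) * 0.08 = 0.16
  s_m <- rbind(rep(0.5, 4), rep(0.5, 4))
  # split 0.02 and 0.06 across the 4 gradients of each voxel
  s_f <- rbind(rep(0.5 - sqrt(0.02 / 4) * 0.5, 4),
               rep(0.5 - sqrt(0.06 / 4) * 0.5, 4))
  fake_fit <- list(scheme = list(J = 4L), dim = c(1L, 2L, 3L),
                   coords = cbind(1L, 1:2, c(2L, 2L)),
                   s_measured = s_m, s_fitted = s_f)
  cs <- chi_slice_matrix(fake_fit)
  expect_equal(dim(cs), c(3L, 4L))
  expect_equal(sum(cs[2, ]), 0.16, tolerance = 1e-12)
  expect_true(all(is.na(cs[c(1, 3), ])))  # slices with no in-mask voxels
})

test_that("chi metrics are invariant to global intensity scaling", {
  st <- test_phantom()$study
  st2 <- st
  st2$b0 <- st$b0 * 3.7
  st2$dwis <- st$dwis * 3.7
  f1 <- fit_study(st); f2 <- fit_study(st2)
  g1 <- chi_square_maps(f1); g2 <- chi_square_maps(f2)
  expect_equal(g1$chi_pix, g2$chi_pix, tolerance = 1e-10)
  expect_equal(g1$chi_slice, g2$chi_slice, tolerance = 1e-10)
})

test_that("an injected slice artifact is the chi-slice matrix maximum", {
  sp <- phantom_spec(grid_shape = c(24L, 24L, 24L), noise_sigma = 5,
                     seed = 33L,
                     artifacts = list(list(type = "slice_artifact",
                                           z = 10L, j = 3L, offset = 400)))
  fit <- fit_study(generate_phantom(sp)$study)
  cs <- chi_slice_matrix(fit)
  peak <- which(cs == max(cs, na.rm = TRUE), arr.ind = TRUE)
  expect_equal(unname(peak[1, ]), c(10L, 3L))
})

test_that("a corrupted gradient stripes its chi-slice column", {
  sp <- phantom_spec(grid_shape = c(24L, 24L, 24L), noise_sigma = 5,
                     seed = 34L,
                     artifacts = list(list(type = "gradient_dropout",
                                           j = 7L, factor = 0.5)))
  fit <- fit_study(generate_phantom(sp)$study)
  cs <- chi_slice_matrix(fit)
  col_means <- colMeans(cs, na.rm = TRUE)
  expect_gt(col_means[7], quantile(col_means[-7], 0.95))
})

test_that("chi histogram finds the noise lobe when air is in the mask", {
  # noiseless fit: a single mode at zero and no noise lobe
  h0 <- chi_histogram(chi_square_maps(fit_study(
    test_phantom_clean()$study))$chi_pix)
  expect_lt(h0$signal_mode, 1e-10)
  expect_true(is.na(h0$noise_mode))
  ph <- test_phantom()
  st <- ph$study
  # let some air into the mask: bimodal, noise mode above signal mode
  st2 <- st
  bg <- which(!st$mask)
  set.seed(9)
  st2$mask[sample(bg, 800)] <- TRUE
  g2 <- chi_square_maps(fit_study(st2))
  h2 <- chi_histogram(g2$chi_pix)
  expect_gt(h2$noise_mode, h2$signal_mode)
  # zoom lower bound is monotone in the percentile parameter
  z90 <- chi_histogram(g2$chi_pix, prob = 0.90)$zoom_window[1]
  z99 <- chi_histogram(g2$chi_pix, prob = 0.99)$zoom_window[1]
  expect_lt(z90, z99)
})

test_that("best/worst slice selection honors bands and tie-breaking", {
  m <- matrix(1, 20, 6)  # all ties
  bw <- best_worst_slices(m, n_bands = 5L, n_each = 3L)
  b1 <- bw[bw$band == 1 & bw$kind == "best", ]
  expect_equal(b1$z, c(1L, 1L, 1L))
  expect_equal(b1$dwi, 1:3)   # (z, j) order breaks ties
  expect_equal(nrow(bw), 5L * 2L * 3L)
  # injected artifact appears in exactly one band's worst list
  m2 <- m; m2[9, 4] <- 50
  bw2 <- best_worst_slices(m2, n_bands = 5L, n_each = 3L)
  hit <- bw2[bw2$kind == "worst" & bw2$chi == 50, ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$z, 9L)
  # short band flagged, not an error
  m3 <- matrix(NA_real_, 10, 3); m3[1:2, 1] <- 1
  bw3 <- best_worst_slices(m3, n_bands = 5L, n_each = 5L)
  expect_true(length(attr(bw3, "short_bands")) >= 1L)
})
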