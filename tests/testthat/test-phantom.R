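test_that("phantom generation is seed-deterministic with shared truth", {
  sp <- phantom_spec(grid_shape = c(16L, 16L, 16L), seed = 5L)
  a <- generate_phantom(sp)
  b <- generate_phantom(sp)
  expect_identical(a$study$dwis, b$study$dwis)
  expect_identical(a$study$b0, b$study$b0)
  sp2 <- sp; sp2$seed <- 6L
  c <- generate_phantom(sp2)
  expect_false(identical(a$study$dwis, c$study$dwis))
  expect_identical(a$truth$tensors, c$truth$tensors)
})

test_that("noiseless phantom signals invert to every region tensor", {
  ph <- test_phantom_clean()
  fit <- fit_study(ph$study)
  lab <- ph$study$labels[fit$idx]
  for (r in 1:25) {
    rows <- which(lab == r)
    expect_equal(fit$d6[rows[1], ], ph$truth$tensors[r, ],
                 tolerance = 1e-8, ignore_attr = TRUE)
    expect_equal(fit$fa[rows[1]], ph$truth$region_table$fa[r],
                 tolerance = 1e-6)
  }
})

test_that("stacked Rician noise has the Rayleigh background mean", {
  ph <- generate_phantom(phantom_spec(grid_shape = c(32L, 32L, 32L),
                                      noise_sigma = 25, seed = 9L))
  bg <- !ph$study$mask
  expect_gt(sum(bg), 1e4)
  # zero-signal Rician is Rayleigh with mean sigma * sqrt(pi/2)
  expect_equal(mean(ph$study$b0[bg]), 25 * sqrt(pi / 2), tolerance = 0.02)
  # high-SNR in-mask SD approaches sigma (Gaussian limit)
  expect_equal(sd(ph$study$b0[ph$study$mask]), 25, tolerance = 0.05)
})

test_that("artifact injections do what they claim", {
  sp <- phantom_spec(grid_shape = c(16L, 16L, 16L), seed = 5L,
                     artifacts = list(
                       list(type = "gradient_dropout", j = 5L, factor = 0),
                       list(type = "slice_artifact", z = 8L, j = 3L,
                            offset = 500),
                       list(type = "motion_row", j = 7L,
                            params = c(2, 0, 0, 0, 0, 5))))
  ph <- generate_phantom(sp)
  m <- ph$study$mask
  expect_true(all(ph$study$dwis[, , , 5][m] == 0))
  base <- generate_phantom(phantom_spec(grid_shape = c(16L, 16L, 16L),
                                        seed = 5L))
  msl <- m[, , 8]
  expect_equal(ph$study$dwis[, , 8, 3][msl],
               pmax(base$study$dwis[, , 8, 3][msl] + 500, 0))
  expect_equal(ph$study$motion$tx_mm[7], 2)
  expect_equal(ph$study$motion$rz_deg[7], 5)
})

test_that("region geometry tiles the mask with adequately sized regions", {
  geo <- phantom_labels(c(24L, 24L, 24L))
  expect_equal(sort(unique(geo$labels[geo$labels > 0])), 1:25)
  expect_true(all(geo$labels[!geo$mask] == 0))
  expect_true(all(table(geo$labels[geo$labels > 0]) >= 50))
  expect_equal(length(unique(geo$region_table$pooled)), 14L)
})

test_that("cohorts record protocol membership and noise scaling", {
  spA <- phantom_spec(grid_shape = c(16L, 16L, 16L), seed = 1L)
  spB <- phantom_spec(grid_shape = c(16L, 16L, 16L), b_value = 2000,
                      n_gradients = 12L, seed = 1L)
  co <- generate_cohort(spA, spB, n_a = 2L, n_b = 2L, seed = 3L,
                        noise_scale = c(1, 3, 1, 1))
  expect_length(co$studies, 4L)
  expect_equal(co$truth_table$protocol, c("A", "A", "B", "B"))
  expect_equal(co$truth_table$noise_sigma[2],
               3 * co$truth_table$noise_sigma[1])
  expect_equal(co$studies[[3]]$scheme$b_value, 2000)
  expect_equal(co$studies[[3]]$scheme$J, 12L)
  # fresh seeds per member: protocol-identical members differ in noise
  expect_false(identical(co$studies[[3]]$dwis, co$studies[[4]]$dwis))
})
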