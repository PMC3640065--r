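# Independent brute-force oracles shared by unit and acceptance tests.

# rejection rate of an actually-simulated two-sample two-sided t-test
simulate_power <- function(es, n, s, delta_b, alpha = 0.05, n_sim = 1e5) {
  x <- matrix(stats::rnorm(n * n_sim, mean = es + delta_b, sd = s), n)
  y <- matrix(stats::rnorm(n * n_sim, mean = 0, sd = s), n)
  mx <- colMeans(x); my <- colMeans(y)
  vx <- colSums((x - rep(mx, each = n))^2)
  vy <- colSums((y - rep(my, each = n))^2)
  sp <- sqrt((vx + vy) / (2 * n - 2))
  tt <- (mx - my) / (sp * sqrt(2 / n))
  mean(abs(tt) > stats::qt(1 - alpha / 2, 2 * n - 2))
}

# single-voxel acquisition emulation: Rician DWIs at the given sigma and a
# b0 acquired with five signal averages (as in the reference protocol)
acquire_voxel <- function(s_true, b0i, sigma) {
  dwi <- dtiqa:::rician(s_true * b0i, sigma)
  b0 <- mean(dtiqa:::rician(rep(b0i, 5L), sigma))
  list(dwi = dwi, b0 = b0, s_m = dwi / b0)
}

# study whose regional DWI standard deviations are exactly `sds`
make_engineered_sd_study <- function(sds = 1:25) {
  geo <- phantom_labels(c(24L, 24L, 24L))
  sc <- test_scheme(J = 8L)
  dim3 <- dim(geo$labels)
  dwis <- array(0, c(dim3, sc$J))
  set.seed(77)
  for (r in seq_along(sds)) {
    vox <- which(geo$labels == r)
    for (j in seq_len(sc$J)) {
      v <- stats::rnorm(length(vox))
      v <- (v - mean(v)) / stats::sd(v)        # exact unit SD
      dwis[vox + (j - 1L) * prod(dim3)] <- 500 + sds[r] * v
    }
  }
  b0 <- array(0, dim3); b0[geo$mask] <- 1000
  new_dwi_study(b0 = b0, dwis = pmax(dwis, 0), mask = geo$mask,
                labels = geo$labels, scheme = sc)
}
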