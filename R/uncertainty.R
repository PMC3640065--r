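# Monte-Carlo uncertainty at sampled voxels: wild-bootstrap estimates of
# the FA standard deviation and SIMEX estimates of FA bias under a stacked
# Rician noise model.

#' Wild-bootstrap estimate of the FA standard deviation
#'
#' Fits the voxel once, takes the absolute residuals eps_j = |S_m,j -
#' S_f,j|, and for each Monte-Carlo replicate shuffles the J residuals and
#' assigns each an independent random sign: S_bs = S_f +/- eps_shuffle
#' (the random sign is what makes the bootstrap "wild"; the shuffle is
#' retained as part of this pipeline's definition). Each replicate is
#' clamped to positivity with the same rule as the primary fit, refit by
#' log-linear least squares, and its FA recorded; sigma_FA is the sample
#' SD of the resulting FA population.
#'
#' @param s_m Length-J vector of measured normalized signals.
#' @param scheme A [gradient_scheme()].
#' @param n_reps Monte-Carlo replicates (default 1000).
#' @param seed Integer seed.
#' @param keep_population Retain the bootstrap FA samples.
#' @return List of class `bootstrap_result`: `sigma_fa`, `fa`, `n_reps`,
#'   `n_dropped`, `flagged` (TRUE when more than 10% of replicates were
#'   dropped), optionally `fa_population`.
#' @export
wild_bootstrap_fa <- function(s_m, scheme, n_reps = 1000L, seed = 1L,
                              keep_population = FALSE) {
  s_m <- clamp_signals(s_m)
  d6 <- fit_tensor_lls(s_m, scheme)
  s_f <- forward_signal(d6, scheme)
  eps <- abs(s_m - s_f)
  J <- scheme$J
  fa_pop <- withr_seed(seed, {
    perm <- matrix(0, J, n_reps)
    for (r in seq_len(n_reps)) perm[, r] <- eps[sample.int(J)]
    signs <- matrix(sample(c(-1, 1), J * n_reps, replace = TRUE), J, n_reps)
    s_bs <- s_f + signs * perm
    fa_from_tensor(fit_tensor_lls(t(s_bs), scheme))
  })
  ok <- is.finite(fa_pop)
  n_drop <- sum(!ok)
  res <- list(sigma_fa = stats::sd(fa_pop[ok]),
              fa = fa_from_eigenvalues(tensor_eigenvalues(d6)),
              n_reps = n_reps, n_dropped = n_drop,
              flagged = n_drop > 0.1 * n_reps)
  if (all(eps == 0)) res$sigma_fa <- 0
  if (keep_population) res$fa_population <- fa_pop[ok]
  structure(res, class = "bootstrap_result")
}

#' SIMEX estimate of FA bias
#'
#' Simulation-extrapolation: corrupts the un-normalized DWI intensities
#' and the b0 with additional Rician noise of variance omega * sigma_hat^2
#' (so the corrupted data has total noise variance (1 + omega) *
#' sigma_hat^2), refits FA for each corruption, models the trend of the
#' mean FA against omega with an order-2 polynomial anchored at the
#' measured value (omega = 0), and extrapolates to the zero-total-noise
#' point omega = -1. The bias estimate is measured FA minus extrapolated
#' FA.
#'
#' @param dwi_m Length-J vector of un-normalized DWI intensities.
#' @param b0 Scalar b0 intensity (> 0).
#' @param scheme A [gradient_scheme()].
#' @param sigma_hat Estimated noise SD in image units.
#' @param omegas Additional-noise variance multipliers (default 2, 4, 6,
#'   8).
#' @param reps Monte-Carlo iterations per omega (default 2000, 4000,
#'   6000, 8000).
#' @param seed Integer seed.
#' @return List of class `simex_result`: `bias_fa`, `fa_measured`,
#'   `fa_extrapolated`, `omegas`, `fa_trend` (mean FA at 0 and each
#'   omega), `flagged` (TRUE when `sigma_hat` is 0 and no simulation was
#'   run).
#' @export
simex_bias_fa <- function(dwi_m, b0, scheme, sigma_hat,
                          omegas = c(2, 4, 6, 8),
                          reps = c(2000L, 4000L, 6000L, 8000L),
                          seed = 1L) {
  stopifnot(length(omegas) == length(reps), b0 > 0, sigma_hat >= 0)
  s_m <- dwi_m / b0
  fa_meas <- fa_from_tensor(fit_tensor_lls(s_m, scheme))
  if (sigma_hat == 0) {
    return(structure(list(bias_fa = 0, fa_measured = fa_meas,
                          fa_extrapolated = fa_meas, omegas = omegas,
                          fa_trend = rep(fa_meas, length(omegas) + 1L),
                          flagged = TRUE), class = "simex_result"))
  }
  if (length(omegas) < 2L)
    stop("order-2 extrapolation needs at least 3 distinct omega points")
  J <- scheme$J
  fa_mean <- withr_seed(seed, {
    vapply(seq_along(omegas), function(i) {
      sd_add <- sqrt(omegas[i]) * sigma_hat
      n <- reps[i]
      dwi_w <- matrix(rician(rep(dwi_m, n), sd_add), J, n)
      b0_w <- rician(rep(b0, n), sd_add)
      s <- t(dwi_w) / b0_w
      mean(fa_from_tensor(fit_tensor_lls(s, scheme)), na.rm = TRUE)
    }, numeric(1))
  })
  om <- c(0, omegas)
  tr <- c(fa_meas, fa_mean)
  cf <- stats::lm.fit(cbind(1, om, om^2), tr)$coefficients
  fa_ext <- unname(cf[1] - cf[2] + cf[3])
  structure(list(bias_fa = fa_meas - fa_ext, fa_measured = fa_meas,
                 fa_extrapolated = fa_ext, omegas = omegas, fa_trend = tr,
                 flagged = FALSE), class = "simex_result")
}

#' Run bootstrap and SIMEX over a voxel sample
#'
#' Applies [wild_bootstrap_fa()] and [simex_bias_fa()] at every sampled
#' voxel, with per-voxel seeds split deterministically from `seed`.
#'
#' @param study A `dwi_study`.
#' @param fit The study's `dti_tensor_fit`.
#' @param sample A `voxel_sample` from [subsample_voxels()].
#' @param sigma_hat Noise SD (e.g. `estimate_noise(study)$chosen_sigma`).
#' @param n_boot Bootstrap replicates per voxel.
#' @param omegas,simex_reps SIMEX settings (see [simex_bias_fa()]).
#' @param seed Master seed.
#' @param run_simex Set FALSE to skip bias estimation (B_FA reported NA).
#' @return Data frame with one row per sampled voxel: `voxel_index`,
#'   `region`, `fa`, `md`, `sigma_fa`, `bias_fa`, `boot_flagged`.
#' @export
estimate_uncertainty <- function(study, fit, sample, sigma_hat,
                                 n_boot = 1000L,
                                 omegas = c(2, 4, 6, 8),
                                 simex_reps = c(2000L, 4000L, 6000L, 8000L),
                                 seed = 1L, run_simex = TRUE) {
  rows <- match(sample$indices, fit$idx)
  keep <- !is.na(rows)
  rows <- rows[keep]
  vox <- sample$indices[keep]
  reg <- sample$region[keep]
  nv <- length(rows)
  seeds <- withr_seed(seed, matrix(sample.int(2147483L, 2L * nv), nv, 2L))
  nvox <- prod(fit$dim)
  b0v <- study$b0[vox]
  out <- data.frame(voxel_index = vox, region = reg,
                    fa = fit$fa[rows], md = fit$md[rows],
                    sigma_fa = NA_real_, bias_fa = NA_real_,
                    boot_flagged = FALSE)
  for (i in seq_len(nv)) {
    sm <- fit$s_measured[rows[i], ]
    bt <- wild_bootstrap_fa(sm, fit$scheme, n_reps = n_boot,
                            seed = seeds[i, 1])
    out$sigma_fa[i] <- bt$sigma_fa
    out$boot_flagged[i] <- bt$flagged
    if (run_simex) {
      dwi_m <- sm * b0v[i]
      sx <- simex_bias_fa(dwi_m, b0v[i], fit$scheme, sigma_hat,
                          omegas = omegas, reps = simex_reps,
                          seed = seeds[i, 2])
      out$bias_fa[i] <- sx$bias_fa
    }
  }
  out
}
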