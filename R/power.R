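# Bias-aware power for a two-sided two-sample t-test, per voxel and
# summarized per region.

#' Power of a two-sided two-sample t-test with a bias difference
#'
#' For two groups of size n with common SD s and a between-group bias
#' difference delta_b, the test statistic follows a noncentral t with
#' df = 2n - 2 and noncentrality (es + delta_b) / (s * sqrt(2/n)):
#' power = 1 - T(t_crit; df, ncp) + T(-t_crit; df, ncp), with t_crit the
#' central-t (1 - alpha/2) quantile. With delta_b = 0 this is the
#' textbook two-sample power equation; bias shifts the curve minimum from
#' ES = 0 to ES = -delta_b, where power equals `alpha_nom`.
#'
#' @param es Effect size(s) in FA units (vectorized).
#' @param n Per-group sample size (>= 2).
#' @param s Common estimated SD (> 0; 0 is handled as a degenerate limit
#'   with a warning).
#' @param delta_b Bias difference between groups (worst case: the voxel's
#'   B_FA).
#' @param alpha_nom Nominal false-positive rate (default 0.05).
#' @return Power values in \[0, 1\], same length as `es`.
#' @export
power_two_sided_t <- function(es, n, s, delta_b = 0, alpha_nom = 0.05) {
  stopifnot(n >= 2, alpha_nom > 0, alpha_nom < 1, s >= 0)
  if (s == 0) {
    warning("s = 0: degenerate power curve (1 everywhere except the minimum)")
    return(ifelse(es + delta_b == 0, alpha_nom, 1))
  }
  df <- 2 * n - 2
  tcrit <- stats::qt(1 - alpha_nom / 2, df)
  ncp <- (es + delta_b) / (s * sqrt(2 / n))
  # pt() with ncp emits benign full-precision notes (~1e-12 accuracy)
  suppressWarnings(
    1 - stats::pt(tcrit, df, ncp = ncp) + stats::pt(-tcrit, df, ncp = ncp))
}

#' Regional power curves with and without bias
#'
#' Evaluates the per-voxel power curve (s = the voxel's sigma_FA; delta_b
#' = 0 and, for the biased companion curve, the voxel's B_FA) at each
#' sampled voxel of a region, and records the per-effect-size median
#' across the region's sampled voxels as the regional curve. Only voxels
#' with finite, positive sigma_FA (and finite B_FA for the biased curve)
#' enter the median.
#'
#' @param uncertainty Data frame from [estimate_uncertainty()].
#' @param regions Region ids to evaluate (default: all present).
#' @param n_list Theoretical per-group sample sizes (default 5, 15, 30).
#' @param es_grid Effect sizes (default 101 points on \[-0.1, 0.1\]).
#' @param alpha_nom Nominal false-positive rate.
#' @return Long data frame: `region`, `n`, `biased`, `es`, `power`;
#'   regions with no usable sampled voxels are skipped with a message.
#' @export
regional_power_curves <- function(uncertainty, regions = NULL,
                                  n_list = c(5L, 15L, 30L),
                                  es_grid = seq(-0.1, 0.1,
                                                length.out = 101L),
                                  alpha_nom = 0.05) {
  if (is.null(regions)) regions <- sort(unique(uncertainty$region))
  res <- list()
  for (r in regions) {
    u <- uncertainty[uncertainty$region == r &
                       is.finite(uncertainty$sigma_fa) &
                       uncertainty$sigma_fa > 0, ]
    if (!nrow(u)) {
      message("region ", r, ": no usable sampled voxels; skipped")
      next
    }
    for (n in n_list) {
      df <- 2 * n - 2
      tcrit <- stats::qt(1 - alpha_nom / 2, df)
      for (biased in c(FALSE, TRUE)) {
        uu <- if (biased) u[is.finite(u$bias_fa), ] else u
        if (!nrow(uu)) next
        db <- if (biased) uu$bias_fa else rep(0, nrow(uu))
        # es x voxel noncentrality matrix; one vectorized pt pair
        ncp <- outer(es_grid, db, "+") /
          rep(uu$sigma_fa * sqrt(2 / n), each = length(es_grid))
        pw <- suppressWarnings(
          1 - stats::pt(tcrit, df, ncp = ncp) +
            stats::pt(-tcrit, df, ncp = ncp))
        res[[length(res) + 1L]] <- data.frame(
          region = r, n = n, biased = biased, es = es_grid,
          power = apply(pw, 1L, stats::median))
      }
    }
  }
  do.call(rbind, res)
}
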