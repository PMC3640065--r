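# Regional noise-estimation heuristic and the voxel subsampling rule used
# by the expensive Monte-Carlo estimators.

#' Estimate image noise from regional signal variation
#'
#' For each labeled region and each DWI volume, takes the standard
#' deviation of the un-normalized intensities across the region's voxels,
#' then the median over DWIs, giving one SD estimate per region. These
#' estimates mix true noise with anatomical variability, so the smallest
#' would be closest to the noise floor; to guard against a single
#' artifact-contaminated region, the second smallest is chosen as the
#' noise estimate. The b0 is excluded.
#'
#' @param study A `dwi_study` with a label volume of at least 2 regions.
#' @return List of class `noise_estimate`: `table` (region id,
#'   `regional_sd`), `regional_sds` (named vector), `chosen_sigma`,
#'   `chosen_region`.
#' @export
estimate_noise <- function(study) {
  stopifnot(inherits(study, "dwi_study"))
  if (is.null(study$labels)) stop("estimate_noise requires a label volume")
  ids <- sort(setdiff(unique(as.vector(study$labels)), 0L))
  if (length(ids) < 2L)
    stop("at least 2 labeled regions are required (second-smallest rule)")
  J <- study$scheme$J
  nvox <- prod(dim(study$b0))
  sds <- matrix(NA_real_, length(ids), J)
  for (r in seq_along(ids)) {
    vox <- which(study$labels == ids[r])
    for (j in seq_len(J))
      sds[r, j] <- stats::sd(study$dwis[vox + (j - 1L) * nvox])
  }
  regional <- apply(sds, 1L, stats::median)
  names(regional) <- ids
  ord <- order(regional)
  chosen <- regional[ord[2L]]
  structure(list(
    table = data.frame(region = ids, regional_sd = unname(regional)),
    regional_sds = regional,
    chosen_sigma = unname(chosen),
    chosen_region = ids[ord[2L]]
  ), class = "noise_estimate")
}

#' @export
print.noise_estimate <- function(x, ...) {
  cat(sprintf(
    "<noise_estimate> sigma = %.4g (region %s, second smallest of %d)\n",
    x$chosen_sigma, x$chosen_region, length(x$regional_sds)))
  invisible(x)
}

#' Subsample voxels for Monte-Carlo estimation
#'
#' Draws `floor(target_fraction * n_in_mask)` voxels uniformly without
#' replacement, then tops up any region below `min_per_region` with
#' additional random draws from that region until it has
#' `min(min_per_region, region size)` voxels. Deterministic given the
#' seed.
#'
#' @param labels Integer label array (0 = background).
#' @param mask Logical/binary array; sampling is restricted to in-mask
#'   labeled voxels.
#' @param target_fraction Fraction of in-mask voxels to draw, in (0, 1].
#' @param min_per_region Per-region floor (default 50).
#' @param seed Integer seed (mandatory).
#' @return List of class `voxel_sample`: `indices` (linear), `region`
#'   (parallel vector), `per_region_counts` (named), `fraction` achieved.
#' @export
subsample_voxels <- function(labels, mask, target_fraction = 0.04,
                             min_per_region = 50L, seed) {
  if (missing(seed)) stop("seed is required for reproducible subsampling")
  if (!is.numeric(target_fraction) || target_fraction <= 0 ||
      target_fraction > 1)
    stop("target_fraction must be in (0, 1]")
  pool <- which(mask > 0 & labels > 0)
  n <- length(pool)
  if (!n) stop("no in-mask labeled voxels to sample")
  withr_seed(seed, {
    n_base <- max(1L, floor(target_fraction * n))
    sel <- if (n_base >= n) pool else pool[sample.int(n, n_base)]
    labv <- labels[pool]
    for (r in sort(unique(labv))) {
      rvox <- pool[labv == r]
      want <- min(min_per_region, length(rvox))
      have <- sum(sel %in% rvox)
      if (have < want) {
        extra <- setdiff(rvox, sel)
        add <- if (length(extra) <= want - have) extra else
          extra[sample.int(length(extra), want - have)]
        sel <- c(sel, add)
      }
    }
    sel <- sort(unique(sel))
    structure(list(
      indices = sel,
      region = labels[sel],
      per_region_counts = table(labels[sel]),
      fraction = length(sel) / n
    ), class = "voxel_sample")
  })
}
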