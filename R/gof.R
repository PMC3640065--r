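# Goodness-of-fit metrics: per-voxel pixel chi-squared, per-slice-per-DWI
# chi-squared with the J/K compatibility factor, histogram noise-lobe
# magnification, and best/worst slice selection for the QA report.

#' Pixel chi-squared
#'
#' Sum over gradients of squared residuals normalized by the measured
#' signal: chi2_pix = sum_j (S_m,j - S_f,j)^2 / S_m,j^2 with S_m floored at
#' `eps` before division. Normalizing by the signal (not its variance) maps
#' both poor fits and high noise to large values; values cluster in a
#' "signal lobe" just above zero and a "noise lobe" near 0.2.
#'
#' @param s_m,s_f Measured and fitted normalized signals: length-J vectors
#'   or N x J matrices.
#' @param eps Floor on S_m (default 1e-6).
#' @return Scalar or length-N vector; `NA` where S_m is all zero.
#' @export
chi_pixel <- function(s_m, s_f, eps = 1e-6) {
  vec <- !is.matrix(s_m)
  if (vec) { s_m <- matrix(s_m, 1L); s_f <- matrix(s_f, 1L) }
  stopifnot(identical(dim(s_m), dim(s_f)))
  out <- rowSums(((s_m - s_f) / pmax(s_m, eps))^2)
  out[rowSums(s_m != 0) == 0] <- NA_real_
  if (vec) drop(out) else out
}

#' Slice chi-squared matrix
#'
#' The slice adaptation of the pixel chi-squared: for axial slice z and
#' DWI j, sum the normalized squared residuals over the K in-mask voxels
#' of the slice and rescale by J/K so values remain comparable with the
#' per-voxel metric across slices of different size:
#' chi2_slice(z, j) = (J/K) * sum_k (S_m,jk - S_f,jk)^2 / S_m,jk^2.
#'
#' @param fit A `dti_tensor_fit`.
#' @param eps Floor on S_m before division.
#' @return Matrix of shape (number of axial slices) x J; rows with no
#'   in-mask voxels are `NA` (rendered as a blank band in the report).
#' @export
chi_slice_matrix <- function(fit, eps = 1e-6) {
  J <- fit$scheme$J
  nz <- fit$dim[3]
  terms <- ((fit$s_measured - fit$s_fitted) / pmax(fit$s_measured, eps))^2
  z <- fit$coords[, 3]
  out <- matrix(NA_real_, nz, J,
                dimnames = list(slice = NULL, dwi = NULL))
  for (zz in sort(unique(z))) {
    rows <- z == zz
    K <- sum(rows)
    out[zz, ] <- (J / K) * colSums(terms[rows, , drop = FALSE])
  }
  out
}

#' Compute both chi-squared maps for a fitted study
#'
#' @param fit A `dti_tensor_fit`.
#' @param eps Floor on S_m before division.
#' @return List of class `chi_square_maps`: `chi_pix` (per-voxel vector),
#'   `chi_slice` (slices x J matrix), and the fixed display range
#'   `c(0, 0.2)` used by the report (0.2 renders as saturation).
#' @export
chi_square_maps <- function(fit, eps = 1e-6) {
  structure(list(
    chi_pix = chi_pixel(fit$s_measured, fit$s_fitted, eps = eps),
    chi_slice = chi_slice_matrix(fit, eps = eps),
    display_range = c(0, 0.2)
  ), class = "chi_square_maps")
}

#' Histogram of pixel chi-squared with automatic noise-lobe magnification
#'
#' Besides the full-range histogram, returns a zoom window
#' `[quantile(prob), max]` chosen to magnify the upper (noise-lobe) tail,
#' and the modes of the two histogram lobes when both are present.
#'
#' @param chi_pix Per-voxel chi-squared values (NAs dropped).
#' @param prob Quantile defining the lower zoom bound (default 0.95).
#' @param breaks Histogram bin count.
#' @return List with `histogram` (full range), `zoom_window`,
#'   `zoom_histogram`, `signal_mode` (mode of the bulk below the zoom
#'   bound) and `noise_mode` (mode within the zoom window; NA when the
#'   window is degenerate, e.g. on a noiseless fit).
#' @export
chi_histogram <- function(chi_pix, prob = 0.95, breaks = 100L) {
  v <- chi_pix[is.finite(chi_pix)]
  if (length(v) < 100L)
    stop("need at least 100 in-mask voxels for the chi-squared histogram")
  h <- graphics::hist(v, breaks = breaks, plot = FALSE)
  q <- stats::quantile(v, prob, names = FALSE)
  zoom <- c(q, max(v))
  vz <- v[v >= q]
  vs <- v[v < q]
  if (!length(vs)) vs <- v      # degenerate: all values equal
  hz <- if (length(unique(vz)) > 1L)
    graphics::hist(vz, breaks = breaks, plot = FALSE) else NULL
  hs <- if (length(unique(vs)) > 1L)
    graphics::hist(vs, breaks = breaks, plot = FALSE) else NULL
  mode_of <- function(hh) hh$mids[which.max(hh$counts)]
  list(histogram = h, zoom_window = zoom, zoom_histogram = hz,
       signal_mode = if (is.null(hs)) vs[1] else mode_of(hs),
       noise_mode = if (is.null(hz)) NA_real_ else mode_of(hz))
}

#' Best and worst DWI slices per axial band
#'
#' Splits the brain's axial extent (slices with any finite chi-squared
#' entry) into `n_bands` contiguous bands and returns, per band, the
#' `n_each` lowest ("best") and highest ("worst") finite entries of the
#' slice chi-squared matrix, ties broken by (z, j) order.
#'
#' @param chi_slice Matrix from [chi_slice_matrix()].
#' @param n_bands Number of axial bands (default 5).
#' @param n_each Entries per list per band (default 5).
#' @return Data frame with columns `band`, `kind` ("best"/"worst"), `z`,
#'   `dwi` (1-based), `chi`, and attribute `short_bands` naming bands with
#'   fewer than `n_each` finite entries.
#' @export
best_worst_slices <- function(chi_slice, n_bands = 5L, n_each = 5L) {
  finite_z <- which(rowSums(is.finite(chi_slice)) > 0)
  if (!length(finite_z)) stop("chi_slice has no finite entries")
  zr <- range(finite_z)
  edges <- seq(zr[1], zr[2] + 1L, length.out = n_bands + 1L)
  out <- list(); short <- integer()
  for (b in seq_len(n_bands)) {
    zin <- finite_z[finite_z >= edges[b] & finite_z < edges[b + 1L]]
    if (!length(zin)) { short <- c(short, b); next }
    sub <- chi_slice[zin, , drop = FALSE]
    ok <- which(is.finite(sub), arr.ind = TRUE)
    ent <- data.frame(z = zin[ok[, 1]], dwi = ok[, 2],
                      chi = sub[ok])
    ent <- ent[order(ent$chi, ent$z, ent$dwi), ]
    k <- min(n_each, nrow(ent))
    if (k < n_each) short <- c(short, b)
    best <- ent[seq_len(k), ]
    worst <- ent[order(-ent$chi, ent$z, ent$dwi), ][seq_len(k), ]
    out[[length(out) + 1L]] <-
      rbind(cbind(band = b, kind = "best", best),
            cbind(band = b, kind = "worst", worst))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "short_bands") <- unique(short)
  res
}
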