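# Tensor elements are stored throughout as length-6 vectors (or N x 6
# matrices) in the order (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz), units mm^2/s.

# Design matrix of the log-linearised Stejskal-Tanner relation:
# ln S_j = -b * (gx^2 Dxx + gy^2 Dyy + gz^2 Dzz
#                + 2 gx gy Dxy + 2 gx gz Dxz + 2 gy gz Dyz)
design_matrix <- function(scheme) {
  g <- scheme$directions
  -scheme$b_value * cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
                          2 * g[, 1] * g[, 2],
                          2 * g[, 1] * g[, 3],
                          2 * g[, 2] * g[, 3])
}

d6_to_matrix <- function(d6) {
  matrix(c(d6[1], d6[4], d6[5],
           d6[4], d6[2], d6[6],
           d6[5], d6[6], d6[3]), 3L, 3L)
}

matrix_to_d6 <- function(D) {
  c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3])
}

#' Forward-simulate normalized DWI signals from a diffusion tensor
#'
#' Evaluates the Stejskal-Tanner relation S_j = exp(-b g_j' D g_j) for each
#' gradient direction.
#'
#' @param d6 Tensor elements: a length-6 vector `(Dxx, Dyy, Dzz, Dxy, Dxz,
#'   Dyz)` or an N x 6 matrix of tensors.
#' @param scheme A [gradient_scheme()].
#' @return A length-J vector (single tensor) or N x J matrix of normalized
#'   signals in (0, 1] for positive-semidefinite tensors.
#' @export
forward_signal <- function(d6, scheme) {
  X <- design_matrix(scheme)
  if (is.matrix(d6)) {
    exp(d6 %*% t(X))
  } else {
    exp(drop(X %*% d6))
  }
}

# Replace non-positive / non-finite normalized signals by half the smallest
# positive value in the same voxel, so the log-linear fit is defined.
# Operates on a vector or row-wise on a matrix.
clamp_signals <- function(S) {
  clamp_row <- function(s) {
    bad <- !is.finite(s) | s <= 0
    if (any(bad)) {
      pos <- s[!bad]
      repl <- if (length(pos)) 0.5 * min(pos) else .Machine$double.eps
      s[bad] <- repl
    }
    s
  }
  if (is.matrix(S)) {
    bad <- !is.finite(S) | S <= 0
    if (!any(bad)) return(S)
    idx <- unique(which(bad, arr.ind = TRUE)[, 1])
    for (i in idx) S[i, ] <- clamp_row(S[i, ])
    S
  } else {
    clamp_row(S)
  }
}

#' Fit diffusion tensors by log-linear least squares
#'
#' Ordinary (unweighted) least squares on the log-transformed normalized
#' signals. Non-positive signals are clamped to half the voxel's smallest
#' positive signal before taking logs.
#'
#' @param S_m Normalized signals: length-J vector or N x J matrix (one row
#'   per voxel).
#' @param scheme A [gradient_scheme()].
#' @return Tensor elements in the same shape convention as the input: a
#'   length-6 vector or an N x 6 matrix.
#' @export
fit_tensor_lls <- function(S_m, scheme) {
  X <- design_matrix(scheme)
  sv <- svd(X)
  if (min(sv$d) < 1e-10 * max(sv$d))
    stop(sprintf(
      "degenerate gradient table: design condition number %.3g",
      max(sv$d) / max(min(sv$d), .Machine$double.xmin)))
  P <- sv$v %*% (t(sv$u) / sv$d)   # 6 x J pseudoinverse
  vec <- !is.matrix(S_m)
  S <- clamp_signals(if (vec) matrix(S_m, nrow = 1L) else S_m)
  d6 <- log(S) %*% t(P)
  if (vec) drop(d6) else d6
}

# Closed-form eigenvalues of symmetric 3x3 tensors, vectorised over rows of
# an N x 6 matrix; returns N x 3 sorted descending. Trigonometric solution
# of the characteristic cubic; exact for isotropic tensors via the p2 == 0
# branch.
tensor_eigenvalues <- function(d6) {
  if (!is.matrix(d6)) d6 <- matrix(d6, nrow = 1L)
  a11 <- d6[, 1]; a22 <- d6[, 2]; a33 <- d6[, 3]
  a12 <- d6[, 4]; a13 <- d6[, 5]; a23 <- d6[, 6]
  q <- (a11 + a22 + a33) / 3
  p1 <- a12^2 + a13^2 + a23^2
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 + 2 * p1
  p <- sqrt(pmax(p2, 0) / 6)
  b11 <- a11 - q; b22 <- a22 - q; b33 <- a33 - q
  detB <- b11 * (b22 * b33 - a23^2) -
    a12 * (a12 * b33 - a23 * a13) +
    a13 * (a12 * a23 - b22 * a13)
  r <- ifelse(p > 0, detB / (2 * p^3), 0)
  r <- pmin(1, pmax(-1, r))
  phi <- acos(r) / 3
  e1 <- q + 2 * p * cos(phi)
  e3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  e2 <- 3 * q - e1 - e3
  cbind(e1, e2, e3, deparse.level = 0)
}

#' Fractional anisotropy and mean diffusivity from eigenvalues
#'
#' FA = sqrt(3/2) * ||lambda - mean(lambda)|| / ||lambda||, MD is the
#' eigenvalue mean. For FA, negative eigenvalues (noise excursions) are
#' clamped at zero and the result clamped into \[0, 1\]; the FA of the zero
#' tensor is defined as 0. MD uses the raw eigenvalues.
#'
#' @param ev N x 3 matrix (or length-3 vector) of eigenvalues.
#' @return For `fa_from_eigenvalues` a vector of FA values in \[0, 1\];
#'   for `md_from_eigenvalues` a vector of mean diffusivities (mm^2/s).
#' @export
fa_from_eigenvalues <- function(ev) {
  if (!is.matrix(ev)) ev <- matrix(ev, nrow = 1L)
  ev <- pmax(ev, 0)
  mn <- rowMeans(ev)
  num <- rowSums((ev - mn)^2)
  den <- rowSums(ev^2)
  fa <- sqrt(1.5) * sqrt(num / ifelse(den > 0, den, 1))
  fa[den <= 0] <- 0
  pmin(1, pmax(0, fa))
}

#' @rdname fa_from_eigenvalues
#' @export
md_from_eigenvalues <- function(ev) {
  if (!is.matrix(ev)) ev <- matrix(ev, nrow = 1L)
  rowMeans(ev)
}

# FA straight from tensor elements (used by the Monte-Carlo inner loops).
fa_from_tensor <- function(d6) {
  fa_from_eigenvalues(tensor_eigenvalues(d6))
}

# Principal eigenvectors (unit, N x 3) by per-voxel eigendecomposition.
# Sign/tie convention: the entry of largest magnitude is made positive and
# ties between eigenvalues are resolved by eigen()'s ordering, giving a
# reproducible e1.
principal_eigenvectors <- function(d6) {
  if (!is.matrix(d6)) d6 <- matrix(d6, nrow = 1L)
  out <- matrix(0, nrow(d6), 3L)
  for (i in seq_len(nrow(d6))) {
    es <- eigen(d6_to_matrix(d6[i, ]), symmetric = TRUE)
    v <- es$vectors[, 1L]
    j <- which.max(abs(v))
    if (v[j] < 0) v <- -v
    out[i, ] <- v
  }
  out
}

#' Normalize DWI volumes by the b0 volume
#'
#' Divides each diffusion-weighted volume by the non-diffusion-weighted b0
#' voxelwise, producing the J normalized signal vectors the tensor model is
#' fit to. In-mask voxels where b0 <= 0 are dropped from the analysis mask
#' (counted in the result); values above 1 are legal noise excursions and
#' are only counted.
#'
#' @param study A `dwi_study` (see [load_study()] / [generate_phantom()]).
#' @return A list with `s_measured` (N x J matrix over retained in-mask
#'   voxels), `idx` (linear voxel indices), `coords` (N x 3 voxel indices,
#'   1-based), `mask` (effective analysis mask array), `n_b0_dropped`,
#'   `n_over_unity`.
#' @export
normalize_signals <- function(study) {
  stopifnot(inherits(study, "dwi_study"))
  mask <- study$mask > 0
  if (!any(mask)) stop("empty mask: no in-mask voxels to analyse")
  b0_bad <- mask & !(study$b0 > 0)
  eff <- mask & study$b0 > 0
  idx <- which(eff)
  n <- length(idx)
  J <- study$scheme$J
  S <- matrix(0, n, J)
  b0v <- study$b0[idx]
  nvox <- prod(dim(study$b0))
  for (j in seq_len(J)) {
    S[, j] <- study$dwis[idx + (j - 1L) * nvox] / b0v
  }
  list(
    s_measured = S,
    idx = idx,
    coords = arrayInd(idx, dim(study$b0)),
    mask = eff,
    n_b0_dropped = sum(b0_bad),
    n_over_unity = sum(S > 1)
  )
}

#' Fit the diffusion tensor across a study
#'
#' Normalizes the DWIs by b0, fits a tensor per in-mask voxel by log-linear
#' least squares, and derives the eigensystem, FA, MD, principal
#' eigenvector and per-voxel squared fitting error.
#'
#' @param study A `dwi_study`.
#' @return An object of class `dti_tensor_fit` holding per-voxel results
#'   over the analysis mask: `d6` (N x 6 tensors), `eigenvalues` (N x 3,
#'   descending), `e1` (N x 3 unit vectors), `fa`, `md`, `s_measured`,
#'   `s_fitted` (N x J), `squared_error` (N), plus `mask`, `idx`, `coords`,
#'   `scheme` and bookkeeping counts. Use [fit_map()] to expand any
#'   per-voxel field into a 3D volume.
#' @export
fit_study <- function(study) {
  nz <- normalize_signals(study)
  d6 <- fit_tensor_lls(nz$s_measured, study$scheme)
  ev <- tensor_eigenvalues(d6)
  sf <- forward_signal(d6, study$scheme)
  fit <- list(
    scheme = study$scheme,
    dim = dim(study$b0),
    voxel_size = study$voxel_size,
    mask = nz$mask,
    idx = nz$idx,
    coords = nz$coords,
    d6 = d6,
    eigenvalues = ev,
    e1 = principal_eigenvectors(d6),
    fa = fa_from_eigenvalues(ev),
    md = md_from_eigenvalues(ev),
    s_measured = nz$s_measured,
    s_fitted = sf,
    squared_error = rowSums((nz$s_measured - sf)^2),
    b0 = study$b0,
    n_b0_dropped = nz$n_b0_dropped,
    n_over_unity = nz$n_over_unity,
    n_negative_ev = sum(ev[, 3] < 0)
  )
  class(fit) <- "dti_tensor_fit"
  fit
}

#' @export
print.dti_tensor_fit <- function(x, ...) {
  cat(sprintf(
    "<dti_tensor_fit> %d voxels, J = %d, b = %g s/mm^2\n  FA median %.3f, MD median %.3g mm^2/s, %d voxels with negative eigenvalues\n",
    length(x$idx), x$scheme$J, x$scheme$b_value,
    stats::median(x$fa), stats::median(x$md), x$n_negative_ev))
  invisible(x)
}

#' Expand a per-voxel quantity into a 3D (or 4D) volume
#'
#' @param fit A `dti_tensor_fit`.
#' @param what Name of a per-voxel field (`"fa"`, `"md"`,
#'   `"squared_error"`, `"e1"`, `"d6"`, ...) or a numeric vector/matrix
#'   with one row per in-mask voxel.
#' @param fill Value outside the mask (default `NA`).
#' @return A 3D array, or a 4D array when the field has several components.
#' @export
fit_map <- function(fit, what = "fa", fill = NA_real_) {
  v <- if (is.character(what)) fit[[what]] else what
  if (is.null(v)) stop("unknown per-voxel field: ", what)
  if (is.matrix(v)) {
    out <- array(fill, c(fit$dim, ncol(v)))
    nvox <- prod(fit$dim)
    for (k in seq_len(ncol(v))) out[fit$idx + (k - 1L) * nvox] <- v[, k]
  } else {
    out <- array(fill, fit$dim)
    out[fit$idx] <- v
  }
  out
}

#' Count residual-outlier voxels per DWI
#'
#' A voxel/DWI pair is scored an outlier when its un-normalized absolute
#' residual |S_m - S_f| * b0 exceeds `threshold` times the noise standard
#' deviation. This residual-threshold count is this package's own
#' definition, standing in for the robust-fit outlier maps produced by
#' iterative reweighting schemes.
#'
#' @param fit A `dti_tensor_fit`.
#' @param noise_sigma Noise standard deviation in image-intensity units
#'   (e.g. from [estimate_noise()]); must be positive.
#' @param threshold Multiplier on `noise_sigma` (default 3).
#' @return Integer vector of length J: in-mask outlier count per DWI.
#' @export
outlier_voxels_per_dwi <- function(fit, noise_sigma, threshold = 3) {
  if (!is.numeric(noise_sigma) || length(noise_sigma) != 1L || noise_sigma <= 0)
    stop("noise_sigma must be a positive scalar")
  res <- abs(fit$s_measured - fit$s_fitted) * fit$b0[fit$idx]
  as.integer(colSums(res > threshold * noise_sigma))
}
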