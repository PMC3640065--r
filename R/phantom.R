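# Synthetic DTI phantom: a piecewise-constant tensor field over a labeled
# ellipsoidal "brain", forward-simulated DWIs, stacked Rician noise, and
# injectable corruption with known ground truth.

#' Build the phantom's region label geometry
#'
#' Tiles an ellipsoidal brain-like mask with 25 regions: 3 midline regions
#' (inferior/middle/superior bands of a central sagittal slab) and 11
#' left/right region pairs (quantile sectors of each hemisphere). Region
#' ids increase foot-to-head within the midline set, which doubles as an
#' orientation marker for axis 3.
#'
#' @param grid_shape Integer length-3 volume dimensions.
#' @return List with `mask` (logical array), `labels` (integer array, 0 =
#'   background), and `region_table`: data frame with columns `id`, `name`,
#'   `pooled` (the 14-way pooled region name) and `side`.
#' @export
phantom_labels <- function(grid_shape = c(32L, 32L, 32L)) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 12L))
  ctr <- (grid_shape + 1) / 2
  rad <- grid_shape / 2 - 1
  x <- (seq_len(grid_shape[1]) - ctr[1]) / rad[1]
  y <- (seq_len(grid_shape[2]) - ctr[2]) / rad[2]
  z <- (seq_len(grid_shape[3]) - ctr[3]) / rad[3]
  X <- array(rep(x, times = grid_shape[2] * grid_shape[3]), grid_shape)
  Y <- array(rep(rep(y, each = grid_shape[1]), times = grid_shape[3]),
             grid_shape)
  Z <- array(rep(z, each = grid_shape[1] * grid_shape[2]), grid_shape)
  mask <- (X^2 + Y^2 + Z^2) <= 1
  labels <- array(0L, grid_shape)

  idx <- which(mask)
  xs <- X[idx]; ys <- Y[idx]; zs <- Z[idx]
  mid <- abs(xs) <= 0.18
  # midline: 3 z-bands, ids 1..3, inferior -> superior
  zmid <- zs[mid]
  br <- stats::quantile(zmid, c(1, 2) / 3)
  band <- 1L + (zmid > br[1]) + (zmid > br[2])
  labels[idx[mid]] <- band
  # hemispheres: 11 quantile sectors per side along a z/y sweep
  for (side in 1:2) {                       # 1 = left (x < 0), 2 = right
    sel <- !mid & (if (side == 1) xs < 0 else xs >= 0)
    sc <- zs[sel] + 0.25 * ys[sel]
    qb <- stats::quantile(sc, seq_len(10) / 11)
    pair <- 1L + rowSums(outer(sc, qb, ">"))
    labels[idx[sel]] <- 3L + (pair - 1L) * 2L + side
  }
  mid_names <- c("midline_inferior", "midline_middle", "midline_superior")
  ids <- 1:25
  name <- character(25); pooled <- character(25); side <- character(25)
  name[1:3] <- mid_names; pooled[1:3] <- mid_names; side[1:3] <- "midline"
  for (p in 1:11) {
    for (s in 1:2) {
      id <- 3L + (p - 1L) * 2L + s
      side[id] <- c("left", "right")[s]
      pooled[id] <- sprintf("pair%02d", p)
      name[id] <- sprintf("pair%02d_%s", p, side[id])
    }
  }
  list(mask = mask, labels = labels,
       region_table = data.frame(id = ids, name = name, pooled = pooled,
                                 side = side, stringsAsFactors = FALSE))
}

# Axially symmetric tensor with the requested FA and MD, principal axis u.
# With eigenvalues MD(1+2d), MD(1-d), MD(1-d):  FA = 3d / sqrt(3 + 6 d^2),
# inverted as d = FA * sqrt(3 / (9 - 6 FA^2)).
tensor_from_fa_md <- function(fa, md, u = c(1, 0, 0)) {
  stopifnot(fa >= 0, fa <= 1, md > 0)
  d <- fa * sqrt(3 / (9 - 6 * fa^2))
  l1 <- md * (1 + 2 * d); l23 <- md * (1 - d)
  u <- u / sqrt(sum(u^2))
  D <- l23 * diag(3) + (l1 - l23) * tcrossprod(u)
  matrix_to_d6(D)
}

#' Default ground-truth region tensors
#'
#' One tensor per region (left/right partners share a tensor so bilateral
#' pooling is exact in truth). FA spans 0.1-0.9 and MD (0.6-3.0)e-3 mm^2/s
#' across the 14 pooled regions -- anisotropic white-matter-like sectors
#' through nearly isotropic gray-matter-like ones -- with the principal
#' axis sweeping orientation so eigenvector maps are non-trivial.
#'
#' @param region_table As returned by [phantom_labels()].
#' @return A 25 x 6 matrix of tensor elements plus attributes `fa`, `md`
#'   (per-region truth).
#' @export
default_region_tensors <- function(region_table) {
  pooled <- unique(region_table$pooled)
  np <- length(pooled)
  fa_p <- seq(0.1, 0.9, length.out = np)
  md_p <- seq(3.0e-3, 0.6e-3, length.out = np)
  th <- seq(0, pi, length.out = np)
  out <- matrix(0, nrow(region_table), 6L)
  fa <- md <- numeric(nrow(region_table))
  for (i in seq_len(nrow(region_table))) {
    p <- match(region_table$pooled[i], pooled)
    u <- c(cos(th[p]), sin(th[p]) * 0.8, sin(th[p]) * 0.6)
    out[i, ] <- tensor_from_fa_md(fa_p[p], md_p[p], u)
    fa[i] <- fa_p[p]; md[i] <- md_p[p]
  }
  attr(out, "fa") <- fa
  attr(out, "md") <- md
  out
}

#' Specify a synthetic DTI phantom
#'
#' Defaults emulate a 32-direction, b = 700 s/mm^2 pediatric-style
#' protocol on a 32^3 grid with noise giving a b0 SNR of about 40.
#'
#' @param grid_shape Volume dimensions (default 32^3).
#' @param b_value Diffusion weighting, s/mm^2.
#' @param n_gradients Number of DWI directions (ignored when `directions`
#'   supplied).
#' @param directions Optional J x 3 gradient table; generated by
#'   electrostatic repulsion from `seed` when omitted.
#' @param noise_sigma Rician noise standard deviation, image-intensity
#'   units.
#' @param b0_intensity Noiseless in-mask b0 intensity.
#' @param region_tensors Optional 25 x 6 matrix of ground-truth tensors.
#' @param voxel_size Voxel edge lengths in mm.
#' @param seed Integer seed controlling the gradient table, noise and
#'   synthetic motion.
#' @param artifacts List of corruption injections; each element is a list
#'   with `type` in `"gradient_dropout"` (`j`, `factor`),
#'   `"slice_artifact"` (`z`, `j`, `offset`) or `"motion_row"` (`j`,
#'   `params` = 6 numbers: tx, ty, tz mm then rx, ry, rz deg).
#' @param simulate_motion Attach a smooth synthetic motion table (default
#'   TRUE).
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(grid_shape = c(32L, 32L, 32L),
                         b_value = 700,
                         n_gradients = 32L,
                         directions = NULL,
                         noise_sigma = 25,
                         b0_intensity = 1000,
                         region_tensors = NULL,
                         voxel_size = c(2.2, 2.2, 2.2),
                         seed = 42L,
                         artifacts = list(),
                         simulate_motion = TRUE) {
  stopifnot(noise_sigma >= 0, b0_intensity > 0, n_gradients >= 7L)
  structure(list(
    grid_shape = as.integer(grid_shape), b_value = b_value,
    n_gradients = as.integer(n_gradients), directions = directions,
    noise_sigma = noise_sigma, b0_intensity = b0_intensity,
    region_tensors = region_tensors, voxel_size = voxel_size,
    seed = as.integer(seed), artifacts = artifacts,
    simulate_motion = simulate_motion
  ), class = "phantom_spec")
}

# Rician corruption: magnitude of (v + sigma N1) + i sigma N2.
rician <- function(v, sigma) {
  if (sigma <= 0) return(v)
  sqrt((v + stats::rnorm(length(v), sd = sigma))^2 +
         stats::rnorm(length(v), sd = sigma)^2)
}

#' Generate a synthetic DTI study with known ground truth
#'
#' Forward-simulates noiseless DWIs from the piecewise-constant tensor
#' field via the Stejskal-Tanner relation, scales by the b0 intensity,
#' applies independent Rician corruption to every DWI and the b0 (the
#' stacked noise model), then applies the requested artifact injections.
#' Deterministic given the spec's seed.
#'
#' @param spec A [phantom_spec()].
#' @return List with `study` (a `dwi_study`) and `truth`: region table
#'   with per-region FA/MD, the 25 x 6 tensor matrix, `sigma`, and
#'   ground-truth `fa_map`, `md_map`, `e1` (25 x 3 per-region principal
#'   axes).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  geo <- phantom_labels(spec$grid_shape)
  counts <- table(geo$labels[geo$labels > 0])
  if (length(counts) < 25L || any(counts == 0))
    stop("phantom geometry produced an empty region; enlarge grid_shape")
  dirs <- spec$directions
  if (is.null(dirs))
    dirs <- gradient_table_repulsion(spec$n_gradients, seed = spec$seed)
  scheme <- gradient_scheme(spec$b_value, dirs)
  tens <- spec$region_tensors
  if (is.null(tens)) tens <- default_region_tensors(geo$region_table)
  stopifnot(nrow(tens) == 25L, ncol(tens) == 6L)

  S_region <- forward_signal(tens, scheme)          # 25 x J
  dim3 <- spec$grid_shape
  nvox <- prod(dim3)
  J <- scheme$J
  lab <- geo$labels
  inb <- lab > 0
  b0 <- array(0, dim3)
  b0[inb] <- spec$b0_intensity
  dwis <- array(0, c(dim3, J))
  labv <- lab[inb]
  for (j in seq_len(J)) {
    vol <- array(0, dim3)
    vol[inb] <- spec$b0_intensity * S_region[labv, j]
    dwis[, , , j] <- vol
  }

  motion <- NULL
  withr_seed(spec$seed, {
    if (spec$noise_sigma > 0) {
      b0[] <- rician(as.vector(b0), spec$noise_sigma)
      dwis[] <- rician(as.vector(dwis), spec$noise_sigma)
    }
    if (isTRUE(spec$simulate_motion)) {
      drift <- matrix(stats::rnorm(J * 6L, sd = 0.08), J, 6L)
      motion <- data.frame(
        dwi_index = seq_len(J),
        tx_mm = cumsum(drift[, 1]), ty_mm = cumsum(drift[, 2]),
        tz_mm = cumsum(drift[, 3]),
        rx_deg = cumsum(drift[, 4] * 2), ry_deg = cumsum(drift[, 5] * 2),
        rz_deg = cumsum(drift[, 6] * 2))
    }
  })

  for (a in spec$artifacts) {
    if (identical(a$type, "gradient_dropout")) {
      v <- dwis[, , , a$j]; v[inb] <- v[inb] * a$factor
      dwis[, , , a$j] <- v
    } else if (identical(a$type, "slice_artifact")) {
      sl <- dwis[, , a$z, a$j]
      msl <- inb[, , a$z]
      sl[msl] <- pmax(sl[msl] + a$offset, 0)
      dwis[, , a$z, a$j] <- sl
    } else if (identical(a$type, "motion_row")) {
      if (is.null(motion))
        motion <- data.frame(dwi_index = seq_len(J), tx_mm = 0, ty_mm = 0,
                             tz_mm = 0, rx_deg = 0, ry_deg = 0, rz_deg = 0)
      motion[a$j, -1] <- as.list(a$params)
    } else {
      stop("unknown artifact type: ", a$type)
    }
  }

  study <- new_dwi_study(b0 = b0, dwis = dwis, mask = inb,
                         labels = lab, motion = motion, scheme = scheme,
                         voxel_size = spec$voxel_size)
  fa_r <- attr(tens, "fa")
  md_r <- attr(tens, "md")
  if (is.null(fa_r)) {
    evr <- tensor_eigenvalues(tens)
    fa_r <- fa_from_eigenvalues(evr)
    md_r <- md_from_eigenvalues(evr)
  }
  fa_map <- array(NA_real_, dim3); fa_map[inb] <- fa_r[labv]
  md_map <- array(NA_real_, dim3); md_map[inb] <- md_r[labv]
  truth <- list(
    region_table = cbind(geo$region_table, fa = fa_r, md = md_r),
    tensors = tens, sigma = spec$noise_sigma,
    fa_map = fa_map, md_map = md_map,
    e1 = principal_eigenvectors(tens),
    scheme = scheme
  )
  list(study = study, truth = truth)
}

#' Generate a two-protocol phantom cohort
#'
#' Draws independent phantoms from two specs (fresh per-study seeds derived
#' from `seed`), recording protocol membership and any per-member noise
#' scaling in a truth table -- the setting used to test that QA feature
#' vectors cluster by protocol and that aberrant members stand out.
#'
#' @param spec_a,spec_b [phantom_spec()] objects for the two protocols.
#' @param n_a,n_b Members per protocol.
#' @param seed Cohort-level seed.
#' @param noise_scale Optional numeric vector of length `n_a + n_b`
#'   multiplying each member's `noise_sigma` (default all 1); use e.g. 3
#'   for one member to plant a within-protocol quality outlier.
#' @return List with `studies` (list of `dwi_study`), `truths` and a
#'   `truth_table` data frame (`dataset_id`, `protocol`, `seed`,
#'   `noise_sigma`).
#' @export
generate_cohort <- function(spec_a, spec_b, n_a, n_b, seed = 1L,
                            noise_scale = NULL) {
  n <- n_a + n_b
  if (is.null(noise_scale)) noise_scale <- rep(1, n)
  stopifnot(length(noise_scale) == n)
  seeds <- withr_seed(seed, sample.int(1000000L, n))
  studies <- vector("list", n)
  truths <- vector("list", n)
  tab <- data.frame(dataset_id = sprintf("ds%02d", seq_len(n)),
                    protocol = rep(c("A", "B"), c(n_a, n_b)),
                    seed = seeds, noise_sigma = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    sp <- if (i <= n_a) spec_a else spec_b
    sp$seed <- seeds[i]
    sp$noise_sigma <- sp$noise_sigma * noise_scale[i]
    tab$noise_sigma[i] <- sp$noise_sigma
    gen <- generate_phantom(sp)
    studies[[i]] <- gen$study
    truths[[i]] <- gen$truth
  }
  list(studies = studies, truths = truths, truth_table = tab)
}
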