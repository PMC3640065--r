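# Reading and writing the standard files the pipeline touches: NIfTI-1
# volumes via RNifti, FSL-dialect bval/bvec text, motion TSV, CSV/JSON
# outputs, plus the manifest of stored pipeline outputs.

dtiqa_error <- function(class, msg, ...) {
  stop(structure(class = c(class, "dtiqa_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

#' Construct a DWI study container
#'
#' @param b0 3D array of non-diffusion-weighted intensities.
#' @param dwis 4D array (x, y, z, J) of diffusion-weighted volumes; axis 3
#'   is the axial (foot-to-head) direction.
#' @param mask Binary/logical 3D array.
#' @param labels Optional integer 3D array; 0 = background.
#' @param motion Optional data frame with columns `dwi_index`, `tx_mm`,
#'   `ty_mm`, `tz_mm`, `rx_deg`, `ry_deg`, `rz_deg`.
#' @param scheme A [gradient_scheme()] with J matching `dim(dwis)[4]`.
#' @param voxel_size Length-3 voxel edge lengths in mm.
#' @return A validated object of class `dwi_study`.
#' @export
new_dwi_study <- function(b0, dwis, mask = NULL, labels = NULL,
                          motion = NULL, scheme, voxel_size = c(1, 1, 1)) {
  d3 <- dim(b0)
  if (length(d3) != 3L)
    dtiqa_error("dtiqa_structural_error", "b0 must be a 3D volume")
  if (length(dim(dwis)) != 4L || !identical(dim(dwis)[1:3], d3))
    dtiqa_error("dtiqa_structural_error",
                "dwis must be 4D and share the b0 grid")
  if (dim(dwis)[4] != scheme$J)
    dtiqa_error("dtiqa_structural_error",
                "gradient table has %d directions but 4D series has %d DWIs",
                scheme$J, dim(dwis)[4])
  if (any(dwis < 0)) dtiqa_error("dtiqa_structural_error",
                                 "negative DWI intensities")
  if (is.null(mask)) mask <- array(TRUE, d3)
  if (!identical(dim(mask), d3))
    dtiqa_error("dtiqa_structural_error", "mask grid mismatch")
  mask <- mask > 0
  if (!is.null(labels)) {
    if (!identical(dim(labels), d3))
      dtiqa_error("dtiqa_structural_error", "labels grid mismatch")
    labels <- array(as.integer(labels), d3)
    labels[!mask] <- 0L
  }
  if (!is.null(motion)) {
    need <- c("dwi_index", "tx_mm", "ty_mm", "tz_mm",
              "rx_deg", "ry_deg", "rz_deg")
    if (!all(need %in% names(motion)))
      dtiqa_error("dtiqa_structural_error",
                  "motion table must have columns %s",
                  paste(need, collapse = ", "))
  }
  structure(list(b0 = b0, dwis = dwis, mask = mask, labels = labels,
                 motion = motion, scheme = scheme,
                 voxel_size = as.numeric(voxel_size)),
            class = "dwi_study")
}

#' @export
print.dwi_study <- function(x, ...) {
  cat(sprintf(
    "<dwi_study> %s grid, J = %d, b = %g s/mm^2, %d in-mask voxels%s%s\n",
    paste(dim(x$b0), collapse = "x"), x$scheme$J, x$scheme$b_value,
    sum(x$mask),
    if (is.null(x$labels)) "" else
      sprintf(", %d regions", length(setdiff(unique(as.vector(x$labels)), 0L))),
    if (is.null(x$motion)) "" else ", motion table present"))
  invisible(x)
}

read_nifti_ras <- function(path) {
  img <- RNifti::readNifti(path)
  ori <- tryCatch(RNifti::orientation(img), error = function(e) NULL)
  if (!is.null(ori) && !is.na(ori) && nzchar(ori) && ori != "RAS")
    tryCatch(RNifti::orientation(img) <- "RAS", error = function(e) NULL)
  img
}

read_gradient_table <- function(bval_path, bvec_path) {
  if (!file.exists(bvec_path) || !file.exists(bval_path))
    dtiqa_error("dtiqa_corrupt_header",
                "corrupt header: missing gradient table (%s)",
                if (file.exists(bval_path)) bvec_path else bval_path)
  bvals <- scan(bval_path, quiet = TRUE)
  bv <- as.matrix(utils::read.table(bvec_path))
  if (nrow(bv) != 3L && ncol(bv) == 3L) bv <- t(bv)
  if (nrow(bv) != 3L)
    dtiqa_error("dtiqa_corrupt_header",
                "corrupt header: bvec file is not 3 x N")
  if (ncol(bv) != length(bvals))
    dtiqa_error("dtiqa_corrupt_header",
                "corrupt header: %d b-values but %d gradient columns",
                length(bvals), ncol(bv))
  list(bvals = bvals, bvecs = bv)
}

#' Load a DWI study from NIfTI + FSL-style gradient files
#'
#' Reads the 4D series, reorients to RAS, identifies b0 volumes as the
#' zero-vector gradient-table entries (several b0s are averaged into one),
#' normalizes the remaining directions to unit length, and validates the
#' result. Motion parameters, when supplied, are expected in the scanner
#' frame after any external registration; if gradients were rotated during
#' registration, supply the rotated bvec file.
#'
#' @param dwi_path 4D NIfTI file (b0 volumes included).
#' @param bval_path,bvec_path FSL-dialect whitespace-separated text files.
#' @param mask_path,labels_path,motion_path Optional NIfTI mask, integer
#'   region labels, and TSV motion table.
#' @return A `dwi_study`.
#' @export
load_study <- function(dwi_path, bval_path, bvec_path, mask_path = NULL,
                       labels_path = NULL, motion_path = NULL) {
  img <- read_nifti_ras(dwi_path)
  arr <- as.array(img)
  if (length(dim(arr)) == 3L) dim(arr) <- c(dim(arr), 1L)
  gt <- read_gradient_table(bval_path, bvec_path)
  nvol <- dim(arr)[4]
  if (ncol(gt$bvecs) != nvol)
    dtiqa_error("dtiqa_structural_error",
                "gradient table lists %d volumes but 4D series has %d",
                ncol(gt$bvecs), nvol)
  nrm <- sqrt(colSums(gt$bvecs^2))
  is_b0 <- nrm < 1e-6 | gt$bvals <= 0
  if (!any(is_b0))
    dtiqa_error("dtiqa_no_b0", "no b_o volume present in the series")
  if (all(is_b0))
    dtiqa_error("dtiqa_structural_error", "no diffusion-weighted volumes")
  b0 <- if (sum(is_b0) == 1L) arr[, , , which(is_b0)] else
    apply(arr[, , , is_b0, drop = FALSE], 1:3, mean)
  dwis <- arr[, , , !is_b0, drop = FALSE]
  dirs <- t(gt$bvecs[, !is_b0, drop = FALSE])
  bval <- stats::median(gt$bvals[!is_b0])
  scheme <- gradient_scheme(bval, dirs)
  pd <- tryCatch(RNifti::pixdim(img)[1:3], error = function(e) c(1, 1, 1))
  mask <- if (!is.null(mask_path)) as.array(read_nifti_ras(mask_path)) else NULL
  labels <- if (!is.null(labels_path))
    as.array(read_nifti_ras(labels_path)) else NULL
  motion <- if (!is.null(motion_path))
    utils::read.table(motion_path, header = TRUE, sep = "\t") else NULL
  new_dwi_study(b0 = b0, dwis = dwis, mask = mask, labels = labels,
                motion = motion, scheme = scheme, voxel_size = pd)
}

write_vol <- function(arr, path, voxel_size, datatype = "float") {
  img <- RNifti::asNifti(arr)
  nd <- length(dim(arr))
  RNifti::pixdim(img) <- c(voxel_size, rep(1, nd - 3L))
  RNifti::writeNifti(img, path, datatype = datatype)
  path
}

#' Write a DWI study to disk in the loader's format
#'
#' Writes `dwi.nii.gz` (b0 first, then the J DWIs), `dwi.bval` /
#' `dwi.bvec`, `mask.nii.gz`, `labels.nii.gz` (if present) and
#' `motion.tsv` (if present), so that [load_study()] round-trips the
#' study.
#'
#' @param study A `dwi_study`.
#' @param dir Output directory (created if needed).
#' @return Named list of written file paths.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  J <- study$scheme$J
  arr <- array(0, c(dim(study$b0), J + 1L))
  arr[, , , 1] <- study$b0
  arr[, , , 2:(J + 1L)] <- study$dwis
  vs <- study$voxel_size
  paths <- list(dwi = write_vol(arr, file.path(dir, "dwi.nii.gz"), vs))
  writeLines(paste(c(0, rep(study$scheme$b_value, J)), collapse = " "),
             file.path(dir, "dwi.bval"))
  bv <- cbind(0, t(study$scheme$directions))
  utils::write.table(format(bv, digits = 10), file.path(dir, "dwi.bvec"),
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  paths$bval <- file.path(dir, "dwi.bval")
  paths$bvec <- file.path(dir, "dwi.bvec")
  paths$mask <- write_vol(study$mask + 0L, file.path(dir, "mask.nii.gz"),
                          vs, datatype = "int16")
  if (!is.null(study$labels))
    paths$labels <- write_vol(study$labels, file.path(dir, "labels.nii.gz"),
                              vs, datatype = "int16")
  if (!is.null(study$motion)) {
    utils::write.table(study$motion, file.path(dir, "motion.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    paths$motion <- file.path(dir, "motion.tsv")
  }
  paths
}

#' Reload a study previously written by [write_study()]
#'
#' @param dir Directory passed to [write_study()].
#' @return A `dwi_study`.
#' @export
read_study_dir <- function(dir) {
  load_study(
    dwi_path = file.path(dir, "dwi.nii.gz"),
    bval_path = file.path(dir, "dwi.bval"),
    bvec_path = file.path(dir, "dwi.bvec"),
    mask_path = file.path(dir, "mask.nii.gz"),
    labels_path = {
      p <- file.path(dir, "labels.nii.gz"); if (file.exists(p)) p else NULL
    },
    motion_path = {
      p <- file.path(dir, "motion.tsv"); if (file.exists(p)) p else NULL
    })
}

#' Save the stored pipeline outputs
#'
#' Writes the scalar and vector maps (FA, MD, per-voxel squared error,
#' principal eigenvector, 6-component tensor field) as NIfTI, the
#' segmented b0 (region labels) when available, and the tabular outputs
#' (noise estimate, per-voxel sigma_FA / B_FA samples, power curves,
#' chi-squared slice matrix, feature vector) as CSV, then a JSON manifest
#' naming each item. The input volumes are stored as loaded -- no
#' registration or eddy-current correction is applied by this package, and
#' the manifest flags them accordingly.
#'
#' @param fit A `dti_tensor_fit`.
#' @param metrics A list of QA results as produced by [run_qa_pipeline()];
#'   any of `noise`, `gof`, `uncertainty`, `power`, `summary`,
#'   `feature_vector`, `outlier_counts`, `labels` may be present.
#' @param out_dir Output directory.
#' @return (Invisibly) the manifest as a named list of relative paths.
#' @export
save_outputs <- function(fit, metrics = list(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  vs <- fit$voxel_size
  if (is.null(vs)) vs <- c(1, 1, 1)
  manifest <- list()
  wr <- function(name, file) manifest[[name]] <<- file
  write_vol(fit_map(fit, "fa", fill = 0), file.path(out_dir, "fa.nii.gz"), vs)
  wr("fa", "fa.nii.gz")
  write_vol(fit_map(fit, "md", fill = 0), file.path(out_dir, "md.nii.gz"), vs)
  wr("md", "md.nii.gz")
  write_vol(fit_map(fit, "squared_error", fill = 0),
            file.path(out_dir, "squared_error.nii.gz"), vs)
  wr("squared_error", "squared_error.nii.gz")
  write_vol(fit_map(fit, "e1", fill = 0), file.path(out_dir, "e1.nii.gz"), vs)
  wr("e1", "e1.nii.gz")
  write_vol(fit_map(fit, "d6", fill = 0),
            file.path(out_dir, "tensor.nii.gz"), vs)
  wr("tensor", "tensor.nii.gz")
  if (!is.null(metrics$labels)) {
    write_vol(metrics$labels, file.path(out_dir, "segmented_b0.nii.gz"), vs,
              datatype = "int16")
    wr("segmented_b0", "segmented_b0.nii.gz")
  }
  if (!is.null(metrics$noise)) {
    utils::write.csv(metrics$noise$table,
                     file.path(out_dir, "noise_estimate.csv"),
                     row.names = FALSE)
    wr("noise_estimate", "noise_estimate.csv")
  }
  if (!is.null(metrics$uncertainty)) {
    u <- metrics$uncertainty
    utils::write.csv(u, file.path(out_dir, "uncertainty_samples.csv"),
                     row.names = FALSE)
    wr("sigma_fa", "uncertainty_samples.csv")
    if ("bias_fa" %in% names(u) && any(is.finite(u$bias_fa))) {
      wr("b_fa", "uncertainty_samples.csv")
    } else {
      message("SIMEX bias not computed; B_FA omitted from stored outputs")
      manifest$b_fa_omitted <- TRUE
    }
  }
  if (!is.null(metrics$power)) {
    utils::write.csv(metrics$power, file.path(out_dir, "power_curves.csv"),
                     row.names = FALSE)
    wr("power_curves", "power_curves.csv")
  }
  if (!is.null(metrics$gof)) {
    utils::write.csv(as.data.frame(metrics$gof$chi_slice),
                     file.path(out_dir, "chi_slice.csv"), row.names = FALSE)
    wr("chi_slice", "chi_slice.csv")
  }
  if (!is.null(metrics$outlier_counts)) {
    utils::write.csv(
      data.frame(dwi_index = seq_along(metrics$outlier_counts),
                 outlier_voxels = metrics$outlier_counts),
      file.path(out_dir, "outlier_counts.csv"), row.names = FALSE)
    wr("outlier_counts", "outlier_counts.csv")
  }
  if (!is.null(metrics$feature_vector)) {
    fv <- metrics$feature_vector
    utils::write.csv(data.frame(feature = names(fv), value = as.numeric(fv)),
                     file.path(out_dir, "feature_vector.csv"),
                     row.names = FALSE)
    wr("feature_vector", "feature_vector.csv")
  }
  manifest$registered_data <-
    "inputs stored as-is; registration/eddy-current correction not applied"
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
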