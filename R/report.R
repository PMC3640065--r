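# Four-page graphical QA report, rendered with base graphics to PDF.
# Page 1: acquisition header, motion, residual-outlier counts, slice
# chi-squared heatmap (shared DWI abscissa, horizontally aligned),
# chi-squared histogram with noise-lobe zoom, best/worst slice thumbnails.
# Page 2: region schematic + regional boxplots of MD, FA, sigma_FA, B_FA
# with optional reference distributions. Page 3: mid-axial maps, power
# curves, orientation-labeled e1 colormaps. Page 4: e1 vector overlays.

chi_palette <- function(n = 64L)
  grDevices::hcl.colors(n, "YlOrRd", rev = TRUE)

# x = DWI index, y = axial slice; values saturate at the fixed 0.2 upper
# display bound; slices with no in-mask voxels render as the background
# blue band.
draw_chi_slice_panel <- function(chi_slice, main = "slice chi-squared") {
  m <- pmin(chi_slice, 0.2)
  graphics::par(bg = "white")
  graphics::image(x = seq_len(ncol(m)), y = seq_len(nrow(m)), z = t(m),
                  zlim = c(0, 0.2), col = chi_palette(),
                  xlab = "DWI index", ylab = "axial slice", main = main,
                  useRaster = FALSE)
  na_rows <- which(rowSums(is.finite(m)) == 0)
  for (zz in na_rows)
    graphics::rect(0.5, zz - 0.5, ncol(m) + 0.5, zz + 0.5,
                   col = "steelblue", border = NA)
}

draw_slice_image <- function(sl, main = "", col = grDevices::gray.colors(64),
                             zlim = NULL) {
  sl[!is.finite(sl)] <- 0
  if (is.null(zlim)) zlim <- range(sl, finite = TRUE)
  if (diff(zlim) == 0) zlim <- zlim + c(0, 1e-12)
  graphics::image(sl, col = col, zlim = zlim, axes = FALSE, main = main,
                  cex.main = 0.7, useRaster = TRUE)
}

# RGB orientation raster for one slice of the e1 map: R = right-left,
# G = anterior-posterior, B = foot-head, intensity weighted by FA.
e1_rgb_slice <- function(fit, plane = c("axial", "coronal", "sagittal"),
                         index = NULL) {
  plane <- match.arg(plane)
  e1 <- fit_map(fit, "e1", fill = 0)
  fa <- fit_map(fit, "fa", fill = 0)
  d <- fit$dim
  sl <- switch(plane,
    axial    = list(e1[, , if (is.null(index)) ceiling(d[3] / 2) else index, ],
                    fa[, , if (is.null(index)) ceiling(d[3] / 2) else index]),
    coronal  = list(e1[, if (is.null(index)) ceiling(d[2] / 2) else index, , ],
                    fa[, if (is.null(index)) ceiling(d[2] / 2) else index, ]),
    sagittal = list(e1[if (is.null(index)) ceiling(d[1] / 2) else index, , , ],
                    fa[if (is.null(index)) ceiling(d[1] / 2) else index, , ]))
  ev <- abs(sl[[1]]); w <- pmin(pmax(sl[[2]], 0), 1)
  r <- pmin(ev[, , 1] * w, 1); g <- pmin(ev[, , 2] * w, 1)
  b <- pmin(ev[, , 3] * w, 1)
  rgb_mat <- grDevices::rgb(r, g, b)
  dim(rgb_mat) <- dim(r)
  list(rgb = rgb_mat, e1 = sl[[1]], fa = sl[[2]])
}

draw_rgb_slice <- function(rgb_mat, main = "", labels = c("", "")) {
  nx <- nrow(rgb_mat); ny <- ncol(rgb_mat)
  graphics::plot(NA, xlim = c(0, nx), ylim = c(0, ny), asp = 1,
                 axes = FALSE, xlab = "", ylab = "", main = main,
                 cex.main = 0.7)
  # rasterImage draws rows top-down; transpose + flip so x is axis 1 and
  # increasing y is up the plot
  graphics::rasterImage(t(rgb_mat)[ny:1, , drop = FALSE], 0, 0, nx, ny,
                        interpolate = FALSE)
  if (nzchar(labels[1]))
    graphics::mtext(labels[1], side = 1, cex = 0.5, line = 0)
  if (nzchar(labels[2]))
    graphics::mtext(labels[2], side = 2, cex = 0.5, line = 0)
}

bxp_from_summary <- function(rows, main, reference = NULL, ylab = "") {
  rows <- rows[order(rows$region), ]
  ok <- is.finite(rows$median)
  if (!any(ok)) {
    graphics::plot.new(); graphics::title(main = paste(main, "(no data)"))
    return(invisible())
  }
  stats_mat <- t(as.matrix(rows[, c("whisker_lo", "q1", "median", "q3",
                                    "whisker_hi")]))
  n <- nrow(rows)
  at <- seq_len(n)
  z <- list(stats = stats_mat, n = rows$n,
            conf = matrix(NA, 2, n), out = numeric(0),
            group = numeric(0), names = rows$region)
  graphics::bxp(z, at = at, boxwex = 0.5, border = "blue4",
                main = main, las = 2, cex.axis = 0.45, cex.main = 0.8,
                ylab = ylab, outline = FALSE, show.names = TRUE)
  if (!is.null(reference)) {
    ref <- reference[match(rows$region, reference$region), ]
    if (any(is.finite(ref$median))) {
      zr <- list(stats = t(as.matrix(
                   ref[, c("whisker_lo", "q1", "median", "q3",
                           "whisker_hi")])),
                 n = ref$n, conf = matrix(NA, 2, nrow(ref)),
                 out = numeric(0), group = numeric(0), names = ref$region)
      graphics::bxp(zr, at = at + 0.28, boxwex = 0.18, border = "black",
                    add = TRUE, axes = FALSE, outline = FALSE,
                    show.names = FALSE)
    }
  }
}

draw_power_panel <- function(power_df, region, main) {
  pd <- power_df[power_df$region == region, ]
  if (!nrow(pd)) {
    graphics::plot.new(); graphics::title(main = paste(main, "(no data)"))
    return(invisible())
  }
  graphics::plot(NA, xlim = range(pd$es), ylim = c(0, 1),
                 xlab = "effect size (FA)", ylab = "power", main = main,
                 cex.main = 0.8)
  cols <- c("5" = "black", "15" = "red", "30" = "blue")
  for (n in unique(pd$n)) {
    for (biased in c(TRUE, FALSE)) {
      cur <- pd[pd$n == n & pd$biased == biased, ]
      if (nrow(cur))
        graphics::lines(cur$es, cur$power,
                        col = cols[as.character(n)],
                        lty = if (biased) 1 else 2)
    }
  }
  graphics::legend("bottomright", cex = 0.5, lty = c(1, 2),
                   legend = c("with bias", "without bias"))
  graphics::legend("bottomleft", cex = 0.5, col = cols, lty = 1,
                   legend = paste0("n = ", names(cols)))
}

regional_median_map <- function(fit, uncertainty, labels, metric) {
  out <- array(NA_real_, fit$dim)
  for (r in sort(unique(uncertainty$region))) {
    v <- uncertainty[[metric]][uncertainty$region == r]
    v <- v[is.finite(v)]
    if (length(v)) out[labels == r & fit$mask] <- stats::median(v)
  }
  out
}

#' Render the four-page QA report
#'
#' @param study The `dwi_study` (for motion table, DWI thumbnails and
#'   header info).
#' @param fit The `dti_tensor_fit`.
#' @param metrics List with mandatory components `gof`
#'   ([chi_square_maps()]), `noise` ([estimate_noise()]), `uncertainty`
#'   ([estimate_uncertainty()]), `power` ([regional_power_curves()]),
#'   `summary` ([summarize_regions()]); optional `outlier_counts`,
#'   `sample`.
#' @param reference Optional reference-cohort regional summary (same
#'   columns as `summary`; drawn as thin black boxplots beside the
#'   dataset's).
#' @param out_path Output PDF path.
#' @param png_dir Optional directory for per-page PNG copies.
#' @return (Invisibly) `out_path`.
#' @export
render_report <- function(study, fit, metrics, reference = NULL, out_path,
                          png_dir = NULL) {
  for (need in c("gof", "noise", "uncertainty", "power", "summary"))
    if (is.null(metrics[[need]]))
      stop("missing mandatory metric: ", need)
  labels <- if (!is.null(study$labels)) study$labels else metrics$labels
  pages <- list(
    function() report_page1(study, fit, metrics),
    function() report_page2(metrics, reference),
    function() report_page3(fit, metrics, labels),
    function() report_page4(fit)
  )
  grDevices::pdf(out_path, width = 8.27, height = 11.69, onefile = TRUE)
  on.exit(grDevices::dev.off(), add = TRUE)
  for (p in pages) p()
  if (!is.null(png_dir)) {
    dir.create(png_dir, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_along(pages)) {
      grDevices::png(file.path(png_dir, sprintf("page%d.png", i)),
                     width = 1200, height = 1700, res = 150)
      pages[[i]]()
      grDevices::dev.off()
    }
  }
  invisible(out_path)
}

report_page1 <- function(study, fit, metrics) {
  graphics::par(mfrow = c(1, 1))
  layout_mat <- matrix(c(1, 1,
                         2, 2,
                         3, 3,
                         4, 4,
                         5, 5,
                         6, 7,
                         8, 8), ncol = 2, byrow = TRUE)
  graphics::layout(layout_mat,
                   heights = c(0.9, 1, 1, 1, 1.6, 1.4, 1.4))
  op <- graphics::par(mar = c(2.2, 4, 1.5, 1), cex = 0.6)
  on.exit({ graphics::par(op); graphics::layout(1) }, add = TRUE)
  # header
  graphics::plot.new()
  hdr <- sprintf(
    "DTI QA report | grid %s | J = %d DWIs | b = %g s/mm^2 | voxel %s mm | noise sigma = %.3g%s",
    paste(fit$dim, collapse = "x"), fit$scheme$J, fit$scheme$b_value,
    paste(signif(fit$voxel_size, 3), collapse = "x"),
    metrics$noise$chosen_sigma,
    if (!is.null(metrics$sample))
      sprintf(" | sampled %.1f%% of mask", 100 * metrics$sample$fraction)
    else "")
  graphics::text(0.5, 0.7, "Page 1: input data quality", font = 2,
                 cex = 1.3)
  graphics::text(0.5, 0.25, hdr, cex = 0.85)
  J <- fit$scheme$J
  # motion panels (shared DWI abscissa)
  if (!is.null(study$motion)) {
    m <- study$motion
    graphics::matplot(m$dwi_index,
                      as.matrix(m[, c("tx_mm", "ty_mm", "tz_mm")]),
                      type = "l", lty = 1, col = c("red", "green4", "blue"),
                      xlab = "", ylab = "translation (mm)", xlim = c(1, J))
    graphics::matplot(m$dwi_index,
                      as.matrix(m[, c("rx_deg", "ry_deg", "rz_deg")]),
                      type = "l", lty = 1, col = c("red", "green4", "blue"),
                      xlab = "", ylab = "rotation (deg)", xlim = c(1, J))
  } else {
    for (lab in c("translation (mm)", "rotation (deg)")) {
      graphics::plot(NA, xlim = c(1, J), ylim = c(-1, 1), xlab = "",
                     ylab = lab)
      graphics::text(mean(c(1, J)), 0, "motion table not available",
                     col = "gray40")
    }
  }
  # residual-outlier counts
  if (!is.null(metrics$outlier_counts)) {
    graphics::plot(seq_len(J), metrics$outlier_counts, type = "h",
                   xlab = "", ylab = "outlier voxels", xlim = c(1, J))
  } else {
    graphics::plot(NA, xlim = c(1, J), ylim = c(0, 1), xlab = "",
                   ylab = "outlier voxels")
    graphics::text(mean(c(1, J)), 0.5, "not available", col = "gray40")
  }
  draw_chi_slice_panel(metrics$gof$chi_slice)
  # chi_pix histogram with noise-lobe zoom
  ch <- chi_histogram(metrics$gof$chi_pix)
  graphics::plot(ch$histogram, main = "pixel chi-squared", xlab = "",
                 col = "gray80", border = "gray50", cex.main = 0.8)
  if (!is.null(ch$zoom_histogram)) {
    graphics::plot(ch$zoom_histogram,
                   main = sprintf("noise-lobe zoom [%.3g, %.3g]",
                                  ch$zoom_window[1], ch$zoom_window[2]),
                   xlab = "", col = "indianred", border = "gray50",
                   cex.main = 0.8)
  } else {
    graphics::plot.new(); graphics::title(main = "noise-lobe zoom (empty)")
  }
  # best/worst thumbnails: top entry per axial band
  bw <- best_worst_slices(metrics$gof$chi_slice)
  tops <- do.call(rbind, lapply(split(bw, list(bw$band, bw$kind)),
                                function(d) d[1, , drop = FALSE]))
  tops <- tops[order(tops$kind, tops$band), ]
  graphics::par(mar = c(0.5, 0.5, 1.5, 0.5))
  smap <- fit_map(fit, "s_measured", fill = 0)
  graphics::plot.new()
  n <- nrow(tops)
  w <- 1 / max(n, 1)
  for (i in seq_len(n)) {
    sl <- smap[, , tops$z[i], tops$dwi[i]]
    rng <- range(sl, finite = TRUE); if (diff(rng) == 0) rng[2] <- rng[1] + 1
    gcol <- grDevices::gray((sl - rng[1]) / diff(rng))
    dim(gcol) <- dim(sl)
    ny <- ncol(gcol)
    graphics::rasterImage(t(gcol)[ny:1, , drop = FALSE],
                          (i - 1) * w + 0.05 * w, 0.05,
                          i * w - 0.05 * w, 0.85, interpolate = FALSE)
    graphics::text((i - 0.5) * w, 0.95,
                   sprintf("%s b%d z%d j%d", substr(tops$kind[i], 1, 1),
                           tops$band[i], tops$z[i], tops$dwi[i]),
                   cex = 0.45)
  }
  graphics::title(main = "best (b) / worst (w) DWI slices per axial fifth",
                  cex.main = 0.8)
}

report_page2 <- function(metrics, reference = NULL) {
  summ <- metrics$summary
  full <- summ[summ$region_set == "full", ]
  graphics::layout(matrix(c(1, 2, 3, 4, 5, 5), ncol = 2, byrow = TRUE),
                   heights = c(1, 1, 0.8))
  op <- graphics::par(mar = c(5, 3.5, 2, 0.5), cex = 0.6)
  on.exit({ graphics::par(op); graphics::layout(1) }, add = TRUE)
  titles <- c(md = "MD per region (mm^2/s)", fa = "FA per region",
              sigma_fa = "sigma_FA per region (sampled voxels)",
              bias_fa = "FA bias per region (sampled voxels)")
  for (m in qa_metric_names) {
    ref <- if (!is.null(reference))
      reference[reference$region_set == "full" & reference$metric == m, ]
    else NULL
    bxp_from_summary(full[full$metric == m, ], titles[[m]],
                     reference = ref)
  }
  graphics::plot.new()
  rt <- attr(summ, "region_table")
  graphics::title(main = "Page 2: regional output distributions",
                  cex.main = 1.1)
  txt <- if (!is.null(rt))
    sprintf("%d regions, pooled bilaterally to %d (blue = this dataset%s)",
            nrow(rt), length(unique(rt$pooled)),
            if (is.null(reference)) "" else "; black = reference cohort")
  else ""
  graphics::text(0.5, 0.5, txt, cex = 0.9)
}

report_page3 <- function(fit, metrics, labels) {
  graphics::layout(matrix(c(1, 2, 3, 4,
                            5, 5, 6, 6,
                            7, 8, 9, 9), ncol = 4, byrow = TRUE),
                   heights = c(1, 1.1, 1))
  op <- graphics::par(mar = c(1, 1, 2, 1), cex = 0.6)
  on.exit({ graphics::par(op); graphics::layout(1) }, add = TRUE)
  zmid <- ceiling(fit$dim[3] / 2)
  md_map <- fit_map(fit, "md"); fa_map <- fit_map(fit, "fa")
  draw_slice_image(md_map[, , zmid], "MD (mid-axial)")
  draw_slice_image(fa_map[, , zmid], "FA (mid-axial)", zlim = c(0, 1))
  sg <- regional_median_map(fit, metrics$uncertainty, labels, "sigma_fa")
  bf <- regional_median_map(fit, metrics$uncertainty, labels, "bias_fa")
  draw_slice_image(sg[, , zmid], "regional median sigma_FA")
  draw_slice_image(bf[, , zmid], "regional median B_FA")
  regs <- unique(metrics$power$region)
  draw_power_panel(metrics$power, regs[1],
                   sprintf("power, region %s", regs[1]))
  draw_power_panel(metrics$power, regs[min(2, length(regs))],
                   sprintf("power, region %s", regs[min(2, length(regs))]))
  ax <- e1_rgb_slice(fit, "axial")
  draw_rgb_slice(ax$rgb, "e1 colormap (axial)",
                 c("R = right-left", "G = ant-post"))
  co <- e1_rgb_slice(fit, "coronal")
  draw_rgb_slice(co$rgb, "e1 colormap (coronal)",
                 c("R = right-left", "B = foot-head"))
  sa <- e1_rgb_slice(fit, "sagittal")
  draw_rgb_slice(sa$rgb, "e1 colormap (sagittal)",
                 c("G = ant-post", "B = foot-head"))
}

# in-plane line segments scaled by the in-plane |e1| component
draw_vector_overlay <- function(fit, plane, crop = 1, main = "") {
  sl <- e1_rgb_slice(fit, plane)
  nx <- nrow(sl$rgb); ny <- ncol(sl$rgb)
  cx <- nx / 2; cy <- ny / 2
  hw <- nx / (2 * crop); hh <- ny / (2 * crop)
  graphics::plot(NA, xlim = c(cx - hw, cx + hw), ylim = c(cy - hh, cy + hh),
                 asp = 1, axes = FALSE, xlab = "", ylab = "", main = main,
                 cex.main = 0.7)
  graphics::rasterImage(t(sl$rgb)[ny:1, , drop = FALSE], 0, 0, nx, ny,
                        interpolate = FALSE)
  comp <- switch(plane, axial = c(1, 2), coronal = c(1, 3),
                 sagittal = c(2, 3))
  step <- max(1L, floor(4 / crop))
  for (i in seq(1, nx, by = step)) {
    for (j in seq(1, ny, by = step)) {
      if (!is.finite(sl$fa[i, j]) || sl$fa[i, j] <= 0) next
      u <- sl$e1[i, j, comp[1]]; v <- sl$e1[i, j, comp[2]]
      len <- 0.45 * step * sqrt(u^2 + v^2)
      graphics::segments(i - 0.5 - len * u, j - 0.5 - len * v,
                         i - 0.5 + len * u, j - 0.5 + len * v,
                         col = "white", lwd = 0.4)
    }
  }
}

report_page4 <- function(fit) {
  graphics::layout(matrix(1:6, ncol = 2, byrow = TRUE))
  op <- graphics::par(mar = c(1, 1, 2, 1), cex = 0.6)
  on.exit({ graphics::par(op); graphics::layout(1) }, add = TRUE)
  for (crop in c(1, 2, 4)) {
    draw_vector_overlay(fit, "axial", crop,
                        sprintf("e1 overlay, axial (%dx)", crop))
    draw_vector_overlay(fit, "coronal", crop,
                        sprintf("e1 overlay, coronal (%dx)", crop))
  }
}
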