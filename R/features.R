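# Regional summaries, the 112-element QA feature vector, z-scored PCA
# embedding of a cohort, and within-protocol outlier flagging.

qa_metric_names <- c("md", "fa", "sigma_fa", "bias_fa")

box_stats <- function(v) {
  v <- v[is.finite(v)]
  if (!length(v))
    return(data.frame(n = 0L, median = NA_real_, q1 = NA_real_,
                      q3 = NA_real_, whisker_lo = NA_real_,
                      whisker_hi = NA_real_, n_outliers = NA_integer_,
                      mean = NA_real_, sd = NA_real_))
  bs <- grDevices::boxplot.stats(v)
  data.frame(n = length(v), median = bs$stats[3], q1 = bs$stats[2],
             q3 = bs$stats[4], whisker_lo = bs$stats[1],
             whisker_hi = bs$stats[5], n_outliers = length(bs$out),
             mean = mean(v), sd = stats::sd(v))
}

#' Regional boxplot summaries of MD, FA, sigma_FA and B_FA
#'
#' MD and FA are summarized over every in-mask voxel of each region;
#' sigma_FA and B_FA over the region's Monte-Carlo-sampled voxels only.
#' Statistics are Tukey boxplot five-numbers (quartiles, 1.5 IQR
#' whiskers, outlier count) plus mean and SD, reported for the full
#' region set and for the bilateral-pooled set (left + right voxels
#' united).
#'
#' @param fit A `dti_tensor_fit`.
#' @param uncertainty Data frame from [estimate_uncertainty()] (may be
#'   NULL: sigma_FA/B_FA rows are then absent).
#' @param labels Integer label array.
#' @param region_table Data frame mapping `id` to `name` and `pooled`
#'   (default: the phantom's 25-region dictionary when it matches,
#'   otherwise identity names). Users with their own label sets supply
#'   their own pooling map here.
#' @return Data frame of class `regional_summary` with columns
#'   `region_set` ("full"/"pooled"), `region`, `metric`, and the
#'   statistics columns; empty regions yield NA rows.
#' @export
summarize_regions <- function(fit, uncertainty = NULL, labels,
                              region_table = NULL) {
  ids <- sort(setdiff(unique(as.vector(labels)), 0L))
  if (is.null(region_table)) {
    region_table <- if (length(ids) == 25L)
      phantom_labels(fit$dim)$region_table
    else
      data.frame(id = ids, name = as.character(ids),
                 pooled = as.character(ids), stringsAsFactors = FALSE)
  }
  labv <- labels[fit$idx]
  vox_vals <- list(md = fit$md, fa = fit$fa)
  samp_reg <- uncertainty$region
  samp_vals <- if (!is.null(uncertainty))
    list(sigma_fa = uncertainty$sigma_fa, bias_fa = uncertainty$bias_fa)
  else list()
  one_set <- function(set_name, groups) {
    out <- list()
    for (g in names(groups)) {
      g_ids <- groups[[g]]
      vsel <- labv %in% g_ids
      for (m in names(vox_vals)) {
        st <- box_stats(vox_vals[[m]][vsel])
        out[[length(out) + 1L]] <- cbind(
          region_set = set_name, region = g, metric = m, st)
      }
      for (m in names(samp_vals)) {
        st <- box_stats(samp_vals[[m]][samp_reg %in% g_ids])
        out[[length(out) + 1L]] <- cbind(
          region_set = set_name, region = g, metric = m, st)
      }
    }
    do.call(rbind, out)
  }
  full_groups <- stats::setNames(as.list(region_table$id), region_table$name)
  pooled_groups <- split(region_table$id, region_table$pooled)
  res <- rbind(one_set("full", full_groups),
               one_set("pooled", pooled_groups))
  rownames(res) <- NULL
  class(res) <- c("regional_summary", class(res))
  attr(res, "region_table") <- region_table
  res
}

#' Build the QA feature vector
#'
#' Condenses the pooled regional summary into one vector per dataset:
#' mean and SD of each of the four metrics (MD, FA, sigma_FA, B_FA) in
#' each pooled region, region-major in alphabetical region order. With
#' the default 14-way pooling this yields exactly 14 x 4 x 2 = 112
#' elements. Missing statistics stay NA here and are mean-imputed at
#' embedding time.
#'
#' @param summary A `regional_summary`.
#' @param expected_regions Expected pooled-region count (default 14);
#'   pass NULL to accept any custom region set.
#' @return Named numeric vector of class `qa_feature_vector`.
#' @export
build_feature_vector <- function(summary, expected_regions = 14L) {
  pooled <- summary[summary$region_set == "pooled", ]
  regions <- sort(unique(pooled$region))
  if (!is.null(expected_regions) && length(regions) != expected_regions)
    stop(sprintf("pooled region set has %d regions, expected %d; %s",
                 length(regions), expected_regions,
                 "pass expected_regions = NULL for a custom set"))
  vals <- c(); nms <- c()
  for (r in regions) {
    for (m in qa_metric_names) {
      row <- pooled[pooled$region == r & pooled$metric == m, ]
      mu <- if (nrow(row)) row$mean[1] else NA_real_
      sd <- if (nrow(row)) row$sd[1] else NA_real_
      vals <- c(vals, mu, sd)
      nms <- c(nms, paste(r, m, c("mean", "sd"), sep = "."))
    }
  }
  structure(stats::setNames(vals, nms), class = "qa_feature_vector")
}

#' PCA embedding of a cohort of QA feature vectors
#'
#' Columns are z-scored over the cohort (mean 0, SD 1); NA entries are
#' imputed with the cohort column mean (flagged), constant columns are
#' dropped (recorded), and the principal components are extracted by SVD.
#' Component signs are fixed by making each loading's largest-magnitude
#' entry positive, so the embedding is fully deterministic.
#'
#' @param vectors A list of [build_feature_vector()] outputs or a
#'   datasets x features numeric matrix.
#' @param n_components Components to retain (default 2).
#' @return List of class `cohort_embedding`: `scores` (datasets x
#'   n_components), `loadings`, `explained` (variance fractions, all
#'   components), `dropped_columns`, `n_imputed`, `zscored`.
#' @export
embed_cohort <- function(vectors, n_components = 2L) {
  X <- if (is.matrix(vectors)) vectors else do.call(rbind, vectors)
  if (nrow(X) < 3L) stop("cohort embedding needs at least 3 datasets")
  n_imp <- 0L
  for (j in seq_len(ncol(X))) {
    na <- !is.finite(X[, j])
    if (any(na)) {
      if (all(na)) next
      X[na, j] <- mean(X[!na, j])
      n_imp <- n_imp + sum(na)
    }
  }
  mu <- colMeans(X)
  sg <- apply(X, 2L, stats::sd)
  keep <- is.finite(sg) & sg > 0
  if (!any(keep)) stop("all feature columns are constant")
  Z <- sweep(sweep(X[, keep, drop = FALSE], 2L, mu[keep]), 2L, sg[keep],
             "/")
  sv <- svd(scale(Z, center = TRUE, scale = FALSE))
  expl <- sv$d^2 / sum(sv$d^2)
  k <- min(n_components, length(sv$d))
  load <- sv$v[, seq_len(k), drop = FALSE]
  for (c in seq_len(k)) {
    i <- which.max(abs(load[, c]))
    if (load[i, c] < 0) { load[, c] <- -load[, c]; sv$u[, c] <- -sv$u[, c] }
  }
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  rownames(scores) <- rownames(X)
  structure(list(scores = scores, loadings = load, explained = expl,
                 dropped_columns = colnames(X)[!keep], n_imputed = n_imp,
                 zscored = Z),
            class = "cohort_embedding")
}

#' Flag within-group outliers in the embedding
#'
#' Within each group (protocol/study), computes each dataset's robust
#' distance from the group median in score space -- componentwise robust
#' z-scores (median/MAD) combined in quadrature -- and flags datasets
#' whose distance exceeds `threshold`. Cohorts cluster by protocol, so a
#' large within-protocol distance marks a quality suspect.
#'
#' @param embedding A `cohort_embedding`.
#' @param groups Group label per dataset.
#' @param threshold Robust-distance cutoff (default 3.5).
#' @return Data frame: `dataset`, `group`, `distance`, `flagged`; groups
#'   with fewer than 4 members are skipped with a warning.
#' @export
flag_outliers <- function(embedding, groups, threshold = 3.5) {
  sc <- embedding$scores
  stopifnot(length(groups) == nrow(sc))
  ids <- rownames(sc)
  if (is.null(ids)) ids <- sprintf("ds%02d", seq_len(nrow(sc)))
  out <- list()
  for (g in unique(groups)) {
    rows <- which(groups == g)
    if (length(rows) < 4L) {
      warning("group ", g, " has fewer than 4 datasets; skipped")
      next
    }
    s <- sc[rows, , drop = FALSE]
    med <- apply(s, 2L, stats::median)
    madv <- apply(s, 2L, stats::mad)
    madv[madv == 0] <- apply(s[, madv == 0, drop = FALSE], 2L,
                             stats::sd) + 1e-12
    z <- sweep(sweep(s, 2L, med), 2L, madv, "/")
    d <- sqrt(rowSums(z^2))
    out[[length(out) + 1L]] <- data.frame(
      dataset = ids[rows], group = g, distance = d,
      flagged = d > threshold, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
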