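# End-to-end orchestration: load -> normalize -> fit -> noise estimate ->
# goodness of fit -> subsample -> bootstrap -> SIMEX -> power -> regional
# summaries -> feature vector -> stored outputs -> report.

#' Pipeline configuration
#'
#' @param fast Use reduced Monte-Carlo settings (bootstrap 100 reps,
#'   SIMEX 200 reps per omega) suited to desk-scale runs; the full
#'   settings are 1000 bootstrap reps and 2000/4000/6000/8000 SIMEX reps.
#' @param n_boot,omegas,simex_reps,target_fraction,min_per_region,
#'   outlier_threshold,n_list,alpha_nom,render_report Individual
#'   overrides.
#' @return Named list of settings.
#' @export
qa_config <- function(fast = FALSE,
                      n_boot = if (fast) 100L else 1000L,
                      omegas = c(2, 4, 6, 8),
                      simex_reps = if (fast) rep(200L, 4L) else
                        c(2000L, 4000L, 6000L, 8000L),
                      target_fraction = 0.04,
                      min_per_region = 50L,
                      outlier_threshold = 3,
                      n_list = c(5L, 15L, 30L),
                      alpha_nom = 0.05,
                      render_report = TRUE) {
  list(n_boot = n_boot, omegas = omegas, simex_reps = simex_reps,
       target_fraction = target_fraction, min_per_region = min_per_region,
       outlier_threshold = outlier_threshold, n_list = n_list,
       alpha_nom = alpha_nom, render_report = render_report)
}

#' Run the full QA pipeline on one study
#'
#' @param study A `dwi_study` (e.g. from [load_study()] or
#'   [generate_phantom()]); must carry a label volume for the regional
#'   stages.
#' @param out_dir Output directory for stored outputs and the report
#'   (NULL: nothing written, results returned only).
#' @param seed Master seed; every stochastic stage draws its own seed
#'   from it.
#' @param config Settings from [qa_config()].
#' @param region_table Optional label dictionary / pooling map (see
#'   [summarize_regions()]).
#' @param reference Optional reference regional summary for the report.
#' @param verbose Log each stage.
#' @return List of class `qa_result`: `fit`, `metrics` (noise, gof,
#'   sample, uncertainty, power, summary, feature_vector,
#'   outlier_counts), `manifest`, `report` (PDF path or NULL), `timings`.
#' @export
run_qa_pipeline <- function(study, out_dir = NULL, seed = 1L,
                            config = qa_config(), region_table = NULL,
                            reference = NULL, verbose = TRUE) {
  stopifnot(inherits(study, "dwi_study"))
  log_stage <- function(...) if (verbose) message(sprintf(...))
  timings <- c()
  tick <- function(name, expr) {
    t0 <- proc.time()[3]
    r <- force(expr)
    timings[name] <<- proc.time()[3] - t0
    log_stage("stage %-12s %6.1fs", name, timings[name])
    r
  }
  stage_seeds <- withr_seed(seed, sample.int(2147483L, 4L))

  fit <- tick("fit", fit_study(study))
  noise <- tick("noise", estimate_noise(study))
  gof <- tick("gof", chi_square_maps(fit))
  outl <- tick("outliers", {
    if (noise$chosen_sigma > 0)
      outlier_voxels_per_dwi(fit, noise$chosen_sigma,
                             threshold = config$outlier_threshold)
    else rep(0L, fit$scheme$J)
  })
  samp <- tick("sample", subsample_voxels(
    study$labels, study$mask, target_fraction = config$target_fraction,
    min_per_region = config$min_per_region, seed = stage_seeds[1]))
  unc <- tick("uncertainty", estimate_uncertainty(
    study, fit, samp, sigma_hat = noise$chosen_sigma,
    n_boot = config$n_boot, omegas = config$omegas,
    simex_reps = config$simex_reps, seed = stage_seeds[2]))
  power <- tick("power", regional_power_curves(
    unc, n_list = config$n_list, alpha_nom = config$alpha_nom))
  summ <- tick("summary", summarize_regions(
    fit, unc, study$labels, region_table = region_table))
  fv <- tick("features", tryCatch(
    build_feature_vector(summ),
    error = function(e) {
      log_stage("feature vector skipped: %s", conditionMessage(e))
      NULL
    }))

  metrics <- list(noise = noise, gof = gof, sample = samp,
                  uncertainty = unc, power = power, summary = summ,
                  feature_vector = fv, outlier_counts = outl,
                  labels = study$labels)
  manifest <- NULL; report <- NULL
  if (!is.null(out_dir)) {
    manifest <- tick("save", save_outputs(fit, metrics, out_dir))
    if (isTRUE(config$render_report)) {
      report <- file.path(out_dir, "qa_report.pdf")
      tick("report", render_report(study, fit, metrics,
                                   reference = reference,
                                   out_path = report))
      manifest$qa_report <- "qa_report.pdf"
      jsonlite::write_json(
        c(manifest, list(seed = seed,
                         stage_seeds = as.list(stage_seeds))),
        file.path(out_dir, "manifest.json"), auto_unbox = TRUE,
        pretty = TRUE)
    }
  }
  structure(list(fit = fit, metrics = metrics, manifest = manifest,
                 report = report, timings = timings),
            class = "qa_result")
}

#' @export
print.qa_result <- function(x, ...) {
  cat(sprintf(
    "<qa_result> %d voxels fit, sigma = %.3g, %d sampled voxels, total %.1fs\n",
    length(x$fit$idx), x$metrics$noise$chosen_sigma,
    nrow(x$metrics$uncertainty), sum(x$timings)))
  invisible(x)
}
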