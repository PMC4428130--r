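#' End-to-end analysis configuration
#'
#' Exactly one of `phantom` (a [phantom_spec()]) or `series_path` (+
#' `mask_path`) must be given. The pipeline smooths, builds the design,
#' runs the reference frequentist GLM and the variational-Bayes fit,
#' converts the task-contrast posterior to percent signal change, predicts
#' gamma for each requested scenario, classifies voxels at the given LBT,
#' and — when ground truth is available — scores the activated label
#' against it.
#'
#' @param phantom optional [phantom_spec()].
#' @param series_path,mask_path,confounds_path optional NIfTI/TSV inputs.
#' @param tr_s repetition time when reading files.
#' @param protocol a [stimulus_protocol()]; defaults to the phantom's block
#'   design (required for file input).
#' @param scenario `"loci"`, `"extent"` or `"both"`.
#' @param fwhm_mm pre-smoothing kernel FWHM in mm (0 disables).
#' @param lbt log Bayes factor threshold.
#' @param fwe_alpha familywise error level for the frequentist reference.
#' @param ar_order VB noise model order.
#' @param vb_args extra arguments passed to [vb_fit()].
#' @param output_dir optional directory: maps, tables, a YAML run report
#'   and a log are written there.
#' @param seed integer seed recorded in the report (the analysis itself is
#'   deterministic).
#' @return An object of class `run_config`.
#' @export
run_config <- function(phantom = NULL, series_path = NULL, mask_path = NULL,
                       confounds_path = NULL, tr_s = NULL, protocol = NULL,
                       scenario = c("both", "loci", "extent"),
                       fwhm_mm = 4, lbt = 10, fwe_alpha = 0.05,
                       ar_order = 2L, vb_args = list(),
                       output_dir = NULL, seed = 1L) {
  scenario <- match.arg(scenario)
  if (is.null(phantom) == is.null(series_path))
    stop("exactly one of `phantom` or `series_path` must be given")
  if (!is.null(phantom)) stopifnot(inherits(phantom, "phantom_spec"))
  if (!is.null(series_path) && is.null(protocol))
    stop("file input needs an explicit stimulus `protocol`")
  structure(list(phantom = phantom, series_path = series_path,
                 mask_path = mask_path, confounds_path = confounds_path,
                 tr_s = tr_s, protocol = protocol, scenario = scenario,
                 fwhm_mm = fwhm_mm, lbt = lbt, fwe_alpha = fwe_alpha,
                 ar_order = as.integer(ar_order), vb_args = vb_args,
                 output_dir = output_dir, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full posterior-probability-mapping pipeline
#'
#' Stages: smooth, design, frequentist reference fit, VB fit, percent
#' effect map, gamma prediction per scenario, PPM classification, cluster
#' metrics against ground truth (phantom input only), output writing. Any
#' stage failure aborts with the stage name; partial outputs written so far
#' are kept next to a `FAILED` marker file.
#'
#' @param config a [run_config()].
#' @return A list of class `ppm_run` with the fitted objects, per-scenario
#'   results, and the run report.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$output_dir
  log_lines <- character()
  note <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    log_lines <<- c(log_lines, line)
    invisible(NULL)
  }
  stage <- "setup"
  on_fail <- function(e) {
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      writeLines(c(log_lines, paste("FAILED at stage:", stage),
                   conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
    }
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  }
  tryCatch({
    truth <- NULL
    if (!is.null(config$phantom)) {
      stage <- "simulate"
      note("generating phantom (seed ", config$phantom$seed, ")")
      ph <- generate_phantom(config$phantom)
      series <- ph$series
      truth <- ph$truth
      protocol <- phantom_protocol(config$phantom)
      confounds <- NULL
    } else {
      stage <- "read"
      note("reading ", config$series_path)
      series <- read_bold(config$series_path, config$mask_path, config$tr_s)
      protocol <- config$protocol
      confounds <- if (!is.null(config$confounds_path))
        read_confounds(config$confounds_path)
    }

    stage <- "smooth"
    if (config$fwhm_mm > 0) {
      note("Gaussian smoothing, FWHM ", config$fwhm_mm, " mm")
      series <- gaussian_smooth(series, config$fwhm_mm)
    }

    stage <- "design"
    design <- build_design_matrix(protocol, confounds)
    contrast <- positive_task_contrast(design)
    note("design: ", ncol(design$matrix), " regressors x ",
         nrow(design$matrix), " scans")

    stage <- "fit-frequentist"
    freq <- fit_glm(series, design)
    tm <- t_map(freq, contrast)
    n_vox <- sum(series$mask)
    t_fwe <- t_from_fwe(config$fwe_alpha, freq$dof, n_vox)
    note("frequentist reference: dof ", freq$dof, ", Bonferroni t(",
         config$fwe_alpha, ") = ", signif(t_fwe, 4))

    stage <- "fit-vb"
    vb <- do.call(vb_fit, c(list(series = series, design = design,
                                 ar_order = config$ar_order),
                            config$vb_args))
    note("VB fit: ", vb$iterations, " iterations (", vb$stop_reason, ")")

    stage <- "effect-map"
    effect <- to_percent(contrast_posterior(vb, contrast), vb)

    stage <- "classify"
    scenarios <- if (config$scenario == "both") c("loci", "extent")
    else config$scenario
    results <- list()
    for (sc in scenarios) {
      model <- threshold_model(sc)
      gamma <- predict(model, effect)
      ppm <- classify_voxels(effect, lbt = config$lbt, gamma = gamma)
      note("scenario ", sc, ": gamma = ", signif(gamma, 4), ", activated ",
           sum(ppm$labels == 1L), " voxels")
      metrics <- NULL
      if (!is.null(truth)) {
        metrics <- confusion_metrics(ppm$labels == 1L,
                                     truth$label_map == 1L, series$mask)
        note("scenario ", sc, ": sensitivity ",
             signif(metrics$sensitivity, 4), ", FDR ",
             signif(metrics$fdr, 4))
      }
      results[[sc]] <- list(model = model, gamma = gamma, ppm = ppm,
                            metrics = metrics)
    }

    stage <- "report"
    report <- list(
      seed = config$seed,
      package_version = as.character(utils::packageVersion("bayesppm")),
      r_version = R.version.string,
      scans = nrow(design$matrix), voxels = n_vox,
      fwhm_mm = config$fwhm_mm, ar_order = config$ar_order,
      lbt = config$lbt, p_threshold = lbt_to_probability(config$lbt),
      fwe_alpha = config$fwe_alpha, t_fwe = t_fwe,
      vb_iterations = vb$iterations, vb_converged = vb$converged,
      free_energy = utils::tail(vb$free_energy, 1),
      scenarios = lapply(results, function(r)
        list(slope = r$model$slope, top_fraction = r$model$top_fraction,
             gamma = r$gamma,
             sensitivity = if (!is.null(r$metrics)) r$metrics$sensitivity,
             fdr = if (!is.null(r$metrics)) r$metrics$fdr)),
      config_hash = config_hash(config))

    if (!is.null(out_dir)) {
      stage <- "write"
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      vs <- series$voxel_size_mm
      write_volume(series, file.path(out_dir, "series_smoothed.nii"))
      write_mask(series$mask, file.path(out_dir, "mask.nii"), vs)
      write_volume(tm, file.path(out_dir, "tmap.nii"), vs)
      write_volume(effect, file.path(out_dir, "effect_percent.nii"), vs)
      for (sc in names(results)) {
        write_volume(results[[sc]]$ppm,
                     file.path(out_dir, paste0("labels_", sc, ".nii")), vs)
      }
      if (!is.null(truth))
        write_volume(truth$label_map, file.path(out_dir, "truth_labels.nii"),
                     vs)
      write_design_matrix(design, file.path(out_dir, "design.tsv"))
      yaml::write_yaml(report, file.path(out_dir, "run_report.yaml"))
      writeLines(log_lines, file.path(out_dir, "run.log"))
      note("outputs written to ", out_dir)
    }

    structure(list(series = series, design = design, freq = freq, tmap = tm,
                   vb = vb, effect = effect, results = results,
                   truth = truth, report = report, log = log_lines),
              class = "ppm_run")
  }, error = on_fail)
}

config_hash <- function(config) {
  flat <- paste(utils::capture.output(utils::str(config, digits.d = 12)),
                collapse = "\n")
  bytes <- as.numeric(charToRaw(flat))
  sum(bytes * seq_along(bytes)) %% 2147483647
}

#' @export
print.ppm_run <- function(x, ...) {
  cat("<ppm_run> ", x$report$scans, " scans, ", x$report$voxels,
      " voxels; LBT ", x$report$lbt, "\n", sep = "")
  for (sc in names(x$results)) {
    r <- x$results[[sc]]
    cat("  ", sc, ": gamma ", signif(r$gamma, 4), ", activated ",
        sum(r$ppm$labels == 1L), " voxels", sep = "")
    if (!is.null(r$metrics))
      cat("; sensitivity ", signif(r$metrics$sensitivity, 3),
          ", FDR ", signif(r$metrics$fdr, 3), sep = "")
    cat("\n")
  }
  invisible(x)
}
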