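#' Pipeline configuration
#'
#' Composite configuration for the end-to-end run: a simulation block (the
#' pipeline's demonstration mode generates its input), a preprocessing
#' block, classification settings and selection settings.
#'
#' @param simulation a [sim_config()] (or `NULL` when runs are supplied to
#'   [run_pipeline()] directly).
#' @param preprocess a [preprocess_config()].
#' @param K,seed,lambda,threshold classification settings: folds, fold seed,
#'   L2 penalty, decision threshold.
#' @param alpha feature-selection significance threshold.
#' @param select_features whether to run the feature-selection stage.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(simulation = sim_config(seed = 1),
                            preprocess = preprocess_config(),
                            K = 10, seed = 1, lambda = 1e-2,
                            threshold = 0.5, alpha = 0.05,
                            select_features = TRUE) {
  assert_count(K, "K", min = 2L)
  assert_count(seed, "seed", min = 0L)
  assert_scalar_number(lambda, "lambda", min = 0)
  assert_scalar_number(threshold, "threshold", min = 0)
  assert_scalar_number(alpha, "alpha", min = 0, strict_min = TRUE)
  structure(list(simulation = simulation, preprocess = preprocess,
                 K = as.integer(K), seed = as.integer(seed), lambda = lambda,
                 threshold = threshold, alpha = alpha,
                 select_features = isTRUE(select_features)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors the [pipeline_config()] structure, with `simulation:`
#' and `preprocess:` blocks holding the [sim_config()] /
#' [preprocess_config()] fields. Unknown fields raise a configuration
#' error; the simulation seed is mandatory.
#'
#' @param path YAML file path.
#' @return a validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("simulation", "preprocess", "K", "seed", "lambda", "threshold",
             "alpha", "select_features")
  extra <- setdiff(names(raw), known)
  if (length(extra) > 0) {
    abort(sprintf("unknown pipeline config field(s): %s",
                  paste(extra, collapse = ", ")),
          class = "msitma_config_error")
  }
  sim <- if (!is.null(raw$simulation)) do.call(sim_config, raw$simulation)
  pre <- if (!is.null(raw$preprocess)) do.call(preprocess_config, raw$preprocess)
         else preprocess_config()
  args <- raw[setdiff(names(raw), c("simulation", "preprocess"))]
  do.call(pipeline_config, c(list(simulation = sim, preprocess = pre), args))
}

#' Path of the bundled demonstration configuration
#'
#' @return file path to the demo YAML shipped with the package.
#' @export
demo_config_path <- function() {
  system.file("extdata", "demo_config.yaml", package = "msitma",
              mustWork = TRUE)
}

pipeline_stage <- function(name, manifest_env, out_dir, expr) {
  t0 <- proc.time()[["elapsed"]]
  message(sprintf("[msitma] stage %-16s ...", name))
  res <- tryCatch(expr, error = function(e) {
    if (!is.null(out_dir)) {
      writeLines(manifest_env$done, file.path(out_dir, "MANIFEST"))
    }
    abort(sprintf("pipeline aborted in stage '%s': %s", name,
                  conditionMessage(e)),
          class = "msitma_pipeline_error", parent = e)
  })
  manifest_env$done <- c(manifest_env$done, name)
  message(sprintf("[msitma] stage %-16s done in %.2f s", name,
                  proc.time()[["elapsed"]] - t0))
  res
}

#' Run the full pipeline
#'
#' Executes simulate (optional) -> preprocess (common axis, recalibration,
#' rasterisation, segmentation, spatial filtering, reference scaling) ->
#' core extraction with median fold change normalisation -> slide-aware
#' cross-validated weighted logistic regression -> feature selection with
#' refit. When `out_dir` is given, writes the core table, ROC points and
#' per-feature statistics as CSV, the run report as JSON, and a MANIFEST of
#' completed stages (also on failure, so partial output is accounted for).
#'
#' @param config a [pipeline_config()].
#' @param runs,cores optional precomputed input (list of `msi_run` plus the
#'   core annotation tibble); when `NULL`, the simulation block generates
#'   them.
#' @param out_dir optional output directory (created if absent).
#' @return invisible list: `report` (everything a rerun needs: parameters
#'   used, per-run ppm offsets and scalars, retained feature count, metric
#'   sets), `core_table`, `cv_full`, `selection` (`NULL` unless
#'   `select_features`).
#' @export
run_pipeline <- function(config, runs = NULL, cores = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  manifest <- new.env(parent = emptyenv())
  manifest$done <- character(0)

  if (is.null(runs)) {
    sim <- pipeline_stage("simulate", manifest, out_dir, {
      if (is.null(config$simulation)) {
        abort("no input runs and no simulation block in the config.",
              class = "msitma_config_error")
      }
      simulate_dataset(config$simulation)
    })
    runs <- sim$runs
    cores <- sim$cores
  }
  pre <- config$preprocess

  axis <- pipeline_stage("common_axis", manifest, out_dir, {
    peaklists <- lapply(runs, function(r) {
      tibble::tibble(mz = r$axis, intensity = colMeans(r$intensities))
    })
    build_common_axis(peaklists, pre$ppm_tol)
  })

  runs <- pipeline_stage("recalibrate", manifest, out_dir, {
    lapply(runs, recalibrate_run_matrix, axis = axis, ppm_tol = pre$ppm_tol)
  })
  offsets <- vapply(runs, attr, numeric(1), "offset_ppm")
  names(offsets) <- vapply(runs, `[[`, character(1), "run_id")

  runs <- pipeline_stage("rasterize", manifest, out_dir,
                         rasterize_runs(runs, axis, pre$ppm_tol))

  segs <- pipeline_stage("segment", manifest, out_dir, {
    lapply(runs, segment_kmeans, k = 2, seed = pre$kmeans_seed,
           background_tic_fraction = pre$background_tic_fraction)
  })

  retained <- pipeline_stage("spatial_filter", manifest, out_dir, {
    per_run <- lapply(seq_along(runs), function(i) {
      scores <- spatial_filter_features(runs[[i]], segs[[i]]$tissue_mask,
                                        pre$spatial_filter_min_fraction)
      scores$retained
    })
    # keep features plausible on every run
    which(Reduce(`&`, per_run))
  })
  if (length(retained) == 0) {
    abort("pipeline aborted in stage 'spatial_filter': no feature retained.",
          class = "msitma_pipeline_error")
  }
  runs <- lapply(runs, function(r) {
    msi_run(r$intensities[, retained, drop = FALSE], r$coords,
            r$axis[retained], r$run_id, r$slide_id, r$pixel_size_um)
  })
  axis <- axis[retained]

  assignments <- pipeline_stage("assign_cores", manifest, out_dir, {
    lapply(seq_along(runs), function(i) {
      slide_cores <- cores[cores$slide_id == runs[[i]]$slide_id, ]
      assign_pixels_to_cores(runs[[i]], slide_cores, segs[[i]]$tissue_mask)
    })
  })

  scaled <- pipeline_stage("reference_scale", manifest, out_dir, {
    ref_masks <- lapply(seq_along(runs), function(i) {
      ref_ids <- cores$core_id[cores$slide_id == runs[[i]]$slide_id &
                                 cores$label == "reference"]
      if (length(ref_ids) == 0) {
        abort(sprintf("reference_intensity_scale: slide '%s' has no reference core.",
                      runs[[i]]$slide_id),
              class = "msitma_validation_error")
      }
      assignments[[i]] %in% ref_ids
    })
    reference_intensity_scale(runs, ref_masks)
  })
  runs <- scaled$runs

  core_table <- pipeline_stage("extract_cores", manifest, out_dir, {
    tables <- lapply(seq_along(runs), function(i) {
      slide_cores <- cores[cores$slide_id == runs[[i]]$slide_id, ]
      average_core_spectra(runs[[i]], assignments[[i]], slide_cores)
    })
    bind_core_tables(tables)
  })

  core_table <- pipeline_stage("mfc_normalize", manifest, out_dir, {
    norm <- median_fold_change_normalize(core_table$spectrum)
    core_table$spectrum <- norm$X
    core_table$mfc_factor <- norm$factors
    core_table
  })

  cv_full <- pipeline_stage("classify", manifest, out_dir, {
    table <- as_core_feature_table(core_table)
    cross_validate(table, K = config$K, seed = config$seed,
                   lambda = config$lambda, threshold = config$threshold)
  })

  selection <- NULL
  if (config$select_features) {
    selection <- pipeline_stage("select_features", manifest, out_dir, {
      table <- as_core_feature_table(core_table)
      select_and_refit(table, K = config$K, cv_seed = config$seed,
                       lambda = config$lambda, alpha = config$alpha)
    })
  }

  report <- list(
    parameters = list(
      ppm_tol = pre$ppm_tol, snr_min = pre$snr_min,
      kmeans_seed = pre$kmeans_seed,
      background_tic_fraction = pre$background_tic_fraction,
      spatial_filter_min_fraction = pre$spatial_filter_min_fraction,
      K = config$K, seed = config$seed, lambda = config$lambda,
      threshold = config$threshold, alpha = config$alpha),
    simulation = if (!is.null(config$simulation))
      unclass(config$simulation),
    n_axis = length(axis) ,
    run_offsets_ppm = as.list(offsets),
    reference_scalars = as.list(scaled$scalars),
    n_features_retained = length(retained),
    n_cores = nrow(core_table),
    metrics_full = c(as.list(cv_full$metrics), auc = cv_full$auc,
                     confusion = as.list(cv_full$confusion)),
    metrics_reduced = if (!is.null(selection))
      c(as.list(selection$cv_reduced$metrics), auc = selection$cv_reduced$auc,
        confusion = as.list(selection$cv_reduced$confusion)),
    n_selected = if (!is.null(selection)) length(selection$selected))

  if (!is.null(out_dir)) {
    pipeline_stage("write_outputs", manifest, out_dir, {
      write_core_table(core_table, file.path(out_dir, "core_table.csv"))
      utils::write.csv(cv_full$roc, file.path(out_dir, "roc_full.csv"),
                       row.names = FALSE)
      if (!is.null(selection)) {
        utils::write.csv(selection$cv_reduced$roc,
                         file.path(out_dir, "roc_reduced.csv"),
                         row.names = FALSE)
        utils::write.csv(selection$features,
                         file.path(out_dir, "feature_selection.csv"),
                         row.names = FALSE)
      }
      jsonlite::write_json(report, file.path(out_dir, "report.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    })
    writeLines(manifest$done, file.path(out_dir, "MANIFEST"))
  }

  invisible(list(report = report, core_table = core_table,
                 cv_full = cv_full, selection = selection))
}
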