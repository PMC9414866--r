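#' Configuration of a full synthetic study run
#'
#' Bundles every knob of the simulate-extract-select-classify pipeline.
#' The defaults reproduce the reference study conditions: 12 horses, 6
#' riders (2 per bodyweight group), pre- and post-exercise imaging (144
#' images), 64 x 64 false-color images with two 24 x 24 ROIs, default
#' entropy parameters and 64-level GLCM features, alpha = 0.05.
#'
#' @param seed Global seed; per-image seeds are derived as `seed + i` for
#'   image `i` (the documented fan-out scheme).
#' @param n_horses Number of horses.
#' @param riders Rider roster, see [default_riders()].
#' @param model [texture_model()].
#' @param image_size `c(height, width)` in pixels.
#' @param params [entropy_params()].
#' @param glcm_levels Gray levels of the GLCM features.
#' @param alpha Significance level used by all selection tests.
#' @param horse_weight_sd,saddle_weight_sd Optional weight jitter (kg).
#' @return A list of class `study_config`.
#' @export
study_config <- function(seed = 1, n_horses = 12, riders = default_riders(),
                         model = texture_model(), image_size = c(64, 64),
                         params = entropy_params(), glcm_levels = 64,
                         alpha = 0.05, horse_weight_sd = 0,
                         saddle_weight_sd = 0) {
  structure(
    list(seed = as.integer(seed), n_horses = n_horses, riders = riders,
         model = model, image_size = image_size, params = params,
         glcm_levels = glcm_levels, alpha = alpha,
         horse_weight_sd = horse_weight_sd,
         saddle_weight_sd = saddle_weight_sd),
    class = "study_config"
  )
}

#' Run the full pipeline: simulate, extract, select, classify
#'
#' Executes the four stages in order on a synthetic study and optionally
#' writes every stage output (`design.csv`, `measures.csv`, `ledger.csv`,
#' `glcm_ledger.csv`, `accuracy.csv`, `roi_specs.json`, `manifest.json`)
#' to `out_dir`. Re-running with the same configuration and seed
#' reproduces all CSV outputs byte-identically. The selection stage can
#' also be run on externally supplied measures via [select_measures()]
#' (real-data mode); this driver covers the synthetic path.
#'
#' @param config A [study_config()].
#' @param out_dir Optional output directory.
#' @return Object of class `equitherm_run`: list with `design`,
#'   `measures`, `selection`, `accuracy` and `manifest`.
#' @export
run_full <- function(config = study_config(), out_dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  design <- make_design(
    n_horses = config$n_horses, riders = config$riders,
    horse_weight_sd = config$horse_weight_sd,
    saddle_weight_sd = config$saddle_weight_sd, seed = config$seed
  )
  roi_specs <- default_roi_specs(config$image_size)
  measures <- study_measures(design, config$model, config$image_size,
                             config$params, config$glcm_levels,
                             seed = config$seed, roi_specs = roi_specs)
  selection <- suppressWarnings(
    select_measures(measures, config$alpha)
  )
  accuracy <- detection_accuracy(measures, selection)
  manifest <- list(
    package_version = as.character(utils::packageVersion("equitherm")),
    seed = config$seed,
    seed_scheme = "design uses seed; image i uses seed + i",
    n_images = nrow(design),
    image_size = config$image_size,
    alpha = config$alpha,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  run <- structure(
    list(design = design, measures = measures, selection = selection,
         accuracy = accuracy, manifest = manifest),
    class = "equitherm_run"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(design = "design.csv", measures = "measures.csv",
               ledger = "ledger.csv", glcm_ledger = "glcm_ledger.csv",
               accuracy = "accuracy.csv")
    utils::write.csv(design, file.path(out_dir, paths["design"]),
                     row.names = FALSE)
    utils::write.csv(measures, file.path(out_dir, paths["measures"]),
                     row.names = FALSE)
    utils::write.csv(selection$ledger, file.path(out_dir, paths["ledger"]),
                     row.names = FALSE)
    utils::write.csv(selection$glcm, file.path(out_dir, paths["glcm_ledger"]),
                     row.names = FALSE)
    utils::write.csv(accuracy, file.path(out_dir, paths["accuracy"]),
                     row.names = FALSE)
    write_roi_specs(roi_specs, file.path(out_dir, "roi_specs.json"))
    manifest$digests <- as.list(tools::md5sum(file.path(out_dir, paths)))
    names(manifest$digests) <- paths
    run$manifest <- manifest
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  run
}

#' Human-readable summary of a pipeline run
#'
#' Prints the selection pass-matrices (which measure/component/ROI
#' combinations passed each criterion) and the accuracy grid of the
#' selected combinations at the three thresholds.
#'
#' @param run An [run_full()] result.
#' @return The report lines, invisibly.
#' @export
report <- function(run) {
  stopifnot(inherits(run, "equitherm_run"))
  l <- run$selection$ledger
  lines <- c(
    sprintf("equitherm run: %d images, %d candidate combinations",
            run$manifest$n_images, nrow(l)),
    sprintf("criterion 1 passed: %d; criterion 2: %d; criterion 3: %d",
            sum(l$crit1_pass), sum(l$crit2_pass), sum(l$crit3_pass))
  )
  sel <- l[l$crit3_pass, ]
  if (nrow(sel) == 0) {
    lines <- c(lines, "no combination selected")
  } else {
    lines <- c(lines, sprintf("selected: %s / %s / %s",
                              sel$measure, sel$component, sel$roi))
  }
  if (nrow(run$accuracy) > 0) {
    a <- run$accuracy
    lines <- c(lines, "accuracy (Se/Sp/PPV/NPV by threshold):")
    for (i in seq_len(nrow(a))) {
      lines <- c(lines, sprintf(
        "  %s/%s/%s @ %-4s Se %.2f Sp %.2f PPV %s NPV %s",
        a$measure[i], a$component[i], a$roi[i], a$threshold[i],
        a$Se[i], a$Sp[i],
        ifelse(is.na(a$PPV[i]), "NA", sprintf("%.2f", a$PPV[i])),
        ifelse(is.na(a$NPV[i]), "NA", sprintf("%.2f", a$NPV[i]))
      ))
    }
  }
  cat(paste(lines, collapse = "\n"), "\n")
  invisible(lines)
}

#' @export
print.equitherm_run <- function(x, ...) {
  report(x)
  invisible(x)
}
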