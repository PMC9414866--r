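#' Entropy and GLCM measures of one thermogram
#'
#' Extracts both ROIs from a thermogram, decomposes each into grayscale
#' plus red/green/blue component matrices, and computes the five
#' bidimensional entropy measures and the three entropy-related GLCM
#' texture features on every component. Returns the tidy long
#' MeasureTable rows for this image.
#'
#' @param tg A [generate_thermogram()] object, or any list with elements
#'   `rgb`, `roi_specs` and a `metadata` row carrying `horse`, `rider`,
#'   `group`, `session`, `ratio`.
#' @param params [entropy_params()] for the entropy measures.
#' @param glcm_levels Gray levels for the GLCM features.
#' @return A tibble with columns `horse`, `rider`, `group`, `session`,
#'   `ratio`, `roi`, `component`, `measure`, `measure_type`, `value`.
#' @export
thermogram_measures <- function(tg, params = entropy_params(),
                                glcm_levels = 64) {
  meta <- tg$metadata
  rows <- list()
  for (roi in tg$roi_specs) {
    comp <- decompose_components(extract_roi(tg$rgb, roi))
    for (cn in c("gray", "red", "green", "blue")) {
      patch <- comp[[cn]]
      ent <- entropy_profile(patch, params)
      glc <- entropy_features(glcm(patch, levels = glcm_levels))
      rows[[length(rows) + 1]] <- tibble::tibble(
        horse = meta$horse, rider = meta$rider,
        group = as.character(meta$group),
        session = as.character(meta$session), ratio = meta$ratio,
        roi = roi$label, component = cn,
        measure = c(names(ent), names(glc)),
        measure_type = rep(c("entropy", "glcm"), c(length(ent), length(glc))),
        value = unname(c(ent, glc))
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Extract the MeasureTable of a full synthetic study
#'
#' Generates one thermogram per design row (seeded reproducibly: image
#' `i` uses `seed + i`) and accumulates the per-image measures into the
#' study's tidy MeasureTable. Degenerate-patch warnings (e.g. a constant
#' color component, whose dispersion entropy is 0 by rule) and
#' undefined-sample-entropy warnings are muffled here and counted in the
#' `n_degenerate` attribute, so that batch extraction stays quiet.
#'
#' @param design A [make_design()] table.
#' @param model A [texture_model()].
#' @param size Image size `c(height, width)`.
#' @param params [entropy_params()].
#' @param glcm_levels Gray levels for the GLCM features.
#' @param seed Integer base seed for the per-image noise.
#' @param roi_specs ROI layout.
#' @return MeasureTable tibble (see [thermogram_measures()]).
#' @export
study_measures <- function(design, model = texture_model(), size = c(64, 64),
                           params = entropy_params(), glcm_levels = 64,
                           seed = 1, roi_specs = default_roi_specs(size)) {
  n_deg <- 0L
  out <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    tg <- generate_thermogram(design[i, ], model, size, roi_specs,
                              seed = seed + i)
    out[[i]] <- withCallingHandlers(
      thermogram_measures(tg, params, glcm_levels),
      equitherm_warning = function(w) {
        n_deg <<- n_deg + 1L
        invokeRestart("muffleWarning")
      }
    )
  }
  res <- dplyr::bind_rows(out)
  attr(res, "n_degenerate") <- n_deg
  res
}

#' Extract measures from image files (real-data mode)
#'
#' Computes the same MeasureTable as [study_measures()] from images on
#' disk: a design/metadata table whose `image` column names the files, and
#' a shared ROI specification.
#'
#' @param design Data frame with one row per image; must contain `image`
#'   (file path) plus `horse`, `rider`, `group`, `session`, `ratio`.
#' @param roi_specs List of [roi_spec()] objects, or a path to a
#'   `roi_specs.json` file.
#' @param params [entropy_params()].
#' @param glcm_levels Gray levels for the GLCM features.
#' @return MeasureTable tibble.
#' @export
image_file_measures <- function(design, roi_specs, params = entropy_params(),
                                glcm_levels = 64) {
  if (is.character(roi_specs)) roi_specs <- read_roi_specs(roi_specs)
  out <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    tg <- list(rgb = load_image(design$image[i]), roi_specs = roi_specs,
               metadata = design[i, ])
    out[[i]] <- withCallingHandlers(
      thermogram_measures(tg, params, glcm_levels),
      equitherm_warning = function(w) invokeRestart("muffleWarning")
    )
  }
  dplyr::bind_rows(out)
}

#' Read or write a MeasureTable CSV
#'
#' Thin wrappers fixing the column layout of the pipeline's central
#' exchange file `measures.csv`.
#'
#' @param measures MeasureTable tibble.
#' @param path CSV path.
#' @return `read_measures()` returns a tibble; `write_measures()` returns
#'   `path` invisibly.
#' @export
write_measures <- function(measures, path) {
  utils::write.csv(measures, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_measures
#' @export
read_measures <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
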