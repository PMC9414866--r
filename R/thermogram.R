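#' Texture model for synthetic thermograms
#'
#' Parameterizes the synthetic temperature field: a spatially smooth
#' background (Gaussian-smoothed white noise with a given correlation
#' length) plus i.i.d. irregularity noise whose amplitude depends on
#' session and rider group, plus a multiplicative hot-region gain inside
#' the ROI masks after exercise. Irregularity is the single monotone dial
#' of the model: the post-exercise amplitude must exceed the pre-exercise
#' amplitude in every group, and must increase from the light through the
#' moderate to the heavy group, emulating the increasingly irregular and
#' complex thermal texture of a loaded back.
#'
#' Default amplitudes are 0.5 (all groups, pre-exercise) and 1.0 / 1.5 /
#' 2.0 for the L / M / H groups post-exercise, on a background of SD 4.0
#' intensity units with an 8-pixel correlation length.
#'
#' @param base_temperature Mean background level, arbitrary intensity units.
#' @param background_sd Standard deviation of the smooth background field.
#' @param smooth_field_scale Correlation length of the background, pixels.
#' @param amp_pre Pre-exercise irregularity amplitude (all groups).
#' @param amp_post Named vector of post-exercise amplitudes for groups
#'   `L`, `M`, `H`.
#' @param hot_region_gain Multiplier applied to the field inside the ROI
#'   masks on post-exercise images (exercise-induced warm regions).
#' @param colormap Name of the false-color lookup table; only `"thermal"`
#'   (the shipped blue-green-red map) is defined.
#' @return An object of class `texture_model`.
#' @export
texture_model <- function(base_temperature = 30, background_sd = 4,
                          smooth_field_scale = 8, amp_pre = 0.5,
                          amp_post = c(L = 1.0, M = 1.5, H = 2.0),
                          hot_region_gain = 1.25, colormap = "thermal") {
  amp_post <- amp_post[c("L", "M", "H")]
  if (any(is.na(amp_post)) || any(amp_post < 0) || amp_pre < 0) {
    stop_equitherm("amplitudes must be non-negative and named L, M, H",
                   "equitherm_error_config")
  }
  if (!all(amp_post > amp_pre)) {
    stop_equitherm("post-exercise amplitude must exceed pre-exercise in every group",
                   "equitherm_error_config")
  }
  if (!(amp_post["L"] < amp_post["M"] && amp_post["M"] < amp_post["H"])) {
    stop_equitherm("post-exercise amplitudes must increase L < M < H",
                   "equitherm_error_config")
  }
  structure(
    list(base_temperature = base_temperature, background_sd = background_sd,
         smooth_field_scale = smooth_field_scale, amp_pre = amp_pre,
         amp_post = amp_post, hot_region_gain = hot_region_gain,
         colormap = colormap),
    class = "texture_model"
  )
}

#' Irregularity amplitude of a texture model
#'
#' @param model A [texture_model()].
#' @param session `"pre"` or `"post"`.
#' @param group Rider group `"L"`, `"M"` or `"H"`.
#' @return Non-negative noise amplitude.
#' @export
irregularity_amplitude <- function(model, session, group) {
  if (identical(as.character(session), "pre")) {
    model$amp_pre
  } else {
    unname(model$amp_post[as.character(group)])
  }
}

#' Rectangular region-of-interest specification
#'
#' Coordinates are 0-based and half-open: the ROI covers pixel columns
#' `x0 .. x1-1` and rows `y0 .. y1-1`.
#'
#' @param label ROI label, e.g. `"ROI1_withers"`.
#' @param x0,y0,x1,y1 Corner coordinates (0-based, half-open).
#' @return A list of class `roi_spec`.
#' @export
roi_spec <- function(label, x0, y0, x1, y1) {
  if (x1 <= x0 || y1 <= y0) {
    stop_equitherm("ROI must have positive extent (x1 > x0, y1 > y0)",
                   "equitherm_error_dimension")
  }
  if (x0 < 0 || y0 < 0) {
    stop_equitherm("ROI coordinates must be non-negative",
                   "equitherm_error_dimension")
  }
  structure(list(label = label, x0 = as.integer(x0), y0 = as.integer(y0),
                 x1 = as.integer(x1), y1 = as.integer(y1)),
            class = "roi_spec")
}

#' Default ROI layout
#'
#' Two 24 x 24 ROIs placed side by side and vertically centered: the
#' withers area (ROI 1) on the left and the thoracic spine area (ROI 2) on
#' the right. Requires an image of at least 64 x 64 pixels.
#'
#' @param size Image size `c(height, width)` in pixels.
#' @return List of two [roi_spec()] objects.
#' @export
default_roi_specs <- function(size = c(64, 64)) {
  H <- size[1]; W <- size[2]
  if (H < 64 || W < 64) {
    stop_equitherm("default ROI layout needs an image of at least 64 x 64",
                   "equitherm_error_dimension")
  }
  y0 <- floor(H / 2) - 12
  list(
    roi_spec("ROI1_withers", floor(W / 2) - 28, y0, floor(W / 2) - 4, y0 + 24),
    roi_spec("ROI2_thoracic", floor(W / 2) + 4, y0, floor(W / 2) + 28, y0 + 24)
  )
}

#' Blue-green-red thermal lookup table
#'
#' A fixed 256-entry false-color map: blue decreases monotonically with
#' temperature and vanishes above mid-range, red is zero below mid-range
#' and increases monotonically, green peaks at mid-range. The hottest
#' pixel therefore always has a larger red than blue value and the coldest
#' the reverse, mirroring how thermal cameras render warm and cold areas.
#'
#' @return A 256 x 3 integer matrix of 8-bit R, G, B values.
#' @export
thermal_colormap <- function() {
  t <- (0:255) / 255
  clamp01 <- function(v) pmin(pmax(v, 0), 1)
  cbind(
    red = as.integer(round(255 * clamp01(2 * (t - 0.5)))),
    green = as.integer(round(255 * (1 - abs(2 * t - 1)))),
    blue = as.integer(round(255 * clamp01(2 * (0.5 - t))))
  )
}

#' Render a temperature field as a false-color 8-bit image
#'
#' The field is min-max normalized and mapped through the 256-entry
#' [thermal_colormap()]. A constant field has zero range; by documented
#' rule every pixel then maps to the middle colormap entry.
#'
#' @param field Numeric matrix of temperatures (finite).
#' @param colormap Colormap name; `"thermal"` only.
#' @return An `H x W x 3` integer array of 8-bit values.
#' @export
render_false_color <- function(field, colormap = "thermal") {
  if (!identical(colormap, "thermal")) {
    stop_equitherm("unknown colormap", "equitherm_error_parameter")
  }
  if (any(!is.finite(field))) {
    stop_equitherm("temperature field must be finite", "equitherm_error_parameter")
  }
  lut <- thermal_colormap()
  rng <- max(field) - min(field)
  idx <- if (rng == 0) {
    matrix(128L, nrow(field), ncol(field))
  } else {
    pmin(floor((field - min(field)) / rng * 255) + 1L, 256L)
  }
  out <- array(0L, c(nrow(field), ncol(field), 3L))
  for (ch in 1:3) out[, , ch] <- lut[idx, ch]
  out
}

# smooth standardized background: white noise convolved with a separable
# Gaussian kernel (circular edges), rescaled to zero mean / unit SD
smooth_noise_field <- function(H, W, scale) {
  z <- matrix(stats::rnorm(H * W), H, W)
  # kernel support capped so filtering stays defined on small fields
  half <- min(max(1L, ceiling(3 * scale)), floor((min(H, W) - 1) / 2))
  kern <- exp(-((-half:half)^2) / (2 * scale^2))
  kern <- kern / sum(kern)
  sm <- stats::filter(z, kern, circular = TRUE)
  sm <- t(stats::filter(t(sm), kern, circular = TRUE))
  sm <- matrix(as.numeric(sm), H, W)
  (sm - mean(sm)) / stats::sd(sm)
}

roi_mask <- function(size, roi) {
  m <- matrix(FALSE, size[1], size[2])
  m[(roi$y0 + 1):roi$y1, (roi$x0 + 1):roi$x1] <- TRUE
  m
}

#' Generate one synthetic false-color thermogram
#'
#' Builds the temperature field for one study-design row -- smooth
#' background plus session/group-dependent irregularity noise, with the
#' hot-region gain applied inside the ROI masks for post-exercise rows --
#' and renders it through the false-color map. Deterministic given
#' `seed`.
#'
#' @param design_row One row of [make_design()] (needs `session`, `group`).
#' @param model A [texture_model()].
#' @param size Image size `c(height, width)`, at least large enough to
#'   contain both ROIs.
#' @param roi_specs List of two [roi_spec()] rectangles.
#' @param seed Optional integer seed.
#' @return An object of class `thermogram`: list with `rgb` (8-bit
#'   `H x W x 3` array), `temperature_field`, `roi_specs`, `metadata`.
#' @export
generate_thermogram <- function(design_row, model = texture_model(),
                                size = c(64, 64),
                                roi_specs = default_roi_specs(size),
                                seed = NULL) {
  H <- size[1]; W <- size[2]
  for (roi in roi_specs) {
    if (roi$x1 > W || roi$y1 > H) {
      stop_equitherm(sprintf("ROI %s lies outside the %d x %d image",
                             roi$label, H, W),
                     "equitherm_error_dimension")
    }
  }
  if (!is.null(seed)) set.seed(seed)
  bg <- model$base_temperature +
    model$background_sd * smooth_noise_field(H, W, model$smooth_field_scale)
  amp <- irregularity_amplitude(model, design_row$session, design_row$group)
  field <- bg + amp * matrix(stats::rnorm(H * W), H, W)
  if (identical(as.character(design_row$session), "post")) {
    for (roi in roi_specs) {
      msk <- roi_mask(size, roi)
      field[msk] <- field[msk] * model$hot_region_gain
    }
  }
  structure(
    list(rgb = render_false_color(field, model$colormap),
         temperature_field = field, roi_specs = roi_specs,
         metadata = design_row),
    class = "thermogram"
  )
}

#' Write a thermogram's false-color image as PNG
#'
#' @param tg A [generate_thermogram()] object.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_thermogram <- function(tg, path) {
  png::writePNG(tg$rgb / 255, path)
  invisible(path)
}
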