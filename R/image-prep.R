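#' Load an RGB image as an 8-bit array
#'
#' Reads a PNG or TIFF file and returns an `H x W x 3` integer array of
#' 8-bit values. 16-bit inputs are rescaled to 8 bits by integer division
#' of the 16-bit code by 257 (so 65535 maps to 255). Grayscale files and
#' files with an alpha channel are rejected: the extraction pipeline is
#' defined on 3-channel false-color images only.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return `H x W x 3` integer array with values in `[0, 255]`.
#' @export
load_image <- function(path) {
  if (!file.exists(path)) {
    stop_equitherm(sprintf("file not found: %s", path), "equitherm_error_io")
  }
  ext <- tolower(tools::file_ext(path))
  img <- tryCatch(
    switch(ext,
      png = png::readPNG(path),
      tif = ,
      tiff = tiff::readTIFF(path),
      stop_equitherm(sprintf("unsupported image format: .%s (PNG/TIFF only)", ext),
                     "equitherm_error_io")
    ),
    error = function(e) {
      if (inherits(e, "equitherm_error")) stop(e)
      stop_equitherm(sprintf("cannot decode %s: %s", path, conditionMessage(e)),
                     "equitherm_error_io")
    }
  )
  if (length(dim(img)) != 3 || dim(img)[3] != 3) {
    stop_equitherm(
      "image must have exactly 3 channels (grayscale and alpha are rejected)",
      "equitherm_error_io"
    )
  }
  # readPNG/readTIFF return doubles in [0,1]: k/255 for 8-bit, k/65535 for
  # 16-bit. Recover the integer codes; if the 8-bit reconstruction is not
  # integral the file was 16-bit and the code is divided down by 257.
  v255 <- img * 255
  if (max(abs(v255 - round(v255))) < 1e-6) {
    out <- round(v255)
  } else {
    out <- floor(img * 65535 + 0.5) %/% 257
  }
  storage.mode(out) <- "integer"
  out
}

#' Extract a rectangular ROI from an RGB array
#'
#' ROI coordinates are 0-based and half-open (`[x0, x1) x [y0, y1)`, x
#' along columns, y along rows). Out-of-bounds ROIs raise a dimension
#' error.
#'
#' @param rgb `H x W x 3` array.
#' @param roi A [roi_spec()].
#' @return The `(y1-y0) x (x1-x0) x 3` sub-array.
#' @export
extract_roi <- function(rgb, roi) {
  d <- dim(rgb)
  if (roi$x1 > d[2] || roi$y1 > d[1]) {
    stop_equitherm(sprintf("ROI %s exceeds image bounds", roi$label),
                   "equitherm_error_dimension")
  }
  rgb[(roi$y0 + 1):roi$y1, (roi$x0 + 1):roi$x1, , drop = FALSE]
}

#' Decompose an RGB patch into grayscale and color component matrices
#'
#' Red, green and blue are the raw channel slices; grayscale is the
#' ITU-R BT.601 luma `0.299 R + 0.587 G + 0.114 B`, rounded half away from
#' zero. Stacking the three color components reproduces the input exactly,
#' and the gray value always lies between the per-pixel channel minimum
#' and maximum.
#'
#' @param rgb `H x W x 3` array of 8-bit values.
#' @return An object of class `component_set`: list of matrices `gray`,
#'   `red`, `green`, `blue`.
#' @export
decompose_components <- function(rgb) {
  d <- dim(rgb)
  if (length(d) != 3 || d[3] != 3) {
    stop_equitherm("input must be an H x W x 3 array", "equitherm_error_dimension")
  }
  red <- matrix(as.numeric(rgb[, , 1]), d[1], d[2])
  green <- matrix(as.numeric(rgb[, , 2]), d[1], d[2])
  blue <- matrix(as.numeric(rgb[, , 3]), d[1], d[2])
  gray <- floor(0.299 * red + 0.587 * green + 0.114 * blue + 0.5)
  structure(list(gray = gray, red = red, green = green, blue = blue),
            class = "component_set")
}

#' Read and write ROI specifications as JSON
#'
#' The JSON layout is `{"image": <name or null>, "rois": [{"label", "x0",
#' "y0", "x1", "y1"}, ...]}` with 0-based half-open coordinates.
#'
#' @param path JSON file path.
#' @param specs List of [roi_spec()] objects.
#' @param image Optional image name recorded in the file.
#' @return `read_roi_specs()` returns a list of [roi_spec()] objects;
#'   `write_roi_specs()` returns `path` invisibly.
#' @export
write_roi_specs <- function(specs, path, image = NULL) {
  payload <- list(
    image = image,
    rois = lapply(specs, function(r) r[c("label", "x0", "y0", "x1", "y1")])
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_roi_specs
#' @export
read_roi_specs <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(payload$rois, function(r) {
    roi_spec(r$label, r$x0, r$y0, r$x1, r$y1)
  })
}
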