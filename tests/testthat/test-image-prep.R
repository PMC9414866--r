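test_that("PNG images round-trip through write and load", {
  rgb <- array(sample(0:255, 4 * 5 * 3, replace = TRUE), c(4, 5, 3))
  path <- withr::local_tempfile(fileext = ".png")
  png::writePNG(rgb / 255, path)
  expect_equal(load_image(path), rgb, ignore_attr = TRUE)
})

test_that("undecodable and unsupported files raise IO errors", {
  txt <- withr::local_tempfile(fileext = ".png")
  writeLines("not an image", txt)
  expect_error(load_image(txt), class = "equitherm_error_io")
  expect_error(load_image(file.path(tempdir(), "nope.png")),
               class = "equitherm_error_io")
  bmp <- withr::local_tempfile(fileext = ".bmp")
  writeLines("x", bmp)
  expect_error(load_image(bmp), class = "equitherm_error_io")
})

test_that("grayscale files are rejected", {
  gray <- matrix(runif(12), 3, 4)
  path <- withr::local_tempfile(fileext = ".png")
  png::writePNG(gray, path)
  expect_error(load_image(path), class = "equitherm_error_io")
})

test_that("16-bit TIFFs are rescaled by integer division by 257", {
  set.seed(5)
  codes <- array(sample(0:65535, 3 * 3 * 3, replace = TRUE), c(3, 3, 3))
  path <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(codes / 65535, path, bits.per.sample = 16L)
  expect_equal(load_image(path), codes %/% 257, ignore_attr = TRUE)
})

test_that("ROI extraction honors 0-based half-open coordinates", {
  rgb <- array(sample(0:255, 6 * 8 * 3, replace = TRUE), c(6, 8, 3))
  whole <- extract_roi(rgb, roi_spec("all", 0, 0, 8, 6))
  expect_equal(whole, rgb)
  px <- extract_roi(rgb, roi_spec("one", 0, 0, 1, 1))
  expect_equal(dim(px), c(1, 1, 3))
  expect_equal(as.vector(px), as.vector(rgb[1, 1, ]))
  # nested extraction composes with direct extraction
  outer <- extract_roi(rgb, roi_spec("outer", 1, 1, 7, 5))
  inner <- extract_roi(outer, roi_spec("inner", 2, 1, 5, 4))
  direct <- extract_roi(rgb, roi_spec("direct", 3, 2, 6, 5))
  expect_equal(inner, direct)
  expect_error(extract_roi(rgb, roi_spec("oob", 0, 0, 9, 6)),
               class = "equitherm_error_dimension")
  expect_error(roi_spec("bad", 3, 0, 3, 5), class = "equitherm_error_dimension")
})

test_that("component decomposition follows BT.601 luma with half-up rounding", {
  px <- function(r, g, b) array(c(r, g, b), c(1, 1, 3))
  cs <- decompose_components(px(255, 0, 0))
  expect_equal(cs$red[1, 1], 255)
  expect_equal(cs$green[1, 1], 0)
  expect_equal(cs$blue[1, 1], 0)
  expect_equal(cs$gray[1, 1], 76)  # 0.299 * 255 = 76.245
  expect_equal(decompose_components(px(0, 0, 255))$gray[1, 1], 29)  # 29.07
  ach <- decompose_components(px(77, 77, 77))
  expect_equal(unique(c(ach$gray, ach$red, ach$green, ach$blue)), 77)
})

test_that("decomposition is lossless and gray lies within the channel range", {
  set.seed(9)
  rgb <- array(sample(0:255, 5 * 5 * 3, replace = TRUE), c(5, 5, 3))
  cs <- decompose_components(rgb)
  rebuilt <- array(c(cs$red, cs$green, cs$blue), dim(rgb))
  expect_equal(rebuilt, rgb, ignore_attr = TRUE)
  lo <- pmin(cs$red, cs$green, cs$blue)
  hi <- pmax(cs$red, cs$green, cs$blue)
  expect_true(all(cs$gray >= lo & cs$gray <= hi))
  expect_error(decompose_components(array(0, c(2, 2, 4))),
               class = "equitherm_error_dimension")
})

test_that("ROI specifications round-trip through JSON", {
  specs <- default_roi_specs(c(64, 64))
  path <- withr::local_tempfile(fileext = ".json")
  write_roi_specs(specs, path, image = "demo.png")
  back <- read_roi_specs(path)
  expect_equal(length(back), 2)
  expect_equal(back[[1]]$label, specs[[1]]$label)
  expect_equal(unlist(back[[2]][c("x0", "y0", "x1", "y1")]),
               unlist(specs[[2]][c("x0", "y0", "x1", "y1")]))
})
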