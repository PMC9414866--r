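design_row <- function(session = "pre", group = "L") {
  d <- make_design()
  d[d$session == session & d$group == group, ][1, ]
}

test_that("thermogram generation is bit-identical under a fixed seed", {
  row <- design_row("post", "H")
  a <- generate_thermogram(row, seed = 7)
  b <- generate_thermogram(row, seed = 7)
  expect_identical(a$rgb, b$rgb)
  expect_identical(a$temperature_field, b$temperature_field)
  c <- generate_thermogram(row, seed = 8)
  expect_false(identical(a$rgb, c$rgb))
})

test_that("zero irregularity amplitude reproduces the smooth background exactly", {
  model <- texture_model(amp_pre = 0, amp_post = c(L = 1, M = 1.5, H = 2))
  row <- design_row("pre", "L")
  tg <- generate_thermogram(row, model, seed = 3)
  # replay the generator's own background construction under the same seed
  set.seed(3)
  bg <- model$base_temperature + model$background_sd *
    equitherm:::smooth_noise_field(64, 64, model$smooth_field_scale)
  expect_identical(tg$temperature_field, bg)
})

test_that("the hot-region gain is applied inside ROI masks post-exercise only", {
  model <- texture_model(amp_pre = 0, hot_region_gain = 2)
  pre <- generate_thermogram(design_row("pre", "L"), model, seed = 5)
  post_row <- design_row("post", "L")
  post_row$session <- factor("post", levels = c("pre", "post"))
  post <- generate_thermogram(post_row,
                              texture_model(amp_pre = 0, amp_post = c(L = 1e-9, M = 2e-9, H = 3e-9),
                                            hot_region_gain = 2),
                              seed = 5)
  roi <- pre$roi_specs[[1]]
  inside_pre <- pre$temperature_field[(roi$y0 + 1):roi$y1, (roi$x0 + 1):roi$x1]
  inside_post <- post$temperature_field[(roi$y0 + 1):roi$y1, (roi$x0 + 1):roi$x1]
  expect_equal(inside_post, 2 * inside_pre, tolerance = 1e-6)
  # outside the masks the fields agree
  msk <- equitherm:::roi_mask(c(64, 64), pre$roi_specs[[1]]) |
    equitherm:::roi_mask(c(64, 64), pre$roi_specs[[2]])
  expect_equal(pre$temperature_field[!msk], post$temperature_field[!msk],
               tolerance = 1e-6)
})

test_that("texture model invariants are enforced", {
  expect_error(texture_model(amp_pre = 1, amp_post = c(L = 0.5, M = 1.5, H = 2)),
               class = "equitherm_error_config")
  expect_error(texture_model(amp_post = c(L = 2, M = 1.5, H = 1.9)),
               class = "equitherm_error_config")
  m <- texture_model()
  expect_equal(irregularity_amplitude(m, "pre", "H"), 0.5)
  expect_equal(irregularity_amplitude(m, "post", "M"), 1.5)
})

test_that("false-color rendering maps heat to red monotonically", {
  set.seed(2)
  f <- matrix(rnorm(400), 20, 20)
  rgb <- render_false_color(f)
  hot <- which(f == max(f), arr.ind = TRUE)[1, ]
  cold <- which(f == min(f), arr.ind = TRUE)[1, ]
  expect_equal(rgb[hot[1], hot[2], 1], max(rgb[, , 1]))
  expect_gt(rgb[hot[1], hot[2], 1], rgb[hot[1], hot[2], 3])
  expect_gt(rgb[cold[1], cold[2], 3], rgb[cold[1], cold[2], 1])
  # constant field: uniform mid-colormap image by rule
  cst <- render_false_color(matrix(1, 4, 4))
  expect_equal(length(unique(as.vector(cst[, , 1]))), 1)
  expect_equal(cst[1, 1, ], thermal_colormap()[128, ], ignore_attr = TRUE)
  # linear gradient: red channel non-decreasing along the gradient axis
  grad <- render_false_color(matrix(rep(1:32, each = 4), 4, 32))
  reds <- grad[1, , 1]
  expect_true(all(diff(reds) >= 0))
  blues <- grad[1, , 3]
  expect_true(all(diff(blues) <= 0))
  expect_error(render_false_color(matrix(c(1, Inf), 1, 2)),
               class = "equitherm_error_parameter")
})

test_that("ROIs outside the image raise a dimension error", {
  row <- design_row()
  expect_error(
    generate_thermogram(row, size = c(64, 64),
                        roi_specs = list(roi_spec("big", 50, 50, 80, 80)),
                        seed = 1),
    class = "equitherm_error_dimension"
  )
})

test_that("dispersion entropy of the red ROI increases with noise amplitude", {
  amps <- c(0.3, 1, 2.5)
  mean_disp <- sapply(amps, function(a) {
    vals <- sapply(1:10, function(s) {
      model <- texture_model(amp_pre = a, amp_post = c(L = a + 1, M = a + 2, H = a + 3))
      tg <- generate_thermogram(design_row("pre", "L"), model, seed = 100 + s)
      comp <- decompose_components(extract_roi(tg$rgb, tg$roi_specs[[1]]))
      dispen2d(comp$red)$value
    })
    mean(vals)
  })
  expect_true(all(diff(mean_disp) > 0))
})
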