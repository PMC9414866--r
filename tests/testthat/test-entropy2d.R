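test_that("constant patches give zero entropy under the degenerate rules", {
  cst <- matrix(7, 8, 8)
  prof <- suppressWarnings(entropy_profile(cst))
  expect_equal(unname(prof), rep(0, 5))
  # sample entropy: sigma = 0 makes r = 0 and 0 <= 0 counts as a match
  s <- sampen2d(cst)
  expect_equal(s$value, 0)
  expect_equal(s$phi_m, 1)
  expect_equal(s$phi_m1, 1)
  # dispersion entropy warns (documented degenerate rule), does not error
  expect_warning(dispen2d(cst), class = "equitherm_warning_degenerate")
})

test_that("checkerboard sample entropy is zero with match density 32/72", {
  cb <- outer(1:4, 1:4, function(i, j) (i + j) %% 2)
  s <- sampen2d(cb, entropy_params(m = 1, r = 0.5, r_is_fraction = FALSE))
  expect_equal(s$phi_m, 32 / 72)
  expect_equal(s$phi_m1, 32 / 72)
  expect_equal(s$value, 0)
})

test_that("monotone gradients and constants give zero permutation entropy", {
  expect_equal(permen2d(matrix(1:9, 3, 3))$value, 0)
  expect_equal(permen2d(matrix(5, 6, 6))$value, 0)
  # a single ordinal pattern regardless of normalization
  expect_equal(permen2d(matrix(1:64, 8, 8),
                        entropy_params(normalized = FALSE))$value, 0)
})

test_that("two equally occupied distance bins give one bit of DistEn", {
  # 3 zeros + 6 ones: 18 zero distances and 18 unit distances among the
  # single-pixel windows, so the histogram has two equal bins
  p <- matrix(c(0, 0, 0, 1, 1, 1, 1, 1, 1), 3, 3)
  v <- disten2d(p, entropy_params(m = 1, M = 16, normalized = FALSE))
  expect_equal(v$value, 1)
  expect_equal(sum(v$probs > 0), 2)
  expect_equal(unname(v$probs[v$probs > 0]), c(0.5, 0.5))
})

test_that("a maximal-entropy dispersion census gives normalized value 1", {
  # de Bruijn row 0,0,1,1,0 maps to classes 1,1,2,2,1: the four 1x2
  # dispersion patterns occur exactly once each
  p <- matrix(c(0, 0, 100, 100, 0), 1, 5)
  v <- dispen2d(p, entropy_params(dn = 1, dm = 2, c = 2))
  expect_equal(v$value, 1)
  expect_equal(length(v$probs), 4)
})

test_that("window-count prefactor divides the raw Shannon sum by the window count", {
  p <- noise_patch(10, 3)
  for (f in list(permen2d, dispen2d)) {
    lit <- f(p, entropy_params(window_prefactor = TRUE))
    expect_equal(lit$value, lit$raw / lit$n_windows)
  }
})

test_that("implementations match the brute-force oracles on seeded patches", {
  pars_abs <- entropy_params(r = 85, r_is_fraction = FALSE)
  for (seed in 1:10) {
    p <- level_patch(9, seed)
    expect_equal(sampen2d(p, pars_abs)$value, sampen2d_ref(p, pars_abs),
                 tolerance = 1e-12)
    expect_equal(fuzzen2d(p, pars_abs)$value, fuzzen2d_ref(p, pars_abs),
                 tolerance = 1e-12)
    q <- noise_patch(12, seed + 100)
    pars <- entropy_params()
    expect_equal(permen2d(q, pars)$value, permen2d_ref(q, pars),
                 tolerance = 1e-12)
    expect_equal(dispen2d(q, pars)$value, dispen2d_ref(q, pars),
                 tolerance = 1e-12)
    expect_equal(disten2d(q, pars)$value, disten2d_ref(q, pars),
                 tolerance = 1e-12)
  }
})

test_that("entropy values respect their documented ranges", {
  for (seed in 1:5) {
    p <- smooth_patch(12, seed, noise_sd = 0.3)
    prof <- suppressWarnings(entropy_profile(p))
    expect_true(is.na(prof["SampEn"]) || prof["SampEn"] >= 0)
    expect_gte(prof[["FuzzEn"]], 0)
    expect_true(prof[["PermEn"]] >= 0 && prof[["PermEn"]] <= 1)
    expect_true(prof[["DispEn"]] >= 0 && prof[["DispEn"]] <= 1)
    expect_true(prof[["DistEn"]] >= 0 && prof[["DistEn"]] <= 1)
    # fuzzy match density cannot grow when windows are extended
    fz <- fuzzen2d(p)
    expect_lte(fz$phi_m1, fz$phi_m + 1e-12)
  }
})

test_that("documented invariances hold exactly", {
  pars <- entropy_params()
  for (seed in 1:5) {
    p <- smooth_patch(10, seed, noise_sd = 0.5)
    aff <- 2 * p + 32  # dyadic affine map, exact in floating point
    # fraction-of-SD tolerance makes SampEn/FuzzEn affine invariant;
    # when the measure is undefined it is undefined for both
    s_p <- tryCatch(sampen2d(p, pars)$value, error = function(e) e)
    s_a <- tryCatch(sampen2d(aff, pars)$value, error = function(e) e)
    if (inherits(s_p, "condition") || inherits(s_a, "condition")) {
      expect_s3_class(s_p, "equitherm_error_undefined_entropy")
      expect_s3_class(s_a, "equitherm_error_undefined_entropy")
    } else {
      expect_equal(s_p, s_a, tolerance = 1e-12)
    }
    # fuzzy membership exp(-d^n / r): invariant when the absolute
    # tolerance is rescaled by a^n (a = 2, n = 2)
    expect_equal(
      fuzzen2d(p, entropy_params(r = 20, r_is_fraction = FALSE))$value,
      fuzzen2d(aff, entropy_params(r = 80, r_is_fraction = FALSE))$value,
      tolerance = 1e-12
    )
    expect_equal(dispen2d(p, pars)$value, dispen2d(aff, pars)$value,
                 tolerance = 1e-12)
    expect_equal(disten2d(p, pars)$value, disten2d(aff, pars)$value,
                 tolerance = 1e-12)
    # rotation invariance for the full-window-set census measures
    rot <- t(p)[ncol(p):1, ]
    expect_equal(dispen2d(p, pars)$value, dispen2d(rot, pars)$value,
                 tolerance = 1e-12)
    expect_equal(disten2d(p, pars)$value, disten2d(rot, pars)$value,
                 tolerance = 1e-12)
    # ordinal patterns: strictly increasing transforms, and rotations on
    # tie-free patches
    set.seed(seed)
    tf <- matrix(sample(1:100), 10, 10)
    rot_tf <- t(tf)[ncol(tf):1, ]
    expect_equal(permen2d(tf, pars)$value, permen2d(rot_tf, pars)$value,
                 tolerance = 1e-12)
    expect_identical(permen2d(tf, pars)$value, permen2d(tf^3, pars)$value)
  }
})

test_that("undefined sample entropy raises a classed error", {
  # dense 8-bit noise: window matches at r = 0.2 sigma are essentially
  # impossible, the conditional probability is 0/0
  expect_error(sampen2d(noise_patch(12, 1)),
               class = "equitherm_error_undefined_entropy")
  # and entropy_profile degrades it to NA with a warning
  expect_warning(prof <- entropy_profile(noise_patch(12, 1)),
                 class = "equitherm_warning_undefined")
  expect_true(is.na(prof[["SampEn"]]))
})

test_that("dimension and parameter errors are raised", {
  expect_error(sampen2d(matrix(0, 3, 3)), class = "equitherm_error_dimension")
  expect_error(disten2d(matrix(0, 1, 2), entropy_params(m = 2)),
               class = "equitherm_error_dimension")
  expect_error(entropy_params(c = 1), class = "equitherm_error_parameter")
  expect_error(entropy_params(m = 0), class = "equitherm_error_parameter")
  expect_error(fuzzen2d(noise_patch(8, 2),
                        entropy_params(r = 0, r_is_fraction = FALSE)),
               class = "equitherm_error_parameter")
})
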