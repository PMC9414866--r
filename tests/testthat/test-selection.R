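test_that("the normality gate separates gaussian from heavy-tailed series", {
  gaussian_hits <- sum(sapply(1:100, function(s) {
    set.seed(s)
    normality_gate(rnorm(24)) == "gaussian"
  }))
  expect_gte(gaussian_hits, 90)
  mixture_hits <- sum(sapply(1:100, function(s) {
    set.seed(s)
    x <- ifelse(runif(24) < 0.1, rnorm(24, 0, 10), rnorm(24))
    normality_gate(x) == "non_gaussian"
  }))
  expect_gt(mixture_hits, 50)
  expect_warning(g <- normality_gate(rep(3, 10)),
                 class = "equitherm_warning_degenerate")
  expect_equal(g, "non_gaussian")
  expect_error(normality_gate(c(1, 2)), class = "equitherm_error_parameter")
})

test_that("the paired pre/post test reproduces the closed-form t example", {
  res <- paired_prepost_test(c(1, 2, 3, 4), c(3, 3, 5, 6))
  expect_equal(res$test, "paired_t")
  expect_equal(res$statistic, 7, tolerance = 1e-12)
  expect_equal(res$p, 2 * pt(-7, 3), tolerance = 1e-12)
  expect_warning(null <- paired_prepost_test(1:5, 1:5),
                 class = "equitherm_warning_degenerate")
  expect_equal(null$p, 1)
})

test_that("the paired test detects a 3-SD planted shift almost surely", {
  hits <- sum(sapply(1:100, function(s) {
    set.seed(s)
    pre <- rnorm(24)
    post <- pre + 3 + rnorm(24, 0, 0.5)
    suppressWarnings(paired_prepost_test(pre, post))$p < 0.05
  }))
  expect_gte(hits, 99)
})

test_that("the three-group comparison matches the one-way ANOVA oracle", {
  # identical groups: no effect
  base <- c(1.2, 2.1, 2.9, 4.4)
  res0 <- group_comparison(base, base, base)
  expect_gt(res0$omnibus_p, 0.05)
  # frozen toy groups: SSB = 62 (df 2), SSW = 6 (df 6) gives F = 31
  res <- group_comparison(c(1, 2, 3), c(2, 3, 4), c(7, 8, 9))
  expect_equal(res$test, "anova_tukey")
  expect_equal(res$omnibus_p, stats::pf(31, 2, 6, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_lt(res$pairwise[["L-H"]], 0.05)
})

test_that("a planted group gradient is detected in the L-H contrast", {
  hits <- sum(sapply(1:100, function(s) {
    set.seed(s)
    res <- suppressWarnings(
      group_comparison(rnorm(24), rnorm(24, 1.5), rnorm(24, 3))
    )
    res$pairwise[["L-H"]] < 0.05
  }))
  expect_gte(hits, 95)
})

test_that("Dunn's test matches an independent manual computation", {
  L <- c(1, 3, 5, 7); M <- c(2, 4, 6, 8); H <- c(10, 12, 14, 16)
  y <- c(L, M, H)
  g <- factor(rep(c("L", "M", "H"), each = 4), levels = c("L", "M", "H"))
  got <- equitherm:::dunn_test(y, g)
  # manual route: joint ranks, no ties
  rk <- rank(y)
  N <- 12
  mr <- tapply(rk, g, mean)
  se <- sqrt((N * (N + 1) / 12) * (1 / 4 + 1 / 4))
  z_LH <- (mr[["L"]] - mr[["H"]]) / se
  expect_equal(got[["L-H"]], min(1, 2 * pnorm(-abs(z_LH)) * 3),
               tolerance = 1e-12)
  # the nonparametric branch engages for clearly non-gaussian series
  set.seed(1)
  a <- exp(rnorm(20, 0, 2)); b <- exp(rnorm(20, 0, 2)); c <- exp(rnorm(20, 2, 2))
  res <- suppressWarnings(group_comparison(a, b, c))
  expect_equal(res$test, "kruskal_dunn")
})

test_that("slope comparison handles the exact parallel and scaled cases", {
  x <- c(1, 2, 3, 4, 5, 6)
  y1 <- 2 * x + rnorm(6, 0, 0.01)
  par <- compare_slopes(x, y1, y1 + 5)
  expect_gt(par$p_slopes, 0.05)
  expect_equal(par$pooled_slope, par$slope_1, tolerance = 1e-6)
  expect_lt(par$p_intercepts, 0.05)
  expect_true(is.na(par$pooled_intercept))
  # noiseless y2 = 2 * y1: exact separation, slopes differ
  y <- 1.5 * x
  sep <- compare_slopes(x, y, 2 * y)
  expect_lt(sep$p_slopes, 0.05)
  expect_error(compare_slopes(rep(1, 6), y1, y1),
               class = "equitherm_error_parameter")
})

test_that("the slope-equality F statistic matches the residual-sum oracle", {
  for (seed in 1:10) {
    set.seed(seed)
    x <- runif(30, 0, 10)
    y1 <- 1 + 0.5 * x + rnorm(30, 0, 0.8)
    y2 <- 2 + 0.7 * x + rnorm(30, 0, 0.8)
    got <- compare_slopes(x, y1, y2)
    # textbook ANCOVA from explicit residual sums of squares
    rss <- function(x, y) sum(lm(y ~ x)$residuals^2)
    rss_sep <- rss(x, y1) + rss(x, y2)
    sxx <- sum((x - mean(x))^2)
    b_common <- (sum((x - mean(x)) * (y1 - mean(y1))) +
                   sum((x - mean(x)) * (y2 - mean(y2)))) / (2 * sxx)
    rss_com <- sum((y1 - mean(y1) - b_common * (x - mean(x)))^2) +
      sum((y2 - mean(y2) - b_common * (x - mean(x)))^2)
    F_oracle <- (rss_com - rss_sep) / (rss_sep / (2 * 30 - 4))
    expect_equal(got$F_slopes, F_oracle, tolerance = 1e-10)
    slope1_oracle <- sum((x - mean(x)) * (y1 - mean(y1))) / sxx
    expect_equal(got$slope_1, slope1_oracle, tolerance = 1e-10)
  }
})

test_that("criterion 1 recovers effects planted in the red channel only", {
  reps <- 5
  red_pass <- 0; other_pass <- 0
  for (s in 1:reps) {
    m <- synth_measures(seed = s, effect_components = "red", post_shift = 2)
    c1 <- criterion1_select(m)
    red_pass <- red_pass + sum(c1$crit1_pass[c1$component == "red"])
    other_pass <- other_pass + sum(c1$crit1_pass[c1$component != "red"])
  }
  expect_gte(red_pass / (reps * 10), 0.9)
  expect_lte(other_pass / (reps * 30), 0.05)
})

test_that("criterion 1 evaluates exactly 40 combinations and rejects null data", {
  m <- synth_measures(seed = 3, effect_components = character(0))
  c1 <- criterion1_select(m)
  expect_equal(nrow(c1), 40)
  # pre identical to post: every paired difference is zero, p = 1
  m2 <- m
  key <- paste(m2$horse, m2$rider, m2$roi, m2$component, m2$measure)
  pre_rows <- m2$session == "pre"
  post_rows <- m2$session == "post"
  m2$value[post_rows] <- m2$value[pre_rows][match(key[post_rows], key[pre_rows])]
  c1b <- suppressWarnings(criterion1_select(m2))
  expect_equal(sum(c1b$crit1_pass), 0)
})

test_that("criterion 3 drops weak GLCM features and unrelated measures", {
  # controlled series on a shared regressor, raw slopes (no standardization)
  set.seed(42)
  d <- make_design()
  post <- d[d$session == "post", ]
  x <- post$ratio
  mk <- function(measure, type, values) {
    tibble::tibble(
      horse = post$horse, rider = post$rider, group = as.character(post$group),
      session = "post", ratio = x, roi = "ROI1_withers", component = "red",
      measure = measure, measure_type = type, value = values
    )
  }
  pre_stub <- function(tbl) { tbl$session <- "pre"; tbl$value <- 0; tbl }
  n <- nrow(post)
  dispen <- x + rnorm(n, 0, 0.05)
  measures <- dplyr::bind_rows(
    mk("DispEn", "entropy", dispen),
    mk("DistEn", "entropy", 5 * x + rnorm(n, 0, 0.05)),
    mk("SumEntrp", "glcm", dispen + 0.3 + rnorm(n, 0, 0.01)),
    mk("Entropy", "glcm", dispen - 0.2 + rnorm(n, 0, 0.01)),
    mk("DifEntrp", "glcm", 0.2 * x + rnorm(n, 0, 0.05))
  )
  measures <- dplyr::bind_rows(measures, pre_stub(measures))
  ent <- tibble::tibble(measure = c("DispEn", "DistEn"), component = "red",
                        roi = "ROI1_withers")
  glc <- tibble::tibble(measure = c("SumEntrp", "Entropy", "DifEntrp"),
                        component = "red", roi = "ROI1_withers")
  res <- criterion3_select(measures, ent, glc, standardize = FALSE)
  # DifEntrp's slope is below half of both entropy slopes: dropped
  expect_true(res$glcm$dropped[res$glcm$measure == "DifEntrp"])
  expect_false(any(res$glcm$dropped[res$glcm$measure != "DifEntrp"]))
  # DispEn tracks both retained features; DistEn (slope 5) tracks none
  expect_true(res$ledger$crit3_pass[res$ledger$measure == "DispEn"])
  expect_false(res$ledger$crit3_pass[res$ledger$measure == "DistEn"])
  expect_error(criterion3_select(measures, ent, glc[1, ]),
               class = "equitherm_error_parameter")
})

test_that("the full selection procedure recovers a red-channel gradient", {
  m <- synth_measures(seed = 11, effect_components = "red",
                      post_shift = 1, group_step = 1)
  sel <- suppressWarnings(select_measures(m))
  l <- sel$ledger
  expect_equal(nrow(l), 40)
  expect_gt(sum(l$crit1_pass[l$component == "red"]), 5)
  expect_gt(sum(l$crit3_pass), 0)
  expect_true(all(l$component[l$crit3_pass] == "red"))
})
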