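#' Shapiro-Wilk normality gate
#'
#' Classifies a data series as `"gaussian"` (Shapiro-Wilk p >= 0.05) or
#' `"non_gaussian"`. Every parametric-vs-nonparametric branch of the
#' selection procedure goes through this gate. A constant series has zero
#' variance, for which the test is undefined; by documented rule it is
#' classified `"non_gaussian"` (with a warning), which routes it to the
#' rank-based branch where it is handled gracefully.
#'
#' @param x Numeric series, at least 3 finite values.
#' @param alpha Gate level (default 0.05).
#' @return `"gaussian"` or `"non_gaussian"`.
#' @export
normality_gate <- function(x, alpha = 0.05) {
  x <- x[is.finite(x)]
  if (length(x) < 3) {
    stop_equitherm("normality gate needs at least 3 finite values",
                   "equitherm_error_parameter")
  }
  if (stats::sd(x) == 0) {
    warn_equitherm("constant series: classified non_gaussian by rule",
                   "equitherm_warning_degenerate")
    return("non_gaussian")
  }
  if (stats::shapiro.test(x)$p.value >= alpha) "gaussian" else "non_gaussian"
}

#' Paired pre/post comparison
#'
#' Paired t-test when both series pass the normality gate, Wilcoxon
#' matched-pairs signed-rank test (normal approximation with continuity
#' correction) otherwise; two-sided. If every paired difference is zero
#' the Wilcoxon statistic is undefined and p = 1 is reported with a
#' warning (no evidence of any effect).
#'
#' @param pre,post Equal-length paired series (same horse-rider pairs in
#'   the same order).
#' @param alpha Level of the normality gate.
#' @return List with `p`, `test` (`"paired_t"` or `"wilcoxon"`), and
#'   `statistic`.
#' @export
paired_prepost_test <- function(pre, post, alpha = 0.05) {
  if (length(pre) != length(post)) {
    stop_equitherm("pre and post must have equal length",
                   "equitherm_error_parameter")
  }
  if (all(post - pre == 0)) {
    warn_equitherm("all paired differences are zero; p = 1 by rule",
                   "equitherm_warning_degenerate")
    return(list(p = 1, test = "degenerate", statistic = NA_real_))
  }
  gate <- suppressWarnings(
    c(normality_gate(pre, alpha), normality_gate(post, alpha))
  )
  if (all(gate == "gaussian")) {
    ht <- stats::t.test(post, pre, paired = TRUE)
    list(p = ht$p.value, test = "paired_t", statistic = unname(ht$statistic))
  } else {
    ht <- suppressWarnings(
      stats::wilcox.test(post, pre, paired = TRUE, exact = FALSE)
    )
    list(p = ht$p.value, test = "wilcoxon", statistic = unname(ht$statistic))
  }
}

# Dunn's post-hoc z tests on the joint ranks after a Kruskal-Wallis
# omnibus, with tie correction and Bonferroni adjustment over the three
# pairwise comparisons. No installed package provides this test.
dunn_test <- function(values, groups) {
  N <- length(values)
  rk <- rank(values)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  lv <- levels(groups)
  mean_rank <- tapply(rk, groups, mean)
  n <- tapply(rk, groups, length)
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  p <- vapply(pairs, function(pr) {
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / n[pr[1]] + 1 / n[pr[2]]))
    z <- (mean_rank[pr[1]] - mean_rank[pr[2]]) / se
    min(1, 2 * stats::pnorm(-abs(z)) * length(pairs))  # Bonferroni
  }, 0)
  stats::setNames(p, vapply(pairs, paste, "", collapse = "-"))
}

#' Three-group comparison (L vs M vs H)
#'
#' Ordinary one-way ANOVA followed by Tukey's multiple-comparison test
#' when all three series pass the normality gate; Kruskal-Wallis followed
#' by Dunn's test (Bonferroni-adjusted over the three pairs) otherwise.
#'
#' @param L,M,H Numeric series, at least 2 values each.
#' @param alpha Level of the normality gate.
#' @return List with `omnibus_p`, `pairwise` (named p-values for
#'   `L-M`, `L-H`, `M-H`) and `test` (`"anova_tukey"` or
#'   `"kruskal_dunn"`).
#' @export
group_comparison <- function(L, M, H, alpha = 0.05) {
  if (length(L) < 2 || length(M) < 2 || length(H) < 2) {
    stop_equitherm("each group needs at least 2 values",
                   "equitherm_error_parameter")
  }
  g <- factor(rep(c("L", "M", "H"), c(length(L), length(M), length(H))),
              levels = c("L", "M", "H"))
  y <- c(L, M, H)
  gate <- suppressWarnings(vapply(list(L, M, H), normality_gate, "", alpha))
  if (all(gate == "gaussian")) {
    fit <- stats::aov(y ~ g)
    omnibus <- summary(fit)[[1]][["Pr(>F)"]][1]
    tk <- stats::TukeyHSD(fit)$g
    pw <- stats::setNames(tk[, "p adj"], rownames(tk))
    pairwise <- c(`L-M` = unname(pw["M-L"]), `L-H` = unname(pw["H-L"]),
                  `M-H` = unname(pw["H-M"]))
    list(omnibus_p = omnibus, pairwise = pairwise, test = "anova_tukey")
  } else {
    kw <- stats::kruskal.test(y, g)
    dn <- dunn_test(y, g)
    pairwise <- c(`L-M` = unname(dn["L-M"]), `L-H` = unname(dn["L-H"]),
                  `M-H` = unname(dn["M-H"]))
    list(omnibus_p = kw$p.value, pairwise = pairwise, test = "kruskal_dunn")
  }
}

# split a MeasureTable into per-combination chunks and iterate f over them
combo_split <- function(measures, type) {
  m <- measures[measures$measure_type == type, , drop = FALSE]
  split(m, interaction(m$measure, m$component, m$roi, drop = TRUE))
}

#' Criterion 1: exercise dependence in every rider group
#'
#' A (measure, component, ROI) combination passes only if the
#' pre-vs-post-exercise paired comparison is significant at `alpha` in the
#' light, moderate and heavy groups simultaneously.
#'
#' @param measures MeasureTable (entropy rows are evaluated).
#' @param alpha Significance level.
#' @return Tibble with one row per combination: group p-values, tests used
#'   and `crit1_pass`.
#' @export
criterion1_select <- function(measures, alpha = 0.05) {
  chunks <- combo_split(measures, "entropy")
  out <- lapply(chunks, function(ch) {
    res <- lapply(c("L", "M", "H"), function(g) {
      sub <- ch[ch$group == g, ]
      pre <- sub[sub$session == "pre", ]
      post <- sub[sub$session == "post", ]
      if (nrow(pre) == 0 || nrow(post) == 0) {
        stop_equitherm(sprintf("missing session data for group %s", g),
                       "equitherm_error_structure")
      }
      pre <- pre[order(pre$horse, pre$rider), ]
      post <- post[order(post$horse, post$rider), ]
      if (!identical(paste(pre$horse, pre$rider), paste(post$horse, post$rider))) {
        stop_equitherm("pre/post rows are not paired by (horse, rider)",
                       "equitherm_error_structure")
      }
      ok <- is.finite(pre$value) & is.finite(post$value)
      if (sum(ok) < 3) {
        # too few defined pairs (e.g. sample entropy undefined on most
        # images): the combination cannot demonstrate exercise dependence
        list(p = NA_real_, test = "insufficient_data", statistic = NA_real_)
      } else {
        suppressWarnings(paired_prepost_test(pre$value[ok], post$value[ok],
                                             alpha))
      }
    })
    p <- vapply(res, function(r) r$p, 0)
    tibble::tibble(
      measure = ch$measure[1], component = ch$component[1], roi = ch$roi[1],
      p_L = p[1], p_M = p[2], p_H = p[3],
      test_L = res[[1]]$test, test_M = res[[2]]$test, test_H = res[[3]]$test,
      crit1_pass = all(is.finite(p) & p < alpha)
    )
  })
  dplyr::arrange(dplyr::bind_rows(out), .data$roi, .data$component, .data$measure)
}

#' Criterion 2: rider-group dependence of post-exercise values
#'
#' Compares the post-exercise values of each combination across the L, M
#' and H groups with [group_comparison()]. A combination passes when the
#' omnibus test is significant at `alpha`.
#'
#' @param measures MeasureTable.
#' @param alpha Significance level.
#' @param measure_type `"entropy"` or `"glcm"` rows to evaluate.
#' @return Tibble with omnibus and pairwise p-values and `crit2_pass`.
#' @export
criterion2_select <- function(measures, alpha = 0.05,
                              measure_type = "entropy") {
  chunks <- combo_split(measures, measure_type)
  out <- lapply(chunks, function(ch) {
    post <- ch[ch$session == "post" & is.finite(ch$value), ]
    n_per <- table(factor(post$group, levels = c("L", "M", "H")))
    if (any(n_per < 2)) {
      return(tibble::tibble(
        measure = ch$measure[1], component = ch$component[1], roi = ch$roi[1],
        omnibus_p = NA_real_, p_LM = NA_real_, p_LH = NA_real_,
        p_MH = NA_real_, test = "insufficient_data", crit2_pass = FALSE
      ))
    }
    res <- suppressWarnings(group_comparison(
      post$value[post$group == "L"], post$value[post$group == "M"],
      post$value[post$group == "H"], alpha
    ))
    tibble::tibble(
      measure = ch$measure[1], component = ch$component[1], roi = ch$roi[1],
      omnibus_p = res$omnibus_p,
      p_LM = res$pairwise["L-M"], p_LH = res$pairwise["L-H"],
      p_MH = res$pairwise["M-H"],
      test = res$test, crit2_pass = res$omnibus_p < alpha
    )
  })
  dplyr::arrange(dplyr::bind_rows(out), .data$roi, .data$component, .data$measure)
}

#' Compare two regression slopes on a common regressor
#'
#' Least-squares fits of `y1 ~ x` and `y2 ~ x`, followed by the ANCOVA
#' F-test of slope equality (separate-slopes model against the
#' common-slope model). When the slopes do not differ (p > `alpha`) the
#' pooled slope is reported and the intercepts are compared (common-slope
#' model against the single-line model); when the intercepts also do not
#' differ the pooled intercept is reported.
#'
#' @param x Common regressor.
#' @param y1,y2 Response series, same length as `x`.
#' @param alpha Significance level.
#' @return List of class `slope_comparison` with `slope_1`, `slope_2`,
#'   `F_slopes`, `p_slopes`, `pooled_slope` (NA unless slopes equal),
#'   `F_intercepts`, `p_intercepts`, `pooled_intercept`.
#' @export
compare_slopes <- function(x, y1, y2, alpha = 0.05) {
  if (stats::sd(x) == 0) {
    stop_equitherm("regressor x has zero variance", "equitherm_error_parameter")
  }
  if (length(y1) != length(x) || length(y2) != length(x)) {
    stop_equitherm("x, y1, y2 must have equal length", "equitherm_error_parameter")
  }
  df <- data.frame(y = c(y1, y2), x = c(x, x),
                   s = factor(rep(c("1", "2"), each = length(x))))
  fit_sep <- stats::lm(y ~ x * s, data = df)
  fit_par <- stats::lm(y ~ x + s, data = df)
  fit_com <- stats::lm(y ~ x, data = df)
  # nested-model F from residual deviances; a numerator clipped at zero
  # keeps exactly-parallel series (rounding-level negative sums of
  # squares) at F = 0, p = 1 instead of NA
  nested_f <- function(reduced, full) {
    df_num <- stats::df.residual(reduced) - stats::df.residual(full)
    df_den <- stats::df.residual(full)
    num <- max(0, stats::deviance(reduced) - stats::deviance(full)) / df_num
    den <- stats::deviance(full) / df_den
    if (num == 0) return(list(F = 0, p = 1))
    f <- num / den  # den = 0 gives Inf, p = 0 (exact separation)
    list(F = f, p = stats::pf(f, df_num, df_den, lower.tail = FALSE))
  }
  a_slope <- nested_f(fit_par, fit_sep)
  F_slopes <- a_slope$F
  p_slopes <- a_slope$p
  slope_1 <- unname(stats::coef(stats::lm(y1 ~ x))[2])
  slope_2 <- unname(stats::coef(stats::lm(y2 ~ x))[2])
  pooled_slope <- NA_real_
  F_int <- NA_real_; p_int <- NA_real_; pooled_int <- NA_real_
  if (is.finite(p_slopes) && p_slopes > alpha) {
    pooled_slope <- unname(stats::coef(fit_par)["x"])
    a_int <- nested_f(fit_com, fit_par)
    F_int <- a_int$F
    p_int <- a_int$p
    if (is.finite(p_int) && p_int > alpha) {
      pooled_int <- unname(stats::coef(fit_com)[1])
    }
  }
  structure(
    list(slope_1 = slope_1, slope_2 = slope_2,
         F_slopes = F_slopes, p_slopes = p_slopes, pooled_slope = pooled_slope,
         F_intercepts = F_int, p_intercepts = p_int,
         pooled_intercept = pooled_int),
    class = "slope_comparison"
  )
}

#' @export
print.slope_comparison <- function(x, ...) {
  cat(sprintf("slopes: %.4f vs %.4f | F = %.3f, p = %.4g\n",
              x$slope_1, x$slope_2, x$F_slopes, x$p_slopes))
  if (is.finite(x$pooled_slope)) {
    cat(sprintf("pooled slope %.4f | intercepts: F = %.3f, p = %.4g\n",
                x$pooled_slope, x$F_intercepts, x$p_intercepts))
  }
  invisible(x)
}

# align a combination's post-exercise values to the (horse, rider) order
# and return a data frame of x (bodyweight ratio) and y (value)
combo_post_series <- function(measures, measure, component, roi,
                              standardize = TRUE) {
  sub <- measures[measures$measure == measure &
                    measures$component == component &
                    measures$roi == roi & measures$session == "post", ]
  sub <- sub[order(sub$horse, sub$rider), ]
  y <- sub$value
  if (standardize) {
    mu <- mean(y, na.rm = TRUE)
    sg <- stats::sd(y, na.rm = TRUE)
    if (is.finite(sg) && sg > 0) y <- (y - mu) / sg
  }
  data.frame(key = paste(sub$horse, sub$rider), x = sub$ratio, y = y)
}

#' Criterion 3: slope similarity with the GLCM entropy features
#'
#' For every criterion-2-passing entropy combination and every selected
#' GLCM feature combination, the post-exercise values are regressed on the
#' rider:horse bodyweight ratio and the slopes are compared with
#' [compare_slopes()]. Because the entropy measures and the GLCM features
#' live on incommensurate scales, each series is standardized (zero mean,
#' unit SD) before the comparison, so slope equality measures equal
#' association strength with the ratio.
#'
#' Two rules are applied: (a) a GLCM feature is dropped when its slope is
#' below half the entropy-measure slope for more than half of the entropy
#' combinations compared; (b) an entropy combination is selected when its
#' slope does not differ (p > `alpha`) from at least two retained GLCM
#' features.
#'
#' @param measures MeasureTable.
#' @param entropy_combos Tibble of criterion-2-passing entropy
#'   combinations (`measure`, `component`, `roi`).
#' @param glcm_combos Tibble of selected GLCM combinations (at least 2
#'   rows).
#' @param alpha Significance level.
#' @param standardize Standardize each series before the slope comparison
#'   (default TRUE).
#' @return List with `ledger` (entropy combinations plus
#'   `n_equal_slopes`, `slope`, `crit3_pass`), `glcm` (GLCM combinations
#'   plus `slope`, `dropped`), and the pairwise comparison table
#'   `comparisons`.
#' @export
criterion3_select <- function(measures, entropy_combos, glcm_combos,
                              alpha = 0.05, standardize = TRUE) {
  if (nrow(glcm_combos) < 2) {
    stop_equitherm("criterion 3 needs at least two GLCM feature combinations",
                   "equitherm_error_parameter")
  }
  ent_series <- lapply(seq_len(nrow(entropy_combos)), function(i) {
    combo_post_series(measures, entropy_combos$measure[i],
                      entropy_combos$component[i], entropy_combos$roi[i],
                      standardize)
  })
  glcm_series <- lapply(seq_len(nrow(glcm_combos)), function(i) {
    combo_post_series(measures, glcm_combos$measure[i],
                      glcm_combos$component[i], glcm_combos$roi[i],
                      standardize)
  })
  slope_of <- function(s) unname(stats::coef(stats::lm(y ~ x, data = s))[2])
  ent_slopes <- vapply(ent_series, slope_of, 0)
  glcm_slopes <- vapply(glcm_series, slope_of, 0)

  # rule (a): drop GLCM features with slope below half the entropy slopes
  dropped <- vapply(seq_along(glcm_series), function(j) {
    if (length(ent_slopes) == 0) return(FALSE)
    mean(glcm_slopes[j] < 0.5 * ent_slopes) > 0.5
  }, TRUE)
  retained <- which(!dropped)
  if (length(retained) < 2) {
    warn_equitherm(
      "fewer than two GLCM features retained; no entropy measure can pass criterion 3",
      "equitherm_warning_selection"
    )
  }

  # rule (b): slope equality against every retained GLCM feature
  comparisons <- list()
  n_equal <- integer(length(ent_series))
  for (i in seq_along(ent_series)) {
    for (j in retained) {
      merged <- merge(ent_series[[i]], glcm_series[[j]], by = "key")
      ok <- is.finite(merged$y.x) & is.finite(merged$y.y)
      cmp <- compare_slopes(merged$x.x[ok], merged$y.x[ok], merged$y.y[ok],
                            alpha)
      equal <- is.finite(cmp$p_slopes) && cmp$p_slopes > alpha
      if (equal) n_equal[i] <- n_equal[i] + 1L
      comparisons[[length(comparisons) + 1]] <- tibble::tibble(
        measure = entropy_combos$measure[i],
        component = entropy_combos$component[i],
        roi = entropy_combos$roi[i],
        glcm_measure = glcm_combos$measure[j],
        glcm_component = glcm_combos$component[j],
        glcm_roi = glcm_combos$roi[j],
        p_slopes = cmp$p_slopes, pooled_slope = cmp$pooled_slope,
        p_intercepts = cmp$p_intercepts, slopes_equal = equal
      )
    }
  }
  ledger <- entropy_combos
  ledger$slope <- ent_slopes
  ledger$n_equal_slopes <- n_equal
  ledger$crit3_pass <- n_equal >= 2
  glcm_out <- glcm_combos
  glcm_out$slope <- glcm_slopes
  glcm_out$dropped <- dropped
  list(ledger = ledger, glcm = glcm_out,
       comparisons = dplyr::bind_rows(comparisons))
}

#' Run the full three-criterion selection procedure
#'
#' Applies criterion 1 (exercise dependence in all three rider groups) to
#' the 40 entropy combinations, criterion 2 (rider-group dependence of the
#' post-exercise values) to the criterion-1 passers, selects the GLCM
#' feature combinations by the same group-dependence test, and applies
#' criterion 3 (slope similarity with at least two retained GLCM
#' features). If fewer than two GLCM combinations show group dependence,
#' criterion 3 cannot select anything and all combinations fail it (with a
#' warning).
#'
#' @param measures MeasureTable of a full study.
#' @param alpha Significance level used throughout.
#' @param standardize Standardize series in the criterion-3 slope
#'   comparison.
#' @return An object of class `selection_ledger`: list with the entropy
#'   `ledger` (one row per combination, all criteria), the `glcm` ledger,
#'   the criterion-3 `comparisons` table and `alpha`.
#' @export
select_measures <- function(measures, alpha = 0.05, standardize = TRUE) {
  c1 <- criterion1_select(measures, alpha)
  pass1 <- c1[c1$crit1_pass, c("measure", "component", "roi")]
  if (nrow(pass1) > 0) {
    keep <- paste(measures$measure, measures$component, measures$roi) %in%
      paste(pass1$measure, pass1$component, pass1$roi)
    c2 <- criterion2_select(measures[keep & measures$measure_type == "entropy", ,
                                     drop = FALSE], alpha, "entropy")
    ledger <- dplyr::left_join(
      c1, c2[, c("measure", "component", "roi", "omnibus_p",
                 "p_LM", "p_LH", "p_MH", "test", "crit2_pass")],
      by = c("measure", "component", "roi")
    )
    ledger$crit2_pass[is.na(ledger$crit2_pass)] <- FALSE
  } else {
    ledger <- c1
    ledger$omnibus_p <- NA_real_
    ledger$p_LM <- NA_real_; ledger$p_LH <- NA_real_; ledger$p_MH <- NA_real_
    ledger$test <- NA_character_
    ledger$crit2_pass <- FALSE
  }
  glcm_c2 <- criterion2_select(measures, alpha, "glcm")
  ent_pass <- ledger[ledger$crit1_pass & ledger$crit2_pass,
                     c("measure", "component", "roi")]
  glcm_sel <- glcm_c2[glcm_c2$crit2_pass, c("measure", "component", "roi")]
  comparisons <- tibble::tibble()
  glcm_ledger <- glcm_c2
  glcm_ledger$dropped <- NA
  ledger$slope <- NA_real_
  ledger$n_equal_slopes <- NA_integer_
  ledger$crit3_pass <- FALSE
  if (nrow(ent_pass) > 0 && nrow(glcm_sel) >= 2) {
    c3 <- criterion3_select(measures, ent_pass, glcm_sel, alpha, standardize)
    comparisons <- c3$comparisons
    for (i in seq_len(nrow(c3$ledger))) {
      k <- which(ledger$measure == c3$ledger$measure[i] &
                   ledger$component == c3$ledger$component[i] &
                   ledger$roi == c3$ledger$roi[i])
      ledger$slope[k] <- c3$ledger$slope[i]
      ledger$n_equal_slopes[k] <- c3$ledger$n_equal_slopes[i]
      ledger$crit3_pass[k] <- c3$ledger$crit3_pass[i]
    }
    for (j in seq_len(nrow(c3$glcm))) {
      k <- which(glcm_ledger$measure == c3$glcm$measure[j] &
                   glcm_ledger$component == c3$glcm$component[j] &
                   glcm_ledger$roi == c3$glcm$roi[j])
      glcm_ledger$dropped[k] <- c3$glcm$dropped[j]
    }
  } else if (nrow(ent_pass) > 0) {
    warn_equitherm(
      "fewer than two group-dependent GLCM combinations; criterion 3 selects nothing",
      "equitherm_warning_selection"
    )
  }
  structure(list(ledger = ledger, glcm = glcm_ledger,
                 comparisons = comparisons, alpha = alpha),
            class = "selection_ledger")
}

#' @export
print.selection_ledger <- function(x, ...) {
  l <- x$ledger
  cat(sprintf("Selection ledger: %d combinations at alpha = %g\n",
              nrow(l), x$alpha))
  cat(sprintf("  criterion 1 (exercise-dependent, all groups): %d\n",
              sum(l$crit1_pass)))
  cat(sprintf("  criterion 2 (rider-group-dependent):          %d\n",
              sum(l$crit2_pass)))
  cat(sprintf("  criterion 3 (GLCM slope similarity):          %d\n",
              sum(l$crit3_pass)))
  sel <- l[l$crit3_pass, ]
  if (nrow(sel) == 0) {
    cat("  no combination selected\n")
  } else {
    for (i in seq_len(nrow(sel))) {
      cat(sprintf("  selected: %s / %s / %s\n", sel$measure[i],
                  sel$component[i], sel$roi[i]))
    }
  }
  invisible(x)
}
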