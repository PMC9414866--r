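#' Three detection thresholds from a reference sample
#'
#' Sample mean minus one SD, the mean, and mean plus one SD (sample SD,
#' n-1 denominator) of a reference set of measure values -- here the
#' pooled light + heavy post-exercise values, so no group label is used at
#' threshold-setting time.
#'
#' @param values Numeric vector, at least 2 values.
#' @return Object of class `threshold_set`: list with `low`, `mid`,
#'   `high`, `mean`, `sd`, `n`.
#' @examples
#' make_thresholds(c(1, 2, 3))  # 1, 2, 3
#' @export
make_thresholds <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 2) {
    stop_equitherm("need at least 2 values to set thresholds",
                   "equitherm_error_parameter")
  }
  m <- mean(values); s <- stats::sd(values)
  structure(list(low = m - s, mid = m, high = m + s,
                 mean = m, sd = s, n = length(values)),
            class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat(sprintf("thresholds (n = %d): m - SD = %.4f, mean = %.4f, m + SD = %.4f\n",
              x$n, x$low, x$mid, x$high))
  invisible(x)
}

#' Confusion counts and derived accuracy metrics
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, positive predictive
#' value `TP/(TP+FP)` and negative predictive value `TN/(TN+FN)`, with the
#' heavy rider group as the positive class. An undefined ratio (zero
#' denominator) is reported as `NA`, never as 0. Values are kept at full
#' precision; the print method rounds to 2 decimals as in reporting.
#'
#' @param tp,fp,tn,fn Confusion counts.
#' @return Object of class `confusion_summary`.
#' @examples
#' confusion_summary(22, 13, 11, 2)  # Se 0.92, Sp 0.46, PPV 0.63, NPV 0.85
#' @export
confusion_summary <- function(tp, fp, tn, fn) {
  ratio <- function(a, b) if (a + b == 0) NA_real_ else a / (a + b)
  structure(
    list(TP = tp, FP = fp, TN = tn, FN = fn,
         Se = ratio(tp, fn), Sp = ratio(tn, fp),
         PPV = ratio(tp, fp), NPV = ratio(tn, fn)),
    class = "confusion_summary"
  )
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  TN %d  FN %d\n", x$TP, x$FP, x$TN, x$FN))
  cat(sprintf("Se %.2f  Sp %.2f  PPV %.2f  NPV %.2f\n",
              x$Se, x$Sp, x$PPV, x$NPV))
  invisible(x)
}

#' Classify light vs heavy riders at one threshold
#'
#' An observation is predicted heavy (the positive class, coded 1) when
#' its measure value is strictly above the threshold and light (0) when at
#' or below it -- ties go to light, the literal reading of "above the
#' threshold".
#'
#' @param values_light,values_heavy Post-exercise measure values of the
#'   light and heavy rider groups.
#' @param threshold Numeric cutoff.
#' @return A [confusion_summary()].
#' @export
classify_and_score <- function(values_light, values_heavy, threshold) {
  values_light <- values_light[is.finite(values_light)]
  values_heavy <- values_heavy[is.finite(values_heavy)]
  if (length(values_light) == 0 || length(values_heavy) == 0) {
    stop_equitherm("both groups must be non-empty", "equitherm_error_parameter")
  }
  tp <- sum(values_heavy > threshold)
  fn <- length(values_heavy) - tp
  fp <- sum(values_light > threshold)
  tn <- length(values_light) - fp
  confusion_summary(tp, fp, tn, fn)
}

#' Score a measure at all three thresholds
#'
#' One [classify_and_score()] evaluation per threshold, low to high. By
#' the strict-inequality rule the sensitivity is non-increasing and the
#' specificity non-decreasing in the threshold.
#'
#' @param values_light,values_heavy Group values.
#' @param thresholds A [make_thresholds()] set.
#' @return Tibble with one row per threshold: counts and Se/Sp/PPV/NPV.
#' @export
threshold_sweep <- function(values_light, values_heavy, thresholds) {
  if (!inherits(thresholds, "threshold_set")) {
    stop_equitherm("thresholds must be a threshold_set",
                   "equitherm_error_parameter")
  }
  lv <- c(low = thresholds$low, mid = thresholds$mid, high = thresholds$high)
  rows <- lapply(names(lv), function(nm) {
    cs <- classify_and_score(values_light, values_heavy, lv[[nm]])
    tibble::tibble(threshold = nm, cutoff = lv[[nm]],
                   TP = cs$TP, FP = cs$FP, TN = cs$TN, FN = cs$FN,
                   Se = cs$Se, Sp = cs$Sp, PPV = cs$PPV, NPV = cs$NPV)
  })
  dplyr::bind_rows(rows)
}

#' Accuracy of bodyweight-ratio detection for the selected combinations
#'
#' For every criterion-3-selected entropy combination (and, for
#' comparison, every retained group-dependent GLCM combination) the light
#' and heavy post-exercise values are scored at the three thresholds
#' computed from their pooled values, mirroring the accuracy-table layout
#' measure x component x ROI x threshold x (Se, Sp, PPV, NPV).
#'
#' @param measures MeasureTable.
#' @param selection A [select_measures()] ledger.
#' @return Tibble of accuracy rows.
#' @export
detection_accuracy <- function(measures, selection) {
  l <- selection$ledger
  combos <- l[l$crit3_pass, c("measure", "component", "roi")]
  g <- selection$glcm
  if (!is.null(g$dropped)) {
    keep <- g$crit2_pass & !is.na(g$dropped) & !g$dropped
    combos <- rbind(combos, g[keep, c("measure", "component", "roi")])
  }
  if (nrow(combos) == 0) return(tibble::tibble())
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    sub <- measures[measures$measure == combos$measure[i] &
                      measures$component == combos$component[i] &
                      measures$roi == combos$roi[i] &
                      measures$session == "post", ]
    light <- sub$value[sub$group == "L" & is.finite(sub$value)]
    heavy <- sub$value[sub$group == "H" & is.finite(sub$value)]
    thr <- make_thresholds(c(light, heavy))
    sw <- threshold_sweep(light, heavy, thr)
    tibble::tibble(measure = combos$measure[i],
                   component = combos$component[i], roi = combos$roi[i], sw)
  })
  dplyr::bind_rows(rows)
}
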