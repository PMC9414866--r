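#!/usr/bin/env Rscript
# Stage 4 -- light-vs-heavy detection accuracy.
#
# For every combination that survived criterion 3 (plus the retained GLCM
# features for comparison), the post-exercise values of the light and
# heavy rider groups are classified at three thresholds -- mean - SD,
# mean, mean + SD of the pooled values -- and scored by sensitivity,
# specificity, PPV and NPV. Writes results/accuracy.csv.

suppressPackageStartupMessages(library(equitherm))

out_dir <- "results"
measures <- read_measures(file.path(out_dir, "measures.csv"))
sel <- suppressWarnings(select_measures(measures, alpha = 0.05))
accuracy <- detection_accuracy(measures, sel)
write.csv(accuracy, file.path(out_dir, "accuracy.csv"), row.names = FALSE)

if (nrow(accuracy) == 0) {
  cat("no combination selected; nothing to score\n")
} else {
  for (i in seq_len(nrow(accuracy))) {
    a <- accuracy[i, ]
    cat(sprintf("%s / %s / %s @ %-4s  Se %.2f  Sp %.2f  PPV %s  NPV %s\n",
                a$measure, a$component, a$roi, a$threshold, a$Se, a$Sp,
                ifelse(is.na(a$PPV), "NA", sprintf("%.2f", a$PPV)),
                ifelse(is.na(a$NPV), "NA", sprintf("%.2f", a$NPV))))
  }
}
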