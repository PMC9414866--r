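#!/usr/bin/env Rscript
# Stage 3 -- three-criterion measure selection.
#
# Criterion 1: paired pre/post-exercise comparison (paired t or Wilcoxon
# after a Shapiro-Wilk gate) must be significant in the light, moderate
# and heavy groups simultaneously. Criterion 2: post-exercise values must
# differ across rider groups (ANOVA + Tukey or Kruskal-Wallis + Dunn).
# Criterion 3: the regression slope on the bodyweight ratio (standardized
# series) must be statistically indistinguishable from at least two
# retained GLCM entropy features. Writes results/ledger.csv and
# results/glcm_ledger.csv.

suppressPackageStartupMessages(library(equitherm))

out_dir <- "results"
measures <- read_measures(file.path(out_dir, "measures.csv"))
sel <- suppressWarnings(select_measures(measures, alpha = 0.05))

write.csv(sel$ledger, file.path(out_dir, "ledger.csv"), row.names = FALSE)
write.csv(sel$glcm, file.path(out_dir, "glcm_ledger.csv"), row.names = FALSE)
if (nrow(sel$comparisons) > 0) {
  write.csv(sel$comparisons, file.path(out_dir, "slope_comparisons.csv"),
            row.names = FALSE)
}
# full p-value provenance in one machine-readable document
jsonlite::write_json(
  list(alpha = sel$alpha, entropy = sel$ledger, glcm = sel$glcm,
       slope_comparisons = sel$comparisons),
  file.path(out_dir, "ledger.json"), auto_unbox = TRUE, pretty = TRUE,
  digits = NA
)

print(sel)
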