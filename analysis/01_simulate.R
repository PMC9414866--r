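#!/usr/bin/env Rscript
# Stage 1 -- simulate the imaging study.
#
# Builds the crossed horse-by-rider design (12 horses x 6 riders, pre- and
# post-exercise: 144 images) and renders one false-color thermogram per
# design row with the default texture model: smooth background (SD 4,
# correlation length 8 px), irregularity noise 0.5 pre-exercise and
# 1.0/1.5/2.0 post-exercise for the light/moderate/heavy rider groups, and
# a 1.25x hot-region gain inside the two 24 x 24 ROIs after exercise.
#
# Writes results/design.csv, results/roi_specs.json and one PNG per image
# under results/images/.

suppressPackageStartupMessages(library(equitherm))

seed <- 1L
out_dir <- "results"
img_dir <- file.path(out_dir, "images")
dir.create(img_dir, showWarnings = FALSE, recursive = TRUE)

design <- make_design(seed = seed)
write.csv(design, file.path(out_dir, "design.csv"), row.names = FALSE)

roi_specs <- default_roi_specs(c(64, 64))
write_roi_specs(roi_specs, file.path(out_dir, "roi_specs.json"))

model <- texture_model()
for (i in seq_len(nrow(design))) {
  row <- design[i, ]
  tg <- generate_thermogram(row, model, c(64, 64), roi_specs, seed = seed + i)
  write_thermogram(tg, file.path(
    img_dir, sprintf("%s_%s_%s.png", row$horse, row$rider, row$session)
  ))
}

cat(sprintf("simulated %d thermograms (%d pre, %d post) into %s\n",
            nrow(design), sum(design$session == "pre"),
            sum(design$session == "post"), img_dir))
cat(sprintf("rider:horse bodyweight ratios span %.1f%% to %.1f%%\n",
            min(design$ratio), max(design$ratio)))
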