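# Seeded patch generators used throughout the suite.

# integer patch with a restricted alphabet: spaced levels keep the sample
# entropy well defined at moderate absolute tolerances
level_patch <- function(n, seed, levels = 6, spacing = 40) {
  set.seed(seed)
  matrix(sample(0:(levels - 1) * spacing, n * n, replace = TRUE), n, n)
}

# full 8-bit uniform noise
noise_patch <- function(n, seed) {
  set.seed(seed)
  matrix(sample(0:255, n * n, replace = TRUE), n, n)
}

# smooth correlated field plus optional i.i.d. noise, rescaled to [0, 255]
smooth_patch <- function(n, seed, noise_sd = 0, scale = 4) {
  set.seed(seed)
  pad <- n + 4 * scale
  z <- matrix(rnorm(pad^2), pad, pad)
  k <- exp(-((-(2 * scale):(2 * scale))^2) / (2 * scale^2))
  k <- k / sum(k)
  z <- stats::filter(z, k, circular = TRUE)
  z <- t(stats::filter(t(z), k, circular = TRUE))
  z <- matrix(as.numeric(z), pad, pad)[(2 * scale + 1):(2 * scale + n),
                                       (2 * scale + 1):(2 * scale + n)]
  z <- z / sd(z) + rnorm(n^2, 0, noise_sd)
  round((z - min(z)) / (max(z) - min(z)) * 255)
}

# MeasureTable built directly from distributions (no images): entropy and
# GLCM rows for the full crossed design, optionally with a planted
# post-exercise shift in chosen components and a group gradient
synth_measures <- function(seed, n_horses = 12,
                           effect_components = character(0),
                           post_shift = 1, group_step = 0.5, sd = 1) {
  set.seed(seed)
  riders <- equitherm::default_riders()
  design <- equitherm::make_design(n_horses = n_horses, riders = riders)
  combos <- expand.grid(
    measure = c("SampEn", "FuzzEn", "PermEn", "DispEn", "DistEn"),
    component = c("gray", "red", "green", "blue"),
    roi = c("ROI1_withers", "ROI2_thoracic"),
    stringsAsFactors = FALSE
  )
  glcm_combos <- expand.grid(
    measure = c("SumEntrp", "Entropy", "DifEntrp"),
    component = c("gray", "red", "green", "blue"),
    roi = c("ROI1_withers", "ROI2_thoracic"),
    stringsAsFactors = FALSE
  )
  step <- c(L = 0, M = group_step, H = 2 * group_step)
  make_rows <- function(cmb, type) {
    out <- vector("list", nrow(cmb))
    for (i in seq_len(nrow(cmb))) {
      eff <- cmb$component[i] %in% effect_components
      mu <- ifelse(design$session == "post" & eff,
                   post_shift + step[as.character(design$group)], 0)
      out[[i]] <- tibble::tibble(
        horse = design$horse, rider = design$rider,
        group = as.character(design$group),
        session = as.character(design$session), ratio = design$ratio,
        roi = cmb$roi[i], component = cmb$component[i],
        measure = cmb$measure[i], measure_type = type,
        value = rnorm(nrow(design), mu, sd)
      )
    }
    dplyr::bind_rows(out)
  }
  dplyr::bind_rows(make_rows(combos, "entropy"),
                   make_rows(glcm_combos, "glcm"))
}
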