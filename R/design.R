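#' Rider:horse bodyweight ratio
#'
#' The ratio of combined rider and saddle weight to horse bodyweight,
#' expressed as a percentage and reported to one decimal place:
#' `100 * (rider_kg + saddle_kg) / horse_kg`. Published guidance reads
#' roughly 10--12% as a fitting rider, >12--15% as overweight and >15% as
#' obese relative to the horse's size.
#'
#' @param rider_kg,saddle_kg,horse_kg Weights in kilograms (vectorized).
#' @param digits Decimal places of the reported percentage (default 1).
#' @return Percentage(s), rounded to `digits` decimals.
#' @examples
#' bodyweight_ratio(59.0, 4.3, 566.7)  # 11.2, a light rider
#' bodyweight_ratio(91.5, 4.3, 566.7)  # 16.9, a heavy rider
#' @export
bodyweight_ratio <- function(rider_kg, saddle_kg, horse_kg, digits = 1) {
  if (any(horse_kg <= 0)) {
    stop_equitherm("horse bodyweight must be positive", "equitherm_error_parameter")
  }
  if (any(rider_kg < 0) || any(saddle_kg < 0)) {
    stop_equitherm("rider and saddle weights must be non-negative",
                   "equitherm_error_parameter")
  }
  round(100 * (rider_kg + saddle_kg) / horse_kg, digits)
}

#' Default rider roster
#'
#' Six riders, two per bodyweight group, with individual weights matching
#' the reference group means (light 59.0 kg, moderate 76.0 kg, heavy
#' 91.5 kg) and heights averaging 166.8 cm.
#'
#' @return A tibble with columns `rider`, `group`, `rider_kg`, `height_cm`.
#' @export
default_riders <- function() {
  tibble::tibble(
    rider = paste0("R", 1:6),
    group = factor(c("L", "L", "M", "M", "H", "H"), levels = c("L", "M", "H")),
    rider_kg = c(58, 60, 75, 77, 91, 92),
    height_cm = c(165, 168, 163, 170, 172, 163)
  )
}

#' Build the crossed horse-by-rider study design
#'
#' Enumerates every (horse, rider, session) combination of the imaging
#' study: each horse is paired with every rider exactly once per session
#' (pre- and post-exercise), giving `n_horses * n_riders * 2` rows -- 144
#' with the defaults of 12 horses and 6 riders. Horse bodyweights default
#' to the reference mean of 566.7 kg and saddles to 4.3 kg; optional
#' Gaussian jitter (reproducible under `seed`) perturbs them per horse.
#'
#' @param n_horses Number of horses (>= 1).
#' @param riders Rider roster as returned by [default_riders()]: one row
#'   per rider with `rider`, `group` (levels L/M/H, equally sized),
#'   `rider_kg`.
#' @param horse_weight_mean,horse_weight_sd Horse bodyweight distribution
#'   in kg; `sd = 0` (default) gives identical horses.
#' @param saddle_weight,saddle_weight_sd Saddle weight per horse in kg.
#' @param seed Optional integer seed for the weight jitter.
#' @return A tibble with one row per (horse, rider, session) and a
#'   `ratio` column holding the rider:horse bodyweight ratio (%).
#' @examples
#' d <- make_design()
#' nrow(d)           # 144
#' table(d$session)  # 72 pre, 72 post
#' @export
make_design <- function(n_horses = 12, riders = default_riders(),
                        horse_weight_mean = 566.7, horse_weight_sd = 0,
                        saddle_weight = 4.3, saddle_weight_sd = 0,
                        seed = NULL) {
  if (n_horses < 1) {
    stop_equitherm("need at least one horse", "equitherm_error_config")
  }
  if (!all(c("rider", "group", "rider_kg") %in% names(riders)) ||
      nrow(riders) < 1) {
    stop_equitherm("riders must have columns rider, group, rider_kg",
                   "equitherm_error_config")
  }
  riders$group <- factor(riders$group, levels = c("L", "M", "H"))
  if (any(is.na(riders$group))) {
    stop_equitherm("rider groups must be L, M or H", "equitherm_error_config")
  }
  sizes <- table(riders$group)
  sizes <- sizes[sizes > 0]  # groups in use must be equally sized
  if (length(sizes) == 0 || length(unique(as.integer(sizes))) != 1) {
    stop_equitherm(
      "rider groups must be balanced: equal riders per group in every group used",
      "equitherm_error_config"
    )
  }
  if (!is.null(seed)) set.seed(seed)
  horses <- tibble::tibble(
    horse = sprintf("H%02d", seq_len(n_horses)),
    horse_kg = horse_weight_mean +
      if (horse_weight_sd > 0) stats::rnorm(n_horses, 0, horse_weight_sd) else 0,
    saddle_kg = saddle_weight +
      if (saddle_weight_sd > 0) stats::rnorm(n_horses, 0, saddle_weight_sd) else 0
  )
  out <- tidyr::expand_grid(
    horses,
    riders[, c("rider", "group", "rider_kg")],
    session = factor(c("pre", "post"), levels = c("pre", "post"))
  )
  out$ratio <- bodyweight_ratio(out$rider_kg, out$saddle_kg, out$horse_kg)
  dplyr::arrange(out, .data$horse, .data$rider, .data$session)
}
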