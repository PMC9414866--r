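#' Two-dimensional sample entropy
#'
#' Negative natural log of the conditional probability that two
#' `(m+1) x (m+1)` pixel windows match within tolerance `r` given that
#' their `m x m` sub-windows match. Windows are enumerated densely at
#' stride 1 and the two stages share the same top-aligned anchor grid (all
#' top-left corners that admit an `(m+1) x (m+1)` window), so the ratio of
#' match densities keeps its conditional-probability interpretation.
#' Matching uses the Chebyshev distance (maximum absolute pixel
#' difference); self-pairs are excluded.
#'
#' Regular or periodic textures give values near zero; irregular textures
#' give large values. When no `(m+1)`-stage (or no `m`-stage) pair matches
#' the measure is undefined and a classed error
#' (`equitherm_error_undefined_entropy`) is thrown -- an undefined value is
#' deliberately distinct from zero.
#'
#' @param patch Numeric matrix of pixel intensities (one ROI, one color
#'   component).
#' @param params An [entropy_params()] object.
#' @return A list with elements `value`, `phi_m`, `phi_m1` and the resolved
#'   tolerance `r`.
#' @examples
#' p <- outer(1:4, 1:4, function(i, j) (i + j) %% 2)  # checkerboard
#' sampen2d(p, entropy_params(m = 1, r = 0.5, r_is_fraction = FALSE))$value
#' @export
sampen2d <- function(patch, params = entropy_params()) {
  patch <- validate_patch(patch)
  m <- params$m
  if (nrow(patch) <= m + 1 || ncol(patch) <= m + 1) {
    stop_equitherm("patch must be strictly larger than (m+1) x (m+1)",
                   "equitherm_error_dimension")
  }
  r <- resolve_r(patch, params)
  phi <- cpp_sampen_phi(patch, m, r)
  if (phi[1] == 0 || phi[2] == 0) {
    stop_equitherm(
      "sample entropy undefined: no matching window pairs at tolerance r",
      "equitherm_error_undefined_entropy"
    )
  }
  list(value = -log(phi[2] / phi[1]), phi_m = phi[1], phi_m1 = phi[2], r = r)
}

#' Two-dimensional fuzzy entropy
#'
#' Like [sampen2d()] but with a continuous exponential similarity
#' membership `exp(-d^n / r)` in place of the hard threshold, where `d` is
#' the Chebyshev distance between windows after removing each window's mean
#' (local baseline). The soft membership makes the measure continuous in
#' the pixel values and defined even when no window pair matches exactly.
#'
#' @inheritParams sampen2d
#' @return A list with elements `value`, `phi_m`, `phi_m1` and the resolved
#'   tolerance `r`.
#' @export
fuzzen2d <- function(patch, params = entropy_params()) {
  patch <- validate_patch(patch)
  m <- params$m
  if (nrow(patch) <= m + 1 || ncol(patch) <= m + 1) {
    stop_equitherm("patch must be strictly larger than (m+1) x (m+1)",
                   "equitherm_error_dimension")
  }
  r <- resolve_r(patch, params)
  if (r == 0) {
    if (stats::sd(patch) == 0) {
      # constant patch: all distances are zero, every membership is 1
      return(list(value = 0, phi_m = 1, phi_m1 = 1, r = 0))
    }
    stop_equitherm("fuzzy tolerance r resolved to zero on a non-constant patch",
                   "equitherm_error_parameter")
  }
  phi <- cpp_fuzzen_phi(patch, m, r, params$n, params$fuzzy_center)
  list(value = -log(phi[2] / phi[1]), phi_m = phi[1], phi_m1 = phi[2], r = r)
}

#' Two-dimensional permutation entropy
#'
#' Shannon entropy of the ordinal (rank-order) patterns of all dense
#' `dn x dm` pixel windows. Each window is flattened row-major and ranked
#' with ties broken by position (stable ranking), so the pattern census is
#' deterministic. By default the entropy is normalized by
#' `ln((dn*dm)!)` so that values lie in `[0, 1]`: near 0 for pixels that
#' always appear in the same order (gradients, constants), near 1 for
#' highly disordered pixels.
#'
#' @inheritParams sampen2d
#' @return A list with `value`, the raw Shannon sum `raw`, the pattern
#'   probability vector `probs` (named by rank pattern) and the window
#'   count `n_windows`.
#' @export
permen2d <- function(patch, params = entropy_params()) {
  patch <- validate_patch(patch)
  W <- window_matrix(patch, params$dn, params$dm)
  k <- ncol(W)
  # stable (position tie-break) ranks, vectorized over windows
  ranks <- matrix(1L, nrow(W), k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (j == i) next
      ranks[, i] <- ranks[, i] +
        ((W[, j] < W[, i]) | (W[, j] == W[, i] & j < i))
    }
  }
  key <- as.vector((ranks - 1) %*% k^(0:(k - 1)))
  cens <- table(key)
  p <- as.vector(cens) / nrow(W)
  raw <- -sum(p * log(p))
  value <- scale_census_entropy(raw, lfactorial(k), nrow(W), params)
  list(value = value, raw = raw,
       probs = stats::setNames(p, names(cens)), n_windows = nrow(W))
}

#' Two-dimensional dispersion entropy
#'
#' Pixels are mapped through the Gaussian cumulative distribution function
#' (with the patch mean and standard deviation) and discretized into `c`
#' classes via `z = round(c * v + 0.5)` (half-up, clamped to `[1, c]`).
#' The Shannon entropy of the resulting `dn x dm` dispersion-pattern
#' census is returned, by default normalized by `ln(c^(dn*dm))`. The
#' measure attains its maximum when all patterns are equiprobable and its
#' minimum (0) for a single pattern.
#'
#' A constant patch has zero standard deviation, so the Gaussian mapping is
#' degenerate: by documented rule all pixels map to the middle class, a
#' single pattern results and the entropy is 0 (a classed warning
#' `equitherm_warning_degenerate` is emitted, not an error).
#'
#' @inheritParams sampen2d
#' @return A list with `value`, `raw`, `probs`, `n_windows`, and the
#'   mapping moments `mu` and `sigma`.
#' @export
dispen2d <- function(patch, params = entropy_params()) {
  patch <- validate_patch(patch)
  mu <- mean(patch)
  sigma <- stats::sd(patch)
  if (sigma == 0) {
    warn_equitherm(
      "constant patch: Gaussian mapping degenerate, dispersion entropy is 0",
      "equitherm_warning_degenerate"
    )
    nw <- (nrow(patch) - params$dn + 1) * (ncol(patch) - params$dm + 1)
    return(list(value = 0, raw = 0, probs = c(`1` = 1), n_windows = nw,
                mu = mu, sigma = 0))
  }
  cc <- params$c
  v <- stats::pnorm(patch, mean = mu, sd = sigma)
  z <- pmin(pmax(floor(cc * v + 1), 1), cc)  # round(c*v + 0.5), half-up
  W <- window_matrix(z, params$dn, params$dm)
  k <- ncol(W)
  key <- as.vector((W - 1) %*% cc^(0:(k - 1)))
  cens <- table(key)
  p <- as.vector(cens) / nrow(W)
  raw <- -sum(p * log(p))
  value <- scale_census_entropy(raw, k * log(cc), nrow(W), params)
  list(value = value, raw = raw,
       probs = stats::setNames(p, names(cens)), n_windows = nrow(W),
       mu = mu, sigma = sigma)
}

#' Two-dimensional distribution entropy
#'
#' Shannon entropy (in bits) of the empirical distribution of all pairwise
#' Chebyshev distances between the dense `m x m` windows of the patch. The
#' distance multiset (self-pairs excluded) is histogrammed into `M` equal
#' bins spanning `(0, d_max]` -- zero distances fall in the first bin, and
#' an all-zero distance multiset occupies a single bin -- and
#' `DistEn = -sum(p_t * log2(p_t))`. With `normalized = TRUE` the value is
#' divided by `log2(M)`. Binning relative to the per-patch maximum
#' distance makes the measure invariant to positive affine intensity
#' rescaling.
#'
#' @inheritParams sampen2d
#' @return A list with `value`, bin probabilities `probs`, `d_max` absent
#'   (binning is internal) and the window count `n_windows`.
#' @export
disten2d <- function(patch, params = entropy_params()) {
  patch <- validate_patch(patch)
  m <- params$m
  if (nrow(patch) < m || ncol(patch) < m) {
    stop_equitherm("patch smaller than the m x m window",
                   "equitherm_error_dimension")
  }
  nw <- (nrow(patch) - m + 1) * (ncol(patch) - m + 1)
  if (nw < 2) {
    stop_equitherm("need at least two windows for distribution entropy",
                   "equitherm_error_dimension")
  }
  counts <- cpp_disten_hist(patch, m, params$M)
  p <- counts / sum(counts)
  nz <- p[p > 0]
  raw <- -sum(nz * log2(nz))
  value <- if (params$normalized) raw / log2(params$M) else raw
  list(value = value, raw = raw, probs = p, n_windows = nw)
}

# shared normalization for the census-type measures (PermEn/DispEn)
scale_census_entropy <- function(raw, log_pattern_count, n_windows, params) {
  if (params$window_prefactor) {
    raw / n_windows
  } else if (params$normalized) {
    raw / log_pattern_count
  } else {
    raw
  }
}

#' All five bidimensional entropy measures of a patch
#'
#' Convenience wrapper returning the five measures as a named numeric
#' vector. An undefined sample entropy (no matching window pairs) is
#' reported as `NA` with a classed warning rather than an error, so that
#' batch extraction over many images does not abort.
#'
#' @inheritParams sampen2d
#' @return Named numeric vector `c(SampEn, FuzzEn, PermEn, DispEn, DistEn)`.
#' @export
entropy_profile <- function(patch, params = entropy_params()) {
  samp <- tryCatch(sampen2d(patch, params)$value,
    equitherm_error_undefined_entropy = function(e) {
      warn_equitherm("sample entropy undefined on this patch; reported as NA",
                     "equitherm_warning_undefined")
      NA_real_
    })
  c(SampEn = samp,
    FuzzEn = fuzzen2d(patch, params)$value,
    PermEn = permen2d(patch, params)$value,
    DispEn = dispen2d(patch, params)$value,
    DistEn = disten2d(patch, params)$value)
}
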