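#' Parameters of the bidimensional entropy measures
#'
#' Collects every tunable of the five two-dimensional entropy measures in one
#' validated object. The defaults follow the prevailing conventions of the
#' bidimensional-entropy literature: template size `m = 2`, tolerance
#' `r = 0.2` as a fraction of the patch standard deviation, fuzzy exponent
#' `n = 2`, a `2 x 2` embedding for the ordinal and dispersion measures,
#' `c = 3` dispersion classes (so the 3^4 = 81 dispersion patterns stay
#' estimable on small regions of interest) and `M = 512` histogram bins for
#' the distribution entropy.
#'
#' @param m Template window size for the sample, fuzzy and distribution
#'   entropies. Sample/fuzzy entropy compare `m x m` against
#'   `(m+1) x (m+1)` windows; distribution entropy uses `m x m` windows.
#' @param r Similarity tolerance for the sample and fuzzy entropies. When
#'   `r_is_fraction = TRUE` (default) the tolerance used on a patch is
#'   `r * sd(patch)`; otherwise `r` is in absolute intensity units.
#' @param r_is_fraction Interpret `r` as a fraction of the patch standard
#'   deviation?
#' @param n Fuzzy membership exponent: similarity of two windows at
#'   Chebyshev distance `d` is `exp(-d^n / r)`.
#' @param dn,dm Embedding window dimensions (rows, columns) for the
#'   permutation and dispersion entropies.
#' @param c Number of dispersion classes.
#' @param M Number of histogram bins for the distribution entropy.
#' @param normalized Return permutation, dispersion and distribution
#'   entropies normalized to `[0, 1]` (by `ln((dn*dm)!)`, `ln(c^(dn*dm))`
#'   and `log2(M)` respectively)?
#' @param window_prefactor Use the alternative normalization that divides
#'   the raw Shannon sum of the permutation and dispersion entropies by the
#'   number of embedding windows instead of the log pattern count. Both
#'   conventions circulate in the literature; the pattern-count
#'   normalization is the default because it keeps the measures in
#'   `[0, 1]`.
#' @param fuzzy_center Remove each window's mean (local baseline) before
#'   computing fuzzy similarities? This is the original two-dimensional
#'   fuzzy-entropy formulation.
#'
#' @return An object of class `entropy_params`.
#' @examples
#' entropy_params()
#' entropy_params(m = 1, r = 0.5, r_is_fraction = FALSE)
#' @export
entropy_params <- function(m = 2, r = 0.2, r_is_fraction = TRUE, n = 2,
                           dn = 2, dm = 2, c = 3, M = 512,
                           normalized = TRUE, window_prefactor = FALSE,
                           fuzzy_center = TRUE) {
  if (m < 1) stop_equitherm("m must be >= 1", "equitherm_error_parameter")
  if (r < 0) stop_equitherm("r must be >= 0", "equitherm_error_parameter")
  if (n <= 0) stop_equitherm("n must be > 0", "equitherm_error_parameter")
  if (dn * dm < 2) {
    stop_equitherm("embedding window must have at least 2 cells",
                   "equitherm_error_parameter")
  }
  if (c < 2) stop_equitherm("c must be >= 2", "equitherm_error_parameter")
  if (M < 2) stop_equitherm("M must be >= 2", "equitherm_error_parameter")
  structure(
    list(m = as.integer(m), r = r, r_is_fraction = isTRUE(r_is_fraction),
         n = n, dn = as.integer(dn), dm = as.integer(dm),
         c = as.integer(c), M = as.integer(M),
         normalized = isTRUE(normalized),
         window_prefactor = isTRUE(window_prefactor),
         fuzzy_center = isTRUE(fuzzy_center)),
    class = "entropy_params"
  )
}

#' @export
print.entropy_params <- function(x, ...) {
  cat("Bidimensional entropy parameters\n")
  cat(sprintf("  m = %d, r = %g%s, n = %g\n", x$m, x$r,
              if (x$r_is_fraction) " (fraction of patch SD)" else "", x$n))
  cat(sprintf("  embedding %d x %d, c = %d classes, M = %d bins\n",
              x$dn, x$dm, x$c, x$M))
  cat(sprintf("  normalized = %s, window_prefactor = %s, fuzzy_center = %s\n",
              x$normalized, x$window_prefactor, x$fuzzy_center))
  invisible(x)
}

# resolve the tolerance actually used on a patch
resolve_r <- function(patch, params) {
  if (params$r_is_fraction) params$r * stats::sd(patch) else params$r
}

validate_patch <- function(patch) {
  if (!is.matrix(patch) || !is.numeric(patch)) {
    stop_equitherm("patch must be a numeric matrix", "equitherm_error_dimension")
  }
  if (any(!is.finite(patch))) {
    stop_equitherm("patch contains non-finite values", "equitherm_error_dimension")
  }
  storage.mode(patch) <- "double"
  patch
}

# dense stride-1 windows of size dn x dm, one row per window, flattened
# row-major within the window (row 1 left-to-right, then row 2, ...)
window_matrix <- function(x, dn, dm) {
  H <- nrow(x); W <- ncol(x)
  ah <- H - dn + 1L; aw <- W - dm + 1L
  if (ah < 1L || aw < 1L) {
    stop_equitherm("patch too small for the requested window size",
                   "equitherm_error_dimension")
  }
  base <- rep(seq_len(ah), times = aw) + (rep(seq_len(aw), each = ah) - 1L) * H
  out <- matrix(0, ah * aw, dn * dm)
  for (a in 0:(dn - 1L)) {
    for (b in 0:(dm - 1L)) {
      out[, a * dm + b + 1L] <- x[base + a + b * H]
    }
  }
  out
}
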