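#' Gray level co-occurrence matrix
#'
#' Builds the co-occurrence probability matrix of a quantized intensity
#' patch over one or more pixel offsets, together with its diagonal
#' (`p_{x+y}`) and antidiagonal (`p_{x-y}`) marginals. Defaults follow the
#' conventional texture-analysis settings: 64 gray levels by uniform
#' binning of `[0, 255]`, the four distance-1 directions (0, 45, 90 and
#' 135 degrees), symmetric accumulation, and averaging of the per-direction
#' normalized matrices.
#'
#' @param patch Numeric matrix of intensities in `[0, 255]` (or already
#'   quantized levels, see `quantize`).
#' @param levels Number of gray levels `L`.
#' @param offsets List of integer `c(row, col)` pixel offsets. The defaults
#'   are the four standard directions at distance 1.
#' @param symmetric Accumulate each pair in both orders?
#' @param quantize `"range256"` bins `[0, 255]` uniformly into `levels`
#'   bins; `"none"` treats the patch values as zero-based levels
#'   `0 .. levels-1` directly (the scikit-image convention).
#' @return An object of class `glcm`: list with the `L x L` probability
#'   matrix `P` (entries sum to 1), marginals `p_sum` (indices `2 .. 2L`)
#'   and `p_diff` (indices `0 .. L-1`), plus the settings used.
#' @examples
#' g <- glcm(matrix(c(0, 255, 0, 255), 2, 2), levels = 2)
#' sum(g$P)
#' @export
glcm <- function(patch, levels = 64,
                 offsets = list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L)),
                 symmetric = TRUE, quantize = c("range256", "none")) {
  quantize <- match.arg(quantize)
  if (!is.matrix(patch) || length(patch) == 0) {
    stop_equitherm("patch must be a non-empty numeric matrix",
                   "equitherm_error_dimension")
  }
  L <- as.integer(levels)
  q <- if (quantize == "range256") {
    if (min(patch) < 0 || max(patch) > 255) {
      stop_equitherm("patch values must lie in [0, 255] for range256 quantization",
                     "equitherm_error_parameter")
    }
    pmin(floor(patch * L / 256) + 1L, L)
  } else {
    if (min(patch) < 0 || max(patch) > L - 1 || any(patch != floor(patch))) {
      stop_equitherm("with quantize = 'none' values must be integers in [0, levels)",
                     "equitherm_error_parameter")
    }
    patch + 1L
  }
  H <- nrow(q); W <- ncol(q)
  acc <- matrix(0, L, L)
  n_used <- 0L
  for (off in offsets) {
    dr <- off[1]; dc <- off[2]
    ri <- seq_len(H)[seq_len(H) + dr >= 1 & seq_len(H) + dr <= H]
    ci <- seq_len(W)[seq_len(W) + dc >= 1 & seq_len(W) + dc <= W]
    if (length(ri) == 0 || length(ci) == 0) next
    from <- q[ri, ci, drop = FALSE]
    to <- q[ri + dr, ci + dc, drop = FALSE]
    counts <- tabulate(as.vector(from) + (as.vector(to) - 1L) * L, nbins = L * L)
    Pd <- matrix(counts, L, L)
    if (symmetric) Pd <- Pd + t(Pd)
    tot <- sum(Pd)
    if (tot == 0) next
    acc <- acc + Pd / tot
    n_used <- n_used + 1L
  }
  if (n_used == 0L) {
    stop_equitherm("no valid pixel pairs for the given offsets",
                   "equitherm_error_dimension")
  }
  P <- acc / n_used
  # marginals over the diagonal sum i+j and absolute difference |i-j|
  s <- row(P) + col(P)
  d <- abs(row(P) - col(P))
  p_sum <- vapply(2:(2 * L), function(k) sum(P[s == k]), 0)
  p_diff <- vapply(0:(L - 1), function(k) sum(P[d == k]), 0)
  structure(
    list(P = P, levels = L, offsets = offsets, symmetric = symmetric,
         p_sum = stats::setNames(p_sum, 2:(2 * L)),
         p_diff = stats::setNames(p_diff, 0:(L - 1))),
    class = "glcm"
  )
}

#' Entropy-related GLCM texture features
#'
#' The three entropy-type Haralick features of a co-occurrence matrix,
#' in natural log units with the convention `0 * ln 0 = 0`:
#' `Entropy = -sum P(i,j) ln P(i,j)`,
#' `SumEntrp = -sum p_{x+y}(k) ln p_{x+y}(k)` and
#' `DifEntrp = -sum p_{x-y}(k) ln p_{x-y}(k)`.
#'
#' @param C A [glcm()] object.
#' @return Named numeric vector `c(SumEntrp, Entropy, DifEntrp)`.
#' @export
entropy_features <- function(C) {
  if (!inherits(C, "glcm")) {
    stop_equitherm("C must be a glcm object", "equitherm_error_parameter")
  }
  plogp <- function(p) {
    p <- p[p > 0]
    -sum(p * log(p))
  }
  c(SumEntrp = plogp(C$p_sum), Entropy = plogp(C$P), DifEntrp = plogp(C$p_diff))
}

#' @export
print.glcm <- function(x, ...) {
  cat(sprintf("GLCM: %d levels, %d offset(s), symmetric = %s\n",
              x$levels, length(x$offsets), x$symmetric))
  cat(sprintf("  nonzero cells: %d, sum = %.6f\n", sum(x$P > 0), sum(x$P)))
  invisible(x)
}
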