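# Exhaustive-enumeration reference implementations of the five
# bidimensional entropy measures. These are deliberately naive (explicit
# loops over windows and window pairs, no shared code with the fast path)
# and exist so the optimized implementations can be checked against an
# independent route on small patches. They are exported for verification
# use but are far too slow for production extraction.

#' Brute-force reference implementations of the entropy measures
#'
#' `sampen2d_ref()`, `fuzzen2d_ref()`, `permen2d_ref()`, `dispen2d_ref()`
#' and `disten2d_ref()` recompute each measure by explicit enumeration of
#' every window (pair). They follow the same documented semantics as the
#' fast implementations -- shared top-aligned anchors for the sample/fuzzy
#' stages, row-major window flattening with positional tie-break for the
#' ordinal patterns, half-up class rounding for the dispersion mapping,
#' `(0, d_max]` equal bins for the distance histogram -- but share no code
#' with them.
#'
#' @inheritParams sampen2d
#' @return The entropy value (numeric scalar).
#' @name entropy2d_reference
NULL

#' @rdname entropy2d_reference
#' @export
sampen2d_ref <- function(patch, params = entropy_params()) {
  m <- params$m
  r <- if (params$r_is_fraction) params$r * stats::sd(patch) else params$r
  H <- nrow(patch); W <- ncol(patch)
  anchors <- expand.grid(i = seq_len(H - m), j = seq_len(W - m))
  nw <- nrow(anchors)
  cm <- 0; cm1 <- 0
  for (p in seq_len(nw)) {
    for (q in seq_len(nw)) {
      if (p == q) next
      ip <- anchors$i[p]; jp <- anchors$j[p]
      iq <- anchors$i[q]; jq <- anchors$j[q]
      wm_p <- patch[ip:(ip + m - 1), jp:(jp + m - 1)]
      wm_q <- patch[iq:(iq + m - 1), jq:(jq + m - 1)]
      if (max(abs(wm_p - wm_q)) <= r) {
        cm <- cm + 1
        w1_p <- patch[ip:(ip + m), jp:(jp + m)]
        w1_q <- patch[iq:(iq + m), jq:(jq + m)]
        if (max(abs(w1_p - w1_q)) <= r) cm1 <- cm1 + 1
      }
    }
  }
  if (cm == 0 || cm1 == 0) {
    stop_equitherm("reference sample entropy undefined",
                   "equitherm_error_undefined_entropy")
  }
  -log(cm1 / cm)
}

#' @rdname entropy2d_reference
#' @export
fuzzen2d_ref <- function(patch, params = entropy_params()) {
  m <- params$m
  r <- if (params$r_is_fraction) params$r * stats::sd(patch) else params$r
  H <- nrow(patch); W <- ncol(patch)
  anchors <- expand.grid(i = seq_len(H - m), j = seq_len(W - m))
  nw <- nrow(anchors)
  win <- function(i, j, size) {
    w <- patch[i:(i + size - 1), j:(j + size - 1)]
    if (params$fuzzy_center) w - mean(w) else w
  }
  sm <- 0; sm1 <- 0
  for (p in seq_len(nw)) {
    for (q in seq_len(nw)) {
      if (p == q) next
      dm_ <- max(abs(win(anchors$i[p], anchors$j[p], m) -
                     win(anchors$i[q], anchors$j[q], m)))
      dm1 <- max(abs(win(anchors$i[p], anchors$j[p], m + 1) -
                     win(anchors$i[q], anchors$j[q], m + 1)))
      sm <- sm + exp(-dm_^params$n / r)
      sm1 <- sm1 + exp(-dm1^params$n / r)
    }
  }
  -log(sm1 / sm)
}

# stable ranks computed from first principles: rank of element i is the
# number of strictly smaller elements plus the number of equal elements
# appearing earlier, plus one
stable_ranks <- function(w) {
  k <- length(w)
  out <- integer(k)
  for (i in seq_len(k)) {
    earlier_equal <- if (i > 1) sum(w[seq_len(i - 1)] == w[i]) else 0
    out[i] <- sum(w < w[i]) + earlier_equal + 1
  }
  out
}

#' @rdname entropy2d_reference
#' @export
permen2d_ref <- function(patch, params = entropy_params()) {
  dn <- params$dn; dm <- params$dm
  H <- nrow(patch); W <- ncol(patch)
  pats <- character(0)
  for (i in seq_len(H - dn + 1)) {
    for (j in seq_len(W - dm + 1)) {
      w <- as.vector(t(patch[i:(i + dn - 1), j:(j + dm - 1)]))  # row-major
      pats <- c(pats, paste(stable_ranks(w), collapse = "-"))
    }
  }
  p <- as.vector(table(pats)) / length(pats)
  raw <- -sum(p * log(p))
  if (params$window_prefactor) return(raw / length(pats))
  if (params$normalized) raw / lfactorial(dn * dm) else raw
}

#' @rdname entropy2d_reference
#' @export
dispen2d_ref <- function(patch, params = entropy_params()) {
  mu <- mean(patch); sigma <- stats::sd(patch)
  cc <- params$c
  if (sigma == 0) return(0)
  dn <- params$dn; dm <- params$dm
  H <- nrow(patch); W <- ncol(patch)
  zmap <- function(x) {
    v <- stats::pnorm((x - mu) / sigma)
    min(max(floor(cc * v + 1), 1), cc)
  }
  pats <- character(0)
  for (i in seq_len(H - dn + 1)) {
    for (j in seq_len(W - dm + 1)) {
      w <- as.vector(t(patch[i:(i + dn - 1), j:(j + dm - 1)]))
      pats <- c(pats, paste(vapply(w, zmap, 0), collapse = "-"))
    }
  }
  p <- as.vector(table(pats)) / length(pats)
  raw <- -sum(p * log(p))
  if (params$window_prefactor) return(raw / length(pats))
  if (params$normalized) raw / (dn * dm * log(cc)) else raw
}

#' @rdname entropy2d_reference
#' @export
disten2d_ref <- function(patch, params = entropy_params()) {
  m <- params$m; M <- params$M
  H <- nrow(patch); W <- ncol(patch)
  wins <- list()
  for (i in seq_len(H - m + 1)) {
    for (j in seq_len(W - m + 1)) {
      wins[[length(wins) + 1]] <- patch[i:(i + m - 1), j:(j + m - 1)]
    }
  }
  nw <- length(wins)
  d <- numeric(0)
  for (p in seq_len(nw - 1)) {
    for (q in (p + 1):nw) {
      d <- c(d, max(abs(wins[[p]] - wins[[q]])))
    }
  }
  dmax <- max(d)
  if (dmax == 0) return(0)
  bins <- ifelse(d == 0, 1L, pmin(pmax(ceiling(d / dmax * M), 1L), M))
  p <- as.vector(table(bins)) / length(bins)
  raw <- -sum(p * log2(p))
  if (params$normalized) raw / log2(M) else raw
}
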