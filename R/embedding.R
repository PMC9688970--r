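#' Embedding configuration for the multivariate entropy measures
#'
#' Collects every parameter of the entropy kernels: per-channel embedding
#' (patch) sizes, match tolerance, fuzzy power and frequency-normalization
#' mode.
#'
#' @param M Integer vector of per-channel patch sizes `[m_1, ..., m_q]`,
#'   all `>= 1`; channel `k` contributes an `m_k x m_k` patch to each
#'   composite delay vector.  `n = max(M)` sets the shared anchor grid.
#' @param r Tolerance `> 0`, in absolute intensity units: a hard match
#'   threshold for sample entropy, the similarity scale for fuzzy entropy.
#'   Images normalized to sigma = 1 make `r` effectively relative; the
#'   kernels neither check nor enforce normalization.
#' @param s Fuzzy power `> 0` shaping the similarity fall-off
#'   `exp(-d^s / r)`; required by the fuzzy measure only.
#' @param normalization `"consistent"` (default) divides match counts by
#'   the actual number of comparison vectors minus the self-match
#'   (`N_m - 1` at dimension m, `q * N_m - 1` at the extended dimension);
#'   `"literal"` uses the constants printed in the defining equations
#'   (`N_m - n - 1` and `q * (N_m - n) - 1`), carried over from the 1D
#'   notation.  The two differ by a constant offset `ln(c)` in the
#'   entropy.
#' @return A list of class `embedding_config` with derived field
#'   `n = max(M)`.
#' @export
embedding_config <- function(M, r, s = NULL,
                             normalization = c("consistent", "literal")) {
  M <- as.integer(M)
  if (length(M) < 1L || any(is.na(M)) || any(M < 1L)) {
    stop("`M` must be a vector of positive integer patch sizes", call. = FALSE)
  }
  if (!is.numeric(r) || length(r) != 1L || is.na(r) || r <= 0) {
    stop("`r` must be a single positive tolerance", call. = FALSE)
  }
  if (!is.null(s)) {
    if (!is.numeric(s) || length(s) != 1L || is.na(s) || s <= 0) {
      stop("`s` must be a single positive fuzzy power", call. = FALSE)
    }
  }
  structure(list(M = M, r = r, s = s, n = max(M),
                 normalization = match.arg(normalization)),
            class = "embedding_config")
}

#' @export
print.embedding_config <- function(x, ...) {
  cat(sprintf("<embedding_config M=[%s] r=%g%s n=%d, %s normalization>\n",
              paste(x$M, collapse = ","), x$r,
              if (is.null(x$s)) "" else sprintf(" s=%g", x$s),
              x$n, x$normalization))
  invisible(x)
}

# Delay-vector matrix: one composite vector per ROW, built on the anchor
# grid of margin `n` (rows 1..H-n, cols 1..W-n of the image, anchor row
# varying fastest).  Element order follows the defining enumeration: for
# each channel in order, the patch is read out row-wise (column offset
# varying fastest), channels concatenated.  `M` may exceed nothing: each
# m_k must satisfy m_k <= n + 1 so the patch fits on the common grid.
delay_matrix <- function(a, M, n) {
  d <- dim(a)
  h <- d[1L]; w <- d[2L]; q <- d[3L]
  if (length(M) != q) stop("length(M) must equal the channel count", call. = FALSE)
  if (max(M) > n + 1L) stop("patch size exceeds anchor-grid margin", call. = FALSE)
  nh <- h - n; nw <- w - n
  if (nh < 1L || nw < 1L) stop("image too small for this embedding", call. = FALSE)
  cols <- vector("list", sum(M^2))
  t <- 0L
  for (k in seq_len(q)) {
    mk <- M[k]
    for (dr in 0:(mk - 1L)) {      # row offset (slow, per the enumeration)
      for (dc in 0:(mk - 1L)) {    # column offset (fast)
        t <- t + 1L
        cols[[t]] <- as.vector(a[(1L + dr):(nh + dr), (1L + dc):(nw + dc), k])
      }
    }
  }
  do.call(cbind, cols)
}

#' Build the composite delay vectors of an image
#'
#' Forms the `N_m = (W - n) * (H - n)` composite delay vectors of a
#' multichannel image, where `n = max(M)`.  The vector anchored at pixel
#' `(i, j)` concatenates, channel by channel, the `m_k x m_k` patch of
#' channel `k` whose top-left corner is `(i, j)`, read out row-wise, so
#' each channel contributes `m_k^2` elements and the total length is
#' `m = sum(M^2)`.
#'
#' @param img An [mcimage] (or coercible array).
#' @param cfg An [embedding_config()]; `length(cfg$M)` must equal the
#'   channel count.
#' @return An `N_m x m` numeric matrix, one composite vector per row.
#'   Attribute `"anchors"` holds the 0-based `(row, col)` anchor of each
#'   vector, in row order of the matrix.
#' @examples
#' img <- mcimage(matrix(1:9, 3, 3, byrow = TRUE))
#' v <- build_composite_delay_vectors(img, embedding_config(M = 2, r = 1))
#' v[1, ]  # patch at (0,0): 1 2 4 5
#' @export
build_composite_delay_vectors <- function(img, cfg) {
  img <- as_mcimage(img)
  a <- pixel_array(img)
  d <- dim(a)
  if (length(cfg$M) != d[3L]) {
    stop(sprintf("length(M) = %d but image has %d channel(s)",
                 length(cfg$M), d[3L]), call. = FALSE)
  }
  n <- cfg$n
  if (d[1L] - n < 1L || d[2L] - n < 1L) {
    stop(sprintf(
      "image %dx%d too small for n = %d: no anchor fits",
      d[1L], d[2L], n), call. = FALSE)
  }
  v <- delay_matrix(a, cfg$M, n)
  nh <- d[1L] - n; nw <- d[2L] - n
  attr(v, "anchors") <- cbind(row = rep(0:(nh - 1L), times = nw),
                              col = rep(0:(nw - 1L), each = nh))
  v
}

#' Chebyshev (maximum-norm) distance between two composite vectors
#'
#' The largest absolute element-wise difference, pooled over all elements
#' (all channels) of the composite vectors.
#'
#' @param u,v Numeric vectors of equal length.
#' @return A single non-negative number.
#' @export
chebyshev_distance <- function(u, v) {
  if (length(u) != length(v)) {
    stop("vectors must have equal length", call. = FALSE)
  }
  max(abs(u - v))
}
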