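# Deliberately naive reference implementations of the two entropy measures,
# written as literal loops over anchors, pairs and vector elements, sharing
# no code with the optimized kernels.  They exist to verify the optimized
# path and are O(N_m^2 * m) in plain R: use them on small images only.

# All composite delay vectors of `a` with per-channel patch size vector mm,
# on the anchor grid of margin n, as a list (anchor column varying fastest,
# then anchor row -- order is irrelevant to the measures).
brute_vectors <- function(a, mm, n) {
  h <- dim(a)[1L]; w <- dim(a)[2L]; q <- dim(a)[3L]
  out <- list()
  for (ar in 1:(h - n)) {
    for (ac in 1:(w - n)) {
      v <- numeric(0)
      for (k in 1:q) {
        for (dr in 0:(mm[k] - 1L)) {
          for (dc in 0:(mm[k] - 1L)) {
            v <- c(v, a[ar + dr, ac + dc, k])
          }
        }
      }
      out[[length(out) + 1L]] <- v
    }
  }
  out
}

brute_dist <- function(u, v) {
  dmax <- 0
  for (e in seq_along(u)) {
    d <- abs(u[e] - v[e])
    if (d > dmax) dmax <- d
  }
  dmax
}

# Shared skeleton: per-vector statistic at both dimensions, averaged.
# `stat` maps a distance to a contribution (0/1 match or fuzzy similarity).
brute_entropy <- function(img, M, r, stat, normalization) {
  img <- as_mcimage(img)
  a <- pixel_array(img)
  q <- dim(a)[3L]
  M <- as.integer(M)
  stopifnot(length(M) == q, all(M == M[1L]))
  n <- max(M)
  nm <- (dim(a)[1L] - n) * (dim(a)[2L] - n)
  if (nm < 2L) stop("image too small", call. = FALSE)

  if (normalization == "consistent") {
    den_b <- nm - 1
    den_e <- q * nm - 1
    out_b <- nm
    out_e <- q * nm
  } else {
    den_b <- nm - n - 1
    den_e <- q * (nm - n) - 1
    out_b <- nm - n
    out_e <- q * (nm - n)
  }

  vb <- brute_vectors(a, M, n)
  bsum <- 0
  for (i in seq_along(vb)) {
    ci <- 0
    for (j in seq_along(vb)) {
      if (i == j) next
      ci <- ci + stat(brute_dist(vb[[i]], vb[[j]]), r)
    }
    bsum <- bsum + ci / den_b
  }
  b_m <- bsum / out_b

  ve <- list()
  for (k in 1:q) {
    mk <- M
    mk[k] <- mk[k] + 1L
    ve <- c(ve, brute_vectors(a, mk, n))
  }
  esum <- 0
  for (i in seq_along(ve)) {
    ci <- 0
    for (j in seq_along(ve)) {
      if (i == j) next
      ci <- ci + stat(brute_dist(ve[[i]], ve[[j]]), r)
    }
    esum <- esum + ci / den_e
  }
  b_m1 <- esum / out_e

  list(b_m = b_m, b_m1 = b_m1, nm = nm)
}

#' Brute-force reference implementations of the entropy measures
#'
#' Literal triple-loop implementations (anchors, pairs, vector elements)
#' of multivariate sample and fuzzy entropy, kept deliberately independent
#' of the optimized kernels so they can serve as a verification oracle.
#' Quadratic in the number of delay vectors and written in plain R: only
#' suitable for small images.
#'
#' @param img An [mcimage] (or coercible array).
#' @param M Per-channel patch sizes (all equal).
#' @param r Tolerance.
#' @param s Fuzzy power (fuzzy variant only).
#' @param normalization `"consistent"` or `"literal"`; see
#'   [embedding_config()].
#' @return A list with `value`, `b_m`, `b_m1` and `defined`.
#' @seealso [msampen_rgb()], [mfuzen_rgb()]
#' @export
msampen_rgb_brute <- function(img, M, r, normalization = "consistent") {
  b <- brute_entropy(img, M, r, function(d, r) as.numeric(d <= r), normalization)
  defined <- b$b_m > 0 && b$b_m1 > 0
  list(value = if (defined) -log(b$b_m1 / b$b_m) else NA_real_,
       b_m = b$b_m, b_m1 = b$b_m1, defined = defined)
}

#' @rdname msampen_rgb_brute
#' @export
mfuzen_rgb_brute <- function(img, M, r, s, normalization = "consistent") {
  b <- brute_entropy(img, M, r, function(d, r) exp(-(d^s) / r), normalization)
  defined <- b$b_m > 0 && b$b_m1 > 0
  list(value = if (defined) -log(b$b_m1 / b$b_m) else NA_real_,
       b_m = b$b_m, b_m1 = b$b_m1, defined = defined)
}
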