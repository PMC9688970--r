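# Independently coded bi-dimensional (univariate, grayscale) entropy
# references: square patches of size m and m+1 anchored on the common
# (H-m) x (W-m) grid, Chebyshev matching with self-matches excluded,
# frequencies averaged over vectors.  Used to check the q = 1 reduction of
# the multivariate kernels; deliberately built from full distance matrices
# rather than pair loops.

patch_rows <- function(x, m, n) {
  h <- nrow(x); w <- ncol(x)
  anchors <- expand.grid(ar = 1:(h - n), ac = 1:(w - n))
  t(mapply(function(ar, ac) as.vector(x[ar:(ar + m - 1L), ac:(ac + m - 1L)]),
           anchors$ar, anchors$ac))
}

cheb_mat <- function(P) {
  N <- nrow(P)
  D <- matrix(0, N, N)
  for (i in seq_len(N)) {
    D[i, ] <- apply(abs(sweep(P, 2L, P[i, ], `-`)), 1L, max)
  }
  D
}

sampen2d_ref <- function(x, m, r) {
  Dm <- cheb_mat(patch_rows(x, m, m)); diag(Dm) <- Inf
  De <- cheb_mat(patch_rows(x, m + 1L, m)); diag(De) <- Inf
  b <- mean(rowSums(Dm <= r) / (nrow(Dm) - 1L))
  a <- mean(rowSums(De <= r) / (nrow(De) - 1L))
  defined <- a > 0 && b > 0
  list(value = if (defined) -log(a / b) else NA_real_,
       b_m = b, b_m1 = a, defined = defined)
}

fuzen2d_ref <- function(x, m, r, s) {
  Dm <- cheb_mat(patch_rows(x, m, m)); diag(Dm) <- NA
  De <- cheb_mat(patch_rows(x, m + 1L, m)); diag(De) <- NA
  b <- mean(rowMeans(exp(-(Dm^s) / r), na.rm = TRUE))
  a <- mean(rowMeans(exp(-(De^s) / r), na.rm = TRUE))
  list(value = -log(a / b), b_m = b, b_m1 = a, defined = TRUE)
}
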