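# Entropy kernels: multivariate sample and fuzzy entropy for multichannel
# images.  The heavy pair loops live in src/entropy_kernels.cpp; this file
# builds the delay-vector matrices, applies the frequency normalization and
# packages results.

entropy_result <- function(value, b_m, b_m1, n_vectors, defined, method, cfg) {
  structure(list(value = value, b_m = b_m, b_m1 = b_m1,
                 n_vectors = n_vectors, defined = defined,
                 method = method, cfg = cfg),
            class = "entropy_result")
}

#' @export
print.entropy_result <- function(x, ...) {
  cat(sprintf("<%s M=[%s] r=%g%s> ", x$method,
              paste(x$cfg$M, collapse = ","), x$cfg$r,
              if (is.null(x$cfg$s)) "" else sprintf(" s=%g", x$cfg$s)))
  if (x$defined) {
    cat(sprintf("value = %.6f  (b_m = %.6g, b_m1 = %.6g, N_m = %d)\n",
                x$value, x$b_m, x$b_m1, x$n_vectors))
  } else {
    cat("undefined (no matches at one of the two dimensions)\n")
  }
  invisible(x)
}

# Validates the configuration against the image, builds the base (dim m)
# and extended (dim m+1) delay-vector matrices transposed for the C++
# kernels (vectors as columns), and returns the bookkeeping counts.
entropy_setup <- function(img, cfg) {
  stopifnot(inherits(cfg, "embedding_config"))
  img <- as_mcimage(img)
  a <- pixel_array(img)
  d <- dim(a)
  q <- d[3L]
  if (length(cfg$M) != q) {
    stop(sprintf("length(M) = %d but image has %d channel(s)",
                 length(cfg$M), q), call. = FALSE)
  }
  if (!all(cfg$M == cfg$M[1L])) {
    stop(paste0(
      "the entropy kernels require equal per-channel embedding sizes ",
      "(M = [c,...,c]): extending different channels otherwise yields ",
      "composite vectors of different lengths, between which the pooled ",
      "Chebyshev distance is undefined"), call. = FALSE)
  }
  n <- cfg$n
  if (d[1L] - n < 2L || d[2L] - n < 2L) {
    stop(sprintf("image %dx%d too small for n = %d: need W - n >= 2 and H - n >= 2",
                 d[2L], d[1L], n), call. = FALSE)
  }
  nm <- (d[1L] - n) * (d[2L] - n)
  if (cfg$normalization == "literal" &&
      (nm - n - 1 <= 0 || q * (nm - n) - 1 <= 0)) {
    stop("image too small for the literal normalization constants", call. = FALSE)
  }
  base <- t(delay_matrix(a, cfg$M, n))
  # Extended dimension: channel k's patch enlarged from m_k to m_k + 1 on
  # the same anchor grid (the enlarged patch always fits: anchors reach at
  # most W - n - 1, and the patch spans m_k <= n further pixels).  All
  # q * N_m extended vectors are pooled.
  ext <- vector("list", q)
  for (k in seq_len(q)) {
    mk <- cfg$M
    mk[k] <- mk[k] + 1L
    ext[[k]] <- t(delay_matrix(a, mk, n))
  }
  ext <- do.call(cbind, ext)
  # Pair totals are permutation-invariant; sorting the vectors by first
  # element lets the C++ kernels prune the pair loop.
  base <- base[, order(base[1L, ]), drop = FALSE]
  ext <- ext[, order(ext[1L, ]), drop = FALSE]
  list(base = base, ext = ext, q = q, n = n, nm = nm)
}

# Denominators for turning pair totals into mean frequencies of occurrence.
# Each total is a sum over ordered pairs; dividing by (#vectors x
# per-vector denominator) yields the mean per-vector frequency.
norm_denoms <- function(nm, n, q, normalization) {
  if (normalization == "consistent") {
    list(base = nm * (nm - 1), ext = (q * nm) * (q * nm - 1))
  } else {
    list(base = (nm - n) * (nm - n - 1),
         ext = (q * (nm - n)) * (q * (nm - n) - 1))
  }
}

#' Multivariate sample entropy of a multichannel image
#'
#' The negative log conditional probability that two pixel neighborhoods
#' that match within tolerance `r` at embedding dimension `m` (composite
#' patches of all channels) still match when any one channel's patch is
#' enlarged by one.  Matching uses the Chebyshev distance over composite
#' delay vectors; self-matches are excluded.  Higher values mean a more
#' irregular texture.
#'
#' When no pair matches at either dimension the estimate is undefined;
#' this is reported through `defined = FALSE` (never an error), so
#' multiscale profiles can record gaps.
#'
#' @param img An [mcimage] (or coercible array); for the measures to be
#'   comparable across images it should be normalized (see
#'   [normalize_image()]), but the kernel itself runs on the values as
#'   given.
#' @param cfg An [embedding_config()] (the fuzzy power `s` is ignored
#'   here).  All entries of `cfg$M` must be equal.
#' @return An `entropy_result`: fields `value` (`-log(b_m1 / b_m)`, or
#'   `NA` when undefined), `b_m`, `b_m1` (mean frequencies of occurrence
#'   at the two dimensions), `n_vectors` (`N_m`), `defined`.
#' @examples
#' img <- generate_mix2d(mix_params(p = 0.5, shape = c(30, 30), q = 3, seed = 1))
#' msampen_rgb(img, embedding_config(M = c(2, 2, 2), r = 0.5))
#' @seealso [mfuzen_rgb()], [msampen_rgb_brute()] (reference
#'   implementation), [multiscale_profile()]
#' @export
msampen_rgb <- function(img, cfg) {
  st <- entropy_setup(img, cfg)
  den <- norm_denoms(st$nm, st$n, st$q, cfg$normalization)
  p_total <- pair_match_total(st$base, cfg$r)
  q_total <- pair_match_total(st$ext, cfg$r)
  b_m <- p_total / den$base
  b_m1 <- q_total / den$ext
  defined <- p_total > 0 && q_total > 0
  entropy_result(value = if (defined) -log(b_m1 / b_m) else NA_real_,
                 b_m = b_m, b_m1 = b_m1, n_vectors = st$nm,
                 defined = defined, method = "msampen", cfg = cfg)
}

#' Multivariate fuzzy entropy of a multichannel image
#'
#' Replaces the hard match threshold of [msampen_rgb()] with the graded
#' similarity `exp(-d^s / r)` (`d` the Chebyshev distance, `s` the fuzzy
#' power), averaged over all ordered non-self pairs at both embedding
#' dimensions; the entropy is `-log` of the ratio of the two mean
#' similarities.  Because every pair contributes a positive similarity,
#' the fuzzy measure is defined for any valid input.
#'
#' @inheritParams msampen_rgb
#' @param cfg An [embedding_config()] with the fuzzy power `s` set.
#' @return An `entropy_result` (see [msampen_rgb()]); `b_m`/`b_m1` hold
#'   the mean similarity degrees.
#' @examples
#' img <- generate_mix2d(mix_params(p = 0.5, shape = c(30, 30), q = 3, seed = 1))
#' mfuzen_rgb(img, embedding_config(M = c(2, 2, 2), r = 0.15, s = 2))
#' @export
mfuzen_rgb <- function(img, cfg) {
  if (is.null(cfg$s)) {
    stop("fuzzy entropy requires the fuzzy power `s` in the embedding config",
         call. = FALSE)
  }
  st <- entropy_setup(img, cfg)
  den <- norm_denoms(st$nm, st$n, st$q, cfg$normalization)
  s_total <- pair_similarity_total(st$base, cfg$r, cfg$s)
  t_total <- pair_similarity_total(st$ext, cfg$r, cfg$s)
  phi_m <- s_total / den$base
  phi_m1 <- t_total / den$ext
  defined <- s_total > 0 && t_total > 0
  entropy_result(value = if (defined) -log(phi_m1 / phi_m) else NA_real_,
                 b_m = phi_m, b_m1 = phi_m1, n_vectors = st$nm,
                 defined = defined, method = "mfuzen", cfg = cfg)
}
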