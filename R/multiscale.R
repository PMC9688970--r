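#' Coarse-grain an image at scale factor tau
#'
#' Each channel is partitioned into non-overlapping `tau x tau` blocks
#' starting at the top-left corner and each block is replaced by its mean
#' (the bi-dimensional analogue of the classic 1D coarse-graining used in
#' multiscale entropy).  Trailing rows/columns that do not fill a block
#' are discarded; no padding is applied, as padding would inject
#' artificial regularity.
#'
#' @param img An [mcimage] (or coercible array).
#' @param tau Scale factor `>= 1`.
#' @return An [mcimage] of dimension `floor(H/tau) x floor(W/tau) x q`.
#' @examples
#' coarse_grain(mcimage(matrix(1:16, 4, 4, byrow = TRUE)), 2)
#' @export
coarse_grain <- function(img, tau) {
  img <- as_mcimage(img)
  tau <- as.integer(tau)
  if (length(tau) != 1L || is.na(tau) || tau < 1L) {
    stop("`tau` must be a positive integer", call. = FALSE)
  }
  a <- pixel_array(img)
  d <- dim(a)
  hc <- d[1L] %/% tau
  wc <- d[2L] %/% tau
  if (hc < 1L || wc < 1L) {
    stop(sprintf("tau = %d exceeds image size %dx%d", tau, d[1L], d[2L]),
         call. = FALSE)
  }
  if (tau == 1L) return(img)
  out <- array(0, dim = c(hc, wc, d[3L]))
  for (k in seq_len(d[3L])) {
    blk <- array(a[seq_len(hc * tau), seq_len(wc * tau), k],
                 dim = c(tau, hc, tau, wc))
    out[, , k] <- apply(blk, c(2L, 4L), mean)
  }
  mcimage(out, channel_names = attr(img, "channel_names"),
          provenance = attr(img, "provenance"))
}

#' Multiscale entropy profile of an image
#'
#' Evaluates an entropy measure on coarse-grained versions of the image at
#' scale factors `tau = 1..tau_max`.  The resulting ordered vector of
#' entropies is the texture feature vector used for classification.  The
#' tolerance `r` is held fixed across scales (no per-scale
#' re-normalization), the standard multiscale-entropy convention: the
#' variance reduction of coarse-graining is precisely what makes the
#' entropy of uncorrelated noise fall with `tau`.
#'
#' Scales at which the entropy is undefined (no matches) or the
#' coarse-grained image is too small for the embedding are recorded as
#' `NA` with `defined = FALSE` and a reason — they are flagged, never
#' dropped.
#'
#' @param img An [mcimage] (or coercible array).
#' @param cfg An [embedding_config()].
#' @param method `"msampen"` or `"mfuzen"`.
#' @param tau_max Largest scale factor (the profile has `tau_max` entries).
#' @return A `multiscale_profile`: list with `values` (length `tau_max`),
#'   `defined` (logical mask), `reasons` (per-scale notes), `method`,
#'   `cfg`.
#' @examples
#' img <- generate_mix2d(mix_params(p = 1, shape = c(40, 40), q = 3, seed = 1))
#' multiscale_profile(img, embedding_config(M = c(1, 1, 1), r = 0.5),
#'                    method = "msampen", tau_max = 3)
#' @export
multiscale_profile <- function(img, cfg, method = c("msampen", "mfuzen"),
                               tau_max = 10L) {
  method <- match.arg(method)
  tau_max <- as.integer(tau_max)
  if (length(tau_max) != 1L || is.na(tau_max) || tau_max < 1L) {
    stop("`tau_max` must be a positive integer", call. = FALSE)
  }
  img <- as_mcimage(img)
  fn <- if (method == "msampen") msampen_rgb else mfuzen_rgb
  values <- rep(NA_real_, tau_max)
  defined <- logical(tau_max)
  reasons <- character(tau_max)
  for (tau in seq_len(tau_max)) {
    cg <- tryCatch(coarse_grain(img, tau), error = function(e) e)
    if (inherits(cg, "error")) {
      reasons[tau] <- conditionMessage(cg)
      next
    }
    res <- tryCatch(fn(cg, cfg), error = function(e) e)
    if (inherits(res, "error")) {
      reasons[tau] <- conditionMessage(res)
    } else if (!res$defined) {
      reasons[tau] <- "entropy undefined (no matches)"
    } else {
      values[tau] <- res$value
      defined[tau] <- TRUE
      reasons[tau] <- ""
    }
  }
  structure(list(method = method, cfg = cfg, tau = seq_len(tau_max),
                 values = values, defined = defined, reasons = reasons),
            class = "multiscale_profile")
}

#' @export
print.multiscale_profile <- function(x, ...) {
  cat(sprintf("<multiscale_profile %s M=[%s] r=%g, tau = 1..%d>\n",
              x$method, paste(x$cfg$M, collapse = ","), x$cfg$r,
              length(x$values)))
  vals <- ifelse(x$defined, sprintf("%.4f", x$values), "undef")
  cat(" ", paste(sprintf("tau%d=%s", x$tau, vals), collapse = "  "), "\n")
  invisible(x)
}
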