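#' Center-crop an image
#'
#' Extracts a centered window of the requested size.  The crop offset on
#' each axis is `floor((source - target) / 2)`, fixed so that results are
#' bit-reproducible.
#'
#' @param img An [mcimage] (or coercible array).
#' @param size Target size: a single integer (square crop) or `c(H, W)`.
#' @return The cropped [mcimage].
#' @examples
#' img <- mcimage(matrix(1:36, 6, 6))
#' dim(center_crop(img, 2))
#' @export
center_crop <- function(img, size) {
  img <- as_mcimage(img)
  d <- dim(img)
  size <- as.integer(size)
  if (length(size) == 1L) size <- c(size, size)
  if (length(size) != 2L || any(is.na(size)) || any(size < 1L)) {
    stop("`size` must be one or two positive integers", call. = FALSE)
  }
  if (size[1L] > d[1L] || size[2L] > d[2L]) {
    stop(sprintf("crop size %dx%d exceeds image size %dx%d",
                 size[1L], size[2L], d[1L], d[2L]), call. = FALSE)
  }
  off <- c((d[1L] - size[1L]) %/% 2L, (d[2L] - size[2L]) %/% 2L)
  out <- unclass(img)[off[1L] + seq_len(size[1L]),
                      off[2L] + seq_len(size[2L]), , drop = FALSE]
  mcimage(out, channel_names = attr(img, "channel_names"),
          provenance = attr(img, "provenance"))
}

#' Z-normalize an image
#'
#' Centers and scales pixel intensities to mean 0 and standard deviation 1.
#' By default the mean and SD are pooled over all pixels and channels of
#' the image (a single mu and sigma per image), which preserves the
#' relative intensities between channels that the multivariate Chebyshev
#' distance compares; `per_channel = TRUE` normalizes each channel
#' separately.  The population SD convention (divide by the pixel count)
#' is used.
#'
#' @param img An [mcimage] (or coercible array).
#' @param per_channel Normalize each channel independently (default `FALSE`).
#' @return The normalized [mcimage].
#' @examples
#' normalize_image(mcimage(matrix(c(0, 2), 1, 2)))  # -> -1, 1
#' @export
normalize_image <- function(img, per_channel = FALSE) {
  img <- as_mcimage(img)
  a <- pixel_array(img)
  zscore <- function(x) {
    mu <- mean(x)
    sigma <- sqrt(mean((x - mu)^2))
    if (sigma < 1e-15 * max(1, abs(mu))) {
      stop("constant image: standard deviation is zero, cannot normalize",
           call. = FALSE)
    }
    (x - mu) / sigma
  }
  if (per_channel) {
    for (k in seq_len(dim(a)[3L])) a[, , k] <- zscore(a[, , k])
  } else {
    a <- zscore(a)
  }
  mcimage(a, channel_names = attr(img, "channel_names"),
          provenance = attr(img, "provenance"))
}

#' Convert an RGB image to grayscale
#'
#' Weighted luma combination with ITU-R BT.601 coefficients
#' (0.2989 R + 0.5870 G + 0.1140 B), the de-facto default of mainstream
#' image toolchains.  Used to feed the univariate (q = 1) entropy
#' baselines.
#'
#' @param img A three-channel [mcimage].
#' @return A single-channel [mcimage].
#' @export
to_grayscale <- function(img) {
  img <- as_mcimage(img)
  if (dim(img)[3L] != 3L) {
    stop("grayscale conversion requires exactly 3 channels, got ",
         dim(img)[3L], call. = FALSE)
  }
  a <- pixel_array(img)
  g <- 0.2989 * a[, , 1L] + 0.5870 * a[, , 2L] + 0.1140 * a[, , 3L]
  mcimage(array(g, dim = c(dim(a)[1:2], 1L)),
          provenance = attr(img, "provenance"))
}
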