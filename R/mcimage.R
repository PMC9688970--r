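#' Multichannel image container
#'
#' A thin S3 wrapper around an `H x W x q` numeric array of pixel
#' intensities, the carrier used throughout the package for raw,
#' normalized and coarse-grained images.  Pixel `(i, j)` lives in row `i`,
#' column `j`; channel is the third margin.
#'
#' @param pixels Numeric `H x W x q` array, or an `H x W` matrix (taken as
#'   a single-channel image).
#' @param channel_names Optional character vector of length `q`
#'   (e.g. `c("R", "G", "B")`).
#' @param provenance Optional string recording where the pixels came from
#'   (file path or generator tag).
#' @return An object of class `mcimage`.
#' @examples
#' img <- mcimage(array(runif(4 * 5 * 3), dim = c(4, 5, 3)),
#'                channel_names = c("R", "G", "B"))
#' dim(img)
#' @export
mcimage <- function(pixels, channel_names = NULL, provenance = NULL) {
  if (is.matrix(pixels)) {
    pixels <- array(pixels, dim = c(dim(pixels), 1L))
  }
  if (!is.array(pixels) || length(dim(pixels)) != 3L) {
    stop("`pixels` must be an H x W x q array or an H x W matrix", call. = FALSE)
  }
  if (!is.numeric(pixels)) stop("`pixels` must be numeric", call. = FALSE)
  if (any(dim(pixels) < 1L)) stop("all image dimensions must be >= 1", call. = FALSE)
  if (!all(is.finite(pixels))) stop("pixel values must all be finite", call. = FALSE)
  storage.mode(pixels) <- "double"
  q <- dim(pixels)[3L]
  if (!is.null(channel_names)) {
    if (length(channel_names) != q) {
      stop("`channel_names` must have one entry per channel", call. = FALSE)
    }
    attr(pixels, "channel_names") <- as.character(channel_names)
  }
  if (!is.null(provenance)) attr(pixels, "provenance") <- as.character(provenance)
  class(pixels) <- c("mcimage", "array")
  pixels
}

#' @export
print.mcimage <- function(x, ...) {
  d <- dim(x)
  cn <- attr(x, "channel_names")
  cat(sprintf("<mcimage %d x %d, %d channel%s%s>\n", d[1L], d[2L], d[3L],
              if (d[3L] == 1L) "" else "s",
              if (is.null(cn)) "" else paste0(" (", paste(cn, collapse = ","), ")")))
  cat(sprintf("  range [%.4g, %.4g], mean %.4g\n", min(x), max(x), mean(x)))
  prov <- attr(x, "provenance")
  if (!is.null(prov)) cat("  provenance:", prov, "\n")
  invisible(x)
}

#' @rdname mcimage
#' @param x Object to test or coerce.
#' @export
is_mcimage <- function(x) inherits(x, "mcimage")

#' @rdname mcimage
#' @export
as_mcimage <- function(x) {
  if (is_mcimage(x)) return(x)
  mcimage(x)
}

# Bare 3D double array (drops the class so downstream arithmetic stays plain).
pixel_array <- function(img) {
  img <- as_mcimage(img)
  a <- unclass(img)
  attr(a, "channel_names") <- NULL
  attr(a, "provenance") <- NULL
  a
}

#' Read a raster image into an mcimage
#'
#' Reads PNG or TIFF files into float intensities in `[0, 1]`.  An alpha
#' channel, if present, is dropped.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return An [mcimage] with provenance set to `path`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  a <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format '", ext, "' (PNG and TIFF are supported)",
         call. = FALSE)
  )
  if (is.matrix(a)) a <- array(a, dim = c(dim(a), 1L))
  if (dim(a)[3L] == 4L) a <- a[, , 1:3, drop = FALSE]  # drop alpha
  cn <- if (dim(a)[3L] == 3L) c("R", "G", "B") else NULL
  mcimage(a, channel_names = cn, provenance = path)
}

#' Plain-text array container for float images
#'
#' The portable container used for synthetic fixtures: a one-line header
#' `rgbentropy-mcimage H W q` followed by one `%.17g` value per line in
#' column-major order (row fastest, then column, then channel).  Lossless
#' for doubles and diffable.
#'
#' @param img An [mcimage] (or coercible array).
#' @param path Output/input file path.
#' @return `write_mcimage_text` returns `path` invisibly;
#'   `read_mcimage_text` returns an [mcimage].
#' @export
write_mcimage_text <- function(img, path) {
  a <- pixel_array(img)
  d <- dim(a)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("rgbentropy-mcimage %d %d %d", d[1L], d[2L], d[3L]), con)
  writeLines(sprintf("%.17g", as.vector(a)), con)
  invisible(path)
}

#' @rdname write_mcimage_text
#' @export
read_mcimage_text <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1L], " ", fixed = TRUE)[[1L]]
  if (length(hdr) != 4L || hdr[1L] != "rgbentropy-mcimage") {
    stop("not an rgbentropy-mcimage file: ", path, call. = FALSE)
  }
  d <- as.integer(hdr[2:4])
  vals <- as.numeric(lines[-1L])
  if (length(vals) != prod(d)) stop("corrupt mcimage file: ", path, call. = FALSE)
  mcimage(array(vals, dim = d), provenance = path)
}

#' Render an mcimage to an 8-bit PNG for visual inspection
#'
#' Min–max scales the float data to `[0, 1]` and writes a PNG.  Intended
#' for eyeballing synthetic fixtures only; entropy is always computed on
#' the float data, never on this rendering.
#'
#' @param img An [mcimage] with 1 or 3 channels.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mcimage_png <- function(img, path) {
  a <- pixel_array(img)
  rng <- range(a)
  scaled <- if (rng[2L] > rng[1L]) (a - rng[1L]) / (rng[2L] - rng[1L]) else a * 0
  if (dim(scaled)[3L] == 1L) scaled <- scaled[, , 1L]
  png::writePNG(scaled, path)
  invisible(path)
}
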