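#' MIX process parameters
#'
#' Bundles the parameters of the MIX family of controlled-irregularity
#' stochastic processes.  A MIX(p) process replaces, independently at each
#' sample (1D) or pixel (2D), a deterministic sinusoidal template with
#' uniform white noise on `[-3, 3]`, with probability `p`.  `p` is the
#' irregularity dial: `p = 0` is a purely periodic pattern, `p = 1` pure
#' noise.
#'
#' @param p Noise probability in `[0, 1]`.
#' @param n Signal length (1D) — positive integer.
#' @param shape Image dimensions `c(H, W)` (2D) — positive integers.
#' @param q Number of channels/variates, `>= 1` (3 for RGB).
#' @param seed Integer seed; identical parameters and seed give
#'   bit-identical output.
#' @param shared_mask If `TRUE`, one Bernoulli mask `Z` is drawn per
#'   location and shared by all channels (the literal reading of the
#'   generating equation, which carries no channel index on `Z`); the
#'   noise values stay channel-specific.  Default `FALSE`: `Z` and the
#'   noise are both drawn independently per channel, so each variate is a
#'   distinct MIX process.
#' @return A list of class `mix_params`.
#' @seealso [generate_mix1d()], [generate_mix2d()]
#' @export
mix_params <- function(p, n = NULL, shape = NULL, q = 1L, seed = 1L,
                       shared_mask = FALSE) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
    stop("`p` must be a single probability in [0, 1]", call. = FALSE)
  }
  if (!is.null(n)) {
    n <- as.integer(n)
    if (length(n) != 1L || is.na(n) || n < 1L) {
      stop("`n` must be a positive integer", call. = FALSE)
    }
  }
  if (!is.null(shape)) {
    shape <- as.integer(shape)
    if (length(shape) != 2L || any(is.na(shape)) || any(shape < 1L)) {
      stop("`shape` must be two positive integers c(H, W)", call. = FALSE)
    }
  }
  q <- as.integer(q)
  if (length(q) != 1L || is.na(q) || q < 1L) {
    stop("`q` must be a positive integer", call. = FALSE)
  }
  structure(list(p = p, n = n, shape = shape, q = q,
                 seed = as.integer(seed), shared_mask = isTRUE(shared_mask)),
            class = "mix_params")
}

# Sine template value at 0-based index i.
mix_sine <- function(i) sin(2 * pi * i / 12)

#' Generate a multivariate 1D MIX signal
#'
#' Sample `i` (0-based) of channel `k` is
#' `(1 - Z) * sin(2*pi*i/12) + Z * Y` with `Z ~ Bernoulli(p)` and
#' `Y ~ Uniform[-3, 3]`.  By default both are drawn independently per
#' sample and per channel; see [mix_params()] for the `shared_mask`
#' variant.  One seeded RNG stream per call: all `Z` first, then all `Y`,
#' filled in column-major order (sample fastest, then channel), so the
#' stream — and hence the output — is fully determined by the parameters.
#'
#' @param params A [mix_params()] with `n` set.
#' @return An `n x q` numeric matrix, one column per variate.
#' @examples
#' s <- generate_mix1d(mix_params(p = 0, n = 24, q = 3, seed = 7))
#' s[4, 1]  # sin(2*pi*3/12) = 1
#' @export
generate_mix1d <- function(params) {
  stopifnot(inherits(params, "mix_params"))
  if (is.null(params$n)) stop("`params$n` must be set for 1D generation", call. = FALSE)
  n <- params$n; q <- params$q
  set.seed(params$seed)
  if (params$shared_mask) {
    z <- matrix(runif(n) < params$p, n, q)
  } else {
    z <- matrix(runif(n * q) < params$p, n, q)
  }
  y <- matrix(runif(n * q, -3, 3), n, q)
  x <- matrix(mix_sine(seq_len(n) - 1), n, q)
  out <- ifelse(z, y, x)
  dimnames(out) <- NULL
  out
}

#' Generate a multichannel 2D MIX image
#'
#' Pixel `(i, j)` (0-based) of channel `k` is
#' `(1 - Z) * (sin(2*pi*i/12) + sin(2*pi*j/12)) + Z * Y` with
#' `Z ~ Bernoulli(p)`, `Y ~ Uniform[-3, 3]`, independent per pixel and per
#' channel by default (`shared_mask` shares `Z` across channels).  RNG
#' stream order as in [generate_mix1d()]: all `Z`, then all `Y`,
#' column-major (row fastest, then column, then channel).
#'
#' @param params A [mix_params()] with `shape` set.
#' @return An [mcimage] of dimension `H x W x q` with provenance tag
#'   `mix2d(p=..., seed=...)`.
#' @examples
#' img <- generate_mix2d(mix_params(p = 0, shape = c(12, 12), q = 3, seed = 1))
#' img[4, 4, 1]  # sin(pi/2) + sin(pi/2) = 2
#' @export
generate_mix2d <- function(params) {
  stopifnot(inherits(params, "mix_params"))
  if (is.null(params$shape)) stop("`params$shape` must be set for 2D generation", call. = FALSE)
  h <- params$shape[1L]; w <- params$shape[2L]; q <- params$q
  set.seed(params$seed)
  if (params$shared_mask) {
    z <- array(rep(runif(h * w) < params$p, q), dim = c(h, w, q))
  } else {
    z <- array(runif(h * w * q) < params$p, dim = c(h, w, q))
  }
  y <- array(runif(h * w * q, -3, 3), dim = c(h, w, q))
  # template: rows index i, columns j, both 0-based in the sine argument
  tmpl <- outer(mix_sine(seq_len(h) - 1), mix_sine(seq_len(w) - 1), `+`)
  x <- array(rep(tmpl, q), dim = c(h, w, q))
  out <- ifelse(z, y, x)
  mcimage(out,
          channel_names = if (q == 3L) c("R", "G", "B") else NULL,
          provenance = sprintf("mix2d(p=%g, seed=%d)", params$p, params$seed))
}
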