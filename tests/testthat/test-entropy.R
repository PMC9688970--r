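# Entropy kernels: agreement with the naive reference implementations,
# exact degenerate cases, geometric invariances, tolerance monotonicity.

test_that("optimized kernels match the brute-force references on small images", {
  cases <- expand.grid(q = c(1, 3), mfac = c(1, 2), r = c(0.15, 1),
                       KEEP.OUT.ATTRS = FALSE)
  for (ci in seq_len(nrow(cases))) {
    q <- cases$q[ci]; r <- cases$r[ci]
    M <- rep(cases$mfac[ci], q)
    img <- rand_image(8, 8, q, seed = 100 + ci)
    cfg <- embedding_config(M = M, r = r, s = 2)

    a <- msampen_rgb(img, cfg)
    b <- msampen_rgb_brute(img, M, r)
    expect_identical(a$defined, b$defined)
    expect_equal(a$b_m, b$b_m, tolerance = 1e-12)
    expect_equal(a$b_m1, b$b_m1, tolerance = 1e-12)
    if (a$defined) expect_equal(a$value, b$value, tolerance = 1e-10)

    af <- mfuzen_rgb(img, cfg)
    bf <- mfuzen_rgb_brute(img, M, r, s = 2)
    expect_equal(af$value, bf$value, tolerance = 1e-10)
  }
})

test_that("both normalization modes agree with their brute-force counterparts", {
  img <- rand_image(8, 8, 3, seed = 42)
  for (mode in c("consistent", "literal")) {
    cfg <- embedding_config(M = c(2, 2, 2), r = 1, s = 2, normalization = mode)
    a <- msampen_rgb(img, cfg)
    b <- msampen_rgb_brute(img, c(2, 2, 2), 1, normalization = mode)
    expect_equal(a$value, b$value, tolerance = 1e-10)
    af <- mfuzen_rgb(img, cfg)
    bf <- mfuzen_rgb_brute(img, c(2, 2, 2), 1, s = 2, normalization = mode)
    expect_equal(af$value, bf$value, tolerance = 1e-10)
  }
})

test_that("literal and consistent normalizations differ by the predicted constant", {
  # B = T/den in each mode, so the entropy offset is a pure function of the
  # four denominators -- identical across images and tolerances.
  nm <- (10 - 2) * (10 - 2); n <- 2; q <- 3
  offset <- log((q * (nm - n) - 1) / (q * nm - 1) * (nm - 1) / (nm - n - 1))
  for (seed in c(1, 2)) {
    img <- rand_image(10, 10, 3, seed = seed)
    for (r in c(0.5, 1)) {
      cc <- embedding_config(M = c(2, 2, 2), r = r, s = 2)
      cl <- embedding_config(M = c(2, 2, 2), r = r, s = 2,
                             normalization = "literal")
      expect_equal(mfuzen_rgb(img, cl)$value - mfuzen_rgb(img, cc)$value,
                   offset, tolerance = 1e-10)
      sa <- msampen_rgb(img, cc); sl <- msampen_rgb(img, cl)
      if (sa$defined) {
        expect_equal(sl$value - sa$value, offset, tolerance = 1e-10)
      }
    }
  }
})

test_that("q = 1 kernels reduce to the univariate bi-dimensional measures", {
  for (seed in 1:3) {
    img <- rand_image(10, 10, 1, seed = 200 + seed)
    cfg <- embedding_config(M = 2, r = 1.5, s = 2)
    a <- msampen_rgb(img, cfg)
    ref <- sampen2d_ref(img[, , 1], 2L, 1.5)
    expect_identical(a$defined, ref$defined)
    expect_equal(a$value, ref$value, tolerance = 1e-10)
    af <- mfuzen_rgb(img, embedding_config(M = 2, r = 0.15, s = 2))
    reff <- fuzen2d_ref(img[, , 1], 2L, 0.15, 2)
    expect_equal(af$value, reff$value, tolerance = 1e-10)
  }
})

test_that("a constant array has zero entropy under both measures", {
  const <- array(2.5, dim = c(10, 10, 3))
  cfg <- embedding_config(M = c(2, 2, 2), r = 0.1, s = 2)
  s <- msampen_rgb(const, cfg)
  expect_true(s$defined)
  expect_identical(s$value, 0)
  expect_identical(s$b_m, 1)
  expect_identical(s$b_m1, 1)
  f <- mfuzen_rgb(const, cfg)
  expect_identical(f$value, 0)
})

test_that("fuzzy entropy vanishes as r grows large", {
  img <- rand_image(10, 10, 3, seed = 55)
  rs <- c(1, 10, 1e3, 1e6)
  vals <- vapply(rs, function(r) {
    mfuzen_rgb(img, embedding_config(M = c(1, 1, 1), r = r, s = 2))$value
  }, numeric(1))
  expect_true(all(diff(vals) < 0))   # monotone decay toward 0
  expect_lt(vals[length(vals)], 1e-6)
})

test_that("entropy is invariant to intensity shifts", {
  # distances depend on pixel differences only, so adding a constant to
  # every pixel changes nothing at either dimension
  img <- rand_image(12, 12, 3, seed = 7)
  cfg <- embedding_config(M = c(2, 2, 2), r = 0.8, s = 2)
  for (shift in c(3.7, -120)) {
    expect_equal(msampen_rgb(img + shift, cfg)$value,
                 msampen_rgb(img, cfg)$value, tolerance = 1e-12)
    expect_equal(mfuzen_rgb(img + shift, cfg)$value,
                 mfuzen_rgb(img, cfg)$value, tolerance = 1e-12)
  }
})

test_that("single-channel entropy is invariant to transposition", {
  # with q = 1 there is a single extension class, so transposing the image
  # permutes every compared pair of vectors identically
  for (seed in c(3, 4)) {
    img <- rand_image(12, 12, 1, seed = seed)
    cfg <- embedding_config(M = 2, r = 0.8, s = 2)
    tr <- aperm(img, c(2, 1, 3))
    expect_equal(msampen_rgb(tr, cfg)$value, msampen_rgb(img, cfg)$value,
                 tolerance = 1e-12)
    expect_equal(mfuzen_rgb(tr, cfg)$value, mfuzen_rgb(img, cfg)$value,
                 tolerance = 1e-12)
  }
})

test_that("the base-dimension statistic is invariant to transposition and channel relabeling", {
  # at dimension m every composite vector is permuted the same way, so
  # b_m is preserved; the pooled cross-channel comparisons at dimension
  # m+1 do not share this symmetry (see the methods vignette)
  img <- rand_image(12, 12, 3, seed = 7)
  cfg <- embedding_config(M = c(2, 2, 2), r = 0.8, s = 2)
  b <- msampen_rgb(img, cfg)$b_m
  expect_equal(msampen_rgb(aperm(img, c(2, 1, 3)), cfg)$b_m, b,
               tolerance = 1e-12)
  expect_equal(msampen_rgb(img[, , c(3, 1, 2), drop = FALSE], cfg)$b_m, b,
               tolerance = 1e-12)
  bf <- mfuzen_rgb(img, cfg)$b_m
  expect_equal(mfuzen_rgb(aperm(img, c(2, 1, 3)), cfg)$b_m, bf,
               tolerance = 1e-12)
  expect_equal(mfuzen_rgb(img[, , c(3, 1, 2), drop = FALSE], cfg)$b_m, bf,
               tolerance = 1e-12)
})

test_that("entropy is non-increasing in the tolerance r", {
  img <- rand_image(12, 12, 3, seed = 23)
  rgrid <- c(0.1, 0.2, 0.4, 0.8, 1.6, 3.2)
  cfgs <- lapply(rgrid, function(r) embedding_config(M = c(1, 1, 1), r = r, s = 2))
  fuz <- vapply(cfgs, function(cfg) mfuzen_rgb(img, cfg)$value, numeric(1))
  expect_true(all(diff(fuz) <= 1e-12))
  smp <- vapply(cfgs, function(cfg) {
    res <- msampen_rgb(img, cfg)
    if (res$defined) res$value else NA_real_
  }, numeric(1))
  smp <- smp[!is.na(smp)]
  expect_true(all(diff(smp) <= 1e-12))
  expect_gte(length(smp), 3)  # enough defined values for the check to bite
})

test_that("zero matches yield a flagged undefined result, not an error", {
  img <- rand_image(8, 8, 3, seed = 1)  # r far too small for any match
  res <- msampen_rgb(img, embedding_config(M = c(2, 2, 2), r = 1e-6))
  expect_false(res$defined)
  expect_true(is.na(res$value))
  expect_identical(res$b_m, 0)
})

test_that("entropy kernels validate their inputs", {
  img <- rand_image(8, 8, 3, seed = 1)
  expect_error(msampen_rgb(img, embedding_config(M = c(2, 2), r = 0.2)),
               "channel")
  expect_error(msampen_rgb(img, embedding_config(M = c(1, 2, 2), r = 0.2)),
               "equal per-channel")
  expect_error(mfuzen_rgb(img, embedding_config(M = c(1, 1, 1), r = 0.2)),
               "fuzzy power")
  expect_error(msampen_rgb(rand_image(3, 3, 1, seed = 1),
                           embedding_config(M = 2, r = 0.2)), "too small")
})
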