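# MIX generators: deterministic template at p = 0, pure noise at p = 1,
# Bernoulli mixing in between, bit-reproducibility under a fixed seed.

test_that("p = 0 gives the pure sine template in 1D and 2D", {
  sig <- generate_mix1d(mix_params(p = 0, n = 24, q = 3, seed = 5))
  tmpl <- sin(2 * pi * (0:23) / 12)
  for (k in 1:3) expect_equal(sig[, k], tmpl, tolerance = 1e-12)
  expect_equal(sig[4, 2], 1.0)  # i = 3 (0-based): sin(pi/2)

  img <- generate_mix2d(mix_params(p = 0, shape = c(24, 24), q = 3, seed = 5))
  expect_equal(img[1, 1, 1], 0)       # (0,0): sin(0) + sin(0)
  expect_equal(img[4, 4, 2], 2)       # (3,3): sin(pi/2) + sin(pi/2)
  # periodic with period 12 along both axes
  expect_equal(unclass(img)[1:12, , ], unclass(img)[13:24, , ])
  expect_equal(unclass(img)[, 1:12, ], unclass(img)[, 13:24, ])
})

test_that("p = 1 is uniform white noise on [-3, 3]", {
  sig <- generate_mix1d(mix_params(p = 1, n = 1e5, q = 1, seed = 9))
  n <- length(sig)
  expect_lt(abs(mean(sig)), 3 * sqrt(3) / sqrt(n))  # 3 sigma/sqrt(N) around 0
  expect_equal(var(as.vector(sig)), 3, tolerance = 0.05)

  img <- generate_mix2d(mix_params(p = 1, shape = c(100, 100), q = 1, seed = 9))
  tmpl <- outer(sin(2 * pi * (0:99) / 12), sin(2 * pi * (0:99) / 12), `+`)
  expect_equal(sum(img[, , 1] == tmpl), 0)  # no template pixel survives
  ks <- suppressWarnings(ks.test(as.vector(img), "punif", -3, 3))
  expect_gt(ks$p.value, 0.01)
})

test_that("the fraction of noise-replaced samples concentrates around p", {
  # 1D at the Bernoulli-rate tolerance of +/- 0.01 at N = 1e5
  sig <- generate_mix1d(mix_params(p = 0.5, n = 1e5, q = 1, seed = 3))
  tmpl <- sin(2 * pi * (seq_len(1e5) - 1) / 12)
  frac <- mean(sig[, 1] != tmpl)  # exact coincidence has probability zero
  expect_lt(abs(frac - 0.5), 0.01)

  # 2D binomial concentration at 4 * sqrt(p(1-p)/N)
  for (p in c(0.1, 0.5, 0.9)) {
    img <- generate_mix2d(mix_params(p = p, shape = c(100, 100), q = 1,
                                     seed = 31))
    tmpl2 <- outer(sin(2 * pi * (0:99) / 12), sin(2 * pi * (0:99) / 12), `+`)
    frac2 <- mean(img[, , 1] != tmpl2)
    expect_lt(abs(frac2 - p), 4 * sqrt(p * (1 - p) / 1e4))
  }
})

test_that("generation is bit-identical under a fixed seed and varies across seeds", {
  pars <- mix_params(p = 0.4, shape = c(30, 20), q = 3, seed = 77)
  expect_identical(unclass(generate_mix2d(pars)), unclass(generate_mix2d(pars)))
  pars2 <- mix_params(p = 0.4, shape = c(30, 20), q = 3, seed = 78)
  expect_false(identical(unclass(generate_mix2d(pars)),
                         unclass(generate_mix2d(pars2))))
  s1 <- generate_mix1d(mix_params(p = 0.4, n = 50, q = 2, seed = 12))
  expect_identical(s1, generate_mix1d(mix_params(p = 0.4, n = 50, q = 2,
                                                 seed = 12)))
})

test_that("channels are independent by default and share Z under shared_mask", {
  tmpl <- outer(sin(2 * pi * (0:49) / 12), sin(2 * pi * (0:49) / 12), `+`)
  ind <- generate_mix2d(mix_params(p = 0.5, shape = c(50, 50), q = 3, seed = 2))
  m1 <- ind[, , 1] != tmpl
  m2 <- ind[, , 2] != tmpl
  expect_false(identical(m1, m2))

  sh <- generate_mix2d(mix_params(p = 0.5, shape = c(50, 50), q = 3, seed = 2,
                                  shared_mask = TRUE))
  s1 <- sh[, , 1] != tmpl
  s2 <- sh[, , 2] != tmpl
  expect_identical(s1, s2)                    # same mask ...
  expect_false(identical(sh[, , 1][s1], sh[, , 2][s2]))  # ... distinct noise
})

test_that("invalid MIX parameters are rejected", {
  expect_error(mix_params(p = -0.1, n = 10), "probability")
  expect_error(mix_params(p = 1.2, n = 10), "probability")
  expect_error(mix_params(p = 0.5, n = 0), "positive")
  expect_error(mix_params(p = 0.5, shape = c(5, 0)), "positive")
  expect_error(mix_params(p = 0.5, n = 5, q = 0), "positive")
  expect_error(generate_mix1d(mix_params(p = 0.5, shape = c(4, 4))), "n")
  expect_error(generate_mix2d(mix_params(p = 0.5, n = 9)), "shape")
})
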