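# Seeded fixtures, generated in code at test time.

rand_image <- function(h, w, q = 1L, seed = 1L, lo = -1, hi = 1) {
  set.seed(seed)
  array(runif(h * w * q, lo, hi), dim = c(h, w, q))
}

# 3x3 single-channel image with values 1..9 laid out row-major
# (pixel (row 0, col 0) = 1, (0,1) = 2, ..., (2,2) = 9).
img_1to9 <- function() mcimage(matrix(1:9, 3, 3, byrow = TRUE))
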