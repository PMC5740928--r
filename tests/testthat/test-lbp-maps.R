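test_that("scale stack radii follow the sqrt(2) schedule and filtering
           preserves constants and mass", {
  img <- matrix(5, 40, 40)
  st <- build_scale_stack(img, neighborhood_spec(8, 1), 4)
  expect_equal(vapply(st$levels, `[[`, numeric(1), "R"),
               c(1, sqrt(2), 2, 2 * sqrt(2)))
  for (lev in st$levels) expect_equal(lev$image, img)
  # sigma below the cutoff: identity on arbitrary content
  rimg <- random_image(20, 3)
  expect_identical(gaussian_filter(rimg, 0.25), rimg)
  # unit impulse: kernel mass sums to 1
  imp <- matrix(0, 41, 41); imp[21, 21] <- 1
  expect_equal(sum(gaussian_filter(imp, 2.3)), 1, tolerance = 1e-6)
  expect_error(build_scale_stack(matrix(0, 8, 8), neighborhood_spec(), 8),
               "too small")
})

test_that("circular sampling is exact on grid points and linear ramps", {
  img <- matrix(7, 10, 10)
  expect_equal(sample_circle(img, 5, 5, neighborhood_spec(8, 2)),
               rep(7, 8))
  set.seed(4)
  rimg <- matrix(runif(100), 10, 10)
  v <- sample_circle(rimg, 5, 5, neighborhood_spec(4, 1))
  expect_equal(v, c(rimg[5, 6], rimg[4, 5], rimg[5, 4], rimg[6, 5]),
               tolerance = 1e-12)
  # ramp f(x, y) = x: bilinear interpolation is exact
  ramp <- matrix(rep(1:20, each = 20), 20, 20, byrow = TRUE)
  ramp <- t(ramp)  # value = column index
  R <- 2.3
  v <- sample_circle(ramp, 10, 10, neighborhood_spec(8, R))
  expect_equal(v, 10 + R * cos(2 * pi * (0:7) / 8), tolerance = 1e-9)
})

test_that("sign and magnitude code images match the naive double-loop
           oracle bitwise", {
  spec <- neighborhood_spec(8, 1.5)
  for (seed in 1:3) {
    img <- random_image(16, seed)
    ref <- oracle_lbp(img, spec)
    s <- sign_lbp_image(img, spec)
    expect_identical(s$valid, ref$valid)
    expect_equal(s$codes[s$valid], ref$sign[ref$valid])
    th <- magnitude_thresholds(img, spec)
    expect_equal(th$t, ref$t, tolerance = 1e-12)
    m <- magnitude_lbp_image(img, spec, th)
    expect_equal(m$codes[m$valid], ref$mag[ref$valid])
  }
})

test_that("degenerate inputs give the printed constant codes", {
  spec <- neighborhood_spec(8, 1)
  img <- matrix(3, 12, 12)
  s <- sign_lbp_image(img, spec)
  expect_true(all(s$codes[s$valid] == 255))      # s(0) = 1 on every bit
  th <- magnitude_thresholds(img, spec)
  expect_equal(th$t, rep(0, 8))
  m <- magnitude_lbp_image(img, spec, th)
  expect_true(all(m$codes[m$valid] == 255))
  # single bright pixel: centre exceeds all neighbours -> code 0
  img2 <- matrix(0, 12, 12); img2[6, 6] <- 10
  s2 <- sign_lbp_image(img2, spec)
  expect_equal(s2$codes[6, 6], 0)
  # thresholds scale linearly with intensity
  set.seed(9)
  img3 <- matrix(runif(144), 12, 12)
  expect_equal(magnitude_thresholds(3 * img3, spec)$t,
               3 * magnitude_thresholds(img3, spec)$t, tolerance = 1e-12)
})

test_that("code images are invariant to affine intensity maps and
           equivariant under quarter turns", {
  spec <- neighborhood_spec(8, 2.8)
  img <- random_image(24, 11)
  s1 <- sign_lbp_image(img, spec)
  s2 <- sign_lbp_image(2.5 * img - 17, spec)
  expect_identical(s1$codes, s2$codes)
  t1 <- magnitude_thresholds(img, spec)
  t2 <- magnitude_thresholds(2.5 * img - 17, spec)
  m1 <- magnitude_lbp_image(img, spec, t1)
  m2 <- magnitude_lbp_image(2.5 * img - 17, spec, t2)
  expect_identical(m1$codes, m2$codes)
  # quarter-turn: histogram of codes rotated by P/4 is preserved exactly
  s_rot <- sign_lbp_image(rot90_ccw(img), spec)
  h1 <- tabulate(rotate_code(s1$codes[s1$valid], 2, 8) + 1, 256)
  h2 <- tabulate(s_rot$codes[s_rot$valid] + 1, 256)
  expect_identical(h1, h2)
})

test_that("validity equals the geometric all-samples-inside rule", {
  spec <- neighborhood_spec(8, 2.8)
  img <- random_image(16, 2)
  s <- sign_lbp_image(img, spec)
  ref <- oracle_region_split(matrix(TRUE, 16, 16), spec)
  expect_identical(s$valid, ref$interior)
})
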