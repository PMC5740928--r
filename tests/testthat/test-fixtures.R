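test_that("texture generation is deterministic and class spectra peak in
           their active slots", {
  spec <- texture_spec(1, 0.05, ratios = c(1, 2.5), amps = c(1, 0))
  a <- gen_texture(spec, size = 64, degrees = 33, scale = 1.1, seed = 9)
  b <- gen_texture(spec, size = 64, degrees = 33, scale = 1.1, seed = 9)
  expect_identical(a, b)
  c2 <- gen_texture(spec, size = 64, degrees = 33, scale = 1.1, seed = 10)
  expect_false(identical(a, c2))
  # periodogram of an unrotated, unscaled instance peaks at the band
  img <- gen_texture(spec, size = 128, seed = 5)
  sp <- Mod(stats::fft(img - mean(img)))^2
  fx <- c(0:64, -(63:1)) / 128
  rad <- sqrt(outer(fx^2, fx^2, `+`))
  peak <- rad[which.max(sp)]
  expect_gt(peak, 0.035); expect_lt(peak, 0.07)
  # dataset-level determinism
  d1 <- gen_texture_dataset(2, 2, seed = 7, size = 48)
  d2 <- gen_texture_dataset(2, 2, seed = 7, size = 48)
  expect_identical(d1$images, d2$images)
  expect_equal(d1$labels, rep(c("class01", "class02"), each = 2))
  # Nyquist guard refuses bands pushed past the limit by shrinking
  expect_error(gen_texture(texture_spec(1, 0.2, ratio = 2.4), scale = 0.8),
               "Nyquist")
  expect_error(
    gen_texture_dataset(2, 1, scale_range = c(0.5, 1),
                        specs = list(texture_spec(1, 0.2, ratio = 2),
                                     texture_spec(2, 0.25, ratio = 2))),
    "Nyquist")
})

test_that("default class layout assigns distinct slot pairs", {
  specs <- ffirst:::default_texture_specs(10)
  sets <- lapply(specs, function(s) which(s$amps > 0))
  expect_equal(length(unique(sets)), 10)
  for (i in 1:9) for (j in (i + 1):10)
    expect_gte(length(setdiff(sets[[i]], sets[[j]])) +
                 length(setdiff(sets[[j]], sets[[i]])), 2)
  # all bands respect the Nyquist guard at maximum shrink
  for (s in specs)
    expect_lte(ffirst:::max_band_freq(s) / 0.8, 0.45)
})

test_that("leaf images segment to their ground-truth masks", {
  specs <- border_only_leaf_specs(2)
  lf <- gen_leaf(specs[[1]], size = 96, degrees = 20, seed = 3)
  expect_true(all(lf$image[!lf$mask] > 0.8))
  m <- leaf_mask(lf$image)
  iou <- sum(m & lf$mask) / sum(m | lf$mask)
  expect_gte(iou, 0.98)
  ds <- gen_leaf_dataset(specs, n_per_class = 2, seed = 1, size = 96)
  expect_equal(length(ds$images), 4)
  for (i in seq_along(ds$images)) {
    m <- leaf_mask(ds$images[[i]])
    expect_gte(sum(m & ds$masks[[i]]) / sum(m | ds$masks[[i]]), 0.98)
  }
  expect_error(leaf_spec(1, axes = c(1, 30)), "degenerate")
  expect_error(gen_leaf_dataset(specs[1], 2), "two leaf specs")
})

test_that("border-only leaf classes have statistically indistinguishable
           interiors", {
  # permutation test on interior descriptor distances: classes differing
  # only in serration/border texture should not separate at the 1% level
  specs <- border_only_leaf_specs(2)
  ds <- gen_leaf_dataset(specs, n_per_class = 8, seed = 2, size = 96)
  cfg <- ffirst_config(scales = 5, window = 5)
  D <- t(vapply(seq_along(ds$images), function(i)
    extract_ffirst(ds$images[[i]], ds$masks[[i]], cfg,
                   "interior")$vectors[1, ],
    numeric(5 * 574)))
  lab <- ds$provenance$class
  dm <- as.matrix(dist(D))
  # statistic: between-class mean distance minus within-class
  stat <- function(lab) {
    same <- outer(lab, lab, `==`) & upper.tri(dm)
    diff <- outer(lab, lab, `!=`) & upper.tri(dm)
    mean(dm[diff]) - mean(dm[same])
  }
  obs <- stat(lab)
  set.seed(99)
  perm <- replicate(199, stat(sample(lab)))
  pval <- (1 + sum(perm >= obs)) / 200
  expect_gt(pval, 0.01)
})
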