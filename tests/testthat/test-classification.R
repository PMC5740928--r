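test_that("the explicit feature map reproduces the additive kernel", {
  fm <- feature_map_config()
  expect_equal(intersection_map(numeric(5), fm), matrix(0, 1, 15))
  set.seed(41)
  errs <- replicate(100, {
    x <- runif(150); x <- x / sum(x)
    y <- runif(150); y <- y / sum(y)
    k_hat <- sum(intersection_map(x, fm) * intersection_map(y, fm))
    k_ref <- additive_kernel(x, y)
    abs(k_hat - k_ref) / k_ref
  })
  expect_lt(max(errs), 0.05)
  # chi-square variant approximates its kernel too
  fm2 <- feature_map_config("chi2")
  set.seed(42)
  x <- runif(100); x <- x / sum(x); y <- runif(100); y <- y / sum(y)
  k_hat <- sum(intersection_map(x, fm2) * intersection_map(y, fm2))
  expect_lt(abs(k_hat - additive_kernel(x, y, "chi2")) /
              additive_kernel(x, y, "chi2"), 0.1)
  expect_error(intersection_map(c(-1, 2), fm), "non-negative")
})

test_that("the dual coordinate descent solver separates separable data
           deterministically", {
  set.seed(43)
  n <- 60
  X <- rbind(matrix(rnorm(n * 5, 2), n, 5), matrix(rnorm(n * 5, -2), n, 5))
  y <- rep(c(1, -1), each = n)
  Xt <- t(cbind(X, 1))
  fit <- ffirst:::dcd_svm(Xt, y, 1, 1e-4, 500, 7)
  dec <- ffirst:::dense_decision(Xt, fit$w)
  expect_true(all(sign(dec) == y))
  fit2 <- ffirst:::dcd_svm(Xt, y, 1, 1e-4, 500, 7)
  expect_identical(fit$w, fit2$w)
  # duality-gap style check: all alphas within box, violation below tol
  expect_true(all(fit$alpha >= 0 & fit$alpha <= 1))
  expect_lt(fit$max_violation, 1e-4)
})

test_that("Platt calibration yields a decreasing sigmoid centred near the
           boundary on balanced data", {
  set.seed(44)
  dec <- c(rnorm(200, 1.2), rnorm(200, -1.2))
  lab <- rep(c(1L, 0L), each = 200)
  ab <- ffirst:::platt_fit(dec, lab)
  expect_lt(ab["A"], 0)          # monotone increasing posterior in f
  p0 <- ffirst:::platt_prob(0, ab["A"], ab["B"])
  expect_gt(p0, 0.4); expect_lt(p0, 0.6)
  ps <- ffirst:::platt_prob(seq(-3, 3, 0.5), ab["A"], ab["B"])
  expect_true(all(diff(ps) > 0))
})

make_stub_descriptor <- function(vec, fingerprint = "stub") {
  structure(list(vectors = matrix(vec, 1), empty = FALSE,
                 variant = "all", fingerprint = fingerprint),
            class = "ffirst_descriptor")
}

test_that("posterior fusion follows the sum/product rules with the
           documented tie-breaks", {
  wi <- list(post = matrix(c(0.6, 0.4), 1, dimnames = list(NULL, c("c1", "c2"))),
             windows = 1L)
  wb <- list(post = matrix(c(0.3, 0.7), 1, dimnames = list(NULL, c("c1", "c2"))),
             windows = 1L)
  fs <- ffirst:::fuse_posteriors(wi, wb, "ibsum")
  expect_equal(unname(fs$score), c(0.9, 1.1))
  expect_equal(names(which.max(fs$score)), "c2")
  fp <- ffirst:::fuse_posteriors(wi, wb, "ibprod")
  expect_equal(unname(fp$score), c(0.18, 0.28))
  # uniform border posteriors preserve the interior argmax under product
  wb_u <- list(post = matrix(c(0.5, 0.5), 1, dimnames = list(NULL, c("c1", "c2"))),
               windows = 1L)
  fu <- ffirst:::fuse_posteriors(wi, wb_u, "ibprod")
  expect_equal(which.max(fu$score), which.max(wi$post[1, ]))
  # multi-window: max over windows after fusing per window
  wi2 <- list(post = matrix(c(0.2, 0.9, 0.1, 0.3), 2), windows = c(1L, 2L))
  wb2 <- list(post = matrix(c(0.5, 0.1, 0.9, 0.2), 2), windows = c(1L, 2L))
  f2 <- ffirst:::fuse_posteriors(wi2, wb2, "ibsum")
  expect_equal(f2$score, c(1.0, 1.0))
})

test_that("an end-to-end model separates two separable texture classes
           and reports calibrated posteriors", {
  specs <- list(texture_spec(1, 0.05, ratios = c(1, 3), amps = c(1, 0)),
                texture_spec(2, 0.05, ratios = c(1, 3), amps = c(0, 1)))
  ds <- gen_texture_dataset(2, 12, rotation_range = c(0, 360),
                            scale_range = c(1, 1), seed = 3, size = 96,
                            specs = specs)
  cfg <- ffirst_config(scales = 6, window = 4)
  desc <- lapply(ds$images, extract_ffirst, mask = NULL, config = cfg,
                 variant = "all")
  tr <- rep(rep(c(TRUE, FALSE), c(8, 4)), 2)
  m <- train_ova(desc[tr], ds$labels[tr], seed = 5)
  # training accuracy on separable classes is perfect
  pr_tr <- vapply(which(tr), function(i)
    predict_image(m, desc[[i]], variant = "a")$class, "")
  expect_equal(mean(pr_tr == ds$labels[tr]), 1)
  pr_te <- vapply(which(!tr), function(i)
    predict_image(m, desc[[i]], variant = "a")$class, "")
  expect_equal(mean(pr_te == ds$labels[!tr]), 1)
  # determinism of the whole training path
  m2 <- train_ova(desc[tr], ds$labels[tr], seed = 5)
  expect_identical(m$weights, m2$weights)
  expect_identical(m$platt, m2$platt)
  # posteriors are probabilities and fingerprints are enforced
  p <- predict_image(m, desc[[which(!tr)[1]]], variant = "a")
  expect_true(all(p$posteriors >= 0 & p$posteriors <= 1))
  bad <- desc[[1]]; bad$fingerprint <- "other"
  expect_error(predict_image(m, bad, variant = "a"), "fingerprint")
  expect_error(train_ova(desc[tr][1:8], rep("one", 8), seed = 1),
               "two classes")
})

test_that("ranks and retrieval metrics follow the reciprocal-rank
           definition", {
  expect_equal(evaluate_ranks(1)$mrr, 1.0)
  expect_equal(evaluate_ranks(c(2, 2))$mrr, 0.5)
  ev <- evaluate_ranks(c(1, 2, 4))
  expect_equal(ev$mrr, (1 + 0.5 + 0.25) / 3)
  expect_equal(ev$mrr, 0.58333, tolerance = 1e-5)
  expect_equal(ev$top1, 1 / 3)
  expect_equal(ev$top5, 1)
  expect_error(evaluate_ranks(integer(0)), "empty")
  expect_error(evaluate_ranks(c(1, 0)), ">= 1")
  s <- c(a = 0.3, b = 0.9, c = 0.3)
  expect_equal(rank_of_truth(s, "b"), 1L)
  expect_equal(rank_of_truth(s, "a"), 2L)
  expect_equal(rank_of_truth(s, "c"), 3L)   # tie resolves to lower index
})

test_that("cost tuning picks a grid value and keeps the model usable", {
  specs <- list(texture_spec(1, 0.05, ratios = c(1, 3), amps = c(1, 0)),
                texture_spec(2, 0.05, ratios = c(1, 3), amps = c(0, 1)))
  ds <- gen_texture_dataset(2, 6, scale_range = c(1, 1), seed = 13,
                            size = 64, specs = specs)
  cfg <- ffirst_config(scales = 4, window = 3)
  desc <- lapply(ds$images, extract_ffirst, mask = NULL, config = cfg,
                 variant = "all")
  m <- train_ova(desc, ds$labels, seed = 3, tune_C = TRUE)
  expect_true(m$C %in% c(0.01, 0.1, 1, 10, 100))
  p <- predict_image(m, desc[[1]], variant = "a")
  expect_true(p$class %in% m$classes)
})
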