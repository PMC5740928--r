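tab8 <- enumerate_orbits(8)

# build a code_image from a bare code matrix (all pixels valid)
as_codes <- function(m, P = 8) ffirst:::code_image(m, m >= 0, P)

test_that("orbit histograms conserve mass and match a naive tally", {
  set.seed(5)
  m <- matrix(sample(0:255, 400, replace = TRUE), 20, 20)
  h <- orbit_histogram(as_codes(m), tab8)
  expect_equal(h$total, 400)
  expect_equal(sum(unlist(h$freq)), 1, tolerance = 1e-12)
  # naive tally: counts of each code via table()
  raw <- tabulate(as.vector(m) + 1L, 256)
  for (j in seq_len(36)) {
    expect_equal(h$counts[[j]], raw[tab8$members[[j]] + 1L],
                 info = paste("orbit", j))
  }
  # constant image: all mass in the all-ones orbit
  cimg <- matrix(1, 10, 10)
  s <- sign_lbp_image(cimg, neighborhood_spec(8, 1))
  hc <- orbit_histogram(s, tab8)
  all1 <- which(tab8$orbits$canonical == 255)
  expect_equal(hc$freq[[all1]][1], 1)
})

test_that("HF magnitudes follow delta/uniform DFT identities and the
           expected layouts", {
  # single nonzero bin in a period-8 orbit: flat spectrum
  h <- orbit_histogram(as_codes(matrix(1, 5, 5)), tab8)  # code 1, orbit of 1
  v <- hf_magnitudes(h, tab8, "full")
  orb1 <- tab8$codes$orbit_id[2]   # orbit of code 1 (period 8)
  starts <- cumsum(c(0, head(tab8$orbits$size %/% 2 + 1, -1)))
  idx <- starts[orb1] + 1:5
  expect_equal(v[idx], rep(1, 5))  # delta of mass 1: all magnitudes 1
  # uniform histogram over an orbit: DC only
  codes <- rep(vapply(0:7, function(k) rotate_code(1, k, 8), numeric(1)), 4)
  hu <- orbit_histogram(as_codes(matrix(codes, 4, 8, byrow = TRUE)), tab8)
  vu <- hf_magnitudes(hu, tab8, "full")
  expect_equal(vu[idx], c(1, 0, 0, 0, 0), tolerance = 1e-12)
  # layout sizes: full 163 per type; uniform 38 per type
  expect_equal(length(v), 163)
  expect_equal(sum(tab8$orbits$size %/% 2 + 1), 163)
  expect_equal(length(hf_magnitudes(h, tab8, "uniform")),
               (8 - 1) * 5 + 3)
  # conjugate symmetry of the underlying spectra
  set.seed(6)
  hr <- orbit_histogram(as_codes(matrix(sample(0:255, 256, TRUE), 16, 16)),
                        tab8)
  sp <- ffirst:::orbit_spectra(hr)
  for (j in which(tab8$orbits$size >= 2)) {
    d <- tab8$orbits$size[j]
    for (u in seq_len(d - 1))
      expect_equal(sp[[j]][u + 1], Conj(sp[[j]][d - u + 1]),
                   tolerance = 1e-12)
  }
})

test_that("adjacent-orbit invariants cancel rotation phases", {
  # real positive first coefficients: feature = sqrt(a * b), Im = 0
  pairs <- ffirst:::hf_plus_pairs(tab8, "full")
  expect_equal(nrow(pairs), 31)   # 2 period-4 pairs + 29 period-8 pairs
  expect_equal(nrow(ffirst:::hf_plus_pairs(tab8, "uniform")), 7 - 1)
  # craft a histogram with known spectra: delta at rotation 0 in two
  # adjacent period-8 orbits gives H(n,1) = a, H(n+1,1) = b (real after
  # scaling by mass); z = a*b, feature = sqrt(a*b)
  h <- orbit_histogram(as_codes(matrix(c(1, 1, 3, 3), 2, 2)), tab8)
  ids <- tab8$codes$orbit_id[c(2, 4)]  # codes 1 and 3 (adjacent orbits)
  p <- hf_plus(h, tab8, "full")
  k <- which(pairs[, 1] == ids[1] & pairs[, 2] == ids[2])
  expect_gt(length(k), 0)
  expect_equal(p[2 * k - 1], sqrt(0.5 * 0.5), tolerance = 1e-12)
  expect_equal(p[2 * k], 0, tolerance = 1e-12)
  # phase cancellation: rotating every code leaves all features fixed
  set.seed(8)
  m <- matrix(sample(0:255, 900, TRUE), 30, 30)
  p0 <- hf_plus(orbit_histogram(as_codes(m), tab8), tab8, "full")
  for (k in c(1, 3, 5)) {
    pk <- hf_plus(orbit_histogram(as_codes(rotate_code(m, k, 8)), tab8),
                  tab8, "full")
    expect_equal(pk, p0, tolerance = 1e-12)
  }
})

test_that("scale descriptors have the configured layout and are exactly
           invariant to code rotation", {
  lay <- descriptor_layout(8, "uniform", FALSE)
  expect_equal(max(lay$end), 76)
  expect_equal(max(descriptor_layout(8, "full", FALSE)$end), 326)
  expect_equal(max(descriptor_layout(8, "full", TRUE)$end),
               326 + 4 * 31 * 2)
  set.seed(12)
  ms <- matrix(sample(0:255, 400, TRUE), 20, 20)
  mm <- matrix(sample(0:255, 400, TRUE), 20, 20)
  for (mode in c("full", "uniform")) {
    d0 <- scale_descriptor(as_codes(ms), as_codes(mm), tab8, mode, TRUE)
    expect_true(all(is.finite(d0$values)))
    expect_false(d0$empty)
    for (k in c(2, 7)) {
      dk <- scale_descriptor(as_codes(rotate_code(ms, k, 8)),
                             as_codes(rotate_code(mm, k, 8)),
                             tab8, mode, TRUE)
      expect_equal(dk$values, d0$values, tolerance = 1e-12)
    }
  }
  # empty region: zero vector with flag
  e <- ffirst:::code_image(matrix(0, 5, 5), matrix(FALSE, 5, 5), 8)
  de <- scale_descriptor(e, e, tab8, "full", TRUE)
  expect_true(de$empty)
  expect_equal(de$values, numeric(574))
})

test_that("uniform-mode magnitudes agree with the full-set values on the
           uniform orbits plus pooled extras", {
  set.seed(13)
  m <- matrix(sample(0:255, 400, TRUE), 20, 20)
  h <- orbit_histogram(as_codes(m), tab8)
  vu <- hf_magnitudes(h, tab8, "uniform")
  vf <- hf_magnitudes(h, tab8, "full")
  starts <- cumsum(c(0, head(tab8$orbits$size %/% 2 + 1, -1)))
  uni <- which(tab8$orbits$uniform & tab8$orbits$ones %in% 1:7)
  from_full <- unlist(lapply(uni, function(j) vf[starts[j] + 1:5]))
  expect_equal(vu[1:35], from_full, tolerance = 1e-12)
  # extras: constant-pattern frequencies and pooled non-uniform mass
  expect_equal(vu[36], h$freq[[which(tab8$orbits$canonical == 0)]][1])
  expect_equal(vu[37], h$freq[[which(tab8$orbits$canonical == 255)]][1])
  nonuni <- which(!tab8$orbits$uniform)
  expect_equal(vu[38], sum(unlist(h$freq[nonuni])), tolerance = 1e-12)
})
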