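# Rotation-invariant histogram Fourier features of LBP code images.
#
# Occurrence histograms are collected per rotation orbit, ordered by
# rotation index, and normalized by the number of described pixels. A DFT
# along each orbit turns image rotation (a cyclic shift of the orbit
# histogram) into a pure phase, so the DFT magnitudes are rotation
# invariants; because the histogram is real, only floor(d/2)+1 magnitudes
# are informative for an orbit of period d. Additional invariants are
# formed from products of first DFT coefficients of adjacent same-period
# orbits, whose phases cancel under rotation.

#' Orbit-indexed histogram of a code image
#'
#' Tallies valid pixels by (orbit, rotation index) and normalizes by the
#' total so descriptors are comparable across region sizes.
#'
#' @param codes a `code_image`.
#' @param table an `orbit_table` with matching P.
#' @return object of class `orbit_histogram`: list with `freq` (list of
#'   per-orbit numeric vectors ordered by rotation index), `counts`,
#'   `total` (valid pixel count) and `empty` flag.
#' @export
orbit_histogram <- function(codes, table) {
  stopifnot(inherits(codes, "code_image"), inherits(table, "orbit_table"),
            codes$P == table$P)
  P <- table$P
  vals <- codes$codes[codes$valid]
  total <- length(vals)
  raw <- tabulate(vals + 1L, nbins = 2^P)
  freq <- lapply(table$members, function(m) {
    v <- raw[m + 1L]
    if (total > 0) v / total else v * 0
  })
  counts <- lapply(table$members, function(m) raw[m + 1L])
  structure(list(freq = freq, counts = counts, total = total,
                 empty = total == 0, P = P),
            class = "orbit_histogram")
}

# per-orbit DFTs (length = orbit period) of the normalized histogram
orbit_spectra <- function(hist) {
  lapply(hist$freq, stats::fft)
}

#' Histogram-Fourier magnitude block
#'
#' In full mode: for every orbit of period d, the magnitudes |H(n,u)|,
#' u = 0..floor(d/2). In uniform mode: the P-1 uniform orbits with
#' 0 < n < P ones each contribute floor(P/2)+1 magnitudes, then three
#' extra bins are appended: the two constant ("1-uniform") patterns
#' (all-zeros, all-ones) and the pooled mass of all non-uniform patterns.
#'
#' @param hist an [orbit_histogram()].
#' @param table the matching `orbit_table`.
#' @param mode "full" or "uniform".
#' @return numeric vector of non-negative magnitudes.
#' @export
hf_magnitudes <- function(hist, table, mode = c("full", "uniform")) {
  mode <- match.arg(mode)
  stopifnot(inherits(hist, "orbit_histogram"), hist$P == table$P)
  spectra <- orbit_spectra(hist)
  if (mode == "full") {
    out <- lapply(seq_along(spectra), function(j) {
      d <- table$orbits$size[j]
      Mod(spectra[[j]][seq_len(d %/% 2 + 1)])
    })
    return(unlist(out))
  }
  P <- table$P
  uni <- which(table$orbits$uniform & table$orbits$ones > 0 &
                 table$orbits$ones < P)
  out <- lapply(uni, function(j) Mod(spectra[[j]][seq_len(P %/% 2 + 1)]))
  all0 <- which(table$orbits$canonical == 0)
  all1 <- which(table$orbits$canonical == 2^P - 1)
  nonuni <- which(!table$orbits$uniform)
  extra <- c(hist$freq[[all0]][1], hist$freq[[all1]][1],
             sum(unlist(hist$freq[nonuni])))
  c(unlist(out), extra)
}

# same-period adjacent orbit pairs in canonical order, restricted to the
# orbits used by `mode`; returns a 2-column matrix of orbit ids
hf_plus_pairs <- function(table, mode = c("full", "uniform")) {
  mode <- match.arg(mode)
  ob <- table$orbits
  if (mode == "uniform")
    ob <- ob[ob$uniform & ob$ones > 0 & ob$ones < table$P, , drop = FALSE]
  ob <- ob[ob$size >= 2, , drop = FALSE]
  pairs <- NULL
  for (d in sort(unique(ob$size))) {
    ids <- ob$orbit_id[ob$size == d]          # already canonical-ascending
    if (length(ids) >= 2)
      pairs <- rbind(pairs, cbind(ids[-length(ids)], ids[-1]))
  }
  if (is.null(pairs)) matrix(integer(0), 0, 2) else pairs
}

#' Extra rotation invariants from first DFT coefficients
#'
#' For each adjacent pair of same-period orbits (canonical order), the
#' product z = H(n,1) * conj(H(n+1,1)) is rotation-invariant because both
#' coefficients pick up the same phase under a cyclic shift. The emitted
#' features are Re(w) and Im(w) of w = z / sqrt(|z|) (0 when z = 0):
#' this has the magnitude of the complex square root of z - matching the
#' scale of the plain HF magnitudes - but unlike the principal square
#' root it has no branch cut, so exact rotation invariance survives
#' floating point when z falls near the negative real axis. Orbits of
#' period < 2 have no u = 1 coefficient and are skipped.
#'
#' @param hist an [orbit_histogram()].
#' @param table the matching `orbit_table`.
#' @param mode "full" (pairs over all orbits) or "uniform" (pairs over the
#'   uniform orbits with 0 < ones < P only).
#' @return numeric vector (signed), 2 entries per pair.
#' @export
hf_plus <- function(hist, table, mode = c("full", "uniform")) {
  mode <- match.arg(mode)
  stopifnot(inherits(hist, "orbit_histogram"), hist$P == table$P)
  spectra <- orbit_spectra(hist)
  pairs <- hf_plus_pairs(table, mode)
  if (nrow(pairs) == 0) return(numeric(0))
  out <- numeric(2 * nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    z <- spectra[[pairs[k, 1]]][2] * Conj(spectra[[pairs[k, 2]]][2])
    w <- if (Mod(z) > 0) z / sqrt(Mod(z)) else 0 + 0i
    out[2 * k - 1] <- Re(w)
    out[2 * k] <- Im(w)
  }
  out
}

# split signed features into non-negative (positive-part, negative-part)
# channel pairs, as required by the intersection-kernel feature map
split_signed <- function(x) {
  if (length(x) == 0) return(numeric(0))
  as.vector(rbind(pmax(x, 0), pmax(-x, 0)))
}

#' Per-scale descriptor layout
#'
#' Dimensionality of one scale's descriptor as a pure function of
#' (P, mode, plus), with named index ranges for auditability.
#'
#' @param P neighbourhood size.
#' @param mode "full" or "uniform".
#' @param plus include the adjacent-orbit invariants.
#' @return data.frame with columns `block`, `start`, `end` (1-based,
#'   inclusive); total dimension is `max(end)`.
#' @export
descriptor_layout <- function(P = 8L, mode = c("full", "uniform"),
                              plus = TRUE) {
  mode <- match.arg(mode)
  table <- orbit_table_cached(P)
  n_hf <- if (mode == "full") {
    sum(table$orbits$size %/% 2 + 1)
  } else {
    (P - 1) * (P %/% 2 + 1) + 3
  }
  n_plus <- 4 * nrow(hf_plus_pairs(table, mode))  # 2 per pair, sign-split
  blocks <- data.frame(block = c("hf_sign", "hf_mag"),
                       len = c(n_hf, n_hf))
  if (plus)
    blocks <- rbind(blocks,
                    data.frame(block = c("hfplus_sign", "hfplus_mag"),
                               len = c(n_plus, n_plus)))
  blocks$end <- cumsum(blocks$len)
  blocks$start <- blocks$end - blocks$len + 1L
  blocks[, c("block", "start", "end")]
}

#' Descriptor of one scale from its sign- and magnitude-LBP code images
#'
#' Concatenates the histogram-Fourier magnitude blocks of both code
#' images and, when `plus`, the sign-split adjacent-orbit invariants of
#' each: `[HF-S | HF-M | HF+S | HF+M]`. All entries are non-negative.
#'
#' @param sign_codes,mag_codes `code_image`s from the same level/region.
#' @param table the matching `orbit_table`.
#' @param mode "full" or "uniform".
#' @param plus include the adjacent-orbit invariants.
#' @return object of class `scale_descriptor`: list with `values`,
#'   `empty`, `layout`.
#' @export
scale_descriptor <- function(sign_codes, mag_codes, table,
                             mode = c("full", "uniform"), plus = TRUE) {
  mode <- match.arg(mode)
  stopifnot(inherits(sign_codes, "code_image"),
            inherits(mag_codes, "code_image"))
  if (sign_codes$P != table$P || mag_codes$P != table$P)
    stop("code images and orbit table disagree on P", call. = FALSE)
  layout <- descriptor_layout(table$P, mode, plus)
  dim_total <- max(layout$end)
  hs <- orbit_histogram(sign_codes, table)
  hm <- orbit_histogram(mag_codes, table)
  if (hs$empty || hm$empty) {
    return(structure(list(values = numeric(dim_total), empty = TRUE,
                          layout = layout), class = "scale_descriptor"))
  }
  v <- c(hf_magnitudes(hs, table, mode), hf_magnitudes(hm, table, mode))
  if (plus)
    v <- c(v, split_signed(hf_plus(hs, table, mode)),
           split_signed(hf_plus(hm, table, mode)))
  structure(list(values = v, empty = FALSE, layout = layout),
            class = "scale_descriptor")
}
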