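# Independent brute-force oracles and small fixture builders shared by
# the unit and acceptance tests. These deliberately re-derive results by
# naive enumeration so they cannot share bugs with the vectorized paths.

# group all 2^P codes into rotation orbits by explicit repeated rotation
oracle_orbits <- function(P) {
  codes <- 0:(2^P - 1)
  seen <- rep(FALSE, 2^P)
  orbits <- list()
  for (c0 in codes) {
    if (seen[c0 + 1]) next
    members <- unique(vapply(0:(P - 1), function(k)
      rotate_code(c0, k, P), numeric(1)))
    seen[members + 1] <- TRUE
    orbits[[length(orbits) + 1L]] <- sort(members)
  }
  orbits
}

# naive per-pixel double-loop LBP codes (sign and magnitude) using
# sample_circle; describes pixels where all samples stay in the image
oracle_lbp <- function(level, spec) {
  H <- nrow(level); W <- ncol(level)
  sign_codes <- matrix(NA_real_, H, W)
  absdiff <- array(NA_real_, c(H, W, spec$P))
  for (r in seq_len(H)) for (c in seq_len(W)) {
    v <- tryCatch(sample_circle(level, c, r, spec), error = function(e) NULL)
    if (is.null(v)) next
    d <- level[r, c] - v
    sign_codes[r, c] <- sum(2^(seq_len(spec$P) - 1) * (d <= 0))
    absdiff[r, c, ] <- abs(d)
  }
  valid <- !is.na(sign_codes)
  t_p <- vapply(seq_len(spec$P), function(p)
    mean(absdiff[, , p][valid]), numeric(1))
  mag_codes <- matrix(NA_real_, H, W)
  for (r in seq_len(H)) for (c in seq_len(W)) {
    if (!valid[r, c]) next
    mag_codes[r, c] <- sum(2^(seq_len(spec$P) - 1) *
                             ((absdiff[r, c, ] - t_p) <= 0))
  }
  list(sign = sign_codes, mag = mag_codes, valid = valid, t = t_p)
}

# exhaustive-search Otsu on the same 256-bin quantization
oracle_otsu <- function(image) {
  lo <- min(image); hi <- max(image)
  q <- pmin(floor((image - lo) / (hi - lo) * 256), 255)
  h <- tabulate(q + 1L, nbins = 256)
  best <- -Inf; best_k <- 1
  for (k in 1:256) {
    w0 <- sum(h[1:k]); w1 <- sum(h) - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(h[1:k] * (0:(k - 1))) / w0
    mu1 <- sum(h[(k + 1):256] * (k:255)) / w1
    v <- w0 * w1 * (mu0 - mu1)^2
    if (v > best + 1e-9) { best <- v; best_k <- k }
  }
  lo + (best_k - 0.5) / 256 * (hi - lo)
}

disk_mask <- function(n, radius, centre = (n + 1) / 2) {
  d <- sqrt(outer((seq_len(n) - centre)^2, (seq_len(n) - centre)^2, `+`))
  d <= radius
}

# geometric oracle for region_split: per-pixel loop over sample points,
# sample membership = all bilinear support pixels inside the mask
oracle_region_split <- function(mask, spec) {
  H <- nrow(mask); W <- ncol(mask)
  off <- ffirst:::neighbor_offsets(spec$P, spec$R)
  inside <- matrix(FALSE, H, W)
  snap <- function(z) { r <- round(z); if (abs(z - r) < 1e-9) r else z }
  for (r in seq_len(H)) for (c in seq_len(W)) {
    ok <- TRUE
    for (p in seq_len(spec$P)) {
      rs <- snap(r - off$dy[p]); cs <- snap(c + off$dx[p])
      r0 <- floor(rs); c0 <- floor(cs)
      fy <- rs - r0; fx <- cs - c0
      rows <- if (fy > 0) c(r0, r0 + 1) else r0
      cols <- if (fx > 0) c(c0, c0 + 1) else c0
      if (any(rows < 1 | rows > H) || any(cols < 1 | cols > W) ||
          !all(mask[rows, cols])) { ok <- FALSE; break }
    }
    inside[r, c] <- ok
  }
  list(interior = mask & inside, border = mask & !inside)
}

random_image <- function(n, seed) {
  set.seed(seed)
  matrix(runif(n * n), n, n)
}
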