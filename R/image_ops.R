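# Low-level raster utilities: portable graymap I/O, luminance conversion,
# separable Gaussian filtering with reflective boundaries, exact 90-degree
# rotation, and bilinear affine resampling.
#
# Images are plain numeric matrices, indexed [row, col], row 1 at the top.
# The geometric convention used everywhere: x = column, y = row with the
# y axis pointing up, so the sample point of neighbour p at angle
# theta = 2*pi*p/P and radius R relative to centre (row, col) is
# (row - R*sin(theta), col + R*cos(theta)).

SNAP_EPS <- 1e-9

check_gray <- function(image) {
  if (!is.matrix(image) || !is.numeric(image))
    stop("image must be a numeric matrix", call. = FALSE)
  if (nrow(image) < 3 || ncol(image) < 3)
    stop("image must be at least 3x3", call. = FALSE)
  if (any(!is.finite(image)))
    stop("image must contain only finite values", call. = FALSE)
  image
}

#' Convert an RGB array to luminance
#'
#' Fixed ITU-R BT.601 weights (0.299, 0.587, 0.114).
#'
#' @param rgb numeric array `height x width x 3`.
#' @return a grayscale matrix.
#' @export
rgb_to_gray <- function(rgb) {
  stopifnot(is.array(rgb), length(dim(rgb)) == 3, dim(rgb)[3] >= 3)
  0.299 * rgb[, , 1] + 0.587 * rgb[, , 2] + 0.114 * rgb[, , 3]
}

#' Read a portable graymap (PGM) image
#'
#' Supports both plain (P2) and binary (P5, maxval <= 255) variants.
#' Other raster formats are not supported in this environment; convert to
#' PGM or CSV first.
#'
#' @param path file path.
#' @return numeric matrix of raw intensity values (0..maxval).
#' @export
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 2))
  if (!magic %in% c("P2", "P5"))
    stop("not a PGM file (P2/P5): ", path, call. = FALSE)
  # token reader skipping whitespace and '#' comments
  next_token <- function() {
    tok <- character(0)
    repeat {
      ch <- rawToChar(readBin(con, "raw", 1))
      if (length(ch) == 0 || ch == "") stop("truncated PGM header")
      if (ch == "#") {
        repeat {
          ch <- rawToChar(readBin(con, "raw", 1))
          if (ch == "\n") break
        }
        next
      }
      if (grepl("[[:space:]]", ch)) {
        if (length(tok) > 0) break else next
      }
      tok <- c(tok, ch)
    }
    paste(tok, collapse = "")
  }
  w <- as.integer(next_token()); h <- as.integer(next_token())
  maxval <- as.integer(next_token())
  n <- w * h
  if (magic == "P5") {
    if (maxval > 255) stop("16-bit binary PGM not supported")
    vals <- as.integer(readBin(con, "raw", n))
  } else {
    vals <- scan(con, what = integer(), n = n, quiet = TRUE)
  }
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

#' Write a matrix as a plain-text PGM (P2)
#'
#' Values are clamped to `[0, maxval]` and rounded.
#'
#' @param image numeric matrix.
#' @param path output path.
#' @param maxval maximum gray value (default 255).
#' @export
write_pgm <- function(image, path, maxval = 255L) {
  v <- round(pmin(pmax(image, 0), maxval))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(image), nrow(image)), as.character(maxval)), con)
  utils::write.table(v, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a grayscale image or mask from PGM or CSV
#'
#' @param path file ending in .pgm or .csv; anything else errors.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "pgm") return(read_pgm(path))
  if (ext == "csv")
    return(as.matrix(utils::read.csv(path, header = FALSE)))
  stop("unsupported image format '", ext,
       "': only PGM (P2/P5) and headerless CSV are supported here",
       call. = FALSE)
}

# --- integer shifts and bilinear sampling ---------------------------------

# shift image content by (dr, dc) integer pixels; vacated cells get `fill`.
# out[r, c] = m[r + dr, c + dc] where in range.
shift_int <- function(m, dr, dc, fill = NA_real_) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(fill, H, W)
  r_dst <- max(1, 1 - dr):min(H, H - dr)
  c_dst <- max(1, 1 - dc):min(W, W - dc)
  if (length(r_dst) < 1 || length(c_dst) < 1 || r_dst[1] > r_dst[length(r_dst)] ||
      c_dst[1] > c_dst[length(c_dst)]) return(out)
  out[r_dst, c_dst] <- m[r_dst + dr, c_dst + dc]
  out
}

# snap a real offset to integer when within SNAP_EPS, so that samples that
# mathematically fall on grid points do not pick up zero-weight neighbours
snap_offset <- function(d) {
  r <- round(d)
  ifelse(abs(d - r) < SNAP_EPS, r, d)
}

# Bilinear sample of m at (row + dy_img, col + dx_img) for every pixel,
# where dy_img is measured DOWN the rows. Returns list(values, valid):
# valid is TRUE when every support pixel with nonzero weight is inside the
# image. Constant offsets only (vectorized over the whole image).
bilinear_shift <- function(m, dy_img, dx_img) {
  dy_img <- snap_offset(dy_img); dx_img <- snap_offset(dx_img)
  r0 <- floor(dy_img); c0 <- floor(dx_img)
  fy <- dy_img - r0;   fx <- dx_img - c0
  acc <- NULL; valid <- NULL
  add <- function(w, dr, dc) {
    if (w == 0) return()
    s <- shift_int(m, dr, dc)
    ok <- !is.na(s)
    s[!ok] <- 0
    if (is.null(acc)) { acc <<- w * s; valid <<- ok }
    else { acc <<- acc + w * s; valid <<- valid & ok }
  }
  add((1 - fy) * (1 - fx), r0,     c0)
  add((1 - fy) * fx,       r0,     c0 + 1)
  add(fy * (1 - fx),       r0 + 1, c0)
  add(fy * fx,             r0 + 1, c0 + 1)
  list(values = acc, valid = valid)
}

# TRUE where every nonzero-weight support pixel of the sample at offset
# (dy_img, dx_img) lies inside `mask` (and inside the image frame).
mask_shift_all <- function(mask, dy_img, dx_img) {
  dy_img <- snap_offset(dy_img); dx_img <- snap_offset(dx_img)
  r0 <- floor(dy_img); c0 <- floor(dx_img)
  fy <- dy_img - r0;   fx <- dx_img - c0
  res <- NULL
  add <- function(w, dr, dc) {
    if (w == 0) return()
    s <- shift_int(mask * 1, dr, dc, fill = 0) > 0
    if (is.null(res)) res <<- s else res <<- res & s
  }
  add((1 - fy) * (1 - fx), r0,     c0)
  add((1 - fy) * fx,       r0,     c0 + 1)
  add(fy * (1 - fx),       r0 + 1, c0)
  add(fy * fx,             r0 + 1, c0 + 1)
  res
}

# --- neighbour offset table ----------------------------------------------

# Offsets (dx east, dy up) of the P samples at radius R. For P divisible
# by 4 the table is built from the first quadrant and completed by exact
# 90-degree rotations (dx, dy) -> (-dy, dx), which makes 90-degree image
# rotation an exact permutation of the sample set.
neighbor_offsets <- function(P, R) {
  dx <- numeric(P); dy <- numeric(P)
  if (P %% 4 == 0) {
    q <- P / 4
    for (p in 0:(q - 1)) {
      th <- 2 * pi * p / P
      dx[p + 1] <- R * cos(th); dy[p + 1] <- R * sin(th)
    }
    for (p in q:(P - 1)) {
      dx[p + 1] <- -dy[p - q + 1]
      dy[p + 1] <-  dx[p - q + 1]
    }
  } else {
    th <- 2 * pi * (0:(P - 1)) / P
    dx <- R * cos(th); dy <- R * sin(th)
  }
  dx <- snap_offset(dx); dy <- snap_offset(dy)
  list(dx = dx, dy = dy)
}

# --- Gaussian filtering ---------------------------------------------------

# truncated, renormalized sampled Gaussian; radius 3*sigma
gaussian_kernel <- function(sigma) {
  rad <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-rad:rad)^2) / (2 * sigma^2))
  k / sum(k)
}

# reflect ("symmetric") padding indices for length n, pad p: for p < n
reflect_idx <- function(n, p) {
  c(rev(seq_len(p)), seq_len(n), n + 1 - seq_len(p))
}

#' Separable Gaussian filter with reflective boundary handling
#'
#' Filtering is skipped (identity) when `sigma` is below 0.3, where the
#' discrete kernel is negligible. The kernel is 90-degree symmetric and
#' the symmetric padding commutes with quarter-turn rotation, so filtering
#' is exactly equivariant under 90-degree rotations.
#'
#' @param image numeric matrix.
#' @param sigma Gaussian standard deviation in pixels.
#' @export
gaussian_filter <- function(image, sigma) {
  check_gray(image)
  if (sigma < 0.3) return(image)
  k <- gaussian_kernel(sigma)
  rad <- (length(k) - 1L) %/% 2L
  if (rad >= nrow(image) || rad >= ncol(image))
    stop("image too small for Gaussian support (sigma = ", sigma, ")",
         call. = FALSE)
  # filter columns (along rows), then rows
  pad <- image[reflect_idx(nrow(image), rad), , drop = FALSE]
  tmp <- matrix(0, nrow(image), ncol(image))
  for (j in seq_along(k))
    tmp <- tmp + k[j] * pad[j:(j + nrow(image) - 1L), , drop = FALSE]
  pad <- tmp[, reflect_idx(ncol(image), rad), drop = FALSE]
  out <- matrix(0, nrow(image), ncol(image))
  for (j in seq_along(k))
    out <- out + k[j] * pad[, j:(j + ncol(image) - 1L), drop = FALSE]
  out
}

# --- rotations and resampling --------------------------------------------

#' Rotate a matrix counter-clockwise by 90 degrees
#' @param m matrix.
#' @export
rot90_ccw <- function(m) t(m)[ncol(m):1, , drop = FALSE]

#' Bilinear affine resampling (rotation about the centre plus scaling)
#'
#' Output pixel (r, c) is sampled from the source at the location obtained
#' by rotating by `-degrees` and scaling by `1/scale` about the image
#' centre, i.e. the image content appears rotated counter-clockwise by
#' `degrees` and magnified by `scale`. Samples outside the source are set
#' to `fill`.
#'
#' @param image source matrix.
#' @param degrees counter-clockwise rotation of the content.
#' @param scale magnification factor (> 0).
#' @param out_dim `c(rows, cols)` of the output (default: source size).
#' @param fill value for out-of-source samples (default mean intensity).
#' @export
warp_affine <- function(image, degrees = 0, scale = 1, out_dim = dim(image),
                        fill = mean(image)) {
  check_gray(image)
  H <- nrow(image); W <- ncol(image)
  Ho <- out_dim[1]; Wo <- out_dim[2]
  th <- degrees * pi / 180
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  oy <- (Ho + 1) / 2; ox <- (Wo + 1) / 2
  cs <- cos(th); sn <- sin(th)
  # y axis up: convert rows to y-up, rotate by -th, scale by 1/scale
  co <- rep(seq_len(Wo), each = Ho) - ox
  ro <- rep(seq_len(Ho), times = Wo) - oy
  xo <- co; yo <- -ro
  xs <- (cs * xo + sn * yo) / scale
  ys <- (-sn * xo + cs * yo) / scale
  cs_src <- xs + cx
  rs_src <- -ys + cy
  r0 <- floor(rs_src); c0 <- floor(cs_src)
  fy <- rs_src - r0; fx <- cs_src - c0
  out <- rep(fill, length(r0))
  inside <- r0 >= 1 & r0 + 1 <= H & c0 >= 1 & c0 + 1 <= W
  idx <- function(r, c) (c - 1L) * H + r
  i <- which(inside)
  if (length(i)) {
    v00 <- image[idx(r0[i], c0[i])]
    v01 <- image[idx(r0[i], c0[i] + 1)]
    v10 <- image[idx(r0[i] + 1, c0[i])]
    v11 <- image[idx(r0[i] + 1, c0[i] + 1)]
    out[i] <- (1 - fy[i]) * (1 - fx[i]) * v00 + (1 - fy[i]) * fx[i] * v01 +
      fy[i] * (1 - fx[i]) * v10 + fy[i] * fx[i] * v11
  }
  matrix(out, Ho, Wo)
}

#' Downsample an image by a factor with Gaussian anti-aliasing
#'
#' @param image source matrix.
#' @param factor size ratio in (0, 1]; 1/sqrt(2) halves the area.
#' @export
downsample <- function(image, factor) {
  stopifnot(factor > 0, factor <= 1)
  if (factor < 1) {
    sigma <- 0.5 * sqrt(1 / factor^2 - 1)
    image <- gaussian_filter(image, sigma)
  }
  out_dim <- pmax(c(3L, 3L), round(dim(image) * factor))
  warp_affine(image, degrees = 0, scale = factor, out_dim = out_dim)
}
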