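# Per-pixel sign- and magnitude-LBP code images on a Gaussian scale stack.
#
# The sign code sets bit p when f(x,y) - f(x_p,y_p) <= 0 (ties give 1, as
# printed); the magnitude code sets bit p when |f(x,y) - f(x_p,y_p)| is at
# or below the adaptive threshold t_p, the mean absolute difference of
# neighbour p over all described pixels. Both codes are invariant to
# affine intensity changes a*f + b (a > 0), which is what makes the
# descriptor robust to illumination.

#' Circular neighbourhood specification
#'
#' @param P number of samples on the circle (>= 1).
#' @param R circle radius in pixels (> 0).
#' @export
neighborhood_spec <- function(P = 8L, R = 1) {
  P <- check_P(P)
  if (!is.numeric(R) || length(R) != 1 || !is.finite(R) || R <= 0)
    stop("R must be a single positive number", call. = FALSE)
  structure(list(P = P, R = R), class = "neighborhood_spec")
}

#' Build the Gaussian scale stack for multi-scale LBP
#'
#' Level i holds the image filtered with an isotropic Gaussian of
#' sigma_i = r_i / 2 where r_i = R_i * sin(pi/P) is the effective sample
#' radius, so ~95% of the filter mass falls within the effective area.
#' Radii follow R_1 = 1, R_i = R_{i-1} * sqrt(2). Filtering is skipped
#' when sigma_i < 0.3.
#'
#' @param image grayscale matrix.
#' @param spec a [neighborhood_spec()] (its R is ignored; radii come from
#'   the schedule).
#' @param n_scales number of levels (>= 1).
#' @return object of class `scale_stack`: list of levels with fields
#'   `index`, `R`, `r_eff`, `sigma`, `image`.
#' @export
build_scale_stack <- function(image, spec = neighborhood_spec(), n_scales = 8L) {
  check_gray(image)
  stopifnot(n_scales >= 1)
  sched <- radii_schedule_raw(spec$P, n_scales)
  Rmax <- sched$R[n_scales]
  if (min(dim(image)) <= 2 * ceiling(Rmax) + 1)
    stop("image too small for the coarsest scale (R = ",
         round(Rmax, 2), ")", call. = FALSE)
  levels <- lapply(seq_len(n_scales), function(i) {
    list(index = i, R = sched$R[i], r_eff = sched$r_eff[i],
         sigma = sched$sigma[i],
         image = gaussian_filter(image, sched$sigma[i]))
  })
  structure(list(P = spec$P, levels = levels), class = "scale_stack")
}

#' @export
print.scale_stack <- function(x, ...) {
  cat("scale_stack: P =", x$P, "-", length(x$levels), "levels, R =",
      paste(round(vapply(x$levels, `[[`, numeric(1), "R"), 3),
            collapse = ", "), "\n")
  invisible(x)
}

radii_schedule_raw <- function(P, S) {
  R <- 2^((seq_len(S) - 1) / 2)       # 1, sqrt2, 2, ...
  r_eff <- R * sin(pi / P)
  sigma <- r_eff / 2
  list(R = R, r_eff = r_eff, sigma = sigma)
}

#' Sample the P circular neighbours at one location
#'
#' Bilinear interpolation at angle 2*pi*p/P, radius R, neighbour 0 east,
#' angles counter-clockwise (y up). Errors when any sample falls outside
#' the image.
#'
#' @param level grayscale matrix.
#' @param x column coordinate (1-based, may be fractional).
#' @param y row coordinate (1-based, may be fractional).
#' @param spec a [neighborhood_spec()].
#' @return numeric vector of P sampled values.
#' @export
sample_circle <- function(level, x, y, spec) {
  check_gray(level)
  off <- neighbor_offsets(spec$P, spec$R)
  vals <- numeric(spec$P)
  for (p in seq_len(spec$P)) {
    cs <- snap_offset(x + off$dx[p])
    rs <- snap_offset(y - off$dy[p])
    r0 <- floor(rs); c0 <- floor(cs)
    fy <- rs - r0; fx <- cs - c0
    rmax <- if (fy > 0) r0 + 1 else r0
    cmax <- if (fx > 0) c0 + 1 else c0
    if (r0 < 1 || c0 < 1 || rmax > nrow(level) || cmax > ncol(level))
      stop("sample point outside image", call. = FALSE)
    v <- (1 - fy) * (1 - fx) * level[r0, c0]
    if (fx > 0) v <- v + (1 - fy) * fx * level[r0, c0 + 1]
    if (fy > 0) v <- v + fy * (1 - fx) * level[r0 + 1, c0]
    if (fy > 0 && fx > 0) v <- v + fy * fx * level[r0 + 1, c0 + 1]
    vals[p] <- v
  }
  vals
}

# Sample all P neighbours for every pixel at once.
# Returns list(values = list of P matrices, valid = matrix TRUE where all
# P samples have their full bilinear support inside the image).
sample_neighbors <- function(level, spec) {
  off <- neighbor_offsets(spec$P, spec$R)
  values <- vector("list", spec$P)
  valid <- NULL
  for (p in seq_len(spec$P)) {
    bs <- bilinear_shift(level, dy_img = -off$dy[p], dx_img = off$dx[p])
    values[[p]] <- bs$values
    valid <- if (is.null(valid)) bs$valid else valid & bs$valid
  }
  list(values = values, valid = valid)
}

# region membership of all P sample points: TRUE where every sample's
# bilinear support lies inside `mask`
samples_in_mask <- function(mask, spec) {
  off <- neighbor_offsets(spec$P, spec$R)
  res <- NULL
  for (p in seq_len(spec$P)) {
    s <- mask_shift_all(mask, dy_img = -off$dy[p], dx_img = off$dx[p])
    res <- if (is.null(res)) s else res & s
  }
  res
}

code_image <- function(codes, valid, P) {
  codes[!valid] <- NA_real_
  structure(list(codes = codes, valid = valid, P = P), class = "code_image")
}

#' @export
print.code_image <- function(x, ...) {
  cat("code_image: P =", x$P, "-", sum(x$valid), "valid pixels of",
      length(x$valid), "\n")
  invisible(x)
}

#' Sign-LBP code image
#'
#' Bit p of the code at (x, y) is set iff
#' `f(x,y) - f(x_p,y_p) <= 0`. Pixels are described only where the centre
#' lies in `region` and every sample point has its bilinear support
#' inside the image; other pixels are flagged invalid.
#'
#' @param level grayscale matrix (one scale-stack level).
#' @param spec a [neighborhood_spec()].
#' @param region logical matrix of centre pixels to describe (default:
#'   whole image).
#' @return object of class `code_image` (fields `codes`, `valid`, `P`).
#' @export
sign_lbp_image <- function(level, spec, region = NULL) {
  check_gray(level)
  if (is.null(region)) region <- matrix(TRUE, nrow(level), ncol(level))
  stopifnot(identical(dim(region), dim(level)))
  sn <- sample_neighbors(level, spec)
  valid <- region & sn$valid
  codes <- matrix(0, nrow(level), ncol(level))
  for (p in seq_len(spec$P))
    codes <- codes + 2^(p - 1) * ((level - sn$values[[p]]) <= 0)
  code_image(codes, valid, spec$P)
}

#' Adaptive magnitude thresholds
#'
#' t_p is the mean of |f(x,y) - f(x_p,y_p)| for neighbour p over all
#' described (valid) pixels of the region.
#'
#' @inheritParams sign_lbp_image
#' @return object of class `magnitude_thresholds`: list with `t` (length
#'   P) and `m` (number of pooled pixels).
#' @export
magnitude_thresholds <- function(level, spec, region = NULL) {
  check_gray(level)
  if (is.null(region)) region <- matrix(TRUE, nrow(level), ncol(level))
  sn <- sample_neighbors(level, spec)
  valid <- region & sn$valid
  m <- sum(valid)
  if (m == 0) stop("no valid pixels for magnitude thresholds", call. = FALSE)
  t <- vapply(seq_len(spec$P), function(p)
    mean(abs(level - sn$values[[p]])[valid]), numeric(1))
  structure(list(t = t, m = m, P = spec$P), class = "magnitude_thresholds")
}

#' Magnitude-LBP code image
#'
#' Bit p is set iff `|f(x,y) - f(x_p,y_p)| - t_p <= 0`.
#'
#' @inheritParams sign_lbp_image
#' @param thresholds a [magnitude_thresholds()] computed on the same level
#'   and region.
#' @export
magnitude_lbp_image <- function(level, spec, thresholds, region = NULL) {
  check_gray(level)
  stopifnot(inherits(thresholds, "magnitude_thresholds"),
            thresholds$P == spec$P)
  if (is.null(region)) region <- matrix(TRUE, nrow(level), ncol(level))
  sn <- sample_neighbors(level, spec)
  valid <- region & sn$valid
  codes <- matrix(0, nrow(level), ncol(level))
  for (p in seq_len(spec$P))
    codes <- codes + 2^(p - 1) *
      ((abs(level - sn$values[[p]]) - thresholds$t[p]) <= 0)
  code_image(codes, valid, spec$P)
}
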