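# Object segmentation for leaf-style images (dark object on near-uniform
# light background) and the radius-dependent interior/border split used by
# the segmentation-aware descriptor variants.

#' Otsu's threshold
#'
#' Maximizes the between-class variance of the 256-bin histogram of
#' min-max normalized intensities; ties broken toward the lower
#' threshold. The returned value is on the original intensity scale:
#' pixels with `image <= threshold` form the lower class.
#'
#' @param image grayscale matrix with at least two distinct values.
#' @export
otsu_threshold <- function(image) {
  check_gray(image)
  lo <- min(image); hi <- max(image)
  if (hi <= lo) stop("constant image has no threshold", call. = FALSE)
  bins <- 256L
  q <- pmin(floor((image - lo) / (hi - lo) * bins), bins - 1L)
  h <- tabulate(q + 1L, nbins = bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * (seq_len(bins) - 1L))
  mu_t <- mu[bins]
  denom <- omega * (1 - omega)
  sigma_b <- ifelse(denom > 0, (mu_t * omega - mu)^2 / denom, -Inf)
  k <- which.max(sigma_b)  # first maximum = lower threshold on ties
  # upper edge of bin k-1 mapped back to intensity scale
  lo + (k - 0.5) / bins * (hi - lo)
}

# 8-connected component labelling by frontier expansion; mask is logical
label_components <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  nb <- c(-1L, 1L, -H, H, -H - 1L, -H + 1L, H - 1L, H + 1L)
  row_of <- function(idx) ((idx - 1L) %% H) + 1L
  cur <- 0L
  todo <- which(mask)
  in_mask <- mask
  while (length(todo) > 0) {
    seed <- todo[1]
    cur <- cur + 1L
    frontier <- seed
    lab[seed] <- cur
    while (length(frontier) > 0) {
      r0 <- row_of(rep(frontier, times = length(nb)))
      cand_all <- as.vector(outer(frontier, nb, `+`))
      rr <- row_of(cand_all)
      ok <- cand_all >= 1 & cand_all <= H * W & abs(rr - r0) <= 1
      cand <- unique(cand_all[ok])
      cand <- cand[in_mask[cand] & lab[cand] == 0L]
      lab[cand] <- cur
      frontier <- cand
    }
    todo <- todo[lab[todo] == 0L]
  }
  lab
}

# fill holes: background flood fill from the frame; unreached background
# becomes foreground
fill_holes <- function(mask) {
  bg <- !mask
  H <- nrow(mask); W <- ncol(mask)
  reach <- matrix(FALSE, H, W)
  frontier <- which(bg & (row(mask) %in% c(1L, H) | col(mask) %in% c(1L, W)))
  reach[frontier] <- TRUE
  nb <- c(-1L, 1L, -H, H)
  row_of <- function(idx) ((idx - 1L) %% H) + 1L
  while (length(frontier) > 0) {
    cand_all <- as.vector(outer(frontier, nb, `+`))
    r0 <- row_of(rep(frontier, times = length(nb)))
    rr <- row_of(cand_all)
    ok <- cand_all >= 1 & cand_all <= H * W & abs(rr - r0) <= 1
    cand <- unique(cand_all[ok])
    cand <- cand[bg[cand] & !reach[cand]]
    reach[cand] <- TRUE
    frontier <- cand
  }
  mask | (bg & !reach)
}

#' Segment a leaf-style object
#'
#' Thresholds with Otsu's method (object assumed darker than background,
#' or `polarity = "auto"` to pick the side that touches the image frame
#' less), keeps the largest 8-connected component and fills its holes.
#'
#' @param image grayscale matrix.
#' @param polarity "dark" (default), "light", or "auto".
#' @return logical matrix (TRUE = object).
#' @export
leaf_mask <- function(image, polarity = c("dark", "light", "auto")) {
  polarity <- match.arg(polarity)
  th <- otsu_threshold(image)
  dark <- image <= th
  mask <- switch(polarity,
    dark = dark,
    light = !dark,
    auto = {
      frame <- row(image) %in% c(1L, nrow(image)) |
        col(image) %in% c(1L, ncol(image))
      if (mean(dark[frame]) <= mean((!dark)[frame])) dark else !dark
    })
  if (!any(mask))
    stop("segmentation failure: empty foreground", call. = FALSE)
  lab <- label_components(mask)
  sizes <- tabulate(lab[lab > 0L])
  keep <- lab == which.max(sizes)
  fill_holes(keep)
}

#' Split a mask into interior and border at a given LBP radius
#'
#' A mask pixel belongs to the border when at least one of its P sample
#' points at radius R falls outside the mask (the image frame counts as
#' outside); the remaining mask pixels are the interior. Membership of a
#' sample point uses its full bilinear support: the point is inside only
#' if every pixel with nonzero interpolation weight is inside the mask.
#'
#' @param mask logical matrix.
#' @param spec a [neighborhood_spec()] giving P and R.
#' @return object of class `region_pair`: list with logical `interior`,
#'   `border`, and `R`.
#' @export
region_split <- function(mask, spec) {
  stopifnot(is.matrix(mask), is.logical(mask))
  inside <- samples_in_mask(mask, spec)
  interior <- mask & inside
  border <- mask & !inside
  structure(list(interior = interior, border = border, R = spec$R),
            class = "region_pair")
}
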