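# Assembly of per-scale descriptors into sliding multi-scale descriptors.
#
# Radii grow geometrically with step sqrt(2) from R_1 = 1; descriptors of
# c adjacent scales are concatenated into one vector, and the window
# slides over the S = c + n_conc - 1 scales producing n_conc vectors per
# image region. Matching a rescaled texture then amounts to matching a
# shifted window, which is what the max-posterior fusion over windows
# exploits at prediction time.

#' Multi-scale descriptor configuration
#'
#' @param P circular samples per neighbourhood.
#' @param scales total number of scales S.
#' @param window number of adjacent scales c concatenated per descriptor.
#' @param mode "full" (all orbits) or "uniform" (uniform patterns plus
#'   three pooled bins).
#' @param plus include the adjacent-orbit first-coefficient invariants.
#' @return object of class `ffirst_config`; `n_conc = S - c + 1`.
#' @export
ffirst_config <- function(P = 8L, scales = 8L, window = 5L,
                          mode = c("full", "uniform"), plus = TRUE) {
  mode <- match.arg(mode)
  P <- check_P(P)
  stopifnot(window >= 1, scales >= window)
  structure(list(P = P, scales = as.integer(scales),
                 window = as.integer(window),
                 n_conc = as.integer(scales - window + 1L),
                 mode = mode, plus = plus),
            class = "ffirst_config")
}

#' @export
print.ffirst_config <- function(x, ...) {
  cat("ffirst_config: P =", x$P, ", S =", x$scales, ", c =", x$window,
      "(", x$n_conc, "windows ), mode =", x$mode,
      if (x$plus) "+plus" else "", "\n")
  invisible(x)
}

config_fingerprint <- function(config) {
  paste(config$P, config$scales, config$window, config$mode,
        config$plus, sep = "|")
}

#' Radii schedule of a configuration
#'
#' R_1 = 1, R_i = R_{i-1} * sqrt(2); effective radius
#' r_i = R_i * sin(pi/P); Gaussian sigma_i = r_i / 2.
#'
#' @param config an [ffirst_config()].
#' @return data.frame with columns `R`, `r_eff`, `sigma`.
#' @export
radii_schedule <- function(config) {
  s <- radii_schedule_raw(config$P, config$scales)
  data.frame(R = s$R, r_eff = s$r_eff, sigma = s$sigma)
}

#' Sliding concatenation of per-scale descriptor vectors
#'
#' @param per_scale list of S numeric vectors (equal length).
#' @param c_window window length c.
#' @return matrix with `S - c + 1` rows; row j is the concatenation of
#'   scales j..j+c-1.
#' @export
sliding_concat <- function(per_scale, c_window) {
  S <- length(per_scale)
  if (S < c_window) stop("fewer scales than window length", call. = FALSE)
  n_conc <- S - c_window + 1L
  t(vapply(seq_len(n_conc), function(j)
    unlist(per_scale[j:(j + c_window - 1L)], use.names = FALSE),
    numeric(length(per_scale[[1]]) * c_window)))
}

resolve_region <- function(mask, spec, variant) {
  if (variant == "all") return(mask)
  rp <- region_split(mask, spec)
  if (variant == "interior") rp$interior else rp$border
}

#' Extract the multi-scale rotation-invariant descriptor of a region
#'
#' Builds the Gaussian scale stack, resolves the described region per
#' scale (for "interior"/"border" the split depends on the scale's
#' radius), computes sign- and magnitude-LBP histogram-Fourier features
#' per scale and concatenates sliding windows of `window` adjacent scales
#' into `n_conc` vectors, each L1-normalized. Windows in which every
#' scale had an empty region are flagged empty (zero vectors).
#'
#' @param image grayscale matrix.
#' @param mask logical matrix or NULL (whole image); required for
#'   variants other than "all".
#' @param config an [ffirst_config()].
#' @param variant "all", "interior" or "border".
#' @return object of class `ffirst_descriptor`: list with `vectors`
#'   (n_conc x c*D matrix), `empty` (per-window flag), `variant`,
#'   `fingerprint`.
#' @export
extract_ffirst <- function(image, mask = NULL, config = ffirst_config(),
                           variant = c("all", "interior", "border")) {
  variant <- match.arg(variant)
  check_gray(image)
  if (is.null(mask)) {
    mask <- matrix(TRUE, nrow(image), ncol(image))
  }
  stopifnot(identical(dim(mask), dim(image)))
  table <- orbit_table_cached(config$P)
  stack <- build_scale_stack(image, neighborhood_spec(config$P, 1),
                             config$scales)
  per_scale <- vector("list", config$scales)
  scale_empty <- logical(config$scales)
  for (i in seq_len(config$scales)) {
    lev <- stack$levels[[i]]
    spec_i <- neighborhood_spec(config$P, lev$R)
    region <- resolve_region(mask, spec_i, variant)
    if (!any(region)) {
      layout <- descriptor_layout(config$P, config$mode, config$plus)
      per_scale[[i]] <- numeric(max(layout$end))
      scale_empty[i] <- TRUE
      next
    }
    sn <- sample_neighbors(lev$image, spec_i)
    valid <- region & sn$valid
    if (!any(valid)) {
      layout <- descriptor_layout(config$P, config$mode, config$plus)
      per_scale[[i]] <- numeric(max(layout$end))
      scale_empty[i] <- TRUE
      next
    }
    sc <- matrix(0, nrow(image), ncol(image))
    mc <- matrix(0, nrow(image), ncol(image))
    tp <- numeric(config$P)
    for (p in seq_len(config$P)) {
      diff <- lev$image - sn$values[[p]]
      sc <- sc + 2^(p - 1) * (diff <= 0)
      tp[p] <- mean(abs(diff)[valid])
    }
    for (p in seq_len(config$P)) {
      diff <- lev$image - sn$values[[p]]
      mc <- mc + 2^(p - 1) * ((abs(diff) - tp[p]) <= 0)
    }
    sd_i <- scale_descriptor(code_image(sc, valid, config$P),
                             code_image(mc, valid, config$P),
                             table, config$mode, config$plus)
    per_scale[[i]] <- sd_i$values
    scale_empty[i] <- sd_i$empty
  }
  vectors <- sliding_concat(per_scale, config$window)
  empty <- vapply(seq_len(config$n_conc), function(j)
    all(scale_empty[j:(j + config$window - 1L)]), logical(1))
  # L1 normalization per window
  for (j in seq_len(nrow(vectors))) {
    s <- sum(abs(vectors[j, ]))
    if (s > 0) vectors[j, ] <- vectors[j, ] / s
  }
  structure(list(vectors = vectors, empty = empty, variant = variant,
                 fingerprint = config_fingerprint(config)),
            class = "ffirst_descriptor")
}

#' @export
print.ffirst_descriptor <- function(x, ...) {
  cat("ffirst_descriptor:", nrow(x$vectors), "windows x",
      ncol(x$vectors), "dims, variant =", x$variant,
      "(", sum(x$empty), "empty )\n")
  invisible(x)
}

#' Per-scale descriptor sequence of an image region
#'
#' Convenience wrapper returning the S un-concatenated per-scale vectors
#' (used e.g. to study scale-shift behaviour).
#'
#' @inheritParams extract_ffirst
#' @return matrix S x D.
#' @export
per_scale_sequence <- function(image, mask = NULL, config = ffirst_config(),
                               variant = "all") {
  cfg1 <- config
  cfg1$window <- 1L
  cfg1$n_conc <- cfg1$scales
  d <- extract_ffirst(image, mask, cfg1, variant)
  d$vectors
}
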