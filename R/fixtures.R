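# Deterministic synthetic fixtures: class-structured isotropic textures
# and leaf-like objects with controlled rotation and scale.
#
# Texture classes are isotropic multi-band noises. Because the
# descriptor under test is rotation-invariant and the evaluation applies
# random scaling, class identity must not be carried by orientation, and
# cannot be carried by absolute frequency alone: rescaling by s maps a
# band at f to a band at f/s, so self-similar single-band spectra of
# different classes collide under the stated scale range. Class identity
# is therefore a spectral code: a fixed grid of 5 radial frequency slots
# in geometric progression (step 1.68, wider than the 1.25/0.8 = 1.5625
# scale spread, so a rescaled slot grid can never align with a shifted
# copy of itself), with each class activating a distinct PAIR of slots.
# The set of active frequency ratios is invariant to rotation and scale,
# and any two classes differ in at least two slots.

#' Texture class specification
#'
#' An isotropic texture built as a sum of radial band-pass noise
#' components at frequencies `f0 * ratios` with amplitudes `amps`.
#'
#' @param class_id integer class index (>= 1).
#' @param f0 base frequency (cycles/pixel).
#' @param bandwidth relative bandwidth (sigma / centre) of each band.
#' @param ratio frequency ratio of a secondary band to the primary
#'   (two-band shorthand; ignored when `ratios` is given).
#' @param amp2 amplitude of the secondary band (two-band shorthand).
#' @param ratios multiples of `f0` at which bands sit (overrides the
#'   two-band shorthand).
#' @param amps amplitudes, same length as `ratios`.
#' @param contrast intensity standard deviation of the texture in [0,1]
#'   units.
#' @export
texture_spec <- function(class_id, f0, bandwidth = 0.15, ratio = 2,
                         amp2 = 0.8, ratios = NULL, amps = NULL,
                         contrast = 0.12) {
  if (is.null(ratios)) {
    stopifnot(ratio > 1, amp2 >= 0)
    ratios <- c(1, ratio)
    amps <- c(1, amp2)
  }
  stopifnot(f0 > 0, bandwidth > 0, length(ratios) == length(amps),
            all(ratios > 0), all(amps >= 0), any(amps > 0))
  structure(list(class_id = class_id, f0 = f0, bandwidth = bandwidth,
                 ratios = ratios, amps = amps, contrast = contrast),
            class = "texture_spec")
}

# default class layout: 5 frequency slots at f0 * 1.68^(0:4); class k
# activates the k-th pair of slots (lexicographic over combn(5, 2)),
# so all classes have equal energy and pairwise slot-Hamming distance
# >= 2; up to 15 classes by continuing with slot triples
default_texture_specs <- function(n_classes, f0 = 0.044) {
  slots <- 1.68^(0:4)
  pairs <- utils::combn(5, 2)
  sets <- lapply(seq_len(ncol(pairs)), function(j) pairs[, j])
  if (n_classes > ncol(pairs)) {
    triples <- utils::combn(5, 3)
    sets <- c(sets, lapply(seq_len(ncol(triples)), function(j) triples[, j]))
  }
  if (n_classes > length(sets))
    stop("default layout supports at most ", length(sets), " classes",
         call. = FALSE)
  lapply(seq_len(n_classes), function(k) {
    amps <- numeric(5)
    amps[sets[[k]]] <- 1
    texture_spec(class_id = k, f0 = f0, ratios = slots, amps = amps)
  })
}

# radial band-pass filtered Gaussian noise field of size n x n
bandpass_noise <- function(n, f0, rel_bw) {
  noise <- matrix(stats::rnorm(n * n), n, n)
  fr <- stats::fft(noise)
  fx <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / n
  rad <- sqrt(outer(fx^2, fx^2, `+`))
  g <- exp(-((rad - f0)^2) / (2 * (rel_bw * f0)^2))
  g[1, 1] <- 0
  out <- Re(stats::fft(fr * g, inverse = TRUE)) / (n * n)
  out / stats::sd(out)
}

# render one texture instance (pre rotation/scale) at field size n
render_texture_field <- function(spec, n) {
  base <- matrix(0, n, n)
  for (j in seq_along(spec$ratios)) {
    if (spec$amps[j] <= 0) next
    base <- base + spec$amps[j] *
      bandpass_noise(n, spec$f0 * spec$ratios[j], spec$bandwidth)
  }
  base <- base / stats::sd(base)
  0.5 + spec$contrast * base
}

max_band_freq <- function(spec) max(spec$f0 * spec$ratios[spec$amps > 0])

#' Generate one texture instance
#'
#' Deterministic in (spec, seed): the same call returns bit-identical
#' pixels. The field is synthesized at a size large enough that rotating
#' by `degrees` and scaling by `scale` leaves no out-of-field samples in
#' the final `size x size` crop.
#'
#' @param spec a [texture_spec()].
#' @param size output side length in pixels.
#' @param degrees content rotation (counter-clockwise).
#' @param scale content magnification (instance scale).
#' @param seed integer seed.
#' @return grayscale matrix in [0, 1].
#' @export
gen_texture <- function(spec, size = 128L, degrees = 0, scale = 1,
                        seed = 1L) {
  if (max_band_freq(spec) / min(scale, 1) > 0.45)
    stop("band exceeds the Nyquist guard after scaling", call. = FALSE)
  field_n <- ceiling(size * sqrt(2) / min(scale, 1)) + 8L
  set.seed(as.integer(seed %% .Machine$integer.max))
  field <- render_texture_field(spec, field_n)
  img <- warp_affine(field, degrees = degrees, scale = scale,
                     out_dim = c(size, size), fill = 0.5)
  pmin(pmax(img, 0), 1)
}

#' Generate a class-structured texture dataset
#'
#' Each instance is independently rotated and scaled uniformly within the
#' given ranges. All randomness derives from `seed`; the same arguments
#' reproduce the dataset bit-identically.
#'
#' @param n_classes number of classes (>= 2).
#' @param n_per_class instances per class.
#' @param rotation_range length-2 degrees interval (default 0..360).
#' @param scale_range length-2 magnification interval (default
#'   0.8..1.25).
#' @param seed integer base seed.
#' @param size image side length.
#' @param specs optional list of [texture_spec()]s overriding the default
#'   class layout.
#' @param dir optional directory; when given, images are written as PGM
#'   with a `manifest.csv` (path, label) and a provenance CSV.
#' @return list with `images` (list of matrices), `labels`,
#'   `provenance` (data.frame with rotation/scale/seed per instance).
#' @export
gen_texture_dataset <- function(n_classes = 10L, n_per_class = 10L,
                                rotation_range = c(0, 360),
                                scale_range = c(0.8, 1.25),
                                seed = 0L, size = 128L, specs = NULL,
                                dir = NULL) {
  if (n_classes < 2) stop("need at least two classes", call. = FALSE)
  if (is.null(specs)) specs <- default_texture_specs(n_classes)
  stopifnot(length(specs) == n_classes)
  for (s in specs)
    if (max_band_freq(s) / min(scale_range) > 0.45)
      stop("class band exceeds the Nyquist guard at maximum shrink",
           call. = FALSE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  total <- n_classes * n_per_class
  rot <- stats::runif(total, rotation_range[1], rotation_range[2])
  sc <- stats::runif(total, scale_range[1], scale_range[2])
  inst_seed <- sample.int(2^30, total)
  images <- vector("list", total)
  labels <- character(total)
  prov <- data.frame(index = seq_len(total), class = integer(total),
                     rotation = rot, scale = sc, seed = inst_seed)
  i <- 0L
  for (k in seq_len(n_classes)) {
    for (j in seq_len(n_per_class)) {
      i <- i + 1L
      images[[i]] <- gen_texture(specs[[k]], size = size,
                                 degrees = rot[i], scale = sc[i],
                                 seed = inst_seed[i])
      labels[i] <- sprintf("class%02d", k)
      prov$class[i] <- k
    }
  }
  out <- list(images = images, labels = labels, provenance = prov,
              specs = specs)
  if (!is.null(dir)) write_dataset(out, dir)
  out
}

write_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(ds$images))
  for (i in seq_along(ds$images)) {
    paths[i] <- sprintf("img%04d.pgm", i)
    write_pgm(ds$images[[i]] * 255, file.path(dir, paths[i]))
    if (!is.null(ds$masks))
      write_pgm(ds$masks[[i]] * 255, file.path(dir, sprintf("mask%04d.pgm", i)))
  }
  manifest <- data.frame(path = paths, label = ds$labels)
  if (!is.null(ds$masks))
    manifest$mask_path <- sprintf("mask%04d.pgm", seq_along(ds$images))
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  utils::write.csv(ds$provenance, file.path(dir, "provenance.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Leaf-like object specification
#'
#' An ellipse with a serrated contour, interior texture, and a distinct
#' texture band along the border, on a near-white background.
#'
#' @param class_id class index.
#' @param axes length-2 semi-axes in pixels.
#' @param serration_amp contour modulation amplitude (fraction of
#'   radius).
#' @param serration_freq number of serration periods around the contour.
#' @param interior a [texture_spec()] for the leaf interior.
#' @param border_band a [texture_spec()] for the border band.
#' @param band_width width of the border texture band in pixels.
#' @param background background intensity in [0, 1].
#' @export
leaf_spec <- function(class_id, axes = c(44, 30), serration_amp = 0.04,
                      serration_freq = 12,
                      interior = texture_spec(class_id, 0.12, amp2 = 0),
                      border_band = texture_spec(class_id, 0.25, amp2 = 0),
                      band_width = 2, background = 0.92) {
  if (any(axes <= 2)) stop("degenerate leaf axes", call. = FALSE)
  structure(list(class_id = class_id, axes = axes,
                 serration_amp = serration_amp,
                 serration_freq = serration_freq, interior = interior,
                 border_band = border_band, band_width = band_width,
                 background = background),
            class = "leaf_spec")
}

# signed "radius fraction" of pixels relative to the serrated ellipse:
# <= 1 inside
leaf_rho <- function(H, W, spec, degrees = 0) {
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  x <- matrix(rep(seq_len(W), each = H), H, W) - cx
  y <- -(matrix(rep(seq_len(H), times = W), H, W) - cy)
  th <- degrees * pi / 180
  xr <- cos(th) * x + sin(th) * y
  yr <- -sin(th) * x + cos(th) * y
  phi <- atan2(yr / spec$axes[2], xr / spec$axes[1])
  r_mod <- 1 + spec$serration_amp * sin(spec$serration_freq * phi)
  sqrt((xr / spec$axes[1])^2 + (yr / spec$axes[2])^2) / r_mod
}

#' Generate one leaf-like image with its true mask
#'
#' @param spec a [leaf_spec()].
#' @param size image side length.
#' @param degrees object rotation.
#' @param seed integer seed.
#' @return list with `image` (matrix in [0,1]) and `mask` (logical).
#' @export
gen_leaf <- function(spec, size = 128L, degrees = 0, seed = 1L) {
  set.seed(as.integer(seed %% .Machine$integer.max))
  H <- W <- size
  rho <- leaf_rho(H, W, spec, degrees)
  mask <- rho <= 1
  if (!any(mask)) stop("leaf does not intersect the image", call. = FALSE)
  # distance-like band coordinate: rho close to 1 near the contour
  band <- mask & (rho >= 1 - spec$band_width / mean(spec$axes))
  tex_int <- render_texture_field(spec$interior, size)
  tex_bor <- render_texture_field(spec$border_band, size)
  img <- matrix(spec$background, H, W) +
    0.01 * matrix(stats::rnorm(H * W), H, W)
  leaf_int <- 0.35 + spec$interior$contrast * (tex_int - 0.5) / 0.12
  leaf_bor <- 0.30 + spec$border_band$contrast * (tex_bor - 0.5) / 0.12
  img[mask] <- leaf_int[mask]
  img[band] <- leaf_bor[band]
  list(image = pmin(pmax(img, 0), 1), mask = mask)
}

#' Generate a leaf dataset with ground-truth masks
#'
#' @param specs list of [leaf_spec()]s (>= 2).
#' @param n_per_class instances per class.
#' @param seed integer base seed.
#' @param size image side length.
#' @param rotation_range degrees interval for random object rotation.
#' @param dir optional output directory (PGM + manifest).
#' @return list with `images`, `masks`, `labels`, `provenance`.
#' @export
gen_leaf_dataset <- function(specs, n_per_class = 10L, seed = 0L,
                             size = 128L, rotation_range = c(0, 360),
                             dir = NULL) {
  if (length(specs) < 2) stop("need at least two leaf specs", call. = FALSE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  total <- length(specs) * n_per_class
  rot <- stats::runif(total, rotation_range[1], rotation_range[2])
  inst_seed <- sample.int(2^30, total)
  images <- vector("list", total); masks <- vector("list", total)
  labels <- character(total)
  prov <- data.frame(index = seq_len(total), class = integer(total),
                     rotation = rot, seed = inst_seed)
  i <- 0L
  for (k in seq_along(specs)) {
    for (j in seq_len(n_per_class)) {
      i <- i + 1L
      lf <- gen_leaf(specs[[k]], size = size, degrees = rot[i],
                     seed = inst_seed[i])
      images[[i]] <- lf$image; masks[[i]] <- lf$mask
      labels[i] <- sprintf("leaf%02d", k)
      prov$class[i] <- k
    }
  }
  out <- list(images = images, masks = masks, labels = labels,
              provenance = prov, specs = specs)
  if (!is.null(dir)) write_dataset(out, dir)
  out
}

#' Default leaf classes differing only at the border
#'
#' Identical interior texture and overall shape; classes differ in
#' serration and border-band frequency only. Used to demonstrate that
#' border description carries discriminative information that interior
#' description misses.
#'
#' @param n_classes number of classes (2..4).
#' @export
border_only_leaf_specs <- function(n_classes = 3L) {
  stopifnot(n_classes >= 2, n_classes <= 4)
  serr_amp <- c(0.015, 0.05, 0.09, 0.13)
  serr_freq <- c(6, 13, 20, 27)
  border_f <- c(0.10, 0.18, 0.26, 0.34)
  interior <- texture_spec(0, f0 = 0.12, amp2 = 0, contrast = 0.10)
  lapply(seq_len(n_classes), function(k)
    leaf_spec(k, axes = c(44, 30), serration_amp = serr_amp[k],
              serration_freq = serr_freq[k],
              interior = interior,
              border_band = texture_spec(k, border_f[k], amp2 = 0,
                                         contrast = 0.10),
              band_width = 2))
}
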