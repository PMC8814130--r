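# Deterministic geometric normalisation (crop + area-average downsample)
# and stochastic train-time augmentation (horizontal flip, multiplicative
# brightness, small rotation). The evaluation path (training = FALSE) is a
# pure function of the input pixels.

#' Preprocessing parameters
#'
#' Raw B-scans are first cropped to the retina-bearing region and then
#' downsampled to the network input size. Defaults follow the clinical
#' pipeline (596 x 1264 raw, 380 x 764 crop, 163 x 254 network input); the
#' `"small"` and `"tiny"` presets scale those numbers proportionally for
#' the 128 x 256 and 64 x 128 synthetic image presets.
#'
#' @param crop_height,crop_width crop window size in pixels.
#' @param crop_origin integer `(row, col)` of the window's top-left corner,
#'   1-based, or `NULL` for a centred window (fovea-centred scans make the
#'   centre crop the natural default).
#' @param target_height,target_width output size after downsampling.
#' @param preset `"full"`, `"small"` or `"tiny"`; explicit arguments
#'   override preset values.
#' @return object of class `preprocess_params`.
#' @export
preprocess_params <- function(crop_height = NULL, crop_width = NULL,
                              crop_origin = NULL,
                              target_height = NULL, target_width = NULL,
                              preset = c("full", "small", "tiny")) {
  preset <- match.arg(preset)
  def <- switch(preset,
                full = c(380L, 764L, 163L, 254L),
                small = c(82L, 155L, 35L, 52L),
                tiny = c(41L, 77L, 18L, 26L))
  p <- list(
    crop_height = as.integer(crop_height %||% def[1]),
    crop_width = as.integer(crop_width %||% def[2]),
    crop_origin = crop_origin,
    target_height = as.integer(target_height %||% def[3]),
    target_width = as.integer(target_width %||% def[4]))
  if (p$target_height <= 0 || p$target_width <= 0)
    stop("target dimensions must be strictly positive")
  if (p$crop_height <= 0 || p$crop_width <= 0)
    stop("crop dimensions must be strictly positive")
  structure(p, class = "preprocess_params")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Augmentation parameters
#'
#' Train-time augmentation, applied in the declared order
#' flip -> brightness -> rotation: horizontal flip with probability
#' `hflip_probability`, a multiplicative brightness factor drawn uniformly
#' from `brightness_range` (clipped to `[0, 255]`), and rotation by an angle
#' drawn uniformly from `[-max_rotation_deg, +max_rotation_deg]` about the
#' image centre (bilinear resampling, exposed corners filled with black).
#'
#' @param hflip_probability probability of a horizontal flip.
#' @param brightness_range multiplicative interval, default `c(0.7, 1.3)`.
#' @param max_rotation_deg maximum absolute rotation, degrees (default 15).
#' @param enabled master switch; augmentation only runs on training inputs.
#' @return object of class `augment_params`.
#' @export
augment_params <- function(hflip_probability = 0.5,
                           brightness_range = c(0.7, 1.3),
                           max_rotation_deg = 15, enabled = TRUE) {
  if (hflip_probability < 0 || hflip_probability > 1)
    stop("hflip_probability must be in [0, 1]")
  if (length(brightness_range) != 2 || any(brightness_range <= 0) ||
      brightness_range[1] > brightness_range[2])
    stop("brightness_range endpoints must be positive with low <= high")
  if (max_rotation_deg < 0) stop("max_rotation_deg must be >= 0")
  structure(list(hflip_probability = hflip_probability,
                 brightness_range = brightness_range,
                 max_rotation_deg = max_rotation_deg,
                 enabled = isTRUE(enabled)),
            class = "augment_params")
}

#' Crop a B-scan to the retina-bearing window
#'
#' @param image a `slice_image`.
#' @param p a [preprocess_params()] object.
#' @return a `slice_image` of size `crop_height x crop_width x 3`; pixels
#'   are an untouched sub-grid of the input, lesion flag and slice index
#'   preserved.
#' @export
crop_slice <- function(image, p = preprocess_params()) {
  d <- dim(image$pixels)
  org <- p$crop_origin %||% c((d[1] - p$crop_height) %/% 2L + 1L,
                              (d[2] - p$crop_width) %/% 2L + 1L)
  r0 <- as.integer(org[1]); c0 <- as.integer(org[2])
  if (r0 < 1 || r0 + p$crop_height - 1L > d[1])
    stop("crop window exceeds image height (", d[1], " rows, window ",
         r0, ":", r0 + p$crop_height - 1L, ")")
  if (c0 < 1 || c0 + p$crop_width - 1L > d[2])
    stop("crop window exceeds image width (", d[2], " cols, window ",
         c0, ":", c0 + p$crop_width - 1L, ")")
  px <- image$pixels[r0:(r0 + p$crop_height - 1L),
                     c0:(c0 + p$crop_width - 1L), , drop = FALSE]
  new_slice_image_keep(px, image)
}

new_slice_image_keep <- function(pixels, template) {
  structure(list(pixels = pixels, slice_index = template$slice_index,
                 is_lesion_cut = template$is_lesion_cut),
            class = "slice_image")
}

# Area-average resampling weights: rows of the returned n_out x n_in matrix
# are the fractional overlaps of each output interval with the input pixels,
# normalised to sum to 1 (mass-preserving for constant images).
resample_weights <- function(n_in, n_out) {
  w <- matrix(0, n_out, n_in)
  scale <- n_in / n_out
  for (i in seq_len(n_out)) {
    lo <- (i - 1) * scale; hi <- i * scale
    j0 <- floor(lo) + 1L; j1 <- ceiling(hi)
    for (j in j0:min(j1, n_in))
      w[i, j] <- min(hi, j) - max(lo, j - 1)
  }
  w / rowSums(w)
}

#' Downsample a cropped B-scan to the network input size
#'
#' Area-average (anti-aliased) resampling: each output pixel is the exact
#' mean of the input area it covers, the standard choice for large
#' downscale factors.
#'
#' @inheritParams crop_slice
#' @return a `slice_image` of size `target_height x target_width x 3`
#'   (numeric pixels).
#' @export
downsample_slice <- function(image, p = preprocess_params()) {
  d <- dim(image$pixels)
  if (d[1] < p$target_height || d[2] < p$target_width)
    stop("downsample target (", p$target_height, "x", p$target_width,
         ") exceeds input size (", d[1], "x", d[2], "); upsampling is out",
         " of contract")
  wr <- resample_weights(d[1], p$target_height)
  wc <- resample_weights(d[2], p$target_width)
  out <- array(0, c(p$target_height, p$target_width, 3L))
  for (ch in 1:3) out[, , ch] <- wr %*% image$pixels[, , ch] %*% t(wc)
  new_slice_image_keep(out, image)
}

rotate_bilinear <- function(px, angle_deg) {
  if (angle_deg == 0) return(px)
  d <- dim(px)
  h <- d[1]; w <- d[2]
  th <- angle_deg * pi / 180
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  dr <- matrix(seq_len(h) - cy, h, w)
  dc <- matrix(seq_len(w) - cx, h, w, byrow = TRUE)
  sr <- cy + cos(th) * dr - sin(th) * dc
  sc <- cx + sin(th) * dr + cos(th) * dc
  r1 <- floor(sr); c1 <- floor(sc)
  fr <- sr - r1; fc <- sc - c1
  out <- array(0, d)
  gather <- function(mat, ri, ci) {
    v <- numeric(length(ri))
    ok <- ri >= 1 & ri <= h & ci >= 1 & ci <= w
    v[ok] <- mat[cbind(ri[ok], ci[ok])]
    v
  }
  for (ch in seq_len(d[3])) {
    m <- px[, , ch]
    v <- (1 - fr) * (1 - fc) * gather(m, r1, c1) +
      fr * (1 - fc) * gather(m, r1 + 1, c1) +
      (1 - fr) * fc * gather(m, r1, c1 + 1) +
      fr * fc * gather(m, r1 + 1, c1 + 1)
    out[, , ch] <- v
  }
  out
}

#' Augment one training image
#'
#' Applies, in order: horizontal flip (probability
#' `a$hflip_probability`), multiplicative brightness drawn uniformly from
#' `a$brightness_range` with clipping to `[0, 255]`, and rotation by an
#' angle drawn uniformly from `[-max_rotation_deg, max_rotation_deg]`
#' (bilinear, black fill). Output dimensions are unchanged. Draws come from
#' the current RNG stream; seed upstream for reproducibility.
#'
#' @param image a `slice_image`.
#' @param a an [augment_params()] object.
#' @return augmented `slice_image`.
#' @export
augment_slice <- function(image, a = augment_params()) {
  px <- image$pixels
  if (a$hflip_probability > 0 && stats::runif(1) < a$hflip_probability)
    px <- px[, rev(seq_len(dim(px)[2])), , drop = FALSE]
  f <- stats::runif(1, a$brightness_range[1], a$brightness_range[2])
  if (f != 1) px <- pmin(pmax(px * f, 0), 255)
  if (a$max_rotation_deg > 0) {
    ang <- stats::runif(1, -a$max_rotation_deg, a$max_rotation_deg)
    px <- rotate_bilinear(px, ang)
  }
  new_slice_image_keep(px, image)
}

#' Preprocess a whole volume
#'
#' Crops then downsamples every slice; augmentation is applied per slice
#' only when `training = TRUE` and `a$enabled`. Slice order is preserved.
#'
#' @param case an `oct_case`.
#' @param p a [preprocess_params()] object.
#' @param a an [augment_params()] object.
#' @param training logical; the evaluation path (`FALSE`) is deterministic.
#' @param seed optional integer seeding the augmentation draws.
#' @return list of preprocessed `slice_image`s in slice order.
#' @export
preprocess_volume <- function(case, p = preprocess_params(),
                              a = augment_params(), training = FALSE,
                              seed = NULL) {
  with_seed(seed, {
    idx <- order(vapply(case$slices, `[[`, integer(1), "slice_index"))
    lapply(case$slices[idx], function(s) {
      s <- downsample_slice(crop_slice(s, p), p)
      if (training && a$enabled) s <- augment_slice(s, a) else s
    })
  })
}
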