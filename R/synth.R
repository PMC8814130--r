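# Synthetic SD-OCT volume generator: layered retina-like background with
# class-dependent lesion phenotypes (fluid dome for acute CSC, outer-band
# atrophy for chronic CSC), confined to a contiguous central run of
# "lesion cuts" within each 25-slice volume.

CSC_LABELS <- c("acute", "chronic", "normal")

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

check_label <- function(label) {
  if (!(is.character(label) && length(label) == 1 && label %in% CSC_LABELS))
    stop("unknown class label: ", paste(label, collapse = ","),
         " (expected one of ", paste(CSC_LABELS, collapse = ", "), ")",
         call. = FALSE)
  label
}

#' Parameters of the synthetic OCT-volume generator
#'
#' Defines the geometry and signal model of the simulated B-scans. The
#' defaults emulate the clinical acquisition the pipeline targets: volumes of
#' 25 horizontal axial scans rendered as 596 x 1264 grayscale-as-RGB images,
#' with the lesion visible on a contiguous central run of 5-15 slices for
#' CSC cases. A `"small"` preset (128 x 256) keeps desk-scale experiments
#' fast while exercising the same code paths.
#'
#' @param image_height,image_width raw B-scan size in pixels.
#' @param n_slices_per_case number of B-scans per volume.
#' @param lesion_slice_range integer `(min, max)`: the number of lesion cuts
#'   in a CSC volume is drawn uniformly from this range.
#' @param noise_sd additive Gaussian pixel noise, gray levels (0-255 scale).
#' @param class_signal named list of per-class shape parameters; see
#'   Details.
#' @param preset `"full"` (596 x 1264) or `"small"` (128 x 256); explicit
#'   height/width arguments override the preset.
#'
#' @details `class_signal$acute` controls the hypo-intense subretinal-fluid
#' dome (`dome_height_frac`, `dome_width_frac`, fractions of image size, and
#' `dome_intensity`, the fluid gray level). `class_signal$chronic` controls
#' the photoreceptor/RPE atrophy (`atrophy_depth_frac`, `atrophy_width_frac`,
#' `irregularity` in `[0, 1]`). Lesion severity tapers towards the ends of
#' the lesion run, so edge cuts are subtler than central cuts.
#'
#' @return an object of class `synth_params`.
#' @export
synth_params <- function(image_height = NULL, image_width = NULL,
                         n_slices_per_case = 25L,
                         lesion_slice_range = c(5L, 15L),
                         noise_sd = 10,
                         class_signal = NULL,
                         preset = c("full", "small")) {
  preset <- match.arg(preset)
  dims <- if (preset == "small") c(128L, 256L) else c(596L, 1264L)
  h <- as.integer(if (is.null(image_height)) dims[1] else image_height)
  w <- as.integer(if (is.null(image_width)) dims[2] else image_width)
  n <- as.integer(n_slices_per_case)
  rng <- as.integer(lesion_slice_range)
  if (h < 16 || w < 16) stop("image dimensions must be at least 16 pixels")
  if (n < 1) stop("n_slices_per_case must be >= 1")
  if (length(rng) != 2 || rng[1] < 1 || rng[2] > n || rng[1] > rng[2])
    stop("lesion_slice_range must lie within [1, n_slices_per_case]")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  sig <- list(
    acute = list(dome_height_frac = 0.16, dome_width_frac = 0.18,
                 dome_intensity = 35),
    chronic = list(atrophy_depth_frac = 0.10, atrophy_width_frac = 0.22,
                   irregularity = 0.6))
  if (!is.null(class_signal))
    sig <- utils::modifyList(sig, class_signal)
  structure(list(image_height = h, image_width = w, n_slices_per_case = n,
                 lesion_slice_range = rng, noise_sd = noise_sd,
                 class_signal = sig),
            class = "synth_params")
}

# Layered background geometry shared by all classes; returns per-column
# retina top/bottom rows and the clean (noise-free) background image.
synth_background <- function(p) {
  h <- p$image_height; w <- p$image_width
  x <- seq_len(w)
  rel <- (x - w / 2) / (w / 2)
  top <- 0.32 * h + 0.08 * h * rel^2        # gentle foveal curvature
  bot <- top + 0.28 * h
  rowm <- matrix(seq_len(h), h, w)
  topm <- matrix(top, h, w, byrow = TRUE)
  botm <- matrix(bot, h, w, byrow = TRUE)
  img <- matrix(25, h, w)                    # vitreous / deep background
  img[rowm >= botm & rowm < botm + 0.08 * h] <- 45          # choroid glow
  img[rowm >= topm + 0.14 * h & rowm < botm - 0.04 * h] <- 90 # outer band
  img[rowm >= topm + 0.03 * h & rowm < topm + 0.14 * h] <- 130 # inner band
  img[rowm >= topm & rowm < topm + 0.03 * h] <- 200         # ILM line
  img[rowm >= botm - 0.04 * h & rowm < botm] <- 210         # RPE line
  list(img = img, top = top, bot = bot, rowm = rowm, topm = topm,
       botm = botm)
}

#' Region of the acute subretinal-fluid dome at full severity
#'
#' Row/column index ranges of the hypo-intense dome drawn by
#' [render_slice()] for acute lesion cuts, used to probe the class signal
#' (e.g. comparing region means between an acute lesion cut and a normal
#' slice).
#'
#' @param params a [synth_params()] object.
#' @return list with integer vectors `rows` and `cols`.
#' @export
acute_dome_region <- function(params) {
  h <- params$image_height; w <- params$image_width
  cx <- w / 2
  a <- params$class_signal$acute$dome_width_frac * w
  top0 <- 0.32 * h                 # retina top at image centre
  bot0 <- top0 + 0.28 * h
  rpe_top <- bot0 - 0.04 * h
  hh <- params$class_signal$acute$dome_height_frac * h
  rows <- seq.int(max(1L, floor(rpe_top - hh * 0.9)), floor(rpe_top) - 1L)
  cols <- seq.int(max(1L, floor(cx - a * 0.5)), min(w, ceiling(cx + a * 0.5)))
  list(rows = rows, cols = cols)
}

#' Render one synthetic B-scan
#'
#' Draws a layered retina-like background (ILM, inner and outer bands, RPE,
#' choroid glow) plus Gaussian noise. For an acute lesion cut a smooth
#' hypo-intense dome (subretinal fluid) is drawn above the RPE; for a
#' chronic lesion cut the outer band is locally thinned and made irregular
#' (photoreceptor/RPE atrophy). Normal slices and non-lesion cuts contain
#' bands and noise only.
#'
#' @param label one of `"acute"`, `"chronic"`, `"normal"`.
#' @param is_lesion logical: does this slice show the lesion? Must be
#'   `FALSE` for `"normal"`.
#' @param params a [synth_params()] object.
#' @param severity lesion strength in `(0, 1]`; tapered automatically along
#'   the lesion run by [generate_case()].
#' @param slice_index 0-based position of the slice in its volume.
#' @param seed optional integer; when given, rendering is a pure function of
#'   `(arguments, seed)`.
#' @return a `slice_image`: list with `pixels` (H x W x 3 integer array in
#'   `[0, 255]`), `slice_index` and `is_lesion_cut`.
#' @export
render_slice <- function(label, is_lesion, params = synth_params(),
                         severity = 1, slice_index = 0L, seed = NULL) {
  check_label(label)
  if (label == "normal" && is_lesion)
    stop("normal slices cannot be lesion cuts")
  with_seed(seed, {
    h <- params$image_height; w <- params$image_width
    bg <- synth_background(params)
    img <- bg$img
    if (is_lesion) {
      x <- seq_len(w)
      cx <- w / 2 + stats::runif(1, -0.03, 0.03) * w
      if (label == "acute") {
        sg <- params$class_signal$acute
        a <- sg$dome_width_frac * w * (0.6 + 0.4 * severity)
        hh <- sg$dome_height_frac * h * severity
        dome <- sqrt(pmax(0, 1 - ((x - cx) / a)^2))
        rpe_top <- bg$botm - 0.04 * h
        upper <- rpe_top - matrix(hh * dome, h, w, byrow = TRUE)
        sel <- bg$rowm >= upper & bg$rowm < rpe_top &
          matrix(dome > 0, h, w, byrow = TRUE)
        img[sel] <- sg$dome_intensity
      } else {
        sg <- params$class_signal$chronic
        a <- sg$atrophy_width_frac * w * (0.6 + 0.4 * severity)
        depth <- sg$atrophy_depth_frac * h * severity
        phase <- stats::runif(1, 0, 2 * pi)
        jag <- 0.5 + 0.5 * sin(2 * pi * 6 * x / w + phase)
        prof <- pmax(0, 1 - abs((x - cx) / a))
        d <- depth * (0.4 + sg$irregularity * jag) * prof
        lower <- bg$botm                       # erode outer band + RPE
        upper <- lower - 0.04 * h - matrix(d, h, w, byrow = TRUE)
        sel <- bg$rowm >= upper & bg$rowm < lower &
          matrix(prof > 0, h, w, byrow = TRUE)
        img[sel] <- 55                          # atrophic, hypo-reflective
        dimsel <- bg$rowm >= bg$topm + 0.14 * h & bg$rowm < upper &
          matrix(prof > 0.3, h, w, byrow = TRUE)
        img[dimsel] <- img[dimsel] - 25 * severity
      }
    }
    if (params$noise_sd > 0)
      img <- img + matrix(stats::rnorm(h * w, 0, params$noise_sd), h, w)
    img <- round(pmin(255, pmax(0, img)))
    px <- array(0L, c(h, w, 3L))
    px[, , 1] <- as.integer(img); px[, , 2] <- px[, , 1]
    px[, , 3] <- px[, , 1]
    new_slice_image(px, slice_index, is_lesion)
  })
}

new_slice_image <- function(pixels, slice_index, is_lesion_cut) {
  structure(list(pixels = pixels, slice_index = as.integer(slice_index),
                 is_lesion_cut = isTRUE(is_lesion_cut)),
            class = "slice_image")
}

#' Assign lesion cuts within a volume
#'
#' Normal volumes get an all-`FALSE` mask. CSC volumes get one contiguous
#' run of `TRUE` flags — real macular lesions span adjacent B-scans — whose
#' length is drawn uniformly from `params$lesion_slice_range` and whose
#' centre is drawn near the volume midline.
#'
#' @inheritParams render_slice
#' @return logical vector of length `params$n_slices_per_case`.
#' @export
assign_lesion_cuts <- function(label, params = synth_params(), seed = NULL) {
  check_label(label)
  n <- params$n_slices_per_case
  if (label == "normal") return(rep(FALSE, n))
  with_seed(seed, {
    r <- params$lesion_slice_range
    len <- if (r[1] == r[2]) r[1] else sample(r[1]:r[2], 1)
    mid <- (n + 1) / 2
    jitter_max <- max(0, floor((n - len) / 2))
    js <- seq.int(-jitter_max, jitter_max)
    centre <- mid + js[sample.int(length(js), 1)] * 0.5
    start <- max(1L, min(n - len + 1L, as.integer(round(centre - len / 2))))
    mask <- rep(FALSE, n)
    mask[start:(start + len - 1L)] <- TRUE
    mask
  })
}

#' Generate one synthetic case (patient volume)
#'
#' Composes [assign_lesion_cuts()] and [render_slice()]: lesion severity is
#' tapered (cosine) from the centre of the lesion run towards its ends, so
#' edge cuts carry a weaker signal and per-slice classification stays
#' imperfect at realistic noise levels.
#'
#' @param label case label: `"acute"`, `"chronic"` or `"normal"`.
#' @param params a [synth_params()] object.
#' @param case_id identifier string.
#' @param seed optional integer for full determinism.
#' @return an `oct_case`: list with `case_id`, `label`, and `slices` (list
#'   of `slice_image`, ordered by `slice_index`).
#' @export
generate_case <- function(label, params = synth_params(),
                          case_id = "case0001", seed = NULL) {
  check_label(label)
  with_seed(seed, {
    mask <- assign_lesion_cuts(label, params)
    run <- which(mask)
    slices <- vector("list", params$n_slices_per_case)
    for (i in seq_len(params$n_slices_per_case)) {
      sev <- 1
      if (mask[i] && length(run) > 1) {
        centre <- mean(range(run))
        half <- (max(run) - min(run)) / 2 + 0.5
        sev <- 0.4 + 0.6 * cos(pi / 2 * abs(i - centre) / half)
      }
      slices[[i]] <- render_slice(label, mask[i], params, severity = sev,
                                  slice_index = i - 1L)
    }
    structure(list(case_id = case_id, label = label, slices = slices),
              class = "oct_case")
  })
}

#' Generate a labelled synthetic dataset
#'
#' Produces `n_normal + n_acute + n_chronic` cases with unique ids. The
#' `"table1"` cohort preset (82 normal, 109 acute, 106 chronic; 25 slices
#' each, 7425 images in total) is available through
#' [generate_dataset_preset()]. Each case draws from its own RNG stream
#' derived from `seed` and the case index, so generation is reproducible
#' and order-independent.
#'
#' @param n_normal,n_acute,n_chronic non-negative case counts.
#' @param params a [synth_params()] object.
#' @param seed integer master seed.
#' @return list of `oct_case` objects.
#' @export
generate_dataset <- function(n_normal, n_acute, n_chronic,
                             params = synth_params(), seed = 1L) {
  counts <- c(normal = n_normal, acute = n_acute, chronic = n_chronic)
  if (any(counts < 0)) stop("case counts must be non-negative")
  labels <- rep(c("normal", "acute", "chronic"), counts)
  cases <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    case_seed <- (as.numeric(seed) * 48271 + i * 16807) %% 2147483629 + 1
    cases[[i]] <- generate_case(labels[i], params,
                                case_id = sprintf("case%04d", i),
                                seed = as.integer(case_seed))
  }
  cases
}

#' @rdname generate_dataset
#' @param preset cohort preset name; `"table1"` is the full clinical cohort
#'   composition (82/109/106), `"small"` a 20/20/20 desk-scale cohort.
#' @export
generate_dataset_preset <- function(preset = c("table1", "small"),
                                    params = synth_params(), seed = 1L) {
  preset <- match.arg(preset)
  n <- if (preset == "table1") c(82L, 109L, 106L) else c(20L, 20L, 20L)
  generate_dataset(n[1], n[2], n[3], params, seed)
}

#' @export
print.oct_case <- function(x, ...) {
  cat(sprintf("<oct_case %s> label=%s, %d slices, %d lesion cuts\n",
              x$case_id, x$label, length(x$slices),
              sum(vapply(x$slices, `[[`, logical(1), "is_lesion_cut"))))
  invisible(x)
}

case_labels <- function(cases)
  vapply(cases, `[[`, character(1), "label")

case_ids <- function(cases)
  vapply(cases, `[[`, character(1), "case_id")

lesion_mask <- function(case)
  vapply(case$slices, `[[`, logical(1), "is_lesion_cut")

n_slices_total <- function(cases)
  sum(vapply(cases, function(cs) length(cs$slices), integer(1)))
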