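# Spacing-aware preprocessing: intensity normalisation, physical-space
# resampling, pad-or-crop to the fixed network grid, and additive-noise
# augmentation.  Stage order follows the pipeline: normalise -> resample ->
# pad/crop, with noise last and train-time only.

#' Preprocessing configuration
#'
#' @param target_spacing Either the string `"keep"` (no resampling, the
#'   default for phantom work) or a length-3 mm spacing to resample to.
#' @param target_shape Length-3 voxel grid the network consumes; every axis
#'   must be divisible by 16 so that four stride-2 stages divide evenly.
#' @param normalization `"zscore"` (per-volume mean 0, sd 1) or `"minmax"`
#'   (range \[0, 1\]).
#' @param pad_value Intensity used to fill when padding images (0 after
#'   z-scoring is approximately the background mean).
#' @param noise_sigma Standard deviation of the additive Gaussian noise
#'   augmentation, in normalised intensity units; 0 disables it.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(target_spacing = "keep",
                              target_shape = c(128L, 128L, 48L),
                              normalization = c("zscore", "minmax"),
                              pad_value = 0,
                              noise_sigma = 0.05) {
  normalization <- match.arg(normalization)
  target_shape <- as.integer(target_shape)
  if (length(target_shape) != 3L || any(target_shape <= 0))
    stop("target_shape must be three positive integers")
  bad <- which(target_shape %% 16L != 0L)
  if (length(bad))
    stop(sprintf("target_shape axis %d (%d voxels) is not divisible by 16",
                 bad[1], target_shape[bad[1]]))
  if (!identical(target_spacing, "keep")) {
    target_spacing <- as.numeric(target_spacing)
    if (length(target_spacing) != 3L || any(target_spacing <= 0))
      stop("target_spacing must be \"keep\" or three positive values")
  }
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  structure(list(target_spacing = target_spacing, target_shape = target_shape,
                 normalization = normalization, pad_value = pad_value,
                 noise_sigma = noise_sigma),
            class = "preprocess_config")
}

#' Normalise volume intensities
#'
#' `zscore` standardises to per-volume mean 0 and (population) standard
#' deviation 1; `minmax` rescales affinely to \[0, 1\].  Constant volumes map
#' to all zeros under both modes.
#'
#' @param vol An [image_volume].
#' @param mode `"zscore"` or `"minmax"`.
#' @return A normalised [image_volume] on the same grid.
#' @export
normalize_intensity <- function(vol, mode = c("zscore", "minmax")) {
  if (length(mode) == 1L && !mode %in% c("zscore", "minmax"))
    stop(sprintf("unknown normalization mode '%s'", mode))
  mode <- match.arg(mode)
  x <- vol$data
  if (mode == "zscore") {
    mu <- mean(x)
    sg <- sqrt(mean((x - mu)^2))
    y <- if (sg < 1e-8) array(0, dim(x)) else (x - mu) / sg
  } else {
    lo <- min(x); hi <- max(x)
    y <- if (hi - lo < 1e-8) array(0, dim(x)) else (x - lo) / (hi - lo)
  }
  image_volume(y, vol$spacing, vol$origin)
}

resample_shape <- function(shape, spacing, target_spacing) {
  pmax(1L, as.integer(floor(shape * spacing / target_spacing + 0.5)))
}

#' Resample a volume to a target physical spacing
#'
#' The output grid has `round(shape * spacing / target_spacing)` voxels per
#' axis (minimum 1) at exactly the target spacing.  Images use trilinear
#' interpolation; masks must use `"nearest"` so they remain binary.
#'
#' @param vol An [image_volume] or [label_volume].
#' @param target_spacing Length-3 positive mm spacing.
#' @param interpolation `"linear"` or `"nearest"`.
#' @return A volume of the same class on the new grid.
#' @export
resample <- function(vol, target_spacing, interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  target_spacing <- as.numeric(target_spacing)
  if (length(target_spacing) != 3L || any(!is.finite(target_spacing)) || any(target_spacing <= 0))
    stop("target spacing must be three strictly positive values")
  shape <- dim(vol$data)
  if (all(abs(target_spacing - vol$spacing) < 1e-12)) return(vol)
  out_shape <- resample_shape(shape, vol$spacing, target_spacing)
  scale <- target_spacing / vol$spacing     # source voxels per output voxel
  x <- vol$data
  dim(x) <- c(shape, 1L)
  y <- cpp_resize3d(x, as.integer(c(shape, 1L)), as.integer(out_shape),
                    scale, interpolation == "nearest")
  dim(y) <- out_shape
  if (inherits(vol, "label_volume"))
    label_volume(y, target_spacing, vol$origin)
  else
    image_volume(y, target_spacing, vol$origin)
}

pad_crop_array <- function(a, target_shape, pad_value) {
  d <- dim(a)
  out <- array(pad_value, target_shape)
  # source range per axis (crop: symmetric, extra voxel removed high side)
  src_lo <- pmax(0L, (d - target_shape) %/% 2L)
  n <- pmin(d, target_shape)
  # destination range per axis (pad: symmetric, extra voxel on high side)
  dst_lo <- pmax(0L, (target_shape - d) %/% 2L)
  out[dst_lo[1] + seq_len(n[1]), dst_lo[2] + seq_len(n[2]), dst_lo[3] + seq_len(n[3])] <-
    a[src_lo[1] + seq_len(n[1]), src_lo[2] + seq_len(n[2]), src_lo[3] + seq_len(n[3])]
  out
}

#' Pad or crop a volume to an exact target shape
#'
#' Per axis: smaller inputs are padded symmetrically with `pad_value` (the
#' extra voxel goes on the high side when the difference is odd); larger
#' inputs are centre-cropped (the extra voxel is removed from the high side).
#' Masks always pad with 0.
#'
#' @param vol An [image_volume] or [label_volume].
#' @param target_shape Length-3 positive integer shape.
#' @param pad_value Fill intensity for images.
#' @return A volume of the same class with exactly `target_shape` voxels.
#' @export
pad_or_crop <- function(vol, target_shape, pad_value = 0) {
  target_shape <- as.integer(target_shape)
  if (length(target_shape) != 3L || any(target_shape <= 0))
    stop("target_shape must be three positive integers")
  if (identical(dim(vol$data), target_shape)) return(vol)
  if (inherits(vol, "label_volume")) {
    label_volume(pad_crop_array(vol$data, target_shape, 0), vol$spacing, vol$origin)
  } else {
    image_volume(pad_crop_array(vol$data, target_shape, pad_value), vol$spacing, vol$origin)
  }
}

with_preserved_rng <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Add Gaussian noise to an image volume
#'
#' Adds zero-mean normal noise of standard deviation `sigma` element-wise;
#' deterministic for a given `seed`; `sigma = 0` is the identity.
#'
#' @param vol An [image_volume].
#' @param sigma Noise standard deviation (>= 0) in intensity units.
#' @param seed Optional integer seed; the caller's RNG state is preserved.
#' @return A noisy [image_volume].
#' @export
add_noise <- function(vol, sigma, seed = NULL) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(vol)
  noise <- with_preserved_rng(seed, rnorm(length(vol$data), 0, sigma))
  image_volume(vol$data + noise, vol$spacing, vol$origin)
}

#' Preprocess one image/label case
#'
#' Applies normalise -> resample -> pad/crop to the image, and resample
#' (nearest) -> pad/crop (zero fill) to the label; Gaussian noise is added to
#' the image only when `augment` is set.  Outputs share `target_shape` and,
#' when resampling is enabled, the target spacing.
#'
#' @param image An [image_volume].
#' @param label A [label_volume] on the same grid.
#' @param config A [preprocess_config].
#' @param augment Logical; add noise at `config$noise_sigma`?
#' @param seed Optional seed for the augmentation noise.
#' @return List with preprocessed `image` and `label`.
#' @export
preprocess_case <- function(image, label, config = preprocess_config(),
                            augment = FALSE, seed = NULL) {
  stopifnot(inherits(config, "preprocess_config"))
  if (!identical(dim(image$data), dim(label$data)))
    stop("misaligned pair: image and label shapes differ")
  img <- normalize_intensity(image, config$normalization)
  lab <- label
  if (!identical(config$target_spacing, "keep")) {
    img <- resample(img, config$target_spacing, "linear")
    lab <- resample(lab, config$target_spacing, "nearest")
  }
  img <- pad_or_crop(img, config$target_shape, config$pad_value)
  lab <- pad_or_crop(lab, config$target_shape)
  if (augment && config$noise_sigma > 0)
    img <- add_noise(img, config$noise_sigma, seed)
  list(image = img, label = lab)
}
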