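# Synthetic 3D phantoms with the statistical character of T2-weighted pelvic
# MRI of uterine fibroids: a smooth low-frequency background, a brighter
# uterus-like ellipsoid, one to a few small randomly oriented ellipsoidal
# lesions at deliberately low contrast, anisotropic voxel spacing (fine
# in-plane, thick slices) and additive Gaussian noise.  Ellipsoids are a
# stand-in for real anatomy: they exercise every pipeline operator without
# any claim of anatomical realism.

#' Phantom generator configuration
#'
#' Defaults echo the acquisition geometry of a 512-matrix / 6 mm-slice
#' pelvic protocol (0.76 x 0.76 x 6 mm voxels on a 128x128x48 grid) and the
#' "small, low-contrast, variably placed" lesion regime: 1-3 lesions of 5-25
#' mm semi-axis at 0.25 normalised-intensity contrast against the local
#' background, with noise of sd 0.05.
#'
#' @param shape Length-3 voxel grid.
#' @param spacing Length-3 mm voxel spacing.
#' @param n_lesions Length-2 integer range (min, max) of lesion count.
#' @param lesion_radius_mm Length-2 range the per-axis semi-axes (mm) are
#'   drawn from.
#' @param lesion_contrast Intensity offset of lesion vs surrounding tissue in
#'   normalised units (>= 0; lesions are rendered hypointense).
#' @param background_texture_scale Amplitude of the smooth background field.
#' @param noise_sigma Additive Gaussian noise sd.
#' @param max_foreground_fraction Cap on the total lesion volume fraction;
#'   later lesions are shrunk to respect it (keeps the class-imbalance
#'   regime that motivates the Dice objective).
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(shape = c(128L, 128L, 48L),
                           spacing = c(0.76, 0.76, 6.0),
                           n_lesions = c(1L, 3L),
                           lesion_radius_mm = c(5, 25),
                           lesion_contrast = 0.25,
                           background_texture_scale = 0.1,
                           noise_sigma = 0.05,
                           max_foreground_fraction = 0.05) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape <= 0)) stop("shape must be three positive integers")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) stop("spacing must be three positive values")
  n_lesions <- as.integer(n_lesions)
  if (length(n_lesions) == 1L) n_lesions <- rep(n_lesions, 2L)
  if (any(n_lesions < 1L) || n_lesions[1] > n_lesions[2]) stop("invalid n_lesions range")
  if (length(lesion_radius_mm) == 1L) lesion_radius_mm <- rep(lesion_radius_mm, 2L)
  if (any(lesion_radius_mm <= 0) || lesion_radius_mm[1] > lesion_radius_mm[2])
    stop("lesion radii must be positive and ordered")
  if (lesion_contrast < 0) stop("lesion_contrast must be >= 0")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  structure(list(shape = shape, spacing = spacing, n_lesions = n_lesions,
                 lesion_radius_mm = as.numeric(lesion_radius_mm),
                 lesion_contrast = lesion_contrast,
                 background_texture_scale = background_texture_scale,
                 noise_sigma = noise_sigma,
                 max_foreground_fraction = max_foreground_fraction),
            class = "phantom_config")
}

#' A small phantom configuration for desk-scale tests
#'
#' 32x32x16 voxels at mildly anisotropic 1 x 1 x 2 mm spacing with 3-6 mm
#' lesions -- the companion of [tiny_network_config()].
#'
#' @param ... Overrides passed to [phantom_config()].
#' @return A `phantom_config`.
#' @export
tiny_phantom_config <- function(...) {
  args <- modifyList(list(shape = c(32L, 32L, 16L), spacing = c(1, 1, 2),
                          lesion_radius_mm = c(3, 6), n_lesions = c(1L, 2L)),
                     list(...))
  do.call(phantom_config, args)
}

random_rotation <- function() {
  m <- matrix(rnorm(9), 3, 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# mm coordinates of every voxel centre along one axis
axis_mm <- function(n, sp) (seq_len(n) - 1) * sp

smooth_field <- function(shape, coarse = 8L) {
  cs <- pmax(2L, pmin(shape, coarse))
  field <- array(rnorm(prod(cs)), c(cs, 1L))
  up <- cpp_resize3d(field, as.integer(c(cs, 1L)), as.integer(shape),
                     as.numeric(cs / shape), FALSE)
  dim(up) <- shape
  up
}

ellipsoid_mask <- function(shape, spacing, center_mm, radii_mm, rot) {
  xs <- axis_mm(shape[1], spacing[1]) - center_mm[1]
  ys <- axis_mm(shape[2], spacing[2]) - center_mm[2]
  zs <- axis_mm(shape[3], spacing[3]) - center_mm[3]
  # bounding box in voxel indices to keep the quadratic form evaluation local
  rmax <- max(radii_mm)
  ix <- which(abs(xs) <= rmax); iy <- which(abs(ys) <= rmax); iz <- which(abs(zs) <= rmax)
  mask <- array(0, shape)
  if (!length(ix) || !length(iy) || !length(iz)) return(mask)
  gx <- xs[ix]; gy <- ys[iy]; gz <- zs[iz]
  co <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  local_ <- co %*% rot                     # rotate into the ellipsoid frame
  q <- (local_[, 1] / radii_mm[1])^2 + (local_[, 2] / radii_mm[2])^2 +
    (local_[, 3] / radii_mm[3])^2
  sub <- array(as.numeric(q <= 1), c(length(ix), length(iy), length(iz)))
  mask[ix, iy, iz] <- sub
  mask
}

#' Generate one synthetic image/label pair
#'
#' Deterministic in `seed`.  The image is a smooth random background plus a
#' brighter uterus-like ellipsoid; lesions are randomly oriented ellipsoids
#' placed inside it (never nearer than 2 voxels to the volume border),
#' rendered as an exact intensity offset of `-lesion_contrast`, with
#' Gaussian noise added last.  The label is the union of the lesion
#' ellipsoids.
#'
#' @param config A [phantom_config()].
#' @param seed Integer seed.
#' @return List with `image` ([image_volume]), `label` ([label_volume]) and
#'   `stats` (lesion count and foreground fraction).
#' @export
generate_phantom <- function(config = phantom_config(), seed = 1L) {
  stopifnot(inherits(config, "phantom_config"))
  with_preserved_rng(seed, {
    shape <- config$shape; spacing <- config$spacing
    extent <- shape * spacing
    rmin <- config$lesion_radius_mm[1]
    # margin: lesion bounding radius + 2 voxels inside the border on each axis
    if (any(2 * rmin + (2 + 2) * spacing >= extent))
      stop("lesion radius too large for the volume shape")
    img <- 0.2 + config$background_texture_scale * smooth_field(shape)
    # uterus-like bright ellipsoid around the volume centre
    ut_center <- extent / 2 + rnorm(3, 0, extent / 30)
    ut_radii <- extent * runif(3, 0.28, 0.38)
    ut <- ellipsoid_mask(shape, spacing, ut_center, ut_radii, diag(3))
    img <- img + 0.3 * ut
    label <- array(0, shape)
    n_les <- if (config$n_lesions[1] == config$n_lesions[2]) config$n_lesions[1]
    else sample(seq(config$n_lesions[1], config$n_lesions[2]), 1L)
    vol_mm3 <- prod(extent)
    placed <- 0L
    fg_mm3 <- 0
    for (l in seq_len(n_les)) {
      radii <- runif(3, config$lesion_radius_mm[1], config$lesion_radius_mm[2])
      # cap total analytic lesion volume to keep lesions a small fraction
      les_mm3 <- 4 / 3 * pi * prod(radii)
      budget <- config$max_foreground_fraction * vol_mm3 - fg_mm3
      if (les_mm3 > budget) {
        sc <- (budget / les_mm3)^(1 / 3)
        if (sc < rmin / max(radii)) break   # no room left for a meaningful lesion
        radii <- radii * sc
        les_mm3 <- 4 / 3 * pi * prod(radii)
      }
      rot <- random_rotation()
      rbound <- max(radii)
      lo <- rbound + 2 * spacing
      hi <- extent - rbound - 2 * spacing
      if (any(hi <= lo)) stop("lesion radius too large for the volume shape")
      ok <- FALSE
      for (try_ in 1:20) {
        center <- lo + runif(3) * (hi - lo)
        # prefer centres inside the uterus ellipsoid
        rel <- (center - ut_center) / ut_radii
        if (sum(rel^2) <= 1 || try_ > 10) { ok <- TRUE; break }
      }
      if (!ok) next
      m <- ellipsoid_mask(shape, spacing, center, radii, rot)
      label <- pmax(label, m)
      fg_mm3 <- fg_mm3 + les_mm3
      placed <- placed + 1L
    }
    img <- img - config$lesion_contrast * label   # hypointense lesions
    if (config$noise_sigma > 0)
      img <- img + rnorm(length(img), 0, config$noise_sigma)
    dim(img) <- shape
    list(image = image_volume(img, spacing),
         label = label_volume(label, spacing),
         stats = list(n_lesions = placed,
                      foreground_fraction = mean(label)))
  })
}

#' Generate and write a phantom dataset
#'
#' Writes `n_cases` NIfTI image/label pairs to `out_dir` plus a
#' `manifest.csv` (case id, file paths, lesion count, foreground fraction).
#' Per-case seeds are `seed + index`, so a dataset is reproducible and
#' extendable.
#'
#' @param n_cases Number of cases (>= 1).
#' @param config A [phantom_config()].
#' @param seed Base seed.
#' @param out_dir Output directory (created if needed).
#' @return The manifest data.frame, invisibly written to
#'   `out_dir/manifest.csv`.
#' @export
generate_dataset <- function(n_cases, config = phantom_config(), seed = 1L,
                             out_dir) {
  if (n_cases < 1) stop("n_cases must be >= 1")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_len(n_cases), function(i) {
    ph <- generate_phantom(config, seed = seed + i)
    cid <- sprintf("case%03d", i)
    ip <- file.path(out_dir, paste0(cid, "_image.nii.gz"))
    lp <- file.path(out_dir, paste0(cid, "_label.nii.gz"))
    write_volume(ph$image, ip)
    write_mask(ph$label, lp)
    data.frame(case_id = cid, image = ip, label = lp,
               n_lesions = ph$stats$n_lesions,
               foreground_fraction = ph$stats$foreground_fraction)
  })
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  manifest
}
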