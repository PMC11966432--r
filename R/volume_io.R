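# NIfTI volume input/output and image/label pairing.
#
# Axis order is fixed internally as (x, y, slice); NIfTI stores exactly this
# order fastest-first, so no reordering is needed at the boundary.  All
# geometry downstream uses voxel spacing only; the origin is carried through
# untouched and re-emitted on write.

#' Construct an image volume
#'
#' An `image_volume` is a 3D array of real intensities together with the
#' physical voxel spacing in millimetres along each axis (in-plane x,
#' in-plane y, slice) and a world-coordinate origin that is carried but never
#' used in computation.
#'
#' @param data 3D numeric array, axes ordered (x, y, slice).
#' @param spacing Numeric length-3, mm per voxel along each axis; all > 0.
#' @param origin Numeric length-3 world coordinate of the first voxel (mm).
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  d <- dim(data)
  if (is.null(d) || length(d) != 3L) stop("unsupported dimensionality: data must be a 3D array")
  if (any(d < 1L)) stop("all three dimensions must be >= 1")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three strictly positive finite values")
  if (anyNA(data) || any(!is.finite(data))) stop("corrupt volume: non-finite voxel values")
  structure(list(data = unname(data) * 1.0, spacing = spacing,
                 origin = as.numeric(origin)),
            class = "image_volume")
}

#' Construct a binary label volume
#'
#' A `label_volume` is a 3D array restricted to values {0, 1} (1 = lesion
#' foreground), with voxel spacing in mm.  When loaded as part of a case it
#' must match its image voxel-for-voxel.
#'
#' @inheritParams image_volume
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  d <- dim(data)
  if (is.null(d) || length(d) != 3L) stop("unsupported dimensionality: data must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be three strictly positive values")
  if (anyNA(data) || any(!is.finite(data))) stop("corrupt volume: non-finite voxel values")
  vals <- unique(as.vector(data))
  if (!all(vals %in% c(0, 1))) stop("label values must lie in {0, 1}")
  structure(list(data = unname(data) * 1.0, spacing = spacing,
                 origin = as.numeric(origin)),
            class = "label_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume %s, spacing %s mm, range [%.3g, %.3g]>\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  cat(sprintf("<label_volume %s, spacing %s mm, %d foreground voxels>\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              as.integer(sum(x$data))))
  invisible(x)
}

nifti_spacing <- function(img) {
  pd <- RNifti::pixdim(img)
  as.numeric(pd[1:3])
}

nifti_origin <- function(img) {
  xf <- try(RNifti::xform(img), silent = TRUE)
  if (inherits(xf, "try-error") || is.null(dim(xf))) return(c(0, 0, 0))
  as.numeric(xf[1:3, 4])
}

read_raw_nifti <- function(path) {
  if (!file.exists(path)) stop(sprintf("not found: %s", path))
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  d <- dim(a)
  if (length(d) == 4L) {
    if (d[4] != 1L) stop("unsupported dimensionality: 4D volume with more than one channel")
    dim(a) <- d[1:3]
  } else if (length(d) != 3L) {
    stop(sprintf("unsupported dimensionality: %dD volume", length(d)))
  }
  if (anyNA(a) || any(!is.finite(a))) stop(sprintf("corrupt volume: non-finite voxels in %s", path))
  a <- array(as.numeric(a), dim(a))   # strip the nifti header attributes
  list(data = a, spacing = nifti_spacing(img), origin = nifti_origin(img))
}

#' Read a NIfTI image volume
#'
#' Intensities are returned as stored (after the format's own scl
#' slope/intercept); the voxel spacing is taken from the header pixdim.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return An [image_volume].
#' @export
read_volume <- function(path) {
  r <- read_raw_nifti(path)
  image_volume(r$data, r$spacing, r$origin)
}

#' Read an image/label pair as one case
#'
#' The label is binarised (any value greater than 0.5 becomes 1) and the pair
#' is validated: shapes must be identical and spacings equal within a
#' relative tolerance of 1e-3.
#'
#' @param image_path,label_path NIfTI file paths.
#' @return A list with elements `image` ([image_volume]) and `label`
#'   ([label_volume]).
#' @export
read_case <- function(image_path, label_path) {
  img <- read_volume(image_path)
  lr <- read_raw_nifti(label_path)
  lab_data <- (lr$data > 0.5) * 1.0
  if (!identical(dim(img$data), dim(lab_data)))
    stop("misaligned pair: image and label shapes differ")
  if (any(abs(lr$spacing - img$spacing) > 1e-3 * pmax(abs(img$spacing), abs(lr$spacing))))
    stop("misaligned pair: image and label spacing differ beyond tolerance")
  list(image = img,
       label = label_volume(lab_data, img$spacing, lr$origin))
}

build_nifti <- function(data, spacing, origin) {
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- spacing
  if (any(origin != 0)) {
    aff <- diag(c(spacing, 1))
    aff[1:3, 4] <- origin
    RNifti::qform(img) <- structure(aff, code = 2L)
  }
  img
}

#' Write an image volume to NIfTI
#'
#' Images are stored as 32-bit float with spacing encoded in the header.
#'
#' @param vol An [image_volume].
#' @param path Output path (`.nii` or `.nii.gz`); parent directory must exist.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "image_volume"))
  if (!dir.exists(dirname(path))) stop(sprintf("cannot write %s: directory does not exist", path))
  img <- build_nifti(vol$data, vol$spacing, vol$origin)
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Write a binary mask to NIfTI
#'
#' Masks are stored as unsigned 8-bit integers.
#'
#' @param mask A [label_volume].
#' @param path Output path; parent directory must exist.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "label_volume"))
  if (!dir.exists(dirname(path))) stop(sprintf("cannot write %s: directory does not exist", path))
  img <- build_nifti(mask$data, mask$spacing, mask$origin)
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}
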