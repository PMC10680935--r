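#' Construct a volume
#'
#' A volume is a 3D scalar lattice with voxel spacing (mm) and a 4x4
#' voxel-to-world affine.  It carries images, bias fields and masks
#' throughout the package.
#'
#' @param data 3D numeric array; all values must be finite.
#' @param spacing Numeric length-3, per-axis voxel size in mm (all > 0).
#' @param affine Optional 4x4 voxel-to-world matrix; defaults to a diagonal
#'   scaling by `spacing`.
#' @return An object of class `bn_volume`: a list with elements `data`,
#'   `spacing` and `affine`.
#' @examples
#' v <- as_volume(array(1, c(8, 8, 8)), spacing = c(1, 1, 1.2))
#' dim(v$data)
#' @export
as_volume <- function(data, spacing = c(1, 1, 1), affine = NULL) {
  if (inherits(data, "bn_volume")) return(data)
  data <- unclass(data)
  if (length(dim(data)) != 3L) {
    stop("volume data must have exactly 3 axes, got ",
         length(dim(data)), call. = FALSE)
  }
  if (!all(is.finite(data))) {
    stop("volume data contains non-finite values", call. = FALSE)
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("spacing must be 3 positive finite numbers", call. = FALSE)
  }
  if (is.null(affine)) affine <- diag(c(spacing, 1))
  stopifnot(is.matrix(affine), all(dim(affine) == c(4, 4)))
  structure(list(data = data, spacing = spacing, affine = affine),
            class = "bn_volume")
}

#' @export
print.bn_volume <- function(x, ...) {
  cat(sprintf("<bn_volume> %s voxels @ %s mm  [%.4g, %.4g]\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.bn_volume <- function(x) dim(x$data)

#' Construct a binary mask aligned with a volume
#'
#' @param data 3D logical (or 0/1 numeric) array.
#' @return An object of class `bn_mask` with elements `data` (logical array)
#'   and `count` (number of foreground voxels).
#' @export
as_mask <- function(data) {
  if (inherits(data, "bn_mask")) return(data)
  if (inherits(data, "bn_volume")) data <- data$data
  if (length(dim(data)) != 3L) stop("mask must be a 3D array", call. = FALSE)
  m <- array(as.logical(data), dim(data))
  if (anyNA(m)) stop("mask contains NA", call. = FALSE)
  structure(list(data = m, count = sum(m)), class = "bn_mask")
}

#' @export
print.bn_mask <- function(x, ...) {
  cat(sprintf("<bn_mask> %s voxels, %d foreground\n",
              paste(dim(x$data), collapse = "x"), x$count))
  invisible(x)
}

#' @export
dim.bn_mask <- function(x) dim(x$data)

# internal: accept bn_volume / bn_mask / bare array, return the array
vol_data <- function(x) {
  if (inherits(x, c("bn_volume", "bn_mask"))) x$data else x
}

mask_data <- function(mask, ref = NULL) {
  m <- vol_data(mask)
  m <- array(as.logical(m), dim(m))
  if (!is.null(ref) && !identical(dim(m), dim(vol_data(ref)))) {
    stop("mask shape does not match volume shape", call. = FALSE)
  }
  m
}

check_same_shape <- function(...) {
  ds <- lapply(list(...), function(x) dim(vol_data(x)))
  if (!all(vapply(ds, identical, logical(1), ds[[1]]))) {
    stop("volume shapes do not match: ",
         paste(vapply(ds, paste, "", collapse = "x"), collapse = " vs "),
         call. = FALSE)
  }
  invisible(ds[[1]])
}

#' Read a NIfTI volume
#'
#' Reads a NIfTI-1/2 file and returns the stored data, spacing and affine
#' exactly as stored, with no reorientation.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A [as_volume()] object.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) {
    stop("expected a 3D image, got ", length(d), " axes in ", path,
         call. = FALSE)
  }
  aff <- RNifti::xform(img)
  code <- attr(aff, "code")
  affine <- matrix(as.numeric(aff), 4, 4)
  spacing <- if (!is.null(code) && code > 0) {
    # column norms of the voxel-to-world map; equals pixdim for well-formed
    # files and survives scale in the sform where the quaternion form cannot
    sqrt(colSums(affine[1:3, 1:3]^2))
  } else {
    RNifti::pixdim(img)[seq_len(3)]
  }
  as_volume(array(as.numeric(img), d), spacing = spacing, affine = affine)
}

#' Write a volume to NIfTI
#'
#' The written file round-trips bit-identically through [read_volume()] for
#' finite double data.
#'
#' @param vol A [as_volume()] object (or 3D array).
#' @param path Output path (`.nii` or `.nii.gz`); parent directory must exist.
#' @param datatype NIfTI storage type, `"double"` by default so round trips
#'   are exact; use `"uint8"` for masks.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, datatype = "double") {
  vol <- as_volume(vol_data(vol),
                   spacing = if (inherits(vol, "bn_volume")) vol$spacing else c(1, 1, 1),
                   affine = if (inherits(vol, "bn_volume")) vol$affine else NULL)
  if (!dir.exists(dirname(path))) {
    stop("parent directory does not exist: ", dirname(path), call. = FALSE)
  }
  img <- RNifti::asNifti(vol$data, datatype = datatype)
  # spacing is carried by the voxel-to-world transform; the sform stores the
  # full matrix (the quaternion qform would lose anisotropic scale)
  img <- RNifti::`sform<-`(img, structure(vol$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a mask to NIfTI (unsigned 8-bit)
#'
#' @param mask A [as_mask()] object.
#' @param path Output path.
#' @param spacing,affine Grid metadata for the stored mask.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path, spacing = c(1, 1, 1), affine = NULL) {
  mask <- as_mask(mask)
  vol <- as_volume(array(as.numeric(mask$data), dim(mask$data)),
                   spacing = spacing, affine = affine)
  write_volume(vol, path, datatype = "uint8")
}

#' Resample a volume to a target spacing
#'
#' The output grid covers the same physical extent as the input; the output
#' shape per axis is `round(shape * spacing / target)` with half-away-from-zero
#' rounding.  Trilinear interpolation for images and fields, nearest-neighbour
#' for masks.
#'
#' @param vol A [as_volume()] object.
#' @param target_spacing Numeric length-3 (mm), all > 0.
#' @param mode `"linear"` or `"nearest"`.
#' @return A resampled [as_volume()] object.
#' @examples
#' v <- as_volume(array(rnorm(16^3), c(16, 16, 16)))
#' dim(resample_volume(v, c(2, 2, 2)))  # 8 8 8
#' @export
resample_volume <- function(vol, target_spacing, mode = c("linear", "nearest")) {
  mode <- match.arg(mode)
  vol <- as_volume(vol_data(vol),
                   spacing = if (inherits(vol, "bn_volume")) vol$spacing else c(1, 1, 1),
                   affine = if (inherits(vol, "bn_volume")) vol$affine else NULL)
  target_spacing <- as.numeric(target_spacing)
  if (length(target_spacing) == 1) target_spacing <- rep(target_spacing, 3)
  if (any(!is.finite(target_spacing)) || any(target_spacing <= 0)) {
    stop("target_spacing must be positive", call. = FALSE)
  }
  src_shape <- dim(vol$data)
  out_shape <- round_half_up(src_shape * vol$spacing / target_spacing)
  out_shape <- pmax(out_shape, 1L)
  out <- cpp_resample(vol$data, as.integer(src_shape), vol$spacing,
                      as.integer(out_shape), target_spacing,
                      mode == "nearest")
  # voxel-to-world update: new voxel j sits at old voxel coordinate
  # i = j * (t/s) + ((t/s) - 1) / 2 per axis
  ratio <- target_spacing / vol$spacing
  A <- vol$affine
  B <- A
  B[, 1:3] <- sweep(A[, 1:3, drop = FALSE], 2, ratio, `*`)
  B[, 4] <- A[, 4] + A[, 1:3, drop = FALSE] %*% ((ratio - 1) / 2)
  as_volume(out, spacing = target_spacing, affine = B)
}

# round-half-away-from-zero on nonnegative grid arithmetic
round_half_up <- function(x) as.integer(floor(x + 0.5))
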