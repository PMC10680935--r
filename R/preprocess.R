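#' Preprocessing transform record
#'
#' Stores the invertible transform log of the preprocessing chain (resampling
#' grid, pad/crop offsets, normalization constants) so a field predicted on
#' the preprocessed grid can be mapped back to native space.
#'
#' @param source_shape,source_spacing Native grid.
#' @param target_spacing Spacing of the resampled grid (mm).
#' @param resampled_shape Shape after resampling, before pad/crop.
#' @param pad_offsets,crop_offsets 3x2 integer matrices of (low, high)
#'   margins applied per axis.
#' @param out_shape Shape after pad/crop.
#' @param norm_xmax 99th-percentile intensity used for normalization (> 0).
#' @param norm_xmin Lower normalization bound (fixed at 0).
#' @return An object of class `bn_prep_record`.
#' @export
prep_record <- function(source_shape = NULL, source_spacing = NULL,
                        target_spacing = NULL, resampled_shape = NULL,
                        pad_offsets = NULL, crop_offsets = NULL,
                        out_shape = NULL, norm_xmax = NULL, norm_xmin = 0) {
  if (!is.null(norm_xmax) && norm_xmax <= 0) {
    stop("norm_xmax must be > 0", call. = FALSE)
  }
  structure(list(source_shape = source_shape, source_spacing = source_spacing,
                 target_spacing = target_spacing,
                 resampled_shape = resampled_shape,
                 pad_offsets = pad_offsets, crop_offsets = crop_offsets,
                 out_shape = out_shape,
                 norm_xmax = norm_xmax, norm_xmin = norm_xmin),
            class = "bn_prep_record")
}

merge_records <- function(a, b) {
  for (nm in names(b)) if (!is.null(b[[nm]])) a[[nm]] <- b[[nm]]
  a
}

#' Pad or crop a volume to a fixed shape
#'
#' Content is centered; excess is split floor/ceil per axis.  Both padding
#' (with `fill`) and cropping are handled, recorded for exact inversion.
#'
#' @param vol A [as_volume()] object.
#' @param shape Integer target shape (default 128^3).
#' @param fill Pad value (default 0, the background convention).
#' @return A list with `volume` (the reshaped volume) and `record`
#'   (a [prep_record()] holding the offsets).
#' @examples
#' out <- pad_crop_to_shape(as_volume(array(1, c(4, 4, 4))), c(6, 6, 6))
#' dim(out$volume)
#' @export
pad_crop_to_shape <- function(vol, shape = c(128, 128, 128), fill = 0) {
  vol <- as_volume(vol_data(vol),
                   spacing = if (inherits(vol, "bn_volume")) vol$spacing else c(1, 1, 1),
                   affine = if (inherits(vol, "bn_volume")) vol$affine else NULL)
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L)) {
    stop("shape must be 3 integers >= 1", call. = FALSE)
  }
  src <- dim(vol$data)
  excess <- shape - src
  pad_lo <- pmax(excess, 0L) %/% 2L
  pad_hi <- pmax(excess, 0L) - pad_lo
  crop_lo <- pmax(-excess, 0L) %/% 2L
  crop_hi <- pmax(-excess, 0L) - crop_lo
  out <- array(fill, shape)
  src_idx <- lapply(1:3, function(k) seq.int(crop_lo[k] + 1L, src[k] - crop_hi[k]))
  dst_idx <- lapply(1:3, function(k) seq.int(pad_lo[k] + 1L, shape[k] - pad_hi[k]))
  out[dst_idx[[1]], dst_idx[[2]], dst_idx[[3]]] <-
    vol$data[src_idx[[1]], src_idx[[2]], src_idx[[3]]]
  rec <- prep_record(source_shape = src,
                     pad_offsets = cbind(lo = pad_lo, hi = pad_hi),
                     crop_offsets = cbind(lo = crop_lo, hi = crop_hi),
                     out_shape = shape)
  list(volume = as_volume(out, spacing = vol$spacing), record = rec)
}

#' Invert a pad/crop using its record
#'
#' Recovers a volume of the pre-pad/crop shape.  Voxels that were cropped
#' away are refilled with `fill` (they are unrecoverable); padded margins are
#' discarded.
#'
#' @param vol The reshaped volume (or array).
#' @param record The [prep_record()] from [pad_crop_to_shape()].
#' @param fill Value for voxels lost to cropping.
#' @return A [as_volume()] object of the original shape.
#' @export
invert_pad_crop <- function(vol, record, fill = 0) {
  x <- vol_data(vol)
  if (!identical(dim(x), as.integer(record$out_shape))) {
    stop("volume shape ", paste(dim(x), collapse = "x"),
         " does not match record out_shape ",
         paste(record$out_shape, collapse = "x"), call. = FALSE)
  }
  src <- as.integer(record$source_shape)
  pad <- record$pad_offsets
  crop <- record$crop_offsets
  out <- array(fill, src)
  src_idx <- lapply(1:3, function(k) seq.int(crop[k, 1] + 1L, src[k] - crop[k, 2]))
  dst_idx <- lapply(1:3, function(k) seq.int(pad[k, 1] + 1L, record$out_shape[k] - pad[k, 2]))
  out[src_idx[[1]], src_idx[[2]], src_idx[[3]]] <-
    x[dst_idx[[1]], dst_idx[[2]], dst_idx[[3]]]
  sp <- if (inherits(vol, "bn_volume")) vol$spacing else c(1, 1, 1)
  as_volume(out, spacing = sp)
}

#' Min-max normalize an image
#'
#' Divides by the 99th intensity percentile (`Xmax`; `Xmin` is 0) and clips
#' the result to `[0, 1]`.  The percentile is the linear-interpolation
#' percentile over all voxels.
#'
#' @param vol A [as_volume()] object with at least one strictly positive
#'   voxel.
#' @return A list with `volume` (normalized) and `record` (stores `Xmax`).
#' @export
minmax_normalize <- function(vol) {
  vol <- as_volume(vol_data(vol),
                   spacing = if (inherits(vol, "bn_volume")) vol$spacing else c(1, 1, 1),
                   affine = if (inherits(vol, "bn_volume")) vol$affine else NULL)
  p99 <- quantile(vol$data, 0.99, names = FALSE, type = 7)
  if (!is.finite(p99) || p99 <= 0) {
    stop("degenerate image: 99th percentile is not positive", call. = FALSE)
  }
  out <- pmin(pmax(vol$data / p99, 0), 1)
  list(volume = as_volume(array(out, dim(vol$data)), spacing = vol$spacing,
                          affine = vol$affine),
       record = prep_record(norm_xmax = p99, norm_xmin = 0))
}

# Otsu threshold on values in [lo, hi]: maximizes between-class variance
# over a fixed histogram.  Hand-rolled because no installed package offers a
# 3D-global Otsu.
otsu_threshold <- function(x, nbins = 256, lo = 0, hi = 1) {
  width <- (hi - lo) / nbins
  h <- tabulate(pmin(pmax(floor((x - lo) / width), 0), nbins - 1) + 1L, nbins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * (seq_len(nbins) - 0.5))
  mu_t <- mu[nbins]
  denom <- omega * (1 - omega)
  sigma_b <- ifelse(denom > 0, (mu_t * omega - mu)^2 / denom, 0)
  lo + which.max(sigma_b) * width
}

# Background/tissue threshold: a single Otsu pass on a T1-like histogram
# tends to split dark (background + CSF) from bright tissue; a second pass
# restricted below the first cut separates true background from the darkest
# tissue class, which is the boundary the brain mask needs.
background_threshold <- function(x) {
  t1 <- otsu_threshold(x)
  below <- x[x <= t1]
  if (length(below) < 2 || max(below) <= 0) return(t1)
  otsu_threshold(below, lo = 0, hi = max(t1, 1e-12))
}

#' Compute a brain mask from a normalized volume
#'
#' Histogram thresholding on the normalized image (a two-stage Otsu scheme:
#' the second pass, restricted below the first cut, separates background
#' from the darkest tissue class), then the largest 6-connected component,
#' then morphological hole filling.  Used to restrict losses and metrics to
#' tissue voxels, avoiding the zero background.
#'
#' @param vol A normalized volume with values in `[0, 1]`.
#' @return A [as_mask()] object.
#' @export
compute_brain_mask <- function(vol) {
  x <- vol_data(vol)
  if (all(x == 0)) stop("empty mask: volume is all zero", call. = FALSE)
  thr <- background_threshold(x)
  m <- x > thr
  if (!any(m)) stop("empty mask: threshold removed all voxels", call. = FALSE)
  lab <- cpp_label_components(m, as.integer(dim(x)))
  counts <- tabulate(lab[lab > 0L])
  keep <- which.max(counts)
  m <- array(lab == keep, dim(x))
  m <- cpp_fill_holes(m, as.integer(dim(x)))
  as_mask(array(m, dim(x)))
}

#' Apply the full preprocessing chain
#'
#' Resample to `target_spacing`, pad/crop to `shape`, min-max normalize, and
#' compute a brain mask, recording every step for inversion.
#'
#' @param vol A native-space [as_volume()] object.
#' @param target_spacing Resampling target (default 2 mm isotropic).
#' @param shape Output shape (default 128^3).
#' @param mask Logical; also compute the brain mask (default TRUE).
#' @return A list with `volume` (normalized, on the fixed grid), `mask`
#'   (a [as_mask()] or NULL), and `record` (a [prep_record()]).
#' @export
preprocess_volume <- function(vol, target_spacing = c(2, 2, 2),
                              shape = c(128, 128, 128), mask = TRUE) {
  vol <- as_volume(vol_data(vol),
                   spacing = if (inherits(vol, "bn_volume")) vol$spacing else c(1, 1, 1),
                   affine = if (inherits(vol, "bn_volume")) vol$affine else NULL)
  native_shape <- dim(vol$data)
  native_spacing <- vol$spacing
  res <- resample_volume(vol, target_spacing, mode = "linear")
  pc <- pad_crop_to_shape(res, shape = shape)
  nm <- minmax_normalize(pc$volume)
  rec <- merge_records(pc$record, nm$record)
  rec$source_shape <- native_shape
  rec$source_spacing <- native_spacing
  rec$target_spacing <- as.numeric(if (length(target_spacing) == 1)
    rep(target_spacing, 3) else target_spacing)
  rec$resampled_shape <- dim(res$data)
  m <- if (mask) compute_brain_mask(nm$volume) else NULL
  list(volume = nm$volume, mask = m, record = rec)
}

#' Map a field from the preprocessed grid back to native space
#'
#' Inverts the pad/crop, then linearly resamples the field onto the native
#' grid.  The field is smooth by construction, which justifies linear
#' interpolation; cropped regions (if any) are filled with the field's edge
#' value 1 so division stays harmless there.
#'
#' @param field A volume on the preprocessed grid (e.g. `exp` of the
#'   predicted log field).
#' @param record The [prep_record()] from [preprocess_volume()].
#' @param native The native-space volume defining the output grid.
#' @param fill Fill value for cropped regions (default 1, the neutral field).
#' @return A [as_volume()] object on the native grid.
#' @export
restore_to_native <- function(field, record, native, fill = 1) {
  x <- vol_data(field)
  if (is.null(record$out_shape) || is.null(record$resampled_shape)) {
    stop("record does not describe a full preprocessing chain", call. = FALSE)
  }
  if (!identical(dim(x), as.integer(record$out_shape))) {
    stop("field shape ", paste(dim(x), collapse = "x"),
         " does not match record out_shape ",
         paste(record$out_shape, collapse = "x"), call. = FALSE)
  }
  native <- as_volume(vol_data(native),
                      spacing = if (inherits(native, "bn_volume")) native$spacing else c(1, 1, 1))
  # the pad/crop inversion works on the resampled grid, not the native one
  pc_rec <- record
  pc_rec$source_shape <- record$resampled_shape
  unpadded <- invert_pad_crop(as_volume(x, spacing = record$target_spacing),
                              pc_rec, fill = fill)
  out <- cpp_resample(unpadded$data, as.integer(record$resampled_shape),
                      record$target_spacing,
                      as.integer(dim(native$data)), native$spacing, FALSE)
  as_volume(out, spacing = native$spacing, affine = native$affine)
}
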