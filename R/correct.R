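#' Correct a volume with a trained network
#'
#' The full inference workflow: preprocess (resample to the training grid,
#' pad/crop, normalize), predict the log field, exponentiate, smooth
#' according to the requested variant, divide the acquired image by the
#' field, optionally match the masked mean of the corrected image to the
#' uncorrected input, and restore everything to the native grid.
#'
#' @param vol Native-space volume (or a NIfTI path).
#' @param net A trained `bn_unet` (or a checkpoint state from
#'   [load_checkpoint()]).
#' @param smoothing A [smoothing_spec()] or one of `"NS"`, `"G"`, `"B"`.
#' @param match_mean If TRUE, the corrected image's masked mean is shifted
#'   to match the input's (an evaluation-time adjustment, off by default).
#' @param target_spacing,shape Preprocessing grid; must match what the
#'   network was trained on.
#' @param deliver `"native"` (default) or `"preprocessed"`: the grid on
#'   which outputs are returned.
#' @param eps Division clamp.
#' @return A list with `corrected` and `field` (volumes on the requested
#'   grid), `mask` (preprocessed-grid mask) and `record`.
#' @export
correct_volume <- function(vol, net, smoothing = "NS", match_mean = FALSE,
                           target_spacing = c(2, 2, 2),
                           shape = c(128, 128, 128),
                           deliver = c("native", "preprocessed"),
                           eps = 1e-6) {
  deliver <- match.arg(deliver)
  if (is.character(vol)) vol <- read_volume(vol)
  if (!inherits(net, "bn_unet")) {
    if (is.list(net) && !is.null(net$unet_config)) net <- checkpoint_network(net)
    else stop("net must be a bn_unet or checkpoint state", call. = FALSE)
  }
  if (is.character(smoothing)) smoothing <- smoothing_spec(smoothing)
  vol <- as_volume(vol_data(vol),
                   spacing = if (inherits(vol, "bn_volume")) vol$spacing else c(1, 1, 1),
                   affine = if (inherits(vol, "bn_volume")) vol$affine else NULL)
  prep <- preprocess_volume(vol, target_spacing = target_spacing, shape = shape)
  logf <- predict_log_field(net, prep$volume)
  field <- as_volume(exp(logf$data), spacing = prep$volume$spacing)
  field <- smooth_field(field, smoothing, eps = eps)
  if (deliver == "preprocessed") {
    corrected <- correct_with_field(prep$volume, field, eps = eps)
    if (match_mean) {
      corrected <- mean_shift_to_reference(corrected, prep$volume, prep$mask)
    }
    return(list(corrected = corrected, field = field, mask = prep$mask,
                record = prep$record))
  }
  field_native <- restore_to_native(field, prep$record, vol)
  corrected <- correct_with_field(vol, field_native, eps = eps)
  if (match_mean) {
    mask_native <- as_mask(
      restore_mask_to_native(prep$mask, prep$record, vol))
    corrected <- mean_shift_to_reference(corrected, vol, mask_native)
  }
  list(corrected = corrected, field = field_native, mask = prep$mask,
       record = prep$record)
}

# nearest-neighbour restore of the preprocessed-grid mask onto the native grid
restore_mask_to_native <- function(mask, record, native) {
  pc_rec <- record
  pc_rec$source_shape <- record$resampled_shape
  m <- invert_pad_crop(as_volume(array(as.numeric(vol_data(mask)),
                                       dim(vol_data(mask))),
                                 spacing = record$target_spacing),
                       pc_rec, fill = 0)
  out <- cpp_resample(m$data, as.integer(record$resampled_shape),
                      record$target_spacing,
                      as.integer(dim(vol_data(native))),
                      if (inherits(native, "bn_volume")) native$spacing else c(1, 1, 1),
                      TRUE)
  array(out > 0.5, dim(vol_data(native)))
}
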