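#' Apply a multiplicative bias field
#'
#' The forward model of intensity inhomogeneity: `a(r) = u(r) * b(r)`
#' voxelwise, where `u` is the corrected image and `b` the strictly positive
#' smooth field.
#'
#' @param u Corrected image (volume or array).
#' @param b Bias field (volume or array), same shape.
#' @return A [as_volume()] object holding the acquired image `u * b`.
#' @examples
#' u <- array(2, c(4, 4, 4)); b <- array(3, c(4, 4, 4))
#' apply_bias(u, b)$data[1]  # 6
#' @export
apply_bias <- function(u, b) {
  check_same_shape(u, b)
  ud <- vol_data(u); bd <- vol_data(b)
  sp <- if (inherits(u, "bn_volume")) u$spacing else c(1, 1, 1)
  as_volume(ud * bd, spacing = sp,
            affine = if (inherits(u, "bn_volume")) u$affine else NULL)
}

#' Correct an acquired image with a known field
#'
#' Divides the acquired image by the (smoothed) bias field, voxelwise:
#' `u = a / max(b, eps)`.  The field is globally defined, so voxels outside
#' any mask are divided likewise; `eps` guards against zeros in the
#' background.
#'
#' @param a Acquired image.
#' @param field Bias field in linear (exponentiated) space.
#' @param mask Optional mask (unused by the division itself; accepted for
#'   interface symmetry with the losses).
#' @param eps Positive clamp for the divisor (default 1e-6 on the normalized
#'   scale).
#' @return A [as_volume()] object with the corrected image.
#' @export
correct_with_field <- function(a, field, mask = NULL, eps = 1e-6) {
  if (!is.numeric(eps) || length(eps) != 1 || eps <= 0) {
    stop("eps must be a positive scalar", call. = FALSE)
  }
  check_same_shape(a, field)
  ad <- vol_data(a); fd <- vol_data(field)
  sp <- if (inherits(a, "bn_volume")) a$spacing else c(1, 1, 1)
  as_volume(ad / pmax(fd, eps), spacing = sp,
            affine = if (inherits(a, "bn_volume")) a$affine else NULL)
}

# internal: shared mask bookkeeping for the losses
loss_mask <- function(mask, ref) {
  m <- mask_data(mask, ref)
  n <- sum(m)
  if (n < 1) stop("empty mask: losses need at least one masked voxel", call. = FALSE)
  list(m = m, n = n)
}

#' Field loss (L2 between predicted and true bias fields)
#'
#' Mean over masked voxels of `(exp(logb_pred) - b_true)^2`: the predicted
#' log field is exponentiated and compared to the ground-truth field in
#' linear space.  A log-space variant comparing `logb_pred` with
#' `log(b_true)` is available via `space = "log"`.
#'
#' @param logb_pred Predicted log field (volume, log-field or array).
#' @param b_true Ground-truth field in linear space.
#' @param mask Mask restricting the loss to tissue voxels.
#' @param space `"linear"` (default) or `"log"`.
#' @param eps Clamp used inside the log-space variant.
#' @return Nonnegative scalar; 0 iff the prediction matches on every masked
#'   voxel.
#' @export
loss_field <- function(logb_pred, b_true, mask, space = c("linear", "log"),
                       eps = 1e-6) {
  space <- match.arg(space)
  check_same_shape(logb_pred, b_true)
  lm <- loss_mask(mask, b_true)
  lp <- vol_data(logb_pred)[lm$m]
  bt <- vol_data(b_true)[lm$m]
  if (space == "linear") {
    mean((exp(lp) - bt)^2)
  } else {
    mean((lp - log(pmax(bt, eps)))^2)
  }
}

#' Corrected-image loss
#'
#' Mean over masked voxels of `(exp(log a - logb_pred) - u_true)^2`: the
#' image corrected with the predicted field, compared with the ground-truth
#' corrected image in linear space.  `a` is clamped at `eps` before the log.
#'
#' @param a Acquired image.
#' @param logb_pred Predicted log field.
#' @param u_true Ground-truth corrected image.
#' @param mask Mask restricting the loss.
#' @param eps Positive clamp (default 1e-6).
#' @return Nonnegative scalar; 0 iff `a / exp(logb_pred) = u_true` on the
#'   mask.
#' @export
loss_corrected <- function(a, logb_pred, u_true, mask, eps = 1e-6) {
  check_same_shape(a, logb_pred, u_true)
  lm <- loss_mask(mask, u_true)
  av <- pmax(vol_data(a)[lm$m], eps)
  lp <- vol_data(logb_pred)[lm$m]
  ut <- vol_data(u_true)[lm$m]
  mean((exp(log(av) - lp) - ut)^2)
}

#' Total training loss
#'
#' The sum of the field loss and the corrected-image loss.
#'
#' @param la,lb Nonnegative finite scalars.
#' @return `la + lb`.
#' @export
total_loss <- function(la, lb) {
  stopifnot(is.finite(la), is.finite(lb), la >= 0, lb >= 0)
  la + lb
}

#' Shift an image's masked mean to match a reference
#'
#' Adds the constant `mean_mask(ref) - mean_mask(img)` so the corrected
#' image's masked mean matches the uncorrected input — compensating global
#' intensity drift of division-based correction.  A multiplicative rescaling
#' variant is available via `mode = "multiplicative"`.
#'
#' @param img Image to shift.
#' @param ref Reference image (same shape).
#' @param mask Mask over which means are computed.
#' @param mode `"additive"` (default) or `"multiplicative"`.
#' @return A [as_volume()] object with matched masked mean.
#' @export
mean_shift_to_reference <- function(img, ref, mask,
                                    mode = c("additive", "multiplicative")) {
  mode <- match.arg(mode)
  check_same_shape(img, ref)
  lm <- loss_mask(mask, ref)
  xd <- vol_data(img)
  m_img <- mean(xd[lm$m])
  m_ref <- mean(vol_data(ref)[lm$m])
  out <- if (mode == "additive") {
    xd + (m_ref - m_img)
  } else {
    if (m_img == 0) stop("multiplicative shift undefined: masked mean is 0", call. = FALSE)
    xd * (m_ref / m_img)
  }
  sp <- if (inherits(img, "bn_volume")) img$spacing else c(1, 1, 1)
  as_volume(out, spacing = sp,
            affine = if (inherits(img, "bn_volume")) img$affine else NULL)
}
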