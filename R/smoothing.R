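#' Smoothing specification for predicted fields
#'
#' Selects among the three post-hoc regularizers of the predicted bias
#' field: `NS` (no smoothing), `G` (truncated Gaussian filtering) and `B`
#' (slicewise multilevel cubic B-spline approximation).  Smoothing operates
#' on the exponentiated (linear-space) field.
#'
#' @param mode One of `"NS"`, `"G"`, `"B"`.
#' @param gaussian_sigma Gaussian standard deviation in voxels (default 3).
#' @param gaussian_kernel Kernel width per axis in voxels, odd (default 19).
#' @param spline_order B-spline degree (default 3, cubic).
#' @param fitting_levels Number of multilevel fitting levels (default 5).
#' @param slice_axis Axis normal to the smoothing slices, 1..3 (default 3,
#'   axial for axis-aligned volumes).
#' @return An object of class `bn_smoothing_spec`.
#' @export
smoothing_spec <- function(mode = c("NS", "G", "B"), gaussian_sigma = 3,
                           gaussian_kernel = 19, spline_order = 3,
                           fitting_levels = 5, slice_axis = 3) {
  mode <- match.arg(mode)
  if (gaussian_kernel %% 2 != 1) stop("gaussian_kernel must be odd", call. = FALSE)
  if (gaussian_sigma <= 0) stop("gaussian_sigma must be > 0", call. = FALSE)
  if (spline_order < 1) stop("spline_order must be >= 1", call. = FALSE)
  if (fitting_levels < 1) stop("fitting_levels must be >= 1", call. = FALSE)
  if (!slice_axis %in% 1:3) stop("slice_axis must be 1, 2 or 3", call. = FALSE)
  structure(list(mode = mode, gaussian_sigma = gaussian_sigma,
                 gaussian_kernel = as.integer(gaussian_kernel),
                 spline_order = as.integer(spline_order),
                 fitting_levels = as.integer(fitting_levels),
                 slice_axis = as.integer(slice_axis)),
            class = "bn_smoothing_spec")
}

#' Truncated, renormalized 1D Gaussian kernel
#'
#' @param sigma Standard deviation in voxels.
#' @param width Odd kernel width in voxels.
#' @return Numeric vector of length `width` summing to 1.
#' @export
gaussian_kernel_1d <- function(sigma, width) {
  if (width %% 2 != 1) stop("kernel width must be odd", call. = FALSE)
  r <- (width - 1) / 2
  k <- dnorm(seq(-r, r), 0, sigma)
  k / sum(k)
}

#' Gaussian field smoothing
#'
#' Separable convolution with a truncated, renormalized Gaussian kernel and
#' reflective boundary handling (which avoids edge attenuation of a
#' multiplicative field near volume borders).  A constant field is preserved
#' exactly because the kernel sums to 1.
#'
#' @param field Volume or array.
#' @param sigma Standard deviation in voxels (default 3).
#' @param kernel Odd kernel width in voxels (default 19).
#' @return Smoothed volume of identical shape.
#' @export
gaussian_smooth <- function(field, sigma = 3, kernel = 19) {
  x <- vol_data(field)
  if (!all(is.finite(x))) stop("field must be finite", call. = FALSE)
  k <- gaussian_kernel_1d(sigma, kernel)
  out <- cpp_separable_filter(x, as.integer(dim(x)), k, FALSE)
  sp <- if (inherits(field, "bn_volume")) field$spacing else c(1, 1, 1)
  as_volume(out, spacing = sp,
            affine = if (inherits(field, "bn_volume")) field$affine else NULL)
}

# Clamped uniform B-spline basis for one axis: `n` sample points at cell
# centers of [0,1], `spans` knot spans, degree `degree`.
bspline_basis <- function(n, spans, degree) {
  knots <- c(rep(0, degree + 1),
             if (spans > 1) seq(0, 1, length.out = spans + 1)[2:spans],
             rep(1, degree + 1))
  x <- (seq_len(n) - 0.5) / n
  splines::splineDesign(knots, x, ord = degree + 1)
}

# Least-squares tensor-product fit of one 2D slice on a (spans x spans)
# control mesh; returns the reconstruction.  A tiny ridge keeps the normal
# equations well-posed when a basis function covers no sample point.
fit_slice_level <- function(S, Bx, By) {
  GxInv <- solve(crossprod(Bx) + diag(1e-10, ncol(Bx)))
  GyInv <- solve(crossprod(By) + diag(1e-10, ncol(By)))
  C <- GxInv %*% crossprod(Bx, S) %*% By %*% GyInv
  Bx %*% C %*% t(By)
}

#' Slicewise multilevel B-spline field smoothing
#'
#' For each 2D slice along `axis`, performs a multilevel least-squares
#' uniform B-spline approximation: level 1 fits a single-span control mesh,
#' each subsequent level doubles the mesh and fits the residual of the
#' accumulated reconstruction, mirroring the coarse-to-fine scheme of
#' B-spline field fitting in iterative bias correction.  The final
#' reconstruction replaces the slice.
#'
#' @param field Volume or array.
#' @param order Spline degree (default 3, cubic).
#' @param levels Fitting levels (default 5; the finest mesh has
#'   `2^(levels-1)` spans per axis).
#' @param axis Slice-normal axis, 1..3 (default 3).
#' @return Smoothed volume of identical shape.
#' @export
bspline_smooth_slicewise <- function(field, order = 3, levels = 5, axis = 3) {
  x <- vol_data(field)
  if (!all(is.finite(x))) stop("field must be finite", call. = FALSE)
  d <- dim(x)
  in_plane <- setdiff(1:3, axis)
  n1 <- d[in_plane[1]]; n2 <- d[in_plane[2]]
  if (n1 * n2 < (order + 1)^2) {
    stop("slice too small for spline order ", order, call. = FALSE)
  }
  basis1 <- lapply(seq_len(levels), function(l) bspline_basis(n1, 2^(l - 1), order))
  basis2 <- lapply(seq_len(levels), function(l) bspline_basis(n2, 2^(l - 1), order))
  out <- x
  idx <- list(quote(expr = ), quote(expr = ), quote(expr = ))
  for (s in seq_len(d[axis])) {
    idx[[axis]] <- s
    S <- matrix(do.call(`[`, c(list(x), idx)), n1, n2)
    recon <- matrix(0, n1, n2)
    for (l in seq_len(levels)) {
      recon <- recon + fit_slice_level(S - recon, basis1[[l]], basis2[[l]])
    }
    out <- do.call(`[<-`, c(list(out), idx, list(recon)))
  }
  sp <- if (inherits(field, "bn_volume")) field$spacing else c(1, 1, 1)
  as_volume(out, spacing = sp,
            affine = if (inherits(field, "bn_volume")) field$affine else NULL)
}

#' Smooth a predicted field according to a specification
#'
#' Dispatches to the no-smoothing passthrough, Gaussian filtering or
#' slicewise B-spline approximation.  Smoothing is applied in linear
#' (exponentiated) field space; the B-spline approximation can undershoot,
#' so its output is clamped at `eps` to preserve positivity.
#'
#' @param field Field volume in linear space.
#' @param spec A [smoothing_spec()].
#' @param eps Positivity clamp applied after B-spline smoothing.
#' @return The smoothed field.
#' @export
smooth_field <- function(field, spec = smoothing_spec("NS"), eps = 1e-6) {
  if (is.character(spec)) spec <- smoothing_spec(spec)
  if (!inherits(spec, "bn_smoothing_spec")) {
    stop("spec must be a smoothing_spec()", call. = FALSE)
  }
  switch(spec$mode,
    NS = {
      sp <- if (inherits(field, "bn_volume")) field$spacing else c(1, 1, 1)
      as_volume(vol_data(field), spacing = sp,
                affine = if (inherits(field, "bn_volume")) field$affine else NULL)
    },
    G = gaussian_smooth(field, spec$gaussian_sigma, spec$gaussian_kernel),
    B = {
      out <- bspline_smooth_slicewise(field, spec$spline_order,
                                      spec$fitting_levels, spec$slice_axis)
      out$data <- pmax(out$data, eps)
      out
    }
  )
}
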