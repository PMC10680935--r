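#' Phantom specification
#'
#' Geometry and intensity model of the synthetic brain phantom: a
#' piecewise-near-constant "brain" of three tissue classes (CSF, grey
#' matter, white matter as concentric ellipsoidal shells) inside a smooth
#' head-shaped ellipsoidal support, on a zero background.
#'
#' @param shape Integer lattice shape (default 48^3; use 128^3 for demos).
#' @param tissue_means Intensities of CSF, GM, WM on `[0, 1]`, strictly
#'   increasing (default 0.15, 0.45, 0.75).
#' @param head_axes Ellipsoid semi-axes as fractions of the lattice per axis,
#'   each in (0, 0.5] (default 0.40, 0.45, 0.40).
#' @param inner_radii Normalized ellipsoidal radii of the WM core and the
#'   GM/CSF boundary (default 0.55, 0.80); CSF fills the remaining shell.
#' @param texture_sd Within-tissue intensity jitter (default 0.02).
#' @param noise_sd Additive Gaussian noise on the acquired image after the
#'   field is applied (default 0.01).
#' @return An object of class `bn_phantom_spec`.
#' @export
phantom_spec <- function(shape = c(48, 48, 48),
                         tissue_means = c(0.15, 0.45, 0.75),
                         head_axes = c(0.40, 0.45, 0.40),
                         inner_radii = c(0.55, 0.80),
                         texture_sd = 0.02, noise_sd = 0.01) {
  shape <- as.integer(shape)
  if (length(shape) == 1) shape <- rep(shape, 3L)
  if (any(shape < 8)) stop("shape entries must be >= 8", call. = FALSE)
  if (length(tissue_means) != 3 || any(diff(tissue_means) <= 0) ||
      any(tissue_means <= 0) || any(tissue_means >= 1)) {
    stop("tissue_means must be 3 strictly increasing values in (0, 1)",
         call. = FALSE)
  }
  if (any(head_axes <= 0) || any(head_axes > 0.5)) {
    stop("head_axes must lie in (0, 0.5]", call. = FALSE)
  }
  if (length(inner_radii) != 2 || any(diff(c(0, inner_radii, 1)) <= 0)) {
    stop("inner_radii must be increasing within (0, 1)", call. = FALSE)
  }
  structure(list(shape = shape, tissue_means = tissue_means,
                 head_axes = head_axes, inner_radii = inner_radii,
                 texture_sd = texture_sd, noise_sd = noise_sd),
            class = "bn_phantom_spec")
}

#' Bias-field specification
#'
#' Model of the strictly positive, smooth, low-spatial-frequency
#' multiplicative field `b = exp(g)`.  Three families for `g`:
#' `gauss_random_field` (Gaussian-filtered white noise), `polynomial`
#' (random low-order polynomial in normalized coordinates) and `bspline`
#' (random coarse control mesh interpolated by cubic tensor B-splines).
#' Each realization is rescaled so `max |g| = log_amplitude` exactly.
#'
#' @param family One of `"gauss_random_field"`, `"polynomial"`, `"bspline"`.
#' @param log_amplitude Half-range of the log field (default 0.3, i.e. field
#'   range about `[0.74, 1.35]` — visible modulation that does not destroy
#'   tissue contrast).
#' @param correlation_length Gaussian filter standard deviation in voxels
#'   for the random-field family (default a quarter of the smallest axis).
#' @param poly_order Total degree for the polynomial family (default 3).
#' @param mesh_size Control points per axis for the B-spline family
#'   (default 5).
#' @return An object of class `bn_field_spec`.
#' @export
field_spec <- function(family = c("gauss_random_field", "polynomial", "bspline"),
                       log_amplitude = 0.3, correlation_length = NULL,
                       poly_order = 3, mesh_size = 5) {
  family <- match.arg(family)
  if (log_amplitude <= 0) stop("log_amplitude must be > 0", call. = FALSE)
  if (poly_order < 1) stop("poly_order must be >= 1", call. = FALSE)
  if (mesh_size < 4) stop("mesh_size must be >= 4", call. = FALSE)
  structure(list(family = family, log_amplitude = log_amplitude,
                 correlation_length = correlation_length,
                 poly_order = as.integer(poly_order),
                 mesh_size = as.integer(mesh_size)),
            class = "bn_field_spec")
}

# normalized ellipsoidal radius over the lattice
ellipsoid_rho <- function(shape, axes) {
  centre <- (shape + 1) / 2
  ax <- axes * shape
  x2 <- ((seq_len(shape[1]) - centre[1]) / ax[1])^2
  y2 <- ((seq_len(shape[2]) - centre[2]) / ax[2])^2
  z2 <- ((seq_len(shape[3]) - centre[3]) / ax[3])^2
  sqrt(outer(outer(x2, y2, `+`), z2, `+`))
}

#' Generate a phantom (corrected-truth image and mask)
#'
#' Nested-ellipsoid brain with three tissue classes at the specified means
#' plus seeded within-tissue jitter; background 0; the mask is the head
#' support.  Deterministic given the seed.
#'
#' @param spec A [phantom_spec()].
#' @param seed Integer seed.
#' @return A list with `u` (the corrected-truth [as_volume()]), `mask`
#'   (a [as_mask()] of the head support) and `labels` (integer array,
#'   0 = background, 1 = CSF, 2 = GM, 3 = WM).
#' @export
generate_phantom <- function(spec = phantom_spec(), seed = 1) {
  rho <- ellipsoid_rho(spec$shape, spec$head_axes)
  lab <- array(0L, spec$shape)
  lab[rho <= 1] <- 1L
  lab[rho < spec$inner_radii[2]] <- 2L
  lab[rho < spec$inner_radii[1]] <- 3L
  if (!any(lab > 0L)) stop("degenerate geometry: empty head support", call. = FALSE)
  u <- array(0, spec$shape)
  inside <- lab > 0L
  withr::with_seed(seed, {
    u[inside] <- spec$tissue_means[lab[inside]] +
      rnorm(sum(inside), 0, spec$texture_sd)
  })
  u[inside] <- pmax(u[inside], 1e-4)  # keep u strictly positive on the mask
  list(u = as_volume(u), mask = as_mask(inside), labels = lab)
}

# tensor-product evaluation of a coarse B-spline control mesh on the lattice
bspline_field_eval <- function(ctrl, shape) {
  m <- dim(ctrl)[1]
  spans <- m - 3  # cubic
  Bs <- lapply(1:3, function(k) bspline_basis(shape[k], spans, 3))
  g <- ctrl
  for (k in 1:3) {
    gm <- matrix(aperm(g, c(k, setdiff(1:3, k))), dim(g)[k])
    gm <- Bs[[k]] %*% gm
    newdim <- c(shape[k], dim(g)[setdiff(1:3, k)])
    g <- aperm(array(gm, newdim), order(c(k, setdiff(1:3, k))))
  }
  g
}

#' Generate a random smooth bias field
#'
#' Returns `b = exp(g)` with `g` drawn from the requested family and
#' rescaled to `max |g| = log_amplitude`, so the field is strictly positive
#' and smooth by construction.
#'
#' @param spec A [field_spec()].
#' @param shape Integer lattice shape.
#' @param seed Integer seed.
#' @return A [as_volume()] holding the field in linear space.
#' @export
generate_bias_field <- function(spec = field_spec(), shape = c(48, 48, 48),
                                seed = 1) {
  shape <- as.integer(if (length(shape) == 1) rep(shape, 3) else shape)
  g <- withr::with_seed(seed, {
    switch(spec$family,
      gauss_random_field = {
        sig <- spec$correlation_length %||% (min(shape) / 4)
        w <- array(rnorm(prod(shape)), shape)
        k <- gaussian_kernel_1d(sig, 2 * ceiling(3 * sig) + 1)
        cpp_separable_filter(w, shape, k, FALSE)
      },
      polynomial = {
        tt <- lapply(shape, function(n) seq(-1, 1, length.out = n))
        pow <- expand.grid(i = 0:spec$poly_order, j = 0:spec$poly_order,
                           k = 0:spec$poly_order)
        pow <- pow[rowSums(pow) <= spec$poly_order & rowSums(pow) > 0, ]
        cf <- rnorm(nrow(pow))
        out <- array(0, shape)
        for (r in seq_len(nrow(pow))) {
          out <- out + cf[r] * outer(outer(tt[[1]]^pow$i[r], tt[[2]]^pow$j[r]),
                                     tt[[3]]^pow$k[r])
        }
        out
      },
      bspline = {
        ctrl <- array(rnorm(spec$mesh_size^3),
                      rep(spec$mesh_size, 3))
        bspline_field_eval(ctrl, shape)
      }
    )
  })
  mx <- max(abs(g))
  if (mx == 0) stop("degenerate field draw (identically zero)", call. = FALSE)
  g <- g / mx * spec$log_amplitude
  as_volume(exp(g))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# derive per-component seeds from a master seed (kept below 2^31)
derive_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(2147483646L, n))
}

#' Generate one paired training/evaluation sample
#'
#' Draws a phantom `u`, a field `b`, and forms the acquired image
#' `a = u * b + noise`.  With `noise_sd = 0` the forward model is exact:
#' `a = u * b` voxelwise.
#'
#' @param pspec A [phantom_spec()].
#' @param fspec A [field_spec()].
#' @param seed Integer seed; phantom, field and noise seeds are derived from
#'   it.
#' @return An object of class `bn_sample`: `acquired`, `corrected_truth`,
#'   `field_truth` (volumes), `mask`, and the generating `seed`/specs.
#' @export
generate_sample <- function(pspec = phantom_spec(), fspec = field_spec(),
                            seed = 1) {
  seeds <- derive_seeds(seed, 3)
  ph <- generate_phantom(pspec, seeds[1])
  b <- generate_bias_field(fspec, pspec$shape, seeds[2])
  a <- ph$u$data * b$data
  if (pspec$noise_sd > 0) {
    a <- a + withr::with_seed(seeds[3],
                              array(rnorm(prod(pspec$shape), 0, pspec$noise_sd),
                                    pspec$shape))
  }
  structure(list(acquired = as_volume(a), corrected_truth = ph$u,
                 field_truth = b, mask = ph$mask, labels = ph$labels,
                 seed = as.integer(seed), phantom_spec = pspec,
                 field_spec = fspec),
            class = "bn_sample")
}

#' @export
print.bn_sample <- function(x, ...) {
  cat(sprintf("<bn_sample> %s, seed %d, %s field\n",
              paste(dim(x$acquired$data), collapse = "x"), x$seed,
              x$field_spec$family))
  invisible(x)
}

#' Generate a dataset of paired samples
#'
#' Per-sample seeds are derived from the master seed and recorded in a
#' manifest from which the dataset can be regenerated bit-identically.
#'
#' @param n Number of samples (>= 1).
#' @param pspec,fspec Specifications shared by all samples.
#' @param seed Master seed.
#' @return A list with `samples` (list of [generate_sample()] results) and
#'   `manifest` (a tibble with one row per sample: id, seed, spec summary).
#' @export
generate_dataset <- function(n, pspec = phantom_spec(), fspec = field_spec(),
                             seed = 1) {
  stopifnot(n >= 1)
  seeds <- derive_seeds(seed, n)
  samples <- lapply(seeds, function(s) generate_sample(pspec, fspec, s))
  manifest <- tibble::tibble(
    id = sprintf("sample%03d", seq_len(n)),
    seed = as.integer(seeds),
    shape = paste(pspec$shape, collapse = "x"),
    family = fspec$family,
    log_amplitude = fspec$log_amplitude,
    noise_sd = pspec$noise_sd,
    texture_sd = pspec$texture_sd
  )
  list(samples = samples, manifest = manifest,
       pspec = pspec, fspec = fspec, seed = as.integer(seed))
}

#' Regenerate a dataset from its manifest
#'
#' @param manifest The manifest tibble of [generate_dataset()].
#' @param pspec,fspec The specifications used originally.
#' @return A list of samples, bit-identical to the original generation.
#' @export
regenerate_from_manifest <- function(manifest, pspec = phantom_spec(),
                                     fspec = field_spec()) {
  lapply(manifest$seed, function(s) generate_sample(pspec, fspec, s))
}

#' Write a dataset to disk as NIfTI quadruples plus a manifest
#'
#' Each sample becomes `<id>_acquired.nii.gz`, `<id>_corrected.nii.gz`,
#' `<id>_field.nii.gz` and `<id>_mask.nii.gz` (unsigned 8-bit), with
#' `manifest.csv` alongside.
#'
#' @param dataset Result of [generate_dataset()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(dataset$samples)) {
    s <- dataset$samples[[i]]
    id <- dataset$manifest$id[i]
    write_volume(s$acquired, file.path(dir, paste0(id, "_acquired.nii.gz")))
    write_volume(s$corrected_truth, file.path(dir, paste0(id, "_corrected.nii.gz")))
    write_volume(s$field_truth, file.path(dir, paste0(id, "_field.nii.gz")))
    write_mask(s$mask, file.path(dir, paste0(id, "_mask.nii.gz")))
  }
  write.csv(dataset$manifest, file.path(dir, "manifest.csv"),
            row.names = FALSE)
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir Directory containing the NIfTI quadruples and `manifest.csv`.
#' @return A list with `samples` and `manifest`.
#' @export
read_dataset <- function(dir) {
  mf <- tibble::as_tibble(read.csv(file.path(dir, "manifest.csv")))
  samples <- lapply(mf$id, function(id) {
    structure(list(
      acquired = read_volume(file.path(dir, paste0(id, "_acquired.nii.gz"))),
      corrected_truth = read_volume(file.path(dir, paste0(id, "_corrected.nii.gz"))),
      field_truth = read_volume(file.path(dir, paste0(id, "_field.nii.gz"))),
      mask = as_mask(read_volume(file.path(dir, paste0(id, "_mask.nii.gz")))$data > 0)
    ), class = "bn_sample")
  })
  list(samples = samples, manifest = mf)
}
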