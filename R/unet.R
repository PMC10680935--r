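#' 3D U-Net configuration
#'
#' Architecture hyperparameters for the log-field estimator.  The network is
#' an encoder–decoder with two 3x3x3 convolutions per resolution level (each
#' followed by instance normalization and leaky ReLU), 2x2x2 max-pool
#' downsampling, transpose-convolution upsampling with channel-concatenating
#' skip connections, and a final 1x1x1 linear convolution with no output
#' nonlinearity (the log field is signed).
#'
#' @param levels Number of encoder/decoder resolution levels (>= 2,
#'   default 4).  Input sides must be divisible by `2^(levels-1)`.
#' @param base_channels Channels at the finest level (default 32); deeper
#'   levels double.
#' @param activation_slope Negative slope of the leaky ReLU (default 0.01).
#' @param pool Downsampling between levels: `"max"` (default, the common
#'   U-Net choice) or `"avg"`.
#' @param seed Integer seed for weight initialization.
#' @return An object of class `bn_unet_config`.
#' @export
unet_config <- function(levels = 4, base_channels = 32,
                        activation_slope = 0.01, pool = c("max", "avg"),
                        seed = 1) {
  pool <- match.arg(pool)
  if (levels < 2) stop("levels must be >= 2", call. = FALSE)
  if (base_channels < 1) stop("base_channels must be >= 1", call. = FALSE)
  structure(list(levels = as.integer(levels),
                 base_channels = as.integer(base_channels),
                 activation_slope = activation_slope, pool = pool,
                 seed = as.integer(seed)),
            class = "bn_unet_config")
}

pool_code <- function(cfg) if (identical(cfg$pool, "max")) 0L else 1L

# Shape table of every parameter tensor, from which both the initializer and
# the parameter count derive.
unet_param_shapes <- function(config) {
  L <- config$levels
  ch <- config$base_channels * 2^(0:(L - 1))
  shapes <- list()
  add <- function(nm, ...) shapes[[nm]] <<- c(...)
  for (l in seq_len(L)) {
    cin <- if (l == 1) 1L else ch[l - 1]
    cl <- ch[l]
    add(paste0("enc", l, "_conv1_W"), 27 * cin, cl)
    add(paste0("enc", l, "_conv1_b"), cl)
    add(paste0("enc", l, "_in1_g"), cl)
    add(paste0("enc", l, "_in1_b"), cl)
    add(paste0("enc", l, "_conv2_W"), 27 * cl, cl)
    add(paste0("enc", l, "_conv2_b"), cl)
    add(paste0("enc", l, "_in2_g"), cl)
    add(paste0("enc", l, "_in2_b"), cl)
  }
  for (l in seq(L - 1, 1)) {
    cl <- ch[l]
    add(paste0("dec", l, "_up_W"), ch[l + 1], 8 * cl)
    add(paste0("dec", l, "_up_b"), cl)
    add(paste0("dec", l, "_conv1_W"), 27 * 2 * cl, cl)
    add(paste0("dec", l, "_conv1_b"), cl)
    add(paste0("dec", l, "_in1_g"), cl)
    add(paste0("dec", l, "_in1_b"), cl)
    add(paste0("dec", l, "_conv2_W"), 27 * cl, cl)
    add(paste0("dec", l, "_conv2_b"), cl)
    add(paste0("dec", l, "_in2_g"), cl)
    add(paste0("dec", l, "_in2_b"), cl)
  }
  add("out_W", ch[1], 1L)
  add("out_b", 1L)
  shapes
}

# He-style initialization for convolutions; normalization gains start at 1,
# shifts at 0; the final 1x1x1 convolution starts at zero so the untrained
# network predicts the identity field exp(0) = 1.
unet_init_params <- function(config) {
  shapes <- unet_param_shapes(config)
  withr::with_seed(config$seed, {
    params <- list()
    for (nm in names(shapes)) {
      sh <- shapes[[nm]]
      if (grepl("_W$", nm)) {
        if (nm == "out_W") {
          params[[nm]] <- matrix(0, sh[1], sh[2])
        } else {
          fanin <- sh[1]
          params[[nm]] <- matrix(rnorm(prod(sh), 0, sqrt(2 / fanin)), sh[1], sh[2])
        }
      } else if (grepl("_g$", nm)) {
        params[[nm]] <- rep(1, sh)
      } else {
        params[[nm]] <- numeric(max(sh, 1))
      }
    }
    params$out_b <- 0
    params
  })
}

#' Build a 3D U-Net
#'
#' Constructs the network with seeded initialization: identical seeds give
#' bit-identical initial parameters.
#'
#' @param config A [unet_config()].
#' @return An object of class `bn_unet` with elements `config` and `params`
#'   (a named list of weight matrices and vectors).
#' @examples
#' net <- build_unet(unet_config(levels = 2, base_channels = 4, seed = 7))
#' glance(net)
#' @export
build_unet <- function(config = unet_config()) {
  if (!inherits(config, "bn_unet_config")) {
    stop("config must be a unet_config()", call. = FALSE)
  }
  structure(list(config = config, params = unet_init_params(config)),
            class = "bn_unet")
}

#' @export
print.bn_unet <- function(x, ...) {
  cat(sprintf("<bn_unet> levels=%d base=%d  %s parameters\n",
              x$config$levels, x$config$base_channels,
              format(n_params(x), big.mark = ",")))
  invisible(x)
}

#' Number of trainable parameters of a network
#'
#' @param net A `bn_unet`.
#' @return Integer parameter count.
#' @export
n_params <- function(net) {
  sum(vapply(net$params, length, integer(1)))
}

check_divisible <- function(shape, levels) {
  div <- 2^(levels - 1)
  if (any(shape %% div != 0)) {
    stop("input shape ", paste(shape, collapse = "x"),
         " not divisible by 2^(levels-1) = ", div, call. = FALSE)
  }
}

#' Predict the log bias field for a normalized volume
#'
#' Runs the network forward: `logb'(r) = f(a(r))`.  A pure function of
#' (weights, input); identical calls give identical outputs.
#'
#' @param net A trained or untrained `bn_unet`.
#' @param a_norm Normalized acquired volume in `[0, 1]` whose sides are
#'   divisible by `2^(levels-1)`.
#' @return An object of class `bn_log_field` (a volume of log-field values).
#' @export
predict_log_field <- function(net, a_norm) {
  x <- vol_data(a_norm)
  if (!all(is.finite(x))) stop("input contains non-finite values", call. = FALSE)
  d <- dim(x)
  check_divisible(d, net$config$levels)
  out <- cpp_unet_forward(net$params, x, as.integer(d),
                          net$config$levels, net$config$activation_slope,
                          pool_code(net$config))
  sp <- if (inherits(a_norm, "bn_volume")) a_norm$spacing else c(1, 1, 1)
  lf <- as_volume(out, spacing = sp,
                  affine = if (inherits(a_norm, "bn_volume")) a_norm$affine else NULL)
  class(lf) <- c("bn_log_field", class(lf))
  lf
}

#' @rdname biasnet-tidiers
#' @exportS3Method generics::tidy
tidy.bn_unet <- function(x, ...) {
  shapes <- unet_param_shapes(x$config)
  tibble::tibble(
    name = names(shapes),
    rows = vapply(shapes, function(s) as.integer(s[1]), integer(1)),
    cols = vapply(shapes, function(s) as.integer(if (length(s) > 1) s[2] else 1L),
                  integer(1)),
    n = vapply(x$params[names(shapes)], length, integer(1))
  )
}

#' @rdname biasnet-tidiers
#' @exportS3Method generics::glance
glance.bn_unet <- function(x, ...) {
  tibble::tibble(levels = x$config$levels,
                 base_channels = x$config$base_channels,
                 n_params = n_params(x))
}

#' Broom-style tidiers and plots for package objects
#'
#' [generics::tidy()] summarises components (network parameter tensors,
#' per-epoch losses, pairwise comparisons); [generics::glance()] gives
#' one-row summaries; [ggplot2::autoplot()] plots histories and evaluation
#' reports.
#'
#' @param x,object The object to summarise or plot.
#' @param ... Unused.
#' @name biasnet-tidiers
NULL
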