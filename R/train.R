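#' Training configuration
#'
#' Optimization hyperparameters for [train_model()].  The production default
#' learning rate follows the Adam protocol used for corpus-scale training
#' (1e-4); desk-scale runs of a few hundred optimizer steps converge with
#' `learning_rate = 1e-3` (see the package vignette).
#'
#' @param learning_rate Adam step size (> 0, default 1e-4).
#' @param epochs Number of passes over the training set (default 10).
#' @param batch_size Samples per gradient step; gradients are averaged over
#'   the batch (default 1).
#' @param seed Integer seed controlling shuffling (and any noise).
#' @param smoothing_in_loss If TRUE, the exponentiated prediction is Gaussian
#'   smoothed (differentiably, with the exact adjoint in the backward pass)
#'   before entering the loss.  Default FALSE: smoothing is a post-hoc step
#'   on the predicted field, outside the loss path.
#' @param smoothing Gaussian [smoothing_spec()] used when
#'   `smoothing_in_loss = TRUE`.
#' @param loss_space `"linear"` (default: both loss terms compare
#'   exponentiated quantities) or `"log"` (field loss in log space only).
#' @param eps Positivity clamp used inside the losses.
#' @param beta1,beta2 Adam moment-decay rates (defaults 0.9 / 0.999).
#' @return An object of class `bn_train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, epochs = 10, batch_size = 1,
                         seed = 1, smoothing_in_loss = FALSE,
                         smoothing = smoothing_spec("G"),
                         loss_space = c("linear", "log"), eps = 1e-6,
                         beta1 = 0.9, beta2 = 0.999) {
  loss_space <- match.arg(loss_space)
  if (learning_rate <= 0) stop("learning_rate must be > 0", call. = FALSE)
  if (epochs < 1) stop("epochs must be >= 1", call. = FALSE)
  if (batch_size < 1) stop("batch_size must be >= 1", call. = FALSE)
  if (beta1 < 0 || beta1 >= 1 || beta2 < 0 || beta2 >= 1) {
    stop("beta1 and beta2 must lie in [0, 1)", call. = FALSE)
  }
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 smoothing_in_loss = isTRUE(smoothing_in_loss),
                 smoothing = smoothing, loss_space = loss_space, eps = eps,
                 beta1 = beta1, beta2 = beta2),
            class = "bn_train_config")
}

#' Split sample ids into train/validation/test
#'
#' Seeded-shuffle split with floor-then-distribute-remainder sizing, so 100
#' items under the default fractions give exactly 90/5/5.  The three lists
#' are disjoint and exhaustive.
#'
#' @param items Vector of sample ids (length >= 3).
#' @param fractions Length-3 nonnegative fractions summing to 1 (default
#'   `c(0.90, 0.05, 0.05)`).
#' @param seed Integer shuffle seed.
#' @return A list with `train`, `validation`, `test`.
#' @export
split_dataset <- function(items, fractions = c(0.90, 0.05, 0.05), seed = 1) {
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop("fractions must sum to 1", call. = FALSE)
  }
  n <- length(items)
  if (n < 3) stop("need at least 3 items to split", call. = FALSE)
  base <- floor(n * fractions)
  rem <- n - sum(base)
  if (rem > 0) {
    frac_part <- n * fractions - base
    order_idx <- order(-frac_part, seq_along(fractions))
    base[order_idx[seq_len(rem)]] <- base[order_idx[seq_len(rem)]] + 1
  }
  shuffled <- withr::with_seed(seed, sample(items))
  ends <- cumsum(base)
  list(train = shuffled[seq_len(base[1])],
       validation = shuffled[seq.int(ends[1] + 1, length.out = base[2])],
       test = shuffled[seq.int(ends[2] + 1, length.out = base[3])])
}

# ---- Adam optimizer state ---------------------------------------------------
adam_init <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0),
       t = 0L)
}

adam_update <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# internal: one combined forward/backward pass returning loss pieces + grads
sample_step <- function(params, cfg, sample, tcfg) {
  a <- vol_data(sample$acquired)
  gk <- if (tcfg$smoothing_in_loss) {
    gaussian_kernel_1d(tcfg$smoothing$gaussian_sigma,
                       tcfg$smoothing$gaussian_kernel)
  } else numeric(0)
  cpp_unet_train_step(params, vol_data(sample$input), as.integer(dim(a)),
                      cfg$levels, cfg$activation_slope, pool_code(cfg),
                      a, vol_data(sample$field_truth),
                      vol_data(sample$corrected_truth),
                      mask_data(sample$mask), tcfg$eps,
                      if (tcfg$loss_space == "linear") 0L else 1L, gk)
}

# normalized network input for a sample (cached on first use)
sample_input <- function(sample) {
  if (!is.null(sample$input)) return(sample)
  nm <- minmax_normalize(as_volume(vol_data(sample$acquired)))
  sample$input <- nm$volume
  sample
}

sample_losses <- function(params, cfg, sample, tcfg) {
  st <- sample_step(params, cfg, sample, tcfg)
  list(loss = st$loss, la = st$la, lb = st$lb)
}

#' Train the log-field estimator
#'
#' Seeded Adam training with per-epoch history and validation-based model
#' selection: the returned weights are those of the epoch with minimal
#' validation total loss.  Fully reproducible given (seed, config, data) on
#' a single CPU thread.
#'
#' @param train,val Nonempty lists of samples (see [generate_sample()]);
#'   each needs `acquired`, `corrected_truth`, `field_truth`, `mask`.
#' @param unet_cfg A [unet_config()].
#' @param train_cfg A [train_config()].
#' @param resume A checkpoint list from [load_checkpoint()] (or the `state`
#'   of a previous run) to continue training from; `train_cfg$epochs` is then
#'   the total epoch count including the completed ones.
#' @param verbose Print per-epoch progress.
#' @return An object of class `bn_trained`: `network` (best-on-validation
#'   `bn_unet`), `history` (tibble with per-epoch train/validation losses),
#'   `best_epoch`, and `state` (full optimizer/RNG state for resuming).
#' @export
train_model <- function(train, val, unet_cfg = unet_config(),
                        train_cfg = train_config(), resume = NULL,
                        verbose = FALSE) {
  if (length(train) < 1 || length(val) < 1) {
    stop("train and val must be nonempty", call. = FALSE)
  }
  train <- lapply(train, sample_input)
  val <- lapply(val, sample_input)

  if (is.null(resume)) {
    params <- unet_init_params(unet_cfg)
    opt <- adam_init(params)
    history <- list()
    best <- list(loss = Inf, params = params, epoch = 0L)
    epoch0 <- 0L
    rng <- withr::with_seed(train_cfg$seed, .Random.seed)
  } else {
    params <- resume$params
    opt <- resume$opt
    history <- resume$history_rows
    best <- resume$best
    epoch0 <- resume$epochs_done
    rng <- resume$rng
    unet_cfg <- resume$unet_config
  }

  old_seed <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  assign(".Random.seed", rng, globalenv())

  nb <- train_cfg$batch_size
  for (ep in seq.int(epoch0 + 1L, length.out = max(0L, train_cfg$epochs - epoch0))) {
    ord <- sample(length(train))
    batches <- split(ord, ceiling(seq_along(ord) / nb))
    ep_loss <- ep_la <- ep_lb <- 0
    for (bt in batches) {
      acc <- NULL
      bl <- bla <- blb <- 0
      for (i in bt) {
        st <- sample_step(params, unet_cfg, train[[i]], train_cfg)
        if (!is.finite(st$loss)) {
          stop(sprintf("non-finite training loss at epoch %d (sample %d): %g",
                       ep, i, st$loss), call. = FALSE)
        }
        bl <- bl + st$loss; bla <- bla + st$la; blb <- blb + st$lb
        acc <- if (is.null(acc)) st$grads else
          Map(`+`, acc, st$grads)
      }
      if (length(bt) > 1) acc <- lapply(acc, `/`, length(bt))
      up <- adam_update(params, acc, opt, train_cfg$learning_rate,
                        beta1 = train_cfg$beta1, beta2 = train_cfg$beta2)
      params <- up$params; opt <- up$state
      ep_loss <- ep_loss + bl; ep_la <- ep_la + bla; ep_lb <- ep_lb + blb
    }
    ntr <- length(train)
    vl <- lapply(val, function(s) sample_losses(params, unet_cfg, s, train_cfg))
    val_loss <- mean(vapply(vl, `[[`, numeric(1), "loss"))
    row <- tibble::tibble(epoch = ep,
                          train_loss = ep_loss / ntr, train_la = ep_la / ntr,
                          train_lb = ep_lb / ntr,
                          val_loss = val_loss,
                          val_la = mean(vapply(vl, `[[`, numeric(1), "la")),
                          val_lb = mean(vapply(vl, `[[`, numeric(1), "lb")))
    history[[length(history) + 1L]] <- row
    if (val_loss < best$loss) {
      best <- list(loss = val_loss, params = params, epoch = ep)
    }
    if (verbose) {
      message(sprintf("epoch %3d  train %.6g  val %.6g%s", ep,
                      row$train_loss, val_loss,
                      if (best$epoch == ep) "  *" else ""))
    }
  }

  history_tbl <- dplyr::bind_rows(history)
  class(history_tbl) <- c("bn_history", class(history_tbl))
  net <- structure(list(config = unet_cfg, params = best$params),
                   class = "bn_unet")
  state <- list(params = params, opt = opt, history_rows = history,
                best = best, epochs_done = train_cfg$epochs,
                rng = get(".Random.seed", globalenv()),
                unet_config = unet_cfg, train_config = train_cfg)
  structure(list(network = net, history = history_tbl,
                 best_epoch = best$epoch, best_val_loss = best$loss,
                 state = state),
            class = "bn_trained")
}

#' @export
print.bn_trained <- function(x, ...) {
  cat(sprintf("<bn_trained> %d epochs, best epoch %d (val loss %.5g)\n",
              nrow(x$history), x$best_epoch, x$best_val_loss))
  invisible(x)
}

#' @rdname biasnet-tidiers
#' @exportS3Method generics::tidy
tidy.bn_trained <- function(x, ...) {
  tidyr::pivot_longer(x$history,
                      cols = -"epoch",
                      names_to = c("split", "term"),
                      names_pattern = "(train|val)_(.*)",
                      values_to = "value")
}

#' @rdname biasnet-tidiers
#' @exportS3Method generics::glance
glance.bn_trained <- function(x, ...) {
  tibble::tibble(epochs = nrow(x$history), best_epoch = x$best_epoch,
                 best_val_loss = x$best_val_loss,
                 final_train_loss = x$history$train_loss[nrow(x$history)])
}

#' @rdname biasnet-tidiers
#' @exportS3Method ggplot2::autoplot
autoplot.bn_history <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object),
                            cols = c("train_loss", "val_loss"),
                            names_to = "split", values_to = "loss")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                   colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epoch", y = "total loss", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.bn_trained <- function(object, ...) autoplot(object$history, ...)

CHECKPOINT_VERSION <- "biasnet-checkpoint-1"

#' Save a training checkpoint
#'
#' Stores configs, weights, optimizer state and RNG state, versioned, so a
#' reload restores bit-identical weights and a resumable optimizer.
#'
#' @param trained A `bn_trained` object (or its `state`).
#' @param path Output path (`.rds`).
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(trained, path) {
  state <- if (inherits(trained, "bn_trained")) trained$state else trained
  obj <- list(version = CHECKPOINT_VERSION, state = state)
  saveRDS(obj, path)
  invisible(path)
}

#' Load a training checkpoint
#'
#' @param path Path written by [save_checkpoint()].
#' @return The checkpoint `state` list; its best-on-validation network is
#'   available via [checkpoint_network()], and it can be passed to
#'   [train_model()]'s `resume` argument.
#' @export
load_checkpoint <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e) {
    stop("cannot read checkpoint ", path, ": ", conditionMessage(e),
         call. = FALSE)
  })
  if (!is.list(obj) || !identical(obj$version, CHECKPOINT_VERSION)) {
    stop("incompatible checkpoint version in ", path,
         " (expected ", CHECKPOINT_VERSION, ")", call. = FALSE)
  }
  obj$state
}

#' Extract the best-on-validation network from a checkpoint state
#'
#' @param state A checkpoint state from [load_checkpoint()].
#' @return A `bn_unet`.
#' @export
checkpoint_network <- function(state) {
  structure(list(config = state$unet_config, params = state$best$params),
            class = "bn_unet")
}
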