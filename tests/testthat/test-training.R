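test_that("dataset splitting is exact, disjoint, exhaustive and seeded", {
  ids <- sprintf("scan%03d", 1:100)
  sp <- split_dataset(ids, c(0.90, 0.05, 0.05), seed = 4)
  expect_length(sp$train, 90L)
  expect_length(sp$validation, 5L)
  expect_length(sp$test, 5L)
  expect_setequal(c(sp$train, sp$validation, sp$test), ids)
  expect_length(intersect(sp$train, sp$validation), 0L)
  expect_length(intersect(sp$train, sp$test), 0L)

  # same seed -> identical; different seed -> different
  expect_identical(split_dataset(ids, seed = 4), sp)
  expect_false(identical(split_dataset(ids, seed = 5), sp))

  # remainder distribution: 7 items at default fractions -> 6/1/0 or 6/0/1
  sp7 <- split_dataset(letters[1:7], seed = 1)
  expect_length(sp7$train, 6L)
  expect_identical(sort(unname(lengths(sp7))), c(0L, 1L, 6L))
  expect_setequal(unlist(sp7), letters[1:7])

  expect_error(split_dataset(ids, c(0.5, 0.4, 0.2)), "sum to 1")
  expect_error(split_dataset(ids[1:2]), "at least 3")
})

make_train_pair <- function(shape = 16, n_train = 2) {
  samples <- lapply(seq_len(n_train + 1),
                    function(i) tiny_sample(seed = 100 + i, shape = shape,
                                            noise_sd = 0.01))
  list(train = samples[seq_len(n_train)], val = samples[n_train + 1])
}

test_that("training reduces loss, selects on validation, and reproduces", {
  dat <- make_train_pair()
  ucfg <- unet_config(levels = 2, base_channels = 4, seed = 5)
  tcfg <- train_config(learning_rate = 1e-3, epochs = 4, seed = 9)
  fit <- train_model(dat$train, dat$val, ucfg, tcfg)

  expect_s3_class(fit$history, "tbl_df")
  expect_identical(nrow(fit$history), 4L)
  expect_named(fit$history, c("epoch", "train_loss", "train_la", "train_lb",
                              "val_loss", "val_la", "val_lb"))
  expect_lt(fit$history$train_loss[4], fit$history$train_loss[1])

  # selection contract: returned val loss is the history minimum
  expect_equal(fit$best_val_loss, min(fit$history$val_loss))
  expect_identical(fit$best_epoch,
                   fit$history$epoch[which.min(fit$history$val_loss)])

  # determinism: identical seeds/config -> identical history and weights
  fit2 <- train_model(dat$train, dat$val, ucfg, tcfg)
  expect_equal(fit$history, fit2$history)
  expect_identical(fit$network$params, fit2$network$params)

  # tidiers
  expect_true(all(c("split", "term", "value") %in% names(tidy(fit))))
  expect_identical(glance(fit)$best_epoch, fit$best_epoch)

  expect_error(train_model(list(), dat$val, ucfg, tcfg), "nonempty")
})

test_that("checkpoints round-trip weights and resume the trajectory", {
  dir <- withr::local_tempdir()
  dat <- make_train_pair()
  ucfg <- unet_config(levels = 2, base_channels = 4, seed = 5)

  # uninterrupted 4-epoch run
  fit_full <- train_model(dat$train, dat$val, ucfg,
                          train_config(learning_rate = 1e-3, epochs = 4,
                                       seed = 9))

  # 2 epochs, checkpoint, resume to 4
  fit_half <- train_model(dat$train, dat$val, ucfg,
                          train_config(learning_rate = 1e-3, epochs = 2,
                                       seed = 9))
  p <- file.path(dir, "ckpt.rds")
  save_checkpoint(fit_half, p)
  state <- load_checkpoint(p)

  # loaded network predicts identically to the pre-save one
  x <- as_volume(array(runif(16^3), c(16, 16, 16)))
  expect_identical(predict_log_field(checkpoint_network(state), x)$data,
                   predict_log_field(fit_half$network, x)$data)

  fit_resumed <- train_model(dat$train, dat$val, ucfg,
                             train_config(learning_rate = 1e-3, epochs = 4,
                                          seed = 9),
                             resume = state)
  expect_identical(nrow(fit_resumed$history), 4L)
  expect_equal(fit_resumed$history$train_loss,
               fit_full$history$train_loss, tolerance = 1e-12)
  expect_equal(fit_resumed$network$params, fit_full$network$params,
               tolerance = 1e-12)

  # truncated file -> explicit load error
  raw_bytes <- readBin(p, "raw", file.size(p))
  trunc_path <- file.path(dir, "trunc.rds")
  writeBin(raw_bytes[1:20], trunc_path)
  expect_error(load_checkpoint(trunc_path), "cannot read checkpoint")

  # wrong payload -> version error
  other <- file.path(dir, "other.rds")
  saveRDS(list(version = "something-else"), other)
  expect_error(load_checkpoint(other), "incompatible")
})

test_that("single-sample training loss is monotone over smoothed windows", {
  s <- tiny_sample(seed = 55, shape = 16, noise_sd = 0.01)
  ucfg <- unet_config(levels = 2, base_channels = 4, seed = 2)
  tcfg <- train_config(learning_rate = 1e-3, epochs = 60, seed = 3)
  fit <- train_model(list(s), list(s), ucfg, tcfg)
  losses <- fit$history$train_loss
  w <- vapply(seq_len(3), function(k) {
    mean(losses[((k - 1) * 20 + 1):(k * 20)])
  }, numeric(1))
  expect_true(all(diff(w) < 0))
  expect_lt(losses[60], 0.5 * losses[1])
})
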