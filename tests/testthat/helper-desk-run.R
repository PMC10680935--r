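# The desk-scale field-recovery experiment: train a levels=3/base=8 network
# on 64 synthetic 48^3 samples (Gaussian-random-field bias, log-amplitude
# 0.3, noise 0.01) for 10 epochs and score 16 held-out samples.  Computed
# once per test session and shared by the tests that examine it.

desk_run_env <- new.env(parent = emptyenv())

desk_scale_run <- function() {
  if (!is.null(desk_run_env$result)) return(desk_run_env$result)

  pspec <- phantom_spec(shape = 48, noise_sd = 0.01)
  fspec <- field_spec("gauss_random_field", log_amplitude = 0.3,
                      correlation_length = 12)
  train <- generate_dataset(64, pspec, fspec, seed = 2024)$samples
  val <- generate_dataset(8, pspec, fspec, seed = 2025)$samples
  test <- generate_dataset(16, pspec, fspec, seed = 2026)$samples

  ucfg <- unet_config(levels = 3, base_channels = 8, seed = 7)
  tcfg <- train_config(learning_rate = 1e-3, epochs = 10, seed = 7)
  fit <- train_model(train, val, ucfg, tcfg)

  modes <- c("NS", "G", "B")
  scores <- purrr::map_dfr(seq_along(test), function(i) {
    s <- test[[i]]
    a_norm <- minmax_normalize(s$acquired)$volume
    lp <- predict_log_field(fit$network, a_norm)
    # PSNR after matching the masked mean to the reference, mirroring the
    # mean-shift adjustment of the evaluation protocol
    shifted_psnr <- function(img, s) {
      psnr(mean_shift_to_reference(img, s$corrected_truth, s$mask),
           s$corrected_truth, s$mask)
    }
    rows <- purrr::map_dfr(modes, function(mode) {
      fld <- smooth_field(as_volume(exp(lp$data)), smoothing_spec(mode))
      corrected <- correct_with_field(s$acquired, fld)
      tibble::tibble(case_id = sprintf("case%02d", i), method = mode,
                     value = shifted_psnr(corrected, s))
    })
    dplyr::bind_rows(
      rows,
      tibble::tibble(case_id = sprintf("case%02d", i), method = "acquired",
                     value = shifted_psnr(s$acquired, s)),
      tibble::tibble(case_id = sprintf("case%02d", i), method = ".corr",
                     value = cor(lp$data[s$mask$data],
                                 log(s$field_truth$data)[s$mask$data]))
    )
  })
  desk_run_env$result <- list(fit = fit, scores = scores)
  desk_run_env$result
}

desk_median <- function(scores, method) {
  median(scores$value[scores$method == method])
}
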