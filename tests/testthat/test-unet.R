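test_that("network initialization is seeded and reproducible", {
  n1 <- tiny_net(seed = 42)
  n2 <- tiny_net(seed = 42)
  expect_identical(n1$params, n2$params)
  n3 <- tiny_net(seed = 43)
  expect_false(identical(n1$params, n3$params))
})

test_that("parameter count matches a hand-derived layer-by-layer sum", {
  # levels = 2, base = 4: channels c(4, 8)
  # enc1: conv 1->4 (27*1*4 + 4) + IN(4+4) + conv 4->4 (27*4*4 + 4) + IN(8)
  # enc2: conv 4->8 (27*4*8 + 8) + IN(16) + conv 8->8 (27*8*8 + 8) + IN(16)
  # dec1: up 8->4 (2^3*8*4 + 4) + conv 8->4 (27*8*4 + 4) + IN(8)
  #       + conv 4->4 (27*4*4 + 4) + IN(8)
  # out:  1x1x1 conv 4->1 (4 + 1)
  hand <- (27 * 1 * 4 + 4) + 8 + (27 * 4 * 4 + 4) + 8 +
    (27 * 4 * 8 + 8) + 16 + (27 * 8 * 8 + 8) + 16 +
    (8 * 8 * 4 + 4) + (27 * 8 * 4 + 4) + 8 + (27 * 4 * 4 + 4) + 8 +
    (4 + 1)
  net <- tiny_net(levels = 2, base = 4)
  expect_equal(n_params(net), hand)
  expect_equal(sum(tidy(net)$n), hand)
  expect_equal(glance(net)$n_params, hand)
})

test_that("forward pass preserves shape and is deterministic", {
  net <- tiny_net(levels = 2, base = 4, seed = 3)
  for (n in c(16L, 32L)) {
    x <- as_volume(array(runif(n^3), c(n, n, n)))
    lf <- predict_log_field(net, x)
    expect_identical(dim(lf$data), c(n, n, n))
    expect_true(all(is.finite(lf$data)))
  }
  net3 <- tiny_net(levels = 3, base = 4, seed = 3)
  x <- as_volume(array(runif(24^3), c(24, 24, 24)))
  expect_identical(dim(predict_log_field(net3, x)$data), c(24L, 24L, 24L))

  # identical weights + input -> identical output
  x2 <- as_volume(array(runif(16^3), c(16, 16, 16)))
  expect_identical(predict_log_field(net, x2)$data,
                   predict_log_field(net, x2)$data)

  # indivisible shape fails loudly
  bad <- as_volume(array(0.5, c(15, 16, 16)))
  expect_error(predict_log_field(net, bad), "divisible")
  xn <- array(0.5, c(16, 16, 16)); xn[1] <- NA
  expect_error(predict_log_field(net, xn), "finite")
})

test_that("untrained outputs are finite and bounded over seeded draws", {
  for (seed in 1:10) {
    net <- tiny_net(levels = 2, base = 4, seed = seed)
    x <- withr::with_seed(seed, array(runif(16^3), c(16, 16, 16)))
    lf <- predict_log_field(net, x)
    expect_true(all(is.finite(lf$data)))
    expect_lt(max(abs(lf$data)), 100)
  }
})

test_that("loss gradients are finite for every parameter", {
  s <- tiny_sample(seed = 8, noise_sd = 0.01)
  net <- tiny_net(levels = 2, base = 4, seed = 2)
  tcfg <- train_config(seed = 1)
  st <- biasnet:::sample_step(net$params, net$config,
                              biasnet:::sample_input(s), tcfg)
  expect_true(all(vapply(st$grads, function(g) all(is.finite(g)), logical(1))))
  expect_setequal(names(st$grads), names(net$params))

  # gradients against central finite differences on a few parameters
  f_loss <- function(p) biasnet:::sample_step(p, net$config,
                                              biasnet:::sample_input(s),
                                              tcfg)$loss
  set.seed(31)
  for (nm in c("enc1_conv1_W", "dec1_conv2_W", "out_W", "enc2_in1_g")) {
    i <- sample(length(net$params[[nm]]), 1)
    h <- 5e-3
    p_hi <- net$params; p_hi[[nm]][i] <- p_hi[[nm]][i] + h
    p_lo <- net$params; p_lo[[nm]][i] <- p_lo[[nm]][i] - h
    num <- (f_loss(p_hi) - f_loss(p_lo)) / (2 * h)
    ana <- st$grads[[nm]][i]
    # forward passes run in single precision; compare at matching tolerance
    expect_lt(abs(num - ana) / max(abs(num) + abs(ana), 1e-4), 0.1)
  }

  # with smoothing in the loss path (on a perturbed net: the freshly built
  # network predicts the constant identity field, which every smoother fixes)
  p_pert <- net$params
  p_pert$out_W <- matrix(withr::with_seed(6, rnorm(length(p_pert$out_W), 0, 0.3)),
                         nrow(p_pert$out_W))
  tcfg_s <- train_config(smoothing_in_loss = TRUE,
                         smoothing = smoothing_spec("G", gaussian_sigma = 2,
                                                    gaussian_kernel = 7))
  st_plain <- biasnet:::sample_step(p_pert, net$config,
                                    biasnet:::sample_input(s), tcfg)
  st_s <- biasnet:::sample_step(p_pert, net$config,
                                biasnet:::sample_input(s), tcfg_s)
  expect_true(all(vapply(st_s$grads, function(g) all(is.finite(g)),
                         logical(1))))
  expect_false(isTRUE(all.equal(st_s$loss, st_plain$loss)))
})
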