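# Shared fixtures: tiny phantoms, fields and networks built in code.

tiny_pspec <- function(shape = 16, noise_sd = 0, texture_sd = 0.02) {
  phantom_spec(shape = shape, noise_sd = noise_sd, texture_sd = texture_sd)
}

tiny_fspec <- function(family = "gauss_random_field", log_amplitude = 0.3) {
  field_spec(family = family, log_amplitude = log_amplitude,
             correlation_length = 4)
}

tiny_sample <- function(seed = 1, shape = 16, noise_sd = 0) {
  generate_sample(tiny_pspec(shape, noise_sd), tiny_fspec(), seed = seed)
}

tiny_net <- function(levels = 2, base = 4, seed = 1) {
  build_unet(unet_config(levels = levels, base_channels = base, seed = seed))
}

# a smooth separable analytic field on [0,1]^3, evaluated at voxel centers
analytic_field <- function(shape, spacing = c(1, 1, 1)) {
  cc <- lapply(1:3, function(k) ((seq_len(shape[k]) - 0.5) * spacing[k]))
  ext <- shape * spacing
  fx <- 1 + 0.2 * sin(pi * cc[[1]] / ext[1])
  fy <- 1 + 0.1 * cos(pi * cc[[2]] / ext[2])
  fz <- 1 + 0.15 * sin(pi * cc[[3]] / ext[3])
  outer(outer(fx, fy), fz)
}

# shift an array along one axis with edge replication
abind_shift <- function(x, by, axis) {
  d <- dim(x)
  idx <- pmin(pmax(seq_len(d[axis]) + by, 1), d[axis])
  sel <- rep(list(quote(expr = )), 3)
  sel[[axis]] <- idx
  do.call(`[`, c(list(x), sel))
}

# independent sort-based linear-interpolation percentile (oracle)
sort_percentile <- function(x, p) {
  s <- sort(x)
  h <- (length(s) - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}
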