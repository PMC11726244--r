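# Shared fixtures, built lazily and cached for the session.
.fixtures <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixtures))
    assign(name, expr, envir = .fixtures)
  get(name, envir = .fixtures)
}

# Small, easy-to-segment phantom conditions for unit tests (high contrast,
# low noise, coarse grid).
small_phantom_cfg <- function(...) {
  args <- list(grid_shape = c(32, 32, 16), voxel_spacing = c(3, 3, 6),
               tumor_radius_range = c(8, 20), tumor_contrast = 80,
               noise_sd = 3, bias_amplitude = 0.1)
  do.call(phantom_config, utils::modifyList(args, list(...)))
}

small_unet_cfg <- function(...) {
  unet_config(n_levels = 2, base_channels = 4, input_size = c(32, 32, 16),
              ...)
}

# Single-site config with image-free covariate-driven hazard.
clinical_sim_cfg <- function(seed = 1, censor_rate = 0.25,
                             intercept = -3.2) {
  phantom_config(hazard_coeffs = list(
                   intercept = intercept, log_volume = 0, age_z = -0.5,
                   resection = c(GTR = -0.8, STR = 0.4, biopsy = 0.8)),
                 censor_rate = censor_rate,
                 site_mix = list(A = list(prop = 1)), seed = seed)
}

# Random valid survival curves on an equidistant grid.
mk_random_curves <- function(n, J = 8, tmax = 100) {
  h <- matrix(stats::runif(n * J, 0.01, 0.4), n, J)
  S <- cbind(1, t(apply(1 - h, 1, cumprod)))
  structure(S, class = c("survival_curves", "matrix"),
            grid = make_time_grid(tmax, J))
}

# Curves implied by a constant per-subject hazard (the generator's truth).
constant_hazard_curves <- function(h, n_bins, bin_width) {
  S <- t(vapply(h, function(hi) c(1, cumprod(rep(1 - hi, n_bins))),
                numeric(n_bins + 1)))
  structure(S, class = c("survival_curves", "matrix"),
            grid = make_time_grid(n_bins * bin_width, n_bins))
}

# Framed volumes + masks for a cohort of easy phantoms (cached).
framed_small_cohort <- function(n = 40, seed = 1) {
  cached(sprintf("framed_%d_%d", n, seed), {
    cfg <- small_phantom_cfg(seed = seed)
    co <- generate_cohort(n, cfg)
    framed <- lapply(co$images, function(im) {
      br <- extract_brain(im$volume)
      fv <- normalize_and_frame(im$volume, br, c(32, 32, 16))
      list(volume = fv, mask = frame_like(im$mask, fv))
    })
    list(clinical = co$clinical,
         volumes = lapply(framed, `[[`, "volume"),
         masks = lapply(framed, `[[`, "mask"))
  })
}

# A trained small segmentation model on easy phantoms (cached; the single
# expensive unit-test fixture).
trained_small_segmenter <- function() {
  cached("small_segmenter", {
    fx <- framed_small_cohort(40, seed = 1)
    train_segmentation(fx$volumes[1:30], fx$masks[1:30], small_unet_cfg(),
                       seg_train_config(epochs = 6, lr = 2e-3))
  })
}

dice_coef <- function(a, b) {
  2 * sum(a * b) / (sum(a) + sum(b) + 1e-12)
}
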