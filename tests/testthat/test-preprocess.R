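make_grid_arrays <- function(d, sp) {
  xs <- (seq_len(d[1]) - 0.5) * sp[1]
  ys <- (seq_len(d[2]) - 0.5) * sp[2]
  zs <- (seq_len(d[3]) - 0.5) * sp[3]
  list(X = array(xs, d), Y = array(rep(ys, each = d[1]), d),
       Z = array(rep(zs, each = d[1] * d[2]), d))
}

test_that("bias correction removes most of a known smooth field", {
  d <- c(48, 48, 24); sp <- c(2, 2, 4)
  g <- make_grid_arrays(d, sp)
  field <- 1 + 0.3 * cos(pi * g$X / 96) * cos(pi * g$Y / 96 + 1) +
    0.2 * cos(pi * g$Z / 96 + 0.5)
  brain <- tumor_mask(array(1, d), sp)
  v <- image_volume(100 * field, sp)
  out <- correct_bias(v, brain, 30)
  cv <- function(x) stats::sd(x) / mean(x)
  expect_lte(cv(out$voxels) / cv(v$voxels), 0.25)
})

test_that("bias correction is the identity on a flat unbiased image and preserves the mean", {
  d <- c(24, 24, 12)
  brain <- tumor_mask(array(1, d), c(2, 2, 4))
  flat <- image_volume(array(50, d), c(2, 2, 4))
  out <- correct_bias(flat, brain, 30)
  expect_lt(max(abs(out$voxels / flat$voxels - 1)), 1e-6)

  set.seed(1)
  noisy <- image_volume(array(100 + stats::rnorm(prod(d), 0, 10), d),
                        c(2, 2, 4))
  out2 <- correct_bias(noisy, brain, 30)
  ratio <- mean(out2$voxels) / mean(noisy$voxels)
  expect_gte(ratio, 0.99); expect_lte(ratio, 1.01)

  neg <- image_volume(array(c(-1, rep(10, prod(d) - 1)), d), c(2, 2, 4))
  expect_error(correct_bias(neg, brain), "nonpositive")
})

test_that("resampling: constant stays constant, identity path, ramp is exact", {
  d <- c(20, 20, 8)
  const <- image_volume(array(7, d), c(2, 2, 2))
  out <- resample(const, c(1, 1, 2))
  expect_true(all(out$voxels == 7))
  expect_equal(out$spacing, c(1, 1, 2))
  expect_lte(max(abs(dim(out$voxels) * out$spacing - d * const$spacing)),
             max(out$spacing))

  same <- resample(const, c(2, 2, 2))
  expect_identical(same$voxels, const$voxels)

  ramp <- array(rep(seq(0, 10, length.out = 20), 20 * 8), d)
  v <- image_volume(ramp, c(2, 2, 2))
  r <- resample(v, c(1, 1, 2))
  xs_out <- ((seq_len(dim(r$voxels)[1]) - 0.5) * 1) / 2 + 0.5
  expected <- (pmin(pmax(xs_out, 1), 20) - 1) * 10 / 19
  expect_lt(max(abs(r$voxels[, 10, 4] - expected)), 1e-5)
})

test_that("resample then inverse-resample returns a smooth volume within 2% RMS", {
  d <- c(24, 24, 24)
  g <- make_grid_arrays(d, c(2, 2, 2))
  smooth <- image_volume(10 + sin(pi * g$X / 48) * cos(pi * g$Y / 48) +
                           cos(pi * g$Z / 48), c(2, 2, 2))
  there <- resample(smooth, c(1, 1, 1))
  back <- resample(there, c(2, 2, 2))
  n <- pmin(dim(back$voxels), d)
  rms <- sqrt(mean((back$voxels[1:n[1], 1:n[2], 1:n[3]] -
                      smooth$voxels[1:n[1], 1:n[2], 1:n[3]])^2))
  expect_lt(rms / sqrt(mean(smooth$voxels^2)), 0.02)
})

test_that("brain extraction recovers the phantom brain and passes external masks through", {
  cfg <- small_phantom_cfg(noise_sd = 2, bias_amplitude = 0, seed = 2)
  ph <- generate_phantom(cfg, 1)
  truth <- as.numeric(ph$volume$voxels > 50)  # noise-free foreground is 100+
  mask <- extract_brain(ph$volume)
  expect_gte(dice_coef(mask$voxels, truth), 0.95)

  expect_error(extract_brain(image_volume(array(0, c(8, 8, 8)))),
               "foreground")

  ext <- tumor_mask(array(1, dim(ph$volume$voxels)), ph$volume$spacing)
  expect_identical(extract_brain(ph$volume, external = ext), ext)
})

test_that("normalisation z-scores within the mask and framing preserves the tumor", {
  cfg <- small_phantom_cfg(seed = 3)
  ph <- generate_phantom(cfg, 2)
  brain <- extract_brain(ph$volume)
  framed <- normalize_and_frame(ph$volume, brain, c(32, 32, 16))
  fb <- frame_like(brain, framed)
  m <- fb$voxels > 0
  expect_lt(abs(mean(framed$voxels[m])), 0.05)  # crop may trim mask edges
  expect_equal(stats::sd(framed$voxels[framed$voxels != 0 | m]), 1,
               tolerance = 0.05)

  # padding a small volume keeps the tumor centroid within one voxel
  small <- image_volume(ph$volume$voxels[1:24, 1:24, 1:12],
                        ph$volume$spacing)
  sb <- tumor_mask(brain$voxels[1:24, 1:24, 1:12], ph$volume$spacing)
  pad <- normalize_and_frame(small, sb, c(32, 32, 16))
  expect_identical(dim(pad$voxels), c(32L, 32L, 16L))

  flat <- image_volume(array(5, c(8, 8, 8)))
  allm <- tumor_mask(array(1, c(8, 8, 8)))
  expect_error(normalize_and_frame(flat, allm, c(8, 8, 8)), "variance")
})

test_that("cropping about the centroid retains all mask voxels when they fit", {
  arr <- array(0, c(40, 40, 20))
  arr[18:26, 12:20, 8:12] <- 1   # off-center blob
  vol <- image_volume(arr + stats::rnorm(length(arr), 0, 0.01))
  mask <- tumor_mask(array(as.numeric(arr > 0), dim(arr)))
  framed <- normalize_and_frame(vol, mask, c(16, 16, 8))
  fm <- frame_like(mask, framed)
  expect_equal(sum(fm$voxels), sum(mask$voxels))
})

test_that("the full chain is deterministic, shape-stable and finite", {
  cfg <- small_phantom_cfg(seed = 9)
  ph <- generate_phantom(cfg, 3)
  pcfg <- preprocess_config(target_spacing_mm = c(3, 3, 6),
                            input_size = c(32, 32, 16))
  a <- preprocess_volume(ph$volume, pcfg, mask = ph$mask)
  b <- preprocess_volume(ph$volume, pcfg, mask = ph$mask)
  expect_identical(a$volume$voxels, b$volume$voxels)
  expect_identical(dim(a$volume$voxels), c(32L, 32L, 16L))
  expect_true(all(is.finite(a$volume$voxels)))
  expect_true(all(a$mask$voxels %in% c(0, 1)))
})
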