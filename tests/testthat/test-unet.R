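test_that("network construction: determinism, feature-dim bookkeeping, preconditions", {
  cfg <- small_unet_cfg(seed = 5)
  a <- build_unet(cfg); b <- build_unet(cfg)
  expect_identical(a$params, b$params)
  expect_equal(cfg$feature_dim,
               cfg$base_channels * cfg$channel_growth^(cfg$n_levels - 1) *
                 prod(cfg$pooled_grid))
  expect_error(unet_config(n_levels = 1), "downsample")
  expect_error(unet_config(n_levels = 3, input_size = c(16, 16, 8),
                           pooled_grid = c(8, 8, 8)), "pooled_grid")
})

test_that("analytic gradients match central finite differences", {
  set.seed(2)
  cfg <- unet_config(n_levels = 2, base_channels = 2,
                     pooled_grid = c(1, 1, 1), input_size = c(8, 8, 8),
                     seed = 3)
  net <- build_unet(cfg)
  x <- array(stats::rnorm(8 * 8 * 8), c(8, 8, 8, 1))
  y <- array(as.numeric(stats::runif(8 * 8 * 8) < 0.3), c(8, 8, 8))
  lossfun <- function(params) {
    fw <- gliohazard:::unet_fwd(params, cfg, x)
    gliohazard:::seg_loss(fw$logits, y)$loss
  }
  fw <- gliohazard:::unet_fwd(net$params, cfg, x, keep_cache = TRUE)
  sl <- gliohazard:::seg_loss(fw$logits, y)
  gr <- gliohazard:::unet_bwd(net$params, cfg, fw, sl$grad)
  eps <- 1e-5
  for (nm in names(net$params)) {
    for (t in 1:2) {
      i <- sample(length(net$params[[nm]]), 1)
      p1 <- net$params; p1[[nm]][i] <- p1[[nm]][i] + eps
      p2 <- net$params; p2[[nm]][i] <- p2[[nm]][i] - eps
      fd <- (lossfun(p1) - lossfun(p2)) / (2 * eps)
      expect_lt(abs(fd - gr[[nm]][i]) /
                  max(1e-6, abs(fd) + abs(gr[[nm]][i])), 1e-4)
    }
  }
})

test_that("training on easy phantoms reduces loss and segments held-out tumors", {
  model <- trained_small_segmenter()
  expect_lt(model$loss_log[length(model$loss_log)], model$loss_log[1])
  fx <- framed_small_cohort(40, seed = 1)
  dice <- vapply(31:40, function(i) {
    pred <- segment(model, fx$volumes[[i]])
    dice_coef(pred$voxels, fx$masks[[i]]$voxels)
  }, numeric(1))
  expect_gte(mean(dice), 0.70)
})

test_that("zero learning rate leaves parameters and loss unchanged", {
  fx <- framed_small_cohort(40, seed = 1)
  cfg <- small_unet_cfg(seed = 2)
  m0 <- build_unet(cfg)
  m <- train_segmentation(fx$volumes[1:10], fx$masks[1:10], cfg,
                          seg_train_config(epochs = 2, lr = 0))
  expect_equal(m$params, m0$params, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_lt(diff(range(m$loss_log)), 1e-8)
})

test_that("training preconditions: enough phantoms, nonempty masks, fixed-seed reproducibility", {
  fx <- framed_small_cohort(40, seed = 1)
  expect_error(train_segmentation(fx$volumes[1:5], fx$masks[1:5],
                                  small_unet_cfg()), "at least 10")
  empty <- lapply(1:10, function(i)
    tumor_mask(array(0, c(32, 32, 16)), c(3, 3, 6)))
  expect_error(train_segmentation(fx$volumes[1:10], empty,
                                  small_unet_cfg()), "empty")
  cfg <- small_unet_cfg(seed = 4)
  tc <- seg_train_config(epochs = 1, lr = 1e-3, seed = 9)
  m1 <- train_segmentation(fx$volumes[1:10], fx$masks[1:10], cfg, tc)
  m2 <- train_segmentation(fx$volumes[1:10], fx$masks[1:10], cfg, tc)
  expect_equal(m1$loss_log, m2$loss_log, tolerance = 1e-10)
})

test_that("segmentation handles degenerate input and is deterministic", {
  model <- trained_small_segmenter()
  zero <- array(0, c(32, 32, 16))
  mk <- segment(model, zero)
  expect_true(all(mk$voxels %in% c(0, 1)))
  expect_identical(segment(model, zero)$voxels, mk$voxels)
  expect_error(segment(model, array(0, c(10, 10, 10))),
               "does not match")
})

test_that("feature extraction is pure, fixed-length, and carries geometric signal", {
  model <- trained_small_segmenter()
  fx <- framed_small_cohort(40, seed = 1)
  f1 <- extract_features(model, fx$volumes[[1]])
  expect_identical(f1, extract_features(model, fx$volumes[[1]]))
  expect_length(f1, model$config$feature_dim)

  feats <- extract_feature_matrix(model, fx$volumes)
  vols <- fx$clinical$log_volume_cm3
  # volumes differing in size give distinct features
  i_small <- which.min(vols); i_big <- which.max(vols)
  expect_gt(sqrt(sum((feats[i_small, ] - feats[i_big, ])^2)), 0)

  # linear probe on leading principal components predicts log volume
  pc <- stats::prcomp(feats, rank. = 8)$x
  tr <- 1:30; te <- 31:40
  fit <- stats::lm(vols[tr] ~ pc[tr, ])
  pred <- cbind(1, pc[te, ]) %*% stats::coef(fit)
  r2 <- 1 - sum((vols[te] - pred)^2) / sum((vols[te] - mean(vols[tr]))^2)
  expect_gte(r2, 0.5)

  # permutation control: shuffled labels are not predictable
  set.seed(7)
  r2p <- replicate(5, {
    vp <- sample(vols)
    fitp <- stats::lm(vp[tr] ~ pc[tr, ])
    predp <- cbind(1, pc[te, ]) %*% stats::coef(fitp)
    1 - sum((vp[te] - predp)^2) / sum((vp[te] - mean(vp[tr]))^2)
  })
  expect_gt(r2, max(r2p))
})
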