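#' Stratified development/test split with cross-validation folds
#'
#' Subjects are stratified by (event status, site); within each stratum
#' \code{dev_frac} go to development (within one subject of the target) and
#' development subjects receive balanced 3-fold assignments. The test set is
#' never touched by any fitted statistic downstream.
#'
#' @param clinical data.frame with \code{id}, \code{site}, \code{event}.
#' @param dev_frac development fraction (default 0.7).
#' @param n_folds cross-validation folds on the development set (default 3).
#' @param seed RNG seed.
#' @return An object of class \code{split_plan}: data.frame (id, stratum,
#'   assignment, fold).
#' @export
split_cohort <- function(clinical, dev_frac = 0.7, n_folds = 3, seed = 1L) {
  stratum <- paste0("event", clinical$event, ".site", clinical$site)
  counts <- table(stratum)
  small <- names(counts)[counts < 2]
  if (length(small))
    stop(sprintf("stratum '%s' has fewer than 2 subjects", small[1]))
  assignment <- character(nrow(clinical))
  fold <- rep(NA_integer_, nrow(clinical))
  with_seed(as.integer(seed), {
    for (s in unique(stratum)) {
      idx <- sample(which(stratum == s))
      n_dev <- round(dev_frac * length(idx))
      dev_ids <- idx[seq_len(n_dev)]
      assignment[dev_ids] <- "dev"
      assignment[setdiff(idx, dev_ids)] <- "test"
      if (n_dev > 0)
        fold[dev_ids] <- rep_len(seq_len(n_folds), n_dev)
    }
  })
  structure(data.frame(id = clinical$id, stratum = stratum,
                       assignment = assignment, fold = fold,
                       stringsAsFactors = FALSE),
            class = c("split_plan", "data.frame"))
}

#' Experiment configuration
#'
#' Bundles the stage configurations for \code{\link{run_experiment}}. The
#' defaults are desk-scale (small grids) so a full three-model comparison
#' runs on a laptop CPU.
#'
#' @param n_cohort cohort size for the survival analysis.
#' @param n_pretrain phantoms used to pretrain the segmentation network
#'   (disjoint seeds from the cohort, mirroring a segmentation model
#'   pretrained on separate data).
#' @param phantom a \code{\link{phantom_config}}.
#' @param unet a \code{\link{unet_config}}.
#' @param seg_train a \code{\link{seg_train_config}}.
#' @param n_bins,hidden,dropout survival-network settings.
#' @param surv_train a \code{\link{surv_train_config}}.
#' @param modes model variants to fit.
#' @param horizon_months risk horizon (default 36).
#' @param n_boot bootstrap iterations for the test-set C_td CI.
#' @param seed master seed; all stage seeds derive from it.
#' @return list of class \code{experiment_config}.
#' @export
experiment_config <- function(n_cohort = 150, n_pretrain = 30,
                              phantom = phantom_config(),
                              unet = unet_config(),
                              seg_train = seg_train_config(),
                              n_bins = 20, hidden = 32, dropout = 0.1,
                              surv_train = surv_train_config(),
                              modes = c("clinical", "image", "multimodal"),
                              horizon_months = 36, n_boot = 200,
                              seed = 1L) {
  structure(list(n_cohort = n_cohort, n_pretrain = n_pretrain,
                 phantom = phantom, unet = unet, seg_train = seg_train,
                 n_bins = n_bins, hidden = hidden, dropout = dropout,
                 surv_train = surv_train, modes = modes,
                 horizon_months = horizon_months, n_boot = n_boot,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

config_hash <- function(config) {
  txt <- paste(deparse(config), collapse = "")
  sprintf("%08x", sum(utf8ToInt(txt) * (seq_along(utf8ToInt(txt)) %% 251)) %%
            .Machine$integer.max)
}

# Frame phantom volumes/masks to the network input size (phantoms are
# already bias-free enough for segmentation training; the full chain is
# exercised separately and in preprocess tests).
frame_phantom <- function(img, input_size) {
  vol <- img$volume
  brain <- extract_brain(vol)
  framed <- normalize_and_frame(vol, brain, input_size)
  list(volume = framed,
       mask = if (!is.null(img$mask)) frame_like(img$mask, framed))
}

#' Pretrain the segmentation network on phantoms
#'
#' @param config an \code{\link{experiment_config}}.
#' @return trained \code{unet3d}.
#' @export
pretrain_segmenter <- function(config) {
  ph_cfg <- config$phantom
  ph_cfg$seed <- combine_seed(config$seed, 7919L)
  pre <- generate_cohort(config$n_pretrain, ph_cfg, image = TRUE,
                         seed_offset = 500000L)
  framed <- lapply(pre$images, frame_phantom, config$unet$input_size)
  train_segmentation(lapply(framed, `[[`, "volume"),
                     lapply(framed, `[[`, "mask"),
                     config$unet, config$seg_train)
}

#' Run the full multimodal survival experiment
#'
#' Generates (or accepts) a phantom cohort, pretrains the segmentation
#' U-Net on disjoint phantoms, extracts frozen-encoder features, splits
#' 70/30 stratified by (event, site), selects the training epoch count by
#' 3-fold cross-validated validation loss, refits each model variant on the
#' full development set, and evaluates on the held-out test set:
#' time-dependent C-index with bootstrap CI, time-dependent AUC at the
#' horizon, expected calibration error, integrated Brier score and
#' median-split risk stratification (threshold from pooled out-of-fold
#' development predictions).
#'
#' @param config an \code{\link{experiment_config}}.
#' @param segmenter optionally, an already-pretrained \code{unet3d}.
#' @param cohort optionally, a pre-generated cohort from
#'   \code{\link{generate_cohort}}.
#' @param features optionally, a precomputed feature matrix aligned with
#'   \code{cohort$clinical} (skips framing and extraction; the frozen
#'   encoder makes features reusable across seeds).
#' @param out_dir optional directory for the JSON report and CSV curves.
#' @return list of class \code{experiment_report}: per-mode metrics,
#'   the split plan, the segmenter hash before/after, and the config hash.
#' @export
run_experiment <- function(config, segmenter = NULL, cohort = NULL,
                           features = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  need_images <- any(config$modes %in% c("image", "multimodal"))
  need_extract <- need_images && is.null(features)
  if (is.null(segmenter) && need_extract)
    segmenter <- pretrain_segmenter(config)

  ph_cfg <- config$phantom
  ph_cfg$seed <- combine_seed(config$seed, 104729L)
  if (is.null(cohort))
    cohort <- generate_cohort(config$n_cohort, ph_cfg,
                              image = need_extract)
  clinical <- cohort$clinical

  feats <- features
  hash_before <- NULL
  if (need_extract) {
    framed <- lapply(cohort$images, frame_phantom, config$unet$input_size)
    feats <- extract_feature_matrix(segmenter,
                                    lapply(framed, `[[`, "volume"),
                                    ids = clinical$id)
    hash_before <- param_hash(segmenter$params)
  }

  cm <- clinical_matrix(clinical, na_action = "drop")
  keep <- cm$keep
  clinical <- clinical[keep, , drop = FALSE]
  xc <- cm$x
  if (!is.null(feats)) feats <- feats[keep, , drop = FALSE]

  plan <- split_cohort(clinical, seed = combine_seed(config$seed, 15485863L))
  dev <- which(plan$assignment == "dev")
  test <- which(plan$assignment == "test")

  grid <- make_time_grid(clinical$time_months[dev], config$n_bins)
  targets <- discretize(clinical$time_months, clinical$event, grid)

  results <- list()
  for (mode in config$modes) {
    results[[mode]] <- fit_and_evaluate_mode(
      mode, feats, xc, targets, grid, clinical, dev, test, plan, config)
  }

  report <- structure(
    list(metrics = results, split = plan, grid = grid,
         config_hash = config_hash(config),
         encoder_hash = list(before = hash_before,
                             after = if (need_extract)
                               param_hash(segmenter$params)),
         n = nrow(clinical), seed = config$seed),
    class = "experiment_report")

  if (!is.null(out_dir)) write_report(report, results, out_dir)
  report
}

# CV epoch selection + refit + held-out evaluation for one model variant.
fit_and_evaluate_mode <- function(mode, feats, xc, targets, grid, clinical,
                                  dev, test, plan, config) {
  xi <- if (mode %in% c("image", "multimodal")) feats
  xcl <- if (mode %in% c("clinical", "multimodal")) xc
  folds <- plan$fold[dev]
  oof_risk <- numeric(length(dev))
  best_epochs <- integer(0)
  for (f in sort(unique(folds))) {
    val <- dev[folds == f]
    tr_ids <- c(dev[folds != f], val)  # val rows appended, flagged below
    net <- build_survival_net(mode,
                              image_dim = if (!is.null(xi)) ncol(xi),
                              n_bins = grid$n_bins, hidden = config$hidden,
                              dropout = config$dropout,
                              seed = combine_seed(config$seed, 31L + f))
    cfg_f <- config$surv_train
    cfg_f$early_stop <- TRUE
    cfg_f$seed <- combine_seed(config$seed, 131L + f)
    fit <- train_survival(net, targets[tr_ids, ],
                          x_image = if (!is.null(xi))
                            xi[tr_ids, , drop = FALSE],
                          x_clinical = if (!is.null(xcl))
                            xcl[tr_ids, , drop = FALSE],
                          grid = grid, cfg = cfg_f,
                          val_ids = seq(length(tr_ids) - length(val) + 1,
                                        length(tr_ids)))
    best_epochs <- c(best_epochs, which.min(fit$val_loss))
    curves <- predict_survival(fit,
                               x_image = if (!is.null(xi))
                                 xi[val, , drop = FALSE],
                               x_clinical = if (!is.null(xcl))
                                 xcl[val, , drop = FALSE])
    oof_risk[folds == f] <- risk_score(curves, config$horizon_months)
  }

  cfg_r <- config$surv_train
  cfg_r$epochs <- max(5L, round(mean(best_epochs)))
  cfg_r$seed <- combine_seed(config$seed, 997L)
  net <- build_survival_net(mode,
                            image_dim = if (!is.null(xi)) ncol(xi),
                            n_bins = grid$n_bins, hidden = config$hidden,
                            dropout = config$dropout,
                            seed = combine_seed(config$seed, 499L))
  fit <- train_survival(net, targets[dev, ],
                        x_image = if (!is.null(xi))
                          xi[dev, , drop = FALSE],
                        x_clinical = if (!is.null(xcl))
                          xcl[dev, , drop = FALSE],
                        grid = grid, cfg = cfg_r)

  curves <- predict_survival(fit,
                             x_image = if (!is.null(xi))
                               xi[test, , drop = FALSE],
                             x_clinical = if (!is.null(xcl))
                               xcl[test, , drop = FALSE])
  tt <- clinical$time_months[test]
  te <- clinical$event[test]
  risk <- risk_score(curves, config$horizon_months)

  ctd_ci <- bootstrap_ci(
    function(idx) ctd_index(curves[idx, , drop = FALSE], tt[idx], te[idx]),
    n = length(test), n_boot = config$n_boot,
    seed = combine_seed(config$seed, 2027L), name = paste0("Ctd_", mode))

  auc <- tryCatch(td_auc(risk, tt, te, config$horizon_months),
                  error = function(e) NA_real_)
  ece <- ece_calibration(1 - risk, tt, te, horizon = config$horizon_months)
  ibs <- integrated_brier(curves, tt, te)
  strat <- stratify_median(oof_risk, risk, tt, te, config$horizon_months)

  list(mode = mode, ctd = ctd_ci, td_auc = auc, ece = ece$ece, ibs = ibs,
       stratification = strat, best_epochs = best_epochs, model = fit,
       test_curves = curves, oof_risk = oof_risk)
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report> n=%d, config %s, seed %d\n", x$n,
              x$config_hash, x$seed))
  for (m in names(x$metrics)) {
    r <- x$metrics[[m]]
    cat(sprintf(
      "  %-10s Ctd %.3f (%.3f-%.3f)  AUC %.3f  ECE %.3f  IBS %.3f\n",
      m, r$ctd$point, r$ctd$ci_low, r$ctd$ci_high, r$td_auc, r$ece, r$ibs))
  }
  invisible(x)
}

write_report <- function(report, results, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  metrics <- lapply(results, function(r)
    list(ctd = list(point = r$ctd$point, ci_low = r$ctd$ci_low,
                    ci_high = r$ctd$ci_high, n_boot = r$ctd$n_boot,
                    seed = r$ctd$seed),
         td_auc = r$td_auc, ece = r$ece, ibs = r$ibs,
         logrank_p = r$stratification$logrank$p,
         efs_horizon = as.list(r$stratification$efs_horizon)))
  jsonlite::write_json(
    list(config_hash = report$config_hash, seed = report$seed,
         n = report$n, metrics = metrics),
    file.path(out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
  for (m in names(results)) {
    S <- unclass(results[[m]]$test_curves)
    df <- data.frame(edge_months = rep(report$grid$edges, each = nrow(S)),
                     subject = rep(seq_len(nrow(S)), ncol(S)),
                     S = as.numeric(S))
    utils::write.csv(df, file.path(out_dir, paste0("curves_", m, ".csv")),
                     row.names = FALSE)
  }
  invisible(out_dir)
}

#' Incremental fine-tuning on an external site
#'
#' Fine-tunes a fitted survival network head on increasing fractions of an
#' external site's development data (the image encoder stays frozen
#' throughout — the network consumes fixed feature vectors) and evaluates
#' each on the external held-out subjects. Fraction 0 reports the base
#' model unchanged.
#'
#' @param base_net fitted \code{hazard_net}.
#' @param x_image,x_clinical external-site inputs (site disjoint from the
#'   base training data).
#' @param times,events external-site outcome.
#' @param fractions fractions of the external development pool to use.
#' @param cfg fine-tuning \code{\link{surv_train_config}} (typically few
#'   epochs, low learning rate).
#' @param holdout_frac external subjects held out for evaluation.
#' @param horizon_months risk horizon.
#' @param seed RNG seed.
#' @return data.frame (fraction, n_used, ctd); fractions yielding fewer
#'   than 5 subjects are skipped with a warning.
#' @export
finetune_incremental <- function(base_net, x_image = NULL,
                                 x_clinical = NULL, times, events,
                                 fractions = c(0, 0.25, 0.5, 1),
                                 cfg = surv_train_config(epochs = 30,
                                                         lr = 1e-3),
                                 holdout_frac = 0.3, horizon_months = 36,
                                 seed = 1L) {
  n <- length(times)
  idx <- with_seed(as.integer(seed), sample.int(n))
  n_hold <- max(2L, round(holdout_frac * n))
  hold <- idx[seq_len(n_hold)]
  pool <- idx[-seq_len(n_hold)]
  grid <- base_net$grid
  targets <- discretize(times, events, grid)
  eval_ctd <- function(net) {
    curves <- predict_survival(net,
                               x_image = if (!is.null(x_image))
                                 x_image[hold, , drop = FALSE],
                               x_clinical = if (!is.null(x_clinical))
                                 x_clinical[hold, , drop = FALSE])
    ctd_index(curves, times[hold], events[hold])
  }
  rows <- list()
  for (f in fractions) {
    if (f == 0) {
      rows[[length(rows) + 1]] <-
        data.frame(fraction = 0, n_used = 0, ctd = eval_ctd(base_net))
      next
    }
    use <- pool[seq_len(round(f * length(pool)))]
    if (length(use) < 5) {
      warning(sprintf("fraction %.2f yields %d (< 5) subjects; skipped",
                      f, length(use)))
      next
    }
    cfg_f <- cfg
    cfg_f$seed <- combine_seed(seed, round(1000 * f))
    tuned <- train_survival(base_net, targets[use, ],
                            x_image = if (!is.null(x_image))
                              x_image[use, , drop = FALSE],
                            x_clinical = if (!is.null(x_clinical))
                              x_clinical[use, , drop = FALSE],
                            cfg = cfg_f, keep_norm = TRUE)
    rows[[length(rows) + 1]] <-
      data.frame(fraction = f, n_used = length(use), ctd = eval_ctd(tuned))
  }
  do.call(rbind, rows)
}

# --- from-scratch CNN baseline ---------------------------------------------

#' Train an end-to-end CNN survival model from scratch
#'
#' A small 3D CNN (the U-Net encoder architecture) followed by adaptive
#' average pooling and two fully connected layers emitting per-bin hazard
#' logits, trained end-to-end with the logistic-hazard loss — the
#' no-transfer baseline against the frozen-encoder feature pathway.
#'
#' @param volumes list of framed volumes.
#' @param targets data.frame from \code{\link{discretize}}.
#' @param grid the \code{time_grid}.
#' @param unet_cfg encoder architecture (\code{\link{unet_config}}).
#' @param hidden width of the fully connected layer.
#' @param epochs,lr,batch,seed optimiser settings.
#' @return An object of class \code{scratch_cnn}.
#' @export
scratch_baseline <- function(volumes, targets, grid,
                             unet_cfg = unet_config(n_levels = 2,
                                                    base_channels = 4),
                             hidden = 16, epochs = 6, lr = 1e-3,
                             batch = 4, seed = 1L) {
  xs <- lapply(volumes, as_input4d)
  n <- length(xs)
  stopifnot(n == nrow(targets))
  enc <- build_unet(unet_cfg)$params
  enc <- enc[grep("^e", names(enc))]
  fdim <- unet_cfg$feature_dim
  J <- grid$n_bins
  head <- with_seed(combine_seed(seed, 11L), list(
    hW1 = matrix(stats::rnorm(fdim * hidden, 0, sqrt(2 / fdim)), fdim,
                 hidden),
    hb1 = numeric(hidden),
    hW2 = matrix(stats::rnorm(hidden * J, 0, sqrt(1 / hidden)), hidden, J),
    hb2 = numeric(J)))
  params <- c(enc, head)
  state <- adam_init(params)
  losses <- numeric(epochs)
  t_step <- 0L
  with_seed(as.integer(seed), {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      starts <- seq(1, n, by = batch)
      ep_loss <- 0
      for (s in starts) {
        ids <- ord[s:min(s + batch - 1, n)]
        gacc <- lapply(params, function(p) p * 0)
        bl <- 0
        for (i in ids) {
          fw <- unet_encoder_fwd(params, unet_cfg, xs[[i]],
                                 keep_cache = TRUE)
          pooled <- adaptive_pool(fw$bottleneck, unet_cfg$pooled_grid)
          feat <- matrix(as.numeric(pooled), 1, fdim)
          A1 <- pmax(feat %*% params$hW1 +
                       matrix(params$hb1, 1, hidden), 0)
          Z <- A1 %*% params$hW2 + matrix(params$hb2, 1, J)
          Z <- pmin(pmax(Z, -15), 15)
          lg <- hnet_loss_grad(Z, targets$bin[i], targets$event[i])
          G <- lg$grad / length(ids)
          gacc$hW2 <- gacc$hW2 + t(A1) %*% G
          gacc$hb2 <- gacc$hb2 + colSums(G)
          gA1 <- (G %*% t(params$hW2)) * (A1 > 0)
          gacc$hW1 <- gacc$hW1 + t(feat) %*% gA1
          gacc$hb1 <- gacc$hb1 + colSums(gA1)
          gfeat <- gA1 %*% t(params$hW1)
          gpool <- array(gfeat, dim(pooled))
          gbot <- adaptive_pool_bwd(gpool, dim(fw$bottleneck))
          gacc <- unet_encoder_bwd(params, unet_cfg, fw$cache,
                                   gbot / length(ids), NULL, gacc)
          bl <- bl + lg$loss / length(ids)
        }
        t_step <- t_step + 1L
        upd <- adam_step(params, gacc, state, lr, t_step)
        params <- upd$params; state <- upd$state
        ep_loss <- ep_loss + bl * length(ids) / n
      }
      losses[ep] <- ep_loss
    }
  })
  structure(list(params = params, unet_cfg = unet_cfg, hidden = hidden,
                 grid = grid, loss_log = losses),
            class = "scratch_cnn")
}

#' @export
print.scratch_cnn <- function(x, ...) {
  cat(sprintf("<scratch_cnn> encoder %d levels, %d bins; final loss %.4f\n",
              x$unet_cfg$n_levels, x$grid$n_bins,
              x$loss_log[length(x$loss_log)]))
  invisible(x)
}

#' @export
predict.scratch_cnn <- function(object, volumes, ...) {
  params <- object$params
  cfg <- object$unet_cfg
  J <- object$grid$n_bins
  S <- t(vapply(volumes, function(v) {
    fw <- unet_encoder_fwd(params, cfg, as_input4d(v))
    pooled <- adaptive_pool(fw$bottleneck, cfg$pooled_grid)
    feat <- matrix(as.numeric(pooled), 1, cfg$feature_dim)
    A1 <- pmax(feat %*% params$hW1 + matrix(params$hb1, 1, object$hidden),
               0)
    Z <- A1 %*% params$hW2 + matrix(params$hb2, 1, J)
    Z <- pmin(pmax(Z, -15), 15)
    h <- stats::plogis(as.numeric(Z))
    c(1, cumprod(1 - h))
  }, numeric(J + 1)))
  structure(S, class = c("survival_curves", "matrix"), grid = object$grid)
}
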