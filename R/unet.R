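#' 3D U-Net configuration
#'
#' A compact encoder--decoder segmentation network with skip connections.
#' The deepest encoder activation, adaptive-average-pooled to
#' \code{pooled_grid} and flattened, is the deep image feature vector used
#' by the survival models; \code{feature_dim} is therefore
#' \code{base_channels * channel_growth^(n_levels - 1) * prod(pooled_grid)}.
#' The full-size preset (5 levels, 32 base channels, 2 x 2 x 2 pooled grid,
#' input 96 x 192 x 192) yields 512 bottleneck channels and a 4096-long
#' feature vector.
#'
#' @param n_levels number of resolution levels (>= 2; each level below the
#'   first halves the grid).
#' @param base_channels channels at the first level.
#' @param channel_growth per-level channel multiplier.
#' @param pooled_grid adaptive-average-pool target at the bottleneck.
#' @param input_size expected framed input size (voxels); used to validate
#'   that the bottleneck is at least \code{pooled_grid}.
#' @param seed integer; parameter initialisation seed.
#' @param full_size if TRUE, use the full-size defaults above.
#' @return An object of class \code{unet_config}.
#' @export
unet_config <- function(n_levels = 3, base_channels = 8, channel_growth = 2,
                        pooled_grid = c(2, 2, 2),
                        input_size = c(64, 64, 32), seed = 1L,
                        full_size = FALSE) {
  if (full_size) {
    n_levels <- 5; base_channels <- 32; channel_growth <- 2
    pooled_grid <- c(2, 2, 2); input_size <- c(96, 192, 192)
  }
  if (n_levels < 2)
    stop("n_levels must be >= 2: the encoder must downsample")
  channels <- base_channels * channel_growth^(seq_len(n_levels) - 1)
  bottleneck <- as.integer(input_size / 2^(n_levels - 1))
  if (any(input_size %% 2^(n_levels - 1) != 0))
    stop("input_size must be divisible by 2^(n_levels - 1)")
  if (any(pooled_grid > bottleneck))
    stop(sprintf(
      "pooled_grid (%s) exceeds the bottleneck spatial size (%s)",
      paste(pooled_grid, collapse = "x"),
      paste(bottleneck, collapse = "x")))
  structure(list(n_levels = as.integer(n_levels),
                 base_channels = as.integer(base_channels),
                 channel_growth = channel_growth,
                 channels = as.integer(channels),
                 pooled_grid = as.integer(pooled_grid),
                 input_size = as.integer(input_size),
                 feature_dim = as.integer(channels[n_levels] *
                                            prod(pooled_grid)),
                 seed = as.integer(seed)),
            class = "unet_config")
}

he_init <- function(k, cin, cout) {
  array(stats::rnorm(k^3 * cin * cout, 0, sqrt(2 / (k^3 * cin))),
        dim = c(k, k, k, cin, cout))
}

#' Build a 3D segmentation U-Net
#'
#' Parameters are He-initialised deterministically under \code{config$seed}.
#'
#' @param config a \code{\link{unet_config}}.
#' @return An object of class \code{unet3d} (config + named parameter list).
#' @export
build_unet <- function(config) {
  stopifnot(inherits(config, "unet_config"))
  ch <- config$channels
  L <- config$n_levels
  params <- with_seed(config$seed, {
    p <- list()
    cin <- 1L
    for (l in seq_len(L)) {
      p[[sprintf("e%dc1.W", l)]] <- he_init(3, cin, ch[l])
      p[[sprintf("e%dc1.b", l)]] <- numeric(ch[l])
      p[[sprintf("e%dc2.W", l)]] <- he_init(3, ch[l], ch[l])
      p[[sprintf("e%dc2.b", l)]] <- numeric(ch[l])
      cin <- ch[l]
    }
    for (l in rev(seq_len(L - 1))) {
      p[[sprintf("d%dc1.W", l)]] <- he_init(3, ch[l + 1] + ch[l], ch[l])
      p[[sprintf("d%dc1.b", l)]] <- numeric(ch[l])
      p[[sprintf("d%dc2.W", l)]] <- he_init(3, ch[l], ch[l])
      p[[sprintf("d%dc2.b", l)]] <- numeric(ch[l])
    }
    p[["out.W"]] <- he_init(1, ch[1], 2L)
    p[["out.b"]] <- numeric(2L)
    p
  })
  structure(list(config = config, params = params, loss_log = NULL),
            class = "unet3d")
}

#' @export
print.unet3d <- function(x, ...) {
  cfg <- x$config
  np <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf(
    "<unet3d> %d levels, channels %s, feature_dim %d, %s parameters\n",
    cfg$n_levels, paste(cfg$channels, collapse = "/"), cfg$feature_dim,
    format(np, big.mark = ",")))
  if (!is.null(x$loss_log))
    cat(sprintf("  trained %d epochs, final loss %.4f\n",
                length(x$loss_log), x$loss_log[length(x$loss_log)]))
  invisible(x)
}

# --- low-level wrappers -----------------------------------------------------

conv_fwd <- function(x, W, b) {
  d <- dim(x)
  out <- conv3d_fwd(x, d[1:3], W, b, dim(W)[1], d[4], dim(W)[5])
  array(out, c(d[1:3], dim(W)[5]))
}

conv_bwd_input <- function(g, W) {
  d <- dim(g)
  out <- conv3d_grad_input(g, d[1:3], W, dim(W)[1], dim(W)[4], dim(W)[5])
  array(out, c(d[1:3], dim(W)[4]))
}

conv_bwd_weights <- function(x, g, k) {
  d <- dim(x)
  r <- conv3d_grad_weights(x, g, d[1:3], k, d[4], dim(g)[4])
  list(gW = array(r$gW, c(k, k, k, d[4], dim(g)[4])), gb = r$gb)
}

pool_fwd <- function(x) {
  d <- dim(x)
  r <- maxpool3d_fwd(x, d[1:3], d[4])
  list(out = array(r$out, c(d[1:3] %/% 2L, d[4])), argmax = r$argmax,
       in_len = length(x))
}

pool_bwd <- function(g, pool) {
  d2 <- dim(g)
  array(maxpool3d_bwd(g, pool$argmax, pool$in_len),
        c(d2[1:3] * 2L, d2[4]))
}

upsample2 <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2),
    rep(seq_len(d[3]), each = 2), , drop = FALSE]
}

upsample2_bwd <- function(g) {
  d <- dim(g)
  h <- d[1:3] %/% 2L
  dim(g) <- c(2, h[1], 2, h[2], 2, h[3], d[4])
  g <- aperm(g, c(1, 3, 5, 2, 4, 6, 7))
  dim(g) <- c(8, prod(h) * d[4])
  array(colSums(g), c(h, d[4]))
}

# Adaptive average pooling of a (x, y, z, c) activation to pooled_grid.
adaptive_pool <- function(x, grid) {
  d <- dim(x)
  out <- array(0, c(grid, d[4]))
  cuts <- lapply(1:3, function(ax) round(seq(0, d[ax], length.out =
                                               grid[ax] + 1)))
  for (i in seq_len(grid[1])) for (j in seq_len(grid[2]))
    for (k in seq_len(grid[3])) {
      xi <- (cuts[[1]][i] + 1):cuts[[1]][i + 1]
      yj <- (cuts[[2]][j] + 1):cuts[[2]][j + 1]
      zk <- (cuts[[3]][k] + 1):cuts[[3]][k + 1]
      out[i, j, k, ] <- apply(x[xi, yj, zk, , drop = FALSE], 4, mean)
    }
  out
}

# Adjoint of adaptive_pool: spread each pooled gradient uniformly.
adaptive_pool_bwd <- function(g, in_dim) {
  grid <- dim(g)[1:3]
  out <- array(0, in_dim)
  cuts <- lapply(1:3, function(ax) round(seq(0, in_dim[ax], length.out =
                                               grid[ax] + 1)))
  for (i in seq_len(grid[1])) for (j in seq_len(grid[2]))
    for (k in seq_len(grid[3])) {
      xi <- (cuts[[1]][i] + 1):cuts[[1]][i + 1]
      yj <- (cuts[[2]][j] + 1):cuts[[2]][j + 1]
      zk <- (cuts[[3]][k] + 1):cuts[[3]][k + 1]
      ncell <- length(xi) * length(yj) * length(zk)
      for (c in seq_len(in_dim[4]))
        out[xi, yj, zk, c] <- out[xi, yj, zk, c] + g[i, j, k, c] / ncell
    }
  out
}

# --- forward / backward -----------------------------------------------------

as_input4d <- function(vol) {
  x <- if (inherits(vol, "image_volume")) vol$voxels else vol
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  x
}

# Encoder pass. Returns bottleneck activation, per-level skips and (if
# keep_cache) everything needed for the backward pass.
unet_encoder_fwd <- function(params, cfg, x, keep_cache = FALSE) {
  L <- cfg$n_levels
  skips <- vector("list", L)
  cache <- if (keep_cache) list(levels = vector("list", L)) else NULL
  for (l in seq_len(L)) {
    x_in <- x
    a1 <- conv_fwd(x_in, params[[sprintf("e%dc1.W", l)]],
                   params[[sprintf("e%dc1.b", l)]])
    r1 <- pmax(a1, 0)
    a2 <- conv_fwd(r1, params[[sprintf("e%dc2.W", l)]],
                   params[[sprintf("e%dc2.b", l)]])
    r2 <- pmax(a2, 0)
    skips[[l]] <- r2
    pool <- NULL
    if (l < L) {
      pool <- pool_fwd(r2)
      x <- pool$out
    } else x <- r2
    if (keep_cache)
      cache$levels[[l]] <- list(x_in = x_in, m1 = a1 > 0, r1 = r1,
                                m2 = a2 > 0, pool = pool)
    rm(a1, a2)
  }
  list(bottleneck = x, skips = skips, cache = cache)
}

# Backward through the encoder given gradients on the bottleneck output and
# (optionally) on each skip. Accumulates parameter gradients into `grads`.
unet_encoder_bwd <- function(params, cfg, cache, g_bottleneck,
                             g_skips = NULL, grads) {
  L <- cfg$n_levels
  g <- g_bottleneck
  for (l in rev(seq_len(L))) {
    cv <- cache$levels[[l]]
    if (l < L) {
      g <- pool_bwd(g, cv$pool)
      if (!is.null(g_skips) && !is.null(g_skips[[l]]))
        g <- g + g_skips[[l]]
    } else if (!is.null(g_skips) && !is.null(g_skips[[l]])) {
      g <- g + g_skips[[l]]
    }
    ga2 <- g * cv$m2
    wg <- conv_bwd_weights(cv$r1, ga2, 3L)
    grads[[sprintf("e%dc2.W", l)]] <- grads[[sprintf("e%dc2.W", l)]] + wg$gW
    grads[[sprintf("e%dc2.b", l)]] <- grads[[sprintf("e%dc2.b", l)]] + wg$gb
    gr1 <- conv_bwd_input(ga2, params[[sprintf("e%dc2.W", l)]])
    ga1 <- gr1 * cv$m1
    wg <- conv_bwd_weights(cv$x_in, ga1, 3L)
    grads[[sprintf("e%dc1.W", l)]] <- grads[[sprintf("e%dc1.W", l)]] + wg$gW
    grads[[sprintf("e%dc1.b", l)]] <- grads[[sprintf("e%dc1.b", l)]] + wg$gb
    g <- conv_bwd_input(ga1, params[[sprintf("e%dc1.W", l)]])
  }
  grads
}

# Full forward (encoder + decoder + 1x1 output conv) -> voxelwise logits.
unet_fwd <- function(params, cfg, x, keep_cache = FALSE) {
  enc <- unet_encoder_fwd(params, cfg, x, keep_cache)
  L <- cfg$n_levels
  y <- enc$bottleneck
  dcache <- if (keep_cache) vector("list", L - 1) else NULL
  for (l in rev(seq_len(L - 1))) {
    u <- upsample2(y)
    cc <- array(c(u, enc$skips[[l]]),
                c(dim(u)[1:3], dim(u)[4] + dim(enc$skips[[l]])[4]))
    a1 <- conv_fwd(cc, params[[sprintf("d%dc1.W", l)]],
                   params[[sprintf("d%dc1.b", l)]])
    r1 <- pmax(a1, 0)
    a2 <- conv_fwd(r1, params[[sprintf("d%dc2.W", l)]],
                   params[[sprintf("d%dc2.b", l)]])
    y <- pmax(a2, 0)
    if (keep_cache)
      dcache[[l]] <- list(cc = cc, m1 = a1 > 0, r1 = r1, m2 = a2 > 0,
                          n_up = dim(u)[4])
  }
  logits <- conv_fwd(y, params[["out.W"]], params[["out.b"]])
  list(logits = logits, y1 = y, enc = enc, dcache = dcache)
}

# Backward from d(loss)/d(logits); returns the full gradient list.
unet_bwd <- function(params, cfg, fw, glogits) {
  grads <- lapply(params, function(p) array(0, dim(p) %||% length(p)))
  wg <- conv_bwd_weights(fw$y1, glogits, 1L)
  grads[["out.W"]] <- wg$gW
  grads[["out.b"]] <- wg$gb
  g <- conv_bwd_input(glogits, params[["out.W"]])
  L <- cfg$n_levels
  g_skips <- vector("list", L)
  for (l in seq_len(L - 1)) {
    dc <- fw$dcache[[l]]
    ga2 <- g * dc$m2
    wg <- conv_bwd_weights(dc$r1, ga2, 3L)
    grads[[sprintf("d%dc2.W", l)]] <- wg$gW
    grads[[sprintf("d%dc2.b", l)]] <- wg$gb
    gr1 <- conv_bwd_input(ga2, params[[sprintf("d%dc2.W", l)]])
    ga1 <- gr1 * dc$m1
    wg <- conv_bwd_weights(dc$cc, ga1, 3L)
    grads[[sprintf("d%dc1.W", l)]] <- wg$gW
    grads[[sprintf("d%dc1.b", l)]] <- wg$gb
    gc <- conv_bwd_input(ga1, params[[sprintf("d%dc1.W", l)]])
    nu <- dc$n_up
    gu <- gc[, , , seq_len(nu), drop = FALSE]
    g_skips[[l]] <- gc[, , , -seq_len(nu), drop = FALSE]
    g <- upsample2_bwd(gu)
  }
  unet_encoder_bwd(params, cfg, fw$enc$cache, g, g_skips, grads)
}

# Dice + cross-entropy loss on 2-class voxel logits; returns loss and
# gradient w.r.t. logits.
seg_loss <- function(logits, ymask, eps = 1) {
  d <- dim(logits)
  z0 <- logits[, , , 1]; z1 <- logits[, , , 2]
  zm <- pmax(z0, z1)
  p1 <- exp(z1 - zm) / (exp(z0 - zm) + exp(z1 - zm))
  y <- if (length(dim(ymask)) == 4L) ymask[, , , 1] else ymask
  n <- length(y)
  ce <- -mean(y * log(pmax(p1, 1e-12)) + (1 - y) * log(pmax(1 - p1, 1e-12)))
  sp <- sum(p1); sy <- sum(y); spy <- sum(p1 * y)
  dice <- 1 - (2 * spy + eps) / (sp + sy + eps)
  # d(loss)/dz1: CE part collapses to (p1 - y)/n; Dice part goes through
  # the softmax derivative p1 (1 - p1)
  gdice <- -(2 * y * (sp + sy + eps) - (2 * spy + eps)) / (sp + sy + eps)^2
  gz1 <- (p1 - y) / n + gdice * p1 * (1 - p1)
  g <- array(0, d)
  g[, , , 1] <- -gz1
  g[, , , 2] <- gz1
  list(loss = ce + dice, dice = dice, grad = g)
}

#' Segmentation training configuration
#' @param epochs,lr,batch,seed optimiser settings (Adam).
#' @export
seg_train_config <- function(epochs = 8, lr = 1e-3, batch = 2, seed = 1L) {
  list(epochs = epochs, lr = lr, batch = batch, seed = as.integer(seed))
}

#' Train the segmentation U-Net on phantoms
#'
#' Minimises Dice + cross-entropy over voxelwise two-class softmax outputs
#' with Adam. Deterministic under \code{train_cfg$seed}.
#'
#' @param volumes list of framed volumes (\code{image_volume} or 3D arrays),
#'   at least 10.
#' @param masks list of matching binary tumor masks.
#' @param config a \code{\link{unet_config}}.
#' @param train_cfg a \code{\link{seg_train_config}}.
#' @return A trained \code{unet3d} with per-epoch \code{$loss_log}.
#' @export
train_segmentation <- function(volumes, masks, config,
                               train_cfg = seg_train_config()) {
  if (length(volumes) < 10)
    stop("need at least 10 training phantoms")
  if (length(volumes) != length(masks))
    stop("volumes and masks must align")
  ys <- lapply(masks, as_input4d)
  if (all(vapply(ys, sum, numeric(1)) == 0))
    stop("all training masks are empty")
  xs <- lapply(volumes, as_input4d)
  model <- build_unet(config)
  params <- model$params
  state <- adam_init(params)
  losses <- numeric(train_cfg$epochs)
  t_step <- 0L
  with_seed(train_cfg$seed, {
    for (ep in seq_len(train_cfg$epochs)) {
      ord <- sample.int(length(xs))
      ep_loss <- 0
      bs <- max(1L, min(train_cfg$batch, length(xs)))
      starts <- seq(1, length(ord), by = bs)
      for (s in starts) {
        ids <- ord[s:min(s + bs - 1, length(ord))]
        gacc <- NULL
        bl <- 0
        for (i in ids) {
          fw <- unet_fwd(params, config, xs[[i]], keep_cache = TRUE)
          sl <- seg_loss(fw$logits, ys[[i]])
          gr <- unet_bwd(params, config, fw, sl$grad / length(ids))
          gacc <- if (is.null(gacc)) gr
                  else mapply(`+`, gacc, gr, SIMPLIFY = FALSE)
          bl <- bl + sl$loss / length(ids)
        }
        t_step <- t_step + 1L
        upd <- adam_step(params, gacc, state, train_cfg$lr, t_step)
        params <- upd$params; state <- upd$state
        ep_loss <- ep_loss + bl * length(ids) / length(ord)
      }
      losses[ep] <- ep_loss
    }
  })
  model$params <- params
  model$loss_log <- losses
  model
}

#' Segment a framed volume
#'
#' @param model a trained \code{unet3d}.
#' @param vol framed \code{image_volume} or 3D array matching the configured
#'   input size.
#' @return A \code{tumor_mask} (voxelwise argmax of the class scores).
#' @export
segment <- function(model, vol) {
  x <- as_input4d(vol)
  if (!identical(dim(x)[1:3], as.integer(model$config$input_size)))
    stop(sprintf("input shape %s does not match the configured frame %s",
                 paste(dim(x)[1:3], collapse = "x"),
                 paste(model$config$input_size, collapse = "x")))
  fw <- unet_fwd(model$params, model$config, x)
  mk <- as.numeric(fw$logits[, , , 2] > fw$logits[, , , 1])
  sp <- if (inherits(vol, "image_volume")) vol$spacing else c(1, 1, 1)
  tumor_mask(array(mk, dim(x)[1:3]), sp)
}

check_input_shape <- function(cfg, x) {
  d <- dim(x)[1:3]
  if (any(d %% 2^(cfg$n_levels - 1) != 0))
    stop(sprintf("input shape %s is not divisible by the %d-level pooling",
                 paste(d, collapse = "x"), cfg$n_levels))
  if (any(d %/% 2^(cfg$n_levels - 1) < cfg$pooled_grid))
    stop("input too small: bottleneck smaller than pooled_grid")
  invisible(TRUE)
}

#' Extract deep image features from the frozen encoder
#'
#' Runs the encoder only, adaptive-average-pools the deepest activation to
#' the configured grid and flattens it. A pure function of
#' \code{(model, vol)}.
#'
#' @param model a \code{unet3d} (trained or not).
#' @param vol framed volume.
#' @param subject_id optional id attached to the result.
#' @return Numeric vector of length \code{model$config$feature_dim}.
#' @export
extract_features <- function(model, vol, subject_id = NULL) {
  x <- as_input4d(vol)
  check_input_shape(model$config, x)
  cfg <- model$config
  L <- cfg$n_levels
  params <- model$params
  for (l in seq_len(L)) {
    x <- pmax(conv_fwd(x, params[[sprintf("e%dc1.W", l)]],
                       params[[sprintf("e%dc1.b", l)]]), 0)
    x <- pmax(conv_fwd(x, params[[sprintf("e%dc2.W", l)]],
                       params[[sprintf("e%dc2.b", l)]]), 0)
    if (any(!is.finite(x)))
      stop(sprintf("non-finite activations at encoder level %d", l))
    if (l < L) x <- pool_fwd(x)$out
  }
  feats <- as.numeric(adaptive_pool(x, cfg$pooled_grid))
  stopifnot(length(feats) == cfg$feature_dim)
  if (!is.null(subject_id)) attr(feats, "subject_id") <- subject_id
  feats
}

#' Feature matrix for a list of volumes
#'
#' @param model a \code{unet3d}.
#' @param volumes list of framed volumes.
#' @param ids optional subject ids (rownames).
#' @return matrix n x feature_dim.
#' @export
extract_feature_matrix <- function(model, volumes, ids = NULL) {
  out <- t(vapply(volumes, function(v) extract_features(model, v),
                  numeric(model$config$feature_dim)))
  if (!is.null(ids)) rownames(out) <- ids
  out
}

#' Hash of a parameter list (encoder-freezing checks)
#' @param params named list of numeric arrays (e.g. \code{model$params}).
#' @return A single numeric digest; equal inputs give equal digests.
#' @export
param_hash <- function(params) {
  v <- unlist(params, use.names = FALSE)
  c(sum(v), sum(v^2), sum(v * seq_along(v) %% 97))
}

# --- Adam -------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))
}

adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
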