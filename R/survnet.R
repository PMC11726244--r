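#' Discrete time grid for survival modelling
#'
#' Builds the time grid over which the logistic-hazard model estimates
#' per-bin conditional event probabilities. Bins are half-open, right-closed
#' intervals \code{(edge[j], edge[j+1]]}.
#'
#' @param times observed times (months), max > 0.
#' @param n_bins number of bins (>= 1).
#' @param scheme \code{"equidistant"} (uniform over [0, max(times)]) or
#'   \code{"quantile"} (edges at event-time quantiles, deduplicated).
#' @param events 0/1 event indicators; required for the quantile scheme.
#' @return An object of class \code{time_grid} with \code{$edges}
#'   (\code{edges[1] = 0}) and \code{$n_bins}.
#' @export
make_time_grid <- function(times, n_bins = 20,
                           scheme = c("equidistant", "quantile"),
                           events = NULL) {
  scheme <- match.arg(scheme)
  if (n_bins < 1) stop("n_bins must be >= 1")
  if (max(times) <= 0) stop("max(times) must be positive")
  if (scheme == "equidistant") {
    edges <- seq(0, max(times), length.out = n_bins + 1)
  } else {
    et <- if (is.null(events)) times else times[events == 1]
    if (length(unique(et)) < n_bins)
      stop("n_bins exceeds the number of distinct event times")
    qs <- stats::quantile(et, probs = seq_len(n_bins) / n_bins, type = 1)
    edges <- unique(c(0, qs))
    edges[length(edges)] <- max(edges[length(edges)], max(times))
  }
  structure(list(edges = as.numeric(edges),
                 n_bins = length(edges) - 1L),
            class = "time_grid")
}

#' @export
print.time_grid <- function(x, ...) {
  cat(sprintf("<time_grid> %d bins over [0, %.4g] months\n",
              x$n_bins, max(x$edges)))
  invisible(x)
}

#' Assign observed times to discrete bins
#'
#' Right-closed convention: a time exactly on an interior edge belongs to
#' the earlier bin. Times beyond the last edge clamp to the last bin.
#'
#' @param times positive observed times.
#' @param events 0/1 event indicators.
#' @param grid a \code{\link{time_grid}}.
#' @return data.frame with \code{bin} (1-based, in 1..n_bins) and
#'   \code{event}.
#' @export
discretize <- function(times, events, grid) {
  if (any(times <= 0)) stop("times must be positive")
  k <- findInterval(times, grid$edges, left.open = TRUE)
  k <- pmin(pmax(k, 1L), grid$n_bins)
  data.frame(bin = as.integer(k), event = as.integer(events))
}

#' Logistic-hazard negative log-likelihood
#'
#' For a subject with event indicator d in bin k and per-bin hazards h:
#' \deqn{-\left[\sum_{j<k} \log(1-h_j) + d \log h_k + (1-d)\log(1-h_k)\right]}
#' averaged over subjects.
#'
#' @param h matrix n x n_bins (or vector for one subject) of hazards in the
#'   open interval (0, 1).
#' @param bin 1-based bin index per subject.
#' @param event 0/1 per subject.
#' @return Mean negative log-likelihood (scalar).
#' @export
logistic_hazard_loss <- function(h, bin, event) {
  if (is.vector(h)) h <- matrix(h, nrow = 1)
  if (any(h <= 0) || any(h >= 1))
    stop("hazards must lie strictly inside (0, 1); clamp logits upstream")
  n <- nrow(h)
  stopifnot(length(bin) == n, length(event) == n)
  ll <- vapply(seq_len(n), function(i) {
    k <- bin[i]
    s <- if (k > 1) sum(log(1 - h[i, seq_len(k - 1)])) else 0
    s + event[i] * log(h[i, k]) + (1 - event[i]) * log(1 - h[i, k])
  }, numeric(1))
  -mean(ll)
}

#' Build a logistic-hazard survival network
#'
#' A 3-layer fully connected network emitting one logit per time bin. In
#' \code{"clinical"} mode the clinical vector (age_z + one-hot resection,
#' 4 values) is the sole input; in \code{"image"} mode the deep image
#' features are; in \code{"multimodal"} mode image features feed the stack
#' and the clinical vector is concatenated onto the activations entering the
#' final layer.
#'
#' @param mode one of \code{"clinical"}, \code{"image"},
#'   \code{"multimodal"}.
#' @param image_dim image-feature dimension (image / multimodal modes).
#' @param clinical_dim clinical-vector dimension (default 4).
#' @param n_bins number of output logits.
#' @param hidden hidden width.
#' @param dropout dropout rate during training.
#' @param seed initialisation seed.
#' @return An object of class \code{hazard_net}.
#' @export
build_survival_net <- function(mode = c("clinical", "image", "multimodal"),
                               image_dim = NULL, clinical_dim = 4L,
                               n_bins = 20L, hidden = 128L, dropout = 0.2,
                               seed = 1L) {
  mode <- match.arg(mode)
  if (mode %in% c("image", "multimodal") &&
      (is.null(image_dim) || image_dim < 1))
    stop(sprintf("mode '%s' requires image features (image_dim)", mode))
  if (mode %in% c("clinical", "multimodal") &&
      (is.null(clinical_dim) || clinical_dim < 1))
    stop(sprintf("mode '%s' requires a clinical input (clinical_dim)", mode))
  din <- switch(mode, clinical = clinical_dim, image = image_dim,
                multimodal = image_dim)
  dlast <- hidden + if (mode == "multimodal") clinical_dim else 0L
  params <- with_seed(as.integer(seed), {
    list(W1 = matrix(stats::rnorm(din * hidden, 0, sqrt(2 / din)),
                     din, hidden),
         b1 = numeric(hidden),
         W2 = matrix(stats::rnorm(hidden * hidden, 0, sqrt(2 / hidden)),
                     hidden, hidden),
         b2 = numeric(hidden),
         W3 = matrix(stats::rnorm(dlast * n_bins, 0, sqrt(1 / dlast)),
                     dlast, n_bins),
         b3 = numeric(n_bins))
  })
  structure(list(mode = mode, image_dim = image_dim,
                 clinical_dim = clinical_dim, n_bins = as.integer(n_bins),
                 hidden = as.integer(hidden), dropout = dropout,
                 seed = as.integer(seed), params = params,
                 norm = NULL, grid = NULL, loss_log = NULL,
                 val_loss = NULL, trained = FALSE),
            class = "hazard_net")
}

# Forward pass -> list(logits, caches). X/C are n x d matrices (already
# normalised); drop masks are NULL at prediction time.
hnet_fwd <- function(net, X, C, drop1 = NULL, drop2 = NULL) {
  p <- net$params
  inp <- if (net$mode == "clinical") C else X
  A1 <- pmax(sweep(inp %*% p$W1, 2, p$b1, `+`), 0)
  if (!is.null(drop1)) A1 <- A1 * drop1
  A2 <- pmax(sweep(A1 %*% p$W2, 2, p$b2, `+`), 0)
  if (!is.null(drop2)) A2 <- A2 * drop2
  H <- if (net$mode == "multimodal") cbind(A2, C) else A2
  Z <- sweep(H %*% p$W3, 2, p$b3, `+`)
  Z <- pmin(pmax(Z, -15), 15)  # keep hazards in the open interval
  list(Z = Z, inp = inp, A1 = A1, A2 = A2, H = H)
}

# Loss + gradient w.r.t. logits for discrete targets (stable softplus form).
hnet_loss_grad <- function(Z, bin, event) {
  sp <- function(z) pmax(z, 0) + log1p(exp(-abs(z)))
  n <- nrow(Z); J <- ncol(Z)
  before <- outer(bin, seq_len(J), `>`)        # j < k
  at <- outer(bin, seq_len(J), `==`)
  h <- stats::plogis(Z)
  loss <- sum(sp(Z) * before) +
    sum((event * sp(-Z) + (1 - event) * sp(Z)) * at)
  G <- h * before + (h - event) * at
  list(loss = loss / n, grad = G / n)
}

hnet_bwd <- function(net, fw, G, drop1, drop2) {
  p <- net$params
  gW3 <- t(fw$H) %*% G
  gb3 <- colSums(G)
  gH <- G %*% t(p$W3)
  gA2 <- if (net$mode == "multimodal")
    gH[, seq_len(net$hidden), drop = FALSE] else gH
  gA2 <- gA2 * (fw$A2 > 0)
  if (!is.null(drop2)) gA2 <- gA2 * drop2
  gW2 <- t(fw$A1) %*% gA2
  gb2 <- colSums(gA2)
  gA1 <- (gA2 %*% t(p$W2)) * (fw$A1 > 0)
  if (!is.null(drop1)) gA1 <- gA1 * drop1
  gW1 <- t(fw$inp) %*% gA1
  gb1 <- colSums(gA1)
  list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2, W3 = gW3, b3 = gb3)
}

#' Survival-network training configuration
#' @param epochs,lr,batch,seed Adam settings.
#' @param early_stop keep the best-epoch weights by validation loss (needs
#'   \code{val_ids} in \code{\link{train_survival}}).
#' @export
surv_train_config <- function(epochs = 150, lr = 5e-3, batch = 64,
                              seed = 1L, early_stop = FALSE) {
  list(epochs = epochs, lr = lr, batch = batch, seed = as.integer(seed),
       early_stop = early_stop)
}

# z-score columns with training statistics; constant columns pass through.
fit_normalizer <- function(M) {
  if (is.null(M)) return(NULL)
  mu <- colMeans(M)
  sd_ <- apply(M, 2, stats::sd)
  sd_[!is.finite(sd_) | sd_ == 0] <- 1
  list(mu = mu, sd = sd_)
}

apply_normalizer <- function(M, nz) {
  if (is.null(M)) return(NULL)
  sweep(sweep(M, 2, nz$mu, `-`), 2, nz$sd, `/`)
}

#' Train a logistic-hazard survival network
#'
#' Minimises the mean logistic-hazard negative log-likelihood with Adam.
#' Input columns (image features and the clinical age column) are z-scored
#' with statistics computed on the training rows only; the statistics are
#' stored in the model and re-applied at prediction time. Deterministic
#' under \code{cfg$seed}. Encoder weights are never touched: the network
#' consumes precomputed feature vectors.
#'
#' @param net a \code{\link{build_survival_net}} model.
#' @param targets data.frame from \code{\link{discretize}} (bin, event).
#' @param x_image n x image_dim matrix (image / multimodal modes).
#' @param x_clinical n x clinical_dim matrix (clinical / multimodal modes).
#' @param grid the \code{\link{time_grid}} the targets were built on
#'   (stored for prediction).
#' @param cfg a \code{\link{surv_train_config}}.
#' @param val_ids optional row indices held out for validation-loss
#'   tracking/early stopping (excluded from gradient updates and from the
#'   normalisation statistics).
#' @param keep_norm reuse the normalisation statistics already stored in
#'   \code{net} (for fine-tuning a fitted model on new data).
#' @return The fitted \code{hazard_net} with \code{$loss_log} (and
#'   \code{$val_loss} if \code{val_ids} given).
#' @export
train_survival <- function(net, targets, x_image = NULL, x_clinical = NULL,
                           grid = NULL, cfg = surv_train_config(),
                           val_ids = NULL, keep_norm = FALSE) {
  stopifnot(inherits(net, "hazard_net"))
  n <- nrow(targets)
  if (sum(targets$event) == 0)
    warning("no events in training data; the fitted hazards will be ",
            "near zero")
  tr <- setdiff(seq_len(n), val_ids)
  norm <- if (keep_norm && !is.null(net$norm)) net$norm else list(
    image = if (!is.null(x_image))
      fit_normalizer(x_image[tr, , drop = FALSE]),
    clinical = if (!is.null(x_clinical))
      fit_normalizer(x_clinical[tr, , drop = FALSE]))
  X <- if (!is.null(x_image)) apply_normalizer(x_image, norm$image)
  C <- if (!is.null(x_clinical)) apply_normalizer(x_clinical, norm$clinical)

  params <- net$params
  state <- adam_init(params)
  losses <- numeric(cfg$epochs)
  vlosses <- if (length(val_ids)) numeric(cfg$epochs) else NULL
  best <- list(loss = Inf, params = params)
  t_step <- 0L
  with_seed(cfg$seed, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample(tr)
      starts <- seq(1, length(ord), by = cfg$batch)
      ep_loss <- 0
      for (s in starts) {
        ids <- ord[s:min(s + cfg$batch - 1, length(ord))]
        Xb <- if (!is.null(X)) X[ids, , drop = FALSE]
        Cb <- if (!is.null(C)) C[ids, , drop = FALSE]
        m <- length(ids)
        d1 <- if (net$dropout > 0)
          matrix(stats::rbinom(m * net$hidden, 1, 1 - net$dropout) /
                   (1 - net$dropout), m, net$hidden)
        d2 <- if (net$dropout > 0)
          matrix(stats::rbinom(m * net$hidden, 1, 1 - net$dropout) /
                   (1 - net$dropout), m, net$hidden)
        net$params <- params
        fw <- hnet_fwd(net, Xb, Cb, d1, d2)
        lg <- hnet_loss_grad(fw$Z, targets$bin[ids], targets$event[ids])
        gr <- hnet_bwd(net, fw, lg$grad, d1, d2)
        t_step <- t_step + 1L
        upd <- adam_step(params, gr, state, cfg$lr, t_step)
        params <- upd$params; state <- upd$state
        ep_loss <- ep_loss + lg$loss * m / length(ord)
      }
      losses[ep] <- ep_loss
      if (length(val_ids)) {
        net$params <- params
        fwv <- hnet_fwd(net, if (!is.null(X)) X[val_ids, , drop = FALSE],
                        if (!is.null(C)) C[val_ids, , drop = FALSE])
        vl <- hnet_loss_grad(fwv$Z, targets$bin[val_ids],
                             targets$event[val_ids])$loss
        vlosses[ep] <- vl
        if (cfg$early_stop && vl < best$loss)
          best <- list(loss = vl, params = params)
      }
    }
  })
  net$params <- if (cfg$early_stop && length(val_ids) && best$loss < Inf)
    best$params else params
  net$norm <- norm
  net$grid <- grid %||% net$grid
  net$loss_log <- losses
  net$val_loss <- vlosses
  net$trained <- TRUE
  net
}

#' Predict personalised survival curves
#'
#' Hazards are the sigmoids of the network logits; survival at grid edge j
#' is the running product of (1 - h) over the first j bins, step-constant
#' between edges. Every returned curve satisfies S(0) = 1 and is
#' nonincreasing within [0, 1].
#'
#' @param net a fitted \code{hazard_net}.
#' @param x_image,x_clinical input matrices (unnormalised; training
#'   statistics are applied internally).
#' @param grid optional \code{time_grid} (defaults to the training grid).
#' @return An object of class \code{survival_curves}: matrix n x
#'   (n_bins + 1) of survival probabilities at the grid edges, with the
#'   grid attached as attribute.
#' @export
predict_survival <- function(net, x_image = NULL, x_clinical = NULL,
                             grid = NULL) {
  stopifnot(inherits(net, "hazard_net"))
  grid <- grid %||% net$grid
  if (is.null(grid)) stop("no time grid: pass 'grid' or train the model")
  X <- if (!is.null(x_image) && !is.null(net$norm))
    apply_normalizer(x_image, net$norm$image) else x_image
  C <- if (!is.null(x_clinical) && !is.null(net$norm))
    apply_normalizer(x_clinical, net$norm$clinical) else x_clinical
  fw <- hnet_fwd(net, X, C)
  h <- stats::plogis(fw$Z)
  S <- cbind(1, t(apply(1 - h, 1, cumprod)))
  if (ncol(h) == 1) S <- cbind(1, 1 - h)
  colnames(S) <- NULL
  stopifnot(all(S >= 0 & S <= 1), all(S[, 1] == 1),
            all(diff(t(S)) <= 1e-12))
  structure(S, class = c("survival_curves", "matrix"), grid = grid)
}

#' @export
`[.survival_curves` <- function(x, i, j, ..., drop = TRUE) {
  X <- unclass(x)
  if (missing(j)) {
    # row subset keeps the class and the time grid
    structure(X[i, , drop = FALSE], class = class(x),
              grid = attr(x, "grid"))
  } else if (missing(i)) {
    X[, j, drop = drop]
  } else {
    X[i, j, drop = drop]
  }
}

#' Evaluate survival curves at a time point (step interpolation)
#' @param curves a \code{survival_curves} object.
#' @param t time in months (within the grid).
#' @return numeric vector S(t) per subject.
#' @export
surv_at <- function(curves, t) {
  grid <- attr(curves, "grid")
  if (t > max(grid$edges) + 1e-9)
    stop(sprintf("time %.3g beyond the last grid edge %.3g", t,
                 max(grid$edges)))
  j <- findInterval(t, grid$edges)
  unname(curves[, j])
}

#' 3-year (or other horizon) risk score
#'
#' The scalar risk is 1 - S(horizon), with S step-interpolated on the grid.
#'
#' @param curves a \code{survival_curves} object.
#' @param horizon_months horizon (default 36, within the grid).
#' @return numeric vector of risks in [0, 1].
#' @export
risk_score <- function(curves, horizon_months = 36) {
  1 - surv_at(curves, horizon_months)
}

#' Univariable covariate screening
#'
#' Runs a univariable Cox regression per candidate covariate and retains
#' those with Wald p below the threshold (0.15, the conventional a-priori
#' screening level).
#'
#' @param data data.frame of candidate covariates (numeric or
#'   factor-codable columns).
#' @param times,events outcome.
#' @param candidates column names to screen (default all).
#' @param p_threshold retention threshold.
#' @return data.frame (covariate, beta, hr, p, selected); constant
#'   covariates are excluded with a warning.
#' @export
select_covariates <- function(data, times, events,
                              candidates = colnames(data),
                              p_threshold = 0.15) {
  if (length(candidates) < 2)
    stop("need at least 2 candidate covariates to screen")
  rows <- lapply(candidates, function(nm) {
    x <- data[[nm]]
    if (!is.numeric(x)) x <- as.numeric(as.factor(x))
    if (length(unique(x)) < 2) {
      warning(sprintf("covariate '%s' is constant; excluded", nm))
      return(data.frame(covariate = nm, beta = NA_real_, hr = NA_real_,
                        p = NA_real_, selected = FALSE))
    }
    fit <- cox_univariable(x, times, events)
    data.frame(covariate = nm, beta = fit$beta, hr = fit$hr,
               p = fit$p_wald, selected = is.finite(fit$p_wald) &&
                 fit$p_wald < p_threshold)
  })
  do.call(rbind, rows)
}

#' Encode the clinical feature vector
#'
#' Age (raw years; z-scored inside the network with training statistics)
#' plus one-hot extent of resection (GTR, STR, biopsy). Subjects with
#' missing resection are dropped by default or assigned the modal level.
#'
#' @param clinical data.frame with \code{age_years} and \code{resection}.
#' @param na_action \code{"drop"} or \code{"impute"} (modal level).
#' @return list(x: matrix n x 4, keep: logical row filter applied).
#' @export
clinical_matrix <- function(clinical, na_action = c("drop", "impute")) {
  na_action <- match.arg(na_action)
  res <- as.character(clinical$resection)
  known <- res %in% c("GTR", "STR", "biopsy")
  keep <- rep(TRUE, nrow(clinical))
  if (any(!known)) {
    if (na_action == "drop") keep <- known
    else res[!known] <- names(which.max(table(res[known])))
  }
  res <- res[keep]
  x <- cbind(age = clinical$age_years[keep],
             GTR = as.numeric(res == "GTR"),
             STR = as.numeric(res == "STR"),
             biopsy = as.numeric(res == "biopsy"))
  list(x = x, keep = keep)
}

# --- S3 methods -------------------------------------------------------------

#' @export
print.hazard_net <- function(x, ...) {
  cat(sprintf("<hazard_net> mode=%s, %d bins, hidden %d%s\n", x$mode,
              x$n_bins, x$hidden,
              if (x$trained) ", trained" else " (untrained)"))
  if (!is.null(x$loss_log))
    cat(sprintf("  final training loss %.4f over %d epochs\n",
                x$loss_log[length(x$loss_log)], length(x$loss_log)))
  invisible(x)
}

#' @export
summary.hazard_net <- function(object, ...) {
  print(object)
  dims <- switch(object$mode,
    clinical = sprintf("clinical(%d) -> %d -> %d -> %d",
                       object$clinical_dim, object$hidden, object$hidden,
                       object$n_bins),
    image = sprintf("image(%d) -> %d -> %d -> %d", object$image_dim,
                    object$hidden, object$hidden, object$n_bins),
    multimodal = sprintf("image(%d) -> %d -> [%d + clinical(%d)] -> %d",
                         object$image_dim, object$hidden, object$hidden,
                         object$clinical_dim, object$n_bins))
  cat("  architecture:", dims, "\n")
  if (!is.null(object$val_loss))
    cat(sprintf("  best validation loss %.4f\n", min(object$val_loss)))
  invisible(object)
}

#' @export
predict.hazard_net <- function(object, x_image = NULL, x_clinical = NULL,
                               type = c("survival", "risk", "hazard"),
                               horizon_months = 36, ...) {
  type <- match.arg(type)
  curves <- predict_survival(object, x_image, x_clinical)
  switch(type,
         survival = curves,
         risk = risk_score(curves, horizon_months),
         hazard = {
           S <- unclass(curves)
           1 - S[, -1, drop = FALSE] / S[, -ncol(S), drop = FALSE]
         })
}

#' @export
plot.hazard_net <- function(x, ...) {
  if (is.null(x$loss_log)) stop("model not trained; nothing to plot")
  graphics::plot(x$loss_log, type = "l", xlab = "epoch",
                 ylab = "training loss", main = "logistic-hazard loss", ...)
  if (!is.null(x$val_loss))
    graphics::lines(x$val_loss, lty = 2)
  invisible(x)
}

#' @export
simulate.hazard_net <- function(object, nsim = 1, seed = NULL,
                                x_image = NULL, x_clinical = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  curves <- predict_survival(object, x_image, x_clinical)
  S <- unclass(curves)
  h <- 1 - S[, -1, drop = FALSE] / S[, -ncol(S), drop = FALSE]
  edges <- attr(curves, "grid")$edges
  w <- diff(edges)
  out <- replicate(nsim, {
    apply(h, 1, function(hi) {
      hit <- which(stats::runif(length(hi)) < hi)
      if (length(hit)) edges[hit[1]] + stats::runif(1) * w[hit[1]]
      else NA_real_  # survived the grid (administratively censored)
    })
  })
  drop(out)
}

#' @export
plot.survival_curves <- function(x, max_curves = 30, ...) {
  edges <- attr(x, "grid")$edges
  n <- min(nrow(x), max_curves)
  graphics::matplot(edges, t(unclass(x)[seq_len(n), , drop = FALSE]),
                    type = "s", lty = 1, col = grDevices::grey(0.4, 0.5),
                    xlab = "months", ylab = "S(t)", ylim = c(0, 1), ...)
  invisible(x)
}
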