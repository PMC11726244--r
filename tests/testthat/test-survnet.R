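test_that("time grids: equidistant edges, single bin, quantile balance", {
  g <- make_time_grid(c(10, 50, 100), 4)
  expect_equal(g$edges, c(0, 25, 50, 75, 100))
  g1 <- make_time_grid(c(3, 9), 1)
  expect_equal(g1$edges, c(0, 9))

  set.seed(1)
  times <- stats::rexp(500, 1 / 20)^1.3  # skewed
  events <- stats::rbinom(500, 1, 0.7)
  gq <- make_time_grid(times, 5, scheme = "quantile", events = events)
  tg <- discretize(times[events == 1], events[events == 1], gq)
  counts <- table(factor(tg$bin, levels = seq_len(gq$n_bins)))
  expect_lte(max(counts) - min(counts), max(1, sum(events) * 0.02 + 1))

  expect_error(make_time_grid(c(1, 2, 3), 10, scheme = "quantile",
                              events = c(1, 1, 0)), "distinct event times")
})

test_that("discretisation follows the right-closed convention and matches a linear scan", {
  g <- make_time_grid(c(100), 4)  # edges 0,25,50,75,100
  expect_equal(discretize(25, 1, g)$bin, 1L)  # interior edge -> earlier bin
  expect_equal(discretize(0.1, 1, g)$bin, 1L)
  expect_equal(discretize(1000, 0, g)$bin, 4L)  # clamp
  expect_error(discretize(0, 1, g), "positive")

  set.seed(2)
  for (r in 1:20) {
    edges <- sort(stats::runif(5, 1, 100))
    grid <- structure(list(edges = c(0, edges), n_bins = 5L),
                      class = "time_grid")
    t_ <- stats::runif(50, 0.01, 120)
    got <- discretize(t_, rep(1, 50), grid)$bin
    want <- vapply(t_, function(ti) {
      for (j in seq_len(5)) {
        if (ti > grid$edges[j] && ti <= grid$edges[j + 1]) return(j)
      }
      5L
    }, integer(1))
    expect_identical(got, as.integer(want))
  }
})

test_that("logistic-hazard loss matches closed forms and finite differences", {
  expect_equal(logistic_hazard_loss(matrix(0.5, 1, 1), 1, 1), -log(0.5),
               tolerance = 1e-12)
  expect_equal(logistic_hazard_loss(matrix(c(0.2, 0.3), 1), 2, 0),
               -(log(0.8) + log(0.7)), tolerance = 1e-12)
  expect_error(logistic_hazard_loss(matrix(c(0, 0.5), 1), 2, 1),
               "strictly inside")

  set.seed(3)
  for (r in 1:5) {
    n <- 6; J <- 5
    Z <- matrix(stats::rnorm(n * J), n, J)
    bin <- sample(J, n, replace = TRUE)
    d <- stats::rbinom(n, 1, 0.5)
    lg <- gliohazard:::hnet_loss_grad(Z, bin, d)
    eps <- 1e-5
    for (t in 1:4) {
      i <- sample(n, 1); j <- sample(J, 1)
      Zp <- Z; Zp[i, j] <- Zp[i, j] + eps
      Zm <- Z; Zm[i, j] <- Zm[i, j] - eps
      fd <- (gliohazard:::hnet_loss_grad(Zp, bin, d)$loss -
               gliohazard:::hnet_loss_grad(Zm, bin, d)$loss) / (2 * eps)
      expect_lt(abs(fd - lg$grad[i, j]), 1e-4)
    }
  }
})

test_that("network construction: dimensions per mode, seeded init, input requirements", {
  net <- build_survival_net("clinical", n_bins = 7, hidden = 16, seed = 1)
  expect_identical(dim(net$params$W1), c(4L, 16L))
  expect_identical(dim(net$params$W3), c(16L, 7L))
  mm <- build_survival_net("multimodal", image_dim = 32, n_bins = 7,
                           hidden = 16, seed = 1)
  expect_identical(dim(mm$params$W3), c(20L, 7L))  # hidden + 4 clinical
  expect_identical(build_survival_net("image", image_dim = 10)$params,
                   build_survival_net("image", image_dim = 10)$params)
  expect_error(build_survival_net("multimodal", image_dim = NULL),
               "image features")
})

test_that("training recovers the simulated clinical risk ordering", {
  cfg <- clinical_sim_cfg(seed = 21)
  co <- generate_cohort(600, cfg, image = FALSE)$clinical
  cm <- clinical_matrix(co, "drop")
  cl <- co[cm$keep, ]
  tr <- 1:400; te <- 401:nrow(cl)
  grid <- make_time_grid(cl$time_months[tr], 20)
  tg <- discretize(cl$time_months, cl$event, grid)
  net <- build_survival_net("clinical", n_bins = 20, hidden = 32,
                            dropout = 0.1, seed = 21)
  fit <- train_survival(net, tg[tr, ], x_clinical = cm$x[tr, ],
                        grid = grid,
                        cfg = surv_train_config(epochs = 120, seed = 21))
  risk <- predict(fit, x_clinical = cm$x[te, ], type = "risk")
  tau <- stats::cor(risk, cl$true_linear_predictor[te],
                    method = "kendall")
  expect_gt(tau, 0.5)
})

test_that("zero learning rate gives a flat loss log; no events warns", {
  x <- matrix(stats::rnorm(80), 20, 4)
  g <- make_time_grid(c(50), 5)
  tg <- data.frame(bin = sample(5, 20, replace = TRUE),
                   event = stats::rbinom(20, 1, 0.5))
  net <- build_survival_net("clinical", n_bins = 5, hidden = 8,
                            dropout = 0, seed = 2)
  fit <- train_survival(net, tg, x_clinical = x, grid = g,
                        cfg = surv_train_config(epochs = 5, lr = 0))
  expect_lt(diff(range(fit$loss_log)), 1e-10)
  expect_equal(fit$params, net$params, tolerance = 1e-12)

  tg0 <- tg; tg0$event <- 0L
  expect_warning(
    train_survival(net, tg0, x_clinical = x, grid = g,
                   cfg = surv_train_config(epochs = 3)),
    "no events")
})

test_that("training loss decreases over epochs for a learnable signal", {
  cfg <- clinical_sim_cfg(seed = 5)
  cl <- generate_cohort(200, cfg, image = FALSE)$clinical
  cm <- clinical_matrix(cl, "drop")
  cl <- cl[cm$keep, ]
  grid <- make_time_grid(cl$time_months, 10)
  tg <- discretize(cl$time_months, cl$event, grid)
  net <- build_survival_net("clinical", n_bins = 10, hidden = 16,
                            dropout = 0, seed = 3)
  fit <- train_survival(net, tg, x_clinical = cm$x, grid = grid,
                        cfg = surv_train_config(epochs = 60, seed = 3))
  # allow a few non-monotone epochs (stochastic mini-batches)
  worse <- mean(diff(fit$loss_log) > 0)
  expect_lt(worse, 0.3)
  expect_lt(fit$loss_log[60], fit$loss_log[1])
})

test_that("survival curves obey their closed forms and monotonicity", {
  g <- make_time_grid(c(20), 2)
  net <- build_survival_net("clinical", n_bins = 2, hidden = 4, seed = 1)
  # force logits: h = 0.5 in both bins
  net$params$W3[] <- 0; net$params$b3[] <- 0
  net$norm <- list(image = NULL, clinical = NULL)
  net$grid <- g; net$trained <- TRUE
  net$norm$clinical <- gliohazard:::fit_normalizer(matrix(0, 2, 4))
  S <- predict_survival(net, x_clinical = matrix(0, 1, 4))
  expect_equal(as.numeric(unclass(S)), c(1, 0.5, 0.25), tolerance = 1e-12)

  net$params$b3[] <- -15  # hazards ~ 0
  S1 <- predict_survival(net, x_clinical = matrix(0, 1, 4))
  expect_gt(min(S1), 0.999)

  for (r in 1:50) {
    cv <- mk_random_curves(20, J = 10)
    expect_true(all(diff(t(unclass(cv))) <= 1e-12))
  }
})

test_that("risk scores step-interpolate the curve and respect the grid bounds", {
  cv <- mk_random_curves(10, J = 8, tmax = 96)
  edges <- attr(cv, "grid")$edges
  expect_equal(risk_score(cv, 36), 1 - cv[, findInterval(36, edges)],
               ignore_attr = TRUE)
  S <- unclass(cv)
  expect_equal(surv_at(cv, edges[4]), unname(S[, 4]))
  mid <- (edges[4] + edges[5]) / 2
  expect_equal(surv_at(cv, mid), unname(S[, 4]))  # step-constant
  expect_error(risk_score(cv, 1000), "beyond")
  one <- structure(matrix(1, 2, 9), class = c("survival_curves", "matrix"),
                   grid = attr(cv, "grid"))
  expect_equal(risk_score(one, 36), c(0, 0))
})

test_that("covariate screening keeps true signals and drops noise", {
  retained <- matrix(NA, 5, 3)
  for (s in 1:5) {
    cfg <- clinical_sim_cfg(seed = 300 + s)
    cl <- generate_cohort(400, cfg, image = FALSE)$clinical
    cl$gtr <- as.numeric(cl$resection == "GTR")
    cl$sexM <- as.numeric(cl$sex == "M")
    sel <- select_covariates(cl[, c("age_years", "gtr", "sexM")],
                             cl$time_months, cl$event)
    retained[s, ] <- sel$selected
  }
  expect_gte(sum(retained[, 1] & retained[, 2]), 4)  # age + resection
  expect_lte(sum(retained[, 3]), 2)                  # sex is null

  cl <- generate_cohort(100, clinical_sim_cfg(seed = 9),
                        image = FALSE)$clinical
  cl$const <- 1
  cl$age2 <- cl$age_years
  expect_warning(
    sel <- select_covariates(cl[, c("age_years", "const", "age2")],
                             cl$time_months, cl$event),
    "constant")
  expect_false(sel$selected[sel$covariate == "const"])
})

test_that("null covariates are retained at roughly the screening rate", {
  set.seed(17)
  hits <- replicate(300, {
    n <- 80
    x <- stats::rnorm(n)
    tm <- stats::rexp(n, 1 / 30)
    ev <- stats::rbinom(n, 1, 0.7)
    cox_univariable(x, tm, ev)$p_wald < 0.15
  })
  expect_gt(mean(hits), 0.09)
  expect_lt(mean(hits), 0.22)
})

test_that("a strong single covariate is retained decisively", {
  cfg <- clinical_sim_cfg(seed = 77)
  cl <- generate_cohort(400, cfg, image = FALSE)$clinical
  fit <- cox_univariable(cl$true_linear_predictor, cl$time_months,
                         cl$event)
  expect_gt(fit$hr, 1)
  expect_lt(fit$p_wald, 0.001)
})

test_that("hazard_net methods: print, summary, simulate, plot data", {
  g <- make_time_grid(c(60), 6)
  net <- build_survival_net("clinical", n_bins = 6, hidden = 8, seed = 4)
  x <- matrix(stats::rnorm(40), 10, 4)
  tg <- data.frame(bin = sample(6, 10, replace = TRUE),
                   event = rep(c(0, 1), 5))
  fit <- train_survival(net, tg, x_clinical = x, grid = g,
                        cfg = surv_train_config(epochs = 3))
  expect_output(print(fit), "hazard_net")
  expect_output(summary(fit), "architecture")
  sim <- simulate(fit, nsim = 1, seed = 1, x_clinical = x)
  expect_length(sim, 10)
  expect_true(all(is.na(sim) | sim <= max(g$edges)))
  h <- predict(fit, x_clinical = x, type = "hazard")
  expect_true(all(h > 0 & h < 1))
})
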