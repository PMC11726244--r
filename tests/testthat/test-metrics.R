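# Brute-force pair enumeration -- the independent oracle for the
# time-dependent concordance index.
ctd_bruteforce <- function(curves, times, events) {
  S <- unclass(curves)
  edges <- attr(curves, "grid")$edges
  n <- length(times)
  conc <- 0; tot <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || events[i] != 1) next
    if (!(times[j] > times[i] ||
          (times[j] == times[i] && events[j] == 0))) next
    jj <- findInterval(min(times[i], max(edges)), edges)
    si <- S[i, jj]; sj <- S[j, jj]
    conc <- conc + (si < sj) + 0.5 * (si == sj)
    tot <- tot + 1
  }
  if (tot == 0) stop("no comparable pairs")
  conc / tot
}

test_that("Ctd: perfect anti-ordering gives 1, shared curve gives 1/2, errors without events", {
  g <- make_time_grid(c(100), 10)
  n <- 12
  # times at/after the first interior edge so curves differ at T_i
  times <- seq(10, 100, length.out = n)
  events <- rep(1, n)
  h <- seq(0.5, 0.05, length.out = n)  # early events get high hazards
  cv <- constant_hazard_curves(h, 10, 10)
  expect_equal(ctd_index(cv, times, events), 1)

  same <- structure(matrix(rep(seq(1, 0.3, length.out = 11), each = n),
                           n, 11),
                    class = c("survival_curves", "matrix"), grid = g)
  expect_equal(ctd_index(same, times, events), 0.5)
  expect_error(ctd_index(cv, times, rep(0, n)), "event")
})

test_that("Ctd agrees exactly with exhaustive pair enumeration on random instances", {
  set.seed(5)
  for (r in 1:50) {
    n <- sample(5:30, 1)
    cv <- mk_random_curves(n, J = sample(4:12, 1))
    times <- stats::runif(n, 1, 100)
    if (r %% 3 == 0) times <- round(times / 10) * 10  # induce ties
    events <- stats::rbinom(n, 1, 0.6)
    if (sum(events) == 0) next
    expect_identical(ctd_index(cv, times, events),
                     ctd_bruteforce(cv, times, events))
  }
})

test_that("Ctd and td-AUC are invariant to strictly monotone risk transforms", {
  set.seed(6)
  n <- 100
  cv <- mk_random_curves(n, J = 10)
  times <- stats::runif(n, 1, 100)
  events <- stats::rbinom(n, 1, 0.6)
  risk <- risk_score(cv, 50)
  a1 <- td_auc(risk, times, events, 50)
  a2 <- td_auc(stats::qlogis(pmin(pmax(risk, 1e-6), 1 - 1e-6)) * 3 + 1,
               times, events, 50)
  expect_equal(a1, a2, tolerance = 1e-12)
})

test_that("bootstrap CI: degenerate statistic, seed determinism, coverage", {
  const <- bootstrap_ci(function(idx) 0.42, n = 30, n_boot = 50, seed = 1)
  expect_equal(const$ci_low, 0.42)
  expect_equal(const$ci_high, 0.42)

  set.seed(2)
  x <- stats::rnorm(40, 2)
  stat <- function(idx) mean(x[idx])
  a <- bootstrap_ci(stat, 40, n_boot = 200, seed = 7)
  b <- bootstrap_ci(stat, 40, n_boot = 200, seed = 7)
  expect_identical(c(a$ci_low, a$ci_high), c(b$ci_low, b$ci_high))
  expect_true(a$ci_low <= a$point && a$point <= a$ci_high)

  # coverage of a 95% interval for a mean over replications
  set.seed(3)
  cover <- replicate(200, {
    y <- stats::rnorm(40, 1)
    ci <- bootstrap_ci(function(idx) mean(y[idx]), 40, n_boot = 200,
                       seed = sample.int(1e6, 1))
    ci$ci_low <= 1 && 1 <= ci$ci_high
  })
  expect_gt(mean(cover), 0.91)
  expect_lt(mean(cover), 0.99)
})

test_that("td-AUC: perfect separation, rank-sum equivalence without censoring, null behavior", {
  n <- 60
  times <- c(stats::runif(n / 2, 1, 30), stats::runif(n / 2, 40, 100))
  events <- rep(1, n)
  risk <- -times
  expect_equal(td_auc(risk, times, events, 36), 1)

  set.seed(8)
  times <- stats::rexp(300, 1 / 40)
  events <- rep(1, 300)
  risk <- -times + stats::rnorm(300, 0, 15)
  y <- as.numeric(times <= 36)
  r <- rank(risk)
  auc_rank <- (sum(r[y == 1]) - sum(y) * (sum(y) + 1) / 2) /
    (sum(y) * sum(1 - y))
  expect_equal(td_auc(risk, times, events, 36), auc_rank,
               tolerance = 1e-12)

  set.seed(9)
  times <- stats::rexp(500, 1 / 40)
  cens <- stats::runif(500, 20, 200)
  ev <- as.numeric(times <= cens)
  obs <- pmin(times, cens)
  auc0 <- td_auc(stats::rnorm(500), obs, ev, 36)
  expect_gt(auc0, 0.44); expect_lt(auc0, 0.56)

  expect_error(td_auc(1:5, rep(100, 5), rep(1, 5), 36), "events")
})

test_that("Brier score: boundary value, MSE equivalence, loop-oracle IBS", {
  n <- 20
  g <- make_time_grid(c(50), 5)
  ones <- structure(matrix(1, n, 6),
                    class = c("survival_curves", "matrix"), grid = g)
  times <- stats::runif(n, 1, 30)
  expect_equal(brier_score(ones, times, rep(1, n), 36), 1)

  set.seed(10)
  cv <- mk_random_curves(n, J = 5, tmax = 50)
  times <- stats::runif(n, 1, 49)
  ev <- rep(1, n)
  t0 <- 25
  expect_equal(brier_score(cv, times, ev, t0),
               mean((as.numeric(times > t0) - surv_at(cv, t0))^2),
               tolerance = 1e-12)

  # IBS vs a brute-force double loop over trapezoids, no censoring
  eval_t <- attr(cv, "grid")$edges[-1]
  ibs <- integrated_brier(cv, times, ev, eval_times = eval_t)
  bs <- vapply(eval_t, function(tt)
    mean((as.numeric(times > tt) - surv_at(cv, tt))^2), numeric(1))
  acc <- 0
  for (i in seq_len(length(eval_t) - 1))
    acc <- acc + (eval_t[i + 1] - eval_t[i]) * (bs[i] + bs[i + 1]) / 2
  expect_equal(ibs, acc / (max(eval_t) - min(eval_t)), tolerance = 1e-10)
})

test_that("calibration: hand-computed two-bin example and degenerate cases", {
  # 6 subjects, no censoring, predictions clear of bin edges: two bins of 3
  pred <- c(0.95, 0.93, 0.91, 0.15, 0.12, 0.18)
  times <- c(100, 100, 100, 10, 10, 100)
  events <- c(0, 0, 0, 1, 1, 0)
  # high bin: pred mean 0.93, observed 1; low bin: pred 0.15, observed 1/3
  out <- ece_calibration(pred, times, events, n_bins = 10, horizon = 36)
  hand <- (3 * abs(0.93 - 1) + 3 * abs(0.15 - 1 / 3)) / 6
  expect_equal(out$ece, hand, tolerance = 1e-12)

  # perfect prediction of no events
  out2 <- ece_calibration(rep(1, 10), rep(100, 10), rep(0, 10),
                          horizon = 36)
  expect_equal(out2$ece, 0)

  # all predictions identical -> single merged bin
  out3 <- ece_calibration(rep(0.5, 8), c(rep(10, 4), rep(100, 4)),
                          c(rep(1, 4), rep(0, 4)), horizon = 36)
  expect_equal(nrow(out3$table), 1)
  expect_equal(out3$ece, abs(0.5 - 0.5), tolerance = 1e-12)
  expect_error(ece_calibration(c(1.2, 0.5), c(1, 2), c(1, 0)), "0, 1")
})

test_that("KM estimator: empirical survival without censoring, all-censored, textbook instance", {
  times <- c(3, 5, 5, 8, 10)
  km <- km_estimator(times, rep(1, 5))
  expect_equal(km_at(km, c(3, 5, 8, 10)), c(0.8, 0.4, 0.2, 0))

  km2 <- km_estimator(times, rep(0, 5))
  expect_true(all(km2$S == 1))

  # classic 10-subject worked example (+ = censored):
  # 1, 2+, 3, 4, 4+, 5+, 6, 8, 9+, 10
  t10 <- c(1, 2, 3, 4, 4, 5, 6, 8, 9, 10)
  e10 <- c(1, 0, 1, 1, 0, 0, 1, 1, 0, 1)
  km3 <- km_estimator(t10, e10)
  hand <- c(9 / 10, 9 / 10 * 7 / 8, 9 / 10 * 7 / 8 * 6 / 7,
            9 / 10 * 7 / 8 * 6 / 7 * 3 / 4,
            9 / 10 * 7 / 8 * 6 / 7 * 3 / 4 * 2 / 3,
            0)
  expect_equal(km_at(km3, c(1, 3, 4, 6, 8, 10)), hand, tolerance = 1e-12)

  # cross-check against the survival package on random data
  set.seed(11)
  tt <- stats::rexp(60, 1 / 20); ee <- stats::rbinom(60, 1, 0.6)
  sf <- survival::survfit(survival::Surv(tt, ee) ~ 1)
  expect_equal(km_at(km_estimator(tt, ee), sf$time), sf$surv,
               tolerance = 1e-12)
})

test_that("log-rank: identical groups give chi2 = 0, hand-computed sums match, survdiff agrees", {
  t1 <- c(2, 4, 6, 8); e1 <- c(1, 1, 0, 1)
  lr0 <- logrank_test(t1, e1, t1, e1)
  expect_equal(lr0$chi2, 0)
  expect_equal(lr0$p, 1)

  # hand-computed small instance
  ta <- c(1, 3); ea <- c(1, 1)
  tb <- c(2, 4); eb <- c(1, 0)
  # t=1: n=(2,2), d=1 in A: O-E = 1 - 2/4
  # t=2: n=(1,2), d=1 in B: O-E = 0 - 1/3
  # t=3: n=(1,1), d=1 in A: O-E = 1 - 1/2
  ome <- (1 - 0.5) + (0 - 1 / 3) + (1 - 0.5)
  lr <- logrank_test(ta, ea, tb, eb)
  expect_equal(lr$obs_minus_exp, ome, tolerance = 1e-12)

  set.seed(12)
  tt <- stats::rexp(80, 1 / 25); ee <- stats::rbinom(80, 1, 0.7)
  gg <- rep(1:2, each = 40)
  sd_ <- survival::survdiff(survival::Surv(tt, ee) ~ gg)
  lr2 <- logrank_test(tt[gg == 1], ee[gg == 1], tt[gg == 2], ee[gg == 2])
  expect_equal(lr2$chi2, unname(sd_$chisq), tolerance = 1e-10)
  expect_error(logrank_test(c(1, 2), c(0, 0), c(3), c(0)), "events")
})

test_that("median-split stratification: threshold from validation, balanced groups, boundary", {
  set.seed(13)
  val <- stats::runif(300)           # symmetric around 0.5
  test_r <- stats::runif(200)
  times <- stats::rexp(200, 1 / 50 * exp(2 * (test_r - 0.5)))
  events <- stats::rbinom(200, 1, 0.8)
  st <- stratify_median(val, test_r, times, events)
  expect_lt(abs(sum(st$group == "high") - 100), 20)
  expect_true(st$threshold == stats::median(val))

  expect_warning(st2 <- stratify_median(rep(0.9, 10), rep(0.1, 20),
                                        stats::rexp(20, 1 / 20),
                                        rep(1, 20)),
                 "empty")
  expect_true(is.na(st2$logrank$p))
})

test_that("metric ranges hold across random inputs", {
  set.seed(14)
  for (r in 1:10) {
    n <- 40
    cv <- mk_random_curves(n, J = 6)
    tm <- stats::runif(n, 1, 100)
    ev <- stats::rbinom(n, 1, 0.7)
    if (sum(ev) == 0) next
    x <- ctd_index(cv, tm, ev)
    expect_gte(x, 0); expect_lte(x, 1)
    ib <- integrated_brier(cv, tm, ev)
    expect_gte(ib, 0)
    ec <- ece_calibration(surv_at(cv, 50), tm, ev, horizon = 50)$ece
    expect_gte(ec, 0); expect_lte(ec, 1)
  }
})
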