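#' Kaplan-Meier product-limit estimator
#'
#' Standard tie convention: events precede censorings at tied times (both
#' are in the risk set at the tied time; censored subjects leave after).
#'
#' @param times observed times.
#' @param events 0/1 indicators.
#' @return An object of class \code{km_curve}: data at each distinct
#'   observed time (\code{time, at_risk, n_events, n_censored, S}).
#' @export
km_estimator <- function(times, events) {
  stopifnot(length(times) >= 1, length(times) == length(events))
  ut <- sort(unique(times))
  at_risk <- vapply(ut, function(t) sum(times >= t), numeric(1))
  d <- vapply(ut, function(t) sum(times == t & events == 1), numeric(1))
  cns <- vapply(ut, function(t) sum(times == t & events == 0), numeric(1))
  S <- cumprod(1 - d / at_risk)
  structure(list(time = ut, at_risk = at_risk, n_events = d,
                 n_censored = cns, S = S, n = length(times)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve> n=%d, %d events over %d distinct times; S(max)=%.3f\n",
              x$n, sum(x$n_events), length(x$time), x$S[length(x$S)]))
  invisible(x)
}

#' Evaluate a KM curve at arbitrary times
#'
#' @param km a \code{km_curve}.
#' @param t times; \code{left = TRUE} gives the left limit S(t-).
#' @param left evaluate the left-continuous version.
#' @return numeric vector of survival probabilities (1 before the first
#'   observed time).
#' @export
km_at <- function(km, t, left = FALSE) {
  idx <- if (left) findInterval(t - 1e-12, km$time)
         else findInterval(t, km$time)
  out <- c(1, km$S)[idx + 1]
  out
}

#' Two-group log-rank test
#'
#' @param times_a,events_a group A outcome.
#' @param times_b,events_b group B outcome.
#' @return list(chi2, p, obs_minus_exp) -- the 1-df chi-square statistic and
#'   p-value.
#' @export
logrank_test <- function(times_a, events_a, times_b, events_b) {
  if (!length(times_a) || !length(times_b))
    stop("both groups must be nonempty")
  if (sum(events_a) + sum(events_b) == 0)
    stop("no events: log-rank test undefined")
  times <- c(times_a, times_b)
  events <- c(events_a, events_b)
  grp <- rep(c(1, 2), c(length(times_a), length(times_b)))
  ut <- sort(unique(times[events == 1]))
  o_minus_e <- 0; v <- 0
  for (t in ut) {
    n1 <- sum(times_a >= t); n2 <- sum(times_b >= t)
    nj <- n1 + n2
    dj <- sum(times == t & events == 1)
    d1 <- sum(times_a == t & events_a == 1)
    o_minus_e <- o_minus_e + d1 - dj * n1 / nj
    if (nj > 1)
      v <- v + dj * (n1 / nj) * (n2 / nj) * (nj - dj) / (nj - 1)
  }
  chi2 <- if (v > 0) o_minus_e^2 / v else 0
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       obs_minus_exp = o_minus_e)
}

#' Time-dependent concordance index (Antolini)
#'
#' Over comparable pairs — i has an event and either T_i < T_j, or
#' T_i = T_j with j censored — a pair is concordant when the predicted
#' survival of i evaluated at T_i is lower than that of j at the same time;
#' prediction ties count 1/2.
#'
#' @param curves a \code{survival_curves} matrix (n x edges) with its grid.
#' @param times,events outcome per subject (rows of \code{curves}).
#' @return Concordant fraction in [0, 1].
#' @export
ctd_index <- function(curves, times, events) {
  n <- nrow(curves)
  if (n < 2 || sum(events) < 1)
    stop("need >= 2 subjects and >= 1 event")
  grid <- attr(curves, "grid")
  conc <- 0; tot <- 0
  for (i in which(events == 1)) {
    j <- findInterval(min(times[i], max(grid$edges)), grid$edges)
    s_at <- curves[, j]
    comp <- (times > times[i]) | (times == times[i] & events == 0)
    comp[i] <- FALSE
    if (!any(comp)) next
    conc <- conc + sum((s_at[i] < s_at[comp]) + 0.5 * (s_at[i] == s_at[comp]))
    tot <- tot + sum(comp)
  }
  if (tot == 0) stop("no comparable pairs")
  conc / tot
}

#' Percentile bootstrap confidence interval
#'
#' Subject-level resampling with replacement; resamples on which the
#' statistic is undefined (e.g. no comparable pairs) are redrawn, counted,
#' and capped.
#'
#' @param statistic function(indices) -> scalar, closed over the dataset.
#' @param n number of subjects.
#' @param n_boot resampling iterations (default 1000).
#' @param level confidence level (default 0.95).
#' @param seed RNG seed.
#' @param name label for the result.
#' @param max_redraw cap on redraws of invalid resamples.
#' @return An object of class \code{metric_result} with point estimate and
#'   percentile interval.
#' @export
bootstrap_ci <- function(statistic, n, n_boot = 1000, level = 0.95,
                         seed = 1L, name = "statistic",
                         max_redraw = 10 * n_boot) {
  point <- statistic(seq_len(n))
  redrawn <- 0
  vals <- with_seed(as.integer(seed), {
    out <- numeric(n_boot)
    b <- 1
    while (b <= n_boot) {
      idx <- sample.int(n, n, replace = TRUE)
      v <- tryCatch(statistic(idx), error = function(e) NA_real_)
      if (is.finite(v)) {
        out[b] <- v
        b <- b + 1
      } else {
        redrawn <- redrawn + 1
        if (redrawn > max_redraw)
          stop("bootstrap redraw cap exceeded: statistic undefined on ",
               "too many resamples")
      }
    }
    out
  })
  a <- (1 - level) / 2
  ci <- unname(stats::quantile(vals, c(a, 1 - a), type = 7))
  structure(list(name = name, point = point, ci_low = ci[1],
                 ci_high = ci[2], n_boot = n_boot, seed = seed,
                 level = level, n_redrawn = redrawn),
            class = "metric_result")
}

#' @export
print.metric_result <- function(x, ...) {
  cat(sprintf("%s: %.4f (%.0f%% CI %.4f-%.4f; %d bootstrap resamples)\n",
              x$name, x$point, 100 * x$level, x$ci_low, x$ci_high,
              x$n_boot))
  invisible(x)
}

# Censoring-distribution KM (for IPCW weights).
censoring_km <- function(times, events) km_estimator(times, 1 - events)

#' Time-dependent AUC (cumulative/dynamic, IPCW)
#'
#' Cases are subjects with an event by the horizon; controls are subjects
#' still at risk beyond it. Observations are weighted by the inverse of the
#' censoring-distribution Kaplan-Meier estimate.
#'
#' @param risk higher = riskier scalar scores.
#' @param times,events outcome.
#' @param horizon months (default 36).
#' @return Weighted AUC in [0, 1].
#' @export
td_auc <- function(risk, times, events, horizon = 36) {
  cases <- times <= horizon & events == 1
  controls <- times > horizon
  if (!any(cases) || !any(controls))
    stop("need events by the horizon and subjects at risk beyond it")
  G <- censoring_km(times, events)
  g_case <- km_at(G, times[cases], left = TRUE)
  g_ctrl <- km_at(G, horizon)
  if (any(g_case <= 0) || g_ctrl <= 0)
    stop("censoring distribution reaches 0 before the horizon")
  w_case <- 1 / g_case
  w_ctrl <- rep(1 / g_ctrl, sum(controls))
  rc <- risk[cases]; rk <- risk[controls]
  num <- 0
  for (i in seq_along(rc)) {
    num <- num + w_case[i] *
      sum(w_ctrl * ((rc[i] > rk) + 0.5 * (rc[i] == rk)))
  }
  num / (sum(w_case) * sum(w_ctrl))
}

#' Brier score and integrated Brier score (IPCW)
#'
#' \code{brier_score} is the inverse-probability-of-censoring-weighted mean
#' squared difference between the predicted survival at \code{t} and the
#' observed survival status; \code{integrated_brier} integrates it over the
#' evaluation times by the trapezoidal rule, normalised by their span.
#'
#' @param curves a \code{survival_curves} object.
#' @param times,events outcome.
#' @param t evaluation time.
#' @return scalar score.
#' @export
brier_score <- function(curves, times, events, t) {
  S_t <- surv_at(curves, t)
  G <- censoring_km(times, events)
  had_event <- times <= t & events == 1
  at_risk <- times > t
  out <- numeric(length(times))
  if (any(had_event)) {
    g <- km_at(G, times[had_event], left = TRUE)
    if (any(g <= 0))
      stop(sprintf("censoring KM reaches 0 before t = %.4g", t))
    out[had_event] <- S_t[had_event]^2 / g
  }
  if (any(at_risk)) {
    g <- km_at(G, t)
    if (g <= 0)
      stop(sprintf("censoring KM reaches 0 at t = %.4g", t))
    out[at_risk] <- (1 - S_t[at_risk])^2 / g
  }
  mean(out)
}

#' @rdname brier_score
#' @param eval_times times to integrate over (default: grid edges within
#'   the observed follow-up).
#' @export
integrated_brier <- function(curves, times, events, eval_times = NULL) {
  grid <- attr(curves, "grid")
  if (is.null(eval_times))
    eval_times <- grid$edges[grid$edges <= max(times)]
  eval_times <- sort(unique(eval_times))
  if (length(eval_times) < 2) stop("need >= 2 evaluation times")
  bs <- vapply(eval_times, function(t) brier_score(curves, times, events, t),
               numeric(1))
  span <- diff(range(eval_times))
  sum(diff(eval_times) * (utils::head(bs, -1) + utils::tail(bs, -1)) / 2) /
    span
}

#' Expected calibration error at a horizon
#'
#' Predictions (survival probabilities at the horizon) are grouped into
#' equal-width bins; within each bin the observed event-free proportion is
#' the Kaplan-Meier survival at the horizon (censoring-aware; a
#' censoring-naive mode drops subjects censored before the horizon). Bins
#' with fewer than 2 subjects are merged with their neighbor. ECE is the
#' subject-count-weighted mean absolute discrepancy.
#'
#' @param pred_surv predicted S(horizon) in [0, 1].
#' @param times,events outcome.
#' @param n_bins number of equal-width probability bins (default 10).
#' @param horizon months (default 36).
#' @param censoring \code{"km"} (default) or \code{"naive"}.
#' @return list(ece, table) where table has one row per (merged) bin.
#' @export
ece_calibration <- function(pred_surv, times, events, n_bins = 10,
                            horizon = 36, censoring = c("km", "naive")) {
  censoring <- match.arg(censoring)
  if (any(pred_surv < 0 | pred_surv > 1))
    stop("predictions must lie in [0, 1]")
  edges <- seq(0, 1, length.out = n_bins + 1)
  bin <- pmin(pmax(findInterval(pred_surv, edges, rightmost.closed = TRUE),
                   1L), n_bins)
  groups <- split(seq_along(pred_surv), bin)
  # merge bins with < 2 subjects into the next (or previous, for the last)
  merged <- list()
  carry <- integer(0)
  for (g in groups) {
    cur <- c(carry, g)
    if (length(cur) < 2) carry <- cur
    else { merged[[length(merged) + 1]] <- cur; carry <- integer(0) }
  }
  if (length(carry)) {
    if (length(merged))
      merged[[length(merged)]] <- c(merged[[length(merged)]], carry)
    else merged[[1]] <- carry
  }
  rows <- lapply(merged, function(idx) {
    obs <- if (censoring == "km") {
      km <- km_estimator(times[idx], events[idx])
      km_at(km, horizon)
    } else {
      keep <- !(times[idx] < horizon & events[idx] == 0)
      if (!any(keep)) return(NULL)
      mean(times[idx][keep] > horizon)
    }
    data.frame(n = length(idx), pred = mean(pred_surv[idx]), observed = obs)
  })
  tab <- do.call(rbind, rows)
  ece <- sum(tab$n * abs(tab$pred - tab$observed)) / sum(tab$n)
  list(ece = ece, table = tab)
}

#' Median-split risk stratification
#'
#' The threshold is the median risk score of the validation set, applied
#' unchanged to the test set (ties go to the low-risk group).
#'
#' @param risks_validation risk scores defining the threshold.
#' @param risks_test test-set risk scores.
#' @param times_test,events_test test-set outcome.
#' @param horizon months for the per-group event-free survival (default 36).
#' @return list(threshold, group, km (per group), logrank (chi2/p),
#'   efs_horizon (named low/high)); the log-rank p is NA with a warning if a
#'   group is empty.
#' @export
stratify_median <- function(risks_validation, risks_test, times_test,
                            events_test, horizon = 36) {
  if (!length(risks_validation)) stop("validation risks are empty")
  thr <- stats::median(risks_validation)
  high <- risks_test > thr
  group <- factor(ifelse(high, "high", "low"), levels = c("low", "high"))
  if (!any(high) || all(high)) {
    warning("one risk group is empty; log-rank p undefined")
    km1 <- km_estimator(times_test, events_test)
    efs <- km_at(km1, min(horizon, max(times_test)))
    return(list(threshold = thr, group = group,
                km = list(all = km1), logrank = list(chi2 = NA, p = NA),
                efs_horizon = efs))
  }
  km_lo <- km_estimator(times_test[!high], events_test[!high])
  km_hi <- km_estimator(times_test[high], events_test[high])
  lr <- logrank_test(times_test[!high], events_test[!high],
                     times_test[high], events_test[high])
  list(threshold = thr, group = group,
       km = list(low = km_lo, high = km_hi),
       logrank = lr,
       efs_horizon = c(low = km_at(km_lo, horizon),
                       high = km_at(km_hi, horizon)))
}
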