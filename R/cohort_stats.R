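#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p by probability-mass summation: the sum of hypergeometric
#' probabilities of all tables (with the observed margins) whose probability
#' does not exceed the observed table's, with a relative slack of 1e-7 —
#' the common convention, stated explicitly because software conventions
#' differ.
#'
#' @param tab 2x2 matrix (or a, b, c, d counts as a length-4 vector,
#'   row-wise): rows = category levels, columns = cohorts.
#' @return Two-sided p-value. A zero margin gives p = 1 with a warning.
#' @export
fisher_exact_2x2 <- function(tab) {
  if (!is.matrix(tab)) tab <- matrix(tab, 2, 2, byrow = TRUE)
  stopifnot(all(dim(tab) == 2), all(tab >= 0), all(tab == round(tab)))
  a <- tab[1, 1]
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  if (m == 0 || n == 0 || k == 0 || k == m + n) {
    warning("a table margin is zero; p = 1")
    return(1)
  }
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Wilcoxon rank-sum test
#'
#' Exact null distribution when min(n, m) <= 10 and there are no ties;
#' normal approximation with tie correction otherwise.
#'
#' @param x,y numeric samples (both nonempty).
#' @return Two-sided p-value (1 if all values are identical).
#' @export
wilcoxon_ranksum <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be nonempty")
  if (length(unique(c(x, y))) == 1) return(1)
  has_ties <- anyDuplicated(c(x, y)) > 0
  exact <- min(length(x), length(y)) <= 10 && !has_ties
  res <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = !exact))
  unname(res$p.value)
}

#' Univariable Cox proportional-hazards regression
#'
#' One covariate at a time, Breslow tie handling (robust screening role;
#' set \code{ties = "efron"} for the alternative), Wald p-value.
#'
#' @param x numeric covariate (nonconstant).
#' @param times,events outcome (>= 2 events).
#' @param ties \code{"breslow"} (default) or \code{"efron"}.
#' @return An object of class \code{cox_fit}: list(beta, hr, se, p_wald,
#'   converged).
#' @export
cox_univariable <- function(x, times, events, ties = "breslow") {
  if (length(unique(x)) < 2) stop("constant covariate")
  if (sum(events) < 2) stop("need >= 2 events")
  fit <- tryCatch(
    survival::coxph(survival::Surv(times, events) ~ x, ties = ties),
    warning = function(w) {
      f <- suppressWarnings(
        survival::coxph(survival::Surv(times, events) ~ x, ties = ties))
      attr(f, "monotone_likelihood") <- TRUE
      f
    })
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(stats::vcov(fit)[1, 1]))
  converged <- is.null(attr(fit, "monotone_likelihood")) &&
    is.finite(beta) && abs(beta) < 15
  structure(list(beta = beta, hr = exp(beta), se = se,
                 p_wald = 2 * stats::pnorm(-abs(beta / se)),
                 converged = converged),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("<cox_fit> beta=%.4f (HR %.3f), se=%.4f, Wald p=%.4g%s\n",
              x$beta, x$hr, x$se, x$p_wald,
              if (!x$converged) " [nonconvergence flagged]" else ""))
  invisible(x)
}

# Breslow log partial likelihood for a single covariate -- the
# grid-search/verification core used by tests and diagnostics.
breslow_loglik <- function(beta, x, times, events) {
  s <- 0
  for (t in sort(unique(times[events == 1]))) {
    d <- which(times == t & events == 1)
    risk <- which(times >= t)
    s <- s + beta * sum(x[d]) -
      length(d) * log(sum(exp(beta * x[risk])))
  }
  s
}

#' Table-1-style cohort description
#'
#' Per-site counts/percentages for categorical rows (Fisher's exact test,
#' 2x2 on the first level vs the rest when more than two levels) and
#' median [range] for continuous rows (Wilcoxon rank-sum), in a fixed row
#' order.
#'
#' @param clinical cohort data.frame with a \code{site} column.
#' @param continuous,categorical column names to summarise.
#' @return data.frame (variable, level, per-site summary columns, p).
#' @export
cohort_table <- function(clinical,
                         continuous = c("age_years", "time_months"),
                         categorical = c("sex", "resection", "chemo",
                                         "radiotherapy", "event")) {
  sites <- sort(unique(as.character(clinical$site)))
  if (length(sites) < 2) stop("need >= 2 sites")
  s1 <- clinical$site == sites[1]
  s2 <- clinical$site == sites[2]
  rows <- list()
  for (v in continuous) {
    x <- clinical[[v]]
    p <- wilcoxon_ranksum(x[s1], x[s2])
    rows[[length(rows) + 1]] <- data.frame(
      variable = v, level = "median [range]",
      site_a = sprintf("%.1f [%.1f, %.1f]", stats::median(x[s1]),
                       min(x[s1]), max(x[s1])),
      site_b = sprintf("%.1f [%.1f, %.1f]", stats::median(x[s2]),
                       min(x[s2]), max(x[s2])),
      p = p)
  }
  for (v in categorical) {
    x <- as.character(clinical[[v]])
    levs <- sort(unique(x))
    t1 <- table(factor(x[s1], levels = levs))
    t2 <- table(factor(x[s2], levels = levs))
    tab <- rbind(c(t1[1], t2[1]),
                 c(sum(t1[-1]), sum(t2[-1])))
    p <- fisher_exact_2x2(tab)
    for (ii in seq_along(levs)) {
      rows[[length(rows) + 1]] <- data.frame(
        variable = v, level = levs[ii],
        site_a = sprintf("%d (%.0f%%)", t1[ii], 100 * t1[ii] / sum(t1)),
        site_b = sprintf("%d (%.0f%%)", t2[ii], 100 * t2[ii] / sum(t2)),
        p = ifelse(ii == 1, p, NA))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  names(out)[names(out) == "site_a"] <- paste0("site_", sites[1])
  names(out)[names(out) == "site_b"] <- paste0("site_", sites[2])
  out
}
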