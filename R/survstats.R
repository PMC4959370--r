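#' Two-sample log-rank test
#'
#' Standard (unweighted) two-sample log-rank test on the pooled risk sets,
#' with the chi-square statistic referred to a 1-df chi-square distribution.
#' When ties occur between an event and a censoring time at the same instant,
#' the event precedes the censoring (the usual convention, as in
#' [survival::survdiff()], which performs the computation).
#'
#' @param time_a,event_a Follow-up times and event indicators (1 = event,
#'   0 = censored) for group A.
#' @param time_b,event_b Same for group B.
#' @return List of class `logrank_test`: `statistic` (chi-square),
#'   `p_value`, `observed` and `expected` event counts (named vectors,
#'   groups A and B), and `degenerate` (`TRUE` when no events occurred, in
#'   which case the statistic is 0 and p = 1).
#' @examples
#' lr <- logrank_test(c(2, 4, 6, 8), c(1, 1, 0, 1), c(3, 5, 7, 9), c(1, 0, 1, 1))
#' lr$p_value
#' @export
logrank_test <- function(time_a, event_a, time_b, event_b) {
  .check_surv(time_a, event_a, "A")
  .check_surv(time_b, event_b, "B")
  if (sum(event_a) + sum(event_b) == 0) {
    res <- list(statistic = 0, p_value = 1,
                observed = c(A = 0, B = 0),
                expected = c(A = 0, B = 0), degenerate = TRUE)
    class(res) <- "logrank_test"
    return(res)
  }
  grp <- factor(rep(c("A", "B"), c(length(time_a), length(time_b))))
  fit <- survival::survdiff(
    survival::Surv(c(time_a, time_b), c(event_a, event_b)) ~ grp)
  stat <- unname(fit$chisq)
  res <- list(statistic = stat,
              p_value = pchisq(stat, df = 1, lower.tail = FALSE),
              observed = setNames(as.numeric(fit$obs), c("A", "B")),
              expected = setNames(as.numeric(fit$exp), c("A", "B")),
              degenerate = FALSE)
  class(res) <- "logrank_test"
  res
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("Log-rank test: chi-square = %.4g, p = %.4g%s\n",
              x$statistic, x$p_value,
              if (x$degenerate) " (degenerate: no events)" else ""))
  cat(sprintf("  observed events A/B: %g/%g, expected: %.3g/%.3g\n",
              x$observed[1], x$observed[2], x$expected[1], x$expected[2]))
  invisible(x)
}

#' Hazard ratio of group A relative to group B
#'
#' Default estimator is the univariate Cox partial-likelihood estimate with a
#' single binary group covariate and Efron handling of tied event times
#' (via [survival::coxph()]).  The simpler Pike estimator
#' (O_A/E_A) / (O_B/E_B) from the log-rank risk tables is available as an
#' alternative.  HR > 1 means group A carries elevated hazard.
#'
#' @inheritParams logrank_test
#' @param estimator `"cox"` (default) or `"pike"`.
#' @return Positive scalar, or `NA` when either group has no events (the
#'   ratio is then undefined and callers should treat the comparison as
#'   degenerate).
#' @export
hazard_ratio <- function(time_a, event_a, time_b, event_b,
                         estimator = c("cox", "pike")) {
  estimator <- match.arg(estimator)
  .check_surv(time_a, event_a, "A")
  .check_surv(time_b, event_b, "B")
  if (sum(event_a) == 0 || sum(event_b) == 0) return(NA_real_)
  time <- c(time_a, time_b)
  event <- c(event_a, event_b)
  x <- rep(c(1, 0), c(length(time_a), length(time_b)))
  if (estimator == "cox") {
    fit <- survival::coxph(survival::Surv(time, event) ~ x, ties = "efron")
    unname(exp(fit$coefficients))
  } else {
    fit <- survival::survdiff(survival::Surv(time, event) ~ x)
    # survdiff orders groups by factor level: x=0 (B) first, x=1 (A) second
    (fit$obs[2] / fit$exp[2]) / (fit$obs[1] / fit$exp[1])
  }
}

#' Kaplan-Meier (product-limit) survival curve
#'
#' Product-limit estimate of the survival function under right censoring.
#' Subjects censored exactly at an event time remain at risk for that event
#' (the standard convention).  Computation is delegated to
#' [survival::survfit()].
#'
#' @param time Follow-up times (non-negative).
#' @param event Event indicators, 1 = event, 0 = censored.
#' @return List of class `km_curve` with components `time` (ascending unique
#'   follow-up times), `surv` (estimated S(t)), `n_risk`, `n_event`,
#'   `n_censor`, and `n` (subjects).
#' @export
km_curve <- function(time, event) {
  .check_surv(time, event, "input")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.type = "none")
  res <- list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
              n_event = fit$n.event, n_censor = fit$n.censor,
              n = length(time))
  class(res) <- "km_curve"
  res
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: %d subjects, %d events, final S(t) = %.3f\n",
              x$n, sum(x$n_event), tail(x$surv, 1)))
  invisible(x)
}

#' Draw one or more Kaplan-Meier curves
#'
#' @param x A `km_curve` or a named list of them (one line per curve).
#' @param col Line colours, recycled.
#' @param xlab,ylab,main Usual plot annotations.
#' @param ... Passed to [plot()].
#' @return Invisibly, `x`.
#' @export
plot.km_curve <- function(x, col = "black", xlab = "Time",
                          ylab = "Survival probability", main = NULL, ...) {
  plot(c(0, x$time), c(1, x$surv), type = "s", ylim = c(0, 1), col = col,
       xlab = xlab, ylab = ylab, main = main, ...)
  cens <- x$n_censor > 0
  if (any(cens)) points(x$time[cens], x$surv[cens], pch = 3, col = col)
  invisible(x)
}

#' Adjust p-values for multiple testing
#'
#' Benjamini-Hochberg step-up adjustment by default (Bonferroni and Holm
#' selectable); a thin validating wrapper over [stats::p.adjust()].
#'
#' @param p Numeric vector of p-values in \[0, 1\]; `NA` entries (untested
#'   items) are passed through.
#' @param method `"BH"`, `"bonferroni"`, or `"holm"`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
adjust_pvalues <- function(p, method = c("BH", "bonferroni", "holm")) {
  method <- match.arg(method)
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = method)
}

.check_surv <- function(time, event, label) {
  if (length(time) == 0L)
    stop("survival group ", label, " is empty")
  if (length(time) != length(event))
    stop("time and event lengths differ in group ", label)
  if (anyNA(time) || any(time < 0))
    stop("times in group ", label, " must be non-negative and complete")
  if (anyNA(event) || !all(event %in% c(0, 1)))
    stop("event indicators in group ", label, " must be 0 or 1")
  invisible(TRUE)
}
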