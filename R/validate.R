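#' Validate a prognostic module on an (held-out) cohort
#'
#' Scores the cohort with the module genes present in its expression matrix
#' (cross-platform matching: absent genes are dropped, with a minimum per
#' side), stratifies the samples, and compares the extreme score strata by
#' the log-rank test and hazard ratio, attaching a Kaplan-Meier curve per
#' stratum.
#'
#' @param module A `progmod_module`.
#' @param expr Numeric matrix, genes x samples, sample-aligned with `surv`
#'   (see [align_samples()]).
#' @param surv Survival data.frame (`sample`, `time`, `event`).
#' @param scheme Stratification scheme, see [stratify()].
#' @param mode Scoring mode, see [module_score()].
#' @param min_matched Minimum matched genes required per module side
#'   (default 3).
#' @param dataset Optional label for the cohort, carried into the report.
#' @return List of class `progmod_validation`: matched gene sets and counts,
#'   `scores`, `groups`, `logrank` (statistic, p), `hazard_ratio` (high vs
#'   low stratum), and `km` (named list of [km_curve()] objects per stratum).
#' @export
validate_module <- function(module, expr, surv,
                            scheme = c("median", "quartile"),
                            mode = c("ratio", "difference"),
                            min_matched = 3, dataset = NULL) {
  scheme <- match.arg(scheme)
  mode <- match.arg(mode)
  if (!identical(colnames(expr), surv$sample))
    stop("expression columns and survival rows are not aligned; call align_samples() first")
  scores <- module_score(expr, module, mode = mode)
  mh <- attr(scores, "matched_high")
  ml <- attr(scores, "matched_low")
  if (length(mh) < min_matched || length(ml) < min_matched)
    stop(sprintf("only %d high / %d low module genes matched; need >= %d per side",
                 length(mh), length(ml), min_matched))
  groups <- stratify(scores, scheme)
  hi <- which(groups == "high")
  lo <- which(groups == "low")
  lr <- logrank_test(surv$time[hi], surv$event[hi],
                     surv$time[lo], surv$event[lo])
  hr <- hazard_ratio(surv$time[hi], surv$event[hi],
                     surv$time[lo], surv$event[lo])
  km <- lapply(setNames(nm = levels(groups)), function(g) {
    idx <- which(groups == g)
    km_curve(surv$time[idx], surv$event[idx])
  })
  out <- list(dataset = dataset, module = module$label,
              matched_high = mh, matched_low = ml,
              n_matched = c(high = length(mh), low = length(ml)),
              module_size = c(high = length(module$high),
                              low = length(module$low)),
              scheme = scheme, mode = mode,
              scores = scores, groups = groups,
              logrank = list(statistic = lr$statistic, p_value = lr$p_value),
              hazard_ratio = hr, km = km)
  class(out) <- "progmod_validation"
  out
}

#' @export
print.progmod_validation <- function(x, ...) {
  cat(sprintf("Validation of %s%s\n", x$module,
              if (!is.null(x$dataset)) paste0(" on ", x$dataset) else ""))
  cat(sprintf("  matched genes: %d/%d high, %d/%d low\n",
              x$n_matched[["high"]], x$module_size[["high"]],
              x$n_matched[["low"]], x$module_size[["low"]]))
  cat(sprintf("  %s stratification: %s\n", x$scheme,
              paste(sprintf("%s n=%d", levels(x$groups),
                            tabulate(x$groups, length(levels(x$groups)))),
                    collapse = ", ")))
  cat(sprintf("  log-rank high vs low: chi-square = %.3g, p = %.3g, HR = %.3g\n",
              x$logrank$statistic, x$logrank$p_value, x$hazard_ratio))
  invisible(x)
}

#' Plot the per-stratum Kaplan-Meier curves of a validation report
#'
#' @param x A `progmod_validation`.
#' @param col Colours per stratum.
#' @param ... Passed to [plot.km_curve()].
#' @export
plot.progmod_validation <- function(x, col = c(low = "#2166ac",
                                               medium = "#999999",
                                               high = "#b2182b"), ...) {
  strata <- names(x$km)
  first <- TRUE
  for (g in strata) {
    cv <- x$km[[g]]
    if (first) {
      plot(cv, col = col[[g]],
           main = sprintf("%s (log-rank p = %.3g)", x$module,
                          x$logrank$p_value), ...)
      first <- FALSE
    } else {
      lines(c(0, cv$time), c(1, cv$surv), type = "s", col = col[[g]])
      cens <- cv$n_censor > 0
      if (any(cens)) points(cv$time[cens], cv$surv[cens], pch = 3,
                            col = col[[g]])
    }
  }
  legend("bottomleft", legend = paste(strata, "score"),
         col = col[strata], lty = 1, bty = "n")
  invisible(x)
}

#' Associate module scores with categorical clinical covariates
#'
#' For each covariate the scores are summarized per level (n, median,
#' quartiles) and levels are compared with a nonparametric omnibus test:
#' Kruskal-Wallis for three or more levels, Mann-Whitney (Wilcoxon rank-sum)
#' for two.  When the omnibus test is significant at `alpha`, BH-adjusted
#' pairwise Mann-Whitney tests are added.  Covariates that are entirely
#' missing or have fewer than two non-empty levels are skipped with a log
#' entry.
#'
#' @param scores Named numeric vector of module scores (names = samples).
#' @param clinical data.frame with a `sample` column and covariate columns.
#' @param covariates Covariate column names (default: every column except
#'   `sample`, `time`, `event`).
#' @param alpha Omnibus significance level gating the pairwise tests
#'   (default 0.05).
#' @return Named list of class `progmod_association`; per covariate a list
#'   with `summary` (per-level data.frame), `omnibus_test`, `omnibus_p`, and
#'   `pairwise_p` (matrix or `NULL`).
#' @export
associate_scores <- function(scores, clinical, covariates = NULL,
                             alpha = 0.05) {
  if (is.null(covariates))
    covariates <- setdiff(colnames(clinical), c("sample", "time", "event"))
  idx <- match(clinical$sample, names(scores))
  out <- list()
  for (cov in covariates) {
    if (!cov %in% colnames(clinical)) {
      .log("covariate '%s' not in clinical table; skipped", cov)
      next
    }
    val <- factor(clinical[[cov]])
    ok <- !is.na(val) & !is.na(idx)
    s <- scores[idx[ok]]
    f <- droplevels(val[ok])
    if (length(levels(f)) < 2L) {
      .log("covariate '%s' has < 2 non-empty levels; skipped", cov)
      next
    }
    summ <- do.call(rbind, lapply(levels(f), function(l) {
      v <- s[f == l]
      data.frame(level = l, n = length(v), median = median(v),
                 q25 = unname(quantile(v, 0.25)),
                 q75 = unname(quantile(v, 0.75)),
                 stringsAsFactors = FALSE)
    }))
    if (length(levels(f)) >= 3L) {
      om <- kruskal.test(s, f)
      test_name <- "kruskal-wallis"
    } else {
      om <- wilcox.test(s[f == levels(f)[1L]], s[f == levels(f)[2L]])
      test_name <- "mann-whitney"
    }
    pw <- NULL
    if (om$p.value < alpha && length(levels(f)) >= 3L)
      pw <- pairwise.wilcox.test(s, f, p.adjust.method = "BH")$p.value
    out[[cov]] <- list(covariate = cov, summary = summ,
                       omnibus_test = test_name,
                       omnibus_p = unname(om$p.value), pairwise_p = pw)
  }
  class(out) <- "progmod_association"
  out
}

#' @export
print.progmod_association <- function(x, ...) {
  if (!length(x)) {
    cat("No covariate associations computed\n")
    return(invisible(x))
  }
  for (a in x) {
    cat(sprintf("%s: %s p = %.3g (%s)\n", a$covariate, a$omnibus_test,
                a$omnibus_p,
                paste(sprintf("%s n=%d med=%.3g", a$summary$level,
                              a$summary$n, a$summary$median),
                      collapse = "; ")))
  }
  invisible(x)
}
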