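#' Fit prognostic gene-expression modules to a training cohort
#'
#' The full discovery pipeline as one fitting call.  Every gene is screened
#' for association with poor survival by a quartile-split log-rank test with
#' hazard-ratio and fold-change filters ([screen_all()]); the high-risk and
#' low-risk gene lists are clustered into co-expression cliques and paired
#' into modules by maximal bi-clique search over their anticorrelations
#' ([build_modules()]); each module scores every patient as the median
#' expression of its high-risk genes over (ratio) or minus (difference) its
#' low-risk genes ([module_score()]); patients are stratified at the score
#' median or quartiles ([stratify()]) and the extreme strata compared by the
#' log-rank test.
#'
#' @param expr Numeric matrix, genes x samples (gene rownames, sample
#'   colnames).
#' @param surv Survival data.frame (`sample`, `time`, `event`, optional
#'   covariate columns), as from [read_survival()].  Samples are aligned to
#'   the expression matrix automatically.
#' @param scale_hint `"linear"` or `"log"`: the scale of the expression
#'   values.  Controls fold-change computation and the default score mode.
#' @param screen A [screen_control()]; its `scale_hint` is overridden by the
#'   argument above.
#' @param pos_threshold,neg_threshold,min_cluster_size,max_clusters Module
#'   construction parameters, see [build_modules()].
#' @param score_mode `"auto"` (ratio for linear data, difference for log),
#'   `"ratio"`, or `"difference"`.
#' @param scheme Stratification scheme, see [stratify()].
#' @return Object of class `progmod`: list with the aligned cohort size, the
#'   screening result (`$screen`), the fitted `$modules`, per-module
#'   training `$scores`, `$strata`, and `$training` statistics (log-rank p,
#'   HR between extreme strata), plus the fitting parameters.  Methods:
#'   [print.progmod()], [summary.progmod()], [predict.progmod()],
#'   [plot.progmod()].
#' @examples
#' sim <- simulate_cohort(sim_config(n_samples = 150, n_genes = 60,
#'   blocks = list(sim_block(8, "high_risk", 0.8),
#'                 sim_block(8, "low_risk", 0.8)),
#'   cross_r = 0.6, beta = 1.2, censoring = 0.2), seed = 7)
#' fit <- progmod(sim$expr, sim$clinical, scale_hint = "log",
#'                screen = screen_control(adj_p_cutoff = 0.01),
#'                min_cluster_size = 5)
#' fit
#' @export
progmod <- function(expr, surv, scale_hint = c("linear", "log"),
                    screen = screen_control(),
                    pos_threshold = 0.4, neg_threshold = 0.4,
                    min_cluster_size = 16, max_clusters = 2,
                    score_mode = c("auto", "ratio", "difference"),
                    scheme = c("median", "quartile")) {
  scale_hint <- match.arg(scale_hint)
  score_mode <- match.arg(score_mode)
  scheme <- match.arg(scheme)
  screen$scale_hint <- scale_hint
  mode <- if (score_mode == "auto") {
    if (scale_hint == "log") "difference" else "ratio"
  } else score_mode
  al <- align_samples(expr, surv)
  scr <- screen_all(al$expr, al$surv, screen)
  modules <- build_modules(al$expr, scr$high, scr$low,
                           pos_threshold = pos_threshold,
                           neg_threshold = neg_threshold,
                           min_cluster_size = min_cluster_size,
                           max_clusters = max_clusters)
  scores <- list()
  strata <- list()
  training <- list()
  for (m in modules) {
    s <- module_score(al$expr, m, mode = mode)
    g <- stratify(s, scheme)
    hi <- which(g == "high")
    lo <- which(g == "low")
    lr <- logrank_test(al$surv$time[hi], al$surv$event[hi],
                       al$surv$time[lo], al$surv$event[lo])
    training[[m$label]] <- list(
      logrank_p = lr$p_value, logrank_statistic = lr$statistic,
      hazard_ratio = hazard_ratio(al$surv$time[hi], al$surv$event[hi],
                                  al$surv$time[lo], al$surv$event[lo]))
    scores[[m$label]] <- s
    strata[[m$label]] <- g
  }
  out <- list(call = match.call(), n_samples = ncol(al$expr),
              n_genes = nrow(al$expr), scale_hint = scale_hint,
              mode = mode, scheme = scheme,
              params = list(pos_threshold = pos_threshold,
                            neg_threshold = neg_threshold,
                            min_cluster_size = min_cluster_size,
                            max_clusters = max_clusters),
              screen = scr, modules = modules, scores = scores,
              strata = strata, training = training, surv = al$surv)
  class(out) <- "progmod"
  out
}

#' @export
print.progmod <- function(x, ...) {
  cat(sprintf("Prognostic module fit: %d genes x %d samples\n",
              x$n_genes, x$n_samples))
  cat(sprintf("  screen: %d high-risk, %d low-risk genes (adj p < %g)\n",
              length(x$screen$high), length(x$screen$low),
              x$screen$control$adj_p_cutoff))
  if (!length(x$modules)) {
    cat("  no modules found\n")
    return(invisible(x))
  }
  for (m in x$modules)
    cat(sprintf("  %s: %d high + %d low genes, training log-rank p = %.3g\n",
                m$label, length(m$high), length(m$low),
                x$training[[m$label]]$logrank_p))
  invisible(x)
}

#' Summarize a prognostic module fit
#'
#' @param object A `progmod` fit.
#' @param ... Unused.
#' @return data.frame with one row per module: gene counts, training
#'   log-rank statistic and p, and hazard ratio of the high- vs low-score
#'   stratum.
#' @export
summary.progmod <- function(object, ...) {
  if (!length(object$modules))
    return(data.frame(module = character(), n_high = integer(),
                      n_low = integer(), logrank_statistic = numeric(),
                      logrank_p = numeric(), hazard_ratio = numeric()))
  do.call(rbind, lapply(object$modules, function(m) {
    tr <- object$training[[m$label]]
    data.frame(module = m$label, n_high = length(m$high),
               n_low = length(m$low),
               logrank_statistic = tr$logrank_statistic,
               logrank_p = tr$logrank_p, hazard_ratio = tr$hazard_ratio,
               stringsAsFactors = FALSE)
  }))
}

#' Score and stratify a new cohort with a fitted module set
#'
#' Module genes absent from the new matrix are dropped (cross-platform
#' matching) with at least `min_matched` genes required per side.
#'
#' @param object A `progmod` fit.
#' @param newdata Numeric expression matrix, genes x samples, on the same
#'   scale as the training data.
#' @param type `"score"` returns a samples x modules matrix of scores,
#'   `"group"` the corresponding stratum labels.
#' @param scheme Stratification scheme for `type = "group"` (defaults to the
#'   fit's).
#' @param min_matched Minimum matched genes per module side (default 3).
#' @param ... Unused.
#' @return Matrix (scores) or data.frame of factors (groups), samples in
#'   rows, one column per module.
#' @export
predict.progmod <- function(object, newdata, type = c("score", "group"),
                            scheme = object$scheme, min_matched = 3, ...) {
  type <- match.arg(type)
  if (!length(object$modules)) stop("fit contains no modules")
  score_list <- lapply(object$modules, function(m) {
    s <- module_score(newdata, m, mode = object$mode)
    if (length(attr(s, "matched_high")) < min_matched ||
        length(attr(s, "matched_low")) < min_matched)
      stop(sprintf("%s: fewer than %d matched genes on one side",
                   m$label, min_matched))
    s
  })
  labels <- vapply(object$modules, `[[`, character(1), "label")
  if (type == "score") {
    out <- do.call(cbind, lapply(score_list, as.numeric))
    dimnames(out) <- list(colnames(newdata), labels)
    return(out)
  }
  out <- as.data.frame(lapply(score_list, stratify, scheme = scheme),
                       col.names = labels, check.names = FALSE)
  rownames(out) <- colnames(newdata)
  out
}

#' Kaplan-Meier plot of the training strata of a fitted module
#'
#' Draws one product-limit curve per score stratum of the training cohort.
#'
#' @param x A `progmod` fit.
#' @param module Module label or index (default the first, largest module).
#' @param col Colours per stratum.
#' @param ... Passed to [plot.km_curve()] for the first curve.
#' @export
plot.progmod <- function(x, module = 1L,
                         col = c(low = "#2166ac", medium = "#999999",
                                 high = "#b2182b"), ...) {
  if (!length(x$modules)) stop("fit contains no modules")
  labels <- vapply(x$modules, `[[`, character(1), "label")
  lab <- if (is.character(module)) module else labels[module]
  if (!lab %in% labels) stop("unknown module: ", lab)
  groups <- x$strata[[lab]]
  first <- TRUE
  for (g in levels(groups)) {
    idx <- which(groups == g)
    cv <- km_curve(x$surv$time[idx], x$surv$event[idx])
    if (first) {
      plot(cv, col = col[[g]],
           main = sprintf("%s, training cohort (log-rank p = %.3g)", lab,
                          x$training[[lab]]$logrank_p), ...)
      first <- FALSE
    } else {
      lines(c(0, cv$time), c(1, cv$surv), type = "s", col = col[[g]])
    }
  }
  legend("bottomleft", legend = paste(levels(groups), "score"),
         col = col[levels(groups)], lty = 1, bty = "n")
  invisible(x)
}
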