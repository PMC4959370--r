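#' Per-sample prognostic score for one module
#'
#' For each sample the score is the median expression of the module's
#' high-risk genes over the median expression of its low-risk genes (ratio
#' mode, the definition for linear-scale data).  For log-scale data use
#' difference mode, median(high) - median(low), which is the same quantity
#' on the log scale.  Module genes missing from the matrix are dropped with
#' a logged count (mirroring cross-platform gene matching); at least one
#' gene per side must remain.
#'
#' @param expr Numeric matrix, genes x samples.
#' @param module A `progmod_module` (or any list with `high` and `low`
#'   character vectors).
#' @param mode `"ratio"` or `"difference"`.
#' @return Named numeric vector of scores, one per sample, with attributes
#'   `matched_high` and `matched_low` (the genes actually used).
#' @export
module_score <- function(expr, module, mode = c("ratio", "difference")) {
  mode <- match.arg(mode)
  mh <- intersect(module$high, rownames(expr))
  ml <- intersect(module$low, rownames(expr))
  dropped <- (length(module$high) - length(mh)) +
    (length(module$low) - length(ml))
  if (dropped > 0L)
    .log("%d/%d module gene(s) absent from the matrix were dropped",
         dropped, length(module$high) + length(module$low))
  if (!length(mh) || !length(ml))
    stop("no ", if (length(mh)) "low" else "high",
         "-risk module genes present in the expression matrix")
  med_high <- apply(expr[mh, , drop = FALSE], 2L, median)
  med_low <- apply(expr[ml, , drop = FALSE], 2L, median)
  if (mode == "ratio") {
    if (any(med_low <= 0))
      stop("low-risk side has non-positive median expression for some ",
           "samples; ratio scores are undefined - use mode = 'difference' ",
           "for log-scale data")
    score <- med_high / med_low
  } else {
    score <- med_high - med_low
  }
  structure(score, matched_high = mh, matched_low = ml)
}

#' Stratify samples by prognostic score
#'
#' Median scheme: samples scoring strictly above the median score are
#' `high`, the rest `low`.  Quartile scheme: the `floor(n/4)` top-scoring
#' samples are `high`, the bottom `floor(n/4)` are `low`, the remainder
#' `medium`; ties are resolved deterministically by (score, stable sample
#' order).
#'
#' @param scores Named numeric vector (see [module_score()]).
#' @param scheme `"median"` or `"quartile"`.
#' @return Named factor of group labels with levels `low`/`high` (median) or
#'   `low`/`medium`/`high` (quartile).
#' @export
stratify <- function(scores, scheme = c("median", "quartile")) {
  scheme <- match.arg(scheme)
  n <- length(scores)
  if (n < 2L) stop("need at least 2 samples to stratify")
  if (length(unique(scores)) == 1L)
    stop("all scores identical; no stratification possible")
  nm <- names(scores)
  if (scheme == "median") {
    lab <- ifelse(scores > median(scores), "high", "low")
    out <- factor(lab, levels = c("low", "high"))
  } else {
    if (n < 4L) stop("quartile scheme needs >= 4 samples")
    k <- floor(n / 4)
    ord <- order(scores)                # stable under ties
    lab <- rep("medium", n)
    lab[ord[seq_len(k)]] <- "low"
    lab[ord[seq.int(n - k + 1L, n)]] <- "high"
    out <- factor(lab, levels = c("low", "medium", "high"))
  }
  names(out) <- nm
  out
}
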