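#' Control parameters for the genome-wide survival screen
#'
#' @param adj_p_cutoff Adjusted-p threshold below which a gene may be called
#'   prognostic (default 0.001).
#' @param fc_high_cutoff Minimum fold separation between the high- and
#'   low-expression quartile groups for a high-risk call (default 2).
#' @param fc_low_cutoff Maximum inverse separation (low/high) for a low-risk
#'   call (default 0.5, i.e. the same 2-fold separation).
#' @param fraction Fraction of samples in each extreme expression group
#'   (default 0.25: first vs fourth quartile).
#' @param p_adjust_method Multiple-testing adjustment; see [adjust_pvalues()].
#' @param hr_estimator Hazard-ratio estimator; see [hazard_ratio()].
#' @param fold_mode `"separation"` (default) calls a gene when the two
#'   quartile groups' median expression differs by the stated fold in
#'   magnitude, with direction carried entirely by the hazard ratio.
#'   `"literal"` applies the ratio exactly as written per direction
#'   (first-quartile/fourth-quartile > `fc_high_cutoff` for high-risk calls);
#'   because quartile groups are ordered by the gene's own expression this
#'   ratio never exceeds 1, so literal mode is provided for transparency
#'   only and selects no high-risk genes.
#' @param scale_hint `"linear"` or `"log"`: scale of the expression values.
#'   Fold changes are formed on the linear scale; log-scale (base-2) values
#'   are exponentiated first.
#' @return List of class `screen_control`.
#' @export
screen_control <- function(adj_p_cutoff = 0.001, fc_high_cutoff = 2,
                           fc_low_cutoff = 0.5, fraction = 0.25,
                           p_adjust_method = "BH",
                           hr_estimator = c("cox", "pike"),
                           fold_mode = c("separation", "literal"),
                           scale_hint = c("linear", "log")) {
  stopifnot(adj_p_cutoff > 0, fc_high_cutoff > 0, fc_low_cutoff > 0,
            fraction > 0, fraction <= 0.5)
  out <- list(adj_p_cutoff = adj_p_cutoff, fc_high_cutoff = fc_high_cutoff,
              fc_low_cutoff = fc_low_cutoff, fraction = fraction,
              p_adjust_method = p_adjust_method,
              hr_estimator = match.arg(hr_estimator),
              fold_mode = match.arg(fold_mode),
              scale_hint = match.arg(scale_hint))
  class(out) <- "screen_control"
  out
}

#' Split samples into extreme expression-quartile groups for one gene
#'
#' The low group holds the `floor(n * fraction)` samples with the smallest
#' expression of the gene, the high group the same number with the largest.
#' Ties spanning a cut are resolved deterministically by (value, stable
#' sample order).
#'
#' @param values Numeric expression values for one gene.
#' @param sample_ids Sample identifiers aligned with `values` (defaults to
#'   `names(values)`).
#' @param fraction Fraction per extreme group, in (0, 0.5].
#' @return List with character vectors `low` and `high` (disjoint).
#' @export
quartile_groups <- function(values, sample_ids = names(values),
                            fraction = 0.25) {
  n <- length(values)
  if (is.null(sample_ids)) sample_ids <- as.character(seq_len(n))
  stopifnot(length(sample_ids) == n, fraction > 0, fraction <= 0.5)
  if (n < 8L) stop("quartile grouping requires >= 8 samples, got ", n)
  k <- floor(n * fraction)
  if (k < 2L) stop("extreme groups would have fewer than 2 samples")
  ord <- order(values)           # stable: ties keep sample order
  list(low = sample_ids[ord[seq_len(k)]],
       high = sample_ids[ord[seq.int(n - k + 1L, n)]])
}

# hr, logrank p and fold change for one gene; direction decided by callers
.screen_gene_core <- function(x, surv, control) {
  if (var(x) == 0)
    return(list(hr = NA_real_, p_raw = NA_real_, fold_change = NA_real_,
                flag = "degenerate"))
  grp <- quartile_groups(x, surv$sample, control$fraction)
  lo <- match(grp$low, surv$sample)
  hi <- match(grp$high, surv$sample)
  lr <- logrank_test(surv$time[hi], surv$event[hi],
                     surv$time[lo], surv$event[lo])
  hr <- hazard_ratio(surv$time[hi], surv$event[hi],
                     surv$time[lo], surv$event[lo],
                     estimator = control$hr_estimator)
  xs <- if (control$scale_hint == "log") 2^x else x
  med_hi <- median(xs[hi])
  med_lo <- median(xs[lo])
  fc <- if (med_lo > 0) med_hi / med_lo else NA_real_
  flag <- if (is.na(hr)) "no_events"
          else if (lr$degenerate) "degenerate"
          else if (is.na(fc)) "nonpositive_fold"
          else ""
  list(hr = hr, p_raw = lr$p_value, fold_change = fc, flag = flag)
}

.screen_direction <- function(hr, p_adj, fc, flag, control) {
  dir <- rep("NONE", length(hr))
  ok <- flag == "" & !is.na(hr) & !is.na(p_adj) & !is.na(fc) &
    p_adj < control$adj_p_cutoff
  if (control$fold_mode == "separation") {
    dir[ok & hr > 1 & fc >= control$fc_high_cutoff] <- "HIGH_POOR"
    dir[ok & hr < 1 & (1 / fc) <= control$fc_low_cutoff] <- "LOW_POOR"
  } else {                       # literal per-direction ratios as written
    dir[ok & hr > 1 & (1 / fc) > control$fc_high_cutoff] <- "HIGH_POOR"
    dir[ok & hr < 1 & fc < control$fc_low_cutoff] <- "LOW_POOR"
  }
  dir
}

#' Screen a single gene for association with poor survival
#'
#' Samples are split into the gene's extreme expression quartiles; the
#' groups are compared by the log-rank test and the hazard ratio of the
#' high-expression group relative to the low-expression group; the fold
#' change is the ratio of the two groups' median expression on the linear
#' scale.  A gene is `HIGH_POOR` when HR > 1 with significant adjusted p and
#' sufficient fold separation, `LOW_POOR` when HR < 1 under the same
#' separation criterion, `NONE` otherwise.  For a single gene the adjusted
#' p equals the raw p; genome-wide adjustment is applied by [screen_all()].
#'
#' @param x Expression values for one gene, aligned with `surv$sample`.
#' @param surv Survival data.frame (columns `sample`, `time`, `event`).
#' @param control A [screen_control()].
#' @return One-row data.frame: `hr`, `p_raw`, `p_adj`, `fold_change`,
#'   `direction`, `flag`.
#' @export
screen_gene <- function(x, surv, control = screen_control()) {
  stopifnot(length(x) == nrow(surv))
  core <- .screen_gene_core(x, surv, control)
  direction <- .screen_direction(core$hr, core$p_raw, core$fold_change,
                                 core$flag, control)
  data.frame(hr = core$hr, p_raw = core$p_raw, p_adj = core$p_raw,
             fold_change = core$fold_change, direction = direction,
             flag = core$flag, stringsAsFactors = FALSE)
}

#' Genome-wide survival screen
#'
#' Applies [screen_gene()]'s statistics to every gene, adjusts the log-rank
#' p-values across all tested genes (degenerate genes excluded), and calls
#' each gene `HIGH_POOR`, `LOW_POOR`, or `NONE`.
#'
#' @param expr Numeric matrix, genes x samples, columns aligned with
#'   `surv$sample` (see [align_samples()]).
#' @param surv Survival data.frame.
#' @param control A [screen_control()].
#' @return List of class `progmod_screen`: `stats` (data.frame with columns
#'   `gene`, `hr`, `p_raw`, `p_adj`, `fold_change`, `direction`, `flag`),
#'   `high` and `low` (character vectors of called genes), and `control`.
#' @export
screen_all <- function(expr, surv, control = screen_control()) {
  if (!identical(colnames(expr), surv$sample))
    stop("expression columns and survival rows are not aligned; call align_samples() first")
  genes <- rownames(expr)
  if (is.null(genes)) stop("expression matrix must have gene rownames")
  cores <- vector("list", length(genes))
  for (i in seq_along(genes))
    cores[[i]] <- .screen_gene_core(expr[i, ], surv, control)
  stats <- data.frame(
    gene = genes,
    hr = vapply(cores, `[[`, numeric(1), "hr"),
    p_raw = vapply(cores, `[[`, numeric(1), "p_raw"),
    fold_change = vapply(cores, `[[`, numeric(1), "fold_change"),
    flag = vapply(cores, `[[`, character(1), "flag"),
    stringsAsFactors = FALSE)
  stats$p_adj <- adjust_pvalues(stats$p_raw, method = control$p_adjust_method)
  stats$direction <- .screen_direction(stats$hr, stats$p_adj,
                                       stats$fold_change, stats$flag, control)
  stats <- stats[, c("gene", "hr", "p_raw", "p_adj", "fold_change",
                     "direction", "flag")]
  out <- list(stats = stats,
              high = stats$gene[stats$direction == "HIGH_POOR"],
              low = stats$gene[stats$direction == "LOW_POOR"],
              control = control)
  class(out) <- "progmod_screen"
  out
}

#' @export
print.progmod_screen <- function(x, ...) {
  cat(sprintf(paste0(
    "Genome-wide survival screen: %d genes tested\n",
    "  high-expressed in poor survival: %d\n",
    "  low-expressed in poor survival:  %d\n",
    "  flagged (degenerate / no events): %d\n"),
    nrow(x$stats), length(x$high), length(x$low),
    sum(x$stats$flag != "")))
  invisible(x)
}
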