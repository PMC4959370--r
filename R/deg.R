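#' Differential expression between two sample groups
#'
#' Per-gene Welch (unequal-variance) t-test on log-scale expression with
#' Benjamini-Hochberg FDR control.  A gene is called `UP` when its mean
#' log2 fold change (group of interest minus reference) is at least
#' `lfc_cutoff` with raw p below `p_cutoff` and FDR below `fdr_cutoff`;
#' `DOWN` symmetrically; `NONE` otherwise.  Genes constant in both groups
#' are flagged and not tested.
#'
#' @param expr Numeric matrix, genes x samples, log2 scale (linear-scale
#'   input is log2-transformed and must then be strictly positive).
#' @param labels Logical or two-level factor over samples; `TRUE` (or the
#'   second factor level) marks the group of interest (e.g. TNBC).
#' @param p_cutoff,fdr_cutoff,lfc_cutoff Call thresholds (defaults 0.05,
#'   0.05, 0.5).
#' @param scale_hint `"log"` (default) or `"linear"`.
#' @return data.frame of class `progmod_deg` with columns `gene`, `logfc`,
#'   `p_raw`, `p_fdr`, `call`, `flag`.
#' @export
deg_screen <- function(expr, labels, p_cutoff = 0.05, fdr_cutoff = 0.05,
                       lfc_cutoff = 0.5, scale_hint = c("log", "linear")) {
  scale_hint <- match.arg(scale_hint)
  if (is.factor(labels) || is.character(labels)) {
    f <- factor(labels)
    if (length(levels(f)) != 2L)
      stop("labels must have exactly two levels, got ",
           length(levels(f)))
    labels <- f == levels(f)[2L]
  }
  stopifnot(is.logical(labels), length(labels) == ncol(expr))
  if (anyNA(labels)) stop("labels must be complete")
  if (sum(labels) < 2L || sum(!labels) < 2L)
    stop("each group needs at least 2 samples")
  if (scale_hint == "linear") {
    if (any(expr <= 0))
      stop("linear-scale expression must be positive for log2 transform")
    expr <- log2(expr)
  }
  genes <- rownames(expr)
  n <- nrow(expr)
  logfc <- p_raw <- rep(NA_real_, n)
  flag <- character(n)
  for (i in seq_len(n)) {
    g1 <- expr[i, labels]
    g0 <- expr[i, !labels]
    logfc[i] <- mean(g1) - mean(g0)
    if (var(g1) == 0 && var(g0) == 0) {
      flag[i] <- "degenerate"
      logfc[i] <- if (logfc[i] == 0) 0 else logfc[i]
      next
    }
    p_raw[i] <- tryCatch(t.test(g1, g0)$p.value,
                         error = function(e) NA_real_)
    if (is.na(p_raw[i])) flag[i] <- "degenerate"
  }
  p_fdr <- adjust_pvalues(p_raw, method = "BH")
  call <- rep("NONE", n)
  ok <- flag == "" & !is.na(p_raw) & p_raw < p_cutoff & p_fdr < fdr_cutoff
  call[ok & logfc >= lfc_cutoff] <- "UP"
  call[ok & logfc <= -lfc_cutoff] <- "DOWN"
  out <- data.frame(gene = genes, logfc = logfc, p_raw = p_raw,
                    p_fdr = p_fdr, call = call, flag = flag,
                    stringsAsFactors = FALSE)
  class(out) <- c("progmod_deg", "data.frame")
  out
}

#' Overlap of differential-expression calls with module gene sets
#'
#' @param deg A [deg_screen()] result (or a data.frame with `gene` and
#'   `call` columns).
#' @param modules List of `progmod_module` objects.
#' @return List, one element per module, each holding the identities and
#'   counts of high-side and low-side genes called `UP` / `DOWN`.
#' @export
overlap_modules <- function(deg, modules) {
  up <- deg$gene[deg$call == "UP"]
  down <- deg$gene[deg$call == "DOWN"]
  lapply(modules, function(m) {
    res <- list(module = m$label,
                high_up = intersect(m$high, up),
                high_down = intersect(m$high, down),
                low_up = intersect(m$low, up),
                low_down = intersect(m$low, down))
    res$counts <- c(high_up = length(res$high_up),
                    high_down = length(res$high_down),
                    low_up = length(res$low_up),
                    low_down = length(res$low_down))
    res
  })
}

#' Intersect differential-expression calls across datasets
#'
#' Replicated-call helper: a gene is retained as `UP` (resp. `DOWN`) when it
#' is called `UP` (`DOWN`) in every supplied [deg_screen()] table.
#'
#' @param deg_list List of `progmod_deg` tables from independent datasets.
#' @return List with character vectors `up` and `down`.
#' @export
deg_intersect <- function(deg_list) {
  stopifnot(length(deg_list) >= 1L)
  up <- Reduce(intersect, lapply(deg_list, function(d) d$gene[d$call == "UP"]))
  down <- Reduce(intersect,
                 lapply(deg_list, function(d) d$gene[d$call == "DOWN"]))
  list(up = up, down = down)
}
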