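#' Describe one planted co-expression block
#'
#' @param size Number of genes in the block (>= 2).
#' @param direction `"high_risk"` (expression rises with the hazard-driving
#'   latent activity) or `"low_risk"` (falls with it).
#' @param within_r Target Pearson correlation between two genes of the block
#'   (in (0, 1)).
#' @return List of class `sim_block`.
#' @export
sim_block <- function(size, direction = c("high_risk", "low_risk"),
                      within_r = 0.7) {
  direction <- match.arg(direction)
  stopifnot(size >= 2, within_r > 0, within_r < 1)
  structure(list(size = size, direction = direction, within_r = within_r),
            class = "sim_block")
}

#' Configuration for the synthetic cohort generator
#'
#' The generator plants blocks of co-expressed genes driven by a single
#' shared latent activity per cohort: high-risk blocks load positively on
#' it, low-risk blocks negatively, so anticorrelation between the two sides
#' arises mechanically.  Survival follows a proportional-hazards exponential
#' model in the latent activity; censoring is independent and calibrated to
#' a target rate; binary clinical covariates follow logistic models in the
#' same activity.
#'
#' @param n_samples,n_genes Cohort dimensions.
#' @param blocks List of [sim_block()]s; remaining genes are pure noise.
#' @param cross_r Target cross-block correlation magnitude between a
#'   high-risk and a low-risk gene (must not exceed any block's `within_r`).
#'   `NULL` puts all block signal on the shared factor, so the cross
#'   correlation equals the geometric mean of the within correlations and
#'   the closed form r = loading^2 / (loading^2 + noise_sd^2) holds exactly.
#' @param beta Log hazard ratio per unit (1 SD) of latent activity.
#' @param baseline_hazard Exponential baseline event rate (per study time
#'   unit).
#' @param censoring Target censoring fraction in \[0, 1).
#' @param noise_sd Residual SD of every gene.
#' @param baseline_range Range of per-gene baseline means, drawn uniformly;
#'   defaults emulate log2 microarray intensities (`scale_hint = "log"`).
#' @param covariates Named list; each element is
#'   `list(levels = c(ref, assoc), base_rate, slope)` where `base_rate` is
#'   the marginal probability of the activity-associated level at zero slope
#'   and `slope` its log-odds increase per unit activity.  Defaults plant
#'   ER-negative, TNBC, grade-3 and TP53-mutant labels at prevalences
#'   typical of breast-cancer cohorts, all enriched at high activity.
#' @param seed Optional integer seed making the draw fully reproducible.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_samples = 400, n_genes = 2000,
                       blocks = list(sim_block(20, "high_risk", 0.7),
                                     sim_block(20, "low_risk", 0.7)),
                       cross_r = 0.5, beta = 1, baseline_hazard = 0.1,
                       censoring = 0.3, noise_sd = 1,
                       baseline_range = c(6, 10),
                       covariates = default_sim_covariates(),
                       seed = NULL) {
  stopifnot(n_samples >= 8, n_genes >= 1, censoring >= 0, censoring < 1,
            noise_sd >= 0, baseline_hazard > 0)
  total_block <- sum(vapply(blocks, `[[`, numeric(1), "size"))
  if (total_block > n_genes)
    stop("block sizes (", total_block, ") exceed n_genes (", n_genes, ")")
  if (!is.null(cross_r)) {
    stopifnot(cross_r > 0, cross_r < 1)
    for (b in blocks)
      if (cross_r > b$within_r)
        stop("cross_r must not exceed any block's within_r")
  }
  structure(list(n_samples = n_samples, n_genes = n_genes, blocks = blocks,
                 cross_r = cross_r, beta = beta,
                 baseline_hazard = baseline_hazard, censoring = censoring,
                 noise_sd = noise_sd, baseline_range = baseline_range,
                 covariates = covariates, seed = seed),
            class = "sim_config")
}

#' @rdname sim_config
#' @export
default_sim_covariates <- function() {
  list(ER = list(levels = c("pos", "neg"), base_rate = 0.22, slope = 1.0),
       TNBC = list(levels = c("nonTNBC", "TNBC"), base_rate = 0.16,
                   slope = 1.0),
       grade = list(levels = c("1-2", "3"), base_rate = 0.48, slope = 0.8),
       TP53 = list(levels = c("wt", "mut"), base_rate = 0.30, slope = 0.8))
}

# censoring-rate calibration: find the exponential censoring rate rc with
# E_a[ rc / (rc + lambda(a)) ] = target, a ~ N(0,1), lambda = b0 * exp(beta a)
.censoring_rate <- function(target, baseline, beta) {
  if (target <= 0) return(0)
  pcens <- function(rc) {
    integrate(function(a) dnorm(a) * rc / (rc + baseline * exp(beta * a)),
              -Inf, Inf)$value
  }
  lo <- baseline * 1e-8
  hi <- baseline * 1e8
  uniroot(function(rc) pcens(rc) - target, c(lo, hi), tol = 1e-10)$root
}

#' Simulate an expression + survival cohort with planted prognostic blocks
#'
#' See [sim_config()] for the generative model.  Block genes occupy the
#' first rows of the matrix (the truth table records membership); remaining
#' genes are independent noise.  Expression is emitted on a log2-like
#' intensity scale (`scale_hint = "log"`), so downstream scoring should use
#' difference mode.
#'
#' @param config A [sim_config()].
#' @param seed Overrides `config$seed` when given.
#' @return List of class `progmod_sim`: `expr` (genes x samples matrix),
#'   `clinical` (data.frame `sample`, `time`, `event`, covariates),
#'   `truth` (per-gene block membership, per-sample latent `activity`,
#'   `beta`, the calibrated `censoring_rate`, and the `config`), and
#'   `scale_hint` (`"log"`).
#' @export
simulate_cohort <- function(config = sim_config(), seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_samples
  p <- config$n_genes
  sigma <- config$noise_sd
  activity <- rnorm(n)
  gene_ids <- sprintf("gene_%05d", seq_len(p))
  sample_ids <- sprintf("sample_%04d", seq_len(n))
  expr <- matrix(rnorm(p * n, sd = sigma), nrow = p,
                 dimnames = list(gene_ids, sample_ids))
  baseline <- runif(p, config$baseline_range[1L], config$baseline_range[2L])
  expr <- expr + baseline
  membership <- data.frame(gene = gene_ids, block = NA_integer_,
                           direction = "none", stringsAsFactors = FALSE)
  row0 <- 0L
  for (bi in seq_along(config$blocks)) {
    b <- config$blocks[[bi]]
    # noiseless limit: within-block correlation is exactly 1 regardless of
    # the target; signal variance is set to 1 arbitrarily
    tau2 <- if (sigma > 0) sigma^2 / (1 - b$within_r) else 1
    v <- if (sigma > 0) tau2 * b$within_r else tau2
    l_shared2 <- if (is.null(config$cross_r)) v else config$cross_r * tau2
    l_block <- sqrt(v - l_shared2)
    l_shared <- sqrt(l_shared2)
    u <- rnorm(n)                               # block-specific factor
    signal <- l_shared * activity + l_block * u
    if (b$direction == "low_risk") signal <- -signal
    rows <- row0 + seq_len(b$size)
    expr[rows, ] <- expr[rows, ] + rep(signal, each = b$size)
    membership$block[rows] <- bi
    membership$direction[rows] <- b$direction
    row0 <- row0 + b$size
  }
  rate <- config$baseline_hazard * exp(config$beta * activity)
  t_event <- rexp(n, rate)
  cens_rate <- .censoring_rate(config$censoring, config$baseline_hazard,
                               config$beta)
  t_cens <- if (cens_rate > 0) rexp(n, cens_rate) else rep(Inf, n)
  time <- pmin(t_event, t_cens)
  event <- as.numeric(t_event <= t_cens)       # ties: event precedes censoring
  clinical <- data.frame(sample = sample_ids, time = time, event = event,
                         stringsAsFactors = FALSE)
  for (cv in names(config$covariates)) {
    spec <- config$covariates[[cv]]
    pr <- plogis(qlogis(spec$base_rate) + spec$slope * activity)
    lvl <- ifelse(rbinom(n, 1L, pr) == 1L, spec$levels[2L], spec$levels[1L])
    clinical[[cv]] <- factor(lvl, levels = spec$levels)
  }
  out <- list(expr = expr, clinical = clinical,
              truth = list(membership = membership, activity = activity,
                           beta = config$beta, censoring_rate = cens_rate,
                           config = config),
              scale_hint = "log")
  class(out) <- "progmod_sim"
  out
}

#' @export
print.progmod_sim <- function(x, ...) {
  cfg <- x$truth$config
  planted <- sum(x$truth$membership$direction != "none")
  cat(sprintf(paste0(
    "Synthetic cohort: %d genes x %d samples (%d planted in %d block(s))\n",
    "  events: %d/%d (censoring %.0f%%), beta = %.2g per SD activity\n"),
    nrow(x$expr), ncol(x$expr), planted, length(cfg$blocks),
    sum(x$clinical$event), nrow(x$clinical),
    100 * mean(1 - x$clinical$event), cfg$beta))
  invisible(x)
}

#' Tiny deterministic fixture cohort
#'
#' A fixed 16-gene x 24-sample cohort used in examples and unit tests: two
#' noiseless 4-gene blocks (one high-risk, one low-risk, exactly +/-1
#' correlated), eight pure-noise genes, deterministic survival with hazard
#' increasing in the latent activity, and a TNBC-like covariate.
#' Regeneration is bit-identical.
#'
#' @return A `progmod_sim` list (see [simulate_cohort()]); noiseless block
#'   genes, so build modules from it with `noise` in mind (correlations are
#'   exactly +/-1).
#' @export
fixture_small <- function() {
  n <- 24L
  set.seed(197407L)
  activity <- as.numeric(scale(qnorm((1:n - 0.5) / n)))
  sample_ids <- sprintf("s%02d", seq_len(n))
  gene_ids <- sprintf("g%02d", 1:16)
  expr <- matrix(0, 16L, n, dimnames = list(gene_ids, sample_ids))
  hi_load <- c(1, 2, 0.5, 1.5)
  lo_load <- c(1.2, 0.8, 1, 2)
  for (k in 1:4) expr[k, ] <- 8 + hi_load[k] * activity
  for (k in 1:4) expr[4L + k, ] <- 8 - lo_load[k] * activity
  expr[9:16, ] <- 8 + matrix(rnorm(8L * n), 8L, n)
  rate <- 0.2 * exp(activity)
  time <- round(log(2) / rate, 3)      # median survival under each hazard
  event <- rep(c(1, 1, 0), length.out = n)
  clinical <- data.frame(sample = sample_ids, time = time, event = event,
                         TNBC = factor(ifelse(activity > 0.8, "TNBC",
                                              "nonTNBC"),
                                       levels = c("nonTNBC", "TNBC")),
                         stringsAsFactors = FALSE)
  membership <- data.frame(gene = gene_ids,
                           block = c(rep(1L, 4), rep(2L, 4),
                                     rep(NA_integer_, 8)),
                           direction = c(rep("high_risk", 4),
                                         rep("low_risk", 4),
                                         rep("none", 8)),
                           stringsAsFactors = FALSE)
  out <- list(expr = expr, clinical = clinical,
              truth = list(membership = membership, activity = activity,
                           beta = 1, censoring_rate = NA_real_,
                           config = NULL),
              scale_hint = "log")
  class(out) <- "progmod_sim"
  out
}
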