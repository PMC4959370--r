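# Independent brute-force oracles used to cross-check the package's
# survival statistics and graph searches.  These deliberately share no code
# with the implementation paths they verify.

# two-sample log-rank chi-square from first principles: observed-minus-
# expected events and hypergeometric variance accumulated over the pooled
# distinct event times (group1 = TRUE half of `group`)
oracle_logrank <- function(time, event, group) {
  stopifnot(is.logical(group))
  ev_times <- sort(unique(time[event == 1]))
  oe <- v <- 0
  for (t in ev_times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group)
    oe <- oe + d1 - d * n1 / n
    if (n > 1)
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  stat <- if (v > 0) oe^2 / v else 0
  list(statistic = stat,
       p_value = pchisq(stat, df = 1, lower.tail = FALSE),
       o_minus_e = oe, variance = v)
}

# product-limit estimator computed by explicit risk-set bookkeeping
oracle_km <- function(time, event) {
  times <- sort(unique(time))
  s <- 1
  out_t <- out_s <- numeric(0)
  for (t in times) {
    n_risk <- sum(time >= t)
    d <- sum(time == t & event == 1)
    if (d > 0) s <- s * (1 - d / n_risk)
    out_t <- c(out_t, t)
    out_s <- c(out_s, s)
  }
  data.frame(time = out_t, surv = out_s)
}

# Efron-tie-corrected Cox log partial likelihood for a binary covariate,
# maximized by golden-section search over beta (independent of coxph)
oracle_cox_loglik <- function(beta, time, event, x) {
  ev_times <- sort(unique(time[event == 1]))
  ll <- 0
  for (t in ev_times) {
    risk <- time >= t
    tied <- time == t & event == 1
    d <- sum(tied)
    s0 <- sum(exp(beta * x[risk]))
    s0d <- sum(exp(beta * x[tied]))
    ll <- ll + beta * sum(x[tied])
    for (l in seq_len(d) - 1)
      ll <- ll - log(s0 - (l / d) * s0d)
  }
  ll
}

oracle_cox_hr <- function(time_a, event_a, time_b, event_b) {
  time <- c(time_a, time_b)
  event <- c(event_a, event_b)
  x <- rep(c(1, 0), c(length(time_a), length(time_b)))
  opt <- optimize(oracle_cox_loglik, c(-15, 15), maximum = TRUE,
                  time = time, event = event, x = x, tol = 1e-10)
  exp(opt$maximum)
}

# Benjamini-Hochberg step-up by the direct min-over-larger-ranks formula
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  sorted <- p[ord]
  for (i in seq_len(m))
    adj[ord[i]] <- min(1, min(sorted[i:m] * m / (i:m)))
  adj
}

# exhaustive maximum-clique search over all vertex subsets (n <= ~15);
# returns all maximum cliques as sorted name vectors
oracle_max_cliques <- function(adj) {
  n <- nrow(adj)
  stopifnot(n <= 16)
  nm <- rownames(adj)
  best_size <- 0
  best <- list()
  for (mask in seq_len(2^n) - 1) {
    members <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    k <- length(members)
    if (k < best_size || k == 0) next
    is_clique <- TRUE
    if (k > 1) {
      sub <- adj[members, members]
      is_clique <- all(sub[upper.tri(sub)])
    }
    if (!is_clique) next
    if (k > best_size) {
      best_size <- k
      best <- list(sort(nm[members]))
    } else {
      best <- c(best, list(sort(nm[members])))
    }
  }
  best
}

# exhaustive maximal-biclique search: closures of every non-empty subset of
# side A; returns the max-edge maximal biclique under the same objective and
# tie-breaks as the implementation (edges, then min side, then lexicographic)
oracle_max_edge_biclique <- function(adj) {
  na <- nrow(adj)
  stopifnot(na <= 10)
  a_names <- rownames(adj)
  b_names <- colnames(adj)
  best <- NULL
  best_key <- c(-1, -1)
  lex_less <- function(a, b) {
    n <- min(length(a), length(b))
    for (i in seq_len(n)) {
      if (a[i] < b[i]) return(TRUE)
      if (a[i] > b[i]) return(FALSE)
    }
    length(a) < length(b)
  }
  seen <- character(0)
  for (mask in seq_len(2^na - 1)) {
    a_sub <- which(bitwAnd(mask, 2^(seq_len(na) - 1)) > 0)
    b_sub <- which(apply(adj[a_sub, , drop = FALSE], 2, all))
    if (!length(b_sub)) next
    # close on the A side to get a maximal biclique
    a_closed <- which(apply(adj[, b_sub, drop = FALSE], 1, all))
    key_str <- paste(c(a_closed, NA, b_sub), collapse = ",")
    if (key_str %in% seen) next
    seen <- c(seen, key_str)
    sa <- sort(a_names[a_closed])
    sb <- sort(b_names[b_sub])
    key <- c(length(sa) * length(sb), min(length(sa), length(sb)))
    take <- key[1] > best_key[1] ||
      (key[1] == best_key[1] && key[2] > best_key[2]) ||
      (identical(key, best_key) && lex_less(c(sa, sb), c(best$high, best$low)))
    if (take) {
      best <- list(high = sa, low = sb)
      best_key <- key
    }
  }
  best
}

# direct edge-check validators used on emitted clusters and modules
is_clique_in <- function(adj, members) {
  idx <- match(members, rownames(adj))
  k <- length(idx)
  if (k < 2) return(TRUE)
  sub <- adj[idx, idx]
  all(sub[upper.tri(sub)])
}

# random right-censored survival fixture
random_surv_fixture <- function(n, seed) {
  set.seed(seed)
  time <- round(rexp(n, 0.2), 1)   # rounding induces ties
  event <- rbinom(n, 1, 0.7)
  list(time = time, event = event,
       group = seq_len(n) <= n %/% 2)
}

# random undirected graph as a logical adjacency matrix
random_graph_adj <- function(n, p_edge, seed) {
  set.seed(seed)
  adj <- matrix(FALSE, n, n, dimnames = list(letters[seq_len(n)],
                                             letters[seq_len(n)]))
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      adj[i, j] <- adj[j, i] <- runif(1) < p_edge
  adj
}

# igraph object from a logical adjacency matrix
graph_from_adj <- function(adj) {
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
}

# small aligned expression + survival pair used across unit tests
small_cohort <- function(n = 40, p = 10, seed = 11) {
  set.seed(seed)
  expr <- matrix(rnorm(p * n, mean = 8), p, n,
                 dimnames = list(sprintf("g%02d", seq_len(p)),
                                 sprintf("s%02d", seq_len(n))))
  surv <- data.frame(sample = colnames(expr),
                     time = round(rexp(n, 0.1), 2),
                     event = rbinom(n, 1, 0.7),
                     stringsAsFactors = FALSE)
  list(expr = expr, surv = surv)
}
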