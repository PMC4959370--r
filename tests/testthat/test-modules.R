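# expression matrix whose genes are latent-factor driven, for graph tests
factor_expr <- function(n_samples, loadings, seed, noise = 1) {
  set.seed(seed)
  a <- rnorm(n_samples)
  expr <- t(vapply(loadings, function(l) l * a + rnorm(n_samples, sd = noise),
                   numeric(n_samples)))
  dimnames(expr) <- list(sprintf("g%02d", seq_along(loadings)),
                         sprintf("s%03d", seq_len(n_samples)))
  expr
}

test_that("correlation graph edges equal a direct covariance/sigma oracle", {
  expr <- factor_expr(60, c(2, 1.5, 1, -1, -2), seed = 3)
  g <- correlation_graph(expr, threshold = 0.3, sign_mode = "positive")
  cm <- cor(t(expr))
  el <- igraph::as_edgelist(g)
  # every edge carries the Pearson r of its endpoints and exceeds threshold
  expect_true(all(abs(igraph::E(g)$weight - cm[el]) < 1e-12))
  expect_true(all(cm[el] > 0.3))
  # and no above-threshold pair is missing
  expect_equal(igraph::ecount(g), sum(cm[upper.tri(cm)] > 0.3))

  gn <- correlation_graph(expr, threshold = 0.3, sign_mode = "negative")
  eln <- igraph::as_edgelist(gn)
  expect_true(all(cm[eln] <= -0.3))
  expect_equal(igraph::ecount(gn), sum(cm[upper.tri(cm)] <= -0.3))
})

test_that("duplicated genes form a complete subgraph; constant genes are excluded", {
  set.seed(4)
  base <- rnorm(30)
  expr <- rbind(gA = base, gB = base, gC = base,
                gD = rnorm(30), gE = rep(1, 30))
  colnames(expr) <- sprintf("s%02d", 1:30)
  expect_message(g <- correlation_graph(expr, threshold = 0.4), "zero-variance")
  expect_false("gE" %in% igraph::V(g)$name)
  sub <- igraph::induced_subgraph(g, c("gA", "gB", "gC"))
  expect_equal(igraph::ecount(sub), 3)  # complete triangle at r = 1
})

test_that("independent genes stay essentially unconnected at threshold 0.4", {
  set.seed(6)
  expr <- matrix(rnorm(30 * 500), 30, 500,
                 dimnames = list(sprintf("g%02d", 1:30),
                                 sprintf("s%03d", 1:500)))
  g <- correlation_graph(expr, threshold = 0.4)
  density <- igraph::ecount(g) / choose(30, 2)
  expect_lt(density, 0.01)
})

test_that("iterative clique extraction matches brute-force enumeration", {
  # complete graph: single cluster holding everything
  adj <- matrix(TRUE, 20, 20, dimnames = list(paste0("g", 1:20),
                                              paste0("g", 1:20)))
  diag(adj) <- FALSE
  cl <- extract_cliques(graph_from_adj(adj), min_size = 16)
  expect_length(cl, 1)
  expect_length(cl[[1]], 20)

  # edgeless graph: nothing to extract
  none <- matrix(FALSE, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  expect_length(extract_cliques(graph_from_adj(none), min_size = 2), 0)

  # random graphs: first extracted clique equals the exhaustive maximum
  # clique (largest, ties to the lexicographically smallest set), and the
  # full iterative extraction matches an oracle that repeats removal
  for (seed in 1:6) {
    adj <- random_graph_adj(12 + seed %% 3, p_edge = 0.55, seed = 900 + seed)
    got <- extract_cliques(graph_from_adj(adj), min_size = 2,
                           max_clusters = 3)
    cur <- adj
    expected <- list()
    while (length(expected) < 3 && nrow(cur) > 0) {
      cands <- oracle_max_cliques(cur)
      if (!length(cands) || length(cands[[1]]) < 2) break
      best <- cands[[1]]
      for (s in cands[-1]) {
        cmp <- progmod:::.lex_less(s, best)
        if (cmp) best <- s
      }
      expected[[length(expected) + 1]] <- best
      keep <- setdiff(rownames(cur), best)
      cur <- cur[keep, keep, drop = FALSE]
    }
    expect_identical(got, expected)
    # post-hoc validator: every emitted cluster is a genuine clique
    for (cl in got) expect_true(is_clique_in(adj, cl))
  }
})

test_that("bi-clique pairing matches the exhaustive closure oracle", {
  for (seed in 1:8) {
    set.seed(700 + seed)
    na <- sample(4:6, 1); nb <- sample(4:6, 1)
    adj <- matrix(runif(na * nb) < 0.55, na, nb,
                  dimnames = list(paste0("h", seq_len(na)),
                                  paste0("l", seq_len(nb))))
    got <- progmod:::.max_edge_biclique(adj)
    want <- oracle_max_edge_biclique(adj)
    expect_identical(got, want)
    if (!is.null(got)) {
      # all-pairs cross-edge property holds by direct checking
      expect_true(all(adj[got$high, got$low]))
    }
  }
  # no cross edges -> no bi-clique
  empty <- matrix(FALSE, 3, 3, dimnames = list(paste0("h", 1:3),
                                               paste0("l", 1:3)))
  expect_null(progmod:::.max_edge_biclique(empty))
})

test_that("cluster pairing emits modules ordered by size with full provenance", {
  # two anticorrelated noiseless blocks -> complete bipartite negative graph
  set.seed(12)
  a <- rnorm(40)
  expr <- rbind(h1 = 2 * a, h2 = a, h3 = 1.5 * a,
                l1 = -a, l2 = -0.5 * a)
  colnames(expr) <- sprintf("s%02d", 1:40)
  mods <- pair_clusters(list(c("h1", "h2", "h3")), list(c("l1", "l2")),
                        expr, neg_threshold = 0.4)
  expect_length(mods, 1)
  expect_equal(mods[[1]]$high, c("h1", "h2", "h3"))
  expect_equal(mods[[1]]$low, c("l1", "l2"))
  expect_equal(mods[[1]]$label, "module 1")

  # uncorrelated cluster pair yields no module
  set.seed(13)
  expr2 <- rbind(expr, x1 = rnorm(40), x2 = rnorm(40))
  expect_message(
    none <- pair_clusters(list(c("h1", "h2")), list(c("x1", "x2")),
                          expr2, neg_threshold = 0.4),
    "no anticorrelation")
  expect_length(none, 0)
})

test_that("module construction recovers planted blocks and honours invariants", {
  hits <- 0
  for (seed in 41:43) {
    sim <- simulate_cohort(sim_config(
      n_samples = 300, n_genes = 80,
      blocks = list(sim_block(18, "high_risk", 0.7),
                    sim_block(18, "low_risk", 0.7)),
      cross_r = 0.6, beta = 1, censoring = 0.2), seed = seed)
    truth <- sim$truth$membership
    high <- truth$gene[truth$direction == "high_risk"]
    low <- truth$gene[truth$direction == "low_risk"]
    mods <- build_modules(sim$expr, high, low, min_cluster_size = 16)
    expect_length(mods, 1)
    m <- mods[[1]]
    if (length(intersect(m$high, high)) >= 0.8 * length(high) &&
        length(intersect(m$low, low)) >= 0.8 * length(low)) hits <- hits + 1
    # every emitted module satisfies the all-pairs anticorrelation property
    cm <- cor(t(sim$expr[m$high, , drop = FALSE]),
              t(sim$expr[m$low, , drop = FALSE]))
    expect_true(all(cm <= -0.4))
    # and each side is a clique of the positive graph
    ch <- cor(t(sim$expr[m$high, , drop = FALSE]))
    expect_true(all(ch[upper.tri(ch)] > 0.4))

    # sample-permutation invariance
    perm <- sample(ncol(sim$expr))
    mods_perm <- build_modules(sim$expr[, perm], high, low,
                               min_cluster_size = 16)
    expect_identical(mods_perm, mods)
  }
  expect_equal(hits, 3)

  # an empty screened list yields no modules
  expect_length(build_modules(matrix(1:4, 2), character(0), "g1"), 0)
})
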