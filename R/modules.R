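#' Build a thresholded Pearson correlation graph over a gene set
#'
#' Pairwise Pearson correlations are computed across all samples; in
#' positive mode genes are connected when r strictly exceeds the threshold,
#' in negative mode when r <= -threshold (the negative bound is inclusive).
#' Zero-variance genes cannot enter a correlation and are excluded with a
#' logged count.
#'
#' @param expr Numeric matrix, genes x samples (>= 3 samples).
#' @param genes Character vector of genes to include (subset of rownames).
#' @param threshold Positive correlation magnitude threshold (default 0.4).
#' @param sign_mode `"positive"` or `"negative"`.
#' @return An [igraph::graph] with vertex names = gene IDs, edge attribute
#'   `weight` = r, and graph attributes `sign_mode` and `threshold`.
#' @export
correlation_graph <- function(expr, genes = rownames(expr), threshold = 0.4,
                              sign_mode = c("positive", "negative")) {
  sign_mode <- match.arg(sign_mode)
  stopifnot(threshold > 0, ncol(expr) >= 3L)
  missing_genes <- setdiff(genes, rownames(expr))
  if (length(missing_genes))
    stop("genes absent from expression matrix: ",
         paste(head(missing_genes, 5L), collapse = ", "))
  sub <- expr[genes, , drop = FALSE]
  constant <- apply(sub, 1L, var) == 0
  if (any(constant)) {
    .log("excluded %d zero-variance gene(s) from correlation graph",
         sum(constant))
    sub <- sub[!constant, , drop = FALSE]
  }
  cmat <- cor(t(sub))
  adj <- if (sign_mode == "positive") cmat > threshold else cmat <= -threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  ew <- cmat[igraph::as_edgelist(g)]
  g <- igraph::set_edge_attr(g, "weight", value = ew)
  g <- igraph::set_graph_attr(g, "sign_mode", sign_mode)
  g <- igraph::set_graph_attr(g, "threshold", threshold)
  g
}

# TRUE when sorted character set a precedes b lexicographically
.lex_less <- function(a, b) {
  n <- min(length(a), length(b))
  for (i in seq_len(n)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  length(a) < length(b)
}

# canonical representative among same-size candidate gene sets
.lex_min_set <- function(sets) {
  best <- sets[[1L]]
  for (s in sets[-1L]) if (.lex_less(s, best)) best <- s
  best
}

#' Iteratively extract maximum cliques as co-expression clusters
#'
#' Repeatedly finds a maximum clique of the graph (exact search via
#' [igraph::largest_cliques()]), records it as a cluster when its size meets
#' `min_size`, removes its vertices, and repeats until no qualifying clique
#' remains or `max_clusters` clusters were taken.  Equal-size maximum
#' cliques are tie-broken to the lexicographically smallest gene-ID set, so
#' the result is deterministic and independent of vertex order.
#'
#' @param graph An [igraph::graph] with named vertices (see
#'   [correlation_graph()]).
#' @param min_size Minimum cluster size (default 16, i.e. more than 15
#'   genes).
#' @param max_clusters Maximum number of clusters to extract (default 2).
#' @return List of character vectors (sorted gene IDs), in extraction order.
#' @export
extract_cliques <- function(graph, min_size = 16, max_clusters = 2) {
  stopifnot(min_size >= 1, max_clusters >= 1)
  clusters <- list()
  g <- graph
  while (length(clusters) < max_clusters && igraph::vcount(g) > 0L) {
    cliques <- igraph::largest_cliques(g)
    if (!length(cliques) || length(cliques[[1L]]) < min_size) break
    sets <- lapply(cliques, function(cl) sort(names(cl)))
    best <- .lex_min_set(sets)
    clusters[[length(clusters) + 1L]] <- best
    g <- igraph::delete_vertices(g, best)
  }
  clusters
}

# max-edge maximal bi-clique between two vertex sets of a bipartite
# negative-correlation graph; adj is a logical |A| x |B| cross-edge matrix.
# Reduction: maximal bi-cliques of the bipartite graph are exactly the
# maximal cliques of the auxiliary graph in which each side is made
# complete, restricted to cliques touching both sides.
.max_edge_biclique <- function(adj) {
  a_names <- rownames(adj)
  b_names <- colnames(adj)
  if (!any(adj)) return(NULL)
  na <- length(a_names)
  nb <- length(b_names)
  full <- matrix(FALSE, na + nb, na + nb,
                 dimnames = list(c(a_names, b_names), c(a_names, b_names)))
  full[seq_len(na), seq_len(na)] <- TRUE
  full[na + seq_len(nb), na + seq_len(nb)] <- TRUE
  full[seq_len(na), na + seq_len(nb)] <- adj
  full[na + seq_len(nb), seq_len(na)] <- t(adj)
  diag(full) <- FALSE
  h <- igraph::graph_from_adjacency_matrix(full, mode = "undirected")
  cliques <- igraph::max_cliques(h, min = 2L)
  best <- NULL
  best_key <- c(-1, -1)
  for (cl in cliques) {
    nm <- names(cl)
    side_a <- sort(nm[nm %in% a_names])
    side_b <- sort(nm[nm %in% b_names])
    if (!length(side_a) || !length(side_b)) next
    key <- c(length(side_a) * length(side_b),
             min(length(side_a), length(side_b)))
    take <- key[1L] > best_key[1L] ||
      (key[1L] == best_key[1L] && key[2L] > best_key[2L]) ||
      (identical(key, best_key) &&
         .lex_less(c(side_a, side_b), c(best$high, best$low)))
    if (take) {
      best <- list(high = side_a, low = side_b)
      best_key <- key
    }
  }
  best
}

#' Pair co-expression clusters into prognostic modules by bi-clique search
#'
#' For every (high-risk cluster, low-risk cluster) pair, a bipartite graph is
#' built connecting gene pairs whose Pearson correlation is <= -neg_threshold,
#' and the maximal bi-clique with the most edges is extracted (ties broken by
#' the larger minimum side, then lexicographically).  A module is emitted
#' when both sides of the bi-clique are non-empty; modules are ordered by
#' total gene count (descending) and labelled `module 1`, `module 2`, ...
#'
#' @param high_clusters,low_clusters Lists of gene-ID vectors (see
#'   [extract_cliques()]).
#' @param expr Numeric matrix, genes x samples.
#' @param neg_threshold Anticorrelation magnitude threshold (default 0.4;
#'   the bound is inclusive: r = -0.4 connects).
#' @return List of modules; each is a list with `label`, `high`, `low`, and
#'   `source` (the (high, low) cluster ranks it came from).
#' @export
pair_clusters <- function(high_clusters, low_clusters, expr,
                          neg_threshold = 0.4) {
  modules <- list()
  for (i in seq_along(high_clusters)) {
    for (j in seq_along(low_clusters)) {
      hg <- high_clusters[[i]]
      lg <- low_clusters[[j]]
      cmat <- cor(t(expr[hg, , drop = FALSE]), t(expr[lg, , drop = FALSE]))
      adj <- cmat <= -neg_threshold
      dimnames(adj) <- list(hg, lg)
      bic <- .max_edge_biclique(adj)
      if (is.null(bic)) {
        .log("cluster pair (high %d, low %d): no anticorrelation edges, no module",
             i, j)
        next
      }
      modules[[length(modules) + 1L]] <-
        list(high = bic$high, low = bic$low, source = c(high = i, low = j))
    }
  }
  if (!length(modules)) return(modules)
  sizes <- vapply(modules, function(m) length(m$high) + length(m$low),
                  numeric(1))
  ord <- order(-sizes,
               vapply(modules, function(m) m$source[["high"]], numeric(1)),
               vapply(modules, function(m) m$source[["low"]], numeric(1)))
  modules <- modules[ord]
  for (k in seq_along(modules)) {
    modules[[k]]$label <- paste("module", k)
    modules[[k]] <- modules[[k]][c("label", "high", "low", "source")]
    class(modules[[k]]) <- "progmod_module"
  }
  modules
}

#' @export
print.progmod_module <- function(x, ...) {
  cat(sprintf("%s: %d high-risk + %d low-risk genes (clusters H%d x L%d)\n",
              x$label, length(x$high), length(x$low),
              x$source[["high"]], x$source[["low"]]))
  invisible(x)
}

#' Build prognostic modules from screened gene lists
#'
#' Composition of [correlation_graph()], [extract_cliques()] (run separately
#' on the high-risk and low-risk gene lists with the positive threshold) and
#' [pair_clusters()] (negative threshold across the lists).  Deterministic
#' given inputs and parameters.
#'
#' @param expr Numeric matrix, genes x samples.
#' @param high_list,low_list Genes called `HIGH_POOR` / `LOW_POOR` by
#'   [screen_all()].
#' @param pos_threshold,neg_threshold Pearson thresholds for within-list
#'   co-expression (exclusive, default 0.4) and cross-list anticorrelation
#'   (inclusive, default 0.4).
#' @param min_cluster_size Minimum genes per co-expression cluster
#'   (default 16).
#' @param max_clusters Clusters retained per direction (default 2, i.e. up
#'   to 4 modules).
#' @return List of `progmod_module` objects (possibly empty).
#' @export
build_modules <- function(expr, high_list, low_list, pos_threshold = 0.4,
                          neg_threshold = 0.4, min_cluster_size = 16,
                          max_clusters = 2) {
  if (!length(high_list) || !length(low_list)) return(list())
  g_high <- correlation_graph(expr, high_list, pos_threshold, "positive")
  g_low <- correlation_graph(expr, low_list, pos_threshold, "positive")
  hc <- extract_cliques(g_high, min_cluster_size, max_clusters)
  lc <- extract_cliques(g_low, min_cluster_size, max_clusters)
  if (!length(hc) || !length(lc)) {
    .log("no co-expression cluster of size >= %d on %s side; no modules",
         min_cluster_size, if (length(hc)) "low" else "high")
    return(list())
  }
  pair_clusters(hc, lc, expr, neg_threshold)
}
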