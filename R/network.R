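#' Centered log-ratio transform
#'
#' Applies the CLR transform per sample after adding a pseudocount, making
#' compositional counts amenable to covariance-based network inference.
#'
#' @param counts sample x taxon matrix of nonnegative counts.
#' @param pseudocount value added to every count before taking logs.
#' @return real matrix; every row sums to zero.
#' @export
clr_transform <- function(counts, pseudocount = 1) {
  check_counts(counts)
  x <- log(counts + pseudocount)
  if (!all(is.finite(x))) stop("non-finite values after log transform")
  sweep(x, 1, rowMeans(x), "-")
}

# correlation matrix robust to constant columns in a subsample
safe_cor <- function(x) {
  s <- suppressWarnings(stats::cor(x))
  s[!is.finite(s)] <- 0
  diag(s) <- 1
  s
}

mb_lambda_path <- function(S, nlambda, lambda_min_ratio) {
  lmax <- max(abs(S[upper.tri(S)]))
  if (lmax <= 0) lmax <- 1e-3
  exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = nlambda))
}

#' Meinshausen-Buhlmann neighborhood selection along a lambda path
#'
#' For each taxon, fits an L1-penalised regression of its (standardised CLR)
#' column on all others along a decreasing log-spaced lambda path starting at
#' the smallest lambda giving an empty graph; an edge is present when either
#' (`"OR"`, default) or both (`"AND"`) of the two neighborhoods select it.
#'
#' @param x CLR-transformed matrix (samples x taxa).
#' @param nlambda number of path values (default 100).
#' @param lambda_min_ratio ratio of the smallest to the largest lambda
#'   (default `1e-3`).
#' @param rule edge symmetrisation rule, `"OR"` or `"AND"`.
#' @param lambda_path optional explicit path (descending).
#' @return an `mb_path` object: `lambdas`, logical `support` matrix
#'   (taxon pairs x lambdas, upper-triangle order), `sparsity` per lambda,
#'   and the taxon names.
#' @export
mb_neighborhood_selection <- function(x, nlambda = 100, lambda_min_ratio = 1e-3,
                                      rule = c("OR", "AND"),
                                      lambda_path = NULL) {
  rule <- match.arg(rule)
  if (nrow(x) < 4) stop("need at least 4 samples for neighborhood selection")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("degenerate (constant) column(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  xs <- scale(x)
  S <- safe_cor(xs)
  if (is.null(lambda_path)) lambda_path <- mb_lambda_path(S, nlambda, lambda_min_ratio)
  sup <- mb_support_cpp(S, lambda_path, rule = if (rule == "OR") 0L else 1L)
  structure(list(lambdas = lambda_path,
                 support = sup == 1L,
                 sparsity = colMeans(sup),
                 taxa = colnames(x),
                 rule = rule),
            class = "mb_path")
}

#' Adjacency matrix at one point of an MB path
#'
#' @param path an `mb_path` from [mb_neighborhood_selection()].
#' @param index lambda index (1 = sparsest).
#' @return symmetric logical adjacency matrix with zero diagonal.
#' @export
mb_adjacency <- function(path, index) {
  p <- length(path$taxa)
  adj <- matrix(FALSE, p, p, dimnames = list(path$taxa, path$taxa))
  adj[upper.tri(adj)] <- path$support[, index]
  adj | t(adj)
}

#' StARS stability selection for an MB co-occurrence network
#'
#' Estimates edge-selection frequencies over random subsamples of size
#' `floor(10 * sqrt(n))` (capped at `n - 1`), computes the graph instability
#' `mean(2 * f * (1 - f))` per lambda, monotonises it by a running supremum
#' from the sparse end of the path, and refits the MB graph on the full data
#' at the densest lambda whose monotonised instability stays at or below
#' `instability_threshold`.  Isolated taxa are dropped from the final graph.
#'
#' @param counts count matrix for one design combination (samples x taxa).
#' @param kingdom named character vector (`"bacteria"`/`"fungi"`) per taxon.
#' @param nlambda,lambda_min_ratio,rule passed to
#'   [mb_neighborhood_selection()].
#' @param n_subsamples number of subsamples (default 50).
#' @param instability_threshold StARS threshold (default 0.05).
#' @param pseudocount CLR pseudocount.
#' @param combination label stored on the network.
#' @param seed integer seed for the subsampling.
#' @return an `mb_network`: `graph` (igraph with `kingdom` vertex attribute
#'   and signed `weight` edge metadata), `lambdas`, `instability`,
#'   `selected_index`, `selected_lambda`, `edge_freq`, and bookkeeping.
#' @export
stability_select <- function(counts, kingdom = NULL,
                             nlambda = 100, lambda_min_ratio = 1e-3,
                             rule = c("OR", "AND"),
                             n_subsamples = 50, instability_threshold = 0.05,
                             pseudocount = 1, combination = NA_character_,
                             seed = 1L) {
  rule <- match.arg(rule)
  if (n_subsamples < 2) stop("need at least 2 subsamples")
  x <- clr_transform(counts, pseudocount)
  # drop taxa that are constant on the full data (all-zero in this cell)
  sds <- apply(x, 2, stats::sd)
  x <- x[, sds > 0, drop = FALSE]
  n <- nrow(x)
  if (n < 4) stop("need at least 4 samples")
  p <- ncol(x)
  xs <- scale(x)
  S_full <- safe_cor(xs)
  lambda_path <- mb_lambda_path(S_full, nlambda, lambda_min_ratio)
  # subsample size 10*sqrt(n), capped at 0.8n for small n so subsamples
  # stay distinct enough to register instability
  m_sub <- max(4L, min(floor(10 * sqrt(n)), floor(0.8 * n), n - 1))

  set.seed(seed)
  rule_int <- if (rule == "OR") 0L else 1L
  sub_rows <- lapply(seq_len(n_subsamples), function(b) sample.int(n, m_sub))
  S_sub <- lapply(sub_rows, function(rows)
    safe_cor(scale(x[rows, , drop = FALSE])))
  # walk the path from the sparse end in chunks: the selected lambda lies
  # before the first crossing of the monotonised instability, so denser
  # lambdas need never be fitted
  npair <- p * (p - 1) / 2
  chunk <- 10L
  nlam <- length(lambda_path)
  freq <- matrix(0, npair, 0)
  instability <- numeric(0)
  idx <- 0L
  while (idx < nlam) {
    take <- seq(idx + 1L, min(idx + chunk, nlam))
    fc <- matrix(0, npair, length(take))
    for (b in seq_len(n_subsamples))
      fc <- fc + mb_support_cpp(S_sub[[b]], lambda_path[take], rule = rule_int)
    fc <- fc / n_subsamples
    freq <- cbind(freq, fc)
    instability <- c(instability, colMeans(2 * fc * (1 - fc)))
    idx <- idx + length(take)
    if (any(cummax(instability) > instability_threshold)) break
  }
  mono <- cummax(instability)
  ok <- which(mono <= instability_threshold)
  if (length(ok) == 0L) {
    warning("no lambda met the instability threshold; returning sparsest graph")
    sel <- 1L
  } else sel <- max(ok)

  full <- mb_neighborhood_selection(x, lambda_path = lambda_path[seq_len(sel)],
                                    rule = rule)
  adj <- mb_adjacency(full, sel)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  if (!is.null(kingdom))
    igraph::V(g)$kingdom <- unname(kingdom[igraph::V(g)$name])
  else igraph::V(g)$kingdom <- NA_character_
  if (igraph::ecount(g) > 0) {
    el <- igraph::as_edgelist(g)
    igraph::E(g)$weight <- S_full[cbind(match(el[, 1], colnames(x)),
                                        match(el[, 2], colnames(x)))]
  }
  iso <- igraph::degree(g) == 0
  g <- igraph::delete_vertices(g, which(iso))

  structure(list(graph = g, combination = combination,
                 lambdas = lambda_path, instability = instability,
                 selected_index = sel, selected_lambda = lambda_path[sel],
                 edge_freq = freq, n_subsamples = n_subsamples,
                 instability_threshold = instability_threshold,
                 subsample_size = m_sub,
                 taxa = colnames(x), n_samples = n, seed = seed),
            class = "mb_network")
}

#' @export
print.mb_network <- function(x, ...) {
  cat("mb_network", if (!is.na(x$combination)) paste0("[", x$combination, "]"),
      ":", igraph::vcount(x$graph), "nodes,", igraph::ecount(x$graph),
      "edges; lambda =", signif(x$selected_lambda, 4),
      "(index", x$selected_index, "of", length(x$lambdas), ")\n")
  invisible(x)
}

#' @export
summary.mb_network <- function(object, ...) {
  part <- detect_modules(object)
  network_summary(object, part)
}

#' @export
plot.mb_network <- function(x, ...) {
  g <- x$graph
  cols <- ifelse(igraph::V(g)$kingdom == "fungi", "#D95F02", "#1B9E77")
  igraph::plot.igraph(g, vertex.size = 4, vertex.label = NA,
                      vertex.color = cols, ...)
  invisible(x)
}

as_igraph <- function(network) {
  if (inherits(network, "mb_network")) network$graph
  else if (inherits(network, "igraph")) network
  else stop("expected an mb_network or igraph object")
}

#' Detect modules (subcommunities) by greedy modularity optimisation
#'
#' Clauset-Newman-Moore hierarchical agglomeration
#' (`igraph::cluster_fast_greedy`).  An edgeless graph yields singleton
#' modules with undefined modularity.
#'
#' @param network an `mb_network` or igraph object.
#' @return a `module_partition`: named `membership` vector, `sizes`,
#'   `modularity`.
#' @export
detect_modules <- function(network) {
  g <- as_igraph(network)
  if (igraph::vcount(g) == 0) stop("network has no nodes")
  g <- igraph::simplify(g)
  # unweighted clustering: signed co-occurrence weights are metadata only
  if ("weight" %in% igraph::edge_attr_names(g))
    g <- igraph::delete_edge_attr(g, "weight")
  if (igraph::ecount(g) == 0) {
    memb <- stats::setNames(seq_len(igraph::vcount(g)), igraph::V(g)$name)
    return(structure(list(membership = memb,
                          sizes = table(memb), modularity = NA_real_),
                     class = "module_partition"))
  }
  cl <- igraph::cluster_fast_greedy(g, weights = NULL)
  memb <- stats::setNames(as.integer(igraph::membership(cl)), igraph::V(g)$name)
  structure(list(membership = memb, sizes = table(memb),
                 modularity = igraph::modularity(g, memb)),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat("module_partition:", length(x$sizes), "modules over",
      length(x$membership), "nodes; Q =",
      if (is.na(x$modularity)) "NA" else signif(x$modularity, 4), "\n")
  invisible(x)
}

#' Node centralities of a co-occurrence network
#'
#' Degree, normalised betweenness, closeness (computed within each connected
#' component; `harmonic = TRUE` gives harmonic closeness over all nodes), and
#' eigenvector centrality scaled to a maximum of 1.
#'
#' @param network an `mb_network` or igraph.
#' @param harmonic use harmonic closeness instead of per-component closeness.
#' @return data.frame (node, kingdom, degree, betweenness, closeness,
#'   eigenvector).
#' @export
centralities <- function(network, harmonic = FALSE) {
  g <- as_igraph(network)
  if (igraph::vcount(g) == 0) stop("network has no nodes")
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, normalized = TRUE)
  d <- igraph::distances(g)
  if (harmonic) {
    inv <- 1 / d
    diag(inv) <- 0
    inv[!is.finite(inv)] <- 0
    clo <- rowSums(inv) / (nrow(d) - 1)
  } else {
    comp <- igraph::components(g)$membership
    clo <- vapply(seq_len(nrow(d)), function(i) {
      same <- which(comp == comp[i])
      same <- setdiff(same, i)
      if (!length(same)) return(NA_real_)
      length(same) / sum(d[i, same])
    }, numeric(1))
  }
  eig <- igraph::eigen_centrality(g)$vector  # scaled to max 1 by igraph
  data.frame(node = igraph::V(g)$name,
             kingdom = igraph::V(g)$kingdom %||% NA_character_,
             degree = unname(deg), betweenness = unname(btw),
             closeness = unname(clo), eigenvector = unname(eig),
             stringsAsFactors = FALSE)
}

# two-sample KS statistic (fast, ties handled by ECDF difference)
ks_statistic <- function(x, y) {
  all_v <- sort(unique(c(x, y)))
  Fx <- stats::ecdf(x)(all_v)
  Fy <- stats::ecdf(y)(all_v)
  max(abs(Fx - Fy))
}

#' Compare centrality distributions between two networks
#'
#' For each centrality index, reports the two-sample Kolmogorov-Smirnov test
#' on the observed vectors together with a bootstrap (resampling both vectors
#' with replacement) confidence interval on the KS statistic.  Stars follow
#' the thresholds 0.05, 0.01, 0.0001.
#'
#' @param setA,setB data.frames from [centralities()].
#' @param n_bootstrap bootstrap iterations (default 10000).
#' @param seed integer seed.
#' @return data.frame per index: `statistic`, `p_value`, bootstrap mean and
#'   95% CI, `n_bootstrap`, `stars`.
#' @export
compare_centrality_distributions <- function(setA, setB, n_bootstrap = 10000,
                                             seed = 1L) {
  idx <- intersect(c("degree", "betweenness", "closeness", "eigenvector"),
                   intersect(names(setA), names(setB)))
  if (!length(idx)) stop("no shared centrality columns")
  set.seed(seed)
  out <- lapply(idx, function(v) {
    a <- setA[[v]][is.finite(setA[[v]])]
    b <- setB[[v]][is.finite(setB[[v]])]
    if (!length(a) || !length(b)) stop("empty centrality vector for ", v)
    obs <- ks_statistic(a, b)
    pv <- suppressWarnings(stats::ks.test(a, b)$p.value)
    boot <- vapply(seq_len(n_bootstrap), function(i) {
      ks_statistic(sample(a, replace = TRUE), sample(b, replace = TRUE))
    }, numeric(1))
    data.frame(index = v, statistic = obs, p_value = pv,
               boot_mean = mean(boot),
               boot_lo = unname(stats::quantile(boot, 0.025)),
               boot_hi = unname(stats::quantile(boot, 0.975)),
               n_bootstrap = n_bootstrap,
               stars = if (pv <= 1e-4) "****" else if (pv <= 0.01) "**"
                       else if (pv <= 0.05) "*" else "",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Topology summary of a network and its partition
#'
#' @param network an `mb_network` or igraph.
#' @param partition optional `module_partition`; detected if missing.
#' @return list: node/edge counts (total and per kingdom pairing), global
#'   clustering coefficient, modularity `Q` (NA when edgeless), module count.
#' @export
network_summary <- function(network, partition = NULL) {
  g <- as_igraph(network)
  if (is.null(partition) && igraph::vcount(g) > 0)
    partition <- detect_modules(network)
  kg <- igraph::V(g)$kingdom
  el <- if (igraph::ecount(g) > 0) igraph::as_edgelist(g) else
    matrix(character(), 0, 2)
  ek <- if (nrow(el)) {
    k1 <- kg[match(el[, 1], igraph::V(g)$name)]
    k2 <- kg[match(el[, 2], igraph::V(g)$name)]
    pair <- paste(pmin(k1, k2), pmax(k1, k2), sep = "-")
    table(pair)
  } else table(character())
  list(n_nodes = igraph::vcount(g),
       n_edges = igraph::ecount(g),
       nodes_per_kingdom = table(kg),
       edges_per_kingdom_pair = ek,
       clustering_coefficient = igraph::transitivity(g, type = "global"),
       modularity = if (is.null(partition)) NA_real_ else partition$modularity,
       n_modules = if (is.null(partition)) NA_integer_ else
         length(partition$sizes))
}
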