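test_that("CLR rows sum to zero and uniform compositions map to zero", {
  b <- tiny_bundle()
  x <- clr_transform(b$counts)
  expect_lt(max(abs(rowSums(x))), 1e-9)
  u <- matrix(1L, 3, 4, dimnames = list(paste0("s", 1:3), paste0("t", 1:4)))
  expect_equal(unname(clr_transform(u, pseudocount = 0)),
               matrix(0, 3, 4), tolerance = 1e-12)
})

test_that("MB lasso path matches coordinate-descent and glmnet oracles", {
  set.seed(4)
  n <- 40
  x1 <- rnorm(n)
  x2 <- 0.9 * x1 + 0.3 * rnorm(n)
  x3 <- rnorm(n)
  X <- scale(cbind(x1, x2, x3))
  S <- crossprod(X) / (n - 1)
  S <- stats::cov2cor(S)
  lambdas <- exp(seq(log(0.9), log(0.9e-3), length.out = 25))
  for (j in 1:3) {
    beta_cpp <- lasso_path_node_cpp(S, j, lambdas, tol = 1e-12, maxit = 50000)
    Xs <- X / sqrt(n - 1) # scaling under which S = X'X / n
    for (m in c(1, 8, 15, 25)) {
      b_or <- cd_lasso_oracle(Xs[, -j, drop = FALSE] * sqrt(nrow(X)),
                              Xs[, j] * sqrt(nrow(X)), lambdas[m])
      expect_equal(unname(beta_cpp[-j, m]), b_or, tolerance = 1e-6)
    }
    # independent solver: glmnet on the same standardized problem
    g <- glmnet::glmnet(X[, -j, drop = FALSE] / sqrt(n - 1) * sqrt(n),
                        X[, j] / sqrt(n - 1) * sqrt(n),
                        lambda = lambdas, standardize = FALSE,
                        intercept = FALSE, thresh = 1e-14)
    expect_equal(unname(as.matrix(g$beta)), unname(beta_cpp[-j, ]),
                 tolerance = 1e-4, ignore_attr = TRUE)
  }
})

test_that("lambda at or above lambda_max gives an empty graph; sparsity is monotone", {
  set.seed(5)
  x <- matrix(rnorm(100 * 10), 100, 10,
              dimnames = list(paste0("s", 1:100), paste0("t", 1:10)))
  fit <- mb_neighborhood_selection(x, nlambda = 40)
  expect_equal(sum(fit$support[, 1]), 0)  # first lambda = lambda_max: empty
  expect_true(all(diff(fit$sparsity) >= 0))  # density grows as lambda shrinks
})

test_that("a perfectly correlated pair survives longest on the path", {
  set.seed(6)
  n <- 60
  a <- rnorm(n)
  x <- cbind(t1 = a, t2 = a + 0.01 * rnorm(n), t3 = rnorm(n), t4 = rnorm(n))
  rownames(x) <- paste0("s", 1:n)
  fit <- mb_neighborhood_selection(x, nlambda = 50)
  first_active <- apply(fit$support, 1, function(r) {
    w <- which(r)
    if (length(w)) min(w) else Inf
  })
  # pair (1,2) is the first entry in upper-triangle column-major order
  expect_equal(unname(which.min(first_active)), 1L)
})

test_that("StARS on pure noise selects a near-empty graph, deterministically", {
  set.seed(8)
  m <- matrix(rpois(40 * 30, 20), 40, 30,
              dimnames = list(paste0("s", 1:40), paste0("t", 1:30)))
  net1 <- stability_select(m, n_subsamples = 20, seed = 3)
  net2 <- stability_select(m, n_subsamples = 20, seed = 3)
  # near-empty: the refit at the instability point keeps a stray edge or two
  # per node at most, far below any planted-structure density
  dens <- igraph::ecount(net1$graph) / choose(30, 2)
  expect_lt(dens, 0.03)
  expect_identical(igraph::as_edgelist(net1$graph),
                   igraph::as_edgelist(net2$graph))
})

test_that("planted blocks give much denser within- than between-block edges", {
  b <- simulate_dataset(simulation_config(
    n_samples_per_cell = 18, n_bacteria = 60, n_fungi = 40,
    n_modules = 3, module_cohesion = 2.0,
    depth_bacteria = 5000, depth_fungi = 3000, seed = 7))
  net <- stability_select(b$counts, n_subsamples = 20, seed = 5)
  truth <- b$truth$modules
  el <- igraph::as_edgelist(net$graph)
  m1 <- truth[el[, 1]]
  m2 <- truth[el[, 2]]
  both <- !is.na(m1) & !is.na(m2)
  within <- sum(both & m1 == m2)
  between <- sum(both & m1 != m2)
  sizes <- table(truth)
  n_within_pairs <- sum(choose(sizes, 2))
  n_between_pairs <- choose(sum(sizes), 2) - n_within_pairs
  expect_gte((within / n_within_pairs) / max(between / n_between_pairs, 1e-9), 5)
})

test_that("greedy modularity separates two cliques with the hand-computed Q", {
  g <- igraph::disjoint_union(igraph::make_full_graph(5),
                              igraph::make_full_graph(5))
  igraph::V(g)$name <- paste0("v", 1:10)
  igraph::V(g)$kingdom <- rep(c("bacteria", "fungi"), each = 5)
  part <- detect_modules(g)
  expect_equal(length(part$sizes), 2L)
  expect_true(all(part$sizes == 5))
  # Q = sum_i (e_ii - a_i^2) = 2 * (0.5 - 0.25) = 0.5 for two equal cliques
  expect_equal(part$modularity, 0.5, tolerance = 1e-12)
  # detected partition never scores below the trivial one-module partition
  expect_gte(part$modularity, 0)
  s <- network_summary(g, part)
  expect_equal(s$n_modules, 2L)
  expect_equal(s$clustering_coefficient, 1)
})

test_that("edgeless networks yield singleton modules and NA modularity", {
  g <- igraph::make_empty_graph(4, directed = FALSE)
  igraph::V(g)$name <- paste0("v", 1:4)
  igraph::V(g)$kingdom <- "bacteria"
  part <- detect_modules(g)
  expect_equal(length(part$sizes), 4L)
  expect_true(is.na(part$modularity))
  expect_true(is.na(network_summary(g, part)$modularity))
})

test_that("centralities match closed forms on path, star and cycle graphs", {
  path <- igraph::make_graph(~ a - b, b - c)
  igraph::V(path)$kingdom <- "bacteria"
  cp <- centralities(path)
  expect_equal(cp$betweenness[cp$node == "b"], 1)
  expect_equal(cp$betweenness[cp$node == "a"], 0)
  star <- igraph::make_star(5, "undirected", center = 1)
  igraph::V(star)$name <- paste0("v", 1:5)
  igraph::V(star)$kingdom <- "fungi"
  cs <- centralities(star)
  expect_equal(max(cs$degree), 4)
  expect_equal(cs$eigenvector[which.max(cs$degree)], 1)  # scaled to max 1
  cyc <- igraph::make_ring(5)
  igraph::V(cyc)$name <- paste0("v", 1:5)
  igraph::V(cyc)$kingdom <- "bacteria"
  cc <- centralities(cyc)
  for (v in c("degree", "betweenness", "closeness", "eigenvector"))
    expect_lt(diff(range(cc[[v]])), 1e-9)
})

test_that("closeness is computed within connected components", {
  g <- igraph::disjoint_union(igraph::make_full_graph(3),
                              igraph::make_full_graph(2))
  igraph::V(g)$name <- paste0("v", 1:5)
  igraph::V(g)$kingdom <- "bacteria"
  cc <- centralities(g)
  expect_equal(cc$closeness, rep(1, 5))  # all distances 1 within components
})

test_that("KS comparison: identical inputs give statistic 0, disjoint give 1", {
  a <- data.frame(degree = c(1, 2, 3, 4), betweenness = c(0, 0.1, 0.2, 0.3),
                  closeness = 1:4 / 4, eigenvector = 1:4 / 4)
  same <- compare_centrality_distributions(a, a, n_bootstrap = 50, seed = 1)
  expect_true(all(same$statistic == 0))
  expect_true(all(same$p_value == 1))
  b <- a + 10
  diff_ <- compare_centrality_distributions(a, b, n_bootstrap = 50, seed = 1)
  expect_true(all(diff_$statistic == 1))
})

test_that("stability selection degenerates sanely at permissive threshold", {
  set.seed(9)
  m <- matrix(rpois(30 * 12, 15), 30, 12,
              dimnames = list(paste0("s", 1:30), paste0("t", 1:12)))
  net <- stability_select(m, n_subsamples = 2, instability_threshold = 1,
                          nlambda = 20, seed = 2)
  # threshold 1 admits every lambda: the densest path graph is selected
  expect_equal(net$selected_index, 20L)
})
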