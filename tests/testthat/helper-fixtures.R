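# Small shared fixtures, built in code.

tiny_bundle <- function(seed = 42L, ...) {
  simulate_dataset(simulation_config(
    n_samples_per_cell = 4L, n_bacteria = 30L, n_fungi = 20L,
    n_modules = 3L, depth_bacteria = 2000L, depth_fungi = 1000L,
    seed = seed, ...))
}

toy_counts <- function() {
  m <- matrix(c(10L, 5L, 0L,
                8L, 4L, 2L,
                12L, 0L, 6L,
                6L, 3L, 3L), nrow = 4, byrow = TRUE,
              dimnames = list(paste0("s", 1:4), paste0("t", 1:3)))
  m
}

toy_design <- function(n_per_cell = 3L) {
  cells <- expand.grid(diversity_level = c("Mono", "Two", "Multi"),
                       mycorrhizal_type = c("EcM", "AM"),
                       stringsAsFactors = FALSE)
  do.call(rbind, lapply(seq_len(nrow(cells)), function(i)
    data.frame(sample_id = sprintf("s_%s_%s_%d", cells$mycorrhizal_type[i],
                                   cells$diversity_level[i], seq_len(n_per_cell)),
               mycorrhizal_type = cells$mycorrhizal_type[i],
               diversity_level = cells$diversity_level[i],
               plot_id = "p1", stringsAsFactors = FALSE)))
}

# plain-R coordinate-descent lasso on standardized inputs:
# min 0.5/n ||y - Xb||^2 + lambda ||b||_1  (no intercept)
cd_lasso_oracle <- function(X, y, lambda, iters = 5000, tol = 1e-12) {
  p <- ncol(X)
  n <- nrow(X)
  b <- rep(0, p)
  for (it in seq_len(iters)) {
    b_old <- b
    for (j in seq_len(p)) {
      r <- y - X[, -j, drop = FALSE] %*% b[-j]
      z <- sum(X[, j] * r) / n
      d <- sum(X[, j]^2) / n
      b[j] <- sign(z) * max(abs(z) - lambda, 0) / d
    }
    if (max(abs(b - b_old)) < tol) break
  }
  b
}

# all permutations of 1..n as a list of integer vectors
combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  sub <- combinat_perms(n - 1)
  out <- list()
  for (s in sub) for (pos in 0:(n - 1)) {
    out[[length(out) + 1L]] <- append(s, n, after = pos)
  }
  out
}

# exact Benjamini-Hochberg step-up, written independently of p.adjust
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}
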