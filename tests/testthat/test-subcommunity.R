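test_that("the module functional product reproduces the worked 2x3 * 3x2 example", {
  mod_abund <- matrix(c(0.10, 0.19, 0.07,
                        0.02, 0.03, 0.06), 2, 3, byrow = TRUE,
                      dimnames = list(c("mod1", "mod2"), c("t1", "t2", "t3")))
  content <- matrix(c(1, 7,
                      2, 1,
                      4, 3), 3, 2, byrow = TRUE,
                    dimnames = list(c("t1", "t2", "t3"), c("e1", "e2")))
  fam <- module_functional_abundance(mod_abund, content)
  expected <- matrix(c(0.76, 1.10,
                       0.32, 0.35), 2, 2, byrow = TRUE,
                     dimnames = list(c("mod1", "mod2"), c("e1", "e2")))
  expect_equal(fam, expected, tolerance = 1e-12)
  # zero abundance row maps to a zero functional row
  z <- mod_abund
  z["mod2", ] <- 0
  expect_true(all(module_functional_abundance(z, content)["mod2", ] == 0))
  # identity content returns the abundances unchanged
  id <- diag(3)
  dimnames(id) <- list(c("t1", "t2", "t3"), c("t1", "t2", "t3"))
  expect_equal(unname(module_functional_abundance(mod_abund, id)),
               unname(mod_abund))
})

test_that("module functional abundances conserve the community-level product", {
  b <- tiny_bundle()
  rel <- relative_abundance(b$counts)
  memb <- b$truth$modules
  memb[is.na(memb)] <- max(memb, na.rm = TRUE) + 1L  # background as own module
  part <- structure(list(membership = memb, sizes = table(memb),
                         modularity = NA_real_), class = "module_partition")
  ma <- module_abundance_matrix(rel, part)
  # rows of ma sum (over modules) to the community mean relative abundances
  expect_equal(colSums(ma), colMeans(rel), tolerance = 1e-12)
  fam_mod <- module_functional_abundance(ma, b$ec_content)
  fam_comm <- community_functional_abundance(rel, b$ec_content)
  expect_equal(colSums(fam_mod), colMeans(fam_comm), tolerance = 1e-9)
})

test_that("PCoA reproduces distances, orders axes, handles duplicates", {
  set.seed(18)
  fam <- matrix(rexp(6 * 8), 6, 8,
                dimnames = list(paste0("m", 1:6), paste0("e", 1:8)))
  ord <- pcoa_modules(fam)
  ev <- ord$eigenvalues
  expect_true(all(diff(ev) <= 1e-9))  # sorted decreasing
  # Gower property: distances among coordinates reproduce the input
  # distances when using all positive axes (approximately, since negative
  # eigenvalues are excluded)
  rec <- as.matrix(dist(ord$coordinates))
  orig <- as.matrix(ord$distance)
  expect_lt(max(abs(rec - orig)), 0.2 * max(orig))
  # duplicated module lands on coincident coordinates
  fam2 <- rbind(fam, dup = fam[1, ])
  ord2 <- pcoa_modules(fam2)
  expect_lt(max(abs(ord2$coordinates["m1", ] - ord2$coordinates["dup", ])),
            1e-8)
  expect_error(pcoa_modules(fam[1:2, ]), "at least 3")
})

test_that("three equidistant modules give equal leading eigenvalues", {
  d <- matrix(0.5, 3, 3)
  diag(d) <- 0
  dimnames(d) <- list(paste0("m", 1:3), paste0("m", 1:3))
  ord <- ape::pcoa(as.dist(d))
  ev <- ord$values$Eigenvalues
  expect_equal(ev[1], ev[2], tolerance = 1e-9)
})

test_that("envfit recovers an axis-aligned enzyme exactly and matches OLS r2", {
  set.seed(19)
  fam <- matrix(rexp(5 * 6), 5, 6,
                dimnames = list(paste0("m", 1:5), paste0("e", 1:6)))
  ord <- pcoa_modules(fam)
  coords <- ord$coordinates[, 1:2]
  cat6 <- ec_catalog(data.frame(ec = sprintf("1.1.1.%d", 1:6),
                                name = letters[1:6],
                                cycles = rep(c("C", "N", "P"), 2)))
  fam_t <- fam
  colnames(fam_t) <- cat6$ec
  fam_t[, 1] <- coords[, 1]  # enzyme identical to axis 1
  ef <- envfit_enzymes(ord, fam_t, cat6, n_perm = 199, alpha = 0.05, seed = 3)
  v1 <- ef$vectors[ef$vectors$ec == cat6$ec[1], ]
  expect_equal(v1$r2, 1, tolerance = 1e-9)
  expect_equal(abs(v1$axis1), 1, tolerance = 1e-6)
  expect_lt(abs(v1$axis2), 1e-6)
  # r2 equals brute-force OLS R^2 for every enzyme
  for (j in seq_len(ncol(fam_t))) {
    r2 <- summary(lm(fam_t[, j] ~ coords[, 1] + coords[, 2]))$r.squared
    expect_equal(ef$vectors$r2[ef$vectors$ec == colnames(fam_t)[j]], r2,
                 tolerance = 1e-8)
  }
  # constant enzyme vector is skipped with a warning
  fam_c <- fam_t
  fam_c[, 2] <- 1
  expect_warning(envfit_enzymes(ord, fam_c, cat6, n_perm = 99, seed = 1),
                 "constant")
})

test_that("pairwise module tests: identical profiles null, dominated profiles significant", {
  cat12 <- ec_catalog(data.frame(ec = sprintf("1.2.3.%d", 1:12),
                                 name = letters[1:12],
                                 cycles = rep(c("C", "N", "P"), 4)))
  base <- matrix(rexp(12, 0.5) + 0.5, 1, 12,
                 dimnames = list("1", cat12$ec))
  same <- pairwise_module_tests(base, base, cat12, combos = "CNP")
  expect_equal(same$p, 1)
  expect_equal(same$direction, "none")
  dbl <- pairwise_module_tests(base, 2 * base, cat12, combos = "CNP")
  expect_lt(dbl$p, 0.01)
  expect_equal(dbl$direction, "B")
})

test_that("signed-rank p matches exhaustive enumeration on 8 paired values", {
  set.seed(20)
  x <- rexp(8) + 0.1
  y <- x + c(0.5, -0.2, 0.3, 0.4, -0.1, 0.2, 0.6, -0.3)
  d <- y - x
  # exact null: all 2^8 sign assignments of |d| ranks
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), 8))
  v_all <- as.matrix(signs) %*% r
  p_exact <- min(2 * min(mean(v_all <= v_obs), mean(v_all >= v_obs)), 1)
  got <- wilcox.test(y, x, paired = TRUE)$p.value
  expect_equal(got, p_exact, tolerance = 1e-12)
})

test_that("BH-adjusted p-values are monotone in the raw p-values", {
  set.seed(21)
  p <- runif(30)
  adj <- p.adjust(p, "BH")
  o <- order(p)
  expect_true(all(diff(adj[o]) >= -1e-12))
})
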