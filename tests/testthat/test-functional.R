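test_that("catalog filtering restricts columns, counts cycles, applies NSTI", {
  cat57 <- nutrient_catalog()
  expect_equal(nrow(cat57), 57L)
  content <- matrix(1, 3, 3,
                    dimnames = list(c("a1", "a2", "a3"),
                                    c(cat57$ec[1], cat57$ec[20], "9.9.9.9")))
  out <- filter_catalog(content, cat57)
  expect_setequal(colnames(out), c(cat57$ec[1], cat57$ec[20]))
  rep <- attr(out, "report")
  expect_equal(rep$n_ecs_total, 2L)
  expect_gte(sum(rep$per_cycle), rep$n_ecs_total)  # multi-cycle counted per cycle
  # NSTI exclusion
  out2 <- filter_catalog(content, cat57, nsti = c(a1 = 0.1, a2 = 3, a3 = 0.2))
  expect_false("a2" %in% rownames(out2))
  expect_identical(attr(out2, "report")$nsti_removed, "a2")
  # disjoint catalog errors
  bad <- matrix(1, 1, 1, dimnames = list("a1", "9.9.9.9"))
  expect_error(filter_catalog(bad, cat57), "no overlap")
})

test_that("community functional abundance is the matrix product, linear in both inputs", {
  rel <- matrix(c(0.2, 0.8,
                  0.5, 0.5), 2, 2, byrow = TRUE,
                dimnames = list(c("s1", "s2"), c("t1", "t2")))
  content <- matrix(c(1, 7,
                      2, 1), 2, 2, byrow = TRUE,
                    dimnames = list(c("t1", "t2"), c("e1", "e2")))
  fam <- community_functional_abundance(rel, content)
  hand <- rel %*% content
  expect_equal(fam, hand, tolerance = 1e-15)
  # single taxon at relative abundance 1 with 3 copies -> abundance 3
  one <- community_functional_abundance(
    matrix(1, 1, 1, dimnames = list("s", "t1")),
    matrix(3, 1, 1, dimnames = list("t1", "e1")))
  expect_equal(as.numeric(one), 3)
  # linearity (superposition) in both arguments
  expect_equal(community_functional_abundance(rel, 2 * content), 2 * fam)
  rel2 <- rel
  rel2[1, ] <- rel2[1, ] * 0.5
  expect_equal(community_functional_abundance(rel + rel2, content),
               fam + community_functional_abundance(rel2, content),
               tolerance = 1e-12)
  expect_error(community_functional_abundance(
    rel, matrix(1, 1, 1, dimnames = list("x", "e1"))), "missing")
})

test_that("combination slices follow union set logic and monotonicity", {
  cat3 <- ec_catalog(data.frame(ec = c("1.1.1.1", "2.2.2.2", "3.3.3.3"),
                                name = c("a", "b", "c"),
                                cycles = c("C", "N", "C,N")))
  fam <- matrix(1, 2, 3, dimnames = list(c("u1", "u2"), cat3$ec))
  expect_setequal(colnames(slice_combination(fam, "C", cat3)),
                  c("1.1.1.1", "3.3.3.3"))
  expect_identical(colnames(slice_combination(fam, "CNP", cat3)),
                   colnames(fam))   # CNP = identity
  cn <- colnames(slice_combination(fam, "CN", cat3))
  expect_true(all(colnames(slice_combination(fam, "C", cat3)) %in% cn))
  expect_true(all(colnames(slice_combination(fam, "N", cat3)) %in% cn))
  expect_warning(slice_combination(fam[, 1, drop = FALSE], "P", cat3), "empty")
})

test_that("Shannon diversity hits closed forms and the worked module row", {
  fam <- rbind(uniform = rep(1, 5), single = c(1, 0, 0, 0, 0))
  colnames(fam) <- paste0("e", 1:5)
  H <- shannon_functional_diversity(fam)
  expect_equal(unname(H["uniform"]), log(5), tolerance = 1e-12)
  expect_equal(unname(H["single"]), 0)
  # hand-computed entropy of the first worked-example module row (0.76, 1.10)
  row <- matrix(c(0.76, 1.10), 1, dimnames = list("mod1", c("e1", "e2")))
  p <- c(0.76, 1.10) / 1.86
  expect_equal(unname(shannon_functional_diversity(row)),
               -sum(p * log(p)), tolerance = 1e-12)
  expect_error(shannon_functional_diversity(rbind(z = c(0, 0))), "zero")
})

test_that("diversity tests are null on identical groups and BH matches the oracle", {
  des <- toy_design(6L)
  # identical groups: the same six H values replicated in every design cell
  H <- setNames(rep(seq(1.0, 2.0, length.out = 6), times = 6), des$sample_id)
  res <- diversity_tests(H, des)
  expect_true(all(res$anova$F < 1e-9))
  expect_true(all(res$anova$p > 0.99))
  expect_true(all(res$posthoc$p_adj > 0.99))
  # BH step-up equals an independent implementation on random p-vectors
  set.seed(15)
  for (i in 1:10) {
    p <- runif(sample(3:20, 1))
    expect_equal(p.adjust(p, "BH"), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("a mycorrhizal shift planted only in Mono is recovered by the post hoc tests", {
  des <- toy_design(18L)
  set.seed(16)
  hits <- 0L
  for (rep in 1:10) {
    H <- rnorm(nrow(des), 2, 0.3)
    shift <- des$diversity_level == "Mono" & des$mycorrhizal_type == "EcM"
    H[shift] <- H[shift] + 2 * 0.3   # 2 sd effect
    names(H) <- des$sample_id
    res <- diversity_tests(H, des)
    ph <- res$posthoc
    if (ph$p_adj[ph$diversity_level == "Mono"] <= 0.01 &&
        all(ph$p_adj[ph$diversity_level != "Mono"] > 0.01)) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("PERMANOVA matches exhaustive enumeration on a two-group toy", {
  set.seed(17)
  n <- 6
  fam <- matrix(rexp(n * 4), n, 4,
                dimnames = list(paste0("s", 1:n), paste0("e", 1:4)))
  g <- rep(c("A", "B"), each = 3)
  d <- vegan::vegdist(fam, "bray")
  # brute force: pseudo-F from the Gower-centred inner product, all 20
  # group assignments
  dm <- as.matrix(d)^2
  G <- -0.5 * scale(t(scale(t(dm), scale = FALSE)), scale = FALSE)
  f_stat <- function(lab) {
    sst <- sum(diag(G))
    H <- model.matrix(~ factor(lab))
    P <- H %*% solve(crossprod(H)) %*% t(H)
    ssb <- sum(diag(P %*% G))
    (ssb / 1) / ((sst - ssb) / (n - 2))
  }
  f_obs <- f_stat(g)
  combos <- combn(n, 3)
  f_all <- apply(combos, 2, function(idx) {
    lab <- rep("B", n)
    lab[idx] <- "A"
    f_stat(lab)
  })
  p_exact <- mean(f_all >= f_obs - 1e-12)
  # package route: adonis2 under the hood with all row permutations
  des <- data.frame(sample_id = rownames(fam),
                    mycorrhizal_type = g,
                    diversity_level = "Mono", plot_id = "p")
  perm_mat <- do.call(rbind, combinat_perms(n))
  res <- vegan::adonis2(d ~ factor(g), permutations = perm_mat[-1, ])
  expect_equal(res$F[1], f_obs, tolerance = 1e-10)
  expect_equal(res$`Pr(>F)`[1], p_exact, tolerance = 1e-10)
})

test_that("two-factor PERMANOVA partitions variance to 1 and controls resolution", {
  b <- tiny_bundle()
  rel <- relative_abundance(b$counts)
  fam <- community_functional_abundance(rel, b$ec_content)
  res <- permanova_func(fam, b$design, n_perm = 99, seed = 1)
  expect_equal(sum(res$r2[res$term != "Total"]), 1, tolerance = 1e-9)
  expect_true(all(res$r2 >= 0 & res$r2 <= 1))
  expect_true(all(res$p[!is.na(res$p)] >= 1 / 100))
})

test_that("combination-wise PERMANOVA adjusts per term across the seven slices", {
  b <- tiny_bundle()
  rel <- relative_abundance(b$counts)
  fam <- community_functional_abundance(rel, b$ec_content)
  res <- permanova_combinations(fam, b$catalog, b$design, n_perm = 99, seed = 2)
  expect_setequal(unique(res$combo), nutrient_combinations())
  for (trm in c("M", "L", "M:L")) {
    sub <- res[res$term == trm, ]
    expect_equal(sub$p_adj, p.adjust(sub$p, "BH"))
  }
})
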