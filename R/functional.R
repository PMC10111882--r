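#' Filter predicted EC content to a nutrient-cycling catalog
#'
#' Restricts the taxon x EC content table to catalog ECs, optionally removes
#' taxa whose NSTI exceeds a reliability cutoff, and reports per-kingdom EC
#' counts with the per-cycle breakdown of the deduplicated union.
#'
#' @param ec_content taxon x EC matrix of predicted gene-family copy numbers.
#' @param catalog an `ec_catalog`.
#' @param nsti optional named NSTI vector per taxon.
#' @param nsti_max NSTI cutoff (default 2, the conventional default); taxa
#'   above it are removed.
#' @param kingdom optional named kingdom vector for the per-kingdom report.
#' @return filtered matrix with attribute `"report"`: list with
#'   `n_ecs_total`, `per_kingdom`, `per_cycle`, `nsti_removed`.
#' @export
filter_catalog <- function(ec_content, catalog, nsti = NULL, nsti_max = 2,
                           kingdom = NULL) {
  stopifnot(inherits(catalog, "ec_catalog"))
  shared <- intersect(colnames(ec_content), catalog$ec)
  if (!length(shared))
    stop("no overlap between EC content columns and the catalog")
  out <- ec_content[, shared, drop = FALSE]
  removed <- character()
  if (!is.null(nsti)) {
    high <- names(nsti)[nsti > nsti_max]
    removed <- intersect(rownames(out), high)
    if (length(removed)) out <- out[setdiff(rownames(out), removed), , drop = FALSE]
  }
  present <- colnames(out)[colSums(out) > 0]
  cyc <- catalog_cycles(catalog)[present]
  per_cycle <- vapply(c("C", "N", "P"), function(l)
    sum(vapply(cyc, function(x) l %in% x, logical(1))), integer(1))
  per_kingdom <- if (!is.null(kingdom)) {
    kg <- kingdom[rownames(out)]
    vapply(split(rownames(out), kg), function(tx)
      sum(colSums(out[tx, , drop = FALSE]) > 0), integer(1))
  } else NULL
  attr(out, "report") <- list(n_ecs_total = length(present),
                              per_kingdom = per_kingdom,
                              per_cycle = per_cycle,
                              nsti_removed = removed)
  out
}

#' Community-level functional abundance
#'
#' Propagates predicted EC gene-family content to the community:
#' `value(sample, ec) = sum_taxa rel_abund(sample, taxon) * content(taxon, ec)`,
#' a plain matrix product summing fungal and bacterial contributions.
#'
#' @param rel_abund sample x taxon relative abundances.
#' @param ec_content taxon x EC content matrix (rows must cover the taxa).
#' @return sample x EC functional abundance matrix.
#' @export
community_functional_abundance <- function(rel_abund, ec_content) {
  taxa <- colnames(rel_abund)
  miss <- setdiff(taxa, rownames(ec_content))
  if (length(miss))
    stop("taxa missing from EC content: ", paste(utils::head(miss, 5), collapse = ", "),
         if (length(miss) > 5) " ...")
  rel_abund %*% ec_content[taxa, , drop = FALSE]
}

#' Slice a functional-abundance matrix by nutrient combination
#'
#' Keeps the EC columns whose cycle annotation intersects the combination
#' (union rule; `CNP` is the identity slice).  Values are never changed,
#' only columns dropped.
#'
#' @param fam unit x EC functional-abundance matrix.
#' @param combo one of `"C","N","P","CN","CP","NP","CNP"`.
#' @param catalog an `ec_catalog` covering the columns.
#' @return the sliced matrix with attribute `"combo"`.
#' @export
slice_combination <- function(fam, combo, catalog) {
  ecs <- intersect(colnames(fam), combo_ecs(catalog, combo))
  if (!length(ecs)) warning("empty slice for combination ", combo)
  out <- fam[, ecs, drop = FALSE]
  attr(out, "combo") <- combo
  out
}

#' Shannon diversity of functional abundances
#'
#' `H = -sum p_e log p_e` per unit row, with `p_e` the row-normalised
#' abundance (natural log).
#'
#' @param fam unit x EC functional-abundance matrix.
#' @return named numeric vector of H values.
#' @export
shannon_functional_diversity <- function(fam) {
  rs <- rowSums(fam)
  if (any(rs == 0))
    stop("zero functional abundance row(s): ",
         paste(rownames(fam)[rs == 0], collapse = ", "))
  vegan::diversity(fam / rs, index = "shannon")
}

#' Two-way ANOVA and per-level post hoc tests of functional diversity
#'
#' Fits `H ~ mycorrhizal_type * diversity_level` with type-II sums of
#' squares, then runs a Welch t test of EcM vs AM within each diversity
#' level; the post hoc p-values are BH-adjusted within the family.
#' Stars follow the thresholds 0.01 and 0.001.
#'
#' @param H named vector of Shannon values (names = sample ids).
#' @param design design table.
#' @return list: `anova` (data.frame of factor, df, F, p), `posthoc`
#'   (data.frame of diversity level, t, p, p_adj, stars).
#' @export
diversity_tests <- function(H, design) {
  design <- check_design(design)
  df <- merge(data.frame(sample_id = names(H), H = unname(H)),
              design, by = "sample_id")
  df$mycorrhizal_type <- factor(df$mycorrhizal_type)
  df$diversity_level <- factor(df$diversity_level)
  if (nlevels(df$mycorrhizal_type) < 2 || nlevels(df$diversity_level) < 2)
    stop("need at least two levels per factor")
  cellm <- table(df$mycorrhizal_type, df$diversity_level)
  if (any(cellm < 2)) stop("a design cell has fewer than 2 samples")
  fit <- stats::aov(H ~ mycorrhizal_type * diversity_level, data = df)
  a2 <- car::Anova(fit, type = 2)
  an <- data.frame(factor = rownames(a2)[seq_len(3)],
                   df = a2$Df[seq_len(3)], F = a2$`F value`[seq_len(3)],
                   p = a2$`Pr(>F)`[seq_len(3)], stringsAsFactors = FALSE)
  ph <- do.call(rbind, lapply(levels(df$diversity_level), function(lv) {
    sub <- df[df$diversity_level == lv, ]
    tt <- stats::t.test(H ~ mycorrhizal_type, data = sub)
    data.frame(diversity_level = lv, t = unname(tt$statistic),
               p = tt$p.value, stringsAsFactors = FALSE)
  }))
  ph$p_adj <- stats::p.adjust(ph$p, "BH")
  ph$stars <- ifelse(ph$p_adj <= 0.001, "***",
                     ifelse(ph$p_adj <= 0.01, "**", ""))
  list(anova = an, posthoc = ph)
}

#' Two-factor PERMANOVA of a functional-abundance slice
#'
#' Bray-Curtis distance PERMANOVA with sequential (type-I) terms
#' mycorrhizal type, diversity level and their interaction, free row
#' permutation (`vegan::adonis2`, `by = "terms"`).
#'
#' @param fam sample x EC functional-abundance matrix.
#' @param design design table for the samples.
#' @param n_perm permutations (default 999).
#' @param seed integer seed.
#' @return data.frame: term, df, pseudo_f, r2, p (plus Residual/Total rows
#'   with NA statistics).
#' @export
permanova_func <- function(fam, design, n_perm = 999, seed = 1L) {
  design <- check_design(design)
  design <- design[match(rownames(fam), design$sample_id), ]
  dat <- data.frame(M = factor(design$mycorrhizal_type),
                    L = factor(design$diversity_level))
  if (any(table(dat$M, dat$L) < 2)) stop("a design cell has fewer than 2 samples")
  d <- vegan::vegdist(fam, method = "bray")
  if (any(!is.finite(as.vector(d)))) stop("degenerate distance matrix")
  set.seed(seed)
  res <- vegan::adonis2(d ~ M * L, data = dat, permutations = n_perm,
                        by = "terms")
  data.frame(term = rownames(res), df = res$Df, pseudo_f = res$F,
             r2 = res$R2, p = res$`Pr(>F)`, stringsAsFactors = FALSE)
}

#' PERMANOVA across all seven nutrient combinations with BH adjustment
#'
#' Runs [permanova_func()] on each combination slice and BH-adjusts the
#' p-values per term across the seven combinations (one family per factor).
#'
#' @param fam full sample x EC functional-abundance matrix.
#' @param catalog an `ec_catalog`.
#' @param design design table.
#' @param n_perm permutations.
#' @param seed integer seed.
#' @return data.frame: combo, term, df, pseudo_f, r2, p, p_adj.
#' @export
permanova_combinations <- function(fam, catalog, design, n_perm = 999,
                                   seed = 1L) {
  res <- do.call(rbind, lapply(nutrient_combinations(), function(cmb) {
    sl <- slice_combination(fam, cmb, catalog)
    out <- permanova_func(sl, design, n_perm = n_perm,
                          seed = derive_seed(seed, paste0("perm", cmb)))
    out$combo <- cmb
    out
  }))
  res$p_adj <- NA_real_
  for (trm in unique(res$term)) {
    sel <- res$term == trm & !is.na(res$p)
    res$p_adj[sel] <- stats::p.adjust(res$p[sel], "BH")
  }
  res[, c("combo", "term", "df", "pseudo_f", "r2", "p", "p_adj")]
}
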