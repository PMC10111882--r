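#' Module x taxon mean relative-abundance matrix
#'
#' For each module of a partition, the mean relative abundance of each
#' member taxon across the network's samples; zero for non-members.
#'
#' @param rel_abund sample x taxon relative abundances.
#' @param partition a `module_partition`.
#' @param modules optional subset of module ids (default: all).
#' @return module x taxon matrix (rownames are module ids as character).
#' @export
module_abundance_matrix <- function(rel_abund, partition, modules = NULL) {
  stopifnot(inherits(partition, "module_partition"))
  ids <- sort(unique(partition$membership))
  if (!is.null(modules)) ids <- intersect(ids, as.integer(modules))
  out <- matrix(0, length(ids), ncol(rel_abund),
                dimnames = list(as.character(ids), colnames(rel_abund)))
  for (i in seq_along(ids)) {
    members <- names(partition$membership)[partition$membership == ids[i]]
    members <- intersect(members, colnames(rel_abund))
    if (length(members))
      out[i, members] <- colMeans(rel_abund[, members, drop = FALSE])
  }
  out
}

#' Module-level functional abundance (mean-abundance x EC-content product)
#'
#' The module x EC functional-abundance matrix is the plain matrix product
#' of the module x taxon mean relative abundances with the taxon x EC
#' predicted gene-family content:
#' `value(module, ec) = sum_t mod_abund(module, t) * content(t, ec)`.
#'
#' @param mod_abund module x taxon mean relative-abundance matrix.
#' @param ec_content taxon x EC content matrix covering the taxa.
#' @return module x EC functional-abundance matrix.
#' @export
module_functional_abundance <- function(mod_abund, ec_content) {
  taxa <- colnames(mod_abund)
  miss <- setdiff(taxa, rownames(ec_content))
  if (length(miss))
    stop("taxa missing from EC content: ",
         paste(utils::head(miss, 5), collapse = ", "),
         if (length(miss) > 5) " ...")
  mod_abund %*% ec_content[taxa, , drop = FALSE]
}

#' PCoA ordination of module functional abundances
#'
#' Classical metric scaling (`ape::pcoa`) of the Bray-Curtis distances among
#' module functional-abundance profiles.  Axes are ordered by eigenvalue;
#' negative eigenvalues are reported and their axes excluded from downstream
#' vector fitting.
#'
#' @param fam module x EC functional-abundance matrix (>= 3 modules).
#' @param distance dissimilarity index (default `"bray"`).
#' @return list: `coordinates` (modules x positive-eigenvalue axes),
#'   `eigenvalues` (all), `distance` (the dissimilarity object).
#' @export
pcoa_modules <- function(fam, distance = "bray") {
  if (nrow(fam) < 3) stop("need at least 3 modules for ordination")
  d <- vegan::vegdist(fam, method = distance)
  ord <- ape::pcoa(d)
  ev <- ord$values$Eigenvalues
  pos <- which(ev > sqrt(.Machine$double.eps) * max(abs(ev)))
  coords <- ord$vectors[, pos, drop = FALSE]
  rownames(coords) <- rownames(fam)
  list(coordinates = coords, eigenvalues = ev, distance = d)
}

#' Fit enzyme vectors onto a module ordination
#'
#' Least-squares fit of each enzyme's abundance across modules onto the
#' first two ordination axes (`vegan::envfit`), with permutation p-values.
#' Constant enzyme vectors are skipped with a warning.  Enzymes with
#' `p < alpha` form the significant set, reported with per-cycle counts.
#'
#' @param ord result of [pcoa_modules()].
#' @param fam module x EC functional-abundance matrix (same modules).
#' @param catalog an `ec_catalog` (for the per-cycle counts).
#' @param n_perm permutations (default 999).
#' @param alpha significance threshold (default 0.01).
#' @param seed integer seed.
#' @return list: `vectors` (data.frame ec, axis1, axis2, r2, p,
#'   significant), `significant_ecs`, `per_cycle_counts`.
#' @export
envfit_enzymes <- function(ord, fam, catalog, n_perm = 999, alpha = 0.01,
                           seed = 1L) {
  coords <- ord$coordinates[, seq_len(min(2, ncol(ord$coordinates))),
                            drop = FALSE]
  if (ncol(coords) < 2) stop("need two positive-eigenvalue axes")
  env <- as.data.frame(fam[rownames(coords), , drop = FALSE])
  keep <- vapply(env, function(x) stats::sd(x) > 0, logical(1))
  if (any(!keep))
    warning("skipping constant enzyme vector(s): ",
            paste(names(env)[!keep], collapse = ", "))
  env <- env[, keep, drop = FALSE]
  if (!ncol(env)) stop("no non-constant enzyme vectors")
  set.seed(seed)
  ef <- vegan::envfit(coords, env, permutations = n_perm)
  arr <- ef$vectors$arrows
  vectors <- data.frame(ec = rownames(arr),
                        axis1 = arr[, 1], axis2 = arr[, 2],
                        r2 = ef$vectors$r, p = ef$vectors$pvals,
                        stringsAsFactors = FALSE)
  vectors$significant <- vectors$p < alpha
  sig <- vectors$ec[vectors$significant]
  cyc <- catalog_cycles(catalog)[sig]
  per_cycle <- vapply(c("C", "N", "P"), function(l)
    sum(vapply(cyc, function(x) l %in% x, logical(1))), integer(1))
  list(vectors = vectors, significant_ecs = sig,
       per_cycle_counts = per_cycle)
}

#' Pairwise module comparisons of functional abundances
#'
#' For each (EcM module, AM module) pair within a diversity level and each
#' nutrient combination, a paired Wilcoxon signed-rank test across the
#' shared EC columns of the two modules' functional-abundance vectors
#' (`paired = FALSE` switches to the rank-sum variant).  P-values are
#' BH-adjusted across all pairs x combinations; direction is the module with
#' the larger median.  Fewer than 6 paired ECs triggers a warning (the exact
#' small-sample null is used automatically).
#'
#' @param fam_a,fam_b module x EC functional-abundance matrices for the two
#'   networks (e.g. EcM and AM at one diversity level).
#' @param catalog an `ec_catalog`.
#' @param combos combinations to test (default all seven).
#' @param alpha significance threshold on adjusted p (default 0.01).
#' @param paired use the signed-rank (paired over ECs) test; default TRUE.
#' @return data.frame: module_a, module_b, combo, n_ecs, statistic, p,
#'   p_adj, direction (`"A"`/`"B"`/`"none"`), stars.
#' @export
pairwise_module_tests <- function(fam_a, fam_b, catalog,
                                  combos = nutrient_combinations(),
                                  alpha = 0.01, paired = TRUE) {
  rows <- list()
  for (cmb in combos) {
    sa <- slice_combination(fam_a, cmb, catalog)
    sb <- slice_combination(fam_b, cmb, catalog)
    shared <- intersect(colnames(sa), colnames(sb))
    for (ma in rownames(sa)) for (mb in rownames(sb)) {
      x <- sa[ma, shared]
      y <- sb[mb, shared]
      if (all(x == 0) && all(y == 0)) next
      if (length(shared) < 6)
        warning("fewer than 6 paired ECs for modules ", ma, "/", mb,
                " in ", cmb, "; exact small-sample test used")
      wt <- if (all(x == y)) list(statistic = c(V = 0), p.value = 1)
      else suppressWarnings(
        if (paired) stats::wilcox.test(x, y, paired = TRUE)
        else stats::wilcox.test(x, y))
      rows[[length(rows) + 1L]] <- data.frame(
        module_a = ma, module_b = mb, combo = cmb, n_ecs = length(shared),
        statistic = unname(wt$statistic), p = wt$p.value,
        direction = if (stats::median(x) > stats::median(y)) "A"
                    else if (stats::median(x) < stats::median(y)) "B"
                    else "none",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(data.frame())
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, "BH")
  out$stars <- ifelse(out$p_adj <= 0.001, "***",
                      ifelse(out$p_adj <= alpha, "**", ""))
  out
}
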