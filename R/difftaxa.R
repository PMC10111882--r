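#' Per-ASV functional-abundance vectors
#'
#' For each ASV and sample, the relative abundance multiplied by the ASV's
#' total predicted EC copy number over the chosen nutrient-combination slice.
#'
#' @param rel_abund sample x ASV relative abundances.
#' @param ec_content ASV x EC content matrix.
#' @param catalog an `ec_catalog`.
#' @param combo nutrient combination (default `"CNP"`).
#' @return sample x ASV matrix of functional values, attribute `"combo"`.
#' @export
asv_functional_vectors <- function(rel_abund, ec_content, catalog,
                                   combo = "CNP") {
  taxa <- colnames(rel_abund)
  miss <- setdiff(taxa, rownames(ec_content))
  if (length(miss))
    stop("taxa missing from EC content: ",
         paste(utils::head(miss, 5), collapse = ", "),
         if (length(miss) > 5) " ...")
  ecs <- intersect(colnames(ec_content), combo_ecs(catalog, combo))
  total <- rowSums(ec_content[taxa, ecs, drop = FALSE])
  out <- sweep(rel_abund, 2, total[taxa], "*")
  attr(out, "combo") <- combo
  out
}

#' Differentially abundant ASVs between paired modules of two networks
#'
#' For each previously significant (module A, module B) pair, every ASV
#' present in either module is tested by a two-sample Wilcoxon rank-sum test
#' between the two networks' per-sample functional values, BH-adjusted
#' within the pair (or jointly across all pairs with
#' `bh_scope = "joint"`).  An ASV absent from both modules is skipped.
#'
#' @param vec_a,vec_b sample x ASV functional-value matrices for the two
#'   networks (see [asv_functional_vectors()]).
#' @param partition_a,partition_b `module_partition`s of the two networks.
#' @param pairs data.frame with columns `module_a`, `module_b`.
#' @param alpha adjusted-p significance threshold (default 0.01).
#' @param bh_scope `"per_pair"` (default) or `"joint"`.
#' @return list: `tests` (asv, module_a, module_b, p, p_adj, direction),
#'   `significant` (unique significant ASV ids across pairs).
#' @export
differential_asvs <- function(vec_a, vec_b, partition_a, partition_b, pairs,
                              alpha = 0.01,
                              bh_scope = c("per_pair", "joint")) {
  bh_scope <- match.arg(bh_scope)
  stopifnot(inherits(partition_a, "module_partition"),
            inherits(partition_b, "module_partition"))
  res <- list()
  for (i in seq_len(nrow(pairs))) {
    ma <- as.integer(pairs$module_a[i])
    mb <- as.integer(pairs$module_b[i])
    mem_a <- names(partition_a$membership)[partition_a$membership == ma]
    mem_b <- names(partition_b$membership)[partition_b$membership == mb]
    asvs <- union(mem_a, mem_b)
    asvs <- asvs[asvs %in% colnames(vec_a) | asvs %in% colnames(vec_b)]
    if (!length(asvs)) next
    p <- vapply(asvs, function(a) {
      xa <- if (a %in% colnames(vec_a)) vec_a[, a] else rep(0, nrow(vec_a))
      xb <- if (a %in% colnames(vec_b)) vec_b[, a] else rep(0, nrow(vec_b))
      if (all(xa == 0) && all(xb == 0)) return(NA_real_)
      suppressWarnings(stats::wilcox.test(xa, xb)$p.value)
    }, numeric(1))
    keep <- !is.na(p)
    if (!any(keep)) next
    med_a <- vapply(asvs, function(a)
      if (a %in% colnames(vec_a)) stats::median(vec_a[, a]) else 0, numeric(1))
    med_b <- vapply(asvs, function(a)
      if (a %in% colnames(vec_b)) stats::median(vec_b[, a]) else 0, numeric(1))
    df <- data.frame(asv = asvs[keep], module_a = ma, module_b = mb,
                     p = p[keep],
                     direction = ifelse(med_a[keep] > med_b[keep], "A",
                                        ifelse(med_a[keep] < med_b[keep],
                                               "B", "none")),
                     stringsAsFactors = FALSE)
    if (bh_scope == "per_pair") df$p_adj <- stats::p.adjust(df$p, "BH")
    res[[length(res) + 1L]] <- df
  }
  if (!length(res))
    return(list(tests = data.frame(), significant = character()))
  tests <- do.call(rbind, res)
  if (bh_scope == "joint") tests$p_adj <- stats::p.adjust(tests$p, "BH")
  list(tests = tests,
       significant = sort(unique(tests$asv[tests$p_adj <= alpha])))
}

#' Aggregate significant ASVs to class-level contributions
#'
#' Per nutrient combination, sums the mean functional abundance of the
#' significant ASVs by taxonomic class and divides by the total community
#' functional abundance of that combination.  The top two classes per
#' kingdom (ties broken lexicographically by class name) are flagged and
#' their summed percentage reported.
#'
#' @param sig_asvs character vector of significant ASV ids.
#' @param rel_abund sample x ASV relative abundances of the community.
#' @param ec_content ASV x EC content matrix.
#' @param taxonomy taxonomy table with `asv`, `kingdom`, `class`.
#' @param catalog an `ec_catalog`.
#' @param combos combinations to aggregate (default all seven).
#' @return data.frame of class `class_contribution`: combo, class, kingdom,
#'   proportion, top_two; attribute `"top_summary"` gives the summed top-two
#'   percentage per combo.
#' @export
aggregate_to_class <- function(sig_asvs, rel_abund, ec_content, taxonomy,
                               catalog, combos = nutrient_combinations()) {
  if (!length(sig_asvs)) {
    out <- data.frame(combo = character(), class = character(),
                      kingdom = character(), proportion = numeric(),
                      top_two = logical())
    class(out) <- c("class_contribution", "data.frame")
    return(out)
  }
  cls <- stats::setNames(taxonomy$class, taxonomy$asv)
  kg <- stats::setNames(taxonomy$kingdom, taxonomy$asv)
  cls[is.na(cls) | cls == ""] <-
    paste0("Unclassified_", kg[is.na(cls) | cls == ""])
  rows <- list()
  top_summary <- stats::setNames(numeric(length(combos)), combos)
  for (cmb in combos) {
    vec <- asv_functional_vectors(rel_abund, ec_content, catalog, cmb)
    total <- sum(colMeans(vec))
    if (total == 0) next
    sig <- intersect(sig_asvs, colnames(vec))
    contrib <- colMeans(vec[, sig, drop = FALSE])
    by_class <- tapply(contrib, cls[sig], sum) / total
    df <- data.frame(combo = cmb, class = names(by_class),
                     kingdom = vapply(names(by_class), function(cl) {
                       unique(kg[sig][cls[sig] == cl])[1]
                     }, character(1)),
                     proportion = as.numeric(by_class),
                     stringsAsFactors = FALSE)
    df$top_two <- FALSE
    for (k in unique(df$kingdom)) {
      sub <- df[df$kingdom == k, ]
      ord <- order(-sub$proportion, sub$class)
      top <- sub$class[ord][seq_len(min(2, nrow(sub)))]
      df$top_two[df$kingdom == k & df$class %in% top] <- TRUE
    }
    top_summary[cmb] <- 100 * sum(df$proportion[df$top_two])
    rows[[cmb]] <- df
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "top_summary") <- top_summary
  class(out) <- c("class_contribution", "data.frame")
  out
}

#' Export class contributions as a Sankey-style JSON
#'
#' Nodes are classes and nutrient-combination labels; links carry the
#' contribution proportions.  The export round-trips losslessly through
#' [sankey_to_table()].
#'
#' @param contrib a `class_contribution` data.frame.
#' @param path optional file to write the JSON to.
#' @return the JSON string, invisibly when `path` is given.
#' @export
export_sankey <- function(contrib, path = NULL) {
  if (!nrow(contrib)) stop("empty contribution table")
  nodes <- rbind(
    data.frame(name = unique(contrib$class), type = "class",
               stringsAsFactors = FALSE),
    data.frame(name = unique(contrib$combo), type = "combo",
               stringsAsFactors = FALSE))
  links <- data.frame(source = contrib$class, target = contrib$combo,
                      value = contrib$proportion,
                      kingdom = contrib$kingdom, top_two = contrib$top_two,
                      stringsAsFactors = FALSE)
  js <- jsonlite::toJSON(list(nodes = nodes, links = links),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Rebuild a contribution table from a Sankey JSON
#'
#' @param json JSON string or path produced by [export_sankey()].
#' @return data.frame with combo, class, kingdom, proportion, top_two.
#' @export
sankey_to_table <- function(json) {
  x <- jsonlite::fromJSON(json)
  data.frame(combo = x$links$target, class = x$links$source,
             kingdom = x$links$kingdom, proportion = x$links$value,
             top_two = x$links$top_two, stringsAsFactors = FALSE)
}
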