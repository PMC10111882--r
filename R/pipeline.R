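#' Pipeline configuration
#'
#' Collects every stage parameter of the end-to-end analysis
#' (simulate/load -> preprocess -> network -> soil -> function -> compare ->
#' difftaxa -> report).  A run is fully determined by the configuration and
#' its single global seed, which is expanded into per-stage seeds with
#' [derive_seed()].
#'
#' @param simulate a [simulation_config()], or `NULL` to read tables from
#'   `input_dir`.
#' @param input_dir directory with a bundle written by [write_bundle()]
#'   (used when `simulate` is `NULL`).
#' @param depth_bacteria,depth_fungi rarefaction depths.
#' @param abund_threshold,abund_mode abundance filter settings
#'   (see [filter_abundance()]).
#' @param prev_fraction per-combination prevalence fraction (default 1/3).
#' @param nlambda,lambda_min_ratio,n_subsamples,instability_threshold
#'   network-inference settings (see [stability_select()]).
#' @param min_module_size smallest module screened for soil response.
#' @param n_perm permutations for dbRDA/PERMANOVA/envfit.
#' @param alpha_soil significance level of the soil screen.
#' @param alpha_pairs adjusted-p threshold for module pair tests.
#' @param alpha_taxa adjusted-p threshold for differential ASVs.
#' @param seed global integer seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(simulate = simulation_config(),
                            input_dir = NULL,
                            depth_bacteria = 28897L, depth_fungi = 16542L,
                            abund_threshold = 0.03,
                            abund_mode = "total_vs_mean_total",
                            prev_fraction = 1 / 3,
                            nlambda = 100, lambda_min_ratio = 1e-3,
                            n_subsamples = 50, instability_threshold = 0.05,
                            min_module_size = 40,
                            n_perm = 999,
                            alpha_soil = 0.05, alpha_pairs = 0.01,
                            alpha_taxa = 0.01,
                            seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; a `simulate`
#' mapping is passed to [simulation_config()].
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulate)) {
    if (!is.null(y$simulate$soil_effect_sizes))
      y$simulate$soil_effect_sizes <- unlist(y$simulate$soil_effect_sizes)
    y$simulate <- do.call(simulation_config, y$simulate)
  }
  do.call(pipeline_config, y)
}

#' Rarefy, filter and assemble per-combination data sets
#'
#' Applies the standard preprocessing chain to a bundle: per-kingdom
#' rarefaction, per-kingdom abundance filtering, per-combination prevalence
#' filtering, and the union merge of the per-combination filtered sets into
#' one table per kingdom (then combined across kingdoms).
#'
#' @param bundle a `synthetic_bundle` (or any list with `counts`,
#'   `taxonomy`, `design`).
#' @param depth_bacteria,depth_fungi rarefaction depths.
#' @param abund_threshold,abund_mode,prev_fraction filter settings.
#' @param seed integer seed for the rarefaction.
#' @return list: `per_cell` (named list of per-combination count matrices,
#'   both kingdoms), `merged` (all retained samples x union taxa), `rel`
#'   (relative abundances of `merged`), `kingdom`, `design` (retained
#'   samples).
#' @export
preprocess_bundle <- function(bundle, depth_bacteria = 28897L,
                              depth_fungi = 16542L, abund_threshold = 0.03,
                              abund_mode = "total_vs_mean_total",
                              prev_fraction = 1 / 3, seed = 1L) {
  kingdom <- stats::setNames(bundle$taxonomy$kingdom, bundle$taxonomy$asv)
  design <- check_design(bundle$design)
  by_kg <- list()
  for (kg in c("bacteria", "fungi")) {
    tx <- names(kingdom)[kingdom == kg]
    depth <- if (kg == "bacteria") depth_bacteria else depth_fungi
    cnt <- bundle$counts[, intersect(colnames(bundle$counts), tx), drop = FALSE]
    cnt <- rarefy_counts(cnt, depth, seed = derive_seed(seed, paste0("rarefy_", kg)))
    cnt <- suppressMessages(filter_abundance(cnt, abund_threshold, abund_mode))
    by_kg[[kg]] <- cnt
  }
  samples <- intersect(rownames(by_kg$bacteria), rownames(by_kg$fungi))
  design <- design[design$sample_id %in% samples, ]
  per_cell <- list()
  merged_kg <- list()
  for (kg in c("bacteria", "fungi")) {
    cnt <- by_kg[[kg]][samples, , drop = FALSE]
    f <- filter_prevalence(cnt, design, prev_fraction)
    merged_kg[[kg]] <- merge_filtered_union(cnt, f)
    for (cmb in names(f)) {
      per_cell[[cmb]] <- if (is.null(per_cell[[cmb]])) f[[cmb]] else
        cbind(per_cell[[cmb]], f[[cmb]])
    }
  }
  merged <- cbind(merged_kg$bacteria, merged_kg$fungi)
  list(per_cell = per_cell, merged = merged,
       rel = relative_abundance(merged),
       kingdom = kingdom[colnames(merged)], design = design)
}

log_stage <- function(con, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
  message(msg)
  if (!is.null(con)) writeLines(msg, con)
}

run_stage <- function(name, con, expr) {
  log_stage(con, "stage ", name, " started")
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes simulate/load, preprocessing, per-combination network inference
#' and module detection, the soil-responsiveness screen, community
#' functional profiling (Shannon diversity tests and PERMANOVA across the
#' seven nutrient combinations), per-diversity-level module ordination and
#' pairwise functional comparisons, and per-taxon differential analysis with
#' class aggregation.  All stage outputs are written as TSV/JSON under
#' `out_dir` together with `summary.json` and a structured log.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created).
#' @return the summary list, invisibly; files are written under `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  con <- file(file.path(out_dir, "run.log"), open = "wt")
  on.exit(close(con), add = TRUE)
  f <- function(...) file.path(out_dir, ...)
  seed <- config$seed

  bundle <- run_stage("simulate", con, {
    if (!is.null(config$simulate)) simulate_dataset(config$simulate)
    else if (!is.null(config$input_dir)) read_bundle(config$input_dir)
    else stop("neither a simulation config nor an input directory given")
  })
  catalog <- bundle$catalog %||% nutrient_catalog()

  prep <- run_stage("preprocess", con, preprocess_bundle(
    bundle, config$depth_bacteria, config$depth_fungi,
    config$abund_threshold, config$abund_mode, config$prev_fraction,
    seed = derive_seed(seed, "preprocess")))
  log_stage(con, "preprocess: ", ncol(prep$merged), " taxa union, ",
            nrow(prep$merged), " samples")

  networks <- run_stage("network", con, {
    lapply(stats::setNames(nm = names(prep$per_cell)), function(cmb) {
      stability_select(prep$per_cell[[cmb]], kingdom = prep$kingdom,
                       nlambda = config$nlambda,
                       lambda_min_ratio = config$lambda_min_ratio,
                       n_subsamples = config$n_subsamples,
                       instability_threshold = config$instability_threshold,
                       combination = cmb,
                       seed = derive_seed(seed, paste0("net_", cmb)))
    })
  })
  partitions <- lapply(networks, detect_modules)
  for (cmb in names(networks)) {
    export_network(networks[[cmb]],
                   f(paste0("network_", gsub("\\|", "_", cmb), ".tsv")))
    write_table(data.frame(node = names(partitions[[cmb]]$membership),
                           module = unname(partitions[[cmb]]$membership)),
                f(paste0("modules_", gsub("\\|", "_", cmb), ".tsv")))
  }

  soil_screens <- run_stage("soil", con, {
    lapply(stats::setNames(nm = names(networks)), function(cmb) {
      ids <- prep$design$sample_id[combination_labels(prep$design) == cmb]
      rel_cell <- relative_abundance(prep$merged[ids, , drop = FALSE])
      module_soil_screen(rel_cell, partitions[[cmb]],
                         bundle$soil[ids, , drop = FALSE],
                         min_size = config$min_module_size,
                         n_perm = config$n_perm, alpha = config$alpha_soil,
                         seed = derive_seed(seed, paste0("soil_", cmb)))
    })
  })
  soil_tab <- do.call(rbind, lapply(names(soil_screens), function(cmb) {
    s <- soil_screens[[cmb]]
    if (is.null(s) || !nrow(s)) return(NULL)
    cbind(combination = cmb, s)
  }))
  if (!is.null(soil_tab)) write_table(soil_tab, f("soil_screen.tsv"))

  func <- run_stage("function", con, {
    ecc <- filter_catalog(bundle$ec_content, catalog, nsti = bundle$nsti,
                          kingdom = stats::setNames(bundle$taxonomy$kingdom,
                                                    bundle$taxonomy$asv))
    keep <- intersect(colnames(prep$rel), rownames(ecc))
    rel <- prep$rel[, keep, drop = FALSE]
    fam <- community_functional_abundance(rel, ecc[keep, , drop = FALSE])
    div <- lapply(stats::setNames(nm = nutrient_combinations()), function(cmb) {
      sl <- slice_combination(fam, cmb, catalog)
      H <- shannon_functional_diversity(sl[rowSums(sl) > 0, , drop = FALSE])
      diversity_tests(H, prep$design)
    })
    perm <- permanova_combinations(fam, catalog, prep$design,
                                   n_perm = config$n_perm,
                                   seed = derive_seed(seed, "permanova"))
    list(ec_content = ecc, rel = rel, fam = fam, diversity = div,
         permanova = perm)
  })
  write_table(func$permanova, f("permanova.tsv"))
  write_matrix_tsv(func$fam, f("functional_abundance.tsv"),
                   id_col = "sample_id")

  compare <- run_stage("compare", con, {
    levels_ <- unique(prep$design$diversity_level)
    out <- list()
    for (lv in levels_) {
      cmb_e <- paste0("EcM|", lv)
      cmb_a <- paste0("AM|", lv)
      if (!cmb_e %in% names(networks) || !cmb_a %in% names(networks)) next
      resp <- function(cmb) {
        s <- soil_screens[[cmb]]
        if (is.null(s) || !nrow(s)) integer() else s$module[s$soil_responsive]
      }
      mods_e <- resp(cmb_e)
      mods_a <- resp(cmb_a)
      if (!length(mods_e) || !length(mods_a)) next
      fam_mod <- function(cmb, mods) {
        ids <- prep$design$sample_id[combination_labels(prep$design) == cmb]
        rel_cell <- relative_abundance(prep$merged[ids, , drop = FALSE])
        rel_cell <- rel_cell[, intersect(colnames(rel_cell),
                                         rownames(func$ec_content)),
                             drop = FALSE]
        ma <- module_abundance_matrix(rel_cell, partitions[[cmb]], mods)
        module_functional_abundance(ma, func$ec_content)
      }
      fme <- fam_mod(cmb_e, mods_e)
      fma <- fam_mod(cmb_a, mods_a)
      pw <- pairwise_module_tests(fme, fma, catalog,
                                  alpha = config$alpha_pairs)
      both <- rbind(fme, fma)
      rownames(both) <- c(paste0("EcM_", rownames(fme)),
                          paste0("AM_", rownames(fma)))
      ord_fit <- if (nrow(both) >= 3) {
        ord <- pcoa_modules(both)
        if (ncol(ord$coordinates) >= 2)
          envfit_enzymes(ord, both, catalog, n_perm = config$n_perm,
                         seed = derive_seed(seed, paste0("envfit_", lv)))
        else NULL
      } else NULL
      out[[lv]] <- list(pairwise = pw, fam_ecm = fme, fam_am = fma,
                        mods_e = mods_e, mods_a = mods_a, envfit = ord_fit)
    }
    out
  })
  pw_all <- do.call(rbind, lapply(names(compare), function(lv) {
    pw <- compare[[lv]]$pairwise
    if (!nrow(pw)) return(NULL)
    cbind(diversity_level = lv, pw)
  }))
  if (!is.null(pw_all)) write_table(pw_all, f("module_pairs.tsv"))

  difftax <- run_stage("difftaxa", con, {
    sig_all <- character()
    for (lv in names(compare)) {
      cm <- compare[[lv]]
      pw <- cm$pairwise
      if (!nrow(pw)) next
      # every pair significant in any nutrient combination is tested on the
      # ASVs' overall CNP functional values
      sig_pairs <- pw[!is.na(pw$p_adj) & pw$p_adj <= config$alpha_pairs,
                      c("module_a", "module_b")]
      if (!nrow(sig_pairs)) next
      cmb_e <- paste0("EcM|", lv)
      cmb_a <- paste0("AM|", lv)
      vecs <- function(cmb) {
        ids <- prep$design$sample_id[combination_labels(prep$design) == cmb]
        rel_cell <- relative_abundance(prep$merged[ids, , drop = FALSE])
        rel_cell <- rel_cell[, intersect(colnames(rel_cell),
                                         rownames(func$ec_content)),
                             drop = FALSE]
        asv_functional_vectors(rel_cell, func$ec_content, catalog, "CNP")
      }
      da <- differential_asvs(vecs(cmb_e), vecs(cmb_a),
                              partitions[[cmb_e]], partitions[[cmb_a]],
                              unique(sig_pairs), alpha = config$alpha_taxa)
      sig_all <- union(sig_all, da$significant)
    }
    contrib <- aggregate_to_class(sig_all, func$rel, func$ec_content,
                                  bundle$taxonomy, catalog)
    list(significant = sig_all, contributions = contrib)
  })
  if (nrow(difftax$contributions)) {
    write_table(as.data.frame(difftax$contributions), f("class_contributions.tsv"))
    export_sankey(difftax$contributions, f("sankey.json"))
  }

  n_resp <- if (is.null(soil_tab)) 0L else sum(soil_tab$soil_responsive)
  n_pairs_sig <- if (is.null(pw_all)) 0L else
    length(unique(paste(pw_all$diversity_level, pw_all$module_a,
                        pw_all$module_b)[!is.na(pw_all$p_adj) &
                                           pw_all$p_adj <= config$alpha_pairs]))
  ts <- attr(difftax$contributions, "top_summary")
  summary <- list(
    n_samples = nrow(prep$merged),
    n_taxa_union = ncol(prep$merged),
    n_networks = length(networks),
    n_modules_total = sum(vapply(partitions, function(p)
      length(p$sizes), integer(1))),
    n_modules_screened = if (is.null(soil_tab)) 0L else nrow(soil_tab),
    n_soil_responsive = n_resp,
    n_significant_module_pairs = n_pairs_sig,
    n_differential_asvs = length(difftax$significant),
    top_two_contribution_pct = if (!is.null(ts) && length(ts))
      list(min = min(ts[ts > 0]), max = max(ts)) else NULL,
    seed = seed)
  jsonlite::write_json(summary, f("summary.json"), auto_unbox = TRUE,
                       digits = NA)
  log_stage(con, "pipeline complete")
  invisible(list(summary = summary, networks = networks,
                 partitions = partitions, soil = soil_screens,
                 functional = func, compare = compare, difftaxa = difftax,
                 prep = prep, bundle = bundle))
}
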