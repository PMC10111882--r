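#' Configuration for the synthetic-data generator
#'
#' Defines the study conditions emulated by [simulate_dataset()]: a balanced
#' two-factor design (mycorrhizal type EcM/AM crossed with diversity levels
#' Mono/Two/Multi, 18 samples per cell by default), bacterial and fungal taxa
#' with planted co-occurrence modules spanning both kingdoms, soil chemistry
#' with realistic correlations, and per-class predicted EC gene-family
#' profiles with planted module-level enrichments.
#'
#' `module_cohesion` is the variance of a shared per-(sample, module) latent
#' factor relative to unit taxon-level noise, so the within-module latent
#' correlation equals `cohesion / (1 + cohesion)`.
#'
#' @param n_samples_per_cell samples per design cell (6 cells).
#' @param n_bacteria,n_fungi taxa per kingdom.
#' @param n_modules number of planted interkingdom modules.
#' @param module_cohesion within-module association strength (>= 0).
#' @param module_fraction fraction of taxa assigned to planted modules; the
#'   remainder are independent background taxa.
#' @param soil_effect_sizes named numeric vector mapping a soil variable to
#'   the latent-mean shift per standard deviation of that variable; planted
#'   module `b` is associated with the `b`-th entry (modules beyond the
#'   vector length are not soil-associated).
#' @param enzyme_effect planted enrichment of selected (module, EC) pairs:
#'   base copy numbers are multiplied by `1 + enzyme_effect`.
#' @param mycorrhizal_effect optional planted tree-mycorrhizal-type contrast
#'   (default 0 = none): the latent means of the first planted module are
#'   raised by this amount in EcM samples and those of the second module in
#'   AM samples, recorded in `truth$type_enriched`.
#' @param n_enriched_ecs ECs enriched per module.
#' @param depth_bacteria,depth_fungi library sizes per kingdom.
#' @param count_model `"lognormal_multinomial"` (default) or `"negbin"`.
#' @param seed integer seed; fully determines the output.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_samples_per_cell = 18L,
                              n_bacteria = 200L, n_fungi = 150L,
                              n_modules = 6L,
                              module_cohesion = 2.0,
                              module_fraction = 0.7,
                              soil_effect_sizes = c(pH = 1.0, NO3 = 0.8, TP = 0.8),
                              enzyme_effect = 1.0,
                              mycorrhizal_effect = 0,
                              n_enriched_ecs = 5L,
                              depth_bacteria = 28897L,
                              depth_fungi = 16542L,
                              count_model = c("lognormal_multinomial", "negbin"),
                              seed = 1L) {
  count_model <- match.arg(count_model)
  cfg <- list(n_samples_per_cell = as.integer(n_samples_per_cell),
              n_bacteria = as.integer(n_bacteria),
              n_fungi = as.integer(n_fungi),
              n_modules = as.integer(n_modules),
              module_cohesion = module_cohesion,
              module_fraction = module_fraction,
              soil_effect_sizes = soil_effect_sizes,
              enzyme_effect = enzyme_effect,
              mycorrhizal_effect = mycorrhizal_effect,
              n_enriched_ecs = as.integer(n_enriched_ecs),
              depth_bacteria = as.integer(depth_bacteria),
              depth_fungi = as.integer(depth_fungi),
              count_model = count_model,
              seed = as.integer(seed))
  with(cfg, {
    if (n_samples_per_cell < 1L || n_bacteria < 1L || n_fungi < 1L)
      stop("sample and taxon counts must be positive")
    if (depth_bacteria < 1L || depth_fungi < 1L)
      stop("sequencing depths must be positive")
    if (n_modules > n_bacteria + n_fungi)
      stop("n_modules exceeds the total number of taxa")
    if (module_cohesion < 0 || enzyme_effect < 0 || mycorrhizal_effect < 0)
      stop("module_cohesion, enzyme_effect and mycorrhizal_effect must be >= 0")
  })
  class(cfg) <- "simulation_config"
  cfg
}

FUNGAL_CLASSES <- c("Agaricomycetes", "Sordariomycetes", "Eurotiomycetes",
                    "Leotiomycetes", "Dothideomycetes", "Tremellomycetes",
                    "Mortierellomycetes")
BACTERIAL_CLASSES <- c("Acidobacteria", "Alphaproteobacteria", "Actinobacteria",
                       "Verrucomicrobia", "Gammaproteobacteria", "Bacteroidia",
                       "Planctomycetia")

# correlated soil chemistry with realistic signs (TOC-TN-SOM positive block)
simulate_soil <- function(n) {
  toc <- exp(stats::rnorm(n, log(30), 0.25))
  tn <- 0.08 * toc * exp(stats::rnorm(n, 0, 0.15))
  tp <- exp(stats::rnorm(n, log(0.45), 0.25))
  som <- 1.72 * toc * exp(stats::rnorm(n, 0, 0.08))
  nh4 <- exp(stats::rnorm(n, log(8), 0.4))
  no3 <- exp(stats::rnorm(n, log(4), 0.5))
  ph <- stats::rnorm(n, 4.6, 0.35)
  moisture <- stats::plogis(stats::rnorm(n, -1.0, 0.35))
  data.frame(pH = ph, moisture = moisture, TOC = toc, TN = tn, TP = tp,
             NH4 = nh4, NO3 = no3, SOM = som,
             C.N = toc / tn, C.P = toc / tp, N.P = tn / tp)
}

#' Simulate a complete synthetic interkingdom dataset
#'
#' Draws latent log-abundances from a block-structured factor model (blocks =
#' planted modules spanning both kingdoms, zero off-block correlation),
#' shifts latent means of soil-associated modules along standardized soil
#' covariates, and samples counts per kingdom to the configured depth.
#' Predicted EC content is drawn around class-level base profiles over the
#' catalog, with planted (module, EC) pairs multiplied by
#' `1 + enzyme_effect`.  Ground truth sufficient to score recovery is
#' returned alongside the tables.
#'
#' @param config a [simulation_config()].
#' @param catalog EC catalog; defaults to [nutrient_catalog()].
#' @return a `synthetic_bundle`: list with `counts` (sample x taxon integer
#'   matrix), `taxonomy`, `soil`, `design`, `ec_content` (taxon x EC matrix),
#'   `nsti`, `catalog`, `truth`, `config`.
#' @export
#' @examples
#' b <- simulate_dataset(simulation_config(n_samples_per_cell = 3,
#'   n_bacteria = 20, n_fungi = 10, n_modules = 2,
#'   depth_bacteria = 500, depth_fungi = 300, seed = 7))
#' dim(b$counts)
simulate_dataset <- function(config = simulation_config(),
                             catalog = nutrient_catalog()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  cells <- expand.grid(diversity_level = c("Mono", "Two", "Multi"),
                       mycorrhizal_type = c("EcM", "AM"),
                       stringsAsFactors = FALSE)
  n_cell <- config$n_samples_per_cell
  design <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    data.frame(sample_id = sprintf("S%s_%s_%02d", cells$mycorrhizal_type[i],
                                   cells$diversity_level[i], seq_len(n_cell)),
               mycorrhizal_type = cells$mycorrhizal_type[i],
               diversity_level = cells$diversity_level[i],
               plot_id = sprintf("P%s%s%02d", substr(cells$mycorrhizal_type[i], 1, 1),
                                 substr(cells$diversity_level[i], 1, 2),
                                 ((seq_len(n_cell) - 1L) %/% 3L) + 1L),
               stringsAsFactors = FALSE)
  }))
  n <- nrow(design)

  soil <- simulate_soil(n)
  rownames(soil) <- design$sample_id
  soil_std <- scale(as.matrix(soil))

  taxa <- c(sprintf("B%04d", seq_len(config$n_bacteria)),
            sprintf("F%04d", seq_len(config$n_fungi)))
  kingdom <- rep(c("bacteria", "fungi"),
                 c(config$n_bacteria, config$n_fungi))
  names(kingdom) <- taxa
  p <- length(taxa)

  # planted modules: round-robin over each kingdom so every module spans both
  module <- rep(NA_integer_, p)
  n_mod_taxa <- floor(config$module_fraction * p)
  in_mod <- c(seq_len(floor(n_mod_taxa * config$n_bacteria / p)),
              config$n_bacteria +
                seq_len(n_mod_taxa - floor(n_mod_taxa * config$n_bacteria / p)))
  module[in_mod] <- rep_len(seq_len(config$n_modules), length(in_mod))
  names(module) <- taxa

  classes <- ifelse(kingdom == "bacteria",
                    sample(BACTERIAL_CLASSES, p, replace = TRUE,
                           prob = c(0.22, 0.2, 0.16, 0.12, 0.12, 0.1, 0.08)),
                    sample(FUNGAL_CLASSES, p, replace = TRUE,
                           prob = c(0.24, 0.2, 0.16, 0.14, 0.1, 0.09, 0.07)))
  taxonomy <- data.frame(
    asv = taxa, kingdom = kingdom,
    phylum = paste0("phy_", substr(classes, 1, 4)),
    class = classes,
    order = paste0("o_", seq_len(p)), family = paste0("f_", seq_len(p)),
    genus = paste0("g_", seq_len(p)), stringsAsFactors = FALSE)

  # soil association: module b shifts along the b-th configured soil variable
  ses <- config$soil_effect_sizes
  n_assoc <- min(length(ses), config$n_modules)
  soil_assoc <- if (n_assoc > 0L)
    data.frame(module = seq_len(n_assoc), variable = names(ses)[seq_len(n_assoc)],
               effect = unname(ses[seq_len(n_assoc)]), stringsAsFactors = FALSE)
  else data.frame(module = integer(), variable = character(), effect = numeric())
  bad_var <- setdiff(soil_assoc$variable, colnames(soil))
  if (length(bad_var))
    stop("soil_effect_sizes names not in soil table: ",
         paste(bad_var, collapse = ", "))

  # latent log-abundances: taxon baseline + shared module factor + noise
  mu <- stats::rnorm(p, 0, 1)
  z <- matrix(stats::rnorm(n * p), n, p)
  z <- sweep(z, 2, mu, "+")
  fac <- matrix(stats::rnorm(n * config$n_modules), n, config$n_modules)
  for (b in seq_len(config$n_modules)) {
    members <- which(!is.na(module) & module == b)
    if (!length(members)) next
    z[, members] <- z[, members] + sqrt(config$module_cohesion) * fac[, b]
    hit <- soil_assoc$module == b
    if (any(hit)) {
      v <- soil_assoc$variable[hit][1]
      # heterogeneous response: member taxa differ in how strongly they
      # track the soil covariate, so the module's internal composition
      # (not just its total load) carries the association
      w <- stats::runif(length(members), 0.25, 1.75)
      z[, members] <- z[, members] +
        (soil_std[, v] %o% w) * soil_assoc$effect[hit][1]
    }
  }

  # optional planted tree-type contrast: module 1 favoured under EcM,
  # module 2 under AM
  type_enriched <- data.frame(module = integer(), favored = character(),
                              effect = numeric())
  if (config$mycorrhizal_effect > 0 && config$n_modules >= 1) {
    fav <- c("EcM", "AM")[seq_len(min(2L, config$n_modules))]
    for (i in seq_along(fav)) {
      members <- which(!is.na(module) & module == i)
      in_type <- design$mycorrhizal_type == fav[i]
      if (length(members))
        z[in_type, members] <- z[in_type, members] + config$mycorrhizal_effect
      type_enriched <- rbind(type_enriched,
                             data.frame(module = i, favored = fav[i],
                                        effect = config$mycorrhizal_effect))
    }
  }

  counts <- matrix(0L, n, p, dimnames = list(design$sample_id, taxa))
  for (kg in c("bacteria", "fungi")) {
    idx <- which(kingdom == kg)
    depth <- if (kg == "bacteria") config$depth_bacteria else config$depth_fungi
    if (config$count_model == "lognormal_multinomial") {
      pr <- exp(z[, idx, drop = FALSE])
      pr <- pr / rowSums(pr)
      for (s in seq_len(n))
        counts[s, idx] <- stats::rmultinom(1, depth, pr[s, ])
    } else {
      mu_nb <- exp(z[, idx, drop = FALSE])
      mu_nb <- depth * mu_nb / rowSums(mu_nb)
      counts[, idx] <- matrix(stats::rnbinom(n * length(idx), size = 5,
                                             mu = as.vector(mu_nb)),
                              n, length(idx))
    }
  }

  # class-level EC base profiles, kingdom-weighted by cycle
  ecs <- catalog$ec
  cyc <- catalog_cycles(catalog)
  all_classes <- unique(classes)
  base <- matrix(0, length(all_classes), length(ecs),
                 dimnames = list(all_classes, ecs))
  for (cl in all_classes) {
    kg <- if (cl %in% FUNGAL_CLASSES) "fungi" else "bacteria"
    w <- vapply(cyc, function(x) {
      if (kg == "fungi") ifelse("C" %in% x, 1.4, 0.8)
      else ifelse("C" %in% x, 0.9, 1.2)
    }, numeric(1))
    present <- stats::rbinom(length(ecs), 1, 0.55)
    base[cl, ] <- present * round(stats::rgamma(length(ecs), 2, 0.8) * w)
  }

  enriched <- do.call(rbind, lapply(seq_len(config$n_modules), function(b) {
    data.frame(module = b,
               ec = sample(ecs, min(config$n_enriched_ecs, length(ecs))),
               stringsAsFactors = FALSE)
  }))

  ec_content <- matrix(0, p, length(ecs), dimnames = list(taxa, ecs))
  for (j in seq_len(p)) {
    lam <- base[classes[j], ]
    b <- module[j]
    if (!is.na(b)) {
      hit <- enriched$ec[enriched$module == b]
      lam[hit] <- lam[hit] * (1 + config$enzyme_effect) + 0.5
    }
    ec_content[j, ] <- stats::rpois(length(ecs), lam)
  }

  nsti <- stats::runif(p, 0.01, 0.6)
  names(nsti) <- taxa
  # one unreliable prediction per kingdom, above the conventional cutoff of 2
  nsti[sample(which(kingdom == "bacteria"), 1)] <- 2.5
  nsti[sample(which(kingdom == "fungi"), 1)] <- 2.5

  bundle <- list(counts = counts, taxonomy = taxonomy, soil = soil,
                 design = design, ec_content = ec_content, nsti = nsti,
                 catalog = catalog,
                 truth = list(modules = module, soil_assoc = soil_assoc,
                              enriched = enriched,
                              type_enriched = type_enriched),
                 config = config)
  class(bundle) <- "synthetic_bundle"
  bundle
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat("synthetic_bundle:", nrow(x$counts), "samples,",
      sum(x$taxonomy$kingdom == "bacteria"), "bacterial +",
      sum(x$taxonomy$kingdom == "fungi"), "fungal taxa,",
      x$config$n_modules, "planted modules (seed", x$config$seed, ")\n")
  invisible(x)
}

#' Write a synthetic bundle to a directory of TSV tables
#'
#' @param bundle a `synthetic_bundle`.
#' @param directory output directory (created if absent).
#' @return the manifest (list of files plus the config seed), invisibly
#'   written to `manifest.json`.
#' @export
write_bundle <- function(bundle, directory) {
  stopifnot(inherits(bundle, "synthetic_bundle"))
  if (ncol(bundle$counts) == 0L || nrow(bundle$counts) == 0L)
    stop("refusing to write an empty bundle (no taxa or no samples)")
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  f <- function(x) file.path(directory, x)
  write_matrix_tsv(bundle$counts, f("counts.tsv"), id_col = "sample_id")
  write_table(bundle$taxonomy, f("taxonomy.tsv"))
  write_matrix_tsv(as.matrix(bundle$soil), f("soil.tsv"), id_col = "sample_id")
  write_table(bundle$design, f("design.tsv"))
  write_matrix_tsv(bundle$ec_content, f("ec_content.tsv"), id_col = "asv")
  write_table(data.frame(asv = names(bundle$nsti), nsti = unname(bundle$nsti)),
              f("nsti.tsv"))
  write_table(as.data.frame(bundle$catalog), f("catalog.tsv"))
  truth <- list(
    modules = as.list(bundle$truth$modules[!is.na(bundle$truth$modules)]),
    soil_assoc = bundle$truth$soil_assoc,
    enriched = bundle$truth$enriched)
  jsonlite::write_json(truth, f("truth.json"), auto_unbox = TRUE, digits = NA)
  manifest <- list(
    files = c("counts.tsv", "taxonomy.tsv", "soil.tsv", "design.tsv",
              "ec_content.tsv", "nsti.tsv", "catalog.tsv", "truth.json"),
    seed = bundle$config$seed,
    n_samples = nrow(bundle$counts), n_taxa = ncol(bundle$counts))
  jsonlite::write_json(manifest, f("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}

#' Read a bundle written by [write_bundle()]
#'
#' @param directory directory containing the bundle tables.
#' @return a `synthetic_bundle` (without the generating config; `truth` is
#'   restored from `truth.json`).
#' @export
read_bundle <- function(directory) {
  f <- function(x) file.path(directory, x)
  counts <- read_matrix_tsv(f("counts.tsv"))
  storage.mode(counts) <- "integer"
  taxonomy <- read_table(f("taxonomy.tsv"))
  soil <- read_table(f("soil.tsv"))
  rownames(soil) <- soil$sample_id
  soil$sample_id <- NULL
  design <- read_table(f("design.tsv"))
  ec_content <- read_matrix_tsv(f("ec_content.tsv"))
  nsti_df <- read_table(f("nsti.tsv"))
  nsti <- stats::setNames(nsti_df$nsti, nsti_df$asv)
  catalog <- ec_catalog(read_table(f("catalog.tsv")))
  truth <- NULL
  if (file.exists(f("truth.json"))) {
    tr <- jsonlite::read_json(f("truth.json"), simplifyVector = TRUE)
    truth <- list(modules = unlist(tr$modules),
                  soil_assoc = as.data.frame(tr$soil_assoc),
                  enriched = as.data.frame(tr$enriched))
  }
  bundle <- list(counts = counts, taxonomy = taxonomy, soil = soil,
                 design = design, ec_content = ec_content, nsti = nsti,
                 catalog = catalog, truth = truth, config = NULL)
  class(bundle) <- "synthetic_bundle"
  bundle
}
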