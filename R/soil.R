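#' Standardise soil variables
#'
#' Centres each column to mean zero and scales to unit standard deviation
#' (n - 1 denominator).
#'
#' @param soil data.frame or matrix of numeric soil variables.
#' @return data.frame of standardised variables, attribute
#'   `"standardized" = TRUE`.
#' @export
standardize_soil <- function(soil) {
  m <- as.matrix(soil)
  if (!is.numeric(m)) stop("soil table must be numeric")
  if (anyNA(m)) stop("soil table contains missing values")
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0))
    stop("constant soil column(s): ",
         paste(colnames(m)[sds == 0], collapse = ", "))
  out <- as.data.frame(scale(m))
  rownames(out) <- rownames(soil)
  attr(out, "standardized") <- TRUE
  out
}

#' Iterative VIF filter for collinear predictors
#'
#' Repeatedly drops the variable with the largest variance inflation factor
#' (`VIF_j = 1 / (1 - R2_j)` from regressing variable j on the rest) until
#' all VIFs fall below `threshold`.  Perfectly collinear variables are
#' handled by dropping one member of the collinear set.
#'
#' @param soil data.frame of numeric predictors (>= 2 columns).
#' @param threshold VIF threshold (default 10).
#' @return list: `retained` (column names), `dropped`, `vif` (final values).
#' @export
vif_filter <- function(soil, threshold = 10) {
  m <- as.matrix(soil)
  if (ncol(m) < 2) stop("need at least 2 variables")
  vars <- colnames(m)
  dropped <- character()
  compute_vif <- function(cols) {
    vapply(cols, function(v) {
      r2 <- summary(stats::lm(m[, v] ~ m[, setdiff(cols, v), drop = FALSE]))$r.squared
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, numeric(1))
  }
  while (length(vars) >= 2) {
    v <- compute_vif(vars)
    if (all(v < threshold)) break
    worst <- names(v)[which.max(v)]
    dropped <- c(dropped, worst)
    vars <- setdiff(vars, worst)
  }
  vif_final <- if (length(vars) >= 2) compute_vif(vars) else
    stats::setNames(rep(1, length(vars)), vars)
  list(retained = vars, dropped = dropped, vif = vif_final)
}

#' Distance-based redundancy analysis of a module on soil chemistry
#'
#' Runs `vegan::capscale` on the Bray-Curtis distance of the module members'
#' relative abundances against the soil predictors, then permutation-tests
#' the global model and the marginal contribution of each variable.  Only
#' real (positive-eigenvalue) PCoA axes enter the constrained stage, matching
#' capscale's default handling of negative eigenvalues.
#'
#' @param module_abund sample x member-taxon abundance matrix.
#' @param soil standardised soil predictors (same samples).
#' @param n_perm permutations (default 999).
#' @param seed integer seed.
#' @param sqrt_dist passed to capscale (`sqrt.dist`); FALSE by default.
#' @return list: `model`, `global_p`, `global_f`, `terms` (data.frame with
#'   per-variable pseudo-F and p), `soil_responsive` flag at `alpha`.
#' @param alpha per-variable significance level for the responsiveness flag.
#' @export
dbrda_module <- function(module_abund, soil, n_perm = 999, seed = 1L,
                         alpha = 0.05, sqrt_dist = FALSE) {
  if (nrow(module_abund) != nrow(soil))
    stop("module abundance and soil tables have different sample counts")
  if (all(module_abund == 0)) stop("module abundance is all zero")
  if (nrow(soil) < ncol(soil) + 2)
    stop("too few samples for ", ncol(soil), " predictors")
  if (anyDuplicated(t(as.matrix(soil))))
    stop("duplicate soil columns; apply vif_filter first")
  dat <- as.data.frame(soil)
  set.seed(seed)
  mod <- vegan::capscale(module_abund ~ ., data = dat, distance = "bray",
                         sqrt.dist = sqrt_dist)
  glob <- vegan::anova.cca(mod, permutations = n_perm)
  marg <- vegan::anova.cca(mod, by = "margin", permutations = n_perm)
  k <- nrow(marg) - 1L
  terms <- data.frame(variable = rownames(marg)[seq_len(k)],
                      pseudo_f = marg$F[seq_len(k)],
                      p = marg$`Pr(>F)`[seq_len(k)],
                      stringsAsFactors = FALSE)
  list(model = mod,
       global_f = glob$F[1], global_p = glob$`Pr(>F)`[1],
       terms = terms,
       soil_responsive = any(terms$p <= alpha))
}

#' Stepwise soil-variable selection for a module ordination
#'
#' Forward-with-backward selection on permutation p-values
#' (`vegan::ordistep`; add at `alpha_enter`, drop at `alpha_exit`), starting
#' from the intercept-only capscale model.  Apply [vif_filter()] first.
#'
#' @param module_abund sample x member-taxon abundance matrix.
#' @param soil standardised soil predictors (post-VIF).
#' @param alpha_enter,alpha_exit inclusion/exclusion p thresholds
#'   (defaults 0.05 / 0.1).
#' @param n_perm permutations per step.
#' @param seed integer seed; selection is deterministic given the seed.
#' @return character vector of selected variable names (possibly empty).
#' @export
stepwise_select <- function(module_abund, soil, alpha_enter = 0.05,
                            alpha_exit = 0.1, n_perm = 199, seed = 1L) {
  dat <- as.data.frame(soil)
  set.seed(seed)
  m0 <- vegan::capscale(module_abund ~ 1, data = dat, distance = "bray")
  m1 <- vegan::capscale(module_abund ~ ., data = dat, distance = "bray")
  sel <- suppressMessages(vegan::ordistep(
    m0, scope = stats::formula(m1), direction = "both",
    Pin = alpha_enter, Pout = alpha_exit,
    permutations = n_perm, trace = FALSE))
  attr(stats::terms(sel), "term.labels")
}

#' Screen every module of a partition for soil responsiveness
#'
#' For each module of size at least `min_size`: VIF-filter the standardised
#' soil table, select variables by [stepwise_select()], refit the final
#' dbRDA on the selected variables, and flag the module as soil-responsive
#' when at least one selected variable is significant in the final model.
#'
#' @param rel_abund sample x taxon relative abundances for the combination's
#'   samples.
#' @param partition a `module_partition`.
#' @param soil raw soil table (standardised internally; same samples).
#' @param min_size minimum module size considered (default 40).
#' @param vif_threshold VIF cutoff (default 10).
#' @param n_perm permutations for the final model tests.
#' @param alpha significance level for the responsiveness flag.
#' @param seed integer seed.
#' @return data.frame per screened module: `module`, `size`,
#'   `selected_vars`, `global_f`, `global_p`, `soil_responsive`.
#' @export
module_soil_screen <- function(rel_abund, partition, soil, min_size = 40,
                               vif_threshold = 10, n_perm = 999,
                               alpha = 0.05, seed = 1L) {
  stopifnot(inherits(partition, "module_partition"))
  soil_std <- standardize_soil(soil)
  keep_mods <- names(partition$sizes)[partition$sizes >= min_size]
  rows <- lapply(keep_mods, function(mid) {
    members <- names(partition$membership)[partition$membership == as.integer(mid)]
    members <- intersect(members, colnames(rel_abund))
    sub <- rel_abund[, members, drop = FALSE]
    # analyse the module as its own community: renormalising within the
    # module removes the shared closure factor a shift elsewhere in the
    # composition would otherwise impose on every member
    tot <- rowSums(sub)
    sub <- sub[tot > 0, , drop = FALSE] / tot[tot > 0]
    if (all(sub == 0))
      return(data.frame(module = as.integer(mid), size = length(members),
                        selected_vars = "", global_f = NA_real_,
                        global_p = NA_real_, soil_responsive = FALSE))
    vf <- vif_filter(soil_std, vif_threshold)
    soil_use <- soil_std[rownames(sub), vf$retained, drop = FALSE]
    # double stopping rule: only run selection when the global model with all
    # retained predictors is itself significant, which keeps the
    # false-flag rate of the screen near the nominal level
    glob <- dbrda_module(sub, soil_use, n_perm = n_perm,
                         seed = derive_seed(seed, paste0("glob", mid)),
                         alpha = alpha)
    if (is.na(glob$global_p) || glob$global_p > alpha)
      return(data.frame(module = as.integer(mid), size = length(members),
                        selected_vars = "", global_f = glob$global_f,
                        global_p = glob$global_p, soil_responsive = FALSE))
    sel <- stepwise_select(sub, soil_use, n_perm = n_perm,
                           seed = derive_seed(seed, paste0("step", mid)))
    if (length(sel) == 0L)
      return(data.frame(module = as.integer(mid), size = length(members),
                        selected_vars = "", global_f = NA_real_,
                        global_p = NA_real_, soil_responsive = FALSE))
    fit <- dbrda_module(sub, soil_use[, sel, drop = FALSE], n_perm = n_perm,
                        seed = derive_seed(seed, paste0("dbrda", mid)),
                        alpha = alpha)
    data.frame(module = as.integer(mid), size = length(members),
               selected_vars = paste(sel, collapse = ","),
               global_f = fit$global_f, global_p = fit$global_p,
               soil_responsive = fit$soil_responsive)
  })
  do.call(rbind, rows)
}
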