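#' Rarefy a count table to fixed depth
#'
#' Subsamples each sample's reads without replacement to exactly `depth`
#' reads.  Samples whose total is below `depth` are dropped with a warning;
#' rarefying a sample whose total already equals `depth` leaves it unchanged.
#'
#' @param counts sample x taxon integer matrix.
#' @param depth target reads per sample (>= 1).
#' @param seed integer seed; the subsampling is deterministic given the seed.
#' @return rarefied count matrix whose retained rows each sum to `depth`.
#' @export
rarefy_counts <- function(counts, depth, seed = 1L) {
  check_counts(counts)
  if (depth < 1) stop("depth must be >= 1")
  totals <- rowSums(counts)
  keep <- totals >= depth
  if (!any(keep))
    stop("rarefaction depth ", depth, " exceeds every sample total")
  if (any(!keep))
    warning(sum(!keep), " sample(s) below depth ", depth, " dropped: ",
            paste(rownames(counts)[!keep], collapse = ", "))
  counts <- counts[keep, , drop = FALSE]
  set.seed(seed)
  exact <- rowSums(counts) == depth
  out <- counts
  if (any(!exact)) {
    # rrarefy's "observed counts" heuristic misfires on small test tables
    sub <- withCallingHandlers(
      vegan::rrarefy(counts[!exact, , drop = FALSE], depth),
      warning = function(w) {
        if (grepl("observed counts", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    out[!exact, ] <- sub
  }
  storage.mode(out) <- "integer"
  out
}

#' Abundance filter for rare taxa
#'
#' Removes low-abundance taxa.  The criterion "abundance above 3% of the
#' mean total sequencing reads" admits several readings, so three modes are
#' provided:
#' \describe{
#'   \item{`"mean_count_vs_mean_total"`}{keep taxa whose mean count per
#'     sample exceeds `threshold / 100` per cent of the mean sample total,
#'     i.e. mean count > (threshold/100)/100 x mean total.}
#'   \item{`"total_vs_mean_total"` (default)}{keep taxa whose total count
#'     across samples exceeds `threshold` (as a fraction) of the mean sample
#'     total.}
#'   \item{`"relative_mean"`}{keep taxa whose mean relative abundance
#'     exceeds `threshold`.}
#' }
#' The number of retained taxa is reported via `message()` so users can
#' compare against counts from their own data.
#'
#' @param counts sample x taxon matrix.
#' @param threshold filter threshold; a fraction in (0, 1] for the default
#'   mode (0.03 reproduces a "3% of mean total" rule).
#' @param mode one of the modes above.
#' @return filtered count matrix (same samples, fewer taxa).
#' @export
filter_abundance <- function(counts, threshold = 0.03,
                             mode = c("total_vs_mean_total",
                                      "mean_count_vs_mean_total",
                                      "relative_mean")) {
  check_counts(counts)
  mode <- match.arg(mode)
  if (nrow(counts) == 0L) stop("count table has no samples")
  if (threshold < 0 || threshold > 1)
    stop("threshold must lie in [0, 1] for fractional modes")
  mean_total <- mean(rowSums(counts))
  keep <- switch(mode,
    total_vs_mean_total = colSums(counts) / nrow(counts) > threshold * mean_total,
    mean_count_vs_mean_total = colMeans(counts) > (threshold / 100) * mean_total,
    relative_mean = {
      rel <- counts / pmax(rowSums(counts), 1)
      colMeans(rel) > threshold
    })
  if (threshold == 0) keep <- colSums(counts) > 0
  if (!any(keep))
    stop("abundance filter removed every taxon (threshold ", threshold, ")")
  message("filter_abundance: retained ", sum(keep), " of ", ncol(counts),
          " taxa (mode ", mode, ", threshold ", threshold, ")")
  counts[, keep, drop = FALSE]
}

#' Per-combination prevalence filter
#'
#' Within each (mycorrhizal type x diversity level) cell, keeps taxa present
#' (count > 0) in at least `min_fraction` of that cell's samples.
#'
#' @param counts sample x taxon matrix.
#' @param design design table matching the samples.
#' @param min_fraction minimum presence fraction, in (0, 1]; default 1/3.
#' @return named list of per-combination count matrices (samples of that
#'   cell, taxa passing the filter there), with attribute `"union"` giving
#'   the union of retained taxa over all cells.
#' @export
filter_prevalence <- function(counts, design, min_fraction = 1 / 3) {
  check_counts(counts)
  design <- check_design(design)
  if (min_fraction <= 0 || min_fraction > 1)
    stop("min_fraction must lie in (0, 1]")
  combos <- combination_labels(design)
  out <- list()
  for (cmb in unique(combos)) {
    ids <- design$sample_id[combos == cmb]
    ids <- intersect(ids, rownames(counts))
    if (length(ids) == 0L) stop("combination ", cmb, " has no samples")
    sub <- counts[ids, , drop = FALSE]
    prev <- colMeans(sub > 0)
    out[[cmb]] <- sub[, prev >= min_fraction, drop = FALSE]
  }
  attr(out, "union") <- sort(unique(unlist(lapply(out, colnames))))
  out
}

#' Merge per-combination filtered tables by taxon union
#'
#' Mirrors the convention of merging the per-combination filtered data sets
#' into a single table (all samples, union of retained taxa) before
#' functional prediction.
#'
#' @param counts the full sample x taxon matrix (pre-filter counts).
#' @param filtered result of [filter_prevalence()].
#' @return count matrix restricted to the union of retained taxa.
#' @export
merge_filtered_union <- function(counts, filtered) {
  u <- attr(filtered, "union")
  if (is.null(u)) u <- sort(unique(unlist(lapply(filtered, colnames))))
  counts[, intersect(colnames(counts), u), drop = FALSE]
}

#' Relative abundance (total-sum scaling)
#'
#' @param counts sample x taxon matrix with positive row sums.
#' @return matrix whose rows sum to 1.
#' @export
relative_abundance <- function(counts) {
  check_counts(counts)
  rs <- rowSums(counts)
  if (any(rs == 0))
    stop("zero-sum sample(s): ", paste(rownames(counts)[rs == 0], collapse = ", "))
  counts / rs
}
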