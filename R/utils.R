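#' @useDynLib nutrinet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a per-stage seed from a global seed
#'
#' Expands one global integer seed into reproducible per-stage seeds so that
#' individual pipeline stages can be rerun in isolation.  Uses a
#' splitmix-style multiply-and-fold on 31-bit integer arithmetic; the result
#' is always a valid positive R integer.
#'
#' @param seed global integer seed.
#' @param stage stage name (character) or index (integer).
#' @return a positive integer seed, deterministic in `(seed, stage)`.
#' @export
#' @examples
#' derive_seed(1L, "network")
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  if (is.character(stage)) {
    stage <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  }
  m <- 2147483647 # 2^31 - 1
  x <- (abs(as.double(seed)) %% m)
  x <- (x * 48271 + as.double(stage) * 1299721 + 12345) %% m
  x <- (x * 69621) %% m
  as.integer(x) + 1L
}

# validate a samples x taxa count matrix
check_counts <- function(counts, what = "counts") {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop(what, " must be a numeric matrix (samples x taxa)")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop(what, " must have sample rownames and taxon colnames")
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts)))
    stop(what, " has duplicated sample or taxon ids")
  if (any(counts < 0)) stop(what, " contains negative values")
  invisible(counts)
}

check_design <- function(design) {
  need <- c("sample_id", "mycorrhizal_type", "diversity_level")
  miss <- setdiff(need, names(design))
  if (length(miss))
    stop("design table lacks column(s): ", paste(miss, collapse = ", "))
  design$mycorrhizal_type <- as.character(design$mycorrhizal_type)
  design$diversity_level <- as.character(design$diversity_level)
  design
}

#' Combination label for a design row
#'
#' @param design design table with `mycorrhizal_type` and `diversity_level`.
#' @return character vector like `"EcM|Mono"`, one per sample.
#' @export
combination_labels <- function(design) {
  design <- check_design(design)
  paste(design$mycorrhizal_type, design$diversity_level, sep = "|")
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between a detected and a reference partition,
#' computed on the ids common to both labelings.
#'
#' @param detected named vector of cluster labels.
#' @param reference named vector of reference labels.
#' @return list with `ari` and `n` (ids scored).
#' @export
score_partition_recovery <- function(detected, reference) {
  ids <- intersect(names(detected), names(reference))
  if (length(ids) < 2L) stop("fewer than two ids common to both partitions")
  list(ari = mclust::adjustedRandIndex(detected[ids], reference[ids]),
       n = length(ids))
}
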