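#' Construct or validate an EC nutrient-cycling catalog
#'
#' A catalog maps Enzyme Commission (EC) numbers to the nutrient cycles
#' (carbon, nitrogen, phosphorus) the enzyme participates in.  Cycles are
#' stored as a comma-separated subset of `C,N,P`.
#'
#' @param df data.frame with columns `ec`, `name`, `cycles`.
#' @return validated data.frame of class `ec_catalog`.
#' @export
ec_catalog <- function(df) {
  need <- c("ec", "name", "cycles")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("catalog lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(df) == 0L) stop("catalog is empty")
  if (anyDuplicated(df$ec)) stop("catalog has duplicated EC numbers")
  if (!all(grepl("^[0-9]+(\\.[0-9n]+){3}$", df$ec)))
    stop("EC numbers must look like a.b.c.d")
  cyc <- strsplit(as.character(df$cycles), ",", fixed = TRUE)
  bad <- vapply(cyc, function(x) length(x) == 0L || !all(x %in% c("C", "N", "P")),
                logical(1))
  if (any(bad))
    stop("invalid cycle label(s) for EC ", paste(df$ec[bad], collapse = ", "))
  out <- df[, need]
  class(out) <- c("ec_catalog", "data.frame")
  out
}

#' Built-in 57-enzyme C/N/P catalog
#'
#' Returns the catalog shipped with the package: 57 EC numbers covering
#' carbon (16), nitrogen (18) and phosphorus (23) cycling enzymes commonly
#' profiled in soil microbiome studies.  The catalog is a synthetic curation
#' assembled for this package; substitute your own via [ec_catalog()].
#'
#' @return an `ec_catalog` data.frame.
#' @export
#' @examples
#' cat57 <- nutrient_catalog()
#' table(cat57$cycles)
nutrient_catalog <- function() {
  path <- system.file("extdata", "ec_catalog_cnp57_synthetic.tsv",
                      package = "nutrinet", mustWork = TRUE)
  ec_catalog(read_table(path, schema = c(ec = "character", name = "character",
                                         cycles = "character")))
}

# list of cycle-label character vectors, named by EC
catalog_cycles <- function(catalog) {
  cyc <- strsplit(as.character(catalog$cycles), ",", fixed = TRUE)
  names(cyc) <- catalog$ec
  cyc
}

#' ECs belonging to a nutrient-cycle combination
#'
#' Membership uses the union rule: combination `CN` contains every EC
#' annotated to C or to N, so `CNP` always equals the full catalog.
#'
#' @param catalog an `ec_catalog`.
#' @param combo one of `"C","N","P","CN","CP","NP","CNP"`.
#' @return character vector of EC numbers.
#' @export
combo_ecs <- function(catalog, combo) {
  combo <- match.arg(combo, c("C", "N", "P", "CN", "CP", "NP", "CNP"))
  letters_wanted <- strsplit(combo, "")[[1]]
  cyc <- catalog_cycles(catalog)
  keep <- vapply(cyc, function(x) any(x %in% letters_wanted), logical(1))
  catalog$ec[keep]
}

#' All seven nutrient-cycle combinations
#' @return character vector `c("C","N","P","CN","CP","NP","CNP")`.
#' @export
nutrient_combinations <- function() c("C", "N", "P", "CN", "CP", "NP", "CNP")
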