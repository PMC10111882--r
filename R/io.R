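#' Read a schema-validated TSV table
#'
#' Reads a tab-separated table with a header row; lines starting with `#` are
#' ignored.  When `schema` is given, column presence and type are validated
#' and violations are reported by column name.
#'
#' @param path file path.
#' @param schema optional named character vector mapping column name to one of
#'   `"character"`, `"numeric"`, `"integer"`.
#' @return a data.frame.  An empty-but-headered file yields a 0-row table.
#' @export
read_table <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(schema)) {
    miss <- setdiff(names(schema), names(df))
    if (length(miss))
      stop("table ", path, " lacks column(s): ", paste(miss, collapse = ", "))
    for (col in names(schema)) {
      ok <- switch(schema[[col]],
        character = is.character(df[[col]]) || nrow(df) == 0L,
        numeric   = is.numeric(df[[col]])  || nrow(df) == 0L,
        integer   = (is.numeric(df[[col]]) &&
                       all(df[[col]] == round(df[[col]]))) || nrow(df) == 0L,
        stop("unknown schema type: ", schema[[col]]))
      if (!ok)
        stop("column '", col, "' in ", path, " is not of type ", schema[[col]])
    }
  }
  df
}

#' Write a TSV table
#'
#' @param df data.frame (or matrix, written with a leading id column named by
#'   `id_col`).
#' @param path output path.
#' @param id_col name for the rownames column when `df` is a matrix.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path, id_col = "id") {
  if (is.matrix(df)) {
    df <- data.frame(rownames(df), df, check.names = FALSE,
                     stringsAsFactors = FALSE)
    names(df)[1] <- id_col
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# matrix <-> TSV helpers (first column = row ids)
write_matrix_tsv <- function(m, path, id_col = "id") {
  write_table(m, path, id_col = id_col)
}

read_matrix_tsv <- function(path) {
  df <- read_table(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- as.character(df[[1]])
  m
}

#' Export a network as an edge-list TSV (and optionally GraphML)
#'
#' @param network a `mb_network` object (see [stability_select()]).
#' @param path output TSV path.
#' @param graphml optional GraphML path.
#' @return `path`, invisibly.
#' @export
export_network <- function(network, path, graphml = NULL) {
  g <- network$graph
  el <- igraph::as_edgelist(g)
  df <- data.frame(from = el[, 1], to = el[, 2],
                   from_kingdom = igraph::V(g)$kingdom[match(el[, 1], igraph::V(g)$name)],
                   to_kingdom = igraph::V(g)$kingdom[match(el[, 2], igraph::V(g)$name)],
                   stringsAsFactors = FALSE)
  write_table(df, path)
  if (!is.null(graphml)) igraph::write_graph(g, graphml, format = "graphml")
  invisible(path)
}
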