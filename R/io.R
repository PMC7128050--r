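#' Read and write the pipeline's tabular file formats
#'
#' Expression matrices are features x samples TSV with a header row of sample
#' ids and feature ids in the first column. The clinical table has columns
#' `sample_id`, `stage` (`low`, `III`, `IV`, or raw `I`/`II` which are merged
#' at load time), `os_time` and `os_event`. PPI edge lists use the STRING
#' dialect (`protein1`, `protein2`, `combined_score` on the 0-1000 scale).
#' Interaction catalogs have `regulator_id`, `target_id`, `target_class`.
#'
#' @param path file path.
#' @return `read_expression_tsv` returns a numeric matrix with feature row
#'   names and sample column names.
#' @keywords internal
#' @name ncmod-io
NULL

read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  mat <- as.matrix(df[-1L])
  storage.mode(mat) <- "double"
  rownames(mat) <- ids
  mat
}

write_expression_tsv <- function(mat, path) {
  df <- data.frame(feature_id = rownames(mat), mat,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Read a gene-set collection in GMT format
#'
#' Standard GMT: one set per line, tab separated: set name, description,
#' then member gene ids. `write_gmt` is the inverse.
#'
#' @param path file path.
#' @return named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad)) {
    stopf("malformed GMT line(s) %s in %s (need name, description, >=1 gene)",
          paste(bad, collapse = ", "), path)
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, "", 1L)
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @param descriptions optional character vector of set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Write or read a network in GraphML
#'
#' Thin wrappers around [igraph::write_graph()] / [igraph::read_graph()] so
#' every module serializes networks the same way.
#'
#' @param graph an igraph object.
#' @param path file path.
#' @return `read_graphml` returns an igraph object.
#' @export
write_graphml <- function(graph, path) {
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}

#' @rdname write_graphml
#' @export
read_graphml <- function(path) {
  igraph::read_graph(path, format = "graphml")
}
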