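# Plain-text readers and writers for the pipeline's standard formats:
# TSV matrices, edge lists, SIF, GraphML (via igraph), FASTA (via
# Biostrings), seed lists and motif tables.

#' Write / read a genes x columns numeric matrix as TSV
#'
#' First column `gene_id`, header row of sample/array IDs.
#'
#' @param values numeric matrix with rownames.
#' @param path file path.
#' @return `read_matrix_tsv` returns the numeric matrix.
#' @export
write_matrix_tsv <- function(values, path) {
  df <- data.frame(gene_id = rownames(values), values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write a weighted edge list as 3-column TSV
#'
#' @param net an [igraph::graph] with optional `weight` edge attribute, or
#'   a data frame `from`, `to`, `r2`.
#' @param path file path.
#' @export
write_edges_tsv <- function(net, path) {
  if (inherits(net, "igraph")) {
    el <- igraph::as_data_frame(net, what = "edges")
    names(el)[names(el) == "weight"] <- "r2"
  } else el <- net
  el <- el[order(el$from, el$to), c("from", "to", "r2"), drop = FALSE]
  write.table(el, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edges_tsv
#' @export
read_edges_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Export a network in SIF format (Cytoscape interchange)
#'
#' One `source co_expressed target` line per edge; isolated nodes written
#' as bare node lines.
#'
#' @param net an [igraph::graph].
#' @param path file path.
#' @export
write_sif <- function(net, path) {
  el <- igraph::as_data_frame(net, what = "edges")
  lines <- sprintf("%s\tco_expressed\t%s", el$from, el$to)
  isolated <- setdiff(igraph::V(net)$name,
                      unique(c(el$from, el$to)))
  writeLines(c(sort(lines), sort(isolated)), path)
  invisible(path)
}

#' Export a network in GraphML format
#'
#' @param net an [igraph::graph].
#' @param path file path.
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(net, path, format = "graphml")
  invisible(path)
}

#' Write / read promoter sequences as FASTA
#'
#' @param sequences named character vector of sequences.
#' @param path file path.
#' @return `read_promoters_fasta` returns a named character vector.
#' @export
write_promoters_fasta <- function(sequences, path) {
  x <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

#' @rdname write_promoters_fasta
#' @export
read_promoters_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Read a seed gene list (one ID per line)
#'
#' Blank lines and `#` comments are ignored.
#'
#' @param path file path.
#' @return Character vector of gene IDs.
#' @export
read_seed_list <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Read a known-motif table (TSV: name, IUPAC pattern)
#'
#' @param path file path.
#' @return Data frame `name`, `pattern`.
#' @export
read_motif_table <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   comment.char = "#")
  stopifnot(all(c("name", "pattern") %in% names(df)))
  df
}
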