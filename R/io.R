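# Plain-text I/O: dense matrix TSVs (header row + leading column of node
# ids), node metadata tables, time-series panels. Round trips reproduce
# values to full double precision.

#' Write a weighted network as a dense TSV
#'
#' Header row of node ids, first column of node ids (`node_id`), full
#' double-precision values.
#'
#' @param net A `weighted_network`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_network_tsv <- function(net, path) {
  stopifnot(inherits(net, "weighted_network"))
  df <- data.frame(node_id = net$nodes,
                   format(net$weights, digits = 17, trim = TRUE,
                          scientific = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("node_id", net$nodes)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a weighted network from a dense TSV
#'
#' Expects the layout written by [write_network_tsv]. Rejects (naming the
#' offending entries) missing values, duplicate node ids, row/column id
#' mismatches, asymmetry beyond 1e-9 and a nonzero diagonal.
#'
#' @param path Input file.
#' @return A `weighted_network`.
#' @export
read_network_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (colnames(df)[1] != "node_id")
    stop("first column must be 'node_id': ", path)
  nodes <- as.character(df[[1]])
  W <- as.matrix(df[, -1, drop = FALSE])
  if (!identical(colnames(W), nodes))
    stop("row and column node ids disagree in ", path)
  if (anyNA(W)) {
    bad <- which(is.na(W), arr.ind = TRUE)[1, ]
    stop(sprintf("missing value at [%s, %s] in %s",
                 nodes[bad[1]], nodes[bad[2]], path))
  }
  storage.mode(W) <- "double"
  weighted_network(W, nodes = nodes)   # validates symmetry/diagonal/dupes
}

#' Read a node partition from a TSV
#'
#' Columns `node_id`, `hemisphere` (L/R), `rsn` (one of [RSN_LABELS]);
#' unknown labels are rejected with the allowed list.
#'
#' @param path Input file.
#' @return A `node_partition`.
#' @export
read_partition_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("node_id", "hemisphere", "rsn")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("partition file missing column(s): ",
                         paste(miss, collapse = ", "))
  node_partition(df$node_id, df$hemisphere, df$rsn)
}

#' Write a time-series panel as TSV
#'
#' @param panel A `timeseries_panel`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_timeseries_tsv <- function(panel, path) {
  stopifnot(inherits(panel, "timeseries_panel"))
  df <- as.data.frame(format(panel$data, digits = 17, trim = TRUE,
                             scientific = TRUE), check.names = FALSE)
  colnames(df) <- panel$nodes
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a time-series panel from TSV
#'
#' Rows = timepoints, columns = nodes, header = node ids.
#'
#' @param path Input file.
#' @return A `timeseries_panel`.
#' @export
read_timeseries_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  X <- as.matrix(df)
  storage.mode(X) <- "double"
  timeseries_panel(X, nodes = colnames(df))
}
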