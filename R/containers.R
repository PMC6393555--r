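# Core containers: weighted networks, multiplex pairs, node partitions,
# time-series panels. All are plain S3 wrappers around base matrices so that
# downstream statistics stay transparent and easy to audit.

#' The seven canonical resting-state network labels
#'
#' Cortical subsystems of the widely used seven-network resting-state
#' parcellation. Every node partition must draw its `rsn` labels from this set.
#'
#' @export
RSN_LABELS <- c("Visual", "Somatomotor", "DorsalAttention", "VentralAttention",
                "Limbic", "FrontoParietal", "DefaultMode")

# numeric tolerance below which a weight is treated as absent
.WEIGHT_EPS <- 1e-12

#' Construct a weighted network layer
#'
#' A layer of the multiplex model: an ordered node set together with a
#' symmetric signed weight matrix with zero diagonal. Structural connectivity
#' (SC) layers carry nonnegative streamline counts; functional connectivity
#' (FC) layers carry signed partial correlations in \[-1, 1\]. Adjacency,
#' degree and strength are derived, never stored.
#'
#' @param weights Symmetric numeric matrix; diagonal must be (numerically)
#'   zero. Asymmetry beyond `1e-9` is an error.
#' @param nodes Character vector of node ids, one per row/column. Defaults to
#'   existing dimnames or `n1..nN`.
#' @return An object of class `weighted_network`.
#' @export
weighted_network <- function(weights, nodes = NULL) {
  if (!is.matrix(weights) || !is.numeric(weights))
    stop("`weights` must be a numeric matrix")
  n <- nrow(weights)
  if (ncol(weights) != n) stop("`weights` must be square")
  if (anyNA(weights)) stop("`weights` contains missing values")
  asym <- max(abs(weights - t(weights)))
  if (asym > 1e-9) {
    bad <- which(abs(weights - t(weights)) == asym, arr.ind = TRUE)[1, ]
    stop(sprintf("weight matrix asymmetric at [%d, %d] (|w_ij - w_ji| = %.3g)",
                 bad[1], bad[2], asym))
  }
  if (max(abs(diag(weights))) > .WEIGHT_EPS)
    stop("weight matrix must have a zero diagonal")
  if (is.null(nodes)) {
    nodes <- rownames(weights)
    if (is.null(nodes)) nodes <- paste0("n", seq_len(n))
  }
  nodes <- as.character(nodes)
  if (length(nodes) != n) stop("`nodes` length must match matrix dimension")
  if (anyDuplicated(nodes)) stop("duplicate node ids: ",
                                 paste(nodes[duplicated(nodes)], collapse = ", "))
  weights <- (weights + t(weights)) / 2   # exact symmetry by construction
  diag(weights) <- 0
  dimnames(weights) <- list(nodes, nodes)
  structure(list(nodes = nodes, weights = weights), class = "weighted_network")
}

#' @export
print.weighted_network <- function(x, ...) {
  m <- n_edges(x)
  cat(sprintf("<weighted_network> %d nodes, %d edges, weights in [%.3g, %.3g]\n",
              length(x$nodes), m, min(x$weights), max(x$weights)))
  invisible(x)
}

#' Binary adjacency of a weighted network
#'
#' `A_ij = 1` whenever `|w_ij|` exceeds the numeric zero threshold (1e-12).
#'
#' @param net A `weighted_network`.
#' @return Integer 0/1 matrix.
#' @export
adjacency <- function(net) {
  stopifnot(inherits(net, "weighted_network"))
  a <- (abs(net$weights) > .WEIGHT_EPS) * 1L
  dimnames(a) <- dimnames(net$weights)
  a
}

#' Node degree (number of incident edges)
#'
#' @param net A `weighted_network`.
#' @return Named integer vector `k_i`.
#' @export
degree <- function(net) {
  rowSums(adjacency(net))
}

#' Node strength (signed sum of incident weights)
#'
#' The strength of node *i* is the sum of the weights of all its incident
#' edges. Weights are signed: in an FC layer a node whose positive and
#' negative edges balance out has strength near zero.
#'
#' @param net A `weighted_network`.
#' @param node Optional node id (or vector of ids); when omitted, returns the
#'   full named strength vector.
#' @param absolute If `TRUE` use absolute weights (sensitivity analysis only).
#' @return Numeric strength value(s).
#' @export
strength <- function(net, node = NULL, absolute = FALSE) {
  stopifnot(inherits(net, "weighted_network"))
  w <- if (absolute) abs(net$weights) else net$weights
  s <- rowSums(w)
  if (is.null(node)) return(s)
  miss <- setdiff(as.character(node), net$nodes)
  if (length(miss)) stop("unknown node(s): ", paste(miss, collapse = ", "))
  s[as.character(node)]
}

#' Number of (undirected) edges of a weighted network
#' @param net A `weighted_network`.
#' @return Integer edge count.
#' @export
n_edges <- function(net) {
  sum(adjacency(net)[upper.tri(net$weights)])
}

# edge list as an m x 2 integer index matrix (i < j), plus weights
.edge_list <- function(net) {
  idx <- which(upper.tri(net$weights) & abs(net$weights) > .WEIGHT_EPS,
               arr.ind = TRUE)
  list(i = idx[, 1], j = idx[, 2],
       w = net$weights[cbind(idx[, 1], idx[, 2])])
}

#' Construct a two-layer multiplex pair
#'
#' Couples an SC and an FC layer one-to-one: both layers must carry exactly
#' the same node ids in the same order, and every node is linked to its own
#' replica in the other layer (the coupling is implicit, not stored).
#'
#' @param sc,fc `weighted_network` layers on the same node set.
#' @return An object of class `multiplex_pair`.
#' @export
multiplex_pair <- function(sc, fc) {
  stopifnot(inherits(sc, "weighted_network"), inherits(fc, "weighted_network"))
  if (!identical(sc$nodes, fc$nodes))
    stop("SC and FC layers must share an identical ordered node set")
  structure(list(sc = sc, fc = fc, nodes = sc$nodes), class = "multiplex_pair")
}

#' @export
print.multiplex_pair <- function(x, ...) {
  cat(sprintf("<multiplex_pair> %d coupled nodes; SC: %d edges, FC: %d edges\n",
              length(x$nodes), n_edges(x$sc), n_edges(x$fc)))
  invisible(x)
}

#' Construct a node partition (hemisphere and resting-state network labels)
#'
#' @param nodes Character vector of node ids.
#' @param hemisphere Character vector in `{"L", "R"}`, one per node.
#' @param rsn Character vector of resting-state-network labels, one per node;
#'   must be drawn from [RSN_LABELS].
#' @return An object of class `node_partition` (a data.frame with columns
#'   `node_id`, `hemisphere`, `rsn`).
#' @export
node_partition <- function(nodes, hemisphere, rsn) {
  nodes <- as.character(nodes)
  hemisphere <- as.character(hemisphere)
  rsn <- as.character(rsn)
  if (length(hemisphere) != length(nodes) || length(rsn) != length(nodes))
    stop("`hemisphere` and `rsn` must have one entry per node")
  if (anyDuplicated(nodes)) stop("duplicate node ids in partition")
  bad_h <- setdiff(unique(hemisphere), c("L", "R"))
  if (length(bad_h)) stop("hemisphere labels must be 'L' or 'R'; found: ",
                          paste(bad_h, collapse = ", "))
  bad_r <- setdiff(unique(rsn), RSN_LABELS)
  if (length(bad_r))
    stop("unknown RSN label(s): ", paste(bad_r, collapse = ", "),
         "; allowed: ", paste(RSN_LABELS, collapse = ", "))
  structure(data.frame(node_id = nodes, hemisphere = hemisphere, rsn = rsn,
                       stringsAsFactors = FALSE),
            class = c("node_partition", "data.frame"))
}

#' Default hemisphere / RSN labelling
#'
#' First half of the node list is assigned to the left hemisphere, second half
#' to the right; within each hemisphere the seven RSN labels are assigned in
#' contiguous blocks of (near-)equal size.
#'
#' @param nodes Character vector of node ids.
#' @return A `node_partition`.
#' @export
default_partition <- function(nodes) {
  nodes <- as.character(nodes)
  n <- length(nodes)
  if (n < 2) stop("need at least 2 nodes to split into hemispheres")
  n_left <- ceiling(n / 2)
  hemi <- rep(c("L", "R"), c(n_left, n - n_left))
  blocks <- function(k) {
    sizes <- diff(round(seq(0, k, length.out = 8)))
    rep(RSN_LABELS, sizes)
  }
  node_partition(nodes, hemi, c(blocks(n_left), blocks(n - n_left)))
}

# validate that a partition covers exactly the nodes of a network
.check_partition <- function(part, nodes) {
  stopifnot(inherits(part, "node_partition"))
  miss <- setdiff(nodes, part$node_id)
  extra <- setdiff(part$node_id, nodes)
  if (length(miss)) stop("partition missing node(s): ",
                         paste(utils::head(miss, 5), collapse = ", "))
  if (length(extra)) stop("partition labels unknown node(s): ",
                          paste(utils::head(extra, 5), collapse = ", "))
  part[match(nodes, part$node_id), , drop = FALSE]
}

#' Construct a time-series panel
#'
#' One subject's regional time series: a timepoints x nodes matrix whose
#' columns follow the node ordering of the accompanying networks.
#'
#' @param data Numeric matrix, rows = timepoints, columns = nodes.
#' @param nodes Character node ids, one per column.
#' @return An object of class `timeseries_panel`.
#' @export
timeseries_panel <- function(data, nodes = NULL) {
  if (!is.matrix(data) || !is.numeric(data)) stop("`data` must be a numeric matrix")
  if (anyNA(data)) stop("time series contain missing values")
  if (nrow(data) < 2) stop("need at least 2 timepoints")
  if (is.null(nodes)) {
    nodes <- colnames(data)
    if (is.null(nodes)) nodes <- paste0("n", seq_len(ncol(data)))
  }
  nodes <- as.character(nodes)
  if (length(nodes) != ncol(data)) stop("`nodes` length must match column count")
  if (anyDuplicated(nodes)) stop("duplicate node ids")
  colnames(data) <- nodes
  structure(list(nodes = nodes, data = data, n_timepoints = nrow(data)),
            class = "timeseries_panel")
}

#' @export
print.timeseries_panel <- function(x, ...) {
  cat(sprintf("<timeseries_panel> %d timepoints x %d nodes\n",
              x$n_timepoints, length(x$nodes)))
  invisible(x)
}
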