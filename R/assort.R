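# Node-strength assortativity within layers, between subnetwork blocks and
# between the coupled layers of a multiplex pair.
#
# The within-layer coefficient is the edge-based Pearson correlation of
# endpoint strengths,
#
#   r = sum_ij (A_ij - k_i k_j / 2m) s_i s_j
#       -------------------------------------
#       sum_ij (k_i d_ij - k_i k_j / 2m) s_i s_j
#
# with A the binary adjacency, k_i the degree, s_i the signed strength, m the
# edge count and d_ij the Kronecker delta. This equals the Pearson correlation
# of the strengths at the two ends of an edge, taken over all 2m ordered edge
# endpoints; the Spearman variant replaces the strengths by their midranks
# over that same endpoint multiset (a node of degree k_i contributes its
# strength k_i times).

#' Assortativity value container
#'
#' Wraps an assortativity coefficient together with the number of edges it was
#' computed over and the correlation method. Degenerate inputs (fewer than two
#' edges, or zero variance of endpoint strengths) yield an explicit undefined
#' marker (`value = NA`) with a reason; undefined values are never reported as
#' zero.
#'
#' @param value Numeric in \[-1, 1\] or `NA` for undefined.
#' @param n_edges_used Number of (undirected) edges entering the statistic.
#' @param method `"pearson"` or `"spearman"`.
#' @param reason For undefined values, a short explanation.
#' @return An object of class `assortativity_value`.
#' @export
assortativity_value <- function(value, n_edges_used, method, reason = NULL) {
  structure(list(value = value, n_edges_used = as.integer(n_edges_used),
                 method = method, reason = reason),
            class = "assortativity_value")
}

#' @export
print.assortativity_value <- function(x, ...) {
  if (is_defined(x)) {
    cat(sprintf("<assortativity> %.6f (%s, %d edges)\n",
                x$value, x$method, x$n_edges_used))
  } else {
    cat(sprintf("<assortativity> undefined (%s): %s\n", x$method,
                if (is.null(x$reason)) "unknown" else x$reason))
  }
  invisible(x)
}

#' Is an assortativity value defined?
#' @param x An `assortativity_value`.
#' @return Logical.
#' @export
is_defined <- function(x) {
  inherits(x, "assortativity_value") && !is.na(x$value)
}

# midranks of strengths over the edge-endpoint multiset: node i appears k_i
# times, ties receive the average of the ranks they span. Nodes with k = 0 do
# not occur in the multiset; their rank is irrelevant (returned as 0).
.endpoint_midrank <- function(s, k) {
  r <- numeric(length(s))
  on <- which(k > 0)
  if (!length(on)) return(r)
  ord <- on[order(s[on])]
  mult <- k[ord]
  ends <- cumsum(mult)
  starts <- ends - mult + 1
  # merge runs of equal strength into tie groups
  g <- cumsum(c(1, diff(s[ord]) != 0))
  for (grp in split(seq_along(ord), g)) {
    r[ord[grp]] <- (starts[grp[1]] + ends[grp[length(grp)]]) / 2
  }
  r
}

# Core evaluator: assortativity of endpoint values s over adjacency A (may be
# a restricted adjacency; k is then the restricted degree).
.assort_matrix <- function(A, s, method) {
  k <- rowSums(A)
  twom <- sum(k)
  m <- twom / 2
  if (m < 2)
    return(assortativity_value(NA_real_, m, method,
                               "fewer than 2 edges in the (restricted) edge set"))
  if (method == "spearman") s <- .endpoint_midrank(s, k)
  ks <- sum(k * s)
  num <- as.numeric(t(s) %*% A %*% s) - ks^2 / twom
  den <- sum(k * s^2) - ks^2 / twom
  scale_ref <- max(sum(k * s^2), 1e-300)
  if (abs(den) <= 1e-12 * max(1, scale_ref))
    return(assortativity_value(NA_real_, m, method,
                               "zero variance of endpoint strengths"))
  assortativity_value(min(1, max(-1, num / den)), m, method)
}

#' Within-layer node-strength assortativity
#'
#' Edge-based correlation between the strengths of connected node pairs.
#' Positive values mean nodes of similar strength tend to be linked
#' (assortative mixing); negative values mean strong nodes preferentially
#' attach to weak ones (disassortative mixing).
#'
#' @param net A `weighted_network`.
#' @param method `"pearson"` (default) or `"spearman"` (midranks over the
#'   edge-endpoint multiset; invariant under monotone strength transforms).
#' @param absolute Use absolute weights for strengths (sensitivity analysis
#'   only; default `FALSE`, signed strengths).
#' @return An `assortativity_value`.
#' @export
within_layer_assortativity <- function(net, method = c("pearson", "spearman"),
                                       absolute = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(net, "weighted_network"))
  .assort_matrix(adjacency(net), strength(net, absolute = absolute), method)
}

#' Block (subnetwork-pair) assortativity
#'
#' Restricts the assortativity sums to the edges running between two
#' resting-state-network blocks (or inside one block when `block_a ==
#' block_b`), filling one cell of the 7 x 7 block matrix.
#'
#' @param net A `weighted_network`.
#' @param part A `node_partition` covering the network's nodes.
#' @param block_a,block_b RSN labels (see [RSN_LABELS]).
#' @param strength_scope `"block"` recomputes degrees and strengths from the
#'   restricted edge set alone (self-contained, default); `"global"` keeps
#'   whole-network strengths and only restricts which edges enter the sums.
#' @param method `"pearson"` or `"spearman"`.
#' @return An `assortativity_value`; undefined (not zero) when fewer than two
#'   edges connect the blocks.
#' @export
block_assortativity <- function(net, part, block_a, block_b,
                                strength_scope = c("block", "global"),
                                method = c("pearson", "spearman")) {
  method <- match.arg(method)
  strength_scope <- match.arg(strength_scope)
  stopifnot(inherits(net, "weighted_network"))
  part <- .check_partition(part, net$nodes)
  for (b in c(block_a, block_b))
    if (!b %in% RSN_LABELS)
      stop("unknown RSN label '", b, "'; allowed: ",
           paste(RSN_LABELS, collapse = ", "))
  in_a <- part$rsn == block_a
  in_b <- part$rsn == block_b
  if (!any(in_a) || !any(in_b)) stop("empty block(s)")
  mask <- outer(in_a, in_b, "&") | outer(in_b, in_a, "&")
  diag(mask) <- FALSE
  Ar <- adjacency(net) * mask
  if (strength_scope == "block") {
    s <- rowSums(net$weights * mask)
  } else {
    s <- strength(net)
  }
  .assort_matrix(Ar, s, method)
}

#' Full 7 x 7 block-assortativity matrix
#'
#' Convenience wrapper evaluating [block_assortativity] for every ordered pair
#' of RSN labels. Cells whose restricted edge set is degenerate are `NA`.
#'
#' @inheritParams block_assortativity
#' @return A symmetric 7 x 7 numeric matrix (dimnames = RSN labels) with `NA`
#'   for undefined cells.
#' @export
block_assortativity_matrix <- function(net, part,
                                       strength_scope = c("block", "global"),
                                       method = c("pearson", "spearman")) {
  method <- match.arg(method)
  strength_scope <- match.arg(strength_scope)
  out <- matrix(NA_real_, 7, 7, dimnames = list(RSN_LABELS, RSN_LABELS))
  present <- which(RSN_LABELS %in% part$rsn)
  for (a in present) {
    for (b in present[present >= a]) {
      v <- block_assortativity(net, part, RSN_LABELS[a], RSN_LABELS[b],
                               strength_scope, method)
      out[a, b] <- out[b, a] <- v$value
    }
  }
  out
}

#' Between-layer (multiplex) strength assortativity
#'
#' Correlation of corresponding nodes' strengths across the two coupled
#' layers. Under one-to-one multiplex coupling every node has exactly one
#' interlayer link, so the edge-based assortativity statistic over the
#' coupling edges reduces to the correlation of the two strength vectors.
#'
#' @param mx A `multiplex_pair`.
#' @param node_subset Optional character vector of node ids (e.g. one RSN's
#'   nodes, or one hemisphere); default all nodes. At least 3 nodes required.
#' @param method `"pearson"` or `"spearman"`.
#' @param absolute Use absolute weights for strengths.
#' @return An `assortativity_value` (`n_edges_used` = number of coupling
#'   links, i.e. nodes).
#' @export
between_layer_assortativity <- function(mx, node_subset = NULL,
                                        method = c("pearson", "spearman"),
                                        absolute = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(mx, "multiplex_pair"))
  nodes <- if (is.null(node_subset)) mx$nodes else as.character(node_subset)
  miss <- setdiff(nodes, mx$nodes)
  if (length(miss)) stop("unknown node(s): ", paste(miss, collapse = ", "))
  if (length(nodes) < 3)
    stop("need at least 3 coupled nodes")
  s_sc <- strength(mx$sc, absolute = absolute)[nodes]
  s_fc <- strength(mx$fc, absolute = absolute)[nodes]
  if (stats::sd(s_sc) <= 1e-12 * max(1, mean(abs(s_sc))) ||
      stats::sd(s_fc) <= 1e-12 * max(1, mean(abs(s_fc))))
    return(assortativity_value(NA_real_, length(nodes), method,
                               "zero variance in a layer's strength vector"))
  v <- stats::cor(s_sc, s_fc, method = method)
  assortativity_value(min(1, max(-1, v)), length(nodes), method)
}

#' Restrict a network or multiplex pair to one hemisphere
#'
#' Returns the induced subnetwork(s) on the nodes of one hemisphere;
#' interhemispheric edges are dropped. All assortativity operations then apply
#' to the restricted object.
#'
#' @param x A `weighted_network` or `multiplex_pair`.
#' @param part A `node_partition` covering the nodes.
#' @param side `"L"` or `"R"`.
#' @return Object of the same class as `x`, restricted to `side`.
#' @export
hemisphere_split <- function(x, part, side = c("L", "R")) {
  side <- match.arg(side)
  UseMethod("hemisphere_split")
}

#' @export
hemisphere_split.weighted_network <- function(x, part, side = c("L", "R")) {
  side <- match.arg(side)
  part <- .check_partition(part, x$nodes)
  keep <- part$node_id[part$hemisphere == side]
  if (!length(keep)) stop("hemisphere '", side, "' is empty")
  idx <- match(keep, x$nodes)
  weighted_network(x$weights[idx, idx, drop = FALSE], nodes = keep)
}

#' @export
hemisphere_split.multiplex_pair <- function(x, part, side = c("L", "R")) {
  side <- match.arg(side)
  multiplex_pair(hemisphere_split(x$sc, part, side),
                 hemisphere_split(x$fc, part, side))
}

#' Restrict a node partition to one hemisphere
#'
#' @param part A `node_partition`.
#' @param side `"L"` or `"R"`.
#' @return A `node_partition` for that hemisphere's nodes.
#' @export
partition_side <- function(part, side = c("L", "R")) {
  side <- match.arg(side)
  stopifnot(inherits(part, "node_partition"))
  keep <- part$hemisphere == side
  if (!any(keep)) stop("hemisphere '", side, "' is empty")
  node_partition(part$node_id[keep], part$hemisphere[keep], part$rsn[keep])
}
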