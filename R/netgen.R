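# Synthetic weighted networks, degree-preserving assortativity rewiring and
# labelled multiplex cohorts with known ground truth.

#' Generate a random weighted network
#'
#' Draws a uniform random graph at the requested edge density and attaches
#' edge weights from one of two models: `lognormal-positive` (strictly
#' positive, heavy-tailed weights emulating tractography streamline counts,
#' SC-like) or `signed-sparse` (mixed-sign weights in \[-1, 1\] emulating
#' sparse partial correlations, FC-like; positive edges are more frequent, as
#' in empirical functional connectivity).
#'
#' @param n_nodes Number of nodes.
#' @param edge_density Fraction of the `n (n - 1) / 2` node pairs carrying an
#'   edge, in (0, 1].
#' @param weight_model `"lognormal-positive"` or `"signed-sparse"`.
#' @param seed Integer seed; the generator is a pure function of
#'   (parameters, seed).
#' @return A `weighted_network`.
#' @export
make_weighted_network <- function(n_nodes, edge_density,
                                  weight_model = c("lognormal-positive",
                                                   "signed-sparse"),
                                  seed = 1L) {
  weight_model <- match.arg(weight_model)
  if (!(edge_density > 0 && edge_density <= 1))
    stop("edge_density must be in (0, 1]")
  if (n_nodes < 2) stop("need at least 2 nodes")
  n_pairs <- n_nodes * (n_nodes - 1) / 2
  m <- round(edge_density * n_pairs)
  if (m < 2)
    stop("edge_density ", edge_density, " yields fewer than 2 edges at n = ",
         n_nodes)
  set.seed(seed)
  picked <- sample.int(n_pairs, m)
  w_vals <- switch(weight_model,
    "lognormal-positive" = stats::rlnorm(m, meanlog = 2, sdlog = 1),
    "signed-sparse" = stats::runif(m, 0.05, 0.8) *
      sample(c(-1, 1), m, replace = TRUE, prob = c(0.4, 0.6)))
  W <- matrix(0, n_nodes, n_nodes)
  ut <- which(upper.tri(W))
  W[ut[picked]] <- w_vals
  W <- W + t(W)
  weighted_network(W, nodes = paste0("n", seq_len(n_nodes)))
}

#' Rewire a network toward a target strength assortativity
#'
#' Greedy degree-preserving double-edge swaps: repeatedly propose swapping the
#' endpoints of two randomly chosen disjoint edges and accept a swap only if
#' it moves the measured strength assortativity strictly toward `target`.
#' The binary degree sequence and the multiset of edge weights are exactly
#' preserved (weights travel with their edges); only which node pairs are
#' linked changes.
#'
#' If the target (within `tol`) cannot be reached within `max_iters`
#' proposals, the best-effort network is returned with the achieved value
#' recorded in its attributes -- never a silent success.
#'
#' @param net A `weighted_network` with at least 4 edges.
#' @param target Target assortativity in \[-1, 1\].
#' @param max_iters Maximum number of swap proposals.
#' @param tol Convergence tolerance on |achieved - target|.
#' @param seed Integer seed.
#' @return A `weighted_network` with attributes `achieved` (final
#'   assortativity), `n_swaps` (accepted swaps), `n_proposals`, and
#'   `converged` (logical).
#' @export
rewire_to_target_assortativity <- function(net, target, max_iters = 20000L,
                                           tol = 0.02, seed = 1L) {
  stopifnot(inherits(net, "weighted_network"))
  if (target < -1 || target > 1) stop("target must be in [-1, 1]")
  el <- .edge_list(net)
  m <- length(el$w)
  if (m < 4) stop("need at least 4 edges to rewire")
  n <- length(net$nodes)
  e1 <- el$i; e2 <- el$j; w <- el$w
  s <- strength(net)
  names(s) <- NULL
  adj <- adjacency(net) > 0
  r_cur <- .assort_from_endpoints(s[e1], s[e2])
  if (is.na(r_cur)) stop("assortativity undefined on input network")
  if (abs(r_cur - target) <= tol) {
    out <- net
    attr(out, "achieved") <- r_cur
    attr(out, "n_swaps") <- 0L
    attr(out, "n_proposals") <- 0L
    attr(out, "converged") <- TRUE
    return(out)
  }
  set.seed(seed)
  n_swaps <- 0L
  it <- 0L
  # pre-draw proposal randomness in blocks to keep the loop cheap
  while (it < max_iters && abs(r_cur - target) > tol) {
    block <- min(2000L, max_iters - it)
    pe <- matrix(sample.int(m, 2L * block, replace = TRUE), ncol = 2)
    po <- sample(c(TRUE, FALSE), block, replace = TRUE)
    for (b in seq_len(block)) {
      it <- it + 1L
      ea <- pe[b, 1]; eb <- pe[b, 2]
      if (ea == eb) next
      a <- e1[ea]; bb <- e2[ea]; cc <- e1[eb]; d <- e2[eb]
      if (length(unique(c(a, bb, cc, d))) < 4) next
      if (po[b]) { # (a,b)+(c,d) -> (a,d)+(c,b)
        na1 <- a; nb1 <- d; na2 <- cc; nb2 <- bb
        ch_up <- d; ch_dn <- bb     # node gaining w[ea], node losing it
      } else {     # (a,b)+(c,d) -> (a,c)+(b,d)
        na1 <- a; nb1 <- cc; na2 <- bb; nb2 <- d
        ch_up <- cc; ch_dn <- bb
      }
      if (adj[na1, nb1] || adj[na2, nb2]) next
      dw <- w[ea] - w[eb]
      s_new <- s
      s_new[ch_up] <- s_new[ch_up] + dw
      s_new[ch_dn] <- s_new[ch_dn] - dw
      e1_new <- e1; e2_new <- e2
      e1_new[ea] <- na1; e2_new[ea] <- nb1
      e1_new[eb] <- na2; e2_new[eb] <- nb2
      r_new <- .assort_from_endpoints(s_new[e1_new], s_new[e2_new])
      if (is.na(r_new)) next
      if (abs(r_new - target) < abs(r_cur - target)) {
        adj[a, bb] <- adj[bb, a] <- FALSE
        adj[cc, d] <- adj[d, cc] <- FALSE
        adj[na1, nb1] <- adj[nb1, na1] <- TRUE
        adj[na2, nb2] <- adj[nb2, na2] <- TRUE
        e1 <- e1_new; e2 <- e2_new
        s <- s_new
        r_cur <- r_new
        n_swaps <- n_swaps + 1L
        if (abs(r_cur - target) <= tol) break
      }
    }
  }
  W <- matrix(0, n, n)
  W[cbind(e1, e2)] <- w
  W[cbind(e2, e1)] <- w
  out <- weighted_network(W, nodes = net$nodes)
  attr(out, "achieved") <- r_cur
  attr(out, "n_swaps") <- n_swaps
  attr(out, "n_proposals") <- it
  attr(out, "converged") <- abs(r_cur - target) <= tol
  out
}

#' Specification of a synthetic multiplex cohort
#'
#' Bundles the knobs of [generate_cohort]: cohort and network size, target
#' within-layer assortativities for the SC and FC layers, the target
#' between-layer strength correlation, edge densities, and the between-subject
#' weight jitter.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param n_nodes Nodes per layer (>= 8).
#' @param target_sc_assort,target_fc_assort,target_between_assort Targets in
#'   \[-1, 1\].
#' @param edge_density_sc,edge_density_fc Densities in (0, 1].
#' @param noise_sd Nonnegative between-subject weight jitter (log-normal
#'   multiplicative for SC, additive for FC).
#' @param seed Integer master seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 30L, n_nodes = 100L,
                        target_sc_assort = 0.10, target_fc_assort = -0.15,
                        target_between_assort = 0.10,
                        edge_density_sc = 0.15, edge_density_fc = 0.10,
                        noise_sd = 0.05, seed = 1L) {
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  if (n_nodes < 8) stop("n_nodes must be >= 8")
  for (d in c(edge_density_sc, edge_density_fc))
    if (!(d > 0 && d <= 1)) stop("edge densities must be in (0, 1]")
  for (t in c(target_sc_assort, target_fc_assort, target_between_assort))
    if (t < -1 || t > 1) stop("assortativity targets must be in [-1, 1]")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  structure(list(n_subjects = as.integer(n_subjects),
                 n_nodes = as.integer(n_nodes),
                 target_sc_assort = target_sc_assort,
                 target_fc_assort = target_fc_assort,
                 target_between_assort = target_between_assort,
                 edge_density_sc = edge_density_sc,
                 edge_density_fc = edge_density_fc,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "cohort_spec")
}

# blend FC edge weights toward (or away from) SC strengths so that the
# between-layer strength correlation approaches `target`; mixing coefficient
# found by bisection. Returns the blended weighted_network.
.blend_between <- function(fc, s_sc, target, tol = 0.02) {
  el <- .edge_list(fc)
  if (length(el$w) < 2) return(fc)
  z <- as.numeric(scale(s_sc))
  if (any(!is.finite(z))) return(fc)
  sgn <- if (target < 0) -1 else 1
  u <- sgn * (z[el$i] + z[el$j]) / 2 * stats::sd(abs(el$w))
  n <- length(fc$nodes)
  build <- function(gamma) {
    w_new <- (1 - gamma) * el$w + gamma * u
    # keep edges present (support preservation) and FC-scaled
    w_new <- sign(w_new + (w_new == 0) * 1e-6) * pmax(abs(w_new), 1e-4)
    w_new <- pmin(1, pmax(-1, w_new))
    W <- matrix(0, n, n)
    W[cbind(el$i, el$j)] <- w_new
    W[cbind(el$j, el$i)] <- w_new
    weighted_network(W, nodes = fc$nodes)
  }
  f <- function(gamma) {
    stats::cor(strength(build(gamma)), s_sc) - target
  }
  f0 <- f(0)
  if (abs(f0) <= tol) return(build(0))
  f1 <- f(1)
  if (sign(f0) == sign(f1)) {
    # target unreachable: return the closer endpoint (best effort)
    return(build(if (abs(f0) <= abs(f1)) 0 else 1))
  }
  lo <- 0; hi <- 1
  flo <- f0
  for (iter in 1:40) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm) <= tol) return(build(mid))
    if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
  }
  build((lo + hi) / 2)
}

#' Generate a labelled synthetic multiplex cohort
#'
#' For each subject, an SC-like layer (lognormal-positive weights) and an
#' FC-like layer (signed-sparse weights) are drawn independently, rewired by
#' degree-preserving swaps toward the target within-layer assortativities,
#' jittered by `noise_sd` so subjects differ, and finally the FC edge weights
#' are blended toward the SC strength profile by bisection so the
#' between-layer strength correlation approaches its target. All subjects
#' share the node set and the hemisphere/RSN partition ([default_partition]
#' unless overridden).
#'
#' Joint targets may be infeasible; the achieved per-subject values are always
#' reported in the `achieved` element, never silently dropped.
#'
#' @param spec A `cohort_spec`.
#' @param partition Optional `node_partition`; default [default_partition].
#' @param rewire_iters Swap-proposal budget per layer.
#' @return An object of class `mx_cohort`: list with `subjects` (list of
#'   `multiplex_pair`), `partition`, `spec` and `achieved` (data.frame of
#'   per-subject measured within-SC, within-FC and between-layer values).
#' @export
generate_cohort <- function(spec, partition = NULL, rewire_iters = 20000L) {
  stopifnot(inherits(spec, "cohort_spec"))
  nodes <- paste0("n", seq_len(spec$n_nodes))
  if (is.null(partition)) partition <- default_partition(nodes)
  partition <- .check_partition(partition, nodes)
  subjects <- vector("list", spec$n_subjects)
  achieved <- data.frame(subject = seq_len(spec$n_subjects),
                         within_sc = NA_real_, within_fc = NA_real_,
                         between = NA_real_)
  for (k in seq_len(spec$n_subjects)) {
    sc <- make_weighted_network(spec$n_nodes, spec$edge_density_sc,
                                "lognormal-positive",
                                seed = .derive_seed(spec$seed, 11L, k))
    sc <- rewire_to_target_assortativity(sc, spec$target_sc_assort,
                                         max_iters = rewire_iters, tol = 0.02,
                                         seed = .derive_seed(spec$seed, 12L, k))
    fc <- make_weighted_network(spec$n_nodes, spec$edge_density_fc,
                                "signed-sparse",
                                seed = .derive_seed(spec$seed, 21L, k))
    fc <- rewire_to_target_assortativity(fc, spec$target_fc_assort,
                                         max_iters = rewire_iters, tol = 0.02,
                                         seed = .derive_seed(spec$seed, 22L, k))
    if (spec$noise_sd > 0) {
      set.seed(.derive_seed(spec$seed, 31L, k))
      Wsc <- sc$weights
      ut <- upper.tri(Wsc)
      jit <- exp(stats::rnorm(sum(ut), 0, spec$noise_sd))
      Wsc[ut] <- Wsc[ut] * jit
      Wsc[lower.tri(Wsc)] <- t(Wsc)[lower.tri(Wsc)]
      sc <- weighted_network(Wsc, nodes = nodes)
      Wfc <- fc$weights
      nz <- ut & abs(Wfc) > .WEIGHT_EPS
      eps <- stats::rnorm(sum(nz), 0, spec$noise_sd * stats::sd(abs(Wfc[nz])))
      Wfc[nz] <- pmin(1, pmax(-1, Wfc[nz] + eps))
      Wfc[nz][abs(Wfc[nz]) < 1e-4] <- 1e-4   # jitter must not delete edges
      Wfc[lower.tri(Wfc)] <- t(Wfc)[lower.tri(Wfc)]
      fc <- weighted_network(Wfc, nodes = nodes)
    }
    fc <- .blend_between(fc, strength(sc), spec$target_between_assort)
    sc <- weighted_network(sc$weights, nodes = nodes)  # drop rewire attrs
    mx <- multiplex_pair(sc, fc)
    subjects[[k]] <- mx
    achieved$within_sc[k] <- within_layer_assortativity(sc)$value
    achieved$within_fc[k] <- within_layer_assortativity(fc)$value
    achieved$between[k] <- between_layer_assortativity(mx)$value
  }
  structure(list(subjects = subjects, partition = partition, spec = spec,
                 achieved = achieved),
            class = "mx_cohort")
}

#' @export
print.mx_cohort <- function(x, ...) {
  cat(sprintf("<mx_cohort> %d subjects, %d nodes\n",
              length(x$subjects), x$spec$n_nodes))
  cat(sprintf("  achieved medians: within-SC %.3f, within-FC %.3f, between %.3f\n",
              stats::median(x$achieved$within_sc, na.rm = TRUE),
              stats::median(x$achieved$within_fc, na.rm = TRUE),
              stats::median(x$achieved$between, na.rm = TRUE)))
  invisible(x)
}

#' Inject a lateralized assortativity shift into a cohort
#'
#' Rewires the induced single-hemisphere subgraph of one layer of every
#' subject toward (its current within-hemisphere assortativity - `shift`),
#' using degree-preserving swaps confined to that hemisphere's intra-
#' hemispheric edges. Interhemispheric edges, the global degree sequence and
#' the edge-weight multiset are untouched. Used to create a known ground-truth
#' hemispheric difference for validating the lateralization test.
#'
#' @param cohort An `mx_cohort`.
#' @param shift Amount by which to lower the within-hemisphere assortativity
#'   (positive = more disassortative).
#' @param layer `"fc"` or `"sc"`.
#' @param side `"L"` or `"R"`.
#' @param seed Integer seed.
#' @param max_iters Swap budget per subject.
#' @return The modified `mx_cohort` (achieved values re-measured).
#' @export
inject_lateralized_shift <- function(cohort, shift, layer = c("fc", "sc"),
                                     side = c("L", "R"), seed = 1L,
                                     max_iters = 20000L) {
  layer <- match.arg(layer)
  side <- match.arg(side)
  stopifnot(inherits(cohort, "mx_cohort"))
  part <- cohort$partition
  idx <- match(part$node_id[part$hemisphere == side], cohort$subjects[[1]]$nodes)
  for (k in seq_along(cohort$subjects)) {
    mx <- cohort$subjects[[k]]
    net <- mx[[layer]]
    sub <- weighted_network(net$weights[idx, idx, drop = FALSE],
                            nodes = net$nodes[idx])
    cur <- within_layer_assortativity(sub)$value
    if (is.na(cur)) next
    sub2 <- rewire_to_target_assortativity(
      sub, max(-1, cur - shift), max_iters = max_iters, tol = 0.02,
      seed = .derive_seed(seed, 41L, k))
    W <- net$weights
    W[idx, idx] <- sub2$weights
    net2 <- weighted_network(W, nodes = net$nodes)
    mx <- if (layer == "fc") multiplex_pair(mx$sc, net2) else
      multiplex_pair(net2, mx$fc)
    cohort$subjects[[k]] <- mx
    cohort$achieved$within_sc[k] <- within_layer_assortativity(mx$sc)$value
    cohort$achieved$within_fc[k] <- within_layer_assortativity(mx$fc)$value
    cohort$achieved$between[k] <- between_layer_assortativity(mx)$value
  }
  cohort
}

#' Write a cohort to disk
#'
#' Per-subject dense matrix TSVs (`sub-<k>_sc.tsv`, `sub-<k>_fc.tsv`), one
#' `nodes.tsv` (columns `node_id`, `hemisphere`, `rsn`), and a `cohort.json`
#' manifest recording the generating spec and the achieved per-subject
#' targets.
#'
#' @param cohort An `mx_cohort`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "mx_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (k in seq_along(cohort$subjects)) {
    mx <- cohort$subjects[[k]]
    write_network_tsv(mx$sc, file.path(dir, sprintf("sub-%03d_sc.tsv", k)))
    write_network_tsv(mx$fc, file.path(dir, sprintf("sub-%03d_fc.tsv", k)))
  }
  utils::write.table(as.data.frame(cohort$partition),
                     file.path(dir, "nodes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(spec = unclass(cohort$spec), achieved = cohort$achieved)
  jsonlite::write_json(manifest, file.path(dir, "cohort.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
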