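# Independent oracles and small fixture builders used across the suite.

# Brute-force assortativity: explicitly enumerate the 2m ordered
# edge-endpoint strength pairs and hand them to stats::cor. Completely
# independent of the package's matrix-form evaluator.
oracle_assort <- function(net, method = "pearson", s = NULL) {
  if (is.null(s)) s <- strength(net)
  W <- net$weights
  idx <- which(upper.tri(W) & abs(W) > 1e-12, arr.ind = TRUE)
  if (nrow(idx) < 2) return(NA_real_)
  x <- s[idx[, 1]]; y <- s[idx[, 2]]
  X <- c(x, y); Y <- c(y, x)
  if (stats::sd(X) < 1e-12 || stats::sd(Y) < 1e-12) return(NA_real_)
  stats::cor(X, Y, method = method)
}

# brute-force restricted (block) oracle with explicit endpoint enumeration
oracle_block_assort <- function(net, part, a, b, scope = "block",
                                method = "pearson") {
  W <- net$weights
  in_a <- part$rsn == a; in_b <- part$rsn == b
  mask <- (outer(in_a, in_b, "&") | outer(in_b, in_a, "&"))
  diag(mask) <- FALSE
  keep <- upper.tri(W) & abs(W) > 1e-12 & mask
  idx <- which(keep, arr.ind = TRUE)
  if (nrow(idx) < 2) return(NA_real_)
  s <- if (scope == "global") strength(net) else rowSums(W * mask)
  x <- s[idx[, 1]]; y <- s[idx[, 2]]
  X <- c(x, y); Y <- c(y, x)
  if (stats::sd(X) < 1e-12) return(NA_real_)
  stats::cor(X, Y, method = method)
}

# random weighted test network (mixed-sign or positive weights)
rand_net <- function(n, density = 0.3, signed = FALSE, seed = 1) {
  set.seed(seed)
  W <- matrix(0, n, n)
  ut <- which(upper.tri(W))
  m <- max(2, round(density * length(ut)))
  picked <- sample(ut, m)
  w <- stats::runif(m, 0.2, 2)
  if (signed) w <- w * sample(c(-1, 1), m, replace = TRUE)
  W[picked] <- w
  W <- W + t(W)
  weighted_network(W)
}

# partition assigning labels cyclically (irregular block sizes)
rand_partition <- function(nodes, seed = 1) {
  set.seed(seed)
  node_partition(nodes,
                 sample(c("L", "R"), length(nodes), replace = TRUE,
                        prob = c(0.5, 0.5)),
                 sample(RSN_LABELS, length(nodes), replace = TRUE))
}

# exact enumeration of the sign-flip null for small n: two-tailed p of the
# median statistic over all 2^n sign patterns, with add-one correction
# matching the Monte-Carlo convention is NOT applied here (exact p).
oracle_exact_signflip_p <- function(d, statistic = stats::median) {
  n <- length(d)
  t_obs <- abs(statistic(d))
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  t_perm <- apply(signs * rep(d, each = nrow(signs)) , 1,
                  function(z) abs(statistic(z)))
  mean(t_perm >= t_obs - 1e-12)
}
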