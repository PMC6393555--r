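# Sparse functional connectivity as elastic-net regularized partial
# correlations, estimated node-wise by penalized regression.
#
# For each node i, its (z-scored) series y is regressed on all other nodes'
# series X under the elastic-net penalty
#
#   beta_hat = argmin ||y - X beta||^2 + lambda [ (1 - alpha)/2 ||beta||_2^2
#                                                 + alpha ||beta||_1 ]
#
# (glmnet parameterization; alpha = 1 is the LASSO). The two directed
# coefficient estimates are then symmetrized into a partial correlation:
#
#   rho_ij = sign(b_ij) * min{1, sqrt(b_ij * b_ji)}  if sign(b_ij) == sign(b_ji)
#          = 0                                        otherwise
#
# which keeps rho well-defined in [-1, 1] and sparse. (lambda, alpha) are
# chosen by k-fold cross-validation, either on a grid or by
# expected-improvement search over a Gaussian-process surrogate of the CV
# loss surface.

# coefficients treated as zero below this magnitude
.BETA_EPS <- 1e-10

#' Configuration for elastic-net FC estimation
#'
#' @param alpha_range L1/L2 mixing range, within (0, 1]; `alpha = 1` is pure
#'   LASSO.
#' @param lambda_range Penalty range on a *relative* scale: each node
#'   regression uses `lambda = rel * lambda_max_i`, where `lambda_max_i` is
#'   that regression's smallest all-zero penalty, so one shared relative
#'   penalty is comparable across nodes. Searched on a log scale.
#' @param n_folds Cross-validation folds (>= 2; default 10).
#' @param search_method `"ei-search"` (Gaussian-process surrogate, sampling
#'   where expected improvement is maximal) or `"grid"` (exhaustive lattice).
#' @param n_search_points Total CV evaluations (>= 3 for ei-search; for grid,
#'   the lattice is the most-square factorization of this count).
#' @param fold_scheme `"contiguous-blocks"` (default; respects temporal
#'   autocorrelation of real series) or `"random"`.
#' @param per_node Tune (lambda, alpha) separately for every node regression
#'   instead of once per subject (default `FALSE`: one pair per subject,
#'   minimizing CV loss averaged over all node regressions).
#' @param seed Integer seed for fold assignment and the search.
#' @return An object of class `elastic_net_config`.
#' @export
elastic_net_config <- function(alpha_range = c(0.05, 1),
                               lambda_range = c(1e-4, 1),
                               n_folds = 10L,
                               search_method = c("ei-search", "grid"),
                               n_search_points = 20L,
                               fold_scheme = c("contiguous-blocks", "random"),
                               per_node = FALSE,
                               seed = 1L) {
  search_method <- match.arg(search_method)
  fold_scheme <- match.arg(fold_scheme)
  if (n_folds < 2) stop("n_folds must be >= 2")
  if (!(alpha_range[1] > 0 && alpha_range[2] <= 1 &&
        alpha_range[1] <= alpha_range[2]))
    stop("alpha_range must lie within (0, 1]")
  if (!(lambda_range[1] > 0 && lambda_range[1] <= lambda_range[2]))
    stop("lambda_range must be positive and ordered")
  structure(list(alpha_range = alpha_range, lambda_range = lambda_range,
                 n_folds = as.integer(n_folds), search_method = search_method,
                 n_search_points = as.integer(n_search_points),
                 fold_scheme = fold_scheme, per_node = per_node,
                 seed = as.integer(seed)),
            class = "elastic_net_config")
}

# z-score panel columns; fails naming any constant column
.zscore_panel <- function(panel) {
  X <- panel$data
  sds <- apply(X, 2, stats::sd)
  if (any(sds <= .WEIGHT_EPS))
    stop("constant time-series column(s): ",
         paste(panel$nodes[sds <= .WEIGHT_EPS], collapse = ", "))
  scale(X)
}

# smallest penalty with an all-zero solution for response column `i`
# (glmnet convention, intercept-free standardized data)
.lambda_max <- function(Z, i, alpha) {
  max(abs(crossprod(Z[, -i, drop = FALSE], Z[, i]))) /
    (nrow(Z) * max(alpha, 1e-3))
}

# single elastic-net fit at one absolute lambda; a short decreasing path is
# used for a warm-started, accurate solution at the target penalty
.glmnet_at <- function(x, y, alpha, lambda) {
  lmax <- max(abs(crossprod(x, y))) / (length(y) * max(alpha, 1e-3))
  if (lambda >= lmax) {
    fit <- glmnet::glmnet(x, y, alpha = alpha, lambda = lambda,
                          standardize = FALSE, intercept = FALSE,
                          thresh = 1e-10)
    return(as.numeric(fit$beta[, 1]))
  }
  path <- exp(seq(log(lmax), log(lambda), length.out = 25))
  fit <- glmnet::glmnet(x, y, alpha = alpha, lambda = path,
                        standardize = FALSE, intercept = FALSE,
                        thresh = 1e-10)
  as.numeric(fit$beta[, ncol(fit$beta)])
}

#' Elastic-net regression of one node on all others
#'
#' Fits the penalized regression of `node`'s (z-scored) series on all other
#' nodes' series at a fixed absolute penalty `lambda` and mixing `alpha`.
#' `alpha = 1` reduces to the pure L1 (LASSO) solution; very large `lambda`
#' shrinks every coefficient to exactly zero. Deterministic given its inputs.
#'
#' @param panel A `timeseries_panel` (z-scored internally).
#' @param node Node id (response).
#' @param lambda Absolute penalty (>= 0 scale of the standardized problem).
#' @param alpha Mixing parameter in (0, 1].
#' @return A list of class `node_regression` with `node`, `betas` (named
#'   coefficients, on the standardized scale, self excluded), `chosen_lambda`,
#'   `chosen_alpha`, `cv_loss` (`NA`; filled by the selection step).
#' @export
fit_node_regression <- function(panel, node, lambda, alpha) {
  stopifnot(inherits(panel, "timeseries_panel"))
  if (!(alpha > 0 && alpha <= 1)) stop("alpha must be in (0, 1]")
  if (lambda < 0) stop("lambda must be nonnegative")
  i <- match(as.character(node), panel$nodes)
  if (is.na(i)) stop("unknown node: ", node)
  Z <- .zscore_panel(panel)
  betas <- .glmnet_at(Z[, -i, drop = FALSE], Z[, i], alpha, lambda)
  names(betas) <- panel$nodes[-i]
  structure(list(node = as.character(node), betas = betas,
                 chosen_lambda = lambda, chosen_alpha = alpha,
                 cv_loss = NA_real_),
            class = "node_regression")
}

# fold assignment over timepoints
.make_folds <- function(n, n_folds, scheme, seed) {
  if (n < 2 * n_folds)
    stop("need at least 2 timepoints per fold (n_timepoints >= 2 * n_folds)")
  if (scheme == "contiguous-blocks") {
    sizes <- diff(round(seq(0, n, length.out = n_folds + 1)))
    rep(seq_len(n_folds), sizes)
  } else {
    set.seed(seed)
    sample(rep(seq_len(n_folds), length.out = n))
  }
}

# mean k-fold CV squared prediction error at one (rel_lambda, alpha),
# averaged over the node regressions in `node_idx`. One glmnet path per
# (node, fold) evaluates every rel_lambda in `rels` at once.
.cv_loss_multi <- function(Z, folds, rels, alpha, node_idx = NULL) {
  if (is.null(node_idx)) node_idx <- seq_len(ncol(Z))
  n_folds <- max(folds)
  tot <- numeric(length(rels))
  count <- 0
  for (i in node_idx) {
    lmax <- .lambda_max(Z, i, alpha)
    lams <- rels * lmax
    # dense warm-start path from lambda_max down past the smallest requested
    # penalty; predictions at the requested penalties interpolate on it
    path <- exp(seq(log(lmax), log(max(min(lams) * 0.9, lmax * 1e-6)),
                    length.out = 20))
    for (f in seq_len(n_folds)) {
      tr <- folds != f
      fit <- glmnet::glmnet(Z[tr, -i, drop = FALSE], Z[tr, i], alpha = alpha,
                            lambda = path, standardize = FALSE,
                            intercept = FALSE, thresh = 1e-9)
      pred <- stats::predict(fit, Z[!tr, -i, drop = FALSE], s = lams,
                             exact = FALSE)
      mse <- colMeans((pred - Z[!tr, i])^2)
      tot <- tot + mse
      count <- count + 1
    }
  }
  tot / count
}

# ---- Gaussian-process surrogate + expected improvement ---------------------

# squared-exponential GP with fixed length scale on [0,1]^2 coordinates
.gp_fit <- function(X, y, ell = 0.3) {
  mu <- mean(y)
  yc <- y - mu
  sf2 <- max(stats::var(y), 1e-12)
  D2 <- as.matrix(stats::dist(X))^2
  K <- sf2 * exp(-0.5 * D2 / ell^2)
  diag(K) <- diag(K) + 1e-8 + 1e-6 * sf2
  L <- chol(K)
  alpha_v <- backsolve(L, forwardsolve(t(L), yc))
  list(X = X, mu = mu, sf2 = sf2, ell = ell, L = L, alpha = alpha_v)
}

.gp_predict <- function(gp, Xnew) {
  d2 <- outer(rowSums(Xnew^2), rowSums(gp$X^2), "+") -
    2 * Xnew %*% t(gp$X)
  Ks <- gp$sf2 * exp(-0.5 * pmax(d2, 0) / gp$ell^2)
  mean_p <- gp$mu + as.numeric(Ks %*% gp$alpha)
  v <- forwardsolve(t(gp$L), t(Ks))
  var_p <- pmax(gp$sf2 - colSums(v^2), 1e-12)
  list(mean = mean_p, sd = sqrt(var_p))
}

.expected_improvement <- function(mean_p, sd_p, best) {
  z <- (best - mean_p) / sd_p
  (best - mean_p) * stats::pnorm(z) + sd_p * stats::dnorm(z)
}

#' Cross-validated hyperparameter selection
#'
#' Chooses the elastic-net penalty and mixing parameter minimizing mean
#' k-fold CV squared prediction error over all node regressions. `"grid"`
#' evaluates an exhaustive log-lambda x alpha lattice; `"ei-search"` seeds a
#' small space-filling design, fits a Gaussian-process surrogate of the CV
#' loss over the (log lambda, alpha) rectangle, and repeatedly evaluates the
#' point of maximal expected improvement until `n_search_points` evaluations
#' are spent. Seeded and reproducible.
#'
#' @param panel A `timeseries_panel`.
#' @param cfg An `elastic_net_config`.
#' @param node_idx Internal: restrict the CV loss to these response columns.
#' @return A list with `lambda` (selected *relative* penalty), `alpha`,
#'   `cv_loss` (CV loss at the selection) and `trace` (data.frame of every
#'   evaluated point: `rel_lambda`, `alpha`, `cv_loss`).
#' @export
select_hyperparameters <- function(panel, cfg = elastic_net_config(),
                                   node_idx = NULL) {
  stopifnot(inherits(panel, "timeseries_panel"),
            inherits(cfg, "elastic_net_config"))
  Z <- .zscore_panel(panel)
  folds <- .make_folds(nrow(Z), cfg$n_folds, cfg$fold_scheme, cfg$seed)
  lr <- log(cfg$lambda_range)
  ar <- cfg$alpha_range

  if (cfg$search_method == "grid") {
    np <- max(1L, cfg$n_search_points)
    # most-square lattice with np total points
    n1 <- max(1L, floor(sqrt(np)))
    while (np %% n1 != 0) n1 <- n1 - 1L
    n2 <- np %/% n1
    n_lam <- max(n1, n2); n_alp <- min(n1, n2)
    lam_grid <- if (n_lam == 1) exp(mean(lr)) else
      exp(seq(lr[1], lr[2], length.out = n_lam))
    alp_grid <- if (n_alp == 1) mean(ar) else
      seq(ar[1], ar[2], length.out = n_alp)
    trace <- NULL
    for (a in alp_grid) {
      losses <- .cv_loss_multi(Z, folds, lam_grid, a, node_idx)
      trace <- rbind(trace, data.frame(rel_lambda = lam_grid, alpha = a,
                                       cv_loss = losses))
    }
  } else {
    np <- cfg$n_search_points
    if (np < 3) stop("ei-search needs at least 3 evaluations")
    set.seed(.derive_seed(cfg$seed, 7L))
    n_init <- min(np, max(4L, ceiling(np / 3)))
    # stratified (jittered latin-hypercube) initial design on [0,1]^2
    u1 <- (sample(n_init) - stats::runif(n_init)) / n_init
    u2 <- (sample(n_init) - stats::runif(n_init)) / n_init
    pts <- cbind(u1, u2)
    eval_pt <- function(u) {
      rel <- exp(lr[1] + u[1] * (lr[2] - lr[1]))
      a <- ar[1] + u[2] * (ar[2] - ar[1])
      c(rel, a, .cv_loss_multi(Z, folds, rel, a, node_idx))
    }
    evals <- t(apply(pts, 1, eval_pt))
    # candidate set for the acquisition maximization
    cg <- as.matrix(expand.grid(seq(0, 1, length.out = 25),
                                seq(0, 1, length.out = 25)))
    while (nrow(evals) < np) {
      gp <- .gp_fit(pts, evals[, 3])
      pr <- .gp_predict(gp, cg)
      ei <- .expected_improvement(pr$mean, pr$sd, min(evals[, 3]))
      # never re-evaluate an existing point
      d2min <- apply(as.matrix(stats::dist(rbind(cg, pts)))[
        seq_len(nrow(cg)), nrow(cg) + seq_len(nrow(pts)), drop = FALSE],
        1, min)
      ei[d2min < 1e-3] <- -Inf
      pick <- cg[which.max(ei), ]
      pts <- rbind(pts, pick)
      evals <- rbind(evals, eval_pt(pick))
    }
    trace <- data.frame(rel_lambda = evals[, 1], alpha = evals[, 2],
                        cv_loss = evals[, 3])
  }
  best <- which.min(trace$cv_loss)
  list(lambda = trace$rel_lambda[best], alpha = trace$alpha[best],
       cv_loss = trace$cv_loss[best], trace = trace)
}

#' Symmetrize directed elastic-net coefficients into partial correlations
#'
#' Applies the sign-consistency rule to a square matrix `B` with
#' `B[i, j]` = coefficient of predictor *j* in the regression of node *i*:
#' `rho_ij = sign(B_ij) min{1, sqrt(B_ij B_ji)}` when the two directed
#' coefficients agree in sign, else 0. Coefficients of magnitude below
#' 1e-10 are treated as zero.
#'
#' @param B Square numeric matrix of directed coefficients (diagonal ignored).
#' @return Symmetric matrix with zero diagonal, entries in \[-1, 1\].
#' @export
symmetrize_partial_correlations <- function(B) {
  stopifnot(is.matrix(B), nrow(B) == ncol(B))
  Bt <- t(B)
  agree <- (B > .BETA_EPS & Bt > .BETA_EPS) |
    (B < -.BETA_EPS & Bt < -.BETA_EPS)
  rho <- matrix(0, nrow(B), ncol(B))
  rho[agree] <- sign(B[agree]) * pmin(1, sqrt(B[agree] * Bt[agree]))
  rho <- (rho + t(rho)) / 2   # exact symmetry (entries already equal)
  diag(rho) <- 0
  dimnames(rho) <- dimnames(B)
  rho
}

#' Estimate sparse functional connectivity from a time-series panel
#'
#' Full estimator: selects (lambda, alpha) by cross-validation
#' ([select_hyperparameters]), fits the elastic-net regression of every node
#' on all others at the chosen penalty (each node's absolute penalty is
#' `rel_lambda * lambda_max_i`), and symmetrizes the directed coefficients
#' into partial correlations ([symmetrize_partial_correlations]). The result
#' is sparse by construction and needs no further thresholding.
#'
#' @param panel A `timeseries_panel`.
#' @param cfg An `elastic_net_config`.
#' @return A `weighted_network` (subclass `partial_corr_matrix`) whose
#'   weights are the estimated partial correlations; attributes `lambda`
#'   (relative), `alpha`, `cv_loss` and `search_trace` record the selection.
#' @export
estimate_fc <- function(panel, cfg = elastic_net_config()) {
  stopifnot(inherits(panel, "timeseries_panel"))
  Z <- .zscore_panel(panel)
  p <- ncol(Z)
  if (p < 3) stop("need at least 3 nodes")
  B <- matrix(0, p, p, dimnames = list(panel$nodes, panel$nodes))
  if (cfg$per_node) {
    sel_list <- lapply(seq_len(p), function(i)
      select_hyperparameters(panel, cfg, node_idx = i))
    sel <- sel_list[[1]]   # recorded trace: first node's search
    for (i in seq_len(p)) {
      li <- sel_list[[i]]$lambda * .lambda_max(Z, i, sel_list[[i]]$alpha)
      B[i, -i] <- .glmnet_at(Z[, -i, drop = FALSE], Z[, i],
                             sel_list[[i]]$alpha, li)
    }
  } else {
    sel <- select_hyperparameters(panel, cfg)
    for (i in seq_len(p)) {
      li <- sel$lambda * .lambda_max(Z, i, sel$alpha)
      B[i, -i] <- .glmnet_at(Z[, -i, drop = FALSE], Z[, i], sel$alpha, li)
    }
  }
  rho <- symmetrize_partial_correlations(B)
  out <- weighted_network(rho, nodes = panel$nodes)
  class(out) <- c("partial_corr_matrix", class(out))
  attr(out, "lambda") <- sel$lambda
  attr(out, "alpha") <- sel$alpha
  attr(out, "cv_loss") <- sel$cv_loss
  attr(out, "search_trace") <- sel$trace
  out
}
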