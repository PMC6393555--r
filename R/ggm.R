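# Ground-truth Gaussian graphical models and sampled time series.
#
# A GGM is stored as a symmetric positive-definite precision matrix P; the
# implied partial correlations are rho_ij = -P_ij / sqrt(P_ii P_jj) (zero
# diagonal), and the support of rho equals the off-diagonal support of P.
# Chain and collider models reproduce the two textbook failure modes of naive
# connectivity estimates: a chain A-B-C has zero partial but nonzero marginal
# correlation between A and C, while a collider (A and B marginally
# independent causes of C) has zero marginal but nonzero partial correlation
# between A and B (Berkson's paradox).

# partial correlations implied by a precision matrix
.pcor_from_precision <- function(P) {
  d <- sqrt(diag(P))
  R <- -P / outer(d, d)
  diag(R) <- 0
  R
}

.ggm_model <- function(precision, nodes) {
  dimnames(precision) <- list(nodes, nodes)
  structure(list(nodes = nodes, precision = precision,
                 partial_corr = .pcor_from_precision(precision)),
            class = "ggm_model")
}

#' @export
print.ggm_model <- function(x, ...) {
  p <- x$partial_corr
  m <- sum(abs(p[upper.tri(p)]) > .WEIGHT_EPS)
  cat(sprintf("<ggm_model> %d nodes, %d conditional-dependence edges\n",
              length(x$nodes), m))
  invisible(x)
}

#' Construct a ground-truth Gaussian graphical model
#'
#' Builds a sparse precision matrix with a prescribed conditional-independence
#' structure:
#' \describe{
#'   \item{`chain`}{3 nodes A-B-C: edges A-B and B-C only, each with partial
#'     correlation `partial_corr_magnitude`; A and C are conditionally
#'     independent but marginally correlated.}
#'   \item{`collider`}{3 nodes where A and B are exactly marginally
#'     independent (zero covariance) yet conditionally dependent given C;
#'     `partial_corr_magnitude` sets \code{|rho_AC| = |rho_BC|}.}
#'   \item{`random-sparse`}{Erdos-Renyi support at `edge_density`, entries of
#'     magnitude `partial_corr_magnitude` with random sign; positive
#'     definiteness enforced by diagonal loading (adding `|lambda_min| + 0.1`
#'     when the smallest eigenvalue is not positive), which preserves support
#'     but shrinks the realized partial correlations.}
#' }
#'
#' @param structure One of `"chain"`, `"collider"`, `"random-sparse"`.
#' @param n_nodes Number of nodes (must be 3 for chain/collider).
#' @param edge_density Fraction of node pairs carrying an edge
#'   (random-sparse only).
#' @param partial_corr_magnitude Target magnitude of nonzero partial
#'   correlations, in (0, 0.9].
#' @param seed Integer seed (random-sparse only; chain/collider are
#'   deterministic).
#' @return A `ggm_model` with fields `nodes`, `precision`, `partial_corr`.
#' @export
make_ggm <- function(structure = c("chain", "collider", "random-sparse"),
                     n_nodes = 3, edge_density = 0.2,
                     partial_corr_magnitude = 0.3, seed = 1L) {
  structure <- match.arg(structure)
  rho <- partial_corr_magnitude
  if (!(rho > 0 && rho <= 0.9))
    stop("partial_corr_magnitude must be in (0, 0.9]")
  if (structure %in% c("chain", "collider")) {
    if (n_nodes != 3) stop("chain/collider models have exactly 3 nodes")
    nodes <- c("A", "B", "C")
    if (structure == "chain") {
      # unit diagonal, P_AB = P_BC = -rho gives pairwise partial corr rho;
      # PD requires rho < 1/sqrt(2), otherwise load the diagonal (support and
      # the exact zero at (A,C) are unaffected).
      P <- diag(3)
      P[1, 2] <- P[2, 1] <- -rho
      P[2, 3] <- P[3, 2] <- -rho
      P <- .load_diagonal(P)
      return(.ggm_model(P, nodes))
    }
    # collider: covariance with Sigma_AB = 0, Sigma_AC = Sigma_BC = c; the
    # precision then has a nonzero (A,B) entry. Choose c so the realized
    # |partial corr(A,C)| equals rho (c must keep 1 - 2c^2 > 0 for PD).
    pcor_ac <- function(cc) {
      S <- diag(3); S[1, 3] <- S[3, 1] <- cc; S[2, 3] <- S[3, 2] <- cc
      P <- solve(S)
      abs(.pcor_from_precision(P)[1, 3])
    }
    upper <- 1 / sqrt(2) - 1e-6
    if (pcor_ac(upper) < rho)
      stop("collider construction cannot reach partial_corr_magnitude ", rho,
           " (not positive definite); use a magnitude <= ",
           signif(pcor_ac(upper), 3))
    cc <- stats::uniroot(function(x) pcor_ac(x) - rho,
                         c(1e-8, upper), tol = 1e-12)$root
    S <- diag(3); S[1, 3] <- S[3, 1] <- cc; S[2, 3] <- S[3, 2] <- cc
    P <- solve(S)
    P[abs(P) < 1e-14] <- 0
    return(.ggm_model(P, nodes))
  }
  # random-sparse
  if (n_nodes < 3) stop("random-sparse models need at least 3 nodes")
  if (!(edge_density > 0 && edge_density <= 1))
    stop("edge_density must be in (0, 1]")
  set.seed(seed)
  nodes <- paste0("n", seq_len(n_nodes))
  n_pairs <- n_nodes * (n_nodes - 1) / 2
  m <- max(1L, round(edge_density * n_pairs))
  picked <- sample.int(n_pairs, m)
  ut <- which(upper.tri(diag(n_nodes)))
  P <- matrix(0, n_nodes, n_nodes)
  P[ut[picked]] <- -rho * sample(c(-1, 1), m, replace = TRUE)
  P <- P + t(P)
  diag(P) <- 1
  P <- .load_diagonal(P)
  .ggm_model(P, nodes)
}

# diagonal loading: add (|lambda_min| + 0.1) when not positive definite;
# fails loudly if the result is still not PD.
.load_diagonal <- function(P) {
  ev <- eigen(P, symmetric = TRUE, only.values = TRUE)$values
  lmin <- min(ev)
  if (lmin <= 1e-8) {
    P <- P + diag(abs(lmin) + 0.1, nrow(P))
    ev <- eigen(P, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0)
      stop("precision matrix not positive definite after diagonal loading")
  }
  P
}

#' Sample a multivariate-normal time series from a GGM
#'
#' Draws `n_timepoints` i.i.d. rows from the zero-mean multivariate normal
#' with covariance `solve(model$precision)`. Rows are independent; no temporal
#' autocorrelation is simulated.
#'
#' @param model A `ggm_model`.
#' @param n_timepoints Number of rows (>= 2).
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @return A `timeseries_panel`.
#' @export
sample_timeseries <- function(model, n_timepoints, seed = 1L) {
  stopifnot(inherits(model, "ggm_model"))
  if (n_timepoints < 2) stop("n_timepoints must be >= 2")
  Sigma <- tryCatch(solve(model$precision),
                    error = function(e) stop("precision matrix is singular"))
  Sigma <- (Sigma + t(Sigma)) / 2
  set.seed(seed)
  X <- MASS::mvrnorm(n = n_timepoints, mu = rep(0, length(model$nodes)),
                     Sigma = Sigma)
  if (n_timepoints == 1) X <- matrix(X, nrow = 1)
  timeseries_panel(X, nodes = model$nodes)
}
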