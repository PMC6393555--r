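# Elastic-net partial-correlation estimation: symmetrization rule, penalty
# limits, hyperparameter search, and recovery of known conditional-
# independence structure.

test_that("symmetrization follows the sign-consistency rule", {
  B <- matrix(0, 2, 2)
  mk <- function(bij, bji) { B[1, 2] <- bij; B[2, 1] <- bji; B }
  # geometric mean when signs agree
  expect_equal(symmetrize_partial_correlations(mk(0.4, 0.1))[1, 2], 0.2)
  # sign disagreement -> exactly 0
  expect_identical(symmetrize_partial_correlations(mk(0.5, -0.2))[1, 2], 0)
  # clipping at 1
  expect_equal(symmetrize_partial_correlations(mk(1.5, 1.5))[1, 2], 1)
  # negative agreeing pair keeps its sign
  expect_equal(symmetrize_partial_correlations(mk(-0.4, -0.1))[1, 2], -0.2)
  # sub-threshold coefficients count as zero
  expect_identical(symmetrize_partial_correlations(mk(1e-12, 0.5))[1, 2], 0)
})

test_that("symmetrized output is always symmetric with zero diagonal in [-1,1]", {
  set.seed(1)
  for (rep in 1:10) {
    B <- matrix(rnorm(49, sd = 2), 7, 7)
    rho <- symmetrize_partial_correlations(B)
    expect_identical(rho, t(rho))
    expect_identical(unname(diag(rho)), rep(0, 7))
    expect_true(all(abs(rho) <= 1))
  }
})

test_that("very large penalty shrinks every coefficient to zero", {
  g <- make_ggm("random-sparse", 8, 0.4, 0.3, seed = 2)
  panel <- sample_timeseries(g, 100, seed = 3)
  fit <- fit_node_regression(panel, "n1", lambda = 1e6, alpha = 0.5)
  expect_true(all(fit$betas == 0))
  expect_false("n1" %in% names(fit$betas))   # no self-coefficient
})

test_that("alpha = 1 reproduces the pure LASSO solution", {
  g <- make_ggm("random-sparse", 10, 0.3, 0.3, seed = 4)
  panel <- sample_timeseries(g, 150, seed = 5)
  Z <- scale(panel$data)
  fit <- fit_node_regression(panel, "n3", lambda = 0.05, alpha = 1)
  ref <- glmnet::glmnet(Z[, -3], Z[, 3], alpha = 1,
                        lambda = exp(seq(log(0.5), log(0.05), length.out = 40)),
                        standardize = FALSE, intercept = FALSE, thresh = 1e-12)
  expect_equal(unname(fit$betas), unname(ref$beta[, 40]), tolerance = 1e-5)
})

test_that("vanishing penalty approaches the inverse-covariance closed form", {
  g <- make_ggm("random-sparse", 6, 0.5, 0.35, seed = 6)
  panel <- sample_timeseries(g, 5000, seed = 7)
  Z <- scale(panel$data)
  p <- ncol(Z)
  B <- matrix(0, p, p)
  for (i in seq_len(p)) {
    f <- fit_node_regression(panel, panel$nodes[i], lambda = 1e-8, alpha = 0.5)
    B[i, -i] <- f$betas
  }
  rho_hat <- symmetrize_partial_correlations(B)
  # oracle: partial correlations from the inverse sample covariance
  Om <- solve(stats::cov(Z))
  d <- sqrt(diag(Om))
  rho_ref <- -Om / outer(d, d); diag(rho_ref) <- 0
  nz <- abs(rho_ref) > 0.05
  expect_lt(max(abs(rho_hat[nz] - rho_ref[nz]) / abs(rho_ref[nz])), 0.01)
})

test_that("constant columns are rejected by name", {
  X <- cbind(rnorm(50), rep(2, 50), rnorm(50))
  panel <- timeseries_panel(X, nodes = c("a", "flat", "c"))
  expect_error(fit_node_regression(panel, "a", 0.1, 0.5), "flat")
})

test_that("hyperparameter search honours its argmin contract and seeds", {
  g <- make_ggm("random-sparse", 10, 0.25, 0.3, seed = 8)
  panel <- sample_timeseries(g, 200, seed = 9)
  cfg <- elastic_net_config(search_method = "ei-search", n_search_points = 12,
                            n_folds = 5, seed = 10)
  sel <- select_hyperparameters(panel, cfg)
  expect_equal(nrow(sel$trace), 12)
  expect_true(all(sel$cv_loss <= sel$trace$cv_loss))
  expect_gt(sel$alpha, 0)
  # seeded reproducibility
  sel2 <- select_hyperparameters(panel, cfg)
  expect_identical(sel$trace, sel2$trace)
  # degenerate one-point grid returns that point
  cfg1 <- elastic_net_config(search_method = "grid", n_search_points = 1,
                             n_folds = 5, seed = 10)
  sel1 <- select_hyperparameters(panel, cfg1)
  expect_equal(nrow(sel1$trace), 1)
  expect_equal(sel1$lambda, sel1$trace$rel_lambda[1])
  # too few points for the surrogate
  expect_error(select_hyperparameters(panel,
    elastic_net_config(search_method = "ei-search", n_search_points = 2,
                       n_folds = 5)), "at least 3")
})

test_that("ei-search finds a selection competitive with a dense grid", {
  g <- make_ggm("random-sparse", 8, 0.3, 0.35, seed = 11)
  panel <- sample_timeseries(g, 150, seed = 12)
  ei <- select_hyperparameters(panel,
    elastic_net_config(search_method = "ei-search", n_search_points = 15,
                       n_folds = 5, seed = 13))
  gr <- select_hyperparameters(panel,
    elastic_net_config(search_method = "grid", n_search_points = 400,
                       n_folds = 5, seed = 13))
  expect_lt(abs(ei$cv_loss - gr$cv_loss) / gr$cv_loss, 0.05)
})

test_that("estimated FC zeroes the chain's indirect link that full correlation keeps", {
  g <- make_ggm("chain", partial_corr_magnitude = 0.5)
  panel <- sample_timeseries(g, 1000, seed = 14)
  fc <- estimate_fc(panel, elastic_net_config(search_method = "grid",
                                              n_search_points = 50,
                                              n_folds = 10, seed = 15))
  expect_lt(abs(fc$weights["A", "C"]), 0.05)
  expect_gt(abs(stats::cor(panel$data[, "A"], panel$data[, "C"])), 0.2)
  # the true direct links survive estimation
  expect_gt(fc$weights["A", "B"], 0.2)
  expect_gt(fc$weights["B", "C"], 0.2)
})

test_that("estimation is deterministic and structurally valid", {
  g <- make_ggm("random-sparse", 10, 0.25, 0.3, seed = 16)
  panel <- sample_timeseries(g, 150, seed = 17)
  cfg <- elastic_net_config(search_method = "ei-search", n_search_points = 8,
                            n_folds = 5, seed = 18)
  a <- estimate_fc(panel, cfg)
  b <- estimate_fc(panel, cfg)
  expect_identical(a$weights, b$weights)
  expect_identical(a$weights, t(a$weights))
  expect_true(all(abs(a$weights) <= 1))
  expect_identical(unname(diag(a$weights)), rep(0, 10))
})
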