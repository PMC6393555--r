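# Within-layer, block and between-layer strength assortativity against
# closed forms and brute-force endpoint-enumeration oracles.

star_net <- function(k = 5, w = 1) {
  W <- matrix(0, k + 1, k + 1)
  W[1, 2:(k + 1)] <- W[2:(k + 1), 1] <- w
  weighted_network(W)
}

test_that("closed-form extremes: star is -1, matched disjoint edges are +1", {
  # star with uniform weights: hub strength k*w, every leaf strength w
  expect_equal(within_layer_assortativity(star_net(5))$value, -1)
  expect_equal(within_layer_assortativity(star_net(9, w = 2.5))$value, -1)
  # two disjoint edges, equal endpoint strengths within each edge but
  # different across edges
  W <- matrix(0, 4, 4)
  W[1, 2] <- W[2, 1] <- 1; W[3, 4] <- W[4, 3] <- 5
  expect_equal(within_layer_assortativity(weighted_network(W))$value, 1)
})

test_that("constant endpoint strengths give an undefined marker, not zero", {
  # triangle with equal weights: all strengths equal -> 0/0
  W <- matrix(1, 3, 3); diag(W) <- 0
  v <- within_layer_assortativity(weighted_network(W))
  expect_false(is_defined(v))
  expect_match(v$reason, "variance")
  # fewer than 2 edges
  W1 <- matrix(0, 3, 3); W1[1, 2] <- W1[2, 1] <- 1
  v1 <- within_layer_assortativity(weighted_network(W1))
  expect_false(is_defined(v1))
  expect_match(v1$reason, "fewer than 2 edges")
})

test_that("matrix-form evaluator matches the brute-force endpoint oracle", {
  for (s in 1:50) {
    n <- sample(6:40, 1)
    net <- rand_net(n, density = runif(1, 0.1, 0.6),
                    signed = (s %% 2 == 0), seed = s)
    for (method in c("pearson", "spearman")) {
      got <- within_layer_assortativity(net, method)
      want <- oracle_assort(net, method)
      if (is.na(want)) {
        expect_false(is_defined(got))
      } else {
        expect_equal(got$value, want, tolerance = 1e-10,
                     label = sprintf("seed %d %s", s, method))
      }
    }
  }
})

test_that("spearman variant is invariant under monotone strength transforms", {
  net <- rand_net(20, density = 0.3, seed = 11)
  base <- within_layer_assortativity(net, "spearman")$value
  # cubing all weights is NOT generally monotone on strengths, so transform
  # strengths directly through the oracle instead
  s <- strength(net)
  for (f in list(function(z) z^3 + 2, function(z) exp(z / max(abs(z))))) {
    expect_equal(oracle_assort(net, "spearman", s = f(s)), base,
                 tolerance = 1e-12)
  }
})

test_that("node relabeling and reordering never change assortativity", {
  net <- rand_net(15, density = 0.4, signed = TRUE, seed = 3)
  r0 <- within_layer_assortativity(net)$value
  set.seed(4)
  perm <- sample(15)
  net2 <- weighted_network(net$weights[perm, perm], nodes = net$nodes[perm])
  expect_equal(within_layer_assortativity(net2)$value, r0, tolerance = 1e-12)
})

test_that("assortativity is invariant to positive rescaling of weights", {
  net <- rand_net(18, density = 0.3, signed = TRUE, seed = 5)
  r0 <- within_layer_assortativity(net)$value
  net2 <- weighted_network(net$weights * 37.5)
  expect_equal(within_layer_assortativity(net2)$value, r0, tolerance = 1e-12)
})

test_that("unweighted case agrees with igraph's degree assortativity", {
  skip_if_not_installed("igraph")
  for (s in 1:5) {
    net <- rand_net(25, density = 0.25, seed = 100 + s)
    A <- adjacency(net)
    unw <- weighted_network(A * 1.0)   # strengths become degrees
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    expect_equal(within_layer_assortativity(unw)$value,
                 igraph::assortativity_degree(g, directed = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("block restriction with one label equals the whole-layer value", {
  net <- rand_net(14, density = 0.4, seed = 7)
  part <- node_partition(net$nodes,
                         rep(c("L", "R"), each = 7),
                         rep("Visual", 14))
  for (scope in c("block", "global")) {
    expect_equal(block_assortativity(net, part, "Visual", "Visual", scope)$value,
                 within_layer_assortativity(net)$value, tolerance = 1e-12)
  }
})

test_that("block cells match the restricted brute-force oracle", {
  for (s in 1:12) {
    net <- rand_net(30, density = 0.35, signed = (s %% 2 == 0), seed = 40 + s)
    part <- rand_partition(net$nodes, seed = s)
    pairs <- list(c("Visual", "Visual"), c("Visual", "DefaultMode"),
                  c("Limbic", "FrontoParietal"))
    for (pr in pairs) {
      if (!all(pr %in% part$rsn)) next
      for (scope in c("block", "global")) {
        got <- block_assortativity(net, part, pr[1], pr[2], scope)
        want <- oracle_block_assort(net, part, pr[1], pr[2], scope)
        if (is.na(want)) {
          expect_false(is_defined(got))
        } else {
          expect_equal(got$value, want, tolerance = 1e-10)
        }
      }
    }
  }
})

test_that("disconnected blocks report undefined, never zero", {
  W <- matrix(0, 8, 8)
  W[1, 2] <- W[2, 1] <- 1; W[2, 3] <- W[3, 2] <- 2   # edges inside nodes 1:4
  net <- weighted_network(W)
  part <- node_partition(net$nodes, rep(c("L", "R"), each = 4),
                         rep(c("Visual", "Limbic"), each = 4))
  v <- block_assortativity(net, part, "Visual", "Limbic")
  expect_false(is_defined(v))
  expect_match(v$reason, "fewer than 2 edges")
})

test_that("between-layer assortativity is the coupled-strength correlation", {
  sc <- rand_net(20, density = 0.3, seed = 21)
  # identical layers correlate perfectly
  expect_equal(between_layer_assortativity(multiplex_pair(sc, sc))$value, 1)
  # negating all FC weights flips the sign
  neg <- weighted_network(-sc$weights)
  expect_equal(between_layer_assortativity(multiplex_pair(sc, neg))$value, -1)
  # random multiplex equals the direct correlation of strength vectors
  fc <- rand_net(20, density = 0.4, signed = TRUE, seed = 22)
  mx <- multiplex_pair(sc, fc)
  for (method in c("pearson", "spearman")) {
    expect_equal(between_layer_assortativity(mx, method = method)$value,
                 stats::cor(strength(sc), strength(fc), method = method),
                 tolerance = 1e-12)
  }
  # node subsets (per-RSN use) respect the subset
  sub <- sc$nodes[1:8]
  expect_equal(between_layer_assortativity(mx, sub)$value,
               stats::cor(strength(sc)[sub], strength(fc)[sub]),
               tolerance = 1e-12)
  expect_error(between_layer_assortativity(mx, sc$nodes[1:2]), "at least 3")
})

test_that("between-layer scale behavior: c > 0 invariant, c < 0 flips sign", {
  sc <- rand_net(15, density = 0.3, seed = 31)
  fc <- rand_net(15, density = 0.4, signed = TRUE, seed = 32)
  r0 <- between_layer_assortativity(multiplex_pair(sc, fc))$value
  fc_pos <- weighted_network(fc$weights * 4)
  fc_neg <- weighted_network(fc$weights * -2)
  expect_equal(between_layer_assortativity(multiplex_pair(sc, fc_pos))$value,
               r0, tolerance = 1e-12)
  expect_equal(between_layer_assortativity(multiplex_pair(sc, fc_neg))$value,
               -r0, tolerance = 1e-12)
})

test_that("hemisphere split partitions nodes and conserves edge counts", {
  net <- rand_net(24, density = 0.3, seed = 41)
  part <- rand_partition(net$nodes, seed = 42)
  L <- hemisphere_split(net, part, "L")
  R <- hemisphere_split(net, part, "R")
  expect_setequal(c(L$nodes, R$nodes), net$nodes)
  inter <- sum(adjacency(net)[part$hemisphere == "L",
                              part$hemisphere == "R"])
  expect_equal(n_edges(L) + n_edges(R) + inter, n_edges(net))
})

test_that("mirror-symmetric networks have equal L and R assortativity", {
  half <- rand_net(10, density = 0.4, seed = 51)
  n <- 20
  W <- matrix(0, n, n)
  W[1:10, 1:10] <- half$weights
  W[11:20, 11:20] <- half$weights   # exact mirror, no interhemispheric edges
  net <- weighted_network(W)
  part <- node_partition(net$nodes, rep(c("L", "R"), each = 10),
                         rep("Visual", n))
  rl <- within_layer_assortativity(hemisphere_split(net, part, "L"))$value
  rr <- within_layer_assortativity(hemisphere_split(net, part, "R"))$value
  expect_equal(rl, rr, tolerance = 1e-12)
})

test_that("measured assortativity keeps the target's sign at 68/114/219 nodes", {
  for (n in c(68, 114, 219)) {
    for (target in c(0.12, -0.12)) {
      net <- make_weighted_network(n, 0.06, "lognormal-positive",
                                   seed = n + (target > 0))
      rw <- rewire_to_target_assortativity(net, target, tol = 0.05,
                                           seed = n + 7)
      expect_equal(sign(within_layer_assortativity(rw)$value), sign(target),
                   label = sprintf("n=%d target=%.2f", n, target))
    }
  }
})
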