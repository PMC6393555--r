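# Synthetic network generators, rewiring and cohort construction.

test_that("weight models produce the expected edge sets and signs", {
  # density 1 on 5 nodes: complete graph, 10 strictly positive edges
  net <- make_weighted_network(5, 1, "lognormal-positive", seed = 1)
  expect_equal(n_edges(net), 10)
  expect_true(all(net$weights[upper.tri(net$weights)] > 0))
  # signed-sparse has both signs at moderate size/density
  fc <- make_weighted_network(25, 0.25, "signed-sparse", seed = 2)
  w <- fc$weights[upper.tri(fc$weights)]
  w <- w[abs(w) > 1e-12]
  expect_gt(sum(w > 0), 0)
  expect_gt(sum(w < 0), 0)
  expect_true(all(abs(w) <= 1))
  # pure function of (parameters, seed)
  expect_identical(make_weighted_network(25, 0.25, "signed-sparse", seed = 2)$weights,
                   fc$weights)
  expect_false(identical(make_weighted_network(25, 0.25, "signed-sparse", seed = 3)$weights,
                         fc$weights))
  expect_error(make_weighted_network(6, 0.01, seed = 1), "fewer than 2 edges")
})

test_that("rewiring returns the input untouched when already at target", {
  net <- make_weighted_network(20, 0.3, "lognormal-positive", seed = 4)
  r0 <- within_layer_assortativity(net)$value
  out <- rewire_to_target_assortativity(net, r0, tol = 0.01, seed = 5)
  expect_identical(out$weights, net$weights)
  expect_equal(attr(out, "n_swaps"), 0L)
  expect_true(attr(out, "converged"))
})

test_that("rewiring reaches targets while conserving degrees and weights", {
  net <- make_weighted_network(60, 0.1, "lognormal-positive", seed = 6)
  for (target in c(0.3, -0.3)) {
    out <- rewire_to_target_assortativity(net, target, tol = 0.05, seed = 7)
    expect_true(attr(out, "converged"))
    achieved <- within_layer_assortativity(out)$value
    expect_lt(abs(achieved - target), 0.05)
    expect_equal(attr(out, "achieved"), achieved, tolerance = 1e-10)
    # binary degree sequence exactly preserved
    expect_identical(sort(unname(degree(out))), sort(unname(degree(net))))
    # edge-weight multiset exactly preserved
    expect_identical(sort(out$weights[upper.tri(out$weights) &
                                        abs(out$weights) > 1e-12]),
                     sort(net$weights[upper.tri(net$weights) &
                                        abs(net$weights) > 1e-12]))
    # node set untouched
    expect_identical(out$nodes, net$nodes)
  }
})

test_that("unreachable targets report best effort, not silent success", {
  net <- make_weighted_network(12, 0.2, "lognormal-positive", seed = 8)
  out <- rewire_to_target_assortativity(net, 1, max_iters = 300, tol = 0.001,
                                        seed = 9)
  expect_false(attr(out, "converged"))
  expect_true(is.finite(attr(out, "achieved")))
  expect_equal(attr(out, "achieved"),
               within_layer_assortativity(out)$value, tolerance = 1e-10)
})

test_that("cohort generation hits target signs and shares node metadata", {
  spec <- cohort_spec(n_subjects = 6, n_nodes = 60, target_sc_assort = 0.10,
                      target_fc_assort = -0.15, target_between_assort = 0.10,
                      edge_density_sc = 0.15, edge_density_fc = 0.12,
                      noise_sd = 0.05, seed = 11)
  co <- generate_cohort(spec)
  expect_length(co$subjects, 6)
  med <- apply(co$achieved[, c("within_sc", "within_fc", "between")], 2,
               stats::median)
  expect_gt(med[["within_sc"]], 0)
  expect_lt(med[["within_fc"]], 0)
  expect_gt(med[["between"]], 0)
  # between-layer blending lands near its target
  expect_equal(med[["between"]], 0.10, tolerance = 0.1)
  # all subjects share node ids and the partition
  for (mx in co$subjects) expect_identical(mx$nodes, co$subjects[[1]]$nodes)
  expect_identical(co$partition$node_id, co$subjects[[1]]$nodes)
  # single-subject boundary
  co1 <- generate_cohort(cohort_spec(n_subjects = 1, n_nodes = 20,
                                     edge_density_sc = 0.3,
                                     edge_density_fc = 0.3, seed = 12))
  expect_length(co1$subjects, 1)
  # determinism
  co2 <- generate_cohort(spec)
  expect_identical(co$subjects[[3]]$fc$weights, co2$subjects[[3]]$fc$weights)
})

test_that("lateralized injection lowers one hemisphere's FC assortativity", {
  spec <- cohort_spec(n_subjects = 4, n_nodes = 60, seed = 13,
                      edge_density_fc = 0.15)
  co <- generate_cohort(spec)
  part <- co$partition
  before <- sapply(co$subjects, function(mx)
    within_layer_assortativity(hemisphere_split(mx$fc, part, "L"))$value)
  co2 <- inject_lateralized_shift(co, shift = 0.15, layer = "fc", side = "L",
                                  seed = 14)
  after <- sapply(co2$subjects, function(mx)
    within_layer_assortativity(hemisphere_split(mx$fc, part, "L"))$value)
  afterR <- sapply(co2$subjects, function(mx)
    within_layer_assortativity(hemisphere_split(mx$fc, part, "R"))$value)
  beforeR <- sapply(co$subjects, function(mx)
    within_layer_assortativity(hemisphere_split(mx$fc, part, "R"))$value)
  expect_true(all(after < before))          # L pushed down
  expect_equal(afterR, beforeR, tolerance = 1e-12)  # R untouched
})

test_that("cohorts round-trip to disk with manifest", {
  dir <- withr::local_tempdir()
  co <- generate_cohort(cohort_spec(n_subjects = 2, n_nodes = 20,
                                    edge_density_sc = 0.3,
                                    edge_density_fc = 0.3, seed = 15))
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "sub-001_sc.tsv")))
  expect_true(file.exists(file.path(dir, "nodes.tsv")))
  manifest <- jsonlite::read_json(file.path(dir, "cohort.json"))
  expect_equal(manifest$spec$n_subjects, 2)
  back <- read_network_tsv(file.path(dir, "sub-002_fc.tsv"))
  expect_equal(back$weights, co$subjects[[2]]$fc$weights, tolerance = 1e-12)
})
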