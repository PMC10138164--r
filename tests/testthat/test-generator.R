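test_that("zero evolution rate reproduces snapshot 0 at every time point", {
  net <- generate_base_network(25, 2, 5, e_rate = 0, seed = 2)
  k0 <- sort(dynetalign:::snapshot_edge_keys(net, 0))
  for (t in 1:4)
    expect_identical(sort(dynetalign:::snapshot_edge_keys(net, t)), k0)
})

test_that("edge count is conserved exactly across snapshots", {
  for (seed in 1:5) {
    net <- generate_base_network(30, 2, 6, e_rate = 0.3, seed = seed)
    counts <- vapply(0:5, function(t)
      length(dynetalign:::snapshot_edge_keys(net, t)), numeric(1))
    expect_true(all(counts == counts[1]))
  }
})

test_that("consecutive-snapshot conservation tracks 1 - e_rate", {
  for (er in c(0, 0.05, 0.2)) {
    sims <- vapply(1:30, function(s) {
      net <- generate_base_network(60, 2, 6, e_rate = er, seed = s)
      mean(consecutive_snapshot_similarity(net, method = "overlap"))
    }, numeric(1))
    expect_lt(abs(mean(sims) - (1 - er)), 0.02)
  }
})

test_that("full rewiring conserves almost nothing (Monte Carlo vs raw edge sets)", {
  conserved <- vapply(1:50, function(s) {
    net <- generate_base_network(30, 2, 2, e_rate = 1, seed = s)
    # brute-force edge-set intersection straight from the event table
    ev <- net$events
    e0 <- paste(ev$u, ev$v)[ev$t == 0]
    e1 <- paste(ev$u, ev$v)[ev$t == 1]
    length(intersect(e0, e1)) / length(e0)
  }, numeric(1))
  # chance re-pick rate: ~m new edges drawn from choose(30, 2) pairs
  expect_lt(mean(conserved), 0.25)
})

test_that("zero divergence with all nodes kept yields an identical twin", {
  H <- generate_base_network(20, 2, 3, seed = 4)
  pair <- derive_counterpart(H, keep_nodes = 20, delta = 0, seed = 5)
  expect_identical(pair$G$events, H$events)
  expect_identical(pair$truth, stats::setNames(H$nodes, H$nodes))
})

test_that("counterpart divergence tracks 1 - delta and truth is injective", {
  sims <- vapply(1:30, function(s) {
    H <- generate_base_network(60, 2, 5, e_rate = 0.05, seed = s)
    pair <- derive_counterpart(H, delta = 0.10, seed = s)
    mean(pair_snapshot_similarity(pair, method = "overlap"))
  }, numeric(1))
  expect_lt(abs(mean(sims) - 0.90), 0.03)
})

test_that("subsampled counterparts keep namesake ids and induced structure", {
  H <- generate_base_network(20, 2, 3, seed = 7)
  pair <- derive_counterpart(H, keep_nodes = 10, delta = 0.1, seed = 7)
  expect_length(pair$G$nodes, 10)
  expect_true(all(pair$G$nodes %in% H$nodes))
  expect_identical(unname(pair$truth), names(pair$truth))
  expect_false(anyDuplicated(pair$truth) > 0)
  expect_setequal(names(pair$truth), pair$G$nodes)
})

test_that("parameter bounds are enforced", {
  expect_error(generate_base_network(20, 2, 3, e_rate = 1.5), "\\[0, 1\\]")
  expect_error(generate_base_network(20, 2, 3, e_rate = -0.1), "\\[0, 1\\]")
  H <- generate_base_network(20, 2, 2, seed = 1)
  expect_error(derive_counterpart(H, delta = 2), "\\[0, 1\\]")
  expect_error(derive_counterpart(H, keep_nodes = 21), "keep_nodes")
  expect_error(inject_noise(H, level = -0.2), "\\[0, 1\\]")
})

test_that("edge-mode noise removes the exact rounded count of triples", {
  net <- generate_base_network(40, 2, 5, e_rate = 0.1, seed = 11)
  n0 <- nrow(net$events)
  for (lv in c(0, 0.05, 0.3)) {
    noisy <- inject_noise(net, lv, mode = "edges", seed = 3)
    expect_equal(nrow(noisy$events), n0 - round(lv * n0))
    expect_identical(noisy$nodes, net$nodes)  # node universe unchanged
    expect_identical(noisy$n_timepoints, net$n_timepoints)
  }
  expect_identical(inject_noise(net, 0, "edges", seed = 1)$events, net$events)
})

test_that("event-mode noise removes whole interactions across all times", {
  net <- generate_base_network(40, 2, 6, e_rate = 0.2, seed = 12)
  keys_all <- dynetalign:::edge_key(net$events$u, net$events$v)
  pairs0 <- unique(keys_all)
  noisy <- inject_noise(net, 0.3, mode = "events", seed = 5)
  keys_left <- unique(dynetalign:::edge_key(noisy$events$u, noisy$events$v))
  removed <- setdiff(pairs0, keys_left)
  expect_equal(length(removed), round(0.3 * length(pairs0)))
  # brute-force scan: no occurrence of a removed pair survives at any t
  expect_equal(sum(dynetalign:::edge_key(noisy$events$u, noisy$events$v)
                   %in% removed), 0)
  # surviving pairs keep every one of their original time occurrences
  kept_mask <- !(keys_all %in% removed)
  expect_identical(noisy$events, {
    ev <- net$events[kept_mask, , drop = FALSE]
    rownames(ev) <- NULL
    ev
  })
})

test_that("snapshot similarity matches hand-computed Jaccard values", {
  g <- function(edges) igraph::graph_from_edgelist(edges, directed = FALSE)
  tri <- g(rbind(c("a", "b"), c("b", "c")))
  expect_equal(snapshot_similarity(tri, tri), 1.0)
  dis <- g(rbind(c("x", "y")))
  expect_equal(snapshot_similarity(tri, dis), 0.0)
  g1 <- g(rbind(c("a", "b"), c("b", "c")))
  g2 <- g(rbind(c("a", "b"), c("c", "d")))
  expect_equal(snapshot_similarity(g1, g2), 1 / 3)
  empty <- igraph::make_empty_graph(directed = FALSE)
  expect_warning(s <- snapshot_similarity(empty, empty), "empty")
  expect_equal(s, 1.0)
})

test_that("generation is reproducible from the seed alone", {
  a <- generate_base_network(30, 2, 4, e_rate = 0.1, seed = 42)
  b <- generate_base_network(30, 2, 4, e_rate = 0.1, seed = 42)
  expect_identical(a$events, b$events)
  c <- generate_base_network(30, 2, 4, e_rate = 0.1, seed = 43)
  expect_false(identical(a$events, c$events))
})
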