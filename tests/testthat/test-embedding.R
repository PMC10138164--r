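test_that("every consecutive pair inside a walk is an edge of the snapshot", {
  tri <- igraph::graph_from_edgelist(
    rbind(c("a", "b"), c("b", "c"), c("a", "c")), directed = FALSE)
  corpus <- sample_walks(tri, walk_params(walks_per_node = 2,
                                          walk_length = 5), seed = 1)
  expect_length(corpus$walks, 6)
  expect_true(all(lengths(corpus$walks) == 5))
  adj <- list(a = c("b", "c"), b = c("a", "c"), c = c("a", "b"))
  for (w in corpus$walks)
    for (i in seq_len(length(w) - 1))
      expect_true(w[i + 1] %in% adj[[w[i]]])
})

test_that("isolated nodes yield singleton walks and enter the vocabulary", {
  g <- igraph::graph_from_edgelist(rbind(c("a", "b")), directed = FALSE)
  g <- igraph::add_vertices(g, 1, name = "lonely")
  corpus <- sample_walks(g, walk_params(walks_per_node = 3,
                                        walk_length = 10), seed = 2)
  lonely <- Filter(function(w) w[1] == "lonely", corpus$walks)
  expect_length(lonely, 3)
  expect_true(all(lengths(lonely) == 1))
  st <- train_skipgram(corpus, tiny_sparams())
  expect_true("lonely" %in% rownames(st$vectors))
})

test_that("unbiased walks traverse a path uniformly (Monte Carlo)", {
  path <- igraph::graph_from_edgelist(rbind(c("a", "b"), c("b", "c")),
                                      directed = FALSE)
  corpus <- sample_walks(path, walk_params(walks_per_node = 50,
                                           walk_length = 100), seed = 3)
  to_a <- 0L
  from_b <- 0L
  for (w in corpus$walks) {
    for (i in seq_len(length(w) - 1)) {
      if (w[i] == "b") {
        from_b <- from_b + 1L
        if (w[i + 1] == "a") to_a <- to_a + 1L
      }
    }
  }
  expect_gt(from_b, 5000)
  expect_lt(abs(to_a / from_b - 0.5), 0.02)
})

test_that("return bias p steers second-order walks (Monte Carlo)", {
  # on a path, with tiny 1/p the walk almost never immediately backtracks,
  # so from the middle of a long path it behaves like a directed sweep
  path5 <- igraph::graph_from_edgelist(
    cbind(paste0("x", 1:19), paste0("x", 2:20)), directed = FALSE)
  corpus <- sample_walks(path5, walk_params(walks_per_node = 20,
                                            walk_length = 30,
                                            p = 100, q = 1), seed = 4)
  backtracks <- 0L
  steps <- 0L
  for (w in corpus$walks) {
    if (length(w) < 3) next
    for (i in 3:length(w)) {
      steps <- steps + 1L
      if (w[i] == w[i - 2]) backtracks <- backtracks + 1L
    }
  }
  # interior path nodes backtrack with probability ~1/101 instead of ~1/2
  expect_lt(backtracks / steps, 0.1)
})

test_that("zero-epoch training with full initial coverage is the identity", {
  net <- generate_base_network(15, 2, 1, seed = 5)
  corpus <- sample_walks(snapshot_at(net, 0), tiny_wparams(), seed = 5)
  first <- train_skipgram(corpus, tiny_sparams(seed = 5, epochs = 1))
  frozen <- train_skipgram(corpus, tiny_sparams(seed = 5, epochs = 0),
                           initial = first)
  expect_identical(frozen$vectors[rownames(first$vectors), ],
                   first$vectors)
})

test_that("vector dimension honours the requested hidden-layer size", {
  net <- generate_base_network(12, 2, 3, seed = 6)
  for (dim in c(4, 16)) {
    st <- temporal_embedding(net, tiny_wparams(),
                             sg_params(dim = dim, epochs = 1, seed = 6))
    expect_equal(ncol(st$vectors), dim)
    expect_equal(nrow(st$vectors), 12)
    expect_true(all(is.finite(st$vectors)))
  }
})

test_that("dimension mismatch between initial state and params is rejected", {
  net <- generate_base_network(12, 2, 1, seed = 7)
  corpus <- sample_walks(snapshot_at(net, 0), tiny_wparams(), seed = 7)
  st8 <- train_skipgram(corpus, sg_params(dim = 8, epochs = 0, seed = 7))
  expect_error(train_skipgram(corpus, sg_params(dim = 16, seed = 7),
                              initial = st8),
               "dimension mismatch")
})

test_that("temporal embedding is deterministic under a fixed seed", {
  net <- generate_base_network(15, 2, 3, seed = 8)
  a <- temporal_embedding(net, tiny_wparams(), tiny_sparams(seed = 8))
  b <- temporal_embedding(net, tiny_wparams(), tiny_sparams(seed = 8))
  expect_identical(a$vectors, b$vectors)
  c <- temporal_embedding(net, tiny_wparams(), tiny_sparams(seed = 9))
  expect_false(identical(a$vectors, c$vectors))
})

test_that("a single time point reduces to one plain Skip-Gram run", {
  net <- generate_base_network(15, 2, 1, seed = 10)
  st <- temporal_embedding(net, tiny_wparams(), tiny_sparams(seed = 10))
  corpus <- sample_walks(snapshot_at(net, 0), tiny_wparams(),
                         seed = dynetalign:::mix_seed(10, 100))
  plain_params <- tiny_sparams(seed = 10)
  plain_params$seed <- dynetalign:::mix_seed(10, 200)
  plain <- train_skipgram(corpus, plain_params)
  expect_identical(st$vectors, plain$vectors)
})

test_that("twin embeddings of identical networks coincide exactly", {
  net <- generate_base_network(20, 2, 3, seed = 11)
  copy <- temporal_network(net$events, n_timepoints = net$n_timepoints,
                           nodes = net$nodes, name = "copy")
  emb <- joint_temporal_embedding(net, copy, tiny_wparams(),
                                  tiny_sparams(seed = 11))
  expect_identical(emb$G$vectors, emb$H$vectors)
  expect_equal(nrow(emb$G$vectors), length(net$nodes))
  expect_equal(nrow(emb$H$vectors), length(copy$nodes))
})

test_that("mismatched time points are rejected for joint embedding", {
  a <- generate_base_network(12, 2, 2, seed = 12)
  b <- generate_base_network(12, 2, 3, seed = 12)
  expect_error(joint_temporal_embedding(a, b, tiny_wparams(),
                                        tiny_sparams()),
               "unequal time points")
})

test_that("networks with no events at all cannot be embedded", {
  empty <- temporal_network(toy_events()[0, ], n_timepoints = 2,
                            nodes = c("a", "b"))
  expect_error(temporal_embedding(empty, tiny_wparams(), tiny_sparams()),
               "no trainable content")
})

test_that("embedding state round-trips through its TSV representation", {
  net <- generate_base_network(10, 2, 2, seed = 13)
  st <- temporal_embedding(net, tiny_wparams(), tiny_sparams(seed = 13))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_embedding(st, path)
  back <- read_embedding(path)
  expect_equal(back$vectors[rownames(st$vectors), ], st$vectors,
               tolerance = 1e-12)
  expect_identical(back$t, st$t)
})
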