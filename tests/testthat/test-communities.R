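test_that("disconnected cliques are recovered exactly", {
  m <- sri_from_weights(clique_blocks(c(6, 6), w = 0.5))
  p <- detect_communities(m)
  expect_length(p$sizes, 2L)
  expect_equal(sort(unname(p$sizes)), c(6L, 6L))
  expect_equal(length(unique(p$assignment[1:6])), 1L)
  expect_equal(length(unique(p$assignment[7:12])), 1L)
})

test_that("a complete uniform graph forms a single community", {
  m <- sri_from_weights(clique_blocks(8, w = 0.3))
  p <- detect_communities(m)
  expect_length(p$sizes, 1L)
})

test_that("an all-zero matrix yields flagged singleton communities", {
  m <- sri_from_weights(matrix(0, 5, 5))
  p <- detect_communities(m)
  expect_true(p$degenerate)
  expect_length(p$sizes, 5L)
  expect_true(is.na(p$modularity))
})

test_that("planted partitions are recovered with high adjusted Rand index", {
  m <- planted_partition_network(6, 11, w_in = 0.4, w_out = 0.02, seed = 3)
  p <- detect_communities(m)
  expect_gte(ari(p$assignment[m$nodes], attr(m, "truth")[m$nodes]), 0.9)

  # single block: one community
  m1 <- planted_partition_network(1, 8, w_in = 0.5, w_out = 0, seed = 1)
  expect_length(detect_communities(m1)$sizes, 1L)
  expect_error(planted_partition_network(2, 1, 0.4, 0.1), "size")
  expect_error(planted_partition_network(2, 5, 0.1, 0.4), "w_in > w_out")
})

test_that("detection is invariant to node relabelling", {
  m <- planted_partition_network(3, 7, w_in = 0.5, w_out = 0.05, seed = 8)
  p1 <- detect_communities(m)
  perm <- sample(length(m$nodes))
  m2 <- m
  m2$nodes <- m$nodes[perm]
  m2$weights <- m$weights[perm, perm]
  p2 <- detect_communities(m2)
  common <- m$nodes
  expect_equal(ari(p1$assignment[common], p2$assignment[common]), 1)
})

test_that("modularity matches closed forms and the igraph reference", {
  W <- clique_blocks(c(5, 5), w = 1)
  two <- rep(1:2, each = 5)
  expect_equal(q_modularity(W, two), 0.5)
  expect_equal(q_modularity(W, rep(1, 10)), 0)
  # singletons on a clique are negative
  K <- clique_blocks(6, w = 1)
  expect_lt(q_modularity(K, 1:6), 0)
  # cross-check against igraph on a random weighted graph
  set.seed(5)
  A <- matrix(runif(64), 8, 8) * (matrix(runif(64), 8, 8) < 0.4)
  A <- (A + t(A)) / 2; diag(A) <- 0
  memb <- sample(1:3, 8, replace = TRUE)
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  expect_equal(q_modularity(A, memb),
               igraph::modularity(g, memb, weights = igraph::E(g)$weight),
               tolerance = 1e-12)
  expect_error(q_modularity(matrix(0, 3, 3), c(1, 1, 2)), "zero-weight")
})

test_that("modularity lies in [-0.5, 1] over random partitions", {
  set.seed(21)
  for (i in 1:20) {
    n <- sample(4:9, 1)
    A <- matrix(runif(n * n), n, n) * (matrix(runif(n * n), n, n) < 0.5)
    A <- (A + t(A)) / 2; diag(A) <- 0
    if (sum(A) == 0) next
    memb <- sample(1:3, n, replace = TRUE)
    Q <- q_modularity(A, memb)
    expect_gte(Q, -0.5)
    expect_lte(Q, 1)
  }
})

test_that("components-as-communities beats any merge of two components", {
  # exhaustive over all partitions coarser than components, small instances
  set.seed(33)
  W <- clique_blocks(c(3, 3, 2), w = runif(1, 0.3, 1))
  comp <- rep(1:3, c(3, 3, 2))
  Qcomp <- q_modularity(W, comp)
  merges <- list(c(1, 1, 2), c(1, 2, 1), c(1, 2, 2), c(1, 1, 1))
  for (mg in merges) {
    expect_gte(Qcomp, q_modularity(W, mg[comp]))
  }
})

test_that("bootstrap consistency is 1 when every encounter is identical", {
  enc <- do.call(rbind, lapply(1:6, function(e) {
    data.frame(period = "p1", encounter = paste0("e", e),
               group = rep(c("g1", "g2"), each = 3),
               individual = LETTERS[1:6], stringsAsFactors = FALSE)
  }))
  r <- bootstrap_community_consistency(enc, "p1", n_boot = 20, seed = 1,
                                       min_community_size = 3)
  expect_equal(r$r_com, 1)
})

test_that("strong planted structure is more consistent than random noise", {
  set.seed(14)
  planted <- do.call(rbind, lapply(1:40, function(e) {
    blk <- sample(1:2, 1)
    mem <- sample(LETTERS[1:6 + (blk - 1) * 6], 3)
    data.frame(period = "p1", encounter = paste0("e", e), group = "g1",
               individual = mem, stringsAsFactors = FALSE)
  }))
  noise <- do.call(rbind, lapply(1:40, function(e) {
    data.frame(period = "p1", encounter = paste0("n", e), group = "g1",
               individual = sample(LETTERS[1:12], 3), stringsAsFactors = FALSE)
  }))
  r_planted <- bootstrap_community_consistency(planted, "p1", n_boot = 30,
                                               seed = 2,
                                               min_community_size = 3)$r_com
  r_noise <- bootstrap_community_consistency(noise, "p1", n_boot = 30,
                                             seed = 2,
                                             min_community_size = 3)$r_com
  expect_gte(r_planted, 0.95)
  expect_gt(r_planted, r_noise)
})

test_that("modularity null test attains the floor on planted structure", {
  set.seed(4)
  enc <- do.call(rbind, lapply(1:60, function(e) {
    blk <- sample(1:2, 1)
    mem <- sample(LETTERS[1:6 + (blk - 1) * 6], 3)
    data.frame(period = "p1", encounter = paste0("e", e), group = "g1",
               individual = mem, stringsAsFactors = FALSE)
  }))
  res <- modularity_null_test(enc, "p1", n_perm = 49, seed = 9,
                              burn_in = 200, thin = 20,
                              min_community_size = 3)
  expect_equal(res$p_value, 1 / 50)
  expect_error(modularity_null_test(enc, "p1", n_perm = 0), "n_perm")
})
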