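test_that("edge filtering honours the |0.4| rule and the mask", {
  V <- matrix(0, 3, 3)
  V[1, 2] <- V[2, 1] <- 0.39
  V[1, 3] <- V[3, 1] <- 0.41
  V[2, 3] <- V[3, 2] <- -0.8   # anticorrelation counts by magnitude
  C <- toy_dccm(V)
  g <- build_network(C, threshold = 0.4)
  e <- igraph::as_edgelist(g)
  expect_equal(nrow(e), 2L)
  expect_false(any(e[, 1] == "A:1" & e[, 2] == "A:2"))  # 0.39 dropped
  expect_equal(sort(igraph::E(g)$corr), c(0.41, 0.8))

  # mask precedence: a masked-out pair gets no edge regardless of |C|
  mask <- matrix(TRUE, 3, 3)
  mask[2, 3] <- mask[3, 2] <- FALSE
  g2 <- build_network(C, mask, threshold = 0.4)
  expect_equal(igraph::ecount(g2), 1L)
  expect_error(build_network(C, threshold = 1.5), "threshold")
})

test_that("a 6-node toy graph matches hand enumeration, monotonically", {
  set.seed(30)
  V <- matrix(runif(36, 0, 0.9), 6, 6)
  V <- (V + t(V)) / 2
  C <- toy_dccm(V)
  for (thr in c(0.2, 0.4, 0.6)) {
    g <- build_network(C, threshold = thr)
    hand <- which(abs(V) >= thr & upper.tri(V), arr.ind = TRUE)
    expect_equal(igraph::ecount(g), nrow(hand))
  }
  # raising the threshold never adds edges
  counts <- vapply(seq(0, 1, by = 0.1),
                   function(t) igraph::ecount(build_network(C, threshold = t)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

two_cliques <- function(n_half = 4, intra = 0.8, bridge = 0.5) {
  n <- 2 * n_half
  V <- matrix(0, n, n)
  V[1:n_half, 1:n_half] <- intra
  V[(n_half + 1):n, (n_half + 1):n] <- intra
  V[n_half, n_half + 1] <- V[n_half + 1, n_half] <- bridge
  diag(V) <- 0
  toy_dccm(V)
}

test_that("divisive clustering splits bridged cliques and matches brute force", {
  C <- two_cliques(4)
  g <- build_network(C, threshold = 0.4)
  A <- igraph::as_adjacency_matrix(g, attr = "corr", sparse = FALSE)
  parts <- girvan_newman(g)
  ks <- vapply(parts, `[[`, numeric(1), "k")
  p2 <- parts[[which(ks == 2)]]
  expect_equal(unname(p2$membership[1:4]), rep(p2$membership[[1]], 4))
  expect_equal(unname(p2$membership[5:8]), rep(p2$membership[[5]], 4))
  expect_false(p2$membership[[1]] == p2$membership[[5]])

  # recorded Q values match direct summation of the modularity formula
  for (p in parts)
    expect_equal(p$modularity, q_direct(A, unname(p$membership)),
                 tolerance = 1e-12)

  # and the best recorded Q equals the exhaustive-search maximum
  bf <- brute_force_max_q(A)
  expect_equal(max(vapply(parts, `[[`, numeric(1), "modularity")), bf$q,
               tolerance = 1e-12)
})

test_that("component partitions, null models and k bounds behave", {
  # disconnected graph: the k = c partition is the component partition
  V <- matrix(0, 5, 5)
  V[1, 2] <- V[2, 1] <- 0.9
  V[3, 4] <- V[4, 3] <- 0.9
  C <- toy_dccm(V)
  g <- build_network(C, threshold = 0.4)  # components {1,2}, {3,4}, {5}
  parts <- girvan_newman(g)
  p3 <- parts[[1]]
  expect_equal(p3$k, 3)
  expect_equal(unname(p3$membership),
               as.integer(igraph::components(g)$membership))

  # complete graph, k = 1: Q = 0 by the null-model identity
  Vc <- matrix(0.7, 4, 4); diag(Vc) <- 0
  gc <- build_network(toy_dccm(Vc), threshold = 0.4)
  parts_c <- girvan_newman(gc)
  expect_equal(parts_c[[1]]$k, 1)
  expect_equal(parts_c[[1]]$modularity, 0)

  expect_error(girvan_newman(gc, k_range = 1:10), "exceeds")
  expect_error(girvan_newman(igraph::make_empty_graph(0, directed = FALSE)),
               "empty")
})

test_that("community-number selection applies the modularity tolerance", {
  mk <- function(k, q) structure(list(membership = NULL, k = k, modularity = q),
                                 class = "community_partition")
  parts <- list(mk(2, 0.30), mk(3, 0.50), mk(4, 0.49))
  expect_equal(select_community_number(parts)$k, 3)
  # gap 0.01 <= 0.02: the preferred k is accepted
  expect_equal(select_community_number(parts, preferred_k = 4)$k, 4)
  # gap 0.20 > 0.02: rejected with the gap reported
  expect_error(select_community_number(list(mk(2, 0.30), mk(3, 0.50)),
                                       preferred_k = 2), "gap 0.2")
  # ties break to smaller k
  expect_equal(select_community_number(list(mk(2, 0.5), mk(5, 0.5)))$k, 2)
  expect_error(select_community_number(list(), NULL), "no partitions")
})

test_that("community networks aggregate sizes and cross strengths", {
  C <- two_cliques(4, bridge = 0.5)
  g <- build_network(C, threshold = 0.4)
  parts <- girvan_newman(g)
  p2 <- parts[[which(vapply(parts, `[[`, numeric(1), "k") == 2)]]
  net <- community_graph(p2, C, threshold = 0.4)
  expect_equal(sum(net$nodes$size), 8L)
  expect_equal(net$nodes$size, c(4L, 4L))
  # single bridging pair above threshold: one edge of strength |C| = 0.5
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$strength, 0.5)

  all_one <- structure(list(membership = stats::setNames(rep(1L, 8),
                                                         rownames(C)),
                            k = 1, modularity = 0),
                       class = "community_partition")
  net1 <- community_graph(all_one, C)
  expect_equal(nrow(net1$nodes), 1L)
  expect_equal(net1$nodes$size, 8L)
  expect_equal(nrow(net1$edges), 0L)
})

test_that("a planted two-block ensemble is recovered as two communities", {
  topo <- generate_toy_structure(20, "extended")
  R <- matrix(0, 20, 20)
  R[1:10, 1:10] <- 0.8
  R[11:20, 11:20] <- 0.8
  diag(R) <- 1
  m <- planted_dynamics_model(topo, 0.5, R, n_frames = 4000)
  tr <- generate_trajectory(m, seed = 31)
  C <- compute_dccm(tr)
  g <- build_network(C, threshold = 0.4)
  parts <- girvan_newman(g)
  best <- select_community_number(parts)
  expect_equal(best$k, 2)
  truth <- rep(1:2, each = 10)
  agree <- max(mean(best$membership == truth),
               mean(best$membership == 3 - truth))
  expect_gte(agree, 0.95)
})
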