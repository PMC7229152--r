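test_that("cross-correlation matches hand-worked and brute-force values", {
  # two sites displaced identically, one oppositely, over 12 frames
  set.seed(81)
  a <- rnorm(12)
  frames <- lapply(seq_len(12), function(f) {
    rbind(c(a[f], 0, 0), c(10 + a[f], 0, 0), c(20 - a[f], 0, 0))
  })
  C <- cross_correlation(traj_from_frames(frames))
  expect_equal(C[1, 2], 1)
  expect_equal(C[1, 3], -1)
  expect_true(isSymmetric(C))
  expect_equal(diag(C), rep(1, 3), ignore_attr = TRUE)

  # brute-force loop oracle on a random 3-site toy
  frames2 <- lapply(1:10, function(f) matrix(rnorm(9), 3, 3))
  traj2 <- traj_from_frames(frames2)
  C2 <- cross_correlation(traj2)
  X <- lapply(1:3, function(i) t(sapply(seq_len(10), function(f) frames2[[f]][i, ])))
  X <- lapply(X, function(m) sweep(m, 2, colMeans(m)))
  for (i in 1:3) for (j in 1:3) {
    num <- mean(rowSums(X[[i]] * X[[j]]))
    den <- sqrt(mean(rowSums(X[[i]]^2)) * mean(rowSums(X[[j]]^2)))
    expect_equal(C2[i, j], num / den, tolerance = 1e-12)
  }
})

test_that("zero-fluctuation sites are guarded, not divided by", {
  frames <- lapply(1:10, function(f) rbind(c(0, 0, 0), c(5 + rnorm(1), 0, 0),
                                           c(10 + rnorm(1), 0, 0)))
  expect_warning(C <- cross_correlation(traj_from_frames(frames)), "zero fluctuation")
  expect_equal(C[1, 2], 0)
  expect_equal(C[1, 1], 1)
})

test_that("contact occupancy counts frames at the strict boundary", {
  mk <- function(d) rbind(c(0, 0, 0), c(d, 0, 0), c(0, 50, 0))
  traj <- traj_from_frames(list(mk(3), mk(3), mk(3), mk(10)), c(1, 5, 9))
  occ <- contact_occupancy(traj, cutoff_A = 4.5)
  expect_equal(occ["1", "5"], 0.75)
  always <- contact_occupancy(traj_from_frames(list(mk(3), mk(3)), c(1, 5, 9)))
  expect_equal(always["1", "5"], 1)
  never <- contact_occupancy(traj_from_frames(list(mk(6), mk(6)), c(1, 5, 9)))
  expect_equal(never["1", "5"], 0)
  # exactly 75% occupancy fails the strict "more than" edge rule
  C <- diag(3); C[1, 2] <- C[2, 1] <- 0.9
  dimnames(C) <- dimnames(occ)
  expect_warning(net <- build_network(C, occ, run_config()), "no edges")
  expect_false(any(net$edges$i == 1 & net$edges$j == 2))
})

test_that("network construction weights edges and excludes neighbors", {
  C <- diag(4)
  C[1, 3] <- C[3, 1] <- 1
  C[1, 4] <- C[4, 1] <- exp(-1)
  C[2, 4] <- C[4, 2] <- -0.5
  C[3, 4] <- C[4, 3] <- 0.2
  occ <- matrix(1, 4, 4)
  rownames(C) <- colnames(C) <- rownames(occ) <- colnames(occ) <- 1:4
  net <- build_network(C, occ, run_config())
  w <- function(i, j) net$edges$weight[net$edges$i == i & net$edges$j == j]
  expect_equal(w(1, 3), 0)                   # |C| = 1: perfect communication
  expect_equal(w(1, 4), 1)                   # |C| = e^-1
  expect_equal(w(2, 4), -log(0.5))           # sign of C irrelevant to weight
  expect_length(w(1, 2), 0)                  # sequence neighbors excluded
  expect_length(w(3, 4), 0)

  # monotone in the occupancy threshold: raising it never adds edges
  set.seed(91)
  occ2 <- matrix(runif(16), 4); occ2 <- (occ2 + t(occ2)) / 2; diag(occ2) <- 1
  dimnames(occ2) <- dimnames(C)
  lo <- build_network(C, occ2, run_config(occupancy_min = 0.3))
  hi <- build_network(C, occ2, run_config(occupancy_min = 0.6))
  expect_true(all(paste(hi$edges$i, hi$edges$j) %in% paste(lo$edges$i, lo$edges$j)))
})

test_that("single-path edge betweenness matches enumeration", {
  # path graph a-b-c: both pairs (a,b) and (a,c) cross edge a-b
  path <- dynamical_network(data.frame(i = c(1, 2), j = c(2, 3),
                                       weight = c(1, 1)), 3)
  eb <- edge_betweenness_paths(path)
  expect_equal(eb$betweenness[eb$i == 1 & eb$j == 2], 2)
  expect_equal(eb$betweenness[eb$i == 2 & eb$j == 3], 2)

  single <- dynamical_network(data.frame(i = 1, j = 2, weight = 0.3), 2)
  expect_equal(edge_betweenness_paths(single)$betweenness, 1)

  # two triangles joined by one bridge: the bridge carries the maximum
  ed <- data.frame(i = c(1, 1, 2, 4, 4, 5, 3),
                   j = c(2, 3, 3, 5, 6, 6, 4),
                   weight = c(1, 1, 1, 1, 1, 1, 1))
  net <- dynamical_network(ed, 6)
  eb2 <- edge_betweenness_paths(net)
  bridge <- which(eb2$i == 3 & eb2$j == 4)
  expect_equal(eb2$betweenness[bridge], max(eb2$betweenness))
  expect_equal(eb2$betweenness[bridge], 9)   # all 3x3 cross pairs

  # random weighted 8-node graph with generic weights: unique shortest paths,
  # so exhaustive enumeration is an exact oracle (and counts sum identically)
  set.seed(92)
  pairs <- t(combn(8, 2))
  keep <- runif(nrow(pairs)) < 0.45
  ed3 <- data.frame(i = pairs[keep, 1], j = pairs[keep, 2],
                    weight = round(runif(sum(keep), 0.2, 2), 3) + runif(sum(keep)) * 1e-4)
  net3 <- dynamical_network(ed3, 8)
  eb3 <- edge_betweenness_paths(net3)
  oracle <- betweenness_oracle(net3$edges, 8)
  expect_equal(eb3$betweenness, unname(oracle[paste(eb3$i, eb3$j)]))
})

test_that("community detection recovers planted and degenerate structures", {
  # two disconnected triangles are two communities
  tri2 <- dynamical_network(data.frame(i = c(1, 1, 2, 4, 4, 5),
                                       j = c(2, 3, 3, 5, 6, 6),
                                       weight = 0.2), 6)
  gn <- girvan_newman(tri2)
  expect_equal(gn$n_communities, 2L)
  expect_equal(gn$membership[1:3], rep(gn$membership[1], 3))
  expect_equal(gn$membership[4:6], rep(gn$membership[4], 3))

  # complete graph with equal weights has no substructure
  k4 <- t(combn(4, 2))
  gk4 <- girvan_newman(dynamical_network(
    data.frame(i = k4[, 1], j = k4[, 2], weight = 0.5), 4))
  expect_equal(gk4$n_communities, 1L)

  # planted two-block graph, 12 nodes, p_in = 0.9, p_out = 0.05
  set.seed(93)
  blocks <- rep(1:2, each = 6)
  pairs <- t(combn(12, 2))
  p <- ifelse(blocks[pairs[, 1]] == blocks[pairs[, 2]], 0.9, 0.05)
  keep <- runif(nrow(pairs)) < p
  ed <- data.frame(i = pairs[keep, 1], j = pairs[keep, 2],
                   affinity = 0.9, occupancy = 1)
  net <- dynamical_network(ed, 12)
  gn2 <- girvan_newman(net)
  expect_equal(compare_partitions(gn2$membership, blocks)$ari, 1)
})

test_that("planted two-community trajectories are partitioned exactly", {
  traj <- make_grouped_trajectory(seed = 5)
  C <- cross_correlation(traj)
  occ <- contact_occupancy(traj, 4.5)
  net <- build_network(C, occ, run_config())
  gn <- girvan_newman(net)
  truth <- attr(traj, "meta")$groups
  expect_equal(gn$n_communities, 2L)
  expect_equal(compare_partitions(gn$membership, truth)$ari, 1)
})

test_that("girvan-newman agrees with the reference implementation on toys", {
  # two triangles joined by a bridge, uniform weights: the one regime where
  # the reference implementation's weight semantics coincide with ours
  ed <- data.frame(i = c(1, 1, 2, 3, 4, 4, 5),
                   j = c(2, 3, 3, 4, 5, 6, 6),
                   weight = 1)
  net <- dynamical_network(ed, 6)
  ours <- girvan_newman(net)
  g <- as_igraph(net)
  refc <- suppressWarnings(
    igraph::cluster_edge_betweenness(g, weights = NULL, modularity = TRUE))
  expect_equal(compare_partitions(ours$membership,
                                  igraph::membership(refc))$ari, 1)
  expect_equal(ours$n_communities, 2L)
})

test_that("optimal paths rank simple paths like exhaustive enumeration", {
  # diamond with unequal weights
  ed <- data.frame(i = c(1, 1, 2, 3, 2),
                   j = c(2, 3, 4, 4, 3),
                   weight = c(0.4, 1.0, 0.9, 0.2, 0.3))
  net <- dynamical_network(ed, 4, resid = c(10, 20, 30, 40))
  got <- optimal_paths(net, 10, 40, n_suboptimal = 5)
  expect_equal(got$status, "ok")
  oracle <- enumerate_simple_paths(net$edges, 4, 1, 4)
  ws <- sort(vapply(oracle, `[[`, numeric(1), "weight"))
  expect_equal(vapply(got$paths, `[[`, numeric(1), "weight"),
               ws[seq_along(got$paths)], tolerance = 1e-12)
  expect_equal(got$paths[[1]]$residues, c(10, 20, 30, 40))  # 0.4+0.3+0.2

  # simple chain
  chain <- dynamical_network(data.frame(i = c(1, 2), j = c(2, 3),
                                        weight = c(0.5, 0.7)), 3)
  p <- optimal_paths(chain, 1, 3, 0)
  expect_equal(p$paths[[1]]$residues, 1:3)
  expect_equal(p$paths[[1]]$weight, 1.2)

  # isolated node
  iso <- dynamical_network(data.frame(i = 1, j = 2, weight = 1), 3)
  expect_equal(optimal_paths(iso, 1, 3)$status, "no path")
})

test_that("partition comparison has the expected closed-form behavior", {
  expect_equal(compare_partitions(c(1, 1, 2, 2), c(2, 2, 1, 1))$ari, 1)
  # all singletons vs one block: chance-level agreement, index 0
  expect_equal(compare_partitions(1:6, rep(1, 6))$ari, 0)
  # one node moved between two blocks of 6: exactly one off-diagonal unit
  a <- rep(1:2, each = 6)
  b <- a; b[6] <- 2
  tab <- compare_partitions(a, b)$table
  expect_equal(sort(as.numeric(tab)), c(0, 1, 5, 6))
  expect_error(compare_partitions(1:3, 1:4), "different node sets")
})
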