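test_that("simple ratio index matches hand-enumerated events", {
  # events: {A,B}, {A}, {B,C} -> SRI(A,B) = 1/3 (both once, either three)
  g <- tiny_gbi()
  net <- simple_ratio_index(g)
  expect_equal(net$adjacency["A", "B"], 1 / 3)
  expect_equal(net$adjacency["A", "C"], 0)          # never co-observed
  expect_equal(net$adjacency["B", "C"], 1 / 2)
  # always together: SRI = 1
  g2 <- gbi_matrix(rbind(c(1, 1), c(1, 1)), individual_ids = c("A", "B"))
  expect_equal(simple_ratio_index(g2)$adjacency["A", "B"], 1)
})

test_that("simple ratio index equals the brute-force oracle on random GBIs", {
  set.seed(5)
  for (rep in 1:30) {
    g <- random_gbi(sample(2:50, 1), sample(2:10, 1), p = runif(1, 0.1, 0.8))
    expect_identical(simple_ratio_index(g)$adjacency, sri_oracle(g))
  }
})

test_that("focal samples convert to one event per sample", {
  f <- focal_sample_set(c("s1", "s2", "s3"), c("A", "B", "C"),
                        list(c("B", "C"), c("C"), character(0)))
  g <- focal_to_gbi(f)
  expect_equal(dim(g), c(3L, 3L))
  expect_equal(unname(g$membership[1, ]), c(1L, 1L, 1L))
  expect_equal(unname(g$membership[3, ]), c(0L, 0L, 1L))   # lone focal
  # two samples sharing members stay distinct rows
  f2 <- focal_sample_set(c("s1", "s2"), c("A", "A"),
                         list("B", "B"))
  expect_equal(nrow(focal_to_gbi(f2)$membership), 2L)
})

test_that("SRI from focal data is invariant to sample order", {
  set.seed(9)
  f <- random_focals(15)
  perm <- sample.int(15)
  f_shuffled <- focal_sample_set(f$sample_id[perm], f$focal[perm],
                                 f$associates[perm], f$time[perm])
  a <- simple_ratio_index(focal_to_gbi(f))$adjacency
  b <- simple_ratio_index(focal_to_gbi(f_shuffled))$adjacency
  expect_equal(b[rownames(a), colnames(a)], a)
})

test_that("trajectory events group individuals by cell and step", {
  # A and B share cell (2,3) at one step; C elsewhere
  x <- rbind(c(2L, 2L, 0L), c(1L, 2L, 3L))
  y <- rbind(c(3L, 3L, 0L), c(1L, 1L, 3L))
  tr <- trajectory_set(x, y, c("A", "B", "C"), n_days = 1, steps_per_day = 2,
                       grid_width = 4, grid_height = 4)
  g <- trajectories_to_gbi(tr)
  sizes <- rowSums(g$membership)
  expect_equal(sort(unname(sizes)), c(1, 1, 1, 1, 2))
  pair_row <- which(sizes == 2)
  expect_equal(unname(g$membership[pair_row, ]), c(1L, 1L, 0L))
  expect_equal(g$event_day, rep(1L, 5))
})

test_that("trajectory networks behave at the co-occurrence extremes", {
  # all individuals in distinct cells throughout -> all-zero network
  x <- matrix(rep(c(0L, 1L, 2L), each = 4), 4, 3)
  y <- matrix(0L, 4, 3)
  tr <- trajectory_set(x, y, c("A", "B", "C"), 2, 2, 4, 4)
  expect_true(all(simple_ratio_index(trajectories_to_gbi(tr))$adjacency == 0))
  # A and B always in the same cell -> SRI 1
  tr2 <- trajectory_set(matrix(1L, 4, 2), matrix(2L, 4, 2), c("A", "B"),
                        2, 2, 4, 4)
  expect_equal(simple_ratio_index(trajectories_to_gbi(tr2))$adjacency["A", "B"], 1)
})

test_that("trajectory SRI is invariant to translating the grid", {
  set.seed(11)
  tr <- random_trajectories(N = 5, w = 4, h = 4)
  shifted <- trajectory_set(tr$x + 3L, tr$y + 2L, colnames(tr$x),
                            tr$n_days, tr$steps_per_day, 8, 8)
  a <- simple_ratio_index(trajectories_to_gbi(tr))$adjacency
  b <- simple_ratio_index(trajectories_to_gbi(shifted))$adjacency
  expect_equal(b, a)
})

test_that("fast trajectory SRI agrees with the GBI construction", {
  set.seed(12)
  for (rep in 1:5) {
    tr <- random_trajectories(N = 5, n_days = 3, steps = 4, w = 3, h = 3)
    expect_equal(socialnull:::.sri_traj_adj(tr),
                 simple_ratio_index(trajectories_to_gbi(tr))$adjacency)
  }
})

test_that("weighted degree sums edge weights and satisfies the handshake identity", {
  A <- matrix(0, 3, 3, dimnames = rep(list(c("A", "B", "C")), 2))
  A["A", "B"] <- A["B", "A"] <- 0.5
  A["A", "C"] <- A["C", "A"] <- 0.25
  net <- weighted_network(A)
  expect_equal(weighted_degree(net)[["A"]], 0.75)
  set.seed(13)
  g <- random_gbi(20, 8)
  net2 <- simple_ratio_index(g)
  expect_equal(sum(weighted_degree(net2)),
               2 * sum(net2$adjacency[upper.tri(net2$adjacency)]))
})

test_that("median thresholding keeps strictly the top half of edges", {
  A <- matrix(0, 4, 4, dimnames = rep(list(letters[1:4]), 2))
  A[1, 2] <- A[2, 1] <- 0.1; A[1, 3] <- A[3, 1] <- 0.2
  A[1, 4] <- A[4, 1] <- 0.3; A[2, 3] <- A[3, 2] <- 0.4
  thr <- threshold_at_median(weighted_network(A))
  kept <- thr$adjacency[upper.tri(thr$adjacency)]
  expect_equal(sum(kept), 2)                       # median 0.25: 0.3 and 0.4
  expect_equal(thr$adjacency[1, 4], 1)
  expect_equal(thr$adjacency[2, 3], 1)
  # equal weights: strictly-above rule removes everything
  B <- matrix(0.5, 3, 3); diag(B) <- 0
  expect_true(all(threshold_at_median(weighted_network(B))$adjacency == 0))
  expect_error(threshold_at_median(weighted_network(matrix(0, 3, 3))),
               "nonzero")
  # binary degree after thresholding is bounded by N - 1
  set.seed(14)
  net <- simple_ratio_index(random_gbi(30, 8))
  expect_true(all(binary_degree(net, "median") <= 7))
})

test_that("dyad categories code both-male 1, mixed 2, both-female 3", {
  nt <- node_table(c("a", "b", "c"), sex = c("M", "F", "M"))
  dc <- dyad_category_matrix(nt, "sex")
  expect_equal(dc$values["a", "c"], 1L)   # both males
  expect_equal(dc$values["a", "b"], 2L)   # mixed
  nt2 <- node_table(c("a", "b"), sex = c("F", "F"))
  expect_equal(dyad_category_matrix(nt2, levels = c("F", "M"))$values["a", "b"],
               3L)
  expect_error(dyad_category_matrix(
    node_table(letters[1:3], sex = c("F", "M", "X"))), "binary")
})

test_that("network metrics cover the documented edge cases", {
  A <- matrix(1, 3, 3); diag(A) <- 0
  net <- weighted_network(A)
  expect_equal(network_metric(net, "mean_strength"), 2)
  expect_equal(network_metric(net, "cv_edge_weights"), 0)
  expect_equal(network_metric(net, "density"), 1)
  empty <- weighted_network(matrix(0, 3, 3))
  expect_equal(network_metric(empty, "density"), 0)
  expect_equal(network_metric(empty, "mean_degree"), 0)
})
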