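test_that("node permutation preserves the attribute multiset and network", {
  set.seed(21)
  nt <- node_table(letters[1:6], sex = c("M", "M", "M", "F", "F", "F"),
                   mass = 1:6)
  np <- node_permutation(nt)
  expect_equal(sort(np$sex), sort(nt$sex))
  expect_equal(sort(np$mass), sort(nt$mass))
  expect_equal(np$individual, nt$individual)
  # attributes move jointly: (sex, mass) pairs survive as pairs
  expect_setequal(paste(np$sex, np$mass), paste(nt$sex, nt$mass))
  # all nodes identical -> output identical
  same <- node_table(letters[1:4], sex = rep("F", 4))
  expect_equal(node_permutation(same), same)
})

test_that("node permutations are uniform over label arrangements", {
  set.seed(22)
  nt <- node_table(c("a", "b", "c"), v = c(1, 2, 3))
  draws <- replicate(3000, paste(node_permutation(nt)$v, collapse = ""))
  tab <- table(draws)
  expect_equal(length(tab), 6L)
  expect_gt(chisq.test(tab)$p.value, 0.01)
})

test_that("restricted node permutation never crosses classes", {
  set.seed(23)
  nt <- node_table(letters[1:4], sex = c("F", "M", "F", "M"))
  grouping <- c("g1", "g1", "g2", "g2")
  for (r in 1:50) {
    np <- restricted_node_permutation(nt, grouping)
    expect_setequal(np$sex[1:2], nt$sex[1:2])
    expect_setequal(np$sex[3:4], nt$sex[3:4])
  }
  # singleton classes force the identity
  expect_equal(restricted_node_permutation(nt, letters[1:4]), nt)
  # grouping can be an attribute name
  nt$site <- grouping
  np <- restricted_node_permutation(nt, "site")
  expect_setequal(np$sex[1:2], nt$sex[1:2])
})

test_that("edge permutation conserves edge count and the weight multiset", {
  set.seed(24)
  A <- matrix(0, 3, 3, dimnames = rep(list(c("A", "B", "C")), 2))
  A[1, 2] <- A[2, 1] <- 0.7
  net <- weighted_network(A)
  for (r in 1:20) {
    ep <- edge_permutation(net)
    w <- ep$adjacency[upper.tri(ep$adjacency)]
    expect_equal(sum(w > 0), 1L)
    expect_equal(sort(w[w > 0]), 0.7)
  }
  B <- matrix(runif(25), 5, 5); B <- B + t(B); diag(B) <- 0
  net2 <- weighted_network(B)
  ep2 <- edge_permutation(net2)
  expect_equal(sort(ep2$adjacency[upper.tri(ep2$adjacency)]),
               sort(B[upper.tri(B)]))
  expect_equal(network_metric(ep2, "density"), 1)
})

test_that("checkerboards are found exactly where they exist", {
  g <- gbi_matrix(rbind(c(1L, 0L), c(0L, 1L)), individual_ids = c("A", "B"))
  cb <- find_checkerboard(g, max_attempts = 1000)
  expect_false(is.null(cb))
  expect_setequal(cb$ids, c("A", "B"))
  # all-ones matrix has no checkerboard
  ones <- gbi_matrix(matrix(1L, 2, 2))
  expect_null(find_checkerboard(ones, max_attempts = 500))
  # a blocking restriction yields none
  g2 <- gbi_matrix(rbind(c(1L, 0L), c(0L, 1L)), event_day = c(1L, 2L))
  expect_null(find_checkerboard(g2, swap_restriction(within_day = TRUE),
                                max_attempts = 500))
  # restrictions referencing absent metadata are rejected up front
  expect_error(find_checkerboard(g, swap_restriction(within_day = TRUE)),
               "event_day")
})

test_that("checkerboard selection is uniform among candidates", {
  set.seed(25)
  g <- gbi_matrix(diag(3) + 0L)
  # candidates: ordered pairs (i, j), i != j, with a = event i, b = event j
  draws <- replicate(1800, {
    cb <- find_checkerboard(g, max_attempts = 1000)
    paste(cb$i, cb$j)
  })
  tab <- table(draws)
  expect_equal(length(tab), 6L)
  expect_gt(chisq.test(tab)$p.value, 0.01)
})

test_that("a datastream swap flips exactly one checkerboard", {
  set.seed(26)
  g <- gbi_matrix(rbind(c(1L, 0L), c(0L, 1L)), individual_ids = c("A", "B"))
  sw <- datastream_swap(g)
  expect_true(attr(sw, "swap_performed"))
  expect_equal(unname(sw$membership), rbind(c(0L, 1L), c(1L, 0L)))
  # impossible swap flags itself instead of looping
  ones <- gbi_matrix(matrix(1L, 2, 2))
  sw2 <- datastream_swap(ones, max_attempts = 200)
  expect_false(attr(sw2, "swap_performed"))
  expect_equal(sw2$membership, ones$membership)
})

test_that("chained datastream swaps conserve group sizes and sighting counts", {
  set.seed(27)
  g <- random_gbi(25, 10, with_meta = TRUE)
  rs <- rowSums(g$membership); cs <- colSums(g$membership)
  cur <- g
  for (s in 1:500) {
    cur <- datastream_swap(cur)
    if (s %% 100 == 0) {
      expect_identical(rowSums(cur$membership), rs)
      expect_identical(colSums(cur$membership), cs)
    }
  }
  # restricted swaps respect the metadata predicates
  restr <- swap_restriction(within_time = TRUE)
  cur <- g
  for (s in 1:100) cur <- datastream_swap(cur, restr)
  expect_identical(rowSums(cur$membership), rs)
  expect_identical(colSums(cur$membership), cs)
  # per time period, each individual's sighting count is conserved too
  for (t in unique(g$event_time)) {
    sel <- g$event_time == t
    expect_identical(colSums(cur$membership[sel, , drop = FALSE]),
                     colSums(g$membership[sel, , drop = FALSE]))
  }
})

test_that("within-class datastream swaps only exchange same-class individuals", {
  set.seed(28)
  g <- random_gbi(20, 8)
  nodes <- node_table(colnames(g$membership),
                      sex = rep(c("F", "M"), each = 4))
  restr <- swap_restriction(within_class = "sex")
  cur <- g
  for (s in 1:200) cur <- datastream_swap(cur, restr, nodes)
  # each sex's column block keeps its row sums (no cross-sex movement)
  f_cols <- nodes$sex == "F"
  expect_identical(rowSums(cur$membership[, f_cols]),
                   rowSums(g$membership[, f_cols]))
  expect_error(datastream_swap(g, restr), "node table")
})

test_that("focal swaps follow the four-distinct-individuals rule", {
  set.seed(29)
  # smallest legal swap
  f <- focal_sample_set(c("s1", "s2"), c("A", "C"), list("B", "D"))
  sw <- focal_swap(f)
  expect_true(attr(sw, "swap_performed"))
  expect_equal(sw$associates[[1]], "D")
  expect_equal(sw$associates[[2]], "B")
  # B occurs in both samples: no swap possible
  f2 <- focal_sample_set(c("s1", "s2"), c("A", "C"), list("B", "B"))
  expect_false(attr(focal_swap(f2, max_attempts = 300), "swap_performed"))
  # associate equals the other focal: no swap possible
  f3 <- focal_sample_set(c("s1", "s2"), c("A", "C"), list("C", "A"))
  expect_false(attr(focal_swap(f3, max_attempts = 300), "swap_performed"))
})

test_that("chained focal swaps conserve sample sizes and occurrence counts", {
  set.seed(30)
  f <- random_focals(20)
  sizes <- lengths(f$associates)
  occ <- focal_occurrence_counts(f)
  cur <- f
  for (s in 1:500) cur <- focal_swap(cur)
  expect_identical(lengths(cur$associates), sizes)
  expect_identical(focal_occurrence_counts(cur), occ)
  expect_identical(cur$focal, f$focal)
  # no associate duplicated or equal to its focal after any number of swaps
  for (k in seq_along(cur$sample_id)) {
    expect_false(anyDuplicated(cur$associates[[k]]) > 0)
    expect_false(cur$focal[k] %in% cur$associates[[k]])
  }
})

test_that("focal swap restrictions apply to times and focal classes", {
  set.seed(31)
  f <- focal_sample_set(c("s1", "s2", "s3", "s4"),
                        c("A", "B", "C", "D"),
                        list("E", "F", "G", "H"),
                        time = c(1L, 1L, 2L, 2L))
  nodes <- node_table(LETTERS[1:8],
                      sex = c("F", "F", "M", "M", "F", "F", "M", "M"))
  restr <- swap_restriction(within_time = TRUE, within_class = "sex")
  for (r in 1:50) {
    sw <- focal_swap(f, restr, nodes)
    if (!isTRUE(attr(sw, "swap_performed"))) next
    moved <- which(vapply(seq_len(4), function(k)
      !setequal(sw$associates[[k]], f$associates[[k]]), logical(1)))
    expect_equal(length(moved), 2L)
    expect_equal(f$time[moved[1]], f$time[moved[2]])
    expect_equal(nodes$sex[match(f$focal[moved[1]], nodes$individual)],
                 nodes$sex[match(f$focal[moved[2]], nodes$individual)])
  }
})

test_that("day shuffling preserves each individual's daily tracks", {
  set.seed(32)
  tr <- random_trajectories(N = 4, n_days = 4, steps = 5)
  sh <- trajectory_day_shuffle(tr)
  expect_identical(daily_track_multisets(sh), daily_track_multisets(tr))
  expect_identical(track_multisets(sh), track_multisets(tr))
  # one individual, two days: identity or exchange
  tr2 <- trajectory_set(matrix(c(0L, 1L), 2, 1), matrix(0L, 2, 1), "A",
                        n_days = 2, steps_per_day = 1, grid_width = 4,
                        grid_height = 4)
  out <- replicate(50, paste(trajectory_day_shuffle(tr2)$x, collapse = ""))
  expect_setequal(unique(out), c("01", "10"))
  # identical constant tracks make the network shuffle-invariant
  tr3 <- trajectory_set(matrix(1L, 6, 3), matrix(1L, 6, 3), c("A", "B", "C"),
                        3, 2, 4, 4)
  expect_equal(socialnull:::.sri_traj_adj(trajectory_day_shuffle(tr3)),
               socialnull:::.sri_traj_adj(tr3))
})

test_that("identity swapping preserves day-level track sets but not individuals'", {
  set.seed(33)
  tr <- random_trajectories(N = 4, n_days = 3, steps = 5)
  sw <- track_identity_swap(tr)
  for (d in seq_len(tr$n_days)) {
    rows <- (d - 1L) * tr$steps_per_day + seq_len(tr$steps_per_day)
    day_tracks <- function(z) sort(unname(apply(
      rbind(z$x[rows, ], z$y[rows, ]), 2, paste, collapse = "|")))
    expect_identical(day_tracks(sw), day_tracks(tr))
  }
  # an individual's own track multiset is generally not preserved
  set.seed(34)
  changed <- replicate(20, {
    sw <- track_identity_swap(tr)
    !identical(track_multisets(sw), track_multisets(tr))
  })
  expect_true(any(changed))
})

test_that("null chains have the right length, are reproducible, and report misses", {
  set.seed(35)
  g <- random_gbi(12, 6)
  stat <- function(d) sum(d$membership)     # conserved under swaps
  r <- run_null_chain(g, "datastream", stat, n_permutations = 40, seed = 7)
  expect_s3_class(r, "permutation_result")
  expect_length(r$null_statistics, 40)
  expect_true(all(r$null_statistics == r$observed_statistic))
  expect_equal(r$p_two_tailed, 1)
  # bit-for-bit reproducibility under a fixed seed
  stat2 <- function(d) network_metric(simple_ratio_index(d),
                                      "cv_edge_weights")
  a <- run_null_chain(g, "datastream", stat2, 25, seed = 42)
  b <- run_null_chain(g, "datastream", stat2, 25, seed = 42)
  expect_identical(a, b)
  # non-finite statistics are recorded as missing and excluded
  flip <- local({ k <- 0; function(d) { k <<- k + 1
    if (k %% 2 == 0) NaN else 1 } })
  r2 <- run_null_chain(g, "datastream", flip, 10, seed = 1)
  expect_equal(r2$n_missing, 5)
  expect_equal(r2$p_two_tailed, 1)
  expect_error(run_null_chain(g, "datastream", stat, 0), "positive")
  expect_error(run_null_chain(g, "node", stat, 5), "node_table")
})

test_that("a single serial swap changes the data by at most four cells", {
  set.seed(36)
  g <- random_gbi(15, 8)
  before <- g$membership
  one <- datastream_swap(g)
  expect_lte(sum(one$membership != before), 4L)
})

test_that("conserved statistics make focal and day-shuffle null series constant", {
  set.seed(37)
  f <- random_focals(10)
  nf <- run_null_chain(f, "focal",
                       function(d) length(unlist(d$associates)), 20)
  expect_true(all(nf$null_statistics == nf$observed_statistic))
  tr <- random_trajectories()
  nt <- run_null_chain(tr, "day-shuffle",
                       function(d) sum(!is.na(d$x)), 20)
  expect_true(all(nt$null_statistics == nt$observed_statistic))
})

test_that("null network series preserve margins and have the right length", {
  set.seed(38)
  g <- random_gbi(15, 6)
  nets <- null_network_series(g, n = 8, swaps_per_step = 3, seed = 2)
  expect_length(nets, 8)
  for (nt in nets) expect_s3_class(nt, "weighted_network")
})
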