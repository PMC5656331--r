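test_that("permutation p-values follow the two-tailed doubling rule", {
  # exactly 2.5% of null values greater than observed, no ties
  nulls <- c(rep(1, 975), rep(3, 25))
  p <- permutation_pvalues(2, nulls)
  expect_equal(p$p_upper, 0.025)
  expect_equal(p$p_two_tailed, 0.05)
  # proportion greater = 0.975: doubling the other tail gives 0.05 again
  nulls2 <- c(rep(3, 975), rep(1, 25))
  p2 <- permutation_pvalues(2, nulls2)
  expect_equal(p2$p_upper, 0.975)
  expect_equal(p2$p_lower, 0.025)
  expect_equal(p2$p_two_tailed, 0.05)
  # observed tied with every null value
  p3 <- permutation_pvalues(1, rep(1, 100))
  expect_equal(p3$p_upper, 1)
  expect_equal(p3$p_lower, 1)
  expect_equal(p3$p_two_tailed, 1)
  expect_error(permutation_pvalues(1, NA_real_), "non-missing")
})

test_that("permutation p-values match brute-force counting on random series", {
  set.seed(41)
  for (rep in 1:25) {
    nulls <- sample(c(rnorm(40), rep(0.3, 10), NA))
    obs <- sample(c(0.3, rnorm(1)), 1)
    expect_equal(permutation_pvalues(obs, nulls),
                 pvalue_oracle(obs, nulls))
    p <- permutation_pvalues(obs, nulls)
    expect_gte(p$p_upper + p$p_lower, 1)    # ties counted on both sides
  }
})

test_that("the slope statistic codes binary attributes alphabetically", {
  nt <- node_table(letters[1:4], sex = c("M", "M", "F", "F"))
  # F coded 0, M coded 1: slope for M = mean(M) - mean(F) = -1
  expect_equal(node_statistic_slope(c(1, 1, 2, 2), nt, "sex"), -1)
  # constant values: slope 0
  expect_equal(node_statistic_slope(rep(2, 4), nt, "sex"), 0)
  # invariant to individual ordering when values are named
  v <- c(a = 1, b = 1, c = 2, d = 2)
  perm <- c(3, 1, 4, 2)
  nt_perm <- node_table(letters[perm], sex = c("M", "M", "F", "F")[perm])
  expect_equal(node_statistic_slope(v, nt_perm, "sex"), -1)
  # numeric predictors use plain OLS
  nt2 <- node_table(letters[1:3], z = c(0, 1, 2))
  expect_equal(node_statistic_slope(c(0, 2, 4), nt2, "z"), 2)
})

test_that("stabilisation series is consistent with the final p-value", {
  set.seed(42)
  r <- run_null_chain(random_gbi(12, 6), "datastream",
                      function(d) network_metric(simple_ratio_index(d),
                                                 "cv_edge_weights"),
                      n_permutations = 30, seed = 3)
  ser <- stabilisation_series(r)
  expect_equal(nrow(ser), 30)
  last <- ser[30, ]
  expect_equal(last$running_p_two_tailed, r$p_two_tailed)
  expect_equal(last$running_mean,
               mean(r$null_statistics, na.rm = TRUE))
  expect_true(all(ser$running_p_two_tailed >= 0 &
                  ser$running_p_two_tailed <= 1))
  # monotone statistic series -> monotone running mean
  fake <- socialnull:::.permutation_result(0.5, sort(runif(20)))
  rm_ <- stabilisation_series(fake)$running_mean
  expect_true(all(diff(rm_) >= 0))
})

test_that("perm_test validates method/data pairings", {
  set.seed(43)
  sim <- simulate_group_data(n_individuals = 12, n_events = 30, seed = 1)
  expect_error(perm_test(strength ~ sex, sim$gbi, sim$nodes, null = "focal"),
               "focal")
  tr <- random_trajectories()
  nt <- node_table(colnames(tr$x), sex = c("F", "F", "M", "M"))
  expect_error(perm_test(strength ~ sex, tr, nt, null = "datastream"),
               "group-by-individual")
  expect_error(perm_test(size ~ sex, sim$gbi, sim$nodes),
               "strength")
  expect_error(perm_test(strength ~ sex, sim$gbi,
                         sim$nodes[-1, ], null = "node"), "cover")
})

test_that("perm_test returns a coherent fitted object", {
  set.seed(44)
  sim <- simulate_group_data(n_individuals = 16, n_events = 40,
                             bias_fraction = 0, seed = 2)
  pt <- perm_test(strength ~ sex, sim$gbi, sim$nodes, null = "node",
                  n_permutations = 99, seed = 5)
  expect_s3_class(pt, "perm_test")
  expect_s3_class(pt, "permutation_result")
  expect_named(coef(pt), "sex")
  expect_length(pt$null_statistics, 99)
  # observed slope equals the slope of strength on sex computed directly
  s <- weighted_degree(simple_ratio_index(sim$gbi))
  expect_equal(unname(coef(pt)),
               node_statistic_slope(s, sim$nodes, "sex"))
  # same seed, same everything
  pt2 <- perm_test(strength ~ sex, sim$gbi, sim$nodes, null = "node",
                   n_permutations = 99, seed = 5)
  expect_identical(pt$null_statistics, pt2$null_statistics)
  # summary and print run
  expect_output(print(pt), "Permutation test")
  expect_output(print(summary(pt)), "Null distribution")
})

test_that("edge and restricted-node nulls run through perm_test", {
  set.seed(45)
  sim <- simulate_group_data(n_individuals = 12, n_events = 30, seed = 3)
  pe <- perm_test(strength ~ sex, sim$gbi, sim$nodes, null = "edge",
                  n_permutations = 50, seed = 1)
  expect_length(pe$null_statistics, 50)
  pr <- perm_test(strength ~ sex, sim$gbi, sim$nodes,
                  null = "node-restricted",
                  grouping = rep(c("x", "y"), 6),
                  n_permutations = 50, seed = 1)
  expect_length(pr$null_statistics, 50)
  expect_error(perm_test(strength ~ sex, sim$gbi, sim$nodes,
                         null = "node-restricted", n_permutations = 5),
               "grouping")
})

test_that("comparing a dataset with itself gives a zero difference", {
  set.seed(46)
  g <- random_gbi(15, 6)
  cmp <- compare_networks(g, g, metric = "mean_strength",
                          n_permutations = 20, seed = 1)
  expect_equal(cmp$observed_statistic, 0)
  expect_length(cmp$null_statistics, 20)
})

test_that("swapping the two networks negates the observed difference", {
  set.seed(47)
  a <- random_gbi(15, 6); b <- random_gbi(20, 6, p = 0.5)
  ab <- compare_networks(a, b, metric = "mean_strength",
                         n_permutations = 15, seed = 9)
  ba <- compare_networks(b, a, metric = "mean_strength",
                         n_permutations = 15, seed = 9)
  expect_equal(ab$observed_statistic, -ba$observed_statistic)
})

test_that("run_experiment writes a reproducible report bundle", {
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  cfg <- list(scenario = list(type = "group", n_individuals = 12,
                              n_events = 30),
              model = "strength ~ sex", nulls = c("datastream", "node"),
              chain = list(n_permutations = 20, swaps_per_step = 1),
              seed = 4)
  res <- run_experiment(cfg, dir1)
  expect_named(res, c("datastream", "node"))
  expect_true(file.exists(file.path(dir1, "summary.json")))
  expect_true(file.exists(file.path(dir1, "datastream_nulls.csv")))
  run_experiment(cfg, dir2)
  for (f in c("summary.json", "datastream_nulls.csv",
              "node_stabilisation.csv", "config.json"))
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
  # invalid configs are rejected
  cfg$chain$n_permutations <- 0
  expect_error(run_experiment(cfg), "positive")
  cfg$chain$n_permutations <- 5
  cfg$scenario$type <- "gps"
  cfg$scenario$n_events <- NULL
  cfg$nulls <- "datastream"
  expect_error(run_experiment(cfg), "group-by-individual")
})
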