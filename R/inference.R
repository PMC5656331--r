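# Test statistics, permutation p-values and the perm_test() fitting interface.

#' Permutation p-values
#'
#' Significance from a null distribution of test statistics: the upper
#' (lower) p-value is the proportion of null statistics greater (less) than
#' or equal to the observed one -- ties count on both sides, which is
#' conservative -- and the two-tailed p-value is twice the smaller tail,
#' clamped at 1. An observed value exceeded by fewer than 2.5% of the null
#' values (or by more than 97.5% of them) is therefore significant at
#' P = 0.05 two-tailed. Missing null values are dropped from the
#' denominator.
#'
#' @param observed observed test statistic.
#' @param null_statistics numeric vector of null statistics (`NA` allowed).
#' @return List with `p_upper`, `p_lower`, `p_two_tailed`.
#' @examples
#' permutation_pvalues(2, c(rep(1, 975), rep(3, 25)))$p_two_tailed  # 0.05
#' @export
permutation_pvalues <- function(observed, null_statistics) {
  nulls <- null_statistics[!is.na(null_statistics)]
  if (!length(nulls)) stop("no non-missing null statistics")
  if (!is.finite(observed)) stop("observed statistic must be finite")
  p_upper <- mean(nulls >= observed)
  p_lower <- mean(nulls <= observed)
  list(p_upper = p_upper, p_lower = p_lower,
       p_two_tailed = min(1, 2 * min(p_upper, p_lower)))
}

#' Node-level slope statistic
#'
#' The ordinary least-squares slope of a per-individual quantity (e.g.
#' weighted degree) on a node attribute, the recommended test statistic for
#' node-level permutation tests: unlike t or Z, the coefficient describes
#' the data rather than departure from a parametric null. Binary attributes
#' are coded 0/1 with the alphabetically first level as reference, so for a
#' sex attribute with values F/M the slope is the male minus female mean.
#'
#' @param node_values named numeric vector of per-individual values (names
#'   matching the node table), or unnamed in node-table order.
#' @param nodes a [node_table()].
#' @param predictor attribute name; binary (character/factor/logical) or
#'   numeric.
#' @return The slope coefficient (a single number).
#' @export
node_statistic_slope <- function(node_values, nodes, predictor) {
  if (!is.null(names(node_values)))
    nodes <- .align_nodes(nodes, names(node_values))
  if (length(node_values) != nrow(nodes))
    stop("node_values must have one entry per individual")
  if (length(node_values) < 3L) stop("slope needs at least 3 individuals")
  x <- .predictor_numeric(nodes[[predictor]], predictor)
  .ols_slope(as.numeric(node_values), x)
}

.predictor_numeric <- function(v, name) {
  if (is.null(v)) stop("attribute not found: ", name)
  if (is.numeric(v)) return(as.numeric(v))
  if (is.logical(v)) return(as.numeric(v))
  v <- as.character(v)
  lev <- sort(unique(v))
  if (length(lev) > 2L)
    stop(sprintf("attribute '%s' must be binary or numeric (levels: %s)",
                 name, paste(lev, collapse = ", ")))
  as.numeric(v == lev[length(lev)])   # alphabetically first level = 0
}

.ols_slope <- function(y, x) {
  xc <- x - mean(x)
  ssx <- sum(xc^2)
  if (ssx == 0) return(NA_real_)   # constant predictor: slope undefined
  sum(xc * y) / ssx
}

#' Stabilisation diagnostics for a permutation chain
#'
#' Tabulates, for each prefix of the null series, the running mean of the
#' null statistic and the two-tailed p-value recomputed on the first k null
#' values. Plotting these against the permutation number shows whether a
#' serial chain has stabilised -- the recommended check before trusting a
#' pre-network permutation p-value.
#'
#' @param result a `"permutation_result"`.
#' @return Data frame with columns `permutation`, `statistic`,
#'   `running_mean`, `running_p_two_tailed`.
#' @export
stabilisation_series <- function(result) {
  nulls <- result$null_statistics
  obs <- result$observed_statistic
  ok <- !is.na(nulls)
  k <- cumsum(ok)
  up <- cumsum(ok & nulls >= obs)
  lo <- cumsum(ok & nulls <= obs)
  p2 <- ifelse(k > 0, pmin(1, 2 * pmin(up / k, lo / k)), NA_real_)
  rmean <- ifelse(k > 0, cumsum(ifelse(ok, nulls, 0)) / k, NA_real_)
  data.frame(permutation = seq_along(nulls), statistic = nulls,
             running_mean = rmean, running_p_two_tailed = p2)
}

# ---------------------------------------------------------------------------
# perm_test: the fitting interface
# ---------------------------------------------------------------------------

#' Permutation test of a node-level model
#'
#' The package's central fitting function. Fits a node-level model of the
#' form `strength ~ attribute` (or `degree ~ attribute`) on the social
#' network built from the observation data, takes the OLS slope as the test
#' statistic, and compares it against the null distribution generated by the
#' requested permutation method. Four steps: build the network from the
#' observed data; compute the test statistic; randomise the data (or the
#' network / node labels) and rebuild; record the statistic for each
#' randomised dataset. Two-tailed significance follows
#' [permutation_pvalues()].
#'
#' The left-hand side of the formula is `strength` (weighted degree) or
#' `degree` (binary degree); the right-hand side a single attribute in
#' `nodes`. The network is built with the simple ratio index by default
#' (`index = "count"` for raw co-occurrence counts); trajectory data use the
#' same-cell-same-step co-occurrence rule.
#'
#' Method/data pairings: `"datastream"` needs group-by-individual data,
#' `"focal"` focal samples, `"day-shuffle"` / `"identity-swap"` trajectory
#' data; `"node"`, `"node-restricted"` and `"edge"` work with any data type
#' because they randomise the network (or its labels) after construction.
#' Mismatches are configuration errors, not silent conversions.
#'
#' @param formula model formula, e.g. `strength ~ sex`.
#' @param data a [gbi_matrix()], [focal_sample_set()] or [trajectory_set()].
#' @param nodes a [node_table()] covering all individuals in `data`.
#' @param null permutation method (see [run_null_chain()]).
#' @param index edge weights: `"sri"` or `"count"`.
#' @param n_permutations recorded null statistics (at least 1000 is
#'   customary).
#' @param restriction optional [swap_restriction()].
#' @param grouping class labels or attribute name for `"node-restricted"`.
#' @param swaps_per_step,burn_in serial-chain controls (see
#'   [run_null_chain()]).
#' @param seed optional integer for exact reproducibility.
#' @param max_attempts rejection budget per swap.
#' @return An object of classes `"perm_test"` and `"permutation_result"`,
#'   with `coef`, `summary`, `plot` and `print` methods. `coefficients`
#'   holds the observed slope; `network` the observed network; `node_values`
#'   the observed per-individual statistic.
#' @examples
#' sim <- simulate_group_data(n_individuals = 20, n_events = 50, seed = 1)
#' pt <- perm_test(strength ~ sex, sim$gbi, sim$nodes, null = "node",
#'                 n_permutations = 200, seed = 2)
#' pt
#' @export
perm_test <- function(formula, data, nodes,
                      null = c("datastream", "node", "node-restricted",
                               "edge", "focal", "day-shuffle",
                               "identity-swap"),
                      index = c("sri", "count"), n_permutations = 1000L,
                      restriction = NULL, grouping = NULL,
                      swaps_per_step = 1L, burn_in = 0L, seed = NULL,
                      max_attempts = 10000L) {
  null <- match.arg(null)
  index <- match.arg(index)
  pf <- .parse_perm_formula(formula)

  builders <- .network_builders(data, index)
  ids <- builders$ids
  nodes <- .align_nodes(nodes, ids)
  x <- .predictor_numeric(nodes[[pf$predictor]], pf$predictor)

  value_fun <- switch(pf$response,
                      strength = function(A) rowSums(A),
                      degree = function(A) rowSums(A > 0))
  slope_of_adj <- function(A) .ols_slope(value_fun(A), x)
  stat_data <- function(d) slope_of_adj(builders$adj(d))

  obs_adj <- builders$adj(data)
  observed_net <- weighted_network(obs_adj, ids)
  node_values <- stats::setNames(value_fun(obs_adj), ids)

  res <- switch(null,
    "datastream" = {
      if (!inherits(data, "gbi"))
        stop("datastream permutations need group-by-individual data; ",
             "convert focal samples explicitly with focal_to_gbi() ",
             "if that is intended")
      run_null_chain(data, "datastream", stat_data, n_permutations,
                     restriction, nodes, swaps_per_step = swaps_per_step,
                     burn_in = burn_in, seed = seed,
                     max_attempts = max_attempts)
    },
    "focal" = {
      if (!inherits(data, "focal_set"))
        stop("focal permutations need focal-sample data")
      run_null_chain(data, "focal", stat_data, n_permutations,
                     restriction, nodes, swaps_per_step = swaps_per_step,
                     burn_in = burn_in, seed = seed,
                     max_attempts = max_attempts)
    },
    "day-shuffle" = , "identity-swap" = {
      if (!inherits(data, "trajectory_set"))
        stop(null, " permutations need trajectory data")
      run_null_chain(data, null, stat_data, n_permutations, seed = seed)
    },
    "node" = {
      vals <- node_values
      run_null_chain(nodes, "node",
                     function(nd) node_statistic_slope(vals, nd,
                                                       pf$predictor),
                     n_permutations, seed = seed)
    },
    "node-restricted" = {
      vals <- node_values
      run_null_chain(nodes, "node-restricted",
                     function(nd) node_statistic_slope(vals, nd,
                                                       pf$predictor),
                     n_permutations, grouping = grouping, seed = seed)
    },
    "edge" = {
      run_null_chain(observed_net, "edge",
                     function(nt) slope_of_adj(nt$adjacency),
                     n_permutations, seed = seed)
    })

  out <- unclass(res)
  out$formula <- formula
  out$null <- null
  out$index <- index
  out$coefficients <- stats::setNames(res$observed_statistic, pf$predictor)
  out$network <- observed_net
  out$node_values <- node_values
  out$nodes <- nodes
  out$call <- match.call()
  class(out) <- c("perm_test", "permutation_result")
  out
}

.parse_perm_formula <- function(formula) {
  if (!inherits(formula, "formula") || length(formula) != 3L)
    stop("formula must look like strength ~ sex")
  response <- all.vars(formula[[2]])
  predictor <- all.vars(formula[[3]])
  if (length(response) != 1L || !response %in% c("strength", "degree"))
    stop("response must be 'strength' or 'degree'")
  if (length(predictor) != 1L)
    stop("exactly one predictor attribute is supported")
  list(response = response, predictor = predictor)
}

# closures that turn a dataset of the observed type into an adjacency matrix
.network_builders <- function(data, index) {
  if (inherits(data, "gbi")) {
    ids <- .gbi_ids(data)
    adj <- if (index == "sri") function(d) .sri_adj(d$membership)
           else function(d) { X <- crossprod(d$membership); diag(X) <- 0; X }
  } else if (inherits(data, "focal_set")) {
    ids <- focal_individuals(data)
    adj <- function(d) {
      g <- focal_to_gbi(d, individual_ids = ids)
      if (index == "sri") .sri_adj(g$membership)
      else { X <- crossprod(g$membership); diag(X) <- 0; X }
    }
  } else if (inherits(data, "trajectory_set")) {
    ids <- .traj_ids(data)
    adj <- if (index == "sri") .sri_traj_adj
           else function(d) {
             g <- trajectories_to_gbi(d)
             X <- crossprod(g$membership); diag(X) <- 0; X
           }
  } else stop("data must be a gbi, focal_set or trajectory_set")
  list(ids = ids, adj = adj)
}

#' @export
print.perm_test <- function(x, ...) {
  cat("Permutation test:", deparse(x$formula), "\n")
  cat(sprintf("  null model: %s (%s index), %d permutations\n",
              x$null, x$index, x$n_permutations))
  cat(sprintf("  observed coefficient: %.6g\n", x$observed_statistic))
  cat(sprintf("  P (two-tailed): %.4g\n", x$p_two_tailed))
  invisible(x)
}

#' @export
coef.perm_test <- function(object, ...) object$coefficients

#' @export
summary.perm_test <- function(object, ...) {
  nn <- object$null_statistics[!is.na(object$null_statistics)]
  structure(list(formula = object$formula, null = object$null,
                 index = object$index,
                 coefficients = object$coefficients,
                 n_permutations = object$n_permutations,
                 n_missing = object$n_missing,
                 null_mean = mean(nn), null_sd = stats::sd(nn),
                 null_quantiles = stats::quantile(nn, c(0.025, 0.5, 0.975)),
                 p_upper = object$p_upper, p_lower = object$p_lower,
                 p_two_tailed = object$p_two_tailed, seed = object$seed),
            class = "summary.perm_test")
}

#' @export
print.summary.perm_test <- function(x, ...) {
  cat("Permutation test:", deparse(x$formula), "\n")
  cat(sprintf("Null model: %s (%s index), %d permutations%s\n", x$null,
              x$index, x$n_permutations,
              if (x$n_missing) sprintf(" (%d missing)", x$n_missing) else ""))
  cat(sprintf("Observed coefficient: %.6g\n", x$coefficients))
  cat(sprintf("Null distribution:    mean %.4g, sd %.4g\n",
              x$null_mean, x$null_sd))
  cat(sprintf("  2.5%% / 50%% / 97.5%%: %.4g / %.4g / %.4g\n",
              x$null_quantiles[1], x$null_quantiles[2], x$null_quantiles[3]))
  cat(sprintf("P upper/lower: %.4g / %.4g\nP two-tailed:  %.4g\n",
              x$p_upper, x$p_lower, x$p_two_tailed))
  invisible(x)
}

# ---------------------------------------------------------------------------
# comparing two networks
# ---------------------------------------------------------------------------

#' Compare two networks with a simultaneous permutation null
#'
#' Tests whether two networks differ in a metric more (or less) than
#' expected by chance. The observed statistic is `metric(A) - metric(B)`;
#' both underlying datasets are then randomised simultaneously -- one
#' data-stream swap per chain step within each -- and the difference is
#' recorded after each step.
#'
#' @param gbi_a,gbi_b the two [gbi_matrix()] datasets (pre-network data are
#'   required for the data-stream null).
#' @param metric a [network_metric()] name.
#' @param n_permutations recorded differences.
#' @param index `"sri"` or `"count"`.
#' @param restriction optional [swap_restriction()] applied within each
#'   dataset.
#' @param nodes_a,nodes_b node tables for `within_class` restrictions.
#' @param swaps_per_step,burn_in,seed,max_attempts chain controls as in
#'   [run_null_chain()].
#' @return A `"permutation_result"` whose statistic is the metric
#'   difference.
#' @export
compare_networks <- function(gbi_a, gbi_b,
                             metric = c("mean_degree", "mean_strength",
                                        "cv_edge_weights", "density"),
                             n_permutations = 1000L,
                             index = c("sri", "count"), restriction = NULL,
                             nodes_a = NULL, nodes_b = NULL,
                             swaps_per_step = 1L, burn_in = 0L, seed = NULL,
                             max_attempts = 10000L) {
  metric <- match.arg(metric)
  index <- match.arg(index)
  if (!inherits(gbi_a, "gbi") || !inherits(gbi_b, "gbi"))
    stop("compare_networks needs the pre-network data of both networks")
  if (!is.null(seed)) set.seed(seed)
  .check_restriction(restriction, gbi = gbi_a, nodes = nodes_a,
                     ids = .gbi_ids(gbi_a))
  .check_restriction(restriction, gbi = gbi_b, nodes = nodes_b,
                     ids = .gbi_ids(gbi_b))
  netfun <- if (index == "sri") simple_ratio_index else co_occurrence_network
  stat <- function(a, b)
    network_metric(netfun(a), metric) - network_metric(netfun(b), metric)
  observed <- stat(gbi_a, gbi_b)
  nulls <- rep(NA_real_, n_permutations)
  cur_a <- gbi_a; cur_b <- gbi_b
  failed <- 0L
  total <- burn_in + swaps_per_step * n_permutations
  rec_at <- burn_in + swaps_per_step * seq_len(n_permutations)
  q <- 0L
  for (s in seq_len(total)) {
    cur_a <- datastream_swap(cur_a, restriction, nodes_a, max_attempts)
    cur_b <- datastream_swap(cur_b, restriction, nodes_b, max_attempts)
    if (!isTRUE(attr(cur_a, "swap_performed")) ||
        !isTRUE(attr(cur_b, "swap_performed"))) failed <- failed + 1L
    if (s == rec_at[q + 1L]) {
      q <- q + 1L
      v <- stat(cur_a, cur_b)
      nulls[q] <- if (is.finite(v)) v else NA_real_
    }
  }
  if (failed > 0L)
    warning(sprintf("%d of %d paired swap steps found no legal move", failed,
                    total))
  .permutation_result(observed, nulls, method = "datastream-paired",
                      seed = seed)
}
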