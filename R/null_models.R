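# Permutation engines. All draws come from R's global RNG so that a single
# set.seed() (or the seed argument of run_null_chain) makes a run exactly
# reproducible.

#' Swap restrictions for pre-network permutations
#'
#' Constrains which checkerboard / focal swaps are legal, so the null model
#' holds non-social structure (time, space, phenotype) constant. For
#' data-stream swaps the predicates compare the metadata of the two events;
#' for focal swaps, of the two samples. `within_class` restricts swaps to
#' pairs of individuals sharing an attribute value; for focal swaps it
#' applies to the two focal individuals (set `class_scope = "all"` to extend
#' it to the swapped associates as well). Restrictions referencing metadata
#' that the data do not carry are rejected when a run starts.
#'
#' @param within_day,within_time,within_location logicals: require the two
#'   events/samples to share the day / sampling period / location.
#' @param within_class optional attribute name (e.g. `"sex"`); requires a
#'   node table wherever the restriction is used.
#' @param class_scope for focal swaps: `"focals"` applies `within_class` to
#'   the two focal individuals, `"all"` also to the two swapped associates.
#'   Data-stream swaps always apply it to the two swapped individuals.
#' @return An object of class `"swap_restriction"`.
#' @export
swap_restriction <- function(within_day = FALSE, within_time = FALSE,
                             within_location = FALSE, within_class = NULL,
                             class_scope = c("focals", "all")) {
  structure(list(within_day = isTRUE(within_day),
                 within_time = isTRUE(within_time),
                 within_location = isTRUE(within_location),
                 within_class = within_class,
                 class_scope = match.arg(class_scope)),
            class = "swap_restriction")
}

.null_restriction <- function() swap_restriction()

# validate a restriction against the data/nodes; returns the class vector
# (per individual) or NULL
.check_restriction <- function(restriction, gbi = NULL, focals = NULL,
                               nodes = NULL, ids = NULL) {
  if (is.null(restriction)) return(NULL)
  if (!inherits(restriction, "swap_restriction"))
    stop("'restriction' must be created with swap_restriction()")
  if (!is.null(gbi)) {
    if (restriction$within_day && is.null(gbi$event_day))
      stop("within_day restriction but the data carry no event_day")
    if (restriction$within_time && is.null(gbi$event_time))
      stop("within_time restriction but the data carry no event_time")
    if (restriction$within_location && is.null(gbi$event_location))
      stop("within_location restriction but the data carry no event_location")
  }
  if (!is.null(focals)) {
    if (restriction$within_day)
      stop("focal samples carry no day metadata; use within_time")
    if (restriction$within_time && is.null(focals$time))
      stop("within_time restriction but the samples carry no time")
    if (restriction$within_location && is.null(focals$location))
      stop("within_location restriction but the samples carry no location")
  }
  if (!is.null(restriction$within_class)) {
    if (is.null(nodes))
      stop("within_class restriction needs a node table")
    nodes <- .align_nodes(nodes, ids)
    cls <- nodes[[restriction$within_class]]
    if (is.null(cls))
      stop("attribute not found in node table: ", restriction$within_class)
    return(as.character(cls))
  }
  NULL
}

# ---------------------------------------------------------------------------
# network permutations
# ---------------------------------------------------------------------------

#' Node permutation
#'
#' Randomises the mapping of phenotypes to nodes: all attribute columns are
#' jointly reassigned by one uniform random permutation of the individuals,
#' leaving the network itself (and hence every node position) untouched.
#' The multiset of each attribute is preserved exactly.
#'
#' @param nodes a [node_table()].
#' @return A permuted [node_table()] (ids in their original order).
#' @export
node_permutation <- function(nodes) {
  n <- nrow(nodes)
  if (n < 2L) stop("node permutation needs at least 2 individuals")
  perm <- sample.int(n)
  out <- nodes
  attr_cols <- setdiff(names(nodes), "individual")
  out[attr_cols] <- nodes[perm, attr_cols, drop = FALSE]
  out
}

#' Restricted node permutation
#'
#' Node permutation applied independently within classes of individuals
#' (e.g. individuals sharing a primary location and time period), so that
#' attribute values never cross class boundaries. With singleton classes the
#' permutation is always the identity.
#'
#' @param nodes a [node_table()].
#' @param grouping an attribute name in `nodes`, or a vector of class labels
#'   covering every individual.
#' @return A permuted [node_table()].
#' @export
restricted_node_permutation <- function(nodes, grouping) {
  if (length(grouping) == 1L && is.character(grouping) &&
      grouping %in% names(nodes))
    grouping <- nodes[[grouping]]
  if (length(grouping) != nrow(nodes))
    stop("grouping must cover all individuals")
  if (anyNA(grouping)) stop("grouping must not contain NA")
  perm <- seq_len(nrow(nodes))
  for (g in unique(grouping)) {
    idx <- which(grouping == g)
    if (length(idx) > 1L) perm[idx] <- idx[sample.int(length(idx))]
  }
  out <- nodes
  attr_cols <- setdiff(names(nodes), "individual")
  out[attr_cols] <- nodes[perm, attr_cols, drop = FALSE]
  out
}

#' Edge permutation
#'
#' Reassigns the multiset of nonzero edge weights uniformly at random to the
#' set of possible dyads, preserving the number of edges and the weight
#' multiset (and hence symmetry, zero diagonal and density).
#'
#' @param net a [weighted_network()] with at least one edge.
#' @return A [weighted_network()].
#' @export
edge_permutation <- function(net) {
  A <- net$adjacency
  N <- nrow(A)
  ut <- which(upper.tri(A))
  w <- A[ut]
  w <- w[w > 0]
  if (!length(w)) stop("edge permutation needs at least one edge")
  B <- matrix(0, N, N, dimnames = dimnames(A))
  pos <- if (length(ut) == 1L) ut else sample(ut, length(w))
  B[pos] <- sample(w)
  B <- B + t(B)
  weighted_network(B, .net_ids(net))
}

# ---------------------------------------------------------------------------
# data-stream (checkerboard) permutation
# ---------------------------------------------------------------------------

#' Find a checkerboard in a group-by-individual matrix
#'
#' A checkerboard is a pair of individuals (i, j) and a pair of events
#' (a, b) with membership pattern 1,0 / 0,1: i in a but not b, j in b but
#' not a. Swapping it exchanges single observations between groups while
#' preserving all row and column totals. Candidates are found by rejection
#' sampling: quadruples are drawn uniformly and tested against the
#' checkerboard pattern and the restriction predicates, which makes the
#' accepted candidate uniform among all legal checkerboards. Returns `NULL`
#' when the attempt budget is exhausted (the chain runner counts and warns).
#'
#' @param gbi a [gbi_matrix()].
#' @param restriction optional [swap_restriction()].
#' @param nodes node table, required for `within_class` restrictions.
#' @param max_attempts rejection-sampling budget per call.
#' @return A list `(i, j, a, b)` of indices (with an `ids` element), or
#'   `NULL` if no candidate was found within the budget.
#' @export
find_checkerboard <- function(gbi, restriction = NULL, nodes = NULL,
                              max_attempts = 10000L) {
  cls <- .check_restriction(restriction, gbi = gbi, nodes = nodes,
                            ids = .gbi_ids(gbi))
  .find_checkerboard_idx(gbi$membership, gbi, restriction, cls, max_attempts)
}

# Candidate checkerboards are sampled by drawing an ordered pair of 1-cells
# (a,i), (b,j) uniformly at random and testing the two complementary zeros
# plus the restriction predicates. Every checkerboard corresponds to exactly
# one such ordered pair, so the first accepted draw is uniform among all
# legal checkerboards, and the acceptance rate is far higher than for naive
# quadruple sampling on sparse data.
.find_checkerboard_idx <- function(M, gbi, restriction, cls, max_attempts) {
  K <- nrow(M); N <- ncol(M)
  if (K < 2L || N < 2L) return(NULL)
  ones <- which(M == 1L)
  if (length(ones) < 2L) return(NULL)
  r <- if (is.null(restriction)) .null_restriction() else restriction
  tried <- 0L
  batch <- 16L                 # grows on failure; most calls hit first batch
  while (tried < max_attempts) {
    nb <- as.integer(min(batch, max_attempts - tried))
    batch <- min(512L, batch * 4L)
    o1 <- ones[sample.int(length(ones), nb, replace = TRUE)]
    o2 <- ones[sample.int(length(ones), nb, replace = TRUE)]
    a <- ((o1 - 1L) %% K) + 1L; i <- ((o1 - 1L) %/% K) + 1L
    b <- ((o2 - 1L) %% K) + 1L; j <- ((o2 - 1L) %/% K) + 1L
    ok <- i != j & a != b &
      M[cbind(a, j)] == 0L & M[cbind(b, i)] == 0L
    if (r$within_day) ok <- ok & gbi$event_day[a] == gbi$event_day[b]
    if (r$within_time) ok <- ok & gbi$event_time[a] == gbi$event_time[b]
    if (r$within_location)
      ok <- ok & gbi$event_location[a] == gbi$event_location[b]
    if (!is.null(cls)) ok <- ok & cls[i] == cls[j]
    hit <- which(ok)
    if (length(hit)) {
      h <- hit[1L]
      return(list(i = i[h], j = j[h], a = a[h], b = b[h],
                  ids = c(colnames(M)[i[h]], colnames(M)[j[h]])))
    }
    tried <- tried + nb
  }
  NULL
}

#' One data-stream (checkerboard) swap
#'
#' Performs a single pre-network data permutation step: a checkerboard is
#' located with [find_checkerboard()] and its four cells are flipped, so that
#' an individual observed in group a now occurs in group b and vice versa.
#' Group sizes (row sums) and per-individual observation counts (column sums)
#' are preserved exactly. If no legal checkerboard is found within the
#' attempt budget the input is returned unchanged with attribute
#' `swap_performed` set to `FALSE`.
#'
#' @inheritParams find_checkerboard
#' @return A [gbi_matrix()] differing from the input in exactly 4 cells (or
#'   unchanged, flagged via `attr(, "swap_performed")`).
#' @export
datastream_swap <- function(gbi, restriction = NULL, nodes = NULL,
                            max_attempts = 10000L) {
  cls <- .check_restriction(restriction, gbi = gbi, nodes = nodes,
                            ids = .gbi_ids(gbi))
  cb <- .find_checkerboard_idx(gbi$membership, gbi, restriction, cls,
                               max_attempts)
  if (is.null(cb)) {
    attr(gbi, "swap_performed") <- FALSE
    return(gbi)
  }
  gbi$membership[cb$a, cb$i] <- 0L
  gbi$membership[cb$a, cb$j] <- 1L
  gbi$membership[cb$b, cb$i] <- 1L
  gbi$membership[cb$b, cb$j] <- 0L
  attr(gbi, "swap_performed") <- TRUE
  gbi
}

# ---------------------------------------------------------------------------
# focal swap
# ---------------------------------------------------------------------------

#' One focal-sample swap
#'
#' The pre-network data permutation for focal-follow data: two samples with
#' different focal individuals are selected at random, one associate is
#' chosen from each, and the two associates exchange samples -- but only when
#' the two focals and the two associates are four distinct individuals and
#' neither associate already occurs in the other sample (focal included).
#' Per-sample associate counts and per-individual occurrence counts are
#' preserved exactly. If no legal swap is found within the budget the input
#' is returned unchanged with `attr(, "swap_performed") = FALSE`.
#'
#' @param focals a [focal_sample_set()].
#' @param restriction optional [swap_restriction()]; `within_time` /
#'   `within_location` compare the two samples, `within_class` the two focal
#'   individuals (or all four with `class_scope = "all"`).
#' @param nodes node table, required for `within_class`.
#' @param max_attempts rejection-sampling budget.
#' @return A [focal_sample_set()].
#' @export
focal_swap <- function(focals, restriction = NULL, nodes = NULL,
                       max_attempts = 10000L) {
  ids <- focal_individuals(focals)
  cls_vec <- .check_restriction(restriction, focals = focals, nodes = nodes,
                                ids = ids)
  cls <- NULL
  if (!is.null(cls_vec)) cls <- stats::setNames(cls_vec, ids)
  r <- if (is.null(restriction)) .null_restriction() else restriction
  n <- length(focals$sample_id)
  if (n < 2L) stop("focal swap needs at least 2 samples")
  for (attempt in seq_len(max_attempts)) {
    ab <- sample.int(n, 2L)
    a <- ab[1L]; b <- ab[2L]
    fa <- focals$focal[a]; fb <- focals$focal[b]
    if (fa == fb) next
    if (r$within_time && focals$time[a] != focals$time[b]) next
    if (r$within_location && focals$location[a] != focals$location[b]) next
    if (!is.null(cls) && cls[[fa]] != cls[[fb]]) next
    aa <- focals$associates[[a]]; ab_ <- focals$associates[[b]]
    if (!length(aa) || !length(ab_)) next
    x <- aa[sample.int(length(aa), 1L)]
    y <- ab_[sample.int(length(ab_), 1L)]
    if (x == y) next
    if (x == fb || y == fa) next                 # four unique individuals
    if (x %in% ab_ || y %in% aa) next            # not in both sets
    if (!is.null(cls) && r$class_scope == "all" && cls[[x]] != cls[[y]]) next
    focals$associates[[a]] <- c(setdiff(aa, x), y)
    focals$associates[[b]] <- c(setdiff(ab_, y), x)
    attr(focals, "swap_performed") <- TRUE
    return(focals)
  }
  attr(focals, "swap_performed") <- FALSE
  focals
}

# ---------------------------------------------------------------------------
# trajectory permutations
# ---------------------------------------------------------------------------

#' Day-shuffle null for trajectories
#'
#' For each individual independently, a uniform random permutation of day
#' labels reassigns its whole daily tracks to new days. Every individual
#' keeps exactly its own multiset of daily tracks -- hence its full spatial
#' distribution and home range -- while temporal alignment between
#' individuals (and so the co-occurrence network) is randomised.
#'
#' @param traj a [trajectory_set()] with `n_days >= 2`.
#' @return A [trajectory_set()].
#' @export
trajectory_day_shuffle <- function(traj) {
  if (traj$n_days < 2L) stop("day shuffle needs at least 2 days")
  S <- traj$steps_per_day
  for (i in seq_len(ncol(traj$x))) {
    perm <- sample.int(traj$n_days)
    rows <- rep((perm - 1L) * S, each = S) + seq_len(S)
    traj$x[, i] <- traj$x[rows, i]
    traj$y[, i] <- traj$y[rows, i]
  }
  traj
}

#' Track identity swap (contrast method)
#'
#' Within each day, a uniform permutation of individual ids reassigns that
#' day's tracks among individuals. The set of tracks present on each day is
#' unchanged, but an individual's own multiset of tracks -- its space use --
#' is generally not preserved: entire chunks of data move between
#' individuals, so this null behaves like a node permutation and is provided
#' as a contrast to [trajectory_day_shuffle()], not as a recommended method.
#'
#' @param traj a [trajectory_set()].
#' @return A [trajectory_set()].
#' @export
track_identity_swap <- function(traj) {
  N <- ncol(traj$x)
  if (N < 2L) stop("identity swap needs at least 2 individuals")
  for (d in seq_len(traj$n_days)) {
    rows <- .day_rows(traj, d)
    perm <- sample.int(N)
    traj$x[rows, ] <- traj$x[rows, perm]
    traj$y[rows, ] <- traj$y[rows, perm]
  }
  traj
}

# ---------------------------------------------------------------------------
# chain runner
# ---------------------------------------------------------------------------

#' Run a permutation null model chain
#'
#' The engine behind [perm_test()]: computes the observed statistic once,
#' generates `n_permutations` null datasets with the requested method,
#' records the statistic for each, and returns the full null series (in
#' permutation order, for stabilisation diagnostics) together with
#' permutation p-values.
#'
#' Serial methods (`"datastream"`, `"focal"`) permute cumulatively: swaps are
#' applied incrementally to one evolving copy of the data, the statistic
#' being recorded every `swaps_per_step` swaps after `burn_in` initial swaps.
#' Independent-draw methods (`"node"`, `"node-restricted"`, `"edge"`,
#' `"day-shuffle"`, `"identity-swap"`) randomise the original data afresh for
#' every recorded statistic. The default `burn_in = 0` follows the
#' convention of reporting the whole chain; inspect the stabilisation series
#' (see [stabilisation_series()]) to judge whether the chain has mixed, and
#' set `burn_in` / `swaps_per_step` accordingly.
#'
#' A non-finite statistic on a permuted dataset is recorded as missing and
#' excluded from the p-value denominator (`n_missing` reports the count). If
#' a serial chain can make no legal move within `max_attempts`, the
#' unchanged statistic is recorded and a warning summarises how often this
#' happened; the chain never loops silently.
#'
#' @param data a [gbi_matrix()] (datastream, node, edge),
#'   [focal_sample_set()] (focal), [trajectory_set()] (day-shuffle,
#'   identity-swap) or [node_table()] / [weighted_network()] for the
#'   network permutations, matching `method`.
#' @param method permutation method; one of `"datastream"`, `"focal"`,
#'   `"node"`, `"node-restricted"`, `"edge"`, `"day-shuffle"`,
#'   `"identity-swap"`.
#' @param statistic function mapping a dataset like `data` to one number.
#' @param n_permutations number of recorded null statistics (>= 1).
#' @param restriction optional [swap_restriction()] (serial methods).
#' @param nodes node table for `within_class` restrictions.
#' @param grouping class labels (or attribute name in `nodes`) for
#'   `"node-restricted"`.
#' @param swaps_per_step swaps between consecutive recorded statistics
#'   (serial methods; default 1).
#' @param burn_in swaps performed before the first recorded statistic
#'   (serial methods; default 0).
#' @param seed optional integer; when given, `set.seed(seed)` is called so
#'   the run is exactly reproducible.
#' @param max_attempts rejection budget per swap.
#' @return An object of class `"permutation_result"`: list with
#'   `observed_statistic`, `null_statistics`, `p_upper`, `p_lower`,
#'   `p_two_tailed`, `n_permutations`, `n_missing`, `n_failed_swaps`,
#'   `method`, `seed`.
#' @examples
#' g <- gbi_matrix(rbind(c(1, 1, 0), c(1, 0, 1), c(0, 1, 1)))
#' r <- run_null_chain(g, "datastream",
#'                     statistic = function(x) network_metric(
#'                       simple_ratio_index(x), "cv_edge_weights"),
#'                     n_permutations = 50, seed = 1)
#' r$p_two_tailed
#' @export
run_null_chain <- function(data, method, statistic, n_permutations,
                           restriction = NULL, nodes = NULL, grouping = NULL,
                           swaps_per_step = 1L, burn_in = 0L, seed = NULL,
                           max_attempts = 10000L) {
  method <- match.arg(method, c("datastream", "focal", "node",
                                "node-restricted", "edge", "day-shuffle",
                                "identity-swap"))
  n_permutations <- as.integer(n_permutations)
  if (is.na(n_permutations) || n_permutations < 1L)
    stop("n_permutations must be a positive integer")
  if (swaps_per_step < 1L) stop("swaps_per_step must be >= 1")
  if (burn_in < 0L) stop("burn_in must be >= 0")
  .need <- function(cl) if (!inherits(data, cl))
    stop(sprintf("method '%s' needs data of class '%s'", method, cl))
  switch(method,
         "datastream" = .need("gbi"),
         "focal" = .need("focal_set"),
         "node" = , "node-restricted" = .need("node_table"),
         "edge" = .need("weighted_network"),
         "day-shuffle" = , "identity-swap" = .need("trajectory_set"))
  if (!is.null(seed)) set.seed(seed)

  observed <- statistic(data)
  if (!is.finite(observed)) stop("statistic is not finite on the observed data")

  nulls <- rep(NA_real_, n_permutations)
  failed <- 0L
  serial <- method %in% c("datastream", "focal")
  if (serial) {
    total <- burn_in + swaps_per_step * n_permutations
    if (method == "datastream") {
      cls <- .check_restriction(restriction, gbi = data, nodes = nodes,
                                ids = .gbi_ids(data))
      chain <- .datastream_chain(data, restriction, cls, statistic,
                                 n_permutations, swaps_per_step, burn_in,
                                 max_attempts)
      nulls <- chain$nulls
      failed <- chain$failed
    } else {
      .check_restriction(restriction, focals = data, nodes = nodes,
                         ids = focal_individuals(data))
      cur <- data
      rec_at <- burn_in + swaps_per_step * seq_len(n_permutations)
      q <- 0L
      for (s in seq_len(total)) {
        cur <- focal_swap(cur, restriction, nodes, max_attempts)
        if (!isTRUE(attr(cur, "swap_performed"))) failed <- failed + 1L
        if (s == rec_at[q + 1L]) {
          q <- q + 1L
          v <- statistic(cur)
          nulls[q] <- if (is.finite(v)) v else NA_real_
        }
      }
    }
    if (failed > 0L)
      warning(sprintf("%d of %d swap steps found no legal move; %s",
                      failed, total,
                      "the unchanged data were carried forward"))
  } else {
    draw_fun <- switch(method,
      "node" = function() node_permutation(data),
      "node-restricted" = {
        if (is.null(grouping))
          stop("node-restricted permutation needs 'grouping'")
        function() restricted_node_permutation(data, grouping)
      },
      "edge" = function() edge_permutation(data),
      "day-shuffle" = function() trajectory_day_shuffle(data),
      "identity-swap" = function() track_identity_swap(data))
    for (q in seq_len(n_permutations)) {
      v <- statistic(draw_fun())
      nulls[q] <- if (is.finite(v)) v else NA_real_
    }
  }
  .permutation_result(observed, nulls, method = method, seed = seed)
}

# serial checkerboard chain on the raw membership matrix: the set of 1-cell
# linear indices is maintained incrementally, so each swap costs a handful of
# scalar operations instead of a matrix scan
.datastream_chain <- function(gbi, restriction, cls, statistic, n_perm,
                              sps, burn, max_attempts) {
  M <- gbi$membership
  K <- nrow(M)
  ones <- which(M == 1L)
  n1 <- length(ones)
  r <- if (is.null(restriction)) .null_restriction() else restriction
  simple <- !r$within_day && !r$within_time && !r$within_location &&
    is.null(cls)
  nulls <- rep(NA_real_, n_perm)
  failed <- 0L
  total <- burn + sps * n_perm
  rec_at <- burn + sps * seq_len(n_perm)
  q <- 0L
  cur <- gbi
  if (n1 >= 2L && K >= 2L && ncol(M) >= 2L) {
    for (s in seq_len(total)) {
      done <- FALSE
      tried <- 0L
      while (tried < max_attempts) {
        tried <- tried + 1L
        p1 <- sample.int(n1, 1L)
        p2 <- sample.int(n1, 1L)
        o1 <- ones[p1]; o2 <- ones[p2]
        a <- ((o1 - 1L) %% K) + 1L; i <- ((o1 - 1L) %/% K) + 1L
        b <- ((o2 - 1L) %% K) + 1L; j <- ((o2 - 1L) %/% K) + 1L
        if (i == j || a == b) next
        oaj <- a + (j - 1L) * K; obi <- b + (i - 1L) * K
        if (M[oaj] != 0L || M[obi] != 0L) next
        if (!simple) {
          if (r$within_day && gbi$event_day[a] != gbi$event_day[b]) next
          if (r$within_time && gbi$event_time[a] != gbi$event_time[b]) next
          if (r$within_location &&
              gbi$event_location[a] != gbi$event_location[b]) next
          if (!is.null(cls) && cls[i] != cls[j]) next
        }
        M[o1] <- 0L; M[o2] <- 0L; M[oaj] <- 1L; M[obi] <- 1L
        ones[p1] <- oaj; ones[p2] <- obi
        done <- TRUE
        break
      }
      if (!done) failed <- failed + 1L
      if (q < n_perm && s == rec_at[q + 1L]) {
        q <- q + 1L
        cur$membership <- M
        v <- statistic(cur)
        nulls[q] <- if (is.finite(v)) v else NA_real_
      }
    }
  } else {
    failed <- total
    for (q in seq_len(n_perm)) {
      v <- statistic(cur)
      nulls[q] <- if (is.finite(v)) v else NA_real_
    }
  }
  list(nulls = nulls, failed = failed)
}

.permutation_result <- function(observed, nulls, method = NULL, seed = NULL) {
  n_missing <- sum(is.na(nulls))
  p <- permutation_pvalues(observed, nulls)
  structure(list(observed_statistic = observed,
                 null_statistics = nulls,
                 p_upper = p$p_upper, p_lower = p$p_lower,
                 p_two_tailed = p$p_two_tailed,
                 n_permutations = length(nulls),
                 n_missing = n_missing,
                 method = method,
                 seed = seed),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("Permutation null model",
      if (!is.null(x$method)) sprintf("(%s)", x$method), "\n")
  cat(sprintf("  observed statistic: %.6g\n", x$observed_statistic))
  cat(sprintf("  null permutations:  %d%s\n", x$n_permutations,
              if (x$n_missing > 0)
                sprintf(" (%d missing)", x$n_missing) else ""))
  cat(sprintf("  P (upper / lower):  %.4g / %.4g\n", x$p_upper, x$p_lower))
  cat(sprintf("  P (two-tailed):     %.4g\n", x$p_two_tailed))
  invisible(x)
}

#' Histogram of the null distribution
#'
#' Plots the null statistic distribution with the observed value marked, or
#' the stabilisation trace of the chain (null statistic against permutation
#' number).
#'
#' @param x a `"permutation_result"`.
#' @param type `"null"` for the histogram, `"stabilisation"` for the trace.
#' @param ... passed to [graphics::hist()] / [plot()].
#' @return `x`, invisibly.
#' @export
plot.permutation_result <- function(x, type = c("null", "stabilisation"),
                                    ...) {
  type <- match.arg(type)
  nn <- x$null_statistics[!is.na(x$null_statistics)]
  if (type == "null") {
    graphics::hist(nn, main = "Null distribution", xlab = "test statistic",
                   xlim = range(c(nn, x$observed_statistic)), ...)
    graphics::abline(v = x$observed_statistic, col = "red", lwd = 2)
  } else {
    plot(seq_along(x$null_statistics), x$null_statistics, type = "l",
         xlab = "permutation", ylab = "null statistic", ...)
    graphics::abline(h = x$observed_statistic, col = "red", lwd = 2)
  }
  invisible(x)
}

#' Series of permuted null networks
#'
#' Runs a data-stream chain and harvests the permuted network every
#' `swaps_per_step` swaps (after `burn_in`), e.g. to feed
#' [mrqap_custom_null()] with nulls that respect the observation structure
#' of the raw data.
#'
#' @inheritParams run_null_chain
#' @param gbi a [gbi_matrix()].
#' @param n number of networks to harvest.
#' @param index `"sri"` or `"count"` edge weights.
#' @return List of `n` [weighted_network()] objects.
#' @export
null_network_series <- function(gbi, n, restriction = NULL, nodes = NULL,
                                swaps_per_step = 1L, burn_in = 0L,
                                seed = NULL, max_attempts = 10000L,
                                index = c("sri", "count")) {
  index <- match.arg(index)
  if (!is.null(seed)) set.seed(seed)
  .check_restriction(restriction, gbi = gbi, nodes = nodes,
                     ids = .gbi_ids(gbi))
  netfun <- if (index == "sri") simple_ratio_index else co_occurrence_network
  out <- vector("list", n)
  cur <- gbi
  for (s in seq_len(burn_in))
    cur <- datastream_swap(cur, restriction, nodes, max_attempts)
  for (q in seq_len(n)) {
    for (s in seq_len(swaps_per_step))
      cur <- datastream_swap(cur, restriction, nodes, max_attempts)
    out[[q]] <- netfun(cur)
  }
  out
}
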