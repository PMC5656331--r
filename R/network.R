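# Network construction and node/dyad summaries.

#' Simple ratio association index
#'
#' Builds the weighted social network from a group-by-individual matrix under
#' the gambit of the group. The edge weight for a dyad (i, j) is the simple
#' ratio index: the number of sampling events containing both i and j divided
#' by the number of events containing i or j (or both). Because each row of
#' the matrix is a single sighting event, "seen but not together" cannot
#' occur within a row and the index needs no correction terms. A dyad never
#' observed at all (0/0) has weight 0.
#'
#' @param gbi a [gbi_matrix()].
#' @return A [weighted_network()] with entries in \[0, 1\].
#' @seealso [co_occurrence_network()] for raw counts.
#' @examples
#' g <- gbi_matrix(rbind(c(1, 1, 0), c(1, 0, 0), c(0, 1, 1)),
#'                 individual_ids = c("A", "B", "C"))
#' simple_ratio_index(g)$adjacency["A", "B"]  # 1/3
#' @export
simple_ratio_index <- function(gbi) {
  weighted_network(.sri_adj(gbi$membership), .gbi_ids(gbi))
}

.sri_adj <- function(M) {
  X <- crossprod(M)                       # co-occurrence counts, diag = n_i
  n <- diag(X)
  denom <- outer(n, n, "+") - X           # events containing i or j
  A <- ifelse(denom > 0, X / denom, 0)
  diag(A) <- 0
  A
}

#' Raw co-occurrence count network
#'
#' Like [simple_ratio_index()] but with the unnormalised number of events in
#' which each dyad was recorded together as the edge weight.
#'
#' @param gbi a [gbi_matrix()].
#' @return A [weighted_network()].
#' @export
co_occurrence_network <- function(gbi) {
  X <- crossprod(gbi$membership)
  diag(X) <- 0
  weighted_network(X, .gbi_ids(gbi))
}

#' Convert focal samples to a group-by-individual matrix
#'
#' Each focal sample becomes one event whose members are the focal individual
#' together with all its associates; sample times are carried over as the
#' event time and sample locations as the event location. Samples sharing the
#' same members remain distinct events.
#'
#' @param focals a [focal_sample_set()].
#' @param individual_ids optional full id set for the columns; default: all
#'   ids appearing in the samples.
#' @return A [gbi_matrix()].
#' @export
focal_to_gbi <- function(focals, individual_ids = NULL) {
  ids <- individual_ids
  if (is.null(ids)) ids <- focal_individuals(focals)
  K <- length(focals$sample_id)
  M <- matrix(0L, K, length(ids), dimnames = list(focals$sample_id, ids))
  for (k in seq_len(K)) {
    memb <- match(c(focals$focal[k], focals$associates[[k]]), ids)
    if (anyNA(memb)) stop("individual_ids does not cover all sample members")
    M[k, memb] <- 1L
  }
  gbi_matrix(M, ids, event_time = focals$time,
             event_location = focals$location, event_ids = focals$sample_id)
}

#' Convert trajectories to a group-by-individual matrix
#'
#' Individuals co-occurring on the grid form a sampling event: with
#' `radius = 0` every (day, step, occupied cell) becomes one event whose
#' members are the individuals in that cell at that step. With `radius > 0`,
#' individuals within Chebyshev distance `radius` of one another at the same
#' step are merged into one event (single-linkage). Events are labelled with
#' their day (`event_day`) and with the global step index as the sampling
#' period (`event_time`). Unrecorded (`NA`) points contribute nothing.
#'
#' @param traj a [trajectory_set()].
#' @param radius non-negative integer co-occurrence radius (Chebyshev).
#' @return A [gbi_matrix()] with one row per event (singletons included).
#' @export
trajectories_to_gbi <- function(traj, radius = 0L) {
  ids <- .traj_ids(traj)
  T <- nrow(traj$x)
  N <- length(ids)
  rows <- integer(0); cols <- integer(0); nev <- 0L
  ev_day <- integer(0); ev_time <- integer(0)
  day_of <- rep(seq_len(traj$n_days), each = traj$steps_per_day)
  for (t in seq_len(T)) {
    px <- traj$x[t, ]; py <- traj$y[t, ]
    pres <- which(!is.na(px))
    if (!length(pres)) next
    if (radius == 0L) {
      cell <- px[pres] + py[pres] * traj$grid_width
      grp <- match(cell, unique(cell))
    } else {
      grp <- .chebyshev_components(px[pres], py[pres], radius)
    }
    for (gidx in seq_len(max(grp))) {
      nev <- nev + 1L
      members <- pres[grp == gidx]
      rows <- c(rows, rep(nev, length(members)))
      cols <- c(cols, members)
      ev_day <- c(ev_day, day_of[t]); ev_time <- c(ev_time, t)
    }
  }
  M <- matrix(0L, nev, N, dimnames = list(NULL, ids))
  M[cbind(rows, cols)] <- 1L
  gbi_matrix(M, ids, event_time = ev_time, event_day = ev_day)
}

# single-linkage components under Chebyshev distance <= radius
.chebyshev_components <- function(px, py, radius) {
  n <- length(px)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (comp[i] != comp[j] &&
          max(abs(px[i] - px[j]), abs(py[i] - py[j])) <= radius) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

# fast SRI straight from trajectories (radius 0), bypassing the GBI:
# co-occurrence = same cell at the same global step; each recorded point is
# one event containing the individual.
.sri_traj_adj <- function(traj) {
  C <- traj$x + traj$y * traj$grid_width
  N <- ncol(C)
  n <- colSums(!is.na(C))
  A <- matrix(0, N, N, dimnames = list(colnames(C), colnames(C)))
  for (i in seq_len(N - 1L)) {
    ci <- C[, i]
    for (j in (i + 1L):N) {
      both <- sum(ci == C[, j], na.rm = TRUE)
      den <- n[i] + n[j] - both
      if (den > 0) A[i, j] <- A[j, i] <- both / den
    }
  }
  A
}

#' Weighted degree (strength)
#'
#' The sum of a node's edge weights, the node-level statistic used throughout
#' the package's worked examples.
#'
#' @param net a [weighted_network()].
#' @return Named numeric vector of strengths.
#' @export
weighted_degree <- function(net) rowSums(net$adjacency)

#' Binary degree
#'
#' Number of nonzero edges per node, optionally after thresholding the
#' network at the median edge weight.
#'
#' @param net a [weighted_network()].
#' @param threshold `"none"` (count nonzero edges as they stand) or
#'   `"median"` (apply [threshold_at_median()] first).
#' @return Named integer vector of degrees.
#' @export
binary_degree <- function(net, threshold = c("none", "median")) {
  threshold <- match.arg(threshold)
  if (threshold == "median") net <- threshold_at_median(net)
  rowSums(net$adjacency > 0)
}

#' Threshold a network at the median edge weight
#'
#' Binarises the network so that the top 50% of edges remain: the median is
#' computed over the nonzero edge weights and edges strictly above it are set
#' to 1, all others to 0. Under this strictly-greater rule a network whose
#' edges all carry the same weight loses every edge.
#'
#' @param net a [weighted_network()] with at least one nonzero edge.
#' @return A binary [weighted_network()].
#' @export
threshold_at_median <- function(net) {
  A <- net$adjacency
  w <- A[upper.tri(A)]
  w <- w[w > 0]
  if (!length(w)) stop("median thresholding needs at least one nonzero edge")
  weighted_network((A > median(w)) + 0, .net_ids(net))
}

#' Dyadic category matrix from a binary node attribute
#'
#' Categorises each dyad by the attribute values of its two members, coded
#' 1 = both carry the alphabetically later value (e.g. both males for a sex
#' attribute with values F/M), 2 = mixed, 3 = both carry the earlier value
#' (both females). The diagonal is 0 and unused.
#'
#' @param nodes a [node_table()].
#' @param attribute name of a binary-valued attribute column.
#' @param levels optional length-2 character vector fixing the two attribute
#'   levels (in sorted order); needed when only one level is present in the
#'   table.
#' @return An object of class `"dyad_category"`: list with the symmetric
#'   integer `values` matrix and the `coding` map.
#' @export
dyad_category_matrix <- function(nodes, attribute = "sex", levels = NULL) {
  v <- as.character(nodes[[attribute]])
  if (is.null(v)) stop("attribute not found: ", attribute)
  lev <- if (is.null(levels)) sort(unique(v)) else sort(levels)
  if (length(lev) != 2L || !all(v %in% lev))
    stop("attribute must be binary-valued, got levels: ",
         paste(sort(unique(v)), collapse = ", "))
  later <- as.integer(v == lev[2])              # e.g. M for sex
  cnt <- outer(later, later, "+")               # number of later-level members
  values <- 3L - cnt
  diag(values) <- 0L
  dimnames(values) <- list(nodes$individual, nodes$individual)
  coding <- c(1L, 2L, 3L)
  names(coding) <- c(paste(lev[2], lev[2], sep = "-"),
                     paste(lev[2], lev[1], sep = "-"),
                     paste(lev[1], lev[1], sep = "-"))
  structure(list(values = values, coding = coding), class = "dyad_category")
}

#' @export
print.dyad_category <- function(x, ...) {
  cat("Dyad category matrix:", nrow(x$values), "nodes; coding:",
      paste(sprintf("%s=%d", names(x$coding), x$coding), collapse = ", "), "\n")
  invisible(x)
}

#' Network-level summary metrics
#'
#' @param net a [weighted_network()].
#' @param metric one of `"mean_degree"` (mean number of nonzero edges per
#'   node), `"mean_strength"` (mean [weighted_degree()]), `"cv_edge_weights"`
#'   (coefficient of variation, population formula, over nonzero edge
#'   weights; needs at least one nonzero edge) and `"density"` (realised
#'   fraction of possible dyads).
#' @return A single number.
#' @export
network_metric <- function(net, metric = c("mean_degree", "mean_strength",
                                           "cv_edge_weights", "density")) {
  metric <- match.arg(metric)
  A <- net$adjacency
  w <- A[upper.tri(A)]
  switch(metric,
    mean_degree = mean(rowSums(A > 0)),
    mean_strength = mean(rowSums(A)),
    cv_edge_weights = {
      nz <- w[w > 0]
      if (!length(nz)) stop("cv_edge_weights needs at least one nonzero edge")
      sqrt(mean((nz - mean(nz))^2)) / mean(nz)
    },
    density = if (length(w)) mean(w > 0) else 0
  )
}
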