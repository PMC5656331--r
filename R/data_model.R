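#' socialnull: permutation null models for animal social networks
#'
#' Social network data collected on animals are non-independent by
#' construction, so hypothesis tests on them rely on permutation null models
#' rather than parametric theory. This package implements the standard
#' toolbox: network construction from gambit-of-the-group,
#' focal-follow and trajectory data; node, edge and pre-network data-stream
#' (checkerboard) permutations; focal-sample swaps; day-shuffle nulls for
#' autocorrelated movement data; permutation p-values; and (MR)QAP dyadic
#' regression with pluggable nulls. The central user-facing entry point is
#' [perm_test()], a formula-based fitting function returning a classed result
#' with `print`, `summary`, `coef` and `plot` methods; [mrqap()] plays the
#' same role for dyadic regression. Synthetic-data generators
#' ([simulate_group_data()], [simulate_focal_data()], [simulate_gps_data()])
#' emulate the three observation modes with a controllable sex effect on
#' sociality and a controllable observation bias, so every method can be
#' exercised without field data.
#'
#' @importFrom stats cov lm median pnorm quantile rbinom rpois runif sd var
#' @importFrom utils read.csv write.csv head tail
#' @importFrom graphics abline hist legend lines par
#' @keywords internal
"_PACKAGE"

# ---------------------------------------------------------------------------
# group-by-individual matrix
# ---------------------------------------------------------------------------

#' Group-by-individual matrix
#'
#' The canonical "pre-network" container for gambit-of-the-group data: a
#' binary matrix with one row per sampling event (group) and one column per
#' individual, 1 meaning the individual was recorded in that event. Optional
#' per-event metadata (an integer sampling-period index, an integer day and a
#' categorical location) support restricted data-stream permutations.
#' Individuals absent from an event are 0, never missing: the matrix is dense,
#' which is what the checkerboard swap of [datastream_swap()] is defined on.
#'
#' @param membership binary matrix (events x individuals). Dimnames are used
#'   for event and individual ids when present.
#' @param individual_ids character vector of unique individual ids; defaults
#'   to `colnames(membership)`.
#' @param event_time optional integer vector (length = rows): sampling-period
#'   index. "Same time period" restrictions compare these integers for
#'   equality.
#' @param event_day optional integer vector (length = rows).
#' @param event_location optional character vector (length = rows).
#' @param event_ids optional character vector of unique event ids.
#'
#' @return An object of class `"gbi"`: a list with elements `membership`
#'   (integer matrix with dimnames), `event_time`, `event_day`,
#'   `event_location`.
#' @seealso [read_gbi()], [simple_ratio_index()], [datastream_swap()]
#' @export
gbi_matrix <- function(membership, individual_ids = colnames(membership),
                       event_time = NULL, event_day = NULL,
                       event_location = NULL, event_ids = rownames(membership)) {
  membership <- as.matrix(membership)
  K <- nrow(membership)
  N <- ncol(membership)
  if (is.null(individual_ids)) individual_ids <- paste0("ind", seq_len(N))
  individual_ids <- as.character(individual_ids)
  if (length(individual_ids) != N)
    stop("individual_ids must have one entry per membership column")
  if (anyDuplicated(individual_ids))
    stop("duplicate individual ids")
  storage.mode(membership) <- "integer"
  if (anyNA(membership) || !all(membership %in% c(0L, 1L)))
    stop("membership entries must be 0 or 1")
  if (K < 1L) stop("a group-by-individual matrix needs at least one event")
  if (any(rowSums(membership) < 1L))
    stop("every event must contain at least one individual (all-zero row found)")
  if (is.null(event_ids)) event_ids <- paste0("e", seq_len(K))
  event_ids <- as.character(event_ids)
  if (length(event_ids) != K || anyDuplicated(event_ids))
    stop("event ids must be unique, one per row")
  dimnames(membership) <- list(event_ids, individual_ids)
  chk_meta <- function(x, nm, mode) {
    if (is.null(x)) return(NULL)
    if (length(x) != K) stop(sprintf("%s must have length %d", nm, K))
    if (mode == "integer") {
      xi <- as.integer(x)
      if (anyNA(xi)) stop(sprintf("%s must be integer-valued", nm))
      xi
    } else as.character(x)
  }
  structure(list(membership = membership,
                 event_time = chk_meta(event_time, "event_time", "integer"),
                 event_day = chk_meta(event_day, "event_day", "integer"),
                 event_location = chk_meta(event_location, "event_location", "character")),
            class = "gbi")
}

#' @export
print.gbi <- function(x, ...) {
  cat(sprintf("Group-by-individual matrix: %d events x %d individuals (%d presences)\n",
              nrow(x$membership), ncol(x$membership), sum(x$membership)))
  meta <- c("event_time", "event_day", "event_location")
  have <- meta[!vapply(x[meta], is.null, logical(1))]
  if (length(have)) cat("Event metadata:", paste(have, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.gbi <- function(x) dim(x$membership)

.gbi_ids <- function(gbi) colnames(gbi$membership)

# ---------------------------------------------------------------------------
# focal samples
# ---------------------------------------------------------------------------

#' Focal sample set
#'
#' Data from focal follows: each sample records one focal individual together
#' with the set of its associates during the bout. The focal is never listed
#' among its own associates and associate sets contain no duplicates.
#'
#' @param sample_id character vector of unique sample ids.
#' @param focal character vector of focal individual ids.
#' @param associates list of character vectors (possibly empty) of associate
#'   ids, one per sample.
#' @param time optional integer vector: sampling-period index per sample.
#' @param location optional character vector per sample.
#'
#' @return An object of class `"focal_set"`.
#' @seealso [read_focal()], [focal_to_gbi()], [focal_swap()]
#' @export
focal_sample_set <- function(sample_id, focal, associates, time = NULL,
                             location = NULL) {
  sample_id <- as.character(sample_id)
  focal <- as.character(focal)
  n <- length(sample_id)
  if (length(focal) != n || length(associates) != n)
    stop("sample_id, focal and associates must have equal length")
  if (anyDuplicated(sample_id)) stop("duplicate sample ids")
  associates <- lapply(associates, as.character)
  for (k in seq_len(n)) {
    a <- associates[[k]]
    if (anyDuplicated(a))
      stop(sprintf("sample %s: duplicated associate", sample_id[k]))
    if (focal[k] %in% a)
      stop(sprintf("sample %s: focal individual listed among its own associates",
                   sample_id[k]))
  }
  if (!is.null(time)) {
    if (length(time) != n) stop("time must have one entry per sample")
    time <- as.integer(time)
    if (anyNA(time)) stop("time must be integer-valued")
  }
  if (!is.null(location)) {
    if (length(location) != n) stop("location must have one entry per sample")
    location <- as.character(location)
  }
  structure(list(sample_id = sample_id, focal = focal,
                 associates = associates, time = time, location = location),
            class = "focal_set")
}

#' @export
print.focal_set <- function(x, ...) {
  cat(sprintf("Focal sample set: %d samples, %d individuals\n",
              length(x$sample_id), length(focal_individuals(x))))
  invisible(x)
}

#' @export
length.focal_set <- function(x) length(x$sample_id)

#' Individuals appearing in a focal sample set
#'
#' @param focals a [focal_sample_set()].
#' @return Sorted character vector of all ids appearing as focal or associate.
#' @export
focal_individuals <- function(focals) {
  sort(unique(c(focals$focal, unlist(focals$associates))))
}

# ---------------------------------------------------------------------------
# trajectories
# ---------------------------------------------------------------------------

#' Trajectory set
#'
#' Discretised movement data: per-individual, per-day sequences of grid-cell
#' positions, the raw material of day-shuffle null models. Coordinates are
#' 0-based integers on a `grid_width` x `grid_height` arena. Internally
#' positions are stored as two (`n_days * steps_per_day`) x individuals
#' matrices; `NA` marks a point that was not recorded (e.g. removed by an
#' observation bias), which is how partially observed tracks are represented
#' while each (individual, day) track still spans a full day of steps.
#'
#' @param x,y integer matrices (`n_days * steps_per_day` rows, one column per
#'   individual) of 0-based grid coordinates; `NA` = unrecorded point. Rows
#'   are ordered day 1 step 1, day 1 step 2, ..., day 2 step 1, ...
#' @param individual_ids character vector of unique ids (defaults to column
#'   names of `x`).
#' @param n_days,steps_per_day integers describing the day blocking of rows.
#' @param grid_width,grid_height arena size in cells (at least 2 x 2).
#'
#' @return An object of class `"trajectory_set"`.
#' @seealso [read_trajectories()], [trajectories_to_gbi()],
#'   [trajectory_day_shuffle()]
#' @export
trajectory_set <- function(x, y, individual_ids = colnames(x), n_days,
                           steps_per_day, grid_width, grid_height) {
  x <- as.matrix(x); y <- as.matrix(y)
  storage.mode(x) <- "integer"; storage.mode(y) <- "integer"
  n_days <- as.integer(n_days); steps_per_day <- as.integer(steps_per_day)
  grid_width <- as.integer(grid_width); grid_height <- as.integer(grid_height)
  if (grid_width < 2L || grid_height < 2L) stop("grid must be at least 2 x 2")
  if (n_days < 1L || steps_per_day < 1L)
    stop("n_days and steps_per_day must be positive")
  if (!identical(dim(x), dim(y))) stop("x and y must have identical dimensions")
  if (nrow(x) != n_days * steps_per_day)
    stop("x and y must have n_days * steps_per_day rows")
  N <- ncol(x)
  if (is.null(individual_ids)) individual_ids <- paste0("ind", seq_len(N))
  individual_ids <- as.character(individual_ids)
  if (length(individual_ids) != N || anyDuplicated(individual_ids))
    stop("individual ids must be unique, one per column")
  if (xor(anyNA(x), anyNA(y)) ||
      (anyNA(x) && !identical(which(is.na(x)), which(is.na(y)))))
    stop("x and y must be NA at the same points")
  ok <- is.na(x) | (x >= 0L & x < grid_width)
  if (!all(ok)) stop("x coordinates outside [0, grid_width)")
  ok <- is.na(y) | (y >= 0L & y < grid_height)
  if (!all(ok)) stop("y coordinates outside [0, grid_height)")
  colnames(x) <- colnames(y) <- individual_ids
  structure(list(x = x, y = y, n_days = n_days, steps_per_day = steps_per_day,
                 grid_width = grid_width, grid_height = grid_height),
            class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat(sprintf(
    "Trajectory set: %d individuals, %d days x %d steps on a %d x %d grid (%d points, %d missing)\n",
    ncol(x$x), x$n_days, x$steps_per_day, x$grid_width, x$grid_height,
    length(x$x), sum(is.na(x$x))))
  invisible(x)
}

.traj_ids <- function(traj) colnames(traj$x)

# row indices of one day block
.day_rows <- function(traj, day) {
  (day - 1L) * traj$steps_per_day + seq_len(traj$steps_per_day)
}

# ---------------------------------------------------------------------------
# node table
# ---------------------------------------------------------------------------

#' Node attribute table
#'
#' Per-individual attributes (e.g. sex) used as predictors in node-level
#' tests and shuffled by node permutations. A thin data-frame subclass whose
#' first column, `individual`, holds unique ids.
#'
#' @param individual character vector of unique individual ids.
#' @param ... named attribute vectors, each of the same length.
#' @return An object of class `"node_table"` (also a data frame).
#' @seealso [read_nodes()], [node_permutation()]
#' @export
node_table <- function(individual, ...) {
  individual <- as.character(individual)
  if (anyDuplicated(individual)) stop("duplicate individual ids")
  attrs <- list(...)
  if (length(attrs) && (is.null(names(attrs)) || any(names(attrs) == "")))
    stop("attributes must be named")
  for (nm in names(attrs))
    if (length(attrs[[nm]]) != length(individual))
      stop(sprintf("attribute '%s' must have one value per individual", nm))
  out <- data.frame(individual = individual, attrs,
                    stringsAsFactors = FALSE, check.names = FALSE)
  class(out) <- c("node_table", "data.frame")
  out
}

.as_node_table <- function(df) {
  if (!"individual" %in% names(df)) stop("node table needs an 'individual' column")
  do.call(node_table, c(list(individual = df$individual),
                        df[setdiff(names(df), "individual")]))
}

# align a node table to a given id order; error on mismatch
.align_nodes <- function(nodes, ids) {
  if (!inherits(nodes, "node_table")) stop("'nodes' must be a node_table")
  idx <- match(ids, nodes$individual)
  if (anyNA(idx))
    stop("node table does not cover all individuals: ",
         paste(ids[is.na(idx)], collapse = ", "))
  out <- nodes[idx, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("node_table", "data.frame")
  out
}

# ---------------------------------------------------------------------------
# weighted network
# ---------------------------------------------------------------------------

#' Weighted social network
#'
#' A symmetric non-negative adjacency matrix with a zero diagonal, labelled by
#' individual ids. Association-index networks additionally have all entries
#' in \[0, 1\].
#'
#' @param adjacency symmetric numeric matrix, zero diagonal, entries >= 0.
#' @param individual_ids character vector of unique ids (defaults to
#'   `rownames(adjacency)`).
#' @return An object of class `"weighted_network"`.
#' @seealso [simple_ratio_index()], [weighted_degree()], [write_network()]
#' @export
weighted_network <- function(adjacency, individual_ids = rownames(adjacency)) {
  adjacency <- as.matrix(adjacency)
  storage.mode(adjacency) <- "double"
  N <- nrow(adjacency)
  if (ncol(adjacency) != N) stop("adjacency must be square")
  if (is.null(individual_ids)) individual_ids <- paste0("ind", seq_len(N))
  individual_ids <- as.character(individual_ids)
  if (length(individual_ids) != N || anyDuplicated(individual_ids))
    stop("individual ids must be unique, one per node")
  if (anyNA(adjacency)) stop("adjacency must not contain NA")
  if (!isTRUE(all.equal(adjacency, t(adjacency), tolerance = 0)) &&
      !identical(adjacency, t(adjacency)))
    stop("adjacency must be exactly symmetric")
  if (any(diag(adjacency) != 0)) stop("adjacency diagonal must be zero")
  if (any(adjacency < 0)) stop("adjacency entries must be non-negative")
  dimnames(adjacency) <- list(individual_ids, individual_ids)
  structure(list(adjacency = adjacency), class = "weighted_network")
}

#' @export
print.weighted_network <- function(x, ...) {
  A <- x$adjacency
  m <- sum(A[upper.tri(A)] > 0)
  cat(sprintf("Weighted network: %d nodes, %d edges, total edge weight %.4g\n",
              nrow(A), m, sum(A[upper.tri(A)])))
  invisible(x)
}

#' @export
dim.weighted_network <- function(x) dim(x$adjacency)

.net_ids <- function(net) rownames(net$adjacency)
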