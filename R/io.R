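# CSV readers and writers for the observation and network formats.
# Conventions:
#   GBI:        event_id,event_time,event_day,event_location,<id1>,<id2>,...
#   focal:      sample_id,focal_id,associates,time,location  (associates ';'-sep)
#   trajectory: individual,day,step,x,y (long; day/step 1-based in files)
#   nodes:      individual,sex[,...]
#   network:    edge-list id_i,id_j,weight (i<j), square adjacency CSV, GraphML

.gbi_reserved <- c("event_id", "event_time", "event_day", "event_location")

#' Read / write a group-by-individual matrix
#'
#' The CSV has one row per sampling event. Columns named `event_id`,
#' `event_time`, `event_day`, `event_location` are treated as metadata (all
#' optional); every other column is a 0/1 membership column named by the
#' individual, unless `membership_cols` names them explicitly.
#'
#' @param path file path.
#' @param membership_cols optional character vector naming the membership
#'   columns; default: all non-reserved columns.
#' @return [read_gbi()] returns a validated [gbi_matrix()];
#'   [write_gbi()] returns `path` invisibly.
#' @export
read_gbi <- function(path, membership_cols = NULL) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (is.null(membership_cols))
    membership_cols <- setdiff(names(df), .gbi_reserved)
  if (!length(membership_cols)) stop("no membership columns found")
  missing_cols <- setdiff(membership_cols, names(df))
  if (length(missing_cols))
    stop("membership columns absent from file: ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(membership_cols)) stop("duplicate individual ids")
  memb <- as.matrix(df[membership_cols])
  if (anyNA(memb) || !all(memb %in% c(0, 1)))
    stop("non-binary membership value in ", path)
  gbi_matrix(memb,
             individual_ids = membership_cols,
             event_time = df[["event_time"]],
             event_day = df[["event_day"]],
             event_location = df[["event_location"]],
             event_ids = if ("event_id" %in% names(df))
               as.character(df$event_id) else NULL)
}

#' @rdname read_gbi
#' @param gbi a [gbi_matrix()].
#' @export
write_gbi <- function(gbi, path) {
  df <- data.frame(event_id = rownames(gbi$membership),
                   stringsAsFactors = FALSE)
  for (nm in c("event_time", "event_day", "event_location"))
    if (!is.null(gbi[[nm]])) df[[sub("^event_", "event_", nm)]] <- gbi[[nm]]
  df <- cbind(df, as.data.frame(gbi$membership, check.names = FALSE))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write focal samples
#'
#' Columns: `sample_id,focal_id,associates,time,location` with `associates`
#' a `;`-separated list (empty for a lone focal); `time` and `location` are
#' optional.
#'
#' @param path file path.
#' @return [read_focal()] returns a validated [focal_sample_set()];
#'   [write_focal()] returns `path` invisibly.
#' @export
read_focal <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(associates = "character"))
  need <- c("sample_id", "focal_id", "associates")
  if (!all(need %in% names(df)))
    stop("focal CSV needs columns: ", paste(need, collapse = ", "))
  assoc <- strsplit(ifelse(is.na(df$associates), "", df$associates), ";",
                    fixed = TRUE)
  assoc <- lapply(assoc, function(a) a[nzchar(a)])
  focal_sample_set(df$sample_id, df$focal_id, assoc,
                   time = df[["time"]], location = df[["location"]])
}

#' @rdname read_focal
#' @param focals a [focal_sample_set()].
#' @export
write_focal <- function(focals, path) {
  df <- data.frame(sample_id = focals$sample_id,
                   focal_id = focals$focal,
                   associates = vapply(focals$associates, paste,
                                       character(1), collapse = ";"),
                   stringsAsFactors = FALSE)
  if (!is.null(focals$time)) df$time <- focals$time
  if (!is.null(focals$location)) df$location <- focals$location
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write discretised trajectories
#'
#' Long format with columns `individual,day,step,x,y`. Days and steps are
#' 1-based in files; grid coordinates are 0-based integers. Every
#' (individual, day) track must contain exactly `steps_per_day` rows in step
#' order; `x`/`y` may be `NA` for points that were not recorded.
#'
#' @param path file path.
#' @param grid_width,grid_height arena size; inferred from the data maxima
#'   when `NULL`.
#' @return [read_trajectories()] returns a validated [trajectory_set()];
#'   [write_trajectories()] returns `path` invisibly.
#' @export
read_trajectories <- function(path, grid_width = NULL, grid_height = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("individual", "day", "step", "x", "y")
  if (!all(need %in% names(df)))
    stop("trajectory CSV needs columns: ", paste(need, collapse = ", "))
  ids <- unique(as.character(df$individual))
  n_days <- max(df$day)
  steps <- sort(unique(df$step))
  steps_per_day <- max(df$step)
  if (!identical(steps, seq_len(steps_per_day)))
    stop("steps must be 1..steps_per_day")
  T <- n_days * steps_per_day
  x <- matrix(NA_integer_, T, length(ids), dimnames = list(NULL, ids))
  y <- x
  row_of <- (df$day - 1L) * steps_per_day + df$step
  col_of <- match(as.character(df$individual), ids)
  cnt <- table(factor(col_of, levels = seq_along(ids)),
               factor(df$day, levels = seq_len(n_days)))
  if (any(cnt != steps_per_day))
    stop("ragged track: every (individual, day) needs exactly ",
         steps_per_day, " rows")
  if (anyDuplicated(cbind(row_of, col_of)))
    stop("duplicated (individual, day, step) row")
  x[cbind(row_of, col_of)] <- as.integer(df$x)
  y[cbind(row_of, col_of)] <- as.integer(df$y)
  if (is.null(grid_width)) grid_width <- max(x, 1L, na.rm = TRUE) + 1L
  if (is.null(grid_height)) grid_height <- max(y, 1L, na.rm = TRUE) + 1L
  trajectory_set(x, y, ids, n_days, steps_per_day, grid_width, grid_height)
}

#' @rdname read_trajectories
#' @param traj a [trajectory_set()].
#' @export
write_trajectories <- function(traj, path) {
  ids <- .traj_ids(traj)
  T <- nrow(traj$x)
  day <- rep(rep(seq_len(traj$n_days), each = traj$steps_per_day),
             times = length(ids))
  step <- rep(rep(seq_len(traj$steps_per_day), times = traj$n_days),
              times = length(ids))
  df <- data.frame(individual = rep(ids, each = T), day = day, step = step,
                   x = as.vector(traj$x), y = as.vector(traj$y))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a node attribute table
#'
#' Columns: `individual` plus any attribute columns (e.g. `sex`).
#'
#' @param path file path.
#' @return [read_nodes()] returns a [node_table()]; [write_nodes()] returns
#'   `path` invisibly.
#' @export
read_nodes <- function(path) {
  .as_node_table(read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_nodes
#' @param nodes a [node_table()].
#' @export
write_nodes <- function(nodes, path) {
  write.csv(as.data.frame(nodes), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a weighted network
#'
#' Three formats: `"edgelist"` (`id_i,id_j,weight`, each unordered dyad with
#' nonzero weight once, i before j in id order), `"adjacency"` (square CSV
#' with ids as header and first column) and `"graphml"`. The edge list drops
#' isolated nodes; pass `individual_ids` to [read_network()] to restore them.
#'
#' @param net a [weighted_network()].
#' @param path file path.
#' @param format one of `"edgelist"`, `"adjacency"`, `"graphml"`.
#' @return [write_network()] returns `path` invisibly; [read_network()] a
#'   [weighted_network()].
#' @export
write_network <- function(net, path,
                          format = c("edgelist", "adjacency", "graphml")) {
  format <- match.arg(format)
  A <- net$adjacency
  if (format == "edgelist") {
    idx <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
    df <- data.frame(id_i = rownames(A)[idx[, 1]],
                     id_j = colnames(A)[idx[, 2]],
                     weight = A[idx])
    df <- df[order(df$id_i, df$id_j), , drop = FALSE]
    write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else if (format == "adjacency") {
    df <- data.frame(individual = rownames(A), A, check.names = FALSE)
    write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                             weighted = TRUE)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' @rdname write_network
#' @param individual_ids optional full id set (edge-list format only), so
#'   that isolated nodes survive a round trip.
#' @export
read_network <- function(path,
                         format = c("edgelist", "adjacency", "graphml"),
                         individual_ids = NULL) {
  format <- match.arg(format)
  if (format == "edgelist") {
    df <- read.csv(path, stringsAsFactors = FALSE)
    ids <- individual_ids
    if (is.null(ids)) ids <- sort(unique(c(df$id_i, df$id_j)))
    A <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    A[cbind(match(df$id_i, ids), match(df$id_j, ids))] <- df$weight
    A[cbind(match(df$id_j, ids), match(df$id_i, ids))] <- df$weight
    weighted_network(A, ids)
  } else if (format == "adjacency") {
    df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    ids <- as.character(df$individual)
    A <- as.matrix(df[, -1, drop = FALSE])
    dimnames(A) <- list(ids, ids)
    weighted_network(A, ids)
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    A <- as.matrix(igraph::as_adjacency_matrix(g, attr = "weight",
                                               sparse = FALSE))
    ids <- igraph::vertex_attr(g, "name")
    if (is.null(ids)) ids <- igraph::vertex_attr(g, "id")
    if (!is.null(ids)) dimnames(A) <- list(ids, ids)
    weighted_network(A)
  }
}
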