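# Shared fixtures: small hand-built datasets and independent brute-force
# oracles, all generated in code.

tiny_gbi <- function() {
  gbi_matrix(rbind(c(1L, 1L, 0L), c(1L, 0L, 0L), c(0L, 1L, 1L)),
             individual_ids = c("A", "B", "C"),
             event_time = c(1L, 1L, 2L))
}

# random dense GBI with guaranteed non-empty rows
random_gbi <- function(K, N, p = 0.3, with_meta = FALSE) {
  M <- matrix(rbinom(K * N, 1L, p), K, N)
  empty <- rowSums(M) == 0L
  for (k in which(empty)) M[k, sample.int(N, 1L)] <- 1L
  gbi_matrix(M, individual_ids = sprintf("i%02d", seq_len(N)),
             event_time = if (with_meta) sample.int(3, K, TRUE),
             event_day = if (with_meta) sample.int(2, K, TRUE),
             event_location = if (with_meta) sample(c("L1", "L2"), K, TRUE))
}

random_focals <- function(n_samples = 12, ids = LETTERS[1:8]) {
  focal <- sample(ids, n_samples, replace = TRUE)
  associates <- lapply(seq_len(n_samples), function(k) {
    pool <- setdiff(ids, focal[k])
    sample(pool, sample.int(min(4, length(pool)), 1L))
  })
  focal_sample_set(paste0("s", seq_len(n_samples)), focal, associates,
                   time = sample.int(3, n_samples, TRUE),
                   location = sample(c("L1", "L2"), n_samples, TRUE))
}

random_trajectories <- function(N = 4, n_days = 3, steps = 5, w = 4, h = 4) {
  T <- n_days * steps
  trajectory_set(matrix(sample(0:(w - 1), T * N, TRUE), T, N),
                 matrix(sample(0:(h - 1), T * N, TRUE), T, N),
                 sprintf("i%d", seq_len(N)), n_days, steps, w, h)
}

# brute-force simple ratio index: per-dyad enumeration over events
sri_oracle <- function(gbi) {
  M <- gbi$membership
  N <- ncol(M)
  A <- matrix(0, N, N, dimnames = list(colnames(M), colnames(M)))
  for (i in seq_len(N)) for (j in seq_len(N)) {
    if (i == j) next
    both <- 0L; either <- 0L
    for (k in seq_len(nrow(M))) {
      if (M[k, i] == 1L && M[k, j] == 1L) both <- both + 1L
      if (M[k, i] == 1L || M[k, j] == 1L) either <- either + 1L
    }
    A[i, j] <- if (either > 0L) both / either else 0
  }
  A
}

# brute-force permutation p-values by direct counting
pvalue_oracle <- function(observed, nulls) {
  nulls <- nulls[!is.na(nulls)]
  up <- sum(nulls >= observed) / length(nulls)
  lo <- sum(nulls <= observed) / length(nulls)
  list(p_upper = up, p_lower = lo, p_two_tailed = min(1, 2 * min(up, lo)))
}

# per-individual multiset of visited cells (sorted, NA kept) for conservation
track_multisets <- function(traj) {
  lapply(seq_len(ncol(traj$x)), function(i) {
    keys <- paste(traj$x[, i], traj$y[, i])
    sort(keys)
  })
}

# per-individual multiset of whole daily tracks
daily_track_multisets <- function(traj) {
  lapply(seq_len(ncol(traj$x)), function(i) {
    tr <- vapply(seq_len(traj$n_days), function(d) {
      rows <- (d - 1L) * traj$steps_per_day + seq_len(traj$steps_per_day)
      paste(traj$x[rows, i], traj$y[rows, i], collapse = "|")
    }, character(1))
    sort(tr)
  })
}

focal_occurrence_counts <- function(focals) {
  ids <- focal_individuals(focals)
  tab <- table(factor(c(focals$focal, unlist(focals$associates)),
                      levels = ids))
  as.vector(tab)
}
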