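# Synthetic-data generators for the three observation modes. Each emulates a
# population in which females truly have stronger social bonds than males,
# plus an observation bias under which a fraction of female records is lost
# -- the scenario in which naive tests and node permutations fail while
# pre-network data permutations succeed. All generators are
# seed-deterministic and attach their parameter list as attribute "spec".

#' Simulate gambit-of-the-group observation data
#'
#' Generates a group-by-individual matrix under a balanced homophily model.
#' Every sampling event has a seed individual drawn uniformly at random.
#' Males join any event with probability `p_base`. Females concentrate the
#' same total sociality on events seeded by other females: they join
#' female-seeded events with probability `p_base * (1 + effect)` and
#' male-seeded events with probability `p_base * (1 - effect)`, where
#' `effect` is `female_sociality_effect`. Both sexes are therefore observed
#' equally often in expectation, but female-female dyads co-occur more --
#' females have stronger bonds, and a higher weighted degree, without being
#' more detectable. At `effect = 0` the model collapses to fully
#' exchangeable independent joining (the baseline null scenario). Events
#' that would be empty are redrawn.
#'
#' With `bias_fraction > 0` the returned matrix has that fraction of female
#' occurrences deleted via [apply_observation_bias()] -- females are present
#' but unrecorded -- which is the observation bias under which the apparent
#' sex difference in the observed data vanishes.
#'
#' @param n_individuals population size (split by `sex_ratio`).
#' @param sex_ratio fraction of females.
#' @param n_events number of sampling events before bias.
#' @param p_base per-event joining probability for males.
#' @param female_sociality_effect bond-concentration parameter in \[0, 1\];
#'   0 = no sex difference.
#' @param bias_fraction fraction of female occurrences deleted (0 = none).
#' @param seed optional integer seed.
#' @return List with elements `gbi` (a [gbi_matrix()], `event_time` = event
#'   index) and `nodes` (a [node_table()] with a `sex` attribute, F/M).
#' @examples
#' sim <- simulate_group_data(n_individuals = 20, n_events = 50, seed = 1)
#' table(sim$nodes$sex)
#' @export
simulate_group_data <- function(n_individuals = 50, sex_ratio = 0.5,
                                n_events = 200, p_base = 0.15,
                                female_sociality_effect = 0.4,
                                bias_fraction = 0.2, seed = NULL) {
  spec <- list(scenario = "group", n_individuals = n_individuals,
               sex_ratio = sex_ratio, n_events = n_events, p_base = p_base,
               female_sociality_effect = female_sociality_effect,
               bias_fraction = bias_fraction, seed = seed)
  .check_sim_args(sex_ratio, bias_fraction, female_sociality_effect)
  if (n_events < 1) stop("n_events must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  nodes <- .sim_nodes(n_individuals, sex_ratio)
  female <- nodes$sex == "F"
  p_hi <- min(1, p_base * (1 + female_sociality_effect))
  p_lo <- p_base * (1 - female_sociality_effect)
  M <- matrix(0L, n_events, n_individuals,
              dimnames = list(paste0("e", seq_len(n_events)),
                              nodes$individual))
  for (k in seq_len(n_events)) {
    repeat {
      s <- sample.int(n_individuals, 1L)
      pj <- rep(p_base, n_individuals)
      pj[female] <- if (female[s]) p_hi else p_lo
      memb <- runif(n_individuals) < pj
      memb[s] <- TRUE
      if (any(memb)) break
    }
    M[k, ] <- as.integer(memb)
  }
  gbi <- gbi_matrix(M, nodes$individual,
                    event_time = seq_len(n_events))
  if (bias_fraction > 0)
    gbi <- apply_observation_bias(gbi, nodes, fraction = bias_fraction)
  attr(gbi, "spec") <- spec
  list(gbi = gbi, nodes = nodes)
}

.sim_nodes <- function(n_individuals, sex_ratio) {
  if (n_individuals < 4) stop("need at least 4 individuals")
  n_f <- round(n_individuals * sex_ratio)
  ids <- sprintf("id%03d", seq_len(n_individuals))
  node_table(ids, sex = c(rep("F", n_f), rep("M", n_individuals - n_f)))
}

.check_sim_args <- function(sex_ratio, bias_fraction, effect) {
  if (sex_ratio < 0 || sex_ratio > 1) stop("sex_ratio must be in [0, 1]")
  if (bias_fraction < 0 || bias_fraction > 1)
    stop("bias_fraction must be in [0, 1]")
  if (effect < 0) stop("female_sociality_effect must be >= 0")
  if (effect > 1) stop("female_sociality_effect must be <= 1")
}

#' Apply an observation bias to a group-by-individual matrix
#'
#' Deletes each occurrence (1-cell) of individuals in the target class
#' independently with the given probability, emulating individuals that are
#' present but harder to record (e.g. inconspicuous females recorded in only
#' 80% of the samples at `fraction = 0.2`). Occurrences of other individuals
#' are untouched; events left empty are dropped.
#'
#' @param gbi a [gbi_matrix()].
#' @param nodes a [node_table()] covering the matrix's individuals.
#' @param attribute attribute column defining the class (default `"sex"`).
#' @param target attribute value whose occurrences are thinned (default
#'   `"F"`).
#' @param fraction deletion probability per occurrence, in \[0, 1\].
#' @return A [gbi_matrix()].
#' @export
apply_observation_bias <- function(gbi, nodes, attribute = "sex",
                                   target = "F", fraction = 0.2) {
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  nodes <- .align_nodes(nodes, .gbi_ids(gbi))
  is_target <- as.character(nodes[[attribute]]) == as.character(target)
  M <- gbi$membership
  if (fraction > 0 && any(is_target)) {
    del <- matrix(FALSE, nrow(M), ncol(M))
    ncol_t <- sum(is_target)
    del[, is_target] <- runif(nrow(M) * ncol_t) < fraction
    M[del & M == 1L] <- 0L
  }
  keep <- rowSums(M) > 0L
  gbi_matrix(M[keep, , drop = FALSE], .gbi_ids(gbi),
             event_time = gbi$event_time[keep],
             event_day = gbi$event_day[keep],
             event_location = gbi$event_location[keep],
             event_ids = rownames(gbi$membership)[keep])
}

#' Simulate focal-follow observation data
#'
#' The focal-sampling counterpart of [simulate_group_data()]: focal
#' individuals rotate through the population (every individual is focal in
#' at least one sample when `n_samples >= n_individuals`), and each sample
#' records the focal with the associates that joined it. Joining follows
#' the same balanced homophily model with the focal as the seed: males join
#' any focal with probability `p_base`; females join female focals with
#' probability `p_base * (1 + effect)` and male focals with
#' `p_base * (1 - effect)`. The observation bias then deletes each female
#' *associate* record with probability `bias_fraction` (focal records are
#' kept -- the follow happened; it is the associates that go unrecorded).
#'
#' @inheritParams simulate_group_data
#' @param n_samples number of focal samples.
#' @return List with `focals` (a [focal_sample_set()], `time` = sample
#'   index) and `nodes`.
#' @export
simulate_focal_data <- function(n_individuals = 50, sex_ratio = 0.5,
                                n_samples = 200, p_base = 0.15,
                                female_sociality_effect = 0.4,
                                bias_fraction = 0.2, seed = NULL) {
  spec <- list(scenario = "focal", n_individuals = n_individuals,
               sex_ratio = sex_ratio, n_samples = n_samples, p_base = p_base,
               female_sociality_effect = female_sociality_effect,
               bias_fraction = bias_fraction, seed = seed)
  .check_sim_args(sex_ratio, bias_fraction, female_sociality_effect)
  if (n_samples < 1) stop("n_samples must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  nodes <- .sim_nodes(n_individuals, sex_ratio)
  female <- nodes$sex == "F"
  p_hi <- min(1, p_base * (1 + female_sociality_effect))
  p_lo <- p_base * (1 - female_sociality_effect)
  # rotating focal schedule in shuffled order
  focal_idx <- rep(sample.int(n_individuals), length.out = n_samples)
  associates <- vector("list", n_samples)
  for (k in seq_len(n_samples)) {
    f <- focal_idx[k]
    pj <- rep(p_base, n_individuals)
    pj[female] <- if (female[f]) p_hi else p_lo
    join <- runif(n_individuals) < pj
    join[f] <- FALSE
    if (bias_fraction > 0)
      join[female & join] <- runif(sum(female & join)) >= bias_fraction
    associates[[k]] <- nodes$individual[join]
  }
  focals <- focal_sample_set(paste0("s", seq_len(n_samples)),
                             nodes$individual[focal_idx], associates,
                             time = seq_len(n_samples))
  attr(focals, "spec") <- spec
  list(focals = focals, nodes = nodes)
}

#' Simulate GPS trajectory data
#'
#' Simulates individual movement on a discrete grid arena. At each step
#' every individual moves to one of the cells in its Moore neighbourhood
#' (staying put allowed; the arena boundary clips the neighbourhood). Males
#' choose uniformly. Females weight cells that held at least one conspecific
#' (any other individual) at the previous step by `attraction_multiplier`
#' -- with the multiplier at its default of 5, a female is 5 times more
#' likely to move to a neighbouring cell containing a conspecific than to an
#' empty one. All individuals update simultaneously against previous-step
#' occupancy. Tracks run continuously across days; `bias_fraction` then
#' deletes each female (day, step) point independently, leaving `NA`s.
#'
#' @param grid_width,grid_height arena size in cells.
#' @param n_individuals population size.
#' @param sex_ratio fraction of females.
#' @param n_days,steps_per_day track segmentation.
#' @param attraction_multiplier female weight (>= 1) toward previously
#'   occupied neighbouring cells; 1 = everyone moves at random.
#' @param bias_fraction fraction of female points deleted.
#' @param seed optional integer seed.
#' @return List with `traj` (a [trajectory_set()]) and `nodes`.
#' @export
simulate_gps_data <- function(grid_width = 5, grid_height = 5,
                              n_individuals = 30, sex_ratio = 0.5,
                              n_days = 20, steps_per_day = 15,
                              attraction_multiplier = 5,
                              bias_fraction = 0.2, seed = NULL) {
  spec <- list(scenario = "gps", grid_width = grid_width,
               grid_height = grid_height, n_individuals = n_individuals,
               sex_ratio = sex_ratio, n_days = n_days,
               steps_per_day = steps_per_day,
               attraction_multiplier = attraction_multiplier,
               bias_fraction = bias_fraction, seed = seed)
  if (attraction_multiplier < 1) stop("attraction_multiplier must be >= 1")
  .check_sim_args(sex_ratio, bias_fraction, 0)
  if (!is.null(seed)) set.seed(seed)
  nodes <- .sim_nodes(n_individuals, sex_ratio)
  female <- nodes$sex == "F"
  T <- n_days * steps_per_day
  X <- matrix(NA_integer_, T, n_individuals,
              dimnames = list(NULL, nodes$individual))
  Y <- X
  px <- sample.int(grid_width, n_individuals, replace = TRUE) - 1L
  py <- sample.int(grid_height, n_individuals, replace = TRUE) - 1L
  X[1L, ] <- px; Y[1L, ] <- py
  for (t in 2L:T) {
    occ <- table(factor(px + py * grid_width,
                        levels = 0:(grid_width * grid_height - 1L)))
    nx <- px; ny <- py
    for (i in seq_len(n_individuals)) {
      cx <- px[i] + (-1L):1L
      cy <- py[i] + (-1L):1L
      cx <- cx[cx >= 0L & cx < grid_width]
      cy <- cy[cy >= 0L & cy < grid_height]
      cand <- expand.grid(x = cx, y = cy)
      w <- rep(1, nrow(cand))
      if (female[i] && attraction_multiplier > 1) {
        cell <- cand$x + cand$y * grid_width
        others <- as.integer(occ[cell + 1L]) -
          (cell == px[i] + py[i] * grid_width)
        w[others >= 1L] <- attraction_multiplier
      }
      pick <- sample.int(nrow(cand), 1L, prob = w)
      nx[i] <- cand$x[pick]; ny[i] <- cand$y[pick]
    }
    px <- nx; py <- ny
    X[t, ] <- px; Y[t, ] <- py
  }
  if (bias_fraction > 0 && any(female)) {
    del <- matrix(FALSE, T, n_individuals)
    del[, female] <- runif(T * sum(female)) < bias_fraction
    X[del] <- NA_integer_; Y[del] <- NA_integer_
  }
  traj <- trajectory_set(X, Y, nodes$individual, n_days, steps_per_day,
                         grid_width, grid_height)
  attr(traj, "spec") <- spec
  list(traj = traj, nodes = nodes)
}
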