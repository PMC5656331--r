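# Dyadic matrix regression with permutation inference: QAP (dependent-network
# node permutation), MRQAP with double semi-partialing, and MRQAP against an
# externally supplied set of null networks.

#' (Multiple) quadratic assignment procedure regression
#'
#' Regression where the response and the predictors are all networks:
#' observations are the unordered dyads (upper triangle, since all matrices
#' here are symmetric), coefficients come from ordinary least squares, and
#' significance comes from permutations, comparing the observed slope of
#' each predictor to the slopes generated by the randomisations:
#'
#' * `method = "qap"`: node permutation of the dependent network only
#'   (simultaneous row/column permutation), the classical QAP-y test.
#' * `method = "dsp"`: double semi-partialing. Each predictor is
#'   residualised on the remaining predictors by dyadic OLS, the residual
#'   matrix is node-permuted and substituted into the design, and the
#'   refitted coefficient of the permuted residuals forms that predictor's
#'   null distribution. With a single predictor this is statistically
#'   equivalent to QAP-y. Estimation is unchanged -- the reported
#'   coefficients are always the plain OLS coefficients; only the null
#'   distribution differs.
#' * `method = "custom"`: the null distribution of every coefficient comes
#'   from refitting the model with each network in `null_networks`
#'   substituted for the dependent network, so any null model (e.g. a
#'   data-stream permutation via [null_network_series()]) can drive the
#'   inference.
#'
#' Dyadic-category predictors (see [dyad_category_matrix()]) are used as a
#' single numeric predictor by default, mirroring a one-coefficient
#' similarity test.
#'
#' @param dep dependent network: a [weighted_network()] or symmetric matrix.
#' @param predictors a named list of predictors ([weighted_network()],
#'   [dyad_category_matrix()] results, or symmetric matrices), or a single
#'   such object.
#' @param method `"qap"`, `"dsp"` or `"custom"`.
#' @param n_permutations number of permutations (ignored for `"custom"`).
#' @param null_networks for `"custom"`: list of networks/matrices with the
#'   same nodes (in the same order) as `dep`.
#' @param seed optional integer for reproducibility.
#' @return An object of class `"mrqap"`: coefficients, per-predictor
#'   `p_upper` / `p_lower` / `p_two_tailed`, the per-predictor null
#'   coefficient series, `method` and `n_permutations`.
#' @seealso [qap_regression()], [mrqap_dsp()], [mrqap_custom_null()]
#' @export
mrqap <- function(dep, predictors, method = c("qap", "dsp", "custom"),
                  n_permutations = 1000L, null_networks = NULL, seed = NULL) {
  method <- match.arg(method)
  switch(method,
         qap = qap_regression(dep, predictors, n_permutations, seed = seed),
         dsp = mrqap_dsp(dep, predictors, n_permutations, seed = seed),
         custom = {
           if (is.null(null_networks))
             stop("method 'custom' needs null_networks")
           mrqap_custom_null(dep, predictors, null_networks)
         })
}

.dyad_matrix <- function(x, what = "matrix") {
  m <- if (inherits(x, "weighted_network")) x$adjacency
       else if (inherits(x, "dyad_category")) x$values
       else as.matrix(x)
  storage.mode(m) <- "double"
  if (nrow(m) != ncol(m)) stop(what, " must be square")
  if (!identical(m, t(m))) stop(what, " must be symmetric")
  m
}

.mrqap_design <- function(dep, predictors) {
  Y <- .dyad_matrix(dep, "dependent network")
  N <- nrow(Y)
  if (!is.list(predictors) || inherits(predictors, c("weighted_network",
                                                     "dyad_category")))
    predictors <- list(predictors)
  nm <- names(predictors)
  if (is.null(nm)) nm <- rep("", length(predictors))
  nm[nm == ""] <- paste0("x", seq_along(predictors))[nm == ""]
  Xm <- lapply(predictors, .dyad_matrix, what = "predictor")
  for (m in Xm) if (nrow(m) != N) stop("all matrices must have the same size")
  ut <- upper.tri(Y)
  X <- cbind(`(Intercept)` = 1, vapply(Xm, function(m) m[ut],
                                       numeric(sum(ut))))
  colnames(X) <- c("(Intercept)", nm)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("rank-deficient design (constant or collinear predictor)")
  list(Y = Y, Xm = Xm, X = X, ut = ut, N = N, names = nm, qr = qrX,
       proj = solve(crossprod(X), t(X)))   # p x D: coef = proj %*% y
}

.mrqap_result <- function(d, coefs, null_list, method, n_perm) {
  p_upper <- p_lower <- p_two <- stats::setNames(numeric(length(d$names)),
                                                 d$names)
  for (nm in d$names) {
    p <- permutation_pvalues(coefs[nm], null_list[[nm]])
    p_upper[nm] <- p$p_upper; p_lower[nm] <- p$p_lower
    p_two[nm] <- p$p_two_tailed
  }
  structure(list(coefficients = coefs, p_upper = p_upper, p_lower = p_lower,
                 p_two_tailed = p_two, null_coefficients = null_list,
                 method = method, n_permutations = n_perm,
                 predictor_names = d$names, n_nodes = d$N),
            class = "mrqap")
}

#' @rdname mrqap
#' @export
qap_regression <- function(dep, predictors, n_permutations = 1000L,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- .mrqap_design(dep, predictors)
  y <- d$Y[d$ut]
  coefs <- drop(d$proj %*% y)
  nulls <- matrix(NA_real_, n_permutations, length(d$names),
                  dimnames = list(NULL, d$names))
  for (q in seq_len(n_permutations)) {
    pi <- sample.int(d$N)
    yq <- d$Y[pi, pi][d$ut]
    nulls[q, ] <- drop(d$proj %*% yq)[-1L]
  }
  .mrqap_result(d, coefs[-1L], as.list(as.data.frame(nulls)), "qap-y",
                n_permutations)
}

#' @rdname mrqap
#' @export
mrqap_dsp <- function(dep, predictors, n_permutations = 1000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- .mrqap_design(dep, predictors)
  y <- d$Y[d$ut]
  coefs <- drop(d$proj %*% y)[-1L]
  p <- length(d$names)
  nulls <- vector("list", p)
  names(nulls) <- d$names
  for (i in seq_len(p)) {
    # residualise predictor i on the others (dyadic OLS, intercept included)
    Xother <- d$X[, -(i + 1L), drop = FALSE]
    xi <- d$X[, i + 1L]
    ei <- xi - Xother %*% solve(crossprod(Xother), crossprod(Xother, xi))
    # fold residuals back into a symmetric matrix for node permutation
    E <- matrix(0, d$N, d$N)
    E[d$ut] <- ei
    E <- E + t(E)
    null_i <- numeric(n_permutations)
    for (q in seq_len(n_permutations)) {
      pi_ <- sample.int(d$N)
      Xq <- d$X
      Xq[, i + 1L] <- E[pi_, pi_][d$ut]
      bq <- tryCatch(qr.coef(qr(Xq), y), error = function(e) NULL)
      null_i[q] <- if (is.null(bq)) NA_real_ else bq[i + 1L]
    }
    nulls[[i]] <- null_i
  }
  .mrqap_result(d, coefs, nulls, "dsp", n_permutations)
}

#' @rdname mrqap
#' @export
mrqap_custom_null <- function(dep, predictors, null_networks) {
  d <- .mrqap_design(dep, predictors)
  y <- d$Y[d$ut]
  coefs <- drop(d$proj %*% y)[-1L]
  n <- length(null_networks)
  if (n < 1L) stop("need at least one null network")
  nulls <- matrix(NA_real_, n, length(d$names),
                  dimnames = list(NULL, d$names))
  for (q in seq_len(n)) {
    Yq <- .dyad_matrix(null_networks[[q]], "null network")
    if (nrow(Yq) != d$N) stop("null network size mismatch")
    nulls[q, ] <- drop(d$proj %*% Yq[d$ut])[-1L]
  }
  .mrqap_result(d, coefs, as.list(as.data.frame(nulls)), "custom-null", n)
}

#' @export
print.mrqap <- function(x, ...) {
  cat(sprintf("MRQAP (%s), %d dyadic observations, %d permutations\n",
              x$method, x$n_nodes * (x$n_nodes - 1) / 2, x$n_permutations))
  tab <- data.frame(coefficient = x$coefficients,
                    p_two_tailed = x$p_two_tailed,
                    row.names = x$predictor_names)
  print(tab, digits = 4)
  invisible(x)
}

#' @export
coef.mrqap <- function(object, ...) object$coefficients

#' @export
summary.mrqap <- function(object, ...) {
  tab <- data.frame(
    coefficient = object$coefficients,
    null_mean = vapply(object$null_coefficients, mean, 1, na.rm = TRUE),
    null_sd = vapply(object$null_coefficients, sd, 1, na.rm = TRUE),
    p_upper = object$p_upper, p_lower = object$p_lower,
    p_two_tailed = object$p_two_tailed,
    row.names = object$predictor_names)
  structure(list(method = object$method, table = tab,
                 n_permutations = object$n_permutations),
            class = "summary.mrqap")
}

#' @export
print.summary.mrqap <- function(x, ...) {
  cat(sprintf("MRQAP (%s), %d permutations\n", x$method, x$n_permutations))
  print(x$table, digits = 4)
  invisible(x)
}
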