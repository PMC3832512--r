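#' Numerically stable logistic sigmoid
#'
#' @param a Numeric vector.
#' @return `1 / (1 + exp(-a))`, saturating to 0/1 without overflow for large
#'   `|a|`.
#' @export
sigmoid <- function(a) {
  out <- numeric(length(a))
  pos <- !is.na(a) & a >= 0
  out[pos] <- 1 / (1 + exp(-a[pos]))
  neg <- !is.na(a) & a < 0
  ea <- exp(a[neg])
  out[neg] <- ea / (1 + ea)
  out[is.na(a)] <- NA_real_
  out
}

#' K-nearest-neighbour configuration
#'
#' @param k Number of neighbours (default 10; must satisfy `k <= N - 1` in
#'   leave-one-out use).
#' @param standardize Z-scale each predictor before computing Euclidean
#'   distances? Off by default: audiometric predictors share the dB scale.
#' @return An object of class `knn_config`.
#' @export
knn_config <- function(k = 10, standardize = FALSE) {
  k <- as.integer(k)
  if (k < 1) stop("k must be a positive integer")
  structure(list(k = k, standardize = standardize), class = "knn_config")
}

#' K-nearest-neighbour posterior probability
#'
#' The posterior probability of a positive outcome for a query point is the
#' fraction of positive labels among its `k` nearest training points by
#' Euclidean distance. If several training points tie with the k-th distance,
#' all tied points are included, so the result does not depend on record
#' order; posteriors then lie on the grid `0, 1/k', ..., 1` for the attained
#' neighbourhood size `k'`.
#'
#' @param train_x Numeric training matrix (rows = records) or vector (1-D).
#' @param train_y Binary outcomes (0/1), one per training row.
#' @param query Numeric matrix of query points (or a single vector).
#' @param config A [knn_config()].
#' @return Numeric vector of posteriors in \[0, 1\], one per query row.
#' @export
knn_posterior <- function(train_x, train_y, query, config = knn_config()) {
  train_x <- as_pred_matrix(train_x)
  query <- as_pred_matrix(query, d = ncol(train_x))
  n <- nrow(train_x)
  if (n == 0) stop("training set must be non-empty")
  if (length(train_y) != n) stop("train_y must match train_x rows")
  if (config$k > n) {
    stop("k = ", config$k, " exceeds the training-set size ", n)
  }
  if (ncol(query) != ncol(train_x)) {
    stop("query dimension ", ncol(query), " does not match training dimension ",
         ncol(train_x))
  }
  if (config$standardize) {
    mu <- colMeans(train_x)
    sdv <- apply(train_x, 2, stats::sd)
    sdv[sdv == 0] <- 1
    train_x <- sweep(sweep(train_x, 2, mu), 2, sdv, "/")
    query <- sweep(sweep(query, 2, mu), 2, sdv, "/")
  }
  y <- as.numeric(train_y)
  vapply(seq_len(nrow(query)), function(i) {
    d2 <- colSums((t(train_x) - query[i, ])^2)
    knn_vote(d2, y, config$k)
  }, numeric(1))
}

# Tie-expanded neighbour vote on squared distances.
knn_vote <- function(d2, y, k) {
  kth <- sort(d2, partial = k)[k]
  nb <- d2 <= kth + 1e-12 * max(1, kth)
  sum(y[nb]) / sum(nb)
}

as_pred_matrix <- function(x, d = NULL) {
  if (is.null(dim(x))) {
    x <- if (!is.null(d) && d == 1) matrix(x, ncol = 1) else
      if (is.null(d)) matrix(x, ncol = 1) else matrix(x, ncol = d, byrow = TRUE)
  }
  storage.mode(x) <- "double"
  as.matrix(x)
}

#' Fit a logistic posterior model by maximum likelihood
#'
#' Fits `p(positive | x) = sigmoid(w0 + w'x)` (linear) or with each
#' predictor's square appended as an extra predictor (quadratic; no cross
#' terms). Fitting is iteratively reweighted least squares via
#' [stats::glm()]. Complete separation is detected by coefficient-norm
#' divergence and raised as an error, as is a single-class outcome vector.
#'
#' @param x Predictor matrix (rows = records) or vector.
#' @param y Binary outcomes (0/1).
#' @param expansion `"linear"` or `"quadratic"`.
#' @return An object of class `logistic_model` with elements `weights`
#'   (intercept first), `expansion`, `converged`, `loglik`.
#' @export
logistic_fit <- function(x, y, expansion = c("linear", "quadratic")) {
  expansion <- match.arg(expansion)
  x <- as_pred_matrix(x)
  y <- as.integer(y)
  if (nrow(x) != length(y)) stop("x and y lengths differ")
  if (nrow(x) < 2) stop("need at least 2 records")
  if (length(unique(y)) < 2) {
    stop("degenerate fit: outcome vector contains a single class")
  }
  xx <- expand_design(x, expansion)
  fit <- suppressWarnings(
    stats::glm.fit(cbind(1, xx), y, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-8, maxit = 100))
  )
  w <- fit$coefficients
  # complete separation: the deviance collapses to 0 (every case fitted with
  # probability 1) or the coefficient norm diverges
  if (any(!is.finite(w)) || sqrt(sum(w^2)) > 1e4 || fit$deviance < 1e-6) {
    stop("non-convergence: complete separation detected ",
         "(likelihood maximised only in the limit of infinite weights)")
  }
  structure(list(weights = unname(w), expansion = expansion,
                 converged = fit$converged,
                 loglik = -fit$deviance / 2,
                 d = ncol(x)),
            class = "logistic_model")
}

expand_design <- function(x, expansion) {
  if (expansion == "quadratic") cbind(x, x^2) else x
}

#' Posterior probabilities from a fitted logistic model
#'
#' @param model A [logistic_fit()] result.
#' @param x Predictor matrix or vector (original predictors; the quadratic
#'   expansion, if any, is applied internally).
#' @return Numeric vector of posteriors.
#' @export
logistic_posterior <- function(model, x) {
  stopifnot(inherits(model, "logistic_model"))
  x <- as_pred_matrix(x, d = model$d)
  if (ncol(x) != model$d) {
    stop("query dimension ", ncol(x), " does not match model dimension ",
         model$d)
  }
  xx <- expand_design(x, model$expansion)
  sigmoid(drop(cbind(1, xx) %*% model$weights))
}

#' Leave-one-out cross-validated posteriors
#'
#' Each record's posterior probability of a positive outcome is computed by a
#' model trained on all other records — the "virtual screening test" score.
#' Deterministic given the inputs; for KNN the id-to-posterior mapping is
#' invariant under record permutation (tie-expanded neighbourhoods).
#'
#' @param x Predictor matrix (rows = records) or vector.
#' @param y Binary outcomes (0/1).
#' @param method A [knn_config()] for KNN, or `"linear"`/`"quadratic"` for
#'   logistic regression.
#' @param ids Optional record identifiers (defaults to row numbers).
#' @return A data.frame of class `posterior_set` with columns `patient_id`,
#'   `posterior`, `outcome`.
#' @export
loocv_posteriors <- function(x, y, method = knn_config(), ids = NULL) {
  x <- as_pred_matrix(x)
  y <- as.integer(y)
  n <- nrow(x)
  if (n != length(y)) stop("x and y lengths differ")
  if (n < 3) stop("leave-one-out cross-validation needs at least 3 records")
  if (is.null(ids)) ids <- as.character(seq_len(n))
  if (inherits(method, "knn_config")) {
    if (method$k > n - 1) {
      stop("k = ", method$k, " exceeds the leave-one-out training size ",
           n - 1)
    }
    xs <- x
    if (method$standardize) {
      mu <- colMeans(x)
      sdv <- apply(x, 2, stats::sd)
      sdv[sdv == 0] <- 1
      xs <- sweep(sweep(x, 2, mu), 2, sdv, "/")
    }
    # full squared-distance matrix; self-distance excluded per fold
    g <- tcrossprod(xs)
    sq <- diag(g)
    d2 <- outer(sq, sq, "+") - 2 * g
    d2[d2 < 0] <- 0
    yy <- as.numeric(y)
    post <- vapply(seq_len(n), function(i) {
      knn_vote(d2[i, -i], yy[-i], method$k)
    }, numeric(1))
  } else if (is.character(method) && length(method) == 1 &&
             method %in% c("linear", "quadratic")) {
    post <- vapply(seq_len(n), function(i) {
      yi <- y[-i]
      if (length(unique(yi)) < 2) {
        stop("fold error: leaving out record ", ids[i],
             " removes the only record of one class")
      }
      m <- logistic_fit(x[-i, , drop = FALSE], yi, method)
      logistic_posterior(m, x[i, , drop = FALSE])
    }, numeric(1))
  } else {
    stop("method must be a knn_config or \"linear\"/\"quadratic\"")
  }
  structure(data.frame(patient_id = ids, posterior = post, outcome = y,
                       stringsAsFactors = FALSE),
            class = c("posterior_set", "data.frame"))
}
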