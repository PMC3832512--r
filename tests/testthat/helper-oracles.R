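# Independent brute-force oracles used across the test files. These stay
# deliberately naive: full enumeration, no shared code with the implementation.

# ATR: enumerate every contiguous window, floor at 0
atr_bruteforce <- function(pretest, posttest) {
  red <- pretest - posttest
  n <- length(red)
  best <- 0
  for (i in seq_len(n)) {
    for (j in i:n) best <- max(best, sum(red[i:j]))
  }
  best
}

# KNN posterior: full distance sort with tie expansion
knn_bruteforce <- function(train_x, train_y, q, k) {
  train_x <- as.matrix(train_x)
  d <- sqrt(rowSums((train_x - matrix(q, nrow(train_x), ncol(train_x),
                                      byrow = TRUE))^2))
  kth <- sort(d)[k]
  nb <- d <= kth + 1e-9 * max(1, kth)
  mean(train_y[nb])
}

# AUC by explicit pair counting with half credit for ties
auc_paircount <- function(scores, outcomes) {
  sp <- scores[outcomes == 1]
  sn <- scores[outcomes == 0]
  tot <- 0
  for (a in sp) tot <- tot + sum(a > sn) + 0.5 * sum(a == sn)
  tot / (length(sp) * length(sn))
}

# Exhaustive rectangle search with the package's tie rules, coded naively
region_bruteforce <- function(x, y, outcomes, min_fraction, step) {
  gx <- seq(floor(min(x) / step) * step, ceiling(max(x) / step) * step,
            by = step)
  gy <- seq(floor(min(y) / step) * step, ceiling(max(y) / step) * step,
            by = step)
  need <- ceiling(min_fraction * length(x))
  best <- NULL
  for (i in seq_along(gx)) for (j in i:length(gx)) {
    for (k in seq_along(gy)) for (l in k:length(gy)) {
      inside <- x >= gx[i] & x <= gx[j] & y >= gy[k] & y <= gy[l]
      n_in <- sum(inside)
      if (n_in < need) next
      cand <- list(rate = sum(outcomes[inside] == 1) / n_in, n_in = n_in,
                   area = (gx[j] - gx[i]) * (gy[l] - gy[k]),
                   bounds = c(gx[i], gx[j], gy[k], gy[l]))
      if (is.null(best) || better_region(cand, best)) best <- cand
    }
  }
  best
}

better_region <- function(a, b) {
  key_a <- c(-a$rate, -a$n_in, a$area, a$bounds)
  key_b <- c(-b$rate, -b$n_in, b$area, b$bounds)
  for (i in seq_along(key_a)) {
    if (key_a[i] < key_b[i]) return(TRUE)
    if (key_a[i] > key_b[i]) return(FALSE)
  }
  FALSE
}

# Bernoulli log-likelihood of a linear logistic model
logistic_loglik <- function(w, x, y) {
  eta <- cbind(1, x) %*% w
  sum(y * eta - log1p(exp(eta)))
}

# coarse-to-fine grid search MLE in 2 parameters (1-D linear model)
logistic_gridsearch <- function(x, y, lim = 5) {
  best <- c(0, 0)
  width <- lim
  for (stage in 1:4) {
    g0 <- seq(best[1] - width, best[1] + width, length.out = 41)
    g1 <- seq(best[2] - width, best[2] + width, length.out = 41)
    ll <- outer(g0, g1, Vectorize(function(a, b) {
      logistic_loglik(c(a, b), x, y)
    }))
    ix <- which(ll == max(ll), arr.ind = TRUE)[1, ]
    best <- c(g0[ix[1]], g1[ix[2]])
    width <- width / 10
  }
  best
}

default_glycerol_cohort <- function(seed = 3) {
  gen_cohort_audiograms(audiogram_scenario(seed = seed))
}
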