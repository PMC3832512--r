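#' Confusion counts at a threshold
#'
#' The prediction is positive iff `posterior > tau` (strict); ties go to
#' "do not test". This convention is used throughout the package.
#'
#' @param posteriors Numeric vector in \[0, 1\].
#' @param outcomes Binary vector (0/1), same length.
#' @param tau Decision threshold.
#' @return An object of class `confusion`: list with `tp`, `fp`, `tn`, `fn`,
#'   `tau`, `n`.
#' @export
confusion_at_threshold <- function(posteriors, outcomes, tau) {
  if (length(posteriors) != length(outcomes)) {
    stop("posteriors and outcomes must have the same length")
  }
  pred <- posteriors > tau
  pos <- outcomes == 1
  structure(list(tp = sum(pred & pos), fp = sum(pred & !pos),
                 tn = sum(!pred & !pos), fn = sum(!pred & pos),
                 tau = tau, n = length(outcomes)),
            class = "confusion")
}

#' @export
print.confusion <- function(x, ...) {
  cat(sprintf("confusion at tau = %g: TP %d, FP %d, TN %d, FN %d (N = %d)\n",
              x$tau, x$tp, x$fp, x$tn, x$fn, x$n))
  invisible(x)
}

#' Rates from confusion counts
#'
#' @param cm A [confusion_at_threshold()] result.
#' @return List with `fpr` (false-positive rate), `tpr` (true-positive rate /
#'   sensitivity) and `rpp` (rate of positive predictions: the proportion of
#'   candidates that would be selected for testing). A rate with a zero
#'   denominator is returned as `NA` (undefined), not an error.
#' @export
rates <- function(cm) {
  stopifnot(inherits(cm, "confusion"))
  negs <- cm$fp + cm$tn
  poss <- cm$tp + cm$fn
  list(fpr = if (negs > 0) cm$fp / negs else NA_real_,
       tpr = if (poss > 0) cm$tp / poss else NA_real_,
       rpp = if (cm$n > 0) (cm$tp + cm$fp) / cm$n else NA_real_)
}

#' Positive and negative predictive values
#'
#' The PPV is the probability that a positive prediction would be confirmed by
#' actually performing the test; the NPV likewise for negative predictions.
#' To guarantee a minimum estimation quality, a value is masked (`NA`) unless
#' it is based on strictly more than `min_count` predictions.
#'
#' @param cm A [confusion_at_threshold()] result.
#' @param min_count Masking count, default 20 (strict: "more than 20").
#' @return List with `ppv` and `npv` (possibly `NA`).
#' @export
predictive_values <- function(cm, min_count = 20) {
  stopifnot(inherits(cm, "confusion"), min_count >= 0)
  np <- cm$tp + cm$fp
  nn <- cm$tn + cm$fn
  list(ppv = if (np > min_count) cm$tp / np else NA_real_,
       npv = if (nn > min_count) cm$tn / nn else NA_real_)
}

#' Likelihood ratio positive
#'
#' @param tpr,fpr True- and false-positive rates.
#' @return `tpr / fpr`; `Inf` when `fpr` is 0.
#' @export
lr_plus <- function(tpr, fpr) {
  ifelse(fpr == 0, Inf, tpr / fpr)
}

#' Probability/odds transforms
#'
#' `odds(p) = p / (1 - p)` and `prob_from_odds(o) = o / (1 + o)` are mutual
#' inverses; `post_test_odds` multiplies pre-test odds by a likelihood ratio.
#'
#' @param p Probability in \[0, 1\).
#' @return For `odds`, the odds (`Inf` at p = 1).
#' @export
odds <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p must be in [0, 1]")
  ifelse(p == 1, Inf, p / (1 - p))
}

#' @rdname odds
#' @param o Odds (>= 0).
#' @export
prob_from_odds <- function(o) {
  if (any(o < 0, na.rm = TRUE)) stop("odds must be non-negative")
  ifelse(is.infinite(o), 1, o / (1 + o))
}

#' @rdname odds
#' @param pretest_p Pre-test probability (e.g. the prevalence).
#' @param lr Likelihood ratio.
#' @export
post_test_odds <- function(pretest_p, lr) {
  odds(pretest_p) * lr
}

#' Area under the ROC curve (Mann-Whitney statistic)
#'
#' Computed as the rank statistic with half credit for ties, which is
#' identical to the trapezoidal area under the empirical ROC curve and is
#' well-defined under the heavy ties produced by KNN posteriors.
#'
#' @param posteriors Numeric scores.
#' @param outcomes Binary vector (0/1).
#' @return AUC in \[0, 1\].
#' @export
auc <- function(posteriors, outcomes) {
  pos <- outcomes == 1
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) {
    stop("AUC needs both classes present")
  }
  r <- rank(posteriors, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Empirical ROC curve
#'
#' Thresholds are the unique score values in descending order preceded by a
#' sentinel above the maximum (so the (0, 0) corner is always present); the
#' prediction rule is strictly `posterior > threshold`. Confusion counts,
#' rates, predictive values (masked below `min_count`) and LR+ are tabulated
#' at each threshold.
#'
#' @param posteriors Numeric scores.
#' @param outcomes Binary vector (0/1).
#' @param min_count Masking count for predictive values, default 20.
#' @return An object of class `roc_curve`: a data.frame with columns
#'   `threshold`, `tp`, `fp`, `tn`, `fn`, `fpr`, `tpr`, `rpp`, `ppv`, `npv`,
#'   `lr_plus` and an `auc` attribute.
#' @export
roc_curve <- function(posteriors, outcomes, min_count = 20) {
  pos <- outcomes == 1
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("ROC curve needs both classes present")
  n <- length(posteriors)
  ord <- order(posteriors, decreasing = TRUE)
  sp <- posteriors[ord]
  sy <- pos[ord]
  cum_tp <- cumsum(sy)
  cum_fp <- cumsum(!sy)
  u <- unique(sp)                      # descending unique values
  counts <- tabulate(match(sp, u))     # multiplicity of each unique value
  cumc <- cumsum(counts)
  # strict rule: at threshold u[j], predicted positive are scores > u[j],
  # i.e. everything before the first occurrence of u[j]
  m <- c(0L, 0L, cumc[-length(cumc)])  # sentinel, then per unique value
  thr <- c(u[1] + 1, u)
  tp <- ifelse(m == 0, 0, cum_tp[pmax(m, 1)])
  fp <- ifelse(m == 0, 0, cum_fp[pmax(m, 1)])
  # the lowest attainable operating point, everything predicted positive,
  # corresponds to any threshold below min(sp); append it
  thr <- c(thr, u[length(u)] - 1)
  tp <- c(tp, n1)
  fp <- c(fp, n0)
  fn <- n1 - tp
  tn <- n0 - fp
  npred_pos <- tp + fp
  npred_neg <- tn + fn
  out <- data.frame(
    threshold = thr,
    tp = tp, fp = fp, tn = tn, fn = fn,
    fpr = fp / n0, tpr = tp / n1, rpp = (tp + fp) / n,
    ppv = ifelse(npred_pos > min_count, tp / npred_pos, NA_real_),
    npv = ifelse(npred_neg > min_count, tn / npred_neg, NA_real_),
    lr_plus = ifelse(npred_pos > min_count & fp > 0,
                     (tp / n1) / (fp / n0),
                     ifelse(fp == 0 & tp > 0 & npred_pos > min_count,
                            Inf, NA_real_))
  )
  structure(out, class = c("roc_curve", "data.frame"),
            auc = auc(posteriors, outcomes))
}

#' AUC of the binormal model
#'
#' For a score that is normal within each class (`mu0`, `sigma0` for the
#' negative class; `mu1`, `sigma1` for the positive), the AUC is
#' `pnorm((mu1 - mu0) / sqrt(sigma0^2 + sigma1^2))`.
#'
#' @param mu0,mu1 Class-conditional means.
#' @param sigma0,sigma1 Class-conditional standard deviations (> 0).
#' @return The AUC.
#' @export
binormal_auc <- function(mu0, mu1, sigma0 = 1, sigma1 = 1) {
  if (any(sigma0 <= 0) || any(sigma1 <= 0)) stop("sigmas must be positive")
  stats::pnorm((mu1 - mu0) / sqrt(sigma0^2 + sigma1^2))
}

#' Area-related index d_a from an AUC
#'
#' `d_a = sqrt(2) * qnorm(auc)`; under equal class variances it reduces to
#' the index of detectability d' and inverts [binormal_auc()].
#'
#' @param auc AUC strictly between 0 and 1.
#' @return `d_a` (infinite at AUC 0 or 1).
#' @export
da_from_auc <- function(auc) {
  if (any(auc < 0 | auc > 1)) stop("auc must be in [0, 1]")
  sqrt(2) * stats::qnorm(auc)
}

#' Point on the equal-variance binormal ROC curve
#'
#' Parametric representation `tpr = pnorm(d' - qnorm(1 - fpr))`.
#'
#' @param d_prime Index of detectability.
#' @param fpr False-positive rate(s) in \[0, 1\]; the boundary values map to
#'   the limits 0 and 1.
#' @return True-positive rate(s).
#' @export
binormal_roc_point <- function(d_prime, fpr) {
  if (any(fpr < 0 | fpr > 1)) stop("fpr must be in [0, 1]")
  out <- stats::pnorm(d_prime - stats::qnorm(1 - fpr))
  out[fpr == 0] <- 0
  out[fpr == 1] <- 1
  out
}
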