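#' Loss matrices and decision thresholds
#'
#' A loss matrix `L[true + 1, assigned + 1]` holds the loss of assigning a
#' patient whose true class is `true` (0 = negative, 1 = positive outcome)
#' to class `assigned` (1 = select for testing). For the optimal decision
#' threshold to lie strictly inside (0, 1) both error losses must exceed the
#' corresponding correct-assignment losses.
#'
#' @param l00,l01,l10,l11 Entries `L[true][assigned]`.
#' @return A 2x2 matrix with dimnames `true`/`assigned`.
#' @export
loss_matrix <- function(l00, l01, l10, l11) {
  L <- matrix(c(l00, l10, l01, l11), nrow = 2,
              dimnames = list(true = c("0", "1"), assigned = c("0", "1")))
  if (any(!is.finite(L))) stop("loss matrix entries must be finite")
  L
}

#' Clinical-design loss matrix from effective cost and benefit
#'
#' Fixes the zero of the loss scale at the perfect classifier
#' (`L00 = L11 = 0`); a false positive then contributes the effective cost
#' `C` of a wasted test and a false negative the missed effective benefit
#' `B - C`.
#'
#' @param cost Effective cost `C` of performing the test (> 0).
#' @param benefit Effective benefit `B` of a positive outcome.
#' @return A [loss_matrix()]. When `B <= C`, testing is never beneficial and
#'   a warning is issued.
#' @export
loss_matrix_clinical <- function(cost, benefit) {
  if (cost <= 0) stop("cost must be positive")
  if (benefit <= cost) {
    warning("benefit does not exceed cost: testing is never beneficial")
  }
  loss_matrix(0, cost, benefit - cost, 0)
}

#' Optimal decision threshold from a loss matrix
#'
#' The expected-loss-minimizing rule selects a patient for testing iff the
#' posterior exceeds `p* = (L01 - L00) / ((L01 - L00) + (L10 - L11))`.
#'
#' @param L A [loss_matrix()].
#' @return The threshold probability `p*` in (0, 1).
#' @export
threshold_from_loss_matrix <- function(L) {
  d01 <- L["0", "1"] - L["0", "0"]
  d10 <- L["1", "0"] - L["1", "1"]
  if (d01 <= 0 || d10 <= 0) {
    stop("no interior threshold: need L01 > L00 and L10 > L11")
  }
  d01 / (d01 + d10)
}

#' Optimal decision threshold from costs and benefits
#'
#' With test cost `C_test` and outcome benefits `B_neg < B_pos`, the
#' threshold is `p* = (C_test - B_neg) / (B_pos - B_neg)`; with `B_neg = 0`
#' this is the cost-benefit ratio `C_test / B_pos`.
#'
#' @param c_test Cost of performing the test.
#' @param b_pos Benefit of a positive outcome.
#' @param b_neg Benefit of a negative outcome (default 0, appropriate for a
#'   low-sensitivity test).
#' @return The threshold probability `p*`.
#' @export
threshold_from_costbenefit <- function(c_test, b_pos, b_neg = 0) {
  if (b_pos <= b_neg) stop("b_pos must exceed b_neg")
  (c_test - b_neg) / (b_pos - b_neg)
}

#' Expected loss per patient from confusion counts
#'
#' `C_pred + (TN*L00 + FP*L01 + FN*L10 + TP*L11) / N`. Only the loss
#' differences `L01 - L00` and `L10 - L11` matter when comparing two
#' classifiers or thresholds; constants added per true-class row cancel.
#'
#' @param cm A [confusion_at_threshold()] result.
#' @param L A [loss_matrix()].
#' @param c_pred Cost of making the prediction itself (default 0).
#' @return Expected loss per patient.
#' @export
expected_loss_counts <- function(cm, L, c_pred = 0) {
  stopifnot(inherits(cm, "confusion"))
  if (cm$tp + cm$fp + cm$tn + cm$fn != cm$n) {
    stop("confusion counts do not sum to N")
  }
  if (cm$n == 0) stop("N must be positive")
  c_pred + (cm$tn * L["0", "0"] + cm$fp * L["0", "1"] +
            cm$fn * L["1", "0"] + cm$tp * L["1", "1"]) / cm$n
}

#' Expected loss per tested subject in a screening study
#'
#' For a study that must recruit until a fixed number of subjects has been
#' tested, the loss per tested subject is
#' `C_screen / RPP + C_test - B_pos * PPV`: screening `1 / RPP` candidates to
#' find one selected for testing, paying the test cost, and receiving the
#' benefit only for the PPV fraction of positive outcomes.
#'
#' @param rpp Rate of positive predictions (> 0).
#' @param ppv Positive predictive value in \[0, 1\].
#' @param c_screen Per-candidate screening cost (>= 0).
#' @param c_test Test cost.
#' @param b_pos Benefit of a positive outcome.
#' @return Expected loss per tested subject; `Inf` when `rpp` is 0 (no one is
#'   ever tested).
#' @export
expected_loss_screening <- function(rpp, ppv, c_screen, c_test, b_pos) {
  if (any(ppv < 0 | ppv > 1, na.rm = TRUE)) stop("ppv must be in [0, 1]")
  if (c_screen < 0) stop("c_screen must be non-negative")
  ifelse(rpp <= 0, Inf, c_screen / rpp + c_test - b_pos * ppv)
}

#' Expected loss as a function of the decision threshold
#'
#' Evaluates the expected loss of the rule "select for testing iff posterior
#' > tau" over a threshold grid, for either the clinical design (loss matrix
#' from effective cost/benefit) or the screening-study design (per tested
#' subject). By default the grid is the set of attained posterior values plus
#' the endpoints 0 and 1: KNN posteriors are discrete, so no other thresholds
#' change the decision. The tau = 0 grid point represents the test-all policy
#' (every patient selected), matching the endpoint algebra
#' `loss(0) = (1 - prevalence) * C` for the clinical design.
#'
#' @param posteriors Numeric vector of posteriors (or a `posterior_set`).
#' @param outcomes Binary outcomes; ignored when `posteriors` is a
#'   `posterior_set`.
#' @param design `"clinical"` or `"screening"`.
#' @param cost,benefit Clinical design: effective cost `C` and benefit `B`.
#' @param c_screen,c_test,b_pos Screening design parameters.
#' @param c_pred Prediction cost (clinical design), default 0.
#' @param thresholds Optional explicit grid in \[0, 1\]; the endpoints 0 and 1
#'   are always included.
#' @return An object of class `loss_curve`: data.frame with columns
#'   `threshold` and `expected_loss` (ascending thresholds), with attributes
#'   `argmin` (threshold attaining the minimal loss; ties broken toward the
#'   larger threshold, i.e. testing fewer patients) and `min_loss`.
#'   Screening-design points where no patient is selected are `NA` (masked).
#' @export
loss_curve <- function(posteriors, outcomes = NULL,
                       design = c("clinical", "screening"),
                       cost = 1, benefit = 2,
                       c_screen = 0.25, c_test = 1, b_pos = 10,
                       c_pred = 0, thresholds = NULL) {
  design <- match.arg(design)
  if (inherits(posteriors, "posterior_set")) {
    outcomes <- posteriors$outcome
    posteriors <- posteriors$posterior
  }
  if (is.null(outcomes)) stop("outcomes are required")
  if (is.null(thresholds)) thresholds <- unique(posteriors)
  if (any(thresholds < 0 | thresholds > 1)) {
    stop("thresholds must lie in [0, 1]")
  }
  tau <- sort(unique(c(0, thresholds, 1)))
  n <- length(posteriors)
  pos <- outcomes == 1
  n1 <- sum(pos)
  n0 <- n - n1
  # counts at each tau via one sort (strict rule p > tau);
  # tau = 0 is the test-all policy: all predicted positive
  ord <- order(posteriors, decreasing = TRUE)
  sy <- pos[ord]
  sp <- posteriors[ord]
  cum_tp <- c(0, cumsum(sy))
  cum_fp <- c(0, cumsum(!sy))
  npred <- n - findInterval(tau, sp[n:1])         # count of sp > tau
  npred[tau == 0] <- n
  tp <- cum_tp[npred + 1]
  fp <- cum_fp[npred + 1]
  fn <- n1 - tp
  tn <- n0 - fp
  if (design == "clinical") {
    L <- loss_matrix_clinical(cost, benefit)
    el <- c_pred + (tn * L["0", "0"] + fp * L["0", "1"] +
                    fn * L["1", "0"] + tp * L["1", "1"]) / n
  } else {
    rpp <- (tp + fp) / n
    ppv <- ifelse(tp + fp > 0, tp / (tp + fp), NA_real_)
    el <- ifelse(rpp > 0,
                 c_screen / rpp + c_test - b_pos * ppv,
                 NA_real_)
  }
  ok <- !is.na(el)
  min_loss <- min(el[ok])
  argmin <- max(tau[ok][el[ok] == min_loss])  # ties -> larger threshold
  structure(data.frame(threshold = tau, expected_loss = el),
            class = c("loss_curve", "data.frame"),
            design = design, argmin = argmin, min_loss = min_loss)
}

#' @export
print.loss_curve <- function(x, ...) {
  cat(sprintf("loss_curve (%s design): %d thresholds; minimum %.6g at tau = %.6g\n",
              attr(x, "design"), nrow(x), attr(x, "min_loss"),
              attr(x, "argmin")))
  invisible(x)
}

#' Net benefit of a threshold choice (decision-curve analysis)
#'
#' `NB = TP/N - (FP/N) * p_t / (1 - p_t)`. With the screening-style loss
#' matrix `L00 = L10 = 0`, `L01 = c`, `L11 = c - b` and `p_t = c / b`, the
#' expected loss equals `-(b - c)` times the net benefit, so both rank
#' thresholds identically.
#'
#' @param cm A [confusion_at_threshold()] result.
#' @param p_t Threshold probability strictly inside (0, 1).
#' @return The net benefit.
#' @export
net_benefit <- function(cm, p_t) {
  stopifnot(inherits(cm, "confusion"))
  if (p_t <= 0 || p_t >= 1) stop("p_t must lie strictly inside (0, 1)")
  cm$tp / cm$n - (cm$fp / cm$n) * p_t / (1 - p_t)
}
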