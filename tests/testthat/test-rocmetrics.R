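test_that("confusion counts partition the cohort under the strict rule", {
  p <- c(0.2, 0.6, 0.6, 0.9)
  y <- c(0, 0, 1, 1)
  cm <- confusion_at_threshold(p, y, 0.5)
  expect_equal(c(cm$tp, cm$fp, cm$tn, cm$fn), c(2, 1, 1, 0))
  cm1 <- confusion_at_threshold(p, y, 1)
  expect_equal(cm1$tp + cm1$fp, 0)
  cm0 <- confusion_at_threshold(p, y, 0.1)
  expect_equal(c(cm0$tp, cm0$fp), c(2, 2))
  # strictness: posterior equal to the threshold is not selected
  cme <- confusion_at_threshold(p, y, 0.6)
  expect_equal(c(cme$tp, cme$fp), c(1, 0))
  expect_error(confusion_at_threshold(c(0.5), c(0, 1), 0.5), "length")
})

test_that("rates handle zero denominators as undefined markers", {
  cm <- confusion_at_threshold(c(0.2, 0.6, 0.6, 0.9), c(0, 0, 1, 1), 0.5)
  r <- rates(cm)
  expect_equal(r$tpr, 1)
  expect_equal(r$fpr, 0.5)
  expect_equal(r$rpp, 0.75)
  r0 <- rates(confusion_at_threshold(c(0.2, 0.3), c(0, 1), 0.9))
  expect_equal(r0$rpp, 0)
  expect_equal(r0$tpr, 0)
  expect_equal(r0$fpr, 0)
  rna <- rates(confusion_at_threshold(c(0.2, 0.9), c(1, 1), 0.5))
  expect_true(is.na(rna$fpr))  # no negative cases
})

test_that("predictive values apply the strict more-than-min_count mask", {
  cm <- confusion_at_threshold(c(rep(0.8, 4), 0.1), c(1, 1, 1, 0, 0), 0.5)
  expect_equal(predictive_values(cm, 0)$ppv, 0.75)
  # exactly min_count predictions -> masked ("more than")
  p20 <- c(rep(0.9, 20), rep(0.1, 5))
  y20 <- c(rep(1, 15), rep(0, 10))
  cm20 <- confusion_at_threshold(p20, y20, 0.5)
  expect_equal(cm20$tp + cm20$fp, 20)
  expect_true(is.na(predictive_values(cm20, 20)$ppv))
  expect_false(is.na(predictive_values(cm20, 19)$ppv))
})

test_that("PPV at the lowest threshold equals prevalence, NPV its complement", {
  set.seed(41)
  p <- runif(200)
  y <- rbinom(200, 1, 0.35)
  prev <- mean(y)
  cm_all <- confusion_at_threshold(p, y, 0)       # everything above 0
  expect_equal(predictive_values(cm_all, 0)$ppv, prev)
  cm_none <- confusion_at_threshold(p, y, 1)
  expect_equal(predictive_values(cm_none, 0)$npv, 1 - prev)
})

test_that("auc equals explicit pair counting, trapezoid and pROC", {
  expect_equal(auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(auc(rep(0.5, 10), rep(0:1, 5)), 0.5)
  s <- c(0.2, 0.6, 0.6, 0.9)
  y <- c(0, 0, 1, 1)
  expect_equal(auc(s, 1 - y), 1 - auc(s, y))
  expect_error(auc(1:3, c(1, 1, 1)), "both classes")

  set.seed(42)
  for (rep in 1:500) {
    n <- sample(4:30, 1)
    sc <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # heavy ties
    yy <- c(0, 1, rbinom(n - 2, 1, 0.5))
    a <- auc(sc, yy)
    expect_equal(a, auc_paircount(sc, yy), tolerance = 1e-12)
    # trapezoidal area under the empirical ROC staircase
    rc <- roc_curve(sc, yy)
    trap <- sum(diff(rc$fpr) * (utils::head(rc$tpr, -1) +
                                  utils::tail(rc$tpr, -1)) / 2)
    expect_equal(a, trap, tolerance = 1e-12)
  }

  skip_if_not_installed("pROC")
  set.seed(43)
  sc <- round(runif(300), 2)
  yy <- rbinom(300, 1, 0.4)
  expect_equal(auc(sc, yy),
               as.numeric(pROC::auc(pROC::roc(yy, sc, quiet = TRUE))))
})

test_that("ROC staircase is monotone with both corners present", {
  rc <- roc_curve(c(0.2, 0.6, 0.6, 0.9), c(0, 0, 1, 1))
  expect_equal(nrow(rc), 5)  # sentinel + 3 unique values + test-all point
  expect_equal(c(rc$fpr[1], rc$tpr[1]), c(0, 0))
  expect_equal(c(rc$fpr[nrow(rc)], rc$tpr[nrow(rc)]), c(1, 1))
  expect_true(all(diff(rc$fpr) >= 0))
  expect_true(all(diff(rc$tpr) >= 0))
  expect_true(all(diff(rc$rpp) >= 0))

  # perfect separation passes through (0, 1)
  rcp <- roc_curve(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_true(any(rcp$fpr == 0 & rcp$tpr == 1))
  expect_equal(attr(rcp, "auc"), 1)
  # all-tied scores: chance diagonal only
  rct <- roc_curve(rep(0.4, 6), c(1, 0, 1, 0, 1, 0))
  expect_equal(attr(rct, "auc"), 0.5)
  expect_error(roc_curve(1:3, c(0, 0, 0)), "both classes")
})

test_that("ROC staircase is invariant under strictly monotone score transforms", {
  set.seed(44)
  sc <- runif(80)
  yy <- rbinom(80, 1, 0.5)
  rc1 <- roc_curve(sc, yy)
  rc2 <- roc_curve(plogis(3 * sc - 1), yy)
  expect_equal(rc1[c("fpr", "tpr", "rpp")], rc2[c("fpr", "tpr", "rpp")])
  expect_equal(attr(rc1, "auc"), attr(rc2, "auc"))
})

test_that("likelihood ratio and odds transforms follow the definitions", {
  expect_equal(lr_plus(0.6, 0.3), 2)
  expect_equal(lr_plus(0.4, 0.4), 1)
  expect_equal(lr_plus(0.4, 0), Inf)
  expect_equal(odds(0.5), 1)
  expect_equal(prob_from_odds(odds(0.5)), 0.5)
  expect_equal(odds(1), Inf)
  expect_error(odds(1.2), "\\[0, 1\\]")
  p <- seq(0.05, 0.95, 0.05)
  expect_equal(prob_from_odds(odds(p)), p)
  # printed prevalence 0.39 and LR+ 2.11
  pto <- post_test_odds(0.39, 2.11)
  expect_equal(pto, 0.39 / 0.61 * 2.11)
  expect_equal(round(prob_from_odds(pto), 3), 0.574)
  expect_equal(prob_from_odds(post_test_odds(0.39, 1)), 0.39)
})

test_that("binormal AUC, d_a and the parametric ROC are mutually consistent", {
  expect_equal(binormal_auc(0, 0), 0.5)
  expect_equal(binormal_auc(0, 1), pnorm(1 / sqrt(2)))
  expect_equal(binormal_auc(0, 1), 0.7602, tolerance = 1e-4)
  expect_equal(binormal_auc(1, 0), 1 - binormal_auc(0, 1))
  expect_error(binormal_auc(0, 1, 0), "positive")

  expect_equal(da_from_auc(0.5), 0)
  expect_equal(da_from_auc(pnorm(1 / sqrt(2))), 1, tolerance = 1e-12)
  expect_equal(da_from_auc(1), Inf)
  # round trip at 1e-10 across the range: d_a as an equal-variance separation
  for (a in c(0.55, 0.6602, 0.7602, 0.9, 0.99)) {
    expect_equal(binormal_auc(0, da_from_auc(a)), a, tolerance = 1e-10)
  }

  expect_equal(binormal_roc_point(0, 0.3), 0.3)  # chance line
  expect_equal(binormal_roc_point(1, 0.5), pnorm(1))
  expect_equal(binormal_roc_point(2, c(0, 1)), c(0, 1))
  # quadrature over the parametric curve recovers pnorm(d'/sqrt(2))
  fgrid <- seq(0, 1, length.out = 20001)
  tpr <- binormal_roc_point(1.3, fgrid)
  area <- sum(diff(fgrid) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  expect_equal(area, pnorm(1.3 / sqrt(2)), tolerance = 1e-6)
})

test_that("empirical AUC of binormal scores matches the closed form", {
  d <- gen_scores_binormal(50000, prevalence = 0.4, d_prime = 1, seed = 45)
  a <- auc(d$score, d$outcome)
  n1 <- sum(d$outcome)
  n0 <- sum(1 - d$outcome)
  # Hanley-McNeil standard error of the empirical AUC
  th <- pnorm(1 / sqrt(2))
  q1 <- th / (2 - th)
  q2 <- 2 * th^2 / (1 + th)
  se <- sqrt((th * (1 - th) + (n1 - 1) * (q1 - th^2) +
                (n0 - 1) * (q2 - th^2)) / (n1 * n0))
  expect_lt(abs(a - th), 3 * se)
})
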