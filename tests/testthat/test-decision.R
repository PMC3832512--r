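test_that("decision thresholds follow the loss-matrix formula", {
  expect_equal(threshold_from_loss_matrix(loss_matrix(0, 1, 1, 0)), 0.5)
  expect_equal(threshold_from_loss_matrix(loss_matrix(0, 1, 9, 0)), 0.1)
  expect_error(threshold_from_loss_matrix(loss_matrix(1, 1, 2, 0)),
               "interior")
  expect_error(loss_matrix(0, Inf, 1, 0), "finite")
})

test_that("cost-benefit thresholds reduce to the cost-benefit ratio", {
  expect_equal(threshold_from_costbenefit(1, 2), 0.5)
  expect_equal(threshold_from_costbenefit(1, 3), 1 / 3)
  expect_equal(threshold_from_costbenefit(1, 2, b_neg = 0.5), 1 / 3)
  expect_error(threshold_from_costbenefit(1, 0.5, b_neg = 1), "exceed")
  # the clinical loss matrix reproduces C/B
  for (cb in list(c(1, 2), c(1, 10), c(0.5, 4))) {
    L <- loss_matrix_clinical(cb[1], cb[2])
    expect_equal(threshold_from_loss_matrix(L), cb[1] / cb[2])
  }
})

test_that("the clinical loss matrix zeroes correct assignments", {
  L <- loss_matrix_clinical(1, 2)
  expect_equal(unname(L), matrix(c(0, 1, 1, 0), 2))
  expect_equal(loss_matrix_clinical(1, 10)["1", "0"], 9)
  expect_warning(loss_matrix_clinical(2, 1), "never beneficial")
})

test_that("expected loss from counts matches hand substitution", {
  # perfect classifier has zero loss under the clinical matrix
  cm_perfect <- confusion_at_threshold(c(0.9, 0.9, 0.1), c(1, 1, 0), 0.5)
  expect_equal(expected_loss_counts(cm_perfect, loss_matrix_clinical(1, 2)), 0)

  cm <- structure(list(tp = 3, fp = 2, tn = 4, fn = 1, tau = 0.5, n = 10),
                  class = "confusion")
  expect_equal(expected_loss_counts(cm, loss_matrix_clinical(1, 3)), 0.4)
  expect_equal(expected_loss_counts(cm, loss_matrix_clinical(1, 3),
                                    c_pred = 0.1), 0.5)
  bad <- structure(list(tp = 3, fp = 2, tn = 4, fn = 1, tau = 0.5, n = 9),
                   class = "confusion")
  expect_error(expected_loss_counts(bad, loss_matrix_clinical(1, 3)),
               "sum to N")
})

test_that("loss differences are invariant under per-row constant shifts", {
  set.seed(51)
  for (rep in 1:50) {
    L <- loss_matrix(runif(1), runif(1, 1, 2), runif(1, 1, 2), runif(1))
    c0 <- rnorm(1)
    c1 <- rnorm(1)
    Ls <- loss_matrix(L[1, 1] + c0, L[1, 2] + c0, L[2, 1] + c1, L[2, 2] + c1)
    n <- 50
    tp <- sample(0:20, 2)
    fp <- sample(0:10, 2)
    cms <- lapply(1:2, function(i) {
      structure(list(tp = tp[i], fp = fp[i], tn = 20 - fp[i],
                     fn = n - tp[i] - fp[i] - (20 - fp[i]), tau = 0.5, n = n),
                class = "confusion")
    })
    d <- expected_loss_counts(cms[[1]], L) - expected_loss_counts(cms[[2]], L)
    ds <- expected_loss_counts(cms[[1]], Ls) -
      expected_loss_counts(cms[[2]], Ls)
    expect_equal(d, ds, tolerance = 1e-12)
  }
})

test_that("screening-design loss follows the per-tested-subject accounting", {
  expect_equal(expected_loss_screening(0.5, 0.6, 0.25, 1, 10), -4.5)
  expect_equal(expected_loss_screening(0.3, 0.1, 0, 1, 10), 0)  # break even
  expect_equal(expected_loss_screening(0, 0.5, 0.25, 1, 10), Inf)
  # linear in the screening cost at fixed rpp
  l1 <- expected_loss_screening(0.4, 0.5, 1, 1, 10)
  l2 <- expected_loss_screening(0.4, 0.5, 2, 1, 10)
  l3 <- expected_loss_screening(0.4, 0.5, 3, 1, 10)
  expect_equal(l3 - l2, l2 - l1)
  expect_gt(l2, l1)
})

test_that("clinical loss-curve endpoints equal (1 - prevalence) when B = 1/prev", {
  co <- default_glycerol_cohort()
  X <- make_predictors(co, "7F")
  ps <- loocv_posteriors(X, co$data$outcome, knn_config(10))
  prev <- mean(ps$outcome)
  lc <- loss_curve(ps, design = "clinical", cost = 1, benefit = 1 / prev)
  expect_equal(lc$expected_loss[1], 1 - prev)            # test all
  expect_equal(lc$expected_loss[nrow(lc)], 1 - prev)     # test none
  expect_lt(attr(lc, "min_loss"), 1 - prev)              # interior is better
  # benefit == cost: refraining from testing is optimal
  lc1 <- suppressWarnings(loss_curve(ps, design = "clinical", cost = 1,
                                     benefit = 1))
  expect_equal(attr(lc1, "argmin"), 1)
  expect_equal(attr(lc1, "min_loss"), 0)
})

test_that("rising screening costs push the optimal threshold toward test-all", {
  co <- default_glycerol_cohort()
  X <- make_predictors(co, "7F")
  ps <- loocv_posteriors(X, co$data$outcome, knn_config(10))
  argmins <- vapply(c(0.25, 1, 4), function(cs) {
    attr(loss_curve(ps, design = "screening", c_screen = cs, c_test = 1,
                    b_pos = 10), "argmin")
  }, numeric(1))
  # selectivity decreases monotonically; with screening costing several times
  # the test itself, selecting candidates is counterproductive (test all)
  expect_true(all(diff(argmins) <= 0))
  expect_equal(argmins[3], 0)
  expect_gt(argmins[1], 0.2)
})

test_that("net benefit matches substitution and the expected-loss equivalence", {
  cm0 <- confusion_at_threshold(c(0.1, 0.2), c(0, 1), 0.9)
  expect_equal(net_benefit(cm0, 0.3), 0)
  cm <- structure(list(tp = 30, fp = 20, tn = 30, fn = 20, tau = 0.5,
                       n = 100), class = "confusion")
  expect_equal(net_benefit(cm, 0.2), 0.25)
  expect_error(net_benefit(cm, 0), "strictly inside")
  expect_error(net_benefit(cm, 1), "strictly inside")

  # affine identity: with L00 = L10 = 0, L01 = c, L11 = c - b, p_t = c/b:
  # expected loss == -(b - c) * net benefit, for any confusion table
  set.seed(52)
  for (rep in 1:100) {
    n <- sample(10:200, 1)
    tp <- sample(0:n, 1)
    fp <- sample(0:(n - tp), 1)
    tn <- sample(0:(n - tp - fp), 1)
    fn <- n - tp - fp - tn
    cmr <- structure(list(tp = tp, fp = fp, tn = tn, fn = fn, tau = 0.5,
                          n = n), class = "confusion")
    b <- runif(1, 1.5, 10)
    cc <- runif(1, 0.2, b - 0.5)
    L <- loss_matrix(0, cc, 0, cc - b)
    expect_equal(expected_loss_counts(cmr, L),
                 -(b - cc) * net_benefit(cmr, cc / b),
                 tolerance = 1e-10)
  }
})

test_that("net-benefit and expected-loss rank thresholds identically", {
  set.seed(53)
  p <- runif(300)
  y <- rbinom(300, 1, p)
  b <- 4
  cc <- 1
  taus <- seq(0.05, 0.95, 0.05)
  L <- loss_matrix(0, cc, 0, cc - b)
  el <- vapply(taus, function(t) {
    expected_loss_counts(confusion_at_threshold(p, y, t), L)
  }, numeric(1))
  nb <- vapply(taus, function(t) {
    net_benefit(confusion_at_threshold(p, y, t), cc / b)
  }, numeric(1))
  expect_equal(order(el), order(-nb))
})

test_that("loss-curve argmin tracks the analytic threshold on calibrated data", {
  set.seed(54)
  n <- 20000
  p <- runif(n)
  y <- rbinom(n, 1, p)
  grid <- seq(0, 1, 0.01)
  lc <- loss_curve(p, y, design = "clinical", cost = 1, benefit = 4,
                   thresholds = grid)
  expect_lt(abs(attr(lc, "argmin") - 0.25), 0.02 + 1e-12)
})
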