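test_that("the interval equation has its fixed points and limits", {
  expect_equal(vb_interval(50, 100, 0.01, 0), 50)              # D = 0
  expect_equal(vb_interval(50, 100, log(2), 1), 75)            # half-gap step
  expect_equal(vb_interval(100, 100, 0.3, 500), 100)           # S1 = A
  expect_equal(vb_interval(10, 130, 0.005, 1e7), 130)          # horizon limit
  # monotone in D when S1 < A
  d <- seq(0, 1000, 50)
  expect_true(all(diff(vb_interval(10, 130, 0.004, d)) > 0))
})

test_that("with no individual heterogeneity the fit collapses to nonlinear least squares", {
  set.seed(14)
  sim <- simulate_growth_intervals(60, 2,
                                   truth = list(A = 130, k = 0.006, A_GS = 0,
                                                k_GS = 0, sd_a = 0, sd_k = 0,
                                                sigma = 8))
  # random-effect SDs held at zero: the marginal likelihood is the plain
  # nonlinear least-squares criterion
  fit0 <- fit_growth(sim$intervals, with_group_size = FALSE,
                     random_effects = character(0))
  nls_fit <- stats::nls(S2 ~ A - (A - S1) * exp(-exp(logk) * D),
                        data = sim$intervals,
                        start = list(A = 140, logk = log(0.004)))
  cf <- stats::coef(nls_fit)
  expect_equal(fit0$A, unname(cf["A"]), tolerance = 1e-4)
  expect_equal(fit0$k, exp(unname(cf["logk"])), tolerance = 1e-4)

  # the full hierarchy, free to estimate the (truly absent) heterogeneity,
  # leaves the fixed effects essentially at the least-squares solution
  fit <- fit_growth(sim$intervals, with_group_size = FALSE)
  expect_equal(fit$A, unname(cf["A"]), tolerance = 0.02)
  expect_equal(fit$k, exp(unname(cf["logk"])), tolerance = 0.05)
})

test_that("hierarchical truth is recovered and dominates the no-random-effect fit", {
  set.seed(20)
  sim <- simulate_growth_intervals(150, 2,
                                   truth = list(A = 130, k = 0.006, A_GS = -9,
                                                k_GS = 5e-4, sd_a = 10,
                                                sd_k = 8e-4, sigma = 8))
  fit <- fit_growth(sim$intervals, with_group_size = TRUE)
  fe <- fit$fixed
  est <- function(term) fe$estimate[fe$term == term]
  se <- function(term) fe$se[fe$term == term]
  expect_lt(abs(est("A") - 130), 2 * se("A"))
  expect_lt(abs(est("A_GS") - (-9)), 2 * se("A_GS"))
  expect_gt(fit$sd_a, 2)      # heterogeneity detected, not at the boundary
  expect_equal(fit$loglik,
               max(fit$loglik,
                   fit_growth(sim$intervals, with_group_size = TRUE,
                              random_effects = character(0))$loglik))

  # cross-check the fixed effects against the conditional-linearisation
  # fitter in nlme on the same data
  library(nlme)
  gz <- (sim$intervals$group_size - mean(sim$intervals$group_size)) /
    sd(sim$intervals$group_size)
  d <- cbind(sim$intervals, gz = gz)
  nl <- nlme::nlme(S2 ~ (A + ags * gz) - ((A + ags * gz) - S1) *
                     exp(-(k + kgs * gz) * D),
                   fixed = A + ags + k + kgs ~ 1,
                   random = nlme::pdDiag(A + k ~ 1),
                   groups = ~individual_id, data = d,
                   start = c(A = est("A"), ags = est("A_GS"), k = est("k"),
                             kgs = est("k_GS")))
  fx <- nlme::fixef(nl)
  expect_equal(est("A"), unname(fx["A"]), tolerance = 0.02)
  expect_equal(est("A_GS"), unname(fx["ags"]), tolerance = 0.1)
  expect_equal(est("k"), unname(fx["k"]), tolerance = 0.05)
})

test_that("estimates are invariant to row order and day/year rescaling", {
  set.seed(31)
  sim <- simulate_growth_intervals(80, 2,
                                   truth = list(A = 130, k = 0.006, A_GS = -6,
                                                k_GS = 0, sd_a = 8, sd_k = 0,
                                                sigma = 6))
  f1 <- fit_growth(sim$intervals, with_group_size = TRUE,
                   random_effects = "A")
  shuffled <- sim$intervals[sample(nrow(sim$intervals)), ]
  f2 <- fit_growth(shuffled, with_group_size = TRUE, random_effects = "A")
  expect_equal(f1$A, f2$A, tolerance = 1e-6)
  expect_equal(f1$k, f2$k, tolerance = 1e-5)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-8)

  rescaled <- sim$intervals
  rescaled$D <- rescaled$D / 365.25
  f3 <- fit_growth(rescaled, with_group_size = TRUE, random_effects = "A")
  expect_equal(f3$k, f1$k * 365.25, tolerance = 5e-3)
  expect_equal(f3$A, f1$A, tolerance = 1e-3)
})

test_that("predicted trajectories start at S0, reach the asymptote and order by group size", {
  set.seed(44)
  sim <- simulate_growth_intervals(120, 2,
                                   truth = list(A = 130, k = 0.006, A_GS = -9,
                                                k_GS = 8e-4, sd_a = 8,
                                                sd_k = 5e-4, sigma = 6))
  fit <- fit_growth(sim$intervals, with_group_size = TRUE)
  mean_gs <- fit$gs_transform$mean
  tr <- predict_growth_curve(fit, S0 = 10, group_size = mean_gs,
                             horizon = 365 * 12)
  expect_equal(tr$mean[1], 10)
  expect_equal(tr$mean[nrow(tr)], fit$A, tolerance = 0.01)
  expect_true(all(tr$lower <= tr$mean & tr$mean <= tr$upper))

  # with A_GS < 0 and k_GS > 0: larger groups grow faster early but level
  # off at a lower asymptote
  small <- predict_growth_curve(fit, 10, group_size = 4, horizon = 365 * 12)
  large <- predict_growth_curve(fit, 10, group_size = 20, horizon = 365 * 12)
  expect_true(fit$A_GS < 0 && fit$k_GS > 0)
  expect_gt(large$mean[10], small$mean[10])
  expect_lt(large$mean[nrow(large)], small$mean[nrow(small)])
})
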