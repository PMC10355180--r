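test_that("the zero-variance limit of the GLMM equals hand-coded Poisson IRLS", {
  set.seed(2)
  sim <- simulate_recruitment_events(30, 3, beta_gs = 0.25, sd_group = 0)
  fit <- fit_recruitment_glmm(sim$events, rainfall = "rain_geometric")
  ev <- sim$events
  zs <- function(x) (x - mean(x)) / sd(x)
  X <- cbind(1, zs(ev$group_size_t1), zs(ev$breeding_female_mass),
             zs(ev$rain_geometric))
  beta_irls <- hand_poisson_irls(X, ev$n_recruits,
                                 offset = log(ev$interval_days / 182.5))
  # true variance is 0, so the fitted random-intercept SD collapses and the
  # fixed effects agree with the plain Poisson regression
  expect_lt(fit$sd_group, 0.05)
  expect_equal(fit$coefficients$estimate, drop(beta_irls), tolerance = 2e-3)

  # forcing the boundary exactly: a GLM equals the IRLS oracle to 1e-6
  glm_fit <- stats::glm(ev$n_recruits ~ X - 1 +
                          offset(log(ev$interval_days / 182.5)),
                        family = stats::poisson())
  expect_equal(unname(stats::coef(glm_fit)), drop(beta_irls), tolerance = 1e-6)
})

test_that("the group-size effect is recovered within 2 SE at the study design size", {
  set.seed(8)
  sim <- simulate_recruitment_events(30, 3, intercept = log(2), beta_gs = 0.2,
                                     sd_group = 0.3)
  fit <- fit_recruitment_glmm(sim$events)
  co <- fit$coefficients
  b <- co$estimate[co$term == "group_size_t1_z"]
  se <- co$se[co$term == "group_size_t1_z"]
  expect_lt(abs(b - 0.2), 2 * se)
  expect_equal(fit$aic, 2 * fit$n_par - 2 * fit$loglik)
})

test_that("offset rescaling shifts only the intercept", {
  set.seed(12)
  sim <- simulate_recruitment_events(25, 3, beta_gs = 0.3, sd_group = 0.2)
  f_days <- fit_recruitment_glmm(sim$events)
  ev_weeks <- sim$events
  ev_weeks$interval_days <- ev_weeks$interval_days * 2   # double every exposure
  f_weeks <- fit_recruitment_glmm(ev_weeks)
  cd <- f_days$coefficients; cw <- f_weeks$coefficients
  expect_equal(cd$estimate[cd$term == "(Intercept)"] - log(2),
               cw$estimate[cw$term == "(Intercept)"], tolerance = 1e-4)
  expect_equal(cd$estimate[cd$term != "(Intercept)"],
               cw$estimate[cw$term != "(Intercept)"], tolerance = 1e-4)
})

test_that("rainfall variants tie with constant covariates and AIC follows its definition", {
  set.seed(3)
  sim <- simulate_recruitment_events(20, 3, beta_gs = 0.2, sd_group = 0.2)
  ev <- sim$events
  ev$rain_geometric <- ev$rain_arithmetic <- ev$rain_total <-
    ev$rain_geometric            # identical covariate across variants
  cmp <- compare_rainfall_variants(ev)
  expect_equal(diff(range(cmp$table$AIC)), 0, tolerance = 1e-6)
  for (f in cmp$fits)
    expect_equal(f$aic, 2 * f$n_par - 2 * f$loglik)
})

test_that("the geometric-mean rainfall variant wins model selection when it drives the data", {
  set.seed(17)
  wins <- 0L
  n_rep <- 40
  for (r in seq_len(n_rep)) {
    sim <- simulate_recruitment_events(30, 3, beta_gs = 0.15, beta_rain = 0.5,
                                       sd_group = 0.2)
    cmp <- compare_rainfall_variants(sim$events, nAGQ = 1)
    wins <- wins + (cmp$table$variant[1] == "geometric")
  }
  expect_gt(wins / n_rep, 0.5)
})

test_that("Welch's t-test matches the textbook formula", {
  a <- c(1, 2, 3, 4); b <- c(2, 3, 4, 5)
  res <- welch_t_test(a, b)
  se <- sqrt(var(a) / 4 + var(b) / 4)
  t_hand <- (mean(a) - mean(b)) / se
  df_hand <- se^4 / ((var(a) / 4)^2 / 3 + (var(b) / 4)^2 / 3)
  expect_equal(res$t, t_hand)      # = -1 / sqrt(5/6)
  expect_equal(res$t, -1 / sqrt(5 / 6))
  expect_equal(res$df, df_hand)    # = 6 by symmetry
  expect_equal(res$p_value, 2 * stats::pt(-abs(t_hand), df_hand))

  same <- welch_t_test(c(2, 2, 2), c(2, 2, 2))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
})

test_that("variance inflation factors follow 1 / (1 - R^2)", {
  set.seed(5)
  # orthogonal covariates -> all VIFs 1
  X <- qr.Q(qr(matrix(rnorm(300), 100, 3)))
  colnames(X) <- c("a", "b", "c")
  expect_equal(unname(vif(X)), rep(1, 3), tolerance = 1e-6)

  # known correlation 0.6 -> VIF = 1 / (1 - 0.36) = 1.5625
  n <- 2e5
  x1 <- rnorm(n); x2 <- 0.6 * x1 + sqrt(1 - 0.36) * rnorm(n)
  v <- vif(cbind(x1 = x1, x2 = x2))
  expect_equal(unname(v), rep(1.5625, 2), tolerance = 0.02)

  # duplicated covariate -> infinite VIF
  expect_true(all(is.infinite(vif(cbind(x1, x1)))))
})

test_that("the pairing contrast compares 6-monthly rates and honours exclusions", {
  set.seed(6)
  ev <- simulate_recruitment_events(16, 1, sd_group = 0.2)$events
  ev$established <- rep(c(TRUE, FALSE), each = 8)
  res <- pairing_contrast(ev)
  rate <- standardize_rate(ev$n_recruits, ev$interval_days)
  expect_equal(unname(res$new_pairs["mean"]), mean(rate[!ev$established]))
  expect_equal(unname(res$established["n"]), 8)
  # removing a group from the established stratum shrinks its n
  res2 <- pairing_contrast(ev, male_removed = ev$group_id[1])
  expect_equal(unname(res2$established["n"]), 7)
})
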