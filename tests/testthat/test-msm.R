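test_that("intensity matrices have the log-linear structure and zero row sums", {
  st <- transition_structure()
  m <- intensity_model(st, rep(log(1), 6))
  Q <- build_Q(m)
  expect_equal(Q[st$allowed], rep(1, 6))
  expect_equal(rowSums(Q), rep(0, 4), ignore_attr = TRUE)
  expect_equal(Q[4, 4], 0)            # absorbing

  # beta = 0 -> Q independent of the covariate
  m2 <- intensity_model(st, log(c(0.2, 0.1, 0.4, 0.5, 0.3, 0.15)),
                        covariate_spec = data.frame(covariate = "gs",
                                                    from = 1, to = 4),
                        beta = 0)
  expect_equal(build_Q(m2, c(gs = 2)), build_Q(m2, c(gs = -3)))

  # covariate effect multiplies the intensity by exp(beta * z)
  m3 <- intensity_model(st, log(c(0.2, 0.1, 0.4, 0.5, 0.3, 0.15)),
                        covariate_spec = data.frame(covariate = "gs",
                                                    from = 1, to = 4),
                        beta = 0.3)
  expect_equal(build_Q(m3, c(gs = 2))[1, 4], 0.5 * exp(0.6))

  set.seed(1)
  for (i in 1:10) {
    th <- rnorm(6)
    Qr <- build_Q(intensity_model(st, th))
    expect_equal(rowSums(Qr), rep(0, 4), ignore_attr = TRUE,
                 tolerance = 1e-12)
  }
})

test_that("transition probabilities match the Kolmogorov forward equations", {
  # identity at t = 0 and the two-state closed form
  Q2 <- matrix(c(-0.7, 0.7, 0, 0), 2, 2, byrow = TRUE)
  expect_equal(transition_matrix(Q2, 0), diag(2), ignore_attr = TRUE)
  expect_equal(transition_matrix(Q2, 1.3)[1, 1], exp(-0.7 * 1.3))

  # ODE oracle: dP/dt = P Q integrated numerically, 100 random 4-state Q
  library(deSolve)
  set.seed(42)
  worst <- 0
  for (i in 1:100) {
    Q <- make_random_Q()
    t1 <- stats::runif(1, 0.1, 2)
    deriv <- function(t, y, parms) list(as.vector(matrix(y, 4, 4) %*% Q))
    sol <- deSolve::ode(y = as.vector(diag(4)), times = c(0, t1), func = deriv,
                        parms = NULL, rtol = 1e-12, atol = 1e-12)
    P_ode <- matrix(sol[2, -1], 4, 4)
    P <- transition_matrix(Q, t1)
    worst <- max(worst, max(abs(P - P_ode)))
    expect_equal(rowSums(P), rep(1, 4), ignore_attr = TRUE, tolerance = 1e-10)
    expect_true(all(P >= 0 & P <= 1 + 1e-12))
  }
  expect_lt(worst, 1e-8)
})

test_that("Chapman-Kolmogorov holds and absorption saturates", {
  set.seed(7)
  for (i in 1:20) {
    Q <- make_random_Q()
    t <- stats::runif(1, 0.1, 1.5); s <- stats::runif(1, 0.1, 1.5)
    expect_equal(transition_matrix(Q, t + s),
                 transition_matrix(Q, t) %*% transition_matrix(Q, s),
                 tolerance = 1e-8)
  }
  # the absorbing column tends to 1 from every transient state
  Q <- make_random_Q()
  expect_equal(transition_matrix(Q, 200)[, 4], rep(1, 4), ignore_attr = TRUE,
               tolerance = 1e-8)
})

test_that("panel likelihood equals its definition and a fine discretisation", {
  st2 <- transition_structure(2, rbind(c(1, 2)), absorbing = 2,
                              labels = c("alive", "dead"))
  m <- intensity_model(st2, log(0.5))
  # one female, one interval: log of the single P entry
  pan <- data.frame(individual_id = "a", t = c(0, 1.2), state = c(1, 1))
  expect_equal(panel_loglik(pan, m), log(exp(-0.5 * 1.2)))
  pan2 <- data.frame(individual_id = "a", t = c(0, 1.2), state = c(1, 2))
  expect_equal(panel_loglik(pan2, m), log(1 - exp(-0.5 * 1.2)))

  # impossible transition under the structure -> -Inf
  pan_bad <- data.frame(individual_id = "a", t = c(0, 1), state = c(2, 1))
  expect_identical(panel_loglik(pan_bad, m), -Inf)

  # tiny mixed dataset vs discrete-time approximation with step 1e-4
  pan3 <- data.frame(individual_id = c("a", "a", "b", "b", "c", "c"),
                     t = c(0, 0.6, 0, 1.1, 0, 0.35),
                     state = c(1, 1, 1, 2, 1, 2))
  h <- 1e-4
  Q <- build_Q(m)
  step <- diag(2) + Q * h
  dimnames(step) <- NULL
  Pt <- function(t) {
    P <- diag(2)
    for (i in seq_len(round(t / h))) P <- P %*% step
    P
  }
  ll_disc <- log(Pt(0.6)[1, 1]) + log(Pt(1.1)[1, 2]) + log(Pt(0.35)[1, 2])
  expect_equal(panel_loglik(pan3, m), ll_disc, tolerance = 1e-3)

  # splitting an interval at an observed intermediate state of an absorbing
  # chain with one live state is likelihood-neutral (P(t+s) = P(t) P(s))
  pan4 <- data.frame(individual_id = "a", t = c(0, 0.5, 1.2), state = c(1, 1, 1))
  pan5 <- data.frame(individual_id = "a", t = c(0, 1.2), state = c(1, 1))
  expect_equal(panel_loglik(pan4, m), panel_loglik(pan5, m))
})

test_that("two-state MLE matches a one-parameter numerical MLE and closed-form survival", {
  set.seed(3)
  st2 <- transition_structure(2, rbind(c(1, 2)), absorbing = 2,
                              labels = c("alive", "dead"))
  truth <- intensity_model(st2, log(0.45))
  pan <- simulate_panels(300, truth, obs_times = seq(0, 2, by = 0.5))
  fit <- fit_msm(pan, st2)
  lambda_hat <- exp(unname(fit$par[1]))

  # independent one-parameter MLE by golden-section search on the closed form
  cl <- pan[order(pan$individual_id, pan$t), ]
  id <- cl$individual_id
  keep <- which(id[-1] == id[-nrow(cl)])
  dt <- cl$t[keep + 1] - cl$t[keep]
  died <- cl$state[keep + 1] == 2
  nll <- function(lam) -sum(ifelse(died, log(1 - exp(-lam * dt)), -lam * dt))
  opt <- stats::optimize(nll, c(1e-4, 5), tol = 1e-12)
  expect_equal(lambda_hat, opt$minimum, tolerance = 1e-6)

  # fitted one-year survival equals exp(-lambda_hat) exactly
  s1 <- survival_from_state(fit, 1, 1)$survival
  expect_equal(s1, exp(-lambda_hat), tolerance = 1e-12)
  # and truth is recovered within 3 SE on the log scale
  expect_lt(abs(fit$par[1] - log(0.45)) / sqrt(fit$vcov[1, 1]), 3)

  # initialising at the truth still converges to a maximum at least as good
  fit2 <- fit_msm(pan, st2, init = log(0.45))
  expect_gte(fit2$loglik + 1e-8, panel_loglik(pan, truth))
})

test_that("hazard ratios, intensity ratios and sojourn times follow the delta method", {
  set.seed(9)
  st <- transition_structure()
  spec <- data.frame(covariate = "gs", from = c(1, 3), to = c(4, 4))
  truth <- intensity_model(st, log(c(0.35, 0.3, 0.45, 0.44, 0.23, 0.134)),
                           covariate_spec = spec, beta = c(0.05, 0.0))
  cov <- data.frame(gs = sample(seq(-2, 2, 0.5), 500, replace = TRUE))
  pan <- simulate_panels(500, truth, obs_times = seq(0, 3, by = 0.5),
                         start_states = sample(1:3, 500, TRUE, c(.7, .15, .15)),
                         covariate_values = cov)
  fit <- fit_msm(pan, st, covariate_spec = spec)

  hr <- hazard_ratio(fit, 1, 4, "gs")
  b <- unname(fit$par["beta_gs_1.4"]); se <- sqrt(fit$vcov["beta_gs_1.4", "beta_gs_1.4"])
  expect_equal(hr$hr, exp(b))
  expect_equal(hr$lower, exp(b - 1.96 * se))
  expect_equal(hr$upper, exp(b + 1.96 * se))

  # qratio of a pair with itself is exactly 1 with a zero-width interval
  qr_same <- qratio(fit, c(1, 4), c(1, 4))
  expect_equal(qr_same$ratio, 1)
  expect_equal(qr_same$se_log, 0)

  # delta method on the log ratio, hand-computed from the fitted covariance
  qr <- qratio(fit, c(1, 4), c(2, 4))
  lr <- unname(fit$par["q_1.4"] - fit$par["q_2.4"])
  v <- fit$vcov["q_1.4", "q_1.4"] + fit$vcov["q_2.4", "q_2.4"] -
    2 * fit$vcov["q_1.4", "q_2.4"]
  expect_equal(qr$ratio, exp(lr))
  expect_equal(qr$lower, exp(lr - 1.96 * sqrt(v)))

  # sojourn: reciprocal of the total outflow at reference covariates
  so <- sojourn_time(fit, 2)
  outflow <- exp(unname(fit$par["q_2.3"])) + exp(unname(fit$par["q_2.4"]))
  expect_equal(so$mean, 1 / outflow)
  # invariant to how the outflow is split, holding the row sum fixed
  m_a <- intensity_model(st, log(c(0.3, 0.3, 0.1, 0.3, 0.4, 0.2)))
  m_b <- intensity_model(st, log(c(0.45, 0.05, 0.1, 0.4, 0.4, 0.2)))
  expect_equal(-1 / build_Q(m_a)[1, 1], -1 / build_Q(m_b)[1, 1])
})

test_that("Kaplan-Meier from panels matches the hand product-limit estimator", {
  # textbook fixture: deaths at 1 and 2, censorings at 1.5 and 3
  pan <- data.frame(
    individual_id = rep(c("a", "b", "c", "d"), each = 2),
    t = c(0, 1, 0, 2, 0, 1.5, 0, 3),
    state = c(1, 4, 1, 4, 1, 1, 1, 1))
  km <- kaplan_meier(pan, 1)
  s2 <- summary(km, times = 2)$surv
  expect_equal(s2, 0.375)
  expect_equal(s2, hand_km(c(1, 2, 1.5, 3), c(1, 1, 0, 0), 2))

  # no deaths -> flat at 1
  pan2 <- data.frame(individual_id = rep(c("a", "b"), each = 2),
                     t = c(0, 1, 0, 2), state = 1)
  km2 <- kaplan_meier(pan2, 1)
  expect_true(all(km2$surv == 1))

  # agreement with the reference product-limit on random panel data
  set.seed(5)
  st2 <- transition_structure(2, rbind(c(1, 2)), absorbing = 2)
  pan3 <- simulate_panels(120, intensity_model(st2, log(0.6)),
                          obs_times = seq(0, 3, 0.75))
  km3 <- kaplan_meier(pan3, 1, absorbing = 2)
  time <- numeric(0); status <- integer(0)
  for (id in unique(pan3$individual_id)) {
    p <- pan3[pan3$individual_id == id, ]
    hit <- which(p$state == 2)
    if (length(hit)) { time <- c(time, p$t[hit[1]]); status <- c(status, 1L) }
    else { time <- c(time, max(p$t)); status <- c(status, 0L) }
  }
  for (at in sort(unique(time[status == 1])))
    expect_equal(summary(km3, times = at)$surv, hand_km(time, status, at))

  expect_error(kaplan_meier(pan2, 3), "no individuals")
})
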