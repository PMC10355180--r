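#' Allowed-transition structure for a multi-state model
#'
#' Defines the states, the permitted instantaneous transitions and the
#' absorbing states of a continuous-time multi-state Markov model. The default
#' is the four-state female life-history model used throughout the package:
#' natal non-breeder (NB), single female (SF), breeding female (BF) and
#' disappeared/dead (GONE), with transitions NB->SF, NB->BF, SF->BF and each
#' alive state -> GONE.
#'
#' @param n_states number of states.
#' @param allowed two-column integer matrix of permitted (from, to) pairs.
#' @param absorbing integer vector of absorbing states (no outgoing pairs).
#' @param labels optional character state labels.
#' @return An object of class `msm_structure`.
#' @export
transition_structure <- function(n_states = 4L,
                                 allowed = rbind(c(1L, 2L), c(1L, 3L), c(2L, 3L),
                                                 c(1L, 4L), c(2L, 4L), c(3L, 4L)),
                                 absorbing = 4L,
                                 labels = NULL) {
  allowed <- matrix(as.integer(allowed), ncol = 2L,
                    dimnames = list(NULL, c("from", "to")))
  if (any(allowed[, 1] == allowed[, 2]))
    stop("allowed transitions must have from != to")
  if (any(allowed < 1L) || any(allowed > n_states))
    stop("allowed transitions reference states outside 1..n_states")
  if (any(allowed[, 1] %in% absorbing))
    stop("absorbing states cannot have outgoing transitions")
  if (is.null(labels)) {
    labels <- if (n_states == 4L) c("NB", "SF", "BF", "GONE")
              else paste0("S", seq_len(n_states))
  }
  structure(list(n_states = as.integer(n_states), allowed = allowed,
                 absorbing = as.integer(absorbing), labels = labels),
            class = "msm_structure")
}

#' Two-state philopatry structure (natal -> dispersed/left)
#'
#' Preset used for the time-to-dispersal analysis: state 1 = still in the
#' natal group, state 2 = has left (absorbing).
#' @return An `msm_structure` with two states.
#' @export
philopatry_structure <- function() {
  transition_structure(n_states = 2L, allowed = rbind(c(1L, 2L)),
                       absorbing = 2L, labels = c("natal", "left"))
}

pair_index <- function(structure, from, to) {
  idx <- which(structure$allowed[, 1] == from & structure$allowed[, 2] == to)
  if (length(idx) != 1L)
    stop(sprintf("transition %d->%d is not in the allowed structure", from, to))
  idx
}

#' Intensity model: baseline log-intensities plus covariate effects
#'
#' Bundles a transition structure with per-transition baseline log-intensities
#' `theta` (units log(1/time)) and log-linear covariate coefficients, so that
#' q_rs(z) = exp(theta_rs + beta_rs . z).
#'
#' @param structure an `msm_structure`.
#' @param theta numeric vector, one baseline log-intensity per allowed pair.
#' @param covariate_spec data.frame with columns `covariate`, `from`, `to`:
#'   one row per covariate coefficient (which covariate acts on which
#'   transition). May be `NULL` for a covariate-free model.
#' @param beta numeric vector of coefficients, one per `covariate_spec` row.
#' @return An object of class `msm_model`.
#' @export
intensity_model <- function(structure, theta, covariate_spec = NULL, beta = NULL) {
  stopifnot(inherits(structure, "msm_structure"))
  npair <- nrow(structure$allowed)
  if (length(theta) != npair)
    stop("theta must have one entry per allowed transition")
  if (is.null(covariate_spec)) {
    covariate_spec <- data.frame(covariate = character(0), from = integer(0),
                                 to = integer(0))
    beta <- numeric(0)
  }
  if (length(beta) != nrow(covariate_spec))
    stop("beta must have one entry per covariate_spec row")
  # validate the referenced transitions
  if (nrow(covariate_spec))
    invisible(mapply(pair_index, covariate_spec$from, covariate_spec$to,
                     MoreArgs = list(structure = structure)))
  out <- list(structure = structure, theta = as.numeric(theta),
              covariate_spec = covariate_spec, beta = as.numeric(beta),
              covariate_names = unique(as.character(covariate_spec$covariate)))
  class(out) <- "msm_model"
  out
}

# npair x ncov dense coefficient matrix from the sparse covariate spec
beta_matrix <- function(model) {
  npair <- nrow(model$structure$allowed)
  cn <- model$covariate_names
  B <- matrix(0, npair, max(1L, length(cn)))
  if (length(cn) == 0L) return(B[, 0, drop = FALSE])
  B <- matrix(0, npair, length(cn), dimnames = list(NULL, cn))
  sp <- model$covariate_spec
  for (i in seq_len(nrow(sp))) {
    p <- pair_index(model$structure, sp$from[i], sp$to[i])
    B[p, as.character(sp$covariate[i])] <- model$beta[i]
  }
  B
}

#' Build the transition intensity matrix Q(z)
#'
#' Off-diagonal entries are exp(theta + beta . z) on allowed transitions and 0
#' elsewhere; diagonal entries make each row sum to zero.
#'
#' @param model an `msm_model`.
#' @param covariates named numeric vector of covariate values (may be empty).
#' @return Square intensity matrix with state labels on the dimnames.
#' @export
build_Q <- function(model, covariates = numeric(0)) {
  st <- model$structure
  n <- st$n_states
  Q <- matrix(0, n, n, dimnames = list(st$labels, st$labels))
  B <- beta_matrix(model)
  z <- resolve_covariates(model, covariates)
  for (p in seq_len(nrow(st$allowed))) {
    lin <- model$theta[p]
    if (length(z)) lin <- lin + sum(B[p, ] * z)
    Q[st$allowed[p, 1], st$allowed[p, 2]] <- exp(lin)
  }
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q
}

resolve_covariates <- function(model, covariates) {
  cn <- model$covariate_names
  if (length(cn) == 0L) return(numeric(0))
  if (length(covariates) == 0L) return(stats::setNames(rep(0, length(cn)), cn))
  if (is.null(names(covariates)) && length(covariates) == length(cn))
    return(stats::setNames(as.numeric(covariates), cn))
  miss <- setdiff(cn, names(covariates))
  if (length(miss)) stop("missing covariate values: ", paste(miss, collapse = ", "))
  stats::setNames(as.numeric(covariates[cn]), cn)
}

#' Transition probability matrix P(t) = exp(tQ)
#'
#' @param Q a valid intensity matrix (rows sum to zero, non-negative
#'   off-diagonals).
#' @param t elapsed time, >= 0, in the time units of `Q`.
#' @return Stochastic matrix of state-to-state transition probabilities.
#' @export
transition_matrix <- function(Q, t) {
  stopifnot(is.matrix(Q), nrow(Q) == ncol(Q), t >= 0)
  P <- expm_pade(Q * t)
  if (any(!is.finite(P)))
    stop("non-finite entries in exp(tQ); t = ", t,
         ", max |Q| = ", max(abs(Q)))
  # clip tiny negative round-off
  P[P < 0 & P > -1e-12] <- 0
  dimnames(P) <- dimnames(Q)
  P
}

# ---------------------------------------------------------------------------
# Panel likelihood

# Collapse a state-panel table into transition blocks sharing (dt, covariates).
# panel: data.frame with individual_id, t (model time), state, covariate cols.
collapse_panel <- function(panel, covariate_names) {
  stopifnot(all(c("individual_id", "t", "state") %in% names(panel)))
  miss <- setdiff(covariate_names, names(panel))
  if (length(miss)) stop("panel lacks covariate columns: ",
                         paste(miss, collapse = ", "))
  panel <- panel[order(panel$individual_id, panel$t), , drop = FALSE]
  id <- panel$individual_id
  n <- nrow(panel)
  same <- id[-1] == id[-n]
  i1 <- which(same)          # left endpoint rows of consecutive pairs
  dt <- panel$t[i1 + 1L] - panel$t[i1]
  if (any(dt <= 0))
    stop("panel has non-increasing observation times within an individual")
  from <- panel$state[i1]
  to <- panel$state[i1 + 1L]
  Z <- if (length(covariate_names))
    as.matrix(panel[i1, covariate_names, drop = FALSE]) else
    matrix(0, length(i1), 0)
  if (length(covariate_names) && anyNA(Z))
    stop("missing covariate values at interval left endpoints")

  key_bz <- apply(cbind(signif(dt, 12), if (ncol(Z)) signif(Z, 12)), 1,
                  paste, collapse = "\r")
  bid <- match(key_bz, unique(key_bz))
  ub <- !duplicated(bid)
  block_dt <- dt[ub]
  block_z <- Z[ub, , drop = FALSE]

  key_row <- paste(bid, from, to, sep = "\r")
  rid <- match(key_row, unique(key_row))
  ur <- !duplicated(rid)
  list(block_dt = block_dt, block_z = block_z,
       row_block = bid[ur], row_from = from[ur], row_to = to[ur],
       row_count = as.numeric(tabulate(rid)),
       n_transitions = length(i1))
}

#' Panel-data log-likelihood of a multi-state Markov model
#'
#' Sums, over individuals and consecutive observation pairs, the log
#' transition probability of the observed state change over the elapsed time,
#' with covariates held piecewise-constant at their value at the interval's
#' left endpoint.
#'
#' @param panel state-panel data.frame with columns `individual_id`, `t`
#'   (model time, strictly increasing within individual), `state`, and any
#'   covariate columns the model uses.
#' @param model an `msm_model`.
#' @return Scalar log-likelihood (`-Inf` if any observed transition is
#'   impossible under the structure).
#' @export
panel_loglik <- function(panel, model) {
  cl <- collapse_panel(panel, model$covariate_names)
  msm_panel_loglik_cpp(model$theta, beta_matrix(model),
                       model$structure$allowed[, 1], model$structure$allowed[, 2],
                       model$structure$n_states,
                       cl$block_dt, cl$block_z,
                       cl$row_block, cl$row_from, cl$row_to, cl$row_count)
}

# Crude starting intensities: observed transition counts / aggregate time at
# risk, treating panel transitions as if exactly observed.
crude_inits <- function(panel, structure) {
  panel <- panel[order(panel$individual_id, panel$t), , drop = FALSE]
  id <- panel$individual_id
  n <- nrow(panel)
  same <- id[-1] == id[-n]
  i1 <- which(same)
  from <- panel$state[i1]; to <- panel$state[i1 + 1L]
  dt <- panel$t[i1 + 1L] - panel$t[i1]
  theta <- numeric(nrow(structure$allowed))
  for (p in seq_len(nrow(structure$allowed))) {
    r <- structure$allowed[p, 1]; s <- structure$allowed[p, 2]
    cnt <- sum(from == r & to == s)
    atrisk <- sum(dt[from == r])
    q <- (cnt + 0.5) / max(atrisk, 1e-8)
    theta[p] <- log(max(q, 1e-4))
  }
  theta
}

#' Fit a multi-state Markov model to panel data by maximum likelihood
#'
#' Maximises the panel likelihood over the unconstrained parameters
#' (baseline log-intensities `theta` and covariate coefficients `beta`) with a
#' quasi-Newton optimiser; standard errors come from the inverse of a
#' finite-difference observed information matrix.
#'
#' @param panel state-panel data.frame (see [panel_loglik()]).
#' @param structure an `msm_structure`.
#' @param covariate_spec optional data.frame (`covariate`, `from`, `to`)
#'   declaring which covariates act on which transitions.
#' @param init optional starting values `c(theta, beta)`; defaults to crude
#'   intensities from observed transition counts with `beta = 0`.
#' @param reltol relative function-convergence tolerance passed to the
#'   optimiser.
#' @param maxit maximum iterations.
#' @return An object of class `msm_fit`: the fitted `msm_model`, log-likelihood,
#'   parameter covariance matrix (or `NULL` with `se_available = FALSE` when
#'   the observed information is singular) and convergence diagnostics.
#' @export
fit_msm <- function(panel, structure, covariate_spec = NULL, init = NULL,
                    reltol = 1e-10, maxit = 500L) {
  ncov_par <- if (is.null(covariate_spec)) 0L else nrow(covariate_spec)
  model0 <- intensity_model(structure, rep(0, nrow(structure$allowed)),
                            covariate_spec, rep(0, ncov_par))
  cl <- collapse_panel(panel, model0$covariate_names)
  npair <- nrow(structure$allowed)

  # check every observed transition is permitted (possibly via intermediates):
  # a pair (r, s) is feasible iff s is reachable from r in the allowed digraph
  nst <- structure$n_states
  A <- matrix(FALSE, nst, nst)
  A[structure$allowed] <- TRUE
  reach <- A | diag(nst) > 0
  for (k in seq_len(nst)) reach <- (reach %*% reach) > 0
  bad <- !reach[cbind(cl$row_from, cl$row_to)]
  if (any(bad))
    stop("observed transition(s) impossible under the structure: ",
         paste(unique(paste0(cl$row_from[bad], "->", cl$row_to[bad])),
               collapse = ", "))

  make_model <- function(par) {
    intensity_model(structure, par[seq_len(npair)], covariate_spec,
                    if (ncov_par) par[npair + seq_len(ncov_par)] else numeric(0))
  }
  negll <- function(par) {
    m <- make_model(par)
    ll <- msm_panel_loglik_cpp(m$theta, beta_matrix(m),
                               structure$allowed[, 1], structure$allowed[, 2],
                               structure$n_states, cl$block_dt, cl$block_z,
                               cl$row_block, cl$row_from, cl$row_to, cl$row_count)
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  if (is.null(init)) init <- c(crude_inits(panel, structure), rep(0, ncov_par))
  if (length(init) != npair + ncov_par) stop("init has wrong length")

  opt <- stats::optim(init, negll, method = "BFGS",
                      control = list(reltol = reltol, maxit = maxit))
  # polish: restart once from the optimum (helps attain tight tolerances)
  opt2 <- stats::optim(opt$par, negll, method = "BFGS",
                       control = list(reltol = reltol, maxit = maxit))
  if (opt2$value <= opt$value) opt <- opt2
  if (opt$convergence != 0)
    stop("MSM optimiser failed to converge (code ", opt$convergence, "); ",
         "final negative log-likelihood ", format(opt$value))

  H <- stats::optimHess(opt$par, negll)
  vcov <- tryCatch(solve(H), error = function(e) NULL)
  se_available <- !is.null(vcov) && all(is.finite(vcov)) &&
    all(diag(vcov) >= 0)
  if (!se_available) vcov <- NULL

  model <- make_model(opt$par)
  par_names <- c(paste0("q_", structure$allowed[, 1], ".", structure$allowed[, 2]),
                 if (ncov_par) paste0("beta_", covariate_spec$covariate, "_",
                                      covariate_spec$from, ".", covariate_spec$to))
  names(opt$par) <- par_names
  if (!is.null(vcov)) dimnames(vcov) <- list(par_names, par_names)

  res <- list(model = model, par = opt$par, loglik = -opt$value,
              vcov = vcov, se_available = se_available,
              npair = npair, ncov_par = ncov_par,
              n_transitions = cl$n_transitions,
              convergence = opt$convergence, counts = opt$counts)
  class(res) <- "msm_fit"
  res
}

#' @export
print.msm_fit <- function(x, ...) {
  cat("Multi-state Markov model fit\n")
  cat(sprintf("  log-likelihood: %.4f over %d observed transitions\n",
              x$loglik, x$n_transitions))
  se <- if (x$se_available) sqrt(diag(x$vcov)) else rep(NA_real_, length(x$par))
  print(data.frame(estimate = x$par, se = se))
  invisible(x)
}

fit_se <- function(fit) {
  if (!fit$se_available) return(rep(NA_real_, length(fit$par)))
  sqrt(diag(fit$vcov))
}

#' Hazard ratio for a covariate on one transition
#'
#' Multiplicative effect of a unit covariate increase on the transition
#' intensity: exp(beta) with a Wald 95% interval exp(beta +/- 1.96 se).
#'
#' @param fit an `msm_fit`.
#' @param from,to the transition.
#' @param covariate covariate name.
#' @return List with `hr`, `lower`, `upper`, `beta`, `se` (`lower`/`upper`
#'   `NA` with `ci_available = FALSE` when standard errors are unavailable).
#' @export
hazard_ratio <- function(fit, from, to, covariate) {
  sp <- fit$model$covariate_spec
  k <- which(as.character(sp$covariate) == covariate & sp$from == from & sp$to == to)
  if (length(k) != 1L)
    stop("covariate '", covariate, "' is not attached to transition ",
         from, "->", to)
  idx <- fit$npair + k
  b <- unname(fit$par[idx])
  se <- unname(fit_se(fit)[idx])
  ci_ok <- is.finite(se)
  list(hr = exp(b),
       lower = if (ci_ok) exp(b - 1.96 * se) else NA_real_,
       upper = if (ci_ok) exp(b + 1.96 * se) else NA_real_,
       beta = b, se = se, ci_available = ci_ok)
}

#' Ratio of two transition intensities with a delta-method interval
#'
#' Computes q_a(z) / q_b(z) at reference covariate values (default 0, the
#' sample mean on the z-scored scale). The variance of the log ratio follows
#' from the delta method, var = g' V g, with g the gradient of the difference
#' of the two linear predictors with respect to the parameter vector.
#'
#' @param fit an `msm_fit`.
#' @param pair_a,pair_b length-2 integer vectors (from, to).
#' @param covariates named covariate values (default all zero).
#' @return List with `ratio`, `lower`, `upper`, `se_log`.
#' @export
qratio <- function(fit, pair_a, pair_b, covariates = numeric(0)) {
  st <- fit$model$structure
  z <- resolve_covariates(fit$model, covariates)
  lin_grad <- function(pair) {
    g <- numeric(length(fit$par))
    p <- pair_index(st, pair[1], pair[2])
    g[p] <- 1
    sp <- fit$model$covariate_spec
    if (nrow(sp)) for (k in seq_len(nrow(sp))) {
      if (sp$from[k] == pair[1] && sp$to[k] == pair[2])
        g[fit$npair + k] <- z[[as.character(sp$covariate[k])]]
    }
    g
  }
  ga <- lin_grad(pair_a); gb <- lin_grad(pair_b)
  g <- ga - gb
  logratio <- sum(g * fit$par)
  if (fit$se_available) {
    v <- drop(t(g) %*% fit$vcov %*% g)
    se <- sqrt(max(v, 0))
  } else se <- NA_real_
  list(ratio = exp(logratio),
       lower = exp(logratio - 1.96 * se),
       upper = exp(logratio + 1.96 * se),
       se_log = se)
}

#' Mean sojourn time in a transient state
#'
#' Expected time spent in a state before any transition, -1/q_rr evaluated at
#' reference covariates, with a delta-method interval on the log scale.
#'
#' @param fit an `msm_fit`.
#' @param state a non-absorbing state.
#' @param covariates named covariate values (default all zero).
#' @return List with `mean`, `lower`, `upper` in model time units.
#' @export
sojourn_time <- function(fit, state, covariates = numeric(0)) {
  st <- fit$model$structure
  if (state %in% st$absorbing) stop("state ", state, " is absorbing")
  z <- resolve_covariates(fit$model, covariates)
  out_pairs <- which(st$allowed[, 1] == state)
  if (!length(out_pairs)) stop("state ", state, " has no outgoing transitions")
  B <- beta_matrix(fit$model)
  q <- vapply(out_pairs, function(p) {
    lin <- fit$model$theta[p]
    if (length(z)) lin <- lin + sum(B[p, ] * z)
    exp(lin)
  }, numeric(1))
  total <- sum(q)
  # gradient of log(total outflow) wrt parameters
  g <- numeric(length(fit$par))
  for (j in seq_along(out_pairs)) g[out_pairs[j]] <- q[j] / total
  sp <- fit$model$covariate_spec
  if (nrow(sp)) for (k in seq_len(nrow(sp))) {
    j <- match(pair_index(st, sp$from[k], sp$to[k]), out_pairs)
    if (!is.na(j))
      g[fit$npair + k] <- z[[as.character(sp$covariate[k])]] * q[j] / total
  }
  se <- if (fit$se_available) sqrt(max(drop(t(g) %*% fit$vcov %*% g), 0)) else NA_real_
  list(mean = 1 / total,
       lower = 1 / total * exp(-1.96 * se),
       upper = 1 / total * exp(1.96 * se))
}

#' Model-based survival from a state
#'
#' Probability of not having reached the absorbing disappeared/dead state by
#' time t, starting from `state`: S_r(t) = 1 - P_(r,GONE)(t).
#'
#' @param fit an `msm_fit`.
#' @param state starting state.
#' @param times numeric vector of times (model units).
#' @param covariates named covariate values (default all zero).
#' @return data.frame with columns `time` and `survival`.
#' @export
survival_from_state <- function(fit, state, times, covariates = numeric(0)) {
  st <- fit$model$structure
  if (length(st$absorbing) != 1L)
    stop("survival_from_state requires exactly one absorbing state")
  Q <- build_Q(fit$model, covariates)
  surv <- vapply(times, function(t) {
    P <- transition_matrix(Q, t)
    unname(1 - P[state, st$absorbing])
  }, numeric(1))
  data.frame(time = times, survival = surv)
}

#' Empirical Kaplan-Meier survival from a state
#'
#' Product-limit estimate of time from first observation in `from_state` until
#' the observed transition to the absorbing state, right-censoring individuals
#' whose follow-up ends (or who move to another live state) without an
#' observed disappearance.
#'
#' @param panel state-panel data.frame (`individual_id`, `t`, `state`).
#' @param from_state the state whose survivors are followed.
#' @param absorbing the absorbing state code (default 4).
#' @return A `survfit` object (see [survival::survfit()]); its `time`,
#'   `surv` and `n.censor` components give the step function and censor marks.
#' @export
kaplan_meier <- function(panel, from_state, absorbing = 4L) {
  panel <- panel[order(panel$individual_id, panel$t), , drop = FALSE]
  ids <- unique(panel$individual_id)
  time <- numeric(0); status <- integer(0)
  for (id in ids) {
    p <- panel[panel$individual_id == id, , drop = FALSE]
    k <- which(p$state == from_state)
    if (!length(k)) next
    entry <- p$t[k[1]]
    after <- p[p$t > entry, , drop = FALSE]
    hit <- which(after$state == absorbing)
    if (length(hit)) {
      # only an event if reached straight from the focal state's run
      prior <- after$state[seq_len(hit[1] - 1L)]
      if (all(prior == from_state)) {
        time <- c(time, after$t[hit[1]] - entry); status <- c(status, 1L)
        next
      }
    }
    run_end <- c(which(after$state != from_state), nrow(after) + 1L)[1] - 1L
    last_in_state <- if (run_end >= 1L) after$t[run_end] else entry
    time <- c(time, last_in_state - entry); status <- c(status, 0L)
  }
  if (!length(time))
    stop("no individuals ever observed in state ", from_state)
  keep <- time > 0 | status == 1L
  survival::survfit(survival::Surv(time[keep], status[keep]) ~ 1)
}
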