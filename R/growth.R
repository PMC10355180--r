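#' Von Bertalanffy interval prediction
#'
#' Size at recapture after `D` days given size `S1` at capture, asymptote `A`
#' and growth rate constant `k` (per day): `A - (A - S1) * exp(-k * D)`.
#' Equals `S1` at `D = 0` and approaches `A` as `D` grows.
#'
#' @param S1 size at capture (g or mm).
#' @param A asymptotic size.
#' @param k growth rate constant (1/day).
#' @param D elapsed days (>= 0).
#' @return Predicted size at recapture.
#' @export
vb_interval <- function(S1, A, k, D) {
  stopifnot(all(D >= 0))
  A - (A - S1) * exp(-k * D)
}

# Inner Laplace step: for each individual, find the mode of the penalised
# deviations (a_i, kd_i) by damped Gauss-Newton, vectorised across
# individuals (each solve is a closed-form 2x2).
#
# Arguments are interval-level vectors plus the individual index `gi`.
# Returns the per-individual modes, the penalised objective at the mode and
# the log-determinant of the (Gauss-Newton) Hessian.
vb_inner_modes <- function(S1, S2, D, Agrp, kgrp, gi, nind,
                           sigma2, sa2, sk2, use_a, use_k,
                           max_iter = 50L, tol = 1e-11) {
  a <- numeric(nind); kd <- numeric(nind)
  pen_a <- if (use_a) 1 / sa2 else Inf
  pen_k <- if (use_k) 1 / sk2 else Inf

  obj <- function(a, kd) {
    mu <- vb_interval(S1, Agrp + a[gi], kgrp + kd[gi], D)
    rss_i <- rowsum((S2 - mu)^2, gi, reorder = TRUE)[, 1]
    rss_i / (2 * sigma2) +
      (if (use_a) a^2 / (2 * sa2) else 0) +
      (if (use_k) kd^2 / (2 * sk2) else 0)
  }
  h <- obj(a, kd)
  for (it in seq_len(max_iter)) {
    Ai <- Agrp + a[gi]; ki <- kgrp + kd[gi]
    e <- exp(-ki * D)
    mu <- Ai - (Ai - S1) * e
    r <- S2 - mu
    Ja <- 1 - e                    # d mu / d a
    Jk <- (Ai - S1) * D * e        # d mu / d kd
    # per-individual normal equations (Gauss-Newton + ridge from the prior)
    Haa <- rowsum(Ja * Ja, gi)[, 1] / sigma2 + (if (use_a) 1 / sa2 else 1)
    Hkk <- rowsum(Jk * Jk, gi)[, 1] / sigma2 + (if (use_k) 1 / sk2 else 1)
    Hak <- rowsum(Ja * Jk, gi)[, 1] / sigma2
    ga <- rowsum(r * Ja, gi)[, 1] / sigma2 - (if (use_a) a / sa2 else 0)
    gk <- rowsum(r * Jk, gi)[, 1] / sigma2 - (if (use_k) kd / sk2 else 0)
    if (!use_a) { ga <- 0 * ga; Hak <- 0 * Hak }
    if (!use_k) { gk <- 0 * gk; Hak <- 0 * Hak }
    det2 <- Haa * Hkk - Hak^2
    da <- (Hkk * ga - Hak * gk) / det2
    dk <- (Haa * gk - Hak * ga) / det2
    step <- 1
    repeat {
      h_new <- obj(a + step * da, kd + step * dk)
      if (all(h_new <= h + 1e-12) || step < 1e-6) break
      step <- step / 2
    }
    a <- a + step * da; kd <- kd + step * dk
    moved <- max(abs(step * da) / (1 + abs(Agrp[1])),
                 abs(step * dk) / (1 + abs(kgrp[1])))
    h <- obj(a, kd)
    if (moved < tol) break
  }
  # log-determinant of the per-individual Hessian at the mode
  Ai <- Agrp + a[gi]; ki <- kgrp + kd[gi]
  e <- exp(-ki * D)
  Ja <- 1 - e; Jk <- (Ai - S1) * D * e
  Haa <- rowsum(Ja * Ja, gi)[, 1] / sigma2 + (if (use_a) 1 / sa2 else 0)
  Hkk <- rowsum(Jk * Jk, gi)[, 1] / sigma2 + (if (use_k) 1 / sk2 else 0)
  Hak <- rowsum(Ja * Jk, gi)[, 1] / sigma2
  logdet <- if (use_a && use_k) log(Haa * Hkk - Hak^2)
            else if (use_a) log(Haa)
            else if (use_k) log(Hkk)
            else numeric(nind)
  list(a = a, kd = kd, h = h, logdet = logdet)
}

# Laplace-approximate marginal log-likelihood of the hierarchical vB model.
vb_marginal_loglik <- function(par, dat, with_gs, use_a, use_k) {
  p <- vb_unpack(par, with_gs, use_a, use_k)
  sigma2 <- p$sigma^2
  Agrp <- p$A + p$A_GS * dat$gs_z
  kgrp <- p$k + p$k_GS * dat$gs_z
  n <- nrow(dat)
  d <- use_a + use_k
  ni <- tabulate(dat$gi, nbins = dat$nind)

  if (d == 0L) {
    mu <- vb_interval(dat$S1, Agrp, kgrp, dat$D)
    return(sum(stats::dnorm(dat$S2, mu, p$sigma, log = TRUE)))
  }
  inner <- vb_inner_modes(dat$S1, dat$S2, dat$D, Agrp, kgrp, dat$gi, dat$nind,
                          sigma2, p$sd_a^2, p$sd_k^2, use_a, use_k)
  ll_i <- -inner$h - ni / 2 * log(2 * pi * sigma2) -
    (if (use_a) 0.5 * log(2 * pi * p$sd_a^2) else 0) -
    (if (use_k) 0.5 * log(2 * pi * p$sd_k^2) else 0) +
    d / 2 * log(2 * pi) - 0.5 * inner$logdet
  sum(ll_i)
}

vb_unpack <- function(par, with_gs, use_a, use_k) {
  i <- 0L
  nxt <- function() { i <<- i + 1L; par[i] }
  A <- nxt(); k <- exp(nxt())
  A_GS <- if (with_gs) nxt() else 0
  k_GS <- if (with_gs) nxt() else 0
  sd_a <- if (use_a) exp(nxt()) else 0
  sd_k <- if (use_k) exp(nxt()) else 0
  sigma <- exp(nxt())
  list(A = A, k = k, A_GS = A_GS, k_GS = k_GS, sd_a = sd_a, sd_k = sd_k,
       sigma = sigma)
}

vb_start <- function(intervals, with_gs, use_a, use_k) {
  A0 <- 1.05 * max(c(intervals$S1, intervals$S2))
  # k from the linearised gap decay: log(A0-S2) - log(A0-S1) = -k D
  y <- log(A0 - intervals$S2) - log(A0 - intervals$S1)
  k0 <- max(sum(-y * intervals$D) / sum(intervals$D^2), 1e-5)
  mu0 <- vb_interval(intervals$S1, A0, k0, intervals$D)
  v0 <- max(stats::var(intervals$S2 - mu0), 1e-6)
  c(A0, log(k0),
    if (with_gs) c(0, 0),
    if (use_a) 0.5 * log(0.1 * v0),
    if (use_k) log(0.1 * k0),
    0.5 * log(0.8 * v0))
}

#' Fit the hierarchical von Bertalanffy interval growth model
#'
#' Maximum marginal likelihood for the interval equation
#' `S2 = A' - (A' - S1) exp(-k' D) + e`, `e ~ N(0, sigma^2)`, where
#' `A' = A + A_GS * GS_z + a_i` and `k' = k + k_GS * GS_z + kd_i`, with
#' independent zero-mean normal individual deviations `a_i` (asymptote) and
#' `kd_i` (rate constant) integrated out by Laplace approximation
#' (per-individual damped Gauss-Newton inner optimisation). Group size is
#' z-scored internally, so `A` and `k` are the estimates at the mean group
#' size. A random-effect standard deviation collapsing to the boundary
#' (below 1e-3 of its natural scale) triggers a refit with that effect
#' dropped, recorded in `$dropped`.
#'
#' @param intervals data.frame from [build_growth_intervals()] (columns
#'   `individual_id, S1, S2, D, group_size`).
#' @param with_group_size include the `A_GS`/`k_GS` group-size terms.
#' @param random_effects character subset of `c("A", "k")`; which parameters
#'   carry individual deviations.
#' @param reltol,maxit optimiser control.
#' @return Object of class `growth_fit`: fixed effects with SEs and Wald
#'   p-values, random-effect SDs, residual SD, log-likelihood, the z-score
#'   transform used for group size, and convergence details.
#' @export
fit_growth <- function(intervals, with_group_size = FALSE,
                       random_effects = c("A", "k"),
                       reltol = 1e-10, maxit = 1000L) {
  stopifnot(all(c("individual_id", "S1", "S2", "D") %in% names(intervals)))
  if (any(intervals$S1 <= 0) || any(intervals$S2 <= 0))
    stop("sizes must be positive")
  use_a <- "A" %in% random_effects
  use_k <- "k" %in% random_effects
  gs_t <- NULL
  gs_z <- rep(0, nrow(intervals))
  if (with_group_size) {
    if (!"group_size" %in% names(intervals))
      stop("with_group_size = TRUE requires a group_size column")
    gs_t <- zscore(intervals$group_size)
    gs_z <- gs_t$values
  }
  gi <- match(intervals$individual_id, unique(intervals$individual_id))
  dat <- list(S1 = intervals$S1, S2 = intervals$S2, D = intervals$D,
              gs_z = gs_z, gi = gi, nind = max(gi))

  fit_one <- function(use_a, use_k) {
    start <- vb_start(intervals, with_group_size, use_a, use_k)
    negll <- function(par) {
      ll <- tryCatch(vb_marginal_loglik(par, dat, with_group_size, use_a, use_k),
                     error = function(e) -Inf)
      if (!is.finite(ll)) return(1e10)
      -ll
    }
    psc <- pmax(abs(start), 0.1)
    opt <- stats::optim(start, negll, method = "BFGS",
                        control = list(reltol = reltol, maxit = maxit,
                                       parscale = psc))
    opt2 <- stats::optim(opt$par, negll, method = "BFGS",
                         control = list(reltol = reltol, maxit = maxit,
                                        parscale = psc))
    if (opt2$value <= opt$value) opt <- opt2
    if (opt$convergence != 0)
      stop("growth model failed to converge (code ", opt$convergence, ")")
    H <- stats::optimHess(opt$par, negll,
                          control = list(parscale = psc,
                                         ndeps = rep(1e-4, length(psc))))
    vcov <- tryCatch(solve(H), error = function(e) NULL)
    list(opt = opt, vcov = vcov, use_a = use_a, use_k = use_k)
  }

  res <- fit_one(use_a, use_k)
  p <- vb_unpack(res$opt$par, with_group_size, res$use_a, res$use_k)
  dropped <- character(0)
  scale_a <- stats::sd(intervals$S2)
  boundary_a <- res$use_a && p$sd_a < 1e-3 * scale_a
  boundary_k <- res$use_k && p$sd_k < 1e-3 * p$k
  if (boundary_a || boundary_k) {
    dropped <- c(if (boundary_a) "A", if (boundary_k) "k")
    res <- fit_one(res$use_a && !boundary_a, res$use_k && !boundary_k)
    p <- vb_unpack(res$opt$par, with_group_size, res$use_a, res$use_k)
  }

  # fixed-effect table with delta-method SE for k (optimised as log k)
  par_names <- c("A", "log_k",
                 if (with_group_size) c("A_GS", "k_GS"),
                 if (res$use_a) "log_sd_a", if (res$use_k) "log_sd_k",
                 "log_sigma")
  se <- if (!is.null(res$vcov)) sqrt(pmax(diag(res$vcov), 0)) else
    rep(NA_real_, length(res$opt$par))
  names(se) <- par_names
  fe <- data.frame(
    term = c("A", "k", if (with_group_size) c("A_GS", "k_GS")),
    estimate = c(p$A, p$k, if (with_group_size) c(p$A_GS, p$k_GS)),
    se = c(se[["A"]], p$k * se[["log_k"]],
           if (with_group_size) c(se[["A_GS"]], se[["k_GS"]])),
    stringsAsFactors = FALSE)
  fe$z <- fe$estimate / fe$se
  fe$p_value <- 2 * stats::pnorm(-abs(fe$z))

  out <- list(fixed = fe, A = p$A, k = p$k, A_GS = p$A_GS, k_GS = p$k_GS,
              sd_a = p$sd_a, sd_k = p$sd_k, sigma = p$sigma,
              loglik = -res$opt$value, par = res$opt$par, vcov = res$vcov,
              par_names = par_names, with_group_size = with_group_size,
              random_effects = c(if (res$use_a) "A", if (res$use_k) "k"),
              dropped = dropped, gs_transform = gs_t,
              n_intervals = nrow(intervals), n_individuals = dat$nind)
  class(out) <- "growth_fit"
  out
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("Von Bertalanffy interval growth model (%d intervals, %d individuals)\n",
              x$n_intervals, x$n_individuals))
  print(x$fixed, row.names = FALSE)
  cat(sprintf("  random-effect SDs: sd_a = %.3g, sd_k = %.3g; residual sigma = %.3g\n",
              x$sd_a, x$sd_k, x$sigma))
  if (length(x$dropped))
    cat("  boundary random effect(s) dropped:", paste(x$dropped, collapse = ", "), "\n")
  cat(sprintf("  log-likelihood: %.3f\n", x$loglik))
  invisible(x)
}

#' Predicted growth trajectory with delta-method confidence band
#'
#' Population-level trajectory from a starting size `S0` at the requested
#' group size: `S(t) = A' - (A' - S0) exp(-k' t)` with
#' `A' = A + A_GS * GS_z`, `k' = k + k_GS * GS_z`. The 95% band propagates the
#' covariance of the fixed effects through the gradient of `S(t)`.
#'
#' @param fit a `growth_fit`.
#' @param S0 starting size (default 10 g, the size of a pup at parturition).
#' @param group_size group size on the raw scale (converted with the fit's
#'   stored z-score transform; ignored unless the fit includes group size).
#' @param horizon trajectory length in days.
#' @param by grid step in days.
#' @return data.frame with `day, mean, lower, upper`.
#' @export
predict_growth_curve <- function(fit, S0 = 10, group_size = NULL,
                                 horizon = 365 * 4, by = 5) {
  gs_z <- 0
  if (fit$with_group_size && !is.null(group_size))
    gs_z <- (group_size - fit$gs_transform$mean) / fit$gs_transform$sd
  Ag <- fit$A + fit$A_GS * gs_z
  kg <- fit$k + fit$k_GS * gs_z
  t <- seq(0, horizon, by = by)
  e <- exp(-kg * t)
  mean_s <- Ag - (Ag - S0) * e

  lower <- upper <- rep(NA_real_, length(t))
  if (!is.null(fit$vcov)) {
    idx <- match(c("A", "log_k",
                   if (fit$with_group_size) c("A_GS", "k_GS")),
                 fit$par_names)
    V <- fit$vcov[idx, idx, drop = FALSE]
    dS_dA <- 1 - e
    dS_dk <- (Ag - S0) * t * e
    G <- cbind(dS_dA,                 # d/dA
               dS_dk * kg)            # d/d log k (chain rule)
    if (fit$with_group_size)
      G <- cbind(G, dS_dA * gs_z, dS_dk * gs_z)
    sd_s <- sqrt(pmax(rowSums((G %*% V) * G), 0))
    lower <- mean_s - 1.96 * sd_s
    upper <- mean_s + 1.96 * sd_s
  }
  data.frame(day = t, mean = mean_s, lower = lower, upper = upper)
}
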