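#' Fit the within-group recruitment Poisson mixed model
#'
#' Number of recruits per group capture-recapture event modelled with Poisson
#' error and a log link, fixed effects of group size at first capture,
#' breeding-female body mass and rainfall (all z-scored internally), a random
#' intercept for group identity, and the logged trapping interval (scaled to
#' 182.5 days, so the intercept is the log 6-monthly rate at mean covariates)
#' as a fixed offset. Marginal likelihood by adaptive Gauss-Hermite
#' quadrature (`nAGQ` nodes; 1 = Laplace).
#'
#' @param events recruitment-event data.frame from
#'   [build_recruitment_events()] (or the synthetic generator); must contain
#'   `n_recruits`, `interval_days`, `group_id` and the covariate columns.
#' @param rainfall which rainfall covariate column to use
#'   (`"rain_geometric"`, `"rain_arithmetic"`, `"rain_total"`, or `NULL` to
#'   omit rainfall).
#' @param interaction add the group-size x rainfall interaction.
#' @param covariates character vector of further covariate columns; defaults
#'   to group size and breeding-female mass where present.
#' @param nAGQ number of adaptive Gauss-Hermite nodes (default 15; 1 =
#'   Laplace).
#' @param random fit the group random intercept (`TRUE`, default). With
#'   `FALSE` the zero-variance limit is fitted: a plain Poisson regression
#'   with the same offset and covariates.
#' @return Object of class `recruitment_fit`: coefficient table
#'   (estimate, se, z, p), random-intercept SD, log-likelihood, AIC, the
#'   underlying `glmerMod`, and the z-score transforms used.
#' @export
fit_recruitment_glmm <- function(events, rainfall = "rain_geometric",
                                 interaction = FALSE,
                                 covariates = NULL, nAGQ = 15,
                                 random = TRUE) {
  stopifnot(all(c("n_recruits", "interval_days", "group_id") %in% names(events)))
  if (is.null(covariates))
    covariates <- intersect(c("group_size_t1", "breeding_female_mass"),
                            names(events))
  terms <- covariates
  if (!is.null(rainfall)) {
    if (!rainfall %in% names(events))
      stop("rainfall column not found: ", rainfall)
    terms <- c(terms, rainfall)
  }
  d <- data.frame(n_recruits = events$n_recruits,
                  group_id = factor(events$group_id),
                  off = log(events$interval_days / 182.5))
  transforms <- list()
  for (v in terms) {
    zt <- zscore(events[[v]])
    d[[paste0(v, "_z")]] <- zt$values
    transforms[[v]] <- zt[c("mean", "sd")]
  }
  rhs <- paste0(terms, "_z")
  if (interaction) {
    if (is.null(rainfall) || !"group_size_t1" %in% covariates)
      stop("interaction requires both group size and rainfall")
    rhs <- c(rhs, paste0("group_size_t1_z:", rainfall, "_z"))
  }
  if (random) {
    form <- stats::as.formula(paste("n_recruits ~",
                                    paste(rhs, collapse = " + "),
                                    "+ offset(off) + (1 | group_id)"))
    # a singular fit (variance at the zero boundary) is an expected outcome,
    # reported through the `boundary` flag rather than a console message
    fit <- suppressMessages(
      lme4::glmer(form, data = d, family = stats::poisson(), nAGQ = nAGQ))
    sm <- summary(fit)$coefficients
    sd_group <- sqrt(unname(lme4::VarCorr(fit)$group_id[1, 1]))
    boundary <- lme4::isSingular(fit)
  } else {
    form <- stats::as.formula(paste("n_recruits ~",
                                    paste(rhs, collapse = " + "),
                                    "+ offset(off)"))
    fit <- stats::glm(form, data = d, family = stats::poisson())
    sm <- summary(fit)$coefficients
    sd_group <- 0
    boundary <- TRUE
  }
  coefs <- data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                      z = sm[, 3], p_value = sm[, 4], row.names = NULL,
                      stringsAsFactors = FALSE)
  ll <- as.numeric(stats::logLik(fit))
  npar <- attr(stats::logLik(fit), "df")
  out <- list(coefficients = coefs, sd_group = sd_group, loglik = ll,
              n_par = npar, aic = 2 * npar - 2 * ll,
              boundary = boundary, rainfall = rainfall,
              transforms = transforms, model = fit, n_events = nrow(d))
  class(out) <- "recruitment_fit"
  out
}

#' @export
print.recruitment_fit <- function(x, ...) {
  cat(sprintf("Poisson recruitment GLMM (%d events; offset log(D/182.5))\n",
              x$n_events))
  print(x$coefficients, row.names = FALSE)
  cat(sprintf("  group random-intercept SD: %.4f%s\n", x$sd_group,
              if (x$boundary) " (boundary: equals a plain Poisson GLM)" else ""))
  cat(sprintf("  logLik %.3f, AIC %.2f\n", x$loglik, x$aic))
  invisible(x)
}

#' Compare rainfall-covariate variants of the recruitment model by AIC
#'
#' Refits the recruitment GLMM with the geometric-mean, arithmetic-mean and
#' total rainfall covariates over an identical event set and tabulates AICs.
#'
#' @param events recruitment-event data.frame with all three rainfall columns.
#' @param ... passed to [fit_recruitment_glmm()].
#' @return list with `table` (data.frame sorted by AIC: variant, loglik,
#'   n_par, AIC, delta_AIC) and `fits` (the three `recruitment_fit`s).
#' @export
compare_rainfall_variants <- function(events, ...) {
  variants <- c(geometric = "rain_geometric", arithmetic = "rain_arithmetic",
                total = "rain_total")
  keep <- stats::complete.cases(events[, variants])
  events <- events[keep, , drop = FALSE]
  fits <- lapply(variants, function(v) fit_recruitment_glmm(events, rainfall = v, ...))
  tab <- data.frame(variant = names(variants),
                    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
                    n_par = vapply(fits, `[[`, numeric(1), "n_par"),
                    AIC = vapply(fits, `[[`, numeric(1), "aic"),
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$AIC), ]
  tab$delta_AIC <- tab$AIC - tab$AIC[1]
  rownames(tab) <- NULL
  list(table = tab, fits = fits)
}

#' Welch's unequal-variance t-test
#'
#' Two-sided comparison of two sample means with the Welch-Satterthwaite
#' degrees of freedom; used for the experimental new-pair versus
#' established-group recruitment contrast.
#'
#' @param sample_a,sample_b numeric vectors (each of length >= 2).
#' @return list with `t`, `df`, `p_value`, group means, and the standard
#'   error of the difference.
#' @export
welch_t_test <- function(sample_a, sample_b) {
  stopifnot(length(sample_a) >= 2, length(sample_b) >= 2)
  if (stats::sd(sample_a) == 0 && stats::sd(sample_b) == 0 &&
      mean(sample_a) == mean(sample_b)) {
    # degenerate: identical constants
    return(list(t = 0, df = length(sample_a) + length(sample_b) - 2,
                p_value = 1, mean_a = mean(sample_a), mean_b = mean(sample_b),
                se_diff = 0))
  }
  ht <- stats::t.test(sample_a, sample_b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, mean_a = mean(sample_a), mean_b = mean(sample_b),
       se_diff = unname(ht$stderr))
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` from regressing covariate `j` on the remaining
#' covariates; `Inf` for perfectly collinear columns.
#'
#' @param X numeric matrix or data.frame of covariates (no intercept column).
#' @return Named numeric vector of VIFs.
#' @export
vif <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) < 2) stop("need at least two covariates")
  if (any(apply(X, 2, stats::sd) == 0)) stop("constant covariate column")
  vapply(seq_len(ncol(X)), function(j) {
    r2 <- suppressWarnings(
      summary(stats::lm(X[, j] ~ X[, -j, drop = FALSE]))$r.squared)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1)) |> stats::setNames(colnames(X))
}

#' New-pair versus established-group recruitment contrast
#'
#' Standardises each event's recruit count to a 6-monthly rate and compares
#' experimentally created pairs with established groups by Welch's t-test.
#' Events from groups flagged as having had a male removed are excluded from
#' the established stratum.
#'
#' @param events recruitment-event data.frame with a logical `established`
#'   column (`FALSE` = experimental new pair).
#' @param male_removed optional character vector of group ids to exclude from
#'   the established stratum.
#' @return list with the Welch test (`test`), per-stratum mean +/- SEM and n.
#' @export
pairing_contrast <- function(events, male_removed = character(0)) {
  stopifnot("established" %in% names(events))
  rate <- standardize_rate(events$n_recruits, events$interval_days)
  est <- events$established & !events$group_id %in% male_removed
  new <- !events$established
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  list(test = welch_t_test(rate[new], rate[est]),
       new_pairs = c(n = sum(new), mean = mean(rate[new]), sem = sem(rate[new])),
       established = c(n = sum(est), mean = mean(rate[est]), sem = sem(rate[est])))
}
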