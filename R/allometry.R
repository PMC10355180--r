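sma_line <- function(x, y) {
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0) stop("zero variance in x or y")
  r <- stats::cor(x, y)
  slope <- sign(r) * sy / sx
  if (r == 0) slope <- sy / sx   # sign convention for exactly uncorrelated data
  c(slope = slope, intercept = mean(y) - slope * mean(x), r = r)
}

# log-likelihood of bivariate normal samples under free per-group moments
# (closed-form MLE): -n/2 * (2 log(2pi) + log det(Sigma_hat) + 2)
bvn_full_loglik <- function(x, y) {
  n <- length(x)
  S <- stats::cov(cbind(x, y)) * (n - 1) / n
  detS <- S[1, 1] * S[2, 2] - S[1, 2]^2
  -n / 2 * (2 * log(2 * pi) + log(detS) + 2)
}

bvn_loglik <- function(x, y, mx, my, sx, sy, rho) {
  dx <- (x - mx) / sx; dy <- (y - my) / sy
  q <- (dx^2 - 2 * rho * dx * dy + dy^2) / (1 - rho^2)
  sum(-log(2 * pi * sx * sy * sqrt(1 - rho^2)) - q / 2)
}

# ML fit of the common-allometry model: all groups share the SMA line
# (slope b, intercept a), i.e. sy_g = |b| sx_g and my_g = a + b * mx_g, with
# per-group mean/scale/correlation otherwise free.
common_allometry_loglik <- function(x, y, g) {
  groups <- unique(g)
  G <- length(groups)
  pooled <- sma_line(x, y)
  start <- c(pooled["intercept"], pooled["slope"],
             unlist(lapply(groups, function(gr) {
               xs <- x[g == gr]
               c(mean(xs), log(stats::sd(xs)),
                 atanh(min(max(stats::cor(x[g == gr], y[g == gr]), -0.99), 0.99)))
             })))
  negll <- function(par) {
    a <- par[1]; b <- par[2]
    if (b == 0) return(1e10)
    ll <- 0
    for (i in seq_len(G)) {
      mx <- par[2 + (i - 1) * 3 + 1]
      sx <- exp(par[2 + (i - 1) * 3 + 2])
      rho <- tanh(par[2 + (i - 1) * 3 + 3])
      ll <- ll + bvn_loglik(x[g == groups[i]], y[g == groups[i]],
                            mx, a + b * mx, sx, abs(b) * sx, rho)
    }
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  opt <- stats::optim(start, negll, method = "BFGS",
                      control = list(reltol = 1e-12, maxit = 2000))
  list(loglik = -opt$value, a = opt$par[1], b = opt$par[2],
       n_par = length(start))
}

aicc <- function(loglik, k, n) {
  -2 * loglik + 2 * k + 2 * k * (k + 1) / max(n - k - 1, 1)
}

#' Standardised major axis (SMA) allometric regression
#'
#' Fits the SMA line (slope = sign(r) * SD(y)/SD(x), treating both variables
#' symmetrically) per group and pooled over all data, with seeded percentile
#' bootstrap confidence intervals (case resampling within group). With two or
#' more groups, the common-allometry model (all groups sharing one slope and
#' intercept, fitted by bivariate-normal maximum likelihood under the SMA
#' constraints sd_y = |b| sd_x, mu_y = a + b mu_x) is compared with the
#' separate-lines model by a likelihood-ratio statistic and by
#' small-sample-corrected AIC.
#'
#' @param x,y numeric vectors (e.g. skeletal size and body mass).
#' @param group optional grouping labels.
#' @param B bootstrap resamples (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @return Object of class `sma_fit` with `lines` (per-group and common
#'   estimates with CIs) and, when >= 2 groups, `comparison` (LR statistic,
#'   df, p-value, AICc for both models and which is preferred).
#' @export
sma_fit <- function(x, y, group = NULL, B = 1000, seed = 1) {
  stopifnot(length(x) == length(y), all(is.finite(x)), all(is.finite(y)))
  if (is.null(group)) group <- rep("all", length(x))
  group <- as.character(group)
  groups <- unique(group)
  if (any(table(group) < 3)) stop("each group needs at least 3 points")

  boot_ci <- function(xx, yy, gg) {
    set.seed(seed)
    est <- replicate(B, {
      idx <- unlist(lapply(unique(gg), function(gr) {
        i <- which(gg == gr); sample(i, length(i), replace = TRUE)
      }))
      tryCatch(sma_line(xx[idx], yy[idx])[1:2], error = function(e) c(NA, NA))
    })
    apply(est, 1, stats::quantile, probs = c(0.025, 0.975), na.rm = TRUE)
  }

  rows <- list()
  for (gr in groups) {
    i <- group == gr
    ln <- sma_line(x[i], y[i])
    ci <- boot_ci(x[i], y[i], group[i])
    rows[[gr]] <- data.frame(group = gr, n = sum(i), slope = ln[["slope"]],
                             intercept = ln[["intercept"]], r = ln[["r"]],
                             slope_lo = ci[1, 1], slope_hi = ci[2, 1],
                             intercept_lo = ci[1, 2], intercept_hi = ci[2, 2],
                             stringsAsFactors = FALSE)
  }
  ln <- sma_line(x, y)
  ci <- boot_ci(x, y, group)
  rows[["(common)"]] <- data.frame(group = "(common)", n = length(x),
                                   slope = ln[["slope"]],
                                   intercept = ln[["intercept"]], r = ln[["r"]],
                                   slope_lo = ci[1, 1], slope_hi = ci[2, 1],
                                   intercept_lo = ci[1, 2], intercept_hi = ci[2, 2],
                                   stringsAsFactors = FALSE)
  lines <- do.call(rbind, rows)
  rownames(lines) <- NULL

  comparison <- NULL
  if (length(groups) >= 2) {
    ll_full <- sum(vapply(groups, function(gr)
      bvn_full_loglik(x[group == gr], y[group == gr]), numeric(1)))
    k_full <- 5 * length(groups)
    cm <- common_allometry_loglik(x, y, group)
    k_common <- cm$n_par
    lr <- 2 * (ll_full - cm$loglik)
    df <- k_full - k_common
    a_full <- aicc(ll_full, k_full, length(x))
    a_common <- aicc(cm$loglik, k_common, length(x))
    comparison <- list(lr_stat = lr, df = df,
                       p_value = stats::pchisq(max(lr, 0), df, lower.tail = FALSE),
                       aicc_separate = a_full, aicc_common = a_common,
                       preferred = if (a_common <= a_full) "common" else "separate")
  }
  out <- list(lines = lines, comparison = comparison, B = B, seed = seed)
  class(out) <- "sma_fit"
  out
}

#' @export
print.sma_fit <- function(x, ...) {
  cat("Standardised major axis regression\n")
  print(x$lines, row.names = FALSE)
  if (!is.null(x$comparison)) {
    cat(sprintf("  common vs separate allometry: LR = %.3f (df %d, p = %.3g); ",
                x$comparison$lr_stat, x$comparison$df, x$comparison$p_value))
    cat(sprintf("AICc common %.2f vs separate %.2f -> %s model preferred\n",
                x$comparison$aicc_common, x$comparison$aicc_separate,
                x$comparison$preferred))
  }
  invisible(x)
}
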