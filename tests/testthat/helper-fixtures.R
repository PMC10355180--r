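# Shared fixtures built in code.

# minimal well-formed capture table
fixture_captures <- function() {
  data.frame(
    individual_id = c("A1", "A2", "A3"),
    group_id = c("G1", "G1", "G2"),
    site = "Kuruman",
    capture_date = c("2014-01-10", "2014-01-10", "2014-01-12"),
    sex = c("F", "M", "F"),
    breeder = c(TRUE, TRUE, FALSE),
    body_mass = c(120, 150, 60),
    incisor_width = c(5.5, 6.1, 3.2),
    body_length = c(160, 175, 120),
    group_capture_complete = TRUE,
    stringsAsFactors = FALSE
  )
}

# trapping windows: four half-yearly windows at one site
fixture_windows <- function(n = 4, site = "Kuruman", start = as.Date("2014-01-01"),
                            spacing = 182, length_days = 30) {
  starts <- start + (seq_len(n) - 1) * spacing
  data.frame(site = site, window_id = sprintf("W%02d", seq_len(n)),
             start = starts, end = starts + length_days,
             stringsAsFactors = FALSE)
}

# capture rows for one female across chosen windows
female_capture_rows <- function(id, windows_idx, windows, group = "G1",
                                group_sizes = 3, breeder = FALSE, mass = 80) {
  w <- windows[windows_idx, , drop = FALSE]
  n <- nrow(w)
  group_sizes <- rep_len(group_sizes, n)
  rows <- lapply(seq_len(n), function(j) {
    # the focal female plus filler groupmates so group size is as requested
    filler <- if (group_sizes[j] > 1)
      data.frame(individual_id = sprintf("%s_mate%d", id, seq_len(group_sizes[j] - 1)),
                 group_id = group, site = w$site[j],
                 capture_date = as.character(w$start[j] + 5),
                 sex = "M", breeder = FALSE, body_mass = 120,
                 incisor_width = 5, body_length = 150,
                 group_capture_complete = TRUE, stringsAsFactors = FALSE)
    else NULL
    rbind(data.frame(individual_id = id, group_id = group, site = w$site[j],
                     capture_date = as.character(w$start[j] + 5), sex = "F",
                     breeder = rep_len(breeder, n)[j], body_mass = mass,
                     incisor_width = 4, body_length = 140,
                     group_capture_complete = TRUE, stringsAsFactors = FALSE),
          filler)
  })
  do.call(rbind, rows)
}

# hand-rolled product-limit estimator (independent oracle for Kaplan-Meier)
hand_km <- function(time, status, at) {
  ts <- sort(unique(time[status == 1]))
  s <- 1
  for (tt in ts[ts <= at]) {
    d <- sum(time == tt & status == 1)
    n_risk <- sum(time >= tt)
    s <- s * (1 - d / n_risk)
  }
  s
}

# hand-coded Poisson IRLS with log link and offset (independent GLM oracle)
hand_poisson_irls <- function(X, y, offset = 0, tol = 1e-12, maxit = 100) {
  beta <- rep(0, ncol(X))
  beta[1] <- log(mean(y)) - mean(offset)
  for (i in seq_len(maxit)) {
    eta <- drop(X %*% beta) + offset
    mu <- exp(eta)
    W <- mu
    z <- eta - offset + (y - mu) / mu
    beta_new <- solve(crossprod(X, W * X), crossprod(X, W * z))
    if (max(abs(beta_new - beta)) < tol) {
      beta <- drop(beta_new); break
    }
    beta <- drop(beta_new)
  }
  beta
}

# random intensity matrix with an absorbing final state
make_random_Q <- function(nst = 4) {
  Q <- matrix(stats::runif(nst * nst, 0.05, 1.2), nst, nst)
  Q[nst, ] <- 0                       # absorbing final state
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q
}
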