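#' Simulation configuration for the individual-based generator
#'
#' Default values define the study conditions the generator emulates: a
#' Kalahari population followed for 7 years with twice-yearly trapping
#' windows, groups founded by single dispersing females later joined by
#' males, Poisson recruitment with a log-linear group-size effect, competing
#' exponential hazards of dispersal and disappearance by state, and von
#' Bertalanffy growth from a 10 g birth mass with individual random effects.
#'
#' State intensities are per year. `theta` gives baseline log-intensities for
#' the female transitions NB->SF, NB->BF (breeding-position inheritance,
#' active only while the group lacks a breeding female), SF->BF (arrival of
#' an immigrant male) and the three disappearance hazards; `beta_gs` are
#' per-raw-individual group-size effects on the NB->GONE and BF->GONE
#' hazards.
#'
#' @param seed RNG seed; fixes the full output.
#' @param years study duration (years).
#' @param windows_per_year trapping windows per year.
#' @param window_days length of each trapping window (days).
#' @param n_initial_groups established groups at the start.
#' @param n_initial_singles single dispersed females at the start.
#' @param mean_initial_size mean size of initial established groups.
#' @param theta named log-intensities (see details).
#' @param beta_gs named group-size effects on disappearance hazards.
#' @param male_disperse,male_die,male_die_breeder,male_immigration male rates
#'   (per year).
#' @param recruit_intercept log 6-monthly recruitment rate at reference group
#'   size.
#' @param recruit_beta_gs recruitment group-size effect per standardised unit
#'   (`(gs - gs_ref) / gs_scale`).
#' @param gs_ref,gs_scale centring and scale for group size in the
#'   recruitment rate.
#' @param sex_ratio probability a recruit is female.
#' @param growth list of per-sex growth truths (`A, k, A_GS, k_GS, sd_a,
#'   sd_k, sigma`), `k` per day, `A_GS`/`k_GS` per (gs - gs_ref)/gs_scale.
#' @param birth_mass_mean,birth_mass_sd pup mass at parturition (g).
#' @param p_group_trapped probability a group is trapped in a window.
#' @param detection_p per-individual detection probability within a trapped
#'   group.
#' @param p_incomplete probability the largest non-breeder evades capture
#'   (capture flagged incomplete).
#' @param site site label.
#' @param epoch calendar date of study start.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       years = 7,
                       windows_per_year = 2,
                       window_days = 30,
                       n_initial_groups = 14,
                       n_initial_singles = 8,
                       mean_initial_size = 12,
                       theta = c(nb_sf = log(0.22), nb_bf = log(0.30),
                                 sf_bf = log(0.45),
                                 nb_gone = log(0.44), sf_gone = log(0.23),
                                 bf_gone = log(0.134)),
                       beta_gs = c(nb_gone = 0.003, bf_gone = 0.056),
                       male_disperse = 0.45, male_die = 0.25,
                       male_die_breeder = 0.14, male_immigration = 0.7,
                       recruit_intercept = log(2.3), recruit_beta_gs = 0.216,
                       gs_ref = 8, gs_scale = 5,
                       sex_ratio = 0.5,
                       growth = list(
                         F = list(A = 130, k = 0.0025, A_GS = -9, k_GS = 2e-4,
                                  sd_a = 10, sd_k = 3e-4, sigma = 6),
                         M = list(A = 152, k = 0.0025, A_GS = -8, k_GS = 2e-4,
                                  sd_a = 12, sd_k = 3e-4, sigma = 6)),
                       birth_mass_mean = 10, birth_mass_sd = 1,
                       p_group_trapped = 0.80,
                       detection_p = 1.0,
                       p_incomplete = 0.152,
                       site = "Kuruman",
                       epoch = as.Date("2013-09-01")) {
  cfg <- as.list(environment())
  stopifnot(cfg$p_group_trapped >= 0, cfg$p_group_trapped <= 1,
            cfg$detection_p >= 0, cfg$detection_p <= 1,
            cfg$p_incomplete >= 0, cfg$p_incomplete <= 1,
            all(is.finite(unlist(theta))), years > 0)
  class(cfg) <- "sim_config"
  cfg
}

#' Study-scale preset configuration
#'
#' The default configuration, calibrated so that simulated totals land near
#' the study's scale: roughly 500-1100 unique individuals over 7 years, mean
#' group size around 6 including single females, and a large fraction of
#' groups first captured as a single (predominantly female) individual.
#'
#' @param seed RNG seed.
#' @return A `sim_config`.
#' @export
study_scale_preset <- function(seed = 1) sim_config(seed = seed)

# Exact competing-exponential path of a homogeneous CTMC from start_state,
# followed until t_max or absorption. Returns jump times/states.
simulate_ctmc_path <- function(Q, start_state, t_max) {
  t <- 0; s <- start_state
  times <- numeric(0); states <- integer(0)
  repeat {
    rates <- Q[s, ]; rates[s] <- 0
    total <- sum(rates)
    if (total <= 0) break               # absorbing
    t <- t + stats::rexp(1, total)
    if (t >= t_max) break
    s <- sample.int(length(rates), 1, prob = rates)
    times <- c(times, t); states <- c(states, s)
  }
  list(times = times, states = states)
}

#' Simulate panel observations from a multi-state CTMC
#'
#' Direct generator for inference checks: each individual carries a constant
#' covariate vector, follows the continuous-time chain defined by
#' `model` exactly (competing exponentials), and is observed at the given
#' panel times. Observations after the first visit to an absorbing state are
#' dropped, matching the panel representation.
#'
#' @param n number of individuals.
#' @param model an `msm_model` (truth).
#' @param obs_times observation times (model time units), shared by all
#'   individuals.
#' @param start_states integer vector (length `n` or 1) of initial states.
#' @param covariate_values optional data.frame (`n` rows) of per-individual
#'   covariate values matching the model's covariate names.
#' @return State-panel data.frame (`individual_id, t, state`, covariates).
#' @export
simulate_panels <- function(n, model, obs_times, start_states = 1L,
                            covariate_values = NULL) {
  st <- model$structure
  start_states <- rep_len(start_states, n)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    z <- if (is.null(covariate_values)) numeric(0) else
      unlist(covariate_values[i, , drop = FALSE])
    Q <- build_Q(model, z)
    path <- simulate_ctmc_path(Q, start_states[i], max(obs_times))
    state_at <- function(t) {
      k <- sum(path$times <= t)
      if (k == 0) start_states[i] else path$states[k]
    }
    s <- vapply(obs_times, state_at, integer(1))
    absorbed <- s %in% st$absorbing
    keep <- if (any(absorbed)) seq_len(which(absorbed)[1]) else seq_along(s)
    df <- data.frame(individual_id = sprintf("I%05d", i), t = obs_times[keep],
                     state = s[keep], stringsAsFactors = FALSE)
    if (!is.null(covariate_values))
      for (v in names(covariate_values)) df[[v]] <- covariate_values[i, v]
    out[[i]] <- df
  }
  do.call(rbind, out)
}

#' Simulate growth intervals with known hierarchical truth
#'
#' Direct generator for the von Bertalanffy interval model: individuals get
#' independent normal deviations on asymptote and rate constant, group sizes
#' are drawn as integers and the group-size effects are applied on the
#' empirically z-scored scale (the same scale [fit_growth()] estimates on).
#'
#' @param n_individuals number of individuals.
#' @param n_intervals intervals per individual.
#' @param truth list with `A, k, A_GS, k_GS, sd_a, sd_k, sigma`.
#' @param gs_range integer range of group sizes.
#' @param s1_range starting-size range for the first interval.
#' @param d_range recapture-interval range in days.
#' @return list with `intervals` (data.frame ready for [fit_growth()]) and
#'   `effects` (the individual deviations actually drawn).
#' @export
simulate_growth_intervals <- function(n_individuals, n_intervals = 2,
                                      truth = list(A = 130, k = 0.006,
                                                   A_GS = -9, k_GS = 5e-4,
                                                   sd_a = 10, sd_k = 8e-4,
                                                   sigma = 8),
                                      gs_range = c(2, 16),
                                      s1_range = c(15, 80),
                                      d_range = c(90, 365)) {
  gs <- sample(seq(gs_range[1], gs_range[2]), n_individuals, replace = TRUE)
  gs_z <- (gs - mean(gs)) / stats::sd(gs)
  a <- stats::rnorm(n_individuals, 0, truth$sd_a)
  kd <- stats::rnorm(n_individuals, 0, truth$sd_k)
  rows <- vector("list", n_individuals)
  for (i in seq_len(n_individuals)) {
    Ai <- truth$A + truth$A_GS * gs_z[i] + a[i]
    ki <- truth$k + truth$k_GS * gs_z[i] + kd[i]
    S1 <- stats::runif(1, s1_range[1], s1_range[2])
    recs <- list()
    for (j in seq_len(n_intervals)) {
      D <- stats::runif(1, d_range[1], d_range[2])
      S2 <- vb_interval(S1, Ai, ki, D) + stats::rnorm(1, 0, truth$sigma)
      recs[[j]] <- data.frame(individual_id = sprintf("I%05d", i),
                              sex = "F", S1 = S1, S2 = S2, D = D,
                              group_size = gs[i], stringsAsFactors = FALSE)
      S1 <- S2
    }
    rows[[i]] <- do.call(rbind, recs)
  }
  intervals <- do.call(rbind, rows)
  list(intervals = intervals,
       effects = data.frame(individual_id = sprintf("I%05d", seq_len(n_individuals)),
                            a = a, kd = kd, gs = gs, gs_z = gs_z))
}

#' Simulate recruitment events with known Poisson-GLMM truth
#'
#' Events carry integer group sizes, breeding-female masses, simulated
#' monthly-rainfall summaries (geometric/arithmetic/total over a synthetic
#' preceding year) and Poisson recruit counts with log-linear effects applied
#' on the empirically z-scored covariate scales and exposure proportional to
#' the interval.
#'
#' @param n_groups number of groups (random-intercept levels).
#' @param events_per_group events per group.
#' @param intercept log 6-monthly recruit rate at mean covariates.
#' @param beta_gs group-size effect (per SD of group size).
#' @param beta_rain geometric-mean-rainfall effect (per SD).
#' @param sd_group SD of the group random intercept.
#' @param gs_range integer range of group sizes.
#' @return list with `events` (data.frame for [fit_recruitment_glmm()]) and
#'   `truth` (the drawn random intercepts and linear predictors).
#' @export
simulate_recruitment_events <- function(n_groups = 30, events_per_group = 3,
                                        intercept = log(2), beta_gs = 0.2,
                                        beta_rain = 0, sd_group = 0.3,
                                        gs_range = c(2, 16)) {
  n <- n_groups * events_per_group
  gid <- rep(sprintf("G%03d", seq_len(n_groups)), each = events_per_group)
  u <- stats::rnorm(n_groups, 0, sd_group)
  gs <- sample(seq(gs_range[1], gs_range[2]), n, replace = TRUE)
  bfm <- stats::rnorm(n, 150, 15)
  # synthetic preceding-year rainfall: 12 seasonal log-normal months per event
  rain <- t(vapply(seq_len(n), function(i) {
    wet <- stats::rlnorm(7, log(30), 0.8)
    dry <- stats::rlnorm(5, log(4), 1.0)
    x <- c(wet, dry)
    c(geometric = exp(mean(log(x + 0.1))) - 0.1, arithmetic = mean(x),
      total = sum(x))
  }, numeric(3)))
  D <- stats::runif(n, 100, 365)
  zs <- function(x) (x - mean(x)) / stats::sd(x)
  eta <- intercept + beta_gs * zs(gs) + beta_rain * zs(rain[, "geometric"]) +
    u[match(gid, unique(gid))] + log(D / 182.5)
  events <- data.frame(group_id = gid, interval_days = D, group_size_t1 = gs,
                       breeding_female_mass = bfm,
                       rain_geometric = rain[, "geometric"],
                       rain_arithmetic = rain[, "arithmetic"],
                       rain_total = rain[, "total"],
                       n_recruits = stats::rpois(n, exp(eta)),
                       established = TRUE, stringsAsFactors = FALSE)
  list(events = events, truth = list(u = u, eta = eta, beta_gs = beta_gs,
                                     beta_rain = beta_rain))
}

# ---------------------------------------------------------------------------
# Full individual-based population simulator

#' Simulate a capture-mark-recapture dataset with known ground truth
#'
#' Individual-based, event-time simulation of the study system: females
#' traverse the four-state life history (natal non-breeder, single female,
#' breeding female, disappeared) via competing exponential hazards with
#' group-size effects applied by thinning at events; dispersing females found
#' new singleton groups and are later joined by immigrant males; active
#' breeding groups produce recruits as a Poisson process with a log-linear
#' group-size effect; every individual grows by the von Bertalanffy law with
#' its own random asymptote and rate deviations; periodic trapping windows
#' sample groups, occasionally flagging an incomplete capture in which the
#' largest non-breeder evades. Output is bit-reproducible for a fixed seed.
#'
#' @param config a `sim_config`.
#' @return list with `captures` (capture-record data.frame in the reader's
#'   schema), `windows`, `rainfall`, `truth` (female state-change times,
#'   growth random effects, birth log) and `config`.
#' @export
simulate_population <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cfg <- config
  th <- exp(cfg$theta)

  # --- population state ------------------------------------------------------
  ind <- new.env()
  ind$n <- 0L
  cols <- c("sex", "grp_a", "grp_a_from", "grp_b", "grp_b_from", "birth",
            "m0", "A_mass", "k_mass", "A_inc", "k_inc",
            "t_sf", "t_bf", "t_gone", "t_breeder", "breeder", "alive",
            "in_pop")
  for (nm in cols) ind[[nm]] <- c()
  next_group <- 1L

  new_group <- function() {
    g <- sprintf("G%03d", next_group)
    next_group <<- next_group + 1L
    g
  }
  add_individual <- function(sex, group, birth, t_now, breeder = FALSE,
                             state = 1L, gs_at_entry = cfg$gs_ref) {
    force(gs_at_entry)      # evaluate before the state vectors are touched
    ind$n <- ind$n + 1L
    gr <- cfg$growth[[sex]]
    gz <- (gs_at_entry - cfg$gs_ref) / cfg$gs_scale
    ind$sex <- c(ind$sex, sex)
    ind$grp_a <- c(ind$grp_a, group)
    ind$grp_a_from <- c(ind$grp_a_from, max(birth, t_now))
    ind$grp_b <- c(ind$grp_b, NA_character_)
    ind$grp_b_from <- c(ind$grp_b_from, NA_real_)
    ind$birth <- c(ind$birth, birth)
    ind$m0 <- c(ind$m0, max(stats::rnorm(1, cfg$birth_mass_mean,
                                         cfg$birth_mass_sd), 5))
    ind$A_mass <- c(ind$A_mass,
                    gr$A + gr$A_GS * gz + stats::rnorm(1, 0, gr$sd_a))
    ind$k_mass <- c(ind$k_mass,
                    max(gr$k + gr$k_GS * gz + stats::rnorm(1, 0, gr$sd_k),
                        5e-4))
    ind$A_inc <- c(ind$A_inc, 6.5 + 0.012 * (ind$A_mass[ind$n] - 130) +
                     stats::rnorm(1, 0, 0.25))
    ind$k_inc <- c(ind$k_inc, ind$k_mass[ind$n] * 1.3)
    ind$t_sf <- c(ind$t_sf, if (state >= 2L) t_now else Inf)
    ind$t_bf <- c(ind$t_bf, if (state >= 3L) t_now else Inf)
    ind$t_gone <- c(ind$t_gone, Inf)
    ind$t_breeder <- c(ind$t_breeder, if (breeder) max(birth, t_now) else Inf)
    ind$breeder <- c(ind$breeder, breeder)
    ind$alive <- c(ind$alive, TRUE)
    ind$in_pop <- c(ind$in_pop, TRUE)
    ind$n
  }
  current_group <- function(i) {
    ifelse(!is.na(ind$grp_b[i]), ind$grp_b[i], ind$grp_a[i])
  }
  group_members <- function(g) which(ind$alive & ind$in_pop &
                                       current_group(seq_len(ind$n)) == g)
  remove_from_pop <- function(i, t_now, gone = TRUE) {
    ind$alive[i] <- FALSE
    ind$in_pop[i] <- FALSE
    if (gone) ind$t_gone[i] <- t_now
  }
  # an arriving breeding male is a real dispersing natal male when one is
  # available (so male natal departures are observable); otherwise an
  # unknown immigrant from outside the study area is created
  recruit_breeding_male <- function(g, t_now, gs_target) {
    cand <- which(ind$alive & ind$in_pop & ind$sex == "M" & !ind$breeder &
                    is.na(ind$grp_b) & ind$birth <= t_now - 1.5)
    cand <- cand[current_group(cand) != g]
    if (length(cand)) {
      m <- if (length(cand) == 1) cand else sample(cand, 1)
      old <- current_group(m)
      ind$grp_b[m] <- g
      ind$grp_b_from[m] <- t_now
      ind$breeder[m] <- TRUE
      ind$t_breeder[m] <- t_now
      check_singleton(old, t_now)
    } else {
      add_individual("M", g, birth = t_now - stats::runif(1, 2, 4),
                     t_now = t_now, breeder = TRUE, gs_at_entry = gs_target)
    }
  }
  # group collapse rule: a lone surviving non-breeding female becomes single
  check_singleton <- function(g, t_now) {
    m <- group_members(g)
    if (length(m) == 1 && ind$sex[m] == "F" && !ind$breeder[m] &&
        !is.finite(ind$t_sf[m]))
      ind$t_sf[m] <- t_now
  }

  # --- initial population ----------------------------------------------------
  births <- list()
  for (gidx in seq_len(cfg$n_initial_groups)) {
    g <- new_group()
    size <- max(2, stats::rpois(1, cfg$mean_initial_size))
    bf_age <- stats::runif(1, 3, 6)
    add_individual("F", g, birth = -bf_age, t_now = 0, breeder = TRUE,
                   state = 3L, gs_at_entry = size)
    add_individual("M", g, birth = -stats::runif(1, 3, 6), t_now = 0,
                   breeder = TRUE, gs_at_entry = size)
    for (j in seq_len(max(size - 2, 0))) {
      sex <- if (stats::runif(1) < cfg$sex_ratio) "F" else "M"
      add_individual(sex, g, birth = -stats::runif(1, 0.3, 2.5), t_now = 0,
                     gs_at_entry = size)
    }
  }
  for (s in seq_len(cfg$n_initial_singles)) {
    g <- new_group()
    add_individual("F", g, birth = -stats::runif(1, 1.5, 4), t_now = 0,
                   state = 2L, gs_at_entry = 1)
  }

  # --- event-time dynamics ---------------------------------------------------
  # Gillespie-style exact simulation: all hazards are constant between events
  # (they depend only on state and current group size), so the next event is
  # exponential with the summed rate and chosen proportionally.
  t_now <- 0
  repeat {
    idx <- which(ind$alive & ind$in_pop)
    if (!length(idx)) break
    grp <- current_group(idx)
    gs <- as.numeric(table(grp)[grp])
    sexF <- ind$sex[idx] == "F"
    state <- ifelse(ind$t_bf[idx] <= t_now, 3L,
                    ifelse(ind$t_sf[idx] <= t_now, 2L, 1L))
    bf_by_g <- tapply(ind$breeder[idx] & sexF, grp, any)
    m_by_g <- tapply(!sexF, grp, any)
    n_by_g <- tapply(rep(1, length(idx)), grp, sum)
    has_bf <- as.logical(bf_by_g[grp])

    r_disperse <- ifelse(sexF & state == 1L, th[["nb_sf"]],
                         ifelse(!sexF & !ind$breeder[idx],
                                cfg$male_disperse, 0))
    r_inherit <- ifelse(sexF & state == 1L & !has_bf, th[["nb_bf"]], 0)
    r_joined <- ifelse(sexF & state == 2L, th[["sf_bf"]], 0)
    r_gone <- ifelse(sexF,
                     ifelse(state == 1L,
                            th[["nb_gone"]] *
                              exp(cfg$beta_gs[["nb_gone"]] * gs),
                            ifelse(state == 2L, th[["sf_gone"]],
                                   th[["bf_gone"]] *
                                     exp(cfg$beta_gs[["bf_gone"]] * gs))),
                     ifelse(ind$breeder[idx], cfg$male_die_breeder,
                            cfg$male_die))
    ch_id <- rep(idx, 4L)
    ch_type <- rep(c("disperse", "inherit", "joined", "gone"),
                   each = length(idx))
    ch_rate <- c(r_disperse, r_inherit, r_joined, r_gone)

    ug <- names(n_by_g)
    active <- as.logical(bf_by_g) & as.logical(m_by_g)
    maleless <- as.logical(bf_by_g) & !as.logical(m_by_g)
    g_rate <- ifelse(active,
                     2 * exp(cfg$recruit_intercept + cfg$recruit_beta_gs *
                               (as.numeric(n_by_g) - cfg$gs_ref) / cfg$gs_scale),
                     ifelse(maleless, cfg$male_immigration, 0))
    ch_id <- c(ch_id, -seq_along(ug))
    ch_type <- c(ch_type, ifelse(active, "recruit", "male_immigration"))
    ch_rate <- c(ch_rate, g_rate)

    keep <- ch_rate > 0
    ch_id <- ch_id[keep]; ch_type <- ch_type[keep]; ch_rate <- ch_rate[keep]
    total <- sum(ch_rate)
    if (total <= 0) break
    t_now <- t_now + stats::rexp(1, total)
    if (t_now >= cfg$years) break
    k <- sample.int(length(ch_rate), 1, prob = ch_rate)
    type <- ch_type[k]
    if (ch_id[k] > 0) {
      i <- ch_id[k]; g <- current_group(i)
      if (type == "gone") {
        remove_from_pop(i, t_now)
        check_singleton(g, t_now)
      } else if (type == "disperse" && ind$sex[i] == "F") {
        ind$grp_b[i] <- new_group(); ind$grp_b_from[i] <- t_now
        ind$t_sf[i] <- t_now
        check_singleton(g, t_now)
      } else if (type == "disperse") {      # male leaves the study population
        remove_from_pop(i, t_now, gone = TRUE)
        check_singleton(g, t_now)
      } else if (type == "inherit") {
        ind$breeder[i] <- TRUE; ind$t_bf[i] <- t_now
        ind$t_breeder[i] <- t_now
      } else if (type == "joined") {
        ind$breeder[i] <- TRUE; ind$t_bf[i] <- t_now
        ind$t_breeder[i] <- t_now
        recruit_breeding_male(current_group(i), t_now, gs_target = 2)
      }
    } else {
      g <- ug[-ch_id[k]]
      if (type == "recruit") {
        sex <- if (stats::runif(1) < cfg$sex_ratio) "F" else "M"
        i <- add_individual(sex, g, birth = t_now, t_now = t_now,
                            gs_at_entry = length(group_members(g)) + 1)
        births[[length(births) + 1L]] <-
          data.frame(individual_id = sprintf("I%05d", i), group_id = g,
                     birth_year = t_now, sex = sex, stringsAsFactors = FALSE)
      } else {                              # male immigration
        recruit_breeding_male(g, t_now,
                              gs_target = length(group_members(g)) + 1)
      }
    }
  }

  # --- trapping windows and captures ----------------------------------------
  n_windows <- floor(cfg$years * cfg$windows_per_year)
  win_start <- (seq_len(n_windows) - 1) / cfg$windows_per_year
  windows <- data.frame(site = cfg$site,
                        window_id = sprintf("W%02d", seq_len(n_windows)),
                        start = cfg$epoch + round(win_start * 365.25),
                        end = cfg$epoch + round(win_start * 365.25) +
                          cfg$window_days, stringsAsFactors = FALSE)

  mass_at <- function(i, t) {
    age_d <- (t - ind$birth[i]) * 365.25
    vb_interval(ind$m0[i], ind$A_mass[i], ind$k_mass[i], age_d)
  }
  inc_at <- function(i, t) {
    age_d <- (t - ind$birth[i]) * 365.25
    vb_interval(2, ind$A_inc[i], ind$k_inc[i], age_d)
  }
  member_at <- function(t) {
    # group membership and presence at continuous time t: present from entry
    # into the population until disappearance
    present <- ind$grp_a_from <= t & ind$t_gone > t
    grp <- ifelse(!is.na(ind$grp_b) & ind$grp_b_from <= t, ind$grp_b, ind$grp_a)
    list(present = present, grp = grp)
  }

  caps <- list()
  cap_states <- list()
  for (w in seq_len(n_windows)) {
    t_w <- win_start[w]
    mm <- member_at(t_w + 1e-9)
    for (g in unique(mm$grp[mm$present])) {
      if (stats::runif(1) > cfg$p_group_trapped) next
      day_off <- stats::runif(1, 0, cfg$window_days - 1)
      t_cap <- t_w + day_off / 365.25
      mc <- member_at(t_cap)
      members <- which(mc$present & mc$grp == g)
      if (!length(members)) next
      detected <- members[stats::runif(length(members)) <= cfg$detection_p]
      if (!length(detected)) next
      incomplete <- FALSE
      nb <- detected[!ind$breeder[detected]]
      if (length(nb) >= 1 && stats::runif(1) < cfg$p_incomplete) {
        masses <- vapply(nb, mass_at, numeric(1), t = t_cap)
        detected <- setdiff(detected, nb[which.max(masses)])
        incomplete <- TRUE
      }
      if (!length(detected)) next
      date <- cfg$epoch + round(t_cap * 365.25)
      mass_true <- vapply(detected, mass_at, numeric(1), t = t_cap)
      fdet <- detected[ind$sex[detected] == "F"]
      if (length(fdet))
        cap_states[[length(cap_states) + 1L]] <- data.frame(
          individual_id = sprintf("I%05d", fdet), date = date,
          state = ifelse(ind$t_bf[fdet] <= t_cap, 3L,
                         ifelse(ind$t_sf[fdet] <= t_cap, 2L, 1L)),
          stringsAsFactors = FALSE)
      caps[[length(caps) + 1L]] <- data.frame(
        individual_id = sprintf("I%05d", detected),
        group_id = g, site = cfg$site, capture_date = date,
        sex = ind$sex[detected],
        breeder = ifelse(ind$sex[detected] == "F",
                         ind$t_bf[detected] <= t_cap,
                         ind$t_breeder[detected] <= t_cap),
        body_mass = round(pmax(
          mass_true + stats::rnorm(length(detected), 0,
                                   cfg$growth[["F"]]$sigma), 4)),
        incisor_width = round(pmax(
          vapply(detected, inc_at, numeric(1), t = t_cap) +
            stats::rnorm(length(detected), 0, 0.15), 0.5), 2),
        body_length = round(pmax(
          34 * mass_true^(1 / 3) + stats::rnorm(length(detected), 0, 3), 30)),
        group_capture_complete = !incomplete,
        stringsAsFactors = FALSE)
    }
  }
  captures <- do.call(rbind, caps)
  captures <- captures[order(captures$individual_id, captures$capture_date), ]
  rownames(captures) <- NULL

  # --- rainfall --------------------------------------------------------------
  yr0 <- as.integer(format(cfg$epoch, "%Y")) - 1L
  yrs <- yr0:(yr0 + ceiling(cfg$years) + 1L)
  rainfall <- expand.grid(month = 1:12, year = yrs)[, c("year", "month")]
  wet <- rainfall$month %in% c(10:12, 1:4)
  rainfall$rainfall_mm <- round(ifelse(
    wet, stats::rlnorm(nrow(rainfall), log(30), 0.8),
    stats::rlnorm(nrow(rainfall), log(4), 1.0)), 1)

  truth <- list(
    female_states = data.frame(
      individual_id = sprintf("I%05d", seq_len(ind$n)),
      sex = ind$sex, t_sf = ind$t_sf, t_bf = ind$t_bf, t_gone = ind$t_gone,
      stringsAsFactors = FALSE),
    growth_effects = data.frame(
      individual_id = sprintf("I%05d", seq_len(ind$n)), sex = ind$sex,
      A = ind$A_mass, k = ind$k_mass, m0 = ind$m0, birth_year = ind$birth,
      stringsAsFactors = FALSE),
    births = if (length(births)) do.call(rbind, births) else
      data.frame(individual_id = character(0), group_id = character(0),
                 birth_year = numeric(0), sex = character(0)),
    capture_states = do.call(rbind, cap_states),
    epoch = cfg$epoch)
  list(captures = captures, windows = windows, rainfall = rainfall,
       truth = truth, config = cfg)
}

#' True life-history state of a simulated female at a date
#'
#' @param truth the `truth` element of [simulate_population()] output.
#' @param individual_id female id.
#' @param date calendar date.
#' @return Integer state (1 NB, 2 SF, 3 BF, 4 GONE).
#' @export
truth_state_at <- function(truth, individual_id, date) {
  r <- truth$female_states[truth$female_states$individual_id == individual_id, ]
  if (nrow(r) != 1) stop("unknown individual: ", individual_id)
  t <- as.numeric(as.Date(date) - truth$epoch) / 365.25
  if (r$t_gone <= t) 4L
  else if (r$t_bf <= t) 3L
  else if (r$t_sf <= t) 2L
  else 1L
}
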