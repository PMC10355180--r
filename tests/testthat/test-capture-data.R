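test_that("capture tables read, validate and round-trip", {
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(fixture_captures(), path, row.names = FALSE)
  rec <- read_captures(path)
  expect_equal(nrow(rec), 3)
  expect_s3_class(rec$capture_date, "Date")

  # missing column -> schema error
  broken <- fixture_captures(); broken$sex <- NULL
  utils::write.csv(broken, path, row.names = FALSE)
  expect_error(read_captures(path), "missing required column")

  # unparseable date -> row rejected with its line number
  bad <- fixture_captures(); bad$capture_date[2] <- "not-a-date"
  utils::write.csv(bad, path, row.names = FALSE)
  expect_warning(rec2 <- read_captures(path), "line 3")
  expect_equal(nrow(rec2), 2)

  # duplicated (individual, date) -> dedup with warning
  dup <- rbind(fixture_captures(), fixture_captures()[1, ])
  utils::write.csv(dup, path, row.names = FALSE)
  expect_warning(rec3 <- read_captures(path), "deduplicated")
  expect_equal(nrow(rec3), 3)

  # simulator output round-trips losslessly through write/read
  sim <- simulate_population(sim_config(seed = 3, years = 2,
                                        n_initial_groups = 4,
                                        n_initial_singles = 2))
  write_captures(sim$captures, path)
  back <- read_captures(path)
  attr(back, "diagnostics") <- NULL
  expected <- sim$captures[order(sim$captures$individual_id,
                                 sim$captures$capture_date), ]
  rownames(expected) <- NULL
  expect_equal(back, expected)
})

test_that("female state assignment follows the disappearance and censoring rules", {
  w <- fixture_windows(4)
  # captured in windows 1 and 2 in her natal group, unseen in 3 and 4:
  # panel gains a disappeared row at the start of window 3
  rec <- validate_captures(female_capture_rows("F1", 1:2, w, group_sizes = 3))
  pan <- assign_female_states(rec, w)
  f1 <- pan[pan$individual_id == "F1", ]
  expect_equal(f1$state, c(1L, 1L, 4L))
  expect_equal(f1$t_days[1], 0)
  expect_equal(f1$date[3], w$start[3])
  expect_equal(f1$kind, c("capture", "capture", "gone"))

  # captured once, alone, in the final window: right-censored same-state row
  # at the window's end (<= 80 days later)
  rec2 <- validate_captures(female_capture_rows("F2", 4, w, group_sizes = 1))
  pan2 <- assign_female_states(rec2, w)
  f2 <- pan2[pan2$individual_id == "F2", ]
  expect_equal(f2$state, c(2L, 2L))
  expect_equal(f2$kind[2], "censor")
  expect_lte(f2$t_days[2], 80)

  # a breeder is state 3 even in her natal group (inheritance pooling)
  rec3 <- validate_captures(female_capture_rows("F3", 1:2, w, group_sizes = 4,
                                                breeder = c(FALSE, TRUE)))
  pan3 <- assign_female_states(rec3, w)
  expect_equal(pan3$state[pan3$individual_id == "F3" &
                            pan3$kind == "capture"], c(1L, 3L))

  # unseen for only one window -> no disappearance row
  rec4 <- validate_captures(female_capture_rows("F4", 1:3, w, group_sizes = 3))
  pan4 <- assign_female_states(rec4, w)
  expect_false(any(pan4$state[pan4$individual_id == "F4"] == 4L))
})

test_that("appended rows only follow >=2 fully missed windows and censors stay short", {
  sim <- simulate_population(sim_config(seed = 11, years = 4,
                                        p_incomplete = 0))
  pan <- assign_female_states(sim$captures, sim$windows)
  gone <- pan[pan$kind == "gone", ]
  wst <- sim$windows$start
  for (i in seq_len(nrow(gone))) {
    prior <- pan[pan$individual_id == gone$individual_id[i] &
                   pan$kind == "capture", ]
    last_cap <- max(prior$date)
    # at least two window starts between last capture and study end
    expect_gte(sum(wst > last_cap), 2)
    # the gone row sits at the first window start after the last capture
    expect_equal(gone$date[i], min(wst[wst > last_cap]))
  }
  cens <- pan[pan$kind == "censor", ]
  if (nrow(cens)) {
    caps <- pan[pan$kind == "capture", ]
    last <- tapply(caps$t_days, caps$individual_id, max)
    expect_true(all(cens$t_days - last[cens$individual_id] <= 80))
  }
})

test_that("new-individual classification uses strict sex-specific mass cutoffs", {
  cur <- data.frame(individual_id = c("old", "m95", "f85", "m100", "f79"),
                    sex = c("M", "M", "F", "M", "F"),
                    body_mass = c(150, 95, 85, 100, 79),
                    stringsAsFactors = FALSE)
  res <- classify_new_individuals("old", cur)
  det <- res$detail
  expect_equal(det$class[det$individual_id == "m95"], "recruit")
  expect_equal(det$class[det$individual_id == "f85"], "immigrant")
  expect_equal(det$class[det$individual_id == "m100"], "immigrant") # tie
  expect_equal(det$class[det$individual_id == "f79"], "recruit")
  expect_equal(res$recruits + res$immigrants, 4)

  cur$body_mass[2] <- NA
  expect_error(classify_new_individuals("old", cur), "missing body mass")
  expect_equal(classify_new_individuals("old", cur,
                                        missing_mass = "immigrant")$immigrants, 3)
})

test_that("recruitment event construction applies the interval and residency filters", {
  mk <- function(date, ids, sexes, masses, breeders, complete = TRUE) {
    data.frame(individual_id = ids, group_id = "G1", site = "Kuruman",
               capture_date = as.Date(date), sex = sexes, breeder = breeders,
               body_mass = masses, incisor_width = 4, body_length = 140,
               group_capture_complete = complete, stringsAsFactors = FALSE)
  }
  base1 <- mk("2014-01-01", c("bf", "bm"), c("F", "M"), c(140, 150),
              c(TRUE, FALSE))
  # D = 80 days: excluded
  rec <- rbind(base1, mk("2014-03-22", c("bf", "bm"), c("F", "M"),
                         c(140, 152), c(TRUE, FALSE)))
  ev <- build_recruitment_events(rec, NULL)
  expect_equal(nrow(ev), 0)
  expect_equal(attr(ev, "diagnostics")$interval, 1)

  # valid 200-day pair with one recruit and one immigrant
  rec2 <- rbind(base1, mk("2014-07-20", c("bf", "bm", "kid", "imm"),
                          c("F", "M", "M", "F"), c(140, 152, 40, 95),
                          c(TRUE, FALSE, FALSE, FALSE)))
  ev2 <- build_recruitment_events(rec2, NULL)
  expect_equal(nrow(ev2), 1)
  expect_equal(ev2$n_recruits, 1)
  expect_equal(ev2$n_immigrants, 1)
  expect_equal(ev2$group_size_t1, 2)

  # breeding female changes between captures: excluded
  rec3 <- rbind(base1, mk("2014-07-20", c("bf2", "bm"), c("F", "M"),
                          c(130, 152), c(TRUE, FALSE)))
  ev3 <- build_recruitment_events(rec3, NULL)
  expect_equal(nrow(ev3), 0)
  expect_equal(attr(ev3, "diagnostics")$breeding_female, 1)

  # no large male retained: excluded
  rec4 <- rbind(mk("2014-01-01", c("bf", "m2"), c("F", "M"), c(140, 60),
                   c(TRUE, FALSE)),
                mk("2014-07-20", c("bf", "m2"), c("F", "M"), c(140, 70),
                   c(TRUE, FALSE)))
  ev4 <- build_recruitment_events(rec4, NULL)
  expect_equal(nrow(ev4), 0)

  # incomplete group capture: excluded
  rec5 <- rbind(base1, mk("2014-07-20", c("bf", "bm"), c("F", "M"),
                          c(140, 152), c(TRUE, FALSE), complete = FALSE))
  ev5 <- build_recruitment_events(rec5, NULL)
  expect_equal(nrow(ev5), 0)
})

test_that("recruit plus immigrant counts equal the number of new individuals", {
  sim <- simulate_population(sim_config(seed = 21, years = 4, p_incomplete = 0))
  ev <- build_recruitment_events(sim$captures, NULL, missing_mass = "immigrant")
  expect_gt(nrow(ev), 5)
  for (i in seq_len(nrow(ev))) {
    m1 <- sim$captures[sim$captures$group_id == ev$group_id[i] &
                         sim$captures$capture_date == ev$t1[i], ]
    m2 <- sim$captures[sim$captures$group_id == ev$group_id[i] &
                         sim$captures$capture_date == ev$t2[i], ]
    n_new <- sum(!m2$individual_id %in% m1$individual_id)
    expect_equal(ev$n_recruits[i] + ev$n_immigrants[i], n_new)
  }
})

test_that("rate standardisation and rainfall summaries follow their definitions", {
  expect_equal(standardize_rate(4, 365), 2)
  expect_equal(standardize_rate(0, 123), 0)
  expect_equal(standardize_rate(3, 182.5), 3)
  # linear in count, inverse-linear in interval
  expect_equal(standardize_rate(6, 100), 3 * standardize_rate(2, 100))
  expect_equal(standardize_rate(2, 200), standardize_rate(2, 100) / 2)

  rain <- expand.grid(month = 1:12, year = 2013:2014)[, c("year", "month")]
  rain$rainfall_mm <- 10
  expect_equal(rainfall_covariate(rain, "2014-06-15", "geometric"), 10)
  # alternating 1 and 100: geometric mean 10, arithmetic 50.5 (offset-free check)
  rain$rainfall_mm <- rep(c(1, 100), 12)
  g <- rainfall_covariate(rain, "2014-06-15", "geometric", offset = 0)
  expect_equal(g, 10, tolerance = 1e-12)
  expect_equal(rainfall_covariate(rain, "2014-06-15", "arithmetic"), 50.5)
  expect_equal(rainfall_covariate(rain, "2014-06-15", "total"), 606)
  # zero months defined through the offset
  rain$rainfall_mm[3] <- 0
  d <- 0.1
  idx <- rain$year == 2013 & rain$month %in% 6:12 | rain$year == 2014 & rain$month %in% 1:5
  x <- rain$rainfall_mm[idx]
  expect_equal(rainfall_covariate(rain, "2014-06-15", "geometric", offset = d),
               exp(mean(log(x + d))) - d)
  # insufficient coverage errors
  expect_error(rainfall_covariate(rain[rain$year == 2014, ], "2014-06-15"),
               "coverage")
})

test_that("z-scoring is invertible and idempotent in distribution", {
  z <- zscore(c(1, 2, 3))
  expect_equal(z$values, c(-1, 0, 1))
  x <- rnorm(50, 7, 3)
  z2 <- zscore(x)
  expect_equal(mean(z2$values), 0, tolerance = 1e-12)
  expect_equal(sd(z2$values), 1, tolerance = 1e-12)
  expect_equal(unzscore(z2), x)
  z3 <- zscore(z2$values)
  expect_equal(z3$values, z2$values)
  expect_error(zscore(rep(2, 5)), "constant")
})

test_that("growth intervals respect interval bounds and the breeder exclusion", {
  w <- fixture_windows(4)
  rec <- validate_captures(female_capture_rows("F1", 1:4, w, group_sizes = 3,
                                               breeder = c(FALSE, FALSE, TRUE, TRUE),
                                               mass = 60))
  gi <- build_growth_intervals(rec, "body_mass")
  # only the window1 -> window2 interval survives (breeder from window 3 on)
  expect_equal(nrow(gi[gi$individual_id == "F1", ]), 1)
  expect_equal(gi$D[gi$individual_id == "F1"], 182)
  # incisor intervals are not filtered by breeding status
  gi2 <- build_growth_intervals(rec, "incisor_width")
  expect_equal(nrow(gi2[gi2$individual_id == "F1", ]), 3)
})
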