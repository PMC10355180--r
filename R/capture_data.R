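#' @useDynLib moleratdemog, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

DAYS_PER_YEAR <- 365.25
HALF_YEAR_DAYS <- 182.5

capture_columns <- c("individual_id", "group_id", "site", "capture_date",
                     "sex", "breeder", "body_mass", "incisor_width",
                     "body_length", "group_capture_complete")

#' Read and validate a capture table
#'
#' Reads one-row-per-individual-per-capture records from CSV, parses dates,
#' coerces types and rejects rows that violate basic invariants (unparseable
#' date, non-positive body mass, unknown sex). Duplicated
#' (individual, date) rows are dropped with a warning.
#'
#' @param path CSV file with a header row containing the columns
#'   `individual_id, group_id, site, capture_date, sex, breeder, body_mass,
#'   incisor_width, body_length, group_capture_complete`.
#' @return data.frame of validated capture records, sorted by individual and
#'   date, with a `diagnostics` attribute listing rejected row numbers and
#'   the deduplication report.
#' @export
read_captures <- function(path) {
  if (!file.exists(path)) stop("capture file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(capture_columns, names(raw))
  if (length(miss))
    stop("capture table is missing required column(s): ",
         paste(miss, collapse = ", "))
  validate_captures(raw)
}

#' Validate an in-memory capture table
#'
#' Same checks as [read_captures()] for records already in a data.frame
#' (e.g. emitted by [simulate_population()]).
#' @param raw data.frame with the capture columns.
#' @return Validated, ordered capture data.frame with diagnostics attribute.
#' @export
validate_captures <- function(raw) {
  n <- nrow(raw)
  line <- seq_len(n) + 1L   # header is line 1
  date <- as.Date(as.character(raw$capture_date), format = "%Y-%m-%d")
  bad_date <- is.na(date) & !is.na(raw$capture_date)
  mass <- suppressWarnings(as.numeric(raw$body_mass))
  bad_mass <- !is.na(mass) & mass <= 0
  sex <- as.character(raw$sex)
  bad_sex <- !sex %in% c("F", "M")
  reject <- bad_date | bad_mass | bad_sex
  if (any(reject)) {
    why <- ifelse(bad_date, "unparseable date",
                  ifelse(bad_sex, "sex not F/M", "non-positive body mass"))
    warning(sum(reject), " capture row(s) rejected: ",
            paste(sprintf("line %d (%s)", line[reject], why[reject]),
                  collapse = "; "))
  }
  rec <- data.frame(
    individual_id = as.character(raw$individual_id),
    group_id = as.character(raw$group_id),
    site = as.character(raw$site),
    capture_date = date,
    sex = sex,
    breeder = as.logical(raw$breeder),
    body_mass = mass,
    incisor_width = suppressWarnings(as.numeric(raw$incisor_width)),
    body_length = suppressWarnings(as.numeric(raw$body_length)),
    group_capture_complete = as.logical(raw$group_capture_complete),
    stringsAsFactors = FALSE
  )[!reject, , drop = FALSE]
  dup <- duplicated(rec[, c("individual_id", "capture_date")])
  if (any(dup))
    warning("deduplicated ", sum(dup), " repeated (individual, date) row(s)")
  rec <- rec[!dup, , drop = FALSE]
  # at most one breeding female per group capture
  bf <- rec[rec$breeder & rec$sex == "F", , drop = FALSE]
  if (nrow(bf)) {
    multi <- duplicated(bf[, c("group_id", "capture_date")])
    if (any(multi))
      warning("group capture(s) with >1 flagged breeding female: ",
              paste(unique(paste(bf$group_id[multi], bf$capture_date[multi])),
                    collapse = "; "))
  }
  rec <- rec[order(rec$individual_id, rec$capture_date), , drop = FALSE]
  rownames(rec) <- NULL
  attr(rec, "diagnostics") <- list(n_input = n, n_rejected = sum(reject),
                                   rejected_lines = line[reject],
                                   n_deduplicated = sum(dup))
  rec
}

#' Write a capture table to CSV
#'
#' Inverse of [read_captures()]; a written table re-reads losslessly.
#' @param records capture data.frame.
#' @param path output CSV path.
#' @export
write_captures <- function(records, path) {
  out <- records[, capture_columns]
  out$capture_date <- format(out$capture_date, "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read trapping-window definitions
#'
#' @param path CSV with columns `site, window_id, start, end`.
#' @return data.frame with parsed dates, checked for ordering and
#'   non-overlap within site.
#' @export
read_windows <- function(path) {
  w <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("site", "window_id", "start", "end"), names(w))
  if (length(miss)) stop("window table missing column(s): ",
                         paste(miss, collapse = ", "))
  w$start <- as.Date(w$start); w$end <- as.Date(w$end)
  validate_windows(w)
}

validate_windows <- function(w) {
  if (any(is.na(w$start)) || any(is.na(w$end)))
    stop("unparseable window dates")
  if (any(w$end < w$start)) stop("window end precedes start")
  w <- w[order(w$site, w$start), , drop = FALSE]
  for (s in unique(w$site)) {
    ws <- w[w$site == s, , drop = FALSE]
    if (nrow(ws) > 1 && any(ws$start[-1] <= ws$end[-nrow(ws)]))
      stop("overlapping trapping windows at site ", s)
  }
  rownames(w) <- NULL
  w
}

#' Read monthly rainfall totals
#'
#' @param path CSV with columns `year, month, rainfall_mm`.
#' @return data.frame of monthly totals.
#' @export
read_rainfall <- function(path) {
  r <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("year", "month", "rainfall_mm"), names(r))
  if (length(miss)) stop("rainfall table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(r$rainfall_mm < 0)) stop("negative rainfall totals")
  r
}

# Group sizes per group capture: individuals actually caught, optionally +1
# for incomplete captures (sensitivity switch for the known evader).
group_capture_sizes <- function(records, incomplete_add_one = FALSE) {
  key <- paste(records$group_id, records$capture_date)
  size <- as.numeric(table(key)[key])
  if (incomplete_add_one)
    size <- size + ifelse(records$group_capture_complete, 0, 1)
  size
}

#' Assign life-history states to female capture histories
#'
#' Maps each female capture to one of the live states -- natal non-breeder
#' (1), single female (2), breeding female (3) -- and appends the
#' disappearance and censoring rows that make the panel suitable for the
#' multi-state model:
#' * a female flagged as a breeder is state 3 wherever she breeds (females
#'   inheriting the breeding position in their natal group are pooled with
#'   those that acquired it elsewhere);
#' * a female caught alone in her group is a single female (state 2);
#' * otherwise a female in her natal group (the group of her first capture,
#'   unless overridden) is state 1;
#' * if a female is unseen for at least two consecutive trapping windows at
#'   her site, a disappeared/dead row (state 4) is appended at the start of
#'   the first window following her last capture;
#' * if she was captured within her site's final window she is assumed alive
#'   to that window's end and a same-state row is appended there
#'   (right-censoring of at most the window length, ~80 days).
#'
#' @param records validated capture data.frame.
#' @param windows trapping-window data.frame (`site, window_id, start, end`).
#' @param natal optional named character vector mapping individual_id to natal
#'   group_id; defaults to the group of first capture.
#' @param incomplete_add_one add 1 to group size for incomplete captures.
#' @return data.frame (one row per panel observation) with columns
#'   `individual_id, t` (years since first capture), `t_days`, `state`,
#'   `group_size`, `body_mass`, `date`, `kind`
#'   (`"capture"`, `"gone"` or `"censor"`). Attribute `diagnostics` counts
#'   non-breeding females observed outside their natal group.
#' @export
assign_female_states <- function(records, windows, natal = NULL,
                                 incomplete_add_one = FALSE) {
  windows <- validate_windows(windows)
  records <- records[order(records$individual_id, records$capture_date), ,
                     drop = FALSE]
  records$group_size <- group_capture_sizes(records, incomplete_add_one)
  females <- records[records$sex == "F", , drop = FALSE]
  if (!nrow(females)) stop("no female capture records")

  # every capture must fall inside some declared window at its site
  in_window <- mapply(function(s, d) {
    any(windows$site == s & windows$start <= d & windows$end >= d)
  }, females$site, females$capture_date)
  if (!all(in_window))
    stop(sum(!in_window), " female capture(s) fall outside all declared ",
         "trapping windows at their site")

  nonnatal_nonbreeder <- 0L
  out <- vector("list", length(unique(females$individual_id)))
  ids <- unique(females$individual_id)
  for (i in seq_along(ids)) {
    f <- females[females$individual_id == ids[i], , drop = FALSE]
    natal_group <- if (!is.null(natal) && ids[i] %in% names(natal))
      natal[[ids[i]]] else f$group_id[1]
    state <- integer(nrow(f))
    for (j in seq_len(nrow(f))) {
      if (isTRUE(f$breeder[j])) state[j] <- 3L
      else if (f$group_size[j] == 1) state[j] <- 2L
      else {
        state[j] <- 1L
        if (f$group_id[j] != natal_group)
          nonnatal_nonbreeder <- nonnatal_nonbreeder + 1L
      }
    }
    # forbid reverse transitions in the representation: a female seen as SF or
    # BF is never NB afterwards; demote earlier conflicts is not allowed, so
    # carry the furthest state forward
    state <- cummax(state)

    t0 <- f$capture_date[1]
    t_days <- as.numeric(f$capture_date - t0)
    df <- data.frame(individual_id = ids[i], t_days = t_days, state = state,
                     group_size = f$group_size, body_mass = f$body_mass,
                     date = f$capture_date, kind = "capture",
                     stringsAsFactors = FALSE)

    site <- f$site[nrow(f)]
    last_date <- f$capture_date[nrow(f)]
    wsite <- windows[windows$site == site, , drop = FALSE]
    following <- wsite[wsite$start > last_date, , drop = FALSE]
    if (nrow(following) >= 2) {
      df <- rbind(df, data.frame(
        individual_id = ids[i],
        t_days = as.numeric(following$start[1] - t0),
        state = 4L, group_size = f$group_size[nrow(f)],
        body_mass = f$body_mass[nrow(f)], date = following$start[1],
        kind = "gone", stringsAsFactors = FALSE))
    } else {
      final_w <- wsite[nrow(wsite), , drop = FALSE]
      if (nrow(final_w) && last_date >= final_w$start && last_date <= final_w$end &&
          final_w$end > last_date) {
        df <- rbind(df, data.frame(
          individual_id = ids[i],
          t_days = as.numeric(final_w$end - t0),
          state = state[nrow(f)], group_size = f$group_size[nrow(f)],
          body_mass = f$body_mass[nrow(f)], date = final_w$end,
          kind = "censor", stringsAsFactors = FALSE))
      }
    }
    df$t <- df$t_days / DAYS_PER_YEAR
    out[[i]] <- df
  }
  panel <- do.call(rbind, out)
  panel <- panel[, c("individual_id", "t", "t_days", "state", "group_size",
                     "body_mass", "date", "kind")]
  rownames(panel) <- NULL
  attr(panel, "diagnostics") <-
    list(n_females = length(ids),
         nonnatal_nonbreeder_captures = nonnatal_nonbreeder)
  panel
}

#' Classify new group members as recruits or immigrants
#'
#' An individual present at the second capture of a group but absent at the
#' first is a recruit (assumed born in the group) if its body mass is
#' strictly below the sex-specific cutoff, otherwise an immigrant. Cutoffs
#' default to 100 g for males and 80 g for females; ties go to immigrant.
#'
#' @param previous_members character vector of individual ids at the first
#'   capture.
#' @param current_capture data.frame with `individual_id`, `sex`, `body_mass`
#'   for the second capture.
#' @param cutoffs named numeric vector `c(M = 100, F = 80)` in grams.
#' @param missing_mass policy for new individuals with missing mass:
#'   `"error"` (default), `"immigrant"` or `"drop"`.
#' @return list with counts `recruits`, `immigrants` and a `detail`
#'   data.frame of the new individuals and their classification.
#' @export
classify_new_individuals <- function(previous_members, current_capture,
                                     cutoffs = c(M = 100, F = 80),
                                     missing_mass = c("error", "immigrant", "drop")) {
  missing_mass <- match.arg(missing_mass)
  new <- current_capture[!current_capture$individual_id %in% previous_members, ,
                         drop = FALSE]
  if (!nrow(new))
    return(list(recruits = 0L, immigrants = 0L,
                detail = data.frame(individual_id = character(0),
                                    class = character(0))))
  nomass <- is.na(new$body_mass)
  if (any(nomass)) {
    if (missing_mass == "error")
      stop("new individual(s) with missing body mass: ",
           paste(new$individual_id[nomass], collapse = ", "))
    if (missing_mass == "drop") new <- new[!nomass, , drop = FALSE]
  }
  cut <- cutoffs[new$sex]
  cls <- ifelse(is.na(new$body_mass), "immigrant",
                ifelse(new$body_mass < cut, "recruit", "immigrant"))
  list(recruits = sum(cls == "recruit"), immigrants = sum(cls == "immigrant"),
       detail = data.frame(individual_id = new$individual_id, sex = new$sex,
                           body_mass = new$body_mass, class = cls,
                           stringsAsFactors = FALSE))
}

#' Build group-level recruitment events from capture histories
#'
#' Pairs consecutive captures of each group and keeps pairs that represent an
#' active breeding group observed over a usable interval:
#' * 100 <= interval <= 365 days;
#' * the same breeding female resident at both captures;
#' * at least one large male (>= `large_male_mass` g) retained across both;
#' * both group captures complete.
#' New individuals at the second capture are split into recruits and
#' immigrants by [classify_new_individuals()], and the rainfall covariates
#' over the 12 calendar months preceding the first capture are attached.
#'
#' @param records validated capture data.frame.
#' @param rainfall monthly rainfall data.frame (`year, month, rainfall_mm`),
#'   or `NULL` to skip rainfall covariates.
#' @param min_interval,max_interval interval bounds in days.
#' @param large_male_mass threshold (g) defining a "large" male.
#' @param cutoffs recruit mass cutoffs, see [classify_new_individuals()].
#' @param missing_mass policy passed to [classify_new_individuals()].
#' @param rain_offset offset added to zero-rain months for the geometric mean.
#' @return data.frame of recruitment events (`group_id, t1, t2,
#'   interval_days, group_size_t1, breeding_female_mass, rain_geometric,
#'   rain_arithmetic, rain_total, n_recruits, n_immigrants, n_new`), with a
#'   `diagnostics` attribute recording how many pairs each filter removed.
#' @export
build_recruitment_events <- function(records, rainfall = NULL,
                                     min_interval = 100, max_interval = 365,
                                     large_male_mass = 100,
                                     cutoffs = c(M = 100, F = 80),
                                     missing_mass = "error",
                                     rain_offset = 0.1) {
  key <- paste(records$group_id, records$capture_date)
  caps <- records[!duplicated(key), c("group_id", "capture_date",
                                      "group_capture_complete")]
  caps <- caps[order(caps$group_id, caps$capture_date), , drop = FALSE]
  drops <- c(interval = 0L, incomplete = 0L, breeding_female = 0L,
             large_male = 0L, rainfall = 0L)
  events <- list()
  for (g in unique(caps$group_id)) {
    cg <- caps[caps$group_id == g, , drop = FALSE]
    if (nrow(cg) < 2) next
    for (j in seq_len(nrow(cg) - 1L)) {
      d1 <- cg$capture_date[j]; d2 <- cg$capture_date[j + 1L]
      D <- as.numeric(d2 - d1)
      if (D < min_interval || D > max_interval) {
        drops["interval"] <- drops["interval"] + 1L; next
      }
      m1 <- records[records$group_id == g & records$capture_date == d1, ,
                    drop = FALSE]
      m2 <- records[records$group_id == g & records$capture_date == d2, ,
                    drop = FALSE]
      if (!all(m1$group_capture_complete) || !all(m2$group_capture_complete)) {
        drops["incomplete"] <- drops["incomplete"] + 1L; next
      }
      bf1 <- m1$individual_id[m1$breeder & m1$sex == "F"]
      bf2 <- m2$individual_id[m2$breeder & m2$sex == "F"]
      if (length(bf1) != 1L || length(bf2) != 1L || bf1 != bf2) {
        drops["breeding_female"] <- drops["breeding_female"] + 1L; next
      }
      lm1 <- m1$individual_id[m1$sex == "M" & !is.na(m1$body_mass) &
                                m1$body_mass >= large_male_mass]
      lm2 <- m2$individual_id[m2$sex == "M" & !is.na(m2$body_mass) &
                                m2$body_mass >= large_male_mass]
      if (!length(intersect(lm1, lm2))) {
        drops["large_male"] <- drops["large_male"] + 1L; next
      }
      rain <- c(geometric = NA_real_, arithmetic = NA_real_, total = NA_real_)
      if (!is.null(rainfall)) {
        rain <- tryCatch(
          c(geometric = rainfall_covariate(rainfall, d1, "geometric",
                                           offset = rain_offset),
            arithmetic = rainfall_covariate(rainfall, d1, "arithmetic"),
            total = rainfall_covariate(rainfall, d1, "total")),
          error = function(e) NULL)
        if (is.null(rain)) {
          drops["rainfall"] <- drops["rainfall"] + 1L
          warning("event dropped (group ", g, ", ", d1,
                  "): incomplete rainfall coverage")
          next
        }
      }
      cls <- classify_new_individuals(m1$individual_id, m2,
                                      cutoffs = cutoffs,
                                      missing_mass = missing_mass)
      events[[length(events) + 1L]] <- data.frame(
        group_id = g, t1 = d1, t2 = d2, interval_days = D,
        group_size_t1 = nrow(m1),
        breeding_female_mass = m1$body_mass[m1$individual_id == bf1],
        rain_geometric = rain[["geometric"]],
        rain_arithmetic = rain[["arithmetic"]],
        rain_total = rain[["total"]],
        n_recruits = cls$recruits, n_immigrants = cls$immigrants,
        n_new = cls$recruits + cls$immigrants,
        stringsAsFactors = FALSE)
    }
  }
  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(group_id = character(0), t1 = as.Date(character(0)),
               t2 = as.Date(character(0)), interval_days = numeric(0),
               group_size_t1 = numeric(0), breeding_female_mass = numeric(0),
               rain_geometric = numeric(0), rain_arithmetic = numeric(0),
               rain_total = numeric(0), n_recruits = integer(0),
               n_immigrants = integer(0), n_new = integer(0))
  rownames(ev) <- NULL
  attr(ev, "diagnostics") <- as.list(drops)
  ev
}

#' Standardise a count to a 6-monthly rate
#'
#' @param count number of events (e.g. recruits) over the interval.
#' @param interval_days interval length in days (> 0).
#' @return `count * 182.5 / interval_days`.
#' @export
standardize_rate <- function(count, interval_days) {
  stopifnot(all(interval_days > 0))
  count * HALF_YEAR_DAYS / interval_days
}

#' Rainfall covariate over the preceding year
#'
#' Summarises monthly rainfall over the 12 whole calendar months before the
#' month of `reference_date`. The geometric mean adds `offset` mm to each
#' month before logging (so zero-rain months are defined) and subtracts it
#' from the result.
#'
#' @param monthly data.frame with `year, month, rainfall_mm`.
#' @param reference_date the date anchoring the preceding year.
#' @param kind `"geometric"`, `"arithmetic"` or `"total"`.
#' @param offset zero-rain offset (mm) for the geometric mean.
#' @return Rainfall summary in mm (mm/month for the means).
#' @export
rainfall_covariate <- function(monthly, reference_date,
                               kind = c("geometric", "arithmetic", "total"),
                               offset = 0.1) {
  kind <- match.arg(kind)
  ref <- as.POSIXlt(as.Date(reference_date))
  # 12 whole calendar months before the capture month
  months <- (ref$year + 1900) * 12L + ref$mon - seq_len(12L)  # 0-based index
  yr <- months %/% 12L; mo <- months %% 12L + 1L
  idx <- match(paste(yr, mo), paste(monthly$year, monthly$month))
  if (anyNA(idx))
    stop("rainfall coverage incomplete for the 12 months before ",
         as.Date(reference_date))
  x <- monthly$rainfall_mm[idx]
  switch(kind,
         geometric = exp(mean(log(x + offset))) - offset,
         arithmetic = mean(x),
         total = sum(x))
}

#' z-score a numeric vector, retaining the transform
#'
#' @param values numeric vector with at least two distinct values.
#' @return list of class `zscore` with `values` (standardised), `mean`, `sd`.
#' @export
zscore <- function(values) {
  if (length(unique(values[!is.na(values)])) < 2)
    stop("cannot z-score a constant (or empty) vector")
  m <- mean(values, na.rm = TRUE); s <- stats::sd(values, na.rm = TRUE)
  out <- list(values = (values - m) / s, mean = m, sd = s)
  class(out) <- "zscore"
  out
}

#' Invert a z-score transform
#' @param z a `zscore` object.
#' @param values standardised values (defaults to those stored in `z`).
#' @return Values on the original scale.
#' @export
unzscore <- function(z, values = z$values) values * z$sd + z$mean

#' Build growth intervals from repeat captures
#'
#' Pairs successive captures of each non-breeding individual where the chosen
#' trait was measured at both ends and the recapture interval is 90-365 days.
#' For female body mass, records from the first known breeding capture onward
#' are excluded (removing status/pregnancy effects).
#'
#' @param records validated capture data.frame.
#' @param trait `"body_mass"` or `"incisor_width"`.
#' @param min_days,max_days recapture-interval bounds in days.
#' @param incomplete_add_one add 1 to group size for incomplete captures.
#' @return data.frame with `individual_id, sex, S1, S2, D, group_size`
#'   (group size at the interval's first capture).
#' @export
build_growth_intervals <- function(records, trait = c("body_mass", "incisor_width"),
                                   min_days = 90, max_days = 365,
                                   incomplete_add_one = FALSE) {
  trait <- match.arg(trait)
  records <- records[order(records$individual_id, records$capture_date), ,
                     drop = FALSE]
  records$group_size <- group_capture_sizes(records, incomplete_add_one)
  out <- list()
  for (id in unique(records$individual_id)) {
    r <- records[records$individual_id == id, , drop = FALSE]
    if (trait == "body_mass" && r$sex[1] == "F" && any(r$breeder, na.rm = TRUE)) {
      first_breeder <- min(which(r$breeder))
      r <- r[seq_len(first_breeder - 1L), , drop = FALSE]
    }
    r <- r[!is.na(r[[trait]]), , drop = FALSE]
    if (nrow(r) < 2) next
    for (j in seq_len(nrow(r) - 1L)) {
      D <- as.numeric(r$capture_date[j + 1L] - r$capture_date[j])
      if (D < min_days || D > max_days) next
      out[[length(out) + 1L]] <- data.frame(
        individual_id = id, sex = r$sex[1],
        S1 = r[[trait]][j], S2 = r[[trait]][j + 1L], D = D,
        group_size = r$group_size[j], stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(individual_id = character(0), sex = character(0),
               S1 = numeric(0), S2 = numeric(0), D = numeric(0),
               group_size = numeric(0))
  rownames(res) <- NULL
  res
}
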