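#' Re-run the four field analyses on a deposited dataset
#'
#' Convenience driver for reproducing the published field results once the
#' deposited capture data have been obtained (they are distributed separately
#' from this package, at https://github.com/JThor1990/DMR_GroupSizeEffects)
#' and mapped to the package's input schema. `data_dir` must contain
#' `captures.csv`, `windows.csv` and `rainfall.csv` as documented in
#' [read_captures()], [read_windows()] and [read_rainfall()].
#'
#' @param data_dir directory holding the three input CSVs.
#' @param new_pair_groups character vector of group ids for experimentally
#'   created pairs (for the pairing contrast); may be empty.
#' @param male_removed group ids excluded from the established stratum.
#' @return list with the descriptive group-size summaries, the four-state
#'   survivorship fit and its derived ratios/survival, the two-state
#'   philopatry fits by sex, the recruitment GLMM with rainfall-variant AIC
#'   table, the growth fits by sex, and the allometry comparison.
#' @export
reproduce_field_analysis <- function(data_dir,
                                     new_pair_groups = character(0),
                                     male_removed = character(0)) {
  paths <- file.path(data_dir, c("captures.csv", "windows.csv", "rainfall.csv"))
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("deposited field data not found: ", paste(missing, collapse = ", "),
         "\nDownload the deposited dataset and map it to the package schema ",
         "before calling reproduce_field_analysis().")
  captures <- read_captures(paths[1])
  windows <- read_windows(paths[2])
  rainfall <- read_rainfall(paths[3])
  run_study_pipeline(captures, windows, rainfall,
                     new_pair_groups = new_pair_groups,
                     male_removed = male_removed)
}

#' Run the full study pipeline on in-memory capture data
#'
#' Executes every analysis stage on a validated capture table: descriptive
#' group-size summaries, the four-state female survivorship model with a
#' group-size covariate on the non-breeder and breeder disappearance
#' hazards, the two-state philopatry (time to leaving the natal group) model
#' by sex, the recruitment GLMM with the rainfall-variant comparison and the
#' pairing contrast, sex-specific growth fits, and the single- versus
#' in-group female allometry comparison.
#'
#' @param captures validated capture data.frame.
#' @param windows trapping windows.
#' @param rainfall monthly rainfall.
#' @param new_pair_groups,male_removed see [reproduce_field_analysis()].
#' @param growth_trait trait for the growth fits.
#' @param sma_B bootstrap resamples for the allometry fit.
#' @param seed seed for the bootstrap.
#' @return Nested list of results; see [reproduce_field_analysis()].
#' @export
run_study_pipeline <- function(captures, windows, rainfall,
                               new_pair_groups = character(0),
                               male_removed = character(0),
                               growth_trait = "body_mass",
                               sma_B = 1000, seed = 1) {
  key <- paste(captures$group_id, captures$capture_date)
  sizes <- table(key)
  descriptive <- list(
    n_individuals = length(unique(captures$individual_id)),
    n_group_captures = length(sizes),
    mean_group_size = mean(sizes),
    mean_group_size_excl_singles = mean(sizes[sizes > 1]))

  # --- state-structured survivorship -----------------------------------------
  panel <- assign_female_states(captures, windows)
  panel$gs_z <- (panel$group_size - mean(panel$group_size)) /
    stats::sd(panel$group_size)
  spec <- data.frame(covariate = "gs_z", from = c(1, 3), to = c(4, 4))
  msm_fit <- fit_msm(panel, transition_structure(), covariate_spec = spec)
  survivorship <- list(
    fit = msm_fit,
    qratio_nb_sf = qratio(msm_fit, c(1, 4), c(2, 4)),
    qratio_nb_bf = qratio(msm_fit, c(1, 4), c(3, 4)),
    qratio_sf_bf = qratio(msm_fit, c(2, 4), c(3, 4)),
    annual_survival = vapply(1:3, function(s)
      survival_from_state(msm_fit, s, 1)$survival, numeric(1)),
    hr_gs_nb = hazard_ratio(msm_fit, 1, 4, "gs_z"),
    hr_gs_bf = hazard_ratio(msm_fit, 3, 4, "gs_z"))

  # --- philopatry: two-state time to leaving the natal group, by sex ---------
  philopatry <- lapply(c(F = "F", M = "M"), function(sx) {
    p <- natal_departure_panel(captures, windows, sex = sx)
    fit <- fit_msm(p, philopatry_structure())
    list(fit = fit, sojourn = sojourn_time(fit, 1))
  })
  # sex hazard ratio from the pooled two-state model with a sex covariate
  p_all <- rbind(natal_departure_panel(captures, windows, "F"),
                 natal_departure_panel(captures, windows, "M"))
  fit_sex <- fit_msm(p_all, philopatry_structure(),
                     covariate_spec = data.frame(covariate = "male",
                                                 from = 1, to = 2))
  philopatry$sex_hazard_ratio <- hazard_ratio(fit_sex, 1, 2, "male")

  # --- recruitment -----------------------------------------------------------
  events <- build_recruitment_events(captures, rainfall,
                                     missing_mass = "immigrant")
  events$established <- !events$group_id %in% new_pair_groups
  recruit <- list(
    fit = fit_recruitment_glmm(events),
    variants = compare_rainfall_variants(events),
    interaction = fit_recruitment_glmm(events, interaction = TRUE),
    mean_rate_6mo = mean(standardize_rate(events$n_recruits,
                                          events$interval_days)))
  if (any(!events$established) && sum(events$established) >= 2)
    recruit$pairing <- pairing_contrast(events, male_removed = male_removed)

  # --- growth ----------------------------------------------------------------
  intervals <- build_growth_intervals(captures, growth_trait)
  growth <- lapply(c(F = "F", M = "M"), function(sx) {
    iv <- intervals[intervals$sex == sx, , drop = FALSE]
    fit_growth(iv, with_group_size = TRUE)
  })

  # --- allometry: single vs in-group non-breeding females --------------------
  fem <- captures[captures$sex == "F" & !captures$breeder &
                    !is.na(captures$incisor_width) &
                    !is.na(captures$body_mass), , drop = FALSE]
  fem$group_size <- group_capture_sizes(fem)
  cls <- ifelse(fem$group_size == 1, "single", "ingroup")
  allometry <- if (min(table(cls)) >= 3)
    sma_fit(fem$incisor_width, fem$body_mass, group = cls, B = sma_B,
            seed = seed) else NULL

  list(descriptive = descriptive, survivorship = survivorship,
       philopatry = philopatry, recruitment = recruit, growth = growth,
       allometry = allometry)
}

# Two-state panel: time from first capture in the natal group until the
# individual is no longer there -- first observation outside it (dispersed:
# new group or alone) or, failing that, the disappearance row implied by two
# fully missed trapping windows. Individuals still being caught in their
# natal group at the end are right-censored at their last capture there.
natal_departure_panel <- function(captures, windows, sex) {
  captures$group_size <- group_capture_sizes(captures)
  recs <- captures[captures$sex == sex, , drop = FALSE]
  recs <- recs[order(recs$individual_id, recs$capture_date), , drop = FALSE]
  windows <- validate_windows(windows)
  out <- list()
  for (id in unique(recs$individual_id)) {
    r <- recs[recs$individual_id == id, , drop = FALSE]
    # philopatry concerns individuals first caught as residents of a group:
    # those first caught alone (or already breeding) have already dispersed
    if (r$group_size[1] == 1 || isTRUE(r$breeder[1])) next
    natal <- r$group_id[1]
    left <- which(r$group_id != natal)
    t0 <- r$capture_date[1]
    if (length(left)) {
      dates <- r$capture_date[seq_len(left[1])]
      state <- c(rep(1L, left[1] - 1L), 2L)
    } else {
      dates <- r$capture_date
      state <- rep(1L, nrow(r))
      wsite <- windows[windows$site == r$site[nrow(r)], , drop = FALSE]
      following <- wsite$start[wsite$start > max(dates)]
      if (length(following) >= 2) {        # disappeared: no longer natal
        dates <- c(dates, min(following))
        state <- c(state, 2L)
      }
    }
    if (length(dates) < 2) next
    out[[id]] <- data.frame(
      individual_id = id,
      t = as.numeric(dates - t0) / 365.25,
      state = state, male = as.numeric(sex == "M"),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
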