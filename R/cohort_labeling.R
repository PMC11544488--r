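# Eligibility, deterioration events, carry-forward alignment to the
# reference score stream, and outcome labeling at configured horizons.
#
# The composite outcome is death on a medical-surgical ward or direct
# ward-to-ICU transfer within `horizon_hours` of a score. Event times are
# anchored to vital-sign documentation: a transfer is timed at the last
# ward-located observation before the ICU interval begins, a ward death at
# the last recorded vital sign.

#' Evaluation configuration
#'
#' @param horizon_hours Outcome horizon: 12, 24 (primary) or 48.
#' @param outcome_type `"deterioration"` (ward death or ward-to-ICU
#'   transfer) or `"death"` (ward death only).
#' @param n_bootstrap Bootstrap iterations (one observation per encounter
#'   drawn per iteration).
#' @param random_seed Seed for all bootstrap resampling.
#' @param alpha Two-sided significance level.
#' @param reference_score Comparator score for threshold anchoring and
#'   paired tests.
#' @param moderate_anchor,high_anchor Reference-score thresholds anchoring
#'   the moderate-risk (sensitivity-matched) and high-risk
#'   (specificity-matched) triggers.
#' @return List of class `"evaluation_config"`.
#' @export
evaluation_config <- function(horizon_hours = 24,
                              outcome_type = c("deterioration", "death"),
                              n_bootstrap = 100L,
                              random_seed = 1L,
                              alpha = 0.05,
                              reference_score = "NEWS",
                              moderate_anchor = 5,
                              high_anchor = 7) {
  outcome_type <- match.arg(outcome_type)
  stopifnot(horizon_hours %in% c(12, 24, 48), n_bootstrap >= 1)
  structure(list(horizon_hours = horizon_hours, outcome_type = outcome_type,
                 n_bootstrap = as.integer(n_bootstrap),
                 random_seed = as.integer(random_seed), alpha = alpha,
                 reference_score = reference_score,
                 moderate_anchor = moderate_anchor, high_anchor = high_anchor),
            class = "evaluation_config")
}

#' Eligibility filter
#'
#' Retains adult encounters (age >= 18) with at least one medical-surgical
#' ward interval. Exclusion counts by reason are attached as attribute
#' `"exclusions"`.
#'
#' @param encounters Encounter tibble.
#' @param locations Location-interval tibble.
#' @return Filtered encounter tibble.
#' @export
eligibility_filter <- function(encounters, locations) {
  ward_ids <- unique(locations$encounter_id[locations$location == "ward"])
  minor <- !is.na(encounters$age_years) & encounters$age_years < 18
  no_ward <- !encounters$encounter_id %in% ward_ids
  keep <- !minor & !no_ward
  structure(encounters[keep, , drop = FALSE],
            exclusions = c(age_under_18 = sum(minor),
                           no_ward_stay = sum(no_ward & !minor)))
}

#' Extract deterioration events for one encounter
#'
#' One `ward_to_icu` event per ward-to-ICU interval transition, timed at the
#' last ward-located observation preceding the transition; one `ward_death`
#' event when the disposition is dead and the final location interval is a
#' ward, timed at the last recorded vital sign.
#'
#' @param encounter One-row encounter tibble.
#' @param locations Location intervals of that encounter.
#' @param observations Observations of that encounter.
#' @return Tibble `(encounter_id, event_time, event_type)` ordered by time.
#' @export
extract_events <- function(encounter, locations, observations) {
  loc <- dplyr::arrange(locations[locations$encounter_id == encounter$encounter_id, ],
                        .data$start_time)
  obs <- dplyr::arrange(observations[observations$encounter_id == encounter$encounter_id, ],
                        .data$time)
  ward_obs <- obs[obs$location == "ward", , drop = FALSE]
  events <- list()
  if (nrow(loc) > 1) {
    trans <- which(loc$location[-nrow(loc)] == "ward" & loc$location[-1] == "icu")
    for (i in trans) {
      boundary <- loc$end_time[i]
      prior <- ward_obs$time[ward_obs$time <= boundary]
      if (length(prior)) {
        events[[length(events) + 1L]] <- tibble::tibble(
          encounter_id = encounter$encounter_id,
          event_time = max(prior), event_type = "ward_to_icu")
      }
    }
  }
  if (identical(encounter$disposition, "dead") &&
      nrow(loc) && loc$location[nrow(loc)] == "ward") {
    if (nrow(obs)) {
      events[[length(events) + 1L]] <- tibble::tibble(
        encounter_id = encounter$encounter_id,
        event_time = max(obs$time), event_type = "ward_death")
    } else {
      warning("encounter ", encounter$encounter_id,
              ": dead disposition with no observations; death event skipped")
    }
  }
  if (!length(events)) {
    return(tibble::tibble(encounter_id = character(),
                          event_time = as.POSIXct(character(), tz = "UTC"),
                          event_type = character()))
  }
  dplyr::arrange(dplyr::bind_rows(events), .data$event_time)
}

#' Extract deterioration events for a whole cohort
#'
#' @param encounters Eligible encounter tibble.
#' @param locations Location intervals.
#' @param observations Observations.
#' @return Event tibble over all encounters.
#' @export
extract_events_cohort <- function(encounters, locations, observations) {
  obs_dt <- data.table::as.data.table(
    observations[, c("encounter_id", "time", "location")])
  loc_dt <- data.table::as.data.table(locations)
  data.table::setorder(obs_dt, encounter_id, time)
  data.table::setorder(loc_dt, encounter_id, start_time)

  # ward->icu transitions
  loc_dt[, next_loc := data.table::shift(location, type = "lead"),
         by = encounter_id]
  trans <- loc_dt[location == "ward" & next_loc == "icu"]
  icu_events <- NULL
  if (nrow(trans)) {
    ward_obs <- obs_dt[location == "ward"]
    ward_obs[, obs_time := time]
    data.table::setkey(ward_obs, encounter_id, time)
    hit <- ward_obs[trans[, .(encounter_id, time = end_time)],
                    on = c("encounter_id", "time"), roll = TRUE]
    icu_events <- tibble::tibble(encounter_id = hit$encounter_id,
                                 event_time = hit$obs_time,
                                 event_type = "ward_to_icu")
    icu_events <- icu_events[!is.na(icu_events$event_time), , drop = FALSE]
  }
  last_loc <- loc_dt[, .(final = location[.N]), by = encounter_id]
  dead_ward <- encounters$encounter_id[
    encounters$disposition == "dead" &
      encounters$encounter_id %in% last_loc[final == "ward"]$encounter_id]
  death_events <- NULL
  if (length(dead_ward)) {
    last_obs <- obs_dt[encounter_id %in% dead_ward,
                       .(event_time = max(time)), by = encounter_id]
    skipped <- setdiff(dead_ward, last_obs$encounter_id)
    if (length(skipped)) {
      warning(length(skipped),
              " dead encounter(s) with no observations; death event skipped")
    }
    death_events <- tibble::tibble(encounter_id = last_obs$encounter_id,
                                   event_time = last_obs$event_time,
                                   event_type = "ward_death")
  }
  out <- dplyr::bind_rows(icu_events, death_events)
  if (!nrow(out)) {
    return(tibble::tibble(encounter_id = character(),
                          event_time = as.POSIXct(character(), tz = "UTC"),
                          event_type = character()))
  }
  dplyr::arrange(out, .data$encounter_id, .data$event_time)
}

#' Align score streams to a reference grid
#'
#' Last-observation-carried-forward alignment: at each reference time the
#' value of every other score is its most recent value at or before that
#' time, `NA` if none exists yet. The reference is normally the densest
#' stream.
#'
#' @param reference Score-series tibble providing the time grid.
#' @param others List of score-series tibbles to align.
#' @param max_age_hours Optional staleness limit; carried values older than
#'   this are set `NA`. Default `Inf` (unconditional carry-forward).
#' @return Long tibble `(encounter_id, time, score_name, value)` containing
#'   the reference's own points plus every aligned score.
#' @export
align_scores <- function(reference, others = list(), max_age_hours = Inf) {
  if (!nrow(reference)) {
    return(tibble::tibble(encounter_id = character(),
                          time = as.POSIXct(character(), tz = "UTC"),
                          score_name = character(), value = numeric()))
  }
  grid <- data.table::data.table(encounter_id = reference$encounter_id,
                                 time = reference$time)
  data.table::setkey(grid, encounter_id, time)
  pieces <- list(tibble::tibble(encounter_id = reference$encounter_id,
                                time = reference$time,
                                score_name = reference$score_name,
                                value = reference$value))
  for (s in others) {
    nm <- if (nrow(s)) s$score_name[[1]] else next
    dt <- data.table::data.table(encounter_id = s$encounter_id,
                                 time = s$time, value = s$value,
                                 src_time = s$time)
    data.table::setkey(dt, encounter_id, time)
    roll_window <- if (is.finite(max_age_hours)) max_age_hours * 3600 else Inf
    hit <- dt[grid, on = c("encounter_id", "time"), roll = roll_window]
    pieces[[length(pieces) + 1L]] <- tibble::tibble(
      encounter_id = hit$encounter_id, time = hit$time,
      score_name = nm, value = hit$value)
  }
  out <- dplyr::bind_rows(pieces)
  dplyr::arrange(out, .data$encounter_id, .data$time, .data$score_name)
}

#' Label an aligned grid at a configured horizon
#'
#' `label = 1` iff the first qualifying event falls in the half-open window
#' `(time, time + horizon]`; a row simultaneous with the event does not
#' predict it. Rows at or after the first qualifying event are dropped so no
#' post-onset scores enter observation-level analysis.
#'
#' @param grid Long aligned tibble from [align_scores()].
#' @param events Event tibble from [extract_events_cohort()].
#' @param config [evaluation_config()].
#' @return Labeled tibble: grid columns plus `label`, `horizon_hours`,
#'   `outcome_type`.
#' @export
label_grid <- function(grid, events, config = evaluation_config()) {
  qual <- if (config$outcome_type == "death") {
    events[events$event_type == "ward_death", , drop = FALSE]
  } else {
    events
  }
  first_event <- first_event_times(qual)
  out <- dplyr::left_join(grid, first_event, by = "encounter_id")
  keep <- is.na(out$first_event_time) | out$time < out$first_event_time
  out <- out[keep, , drop = FALSE]
  dh <- hours_between(out$time, out$first_event_time)
  out$label <- as.integer(!is.na(dh) & dh > 0 & dh <= config$horizon_hours)
  out$horizon_hours <- config$horizon_hours
  out$outcome_type <- config$outcome_type
  out$first_event_time <- NULL
  out
}

first_event_times <- function(events) {
  if (!nrow(events)) {
    return(tibble::tibble(encounter_id = character(),
                          first_event_time = as.POSIXct(character(), tz = "UTC")))
  }
  dplyr::summarise(dplyr::group_by(events, .data$encounter_id),
                   first_event_time = min(.data$event_time), .groups = "drop")
}

#' Encounter-level summaries for efficiency and lead-time analyses
#'
#' For each encounter and score: the extreme pre-event value (maximum for
#' high-is-risk scores, minimum for low-is-risk), computed over grid rows
#' strictly before the first qualifying event (or all rows when no event);
#' and, per requested threshold, the earliest pre-event time the trigger
#' condition holds (value >= threshold for high-is-risk, <= for
#' low-is-risk).
#'
#' @param grid Long aligned tibble.
#' @param events Event tibble.
#' @param thresholds Named list: score name -> numeric vector of thresholds.
#' @param polarity Named polarity vector (see [default_polarity()]).
#' @param outcome_type As in [evaluation_config()].
#' @return List with `scores` (per encounter x score: `had_event`,
#'   `first_event_time`, `extreme_pre_event`) and `triggers` (per encounter
#'   x score x threshold: `first_trigger_time`).
#' @export
summarize_encounter <- function(grid, events, thresholds = list(),
                                polarity = default_polarity(),
                                outcome_type = "deterioration") {
  qual <- if (outcome_type == "death") {
    events[events$event_type == "ward_death", , drop = FALSE]
  } else {
    events
  }
  first_event <- first_event_times(qual)
  g <- dplyr::left_join(grid, first_event, by = "encounter_id")
  pre <- g[is.na(g$first_event_time) | g$time < g$first_event_time, , drop = FALSE]
  pre <- pre[!is.na(pre$value), , drop = FALSE]

  low <- function(nm) {
    p <- polarity[nm]
    !is.na(p) & p == "low_is_risk"
  }
  # risk-directed extreme: negate low-is-risk values so max() is always the
  # riskiest, then map back to the native scale
  pre$dir <- unname(ifelse(low(pre$score_name), -1, 1))
  scores <- if (nrow(pre)) {
    dplyr::summarise(
      dplyr::group_by(pre, .data$encounter_id, .data$score_name),
      extreme_pre_event = .data$dir[1] * max(.data$dir * .data$value),
      .groups = "drop")
  } else {
    tibble::tibble(encounter_id = character(), score_name = character(),
                   extreme_pre_event = numeric())
  }
  all_enc <- unique(grid$encounter_id)
  base <- tidyr::expand_grid(encounter_id = all_enc,
                             score_name = unique(grid$score_name))
  scores <- dplyr::left_join(base, scores, by = c("encounter_id", "score_name"))
  scores <- dplyr::left_join(scores, first_event, by = "encounter_id")
  scores$had_event <- !is.na(scores$first_event_time)

  trig_rows <- list()
  for (nm in names(thresholds)) {
    sub <- pre[pre$score_name == nm, , drop = FALSE]
    for (th in thresholds[[nm]]) {
      hitrows <- if (low(nm)) sub[sub$value <= th, ] else sub[sub$value >= th, ]
      if (!nrow(hitrows)) next
      ft <- dplyr::summarise(dplyr::group_by(hitrows, .data$encounter_id),
                             first_trigger_time = min(.data$time), .groups = "drop")
      ft$score_name <- nm
      ft$threshold <- th
      trig_rows[[length(trig_rows) + 1L]] <- ft
    }
  }
  triggers <- if (length(trig_rows)) dplyr::bind_rows(trig_rows) else {
    tibble::tibble(encounter_id = character(),
                   first_trigger_time = as.POSIXct(character(), tz = "UTC"),
                   score_name = character(), threshold = numeric())
  }
  list(scores = scores, triggers = triggers)
}
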