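# MEWS / NEWS / NEWS2 engines. All three are pure, deterministic functions
# of the observation (plus, for NEWS2, the encounter's SpO2-scale state).
# Missing-component policy: a component never documented contributes 0; an
# observation with no documented component at all scores NA.

#' Default polarity registry
#'
#' Direction of risk on each score's native scale. Aggregated weighted
#' scores and gradient-boosted/EHR-vendor style indices rise with risk;
#' Rothman-style indices fall with risk.
#'
#' @return Named character vector, values `"high_is_risk"`/`"low_is_risk"`.
#' @export
default_polarity <- function() {
  c(MEWS = "high_is_risk", NEWS = "high_is_risk", NEWS2 = "high_is_risk",
    eCART = "high_is_risk", EDI = "high_is_risk", SEDI = "high_is_risk",
    RI = "low_is_risk", ORACLE = "high_is_risk")
}

band_cache <- new.env(parent = emptyenv())

get_band_table <- function(score) {
  key <- toupper(score)
  if (is.null(band_cache[[key]])) band_cache[[key]] <- load_band_table(key)
  band_cache[[key]]
}

# Vectorised scorer over a data frame of (carried-forward) vitals.
# `scale2` (logical) selects the NEWS2 SpO2 scale per row; ignored otherwise.
score_vitals <- function(df, table, scale2 = NULL) {
  n <- nrow(df)
  total <- integer(n)
  any_present <- logical(n)
  for (comp in table$components) {
    x <- df[[comp$name]]
    if (is.null(x)) x <- rep(NA, n)
    sub <- switch(comp$type,
      numeric = band_points(comp$table, as.numeric(x)),
      scaled = {
        s1 <- band_points(comp$scales$scale1, as.numeric(x))
        on_o2 <- !is.na(df$supplemental_o2) & df$supplemental_o2
        s2 <- ifelse(on_o2,
                     band_points(comp$scales$scale2_o2, as.numeric(x)),
                     band_points(comp$scales$scale2_air, as.numeric(x)))
        use2 <- if (is.null(scale2)) rep(FALSE, n) else scale2
        ifelse(use2, s2, s1)
      },
      categorical = {
        out <- unname(comp$points[as.character(x)])
        out[is.na(x)] <- NA_integer_
        as.integer(out)
      },
      boolean = {
        lx <- as.logical(x)
        ifelse(is.na(lx), NA_integer_, ifelse(lx, comp$true, comp$false))
      }
    )
    any_present <- any_present | !is.na(sub)
    sub[is.na(sub)] <- 0L
    total <- total + sub
  }
  total[!any_present] <- NA_integer_
  total
}

as_obs_row <- function(obs) {
  if (is.data.frame(obs)) return(obs)
  tibble::as_tibble(obs[intersect(names(obs), OBS_CANONICAL)])
}

#' Modified Early Warning Score for one observation
#'
#' Five-component ward MEWS (systolic blood pressure, heart rate,
#' respiratory rate, temperature, AVPU). Missing components contribute 0;
#' all components missing yields `NA`.
#'
#' @param obs A one-row data frame or named list with vital-sign fields.
#' @return Integer score or `NA`.
#' @export
#' @examples
#' mews_score(list(systolic_bp = 120, heart_rate = 80,
#'                 respiratory_rate = 12, temperature = 37, consciousness = "A"))
mews_score <- function(obs) {
  score_vitals(as_obs_row(obs), get_band_table("MEWS"))
}

#' National Early Warning Score for one observation
#'
#' Seven components: respiratory rate, SpO2, supplemental oxygen,
#' temperature, systolic blood pressure, heart rate, consciousness.
#'
#' @inheritParams mews_score
#' @return Integer score or `NA`.
#' @export
news_score <- function(obs) {
  score_vitals(as_obs_row(obs), get_band_table("NEWS"))
}

#' NEWS2 for one observation
#'
#' As [news_score()] with ACVPU consciousness and the dual SpO2 scale:
#' scale 1 before the encounter's scale-switch time, scale 2 (the
#' hypercapnic-respiratory-failure scale) from the switch time through
#' discharge.
#'
#' @inheritParams mews_score
#' @param state SpO2 scale state from [compute_spo2_scale_state()]; `NULL`
#'   means no qualifying blood gas (scale 1 throughout).
#' @return Integer score or `NA`.
#' @export
news2_score <- function(obs, state = NULL) {
  row <- as_obs_row(obs)
  scale2 <- rep(FALSE, nrow(row))
  if (!is.null(state) && !is.null(state$switch_time) && !is.na(state$switch_time)) {
    scale2 <- !is.na(row$time) & row$time >= state$switch_time
    if (is.null(row$time)) scale2 <- rep(TRUE, nrow(row))
  }
  score_vitals(row, get_band_table("NEWS2"), scale2 = scale2)
}

#' SpO2 scale state for one encounter
#'
#' The switch time is the earliest observation time at which PaCO2 exceeds
#' 45 mm Hg with a concurrent FiO2 above 21% (i.e. on supplemental oxygen).
#' By default "concurrent" means the carried-forward FiO2 at the blood-gas
#' timestamp, since oxygen settings and gases are charted asynchronously;
#' `strict_simultaneous = TRUE` requires both values documented on the same
#' row.
#'
#' @param observations Time-sorted observations of a single encounter.
#' @param strict_simultaneous Require FiO2 documented on the same row as the
#'   qualifying PaCO2.
#' @return List with `encounter_id` and `switch_time` (POSIXct or `NA`).
#' @export
compute_spo2_scale_state <- function(observations, strict_simultaneous = FALSE) {
  obs <- dplyr::arrange(observations, .data$time)
  fio2 <- if (strict_simultaneous) obs$fio2 else locf(obs$fio2)
  hit <- !is.na(obs$paco2) & obs$paco2 > 45 & !is.na(fio2) & fio2 > 21
  list(
    encounter_id = if (nrow(obs)) obs$encounter_id[[1]] else NA_character_,
    switch_time = if (any(hit)) obs$time[which(hit)[1]] else as.POSIXct(NA)
  )
}

locf <- function(x) {
  i <- cumsum(!is.na(x))
  out <- x[which(!is.na(x))[pmax(i, 1)]]
  out[i == 0] <- if (is.numeric(x)) NA_real_ else NA
  out
}

VITAL_COMPONENTS <- c("respiratory_rate", "spo2", "supplemental_o2", "fio2",
                      "temperature", "systolic_bp", "heart_rate",
                      "consciousness", "paco2")

carry_forward_vitals <- function(observations) {
  dt <- data.table::as.data.table(observations)
  data.table::setorder(dt, encounter_id, time)
  dt[, (VITAL_COMPONENTS) := lapply(.SD, locf), by = encounter_id,
     .SDcols = VITAL_COMPONENTS]
  tibble::as_tibble(dt)
}

#' Score stream for one encounter
#'
#' Re-scores at every observation time using the latest carried-forward
#' value of every component (any newly documented component triggers
#' rescoring). Times where the engine returns `NA` (nothing documented yet)
#' emit no point.
#'
#' @param observations Observations of a single encounter.
#' @param engine `"MEWS"`, `"NEWS"` or `"NEWS2"`.
#' @param strict_simultaneous Passed to [compute_spo2_scale_state()].
#' @return A score-series tibble (`encounter_id, score_name, time, value`).
#' @export
score_stream <- function(observations, engine = c("NEWS", "NEWS2", "MEWS"),
                         strict_simultaneous = FALSE) {
  engine <- match.arg(engine)
  score_streams(observations, engine, strict_simultaneous)
}

#' Score streams for a whole cohort
#'
#' Vectorised version of [score_stream()] over all encounters at once.
#'
#' @param observations Observations of one or more encounters.
#' @inheritParams score_stream
#' @return Score-series tibble sorted by `(encounter_id, time)`.
#' @export
score_streams <- function(observations, engine = c("NEWS", "NEWS2", "MEWS"),
                          strict_simultaneous = FALSE) {
  engine <- match.arg(engine)
  if (!nrow(observations)) {
    return(tibble::tibble(encounter_id = character(), score_name = character(),
                          time = as.POSIXct(character(), tz = "UTC"),
                          value = numeric()))
  }
  ward <- observations[observations$location == "ward", , drop = FALSE]
  # duplicates: last written wins
  ward <- ward[!duplicated(ward[, c("encounter_id", "time")], fromLast = TRUE), ]
  cf <- carry_forward_vitals(ward)
  scale2 <- rep(FALSE, nrow(cf))
  if (engine == "NEWS2") {
    ward_sorted <- dplyr::arrange(ward, .data$encounter_id, .data$time)
    fio2 <- if (strict_simultaneous) ward_sorted$fio2 else cf$fio2
    raw_paco2 <- ward_sorted$paco2
    qualifying <- !is.na(raw_paco2) & raw_paco2 > 45 & !is.na(fio2) & fio2 > 21
    dt <- data.table::data.table(encounter_id = cf$encounter_id, q = qualifying)
    scale2 <- dt[, cumsum(q) > 0, by = encounter_id]$V1
  }
  value <- score_vitals(cf, get_band_table(engine), scale2 = scale2)
  out <- tibble::tibble(encounter_id = cf$encounter_id, score_name = engine,
                        time = cf$time, value = as.numeric(value))
  out[!is.na(out$value), , drop = FALSE]
}

#' Adapt an externally supplied score stream
#'
#' Reads a CSV of `(encounter_id, time, value)` rows for one named score
#' (e.g. a proprietary deterioration index exported from the EHR), validates
#' it against the known encounters, and returns score series with the
#' declared polarity recorded as an attribute.
#'
#' @param path CSV path.
#' @param score_name Label for the score.
#' @param polarity `"high_is_risk"` or `"low_is_risk"`.
#' @param known_encounters Optional character vector; rows for unknown
#'   encounters are skipped with a warning.
#' @return Score-series tibble with attribute `polarity`.
#' @export
external_score_adapter <- function(path, score_name,
                                   polarity = c("high_is_risk", "low_is_risk"),
                                   known_encounters = NULL) {
  polarity <- match.arg(polarity)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  needed <- c("encounter_id", "time", "value")
  if (length(setdiff(needed, names(raw)))) {
    stop("external score file must have columns: ", paste(needed, collapse = ", "))
  }
  out <- tibble::tibble(
    encounter_id = raw$encounter_id,
    score_name = score_name,
    time = parse_time_min(raw$time),
    value = suppressWarnings(as.numeric(raw$value))
  )
  bad <- is.na(out$value) | is.na(out$time) | is.na(out$encounter_id)
  if (any(bad)) {
    warning(sum(bad), " row(s) rejected (non-numeric value or bad timestamp) in ", path)
    out <- out[!bad, , drop = FALSE]
  }
  if (!is.null(known_encounters)) {
    unk <- !out$encounter_id %in% known_encounters
    if (any(unk)) {
      warning(sum(unk), " row(s) for unknown encounter(s) skipped in ", path)
      out <- out[!unk, , drop = FALSE]
    }
  }
  out <- dplyr::arrange(out, .data$encounter_id, .data$time)
  out <- out[!duplicated(out[, c("encounter_id", "time")], fromLast = TRUE), ]
  structure(out, polarity = polarity)
}
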