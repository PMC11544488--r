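# Shared fixture builders and independent brute-force oracles.

T0 <- as.POSIXct("2023-06-01 08:00", tz = "UTC")

at_hours <- function(h) T0 + round(h * 60) * 60

# one observation row; unspecified vitals are missing
obs_row <- function(encounter_id = "e1", hours = 0, location = "ward", ...) {
  defaults <- list(respiratory_rate = NA_real_, spo2 = NA_real_,
                   supplemental_o2 = NA, fio2 = NA_real_,
                   temperature = NA_real_, systolic_bp = NA_real_,
                   heart_rate = NA_real_, consciousness = NA_character_,
                   paco2 = NA_real_)
  over <- list(...)
  defaults[names(over)] <- over
  tibble::tibble(encounter_id = encounter_id, time = at_hours(hours),
                 !!!defaults, location = location)
}

obs_normal <- function(encounter_id = "e1", hours = 0, ...) {
  args <- list(respiratory_rate = 14, spo2 = 98, supplemental_o2 = FALSE,
               temperature = 37, systolic_bp = 120, heart_rate = 70,
               consciousness = "A")
  over <- list(...)
  args[names(over)] <- over
  do.call(obs_row, c(list(encounter_id = encounter_id, hours = hours), args))
}

encounter_row <- function(encounter_id = "e1", admit = 0, discharge = 96,
                          age = 60, campus = "A", disposition = "alive") {
  tibble::tibble(encounter_id = encounter_id, campus = campus,
                 age_years = age, admit_time = at_hours(admit),
                 discharge_time = at_hours(discharge),
                 disposition = disposition)
}

location_interval <- function(encounter_id = "e1", start = 0, end = 96,
                              location = "ward") {
  tibble::tibble(encounter_id = encounter_id, start_time = at_hours(start),
                 end_time = at_hours(end), location = location)
}

score_series <- function(encounter_id, score_name, hours, values) {
  tibble::tibble(encounter_id = encounter_id, score_name = score_name,
                 time = at_hours(hours), value = values)
}

# score an observation documenting a single component
single_component_score <- function(engine, field, value, extra = list()) {
  args <- c(list(encounter_id = "x", hours = 0), setNames(list(value), field),
            extra)
  obs <- do.call(obs_row, args)
  switch(engine,
         MEWS = mews_score(obs), NEWS = news_score(obs),
         NEWS2 = news2_score(obs))
}

# brute-force AUROC: explicit pair counting with half-credit ties
auc_pair_count <- function(labels, values) {
  pos <- values[labels == 1]
  neg <- values[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# brute-force LOCF: latest source value at or before each target time
locf_scan <- function(src_times, src_values, targets) {
  vapply(targets, function(t) {
    ok <- which(src_times <= t)
    if (!length(ok)) NA_real_ else src_values[max(ok)]
  }, numeric(1))
}

# sign-swap permutation oracle for the paired AUC difference
permutation_delong_p <- function(labels, va, vb, n_perm = 2000) {
  auc <- function(v) {
    r <- rank(v, ties.method = "average")
    n1 <- sum(labels == 1); n0 <- sum(labels == 0)
    (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  obs_diff <- abs(auc(va) - auc(vb))
  n <- length(labels)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    swap <- runif(n) < 0.5
    a2 <- ifelse(swap, vb, va)
    b2 <- ifelse(swap, va, vb)
    if (abs(auc(a2) - auc(b2)) >= obs_diff - 1e-12) hits <- hits + 1L
  }
  hits / n_perm
}

# hand-transcribed expected subscores at band edges (edge value and 1 unit
# below), checked by scoring observations that document only one component
news_rr_cases <- c("8" = 3, "9" = 1, "11" = 1, "12" = 0, "20" = 0, "21" = 2,
                   "24" = 2, "25" = 3)
news_spo2_cases <- c("91" = 3, "92" = 2, "93" = 2, "94" = 1, "95" = 1, "96" = 0)
news_temp_cases <- c("35" = 3, "35.1" = 1, "36" = 1, "36.1" = 0, "38" = 0,
                     "38.1" = 1, "39" = 1, "39.1" = 2)
news_sbp_cases <- c("90" = 3, "91" = 2, "100" = 2, "101" = 1, "110" = 1,
                    "111" = 0, "219" = 0, "220" = 3)
news_hr_cases <- c("40" = 3, "41" = 1, "50" = 1, "51" = 0, "90" = 0, "91" = 1,
                   "110" = 1, "111" = 2, "130" = 2, "131" = 3)
news_avpu_cases <- c(A = 0, C = 3, V = 3, P = 3, U = 3)

mews_sbp_cases <- c("70" = 3, "71" = 2, "80" = 2, "81" = 1, "100" = 1,
                    "101" = 0, "199" = 0, "200" = 2)
mews_hr_cases <- c("40" = 2, "41" = 1, "50" = 1, "51" = 0, "100" = 0,
                   "101" = 1, "110" = 1, "111" = 2, "129" = 2, "130" = 3)
mews_rr_cases <- c("8" = 2, "9" = 0, "14" = 0, "15" = 1, "20" = 1, "21" = 2,
                   "29" = 2, "30" = 3)
mews_temp_cases <- c("34.9" = 2, "35" = 0, "38.4" = 0, "38.5" = 2)
mews_avpu_cases <- c(A = 0, C = 1, V = 1, P = 2, U = 3)

news2_spo2_scale1_cases <- news_spo2_cases
news2_spo2_scale2_air_cases <- c("83" = 3, "84" = 2, "85" = 2, "86" = 1,
                                 "87" = 1, "88" = 0, "92" = 0, "93" = 0,
                                 "97" = 0)
news2_spo2_scale2_o2_cases <- c("83" = 3, "84" = 2, "87" = 1, "88" = 0,
                                "92" = 0, "93" = 1, "94" = 1, "95" = 2,
                                "96" = 2, "97" = 3, "100" = 3)

# small deterministic cohort: 4 encounters, 2 events
tiny_cohort <- function() {
  enc <- dplyr::bind_rows(
    encounter_row("e1", 0, 60, disposition = "alive"),
    encounter_row("e2", 0, 50, disposition = "dead"),   # ward death at 40h
    encounter_row("e3", 0, 80, disposition = "alive"),  # ward->icu at 50h
    encounter_row("e4", 0, 70, disposition = "alive", campus = "B")
  )
  loc <- dplyr::bind_rows(
    location_interval("e1", 0, 60),
    location_interval("e2", 0, 50),
    location_interval("e3", 0, 50), location_interval("e3", 50, 80, "icu"),
    location_interval("e4", 0, 70)
  )
  obs <- dplyr::bind_rows(
    lapply(seq(0, 56, by = 8), function(h) obs_normal("e1", h)),
    lapply(seq(0, 40, by = 8), function(h) obs_normal("e2", h)),
    lapply(seq(0, 48, by = 8), function(h) obs_normal("e3", h)),
    lapply(seq(0, 64, by = 8), function(h) obs_normal("e4", h))
  )
  list(encounters = enc, locations = loc, observations = obs)
}
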