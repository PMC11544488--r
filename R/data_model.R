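# Tidy readers, writers and validation for ward observation and encounter
# tables. Timestamps are ISO-8601 in files and POSIXct (UTC, minutes
# resolution) in memory; all durations downstream are hours as reals.

OBS_CANONICAL <- c(
  "encounter_id", "time", "respiratory_rate", "spo2", "supplemental_o2",
  "fio2", "temperature", "systolic_bp", "heart_rate", "consciousness",
  "paco2", "location"
)

ENC_CANONICAL <- c(
  "encounter_id", "campus", "age_years", "admit_time", "discharge_time",
  "disposition"
)

CONSCIOUSNESS_LEVELS <- c("A", "C", "V", "P", "U")
LOCATION_LEVELS <- c("ward", "icu", "other")

#' Column-mapping dialect for ward CSV files
#'
#' EHR exports have no standard header set, so readers take a dialect: a
#' named list mapping canonical field names to the column names found in the
#' file. The default is the identity mapping over the canonical names.
#'
#' @param ... Named overrides, e.g. `spo2 = "SpO2_pct"`.
#' @return Named list mapping canonical names to file column names.
#' @export
#' @examples
#' csv_dialect(heart_rate = "pulse")
csv_dialect <- function(...) {
  d <- as.list(setNames(OBS_CANONICAL, OBS_CANONICAL))
  over <- list(...)
  bad <- setdiff(names(over), OBS_CANONICAL)
  if (length(bad)) {
    stop("unknown canonical field(s) in dialect: ", paste(bad, collapse = ", "))
  }
  d[names(over)] <- over
  d
}

parse_time_min <- function(x) {
  x <- as.character(x)
  t <- suppressWarnings(readr::parse_datetime(x))
  # tolerate a date-only column
  miss <- is.na(t) & !is.na(x)
  if (any(miss)) {
    d <- suppressWarnings(readr::parse_date(x[miss]))
    t[miss] <- as.POSIXct(d, tz = "UTC")
  }
  attr(t, "tzone") <- "UTC"
  as.POSIXct(round(t, units = "mins"), tz = "UTC")
}

hours_between <- function(a, b) as.numeric(difftime(b, a, units = "hours"))

new_diagnostics <- function() {
  tibble::tibble(line = integer(), field = character(), message = character())
}

add_diag <- function(diag, line, field, message) {
  dplyr::bind_rows(diag, tibble::tibble(
    line = as.integer(line), field = field, message = message
  ))
}

#' Read ward observations from CSV
#'
#' Parses, validates and time-sorts one row per documented measurement
#' vector. Invalid rows are rejected, each with exactly one line-numbered
#' diagnostic attached to the result (attribute `"diagnostics"`); duplicate
#' `(encounter_id, time)` rows are kept and flagged in the diagnostics so
#' carry-forward logic (last written wins) stays auditable.
#'
#' @param path CSV file with a header row.
#' @param dialect Column mapping from [csv_dialect()]. Fields mapped to
#'   columns absent from the file are treated as entirely missing, except the
#'   required `encounter_id` and `time`.
#' @param max_diagnostics Cap on stored row-level diagnostics.
#' @return A tibble of valid observations sorted by `(encounter_id, time)`,
#'   with attributes `diagnostics` (tibble) and `n_input` (raw row count).
#' @export
read_observations <- function(path, dialect = csv_dialect(),
                              max_diagnostics = 1000L) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  for (req in c("encounter_id", "time")) {
    if (!dialect[[req]] %in% names(raw)) {
      stop("missing required column '", dialect[[req]], "' (", req, ") in ", path)
    }
  }
  n_input <- nrow(raw)
  diag <- new_diagnostics()

  get_col <- function(field) {
    col <- dialect[[field]]
    if (col %in% names(raw)) raw[[col]] else rep(NA_character_, n_input)
  }
  num <- function(x) suppressWarnings(as.numeric(x))
  obs <- tibble::tibble(
    encounter_id = get_col("encounter_id"),
    time = parse_time_min(get_col("time")),
    respiratory_rate = num(get_col("respiratory_rate")),
    spo2 = num(get_col("spo2")),
    supplemental_o2 = parse_logical_lenient(get_col("supplemental_o2")),
    fio2 = num(get_col("fio2")),
    temperature = num(get_col("temperature")),
    systolic_bp = num(get_col("systolic_bp")),
    heart_rate = num(get_col("heart_rate")),
    consciousness = toupper(trimws(get_col("consciousness"))),
    paco2 = num(get_col("paco2")),
    location = tolower(trimws(get_col("location")))
  )
  obs$consciousness[obs$consciousness %in% c("", "NA")] <- NA_character_
  obs$location[is.na(obs$location) | obs$location == ""] <- "ward"

  line <- seq_len(n_input) + 1L  # header is line 1
  bad <- rep(FALSE, n_input)
  flag <- function(cond, field, msg) {
    cond <- which(cond & !bad)
    for (i in cond) diag <<- add_diag(diag, line[i], field, msg)
    bad[cond] <<- TRUE
  }
  flag(is.na(obs$encounter_id) | obs$encounter_id == "", "encounter_id",
       "missing encounter id")
  flag(is.na(obs$time) & !is.na(get_col("time")), "time",
       "unparseable timestamp")
  flag(is.na(obs$time), "time", "missing timestamp")
  flag(!is.na(obs$spo2) & (obs$spo2 < 0 | obs$spo2 > 100), "spo2",
       "spo2 outside [0,100]")
  flag(!is.na(obs$fio2) & (obs$fio2 < 21 | obs$fio2 > 100), "fio2",
       "fio2 outside [21,100]")
  for (f in c("respiratory_rate", "temperature", "systolic_bp", "heart_rate",
              "paco2")) {
    flag(!is.na(obs[[f]]) & obs[[f]] < 0, f, paste0(f, " negative"))
  }
  flag(!is.na(obs$consciousness) &
         !obs$consciousness %in% CONSCIOUSNESS_LEVELS,
       "consciousness", "consciousness not one of A/C/V/P/U")
  flag(!obs$location %in% LOCATION_LEVELS, "location",
       "location not one of ward/icu/other")

  kept <- obs[!bad, , drop = FALSE]
  dup <- duplicated(kept[, c("encounter_id", "time")]) |
    duplicated(kept[, c("encounter_id", "time")], fromLast = TRUE)
  if (any(dup)) {
    diag <- add_diag(diag, NA_integer_, "time",
                     sprintf("%d duplicate (encounter_id, time) rows kept; last written wins on carry-forward",
                             sum(dup)))
  }
  kept <- dplyr::arrange(kept, .data$encounter_id, .data$time)
  if (nrow(diag) > max_diagnostics) diag <- utils::head(diag, max_diagnostics)
  structure(kept, diagnostics = diag, n_input = n_input)
}

parse_logical_lenient <- function(x) {
  up <- toupper(trimws(x))
  out <- rep(NA, length(x))
  out[up %in% c("TRUE", "T", "1", "YES", "Y")] <- TRUE
  out[up %in% c("FALSE", "F", "0", "NO", "N")] <- FALSE
  out
}

#' Read encounter metadata and location-change log
#'
#' Encounters come from one CSV (id, campus, age, admit/discharge, final
#' disposition); ward/ICU location intervals are reconstructed from a
#' location-change log (`encounter_id, start_time, location`), each interval
#' ending where the next begins and the last at discharge. Encounters whose
#' intervals are non-contiguous, overlap, or fall outside the admission
#' bounds are rejected with the gap size in the diagnostic.
#'
#' @param encounters_path CSV of encounter metadata.
#' @param locations_path CSV location-change log. If `NULL`, every encounter
#'   is assumed to be a single ward stay spanning admission to discharge.
#' @return List with `encounters` (tibble) and `locations` (tibble of
#'   `encounter_id, start_time, end_time, location`), plus a `diagnostics`
#'   attribute on the list.
#' @export
read_encounters <- function(encounters_path, locations_path = NULL) {
  if (!file.exists(encounters_path)) stop("file not found: ", encounters_path)
  raw <- readr::read_csv(encounters_path,
                         col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  missing_cols <- setdiff(ENC_CANONICAL, names(raw))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  diag <- new_diagnostics()
  enc <- tibble::tibble(
    encounter_id = raw$encounter_id,
    campus = raw$campus,
    age_years = suppressWarnings(as.numeric(raw$age_years)),
    admit_time = parse_time_min(raw$admit_time),
    discharge_time = parse_time_min(raw$discharge_time),
    disposition = tolower(trimws(raw$disposition))
  )
  line <- seq_len(nrow(enc)) + 1L
  bad <- rep(FALSE, nrow(enc))
  flag <- function(cond, field, msg) {
    for (i in which(cond & !bad)) diag <<- add_diag(diag, line[i], field, msg[min(i, length(msg))])
    bad[which(cond)] <<- TRUE
  }
  flag(is.na(enc$encounter_id) | enc$encounter_id == "", "encounter_id",
       rep("missing encounter id", nrow(enc)))
  flag(is.na(enc$admit_time), "admit_time", rep("unparseable admit time", nrow(enc)))
  flag(is.na(enc$discharge_time), "discharge_time",
       rep("unparseable discharge time", nrow(enc)))
  flag(!is.na(enc$admit_time) & !is.na(enc$discharge_time) &
         enc$admit_time >= enc$discharge_time, "discharge_time",
       rep("discharge not after admit", nrow(enc)))
  flag(!enc$disposition %in% c("alive", "dead"), "disposition",
       rep("disposition not alive/dead", nrow(enc)))
  flag(is.na(enc$age_years) | enc$age_years < 0, "age_years",
       rep("missing or negative age", nrow(enc)))
  enc <- enc[!bad, , drop = FALSE]

  if (is.null(locations_path)) {
    loc <- tibble::tibble(
      encounter_id = enc$encounter_id,
      start_time = enc$admit_time,
      end_time = enc$discharge_time,
      location = "ward"
    )
  } else {
    lraw <- readr::read_csv(locations_path,
                            col_types = readr::cols(.default = "c"),
                            progress = FALSE)
    needed <- c("encounter_id", "start_time", "location")
    if (length(setdiff(needed, names(lraw)))) {
      stop("location log must have columns: ", paste(needed, collapse = ", "))
    }
    ll <- tibble::tibble(
      encounter_id = lraw$encounter_id,
      start_time = parse_time_min(lraw$start_time),
      location = tolower(trimws(lraw$location))
    )
    ll <- dplyr::arrange(ll, .data$encounter_id, .data$start_time)
    ll <- dplyr::semi_join(ll, enc, by = "encounter_id")
    ll <- dplyr::group_by(ll, .data$encounter_id)
    ll <- dplyr::mutate(ll, end_time = dplyr::lead(.data$start_time))
    ll <- dplyr::ungroup(ll)
    ll <- dplyr::left_join(ll,
                           enc[, c("encounter_id", "admit_time", "discharge_time")],
                           by = "encounter_id")
    ll$end_time[is.na(ll$end_time)] <- ll$discharge_time[is.na(ll$end_time)]

    # contiguity: first interval starts at admission, last ends at discharge
    bad_enc <- character()
    firsts <- dplyr::slice_head(dplyr::group_by(ll, .data$encounter_id), n = 1)
    gap_first <- abs(hours_between(firsts$admit_time, firsts$start_time))
    for (i in which(gap_first > 1e-9)) {
      diag <- add_diag(diag, NA_integer_, "start_time",
                       sprintf("encounter %s: %.2f h gap between admission and first location interval",
                               firsts$encounter_id[i], gap_first[i]))
      bad_enc <- c(bad_enc, firsts$encounter_id[i])
    }
    overl <- ll[!is.na(ll$end_time) & ll$end_time <= ll$start_time, ]
    for (i in seq_len(nrow(overl))) {
      diag <- add_diag(diag, NA_integer_, "start_time",
                       sprintf("encounter %s: non-increasing location interval at %s",
                               overl$encounter_id[i], format(overl$start_time[i])))
      bad_enc <- c(bad_enc, overl$encounter_id[i])
    }
    bad_lvl <- ll[!ll$location %in% LOCATION_LEVELS, ]
    for (i in seq_len(nrow(bad_lvl))) {
      diag <- add_diag(diag, NA_integer_, "location",
                       sprintf("encounter %s: unknown location '%s'",
                               bad_lvl$encounter_id[i], bad_lvl$location[i]))
      bad_enc <- c(bad_enc, bad_lvl$encounter_id[i])
    }
    ll <- ll[!ll$encounter_id %in% bad_enc, ]
    enc <- enc[!enc$encounter_id %in% bad_enc, , drop = FALSE]
    no_log <- setdiff(enc$encounter_id, ll$encounter_id)
    extra <- tibble::tibble(
      encounter_id = no_log,
      start_time = enc$admit_time[match(no_log, enc$encounter_id)],
      end_time = enc$discharge_time[match(no_log, enc$encounter_id)],
      location = "ward", admit_time = enc$admit_time[match(no_log, enc$encounter_id)],
      discharge_time = enc$discharge_time[match(no_log, enc$encounter_id)]
    )
    loc <- dplyr::bind_rows(ll, extra)
    loc <- loc[, c("encounter_id", "start_time", "end_time", "location")]
    loc <- dplyr::arrange(loc, .data$encounter_id, .data$start_time)
  }
  structure(list(encounters = enc, locations = loc), diagnostics = diag)
}

#' Write a result table to CSV
#'
#' Deterministic column order (as given), ISO-8601 timestamps, so that a
#' write/read round trip is the identity on valid tables.
#'
#' @param rows Data frame / tibble.
#' @param path Output CSV path; parent directories are created.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  out <- as.data.frame(rows)
  for (j in seq_along(out)) {
    if (inherits(out[[j]], "POSIXct")) {
      out[[j]] <- format(out[[j]], "%Y-%m-%dT%H:%M", tz = "UTC")
    }
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Retrieve row-level diagnostics from a reader result
#' @param x Object returned by [read_observations()] or [read_encounters()].
#' @return Tibble of diagnostics (line, field, message).
#' @export
diagnostics <- function(x) attr(x, "diagnostics")
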