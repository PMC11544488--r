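# Engine correctness against hand-computed band fixtures, the SpO2
# scale-switch rule, carry-forward rescoring, and monotone stress.

test_that("all-normal vitals score zero on every engine", {
  o <- obs_normal()
  expect_identical(mews_score(o), 0L)
  expect_identical(news_score(o), 0L)
  expect_identical(news2_score(o), 0L)
})

test_that("fully missing observations score NA; partial ones score documented components", {
  empty <- obs_row()
  expect_true(is.na(mews_score(empty)))
  expect_true(is.na(news_score(empty)))
  expect_true(is.na(news2_score(empty)))
  # a single documented component scores alone, missing ones contribute 0
  expect_identical(news_score(obs_row(heart_rate = 135)), 3L)
  expect_identical(mews_score(obs_row(consciousness = "U")), 3L)
})

test_that("worked multi-component examples match hand computation", {
  expect_identical(
    mews_score(obs_row(systolic_bp = 75, heart_rate = 115,
                       respiratory_rate = 22, temperature = 39,
                       consciousness = "V")), 9L)  # 2+2+2+2+1
  base <- list(respiratory_rate = 26, spo2 = 90, supplemental_o2 = FALSE,
               temperature = 36.5, systolic_bp = 85, heart_rate = 135,
               consciousness = "A")
  expect_identical(news_score(do.call(obs_row, base)), 12L)  # 3+3+0+0+3+3+0
  base$supplemental_o2 <- TRUE
  expect_identical(news_score(do.call(obs_row, base)), 14L)  # +2 for oxygen
})

test_that("NEWS band edges match the published table", {
  cases <- list(respiratory_rate = news_rr_cases, spo2 = news_spo2_cases,
                temperature = news_temp_cases, systolic_bp = news_sbp_cases,
                heart_rate = news_hr_cases)
  for (field in names(cases)) {
    for (v in names(cases[[field]])) {
      expect_equal(single_component_score("NEWS", field, as.numeric(v)),
                       unname(cases[[field]][v]),
                       label = sprintf("NEWS %s=%s", field, v))
    }
  }
  for (lvl in names(news_avpu_cases)) {
    expect_equal(single_component_score("NEWS", "consciousness", lvl),
                     unname(news_avpu_cases[lvl]))
  }
  expect_equal(single_component_score("NEWS", "supplemental_o2", TRUE), 2L)
  expect_equal(single_component_score("NEWS", "supplemental_o2", FALSE), 0L)
})

test_that("MEWS band edges match the published table", {
  cases <- list(systolic_bp = mews_sbp_cases, heart_rate = mews_hr_cases,
                respiratory_rate = mews_rr_cases, temperature = mews_temp_cases)
  for (field in names(cases)) {
    for (v in names(cases[[field]])) {
      expect_equal(single_component_score("MEWS", field, as.numeric(v)),
                       unname(cases[[field]][v]),
                       label = sprintf("MEWS %s=%s", field, v))
    }
  }
  for (lvl in names(mews_avpu_cases)) {
    expect_equal(single_component_score("MEWS", "consciousness", lvl),
                     unname(mews_avpu_cases[lvl]))
  }
})

test_that("NEWS2 SpO2 subscores follow scale 1, scale 2 air, and scale 2 oxygen bands", {
  for (v in names(news2_spo2_scale1_cases)) {
    expect_equal(single_component_score("NEWS2", "spo2", as.numeric(v)),
                     unname(news2_spo2_scale1_cases[v]),
                     label = sprintf("NEWS2 scale1 spo2=%s", v))
  }
  switched <- list(switch_time = at_hours(-1))
  for (v in names(news2_spo2_scale2_air_cases)) {
    got <- news2_score(obs_row(spo2 = as.numeric(v), supplemental_o2 = FALSE),
                       switched)
    expect_equal(got, unname(news2_spo2_scale2_air_cases[v]),
                     label = sprintf("NEWS2 scale2 air spo2=%s", v))
  }
  for (v in names(news2_spo2_scale2_o2_cases)) {
    got <- news2_score(obs_row(spo2 = as.numeric(v), supplemental_o2 = TRUE),
                       switched)
    expect_equal(got, unname(news2_spo2_scale2_o2_cases[v]) + 2L,
                     label = sprintf("NEWS2 scale2 O2 spo2=%s", v))
  }
})

test_that("scale switch requires PaCO2 > 45 with concurrent FiO2 > 21", {
  # no blood gas ever -> no switch, scale 1 persists
  obs <- dplyr::bind_rows(obs_normal("e1", 0), obs_normal("e1", 4))
  expect_true(is.na(compute_spo2_scale_state(obs)$switch_time))
  # qualifying gas -> switch at that time
  obs <- dplyr::bind_rows(
    obs_normal("e1", 0),
    obs_normal("e1", 10, paco2 = 50, fio2 = 40, supplemental_o2 = TRUE),
    obs_normal("e1", 12))
  expect_equal(compute_spo2_scale_state(obs)$switch_time, at_hours(10))
  # PaCO2 48 on room air (FiO2 21) -> no switch
  obs_air <- dplyr::bind_rows(
    obs_normal("e1", 0),
    obs_normal("e1", 10, paco2 = 48, fio2 = 21))
  expect_true(is.na(compute_spo2_scale_state(obs_air)$switch_time))
  # carried-forward FiO2 counts as concurrent by default, not under strict mode
  obs_cf <- dplyr::bind_rows(
    obs_normal("e1", 9, fio2 = 30, supplemental_o2 = TRUE),
    obs_normal("e1", 10, paco2 = 50))
  expect_equal(compute_spo2_scale_state(obs_cf)$switch_time, at_hours(10))
  expect_true(is.na(compute_spo2_scale_state(obs_cf, strict_simultaneous = TRUE)$switch_time))
})

test_that("scale 2 applies from the switch time through discharge", {
  obs <- dplyr::bind_rows(
    obs_row("e1", 0, spo2 = 90, supplemental_o2 = FALSE),
    obs_row("e1", 10, spo2 = 90, supplemental_o2 = FALSE, paco2 = 48, fio2 = 28),
    obs_row("e1", 20, spo2 = 90, supplemental_o2 = FALSE))
  s <- score_stream(obs, "NEWS2")
  # before switch: scale 1 gives spo2 90 -> 3; at/after switch scale 2 -> 0
  expect_equal(s$value[s$time == at_hours(0)], 3)
  expect_equal(s$value[s$time == at_hours(10)], 0)
  expect_equal(s$value[s$time == at_hours(20)], 0)
})

test_that("score streams rescore with carried-forward vitals", {
  obs <- dplyr::bind_rows(
    obs_row("e1", 0, respiratory_rate = 26, heart_rate = 70),
    obs_row("e1", 2, heart_rate = 135))
  s <- score_stream(obs, "NEWS")
  expect_equal(nrow(s), 2)
  expect_equal(s$value, c(3, 6))  # t2 keeps RR 26 (3) and adds HR 135 (3)
  # single fully-populated observation -> one point
  expect_equal(nrow(score_stream(obs_normal("e9"), "NEWS")), 1)
  # all-missing encounter -> empty series
  expect_equal(nrow(score_stream(obs_row("e8"), "NEWS")), 0)
})

test_that("worsening one vital never lowers the total score", {
  set.seed(42)
  grids <- list(
    respiratory_rate = c(16, 22, 26, 30),
    spo2 = c(98, 95, 93, 90),
    systolic_bp = c(120, 105, 95, 80),
    heart_rate = c(80, 100, 120, 140),
    temperature = c(37, 38.5, 39.5)
  )
  for (engine in c("MEWS", "NEWS", "NEWS2")) {
    scorer <- switch(engine, MEWS = mews_score, NEWS = news_score,
                     NEWS2 = function(o) news2_score(o, NULL))
    for (field in names(grids)) {
      prev <- -Inf
      for (v in grids[[field]]) {
        o <- obs_normal()
        o[[field]] <- v
        cur <- scorer(o)
        expect_gte(cur, prev)
        prev <- cur
      }
    }
  }
})

test_that("external score adapter validates rows and honors declared polarity", {
  f <- tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(
    encounter_id = c("e1", "e1", "e2", "e2", "e3", "e1"),
    time = c("2023-06-01T08:00", "2023-06-01T09:00", "2023-06-01T08:00",
             "2023-06-01T10:00", "2023-06-01T08:00", "2023-06-01T11:00"),
    value = c("80", "40", "60", "55", "70", "oops")
  ), f, progress = FALSE)
  expect_warning(expect_warning(
    s <- external_score_adapter(f, "RI", "low_is_risk",
                                known_encounters = c("e1", "e2")),
    "rejected"), "unknown")
  expect_equal(nrow(s), 4)
  expect_identical(attr(s, "polarity"), "low_is_risk")
  expect_equal(length(unique(s$encounter_id)), 2)
})

test_that("band tables validate disjoint covering intervals", {
  bad <- tempfile(fileext = ".yaml")
  writeLines(c(
    "score_name: BAD", "source_version: x", "components:",
    "  heart_rate:", "    type: numeric", "    range: [0, .inf]",
    "    bands:",
    "      - {interval: \"[0,50)\", points: 1}",
    "      - {interval: \"[60,inf)\", points: 0}"
  ), bad)
  expect_error(load_band_table(bad), "disjoint and covering")
})
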