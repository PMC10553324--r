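cfg <- pd_config()

mk_feat <- function(...) window_features(...)

noon <- as.POSIXct("2024-03-01 12:15:00", tz = "")
night <- as.POSIXct("2024-03-01 23:15:00", tz = "")

test_that("classification precedence follows the eight-state rules", {
  # troublesome dyskinesia: overwhelming majority and max intensity > 2.5
  expect_state(mk_feat(dysk = list(detected = TRUE, fraction = 0.8),
                       max_dysk_intensity = 3.0, active_fraction = 0.9,
                       clock_midpoint = noon), cfg, "ON_TROUBLESOME_DYSK")
  # non-troublesome: majority with max in (0.5, 2.5]
  expect_state(mk_feat(dysk = list(detected = TRUE, fraction = 0.6),
                       max_dysk_intensity = 1.5, active_fraction = 0.9,
                       clock_midpoint = noon),
               cfg, "ON_NON_TROUBLESOME_DYSK")
  # not worn dominates everything
  expect_state(mk_feat(dysk = list(detected = TRUE, fraction = 0.9),
                       max_dysk_intensity = 3, worn_fraction = 0.4,
                       clock_midpoint = noon), cfg, "NOT_WORN")
  # inactivity splits on the clock
  expect_state(mk_feat(active_fraction = 0.05, clock_midpoint = night),
               cfg, "NIGHTTIME_INACTIVITY")
  expect_state(mk_feat(active_fraction = 0.05, clock_midpoint = noon),
               cfg, "DAYTIME_INACTIVITY")
  # OFF: bradykinesia/tremor predominance among active epochs
  expect_state(mk_feat(tremor_fraction = 0.4, brady_fraction = 0.35,
                       active_fraction = 0.8, clock_midpoint = noon),
               cfg, "OFF")
  # ON: active, no relevant tremor/brady, dyskinesia not impactful
  expect_state(mk_feat(active_fraction = 0.9, tremor_fraction = 0.05,
                       max_dysk_intensity = 0.3, clock_midpoint = noon),
               cfg, "ON")
  # leftovers are NOT_DETECTABLE (e.g. impactful dysk without majority)
  expect_state(mk_feat(dysk = list(detected = FALSE, fraction = 0.3),
                       max_dysk_intensity = 1.4, active_fraction = 0.9,
                       clock_midpoint = noon), cfg, "NOT_DETECTABLE")
})

test_that("intensity boundaries: 2.5 splits troublesome, 0.5 splits impactful", {
  base <- function(mx) mk_feat(dysk = list(detected = TRUE, fraction = 0.8),
                               max_dysk_intensity = mx,
                               active_fraction = 0.9, clock_midpoint = noon)
  expect_state(base(2.5), cfg, "ON_NON_TROUBLESOME_DYSK")  # boundary -> NTD
  expect_state(base(2.5 + 1e-9), cfg, "ON_TROUBLESOME_DYSK")
  # monotone: raising intensity can only go NTD -> TD, never back
  states <- vapply(seq(0.6, 4, by = 0.1),
                   function(m) classify_window(base(m), cfg), "")
  td_started <- FALSE
  for (s in states) {
    if (s == "ON_TROUBLESOME_DYSK") td_started <- TRUE
    if (td_started) expect_identical(s, "ON_TROUBLESOME_DYSK")
  }
  # 0.5 is the impactful threshold for plain ON
  on_base <- function(mx) mk_feat(active_fraction = 0.9,
                                  max_dysk_intensity = mx,
                                  clock_midpoint = noon)
  expect_state(on_base(0.5), cfg, "ON")
  expect_state(on_base(0.51), cfg, "NOT_DETECTABLE")
})

test_that("day/night inactivity split sits exactly at 06:00 and 22:00", {
  at <- function(h, m = 0) as.POSIXct(sprintf("2024-03-01 %02d:%02d:00",
                                              h, m), tz = "")
  inact <- function(t) classify_window(mk_feat(active_fraction = 0,
                                               clock_midpoint = t), cfg)
  expect_identical(inact(at(5, 59)), "NIGHTTIME_INACTIVITY")
  expect_identical(inact(at(6, 0)), "DAYTIME_INACTIVITY")   # [06:00,
  expect_identical(inact(at(21, 59)), "DAYTIME_INACTIVITY")
  expect_identical(inact(at(22, 0)), "NIGHTTIME_INACTIVITY") # 22:00)
})

test_that("classify_recording recovers a known schedule and yields one state per interval", {
  sc <- simulation_script(data.frame(
    kind = c("sleep", "normal_activity", "tremor", "dyskinesia_severe"),
    duration_s = rep(1800, 4), tremor_hz = c(NA, NA, 5, NA)),
    start_time = "2024-03-01T03:00:00", seed = 14)
  sim <- simulate_recording(sc)
  tl <- classify_recording(sim$recording)
  expect_equal(nrow(tl$intervals), 4)              # floor(2 h / 30 min)
  expect_identical(as.character(tl$intervals$state),
                   c("NIGHTTIME_INACTIVITY", "ON", "OFF",
                     "ON_TROUBLESOME_DYSK"))
  expect_identical(as.character(tl$intervals$state),
                   as.character(sim$truth$intervals$state))
  # every interval carries exactly one valid state
  expect_false(anyNA(tl$intervals$state))
})

test_that("an off-wrist recording classifies as NOT_WORN throughout", {
  sc <- simulation_script(data.frame(kind = "not_worn", duration_s = 3600),
                          seed = 4)
  sim <- simulate_recording(sc)
  tl <- classify_recording(sim$recording)
  expect_identical(as.character(tl$intervals$state), rep("NOT_WORN", 2))
})

test_that("snap_to_clock aligns the interval grid to :00/:30", {
  sc <- simulation_script(data.frame(kind = "rest", duration_s = 4500),
                          start_time = "2024-03-01T10:07:00", seed = 2)
  rec <- simulate_recording(sc)$recording
  tl <- classify_recording(rec, pd_config(states = list(snap_to_clock = TRUE)))
  expect_identical(format(tl$intervals$start[1], "%H:%M"), "10:30")
  expect_equal(nrow(tl$intervals), 1)
})

test_that("durations summary counts half-hour quanta and percentages", {
  states <- c(rep("OFF", 8), rep("ON", 30), rep("NIGHTTIME_INACTIVITY", 8),
              rep("NOT_WORN", 2))
  tl <- motor_timeline("2024-03-01T00:00:00", states)
  d <- summarize_durations(tl)
  expect_equal(d$hours[d$state == "OFF"], 4)       # 8 x 0.5 h
  expect_equal(sum(d$percent), 100)
  expect_equal(attr(d, "worn_percent"), 100 * 46 / 48)
  uni <- summarize_durations(motor_timeline("2024-03-01T00:00:00",
                                            rep("ON", 10)))
  expect_equal(uni$percent[uni$state == "ON"], 100)
})

test_that("dyskinesia score histogram uses the clinical bin edges", {
  # constant score 1.0 for 2 h of 30-min intervals
  expect_equal(dyskinesia_score_histogram(rep(1, 4), 1800),
               c("1" = 2, "2" = 0, "3" = 0, "4" = 0))
  expect_equal(sum(dyskinesia_score_histogram(rep(0.3, 10), 1800)), 0)
  expect_equal(dyskinesia_score_histogram(c(2, 3), 3600),
               c("1" = 0, "2" = 1, "3" = 1, "4" = 0))
  # edges: 1.5 belongs to score 1, 1.5001 to score 2; 0.5 not impactful
  expect_equal(unname(dyskinesia_score_histogram(c(0.5, 1.5, 2.5, 3.5, 4),
                                                 3600)),
               c(1, 1, 1, 1))
  expect_error(dyskinesia_score_histogram(c(1, 5)), "0, 4")
})

test_that("waking-day percentage uses a 16-hour denominator and caps", {
  expect_equal(waking_day_percent(4), 25)
  expect_equal(waking_day_percent(0), 0)
  expect_equal(waking_day_percent(16), 100)
  expect_equal(waking_day_percent(20), 100)        # capped
})

test_that("timeline CSV roundtrips states and grid", {
  tl <- motor_timeline("2024-03-01T00:00:00",
                       c("OFF", "ON", "NOT_WORN", "ON_TROUBLESOME_DYSK"))
  p <- file.path(tempdir(), "tl.csv")
  write_timeline_csv(tl, p)
  back <- read_timeline_csv(p)
  expect_identical(as.character(back$intervals$state),
                   as.character(tl$intervals$state))
  expect_equal(back$interval_s, 1800)
  expect_equal(back$start_time, tl$start_time)
})
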