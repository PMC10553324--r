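test_that("simulation is deterministic given script and seed", {
  sc <- day_script("fluctuating_day", seed = 5)
  a <- simulate_recording(sc)
  b <- simulate_recording(sc)
  expect_identical(a$recording$ax, b$recording$ax)
  expect_identical(a$recording$temperature$values,
                   b$recording$temperature$values)
  expect_identical(as.character(a$diary$entries),
                   as.character(b$diary$entries))
  d <- simulate_recording(day_script("fluctuating_day", seed = 6))
  expect_false(identical(a$recording$ax, d$recording$ax))
})

test_that("scripts validate kinds, durations, tremor frequency and length", {
  expect_error(simulation_script(data.frame(kind = "jogging",
                                            duration_s = 60)), "unknown")
  expect_error(simulation_script(data.frame(kind = "rest",
                                            duration_s = -5)), "positive")
  expect_error(simulation_script(data.frame(kind = "tremor",
                                            duration_s = 60,
                                            tremor_hz = 9)), "3, 7")
  expect_error(simulation_script(data.frame(kind = "rest",
                                            duration_s = 16 * 86400)),
               "15-day")
})

test_that("a 24-h script yields the full-length recording and 48-interval truth", {
  sim <- simulate_recording(day_script("fluctuating_day", seed = 1))
  expect_equal(length(sim$recording$ax), 24 * 3600 * 50)
  expect_equal(sim$recording$fs, 50)
  expect_equal(length(sim$recording$temperature$values), 86400)
  expect_equal(nrow(sim$truth$intervals), 48)
  expect_equal(length(sim$diary$entries), 48)
})

test_that("tremor segments place their spectral peak at the scripted frequency", {
  sc <- simulation_script(data.frame(kind = "tremor", duration_s = 300,
                                     tremor_hz = 5.2), seed = 8)
  rec <- simulate_recording(sc)$recording
  es <- segment_epochs(rec, 5)
  pk <- vapply(seq_len(length(es)), function(i)
    peak_frequency(compute_epoch_spectrum(get_epoch(es, i)), 0.5, 12),
    numeric(1))
  expect_true(all(pk >= 4.8 & pk <= 5.6))
})

test_that("each kind concentrates its power in its defining band", {
  bands <- list(tremor = c(3, 7), dyskinesia_severe = c(1, 8),
                bradykinesia = c(0.5, 3), normal_activity = c(0.5, 5))
  for (k in names(bands)) {
    sc <- simulation_script(data.frame(kind = k, duration_s = 120,
                                       tremor_hz = 5), seed = 31)
    rec <- simulate_recording(sc)$recording
    es <- segment_epochs(rec, 5)
    sp <- compute_epoch_spectrum(get_epoch(es, 10))
    in_band <- band_power(sp, bands[[k]][1], bands[[k]][2])
    total <- band_power(sp, 0.5, 12)
    expect_gt(in_band / total, 0.6)
  }
})

test_that("not-worn segments cool below the wear threshold and sit still", {
  sc <- simulation_script(data.frame(kind = c("rest", "not_worn"),
                                     duration_s = c(600, 1200)), seed = 9)
  sim <- simulate_recording(sc)
  temp <- sim$recording$temperature$values
  expect_gt(temp[500], 30)                      # worn and warm
  expect_lt(temp[600 + 330], 30)                # < T_wear after ~5 min off
  es <- segment_epochs(sim$recording, 5)
  e <- get_epoch(es, 300)                       # deep in the not-worn span
  expect_false(detect_wear_epoch(e))
})

test_that("dyskinesia amplitude tiers land on either side of the 2.5 cutoff", {
  cfg <- pd_config()
  for (k in c("dyskinesia_mild", "dyskinesia_severe")) {
    sc <- simulation_script(data.frame(kind = k, duration_s = 1800),
                            seed = 12)
    ef <- wristpd:::epoch_features(simulate_recording(sc)$recording, cfg)
    w <- wristpd:::dysk_window_from_powers(ef$feat$p13, ef$feat$p38,
                                           ef$feat$p18, cfg)
    expect_true(w$detected)
    if (k == "dyskinesia_mild") {
      expect_gt(w$max_intensity, 0.5)
      expect_lte(w$max_intensity, 2.5)
    } else {
      expect_gt(w$max_intensity, 2.5)
    }
  }
})

test_that("error-free diaries equal the class-mapped truth; errors flip entries", {
  sim <- simulate_recording(day_script("early_morning_off", seed = 3))
  mapped <- wristpd:::device_to_diary_class(sim$truth$intervals$state)
  mapped[is.na(mapped)] <- "MISSING"
  expect_identical(as.character(sim$diary$entries), mapped)
  noisy <- simulate_recording(day_script("early_morning_off", seed = 3),
                              epsilon = 0.5)
  expect_gt(sum(as.character(noisy$diary$entries) != mapped), 5)
})

test_that("preset days carry their clinical signatures", {
  # wearing-off: an OFF block of 1.5-2 h flanked by ON-side states
  tr <- simulate_recording(day_script("fluctuating_day", seed = 2))$truth
  st <- as.character(tr$intervals$state)
  r <- rle(st)
  off_runs <- which(r$values == "OFF")
  expect_true(any(r$lengths[off_runs] * 0.5 >= 1.5 &
                    r$lengths[off_runs] * 0.5 <= 2))
  # early-morning OFF confined to 06:00-09:00
  tr2 <- simulate_recording(day_script("early_morning_off", seed = 2))$truth
  off_idx <- which(as.character(tr2$intervals$state) == "OFF")
  hours <- (off_idx - 1) * 0.5
  expect_true(length(off_idx) > 0 && all(hours >= 6 & hours < 9))
  # non-fluctuating day never reports dyskinesia
  tr3 <- simulate_recording(day_script("nonfluctuating_day",
                                       seed = 2))$truth
  expect_false(any(grepl("DYSK", tr3$intervals$state)))
  # missed dose spends much more daytime OFF than full adherence
  off_h <- function(p) sum(as.character(simulate_recording(
    day_script(p, seed = 4))$truth$intervals$state) == "OFF") * 0.5
  expect_gt(off_h("missed_dose") - off_h("full_adherence"), 2)
})

test_that("fixture files round-trip through the package readers", {
  dir <- file.path(tempdir(), "fixtures")
  sc <- simulation_script(data.frame(
    kind = c("sleep", "tremor", "normal_activity"),
    duration_s = c(1800, 1800, 1800), tremor_hz = c(NA, 5, NA)), seed = 6)
  sim <- simulate_recording(sc)
  p <- file.path(tempdir(), "fix_rec.csv")
  write_recording_csv(sim$recording, p)
  back <- read_recording_csv(p)
  expect_equal(back$ax, sim$recording$ax, tolerance = 1e-7)
  expect_equal(back$temperature$fs, 1)
  paths <- make_fixture_day("nonfluctuating_day", seed = 1, dir = dir)
  expect_true(all(file.exists(paths)))
  expect_equal(length(read_diary_csv(paths["diary"])$entries), 48)
  expect_equal(nrow(read_timeline_csv(paths["truth"])$intervals), 48)
})
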