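cfg <- pd_config()

test_that("intensity maps anchor at 0.5 and 4.0 and clip monotonically", {
  m <- intensity_map(1e-3, 5e-2, "increasing")
  expect_equal(intensity_from_power(1e-3, m), 0.5)
  expect_equal(intensity_from_power(5e-2, m), 4.0)
  below <- intensity_from_power(c(6e-4, 8e-4, 9.5e-4), m)
  expect_true(all(below >= 0 & below < 0.5))
  expect_true(all(diff(below) > 0))                 # monotone below anchor
  expect_equal(intensity_from_power(1, m), 4)       # clipped above
  expect_equal(intensity_from_power(0, m), 0)
  expect_equal(intensity_from_power(1e-5, m), 0)    # far below: clipped
  d <- intensity_map(1e-4, 5e-3, "decreasing")
  expect_equal(intensity_from_power(1e-4, d), 4.0)  # low power = severe
  expect_equal(intensity_from_power(5e-3, d), 0.5)
  expect_error(intensity_from_power(NaN, m), "finite")
  expect_error(intensity_from_power(-1, m), "non-negative")
  expect_error(intensity_map(2, 1), "anchor")
})

test_that("supination-pronation tremor is detected; lookalikes are not", {
  sp <- compute_epoch_spectrum(tremor_epoch(f = 5, seed = 21), cfg = cfg)
  r <- detect_tremor_epoch(sp, cfg)
  expect_true(r$detected)
  expect_equal(r$peak_hz, 5, tolerance = 0.5)
  expect_true(r$intensity > 0 && r$intensity <= 4)

  # same power confined to the longitudinal axis: gate must reject
  set.seed(22)
  long <- make_epoch(x = sine_wave(5, A = 0.09) + rnorm(250, 0, 0.01) + 0.7,
                     y = rnorm(250, 0, 0.01), z = rnorm(250, 0, 0.01))
  rl <- detect_tremor_epoch(compute_epoch_spectrum(long, cfg = cfg), cfg)
  expect_false(rl$detected)
  expect_equal(rl$intensity, 0)

  # 2 Hz walking-band oscillation: peak outside 3-7 Hz
  walk <- make_epoch(x = sine_wave(2, A = 0.25) + 1,
                     y = sine_wave(2, A = 0.1, phase = 1),
                     z = sine_wave(2, A = 0.1, phase = 2))
  expect_false(detect_tremor_epoch(compute_epoch_spectrum(walk, cfg = cfg),
                                   cfg)$detected)

  # subthreshold power: not detected even with the right pattern
  faint <- compute_epoch_spectrum(tremor_epoch(A = 0.004, noise_sd = 0.001,
                                               seed = 3), cfg = cfg)
  expect_false(detect_tremor_epoch(faint, cfg)$detected)
})

test_that("injected tremor frequency is recovered across the band", {
  set.seed(77)
  hits <- 0; err <- c()
  for (i in 1:40) {
    f <- runif(1, 3.5, 6.5)
    r <- detect_tremor_epoch(
      compute_epoch_spectrum(tremor_epoch(f = f), cfg = cfg), cfg)
    if (r$detected) { hits <- hits + 1; err <- c(err, abs(r$peak_hz - f)) }
  }
  expect_gte(hits / 40, 0.95)
  expect_true(all(err <= 0.5))
})

test_that("posture gate needs upright gravity AND movement", {
  set.seed(8)
  move <- function() rnorm(250, 0, 0.02)
  standing <- make_epoch(1 + move(), 0.05 + move(), 0.05 + move())
  expect_identical(detect_posture_epoch(standing, cfg = cfg),
                   "upright_active")
  lying <- make_epoch(0.1 + move(), 0.95 + move(), 0.3 + move())
  expect_identical(detect_posture_epoch(lying, cfg = cfg), "other")
  still <- make_epoch(rep(1, 250), rnorm(250, 0, 0.001),
                      rnorm(250, 0, 0.001))
  expect_identical(detect_posture_epoch(still, cfg = cfg), "other")
})

test_that("bradykinesia requires upright posture and mid-range slow power", {
  mid <- make_spec(c_psd = band_psd(4e-4, 0.5, 3))  # ~1e-3 g^2 in band
  mid_p <- band_power(mid, 0.5, 3)
  expect_true(mid_p > cfg$detectors$brady$theta_low &&
              mid_p < cfg$detectors$brady$theta_high)
  r <- detect_bradykinesia_epoch(mid, "upright_active", cfg)
  expect_true(r$detected)
  expect_true(r$intensity > 0 && r$intensity <= 4)
  expect_false(detect_bradykinesia_epoch(mid, "other", cfg)$detected)
  # motionless: below the lower threshold
  lo <- make_spec(c_psd = band_psd(2e-5, 0.5, 3))
  expect_false(detect_bradykinesia_epoch(lo, "upright_active",
                                         cfg)$detected)
  # brisk movement: above the upper threshold
  hi <- make_spec(c_psd = band_psd(1e-2, 0.5, 3))
  expect_false(detect_bradykinesia_epoch(hi, "upright_active",
                                         cfg)$detected)
  bad <- pd_config()
  bad$detectors$brady$theta_low <- 1
  expect_error(detect_bradykinesia_epoch(mid, "upright_active", bad),
               "misordered")
  # intensity decreases as residual slow power grows toward theta_high
  p_seq <- c(3e-4, 8e-4, 3e-3)
  ints <- vapply(p_seq, function(lv)
    detect_bradykinesia_epoch(make_spec(c_psd = band_psd(lv / 2.5, 0.5, 3)),
                              "upright_active", cfg)$intensity, 0)
  expect_true(all(diff(ints) < 0))
})

test_that("dyskinesia windows need a dual-band majority; tremor cannot veto", {
  dysk_spec <- make_spec(c_psd = band_psd(1e-3, 1, 8))    # both bands hot
  quiet_spec <- make_spec(c_psd = band_psd(1e-6, 1, 8))
  tremor_spec <- make_spec(c_psd = band_psd(3e-3, 4.4, 5.2))  # 3-8 only
  w <- detect_dyskinesia_window(c(rep(list(dysk_spec), 8),
                                  rep(list(quiet_spec), 2)), cfg)
  expect_true(w$detected)
  expect_equal(w$fraction, 0.8)
  expect_true(w$max_intensity > 0.5)
  wq <- detect_dyskinesia_window(rep(list(quiet_spec), 6), cfg)
  expect_false(wq$detected)
  expect_equal(wq$max_intensity, 0)
  # two isolated tremor epochs inside a dyskinetic window change nothing
  wt <- detect_dyskinesia_window(c(rep(list(dysk_spec), 8),
                                   rep(list(tremor_spec), 2)), cfg)
  expect_true(wt$detected)
  expect_error(detect_dyskinesia_window(list(), cfg), "empty")
  expect_error(detect_dyskinesia_window(list(dysk_spec), cfg), "2 epochs")
})

test_that("dyskinesia decision is invariant to epoch order", {
  set.seed(9)
  specs <- lapply(1:12, function(i)
    make_spec(c_psd = band_psd(runif(1, 1e-6, 2e-3), 1, 8)))
  w1 <- detect_dyskinesia_window(specs, cfg)
  w2 <- detect_dyskinesia_window(specs[sample(12)], cfg)
  expect_equal(w1$detected, w2$detected)
  expect_equal(w1$fraction, w2$fraction)
  expect_equal(w1$max_intensity, w2$max_intensity)
})

test_that("wear detection uses temperature and/or movement", {
  set.seed(10)
  flat <- make_epoch(rnorm(250, 1, 5e-4), rnorm(250, 0, 5e-4),
                     rnorm(250, 0, 5e-4))
  expect_true(detect_wear_epoch(flat, temperature = 33, cfg = cfg))
  expect_false(detect_wear_epoch(flat, temperature = 26, cfg = cfg))
  moving <- make_epoch(rnorm(250, 1, 0.05), rnorm(250, 0, 0.05),
                       rnorm(250, 0, 0.05))
  expect_true(detect_wear_epoch(moving, temperature = NULL, cfg = cfg))
  expect_false(detect_wear_epoch(flat, temperature = NULL, cfg = cfg))
})

test_that("false tremor alarms stay rare on walking, rest and longitudinal epochs", {
  set.seed(55)
  n_fp <- 0; n_tot <- 0
  for (i in 1:20) {
    f0 <- runif(1, 1.6, 2.1)
    walk <- make_epoch(x = sine_wave(f0, A = 0.25) +
                         sine_wave(2 * f0, A = 0.04) + rnorm(250, 1, 0.02),
                       y = rnorm(250, 0, 0.02),
                       z = sine_wave(f0, A = 0.1, phase = 1) +
                         rnorm(250, 0, 0.02))
    rest <- make_epoch(rnorm(250, 0.7, 0.005), rnorm(250, 0.5, 0.005),
                       rnorm(250, 0.5, 0.005))
    lon <- make_epoch(x = sine_wave(runif(1, 3.5, 6.5), A = 0.09) +
                        rnorm(250, 0.7, 0.01),
                      y = rnorm(250, 0.5, 0.01), z = rnorm(250, 0.5, 0.01))
    for (ep in list(walk, rest, lon)) {
      n_tot <- n_tot + 1
      if (detect_tremor_epoch(compute_epoch_spectrum(ep, cfg = cfg),
                              cfg)$detected) n_fp <- n_fp + 1
    }
  }
  expect_lt(n_fp / n_tot, 0.05)
})
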