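#' Segment kinds understood by the simulator
#' @export
segment_kinds <- c("sleep", "rest", "normal_activity", "tremor",
                   "bradykinesia", "dyskinesia_mild", "dyskinesia_severe",
                   "not_worn")

# mapping of segment kind to the ground-truth motor state; inactivity is
# split by clock later
kind_to_state <- c(sleep = "INACTIVITY", rest = "INACTIVITY",
                   normal_activity = "ON", tremor = "OFF",
                   bradykinesia = "OFF",
                   dyskinesia_mild = "ON_NON_TROUBLESOME_DYSK",
                   dyskinesia_severe = "ON_TROUBLESOME_DYSK",
                   not_worn = "NOT_WORN")

#' Build a simulation script
#'
#' An ordered list of labelled segments from which a synthetic wrist
#' recording is generated.  Durations are in seconds; tremor segments may
#' carry a `tremor_hz` in [3, 7] (default 5) and any segment an
#' `amplitude` scale (default 1 multiplies the kind's calibrated tier).
#'
#' @param segments data frame with columns `kind`, `duration_s` and
#'   optionally `tremor_hz`, `amplitude`.
#' @param start_time recording start (`POSIXct` or ISO-8601 string).
#' @param seed integer seed; the whole simulation is deterministic given
#'   the script and seed.
#' @param subject_id opaque label.
#' @return A `"simulation_script"`.
#' @export
simulation_script <- function(segments, start_time = "2024-03-01T00:00:00",
                              seed = 1, subject_id = "sim") {
  stopifnot(is.data.frame(segments),
            all(c("kind", "duration_s") %in% names(segments)))
  if (!all(segments$kind %in% segment_kinds))
    stop("unknown segment kind(s): ",
         paste(setdiff(segments$kind, segment_kinds), collapse = ", "),
         call. = FALSE)
  if (any(segments$duration_s <= 0))
    stop("segment durations must be positive", call. = FALSE)
  if (sum(segments$duration_s) > 15 * 86400)
    stop("total duration exceeds the 15-day device limit", call. = FALSE)
  if (is.null(segments$tremor_hz)) segments$tremor_hz <- NA_real_
  segments$tremor_hz[segments$kind == "tremor" &
                       is.na(segments$tremor_hz)] <- 5
  bad_hz <- segments$kind == "tremor" &
    (segments$tremor_hz < 3 | segments$tremor_hz > 7)
  if (any(bad_hz))
    stop("tremor_hz must lie within [3, 7]", call. = FALSE)
  if (is.null(segments$amplitude)) segments$amplitude <- 1
  segments$amplitude[is.na(segments$amplitude)] <- 1
  structure(list(segments = segments, start_time = parse_time(start_time),
                 seed = as.integer(seed), subject_id = subject_id),
            class = "simulation_script")
}

#' @export
print.simulation_script <- function(x, ...) {
  cat(sprintf("<simulation_script> %d segments, %.2f h total, seed %d\n",
              nrow(x$segments), sum(x$segments$duration_s) / 3600, x$seed))
  invisible(x)
}

# run expr under a fixed seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

# derive a bounded per-segment substream seed (< 2^31)
segment_seed <- function(seed, i) {
  (abs(seed) %% 1000003L) * 1009L + i * 9176L + 17L
}

unit_vec <- function(v) v / sqrt(sum(v^2))

orientations <- list(
  upright = c(1, 0, 0),
  sitting = unit_vec(c(0.7, 0.5, 0.5)),
  lying1 = unit_vec(c(0.15, 0.95, 0.28)),
  lying2 = unit_vec(c(0.10, -0.90, 0.42)),
  lying3 = unit_vec(c(0.05, 0.50, 0.85)),
  table = c(0, 0, 1))

# band-limited Gaussian noise rescaled to an exact target sd
band_noise <- function(n, fs, lo, hi, sd_target) {
  if (n < 16 || sd_target <= 0) return(numeric(n))
  bf <- signal::butter(2, c(lo, hi) / (fs / 2), type = "pass")
  x <- as.numeric(signal::filter(bf$b, bf$a, stats::rnorm(n)))
  s <- stats::sd(x)
  if (s == 0) return(numeric(n))
  x * sd_target / s
}

# rare short movement bursts (sleep turns, fidgeting)
movement_bursts <- function(n, fs, rate_hz, sd_burst) {
  x <- numeric(n)
  k <- stats::rpois(1, rate_hz * n / fs)
  if (k == 0) return(x)
  starts <- sort(sample.int(n, k))
  for (s in starts) {
    len <- round(fs * stats::runif(1, 1, 3))
    j <- s:min(n, s + len - 1)
    x[j] <- x[j] + stats::rnorm(length(j), sd = sd_burst)
  }
  x
}

# generate one segment; returns list(x, y, z) in g including gravity
synth_segment <- function(kind, n, fs, tremor_hz = 5, amplitude = 1) {
  t <- (seq_len(n) - 1) / fs
  ax <- numeric(n); ay <- numeric(n); az <- numeric(n)
  ori <- switch(kind,
    normal_activity = , bradykinesia = orientations$upright,
    sleep = orientations[[sample(c("lying1", "lying2", "lying3"), 1)]],
    not_worn = orientations$table,
    orientations$sitting)
  white <- function(sd) if (sd > 0) stats::rnorm(n, sd = sd) else numeric(n)
  if (kind == "sleep" || kind == "rest") {
    sd0 <- 0.005
    ax <- white(sd0); ay <- white(sd0); az <- white(sd0)
    rate <- if (kind == "sleep") 1 / 600 else 1 / 300
    ax <- ax + movement_bursts(n, fs, rate, 0.05)
    ay <- ay + movement_bursts(n, fs, rate, 0.05)
  } else if (kind == "normal_activity") {
    f0 <- stats::runif(1, 1.7, 2.0)
    ph <- stats::runif(2, 0, 2 * pi)
    ax <- 0.25 * amplitude * sin(2 * pi * f0 * t + ph[1]) +
      0.04 * amplitude * sin(2 * pi * 2 * f0 * t + ph[2]) + white(0.02)
    ay <- white(0.02)
    az <- 0.10 * amplitude * sin(2 * pi * f0 * t + ph[1] + pi / 2) +
      white(0.02)
  } else if (kind == "tremor") {
    f <- tremor_hz + stats::runif(1, -0.15, 0.15)
    ph <- stats::runif(1, 0, 2 * pi)
    am <- 1 + 0.2 * sin(2 * pi * 0.1 * t + stats::runif(1, 0, 2 * pi))
    A <- 0.08 * amplitude
    # forearm rotation: transverse axes near quadrature, little on x
    ax <- 0.25 * A * am * sin(2 * pi * f * t + ph) + white(0.01)
    ay <- 0.70 * A * am * sin(2 * pi * f * t + ph + pi / 2) + white(0.01)
    az <- 0.55 * A * am * sin(2 * pi * f * t + ph + pi) + white(0.01)
  } else if (kind == "bradykinesia") {
    ax <- band_noise(n, fs, 0.5, 3, 0.015 * amplitude) + white(0.005)
    ay <- band_noise(n, fs, 0.5, 3, 0.015 * amplitude) + white(0.005)
    az <- band_noise(n, fs, 0.5, 3, 0.008 * amplitude) + white(0.005)
  } else if (kind == "dyskinesia_mild" || kind == "dyskinesia_severe") {
    sd_t <- if (kind == "dyskinesia_mild") 0.035 else 0.12
    sd_t <- sd_t * amplitude
    ax <- band_noise(n, fs, 1, 8, sd_t) + white(0.005)
    ay <- band_noise(n, fs, 1, 8, sd_t) + white(0.005)
    az <- band_noise(n, fs, 1, 8, sd_t) + white(0.005)
  } else if (kind == "not_worn") {
    ax <- white(0.001); ay <- white(0.001); az <- white(0.001)
  }
  list(x = ax + ori[1], y = ay + ori[2], z = az + ori[3])
}

# near-body temperature: exponential approach (tau = 2 min) to 33 C while
# worn, ambient 24 C while off-wrist; 1 Hz
synth_temperature <- function(kinds, durations, seed) {
  tau <- 120
  targets <- ifelse(kinds == "not_worn", 24, 33)
  n_tot <- sum(round(durations))
  temp <- numeric(n_tot)
  cur <- targets[1]
  pos <- 0
  for (s in seq_along(kinds)) {
    ns <- round(durations[s])
    tt <- targets[s]
    tv <- tt + (cur - tt) * exp(-(seq_len(ns)) / tau)
    temp[pos + seq_len(ns)] <- tv
    cur <- tv[ns]
    pos <- pos + ns
  }
  temp + stats::rnorm(n_tot, sd = 0.05)
}

#' Simulate a wrist recording with ground truth
#'
#' Generates a deterministic (given the seed) tri-axial 50 Hz recording
#' from a [simulation_script()], together with the ground-truth 30-minute
#' state timeline (majority segment kind per interval; inactivity split by
#' local clock) and a patient diary derived from the truth with an
#' optional per-interval error rate.
#'
#' Signal models per kind: tremor is an amplitude-modulated sinusoid at
#' `tremor_hz` placed mainly and near quadrature on the transverse axes
#' (forearm rotation) over a noise background; dyskinesia is band-limited
#' 1-8 Hz noise on all axes at a mild or severe amplitude tier;
#' bradykinesia is low-amplitude 0.5-3 Hz movement in an upright
#' orientation; normal activity carries a 1.7-2 Hz gait component plus
#' broadband noise; sleep/rest are near-floor noise with occasional
#' movement bursts; not-worn is the sensor noise floor with the
#' temperature decaying to ambient.
#'
#' @param script a `"simulation_script"`.
#' @param epsilon per-interval diary error rate in [0, 1]; 0 gives a diary
#'   identical to the class-mapped truth.
#' @param fs sampling rate, Hz.
#' @return List with `recording` (an `"accel_recording"` including a 1 Hz
#'   temperature channel), `truth` (a `"motor_timeline"`) and `diary`
#'   (a `"diary_timeline"`).
#' @export
simulate_recording <- function(script, epsilon = 0, fs = 50) {
  stopifnot(inherits(script, "simulation_script"),
            epsilon >= 0, epsilon <= 1)
  seg <- script$segments
  ns <- round(seg$duration_s * fs)
  parts <- vector("list", nrow(seg))
  for (i in seq_len(nrow(seg))) {
    parts[[i]] <- with_seed(segment_seed(script$seed, i),
      synth_segment(seg$kind[i], ns[i], fs,
                    tremor_hz = seg$tremor_hz[i],
                    amplitude = seg$amplitude[i]))
  }
  temp <- with_seed(segment_seed(script$seed, nrow(seg) + 1L),
                    synth_temperature(seg$kind, seg$duration_s, script$seed))
  rec <- accel_recording(
    start_time = script$start_time,
    ax = unlist(lapply(parts, `[[`, "x")),
    ay = unlist(lapply(parts, `[[`, "y")),
    az = unlist(lapply(parts, `[[`, "z")),
    fs = fs,
    temperature = list(fs = 1, values = temp),
    subject_id = script$subject_id)

  truth <- truth_timeline(script)
  diary <- truth_to_diary(truth, epsilon,
                          seed = segment_seed(script$seed, nrow(seg) + 2L))
  list(recording = rec, truth = truth, diary = diary)
}

# ground-truth timeline: majority segment kind per 30-minute interval
truth_timeline <- function(script, interval_s = 1800) {
  seg <- script$segments
  bounds <- c(0, cumsum(seg$duration_s))
  total <- bounds[length(bounds)]
  n_int <- floor(total / interval_s)
  states <- character(n_int)
  cfg <- pd_config()
  for (i in seq_len(n_int)) {
    a <- (i - 1) * interval_s; b <- i * interval_s
    ov <- pmax(0, pmin(b, bounds[-1]) - pmax(a, bounds[-length(bounds)]))
    per_kind <- tapply(ov, seg$kind, sum)   # majority kind in the interval
    kind <- names(per_kind)[which.max(per_kind)]
    st <- kind_to_state[[kind]]
    if (st == "INACTIVITY") {
      mid <- script$start_time + (a + b) / 2
      st <- if (is_daytime(mid, cfg)) "DAYTIME_INACTIVITY"
            else "NIGHTTIME_INACTIVITY"
    }
    states[i] <- st
  }
  motor_timeline(script$start_time, states, interval_s,
                 subject_id = script$subject_id)
}

truth_to_diary <- function(truth, epsilon = 0, seed = 1) {
  lab <- device_to_diary_class(truth$intervals$state)
  lab[is.na(lab)] <- "MISSING"
  if (epsilon > 0) {
    lab <- with_seed(seed, {
      flip <- stats::runif(length(lab)) < epsilon & lab != "MISSING"
      pool <- setdiff(diary_state_levels, "MISSING")
      lab[flip] <- vapply(lab[flip], function(cur)
        sample(setdiff(pool, cur), 1), character(1))
      lab
    })
  }
  diary_timeline(truth$start_time, lab, truth$interval_s)
}

# ---- preset day scripts ----------------------------------------------

seg_row <- function(kind, minutes, tremor_hz = NA, amplitude = 1)
  data.frame(kind = kind, duration_s = minutes * 60,
             tremor_hz = tremor_hz, amplitude = amplitude)

#' Preset 24-hour day scripts
#'
#' Named day profiles used throughout the tests and examples:
#' `fluctuating_day` (an ON day broken by a 1.5 h wearing-off OFF block
#' and dyskinetic afternoon phases), `early_morning_off` (OFF confined to
#' 06:00-08:30 before the first dose takes effect), `nonfluctuating_day`
#' (tremor/bradykinesia without dyskinesia), `full_adherence` (mild
#' dyskinesia from noon to evening, no OFF) and `missed_dose` (the same
#' day with a long afternoon OFF instead).
#'
#' @param profile preset name.
#' @param seed integer seed.
#' @param start_date calendar date (midnight start), ISO string.
#' @return A `"simulation_script"` covering 24 h on the 30-minute grid.
#' @export
day_script <- function(profile = c("fluctuating_day", "early_morning_off",
                                   "nonfluctuating_day", "full_adherence",
                                   "missed_dose"),
                       seed = 1, start_date = "2024-03-01") {
  profile <- match.arg(profile)
  segs <- switch(profile,
    fluctuating_day = rbind(
      seg_row("sleep", 390),                 # 00:00-06:30
      seg_row("normal_activity", 120),       # 06:30-08:30
      seg_row("tremor", 45, tremor_hz = 5),  # 08:30-09:15  OFF
      seg_row("bradykinesia", 45),           # 09:15-10:00  OFF
      seg_row("dyskinesia_mild", 150),       # 10:00-12:30
      seg_row("rest", 30),                   # 12:30-13:00
      seg_row("normal_activity", 240),       # 13:00-17:00
      seg_row("bradykinesia", 45),           # 17:00-17:45  wearing-off
      seg_row("tremor", 45, tremor_hz = 4.5),# 17:45-18:30  wearing-off
      seg_row("dyskinesia_mild", 150),       # 18:30-21:00
      seg_row("normal_activity", 90),        # 21:00-22:30
      seg_row("sleep", 90)),                 # 22:30-24:00
    early_morning_off = rbind(
      seg_row("sleep", 360),                 # 00:00-06:00
      seg_row("tremor", 75, tremor_hz = 5.5),# 06:00-07:15  OFF
      seg_row("bradykinesia", 75),           # 07:15-08:30  OFF
      seg_row("normal_activity", 210),       # 08:30-12:00
      seg_row("dyskinesia_mild", 120),       # 12:00-14:00
      seg_row("normal_activity", 180),       # 14:00-17:00
      seg_row("dyskinesia_severe", 90),      # 17:00-18:30
      seg_row("normal_activity", 210),       # 18:30-22:00
      seg_row("sleep", 120)),                # 22:00-24:00
    nonfluctuating_day = rbind(
      seg_row("sleep", 420),                 # 00:00-07:00
      seg_row("normal_activity", 150),       # 07:00-09:30
      seg_row("tremor", 60, tremor_hz = 4),  # 09:30-10:30
      seg_row("normal_activity", 180),       # 10:30-13:30
      seg_row("rest", 60),                   # 13:30-14:30
      seg_row("bradykinesia", 60),           # 14:30-15:30
      seg_row("normal_activity", 270),       # 15:30-20:00
      seg_row("rest", 60),                   # 20:00-21:00
      seg_row("sleep", 180)),                # 21:00-24:00
    full_adherence = rbind(
      seg_row("sleep", 420),                 # 00:00-07:00
      seg_row("normal_activity", 300),       # 07:00-12:00
      seg_row("dyskinesia_mild", 240),       # 12:00-16:00
      seg_row("normal_activity", 180),       # 16:00-19:00
      seg_row("dyskinesia_mild", 120),       # 19:00-21:00
      seg_row("normal_activity", 60),        # 21:00-22:00
      seg_row("sleep", 120)),                # 22:00-24:00
    missed_dose = rbind(
      seg_row("sleep", 420),                 # 00:00-07:00
      seg_row("normal_activity", 300),       # 07:00-12:00
      seg_row("bradykinesia", 120),          # 12:00-14:00  OFF
      seg_row("tremor", 120, tremor_hz = 5), # 14:00-16:00  OFF
      seg_row("bradykinesia", 90),           # 16:00-17:30  OFF
      seg_row("tremor", 90, tremor_hz = 4.5),# 17:30-19:00  OFF
      seg_row("normal_activity", 180),       # 19:00-22:00
      seg_row("sleep", 120)))                # 22:00-24:00
  simulation_script(segs, start_time = paste0(start_date, "T00:00:00"),
                    seed = seed, subject_id = profile)
}

#' Write a preset fixture day to disk
#'
#' Simulates a preset day and writes the recording CSV (with temperature
#' sidecar), the ground-truth timeline CSV and the diary CSV.
#'
#' @param profile preset name, see [day_script()].
#' @param seed integer seed.
#' @param dir output directory (created if needed).
#' @param epsilon diary error rate.
#' @return Named character vector of the written paths.
#' @export
make_fixture_day <- function(profile, seed = 1, dir = tempdir(),
                             epsilon = 0) {
  sim <- simulate_recording(day_script(profile, seed), epsilon = epsilon)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  base <- file.path(dir, paste0(profile, "_seed", seed))
  paths <- c(recording = paste0(base, "_recording.csv"),
             truth = paste0(base, "_truth.csv"),
             diary = paste0(base, "_diary.csv"))
  write_recording_csv(sim$recording, paths["recording"])
  write_timeline_csv(sim$truth, paths["truth"])
  write_diary_csv(sim$diary, paths["diary"])
  paths
}
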