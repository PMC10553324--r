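#' The eight motor states
#'
#' Ordered level set used by the 30-minute classifier: `OFF`, `ON`,
#' `ON_NON_TROUBLESOME_DYSK`, `ON_TROUBLESOME_DYSK`, `DAYTIME_INACTIVITY`,
#' `NIGHTTIME_INACTIVITY`, `NOT_WORN`, `NOT_DETECTABLE`.
#'
#' @export
motor_state_levels <- c("OFF", "ON", "ON_NON_TROUBLESOME_DYSK",
                        "ON_TROUBLESOME_DYSK", "DAYTIME_INACTIVITY",
                        "NIGHTTIME_INACTIVITY", "NOT_WORN",
                        "NOT_DETECTABLE")

#' Aggregated features of one 30-minute window
#'
#' Convenience constructor mainly used for testing the classification
#' rules in isolation; [classify_recording()] builds these internally.
#'
#' @param dysk list as returned by [detect_dyskinesia_window()] (fields
#'   `detected`, `fraction`; missing fields default to "no dyskinesia").
#' @param tremor_fraction,brady_fraction shares of *active* epochs with
#'   tremor / bradykinesia detected.
#' @param active_fraction,worn_fraction shares of all epochs in the window.
#' @param max_dysk_intensity maximum gated dyskinesia intensity, [0, 4].
#' @param clock_midpoint `POSIXct` midpoint of the window (local clock).
#' @return A `"window_features"` list.
#' @export
window_features <- function(dysk = list(detected = FALSE, fraction = 0),
                            tremor_fraction = 0, brady_fraction = 0,
                            active_fraction = 0, worn_fraction = 1,
                            max_dysk_intensity = 0,
                            clock_midpoint = as.POSIXct("2024-01-01 12:00:00",
                                                        tz = "")) {
  fr <- c(tremor_fraction, brady_fraction, active_fraction, worn_fraction,
          dysk$fraction %||% 0)
  stopifnot(all(fr >= 0), all(fr <= 1),
            max_dysk_intensity >= 0, max_dysk_intensity <= 4)
  structure(list(dysk = dysk, tremor_fraction = tremor_fraction,
                 brady_fraction = brady_fraction,
                 active_fraction = active_fraction,
                 worn_fraction = worn_fraction,
                 max_dysk_intensity = max_dysk_intensity,
                 clock_midpoint = clock_midpoint),
            class = "window_features")
}

clock_hour <- function(t) {
  lt <- as.POSIXlt(t)
  lt$hour + lt$min / 60 + lt$sec / 3600
}

is_daytime <- function(t, cfg) {
  h <- clock_hour(t)
  h >= cfg$states$day_start & h < cfg$states$day_end   # [06:00, 22:00)
}

#' Classify one 30-minute window into a motor state
#'
#' Deterministic precedence: (1) `NOT_WORN` when the device was off-wrist
#' for at least half the window; (2) `ON_TROUBLESOME_DYSK` when dyskinesia
#' covers an overwhelming majority (`q_over`) of epochs with maximum
#' intensity above 2.5; (3) `ON_NON_TROUBLESOME_DYSK` when dyskinesia
#' covers a majority with maximum intensity in (0.5, 2.5]; (4) daytime or
#' nighttime inactivity when too few epochs are active, split at the
#' configured day window on the local clock; (5) `OFF` when bradykinesia
#' plus tremor predominate among active epochs and exceed the dyskinetic
#' fraction; (6) `ON` when activity is present without relevant
#' bradykinesia/tremor and dyskinesia is not impactful (max intensity
#' at most 0.5); (7) `NOT_DETECTABLE` otherwise.  A window with maximum
#' intensity exactly 2.5 is non-troublesome.
#'
#' @param f a [window_features()] object.
#' @param cfg a [pd_config()] list.
#' @return One of [motor_state_levels].
#' @export
classify_window <- function(f, cfg = pd_config()) {
  st <- cfg$states; dk <- cfg$detectors$dysk
  dfrac <- f$dysk$fraction %||% 0
  ddet <- isTRUE(f$dysk$detected)
  if (f$worn_fraction < 0.5) return("NOT_WORN")
  if (ddet && dfrac >= dk$q_over && f$max_dysk_intensity > 2.5)
    return("ON_TROUBLESOME_DYSK")
  if (ddet && f$max_dysk_intensity > 0.5 && f$max_dysk_intensity <= 2.5)
    return("ON_NON_TROUBLESOME_DYSK")
  if (f$active_fraction < st$a_min)
    return(if (is_daytime(f$clock_midpoint, cfg)) "DAYTIME_INACTIVITY"
           else "NIGHTTIME_INACTIVITY")
  tb <- f$tremor_fraction + f$brady_fraction
  if (tb > st$p_off && tb > dfrac) return("OFF")
  if (tb <= st$p_off && f$max_dysk_intensity <= 0.5) return("ON")
  "NOT_DETECTABLE"
}

#' Classify a whole recording into a motor-state timeline
#'
#' The full pipeline: epoch segmentation, gravity removal, per-epoch Welch
#' spectra, tremor/bradykinesia/dyskinesia/wear detection, aggregation
#' into 30-minute windows and state classification.  This is the central
#' entry point of the package.
#'
#' @param rec an `"accel_recording"` of at least one interval
#'   (default 30 min).
#' @param cfg a [pd_config()] list.
#' @return A `"motor_timeline"`: `$intervals` (one row per 30-minute
#'   interval: `start`, `state`, `max_dysk_intensity`,
#'   `mean_tremor_intensity`, `mean_brady_intensity`, `worn_fraction`,
#'   `active_fraction`, `tremor_fraction`, `brady_fraction`,
#'   `dysk_fraction`), `$epochs` (per-epoch intensity traces) and the
#'   configuration used.
#' @examples
#' \donttest{
#' day <- simulate_recording(day_script("fluctuating_day", seed = 1))
#' tl <- classify_recording(day$recording)
#' summary(tl)
#' }
#' @export
classify_recording <- function(rec, cfg = pd_config()) {
  stopifnot(inherits(rec, "accel_recording"))
  ef <- epoch_features(rec, cfg)
  f <- ef$feat
  interval_s <- cfg$states$interval_s
  m <- interval_s / ef$epoch_s
  if (m != round(m))
    stop("interval_s must be a multiple of the epoch length", call. = FALSE)
  offset_epochs <- 0L
  start0 <- ef$start_time
  if (isTRUE(cfg$states$snap_to_clock)) {
    into <- as.numeric(start0) %% interval_s
    if (into > 0) {
      skip_s <- interval_s - into
      offset_epochs <- ceiling(skip_s / ef$epoch_s)
      start0 <- start0 + offset_epochs * ef$epoch_s
    }
  }
  n_int <- floor((ef$n - offset_epochs) / m)
  if (n_int < 1)
    stop("recording shorter than one classification interval",
         call. = FALSE)
  rows <- vector("list", n_int)
  for (i in seq_len(n_int)) {
    idx <- offset_epochs + (i - 1L) * m + seq_len(m)
    w <- f[idx, ]
    n_active <- sum(w$active)
    dysk <- dysk_window_from_powers(w$p13, w$p38, w$p18, cfg)
    feats <- window_features(
      dysk = dysk,
      tremor_fraction = sum(w$tremor & w$active) / max(1, n_active),
      brady_fraction = sum(w$brady & w$active) / max(1, n_active),
      active_fraction = mean(w$active),
      worn_fraction = mean(w$worn),
      max_dysk_intensity = dysk$max_intensity,
      clock_midpoint = start0 + (i - 0.5) * interval_s)
    rows[[i]] <- data.frame(
      start = start0 + (i - 1) * interval_s,
      state = classify_window(feats, cfg),
      max_dysk_intensity = dysk$max_intensity,
      mean_tremor_intensity = mean(w$tremor_intensity),
      mean_brady_intensity = mean(w$brady_intensity),
      worn_fraction = feats$worn_fraction,
      active_fraction = feats$active_fraction,
      tremor_fraction = feats$tremor_fraction,
      brady_fraction = feats$brady_fraction,
      dysk_fraction = dysk$fraction)
  }
  intervals <- do.call(rbind, rows)
  intervals$state <- factor(intervals$state, levels = motor_state_levels)
  structure(list(start_time = start0, interval_s = interval_s,
                 intervals = intervals,
                 epochs = f[, c("t0", "tremor_intensity", "brady_intensity",
                                "dysk_intensity", "worn", "active")],
                 subject_id = rec$subject_id, cfg = cfg),
            class = "motor_timeline")
}

#' Construct a motor-state timeline directly from labels
#'
#' Used for ground-truth timelines and for reading timelines back from
#' CSV; carries no intensity traces.
#'
#' @param start_time interval-grid origin (`POSIXct` or ISO-8601 string).
#' @param states character vector of [motor_state_levels] values.
#' @param interval_s interval length, s.
#' @param subject_id opaque label.
#' @return A `"motor_timeline"`.
#' @export
motor_timeline <- function(start_time, states, interval_s = 1800,
                           subject_id = "unknown") {
  start_time <- parse_time(start_time)
  if (!all(states %in% motor_state_levels))
    stop("unknown motor state label(s): ",
         paste(setdiff(states, motor_state_levels), collapse = ", "),
         call. = FALSE)
  intervals <- data.frame(
    start = start_time + (seq_along(states) - 1) * interval_s,
    state = factor(states, levels = motor_state_levels))
  structure(list(start_time = start_time, interval_s = interval_s,
                 intervals = intervals, epochs = NULL,
                 subject_id = subject_id, cfg = NULL),
            class = "motor_timeline")
}

#' @export
print.motor_timeline <- function(x, ...) {
  n <- nrow(x$intervals)
  cat(sprintf("<motor_timeline> %d intervals of %g min from %s\n",
              n, x$interval_s / 60, format_time(x$start_time)))
  print(table(x$intervals$state))
  invisible(x)
}

#' @export
summary.motor_timeline <- function(object, ...) {
  summarize_durations(object)
}

#' @export
as.data.frame.motor_timeline <- function(x, ...) x$intervals

#' Per-state durations and percentages
#'
#' Hours per motor state (in half-hour quanta) and percentage of the
#' timeline span, plus the worn percentage (share of intervals not
#' classified `NOT_WORN`).
#'
#' @param tl a `"motor_timeline"`.
#' @return A data frame (class `"state_durations"`) with columns `state`,
#'   `hours`, `percent`; the worn percentage is attached as attribute
#'   `worn_percent`.
#' @export
summarize_durations <- function(tl) {
  stopifnot(inherits(tl, "motor_timeline"))
  counts <- table(tl$intervals$state)
  hours <- as.numeric(counts) * tl$interval_s / 3600
  out <- data.frame(state = names(counts), hours = hours,
                    percent = 100 * as.numeric(counts) /
                      nrow(tl$intervals))
  attr(out, "worn_percent") <-
    100 * mean(tl$intervals$state != "NOT_WORN")
  class(out) <- c("state_durations", "data.frame")
  out
}

#' @export
print.state_durations <- function(x, ...) {
  df <- as.data.frame(x)
  df$hours <- sprintf("%.1f", df$hours)
  df$percent <- sprintf("%.1f%%", df$percent)
  print(df, row.names = FALSE)
  cat(sprintf("worn: %.1f%% of intervals\n", attr(x, "worn_percent")))
  invisible(x)
}

#' Time spent per dyskinesia score
#'
#' Bins a dyskinesia intensity trace into the four clinical score classes:
#' score 1 covers intensities in (0.5, 1.5], score 2 (1.5, 2.5], score 3
#' (2.5, 3.5], score 4 (3.5, 4].  Intensities at or below 0.5 are treated
#' as not impactful and excluded.
#'
#' @param intensity numeric trace of dyskinesia intensities in [0, 4].
#' @param interval_s duration each trace value represents, s.
#' @return Named numeric vector of hours for scores `"1"`..`"4"`.
#' @export
dyskinesia_score_histogram <- function(intensity, interval_s = 1800) {
  if (any(!is.finite(intensity)) || any(intensity < 0) ||
      any(intensity > 4))
    stop("intensity values must lie in [0, 4]", call. = FALSE)
  edges <- c(0.5, 1.5, 2.5, 3.5, 4)
  counts <- vapply(seq_len(4), function(k)
    sum(intensity > edges[k] & intensity <= edges[k + 1]), numeric(1))
  stats::setNames(counts * interval_s / 3600, as.character(1:4))
}

#' Percentage of the waking day
#'
#' Expresses a duration with impactful dyskinesia as a percentage of a
#' 16-hour waking day (capped at 100).
#'
#' @param impactful_hours hours with impactful dyskinesia, in [0, 24].
#' @param waking_day_h waking-day denominator, h.
#' @return Percentage in [0, 100].
#' @export
waking_day_percent <- function(impactful_hours, waking_day_h = 16) {
  stopifnot(impactful_hours >= 0, impactful_hours <= 24, waking_day_h > 0)
  min(100, 100 * impactful_hours / waking_day_h)
}

#' Write a state timeline to CSV
#'
#' @param tl a `"motor_timeline"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_timeline_csv <- function(tl, path) {
  df <- tl$intervals
  df$interval_start <- format_time(df$start)
  keep <- intersect(c("interval_start", "state", "max_dysk_intensity",
                      "mean_tremor_intensity", "mean_brady_intensity",
                      "worn_fraction"), names(df))
  utils::write.csv(df[, keep], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a state timeline from CSV
#'
#' @param path CSV written by [write_timeline_csv()].
#' @return A `"motor_timeline"` (without epoch traces).
#' @export
read_timeline_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("interval_start", "state") %in% names(df)))
    stop("timeline CSV needs interval_start and state columns",
         call. = FALSE)
  starts <- as.POSIXct(sub("T", " ", df$interval_start), tz = "")
  interval_s <- if (nrow(df) > 1)
    as.numeric(difftime(starts[2], starts[1], units = "secs")) else 1800
  tl <- motor_timeline(starts[1], as.character(df$state), interval_s)
  extra <- setdiff(names(df), c("interval_start", "state"))
  for (nm in extra) tl$intervals[[nm]] <- df[[nm]]
  tl
}
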