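#' Wrist accelerometer recording
#'
#' Container for a time-anchored tri-axial wrist acceleration recording in
#' units of g, with optional lower-rate near-body temperature and
#' illuminance channels.  The device convention is that the x axis runs
#' along the forearm (longitudinal) and y/z are transverse; with the arm
#' hanging in a standing posture gravity therefore loads mainly on x.
#'
#' @param start_time recording start as `POSIXct` (local clock) or an
#'   ISO-8601 string such as `"2024-03-01T00:00:00"`.
#' @param ax,ay,az equal-length numeric acceleration series, in g.
#' @param fs sampling rate in Hz (default 50).
#' @param temperature optional `list(fs =, values =)` near-body temperature
#'   channel in degrees Celsius.
#' @param lux optional `list(fs =, values =)` illuminance channel.
#' @param subject_id opaque subject label.
#' @param axis_convention axis-orientation flag; only
#'   `"x_longitudinal"` is defined.
#' @return An object of class `"accel_recording"`.
#' @export
accel_recording <- function(start_time, ax, ay, az, fs = 50,
                            temperature = NULL, lux = NULL,
                            subject_id = "unknown",
                            axis_convention = "x_longitudinal") {
  start_time <- parse_time(start_time)
  if (!is.numeric(fs) || length(fs) != 1 || !is.finite(fs) || fs <= 0)
    stop("fs must be a single positive number", call. = FALSE)
  n <- length(ax)
  if (n < 1 || length(ay) != n || length(az) != n)
    stop("axis series must have equal length >= 1", call. = FALSE)
  for (ch in list(ax, ay, az))
    if (!all(is.finite(ch)))
      stop("non-finite acceleration samples present", call. = FALSE)
  dur <- n / fs
  for (aux_name in c("temperature", "lux")) {
    aux <- get(aux_name)
    if (!is.null(aux)) {
      if (!is.list(aux) || is.null(aux$fs) || is.null(aux$values))
        stop(aux_name, " must be list(fs =, values =)", call. = FALSE)
      aux_dur <- length(aux$values) / aux$fs
      if (abs(aux_dur - dur) > max(1 / fs, 1 / aux$fs) + 1e-9)
        stop(aux_name, " channel does not cover the recording span",
             call. = FALSE)
    }
  }
  structure(list(start_time = start_time, fs = fs,
                 ax = as.numeric(ax), ay = as.numeric(ay),
                 az = as.numeric(az),
                 temperature = temperature, lux = lux,
                 subject_id = subject_id,
                 axis_convention = axis_convention),
            class = "accel_recording")
}

parse_time <- function(x) {
  if (inherits(x, "POSIXct")) return(x)
  t <- as.POSIXct(sub("T", " ", as.character(x)), tz = "",
                  tryFormats = c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M",
                                 "%Y-%m-%d"))
  if (is.na(t)) stop("cannot parse timestamp: ", x, call. = FALSE)
  t
}

format_time <- function(t) format(t, "%Y-%m-%dT%H:%M:%S")

#' @export
print.accel_recording <- function(x, ...) {
  n <- length(x$ax)
  cat(sprintf("<accel_recording> subject %s: %.2f h at %g Hz (%d samples/axis)\n",
              x$subject_id, n / x$fs / 3600, x$fs, n))
  cat("  start:", format_time(x$start_time))
  cat(";  channels: ax ay az",
      if (!is.null(x$temperature)) "temperature",
      if (!is.null(x$lux)) "lux", "\n")
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec an `"accel_recording"`.
#' @return Duration in seconds.
#' @export
recording_duration <- function(rec) length(rec$ax) / rec$fs

#' Write a recording to CSV
#'
#' One row per sample with columns `time_s, ax_g, ay_g, az_g`, preceded by
#' `#`-prefixed header lines carrying `fs`, `start_time` (ISO-8601, local
#' clock), `subject_id` and `axis_convention`.  Optional temperature and
#' lux channels go to sidecar files `<base>_temp.csv` / `<base>_lux.csv`
#' with their own rate in the header.  Values are written with enough
#' digits to round-trip losslessly.
#'
#' @param rec an `"accel_recording"`.
#' @param path output path for the acceleration CSV.
#' @return `path`, invisibly.
#' @export
write_recording_csv <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# fs: ", format(rec$fs, digits = 15)),
    paste0("# start_time: ", format_time(rec$start_time)),
    paste0("# subject_id: ", rec$subject_id),
    paste0("# axis_convention: ", rec$axis_convention),
    "time_s,ax_g,ay_g,az_g"), con)
  n <- length(rec$ax)
  t <- (seq_len(n) - 1) / rec$fs
  writeLines(paste(format(t, digits = 10, trim = TRUE, scientific = FALSE),
                   format(rec$ax, digits = 9, trim = TRUE),
                   format(rec$ay, digits = 9, trim = TRUE),
                   format(rec$az, digits = 9, trim = TRUE), sep = ","), con)
  for (aux_name in c("temperature", "lux")) {
    aux <- rec[[aux_name]]
    side <- sidecar_path(path, aux_name)
    if (is.null(aux)) {
      if (file.exists(side)) unlink(side)
      next
    }
    sc <- file(side, "w")
    writeLines(c(paste0("# fs: ", format(aux$fs, digits = 15)),
                 paste0("time_s,", if (aux_name == "temperature") "temp_c"
                        else "lux")), sc)
    ts <- (seq_along(aux$values) - 1) / aux$fs
    writeLines(paste(format(ts, digits = 10, trim = TRUE, scientific = FALSE),
                     format(aux$values, digits = 9, trim = TRUE), sep = ","),
               sc)
    close(sc)
  }
  invisible(path)
}

sidecar_path <- function(path, aux_name) {
  suffix <- if (aux_name == "temperature") "_temp" else "_lux"
  sub("(\\.[^.]+)?$", paste0(suffix, ".csv"), path, perl = TRUE)
}

read_hash_headers <- function(path, n_max = 10) {
  lines <- readLines(path, n = n_max)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([^:]+):\\s*(.*)$", h))[[1]]
    if (length(m) == 3) kv[[trimws(m[2])]] <- trimws(m[3])
  }
  list(kv = kv, n_header = length(hdr))
}

#' Read a recording from CSV
#'
#' Counterpart of [write_recording_csv()].  Sidecar temperature/lux files
#' are picked up automatically when present.
#'
#' @param path path to the acceleration CSV.
#' @param na_action `"reject"` (default) errors on non-finite samples;
#'   `"interpolate"` fills gaps of at most `max_gap_s` seconds linearly and
#'   errors on longer gaps.
#' @param max_gap_s maximum interpolatable gap, in seconds.
#' @return An `"accel_recording"`.
#' @export
read_recording_csv <- function(path, na_action = c("reject", "interpolate"),
                               max_gap_s = 0.2) {
  na_action <- match.arg(na_action)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  hd <- read_hash_headers(path)
  if (is.null(hd$kv$fs) || is.null(hd$kv$start_time))
    stop("recording header must declare fs and start_time", call. = FALSE)
  fs <- as.numeric(hd$kv$fs)
  if (!is.finite(fs) || fs <= 0)
    stop("invalid fs in header: ", hd$kv$fs, call. = FALSE)
  body <- utils::read.csv(path, skip = hd$n_header,
                          colClasses = "numeric")
  need <- c("ax_g", "ay_g", "az_g")
  if (!all(need %in% names(body)))
    stop("missing mandatory column(s): ",
         paste(setdiff(need, names(body)), collapse = ", "), call. = FALSE)
  ax <- body$ax_g; ay <- body$ay_g; az <- body$az_g
  if (na_action == "interpolate") {
    ax <- fill_gaps(ax, fs, max_gap_s)
    ay <- fill_gaps(ay, fs, max_gap_s)
    az <- fill_gaps(az, fs, max_gap_s)
  }
  aux <- list(temperature = NULL, lux = NULL)
  for (aux_name in names(aux)) {
    side <- sidecar_path(path, aux_name)
    if (file.exists(side)) {
      shd <- read_hash_headers(side)
      sb <- utils::read.csv(side, skip = shd$n_header)
      aux[[aux_name]] <- list(fs = as.numeric(shd$kv$fs),
                              values = as.numeric(sb[[2]]))
    }
  }
  accel_recording(start_time = hd$kv$start_time, ax = ax, ay = ay, az = az,
                  fs = fs, temperature = aux$temperature, lux = aux$lux,
                  subject_id = hd$kv$subject_id %||% "unknown",
                  axis_convention = hd$kv$axis_convention %||%
                    "x_longitudinal")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fill_gaps <- function(x, fs, max_gap_s) {
  bad <- !is.finite(x)
  if (!any(bad)) return(x)
  r <- rle(bad)
  if (any(r$values & r$lengths > max_gap_s * fs))
    stop("non-finite gap longer than ", max_gap_s, " s", call. = FALSE)
  if (all(bad)) stop("no finite samples to interpolate from", call. = FALSE)
  idx <- seq_along(x)
  stats::approx(idx[!bad], x[!bad], xout = idx, rule = 2)$y
}

#' Segment a recording into fixed-length epochs
#'
#' Splits the acceleration series into contiguous, non-overlapping epochs
#' of `epoch_s` seconds; a trailing partial epoch is discarded.  Epoch
#' samples are exact slices of the raw series.  The per-epoch mean of the
#' temperature channel (when present) is carried along for wear detection.
#'
#' @param rec an `"accel_recording"`.
#' @param epoch_s epoch duration in seconds; `epoch_s * fs` must be at
#'   least 8 samples.
#' @return An `"epoch_set"`: epoch matrices (`samples x epochs`) per axis,
#'   offsets `t0`, and per-epoch temperature means.  May hold zero epochs
#'   when the recording is shorter than one epoch.
#' @export
segment_epochs <- function(rec, epoch_s = 5) {
  stopifnot(inherits(rec, "accel_recording"))
  L <- round(epoch_s * rec$fs)
  if (L < 8) stop("epoch too short: need at least 8 samples", call. = FALSE)
  n <- floor(length(rec$ax) / L)
  take <- seq_len(n * L)
  es <- list(fs = rec$fs, epoch_s = epoch_s, L = L, n = n,
             t0 = (seq_len(n) - 1) * epoch_s,
             start_time = rec$start_time,
             x = matrix(rec$ax[take], nrow = L),
             y = matrix(rec$ay[take], nrow = L),
             z = matrix(rec$az[take], nrow = L),
             temp_mean = NULL)
  if (!is.null(rec$temperature) && n > 0) {
    tv <- rec$temperature$values
    Lt <- rec$temperature$fs * epoch_s
    nt <- floor(length(tv) / Lt)
    idx <- pmin(floor((seq_len(n) - 1) * Lt) + 1, length(tv))
    # per-epoch mean over the matching temperature span
    tm <- vapply(seq_len(n), function(i) {
      j0 <- floor((i - 1) * Lt) + 1
      j1 <- min(length(tv), max(j0, floor(i * Lt)))
      mean(tv[j0:j1])
    }, numeric(1))
    es$temp_mean <- tm
  }
  class(es) <- "epoch_set"
  es
}

#' @export
length.epoch_set <- function(x) x$n

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epochs of %g s at %g Hz (%d samples each)\n",
              x$n, x$epoch_s, x$fs, x$L))
  invisible(x)
}

#' Extract a single epoch
#'
#' @param es an `"epoch_set"` from [segment_epochs()].
#' @param i epoch index (1-based).
#' @return An `"epoch"` with fields `index`, `t0`, `duration`, `fs`, the
#'   three axis slices `x`, `y`, `z`, and `temp_mean` (or `NULL`).
#' @export
get_epoch <- function(es, i) {
  stopifnot(inherits(es, "epoch_set"), i >= 1, i <= es$n)
  structure(list(index = i, t0 = es$t0[i], duration = es$epoch_s,
                 fs = es$fs, x = es$x[, i], y = es$y[, i], z = es$z[, i],
                 temp_mean = if (is.null(es$temp_mean)) NULL
                             else es$temp_mean[i]),
            class = "epoch")
}
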