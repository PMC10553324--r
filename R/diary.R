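#' Diary states
#'
#' The four states a patient motor diary distinguishes on its 30-minute
#' grid, plus `MISSING` for intervals the patient left blank.
#' @export
diary_state_levels <- c("ASLEEP", "OFF", "ON_OR_ON_NTD", "ON_TD", "MISSING")

#' Patient diary timeline
#'
#' @param start_time grid origin (`POSIXct` or ISO-8601 string).
#' @param entries character vector of [diary_state_levels] values.
#' @param interval_s grid step, s (30 minutes).
#' @return A `"diary_timeline"`.
#' @export
diary_timeline <- function(start_time, entries, interval_s = 1800) {
  start_time <- parse_time(start_time)
  if (!all(entries %in% diary_state_levels))
    stop("unknown diary state(s): ",
         paste(setdiff(entries, diary_state_levels), collapse = ", "),
         call. = FALSE)
  structure(list(start_time = start_time, interval_s = interval_s,
                 entries = factor(entries, levels = diary_state_levels)),
            class = "diary_timeline")
}

#' @export
print.diary_timeline <- function(x, ...) {
  cat(sprintf("<diary_timeline> %d intervals of %g min from %s\n",
              length(x$entries), x$interval_s / 60,
              format_time(x$start_time)))
  print(table(x$entries))
  invisible(x)
}

normalize_diary_token <- function(tok) {
  t <- gsub("[ \\-]+", "_", tolower(trimws(tok)))
  if (t %in% c("", "na", "missing")) return("MISSING")
  if (t %in% c("asleep", "sleep", "sleeping")) return("ASLEEP")
  if (t == "off") return("OFF")
  if (t %in% c("on", "on_ntd", "on_or_on_ntd",
               "on_with_non_troublesome_dyskinesia",
               "on/on_with_non_troublesome_dyskinesia")) return("ON_OR_ON_NTD")
  if (t %in% c("on_td", "on_with_troublesome_dyskinesia")) return("ON_TD")
  stop("unknown diary state token: '", tok, "'", call. = FALSE)
}

#' Read a patient diary from CSV
#'
#' Expects columns `interval_start` (ISO-8601, local clock) and `state`.
#' Tokens are parsed case-insensitively (`on`, `ON`, `On with troublesome
#' dyskinesia`, ...).  Intervals absent between the first and last row
#' become `MISSING`; duplicated intervals are an error.
#'
#' @param path CSV path.
#' @return A `"diary_timeline"`.
#' @export
read_diary_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character")
  if (!all(c("interval_start", "state") %in% names(df)))
    stop("diary CSV needs interval_start and state columns", call. = FALSE)
  starts <- as.POSIXct(sub("T", " ", df$interval_start), tz = "")
  if (any(is.na(starts)))
    stop("unparsable interval_start value(s)", call. = FALSE)
  if (anyDuplicated(starts))
    stop("duplicate diary interval(s)", call. = FALSE)
  tokens <- vapply(df$state, normalize_diary_token, character(1))
  interval_s <- 1800
  grid <- seq(min(starts), max(starts), by = interval_s)
  off <- as.numeric(difftime(starts, grid[1], units = "secs"))
  if (any(off %% interval_s != 0))
    stop("diary rows are not on a 30-minute grid", call. = FALSE)
  entries <- rep("MISSING", length(grid))
  entries[off / interval_s + 1] <- tokens
  diary_timeline(grid[1], entries, interval_s)
}

#' Write a patient diary to CSV
#'
#' `MISSING` intervals are written with an empty state token so the file
#' round-trips through [read_diary_csv()].
#'
#' @param diary a `"diary_timeline"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_diary_csv <- function(diary, path) {
  starts <- diary$start_time +
    (seq_along(diary$entries) - 1) * diary$interval_s
  st <- as.character(diary$entries)
  st[st == "MISSING"] <- ""
  utils::write.csv(data.frame(interval_start = format_time(starts),
                              state = st),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# device -> diary class mapping; NA marks states excluded from comparison
device_to_diary_class <- function(states) {
  map <- c(OFF = "OFF", ON = "ON_OR_ON_NTD",
           ON_NON_TROUBLESOME_DYSK = "ON_OR_ON_NTD",
           ON_TROUBLESOME_DYSK = "ON_TD",
           DAYTIME_INACTIVITY = "ASLEEP", NIGHTTIME_INACTIVITY = "ASLEEP",
           NOT_WORN = NA, NOT_DETECTABLE = NA)
  unname(map[as.character(states)])
}

#' Pair diary and device timelines interval by interval
#'
#' Matches the two 30-minute grids over their overlapping span and keeps
#' only intervals that can be scored: the diary entry must not be
#' `MISSING` and the device state must not be `NOT_WORN` or
#' `NOT_DETECTABLE`.  Device states are mapped onto the diary's four
#' classes (both inactivity states count as asleep-equivalent, plain `ON`
#' and `ON_NON_TROUBLESOME_DYSK` merge into the diary's combined ON
#' class).
#'
#' @param diary a `"diary_timeline"`.
#' @param device a `"motor_timeline"`.
#' @return Data frame with columns `start`, `diary`, `device` (factors on
#'   the diary classes).
#' @export
align_timelines <- function(diary, device) {
  stopifnot(inherits(diary, "diary_timeline"),
            inherits(device, "motor_timeline"))
  if (diary$interval_s != device$interval_s)
    stop("diary and device use different interval lengths", call. = FALSE)
  dstart <- diary$start_time
  vstart <- device$intervals$start
  shift <- as.numeric(difftime(vstart[1], dstart, units = "secs"))
  if (shift %% diary$interval_s != 0)
    stop("diary and device grids are misaligned; snap the device grid ",
         "to the wall clock (cfg$states$snap_to_clock)", call. = FALSE)
  dstarts <- dstart + (seq_along(diary$entries) - 1) * diary$interval_s
  common <- intersect(as.numeric(dstarts), as.numeric(vstart))
  if (length(common) == 0)
    stop("timelines do not overlap", call. = FALSE)
  di <- match(common, as.numeric(dstarts))
  vi <- match(common, as.numeric(vstart))
  diary_lab <- as.character(diary$entries[di])
  device_lab <- device_to_diary_class(device$intervals$state[vi])
  keep <- diary_lab != "MISSING" & !is.na(device_lab)
  lv <- setdiff(diary_state_levels, "MISSING")
  data.frame(start = as.POSIXct(common, origin = "1970-01-01", tz = "")[keep],
             diary = factor(diary_lab[keep], levels = lv),
             device = factor(device_lab[keep], levels = lv))
}

#' Confusion counts over paired intervals
#'
#' `off_dichotomy` scores OFF against everything else; `on_dichotomy`
#' scores the two ON classes (with or without dyskinesia) against
#' everything else; asleep-equivalents are negatives in both.  `pooled`
#' (the default) sums the two dichotomies elementwise, so every compared
#' interval contributes exactly two counts and
#' `tp + fp + tn + fn = 2 * nrow(pairs)`.
#'
#' @param pairs data frame from [align_timelines()] (columns `diary`,
#'   `device`).
#' @param mode `"pooled"`, `"off_dichotomy"` or `"on_dichotomy"`.
#' @return A `"confusion_counts"` list with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(pairs,
                             mode = c("pooled", "off_dichotomy",
                                      "on_dichotomy")) {
  mode <- match.arg(mode)
  if (is.null(pairs) || nrow(pairs) == 0)
    stop("no compared intervals", call. = FALSE)
  dich <- function(positive) {
    dp <- as.character(pairs$diary) %in% positive
    vp <- as.character(pairs$device) %in% positive
    c(tp = sum(vp & dp), fp = sum(vp & !dp),
      tn = sum(!vp & !dp), fn = sum(!vp & dp))
  }
  counts <- switch(mode,
    off_dichotomy = dich("OFF"),
    on_dichotomy = dich(c("ON_OR_ON_NTD", "ON_TD")),
    pooled = dich("OFF") + dich(c("ON_OR_ON_NTD", "ON_TD")))
  new_confusion_counts(counts["tp"], counts["fp"], counts["tn"],
                       counts["fn"], mode)
}

new_confusion_counts <- function(tp, fp, tn, fn, mode = "pooled") {
  x <- list(tp = as.integer(tp), fp = as.integer(fp),
            tn = as.integer(tn), fn = as.integer(fn), mode = mode)
  if (any(unlist(x[1:4]) < 0)) stop("negative counts", call. = FALSE)
  class(x) <- "confusion_counts"
  x
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts %s> TP %d  FP %d  TN %d  FN %d (total %d)\n",
              x$mode, x$tp, x$fp, x$tn, x$fn, x$tp + x$fp + x$tn + x$fn))
  invisible(x)
}
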