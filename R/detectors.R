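#' Intensity map between band power and a 0-4 clinical-style score
#'
#' Monotone, continuous map from a band power (g^2) to an intensity score
#' on the 0-4 scale used by clinical rating items.  The map is
#' piecewise-linear in `log10(power)` through two anchors and clipped to
#' [0, 4].  For an increasing map the low anchor carries score 0.5 and the
#' high anchor 4.0; a decreasing map (used for bradykinesia, where less
#' residual movement means a worse score) reverses the two.
#'
#' @param anchor_low,anchor_high anchor powers in g^2,
#'   `0 < anchor_low < anchor_high`.
#' @param direction `"increasing"` or `"decreasing"`.
#' @return An `"intensity_map"` object.
#' @export
intensity_map <- function(anchor_low, anchor_high,
                          direction = c("increasing", "decreasing")) {
  direction <- match.arg(direction)
  if (!(is.finite(anchor_low) && is.finite(anchor_high) &&
        anchor_low > 0 && anchor_low < anchor_high))
    stop("need 0 < anchor_low < anchor_high", call. = FALSE)
  structure(list(anchor_power_low = anchor_low,
                 anchor_power_high = anchor_high,
                 direction = direction),
            class = "intensity_map")
}

as_intensity_map <- function(m) {
  if (inherits(m, "intensity_map")) return(m)
  intensity_map(m$anchor_low, m$anchor_high, m$direction)
}

#' Convert band power to an intensity score
#'
#' @param p band power in g^2 (non-negative; vectorised).
#' @param map an [intensity_map()].
#' @return Scores in [0, 4].
#' @export
intensity_from_power <- function(p, map) {
  map <- as_intensity_map(map)
  if (any(!is.finite(p)) || any(p < 0))
    stop("power must be finite and non-negative", call. = FALSE)
  lo <- log10(map$anchor_power_low)
  hi <- log10(map$anchor_power_high)
  s <- suppressWarnings((log10(p) - lo) / (hi - lo))  # log10(0) -> -Inf ok
  s[p == 0] <- -Inf
  raw <- if (map$direction == "increasing") 0.5 + 3.5 * s else 4 - 3.5 * s
  pmin(4, pmax(0, raw))
}

transverse_share <- function(bx, by, bz) {
  tot <- bx + by + bz
  ifelse(tot > 0, (by + bz) / tot, 0)
}

#' Epoch-level tremor detection
#'
#' A rest-tremor epoch must satisfy three conditions: (a) the combined
#' spectrum peaks inside the 3-7 Hz tremor band when searched over
#' 0.5-12 Hz, (b) the supination-pronation gate passes -- the two
#' transverse axes jointly carry at least `rho_axis` of the summed in-band
#' power across axes and their own in-band peak frequencies agree with the
#' combined peak within `delta_f` -- and (c) the combined 3-7 Hz power is
#' at least `theta0`.  The gate targets forearm-rotation tremor and
#' rejects same-frequency oscillation confined to the longitudinal axis.
#'
#' @param spec an `"epoch_spectrum"`.
#' @param cfg a [pd_config()] list.
#' @return List with `detected`, `peak_hz` (`NA` when not detected),
#'   `raw_power` (3-7 Hz combined power, g^2) and `intensity` in [0, 4].
#' @export
detect_tremor_epoch <- function(spec, cfg = pd_config()) {
  tc <- cfg$detectors$tremor
  band <- tc$band; sb <- tc$search_band
  p37 <- band_power(spec, band[1], band[2])
  cpk <- peak_frequency(spec, sb[1], sb[2])
  peak_in_band <- cpk >= band[1] && cpk <= band[2]
  gate <- FALSE
  if (peak_in_band) {
    bx <- band_power(spec, band[1], band[2], "x")
    by <- band_power(spec, band[1], band[2], "y")
    bz <- band_power(spec, band[1], band[2], "z")
    share_ok <- transverse_share(bx, by, bz) >= tc$rho_axis
    py <- peak_frequency(spec, band[1], band[2], "y")
    pz <- peak_frequency(spec, band[1], band[2], "z")
    gate <- share_ok && abs(py - cpk) <= tc$delta_f &&
      abs(pz - cpk) <= tc$delta_f
  }
  detected <- peak_in_band && gate && p37 >= tc$theta0
  list(detected = detected,
       peak_hz = if (detected) cpk else NA_real_,
       raw_power = p37,
       intensity = if (detected)
         intensity_from_power(p37, tc$map) else 0)
}

#' Epoch-level posture detection
#'
#' A wrist device cannot observe trunk posture directly; "standing /
#' non-sedentary" is approximated by the orientation of the low-passed
#' gravity vector (epoch mean) relative to the configured upright
#' reference (device x = forearm longitudinal, arm hanging), combined
#' with an activity floor on the high-passed vector RMS so that a
#' motionless arm never counts as upright-active.
#'
#' @param epoch an `"epoch"` from [get_epoch()] or `list(x =, y =, z =)`
#'   raw (gravity-bearing) slices.
#' @param fs sampling rate, Hz (taken from the epoch when present).
#' @param cfg a [pd_config()] list.
#' @return `"upright_active"` or `"other"`.
#' @export
detect_posture_epoch <- function(epoch, fs = NULL, cfg = pd_config()) {
  fs <- fs %||% epoch$fs
  pc <- cfg$detectors$posture
  g <- c(mean(epoch$x), mean(epoch$y), mean(epoch$z))
  gn <- sqrt(sum(g^2))
  ref <- pc$upright_ref / sqrt(sum(pc$upright_ref^2))
  ang <- if (gn > 0) acos(pmin(1, pmax(-1, sum(g * ref) / gn))) * 180 / pi
         else 180
  hx <- highpass_gravity(epoch$x, fs, cfg$spectral$highpass_hz,
                         cfg$spectral$hp_order)
  hy <- highpass_gravity(epoch$y, fs, cfg$spectral$highpass_hz,
                         cfg$spectral$hp_order)
  hz <- highpass_gravity(epoch$z, fs, cfg$spectral$highpass_hz,
                         cfg$spectral$hp_order)
  rms <- sqrt(mean(hx^2 + hy^2 + hz^2))
  if (ang < pc$alpha_max && rms > pc$rest_floor) "upright_active" else "other"
}

#' Epoch-level bradykinesia detection
#'
#' Bradykinetic slowness is detected only while upright and active, when
#' the 0.5-3 Hz combined band power falls between two thresholds: the
#' lower excludes motionless epochs, the upper excludes movement that is
#' not slow.  Intensity uses a decreasing map (less residual movement =
#' higher score).
#'
#' @param spec an `"epoch_spectrum"`.
#' @param posture posture label from [detect_posture_epoch()].
#' @param cfg a [pd_config()] list.
#' @return List with `detected`, `raw_power` (g^2), `intensity`, `posture`.
#' @export
detect_bradykinesia_epoch <- function(spec, posture, cfg = pd_config()) {
  bc <- cfg$detectors$brady
  if (!(bc$theta_low < bc$theta_high))
    stop("brady thresholds misordered", call. = FALSE)
  p <- band_power(spec, bc$band[1], bc$band[2])
  detected <- identical(posture, "upright_active") &&
    p > bc$theta_low && p < bc$theta_high
  list(detected = detected, raw_power = p,
       intensity = if (detected) intensity_from_power(p, bc$map) else 0,
       posture = posture)
}

# shared window-level dyskinesia rule on precomputed band powers
dysk_window_from_powers <- function(p13, p38, p18, cfg) {
  dk <- cfg$detectors$dysk
  flags <- p13 > dk$theta_lo & p38 > dk$theta_hi
  frac <- mean(flags)
  series <- ifelse(flags, intensity_from_power(p18, dk$map), 0)
  list(detected = frac > dk$q, epoch_flags = flags, fraction = frac,
       intensity_series = series,
       max_intensity = if (length(series)) max(series) else 0)
}

#' Window-level dyskinesia detection
#'
#' An epoch is flagged dyskinetic when both the 1-3 Hz and the 3-8 Hz
#' combined band powers exceed their thresholds; the 30-minute window is
#' dyskinetic when flagged epochs form a majority (`q`).  Requiring a
#' majority means isolated tremor or movement bursts cannot veto or fake
#' a dyskinetic window.  Per-epoch intensity comes from the 1-8 Hz power
#' through an increasing map and is reported only for flagged epochs, so
#' the intensity trace reads 0 during ordinary activity.
#'
#' @param specs list of at least two `"epoch_spectrum"` objects spanning
#'   the window.
#' @param cfg a [pd_config()] list.
#' @return List with `detected`, `epoch_flags`, `fraction`,
#'   `intensity_series` and `max_intensity`.
#' @export
detect_dyskinesia_window <- function(specs, cfg = pd_config()) {
  if (length(specs) == 0) stop("empty dyskinesia window", call. = FALSE)
  if (length(specs) < 2)
    stop("dyskinesia window needs at least 2 epochs", call. = FALSE)
  dk <- cfg$detectors$dysk
  p13 <- vapply(specs, band_power, numeric(1),
                f_lo = dk$band_lo[1], f_hi = dk$band_lo[2])
  p38 <- vapply(specs, band_power, numeric(1),
                f_lo = dk$band_hi[1], f_hi = dk$band_hi[2])
  p18 <- vapply(specs, band_power, numeric(1),
                f_lo = dk$band[1], f_hi = dk$band[2])
  dysk_window_from_powers(p13, p38, p18, cfg)
}

#' Epoch-level wear detection
#'
#' The device counts as worn when the near-body temperature reaches
#' `t_wear` or the high-passed vector RMS reaches the movement floor;
#' without a temperature channel the movement rule alone decides.
#'
#' @param epoch an `"epoch"` (raw slices).
#' @param temperature mean near-body temperature over the epoch in deg C,
#'   or `NULL`; defaults to the epoch's own `temp_mean` when present.
#' @param fs sampling rate, Hz.
#' @param cfg a [pd_config()] list.
#' @return `TRUE` (worn) or `FALSE`.
#' @export
detect_wear_epoch <- function(epoch, temperature = NULL, fs = NULL,
                              cfg = pd_config()) {
  fs <- fs %||% epoch$fs
  wc <- cfg$detectors$wear
  if (is.null(temperature)) temperature <- epoch$temp_mean
  hx <- highpass_gravity(epoch$x, fs, cfg$spectral$highpass_hz,
                         cfg$spectral$hp_order)
  hy <- highpass_gravity(epoch$y, fs, cfg$spectral$highpass_hz,
                         cfg$spectral$hp_order)
  hz <- highpass_gravity(epoch$z, fs, cfg$spectral$highpass_hz,
                         cfg$spectral$hp_order)
  rms <- sqrt(mean(hx^2 + hy^2 + hz^2))
  moving <- rms >= wc$movement_floor
  if (!is.null(temperature)) (temperature >= wc$t_wear) || moving else moving
}

# --- vectorised epoch-level feature extraction used by the classifier ---
#
# Computes, for every epoch of a recording in one pass: band powers,
# tremor/posture/bradykinesia flags and intensities, dyskinesia epoch
# flags and gated intensity, wear and activity flags.  The single-epoch
# detectors above apply the same rules to one spectrum at a time.
epoch_features <- function(rec, cfg = pd_config()) {
  es <- segment_epochs(rec, cfg$spectral$epoch_s)
  if (es$n == 0)
    stop("recording shorter than one epoch", call. = FALSE)
  ss <- epoch_set_spectra(es, cfg)
  fr <- ss$freqs
  nyq <- es$fs / 2
  bp <- function(mat, band)
    as.vector(crossprod(band_weights(fr, band[1], band[2], nyq), mat))
  tc <- cfg$detectors$tremor; bc <- cfg$detectors$brady
  dk <- cfg$detectors$dysk; st <- cfg$states
  p37  <- bp(ss$C, tc$band)
  p053 <- bp(ss$C, bc$band)
  p13  <- bp(ss$C, dk$band_lo)
  p38  <- bp(ss$C, dk$band_hi)
  p18  <- bp(ss$C, dk$band)
  pact <- bp(ss$C, c(0.5, 12))

  # tremor: combined peak location, transverse share, per-axis agreement
  sb_idx <- which(fr >= tc$search_band[1] & fr <= tc$search_band[2])
  cpk <- fr[sb_idx[max.col(t(ss$C[sb_idx, , drop = FALSE]),
                           ties.method = "first")]]
  band_idx <- which(fr >= tc$band[1] & fr <= tc$band[2])
  peak_of <- function(mat)
    fr[band_idx[max.col(t(mat[band_idx, , drop = FALSE]),
                        ties.method = "first")]]
  bx <- bp(ss$X, tc$band); by <- bp(ss$Y, tc$band); bz <- bp(ss$Z, tc$band)
  share <- transverse_share(bx, by, bz)
  py <- peak_of(ss$Y); pz <- peak_of(ss$Z)
  tremor <- cpk >= tc$band[1] & cpk <= tc$band[2] &
    share >= tc$rho_axis &
    abs(py - cpk) <= tc$delta_f & abs(pz - cpk) <= tc$delta_f &
    p37 >= tc$theta0
  tremor_int <- ifelse(tremor, intensity_from_power(p37, tc$map), 0)

  # posture from raw epoch means vs upright reference
  gx <- colMeans(es$x); gy <- colMeans(es$y); gz <- colMeans(es$z)
  gn <- sqrt(gx^2 + gy^2 + gz^2)
  ref <- cfg$detectors$posture$upright_ref
  ref <- ref / sqrt(sum(ref^2))
  cosang <- (gx * ref[1] + gy * ref[2] + gz * ref[3]) / pmax(gn, 1e-12)
  ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  rms <- sqrt(colMeans(ss$hx^2 + ss$hy^2 + ss$hz^2))
  upright <- ang < cfg$detectors$posture$alpha_max &
    rms > cfg$detectors$posture$rest_floor

  brady <- upright & p053 > bc$theta_low & p053 < bc$theta_high
  brady_int <- ifelse(brady, intensity_from_power(p053, bc$map), 0)

  dysk_flag <- p13 > dk$theta_lo & p38 > dk$theta_hi
  dysk_int <- ifelse(dysk_flag, intensity_from_power(p18, dk$map), 0)

  wc <- cfg$detectors$wear
  moving <- rms >= wc$movement_floor
  worn <- if (!is.null(es$temp_mean)) (es$temp_mean >= wc$t_wear) | moving
          else moving
  active <- pact > st$activity_floor

  list(feat = data.frame(t0 = es$t0, p37 = p37, p053 = p053, p13 = p13,
                         p38 = p38, p18 = p18, p_act = pact,
                         tremor = tremor, tremor_peak = cpk,
                         tremor_intensity = tremor_int,
                         upright = upright, brady = brady,
                         brady_intensity = brady_int,
                         dysk_flag = dysk_flag, dysk_intensity = dysk_int,
                         worn = worn, active = active),
       freqs = fr, epoch_s = es$epoch_s, n = es$n,
       start_time = es$start_time, psd_c = ss$C)
}
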