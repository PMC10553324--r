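#' @importFrom stats mvfft
NULL

# symmetric Hann window
hann_window <- function(n) {
  if (n == 1) return(1)
  0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
}

# zero-phase Butterworth filtering with odd-reflection padding at both ends
# (forward-backward pass, so the effective magnitude response is squared)
filt_zerophase <- function(x, b, a, pad) {
  n <- length(x)
  np <- min(n - 1, pad)
  if (np > 0) {
    head <- 2 * x[1] - x[(np + 1):2]
    tail <- 2 * x[n] - x[(n - 1):(n - np)]
    xp <- c(head, x, tail)
  } else xp <- x
  y <- as.numeric(signal::filter(b, a, xp))
  y <- rev(as.numeric(signal::filter(b, a, rev(y))))
  y[(np + 1):(np + n)]
}

#' Remove the gravity component from an acceleration series
#'
#' Fourth-order (by default) Butterworth high-pass applied forward and
#' backward (zero phase).  The default 0.25 Hz cutoff sits below the
#' 0.5 Hz lower edge of the bradykinesia band so that slow pathological
#' movement is preserved while the quasi-static gravity component is
#' removed.
#'
#' @param x numeric series in g.
#' @param fs sampling rate, Hz.
#' @param fc cutoff frequency, Hz.
#' @param order Butterworth order of each pass.
#' @return The high-passed series.
#' @export
highpass_gravity <- function(x, fs, fc = 0.25, order = 4) {
  bf <- signal::butter(order, fc / (fs / 2), type = "high")
  filt_zerophase(x, bf$b, bf$a, pad = round(5 * fs / fc))
}

# Welch averaged periodogram for every column of M (samples x epochs).
# One-sided density normalisation: integrating over (0, Nyquist]
# approximates the per-column variance.
welch_psd_matrix <- function(M, fs, seg_len, hop, demean = TRUE) {
  L <- nrow(M)
  if (L < seg_len)
    stop("epoch shorter than one Welch segment", call. = FALSE)
  starts <- seq(1, L - seg_len + 1, by = max(1, hop))
  w <- hann_window(seg_len)
  W <- sum(w^2)
  nf <- floor(seg_len / 2) + 1
  acc <- matrix(0, nf, ncol(M))
  for (s in starts) {
    S <- M[s:(s + seg_len - 1), , drop = FALSE]
    if (demean) S <- S - rep(colMeans(S), each = seg_len)
    Fm <- stats::mvfft(S * w)
    acc <- acc + (Mod(Fm[seq_len(nf), , drop = FALSE]))^2
  }
  psd <- acc / (length(starts) * fs * W)
  dbl <- 2:(if (seg_len %% 2 == 0) nf - 1 else nf)
  psd[dbl, ] <- 2 * psd[dbl, ]
  list(freqs = (seq_len(nf) - 1) * fs / seg_len, psd = psd)
}

welch_params <- function(fs, cfg) {
  seg_len <- round(cfg$spectral$segment_s * fs)
  hop <- max(1, floor(seg_len * (1 - cfg$spectral$overlap)))
  list(seg_len = seg_len, hop = hop)
}

#' Per-epoch power spectral density
#'
#' Welch-averaged periodogram (Hann window, overlapping segments) for each
#' acceleration axis of one epoch, plus a combined channel.  Gravity is
#' removed by a zero-phase high-pass before estimation (disable with
#' `highpass = FALSE` when the input is already filtered).  By default the
#' combined channel is the sum of the three per-axis PSDs, i.e. the
#' spectrum of total gravity-free acceleration power, so that its integral
#' over (0, Nyquist] approximates the summed per-axis variance;
#' `cfg$spectral$combine = "magnitude"` instead takes the PSD of the
#' high-passed vector-magnitude series.
#'
#' @param epoch an `"epoch"` from [get_epoch()], or a `list(x =, y =, z =)`
#'   of equal-length numeric slices.
#' @param fs sampling rate, Hz (taken from the epoch when present).
#' @param cfg a [pd_config()] list.
#' @param highpass apply gravity removal before estimation.
#' @return An `"epoch_spectrum"`: `freqs`, `psd_x`, `psd_y`, `psd_z`,
#'   `psd_c` (all in g^2/Hz on a shared uniform grid) and `epoch_index`.
#' @export
compute_epoch_spectrum <- function(epoch, fs = NULL, cfg = pd_config(),
                                   highpass = TRUE) {
  fs <- fs %||% epoch$fs
  if (is.null(fs)) stop("sampling rate unknown", call. = FALSE)
  x <- epoch$x; y <- epoch$y; z <- epoch$z
  stopifnot(length(x) == length(y), length(y) == length(z))
  if (highpass) {
    x <- highpass_gravity(x, fs, cfg$spectral$highpass_hz,
                          cfg$spectral$hp_order)
    y <- highpass_gravity(y, fs, cfg$spectral$highpass_hz,
                          cfg$spectral$hp_order)
    z <- highpass_gravity(z, fs, cfg$spectral$highpass_hz,
                          cfg$spectral$hp_order)
  }
  wp <- welch_params(fs, cfg)
  px <- welch_psd_matrix(cbind(x), fs, wp$seg_len, wp$hop)
  py <- welch_psd_matrix(cbind(y), fs, wp$seg_len, wp$hop)
  pz <- welch_psd_matrix(cbind(z), fs, wp$seg_len, wp$hop)
  pc <- if (cfg$spectral$combine == "sum") {
    px$psd + py$psd + pz$psd
  } else {
    m <- sqrt(x^2 + y^2 + z^2)
    welch_psd_matrix(cbind(m), fs, wp$seg_len, wp$hop)$psd
  }
  structure(list(freqs = px$freqs, psd_x = drop(px$psd),
                 psd_y = drop(py$psd), psd_z = drop(pz$psd),
                 psd_c = drop(pc), epoch_index = epoch$index %||% NA_integer_,
                 fs = fs),
            class = "epoch_spectrum")
}

#' @export
print.epoch_spectrum <- function(x, ...) {
  cat(sprintf("<epoch_spectrum> %d bins, 0-%.1f Hz (step %.3g Hz)\n",
              length(x$freqs), max(x$freqs), x$freqs[2] - x$freqs[1]))
  invisible(x)
}

# Integration weights for the piecewise-linear PSD over [a, b]:
# band integral == sum(w * psd).  The half-open top bin between the last
# grid node and Nyquist is treated as flat so bands may extend to fs/2.
band_weights <- function(freqs, a, b, nyquist) {
  if (!is.finite(a) || !is.finite(b) || a < 0 || b > nyquist + 1e-9)
    stop("band outside the frequency grid", call. = FALSE)
  if (!(a < b)) stop("band must have positive width", call. = FALSE)
  K <- length(freqs)
  w <- numeric(K)
  fmax <- freqs[K]
  b1 <- min(b, fmax)
  a1 <- min(a, fmax)
  if (a1 < b1) {
    inner <- which(freqs > a1 & freqs < b1)
    bp <- c(a1, freqs[inner], b1)
    m <- length(bp)
    half <- diff(bp) / 2
    coefs <- c(half, 0) + c(0, half)   # per-breakpoint trapezoid weight
    i <- pmin(pmax(findInterval(bp, freqs), 1L), K - 1L)
    alpha <- (bp - freqs[i]) / (freqs[i + 1] - freqs[i])
    for (j in seq_len(m)) {
      w[i[j]]     <- w[i[j]]     + coefs[j] * (1 - alpha[j])
      w[i[j] + 1] <- w[i[j] + 1] + coefs[j] * alpha[j]
    }
  }
  if (b > fmax) w[K] <- w[K] + (b - max(a, fmax))
  w
}

get_channel <- function(spec, channel) {
  ch <- match.arg(channel, c("combined", "x", "y", "z"))
  switch(ch, combined = spec$psd_c, x = spec$psd_x, y = spec$psd_y,
         z = spec$psd_z)
}

#' Band power from an epoch spectrum
#'
#' Trapezoidal integral of the piecewise-linear PSD over `[f_lo, f_hi]`,
#' in g^2.  Exactly additive over adjacent bands sharing a grid node.
#'
#' @param spec an `"epoch_spectrum"`.
#' @param channel `"combined"` (default), `"x"`, `"y"` or `"z"`.
#' @param f_lo,f_hi band edges in Hz, `0 <= f_lo < f_hi <= fs/2`.
#' @return Band power in g^2 (non-negative).
#' @export
band_power <- function(spec, f_lo, f_hi, channel = "combined") {
  p <- get_channel(spec, channel)
  sum(band_weights(spec$freqs, f_lo, f_hi, spec$fs / 2) * p)
}

#' Peak frequency within a band
#'
#' Frequency of the maximum PSD value among grid nodes inside
#' `[f_lo, f_hi]`; ties break toward the lower frequency.
#'
#' @inheritParams band_power
#' @return Peak frequency in Hz.
#' @export
peak_frequency <- function(spec, f_lo, f_hi, channel = "combined") {
  if (f_lo < 0 || f_hi > spec$fs / 2 + 1e-9)
    stop("band outside the frequency grid", call. = FALSE)
  idx <- which(spec$freqs >= f_lo & spec$freqs <= f_hi)
  if (length(idx) == 0) stop("empty band: no grid nodes inside",
                             call. = FALSE)
  p <- get_channel(spec, channel)
  spec$freqs[idx[which.max(p[idx])]]   # which.max -> first (lowest) maximum
}

# batch spectra for a whole epoch set; axis matrices must already be
# gravity-free when prefiltered = TRUE
epoch_set_spectra <- function(es, cfg = pd_config(), prefiltered = FALSE) {
  X <- es$x; Y <- es$y; Z <- es$z
  if (!prefiltered && es$n > 0) {
    # filter the concatenated series once, then re-slice
    fc <- cfg$spectral$highpass_hz; ord <- cfg$spectral$hp_order
    X <- matrix(highpass_gravity(as.vector(X), es$fs, fc, ord), nrow = es$L)
    Y <- matrix(highpass_gravity(as.vector(Y), es$fs, fc, ord), nrow = es$L)
    Z <- matrix(highpass_gravity(as.vector(Z), es$fs, fc, ord), nrow = es$L)
  }
  wp <- welch_params(es$fs, cfg)
  px <- welch_psd_matrix(X, es$fs, wp$seg_len, wp$hop)
  py <- welch_psd_matrix(Y, es$fs, wp$seg_len, wp$hop)
  pz <- welch_psd_matrix(Z, es$fs, wp$seg_len, wp$hop)
  C <- if (cfg$spectral$combine == "sum") {
    px$psd + py$psd + pz$psd
  } else {
    M <- sqrt(X^2 + Y^2 + Z^2)
    welch_psd_matrix(M, es$fs, wp$seg_len, wp$hop)$psd
  }
  structure(list(freqs = px$freqs, X = px$psd, Y = py$psd, Z = pz$psd,
                 C = C, fs = es$fs, t0 = es$t0, epoch_s = es$epoch_s,
                 n = es$n, hx = X, hy = Y, hz = Z),
            class = "spectra_set")
}

# one epoch_spectrum out of a spectra_set column
spectra_set_epoch <- function(ss, i) {
  structure(list(freqs = ss$freqs, psd_x = ss$X[, i], psd_y = ss$Y[, i],
                 psd_z = ss$Z[, i], psd_c = ss$C[, i], epoch_index = i,
                 fs = ss$fs),
            class = "epoch_spectrum")
}

#' Spectrogram of a whole recording
#'
#' One combined-channel PSD column per epoch: a frequency-by-time matrix
#' suitable for `image()` or CSV export.
#'
#' @param rec an `"accel_recording"`.
#' @param cfg a [pd_config()] list.
#' @return Numeric matrix (frequency bins x epochs) with attributes
#'   `freqs` (Hz) and `t0` (epoch offsets, s).
#' @export
spectrogram_matrix <- function(rec, cfg = pd_config()) {
  es <- segment_epochs(rec, cfg$spectral$epoch_s)
  ss <- epoch_set_spectra(es, cfg)
  m <- ss$C
  attr(m, "freqs") <- ss$freqs
  attr(m, "t0") <- ss$t0
  m
}
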