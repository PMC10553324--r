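# shared in-code fixtures; no data files

default_freqs <- seq(0, 24.8, by = 0.4)

# hand-built epoch spectrum with per-channel PSD levels (constant or vector)
make_spec <- function(c_psd = 0, x_psd = 0, y_psd = 0, z_psd = 0,
                      freqs = default_freqs, fs = 50) {
  expand <- function(p) if (length(p) == 1) rep(p, length(freqs)) else p
  structure(list(freqs = freqs, psd_x = expand(x_psd), psd_y = expand(y_psd),
                 psd_z = expand(z_psd), psd_c = expand(c_psd),
                 epoch_index = 1L, fs = fs),
            class = "epoch_spectrum")
}

# constant PSD only inside [lo, hi]
band_psd <- function(level, lo, hi, freqs = default_freqs) {
  ifelse(freqs >= lo & freqs <= hi, level, 0)
}

# raw 5 s epoch from axis vectors
make_epoch <- function(x, y = NULL, z = NULL, fs = 50, temp_mean = NULL) {
  n <- length(x)
  y <- y %||% numeric(n)
  z <- z %||% numeric(n)
  structure(list(index = 1L, t0 = 0, duration = n / fs, fs = fs,
                 x = x, y = y, z = z, temp_mean = temp_mean),
            class = "epoch")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

sine_wave <- function(f, n = 250, fs = 50, A = 1, phase = 0)
  A * sin(2 * pi * f * (seq_len(n) - 1) / fs + phase)

# short recording built from plain vectors
quick_recording <- function(ax, ay = NULL, az = NULL, fs = 50,
                            start = "2024-03-01T00:00:00", temp = NULL) {
  n <- length(ax)
  accel_recording(start, ax, ay %||% numeric(n), az %||% numeric(n),
                  fs = fs, temperature = temp)
}

# supination-pronation style tremor epoch: transverse quadrature pair
tremor_epoch <- function(f = 5, A = 0.08, n = 250, fs = 50, noise_sd = 0.01,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t <- (seq_len(n) - 1) / fs
  ph <- stats::runif(1, 0, 2 * pi)
  wn <- function() stats::rnorm(n, sd = noise_sd)
  make_epoch(x = 0.25 * A * sin(2 * pi * f * t + ph) + wn() + 0.7,
             y = 0.70 * A * sin(2 * pi * f * t + ph + pi / 2) + wn() + 0.5,
             z = 0.55 * A * sin(2 * pi * f * t + ph + pi) + wn() + 0.5,
             fs = fs)
}

expect_state <- function(f, cfg, state) {
  expect_identical(classify_window(f, cfg), state)
}
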