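# Independent brute-force oracle for the spectral estimator: evaluates the
# Hann-tapered power on the same zero-padded frequency grid by direct O(n^2)
# summation (no FFT), and returns the in-band argmax frequency.

oracle_hann <- function(n) {
  if (n == 1L) return(1)
  k <- seq_len(n) - 1L
  0.5 - 0.5 * cos(2 * pi * k / (n - 1L))
}

oracle_grid_size <- function(n, fs, min_resolution = 0.1) {
  nfft <- max(n, ceiling(fs / min_resolution))
  p <- 1L
  while (p < nfft) p <- p * 2L
  p
}

oracle_dft_power <- function(series, fs, min_resolution = 0.1) {
  n <- length(series)
  x <- (series - mean(series)) * oracle_hann(n)
  nfft <- oracle_grid_size(n, fs, min_resolution)
  j <- 0:(nfft %/% 2)
  k <- seq_len(n) - 1L
  power <- vapply(j, function(jj) {
    ang <- -2 * pi * jj * k / nfft
    Mod(sum(x * complex(real = cos(ang), imaginary = sin(ang))))^2
  }, numeric(1))
  list(frequency = j * fs / nfft, power = power)
}

oracle_peak_frequency <- function(series, fs, band_low = 1, band_high = 12,
                                  min_resolution = 0.1) {
  ps <- oracle_dft_power(series, fs, min_resolution)
  in_band <- ps$frequency >= band_low & ps$frequency <= band_high
  ps$frequency[in_band][which.max(ps$power[in_band])]
}

# Simple sine-wave recording on one axis plus gravity, for fixture-free tests.
make_sine_recording <- function(freq, duration = 10, fs = 50, amplitude = 1,
                                axis = "x") {
  t <- (seq_len(round(duration * fs)) - 1L) / fs
  s <- amplitude * sin(2 * pi * freq * t)
  zero <- numeric(length(t))
  accel_recording(t,
                  ax = if (axis == "x") s else zero,
                  ay = if (axis == "y") s else zero,
                  az = (if (axis == "z") s else zero) + 9.81,
                  sample_rate = fs)
}

# Short-session config so end-to-end tests stay fast without touching the
# published day durations used by the acceptance checks.
short_config <- function(...) {
  protocol_config(day1_duration = 240, daily_duration = 120, ...)
}
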