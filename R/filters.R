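# internal zero-phase filtering helpers shared by the BOLD, EEG and
# phase-locking branches.

# zero-phase (forward-backward) Butterworth band-pass applied to the rows
# of a matrix; order is the per-pass filter order.
bandpass_rows <- function(x, fs, low, high, order = 2) {
  if (!(low > 0 && low < high)) stop("need 0 < low < high")
  if (high >= fs / 2) {
    stop(sprintf("band (%g, %g) Hz infeasible at sampling rate %g Hz", low,
                 high, fs))
  }
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  x <- x - rowMeans(x)
  t(apply(x, 1, function(r) signal::filtfilt(bf, r)))
}

# zero-phase anti-alias low-pass followed by integer-factor subsampling.
decimate_rows <- function(x, fs, target_rate, order = 4) {
  q <- fs / target_rate
  if (abs(q - round(q)) > 1e-9) {
    stop("sampling rate must be an integer multiple of the target rate")
  }
  q <- round(q)
  if (q == 1) return(x)
  bf <- signal::butter(order, 0.8 / q, type = "low")
  y <- t(apply(x, 1, function(r) signal::filtfilt(bf, r)))
  y[, seq(1, ncol(y), by = q), drop = FALSE]
}
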