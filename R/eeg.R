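#' EEG record container
#'
#' @param data Numeric channels x samples matrix (arbitrary potential units).
#' @param sampling_rate Sampling rate in Hz.
#' @param reference Referencing state: `"none"` or `"common-average"`.
#' @param channel_labels Optional channel labels.
#' @return An object of class `eeg_record`.
#' @export
eeg_record <- function(data, sampling_rate,
                       reference = c("none", "common-average"),
                       channel_labels = NULL) {
  data <- as.matrix(data)
  reference <- match.arg(reference)
  if (!all(is.finite(data))) stop("EEG data must be finite")
  if (sampling_rate <= 0) stop("sampling_rate must be positive")
  if (is.null(channel_labels)) {
    channel_labels <- rownames(data)
    if (is.null(channel_labels)) channel_labels <- paste0("CH", seq_len(nrow(data)))
  }
  rownames(data) <- channel_labels
  structure(list(data = data, sampling_rate = sampling_rate,
                 reference = reference, channel_labels = channel_labels),
            class = "eeg_record")
}

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf("eeg_record: %d channels x %d samples @ %g Hz (%s reference)\n",
              nrow(x$data), ncol(x$data), x$sampling_rate, x$reference))
  invisible(x)
}

#' Apply a common average reference
#'
#' Subtracts the across-channel mean from every sample, so each column of
#' the data matrix sums to zero.
#'
#' @param eeg An [eeg_record()].
#' @return The re-referenced [eeg_record()].
#' @export
common_average_reference <- function(eeg) {
  stopifnot(inherits(eeg, "eeg_record"))
  data <- sweep(eeg$data, 2, colMeans(eeg$data))
  eeg_record(data, eeg$sampling_rate, "common-average", eeg$channel_labels)
}

#' Generate random microstate template maps
#'
#' Draws `K` random scalp topographies, average-references each (zero mean
#' across channels), optionally orthogonalises them within the
#' zero-mean subspace, and normalises every column to unit Euclidean norm.
#'
#' @param n_channels Number of channels (must exceed `K` for orthogonal maps).
#' @param K Number of template maps.
#' @param seed Integer seed.
#' @param orthogonal If `TRUE` (default) the maps are mutually orthogonal.
#' @return A channels x K numeric matrix of unit-norm, average-referenced
#'   maps.
#' @export
generate_templates <- function(n_channels, K, seed = 1, orthogonal = TRUE) {
  if (K < 2) stop("K must be >= 2")
  if (orthogonal && n_channels <= K) stop("need n_channels > K for orthogonal maps")
  set.seed(seed)
  maps <- matrix(rnorm(n_channels * K), n_channels, K)
  maps <- sweep(maps, 2, colMeans(maps))
  if (orthogonal) maps <- qr.Q(qr(maps))
  # qr.Q columns lose exact zero-mean only at numerical noise level; recentre
  maps <- sweep(maps, 2, colMeans(maps))
  maps <- sweep(maps, 2, sqrt(colSums(maps^2)), "/")
  rownames(maps) <- paste0("CH", seq_len(n_channels))
  colnames(maps) <- paste0("MS", seq_len(K))
  maps
}

#' Generate ground-truth microstate EEG
#'
#' Builds multichannel EEG as a Markov dwell process over `K` template maps:
#' the active state persists for a geometrically distributed number of
#' samples with the requested mean dwell, then switches uniformly to one of
#' the other states. Within each segment the active template is multiplied
#' by a random polarity (microstates are sign-invariant) and by a positive
#' amplitude envelope obtained by rectifying smoothed Gaussian noise, so the
#' global field power has genuine local maxima. Channel noise is scaled so
#' that the root-mean-square signal-to-noise ratio equals `snr`
#' (`snr = Inf` gives noiseless EEG). The composite is finally
#' common-average referenced.
#'
#' @param templates Channels x K matrix of unit-norm, average-referenced
#'   maps (see [generate_templates()]).
#' @param mean_dwell_ms Positive mean dwell time(s) in ms, recycled to K.
#' @param duration_s Recording length in seconds.
#' @param sampling_rate Sampling rate in Hz (default 100).
#' @param snr Positive signal-to-noise ratio (RMS signal / RMS noise).
#' @param seed Integer seed.
#' @param envelope_smooth_ms Gaussian smoothing scale of the amplitude
#'   envelope (ms).
#' @param envelope_floor Positive floor added to the rectified envelope so
#'   the signal never vanishes.
#' @return A `ground_truth_eeg` object: list with `eeg` ([eeg_record()]),
#'   `templates`, `labels` (per-sample state index), `mean_dwell_ms`,
#'   `noise_sd`, `seed`.
#' @export
generate_microstate_eeg <- function(templates, mean_dwell_ms, duration_s,
                                    sampling_rate = 100, snr = 5, seed = 1,
                                    envelope_smooth_ms = 50,
                                    envelope_floor = 0.2) {
  templates <- as.matrix(templates)
  K <- ncol(templates)
  n_ch <- nrow(templates)
  if (K < 2) stop("K must be >= 2")
  if (max(abs(colSums(templates))) > 1e-6 * n_ch) {
    stop("templates must be average-referenced (zero channel mean)")
  }
  if (max(abs(colSums(templates^2) - 1)) > 1e-6) {
    stop("templates must have unit Euclidean norm")
  }
  mean_dwell_ms <- rep_len(mean_dwell_ms, K)
  if (any(mean_dwell_ms <= 0)) stop("mean dwell times must be positive")
  if (is.na(snr) || snr <= 0) stop("snr must be positive")
  n <- round(duration_s * sampling_rate)
  if (n < 2) stop("duration too short")
  set.seed(seed)

  dwell_samples <- pmax(mean_dwell_ms * sampling_rate / 1000, 1)
  labels <- integer(n)
  signs <- numeric(n)
  t <- 1L
  state <- sample.int(K, 1)
  while (t <= n) {
    p <- 1 / dwell_samples[state]
    len <- rgeom(1, min(p, 1)) + 1L
    seg <- t:min(t + len - 1L, n)
    labels[seg] <- state
    signs[seg] <- sample(c(-1, 1), 1)
    t <- t + len
    nxt <- sample.int(K - 1, 1)
    state <- if (nxt >= state) nxt + 1L else nxt
  }

  # rectified smoothed noise envelope, unit RMS before the floor
  kern_sd <- envelope_smooth_ms * sampling_rate / 1000
  half <- max(1, ceiling(3 * kern_sd))
  kern <- exp(-((-half:half)^2) / (2 * kern_sd^2))
  kern <- kern / sum(kern)
  w <- rnorm(n + 2 * half)
  sm <- stats::filter(w, kern, sides = 2)[(half + 1):(half + n)]
  sm <- sm / sqrt(mean(sm^2))
  envelope <- abs(sm) + envelope_floor

  signal <- templates[, labels, drop = FALSE] *
    rep(envelope * signs, each = n_ch)
  noise_sd <- if (is.infinite(snr)) 0 else sqrt(mean(signal^2)) / snr
  data <- signal
  if (noise_sd > 0) data <- data + matrix(rnorm(n_ch * n, sd = noise_sd), n_ch, n)
  data <- sweep(data, 2, colMeans(data))
  structure(list(eeg = eeg_record(data, sampling_rate, "common-average",
                                  rownames(templates)),
                 templates = templates, labels = labels,
                 mean_dwell_ms = mean_dwell_ms, noise_sd = noise_sd,
                 seed = seed),
            class = "ground_truth_eeg")
}

#' @export
print.ground_truth_eeg <- function(x, ...) {
  cat(sprintf("ground_truth_eeg: K=%d states, %d channels, %.1f s @ %g Hz, noise_sd=%.3g\n",
              ncol(x$templates), nrow(x$templates),
              ncol(x$eeg$data) / x$eeg$sampling_rate, x$eeg$sampling_rate,
              x$noise_sd))
  invisible(x)
}
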