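#' Project neural mass potentials into channel-space EEG
#'
#' Simulated EEG is the lead field applied to the per-region mean
#' excitatory membrane potentials: `data = gain %*% V`. The sampling rate
#' is inherited from the trajectory.
#'
#' @param traj A `neural_mass_trajectory`.
#' @param lf A [lead_field()] whose region order matches the trajectory.
#' @return An [eeg_record()] (unreferenced).
#' @export
project_sources <- function(traj, lf) {
  stopifnot(inherits(lf, "lead_field"))
  if (ncol(lf$gain) != nrow(traj$V)) {
    stop("lead field region count must match the trajectory")
  }
  if (!is.null(traj$region_labels) &&
      !identical(unname(lf$region_labels), unname(traj$region_labels))) {
    stop("lead field region labels must match the trajectory region labels")
  }
  eeg_record(lf$gain %*% traj$V, traj$sampling_rate, "none",
             lf$channel_labels)
}

#' Preprocess simulated EEG for microstate analysis
#'
#' Applies, in order: common average reference, zero-phase band-pass
#' (default 10-15 Hz, the band in which the coupled neural mass dynamics
#' carry their fast oscillatory power), and anti-aliased decimation to the
#' target rate (default 100 Hz).
#'
#' @param eeg An [eeg_record()].
#' @param band Length-2 numeric band edges in Hz.
#' @param target_rate Output sampling rate in Hz; must divide the input
#'   rate and its Nyquist must lie above the band.
#' @param order Butterworth order per filtering pass.
#' @return The preprocessed [eeg_record()] at `target_rate`.
#' @export
preprocess_simulated_eeg <- function(eeg, band = c(10, 15),
                                     target_rate = 100, order = 2) {
  stopifnot(inherits(eeg, "eeg_record"), length(band) == 2)
  if (eeg$sampling_rate <= 2 * band[2]) {
    stop("input sampling rate must exceed twice the upper band edge")
  }
  if (band[2] >= target_rate / 2) {
    stop("band lies above the Nyquist frequency of the target rate")
  }
  x <- sweep(eeg$data, 2, colMeans(eeg$data))
  x <- bandpass_rows(x, eeg$sampling_rate, band[1], band[2], order)
  x <- decimate_rows(x, eeg$sampling_rate, target_rate)
  # re-reference: filtering preserves the zero channel mean only up to
  # numerical error
  x <- sweep(x, 2, colMeans(x))
  eeg_record(x, target_rate, "common-average", eeg$channel_labels)
}
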