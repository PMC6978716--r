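#' Instantaneous phase of band-limited neural trajectories
#'
#' Applies a zero-phase band-pass (default 10-15 Hz) to each region's mean
#' excitatory membrane potential and extracts the analytic-signal phase
#' via the Hilbert transform (FFT construction of the analytic signal).
#'
#' @param traj A `neural_mass_trajectory` (or list with matrix `V` and
#'   `sampling_rate`).
#' @param band Length-2 numeric band edges in Hz.
#' @param order Butterworth order per filtering pass.
#' @return Regions x samples matrix of phases in `(-pi, pi]`.
#' @export
instantaneous_phase <- function(traj, band = c(10, 15), order = 2) {
  fs <- traj$sampling_rate
  if (fs <= 2 * band[2]) stop("sampling rate must exceed twice the band")
  xf <- bandpass_rows(traj$V, fs, band[1], band[2], order)
  t(apply(xf, 1, function(x) Arg(analytic_signal(x))))
}

# analytic signal via the frequency-domain construction: zero the
# negative frequencies, double the positive ones.
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

#' Phase-locking value matrix
#'
#' `PLV[p, q] = |sum_t exp(i (theta_q(t) - theta_p(t)))| / N_T`: the
#' magnitude of the time-averaged unit phasor of the phase difference.
#' 1 means perfect phase locking (including any constant offset); values
#' near `1/sqrt(N_T)` are expected for independent phases.
#'
#' @param theta Regions x samples phase matrix (radians), e.g. from
#'   [instantaneous_phase()].
#' @param band Optional band annotation (Hz).
#' @param region_labels Optional region labels.
#' @return An object of class `plv_matrix`: list with the symmetric
#'   unit-diagonal matrix `plv` in `[0, 1]`, `band`, `n_samples`.
#' @export
plv_matrix <- function(theta, band = c(10, 15), region_labels = NULL) {
  theta <- as.matrix(theta)
  nt <- ncol(theta)
  if (nt < 2) stop("need at least 2 samples")
  E <- exp(1i * t(theta))                    # samples x regions
  G <- Mod(t(Conj(E)) %*% E) / nt
  G <- (G + t(G)) / 2
  G[G > 1] <- 1
  diag(G) <- 1
  if (is.null(region_labels)) region_labels <- rownames(theta)
  if (!is.null(region_labels)) dimnames(G) <- list(region_labels, region_labels)
  structure(list(plv = G, band = band, n_samples = nt),
            class = "plv_matrix")
}

#' @export
print.plv_matrix <- function(x, ...) {
  lt <- x$plv[lower.tri(x$plv)]
  cat(sprintf("plv_matrix: %d regions, band %g-%g Hz, mean off-diagonal PLV %.3f\n",
              nrow(x$plv), x$band[1], x$band[2], mean(lt)))
  invisible(x)
}

#' Phase-locking matrix of a trajectory
#'
#' Convenience wrapper: band-pass + Hilbert phase + PLV, discarding
#' `edge_trim_s` seconds at each end to remove filter and analytic-signal
#' boundary transients before the PLV sum.
#'
#' @param traj A `neural_mass_trajectory`.
#' @param band Length-2 numeric band edges in Hz.
#' @param edge_trim_s Seconds discarded at each end (default 1).
#' @param order Butterworth order per filtering pass.
#' @return A [plv_matrix()].
#' @export
compute_plv <- function(traj, band = c(10, 15), edge_trim_s = 1, order = 2) {
  theta <- instantaneous_phase(traj, band, order)
  trim <- round(edge_trim_s * traj$sampling_rate)
  nt <- ncol(theta)
  if (nt <= 2 * trim + 2) stop("trajectory too short for the edge trim")
  keep <- (trim + 1):(nt - trim)
  plv_matrix(theta[, keep, drop = FALSE], band, traj$region_labels)
}

#' Average PLV matrices elementwise
#'
#' Used to combine the repeated simulations of one parameter point into a
#' single phase-locking matrix.
#'
#' @param plvs List of [plv_matrix()] objects over the same regions.
#' @return A [plv_matrix()] with the elementwise mean.
#' @export
average_plv <- function(plvs) {
  stopifnot(length(plvs) >= 1, all(vapply(plvs, inherits, TRUE, "plv_matrix")))
  m <- Reduce(`+`, lapply(plvs, `[[`, "plv")) / length(plvs)
  structure(list(plv = m, band = plvs[[1]]$band,
                 n_samples = sum(vapply(plvs, `[[`, 1, "n_samples"))),
            class = "plv_matrix")
}
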