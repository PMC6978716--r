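#' Balloon-Windkessel hemodynamic parameters
#'
#' @param kappa Rate of vasodilatory signal decay (1/s), default 0.65.
#' @param gamma Flow induction (feedback) rate (1/s), default 0.41 from the
#'   canonical hemodynamic model literature (the value is not varied here).
#' @param tau Hemodynamic transit time (s), default 0.98.
#' @param alpha Grubb's vessel stiffness exponent, default 0.32.
#' @param rho Resting oxygen extraction fraction, default 0.34.
#' @param V0 Resting blood volume fraction, default 0.02.
#' @return An object of class `hemodynamic_params`.
#' @export
hemodynamic_params <- function(kappa = 0.65, gamma = 0.41, tau = 0.98,
                               alpha = 0.32, rho = 0.34, V0 = 0.02) {
  vals <- c(kappa = kappa, gamma = gamma, tau = tau, alpha = alpha,
            rho = rho, V0 = V0)
  if (any(vals <= 0)) stop("all hemodynamic parameters must be positive")
  structure(as.list(vals), class = "hemodynamic_params")
}

#' Neuronal drive from a membrane potential trajectory
#'
#' The hemodynamic drive is the absolute value of the time derivative of
#' the mean excitatory membrane potential, computed by central finite
#' differences (one-sided at the edges), in model units per second.
#'
#' @param traj A `neural_mass_trajectory` (or any list with a regions x
#'   samples matrix `V` and `sampling_rate` in Hz).
#' @return Non-negative regions x samples drive matrix.
#' @export
neuronal_drive <- function(traj) {
  V <- traj$V
  fs <- traj$sampling_rate
  ns <- ncol(V)
  if (is.null(ns) || ns < 2) stop("need at least 2 samples to differentiate")
  d <- matrix(0, nrow(V), ns)
  if (ns > 2) {
    d[, 2:(ns - 1)] <- (V[, 3:ns, drop = FALSE] -
                        V[, 1:(ns - 2), drop = FALSE]) * fs / 2
  }
  d[, 1] <- (V[, 2] - V[, 1]) * fs
  d[, ns] <- (V[, ns] - V[, ns - 1]) * fs
  abs(d)
}

#' Balloon-Windkessel state derivative
#'
#' For each region: the vasodilatory signal `s` integrates the drive with
#' decay and flow feedback, inflow `f` follows `s`, blood volume `v` fills
#' and empties with outflow `v^(1/alpha)`, and deoxyhemoglobin `q` tracks
#' oxygen extraction `(1 - (1-rho)^(1/f)) / rho` minus clearance.
#'
#' @param state List with positive per-region vectors `f`, `v`, `q` and a
#'   vector `s`.
#' @param z Per-region neuronal drive.
#' @param p A [hemodynamic_params()].
#' @return List with derivatives `ds`, `df`, `dv`, `dq` (per second).
#' @export
hemodynamic_derivative <- function(state, z, p = hemodynamic_params()) {
  s <- state$s; f <- state$f; v <- state$v; q <- state$q
  if (any(f <= 0) || any(v <= 0)) stop("inflow f and volume v must be positive")
  ds <- z - p$kappa * s - p$gamma * (f - 1)
  df <- s
  dv <- (f - v^(1 / p$alpha)) / p$tau
  dq <- (f * (1 - (1 - p$rho)^(1 / f)) / p$rho - v^(1 / p$alpha) * q / v) / p$tau
  list(ds = ds, df = df, dv = dv, dq = dq)
}

#' BOLD readout from volume and deoxyhemoglobin
#'
#' Static non-linear observation combining extra- and intra-vascular
#' signal changes:
#' `y = V0 * (7*rho*(1-q) + 2*(1 - q/v) + (2*rho - 0.2)*(1 - v))`.
#' Zero at the resting point `v = q = 1`.
#'
#' @param v,q Positive blood volume and deoxyhemoglobin content.
#' @param p A [hemodynamic_params()].
#' @return Dimensionless BOLD signal change.
#' @export
bold_readout <- function(v, q, p = hemodynamic_params()) {
  if (any(v <= 0)) stop("volume v must be positive")
  p$V0 * (7 * p$rho * (1 - q) + 2 * (1 - q / v) + (2 * p$rho - 0.2) * (1 - v))
}

#' BOLD time series container
#'
#' @param y Regions x samples matrix of dimensionless BOLD changes.
#' @param sampling_rate Sampling rate in Hz.
#' @param region_labels Optional region labels.
#' @return An object of class `bold_time_series`.
#' @export
bold_time_series <- function(y, sampling_rate, region_labels = NULL) {
  y <- as.matrix(y)
  if (!all(is.finite(y))) stop("BOLD values must be finite")
  if (is.null(region_labels)) {
    region_labels <- rownames(y)
    if (is.null(region_labels)) region_labels <- paste0("R", seq_len(nrow(y)))
  }
  rownames(y) <- region_labels
  structure(list(y = y, sampling_rate = sampling_rate,
                 region_labels = region_labels), class = "bold_time_series")
}

#' @export
print.bold_time_series <- function(x, ...) {
  cat(sprintf("bold_time_series: %d regions x %d samples @ %g Hz\n",
              nrow(x$y), ncol(x$y), x$sampling_rate))
  invisible(x)
}

#' Simulate BOLD signals from a neural mass trajectory
#'
#' Integrates the Balloon-Windkessel equations per region from the resting
#' fixed point `(s, f, v, q) = (0, 1, 1, 1)`, driven by
#' [neuronal_drive()] (linearly interpolated between neural samples), with
#' the same adaptive Runge-Kutta 2(3) scheme used for the neural dynamics,
#' and applies the static BOLD readout at the requested output rate.
#'
#' @param traj A `neural_mass_trajectory`.
#' @param p A [hemodynamic_params()].
#' @param bold_rate Output sampling rate in Hz; the default 0.4 Hz matches
#'   a repetition time of 2.5 s.
#' @param rtol,atol Solver tolerances.
#' @return A [bold_time_series()].
#' @export
simulate_bold <- function(traj, p = hemodynamic_params(), bold_rate = 0.4,
                          rtol = 1e-3, atol = 1e-6) {
  z <- neuronal_drive(traj)
  n <- nrow(z)
  ns <- ncol(z)
  fs <- traj$sampling_rate
  dur <- (ns - 1) / fs
  if (dur < 1 / bold_rate) stop("trajectory shorter than one BOLD sample")
  iV <- seq_len(n); iF <- n + iV; iv <- 2 * n + iV; iq <- 3 * n + iV
  deriv <- function(t, y, parms) {
    s <- y[iV]; f <- y[iF]; v <- y[iv]; q <- y[iq]
    if (any(!is.finite(y)) || any(f <= 0) || any(v <= 0)) {
      bad <- which(f <= 0 | v <= 0 | !is.finite(y[iF]) | !is.finite(y[iv]))
      stop(sprintf("hemodynamic solver failure (region %s)",
                   paste(bad, collapse = ",")))
    }
    pos <- min(max(t * fs, 0), ns - 1)
    i0 <- floor(pos); wfr <- pos - i0
    zt <- z[, i0 + 1] * (1 - wfr) + z[, min(i0 + 2, ns)] * wfr
    list(c(zt - p$kappa * s - p$gamma * (f - 1),
           s,
           (f - v^(1 / p$alpha)) / p$tau,
           (f * (1 - (1 - p$rho)^(1 / f)) / p$rho - v^(1 / p$alpha) * q / v) / p$tau))
  }
  out_times <- seq(0, dur, by = 1 / bold_rate)
  y0 <- c(rep(0, n), rep(1, 3 * n))
  sol <- deSolve::ode(y0, out_times, deriv, parms = NULL,
                      method = deSolve::rkMethod("rk23bs"),
                      rtol = rtol, atol = atol, hmax = 0.5)
  if (attr(sol, "istate")[1] < 0 || nrow(sol) < length(out_times) ||
      !all(is.finite(sol))) {
    stop("hemodynamic solver failed (non-finite state)")
  }
  v <- t(sol[, 1 + iv, drop = FALSE])
  q <- t(sol[, 1 + iq, drop = FALSE])
  y <- p$V0 * (7 * p$rho * (1 - q) + 2 * (1 - q / v) + (2 * p$rho - 0.2) * (1 - v))
  bold_time_series(y, bold_rate, traj$region_labels)
}
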