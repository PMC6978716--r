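#' Larter-Breakspear neural mass parameters
#'
#' Parameter set for the conductance-based neural mass model of one cortical
#' region (mean excitatory membrane potential V, mean inhibitory membrane
#' potential Z, fraction of open potassium channels W), coupled across
#' regions through connectivity-weighted excitatory firing rates. Defaults
#' are the standard published values for this model; voltages and
#' conductances are in dimensionless model units and one model time unit is
#' interpreted as 1 ms, which places the intrinsic fast oscillation in the
#' physiological EEG range.
#'
#' The two swept parameters are `C`, the global coupling strength balancing
#' intra- versus inter-regional excitatory input (in `[0, 1]`), and
#' `delta_V`, the variance of the excitatory firing threshold; the
#' inhibitory threshold variance `delta_Z` is always tied to `delta_V`.
#'
#' @param C Global coupling strength in `[0, 1]`.
#' @param delta_V Variance of the excitatory (and inhibitory) firing
#'   threshold; must be positive.
#' @param T_Ca,delta_Ca,g_Ca,V_Ca Calcium channel threshold, threshold
#'   variance, conductance and Nernst potential.
#' @param T_K,delta_K,g_K,V_K Potassium channel threshold, threshold
#'   variance, conductance and Nernst potential.
#' @param T_Na,delta_Na,g_Na,V_Na Sodium channel threshold, threshold
#'   variance, conductance and Nernst potential.
#' @param V_L,g_L Leak Nernst potential and conductance.
#' @param V_T,Z_T Excitatory and inhibitory firing thresholds.
#' @param Q_Vmax,Q_Zmax Maximal excitatory and inhibitory firing rates.
#' @param I Subcortical input strength.
#' @param a_ee,a_ei,a_ie,a_ne,a_ni Synaptic strengths
#'   (excitatory-excitatory, excitatory-inhibitory, inhibitory-excitatory,
#'   nonspecific-excitatory, nonspecific-inhibitory).
#' @param b_time Time-constant scaling factor of the inhibitory equation
#'   (named to avoid a collision with the microstate smoothing window `b`).
#' @param phi Temperature scaling factor.
#' @param tau_K Potassium relaxation time constant.
#' @param r_NMDA Ratio of NMDA to AMPA receptors.
#' @param delta_subcortical Random modulation of the subcortical input
#'   (default 0: the input `I` is constant; a positive value adds a seeded
#'   per-region constant perturbation of that scale at simulation time).
#' @return An object of class `neural_mass_params`.
#' @export
neural_mass_params <- function(C = 0.5, delta_V = 0.65,
                               T_Ca = -0.01, delta_Ca = 0.15, g_Ca = 1, V_Ca = 1,
                               T_K = 0, delta_K = 0.30, g_K = 2, V_K = -0.7,
                               T_Na = 0.3, delta_Na = 0.15, g_Na = 6.7, V_Na = 0.53,
                               V_L = -0.5, g_L = 0.5, V_T = 0, Z_T = 0,
                               Q_Vmax = 1, Q_Zmax = 1, I = 0.3,
                               a_ee = 0.36, a_ei = 2, a_ie = 2, a_ne = 1,
                               a_ni = 0.4, b_time = 0.1, phi = 0.7, tau_K = 1,
                               r_NMDA = 0.25, delta_subcortical = 0) {
  if (C < 0 || C > 1) stop("C must lie in [0, 1]")
  if (delta_V <= 0) stop("delta_V must be positive")
  p <- list(C = C, delta_V = delta_V, delta_Z = delta_V,
            T_Ca = T_Ca, delta_Ca = delta_Ca, g_Ca = g_Ca, V_Ca = V_Ca,
            T_K = T_K, delta_K = delta_K, g_K = g_K, V_K = V_K,
            T_Na = T_Na, delta_Na = delta_Na, g_Na = g_Na, V_Na = V_Na,
            V_L = V_L, g_L = g_L, V_T = V_T, Z_T = Z_T,
            Q_Vmax = Q_Vmax, Q_Zmax = Q_Zmax, I = I,
            a_ee = a_ee, a_ei = a_ei, a_ie = a_ie, a_ne = a_ne, a_ni = a_ni,
            b_time = b_time, phi = phi, tau_K = tau_K, r_NMDA = r_NMDA,
            delta_subcortical = delta_subcortical)
  structure(p, class = "neural_mass_params")
}

#' @export
print.neural_mass_params <- function(x, ...) {
  cat(sprintf("neural_mass_params: C=%g, delta_V=delta_Z=%g (plus fixed channel/synaptic constants)\n",
              x$C, x$delta_V))
  invisible(x)
}

#' Sigmoid fraction of open voltage-gated ion channels
#'
#' `0.5 * (1 + tanh((V - T_ion) / delta_ion))`: the population-averaged
#' fraction of open channels for a Gaussian distribution of channel
#' thresholds; strictly increasing in `V` with midpoint 0.5 at `V = T_ion`.
#'
#' @param V Membrane potential (vectorised).
#' @param T_ion Channel threshold.
#' @param delta_ion Positive threshold variance.
#' @return Fraction(s) in (0, 1).
#' @export
gating_fraction <- function(V, T_ion, delta_ion) {
  if (any(delta_ion <= 0)) stop("delta_ion must be positive")
  0.5 * (1 + tanh((V - T_ion) / delta_ion))
}

#' Sigmoid population firing rate
#'
#' `0.5 * Q_max * (1 + tanh((x - threshold) / delta))`, the mean firing rate
#' of an excitatory or inhibitory population whose thresholds are Gaussian
#' distributed around `threshold` with variance parameter `delta`.
#'
#' @param x Membrane potential (V or Z, vectorised).
#' @param threshold Firing threshold.
#' @param delta Positive threshold variance.
#' @param Q_max Positive maximal firing rate.
#' @return Rate(s) in (0, Q_max).
#' @export
firing_rate <- function(x, threshold, delta, Q_max) {
  if (any(delta <= 0)) stop("delta must be positive")
  if (any(Q_max <= 0)) stop("Q_max must be positive")
  0.5 * Q_max * (1 + tanh((x - threshold) / delta))
}

#' Connectivity-weighted mean excitatory input
#'
#' For each region `i`, the weighted mean of the other regions' excitatory
#' firing rates, `sum_j u_ij * Q_Vj / sum_j u_ij`. A convex combination:
#' the result always lies within `[min(Q_V), max(Q_V)]`. A region with no
#' neighbours (zero row sum) receives 0 and a warning is emitted.
#'
#' @param Q_V Per-region excitatory firing rates.
#' @param sc A [structural_connectome()].
#' @return Per-region weighted mean input.
#' @export
coupling_input <- function(Q_V, sc) {
  stopifnot(inherits(sc, "structural_connectome"))
  if (length(Q_V) != n_regions(sc)) {
    stop("Q_V length must match the number of regions")
  }
  rs <- rowSums(sc$weights)
  out <- numeric(length(Q_V))
  ok <- rs > 0
  if (!all(ok)) {
    warning("isolated region(s) with zero connectivity receive coupling input 0")
  }
  out[ok] <- as.vector(sc$weights[ok, , drop = FALSE] %*% Q_V) / rs[ok]
  out
}

# core right-hand side; x is c(V, Z, W) stacked, u/rs precomputed.
# regions with zero row sum get coupling input 0 (flagged upstream).
lb_rhs <- function(x, p, u, rs, n, I = p$I) {
  V <- x[seq_len(n)]
  Z <- x[n + seq_len(n)]
  W <- x[2 * n + seq_len(n)]
  m_Ca <- 0.5 * (1 + tanh((V - p$T_Ca) / p$delta_Ca))
  m_Na <- 0.5 * (1 + tanh((V - p$T_Na) / p$delta_Na))
  m_K  <- 0.5 * (1 + tanh((V - p$T_K) / p$delta_K))
  Q_V <- 0.5 * p$Q_Vmax * (1 + tanh((V - p$V_T) / p$delta_V))
  Q_Z <- 0.5 * p$Q_Zmax * (1 + tanh((Z - p$Z_T) / p$delta_Z))
  if (n > 1) {
    avg <- numeric(n)
    ok <- rs > 0
    avg[ok] <- as.vector(u[ok, , drop = FALSE] %*% Q_V) / rs[ok]
  } else {
    avg <- Q_V
  }
  exc_Ca <- p$g_Ca + (1 - p$C) * p$r_NMDA * p$a_ee * Q_V +
    p$C * p$r_NMDA * p$a_ee * avg
  exc_Na <- p$g_Na * m_Na + (1 - p$C) * p$a_ee * Q_V + p$C * p$a_ee * avg
  dV <- -exc_Ca * m_Ca * (V - p$V_Ca) -
    p$g_K * W * (V - p$V_K) - p$g_L * (V - p$V_L) -
    exc_Na * (V - p$V_Na) - p$a_ie * Z * Q_Z + p$a_ne * I
  dZ <- p$b_time * (p$a_ni * I + p$a_ei * V * Q_V)
  # dW/dt = phi * (m_K - W) / tau_K: the standard relaxation form of the
  # potassium gating equation is adopted (the alternative grouping
  # phi*m_K - W/tau_K coincides with it only up to the phi factor).
  dW <- p$phi * (m_K - W) / p$tau_K
  c(dV, dZ, dW)
}

#' Time derivative of the coupled neural mass state
#'
#' Evaluates the full right-hand side of the model for all regions: the
#' excitatory potential equation with calcium, potassium, sodium and leak
#' currents plus local and connectivity-weighted excitatory input (mixed by
#' the global coupling `C`), the slow inhibitory equation, and the
#' potassium gating relaxation.
#'
#' @param state List with numeric per-region vectors `V`, `Z`, `W`.
#' @param params A [neural_mass_params()].
#' @param sc A [structural_connectome()] with matching region count.
#' @return List with per-region derivative vectors `dV`, `dZ`, `dW` (per
#'   model time unit, i.e. per ms).
#' @export
state_derivative <- function(state, params, sc) {
  stopifnot(inherits(params, "neural_mass_params"),
            inherits(sc, "structural_connectome"))
  n <- n_regions(sc)
  if (length(state$V) != n || length(state$Z) != n || length(state$W) != n) {
    stop("state vectors must match the connectome region count")
  }
  d <- lb_rhs(c(state$V, state$Z, state$W), params, sc$weights,
              rowSums(sc$weights), n)
  list(dV = d[seq_len(n)], dZ = d[n + seq_len(n)], dW = d[2 * n + seq_len(n)])
}

#' Draw random initial states
#'
#' `V, Z ~ Uniform(-0.1, 0.1)` and `W ~ Uniform(0.3, 0.4)` per region,
#' seeded. The membrane potentials start in a small neighbourhood of the
#' resting range and the gating variable near its typical operating point.
#'
#' @param n Number of regions.
#' @param seed Integer seed.
#' @return List with vectors `V`, `Z`, `W`.
#' @export
random_initial_state <- function(n, seed = 1) {
  set.seed(seed)
  list(V = runif(n, -0.1, 0.1), Z = runif(n, -0.1, 0.1),
       W = runif(n, 0.3, 0.4))
}

#' Simulate the coupled neural mass model
#'
#' Integrates the model for all regions with an adaptive embedded
#' Runge-Kutta 2(3) pair (Bogacki-Shampine, the method behind MATLAB's
#' `ode23`), then resamples the dense solution onto a uniform output grid.
#' One model time unit is 1 ms, so `duration_s` seconds correspond to
#' `1000 * duration_s` time units. The first `transient_s` seconds are
#' discarded.
#'
#' @param params A [neural_mass_params()].
#' @param sc A [structural_connectome()].
#' @param duration_s Total simulated time in seconds.
#' @param transient_s Initial transient to discard (seconds).
#' @param output_rate Output sampling rate in Hz (default 1000).
#' @param init Either `NULL` (draw from [random_initial_state()] with
#'   `seed`) or a list with vectors `V`, `Z`, `W`.
#' @param seed Integer seed for the initial state (and the subcortical
#'   input perturbation when `delta_subcortical > 0`).
#' @param rtol,atol Relative and absolute solver tolerances.
#' @return A `neural_mass_trajectory`: list with `V` (regions x samples
#'   matrix of excitatory potentials), `sampling_rate`, `t0` (time of the
#'   first retained sample, seconds), `params`, `connectome_id`,
#'   `region_labels`, `seed`.
#' @export
simulate_neural_mass <- function(params, sc, duration_s = 600,
                                 transient_s = 120, output_rate = 1000,
                                 init = NULL, seed = 1,
                                 rtol = 1e-3, atol = 1e-6) {
  stopifnot(inherits(params, "neural_mass_params"),
            inherits(sc, "structural_connectome"))
  if (!(duration_s > transient_s && transient_s >= 0)) {
    stop("need duration_s > transient_s >= 0")
  }
  n <- n_regions(sc)
  if (is.null(init)) init <- random_initial_state(n, seed)
  if (length(init$V) != n || length(init$Z) != n || length(init$W) != n) {
    stop("init vectors must match the connectome region count")
  }
  u <- sc$weights
  rs <- rowSums(u)
  if (n > 1 && any(rs == 0)) {
    warning("isolated region(s): coupling input fixed to 0")
  }
  I <- params$I
  if (params$delta_subcortical > 0) {
    set.seed(seed + 1L)
    I <- I + params$delta_subcortical * rnorm(n)
  }
  dt <- 1000 / output_rate                      # output step in model ms
  times <- seq(0, duration_s * 1000, by = dt)
  y0 <- c(init$V, init$Z, init$W)
  sol <- deSolve::ode(y0, times,
                      function(t, y, parms) list(lb_rhs(y, params, u, rs, n, I)),
                      parms = NULL, method = deSolve::rkMethod("rk23bs"),
                      rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0 || nrow(sol) < length(times) ||
      !all(is.finite(sol))) {
    stop(sprintf(
      "neural mass solver failed at C=%g, delta_V=%g (non-finite state or step underflow)",
      params$C, params$delta_V))
  }
  keep <- sol[, 1] >= transient_s * 1000 - 1e-9
  V <- t(sol[keep, 1 + seq_len(n), drop = FALSE])
  rownames(V) <- sc$region_labels
  structure(list(V = V, sampling_rate = output_rate, t0 = transient_s,
                 params = params, connectome_id = sc$id,
                 region_labels = sc$region_labels, seed = seed),
            class = "neural_mass_trajectory")
}

#' @export
print.neural_mass_trajectory <- function(x, ...) {
  cat(sprintf(
    "neural_mass_trajectory: %d regions x %d samples @ %g Hz (t0=%g s, C=%g, delta_V=%g)\n",
    nrow(x$V), ncol(x$V), x$sampling_rate, x$t0, x$params$C,
    x$params$delta_V))
  invisible(x)
}
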