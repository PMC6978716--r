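# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (loops instead of matrix algebra, fixed-step
# instead of adaptive integration) so agreement is informative.

# scalar, loop-based evaluation of the coupled neural mass right-hand side
oracle_lb_deriv <- function(V, Z, W, p, u) {
  n <- length(V)
  dV <- dZ <- dW <- numeric(n)
  QV <- 0.5 * p$Q_Vmax * (1 + tanh((V - p$V_T) / p$delta_V))
  QZ <- 0.5 * p$Q_Zmax * (1 + tanh((Z - p$Z_T) / p$delta_Z))
  for (i in seq_len(n)) {
    num <- 0; den <- 0
    for (j in seq_len(n)) {
      num <- num + u[i, j] * QV[j]
      den <- den + u[i, j]
    }
    avg <- if (n == 1) QV[i] else if (den > 0) num / den else 0
    m_Ca <- 0.5 * (1 + tanh((V[i] - p$T_Ca) / p$delta_Ca))
    m_Na <- 0.5 * (1 + tanh((V[i] - p$T_Na) / p$delta_Na))
    m_K  <- 0.5 * (1 + tanh((V[i] - p$T_K) / p$delta_K))
    dV[i] <- -(p$g_Ca + (1 - p$C) * p$r_NMDA * p$a_ee * QV[i] +
                 p$C * p$r_NMDA * p$a_ee * avg) * m_Ca * (V[i] - p$V_Ca) -
      p$g_K * W[i] * (V[i] - p$V_K) - p$g_L * (V[i] - p$V_L) -
      (p$g_Na * m_Na + (1 - p$C) * p$a_ee * QV[i] + p$C * p$a_ee * avg) *
        (V[i] - p$V_Na) -
      p$a_ie * Z[i] * QZ[i] + p$a_ne * p$I
    dZ[i] <- p$b_time * (p$a_ni * p$I + p$a_ei * V[i] * QV[i])
    dW[i] <- p$phi * (m_K - W[i]) / p$tau_K
  }
  list(dV = dV, dZ = dZ, dW = dW)
}

# fixed-step classical RK4 on the neural mass system; dt_ms in model ms.
# Returns the V block sampled every `every` steps (including t = 0).
oracle_rk4_lb <- function(params, sc, init, t_end_ms, dt_ms, every = 1) {
  n <- length(init$V)
  y <- c(init$V, init$Z, init$W)
  f <- function(y) {
    d <- oracle_lb_deriv(y[1:n], y[n + 1:n], y[2 * n + 1:n], params,
                         sc$weights)
    c(d$dV, d$dZ, d$dW)
  }
  steps <- round(t_end_ms / dt_ms)
  out <- matrix(NA_real_, n, floor(steps / every) + 1)
  out[, 1] <- y[1:n]
  col <- 1
  for (s in seq_len(steps)) {
    k1 <- f(y)
    k2 <- f(y + dt_ms / 2 * k1)
    k3 <- f(y + dt_ms / 2 * k2)
    k4 <- f(y + dt_ms * k3)
    y <- y + dt_ms / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (s %% every == 0) {
      col <- col + 1
      out[, col] <- y[1:n]
    }
  }
  out
}

# recursive brute-force enumeration of one-to-one microstate assignments:
# all injective maps of the smaller state set into the larger, scored by
# sum(|cor|)/K_max with unmatched slots contributing 0.
oracle_match_score <- function(cmat) {
  ka <- nrow(cmat); kb <- ncol(cmat)
  if (ka > kb) return(oracle_match_score(t(cmat)))
  kmax <- kb
  best <- -Inf
  recurse <- function(row, used, acc) {
    if (row > ka) {
      best <<- max(best, acc / kmax)
      return(invisible(NULL))
    }
    for (j in seq_len(kb)) {
      if (!used[j]) {
        used[j] <- TRUE
        recurse(row + 1, used, acc + abs(cmat[row, j]))
        used[j] <- FALSE
      }
    }
  }
  recurse(1, logical(kb), 0)
  best
}

# small deterministic fixtures -----------------------------------------

make_test_connectome <- function(n = 8, seed = 1, density = 0.35) {
  generate_connectome(n, edge_density = density, interhemispheric_scale = 2,
                      seed = seed)
}

make_test_templates <- function(n_channels = 16, K = 4, seed = 5) {
  generate_templates(n_channels, K, seed = seed)
}

# a trajectory-like object with a prescribed V matrix, for forward-model
# units tests that do not need the ODE solver
fake_trajectory <- function(V, sampling_rate = 1000) {
  structure(list(V = V, sampling_rate = sampling_rate, t0 = 0,
                 region_labels = rownames(V)),
            class = "neural_mass_trajectory")
}

# cumulative phase from wrapped samples: undo 2*pi jumps
unwrap_phase <- function(p) {
  d <- diff(p)
  d <- d - 2 * pi * round(d / (2 * pi))
  c(p[1], p[1] + cumsum(d))
}
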