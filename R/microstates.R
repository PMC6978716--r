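#' Global field power
#'
#' Per-sample standard deviation of the signal across channels (population
#' convention: divisor is the channel count). High-GFP samples have the
#' best topographic signal-to-noise ratio, and microstate templates are
#' estimated at GFP local maxima.
#'
#' @param eeg An [eeg_record()] with at least 2 channels.
#' @return Non-negative per-sample numeric vector.
#' @export
global_field_power <- function(eeg) {
  stopifnot(inherits(eeg, "eeg_record"))
  if (nrow(eeg$data) < 2) stop("GFP needs at least 2 channels")
  x <- sweep(eeg$data, 2, colMeans(eeg$data))
  sqrt(colMeans(x^2))
}

#' Local maxima of a GFP curve
#'
#' Strict interior local maxima: samples greater than both neighbours.
#' A plateau that dominates its neighbours yields its first index.
#' Endpoints are never peaks.
#'
#' @param gfp Numeric series (length >= 3).
#' @return Integer vector of peak indices (possibly empty).
#' @export
gfp_peaks <- function(gfp) {
  if (length(gfp) < 3) stop("need at least 3 samples")
  r <- rle(gfp)
  k <- length(r$values)
  if (k < 3) return(integer(0))
  starts <- cumsum(c(1, r$lengths[-k]))
  inner <- 2:(k - 1)
  is_peak <- r$values[inner] > r$values[inner - 1] &
    r$values[inner] > r$values[inner + 1]
  as.integer(starts[inner][is_peak])
}

#' Microstate model container
#'
#' @param maps Channels x K matrix; every column unit-norm and
#'   average-referenced. Maps are defined up to polarity: a map and its
#'   negation describe the same state.
#' @param ev Optional explained variance of the fit at GFP peaks.
#' @param channel_labels Optional channel labels.
#' @return An object of class `microstate_model` with elements `maps`,
#'   `K`, `ev`.
#' @export
microstate_model <- function(maps, ev = NA_real_, channel_labels = NULL) {
  maps <- as.matrix(maps)
  if (max(abs(colSums(maps))) > 1e-6 * nrow(maps)) {
    stop("maps must be average-referenced")
  }
  if (max(abs(colSums(maps^2) - 1)) > 1e-6) stop("maps must be unit-norm")
  if (is.null(channel_labels)) {
    channel_labels <- rownames(maps)
    if (is.null(channel_labels)) channel_labels <- paste0("CH", seq_len(nrow(maps)))
  }
  rownames(maps) <- channel_labels
  colnames(maps) <- paste0("MS", seq_len(ncol(maps)))
  structure(list(maps = maps, K = ncol(maps), ev = ev),
            class = "microstate_model")
}

#' @export
print.microstate_model <- function(x, ...) {
  cat(sprintf("microstate_model: K=%d maps over %d channels (EV at peaks %.3f)\n",
              x$K, nrow(x$maps), x$ev))
  invisible(x)
}

# spatial correlation between all columns of two channel-map matrices
spatial_correlation <- function(a, b) {
  suppressWarnings(cor(a, b))
}

# one modified-k-means run (polarity invariant, k-means++ init) on the
# unit-normalised peak maps X (channels x P). Returns maps and EV.
ms_kmeans_once <- function(X, K, convergence_eps, max_iter = 200) {
  P <- ncol(X)
  # k-means++: squared-correlation distance 1 - r^2 to the nearest centre
  centers <- matrix(0, nrow(X), K)
  first <- sample.int(P, 1)
  centers[, 1] <- X[, first]
  if (K > 1) {
    best_r2 <- as.vector(crossprod(centers[, 1], X))^2
    for (k in 2:K) {
      d2 <- pmax(1 - best_r2, 0)
      if (sum(d2) <= 0) {
        pick <- sample.int(P, 1)
      } else {
        pick <- sample.int(P, 1, prob = d2)
      }
      centers[, k] <- X[, pick]
      best_r2 <- pmax(best_r2, as.vector(crossprod(centers[, k], X))^2)
    }
  }
  ev_old <- -Inf
  for (iter in seq_len(max_iter)) {
    a <- crossprod(centers, X)              # K x P projections
    r2 <- a^2
    lab <- max.col(t(r2), ties.method = "first")
    top <- r2[cbind(lab, seq_len(P))]
    for (k in seq_len(K)) {
      sel <- lab == k
      if (!any(sel)) {                      # degenerate cluster:
        worst <- which.min(top)             # reseed from worst-fit peak
        centers[, k] <- X[, worst]
        lab[worst] <- k
        sel <- lab == k
      }
      Xk <- X[, sel, drop = FALSE]
      if (ncol(Xk) == 1) {
        u <- Xk[, 1]
      } else {
        u <- svd(Xk, nu = 1, nv = 0)$u[, 1]  # principal topography
      }
      u <- u - mean(u)
      u <- u / sqrt(sum(u^2))
      if (u[which.max(abs(u))] < 0) u <- -u  # fix sign for determinism
      centers[, k] <- u
    }
    a <- crossprod(centers, X)
    r2max <- apply(a^2, 2, max)
    ev <- mean(r2max)                       # X columns are unit-norm
    if (is.finite(ev_old) && abs(ev - ev_old) <= convergence_eps * max(ev, 1e-12)) {
      break
    }
    ev_old <- ev
  }
  list(maps = centers, ev = ev)
}

#' Fit microstate templates (modified k-means)
#'
#' The basic N-microstate algorithm: EEG topographies at GFP peaks are
#' unit-normalised and clustered with a polarity-invariant k-means.
#' Each peak map is assigned to the template maximising the squared
#' spatial correlation, and each template is re-estimated as the principal
#' spatial eigenvector of its assigned maps, until the explained variance
#' changes by less than `convergence_eps` (relative). Initial templates
#' are chosen by the k-means++ rule with squared-correlation distance;
#' the best of `n_restarts` runs by explained variance is kept. Fitted
#' templates with mutual absolute spatial correlation at or above
#' `merge_threshold` are merged by reclustering with K-1 states.
#'
#' @param eeg An [eeg_record()].
#' @param K Number of microstate classes to request (default 4).
#' @param n_restarts Number of random restarts (default 20).
#' @param convergence_eps Relative explained-variance convergence
#'   criterion (default 1e-6).
#' @param merge_threshold Absolute spatial correlation at which two
#'   templates are considered the same state (default 0.9).
#' @param seed Integer seed; the fit is deterministic given the seed.
#' @param use_gfp_peaks If `TRUE` (default) cluster topographies at GFP
#'   local maxima only, otherwise use all samples.
#' @return A [microstate_model()] with `K` or fewer maps.
#' @export
fit_microstates <- function(eeg, K = 4, n_restarts = 20,
                            convergence_eps = 1e-6, merge_threshold = 0.9,
                            seed = 1, use_gfp_peaks = TRUE) {
  stopifnot(inherits(eeg, "eeg_record"))
  if (K < 2) stop("K must be >= 2")
  x <- sweep(eeg$data, 2, colMeans(eeg$data))
  if (use_gfp_peaks) {
    peaks <- gfp_peaks(global_field_power(eeg))
    if (length(peaks) < 10 * K) {
      stop(sprintf("too few GFP peaks (%d) for K=%d (need >= %d)",
                   length(peaks), K, 10 * K))
    }
    X <- x[, peaks, drop = FALSE]
  } else {
    X <- x
  }
  nrm <- sqrt(colSums(X^2))
  X <- X[, nrm > 0, drop = FALSE]
  X <- sweep(X, 2, sqrt(colSums(X^2)), "/")
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- ms_kmeans_once(X, K, convergence_eps)
    if (is.null(best) || fit$ev > best$ev) best <- fit
  }
  rc <- spatial_correlation(best$maps, best$maps)
  diag(rc) <- 0
  if (any(abs(rc) >= merge_threshold, na.rm = TRUE) && K > 2) {
    return(fit_microstates(eeg, K - 1, n_restarts, convergence_eps,
                           merge_threshold, seed, use_gfp_peaks))
  }
  microstate_model(best$maps, ev = best$ev, channel_labels = eeg$channel_labels)
}

#' Microstate segmentation container
#'
#' @param labels Integer per-sample state labels in `1..K` (`NA` marks an
#'   unassigned sample).
#' @param gfp Per-sample global field power.
#' @param sampling_rate Sampling rate in Hz.
#' @return An object of class `microstate_segmentation`.
#' @export
microstate_segmentation <- function(labels, gfp, sampling_rate) {
  if (length(labels) != length(gfp)) stop("labels and gfp lengths differ")
  if (any(gfp < 0)) stop("gfp must be non-negative")
  structure(list(labels = as.integer(labels), gfp = gfp,
                 sampling_rate = sampling_rate),
            class = "microstate_segmentation")
}

#' Segment EEG into microstates with smoothing
#'
#' Assigns every sample to a template by the segmentation-smoothing
#' algorithm: starting from the per-sample argmax of squared spatial
#' correlation, labels are iteratively re-assigned to minimise the
#' noise-normalised squared residual of each sample against its
#' (polarity-free) template minus `lambda_penalty` times the number of
#' same-label neighbours within `window_b` samples on each side, until the
#' objective improves by less than `convergence_eps` (relative). With
#' `lambda_penalty = 0` the result is exactly the unsmoothed argmax
#' labelling.
#'
#' @param eeg An [eeg_record()].
#' @param model A [microstate_model()] fitted on the same channel set.
#' @param window_b Half-width of the smoothing window in samples
#'   (default 3).
#' @param lambda_penalty Non-smoothness penalty weight (default 5).
#' @param convergence_eps Relative objective convergence criterion
#'   (default 1e-6).
#' @param max_iter Iteration cap.
#' @return A [microstate_segmentation()].
#' @export
segment_smooth <- function(eeg, model, window_b = 3, lambda_penalty = 5,
                           convergence_eps = 1e-6, max_iter = 100) {
  stopifnot(inherits(eeg, "eeg_record"), inherits(model, "microstate_model"))
  if (nrow(eeg$data) != nrow(model$maps)) {
    stop("model fitted on an incompatible channel set")
  }
  x <- sweep(eeg$data, 2, colMeans(eeg$data))
  n_ch <- nrow(x)
  Tn <- ncol(x)
  K <- model$K
  a <- crossprod(model$maps, x)             # K x T projections
  x2 <- colSums(x^2)
  lab <- max.col(t(a^2), ties.method = "first")
  if (lambda_penalty != 0 && K > 1) {
    b <- max(0L, as.integer(window_b))
    obj_old <- Inf
    for (iter in seq_len(max_iter)) {
      resid <- x2 - a[cbind(lab, seq_len(Tn))]^2
      e <- max(mean(resid) / (n_ch - 1), 1e-12)   # current noise estimate
      ind <- matrix(0, K, Tn)
      ind[cbind(lab, seq_len(Tn))] <- 1
      cs <- cbind(0, t(apply(ind, 1, cumsum)))    # K x (T+1)
      lo <- pmax(seq_len(Tn) - b, 1)
      hi <- pmin(seq_len(Tn) + b, Tn)
      nb <- cs[, hi + 1, drop = FALSE] - cs[, lo, drop = FALSE] - ind
      cost <- sweep(-a^2, 2, x2, "+") / (2 * e * (n_ch - 1)) -
        lambda_penalty * nb
      new_lab <- max.col(t(-cost), ties.method = "first")
      obj <- sum(cost[cbind(new_lab, seq_len(Tn))])
      if (identical(new_lab, lab)) break
      lab <- new_lab
      if (is.finite(obj_old) &&
          abs(obj_old - obj) <= convergence_eps * max(abs(obj), 1e-12)) break
      obj_old <- obj
    }
  }
  microstate_segmentation(lab, global_field_power(eeg), eeg$sampling_rate)
}

#' Microstate statistics
#'
#' Computes, from a segmentation: the occupation ratio (fraction of
#' assigned samples per state), the mean transition time (mean contiguous
#' dwell per state, ms), the transition probability matrix between
#' successive runs (row-stochastic; rows of states with no outgoing
#' transition are `NA`), and the global explained variance
#' `GEV = sum_t gfp_t^2 r^2(x_t, map_label(t)) / sum_t gfp_t^2`, where `r`
#' is the spatial correlation between each sample and its assigned map.
#'
#' @param seg A [microstate_segmentation()].
#' @param model The [microstate_model()] used for the segmentation.
#' @param eeg The segmented [eeg_record()].
#' @param peaks_only If `TRUE`, restrict the GEV sum to GFP peaks
#'   (default `FALSE`: all assigned samples).
#' @return An object of class `microstate_stats`: list with
#'   `occupation_ratio`, `mean_transition_time_ms`, `transition_matrix`,
#'   `gev`, `n_runs`.
#' @export
microstate_stats <- function(seg, model, eeg, peaks_only = FALSE) {
  stopifnot(inherits(seg, "microstate_segmentation"),
            inherits(model, "microstate_model"),
            inherits(eeg, "eeg_record"))
  K <- model$K
  lab <- seg$labels
  keep <- !is.na(lab)
  occ <- tabulate(lab[keep], nbins = K) / sum(keep)

  r <- rle(lab[keep])
  dwell <- vapply(seq_len(K), function(k) {
    runs <- r$lengths[r$values == k]
    if (length(runs) == 0) NA_real_ else mean(runs) * 1000 / seg$sampling_rate
  }, numeric(1))

  trans <- matrix(0, K, K)
  if (length(r$values) > 1) {
    from <- r$values[-length(r$values)]
    to <- r$values[-1]
    for (i in seq_along(from)) trans[from[i], to[i]] <- trans[from[i], to[i]] + 1
  }
  rs <- rowSums(trans)
  trans <- trans / ifelse(rs > 0, rs, NA_real_)

  x <- sweep(eeg$data, 2, colMeans(eeg$data))
  idx <- which(keep)
  if (peaks_only) idx <- intersect(idx, gfp_peaks(seg$gfp))
  xm <- sweep(x[, idx, drop = FALSE], 2,
              colMeans(x[, idx, drop = FALSE]))   # centre across channels
  maps_c <- sweep(model$maps, 2, colMeans(model$maps))
  num <- colSums(xm * maps_c[, lab[idx], drop = FALSE])
  den <- sqrt(colSums(xm^2) * colSums(maps_c^2)[lab[idx]])
  r2 <- ifelse(den > 0, (num / den)^2, 0)
  g2 <- seg$gfp[idx]^2
  gev <- if (sum(g2) > 0) sum(g2 * r2) / sum(g2) else NA_real_

  structure(list(occupation_ratio = occ, mean_transition_time_ms = dwell,
                 transition_matrix = trans, gev = gev,
                 n_runs = length(r$values)),
            class = "microstate_stats")
}

#' @export
print.microstate_stats <- function(x, ...) {
  cat("microstate_stats:\n")
  cat("  occupation ratio:", sprintf("%.3f", x$occupation_ratio), "\n")
  cat("  mean dwell (ms): ", sprintf("%.1f", x$mean_transition_time_ms), "\n")
  cat(sprintf("  GEV: %.3f over %d runs\n", x$gev, x$n_runs))
  invisible(x)
}

# all injective assignments of 1..k_small into 1..k_big via full
# permutations of the larger index set (exact for k_big <= 6)
assignment_score <- function(cmat) {
  ka <- nrow(cmat); kb <- ncol(cmat)
  kmax <- max(ka, kb)
  if (kmax > 6) stop("exhaustive matching supported for K <= 6 only")
  swap <- ka > kb
  if (swap) cmat <- t(cmat)
  ks <- nrow(cmat)
  per <- pracma::perms(seq_len(kmax))
  best <- -Inf
  best_assign <- NULL
  for (i in seq_len(nrow(per))) {
    pr <- per[i, seq_len(ks)]
    sc <- sum(abs(cmat[cbind(seq_len(ks), pr)])) / kmax
    if (sc > best + 1e-15) {
      best <- sc
      best_assign <- pr
    }
  }
  list(score = best, assign = best_assign, swapped = swap)
}

#' Optimal matching between two microstate models
#'
#' Exhaustively evaluates every one-to-one assignment between the states
#' of two models (all `K!` permutations, exact for `K <= 6`), scoring an
#' assignment by the mean absolute spatial correlation of matched map
#' pairs; when the models have different numbers of states the unmatched
#' slots of the larger model contribute 0 to the mean. Absolute
#' correlation makes the score polarity-invariant.
#'
#' @param a,b [microstate_model()] objects over the same channel set.
#' @return List with `permutation` (for each state of `a`, the index of
#'   the matched state of `b`, `NA` if unmatched), `score` (mean absolute
#'   correlation), and `correlation` (the `K_a x K_b` absolute spatial
#'   correlation matrix).
#' @export
match_microstates <- function(a, b) {
  stopifnot(inherits(a, "microstate_model"), inherits(b, "microstate_model"))
  if (nrow(a$maps) != nrow(b$maps)) {
    stop("models must share the same channel set")
  }
  cmat <- spatial_correlation(a$maps, b$maps)
  res <- assignment_score(cmat)
  perm <- rep(NA_integer_, a$K)
  if (res$swapped) {
    # res$assign maps states of b to states of a
    for (j in seq_len(b$K)) perm[res$assign[j]] <- j
  } else {
    assign_a <- res$assign[seq_len(a$K)]
    perm <- ifelse(assign_a <= b$K, assign_a, NA_integer_)
  }
  list(permutation = perm, score = res$score, correlation = abs(cmat))
}

#' Write microstate maps as tab-delimited text
#'
#' @param model A [microstate_model()].
#' @param path File path.
#' @export
write_microstates_tsv <- function(model, path) {
  stopifnot(inherits(model, "microstate_model"))
  tab <- data.frame(channel = rownames(model$maps), model$maps,
                    check.names = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_microstates_tsv
#' @export
read_microstates_tsv <- function(path) {
  tab <- read.delim(path, row.names = 1, check.names = FALSE)
  microstate_model(as.matrix(tab), channel_labels = rownames(tab))
}
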