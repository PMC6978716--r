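#' Parameter sweep configuration
#'
#' Bundles everything needed to evaluate a grid of (global coupling C,
#' threshold variance delta_V) points: the structural connectome, the
#' region-level lead field, optional target FC matrix and target
#' microstate maps to score against, the repeat structure, and the solver,
#' filter and clustering settings of the two evaluation branches.
#'
#' @param connectome A [structural_connectome()] or path to a connectome
#'   TSV.
#' @param lead_field A [lead_field()] or path to a lead field TSV.
#' @param C_grid,delta_grid Non-empty numeric grids of coupling strengths
#'   and threshold variances; the defaults bracket the regimes where both
#'   evaluation criteria peak.
#' @param target_fc Optional [fc_matrix()] (or TSV path) to score the BOLD
#'   branch against.
#' @param target_maps Optional [microstate_model()] (or TSV path) to score
#'   the EEG branch against.
#' @param n_repeats Repeats per grid point with different initial values
#'   (default 10).
#' @param duration_s,transient_s Simulation length and discarded transient
#'   in seconds (defaults 600 and 120).
#' @param seeds Optional explicit per-repeat seeds (default
#'   `base_seed + 0:(n_repeats-1)`).
#' @param base_seed Base seed for the default repeat seeds.
#' @param output_rate Neural output sampling rate, Hz.
#' @param bold_rate BOLD output rate, Hz (default 0.4, i.e. TR 2.5 s).
#' @param bold_band Band for [bandpass_bold()].
#' @param apply_bold_band Apply the BOLD band-pass before FC? (default
#'   `TRUE`; set `FALSE` for recordings too short to resolve the band).
#' @param regress_global_signal Regress the global mean out of BOLD before
#'   FC? (default `TRUE`).
#' @param eeg_band,eeg_rate Band and target rate of the simulated-EEG
#'   preprocessing.
#' @param K,n_restarts Microstate clustering settings.
#' @param window_b,lambda_penalty Segmentation-smoothing settings.
#' @param rtol,atol Solver tolerances.
#' @return An object of class `sweep_config`.
#' @export
sweep_config <- function(connectome, lead_field,
                         C_grid = seq(0, 0.7, by = 0.05),
                         delta_grid = seq(0.55, 0.75, by = 0.01),
                         target_fc = NULL, target_maps = NULL,
                         n_repeats = 10, duration_s = 600, transient_s = 120,
                         seeds = NULL, base_seed = 1,
                         output_rate = 1000, bold_rate = 0.4,
                         bold_band = c(0.008, 0.1), apply_bold_band = TRUE,
                         regress_global_signal = TRUE,
                         eeg_band = c(10, 15), eeg_rate = 100,
                         K = 4, n_restarts = 20,
                         window_b = 3, lambda_penalty = 5,
                         rtol = 1e-3, atol = 1e-6) {
  if (is.character(connectome)) connectome <- read_connectome_tsv(connectome)
  if (is.character(lead_field)) lead_field <- read_leadfield_tsv(lead_field)
  if (is.character(target_fc)) target_fc <- read_fc_tsv(target_fc)
  if (is.character(target_maps)) target_maps <- read_microstates_tsv(target_maps)
  stopifnot(inherits(connectome, "structural_connectome"),
            inherits(lead_field, "lead_field"))
  if (length(C_grid) == 0 || length(delta_grid) == 0) {
    stop("parameter grids must be non-empty")
  }
  if (n_repeats < 1) stop("n_repeats must be >= 1")
  if (is.null(seeds)) seeds <- base_seed + seq_len(n_repeats) - 1
  if (length(seeds) != n_repeats) stop("need one seed per repeat")
  cfg <- list(connectome = connectome, lead_field = lead_field,
              C_grid = C_grid, delta_grid = delta_grid,
              target_fc = target_fc, target_maps = target_maps,
              n_repeats = n_repeats, duration_s = duration_s,
              transient_s = transient_s, seeds = seeds,
              output_rate = output_rate, bold_rate = bold_rate,
              bold_band = bold_band, apply_bold_band = apply_bold_band,
              regress_global_signal = regress_global_signal,
              eeg_band = eeg_band, eeg_rate = eeg_rate,
              K = K, n_restarts = n_restarts,
              window_b = window_b, lambda_penalty = lambda_penalty,
              rtol = rtol, atol = atol)
  structure(cfg, class = "sweep_config")
}

#' @export
print.sweep_config <- function(x, ...) {
  cat(sprintf(
    "sweep_config: %d x %d grid, %d repeats, %g s (%g s transient), %d regions\n",
    length(x$C_grid), length(x$delta_grid), x$n_repeats, x$duration_s,
    x$transient_s, n_regions(x$connectome)))
  invisible(x)
}

#' Run one repeat of the full evaluation pipeline
#'
#' Simulates the neural mass model at one parameter point and carries the
#' trajectory through both evaluation branches: BOLD -> (band-pass) ->
#' global-signal regression -> FC, and lead-field projection ->
#' preprocessing -> microstate fit + smoothed segmentation -> statistics.
#'
#' @param C,delta Coupling strength and threshold variance.
#' @param cfg A [sweep_config()].
#' @param seed Repeat seed (initial state).
#' @return List with `fc` ([fc_matrix()]), `model`
#'   ([microstate_model()]), `stats` ([microstate_stats()]), `seed`.
#' @export
simulate_observables <- function(C, delta, cfg, seed = 1) {
  stopifnot(inherits(cfg, "sweep_config"))
  params <- neural_mass_params(C = C, delta_V = delta)
  traj <- simulate_neural_mass(params, cfg$connectome,
                               duration_s = cfg$duration_s,
                               transient_s = cfg$transient_s,
                               output_rate = cfg$output_rate,
                               seed = seed, rtol = cfg$rtol, atol = cfg$atol)
  bold <- simulate_bold(traj, bold_rate = cfg$bold_rate,
                        rtol = cfg$rtol, atol = cfg$atol)
  if (isTRUE(cfg$apply_bold_band)) {
    bold <- bandpass_bold(bold, cfg$bold_band[1], cfg$bold_band[2])
  }
  if (isTRUE(cfg$regress_global_signal)) bold <- regress_global(bold)
  fc <- compute_fc(bold)

  eeg <- project_sources(traj, cfg$lead_field)
  eeg <- preprocess_simulated_eeg(eeg, band = cfg$eeg_band,
                                  target_rate = cfg$eeg_rate)
  model <- fit_microstates(eeg, K = cfg$K, n_restarts = cfg$n_restarts,
                           seed = seed)
  seg <- segment_smooth(eeg, model, window_b = cfg$window_b,
                        lambda_penalty = cfg$lambda_penalty)
  stats <- microstate_stats(seg, model, eeg)
  list(fc = fc, model = model, stats = stats, seed = seed)
}

#' Evaluate one parameter point over all repeats
#'
#' Runs [simulate_observables()] for every repeat seed, scores each repeat
#' against the configured targets (FC similarity of the lower triangles;
#' best-permutation mean absolute spatial correlation of the microstate
#' maps), and aggregates the mean and standard deviation across repeats.
#' A repeat whose solver fails is recorded as missing and flagged; the
#' evaluation continues.
#'
#' @param C,delta Coupling strength and threshold variance.
#' @param cfg A [sweep_config()].
#' @return List record with `C`, `delta`, per-repeat vectors
#'   `fc_similarity` and `microstate_similarity`, their means and standard
#'   deviations, the per-repeat `stats`, `seeds`, and `flagged`.
#' @export
evaluate_parameter_point <- function(C, delta, cfg) {
  stopifnot(inherits(cfg, "sweep_config"))
  nr <- cfg$n_repeats
  fc_sim <- rep(NA_real_, nr)
  ms_sim <- rep(NA_real_, nr)
  stats <- vector("list", nr)
  failed <- logical(nr)
  for (i in seq_len(nr)) {
    obs <- tryCatch(
      simulate_observables(C, delta, cfg, seed = cfg$seeds[i]),
      error = function(e) e)
    if (inherits(obs, "error")) {
      failed[i] <- TRUE
      warning(sprintf("repeat %d at (C=%g, delta=%g) failed: %s", i, C,
                      delta, conditionMessage(obs)))
      next
    }
    if (!is.null(cfg$target_fc)) {
      fc_sim[i] <- fc_similarity(obs$fc, cfg$target_fc)
    }
    if (!is.null(cfg$target_maps)) {
      ms_sim[i] <- match_microstates(obs$model, cfg$target_maps)$score
    }
    stats[[i]] <- obs$stats
  }
  list(C = C, delta = delta,
       fc_similarity = fc_sim, microstate_similarity = ms_sim,
       fc_mean = mean(fc_sim, na.rm = TRUE), fc_sd = sd(fc_sim[!failed]),
       ms_mean = mean(ms_sim, na.rm = TRUE), ms_sd = sd(ms_sim[!failed]),
       stats = stats, seeds = cfg$seeds, flagged = any(failed),
       n_ok = sum(!failed))
}

#' Run the full parameter sweep
#'
#' Evaluates every (C, delta_V) grid point with [evaluate_parameter_point()].
#' Per-repeat seeds are fixed by the configuration, so the result is
#' independent of evaluation order and bit-reproducible for an identical
#' configuration (the configuration hash is recorded with the result).
#'
#' @param cfg A [sweep_config()].
#' @return An object of class `sweep_result`: a data frame with one row
#'   per grid point (`C`, `delta`, `fc_mean`, `fc_sd`, `ms_mean`, `ms_sd`,
#'   `n_ok`, `flagged`), with the full per-point records in the
#'   `"records"` attribute and the configuration hash in `"config_hash"`.
#' @export
run_sweep <- function(cfg) {
  stopifnot(inherits(cfg, "sweep_config"))
  grid <- expand.grid(C = cfg$C_grid, delta = cfg$delta_grid,
                      KEEP.OUT.ATTRS = FALSE)
  records <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    records[[i]] <- evaluate_parameter_point(grid$C[i], grid$delta[i], cfg)
  }
  tab <- data.frame(
    C = grid$C, delta = grid$delta,
    fc_mean = vapply(records, `[[`, 1, "fc_mean"),
    fc_sd = vapply(records, `[[`, 1, "fc_sd"),
    ms_mean = vapply(records, `[[`, 1, "ms_mean"),
    ms_sd = vapply(records, `[[`, 1, "ms_sd"),
    n_ok = vapply(records, `[[`, 1L, "n_ok"),
    flagged = vapply(records, `[[`, TRUE, "flagged"))
  if (all(tab$n_ok == 0)) stop("all grid points failed")
  attr(tab, "records") <- records
  attr(tab, "config_hash") <- rlang::hash(unclass(cfg))
  class(tab) <- c("sweep_result", "data.frame")
  tab
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("sweep_result: %d grid points (config %s)\n", nrow(x),
              attr(x, "config_hash")))
  print.data.frame(x, digits = 3)
  invisible(x)
}

#' Write sweep results to a directory
#'
#' Writes `results.tsv` (the per-point table), `records.json` (per-point
#' similarity vectors and microstate statistics) and `config_hash.txt`.
#'
#' @param result A `sweep_result` from [run_sweep()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sweep_results <- function(result, dir) {
  stopifnot(inherits(result, "sweep_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(as.data.frame(result), file.path(dir, "results.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  recs <- lapply(attr(result, "records"), function(r) {
    r$stats <- lapply(r$stats, function(s) {
      if (is.null(s)) NULL else unclass(s)
    })
    r
  })
  jsonlite::write_json(recs, file.path(dir, "records.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  writeLines(attr(result, "config_hash"), file.path(dir, "config_hash.txt"))
  invisible(dir)
}

#' Heatmap of a sweep similarity surface
#'
#' @param result A `sweep_result`.
#' @param which `"fc"` or `"microstate"`.
#' @param ... Passed to [graphics::image()].
#' @return The plotted matrix (delta x C), invisibly.
#' @export
plot_sweep_similarity <- function(result, which = c("fc", "microstate"), ...) {
  stopifnot(inherits(result, "sweep_result"))
  which <- match.arg(which)
  col <- if (which == "fc") "fc_mean" else "ms_mean"
  Cs <- sort(unique(result$C))
  ds <- sort(unique(result$delta))
  m <- matrix(NA_real_, length(Cs), length(ds))
  for (i in seq_len(nrow(result))) {
    m[match(result$C[i], Cs), match(result$delta[i], ds)] <- result[[col]][i]
  }
  image(Cs, ds, m, xlab = "global coupling C",
        ylab = expression(delta[V]), main = paste(which, "similarity"),
        col = hcl.colors(64, "viridis"), ...)
  invisible(m)
}

#' Desk-scale example configuration
#'
#' A small, fast preset used by the examples and the package's own
#' end-to-end checks: an 8-region synthetic connectome, a 32-channel
#' synthetic lead field reduced to region resolution, 60 s simulations
#' (10 s transient), 2 repeats, BOLD at 2 Hz without the slow band-pass
#' (60 s is too short to resolve 0.008 Hz), and a 2 x 2 parameter grid
#' around the two dynamical regimes of interest. Targets (FC and maps)
#' are generated from a reference simulation with the intact connectome
#' at `target_point`, standing in for empirical recordings.
#'
#' @param seed Base seed for the synthetic inputs and repeats.
#' @param n_regions,n_channels,n_sources Synthetic input sizes.
#' @param duration_s,transient_s,n_repeats Repeat structure.
#' @param C_grid,delta_grid Parameter grids.
#' @param target_point `(C, delta)` of the target-generating reference run
#'   (`NULL` to skip target generation).
#' @param ... Further arguments passed to [sweep_config()].
#' @return A [sweep_config()] with targets filled in.
#' @export
desk_sweep_config <- function(seed = 1, n_regions = 8, n_channels = 32,
                              n_sources = 160, duration_s = 60,
                              transient_s = 10, n_repeats = 2,
                              C_grid = c(0.25, 0.5),
                              delta_grid = c(0.63, 0.7),
                              target_point = c(0.5, 0.63), ...) {
  sc <- generate_connectome(n_regions, edge_density = 0.35,
                            interhemispheric_scale = 2, seed = seed)
  roi <- roi_assignment(n_sources, n_regions)
  dense <- generate_leadfield(n_channels, n_sources, roi, smoothness = 0.5,
                              seed = seed + 1)
  lf <- reduce_leadfield(dense, roi, energy_fraction = 0.8,
                         region_labels = sc$region_labels)
  cfg <- sweep_config(sc, lf, C_grid = C_grid, delta_grid = delta_grid,
                      n_repeats = n_repeats, duration_s = duration_s,
                      transient_s = transient_s, base_seed = seed + 100,
                      bold_rate = 2, apply_bold_band = FALSE, ...)
  if (!is.null(target_point)) {
    ref <- simulate_observables(target_point[1], target_point[2], cfg,
                                seed = seed + 500)
    cfg$target_fc <- ref$fc
    cfg$target_maps <- ref$model
  }
  cfg
}

#' Read a sweep configuration from YAML
#'
#' The YAML file holds scalar settings plus paths to the connectome, lead
#' field and optional target TSV files; field names match the arguments
#' of [sweep_config()].
#'
#' @param path Path to a YAML configuration file.
#' @return A [sweep_config()].
#' @export
read_sweep_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), names(formals(sweep_config)))]
  do.call(sweep_config, args)
}
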