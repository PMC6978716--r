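#' Lead field container (channels x regions gain)
#'
#' Linear gain matrix mapping region-level source activity to scalp channel
#' measurements. Columns correspond to regions in the same order as the
#' connectome used for simulation.
#'
#' @param gain Numeric channels x regions matrix.
#' @param channel_labels,region_labels Optional dimension labels.
#' @return An object of class `lead_field`.
#' @export
lead_field <- function(gain, channel_labels = NULL, region_labels = NULL) {
  gain <- as.matrix(gain)
  if (!all(is.finite(gain))) stop("lead field gain must be finite")
  if (any(colSums(abs(gain)) == 0)) {
    stop("lead field has an all-zero region column")
  }
  if (is.null(channel_labels)) {
    channel_labels <- rownames(gain)
    if (is.null(channel_labels)) {
      channel_labels <- paste0("CH", seq_len(nrow(gain)))
    }
  }
  if (is.null(region_labels)) {
    region_labels <- colnames(gain)
    if (is.null(region_labels)) region_labels <- paste0("R", seq_len(ncol(gain)))
  }
  dimnames(gain) <- list(channel_labels, region_labels)
  structure(list(gain = gain, channel_labels = channel_labels,
                 region_labels = region_labels), class = "lead_field")
}

#' @export
print.lead_field <- function(x, ...) {
  cat(sprintf("lead_field: %d channels x %d regions\n",
              nrow(x$gain), ncol(x$gain)))
  invisible(x)
}

#' Balanced round-robin ROI assignment for sources
#'
#' @param n_sources Number of dense sources.
#' @param n_rois Number of regions of interest.
#' @return Integer vector of length `n_sources` with values in `1..n_rois`.
#' @export
roi_assignment <- function(n_sources, n_rois) {
  if (n_rois > n_sources) stop("need at least one source per ROI")
  rep_len(seq_len(n_rois), n_sources)
}

#' Generate a synthetic dense lead field
#'
#' Stands in for a boundary-element head model. Channels are placed evenly
#' on a unit ring (a schematic scalp montage); each ROI gets a random centre
#' inside the ring and its sources are jittered around that centre. The gain
#' from source `s` to channel `c` is the spatial kernel
#' `exp(-d(c, s) / smoothness)`, so columns of sources in the same ROI are
#' strongly correlated across channels, with the correlation length
#' controlled by `smoothness`. The exponential (Matern-1/2) kernel is used
#' because its slowly decaying spectrum keeps the gain matrix at full
#' numerical row rank whenever `n_channels <= n_sources`.
#'
#' @param n_channels Number of scalp channels.
#' @param n_sources Number of dense cortical sources.
#' @param roi_of_source Integer vector assigning every source to exactly one
#'   ROI (see [roi_assignment()]).
#' @param smoothness Positive kernel length-scale (ring has radius 1).
#' @param seed Integer seed; output is deterministic given the seed.
#' @param roi_spread Standard deviation of the per-source jitter around the
#'   ROI centre.
#' @return A dense numeric channels x sources gain matrix with channel row
#'   names; the ROI assignment is kept in the `"roi_of_source"` attribute.
#' @export
generate_leadfield <- function(n_channels, n_sources, roi_of_source,
                               smoothness = 0.5, seed = 1, roi_spread = 0.05) {
  if (length(roi_of_source) != n_sources || anyNA(roi_of_source)) {
    stop("every source must be assigned to exactly one ROI")
  }
  if (smoothness <= 0) stop("smoothness must be positive")
  roi_of_source <- as.integer(factor(roi_of_source))
  set.seed(seed)
  theta <- 2 * pi * (seq_len(n_channels) - 1) / n_channels
  chan_pos <- cbind(cos(theta), sin(theta))
  n_roi <- max(roi_of_source)
  # ROI centres on an annulus: cortical patches lie near the scalp surface,
  # and keeping them away from the ring centre keeps every source's
  # channel-distance profile informative
  r <- 0.35 + 0.35 * runif(n_roi)
  a <- 2 * pi * runif(n_roi)
  centers <- cbind(r * cos(a), r * sin(a))
  src_pos <- centers[roi_of_source, , drop = FALSE] +
    matrix(rnorm(2 * n_sources, sd = roi_spread), ncol = 2)
  d <- sqrt(outer(chan_pos[, 1], src_pos[, 1], "-")^2 +
            outer(chan_pos[, 2], src_pos[, 2], "-")^2)
  gain <- exp(-d / smoothness)
  rownames(gain) <- paste0("CH", seq_len(n_channels))
  attr(gain, "roi_of_source") <- roi_of_source
  gain
}

#' Reduce a dense lead field to region resolution by per-ROI SVD
#'
#' For each ROI the channels x (ROI sources) gain block is decomposed by
#' singular value decomposition; the leading components whose cumulative
#' singular-value sum first reaches `energy_fraction` of the total are
#' retained, the block is reconstructed from them, and the reconstructed
#' columns are averaged into a single channel vector for that region. With
#' `energy_fraction = 1` (or a rank-1 block) this reduces exactly to the
#' plain per-ROI column mean; for spatially smooth lead fields the two are
#' nearly identical.
#'
#' @param dense Numeric channels x sources gain matrix.
#' @param roi_of_source Integer ROI assignment per source (defaults to the
#'   `"roi_of_source"` attribute of `dense`).
#' @param energy_fraction Fraction in (0, 1] of the cumulative singular-value
#'   sum to retain (default 0.8).
#' @param region_labels Optional labels for the reduced columns.
#' @param n_rois Declared number of ROIs (integer assignments `1..n_rois`);
#'   an ROI with no assigned source is rejected.
#' @return A [lead_field()] with one column per ROI.
#' @export
reduce_leadfield <- function(dense, roi_of_source = attr(dense, "roi_of_source"),
                             energy_fraction = 0.8, region_labels = NULL,
                             n_rois = NULL) {
  dense <- as.matrix(dense)
  if (is.null(roi_of_source)) stop("roi_of_source is required")
  if (length(roi_of_source) != ncol(dense) || anyNA(roi_of_source)) {
    stop("every source must be assigned to exactly one ROI")
  }
  if (energy_fraction <= 0 || energy_fraction > 1) {
    stop("energy_fraction must lie in (0, 1]")
  }
  if (!is.null(n_rois) && is.numeric(roi_of_source) &&
      any(tabulate(roi_of_source, nbins = n_rois) == 0)) {
    stop("empty ROI: every declared ROI needs at least one source")
  }
  rois <- sort(unique(roi_of_source))
  gain <- matrix(0, nrow(dense), length(rois))
  for (j in seq_along(rois)) {
    block <- dense[, roi_of_source == rois[j], drop = FALSE]
    sv <- svd(block)
    cum <- cumsum(sv$d) / sum(sv$d)
    r <- which(cum >= energy_fraction - 1e-12)[1]
    rec <- sv$u[, seq_len(r), drop = FALSE] %*%
      (sv$d[seq_len(r)] * t(sv$v[, seq_len(r), drop = FALSE]))
    gain[, j] <- rowMeans(rec)
  }
  if (is.null(region_labels)) region_labels <- paste0("R", rois)
  lead_field(gain, rownames(dense), region_labels)
}

#' Read / write a lead field as tab-delimited text
#'
#' Square-format table: channel labels as row header column, region labels
#' as column headers.
#'
#' @param path File path.
#' @export
read_leadfield_tsv <- function(path) {
  tab <- read.delim(path, row.names = 1, check.names = FALSE)
  lead_field(as.matrix(tab), rownames(tab), colnames(tab))
}

#' @rdname read_leadfield_tsv
#' @param lf A [lead_field()] to write.
#' @export
write_leadfield_tsv <- function(lf, path) {
  stopifnot(inherits(lf, "lead_field"))
  tab <- data.frame(channel = lf$channel_labels, lf$gain, check.names = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
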