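#' Functional connectivity matrix container
#'
#' @param r Square symmetric matrix of Pearson correlations with unit
#'   diagonal.
#' @param region_labels Optional region labels.
#' @return An object of class `fc_matrix`.
#' @export
fc_matrix <- function(r, region_labels = NULL) {
  r <- as.matrix(r)
  if (nrow(r) != ncol(r)) stop("FC matrix must be square")
  if (any(abs(r) > 1 + 1e-8, na.rm = TRUE)) stop("correlations must lie in [-1, 1]")
  if (max(abs(r - t(r))) > 1e-8) stop("FC matrix must be symmetric")
  if (is.null(region_labels)) {
    region_labels <- rownames(r)
    if (is.null(region_labels)) region_labels <- paste0("R", seq_len(nrow(r)))
  }
  dimnames(r) <- list(region_labels, region_labels)
  structure(list(r = r, region_labels = region_labels), class = "fc_matrix")
}

#' @export
print.fc_matrix <- function(x, ...) {
  lt <- x$r[lower.tri(x$r)]
  cat(sprintf("fc_matrix: %d regions, mean off-diagonal r = %.3f\n",
              nrow(x$r), mean(lt)))
  invisible(x)
}

#' Band-pass filter BOLD signals
#'
#' Zero-phase (forward-backward Butterworth) band-pass with the standard
#' resting-state transmission range 0.008-0.1 Hz as default; the mean of
#' each region's series is removed.
#'
#' @param y A [bold_time_series()].
#' @param low,high Band edges in Hz (`high` must be below Nyquist).
#' @param order Butterworth order per pass (default 2).
#' @return The filtered [bold_time_series()].
#' @export
bandpass_bold <- function(y, low = 0.008, high = 0.1, order = 2) {
  stopifnot(inherits(y, "bold_time_series"))
  out <- bandpass_rows(y$y, y$sampling_rate, low, high, order)
  bold_time_series(out, y$sampling_rate, y$region_labels)
}

#' Regress the global signal out of BOLD series
#'
#' The across-region mean time course is regressed out of every region's
#' series by least squares with an intercept; residuals are returned and
#' are orthogonal to the global regressor. If the global signal has zero
#' variance the input is returned unchanged with a warning.
#'
#' @param y A [bold_time_series()] with at least two regions.
#' @return A [bold_time_series()] of residuals.
#' @export
regress_global <- function(y) {
  stopifnot(inherits(y, "bold_time_series"))
  if (nrow(y$y) < 2) stop("need at least 2 regions")
  g <- colMeans(y$y)
  if (var(g) < .Machine$double.eps) {
    warning("global signal has zero variance; returning input unchanged")
    return(y)
  }
  X <- cbind(1, g)
  res <- t(lm.fit(X, t(y$y))$residuals)
  bold_time_series(res, y$sampling_rate, y$region_labels)
}

#' Compute a functional connectivity matrix from BOLD
#'
#' Pearson correlations at zero lag between all region pairs. A region
#' with zero variance gets zero correlations (and unit self-correlation)
#' with a warning.
#'
#' @param y A [bold_time_series()] with at least 3 samples.
#' @return An [fc_matrix()].
#' @export
compute_fc <- function(y) {
  stopifnot(inherits(y, "bold_time_series"))
  if (ncol(y$y) < 3) stop("need at least 3 samples")
  v <- apply(y$y, 1, var)
  bad <- v <= .Machine$double.eps
  r <- matrix(0, nrow(y$y), nrow(y$y))
  if (any(!bad)) {
    r[!bad, !bad] <- cor(t(y$y[!bad, , drop = FALSE]))
  }
  if (any(bad)) {
    warning(sprintf("zero-variance region(s) %s: correlations set to 0",
                    paste(which(bad), collapse = ",")))
  }
  diag(r) <- 1
  fc_matrix(r, y$region_labels)
}

#' Similarity between two FC matrices
#'
#' Pearson correlation between the strictly-lower-triangle entries of the
#' two matrices (diagonal excluded). This is the standard FC-fitting score
#' used when comparing simulated with empirical resting-state
#' connectivity.
#'
#' @param a,b [fc_matrix()] objects over the same regions in the same
#'   order.
#' @return Scalar in `[-1, 1]`.
#' @export
fc_similarity <- function(a, b) {
  stopifnot(inherits(a, "fc_matrix"), inherits(b, "fc_matrix"))
  if (!identical(dim(a$r), dim(b$r)) ||
      !identical(a$region_labels, b$region_labels)) {
    stop("FC matrices must share the same regions in the same order")
  }
  lt <- lower.tri(a$r)
  cor(a$r[lt], b$r[lt])
}

#' Read / write an FC matrix as tab-delimited text
#'
#' @param path File path.
#' @export
read_fc_tsv <- function(path) {
  tab <- read.delim(path, row.names = 1, check.names = FALSE)
  fc_matrix(as.matrix(tab), rownames(tab))
}

#' @rdname read_fc_tsv
#' @param fc An [fc_matrix()] to write.
#' @export
write_fc_tsv <- function(fc, path) {
  stopifnot(inherits(fc, "fc_matrix"))
  tab <- data.frame(region = fc$region_labels, fc$r, check.names = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
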