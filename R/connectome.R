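#' Structural connectome container
#'
#' A weighted, undirected region-by-region graph of anatomical connection
#' strengths. Weights constrain the inter-regional excitatory coupling of the
#' neural mass model: region `i` receives the connectivity-weighted mean of
#' the other regions' excitatory firing rates, with weights `weights[i, j]`.
#'
#' @param weights Square numeric matrix of non-negative connection strengths
#'   (arbitrary units). Must be symmetric with a zero diagonal.
#' @param region_labels Character vector of region identifiers (defaults to
#'   the matrix dimnames, or `R1..Rn`).
#' @param hemisphere Per-region tag, one of `"left"`, `"right"`, `"none"`.
#' @param id Optional provenance tag carried into simulated trajectories.
#' @param tol Numeric tolerance for the symmetry check.
#'
#' @return An object of class `structural_connectome`: a list with elements
#'   `weights`, `region_labels`, `hemisphere`, `id`.
#' @export
structural_connectome <- function(weights, region_labels = NULL,
                                  hemisphere = NULL, id = "connectome",
                                  tol = 1e-8) {
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights)) {
    stop("connectome weight matrix must be square")
  }
  n <- nrow(weights)
  if (!is.numeric(weights) || anyNA(weights)) {
    stop("connectome weights must be numeric and free of NA")
  }
  if (any(weights < 0)) stop("connectome weights must be non-negative")
  if (max(abs(weights - t(weights))) > tol * max(1, max(abs(weights)))) {
    stop("connectome weight matrix must be symmetric")
  }
  if (any(diag(weights) != 0)) stop("connectome diagonal must be zero")
  # symmetrize exactly so downstream equality checks are bitwise
  weights <- (weights + t(weights)) / 2
  diag(weights) <- 0
  if (is.null(region_labels)) {
    region_labels <- rownames(weights)
    if (is.null(region_labels)) region_labels <- paste0("R", seq_len(n))
  }
  if (length(region_labels) != n) {
    stop("region_labels length must match the number of regions")
  }
  if (is.null(hemisphere)) hemisphere <- rep("none", n)
  hemisphere <- match.arg(hemisphere, c("left", "right", "none"),
                          several.ok = TRUE)
  if (length(hemisphere) == 1) hemisphere <- rep(hemisphere, n)
  if (length(hemisphere) != n) {
    stop("hemisphere length must match the number of regions")
  }
  dimnames(weights) <- list(region_labels, region_labels)
  structure(list(weights = weights, region_labels = region_labels,
                 hemisphere = hemisphere, id = id),
            class = "structural_connectome")
}

#' @export
print.structural_connectome <- function(x, ...) {
  n <- length(x$region_labels)
  m <- sum(x$weights[upper.tri(x$weights)] > 0)
  cat(sprintf("structural_connectome '%s': %d regions, %d edges (density %.2f)\n",
              x$id, n, m, m / (n * (n - 1) / 2)))
  invisible(x)
}

n_regions <- function(sc) length(sc$region_labels)

#' Generate a synthetic structural connectome
#'
#' Emulates key features of tractography-derived connectomes: non-negative
#' symmetric weights with a heavy-tailed (log-normal) strength distribution,
#' sparse off-diagonal structure, and stronger interhemispheric homotopic
#' connections. The first `n_regions/2` regions form the left hemisphere and
#' region `i` is homotopic to region `i + n_regions/2`; homotopic edges are
#' always present and their weights are multiplied by
#' `interhemispheric_scale`.
#'
#' @param n_regions Even integer >= 4, number of cortical regions.
#' @param edge_density Fraction in (0, 1]: probability that a non-homotopic
#'   region pair is connected.
#' @param interhemispheric_scale Positive multiplier applied to homotopic
#'   left-right edge weights.
#' @param seed Integer seed; output is deterministic given the seed.
#' @param weight_meanlog,weight_sdlog Log-normal parameters of the base edge
#'   strength distribution.
#'
#' @return A [structural_connectome()].
#' @export
generate_connectome <- function(n_regions, edge_density = 0.3,
                                interhemispheric_scale = 2, seed = 1,
                                weight_meanlog = 0, weight_sdlog = 1.5) {
  if (n_regions < 4 || n_regions %% 2 != 0) {
    stop("n_regions must be an even integer >= 4")
  }
  if (edge_density <= 0 || edge_density > 1) {
    stop("edge_density must lie in (0, 1]")
  }
  if (interhemispheric_scale <= 0) {
    stop("interhemispheric_scale must be positive")
  }
  set.seed(seed)
  half <- n_regions / 2
  ut <- upper.tri(matrix(0, n_regions, n_regions))
  idx <- which(ut, arr.ind = TRUE)          # column-major pair order
  m <- nrow(idx)
  present <- runif(m) <= edge_density
  w <- rlnorm(m, meanlog = weight_meanlog, sdlog = weight_sdlog)
  homotopic <- idx[, 2] == idx[, 1] + half
  present[homotopic] <- TRUE
  w[homotopic] <- w[homotopic] * interhemispheric_scale
  w[!present] <- 0
  weights <- matrix(0, n_regions, n_regions)
  weights[ut] <- w
  weights <- weights + t(weights)
  labels <- c(paste0("L", seq_len(half)), paste0("R", seq_len(half)))
  hemi <- c(rep("left", half), rep("right", half))
  structural_connectome(weights, labels, hemi,
                        id = sprintf("synthetic-n%d-seed%d", n_regions, seed))
}

#' Shuffle connectome weights (null model)
#'
#' Permutes the strictly-upper-triangle weights uniformly at random and
#' mirrors them back, destroying the topology while preserving the weight
#' multiset, symmetry and the zero diagonal. Used as the
#' shuffled-connectivity control when scoring simulated dynamics.
#'
#' @param sc A [structural_connectome()].
#' @param seed Integer seed for the permutation.
#' @return A [structural_connectome()] with permuted weights.
#' @export
shuffle_connectome <- function(sc, seed = 1) {
  stopifnot(inherits(sc, "structural_connectome"))
  set.seed(seed)
  w <- sc$weights
  ut <- upper.tri(w)
  vals <- w[ut]
  w[ut] <- vals[sample.int(length(vals))]
  w[lower.tri(w)] <- t(w)[lower.tri(w)]
  structural_connectome(w, sc$region_labels, sc$hemisphere,
                        id = paste0(sc$id, "-shuffled", seed))
}

#' Read / write a connectome as tab-delimited text
#'
#' The format is a square numeric table with region labels as both row and
#' column headers.
#'
#' @param path File path.
#' @param hemisphere Optional per-region hemisphere tags (recycled;
#'   `"none"` by default).
#' @return `read_connectome_tsv` returns a [structural_connectome()];
#'   `write_connectome_tsv` returns `path` invisibly.
#' @export
read_connectome_tsv <- function(path, hemisphere = NULL) {
  tab <- read.delim(path, row.names = 1, check.names = FALSE)
  structural_connectome(as.matrix(tab), rownames(tab), hemisphere,
                        id = basename(path))
}

#' @rdname read_connectome_tsv
#' @param sc A [structural_connectome()] to write.
#' @export
write_connectome_tsv <- function(sc, path) {
  stopifnot(inherits(sc, "structural_connectome"))
  tab <- data.frame(region = sc$region_labels, sc$weights,
                    check.names = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
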