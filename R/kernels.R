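#' Pairwise distance matrix
#'
#' Full symmetric matrix of distances between sampling locations, either
#' planar Euclidean (coordinate units) or great-circle on a sphere of radius
#' 6371.0088 km (result in km; coordinates must then be lon/lat degrees).
#'
#' @param coords n x 2 numeric matrix of coordinates.
#' @param metric `"planar"` or `"great-circle"`.
#' @return n x n distance matrix with attribute `metric`.
#' @export
pairwise_distances <- function(coords, metric = c("planar", "great-circle")) {
  metric <- match.arg(metric)
  coords <- as.matrix(coords)
  if (!all(is.finite(coords))) stop("coordinates must be finite", call. = FALSE)
  if (metric == "great-circle") {
    if (any(abs(coords[, 1L]) > 180) || any(abs(coords[, 2L]) > 90)) {
      stop("great-circle coordinates must be lon in [-180,180], lat in [-90,90]",
           call. = FALSE)
    }
    d <- geosphere::distm(coords, fun = function(a, b) {
      geosphere::distHaversine(a, b, r = 6371.0088)
    })
  } else {
    d <- as.matrix(stats::dist(coords))
  }
  dimnames(d) <- NULL
  # symmetrize against floating-point asymmetry from the pairwise evaluation
  d <- (d + t(d)) / 2
  diag(d) <- 0
  attr(d, "metric") <- metric
  d
}

#' Adaptive bandwidths from nearest-neighbour distances
#'
#' For each location, the distance to its N-th nearest neighbour (self
#' excluded), used as a per-location kernel bandwidth on irregular designs.
#'
#' @param d distance matrix from [pairwise_distances()].
#' @param n_neighbors integer N, 2 <= N <= n-1 (N = 1 is allowed for
#'   degenerate test designs).
#' @return numeric vector of n bandwidths.
#' @export
adaptive_bandwidths <- function(d, n_neighbors) {
  d <- as.matrix(d)
  n <- nrow(d)
  N <- as.integer(n_neighbors)
  if (N < 1L || N > n - 1L) {
    stop("n_neighbors must be between 1 and n-1", call. = FALSE)
  }
  vapply(seq_len(n), function(i) {
    sort(d[i, -i])[N]
  }, numeric(1))
}

#' Bi-square kernel weights
#'
#' Computes the n x n spatial weight matrix
#' \deqn{w_{ij} = (1 - (d_{ij}/\tau_i)^2)^2 \quad d_{ij} < \tau_i, \qquad
#'       w_{ij} = 0 \quad d_{ij} \ge \tau_i,}
#' with a single fixed bandwidth or per-location adaptive bandwidths. The
#' kernel has compact support: weights vanish exactly at and beyond the
#' bandwidth. The self-weight \eqn{w_{ii} = 1} is included by default;
#' leave-one-out procedures disable it.
#'
#' @param d distance matrix.
#' @param bandwidth positive scalar (fixed mode) or vector of n per-location
#'   bandwidths (e.g. from [adaptive_bandwidths()]).
#' @param self_weight include the focal location itself (default `TRUE`)?
#' @return object of class `kernel_weights`: list with `w` (n x n),
#'   `bandwidth`, `self_weight`.
#' @export
bisquare_weights <- function(d, bandwidth, self_weight = TRUE) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (length(bandwidth) != 1L && length(bandwidth) != n) {
    stop("bandwidth must be a scalar or one value per location", call. = FALSE)
  }
  tau <- rep_len(as.numeric(bandwidth), n)
  if (any(tau <= 0) || any(!is.finite(tau))) {
    stop("bandwidths must be positive and finite", call. = FALSE)
  }
  u <- sweep(d, 1L, tau, "/")  # row i scaled by tau_i
  u <- pmin(u, 1)
  w <- ifelse(u < 1, (1 - u^2)^2, 0)
  if (!self_weight) {
    diag(w) <- 0
  } else {
    diag(w) <- 1
  }
  isolated <- which(rowSums(w) <= 0)
  if (length(isolated)) {
    stop("isolated location(s) with empty neighbourhood: ",
         paste(isolated, collapse = ", "), call. = FALSE)
  }
  structure(list(w = w, bandwidth = tau, self_weight = self_weight,
                 kernel = "bisquare"),
            class = "kernel_weights")
}

#' Evaluate the bi-square kernel
#'
#' @param d nonnegative distances.
#' @param tau positive bandwidth.
#' @return weights in `[0, 1]`, zero at and beyond `tau`.
#' @export
bisquare_kernel <- function(d, tau) {
  stopifnot(all(tau > 0))
  ifelse(d < tau, (1 - (d / tau)^2)^2, 0)
}

#' Default candidate bandwidth grid
#'
#' Log-spaced candidates from the 5th percentile of nearest-neighbour
#' distances to the maximum pairwise distance, for cross-validated bandwidth
#' selection.
#'
#' @param d distance matrix.
#' @param length.out number of candidates (default 20).
#' @return increasing numeric vector of candidate bandwidths.
#' @export
default_bandwidth_grid <- function(d, length.out = 20L) {
  d <- as.matrix(d)
  n <- nrow(d)
  nn <- vapply(seq_len(n), function(i) min(d[i, -i]), numeric(1))
  lo <- stats::quantile(nn, 0.05, names = FALSE)
  hi <- max(d)
  if (lo <= 0) lo <- min(nn[nn > 0], hi / 100)
  exp(seq(log(lo), log(hi), length.out = length.out))
}
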