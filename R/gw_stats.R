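#' Geographically weighted summary statistics
#'
#' Weighted analogues of the mean, standard deviation, covariance and Pearson
#' correlation, evaluated with the kernel weight row of a focal location so
#' that their values vary over space. All use the population-style divisor
#' (the weight sum), matching the weighted-covariance definition
#' \deqn{\mathrm{cov}_i(y_1, y_2) =
#'   \frac{\sum_j w_{ij} (y_{1j} - \bar y_{1i})(y_{2j} - \bar y_{2i})}
#'        {\sum_j w_{ij}}.}
#' With uniform weights each statistic reduces to its global (n-divisor)
#' counterpart.
#'
#' @param y,y1,y2 numeric vectors of length n.
#' @param w nonnegative weight vector of length n with positive sum.
#' @return a scalar.
#' @name gw_statistics
NULL

check_weights <- function(y, w) {
  if (length(w) != length(y)) stop("weights must match data length", call. = FALSE)
  if (any(w < 0)) stop("weights must be nonnegative", call. = FALSE)
  sw <- sum(w)
  if (sw <= 0) stop("empty neighbourhood: all weights are zero", call. = FALSE)
  sw
}

#' @rdname gw_statistics
#' @export
gw_mean <- function(y, w) {
  sw <- check_weights(y, w)
  sum(y * w) / sw
}

#' @rdname gw_statistics
#' @export
gw_covariance <- function(y1, y2, w) {
  sw <- check_weights(y1, w)
  m1 <- sum(y1 * w) / sw
  m2 <- sum(y2 * w) / sw
  sum(w * (y1 - m1) * (y2 - m2)) / sw
}

#' @rdname gw_statistics
#' @export
gw_sd <- function(y, w) {
  sqrt(gw_covariance(y, y, w))
}

#' @rdname gw_statistics
#' @export
gw_correlation <- function(y1, y2, w) {
  s1 <- gw_sd(y1, w)
  s2 <- gw_sd(y2, w)
  if (s1 <= 0 || s2 <= 0) {
    stop("undefined local correlation: zero weighted standard deviation",
         call. = FALSE)
  }
  r <- gw_covariance(y1, y2, w) / (s1 * s2)
  # clip only Cauchy-Schwarz rounding overshoot
  if (abs(r) > 1 && abs(r) - 1 <= 1e-12) r <- sign(r)
  r
}

#' Local geographically weighted covariance matrix
#'
#' The p x p matrix of pairwise weighted covariances at a focal location:
#' columns are locally centred at their weighted means and the divisor is the
#' weight sum. Symmetric and positive semidefinite by construction.
#'
#' @param z n x p numeric matrix (typically globally standardized data).
#' @param w weight vector of length n (one kernel row).
#' @return p x p covariance matrix.
#' @export
gw_covariance_matrix <- function(z, w) {
  z <- if (inherits(z, "standardized_matrix")) z$z else as.matrix(z)
  sw <- check_weights(z[, 1L], w)
  m <- colSums(z * w) / sw
  zc <- sweep(z, 2L, m, "-")
  s <- crossprod(zc, zc * w) / sw
  (s + t(s)) / 2
}

#' Geographically weighted correlation field
#'
#' The local correlation between one pair of variables evaluated at every
#' sampling location, the quantity mapped to reveal spatially varying
#' relationships (e.g. between As and Cd in contaminated soils).
#'
#' @param table a [sample_table()].
#' @param pair character vector of two variable names.
#' @param weights a `kernel_weights` object conforming to the table.
#' @return a data frame with columns `location_id`, `x`, `y`, `r`, of class
#'   `gw_correlation_field`.
#' @export
gw_correlation_field <- function(table, pair, weights) {
  stopifnot(inherits(table, "sample_table"))
  w <- if (inherits(weights, "kernel_weights")) weights$w else as.matrix(weights)
  if (nrow(w) != table$n) stop("weights do not conform to the table", call. = FALSE)
  unknown <- setdiff(pair, table$variable_names)
  if (length(unknown)) {
    stop("unknown variable(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (length(pair) != 2L) stop("pair must name two variables", call. = FALSE)
  y1 <- table$values[, pair[1L]]
  y2 <- table$values[, pair[2L]]
  r <- vapply(seq_len(table$n), function(i) {
    if (pair[1L] == pair[2L]) 1 else gw_correlation(y1, y2, w[i, ])
  }, numeric(1))
  out <- data.frame(location_id = table$ids,
                    x = table$coords[, 1L], y = table$coords[, 2L], r = r,
                    row.names = NULL)
  attr(out, "pair") <- pair
  class(out) <- c("gw_correlation_field", "data.frame")
  out
}
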