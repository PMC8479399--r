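#' Geographically weighted principal component analysis
#'
#' Fits a GWPCA: at every sampling location a kernel-weighted covariance
#' matrix of the globally standardized data is eigendecomposed, yielding
#' location-specific eigenvalues, loadings, cumulative
#' proportion-of-total-variance (PTV) surfaces and winning-variable maps.
#' The bi-square kernel
#' \eqn{w_{ij} = (1 - (d_{ij}/\tau)^2)^2} for \eqn{d_{ij} < \tau} controls
#' the neighbourhood; the bandwidth \eqn{\tau} is either supplied or selected
#' by leave-one-out cross-validation over a candidate grid.
#'
#' Standardization is performed once, globally, before any weighting; the
#' number of retained components `k` is fixed across locations (default: the
#' number of global eigenvalues exceeding one). Local loading columns are
#' sign-aligned to the global PCA loadings so that maps are comparable across
#' locations; winning variables use absolute loadings and are unaffected by
#' the alignment.
#'
#' @param table a [sample_table()].
#' @param k number of retained components; `NULL` uses the global
#'   eigenvalue-greater-than-one count.
#' @param bandwidth fixed kernel bandwidth (distance units). `NULL` triggers
#'   leave-one-out cross-validated selection over `candidates`.
#' @param candidates candidate bandwidth grid for cross-validation; `NULL`
#'   uses [default_bandwidth_grid()] (20 log-spaced values).
#' @param adaptive logical; if `TRUE`, `bandwidth` is interpreted as a
#'   neighbour count N and per-location bandwidths are the distances to the
#'   N-th nearest neighbour.
#' @param metric distance metric, `"planar"` or `"great-circle"`.
#' @param cv_k number of components used inside the cross-validation score
#'   (default `k`); must be < p.
#'
#' @return object of class `gwpca`: list with elements
#'   \describe{
#'     \item{table, z}{the input table and its standardization}
#'     \item{k, bandwidth, adaptive, metric}{fit settings}
#'     \item{global}{the [eigen_pca()] of the standardized data}
#'     \item{eigenvalues}{n x p matrix of local eigenvalues (descending per row)}
#'     \item{loadings}{p x p x n array of sign-aligned local loadings}
#'     \item{ptv}{length-n cumulative first-k PTV surface}
#'     \item{winners}{n x k matrix of winning-variable labels}
#'     \item{cv}{the `gwpca_cv` object when the bandwidth was cross-validated}
#'   }
#' @seealso [gw_correlation_field()], [cv_bandwidth()], [local_scores()]
#' @export
gwpca <- function(table, k = NULL, bandwidth = NULL, candidates = NULL,
                  adaptive = FALSE, metric = c("planar", "great-circle"),
                  cv_k = NULL) {
  stopifnot(inherits(table, "sample_table"))
  metric <- match.arg(metric)
  if (table$coord_type == "degrees" && metric == "planar") {
    warning("coordinates are declared as lon/lat degrees but distances are ",
            "planar; consider metric = \"great-circle\"", call. = FALSE)
  }
  z <- standardize(table)
  global <- eigen_pca(stats::cor(table$values))
  p <- table$p
  if (is.null(k)) k <- max(1L, global$retained)
  k <- as.integer(k)
  if (k < 1L || k > p) stop("k must be between 1 and p", call. = FALSE)

  d <- pairwise_distances(table$coords, metric)
  cv <- NULL
  if (is.null(bandwidth)) {
    if (adaptive) {
      stop("cross-validated selection is implemented for fixed bandwidths; ",
           "supply an adaptive neighbour count explicitly", call. = FALSE)
    }
    if (is.null(candidates)) candidates <- default_bandwidth_grid(d)
    cv <- cv_bandwidth(z, table$coords, k = if (is.null(cv_k)) k else cv_k,
                       candidates = candidates, d = d)
    bandwidth <- cv$selected
  }
  bw <- if (adaptive) adaptive_bandwidths(d, bandwidth) else bandwidth
  weights <- bisquare_weights(d, bw)

  field <- local_eigenstructure(z, weights, k = k,
                                variable_names = table$variable_names)
  field <- align_signs(field, global)
  winners <- vapply(seq_len(k), function(comp) {
    winning_variables(field, comp)
  }, character(table$n))
  winners <- matrix(winners, nrow = table$n,
                    dimnames = list(table$ids, paste0("PC", seq_len(k))))

  structure(
    list(table = table, z = z, k = k,
         bandwidth = bw, adaptive = adaptive, metric = metric,
         global = global, weights = weights,
         eigenvalues = field$eigenvalues, loadings = field$loadings,
         ptv = field$ptv, winners = winners, cv = cv),
    class = "gwpca"
  )
}

#' Local eigenstructure of the weighted covariance field
#'
#' For each location i, builds the kernel-weighted covariance matrix of the
#' standardized data, eigendecomposes it (eigenvalues descending,
#' sign-convention loadings), and records the cumulative first-k PTV.
#'
#' @param z a `standardized_matrix` (or plain matrix).
#' @param weights `kernel_weights` (or plain n x n matrix).
#' @param k retained-component count, 1 <= k <= p.
#' @param variable_names optional variable labels.
#' @return object of class `local_eigen_field`: `eigenvalues` (n x p),
#'   `loadings` (p x p x n), `ptv` (length n), `k`, `variable_names`.
#' @export
local_eigenstructure <- function(z, weights, k, variable_names = NULL) {
  zm <- if (inherits(z, "standardized_matrix")) z$z else as.matrix(z)
  w <- if (inherits(weights, "kernel_weights")) weights$w else as.matrix(weights)
  n <- nrow(zm)
  p <- ncol(zm)
  k <- as.integer(k)
  if (k < 1L || k > p) stop("k must be between 1 and p", call. = FALSE)
  if (nrow(w) != n) stop("weights do not conform to the data", call. = FALSE)
  if (is.null(variable_names)) variable_names <- colnames(zm)
  if (is.null(variable_names)) variable_names <- paste0("V", seq_len(p))

  values <- matrix(NA_real_, n, p)
  loadings <- array(NA_real_, c(p, p, n))
  ptv <- numeric(n)
  deficient <- integer(0)
  for (i in seq_len(n)) {
    wi <- w[i, ]
    if (sum(wi) <= 0) {
      stop("empty neighbourhood at location ", i, call. = FALSE)
    }
    if (sum(wi > 0) < p) deficient <- c(deficient, i)
    sig <- gw_covariance_matrix(zm, wi)
    e <- eigen(sig, symmetric = TRUE)
    values[i, ] <- e$values
    loadings[, , i] <- fix_signs(e$vectors)
    ptv[i] <- sum(e$values[seq_len(k)]) / sum(e$values)
  }
  if (length(deficient)) {
    warning("rank-deficient local covariance (fewer positive-weight ",
            "neighbours than variables) at location(s): ",
            paste(utils::head(deficient, 10L), collapse = ", "),
            if (length(deficient) > 10L) ", ...", call. = FALSE)
  }
  structure(list(eigenvalues = values, loadings = loadings, ptv = ptv,
                 k = k, variable_names = variable_names),
            class = "local_eigen_field")
}

#' Align local loading signs to a global reference
#'
#' Each local loading column is flipped so that its projection on the
#' corresponding global loading column is nonnegative. Idempotent; winning
#' variables (which use absolute loadings) are unchanged.
#'
#' @param field a `local_eigen_field` (or `gwpca` fit).
#' @param reference a `global_pca` with the same p.
#' @return the field with aligned loadings.
#' @export
align_signs <- function(field, reference) {
  stopifnot(inherits(reference, "global_pca"))
  L <- field$loadings
  p <- dim(L)[1L]
  if (nrow(reference$loadings) != p) stop("dimension mismatch", call. = FALSE)
  for (i in seq_len(dim(L)[3L])) {
    proj <- colSums(L[, , i] * reference$loadings)
    flip <- proj < 0
    if (any(flip)) L[, flip, i] <- -L[, flip, i]
  }
  field$loadings <- L
  field
}

#' Winning variable per location for one component
#'
#' The variable with the largest absolute loading on the given local
#' component at each location; exact ties resolve to the lowest variable
#' index (a message reports how many locations tied).
#'
#' @param field a `local_eigen_field` or `gwpca` fit.
#' @param component component index (<= k for a fit).
#' @return character vector of variable labels, one per location.
#' @export
winning_variables <- function(field, component = 1L) {
  L <- field$loadings
  vn <- field$variable_names
  if (is.null(vn)) vn <- field$table$variable_names
  component <- as.integer(component)
  if (component < 1L || component > dim(L)[1L]) {
    stop("component out of range", call. = FALSE)
  }
  n <- dim(L)[3L]
  ties <- 0L
  winners <- character(n)
  for (i in seq_len(n)) {
    a <- abs(L[, component, i])
    top <- which(a == max(a))
    if (length(top) > 1L) ties <- ties + 1L
    winners[i] <- vn[top[1L]]
  }
  if (ties > 0L) {
    message("winning-variable ties at ", ties,
            " location(s); resolved to the lowest variable index")
  }
  winners
}

#' Cumulative PTV surface
#'
#' The per-location share of total local variance carried by the first `k`
#' local components — the quantity mapped to show where the retained
#' components summarise the data well.
#'
#' @param field a `local_eigen_field` or `gwpca` fit.
#' @param k number of leading components; defaults to the field's `k`.
#' @return numeric vector of shares in (0, 1], one per location.
#' @export
ptv_surface <- function(field, k = NULL) {
  if (is.null(k)) return(field$ptv)
  k <- as.integer(k)
  ev <- field$eigenvalues
  if (k < 1L || k > ncol(ev)) stop("k out of range", call. = FALSE)
  rowSums(ev[, seq_len(k), drop = FALSE]) / rowSums(ev)
}

#' Local component scores
#'
#' Projection of the full standardized data matrix onto the loadings of one
#' location: `T(i) = Z L(i)`. The weighted covariance of the score columns
#' under location i's kernel row equals the diagonal matrix of local
#' eigenvalues.
#'
#' @param z a `standardized_matrix` or plain matrix (the data the field was
#'   computed from), or a `gwpca` fit (then `field` is taken from it).
#' @param field a `local_eigen_field` (ignored when `z` is a fit).
#' @param i location index.
#' @return n x p matrix of local scores.
#' @export
local_scores <- function(z, field = NULL, i) {
  if (inherits(z, "gwpca")) {
    field <- z
    zm <- z$z$z
  } else {
    zm <- if (inherits(z, "standardized_matrix")) z$z else as.matrix(z)
  }
  n_loc <- dim(field$loadings)[3L]
  i <- as.integer(i)
  if (i < 1L || i > n_loc) stop("location index out of range", call. = FALSE)
  zm %*% field$loadings[, , i]
}

#' Leave-one-out cross-validated bandwidth selection
#'
#' For each candidate bandwidth, every location's observation is predicted
#' from the first `k` local components estimated with that observation's own
#' weight forced to zero; the score is the summed squared reconstruction
#' residual
#' \deqn{CV(\tau) = \sum_i \| z_i - m_i - L_k(i) L_k(i)^T (z_i - m_i) \|^2,}
#' with \eqn{m_i} the leave-one-out weighted mean vector. The selected
#' bandwidth minimises the score. Candidates that leave any location with an
#' empty neighbourhood score `+Inf` and are flagged.
#'
#' @param z a `standardized_matrix` or plain matrix.
#' @param coords n x 2 coordinates (ignored when `d` is supplied).
#' @param k components used in the reconstruction, 1 <= k < p.
#' @param candidates positive candidate bandwidths.
#' @param metric distance metric.
#' @param d optional precomputed distance matrix.
#' @return object of class `gwpca_cv`: data frame-ish list with `candidates`,
#'   `scores`, `selected`, `infeasible` (logical per candidate).
#' @export
cv_bandwidth <- function(z, coords, k, candidates,
                         metric = c("planar", "great-circle"), d = NULL) {
  zm <- if (inherits(z, "standardized_matrix")) z$z else as.matrix(z)
  n <- nrow(zm)
  p <- ncol(zm)
  k <- as.integer(k)
  if (k >= p) {
    stop("cross-validation requires k < p: with k = p the reconstruction ",
         "is exact and the score degenerates to zero", call. = FALSE)
  }
  if (k < 1L) stop("k must be at least 1", call. = FALSE)
  candidates <- sort(as.numeric(candidates))
  if (any(candidates <= 0)) stop("candidates must be positive", call. = FALSE)
  if (is.null(d)) d <- pairwise_distances(coords, match.arg(metric))

  scores <- numeric(length(candidates))
  for (ci in seq_along(candidates)) {
    tau <- candidates[ci]
    w <- bisquare_kernel(d, tau)
    diag(w) <- 0
    total <- 0
    for (i in seq_len(n)) {
      wi <- w[i, ]
      sw <- sum(wi)
      if (sw <= 0) { total <- Inf; break }
      m <- colSums(zm * wi) / sw
      zc <- sweep(zm, 2L, m, "-")
      sig <- crossprod(zc, zc * wi) / sw
      e <- eigen((sig + t(sig)) / 2, symmetric = TRUE)
      Lk <- e$vectors[, seq_len(k), drop = FALSE]
      resid <- (zm[i, ] - m) - Lk %*% crossprod(Lk, zm[i, ] - m)
      total <- total + sum(resid^2)
    }
    scores[ci] <- total
  }
  infeasible <- !is.finite(scores)
  if (all(infeasible)) {
    stop("every candidate bandwidth leaves some location with an empty ",
         "neighbourhood", call. = FALSE)
  }
  if (any(infeasible)) {
    warning(sum(infeasible), " candidate bandwidth(s) left empty ",
            "neighbourhoods and were scored +Inf", call. = FALSE)
  }
  best <- which.min(scores)
  structure(list(candidates = candidates, scores = scores,
                 selected = candidates[best], k = k,
                 infeasible = infeasible),
            class = "gwpca_cv")
}

#' @export
print.gwpca_cv <- function(x, ...) {
  cat("Leave-one-out bandwidth cross-validation\n")
  print(data.frame(bandwidth = signif(x$candidates, 5),
                   cv_score = signif(x$scores, 6)))
  cat("Selected bandwidth:", signif(x$selected, 6), "\n")
  invisible(x)
}

#' @export
print.gwpca <- function(x, digits = 3, ...) {
  cat(sprintf("Geographically weighted PCA: %d locations, %d variables, k = %d\n",
              x$table$n, x$table$p, x$k))
  bw <- unique(signif(x$bandwidth, 5))
  cat(sprintf("Bi-square kernel, %s bandwidth%s = %s (%s distances)\n",
              if (x$adaptive) "adaptive" else "fixed",
              if (length(bw) > 1L) "s" else "",
              if (length(bw) > 4L) paste0(paste(utils::head(bw, 3), collapse = ", "), ", ...")
              else paste(bw, collapse = ", "),
              x$metric))
  if (!is.null(x$cv)) {
    cat(sprintf("Bandwidth selected by leave-one-out CV over %d candidates\n",
                length(x$cv$candidates)))
  }
  cat(sprintf("Cumulative PTV of first %d local components: %.1f%% - %.1f%% (median %.1f%%)\n",
              x$k, 100 * min(x$ptv), 100 * max(x$ptv), 100 * stats::median(x$ptv)))
  cat("Winning variables (component 1):\n")
  print(table(x$winners[, 1L]))
  invisible(x)
}

#' @export
summary.gwpca <- function(object, ...) {
  print(object)
  cat("\nGlobal PCA of the standardized data:\n")
  print(object$global)
  cat("\nLocal eigenvalue ranges:\n")
  rng <- apply(object$eigenvalues, 2L, range)
  dimnames(rng) <- list(c("min", "max"),
                        paste0("PC", seq_len(ncol(rng))))
  print(round(rng, 3))
  invisible(object)
}

#' @export
coef.gwpca <- function(object, ...) object$loadings

#' @export
fitted.gwpca <- function(object, ...) {
  data.frame(location_id = object$table$ids,
             x = object$table$coords[, 1L],
             y = object$table$coords[, 2L],
             cumulative_ptv = object$ptv,
             winner_pc1 = object$winners[, 1L],
             row.names = NULL)
}

#' Map a fitted GWPCA surface
#'
#' Base-graphics point maps of the cumulative PTV surface or a component's
#' winning-variable surface. Visual aid only; all quantitative output is
#' available from the fit object.
#'
#' @param x a `gwpca` fit.
#' @param type `"ptv"` or `"winner"`.
#' @param component component index for winner maps.
#' @param ... passed to [graphics::plot()].
#' @export
plot.gwpca <- function(x, type = c("ptv", "winner"), component = 1L, ...) {
  type <- match.arg(type)
  xy <- x$table$coords
  if (type == "ptv") {
    pal <- grDevices::hcl.colors(100, "viridis")
    idx <- cut(x$ptv, breaks = seq(min(x$ptv), max(x$ptv), length.out = 101),
               include.lowest = TRUE, labels = FALSE)
    graphics::plot(xy, col = pal[idx], pch = 16,
                   main = sprintf("Cumulative PTV of first %d local components", x$k),
                   ...)
  } else {
    win <- factor(x$winners[, component], levels = x$table$variable_names)
    pal <- grDevices::hcl.colors(nlevels(win), "Dark 3")
    graphics::plot(xy, col = pal[as.integer(win)], pch = 16,
                   main = sprintf("Winning variable, component %d", component),
                   ...)
    graphics::legend("topright", legend = levels(win)[tabulate(win, nlevels(win)) > 0],
                     col = pal[tabulate(win, nlevels(win)) > 0], pch = 16, cex = 0.8)
  }
  invisible(x)
}
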