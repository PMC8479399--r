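#' Pearson correlation matrix of a sample table
#'
#' @param table a [sample_table()] or numeric matrix.
#' @return p x p correlation matrix with variable names as dimnames.
#' @export
correlation_matrix <- function(table) {
  y <- if (inherits(table, "sample_table")) table$values else as.matrix(table)
  sds <- apply(y, 2L, stats::sd)
  degenerate <- which(sds <= 0)
  if (length(degenerate)) {
    stop("degenerate (constant) variable(s): ",
         paste(colnames(y)[degenerate], collapse = ", "), call. = FALSE)
  }
  stats::cor(y)
}

# flip each eigenvector column so its largest-magnitude entry is positive
fix_signs <- function(vectors) {
  for (j in seq_len(ncol(vectors))) {
    v <- vectors[, j]
    top <- which.max(abs(v))
    if (v[top] < 0) vectors[, j] <- -v
  }
  vectors
}

#' Principal component analysis by eigendecomposition
#'
#' Eigendecomposition of a correlation (or covariance) matrix with
#' proportion-of-total-variance (PTV) accounting and the
#' eigenvalue-greater-than-one retention rule. Operating on the correlation
#' matrix is the standardized-data setting, in which every variable
#' contributes unit variance and the rule retains components that explain
#' more than one variable's worth of variance.
#'
#' Eigenvectors are sign-ambiguous; each loading column is flipped so its
#' largest-magnitude entry is positive, making results deterministic.
#'
#' @param r symmetric p x p correlation or covariance matrix (e.g. from
#'   [correlation_matrix()]), or a [sample_table()] (the correlation matrix of
#'   its variables is then used).
#' @param tol symmetry tolerance.
#' @return object of class `global_pca`: list with `eigenvalues` (descending),
#'   `loadings` (p x p, columns orthonormal), `ptv`, `cumulative_ptv`,
#'   `retained` (count of eigenvalues > 1) and `variable_names`.
#' @export
eigen_pca <- function(r, tol = 1e-8) {
  if (inherits(r, "sample_table")) r <- correlation_matrix(r)
  r <- as.matrix(r)
  if (nrow(r) != ncol(r) || max(abs(r - t(r))) > tol) {
    stop("input must be a symmetric square matrix", call. = FALSE)
  }
  vn <- colnames(r)
  if (is.null(vn)) vn <- paste0("V", seq_len(ncol(r)))
  e <- eigen((r + t(r)) / 2, symmetric = TRUE)
  values <- e$values
  loadings <- fix_signs(e$vectors)
  dimnames(loadings) <- list(vn, paste0("PC", seq_along(values)))
  total <- sum(values)
  ptv <- values / total
  structure(
    list(eigenvalues = values,
         loadings = loadings,
         ptv = ptv,
         cumulative_ptv = cumsum(ptv),
         retained = retain_count(values),
         variable_names = vn),
    class = "global_pca"
  )
}

#' Component retention by the eigenvalue-greater-than-one rule
#'
#' @param eigenvalues numeric vector sorted in decreasing order.
#' @return number of eigenvalues strictly greater than 1.
#' @export
retain_count <- function(eigenvalues) {
  if (is.unsorted(rev(eigenvalues))) {
    stop("eigenvalues must be sorted in decreasing order", call. = FALSE)
  }
  sum(eigenvalues > 1)
}

#' Cumulative proportion of total variance
#'
#' @param eigenvalues numeric vector (all components).
#' @param k number of leading components.
#' @return share of total variance carried by the first `k` components.
#' @export
cumulative_ptv <- function(eigenvalues, k) {
  k <- as.integer(k)
  if (k < 1L || k > length(eigenvalues)) {
    stop("k must be between 1 and the number of components", call. = FALSE)
  }
  sum(eigenvalues[seq_len(k)]) / sum(eigenvalues)
}

#' @export
print.global_pca <- function(x, digits = 3, ...) {
  p <- length(x$eigenvalues)
  cat(sprintf("Principal component analysis (%d components)\n", p))
  tab <- rbind(`Eigenvalues` = x$eigenvalues,
               `PTV` = x$ptv,
               `Cumulative PTV` = x$cumulative_ptv)
  colnames(tab) <- paste0("PC", seq_len(p))
  print(round(tab, digits))
  cat(sprintf("Retained (eigenvalue > 1): %d component(s)\n", x$retained))
  invisible(x)
}

#' @export
summary.global_pca <- function(object, ...) {
  print(object, ...)
  cat("\nLoadings:\n")
  print(round(object$loadings, 3))
  invisible(object)
}

#' @export
coef.global_pca <- function(object, ...) object$loadings

#' Correlation matrix of eight heavy metals from a Kumasi survey
#'
#' The published 8 x 8 Pearson correlation matrix of soil heavy-metal
#' concentrations (As, Cr, Cu, Fe, Mn, Ni, Zn, Cd) measured at 94 sampling
#' locations in Kumasi, Ghana. The raw concentrations are not publicly
#' available; this printed matrix is the worked-example input for the
#' conventional PCA stage.
#'
#' @return 8 x 8 named correlation matrix.
#' @export
kumasi_correlation <- function() {
  path <- system.file("extdata", "kumasi_correlation.csv", package = "gwpca",
                      mustWork = TRUE)
  m <- as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE))
  storage.mode(m) <- "double"
  m
}
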