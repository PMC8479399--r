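#' Construct a georeferenced sample table
#'
#' A `sample_table` is the single input object of the package: one row per
#' sampling location, planar or lon/lat coordinates, and `p >= 1` numeric
#' measurement variables (typically concentrations in mg/kg).
#'
#' @param ids character or integer vector of unique location identifiers.
#' @param coords numeric matrix or data frame with two columns (x, y or
#'   lon, lat).
#' @param values numeric matrix (n x p) of measurements; column names are the
#'   variable names.
#' @param coord_type `"planar"` for projected coordinates, `"degrees"` for
#'   lon/lat.
#'
#' @return An object of class `sample_table` with elements `ids`, `coords`,
#'   `values`, `coord_type`, `n` and `p`.
#' @export
sample_table <- function(ids, coords, values,
                         coord_type = c("planar", "degrees")) {
  coord_type <- match.arg(coord_type)
  coords <- as.matrix(coords)
  values <- as.matrix(values)
  storage.mode(coords) <- "double"
  storage.mode(values) <- "double"
  ids <- as.character(ids)

  n <- nrow(values)
  p <- ncol(values)
  if (n < 2L) stop("a sample table needs at least 2 locations", call. = FALSE)
  if (p < 1L) stop("a sample table needs at least 1 variable", call. = FALSE)
  if (length(ids) != n) stop("length(ids) must equal nrow(values)", call. = FALSE)
  if (anyDuplicated(ids)) {
    stop("duplicated location ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  if (nrow(coords) != n || ncol(coords) != 2L) {
    stop("coords must be an n x 2 matrix", call. = FALSE)
  }
  if (!all(is.finite(coords))) stop("coordinates must be finite", call. = FALSE)
  if (!all(is.finite(values))) stop("all values must be finite", call. = FALSE)
  vn <- colnames(values)
  if (is.null(vn)) vn <- paste0("V", seq_len(p))
  if (anyDuplicated(vn)) stop("variable names must be unique", call. = FALSE)
  colnames(values) <- vn
  colnames(coords) <- if (coord_type == "degrees") c("lon", "lat") else c("x", "y")
  rownames(values) <- rownames(coords) <- ids

  structure(
    list(ids = ids, coords = coords, values = values,
         coord_type = coord_type, n = n, p = p,
         variable_names = vn),
    class = "sample_table"
  )
}

#' @export
print.sample_table <- function(x, ...) {
  cat(sprintf("Sample table: %d locations x %d variables (%s coordinates)\n",
              x$n, x$p, x$coord_type))
  cat("Variables:", paste(x$variable_names, collapse = ", "), "\n")
  invisible(x)
}

#' Read a sample table from CSV
#'
#' Reads a header-rowed CSV, selects named coordinate and variable columns,
#' and drops rows with missing values in any selected column, reporting the
#' ids of dropped rows.
#'
#' @param path path to a CSV file (UTF-8, "." decimal point, header row).
#' @param coord_columns character vector of two column names holding the
#'   coordinates.
#' @param variable_columns character vector of measurement column names.
#' @param id_column optional name of the identifier column; when `NULL`,
#'   row numbers are used.
#' @param coord_type passed to [sample_table()].
#'
#' @return A `sample_table`. Rows dropped for missing values are reported via
#'   a message and recorded in the `dropped` attribute.
#' @export
read_samples <- function(path, coord_columns, variable_columns,
                         id_column = NULL,
                         coord_type = c("planar", "degrees")) {
  coord_type <- match.arg(coord_type)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                         fileEncoding = "UTF-8")
  needed <- c(id_column, coord_columns, variable_columns)
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (length(coord_columns) != 2L) {
    stop("coord_columns must name exactly two columns", call. = FALSE)
  }

  ids <- if (is.null(id_column)) as.character(seq_len(nrow(raw)))
         else raw[[id_column]]

  numeric_cols <- c(coord_columns, variable_columns)
  parsed <- matrix(NA_real_, nrow(raw), length(numeric_cols),
                   dimnames = list(NULL, numeric_cols))
  for (cn in numeric_cols) {
    cell <- trimws(raw[[cn]])
    blank <- !nzchar(cell)
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(!blank & is.na(num))
    if (length(bad)) {
      stop(sprintf("non-numeric value %s in column '%s', row %d (id %s)",
                   dQuote(cell[bad[1L]]), cn, bad[1L], ids[bad[1L]]),
           call. = FALSE)
    }
    parsed[, cn] <- num
  }

  keep <- stats::complete.cases(parsed)
  dropped <- ids[!keep]
  if (length(dropped)) {
    message("dropped ", length(dropped),
            " row(s) with missing values; ids: ",
            paste(dropped, collapse = ", "))
  }
  tab <- sample_table(
    ids = ids[keep],
    coords = parsed[keep, coord_columns, drop = FALSE],
    values = parsed[keep, variable_columns, drop = FALSE],
    coord_type = coord_type
  )
  attr(tab, "dropped") <- dropped
  tab
}

#' Standardize a sample table to z-scores
#'
#' Centres every variable by its mean and scales by its sample standard
#' deviation (n-1 denominator), so each column of the result has mean 0 and
#' standard deviation 1. The means and standard deviations are retained for
#' the inverse transform.
#'
#' @param table a [sample_table()], or a plain numeric matrix.
#'
#' @return An object of class `standardized_matrix`: list with `z` (n x p
#'   matrix), `means` and `sds` (length-p vectors).
#' @export
standardize <- function(table) {
  y <- if (inherits(table, "sample_table")) table$values else as.matrix(table)
  mu <- colMeans(y)
  sds <- apply(y, 2L, stats::sd)
  degenerate <- which(sds <= 0 | !is.finite(sds))
  if (length(degenerate)) {
    stop("degenerate (constant) variable(s): ",
         paste(colnames(y)[degenerate], collapse = ", "), call. = FALSE)
  }
  z <- sweep(sweep(y, 2L, mu, "-"), 2L, sds, "/")
  structure(list(z = z, means = mu, sds = sds),
            class = "standardized_matrix")
}

#' Invert a standardization
#'
#' @param zmat a `standardized_matrix` from [standardize()].
#' @return the matrix on the original scale.
#' @export
unstandardize <- function(zmat) {
  stopifnot(inherits(zmat, "standardized_matrix"))
  sweep(sweep(zmat$z, 2L, zmat$sds, "*"), 2L, zmat$means, "+")
}

# moment skewness g1 = m3 / m2^(3/2), population moments
moment_skewness <- function(y) {
  m <- mean(y)
  m2 <- mean((y - m)^2)
  if (m2 == 0) return(NaN)
  mean((y - m)^3) / m2^1.5
}

#' Descriptive statistics table
#'
#' Per-variable count, minimum, maximum, mean, lower quartile, median, upper
#' quartile, median absolute deviation and skewness, in that column order.
#' Quartiles use linear interpolation between order statistics
#' (`stats::quantile` type 7); the MAD is the raw median of absolute
#' deviations from the median (no consistency scaling); skewness is the
#' moment coefficient g1.
#'
#' @param table a [sample_table()] or numeric matrix.
#' @return a data frame with one row per variable and columns
#'   `variable, nb, minimum, maximum, mean, lq, median, uq, mad, skewness`.
#' @export
describe <- function(table) {
  y <- if (inherits(table, "sample_table")) table$values else as.matrix(table)
  if (nrow(y) < 2L) stop("describe needs at least 2 observations", call. = FALSE)
  one <- function(col) {
    q <- stats::quantile(col, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    c(nb = length(col),
      minimum = min(col), maximum = max(col), mean = mean(col),
      lq = q[1L], median = q[2L], uq = q[3L],
      mad = stats::median(abs(col - q[2L])),
      skewness = moment_skewness(col))
  }
  stats_mat <- t(apply(y, 2L, one))
  data.frame(variable = colnames(y), stats_mat, row.names = NULL)
}
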