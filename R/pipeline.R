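#' Run the full spatial-heterogeneity analysis pipeline
#'
#' Executes, in order: descriptive statistics, correlation matrix, global PCA
#' with eigenvalue-greater-than-one retention, bandwidth cross-validation
#' (when no bandwidth is given), the geographically weighted PCA, and GW
#' correlation fields for the most correlated variable pairs. Every product
#' is written as CSV (12+ significant digits) plus GeoJSON point exports for
#' the spatial surfaces, together with a run log.
#'
#' @param table a [sample_table()], or a path to a CSV (then `coord_columns`,
#'   `variable_columns`, `id_column` are used to read it).
#' @param output_dir directory for the artifacts (created if needed).
#' @param k retained components (`NULL`: eigenvalue > 1 rule).
#' @param bandwidth fixed bandwidth; `NULL` selects by cross-validation.
#' @param candidates candidate grid for cross-validation.
#' @param metric distance metric.
#' @param n_pairs number of top-correlated variable pairs mapped with GW
#'   correlation (default 3).
#' @param coord_columns,variable_columns,id_column CSV reading options.
#' @param seed integer seed recorded in the log (the pipeline itself is
#'   deterministic given its input).
#' @param verbose print one line per stage.
#' @return (invisibly) a list with the fitted objects and the paths written.
#' @export
run_pipeline <- function(table, output_dir,
                         k = NULL, bandwidth = NULL, candidates = NULL,
                         metric = c("planar", "great-circle"),
                         n_pairs = 3L,
                         coord_columns = c("x", "y"),
                         variable_columns = NULL, id_column = NULL,
                         seed = 1L, verbose = TRUE) {
  metric <- match.arg(metric)
  t0 <- Sys.time()
  say <- function(stage, ...) {
    if (verbose) message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"),
                                 stage, paste0(...)))
  }
  if (is.character(table)) {
    say("read", "reading ", table)
    table <- read_samples(table, coord_columns, variable_columns,
                          id_column = id_column,
                          coord_type = if (metric == "great-circle") "degrees"
                                       else "planar")
  }
  stopifnot(inherits(table, "sample_table"))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  wr <- function(df, name) {
    path <- file.path(output_dir, name)
    utils::write.csv(format(df, digits = 15, scientific = FALSE, trim = TRUE),
                     path, row.names = FALSE, quote = FALSE)
    paths[[name]] <<- path
    path
  }

  say("describe", "descriptive statistics for ", table$p, " variables")
  desc <- describe(table)
  wr(desc, "descriptive_statistics.csv")

  say("correlation", "global correlation matrix")
  corr <- correlation_matrix(table)
  corr_df <- data.frame(variable = rownames(corr), corr, check.names = FALSE)
  wr(corr_df, "correlation_matrix.csv")

  say("pca", "global PCA")
  global <- eigen_pca(corr)
  pca_df <- data.frame(
    quantity = c("eigenvalue", "ptv", "cumulative_ptv"),
    rbind(global$eigenvalues, global$ptv, global$cumulative_ptv),
    check.names = FALSE)
  colnames(pca_df)[-1L] <- paste0("PC", seq_len(table$p))
  wr(pca_df, "global_pca.csv")
  load_df <- data.frame(variable = rownames(global$loadings),
                        global$loadings, check.names = FALSE)
  wr(load_df, "global_loadings.csv")

  say("gwpca", if (is.null(bandwidth)) "bandwidth by leave-one-out CV"
               else paste("fixed bandwidth", bandwidth))
  fit <- gwpca(table, k = k, bandwidth = bandwidth,
               candidates = candidates, metric = metric)
  if (!is.null(fit$cv)) {
    wr(data.frame(bandwidth = fit$cv$candidates, cv_score = fit$cv$scores),
       "cv_trace.csv")
  }

  local_df <- data.frame(
    location_id = table$ids,
    x = table$coords[, 1L], y = table$coords[, 2L],
    fit$eigenvalues,
    cumulative_ptv = fit$ptv,
    fit$winners, check.names = FALSE)
  colnames(local_df)[3L + seq_len(table$p)] <- paste0("lambda", seq_len(table$p))
  colnames(local_df)[ncol(local_df) - fit$k + seq_len(fit$k)] <-
    paste0("winner_pc", seq_len(fit$k))
  wr(local_df, "gwpca_local.csv")

  n <- table$n
  p <- table$p
  long <- data.frame(
    location_id = rep(table$ids, each = p * p),
    component = rep(rep(paste0("PC", seq_len(p)), each = p), times = n),
    variable = rep(table$variable_names, times = n * p),
    loading = as.vector(fit$loadings))
  wr(long, "gwpca_loadings_long.csv")

  say("gwcorr", "GW correlation for top ", n_pairs, " pairs")
  pairs <- top_correlated_pairs(corr, n_pairs)
  gwcorr <- list()
  for (j in seq_len(nrow(pairs))) {
    pr <- c(pairs$var1[j], pairs$var2[j])
    fld <- gw_correlation_field(table, pr, fit$weights)
    nm <- sprintf("gw_correlation_%s_%s.csv", pr[1L], pr[2L])
    wr(fld, nm)
    export_geojson(fld, file.path(output_dir,
                                  sprintf("gw_correlation_%s_%s.geojson",
                                          pr[1L], pr[2L])),
                   kind = "gwcorr")
    gwcorr[[paste(pr, collapse = "_")]] <- fld
  }

  ptv_df <- fitted(fit)
  export_geojson(ptv_df[c("location_id", "x", "y", "cumulative_ptv")],
                 file.path(output_dir, "ptv_surface.geojson"), kind = "ptv")
  export_geojson(ptv_df[c("location_id", "x", "y", "winner_pc1")],
                 file.path(output_dir, "winning_variables.geojson"),
                 kind = "winner")

  log_lines <- c(
    sprintf("gwpca pipeline run %s", format(t0, "%Y-%m-%d %H:%M:%S")),
    sprintf("R version: %s", R.version.string),
    sprintf("seed: %d", seed),
    sprintf("n: %d  p: %d  metric: %s", table$n, table$p, metric),
    sprintf("k: %d", fit$k),
    sprintf("bandwidth: %s", paste(signif(unique(fit$bandwidth), 8), collapse = ", ")),
    sprintf("bandwidth_source: %s", if (is.null(fit$cv)) "fixed" else "loocv"),
    sprintf("elapsed_s: %.2f", as.numeric(difftime(Sys.time(), t0, units = "secs")))
  )
  writeLines(log_lines, file.path(output_dir, "run_log.txt"))

  say("done", "artifacts in ", output_dir)
  invisible(list(table = table, describe = desc, correlation = corr,
                 global = global, fit = fit, gwcorr = gwcorr,
                 pairs = pairs, paths = paths))
}

#' Most correlated variable pairs
#'
#' @param corr correlation matrix.
#' @param n_pairs number of pairs.
#' @return data frame `var1, var2, r` sorted by decreasing `|r|`.
#' @export
top_correlated_pairs <- function(corr, n_pairs = 3L) {
  vn <- rownames(corr)
  idx <- which(upper.tri(corr), arr.ind = TRUE)
  out <- data.frame(var1 = vn[idx[, 1L]], var2 = vn[idx[, 2L]],
                    r = corr[idx])
  out <- out[order(-abs(out$r)), , drop = FALSE]
  utils::head(out, n_pairs)
}

#' Export a spatial surface as GeoJSON points
#'
#' Writes a GeoJSON FeatureCollection of point features whose properties hold
#' the surface value (`value` for numeric surfaces, `label` for categorical
#' winning-variable surfaces) plus `location_id` and `kind`.
#'
#' @param surface data frame with columns `location_id`, `x`, `y` and one
#'   value column (any further columns are ignored).
#' @param path output file path.
#' @param kind `"ptv"`, `"winner"` or `"gwcorr"`.
#' @return the path, invisibly.
#' @export
export_geojson <- function(surface, path, kind = c("ptv", "winner", "gwcorr")) {
  kind <- match.arg(kind)
  stopifnot(nrow(surface) > 0L,
            all(c("location_id", "x", "y") %in% names(surface)))
  value_col <- setdiff(names(surface), c("location_id", "x", "y"))[1L]
  if (is.na(value_col)) stop("surface has no value column", call. = FALSE)
  categorical <- kind == "winner"
  features <- lapply(seq_len(nrow(surface)), function(i) {
    props <- list(location_id = surface$location_id[i], kind = kind)
    if (categorical) props$label <- as.character(surface[[value_col]][i])
    else props$value <- surface[[value_col]][i]
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(surface$x[i], surface$y[i])),
         properties = props)
  })
  gj <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
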