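#' Read a time-series table
#'
#' Reads a TSV/CSV table whose first column is time and whose remaining
#' columns are species. In relative mode, rows whose sum deviates from 1 by
#' less than 0.05 are renormalized with a warning; larger deviations are an
#' error. In absolute mode strict positivity is enforced. Non-uniform grids
#' are accepted (field time series routinely skip sampling days).
#'
#' @param path Path to a delimited text file with a header row.
#' @param mode `"relative"` or `"absolute"`.
#' @return A [composition_series()] or [abundance_series()].
#' @export
read_timeseries <- function(path, mode = c("relative", "absolute")) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("read_timeseries: file not found: ", path)
  df <- as.data.frame(data.table::fread(path, header = TRUE))
  if (ncol(df) < 3L) stop("read_timeseries: need a time column plus >= 2 species")
  if (anyDuplicated(names(df)[-1])) {
    stop("read_timeseries: duplicate species names")
  }
  if (!all(vapply(df, is.numeric, logical(1)))) {
    stop("read_timeseries: non-numeric cells")
  }
  times <- df[[1]]
  if (any(diff(times) <= 0)) stop("read_timeseries: times must be strictly increasing")
  M <- as.matrix(df[, -1, drop = FALSE])
  labels <- names(df)[-1]
  if (mode == "absolute") {
    return(abundance_series(times, M, labels = labels))
  }
  dev <- abs(rowSums(M) - 1)
  if (any(dev >= 0.05)) {
    stop("read_timeseries: row sums deviate from 1 by >= 0.05 (max ",
         signif(max(dev), 3), "); not a composition table")
  }
  if (any(dev > 1e-8)) {
    warning("read_timeseries: renormalizing rows deviating from unit sum ",
            "(max deviation ", signif(max(dev), 3), ")")
    M <- M / rowSums(M)
  }
  composition_series(times, M, labels = labels)
}

#' Write a time-series table
#'
#' Writes the TSV counterpart of [read_timeseries()]: a `time` column
#' followed by one column per species.
#'
#' @param series A [composition_series()] or [abundance_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(series, path) {
  M <- if (inherits(series, "composition_series")) series$X else series$N
  df <- data.frame(time = series$times, M, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize a gLV parameter set to JSON
#'
#' @param params A [glv_params()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_glv_params <- function(params, path) {
  stopifnot(inherits(params, "glv_params"))
  jsonlite::write_json(
    list(r = params$r, B = params$B,
         self_interactions = params$self_interactions,
         labels = params$labels),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a gLV parameter set from JSON
#'
#' @param path Path written by [write_glv_params()].
#' @return A [glv_params()] object.
#' @export
read_glv_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  glv_params(x$r, x$B,
             self_interactions = isTRUE(x$self_interactions),
             labels = x$labels)
}

#' Serialize a fitted iLV model to JSON
#'
#' Records the estimate together with its provenance: winning backend,
#' winning restart, best iteration of the iterative subroutine, and the
#' trajectory RMSE.
#'
#' @param fit An `ilv_fit` from [fit_ilv()] or [ilv_subroutine2()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_result <- function(fit, path) {
  stopifnot(inherits(fit, "ilv_fit"))
  jsonlite::write_json(
    list(method = "ilv", r = fit$params$r, B = fit$params$B,
         x0 = fit$x0, Nsum0 = fit$Nsum0, rmse = fit$rmse,
         backend = fit$backend, restart = fit$restart,
         best_iteration = fit$best_iteration,
         rmse_path = fit$rmse_path),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a benchmark/run configuration file
#'
#' YAML (`.yml`/`.yaml`) or JSON, with fields such as `scenarios`,
#' `methods`, `Nsum_initial_guess`, `restarts`, `seed`.
#'
#' @param path Config file path.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("read_run_config: file not found: ", path)
  if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write an interaction network as an edge-list TSV
#'
#' @param network An [extract_network()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path) {
  stopifnot(inherits(network, "interaction_network"))
  utils::write.table(as.data.frame(network), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
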