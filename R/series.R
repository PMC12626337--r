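#' Relative-abundance (compositional) time series
#'
#' A matrix of relative abundances observed on a strictly increasing time
#' grid. Each row lies on the unit simplex: entries in `[0, 1]` summing to 1
#' (tolerance 1e-8 after ingest normalization).
#'
#' @param times Strictly increasing numeric vector of sampling times.
#' @param X Numeric matrix, one row per time point, one column per species.
#' @param labels Optional character vector of species names; defaults to the
#'   column names of `X` or `sp1, sp2, ...`.
#' @return An object of class `composition_series`.
#' @export
composition_series <- function(times, X, labels = NULL) {
  times <- as.numeric(times)
  X <- as.matrix(X)
  if (length(times) != nrow(X)) {
    stop("composition_series: length(times) must equal nrow(X)")
  }
  if (length(times) < 2L) stop("composition_series: at least 2 time points required")
  if (ncol(X) < 2L) stop("composition_series: at least 2 species required")
  if (any(diff(times) <= 0)) stop("composition_series: times must be strictly increasing")
  if (any(!is.finite(X))) stop("composition_series: non-finite abundances")
  if (any(X < 0) || any(X > 1)) {
    stop("composition_series: relative abundances must lie in [0, 1]")
  }
  dev <- max(abs(rowSums(X) - 1))
  if (dev > 1e-8) {
    stop("composition_series: rows must sum to 1 (max deviation ",
         signif(dev, 3), "); normalize on ingest first")
  }
  if (is.null(labels)) {
    labels <- colnames(X)
    if (is.null(labels)) labels <- paste0("sp", seq_len(ncol(X)))
  }
  colnames(X) <- labels
  structure(list(times = times, X = X, labels = labels),
            class = "composition_series")
}

#' Absolute-abundance time series
#'
#' Strictly positive abundances on a strictly increasing time grid.
#'
#' @inheritParams composition_series
#' @param N Numeric matrix of absolute abundances, one row per time point.
#' @return An object of class `abundance_series`.
#' @export
abundance_series <- function(times, N, labels = NULL) {
  times <- as.numeric(times)
  N <- as.matrix(N)
  if (length(times) != nrow(N)) {
    stop("abundance_series: length(times) must equal nrow(N)")
  }
  if (any(diff(times) <= 0)) stop("abundance_series: times must be strictly increasing")
  if (any(!is.finite(N)) || any(N <= 0)) {
    stop("abundance_series: abundances must be finite and strictly positive")
  }
  if (is.null(labels)) {
    labels <- colnames(N)
    if (is.null(labels)) labels <- paste0("sp", seq_len(ncol(N)))
  }
  colnames(N) <- labels
  structure(list(times = times, N = N, labels = labels),
            class = "abundance_series")
}

#' Convert absolute abundances to a compositional series
#'
#' Divides each row by its total, discarding the (often unobservable)
#' absolute scale.
#'
#' @param series An `abundance_series`.
#' @return A `composition_series` on the same time grid.
#' @export
as_composition <- function(series) {
  stopifnot(inherits(series, "abundance_series"))
  X <- series$N / rowSums(series$N)
  composition_series(series$times, X, labels = series$labels)
}

#' @export
print.composition_series <- function(x, ...) {
  cat("composition_series:", length(x$times), "time points x",
      ncol(x$X), "species (", paste(x$labels, collapse = ", "), ")\n")
  invisible(x)
}

#' @export
print.abundance_series <- function(x, ...) {
  cat("abundance_series:", length(x$times), "time points x",
      ncol(x$N), "species (", paste(x$labels, collapse = ", "), ")\n")
  invisible(x)
}
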