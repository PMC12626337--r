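#' Per-interval logarithmic gradient
#'
#' Finite-difference approximation of d(ln v)/dt on a (possibly non-uniform)
#' grid: `(ln v(t_{k+1}) - ln v(t_k)) / (t_{k+1} - t_k)`. For gLV dynamics
#' this quantity is linear in the abundances of the co-occurring species,
#' which is what turns parameter estimation into per-species regression.
#'
#' @param values Strictly positive numeric vector (clip compositions at a
#'   small floor before calling).
#' @param times Strictly increasing grid of the same length.
#' @return Numeric vector of length `length(values) - 1`.
#' @examples
#' log_gradient(100 * exp(0.3 * 0:5), 0:5)  # all 0.3
#' @export
log_gradient <- function(values, times) {
  values <- as.numeric(values)
  times <- as.numeric(times)
  if (length(values) != length(times) || length(values) < 2L) {
    stop("log_gradient: 'values' and 'times' must have equal length >= 2")
  }
  bad <- which(values <= 0)
  if (length(bad)) {
    stop("log_gradient: non-positive value at index ", bad[1])
  }
  if (any(diff(times) <= 0)) stop("log_gradient: times must be strictly increasing")
  diff(log(values)) / diff(times)
}

# Least-squares solve with a minimum-norm fallback for rank-deficient
# designs (pseudoinverse via SVD, with a warning).
.ls_solve <- function(A, y) {
  fit <- stats::lm.fit(A, y)
  if (fit$rank < ncol(A)) {
    warning("rank-deficient regression design; returning minimum-norm solution")
    sv <- svd(A)
    pos <- sv$d > max(dim(A)) * .Machine$double.eps * sv$d[1]
    return(as.vector(sv$v[, pos, drop = FALSE] %*%
                       ((t(sv$u[, pos, drop = FALSE]) %*% y) / sv$d[pos])))
  }
  unname(fit$coefficients)
}

# Gradient-matching regression shared by the absolute and relative
# baselines and by the iterative subroutine. N is an (n+1) x m positive
# matrix; regressors are evaluated at the interval's left endpoint by
# default (midpoint averaging available via `timing`).
.glv_gradient_fit <- function(N, times, include_self, timing = "left") {
  m <- ncol(N)
  n <- nrow(N) - 1L
  if (n < m + 1L) {
    warning("fewer intervals (", n, ") than regressors + intercept; ",
            "expect a rank-deficient design")
  }
  Npos <- pmax(N, .X_FLOOR)
  Y <- apply(log(Npos), 2, diff) / diff(times)
  if (n == 1L) Y <- matrix(Y, nrow = 1L)
  Z <- switch(timing,
              left = N[seq_len(n), , drop = FALSE],
              midpoint = (N[seq_len(n), , drop = FALSE] +
                            N[1L + seq_len(n), , drop = FALSE]) / 2,
              stop("unknown regressor timing '", timing, "'"))
  r <- numeric(m)
  B <- matrix(0, m, m)
  for (i in seq_len(m)) {
    cols <- if (include_self) seq_len(m) else setdiff(seq_len(m), i)
    co <- .ls_solve(cbind(1, Z[, cols, drop = FALSE]), Y[, i])
    r[i] <- co[1]
    B[i, cols] <- co[-1]
  }
  glv_params(r, B, self_interactions = include_self,
             labels = colnames(N))
}

#' Gradient-matching gLV fit on absolute abundances
#'
#' For each species i, ordinary least squares of the log-gradient of N_i on
#' the left-endpoint abundances of the regress-on species, with intercept:
#' the intercept estimates r_i and the slopes estimate b_ij. This is the
#' classical absolute-data baseline ("gLV_absolute").
#'
#' @param series An [abundance_series()].
#' @param include_self Include the species' own abundance as a regressor
#'   (frees the diagonal b_ii). Default `FALSE`, matching the benchmark runs
#'   on systems without self-regulation; set `TRUE` when the generating
#'   system carries self-interactions.
#' @param timing Where the regressors are evaluated within each interval:
#'   `"left"` (default) or `"midpoint"`.
#' @return A [glv_params()] estimate.
#' @export
fit_glv_absolute <- function(series, include_self = FALSE, timing = "left") {
  stopifnot(inherits(series, "abundance_series"))
  .glv_gradient_fit(series$N, series$times, include_self, timing)
}

#' Gradient-matching gLV fit applied directly to relative abundances
#'
#' The same regression as [fit_glv_absolute()] but with compositions as
#' regressors ("gLV_relative"). Self-interaction columns are always excluded
#' and the diagonal pinned to 0: under the simplex constraint
#' `sum_j x_j = 1`, only `r_i + b_i1` and `b_ij - b_i1` are identifiable, so
#' a free diagonal has infinitely many solutions.
#'
#' @param series A [composition_series()].
#' @inheritParams fit_glv_absolute
#' @return A [glv_params()] estimate with zero diagonal.
#' @export
fit_glv_relative <- function(series, timing = "left") {
  stopifnot(inherits(series, "composition_series"))
  .glv_gradient_fit(series$X, series$times, include_self = FALSE,
                    timing = timing)
}

#' Compositional log-ratio (cLV-style) surrogate fit
#'
#' Chooses the reference species D with the lowest sample variance of
#' relative abundance (ties broken by lowest index), then for each species
#' i != D regresses the log-gradient of the ratio x_i / x_D on the
#' left-endpoint compositions of all species j != D, with intercept. The
#' intercept estimates a contrast involving r_i - r_D and the slopes
#' estimate scaled contrasts of b_ij - b_Dj; only the contrast directions
#' are meaningful, and the fit is scored through contrast cosines (see
#' [cosine_clv()]), never through absolute coefficients.
#'
#' @param series A [composition_series()].
#' @inheritParams fit_glv_absolute
#' @return An object of class `clv_fit`: list with `D` (reference index),
#'   `r_diff` (intercepts, one per i != D), `B_diff` (matrix of slope
#'   contrasts, rows i != D, columns j != D), and `labels`.
#' @export
fit_clv <- function(series, timing = "left") {
  stopifnot(inherits(series, "composition_series"))
  X <- series$X
  m <- ncol(X)
  n <- nrow(X) - 1L
  v <- apply(X, 2, stats::var)
  D <- unname(which.min(v))  # which.min takes the lowest index on ties
  others <- setdiff(seq_len(m), D)
  Xpos <- pmax(X, .X_FLOOR)
  Z <- switch(timing,
              left = X[seq_len(n), others, drop = FALSE],
              midpoint = (X[seq_len(n), others, drop = FALSE] +
                            X[1L + seq_len(n), others, drop = FALSE]) / 2)
  r_diff <- numeric(length(others))
  B_diff <- matrix(0, length(others), length(others),
                   dimnames = list(series$labels[others], series$labels[others]))
  for (k in seq_along(others)) {
    i <- others[k]
    y <- log_gradient(Xpos[, i] / Xpos[, D], series$times)
    co <- .ls_solve(cbind(1, Z), y)
    r_diff[k] <- co[1]
    B_diff[k, ] <- co[-1]
  }
  names(r_diff) <- series$labels[others]
  structure(list(D = D, r_diff = r_diff, B_diff = B_diff,
                 labels = series$labels),
            class = "clv_fit")
}

#' @export
print.clv_fit <- function(x, ...) {
  cat("clv_fit: reference species D =", x$labels[x$D], "\n")
  cat("r contrasts:", signif(x$r_diff, 4), "\n")
  invisible(x)
}

#' Correlation screen between species compositions
#'
#' Pearson or Spearman correlation of each pair of relative-abundance
#' series, used as a naive stand-in for the interaction coefficients b_ij.
#' The diagonal is set to 0 so the matrix can be scored through the same
#' off-diagonal cosine as the model-based estimators.
#'
#' @param series A [composition_series()] with at least 3 time points.
#' @param method `"pearson"` or `"spearman"`.
#' @return Symmetric `m x m` matrix with zero diagonal.
#' @export
correlation_baseline <- function(series, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(inherits(series, "composition_series"))
  if (length(series$times) < 3L) {
    stop("correlation_baseline: at least 3 time points required")
  }
  sds <- apply(series$X, 2, stats::sd)
  C <- suppressWarnings(stats::cor(series$X, method = method))
  if (any(sds == 0)) {
    warning("correlation_baseline: zero-variance series; correlation set to 0")
    C[!is.finite(C)] <- 0
  }
  diag(C) <- 0
  C
}
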