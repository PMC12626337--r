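#' Trajectory root-mean-square error of a fitted gLV model
#'
#' Simulates the compositional system under `params` from `(x0, Nsum0)` at
#' exactly the observed times and returns
#' `sqrt( sum_k sum_j (x_j(t_k) - xhat_j(t_k))^2 / ((n+1) m) )`,
#' the root mean square over all `(n+1) x m` entries including the initial
#' time point (the k = 0 residual is generally nonzero once x(0) has been
#' optimized). Invalid trajectories score `+Inf` by contract.
#'
#' @param observed A [composition_series()].
#' @param params A [glv_params()] candidate.
#' @param x0 Initial composition used for simulation.
#' @param Nsum0 Initial total abundance (scale gauge).
#' @param indices Optional subset of time-point indices over which to average
#'   (used by train/validation splitting); simulation always runs over the
#'   full observed grid from t = 0.
#' @param rtol,atol Solver tolerances.
#' @return Nonnegative scalar (possibly `Inf`).
#' @export
trajectory_rmse <- function(observed, params, x0, Nsum0, indices = NULL,
                            rtol = 1e-8, atol = 1e-8) {
  stopifnot(inherits(observed, "composition_series"))
  tr <- simulate_relative(params, x0, Nsum0, observed$times,
                          rtol = rtol, atol = atol)
  rmse_to_observed(observed, tr, indices = indices)
}

#' RMSE between an observed series and an already-simulated trajectory
#'
#' The workhorse behind [trajectory_rmse()], exposed for scoring a
#' trajectory that has already been simulated (or constructed by hand).
#' `trajectory` needs fields `X` and `valid`; an invalid trajectory scores
#' `+Inf`.
#'
#' @inheritParams trajectory_rmse
#' @param trajectory A `glv_trajectory` (or any list with `X` and `valid`).
#' @return Nonnegative scalar (possibly `Inf`).
#' @export
rmse_to_observed <- function(observed, trajectory, indices = NULL) {
  if (!isTRUE(trajectory$valid)) return(Inf)
  if (is.null(indices)) indices <- seq_along(observed$times)
  sqrt(mean((observed$X[indices, , drop = FALSE] -
               trajectory$X[indices, , drop = FALSE])^2))
}

#' Cosine similarity of off-diagonal interaction coefficients
#'
#' Concatenates the off-diagonal entries of each matrix (row-major, diagonal
#' never enters) and returns the cosine of the angle between the two
#' vectors. Because compositional data identify the b_ij only up to a
#' positive multiplicative constant, this scale-invariant direction metric
#' is the natural recovery score.
#'
#' @param B_hat,B_true Matrices of identical shape, `m >= 2`.
#' @return Scalar in `[-1, 1]`; `NaN` with a warning if either off-diagonal
#'   vector is all zero.
#' @export
cosine_offdiag <- function(B_hat, B_true) {
  B_hat <- as.matrix(B_hat)
  B_true <- as.matrix(B_true)
  if (!all(dim(B_hat) == dim(B_true)) || nrow(B_hat) < 2L) {
    stop("cosine_offdiag: matrices must have identical shape with m >= 2")
  }
  off <- row(B_hat) != col(B_hat)
  # row-major concatenation: transpose before masking
  a <- t(B_hat)[t(off)]
  b <- t(B_true)[t(off)]
  .cosine(a, b)
}

.cosine <- function(a, b) {
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    warning("cosine similarity undefined for a zero vector; returning NaN")
    return(NaN)
  }
  sum(a * b) / (na * nb)
}

#' Contrast cosine similarity for a compositional log-ratio fit
#'
#' A [fit_clv()] surrogate only identifies the contrasts b_ij - b_Dj against
#' its reference species D. This builds the true contrast vector over the
#' same index set the estimate covers (i != D, j != D, i != j, using the
#' estimate's D) and returns the plain cosine.
#'
#' @param clv A `clv_fit` object.
#' @param B_true True interaction matrix.
#' @param r_true Optional true growth rates (unused by the cosine; accepted
#'   for interface symmetry with the other scorers).
#' @return Scalar in `[-1, 1]`.
#' @export
cosine_clv <- function(clv, B_true, r_true = NULL) {
  stopifnot(inherits(clv, "clv_fit"))
  B_true <- as.matrix(B_true)
  m <- nrow(B_true)
  others <- setdiff(seq_len(m), clv$D)
  if (length(others) != nrow(clv$B_diff)) {
    stop("cosine_clv: index sets of estimate and truth do not match")
  }
  est <- c()
  tru <- c()
  for (k in seq_along(others)) {
    i <- others[k]
    for (l in seq_along(others)) {
      j <- others[l]
      if (i == j) next
      est <- c(est, clv$B_diff[k, l])
      tru <- c(tru, B_true[i, j] - B_true[clv$D, j])
    }
  }
  .cosine(est, tru)
}

#' Extract a directed interaction network from fitted coefficients
#'
#' Retains the off-diagonal interactions whose magnitude is at least
#' `threshold_factor` times the smallest nonzero off-diagonal magnitude
#' (exact zeros are never edges and do not set the threshold), labelling
#' positive coefficients as promotion and negative ones as inhibition. The
#' rule is invariant to the compositional scale gauge since it only compares
#' magnitudes within the same fit.
#'
#' @param params A [glv_params()] fit.
#' @param threshold_factor Retention threshold as a multiple of the minimum
#'   off-diagonal magnitude (default 50).
#' @return An object of class `interaction_network`: data frame with columns
#'   `source` (species j), `target` (species i), `weight` (|b_ij|), `sign`
#'   (`"promotion"`/`"inhibition"`), plus a `threshold_factor` attribute.
#' @export
extract_network <- function(params, threshold_factor = 50) {
  stopifnot(inherits(params, "glv_params"))
  B <- params$B
  m <- nrow(B)
  if (m < 2L) stop("extract_network: at least 2 species required")
  labels <- params$labels %||% paste0("sp", seq_len(m))
  off <- abs(B[row(B) != col(B)])
  edges <- data.frame(source = character(), target = character(),
                      weight = numeric(), sign = character(),
                      stringsAsFactors = FALSE)
  if (all(off == 0)) {
    warning("extract_network: all off-diagonal interactions are zero")
  } else {
    thr <- threshold_factor * min(off[off > 0])
    for (i in seq_len(m)) {
      for (j in seq_len(m)) {
        if (i == j || B[i, j] == 0 || abs(B[i, j]) < thr) next
        edges <- rbind(edges, data.frame(
          source = labels[j], target = labels[i],
          weight = abs(B[i, j]),
          sign = if (B[i, j] > 0) "promotion" else "inhibition",
          stringsAsFactors = FALSE))
      }
    }
  }
  structure(edges, threshold_factor = threshold_factor,
            class = c("interaction_network", "data.frame"))
}
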