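#' @importFrom deSolve ode
NULL

# State ceiling beyond which a trajectory is declared blown up. gLV systems
# with mis-specified parameters can diverge in finite time; candidate scoring
# must survive such draws, so blow-ups are flagged, never thrown.
.NSUM_MAX <- 1e8
# Floor applied to compositions before any logarithm.
.X_FLOOR <- 1e-6

#' Right-hand side of the compositional gLV system
#'
#' The gLV equations dN_i/dt = N_i (r_i + sum_j b_ij N_j) can be rewritten in
#' terms of the relative abundances x_i = N_i / N_sum and the latent total
#' N_sum = sum_i N_i:
#'
#'   dN_sum/dt = sum_i ( r_i x_i N_sum + sum_j b_ij x_i x_j N_sum^2 )
#'   dx_i/dt   = ( r_i x_i N_sum + sum_j b_ij x_i x_j N_sum^2
#'                 - x_i dN_sum/dt ) / N_sum
#'
#' The x-derivatives sum to zero analytically, so the simplex constraint is
#' preserved by the flow.
#'
#' @param x Composition vector (entries >= 0, summing to 1 within 1e-6).
#' @param Nsum Positive scalar total abundance.
#' @param params A [glv_params()] object.
#' @return A list with components `dx` (vector) and `dNsum` (scalar).
#' @examples
#' p <- glv_params(c(0.3), matrix(0, 1, 1))
#' glv_relative_rhs(1, 100, p)  # dNsum = 30, dx = 0
#' @export
glv_relative_rhs <- function(x, Nsum, params) {
  stopifnot(inherits(params, "glv_params"))
  if (!all(is.finite(x)) || !is.finite(Nsum)) {
    stop("glv_relative_rhs: non-finite state")
  }
  if (any(x < -1e-12) || abs(sum(x) - 1) > 1e-6) {
    stop("glv_relative_rhs: 'x' must be on the unit simplex")
  }
  if (Nsum <= 0) stop("glv_relative_rhs: 'Nsum' must be positive")
  Bx <- as.vector(params$B %*% x)
  dNsum <- Nsum * sum(params$r * x) + Nsum^2 * sum(x * Bx)
  dx <- x * (params$r + Nsum * Bx - dNsum / Nsum)
  list(dx = dx, dNsum = dNsum)
}

# deSolve-facing RHS. Freezes the derivative once the state has blown up so
# the adaptive solver terminates quickly instead of underflowing its step
# size; validity is judged afterwards in .solve_ode().
.rhs_relative <- function(t, y, p) {
  m <- length(p$r)
  x <- y[seq_len(m)]
  Ns <- y[m + 1L]
  if (!all(is.finite(y)) || abs(Ns) > .NSUM_MAX) return(list(rep(0, m + 1L)))
  Bx <- as.vector(p$B %*% x)
  dNs <- Ns * sum(p$r * x) + Ns^2 * sum(x * Bx)
  list(c(x * (p$r + Ns * Bx - dNs / Ns), dNs))
}

.rhs_absolute <- function(t, y, p) {
  if (!all(is.finite(y)) || any(abs(y) > .NSUM_MAX)) return(list(rep(0, length(y))))
  list(y * (p$r + as.vector(p$B %*% y)))
}

# Largest system the compiled right-hand side supports (matches MAXM in
# src/glv.c); larger systems fall back to the R closures above.
.MAXM_COMPILED <- 25L

# Zero-padded parameter block for the compiled rhs: (m, r, B row-major).
.pack_parms <- function(params) {
  m <- length(params$r)
  pv <- numeric(1L + .MAXM_COMPILED + .MAXM_COMPILED^2)
  pv[1L] <- m
  pv[1L + seq_len(m)] <- params$r
  pv[1L + .MAXM_COMPILED + seq_len(m * m)] <- as.vector(t(params$B))
  pv
}

# Shared solver wrapper: returns the deSolve matrix, or NULL on hard failure.
# Uses the compiled rhs when the system fits; DLSODA diagnostics are routed
# through R's stdout, so capture them to keep candidate scoring loops quiet.
.solve_ode <- function(y0, times, which_rhs, params, rtol, atol) {
  m <- length(params$r)
  out <- NULL
  utils::capture.output(
    out <- try(suppressWarnings(
      if (m <= .MAXM_COMPILED) {
        deSolve::ode(y = y0, times = times,
                     func = if (which_rhs == "relative") "glv_rel_derivs"
                            else "glv_abs_derivs",
                     parms = .pack_parms(params), dllname = "ilv",
                     initfunc = "glv_initmod",
                     method = "lsoda", rtol = rtol, atol = atol,
                     maxsteps = 5000)
      } else {
        deSolve::ode(y = y0, times = times,
                     func = if (which_rhs == "relative") .rhs_relative
                            else .rhs_absolute,
                     parms = params,
                     method = "lsoda", rtol = rtol, atol = atol,
                     maxsteps = 5000)
      }
    ), silent = TRUE),
    type = "output")
  if (inherits(out, "try-error") || nrow(out) < length(times)) return(NULL)
  out
}

#' Simulate the compositional gLV system
#'
#' Integrates the relative-coordinate system (see [glv_relative_rhs()]) with
#' an adaptive LSODA solver and reports the state at the requested grid.
#' Reported composition rows are renormalized to the simplex; the raw solver
#' drift is available in the `drift` field. Integration failure or blow-up
#' (|N_sum| reaching 1e8, or a non-finite/non-positive state) yields a
#' trajectory with `valid = FALSE` rather than an error, so that scoring
#' loops over poor parameter candidates can continue.
#'
#' @param params A [glv_params()] object.
#' @param x0 Initial composition (on the simplex within 1e-6).
#' @param Nsum0 Positive initial total abundance.
#' @param times Strictly increasing time grid starting at the initial time.
#' @param rtol,atol Solver tolerances.
#' @return An object of class `glv_trajectory`: list with `times`, `X`
#'   (renormalized compositions), `Nsum`, `valid`, and `drift` (max absolute
#'   pre-normalization deviation of row sums from 1).
#' @export
simulate_relative <- function(params, x0, Nsum0, times, rtol = 1e-8, atol = 1e-8) {
  stopifnot(inherits(params, "glv_params"))
  x0 <- as.numeric(x0)
  if (!all(is.finite(x0)) || any(x0 < -1e-12) || abs(sum(x0) - 1) > 1e-6) {
    stop("simulate_relative: 'x0' must be on the unit simplex")
  }
  if (!is.finite(Nsum0) || Nsum0 <= 0) stop("simulate_relative: 'Nsum0' must be positive")
  if (any(diff(times) <= 0)) stop("simulate_relative: times must be strictly increasing")
  m <- length(x0)
  out <- .solve_ode(c(x0, Nsum0), times, "relative", params, rtol, atol)
  if (is.null(out)) {
    return(structure(list(times = times,
                          X = matrix(NA_real_, length(times), m),
                          Nsum = rep(NA_real_, length(times)),
                          valid = FALSE, drift = NA_real_),
                     class = "glv_trajectory"))
  }
  Xraw <- out[, 1L + seq_len(m), drop = FALSE]
  Nsum <- out[, m + 2L]
  valid <- all(is.finite(Xraw)) && all(is.finite(Nsum)) &&
    all(Nsum > 0) && max(abs(Nsum)) < .NSUM_MAX
  drift <- if (all(is.finite(Xraw))) max(abs(rowSums(Xraw) - 1)) else NA_real_
  X <- if (valid) Xraw / rowSums(Xraw) else Xraw
  colnames(X) <- params$labels %||% paste0("sp", seq_len(m))
  structure(list(times = times, X = X, Nsum = Nsum, valid = valid,
                 drift = drift),
            class = "glv_trajectory")
}

#' Simulate the gLV system in absolute coordinates
#'
#' Integrates dN_i/dt = N_i (r_i + sum_j b_ij N_j). Serves as the
#' cross-check oracle for [simulate_relative()] (the two descriptions are
#' equivalent under x_i = N_i / N_sum) and as the data source for the
#' absolute-abundance baseline estimator.
#'
#' @inheritParams simulate_relative
#' @param N0 Strictly positive initial abundance vector.
#' @return A list of class `glv_trajectory_absolute` with `times`, `N`, and
#'   `valid`.
#' @export
simulate_absolute <- function(params, N0, times, rtol = 1e-8, atol = 1e-8) {
  stopifnot(inherits(params, "glv_params"))
  N0 <- as.numeric(N0)
  if (!all(is.finite(N0)) || any(N0 <= 0)) {
    stop("simulate_absolute: 'N0' must be strictly positive")
  }
  if (any(diff(times) <= 0)) stop("simulate_absolute: times must be strictly increasing")
  m <- length(N0)
  out <- .solve_ode(N0, times, "absolute", params, rtol, atol)
  if (is.null(out)) {
    return(structure(list(times = times,
                          N = matrix(NA_real_, length(times), m),
                          valid = FALSE),
                     class = "glv_trajectory_absolute"))
  }
  N <- out[, -1L, drop = FALSE]
  valid <- all(is.finite(N)) && all(N > 0) && max(abs(N)) < .NSUM_MAX
  colnames(N) <- params$labels %||% paste0("sp", seq_len(m))
  structure(list(times = times, N = N, valid = valid),
            class = "glv_trajectory_absolute")
}

#' @export
print.glv_trajectory <- function(x, ...) {
  cat("glv_trajectory:", length(x$times), "time points x", ncol(x$X),
      "species; valid:", x$valid, "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
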