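# Shared fixtures: built in code, no files on disk.

periodic_params <- function() make_scenario("periodic")$params

stabilizing_params <- function() make_scenario("stabilizing")$params

# random stable-ish parameter draw used by property loops
random_params <- function(m = 3, r_max = 1, b_max = 0.02) {
  r <- stats::runif(m, -r_max, r_max)
  B <- matrix(stats::runif(m * m, -b_max, b_max), m, m)
  diag(B) <- 0
  glv_params(r, B, self_interactions = FALSE)
}

random_simplex <- function(m = 3) {
  x <- stats::runif(m, 0.05, 1)
  x / sum(x)
}

# noise-free compositional dataset for a preset scenario
clean_dataset <- function(name = "periodic", dt = 1, t_range = NULL) {
  generate_dataset(make_scenario(name, dt = dt, t_range = t_range))
}

# fixed-step RK4 integrator, the independent oracle for the adaptive solver
rk4_absolute <- function(params, N0, t_end, h) {
  f <- function(N) N * (params$r + as.vector(params$B %*% N))
  steps <- round(t_end / h)
  N <- N0
  out <- matrix(NA_real_, steps + 1, length(N0))
  out[1, ] <- N
  for (s in seq_len(steps)) {
    k1 <- f(N); k2 <- f(N + h / 2 * k1)
    k3 <- f(N + h / 2 * k2); k4 <- f(N + h * k3)
    N <- N + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    out[s + 1, ] <- N
  }
  out
}

# explicit pseudoinverse regression oracle (independent of the package path)
pinv_regression <- function(N, times, i, include_self) {
  m <- ncol(N)
  y <- diff(log(pmax(N[, i], 1e-6))) / diff(times)
  cols <- if (include_self) seq_len(m) else setdiff(seq_len(m), i)
  A <- cbind(1, N[-nrow(N), cols, drop = FALSE])
  as.vector(pracma::pinv(A) %*% y)
}
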