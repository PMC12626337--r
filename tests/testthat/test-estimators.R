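test_that("log gradient linearizes exponentials exactly", {
  expect_equal(log_gradient(rep(5, 6), 0:5), rep(0, 5))
  tt <- c(0, 0.5, 1.2, 3, 4.7)
  expect_equal(log_gradient(100 * exp(0.3 * tt), tt), rep(0.3, 4))
  expect_equal(log_gradient(c(100, 200), c(0, 2)), log(2) / 2)
  expect_error(log_gradient(c(1, 0, 2), 0:2), "index 2")
  expect_error(log_gradient(c(1, 2), c(1, 1)), "strictly increasing")
})

test_that("gradient-matching regression equals an explicit pseudoinverse oracle", {
  withr::with_seed(5, {
    for (case in 1:20) {
      m <- sample(2:3, 1)
      npts <- sample(4:5, 1)
      N <- matrix(stats::runif(npts * m, 10, 200), npts, m)
      times <- cumsum(stats::runif(npts, 0.2, 1))
      include_self <- sample(c(TRUE, FALSE), 1)
      fit <- suppressWarnings(
        fit_glv_absolute(abundance_series(times, N),
                         include_self = include_self))
      for (i in seq_len(m)) {
        co <- pinv_regression(N, times, i, include_self)
        expect_equal(fit$r[i], co[1], tolerance = 1e-8, ignore_attr = TRUE)
        cols <- if (include_self) seq_len(m) else setdiff(seq_len(m), i)
        expect_equal(fit$B[i, cols], co[-1], tolerance = 1e-8,
                     ignore_attr = TRUE)
      }
    }
  })
})

test_that("absolute fit recovers independent exponentials in its exact model class", {
  p <- glv_params(c(0.3, -0.1, 0.2), matrix(0, 3, 3))
  times <- seq(0, 2, 0.05)
  ab <- simulate_absolute(p, c(50, 80, 30), times)
  fit <- fit_glv_absolute(abundance_series(times, ab$N))
  expect_lt(max(abs(fit$r - p$r)), 1e-3)
  expect_lt(max(abs(fit$B)), 1e-3)
})

test_that("relative fit is the absolute code path applied to compositions, diagonal pinned", {
  d <- clean_dataset("periodic")
  rel <- fit_glv_relative(d$series)
  as_abun <- suppressWarnings(
    fit_glv_absolute(abundance_series(d$series$times, d$series$X),
                     include_self = FALSE))
  expect_equal(rel$r, as_abun$r)
  expect_equal(rel$B, as_abun$B)
  expect_equal(diag(rel$B), rep(0, 3), ignore_attr = TRUE)
  expect_false(rel$self_interactions)
})

test_that("degenerate designs fall back to a minimum-norm solution", {
  X <- matrix(rep(c(0.5, 0.5), each = 6), 6, 2)
  w <- capture_warnings(fit <- fit_glv_relative(composition_series(0:5, X)))
  expect_true(any(grepl("rank-deficient", w)))
  expect_equal(fit$r, c(0, 0), ignore_attr = TRUE)
  expect_equal(fit$B, matrix(0, 2, 2), ignore_attr = TRUE)
})

test_that("log-ratio surrogate picks the lowest-variance reference species", {
  tt <- 0:6
  x1 <- 0.3 + 0.1 * sin(tt)
  x3 <- rep(0.2, 7)
  X <- cbind(x1, 0.8 - x1, x3)
  X <- X / rowSums(X)
  fit <- suppressWarnings(fit_clv(composition_series(tt, X)))
  expect_equal(fit$D, 3L)
  expect_equal(dim(fit$B_diff), c(2, 2))
})

test_that("log-ratio surrogate recovers contrast directions on model data", {
  d <- clean_dataset("periodic", dt = 0.1)
  fit <- fit_clv(d$series)
  expect_gt(cosine_clv(fit, d$truth$B), 0.9)
})

test_that("correlation screens behave as correlations, not interactions", {
  tt <- 0:9
  x1 <- seq(0.1, 0.3, length.out = 10)
  X <- cbind(x1, 2 * x1, 1 - 3 * x1)
  X <- X / rowSums(X)
  s <- composition_series(tt, X)
  P <- correlation_baseline(s, "pearson")
  expect_equal(P[1, 2], 1, tolerance = 1e-8)
  expect_equal(diag(P), rep(0, 3), ignore_attr = TRUE)
  expect_equal(P, t(P))
  Sx <- correlation_baseline(s, "spearman")
  expect_equal(Sx[1, 3], -1, tolerance = 1e-8)

  Xz <- cbind(rep(0.5, 4), c(0.2, 0.3, 0.25, 0.25), c(0.3, 0.2, 0.25, 0.25))
  Xz <- Xz / rowSums(Xz)
  expect_warning(Cz <- correlation_baseline(composition_series(0:3, Xz)),
                 "zero-variance")
  expect_equal(Cz[1, 2], 0)
  expect_error(correlation_baseline(composition_series(0:1, X[1:2, ])),
               "3 time points")
})

test_that("absolute-data estimator sharpens as sampling becomes denser", {
  truth <- periodic_params()
  cosines <- vapply(c(1, 0.5, 0.1), function(dt) {
    times <- seq(0, 10, dt)
    ab <- simulate_absolute(truth, c(0.3, 0.5, 0.2) * 100, times)
    cosine_offdiag(fit_glv_absolute(abundance_series(times, ab$N))$B,
                   truth$B)
  }, numeric(1))
  expect_true(all(diff(cosines) > 0))
  expect_gt(cosines[3], 0.99)
})
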