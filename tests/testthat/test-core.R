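test_that("relative rhs matches trivial fields and conserves the simplex", {
  m <- 3
  p0 <- glv_params(rep(0, m), matrix(0, m, m))
  rhs <- glv_relative_rhs(c(0.2, 0.3, 0.5), 50, p0)
  expect_equal(rhs$dx, rep(0, m))
  expect_equal(rhs$dNsum, 0)

  # single species: composition is pinned at 1, total grows at rate r
  p1 <- glv_params(0.3, matrix(0, 1, 1))
  rhs1 <- glv_relative_rhs(1, 100, p1)
  expect_equal(rhs1$dx, 0)
  expect_equal(rhs1$dNsum, 30)

  # analytic identity: composition derivatives sum to zero
  rhs2 <- glv_relative_rhs(c(0.3, 0.5, 0.2), 100, periodic_params())
  expect_lt(abs(sum(rhs2$dx)), 1e-12)

  expect_error(glv_relative_rhs(c(NA, 0.5, 0.5), 100, p0), "non-finite")
  expect_error(glv_relative_rhs(c(0.2, 0.3, 0.5), -1, p0), "positive")
  expect_error(glv_relative_rhs(c(0.9, 0.3, 0.5), 100, p0), "simplex")
})

test_that("composition derivatives sum to zero across random states", {
  withr::with_seed(42, {
    for (i in 1:200) {
      p <- random_params(m = sample(2:5, 1), r_max = 1, b_max = 0.05)
      x <- random_simplex(length(p$r))
      Ns <- stats::runif(1, 1, 1000)
      expect_lt(abs(sum(glv_relative_rhs(x, Ns, p)$dx)), 1e-10)
    }
  })
})

test_that("zero parameters give constant trajectories", {
  p <- glv_params(rep(0, 3), matrix(0, 3, 3))
  times <- seq(0, 10, 1)
  tr <- simulate_relative(p, c(0.3, 0.5, 0.2), 100, times)
  expect_true(tr$valid)
  expect_equal(tr$X, matrix(rep(c(0.3, 0.5, 0.2), each = 11), 11, 3),
               ignore_attr = TRUE, tolerance = 1e-8)
  expect_equal(tr$Nsum, rep(100, 11), tolerance = 1e-8)
})

test_that("interaction-free absolute dynamics reduce to exact exponentials", {
  p <- glv_params(c(0.4, -0.2), matrix(0, 2, 2))
  times <- seq(0, 5, 0.5)
  ab <- simulate_absolute(p, c(10, 20), times)
  expect_true(ab$valid)
  expect_equal(ab$N[, 1], 10 * exp(0.4 * times), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(ab$N[, 2], 20 * exp(-0.2 * times), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("adaptive solver agrees with a fixed-step RK4 oracle on a predator-prey cycle", {
  p <- glv_params(c(0.5, -0.5),
                  matrix(c(0, -0.01, 0.01, 0), 2, 2, byrow = TRUE))
  h <- 1e-3
  oracle <- rk4_absolute(p, c(60, 30), t_end = 4, h = h)
  times <- seq(0, 4, 1)
  ab <- simulate_absolute(p, c(60, 30), times)
  idx <- round(times / h) + 1
  expect_true(ab$valid)
  expect_equal(ab$N, oracle[idx, ], tolerance = 1e-5, ignore_attr = TRUE)
})

test_that("relative and absolute descriptions of the same flow agree", {
  times <- seq(0, 10, 1)
  p <- periodic_params()
  x0 <- c(0.3, 0.5, 0.2)
  tr <- simulate_relative(p, x0, 100, times)
  ab <- simulate_absolute(p, x0 * 100, times)
  expect_true(tr$valid && ab$valid)
  expect_lt(max(abs(tr$X - ab$N / rowSums(ab$N))), 1e-6)
  expect_lt(max(abs(tr$Nsum - rowSums(ab$N))), 1e-4)
  expect_true(all(tr$Nsum > 0))
})

test_that("blow-up marks a trajectory invalid instead of raising", {
  p <- glv_params(c(2, 2), matrix(c(0.5, 0.5, 0.5, 0.5), 2, 2))
  tr <- simulate_relative(p, c(0.5, 0.5), 1000, seq(0, 50, 1))
  expect_false(tr$valid)
  ab <- simulate_absolute(p, c(1000, 1000), seq(0, 50, 1))
  expect_false(ab$valid)

  expect_error(simulate_relative(periodic_params(), c(0.9, 0.5, 0.2), 100,
                                 0:5), "simplex")
  expect_error(simulate_relative(periodic_params(), c(0.3, 0.5, 0.2), -5,
                                 0:5), "positive")
  expect_error(simulate_absolute(periodic_params(), c(-1, 2, 3), 0:5),
               "positive")
})

test_that("container constructors enforce their invariants", {
  expect_error(composition_series(c(0, 1, 1), matrix(0.5, 3, 2)),
               "strictly increasing")
  expect_error(composition_series(0, matrix(c(0.6, 0.4), 1, 2)), "2 time")
  expect_error(composition_series(0:1, matrix(c(0.7, 0.7, 0.4, 0.4), 2, 2)),
               "sum to 1")
  expect_error(abundance_series(0:1, matrix(c(1, -1, 2, 3), 2, 2)),
               "positive")
  expect_error(glv_params(c(0.1, Inf), matrix(0, 2, 2)), "finite")
  expect_error(glv_params(c(0.1, 0.2), matrix(1, 2, 2),
                          self_interactions = FALSE), "diagonal")
  s <- abundance_series(0:2, matrix(c(1, 2, 3, 4, 5, 6), 3, 2))
  xc <- as_composition(s)
  expect_equal(rowSums(xc$X), rep(1, 3), ignore_attr = TRUE)
})
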