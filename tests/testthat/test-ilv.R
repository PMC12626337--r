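test_that("configuration validates its fields", {
  expect_error(ilv_config(-1), "positive")
  expect_error(ilv_config(100, M = 0), "M")
  expect_error(ilv_config(100, restarts = 0), "restarts")
  expect_error(ilv_config(100, backends = "newton"), "arg")
  cfg <- ilv_config(200)
  expect_equal(cfg$M, 100L)
  expect_equal(cfg$restarts, 20L)
  expect_setequal(cfg$backends, c("lm-a", "lm-b", "trf"))
})

test_that("a single-iteration refinement returns the plain linear start", {
  d <- clean_dataset("periodic")
  s1 <- ilv_subroutine1(d$series, ilv_config(200, M = 1))
  # step 1 regresses on compositions scaled by the guess: growth rates match
  # the relative fit, interactions are its slopes divided by the guess
  rel <- fit_glv_relative(d$series)
  expect_equal(s1$params$r, rel$r)
  expect_equal(s1$params$B, rel$B / 200)
  expect_equal(s1$best_iteration, 1L)
  expect_length(s1$rmse_path, 1L)
  expect_identical(s1$params, s1$params_step1)
})

test_that("the guess acts as a pure scale gauge on the linear start", {
  d <- clean_dataset("periodic")
  base <- ilv_subroutine1(d$series, ilv_config(200, M = 1))$params
  for (c_fac in c(0.1, 10)) {
    scaled <- ilv_subroutine1(d$series,
                              ilv_config(200 * c_fac, M = 1))$params
    expect_equal(scaled$r, base$r)  # exactly: response is guess-free
    expect_equal(scaled$B, base$B / c_fac)
  }
})

test_that("refinement loop never returns a worse iterate than its start", {
  for (name in c("periodic", "stabilizing", "periodic_long")) {
    d <- clean_dataset(name)
    s1 <- ilv_subroutine1(d$series, ilv_config(200, M = 25))
    expect_lte(s1$rmse, s1$rmse_path[1])
    expect_equal(s1$rmse, min(s1$rmse_path))
    expect_equal(s1$rmse, s1$rmse_path[s1$best_iteration])
  }
})

test_that("iterative refinement substantially improves the oscillatory long-window start", {
  d <- clean_dataset("periodic_long")
  s1 <- ilv_subroutine1(d$series, ilv_config(200, M = 100))
  expect_gt(s1$best_iteration, 1L)
  expect_lt(s1$rmse, s1$rmse_path[1] - 0.01)
})

test_that("nonlinear stage keeps a perfect start untouched and never regresses", {
  d <- clean_dataset("periodic")
  cfg <- ilv_config(100, maxiter = 50)
  perfect <- ilv_subroutine2(d$series, d$truth, c(0.3, 0.5, 0.2), 100,
                             backends = "lm-a", config = cfg)
  expect_equal(perfect$rmse, 0)
  expect_equal(perfect$backend, "start")
  expect_equal(perfect$params$B, d$truth$B, ignore_attr = TRUE)

  s1 <- ilv_subroutine1(d$series, ilv_config(200, M = 1))
  start_rmse <- trajectory_rmse(d$series, s1$params, c(0.3, 0.5, 0.2), 200)
  fit <- ilv_subroutine2(d$series, s1$params, Nsum0 = 200,
                         backends = c("lm-a", "trf"),
                         config = ilv_config(200, maxiter = 30))
  expect_lte(fit$rmse, start_rmse)
  expect_equal(unname(fit$backend_rmse["start"]), start_rmse)
  expect_equal(diag(fit$params$B), rep(0, 3), ignore_attr = TRUE)

  expect_error(ilv_subroutine2(d$series, glv_params(rep(0, 3),
                                                    diag(0.1, 3)),
                               Nsum0 = 100), "zero diagonal")
})

test_that("full fit recovers the oscillatory interaction structure from compositions", {
  d <- clean_dataset("periodic")
  fit <- fit_ilv(d$series, ilv_config(200, restarts = 2, seed = 1))
  expect_gt(cosine_offdiag(fit$params$B, d$truth$B), 0.999)
  expect_lt(max(abs(fit$params$r - d$truth$r)), 1e-3)
  expect_lt(fit$rmse, 1e-6)
  expect_lte(fit$rmse, fit$rmse_start)
  expect_true(fit$backend %in% c("start", "lm-a", "lm-b", "trf"))
})

test_that("restart jitter is reproducible and cannot beat a converged first restart", {
  d <- clean_dataset("periodic")
  f1 <- fit_ilv(d$series, ilv_config(200, restarts = 1, seed = 4))
  f3 <- fit_ilv(d$series, ilv_config(200, restarts = 3, seed = 4))
  expect_lte(f3$rmse, f1$rmse)
  expect_lt(f1$rmse, 1e-8)
  # a converged first restart can only be "beaten" at machine-precision
  # level; the recovered parameters coincide
  expect_equal(f3$params$r, f1$params$r, tolerance = 1e-6)
  expect_equal(f3$params$B, f1$params$B, tolerance = 1e-4)
  f3b <- fit_ilv(d$series, ilv_config(200, restarts = 3, seed = 4))
  expect_identical(f3$params, f3b$params)
  expect_identical(f3$rmse, f3b$rmse)
})

test_that("stability report is seed-deterministic with ordered summaries", {
  d <- clean_dataset("periodic")
  cfg <- ilv_config(200, restarts = 1, M = 10,
                    backends = c("lm-a", "trf"), maxiter = 20)
  rep1 <- optimizer_stability_report(d$series, cfg, runs = 2,
                                     seeds = c(5L, 5L))
  raw <- attr(rep1, "runs")
  expect_equal(raw[1, ], raw[2, ])  # equal seeds, identical runs
  expect_true(all(rep1$min <= rep1$median & rep1$median <= rep1$max))
  expect_error(optimizer_stability_report(d$series, cfg, runs = 1), ">= 2")
})

test_that("stage ablation reproduces the ordering that motivates the two-stage design", {
  d <- clean_dataset("periodic_long")
  ab <- ilv_ablation(d$series, ilv_config(200, restarts = 1, maxiter = 60))
  expect_lte(ab$full, ab$subroutine1_only)
  expect_lte(ab$full, min(ab$subroutine2_only))
  expect_lte(min(ab$subroutine2_only), ab$subroutine2_only[["start"]])
})
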