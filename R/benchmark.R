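#' Run the simulation benchmark grid
#'
#' For every scenario (a design point: parameter setting, sampling interval,
#' time range, noise level) generates the replicate datasets, fits every
#' requested method, and scores the recovery of the interaction
#' coefficients by cosine similarity: the plain off-diagonal cosine for all
#' methods except the compositional log-ratio surrogate, which is scored
#' through its identifiable contrasts ([cosine_clv()]). The absolute-data
#' baseline consumes abundances reconstructed as noisy compositions times
#' the clean simulated total-abundance path, and frees its diagonal exactly
#' when the generating system carries self-interactions. Fully seeded and
#' reproducible.
#'
#' @param scenarios List of [make_scenario()] objects.
#' @param methods Subset of `c("ilv", "clv", "glv_relative", "pearson",
#'   "spearman", "glv_absolute")`.
#' @param Nsum_initial_guess Guess handed to the iLV fits (default 200).
#' @param restarts,M iLV configuration for each fit.
#' @param seed Base seed for the iLV restart jitter.
#' @param noise_mode Passed to [generate_dataset()].
#' @return Data frame with one row per (scenario, method):
#'   `scenario`, `dt`, `t_range`, `noise_level`, `method`, `mean_cosine`,
#'   `sd_cosine` (`NA` for noise-free single-run cells), `n_replicates`.
#' @export
run_benchmark <- function(scenarios,
                          methods = c("ilv", "clv", "glv_relative",
                                      "pearson", "spearman", "glv_absolute"),
                          Nsum_initial_guess = 200, restarts = 20L, M = 100L,
                          seed = 1L, noise_mode = "multiplicative") {
  methods <- match.arg(methods, several.ok = TRUE)
  if (inherits(scenarios, "glv_scenario")) scenarios <- list(scenarios)
  rows <- list()
  scores_list <- list()
  for (si in seq_along(scenarios)) {
    sc <- scenarios[[si]]
    n_rep <- if (sc$noise_level > 0) sc$n_replicates else 1L
    scores <- matrix(NA_real_, n_rep, length(methods),
                     dimnames = list(NULL, methods))
    for (rep_i in seq_len(n_rep)) {
      d <- generate_dataset(sc, rep_i, noise_mode = noise_mode)
      for (mth in methods) {
        scores[rep_i, mth] <- tryCatch(
          .benchmark_score(mth, d, Nsum_initial_guess, restarts, M,
                           .derive_seed(seed, si * 10000L + rep_i)),
          error = function(e) {
            message("benchmark: ", mth, " failed on ", sc$name,
                    " replicate ", rep_i, ": ", conditionMessage(e))
            NA_real_
          })
      }
    }
    for (mth in methods) {
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = sc$name, dt = sc$dt, t_range = sc$t_range,
        noise_level = sc$noise_level, method = mth,
        mean_cosine = mean(scores[, mth], na.rm = TRUE),
        sd_cosine = if (n_rep > 1L) stats::sd(scores[, mth], na.rm = TRUE)
                    else NA_real_,
        n_replicates = n_rep, stringsAsFactors = FALSE)
    }
    scores_list[[sc$name]] <- scores
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  # raw per-replicate scores per scenario, for compare_methods()
  attr(out, "scores") <- scores_list
  out
}

.benchmark_score <- function(method, d, guess, restarts, M, seed) {
  truth <- d$truth
  switch(method,
    ilv = {
      cfg <- ilv_config(guess, M = M, restarts = restarts, seed = seed)
      fit <- fit_ilv(d$series, cfg)
      cosine_offdiag(fit$params$B, truth$B)
    },
    clv = cosine_clv(fit_clv(d$series), truth$B),
    glv_relative = cosine_offdiag(fit_glv_relative(d$series)$B, truth$B),
    pearson = cosine_offdiag(correlation_baseline(d$series, "pearson"),
                             truth$B),
    spearman = cosine_offdiag(correlation_baseline(d$series, "spearman"),
                              truth$B),
    glv_absolute = {
      N <- d$series$X * d$clean$Nsum
      abun <- abundance_series(d$series$times, N)
      fit <- fit_glv_absolute(abun, include_self = truth$self_interactions)
      cosine_offdiag(fit$B, truth$B)
    },
    stop("unknown method '", method, "'"))
}

#' Friedman + one-sided Wilcoxon method comparison
#'
#' The significance protocol used on benchmark tables: a Friedman omnibus
#' test over the paired per-replicate scores; if it rejects at `alpha`, the
#' method with the best mean is compared against each other method by a
#' one-sided paired Wilcoxon signed-rank test, and is flagged best only if
#' it beats every other method at `alpha`. Raw pairwise p-values are
#' reported as in the source protocol, with a Holm-corrected column
#' alongside.
#'
#' @param scores Numeric matrix, one row per replicate, one named column per
#'   method (higher is better by default).
#' @param alpha Significance level (default 0.05).
#' @param higher_is_better Direction of the score (`FALSE` for RMSE-like
#'   losses).
#' @return List with `friedman_p`, `best` (method name or `NA` if no method
#'   is significantly best), `flagged` (logical), and `pairwise` (data frame
#'   with `method`, `p`, `p_holm`).
#' @export
compare_methods <- function(scores, alpha = 0.05, higher_is_better = TRUE) {
  scores <- as.matrix(scores)
  if (ncol(scores) < 2L) stop("compare_methods: need >= 2 methods")
  if (nrow(scores) < 5L) stop("compare_methods: need paired samples of length >= 5")
  if (is.null(colnames(scores))) {
    colnames(scores) <- paste0("method", seq_len(ncol(scores)))
  }
  fr <- suppressWarnings(stats::friedman.test(scores))
  p_omni <- fr$p.value
  if (!is.finite(p_omni)) p_omni <- 1  # constant table: no evidence
  means <- colMeans(scores)
  cand <- if (higher_is_better) names(which.max(means)) else
    names(which.min(means))
  pairwise <- data.frame(method = character(), p = numeric(),
                         p_holm = numeric(), stringsAsFactors = FALSE)
  best <- NA_character_
  flagged <- FALSE
  if (p_omni < alpha) {
    others <- setdiff(colnames(scores), cand)
    alt <- if (higher_is_better) "greater" else "less"
    pv <- vapply(others, function(o) {
      suppressWarnings(stats::wilcox.test(scores[, cand], scores[, o],
                                          paired = TRUE, alternative = alt,
                                          exact = FALSE)$p.value)
    }, numeric(1))
    pv[!is.finite(pv)] <- 1
    pairwise <- data.frame(method = others, p = unname(pv),
                           p_holm = unname(stats::p.adjust(pv, "holm")),
                           stringsAsFactors = FALSE)
    flagged <- all(pv < alpha)
    if (flagged) best <- cand
  }
  list(friedman_p = p_omni, best = best, flagged = flagged,
       pairwise = pairwise)
}

#' Train/validation splitting protocol for real time series
#'
#' Randomly splits the time points into a training and a validation set
#' across repeated runs (the first time point is always assigned to
#' training because the ODE simulation needs its anchor). Each method is
#' fitted using only the training subseries; the fitted model is then
#' simulated over the full grid from t = 0, and the RMSE is evaluated
#' separately over the training and the held-out indices. The compositional
#' log-ratio surrogate is excluded by construction: without absolute
#' coefficients its trajectories cannot be simulated.
#'
#' @param series A [composition_series()].
#' @param n_train Number of training time points (`2 <= n_train < total`).
#' @param runs Number of random splits (default 100).
#' @param methods Subset of `c("ilv", "glv_relative", "glv_absolute")`.
#' @param abundance An [abundance_series()] on the same grid; required when
#'   `"glv_absolute"` is requested.
#' @param config An [ilv_config()] used for the iLV fits.
#' @param seed Seed for the split randomization.
#' @return Data frame with columns `run`, `method`, `train_rmse`,
#'   `val_rmse`; the training index sets are in attribute `"train_indices"`.
#' @export
train_validation_protocol <- function(series, n_train, runs = 100L,
                                      methods = c("ilv", "glv_relative",
                                                  "glv_absolute"),
                                      abundance = NULL, config, seed = 1L) {
  stopifnot(inherits(series, "composition_series"))
  methods <- match.arg(methods, several.ok = TRUE)
  npts <- length(series$times)
  if (n_train < 2L || n_train >= npts) {
    stop("train_validation_protocol: need 2 <= n_train < ", npts)
  }
  if ("glv_absolute" %in% methods && is.null(abundance)) {
    stop("train_validation_protocol: 'abundance' required for glv_absolute")
  }
  splits <- withr::with_seed(seed, {
    lapply(seq_len(runs), function(i) {
      sort(c(1L, sample(2:npts, n_train - 1L)))
    })
  })
  rows <- list()
  for (run_i in seq_len(runs)) {
    tr_idx <- splits[[run_i]]
    va_idx <- setdiff(seq_len(npts), tr_idx)
    sub <- composition_series(series$times[tr_idx],
                              series$X[tr_idx, , drop = FALSE],
                              labels = series$labels)
    for (mth in methods) {
      res <- .tv_fit_rmse(mth, sub, series, abundance, tr_idx, va_idx,
                          config, run_i)
      rows[[length(rows) + 1L]] <- data.frame(
        run = run_i, method = mth, train_rmse = res[1], val_rmse = res[2],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "train_indices") <- splits
  out
}

.tv_fit_rmse <- function(method, sub, series, abundance, tr_idx, va_idx,
                         config, run_i) {
  if (method == "ilv") {
    cfg <- config
    cfg$seed <- .derive_seed(config$seed, run_i)
    fit <- fit_ilv(sub, cfg)
    tr <- simulate_relative(fit$params, fit$x0, fit$Nsum0, series$times,
                            rtol = cfg$rtol, atol = cfg$atol)
  } else if (method == "glv_relative") {
    p <- fit_glv_relative(sub)
    # the regression treats compositions as abundances: gauge Nsum = 1
    tr <- simulate_relative(p, series$X[1L, ], 1, series$times)
  } else {
    subN <- abundance_series(abundance$times[tr_idx],
                             abundance$N[tr_idx, , drop = FALSE],
                             labels = abundance$labels)
    p <- fit_glv_absolute(subN, include_self = FALSE)
    ab <- simulate_absolute(p, abundance$N[1L, ], series$times)
    if (!ab$valid) return(c(Inf, Inf))
    tr <- list(times = series$times, X = ab$N / rowSums(ab$N), valid = TRUE)
  }
  c(rmse_to_observed(series, tr, tr_idx), rmse_to_observed(series, tr, va_idx))
}

#' Format a benchmark table as mean(SD) cells
#'
#' Reshapes the long [run_benchmark()] output into one row per design point
#' and one column per method, with `"mean(SD)"` cells (the SD is omitted for
#' noise-free single-run cells).
#'
#' @param bench Output of [run_benchmark()].
#' @param digits Significant digits.
#' @return Data frame of formatted strings.
#' @export
format_benchmark <- function(bench, digits = 3) {
  key <- interaction(bench$scenario, bench$dt, bench$t_range,
                     bench$noise_level, drop = TRUE)
  methods <- unique(bench$method)
  out <- lapply(split(bench, key), function(d) {
    cells <- vapply(methods, function(mth) {
      row <- d[d$method == mth, ]
      if (!nrow(row)) return(NA_character_)
      if (is.na(row$sd_cosine)) {
        format(signif(row$mean_cosine, digits))
      } else {
        paste0(signif(row$mean_cosine, digits), "(",
               signif(row$sd_cosine, digits), ")")
      }
    }, character(1))
    cbind(d[1, c("scenario", "dt", "t_range", "noise_level")],
          as.data.frame(as.list(cells), stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
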