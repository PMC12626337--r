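#' @importFrom withr with_seed
NULL

# Deterministic per-replicate seed, kept below 2^31.
.derive_seed <- function(base, index) {
  as.integer((as.numeric(base) + 1000003 * as.numeric(index)) %% 2147483629) + 1L
}

# The two printed 3-species parameter settings used throughout the simulation
# study, plus their self-interaction variants. The "periodic" setting
# oscillates (lynx-hare-like); the "stabilizing" setting lets one species
# take over while the others decline (cheese-community-like).
.preset_params <- function() {
  periodic_B <- matrix(c(0,     -0.01,  0.011,
                         0.009,  0,    -0.01,
                         -0.012, 0.015, 0), 3, 3, byrow = TRUE)
  stabilizing_B <- matrix(c(0,     -0.02,  0.016,
                            0.01,   0,    -0.014,
                            -0.017, 0.02,  0), 3, 3, byrow = TRUE)
  list(
    periodic = list(r = c(0.31, -0.6, 0.29), B = periodic_B),
    stabilizing = list(r = c(0.21, -0.4, 0.19), B = stabilizing_B),
    # diagonals for the low / medium / high self-regulation variants
    periodic_diag = list(low = c(-0.0017, -0.0028, -0.0042),
                         medium = c(-0.0065, -0.0052, -0.0076),
                         high = c(-0.012, -0.014, -0.011)),
    stabilizing_diag = list(low = c(-0.0011, -0.0021, -0.0035),
                            medium = c(-0.0064, -0.0086, -0.0053),
                            high = c(-0.01, -0.013, -0.011))
  )
}

#' Named simulation scenario presets
#'
#' Returns one of the study's benchmark presets: the two 3-species parameter
#' settings (`periodic`, `stabilizing`), their low/medium/high
#' self-interaction variants (`periodic_self_low`, ..,
#' `stabilizing_self_high`), a longer oscillatory window used for ablation
#' experiments (`periodic_long`: time range 20, interval 1), and an
#' ill-conditioned variant with a positive second growth rate used to probe
#' optimizer instability (`periodic_unstable`: r2 = +0.6, interval 0.4,
#' time range 20). All presets start from x0 = (0.3, 0.5, 0.2) with total
#' abundance 100.
#'
#' @param name Preset identifier (see above).
#' @param dt Sampling interval; overrides the preset default.
#' @param t_range Final time; overrides the preset default.
#' @param noise_level Gaussian noise fraction (0, 0.05, 0.10, ...).
#' @param n_replicates Number of noisy replicate datasets.
#' @param seed Base RNG seed for replicate noise.
#' @return An object of class `glv_scenario`: list with `name`, `params`,
#'   `x0`, `Nsum0`, `dt`, `t_range`, `noise_level`, `n_replicates`, `seed`.
#' @examples
#' sc <- make_scenario("periodic")
#' sc$params$r
#' @export
make_scenario <- function(name, dt = NULL, t_range = NULL, noise_level = NULL,
                          n_replicates = NULL, seed = NULL) {
  pp <- .preset_params()
  presets <- c("periodic", "stabilizing",
               paste0("periodic_self_", c("low", "medium", "high")),
               paste0("stabilizing_self_", c("low", "medium", "high")),
               "periodic_unstable", "periodic_long")
  if (!name %in% presets) {
    stop("make_scenario: unknown preset '", name, "'; available: ",
         paste(presets, collapse = ", "))
  }
  base <- if (grepl("^periodic", name)) pp$periodic else pp$stabilizing
  r <- base$r
  B <- base$B
  dt_def <- 1
  t_def <- 10
  if (grepl("_self_", name)) {
    lev <- sub(".*_self_", "", name)
    diag(B) <- if (grepl("^periodic", name)) pp$periodic_diag[[lev]] else
      pp$stabilizing_diag[[lev]]
  } else if (name == "periodic_unstable") {
    r[2] <- 0.6
    dt_def <- 0.4
    t_def <- 20
  } else if (name == "periodic_long") {
    t_def <- 20
  }
  sc <- list(name = name,
             params = glv_params(r, B),
             x0 = c(0.3, 0.5, 0.2),
             Nsum0 = 100,
             dt = dt %||% dt_def,
             t_range = t_range %||% t_def,
             noise_level = noise_level %||% 0,
             n_replicates = n_replicates %||% 20L,
             seed = seed %||% 1L)
  if (sc$dt <= 0) stop("make_scenario: 'dt' must be positive")
  if (sc$t_range < 2 * sc$dt) stop("make_scenario: 't_range' must be >= 2*dt")
  if (sc$noise_level < 0) stop("make_scenario: 'noise_level' must be >= 0")
  if (sc$n_replicates < 1) stop("make_scenario: 'n_replicates' must be >= 1")
  class(sc) <- "glv_scenario"
  sc
}

#' @export
print.glv_scenario <- function(x, ...) {
  cat("glv_scenario '", x$name, "': dt = ", x$dt, ", t_range = ", x$t_range,
      ", noise = ", x$noise_level, ", replicates = ", x$n_replicates,
      "\n", sep = "")
  invisible(x)
}

#' Corrupt a composition matrix with observation noise
#'
#' Default model: each entry is multiplied by `(1 + eps)` with
#' `eps ~ Normal(0, level)` i.i.d., then clipped below at `clip` and each row
#' renormalized to the simplex (relative abundances must stay compositional).
#' `mode = "additive"` instead adds `Normal(0, level)` draws before clipping
#' and renormalization.
#'
#' @param X Composition matrix (rows on the simplex).
#' @param level Noise standard deviation as a fraction (e.g. 0.05).
#' @param seed RNG seed; draws are deterministic given the seed.
#' @param mode `"multiplicative"` (default) or `"additive"`.
#' @param clip Lower floor applied before renormalization (keeps downstream
#'   logarithms finite).
#' @param renormalize Renormalize rows to sum 1 (default `TRUE`; `FALSE` is
#'   exposed for noise-magnitude diagnostics only).
#' @return Noisy composition matrix of the same shape.
#' @export
add_noise <- function(X, level, seed = 1L, mode = c("multiplicative", "additive"),
                      clip = 1e-6, renormalize = TRUE) {
  mode <- match.arg(mode)
  X <- as.matrix(X)
  if (level < 0) stop("add_noise: 'level' must be >= 0")
  if (level == 0) return(X)
  Y <- withr::with_seed(seed, {
    eps <- matrix(stats::rnorm(length(X), mean = 0, sd = level),
                  nrow(X), ncol(X))
    if (mode == "multiplicative") X * (1 + eps) else X + eps
  })
  Y <- pmax(Y, clip)
  if (renormalize) Y <- Y / rowSums(Y)
  Y
}

#' Generate one (possibly noisy) benchmark dataset from a scenario
#'
#' Simulates the noise-free compositional trajectory on the grid
#' `seq(0, t_range, by = dt)`, then corrupts it with [add_noise()] using a
#' seed derived deterministically from `(scenario$seed, replicate)`. Returns
#' both the observed series and the generating truth for scoring.
#'
#' @param scenario A [make_scenario()] object.
#' @param replicate Replicate index (1-based, `<= scenario$n_replicates`).
#' @param noise_mode Passed to [add_noise()].
#' @return List with `series` (observed [composition_series()]), `truth`
#'   ([glv_params()]), `clean` (the noise-free `glv_trajectory`, whose
#'   `Nsum` path is used by the absolute-data baseline), `replicate`, `seed`.
#' @export
generate_dataset <- function(scenario, replicate = 1L,
                             noise_mode = "multiplicative") {
  stopifnot(inherits(scenario, "glv_scenario"))
  if (replicate > scenario$n_replicates) {
    stop("generate_dataset: replicate index exceeds scenario$n_replicates")
  }
  times <- seq(0, scenario$t_range, by = scenario$dt)
  clean <- simulate_relative(scenario$params, scenario$x0, scenario$Nsum0, times)
  if (!clean$valid) stop("generate_dataset: scenario trajectory is invalid")
  rep_seed <- .derive_seed(scenario$seed, replicate)
  X <- add_noise(clean$X, scenario$noise_level, seed = rep_seed,
                 mode = noise_mode)
  list(series = composition_series(times, X),
       truth = scenario$params,
       clean = clean,
       replicate = as.integer(replicate),
       seed = rep_seed)
}
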