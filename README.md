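# ilv — iterative Lotka-Volterra inference from compositional time series

Microbiome and community-ecology time series are usually *compositional*:
sequencing yields relative abundances `x_i = N_i / N_sum` whose rows sum
to 1, while the total community size `N_sum` stays unobserved. The
generalized Lotka-Volterra (gLV) model

    dN_i/dt = N_i ( r_i + Σ_j b_ij N_j )

is the standard description of pairwise interaction dynamics, but its
classical estimators need absolute abundances. This package implements an
**iterative Lotka-Volterra (iLV) estimator** that fits gLV growth rates
`r_i` and interaction coefficients `b_ij` from relative abundances alone:

1. an **iterative subroutine** that alternates between gradient-matching
   regression on pseudo-absolute abundances and re-simulation of the
   latent total-abundance path, selecting the minimum-RMSE iterate as a
   warm start, and
2. a **nonlinear least-squares subroutine** that polishes the warm start
   against the full ODE-simulated composition trajectory, racing several
   Levenberg-Marquardt-type backends and multiple seeded restarts.

From compositions, `b_ij` is identifiable only up to a positive constant
and the diagonal `b_ii` not at all (they are pinned to 0); recovery is
scored by the scale-invariant cosine between off-diagonal coefficient
vectors and by the trajectory RMSE of the re-simulated compositions.

The package also ships the simulation benchmark around the estimator: a
gLV community simulator in absolute and compositional coordinates
(compiled right-hand sides), preset scenarios with configurable Gaussian
noise, baseline estimators (gradient matching on absolute or relative
data, a compositional log-ratio surrogate, correlation screens),
Friedman/Wilcoxon method comparison, train/validation splitting for real
datasets, interaction-network extraction, and a small command-line
interface (`inst/scripts/ilv`).

## Worked example

```r
library(ilv)

# simulate the oscillatory benchmark community with 5% observation noise
sc <- make_scenario("periodic", noise_level = 0.05, n_replicates = 20, seed = 1)
d  <- generate_dataset(sc, replicate = 1)

# fit the iterative Lotka-Volterra model from compositions alone
fit <- fit_ilv(d$series, ilv_config(Nsum_initial_guess = 200, restarts = 5, seed = 1))
fit
#> ilv_fit: trajectory RMSE 0.004143 (backend lm-a )
#>   winning restart: 1
#>   iterative-subroutine best iteration: 15 (RMSE 0.1062 )
#> gLV parameters: 3 species (self-interactions pinned to 0)
#> r: 0.3325 -0.6686 -0.0959
#> B:
#>           [,1]      [,2]      [,3]
#> [1,]  0.000000 -0.006488  0.004165
#> [2,]  0.007552  0.000000 -0.010470
#> [3,] -0.006897  0.012040  0.000000

# how well is the interaction direction recovered?
cosine_offdiag(fit$params$B, d$truth$B)
#> [1] 0.9623293

# which interactions stand out?
extract_network(fit$params, threshold_factor = 2)
#>   source target     weight       sign
#> 1    sp3    sp2 0.01047085 inhibition
#> 2    sp2    sp3 0.01204380  promotion
```

Reading the output: the nonlinear stage reduced the trajectory RMSE from
0.106 (best warm-start iterate, found at iteration 15 of 100) to 0.0041,
i.e. the re-simulated compositions deviate from the noisy observations by
about 0.4 percentage points of relative abundance on average. The fitted
off-diagonal interaction vector points within ~16 degrees (cosine 0.962)
of the generating one — the scale of `B` is meaningful only relative to
the chosen `Nsum_initial_guess`, which is why the cosine, not an absolute
error, is the recovery metric. The extracted network keeps the two
interactions at least twice the smallest fitted magnitude: species 3
inhibits species 2 and species 2 promotes species 3, matching the signs
of the generating matrix.

Real datasets enter through `read_timeseries()` (time column + one column
per taxon; absolute counts can be converted with `as_composition()`), or
through the CLI: `Rscript inst/scripts/ilv fit data.tsv --nsum-guess 10`.

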