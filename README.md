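# qsarfs

Wrapper descriptor selection for QSAR regression tables, with genetic
algorithms, object-migration learning automata, and their two hybrids.

## The problem

A QSAR (quantitative structure–activity relationship) study models a
biological activity — typically pIC50 — as a function of numeric molecular
descriptors. Descriptor software produces hundreds of columns for a few
dozen compounds, so the modelling step must first find a small subset that
actually predicts. `qsarfs` is for modellers who need that subset search to
be reproducible, seeded, and testable: it fixes the subset size at 20 % of
the training compounds (the 5:1 sample-to-parameter convention) and
minimizes the RMSE of a multiple linear regression refit on each candidate
subset,

    F = sqrt( sum_i (y_i - yhat_i)^2 / M ),

over all subsets of exactly *k* descriptors.

Four seeded stochastic selectors share that objective:

| selector | idea |
|---|---|
| `run_ga()` | elitist GA: tournament selection, single-point crossover, weight-preserving swap mutation, budget repair |
| `run_la()` | object-migration (Tsetlin) automata: each gene carries a value bit and a memory depth; probed actions are rewarded (deepened) or penalized (retreat, then flip at the frontier) against the MLR-RMSE environment |
| `run_sgala()` | sequential hybrid: GA phase (60 generations) seeds an LA phase (40 epochs) |
| `run_mgala()` | mixed hybrid: the automata update runs inside every GA generation, acting on whole action states |

Around the search: CSV IO and preprocessing (constant-column removal,
Pearson `|r| > 0.80` filter, activity-ranked "Y-ranking" train/test split),
LS-SVR downstream modelling with RBF kernel and exact-LOOCV grid search,
Golbraikh–Tropsha/Roy external validation (criteria R4–R8), leverage-based
applicability-domain assessment (Williams plot data, `h* = 3p/n`), a
synthetic generator with planted ground truth, and a multi-seed experiment
runner with a CLI.

## Worked example

A synthetic 55-compound, 40-descriptor table with a planted 3-descriptor
signal (`D001`–`D003`), two constant columns and two near-duplicate pairs:

```r
library(qsarfs)

gen <- generate_synthetic_table(synthetic_spec(
  n_compounds = 55, n_descriptors = 40, k_true = 3, noise_sd = 0.1,
  n_constant_cols = 2, n_correlated_pairs = 2, seed = 101))

pp <- preprocess_descriptors(gen$table)
pp$log
#> preprocess_log: 2 constant, 2 inter-correlated descriptors removed

sp <- y_rank_split(pp$table, test_fraction = 0.2)
sp
#> split_dataset: 44 train / 11 test compounds (fraction 0.20)

k <- feature_budget(nrow(sp$train$X))   # floor(0.2 * 44) = 8

cfg <- hybrid_config(ga_config(k = k, seed = 1), la_config(k = k, seed = 1))
res <- run_mgala(sp$train, cfg)
res
#> MGALA run (seed 1): best rmse 0.068599, r2 0.9974, 8 descriptors
#>    D001, D002, D003, D004, D021, D032, D034, CORA02
```

The selector recovers all three planted descriptors; the remaining five
slots of the fixed budget absorb noise columns, as expected when the budget
exceeds the true signal size. Downstream LS-SVR modelling and validation:

```r
gs <- grid_search_lssvr(sp$train, res$best_genes,
                        gamma_grid = 10^seq(0, 3, length.out = 7),
                        sigma2_grid = 10^seq(0, 3, length.out = 7))
#> gamma = 1e+03, sigma2 = 1e+03, cv rmse = 0.0873

Xtr <- sp$train$X[, res$best_genes]; Xte <- sp$test$X[, res$best_genes]
mod <- fit_lssvr(Xtr, sp$train$y, gs$gamma, gs$sigma2)
q2  <- loocv_q2(sp$train$y,
                lssvr_loo_predictions(Xtr, sp$train$y, gs$gamma, gs$sigma2))
tropsha_roy_stats(sp$test$y, predict(mod, Xte), q2_train = q2)
#> external validation report
#>   Q2 = 0.996  rp2 = 0.990  r0p2 = 0.988  r'0p2 = 0.987
#>   rm2 = 0.947  r'm2 = 0.934  k = 1.005  k' = 0.995
#>   criteria: R4=pass  R5=pass  R6=pass  R7=pass  R8=pass

applicability_domain(Xtr, Xte, sp$train$y - predict(mod),
                     sp$test$y - predict(mod, Xte),
                     sp$train$compound_ids, sp$test$compound_ids)
#> applicability domain: h* = 0.545, 2/55 compounds outside
```

`Q2`/`rp2` near 1 reflect the planted linear signal plus mild noise; `k`
and `k'` near 1 mean the test predictions sit on the identity line; `h* =
3·8/44 = 0.545` is the leverage threshold of the Williams plot, and two
compounds exceed it (structural extrapolation), none by residual.

## Multi-seed experiments and CLI

```r
rep <- run_experiment(run_config("mgala", dataset = "my_table.csv",
                                 n_repeats = 10, base_seed = 1,
                                 out_dir = "results/"))
```

writes per-run JSON, a summary (avg/min/max/std of RMSE and R²), the mean
best-so-far convergence curve, and the preprocessing log. The same is
scriptable via `inst/cli/qsarfs`:

```sh
Rscript inst/cli/qsarfs run     --config cfg.json --algorithm mgala --seed 1
Rscript inst/cli/qsarfs compare --config cfg.json --out results/
Rscript inst/cli/qsarfs synth   --spec spec.json  --out fixtures/
```

Config files are JSON; flags override file values, which override the
defaults above.

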