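#' Experiment configuration
#'
#' Declarative description of a multi-seed selection experiment: dataset,
#' preprocessing, algorithm, and repeat protocol. Algorithm parameter
#' defaults follow the benchmark protocol (population 100; GA generations
#' 100; LA epochs 100; crossover 0.7; mutation 0.3; memory depth 3;
#' SGALA 60 GA generations + 40 LA epochs; MGALA 100 generations).
#' When `k` is `NULL` the feature budget is derived from the training-set
#' size via [feature_budget()].
#'
#' @param algorithm one of `"ga"`, `"la"`, `"sgala"`, `"mgala"`.
#' @param dataset path to a descriptor CSV, or a [descriptor_table()].
#' @param activity_column,id_column CSV column names.
#' @param correlation_threshold Pearson filter threshold (see
#'   [correlation_filter()]); set `NA` to skip the filter.
#' @param remove_constants drop constant columns first (logical).
#' @param test_fraction held-out fraction for [y_rank_split()].
#' @param fitness_mode `"train_rmse"` or `"loocv_rmse"`.
#' @param k fixed subset size, or `NULL` to use the 20 percent budget.
#' @param population_size,generations,epochs,crossover_rate,mutation_rate,memory_N
#'   algorithm parameters (see [ga_config()], [la_config()]).
#' @param sgala_ga_generations,sgala_la_epochs SGALA phase lengths.
#' @param n_repeats number of repeated runs.
#' @param base_seed seed of the first repeat; repeat `i` uses
#'   `base_seed + i - 1`.
#' @param out_dir optional output directory for per-run and summary JSON.
#' @return object of class `run_config`.
#' @export
run_config <- function(algorithm = c("ga", "la", "sgala", "mgala"),
                       dataset, activity_column = "pIC50",
                       id_column = "compound_id",
                       correlation_threshold = 0.80,
                       remove_constants = TRUE,
                       test_fraction = 0.2,
                       fitness_mode = "train_rmse",
                       k = NULL,
                       population_size = 100L,
                       generations = 100L,
                       epochs = 100L,
                       crossover_rate = 0.7,
                       mutation_rate = 0.3,
                       memory_N = 3L,
                       sgala_ga_generations = 60L,
                       sgala_la_epochs = 40L,
                       n_repeats = 10L,
                       base_seed = 1L,
                       out_dir = NULL) {
  algorithm <- match.arg(algorithm)
  structure(list(algorithm = algorithm, dataset = dataset,
                 activity_column = activity_column, id_column = id_column,
                 correlation_threshold = correlation_threshold,
                 remove_constants = remove_constants,
                 test_fraction = test_fraction,
                 fitness_mode = fitness_mode, k = k,
                 population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 epochs = as.integer(epochs),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 memory_N = as.integer(memory_N),
                 sgala_ga_generations = as.integer(sgala_ga_generations),
                 sgala_la_epochs = as.integer(sgala_la_epochs),
                 n_repeats = as.integer(n_repeats),
                 base_seed = as.integer(base_seed),
                 out_dir = out_dir),
            class = "run_config")
}

# Resolve dataset -> preprocessed split + budget; shared by the runner.
prepare_experiment <- function(cfg) {
  tbl <- cfg$dataset
  if (is.character(tbl))
    tbl <- read_descriptor_table(tbl, cfg$activity_column, cfg$id_column)
  log <- preprocess_log()
  if (isTRUE(cfg$remove_constants)) {
    st <- remove_constant_descriptors(tbl)
    tbl <- st$table
    log <- merge_preprocess_logs(log, st$log)
  }
  if (!is.na(cfg$correlation_threshold)) {
    st <- correlation_filter(tbl, cfg$correlation_threshold)
    tbl <- st$table
    log <- merge_preprocess_logs(log, st$log)
  }
  split <- y_rank_split(tbl, cfg$test_fraction)
  k <- if (is.null(cfg$k)) feature_budget(nrow(split$train$X)) else as.integer(cfg$k)
  list(split = split, k = k, log = log)
}

# Build the per-algorithm config objects for one seed.
algorithm_configs <- function(cfg, k, seed) {
  ga <- ga_config(k, cfg$population_size, cfg$generations,
                  cfg$crossover_rate, cfg$mutation_rate, seed,
                  cfg$fitness_mode)
  la <- la_config(k, cfg$population_size, cfg$epochs, cfg$memory_N,
                  seed, cfg$fitness_mode)
  list(ga = ga, la = la,
       hybrid = hybrid_config(ga, la, cfg$sgala_ga_generations,
                              cfg$sgala_la_epochs))
}

run_one <- function(algorithm, train, cfgs) {
  switch(algorithm,
         ga = run_ga(train, cfgs$ga),
         la = run_la(train, cfgs$la),
         sgala = run_sgala(train, cfgs$hybrid),
         mgala = run_mgala(train, cfgs$hybrid))
}

#' Run a multi-seed selection experiment
#'
#' Preprocesses the dataset, splits it by activity ranking, derives the
#' feature budget, and executes `n_repeats` runs of the configured
#' algorithm with seeds `base_seed .. base_seed + n_repeats - 1`. Returns
#' per-repeat results plus summary statistics (avg/min/max/std of RMSE and
#' R2) and the mean best-so-far convergence curve. If `cfg$out_dir` is
#' set, per-run JSON, the summary JSON, the mean convergence CSV and the
#' preprocessing log are written there.
#'
#' @param cfg a [run_config()].
#' @return object of class `summary_report`.
#' @export
run_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  prep <- prepare_experiment(cfg)
  train <- prep$split$train
  seeds <- cfg$base_seed + seq_len(cfg$n_repeats) - 1L
  runs <- vector("list", cfg$n_repeats)
  for (i in seq_along(seeds)) {
    cfgs <- algorithm_configs(cfg, prep$k, seeds[i])
    runs[[i]] <- tryCatch(
      run_one(cfg$algorithm, train, cfgs),
      error = function(e) {
        warning(sprintf("repeat %d (seed %d) failed during search: %s",
                        i, seeds[i], conditionMessage(e)))
        NULL
      })
  }
  ok <- !vapply(runs, is.null, logical(1))
  if (!any(ok)) stop("all repeats failed", call. = FALSE)
  runs <- runs[ok]
  rmse_v <- vapply(runs, function(r) r$best_rmse, numeric(1))
  r2_v <- vapply(runs, function(r) r$best_r2, numeric(1))
  conv <- do.call(rbind, lapply(runs, function(r) r$convergence))
  best_i <- which.min(rmse_v)
  rep <- structure(list(
    algorithm = cfg$algorithm,
    k = prep$k,
    n_train = nrow(train$X), n_test = nrow(prep$split$test$X),
    seeds = seeds[ok],
    rmse = summary_stats(rmse_v), r2 = summary_stats(r2_v),
    per_repeat_selected = lapply(runs, function(r) r$selected_names),
    best_run = runs[[best_i]],
    mean_convergence = colMeans(conv),
    preprocess_log = prep$log,
    runs = runs),
    class = "summary_report")
  if (!is.null(cfg$out_dir)) write_summary_report(rep, cfg$out_dir)
  rep
}

summary_stats <- function(x) {
  c(avg = mean(x), min = min(x), max = max(x),
    std = if (length(x) > 1L) stats::sd(x) else 0)
}

#' @export
print.summary_report <- function(x, ...) {
  cat(sprintf("%s: %d repeats, k = %d (%d train / %d test)\n",
              toupper(x$algorithm), length(x$seeds), x$k, x$n_train, x$n_test))
  cat(sprintf("  rmse avg %.5g  min %.5g  max %.5g  std %.3g\n",
              x$rmse["avg"], x$rmse["min"], x$rmse["max"], x$rmse["std"]))
  cat(sprintf("  r2   avg %.4f  min %.4f  max %.4f  std %.3g\n",
              x$r2["avg"], x$r2["min"], x$r2["max"], x$r2["std"]))
  cat("  best run:", paste(x$best_run$selected_names, collapse = ", "), "\n")
  invisible(x)
}

write_summary_report <- function(rep, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (r in rep$runs)
    write_run_result(r, file.path(out_dir,
                                  sprintf("%s_seed%d.json", r$algorithm, r$seed)))
  summary <- list(algorithm = rep$algorithm, k = rep$k,
                  n_train = rep$n_train, n_test = rep$n_test,
                  seeds = rep$seeds,
                  rmse = as.list(rep$rmse), r2 = as.list(rep$r2),
                  best_selected = rep$best_run$selected_names)
  jsonlite::write_json(summary,
                       file.path(out_dir, sprintf("%s_summary.json", rep$algorithm)),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(
    data.frame(step = seq_along(rep$mean_convergence),
               mean_best_rmse = rep$mean_convergence),
    file.path(out_dir, sprintf("%s_convergence.csv", rep$algorithm)),
    row.names = FALSE)
  write_preprocess_log(rep$preprocess_log,
                       file.path(out_dir, sprintf("%s_preprocess.json", rep$algorithm)))
  invisible(out_dir)
}

#' Compare several algorithms on the same dataset
#'
#' Runs one [run_experiment()] per config (all configs must share the
#' dataset and budget) and merges the mean convergence curves on a common
#' generation/epoch axis, plus a one-row-per-algorithm comparison table.
#'
#' @param cfgs list of [run_config()] objects.
#' @return list with `summaries` (named list of `summary_report`),
#'   `table` (data frame of summary statistics) and `convergence`
#'   (long-format data frame: algorithm, step, mean_best_rmse).
#' @export
compare_algorithms <- function(cfgs) {
  stopifnot(length(cfgs) >= 1L)
  key <- function(cfg) paste(if (is.character(cfg$dataset)) cfg$dataset else "inline",
                             cfg$test_fraction, format(cfg$k))
  if (length(unique(vapply(cfgs, key, character(1)))) != 1L)
    stop("configuration error: configs differ in dataset or budget", call. = FALSE)
  summaries <- lapply(cfgs, run_experiment)
  names(summaries) <- vapply(cfgs, function(c) c$algorithm, character(1))
  tab <- do.call(rbind, lapply(summaries, function(s)
    data.frame(algorithm = s$algorithm,
               rmse_avg = s$rmse["avg"], rmse_min = s$rmse["min"],
               rmse_max = s$rmse["max"], rmse_std = s$rmse["std"],
               r2_avg = s$r2["avg"], r2_min = s$r2["min"],
               r2_max = s$r2["max"], r2_std = s$r2["std"],
               row.names = NULL)))
  conv <- do.call(rbind, lapply(summaries, function(s)
    data.frame(algorithm = s$algorithm,
               step = seq_along(s$mean_convergence),
               mean_best_rmse = s$mean_convergence)))
  list(summaries = summaries, table = tab, convergence = conv)
}
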