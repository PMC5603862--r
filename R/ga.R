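#' Genetic-algorithm configuration
#'
#' Defaults follow the benchmark protocol used throughout the package:
#' population 100, 100 generations, crossover probability 0.7, mutation
#' probability 0.3. `k` is the fixed subset size every chromosome carries
#' (see [feature_budget()]).
#'
#' @param k subset size (number of selected descriptors).
#' @param population_size number of chromosomes (>= 2).
#' @param generations number of generations (>= 1).
#' @param crossover_rate probability a selected parent pair is recombined.
#' @param mutation_rate probability a child undergoes one swap mutation.
#' @param seed integer seed for the run.
#' @param fitness_mode `"train_rmse"` (default) or `"loocv_rmse"`.
#' @return object of class `ga_config`.
#' @export
ga_config <- function(k, population_size = 100L, generations = 100L,
                      crossover_rate = 0.7, mutation_rate = 0.3,
                      seed = 1L, fitness_mode = "train_rmse") {
  stopifnot(population_size >= 2L, generations >= 1L,
            crossover_rate >= 0, crossover_rate <= 1,
            mutation_rate >= 0, mutation_rate <= 1, k >= 1L)
  structure(list(k = as.integer(k),
                 population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 seed = as.integer(seed),
                 fitness_mode = fitness_mode),
            class = "ga_config")
}

#' Initialize a random population of fixed-size subsets
#'
#' Each chromosome is a logical gene vector over the descriptors with
#' exactly `k` genes set, chosen uniformly at random; duplicates between
#' chromosomes are allowed.
#'
#' @param n_descriptors gene vector length.
#' @param cfg a [ga_config()].
#' @return logical matrix, `population_size x n_descriptors`.
#' @export
init_population <- function(n_descriptors, cfg) {
  if (cfg$k > n_descriptors)
    stop("configuration error: k exceeds the number of descriptors", call. = FALSE)
  pop <- matrix(FALSE, cfg$population_size, n_descriptors)
  for (i in seq_len(cfg$population_size))
    pop[i, sample.int(n_descriptors, cfg$k)] <- TRUE
  pop
}

#' Single-point crossover
#'
#' A cut point is drawn uniformly in `1..n-1`; the two children exchange
#' the tails. When `k` is supplied the children are repaired back to
#' weight `k` with [repair_budget()]; with `k = NULL` the raw children are
#' returned (their weight may differ from the parents').
#'
#' @param a,b logical gene vectors of equal length.
#' @param k subset size to repair to, or `NULL` for raw children.
#' @return list of two gene vectors.
#' @export
single_point_crossover <- function(a, b, k = NULL) {
  n <- length(a)
  if (n < 2L) stop("domain error: need at least 2 genes", call. = FALSE)
  if (length(b) != n) stop("domain error: gene lengths differ", call. = FALSE)
  cut <- sample.int(n - 1L, 1L)
  c1 <- c(a[seq_len(cut)], b[(cut + 1L):n])
  c2 <- c(b[seq_len(cut)], a[(cut + 1L):n])
  if (!is.null(k)) {
    c1 <- repair_budget(c1, k)
    c2 <- repair_budget(c2, k)
  }
  list(c1, c2)
}

#' Order-based (swap) mutation
#'
#' Two distinct positions are drawn uniformly and their gene values are
#' exchanged, which preserves the Hamming weight by construction.
#'
#' @param genes logical gene vector of length >= 2.
#' @return mutated gene vector.
#' @export
order_based_mutation <- function(genes) {
  pos <- sample.int(length(genes), 2L)
  genes[pos] <- genes[rev(pos)]
  genes
}

#' Repair a chromosome to the exact feature budget
#'
#' Surplus selected genes are deselected at random; missing selections are
#' added at random, so the result has weight exactly `k` and stays as
#' close to the input as possible.
#'
#' @param genes logical gene vector.
#' @param k target weight.
#' @return gene vector of weight `k`.
#' @export
repair_budget <- function(genes, k) {
  n <- length(genes)
  if (k > n) stop("configuration error: k exceeds gene length", call. = FALSE)
  w <- sum(genes)
  if (w > k) {
    on_idx <- which(genes)
    genes[resample(on_idx, w - k)] <- FALSE
  } else if (w < k) {
    off_idx <- which(!genes)
    genes[resample(off_idx, k - w)] <- TRUE
  }
  genes
}

# sample() misbehaves when x has length 1; this is the standard guard.
resample <- function(x, size) x[sample.int(length(x), size)]

tournament_pick <- function(rmse_values) {
  pair <- sample.int(length(rmse_values), 2L, replace = TRUE)
  if (rmse_values[pair[1L]] <= rmse_values[pair[2L]]) pair[1L] else pair[2L]
}

# internal population record: genes matrix + cached fitness vectors
eval_population <- function(pop, fitness_fn) {
  rmse_v <- numeric(nrow(pop))
  r2_v <- numeric(nrow(pop))
  for (i in seq_len(nrow(pop))) {
    f <- fitness_fn(pop[i, ])
    rmse_v[i] <- f$rmse
    r2_v[i] <- f$r2
  }
  list(genes = pop, rmse = rmse_v, r2 = r2_v)
}

#' One elitist GA generation
#'
#' The best chromosome is copied unchanged; the remaining slots are filled
#' by binary-tournament parent selection (minimizing RMSE), single-point
#' crossover with probability `crossover_rate` (otherwise the parents are
#' cloned), one swap mutation per child with probability `mutation_rate`,
#' budget repair, and evaluation.
#'
#' @param state list with `genes` (logical matrix), `rmse`, `r2` — an
#'   evaluated population as produced by [init_population()] plus
#'   evaluation.
#' @param cfg a [ga_config()].
#' @param fitness_fn function taking a gene mask, returning
#'   `list(rmse, r2)`.
#' @return updated population state of the same shape.
#' @export
ga_generation <- function(state, cfg, fitness_fn) {
  pop <- state$genes
  n <- ncol(pop)
  size <- nrow(pop)
  new_genes <- matrix(FALSE, size, n)
  new_rmse <- numeric(size)
  new_r2 <- numeric(size)
  elite <- which.min(state$rmse)
  new_genes[1L, ] <- pop[elite, ]
  new_rmse[1L] <- state$rmse[elite]
  new_r2[1L] <- state$r2[elite]
  slot <- 2L
  while (slot <= size) {
    p1 <- tournament_pick(state$rmse)
    p2 <- tournament_pick(state$rmse)
    if (stats::runif(1) < cfg$crossover_rate) {
      kids <- single_point_crossover(pop[p1, ], pop[p2, ], k = cfg$k)
    } else {
      kids <- list(pop[p1, ], pop[p2, ])
    }
    for (child in kids) {
      if (slot > size) break
      if (stats::runif(1) < cfg$mutation_rate) child <- order_based_mutation(child)
      child <- repair_budget(child, cfg$k)
      f <- fitness_fn(child)
      new_genes[slot, ] <- child
      new_rmse[slot] <- f$rmse
      new_r2[slot] <- f$r2
      slot <- slot + 1L
    }
  }
  list(genes = new_genes, rmse = new_rmse, r2 = new_r2)
}

# Shared GA engine: returns final state + best-so-far bookkeeping, so the
# sequential hybrid can hand the last population to the automata phase.
ga_engine <- function(train, cfg, generations, state = NULL) {
  fitness_fn <- make_fitness(train, cfg$fitness_mode)
  if (is.null(state)) {
    state <- eval_population(init_population(ncol(train$X), cfg), fitness_fn)
  }
  best_i <- which.min(state$rmse)
  best <- list(genes = state$genes[best_i, ], rmse = state$rmse[best_i],
               r2 = state$r2[best_i])
  convergence <- numeric(generations)
  for (g in seq_len(generations)) {
    state <- ga_generation(state, cfg, fitness_fn)
    i <- which.min(state$rmse)
    if (state$rmse[i] < best$rmse) {
      best <- list(genes = state$genes[i, ], rmse = state$rmse[i],
                   r2 = state$r2[i])
    }
    convergence[g] <- best$rmse
  }
  list(state = state, best = best, convergence = convergence)
}

#' Run the plain GA descriptor selector
#'
#' Executes `cfg$generations` elitist generations on a preprocessed
#' training table and reports the best subset found, with the
#' best-so-far RMSE per generation as the convergence curve.
#'
#' @param train a preprocessed [descriptor_table()].
#' @param cfg a [ga_config()].
#' @return a `run_result`; see [run_result()].
#' @export
run_ga <- function(train, cfg) {
  set.seed(cfg$seed)
  t0 <- proc.time()[["elapsed"]]
  eng <- ga_engine(train, cfg, cfg$generations)
  run_result("ga", eng$best, eng$convergence, train, cfg$seed,
             proc.time()[["elapsed"]] - t0)
}

#' Search-run result
#'
#' Common result container for all four selectors: the best subset, its
#' fitness, the best-so-far RMSE per generation/epoch, and bookkeeping.
#'
#' @param algorithm one of `"ga"`, `"la"`, `"sgala"`, `"mgala"`.
#' @param best list with `genes`, `rmse`, `r2` (and optionally `depth`).
#' @param convergence numeric best-so-far RMSE curve.
#' @param train the training table (for descriptor names).
#' @param seed the seed used.
#' @param elapsed wall-clock seconds.
#' @return object of class `run_result` with fields `algorithm`,
#'   `best_genes`, `best_rmse`, `best_r2`, `selected_names`,
#'   `convergence`, `depths` (LA-family only, else `NULL`), `seed`,
#'   `elapsed`.
#' @export
run_result <- function(algorithm, best, convergence, train, seed, elapsed) {
  structure(list(algorithm = algorithm,
                 best_genes = best$genes,
                 best_rmse = best$rmse,
                 best_r2 = best$r2,
                 selected_names = train$descriptor_names[best$genes],
                 convergence = convergence,
                 depths = best$depth,
                 seed = seed,
                 elapsed = elapsed),
            class = "run_result")
}

#' @export
print.run_result <- function(x, ...) {
  cat(sprintf("%s run (seed %d): best rmse %.5g, r2 %.4f, %d descriptors\n",
              toupper(x$algorithm), x$seed, x$best_rmse, x$best_r2,
              length(x$selected_names)))
  cat("  ", paste(x$selected_names, collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a run result to JSON
#' @param res a `run_result`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_run_result <- function(res, path) {
  out <- list(algorithm = res$algorithm,
              selected_names = res$selected_names,
              rmse = res$best_rmse, r2 = res$best_r2,
              convergence = res$convergence,
              seed = res$seed, elapsed_seconds = res$elapsed)
  if (!is.null(res$depths)) out$depths <- res$depths
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
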