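#' Learning-automata configuration
#'
#' Object-migration automata with per-action memory depth `memory_N`
#' (default 3). One action per automaton is probed each epoch and rewarded
#' or penalized against the environment, here the MLR-RMSE fitness acting
#' as a deterministic P-model environment (beta = 0 reward, 1 penalty).
#'
#' @param k subset size.
#' @param population_size number of automata.
#' @param epochs number of learning epochs.
#' @param memory_N memory depth (1 = frontier only).
#' @param seed integer seed.
#' @param fitness_mode `"train_rmse"` or `"loocv_rmse"`.
#' @return object of class `la_config`.
#' @export
la_config <- function(k, population_size = 100L, epochs = 100L,
                      memory_N = 3L, seed = 1L, fitness_mode = "train_rmse") {
  stopifnot(population_size >= 1L, epochs >= 1L, memory_N >= 1L, k >= 1L)
  structure(list(k = as.integer(k),
                 population_size = as.integer(population_size),
                 epochs = as.integer(epochs),
                 memory_N = as.integer(memory_N),
                 seed = as.integer(seed),
                 fitness_mode = fitness_mode),
            class = "la_config")
}

#' Construct an automaton
#'
#' An automaton is a candidate subset where each gene (action) also
#' carries a memory depth: depth 1 is the frontier (the action can be
#' flipped by a penalty), depth `memory_N` is the most internal
#' (most confident) state.
#'
#' @param value logical action-value vector (TRUE = descriptor selected).
#' @param depth integer depth vector, same length, entries in
#'   `1..memory_N`.
#' @return object of class `automaton`.
#' @export
automaton <- function(value, depth = rep(1L, length(value))) {
  stopifnot(length(value) == length(depth), all(depth >= 1L))
  structure(list(value = as.logical(value), depth = as.integer(depth)),
            class = "automaton")
}

#' Initialize a population of automata
#'
#' Each automaton selects `k` actions uniformly at random; all depths
#' start at the frontier (depth 1).
#'
#' @param n_descriptors number of actions per automaton.
#' @param cfg a [la_config()].
#' @return list of [automaton()] objects.
#' @export
init_automata <- function(n_descriptors, cfg) {
  if (cfg$k > n_descriptors)
    stop("configuration error: k exceeds the number of descriptors", call. = FALSE)
  lapply(seq_len(cfg$population_size), function(i) {
    v <- logical(n_descriptors)
    v[sample.int(n_descriptors, cfg$k)] <- TRUE
    automaton(v)
  })
}

# Choose the compensating action for a flip of action j: an action of
# opposite value, preferably at the frontier (depth 1), otherwise among
# those of minimum depth; uniform among candidates. Keeps weight at k
# while only touching low-confidence actions.
pick_compensation <- function(a, j) {
  cand <- which(a$value != a$value[j])
  if (length(cand) == 0L)
    stop("domain error: no opposite-valued action to compensate with", call. = FALSE)
  frontier <- cand[a$depth[cand] == 1L]
  if (length(frontier) == 0L)
    frontier <- cand[a$depth[cand] == min(a$depth[cand])]
  resample(frontier, 1L)
}

#' Probe an action against the fitness environment
#'
#' Computes `S1` (the automaton's current RMSE) and `S2` (the RMSE of a
#' trial automaton in which action `j` is flipped and one compensating
#' opposite-valued action is flipped back to preserve the subset size).
#' The trial is discarded: probing never mutates the automaton. The
#' environment signal is `beta = 0` (reward) iff `S1 <= S2`, else
#' `beta = 1` (penalty).
#'
#' @param a an [automaton()].
#' @param j action index to probe.
#' @param fitness_fn mask fitness closure (`make` it from the training
#'   table via [evaluate_subset()] semantics; internally
#'   `function(mask) list(rmse, r2)`).
#' @param S1 optional cached current RMSE; computed if `NULL`.
#' @return list with `S1`, `S2`, `beta`, `comp` (compensating index),
#'   `trial_value` (the trial mask) and `trial_r2`.
#' @export
probe_action <- function(a, j, fitness_fn, S1 = NULL) {
  if (j < 1L || j > length(a$value))
    stop("domain error: action index out of range", call. = FALSE)
  if (is.null(S1)) S1 <- fitness_fn(a$value)$rmse
  comp <- pick_compensation(a, j)
  trial <- a$value
  trial[c(j, comp)] <- !trial[c(j, comp)]
  f2 <- fitness_fn(trial)
  list(S1 = S1, S2 = f2$rmse, beta = as.integer(S1 > f2$rmse),
       comp = comp, trial_value = trial, trial_r2 = f2$r2)
}

#' Reward an action
#'
#' Moves action `j` one step inward (depth + 1, saturating at
#' `memory_N`); the action value is never changed by a reward.
#'
#' @param a an [automaton()].
#' @param j action index.
#' @param memory_N depth bound.
#' @return the updated automaton.
#' @export
reward <- function(a, j, memory_N) {
  a$depth[j] <- min(memory_N, a$depth[j] + 1L)
  a
}

#' Penalize an action
#'
#' An internal action (depth > 1) moves one step toward the frontier,
#' value unchanged. A frontier action (depth 1) has its value flipped,
#' and — to keep the subset size at `k` — one compensating
#' opposite-valued action (frontier-preferred, see the probe rule) is
#' flipped with it; both touched actions are reset to depth 1.
#'
#' @param a an [automaton()].
#' @param j action index.
#' @param comp compensating index to use for a frontier flip; drawn via
#'   the probe rule when `NULL`.
#' @return the updated automaton.
#' @export
penalize <- function(a, j, comp = NULL) {
  if (a$depth[j] > 1L) {
    a$depth[j] <- a$depth[j] - 1L
  } else {
    if (is.null(comp)) comp <- pick_compensation(a, j)
    a$value[c(j, comp)] <- !a$value[c(j, comp)]
    a$depth[c(j, comp)] <- 1L
  }
  a
}

# internal LA population record: automata + cached fitness
eval_automata <- function(automata, fitness_fn) {
  rmse_v <- numeric(length(automata))
  r2_v <- numeric(length(automata))
  for (i in seq_along(automata)) {
    f <- fitness_fn(automata[[i]]$value)
    rmse_v[i] <- f$rmse
    r2_v[i] <- f$r2
  }
  list(automata = automata, rmse = rmse_v, r2 = r2_v)
}

#' One learning epoch over a population of automata
#'
#' For every automaton one action index is drawn uniformly, probed, and
#' then rewarded (`beta = 0`) or penalized (`beta = 1`). A frontier-flip
#' penalty adopts exactly the probed trial (whose RMSE `S2` was strictly
#' better), so the cached fitness is refreshed from the probe.
#'
#' @param st population state: list with `automata`, `rmse`, `r2`.
#' @param cfg a [la_config()].
#' @param fitness_fn mask fitness closure.
#' @return updated population state.
#' @export
la_epoch <- function(st, cfg, fitness_fn) {
  n <- length(st$automata[[1L]]$value)
  for (i in seq_along(st$automata)) {
    a <- st$automata[[i]]
    j <- sample.int(n, 1L)
    pr <- probe_action(a, j, fitness_fn, S1 = st$rmse[i])
    if (pr$beta == 0L) {
      st$automata[[i]] <- reward(a, j, cfg$memory_N)
    } else {
      flips <- a$depth[j] == 1L
      st$automata[[i]] <- penalize(a, j, comp = pr$comp)
      if (flips) {           # adopted the probed trial: refresh cache
        st$rmse[i] <- pr$S2
        st$r2[i] <- pr$trial_r2
      }
    }
  }
  st
}

la_engine <- function(train, cfg, epochs, st = NULL) {
  fitness_fn <- make_fitness(train, cfg$fitness_mode)
  if (is.null(st)) {
    st <- eval_automata(init_automata(ncol(train$X), cfg), fitness_fn)
  }
  best <- la_best(st)
  convergence <- numeric(epochs)
  for (e in seq_len(epochs)) {
    st <- la_epoch(st, cfg, fitness_fn)
    cand <- la_best(st)
    if (cand$rmse < best$rmse) best <- cand
    convergence[e] <- best$rmse
  }
  list(state = st, best = best, convergence = convergence)
}

la_best <- function(st) {
  i <- which.min(st$rmse)
  a <- st$automata[[i]]
  list(genes = a$value, rmse = st$rmse[i], r2 = st$r2[i], depth = a$depth)
}

#' Run the learning-automata descriptor selector
#'
#' Runs `cfg$epochs` epochs on a preprocessed training table; the
#' convergence curve records the best-so-far RMSE per epoch and the best
#' automaton's mask and final depth vector are reported.
#'
#' @param train a preprocessed [descriptor_table()].
#' @param cfg an [la_config()].
#' @return a [run_result()] (with the `depths` field populated).
#' @export
run_la <- function(train, cfg) {
  set.seed(cfg$seed)
  t0 <- proc.time()[["elapsed"]]
  eng <- la_engine(train, cfg, cfg$epochs)
  run_result("la", eng$best, eng$convergence, train, cfg$seed,
             proc.time()[["elapsed"]] - t0)
}
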