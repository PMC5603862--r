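#' Hybrid GA + LA configuration
#'
#' Bundles a GA and an LA configuration. The mixed hybrid (MGALA) runs
#' `ga$generations` generations, each consisting of the GA operators
#' followed by one automata update — generation and epoch counters are one
#' and the same. The sequential hybrid (SGALA) runs
#' `sgala_ga_generations` GA generations and hands the final population to
#' an LA phase of `sgala_la_epochs` epochs (defaults 60 + 40).
#'
#' @param ga a [ga_config()].
#' @param la an [la_config()]; `k` and `population_size` must match `ga`.
#' @param sgala_ga_generations GA phase length for SGALA.
#' @param sgala_la_epochs LA phase length for SGALA.
#' @return object of class `hybrid_config`.
#' @export
hybrid_config <- function(ga, la, sgala_ga_generations = 60L,
                          sgala_la_epochs = 40L) {
  stopifnot(inherits(ga, "ga_config"), inherits(la, "la_config"))
  if (ga$k != la$k)
    stop("configuration error: ga and la budgets (k) differ", call. = FALSE)
  if (ga$population_size != la$population_size)
    stop("configuration error: ga and la population sizes differ", call. = FALSE)
  structure(list(ga = ga, la = la,
                 sgala_ga_generations = as.integer(sgala_ga_generations),
                 sgala_la_epochs = as.integer(sgala_la_epochs)),
            class = "hybrid_config")
}

# Crossover over automata: the cut applies to whole action states, so a
# child inherits value AND learned depth segment-wise from its parents.
crossover_automata <- function(a, b) {
  n <- length(a$value)
  cut <- sample.int(n - 1L, 1L)
  head_idx <- seq_len(cut)
  tail_idx <- (cut + 1L):n
  c1 <- automaton(c(a$value[head_idx], b$value[tail_idx]),
                  c(a$depth[head_idx], b$depth[tail_idx]))
  c2 <- automaton(c(b$value[head_idx], a$value[tail_idx]),
                  c(b$depth[head_idx], a$depth[tail_idx]))
  list(c1, c2)
}

# Swap mutation over automata exchanges whole action states.
mutate_automaton <- function(a) {
  pos <- sample.int(length(a$value), 2L)
  a$value[pos] <- a$value[rev(pos)]
  a$depth[pos] <- a$depth[rev(pos)]
  a
}

# Budget repair for automata: any action whose value the repair changes
# loses its learned confidence and is reset to the frontier.
repair_automaton <- function(a, k) {
  fixed <- repair_budget(a$value, k)
  changed <- which(fixed != a$value)
  a$value <- fixed
  a$depth[changed] <- 1L
  a
}

#' One MGALA generation
#'
#' An elitist GA generation over a population of automata (tournament
#' selection, state-inheriting single-point crossover, state-swap
#' mutation, depth-resetting repair), followed by one learning-automata
#' update (probe + reward/penalize) applied to every individual.
#'
#' @param st population state: list with `automata`, `rmse`, `r2`.
#' @param cfg a [hybrid_config()].
#' @param fitness_fn mask fitness closure.
#' @return updated population state.
#' @export
mgala_generation <- function(st, cfg, fitness_fn) {
  size <- length(st$automata)
  new_automata <- vector("list", size)
  new_rmse <- numeric(size)
  new_r2 <- numeric(size)
  elite <- which.min(st$rmse)
  new_automata[[1L]] <- st$automata[[elite]]
  new_rmse[1L] <- st$rmse[elite]
  new_r2[1L] <- st$r2[elite]
  slot <- 2L
  while (slot <= size) {
    p1 <- tournament_pick(st$rmse)
    p2 <- tournament_pick(st$rmse)
    if (stats::runif(1) < cfg$ga$crossover_rate) {
      kids <- crossover_automata(st$automata[[p1]], st$automata[[p2]])
    } else {
      kids <- list(st$automata[[p1]], st$automata[[p2]])
    }
    for (child in kids) {
      if (slot > size) break
      if (stats::runif(1) < cfg$ga$mutation_rate) child <- mutate_automaton(child)
      child <- repair_automaton(child, cfg$ga$k)
      f <- fitness_fn(child$value)
      new_automata[[slot]] <- child
      new_rmse[slot] <- f$rmse
      new_r2[slot] <- f$r2
      slot <- slot + 1L
    }
  }
  la_epoch(list(automata = new_automata, rmse = new_rmse, r2 = new_r2),
           cfg$la, fitness_fn)
}

#' Run the mixed GA + LA selector (MGALA)
#'
#' Initializes a population of automata at the frontier and runs
#' `cfg$ga$generations` mixed generations ([mgala_generation()]).
#'
#' @param train a preprocessed [descriptor_table()].
#' @param cfg a [hybrid_config()].
#' @return a [run_result()] (with `depths`).
#' @export
run_mgala <- function(train, cfg) {
  set.seed(cfg$ga$seed)
  t0 <- proc.time()[["elapsed"]]
  fitness_fn <- make_fitness(train, cfg$ga$fitness_mode)
  st <- eval_automata(init_automata(ncol(train$X), cfg$la), fitness_fn)
  best <- la_best(st)
  convergence <- numeric(cfg$ga$generations)
  for (g in seq_len(cfg$ga$generations)) {
    st <- mgala_generation(st, cfg, fitness_fn)
    cand <- la_best(st)
    if (cand$rmse < best$rmse) best <- cand
    convergence[g] <- best$rmse
  }
  run_result("mgala", best, convergence, train, cfg$ga$seed,
             proc.time()[["elapsed"]] - t0)
}

#' Run the sequential GA-then-LA selector (SGALA)
#'
#' Runs `cfg$sgala_ga_generations` GA generations; the final GA population
#' seeds the LA phase (all depths reset to the frontier, since chromosomes
#' carry no confidence information), which runs for `cfg$sgala_la_epochs`
#' epochs. The convergence curve concatenates the two phases' best-so-far
#' curves and is globally non-increasing.
#'
#' @param train a preprocessed [descriptor_table()].
#' @param cfg a [hybrid_config()].
#' @return a [run_result()].
#' @export
run_sgala <- function(train, cfg) {
  set.seed(cfg$ga$seed)
  t0 <- proc.time()[["elapsed"]]
  if (cfg$sgala_ga_generations == 0L) {
    eng <- la_engine(train, cfg$la, cfg$sgala_la_epochs)
    res <- run_result("sgala", eng$best, eng$convergence, train,
                      cfg$ga$seed, proc.time()[["elapsed"]] - t0)
    return(res)
  }
  ga_eng <- ga_engine(train, cfg$ga, cfg$sgala_ga_generations)
  best <- ga_eng$best
  convergence <- ga_eng$convergence
  if (cfg$sgala_la_epochs > 0L) {
    automata <- lapply(seq_len(nrow(ga_eng$state$genes)), function(i)
      automaton(ga_eng$state$genes[i, ]))
    st <- list(automata = automata, rmse = ga_eng$state$rmse,
               r2 = ga_eng$state$r2)
    la_eng <- la_engine(train, cfg$la, cfg$sgala_la_epochs, st = st)
    if (la_eng$best$rmse < best$rmse) best <- la_eng$best
    convergence <- c(convergence, pmin(la_eng$convergence, min(convergence)))
  }
  run_result("sgala", best, convergence, train, cfg$ga$seed,
             proc.time()[["elapsed"]] - t0)
}
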