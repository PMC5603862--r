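test_that("init_automata starts at the frontier with the right weight", {
  cfg <- la_config(k = 3, population_size = 6, memory_N = 3)
  set.seed(101)
  pop <- init_automata(10, cfg)
  expect_length(pop, 6L)
  for (a in pop) {
    expect_weight(a$value, 3)
    expect_true(all(a$depth == 1L))
  }
  set.seed(101)
  expect_identical(init_automata(10, cfg), pop)
  expect_error(init_automata(2, cfg), "configuration error")
})

test_that("probe_action is side-effect-free and beta follows S1 vs S2", {
  gen <- generate_synthetic_table(synthetic_spec(25, 8, 2, noise_sd = 0, seed = 102))
  fitness_fn <- qsarfs:::make_fitness(gen$table)

  # automaton sitting on the planted truth: swapping a true descriptor out
  # can only hurt, so probing it must reward (beta = 0)
  truth <- automaton(seq_len(8) %in% gen$truth$true_indices)
  snapshot <- truth
  set.seed(103)
  pr <- probe_action(truth, gen$truth$true_indices[1], fitness_fn)
  expect_identical(truth, snapshot)        # probing never mutates
  expect_equal(pr$beta, 0L)
  expect_lte(pr$S1, pr$S2)
  expect_weight(pr$trial_value, 2)

  # forced improvement: wrong single-descriptor subset, k = 1, n = 2
  two <- descriptor_table(cbind(a = gen$table$X[, gen$truth$true_indices[1]],
                                b = gen$table$X[, 5]),
                          gen$table$y)
  f2 <- qsarfs:::make_fitness(two)
  wrong <- automaton(c(FALSE, TRUE))
  pr2 <- probe_action(wrong, 2L, f2)
  expect_equal(pr2$beta, 1L)
  expect_gt(pr2$S1, pr2$S2)

  # S1 == S2 exactly is a reward
  fit_const <- function(mask) list(rmse = 0.5, r2 = 0)
  pr3 <- probe_action(automaton(c(TRUE, FALSE)), 1L, fit_const)
  expect_equal(pr3$beta, 0L)
})

test_that("reward deepens without flipping; penalize retreats then flips", {
  a <- automaton(c(TRUE, FALSE, TRUE, FALSE), c(1L, 1L, 2L, 3L))

  r <- reward(a, 1, memory_N = 3)
  expect_equal(r$depth[1], 2L)
  expect_identical(r$value, a$value)
  r_sat <- reward(a, 4, memory_N = 3)
  expect_equal(r_sat$depth[4], 3L)         # saturates at N

  # internal penalty: one step toward the frontier, value intact
  p <- penalize(a, 4)
  expect_equal(p$depth[4], 2L)
  expect_identical(p$value, a$value)

  # frontier penalty flips j plus one opposite-valued frontier action
  set.seed(104)
  pf <- penalize(a, 2)                     # value 0 at frontier -> turned on
  expect_true(pf$value[2])
  expect_weight(pf$value, 2)
  flipped_off <- which(a$value & !pf$value)
  expect_length(flipped_off, 1L)
  expect_equal(a$depth[flipped_off], 1L)   # compensation came from the frontier
  expect_equal(pf$depth[2], 1L)
  expect_equal(pf$depth[flipped_off], 1L)

  # weight-k is preserved across many random penalize calls
  set.seed(105)
  for (i in 1:1000) {
    v <- logical(10); v[sample(10, 4)] <- TRUE
    d <- sample(1:3, 10, replace = TRUE)
    out <- penalize(automaton(v, d), sample(10, 1))
    expect_weight(out$value, 4)
    expect_true(all(out$depth >= 1L & out$depth <= 3L))
  }
})

test_that("la_epoch updates cached fitness consistently and never worsens", {
  gen <- generate_synthetic_table(synthetic_spec(30, 10, 3, noise_sd = 0.2, seed = 106))
  fitness_fn <- qsarfs:::make_fitness(gen$table)
  cfg <- la_config(k = 3, population_size = 8, memory_N = 3)

  set.seed(107)
  st <- qsarfs:::eval_automata(init_automata(10, cfg), fitness_fn)
  before <- st$rmse
  for (e in 1:10) {
    st <- la_epoch(st, cfg, fitness_fn)
    # cache agrees with a fresh evaluation of every mask
    fresh <- vapply(st$automata, function(a) fitness_fn(a$value)$rmse, numeric(1))
    expect_equal(st$rmse, fresh, tolerance = 1e-12)
    # adopted flips were strictly improving trials: no automaton worsens
    expect_true(all(st$rmse <= before + 1e-12))
    before <- st$rmse
  }

  # reproducible trajectory for a single automaton
  cfg1 <- la_config(k = 3, population_size = 1)
  set.seed(108)
  s1 <- qsarfs:::eval_automata(init_automata(10, cfg1), fitness_fn)
  for (e in 1:5) s1 <- la_epoch(s1, cfg1, fitness_fn)
  set.seed(108)
  s2 <- qsarfs:::eval_automata(init_automata(10, cfg1), fitness_fn)
  for (e in 1:5) s2 <- la_epoch(s2, cfg1, fitness_fn)
  expect_identical(s1, s2)
})

test_that("memory_N = 1 degenerates to stochastic local search", {
  gen <- generate_synthetic_table(synthetic_spec(25, 8, 2, noise_sd = 0.2, seed = 109))
  fitness_fn <- qsarfs:::make_fitness(gen$table)
  cfg <- la_config(k = 2, population_size = 5, memory_N = 1)
  set.seed(110)
  st <- qsarfs:::eval_automata(init_automata(8, cfg), fitness_fn)
  for (e in 1:20) {
    st <- la_epoch(st, cfg, fitness_fn)
    for (a in st$automata) expect_true(all(a$depth == 1L))
  }
})

test_that("run_la converges on planted signal with best-so-far bookkeeping", {
  gen <- generate_synthetic_table(synthetic_spec(40, 20, 3, noise_sd = 0, seed = 111))
  opt <- oracle_exhaustive(gen$table, 3)

  res <- run_la(gen$table, la_config(k = 3, population_size = 40,
                                     epochs = 60, seed = 1))
  expect_lt(res$best_rmse, opt$rmse + 1e-6)
  expect_length(res$depths, 20L)
  expect_true(all(res$depths >= 1L & res$depths <= 3L))

  one <- run_la(gen$table, la_config(k = 3, population_size = 10,
                                     epochs = 1, seed = 2))
  expect_length(one$convergence, 1L)

  for (seed in 1:3) {
    r <- run_la(gen$table, la_config(k = 3, population_size = 15,
                                     epochs = 10, seed = seed))
    expect_true(all(diff(r$convergence) <= 0))
    expect_gte(r$best_rmse, opt$rmse - 1e-10)
  }
})
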