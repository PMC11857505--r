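# A cheap deterministic stand-in evaluator over the search space: rewards
# configurations near the centre of each grid. Lets GA mechanics be tested
# without fitting any model.
dummy_evaluator <- function(hp) {
  target <- list(n_rfe = 50, n_est = 100, max_depth = 6, min_split = 10,
                 min_leaf = 6)
  score <- sum(vapply(names(target), function(s) {
    -abs(hp[[s]] - target[[s]]) / target[[s]]
  }, numeric(1)))
  score <- score + (hp$crit == "log_loss") + (identical(hp$n_f, "log2"))
  exp(score)
}

test_that("the fitness law and its five-fold weighting claim hold", {
  expect_equal(ga_fitness(1, 50), 2500)
  expect_equal(ga_fitness(0.9, 50), 0.9^15 * 2500)
  expect_equal(ga_fitness(1, 50) / ga_fitness(0.9, 50), (1 / 0.9)^15)
  expect_equal((1 / 0.9)^15, 4.86, tolerance = 0.01)
  expect_equal(round((1 / 0.9)^15), 5)  # "approximately five times"
  expect_equal(ga_fitness(-0.4, 10), 0)  # negative MCC clamps to zero
})

test_that("selection weights are proportional with a uniform fallback", {
  expect_equal(selection_weights(c(1, 1, 2)), c(0.25, 0.25, 0.5))
  expect_equal(selection_weights(c(0, 0, 0)), rep(1 / 3, 3))
  set.seed(4)
  w <- selection_weights(runif(50))
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_error(selection_weights(c(1, -1)), "non-negative")
  # an MCC-1.0 individual outweighs an MCC-0.9 one by (1/0.9)^15
  w2 <- selection_weights(c(ga_fitness(1, 50), ga_fitness(0.9, 50)))
  expect_equal(w2[1] / w2[2], (1 / 0.9)^15, tolerance = 1e-12)
})

test_that("crossover swaps exactly two slots and conserves values", {
  space <- search_space()
  set.seed(12)
  a <- ga_random_individual_for_tests(space, 1)
  b <- ga_random_individual_for_tests(space, 2)
  slots <- c("n_rfe", "n_est", "max_depth", "min_split", "min_leaf",
             "n_f", "crit")
  for (i in 1:100) {
    kids <- ga_crossover(a, b)
    diff_a <- sum(vapply(slots, function(s) {
      !identical(kids[[1]][[s]], a[[s]])
    }, logical(1)))
    same_as_b <- vapply(slots, function(s) identical(kids[[1]][[s]], b[[s]]),
                        logical(1))
    # slots that changed in offspring 1 came from parent b (and vice versa)
    expect_lte(diff_a, 2)
    for (s in slots) {
      vals_parents <- list(a[[s]], b[[s]])
      vals_kids <- list(kids[[1]][[s]], kids[[2]][[s]])
      expect_true(setequal(vals_parents, vals_kids))
    }
  }
  # identical parents are a fixed point
  kids <- ga_crossover(a, a)
  expect_identical(kids[[1]], a)
  expect_identical(kids[[2]], a)
})

test_that("mutation changes at most one slot at the configured rate", {
  space <- search_space()
  set.seed(8)
  ind <- ga_random_individual_for_tests(space, 3)
  slots <- c("n_rfe", "n_est", "max_depth", "min_split", "min_leaf",
             "n_f", "crit")
  hamming <- function(x, y) sum(vapply(slots, function(s) {
    !identical(x[[s]], y[[s]])
  }, numeric(1)))
  # P_mut = 0: no-op
  expect_identical(ga_mutate(ind, space, p_mut = 0), ind)
  # P_mut = 1: exactly one slot differs, and to a value inside the grid
  for (i in 1:100) {
    mut <- ga_mutate(ind, space, p_mut = 1)
    expect_equal(hamming(ind, mut), 1)
  }
  # empirical rate at P_mut = 0.9 over 1000 draws
  rate <- mean(vapply(1:1000, function(i) {
    hamming(ind, ga_mutate(ind, space, p_mut = 0.9)) > 0
  }, logical(1)))
  expect_gt(rate, 0.87)
  expect_lt(rate, 0.93)
})

test_that("one generation creates n_pop - 2*n_elite members, population
           stays at n_pop, and elites persist pristinely", {
  space <- search_space()
  cfg <- ga_config(n_pop = 100, n_elite = 2, n_gen = 1, seed = 5)
  set.seed(cfg$seed)
  pop <- replicate(cfg$n_pop, ga_random_individual_for_tests(space),
                   simplify = FALSE)
  fits <- vapply(pop, dummy_evaluator, numeric(1))
  cache <- new.env(parent = emptyenv())
  state <- list(population = pop, fitnesses = fits, cache = cache,
                space = space, generation = 0L)
  nxt <- ga_next_generation(state, dummy_evaluator, cfg)
  expect_equal(nxt$n_new, 96)
  expect_length(nxt$population, 100)
  # the pristine elite copies keep the best fitness from dropping
  expect_gte(max(nxt$fitnesses), max(fits))
  best <- pop[[which.max(fits)]]
  expect_true(any(vapply(nxt$population, identical, logical(1), best)))
})

test_that("run_ga is seed-deterministic and monotone in best fitness", {
  space <- search_space()
  cfg <- ga_config(n_pop = 20, n_gen = 5, seed = 31)
  r1 <- run_ga(NULL, space, cfg, evaluator = dummy_evaluator)
  r2 <- run_ga(NULL, space, cfg, evaluator = dummy_evaluator)
  expect_identical(r1$history, r2$history)
  expect_identical(r1$best, r2$best)
  expect_true(all(diff(r1$history$best) >= 0))
  expect_equal(nrow(r1$history), 6)  # initial population + 5 generations
  expect_gte(r1$n_evaluated, 20)

  r0 <- run_ga(NULL, space, ga_config(n_pop = 20, n_gen = 0, seed = 31),
               evaluator = dummy_evaluator)
  expect_equal(nrow(r0$history), 1)  # best of the initial population only
})

test_that("GA beats the bulk of random search on the same budget", {
  space <- search_space()
  cfg <- ga_config(n_pop = 20, n_gen = 10, seed = 77)
  ga <- run_ga(NULL, space, cfg, evaluator = dummy_evaluator)
  set.seed(78)
  random_draws <- vapply(1:500, function(i) {
    dummy_evaluator(ga_random_individual_for_tests(space))
  }, numeric(1))
  expect_gte(ga$best_fitness, quantile(random_draws, 0.99))
})
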