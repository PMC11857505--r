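#' Hyperparameter search space for the genetic algorithm
#'
#' Ordered value grids, one per [hyper_params()] field. The default grids
#' are a design choice of this package (the original grids behind the
#' reported ">6.7 million predefined possibilities" are not published):
#' they span 6,771,600 combinations and contain the reported optimum
#' (`n_rfe = 50`, `n_est = 100`, `max_depth = 6`, `min_split = 10`,
#' `min_leaf = 6`, `n_f = "log2"`, `crit = "log_loss"`).
#'
#' @param n_rfe,n_est,max_depth,min_split,min_leaf,n_f,crit value grids
#'   (non-empty vectors; `n_f` may mix `"log2"`, `"sqrt"` and counts).
#' @return list of class `search_space` of the seven grids, with an
#'   attribute `cardinality`.
#' @export
search_space <- function(n_rfe = seq(5L, 150L, by = 5L),
                         n_est = c(25L, 50L, 100L, 200L, 400L, 800L),
                         max_depth = 2:12,
                         min_split = 2:20,
                         min_leaf = 1:12,
                         n_f = list("log2", "sqrt", 3L, 5L, 10L),
                         crit = c("gini", "entropy", "log_loss")) {
  grids <- list(n_rfe = as.list(n_rfe), n_est = as.list(n_est),
                max_depth = as.list(max_depth),
                min_split = as.list(min_split),
                min_leaf = as.list(min_leaf),
                n_f = as.list(n_f), crit = as.list(crit))
  if (any(vapply(grids, length, integer(1)) == 0)) {
    stop("every grid must be non-empty")
  }
  structure(grids, class = "search_space",
            cardinality = prod(vapply(grids, length, integer(1))))
}

#' Genetic-algorithm configuration
#'
#' Defaults follow the published tuning protocol: a population of 100,
#' 2 parents per crossover exchanging 2 hyperparameters, 2 elites kept per
#' generation (one pristine and one mutable copy each), point mutation of
#' 1 hyperparameter with probability 0.90, and 35 generations.
#'
#' @param n_pop population size (default 100).
#' @param n_par parents per crossover (fixed at 2).
#' @param n_cross hyperparameters exchanged per crossover (default 2).
#' @param n_elite elites preserved per generation (default 2);
#'   `n_pop - 2 * n_elite` offspring are generated each generation.
#' @param n_mut hyperparameters mutated per mutation event (default 1).
#' @param p_mut mutation probability per individual (default 0.9).
#' @param n_gen number of generations (default 35).
#' @param seed integer seed.
#' @return list of class `ga_config`.
#' @export
ga_config <- function(n_pop = 100, n_par = 2, n_cross = 2, n_elite = 2,
                      n_mut = 1, p_mut = 0.9, n_gen = 35, seed = 1) {
  stopifnot(n_par == 2, n_mut == 1, p_mut >= 0, p_mut <= 1, n_gen >= 0)
  if (n_pop - 2 * n_elite <= 0) stop("n_pop must exceed 2 * n_elite")
  if ((n_pop - 2 * n_elite) %% 2 != 0) {
    stop("n_pop - 2 * n_elite must be even (offspring come in pairs)")
  }
  structure(list(n_pop = as.integer(n_pop), n_par = 2L,
                 n_cross = as.integer(n_cross),
                 n_elite = as.integer(n_elite), n_mut = 1L, p_mut = p_mut,
                 n_gen = as.integer(n_gen), seed = as.integer(seed)),
            class = "ga_config")
}

#' GA fitness of a hyperparameter set
#'
#' `Fitness = MCC^15 * N_RFE^2`, with negative MCC clamped to 0 so that
#' fitness stays non-negative and selection weights remain well defined.
#' The 15th power makes a perfect classifier (MCC 1.0) about five times
#' heavier than one with MCC 0.9 at equal retention
#' (`(1/0.9)^15 = 4.87`), while the quadratic term rewards retaining more
#' bins.
#'
#' @param mcc Matthews correlation coefficient in `[-1, 1]`.
#' @param n_rfe number of bins retained by RFE (>= 1).
#' @return the fitness value.
#' @examples
#' ga_fitness(1, 50)            # 2500
#' ga_fitness(1, 50) / ga_fitness(0.9, 50)  # ~4.87
#' @export
ga_fitness <- function(mcc, n_rfe) {
  stopifnot(mcc >= -1, mcc <= 1, n_rfe >= 1)
  max(mcc, 0)^15 * n_rfe^2
}

#' Fitness-proportional selection weights
#'
#' Normalizes non-negative fitness values into selection probabilities;
#' a population of all-zero fitness falls back to uniform weights.
#'
#' @param fitnesses numeric vector of non-negative fitness values.
#' @return probability vector summing to 1.
#' @export
selection_weights <- function(fitnesses) {
  if (any(fitnesses < 0)) stop("fitnesses must be non-negative")
  s <- sum(fitnesses)
  if (s == 0) rep(1 / length(fitnesses), length(fitnesses))
  else fitnesses / s
}

#' Two-point hyperparameter crossover
#'
#' Swaps the values of `n_cross` (default 2) distinct hyperparameter slots,
#' chosen uniformly without replacement among the seven, between two
#' parents, yielding two offspring.
#'
#' @param parent_a,parent_b [hyper_params()] objects.
#' @param n_cross number of slots to exchange.
#' @return list of two `hyper_params` offspring.
#' @export
ga_crossover <- function(parent_a, parent_b, n_cross = 2) {
  slots <- c("n_rfe", "n_est", "max_depth", "min_split", "min_leaf",
             "n_f", "crit")
  swap <- sample(slots, n_cross)
  a <- parent_a; b <- parent_b
  for (s in swap) {
    tmp <- a[[s]]; a[[s]] <- b[[s]]; b[[s]] <- tmp
  }
  list(a, b)
}

#' Point mutation of a hyperparameter set
#'
#' With probability `p_mut`, one slot chosen uniformly among those whose
#' grid offers an alternative is reassigned to a uniformly chosen
#' *different* grid value; otherwise the individual is returned unchanged.
#'
#' @param individual a [hyper_params()] within `space`.
#' @param space a [search_space()].
#' @param p_mut mutation probability.
#' @return the (possibly mutated) `hyper_params`.
#' @export
ga_mutate <- function(individual, space, p_mut = 0.9) {
  if (stats::runif(1) >= p_mut) return(individual)
  slots <- names(space)
  # only slots with at least one alternative value are mutable
  mutable <- slots[vapply(slots, function(s) {
    any(!vapply(space[[s]], identical, logical(1), individual[[s]]))
  }, logical(1))]
  if (!length(mutable)) return(individual)
  s <- if (length(mutable) == 1) mutable else sample(mutable, 1)
  alts <- space[[s]][!vapply(space[[s]], identical, logical(1),
                             individual[[s]])]
  individual[[s]] <- alts[[if (length(alts) == 1) 1 else
    sample.int(length(alts), 1)]]
  individual
}

# uniform draw from the search space
ga_random_individual <- function(space) {
  pick <- function(g) g[[if (length(g) == 1) 1 else sample.int(length(g), 1)]]
  hyper_params(n_rfe = pick(space$n_rfe), n_est = pick(space$n_est),
               max_depth = pick(space$max_depth),
               min_split = pick(space$min_split),
               min_leaf = pick(space$min_leaf),
               n_f = pick(space$n_f), crit = pick(space$crit))
}

# evaluate individuals against the cache; returns list(fitnesses, cache)
ga_evaluate <- function(population, evaluator, cache) {
  fitnesses <- numeric(length(population))
  for (i in seq_along(population)) {
    key <- hp_key(population[[i]])
    if (!is.null(cache[[key]])) {
      fitnesses[i] <- cache[[key]]
    } else {
      fit <- tryCatch(evaluator(population[[i]]), error = function(e) {
        warning("evaluator failed for ", key, ": ", conditionMessage(e))
        0
      })
      cache[[key]] <- fit
      fitnesses[i] <- fit
    }
  }
  list(fitnesses = fitnesses, cache = cache)
}

#' Advance the genetic algorithm by one generation
#'
#' From the current evaluated population: selection weights are the
#' normalized fitnesses; `n_pop - 2 * n_elite` offspring are produced by
#' repeatedly drawing 2 parents (with replacement) and crossing them over;
#' the offspring together with one copy of each elite then undergo point
#' mutation; finally a pristine (unmutated) copy of each elite is added,
#' restoring exactly `n_pop` members. The pristine elites make the
#' best-ever fitness non-decreasing.
#'
#' @param state list with `population` (list of [hyper_params()]),
#'   `fitnesses`, `cache`, `generation`.
#' @param evaluator function `hyper_params -> fitness`.
#' @param config a [ga_config()].
#' @return the next state (same shape), with `n_new` = offspring created.
#' @export
ga_next_generation <- function(state, evaluator, config) {
  n_off <- config$n_pop - 2L * config$n_elite
  w <- selection_weights(state$fitnesses)
  offspring <- vector("list", n_off)
  k <- 0L
  while (k < n_off) {
    par_idx <- sample.int(length(state$population), 2, replace = TRUE,
                          prob = w)
    kids <- ga_crossover(state$population[[par_idx[1]]],
                         state$population[[par_idx[2]]], config$n_cross)
    offspring[[k + 1L]] <- kids[[1]]
    offspring[[k + 2L]] <- kids[[2]]
    k <- k + 2L
  }
  elite_idx <- order(-state$fitnesses)[seq_len(config$n_elite)]
  elites <- state$population[elite_idx]
  mutable <- c(offspring, elites)
  mutable <- lapply(mutable, ga_mutate, space = state$space,
                    p_mut = config$p_mut)
  population <- c(mutable, elites)
  ev <- ga_evaluate(population, evaluator, state$cache)
  list(population = population, fitnesses = ev$fitnesses, cache = ev$cache,
       space = state$space, generation = state$generation + 1L,
       n_new = n_off)
}

#' Run the genetic algorithm
#'
#' Tunes the RFE + ensemble pipeline on a screened bin matrix: each
#' individual's `n_rfe` top-ranked bins (from a single cached SVM-RFE
#' elimination order) are classified by LOOCV with its six ensemble
#' hyperparameters, and the resulting MCC enters [ga_fitness()]. Starts
#' from a uniformly sampled population and runs `n_gen` generations.
#'
#' @param matrix a scaled [bin_matrix()] of the *non-perfect* bins (the
#'   stump-perfect bins are screened out upstream).
#' @param space a [search_space()].
#' @param config a [ga_config()]; its `seed` drives the whole trajectory.
#' @param evaluator optional replacement evaluator
#'   (`function(hyper_params) -> fitness`), e.g. for testing; by default
#'   the RFE + LOOCV evaluator described above, whose forest seed is
#'   derived from `config$seed`.
#' @param ranking optional precomputed [rfe_rank()] order for `matrix`,
#'   reused instead of recomputing the elimination.
#' @return list of class `ga_result`: `best` (`hyper_params`),
#'   `best_fitness`, `best_metrics` (LOOCV metrics of `best`, when the
#'   default evaluator is used), `history` (per-generation best/mean
#'   fitness), `n_evaluated` (unique sets evaluated), `final_population`.
#' @export
run_ga <- function(matrix, space = search_space(), config = ga_config(),
                   evaluator = NULL, ranking = NULL) {
  stopifnot(inherits(space, "search_space"), inherits(config, "ga_config"))
  set.seed(config$seed)
  if (is.null(evaluator)) {
    validate_bin_matrix(matrix)
    if (is.null(ranking)) ranking <- rfe_rank(matrix)
    evaluator <- function(hp) {
      keep <- rfe_select(matrix, min(hp$n_rfe, length(ranking)), ranking)
      m <- rf_loocv(subset_bins(matrix, keep), hp, seed = config$seed)
      ga_fitness(m$mcc, length(keep))
    }
  }
  population <- replicate(config$n_pop, ga_random_individual(space),
                          simplify = FALSE)
  ev <- ga_evaluate(population, evaluator, new.env(parent = emptyenv()))
  state <- list(population = population, fitnesses = ev$fitnesses,
                cache = ev$cache, space = space, generation = 0L)
  history <- data.frame(generation = 0L, best = max(state$fitnesses),
                        mean = mean(state$fitnesses))
  best_i <- which.max(state$fitnesses)
  best <- state$population[[best_i]]
  best_fitness <- state$fitnesses[best_i]
  for (g in seq_len(config$n_gen)) {
    state <- ga_next_generation(state, evaluator, config)
    gi <- which.max(state$fitnesses)
    if (state$fitnesses[gi] > best_fitness) {
      best <- state$population[[gi]]
      best_fitness <- state$fitnesses[gi]
    }
    history <- rbind(history,
                     data.frame(generation = g, best = best_fitness,
                                mean = mean(state$fitnesses)))
  }
  best_metrics <- NULL
  if (!is.null(ranking) && inherits(matrix, "bin_matrix")) {
    keep <- rfe_select(matrix, min(best$n_rfe, length(ranking)), ranking)
    best_metrics <- rf_loocv(subset_bins(matrix, keep), best,
                             seed = config$seed)
    best_metrics$retained_bins <- keep
  }
  structure(list(best = best, best_fitness = best_fitness,
                 best_metrics = best_metrics, history = history,
                 n_evaluated = length(ls(state$cache)),
                 final_population = state$population),
            class = "ga_result")
}
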