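#' Configure the genetic algorithm
#'
#' A seeded binary-genome GA shared by both fine-alignment stages: each of
#' the `n_params` motor positions is Gray-encoded on `bits_per_param` bits
#' over its `bounds`, giving the classic 48-gene individual for two motors
#' at 24 bits each. Selection is tournament (k = 2), crossover single-point,
#' mutation per-bit flip, with elitism and an optional early stop. Fitness
#' is minimised, and every evaluation at an already-visited position is
#' served from the evaluation cache instead of calling the fitness function
#' again.
#'
#' @param bounds list of `c(low, high)` per parameter (low <= high; equal
#'   bounds pin the parameter, e.g. a zero search window).
#' @param pop_size population size (>= 2); the two standard accuracy modes
#'   use 20 and 30.
#' @param n_generations number of generations (default 15).
#' @param bits_per_param bits per Gray-encoded parameter (default 24).
#' @param crossover_rate probability of single-point crossover per pair.
#' @param mutation_rate per-bit flip probability; default `1 / genome
#'   length`.
#' @param elitism number of best individuals copied unchanged (>= 1).
#' @param rng_seed integer seed; identical configs and fitness functions
#'   reproduce identical runs.
#' @param early_stop_tol,early_stop_patience stop when the best fitness has
#'   improved by less than `early_stop_tol` for `early_stop_patience`
#'   consecutive generations (`Inf` patience disables).
#' @param cache serve repeated genotypes from the evaluation cache.
#' @return A list of class `ga_config`.
#' @export
ga_config <- function(bounds, pop_size = 20L, n_generations = 15L,
                      bits_per_param = 24L, crossover_rate = 0.9,
                      mutation_rate = NULL, elitism = 1L, rng_seed = 1L,
                      early_stop_tol = 0, early_stop_patience = Inf,
                      cache = TRUE) {
  if (!is.list(bounds) || length(bounds) < 1L)
    stop_bad("`bounds` must be a list of c(low, high) pairs", "ga_error")
  for (b in bounds) {
    if (length(b) != 2L || !all(is.finite(b)) || b[1] > b[2])
      stop_bad("each bound must be a finite c(low, high) with low <= high",
               "ga_error")
  }
  pop_size <- as.integer(pop_size)
  if (pop_size < 2L) stop_bad("`pop_size` must be >= 2", "ga_error")
  if (bits_per_param < 1L) stop_bad("`bits_per_param` must be >= 1", "ga_error")
  if (crossover_rate < 0 || crossover_rate > 1)
    stop_bad("`crossover_rate` must be in [0, 1]", "ga_error")
  L <- length(bounds) * as.integer(bits_per_param)
  if (is.null(mutation_rate)) mutation_rate <- 1 / L
  if (mutation_rate < 0 || mutation_rate > 1)
    stop_bad("`mutation_rate` must be in [0, 1]", "ga_error")
  if (elitism < 1L || elitism > pop_size)
    stop_bad("`elitism` must be between 1 and pop_size", "ga_error")
  structure(list(bounds = bounds, pop_size = pop_size,
                 n_generations = as.integer(n_generations),
                 bits_per_param = as.integer(bits_per_param),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 elitism = as.integer(elitism),
                 rng_seed = as.integer(rng_seed),
                 early_stop_tol = early_stop_tol,
                 early_stop_patience = early_stop_patience,
                 cache = isTRUE(cache)),
            class = "ga_config")
}

# genome (0/1 integer vector) -> per-parameter Gray integers
genome_ints <- function(genome, n_params, bits) {
  m <- matrix(genome, nrow = bits)
  # Gray -> binary: cumulative xor down the bit slice (MSB first)
  bin <- apply(m, 2, function(g) cumsum(g) %% 2)
  pow <- 2^((bits - 1):0)
  as.numeric(colSums(bin * pow))
}

#' Decode a GA genome into motor positions
#'
#' Each parameter's bit slice is Gray-decoded to an integer `k` and mapped
#' affinely onto its bounds: `low + k / (2^bits - 1) * (high - low)`.
#'
#' @param genome integer (0/1) vector of length
#'   `bits_per_param * length(bounds)`.
#' @param bounds list of `c(low, high)` per parameter.
#' @param bits_per_param bits per parameter.
#' @return Numeric vector of decoded parameter values (within bounds).
#' @export
ga_decode <- function(genome, bounds, bits_per_param) {
  n_params <- length(bounds)
  if (length(genome) != n_params * bits_per_param)
    stop_bad("genome length must equal bits_per_param * n_params", "ga_error")
  ints <- genome_ints(genome, n_params, bits_per_param)
  lo <- vapply(bounds, `[`, numeric(1), 1)
  hi <- vapply(bounds, `[`, numeric(1), 2)
  denom <- 2^bits_per_param - 1
  unname(lo + ints / denom * (hi - lo))
}

#' Encode motor positions into a GA genome
#'
#' Inverse of [ga_decode()] up to the encoding resolution:
#' `ga_decode(ga_encode(ga_decode(g)))` equals `ga_decode(g)` exactly.
#'
#' @param values numeric vector of parameter values (clamped to bounds).
#' @inheritParams ga_decode
#' @return Integer (0/1) genome vector.
#' @export
ga_encode <- function(values, bounds, bits_per_param) {
  n_params <- length(bounds)
  stopifnot(length(values) == n_params)
  lo <- vapply(bounds, `[`, numeric(1), 1)
  hi <- vapply(bounds, `[`, numeric(1), 2)
  denom <- 2^bits_per_param - 1
  frac <- ifelse(hi > lo, (pmin(pmax(values, lo), hi) - lo) / (hi - lo), 0)
  ints <- round(frac * denom)
  genome <- integer(0)
  for (k in ints) {
    bin <- as.integer(intToBits(k))[bits_per_param:1]
    if (bits_per_param > 31)
      bin <- c(integer(bits_per_param - 31),
               as.integer(intToBits(k))[31:1])[seq_len(bits_per_param)]
    gray <- bin
    if (bits_per_param > 1)
      gray[2:bits_per_param] <- (bin[2:bits_per_param] +
                                 bin[1:(bits_per_param - 1)]) %% 2
    genome <- c(genome, gray)
  }
  genome
}

cache_key <- function(genome, n_params, bits) {
  paste(genome_ints(genome, n_params, bits), collapse = "_")
}

#' Run the genetic algorithm
#'
#' Minimises `fitness_fn` over the bounded box defined by the config.
#' The initial population is uniform over the bounds (seeded); each
#' generation applies tournament selection (k = 2), single-point crossover,
#' per-bit mutation and elitism. Every fitness call at an already-evaluated
#' position is served from the evaluation cache, so the number of true
#' evaluations never exceeds `pop_size * (n_generations + 1)` and drops
#' further whenever genotypes repeat.
#'
#' @param fitness_fn function taking the decoded parameter vector and
#'   returning a finite, non-negative scalar fitness (lower is better).
#' @param config a [ga_config()].
#' @param initial optional list of parameter vectors seeded into the
#'   initial population (e.g. the incumbent motor position, so the search
#'   can never end worse than it started); the remainder is drawn
#'   uniformly.
#' @return A list of class `ga_result`: `best` (genome, decoded values,
#'   fitness), `history` (per-generation tibble with best/mean fitness and
#'   cumulative evaluation/cache counts), `n_evaluations`, `cache_hits`.
#' @export
ga_evolve <- function(fitness_fn, config, initial = NULL) {
  stopifnot(inherits(config, "ga_config"), is.function(fitness_fn))
  n_params <- length(config$bounds)
  bits <- config$bits_per_param
  L <- n_params * bits
  cache <- new.env(parent = emptyenv())
  n_eval <- 0L
  n_hits <- 0L
  evaluate <- function(genome) {
    key <- cache_key(genome, n_params, bits)
    if (config$cache && !is.null(cache[[key]])) {
      n_hits <<- n_hits + 1L
      return(cache[[key]])
    }
    f <- fitness_fn(ga_decode(genome, config$bounds, bits))
    n_eval <<- n_eval + 1L
    if (config$cache) cache[[key]] <- f
    f
  }
  withr::with_seed(config$rng_seed, {
    pop <- lapply(seq_len(config$pop_size), function(i)
      as.integer(runif(L) < 0.5))
    if (!is.null(initial)) {
      n_seed <- min(length(initial), config$pop_size)
      for (i in seq_len(n_seed))
        pop[[i]] <- ga_encode(initial[[i]], config$bounds, bits)
    }
    fit <- vapply(pop, evaluate, numeric(1))
    history <- vector("list", config$n_generations + 1L)
    history[[1]] <- tibble(generation = 0L, best_fitness = min(fit),
                           mean_fitness = mean(fit),
                           evaluations = n_eval, cache_hits = n_hits)
    best_prev <- min(fit)
    stall <- 0L
    gen_done <- 0L
    for (gen in seq_len(config$n_generations)) {
      ord <- order(fit)
      elite <- pop[ord[seq_len(config$elitism)]]
      n_child <- config$pop_size - config$elitism
      children <- vector("list", n_child)
      i <- 1L
      while (i <= n_child) {
        p1 <- tournament(pop, fit, 2L)
        p2 <- tournament(pop, fit, 2L)
        if (runif(1) < config$crossover_rate && L > 1L) {
          cut <- sample.int(L - 1L, 1L)
          c1 <- c(p1[seq_len(cut)], p2[(cut + 1L):L])
          c2 <- c(p2[seq_len(cut)], p1[(cut + 1L):L])
        } else {
          c1 <- p1; c2 <- p2
        }
        children[[i]] <- mutate_genome(c1, config$mutation_rate)
        i <- i + 1L
        if (i <= n_child) {
          children[[i]] <- mutate_genome(c2, config$mutation_rate)
          i <- i + 1L
        }
      }
      pop <- c(elite, children)
      fit <- vapply(pop, evaluate, numeric(1))
      gen_done <- gen
      history[[gen + 1L]] <- tibble(generation = gen,
                                    best_fitness = min(fit),
                                    mean_fitness = mean(fit),
                                    evaluations = n_eval,
                                    cache_hits = n_hits)
      if (best_prev - min(fit) < config$early_stop_tol) {
        stall <- stall + 1L
      } else {
        stall <- 0L
      }
      best_prev <- min(min(fit), best_prev)
      if (stall >= config$early_stop_patience) break
    }
  })
  history <- dplyr::bind_rows(history[seq_len(gen_done + 1L)])
  k <- which.min(fit)
  structure(list(
    best = list(genome = pop[[k]],
                values = ga_decode(pop[[k]], config$bounds, bits),
                fitness = fit[k]),
    history = history,
    n_evaluations = n_eval,
    cache_hits = n_hits,
    config = config), class = "ga_result")
}

tournament <- function(pop, fit, k) {
  idx <- sample.int(length(pop), k, replace = TRUE)
  pop[[idx[which.min(fit[idx])]]]
}

mutate_genome <- function(genome, rate) {
  flip <- runif(length(genome)) < rate
  genome[flip] <- 1L - genome[flip]
  genome
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf("<ga_result> best fitness %.6g at (%s) after %d evaluations (%d cache hits)\n",
              x$best$fitness, paste(signif(x$best$values, 6), collapse = ", "),
              x$n_evaluations, x$cache_hits))
  invisible(x)
}

#' @export
tidy.ga_result <- function(x, ...) x$history

#' @export
glance.ga_result <- function(x, ...) {
  tibble(best_fitness = x$best$fitness,
         n_generations = max(x$history$generation),
         n_evaluations = x$n_evaluations,
         cache_hits = x$cache_hits)
}

#' @export
autoplot.ga_result <- function(object, ...) {
  ggplot2::ggplot(object$history,
                  ggplot2::aes(x = .data$generation)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$best_fitness,
                                    colour = "best")) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean_fitness,
                                    colour = "mean")) +
    ggplot2::labs(x = "generation", y = "fitness", colour = NULL) +
    ggplot2::theme_minimal()
}
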