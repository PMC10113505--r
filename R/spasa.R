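# Sparrow Search Algorithm (SpaSA) over the unit hypercube [0,1]^D.
#
# The population splits by fitness rank into discoverers (producers, top PD),
# followers (the rest), and a random scout subset (SD).  One update round
# applies, in order, the discoverer, follower, and scout position rules, each
# followed by a hard clamp back into [0,1].
#
# RNG draw-order contract (mirrored by the test-suite oracle):
#   discoverers: R2 once per call; then per solution either alpha ~ U(0,1)
#                (R2 < ST branch) or Q ~ N(0,1)^D (alarm branch)
#   followers:   per solution, rank > N/2: Q ~ N(0,1)^D;
#                otherwise A ~ {-1,+1}^D (sample of size D)
#   scouts:      scout indices via sample(N, SD); then per scout either
#                beta ~ N(0,1) (score != best) or K ~ U(-1,1)

#' SpaSA optimizer settings
#'
#' @param population_size number of sparrows N (>= 2).
#' @param max_iterations number of update rounds T.
#' @param producer_ratio fraction of the (sorted) population acting as
#'   discoverers; the count is \code{max(1, round(ratio * N))}.
#' @param scout_ratio fraction acting as scouts each round, sampled without
#'   replacement.
#' @param safety_threshold alarm threshold ST in \[0.5, 1\]: while the alarm
#'   value R2 (one uniform draw per round) stays below ST, discoverers search
#'   by exponential shrink; otherwise the flock relocates by a normal step.
#' @param epsilon small positive constant guarding the scout division.
#' @param seed optional integer seed for the whole run.
#' @param maximize logical; \code{TRUE} when fitness is an accuracy-like score.
#' @return a \code{spasa_config} object.
#' @export
spasa_config <- function(population_size = 10, max_iterations = 10,
                         producer_ratio = 0.2, scout_ratio = 0.2,
                         safety_threshold = 0.8, epsilon = 1e-50,
                         seed = NULL, maximize = TRUE) {
  assert_number(population_size, "population_size", lo = 2, integer = TRUE)
  assert_number(max_iterations, "max_iterations", lo = 1, integer = TRUE)
  assert_number(producer_ratio, "producer_ratio", lo = 1e-9, hi = 1)
  assert_number(scout_ratio, "scout_ratio", lo = 1e-9, hi = 1)
  if (producer_ratio + scout_ratio > 1 + 1e-12) {
    stop_invalid("producer_ratio + scout_ratio must be <= 1")
  }
  assert_number(safety_threshold, "safety_threshold", lo = 0.5, hi = 1)
  assert_number(epsilon, "epsilon", lo = .Machine$double.xmin)
  if (!is.null(seed)) assert_number(seed, "seed", integer = TRUE)
  structure(
    list(population_size = as.integer(population_size),
         max_iterations = as.integer(max_iterations),
         producer_ratio = producer_ratio, scout_ratio = scout_ratio,
         safety_threshold = safety_threshold, epsilon = epsilon,
         seed = if (is.null(seed)) NULL else as.integer(seed),
         maximize = isTRUE(maximize)),
    class = "spasa_config"
  )
}

n_producers <- function(config) {
  max(1L, as.integer(round(config$producer_ratio * config$population_size)))
}

n_scouts <- function(config) {
  max(1L, as.integer(round(config$scout_ratio * config$population_size)))
}

#' Initialize a SpaSA population
#'
#' Every element of every solution is drawn uniformly from \[0,1\].
#'
#' @param config a [spasa_config()].
#' @param dimension search dimension D (>= 1).
#' @return a \code{spasa_population}: list with \code{solutions}
#'   (N x D matrix), \code{scores} (NULL until evaluated), \code{sorted}.
#' @export
initialize_population <- function(config, dimension) {
  stopifnot(inherits(config, "spasa_config"))
  assert_number(dimension, "dimension", lo = 1, integer = TRUE)
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$population_size
  sol <- matrix(stats::runif(n * dimension), nrow = n, ncol = dimension)
  new_population(sol)
}

new_population <- function(solutions, scores = NULL, sorted = FALSE) {
  structure(list(solutions = solutions, scores = scores, sorted = sorted),
            class = "spasa_population")
}

#' Attach fitness scores to a population
#'
#' @param pop a \code{spasa_population}.
#' @param scores numeric vector parallel to the solutions.
#' @export
set_scores <- function(pop, scores) {
  stopifnot(inherits(pop, "spasa_population"))
  if (length(scores) != nrow(pop$solutions) || anyNA(scores)) {
    stop_invalid("scores must be a complete vector parallel to the solutions")
  }
  new_population(pop$solutions, as.numeric(scores), sorted = FALSE)
}

#' Sort a population by fitness and extract the extremes
#'
#' Solutions are reordered so scores are non-increasing in
#' optimization-preference order (descending for maximization, ascending for
#' minimization); ties keep their original relative order (stable sort).  The
#' best solution is row 1, the worst the last row.
#'
#' @param pop an evaluated \code{spasa_population}.
#' @param maximize logical.
#' @return the sorted population, with \code{best}, \code{worst},
#'   \code{best_score}, \code{worst_score} fields filled in.
#' @export
sort_population <- function(pop, maximize = TRUE) {
  stopifnot(inherits(pop, "spasa_population"))
  if (is.null(pop$scores)) {
    stop("population has no scores; evaluate before sorting", call. = FALSE)
  }
  ord <- order(if (maximize) -pop$scores else pop$scores)
  out <- new_population(pop$solutions[ord, , drop = FALSE], pop$scores[ord],
                        sorted = TRUE)
  out$best <- out$solutions[1, ]
  out$worst <- out$solutions[nrow(out$solutions), ]
  out$best_score <- out$scores[1]
  out$worst_score <- out$scores[length(out$scores)]
  out
}

require_sorted <- function(pop) {
  if (!isTRUE(pop$sorted)) {
    stop("population must be sorted (see sort_population())", call. = FALSE)
  }
  invisible(pop)
}

#' Discoverer (producer) position update
#'
#' The top-ranked PD solutions lead the search.  One alarm value R2 is drawn
#' per call; while \code{R2 < ST} each discoverer shrinks multiplicatively by
#' \code{exp(-t / (alpha * T))} with its own uniform \code{alpha}; otherwise
#' each takes an additive standard-normal step per coordinate.  Results are
#' clamped to \[0,1\].
#'
#' @param pop a sorted, evaluated population.
#' @param config a [spasa_config()].
#' @param t current iteration (1..T).
#' @return the updated population (still marked sorted; scores are the
#'   pre-update snapshot, as the update round uses a fixed ranking).
#' @export
update_discoverers <- function(pop, config, t) {
  require_sorted(pop)
  assert_number(t, "t", lo = 1, hi = config$max_iterations, integer = TRUE)
  sol <- pop$solutions
  pd <- n_producers(config)
  r2 <- stats::runif(1)
  for (i in seq_len(pd)) {
    if (r2 < config$safety_threshold) {
      alpha <- stats::runif(1)
      sol[i, ] <- sol[i, ] * exp(-t / (alpha * config$max_iterations))
    } else {
      q <- stats::rnorm(ncol(sol))
      sol[i, ] <- sol[i, ] + q
    }
    sol[i, ] <- clamp01(sol[i, ])
  }
  pop$solutions <- sol
  pop
}

#' Follower (scrounger) position update
#'
#' The non-producer solutions track the best producer position X_P (row 1
#' after sorting).  A follower whose rank exceeds N/2 (the hungriest) jumps to
#' \code{Q * exp((X_worst - X) / rank^2)} per coordinate; the rest move to
#' \code{X_P + (|X - X_P| . A+) L} with a fresh Rademacher vector A per
#' solution and \code{A+ = t(A) / D}, so the correction is the scalar
#' projection \code{sum(|X - X_P| * A) / D} added to every coordinate.
#' Clamped to \[0,1\].
#'
#' @inheritParams update_discoverers
#' @export
update_followers <- function(pop, config) {
  require_sorted(pop)
  sol <- pop$solutions
  n <- nrow(sol)
  d <- ncol(sol)
  pd <- n_producers(config)
  optimal <- pop$best      # best producer position (rank 1)
  worst <- pop$worst
  for (rank in seq(pd + 1L, length.out = n - pd)) {
    if (rank > n / 2) {
      q <- stats::rnorm(d)
      sol[rank, ] <- q * exp((worst - sol[rank, ]) / rank^2)
    } else {
      a <- sample(c(-1, 1), d, replace = TRUE)
      step <- sum(abs(sol[rank, ] - optimal) * a) / d
      sol[rank, ] <- optimal + step
    }
    sol[rank, ] <- clamp01(sol[rank, ])
  }
  pop$solutions <- sol
  pop
}

#' Scout (anti-predation) position update
#'
#' SD solutions chosen uniformly without replacement react to danger: one not
#' currently at the best score moves toward the best position with a
#' normal step size \code{beta}; one already at the best score takes a step
#' \code{K * |X - X_worst| / ((f_i - f_w) + epsilon)} away, with
#' \code{K ~ U(-1,1)}.  Clamped to \[0,1\].
#'
#' @inheritParams update_discoverers
#' @export
update_scouts <- function(pop, config) {
  require_sorted(pop)
  sol <- pop$solutions
  n <- nrow(sol)
  sd_n <- min(n, n_scouts(config))
  idx <- sample(n, sd_n)
  for (i in idx) {
    if (pop$scores[i] != pop$best_score) {
      beta <- stats::rnorm(1)
      sol[i, ] <- pop$best + beta * abs(sol[i, ] - pop$best)
    } else {
      k <- stats::runif(1, -1, 1)
      sol[i, ] <- sol[i, ] +
        k * (abs(sol[i, ] - pop$worst) /
               ((pop$scores[i] - pop$worst_score) + config$epsilon))
    }
    sol[i, ] <- clamp01(sol[i, ])
  }
  pop$solutions <- sol
  pop
}

#' Run the full SpaSA optimization loop
#'
#' Initializes the population, then for T rounds evaluates every solution,
#' sorts, and applies the discoverer/follower/scout updates.  The best-ever
#' solution and score are tracked across rounds, so the reported history is
#' monotone non-decreasing (for maximization).
#'
#' @param fitness function mapping a numeric vector in \[0,1\]^D to a single
#'   finite score.
#' @param config a [spasa_config()].
#' @param dimension search dimension D.
#' @param checkpoint_path optional JSON file updated after every iteration
#'   (population, scores, RNG state, best-ever), enabling [spasa_resume()].
#' @param on_evaluate optional callback \code{function(iteration, index,
#'   solution, score)} invoked after each fitness evaluation.
#' @return a \code{spasa_result}: list with \code{best_solution},
#'   \code{best_score}, \code{history} (best-ever per iteration),
#'   \code{evaluations} (N * T), \code{config}.
#' @examples
#' cfg <- spasa_config(population_size = 6, max_iterations = 5, seed = 1)
#' res <- spasa_optimize(function(x) -sum((x - 0.5)^2), cfg, dimension = 3)
#' res$best_score
#' @export
spasa_optimize <- function(fitness, config, dimension,
                           checkpoint_path = NULL, on_evaluate = NULL) {
  stopifnot(inherits(config, "spasa_config"), is.function(fitness))
  pop <- initialize_population(config, dimension)
  spasa_loop(fitness, config, pop, t_start = 1L,
             best_solution = NULL, best_score = NULL, history = numeric(0),
             checkpoint_path = checkpoint_path, on_evaluate = on_evaluate)
}

spasa_loop <- function(fitness, config, pop, t_start, best_solution,
                       best_score, history, checkpoint_path, on_evaluate) {
  n <- config$population_size
  better <- if (config$maximize) `>` else `<`
  for (t in seq(t_start, length.out = config$max_iterations - t_start + 1L)) {
    scores <- numeric(n)
    for (i in seq_len(n)) {
      scores[i] <- tryCatch(fitness(pop$solutions[i, ]), error = function(e) {
        stop("fitness evaluation failed at iteration ", t, ", solution ", i,
             ": ", conditionMessage(e), call. = FALSE)
      })
      if (!is.numeric(scores[i]) || length(scores[i]) != 1L ||
          !is.finite(scores[i])) {
        stop("fitness returned a non-finite value at iteration ", t,
             ", solution ", i, call. = FALSE)
      }
      if (!is.null(on_evaluate)) {
        on_evaluate(t, i, pop$solutions[i, ], scores[i])
      }
    }
    pop <- sort_population(set_scores(pop, scores), config$maximize)
    if (is.null(best_score) || better(pop$best_score, best_score)) {
      best_score <- pop$best_score
      best_solution <- pop$best
    }
    history <- c(history, best_score)
    pop <- update_discoverers(pop, config, t)
    pop <- update_followers(pop, config)
    pop <- update_scouts(pop, config)
    if (!is.null(checkpoint_path)) {
      write_spasa_checkpoint(checkpoint_path, config, pop, t, best_solution,
                             best_score, history)
    }
  }
  structure(
    list(best_solution = best_solution, best_score = best_score,
         history = history,
         evaluations = n * config$max_iterations, config = config),
    class = "spasa_result"
  )
}

write_spasa_checkpoint <- function(path, config, pop, t, best_solution,
                                   best_score, history) {
  state <- list(
    iteration = t,
    solutions = unclass(as.data.frame(pop$solutions)),
    scores = pop$scores,
    best_solution = best_solution,
    best_score = best_score,
    history = history,
    rng_state = get(".Random.seed", envir = globalenv()),
    config = config[c("population_size", "max_iterations", "producer_ratio",
                      "scout_ratio", "safety_threshold", "epsilon",
                      "maximize")]
  )
  jsonlite::write_json(state, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Resume a SpaSA run from a JSON checkpoint
#'
#' Restores the population, best-ever tracking, and the RNG stream saved by
#' [spasa_optimize()] with \code{checkpoint_path}, then continues the loop.
#' With the same fitness function, the final result is identical to the
#' uninterrupted run.
#'
#' @param checkpoint_path path written by a previous run.
#' @param fitness the same fitness function.
#' @param config the same [spasa_config()].
#' @return a \code{spasa_result}.
#' @export
spasa_resume <- function(checkpoint_path, fitness, config) {
  state <- jsonlite::read_json(checkpoint_path, simplifyVector = TRUE)
  sol <- as.matrix(as.data.frame(state$solutions))
  dimnames(sol) <- NULL
  # Positions were already updated after the checkpointed iteration; the next
  # loop step re-evaluates and sorts them.
  pop <- new_population(sol, state$scores, sorted = FALSE)
  assign(".Random.seed", as.integer(state$rng_state), envir = globalenv())
  if (state$iteration >= config$max_iterations) {
    return(structure(
      list(best_solution = state$best_solution, best_score = state$best_score,
           history = state$history,
           evaluations = config$population_size * config$max_iterations,
           config = config),
      class = "spasa_result"
    ))
  }
  spasa_loop(fitness, config, pop, t_start = state$iteration + 1L,
             best_solution = state$best_solution,
             best_score = state$best_score, history = state$history,
             checkpoint_path = NULL, on_evaluate = NULL)
}

#' @export
print.spasa_result <- function(x, ...) {
  cat("<spasa_result> best score:", format(x$best_score, digits = 6),
      "after", x$evaluations, "evaluations\n")
  invisible(x)
}
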