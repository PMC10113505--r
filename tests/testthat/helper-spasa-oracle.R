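# Independent, literal transcription of the sparrow-search update round
# (sort, then discoverer / follower / scout loops), written directly from
# the published pseudocode as straight-line code.  It shares only the RNG
# draw-order contract with the package implementation; all arithmetic is
# re-derived here and must stay independent of the package internals.
oracle_update_round <- function(solutions, scores, config, t) {
  ord <- order(if (config$maximize) -scores else scores)
  solutions <- solutions[ord, , drop = FALSE]
  scores <- scores[ord]
  n <- nrow(solutions)
  D <- ncol(solutions)
  best <- solutions[1, ]
  worst <- solutions[n, ]
  optimal <- solutions[1, ]          # best producer position
  bestScore <- scores[1]
  worstScore <- scores[n]
  PD <- max(1, round(config$producer_ratio * n))
  SD <- max(1, round(config$scout_ratio * n))
  ST <- config$safety_threshold
  Tmax <- config$max_iterations
  L <- rep(1, D)

  # discoverers
  R2 <- runif(1)
  i <- 1
  while (i <= PD) {
    if (R2 < ST) {
      alpha <- runif(1)
      solutions[i, ] <- solutions[i, ] * exp(-t / (alpha * Tmax))
    } else {
      Q <- rnorm(D)
      solutions[i, ] <- solutions[i, ] + Q * L
    }
    solutions[i, ] <- pmin(pmax(solutions[i, ], 0), 1)
    i <- i + 1
  }

  # followers
  i <- 1
  while (i <= n - PD) {
    r <- PD + i
    if (r > 0.5 * n) {
      Q <- rnorm(D)
      solutions[r, ] <- Q * exp((worst - solutions[r, ]) / r^2)
    } else {
      A <- sample(c(-1, 1), D, replace = TRUE)
      Aplus <- A / sum(A * A)        # t(A) (A A^T)^-1, A A^T = D
      solutions[r, ] <- optimal +
        sum(abs(solutions[r, ] - optimal) * Aplus) * L
    }
    solutions[r, ] <- pmin(pmax(solutions[r, ], 0), 1)
    i <- i + 1
  }

  # scouts
  idx <- sample(n, min(n, SD))
  for (i in idx) {
    if (scores[i] != bestScore) {
      beta <- rnorm(1)
      solutions[i, ] <- best + beta * abs(solutions[i, ] - best)
    } else {
      K <- runif(1, -1, 1)
      solutions[i, ] <- solutions[i, ] +
        K * (abs(solutions[i, ] - worst) /
               ((scores[i] - worstScore) + config$epsilon))
    }
    solutions[i, ] <- pmin(pmax(solutions[i, ], 0), 1)
  }
  solutions
}

# Package-path equivalent of one full update round.
package_update_round <- function(solutions, scores, config, t) {
  pop <- set_scores(
    structure(list(solutions = solutions, scores = NULL, sorted = FALSE),
              class = "spasa_population"),
    scores
  )
  pop <- sort_population(pop, config$maximize)
  pop <- update_discoverers(pop, config, t)
  pop <- update_followers(pop, config)
  pop <- update_scouts(pop, config)
  pop$solutions
}
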