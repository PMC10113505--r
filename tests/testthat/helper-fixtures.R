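# Shared test fixtures, built in code.

# A tiny image set with unique constant-valued images, so partitions can be
# compared as sets of intensity signatures.
constant_image_set <- function(counts, size = 8) {
  classes <- names(counts) %||% paste0("c", seq_along(counts))
  images <- list()
  labels <- character(0)
  v <- 0
  for (k in seq_along(counts)) {
    for (j in seq_len(counts[[k]])) {
      v <- v + 1
      images <- c(images, list(array(v, c(size, size, 3))))
      labels <- c(labels, classes[k])
    }
  }
  image_set(images, labels, class_names = classes)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

image_signature <- function(img) img[1, 1, 1]

# Linearly separable two-class blobs: class "left" is bright on the left
# half, class "right" on the right half, plus mild noise.
blob_image_set <- function(n_per_class = 12, size = 16, seed = 42,
                           noise_sd = 5) {
  set.seed(seed)
  images <- list()
  labels <- character(0)
  for (cl in c("left", "right")) {
    for (j in seq_len(n_per_class)) {
      img <- array(stats::rnorm(size * size * 3, 60, noise_sd),
                   c(size, size, 3))
      cols <- if (cl == "left") 1:(size / 2) else (size / 2 + 1):size
      img[, cols, ] <- img[, cols, ] + 120
      images <- c(images, list(pmin(pmax(img, 0), 255)))
      labels <- c(labels, cl)
    }
  }
  image_set(images, labels, class_names = c("left", "right"))
}

# Nearest-centroid classification accuracy (the separability oracle).
# Centroids are fit on the odd-indexed members of each class and evaluated
# on the even-indexed ones, so a signal-free set scores at chance level
# instead of benefiting from self-inclusion.
centroid_accuracy <- function(set) {
  flat <- t(vapply(set$images, as.numeric,
                   numeric(length(set$images[[1]]))))
  fit_idx <- eval_idx <- integer(0)
  for (cl in set$class_names) {
    members <- which(set$labels == cl)
    fit_idx <- c(fit_idx, members[seq_along(members) %% 2 == 1])
    eval_idx <- c(eval_idx, members[seq_along(members) %% 2 == 0])
  }
  centroids <- lapply(set$class_names, function(cl) {
    rows <- intersect(fit_idx, which(set$labels == cl))
    colMeans(flat[rows, , drop = FALSE])
  })
  pred <- vapply(eval_idx, function(i) {
    d <- vapply(centroids, function(ce) sum((flat[i, ] - ce)^2), numeric(1))
    set$class_names[which.min(d)]
  }, character(1))
  mean(pred == set$labels[eval_idx])
}

# Equal-budget uniform random search over [0,1]^D.
random_search <- function(fitness, n_evals, dimension, maximize = TRUE) {
  best <- NULL
  for (i in seq_len(n_evals)) {
    x <- runif(dimension)
    s <- fitness(x)
    if (is.null(best) || (maximize && s > best) || (!maximize && s < best)) {
      best <- s
    }
  }
  best
}
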