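# Fitness engine: build a classifier from a training_config, train it a few
# epochs, and score it.  No deep-learning framework exists in this
# environment, so the network is written in base R: a small convolutional
# backbone (three 3x3 conv blocks with ReLU and 2x2 mean pooling, global
# average pooling), a dropout layer, and a softmax head.  Convolutions run
# as im2col matrix products; gradients are analytic.
#
# The eight named pretrained backbones are accepted as pluggable names but
# construct the same surrogate architecture with deterministic SYNTHETIC
# "pretrained" weights (true ImageNet weights are not obtainable offline);
# "surrogate-tiny" is the tested reference.

SPASATUNE_BACKBONES <- c(
  "surrogate-tiny", "VGG16", "VGG19", "Xception", "DenseNet201", "MobileNet",
  "MobileNetV2", "MobileNetV3Large", "NASNetMobile"
)

#' Backbone specification
#'
#' @param name one of the supported backbone names (see
#'   \code{SPASATUNE_BACKBONES}).  Only \code{"surrogate-tiny"} has weights
#'   that mean anything; the other names are accepted for interface
#'   compatibility and build the surrogate architecture with synthetic
#'   deterministic initial weights.
#' @param pretrained_init use the deterministic per-name "pretrained" weights
#'   (\code{TRUE}) or draw fresh initial weights from the current RNG.
#' @export
backbone_spec <- function(name = "surrogate-tiny", pretrained_init = TRUE) {
  if (!name %in% SPASATUNE_BACKBONES) {
    stop_invalid("unknown backbone `", name, "`; valid names: ",
                 paste(SPASATUNE_BACKBONES, collapse = ", "))
  }
  structure(list(name = name, pretrained_init = isTRUE(pretrained_init)),
            class = "backbone_spec")
}

# --- array plumbing --------------------------------------------------------

# Stack an image_set (or list of images) into an (n, h, w, 3) array,
# applying a per-image intensity scaler.
as_batch_array <- function(images, scaler = NULL) {
  if (inherits(images, "image_set")) images <- images$images
  n <- length(images)
  d <- dim(images[[1]])
  X <- array(0, c(n, d[1], d[2], 3))
  for (i in seq_len(n)) {
    img <- images[[i]]
    if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
    if (!is.null(scaler)) img <- scale_image(img, scaler)
    X[i, , , ] <- img
  }
  X
}

# im2col for a 3x3 same-padded convolution: (n*h*w) x (9*c) matrix whose
# column blocks follow (dy, dx) tap order, channels within each block.
im2col3 <- function(X) {
  d <- dim(X)
  n <- d[1]; h <- d[2]; w <- d[3]; c <- d[4]
  Xp <- array(0, c(n, h + 2, w + 2, c))
  Xp[, 2:(h + 1), 2:(w + 1), ] <- X
  cols <- vector("list", 9)
  k <- 0
  for (dy in 0:2) for (dx in 0:2) {
    k <- k + 1
    cols[[k]] <- matrix(Xp[, dy + (1:h), dx + (1:w), , drop = FALSE],
                        n * h * w, c)
  }
  do.call(cbind, cols)
}

col2im3 <- function(dP, n, h, w, c) {
  Gp <- array(0, c(n, h + 2, w + 2, c))
  k <- 0
  for (dy in 0:2) for (dx in 0:2) {
    k <- k + 1
    block <- array(dP[, ((k - 1) * c + 1):(k * c)], c(n, h, w, c))
    Gp[, dy + (1:h), dx + (1:w), ] <- Gp[, dy + (1:h), dx + (1:w), ] + block
  }
  Gp[, 2:(h + 1), 2:(w + 1), , drop = FALSE]
}

pool2_forward <- function(X) {
  d <- dim(X)
  (X[, seq(1, d[2], 2), seq(1, d[3], 2), , drop = FALSE] +
   X[, seq(2, d[2], 2), seq(1, d[3], 2), , drop = FALSE] +
   X[, seq(1, d[2], 2), seq(2, d[3], 2), , drop = FALSE] +
   X[, seq(2, d[2], 2), seq(2, d[3], 2), , drop = FALSE]) / 4
}

pool2_backward <- function(dY, in_dim) {
  dX <- array(0, in_dim)
  q <- dY / 4
  dX[, seq(1, in_dim[2], 2), seq(1, in_dim[3], 2), ] <- q
  dX[, seq(2, in_dim[2], 2), seq(1, in_dim[3], 2), ] <- q
  dX[, seq(1, in_dim[2], 2), seq(2, in_dim[3], 2), ] <- q
  dX[, seq(2, in_dim[2], 2), seq(2, in_dim[3], 2), ] <- q
  dX
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# --- model construction ----------------------------------------------------

#' Build a classifier from a training configuration
#'
#' Constructs the convolutional backbone, freezes the bottom
#' \code{100 - tl_learn_ratio}\% of its layer groups (the surrogate has three
#' conv blocks; \code{ceiling(ratio / 100 * 3)} groups counted from the
#' output end stay trainable, and the dropout + softmax head is always
#' trainable), and attaches the configured loss and optimizer.
#'
#' @param backbone a [backbone_spec()] or backbone name.
#' @param config a [training_config()].
#' @param n_classes number of output classes (>= 2).
#' @param input_size square input side; must be a multiple of 8 (three 2x2
#'   pooling stages).  Default 32 (the desk-scale fixture size); the full
#'   pipeline uses 128.
#' @param class_names optional class vocabulary stored with the model.
#' @return a \code{surrogate_model} handle.
#' @examples
#' m <- build_model("surrogate-tiny", training_config(), n_classes = 4)
#' @export
build_model <- function(backbone, config, n_classes, input_size = 32,
                        class_names = NULL) {
  if (is.character(backbone)) backbone <- backbone_spec(backbone)
  stopifnot(inherits(backbone, "backbone_spec"),
            inherits(config, "training_config"))
  assert_number(n_classes, "n_classes", lo = 2, integer = TRUE)
  assert_number(input_size, "input_size", lo = 8, integer = TRUE)
  if (input_size %% 8 != 0) {
    stop_invalid("`input_size` must be a multiple of 8 (got ", input_size, ")")
  }
  if (backbone$name != "surrogate-tiny") {
    warning("backbone `", backbone$name, "` is built as a surrogate ",
            "architecture with synthetic weights (ImageNet weights are not ",
            "available offline)", call. = FALSE)
  }
  widths <- c(8L, 16L, 32L)
  n_blocks <- length(widths)
  make_weights <- function() {
    c_in <- 3L
    blocks <- vector("list", n_blocks)
    for (b in seq_len(n_blocks)) {
      fan_in <- 9L * c_in
      blocks[[b]] <- list(
        W = matrix(stats::rnorm(fan_in * widths[b], sd = sqrt(2 / fan_in)),
                   fan_in, widths[b]),
        b = rep(0, widths[b])
      )
      c_in <- widths[b]
    }
    head <- list(
      W = matrix(stats::rnorm(widths[n_blocks] * n_classes,
                              sd = sqrt(1 / widths[n_blocks])),
                 widths[n_blocks], n_classes),
      b = rep(0, n_classes)
    )
    list(blocks = blocks, head = head)
  }
  wts <- if (backbone$pretrained_init) {
    with_seed(seed_from_string(paste0(backbone$name, "/", n_classes)),
              make_weights())
  } else {
    make_weights()
  }
  trainable_groups <- ceiling(config$tl_learn_ratio / 100 * n_blocks)
  trainable <- seq_len(n_blocks) > (n_blocks - trainable_groups)
  for (b in seq_len(n_blocks)) wts$blocks[[b]]$trainable <- trainable[b]
  structure(
    list(backbone_name = backbone$name, n_classes = as.integer(n_classes),
         class_names = class_names %||% paste0("class_", seq_len(n_classes)),
         input_size = as.integer(input_size), config = config,
         blocks = wts$blocks, head = wts$head, step = 0L,
         opt_state = NULL, diverged = FALSE),
    class = "surrogate_model"
  )
}

#' Number of trainable parameters
#'
#' @param model a \code{surrogate_model}.
#' @return integer count (head included).
#' @export
n_trainable_params <- function(model) {
  n <- length(model$head$W) + length(model$head$b)
  for (blk in model$blocks) {
    if (blk$trainable) n <- n + length(blk$W) + length(blk$b)
  }
  n
}

#' @export
print.surrogate_model <- function(x, ...) {
  cat("<surrogate_model> backbone:", x$backbone_name,
      " classes:", x$n_classes,
      " trainable params:", n_trainable_params(x), "\n")
  invisible(x)
}

model_forward <- function(model, X, training = FALSE) {
  caches <- if (training) vector("list", length(model$blocks)) else NULL
  A <- X
  for (b in seq_along(model$blocks)) {
    blk <- model$blocks[[b]]
    d <- dim(A)
    P <- im2col3(A)
    Z <- sweep(P %*% blk$W, 2, blk$b, "+")
    mask <- Z > 0
    R <- array(Z * mask, c(d[1], d[2], d[3], ncol(blk$W)))
    if (training) {
      caches[[b]] <- list(P = P, relu_mask = mask, pre_pool_dim = dim(R),
                          in_dim = d)
    }
    A <- pool2_forward(R)
  }
  d <- dim(A)
  feats <- matrix(0, d[1], d[4])
  for (ch in seq_len(d[4])) {
    feats[, ch] <- rowMeans(matrix(A[, , , ch], d[1]))
  }
  drop_mask <- NULL
  feats_d <- feats
  if (training && model$config$dropout > 0) {
    keep <- 1 - model$config$dropout
    drop_mask <- matrix(
      (stats::runif(length(feats)) < keep) / keep, nrow(feats))
    feats_d <- feats * drop_mask
  }
  logits <- sweep(feats_d %*% model$head$W, 2, model$head$b, "+")
  probs <- softmax_rows(logits)
  list(probs = probs, feats = feats_d, drop_mask = drop_mask,
       gap_dim = d, caches = caches)
}

# --- losses ----------------------------------------------------------------
# Each returns list(value, dZ) with dZ the gradient w.r.t. the logits.
# Y is the one-hot matrix, P the softmax probabilities, both n x C.

chain_softmax <- function(P, dP) {
  P * (dP - rowSums(dP * P))
}

loss_grad <- function(loss, P, Y) {
  eps <- 1e-7
  n <- nrow(P); C <- ncol(P)
  switch(loss,
    categorical_crossentropy = list(
      value = -mean(rowSums(Y * log(pmax(P, eps)))),
      dZ = (P - Y) / n
    ),
    kl_divergence = list(
      # for one-hot targets KL(y || p) equals the crossentropy (zero entropy)
      value = -mean(rowSums(Y * log(pmax(P, eps)))),
      dZ = (P - Y) / n
    ),
    poisson = {
      g <- (1 - Y / pmax(P, eps)) / (n * C)
      list(value = mean(P - Y * log(pmax(P, eps))),
           dZ = chain_softmax(P, g))
    },
    hinge = {
      ys <- 2 * Y - 1
      m <- 1 - ys * P
      g <- -(ys * (m > 0)) / (n * C)
      list(value = mean(pmax(m, 0)), dZ = chain_softmax(P, g))
    },
    squared_hinge = {
      ys <- 2 * Y - 1
      m <- pmax(1 - ys * P, 0)
      g <- -(2 * ys * m) / (n * C)
      list(value = mean(m^2), dZ = chain_softmax(P, g))
    },
    categorical_hinge = {
      pos <- rowSums(Y * P)
      negP <- P * (1 - Y) - Y              # true class pushed below any prob
      jmax <- max.col(negP, ties.method = "first")
      neg <- P[cbind(seq_len(n), jmax)]
      active <- (neg - pos + 1) > 0
      g <- matrix(0, n, C)
      g[cbind(seq_len(n), jmax)] <- as.numeric(active)
      g <- g - Y * active
      g <- g / n
      list(value = mean(pmax(neg - pos + 1, 0)), dZ = chain_softmax(P, g))
    },
    stop_invalid("unknown loss `", loss, "`")
  )
}

# --- optimizers ------------------------------------------------------------
# Generic per-array first-order updates with Keras-style defaults.

new_opt_state <- function() list(slots = list())

opt_update <- function(name, param, grad, slot, t) {
  eps <- 1e-7
  get0 <- function(nm) slot[[nm]] %||% array(0, dim(param) %||% length(param))
  switch(name,
    sgd = list(param = param - 0.01 * grad, slot = slot),
    sgd_nesterov = {
      v <- 0.9 * get0("v") - 0.01 * grad
      list(param = param + 0.9 * v - 0.01 * grad, slot = list(v = v))
    },
    adam = {
      m <- 0.9 * get0("m") + 0.1 * grad
      v <- 0.999 * get0("v") + 0.001 * grad^2
      mh <- m / (1 - 0.9^t); vh <- v / (1 - 0.999^t)
      list(param = param - 0.001 * mh / (sqrt(vh) + eps),
           slot = list(m = m, v = v))
    },
    adam_amsgrad = {
      m <- 0.9 * get0("m") + 0.1 * grad
      v <- 0.999 * get0("v") + 0.001 * grad^2
      vmax <- pmax(get0("vmax"), v)
      mh <- m / (1 - 0.9^t); vh <- vmax / (1 - 0.999^t)
      list(param = param - 0.001 * mh / (sqrt(vh) + eps),
           slot = list(m = m, v = v, vmax = vmax))
    },
    nadam = {
      m <- 0.9 * get0("m") + 0.1 * grad
      v <- 0.999 * get0("v") + 0.001 * grad^2
      mh <- m / (1 - 0.9^(t + 1)); vh <- v / (1 - 0.999^t)
      step <- (0.9 * mh + 0.1 * grad / (1 - 0.9^t))
      list(param = param - 0.001 * step / (sqrt(vh) + eps),
           slot = list(m = m, v = v))
    },
    adamax = {
      m <- 0.9 * get0("m") + 0.1 * grad
      u <- pmax(0.999 * get0("u"), abs(grad))
      list(param = param - (0.001 / (1 - 0.9^t)) * m / (u + eps),
           slot = list(m = m, u = u))
    },
    adagrad = {
      acc <- (slot$acc %||% (array(0.1, dim(param) %||% length(param)))) +
        grad^2
      list(param = param - 0.001 * grad / (sqrt(acc) + eps),
           slot = list(acc = acc))
    },
    adadelta = {
      acc <- 0.95 * get0("acc") + 0.05 * grad^2
      delta <- sqrt(get0("dacc") + eps) / sqrt(acc + eps) * grad
      dacc <- 0.95 * get0("dacc") + 0.05 * delta^2
      list(param = param - 0.001 * delta, slot = list(acc = acc, dacc = dacc))
    },
    rmsprop = {
      acc <- 0.9 * get0("acc") + 0.1 * grad^2
      list(param = param - 0.001 * grad / (sqrt(acc) + eps),
           slot = list(acc = acc))
    },
    rmsprop_centered = {
      acc <- 0.9 * get0("acc") + 0.1 * grad^2
      mg <- 0.9 * get0("mg") + 0.1 * grad
      list(param = param - 0.001 * grad / (sqrt(pmax(acc - mg^2, 0)) + eps),
           slot = list(acc = acc, mg = mg))
    },
    ftrl = {
      lr <- 0.001
      nacc <- get0("n") + grad^2
      sigma <- (sqrt(nacc) - sqrt(get0("n"))) / lr
      z <- get0("z") + grad - sigma * param
      list(param = -lr * z / (sqrt(nacc) + eps),
           slot = list(n = nacc, z = z))
    },
    stop_invalid("unknown optimizer `", name, "`")
  )
}

apply_gradients <- function(model, grads) {
  model$step <- model$step + 1L
  if (is.null(model$opt_state)) model$opt_state <- new_opt_state()
  upd <- function(key, param, grad) {
    res <- opt_update(model$config$optimizer, param, grad,
                      model$opt_state$slots[[key]] %||% list(), model$step)
    model$opt_state$slots[[key]] <<- res$slot
    res$param
  }
  for (b in seq_along(model$blocks)) {
    if (!model$blocks[[b]]$trainable || is.null(grads$blocks[[b]])) next
    model$blocks[[b]]$W <- upd(paste0("bW", b), model$blocks[[b]]$W,
                               grads$blocks[[b]]$W)
    model$blocks[[b]]$b <- upd(paste0("bb", b), model$blocks[[b]]$b,
                               grads$blocks[[b]]$b)
  }
  model$head$W <- upd("hW", model$head$W, grads$head$W)
  model$head$b <- upd("hb", model$head$b, grads$head$b)
  model
}

model_backward <- function(model, fwd, dZ) {
  grads <- list(blocks = vector("list", length(model$blocks)), head = NULL)
  grads$head <- list(W = crossprod(fwd$feats, dZ), b = colSums(dZ))
  dF <- dZ %*% t(model$head$W)
  if (!is.null(fwd$drop_mask)) dF <- dF * fwd$drop_mask
  lowest <- which(vapply(model$blocks, `[[`, TRUE, "trainable"))[1]
  if (is.na(lowest)) return(grads)
  gd <- fwd$gap_dim
  dA <- array(0, gd)
  for (ch in seq_len(gd[4])) {
    dA[, , , ch] <- array(dF[, ch] / (gd[2] * gd[3]), gd[1:3])
  }
  for (b in rev(seq_along(model$blocks))) {
    if (b < lowest) break
    cache <- model$blocks[[b]]
    cc <- fwd$caches[[b]]
    dR <- pool2_backward(dA, cc$pre_pool_dim)
    dZm <- matrix(dR, prod(cc$pre_pool_dim[1:3]), cc$pre_pool_dim[4]) *
      cc$relu_mask
    grads$blocks[[b]] <- list(W = crossprod(cc$P, dZm), b = colSums(dZm))
    if (b > lowest) {
      dP <- dZm %*% t(model$blocks[[b]]$W)
      dA <- col2im3(dP, cc$in_dim[1], cc$in_dim[2], cc$in_dim[3], cc$in_dim[4])
    }
  }
  grads
}

one_hot <- function(labels, class_names) {
  Y <- matrix(0, length(labels), length(class_names))
  Y[cbind(seq_along(labels), match(as.character(labels), class_names))] <- 1
  Y
}

#' Train a built model on a labeled image set
#'
#' Minibatch training with the model's configured loss, optimizer, batch
#' size, and (when enabled) on-the-fly augmentation applied to raw images
#' before the intensity scaler.  A non-finite training loss aborts and flags
#' the model as diverged rather than raising.
#'
#' @param model a \code{surrogate_model} from [build_model()].
#' @param data an [image_set()] with raw \[0,255\] images at the model's
#'   input size.
#' @param epochs number of passes over the data.
#' @param seed optional seed applied locally (shuffling, dropout,
#'   augmentation draws).
#' @return the trained model (with \code{$diverged} and
#'   \code{$epochs_run} set).
#' @export
train_classifier <- function(model, data, epochs = 5, seed = NULL) {
  stopifnot(inherits(model, "surrogate_model"), inherits(data, "image_set"))
  assert_number(epochs, "epochs", lo = 1, integer = TRUE)
  if (!is.null(seed)) {
    return(with_seed(seed, train_classifier(model, data, epochs)))
  }
  cfg <- model$config
  n <- length(data$images)
  bs <- min(cfg$batch_size, n)
  augment <- cfg$augment && !is.null(cfg$augmentation)
  Xall <- if (!augment) as_batch_array(data, cfg$scaler) else NULL
  Y <- one_hot(data$labels, model$class_names)
  model$epochs_run <- 0L
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    for (start in seq(1, n, by = bs)) {
      idx <- ord[start:min(start + bs - 1, n)]
      Xb <- if (augment) {
        imgs <- lapply(data$images[idx], augment_image, aug = cfg$augmentation)
        as_batch_array(imgs, cfg$scaler)
      } else {
        Xall[idx, , , , drop = FALSE]
      }
      fwd <- model_forward(model, Xb, training = TRUE)
      lg <- loss_grad(cfg$loss, fwd$probs, Y[idx, , drop = FALSE])
      if (!is.finite(lg$value)) {
        model$diverged <- TRUE
        return(model)
      }
      grads <- model_backward(model, fwd, lg$dZ)
      model <- apply_gradients(model, grads)
    }
    model$epochs_run <- ep
  }
  model
}

#' Predict class probabilities
#'
#' @param object a trained \code{surrogate_model}.
#' @param newdata an [image_set()] or list of raw images at the model's
#'   input size; the model's configured scaler is applied per image.
#' @param ... unused.
#' @return numeric matrix, one probability row per image, columns named by
#'   the model's classes.
#' @export
predict.surrogate_model <- function(object, newdata, ...) {
  X <- as_batch_array(newdata, object$config$scaler)
  probs <- model_forward(object, X, training = FALSE)$probs
  colnames(probs) <- object$class_names
  probs
}

# --- fitness ---------------------------------------------------------------

#' Evaluate the fitness of one hyperparameter configuration
#'
#' Builds the model, trains it for \code{epochs} epochs, and scores it on
#' the evaluation set.  \code{mode = "holdout"} (default) scores on the
#' validation set only; \code{mode = "paper-faithful"} scores on the union
#' of every provided set (training data included, which inflates the score
#' but mirrors the original whole-dataset evaluation).  Any build/training
#' failure, or a non-finite loss, yields a score of 0 with a diagnostic flag
#' instead of an error, so an optimizer exploring bad loss/optimizer
#' pairings can continue.
#'
#' @param backbone a [backbone_spec()] or name.
#' @param config a [training_config()].
#' @param train,validation raw [image_set()]s (same class vocabulary).
#' @param evaluation_set optional explicit evaluation [image_set()]
#'   overriding the mode's default.
#' @param epochs training epochs per fitness call (default 5).
#' @param seed optional seed applied locally.
#' @param mode evaluation-set policy (see above).
#' @return a \code{fitness_result}: list with \code{score} (accuracy
#'   fraction in \[0,1\]), \code{metric_report}, \code{config},
#'   \code{epochs_run}, \code{diverged}, \code{diagnostic}, \code{mode},
#'   \code{model}.
#' @export
evaluate_fitness <- function(backbone, config, train, validation,
                             evaluation_set = NULL, epochs = 5, seed = NULL,
                             mode = c("holdout", "paper-faithful")) {
  mode <- match.arg(mode)
  if (!is.null(seed)) {
    return(with_seed(seed, evaluate_fitness(backbone, config, train,
                                            validation, evaluation_set,
                                            epochs, mode = mode)))
  }
  fail <- function(msg) {
    structure(list(score = 0, metric_report = NULL, config = config,
                   epochs_run = 0L, diverged = TRUE, diagnostic = msg,
                   mode = mode, model = NULL),
              class = "fitness_result")
  }
  res <- tryCatch({
    input_size <- dim(train$images[[1]])[1]
    model <- build_model(backbone, config, length(train$class_names),
                         input_size = input_size,
                         class_names = train$class_names)
    model <- train_classifier(model, train, epochs = epochs)
    if (isTRUE(model$diverged)) return(fail("non-finite training loss"))
    eval_set <- evaluation_set %||% switch(mode,
      holdout = validation,
      `paper-faithful` = combine_image_sets(train, validation)
    )
    probs <- predict(model, eval_set)
    report <- metric_report(eval_set$labels, probs)
    structure(list(score = report$accuracy, metric_report = report,
                   config = config, epochs_run = model$epochs_run,
                   diverged = FALSE, diagnostic = NULL, mode = mode,
                   model = model),
              class = "fitness_result")
  }, error = function(e) fail(conditionMessage(e)))
  res
}

#' @export
print.fitness_result <- function(x, ...) {
  cat("<fitness_result> score:", format(x$score, digits = 4),
      if (x$diverged) paste0(" [failed: ", x$diagnostic, "]") else "",
      "\n")
  invisible(x)
}

#' Combine image sets sharing a class vocabulary
#'
#' @param ... [image_set()]s with identical \code{class_names}.
#' @return one concatenated [image_set()].
#' @export
combine_image_sets <- function(...) {
  sets <- list(...)
  sets <- Filter(Negate(is.null), sets)
  stopifnot(length(sets) >= 1)
  cn <- sets[[1]]$class_names
  for (s in sets) {
    stopifnot(inherits(s, "image_set"), identical(s$class_names, cn))
  }
  image_set(
    do.call(c, lapply(sets, `[[`, "images")),
    do.call(c, lapply(sets, `[[`, "labels")),
    cn,
    do.call(c, lapply(sets, `[[`, "provenance")),
    do.call(c, lapply(sets, `[[`, "source"))
  )
}

# --- two-stage cascade -----------------------------------------------------

#' Two-stage diagnosis: CT class, then histopathology grade
#'
#' Stage 1 classifies the CT image.  A \code{"Normal"} result needs no
#' further grading; \code{"Stone"}/\code{"Cyst"} route to other treatments;
#' a \code{"Tumor"} result proceeds to stage 2, which grades the supplied
#' histopathology image.  A tumor prediction without a histopathology image
#' is flagged \code{"grading pending"}.
#'
#' @param ct_model trained stage-1 \code{surrogate_model} (4 classes).
#' @param histo_model trained stage-2 \code{surrogate_model} (5 grades).
#' @param ct_image raw CT image array at the stage-1 input size.
#' @param histo_image optional raw histopathology image for stage 2.
#' @param trigger_class stage-1 label that triggers grading.
#' @return a list record: \code{stage1_label}, \code{stage1_confidence},
#'   \code{grade} (NA unless graded), \code{grade_confidence}, \code{note}.
#' @export
cascade_predict <- function(ct_model, histo_model, ct_image,
                            histo_image = NULL, trigger_class = "Tumor") {
  p1 <- predict(ct_model, list(ct_image))
  lab1 <- colnames(p1)[which.max(p1[1, ])]
  rec <- list(stage1_label = lab1, stage1_confidence = max(p1[1, ]),
              grade = NA_character_, grade_confidence = NA_real_,
              note = NULL)
  if (identical(lab1, trigger_class)) {
    if (is.null(histo_image)) {
      rec$note <- "grading pending"
    } else {
      p2 <- predict(histo_model, list(histo_image))
      rec$grade <- colnames(p2)[which.max(p2[1, ])]
      rec$grade_confidence <- max(p2[1, ])
      rec$note <- "graded"
    }
  } else if (identical(lab1, "Normal")) {
    rec$note <- "no further grading"
  } else {
    rec$note <- "other treatments"
  }
  rec
}
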