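# Hyperparameter codec: bidirectional mapping between points of the unit
# hypercube [0,1]^D and concrete training configurations.  The optimizer only
# ever sees the continuous encoding; decoding is a pure function.

#' Hyperparameter vocabulary
#'
#' The categorical choices available to the search: six classification losses,
#' eleven first-order weight optimizers, and four image intensity scalers.
#' Order matters — it fixes the decoding of the corresponding solution
#' elements.
#'
#' @name vocabulary
NULL

#' @rdname vocabulary
#' @export
SPASATUNE_LOSSES <- c(
  "categorical_crossentropy", "categorical_hinge", "kl_divergence",
  "poisson", "squared_hinge", "hinge"
)

#' @rdname vocabulary
#' @export
SPASATUNE_OPTIMIZERS <- c(
  "adam", "nadam", "adagrad", "adadelta", "adamax", "rmsprop", "sgd",
  "ftrl", "sgd_nesterov", "rmsprop_centered", "adam_amsgrad"
)

#' @rdname vocabulary
#' @export
SPASATUNE_SCALERS <- c("normalize", "standard", "minmax", "maxabs")

#' Describe one search dimension
#'
#' A dimension spec tells the codec how to map a real value in \[0,1\] onto a
#' concrete hyperparameter value.
#'
#' @param name identifier for the dimension.
#' @param kind one of \code{"categorical"}, \code{"integer"}, \code{"real"},
#'   \code{"boolean"}, \code{"real_pair"}.
#' @param choices character/numeric vector of choices (categorical only).
#' @param low,high numeric bounds (integer/real/real_pair kinds).
#' @param step positive step between integer choices.
#' @param half_width for \code{real_pair}: the decoded scalar is taken as the
#'   interval center and expanded by \code{±half_width}, clipped to
#'   \code{[low, high]}.
#' @return an object of class \code{dimension_spec}.
#' @export
dimension_spec <- function(name, kind, choices = NULL, low = NULL, high = NULL,
                           step = NULL, half_width = 0.3) {
  kind <- match.arg(kind, c("categorical", "integer", "real", "boolean",
                            "real_pair"))
  if (kind == "categorical") {
    if (length(choices) < 1L) stop_invalid("categorical spec needs choices")
  }
  if (kind %in% c("integer", "real", "real_pair")) {
    assert_number(low, "low"); assert_number(high, "high")
    if (low >= high) stop_invalid("`low` must be < `high` for ", name)
  }
  if (kind == "integer") {
    step <- step %||% 1
    assert_number(step, "step", lo = .Machine$double.eps)
    choices <- seq(low, high, by = step)
  }
  structure(
    list(name = name, kind = kind, choices = choices, low = low, high = high,
         step = step, half_width = half_width),
    class = "dimension_spec"
  )
}

n_choices <- function(spec) {
  switch(spec$kind,
    categorical = length(spec$choices),
    integer = length(spec$choices),
    boolean = 2L,
    stop_invalid("dimension `", spec$name, "` is continuous")
  )
}

#' Build the hyperparameter search space
#'
#' Fifteen ordered dimensions: (1) loss, (2) batch size, (3) dropout,
#' (4) transfer-learning learn ratio, (5) optimizer, (6) scaler,
#' (7) augmentation on/off, and (8--15) the augmentation settings (rotation,
#' width/height shift, shear, zoom, horizontal/vertical flip, brightness).
#' The reduced 7-dimension space drops positions 8--15 and never augments.
#'
#' @param include_augmentation logical; \code{FALSE} gives the reduced
#'   7-dimension space.
#' @param brightness_half_width half-width used to expand the decoded
#'   brightness center into a range (the encoding carries a single scalar).
#' @return a \code{search_space} object (list of \code{dimension_spec}s).
#' @examples
#' space <- search_space()
#' length(space$dims) # 15
#' @export
search_space <- function(include_augmentation = TRUE,
                         brightness_half_width = 0.3) {
  dims <- list(
    dimension_spec("loss", "categorical", choices = SPASATUNE_LOSSES),
    dimension_spec("batch_size", "integer", low = 4, high = 48, step = 4),
    dimension_spec("dropout", "real", low = 0, high = 0.6),
    dimension_spec("tl_learn_ratio", "integer", low = 1, high = 100, step = 1),
    dimension_spec("optimizer", "categorical", choices = SPASATUNE_OPTIMIZERS),
    dimension_spec("scaler", "categorical", choices = SPASATUNE_SCALERS),
    dimension_spec("augment", "boolean")
  )
  if (include_augmentation) {
    dims <- c(dims, list(
      dimension_spec("rotation_deg", "integer", low = 0, high = 45, step = 1),
      dimension_spec("width_shift", "real", low = 0, high = 0.25),
      dimension_spec("height_shift", "real", low = 0, high = 0.25),
      dimension_spec("shear", "real", low = 0, high = 0.25),
      dimension_spec("zoom", "real", low = 0, high = 0.25),
      dimension_spec("horizontal_flip", "boolean"),
      dimension_spec("vertical_flip", "boolean"),
      dimension_spec("brightness", "real_pair", low = 0.5, high = 2.0,
                     half_width = brightness_half_width)
    ))
  }
  structure(
    list(dims = dims, include_augmentation = include_augmentation),
    class = "search_space"
  )
}

#' @export
print.search_space <- function(x, ...) {
  cat("<search_space> ", length(x$dims), " dimensions\n", sep = "")
  for (d in x$dims) {
    rng <- switch(d$kind,
      categorical = paste(d$choices, collapse = ", "),
      integer = paste0(d$low, "..", d$high, " step ", d$step),
      real = paste0("[", d$low, ", ", d$high, "]"),
      boolean = "yes/no",
      real_pair = paste0("center in [", d$low, ", ", d$high, "] +/- ",
                         d$half_width))
    cat(sprintf("  %-16s %-11s %s\n", d$name, d$kind, rng))
  }
  invisible(x)
}

#' Map one encoded element onto its concrete hyperparameter value
#'
#' Discrete kinds use the floor-index rule \code{floor(value * n_choices)}
#' (clamped to the last choice at \code{value = 1}); continuous kinds use
#' linear interpolation \code{low + value * (high - low)}; booleans switch at
#' 0.5.  With the 12-value batch-size dimension, \code{value = 0.85} gives
#' \code{floor(0.85 * 12) = 10} (0-based), i.e. the 11th choice, batch size
#' 44.
#'
#' @param value real in \[0,1\].
#' @param spec a \code{dimension_spec}.
#' @return the decoded concrete value.
#' @examples
#' bs <- dimension_spec("batch_size", "integer", low = 4, high = 48, step = 4)
#' map_element(0.85, bs) # 44
#' @export
map_element <- function(value, spec) {
  if (!is.numeric(value) || length(value) != 1L || is.na(value) ||
      value < 0 || value > 1) {
    stop_invalid("encoded value must be a single number in [0,1] (got ",
                 format(value), ")")
  }
  switch(spec$kind,
    categorical = ,
    integer = {
      n <- n_choices(spec)
      idx <- min(floor(value * n), n - 1L)
      spec$choices[[idx + 1L]]
    },
    boolean = value >= 0.5,
    real = spec$low + value * (spec$high - spec$low),
    real_pair = {
      center <- spec$low + value * (spec$high - spec$low)
      c(max(spec$low, center - spec$half_width),
        min(spec$high, center + spec$half_width))
    }
  )
}

#' Decode a solution vector into a training configuration
#'
#' Element-by-element application of [map_element()] in the order fixed by
#' the search space.  When the augmentation flag (element 7) decodes to off,
#' elements 8--15 are carried in the encoding but ignored, so the optimizer
#' always works on a fixed-dimension space.
#'
#' @param solution numeric vector in \[0,1\]^D matching the space dimension.
#' @param space a [search_space()].
#' @return a \code{training_config} object.
#' @examples
#' decode_solution(rep(0, 15), search_space())
#' @export
decode_solution <- function(solution, space = search_space()) {
  D <- length(space$dims)
  if (length(solution) != D) {
    stop_invalid("solution has length ", length(solution),
                 " but the space has ", D, " dimensions")
  }
  vals <- lapply(seq_len(D), function(i) map_element(solution[[i]],
                                                     space$dims[[i]]))
  names(vals) <- vapply(space$dims, `[[`, "", "name")
  augment <- isTRUE(vals$augment) && space$include_augmentation
  aug <- NULL
  if (augment) {
    aug <- augmentation_config(
      rotation_deg = vals$rotation_deg,
      width_shift = vals$width_shift,
      height_shift = vals$height_shift,
      shear = vals$shear,
      zoom = vals$zoom,
      horizontal_flip = vals$horizontal_flip,
      vertical_flip = vals$vertical_flip,
      brightness_range = vals$brightness
    )
  }
  training_config(
    loss = vals$loss, batch_size = vals$batch_size, dropout = vals$dropout,
    tl_learn_ratio = vals$tl_learn_ratio, optimizer = vals$optimizer,
    scaler = vals$scaler, augment = augment, augmentation = aug
  )
}

#' Concrete training configuration
#'
#' @param loss one of [SPASATUNE_LOSSES].
#' @param batch_size minibatch size (4..48, multiples of 4 when decoded).
#' @param dropout dropout probability before the softmax head, in \[0, 0.6\].
#' @param tl_learn_ratio percentage (1..100) of backbone layer groups, counted
#'   from the output end, left trainable during fine-tuning.
#' @param optimizer one of [SPASATUNE_OPTIMIZERS].
#' @param scaler one of [SPASATUNE_SCALERS].
#' @param augment logical: apply on-the-fly augmentation during training.
#' @param augmentation an [augmentation_config()] (required when
#'   \code{augment} is \code{TRUE}).
#' @return a \code{training_config} object.
#' @export
training_config <- function(loss = "categorical_crossentropy", batch_size = 16,
                            dropout = 0, tl_learn_ratio = 100,
                            optimizer = "adam", scaler = "normalize",
                            augment = FALSE, augmentation = NULL) {
  loss <- match.arg(loss, SPASATUNE_LOSSES)
  optimizer <- match.arg(optimizer, SPASATUNE_OPTIMIZERS)
  scaler <- match.arg(scaler, SPASATUNE_SCALERS)
  assert_number(batch_size, "batch_size", lo = 1, integer = TRUE)
  assert_number(dropout, "dropout", lo = 0, hi = 1)
  assert_number(tl_learn_ratio, "tl_learn_ratio", lo = 0, hi = 100,
                integer = TRUE)
  if (augment && is.null(augmentation)) {
    stop_invalid("`augmentation` must be supplied when `augment` is TRUE")
  }
  structure(
    list(loss = loss, batch_size = as.integer(batch_size), dropout = dropout,
         tl_learn_ratio = as.integer(tl_learn_ratio), optimizer = optimizer,
         scaler = scaler, augment = isTRUE(augment),
         augmentation = if (isTRUE(augment)) augmentation else NULL),
    class = "training_config"
  )
}

#' Augmentation settings
#'
#' Defaults are the fixed settings used for augmentation-based class
#' balancing: rotation 30 degrees, 20\% shifts/shear/zoom, both flips, and a
#' \[0.8, 1.2\] brightness multiplier.
#'
#' @param rotation_deg max absolute rotation, degrees, in \[0, 45\].
#' @param width_shift,height_shift,shear,zoom max absolute magnitudes as
#'   fractions, each in \[0, 0.25\] when decoded from the search space.
#' @param horizontal_flip,vertical_flip logical; when enabled each is applied
#'   with probability 0.5.
#' @param brightness_range length-2 multiplier range inside \[0.5, 2\].
#' @return an \code{augmentation_config} object.
#' @export
augmentation_config <- function(rotation_deg = 30, width_shift = 0.2,
                                height_shift = 0.2, shear = 0.2, zoom = 0.2,
                                horizontal_flip = TRUE, vertical_flip = TRUE,
                                brightness_range = c(0.8, 1.2)) {
  assert_number(rotation_deg, "rotation_deg", lo = 0, hi = 360)
  for (nm in c("width_shift", "height_shift", "shear", "zoom")) {
    assert_number(get(nm), nm, lo = 0, hi = 1)
  }
  if (length(brightness_range) != 2L || brightness_range[1] > brightness_range[2]) {
    stop_invalid("`brightness_range` must be an ordered pair")
  }
  structure(
    list(rotation_deg = rotation_deg, width_shift = width_shift,
         height_shift = height_shift, shear = shear, zoom = zoom,
         horizontal_flip = isTRUE(horizontal_flip),
         vertical_flip = isTRUE(vertical_flip),
         brightness_range = as.numeric(brightness_range)),
    class = "augmentation_config"
  )
}

#' Validate a decoded configuration against a search space
#'
#' Checks every decoded value against its dimension's range.  Used as the
#' range oracle in fuzz tests; returns invisibly or stops.
#'
#' @param config a [training_config()].
#' @param space the [search_space()] it should conform to.
#' @export
validate_config <- function(config, space = search_space()) {
  stopifnot(inherits(config, "training_config"))
  ok <- config$loss %in% SPASATUNE_LOSSES &&
    config$batch_size %in% seq(4, 48, 4) &&
    config$dropout >= 0 && config$dropout <= 0.6 &&
    config$tl_learn_ratio >= 1 && config$tl_learn_ratio <= 100 &&
    config$optimizer %in% SPASATUNE_OPTIMIZERS &&
    config$scaler %in% SPASATUNE_SCALERS
  if (ok && config$augment) {
    a <- config$augmentation
    ok <- a$rotation_deg >= 0 && a$rotation_deg <= 45 &&
      all(c(a$width_shift, a$height_shift, a$shear, a$zoom) >= 0) &&
      all(c(a$width_shift, a$height_shift, a$shear, a$zoom) <= 0.25) &&
      a$brightness_range[1] >= 0.5 && a$brightness_range[2] <= 2.0 &&
      a$brightness_range[1] <= a$brightness_range[2]
  }
  if (!ok) stop_invalid("decoded config violates its search-space ranges")
  invisible(config)
}

#' Flatten a configuration to a loggable record (and back)
#'
#' \code{config_record()} produces a flat named list with one field per
#' reporting column ("N/A" for augmentation fields when augmentation is off);
#' \code{parse_config_record()} inverts it.
#'
#' @param config a [training_config()].
#' @return a named list of scalars.
#' @export
config_record <- function(config) {
  stopifnot(inherits(config, "training_config"))
  a <- config$augmentation
  na <- "N/A"
  list(
    loss = config$loss,
    batch_size = config$batch_size,
    dropout = config$dropout,
    tl_learn_ratio = config$tl_learn_ratio,
    optimizer = config$optimizer,
    scaler = config$scaler,
    apply_augmentation = if (config$augment) "Yes" else "No",
    rotation_deg = if (config$augment) a$rotation_deg else na,
    width_shift = if (config$augment) a$width_shift else na,
    height_shift = if (config$augment) a$height_shift else na,
    shear = if (config$augment) a$shear else na,
    zoom = if (config$augment) a$zoom else na,
    horizontal_flip = if (config$augment) {
      if (a$horizontal_flip) "Yes" else "No"
    } else na,
    vertical_flip = if (config$augment) {
      if (a$vertical_flip) "Yes" else "No"
    } else na,
    brightness_low = if (config$augment) a$brightness_range[1] else na,
    brightness_high = if (config$augment) a$brightness_range[2] else na
  )
}

#' @rdname config_record
#' @param record a named list/one-row data.frame as produced by
#'   \code{config_record()}.
#' @export
parse_config_record <- function(record) {
  record <- as.list(record)
  augment <- identical(record$apply_augmentation, "Yes")
  aug <- NULL
  if (augment) {
    aug <- augmentation_config(
      rotation_deg = as.numeric(record$rotation_deg),
      width_shift = as.numeric(record$width_shift),
      height_shift = as.numeric(record$height_shift),
      shear = as.numeric(record$shear),
      zoom = as.numeric(record$zoom),
      horizontal_flip = identical(record$horizontal_flip, "Yes"),
      vertical_flip = identical(record$vertical_flip, "Yes"),
      brightness_range = c(as.numeric(record$brightness_low),
                           as.numeric(record$brightness_high))
    )
  }
  training_config(
    loss = record$loss, batch_size = as.integer(record$batch_size),
    dropout = as.numeric(record$dropout),
    tl_learn_ratio = as.integer(record$tl_learn_ratio),
    optimizer = record$optimizer, scaler = record$scaler,
    augment = augment, augmentation = aug
  )
}

#' @export
print.training_config <- function(x, ...) {
  cat("<training_config>\n")
  cat("  loss:", x$loss, " batch:", x$batch_size,
      " dropout:", format(x$dropout, digits = 3),
      " learn ratio:", x$tl_learn_ratio, "%\n")
  cat("  optimizer:", x$optimizer, " scaler:", x$scaler,
      " augment:", if (x$augment) "yes" else "no", "\n")
  if (x$augment) {
    a <- x$augmentation
    cat(sprintf(
      "  aug: rot %d deg, shift (%.2f, %.2f), shear %.2f, zoom %.2f, flips (%s, %s), brightness [%.2f, %.2f]\n",
      a$rotation_deg, a$width_shift, a$height_shift, a$shear, a$zoom,
      if (a$horizontal_flip) "H" else "-", if (a$vertical_flip) "V" else "-",
      a$brightness_range[1], a$brightness_range[2]))
  }
  invisible(x)
}
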