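# Seeded synthetic image fixtures.  Each class is rendered with a distinct
# parametric texture whose amplitude is controlled by `signal_strength`, so
# class separability is tunable from none (0) to strong (1).  The textures
# are deliberately geometric, not medically realistic: their only contract is
# controllable, monotone separability.

#' Specify a synthetic labeled-image fixture
#'
#' Defaults emulate the two study designs at desk scale: a 4-class CT-like
#' problem (\code{"Cyst"}, \code{"Normal"}, \code{"Stone"}, \code{"Tumor"})
#' with imbalanced counts proportional to the real dataset (scaled to 1\%),
#' and a 5-class histopathology-grade-like problem (\code{"Grade 0"} ..
#' \code{"Grade 4"}) at its actual desk-scale counts (45, 45, 60, 67, 60).
#'
#' @param n_classes 4 or 5 pick the named presets; other values get generic
#'   class names and equal counts.
#' @param per_class_counts named or unnamed positive integer vector, one
#'   entry per class.
#' @param image_size square side in pixels (default 32 for test speed; the
#'   real pipeline resizes to 128).
#' @param signal_strength real in \[0,1\]: 0 makes all class-conditional
#'   distributions identical, 1 gives full-amplitude class textures.
#' @param noise_sd standard deviation of the additive Gaussian pixel noise
#'   (intensity units on the \[0,255\] scale).
#' @param seed integer seed; the same spec always renders identical pixels.
#' @return a \code{fixture_spec} object.
#' @export
fixture_spec <- function(n_classes = 4, per_class_counts = NULL,
                         image_size = 32, signal_strength = 1,
                         noise_sd = 8, seed = 1) {
  assert_number(n_classes, "n_classes", lo = 2, integer = TRUE)
  assert_number(image_size, "image_size", lo = 8, integer = TRUE)
  assert_number(signal_strength, "signal_strength", lo = 0, hi = 1)
  assert_number(noise_sd, "noise_sd", lo = 0)
  assert_number(seed, "seed", integer = TRUE)
  class_names <- if (n_classes == 4) {
    c("Cyst", "Normal", "Stone", "Tumor")
  } else if (n_classes == 5) {
    paste("Grade", 0:4)
  } else {
    paste0("class_", seq_len(n_classes))
  }
  if (is.null(per_class_counts)) {
    per_class_counts <- if (n_classes == 4) {
      c(37, 51, 14, 23)                     # 1% of the 4-class study counts
    } else if (n_classes == 5) {
      c(45, 45, 60, 67, 60)                 # the 5-class study counts
    } else {
      rep(30, n_classes)
    }
  }
  if (length(per_class_counts) != n_classes || any(per_class_counts < 1)) {
    stop_invalid("`per_class_counts` must have one positive entry per class")
  }
  names(per_class_counts) <- class_names
  structure(
    list(n_classes = as.integer(n_classes),
         class_names = class_names,
         per_class_counts = as.integer(per_class_counts),
         image_size = as.integer(image_size),
         signal_strength = signal_strength, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "fixture_spec"
  )
}

# Deterministic class texture on [0,1]^2 coordinates, amplitude in [-1, 1].
# k is the 1-based class index.
class_texture <- function(k, n_classes, size, jitter) {
  xs <- matrix(rep(seq(0, 1, length.out = size), each = size), size)
  ys <- matrix(rep(seq(0, 1, length.out = size), times = size), size)
  cx <- 0.5 + jitter[1]; cy <- 0.5 + jitter[2]
  r <- sqrt((xs - cx)^2 + (ys - cy)^2)
  if (n_classes == 5) {
    # graded blob granularity: spatial frequency grows with the grade
    freq <- 2 + 3 * (k - 1)
    sin(2 * pi * freq * xs + jitter[3]) * sin(2 * pi * freq * ys + jitter[4]) *
      exp(-2 * r)
  } else {
    switch(((k - 1) %% 4) + 1,
      # bright rim around a dark disk (cyst-like ellipse ring)
      2 * exp(-((r - 0.3)^2) / 0.004) - exp(-(r^2) / 0.05),
      # smooth diagonal gradient (unremarkable background)
      (xs + ys) - 1,
      # bright speckles on a dark field (stone-like)
      {
        sp <- 2 * (sin(23 * xs + 17 * ys + jitter[3]) *
                     sin(19 * xs - 29 * ys + jitter[4]))^8 - 0.2
        sp
      },
      # one large soft mass (tumor-like blob)
      1.5 * exp(-(r^2) / 0.03) - 0.2
    )
  }
}

#' Generate a labeled synthetic image set
#'
#' Renders \code{per_class_counts[k]} images for each class as
#' \code{background + signal_strength * texture + noise}, RGB with a mild
#' per-channel tint, clipped to \[0, 255\].  Per-image texture jitter is
#' small (sub-pixel center and phase shifts), so class centroids stay well
#' separated at full signal.
#'
#' @param spec a [fixture_spec()].
#' @return an [image_set()] with provenance \code{"original"}.
#' @examples
#' set <- generate_image_set(fixture_spec(n_classes = 4, image_size = 16,
#'                                        per_class_counts = c(3, 4, 2, 3)))
#' class_counts(set)
#' @export
generate_image_set <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, {
    size <- spec$image_size
    images <- vector("list", sum(spec$per_class_counts))
    labels <- character(length(images))
    tint <- c(1, 0.95, 0.9)
    i <- 0L
    for (k in seq_len(spec$n_classes)) {
      for (j in seq_len(spec$per_class_counts[k])) {
        jitter <- c(stats::runif(2, -0.02, 0.02), stats::runif(2, -0.3, 0.3))
        tex <- class_texture(k, spec$n_classes, size, jitter)
        base <- 120 + 90 * spec$signal_strength * tex
        img <- array(0, c(size, size, 3))
        for (ch in 1:3) {
          img[, , ch] <- base * tint[ch] +
            stats::rnorm(size * size, sd = spec$noise_sd)
        }
        i <- i + 1L
        images[[i]] <- clamp(img, 0, 255)
        labels[i] <- spec$class_names[k]
      }
    }
    image_set(images, labels, class_names = spec$class_names)
  })
}

#' Benchmark objectives on the unit hypercube
#'
#' Deterministic callables for validating the optimizer.  \code{"sphere"}
#' and \code{"rastrigin"} are minimization problems whose domain is mapped
#' from \[0,1\]^D onto \[-5.12, 5.12\]^D, with optimum 0 at the hypercube
#' center; \code{"target-vector"} is the maximization problem
#' \code{1 - mean((x - target)^2)} with optimum 1 at \code{target}.
#' The returned function carries \code{attr(fn, "maximize")},
#' \code{attr(fn, "optimum")} (the location) and
#' \code{attr(fn, "optimum_value")}.
#'
#' @param name one of \code{"sphere"}, \code{"rastrigin"},
#'   \code{"target-vector"}.
#' @param dimension search dimension D.
#' @param target optional target vector for \code{"target-vector"}
#'   (default the hypercube center).
#' @return a fitness function on \[0,1\]^D.
#' @export
benchmark_objective <- function(name, dimension, target = NULL) {
  assert_number(dimension, "dimension", lo = 1, integer = TRUE)
  scale_z <- function(x) (x - 0.5) * 2 * 5.12
  fn <- switch(name,
    sphere = {
      f <- function(x) sum(scale_z(x)^2)
      attr(f, "maximize") <- FALSE
      attr(f, "optimum") <- rep(0.5, dimension)
      attr(f, "optimum_value") <- 0
      f
    },
    rastrigin = {
      f <- function(x) {
        z <- scale_z(x)
        10 * length(z) + sum(z^2 - 10 * cos(2 * pi * z))
      }
      attr(f, "maximize") <- FALSE
      attr(f, "optimum") <- rep(0.5, dimension)
      attr(f, "optimum_value") <- 0
      f
    },
    `target-vector` = {
      tgt <- target %||% rep(0.5, dimension)
      if (length(tgt) != dimension) {
        stop_invalid("`target` must have length `dimension`")
      }
      f <- function(x) 1 - mean((x - tgt)^2)
      attr(f, "maximize") <- TRUE
      attr(f, "optimum") <- tgt
      attr(f, "optimum_value") <- 1
      f
    },
    stop_invalid("unknown objective `", name,
                 "`; choose sphere, rastrigin, or target-vector")
  )
  fn
}
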