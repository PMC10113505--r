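# Image ingestion and preprocessing.  Images are numeric H x W x 3 arrays
# with intensities held as reals in [0, 255] until a scaler is applied.

#' Labeled image set container
#'
#' @param images list of numeric arrays (H x W, H x W x 1, or H x W x 3).
#' @param labels vector of class labels parallel to \code{images}.
#' @param class_names ordered class vocabulary; defaults to the sorted unique
#'   labels.  Classes may be declared with zero images (balancing reports
#'   them as errors by name).
#' @param provenance per-image flag, \code{"original"} or
#'   \code{"augmented"}.
#' @param source integer index of the original image an augmented copy was
#'   derived from (\code{NA} for originals); used for leakage-free splitting.
#' @return an \code{image_set} object.
#' @export
image_set <- function(images, labels, class_names = NULL, provenance = NULL,
                      source = NULL) {
  if (!is.list(images)) stop_invalid("`images` must be a list of arrays")
  if (length(images) != length(labels)) {
    stop_invalid("images and labels are not parallel")
  }
  labels <- as.character(labels)
  class_names <- class_names %||% sort(unique(labels))
  if (!all(labels %in% class_names)) {
    stop_invalid("labels outside class_names: ",
                 paste(setdiff(unique(labels), class_names), collapse = ", "))
  }
  provenance <- provenance %||% rep("original", length(images))
  source <- source %||% rep(NA_integer_, length(images))
  stopifnot(length(provenance) == length(images),
            length(source) == length(images))
  structure(
    list(images = images, labels = labels, class_names = class_names,
         provenance = provenance, source = as.integer(source)),
    class = "image_set"
  )
}

#' @export
print.image_set <- function(x, ...) {
  cat("<image_set> ", length(x$images), " images, ",
      length(x$class_names), " classes\n", sep = "")
  print(class_counts(x))
  invisible(x)
}

#' @export
length.image_set <- function(x) length(x$images)

#' Per-class image counts
#'
#' @param data an [image_set()].
#' @return named integer vector over \code{class_names}.
#' @export
class_counts <- function(data) {
  stopifnot(inherits(data, "image_set"))
  vapply(data$class_names,
         function(cl) sum(data$labels == cl), integer(1))
}

subset_image_set <- function(data, idx) {
  image_set(data$images[idx], data$labels[idx], data$class_names,
            data$provenance[idx], data$source[idx])
}

# --- bicubic resizing ------------------------------------------------------

# Catmull-Rom cubic convolution kernel (a = -0.5), the common bicubic choice.
cubic_kernel <- function(t, a = -0.5) {
  t <- abs(t)
  ifelse(t <= 1, (a + 2) * t^3 - (a + 3) * t^2 + 1,
         ifelse(t < 2, a * t^3 - 5 * a * t^2 + 8 * a * t - 4 * a, 0))
}

# Row-resampling weight matrix (n_out x n_in), pixel-center aligned.
# Out-of-range taps are dropped and the remaining window renormalized to
# sum 1 (the PIL edge convention); interior windows already sum to 1.
bicubic_weights <- function(n_in, n_out) {
  w <- matrix(0, n_out, n_in)
  scale <- n_in / n_out
  for (i in seq_len(n_out)) {
    s <- (i - 0.5) * scale - 0.5      # 0-based source coordinate
    base <- floor(s)
    taps <- (base - 1):(base + 2)
    taps <- taps[taps >= 0 & taps < n_in]
    wts <- cubic_kernel(s - taps)
    w[i, taps + 1] <- wts / sum(wts)
  }
  w
}

#' Resize an image to the model input size by bicubic interpolation
#'
#' Separable cubic-convolution resampling (Catmull-Rom kernel, pixel-center
#' alignment, clamped edges).  Grayscale inputs are replicated to three
#' channels; the output is clipped back into \[0, 255\].
#'
#' @param image numeric H x W, H x W x 1, or H x W x 3 array.
#' @param size output side length (default 128).
#' @return a \code{size x size x 3} numeric array.
#' @export
resize_image <- function(image, size = 128) {
  d <- dim(image)
  if (is.null(d)) stop_invalid("`image` must be a matrix or 3-d array")
  if (any(d[1:2] == 0)) stop_invalid("image has a zero dimension")
  if (length(d) == 2) image <- array(image, c(d, 1L))
  d <- dim(image)
  if (!d[3] %in% c(1L, 3L)) {
    stop_invalid("image must have 1 or 3 channels, got ", d[3])
  }
  wr <- bicubic_weights(d[1], size)
  wc <- bicubic_weights(d[2], size)
  out <- array(0, c(size, size, 3L))
  for (ch in seq_len(3)) {
    src <- image[, , if (d[3] == 1L) 1L else ch]
    out[, , ch] <- clamp(wr %*% src %*% t(wc), 0, 255)
  }
  out
}

# --- intensity scaling -----------------------------------------------------

#' Scale image intensities
#'
#' Four per-image scalers: \code{normalize} divides by the image maximum,
#' \code{standard} subtracts the image mean and divides by its standard
#' deviation, \code{minmax} maps the intensity span onto \[0,1\], and
#' \code{maxabs} divides by the maximum absolute intensity.  Statistics are
#' computed over the whole image (all channels).  A flat image (zero spread)
#' cannot be scaled; the fallback is an all-zero image with a warning.
#'
#' @param image numeric array.
#' @param method one of \code{"normalize"}, \code{"standard"},
#'   \code{"minmax"}, \code{"maxabs"}.
#' @return scaled array of the same shape.
#' @export
scale_image <- function(image, method = c("normalize", "standard", "minmax",
                                          "maxabs")) {
  method <- match.arg(method)
  x <- as.numeric(image)
  flat <- function() {
    warning("flat image cannot be ", method, "-scaled; returning zeros",
            call. = FALSE)
    array(0, dim(image) %||% length(image))
  }
  out <- switch(method,
    normalize = {
      m <- max(x)
      if (m == 0) return(flat())
      image / m
    },
    standard = {
      s <- stats::sd(x)
      if (s == 0) return(flat())
      (image - mean(x)) / s
    },
    minmax = {
      lo <- min(x); hi <- max(x)
      if (hi == lo) return(flat())
      (image - lo) / (hi - lo)
    },
    maxabs = {
      m <- max(abs(x))
      if (m == 0) return(flat())
      image / m
    }
  )
  out
}

# --- augmentation ----------------------------------------------------------

# Reflect an out-of-range 0-based index back into [0, n-1] (mirror with edge
# duplication).
reflect_index <- function(i, n) {
  if (n == 1) return(rep(0L, length(i)))
  p <- 2L * n
  i <- ((i %% p) + p) %% p
  ifelse(i >= n, p - 1L - i, i)
}

# Bilinear sample of one channel at fractional 0-based coordinates.
bilinear_channel <- function(ch, ys, xs) {
  n <- nrow(ch); m <- ncol(ch)
  y0 <- floor(ys); x0 <- floor(xs)
  fy <- ys - y0; fx <- xs - x0
  iy0 <- reflect_index(y0, n) + 1; iy1 <- reflect_index(y0 + 1, n) + 1
  ix0 <- reflect_index(x0, m) + 1; ix1 <- reflect_index(x0 + 1, m) + 1
  v00 <- ch[cbind(iy0, ix0)]; v01 <- ch[cbind(iy0, ix1)]
  v10 <- ch[cbind(iy1, ix0)]; v11 <- ch[cbind(iy1, ix1)]
  (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
}

#' Apply one random augmentation draw to an image
#'
#' Samples a rotation in \code{[-rotation_deg, rotation_deg]}, shifts, shear
#' and zoom magnitudes in \code{[-m, +m]}, optional flips (probability 0.5
#' each when enabled), and a brightness multiplier uniform in
#' \code{brightness_range}; applies the combined affine warp about the image
#' center with reflect padding and bilinear sampling, then the flips and the
#' brightness scaling, clipping to \[0, 255\].  Output shape is preserved.
#' Draw order (rotation, shifts, shear, zoom, flips, brightness) is fixed, so
#' results are deterministic under a seeded RNG.
#'
#' @param image numeric H x W x C array (C = 1 or 3) on the \[0,255\] scale.
#' @param aug an [augmentation_config()].
#' @param seed optional seed applied locally (the caller's RNG stream is
#'   restored afterwards).
#' @return augmented array, same shape as the input.
#' @export
augment_image <- function(image, aug, seed = NULL) {
  stopifnot(inherits(aug, "augmentation_config"))
  if (!is.null(seed)) return(with_seed(seed, augment_image(image, aug)))
  d <- dim(image)
  if (length(d) == 2) {
    out <- augment_image(array(image, c(d, 1L)), aug)
    return(array(out, d))
  }
  h <- d[1]; w <- d[2]

  theta <- stats::runif(1, -aug$rotation_deg, aug$rotation_deg) * pi / 180
  tx <- stats::runif(1, -aug$width_shift, aug$width_shift) * w
  ty <- stats::runif(1, -aug$height_shift, aug$height_shift) * h
  shear <- stats::runif(1, -aug$shear, aug$shear)
  zoom <- 1 + stats::runif(1, -aug$zoom, aug$zoom)
  hflip <- aug$horizontal_flip && stats::runif(1) < 0.5
  vflip <- aug$vertical_flip && stats::runif(1) < 0.5
  bright <- stats::runif(1, aug$brightness_range[1], aug$brightness_range[2])

  identity_warp <- theta == 0 && tx == 0 && ty == 0 && shear == 0 && zoom == 1
  out <- image
  if (!identity_warp) {
    # inverse map: output pixel -> input coordinate (x right, y down),
    # rotation and shear about the image center, then the shift
    cx <- (w - 1) / 2; cy <- (h - 1) / 2
    grid <- expand.grid(y = seq_len(h) - 1, x = seq_len(w) - 1)
    xo <- grid$x - cx - tx
    yo <- grid$y - cy - ty
    ct <- cos(theta); st <- sin(theta)
    xr <- (ct * xo + st * yo) / zoom
    yr <- (-st * xo + ct * yo) / zoom
    xs <- xr + shear * yr + cx
    ys <- yr + cy
    for (ch in seq_len(d[3])) {
      out[, , ch] <- matrix(bilinear_channel(image[, , ch], ys, xs), h, w)
    }
  }
  if (hflip) out <- out[, w:1, , drop = FALSE]
  if (vflip) out <- out[h:1, , , drop = FALSE]
  clamp(out * bright, 0, 255)
}

# --- balancing and splitting -----------------------------------------------

#' Equalize class counts by the up-sample-to-max rule
#'
#' Pure arithmetic used by [balance_by_augmentation()]: every class is raised
#' to the largest pre-balancing class count (no class is reduced).
#'
#' @param counts named non-negative integer vector of per-class counts.
#' @return named integer vector, all entries equal to \code{max(counts)}.
#' @examples
#' balanced_counts(c(Cyst = 3709, Normal = 5077, Stone = 1377, Tumor = 2283))
#' @export
balanced_counts <- function(counts) {
  if (length(counts) == 0 || any(counts < 0)) {
    stop_invalid("`counts` must be non-negative")
  }
  out <- rep(max(counts), length(counts))
  names(out) <- names(counts)
  out
}

#' Balance a dataset by augmentation
#'
#' Raises every class to the size of the largest class by appending augmented
#' copies of uniformly resampled members of that class.  Originals are kept
#' unmodified; copies are flagged \code{"augmented"} and remember their
#' source index so splits can keep derived copies with their source.
#'
#' @param data an [image_set()].
#' @param aug an [augmentation_config()]; defaults to the fixed balancing
#'   settings (30 degree rotation, 20\% shifts/shear/zoom, both flips,
#'   brightness \[0.8, 1.2\]).
#' @param seed optional seed applied locally.
#' @return a balanced [image_set()].
#' @export
balance_by_augmentation <- function(data, aug = augmentation_config(),
                                    seed = NULL) {
  stopifnot(inherits(data, "image_set"))
  if (!is.null(seed)) {
    return(with_seed(seed, balance_by_augmentation(data, aug)))
  }
  counts <- class_counts(data)
  if (any(counts == 0)) {
    stop("cannot balance: class(es) with no images: ",
         paste(names(counts)[counts == 0], collapse = ", "), call. = FALSE)
  }
  target <- max(counts)
  images <- data$images
  labels <- data$labels
  provenance <- data$provenance
  source <- data$source
  for (cl in data$class_names) {
    deficit <- target - counts[[cl]]
    if (deficit == 0) next
    pool <- which(data$labels == cl)
    picks <- pool[sample.int(length(pool), deficit, replace = TRUE)]
    for (p in picks) {
      images <- c(images, list(augment_image(data$images[[p]], aug)))
      labels <- c(labels, cl)
      provenance <- c(provenance, "augmented")
      source <- c(source, p)
    }
  }
  image_set(images, labels, data$class_names, provenance, source)
}

#' Stratified train/validation/test split
#'
#' Shuffles within each class and carves off the test share first, then the
#' validation share from the remaining training portion.  With
#' \code{group_by_source = TRUE} (default), augmented copies travel with
#' their source image so derived copies never leak across partitions; set it
#' to \code{FALSE} for a plain per-image shuffle split.
#'
#' @param data an [image_set()].
#' @param train_ratio share of each class kept for training + validation
#'   (default 0.85; the remaining 15\% is the test set).
#' @param val_ratio share of the training portion carved off for validation
#'   (default 0.15).
#' @param seed optional seed applied locally.
#' @param group_by_source keep augmented copies in their source's partition.
#' @return list with \code{train}, \code{validation}, \code{test}
#'   image sets (disjoint, exhaustive).
#' @export
split_dataset <- function(data, train_ratio = 0.85, val_ratio = 0.15,
                          seed = NULL, group_by_source = TRUE) {
  stopifnot(inherits(data, "image_set"))
  assert_number(train_ratio, "train_ratio", lo = 1e-9, hi = 1 - 1e-9)
  assert_number(val_ratio, "val_ratio", lo = 0, hi = 1 - 1e-9)
  if (!is.null(seed)) {
    return(with_seed(seed,
      split_dataset(data, train_ratio, val_ratio,
                    group_by_source = group_by_source)))
  }
  counts <- class_counts(data)
  small <- counts[counts < 3 & counts > 0]
  if (length(small)) {
    stop("class(es) with fewer than 3 images cannot be split: ",
         paste(names(small), collapse = ", "), call. = FALSE)
  }
  test_idx <- integer(0); val_idx <- integer(0); train_idx <- integer(0)
  for (cl in data$class_names) {
    members <- which(data$labels == cl)
    if (!length(members)) next
    n <- length(members)
    n_test <- round((1 - train_ratio) * n)
    if (group_by_source) {
      # whole source groups (an original plus its augmented copies) are
      # assigned to one partition, so derived copies never leak across
      group_of <- ifelse(is.na(data$source[members]), members,
                         data$source[members])
      groups <- split(members, group_of)
      groups <- groups[sample.int(length(groups))]
      sizes <- lengths(groups)
      cum <- cumsum(sizes)
      k_test <- if (n_test <= 0) 0L else which(cum >= n_test)[1]
      cls_test <- unlist(groups[seq_len(k_test)], use.names = FALSE)
      remaining <- if (k_test < length(groups)) {
        groups[(k_test + 1):length(groups)]
      } else list()
      n_rest <- n - length(cls_test)
      n_val <- round(val_ratio * n_rest)
      cumr <- cumsum(lengths(remaining))
      k_val <- if (n_val <= 0 || !length(remaining)) 0L else {
        w <- which(cumr >= n_val)
        if (length(w)) w[1] else length(remaining)
      }
      cls_val <- unlist(remaining[seq_len(k_val)], use.names = FALSE)
      cls_train <- unlist(
        if (k_val < length(remaining)) remaining[(k_val + 1):length(remaining)]
        else list(), use.names = FALSE)
    } else {
      members <- members[sample.int(n)]
      cls_test <- members[seq_len(n_test)]
      rest <- setdiff(members, cls_test)
      n_val <- round(val_ratio * length(rest))
      cls_val <- rest[seq_len(n_val)]
      cls_train <- setdiff(rest, cls_val)
    }
    test_idx <- c(test_idx, cls_test)
    val_idx <- c(val_idx, cls_val)
    train_idx <- c(train_idx, cls_train)
  }
  list(train = subset_image_set(data, train_idx),
       validation = subset_image_set(data, val_idx),
       test = subset_image_set(data, test_idx))
}

# --- directory I/O (ASCII PPM/PGM trees) -----------------------------------

#' Read and write class-per-subdirectory image trees
#'
#' Plain-text portable pixmaps are used as the on-disk format: color images
#' as ASCII PPM (magic \code{P3}) and grayscale as ASCII PGM (\code{P2}),
#' with one subdirectory per class.  \code{write_image_dir()} rounds
#' intensities to integers in \[0, 255\].
#'
#' @param path directory whose subdirectories are class names.
#' @return \code{read_image_dir()}: an [image_set()].
#' @export
read_image_dir <- function(path) {
  if (!dir.exists(path)) stop_invalid("no such directory: ", path)
  classes <- sort(list.dirs(path, recursive = FALSE, full.names = FALSE))
  if (!length(classes)) stop_invalid("no class subdirectories under ", path)
  images <- list(); labels <- character(0)
  for (cl in classes) {
    files <- sort(list.files(file.path(path, cl),
                             pattern = "\\.(ppm|pgm)$", full.names = TRUE))
    for (f in files) {
      images <- c(images, list(read_pnm(f)))
      labels <- c(labels, cl)
    }
  }
  image_set(images, labels, class_names = classes)
}

#' @rdname read_image_dir
#' @param data an [image_set()] to write.
#' @export
write_image_dir <- function(data, path) {
  stopifnot(inherits(data, "image_set"))
  for (cl in data$class_names) {
    dir.create(file.path(path, cl), recursive = TRUE, showWarnings = FALSE)
  }
  counters <- stats::setNames(integer(length(data$class_names)),
                              data$class_names)
  for (i in seq_along(data$images)) {
    cl <- data$labels[i]
    counters[cl] <- counters[cl] + 1L
    f <- file.path(path, cl, sprintf("img_%05d.ppm", counters[cl]))
    write_pnm(data$images[[i]], f)
  }
  invisible(path)
}

read_pnm <- function(file) {
  tokens <- scan(file, what = character(), quiet = TRUE, comment.char = "#")
  magic <- tokens[1]
  if (!magic %in% c("P2", "P3")) {
    stop_invalid(file, ": unsupported format `", magic,
                 "` (ASCII P2/P3 only)")
  }
  vals <- as.numeric(tokens[-1])
  w <- vals[1]; h <- vals[2]; maxval <- vals[3]
  px <- vals[-(1:3)] * (255 / maxval)
  if (magic == "P2") {
    img <- matrix(px, nrow = h, ncol = w, byrow = TRUE)
    array(rep(img, 3), c(h, w, 3))
  } else {
    # P3 stores r g b per pixel in row-major order
    r <- px[seq(1, length(px), 3)]
    g <- px[seq(2, length(px), 3)]
    b <- px[seq(3, length(px), 3)]
    out <- array(0, c(h, w, 3))
    out[, , 1] <- matrix(r, h, w, byrow = TRUE)
    out[, , 2] <- matrix(g, h, w, byrow = TRUE)
    out[, , 3] <- matrix(b, h, w, byrow = TRUE)
    out
  }
}

write_pnm <- function(image, file) {
  d <- dim(image)
  if (length(d) == 2) image <- array(image, c(d, 1L))
  d <- dim(image)
  vals <- round(clamp(image, 0, 255))
  con <- file(file, "w")
  on.exit(close(con))
  if (d[3] == 1L) {
    writeLines(c("P2", paste(d[2], d[1]), "255"), con)
    body <- apply(vals[, , 1], 1, paste, collapse = " ")
  } else {
    writeLines(c("P3", paste(d[2], d[1]), "255"), con)
    body <- apply(vals, 1, function(row) {
      paste(as.vector(t(row)), collapse = " ")
    })
  }
  writeLines(body, con)
  invisible(file)
}
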