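test_that("backbone names are validated and freezing follows the learn ratio", {
  expect_error(build_model("resnet99", training_config(), 4),
               "valid names")

  full <- build_model("surrogate-tiny",
                      training_config(tl_learn_ratio = 100), 4)
  expect_true(all(vapply(full$blocks, `[[`, TRUE, "trainable")))

  top1 <- build_model("surrogate-tiny", training_config(tl_learn_ratio = 1), 4)
  expect_equal(vapply(top1$blocks, `[[`, TRUE, "trainable"),
               c(FALSE, FALSE, TRUE))

  # trainable parameter count is non-decreasing in the learn ratio
  ratios <- c(1, 25, 40, 67, 80, 100)
  counts <- vapply(ratios, function(r) {
    n_trainable_params(build_model("surrogate-tiny",
                                   training_config(tl_learn_ratio = r), 4))
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))

  expect_warning(build_model("VGG16", training_config(), 4), "synthetic")
})

test_that("forward passes produce probability rows summing to one", {
  m <- build_model("surrogate-tiny", training_config(scaler = "minmax"), 4,
                   input_size = 32, class_names = paste0("k", 1:4))
  set.seed(10)
  imgs <- lapply(1:5, function(i) array(runif(32 * 32 * 3, 0, 255),
                                        c(32, 32, 3)))
  probs <- predict(m, imgs)
  expect_equal(dim(probs), c(5, 4))
  expect_true(all(abs(rowSums(probs) - 1) < 1e-6))
  expect_identical(colnames(probs), paste0("k", 1:4))
})

test_that("the surrogate learns linearly separable blobs within 5 epochs", {
  blobs <- blob_image_set(n_per_class = 16, size = 16, seed = 5)
  parts <- split_dataset(blobs, 0.7, val_ratio = 0.3, seed = 2)
  cfg <- training_config(loss = "categorical_crossentropy", batch_size = 8,
                         optimizer = "adam", scaler = "minmax",
                         tl_learn_ratio = 100)
  res <- evaluate_fitness("surrogate-tiny", cfg, parts$train,
                          parts$validation, epochs = 5, seed = 3)
  expect_false(res$diverged)
  expect_gte(res$score, 0.95)
})

test_that("a single batch is memorized after heavy overfitting", {
  blobs <- blob_image_set(n_per_class = 4, size = 16, seed = 6)
  cfg <- training_config(batch_size = 8, optimizer = "adam",
                         scaler = "minmax", tl_learn_ratio = 100)
  m <- build_model("surrogate-tiny", cfg, 2, input_size = 16,
                   class_names = blobs$class_names)
  m <- train_classifier(m, blobs, epochs = 60, seed = 8)
  probs <- predict(m, blobs)
  pred <- colnames(probs)[max.col(probs)]
  expect_equal(mean(pred == blobs$labels), 1.0)
})

test_that("fitness is deterministic under a fixed seed", {
  blobs <- blob_image_set(n_per_class = 8, size = 16, seed = 7)
  parts <- split_dataset(blobs, 0.7, val_ratio = 0.3, seed = 2)
  cfg <- training_config(batch_size = 4, optimizer = "rmsprop",
                         scaler = "standard", dropout = 0.3)
  r1 <- evaluate_fitness("surrogate-tiny", cfg, parts$train,
                         parts$validation, epochs = 2, seed = 11)
  r2 <- evaluate_fitness("surrogate-tiny", cfg, parts$train,
                         parts$validation, epochs = 2, seed = 11)
  expect_identical(r1$score, r2$score)
})

test_that("every decodable configuration yields a usable fitness result", {
  blobs <- blob_image_set(n_per_class = 5, size = 16, seed = 9)
  parts <- split_dataset(blobs, 0.7, val_ratio = 0.3, seed = 4)
  space <- search_space()
  set.seed(55)
  for (i in 1:12) {
    cfg <- decode_solution(runif(15), space)
    res <- evaluate_fitness("surrogate-tiny", cfg, parts$train,
                            parts$validation, epochs = 1, seed = i)
    expect_s3_class(res, "fitness_result")
    expect_true(res$score >= 0 && res$score <= 1)
  }
})

test_that("failures surface as zero-score results, not errors", {
  blobs <- blob_image_set(n_per_class = 5, size = 16, seed = 13)
  parts <- split_dataset(blobs, 0.7, val_ratio = 0.3, seed = 4)
  # 15x15 inputs cannot pass three 2x2 pooling stages: build_model errors,
  # evaluate_fitness must absorb it
  broken <- image_set(lapply(parts$train$images,
                             function(i) i[1:15, 1:15, , drop = FALSE]),
                      parts$train$labels, parts$train$class_names)
  res <- evaluate_fitness("surrogate-tiny", training_config(), broken,
                          parts$validation, epochs = 1, seed = 1)
  expect_equal(res$score, 0)
  expect_true(res$diverged)
  expect_match(res$diagnostic, "multiple of 8")
})

test_that("augmented training runs and stays in range", {
  blobs <- blob_image_set(n_per_class = 6, size = 16, seed = 21)
  parts <- split_dataset(blobs, 0.7, val_ratio = 0.3, seed = 5)
  cfg <- training_config(batch_size = 4, augment = TRUE,
                         augmentation = augmentation_config(
                           rotation_deg = 10, width_shift = 0.1,
                           height_shift = 0.1, shear = 0.05, zoom = 0.1,
                           brightness_range = c(0.9, 1.1)),
                         scaler = "minmax")
  res <- evaluate_fitness("surrogate-tiny", cfg, parts$train,
                          parts$validation, epochs = 2, seed = 17)
  expect_false(res$diverged)
  expect_gte(res$score, 0)
  expect_equal(res$epochs_run, 2)
})

test_that("paper-faithful evaluation scores the union of the provided sets", {
  blobs <- blob_image_set(n_per_class = 6, size = 16, seed = 30)
  parts <- split_dataset(blobs, 0.7, val_ratio = 0.3, seed = 6)
  res <- evaluate_fitness("surrogate-tiny", training_config(scaler = "minmax"),
                          parts$train, parts$validation, epochs = 1,
                          seed = 2, mode = "paper-faithful")
  n_union <- length(parts$train$images) + length(parts$validation$images)
  expect_equal(res$metric_report$counts$n_samples, n_union)
  expect_identical(res$mode, "paper-faithful")
})

test_that("the cascade routes by stage-1 label and grades tumors", {
  ct <- generate_image_set(fixture_spec(
    n_classes = 4, per_class_counts = rep(10, 4), image_size = 16,
    signal_strength = 1, noise_sd = 3, seed = 41))
  histo <- generate_image_set(fixture_spec(
    n_classes = 5, per_class_counts = rep(8, 5), image_size = 16,
    signal_strength = 1, noise_sd = 3, seed = 42))
  cfg <- training_config(batch_size = 8, optimizer = "adam",
                         scaler = "minmax", tl_learn_ratio = 100)
  ct_model <- train_classifier(
    build_model("surrogate-tiny", cfg, 4, 16, ct$class_names),
    ct, epochs = 6, seed = 1)
  histo_model <- train_classifier(
    build_model("surrogate-tiny", cfg, 5, 16, histo$class_names),
    histo, epochs = 6, seed = 2)

  grades <- paste("Grade", 0:4)
  for (i in seq_along(ct$images)) {
    rec <- cascade_predict(ct_model, histo_model, ct$images[[i]],
                           histo$images[[1]])
    expect_true(rec$stage1_label %in% ct$class_names)
    if (rec$stage1_label == "Tumor") {
      expect_true(rec$grade %in% grades)
      expect_identical(rec$note, "graded")
    } else {
      expect_true(is.na(rec$grade))
      expect_identical(rec$note,
                       if (rec$stage1_label == "Normal") "no further grading"
                       else "other treatments")
    }
    rec2 <- cascade_predict(ct_model, histo_model, ct$images[[i]], NULL)
    if (rec2$stage1_label == "Tumor") {
      expect_identical(rec2$note, "grading pending")
      expect_true(is.na(rec2$grade))
    }
  }
})
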