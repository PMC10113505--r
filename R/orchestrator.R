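# End-to-end search: balance -> split -> SpaSA loop, where each fitness call
# decodes a solution, preprocesses with the decoded scaler/augmentation,
# trains a few epochs, and scores.  One master seed is split hierarchically
# into component seeds (data, balancing, splitting, evaluation, optimizer)
# so changing one component cannot desynchronize the others.

#' Configure a search run
#'
#' @param dataset a [fixture_spec()] (generated at run time), an
#'   [image_set()], or a path to a class-per-subdirectory PPM/PGM tree.
#' @param backbone backbone name or [backbone_spec()].
#' @param spasa a [spasa_config()]; its \code{seed} is overridden by the
#'   run's derived optimizer seed.
#' @param space a [search_space()].
#' @param train_ratio,val_ratio split shares (see [split_dataset()]).
#' @param epochs training epochs per fitness evaluation.
#' @param eval_mode \code{"holdout"} or \code{"paper-faithful"} (see
#'   [evaluate_fitness()]).
#' @param balance apply augmentation-based class balancing before splitting.
#' @param final_test retrain the best configuration and report metrics on
#'   the untouched test partition.
#' @param output_dir optional directory for the JSON-lines evaluation log
#'   and the final result JSON.
#' @param checkpoint_path optional optimizer checkpoint (enables
#'   [run_search()]'s \code{resume_from}).
#' @param seed master seed for the whole run.
#' @return a \code{run_config} object.
#' @export
run_config <- function(dataset, backbone = "surrogate-tiny",
                       spasa = spasa_config(), space = search_space(),
                       train_ratio = 0.85, val_ratio = 0.15, epochs = 5,
                       eval_mode = c("holdout", "paper-faithful"),
                       balance = TRUE, final_test = TRUE, output_dir = NULL,
                       checkpoint_path = NULL, seed = 1) {
  eval_mode <- match.arg(eval_mode)
  stopifnot(inherits(spasa, "spasa_config"), inherits(space, "search_space"))
  assert_number(seed, "seed", integer = TRUE)
  structure(
    list(dataset = dataset, backbone = backbone, spasa = spasa,
         space = space, train_ratio = train_ratio, val_ratio = val_ratio,
         epochs = epochs, eval_mode = eval_mode, balance = isTRUE(balance),
         final_test = isTRUE(final_test), output_dir = output_dir,
         checkpoint_path = checkpoint_path, seed = as.integer(seed)),
    class = "run_config"
  )
}

derive_seeds <- function(seed) {
  with_seed(seed, {
    s <- sample.int(2147483587L, 5)
    list(data = s[1], balance = s[2], split = s[3], evaluate = s[4],
         optimizer = s[5])
  })
}

resolve_dataset <- function(dataset) {
  if (inherits(dataset, "image_set")) return(dataset)
  if (inherits(dataset, "fixture_spec")) return(generate_image_set(dataset))
  if (is.character(dataset)) return(read_image_dir(dataset))
  stop_invalid("`dataset` must be an image_set, fixture_spec, or path")
}

#' Run the full hyperparameter search
#'
#' Loads or generates the dataset, balances it (optional), splits it with
#' source-grouped stratification, then runs the SpaSA loop.  Each fitness
#' evaluation decodes the solution, trains, and scores under a fixed
#' per-run evaluation seed, so fitness is a deterministic function of the
#' solution and the whole run is reproducible from its master seed.  The
#' test partition is untouched during the search and only used for the
#' optional final report.
#'
#' @param config a [run_config()].
#' @param resume_from optional checkpoint path from an interrupted run with
#'   the same configuration.
#' @return a \code{run_result}: best decoded \code{training_config}, best
#'   score, best encoded solution, per-iteration history, evaluation log
#'   (data.frame), optional \code{test_report}, and an environment echo.
#' @export
run_search <- function(config, resume_from = NULL) {
  stopifnot(inherits(config, "run_config"))
  seeds <- derive_seeds(config$seed)
  data <- resolve_dataset(config$dataset)
  if (config$balance) {
    data <- balance_by_augmentation(data, seed = seeds$balance)
  }
  parts <- split_dataset(data, config$train_ratio, config$val_ratio,
                         seed = seeds$split)

  log_env <- new.env(parent = emptyenv())
  log_env$rows <- list()
  log_con <- NULL
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    log_con <- file(file.path(config$output_dir, "evaluations.jsonl"), "w")
    on.exit(close(log_con), add = TRUE)
  }

  fitness <- function(x) {
    decoded <- decode_solution(x, config$space)
    res <- evaluate_fitness(config$backbone, decoded, parts$train,
                            parts$validation, epochs = config$epochs,
                            seed = seeds$evaluate, mode = config$eval_mode)
    row <- c(list(score = res$score, diverged = res$diverged,
                  epochs_run = res$epochs_run), config_record(decoded))
    log_env$rows[[length(log_env$rows) + 1L]] <- row
    if (!is.null(log_con)) {
      writeLines(jsonlite::toJSON(row, auto_unbox = TRUE, digits = NA),
                 log_con)
    }
    res$score
  }

  spasa_cfg <- config$spasa
  spasa_cfg$seed <- seeds$optimizer
  dimension <- length(config$space$dims)
  opt <- if (is.null(resume_from)) {
    spasa_optimize(fitness, spasa_cfg, dimension,
                   checkpoint_path = config$checkpoint_path)
  } else {
    spasa_resume(resume_from, fitness, spasa_cfg)
  }

  best_config <- decode_solution(opt$best_solution, config$space)
  evaluations <- do.call(rbind, lapply(log_env$rows, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE)
  }))

  test_report <- NULL
  if (config$final_test && length(parts$test$images) > 0) {
    final <- evaluate_fitness(config$backbone, best_config, parts$train,
                              parts$validation, evaluation_set = parts$test,
                              epochs = config$epochs, seed = seeds$evaluate,
                              mode = config$eval_mode)
    test_report <- final$metric_report
  }

  result <- structure(
    list(best_config = best_config, best_score = opt$best_score,
         best_solution = opt$best_solution, history = opt$history,
         evaluations = evaluations, test_report = test_report,
         partitions = parts,
         environment = list(r_version = R.version.string,
                            package = "spasatune", seed = config$seed)),
    class = "run_result"
  )
  if (!is.null(config$output_dir)) {
    summary <- list(
      best_config = config_record(best_config),
      best_score = opt$best_score,
      best_solution = opt$best_solution,
      history = opt$history,
      test_metrics = if (!is.null(test_report)) {
        as.data.frame(test_report)
      },
      environment = result$environment
    )
    jsonlite::write_json(summary,
                         file.path(config$output_dir, "run_result.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (!is.null(evaluations)) {
      utils::write.csv(evaluations,
                       file.path(config$output_dir, "evaluations.csv"),
                       row.names = FALSE)
    }
  }
  result
}

#' @export
print.run_result <- function(x, ...) {
  cat("<run_result> best score:", format(x$best_score, digits = 4),
      "over", nrow(x$evaluations), "evaluations\n")
  print(x$best_config)
  invisible(x)
}

#' Run the two-stage cascade over a batch of images
#'
#' Applies [cascade_predict()] to every CT image (with an optional aligned
#' histopathology image) and assembles a per-image report.
#'
#' @param ct_model,histo_model trained stage models.
#' @param ct_images an [image_set()] or list of raw CT images.
#' @param histo_images optional list parallel to \code{ct_images} (NULL
#'   entries allowed) of histopathology images for tumor cases.
#' @param trigger_class stage-1 label that routes to stage 2.
#' @return a data.frame with one row per image: \code{stage1_label},
#'   \code{stage1_confidence}, \code{grade}, \code{grade_confidence},
#'   \code{note}, plus \code{true_label} when \code{ct_images} carries
#'   labels.
#' @export
run_cascade <- function(ct_model, histo_model, ct_images,
                        histo_images = NULL, trigger_class = "Tumor") {
  labels <- NULL
  if (inherits(ct_images, "image_set")) {
    labels <- ct_images$labels
    ct_images <- ct_images$images
  }
  n <- length(ct_images)
  if (!is.null(histo_images)) stopifnot(length(histo_images) == n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    histo <- if (is.null(histo_images)) NULL else histo_images[[i]]
    rec <- cascade_predict(ct_model, histo_model, ct_images[[i]],
                           histo, trigger_class = trigger_class)
    rows[[i]] <- data.frame(
      stage1_label = rec$stage1_label,
      stage1_confidence = rec$stage1_confidence,
      grade = rec$grade, grade_confidence = rec$grade_confidence,
      note = rec$note, stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  if (!is.null(labels)) out$true_label <- labels
  out
}
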