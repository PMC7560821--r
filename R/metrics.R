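#' Evaluate a trained network on a labeled feature cube
#'
#' Computes the study's accuracy surface: the confusion matrix (reference
#' classes in rows, predictions in columns), overall accuracy, and per-class
#' precision, recall and F-1 score, all in percent. Predictions are the
#' argmax of the sequence-level class probabilities, ties broken toward the
#' lowest class index.
#'
#' @param model A trained `bilstm_model`.
#' @param test_cube A labeled `feature_cube` (standardized with the training
#'   statistics).
#' @param n_train,split_mode,seed Optional provenance fields recorded in the
#'   report.
#' @return An object of class `metrics_report` with elements
#'   `overall_accuracy`, `per_class` (data frame: class, precision, recall,
#'   f1), `confusion_matrix`, `n_test`, and the provenance fields.
#' @export
evaluate <- function(model, test_cube, n_train = NA_integer_,
                     split_mode = NA_character_, seed = NA_integer_) {
  stopifnot(inherits(model, "bilstm_model"),
            inherits(test_cube, "feature_cube"))
  if (is.null(test_cube$labels) || !length(test_cube$labels))
    stop("test cube is empty or unlabeled")
  if (!identical(test_cube$class_names, model$class_names))
    stop("test cube class set does not match the model's")
  pred <- predict_classes(model, test_cube$values)
  report_from_predictions(test_cube$labels, pred, model$class_names,
                          n_train = n_train, split_mode = split_mode,
                          seed = seed)
}

# metrics from integer truth/prediction vectors
report_from_predictions <- function(truth, pred, class_names,
                                    n_train = NA_integer_,
                                    split_mode = NA_character_,
                                    seed = NA_integer_) {
  k <- length(class_names)
  cm <- table(factor(truth, levels = seq_len(k)),
              factor(pred, levels = seq_len(k)))
  cm <- matrix(as.integer(cm), k, k,
               dimnames = list(reference = class_names,
                               predicted = class_names))
  structure(c(metrics_from_confusion(cm),
              list(n_test = length(truth), n_train = n_train,
                   split_mode = split_mode, seed = seed)),
            class = "metrics_report")
}

#' Accuracy metrics from a confusion matrix
#'
#' @param cm Square confusion matrix, reference classes in rows and
#'   predicted classes in columns.
#' @return List with `overall_accuracy` (percent), `per_class` data frame
#'   (precision, recall, f1 in percent; 0 where undefined), and the matrix.
#' @export
metrics_from_confusion <- function(cm) {
  stopifnot(is.matrix(cm), nrow(cm) == ncol(cm))
  total <- sum(cm)
  diagv <- diag(cm)
  rs <- rowSums(cm)  # reference counts
  cs <- colSums(cm)  # prediction counts
  recall <- ifelse(rs > 0, diagv / rs, 0)
  precision <- ifelse(cs > 0, diagv / cs, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  list(
    overall_accuracy = 100 * sum(diagv) / total,
    per_class = data.frame(class = rownames(cm),
                           precision = 100 * precision,
                           recall = 100 * recall,
                           f1 = 100 * f1, row.names = NULL),
    confusion_matrix = cm
  )
}

#' @export
print.metrics_report <- function(x, digits = 1, ...) {
  cat(sprintf("<metrics_report> overall accuracy %.*f%% on %d test samples",
              digits, x$overall_accuracy, x$n_test))
  if (!is.na(x$split_mode)) cat(" (", x$split_mode, " split)", sep = "")
  cat("\n")
  df <- x$per_class
  df[-1] <- lapply(df[-1], round, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Serialize a metrics report
#'
#' Writes the report as JSON, the per-class table as a CSV mirroring the
#' study's class-performance table (class, precision %, recall %, F-1 %),
#' and the confusion matrix as CSV.
#'
#' @param report A `metrics_report`.
#' @param json_path,table_path,confusion_path Output paths (`NULL` to skip).
#' @export
write_metrics <- function(report, json_path = NULL, table_path = NULL,
                          confusion_path = NULL) {
  stopifnot(inherits(report, "metrics_report"))
  if (!is.null(json_path)) {
    obj <- list(overall_accuracy = report$overall_accuracy,
                per_class = report$per_class,
                confusion_matrix = unclass(report$confusion_matrix),
                n_test = report$n_test, n_train = report$n_train,
                split_mode = report$split_mode, seed = report$seed)
    jsonlite::write_json(obj, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  if (!is.null(table_path))
    utils::write.csv(report$per_class, table_path, row.names = FALSE)
  if (!is.null(confusion_path))
    utils::write.csv(as.data.frame(report$confusion_matrix),
                     confusion_path)
  invisible(report)
}

#' Train and evaluate a set of architecture variants
#'
#' Trains each configuration on the same training cube and evaluates on the
#' same test cube (identical split and data across variants), mirroring the
#' study's comparison of 1-, 2-, 3- and 4-layer BiLSTM networks. Per-run
#' failures are recorded and the sweep continues.
#'
#' @param configs List of [training_config()] objects.
#' @param train_cube,test_cube Standardized labeled feature cubes.
#' @return Data frame with one row per variant (`n_layers`, `hidden_size`,
#'   `overall_accuracy`, `n_train`, `n_test`, `elapsed_sec`, `error`);
#'   the full `metrics_report`s and loss histories are attached as
#'   attributes `reports` and `histories`.
#' @export
architecture_sweep <- function(configs, train_cube, test_cube) {
  stopifnot(length(configs) >= 1)
  rows <- list(); reports <- list(); histories <- list()
  for (i in seq_along(configs)) {
    cfg <- configs[[i]]
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch({
      model <- train(cfg, train_cube)
      rep <- evaluate(model, test_cube,
                      n_train = dim(train_cube$values)[1L], seed = cfg$seed)
      list(report = rep, history = model$history, error = NA_character_)
    }, error = function(e) list(report = NULL, history = NULL,
                                error = conditionMessage(e)))
    elapsed <- proc.time()[["elapsed"]] - t0
    rows[[i]] <- data.frame(
      n_layers = cfg$n_layers, hidden_size = cfg$hidden_size,
      overall_accuracy = if (is.null(res$report)) NA_real_
                         else res$report$overall_accuracy,
      n_train = dim(train_cube$values)[1L],
      n_test = dim(test_cube$values)[1L],
      elapsed_sec = elapsed, error = res$error)
    reports[[i]] <- res$report
    histories[[i]] <- res$history
  }
  out <- do.call(rbind, rows)
  attr(out, "reports") <- reports
  attr(out, "histories") <- histories
  out
}
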