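#' Add calibrated Gaussian noise to one predictor or one date
#'
#' The added-noise perturbation behind the relevance analysis: Gaussian
#' white noise N(0, sigma^2) with sigma^2 equal to `noise_fraction` (default
#' 3%) of the perturbed signal's amplitude, where amplitude is the max-min
#' range of the targeted values over the evaluation samples. In predictor
#' mode the noise is added to a single predictor at all timesteps; in date
#' mode to all 14 predictors at a single timestep (amplitude then measured
#' per predictor at that date). Untargeted entries are returned bit-for-bit
#' unchanged.
#'
#' An alternative reading of the calibration — sigma (not sigma^2) equal to
#' `noise_fraction` of the amplitude — is available via
#' `sd_rule = "sd_fraction"`.
#'
#' @param cube A `feature_cube`.
#' @param mode `"predictor"` or `"date"`.
#' @param index Predictor index (1--14) or timestep index (1--30).
#' @param noise_fraction Fraction of the signal amplitude used as the noise
#'   variance (default 0.03).
#' @param sd_rule `"variance_fraction"` (sigma^2 = fraction x amplitude,
#'   the default) or `"sd_fraction"` (sigma = fraction x amplitude).
#' @return A perturbed copy of the cube.
#' @export
perturb <- function(cube, mode = c("predictor", "date"), index,
                    noise_fraction = 0.03,
                    sd_rule = c("variance_fraction", "sd_fraction")) {
  stopifnot(inherits(cube, "feature_cube"))
  mode <- match.arg(mode)
  sd_rule <- match.arg(sd_rule)
  d <- dim(cube$values)
  max_idx <- if (mode == "predictor") d[3L] else d[2L]
  if (!is.numeric(index) || length(index) != 1L || index < 1 ||
      index > max_idx)
    stop("index must be a single value in 1..", max_idx, " for ", mode,
         " mode")
  if (any(!is.finite(cube$values))) stop("cube contains non-finite values")
  out <- cube
  noise_sd <- function(amplitude) {
    if (sd_rule == "variance_fraction") sqrt(noise_fraction * amplitude)
    else noise_fraction * amplitude
  }
  if (mode == "predictor") {
    slice <- cube$values[, , index]
    amp <- max(slice) - min(slice)
    if (amp == 0) {
      warning("predictor ", cube$feature_names[index],
              " has zero amplitude; perturbation is a no-op")
      return(out)
    }
    if (noise_fraction > 0)
      out$values[, , index] <- slice +
        stats::rnorm(length(slice), sd = noise_sd(amp))
  } else {
    for (j in seq_len(d[3L])) {
      slice <- cube$values[, index, j]
      amp <- max(slice) - min(slice)
      if (amp == 0) {
        warning("predictor ", cube$feature_names[j], " at timestep ", index,
                " has zero amplitude; left unperturbed")
        next
      }
      if (noise_fraction > 0)
        out$values[, index, j] <- slice +
          stats::rnorm(length(slice), sd = noise_sd(amp))
    }
  }
  out
}

#' Added-noise permutation relevance of predictors or dates
#'
#' Measures how much the classification leans on each input: the overall
#' accuracy on the unperturbed evaluation set is compared with the accuracy
#' after perturbing one predictor at all timesteps (predictor mode) or all
#' predictors at one timestep (date mode) with calibrated Gaussian noise
#' (see [perturb()]). The accuracy drop, averaged over `n_repeats` noise
#' draws, is the item's raw relevance; scores are normalized to the most
#' relevant item (so the top item scores exactly 1), with accidental
#' negative drops clipped to 0.
#'
#' @param model A trained `bilstm_model`.
#' @param cube A labeled, standardized `feature_cube` (typically the test
#'   set).
#' @param mode `"predictor"` (14 items) or `"date"` (30 items).
#' @param n_repeats Independent noise draws averaged per item (default 10).
#' @param noise_fraction See [perturb()].
#' @param seed Integer seed for the noise draws.
#' @param sd_rule See [perturb()].
#' @return An object of class `relevance_result`: `mode`, `item_names`,
#'   `scores` (normalized, in `[0, 1]`), `mean_drops` and
#'   `raw_accuracy_drops` (percentage points, per repeat),
#'   `baseline_accuracy` (%), `all_zero` flag, `n_repeats`,
#'   `noise_fraction`, `seed`.
#' @export
relevance <- function(model, cube, mode = c("predictor", "date"),
                      n_repeats = 10L, noise_fraction = 0.03, seed = 1L,
                      sd_rule = "variance_fraction") {
  stopifnot(inherits(model, "bilstm_model"), inherits(cube, "feature_cube"))
  mode <- match.arg(mode)
  if (is.null(cube$labels)) stop("cube carries no labels")
  if (dim(cube$values)[3L] != model$input_size)
    stop("cube has ", dim(cube$values)[3L], " predictors; model expects ",
         model$input_size)
  d <- dim(cube$values)
  n_items <- if (mode == "predictor") d[3L] else d[2L]
  item_names <- if (mode == "predictor") cube$feature_names
                else paste0("t", seq_len(d[2L]))
  baseline <- mean(predict_classes(model, cube$values) == cube$labels) * 100
  drops <- matrix(NA_real_, n_items, n_repeats,
                  dimnames = list(item_names, NULL))
  set.seed(seed)
  for (item in seq_len(n_items)) {
    for (r in seq_len(n_repeats)) {
      pc <- withCallingHandlers(
        perturb(cube, mode, item, noise_fraction, sd_rule),
        warning = function(w) invokeRestart("muffleWarning"))
      acc <- mean(predict_classes(model, pc$values) == cube$labels) * 100
      drops[item, r] <- baseline - acc
    }
  }
  mean_drops <- rowMeans(drops)
  clipped <- pmax(mean_drops, 0)
  all_zero <- max(clipped) <= 0
  scores <- if (all_zero) rep(0, n_items) else clipped / max(clipped)
  names(scores) <- item_names
  structure(list(
    mode = mode, item_names = item_names, scores = scores,
    mean_drops = mean_drops, raw_accuracy_drops = drops,
    baseline_accuracy = baseline, all_zero = all_zero,
    n_repeats = as.integer(n_repeats), noise_fraction = noise_fraction,
    seed = as.integer(seed)
  ), class = "relevance_result")
}

#' @export
print.relevance_result <- function(x, ...) {
  cat(sprintf(
    "<relevance_result> %s mode, baseline accuracy %.1f%%, %d repeats\n",
    x$mode, x$baseline_accuracy, x$n_repeats))
  top <- sort(x$scores, decreasing = TRUE)
  print(round(utils::head(top, 5L), 3))
  invisible(x)
}

#' Serialize a relevance result as JSON and CSV
#'
#' @param result A `relevance_result`.
#' @param json_path,csv_path Output paths (`NULL` to skip).
#' @export
write_relevance <- function(result, json_path = NULL, csv_path = NULL) {
  stopifnot(inherits(result, "relevance_result"))
  if (!is.null(json_path)) {
    obj <- list(mode = result$mode,
                scores = as.list(result$scores),
                mean_accuracy_drops = as.list(
                  stats::setNames(result$mean_drops, result$item_names)),
                baseline_accuracy = result$baseline_accuracy,
                all_zero = result$all_zero,
                n_repeats = result$n_repeats,
                noise_fraction = result$noise_fraction,
                seed = result$seed)
    jsonlite::write_json(obj, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  if (!is.null(csv_path))
    utils::write.csv(data.frame(item = result$item_names,
                                score = unname(result$scores),
                                mean_drop = unname(result$mean_drops)),
                     csv_path, row.names = FALSE)
  invisible(result)
}

#' Per-timestep class-probability evolution of one sample
#'
#' How the network's belief builds up over the agronomic year: the softmax
#' head applied to the last BiLSTM layer's output at every timestep. For an
#' annual crop such as rice the true-class probability typically stays low
#' through winter and rises sharply over the summer growing cycle.
#'
#' @param model A trained `bilstm_model`.
#' @param sequence One sample: a T x `input_size` matrix (all timesteps
#'   present).
#' @return T x n_classes matrix of probabilities; each row sums to 1.
#' @export
probability_evolution <- function(model, sequence) {
  stopifnot(inherits(model, "bilstm_model"))
  if (is.null(dim(sequence)) || length(dim(sequence)) != 2L)
    stop("sequence must be a T x input_size matrix for a single sample")
  if (ncol(sequence) != model$input_size)
    stop("sequence has ", ncol(sequence), " predictors; model expects ",
         model$input_size)
  fw <- network_forward(model, sequence, mode = "eval")
  out <- matrix(fw$prob_steps[1L, , ], nrow(sequence),
                length(model$class_names),
                dimnames = list(NULL, model$class_names))
  out
}

#' Hidden-unit activation summary
#'
#' Summarizes the last BiLSTM layer's activations in evaluation mode: the
#' per-unit per-timestep mean activation (heatmap), the mean squared
#' activation per acquisition date (averaged over units and samples), and,
#' optionally, the same temporal curve per class. When the class signal is
#' concentrated in one part of the year, the mean squared activation peaks
#' there.
#'
#' @param model A trained `bilstm_model`.
#' @param cube A `feature_cube` (labels required when `by_class = TRUE`).
#' @param by_class Also compute per-class mean squared activation curves.
#' @param chunk_size Samples per forward chunk.
#' @return An object of class `activation_summary`: `heatmap`
#'   (`2*hidden_size` x T), `mean_squared_by_date` (length T),
#'   `per_class_curves` (class x T matrix or `NULL`), `class_counts`,
#'   `n_samples`.
#' @export
activation_summary <- function(model, cube, by_class = FALSE,
                               chunk_size = 1024L) {
  stopifnot(inherits(model, "bilstm_model"), inherits(cube, "feature_cube"))
  d <- dim(cube$values)
  if (d[1L] == 0L) stop("cube contains no samples")
  if (by_class && is.null(cube$labels))
    stop("by_class = TRUE requires a labeled cube")
  n <- d[1L]; T_ <- d[2L]
  nu <- 2L * model$hidden_size
  sum_h <- matrix(0, nu, T_)
  sum_sq_t <- numeric(T_)
  n_classes <- length(model$class_names)
  sum_sq_class <- matrix(0, n_classes, T_)
  counts <- integer(n_classes)
  for (start in seq(1L, n, by = chunk_size)) {
    idx <- start:min(n, start + chunk_size - 1L)
    fw <- network_forward(model, cube$values[idx, , , drop = FALSE],
                          mode = "eval")
    H <- fw$hidden                       # chunk x T x units
    sum_h <- sum_h + t(apply(H, c(2L, 3L), sum))
    sq <- apply(H^2, c(1L, 2L), mean)    # chunk x T, mean over units
    sum_sq_t <- sum_sq_t + colSums(sq)
    if (by_class) {
      labs <- cube$labels[idx]
      for (k in unique(labs)) {
        sel <- labs == k
        sum_sq_class[k, ] <- sum_sq_class[k, ] +
          colSums(sq[sel, , drop = FALSE])
        counts[k] <- counts[k] + sum(sel)
      }
    }
  }
  per_class <- NULL
  if (by_class) {
    per_class <- sum_sq_class / ifelse(counts > 0, counts, NA_real_)
    rownames(per_class) <- model$class_names
  }
  structure(list(
    heatmap = sum_h / n,
    mean_squared_by_date = sum_sq_t / n,
    per_class_curves = per_class,
    class_counts = stats::setNames(counts, model$class_names),
    n_samples = n
  ), class = "activation_summary")
}

#' @export
print.activation_summary <- function(x, ...) {
  cat(sprintf(
    "<activation_summary> %d units x %d timesteps over %d samples; peak mean squared activation at timestep %d\n",
    nrow(x$heatmap), ncol(x$heatmap), x$n_samples,
    which.max(x$mean_squared_by_date)))
  invisible(x)
}
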