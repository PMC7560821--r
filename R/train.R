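#' Training configuration
#'
#' Hyperparameters for [train()]. Architecture defaults mirror the network
#' under study (2 BiLSTM layers, 100 hidden units per direction, 50%
#' dropout); the optimization defaults are the package's own: Adam at
#' learning rate 1e-3, batch size 256, up to 50 epochs with early stopping
#' (patience 8) on an internal 10% validation slice.
#'
#' @param n_layers Number of BiLSTM layers (1--4).
#' @param hidden_size Hidden units per direction.
#' @param dropout_rate Dropout fraction after each BiLSTM layer.
#' @param epochs Maximum training epochs.
#' @param batch_size Mini-batch size.
#' @param learning_rate Adam step size.
#' @param optimizer_name Only `"adam"` is implemented.
#' @param early_stopping_patience Epochs without validation improvement
#'   before stopping (0 disables early stopping).
#' @param validation_fraction Fraction of training samples held out
#'   internally for early stopping.
#' @param class_weights If `TRUE`, weight the loss by inverse class
#'   frequency (default `FALSE`: raw pixel counts, as in the study).
#' @param seed Integer seed governing initialization, shuffling and dropout.
#' @return An object of class `training_config`.
#' @export
training_config <- function(n_layers = 2L, hidden_size = 100L,
                            dropout_rate = 0.5, epochs = 50L,
                            batch_size = 256L, learning_rate = 1e-3,
                            optimizer_name = "adam",
                            early_stopping_patience = 8L,
                            validation_fraction = 0.1,
                            class_weights = FALSE, seed = 1L) {
  stopifnot(epochs >= 1, learning_rate > 0, batch_size >= 1,
            n_layers >= 1, n_layers <= 4,
            validation_fraction >= 0, validation_fraction < 1)
  if (!identical(optimizer_name, "adam"))
    stop("only the 'adam' optimizer is implemented")
  structure(list(
    n_layers = as.integer(n_layers), hidden_size = as.integer(hidden_size),
    dropout_rate = dropout_rate, epochs = as.integer(epochs),
    batch_size = as.integer(batch_size), learning_rate = learning_rate,
    optimizer_name = optimizer_name,
    early_stopping_patience = as.integer(early_stopping_patience),
    validation_fraction = validation_fraction,
    class_weights = class_weights, seed = as.integer(seed)
  ), class = "training_config")
}

# ---- parameter bookkeeping ----------------------------------------------

GATE_FIELDS <- c("W_c", "U_c", "b_c", "W_i", "U_i", "b_i",
                 "W_f", "U_f", "b_f", "W_o", "U_o", "b_o")

# flatten model parameters to a named list of arrays (and back)
flatten_params <- function(model) {
  out <- list()
  for (l in seq_len(model$n_layers)) {
    for (d in c("fwd", "bwd")) {
      for (f in GATE_FIELDS)
        out[[paste(l, d, f, sep = ".")]] <- model$layers[[l]][[d]][[f]]
    }
  }
  out$head_weights <- model$head_weights
  out$head_bias <- model$head_bias
  out
}

set_params <- function(model, params) {
  for (l in seq_len(model$n_layers)) {
    for (d in c("fwd", "bwd")) {
      for (f in GATE_FIELDS)
        model$layers[[l]][[d]][[f]] <- params[[paste(l, d, f, sep = ".")]]
    }
  }
  model$head_weights <- params$head_weights
  model$head_bias <- params$head_bias
  model
}

# split a combined 4h-row gradient (gate order c,i,f,o) into per-gate fields
split_gate_grads <- function(gW, gU, gb, h) {
  sl <- list(c = 1:h, i = (h + 1):(2 * h), f = (2 * h + 1):(3 * h),
             o = (3 * h + 1):(4 * h))
  out <- list()
  for (gname in names(sl)) {
    out[[paste0("W_", gname)]] <- gW[sl[[gname]], , drop = FALSE]
    out[[paste0("U_", gname)]] <- gU[sl[[gname]], , drop = FALSE]
    out[[paste0("b_", gname)]] <- gb[sl[[gname]]]
  }
  out
}

# ---- backpropagation through time ---------------------------------------

# BPTT through one direction of one layer.
# X: layer input (n x T x in); cache from lstm_forward_dir; dH: gradient on
# the aligned outputs (n x T x h); reverse: TRUE for the backward direction
# (which processed t = T..1, so BPTT runs t = 1..T).
dir_backward <- function(X, cache, params, dH, reverse) {
  n <- dim(X)[1L]; T_ <- dim(X)[2L]; in_sz <- dim(X)[3L]
  h <- params$hidden_size
  g <- combine_gates(params)
  gW <- matrix(0, 4L * h, in_sz); gU <- matrix(0, 4L * h, h)
  gb <- numeric(4L * h)
  dX <- array(0, c(n, T_, in_sz))
  dh_carry <- matrix(0, n, h); dc_carry <- matrix(0, n, h)
  ts <- if (reverse) seq_len(T_) else rev(seq_len(T_))
  for (t in ts) {
    cc <- cache[[t]]
    dh <- matrix(dH[, t, ], n) + dh_carry
    do_ <- dh * cc$tc
    dc <- dc_carry + dh * cc$o * (1 - cc$tc^2)
    dg <- dc * cc$i
    di <- dc * cc$g
    df <- dc * cc$c_prev
    da <- cbind(dg * (1 - cc$g^2),
                di * cc$i * (1 - cc$i),
                df * cc$f * (1 - cc$f),
                do_ * cc$o * (1 - cc$o))
    xt <- matrix(X[, t, ], n)
    gW <- gW + crossprod(da, xt)
    gU <- gU + crossprod(da, cc$h_prev)
    gb <- gb + colSums(da)
    dX[, t, ] <- da %*% g$W
    dh_carry <- da %*% g$U
    dc_carry <- dc * cc$f
  }
  c(split_gate_grads(gW, gU, gb, h), list(dX = dX))
}

# gradients of the mean cross-entropy of sequence-level predictions.
# fw: result of network_forward(..., keep_cache = TRUE); Y: one-hot matrix;
# w: optional per-sample weights (mean-normalized).
network_backward <- function(model, fw, x, Y, w = NULL) {
  n <- nrow(Y); T_ <- dim(x)[2L]; hs <- model$hidden_size
  dlogits <- (fw$prob_seq - Y) / n
  if (!is.null(w)) dlogits <- dlogits * (w / mean(w))
  grads <- list(
    head_weights = crossprod(dlogits, fw$final_state),
    head_bias = colSums(dlogits)
  )
  dFinal <- dlogits %*% model$head_weights
  dH <- array(0, c(n, T_, 2L * hs))
  dH[, T_, 1:hs] <- dH[, T_, 1:hs] + dFinal[, 1:hs]
  dH[, 1L, (hs + 1):(2 * hs)] <- dH[, 1L, (hs + 1):(2 * hs)] +
    dFinal[, (hs + 1):(2 * hs)]
  for (l in rev(seq_len(model$n_layers))) {
    cache_l <- fw$caches[[l]]
    if (!is.null(cache_l$mask)) dH <- dH * cache_l$mask
    dHf <- dH[, , 1:hs, drop = FALSE]
    dHb <- dH[, , (hs + 1):(2 * hs), drop = FALSE]
    bf <- dir_backward(cache_l$input, cache_l$fwd, model$layers[[l]]$fwd,
                       dHf, reverse = FALSE)
    bb <- dir_backward(cache_l$input, cache_l$bwd, model$layers[[l]]$bwd,
                       dHb, reverse = TRUE)
    for (f in GATE_FIELDS) {
      grads[[paste(l, "fwd", f, sep = ".")]] <- bf[[f]]
      grads[[paste(l, "bwd", f, sep = ".")]] <- bb[[f]]
    }
    dH <- bf$dX + bb$dX
  }
  grads
}

cross_entropy <- function(prob, Y, w = NULL) {
  p <- rowSums(prob * Y)
  p[p < 1e-12] <- 1e-12
  if (is.null(w)) -mean(log(p)) else -mean(w / mean(w) * log(p))
}

#' Train a stacked BiLSTM classifier
#'
#' Minimizes the categorical cross-entropy of the sequence-level class
#' probabilities by mini-batch Adam with full backpropagation through time.
#' A stratified internal validation slice drives early stopping; the
#' weights from the best validation epoch are restored. Deterministic given
#' the config seed.
#'
#' @param config A [training_config()].
#' @param train_cube A labeled, standardized `feature_cube` of training
#'   samples.
#' @return A trained `bilstm_model`; the per-epoch loss/accuracy history is
#'   attached as `model$history` and the config as `model$training_config`.
#' @export
train <- function(config, train_cube) {
  stopifnot(inherits(config, "training_config"),
            inherits(train_cube, "feature_cube"))
  if (is.null(train_cube$labels)) stop("train_cube carries no labels")
  class_names <- train_cube$class_names
  n_classes <- length(class_names)
  present <- sort(unique(train_cube$labels))
  if (length(setdiff(seq_len(n_classes), present)))
    stop("configured class(es) absent from training data: ",
         paste(class_names[setdiff(seq_len(n_classes), present)],
               collapse = ", "))
  if (length(present) < 2L) stop("training data must contain >= 2 classes")

  x <- train_cube$values
  n <- dim(x)[1L]
  labels <- train_cube$labels
  model <- new_network_model(
    input_size = dim(x)[3L], class_names = class_names,
    n_layers = config$n_layers, hidden_size = config$hidden_size,
    dropout_rate = config$dropout_rate,
    seed = derive_seed(config$seed, 1L))

  set.seed(derive_seed(config$seed, 2L))
  # stratified internal validation slice for early stopping
  val_idx <- integer(0)
  if (config$validation_fraction > 0 && config$early_stopping_patience > 0) {
    for (k in present) {
      idx <- which(labels == k)
      n_val <- floor(config$validation_fraction * length(idx))
      if (n_val >= 1 && n_val < length(idx))
        val_idx <- c(val_idx, sample(idx, n_val))
    }
  }
  fit_idx <- setdiff(seq_len(n), val_idx)

  Y <- matrix(0, n, n_classes)
  Y[cbind(seq_len(n), labels)] <- 1
  w <- NULL
  if (isTRUE(config$class_weights)) {
    freq <- tabulate(labels, n_classes)
    wc <- ifelse(freq > 0, 1 / freq, 0)
    w <- wc[labels]
  }

  params <- flatten_params(model)
  m_state <- lapply(params, function(p) p * 0)
  v_state <- lapply(params, function(p) p * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L
  best_val <- -Inf; best_params <- params; bad_epochs <- 0L
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        train_accuracy = numeric(0),
                        val_accuracy = numeric(0))

  for (epoch in seq_len(config$epochs)) {
    order_idx <- sample(fit_idx)
    batches <- split(order_idx,
                     ceiling(seq_along(order_idx) / config$batch_size))
    epoch_loss <- 0; epoch_n <- 0L; epoch_correct <- 0L
    for (b in batches) {
      xb <- x[b, , , drop = FALSE]
      Yb <- Y[b, , drop = FALSE]
      wb <- if (is.null(w)) NULL else w[b]
      fw <- network_forward(model, xb, mode = "train", keep_cache = TRUE)
      loss <- cross_entropy(fw$prob_seq, Yb, wb)
      if (!is.finite(loss))
        stop("non-finite training loss at epoch ", epoch,
             "; try a smaller learning rate")
      grads <- network_backward(model, fw, xb, Yb, wb)
      step <- step + 1L
      lr_t <- config$learning_rate *
        sqrt(1 - beta2^step) / (1 - beta1^step)
      for (nm in names(params)) {
        gmat <- grads[[nm]]
        m_state[[nm]] <- beta1 * m_state[[nm]] + (1 - beta1) * gmat
        v_state[[nm]] <- beta2 * v_state[[nm]] + (1 - beta2) * gmat^2
        params[[nm]] <- params[[nm]] -
          lr_t * m_state[[nm]] / (sqrt(v_state[[nm]]) + eps)
      }
      model <- set_params(model, params)
      epoch_loss <- epoch_loss + loss * length(b)
      epoch_n <- epoch_n + length(b)
      epoch_correct <- epoch_correct +
        sum(max.col(fw$prob_seq, ties.method = "first") == labels[b])
    }
    train_acc <- epoch_correct / epoch_n
    val_acc <- NA_real_
    if (length(val_idx)) {
      pv <- predict_classes(model, x[val_idx, , , drop = FALSE])
      val_acc <- mean(pv == labels[val_idx])
      if (val_acc > best_val + 1e-12) {
        best_val <- val_acc; best_params <- params; bad_epochs <- 0L
      } else {
        bad_epochs <- bad_epochs + 1L
      }
    }
    history <- rbind(history, data.frame(
      epoch = epoch, train_loss = epoch_loss / epoch_n,
      train_accuracy = train_acc, val_accuracy = val_acc))
    if (length(val_idx) && bad_epochs >= config$early_stopping_patience)
      break
  }
  if (length(val_idx)) model <- set_params(model, best_params)
  model$training_config <- config
  model$history <- history
  model
}

#' Predict class indices for a batch of sequences
#'
#' Argmax of the sequence-level class probabilities, computed in chunks to
#' bound memory; ties break toward the lowest class index.
#'
#' @param model A trained `bilstm_model`.
#' @param x Batch array (samples x T x predictors).
#' @param chunk_size Samples per forward chunk.
#' @return Integer vector of predicted class indices.
#' @export
predict_classes <- function(model, x, chunk_size = 1024L) {
  if (length(dim(x)) == 2L) x <- array(x, c(1L, dim(x)))
  n <- dim(x)[1L]
  out <- integer(n)
  for (start in seq(1L, n, by = chunk_size)) {
    idx <- start:min(n, start + chunk_size - 1L)
    fw <- network_forward(model, x[idx, , , drop = FALSE], mode = "eval")
    out[idx] <- max.col(fw$prob_seq, ties.method = "first")
  }
  out
}

# deterministic derivation of stage seeds from a master seed
derive_seed <- function(master, k) {
  as.integer((as.numeric(master) %% 1000003) * 1009 + k * 9973) %% 2147483647L
}
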