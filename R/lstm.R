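#' LSTM unit parameters
#'
#' One LSTM unit is parameterized by four gate blocks (candidate memory
#' c-tilde, input gate i, forget gate f, output gate o), each with an input
#' weight matrix `W_*` (hidden x input), a recurrent weight matrix `U_*`
#' (hidden x hidden) and a bias `b_*`. Weights initialize uniformly in
#' `±1/sqrt(hidden_size)`; the forget-gate bias starts at 1 (a common recipe
#' that lets early training retain memory), all other biases at 0.
#'
#' @param input_size,hidden_size Dimensions of the unit.
#' @return An object of class `lstm_params`.
#' @export
lstm_params <- function(input_size, hidden_size) {
  r <- 1 / sqrt(hidden_size)
  mk <- function(nr, nc) matrix(stats::runif(nr * nc, -r, r), nr, nc)
  structure(list(
    W_c = mk(hidden_size, input_size), U_c = mk(hidden_size, hidden_size),
    b_c = rep(0, hidden_size),
    W_i = mk(hidden_size, input_size), U_i = mk(hidden_size, hidden_size),
    b_i = rep(0, hidden_size),
    W_f = mk(hidden_size, input_size), U_f = mk(hidden_size, hidden_size),
    b_f = rep(1, hidden_size),
    W_o = mk(hidden_size, input_size), U_o = mk(hidden_size, hidden_size),
    b_o = rep(0, hidden_size),
    input_size = as.integer(input_size),
    hidden_size = as.integer(hidden_size)
  ), class = "lstm_params")
}

# stack the four gate blocks (order: c-tilde, i, f, o) for one fused
# matrix product per timestep
combine_gates <- function(p) {
  list(W = rbind(p$W_c, p$W_i, p$W_f, p$W_o),
       U = rbind(p$U_c, p$U_i, p$U_f, p$U_o),
       b = c(p$b_c, p$b_i, p$b_f, p$b_o),
       h = p$hidden_size)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Single LSTM step
#'
#' Applies one recurrence of the LSTM unit:
#' \deqn{\tilde c_t = \tanh(W_c x_t + U_c h_{t-1} + b_c)}
#' \deqn{i_t = \sigma(W_i x_t + U_i h_{t-1} + b_i)}
#' \deqn{f_t = \sigma(W_f x_t + U_f h_{t-1} + b_f)}
#' \deqn{c_t = i_t \odot \tilde c_t + f_t \odot c_{t-1}}
#' \deqn{o_t = \sigma(W_o x_t + U_o h_{t-1} + b_o)}
#' \deqn{h_t = o_t \odot \tanh(c_t)}
#' with \eqn{\sigma} the logistic function and \eqn{\odot} the elementwise
#' product.
#'
#' @param x_t Input vector (length `input_size`) or batch matrix
#'   (batch x `input_size`).
#' @param h_prev,c_prev Previous hidden and memory state, shaped like the
#'   output (length `hidden_size`, or batch x `hidden_size`).
#' @param params An [lstm_params()] object.
#' @return List with elements `h` and `c` (new hidden and memory state).
#' @export
lstm_step <- function(x_t, h_prev, c_prev, params) {
  stopifnot(inherits(params, "lstm_params"))
  vec_in <- is.null(dim(x_t))
  if (vec_in) {
    x_t <- matrix(x_t, 1L); h_prev <- matrix(h_prev, 1L)
    c_prev <- matrix(c_prev, 1L)
  }
  if (ncol(x_t) != params$input_size)
    stop("x_t has ", ncol(x_t), " columns; params expect input_size ",
         params$input_size)
  if (ncol(h_prev) != params$hidden_size)
    stop("h_prev has ", ncol(h_prev), " columns; params expect hidden_size ",
         params$hidden_size)
  if (!identical(dim(h_prev), dim(c_prev)))
    stop("h_prev and c_prev shapes differ")
  g <- combine_gates(params)
  st <- lstm_cell(x_t, h_prev, c_prev, g)
  if (vec_in) list(h = drop(st$h), c = drop(st$c))
  else list(h = st$h, c = st$c)
}

# fused batched cell; returns gate activations for backprop
lstm_cell <- function(x, h_prev, c_prev, g) {
  h <- g$h
  A <- x %*% t(g$W) + h_prev %*% t(g$U)
  A <- sweep(A, 2L, g$b, `+`)
  ct <- tanh(A[, 1:h, drop = FALSE])
  i <- sigmoid(A[, (h + 1):(2 * h), drop = FALSE])
  f <- sigmoid(A[, (2 * h + 1):(3 * h), drop = FALSE])
  o <- sigmoid(A[, (3 * h + 1):(4 * h), drop = FALSE])
  c_new <- i * ct + f * c_prev
  tc <- tanh(c_new)
  list(h = o * tc, c = c_new, g = ct, i = i, f = f, o = o, tc = tc)
}

# one direction over a batch; X is n x T x input. reverse = TRUE iterates
# the sequence backwards but stores outputs aligned with t.
lstm_forward_dir <- function(X, params, reverse = FALSE, keep_cache = FALSE) {
  n <- dim(X)[1L]; T_ <- dim(X)[2L]
  hs <- params$hidden_size
  g <- combine_gates(params)
  H <- array(0, c(n, T_, hs))
  h <- matrix(0, n, hs); cc <- matrix(0, n, hs)
  order_t <- if (reverse) rev(seq_len(T_)) else seq_len(T_)
  cache <- if (keep_cache) vector("list", T_) else NULL
  for (t in order_t) {
    st <- lstm_cell(matrix(X[, t, ], n), h, cc, g)
    if (keep_cache)
      cache[[t]] <- list(h_prev = h, c_prev = cc, g = st$g, i = st$i,
                         f = st$f, o = st$o, c = st$c, tc = st$tc)
    h <- st$h; cc <- st$c
    H[, t, ] <- h
  }
  list(H = H, cache = cache, order = order_t)
}

#' Bidirectional LSTM layer
#'
#' Runs a forward LSTM over `t = 1..T` and a backward LSTM over the reversed
#' sequence, both from zero initial states, and concatenates the two hidden
#' states at each aligned timestep, so every output position has seen past
#' and future context.
#'
#' @param sequence Matrix of shape T x `input_size` (one sample).
#' @param fwd,bwd [lstm_params()] for the forward and backward direction.
#' @return Matrix T x `2 * hidden_size`; columns `1:hidden_size` are the
#'   forward states, the rest the backward states.
#' @export
bilstm_layer <- function(sequence, fwd, bwd) {
  stopifnot(inherits(fwd, "lstm_params"), inherits(bwd, "lstm_params"))
  if (is.null(dim(sequence)) || nrow(sequence) < 1L)
    stop("sequence must be a non-empty T x input_size matrix")
  X <- array(sequence, c(1L, nrow(sequence), ncol(sequence)))
  Hf <- lstm_forward_dir(X, fwd, reverse = FALSE)$H
  Hb <- lstm_forward_dir(X, bwd, reverse = TRUE)$H
  cbind(matrix(Hf[1L, , ], nrow(sequence)), matrix(Hb[1L, , ], nrow(sequence)))
}

#' Construct an untrained stacked BiLSTM classification network
#'
#' The architecture: `n_layers` BiLSTM layers (each with `hidden_size` units
#' per direction, so layer outputs have `2 * hidden_size` channels), a
#' dropout layer after each BiLSTM layer (active in training mode only), a
#' fully-connected layer mapping the concatenation of the two directions'
#' final states to class scores, and a softmax output.
#'
#' @param input_size Number of predictors per timestep (14 for the standard
#'   feature cube).
#' @param class_names Character vector of class labels.
#' @param n_layers Number of stacked BiLSTM layers (1--4; default 2).
#' @param hidden_size Hidden units per direction (default 100).
#' @param dropout_rate Dropout fraction after each BiLSTM layer
#'   (default 0.5).
#' @param seed Integer seed for weight initialization.
#' @return An object of class `bilstm_model`.
#' @export
new_network_model <- function(input_size, class_names, n_layers = 2L,
                              hidden_size = 100L, dropout_rate = 0.5,
                              seed = 1L) {
  stopifnot(n_layers >= 1L, n_layers <= 4L, hidden_size >= 1L,
            dropout_rate >= 0, dropout_rate < 1, length(class_names) >= 2L)
  set.seed(seed)
  layers <- vector("list", n_layers)
  in_size <- input_size
  for (l in seq_len(n_layers)) {
    layers[[l]] <- list(fwd = lstm_params(in_size, hidden_size),
                        bwd = lstm_params(in_size, hidden_size))
    in_size <- 2L * hidden_size
  }
  n_classes <- length(class_names)
  r <- 1 / sqrt(2 * hidden_size)
  structure(list(
    n_layers = as.integer(n_layers),
    hidden_size = as.integer(hidden_size),
    input_size = as.integer(input_size),
    dropout_rate = dropout_rate,
    layers = layers,
    head_weights = matrix(stats::runif(n_classes * 2L * hidden_size, -r, r),
                          n_classes, 2L * hidden_size),
    head_bias = rep(0, n_classes),
    class_names = class_names,
    training_config = NULL,
    seed = as.integer(seed)
  ), class = "bilstm_model")
}

#' @export
print.bilstm_model <- function(x, ...) {
  cat(sprintf(
    "<bilstm_model> %d BiLSTM layer(s) x %d units/direction, %d -> %d classes%s\n",
    x$n_layers, x$hidden_size, x$input_size, length(x$class_names),
    if (is.null(x$training_config)) " (untrained)" else " (trained)"))
  invisible(x)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Forward pass of the stacked BiLSTM network
#'
#' Propagates a batch of sequences through the BiLSTM stack. In `"train"`
#' mode inverted dropout is applied to every BiLSTM layer's output (so
#' evaluation needs no rescaling); `"eval"` mode is deterministic. The
#' sequence-level class probabilities come from the softmax head applied to
#' the concatenation of the forward direction's final state (after
#' \eqn{x_T}) and the backward direction's final state (after \eqn{x_1},
#' having consumed the reversed series) — both halves have then seen the
#' full series. Per-timestep probabilities reuse the same head on the
#' aligned per-timestep outputs of the last layer.
#'
#' @param model A `bilstm_model`.
#' @param x Batch array (samples x T x `input_size`) or a single T x
#'   `input_size` matrix.
#' @param mode `"eval"` (deterministic) or `"train"` (dropout active; uses
#'   the current RNG state).
#' @param keep_cache Keep per-timestep internals for backpropagation
#'   (internal use).
#' @return List with `prob_seq` (samples x classes), `prob_steps` (samples
#'   x T x classes), `hidden` (samples x T x `2*hidden_size`, last layer),
#'   `final_state` (samples x `2*hidden_size`), and, if requested, `caches`.
#' @export
network_forward <- function(model, x, mode = c("eval", "train"),
                            keep_cache = FALSE) {
  stopifnot(inherits(model, "bilstm_model"))
  mode <- match.arg(mode)
  if (length(dim(x)) == 2L) x <- array(x, c(1L, dim(x)))
  if (dim(x)[3L] != model$input_size)
    stop("input has ", dim(x)[3L], " predictors; model expects ",
         model$input_size)
  n <- dim(x)[1L]; T_ <- dim(x)[2L]
  hs <- model$hidden_size
  caches <- if (keep_cache) vector("list", model$n_layers) else NULL
  H_in <- x
  for (l in seq_len(model$n_layers)) {
    fw <- lstm_forward_dir(H_in, model$layers[[l]]$fwd, FALSE, keep_cache)
    bw <- lstm_forward_dir(H_in, model$layers[[l]]$bwd, TRUE, keep_cache)
    H <- array(0, c(n, T_, 2L * hs))
    H[, , 1:hs] <- fw$H
    H[, , (hs + 1):(2 * hs)] <- bw$H
    mask <- NULL
    if (mode == "train" && model$dropout_rate > 0) {
      keep <- 1 - model$dropout_rate
      mask <- array(stats::rbinom(length(H), 1L, keep) / keep, dim(H))
      H <- H * mask
    }
    if (keep_cache)
      caches[[l]] <- list(input = H_in, fwd = fw$cache, bwd = bw$cache,
                          mask = mask, H_pre_mask = NULL)
    H_in <- H
  }
  if (any(!is.finite(H_in)))
    stop("non-finite activations in forward pass (training divergence?)")
  final_state <- cbind(matrix(H_in[, T_, ], n)[, 1:hs, drop = FALSE],
                       matrix(H_in[, 1L, ], n)[, (hs + 1):(2 * hs),
                                               drop = FALSE])
  logits <- final_state %*% t(model$head_weights)
  logits <- sweep(logits, 2L, model$head_bias, `+`)
  prob_seq <- softmax_rows(logits)
  n_cls <- length(model$class_names)
  prob_steps <- array(0, c(n, T_, n_cls))
  for (t in seq_len(T_)) {
    lt <- matrix(H_in[, t, ], n) %*% t(model$head_weights)
    lt <- sweep(lt, 2L, model$head_bias, `+`)
    prob_steps[, t, ] <- softmax_rows(lt)
  }
  colnames(prob_seq) <- model$class_names
  list(prob_seq = prob_seq, prob_steps = prob_steps, hidden = H_in,
       final_state = final_state, caches = caches)
}

# ---- model container I/O -------------------------------------------------

MODEL_FORMAT_VERSION <- 1L

#' Save / load a network model
#'
#' The model file is a versioned serialized container holding all weight
#' arrays and architecture metadata; a round-trip reproduces forward
#' outputs exactly.
#'
#' @param model A `bilstm_model`.
#' @param path File path.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "bilstm_model"))
  saveRDS(list(format = "phenoclass_model", version = MODEL_FORMAT_VERSION,
               model = model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("cannot read model file (",
                                           "corrupted or truncated?): ",
                                           conditionMessage(e)))
  if (!is.list(obj) || !identical(obj$format, "phenoclass_model"))
    stop("not a phenoclass model file: ", path)
  if (obj$version > MODEL_FORMAT_VERSION)
    stop("model format version ", obj$version, " is newer than supported")
  obj$model
}
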