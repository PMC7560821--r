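# Independent oracles, written as plain scalar loops so they share no code
# path with the package implementation.

sigm <- function(z) 1 / (1 + exp(-z))

# one LSTM recurrence, unit by unit
oracle_lstm_step <- function(x, h_prev, c_prev, p) {
  H <- length(h_prev)
  h_new <- numeric(H); c_new <- numeric(H)
  for (u in seq_len(H)) {
    ct <- tanh(sum(p$W_c[u, ] * x) + sum(p$U_c[u, ] * h_prev) + p$b_c[u])
    i <- sigm(sum(p$W_i[u, ] * x) + sum(p$U_i[u, ] * h_prev) + p$b_i[u])
    f <- sigm(sum(p$W_f[u, ] * x) + sum(p$U_f[u, ] * h_prev) + p$b_f[u])
    o <- sigm(sum(p$W_o[u, ] * x) + sum(p$U_o[u, ] * h_prev) + p$b_o[u])
    c_new[u] <- i * ct + f * c_prev[u]
    h_new[u] <- o * tanh(c_new[u])
  }
  list(h = h_new, c = c_new)
}

# full bidirectional layer by explicit unrolling
oracle_bilstm <- function(seq_mat, fwd, bwd) {
  T_ <- nrow(seq_mat); H <- length(fwd$b_c)
  out <- matrix(0, T_, 2 * H)
  h <- numeric(H); cc <- numeric(H)
  for (t in seq_len(T_)) {
    st <- oracle_lstm_step(seq_mat[t, ], h, cc, fwd)
    h <- st$h; cc <- st$c
    out[t, 1:H] <- h
  }
  h <- numeric(H); cc <- numeric(H)
  for (t in rev(seq_len(T_))) {
    st <- oracle_lstm_step(seq_mat[t, ], h, cc, bwd)
    h <- st$h; cc <- st$c
    out[t, (H + 1):(2 * H)] <- h
  }
  out
}

# 1-layer network: sequence-level and per-timestep probabilities
oracle_network_1layer <- function(seq_mat, fwd, bwd, W_head, b_head) {
  H <- length(fwd$b_c)
  out <- oracle_bilstm(seq_mat, fwd, bwd)
  T_ <- nrow(seq_mat)
  final <- c(out[T_, 1:H], out[1, (H + 1):(2 * H)])
  soft <- function(z) { e <- exp(z - max(z)); e / sum(e) }
  prob_seq <- soft(as.vector(W_head %*% final) + b_head)
  prob_steps <- t(apply(out, 1, function(h)
    soft(as.vector(W_head %*% h) + b_head)))
  list(prob_seq = prob_seq, prob_steps = prob_steps, outputs = out)
}

# brute-force windowed histogram entropy with explicit mirror reflection
oracle_entropy <- function(m, window, n_bins) {
  half <- (window - 1) / 2
  reflect <- function(i, n) {
    while (i < 1 || i > n) {
      if (i < 1) i <- 2 - i
      if (i > n) i <- 2 * n - i
    }
    i
  }
  out <- matrix(0, nrow(m), ncol(m))
  for (r in seq_len(nrow(m))) {
    for (cl in seq_len(ncol(m))) {
      vals <- numeric(0)
      for (dr in -half:half)
        for (dc in -half:half)
          vals <- c(vals, m[reflect(r + dr, nrow(m)),
                            reflect(cl + dc, ncol(m))])
      bin <- pmin(pmax(floor((vals + 1) / 2 * n_bins) + 1, 1), n_bins)
      p <- tabulate(bin, n_bins) / length(vals)
      out[r, cl] <- -sum(p[p > 0] * log2(p[p > 0]))
    }
  }
  out
}

# per-class metrics by explicit counting
oracle_metrics <- function(truth, pred, k) {
  n <- length(truth)
  oa <- 100 * sum(truth == pred) / n
  prec <- rec <- f1 <- numeric(k)
  for (cls in seq_len(k)) {
    tp <- sum(truth == cls & pred == cls)
    prec[cls] <- if (sum(pred == cls) > 0) 100 * tp / sum(pred == cls) else 0
    rec[cls] <- if (sum(truth == cls) > 0) 100 * tp / sum(truth == cls) else 0
    f1[cls] <- if (prec[cls] + rec[cls] > 0)
      2 * prec[cls] * rec[cls] / (prec[cls] + rec[cls]) else 0
  }
  list(oa = oa, precision = prec, recall = rec, f1 = f1)
}

# random small lstm_params drawn from the current RNG state
random_params <- function(input_size, hidden_size, scale = 0.8) {
  p <- lstm_params(input_size, hidden_size)
  for (f in c("W_c", "U_c", "W_i", "U_i", "W_f", "U_f", "W_o", "U_o"))
    p[[f]] <- matrix(rnorm(length(p[[f]]), sd = scale), nrow(p[[f]]),
                     ncol(p[[f]]))
  for (f in c("b_c", "b_i", "b_f", "b_o"))
    p[[f]] <- rnorm(length(p[[f]]), sd = scale)
  p
}
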