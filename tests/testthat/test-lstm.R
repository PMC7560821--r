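zero_params <- function(input, hidden) {
  p <- lstm_params(input, hidden)
  for (f in phenoclass:::GATE_FIELDS)
    p[[f]] <- p[[f]] * 0
  p
}

test_that("lstm_step reproduces hand-computed scalar cases", {
  # all-zero parameters: candidate tanh(0)=0 makes h and c vanish
  p0 <- zero_params(3, 2)
  st <- lstm_step(c(1, -2, 3), c(0, 0), c(0, 0), p0)
  expect_equal(st$h, c(0, 0))
  expect_equal(st$c, c(0, 0))
  # scalar unit with unit weights, zero biases, x = 1
  p1 <- zero_params(1, 1)
  for (f in c("W_c", "U_c", "W_i", "U_i", "W_f", "U_f", "W_o", "U_o"))
    p1[[f]] <- matrix(1, 1, 1)
  st1 <- lstm_step(1, 0, 0, p1)
  ct <- tanh(1); g <- 1 / (1 + exp(-1))
  expect_equal(st1$c, g * ct, tolerance = 1e-12)
  expect_equal(st1$h, g * tanh(g * ct), tolerance = 1e-12)
  expect_equal(st1$c, 0.55674, tolerance = 1e-4)
  expect_equal(st1$h, 0.36960, tolerance = 1e-4)
  # pure-memory limit: saturated forget gate, closed input gate
  pm <- zero_params(1, 1)
  pm$b_f <- 40; pm$b_i <- -40
  stm <- lstm_step(0.3, 0.2, 0.9, pm)
  expect_equal(stm$c, 0.9, tolerance = 1e-9)
})

test_that("lstm_step reports shape mismatches by operand", {
  p <- lstm_params(3, 2)
  expect_error(lstm_step(c(1, 2), c(0, 0), c(0, 0), p), "x_t")
  expect_error(lstm_step(c(1, 2, 3), c(0, 0, 0), c(0, 0, 0), p), "h_prev")
  expect_error(lstm_step(c(1, 2, 3), c(0, 0), 0, p), "shapes differ")
})

test_that("lstm_step matches the scalar-loop oracle on random cases", {
  set.seed(51)
  for (rep in 1:100) {
    p <- random_params(3, 2)
    x <- rnorm(3); h0 <- rnorm(2); c0 <- rnorm(2)
    got <- lstm_step(x, h0, c0, p)
    want <- oracle_lstm_step(x, h0, c0, p)
    expect_equal(got$h, want$h, tolerance = 1e-12)
    expect_equal(got$c, want$c, tolerance = 1e-12)
  }
})

test_that("gate activations stay in their ranges", {
  set.seed(52)
  for (rep in 1:20) {
    p <- random_params(4, 3, scale = 2)
    g <- phenoclass:::combine_gates(p)
    st <- phenoclass:::lstm_cell(matrix(rnorm(4), 1), matrix(rnorm(3), 1),
                                 matrix(rnorm(3), 1), g)
    expect_true(all(st$i > 0 & st$i < 1))
    expect_true(all(st$f > 0 & st$f < 1))
    expect_true(all(st$o > 0 & st$o < 1))
    expect_true(all(abs(st$g) < 1))
    expect_true(all(abs(st$h) < 1))
  }
})

test_that("bilstm_layer aligns directions and matches unrolled iteration", {
  set.seed(53)
  fwd <- random_params(2, 2); bwd <- random_params(2, 2)
  # T = 1: both halves come from the same single input at zero state
  x1 <- matrix(rnorm(2), 1)
  out1 <- bilstm_layer(x1, fwd, bwd)
  expect_equal(out1[1, 1:2], lstm_step(x1[1, ], c(0, 0), c(0, 0), fwd)$h,
               tolerance = 1e-12)
  expect_equal(out1[1, 3:4], lstm_step(x1[1, ], c(0, 0), c(0, 0), bwd)$h,
               tolerance = 1e-12)
  # palindromic sequence with shared parameters: time-reversal swaps halves
  pal <- rbind(c(0.3, -0.2), c(1, 0.5), c(0.3, -0.2))
  outp <- bilstm_layer(pal, fwd, fwd)
  for (t in 1:3) {
    expect_equal(outp[t, 1:2], outp[4 - t, 3:4], tolerance = 1e-12)
  }
  # random 3-step case against the scalar-loop oracle
  x <- matrix(rnorm(6), 3)
  expect_equal(bilstm_layer(x, fwd, bwd), oracle_bilstm(x, fwd, bwd),
               tolerance = 1e-12)
  expect_error(bilstm_layer(numeric(0), fwd, bwd), "non-empty")
})

test_that("network probabilities are proper and eval mode deterministic", {
  set.seed(54)
  m <- new_network_model(5, c("a", "b", "c"), n_layers = 2, hidden_size = 4,
                         seed = 3)
  x <- array(rnorm(4 * 6 * 5), c(4, 6, 5))
  f1 <- network_forward(m, x, mode = "eval")
  f2 <- network_forward(m, x, mode = "eval")
  expect_identical(f1$prob_seq, f2$prob_seq)
  expect_true(all(abs(rowSums(f1$prob_seq) - 1) < 1e-9))
  expect_true(all(f1$prob_seq > 0 & f1$prob_seq < 1))
  expect_true(all(abs(apply(f1$prob_steps, c(1, 2), sum) - 1) < 1e-9))
  # zero head: uniform probabilities everywhere
  m0 <- m
  m0$head_weights <- m0$head_weights * 0
  m0$head_bias <- m0$head_bias * 0
  f0 <- network_forward(m0, x)
  expect_equal(unname(f0$prob_seq), matrix(1 / 3, 4, 3), tolerance = 1e-12)
})

test_that("1-layer network equals the unrolled scalar oracle", {
  set.seed(55)
  for (rep in 1:10) {
    m <- new_network_model(2, c("u", "v"), n_layers = 1, hidden_size = 2,
                           dropout_rate = 0, seed = rep)
    x <- matrix(rnorm(6), 3)
    got <- network_forward(m, x, mode = "eval")
    want <- oracle_network_1layer(x, m$layers[[1]]$fwd, m$layers[[1]]$bwd,
                                  m$head_weights, m$head_bias)
    expect_equal(as.vector(got$prob_seq), want$prob_seq, tolerance = 1e-12)
    expect_equal(matrix(got$prob_steps[1, , ], 3), want$prob_steps,
                 tolerance = 1e-12)
    expect_equal(matrix(got$hidden[1, , ], 3), want$outputs,
                 tolerance = 1e-12)
  }
})

test_that("1-layer network is exactly a bilstm_layer + head composition", {
  set.seed(56)
  m <- new_network_model(3, c("a", "b"), n_layers = 1, hidden_size = 3,
                         seed = 8)
  x <- matrix(rnorm(12), 4)
  out <- bilstm_layer(x, m$layers[[1]]$fwd, m$layers[[1]]$bwd)
  final <- c(out[4, 1:3], out[1, 4:6])
  logits <- as.vector(m$head_weights %*% final) + m$head_bias
  soft <- exp(logits - max(logits)); soft <- soft / sum(soft)
  got <- network_forward(m, x, mode = "eval")
  expect_equal(as.vector(got$prob_seq), soft, tolerance = 1e-14)
})

test_that("averaged train-mode dropout outputs converge to eval outputs", {
  set.seed(57)
  m <- new_network_model(3, c("a", "b"), n_layers = 1, hidden_size = 4,
                         dropout_rate = 0.5, seed = 4)
  x <- matrix(rnorm(9), 3)
  ref <- network_forward(m, x, mode = "eval")$hidden
  n_rep <- 2000
  acc <- ref * 0
  for (r in seq_len(n_rep))
    acc <- acc + network_forward(m, x, mode = "train")$hidden
  # inverted dropout is unbiased; CLT bound at 2000 repeats
  expect_lt(max(abs(acc / n_rep - ref)), 0.1)
})

test_that("backpropagation matches numerical gradients", {
  set.seed(58)
  m <- new_network_model(3, c("a", "b", "c"), n_layers = 2, hidden_size = 3,
                         dropout_rate = 0, seed = 6)
  n <- 4; T_ <- 5
  x <- array(rnorm(n * T_ * 3), c(n, T_, 3))
  lab <- sample(1:3, n, replace = TRUE)
  Y <- matrix(0, n, 3); Y[cbind(1:n, lab)] <- 1
  fw <- network_forward(m, x, mode = "train", keep_cache = TRUE)
  gr <- phenoclass:::network_backward(m, fw, x, Y)
  loss_at <- function(model) {
    f <- network_forward(model, x, mode = "eval")
    phenoclass:::cross_entropy(f$prob_seq, Y)
  }
  params <- phenoclass:::flatten_params(m)
  eps <- 1e-6
  for (nm in c("1.fwd.W_c", "1.bwd.U_f", "2.fwd.W_o", "2.bwd.b_i",
               "head_weights", "head_bias")) {
    for (i in seq_len(min(4, length(params[[nm]])))) {
      up <- params; up[[nm]][i] <- up[[nm]][i] + eps
      dn <- params; dn[[nm]][i] <- dn[[nm]][i] - eps
      num <- (loss_at(phenoclass:::set_params(m, up)) -
                loss_at(phenoclass:::set_params(m, dn))) / (2 * eps)
      expect_equal(gr[[nm]][i], num, tolerance = 1e-6,
                   ignore_attr = TRUE)
    }
  }
})

test_that("model files round-trip and reject corruption", {
  set.seed(59)
  m <- new_network_model(4, c("a", "b"), n_layers = 2, hidden_size = 3,
                         seed = 2)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  back <- load_model(path)
  expect_identical(back$n_layers, m$n_layers)
  expect_identical(back$hidden_size, m$hidden_size)
  expect_identical(back$class_names, m$class_names)
  x <- array(rnorm(2 * 5 * 4), c(2, 5, 4))
  expect_identical(network_forward(back, x)$prob_seq,
                   network_forward(m, x)$prob_seq)
  # truncated file: clean error, not a crash
  bytes <- readBin(path, "raw", file.info(path)$size)
  trunc_path <- withr::local_tempfile(fileext = ".rds")
  writeBin(bytes[seq_len(floor(length(bytes) / 3))], trunc_path)
  expect_error(load_model(trunc_path), "corrupted|cannot read")
  other <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(x = 1), other)
  expect_error(load_model(other), "not a phenoclass model")
})
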