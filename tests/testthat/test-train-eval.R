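test_that("metrics have closed-form values on degenerate predictors", {
  # perfect predictions
  perfect <- phenoclass:::report_from_predictions(
    truth = rep(1:3, each = 10), pred = rep(1:3, each = 10),
    class_names = c("a", "b", "c"))
  expect_equal(perfect$overall_accuracy, 100)
  expect_true(all(perfect$per_class$precision == 100))
  expect_true(all(perfect$per_class$f1 == 100))
  expect_true(all(perfect$confusion_matrix[upper.tri(
    perfect$confusion_matrix)] == 0))
  # constant predictor on a balanced 4-class set
  const <- phenoclass:::report_from_predictions(
    truth = rep(1:4, each = 25), pred = rep(1L, 100),
    class_names = paste0("k", 1:4))
  expect_equal(const$overall_accuracy, 25)
  expect_equal(const$per_class$recall[1], 100)
  expect_equal(const$per_class$precision[1], 25)
  expect_equal(const$per_class$recall[2:4], rep(0, 3))
})

test_that("metrics agree with a brute-force oracle and their own matrix", {
  set.seed(61)
  truth <- sample(1:5, 400, replace = TRUE)
  pred <- ifelse(runif(400) < 0.6, truth, sample(1:5, 400, replace = TRUE))
  rep_ <- phenoclass:::report_from_predictions(truth, pred, paste0("c", 1:5))
  want <- oracle_metrics(truth, pred, 5)
  expect_equal(rep_$overall_accuracy, want$oa)
  expect_equal(rep_$per_class$precision, want$precision)
  expect_equal(rep_$per_class$recall, want$recall)
  expect_equal(rep_$per_class$f1, want$f1)
  # recomputing from the returned confusion matrix is exactly consistent
  again <- metrics_from_confusion(rep_$confusion_matrix)
  expect_equal(again$per_class, rep_$per_class)
  expect_equal(sum(rep_$confusion_matrix), rep_$n_test)
})

test_that("training is deterministic and learns a separable task", {
  sc <- tiny_scene(grid = 24, parcel = 8, seed = 41)
  cubes <- scene_cubes(sc, seed = 43)
  cfg <- training_config(n_layers = 1, hidden_size = 8, epochs = 20,
                         batch_size = 64, early_stopping_patience = 0,
                         seed = 45)
  m1 <- train(cfg, cubes$train)
  m2 <- train(cfg, cubes$train)
  expect_identical(phenoclass:::flatten_params(m1),
                   phenoclass:::flatten_params(m2))
  expect_true(all(is.finite(m1$history$train_loss)))
  expect_gt(tail(m1$history$train_accuracy, 1), 0.5)  # better than chance
  # the final model separates the training data
  expect_gt(evaluate(m1, cubes$train)$overall_accuracy, 99)
  rep_ <- evaluate(m1, cubes$test, n_train = length(cubes$split$train),
                   split_mode = "pixel")
  expect_gt(rep_$overall_accuracy, 99)
  # probabilities and evaluation agree on sample count
  expect_equal(rep_$n_test, length(cubes$split$test))
})

test_that("training validates its inputs", {
  sc <- tiny_scene(grid = 24, parcel = 8, seed = 47)
  cubes <- scene_cubes(sc, seed = 49)
  one_class <- subset_cube(cubes$train, which(cubes$train$labels == 1))
  cfg <- training_config(n_layers = 1, hidden_size = 4, epochs = 1,
                         seed = 1)
  expect_error(train(cfg, one_class), "absent from training data")
  expect_error(training_config(epochs = 0), "epochs")
  expect_error(training_config(learning_rate = 0))
  expect_error(training_config(optimizer_name = "sgd"), "adam")
})

test_that("label noise does not improve held-out accuracy", {
  sc <- tiny_scene(grid = 24, parcel = 8, seed = 51, noise = 0.03,
                   amp1 = 0.3, amp2 = 0.55)
  cubes <- scene_cubes(sc, seed = 53)
  cfg <- training_config(n_layers = 1, hidden_size = 8, epochs = 8,
                         batch_size = 128, early_stopping_patience = 0,
                         seed = 55)
  clean <- evaluate(train(cfg, cubes$train), cubes$test)$overall_accuracy
  noisy_cube <- cubes$train
  set.seed(57)
  flip <- sample(length(noisy_cube$labels),
                 round(0.35 * length(noisy_cube$labels)))
  noisy_cube$labels[flip] <- 3L - noisy_cube$labels[flip]
  noisy <- evaluate(train(cfg, noisy_cube), cubes$test)$overall_accuracy
  expect_lte(noisy, clean + 1)
})

test_that("architecture sweep compares variants on identical data", {
  sc <- tiny_scene(grid = 24, parcel = 8, seed = 61)
  cubes <- scene_cubes(sc, seed = 63)
  cfgs <- list(
    training_config(n_layers = 1, hidden_size = 6, epochs = 2, seed = 65),
    training_config(n_layers = 2, hidden_size = 6, epochs = 2, seed = 65))
  sweep1 <- architecture_sweep(cfgs, cubes$train, cubes$test)
  expect_equal(nrow(sweep1), 2)
  expect_equal(sweep1$n_layers, c(1, 2))
  expect_true(all(sweep1$n_train == sweep1$n_train[1]))
  expect_true(all(sweep1$n_test == sweep1$n_test[1]))
  expect_true(all(is.finite(sweep1$elapsed_sec)))
  expect_length(attr(sweep1, "histories"), 2)
  # reproducible under the same seeds
  sweep2 <- architecture_sweep(cfgs, cubes$train, cubes$test)
  expect_equal(sweep1$overall_accuracy, sweep2$overall_accuracy)
  # a failing variant is recorded, the sweep continues
  bad <- training_config(n_layers = 1, hidden_size = 6, epochs = 2,
                         learning_rate = 1e6, seed = 65)
  sweep3 <- architecture_sweep(list(bad, cfgs[[1]]), cubes$train,
                               cubes$test)
  expect_equal(nrow(sweep3), 2)
  expect_false(is.na(sweep3$overall_accuracy[2]))
})
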