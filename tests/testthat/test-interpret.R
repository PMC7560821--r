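test_that("perturb leaves untargeted entries bit-identical", {
  set.seed(71)
  cube <- raw_cube(array(runif(50 * 10 * 14), c(50, 10, 14)))
  out <- perturb(cube, "predictor", 13, noise_fraction = 0.03)
  expect_identical(out$values[, , -13], cube$values[, , -13])
  expect_false(identical(out$values[, , 13], cube$values[, , 13]))
  outd <- perturb(cube, "date", 4, noise_fraction = 0.03)
  expect_identical(outd$values[, -4, ], cube$values[, -4, ])
  # zero noise fraction: exact identity
  expect_identical(perturb(cube, "predictor", 2, noise_fraction = 0)$values,
                   cube$values)
  expect_error(perturb(cube, "predictor", 15), "1..14")
  expect_error(perturb(cube, "date", 0), "1..10")
})

test_that("a zero-amplitude target is a warned no-op", {
  vals <- array(runif(20 * 5 * 3), c(20, 5, 3))
  vals[, , 2] <- 0.5
  cube <- raw_cube(vals)
  expect_warning(out <- perturb(cube, "predictor", 2), "zero amplitude")
  expect_identical(out$values, cube$values)
})

test_that("added noise has variance noise_fraction x amplitude", {
  # moment check of the sigma^2 = 3% of signal amplitude rule
  set.seed(73)
  n <- 3400  # x 30 timesteps: > 1e5 draws on the targeted slice
  vals <- array(runif(n * 30 * 2, 0, 2), c(n, 30, 2))
  cube <- raw_cube(vals)
  amp <- max(vals[, , 1]) - min(vals[, , 1])
  out <- perturb(cube, "predictor", 1, noise_fraction = 0.03)
  noise <- out$values[, , 1] - vals[, , 1]
  expect_equal(var(as.vector(noise)), 0.03 * amp, tolerance = 0.02)
  expect_lt(abs(mean(noise)), 0.01)
  # alternative reading: sigma (not sigma^2) proportional to amplitude
  out2 <- perturb(cube, "predictor", 1, noise_fraction = 0.03,
                  sd_rule = "sd_fraction")
  noise2 <- out2$values[, , 1] - vals[, , 1]
  expect_equal(sd(as.vector(noise2)), 0.03 * amp, tolerance = 0.02)
})

test_that("date-mode amplitude is measured per predictor at that date", {
  set.seed(75)
  vals <- array(0, c(5000, 3, 2))
  vals[, , 1] <- runif(5000 * 3, 0, 1)    # amplitude ~1
  vals[, , 2] <- runif(5000 * 3, 0, 10)   # amplitude ~10
  cube <- raw_cube(vals)
  out <- perturb(cube, "date", 2, noise_fraction = 0.03)
  v1 <- var(out$values[, 2, 1] - vals[, 2, 1])
  v2 <- var(out$values[, 2, 2] - vals[, 2, 2])
  expect_equal(v1, 0.03 * (max(vals[, 2, 1]) - min(vals[, 2, 1])),
               tolerance = 0.05)
  expect_equal(v2, 0.03 * (max(vals[, 2, 2]) - min(vals[, 2, 2])),
               tolerance = 0.05)
})

# a moderately separable scene whose trained model is shared by the
# relevance behaviour tests below
rel_fixture <- local({
  fixture <- NULL
  function() {
    if (is.null(fixture)) {
      sc <- tiny_scene(grid = 32, parcel = 8, seed = 81, noise = 0.05,
                       amp1 = 0.30, amp2 = 0.45)
      cubes <- scene_cubes(sc, seed = 83)
      cfg <- training_config(n_layers = 1, hidden_size = 8, epochs = 10,
                             batch_size = 128,
                             early_stopping_patience = 0, seed = 85)
      fixture <<- list(model = train(cfg, cubes$train),
                       test = cubes$test)
    }
    fixture
  }
})

test_that("relevance is deterministic and normalized to its top item", {
  fx <- rel_fixture()
  r1 <- relevance(fx$model, fx$test, "predictor", n_repeats = 3, seed = 87)
  r2 <- relevance(fx$model, fx$test, "predictor", n_repeats = 3, seed = 87)
  expect_identical(r1$scores, r2$scores)
  expect_identical(r1$raw_accuracy_drops, r2$raw_accuracy_drops)
  expect_false(r1$all_zero)
  expect_equal(max(r1$scores), 1)
  expect_true(all(r1$scores >= 0 & r1$scores <= 1))
  expect_length(r1$scores, 14)
  # informative pair dominates the uninformative bands
  noise_bands <- setdiff(phenoclass:::S2_BANDS, c("B4", "B8"))
  expect_gt(max(r1$scores[c("NDVI", "B4", "B8")]),
            max(r1$scores[noise_bands]))
})

test_that("zero noise yields the all-zero relevance flag", {
  fx <- rel_fixture()
  r0 <- relevance(fx$model, fx$test, "predictor", n_repeats = 1,
                  noise_fraction = 0, seed = 89)
  expect_true(r0$all_zero)
  expect_true(all(r0$scores == 0))
  expect_true(all(r0$mean_drops == 0))
})

test_that("larger noise fractions do not weaken an informative predictor", {
  fx <- rel_fixture()
  drop_at <- function(nf)
    relevance(fx$model, fx$test, "predictor", n_repeats = 3,
              noise_fraction = nf, seed = 91)$mean_drops[["NDVI"]]
  d_small <- drop_at(0.01)
  d_large <- drop_at(0.25)
  expect_gte(d_large, d_small)
})

test_that("probability evolution rows are proper distributions", {
  fx <- rel_fixture()
  seq1 <- matrix(fx$test$values[1, , ], dim(fx$test$values)[2])
  evo <- probability_evolution(fx$model, seq1)
  expect_equal(dim(evo), c(30, 2))
  expect_true(all(abs(rowSums(evo) - 1) < 1e-9))
  m0 <- fx$model
  m0$head_weights <- m0$head_weights * 0
  m0$head_bias <- m0$head_bias * 0
  flat <- probability_evolution(m0, seq1)
  expect_equal(unname(flat), matrix(0.5, 30, 2), tolerance = 1e-12)
  expect_error(probability_evolution(fx$model, seq1[, 1:3]), "predictors")
  expect_error(probability_evolution(fx$model, fx$test$values), "single")
})

test_that("activation summaries are bounded and recombine by class", {
  fx <- rel_fixture()
  act <- activation_summary(fx$model, fx$test, by_class = TRUE)
  expect_true(all(act$mean_squared_by_date >= 0 &
                    act$mean_squared_by_date < 1))
  expect_true(all(is.finite(act$heatmap)))
  expect_equal(dim(act$heatmap), c(16, 30))
  pooled <- colSums(act$per_class_curves *
                      as.vector(act$class_counts)) / sum(act$class_counts)
  expect_equal(unname(pooled), act$mean_squared_by_date, tolerance = 1e-9)
  empty <- subset_cube(fx$test, integer(0))
  expect_error(activation_summary(fx$model, empty), "no samples")
  unlabeled <- fx$test
  unlabeled$labels <- NULL
  expect_error(activation_summary(fx$model, unlabeled, by_class = TRUE),
               "labeled")
})

test_that("relevance serialization writes JSON and CSV", {
  fx <- rel_fixture()
  r <- relevance(fx$model, fx$test, "date", n_repeats = 1, seed = 93)
  expect_length(r$scores, 30)
  jp <- withr::local_tempfile(fileext = ".json")
  cp <- withr::local_tempfile(fileext = ".csv")
  write_relevance(r, jp, cp)
  js <- jsonlite::read_json(jp, simplifyVector = TRUE)
  expect_equal(js$mode, "date")
  expect_equal(unlist(js$scores), r$scores)
  df <- read.csv(cp)
  expect_equal(nrow(df), 30)
})
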