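test_that("compute_ndvi handles standard and degenerate inputs", {
  expect_equal(compute_ndvi(0.5, 0.1), 2 / 3)
  expect_equal(compute_ndvi(0.3, 0.3), 0)
  expect_equal(compute_ndvi(0, 0), 0)
  expect_error(compute_ndvi(-0.1, 0.2), "non-negative")
  x <- runif(100); y <- runif(100)
  expect_true(all(abs(compute_ndvi(x, y)) <= 1))
})

test_that("ndvi_entropy matches a brute-force oracle exactly", {
  set.seed(33)
  for (rep in 1:3) {
    m <- matrix(runif(16 * 16, -1, 1), 16, 16)
    for (w in c(3L, 5L)) {
      for (nb in c(8L, 16L)) {
        expect_equal(ndvi_entropy(m, w, nb), oracle_entropy(m, w, nb),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("ndvi_entropy limits: constant map and uniform histogram", {
  expect_true(all(ndvi_entropy(matrix(0.4, 10, 10), 5L, 16L) == 0))
  # a 5x5 window whose 25 values occupy 25 bins exactly once
  vals <- -1 + (seq_len(25) - 0.5) * (2 / 25)
  m <- matrix(vals, 5, 5)
  expect_equal(ndvi_entropy(m, 5L, 25L)[3, 3], log2(25))
  expect_error(ndvi_entropy(matrix(0, 4, 4), 5L, 16L), "larger than grid")
  expect_error(ndvi_entropy(matrix(0, 8, 8), 4L, 16L), "odd")
})

test_that("assemble_features builds the frozen 14-predictor order", {
  sc <- tiny_scene()
  cube <- assemble_features(sc)
  expect_equal(dim(cube$values), c(256, 30, 14))
  expect_identical(cube$feature_names[13], "NDVI")
  expect_identical(cube$feature_names[14], "E_NDVI")
  # NDVI column equals compute_ndvi of the B8/B4 columns
  expect_equal(cube$values[, , "NDVI"],
               compute_ndvi(cube$values[, , "B8"], cube$values[, , "B4"]))
  expect_true(all(is.finite(cube$values)))
  expect_true(all(cube$values[, , "E_NDVI"] >= 0))
  # missing band is reported by name
  broken <- sc
  dimnames(broken$reflectance)[[4]][2] <- "B2x"
  expect_error(assemble_features(broken), "B2")
})

test_that("a constant scene yields zero NDVI entropy", {
  profs <- two_class_profiles(amp1 = 0.3, amp2 = 0.3, noise = 0)
  sc <- generate_scene(scene_config(16, 16, parcel_size = 8,
                                    profiles = profs,
                                    class_proportions = c(0.5, 0.5),
                                    noise_sd_other = 0, seed = 3))
  cube <- assemble_features(sc)
  expect_true(all(cube$values[, , "E_NDVI"] == 0))
})

test_that("sample permutation permutes cube rows identically", {
  sc <- tiny_scene()
  cube <- assemble_features(sc)
  perm <- sample(dim(cube$values)[1])
  shuffled <- subset_cube(cube, perm)
  expect_identical(shuffled$values[1, , ], cube$values[perm[1], , ])
  expect_identical(shuffled$labels, cube$labels[perm])
})

test_that("standardization centres and scales each predictor", {
  sc <- tiny_scene()
  cube <- assemble_features(sc)
  z <- standardize(cube)
  for (j in c(1, 13, 14)) {
    expect_lt(abs(mean(z$values[, , j])), 1e-8)
    expect_equal(sd(as.vector(z$values[, , j])), 1, tolerance = 1e-6)
  }
  # validation path reuses the supplied stats unchanged
  z2 <- standardize(cube, stats = z$standardization)
  expect_identical(z2$values, z$values)
  expect_identical(z2$standardization, z$standardization)
})

test_that("zero-variance predictors are left unscaled with a warning", {
  vals <- array(runif(40 * 5 * 3), c(40, 5, 3))
  vals[, , 2] <- 0.7
  cube <- raw_cube(vals)
  expect_warning(z <- standardize(cube), "zero-variance")
  expect_equal(z$standardization$scale[2], 1)
  expect_true(all(z$values[, , 2] == 0))
})

test_that("cube container and wide CSV export round-trip", {
  sc <- tiny_scene()
  cube <- assemble_features(sc)
  path <- withr::local_tempfile(fileext = ".rds")
  write_cube(cube, path)
  expect_identical(read_cube(path)$values, cube$values)
  csv <- withr::local_tempfile(fileext = ".csv")
  cube_to_csv(cube, csv)
  df <- read.csv(csv, check.names = FALSE)
  expect_equal(nrow(df), 256)
  expect_equal(ncol(df), 3 + 30 * 14)
  # spot-check one named cell against the cube
  expect_equal(df[["NDVI@0"]][5], unname(cube$values[5, 1, "NDVI"]))
})
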