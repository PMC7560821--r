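# Small scene factories shared across test files.

two_class_profiles <- function(amp1 = 0.2, amp2 = 0.6, noise = 0.01) {
  list(
    A = phenology_profile("A", ndvi_base = 0.10, ndvi_amplitude = amp1,
                          greenup_day = 150, senescence_day = 300,
                          greenup_rate = 0.08, senescence_rate = 0.08,
                          band_noise_sd = noise),
    B = phenology_profile("B", ndvi_base = 0.10, ndvi_amplitude = amp2,
                          greenup_day = 150, senescence_day = 300,
                          greenup_rate = 0.08, senescence_rate = 0.08,
                          band_noise_sd = noise)
  )
}

tiny_scene <- function(grid = 16, parcel = 8, seed = 11, noise = 0.01,
                       amp1 = 0.2, amp2 = 0.6) {
  generate_scene(scene_config(
    grid, grid, parcel_size = parcel,
    profiles = two_class_profiles(amp1, amp2, noise),
    class_proportions = c(A = 0.5, B = 0.5), noise_sd_other = 0.01,
    seed = seed))
}

# labeled 70/30 standardized cubes from a scene
scene_cubes <- function(scene, mode = "pixel", seed = 21) {
  cube <- assemble_features(scene)
  sp <- split_train_test(scene, 0.7, mode, seed = seed)
  tr <- standardize(subset_cube(cube, sp$train))
  te <- standardize(subset_cube(cube, sp$test),
                    stats = tr$standardization)
  list(train = tr, test = te, split = sp)
}

# a bare feature_cube around a given values array (for perturbation tests)
raw_cube <- function(values, labels = NULL) {
  structure(list(
    values = values,
    feature_names = phenoclass:::FEATURE_NAMES[seq_len(dim(values)[3])],
    sample_index = data.frame(row = seq_len(dim(values)[1]), col = 1L),
    labels = labels,
    class_names = if (is.null(labels)) NULL else
      paste0("K", seq_len(max(labels))),
    parcel_ids = seq_len(dim(values)[1]),
    date_list = seq_len(dim(values)[2]),
    standardization = NULL
  ), class = "feature_cube")
}
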