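#' Configuration for a synthetic labeled scene
#'
#' Collects everything [generate_scene()] needs: grid size, acquisition
#' dates, class phenology profiles, parcel block size, class proportions and
#' the random seed. Defaults follow the study conditions: 30 cloud-free
#' acquisitions spread over one agronomic year (September 1 to August 31),
#' 16 land-use classes with proportions matching the in-situ pixel counts.
#'
#' @param grid_height,grid_width Scene dimensions in pixels; both must be
#'   divisible by `parcel_size`.
#' @param date_list Numeric vector of acquisition days (agronomic
#'   day-of-year, 0 = September 1). Default: 30 evenly spaced days.
#' @param profiles Named list of [phenology_profile()] objects; names are
#'   the class labels.
#' @param parcel_size Side length in pixels of the square parcel blocks that
#'   tile the grid.
#' @param class_proportions Fractions summing to 1, one per profile.
#'   Default: proportional to the study's per-class pixel counts for the
#'   default 16 classes, uniform otherwise.
#' @param noise_sd_other Class-independent noise sd for the non-informative
#'   bands.
#' @param band_baselines Named baseline reflectance per band.
#' @param seed Integer seed making scene generation deterministic.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(grid_height = 64, grid_width = 64,
                         date_list = agronomic_dates(30),
                         profiles = default_profiles(),
                         parcel_size = 8,
                         class_proportions = NULL,
                         noise_sd_other = 0.02,
                         band_baselines = DEFAULT_BAND_BASELINES,
                         seed = 1L) {
  stopifnot(grid_height >= 1, grid_width >= 1, parcel_size >= 1)
  if (is.null(names(profiles)) || any(names(profiles) == ""))
    names(profiles) <- vapply(profiles, `[[`, "", "class_name")
  ok <- vapply(profiles, inherits, TRUE, "phenology_profile")
  if (!all(ok)) stop("profiles must all be phenology_profile objects")
  if (is.null(class_proportions)) {
    class_proportions <-
      if (all(names(profiles) %in% names(CLASS_PIXEL_COUNTS))) {
        cnt <- CLASS_PIXEL_COUNTS[names(profiles)]
        cnt / sum(cnt)
      } else {
        stats::setNames(rep(1 / length(profiles), length(profiles)),
                        names(profiles))
      }
  }
  if (length(class_proportions) != length(profiles))
    stop("class_proportions must have one entry per profile")
  if (abs(sum(class_proportions) - 1) > 1e-9)
    stop("class_proportions must sum to 1")
  if (is.null(names(class_proportions)))
    names(class_proportions) <- names(profiles)
  structure(list(
    grid_height = as.integer(grid_height),
    grid_width = as.integer(grid_width),
    n_dates = length(date_list),
    date_list = as.numeric(date_list),
    profiles = profiles,
    parcel_size = as.integer(parcel_size),
    class_proportions = class_proportions,
    noise_sd_other = noise_sd_other,
    band_baselines = band_baselines,
    seed = as.integer(seed)
  ), class = "scene_config")
}

#' Evenly spaced acquisition days over one agronomic year
#'
#' @param n Number of dates (default 30).
#' @return `n` days spanning day 0 (September 1) to day 364 (August 31).
#' @export
agronomic_dates <- function(n = 30) round(seq(0, 364, length.out = n))

#' Generate a synthetic labeled multispectral scene
#'
#' Tiles the grid into square parcels, assigns each parcel a land-use class
#' (largest-remainder apportionment of `class_proportions` over parcels,
#' then a seeded shuffle), and simulates, for every pixel and date, a
#' 12-band surface-reflectance vector from the class's double-logistic NDVI
#' trajectory with independent pixel-level Gaussian noise. Deterministic
#' given the config seed.
#'
#' @param config A [scene_config()].
#' @return An object of class `labeled_scene` with elements `reflectance`
#'   (height x width x dates x 12 array in `[0, 1]`), `labels` and
#'   `parcel_ids` (integer matrices), `class_names`, `band_names`,
#'   `date_list`, and the generating `config`.
#' @export
generate_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  h <- config$grid_height; w <- config$grid_width
  ps <- config$parcel_size
  if (h %% ps != 0 || w %% ps != 0)
    stop("grid dimensions (", h, "x", w, ") must be divisible by parcel_size (",
         ps, ")")
  n_par_r <- h %/% ps; n_par_c <- w %/% ps
  n_parcels <- n_par_r * n_par_c
  n_classes <- length(config$profiles)
  if (n_classes > n_parcels)
    stop("number of classes (", n_classes, ") exceeds number of parcels (",
         n_parcels, ")")
  set.seed(config$seed)

  # largest-remainder apportionment of parcels to classes, with every
  # configured class guaranteed at least one parcel
  quota <- config$class_proportions * n_parcels
  n_assign <- pmax(1L, floor(quota))
  excess <- sum(n_assign) - n_parcels
  while (excess > 0) {
    donor <- which.max(ifelse(n_assign > 1L, n_assign, -Inf))
    n_assign[donor] <- n_assign[donor] - 1L
    excess <- excess - 1L
  }
  if (excess < 0) {
    extra <- order(quota - floor(quota), decreasing = TRUE)[seq_len(-excess)]
    n_assign[extra] <- n_assign[extra] + 1L
  }
  parcel_class <- sample(rep.int(seq_len(n_classes), n_assign))

  # parcel id map: parcels numbered row-major over the parcel grid
  pr <- (seq_len(h) - 1L) %/% ps           # parcel row of each pixel row
  pc <- (seq_len(w) - 1L) %/% ps
  parcel_ids <- outer(pr, pc, function(r, c) r * n_par_c + c + 1L)
  labels <- matrix(parcel_class[parcel_ids], h, w)

  n_pix <- h * w
  lab_vec <- as.vector(labels)             # column-major pixel order
  refl <- array(NA_real_, dim = c(h, w, config$n_dates, 12L),
                dimnames = list(NULL, NULL, NULL, S2_BANDS))
  for (t in seq_len(config$n_dates)) {
    day <- config$date_list[t]
    slab <- matrix(NA_real_, n_pix, 12L, dimnames = list(NULL, S2_BANDS))
    for (k in seq_len(n_classes)) {
      idx <- which(lab_vec == k)
      if (!length(idx)) next
      prof <- config$profiles[[k]]
      ndvi <- double_logistic_ndvi(day, prof)
      slab[idx, ] <- ndvi_to_reflectance(
        rep(ndvi, length(idx)), prof,
        noise_sd_other = config$noise_sd_other,
        band_baselines = config$band_baselines)
    }
    refl[, , t, ] <- slab
  }
  structure(list(
    reflectance = refl,
    labels = labels,
    parcel_ids = parcel_ids,
    class_names = names(config$profiles),
    band_names = S2_BANDS,
    date_list = config$date_list,
    config = config
  ), class = "labeled_scene")
}

#' @export
print.labeled_scene <- function(x, ...) {
  cat(sprintf("<labeled_scene> %d x %d pixels, %d dates, %d bands, %d classes\n",
              nrow(x$labels), ncol(x$labels), length(x$date_list),
              length(x$band_names), length(x$class_names)))
  print(table(factor(x$class_names[x$labels], levels = x$class_names)))
  invisible(x)
}

#' Split a scene into training and validation index sets
#'
#' Reproduces the study's hold-out protocol: 70% of the samples train the
#' network, 30% validate it, drawn either per pixel (stratified by class) or
#' per parcel (all pixels of a parcel stay on one side, guarding against
#' spatial leakage between neighbouring pixels).
#'
#' @param scene A `labeled_scene`.
#' @param train_fraction Fraction of samples assigned to training
#'   (default 0.7).
#' @param mode `"pixel"` (stratified by class) or `"parcel"`.
#' @param seed Integer seed.
#' @return List with integer vectors `train` and `test` of linear pixel
#'   indices (column-major), disjoint and jointly exhaustive.
#' @export
split_train_test <- function(scene, train_fraction = 0.7,
                             mode = c("pixel", "parcel"), seed = 1L) {
  stopifnot(inherits(scene, "labeled_scene"))
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must lie strictly between 0 and 1")
  mode <- match.arg(mode)
  set.seed(seed)
  lab <- as.vector(scene$labels)
  if (mode == "pixel") {
    train <- integer(0)
    for (k in sort(unique(lab))) {
      idx <- which(lab == k)
      n_tr <- round(train_fraction * length(idx))
      train <- c(train, sample(idx, n_tr))
    }
  } else {
    pid <- as.vector(scene$parcel_ids)
    # class of each parcel (parcels are label-pure by construction)
    par_tab <- unique(data.frame(pid = pid, lab = lab))
    train_parcels <- integer(0)
    for (k in sort(unique(par_tab$lab))) {
      pk <- par_tab$pid[par_tab$lab == k]
      if (length(pk) == 1L)
        warning("class ", scene$class_names[k],
                " owns a single parcel; it will be absent from one side ",
                "of the split")
      n_tr <- round(train_fraction * length(pk))
      n_tr <- max(1L, min(length(pk) - (length(pk) > 1L), n_tr))
      train_parcels <- c(train_parcels, sample(pk, n_tr))
    }
    train <- which(pid %in% train_parcels)
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(lab), train))
}

# ---- scene container I/O -------------------------------------------------

SCENE_FORMAT_VERSION <- 1L

#' Write / read a labeled scene container
#'
#' Scenes are stored as a single versioned serialized container holding the
#' reflectance array, label and parcel maps, band names and dates.
#'
#' @param scene A `labeled_scene`.
#' @param path File path.
#' @return `read_scene` returns the `labeled_scene`; `write_scene` returns
#'   `path` invisibly.
#' @export
write_scene <- function(scene, path) {
  stopifnot(inherits(scene, "labeled_scene"))
  saveRDS(list(format = "phenoclass_scene", version = SCENE_FORMAT_VERSION,
               scene = scene), path)
  invisible(path)
}

#' @rdname write_scene
#' @export
read_scene <- function(path) {
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("cannot read scene container: ",
                                           conditionMessage(e)))
  if (!is.list(obj) || !identical(obj$format, "phenoclass_scene"))
    stop("not a phenoclass scene container: ", path)
  if (obj$version > SCENE_FORMAT_VERSION)
    stop("scene container version ", obj$version, " is newer than supported")
  obj$scene
}

#' Export a scene as a long CSV table
#'
#' One row per pixel-date with the 12 band columns, label, parcel id and
#' coordinates; intended for interoperability with external tools.
#'
#' @param scene A `labeled_scene`.
#' @param path Output CSV path.
#' @export
scene_to_csv <- function(scene, path) {
  h <- nrow(scene$labels); w <- ncol(scene$labels)
  n_dates <- length(scene$date_list)
  rows <- expand.grid(row = seq_len(h), col = seq_len(w),
                      date_index = seq_len(n_dates))
  bands <- sapply(seq_len(12L), function(b)
    as.vector(scene$reflectance[, , , b]))
  colnames(bands) <- scene$band_names
  df <- cbind(rows,
              day = scene$date_list[rows$date_index],
              label = scene$class_names[as.vector(scene$labels)[
                rows$row + (rows$col - 1L) * h]],
              parcel_id = as.vector(scene$parcel_ids)[
                rows$row + (rows$col - 1L) * h],
              as.data.frame(bands))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a scene from per-date multiband GeoTIFF rasters
#'
#' Thin ingestion adapter for real data: a directory of per-date 12-band
#' TIFF rasters plus one single-band label raster. Bands on a different grid
#' are resampled to the label grid by nearest neighbour. Requires the
#' `tiff` package.
#'
#' @param band_paths Character vector of per-date raster file paths, in
#'   acquisition order.
#' @param label_path Path to the label raster (integer classes).
#' @param date_list Acquisition days matching `band_paths`.
#' @param class_names Character vector mapping label integers to names.
#' @return A `labeled_scene` (with `parcel_ids` set to per-pixel ids, as no
#'   parcel geometry is available).
#' @export
read_scene_rasters <- function(band_paths, label_path, date_list,
                               class_names) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for raster ingestion")
  if (length(band_paths) != length(date_list))
    stop("band_paths and date_list lengths differ")
  lab_img <- tiff::readTIFF(label_path, as.is = TRUE)
  if (length(dim(lab_img)) == 3L) lab_img <- lab_img[, , 1L]
  h <- nrow(lab_img); w <- ncol(lab_img)
  refl <- array(NA_real_, c(h, w, length(date_list), 12L),
                dimnames = list(NULL, NULL, NULL, S2_BANDS))
  for (t in seq_along(band_paths)) {
    img <- tiff::readTIFF(band_paths[t])
    if (length(dim(img)) != 3L || dim(img)[3L] < 12L)
      stop("raster ", band_paths[t], " does not have 12 bands")
    for (b in seq_len(12L))
      refl[, , t, b] <- resample_nearest(img[, , b], h, w)
  }
  refl[refl < 0] <- 0; refl[refl > 1] <- 1
  structure(list(
    reflectance = refl,
    labels = matrix(as.integer(lab_img), h, w),
    parcel_ids = matrix(seq_len(h * w), h, w),
    class_names = class_names,
    band_names = S2_BANDS,
    date_list = as.numeric(date_list),
    config = NULL
  ), class = "labeled_scene")
}

# nearest-neighbour resampling of a matrix onto an h x w grid
resample_nearest <- function(m, h, w) {
  if (nrow(m) == h && ncol(m) == w) return(m)
  ri <- pmin(nrow(m), pmax(1L, round((seq_len(h) - 0.5) * nrow(m) / h + 0.5)))
  ci <- pmin(ncol(m), pmax(1L, round((seq_len(w) - 0.5) * ncol(m) / w + 0.5)))
  m[ri, ci, drop = FALSE]
}
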