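#' Normalised difference vegetation index
#'
#' \deqn{NDVI = (B8 - B4) / (B8 + B4)} with the near-infrared (B8) and red
#' (B4) reflectances. The degenerate dark-pixel case `b8 + b4 = 0` returns 0
#' so the pipeline stays total on clipped pixels.
#'
#' @param b8,b4 Non-negative reflectance values (vectorized).
#' @return NDVI values in `[-1, 1]`.
#' @export
compute_ndvi <- function(b8, b4) {
  if (any(b8 < 0, na.rm = TRUE) || any(b4 < 0, na.rm = TRUE))
    stop("reflectances must be non-negative")
  s <- b8 + b4
  out <- ifelse(s == 0, 0, (b8 - b4) / s)
  out
}

#' Local Shannon entropy of an NDVI map
#'
#' For every pixel, the NDVI values in a centred `window` x `window`
#' neighbourhood (edges handled by reflection padding) are histogrammed into
#' `n_bins` equal-width bins over `[-1, 1]`, and the Shannon entropy
#' \eqn{-\sum_k p_k \log_2 p_k} of that histogram is returned, in bits. This
#' is the E_NDVI texture predictor: 0 on homogeneous neighbourhoods, up to
#' `log2(n_bins)` where the window spreads uniformly over all bins.
#'
#' @param ndvi_map Numeric matrix of NDVI values in `[-1, 1]`.
#' @param window Odd window side length, at least 3.
#' @param n_bins Number of histogram bins (at least 2).
#' @return Matrix of entropies, same shape as `ndvi_map`.
#' @export
ndvi_entropy <- function(ndvi_map, window = 5L, n_bins = 16L) {
  stopifnot(is.matrix(ndvi_map))
  if (window %% 2 != 1 || window < 3) stop("window must be odd and >= 3")
  if (n_bins < 2) stop("n_bins must be >= 2")
  h <- nrow(ndvi_map); w <- ncol(ndvi_map)
  if (window > h || window > w)
    stop("window (", window, ") larger than grid (", h, "x", w, ")")
  half <- (window - 1L) %/% 2L
  padded <- pad_reflect(ndvi_map, half)
  # bin index of every padded pixel; values clamped into [1, n_bins]
  bin <- floor((padded + 1) / 2 * n_bins) + 1L
  bin[bin < 1L] <- 1L; bin[bin > n_bins] <- n_bins
  counts <- array(0L, c(h, w, n_bins))
  ij <- cbind(rep(seq_len(h), times = w), rep(seq_len(w), each = h))
  for (di in seq_len(window)) {
    for (dj in seq_len(window)) {
      sub <- bin[di:(di + h - 1L), dj:(dj + w - 1L)]
      idx <- cbind(ij, as.vector(sub))
      counts[idx] <- counts[idx] + 1L
    }
  }
  p <- matrix(counts, h * w, n_bins) / (window * window)
  plogp <- p * log2(p)
  plogp[p == 0] <- 0
  matrix(-rowSums(plogp), h, w)
}

# reflection padding of a matrix by `half` pixels on every side
pad_reflect <- function(m, half) {
  if (half == 0L) return(m)
  ri <- c(rev(seq_len(half) + 1L), seq_len(nrow(m)),
          nrow(m) - seq_len(half))
  ci <- c(rev(seq_len(half) + 1L), seq_len(ncol(m)),
          ncol(m) - seq_len(half))
  m[ri, ci, drop = FALSE]
}

#' Assemble the 14-predictor feature cube from a scene
#'
#' For every acquisition date the 12 surface-reflectance bands are copied,
#' NDVI is computed per pixel, and E_NDVI is computed on that date's NDVI
#' map; pixels are flattened (column-major) to samples. The predictor order
#' is frozen: the 12 bands, then NDVI, then E_NDVI.
#'
#' @param scene A `labeled_scene`.
#' @param window,n_bins Parameters of the E_NDVI texture (see
#'   [ndvi_entropy()]).
#' @return An object of class `feature_cube`: `values` (samples x timesteps
#'   x 14 array), `feature_names`, `sample_index` (pixel coordinates),
#'   `labels` (integer classes), `class_names`, `parcel_ids`, `date_list`,
#'   and `standardization` (`NULL` until [standardize()] is applied).
#' @export
assemble_features <- function(scene, window = 5L, n_bins = 16L) {
  stopifnot(inherits(scene, "labeled_scene"))
  missing <- setdiff(S2_BANDS, dimnames(scene$reflectance)[[4L]])
  if (length(missing))
    stop("scene is missing band(s): ", paste(missing, collapse = ", "))
  h <- nrow(scene$labels); w <- ncol(scene$labels)
  n_pix <- h * w
  n_dates <- length(scene$date_list)
  values <- array(NA_real_, c(n_pix, n_dates, 14L),
                  dimnames = list(NULL, NULL, FEATURE_NAMES))
  for (t in seq_len(n_dates)) {
    for (b in seq_len(12L))
      values[, t, b] <- as.vector(scene$reflectance[, , t, S2_BANDS[b]])
    ndvi_mat <- matrix(compute_ndvi(values[, t, "B8"], values[, t, "B4"]),
                       h, w)
    values[, t, "NDVI"] <- as.vector(ndvi_mat)
    values[, t, "E_NDVI"] <- as.vector(ndvi_entropy(ndvi_mat, window, n_bins))
  }
  structure(list(
    values = values,
    feature_names = FEATURE_NAMES,
    sample_index = data.frame(row = rep(seq_len(h), times = w),
                              col = rep(seq_len(w), each = h)),
    labels = as.vector(scene$labels),
    class_names = scene$class_names,
    parcel_ids = as.vector(scene$parcel_ids),
    date_list = scene$date_list,
    standardization = NULL
  ), class = "feature_cube")
}

#' @export
print.feature_cube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<feature_cube> %d samples x %d timesteps x %d predictors%s\n",
              d[1], d[2], d[3],
              if (is.null(x$standardization)) "" else " (standardized)"))
  invisible(x)
}

#' Subset a feature cube by sample indices
#'
#' @param cube A `feature_cube`.
#' @param idx Integer sample indices.
#' @return A `feature_cube` restricted to those samples.
#' @export
subset_cube <- function(cube, idx) {
  stopifnot(inherits(cube, "feature_cube"))
  out <- cube
  out$values <- cube$values[idx, , , drop = FALSE]
  out$sample_index <- cube$sample_index[idx, , drop = FALSE]
  out$labels <- cube$labels[idx]
  out$parcel_ids <- cube$parcel_ids[idx]
  out
}

#' Z-score standardization of a feature cube
#'
#' Each predictor is centred and scaled over all samples and timesteps. With
#' `stats = NULL` the statistics are fitted (training path) and recorded in
#' the cube; supplying the stats of a training cube applies them unchanged
#' (validation path), preventing information leakage. A zero-variance
#' predictor keeps scale 1 with a warning.
#'
#' @param cube A `feature_cube`.
#' @param stats Optional list with numeric vectors `mean` and `scale`
#'   (length 14), as stored in a standardized cube's `standardization`.
#' @return The standardized `feature_cube`, with `standardization` set.
#' @export
standardize <- function(cube, stats = NULL) {
  stopifnot(inherits(cube, "feature_cube"))
  n_feat <- dim(cube$values)[3L]
  if (is.null(stats)) {
    mu <- apply(cube$values, 3L, mean)
    sc <- apply(cube$values, 3L, stats::sd)
    zero <- !is.finite(sc) | sc == 0
    if (any(zero)) {
      warning("zero-variance predictor(s): ",
              paste(cube$feature_names[zero], collapse = ", "),
              "; scale set to 1")
      sc[zero] <- 1
    }
    stats <- list(mean = mu, scale = sc)
  } else {
    stopifnot(length(stats$mean) == n_feat, length(stats$scale) == n_feat)
  }
  out <- cube
  for (j in seq_len(n_feat))
    out$values[, , j] <- (cube$values[, , j] - stats$mean[j]) / stats$scale[j]
  out$standardization <- stats
  out
}

# ---- cube container I/O --------------------------------------------------

CUBE_FORMAT_VERSION <- 1L

#' Write / read a feature-cube container
#' @param cube A `feature_cube`.
#' @param path File path.
#' @export
write_cube <- function(cube, path) {
  stopifnot(inherits(cube, "feature_cube"))
  saveRDS(list(format = "phenoclass_cube", version = CUBE_FORMAT_VERSION,
               cube = cube), path)
  invisible(path)
}

#' @rdname write_cube
#' @export
read_cube <- function(path) {
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("cannot read cube container: ",
                                           conditionMessage(e)))
  if (!is.list(obj) || !identical(obj$format, "phenoclass_cube"))
    stop("not a phenoclass cube container: ", path)
  obj$cube
}

#' Export a feature cube as a wide CSV (one row per sample)
#'
#' Columns are named `feature@day` for the 14 predictors at each of the
#' acquisition days, preceded by the pixel coordinates and label.
#'
#' @param cube A `feature_cube`.
#' @param path Output CSV path.
#' @export
cube_to_csv <- function(cube, path) {
  d <- dim(cube$values)
  flat <- matrix(aperm(cube$values, c(1L, 3L, 2L)), d[1L], d[2L] * d[3L])
  colnames(flat) <- as.vector(outer(cube$feature_names, cube$date_list,
                                    function(f, d) paste0(f, "@", d)))
  df <- cbind(cube$sample_index,
              label = cube$class_names[cube$labels],
              as.data.frame(flat))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
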