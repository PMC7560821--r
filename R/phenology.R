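#' @keywords internal
"_PACKAGE"

# Sentinel-2 L2A surface-reflectance bands retained by the pipeline (B10 is
# atmosphere-only and excluded from L2A products).
S2_BANDS <- c("B1", "B2", "B3", "B4", "B5", "B6", "B7", "B8", "B8a", "B9",
              "B11", "B12")

# Fixed predictor order of the feature cube: 12 bands, NDVI, NDVI entropy.
FEATURE_NAMES <- c(S2_BANDS, "NDVI", "E_NDVI")

# Class-independent reflectance baselines used for bands that carry no class
# signal. Values are plausible mid-range L2A reflectances per band.
DEFAULT_BAND_BASELINES <- c(
  B1 = 0.10, B2 = 0.09, B3 = 0.11, B4 = 0.12, B5 = 0.16, B6 = 0.22,
  B7 = 0.25, B8 = 0.27, B8a = 0.28, B9 = 0.30, B11 = 0.22, B12 = 0.15
)

#' Create a phenology profile for one land-use class
#'
#' A phenology profile parameterizes the seasonal NDVI trajectory of a class
#' as a double-logistic curve (green-up and senescence transitions) and the
#' spectral rules used to turn NDVI into a 12-band reflectance vector. The
#' day axis is the agronomic year: day 0 is September 1, day 364 is
#' August 31.
#'
#' @param class_name Character label (e.g. `"RIC"` for rice).
#' @param ndvi_base Baseline NDVI outside the growing cycle, in `[-0.2, 0.3]`.
#' @param ndvi_amplitude Seasonal NDVI amplitude, in `[0, 0.8]`;
#'   `ndvi_base + ndvi_amplitude` must not exceed 1.
#' @param greenup_day,senescence_day Inflection days of the green-up and
#'   senescence transitions (agronomic day-of-year, 0--365);
#'   `greenup_day < senescence_day`.
#' @param greenup_rate,senescence_rate Positive logistic slopes (1/day).
#' @param band_noise_sd Gaussian noise sd (reflectance units) applied to the
#'   informative bands of this class.
#' @param informative_bands Subset of the 12 band names that carry class
#'   signal; must include `"B4"` and `"B8"` (the NDVI-defining pair).
#' @param band_sum Target value of `B4 + B8` before noise; together with the
#'   NDVI value it fixes both bands exactly.
#' @param band_coefs Named list of `c(intercept, slope)` pairs giving, for
#'   each informative band other than B4/B8, its affine dependence on NDVI.
#'   Bands omitted here and from `informative_bands` take the
#'   class-independent baseline.
#' @return An object of class `phenology_profile`.
#' @examples
#' rice <- phenology_profile("RIC", ndvi_base = 0.05, ndvi_amplitude = 0.65,
#'                           greenup_day = 260, senescence_day = 350)
#' double_logistic_ndvi(300, rice)
#' @export
phenology_profile <- function(class_name,
                              ndvi_base = 0.15,
                              ndvi_amplitude = 0.4,
                              greenup_day = 200,
                              senescence_day = 300,
                              greenup_rate = 0.1,
                              senescence_rate = 0.1,
                              band_noise_sd = 0.01,
                              informative_bands = c("B4", "B8"),
                              band_sum = 0.45,
                              band_coefs = NULL) {
  stopifnot(is.character(class_name), length(class_name) == 1L)
  if (ndvi_base < -0.2 || ndvi_base > 0.3)
    stop("ndvi_base must lie in [-0.2, 0.3]")
  if (ndvi_amplitude < 0 || ndvi_amplitude > 0.8)
    stop("ndvi_amplitude must lie in [0, 0.8]")
  if (ndvi_base + ndvi_amplitude > 1)
    stop("ndvi_base + ndvi_amplitude must not exceed 1")
  if (!(greenup_day < senescence_day))
    stop("greenup_day must be strictly less than senescence_day")
  if (greenup_rate <= 0 || senescence_rate <= 0)
    stop("logistic rates must be positive")
  if (band_noise_sd < 0) stop("band_noise_sd must be non-negative")
  bad <- setdiff(informative_bands, S2_BANDS)
  if (length(bad)) stop("unknown band name(s): ", paste(bad, collapse = ", "))
  if (!all(c("B4", "B8") %in% informative_bands))
    stop("informative_bands must include B4 and B8")
  if (band_sum <= 0 || band_sum > 1) stop("band_sum must lie in (0, 1]")
  if (!is.null(band_coefs)) {
    if (!all(names(band_coefs) %in% S2_BANDS))
      stop("band_coefs names must be band names")
    if (!all(vapply(band_coefs, length, 0L) == 2L))
      stop("each band_coefs entry must be c(intercept, slope)")
  }
  structure(list(
    class_name = class_name,
    ndvi_base = ndvi_base,
    ndvi_amplitude = ndvi_amplitude,
    greenup_day = greenup_day,
    senescence_day = senescence_day,
    greenup_rate = greenup_rate,
    senescence_rate = senescence_rate,
    band_noise_sd = band_noise_sd,
    informative_bands = informative_bands,
    band_sum = band_sum,
    band_coefs = band_coefs
  ), class = "phenology_profile")
}

#' @export
print.phenology_profile <- function(x, ...) {
  cat(sprintf(
    "<phenology_profile '%s'> NDVI %.2f + %.2f, green-up day %g, senescence day %g\n",
    x$class_name, x$ndvi_base, x$ndvi_amplitude, x$greenup_day,
    x$senescence_day))
  invisible(x)
}

#' Double-logistic seasonal NDVI curve
#'
#' Evaluates the standard remote-sensing greenness model
#' \deqn{NDVI(d) = b + A\left[\frac{1}{1+e^{-r_g (d-d_g)}} -
#'   \frac{1}{1+e^{-r_s (d-d_s)}}\right]}
#' where \eqn{b} is the baseline, \eqn{A} the amplitude, and
#' \eqn{(d_g, r_g)}, \eqn{(d_s, r_s)} the green-up and senescence inflection
#' days and rates.
#'
#' @param day Numeric vector of agronomic day-of-year values.
#' @param profile A [phenology_profile()].
#' @return NDVI values (unitless, within `[-1, 1]`), same length as `day`.
#' @export
double_logistic_ndvi <- function(day, profile) {
  stopifnot(inherits(profile, "phenology_profile"), is.numeric(day))
  up <- stats::plogis(profile$greenup_rate * (day - profile$greenup_day))
  down <- stats::plogis(profile$senescence_rate * (day - profile$senescence_day))
  profile$ndvi_base + profile$ndvi_amplitude * (up - down)
}

#' Map an NDVI value to a 12-band reflectance vector
#'
#' B4 (red) and B8 (near infrared) are solved exactly from the NDVI value and
#' the profile's `band_sum` (so `(B8-B4)/(B8+B4)` equals `ndvi` before
#' noise). Other informative bands are affine functions of NDVI with
#' class-specific coefficients; non-informative bands take the
#' class-independent baseline. Gaussian noise is then added (profile
#' `band_noise_sd` on informative bands, `noise_sd_other` elsewhere) and the
#' result is clipped to `[0, 1]`.
#'
#' @param ndvi NDVI value(s) in `[-1, 1]`.
#' @param profile A [phenology_profile()].
#' @param noise_sd_other Noise sd for the non-informative bands (class
#'   independent so those bands carry no class signal).
#' @param band_baselines Named baseline reflectance per band.
#' @return If `ndvi` has length 1, a named length-12 vector; otherwise a
#'   `length(ndvi)` x 12 matrix with band columns.
#' @export
ndvi_to_reflectance <- function(ndvi, profile,
                                noise_sd_other = 0,
                                band_baselines = DEFAULT_BAND_BASELINES) {
  stopifnot(inherits(profile, "phenology_profile"))
  if (any(!is.finite(ndvi)) || any(ndvi < -1) || any(ndvi > 1))
    stop("ndvi must lie in [-1, 1]")
  n <- length(ndvi)
  out <- matrix(rep(band_baselines[S2_BANDS], each = n), nrow = n,
                dimnames = list(NULL, S2_BANDS))
  s <- profile$band_sum
  out[, "B8"] <- s * (1 + ndvi) / 2
  out[, "B4"] <- s * (1 - ndvi) / 2
  affine <- setdiff(profile$informative_bands, c("B4", "B8"))
  for (b in affine) {
    co <- profile$band_coefs[[b]]
    if (is.null(co))
      stop("informative band ", b, " has no band_coefs entry")
    out[, b] <- co[1] + co[2] * ndvi
  }
  inf <- S2_BANDS %in% profile$informative_bands
  if (profile$band_noise_sd > 0 && any(inf))
    out[, inf] <- out[, inf] +
      stats::rnorm(n * sum(inf), sd = profile$band_noise_sd)
  if (noise_sd_other > 0 && any(!inf))
    out[, !inf] <- out[, !inf] +
      stats::rnorm(n * sum(!inf), sd = noise_sd_other)
  out[out < 0] <- 0
  out[out > 1] <- 1
  if (n == 1L) out[1L, ] else out
}

#' Default 16-class phenology profile set
#'
#' Profiles named after the land-use legend of the Valencia CAP inspections:
#' rice (RIC) with a strong summer cycle, the winter cereals (BAR, OAT, WHE,
#' TRI) with winter--spring cycles, sunflower (SUN) a spring--summer cycle,
#' fallow (FAL) a weak spring flush, and the permanent and natural classes
#' (TRE, FOR, VIN, SHR, DFR, CIT, OLI, PAS, FRU) flat, mutually similar
#' trajectories with low amplitude. Days count from September 1.
#'
#' @param band_noise_sd Noise sd shared by all profiles.
#' @return Named list of [phenology_profile()] objects.
#' @export
default_profiles <- function(band_noise_sd = 0.01) {
  p <- function(name, base, amp, gup, sen, rg = 0.08, rs = 0.08, sum. = 0.45)
    phenology_profile(name, ndvi_base = base, ndvi_amplitude = amp,
                      greenup_day = gup, senescence_day = sen,
                      greenup_rate = rg, senescence_rate = rs,
                      band_noise_sd = band_noise_sd, band_sum = sum.)
  profs <- list(
    # natural vegetation: green most of the year, mild spring bump
    TRE = p("TRE", 0.30, 0.15, 150, 330, 0.03, 0.03),
    FOR = p("FOR", 0.30, 0.20, 140, 340, 0.03, 0.03, sum. = 0.50),
    SHR = p("SHR", 0.25, 0.15, 130, 320, 0.03, 0.03),
    PAS = p("PAS", 0.20, 0.25, 100, 290, 0.04, 0.04),
    # permanent crops: flat-ish, mutually similar
    VIN = p("VIN", 0.18, 0.22, 220, 360, 0.05, 0.06, sum. = 0.42),
    DFR = p("DFR", 0.20, 0.18, 210, 360, 0.04, 0.05),
    CIT = p("CIT", 0.30, 0.12, 160, 350, 0.02, 0.03, sum. = 0.48),
    OLI = p("OLI", 0.22, 0.12, 180, 350, 0.03, 0.03, sum. = 0.40),
    FRU = p("FRU", 0.25, 0.15, 200, 350, 0.04, 0.04, sum. = 0.46),
    # annual crops with strong cycles
    RIC = p("RIC", 0.05, 0.65, 260, 350, 0.15, 0.12, sum. = 0.55),
    SUN = p("SUN", 0.10, 0.55, 225, 320, 0.12, 0.12, sum. = 0.50),
    FAL = p("FAL", 0.12, 0.12, 180, 280, 0.05, 0.05),
    # winter cereals: green-up late autumn, senescence late spring
    BAR = p("BAR", 0.10, 0.50, 80, 265, 0.10, 0.12, sum. = 0.48),
    OAT = p("OAT", 0.10, 0.48, 90, 275, 0.09, 0.11, sum. = 0.48),
    WHE = p("WHE", 0.10, 0.52, 95, 280, 0.10, 0.12, sum. = 0.50),
    TRI = p("TRI", 0.10, 0.46, 85, 270, 0.09, 0.11, sum. = 0.46)
  )
  profs
}

# Per-class pixel counts of the Valencia in-situ checks; used for the default
# class-proportion vector so simulated scenes mirror the study's imbalance.
CLASS_PIXEL_COUNTS <- c(
  TRE = 663995, FOR = 495223, VIN = 240418, RIC = 230935, SHR = 165110,
  DFR = 153727, CIT = 125161, FAL = 84491, BAR = 71623, OLI = 49829,
  PAS = 33408, FRU = 29859, OAT = 28754, WHE = 11437, SUN = 10104,
  TRI = 4252
)
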