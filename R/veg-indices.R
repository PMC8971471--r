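#' Vegetation indices from band reflectance
#'
#' Computes the six broadband vegetation indices used for empirical LAI
#' inversion from blue, green, red and near-infrared reflectance:
#'
#' * `EVI  = 2.5 (NIR - R) / (NIR + 6 R - 7.5 B + 1)`
#' * `EVI2 = 2.5 (NIR - R) / (NIR + 2.4 R + 1)`
#' * `MSR  = (NIR/R - 1) / (sqrt(NIR/R) + 1)`
#' * `NDVI = (NIR - R) / (NIR + R)`
#' * `OSAVI = (NIR - R) / (NIR + R + 0.16)`
#' * `RVI  = NIR / R`
#'
#' The green band is accepted for interface completeness but none of
#' these six indices uses it.
#'
#' @param blue,green,red,nir Band reflectances in \[0, 1\]; vectorized,
#'   recycled to a common length.
#' @return Data frame with columns `evi`, `evi2`, `msr`, `ndvi`,
#'   `osavi`, `rvi`. An index whose denominator is zero (or, for
#'   MSR/RVI, a non-positive red band) is `NA` for that row; the other
#'   indices are still returned.
#' @examples
#' compute_vegetation_indices(blue = 0.05, green = 0.08,
#'                            red = 0.1, nir = 0.4)
#' @export
compute_vegetation_indices <- function(blue, green, red, nir) {
  n <- max(length(blue), length(green), length(red), length(nir))
  blue <- rep_len(blue, n); green <- rep_len(green, n)
  red <- rep_len(red, n); nir <- rep_len(nir, n)
  bands <- cbind(blue, green, red, nir)
  if (any(bands < 0 | bands > 1, na.rm = TRUE)) {
    stop("band reflectances must lie in [0, 1]", call. = FALSE)
  }

  safe_div <- function(num, den) ifelse(den == 0, NA_real_, num / den)

  evi <- safe_div(2.5 * (nir - red), nir + 6 * red - 7.5 * blue + 1)
  evi2 <- safe_div(2.5 * (nir - red), nir + 2.4 * red + 1)
  ndvi <- safe_div(nir - red, nir + red)
  osavi <- safe_div(nir - red, nir + red + 0.16)
  ratio <- ifelse(red > 0, nir / red, NA_real_)
  rvi <- ratio
  msr <- ifelse(is.na(ratio), NA_real_, (ratio - 1) / (sqrt(ratio) + 1))

  data.frame(evi = evi, evi2 = evi2, msr = msr, ndvi = ndvi,
             osavi = osavi, rvi = rvi)
}

#' Functional forms of the published univariate LAI inversion models
#'
#' The form used for each index when reproducing the published
#' single-index inversion models: linear for EVI, NDVI and RVI, power
#' for EVI2, exponential for MSR and OSAVI.
#'
#' @return Named character vector mapping index name to
#'   `"linear"`/`"power"`/`"exponential"`.
#' @export
inversion_form_table <- function() {
  c(evi = "linear", evi2 = "power", msr = "exponential",
    ndvi = "linear", osavi = "exponential", rvi = "linear")
}

#' Published OSAVI LAI inversion model
#'
#' The exponential OSAVI model `LAI = 0.21 * exp(4.68 * OSAVI)` that the
#' pipeline ships as its default single-index inversion model (it is the
#' best-ranked of the six published models). Useful for predicting LAI
#' from reflectance without refitting.
#'
#' @return An `inversion_model` object (see [fit_univariate_inversion()]).
#' @examples
#' predict_lai(osavi_reference_model(), 0.45)
#' @export
osavi_reference_model <- function() {
  new_inversion_model(index = "osavi", form = "exponential",
                      a = 0.21, b = 4.68)
}
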