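#' Band order used throughout the package
#'
#' Six Landsat-style surface-reflectance bands, in the fixed order every
#' trajectory, training window and raster stack uses.
#'
#' @return character vector of length 6
#' @export
band_names <- function() c("blue", "green", "red", "nir", "swir1", "swir2")

#' Annual six-band spectral series for one pixel
#'
#' The unit of data every algorithm in the package consumes: one surface
#' reflectance value per band per calendar year, with a per-year missing
#' flag (cloud/compositing gaps). Reflectance is unitless, nominal range
#' 0-1.
#'
#' @param years integer vector of strictly increasing, consecutive calendar
#'   years.
#' @param reflectance numeric matrix, `length(years)` rows by 6 columns in
#'   [band_names()] order. Rows for missing years may be `NA`.
#' @param missing logical vector flagging years with no valid observation.
#'   Defaults to rows containing any `NA`.
#' @return an `annual_spectra` object (list with `years`, `reflectance`,
#'   `missing`).
#' @export
annual_spectra <- function(years, reflectance, missing = NULL) {
  years <- as.integer(years)
  assert(length(years) >= 1, "at least one year required")
  assert(all(diff(years) == 1L), "years must be strictly increasing and consecutive")
  reflectance <- as.matrix(reflectance)
  assert(ncol(reflectance) == 6, "exactly 6 bands per year required")
  assert(nrow(reflectance) == length(years), "one reflectance row per year required")
  colnames(reflectance) <- band_names()
  if (is.null(missing)) missing <- apply(reflectance, 1, function(r) any(!is.finite(r)))
  missing <- as.logical(missing)
  assert(length(missing) == length(years), "one missing flag per year required")
  ok <- reflectance[!missing, , drop = FALSE]
  assert(all(is.finite(ok)), "reflectance must be finite for all non-missing years")
  structure(list(years = years, reflectance = reflectance, missing = missing),
            class = "annual_spectra")
}

#' @export
print.annual_spectra <- function(x, ...) {
  cat(sprintf("<annual_spectra> %d-%d (%d years, %d missing)\n",
              min(x$years), max(x$years), length(x$years), sum(x$missing)))
  invisible(x)
}

#' @export
length.annual_spectra <- function(x) length(x$years)

#' Slice an annual_spectra to a year range
#' @param x annual_spectra
#' @param from,to first and last calendar year to keep
#' @return annual_spectra
#' @export
slice_years <- function(x, from, to) {
  keep <- x$years >= from & x$years <= to
  assert(any(keep), "requested year range is empty")
  annual_spectra(x$years[keep], x$reflectance[keep, , drop = FALSE], x$missing[keep])
}
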