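#' Normalized burn ratio
#'
#' NBR = (NIR - SWIR2) / (NIR + SWIR2). Sensitive to canopy loss and
#' burning; the index the segmentation stage operates on.
#'
#' @param nir,swir2 non-negative reflectance values (vectorized).
#' @return NBR values in \[-1, 1\]; `NA` where either input is `NA`.
#' @export
compute_nbr <- function(nir, swir2) {
  assert(length(nir) == length(swir2), "nir and swir2 must have equal length")
  ok <- !is.na(nir) & !is.na(swir2)
  assert(all(nir[ok] >= 0) && all(swir2[ok] >= 0), "reflectance must be non-negative")
  if (any(ok & nir == 0 & swir2 == 0))
    stop_bd("NBR undefined: nir and swir2 are both zero")
  (nir - swir2) / (nir + swir2)
}

#' NBR series of an annual_spectra
#' @param spectra annual_spectra
#' @return named numeric vector (names = years), NA for missing years
#' @export
nbr_series <- function(spectra) {
  v <- rep(NA_real_, length(spectra$years))
  obs <- !spectra$missing
  v[obs] <- compute_nbr(spectra$reflectance[obs, "nir"],
                        spectra$reflectance[obs, "swir2"])
  names(v) <- spectra$years
  v
}

#' Year-over-year NBR decrease (dNBR)
#'
#' dNBR at year t is NBR(t-1) - NBR(t): decline-positive, so the severity
#' thresholds 0.1 / 0.15 / 0.25 apply directly to its value. When a year is
#' cloud-masked, the difference is taken between the nearest flanking
#' non-missing years and assigned to the later one; the first observed year
#' has no value.
#'
#' @param spectra annual_spectra with at least 2 non-missing years
#' @return named numeric vector aligned with `spectra$years`; `NA` where
#'   undefined (first observed year, missing years).
#' @export
compute_dnbr_series <- function(spectra) {
  nbr <- nbr_series(spectra)
  idx <- which(!is.na(nbr))
  if (length(idx) == 0) stop_bd("all years missing: dNBR undefined")
  assert(length(idx) >= 2, "at least 2 non-missing years required for dNBR")
  out <- rep(NA_real_, length(nbr))
  out[idx[-1]] <- -diff(nbr[idx])
  names(out) <- names(nbr)
  out
}

#' Defoliation severity from a dNBR drop
#'
#' Partition of the non-negative drop axis: `none` below 0.1 (excluded from
#' the pest reference set), `low` in \[0.1, 0.15), `medium` in \[0.15, 0.25),
#' `high` at 0.25 and above. Negative drops (greening) are `none`.
#'
#' @param dnbr_drop finite numeric vector of decline-positive dNBR values
#' @return factor with levels none, low, medium, high
#' @export
classify_severity <- function(dnbr_drop) {
  assert(all(is.finite(dnbr_drop)), "dnbr_drop must be finite")
  lev <- c("none", "low", "medium", "high")
  lab <- lev[findInterval(dnbr_drop, c(0.1, 0.15, 0.25)) + 1L]
  factor(lab, levels = lev)
}

#' Map codes for defoliation severities
#' @param severity factor/character from [classify_severity()] (not "none")
#' @return integer map code (6 low, 7 medium, 8 high)
#' @export
severity_code <- function(severity) {
  codes <- c(low = 6L, medium = 7L, high = 8L)
  severity <- as.character(severity)
  assert(all(severity %in% names(codes)),
         "severity must be one of low/medium/high")
  unname(codes[severity])
}
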