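# Per-pixel and scene-level glue: segmentation -> window extraction ->
# TempCNN classification -> annual series assembly.

#' Detect and classify disturbances for one pixel
#'
#' Runs the two-step hybrid method on one annual spectral series: NBR
#' segmentation proposes up to 5 most-recent disturbance segments; each
#' segment lasting less than 10 years gets a 10-year window anchored the
#' year before its start and is classified; predicted training classes are
#' remapped to final map codes and stamped onto the annual series.
#'
#' @param spectra annual_spectra
#' @param model trained `tempcnn_model`
#' @param params [seg_params()]
#' @return list with `series` (annual map codes) and `segments`
#'   (data.frame incl. predicted class and map_code)
#' @export
map_pixel <- function(spectra, model, params = seg_params()) {
  nbr <- nbr_series(spectra)
  segs <- if (sum(!is.na(nbr)) >= 6) segment_pixel(nbr, spectra$years, params)
          else data.frame(start_year = integer(0), end_year = integer(0),
                          start_nbr = numeric(0), end_nbr = numeric(0),
                          magnitude = numeric(0))
  segs$class <- character(nrow(segs))
  segs$map_code <- integer(nrow(segs))
  if (nrow(segs)) {
    for (i in seq_len(nrow(segs))) {
      if (!is_classifiable(segs[i, ])) {
        segs$class[i] <- NA_character_; segs$map_code[i] <- 0L
        next
      }
      win <- extract_inference_window(spectra, segs$start_year[i])
      cl <- predict(model, win$window, type = "class")
      segs$class[i] <- cl
      segs$map_code[i] <- remap_to_final(cl)
    }
  }
  list(series = assemble_series(segs, spectra$years), segments = segs)
}

#' Map a whole scene
#'
#' Applies [map_pixel()] to every pixel of a years x 6 x H x W reflectance
#' stack and returns the annual code stack plus a per-pixel segment table.
#'
#' @param spectra array years x 6 x H x W (NA = missing observation)
#' @param years calendar years of the stack
#' @param model trained `tempcnn_model`
#' @param params [seg_params()]
#' @return list with `codes` (integer array years x H x W) and `segments`
#'   (data.frame with row, col, segment fields)
#' @export
map_scene <- function(spectra, years, model, params = seg_params()) {
  H <- dim(spectra)[3]; W <- dim(spectra)[4]
  codes <- array(0L, c(length(years), H, W), dimnames = list(years, NULL, NULL))
  seg_list <- list()
  for (cc in seq_len(W)) for (r in seq_len(H)) {
    refl <- matrix(spectra[, , r, cc], nrow = length(years),
                   dimnames = list(NULL, band_names()))
    sp <- annual_spectra(years, refl)
    res <- map_pixel(sp, model, params)
    codes[, r, cc] <- as.integer(res$series)
    if (nrow(res$segments)) {
      res$segments$row <- r; res$segments$col <- cc
      seg_list[[length(seg_list) + 1]] <- res$segments
    }
  }
  segments <- if (length(seg_list)) do.call(rbind, seg_list)
              else data.frame(start_year = integer(0), end_year = integer(0),
                              start_nbr = numeric(0), end_nbr = numeric(0),
                              magnitude = numeric(0), class = character(0),
                              map_code = integer(0), row = integer(0),
                              col = integer(0))
  list(codes = codes, segments = segments)
}
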