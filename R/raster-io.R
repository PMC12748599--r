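# Plain-text raster I/O. The environment provides no GeoTIFF bindings, so
# rasters are stored as ESRI ASCII grids (.asc), a standard text format
# GDAL/QGIS read natively; georeferencing (corner, cell size) passes
# through unchanged. File naming follows the published products
# (annual_<year>, latest_type, latest_year, ending_year, legend_type.csv).

#' Write a matrix as an ESRI ASCII grid
#' @param m numeric/integer matrix (row 1 = northernmost row)
#' @param path output path (.asc)
#' @param xllcorner,yllcorner,cellsize georeferencing (pass-through)
#' @param nodata value written for `NA`
#' @return invisibly, the path
#' @export
write_ascii_grid <- function(m, path, xllcorner = 0, yllcorner = 0,
                             cellsize = 30, nodata = -9999) {
  hdr <- c(paste("ncols", ncol(m)), paste("nrows", nrow(m)),
           paste("xllcorner", xllcorner), paste("yllcorner", yllcorner),
           paste("cellsize", cellsize), paste("NODATA_value", nodata))
  m[is.na(m)] <- nodata
  body <- apply(m, 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an ESRI ASCII grid
#' @param path .asc path
#' @return numeric matrix with attributes `xllcorner`, `yllcorner`,
#'   `cellsize`; nodata cells are `NA`
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  vals <- stats::setNames(vapply(hdr, function(x) as.numeric(x[2]), 0),
                          tolower(vapply(hdr, `[`, "", 1)))
  m <- do.call(rbind, lapply(lines[-(1:6)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  assert(nrow(m) == vals["nrows"] && ncol(m) == vals["ncols"],
         "grid body does not match header dimensions: ", path)
  m[m == vals["nodata_value"]] <- NA
  attr(m, "xllcorner") <- vals[["xllcorner"]]
  attr(m, "yllcorner") <- vals[["yllcorner"]]
  attr(m, "cellsize") <- vals[["cellsize"]]
  m
}

#' Write a simulated scene to disk
#'
#' One grid per year per band (`sr_<year>_<band>.asc`) plus one label grid
#' per year (`label_<year>.asc`).
#'
#' @param scene result of [simulate_scene()]
#' @param dir output directory (created if needed)
#' @return invisibly, the directory
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (yi in seq_along(scene$years)) {
    y <- scene$years[yi]
    for (b in seq_len(6))
      write_ascii_grid(scene$spectra[yi, b, , ],
                       file.path(dir, sprintf("sr_%d_%s.asc", y, band_names()[b])))
    write_ascii_grid(scene$labels[yi, , ],
                     file.path(dir, sprintf("label_%d.asc", y)))
  }
  invisible(dir)
}

#' Read an annual six-band scene stack
#'
#' Years are inferred from the `sr_<year>_<band>.asc` filenames; a missing
#' year inside the span is flagged (all-`NA` slice), not an error; grids
#' with inconsistent dimensions raise an error naming the offenders.
#'
#' @param dir directory written by [write_scene()] (or following its naming)
#' @return list with `years` (full consecutive span), `spectra` (array
#'   years x 6 x H x W), `missing_years`, `labels` (array, if label grids
#'   are present) and `georef`
#' @export
read_annual_stack <- function(dir) {
  files <- list.files(dir, pattern = "^sr_\\d+_[a-z0-9]+\\.asc$")
  assert(length(files) > 0, "no sr_<year>_<band>.asc files in ", dir)
  info <- regmatches(files, regexec("^sr_(\\d+)_([a-z0-9]+)\\.asc$", files))
  yrs <- as.integer(vapply(info, `[`, "", 2))
  bnd <- vapply(info, `[`, "", 3)
  assert(all(bnd %in% band_names()), "unknown band in filenames")
  present <- sort(unique(yrs))
  assert(length(present) >= 10, "at least 10 annual files required")
  years <- seq(min(present), max(present))
  first <- read_ascii_grid(file.path(dir, files[1]))
  H <- nrow(first); W <- ncol(first)
  bad <- character(0)
  spectra <- array(NA_real_, c(length(years), 6, H, W),
                   dimnames = list(years, band_names(), NULL, NULL))
  for (i in seq_along(files)) {
    g <- read_ascii_grid(file.path(dir, files[i]))
    if (nrow(g) != H || ncol(g) != W) { bad <- c(bad, files[i]); next }
    spectra[as.character(yrs[i]), bnd[i], , ] <- g
  }
  if (length(bad))
    stop_bd("grid dimension mismatch in: ", paste(bad, collapse = ", "))
  labels <- NULL
  lf <- list.files(dir, pattern = "^label_\\d+\\.asc$")
  if (length(lf)) {
    labels <- array(0L, c(length(years), H, W), dimnames = list(years, NULL, NULL))
    for (f in lf) {
      y <- as.integer(sub("^label_(\\d+)\\.asc$", "\\1", f))
      labels[as.character(y), , ] <- as.integer(read_ascii_grid(file.path(dir, f)))
    }
  }
  list(years = years, spectra = spectra,
       missing_years = setdiff(years, present), labels = labels,
       georef = attributes(first)[c("xllcorner", "yllcorner", "cellsize")])
}

#' Write the assembled map products
#'
#' One coded grid per year (`annual_<year>.asc`), the latest-disturbance
#' composites (`latest_type.asc`, `latest_year.asc`, `ending_year.asc`) and
#' the legend (`legend_type.csv`).
#'
#' @param code_stack integer array years x H x W with codes 0-8
#' @param years calendar years of the stack
#' @param dir output directory
#' @param georef list with xllcorner, yllcorner, cellsize (pass-through)
#' @return invisibly, the directory
#' @export
write_products <- function(code_stack, years, dir,
                           georef = list(xllcorner = 0, yllcorner = 0,
                                         cellsize = 30)) {
  assert(all(code_stack %in% 0:8), "map codes outside 0-8 refused")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wg <- function(m, name)
    write_ascii_grid(m, file.path(dir, name), georef$xllcorner %||% 0,
                     georef$yllcorner %||% 0, georef$cellsize %||% 30)
  for (yi in seq_along(years))
    wg(code_stack[yi, , ], sprintf("annual_%d.asc", years[yi]))
  H <- dim(code_stack)[2]; W <- dim(code_stack)[3]
  lt <- matrix(0L, H, W); ly <- matrix(NA_integer_, H, W); ey <- ly
  for (r in seq_len(H)) for (cc in seq_len(W)) {
    s <- stats::setNames(code_stack[, r, cc], years)
    lp <- latest_products(s)
    lt[r, cc] <- lp$latest_type
    ly[r, cc] <- lp$latest_start_year
    ey[r, cc] <- lp$latest_end_year
  }
  wg(lt, "latest_type.asc"); wg(ly, "latest_year.asc"); wg(ey, "ending_year.asc")
  write.csv(map_legend(), file.path(dir, "legend_type.csv"), row.names = FALSE)
  invisible(dir)
}
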