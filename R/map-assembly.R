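# Inference-time subsequence extraction, per-pixel annual disturbance
# series construction, latest-disturbance products, and post-processing
# (sieve and wetland filters).

#' Extract the 10-year inference window for a detected break
#'
#' The window is anchored one year before the break so the classifier sees
#' the healthy state; if that year is missing, the anchor advances to the
#' first non-missing year; and the anchor is clamped to `last_year - 9`
#' (the generalization of the "breaks after 2015 start in 2015" rule for a
#' series ending in 2024). Missing years inside the window are linearly
#' interpolated and flagged.
#'
#' @param spectra annual_spectra covering at least 10 years
#' @param break_year detected disturbance start year (within the series)
#' @return list of class `subsequence`: `anchor_year`, `window` (10 x 6),
#'   `imputed` (logical per window year), `years`
#' @export
extract_inference_window <- function(spectra, break_year) {
  n <- length(spectra$years)
  assert(n >= 10, "series shorter than 10 years")
  assert(break_year %in% spectra$years, "break_year outside the series")
  anchor <- break_year - 1L
  if (anchor < spectra$years[1]) anchor <- spectra$years[1]
  i <- match(anchor, spectra$years)
  while (i <= n && spectra$missing[i]) i <- i + 1L
  assert(i <= n, "no non-missing year at or after the anchor")
  anchor <- spectra$years[i]
  anchor <- min(anchor, spectra$years[n] - 9L)
  win <- slice_years(spectra, anchor, anchor + 9L)
  refl <- win$reflectance
  if (any(win$missing)) {
    full <- spectra$reflectance[!spectra$missing, , drop = FALSE]
    fy <- spectra$years[!spectra$missing]
    for (b in seq_len(6))
      refl[win$missing, b] <- approx(fy, full[, b], xout = win$years[win$missing],
                                     rule = 2)$y
  }
  structure(list(anchor_year = anchor, window = refl,
                 imputed = win$missing, years = win$years),
            class = "subsequence")
}

#' Assemble one pixel's annual disturbance code series
#'
#' Rapid codes (1 wildfire, 2 harvesting, 3 windthrow, 4 water extension)
#' are stamped at a single year: the segment start, except wildfire
#' segments stretched beyond 2 years by missing data, which stamp the
#' segment end. Multi-year codes (5-8, the pest classes) are stamped for
#' every year of the segment span. Code 0 predictions stamp nothing.
#'
#' @param segments data.frame with `start_year`, `end_year`, `map_code`
#'   (non-overlapping in years)
#' @param span integer vector of calendar years the series covers
#' @return integer vector of map codes (class `annual_series`, names =
#'   years)
#' @export
assemble_series <- function(segments, span) {
  out <- stats::setNames(rep(0L, length(span)), span)
  if (!nrow(segments)) return(structure(out, class = "annual_series"))
  segments <- segments[order(segments$start_year), , drop = FALSE]
  if (nrow(segments) > 1) {
    o <- segments[order(segments$start_year), ]
    assert(all(o$start_year[-1] > o$end_year[-nrow(o)]),
           "overlapping stamped events: upstream segments must not overlap")
  }
  for (i in seq_len(nrow(segments))) {
    code <- segments$map_code[i]
    if (code == 0L) next
    s <- segments$start_year[i]; e <- segments$end_year[i]
    if (code %in% rapid_codes()) {
      yr <- if (code == 1L && (e - s) > 2) e else s
      if (as.character(yr) %in% names(out)) out[as.character(yr)] <- code
    } else {
      yrs <- intersect(s:e, span)
      out[as.character(yrs)] <- code
    }
  }
  structure(out, class = "annual_series")
}

#' Latest-disturbance products for one pixel
#'
#' @param series annual code series from [assemble_series()]
#' @return list `latest_type` (code; 0 if never disturbed),
#'   `latest_start_year`, `latest_end_year` (`NA` when undisturbed)
#' @export
latest_products <- function(series) {
  codes <- as.integer(series)
  years <- as.integer(names(series))
  nz <- which(codes != 0L)
  if (!length(nz))
    return(list(latest_type = 0L, latest_start_year = NA_integer_,
                latest_end_year = NA_integer_))
  # events: maximal runs of consecutive years with the same nonzero code
  runs <- rle(codes)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  ev <- which(runs$values != 0L)
  last <- ev[length(ev)]
  list(latest_type = runs$values[last],
       latest_start_year = years[starts[last]],
       latest_end_year = years[ends[last]])
}

label_components <- function(mask) {
  # 8-connected component labelling on a logical matrix (BFS)
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  idx <- which(mask)
  H <- nrow(mask)
  for (start in idx) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      p <- queue[length(queue)]; queue <- queue[-length(queue)]
      r <- (p - 1L) %% H + 1L; cc <- (p - 1L) %/% H + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; c2 <- cc + dc
        if (rr >= 1 && rr <= H && c2 >= 1 && c2 <= ncol(mask)) {
          q <- (c2 - 1L) * H + rr
          if (mask[q] && lab[q] == 0L) { lab[q] <- cur; queue <- c(queue, q) }
        }
      }
    }
  }
  lab
}

#' Remove isolated disturbance patches (sieve filter)
#'
#' For each year, a binary disturbed mask is built from the union of
#' disturbed pixels within a +/-2-year moving window; 8-connected
#' components smaller than `min_pixels` are erased (set to 0) in the
#' central year. The pass is iterated to a fixed point so the operation is
#' idempotent. No pixel ever gains a disturbance.
#'
#' @param stack integer array years x H x W of map codes
#' @param min_pixels component-size threshold (default 12; strictly smaller
#'   components are removed)
#' @param window_years moving-window length (default 5, i.e. +/-2 years)
#' @return list `stack` (filtered array) and `removed` (count of erased
#'   pixel-years)
#' @export
sieve_filter <- function(stack, min_pixels = 12, window_years = 5) {
  assert(length(dim(stack)) == 3, "stack must be years x H x W")
  half <- window_years %/% 2
  ny <- dim(stack)[1]
  removed <- 0L
  repeat {
    changed <- FALSE
    out <- stack
    for (y in seq_len(ny)) {
      win <- max(1, y - half):min(ny, y + half)
      mask <- apply(stack[win, , , drop = FALSE] > 0, c(2, 3), any)
      if (!any(mask)) next
      lab <- label_components(mask)
      sizes <- tabulate(lab)
      small <- which(sizes < min_pixels)
      if (!length(small)) next
      kill <- matrix(lab %in% small, nrow(mask)) & stack[y, , ] > 0
      if (any(kill)) {
        yr <- out[y, , ]
        removed <- removed + sum(kill)
        yr[kill] <- 0L
        out[y, , ] <- yr
        changed <- TRUE
      }
    }
    stack <- out
    if (!changed) break
  }
  list(stack = stack, removed = removed)
}

#' Remove harvest/pest codes inside wetlands
#'
#' Codes 2 (harvesting), 5-8 (pest classes) are set to 0 where the wetland
#' mask is TRUE; wildfire, windthrow and water extension are untouched.
#'
#' @param stack integer array years x H x W of map codes
#' @param wetland_mask logical matrix H x W
#' @return filtered stack
#' @export
wetland_filter <- function(stack, wetland_mask) {
  assert(length(dim(stack)) == 3, "stack must be years x H x W")
  assert(all(dim(stack)[2:3] == dim(wetland_mask)),
         "wetland mask shape does not match the stack")
  target <- c(2L, 5L, 6L, 7L, 8L)
  for (y in seq_len(dim(stack)[1])) {
    yr <- stack[y, , ]
    yr[wetland_mask & yr %in% target] <- 0L
    stack[y, , ] <- yr
  }
  stack
}
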