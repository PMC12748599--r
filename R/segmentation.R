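# Piecewise-linear temporal segmentation of annual NBR series, in the
# LandTrendr family: despike, then greedy insertion of continuous
# piecewise-linear knots, each accepted by an F-test on the SSE reduction.
# Declining runs of fitted vertices become candidate disturbance segments.

#' Segmentation parameters
#'
#' @param max_segments maximum number of fitted linear segments (vertex
#'   budget; default 6).
#' @param min_start_drop cumulative fitted NBR decrease a declining run must
#'   exceed to count as a disturbance, and the exceedance level that defines
#'   its starting year (default 0.1).
#' @param max_returned at most this many most-recent disturbance segments
#'   are returned per pixel (default 5).
#' @param noise_dampening attenuate single-year down-up spikes (undetected
#'   clouds/shadows) before fitting.
#' @param p_enter significance level of the F-test that admits one more
#'   knot (default 0.05).
#' @return a `seg_params` list
#' @export
seg_params <- function(max_segments = 6, min_start_drop = 0.1, max_returned = 5,
                       noise_dampening = TRUE, p_enter = 0.05) {
  assert(min_start_drop > 0, "min_start_drop must be > 0")
  assert(max_returned >= 1, "max_returned must be >= 1")
  assert(max_segments >= 1, "max_segments must be >= 1")
  structure(list(max_segments = as.integer(max_segments),
                 min_start_drop = min_start_drop,
                 max_returned = as.integer(max_returned),
                 noise_dampening = isTRUE(noise_dampening),
                 p_enter = p_enter),
            class = "seg_params")
}

# Single-year spikes that return close to the pre-spike level are cloud
# artifacts; real one-year disturbances stay low afterwards and are left
# untouched (their |y[i+1]-y[i-1]| is comparable to the drop itself).
despike <- function(y) {
  n <- length(y)
  if (n < 3) return(y)
  out <- y
  for (i in 2:(n - 1)) {
    d1 <- y[i] - y[i - 1]; d2 <- y[i] - y[i + 1]
    big <- max(abs(d1), abs(d2))
    if (sign(d1) == sign(d2) && big > 0 &&
        abs(y[i + 1] - y[i - 1]) < 0.25 * big)
      out[i] <- (y[i - 1] + y[i + 1]) / 2
  }
  out
}

hinge_basis <- function(t, knots) {
  X <- cbind(1, t)
  for (k in knots) X <- cbind(X, pmax(t - k, 0))
  X
}

pw_sse <- function(y, t, knots) {
  f <- .lm.fit(hinge_basis(t, knots), y)
  sum(f$residuals^2)
}

#' Fit a piecewise-linear model to an annual NBR series
#'
#' Greedy knot insertion: starting from a single line, repeatedly add the
#' interior year whose continuous hinge term most reduces the residual sum
#' of squares, accepting it while an F-test on the reduction is significant
#' and the segment budget allows. Missing years are linearly interpolated
#' for fitting and flagged.
#'
#' @param nbr numeric NBR series (may contain `NA` for missing years)
#' @param years calendar years (default consecutive from 1)
#' @param params [seg_params()]
#' @return data.frame of fitted vertices (`year`, `fitted`), with
#'   attributes `fitted` (full fitted series), `knots`, and `interpolated`
#'   (logical per year).
#' @export
fit_piecewise <- function(nbr, years = NULL, params = seg_params()) {
  n <- length(nbr)
  if (is.null(years)) years <- seq_len(n)
  assert(sum(!is.na(nbr)) >= 6, "at least 6 non-missing years required")
  interp <- is.na(nbr)
  if (any(interp))
    nbr <- approx(years[!interp], nbr[!interp], xout = years, rule = 2)$y
  y <- if (params$noise_dampening) despike(nbr) else nbr
  t <- as.numeric(years)

  # overfit-then-prune, as in the LandTrendr family: greedy insertion is
  # myopic on step-like breaks (one hinge alone is not significant), so
  # knots are first inserted to the segment budget, then backward-eliminated
  # while their removal is statistically insignificant.
  knots <- numeric(0)
  sse <- pw_sse(y, t, knots)
  candidates <- t[2:(n - 1)]
  while (length(knots) + 1 < params$max_segments && sse > 1e-12) {
    cand <- setdiff(candidates, knots)
    if (!length(cand)) break
    sses <- vapply(cand, function(k) pw_sse(y, t, c(knots, k)), 0)
    best <- which.min(sses)
    if (sse - sses[best] <= 1e-12) break
    knots <- sort(c(knots, cand[best]))
    sse <- sses[best]
  }
  while (length(knots)) {
    sses <- vapply(seq_along(knots), function(i) pw_sse(y, t, knots[-i]), 0)
    worst <- which.min(sses)
    increase <- sses[worst] - sse
    p <- 2 + length(knots)
    drop_knot <- if (increase < 1e-12) TRUE
      else if (sse < 1e-12) FALSE
      else {
        fstat <- increase / (sse / max(n - p, 1))
        pf(fstat, 1, max(n - p, 1), lower.tail = FALSE) >= params$p_enter
      }
    if (!drop_knot) break
    knots <- knots[-worst]
    sse <- sses[worst]
  }

  fit <- .lm.fit(hinge_basis(t, knots), y)
  fitted <- y - fit$residuals
  vy <- c(t[1], knots, t[n])
  vertices <- data.frame(year = as.integer(vy),
                         fitted = approx(t, fitted, xout = vy)$y)
  assert(all(diff(vertices$year) > 0) && all(is.finite(vertices$fitted)),
         "internal: invalid vertices")
  attr(vertices, "fitted") <- fitted
  attr(vertices, "knots") <- knots
  attr(vertices, "interpolated") <- interp
  vertices
}

#' Extract candidate disturbance segments from fitted vertices
#'
#' Maximal runs of consecutive declining fitted segments whose cumulative
#' drop exceeds `min_start_drop` are reported, most recent first, truncated
#' to `max_returned`. The starting year is the first year at which the
#' cumulative fitted decrease within the run exceeds `min_start_drop`; the
#' ending year is the run's last year. `start_nbr`/`end_nbr` and
#' `magnitude = start_nbr - end_nbr` describe the full run.
#'
#' @param vertices result of [fit_piecewise()]
#' @param params [seg_params()]
#' @return data.frame with columns start_year, end_year, start_nbr,
#'   end_nbr, magnitude (zero rows when no disturbance is found)
#' @export
extract_disturbance_segments <- function(vertices, params = seg_params()) {
  nv <- nrow(vertices)
  empty <- data.frame(start_year = integer(0), end_year = integer(0),
                      start_nbr = numeric(0), end_nbr = numeric(0),
                      magnitude = numeric(0))
  if (nv < 2) return(empty)
  decl <- diff(vertices$fitted) < -1e-12
  runs <- rle(decl)
  out <- empty
  pos <- 1L
  for (r in seq_along(runs$lengths)) {
    len <- runs$lengths[r]
    if (runs$values[r]) {
      i0 <- pos; i1 <- pos + len          # vertex indices of the run
      start_nbr <- vertices$fitted[i0]; end_nbr <- vertices$fitted[i1]
      drop <- start_nbr - end_nbr
      if (drop > params$min_start_drop) {
        yrs <- vertices$year[i0]:vertices$year[i1]
        fit_y <- approx(vertices$year[i0:i1], vertices$fitted[i0:i1],
                        xout = yrs)$y
        exceed <- which(start_nbr - fit_y > params$min_start_drop)
        out <- rbind(out, data.frame(
          start_year = yrs[exceed[1]], end_year = vertices$year[i1],
          start_nbr = start_nbr, end_nbr = end_nbr, magnitude = drop))
      }
    }
    pos <- pos + len
  }
  if (!nrow(out)) return(empty)
  assert(!anyDuplicated(out$end_year), "internal: tied segment end years")
  out <- out[order(out$end_year, decreasing = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  head(out, params$max_returned)
}

#' Is a disturbance segment short enough to classify?
#'
#' Only disturbance sequences lasting less than 10 years are passed to the
#' classification step.
#'
#' @param segment one-row data.frame (or list) with start_year, end_year
#' @return logical
#' @export
is_classifiable <- function(segment) {
  (segment$end_year - segment$start_year) < 10
}

#' Segment one pixel's NBR series
#'
#' Convenience wrapper: [fit_piecewise()] then
#' [extract_disturbance_segments()].
#'
#' @param nbr NBR series (NA = missing year)
#' @param years calendar years
#' @param params [seg_params()]
#' @return data.frame of disturbance segments
#' @export
segment_pixel <- function(nbr, years = NULL, params = seg_params()) {
  extract_disturbance_segments(fit_piecewise(nbr, years, params), params)
}
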