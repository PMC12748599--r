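# Class-conditional simulator for six-band annual reflectance trajectories.
# The generator states the package's synthetic world: healthy-conifer
# baseline, linear NBR decline over the event duration, exponential
# recovery toward baseline, band-level changes realized chiefly through
# NIR decrease and SWIR increase (constant NIR+SWIR2 sum, so a stated NBR
# drop is reproduced exactly at zero noise).

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Baseline band means for the stationary land-cover classes
#'
#' Fixed package defaults chosen for class separability (healthy conifer
#' NBR ~ 0.67, water NBR ~ 0.2, rocks ~ -0.05); overridable wherever a
#' baseline argument is exposed.
#'
#' @return matrix (class x 6 bands)
#' @export
band_baselines <- function() {
  m <- rbind(
    forest   = c(0.020, 0.045, 0.030, 0.250, 0.130, 0.050),
    noforest = c(0.040, 0.070, 0.070, 0.280, 0.220, 0.120),
    rocks    = c(0.100, 0.120, 0.140, 0.200, 0.250, 0.220),
    crops    = c(0.035, 0.070, 0.055, 0.330, 0.210, 0.110),
    urban    = c(0.100, 0.120, 0.130, 0.180, 0.200, 0.180),
    water    = c(0.040, 0.050, 0.040, 0.030, 0.020, 0.020)
  )
  colnames(m) <- band_names()
  m
}

undisturbed_classes <- function() rownames(band_baselines())

#' Specification of one disturbance event
#'
#' @param class_label one of the disturbance classes in [class_scheme()]
#'   (`defol_low/medium/high`, `fire`, `harvest_total`, `harvest_partial`,
#'   `windthrow`, or the composite labels).
#' @param onset_year first calendar year of spectral decline.
#' @param duration_years years over which the NBR drop is spread (1 for
#'   rapid stand-replacing classes; pests 1-15).
#' @param magnitude total NBR drop (index units, > 0).
#' @param recovery_rate fraction of the remaining gap to baseline regained
#'   per post-event year (exponential recovery).
#' @return an `event_spec` list
#' @export
event_spec <- function(class_label, onset_year, duration_years, magnitude,
                       recovery_rate = 0.08) {
  rapid <- c("fire", "harvest_total", "harvest_partial", "windthrow", "dams")
  assert(is.character(class_label) && length(class_label) == 1, "one class label")
  duration_years <- as.integer(duration_years)
  assert(duration_years >= 1, "duration_years must be >= 1")
  if (class_label %in% rapid)
    assert(duration_years == 1L,
           "rapid stand-replacing classes have duration 1: ", class_label)
  if (grepl("^defol", class_label))
    assert(duration_years <= 15L, "pest durations span at most 15 years")
  assert(is.finite(magnitude) && magnitude > 0, "magnitude must be > 0")
  assert(recovery_rate >= 0 && recovery_rate < 1, "recovery_rate in [0,1)")
  structure(list(class_label = class_label, onset_year = as.integer(onset_year),
                 duration_years = duration_years, magnitude = magnitude,
                 recovery_rate = recovery_rate),
            class = "event_spec")
}

# Per-class archetype ranges: duration support, per-year NBR rate or total
# magnitude, recovery-rate range. Severity-class rates sit inside the dNBR
# bins (0.1/0.15/0.25) with small guard gaps; cumulative drop capped at
# 0.85 so NBR stays within physical range from a 0.67 baseline.
class_archetypes <- function() {
  list(
    defol_low     = list(dur = 3:6, rate = c(0.105, 0.145), rec = c(0.05, 0.15)),
    defol_medium  = list(dur = 3:6, rate = c(0.155, 0.245), rec = c(0.05, 0.15)),
    defol_high    = list(dur = 1:4, rate = c(0.255, 0.400), rec = c(0.05, 0.15)),
    fire          = list(dur = 1L, mag = c(0.35, 0.60), rec = c(0.03, 0.08)),
    harvest_total = list(dur = 1L, mag = c(0.30, 0.50), rec = c(0.05, 0.10)),
    harvest_partial = list(dur = 1L, mag = c(0.12, 0.25), rec = c(0.08, 0.15)),
    windthrow     = list(dur = 1L, mag = c(0.20, 0.40), rec = c(0.04, 0.10))
  )
}

#' Draw a random event from a class archetype
#'
#' Magnitudes and durations are drawn uniformly from class-specific ranges;
#' defoliation severities draw a per-year dNBR rate inside the class's
#' severity bin, with duration truncated so the cumulative drop stays below
#' 0.85.
#'
#' @param class_label archetype name (see [class_archetypes()])
#' @param onset_year calendar year of onset
#' @return event_spec
#' @export
draw_event <- function(class_label, onset_year) {
  a <- class_archetypes()[[class_label]]
  if (is.null(a)) stop_bd("no archetype for class: ", class_label)
  rec <- runif(1, a$rec[1], a$rec[2])
  if (!is.null(a$rate)) {
    rate <- runif(1, a$rate[1], a$rate[2])
    dur <- if (length(a$dur) > 1) sample(a$dur, 1) else a$dur
    dur <- min(dur, max(1L, floor(0.85 / rate)))
    event_spec(class_label, onset_year, dur, rate * dur, rec)
  } else {
    event_spec(class_label, onset_year, a$dur, runif(1, a$mag[1], a$mag[2]), rec)
  }
}

# NBR path for a sorted list of events on one pixel: linear decline of
# `magnitude` over `duration_years`, then exponential recovery toward the
# pre-disturbance baseline until the next event (or end of span).
nbr_path <- function(events, years, nbr0) {
  n <- length(years)
  nbr <- rep(nbr0, n)
  if (length(events) == 0) return(nbr)
  ord <- order(vapply(events, function(e) e$onset_year, 1L))
  events <- events[ord]
  for (e in events) {
    i0 <- match(e$onset_year, years)
    assert(!is.na(i0), "event onset outside simulated span")
    assert(i0 > 1, "disturbance onset cannot be the first simulated year ",
           "(training windows require a healthy first year)")
    start_val <- nbr[i0 - 1]
    d <- e$duration_years
    for (k in seq_len(d)) {
      i <- i0 + k - 1
      if (i > n) break
      nbr[i] <- start_val - e$magnitude * k / d
    }
    last <- min(i0 + d - 1, n)
    if (last < n) {
      gap <- nbr0 - nbr[last]
      for (i in (last + 1):n) {
        gap <- gap * (1 - e$recovery_rate)
        nbr[i] <- nbr0 - gap
      }
    }
  }
  nbr
}

# Visible/SWIR1 signature of each disturbance family, per unit progress
# p = (NBR drop)/0.5: charring darkens the visible bands after fire, soil
# exposure brightens them strongly after harvest, windthrow and
# defoliation sit in between (grey dead wood / brown needles).
disturbance_profiles <- function() {
  rbind(
    fire       = c(blue = -0.005, green = -0.010, red = -0.005, swir1 = 0.050),
    harvest    = c(blue =  0.030, green =  0.045, red =  0.060, swir1 = 0.110),
    windthrow  = c(blue =  0.010, green =  0.015, red =  0.015, swir1 = 0.075),
    defoliation = c(blue = 0.002, green =  0.005, red =  0.045, swir1 = 0.030)
  )
}

profile_of <- function(class_label) {
  if (grepl("fire$|^fire", class_label)) "fire"
  else if (grepl("harv", class_label)) "harvest"
  else if (class_label == "windthrow") "windthrow"
  else "defoliation"
}

# Map an NBR path to six bands. NIR and SWIR2 keep a constant sum s0 so
# NBR is realized exactly; visible/SWIR1 move along the class-specific
# profile with disturbance progress p(t) = (nbr0 - nbr(t)) / 0.5.
bands_from_nbr <- function(nbr, baseline, profile = "defoliation") {
  s0 <- baseline["nir"] + baseline["swir2"]
  p <- pmax(0, (compute_nbr(baseline["nir"], baseline["swir2"]) - nbr) / 0.5)
  if (length(profile) == 1) profile <- rep(profile, length(nbr))
  delta <- disturbance_profiles()[profile, , drop = FALSE]
  m <- matrix(rep(baseline, each = length(nbr)), ncol = 6,
              dimnames = list(NULL, band_names()))
  for (b in colnames(delta)) m[, b] <- baseline[b] + p * delta[, b]
  m[, "nir"] <- s0 * (1 + nbr) / 2
  m[, "swir2"] <- s0 * (1 - nbr) / 2
  m
}

#' Simulate one pixel's annual six-band trajectory
#'
#' Healthy-conifer baseline before onset, linear NBR decline of
#' `magnitude` over the event duration, exponential recovery afterwards.
#' Undisturbed classes emit stationary class-specific baselines plus noise.
#'
#' @param event an [event_spec()], a list of them (sequential events), or
#'   `NULL` for an undisturbed pixel.
#' @param years simulated calendar span (default 1985:2024).
#' @param noise_sd per-band i.i.d. Gaussian interannual reflectance noise.
#' @param seed optional integer; the draw is deterministic under a seed.
#' @param baseline either an undisturbed class name (see
#'   [band_baselines()]) or a named 6-vector of band means.
#' @return list with `spectra` (annual_spectra) and `labels` (per-year
#'   character: the event class during its active years, the baseline class
#'   otherwise).
#' @export
simulate_trajectory <- function(event = NULL, years = 1985:2024, noise_sd = 0,
                                seed = NULL, baseline = "forest") {
  with_seed(seed, {
    if (is.character(baseline)) {
      base_class <- baseline
      baseline <- band_baselines()[baseline, ]
    } else {
      base_class <- "forest"
      baseline <- stats::setNames(as.numeric(baseline), band_names())
    }
    events <- if (is.null(event)) list()
      else if (inherits(event, "event_spec")) list(event) else event
    nbr0 <- compute_nbr(baseline["nir"], baseline["swir2"])
    nbr <- nbr_path(events, years, nbr0)
    # per-year signature: the profile of the most recent event at that year
    profile <- rep("defoliation", length(years))
    for (e in events[order(vapply(events, function(e) e$onset_year, 1L))])
      profile[years >= e$onset_year] <- profile_of(e$class_label)
    refl <- bands_from_nbr(nbr, baseline, profile)
    if (noise_sd > 0)
      refl <- refl + matrix(rnorm(length(refl), 0, noise_sd), nrow = nrow(refl))
    refl <- pmin(pmax(refl, 1e-4), 1)
    labels <- rep(base_class, length(years))
    for (e in events) {
      act <- years >= e$onset_year & years <= e$onset_year + e$duration_years - 1
      labels[act] <- e$class_label
    }
    list(spectra = annual_spectra(years, refl), labels = labels)
  })
}

#' Concatenate two trajectories end to end
#'
#' Years of the second series are relabelled to continue the first's span
#' consecutively. Used to build composite rare-class signatures (healthy
#' forest followed by a target land cover; pest outbreak followed by fire
#' or harvesting).
#'
#' @param first,second `annual_spectra` objects, or lists with `$spectra`
#'   and `$labels` as returned by [simulate_trajectory()]. `second = NULL`
#'   is the identity.
#' @return same shape as the inputs (annual_spectra, or spectra+labels list)
#' @export
concatenate_trajectories <- function(first, second = NULL) {
  if (is.null(second)) return(first)
  as_pair <- function(x)
    if (inherits(x, "annual_spectra")) list(spectra = x, labels = NULL) else x
  a <- as_pair(first); b <- as_pair(second)
  assert(inherits(a$spectra, "annual_spectra") && inherits(b$spectra, "annual_spectra"),
         "inputs must be annual_spectra (or simulate_trajectory results)")
  ra <- a$spectra$reflectance; rb <- b$spectra$reflectance
  if (ncol(ra) != ncol(rb)) stop_bd("band count mismatch")
  years <- seq(a$spectra$years[1], length.out = nrow(ra) + nrow(rb))
  sp <- annual_spectra(years, rbind(ra, rb), c(a$spectra$missing, b$spectra$missing))
  if (inherits(first, "annual_spectra") && inherits(second, "annual_spectra")) return(sp)
  list(spectra = sp, labels = c(a$labels, b$labels))
}

#' Rectangular patch footprint helper
#' @param row0,col0 top-left pixel (1-based)
#' @param nrow,ncol patch extent in pixels
#' @return two-column integer matrix of (row, col) pixels
#' @export
rect_patch <- function(row0, col0, nrow = 1, ncol = 1) {
  as.matrix(expand.grid(row = row0:(row0 + nrow - 1),
                        col = col0:(col0 + ncol - 1)))
}

patch_connected <- function(pixels) {
  n <- nrow(pixels)
  if (n <= 1) return(TRUE)
  key <- paste(pixels[, 1], pixels[, 2])
  seen <- logical(n); seen[1] <- TRUE; queue <- 1L
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    nb <- expand.grid(dr = -1:1, dc = -1:1)
    for (k in seq_len(nrow(nb))) {
      j <- match(paste(pixels[i, 1] + nb$dr[k], pixels[i, 2] + nb$dc[k]), key)
      if (!is.na(j) && !seen[j]) { seen[j] <- TRUE; queue <- c(queue, j) }
    }
  }
  all(seen)
}

#' Specification of a synthetic raster scene
#'
#' @param width,height scene size in pixels
#' @param years simulated span (default 1985:2024)
#' @param patches list of `list(event = event_spec or list of them,
#'   pixels = two-column (row, col) matrix)`; footprints must be connected
#'   and inside the grid.
#' @param cloud_rate probability a pixel-year is missing, in \[0, 1)
#' @param noise_sd per-band reflectance noise
#' @param seed integer seed for reproducibility
#' @return a `scene_spec` list
#' @export
scene_spec <- function(width, height, years = 1985:2024, patches = list(),
                       cloud_rate = 0, noise_sd = 0.01, seed = 1L) {
  assert(width >= 1 && height >= 1, "scene must have positive size")
  assert(cloud_rate >= 0 && cloud_rate < 1, "cloud_rate in [0,1)")
  for (p in patches) {
    px <- p$pixels
    assert(is.matrix(px) && ncol(px) == 2, "patch pixels must be a 2-column matrix")
    assert(all(px[, 1] >= 1 & px[, 1] <= height & px[, 2] >= 1 & px[, 2] <= width),
           "patch footprint outside the scene grid")
    assert(patch_connected(px), "patch footprint must be a connected pixel set")
  }
  structure(list(width = as.integer(width), height = as.integer(height),
                 years = as.integer(years), patches = patches,
                 cloud_rate = cloud_rate, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

event_years <- function(e) e$onset_year:(e$onset_year + e$duration_years - 1)

#' Simulate a labelled raster scene
#'
#' Every pixel gets a trajectory from [simulate_trajectory()]; patch pixels
#' share their patch's event(s); cloud gaps are i.i.d. missing pixel-years.
#' Labels are final map codes (0-8) stamped over each event's active years.
#'
#' @param spec a [scene_spec()]
#' @return list with `spectra` (array years x 6 x height x width, `NA` at
#'   cloud gaps), `labels` (integer array years x height x width), `years`,
#'   and the spec.
#' @export
simulate_scene <- function(spec) {
  assert(inherits(spec, "scene_spec"), "spec must be a scene_spec")
  with_seed(spec$seed, {
    ny <- length(spec$years); H <- spec$height; W <- spec$width
    events_at <- vector("list", H * W)
    for (pi in seq_along(spec$patches)) {
      p <- spec$patches[[pi]]
      evs <- if (inherits(p$event, "event_spec")) list(p$event) else p$event
      for (k in seq_len(nrow(p$pixels))) {
        id <- (p$pixels[k, 2] - 1) * H + p$pixels[k, 1]
        prev <- events_at[[id]]
        for (e in evs) for (o in prev)
          if (length(intersect(event_years(e), event_years(o))))
            stop_bd("overlapping patches assign conflicting same-year events")
        events_at[[id]] <- c(prev, evs)
      }
    }
    spectra <- array(NA_real_, c(ny, 6, H, W),
                     dimnames = list(spec$years, band_names(), NULL, NULL))
    labels <- array(0L, c(ny, H, W), dimnames = list(spec$years, NULL, NULL))
    for (col in seq_len(W)) for (row in seq_len(H)) {
      id <- (col - 1) * H + row
      tr <- simulate_trajectory(events_at[[id]], spec$years,
                                noise_sd = spec$noise_sd)
      refl <- tr$spectra$reflectance
      if (spec$cloud_rate > 0) {
        gap <- runif(ny) < spec$cloud_rate
        refl[gap, ] <- NA_real_
      }
      spectra[, , row, col] <- refl
      for (e in events_at[[id]]) {
        yrs <- intersect(event_years(e), spec$years)
        labels[match(yrs, spec$years), row, col] <- remap_to_final(e$class_label)
      }
    }
    list(spectra = spectra, labels = labels, years = spec$years, spec = spec)
  })
}
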