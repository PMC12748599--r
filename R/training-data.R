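# Construction of labelled 10-year training subsequences: aerial-survey
# candidate filtering, dNBR severity labelling, random event placement
# inside the window (never the first year), composite rare-class
# generation, and tile-based spatial cross-validation splits.

#' Filter aerial-survey pest candidate points
#'
#' A candidate is kept iff all of: survey severity is medium or severe;
#' source polygon at most 10,000 ha; no overlap with urban, cropland,
#' harvested or burned cover; at least 50% tree cover; coniferous or mixed
#' land cover; and an observed dNBR decrease of at least 0.1 at the event.
#' Rejection reasons are enumerated codes so the filter is auditable.
#'
#' @param points data.frame with columns `severity`
#'   ("light"/"medium"/"severe"), `polygon_area_ha`, `overlaps_excluded_cover`
#'   (logical), `tree_cover_pct`, `landcover`, `dnbr_at_event`
#' @return list with `kept` (data.frame) and `rejected` (data.frame with a
#'   `reason` column; semicolon-joined codes when several predicates fail)
#' @export
filter_pest_candidates <- function(points) {
  req <- c("severity", "polygon_area_ha", "overlaps_excluded_cover",
           "tree_cover_pct", "landcover", "dnbr_at_event")
  miss <- setdiff(req, names(points))
  if (length(miss)) stop_bd("missing candidate field(s): ", paste(miss, collapse = ", "))
  for (f in req) if (anyNA(points[[f]])) stop_bd("missing values in field: ", f)
  assert(all(points$tree_cover_pct >= 0 & points$tree_cover_pct <= 100),
         "tree_cover_pct must be in [0,100]")
  assert(all(points$polygon_area_ha >= 0), "polygon_area_ha must be >= 0")

  checks <- list(
    severity_not_medium_or_severe = points$severity %in% c("medium", "severe"),
    polygon_too_large             = points$polygon_area_ha <= 10000,
    overlaps_excluded_cover       = !points$overlaps_excluded_cover,
    tree_cover_below_50           = points$tree_cover_pct >= 50,
    not_coniferous_or_mixed       = points$landcover %in% c("coniferous", "mixed"),
    dnbr_below_0.1                = points$dnbr_at_event >= 0.1
  )
  pass <- Reduce(`&`, checks)
  reasons <- vapply(seq_len(nrow(points)), function(i) {
    fails <- names(checks)[!vapply(checks, `[`, TRUE, i)]
    paste(fails, collapse = ";")
  }, "")
  rejected <- points[!pass, , drop = FALSE]
  if (nrow(rejected)) rejected$reason <- reasons[!pass]
  else rejected$reason <- character(0)
  list(kept = points[pass, , drop = FALSE], rejected = rejected)
}

#' Severity training label for a filtered pest candidate
#'
#' @param dnbr_at_event decline-positive dNBR at the survey event year
#' @return training class label: defol_low / defol_medium / defol_high
#' @export
label_pest_severity <- function(dnbr_at_event) {
  sev <- classify_severity(dnbr_at_event)
  if (any(sev == "none"))
    stop_bd("dNBR decrease below 0.1: candidate should have been excluded")
  c(low = "defol_low", medium = "defol_medium",
    high = "defol_high")[as.character(sev)]
}

#' Build one 10-year training window from a trajectory
#'
#' For disturbance classes the event start is placed at a uniformly random
#' offset 1..9 within the window (never the first year, so the model always
#' sees a healthy first year); undisturbed classes get a uniformly random
#' 10-year slice.
#'
#' @param trajectory result of [simulate_trajectory()] (spectra + labels),
#'   or an annual_spectra for undisturbed slices
#' @param label training-class label for the example
#' @param onset_year event onset year (`NULL` for undisturbed classes)
#' @param seed optional integer for a deterministic draw
#' @return list of class `training_example`: `window` (10 x 6 matrix),
#'   `label`, `event_offset` (1-9 pre-event years, `NA` if undisturbed),
#'   `years`
#' @export
build_training_window <- function(trajectory, label, onset_year = NULL,
                                  seed = NULL) {
  sp <- if (inherits(trajectory, "annual_spectra")) trajectory else trajectory$spectra
  n <- length(sp$years)
  assert(n >= 10, "trajectory too short for a 10-year window")
  with_seed(seed, {
    if (is.null(onset_year)) {
      start <- sp$years[1] + sample.int(n - 9, 1) - 1
      offset <- NA_integer_
    } else {
      i_on <- match(onset_year, sp$years)
      assert(!is.na(i_on), "onset_year outside the trajectory span")
      lo <- max(1L, i_on - 9L)               # offset <= 9 (event never past window end)
      hi <- min(i_on - 1L, n - 9L)           # offset >= 1 and window inside series
      assert(hi >= lo, "trajectory too short to place the event at offset 1..9")
      start_i <- lo + sample.int(hi - lo + 1L, 1) - 1L
      offset <- i_on - start_i
      start <- sp$years[start_i]
    }
    win <- slice_years(sp, start, start + 9)
    structure(list(window = win$reflectance, label = label,
                   event_offset = offset, years = win$years),
              class = "training_example")
  })
}

composite_pairs <- function() {
  list(crops_change = c("forest", "crops"),
       urban_change = c("forest", "urban"),
       dams         = c("forest", "water"),
       pest_fire    = c("pest", "fire"),
       pest_harv    = c("pest", "harvest"))
}

# Composite trajectory for one rare-class example. Land-cover conversions
# concatenate 10 years of healthy forest with 10 years of the target cover;
# pest composites concatenate the outbreak's declining portion with a rapid
# drop simulated from the degraded end state.
composite_trajectory <- function(class_label) {
  pair <- composite_pairs()[[class_label]]
  if (is.null(pair)) stop_bd("unsupported composite class: ", class_label)
  if (pair[1] == "forest") {
    first <- simulate_trajectory(NULL, years = 1:10, baseline = "forest")
    second <- simulate_trajectory(NULL, years = 11:20, baseline = pair[2])
    tr <- concatenate_trajectories(first, second)
    tr$labels[11] <- class_label       # the conversion year carries the class
    list(trajectory = tr, onset_year = tr$spectra$years[11])
  } else {
    sev <- sample(c("defol_medium", "defol_high"), 1)
    pest <- draw_event(sev, onset_year = 4L)
    span1 <- 1:(3 + pest$duration_years)
    first <- simulate_trajectory(pest, years = span1)
    last_bands <- first$spectra$reflectance[length(span1), ]
    drop2 <- runif(1, 0.10, 0.20)
    ev2 <- event_spec(if (pair[2] == "fire") "fire" else "harvest_total",
                      onset_year = 2L, duration_years = 1L, magnitude = drop2,
                      recovery_rate = runif(1, 0.03, 0.08))
    second <- simulate_trajectory(ev2, years = 1:9, baseline = last_bands)
    tr <- concatenate_trajectories(first, second)
    tr$labels[tr$labels %in% c(sev, "fire", "harvest_total")] <- class_label
    list(trajectory = tr, onset_year = pest$onset_year)
  }
}

#' Generate composite rare-class training examples
#'
#' Supported classes: crops_change, urban_change, dams (healthy forest
#' followed by the target land cover), pest_fire and pest_harv (outbreak
#' followed by fire / salvage harvesting). Trajectories are built with
#' [concatenate_trajectories()] and sliced with [build_training_window()].
#'
#' @param class_label one of the five composite classes
#' @param n number of examples
#' @param noise_sd per-band reflectance noise added to each window
#' @param seed integer seed
#' @return list of `training_example`s
#' @export
make_composite_examples <- function(class_label, n, noise_sd = 0.01, seed = NULL) {
  assert(class_label %in% names(composite_pairs()),
         "unsupported composite class: ", class_label)
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      ct <- composite_trajectory(class_label)
      ex <- build_training_window(ct$trajectory, class_label, ct$onset_year)
      if (noise_sd > 0) {
        ex$window <- ex$window +
          matrix(rnorm(length(ex$window), 0, noise_sd), nrow = 10)
        ex$window <- pmin(pmax(ex$window, 1e-4), 1)
      }
      ex
    })
  })
}

#' Simulate a full labelled training set
#'
#' Draws `n_per_class` examples for every class in [class_scheme()]:
#' archetype events for the disturbance classes, baseline slices for the
#' undisturbed classes, concatenated signatures for the composites. Each
#' example is assigned a random spatial tile id for cross-validation.
#'
#' @param n_per_class examples per training class
#' @param noise_sd per-band reflectance noise
#' @param n_tiles number of spatial tiles examples are attributed to
#' @param seed integer seed
#' @return list with `x` (n x 10 x 6 array), `label` (character vector),
#'   `tile_id` (integer vector)
#' @export
simulate_training_set <- function(n_per_class = 200, noise_sd = 0.01,
                                  n_tiles = 66, seed = 1L) {
  with_seed(seed, {
    sch <- class_scheme()
    xs <- list(); labs <- character(0)
    for (cl in sch$class) {
      exs <- if (cl %in% names(composite_pairs())) {
        make_composite_examples(cl, n_per_class, noise_sd)
      } else if (cl %in% undisturbed_classes()) {
        lapply(seq_len(n_per_class), function(i) {
          tr <- simulate_trajectory(NULL, years = 1:14, noise_sd = noise_sd,
                                    baseline = cl)
          build_training_window(tr, cl)
        })
      } else if (grepl("^defol", cl)) {
        # severity labels follow the survey construction: the class is
        # assigned from the observed (noisy) dNBR at the event, via the
        # 0.1/0.15/0.25 thresholds, with sub-0.1 observations excluded
        lapply(seq_len(n_per_class), function(i) {
          repeat {
            ev <- draw_event(cl, onset_year = 8L)
            span <- 1:(7 + max(10, ev$duration_years + 2))
            tr <- simulate_trajectory(ev, years = span, noise_sd = noise_sd)
            dn <- compute_dnbr_series(tr$spectra)
            obs <- max(dn[as.character(event_years(ev))], na.rm = TRUE)
            if (classify_severity(obs) != "none" &&
                label_pest_severity(obs) == cl)
              return(build_training_window(tr, cl, ev$onset_year))
          }
        })
      } else {
        lapply(seq_len(n_per_class), function(i) {
          ev <- draw_event(cl, onset_year = 8L)
          span <- 1:(7 + max(10, ev$duration_years + 2))
          tr <- simulate_trajectory(ev, years = span, noise_sd = noise_sd)
          build_training_window(tr, cl, ev$onset_year)
        })
      }
      xs <- c(xs, lapply(exs, `[[`, "window"))
      labs <- c(labs, rep(cl, length(exs)))
    }
    x <- array(0, c(length(xs), 10, 6))
    for (i in seq_along(xs)) x[i, , ] <- xs[[i]]
    list(x = x, label = labs,
         tile_id = sample.int(n_tiles, length(labs), replace = TRUE))
  })
}

#' Tile-based spatial cross-validation splits
#'
#' Training points are attributed to a regular grid of spatial tiles.
#' `n_holdout_tiles` tiles are first reserved as an overfitting check and
#' appear in no fold; each of `n_folds` iterations then draws an
#' independent random 90/10 split of the remaining tiles (by tile, never by
#' point).
#'
#' @param tile_id integer tile index per example
#' @param n_tiles total number of tiles in the grid (default 66)
#' @param n_folds number of repeated splits (default 10)
#' @param n_holdout_tiles tiles reserved for validation (default 4)
#' @param test_fraction fraction of non-holdout tiles per test set
#' @param seed integer seed
#' @return list with `holdout_tiles`, `folds` (each `list(train_tiles,
#'   test_tiles)`), and per-example index lists `holdout_idx` and
#'   `fold_idx` (each `list(train, test)`)
#' @export
spatial_cv_split <- function(tile_id, n_tiles = 66, n_folds = 10,
                             n_holdout_tiles = 4, test_fraction = 0.10,
                             seed = 1L) {
  tiles <- seq_len(n_tiles)
  assert(all(tile_id %in% tiles), "tile_id outside 1..n_tiles")
  n_test <- round(test_fraction * (n_tiles - n_holdout_tiles))
  assert(n_tiles - n_holdout_tiles > n_test && n_test >= 1,
         "fewer tiles than required splits")
  with_seed(seed, {
    holdout <- sort(sample(tiles, n_holdout_tiles))
    pool <- setdiff(tiles, holdout)
    folds <- lapply(seq_len(n_folds), function(f) {
      test <- sort(sample(pool, n_test))
      list(train_tiles = setdiff(pool, test), test_tiles = test)
    })
    list(holdout_tiles = holdout, folds = folds,
         holdout_idx = which(tile_id %in% holdout),
         fold_idx = lapply(folds, function(f)
           list(train = which(tile_id %in% f$train_tiles),
                test = which(tile_id %in% f$test_tiles))))
  })
}

#' Write a training set to CSV (id, label, offset-free flat window)
#' @param ts result of [simulate_training_set()]
#' @param path output CSV path
#' @return invisibly, the path
#' @export
write_training_csv <- function(ts, path) {
  n <- dim(ts$x)[1]
  # layout: column index = (band-1)*10 + year, i.e. R's natural flattening
  flat <- matrix(ts$x, nrow = n)
  colnames(flat) <- as.vector(outer(paste0("y", 1:10), band_names(),
                                    function(t, b) paste0(b, "_", t)))
  df <- data.frame(id = seq_len(n), label = ts$label, tile_id = ts$tile_id, flat,
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a training set written by [write_training_csv()]
#' @param path CSV path
#' @return list with `x`, `label`, `tile_id`
#' @export
read_training_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  meta <- c("id", "label", "tile_id")
  flat <- as.matrix(df[, setdiff(names(df), meta)])
  x <- array(flat, c(nrow(df), 10, 6))
  list(x = x, label = df$label, tile_id = df$tile_id)
}
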