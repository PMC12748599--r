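test_that("noiseless event trajectories realize their stated NBR drop exactly", {
  ev <- event_spec("fire", 2000, 1, 0.45, 0.05)
  tr <- simulate_trajectory(ev, 1990:2010, noise_sd = 0)
  d <- compute_dnbr_series(tr$spectra)
  expect_equal(d[["2000"]], 0.45, tolerance = 1e-9)
  # gradual pest: per-year decrement m/d, cumulative m
  ev2 <- event_spec("defol_low", 1995, 10, 0.3, 0)
  tr2 <- simulate_trajectory(ev2, 1990:2010, noise_sd = 0)
  d2 <- compute_dnbr_series(tr2$spectra)
  expect_equal(max(d2, na.rm = TRUE), 0.03, tolerance = 1e-9)
  nbr <- nbr_series(tr2$spectra)
  expect_equal(unname(nbr["1994"] - nbr["2004"]), 0.3, tolerance = 1e-9)
})

test_that("undisturbed classes are stationary at zero noise", {
  for (cl in c("forest", "water", "urban")) {
    tr <- simulate_trajectory(NULL, 1990:2005, noise_sd = 0, baseline = cl)
    expect_equal(unname(compute_dnbr_series(tr$spectra)[-1]),
                 rep(0, 15), tolerance = 1e-12)
    expect_true(all(tr$labels == cl))
  }
})

test_that("archetype draws honour duration/magnitude constraints", {
  set.seed(3)
  for (i in 1:40) {
    cl <- sample(names(borealdist:::class_archetypes()), 1)
    ev <- draw_event(cl, 2000L)
    expect_gt(ev$magnitude, 0)
    if (cl %in% c("fire", "harvest_total", "harvest_partial", "windthrow"))
      expect_equal(ev$duration_years, 1L)
    # realized cumulative drop equals the magnitude at zero noise
    tr <- simulate_trajectory(ev, 1990:2024, noise_sd = 0)
    nbr <- nbr_series(tr$spectra)
    drop <- nbr[["1999"]] - nbr[[as.character(2000 + ev$duration_years - 1)]]
    expect_equal(drop, ev$magnitude, tolerance = 1e-9)
  }
  expect_error(event_spec("fire", 2000, 3, 0.4), "duration 1")
  expect_error(event_spec("fire", 2000, 1, -0.1), "magnitude")
  # onset in the first simulated year is invalid for disturbances
  expect_error(simulate_trajectory(event_spec("fire", 1990, 1, 0.4), 1990:2005),
               "first simulated year")
})

test_that("concatenation relabels years and preserves both signals", {
  forest <- simulate_trajectory(NULL, 1:10, baseline = "forest")
  water <- simulate_trajectory(NULL, 11:20, baseline = "water")
  both <- concatenate_trajectories(forest, water)
  expect_equal(length(both$spectra$years), 20)
  expect_equal(diff(range(both$spectra$years)), 19)
  nbr <- nbr_series(both$spectra)
  expect_lt(nbr[[11]], nbr[[10]] - 0.2)      # water baseline NBR below forest
  expect_true(all(nbr[11:20] < nbr[1] - 0.2))  # drops and stays low
  # identity on empty second
  expect_identical(concatenate_trajectories(forest, NULL), forest)
  # pest then fire: gradual decline then abrupt extra drop
  pest <- simulate_trajectory(event_spec("defol_medium", 4, 5, 0.6, 0), 1:8)
  last <- pest$spectra$reflectance[8, ]
  fire <- simulate_trajectory(event_spec("fire", 2, 1, 0.15, 0.05), 1:6,
                              baseline = last)
  combo <- concatenate_trajectories(pest, fire)
  nbr2 <- nbr_series(combo$spectra)
  expect_equal(unname(diff(nbr2[3:8])), rep(-0.12, 5), tolerance = 1e-9)
  expect_equal(unname(nbr2[9] - nbr2[10]), 0.15, tolerance = 1e-9)
  # band mismatch
  bad <- forest$spectra
  bad$reflectance <- bad$reflectance[, 1:5]
  expect_error(concatenate_trajectories(forest$spectra, bad), "band count")
})

test_that("simulated scenes stamp labels exactly where events are planted", {
  spec0 <- scene_spec(8, 8, years = 1995:2010, patches = list(),
                      cloud_rate = 0, noise_sd = 0, seed = 5)
  sc0 <- simulate_scene(spec0)
  expect_true(all(sc0$labels == 0L))
  expect_equal(dim(sc0$spectra), c(16, 6, 8, 8))

  fire_patch <- rect_patch(2, 2, 4, 5)  # 20 pixels
  spec1 <- scene_spec(10, 10, years = 1995:2010,
                      patches = list(list(event = event_spec("fire", 2000, 1, 0.5),
                                          pixels = fire_patch)),
                      cloud_rate = 0, noise_sd = 0.005, seed = 5)
  sc1 <- simulate_scene(spec1)
  y2000 <- which(sc1$years == 2000)
  expect_equal(sum(sc1$labels[y2000, , ] == 1L), 20)
  expect_equal(sum(sc1$labels[-y2000, , ] != 0L), 0)
  # determinism
  sc1b <- simulate_scene(spec1)
  expect_identical(sc1$spectra, sc1b$spectra)
  expect_identical(sc1$labels, sc1b$labels)
})

test_that("scene validation rejects bad footprints and conflicting events", {
  expect_error(scene_spec(5, 5, patches = list(list(
    event = event_spec("fire", 2000, 1, 0.5),
    pixels = rect_patch(4, 4, 3, 3)))), "outside the scene")
  disconnected <- rbind(c(1, 1), c(5, 5))
  expect_error(scene_spec(5, 5, patches = list(list(
    event = event_spec("fire", 2000, 1, 0.5),
    pixels = disconnected))), "connected")
  # same pixel, overlapping years
  spec <- scene_spec(5, 5, years = 1995:2010,
                     patches = list(
                       list(event = event_spec("fire", 2000, 1, 0.5),
                            pixels = rect_patch(1, 1, 2, 2)),
                       list(event = event_spec("harvest_total", 2000, 1, 0.4),
                            pixels = rect_patch(2, 2, 2, 2))),
                     cloud_rate = 0, noise_sd = 0, seed = 1)
  expect_error(simulate_scene(spec), "conflicting")
})

test_that("cloud gaps appear at the stated rate and labels stay aligned", {
  spec <- scene_spec(12, 12, years = 1990:2019, cloud_rate = 0.2,
                     noise_sd = 0.01, seed = 11)
  sc <- simulate_scene(spec)
  gaps <- apply(is.na(sc$spectra), c(1, 3, 4), any)
  rate <- mean(gaps)
  expect_gt(rate, 0.15); expect_lt(rate, 0.25)
  expect_equal(dim(sc$labels), dim(sc$spectra)[c(1, 3, 4)])
})
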