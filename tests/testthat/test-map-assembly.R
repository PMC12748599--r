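test_that("inference windows anchor one year before the break, with fallbacks", {
  tr <- simulate_trajectory(event_spec("fire", 2005, 1, 0.5), 1984:2024)
  w <- extract_inference_window(tr$spectra, 2005)
  expect_equal(w$years, 2004:2013)
  expect_equal(w$anchor_year, 2004)
  # breaks after (last_year - 9) clamp to the final full window
  w2 <- extract_inference_window(tr$spectra, 2020)
  expect_equal(w2$years, 2015:2024)
  # missing anchor year: advance to the first observed year
  sp <- tr$spectra
  sp$missing[match(2004, sp$years)] <- TRUE
  sp$reflectance[match(2004, sp$years), ] <- NA
  w3 <- extract_inference_window(sp, 2005)
  expect_equal(w3$years, 2005:2014)
  # missing years inside the window are imputed and flagged
  sp2 <- tr$spectra
  sp2$missing[match(2007, sp2$years)] <- TRUE
  sp2$reflectance[match(2007, sp2$years), ] <- NA
  w4 <- extract_inference_window(sp2, 2005)
  expect_true(w4$imputed[match(2007, w4$years)])
  expect_true(all(is.finite(w4$window)))
  short <- simulate_trajectory(NULL, 2000:2008)
  expect_error(extract_inference_window(short$spectra, 2005), "shorter than 10")
})

test_that("series assembly stamps rapid codes once and pest codes per year", {
  span <- 1995:2020
  segs <- data.frame(start_year = 2000, end_year = 2001, map_code = 1L)
  s <- assemble_series(segs, span)
  expect_equal(unname(s[as.character(2000)]), 1L)
  expect_equal(sum(s != 0), 1)
  # wildfire stretched beyond 2 years stamps the end year
  segs2 <- data.frame(start_year = 2000, end_year = 2004, map_code = 1L)
  s2 <- assemble_series(segs2, span)
  expect_equal(unname(s2[as.character(2004)]), 1L)
  expect_equal(sum(s2 != 0), 1)
  # harvesting keeps its start year even when long
  segs2b <- data.frame(start_year = 2000, end_year = 2004, map_code = 2L)
  expect_equal(unname(assemble_series(segs2b, span)[as.character(2000)]), 2L)
  # pest codes cover the whole span
  segs3 <- data.frame(start_year = 2010, end_year = 2015, map_code = 7L)
  s3 <- assemble_series(segs3, span)
  expect_equal(unname(s3[as.character(2010:2015)]), rep(7L, 6))
  expect_equal(sum(s3 != 0), 6)
  # rapid codes: exactly one stamped year per segment
  segs4 <- data.frame(start_year = c(1998, 2006, 2012),
                      end_year = c(1998, 2007, 2012),
                      map_code = c(2L, 3L, 4L))
  s4 <- assemble_series(segs4, span)
  expect_equal(sum(s4 != 0), 3)
  # overlapping segments are an upstream bug
  bad <- data.frame(start_year = c(2000, 2002), end_year = c(2003, 2005),
                    map_code = c(7L, 6L))
  expect_error(assemble_series(bad, span), "overlap")
})

test_that("latest products report the most recent event's code and years", {
  span <- 1985:2024
  segs <- data.frame(start_year = c(1990, 2010), end_year = c(1990, 2014),
                     map_code = c(1L, 7L))
  s <- assemble_series(segs, span)
  lp <- latest_products(s)
  expect_equal(lp$latest_type, 7L)
  expect_equal(lp$latest_start_year, 2010)
  expect_equal(lp$latest_end_year, 2014)
  # start/end always lie inside the segment span
  expect_gte(lp$latest_start_year, 2010); expect_lte(lp$latest_end_year, 2014)
  lp0 <- latest_products(assemble_series(segs[0, ], span))
  expect_equal(lp0$latest_type, 0L)
  expect_true(is.na(lp0$latest_start_year))
  s3 <- assemble_series(data.frame(start_year = 2003, end_year = 2003,
                                   map_code = 3L), span)
  expect_equal(latest_products(s3),
               list(latest_type = 3L, latest_start_year = 2003,
                    latest_end_year = 2003))
})

test_that("sieve filter removes sub-threshold components and is idempotent", {
  stack <- array(0L, c(5, 20, 20))
  # 11-pixel isolated component in year 3
  stack[3, 2:12, 2] <- 1L
  res <- sieve_filter(stack)
  expect_equal(sum(res$stack), 0)
  expect_equal(res$removed, 11)
  # 12 pixels retained
  stack12 <- array(0L, c(5, 20, 20))
  stack12[3, 2:13, 2] <- 1L
  res12 <- sieve_filter(stack12)
  expect_equal(sum(res12$stack > 0), 12)
  # the 5-year window unions small same-place patches across years
  stack5 <- array(0L, c(5, 20, 20))
  stack5[2, 5:10, 5] <- 2L   # 6 pixels year 2
  stack5[4, 5:10, 6] <- 2L   # 6 adjacent pixels year 4 -> union 12
  res5 <- sieve_filter(stack5)
  expect_equal(sum(res5$stack > 0), 12)
  # idempotence and monotonicity on a mixed random stack
  set.seed(2)
  rnd <- array(sample(c(0L, 0L, 0L, 1L, 7L), 6 * 25 * 25, TRUE), c(6, 25, 25))
  r1 <- sieve_filter(rnd)
  r2 <- sieve_filter(r1$stack)
  expect_identical(r2$stack, r1$stack)
  expect_equal(r2$removed, 0L)
  expect_true(all(r1$stack[rnd == 0] == 0))  # never adds disturbance
  # all-zero stack unchanged
  z <- array(0L, c(3, 10, 10))
  expect_identical(sieve_filter(z)$stack, z)
})

test_that("wetland filter clears harvest/pest codes only", {
  stack <- array(0L, c(2, 4, 4))
  stack[1, 1, 1] <- 2L; stack[1, 2, 2] <- 1L; stack[2, 3, 3] <- 7L
  stack[2, 4, 4] <- 3L
  mask <- matrix(TRUE, 4, 4)
  out <- wetland_filter(stack, mask)
  expect_equal(out[1, 1, 1], 0L)   # harvest removed
  expect_equal(out[1, 2, 2], 1L)   # fire untouched
  expect_equal(out[2, 3, 3], 0L)   # pest removed
  expect_equal(out[2, 4, 4], 3L)   # windthrow untouched
  # empty mask is the identity
  expect_identical(wetland_filter(stack, matrix(FALSE, 4, 4)), stack)
  expect_error(wetland_filter(stack, matrix(FALSE, 3, 4)), "shape")
})

test_that("map_pixel composes segmentation, classification and assembly", {
  m <- tiny_model()
  tr <- simulate_trajectory(event_spec("fire", 2000, 1, 0.5, 0.05),
                            1985:2024, noise_sd = 0.003, seed = 31)
  res <- map_pixel(tr$spectra, m)
  expect_equal(nrow(res$segments), 1)
  expect_equal(res$segments$class, "fire")
  stamped <- which(res$series != 0)
  expect_length(stamped, 1)
  expect_lte(abs(as.integer(names(res$series)[stamped]) - 2000), 1)
  # undisturbed pixel maps to all zeros
  und <- simulate_trajectory(NULL, 1985:2024, noise_sd = 0.003, seed = 32)
  expect_true(all(map_pixel(und$spectra, m)$series == 0))
})
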