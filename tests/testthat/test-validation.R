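test_that("confusion matrices tabulate paired labels", {
  cm <- confusion_matrix(c("a", "b", "a"), c("a", "b", "a"), c("a", "b"))
  expect_equal(unname(diag(cm)), c(2L, 1L))
  expect_equal(sum(cm) - sum(diag(cm)), 0L)
  cm0 <- confusion_matrix(character(0), character(0), c("a", "b"))
  expect_equal(sum(cm0), 0L)
  expect_error(confusion_matrix("a", "z", c("a", "b")), "unknown label")
})

test_that("the benchmark matrix reproduces every printed total and percentage", {
  cm <- vilts_benchmark_matrix()
  expect_equal(unname(colSums(cm)), c(542L, 139L, 139L, 22L, 27L, 202L))
  expect_equal(sum(cm), 1071L)
  oc <- omission_commission(cm)
  expect_equal(unname(oc$omission_rounded), c(2, 17, 31, 55, 33, 52))
  expect_equal(unname(oc$commission_rounded), c(21, 2, 14, 58, 22, 19))
  expect_equal(round_half_up(overall_accuracy(cm)), 81)
})

test_that("omission/commission arithmetic and the OA accounting identity hold", {
  id <- diag(5L) * 10L
  dimnames(id) <- list(letters[1:5], letters[1:5])
  oc <- omission_commission(id)
  expect_equal(unname(oc$omission), rep(0, 5))
  expect_equal(unname(oc$commission), rep(0, 5))
  expect_equal(overall_accuracy(id), 100)
  zd <- matrix(c(0L, 3L, 4L, 0L), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(overall_accuracy(zd), 0)
  # identity: correctly-mapped counts from either margin reconcile with OA
  cm <- vilts_benchmark_matrix()
  oc2 <- omission_commission(cm)
  from_om <- sum(colSums(cm) * (1 - oc2$omission / 100))
  from_cm <- sum(rowSums(cm) * (1 - oc2$commission / 100))
  expect_equal(from_om, sum(diag(cm)), tolerance = 1e-9)
  expect_equal(from_cm, sum(diag(cm)), tolerance = 1e-9)
  expect_equal(100 * from_om / sum(cm), overall_accuracy(cm), tolerance = 1e-9)
  # zero-total classes are flagged undefined
  z <- matrix(c(5L, 0L, 0L, 0L), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_true("b" %in% omission_commission(z)$undefined)
})

test_that("area-adjusted accuracy collapses to naive metrics when unstratified", {
  cm <- vilts_benchmark_matrix()
  res <- area_adjusted_accuracy(list(cm), weights = 1)
  expect_equal(res$overall_accuracy, overall_accuracy(cm), tolerance = 1e-9)
  oc <- omission_commission(cm)
  expect_equal(unname(res$commission), unname(oc$commission), tolerance = 1e-9)
  expect_equal(unname(res$omission), unname(oc$omission), tolerance = 1e-9)
  # weights proportional to stratum sizes also collapse
  half1 <- ceiling(cm / 2); half2 <- cm - half1
  w <- c(sum(half1), sum(half2)) / sum(cm)
  res2 <- area_adjusted_accuracy(list(half1, half2), weights = w)
  expect_equal(res2$overall_accuracy, overall_accuracy(cm), tolerance = 1e-6)
})

test_that("two-stratum stratified estimates match the hand-computed values", {
  # hand computation, done before implementation:
  # stratum 1 (W=0.9, n=50): [[45,3],[1,1]]; a_1 = 46/50 = 0.92
  # stratum 2 (W=0.1, n=50): [[10,5],[5,30]]; a_2 = 40/50 = 0.80
  # OA = 0.9*0.92 + 0.1*0.80 = 0.908
  # p_11 = 0.9*45/50 + 0.1*10/50 = 0.83;  p_12 = 0.9*3/50 + 0.1*5/50 = 0.064
  # p_21 = 0.9*1/50 + 0.1*5/50  = 0.028; p_22 = 0.9*1/50 + 0.1*30/50 = 0.078
  s1 <- matrix(c(45L, 1L, 3L, 1L), 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  s2 <- matrix(c(10L, 5L, 5L, 30L), 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  res <- area_adjusted_accuracy(list(s1, s2), weights = c(0.9, 0.1))
  expect_equal(res$overall_accuracy, 90.8, tolerance = 1e-9)
  expect_equal(unname(res$proportions["x", "x"]), 0.83, tolerance = 1e-9)
  expect_equal(unname(res$proportions["x", "y"]), 0.064, tolerance = 1e-9)
  expect_equal(unname(res$proportions["y", "x"]), 0.028, tolerance = 1e-9)
  expect_equal(unname(res$proportions["y", "y"]), 0.078, tolerance = 1e-9)
  # SE of OA: sqrt(0.81*0.92*0.08/49 + 0.01*0.8*0.2/49)
  expect_equal(res$overall_se,
               100 * sqrt(0.81 * 0.92 * 0.08 / 49 + 0.01 * 0.8 * 0.2 / 49),
               tolerance = 1e-9)
  # unanimous strata give zero SE
  u1 <- matrix(c(20L, 0L, 0L, 0L), 2, 2, dimnames = dimnames(s1))
  u2 <- matrix(c(0L, 0L, 0L, 15L), 2, 2, dimnames = dimnames(s1))
  expect_equal(area_adjusted_accuracy(list(u1, u2), c(0.5, 0.5))$overall_se, 0)
  expect_error(area_adjusted_accuracy(list(s1), weights = c(0.5, 0.5)),
               "one weight per stratum")
})

test_that("defoliated-biomass percentage follows the inclusion rules", {
  trees <- data.frame(
    species_group = c("coniferous", "coniferous", "deciduous", "coniferous"),
    dbh_cm = c(20, 15, 30, 8),
    agb = c(60, 40, 50, 25),
    defoliated = c(TRUE, TRUE, FALSE, TRUE))
  # dbh 8 excluded entirely; defoliated conifer = 100 of total 150
  expect_equal(pct_agb_defoliated(trees), 100 * 100 / 150)
  # all coniferous defoliated (no deciduous) -> 100
  allc <- data.frame(species_group = "coniferous", dbh_cm = c(12, 25),
                     agb = c(30, 70), defoliated = TRUE)
  expect_equal(pct_agb_defoliated(allc), 100)
  # only deciduous defoliated -> 0
  dec <- data.frame(species_group = c("deciduous", "coniferous"),
                    dbh_cm = c(20, 20), agb = c(50, 50),
                    defoliated = c(TRUE, FALSE))
  expect_equal(pct_agb_defoliated(dec), 0)
  # ratio arithmetic, scale and order invariance
  q <- data.frame(species_group = c("coniferous", "coniferous"),
                  dbh_cm = c(20, 20), agb = c(25, 75),
                  defoliated = c(TRUE, FALSE))
  expect_equal(pct_agb_defoliated(q), 25)
  q2 <- q; q2$agb <- q2$agb * 7.3
  expect_equal(pct_agb_defoliated(q2), 25)
  expect_equal(pct_agb_defoliated(q[2:1, ]), 25)
  q3 <- q; q3$agb <- 0
  expect_error(pct_agb_defoliated(q3), "zero total AGB")
  expect_error(pct_agb_defoliated(q[, -3]), "agb")
})

test_that("plot measurements are filtered on the stated exclusions", {
  plots <- data.frame(
    plot_id = 1:4,
    agb_t_ha = c(40, 120, 120, 120),
    dead_fraction = c(0.1, 0.85, 0.85, 0.1),
    dead_cause_known = c(TRUE, FALSE, TRUE, TRUE),
    defoliation_type = c("coniferous", "coniferous", "coniferous", "deciduous"))
  res <- filter_plot_measurements(plots)
  expect_equal(res$kept$plot_id, 3)   # dead > 0.8 but cause known -> kept
  expect_match(res$rejected$reason[res$rejected$plot_id == 1], "agb_below_50")
  expect_match(res$rejected$reason[res$rejected$plot_id == 2], "dead_over_80pct")
  expect_match(res$rejected$reason[res$rejected$plot_id == 4], "deciduous_only")
})

test_that("neighbourhood majority prefers disturbed codes on ties", {
  u <- matrix(5L, 5, 5)
  expect_equal(majority_neighborhood_class(u, 3, 3), 5L)
  m <- matrix(0L, 5, 5)
  m[2:4, 2:4] <- c(7L, 7L, 7L, 7L, 7L, 0L, 0L, 0L, 0L)  # 5 pest vs 4 zero
  expect_equal(majority_neighborhood_class(m, 3, 3), 7L)
  tie <- matrix(0L, 3, 3)
  tie[1, ] <- 1L; tie[2, 1] <- 1L; tie[2, 2] <- 2L  # 4 fire, 4 zero, 1 harvest
  expect_equal(majority_neighborhood_class(tie, 2, 2), 1L)
  expect_error(majority_neighborhood_class(u, 1, 3), "edge")
})

test_that("temporal matching uses year-set overlap; R2 is standard", {
  expect_true(temporal_match(2005, 2003:2007))
  expect_false(temporal_match(2005, 2007))
  expect_false(temporal_match(integer(0), 2007))
  expect_error(temporal_match(2005, integer(0)), "non-empty")
  expect_equal(r_squared(1:10, 1:10), 1)
  set.seed(1)
  o <- rnorm(50); p <- o + rnorm(50, 0, 0.1)
  expect_lt(r_squared(p, o), 1)
  expect_gt(r_squared(p, o), 0.9)
})

test_that("the stratified sampling plan allocates by area and respects buffers", {
  strata <- data.frame(stratum = c("pest", "nopest"), area = c(100, 100))
  plan <- vilts_sample_plan(strata, n = 100)
  expect_equal(plan$allocation$n, c(50L, 50L))
  # proportional with largest-remainder rounding sums exactly to n
  s3 <- data.frame(stratum = c("a", "b", "c"), area = c(1, 1, 1))
  expect_equal(sum(vilts_sample_plan(s3, n = 100)$allocation$n), 100L)
  expect_warning(vilts_sample_plan(
    data.frame(stratum = c("a", "b"), area = c(10, 0)), n = 10), "zero-area")
  # all candidates inside the exclusion radius -> empty sample + warning
  cand <- data.frame(x = c(0, 50), y = c(0, 50), stratum = "pest")
  trainpts <- data.frame(x = 10, y = 10)
  expect_warning(
    plan2 <- vilts_sample_plan(data.frame(stratum = "pest", area = 1), n = 2,
                               candidates = cand, training_points = trainpts),
    "eligible")
  expect_equal(nrow(plan2$sample), 0)
  # seeded runs are identical
  set.seed(NULL)
  cand2 <- data.frame(x = runif(200, 0, 1e4), y = runif(200, 0, 1e4),
                      stratum = rep(c("pest", "nopest"), 100))
  p1 <- vilts_sample_plan(strata, n = 40, candidates = cand2, seed = 9)
  p2 <- vilts_sample_plan(strata, n = 40, candidates = cand2, seed = 9)
  expect_identical(p1$sample, p2$sample)
})
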