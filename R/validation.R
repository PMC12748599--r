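# Design-based accuracy assessment: confusion matrices, omission and
# commission errors, overall and stratified area-adjusted accuracy with
# standard errors, plot-level defoliated-biomass analysis, neighbourhood
# majority extraction, temporal agreement, and the stratified sampling
# plan for photo-interpreted validation points.

#' Confusion matrix from paired labels
#'
#' Rows are map (predicted) classes, columns reference classes.
#'
#' @param pred,ref equal-length label vectors
#' @param classes class order for both axes (default: union, in order of
#'   appearance in `classes` of [class_scheme()] then alphabetical)
#' @return integer matrix with dimnames (map x reference)
#' @export
confusion_matrix <- function(pred, ref, classes = NULL) {
  pred <- as.character(pred); ref <- as.character(ref)
  assert(length(pred) == length(ref), "pred and ref must have equal length")
  if (is.null(classes)) classes <- sort(unique(c(pred, ref)))
  bad <- setdiff(unique(c(pred, ref)), classes)
  if (length(bad)) stop_bd("unknown label(s): ", paste(bad, collapse = ", "))
  m <- table(factor(pred, classes), factor(ref, classes))
  out <- matrix(as.integer(m), length(classes), length(classes),
                dimnames = list(map = classes, reference = classes))
  out
}

#' Per-class omission and commission errors
#'
#' commission_i = 100 (1 - n_ii / row_i total): false detections mapped as
#' class i. omission_j = 100 (1 - n_jj / column_j total): missed reference
#' instances. Classes with a zero row/column total get `NA` and are
#' flagged.
#'
#' @param cm square labelled confusion matrix
#' @return list with `commission`, `omission` (raw percents),
#'   `commission_rounded`, `omission_rounded` (round-half-up integers), and
#'   `undefined` (class names with zero totals)
#' @export
omission_commission <- function(cm) {
  assert(nrow(cm) == ncol(cm), "confusion matrix must be square")
  d <- diag(cm)
  rs <- rowSums(cm); cs <- colSums(cm)
  commission <- ifelse(rs > 0, 100 * (1 - d / rs), NA_real_)
  omission <- ifelse(cs > 0, 100 * (1 - d / cs), NA_real_)
  list(commission = commission, omission = omission,
       commission_rounded = round_half_up(commission),
       omission_rounded = round_half_up(omission),
       undefined = rownames(cm)[rs == 0 | cs == 0])
}

#' Overall accuracy (percent)
#' @param cm square confusion matrix with a positive grand total
#' @return percent, 100 * trace / total (unrounded)
#' @export
overall_accuracy <- function(cm) {
  assert(nrow(cm) == ncol(cm), "confusion matrix must be square")
  tot <- sum(cm)
  if (tot == 0) stop_bd("empty confusion matrix")
  100 * sum(diag(cm)) / tot
}

#' Stratified area-adjusted accuracy
#'
#' Design-based estimator for a stratified random sample: each cell
#' proportion is estimated as `sum_h W_h n_hij / n_h`, accuracies derive
#' from the estimated proportions, and the overall-accuracy standard error
#' is the stratified variance of the within-stratum agreement proportions
#' (no finite-population correction). With a single stratum (or weights
#' proportional to stratum sample sizes) the estimates collapse to the
#' naive count-based metrics.
#'
#' @param cms list of confusion matrices, one per stratum (identical
#'   dimnames)
#' @param weights stratum area weights W_h, summing to 1
#' @return list with `proportions` (estimated cell proportions),
#'   `overall_accuracy`, `overall_se`, `users_accuracy` /
#'   `producers_accuracy` (per class, percent), `commission`, `omission`,
#'   and their standard errors (delta-method, percent)
#' @export
area_adjusted_accuracy <- function(cms, weights) {
  assert(length(cms) == length(weights), "one weight per stratum required")
  assert(abs(sum(weights) - 1) < 1e-9, "weights must sum to 1")
  dims <- dim(cms[[1]])
  p <- matrix(0, dims[1], dims[2], dimnames = dimnames(cms[[1]]))
  oa <- 0; v_oa <- 0
  for (h in seq_along(cms)) {
    cm <- cms[[h]]
    assert(all(dim(cm) == dims), "stratum matrices must have equal dimensions")
    n_h <- sum(cm)
    assert(n_h > 0, "empty stratum matrix")
    p <- p + weights[h] * cm / n_h
    a_h <- sum(diag(cm)) / n_h
    oa <- oa + weights[h] * a_h
    if (n_h > 1) v_oa <- v_oa + weights[h]^2 * a_h * (1 - a_h) / (n_h - 1)
  }
  d <- diag(p); rs <- rowSums(p); cs <- colSums(p)
  ua <- ifelse(rs > 0, d / rs, NA_real_)
  pa <- ifelse(cs > 0, d / cs, NA_real_)
  # delta-method SE of the ratio estimators: stratified binomial variance of
  # the diagonal proportion, denominator total treated as fixed
  v_ratio <- function(totals) {
    v <- rep(0, length(d))
    for (h in seq_along(cms)) {
      cm <- cms[[h]]; n_h <- sum(cm)
      if (n_h <= 1) next
      for (i in seq_along(d)) {
        if (is.na(totals[i]) || totals[i] <= 0) next
        q <- cm[i, i] / n_h
        v[i] <- v[i] + weights[h]^2 * q * (1 - q) / (n_h - 1) / totals[i]^2
      }
    }
    v
  }
  se_ua <- sqrt(v_ratio(rs))
  se_pa <- sqrt(v_ratio(cs))
  list(proportions = p,
       overall_accuracy = 100 * oa, overall_se = 100 * sqrt(v_oa),
       users_accuracy = 100 * ua, producers_accuracy = 100 * pa,
       commission = 100 * (1 - ua), omission = 100 * (1 - pa),
       commission_se = 100 * se_ua, omission_se = 100 * se_pa)
}

#' Percentage of plot aboveground biomass in defoliated coniferous trees
#'
#' Only trees with DBH greater than 9 cm enter the totals; only coniferous
#' trees flagged as defoliated enter the numerator.
#'
#' @param trees data.frame with `species_group` ("coniferous"/"deciduous"),
#'   `dbh_cm`, `agb` (t/ha contribution), `defoliated` (logical)
#' @return percent in \[0, 100\]
#' @export
pct_agb_defoliated <- function(trees) {
  req <- c("species_group", "dbh_cm", "agb", "defoliated")
  miss <- setdiff(req, names(trees))
  if (length(miss)) stop_bd("missing tree field(s): ", paste(miss, collapse = ", "))
  assert(all(trees$agb >= 0), "AGB contributions must be >= 0")
  keep <- trees$dbh_cm > 9
  total <- sum(trees$agb[keep])
  if (total <= 0) stop_bd("zero total AGB: percentage undefined")
  defol <- sum(trees$agb[keep & trees$species_group == "coniferous" &
                           trees$defoliated])
  100 * defol / total
}

#' Filter ground-plot measurements for the defoliation analysis
#'
#' Drops measurements with deciduous-only defoliation, more than 80% dead
#' trees from unknown disturbances, or plot AGB below 50 t/ha.
#'
#' @param plots data.frame with `plot_id`, `agb_t_ha`, `dead_fraction`,
#'   `dead_cause_known` (logical), `defoliation_type`
#'   ("none"/"coniferous"/"deciduous")
#' @return list `kept` and `rejected` (with a `reason` column)
#' @export
filter_plot_measurements <- function(plots) {
  req <- c("agb_t_ha", "dead_fraction", "dead_cause_known", "defoliation_type")
  miss <- setdiff(req, names(plots))
  if (length(miss)) stop_bd("missing plot field(s): ", paste(miss, collapse = ", "))
  for (f in req) if (anyNA(plots[[f]])) stop_bd("missing values in field: ", f)
  checks <- list(
    deciduous_only_defoliation = plots$defoliation_type != "deciduous",
    dead_over_80pct_unknown = !(plots$dead_fraction > 0.8 & !plots$dead_cause_known),
    agb_below_50 = plots$agb_t_ha >= 50
  )
  pass <- Reduce(`&`, checks)
  reasons <- vapply(seq_len(nrow(plots)), function(i)
    paste(names(checks)[!vapply(checks, `[`, TRUE, i)], collapse = ";"), "")
  rejected <- plots[!pass, , drop = FALSE]
  if (nrow(rejected)) rejected$reason <- reasons[!pass] else rejected$reason <- character(0)
  list(kept = plots[pass, , drop = FALSE], rejected = rejected)
}

#' Majority map code in the 3x3 neighbourhood of a point
#'
#' Validation statistics use the modal class of the 9 pixels centred on the
#' point. Ties prefer a disturbed code over undisturbed, then the lowest
#' code.
#'
#' @param map integer matrix of map codes
#' @param row,col centre pixel (must have a full 3x3 neighbourhood)
#' @return integer map code
#' @export
majority_neighborhood_class <- function(map, row, col) {
  assert(row >= 2 && row <= nrow(map) - 1 && col >= 2 && col <= ncol(map) - 1,
         "point too close to the raster edge for a 3x3 neighbourhood")
  vals <- as.integer(map[(row - 1):(row + 1), (col - 1):(col + 1)])
  tab <- table(vals)
  best <- as.integer(names(tab)[tab == max(tab)])
  if (length(best) > 1 && any(best > 0)) best <- best[best > 0]
  min(best)
}

#' Temporal overlap match rule
#'
#' A prediction is correct if any predicted disturbance year overlaps the
#' photo-interpreted disturbance years. An empty prediction is a non-match,
#' not an error.
#'
#' @param predicted_years,interpreted_years integer vectors
#' @return logical
#' @export
temporal_match <- function(predicted_years, interpreted_years) {
  assert(length(interpreted_years) >= 1, "interpreted years must be non-empty")
  length(intersect(predicted_years, interpreted_years)) > 0
}

#' Coefficient of determination
#' @param pred,obs paired numeric vectors
#' @return standard R-squared, 1 - SS_res / SS_tot
#' @export
r_squared <- function(pred, obs) {
  assert(length(pred) == length(obs) && length(obs) >= 2, "need paired vectors")
  1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
}

#' Stratified random sampling plan for validation points
#'
#' Allocation proportional to stratum area (largest-remainder rounding to
#' hit `n` exactly); candidate points within `min_distance_m` of any
#' training point are excluded before sampling. Zero-area strata are
#' excluded with a warning.
#'
#' @param strata data.frame with `stratum` and `area`
#' @param n total sample size (default 1100)
#' @param min_distance_m exclusion radius around training points (default
#'   200)
#' @param candidates optional data.frame with `x`, `y`, `stratum`
#' @param training_points optional data.frame with `x`, `y`
#' @param seed integer seed
#' @return list with `allocation` (data.frame stratum/n) and `sample`
#'   (selected candidate rows, when candidates are supplied)
#' @export
vilts_sample_plan <- function(strata, n = 1100, min_distance_m = 200,
                              candidates = NULL, training_points = NULL,
                              seed = 1L) {
  assert(all(strata$area >= 0), "stratum areas must be >= 0")
  if (any(strata$area == 0)) {
    warning("excluding zero-area strata: ",
            paste(strata$stratum[strata$area == 0], collapse = ", "),
            call. = FALSE)
    strata <- strata[strata$area > 0, , drop = FALSE]
  }
  assert(nrow(strata) >= 1, "no strata with positive area")
  exact <- n * strata$area / sum(strata$area)
  alloc <- floor(exact)
  rem <- n - sum(alloc)
  if (rem > 0) {
    o <- order(exact - alloc, decreasing = TRUE)
    alloc[o[seq_len(rem)]] <- alloc[o[seq_len(rem)]] + 1
  }
  allocation <- data.frame(stratum = strata$stratum, n = as.integer(alloc))
  smp <- NULL
  if (!is.null(candidates)) {
    keep <- rep(TRUE, nrow(candidates))
    if (!is.null(training_points) && nrow(training_points)) {
      for (i in seq_len(nrow(candidates))) {
        d2 <- (candidates$x[i] - training_points$x)^2 +
          (candidates$y[i] - training_points$y)^2
        if (any(d2 < min_distance_m^2)) keep[i] <- FALSE
      }
    }
    pool <- candidates[keep, , drop = FALSE]
    smp <- with_seed(seed, {
      picked <- lapply(seq_len(nrow(allocation)), function(i) {
        avail <- which(pool$stratum == allocation$stratum[i])
        take <- min(length(avail), allocation$n[i])
        if (take < allocation$n[i])
          warning("stratum ", allocation$stratum[i], ": only ", take,
                  " eligible candidates for ", allocation$n[i], " requested",
                  call. = FALSE)
        if (take == 0) integer(0) else sort(sample(avail, take))
      })
      pool[unlist(picked), , drop = FALSE]
    })
  }
  list(allocation = allocation, sample = smp)
}

#' Bundled photo-interpretation benchmark confusion matrix
#'
#' A published national-scale validation confusion matrix (1,071
#' photo-interpreted points; map rows NoChange, Wildfire, Harvesting,
#' Windthrow, Pest_Harv, Pest against the same reference columns), shipped
#' as a regression fixture for the accuracy arithmetic.
#'
#' @return integer confusion matrix (6 x 6, map x reference)
#' @export
vilts_benchmark_matrix <- function() {
  path <- system.file("extdata", "vilts_confusion.csv", package = "borealdist")
  df <- read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  names(dimnames(m)) <- c("map", "reference")
  storage.mode(m) <- "integer"
  m
}
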