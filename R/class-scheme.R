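#' Training classes and final map codes
#'
#' The classifier is trained on 18 classes: the three defoliation
#' severities, four abrupt disturbance classes, six undisturbed land-cover
#' classes, and five synthetic "uncommon" composites built by concatenating
#' trajectories (forest-to-crops/urban/water conversions and
#' pest-followed-by-fire/harvesting). Final maps collapse these to nine
#' codes; crop/urban conversions are treated as undisturbed and
#' pest-followed-by-fire is reclassified as wildfire.
#'
#' @return data.frame with `class` (training label), `map_code` (0-8) and
#'   `group` (pest/abrupt/undisturbed/composite).
#' @export
class_scheme <- function() {
  data.frame(
    class = c("defol_low", "defol_medium", "defol_high",
              "fire", "harvest_total", "harvest_partial", "windthrow",
              "forest", "noforest", "rocks", "crops", "urban", "water",
              "crops_change", "urban_change", "dams", "pest_fire", "pest_harv"),
    map_code = c(6L, 7L, 8L,
                 1L, 2L, 2L, 3L,
                 0L, 0L, 0L, 0L, 0L, 0L,
                 0L, 0L, 4L, 1L, 5L),
    group = c(rep("pest", 3), rep("abrupt", 4), rep("undisturbed", 6),
              rep("composite", 5)),
    stringsAsFactors = FALSE
  )
}

#' Map a training label to its final map code
#' @param training_label character vector of training-class labels
#' @return integer map codes in 0..8
#' @export
remap_to_final <- function(training_label) {
  sch <- class_scheme()
  i <- match(training_label, sch$class)
  if (anyNA(i))
    stop_bd("unknown training label: ",
            paste(unique(training_label[is.na(i)]), collapse = ", "))
  sch$map_code[i]
}

#' Map legend: code, label, display colour
#' @return data.frame with columns code, label, color (codes 0-8)
#' @export
map_legend <- function() {
  data.frame(
    code = 0:8,
    label = c("Undisturbed", "Wildfire", "Harvesting", "Windthrow",
              "Water extension", "Defoliation followed by harvesting",
              "Low severity defoliation", "Medium severity defoliation",
              "High severity defoliation"),
    color = c("#d9d9d9", "#e31a1c", "#ff7f00", "#6a3d9a", "#1f78b4",
              "#b15928", "#ffffb3", "#fdb462", "#fb8072"),
    stringsAsFactors = FALSE
  )
}

#' Map codes stamped for a single year (rapid, stand-replacing)
#' @return integer vector
#' @export
rapid_codes <- function() c(1L, 2L, 3L, 4L)

#' Map codes stamped across the whole segment span (multi-year pest)
#' @return integer vector
#' @export
multiyear_codes <- function() c(5L, 6L, 7L, 8L)
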