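#' Pixel-to-mm2 calibration from reference objects
#'
#' Builds the per-view conversion from pixel counts to square millimetres.
#' In practice the references are images of bars covered with millimetre
#' paper placed in the pots, photographed with the experiment's camera
#' settings; each reference contributes the ratio of its known area to its
#' segmented pixel count, and references for the same view are averaged.
#'
#' @param references data.frame with columns `view` (one of `"top"`,
#'   `"front"`, `"side"`), `px_count` (> 0) and `known_mm2` (> 0).
#' @return named list mapping view to mm^2 per pixel, class
#'   `"calibration_model"`.
#' @examples
#' calibrate(data.frame(view = "front", px_count = 400, known_mm2 = 100))
#' @export
calibrate <- function(references) {
  stopifnot(is.data.frame(references),
            all(c("view", "px_count", "known_mm2") %in% names(references)))
  if (any(references$px_count <= 0) || any(references$known_mm2 <= 0))
    stop("px_count and known_mm2 must be positive")
  ratios <- references$known_mm2 / references$px_count
  factors <- tapply(ratios, references$view, mean)
  structure(as.list(factors), class = "calibration_model")
}

#' Apply a calibration model to a pixel area
#' @param model a [calibrate()] result.
#' @param view view name; must be present in the model.
#' @param area_px pixel count(s).
#' @return area(s) in mm^2.
#' @export
apply_calibration <- function(model, view, area_px) {
  if (is.null(model[[view]]))
    stop("no calibration available for view '", view, "'")
  area_px * model[[view]]
}

#' Total green area from three projections
#'
#' Combines the projected areas of the top, front and side views into a
#' single biomass proxy, `A = sqrt(Ax^2 + Ay^2 + Az^2)`. The combination is
#' symmetric, scales linearly with the projections, and is never smaller
#' than the largest single projection. A missing view counts as a zero
#' projection (biasing A low) and is flagged with a warning.
#'
#' @param a_x,a_y,a_z projected areas, same units, each `>= 0`; `NA` is
#'   treated as a missing view.
#' @return total green area in the input units (vectorized).
#' @examples
#' total_green_area(3, 4, 0)  # 5
#' @export
total_green_area <- function(a_x, a_y, a_z) {
  prj <- cbind(a_x, a_y, a_z)
  if (anyNA(prj)) {
    warning("missing view projection treated as zero area")
    prj[is.na(prj)] <- 0
  }
  if (any(prj < 0)) stop("projected areas must be non-negative")
  unname(sqrt(prj[, 1]^2 + prj[, 2]^2 + prj[, 3]^2))
}

#' Normalized green area (NGA)
#'
#' Divides each day's green area by the area on the first measuring day, so
#' cultivars starting at different sizes become comparable; NGA on the first
#' day is 1 by construction.
#'
#' @param days measurement days, strictly increasing.
#' @param areas total green areas, same length; first-day area must be > 0.
#' @return numeric vector of NGA values.
#' @export
normalized_green_area <- function(days, areas) {
  stopifnot(length(days) == length(areas), length(days) >= 1)
  if (is.unsorted(days, strictly = TRUE)) stop("days must be strictly increasing")
  if (is.na(areas[1]) || areas[1] <= 0)
    stop("first-day area must be positive to normalize")
  areas / areas[1]
}

#' Relative growth rate (RGR) of a group
#'
#' `RGR = (mean(ln W2) - mean(ln W1)) / (t2 - t1)`: the difference of the
#' group means of log green areas divided by the elapsed time. Note the mean
#' is taken over log-areas (not the log of the mean area) following the
#' classical growth-analysis formulation of Hoffmann & Poorter.
#'
#' @param areas_t1,areas_t2 positive areas of the group at times `t1`, `t2`.
#' @param t1,t2 measurement times (days), `t2 > t1`.
#' @return growth rate per day.
#' @examples
#' relative_growth_rate(c(10, 20), c(30, 50), 0, 4)
#' @export
relative_growth_rate <- function(areas_t1, areas_t2, t1, t2) {
  if (any(areas_t1 <= 0) || any(areas_t2 <= 0))
    stop("areas must be positive for log growth rates")
  if (t2 <= t1) stop("t2 must exceed t1")
  (mean(log(areas_t2)) - mean(log(areas_t1))) / (t2 - t1)
}

#' Per-plant growth table: total area and NGA
#'
#' Reshapes a long per-view area table into one row per plant and day with
#' the calibrated total green area and its NGA.
#'
#' @param areas data.frame with columns `plant_id`, `day`, `view`, `area_px`.
#' @param calibration optional [calibrate()] model; when supplied, per-view
#'   pixel areas are converted to mm^2 before combination.
#' @return data.frame with `plant_id`, `day`, `a_total`, `nga`.
#' @export
growth_table <- function(areas, calibration = NULL) {
  stopifnot(all(c("plant_id", "day", "view", "area_px") %in% names(areas)))
  a <- areas
  a$area <- if (is.null(calibration)) a$area_px else
    mapply(function(v, p) apply_calibration(calibration, v, p), a$view, a$area_px)
  wide <- stats::reshape(
    a[, c("plant_id", "day", "view", "area")],
    idvar = c("plant_id", "day"), timevar = "view", direction = "wide"
  )
  get_view <- function(v) {
    cn <- paste0("area.", v)
    if (cn %in% names(wide)) wide[[cn]] else rep(NA_real_, nrow(wide))
  }
  wide$a_total <- total_green_area(get_view("top"), get_view("front"),
                                   get_view("side"))
  out <- wide[order(wide$plant_id, wide$day),
              c("plant_id", "day", "a_total")]
  out$nga <- stats::ave(out$a_total, out$plant_id, FUN = function(x) x / x[1])
  rownames(out) <- NULL
  out
}

#' Group RGR over measurement intervals
#'
#' Computes the group relative growth rate for each interval of the series,
#' either between consecutive measuring days (default) or anchored to the
#' first day.
#'
#' @param growth data.frame from [growth_table()] (columns `plant_id`,
#'   `day`, `a_total`).
#' @param anchored if `TRUE`, every interval starts at the first day.
#' @return data.frame with `day1`, `day2`, `rgr`, `n` (plants present on
#'   both days).
#' @export
rgr_series <- function(growth, anchored = FALSE) {
  days <- sort(unique(growth$day))
  if (length(days) < 2) stop("need at least two measurement days for RGR")
  from <- if (anchored) rep(days[1], length(days) - 1) else days[-length(days)]
  to <- days[-1]
  rows <- lapply(seq_along(to), function(i) {
    g1 <- growth[growth$day == from[i], ]
    g2 <- growth[growth$day == to[i], ]
    ids <- intersect(g1$plant_id, g2$plant_id)
    a1 <- g1$a_total[match(ids, g1$plant_id)]
    a2 <- g2$a_total[match(ids, g2$plant_id)]
    data.frame(day1 = from[i], day2 = to[i],
               rgr = relative_growth_rate(a1, a2, from[i], to[i]),
               n = length(ids))
  })
  do.call(rbind, rows)
}
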