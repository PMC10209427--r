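# Constant-rate sediment-core chronology: depth <-> calendar-year
# conversion, slice-duration accounting, and dating of macrofossil finds
# relative to documented introduction years. The net sedimentation rate is
# an input (obtained externally from radiometric dating); only the linear
# age model is implemented here.

#' Core sampling scheme
#'
#' @param slice_thickness_cm thickness of one analysed slice (cm, > 0).
#' @param net_rate_cm_per_yr net sedimentation rate (cm/year, > 0).
#' @param reference_year calendar year of depth 0 (the core top). The
#'   coring year is not always documented; all absolute dates are relative
#'   to this reference.
#' @param area_cm2 optional core cross-sectional area.
#' @return a `core_scheme` object.
#' @export
core_scheme <- function(slice_thickness_cm, net_rate_cm_per_yr,
                        reference_year, area_cm2 = NULL) {
  if (slice_thickness_cm <= 0) stop_("slice thickness must be positive")
  if (net_rate_cm_per_yr <= 0) stop_("sedimentation rate must be positive")
  out <- list(slice_thickness_cm = slice_thickness_cm,
              net_rate_cm_per_yr = net_rate_cm_per_yr,
              reference_year = reference_year, area_cm2 = area_cm2)
  class(out) <- "core_scheme"
  out
}

#' Years of deposition per core slice
#'
#' `slice_thickness / net_rate`, reported to one decimal (e.g. 2.5 cm at
#' 0.69 cm/year is 3.6 years per slice).
#'
#' @param scheme a [core_scheme()].
#' @return years per slice, rounded to 1 decimal.
#' @export
slice_duration <- function(scheme) {
  round(scheme$slice_thickness_cm / scheme$net_rate_cm_per_yr, 1)
}

#' Calendar year of a core depth
#'
#' Linear age model: `reference_year - depth / rate`, rounded to the
#' integer year. Strictly decreasing in depth.
#'
#' @param scheme a [core_scheme()].
#' @param depth_cm nonnegative depth(s) below the core top.
#' @return integer calendar year(s).
#' @export
depth_to_year <- function(scheme, depth_cm) {
  if (any(depth_cm < 0)) stop_("depth must be nonnegative")
  as.integer(round(scheme$reference_year -
                     depth_cm / scheme$net_rate_cm_per_yr))
}

#' Years between a dated layer and a later event
#'
#' @param event_year calendar year of the event (e.g. first documented
#'   introduction).
#' @param layer_year calendar year of the dated layer.
#' @return `event_year - layer_year` (positive when the layer predates the
#'   event).
#' @export
years_before <- function(event_year, layer_year) {
  as.integer(event_year - layer_year)
}

#' Date a macrofossil find
#'
#' Converts a depth interval into a calendar-year interval under the
#' scheme's linear age model.
#'
#' @param scheme a [core_scheme()].
#' @param top_cm,bottom_cm depth interval of the find (top < bottom).
#' @param item free-text description (e.g. "whitefish scale").
#' @return a `macrofossil_find`: list with the depth interval, `year_young`
#'   (from the top depth), `year_old` (from the bottom depth), `item`.
#' @export
date_find <- function(scheme, top_cm, bottom_cm, item = "") {
  if (top_cm >= bottom_cm) stop_("top depth must be above bottom depth")
  out <- list(top_cm = top_cm, bottom_cm = bottom_cm,
              year_young = depth_to_year(scheme, top_cm),
              year_old = depth_to_year(scheme, bottom_cm),
              item = item)
  class(out) <- "macrofossil_find"
  out
}
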