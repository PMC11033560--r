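# Regulatory counting criteria and airborne concentration conversion.

#' Fiber counting criteria
#'
#' The regulatory definition of a countable fiber used for airborne
#' asbestos monitoring: length of at least 5 um (inclusive), width
#' below 3 um (strict), aspect ratio of at least 3 (inclusive).
#'
#' @param min_length_um minimum length in um, inclusive (default 5).
#' @param max_width_um maximum width in um, exclusive (default 3).
#' @param min_aspect_ratio minimum length/width ratio, inclusive
#'   (default 3).
#' @return object of class `counting_criteria`.
#' @export
counting_criteria <- function(min_length_um = 5, max_width_um = 3,
                              min_aspect_ratio = 3) {
  stop_if(min_length_um <= 0 || max_width_um <= 0 || min_aspect_ratio <= 0,
          "all criteria must be positive")
  structure(list(min_length_um = min_length_um,
                 max_width_um = max_width_um,
                 min_aspect_ratio = min_aspect_ratio),
            class = "counting_criteria")
}

#' Decide whether a fiber is countable
#'
#' A fiber counts iff `length_um >= min_length_um` AND
#' `width_um < max_width_um` AND `aspect_ratio >= min_aspect_ratio` —
#' inclusivity exactly as the criteria are written (length and aspect
#' bounds inclusive, width bound strict).
#'
#' @param fiber a `fiber_candidate`, or any list with numeric
#'   `length_um`, `width_um`, `aspect_ratio`.
#' @param criteria a [counting_criteria()].
#' @return logical.
#' @export
apply_criteria <- function(fiber, criteria = counting_criteria()) {
  for (f in c("length_um", "width_um", "aspect_ratio"))
    stop_if(is.null(fiber[[f]]) || !is.finite(fiber[[f]]),
            "fiber is missing measurement '", f, "'")
  fiber$length_um >= criteria$min_length_um &&
    fiber$width_um < criteria$max_width_um &&
    fiber$aspect_ratio >= criteria$min_aspect_ratio
}

#' Count countable and sub-criteria fibers in one field of view
#'
#' @param fibers list of `fiber_candidate` objects (possibly empty).
#' @param criteria a [counting_criteria()].
#' @return named integer vector `c(countable = , subcriteria = )`;
#'   the two always sum to `length(fibers)`.
#' @export
count_field <- function(fibers, criteria = counting_criteria()) {
  if (length(fibers) == 0) return(c(countable = 0L, subcriteria = 0L))
  ok <- vapply(fibers, apply_criteria, TRUE, criteria = criteria)
  c(countable = sum(ok), subcriteria = sum(!ok))
}

#' Air sampling configuration
#'
#' Geometry and air volume used to scale per-field fiber counts to an
#' airborne concentration. The nominal membrane filter is 47 mm in
#' diameter; its effective collection diameter — the portion actually
#' exposed to airflow in the standard filter holder — defaults to
#' 35 mm. The microscope field of view is the 300-um-diameter graticule
#' circle.
#'
#' @param air_volume_L sampled air volume in litres (e.g. 2400).
#' @param filter_diameter_mm nominal filter diameter (default 47).
#' @param effective_diameter_mm effective collection diameter
#'   (default 35, must not exceed the nominal diameter).
#' @param field_diameter_um field-of-view diameter in um (default 300).
#' @return object of class `sampling_config`.
#' @export
sampling_config <- function(air_volume_L = 2400, filter_diameter_mm = 47,
                            effective_diameter_mm = 35,
                            field_diameter_um = 300) {
  stop_if(air_volume_L <= 0 || filter_diameter_mm <= 0 ||
            effective_diameter_mm <= 0 || field_diameter_um <= 0,
          "all sampling parameters must be positive")
  stop_if(effective_diameter_mm > filter_diameter_mm,
          "effective diameter cannot exceed the filter diameter")
  structure(list(air_volume_L = air_volume_L,
                 filter_diameter_mm = filter_diameter_mm,
                 effective_diameter_mm = effective_diameter_mm,
                 field_diameter_um = field_diameter_um),
            class = "sampling_config")
}

#' Convert a mean per-field fiber count to fibers per litre of air
#'
#' Scales the mean count per field of view by the ratio of the
#' effective filter collection area to the field-of-view area (both
#' circles), then divides by the sampled air volume:
#' `mean_fibers_per_field * (A_filter / A_field) / air_volume_L`.
#' With 5.5 fibers per 300-um field, a 35-mm effective diameter and
#' 2400 L of air this gives 31.2 fibers/L (1 d.p.).
#'
#' @param mean_fibers_per_field mean countable fibers per field.
#' @param sampling a [sampling_config()].
#' @return concentration in fibers per litre (unrounded; use
#'   [round_half_up()] with 1 digit for reporting).
#' @export
concentration_fibers_per_L <- function(mean_fibers_per_field,
                                       sampling = sampling_config()) {
  stopifnot(inherits(sampling, "sampling_config"))
  stop_if(mean_fibers_per_field < 0,
          "mean fibers per field must be non-negative")
  a_filter_mm2 <- pi * (sampling$effective_diameter_mm / 2)^2
  a_field_mm2 <- pi * (sampling$field_diameter_um / 2 / 1000)^2
  mean_fibers_per_field * (a_filter_mm2 / a_field_mm2) /
    sampling$air_volume_L
}

#' Round half away from zero
#'
#' Reporting-style rounding where .5 always rounds up in magnitude
#' (R's `round()` rounds half to even).
#'
#' @param x numeric vector.
#' @param digits decimal places (default 0).
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
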