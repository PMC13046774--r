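#' Fit a surface-area fluorescence sizing calibration
#'
#' Sizes particles from total membrane-dye fluorescence: dye uptake is
#' assumed proportional to membrane surface area, so a liposome size
#' standard of known median diameter fixes the proportionality constant
#' k = median(I) / (pi * d_std^2) in fluorescence units per nm^2.
#'
#' @param standard_events An \code{\link{event_table}} of dye-stained size
#'   standard events.
#' @param dye_channel Name of the membrane-dye fluorescence channel.
#' @param standard_median_diameter Median diameter of the standard in nm.
#'   Default 110, the midpoint of the 80-140 nm span of the liposome
#'   standard as characterised by nanoparticle tracking analysis; supply the
#'   standard's own measured median when available.
#' @return An object of class \code{"surface_area_calibration"} with
#'   \code{k_intensity_per_area}, \code{standard_median_diameter}, and
#'   \code{standard_intensity_median}.
#' @examples
#' std <- event_table(data.frame(vfred = rep(38013.27, 10)))
#' cal <- fit_surface_area_calibration(std, "vfred", 110)
#' predict(cal, pi * coef(cal)[["k_intensity_per_area"]] * 100^2)  # 100 nm
#' @export
fit_surface_area_calibration <- function(standard_events, dye_channel,
                                         standard_median_diameter = 110) {
  stopifnot(inherits(standard_events, "event_table"),
            standard_median_diameter > 0)
  intens <- require_channel(standard_events, dye_channel)
  if (length(intens) == 0L) stop("empty standard sample", call. = FALSE)
  if (any(intens < 0)) stop("negative dye intensities", call. = FALSE)
  med <- stats::median(intens)
  if (med <= 0) stop("standard dye intensities are all zero", call. = FALSE)
  structure(list(k_intensity_per_area = med / (pi * standard_median_diameter^2),
                 standard_median_diameter = standard_median_diameter,
                 standard_intensity_median = med,
                 dye_channel = dye_channel),
            class = "surface_area_calibration")
}

#' @export
coef.surface_area_calibration <- function(object, ...) {
  c(k_intensity_per_area = object$k_intensity_per_area)
}

#' @export
print.surface_area_calibration <- function(x, ...) {
  cat("Surface-area fluorescence sizing calibration\n")
  cat(sprintf("  standard: median %g nm at median intensity %.6g ('%s')\n",
              x$standard_median_diameter, x$standard_intensity_median,
              x$dye_channel))
  cat(sprintf("  k = %.6g intensity units per nm^2 of membrane\n",
              x$k_intensity_per_area))
  invisible(x)
}

#' Convert membrane-dye fluorescence to diameter
#'
#' Inverts the surface-area model: d = sqrt(I / (pi * k)).  Zero intensity
#' maps to zero diameter; negative intensities are rejected.
#'
#' @param intensity Non-negative fluorescence intensities.
#' @param cal A \code{"surface_area_calibration"}.
#' @return Diameters in nm.
#' @export
intensity_to_diameter_fluor <- function(intensity, cal) {
  stopifnot(inherits(cal, "surface_area_calibration"))
  if (any(intensity < 0, na.rm = TRUE))
    stop("negative fluorescence intensity", call. = FALSE)
  sqrt(intensity / (pi * cal$k_intensity_per_area))
}

#' @export
#' @rdname intensity_to_diameter_fluor
#' @param object A \code{"surface_area_calibration"}.
#' @param newdata Intensities (vector, or an \code{event_table} containing
#'   the calibration's dye channel).
#' @param ... Unused.
predict.surface_area_calibration <- function(object, newdata, ...) {
  if (inherits(newdata, "event_table") || is.data.frame(newdata))
    newdata <- require_channel(newdata, object$dye_channel)
  intensity_to_diameter_fluor(newdata, object)
}
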