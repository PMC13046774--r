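#' Antibody-binding-capacity bead set
#'
#' Describes one fluorophore's calibration bead set: populations with
#' manufacturer-assigned antibody binding capacities (ABC) and measured
#' median intensities, plus an unstained blank population whose
#' autofluorescence defines the limit of detection.
#'
#' @param assigned_abc Strictly increasing positive ABC values (>= 2).
#' @param median_intensity Median fluorescence per population (> 0).
#' @param blank_median_intensity Median intensity of the blank population.
#' @param blank_sd Robust SD of the blank population (optional; used only
#'   when a k*SD LoD is requested).
#' @return A list of class \code{"abc_bead_set"}.
#' @export
abc_bead_set <- function(assigned_abc, median_intensity,
                         blank_median_intensity, blank_sd = NA_real_) {
  stopifnot(length(assigned_abc) == length(median_intensity))
  if (length(assigned_abc) < 2L)
    stop("need at least 2 calibrated populations", call. = FALSE)
  if (any(assigned_abc <= 0) || any(diff(assigned_abc) <= 0))
    stop("'assigned_abc' must be strictly increasing and positive", call. = FALSE)
  if (any(median_intensity <= 0) || blank_median_intensity <= 0)
    stop("intensities must be positive", call. = FALSE)
  structure(list(assigned_abc = assigned_abc,
                 median_intensity = median_intensity,
                 blank_median_intensity = blank_median_intensity,
                 blank_sd = blank_sd),
            class = "abc_bead_set")
}

#' Fit the ABC calibration regression
#'
#' Least-squares regression of log10(intensity) on log10(ABC) across the
#' calibrated bead populations.  ABC spans orders of magnitude, so the fit
#' is done in log-log space and summarised by a single Pearson correlation
#' coefficient R, the way ABC kit templates report it.
#'
#' @param beads An \code{\link{abc_bead_set}}.
#' @return An object of class \code{"abc_calibration"} with \code{slope},
#'   \code{intercept} (log10-space), \code{r_coefficient}, and the
#'   calibrated ABC range.
#' @examples
#' bs <- abc_bead_set(c(5e3, 2e4, 8e4, 2.5e5),
#'                    2 * c(5e3, 2e4, 8e4, 2.5e5),  # exact power law
#'                    blank_median_intensity = 200)
#' cal <- fit_abc_regression(bs)
#' lod_from_blank(cal, bs$blank_median_intensity)
#' @export
fit_abc_regression <- function(beads) {
  stopifnot(inherits(beads, "abc_bead_set"))
  la <- log10(beads$assigned_abc)
  li <- log10(beads$median_intensity)
  fit <- stats::lm(li ~ la)
  r <- stats::cor(la, li)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_coefficient = r,
                 abc_range = range(beads$assigned_abc)),
            class = "abc_calibration")
}

#' @export
coef.abc_calibration <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
print.abc_calibration <- function(x, ...) {
  cat("ABC calibration (log10-log10)\n")
  cat(sprintf("  log10(I) = %.4f + %.4f * log10(ABC),  R = %.4f\n",
              x$intercept, x$slope, x$r_coefficient))
  cat(sprintf("  calibrated ABC range: %g - %g\n",
              x$abc_range[1L], x$abc_range[2L]))
  invisible(x)
}

#' Limit of detection from the blank population
#'
#' The LoD is the ABC equivalent of the blank population's
#' autofluorescence: the assigned-ABC value at which the fitted regression
#' predicts the blank's median intensity (optionally median + k*SD).  A
#' blank falling outside the calibrated ABC range still yields a finite LoD
#' but is flagged \code{extrapolated}.
#'
#' @param cal An \code{"abc_calibration"}.
#' @param blank_median_intensity Median intensity of the unstained blank.
#' @param k Multiples of the blank SD added to the median before conversion
#'   (default 0: the blank's autofluorescence alone).
#' @param blank_sd Blank SD, required when \code{k > 0}.
#' @return A list with \code{lod} (ABC units) and \code{extrapolated}.
#' @export
lod_from_blank <- function(cal, blank_median_intensity, k = 0,
                           blank_sd = NA_real_) {
  stopifnot(inherits(cal, "abc_calibration"), blank_median_intensity > 0)
  if (cal$slope == 0) stop("degenerate calibration: slope is zero", call. = FALSE)
  intens <- blank_median_intensity + if (k > 0) {
    if (is.na(blank_sd)) stop("'blank_sd' needed when k > 0", call. = FALSE)
    k * blank_sd
  } else 0
  lod <- 10^((log10(intens) - cal$intercept) / cal$slope)
  list(lod = lod,
       extrapolated = lod < cal$abc_range[1L] || lod > cal$abc_range[2L])
}

#' Convert fluorescence intensity to antibody binding capacity
#'
#' Inverse of the fitted log-log regression; monotone in intensity.
#'
#' @param intensity Positive fluorescence intensities.
#' @param cal An \code{"abc_calibration"}.
#' @return ABC values (same length as \code{intensity}).
#' @export
intensity_to_abc <- function(intensity, cal) {
  stopifnot(inherits(cal, "abc_calibration"))
  if (any(intensity <= 0, na.rm = TRUE))
    stop("intensity must be positive", call. = FALSE)
  10^((log10(intensity) - cal$intercept) / cal$slope)
}

#' @export
#' @rdname intensity_to_abc
#' @param object An \code{"abc_calibration"}.
#' @param newdata Intensities to convert.
#' @param ... Unused.
predict.abc_calibration <- function(object, newdata, ...) {
  intensity_to_abc(newdata, object)
}

#' Limit-of-detection panel report
#'
#' Fits each fluorophore's bead set, converts its blank to an ABC-equivalent
#' LoD, and returns a table (one row per fluorophore: LoD and regression R)
#' ranked by ascending LoD -- the shape in which panel sensitivity is
#' compared across fluorophores.
#'
#' @param bead_sets Named list of \code{\link{abc_bead_set}} objects, one
#'   per fluorophore.
#' @param k Blank SD multiplier passed to \code{\link{lod_from_blank}}.
#' @return A data frame with columns \code{fluorophore}, \code{lod_abc},
#'   \code{r_coefficient}, \code{extrapolated}, sorted by \code{lod_abc}.
#' @export
abc_lod_table <- function(bead_sets, k = 0) {
  stopifnot(is.list(bead_sets), length(bead_sets) >= 1L,
            !is.null(names(bead_sets)))
  rows <- lapply(names(bead_sets), function(nm) {
    bs <- bead_sets[[nm]]
    cal <- fit_abc_regression(bs)
    lod <- lod_from_blank(cal, bs$blank_median_intensity, k = k,
                          blank_sd = bs$blank_sd)
    data.frame(fluorophore = nm, lod_abc = lod$lod,
               r_coefficient = cal$r_coefficient,
               extrapolated = lod$extrapolated, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$lod_abc), , drop = FALSE]
}
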