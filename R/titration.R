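# Calcein titration analysis: background subtraction, stain index per
# concentration, optimum and plateau detection.

#' Background-subtracted positive count
#'
#' Removes the buffer + dye autofluorescence contribution from a sample's
#' positive count; negative differences clamp to zero with a warning.
#'
#' @param sample_count,buffer_count Non-negative event counts.
#' @return max(sample - buffer, 0).
#' @export
background_subtract <- function(sample_count, buffer_count) {
  stopifnot(sample_count >= 0, buffer_count >= 0)
  corrected <- sample_count - buffer_count
  if (corrected < 0) {
    warning("buffer count exceeds sample count; clamping to 0")
    corrected <- 0
  }
  corrected
}

#' Stain index
#'
#' Separation between the stained and unstained populations, normalised by
#' the spread of the unstained population:
#' SI = (median_pos - median_neg) / (2 * sd_neg).  Invariant under affine
#' rescaling of the intensity axis.
#'
#' @param pos_median Median intensity of the positive (stained) population.
#' @param neg_median Median intensity of the negative population.
#' @param neg_sd Standard deviation of the negative population (> 0).
#' @return The stain index (dimensionless).
#' @examples
#' stain_index(1000, 100, 50)   # 9
#' @export
stain_index <- function(pos_median, neg_median, neg_sd) {
  if (any(neg_sd <= 0)) stop("'neg_sd' must be positive", call. = FALSE)
  (pos_median - neg_median) / (2 * neg_sd)
}

#' Titration points
#'
#' One row per dye concentration: sample and buffer positive counts plus
#' the population statistics the stain index needs.
#'
#' @param concentration Dye concentrations in uM (>= 0).
#' @param sample_positive_count,buffer_positive_count Counts (>= 0).
#' @param positive_median_intensity,negative_median_intensity,negative_sd
#'   Intensity statistics per concentration.
#' @return A data frame of class \code{"titration_points"}.
#' @export
titration_points <- function(concentration, sample_positive_count,
                             buffer_positive_count,
                             positive_median_intensity,
                             negative_median_intensity, negative_sd) {
  stopifnot(all(concentration >= 0), all(sample_positive_count >= 0),
            all(buffer_positive_count >= 0))
  structure(data.frame(concentration = concentration,
                       sample_positive_count = sample_positive_count,
                       buffer_positive_count = buffer_positive_count,
                       positive_median_intensity = positive_median_intensity,
                       negative_median_intensity = negative_median_intensity,
                       negative_sd = negative_sd),
            class = c("titration_points", "data.frame"))
}

#' Optimal staining concentration from a titration
#'
#' Computes the background-corrected count and stain index at every
#' concentration, then reports (i) the concentration with maximal stain
#' index (ties broken toward the lower concentration) and (ii) the plateau
#' concentration: the lowest concentration whose corrected count comes
#' within \code{plateau_fraction} of the maximum corrected count.  The
#' result is invariant to the ordering of the input rows.
#'
#' @param points A \code{\link{titration_points}} data frame (>= 2 rows).
#' @param plateau_fraction Fractional shortfall from the maximum corrected
#'   count tolerated on the plateau (default 0.1).
#' @return A list with \code{optimal_concentration},
#'   \code{plateau_concentration}, and a \code{table} of per-concentration
#'   corrected counts and stain indices.
#' @export
titration_optimum <- function(points, plateau_fraction = 0.1) {
  stopifnot(is.data.frame(points), nrow(points) >= 2L)
  points <- points[order(points$concentration), , drop = FALSE]
  corrected <- mapply(function(s, b) suppressWarnings(background_subtract(s, b)),
                      points$sample_positive_count,
                      points$buffer_positive_count)
  si <- stain_index(points$positive_median_intensity,
                    points$negative_median_intensity,
                    points$negative_sd)
  if (all(!is.finite(si))) stop("stain index undefined at every point", call. = FALSE)
  best <- which(si == max(si, na.rm = TRUE))[1L]   # ordered ascending: tie -> lower
  plateau_ok <- corrected >= (1 - plateau_fraction) * max(corrected)
  plateau <- points$concentration[which(plateau_ok)[1L]]
  list(optimal_concentration = points$concentration[best],
       plateau_concentration = plateau,
       table = data.frame(concentration = points$concentration,
                          corrected_count = corrected, stain_index = si))
}
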