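#' Bead reference descriptors
#'
#' Builds the table of scatter calibration beads: traceable polystyrene size
#' standards with certified diameter, manufacturer refractive index, and the
#' median scatter intensity measured (or simulated) on the instrument.
#'
#' @param label Character vector of bead labels.
#' @param diameter Certified diameters in nm (> 0).
#' @param ri Refractive indices at the scatter wavelength (default
#'   polystyrene, 1.61 at 405 nm).
#' @param median_intensity Median scatter intensities in instrument units
#'   (> 0).
#' @return A data frame with one row per bead population.
#' @export
bead_reference <- function(label, diameter, ri = 1.61, median_intensity) {
  df <- data.frame(label = as.character(label), diameter = diameter,
                   ri = ri, median_intensity = median_intensity,
                   stringsAsFactors = FALSE)
  if (any(df$diameter <= 0)) stop("bead diameters must be positive", call. = FALSE)
  if (any(df$median_intensity <= 0))
    stop("bead intensities must be positive", call. = FALSE)
  df
}

#' Fit a scatter calibration against Mie theory
#'
#' Scales measured bead scatter intensities onto Mie-model effective
#' cross-sections: both are log10-transformed and the offset beta of
#' log10(I) = slope * log10(sigma_eff) + beta is estimated by least squares
#' (slope fixed at 1 by default, so beta is the log10 instrument gain).  The
#' fitted mapping is then inverted through a vesicle-model cross-section
#' curve so that any in-range scatter intensity can be converted to a
#' scatter-equivalent vesicle diameter.
#'
#' @param beads A data frame from \code{\link{bead_reference}} with >= 2
#'   distinct diameters.  A subset may be excluded (e.g. beads
#'   indistinguishable from instrument background) via \code{exclude}.
#' @param optics An \code{\link{optical_config}}.
#' @param model Function mapping diameter to the vesicle
#'   \code{\link{particle_model}} used for inversion (default
#'   \code{\link{ev_default_model}}).
#' @param slope_free If \code{TRUE}, fit slope and offset (diagnostic
#'   variant); default fits the offset only.
#' @param grid Diameter grid (nm) for the inversion table; default 30 to
#'   1000 nm in 1 nm steps.
#' @param noise_floor_intensity Optional triggering threshold in scatter
#'   units; converted to a minimum resolvable diameter and reported, and
#'   intensities below it are flagged rather than silently dropped.
#' @param exclude Character vector of bead labels to leave out of the fit
#'   (recorded in the result).
#' @return An object of class \code{"scatter_calibration"} with elements
#'   \code{log_offset}, \code{slope}, \code{per_bead_residuals} (log10
#'   units), \code{r_squared}, \code{outlier} flags, \code{inversion_table},
#'   \code{monotone_prefix}, \code{noise_floor_intensity},
#'   \code{min_resolvable_diameter}, \code{beads}, and \code{excluded}.
#' @examples
#' opt <- optical_config()
#' sig <- vapply(c(80, 101, 125, 151), function(d)
#'   effective_scattering_cross_section(polystyrene_bead(d), opt)$sigma_effective,
#'   numeric(1))
#' beads <- bead_reference(c("80", "101", "125", "151"),
#'                         c(80, 101, 125, 151),
#'                         median_intensity = 10^2.5 * sig)
#' cal <- fit_scatter_calibration(beads, opt)
#' coef(cal)                          # log_offset 2.5
#' predict(cal, beads$median_intensity)
#' @export
fit_scatter_calibration <- function(beads, optics, model = ev_default_model,
                                    slope_free = FALSE,
                                    grid = seq(30, 1000, by = 1),
                                    noise_floor_intensity = NULL,
                                    exclude = NULL) {
  stopifnot(is.data.frame(beads), inherits(optics, "optical_config"))
  excluded <- character(0)
  if (!is.null(exclude)) {
    excluded <- intersect(exclude, beads$label)
    beads <- beads[!beads$label %in% exclude, , drop = FALSE]
  }
  if (any(beads$median_intensity <= 0))
    stop("bead intensities must be positive", call. = FALSE)
  if (anyDuplicated(beads$diameter)) {
    warning("beads with identical diameters collapsed to their geometric mean intensity")
    agg <- stats::aggregate(median_intensity ~ diameter + ri, data = beads,
                            FUN = function(v) exp(mean(log(v))))
    agg$label <- as.character(agg$diameter)
    beads <- agg[c("label", "diameter", "ri", "median_intensity")]
  }
  if (nrow(beads) < 2L)
    stop("need at least 2 beads with distinct diameters", call. = FALSE)

  sigma <- vapply(seq_len(nrow(beads)), function(i) {
    effective_scattering_cross_section(
      particle_model(beads$diameter[i], beads$ri[i]), optics)$sigma_effective
  }, numeric(1))
  ls <- log10(sigma)
  li <- log10(beads$median_intensity)
  if (slope_free) {
    fit <- stats::lm(li ~ ls)
    slope <- unname(stats::coef(fit)[2L])
    beta <- unname(stats::coef(fit)[1L])
    fitted <- stats::fitted(fit)
  } else {
    slope <- 1
    beta <- mean(li - ls)
    fitted <- ls + beta
  }
  res <- li - fitted
  sst <- sum((li - mean(li))^2)
  r2 <- if (sst == 0) 1 else max(0, min(1, 1 - sum(res^2) / sst))
  # outlier flags from median-centred (robust) residuals, so that one
  # grossly miscalibrated bead cannot drag the reference level towards
  # itself; 0.05 log10 units (~12% in intensity) is the minimum deviation
  # worth flagging
  res_rob <- (li - slope * ls) - stats::median(li - slope * ls)
  outlier <- vapply(seq_along(res_rob), function(i) {
    peer <- stats::median(abs(res_rob[-i]))
    abs(res_rob[i]) > 3 * peer && abs(res_rob[i]) > 0.05
  }, logical(1))

  curve <- cross_section_curve(grid, optics, model)
  prefix <- attr(curve, "monotone_prefix")
  min_d <- NA_real_
  if (!is.null(noise_floor_intensity)) {
    ls_floor <- (log10(noise_floor_intensity) - beta) / slope
    dom <- curve[seq_len(prefix), ]
    min_d <- if (ls_floor <= log10(dom$sigma[1L])) dom$diameter[1L]
             else if (ls_floor >= log10(dom$sigma[prefix])) NA_real_
             else stats::approx(log10(dom$sigma), dom$diameter,
                                xout = ls_floor)$y
  }
  structure(list(log_offset = beta, slope = slope,
                 per_bead_residuals = stats::setNames(res, beads$label),
                 r_squared = r2, outlier = stats::setNames(outlier, beads$label),
                 inversion_table = as.data.frame(curve),
                 monotone_prefix = prefix,
                 noise_floor_intensity = noise_floor_intensity,
                 min_resolvable_diameter = min_d,
                 beads = cbind(beads, sigma = sigma),
                 excluded = excluded,
                 optics = optics),
            class = "scatter_calibration")
}

#' @export
coef.scatter_calibration <- function(object, ...) {
  c(log_offset = object$log_offset, slope = object$slope)
}

#' @export
print.scatter_calibration <- function(x, ...) {
  cat("Mie scatter calibration\n")
  cat(sprintf("  log10(I) = %s * log10(sigma_eff) %+.4f   (R^2 = %.4f)\n",
              format(x$slope), x$log_offset, x$r_squared))
  cat(sprintf("  beads: %s\n",
              paste(sprintf("%s nm (res %+.3g%s)", x$beads$label,
                            x$per_bead_residuals,
                            ifelse(x$outlier, ", OUTLIER", "")),
                    collapse = "; ")))
  if (length(x$excluded))
    cat(sprintf("  excluded from fit: %s\n", paste(x$excluded, collapse = ", ")))
  dom <- x$inversion_table$diameter[c(1L, x$monotone_prefix)]
  cat(sprintf("  invertible over %g-%g nm (vesicle model)\n", dom[1L], dom[2L]))
  if (!is.na(x$min_resolvable_diameter))
    cat(sprintf("  noise floor: intensities below %g ~ diameters below %.1f nm\n",
                x$noise_floor_intensity, x$min_resolvable_diameter))
  invisible(x)
}

#' @export
summary.scatter_calibration <- function(object, ...) {
  print(object)
  invisible(object)
}

#' Convert scatter intensity to vesicle diameter
#'
#' Inverts the fitted calibration on the monotone domain of the vesicle
#' cross-section curve, by linear interpolation in log10(sigma)-diameter
#' space.  Intensities mapping below the smallest tabulated cross-section
#' (or below the noise floor, when one was supplied) are flagged
#' \code{"below_range"}; intensities above the monotone maximum are flagged
#' \code{"above_range"}; no diameter is reported for either.
#'
#' @param cal A \code{"scatter_calibration"}.
#' @param intensity Numeric vector of scatter intensities.
#' @return A data frame with columns \code{intensity}, \code{diameter} (nm,
#'   \code{NA} when out of range) and \code{flag}
#'   (\code{"ok"}/\code{"below_range"}/\code{"above_range"}).
#' @export
intensity_to_diameter <- function(intensity, cal) {
  stopifnot(inherits(cal, "scatter_calibration"))
  dom <- cal$inversion_table[seq_len(cal$monotone_prefix), ]
  lsig <- rep(NA_real_, length(intensity))
  pos <- is.finite(intensity) & intensity > 0
  lsig[pos] <- (log10(intensity[pos]) - cal$log_offset) / cal$slope
  lo <- log10(dom$sigma[1L]); hi <- log10(dom$sigma[nrow(dom)])
  flag <- rep("ok", length(intensity))
  flag[!pos | lsig < lo] <- "below_range"
  if (!is.null(cal$noise_floor_intensity))
    flag[pos & intensity < cal$noise_floor_intensity] <- "below_range"
  flag[pos & lsig > hi] <- "above_range"
  d <- rep(NA_real_, length(intensity))
  ok <- flag == "ok"
  if (any(ok))
    d[ok] <- stats::approx(log10(dom$sigma), dom$diameter, xout = lsig[ok])$y
  data.frame(intensity = intensity, diameter = d, flag = flag,
             stringsAsFactors = FALSE)
}

#' @export
#' @rdname intensity_to_diameter
#' @param object A \code{"scatter_calibration"}.
#' @param newdata Intensities to convert (vector, or data frame with an
#'   \code{intensity} column).
#' @param ... Unused.
predict.scatter_calibration <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) newdata <- newdata$intensity
  intensity_to_diameter(newdata, object)
}

#' @export
plot.scatter_calibration <- function(x, ...) {
  dom <- x$inversion_table[seq_len(x$monotone_prefix), ]
  graphics::plot(dom$diameter, x$slope * log10(dom$sigma) + x$log_offset,
                 type = "l", xlab = "diameter (nm)",
                 ylab = "log10 scatter intensity",
                 main = "Scatter calibration", ...)
  graphics::points(x$beads$diameter, log10(x$beads$median_intensity),
                   pch = 19, col = ifelse(x$outlier, "red", "black"))
  invisible(x)
}

#' Scatter-equivalent diameter of a reference particle
#'
#' Finds the diameter at which a target particle family (by default the
#' core-shell vesicle model) scatters exactly as much into the collection
#' aperture as a given reference particle -- e.g. the vesicle-model diameter
#' "equivalent" to an 80 nm polystyrene bead on a violet side-scatter
#' channel.  Root finding is bracketed on the monotone domain of the target
#' family's cross-section curve and converges to 0.1 nm.
#'
#' @param reference A \code{\link{particle_model}}.
#' @param optics An \code{\link{optical_config}}.
#' @param model Target family: function diameter -> particle model.
#' @param interval Diameter search interval in nm.
#' @param tol Root tolerance in nm (default 0.1).
#' @return The equivalent diameter in nm.
#' @examples
#' \donttest{
#' scatter_equivalent_diameter(polystyrene_bead(80), optical_config())
#' }
#' @export
scatter_equivalent_diameter <- function(reference, optics,
                                        model = ev_default_model,
                                        interval = c(30, 1000), tol = 0.1) {
  sig_ref <- effective_scattering_cross_section(reference, optics)$sigma_effective
  coarse <- cross_section_curve(seq(interval[1L], interval[2L], length.out = 50L),
                                optics, model)
  prefix <- attr(coarse, "monotone_prefix")
  dom <- coarse[seq_len(prefix), ]
  if (sig_ref < dom$sigma[1L] || sig_ref > dom$sigma[nrow(dom)])
    stop("reference cross-section not representable on the target model's monotone domain",
         call. = FALSE)
  f <- function(d)
    effective_scattering_cross_section(model(d), optics)$sigma_effective - sig_ref
  i <- findInterval(sig_ref, dom$sigma)
  lo <- dom$diameter[max(1L, i)]; hi <- dom$diameter[min(nrow(dom), i + 1L)]
  if (lo == hi) return(lo)
  stats::uniroot(f, c(lo, hi), tol = tol)$root
}
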