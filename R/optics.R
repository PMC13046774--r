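#' Optical configuration of a scatter detection channel
#'
#' Describes the illumination and collection geometry that every scattering
#' computation depends on: the vacuum wavelength of the laser, the refractive
#' index of the suspending medium, and the collection aperture over which the
#' differential scattering cross-section is integrated.  The aperture is a
#' cone centred on the detector axis; for side scatter the axis sits at a
#' polar angle of 90 degrees from the incident beam.  The integral over the
#' cone is evaluated on a tensor Gauss-Legendre grid whose default
#' 24 x 24 = 576 nodes match the collection-angle count used for
#' violet-side-scatter calibration of small-particle cytometers.
#'
#' @param wavelength Vacuum wavelength of the illuminating laser, in nm.
#'   Default 405 (violet laser).
#' @param medium_ri Refractive index of the suspending medium (real,
#'   >= 1).  Default 1.343, water at 405 nm.
#' @param aperture_center Polar angle of the detector axis measured from the
#'   incident beam direction, in degrees.  Default 90 (side scatter).
#' @param half_angle Half-angle of the collection cone, in degrees, in
#'   (0, 90].  Default 60.
#' @param n_polar,n_azimuth Number of Gauss-Legendre nodes along the polar
#'   and azimuthal directions of the aperture grid.  Defaults 24 and 24.
#' @return An object of class \code{"optical_config"}.
#' @examples
#' optical_config()                      # default 405 nm VSSC geometry
#' optical_config(half_angle = 45)      # narrower collection cone
#' @export
optical_config <- function(wavelength = 405, medium_ri = 1.343,
                           aperture_center = 90, half_angle = 60,
                           n_polar = 24, n_azimuth = 24) {
  stopifnot(is.numeric(wavelength), length(wavelength) == 1L, wavelength > 0)
  stopifnot(is.numeric(medium_ri), length(medium_ri) == 1L, medium_ri >= 1)
  if (!(half_angle > 0 && half_angle <= 90))
    stop("'half_angle' must lie in (0, 90] degrees", call. = FALSE)
  n_polar <- as.integer(n_polar); n_azimuth <- as.integer(n_azimuth)
  if (n_polar < 1L || n_azimuth < 1L)
    stop("aperture quadrature needs at least one node per direction", call. = FALSE)
  structure(
    list(wavelength = wavelength, medium_ri = medium_ri,
         aperture_center = aperture_center, half_angle = half_angle,
         n_polar = n_polar, n_azimuth = n_azimuth,
         polarization = "unpolarized"),
    class = "optical_config")
}

#' @export
print.optical_config <- function(x, ...) {
  cat("Optical configuration\n")
  cat(sprintf("  wavelength      : %g nm (vacuum)\n", x$wavelength))
  cat(sprintf("  medium RI       : %g\n", x$medium_ri))
  cat(sprintf("  aperture centre : %g deg polar, half-angle %g deg\n",
              x$aperture_center, x$half_angle))
  cat(sprintf("  quadrature      : %d x %d = %d nodes (unpolarized)\n",
              x$n_polar, x$n_azimuth, x$n_polar * x$n_azimuth))
  invisible(x)
}

#' Optical model of a spherical particle
#'
#' A particle is either a homogeneous sphere (a calibration bead) or a
#' core-shell sphere (a vesicle: aqueous lumen surrounded by a lipid
#' membrane).  Refractive indices may be complex; the imaginary part must be
#' non-negative (absorbing) and defaults to zero.
#'
#' @param diameter Outer diameter in nm (> 0).
#' @param core_ri Refractive index of the core (or of the whole sphere for a
#'   homogeneous particle).
#' @param shell_ri Refractive index of the shell, or \code{NULL} for a
#'   homogeneous sphere.
#' @param shell_thickness Shell thickness in nm, in [0, diameter/2); required
#'   (with \code{shell_ri}) for a core-shell particle.
#' @return An object of class \code{"particle_model"} with fields
#'   \code{kind} (\code{"homogeneous"} or \code{"core_shell"}),
#'   \code{diameter}, \code{core_ri}, and for coated spheres
#'   \code{shell_ri} and \code{shell_thickness}.
#' @seealso \code{\link{polystyrene_bead}}, \code{\link{ev_default_model}}
#' @examples
#' particle_model(100, 1.61)                       # polystyrene bead
#' particle_model(150, 1.38, 1.48, 5)              # vesicle, 5 nm membrane
#' @export
particle_model <- function(diameter, core_ri, shell_ri = NULL,
                           shell_thickness = NULL) {
  stopifnot(is.numeric(diameter), length(diameter) == 1L, diameter > 0)
  check_ri <- function(m, what) {
    if (length(m) != 1L || Re(m) <= 0 || Mod(m) == 0)
      stop(sprintf("non-physical %s refractive index", what), call. = FALSE)
    if (is.complex(m) && Im(m) < 0)
      stop(sprintf("%s refractive index must have non-negative imaginary part",
                   what), call. = FALSE)
    as.complex(m)
  }
  core_ri <- check_ri(core_ri, "core")
  if (is.null(shell_ri) != is.null(shell_thickness))
    stop("supply both 'shell_ri' and 'shell_thickness', or neither",
         call. = FALSE)
  if (is.null(shell_ri)) {
    structure(list(kind = "homogeneous", diameter = diameter,
                   core_ri = core_ri),
              class = "particle_model")
  } else {
    shell_ri <- check_ri(shell_ri, "shell")
    stopifnot(is.numeric(shell_thickness), length(shell_thickness) == 1L)
    if (shell_thickness < 0 || shell_thickness >= diameter / 2)
      stop("'shell_thickness' must lie in [0, diameter/2)", call. = FALSE)
    structure(list(kind = "core_shell", diameter = diameter,
                   core_ri = core_ri, shell_ri = shell_ri,
                   shell_thickness = shell_thickness),
              class = "particle_model")
  }
}

#' @export
print.particle_model <- function(x, ...) {
  fmt_ri <- function(m) if (Im(m) == 0) sprintf("%g", Re(m)) else
    sprintf("%g+%gi", Re(m), Im(m))
  if (x$kind == "homogeneous") {
    cat(sprintf("Homogeneous sphere: d = %g nm, RI = %s\n",
                x$diameter, fmt_ri(x$core_ri)))
  } else {
    cat(sprintf(
      "Core-shell sphere: d = %g nm, core RI = %s, shell RI = %s, shell %g nm\n",
      x$diameter, fmt_ri(x$core_ri), fmt_ri(x$shell_ri), x$shell_thickness))
  }
  invisible(x)
}

#' Convenience particle constructors
#'
#' \code{polystyrene_bead} builds a homogeneous polystyrene sphere
#' (default RI 1.61 at 405 nm; override with the manufacturer's value).
#' \code{ev_default_model} builds the default core-shell vesicle model used
#' for scatter-based sizing: aqueous core of RI 1.38 wrapped in a 5 nm lipid
#' shell of RI 1.48.  These defaults describe a generic small extracellular
#' vesicle and are overridable per instrument profile.
#'
#' @param diameter Outer diameter in nm.
#' @param ri Bead refractive index (polystyrene default 1.61).
#' @param core_ri,shell_ri,shell_thickness Core-shell parameters
#'   (defaults 1.38, 1.48, 5 nm).
#' @return A \code{\link{particle_model}}.
#' @export
polystyrene_bead <- function(diameter, ri = 1.61) {
  particle_model(diameter, ri)
}

#' @rdname polystyrene_bead
#' @export
ev_default_model <- function(diameter, core_ri = 1.38, shell_ri = 1.48,
                             shell_thickness = 5) {
  particle_model(diameter, core_ri, shell_ri, shell_thickness)
}
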