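# Mie scattering for homogeneous and coated spheres.
#
# Conventions: size parameter x = pi * d * n_med / lambda_vac, relative
# refractive index m = n_particle / n_med, wavenumber in the medium
# k = 2 pi n_med / lambda_vac (nm^-1).  Riccati-Bessel functions
# psi_n(z) = z j_n(z) and chi_n(z) = -z y_n(z); xi_n = psi_n - i chi_n.
# psi is computed by downward recurrence (stable for n > |z|), chi by upward
# recurrence (stable); both accept complex arguments.

# psi_0..psi_nmax and derivatives; rows 1..nmax+1 index n = 0..nmax
ricatti_psi <- function(nmax, z) {
  nstart <- nmax + max(15L, ceiling(2 * Mod(z)^(1/3)) + 15L)
  j <- complex(nstart + 2L)
  j[nstart + 2L] <- 0 + 0i
  j[nstart + 1L] <- 1e-30 + 0i
  for (n in nstart:1L) {       # j[n] holds j_{n-1}
    j[n] <- (2 * n + 1) / z * j[n + 1L] - j[n + 2L]
  }
  scale <- (sin(z) / z) / j[1L]
  jn <- j[seq_len(nmax + 1L)] * scale
  psi <- z * jn
  n <- 0:nmax
  # psi_n' = psi_{n-1} - (n/z) psi_n;  psi_{-1} = cos(z)
  dpsi <- c(cos(z), psi[seq_len(nmax)]) - n / z * psi
  list(f = psi, df = dpsi)
}

ricatti_chi <- function(nmax, z) {
  y <- complex(nmax + 1L)
  y[1L] <- -cos(z) / z
  if (nmax >= 1L) y[2L] <- -cos(z) / z^2 - sin(z) / z
  if (nmax >= 2L) for (n in 1:(nmax - 1L)) {
    y[n + 2L] <- (2 * n + 1) / z * y[n + 1L] - y[n]
  }
  chi <- -z * y
  n <- 0:nmax
  # chi_{-1} = sin(z)
  dchi <- c(sin(z), chi[seq_len(nmax)]) - n / z * chi
  list(f = chi, df = dchi)
}

# Wiscombe-style truncation on the outer size parameter
mie_nmax <- function(x) {
  max(3L, as.integer(ceiling(x + 4 * x^(1/3) + 2)))
}

# Scattering coefficients a_n, b_n (n = 1..nmax) for a homogeneous sphere
mie_ab_homogeneous <- function(m, x) {
  nmax <- mie_nmax(x)
  px  <- ricatti_psi(nmax, as.complex(x))
  cx  <- ricatti_chi(nmax, as.complex(x))
  pmx <- ricatti_psi(nmax, m * x)
  xi  <- px$f - 1i * cx$f
  dxi <- px$df - 1i * cx$df
  i <- 2:(nmax + 1L)                      # n = 1..nmax
  num_a <- m * pmx$f[i] * px$df[i] - px$f[i] * pmx$df[i]
  den_a <- m * pmx$f[i] * dxi[i]  - xi[i] * pmx$df[i]
  num_b <- pmx$f[i] * px$df[i] - m * px$f[i] * pmx$df[i]
  den_b <- pmx$f[i] * dxi[i]  - m * xi[i] * pmx$df[i]
  list(a = num_a / den_a, b = num_b / den_b, nmax = nmax)
}

# Coated sphere (Aden-Kerker): core relative index m1 and size parameter x,
# shell relative index m2, outer size parameter y.
mie_ab_coated <- function(m1, x, m2, y) {
  nmax <- mie_nmax(y)
  py   <- ricatti_psi(nmax, as.complex(y))
  cy   <- ricatti_chi(nmax, as.complex(y))
  pm2y <- ricatti_psi(nmax, m2 * y)
  cm2y <- ricatti_chi(nmax, m2 * y)
  pm1x <- ricatti_psi(nmax, m1 * x)
  pm2x <- ricatti_psi(nmax, m2 * x)
  cm2x <- ricatti_chi(nmax, m2 * x)
  xi   <- py$f - 1i * cy$f
  dxi  <- py$df - 1i * cy$df
  i <- 2:(nmax + 1L)
  A <- (m2 * pm2x$f[i] * pm1x$df[i] - m1 * pm2x$df[i] * pm1x$f[i]) /
       (m2 * cm2x$f[i] * pm1x$df[i] - m1 * cm2x$df[i] * pm1x$f[i])
  B <- (m2 * pm1x$f[i] * pm2x$df[i] - m1 * pm1x$df[i] * pm2x$f[i]) /
       (m2 * cm2x$df[i] * pm1x$f[i] - m1 * pm1x$df[i] * cm2x$f[i])
  ga  <- pm2y$f[i]  - A * cm2y$f[i]
  dga <- pm2y$df[i] - A * cm2y$df[i]
  gb  <- pm2y$f[i]  - B * cm2y$f[i]
  dgb <- pm2y$df[i] - B * cm2y$df[i]
  a <- (py$f[i] * dga - m2 * py$df[i] * ga) /
       (xi[i]  * dga - m2 * dxi[i]  * ga)
  b <- (m2 * py$f[i] * dgb - py$df[i] * gb) /
       (m2 * xi[i]  * dgb - dxi[i]  * gb)
  list(a = a, b = b, nmax = nmax)
}

#' Mie scattering coefficient series
#'
#' Computes the partial-wave scattering coefficients (a_n, b_n) of a
#' homogeneous or core-shell sphere under plane-wave illumination, truncated
#' at n_max = ceiling(x + 4 x^(1/3) + 2) where x is the outer size
#' parameter.  Coated-sphere coefficients reduce to the homogeneous-sphere
#' series when the shell has zero thickness or is index-matched to the core.
#'
#' @param particle A \code{\link{particle_model}}.
#' @param optics An \code{\link{optical_config}}.
#' @return A list of class \code{"mie_series"} with complex vectors \code{a}
#'   and \code{b}, the outer size parameter \code{x}, the truncation order
#'   \code{nmax}, and the medium wavenumber \code{k} (nm^-1).
#' @examples
#' s <- mie_series(polystyrene_bead(100), optical_config())
#' mie_qsca(s)
#' @export
mie_series <- function(particle, optics) {
  stopifnot(inherits(particle, "particle_model"),
            inherits(optics, "optical_config"))
  k <- 2 * pi * optics$medium_ri / optics$wavelength
  y <- k * particle$diameter / 2
  if (!is.finite(y)) stop("size parameter is not finite", call. = FALSE)
  m_core <- particle$core_ri / optics$medium_ri
  if (particle$kind == "homogeneous" || particle$shell_thickness == 0 ||
      (particle$kind == "core_shell" &&
       particle$shell_ri == particle$core_ri)) {
    m <- if (particle$kind == "homogeneous") m_core else {
      if (particle$shell_thickness == 0) m_core
      else particle$core_ri / optics$medium_ri
    }
    ab <- mie_ab_homogeneous(m, y)
  } else {
    m_shell <- particle$shell_ri / optics$medium_ri
    x <- k * (particle$diameter / 2 - particle$shell_thickness)
    ab <- mie_ab_coated(m_core, x, m_shell, y)
  }
  structure(list(a = ab$a, b = ab$b, x = y, nmax = ab$nmax, k = k),
            class = "mie_series")
}

#' Total scattering efficiency and cross-section from the series
#'
#' \code{mie_qsca} returns the scattering efficiency
#' Q_sca = (2/x^2) sum (2n+1)(|a_n|^2 + |b_n|^2); \code{mie_csca} the total
#' scattering cross-section C_sca = Q_sca * pi * (d/2)^2 in nm^2.
#'
#' @param series A \code{"mie_series"} object.
#' @return A single numeric value.
#' @export
mie_qsca <- function(series) {
  n <- seq_along(series$a)
  (2 / series$x^2) * sum((2 * n + 1) * (Mod(series$a)^2 + Mod(series$b)^2))
}

#' @rdname mie_qsca
#' @export
mie_csca <- function(series) {
  n <- seq_along(series$a)
  (2 * pi / series$k^2) *
    sum((2 * n + 1) * (Mod(series$a)^2 + Mod(series$b)^2))
}

# Amplitude functions S1, S2 at cos(theta) = mu (vectorised over mu).
# pi_n, tau_n by upward recurrence.
mie_S12 <- function(series, mu) {
  nmax <- length(series$a)
  nm <- length(mu)
  S1 <- complex(nm); S2 <- complex(nm)
  pi_prev <- numeric(nm)        # pi_0 = 0
  pi_cur <- rep(1, nm)          # pi_1 = 1
  for (n in seq_len(nmax)) {
    tau <- n * mu * pi_cur - (n + 1) * pi_prev
    f <- (2 * n + 1) / (n * (n + 1))
    S1 <- S1 + f * (series$a[n] * pi_cur + series$b[n] * tau)
    S2 <- S2 + f * (series$a[n] * tau + series$b[n] * pi_cur)
    pi_next <- ((2 * n + 1) * mu * pi_cur - (n + 1) * pi_prev) / n
    pi_prev <- pi_cur
    pi_cur <- pi_next
  }
  list(S1 = S1, S2 = S2)
}

# Gauss-Legendre nodes/weights on [a, b] (Golub-Welsch via symmetric eigen)
gauss_legendre <- function(n, a = -1, b = 1) {
  if (n == 1L) {
    x <- 0; w <- 2
  } else {
    i <- seq_len(n - 1L)
    beta <- i / sqrt(4 * i^2 - 1)
    J <- matrix(0, n, n)
    J[cbind(i, i + 1L)] <- beta
    J[cbind(i + 1L, i)] <- beta
    e <- eigen(J, symmetric = TRUE)
    x <- e$values
    w <- 2 * e$vectors[1L, ]^2
    o <- order(x); x <- x[o]; w <- w[o]
  }
  list(nodes = (b - a) / 2 * x + (a + b) / 2, weights = (b - a) / 2 * w)
}

# cos(scattering angle) at every aperture node, plus solid-angle weights.
# The aperture is a cone of the given half-angle about a detector axis at
# polar angle `center` from the beam; mu = cos(theta_scatter) for a node at
# cone coordinates (alpha, beta) is
#   mu = cos(alpha) cos(center) - sin(alpha) cos(beta) sin(center).
aperture_nodes <- function(optics, full_sphere = FALSE) {
  h <- if (full_sphere) pi else optics$half_angle * pi / 180
  thc <- optics$aperture_center * pi / 180
  gu <- gauss_legendre(optics$n_polar, cos(h), 1)
  gb <- gauss_legendre(optics$n_azimuth, 0, 2 * pi)
  ca <- rep(gu$nodes, times = optics$n_azimuth)
  sa <- sqrt(pmax(0, 1 - ca^2))
  cb <- rep(cos(gb$nodes), each = optics$n_polar)
  mu <- ca * cos(thc) - sa * cb * sin(thc)
  w <- as.vector(outer(gu$weights, gb$weights))
  list(mu = pmin(1, pmax(-1, mu)), weights = w)
}

#' Effective scattering cross-section over a collection aperture
#'
#' Integrates the unpolarized differential scattering cross-section
#' (|S1|^2 + |S2|^2) / (2 k^2) over the detector's collection solid angle on
#' the tensor Gauss-Legendre aperture grid of the optical configuration
#' (576 nodes by default).  This is the physical quantity a cytometer's
#' scatter intensity is proportional to.
#'
#' @param particle A \code{\link{particle_model}}.
#' @param optics An \code{\link{optical_config}}.
#' @param full_sphere If \code{TRUE}, integrate over the full 4 pi solid
#'   angle instead of the aperture cone; the result then equals the total
#'   scattering cross-section C_sca (a numerical consistency check).
#' @return An object of class \code{"scatter_result"}: a list with
#'   \code{sigma_effective} (nm^2), \code{n_terms_used}, and
#'   \code{converged} (the last series term is below 1e-14 of the series
#'   sum).
#' @examples
#' effective_scattering_cross_section(polystyrene_bead(80), optical_config())
#' @export
effective_scattering_cross_section <- function(particle, optics,
                                               full_sphere = FALSE) {
  series <- mie_series(particle, optics)
  ap <- aperture_nodes(optics, full_sphere = full_sphere)
  S <- mie_S12(series, ap$mu)
  sigma <- sum(ap$weights * (Mod(S$S1)^2 + Mod(S$S2)^2)) / (2 * series$k^2)
  n <- seq_along(series$a)
  terms <- (2 * n + 1) * (Mod(series$a)^2 + Mod(series$b)^2)
  tot <- sum(terms)
  structure(list(sigma_effective = sigma,
                 n_terms_used = series$nmax,
                 converged = tot == 0 || terms[length(terms)] <= 1e-14 * tot),
            class = "scatter_result")
}

#' @export
print.scatter_result <- function(x, ...) {
  cat(sprintf("sigma_eff = %.6g nm^2  (%d series terms%s)\n",
              x$sigma_effective, x$n_terms_used,
              if (x$converged) ", converged" else ", NOT converged"))
  invisible(x)
}

#' Effective cross-section as a function of diameter
#'
#' Tabulates sigma_eff(d) for a family of particles over a diameter grid and
#' finds the largest prefix of the grid on which sigma_eff is strictly
#' increasing -- the domain on which scatter intensity can be inverted to a
#' unique diameter.  In the sub-wavelength regime relevant to vesicles the
#' prefix covers the whole grid.
#'
#' @param diameters Strictly increasing vector of outer diameters (nm).
#' @param optics An \code{\link{optical_config}}.
#' @param model A function mapping an outer diameter to a
#'   \code{\link{particle_model}} (e.g. \code{ev_default_model} or
#'   \code{polystyrene_bead}).
#' @return A data frame with columns \code{diameter} and \code{sigma}, with
#'   attribute \code{"monotone_prefix"} giving the length of the strictly
#'   increasing prefix.
#' @export
cross_section_curve <- function(diameters, optics, model = ev_default_model) {
  if (length(diameters) == 0L) stop("empty diameter grid", call. = FALSE)
  if (any(diff(diameters) <= 0))
    stop("'diameters' must be strictly increasing", call. = FALSE)
  ap <- aperture_nodes(optics)
  sigma <- vapply(diameters, function(d) {
    series <- mie_series(model(d), optics)
    S <- mie_S12(series, ap$mu)
    sum(ap$weights * (Mod(S$S1)^2 + Mod(S$S2)^2)) / (2 * series$k^2)
  }, numeric(1))
  mono <- which(diff(sigma) <= 0)
  prefix <- if (length(mono) == 0L) length(sigma) else mono[1L]
  structure(data.frame(diameter = diameters, sigma = sigma),
            monotone_prefix = prefix)
}
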