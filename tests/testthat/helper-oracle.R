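# Independent Mie oracle for real refractive indices, built on base R
# half-integer Bessel functions and the logarithmic-derivative formulation
# -- a different numerical path (and formulation) from the package's
# downward-recurrence Riccati-Bessel implementation.

oracle_psi <- function(n, z) sqrt(pi * z / 2) * besselJ(z, n + 0.5)
oracle_chi <- function(n, z) -sqrt(pi * z / 2) * besselY(z, n + 0.5)

oracle_mie_ab <- function(m, x) {
  nmax <- ceiling(x + 4 * x^(1/3) + 2)
  n <- seq_len(nmax)
  psi <- oracle_psi(n, x)
  psi0 <- oracle_psi(n - 1, x)
  chi <- oracle_chi(n, x)
  chi0 <- oracle_chi(n - 1, x)
  xi <- psi - 1i * chi
  xi0 <- psi0 - 1i * chi0
  # log-derivative of psi at mx from Bessel values directly
  D <- oracle_psi(n - 1, m * x) / oracle_psi(n, m * x) - n / (m * x)
  a <- ((D / m + n / x) * psi - psi0) / ((D / m + n / x) * xi - xi0)
  b <- ((D * m + n / x) * psi - psi0) / ((D * m + n / x) * xi - xi0)
  list(a = a, b = b)
}

oracle_qsca <- function(diameter, ri, wavelength = 405, medium_ri = 1.343) {
  x <- pi * diameter * medium_ri / wavelength
  ab <- oracle_mie_ab(ri / medium_ri, x)
  n <- seq_along(ab$a)
  (2 / x^2) * sum((2 * n + 1) * (Mod(ab$a)^2 + Mod(ab$b)^2))
}

# binomial 95% CI half-width check helper
within_binomial_ci <- function(observed_fraction, true_fraction, n) {
  half <- 1.96 * sqrt(true_fraction * (1 - true_fraction) / n)
  abs(observed_fraction - true_fraction) <= half
}
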