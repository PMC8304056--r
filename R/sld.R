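#' SLD values
#'
#' A scattering-length density with a real and a (non-negative) imaginary
#' part, both in 1/Angstrom^2.  Neutron SLDs of hydrogenous materials are
#' often negative; the imaginary part (absorption) defaults to zero.
#'
#' @param real Real part, 1/Angstrom^2.
#' @param imag Imaginary part, 1/Angstrom^2, >= 0.
#' @return An object of class `sld_value`.
#' @export
sld_value <- function(real, imag = 0) {
  stopifnot(is.numeric(real), length(real) == 1L, is.finite(real))
  if (imag < 0) stop("imaginary SLD must be >= 0")
  structure(list(real = real, imag = imag), class = "sld_value")
}

as_sld <- function(x) {
  if (inherits(x, "sld_value")) return(x)
  sld_value(as.numeric(x))
}

sld_complex <- function(x) {
  x <- as_sld(x)
  complex(real = x$real, imaginary = x$imag)
}

#' @export
print.sld_value <- function(x, ...) {
  cat(sprintf("SLD: %.4f %+.4fi x 1e-6/A^2\n", x$real * 1e6, x$imag * 1e6))
  invisible(x)
}

#' Define a material by formula and mass density
#'
#' @param formula Named numeric vector of isotope counts per formula unit,
#'   e.g. `c(H = 2, O = 1)` for water or `c(Si = 1)` for silicon.
#' @param mass_density Mass density in g/cm^3.
#' @return An object of class `material` with the derived molar mass (g/mol)
#'   and formula-unit number density (1/Angstrom^3).
#' @export
#' @examples
#' material(c(H = 2, O = 1), 0.997)
material <- function(formula, mass_density) {
  stopifnot(is.numeric(formula), length(formula) >= 1L,
            !is.null(names(formula)), all(nzchar(names(formula))))
  if (any(formula <= 0)) stop("formula counts must be > 0")
  if (!is.numeric(mass_density) || length(mass_density) != 1L ||
      !is.finite(mass_density) || mass_density <= 0)
    stop("mass_density must be a single positive number (g/cm^3)")
  rows <- isotope_row(names(formula))
  molar_mass <- sum(formula * rows$mass_amu)
  # g/cm^3 -> formula units per A^3:  rho/M * N_A * 1e-24
  n_fu <- mass_density / molar_mass * AVOGADRO * 1e-24
  structure(list(formula = formula, mass_density = mass_density,
                 molar_mass = molar_mass, number_density = n_fu),
            class = "material")
}

#' @export
print.material <- function(x, ...) {
  cat("Material:", paste0(names(x$formula), ifelse(x$formula == 1, "",
                                                   x$formula), collapse = ""),
      sprintf("| %.4g g/cm^3 | M = %.3f g/mol | n = %.5g /A^3\n",
              x$mass_density, x$molar_mass, x$number_density))
  invisible(x)
}

#' Scattering-length density of a material
#'
#' Neutron branch: rho = n_fu * sum_j b_j with b_j the coherent scattering
#' lengths of the formula.  X-ray branch: rho = n_fu * r0 * sum_j Z_j, i.e.
#' the Thomson scattering length times the electron count (f1 = Z, f2 = 0;
#' no anomalous dispersion).
#'
#' @param mat A [material()].
#' @param probe `"neutron"` or `"xray"`.
#' @param table Isotope table.
#' @return An [sld_value()] in 1/Angstrom^2.
#' @export
#' @examples
#' material_sld(material(c(H = 2, O = 1), 0.997))   # about -0.56e-6
material_sld <- function(mat, probe = c("neutron", "xray"),
                         table = isotope_table()) {
  stopifnot(inherits(mat, "material"))
  probe <- match.arg(probe)
  rows <- isotope_row(names(mat$formula), table)
  b_sum_fm <- switch(probe,
    neutron = sum(mat$formula * rows$b_coh_fm),
    xray    = sum(mat$formula * rows$Z) * R_ELECTRON_FM)
  sld_value(mat$number_density * b_sum_fm * FM_TO_ANGSTROM)
}

#' Linear solvent mixing of two SLDs
#'
#' Volume-fraction mixing, e.g. of H2O and D2O, applied component-wise to
#' real and imaginary parts.
#'
#' @param sld_a,sld_b Endpoint SLDs (`sld_value` or bare numbers, 1/A^2).
#' @param fraction_b Volume fraction of component b, in \[0, 1\].
#' @return An [sld_value()].
#' @export
mix_solvent_sld <- function(sld_a, sld_b, fraction_b) {
  if (!is.numeric(fraction_b) || length(fraction_b) != 1L ||
      fraction_b < 0 || fraction_b > 1)
    stop("fraction_b must lie in [0, 1]")
  a <- as_sld(sld_a); b <- as_sld(sld_b)
  sld_value((1 - fraction_b) * a$real + fraction_b * b$real,
            (1 - fraction_b) * a$imag + fraction_b * b$imag)
}

#' Solve for the match-point mixing fraction
#'
#' Inverts [mix_solvent_sld()]: finds the fraction of component b whose
#' mixture SLD equals `sld_target` (real parts).  A solution outside
#' \[0, 1\] is clipped and flagged with a warning — the target is then not
#' reachable by mixing the two endpoints.
#'
#' @param sld_target Target SLD to match.
#' @param sld_a,sld_b Endpoint SLDs.
#' @return Fraction of component b (single number in \[0, 1\]).
#' @export
#' @examples
#' # silicon-matched water from the H2O/D2O endpoints:
#' solve_match_fraction(2.07e-6, -0.56e-6, 6.35e-6) # about 0.38
solve_match_fraction <- function(sld_target, sld_a, sld_b) {
  ta <- as_sld(sld_a)$real; tb <- as_sld(sld_b)$real
  tt <- as_sld(sld_target)$real
  if (ta == tb) stop("endpoint SLDs are equal: no mixing fraction exists")
  f <- (tt - ta) / (tb - ta)
  if (f < 0 || f > 1) {
    warning(sprintf(
      "match fraction %.3f outside [0, 1]; clipped (target not reachable)", f))
    f <- min(max(f, 0), 1)
  }
  f
}

#' Refractive index of a medium
#'
#' n = 1 - lambda^2 rho / (2 pi).  For negative-SLD media (e.g. H2O for
#' neutrons) n exceeds 1.
#'
#' @param sld SLD of the medium (real part used).
#' @param wavelength Wavelength in Angstrom, > 0.
#' @return Dimensionless refractive index.
#' @export
refractive_index <- function(sld, wavelength) {
  if (!is.numeric(wavelength) || any(wavelength <= 0))
    stop("wavelength must be > 0")
  1 - wavelength^2 * as_sld(sld)$real / (2 * pi)
}

#' Critical momentum transfer of an interface
#'
#' Q below which total external reflection occurs when the beam travels in
#' the fronting medium and reflects off a backing of higher SLD:
#' Qc = sqrt(16 pi (rho_backing - rho_fronting)).  If the backing SLD does
#' not exceed the fronting SLD there is no total reflection and Qc = 0.
#'
#' @param sld_fronting,sld_backing SLDs of the incidence and reflection
#'   media (real parts used).
#' @return Qc in 1/Angstrom.
#' @export
#' @examples
#' critical_q(2.07e-6, 6.35e-6) # Si against D2O, about 0.0147
critical_q <- function(sld_fronting, sld_backing) {
  drho <- as_sld(sld_backing)$real - as_sld(sld_fronting)$real
  if (drho <= 0) return(0)
  sqrt(16 * pi * drho)
}
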