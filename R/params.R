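# Physical constants (SI)
.k_boltzmann <- 1.380649e-23   # J/K
.e_charge    <- 1.602176634e-19 # C

#' Thermal energy
#'
#' @param T temperature in kelvin.
#' @return kT in joules.
#' @keywords internal
kT_joule <- function(T = 298.15) .k_boltzmann * T

#' Thermal voltage kT/e
#'
#' @param T temperature in kelvin.
#' @return kT/e in volts (25.693 mV at 298.15 K).
#' @export
thermal_voltage <- function(T = 298.15) kT_joule(T) / .e_charge

#' Electrostatic (self-energy) parameters of the pore
#'
#' The pore is approximated as a capacitor holding the fixed protein
#' charge plus the conducting ions, so the electrostatic energy of an
#' n-ion state is `Uc * (nf + z*n)^2`.  `Uc = e^2 / 2C` is the charging
#' energy set by the pore capacitance `C`.
#'
#' @param Uc self-energy per squared unit charge, in kT.  Must be >= 0.
#' @param nf effective fixed pore charge in units of e; may be
#'   non-integer (partial charges, protonation).
#' @param z ionic valence of the permeant species (default +1).
#' @return an object of class `energy_params`.
#' @export
energy_params <- function(Uc = 10, nf = -2.5, z = 1) {
  stopifnot(is.numeric(Uc), length(Uc) == 1L, is.finite(Uc),
            is.numeric(nf), length(nf) == 1L, is.finite(nf),
            is.numeric(z), length(z) == 1L, is.finite(z))
  if (Uc < 0) stop("'Uc' must be non-negative")
  if (z == 0) stop("'z' must be non-zero")
  structure(list(Uc = Uc, nf = nf, z = z), class = "energy_params")
}

#' Per-site binding parameters
#'
#' @param dmu excess chemical potential differences (bulk minus site) in
#'   kT, one per binding site, ordered from the intracellular side.
#'   Larger values mean deeper (more attractive) sites.
#' @param D site diffusivities in m^2/s; recycled to the length of
#'   `dmu`.  Default is a tenth of the bulk Na+ diffusivity.
#' @return an object of class `site_params`.
#' @export
site_params <- function(dmu = c(2.3, 3.4, 2.8, 2.4), D = 1.33e-10) {
  stopifnot(is.numeric(dmu), length(dmu) >= 1L, all(is.finite(dmu)),
            is.numeric(D), all(is.finite(D)))
  D <- rep_len(D, length(dmu))
  if (any(D <= 0)) stop("site diffusivities 'D' must be positive")
  structure(list(dmu = as.numeric(dmu), D = as.numeric(D)),
            class = "site_params")
}

#' Bulk reservoir state
#'
#' @param c solute (permeant ion) concentration in mol/L.
#' @param cw solvent concentration in mol/L (water, ~55.5 M); the mole
#'   fraction entering the ensemble is `x = c/cw`.
#' @param T temperature in kelvin.
#' @param phi reference electric potential in volts.
#' @param mu0_excess bulk excess chemical potential reference in kT.
#' @return an object of class `bath_state`.
#' @export
bath_state <- function(c = 0.14, cw = 55.5, T = 298.15, phi = 0,
                       mu0_excess = 0) {
  stopifnot(is.numeric(c), length(c) == 1L, is.finite(c),
            is.numeric(cw), length(cw) == 1L, is.finite(cw),
            is.numeric(T), length(T) == 1L, is.finite(T))
  if (c <= 0) stop("solute concentration 'c' must be positive")
  if (cw <= 0) stop("solvent concentration 'cw' must be positive")
  if (c >= cw) stop("'c' must be well below the solvent concentration 'cw'")
  if (T <= 0) stop("temperature 'T' must be positive")
  structure(list(c = c, cw = cw, T = T, phi = phi,
                 mu0_excess = mu0_excess),
            class = "bath_state")
}

#' Binding-site geometry of the selectivity filter
#'
#' Defaults are the spheroidal estimates for the four Na+ binding sites
#' of the NaChBac filter (S1-S4, intra- to extracellular), with a total
#' filter length of ~12 Angstrom.
#'
#' @param radius site radii in Angstrom.
#' @param length site lengths in Angstrom.
#' @param area site surface areas in Angstrom^2.
#' @param volume site volumes in Angstrom^3.
#' @param Lc total filter length in Angstrom.
#' @return an object of class `pore_geometry`.
#' @export
pore_geometry <- function(radius = c(3.06, 2.77, 2.75, 2.77),
                          length = c(3, 4, 3, 2),
                          area = c(116, 126, 90, 78),
                          volume = c(117, 129, 80, 63),
                          Lc = 12) {
  n <- unique(c(length(radius), length(length), length(area),
                length(volume)))
  if (length(n) != 1L)
    stop("geometry vectors must have equal length")
  vals <- c(radius, length, area, volume, Lc)
  if (!all(is.finite(vals)) || any(vals <= 0))
    stop("geometry values must be positive and finite")
  structure(list(radius = as.numeric(radius),
                 length = as.numeric(length),
                 area = as.numeric(area),
                 volume = as.numeric(volume),
                 Lc = Lc),
            class = "pore_geometry")
}

#' Electrochemical driving forces across the pore
#'
#' @param dphi applied potential difference in volts (side L,
#'   intracellular, minus side R).
#' @param deta chemical gradient in kT, `deta = ln(xL/xR)`.
#' @param dc concentration difference in mol/L (informational).
#' @param nu_bar mean voltage-drop fraction to reach a site from the
#'   bulk; 1/2 for a symmetrically distributed pore.
#' @param T temperature in kelvin, used to convert `deta` to volts.
#' @return an object of class `driving_forces`.
#' @export
driving_forces <- function(dphi = 0, deta = 0, dc = 0, nu_bar = 0.5,
                           T = 298.15) {
  stopifnot(is.numeric(dphi), is.numeric(deta), is.numeric(nu_bar))
  if (nu_bar <= 0 || nu_bar >= 1) stop("'nu_bar' must lie in (0, 1)")
  structure(list(dphi = dphi, deta = deta, dc = dc, nu_bar = nu_bar,
                 T = T),
            class = "driving_forces")
}

#' Fitted NaChBac parameter set
#'
#' Canonical defaults of the package: the four-site excess chemical
#' potentials, self-energy, effective fixed charge and pore diffusivity
#' for wild-type NaChBac, together with the site geometry.
#'
#' @return a list with elements `energy`, `sites`, `geometry` and
#'   `bath` (a 0.14 M reference bath).
#' @export
nachbac_params <- function() {
  list(energy = energy_params(Uc = 10, nf = -2.5, z = 1),
       sites = site_params(dmu = c(2.3, 3.4, 2.8, 2.4), D = 1.33e-10),
       geometry = pore_geometry(),
       bath = bath_state(c = 0.14))
}
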