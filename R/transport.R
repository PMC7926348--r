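# Linear-response transport: susceptibilities to electrochemical
# gradients, per-site conductivities via the Einstein relation, and the
# series current through the pore.

#' Mole fraction of the solute
#'
#' @param c solute concentration (mol/L).
#' @param cw solvent concentration (mol/L).
#' @return dimensionless mole fraction `c/cw`.
#' @export
mole_fraction <- function(c, cw = 55.5) {
  if (any(c <= 0) || any(cw <= 0))
    stop("concentrations must be positive")
  c / cw
}

#' Chemical gradient between two baths
#'
#' `deta = ln(xL/xR)` in kT.  Concentrations below `clamp` are raised
#' to it before taking the log, so that a nominally ion-free bath
#' yields a finite gradient.
#'
#' @param cL,cR left (intracellular) and right (extracellular) bath
#'   concentrations, mol/L.
#' @param clamp lower concentration limit in mol/L (default 0.1 mM).
#' @return chemical gradient in kT.
#' @examples
#' chemical_gradient(0.020, 0.0001)  # ~5.3 kT
#' @export
chemical_gradient <- function(cL, cR, clamp = 1e-4) {
  if (any(cL < 0) || any(cR < 0)) stop("concentrations must be non-negative")
  if (clamp <= 0 && (any(cL == 0) || any(cR == 0)))
    stop("'clamp' must be positive when a concentration is zero")
  log(pmax(cL, clamp) / pmax(cR, clamp))
}

#' Site susceptibilities to electrochemical gradients
#'
#' The response of the mean site density to a small chemical gradient
#' is set by the occupancy fluctuations:
#' `chi_m = Cov(n_m, N) / (2 kT V_m)` with `N` the total ion count.
#' The electrical susceptibility is the same quantity scaled by twice
#' the mean voltage-drop fraction `nu_bar`, hence equal to the chemical
#' one for a symmetrically distributed pore (`nu_bar = 1/2`).
#'
#' @param ens a [solve_ensemble()] result.
#' @param geom a [pore_geometry()] object (volumes in Angstrom^3).
#' @param nu_bar mean voltage-drop fraction (default 1/2).
#' @return a list with `chi_eta` and `chi_phi`, per-site
#'   susceptibilities in SI units 1/(J m^3), and `cov_nN`, the raw
#'   covariances Cov(n_m, N).
#' @export
susceptibilities <- function(ens, geom, nu_bar = 0.5) {
  stopifnot(inherits(ens, "pore_ensemble"), inherits(geom, "pore_geometry"))
  m <- length(ens$occupancy)
  if (length(geom$volume) != m)
    stop("geometry must provide one volume per site")
  if (any(geom$volume <= 0)) stop("site volumes must be positive")
  cov_nN <- rowSums(ens$covariance)
  kT <- kT_joule(ens$bath$T)
  V <- geom$volume * 1e-30                 # Angstrom^3 -> m^3
  chi_eta <- cov_nN / (2 * kT * V)
  chi_phi <- 2 * nu_bar * chi_eta
  list(chi_eta = chi_eta, chi_phi = chi_phi, cov_nN = cov_nN)
}

#' Finite-difference susceptibility (independent oracle)
#'
#' Numerically differentiates the mean site density of the perturbed
#' ensemble with respect to the chemical gradient (or the dimensionless
#' electrical drive `e*dphi/kT`).  Under a symmetric perturbation of
#' the two baths, each occupied site picks up half of the applied
#' gradient (`nu_bar` of it for the electrical drive), so the central
#' difference converges to the closed-form susceptibility at second
#' order in the step.
#'
#' @inheritParams configuration_free_energy
#' @param geom a [pore_geometry()] object.
#' @param which `"eta"` (chemical) or `"phi"` (electrical).
#' @param step finite-difference step in kT (default 1e-4).
#' @param nu_bar mean voltage-drop fraction for `which = "phi"`.
#' @return per-site susceptibilities in SI units 1/(J m^3).
#' @export
finite_difference_susceptibility <- function(ep, sp, bath, geom,
                                             which = c("eta", "phi"),
                                             step = 1e-4, nu_bar = 0.5) {
  which <- match.arg(which)
  if (!is.numeric(step) || step <= 0) stop("'step' must be positive")
  frac <- if (which == "eta") 0.5 else nu_bar
  occ_at <- function(delta) {
    sp_pert <- sp
    sp_pert$dmu <- sp$dmu + frac * delta
    solve_ensemble(ep, sp_pert, bath)$occupancy
  }
  d_occ <- (occ_at(step) - occ_at(-step)) / (2 * step)
  kT <- kT_joule(bath$T)
  V <- geom$volume * 1e-30
  unname(d_occ) / (kT * V)
}

#' Per-site electrical conductivity
#'
#' Generalised Einstein relation: `sigma_m = (z e)^2 D_m chi_m`, with
#' `chi_m` the mean of the electrical and chemical susceptibilities
#' (identical for `nu_bar = 1/2`).
#'
#' @param chi_eta,chi_phi per-site susceptibilities in 1/(J m^3).
#' @param sp a [site_params()] object (diffusivities in m^2/s).
#' @param z ionic valence.
#' @return per-site conductivities in S/m.  If any susceptibility is
#'   negative the result carries attribute `negative_chi = TRUE`.
#' @export
site_conductivity <- function(chi_eta, chi_phi = chi_eta, sp, z = 1) {
  stopifnot(inherits(sp, "site_params"))
  chi <- (chi_eta + chi_phi) / 2
  sigma <- (z * .e_charge)^2 * sp$D * chi
  if (any(chi < 0)) attr(sigma, "negative_chi") <- TRUE
  sigma
}

#' Series current through the pore
#'
#' The sites act as resistors in series: `R_total = sum(L_m/(A_m
#' sigma_m))`, and the current is the total electrochemical driving
#' force divided by that resistance,
#' `I = (dphi + deta * kT/e) / R_total`.  Positive current flows from
#' the intracellular (L) to the extracellular (R) side.
#'
#' @param sigma per-site conductivities (S/m).
#' @param geom a [pore_geometry()] object (lengths in Angstrom, areas
#'   in Angstrom^2).
#' @param forces a [driving_forces()] object.
#' @return current in amperes, with attributes `R_total` (ohm) and, if
#'   any site is non-conducting, `blocked = TRUE` (current 0: one
#'   blocked site interrupts the series path).
#' @export
pore_current <- function(sigma, geom, forces) {
  stopifnot(inherits(geom, "pore_geometry"),
            inherits(forces, "driving_forces"))
  if (any(sigma <= 0)) {
    out <- 0
    attr(out, "blocked") <- TRUE
    attr(out, "R_total") <- Inf
    return(out)
  }
  L <- geom$length * 1e-10                 # Angstrom  -> m
  A <- geom$area * 1e-20                   # Angstrom^2 -> m^2
  R_total <- sum(L / (A * sigma))
  drive <- forces$dphi + forces$deta * thermal_voltage(forces$T)
  out <- drive / R_total
  attr(out, "R_total") <- R_total
  out
}

#' Reversal potential of a single permeant species
#'
#' Applied potential (side L minus side R) at which the net current
#' vanishes, i.e. where the electrical drive cancels the chemical
#' gradient: `phi_rev = -(kT/e) ln(xL/xR)`, Nernstian in the clamped
#' concentrations.
#'
#' @inheritParams chemical_gradient
#' @param T temperature in kelvin.
#' @return reversal potential in volts.
#' @examples
#' reversal_potential(0.020, 0.0001)  # ~ -0.136 V
#' @export
reversal_potential <- function(cL, cR, clamp = 1e-4, T = 298.15) {
  -thermal_voltage(T) * chemical_gradient(cL, cR, clamp)
}

#' Free-energy barriers to enter each site
#'
#' Free-energy change, in kT, for the `(from_n + 1)`-th ion to enter
#' site m of a pore already holding `from_n` ions (any sites: the
#' electrostatic and combinatorial terms depend only on the count):
#' `dG_m = E(n+1) - E(n) - ln x - dmu_m + ln((n+1)!(M-n-1)!) -
#' ln(n!(M-n)!)`.
#'
#' @inheritParams configuration_free_energy
#' @param from_n number of ions already resident (0 to M-1).
#' @return per-site entry barriers in kT.
#' @examples
#' p <- nachbac_params()
#' entry_barriers(p$energy, p$sites, p$bath, from_n = 2)
#' @export
entry_barriers <- function(ep, sp, bath, from_n = 2) {
  m <- length(sp$dmu)
  if (!is.numeric(from_n) || from_n != round(from_n) ||
      from_n < 0 || from_n > m - 1)
    stop(sprintf("'from_n' must be an integer in [0, %d] (pore not full)",
                 m - 1))
  x <- bath$c / bath$cw
  dE <- electrostatic_energy(from_n + 1, ep) -
        electrostatic_energy(from_n, ep)
  comb <- lfactorial(from_n + 1) + lfactorial(m - from_n - 1) -
          lfactorial(from_n) - lfactorial(m - from_n)
  unname(dE - log(x) - sp$dmu + comb)
}

#' Resonant fixed charge for the n -> n+1 transition
#'
#' Solves for the effective fixed charge `nf` at which the
#' minimum-free-energy n-ion and (n+1)-ion configurations are
#' degenerate (a barrier-less, resonant conduction point of ionic
#' Coulomb blockade).  The minimum-energy n-ion state occupies the n
#' deepest sites (largest dmu).  Because the self-energy is quadratic
#' in `nf` with equal curvature for all n, the crossing is linear in
#' `nf` and solved in closed form.
#'
#' @inheritParams configuration_free_energy
#' @param n_lo ion count of the lower level (0 to M-1).
#' @return resonant charge `nf*` in units of e.
#' @examples
#' p <- nachbac_params()
#' resonance_charge(p$energy, p$sites, p$bath, n_lo = 2)  # ~ -2.70
#' @export
resonance_charge <- function(ep, sp, bath, n_lo = 2) {
  m <- length(sp$dmu)
  if (!is.numeric(n_lo) || n_lo != round(n_lo) || n_lo < 0 || n_lo > m - 1)
    stop(sprintf("'n_lo' must be an integer in [0, %d]", m - 1))
  if (ep$Uc == 0)
    stop("resonant charge is undefined for Uc = 0 (levels never cross)")
  x <- bath$c / bath$cw
  dmu_sorted <- sort(sp$dmu, decreasing = TRUE)
  dmu_added <- dmu_sorted[n_lo + 1]        # site gained by the upper level
  comb <- lfactorial(n_lo + 1) + lfactorial(m - n_lo - 1) -
          lfactorial(n_lo) - lfactorial(m - n_lo)
  b <- -log(x) - dmu_added + comb          # non-electrostatic barrier part
  z <- ep$z
  # Uc*(2 z nf + z^2 (2 n_lo + 1)) + b = 0
  -(z * (2 * n_lo + 1)) / 2 - b / (2 * z * ep$Uc)
}

#' Barrier-less (diffusion-limited) transit rate
#'
#' The rate scale for an ion diffusing the full filter length with no
#' barrier: `rate = D / Lc^2`.
#'
#' @param D diffusivity in m^2/s.
#' @param Lc filter length in Angstrom.
#' @return transit rate in ions/s.
#' @examples
#' diffusion_limited_rate(1.33e-10, 12)  # ~0.9e8 ions/s
#' @export
diffusion_limited_rate <- function(D = 1.33e-10, Lc = 12) {
  if (any(D <= 0) || any(Lc <= 0)) stop("'D' and 'Lc' must be positive")
  D / (Lc * 1e-10)^2
}

#' Current for a fully specified pore and pair of baths
#'
#' Convenience wrapper composing the ensemble, susceptibilities,
#' conductivities and series current.  The equilibrium ensemble for an
#' asymmetric pair of baths is built at the mean of the two bulk
#' concentrations.
#'
#' @inheritParams configuration_free_energy
#' @param geom a [pore_geometry()] object.
#' @param cL,cR left/right bath concentrations in mol/L (clamped below
#'   at `clamp`).
#' @param dphi applied potential (V).
#' @param clamp lower concentration limit (mol/L).
#' @param cw solvent concentration (mol/L).
#' @param T temperature (K).
#' @return current in amperes (attributes as in [pore_current()]).
#' @export
steady_current <- function(ep, sp, geom, cL, cR = cL, dphi = 0,
                           clamp = 1e-4, cw = 55.5, T = 298.15) {
  cL <- max(cL, clamp); cR <- max(cR, clamp)
  bath <- bath_state(c = (cL + cR) / 2, cw = cw, T = T)
  ens <- solve_ensemble(ep, sp, bath)
  chi <- susceptibilities(ens, geom)
  sigma <- site_conductivity(chi$chi_eta, chi$chi_phi, sp, z = ep$z)
  forces <- driving_forces(dphi = dphi,
                           deta = chemical_gradient(cL, cR, clamp),
                           nu_bar = 0.5, T = T)
  pore_current(sigma, geom, forces)
}
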