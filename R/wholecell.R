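# Whole-cell comparison pipeline: normalized IV series over bath
# compositions, effective open probability, current-concentration
# curves.

#' Theoretical whole-cell IV series over a set of bath compositions
#'
#' For each bath concentration and voltage, the equilibrium ensemble
#' is built at the mean of the pipette and (clamped) bath
#' concentrations, the linear-response current computed, and the whole
#' series normalized by the reference current magnitude at -10 mV with
#' a 0.14 M bath (the experimental peak-current convention).
#'
#' @param baths bath (extracellular) Na+ concentrations, mol/L; must
#'   include the 0.14 M reference member.  Zero entries are clamped to
#'   `clamp`.
#' @param pipette pipette (intracellular) Na+ concentration, mol/L.
#' @param ep,sp,geom model parameters ([energy_params()],
#'   [site_params()], [pore_geometry()]).
#' @param voltages applied potentials in volts; must include -10 mV
#'   (within `v_tol`).
#' @param clamp lower concentration limit, mol/L.
#' @param cw,T solvent concentration (mol/L) and temperature (K).
#' @param normalize `"abs"` divides by the absolute reference value
#'   (signed currents keep their sign); `"signed"` divides by the
#'   signed reference.
#' @param v_tol voltage matching tolerance (V).
#' @return a data.frame of class `wholecell_iv` with columns
#'   `bath_Na`, `pipette_Na` (mol/L), `voltage` (V), `current` (A),
#'   `normalized_current`, `deta` (kT) and `phi_rev` (V).
#' @export
wholecell_iv_series <- function(baths, pipette = 0.020,
                                ep = energy_params(),
                                sp = site_params(),
                                geom = pore_geometry(),
                                voltages = seq(-0.100, 0.060, by = 0.010),
                                clamp = 1e-4, cw = 55.5, T = 298.15,
                                normalize = c("abs", "signed"),
                                v_tol = 5e-4) {
  normalize <- match.arg(normalize)
  if (length(baths) == 0 || length(voltages) == 0)
    stop("'baths' and 'voltages' must be non-empty")
  if (!any(abs(baths - 0.14) < 1e-9))
    stop("bath series must include the 0.14 M reference member")
  if (!any(abs(voltages - (-0.010)) < v_tol))
    stop("voltage grid must include the -10 mV reference point")
  grid <- expand.grid(voltage = voltages, bath_Na = baths,
                      KEEP.OUT.ATTRS = FALSE)
  cur <- mapply(function(b, v) {
    as.numeric(steady_current(ep, sp, geom, cL = pipette, cR = b,
                              dphi = v, clamp = clamp, cw = cw, T = T))
  }, grid$bath_Na, grid$voltage)
  ref_idx <- which(abs(grid$bath_Na - 0.14) < 1e-9 &
                     abs(grid$voltage - (-0.010)) < v_tol)[1]
  ref <- cur[ref_idx]
  if (normalize == "abs") ref <- abs(ref)
  out <- data.frame(bath_Na = grid$bath_Na, pipette_Na = pipette,
                    voltage = grid$voltage, current = cur,
                    normalized_current = cur / ref,
                    deta = chemical_gradient(pipette, grid$bath_Na,
                                             clamp),
                    phi_rev = reversal_potential(pipette, grid$bath_Na,
                                                 clamp, T))
  class(out) <- c("wholecell_iv", "data.frame")
  attr(out, "reference_current") <- cur[ref_idx]
  out
}

#' Effective open probability from experiment/theory current ratios
#'
#' Elementwise ratio of experimental to theoretical current on a
#' matched (bath, voltage) grid, relative to the (unknown) open
#' probability at peak current: `p_open = p_eff * p_max`.  Entries
#' where the theoretical current magnitude falls below `floor` are
#' masked (NA) rather than divided.  Sign-discordant points yield
#' negative `p_eff` and are reported, not clipped.
#'
#' @param I_exp,I_theory data.frames with columns `bath_Na`, `voltage`
#'   and a current column (`normalized_current` if present, else
#'   `current`), on identical grids (voltage matched within `v_tol`).
#' @param floor masking threshold on the theoretical current, in the
#'   units of the current column (default 1e-3 pA = 1e-15 A on raw
#'   currents).
#' @param v_tol voltage matching tolerance (V).
#' @return a data.frame of class `gating_estimate` with columns
#'   `bath_Na`, `voltage`, `I_exp`, `I_theory`, `p_eff`.
#' @export
effective_open_probability <- function(I_exp, I_theory, floor = 1e-15,
                                       v_tol = 5e-4) {
  col <- function(d) {
    if ("normalized_current" %in% names(d)) d$normalized_current
    else if ("current" %in% names(d)) d$current
    else stop("current column not found")
  }
  if (nrow(I_exp) != nrow(I_theory))
    stop("experimental and theoretical grids differ in size")
  o1 <- order(I_exp$bath_Na, I_exp$voltage)
  o2 <- order(I_theory$bath_Na, I_theory$voltage)
  e <- I_exp[o1, ]; t <- I_theory[o2, ]
  if (any(abs(e$bath_Na - t$bath_Na) > 1e-9) ||
      any(abs(e$voltage - t$voltage) > v_tol))
    stop("experimental and theoretical grids do not match")
  ie <- col(e); it <- col(t)
  p_eff <- ifelse(abs(it) < floor, NA_real_, ie / it)
  out <- data.frame(bath_Na = t$bath_Na, voltage = t$voltage,
                    I_exp = ie, I_theory = it, p_eff = p_eff)
  class(out) <- c("gating_estimate", "data.frame")
  out
}

#' Current-concentration curve
#'
#' Predicted current versus bulk concentration, either with symmetric
#' baths (driving force from the applied voltage only) or with a fixed
#' pipette and swept bath (driving force including the chemical
#' gradient).
#'
#' @param ep,sp,geom model parameters.
#' @param voltage applied potential (V).
#' @param concentrations swept concentrations (mol/L); zero entries
#'   allowed in `bath_series` mode (clamped).
#' @param mode `"symmetric"` or `"bath_series"`.
#' @param pipette pipette concentration for `bath_series` mode (mol/L).
#' @param clamp,cw,T as elsewhere.
#' @return a data.frame with columns `concentration` (mol/L) and
#'   `current` (A).
#' @export
current_concentration_curve <- function(ep = energy_params(),
                                        sp = site_params(),
                                        geom = pore_geometry(),
                                        voltage = 0.050,
                                        concentrations = seq(0.14, 2,
                                                             by = 0.06),
                                        mode = c("symmetric",
                                                 "bath_series"),
                                        pipette = 0.020, clamp = 1e-4,
                                        cw = 55.5, T = 298.15) {
  mode <- match.arg(mode)
  if (length(concentrations) == 0)
    stop("'concentrations' must be non-empty")
  cur <- vapply(concentrations, function(cc) {
    if (mode == "symmetric")
      as.numeric(steady_current(ep, sp, geom, cL = max(cc, clamp),
                                cR = max(cc, clamp), dphi = voltage,
                                clamp = clamp, cw = cw, T = T))
    else
      as.numeric(steady_current(ep, sp, geom, cL = pipette, cR = cc,
                                dphi = voltage, clamp = clamp,
                                cw = cw, T = T))
  }, numeric(1))
  data.frame(concentration = concentrations, current = cur)
}
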