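# Generators for synthetic occupancy, single-channel IV and whole-cell
# datasets with the statistical structure the analysis assumes, so the
# whole pipeline is testable without external data.

#' Ground-truth record for synthetic data generation
#'
#' Bundles the generating parameters so that any generated dataset can
#' be regenerated bit-for-bit from the record alone.
#'
#' @param dmu true site excess potentials (kT).
#' @param D true pore diffusivity (m^2/s).
#' @param nf,Uc electrostatic parameters (e, kT).
#' @param gating list with `v_half` and `slope` (V) of the Boltzmann
#'   sigmoid used to distort whole-cell currents; the defaults
#'   (-20 mV, 7 mV) place the peak of the gated IV at -10 mV.
#' @param seed integer RNG seed.
#' @return an object of class `truth_record`.
#' @export
truth_record <- function(dmu = c(2.3, 3.4, 2.8, 2.4), D = 1.33e-10,
                         nf = -2.5, Uc = 10,
                         gating = list(v_half = -0.020, slope = 0.007),
                         seed = 1L) {
  stopifnot(is.numeric(dmu), is.numeric(D), D > 0,
            is.list(gating), !is.null(gating$v_half),
            !is.null(gating$slope))
  structure(list(dmu = as.numeric(dmu), D = D, nf = nf, Uc = Uc,
                 gating = gating, seed = as.integer(seed)),
            class = "truth_record")
}

.truth_model <- function(truth) {
  list(ep = energy_params(Uc = truth$Uc, nf = truth$nf),
       sp = site_params(dmu = truth$dmu, D = truth$D))
}

#' Generate block-averaged site occupancy observations
#'
#' Emulates molecular-dynamics block averages: `n_blocks` block means
#' are drawn around the exact equilibrium occupancy of each site
#' (Gaussian, sd `noise_sd`, truncated to [0, 1]) and summarised as a
#' per-site mean and standard error.  The default 0.5 M bath is the
#' typical simulation condition.
#'
#' @param truth a [truth_record()].
#' @param bath_c bulk concentration (mol/L).
#' @param n_blocks number of block means (>= 1).
#' @param noise_sd standard deviation of a block mean.
#' @param cw,T bath parameters.
#' @return a data.frame with columns `site`, `occupancy`, `se`,
#'   `bath_c`.
#' @export
generate_occupancy_observations <- function(truth, bath_c = 0.5,
                                            n_blocks = 10,
                                            noise_sd = 0.02,
                                            cw = 55.5, T = 298.15) {
  stopifnot(inherits(truth, "truth_record"))
  if (n_blocks < 1) stop("'n_blocks' must be >= 1")
  if (noise_sd < 0) stop("'noise_sd' must be non-negative")
  mdl <- .truth_model(truth)
  occ <- solve_ensemble(mdl$ep, mdl$sp,
                        bath_state(c = bath_c, cw = cw, T = T))$occupancy
  set.seed(truth$seed)
  m <- length(occ)
  blocks <- matrix(stats::rnorm(m * n_blocks, mean = rep(occ, n_blocks),
                                sd = noise_sd), nrow = m)
  blocks <- pmin(pmax(blocks, 0), 1)
  mean_b <- rowMeans(blocks)
  se_b <- if (n_blocks > 1) apply(blocks, 1, stats::sd) / sqrt(n_blocks)
          else rep(NA_real_, m)
  data.frame(site = seq_len(m), occupancy = mean_b, se = se_b,
             bath_c = bath_c)
}

#' Generate single-channel IV observations
#'
#' Linear-response currents in symmetric baths over an Ohmic voltage
#' range, with multiplicative Gaussian noise (so the zero-voltage
#' current is exactly zero regardless of the noise seed).
#'
#' @param truth a [truth_record()].
#' @param voltages applied potentials (V), restricted to |V| <= 0.1.
#' @param bath_c symmetric bath concentration (mol/L).
#' @param rel_noise relative noise level (default 5%).
#' @param geom,cw,T as elsewhere.
#' @return a data.frame with columns `voltage` (V), `current` (A),
#'   `bath_L`, `bath_R` (mol/L).
#' @export
generate_singlechannel_iv <- function(truth,
                                      voltages = seq(-0.1, 0.1,
                                                     by = 0.01),
                                      bath_c = 0.14, rel_noise = 0.05,
                                      geom = pore_geometry(),
                                      cw = 55.5, T = 298.15) {
  stopifnot(inherits(truth, "truth_record"))
  if (length(voltages) == 0) stop("'voltages' must be non-empty")
  if (any(abs(voltages) > 0.1 + 1e-12))
    stop("linear-response IV is restricted to |V| <= 100 mV")
  mdl <- .truth_model(truth)
  I0 <- vapply(voltages, function(v) {
    as.numeric(steady_current(mdl$ep, mdl$sp, geom, cL = bath_c,
                              cR = bath_c, dphi = v, cw = cw, T = T))
  }, numeric(1))
  set.seed(truth$seed + 1L)
  I <- I0 * (1 + stats::rnorm(length(I0), sd = rel_noise))
  data.frame(voltage = voltages, current = I, bath_L = bath_c,
             bath_R = bath_c)
}

# Boltzmann open-probability sigmoid
.gating_sigmoid <- function(v, v_half, slope) {
  1 / (1 + exp(-(v - v_half) / slope))
}

#' Generate a synthetic whole-cell normalized IV series
#'
#' Theoretical currents for a bath-concentration series are distorted
#' by a sigmoidal voltage-gating factor `P(V) = 1/(1 + exp(-(V -
#' v_half)/slope))` (so the inward current collapses at strongly
#' negative voltages), normalized against the gated current magnitude
#' at -10 mV with the 0.14 M bath, and perturbed with additive noise
#' of scale `sem` emulating the cell-to-cell standard error.
#'
#' @param truth a [truth_record()].
#' @param bath_series bath Na+ concentrations (mol/L); must include
#'   0.14; zeros are clamped to 0.1 mM.
#' @param pipette pipette Na+ concentration (mol/L).
#' @param voltages applied potentials (V).
#' @param sem additive noise scale on the normalized current.
#' @param geom,clamp,cw,T as elsewhere.
#' @return a data.frame with columns `bath_Na`, `pipette_Na` (mol/L),
#'   `voltage` (V), `normalized_current`, `sem`; attribute
#'   `p_open` holds the gating factor applied at each row.
#' @export
generate_wholecell_dataset <- function(truth,
                                       bath_series = c(0.14, 0.126,
                                                       0.098, 0.07,
                                                       0.042, 0.014, 0),
                                       pipette = 0.020,
                                       voltages = seq(-0.100, 0.060,
                                                      by = 0.010),
                                       sem = 0.05,
                                       geom = pore_geometry(),
                                       clamp = 1e-4, cw = 55.5,
                                       T = 298.15) {
  stopifnot(inherits(truth, "truth_record"))
  if (!any(abs(bath_series - 0.14) < 1e-9))
    stop("bath series must include the 0.14 M reference member")
  mdl <- .truth_model(truth)
  theo <- wholecell_iv_series(baths = pmax(bath_series, clamp),
                              pipette = pipette, ep = mdl$ep,
                              sp = mdl$sp, geom = geom,
                              voltages = voltages, clamp = clamp,
                              cw = cw, T = T)
  p_open <- .gating_sigmoid(theo$voltage, truth$gating$v_half,
                            truth$gating$slope)
  gated <- theo$current * p_open
  ref_idx <- which(abs(theo$bath_Na - 0.14) < 1e-9 &
                     abs(theo$voltage - (-0.010)) < 5e-4)[1]
  norm <- gated / abs(gated[ref_idx])
  set.seed(truth$seed + 2L)
  noisy <- norm + stats::rnorm(length(norm), sd = sem)
  out <- data.frame(bath_Na = theo$bath_Na, pipette_Na = pipette,
                    voltage = theo$voltage,
                    normalized_current = noisy, sem = sem)
  attr(out, "p_open") <- p_open
  attr(out, "noiseless") <- norm
  out
}
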