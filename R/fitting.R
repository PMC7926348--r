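# Least-squares estimation of site excess chemical potentials from
# equilibrium occupancy data and linear-response current data.

# model-predicted occupancies for each observation row
.model_occupancies <- function(dmu, occ, ep, sp, cw, T) {
  sp$dmu <- dmu
  out <- numeric(nrow(occ))
  for (cc in unique(occ$bath_c)) {
    idx <- occ$bath_c == cc
    ens <- solve_ensemble(ep, sp, bath_state(c = cc, cw = cw, T = T))
    out[idx] <- ens$occupancy[occ$site[idx]]
  }
  out
}

# model-predicted currents for each observation row
.model_currents <- function(dmu, iv, ep, sp, geom, cw, T) {
  sp$dmu <- dmu
  vapply(seq_len(nrow(iv)), function(i) {
    as.numeric(steady_current(ep, sp, geom,
                              cL = iv$bath_L[i], cR = iv$bath_R[i],
                              dphi = iv$voltage[i], cw = cw, T = T))
  }, numeric(1))
}

#' Fit site excess chemical potentials
#'
#' Joint bounded least squares of the lattice-ensemble model against
#' equilibrium site-occupancy observations and linear-response current
#' observations.  The two residual blocks are balanced by scaling the
#' current residuals with a weight `w` (default: the largest observed
#' current magnitude), so both blocks are order one.  Differing bath
#' concentrations between the data sets are honoured per observation.
#' The optimiser (Levenberg-Marquardt with box constraints) is run
#' from several random starts drawn inside the box from a fixed seed,
#' and the best solution is returned.
#'
#' @param occ occupancy observations: data.frame with columns `site`
#'   (1-based index), `occupancy`, optional `se`, and `bath_c` (mol/L).
#'   At least one observation per site is required.
#' @param iv current observations (may have zero rows): data.frame
#'   with columns `voltage` (V), `current` (A), `bath_L`, `bath_R`
#'   (mol/L).
#' @param ep an [energy_params()] object; the fit is performed at its
#'   fixed `nf` (reference -2.5).
#' @param geom a [pore_geometry()] object.
#' @param options list of optional controls: `bounds` (length-2, kT,
#'   default `c(0, 8)`), `n_starts` (default 8), `seed` (default 1),
#'   `D` (fixed pore diffusivity, default 1.33e-10 m^2/s), `fit_D`
#'   (logical, default FALSE: fit one shared diffusivity), `weight`
#'   (current-block scale in A), `cw`, `T`.
#' @return an object of class `pore_fit`: `dmu_hat` (kT), `D_hat`
#'   (m^2/s), `ssr`, `residuals` (occupancy block then weighted
#'   current block), `n_starts`, `converged`, `seed`.
#' @export
fit_site_potentials <- function(occ, iv = NULL, ep = energy_params(),
                                geom = pore_geometry(),
                                options = list()) {
  opt <- utils::modifyList(
    list(bounds = c(0, 8), n_starts = 8, seed = 1, D = 1.33e-10,
         fit_D = FALSE, weight = NULL, cw = 55.5, T = 298.15),
    options)
  if (is.null(occ) || nrow(occ) == 0)
    stop("under-determined: occupancy observations are required")
  req <- c("site", "occupancy", "bath_c")
  if (!all(req %in% names(occ)))
    stop("'occ' must have columns site, occupancy, bath_c")
  n_sites <- length(geom$volume)
  if (!all(seq_len(n_sites) %in% occ$site) || max(occ$site) > n_sites)
    stop("under-determined: need at least one occupancy per site")
  if (is.null(iv)) iv <- data.frame(voltage = numeric(0),
                                    current = numeric(0),
                                    bath_L = numeric(0),
                                    bath_R = numeric(0))
  has_iv <- nrow(iv) > 0
  w <- opt$weight
  if (is.null(w)) w <- if (has_iv) max(abs(iv$current)) else 1
  if (w <= 0) w <- 1

  resid_fun <- function(par) {
    dmu <- par[seq_len(n_sites)]
    sp <- site_params(dmu = dmu,
                      D = if (opt$fit_D) par[n_sites + 1] else opt$D)
    r_occ <- .model_occupancies(dmu, occ, ep, sp, opt$cw, opt$T) -
      occ$occupancy
    if (!has_iv) return(r_occ)
    r_iv <- (.model_currents(dmu, iv, ep, sp, geom, opt$cw, opt$T) -
               iv$current) / w
    c(r_occ, r_iv)
  }

  lo <- rep(opt$bounds[1], n_sites)
  hi <- rep(opt$bounds[2], n_sites)
  if (opt$fit_D) { lo <- c(lo, 1e-12); hi <- c(hi, 1e-8) }

  set.seed(opt$seed)
  starts <- matrix(stats::runif(opt$n_starts * length(lo), lo, hi),
                   nrow = opt$n_starts, byrow = TRUE)
  # first start at the centre of the box for reproducible anchoring
  starts[1, ] <- (lo + hi) / 2

  best <- NULL
  converged <- FALSE
  for (k in seq_len(opt$n_starts)) {
    fit_k <- tryCatch(
      minpack.lm::nls.lm(par = starts[k, ], lower = lo, upper = hi,
                         fn = resid_fun,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit_k)) next
    ssr_k <- sum(resid_fun(fit_k$par)^2)
    if (is.null(best) || ssr_k < best$ssr) {
      best <- list(par = fit_k$par, ssr = ssr_k, info = fit_k$info)
      converged <- fit_k$info %in% 1:4
    }
  }
  if (is.null(best))
    return(structure(list(dmu_hat = rep(NA_real_, n_sites),
                          D_hat = opt$D, ssr = NA_real_,
                          residuals = NA_real_,
                          n_starts = opt$n_starts, converged = FALSE,
                          seed = opt$seed, weight = w),
                     class = "pore_fit"))
  dmu_hat <- best$par[seq_len(n_sites)]
  D_hat <- if (opt$fit_D) best$par[n_sites + 1] else opt$D
  structure(list(dmu_hat = dmu_hat, D_hat = D_hat, ssr = best$ssr,
                 residuals = resid_fun(best$par),
                 n_starts = opt$n_starts, converged = converged,
                 seed = opt$seed, weight = w, energy = ep,
                 geometry = geom, cw = opt$cw, T = opt$T),
            class = "pore_fit")
}

#' @export
print.pore_fit <- function(x, ...) {
  cat("Site-potential fit\n")
  cat("  dmu_hat (kT):", paste(sprintf("%.3f", x$dmu_hat),
                               collapse = ", "), "\n")
  cat(sprintf("  D = %.3g m^2/s (%s)\n", x$D_hat,
              if (isTRUE(x$converged)) "converged" else "not converged"))
  cat(sprintf("  ssr = %.3g over %d residuals, %d starts\n",
              x$ssr, length(x$residuals), x$n_starts))
  invisible(x)
}

#' Diagnostics for a site-potential fit
#'
#' Recomputes per-observation residuals, and reports the entry
#' barriers and equilibrium occupancies implied by the fitted
#' potentials at a requested concentration.
#'
#' @param fit a [fit_site_potentials()] result.
#' @param occ,iv the observation tables used in the fit.
#' @param ep,geom as in [fit_site_potentials()].
#' @param at_c concentration (mol/L) at which to report implied
#'   barriers and occupancies (default 0.14).
#' @param from_n resident ion count for the barrier report.
#' @return a list with `residuals_occupancy`, `residuals_current`
#'   (unweighted, A), `ssr`, `barriers` (kT), `occupancy_at_c`.
#' @export
fit_diagnostics <- function(fit, occ, iv = NULL, ep = energy_params(),
                            geom = pore_geometry(), at_c = 0.14,
                            from_n = 2) {
  stopifnot(inherits(fit, "pore_fit"))
  n_sites <- length(fit$dmu_hat)
  if (max(occ$site) > n_sites)
    stop("observation sites do not match the fitted model")
  sp <- site_params(dmu = fit$dmu_hat, D = fit$D_hat)
  r_occ <- .model_occupancies(fit$dmu_hat, occ, ep, sp,
                              fit$cw %||% 55.5, fit$T %||% 298.15) -
    occ$occupancy
  r_iv <- NULL
  if (!is.null(iv) && nrow(iv) > 0)
    r_iv <- .model_currents(fit$dmu_hat, iv, ep, sp, geom,
                            fit$cw %||% 55.5, fit$T %||% 298.15) -
      iv$current
  bath <- bath_state(c = at_c, cw = fit$cw %||% 55.5,
                     T = fit$T %||% 298.15)
  list(residuals_occupancy = r_occ,
       residuals_current = r_iv,
       ssr = sum(r_occ^2) + sum((r_iv / fit$weight)^2),
       barriers = entry_barriers(ep, sp, bath, from_n = from_n),
       occupancy_at_c = solve_ensemble(ep, sp, bath)$occupancy)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
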