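# Exact grand-canonical ensemble of the discrete-site pore.
#
# The filter is a 1-d lattice of M binding sites, each holding at most
# one ion, exchanging ions with two bulk reservoirs.  All moments are
# obtained by exact summation over the 2^M configurations.

#' Enumerate pore occupancy configurations
#'
#' Lists all `2^n_sites` occupancy patterns of the lattice in binary
#' order with site 1 (intracellular end) as the least-significant bit.
#'
#' @param n_sites number of binding sites (default 4).
#' @return a data.frame with one indicator column per site (`S1`,
#'   `S2`, ...), plus `n` (ion count) and `n0` (empty-site count); one
#'   row per configuration.
#' @examples
#' nrow(enumerate_configurations(4))  # 16
#' @export
enumerate_configurations <- function(n_sites = 4) {
  if (!is.numeric(n_sites) || length(n_sites) != 1L ||
      n_sites < 1 || n_sites != round(n_sites))
    stop("'n_sites' must be a positive integer")
  n_sites <- as.integer(n_sites)
  idx <- 0:(2^n_sites - 1L)
  occ <- vapply(seq_len(n_sites) - 1L,
                function(b) bitwAnd(bitwShiftR(idx, b), 1L),
                integer(length(idx)))
  occ <- matrix(occ, nrow = length(idx))
  colnames(occ) <- paste0("S", seq_len(n_sites))
  out <- as.data.frame(occ)
  out$n <- as.integer(rowSums(occ))
  out$n0 <- n_sites - out$n
  out
}

# occupancy indicator matrix (rows = configurations, cols = sites)
.config_matrix <- function(n_sites) {
  cf <- enumerate_configurations(n_sites)
  as.matrix(cf[, seq_len(n_sites), drop = FALSE])
}

#' Electrostatic self-energy of a pore configuration
#'
#' The pore acts as a capacitor of fixed charge `nf` (in e); holding n
#' ions of valence z costs `Uc * (nf + z*n)^2` in kT.  The energy
#' depends only on the ion count, not on which sites are occupied.
#'
#' @param config an occupancy indicator vector/matrix (one row per
#'   configuration), or an integer ion count (vectorized).
#' @param ep an [energy_params()] object.
#' @return electrostatic energy in kT, one value per configuration.
#' @export
electrostatic_energy <- function(config, ep) {
  stopifnot(inherits(ep, "energy_params"))
  n <- .ion_count(config)
  ep$Uc * (ep$nf + ep$z * n)^2
}

# interpret 'config' as either indicator vector(s) or ion count(s)
.ion_count <- function(config) {
  if (is.matrix(config)) return(rowSums(config))
  if (is.data.frame(config)) {
    if ("n" %in% names(config)) return(config$n)
    return(rowSums(as.matrix(config)))
  }
  if (all(config %in% c(0, 1)) && length(config) > 1) return(sum(config))
  config
}

#' Free energy of a pore configuration
#'
#' Equilibrium free energy (in kT) of one occupancy pattern:
#' electrostatic self-energy, minus for each occupied site the entropic
#' gain of drawing an ion from the bulk (`ln x`, with mole fraction
#' `x = c/cw`) plus the site's excess-potential difference, plus the
#' indistinguishability terms `ln(n0!) + ln(n!)` for empty sites and
#' ions.
#'
#' @param config occupancy indicator vector, or matrix with one row per
#'   configuration.
#' @param ep an [energy_params()] object.
#' @param sp a [site_params()] object; `length(sp$dmu)` sets the number
#'   of sites.
#' @param bath a [bath_state()] object.
#' @return free energy G in kT (vectorized over rows of `config`).
#' @export
configuration_free_energy <- function(config, ep, sp, bath) {
  stopifnot(inherits(ep, "energy_params"), inherits(sp, "site_params"),
            inherits(bath, "bath_state"))
  if (!is.matrix(config)) config <- matrix(config, nrow = 1L)
  m <- length(sp$dmu)
  if (ncol(config) != m)
    stop("'config' must have one indicator per site")
  if (!all(config %in% c(0, 1)))
    stop("occupancy indicators must be 0 or 1")
  x <- bath$c / bath$cw
  n <- rowSums(config)
  E <- ep$Uc * (ep$nf + ep$z * n)^2
  drop(E - config %*% sp$dmu - n * log(x) +
         lfactorial(m - n) + lfactorial(n))
}

#' Solve the equilibrium pore ensemble
#'
#' Computes the exact grand-canonical distribution over all occupancy
#' configurations: configuration probabilities `exp(-G/kT)/Z`, the
#' partition function, site occupancies and the occupancy covariance
#' matrix.  The minimum free energy is subtracted before
#' exponentiation, so results are invariant under any uniform shift of
#' G and immune to overflow.
#'
#' @inheritParams configuration_free_energy
#' @return an object of class `pore_ensemble`: a list with
#'   `configurations` (data.frame), `G` (kT), `probabilities`, `Z`,
#'   `log_Z`, `grand_potential` (kT), `occupancy` (per-site means),
#'   `covariance` (site occupancy covariance matrix) and the input
#'   parameters.
#' @examples
#' p <- nachbac_params()
#' ens <- solve_ensemble(p$energy, p$sites, bath_state(c = 0.5))
#' ens$occupancy
#' @export
solve_ensemble <- function(ep, sp, bath) {
  m <- length(sp$dmu)
  cf <- enumerate_configurations(m)
  occ_mat <- as.matrix(cf[, seq_len(m), drop = FALSE])
  G <- configuration_free_energy(occ_mat, ep, sp, bath)
  Gmin <- min(G)
  w <- exp(-(G - Gmin))
  Z <- sum(w) * exp(-Gmin)          # may overflow for extreme G; use log_Z
  log_Z <- log(sum(w)) - Gmin
  p <- w / sum(w)
  occupancy <- drop(crossprod(occ_mat, p))
  second <- crossprod(occ_mat * p, occ_mat)   # <n_m n_m'>
  covariance <- second - tcrossprod(occupancy)
  covariance <- (covariance + t(covariance)) / 2
  names(occupancy) <- colnames(occ_mat)
  dimnames(covariance) <- list(colnames(occ_mat), colnames(occ_mat))
  structure(list(configurations = cf, G = G, probabilities = p,
                 Z = Z, log_Z = log_Z, grand_potential = -log_Z,
                 occupancy = occupancy, covariance = covariance,
                 energy = ep, sites = sp, bath = bath),
            class = "pore_ensemble")
}

#' @export
print.pore_ensemble <- function(x, ...) {
  m <- length(x$occupancy)
  cat(sprintf("Pore ensemble: %d sites, %d configurations\n",
              m, nrow(x$configurations)))
  cat(sprintf("  bath %.4g M (x = %.4g), Uc = %.3g kT, nf = %.3g e\n",
              x$bath$c, x$bath$c / x$bath$cw, x$energy$Uc, x$energy$nf))
  cat(sprintf("  grand potential: %.4f kT\n", x$grand_potential))
  cat("  site occupancy:\n")
  print(round(x$occupancy, 4))
  cat(sprintf("  total <N> = %.4f\n", sum(x$occupancy)))
  invisible(x)
}
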