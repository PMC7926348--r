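# Linear-response transport: gradients, susceptibilities,
# conductivity, series current, barriers, resonance.

test_that("mole fraction and chemical gradient follow their definitions", {
  expect_equal(mole_fraction(0.14, 55.5), 2.5225e-3, tolerance = 1e-4)
  expect_equal(mole_fraction(0.5, 55.5), 9.009e-3, tolerance = 1e-4)
  expect_equal(mole_fraction(55.5, 55.5), 1)
  expect_error(mole_fraction(-1), "positive")

  expect_equal(chemical_gradient(0.020, 0.0001), log(200))
  expect_equal(chemical_gradient(0.020, 0.0001), 5.30, tolerance = 0.01)
  expect_equal(chemical_gradient(0.05, 0.05), 0)
  expect_equal(chemical_gradient(0.14, 0.02), log(7))
  # clamp applies to either side
  expect_equal(chemical_gradient(0.020, 0), chemical_gradient(0.020, 1e-4))
  expect_equal(chemical_gradient(0, 0.020), -chemical_gradient(0.020, 0))
  expect_error(chemical_gradient(0.02, 0, clamp = 0), "clamp")
})

test_that("closed-form susceptibility equals the finite-difference oracle", {
  p <- fitted_pars()
  set.seed(7)
  for (rep in 1:30) {
    pars <- random_pars()
    ens <- solve_ensemble(pars$ep, pars$sp, pars$bath)
    chi <- susceptibilities(ens, p$geometry)
    # step 1e-3 balances truncation against rounding for draws with
    # strongly pinned ion counts (tiny covariances)
    for (w in c("eta", "phi")) {
      fd <- finite_difference_susceptibility(pars$ep, pars$sp,
                                             pars$bath, p$geometry,
                                             which = w, step = 1e-3)
      closed <- if (w == "eta") chi$chi_eta else chi$chi_phi
      scale <- max(abs(closed), 1e-30)
      expect_lt(max(abs(fd - closed)) / scale, 1e-3)
    }
  }
})

test_that("single-site pore susceptibility is the Bernoulli variance", {
  # one site: chi = p(1-p)/(2 kT V)
  ep <- energy_params(Uc = 3, nf = -0.4)
  sp1 <- site_params(dmu = 2.1)
  bath <- bath_state(c = 0.3)
  geom1 <- pore_geometry(radius = 2.8, length = 12, area = 100,
                         volume = 100, Lc = 12)
  ens <- solve_ensemble(ep, sp1, bath)
  p_occ <- unname(ens$occupancy[1])
  chi <- susceptibilities(ens, geom1)
  kT <- 1.380649e-23 * 298.15
  expect_equal(unname(chi$chi_eta),
               p_occ * (1 - p_occ) / (2 * kT * 100e-30),
               tolerance = 1e-12)
  expect_equal(chi$chi_phi, chi$chi_eta)  # nu_bar = 1/2
})

test_that("finite-difference discrepancy shrinks ~4x when the step is halved", {
  p <- fitted_pars()
  bath <- bath_state(c = 0.5)
  ens <- solve_ensemble(p$energy, p$sites, bath)
  closed <- susceptibilities(ens, p$geometry)$chi_eta
  err_at <- function(h) max(abs(
    finite_difference_susceptibility(p$energy, p$sites, bath,
                                     p$geometry, "eta", step = h) -
      closed))
  e1 <- err_at(0.08)
  e2 <- err_at(0.04)
  expect_gt(e1 / e2, 3)
  expect_lt(e1 / e2, 5)
  expect_error(
    finite_difference_susceptibility(p$energy, p$sites, bath,
                                     p$geometry, "eta", step = -1),
    "positive")
})

test_that("a strongly pinned ion count still matches the oracle", {
  # large Uc with nf = -2 pins N = 2; the residual susceptibility is
  # exponentially suppressed, yet oracle and closed form still agree
  p <- fitted_pars()
  ep <- energy_params(Uc = 15, nf = -2)
  bath <- bath_state(c = 0.5)
  ens <- solve_ensemble(ep, p$sites, bath)
  expect_equal(sum(ens$occupancy), 2, tolerance = 1e-5)
  closed <- unname(susceptibilities(ens, p$geometry)$chi_eta)
  ref <- unname(susceptibilities(solve_ensemble(p$energy, p$sites,
                                                bath),
                                 p$geometry)$chi_eta)
  expect_lt(max(abs(closed)) / max(abs(ref)), 1e-4)  # suppressed
  fd <- finite_difference_susceptibility(ep, p$sites, bath, p$geometry,
                                         "eta", step = 1e-3)
  expect_equal(fd, closed, tolerance = 1e-3)
})

test_that("site conductivity is linear in D and zero at zero susceptibility", {
  p <- fitted_pars()
  chi <- c(1e46, 2e46, 3e46, 4e46)
  s1 <- site_conductivity(chi, chi, p$sites)
  sp2 <- site_params(dmu = p$sites$dmu, D = 2 * p$sites$D)
  expect_equal(site_conductivity(chi, chi, sp2), 2 * s1)
  expect_equal(unname(site_conductivity(rep(0, 4), rep(0, 4), p$sites)),
               rep(0, 4))
  flagged <- site_conductivity(c(-1e40, 1e46, 1e46, 1e46),
                               sp = p$sites)
  expect_true(isTRUE(attr(flagged, "negative_chi")))
})

test_that("series current obeys Ohm's law, reversal and blocking", {
  p <- fitted_pars()
  geom <- p$geometry
  sigma <- rep(0.5, 4)
  # pure Ohm: I = dphi / sum(L/(A sigma))
  f <- driving_forces(dphi = 0.05)
  I <- pore_current(sigma, geom, f)
  R_exp <- sum(geom$length * 1e-10 / (geom$area * 1e-20 * sigma))
  expect_equal(as.numeric(I), 0.05 / R_exp)
  expect_equal(attr(I, "R_total"), R_exp)
  # exact reversal: dphi = -deta kT/e
  deta <- 1.7
  f_rev <- driving_forces(dphi = -deta * thermal_voltage(),
                          deta = deta)
  expect_equal(as.numeric(pore_current(sigma, geom, f_rev)), 0)
  # sign follows the net drive
  f_pos <- driving_forces(dphi = 0.01, deta = 0.5)
  f_neg <- driving_forces(dphi = -0.05, deta = 0.5)
  expect_gt(as.numeric(pore_current(sigma, geom, f_pos)), 0)
  expect_lt(as.numeric(pore_current(sigma, geom, f_neg)), 0)
  # one blocked site interrupts the path
  I_blk <- pore_current(c(0.5, 0, 0.5, 0.5), geom, f)
  expect_equal(as.numeric(I_blk), 0)
  expect_true(isTRUE(attr(I_blk, "blocked")))
  # permuting site order leaves the total resistance unchanged
  perm <- c(3, 1, 4, 2)
  geom_p <- pore_geometry(radius = geom$radius[perm],
                          length = geom$length[perm],
                          area = geom$area[perm],
                          volume = geom$volume[perm])
  sig <- c(0.2, 0.4, 0.8, 1.6)
  expect_equal(attr(pore_current(sig[perm], geom_p, f), "R_total"),
               attr(pore_current(sig, geom, f), "R_total"))
})

test_that("reversal potential is Nernstian with clamping", {
  expect_equal(reversal_potential(0.05, 0.05), 0)
  # pipette 20 mM vs ion-free bath clamped at 0.1 mM
  expect_equal(reversal_potential(0.020, 0.0001),
               thermal_voltage() * log(0.0001 / 0.020))
  expect_lt(reversal_potential(0.020, 0), -0.035)
  expect_equal(reversal_potential(0.020, 0),
               reversal_potential(0.020, 1e-4))
  # Nernst slope: a tenfold ratio gives ~59.2 mV
  expect_equal(reversal_potential(0.01, 0.1), 59.16e-3,
               tolerance = 1e-3)
})

test_that("entry barriers match the closed-form decomposition", {
  p <- fitted_pars()
  b <- entry_barriers(p$energy, p$sites, p$bath, from_n = 2)
  x <- 0.14 / 55.5
  expect_equal(b, -log(x) - p$sites$dmu + log(6 / 4),
               tolerance = 1e-12)
  expect_equal(b, c(4.088, 2.988, 3.588, 3.988), tolerance = 1e-3)
  # raising the concentration lowers every barrier by ln(c2/c1)
  b2 <- entry_barriers(p$energy, p$sites, bath_state(c = 0.5),
                       from_n = 2)
  expect_equal(b - b2, rep(log(0.5 / 0.14), 4), tolerance = 1e-12)
  # pure combinatorial term at Uc = 0, dmu = 0, x = 1
  ep0 <- energy_params(Uc = 0, nf = 0)
  sp0 <- site_params(dmu = rep(0, 4))
  b0 <- entry_barriers(ep0, sp0, bath_state(c = 55.4999999, cw = 55.5),
                       from_n = 0)
  expect_equal(b0, rep(log(factorial(1) * factorial(3) /
                             factorial(4)), 4), tolerance = 1e-6)
  # the deepest site has the smallest barrier and largest occupancy
  expect_equal(which.min(b), 2L)
  expect_error(entry_barriers(p$energy, p$sites, p$bath, from_n = 4),
               "pore not full")
})

test_that("resonant charge solves the level-crossing condition", {
  p <- fitted_pars()
  nf_star <- resonance_charge(p$energy, p$sites, p$bath, n_lo = 2)
  expect_equal(nf_star, -2.70, tolerance = 0.01)
  # at nf*, the minimal 2- and 3-ion configurations are equiprobable
  ep_star <- energy_params(Uc = 10, nf = nf_star)
  ens <- solve_ensemble(ep_star, p$sites, p$bath)
  cf <- ens$configurations
  p2 <- max(ens$probabilities[cf$n == 2])
  p3 <- max(ens$probabilities[cf$n == 3])
  expect_equal(p2, p3, tolerance = 1e-10)
  # higher concentration moves nf* toward -2.5
  nf_hi <- resonance_charge(p$energy, p$sites, bath_state(c = 2),
                            n_lo = 2)
  expect_gt(nf_hi, nf_star)
  expect_lt(nf_hi, -2.5)
  # flat sites at x = 1 without combinatorial asymmetry: for huge Uc
  # nf* tends to the pure electrostatic value -(n_lo + 1/2)
  ep_big <- energy_params(Uc = 1e8, nf = 0)
  sp0 <- site_params(dmu = rep(0, 4))
  nf0 <- resonance_charge(ep_big, sp0, bath_state(c = 55.4999, cw = 55.5),
                          n_lo = 1)
  expect_equal(nf0, -1.5, tolerance = 1e-6)
  expect_error(resonance_charge(energy_params(Uc = 0), p$sites, p$bath),
               "Uc = 0")
})

test_that("diffusion-limited rate reproduces the barrier-less scale", {
  rate <- diffusion_limited_rate(1.33e-10, 12)
  expect_equal(rate, 1.33e-10 / (1.2e-9)^2)
  expect_equal(rate, 0.92e8, tolerance = 0.01e8)
  # charge flux scale of the order of tens of pA
  expect_equal(rate * 1.602176634e-19, 1.48e-11, tolerance = 1e-3)
  # doubling the length quarters the rate
  expect_equal(diffusion_limited_rate(1.33e-10, 24), rate / 4)
  expect_error(diffusion_limited_rate(-1, 12), "positive")
})

test_that("predicted currents have the observed order of magnitude", {
  p <- fitted_pars()
  I_2M <- steady_current(p$energy, p$sites, p$geometry, 2, 2, 0.05)
  expect_lt(abs(I_2M) * 1e12, 10)      # < 10 pA at 2 M, 50 mV
  expect_gt(abs(I_2M) * 1e12, 0.5)     # but not vanishing
  I_sym <- steady_current(p$energy, p$sites, p$geometry, 0.14, 0.14, 0)
  expect_equal(as.numeric(I_sym), 0)
})
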