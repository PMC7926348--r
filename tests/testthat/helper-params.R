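# Shared fixtures: the fitted wild-type parameter set and a random
# parameter draw for property-style tests.

fitted_pars <- function() nachbac_params()

random_pars <- function() {
  list(ep = energy_params(Uc = runif(1, 0, 20), nf = runif(1, -4, 0)),
       sp = site_params(dmu = runif(4, 0, 6),
                        D = 10^runif(1, -11, -9)),
       bath = bath_state(c = 10^runif(1, -3, 0.3)))
}

# brute-force ensemble moments via direct summation, independent of
# solve_ensemble's vectorised linear algebra
brute_force_moments <- function(ep, sp, bath) {
  m <- length(sp$dmu)
  cf <- expand.grid(rep(list(0:1), m))
  G <- apply(cf, 1, function(occ)
    configuration_free_energy(as.numeric(occ), ep, sp, bath))
  w <- exp(-(G - min(G)))
  p <- w / sum(w)
  occ <- sapply(seq_len(m), function(j) sum(p * cf[[j]]))
  cov <- matrix(0, m, m)
  for (j in seq_len(m)) for (k in seq_len(m))
    cov[j, k] <- sum(p * cf[[j]] * cf[[k]]) - occ[j] * occ[k]
  list(p = p, occ = occ, cov = cov)
}
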