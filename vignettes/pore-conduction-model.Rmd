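---
title: "A grand-canonical lattice model of multi-ion conduction in a channel selectivity filter"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A grand-canonical lattice model of multi-ion conduction in a channel selectivity filter}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(porelattice)
```

## The model

The selectivity filter of a narrow cation channel is treated as a
one-dimensional lattice of $M$ binding sites (here $M = 4$, labelled
S1–S4 from the intracellular side), each holding at most one ion, in
thermal and diffusive contact with two bulk reservoirs.  A
configuration is an occupancy pattern $\{n_m\}$, $n_m \in \{0, 1\}$;
with four sites there are only $2^4 = 16$ of them, so every ensemble
average in this package is an exact sum — there is no sampling and no
truncation anywhere in the equilibrium core.

The free energy of a configuration with $n = \sum_m n_m$ ions, in
units of $kT$, is

$$G(\{n_m\}) = U_c\,(n_f + z n)^2
  - \sum_m n_m\left(\ln x + \Delta\bar\mu_m\right)
  + \ln n_0! + \ln n!,$$

with the terms meaning:

* **Electrostatic self-energy.** The pore is approximated as a
  capacitor carrying the effective fixed charge $n_f$ (in units of
  $e$; glutamate ring plus partial charges and possible protonation,
  hence non-integer) plus the ionic charge $zn$.  The charging energy
  $U_c = e^2/2C$ is taken as $10\,kT$ by default — the pore
  permittivity is not measurable directly, and this value places the
  model in the ionic-Coulomb-blockade regime that the mutant
  phenomenology supports.  The energy depends on the ion *count*
  only, which is what makes level crossings ("resonances") between
  $n$- and $(n{+}1)$-ion states sharp.
* **Bulk exchange.** Moving an ion from bulk into site $m$ gains the
  ideal-solution entropy $\ln x$, with mole fraction $x = c/c_w$
  ($c_w = 55.5$ M for water), plus the site's excess chemical
  potential difference $\Delta\bar\mu_m$ (bulk minus site; larger
  means a deeper site).
* **Indistinguishability.** $\ln n_0! + \ln n!$ for the $n_0 = M - n$
  empty sites and $n$ ions.  These combinatorial terms are part of the
  model, not a convention: dropping them shifts the entry barriers by
  $\approx 0.4\,kT$ and the resonant charge by $\approx 0.02\,e$, and
  only the form that keeps them reproduces the published barrier set
  and the $n_f^\ast \approx -2.7$ crossing simultaneously.

Probabilities are $P \propto e^{-G}$, normalized over the 16
configurations after subtracting the minimum $G$ (so any uniform
shift of the free energies is exactly inert, and overflow cannot
occur).  `solve_ensemble()` returns the partition function, the
distribution, per-site mean occupancies and the full occupancy
covariance matrix.

```{r ensemble}
p <- nachbac_params()
ens <- solve_ensemble(p$energy, p$sites, bath_state(c = 0.5))
ens
```

With the fitted potentials, S2 is the deepest site and the S1/S4
occupancies are about half of its — the pattern seen in molecular
dynamics at 0.5 M.

## Transport at linear response

A small electrochemical gradient — electrical drive $\delta\phi$ plus
chemical drive $\delta\eta = \ln(x_L/x_R)$ in $kT$ — perturbs each
occupied site's energy.  Linearising the perturbed distribution gives
the susceptibility of the mean site density, which is an equilibrium
fluctuation quantity:

$$\chi_m = \frac{\mathrm{Cov}(n_m, N)}{2\,kT\,V_m},
  \qquad N = \sum_{m'} n_{m'},$$

with $V_m$ the site volume.  The factor $1/2$ comes from the
symmetric perturbation of the two baths; for the electrical drive the
same expression is scaled by $2\bar\nu$ where $\bar\nu$ is the mean
voltage-drop fraction to reach a site, collapsed to $1/2$ for a
symmetrically distributed pore (no per-site drop profile is
modelled).  The generalised Einstein relation then gives per-site
conductivities $\sigma_m = (ze)^2 D_m \chi_m$, and the sites compose
as resistors in series:

$$I = \frac{\delta\phi + \delta\eta\,kT/e}
           {\sum_m L_m/(A_m \sigma_m)}.$$

One non-conducting site therefore blocks the whole pathway
(`pore_current()` reports a `blocked` flag rather than an
unphysical value).  Site lengths $L_m$, areas $A_m$ and volumes $V_m$
are the spheroidal estimates for the four NaChBac sites (mean volume
97 Å³), entered in Å units and converted to SI internally.  The pore
diffusivity is fixed at a tenth of the bulk value,
$D = 1.33\times10^{-10}\,\mathrm{m^2 s^{-1}}$, for all sites; the
corresponding barrier-less transit scale $D/L_c^2 \approx 0.9 \times
10^8$ ions/s, i.e. about 15 pA of charge flux, bounds the currents
the model can produce.

```{r transport}
entry_barriers(p$energy, p$sites, p$bath, from_n = 2)       # kT
resonance_charge(p$energy, p$sites, p$bath, n_lo = 2)       # e
as.numeric(steady_current(p$energy, p$sites, p$geometry,
                          cL = 2, cR = 2, dphi = 0.05)) * 1e12  # pA
```

The entry barrier for the third ion is
$\Delta G_m = [E(3) - E(2)] - \ln x - \Delta\bar\mu_m +
\ln\frac{3!\,1!}{2!\,2!}$; at the reference charge $n_f = -2.5$ the
electrostatic difference vanishes identically, so the barriers are
set by concentration and site depth alone, and raising the bulk
concentration lowers all of them by the same $\ln(c_2/c_1)$.  The
resonant charge solves the degeneracy of the minimum-free-energy 2-
and 3-ion states in closed form (the self-energy parabola has equal
curvature for every $n$, so the crossing is linear in $n_f$).

### The finite-difference oracle

`susceptibilities()` (closed form) is checked against
`finite_difference_susceptibility()`, which differentiates the mean
occupancy of the *perturbed* ensemble numerically and shares no code
with the covariance route.  The default step is $10^{-4}\,kT$; for
property tests over random parameter draws the package's tests use
$10^{-3}\,kT$, because draws with a strongly pinned ion count have
covariances suppressed by many orders of magnitude and a smaller step
pushes the central difference into floating-point cancellation while
the truncation error at $10^{-3}$ is still $O(10^{-6})$ relative.

## Sign and unit conventions

Side L is intracellular (the pipette in whole-cell work), side R
extracellular (the bath); positive current flows L to R.  Voltages
and currents are SI (V, A) inside the package; energies are $kT$;
concentrations mol/L; geometry is entered in Å units.  File formats
carry field units (mV, pA, mM) and `read_table()`/`write_table()`
convert at that boundary only.  The reversal potential returned by
`reversal_potential()` is the applied-voltage zero crossing of the
series current, $-(kT/e)\ln(x_L/x_R)$: for a 20 mM pipette against a
nominally ion-free bath (clamped at 0.1 mM, see below) it is
$-136$ mV, far below the $-35$ mV that would be expected if the bath
were truly Na⁺-free and only Na⁺ carried current — which is why the
zero-bath member of the whole-cell series is treated as the model's
known failure case.

Concentrations below 0.1 mM are clamped to 0.1 mM before any
logarithm (`chemical_gradient()`, the whole-cell pipeline), keeping
the drive finite for the "0 mM" bath; even so that member sits at a
gradient of $\sim 5\,kT$, the edge of the linear-response regime.

## Fitting site potentials

`fit_site_potentials()` estimates $\Delta\bar\mu_{1..4}$ by bounded
nonlinear least squares against equilibrium occupancy observations
and linear-response current observations jointly, with each
observation's own bath concentration honoured (occupancies are
typically measured at 0.5 M, currents at 0.14 M).  Choices made where
the problem is genuinely open:

* **Objective and weighting.** Occupancy residuals are dimensionless
  and $O(1)$; current residuals are divided by a scale $w$ (default:
  the largest observed current magnitude) so both blocks contribute
  at order one.  No published weighting exists for this problem, so
  the weight is exposed as an option; at $w \to \infty$ the fit
  degenerates gracefully to occupancy-only.
* **Optimiser.** Bounded Levenberg–Marquardt (`minpack.lm::nls.lm`)
  with a box of $[0, 8]\,kT$ (covering all plausible site depths) and
  8 multistarts from a fixed seed, first start at the box centre;
  best-of-starts is returned and non-convergence is flagged, not
  thrown.
* **Identifiability.** With occupancy data at a single concentration
  and no current data, the diffusivity $D$ is not identifiable (it
  only scales the current); $D$ is therefore fixed by default and can
  be fitted as a single shared value only when current data are
  present.  The fit is performed at the reference charge
  $n_f = -2.5$.

```{r fit}
tr <- truth_record(seed = 7)
occ <- generate_occupancy_observations(tr, noise_sd = 0.02)
iv  <- generate_singlechannel_iv(tr, voltages = 0.035, rel_noise = 0.05)
fit_site_potentials(occ, iv)
```

## The whole-cell pipeline

Whole-cell recordings sum over all channels of a cell; normalizing by
the peak current (at $-10$ mV with the 0.14 M bath) removes the
unknown channel count and lets the series be compared to a single
model pore.  `wholecell_iv_series()` computes the theoretical
normalized series: for each bath member the equilibrium ensemble is
built at the *mean* of the pipette and bath concentrations (the
equilibrium reference for an asymmetric pair), the current includes
the chemical drive, and normalization divides by the absolute
reference value (a signed-reference mode is provided for
current–concentration figures).  The IV zero crossing of every
member coincides with the closed-form reversal potential to well
under 0.1 mV, by construction of the linear-response current.

`effective_open_probability()` is the elementwise ratio of
experimental to theoretical current on a matched grid, defined
relative to the open probability at peak current ($p_{open} = p_{eff}
\times p_{max}$).  Ratios are reported as-is — values above 1 or
below 0 are informative disagreement, not errors — and entries where
the theoretical current is below a floor (default $10^{-3}$ pA in
raw units) are masked rather than divided.

## Synthetic data: what it emulates and what it does not

`generate_occupancy_observations()` emulates block-averaged MD
occupancies: Gaussian block means (sd 0.02, truncated to $[0,1]$,
default 10 blocks — no occupancy uncertainties are published, so the
noise scale is a stipulation) around the exact ensemble values at
0.5 M.  `generate_singlechannel_iv()` adds 5% multiplicative noise to
linear-response currents in symmetric 0.14 M baths, restricted to the
Ohmic window $|V| \le 100$ mV.  `generate_wholecell_dataset()`
multiplies the theoretical series by a Boltzmann gating sigmoid
$P(V) = 1/(1 + e^{-(V - V_{1/2})/s})$ with $V_{1/2} = -20$ mV and
$s = 7$ mV — gating is described only qualitatively in the
electrophysiology, and these values place the gated peak at $-10$ mV
as observed — then renormalizes and adds SEM-scale noise (0.05).

All generators are bit-reproducible from a `truth_record()`; distinct
seeds change the noise, never the noiseless core.  What passing the
recovery tests shows is that the *pipeline* is consistent: data
generated by the model are fitted back to the generating parameters
(bias $< 0.05\,kT$, RMSE $< 0.2\,kT$ over 50 replicates at the
stated noise).  It does not show that real channels satisfy the
model's assumptions — single-species transport, linear response,
voltage-independent site energetics, and a rigid geometry are all
idealisations, and the far-from-equilibrium regime beyond
$\sim 100$ mV or $\sim 5\,kT$ of chemical drive is explicitly outside
the theory.

## Numerical choices and limitations

* Exact enumeration bounds every equilibrium computation at 16
  states; all test and example problem sizes (IV grids of tens of
  voltages, 50-replicate recovery loops) run in seconds.
* Temperature defaults to 298.15 K ($kT/e = 25.693$ mV) everywhere.
* The resonance solver breaks level-degeneracy ties by the deepest
  available site; equal-depth ties are exactly degenerate and either
  choice gives the same crossing.
* Negative susceptibilities cannot arise from the covariance formula
  with a single species (Cov$(n_m, N) \ge 0$ here in practice), but
  `site_conductivity()` flags rather than clips them in case of
  user-supplied values.
* Known limitations: no mixed-species selectivity (the
  zero-Na⁺-bath disagreement is expected to involve K⁺ block), no
  gating kinetics, no per-site voltage-drop profile, no fitting of
  $U_c$ or $n_f$ (scan them explicitly instead).
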