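# Canonical fitted parameter set for wild-type NaChBac.
# Units: Uc in kT, nf in e, dmu in kT, D in m^2/s, geometry in
# Angstrom units, cw in mol/L, T in K, clamp in mol/L.
energy:
  Uc: 10.0
  nf: -2.5
  z: 1
sites:
  dmu: [2.3, 3.4, 2.8, 2.4]
  D: 1.33e-10
bath:
  cw: 55.5
  T: 298.15
  clamp: 1.0e-4
geometry:
  radius: [3.06, 2.77, 2.75, 2.77]
  length: [3, 4, 3, 2]
  area: [116, 126, 90, 78]
  volume: [117, 129, 80, 63]
  Lc: 12
seed: 1
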