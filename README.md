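# cngperm

Quantitative analysis of large organic cation permeation through
cyclic-nucleotide-gated (CNG) channel mimics, centred on dimethylammonium
(DMA).

Enhanced-sampling molecular dynamics of a CNG-mimic pore yields a
one-dimensional free-energy profile G(z) for a DMA ion along its exit path
that is dominated by a single deep well — deep enough that, taken alone, it
would predict nanomolar binding affinity. Patch-clamp dose–response
measurements instead give an apparent Kd of tens of millimolar. The
resolution is multi-ion: a second DMA entering the filter destabilizes the
bound one by ~25 kJ/mol, raising its exit rate by orders of magnitude.
`cngperm` implements the full quantitative chain behind that argument for
anyone analyzing single-file permeation of large cations:

- **Profile analysis** (`read_profile`, `find_minima`, `barrier_height`,
  `unbinding_distance`, `block_error`): minima with topographic prominence,
  well depths against the bulk plateau, escape barriers, and
  block-averaging errors for correlated series.
- **Kinetic models** (`single_site_flux`, `two_site_stationary`,
  `two_site_flux`, `two_site_flux_limit`, `half_activation`,
  `rates_from_profiles`): the one-site Michaelis–Menten model
  J = kL·X / (X·kL/kR + 1) and the four-state two-site single-file model
  with states E, L, R, D and rates kL, k⁺, k⁻, kR, k̃R. Its stationary flux

      J = X·kL·k⁺·k̃R·(X·kL + kR) /
          [(k⁺+k̃R)·X²kL² + k̃R·(kR+k⁻+k⁺)·X·kL + kR·k⁺·k̃R]

  reduces, for negligible kR, to a Michaelis–Menten form with
  half-activation X½ = (k⁻+k⁺)·k̃R / [(k⁺+k̃R)·kL]. Rates are Arrhenius
  factors exp(−ΔG‡/kT) in units of a common kinetic prefactor.
- **Stochastic oracle** (`simulate_trajectory`, `empirical_flux`,
  `empirical_occupancy`): exact Gillespie simulation of the hopping scheme
  (C++ core), used to verify the analytic solutions.
- **Electrolyte activities** (`activity`, `debye_huckel_log_gamma`,
  `davies_log_gamma`): Debye–Hückel below 100 mM, Davies at and above,
  with log₁₀γ = −0.509·z²√I/(1 + 3.28·d·√I) and
  log₁₀γ = −0.509·(√I/(1+√I) − 0.3·I).
- **Dose–response fitting** (`global_mm_fit`, `bootstrap_khalf`): global
  Michaelis–Menten fit of normalized conductance versus ionic activity with
  one shared half-activation constant and per-voltage maxima.
- **Synthetic data** (`make_profile`, `make_conductance`,
  `make_ar1_series`): seeded generators that emulate the shapes and noise
  of the profiles and electrophysiology, so every stage is testable offline.

## Worked example

```r
library(cngperm)

# free-energy landscape of one vs two ions in the pore
single <- make_profile(profile_spec_single_ion())
double <- make_profile(profile_spec_two_ion())
minima <- find_minima(single, prominence_min = 1,
                      labels = attr(single, "well_labels"))
minima[, c("label", "z_min", "G_min", "depth")]
#>   label z_min G_min depth
#> 1    S3  0.25 -37.4  37.4
#> 2    S4  0.55 -34.4  34.4
#> 3    SX  0.90  -8.0   8.0
#> 4    S0  1.30 -12.0  12.0

global_minimum(single)$depth - global_minimum(double)$depth
#> [1] 25        # kJ/mol of destabilization by the second ion

# hopping rates and the resulting half-activation constant
r <- two_site_rates()           # k+ = e^-0.5, k- = e^-1.5, kR = e^-15, kR~ = e^-7.5
half_activation(r)
#> [1] 0.0007558635   # mol/L: sub-mM, versus nM from the one-site picture

# analytic stationary state, checked against exact stochastic simulation
st <- two_site_stationary(r, X = 1e-3)
tr <- simulate_trajectory(r, X = 1e-3, seed = 11)
c(analytic = st$J, empirical = empirical_flux(tr)$J)
#>     analytic    empirical
#> 0.0003147718 0.0003095256

# dose-response fit on the synthetic electrophysiology dataset
d <- attach_activities(make_conductance(conductance_spec_default()))
fit <- global_mm_fit(d)
fit$K_half_conc_mM
#> [1] 55.29397       # apparent Kd (mM), generating value 52 mM
```

The numbers read as follows: the one-ion landscape has four minima with S3
the global one (15 kT deep); adding a second ion removes 25 kJ/mol of that
depth. Feeding the corresponding Arrhenius rates into the two-site model
gives a half-activation constant around 0.76 mM — many orders of magnitude
above the one-site dissociation constant kR/kL ≈ 3·10⁻⁷ M, and on the
experimental side of the scale. The global fit of the synthetic conductance
data recovers its generating apparent Kd of 52 mM to within the replicate
noise.

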