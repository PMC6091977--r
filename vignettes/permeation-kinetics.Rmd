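---
title: "Single-file permeation kinetics of large cations through a CNG-mimic pore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-file permeation kinetics of large cations through a CNG-mimic pore}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cngperm)
```

## The scientific problem

Cyclic-nucleotide-gated (CNG) channels pass large organic cations such as
dimethylammonium (DMA). Enhanced-sampling molecular dynamics of a CNG-mimic
pore projects the free energy of a single DMA onto one collective variable
— its distance $z$ (nm) from the Val64 ring at the intracellular mouth of
the selectivity filter — and finds a landscape dominated by one deep well
(the S3 site) of roughly $15\,k_BT \approx 37$ kJ/mol, plus secondary
minima (S4, 3 kJ/mol above S3; the off-axis SX; the vestibular S0). Taken
at face value, a well that deep implies nanomolar affinity and essentially
no conduction. Electrophysiology says otherwise: the conductance saturates
with an apparent $K_d$ of tens of millimolar.

The quantitative resolution is multi-ion. When a second DMA enters the
filter, electrostatic repulsion removes about 25 kJ/mol of the bound ion's
well depth and the ion is already unbound 1 nm from Val64 (versus 2 nm for
a single ion). `cngperm` implements every quantitative step of that
argument: profile post-processing, Arrhenius rate extraction, the one- and
two-site kinetic models, an exact stochastic simulator used as an oracle,
electrolyte activity corrections, and the global dose–response fit —
together with synthetic-data generators that stand in for the simulation
and patch-clamp inputs.

## The kinetic models

**One site.** Two states, empty/occupied, entry rate $k_L X$ (with $X$ the
intracellular permeant concentration) and exit rate $k_R$. The stationary
flux is the Michaelis–Menten form

$$J = \frac{k_L X}{X k_L / k_R + 1},$$

with half-saturation at exactly $X_{1/2} = k_R/k_L$
(`single_site_flux()`).

**Two sites, single file.** Four states — empty (E), left site occupied
(L), right site occupied (R), doubly occupied (D) — with transitions
E→L ($k_L X$), L→R ($k^+$), R→L ($k^-$), R→E ($k_R$), R→D ($k_L X$) and
D→L ($\tilde k_R$). Backward crossing from the extracellular side is
neglected: at the strongly depolarized potentials where the conductance is
measured, ions move outward only. Solving the stationary master equation
(`two_site_stationary()`, a linear solve with one balance row replaced by
normalization because the generator matrix is rank-deficient) gives

$$J = \frac{X k_L k^+ \tilde k_R\,(X k_L + k_R)}
  {(k^+{+}\tilde k_R) X^2 k_L^2 + \tilde k_R (k_R{+}k^-{+}k^+) X k_L +
   k_R k^+ \tilde k_R},$$

implemented independently in closed form (`two_site_flux()`); the two
routes agreeing to machine precision is a standing test. When $k_R$ is
negligible relative to every other rate, the flux reduces to a
Michaelis–Menten form (`two_site_flux_limit()`) with

$$X_{1/2} = \frac{(k^- + k^+)\,\tilde k_R}{(k^+ + \tilde k_R)\,k_L}$$

(`half_activation()`). This is the central observation: the two-site model
is *experimentally indistinguishable* from the one-site model by curve
shape — only the meaning of the half-activation constant changes. The
pointwise accuracy of the limiting form is first order in $k_R/(k_L X)$:
with the default rates it is within $10^{-3}$ of the full flux for
$X \ge 1$ mM, degrades to $\sim$0.7% at 10 µM, and normalized to the
saturating flux the two curves agree to $\sim 10^{-4}$ everywhere (these
figures are computed in the test suite).

**Rates.** All rates are Arrhenius factors $e^{-\Delta G^\ddagger/k_BT}$ in
units of a common kinetic prefactor (`arrhenius_rate()`), with barriers
taken from the profiles in units of $k_BT$ at 300 K
($k_BT = 2.494$ kJ/mol). The defaults are $k^+ = e^{-0.5}$,
$k^- = e^{-1.5}$, $k_R = e^{-15}$ and $\tilde k_R = e^{-7.5}$. The entry
step is barrierless, so $k_L$ is not derivable from a profile; it defaults
to 1 prefactor·M$^{-1}$ and all fluxes are reported in prefactor units —
only rate *ratios* and $X_{1/2}$ are physically comparable. With these
defaults the formula gives $X_{1/2} = 7.56\times10^{-4}$ M. The
experimental estimate of the same quantity is 0.6 mM; exact agreement is
not expected, and the package never adjusts $k_L$ to force it, because the
prefactor-scaled entry rate is simply unknown. Two further inconsistencies
in the source numbers are carried, not resolved: a binding depth quoted as
"almost 50 kJ/mol" corresponds to $e^{-20}$, not $e^{-15}$, at 300 K; and
a 25 kJ/mol destabilization corresponds to $e^{\,25/2.494} \approx e^{10}$,
not the $e^{7.5}$ quoted for $\tilde k_R/k_R$. The synthetic profiles use
37.4 kJ/mol (= 15 $k_BT$) and 12.4 kJ/mol so that barrier extraction
reproduces $e^{-15}$ and a 25 kJ/mol reduction exactly; the kinetic
defaults keep the quoted $e^{-7.5}$.

**A property worth knowing.** The flux is non-decreasing in $X$ only in the
repulsive regime $\tilde k_R \ge k_R$ — the regime this channel is in.
If double occupancy *slowed* the exit ($\tilde k_R \ll k_R$), the model
predicts self-block: flux rises, peaks, and collapses toward
$k^+\tilde k_R/(k^++\tilde k_R)$ at high concentration. The test suite
asserts monotonicity only under repulsion and separately asserts the
self-block behaviour outside it.

## Profile analysis

`find_minima()` detects interior minima by *topographic prominence*
(default threshold 1 kJ/mol) rather than raw sign changes, because
simulation profiles carry $\sim$kJ/mol statistical error and sign changes
alone would report grid noise as binding sites. Depths are measured from
the bulk plateau, defined as the mean free energy over the last 10% of the
grid (`bulk_reference()`, `tail_fraction = 0.1`). Flat-bottomed wells are
represented by the leftmost grid point of the flat run; among equally deep
wells `global_minimum()` returns the one at smaller $z$. Escape barriers
(`barrier_height()`) are exhaustive maxima over the path to the grid
boundary. `unbinding_distance()` returns the smallest $z$ beyond the
global minimum from which the profile stays within `tol` (default
1 kJ/mol) of the plateau to the end of the grid; if the profile never
flattens it returns the grid end with a `converged = FALSE` attribute and
a warning. No smoothing is applied. Statistical errors on profile-derived
quantities follow block analysis (`block_error()`): split the correlated
series into contiguous blocks and take $\mathrm{sd}(\text{block means})/
\sqrt{n_\text{blocks}}$, which grows with block size until blocks exceed
the correlation time.

Profile files are plain whitespace-delimited text ($z$ in nm, $G$ in
kJ/mol, optional standard error), with `#`/`#!` comment lines tolerated so
Plumed-style FES dumps read directly.

## Electrolyte activities

Conductance saturates in the thermodynamic *activity* of the permeant, not
its concentration. For a 1:1 salt (ionic strength $I_c$ = concentration)
the activity coefficient is

$$\log_{10}\gamma = \frac{-0.509\,z^2\sqrt{I_c}}{1 + 3.28\,d\,\sqrt{I_c}}
\quad (c < 100\ \mathrm{mM}), \qquad
\log_{10}\gamma = -0.509\left(\frac{\sqrt{I_c}}{1+\sqrt{I_c}} -
0.3\,I_c\right) \quad (c \ge 100\ \mathrm{mM}),$$

with $d = 0.35$ nm for DMA (`debye_huckel_log_gamma()`,
`davies_log_gamma()`, dispatched by `activity()`). Logs are base 10, the
convention under which the 0.509 coefficient applies. The branch switch at
100 mM follows the stated experimental practice; ties go to Davies, and
the discontinuity in $\gamma$ at the switch is below 0.02. The numerical
inverse (`inverse_activity()`) reports fitted constants back on the
concentration scale.

## The global dose–response fit

`global_mm_fit()` fits $g(a, V) = g_{\max}(V)\,a/(a + K)$ to
replicate-level normalized-conductance records with a single shared $K$
and one $g_{\max}$ per voltage, by unweighted least squares. Fitting
replicate records (rather than cell means) preserves information; the
voltages enter only through their $g_{\max}$, so $K$ is invariant under
voltage relabeling and record permutation (tested). Numerically the fit is
variable projection: for fixed $K$ each $g_{\max}(V)$ has a closed-form
linear least-squares solution, leaving a one-dimensional objective in
$\log K$ (positivity for free) minimized by a 200-point log-spaced grid
scan followed by `stats::optimize()` on the bracketing interval. Noiseless
data are recovered to better than $10^{-6}$ relative. Non-convergence
(objective minimized at the search boundary) is flagged, not thrown.

`bootstrap_khalf()` provides a case-resampling bootstrap CI, resampling
replicates within each (voltage, concentration) cell. With $n = 4$
replicates per cell the plain percentile interval is systematically
narrow (resampling $n$ of $n$ underestimates spread by about
$\sqrt{(n-1)/n}$), so the default interval applies Hesterberg's
expanded-percentile correction — the quantile levels are widened to
$\Phi(-z_{\alpha/2}\sqrt{n/(n-1)})$ with $n$ the smallest cell size;
`expand = FALSE` restores the plain percentile interval.

## The stochastic oracle

`simulate_trajectory()` is a direct Gillespie simulation of the four-state
chain (C++ core): exponential waiting times at the total propensity of the
current state, exact transition selection, no tau-leaping — the rates span
seven orders of magnitude and statistical exactness is the point, since
the simulator independently verifies the analytic stationary state.
Randomness comes from R's Mersenne-Twister via `set.seed(seed)`, making
trajectories reproducible across platforms. Default trajectory length is
$1000/J_\text{analytic}$ so a run contains $\sim 10^3$ permeation events
and the flux standard error is a few percent; dwell times are accumulated
in 100 time slices so occupancies can be computed for any burn-in (default
10%) without storing multi-million-event logs. `empirical_flux()` counts
permeation events (R→E and D→L transitions) per unit time, with a
block-analysis standard error; `empirical_occupancy()` returns dwell
fractions. A small pure-R two-state simulator (`simulate_one_site()`)
plays the same role for the one-site model.

One caveat used in the tests: at low concentration the empty state is
visited less than once per trajectory ($p_E \sim 10^{-4}$ with mean E→L
waiting time $1/k_L X$), so the empirical block error of its dwell
fraction can be zero by accident. The occupancy comparisons therefore
floor the block SE with the regenerative-process error scale
$p\sqrt{2/n_\text{visits}}$, with the expected visit count taken from the
analytic inflow rate.

## What the synthetic generators emulate — and what they do not

`make_profile()` builds $G(z) = \text{baseline} - s(z)\sum_i A_i
e^{-(z-c_i)^2/2w_i^2}$, where $s(z)$ is a cubic smoothstep that clamps the
profile onto the baseline at `plateau_start` over a 0.05 nm ramp. Two
design details matter:

- *Depth calibration.* With overlapping Gaussians the realized value at a
  well centre is not the well's own amplitude, so the amplitudes $A_i$ are
  obtained from a small linear solve making $G(c_i) =
  -\text{depth}_i$ exactly. Depth relations between minima are then exact
  by construction rather than approximate.
- *Long-range component.* Each preset adds one broad fixed-amplitude
  Gaussian centred on the outermost well. It models the slow approach to
  bulk, keeping the profile more than 1 kJ/mol below the plateau until
  just before `plateau_start`, so the detected unbinding distance is the
  plateau onset (2 nm one-ion, 1 nm two-ion) rather than the edge of the
  last narrow well.

The one-ion preset (`profile_spec_single_ion()`) places S3/S4/SX/S0 at
$z = 0.25/0.55/0.90/1.30$ nm with depths $37.4/34.4/8/12$ kJ/mol; the
two-ion preset (`profile_spec_two_ion()`) has a single 12.4 kJ/mol well.
The *positions and widths are free design choices* — only the depth
relations (3 kJ/mol S4–S3 offset, 25 kJ/mol two-ion reduction, 15 $k_BT$
global depth) and the plateau onsets carry meaning. Generated profiles are
deterministic; they carry no statistical noise, no metadynamics
reconstruction error, no multi-branch exit paths, and no 2-D structure, so
tests passing on them demonstrate correctness of the *analysis*, not
robustness to every pathology of real free-energy surfaces.

`make_conductance()` emulates the dose–response experiment: concentrations
20/50/110/250 mM, voltages +140 to +200 mV with $g_{\max}$ increasing
linearly with voltage, $n = 4$ replicates, multiplicative Gaussian noise
with 5% CV (the data are reported as mean ± SD without a stated noise
model; multiplicative noise matches conductances spanning a decade), and
normalization to the mean of the (+200 mV, 110 mM) cell. The generating
half-activation constant, 52 mM, is applied on the concentration scale and
converted through the activity map, so the fitted constant converts back
to the concentration scale for comparison. Real records additionally carry
leak currents, rundown, patch-to-patch $g_{\max}$ variability and
correlated noise, none of which are modelled.

`make_ar1_series()` provides a correlated Gaussian fixture with known
autocorrelation for exercising block analysis.

## Problem sizes and numerical choices

Defaults keep every analysis interactive on one CPU: profiles use a
0.01 nm grid (301/201 points); Gillespie runs target $10^3$ permeation
events ($4\times10^4$–$5\times10^6$ transitions depending on
concentration, well under a second in the C++ core); the fit's grid scan
uses 200 points; bootstrap and coverage checks use 100–200 resamples.
Linear solves are dense 4×4 (`base::solve`); probabilities are clipped to
$[0,1]$ after the solve to absorb round-off at extreme rate ratios (the
balance residuals are still verified to $10^{-10}$ in tests). Tie-breaks:
equally deep minima resolve to smaller $z$; flat well bottoms to their
leftmost point; the activity branch boundary at exactly 100 mM to Davies.

## Known limitations

- Rates carry an undetermined common prefactor; absolute fluxes are not in
  physical units, and $k_L$ is a convention (1 prefactor·M$^{-1}$), so
  half-activation values are order-of-magnitude statements.
- The kinetic model has no voltage dependence and no backward crossing; it
  describes the strongly outward-rectified regime only.
- At most two ions are modelled; no mixed-species competition.
- Activity corrections assume a fully dissociated 1:1 salt; no Pitzer/SIT
  extensions.
- The dose–response fit deliberately fits only the Michaelis–Menten form:
  the one- and two-site models share that functional form, so curve shape
  cannot distinguish them — that indistinguishability is the point of the
  analysis, not a gap in it.
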