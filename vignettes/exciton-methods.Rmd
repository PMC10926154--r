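---
title: "Exciton models, electric fields and simulated spectroscopy for chlorophyll networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exciton models, electric fields and simulated spectroscopy for chlorophyll networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(excitonic)
```

## The system and the model

Fucoxanthin–chlorophyll proteins (FCP) are the light-harvesting antennae of
diatoms.  One protomer binds a network of nine chlorophylls — seven Chl-a and
two Chl-c (in the reference structure the Chl-c2 sits at residue slot 403 and
the Chl-c1 at 408) — whose lowest singlet (Q~y~) excitations form a Frenkel
exciton system

$$H \;=\; \sum_n (E_n+\delta E_n(t))\,|n\rangle\langle n| \;+\;
        \sum_{n\neq m} J_{nm}\,|n\rangle\langle m|,$$

with site energies $E_n$ (cm^-1^), excitonic couplings $J_{nm}$ (cm^-1^) and
transition dipoles $\mu_n$ (Debye).  The interesting physics of this antenna
is that in vacuum or organic solvent the Chl-c site energies lie *above*
Chl-a, while inside the protein directed electric fields push the Chl-c
energies *below* the Chl-a band, inverting the energy ladder.  `excitonic`
implements the full analysis chain around that observation: ladder ranking,
electrostatic analysis at the chlorophyll ring atoms, bath spectral
densities, cumulant linear absorption with pool decomposition, and NISE
population dynamics / two-dimensional electronic spectroscopy (2DES).

All internal units are spectroscopic: energies in cm^-1^, time in fs, with
the phase convention $\exp(-i\,2\pi c\,E\,t)$; `exc_const` collects every
conversion factor from CODATA values (e.g. the point-dipole prefactor
$f \approx 5034\,$cm^-1^Å^3^/D^2^ and 1 au of electric field
= 51.422 V/Å — note that 0.01 au is 0.514 V/Å).

## Electric-field analysis

`ring_frame()` puts a chlorophyll into a canonical frame: ring nitrogens in
the $z=0$ plane, their centroid at the origin, and the in-plane $y$ axis
along the NC→NA direction (the Q~y~ axis through the NA/NC pair), with the
$+z$ normal chosen so NA→NB→NC→ND circulate counterclockwise.  This is a
deterministic geometric convention.  Studies that instead rotate the ring
until a test field along $y$ has maximal effect fix the in-plane angle
spectroscopically; the two conventions can differ by an in-plane rotation, so
comparisons of tabulated field components across conventions should be made
on sign patterns, not element-wise values.

`coulomb_field()` evaluates bare point-charge sums in atomic units (no
polarization, no screening), `field_report()` tabulates the components at
MG and NA–ND and flags positive-$y$ components — the direction the Chl-c
excitation energies are most susceptible to.  `scan_shifts()`,
`susceptibility_ratio()` and `difference_dipole_fit()` analyse
energy-versus-field scans; the packaged scan table (`chl_field_scan()`)
yields a maximal Chl-c shift of −0.252 eV against −0.051 eV for Chl-a, a
4.94 ≈ 5-fold susceptibility ratio, and a linear Stark model
$\Delta E = -\Delta\mu\cdot F$ whose residuals expose how strongly
asymmetric the true Chl-c response is (the +y and −y responses differ by an
order of magnitude, so $\Delta\mu$ alone is a coarse summary).

## Spectral densities and synthetic trajectories

The bath enters through spectral densities $J(\omega)$.  Two model forms are
provided: the overdamped Drude term
$J(\omega)=2\lambda\gamma\omega/(\omega^2+\gamma^2)$ and underdamped
intramolecular modes
$J(\omega)=2\lambda_j\omega_j^2\gamma_j\omega/((\omega^2-\omega_j^2)^2+\gamma_j^2\omega^2)$,
both normalized so $(1/\pi)\int J/\omega\,d\omega=\lambda$.  Because the
Drude tail decays only as $1/\omega$, model grids are log-spaced
(`sd_grid()`) and wide enough for the reorganization integral to converge to
a few tenths of a percent.

`sample_trajectory()` synthesizes stationary Gaussian site-energy
fluctuations with the classical fluctuation–dissipation correlation function

$$C(t) = \frac{2 k_B T}{\pi}\int_0^\infty
  \frac{J(\omega)}{\omega}\cos(2\pi c\,\omega t)\,d\omega,$$

so the variance is $2k_BT\lambda$; the power spectrum is integrated over
each FFT bin rather than point-sampled, which makes the variance match the
target on the stored grid essentially exactly.  `sd_from_trajectory()`
inverts this with the matching prefactor
$J(\omega)=2\pi c\,\beta\,\omega\int_0^\infty C(t)\cos(2\pi c\,\omega t)\,dt$
(unbiased autocovariance, Hann window, 4× zero padding), so
extraction∘synthesis is an identity in expectation — the module's central
property test, verified to better than 10% RMS on the support with a
20-trajectory ensemble, and independently against the closed-form
Ornstein–Uhlenbeck ↔ Drude correspondence
$\gamma = 1/(2\pi c\,\tau)$, $\lambda = \beta\sigma^2/2$.
The default lag window is a quarter of the series and extraction averages
all available site columns: variance suppression was preferred over spectral
resolution because the target features (widths ≥ 40 cm^-1^) are much broader
than the window resolution.

The default FCP-like spectral densities (`fcp_default_sds()`) are synthetic
stand-ins chosen once: both pools share Drude $\lambda=40$, $\gamma=40$
cm^-1^; Chl-a adds modes at 750, 1150, 1520 cm^-1^ ($\lambda$ = 25/35/35
cm^-1^, $\gamma_j=100$ cm^-1^), Chl-c the same modes at 0.3× intensity.
These reproduce the qualitative structure the analysis needs — a Chl-a
dominated vibronic sideband about 900–1700 cm^-1^ above the main peak that
disappears when the spectral densities are truncated above 800 cm^-1^ — but
they are not extracted protein spectral densities; quantitative features of
real FCP data (mode positions, relative weights, possible site specificity)
are not emulated, and passing tests show the machinery is correct, not that
real FCP behaves identically.  A $\gamma_j$ of 100 cm^-1^ (fast vibrational
dephasing) keeps the synthetic trajectories short-memory; narrower modes
would need longer trajectories for the same statistics.

## Cumulant absorption

`lineshape_g()` computes the second-order cumulant lineshape function

$$g(t)=\frac{1}{\pi}\int_0^\infty d\omega\,\frac{J(\omega)}{\omega^2}
  \Big[\coth(\beta\omega/2)\,(1-\cos 2\pi c\omega t)
  + i(\sin 2\pi c\omega t - 2\pi c\omega t)\Big],$$

with $\mathrm{Im}\,g(t)/t \to -2\pi c\lambda$.  `absorption_cumulant()` uses
the secular approximation for excitons: $g_k(t)=\sum_n |c_{nk}|^4 g_n(t)$,
which is exact for uncoupled aggregates (a test) and a standard, documented
approximation otherwise; the non-secular corrections of full second-order
cumulant implementations are intentionally out of scope, with the NISE route
(below) serving as the second, independent absorption engine.

Each exciton line is centred at its vertical energy $E_k$:
$A(\omega)\propto\omega\sum_k|\mu_k|^2\,\mathrm{Re}\int_0^\infty
e^{i2\pi c(\omega-E_k)t}e^{-g_k(t)}dt$.  With this centring the first moment
of $A(\omega)/\omega$ equals $E_k$ exactly (the cumulant sum rule used as an
oracle test) and the motional-narrowing limit puts the Lorentzian at
$E_k-\lambda_k$, the 0–0 line, as it must.  Centring at $E_k-\lambda_k$
with the same $g$ convention would break both properties, so the vertical
centring was adopted.  Consequences worth knowing: truncating the spectral
densities above 800 cm^-1^ lowers every $\lambda_k$, so the truncated
spectrum sits slightly *higher* in energy — the same effect that makes a
truncated calculation need a larger rigid shift when aligned to an
experimental curve (`align_shift()` reports exactly that rigid shift, at
grid resolution).  Oscillator strength is conserved under truncation to
within 2% (the $\omega$ prefactor moves slightly with the peak).

No static disorder is added anywhere: site energies are fixed parameters and
all broadening comes from the dynamic bath.

## NISE dynamics and 2DES

`propagate()` integrates the Schrödinger equation over a fluctuating
Hamiltonian, holding $H(t_i)$ constant across each trajectory step and
applying its exact eigendecomposition propagator, which is unitary to
machine precision (norm drift is checked and bounded at 1e-6; measured
drift is ~1e-12/ps).  The default step of 2 fs resolves the exciton band in
a rotating frame at the mean site energy (Nyquist ±8340 cm^-1^).  Couplings
are static — the Hamiltonian is a time-averaged one plus site-diagonal
fluctuations — and cross-site fluctuation correlations are not modelled.

`pool_transfer()` averages populations over ensemble realizations and over
initial conditions (each donor-pool site in turn).  Because the classical
bath has no detailed balance, NISE relaxes toward equal site populations at
long times rather than a Boltzmann distribution; the resonant-dimer test
checks exactly this limit.  On the synthetic FCP network (largest a↔c
coupling clamped at 25 cm^-1^) transfer into the Chl-c pool is slow:
$P_c(100\,\mathrm{fs}) < 0.1$, rising on the picosecond scale, in line with
a Förster estimate from `forster_transfer_time()`
($k = 2\pi\,(2\pi c)\,J^2\,\int L_D L_A\,d\omega$; with 25 cm^-1^ and
realistic overlaps this gives roughly a picosecond).

`response_2d()` accumulates the six impulsive third-order pathways (GSB, SE,
ESA × rephasing/non-rephasing) with cumulative NISE propagators in the one-
and two-exciton manifolds (hard-core bosons, no anharmonicity parameter —
standard for chlorophyll Q~y~ manifolds), isotropically averaged for
parallel ⟨xxxx⟩ polarization via the three pair-contraction weights, and
2D-Fourier transformed with the rotating-frame carrier.  Sign conventions
are bleach-positive; the arcsin contrast map in `autoplot()` is a display
transform only.  Two structural identities serve as standing regression
tests: a single two-level site has identically zero ESA, and for uncoupled
sites the ESA cancels the GSB/SE cross-peak pathways exactly
(per-realization, to machine precision in the time domain).  A Gaussian
apodization along $t_1$/$t_3$ (default $\tau = t_{max}/5$) suppresses
truncation sidelobes below 1e-8 of the maximum so that frequency-domain
checks of this cancellation are meaningful; single-realization spectra still
carry slowly decaying dispersive wings, which is why the fluctuating-case
regression test compares against the exact sum of isolated-site spectra
instead of an empty window.

`diagonal_trace()` reduces a waiting-time series of 2D maps to the mean
signal in a square diagonal region, normalized at $t_2=0$ — the main-peak
(14800–15000 cm^-1^) and vibronic (16100–16400 cm^-1^) regions of the FCP
literature land on the synthetic network's main band and Chl-a vibronic
sideband by construction.  On the stand-in the main-peak trace evolves
slowly (a few percent over 100 fs), as expected for excitons that neither
relax out of the band nor spectrally diffuse on that time scale.  The
vibronic *diagonal* amplitude, by contrast, is second order in the sideband
strength, and with the deliberately modest synthetic mode intensities it
amounts to only ~0.1% of the main peak — at the ensemble noise floor even
for 100 realizations — so its normalized waiting-time value is
noise-dominated here and is reported, not asserted, by the acceptance
script; with strongly vibronic (protein-derived) spectral densities the same
machinery resolves the fast-damped oscillation of that peak.

## Numerical choices

* **Problem sizes.** Tests and the acceptance script run 9-site networks,
  trajectory ensembles of 8–32 realizations of 1024–4096 steps at 2 fs, 2DES
  coherence windows of 128–256 fs, and spectra on 1–20 cm^-1^ grids.  These
  sizes give stable statistics for every asserted quantity while keeping a
  full run on one CPU in minutes; they are stated here as the package's
  reference configuration.
* **Grids.** Spectral densities: log grids (4096 points); absorption: 1
  cm^-1^ output grid from a ≥65536-point zero-padded half-FFT; 2DES: 4×
  zero-padded 2D FFT, bilinear interpolation onto the requested axes.
* **Ties and signs.** Energy-ladder ties break lexicographically by label;
  eigenvector signs are fixed by making the largest-magnitude coefficient
  positive; 2DES rephasing/non-rephasing halves are combined into the purely
  absorptive real part.
* **Degenerate inputs.** Zero spectral densities give exactly zero
  trajectories, lineshapes and (flagged) infinite Förster times; flat
  spectra refuse to align; collinear ring nitrogens and coincident
  charge/evaluation points are hard errors.
* **Determinism.** Every stochastic element is seeded; identical
  (configuration, seed) reproduce byte-identical pipeline artifacts, and the
  ensemble builder derives per-site, per-realization seeds from one master
  seed.

## Known limitations

The synthetic spectral densities and geometries stand in for QM/MM-derived
inputs; absolute spectra and absolute trace values are therefore
illustrative.  The secular cumulant neglects exciton-mixing corrections;
NISE neglects detailed balance (no Stokes shift, equal-population long-time
limit) — the two engines bracket these approximations and agree on peak
positions for fast, weakly coupled baths (tested at 20 cm^-1^).  Pulse
envelopes are not convolved: 2DES is impulsive, so laser-filtering effects
seen in experiments (e.g. suppressed oscillations) are outside the model.
Charge environments are fixed point charges; polarization, induced dipoles
and field gradients are not modelled.  Chl-c1 vs c2 assignment from PDB
residue names requires a user-supplied residue map, since the names do not
distinguish the variants.
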