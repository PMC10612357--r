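---
title: "Profiling kinase variant stability and kinetics with kinstab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling kinase variant stability and kinetics with kinstab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinstab)
```

## Scope and data model

`kinstab` reduces the solution-biophysics characterisation of protein
kinase missense variants to comparable numbers: thermodynamic stability
from chemical equilibrium unfolding, apparent thermal stability from CD
melts, and catalytic parameters from fluorogenic activity assays, joined
into a per-variant comparison ledger against the wild type. The package
operates on instrument-style tabular data (wavelength scans, signal vs
denaturant, signal vs temperature, fluorescence vs time) and never on
proprietary instrument formats. Because no raw spectra are publicly
deposited for the MAPK1/MAPK3 variant panels the reference tables describe,
a first-class synthetic-data generator reproduces the statistical structure
of every input; all tests and the acceptance script run on generated data
plus the packaged parameter tables.

## Spectroscopic observables

Fluorescence emission spectra are summarised by the intensity-averaged
emission wavelength, the intensity-weighted mean
\(\bar\lambda = \sum_i I_i \lambda_i / \sum_i I_i\). It is an integral
measure, robust to point noise, bounded by the scanned range, and invariant
to rescaling of the intensities; red shifts report solvent exposure of
tryptophans, i.e. loss of tertiary packing. (This quantity occasionally
appears in print with the wavelength inverted inside the sum; that form has
units of inverse wavelength and cannot equal a value in nm, so the
conventional weighted mean is implemented.) CD signals are normalised to
mean residue ellipticity with a default mean residue mass of 110 g/mol,
overrideable per protein.

### Counting states by SVD

A series of far-UV spectra along a denaturation coordinate is arranged as a
wavelength-by-condition matrix and decomposed by SVD. The number of
components distinguishable from noise estimates the number of independent
spectral species: 2 for a two-state transition, 3 when an intermediate is
populated. Two policies are exposed because no universal criterion exists:

* **singular value** (default): retain components whose singular value
  exceeds 5 times the median of the trailing half of the singular spectrum
  (an estimate of the noise floor), with an absolute floor of
  \(10^{-8} s_1\) so that noiseless low-rank matrices are not over-counted
  from floating-point residue;
* **autocorrelation**: retain components whose basis spectrum has
  non-centred lag-1 autocorrelation at least 0.8 — signal spectra are
  smooth in wavelength, noise vectors oscillate. The criterion is applied
  to the wavelength-side vectors only: condition grids are short (often
  around 10 points), where the statistic is too diluted to discriminate.

The rank-truncated reconstruction is returned as a denoised series.
Whether denoising should precede transition-curve fitting or serve only
for component counting is left to the user: `svd_analyze()` returns both
the rank and the denoised series, and the fitting functions accept either
the raw or the denoised observable.

## Equilibrium unfolding

The two-state linear extrapolation model assumes the unfolding free energy
is linear in denaturant, \(\Delta G(x) = \Delta G_{H_2O} - m x\), giving

\[ y(x) = \frac{y_N + s_N x + (y_U + s_U x)K(x)}{1 + K(x)}, \qquad
   K(x) = e^{-\Delta G(x)/RT}, \]

with linear native and unfolded baselines. The midpoint identity
\([\mathrm{GdmCl}]_{0.5} = \Delta G_{H_2O}/m\) holds exactly on every fit
by construction. The three-state model adds an intermediate with constant
signal \(F_I\) and per-step midpoints and m values (N→I and I→U), with
linear baselines on the native and unfolded states only. All free energies
and m values are in kcal units with
\(R = 1.987\times10^{-3}\) kcal mol\(^{-1}\) K\(^{-1}\); the default fit
temperature is 283.15 K (10 °C), the temperature at which such unfolding
series are typically acquired.

**Initialisation and bounds.** Baselines start from linear fits to the
first and last 15% of points; midpoints from the extrema of a smoothed
first derivative of the series (the two largest, for the three-state
model, falling back to the 1/3 and 2/3 points of the range); m starts at
1.5 (two-state) or 2.0 (each three-state step) kcal/mol/M and is bounded in
(0, 20]. Fits use Levenberg–Marquardt least squares driven directly on the
residual vector, so exact-fit (noiseless) problems converge cleanly;
standard errors come from the Gauss–Newton covariance.

**Bracketing.** A series whose fitted native population never reaches 70%
at the low end, or whose unfolded population never reaches 70% at the high
end, lacks a baseline and is refused (`unbracketed_transition`) rather than
extrapolated.

**Shared-m global fits.** Replicates of one probe can share a single m
value, the standard way to stabilise the strongly correlated
\((\Delta G, m)\) pair. Sharing across probes is deliberately not the
default: CD and fluorescence report different structural transitions and
published m values differ between probes for essentially every variant.

**Model selection.** Both models are fitted and compared by corrected AIC;
the three-state model must improve AICc by more than 2 (parsimony
tie-break), and an SVD rank of 3 or more overrides the criterion, since a
third independent spectral component is direct physical evidence of an
intermediate. Residual sums of squares are floored at
\((10^{-8}\,\mathrm{span})^2 n\) before entering AICc: on noiseless data
both models reach machine-precision residuals and the log-RSS difference
would otherwise be arbitrary.

**Realistic precision.** With all six two-state parameters free, a single
30-point series at noise σ = 2% of the signal span carries limited
information: the Cramér–Rao bound on \(\Delta G_{H_2O}\) at the wild-type
MAPK1 CD parameters is ≈ 0.30 kcal/mol, and the package's estimator
attains it (unbiased, dispersion matching the reported standard errors —
see the property tests). The triplicate shared-m global fit reduces this
to ≈ 0.17–0.19 kcal/mol, matching the ±0.22 uncertainties typical of
published global fits. Single-series fits at this noise level should not
be expected to pin \(\Delta G_{H_2O}\) better than a few tenths of a
kcal/mol; midpoints are far better determined.

## Thermal melts

Melts of θ222 versus temperature (20→90 °C, 0.5 °C steps, 1 °C/min) are
irreversible for these kinases, so only apparent melting temperatures are
extracted — no van't Hoff enthalpy. The derivative dθ/dT is estimated with
a Savitzky–Golay first-derivative filter (order 2, default window 5 °C);
edge estimates from one-sided windows are excluded. Peaks are accepted by
*topographic prominence* — height above the higher col connecting the peak
to higher terrain, clamped at the zero baseline — at a threshold of 10% of
the global derivative maximum. Prominence, unlike raw derivative height,
rejects noise bumps riding on the shoulder of a genuine transition, which
is what makes biphasic calls trustworthy. The sign of the dominant
derivative extremum orients the search, so results are invariant to affine
transformations of the signal (mdeg vs MRE, instrument polarity). Peak
positions are refined by parabolic interpolation around the discrete
maximum and reported to 0.1 °C.

The 5 °C default window was chosen over narrower settings after direct
measurement: at 2% (of span) signal noise a 2.5 °C window admits multiple
spurious prominent peaks per scan, while 5 °C gives a single clean Tm
across seeds and still resolves transitions separated by about three
transition widths (the practical limit for derivative methods regardless
of window).

## Enzyme kinetics

Progress curves from the chelation-enhanced fluorescence assay are linear
early on; the initial rate is the least-squares slope over the earliest
window satisfying both caps — 60 s and 10% substrate conversion — divided
by the fluorescence-per-product calibration, which is an explicit input
(it is instrument- and peptide-batch-specific and not recoverable from the
data). A slope more than 3 standard errors below zero marks an invalid
assay rather than a zero rate.

Rates over 10 substrate concentrations spanning 0.069–40 µM are fitted to
\(v = V_{max} S/(K_m + S)\); \(k_{cat} = V_{max}/[E]\) (enzyme in µM, from
nM input) and \(k_{cat}/K_m\) follow exactly from the fitted parameters,
so the unit identities hold on every result. A fitted \(K_m\) above the
largest assayed substrate concentration triggers a poor-saturation
warning.

The temperature of maximal activity is taken from the measured grid with
no interpolation (ties resolve to the lower temperature, with a warning; a
maximum on the grid edge warns that the optimum may lie outside the
scanned range). The activation energy is fitted nonlinearly to
\(k = A e^{-E_a/RT}\) on the points at or below \(T_{max}\) only — activity
above \(T_{max}\) reflects inactivation, not the catalytic barrier, and is
excluded rather than silently fitted. The log-linear (Arrhenius-plot)
estimator is retained as an independent check; the two agree to machine
precision on clean data.

## The comparison ledger

Variants are classified by their relation to the common docking site from
a packaged lookup table (group I: mutated residue interacting with the
CD-site; II: in the CD-site; III: elsewhere), shipped as data so other
kinase panels can reuse the reporter. Ledger rows hold variant-minus-wild-
type differences (ΔTm for the NP and P forms, ΔT_max, ΔE_a) and the
catalytic efficiency ratio; tertiary-structure-change and three-state
unfolding flags are recorded judgements, not inferences. Ratios are
formatted to 3 significant figures, scientific below \(10^{-2}\). The
packaged reference tables list efficiencies as reported (rounded) values,
and the ledger's ratios are computed from those columns, which is also how
the published derived cells were produced; recomputing from unrounded
kcat/Km can shift the third significant figure.

## The synthetic-data generator

Each generator evaluates the corresponding forward model on a realistic
grid and adds homoscedastic Gaussian noise, default σ = 2% of the
noiseless span (replicate-level information about heteroscedasticity is
not available from the reference data). Defaults mirror the experiments:
denaturant 0–8 M in 0.25 M steps at 283.15 K; melts 20–90 °C every 0.5 °C;
progress curves 0–300 s; substrate 0.069–40 µM (10 log-spaced
concentrations); assay temperatures {10, 15, 20, 25, 30, 35, 37, 40, 42,
45} °C. Every generator returns its truth record, and identical seeds give
identical bytes without disturbing the caller's RNG stream.

Two stand-ins deserve emphasis. Thermal melts are generated as one or two
logistic transitions — the derivative extremum of a logistic sits exactly
at its centre, which is what makes the generator a valid oracle for the Tm
detector. Activity above \(T_{max}\) declines by a logistic inactivation
factor whose only purpose is to give the \(T_{max}\) finder an interior
maximum; it is not a physical model of thermal inactivation, and the
ascending limb remains exactly Arrhenius so activation energies round-trip
exactly. Progress curves integrate true substrate depletion
(\(dS/dt = -V_{max}S/(K_m+S)\), stiff-safe lsoda), so the initial-rate
window policy is exercised against genuine curvature.

What passing tests on these data do *not* show: robustness to baseline
drift, photobleaching, heteroscedastic or correlated noise, aggregation
during melts, or product inhibition — none of which the generator
emulates. Results on real instrument data should be inspected with those
failure modes in mind.

## Numerical choices and limitations

* Levenberg–Marquardt on raw residuals throughout; bounds only where
  physically required (m > 0, rates ≥ 0). Convergence failures raise
  classed errors; m values at bounds raise a boundary warning.
* The spectroscopic, unfolding and kinetic worked examples reproduce the
  packaged reference values to their printed precision; fitted parameters
  for the *variant* panels are not reproducible without the raw
  instrument data, which were never deposited — the packaged tables serve
  as generator truths and comparison inputs, not as fit targets.
* Problem sizes in the test-suite and acceptance script (200-seed Monte
  Carlo for the stochastic checks, 30–33-point series, 10-point kinetic
  grids) match the reference experiments' designs; they complete in a few
  seconds.
* The three-state fit estimates 9 parameters from one series; with fewer
  than ~25 points or overlapping transitions the (D50, m) pairs correlate
  strongly. The model-selection parsimony rule exists precisely so such
  fits are not over-interpreted.
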