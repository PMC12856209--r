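---
title: "Methods: spectroscopic analysis of G-quadruplex/duplex equilibria"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectroscopic analysis of G-quadruplex/duplex equilibria}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pentaspec)
```

## Scope and scientific background

Guanine-rich short tandem repeats can fold into G-quadruplexes (G4s) —
four-stranded structures of stacked G-tetrads stabilized by K⁺ — but
purine-rich motifs can also adopt noncanonical duplexes, and the two folds
may coexist in equilibrium. The WGGGW pentanucleotide family (W = A or T),
which includes the CANVAS-associated AGGGA motif expanded in the RFC1 gene,
is a prime example: depending on the repeat motif, the repeat number and the
cation (K⁺ versus Li⁺), a strand may fold into intramolecular or
intermolecular G4s, into homopurine duplexes, or remain unstructured.

`pentaspec` implements the spectroscopic workflow used to dissect such
equilibria from UV-absorption and circular dichroism (CD) data:

1. **Repeat design arithmetic** — matched-concentration series (strands at
   `base/n` µM so each sample carries the same concentration of potential G4
   units and G-tetrads), G-run counting, and predicted species sizes for gel
   interpretation.
2. **Melting analysis** — baseline correction against a transparent
   wavelength (335 nm), melting temperature (Tm) from derivative extrema,
   hysteresis quantification with midpoint Tm.
3. **Thermal difference spectra (TDS)** — high-temperature minus
   low-temperature absorbance spectra, and cosine-similarity classification
   against signature templates.
4. **CD decomposition** — the non-G4 fraction *f* of a measured CD spectrum
   as the least-squares convex combination of a pure-G4 and a pure-non-G4
   reference; composite spectra of multi-G4-unit structures.
5. **Synthetic data** — equilibrium and kinetic two-state melting
   simulations and Gaussian-band spectra that stand in for instrument data.

## Design arithmetic

For a motif repeated `n` times, maximal runs of ≥ 3 consecutive guanines are
counted 5′→3′; four such runs fold one potential G4 unit (grouped greedily
left-to-right, matching 1, 2, 3, 4 contiguous units for n = 4, 8, 12, 16 in
WGGGW series). Each G3-based unit stacks three tetrads, so

- unit concentration = ⌊runs/4⌋ × strand concentration,
- tetrad concentration = 3 × unit concentration.

With strands at `24/n` µM every member of a series carries 6 µM potential
units and 18 µM potential tetrads, making TDS, melting amplitudes and CD
intensities directly comparable:

```{r}
design_table("AGGGA")
```

Predicted species sizes assume a full-register two-strand duplex
(`n × motif length` bp), a half-length intramolecular hairpin, or a
full-length intramolecular G4. Slipped (partial-register) duplexes are not
enumerated.

## Tm from derivative extrema

To avoid assuming a two-state transition or fitting high/low-temperature
baselines, Tm is defined operationally as the temperature of the extremum of
dA/dT. The derivative is computed by local-polynomial (Savitzky–Golay-type)
least squares: window of 11 points, degree 2, differentiated analytically,
with shrunken one-sided windows at the series ends. The window preserves
the extremum position for ramps sampled at ≤ 0.5 °C, which is what Tm uses;
the smoothed derivative's amplitude is attenuated by a few parts in a
thousand through sharp transitions, which is why the package reports the
extremum temperature rather than derivative magnitudes.

A transition is called only when the extremal |dA/dT| (interior points,
5 excluded at each edge) exceeds `noise_k = 5` times a robust noise scale —
1.4826 × the median absolute deviation of dA/dT over the coolest and hottest
10 % of points — with a machine-precision floor so numerically flat curves
never count. This operational rule is needed because real series contain
"no transition" cases. The transition amplitude is the absolute difference
between the median corrected absorbance of the 5 lowest- and 5 highest-
temperature points; no baselines are fitted.

Cooling/heating hysteresis indicates a ramp outpacing folding/unfolding
kinetics. The midpoint Tm is `(Tm_cooling + Tm_heating)/2` exactly, and the
pair is flagged hysteretic when the branches differ by more than 1.0 °C by
default (the scale of instrument Tm repeatability; configurable).

## TDS and signature classification

`compute_tds()` subtracts the low-temperature (folded) absorbance spectrum
from the high-temperature (unfolded) one on a common 1-nm grid (the
intersection range of the two spectra; linear interpolation). The TDS shape
is a structural fingerprint. `classify_signature()` scores a TDS or CD
spectrum against a template library by cosine similarity of mean-centered
vectors on a 220–335 nm window — scale- and offset-invariant by
construction — and accepts the best label at a threshold of 0.80, reporting
`unclassified` otherwise (an all-zero spectrum scores 0).

## Two-basis CD decomposition

When G4 and non-G4 folds coexist, the measured CD spectrum is modelled as

CD_calculated(*f*) = *f* · CD_non-G4 + (1 − *f*) · CD_G4,

where the G4 basis is the CD spectrum of a same-length pure-G4 reference
(e.g. a TGGGT series in K⁺) and the non-G4 basis the same oligo family under
non-G4 conditions (Li⁺), both at the same per-unit design concentration.
The package requires caller-supplied bases rather than normalizing spectra
itself; comparability of the references is the caller's responsibility and
the central modelling assumption.

SSR(*f*) = Σᵢ [CD_measured(λᵢ) − CD_calculated(*f*, λᵢ)]² is exactly
quadratic in *f*. `estimate_fraction()` reports both the coarse-grid argmin
over *f* = 0.1 … 0.9 (step 0.1, ties broken toward smaller *f* for
determinism) and the closed-form continuous minimizer — the least-squares
projection of (measured − CD_G4) onto (CD_non-G4 − CD_G4) — clamped to
[0, 1], which removes grid-resolution bias. A basis whose two vectors are
within 10⁻⁶ rad of proportionality is rejected as ill-posed. The SSR window
defaults to the full common grid and can be restricted.

Composite spectra of structures with *m* G4 units are per-unit weighted
means Σwⱼ·Sⱼ / Σwⱼ, consistent with spectra recorded at equal
potential-unit concentration.

```{r}
grid <- 230:320
basis <- basis_set(
  grid,
  cd_g4 = 6 * exp(-(grid - 264)^2 / 98) - 3 * exp(-(grid - 245)^2 / 98),
  cd_non_g4 = 3 * exp(-(grid - 280)^2 / 98) - 3 * exp(-(grid - 258)^2 / 98)
)
mix <- generate_mixture_spectrum(basis, f_true = 0.55, noise_sd = 0.1, seed = 1)
glance(estimate_fraction(mix, basis))
```

## Synthetic data: what it emulates, and what it does not

The generator provides every input the pipeline needs, under a mass-action
two-state model with van't Hoff thermodynamics: K(T) = exp(−(ΔH° − TΔS°)/RT)
with R = 1.987 cal mol⁻¹ K⁻¹ and T in Kelvin (0 °C = 273.15 K). The folded
fraction θ is defined per strand — the quantity absorbance reports — giving
θ = K/(1+K) for molecularity 1 and θ = m·K·C_T^(m−1)·(1−θ)^m for
molecularity m ∈ {2, 4}, solved by bisection (the unique root on (0, 1)).
Closed-form melting temperatures follow from θ = ½: Tm(K) = ΔH/ΔS for
m = 1, ΔH/(ΔS + R ln C_T) for m = 2, and ΔH/(ΔS − R ln 2 + 3R ln C_T) for
m = 4; each is cross-checked against bisection to < 0.01 °C in the test
suite. Intermolecular Tm increases with strand concentration, mirroring the
diagnostic used to assign molecularity experimentally.

Kinetic ramps integrate dθ/dt = m·k_f(T)·C_T^(m−1)·(1−θ)^m − k_u(T)·θ along
a linear temperature program, with Arrhenius folding rates and the
unfolding rate derived from detailed balance, k_u = k_f/K(T), so the
synthetic kinetics can never contradict the thermodynamics. The integrator
is `deSolve::lsoda` with rtol 10⁻⁸/atol 10⁻¹⁰: the fast-kinetics limit of
this system is stiff (rates spanning many orders of magnitude along one
ramp), which a fixed-step explicit scheme cannot cover at any affordable
step size, while lsoda switches methods automatically and reproduces the
equilibrium limit to < 10⁻³ in θ.

Spectra are sums of Gaussian bands with presets for the classic signatures:
parallel G4 CD (+264/−245 nm), antiparallel G4 CD (+295/−265), hybrid G4
CD, non-G4 homopurine duplex CD (+280/−258, the diagnostic the decomposition
relies on), and a G4-type TDS (+243, +273, −295). Band widths (σ ≈ 7 nm)
keep the grid extrema of two-band presets at their nominal centers on a
1-nm grid.

Three model presets mirror the regimes the analyses must distinguish; their
parameter values are simulation conventions chosen once for qualitative
regime matching (no measured ΔH°/ΔS° or rate constants exist for these
systems), not measured quantities:

- `intramolecular_G4` — molecularity 1, ΔH° = −55 kcal/mol, Tm = 71 °C,
  melting amplitude 0.05; no hysteresis at any rate.
- `bimolecular_duplex` — molecularity 2 at 2 µM strands,
  ΔH° = −60 kcal/mol, Tm = 53 °C; Tm shifts with concentration.
- `bimolecular_G4_slow` — molecularity 2 at 1.5 µM strands,
  ΔH° = −80 kcal/mol, Tm = 58 °C, amplitude 0.02, with slow association
  (k_f(Tm) = 400 M⁻¹s⁻¹, activation energy −12 kcal/mol; negative
  association activation energies are typical of nucleic-acid folding).
  Dissociation, fixed by detailed balance, is slow below Tm, producing
  heating−cooling Tm gaps of ≈ 15 °C at 2 °C/min, ≈ 1.5 °C at 0.2 °C/min
  and ≈ 0 at 0.02 °C/min.

Baselines are linear in temperature with equal folded/unfolded slopes
(10⁻⁴ A/°C), i.e. a temperature-independent folded–unfolded absorbance
difference. What the generator does **not** emulate: multi-state or
coupled equilibria (e.g. simultaneous G4 *and* duplex folds on one strand),
wavelength-dependent baselines, instrument drift other than the linear
term, correlated noise, and photometric nonlinearity. Passing tests
therefore demonstrate correctness of the arithmetic and estimators under
the stated model, not robustness to every artefact of real instrument data.

## Numerical choices

- Gas constant 1.987 cal mol⁻¹ K⁻¹ and 273.15 K offset everywhere.
- Bisection for θ: 60 halvings (|Δθ| < 10⁻¹⁸ interval), well below the
  10⁻¹² contract.
- Wavelength arithmetic: intersection range, 1 nm step, linear
  interpolation; extrapolation is refused rather than guessed.
- Grid argmin ties in the SSR profile break toward smaller *f*.
- CSV dialect: comma separator, dot decimal, UTF-8, header required; values
  are written in shortest round-trippable decimal form so read∘write is the
  identity. Numeric parsing uses base R's correctly rounded `strtod` path,
  with errors naming the offending column and row.
- Randomness: every stochastic generator takes an explicit seed and
  restores the ambient RNG state, so pipelines are reproducible per seed
  and generators are side-effect free.

Problem sizes used in the shipped checks — ramps of 181–361 points, 100-
replicate noise calibrations, 100-point thermodynamic sweeps — were chosen
as the smallest sizes at which the tested tolerances are meaningful.

## Known limitations

- The decomposition is two-component; three-way mixtures (G4 + duplex +
  single strand) will bias *f* toward whichever basis best absorbs the
  third component.
- Tm from derivative extrema is a model-free operational statistic; for
  intermolecular species the extremum temperature is not the θ = ½
  temperature, and for hysteretic systems neither branch is an equilibrium
  Tm — the midpoint is a reporting convention, not a thermodynamic
  quantity.
- Amplitudes use the 5 extreme-temperature points and therefore
  underestimate transitions that are incomplete at the range limits (e.g. a
  G4 fraction persisting at 95 °C).
- The classifier compares whole-window shapes; it will not separate
  signatures that differ only outside 220–335 nm.
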