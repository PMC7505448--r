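---
title: "Lipid composition of plasma extracellular vesicles: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lipid composition of plasma extracellular vesicles: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evlipid)
```

# Scope

`evlipid` implements the complementary measurement chain used to
characterize the lipid composition of exosome-like vesicles isolated
from human plasma: tandem-MS lipid identification with a probabilistic
match score, MS1 chromatogram-reconstruction quantification within each
head-group class, ³¹P NMR deconvolution quantification of phospholipid
classes, and the supporting calculators for transwell blood–brain-barrier
(BBB) permeability partitions and dynamic-light-scattering (DLS)
summaries. Because no raw instrument data accompany such studies, the
package also ships a synthetic-data generator whose ground truth is an
editable setpoint file; every analysis stage is validated by parameter
recovery against that truth.

# The lipid mass library

A lipid species is a head-group class (PC, PE, PI, PS, PG, SM, the lyso
forms LPC/LPE/LPI, or cardiolipin) plus its chains in `C:D`
(carbons:double-bonds) notation, `dC:D` for the sphingoid base of SM.
Neutral formulas are assembled compositionally: glycerol + phosphoric
acid + head-group alcohol + fatty acids, minus one water per
condensation bond (two phosphoesters and one ester per chain);
sphingomyelin uses a sphingoid base with an amide-linked N-acyl chain,
and cardiolipin three glycerols and two phosphates. Monoisotopic masses
are element-count sums over an embedded NIST/CODATA table — nothing is
fetched at run time. Example:

```r
pc <- lipid_species("PC", c("16:0", "18:1"))
pc
#> PC 16:0/18:1 (C42H82NO8P, 759.5778 Da)
precursor_mz(pc, "[M+H]+")
#> [1] 760.5851
```

*sn*-positional isomers are deliberately not distinguished
(`16:0/18:1` ≡ `18:1/16:0`): collision-induced dissociation on an
orbitrap instrument cannot resolve them. The default enumeration spans
chains of 12–24 carbons (even) with 0–2 double bonds, covering the
species that dominate plasma-EV lipidomes; wider bounds are a
constructor argument. Supported adducts are [M+H]⁺, [M+Na]⁺, [M−H]⁻ and
[M+HCOO]⁻, all singly charged — which adducts an instrument method
actually samples is configurable at assignment time.

Fragment prediction uses a minimal canonical rule set: in positive mode
choline-head classes yield the phosphocholine ion at *m/z* 184.0733 and
neutral losses of each chain as free acid and as ketene; in negative
mode each ester chain yields its carboxylate anion [RCOO]⁻ plus lyso
ions. Fuller rule systems (e.g. head-group-specific negative-mode
marker ions) can be layered on, but this set is already sufficient to
discriminate chain isomers, which is what the score needs.

# The hypergeometric match score

A candidate is scored by asking how improbable its fragment matches are
under a null in which observed peaks fall uniformly into *m/z*
tolerance bins. With `N` bins across the spectrum span, `T` predicted
fragment bins, `P` observed peaks and `k` matches, the score is

$$ S = -\log_{10} P(X \ge k), \qquad X \sim \mathrm{Hypergeom}(N, T, P). $$

`N` is the spectrum span divided by twice the fragment tolerance (in Da
at the span midpoint), clamped below by `T + P` so the distribution is
always well defined. Matching is greedy nearest-*m/z*: each fragment
consumes at most one peak and vice versa, making the result invariant
to peak ordering and intensity scaling. Intensity is *not* used in the
score — a deliberate match to the count-based formulation, noted as an
extension point. Defaults are 10 ppm (precursor) and 20 ppm (fragment),
the accuracy class of a modern orbitrap, and a minimum score of 2
(match probability ≤ 1 %); the last is a package convention, not a
published threshold, and is exposed as an argument. Manual confirmation
of assignments is supported by `review_table()`, which exports the
top-3 candidates per spectrum with scores and matched fragments instead
of an interactive step.

`merge_iterative_runs()` models iterative-exclusion acquisition (four
runs per polarity, precursors fragmented once never re-triggered):
spectra agreeing within 5 ppm and 0.2 min collapse to the richer one.

# MS1 quantification

Identified species are quantified by extracted-ion chromatograms: per
scan, intensities within ±20 ppm of the precursor are summed; the area
is the trapezoidal integral over a ±0.5 min window around the
assigning MS2 spectrum's retention time (the window half-width is an
argument; full peak area was chosen over apex intensity as the more
noise-robust convention). Quantification is strictly *relative within a
head-group class*: fractions are areas normalized per (class,
replicate), so no response-factor calibration or cross-class comparison
is implied. Replicate spread is summarized with Tukey box statistics
(type-7 quantiles; whiskers to the most extreme point within 1.5 IQR;
points beyond flagged as outliers).

# ³¹P NMR pipeline

The time-domain model is a sum of exponentially damped oscillations;
each phospholipid class contributes one Lorentzian line. The pipeline:

1. **Apodization** — multiply point *k* by `exp(-π · lb · k · dt)` with
   `lb = 3.0` Hz, adding `lb` to every linewidth in exchange for
   signal-to-noise.
2. **Fourier transform** with the first point halved (removes the DC
   offset) and the frequency axis converted to ppm through the 242.93
   MHz carrier.
3. **Zero-order phasing.** The manual phasing step is automated by
   rotating the complex spectrum so its total integral is real and
   maximal, `φ = -Arg(ΣS)` — a closed form under which pure absorptive
   lines carry all their area as positive real signal. (Maximizing only
   the *positive* part of the real spectrum was tried first and
   rejected: dispersive lineshapes have long positive tails that
   inflate that objective, and the resulting phase errors corrupt
   deconvolution.) First-order phasing is out of scope; the simulator
   produces no frequency-dependent phase.
4. **Baseline correction** — polynomial (default order 2) fit to
   signal-free points found by iterative 3σ clipping.
5. **Calibration** — the ppm axis is shifted so the tallest peak (PC,
   the dominant phospholipid in plasma EVs) sits at exactly 0 ppm; ties
   resolve to the highest-ppm candidate with a warning; spectra with no
   peak above 5× the robust noise raise a calibration error.
6. **Deconvolution** — Lorentzian components are seeded at local maxima
   whose *prominence* exceeds 5× the robust noise (median absolute
   deviation). Prominence, not raw height, is essential: noise ripples
   riding on the tails of a strong line clear any height threshold but
   have near-zero prominence. Centers, widths and amplitudes are
   refined by bounded nonlinear least squares (`nlminb`; widths and
   amplitudes log-parameterized; centers confined near their seeds and
   widths capped at 0.5 ppm so a line cannot degenerate into a
   baseline-wide pedestal). Areas use the closed form
   `amplitude · fwhm · π/2`.
7. **Assignment and quantification** — each component is assigned to
   the nearest entry of a chemical-shift table within its tolerance;
   class percent = 100 × class area / total assigned area. Classes
   under 3 % are reported but flagged non-quantifiable, the practical
   limit for minor phospholipids in ³¹P spectra of this kind.

The packaged shift table (`cubo_shifts.csv`) emulates the dispersion of
the CUBO solvent system relative to PC = 0 ppm but is a synthetic
stand-in — the literature values are not reprinted here — and is
explicitly user-editable; all package tests use the generator's own
table so correctness never depends on literature values. Lineshape is
pure Lorentzian (liquid-state ³¹P); Voigt profiles are a noted
extension.

# BBB permeability and DLS

Transwell accounting keeps every dilution explicit: each compartment
carries (reading, sampled volume, total volume), and
`total = reading × total/sampled` — e.g. a basal pellet resuspended 5×
concentrated is just a total volume of 1400 µL against a 280 µL
resuspension. The four-way partition (passed filter, passed BBB,
retained apical, retained in cells) normalizes compartment totals to
100 %. The filter-associated tracer is modeled as a compartment of the
same partition — which is what makes the four published rows sum to
100 — rather than as a separate no-cell control run; totals from such a
control can still be fed through `permeability_percentages()` directly.

DLS summaries use the intensity-weighted mean hydrodynamic diameter and
define PDI as weighted relative variance (var/mean²). This is a
deliberate simplification: instrument PDIs come from cumulant fits of
raw correlograms, which exported intensity distributions cannot
reproduce. On log-normal distributions the two conventions agree
exactly, which is what the generator produces.

# The synthetic world

Generator defaults are the published operating points, stored in one
editable JSON (`paper_like_setpoints.json`):

* **Lipidome** — PC-dominant (50 %), SM second (24 %), a prominent
  lyso-PC 16:0 (10 %, the third most abundant choline-family species),
  minor PI and PE, and *no PS* (not observed in plasma-EV samples by
  either method). Species abundances are drawn log-normally (σ = 0.2)
  around the setpoints per replicate — a realistic biological
  variability of ~20 % — and renormalized.
* **NMR class setpoints** — PC 76.7 %, SM 20.3 %, PE 3.0 %, with
  replicate-level log-normal jitter σ = 0.05 (~5 % relative, matching
  the published replicate SDs of ±3.8 and ±1.0 points). All classes
  share one linewidth per spectrum, drawn uniformly from 0.02–0.08 ppm:
  linewidth in such spectra is dominated by shimming and solvent, which
  affect all lines alike, and the shared width guarantees the PC line
  is the tallest — the premise of the calibration rule. A global ppm
  offset (±0.3) is added and must be absorbed by calibration. SNR is
  defined as tallest spectral peak over spectral noise SD, applied to
  the raw FID (apodization then improves it).
* **MS acquisition** — Gaussian elution (σ = 0.04 min) at random
  retention times in 1–16 min of a 17-min gradient, MS1 scans every
  0.05 min, 5 ppm Gaussian *m/z* jitter, optional uniform decoy peaks
  (the simplest null consistent with the score's assumption), and
  four-run iterative exclusion.
* **BBB / DLS** — the published partition 7.7 / 1.3 / 88.4 / 2.6 and a
  log-normal size distribution with mean 68.8 nm, PDI 0.21.

What the generator does **not** emulate: chromatographic physics, ion
suppression, isotopologue envelopes, chimeric spectra, NMR relaxation
pathways or first-order phase errors, and correlogram-level DLS. A
green recovery test therefore establishes that the *analysis chain* is
faithful to its own model, not that the model captures every instrument
artifact.

# Numerical choices and limitations

* Quantile type 7 (R default) for box statistics; the convention is not
  stated in the field's figures.
* Greedy nearest-*m/z* fragment matching with ties broken by smallest
  Δ*m/z*, then lowest peak *m/z* — deterministic under any input
  ordering.
* `nlminb` can hit its iteration cap on many-component fits; the
  best-so-far fit is returned with a warning and a convergence flag
  rather than an error.
* Degenerate inputs fail loudly: zero-carbon chains, charge ≠ 1,
  empty scan lists, all-zero fluorescence, all-noise spectra.
* Known limitations: no FDR/decoy-database control, no isotope
  correction, no absolute quantification, no ether/plasmalogen or
  oxidized lipids, no first-order NMR phasing.
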