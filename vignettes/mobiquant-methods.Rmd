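---
title: "Methods and design of the mobiquant pipeline"
author: "mobiquant authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the mobiquant pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mobiquant)
```

# The assay

`mobiquant` implements the complete computational side of a MALDI ion-mobility
tandem-MS (MALDI-IM-MS/MS) assay quantifying osimertinib, a third-generation
EGFR tyrosine kinase inhibitor, in human plasma. One sample is one 60-s
analysis of a single matrix spot: the quadrupole isolates the precursor near
m/z 500, collision-induced dissociation produces a major fragment near
m/z 185.1 for the drug and m/z 189.1 for its stable-isotope-labeled internal
standard (IS, [13C,2H3]-osimertinib), and ions are separated by ion mobility
before TOF analysis. The drift time (DT) axis plays the role of a
chromatographic retention axis: the quantity extracted per compound is the
area of its extracted-ion-mobilogram peak ("MobA"), or alternatively the
maximum intensity of the compound's m/z peak in the TIC-combined spectrum
("MassI"). Responses are analyte/IS signal ratios; quantification uses a
1/x²-weighted linear calibration; validation follows the FDA/EMA
bioanalytical guidelines; cross-validation against an LC-MS/MS reference uses
the incurred-sample-reanalysis (ISR) rule.

Every stage operates on explicit data objects (`Acquisition`, `Mobilogram`,
`MobilityPeak`, `CalibrationFit`, `ValidationReport`), and a synthetic
acquisition generator reproduces the assay's signal structure so the whole
pipeline is testable — and its statistical behaviour measurable — without
instrument data.

# Study design arithmetic

Concentrations are stored throughout as *virtual concentrations in plasma*:
spiking `v` µL of a solution at concentration `c` into `V` µL of plasma gives
`c · v / V` — with the assay's 50 µL spike into 100 µL plasma, exactly half
the solution concentration. Solution concentrations are derived on demand and
never stored, avoiding double-conversion bugs. The IS spike volume does not
enter the denominator; referring all concentrations to the plasma volume is
the only convention consistent with the assay's level table (1000…5 ng/mL
from 2000…10 ng/mL solutions). Clinical samples are CAL-like records whose
nominal concentration is unknown (`NA`); solvent replaces the reference spike
so the volume arithmetic is unchanged.

Batch layouts are deterministic expansions of the designs: a validation batch
is 4 technical replicates of blind value (BV), CAL0 and each of the eight
non-zero calibration levels plus 8 replicates of the four QC levels
(72 records); the freeze/thaw batch adds quadruplicates of LQC/MQC/HQC
flagged with three cycles, which are pooled into precision/accuracy as in the
assay and additionally reported as their own row. Recovery and matrix-effect
designs are paired series (QC DIL/QC REC and QC MAT/QC EL) in quadruplicate
at the three QC levels; carry-over blanks sit on the former CAL500 and
CAL1000 positions.

# The synthetic acquisition generator

`simulateSpot()` renders, per spot, three 2D Gaussian peaks on the
(m/z, drift-time) grid — analyte, IS, and a near-isobaric endogenous
interferent offset by +0.03 m/z and +0.04 ms from the analyte fragment — as
centroided peaks split across frames proportionally to a simulated TIC
profile. The expected analyte signal volume is

```
slope · conc · recovery · matrixFactor · spotFactor · replicateFactor
```

with the IS analogous at its fixed virtual concentration (200 ng/mL). Key
modeling choices:

* **m/z centers** default to the midpoints of the assay's extraction windows
  (185.1075 and 189.1325), since exact fragment masses are not part of the
  design; all statistics are window-relative.
* **Resolution modes.** The V (sensitivity, single TOF reflection) and W
  (resolution, double reflection) modes are modeled purely as mass-peak
  widths: FWHM 0.060 vs 0.018 at m/z 185. The instrument's true resolving
  powers are not part of the design; these values are fixed once so that the
  interferent 0.03 m/z away *merges* with the analyte peak in V mode and is
  *resolved* in W mode — the qualitative behaviour that motivates running the
  assay in W mode.
* **Interferent intensity** is concentration-independent, defaulting to the
  response equivalent of 2 ng/mL of analyte. This puts it on the order of the
  LLOQ signal (where the interference argument bites) while keeping its
  W-mode leakage into the analyte window below 1% at the LLOQ.
* **Drift-time axis**: 0–4 ms over 200 bins, mobility peaks of 0.25 ms FWHM
  at 1.85 ms, interferent at +0.04 ms — mobility alone therefore cannot
  separate the two, matching the assay's observation; the bin count is a
  free discretization choice.
* **Noise structure.** Replicate noise is a lognormal multiplier (unit mean,
  parameterized by CV) applied to the *analyte channel only*, so
  `replicateCv` directly parameterizes the CV of the IS-normalized response —
  the quantity every validation statistic sees. Amplitude variation that the
  IS *does* cancel (crystallization/ionization heterogeneity) is a separate
  lognormal spot factor shared by all compounds within a spot. Baseline noise
  is additive Gaussian truncated at zero, rendered once per drift bin at the
  window centers. The lognormal/CV parameterization matches the %CV reporting
  convention of the validation statistics.
* **Deposition order.** Pre-spotted-matrix spots get a high, stable TIC
  profile (lognormal, ~10% CV); extract-first spots get sparse,
  high-variance bursts. The TIC profile shapes how signal distributes over
  frames; totals are ratio-based, so deposition order affects stability, not
  calibration.
* **Role semantics.** BV renders neither analyte nor IS; CAL0 renders the IS
  only; QC REC/MAT/EL are post-extraction-spiked and therefore suffer no
  extraction loss; QC EL (neat eluent) additionally carries neither matrix
  multipliers nor the endogenous interferent; carry-over blanks render a
  residual fraction of the source standard's signal.
* **Recovery semantics.** The package's convention is co-extraction: the
  extraction loss applies identically to analyte and IS. Consequently the
  IS-normalized DIL/REC comparison returns ~100% (demonstrating that the
  normalization works), and the extraction fraction itself is estimated from
  raw analyte areas (`estimateRecovery(..., signal = "raw")`); a diagnostic
  generator mode (`recoveryMode = "analyte_only"`) attenuates only the
  analyte channel so the normalized estimator recovers the fraction
  directly. The default extraction fraction is 0.536.
* **Carry-over fraction** defaults to 2·10⁻⁴ of the source standard's
  signal. It is calibrated against the assay's observed behaviour — blank
  carry-over signals below 17% of the *lowest* LLOQ analyte signal — noting
  that the minimum-signal denominator sits well below the mean LLOQ signal
  under spot heterogeneity, so the fraction must be small enough that the
  ratio respects that bound across seeds.

What the generator does **not** emulate: isotope envelopes, the six minor
fragments of each compound, crystallization physics, detector saturation,
m/z- or DT-calibration drift, and inter-day trends beyond independent batch
seeds. Passing tests therefore demonstrate the correctness and statistical
behaviour of the *pipeline* under the modeled signal structure, not the
performance of any physical instrument. The absolute intensity scale is
arbitrary; every acceptance statistic is ratio-based for this reason.

# Mobilogram extraction and peak integration

`extractMobilogram()` sums centroid intensities per drift bin inside the m/z
window (inclusive bounds); `combineSpectrum()` bins all centroids onto a
0.005-m/z grid (at least five bins across the narrowest window);
`massI()` is the windowed maximum of that profile.

Automatic mobility-peak integration (`detectMobilityPeak()`) is a
deterministic, oracle-checkable reimplementation of apex-tracking
integration, since the vendor algorithm is proprietary:

1. smooth with a local quadratic (Savitzky–Golay) filter, width 5 bins;
2. apex = the highest smoothed local maximum within `dtTolerance`
   (default 0.2 ms) of the expected drift time; ties break toward the
   expected DT, then toward earlier DT — documented and stable;
3. bounds extend from the apex until the smoothed signal falls to the
   baseline estimate + 2 × noise, or to a valley;
4. area = trapezoidal integral of the **raw** signal between the bounds.

The baseline estimate is the median — and the noise the MAD — of the
mobilogram outside expected DT ± 3 × tolerance, robust to the single-peak
structure. A mobilogram with no qualifying maximum yields a zero-area peak at
the expected DT (blanks are data, not errors). All constants are arguments.

# Calibration

`fitWeightedLinear()` minimizes `Σ wᵢ(yᵢ − a − bxᵢ)²` with `wᵢ = 1/xᵢ²`
on nominal x. Zero-concentration samples never enter the fit (their weight is
undefined; the assay fits the non-zero levels only). All individual replicate
responses enter by default — regression on replicates is standard EMA
practice — with a `useLevelMeans` switch. r² is computed on the weighted
model (the weighted-residual convention; which convention vendor software
uses is not documented, so ours is stated). Back-calculation is the exact
inverse `x̂ = (y − a)/b`; negative estimates are reported and flagged, never
clamped — honest blank and carry-over statistics need them.

Curve acceptance: a standard is accepted when its back-calculated bias is
within ±15% (±20% at the lowest level); the curve is accepted when ≥ 75% of
individual standards and ≥ 6 levels pass. The r² floor (default 0.988, the
observed floor of the validated assay) is reported but does not gate the
verdict, since the guidelines impose bias rules rather than r².

Because the interferent is concentration-independent, its residual W-mode
leakage into the analyte window is a constant offset absorbed exactly by the
fitted intercept — which is why a noiseless batch back-calculates every level
exactly, including 5 ng/mL at the LLOQ.

# Validation engine

* CV uses the sample (n−1) standard deviation; bias uses the replicate mean.
* Batch-to-batch statistics pool all replicates across batches (grand
  mean/SD), matching single pooled summary values; a per-batch-means
  alternative is a config switch away.
* Acceptance limits are 15%/±15% (20%/±20% at LLOQ) with a **strict**
  boundary convention by default — a CV of exactly 15.0% fails — matching
  the "<" phrasing of the guidelines; `inclusive = TRUE` flips this per
  call.
* "Signal" in specificity and carry-over ratios means the MobA area in the
  compound's window, consistent with MobA being the validated method. Limits
  are 20% of the lowest LLOQ analyte signal and 5% of the mean IS signal.
* Freeze/thaw records contribute to level precision/accuracy *and* are
  reported as their own row.
* Recovery and matrix-effect sections pass on consistency (replicate CV
  below 15%), since neither quantity has a numeric guideline target; the
  IS-normalized matrix factor and the raw-area recovery are reported.

`runCampaign()` composes everything: four validation batches (freeze/thaw
replicates in batch 3, carry-over blanks after batch 4), six-source
specificity blanks, and the paired recovery and matrix series; per-batch
calibration; a `ValidationReport` with per-criterion pass/fail, serialized to
JSON and Markdown. Campaigns are pure functions of `(config, seed)`;
re-running reproduces artifacts byte-for-byte. Configuration is a single
nested list with the guideline defaults; unknown keys are rejected by name.

# Cross-validation

The ISR rule uses the two-method mean as denominator:
`%diff = 100(a − b)/((a+b)/2)`, conforming within ±20%, with the campaign
passing at ≥ 67% conforming of ≥ 20 incurred samples. Technical duplicates
are averaged per method before pairing (the raw duplicates are retained in
the output); whether the original 72%-of-25 figure was computed on averaged
or per-replicate values is not documented, so the averaged convention is
fixed here. Pearson r and its two-sided p-value come from the t transform on
n − 2 degrees of freedom.

# Problem sizes and numerical tolerances

The test suite and acceptance script run the generator at reduced scale —
4–10 frames per spot and 100–200 drift bins — which the authors consider
adequate because every statistic is a ratio of sums over the same grid;
scale enters only through Monte-Carlo noise, which the seeds fix. Noiseless
identities are asserted to 10⁻⁶ relative (trapezoid-vs-rendering
discretization), algebraic oracles to 10⁻⁸–10⁻¹². The guideline-gate
direction check runs 52 reduced-scale campaigns (26 at replicate CV 5–10%,
26 at 30%) with pass/fail-rate thresholds of 80% fixed in advance. The
cross-validation noise property uses 200 response-level simulations per
noise level.

# Known limitations

* The peak integrator is a functional stand-in for the vendor's apex-tracking
  algorithm, not a clone; only the extraction windows are shared design
  constants.
* The mzML reader ingests only spectra bearing an ion-mobility drift-time
  attribute and maps them onto the package's scan/bin contract; vendor raw
  formats and profile-mode centroiding are out of scope.
* No quadratic/4PL calibration, no LOD estimation below the configured LLOQ,
  no stability panels beyond freeze/thaw bookkeeping, and no Bland–Altman or
  Passing–Bablok analyses.
* Measured validation statistics of the physical assay (its CVs, recovery,
  correlation) arise from instrument data; the package reproduces the
  *rules, arithmetic and qualitative behaviour*, and its synthetic campaigns
  should be read as such.
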