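---
title: "Quantitative MRI file collections: models, validation and fitting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative MRI file collections: models, validation and fitting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qmribids)
```

## The problem this package addresses

Quantitative MRI infers physical tissue parameters from a *set* of images
in which one acquisition parameter is varied while everything else is held
fixed. Unlike conventional weighted images, these sets have no single
contrast label; what identifies them is the acquisition scheme and the
swept dimension. The BIDS convention for such data groups the images into
*entity-linked file collections*: a shared suffix names the scheme
(`VFA`, `MP2RAGE`, `MEGRE`, `TB1DAM`, ...) and linking entities (`echo-`,
`flip-`, `inv-`, `mt-`, `part-`) index or categorize the varied dimension.
Crucially, entities only *index*: the actual parameter values (echo times,
flip angles, inversion times, MT state) live in sidecar JSON metadata,
which is subject to the inheritance principle — one JSON may describe
several images, with deeper, more specific files overriding shallower
ones.

`qmribids` implements the convention end to end: a declarative schema
registry, a parser/validator, a phantom generator that emits valid
datasets, voxelwise fitters, and a derivatives writer with provenance.

## The schema registry

The registry (`inst/schema/qmri-registry.yaml`) is data, not code: one
record per suffix with its folder (`anat` for the eight anatomy
collections, `fmap` for the six B1 collections), entity requirement
levels, required metadata and derivable maps, plus a units table for all
map suffixes. New suffixes can be added without touching code, matching
the extensibility aim of the convention. Every entry carries a `source`
tag: `core` entries are stated by the convention itself, `appendix`
entries are encoded from the BIDS 1.5.0 qMRI appendix it points to. The
validator reports missing appendix-sourced metadata at warning severity by
default and at error severity in strict mode, so the printed-in-convention
subset remains distinguishable.

Units are standardized so maps are interchangeable: relaxation times in
seconds, rates in reciprocal seconds, ratio maps (MTR, myelin water
fraction) in percent, susceptibility in ppm, transmit field in relative
percent where 100 means the nominal flip angle was realized. MTsat and
proton-density maps are in arbitrary units — their acceptable range
depends on anatomy and acquisition — so no range check is enforced for
them. Two spellings of the RF spoiling increment circulate;
`SpoilingRFPhaseIncrement` is canonical here and the other is normalized
on read.

One registry flag deserves explanation: the two volumes of actual
flip-angle imaging (`TB1AFI`) share a single nominal flip angle and differ
in repetition time, so the otherwise-global rule that the linked parameter
must differ across `flip` indices is waived for that suffix
(`param_distinct_exempt`), and the member pair is distinguished by
`RepetitionTimeExcitation`.

## Signal models and their assumptions

All models are pure functions, vectorized over voxels, with angles in
degrees at the interface (the metadata convention) and radians internally.

* **Spoiled gradient echo** (VFA, MTR reference):
  $S = M_0 \sin(b_1\alpha)\,(1-E_1)/(1-E_1\cos(b_1\alpha))$,
  $E_1 = e^{-TR/T_1}$. Assumes ideal spoiling; verified against a
  pulse-by-pulse Bloch recursion to below $10^{-9}$ relative.
* **Inversion recovery**: $S = M_0(1 - 2e^{-TI/T_1} + e^{-TR/T_1})$,
  signed; assumes a saturating readout. Verified against explicit cycle
  iteration.
* **Monoexponential decay**: $S = M_0 e^{-TE/t_c}$ with $t_c = T_2$
  (spin echo) or $T_2^*$ (gradient echo).
* **MP2RAGE**: one cycle — inversion ($m_z \to -\eta m_z$), recovery to
  TI$_1$, gradient-echo block of $n$ excitations, recovery to TI$_2$,
  second block, recovery to the cycle end — is a composition of maps each
  affine in $m_z$, so the steady state is the exact fixed point of the
  composed map, $m_z^* = B/(1-A)$. Signals are read at the central
  excitation of each block (a linear k-space ordering approximation), with
  the inversion sign carried in the phase. The inversion efficiency
  $\eta$ defaults to 0.96, a typical adiabatic value; it is a convention,
  not a measured quantity, and is configurable. Note that $\eta = 0$ in
  this parametrization is a *saturation* ($m_z \to 0$), not "no
  inversion", which is why the constructor requires $\eta \in (0, 1]$.
  The UNI combination
  $\mathrm{Re}(S_1\bar S_2)/(|S_1|^2+|S_2|^2) \in [-0.5, 0.5]$ is
  invariant under any common complex factor — receive field, $M_0$, a
  common phase ramp — and, under this sign convention, monotonically
  *decreasing* in $T_1$ over the working range (short $T_1$ recovers past
  the null before the first readout, giving positive UNI; long $T_1$ is
  still negative there).
* **Double angle** (long-TR limit): $S_1 = M_0\sin(b_1\alpha)$,
  $S_2 = M_0\sin(2b_1\alpha)$, assuming full relaxation between
  excitations.
* **AFI**: the short-TR ideal-spoiling ratio
  $r = (1 + n\cos(b_1\alpha))/(n + \cos(b_1\alpha))$, $n = TR_2/TR_1$.
  The same approximation is used forward (generator) and inverse
  (fitter), keeping the pair self-consistent; a warning is raised when
  the TRs are not small against $T_1$.
* **MTsat** (rational small-angle steady state): off-resonance arms
  $S = A\alpha\,R_1 TR/(\alpha^2/2 + R_1 TR)$; the MT arm adds the
  per-excitation saturation $\delta$ in the denominator. Valid for flip
  angles up to roughly 25° and $TR \ll T_1$.
* **MTR phantom convention**: the generator produces
  $S_{on} = S_{off}(1 - f)$, so the fitted ratio
  $100\,(S_{off}-S_{on})/S_{off}$ recovers $100f$ exactly. MTR is defined
  only as a derived ratio; this forward convention is ours.

## Fitters and numerical choices

Fitters return a `FitResult`: named maps (NaN outside the fitted mask), a
logical mask, units drawn from the registry, and diagnostics. All are
deterministic — identical inputs give bit-identical maps.

* **VFA** uses the linearized solver ($y = S/\sin\alpha$ against
  $x = S/\tan\alpha$; $T_1 = -TR/\ln s$): exact on noiseless data, fast,
  deterministic; its documented noise bias is accepted at this scale. A
  transmit-field map (relative %) rescales the angles voxelwise; without
  it, a transmit error $b_1$ biases $T_1$ toward roughly $b_1^2 T_1$.
* **Inversion recovery** profiles out the linear amplitudes of
  $S = a + b e^{-TI/T_1}$ and minimizes over $T_1$ alone (60-point
  log-grid plus golden-section refinement, tolerance $10^{-12}$) — more
  robust than 3-parameter descent and with no starting-value art. For
  magnitude data every sign-flip position along the sorted TIs is tried
  and the lowest-residual fit kept. Identical voxel signal vectors are
  fitted once and broadcast (piecewise-constant phantoms collapse to a
  handful of fits). Constant signals carry no decay information and are
  masked, as are fits with non-negative exponential amplitude.
* **Monoexponential** fits use signal-weighted log-linear least squares;
  the weights counter the heteroscedasticity the log transform induces.
  Voxels with any non-positive echo are masked.
* **MP2RAGE** builds the UNI($T_1$) lookup on a grid (default 0.05–5 s,
  1 ms step), restricts to the maximal strictly monotonic run (warning if
  the full range is not monotonic), and inverts by linear interpolation;
  out-of-span voxels are masked. Recovery error is bounded by the grid
  step.
* **Double angle / AFI**: ratios pushed outside their physical range by
  noise are *clamped* (and counted in `diagnostics$n_clipped`) rather
  than masked for the double-angle ratio, keeping the map dense; the AFI
  cosine outside $[-1, 1]$ and the degenerate $r = n$ are masked.
* **MTsat** inverts the three-arm model in closed form; degenerate arm
  pairs (equal flip angles, vanishing denominators) are masked.

Mask semantics (NaN outside the mask) are this package's convention; the
standard does not prescribe one.

## The digital phantom

`defaultPhantom()` is a 32³ grid with three nested spheres in empty
background, carrying 3 T literature-typical parameters:

| tissue (sphere radius) | T1 (s) | T2 (s) | T2\* (s) | M0 | MTR frac | δ | χ (ppm) |
|---|---|---|---|---|---|---|---|
| CSF-like (14) | 3.5 | 1.8 | 0.5 | 1000 | 0.02 | 0.001 | 0 |
| gray-matter-like (10) | 1.35 | 0.09 | 0.06 | 850 | 0.30 | 0.025 | 0.02 |
| white-matter-like (6) | 0.85 | 0.07 | 0.05 | 800 | 0.40 | 0.04 | −0.03 |

Later regions overwrite earlier ones, so the spheres nest. Default
protocols are desk-scale 3 T choices: VFA at 6°/20°, TR 15 ms; IR with
TIs 0.1/0.4/0.9/2.0 s, TR 5 s; MP2RAGE with TI 0.7/2.5 s, 4°/5°, 160
excitations of 6.2 ms in a 5 s cycle; spin-echo train 15–120 ms; a
gradient-echo train of 10 echoes, 6–60 ms, chosen to span the
white-matter-like T2\* of 50 ms (max TE ≈ 1.2 × T2\*, the standard design
rule); MTsat arms 6°/25 ms (PD and MT) and 20°/11 ms (T1); double angle
at 60°/120°; AFI at TR 20/100 ms ($n = 5$). Schema-only suffixes (MPM,
TB1EPI, TB1TFL, TB1SRGE, RB1COR) receive structurally valid placeholder
protocols so the generate→validate loop covers all 14 suffixes.

Generated datasets exercise the convention deliberately: one 3-D NIfTI
per entity combination (the 4-D stacking alternative is rejected for
readability, following the convention's consensus), shared constants in a
collection-level JSON resolved through inheritance, per-member JSONs for
varying fields, magnitude/phase MP2RAGE pairs described by a single
per-inversion JSON, and a smooth spatial phase ramp on the phase images
so complex reconstruction is genuinely exercised (the ramp cancels in the
UNI combination). Ground truth is written to a sibling `<out>_truth/`
directory, outside the BIDS tree, keeping the dataset standard-clean.

Noise is applied after forward modeling under a fixed seed; Gaussian is
the analytic default, Rician is available because magnitude MRI noise is
Rician. Noise levels are quoted as 1% of the image signal amplitude
(image SNR 100) — for the monoexponential case that is exactly
$\sigma = M_0/100$, since $M_0$ *is* the TE = 0 signal.

What the phantom does **not** emulate: anatomy, partial volume, k-space
artifacts, motion, imperfect spoiling (the spoiling increment is carried
as metadata, not simulated), slice profiles, B0 inhomogeneity, or
Rician-floor bias in fitters. Passing recovery tests therefore
demonstrates correct model inversion and plumbing, not in-vivo accuracy.

## The validator

Issues are data, not exceptions: a sorted, deterministic data frame of
(code, severity, path, message), with severities fixed per code.
Collection-level checks cover required/forbidden entities, index
contiguity from 1 (gaps are *warnings* — they impede readability),
linked-parameter presence, constancy within an index and distinctness
across `echo`/`flip`/`inv` indices (duplicates are *errors* — they break
model fitting), label sets, and required metadata after inheritance
resolution. Derivative maps are checked for registry units (a `ms`
sidecar on a seconds map is an error, never converted), field strength on
relaxometry maps, `BasedOn` provenance, and plausible value ranges. The
taxonomy itself (codes, two severities) is original to this package.

## Derivatives and provenance

Maps are written with the registry unit, a `BasedOn` list of
dataset-root-relative input paths in parameter-table order,
varying parameters in vector form — one value per linking index (the two
inversion times of an MP2RAGE quartet, the two flip angles of a
double-angle pair) — constants inherited from the raw sidecars including
`MagneticFieldStrength`, and a `GeneratedBy` block naming this package
and version. The derivatives root carries its own
`dataset_description.json` marked `derivative`. JSON output is
byte-stable: keys sorted, UTF-8, 4-space indent, 12 significant digits.

## Problem sizes and test design

The shipped tests run the whole pipeline at phantom scale: a 32³ grid
(11,536 in-phantom voxels), all 14 suffixes generated and validated,
an exhaustive mutation sweep (every required entity and metadata field
deleted in turn, strict mode, expecting detection), noiseless recovery at
fitter tolerances ($<10^{-6}$ relative for the iterative/linearized
inversions, $<10^{-9}$ for log-linear and trigonometric identities, MTR
to rounding, MP2RAGE within the 1 ms lookup step), oracle-equivalence
checks (closed-form vs iterated steady states, $<10^{-10}$), and
stochastic recovery on 10,000 voxels at image SNR 100 (median T1 and
T2\* errors under 2%). These sizes were chosen so the full suite runs in
about a minute on one core while still covering every code path at
voxel scale.

## Known limitations

* Only the qMRI-relevant subset of BIDS is modeled; events, participants
  tables and non-MRI modalities are out of scope, as are DICOM
  conversion, cross-session collection merging and `IntendedFor`
  resolution.
* MPM, TB1EPI, TB1TFL, TB1SRGE and RB1COR have schema and validation
  support but no fitter; multi-component T2 (myelin water fraction) and
  susceptibility (Chimap) computation are likewise out of scope (units
  registry entries only).
* The linking-entity order is not assumed to follow parameter order
  (`inv-1` need not be the shorter inversion time); parameter values are
  always read from metadata.
* MTR's `mt-off` member is required to be co-located with its `mt-on`
  partner.
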