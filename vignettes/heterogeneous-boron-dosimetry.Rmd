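---
title: "Heterogeneous boron distributions in BNCT voxel dosimetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heterogeneous boron distributions in BNCT voxel dosimetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bnctdose)
```

## The problem

In boron neutron capture therapy (BNCT) the tumor dose is dominated by the
^10^B(n,&alpha;)^7^Li capture reaction, so it is governed by the product of
two spatial distributions: boron-10 atoms and thermal neutrons. Most
treatment planning systems nevertheless assume a *homogeneous* boron
distribution — a single tumor-to-normal ratio (TNR) applied to the whole
gross tumor volume (GTV). A ^18^F-BPA PET scan shows that real uptake is
anything but uniform, with intratumoral TNR commonly spanning a factor of
three or more. Treating that distribution as uniform distorts the dose
distribution in two ways: directly, because low-uptake voxels carry less
boron than the ROI mean, and indirectly, because boron's large capture
cross-section depresses the thermal flux downstream of boron-rich regions
(self-shielding).

`bnctdose` quantifies the heterogeneous distribution from PET, propagates
it through a dose engine that captures both mechanisms, and reports the
dose-volume histogram (DVH) and dose statistics of the homogeneous and
heterogeneous models side by side.

## From PET intensity to per-voxel boron

**SUV.** Each PET voxel intensity is converted to a body-weight
standardized uptake value

$$\mathrm{SUV}(V) = \frac{\mathrm{intensity}(V)\cdot\mathrm{ACF}\cdot
\mathrm{BW}}{\mathrm{ID}\cdot 2^{-\Delta t/T_{1/2}}},$$

with injected dose ID (Bq), body weight BW (kg), attenuation correction
factor ACF (1.0 by default — modern scanners correct at reconstruction),
tracer half-life $T_{1/2}$ (109.771 min for fluorine-18, configurable) and
$\Delta t$ the signed interval from activity measurement to scan start.
Tracer decay *during* the acquisition is neglected.

**TNR.** The SUV map is resampled (trilinear) onto the CT grid, where the
GTV is delineated; each tumor voxel's SUV is divided by the mean SUV of a
user-supplied normal-tissue ROI. The mean of the voxel TNR map therefore
equals the conventional ROI-level TNR exactly. The normal ROI is
user-provided (e.g. contralateral brain); the package does not attempt
automatic mirroring, because its placement is a clinical judgement. TNR
values below 1 are retained — low-uptake tumor sub-volumes are precisely
the cold-spot regions the method is meant to expose.

**Boron inventory.** TNR is used as a linear proxy for relative boron
concentration, anchored so that TNR 1 corresponds to a prescribed blood
boron-10 level (default 25 ppm by mass, a typical BPA infusion plateau).
The conversion factor $\xi$ (atoms per voxel per unit TNR) follows from
the voxel mass and the boron-10 atomic mass (10.0129 u). Every
homogeneous-vs-heterogeneous contrast the package reports is invariant to
this anchor — it fixes absolute scale only — and that invariance is
exercised by the test suite. We apply $\xi$ to TNR-scaled values rather
than raw SUV; the two choices differ only by the constant normal-tissue
baseline, which $\xi$ absorbs.

## Groupwise quantization with atom conservation

A transport engine cannot carry one material per voxel: with $M$ tissue
types and $I$ boron levels it needs $M\times I$ materials. The package
therefore quantizes the per-voxel concentration into $I$ evenly spaced
groups (default $I = 50$) with midpoints

$$\bar v_i = \frac{v_{\max}-v_{\min}}{I}\,(i-0.5)+v_{\min},\qquad
i = 1,\dots,I,$$

assigning each voxel the group
$i(V)=\lceil I\,(v(V)-v_{\min})/(v_{\max}-v_{\min})\rceil$. Quantization
alone changes the total boron inventory slightly, so a normalization
factor

$$k = \frac{\sum_V v(V)}{\sum_i N_i\,\bar v_i}$$

rescales the grouped values, making the grouped total equal the exact
total identically. This conservation is what keeps the neutron
suppression in the ROI faithful even for modest $I$; the suite asserts it
to 1 part in 10^9^ across random fields and $I \in \{1,2,5,50,256\}$, and
checks that the per-voxel quantization error shrinks as $I$ grows, so the
default 50 is a memory/accuracy compromise rather than a magic number.

Two conventions are fixed here because the ceiling formula is ill-defined
at the edges: a value exactly at $v_{\min}$ (ceiling 0) is clamped to
group 1, and a degenerate ROI with $v_{\max}=v_{\min}$ becomes a single
group at that value with $k=1$.

## The reference dose engine

The per-voxel dose rate decomposes into boron, neutron and photon
components combined with radiobiological weights

$$\dot D_{\mathrm{BNCT}} = \mathrm{CBE}\cdot\dot D_B +
\mathrm{RBE}_N\cdot\dot D_N + \mathrm{RBE}_P\cdot\dot D_P,$$

with tumor defaults CBE = 3.8 (boronophenylalanine), RBE~N~ = 3.2,
RBE~P~ = 1.0. The boron component is

$$\dot D_B(V) = \frac{N_{B10}(V)\cdot R_{B10}(V)\cdot
E_{\mathrm{cap}}}{\mathrm{Mass}(V)},$$

where $R_{B10} = \sigma_B\,\varphi(V)$ is the capture rate per atom and
$E_\mathrm{cap}$ the locally deposited energy per capture, under the
standard assumption that the &alpha; and ^7^Li ranges are sub-voxel.

The flux $\varphi$ comes from a deliberately simple deterministic engine:
a broad parallel thermal beam attenuated along its axis by a narrow-beam
removal model,

$$\varphi(z) = \varphi_0 \exp\!\Big(-\!\int_0^z \big[\Sigma_t +
\sigma_B\, n_{B10}(s)\big]\,ds\Big),$$

ray-marched per grid column with the optical depth at a voxel center
accumulating all upstream voxels plus half of the voxel's own — which
makes the engine *exact* on homogeneous media, a property the tests
exploit against the closed form. The $\sigma_B n_{B10}$ term is the boron
self-shielding; it can be switched off (`boron_in_transport = FALSE`) to
study the limit where both boron models see identical flux. The engine
sits behind `beam_config()` so a Monte Carlo transport code can replace
it without touching the rest of the pipeline: it is a reference
implementation that reproduces the two mechanisms that matter for the
homo/hetero contrast, not a clinical transport model. Energy-dependent
transport, scattering and secondary-photon production are out of scope;
the neutron and photon components are kerma-style proxies proportional to
the local flux (plus an optional constant photon background).

Default physical constants (all overridable): $\sigma_B$ = 3837 b
(thermal ^10^B capture), $E_\mathrm{cap}$ = 2.33 MeV (capture Q-value
less the 478 keV photon that escapes the voxel), $\Sigma_t$ = 0.1 /cm
(generic tissue removal), $\varphi_0 = 10^9$ n/cm²/s. With the 25 ppm
blood anchor these place the weighted components in the
0.1–10 cGy-Eq/s range typical of clinical BNCT beams; they set absolute
scale only.

**The two boron models.** *Homogeneous*: every tumor voxel is assigned
the ROI-mean TNR — the conventional fixed-TNR assumption. *Heterogeneous*:
the transport sees the grouped ($I$-material) inventory, while the dose
score uses the exact per-voxel inventory, which is closer to the real
boron dose than the grouped value. Both models carry the same total
number of boron atoms by construction.

## Reporting

`compute_dvh()` builds the cumulative DVH over the ROI and the statistics
$\dot D_{\max}$, $\dot D_{\min}$, $\dot D_{\mathrm{mean}}$ and
$\dot D_{80}$ (the rate covering 80 % of the volume, a prescription
index). Conventions fixed where the field's usage is loose:

* $\dot D_{80}$ interpolates linearly between ranks of the
  descending-sorted voxel doses at rank $0.8N$; $\dot D_{\max/\min}$ are
  single-voxel extrema, not percentile-clipped.
* differences are $100\,(\text{hetero}-\text{homo})/\text{homo}$, one
  decimal, sign retained;
* component breakdowns are evaluated at the voxel where the *weighted
  total* attains its extremum, and percentages are taken against the sum
  of the three components at that voxel;
* dose rates are reported in cGy-Eq/s (SI internally, scaled at report
  time).

## The synthetic phantom

Because clinical PET/CT cases cannot ship with a package, every stage is
validated on phantoms with known ground truth. `build_phantom()` lays a
spherical tumor with a prescribed TNR field (uniform, linear gradient,
Gaussian blob, or bimodal) in a water-equivalent volume, then produces
the PET image the scanner would see: isotropic Gaussian PSF blur (default
FWHM 5 mm), mean-preserving block-average downsampling to a coarser PET
grid, and optional Poisson noise (off by default so tests are
deterministic). The default geometry — 1×1×3 mm CT voxels versus 5×5×3 mm
PET voxels — mirrors the voxel-size mismatch of clinical brain PET/CT
protocols, and the default gradient field (TNR 1.64–3.90, ROI mean 2.77)
mirrors a markedly inhomogeneous clinical uptake pattern with the
eligibility-threshold mean of ≈2.77. The default grid is 60×60×20 CT
voxels (≈1400 tumor voxels at 10 mm radius): large enough for stable DVH
statistics, small enough that the full suite runs in seconds.

The blur kernel is renormalized where it overhangs the grid edge, so a
globally constant field is preserved exactly and total activity is
conserved to machine precision away from edges — both tested. Two
derived configurations matter for testing:

* the *exact* phantom (PSF 0, no grid mismatch) makes TNR recovery an
  identity, isolating engine properties: there the homogeneous and
  heterogeneous mean boron doses agree to 10^−9^ relative once
  self-shielding is disabled, because the x-symmetric voxelized sphere
  makes per-slice mean TNR constant along the beam;
* the *standard* phantoms keep blur and mismatch, reproducing the
  partial-volume effect: the recovered mean TNR is biased toward the
  background, and the bias grows monotonically as the tumor shrinks
  (tested across 20/10/5 mm radii at 5 mm PSF).

What the phantom does *not* emulate: PET reconstruction physics
(sinograms, OSEM, scatter/randoms), registration error between PET and
CT (volumes are constructed co-registered; real fusions "may harbor
discrepancies" that the pipeline takes as input), non-water anatomy, and
time-varying tracer kinetics. A passing suite therefore demonstrates the
*method* — quantization, conservation, self-shielding, reporting — not
the fidelity of any clinical SUV chain.

## Design choices on genuinely open points

* **Coordinate convention** LPS patient space, 0-based indices, values at
  voxel centers (matches DICOM); NIfTI I/O converts to/from RAS.
* **ROI membership** is voxel-center-in-polygon (even-odd rule), no
  partial-voxel weighting — the simplest rule that an independent oracle
  can confirm exactly.
* **PET is resampled onto the CT grid**, never the reverse, so the ROI
  stays at the resolution at which it was delineated; out-of-field voxels
  are zero-filled and counted (`n_outside`), since silent truncation of
  the baseline ROI was the one genuinely dangerous failure mode found
  during development.
* **Density** defaults to water (1.0 g/cm³) for all ROI voxels; a
  3-point HU→density lookup (`hu_to_density()`) is available but no
  specific scanner calibration is assumed.
* **Minimal DICOM codec**: the package reads and writes single-frame
  explicit-VR little-endian slices (geometry + rescale tags) for fixture
  interchange. It is not a general DICOM implementation; NIfTI is the
  primary on-disk format.

## Worked example

```{r example, eval = FALSE}
cfg <- run_config(phantom = phantom_spec(), out_dir = "report")
bundle <- run_pipeline(cfg)
bundle$comparison          # homo vs hetero dose statistics + differences
bundle$grouping            # I, bounds, k
bundle$tnr_hist            # TNR-volume histogram
```

On the default gradient phantom the homogeneous model overestimates
$\dot D_{\min}$ and $\dot D_{80}$ by tens of percent and underestimates
$\dot D_{\max}$, while $\dot D_{\mathrm{mean}}$ agrees to a fraction of a
percent — the same total inventory seen by nearly the same flux — with
the residual mean difference attributable to self-shielding and the
partial-volume effect. The exact values for the shipped configurations
are computed, not quoted, by `scripts/acceptance.R` and the test suite.

## Limitations

The reference engine is one-dimensional per column: no lateral scatter,
no beam divergence, no spectrum. Absolute dose rates are therefore
indicative, and only the homogeneous-vs-heterogeneous *contrasts* should
be read quantitatively. Groupwise binning is uniform; quantile binning
might suit heavy-tailed uptake distributions better but is out of scope.
The optimal number of groups for an individual case remains an open
question, which is why `n_groups` is a first-class parameter rather than
a constant.
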