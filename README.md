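# bnctdose

Voxel dosimetry for boron neutron capture therapy (BNCT) with
heterogeneous intratumoral boron distributions quantified from PET/CT.

## The problem

BNCT delivers most of its tumor dose through the ¹⁰B(n,α)⁷Li capture
reaction, so the dose distribution is the product of two spatial fields:
boron-10 atoms and thermal neutron flux. Treatment planning systems
conventionally assume a *homogeneous* boron distribution — one fixed
tumor-to-normal ratio (TNR) for the whole gross tumor volume (GTV) — even
though ¹⁸F-BPA PET shows strongly non-uniform uptake. The homogeneous
assumption distorts the dose twice over: low-uptake voxels carry less
boron than the mean, and boron's large capture cross-section (σ_B ≈
3837 b thermal) depresses the flux downstream of boron-rich regions
(self-shielding). The practical consequence is overestimation of the
minimum dose rate Ḋ_min and of the prescription index Ḋ₈₀, hiding
cold-spots that matter for tumor control.

`bnctdose` is for medical physicists and methods researchers who want to
quantify that distortion. It implements:

- **SUV/TNR mapping** — per-voxel standardized uptake value
  `SUV(V) = I(V)·ACF·BW / (ID·2^(−Δt/T½))`, resampled onto the CT grid
  and normalized by a normal-tissue ROI to a per-voxel TNR map;
- **conservation-normalized groupwise binning** — quantization of the
  per-voxel boron concentration into I evenly spaced groups (default 50)
  with midpoints `v̄ᵢ = (v_max−v_min)/I·(i−0.5)+v_min`, index
  `i(V) = ⌈I·(v(V)−v_min)/(v_max−v_min)⌉` and normalization factor
  `k = Σv(V) / Σᵢ Nᵢ·v̄ᵢ`, so the grouped field carries exactly the
  same total boron as the exact field;
- **a reference dose engine** — deterministic narrow-beam removal
  transport `φ(z) = φ₀·exp(−∫[Σ_t + σ_B·n_B10(s)]ds)` with boron
  self-shielding, capture rate `R_B10 = σ_B·φ`, boron dose
  `Ḋ_B = N_B10·R_B10·E_cap/Mass`, and RBE/CBE weighting
  `Ḋ_BNCT = CBE·Ḋ_B + RBE_N·Ḋ_N + RBE_P·Ḋ_P`
  (defaults CBE 3.8, RBE_N 3.2, RBE_P 1.0);
- **DVH reporting** — cumulative DVH, Ḋ_max/Ḋ_min/Ḋ_mean/Ḋ₈₀, and
  homogeneous-vs-heterogeneous comparison tables with component
  breakdowns at the extremum voxels;
- **a synthetic phantom generator** — known-truth TNR fields with PSF
  blur and PET/CT voxel-size mismatch, reproducing the partial-volume
  effect, so the whole pipeline is testable without patient data.

## Worked example

```r
library(bnctdose)

cfg <- run_config(phantom = phantom_spec())   # default gradient phantom
bundle <- run_pipeline(cfg)
bundle$tnr
bundle$grouping
bundle$comparison
```

prints

```
<tnr_map 'GTV'> 1419 voxels, TNR 1.39-2.98, mean 2.17
<boron_grouping> I=50 groups over [1.39, 2.98], k=0.999755, 1419 voxels
Dose-rate statistics (cGy-Eq/s; difference row in %):
  roi         method  d_max    d_min d_mean    d_80
1 GTV           homo  1.598   1.3047  1.451   1.396
2 GTV         hetero  1.968   0.9274  1.450   1.222
3 GTV difference_pct 23.200 -28.9000 -0.100 -12.500
```

Reading: the phantom's true TNR spans 1.64–3.90 (mean 2.77), but the
PET chain (5 mm PSF, 5×5×3 mm PET voxels vs 1×1×3 mm CT) recovers
1.39–2.98 with mean 2.17 — the partial-volume effect. The groupwise
factor k ≈ 0.9998 confirms the 50-group quantization conserves the boron
inventory. Both boron models agree on the mean dose rate within 0.1 %
(same total atoms, nearly the same flux), but the homogeneous assumption
misses the dose range: it underestimates the hot-spot (Ḋ_max by 23 %)
and overestimates the cold-spot (Ḋ_min by 29 %) and the prescription
index (Ḋ₈₀ by 12.5 %). With `out_dir` set, the run also writes the TNR
histogram, grouping report, DVH curves, comparison tables and a run log.

A thin CLI over the same function lives at `inst/scripts/bnctdose.R`:

```sh
Rscript inst/scripts/bnctdose.R --field bimodal --radius 12 --out report/
```

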