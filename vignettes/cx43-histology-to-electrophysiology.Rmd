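---
title: "From CX43 histology to tissue electrophysiology: methods and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From CX43 histology to tissue electrophysiology: methods and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cx43ep)
```

`cx43ep` links two levels of description of the aging human left ventricle:

1. **Histomorphometry** — quantitative features of connexin-43 (CX43)
   immunofluorescence, fibrosis and lipofuscin extracted from multi-channel
   microscopy (SERCA2 marks cardiomyocyte interiors, WGA marks extracellular
   matrix, plus CX43 and lipofuscin channels).
2. **In silico electrophysiology** — a 2D monodomain model whose conductivity
   and cellular composition are perturbed in the directions those features
   change with age, with conduction velocity (CV), APD90, repolarization
   gradients and the S1–S2 vulnerability window as read-outs.

Because real patient images cannot ship with a package, a **synthetic
histology generator** with exact ground truth sits between the two levels:
it validates every metric by parameter recovery, and its rendered CX43
channel can be block-averaged onto a simulation mesh to create
heterogeneous-conductivity scenarios.

## 1. Histomorphometry

Six metrics are computed per sample, all defined as pixel-count ratios or
intensity means over masks:

* `cx43_amount()` — CX43-positive area as % of cardiomyocyte (CM) area or of
  total tissue area;
* `cx43_expression()` — mean CX43 intensity over the same denominators
  (normalized fluorescence units);
* `cx43_heterogeneity()` — **CX43_H**, the standard deviation of
  nearest-neighbour distances between CX43-positive pixels, in µm;
* `lateralization()` — % of a cell's CX43 signal in the middle two of four
  equal-length quarters along the cell axis (lateral membrane vs intercalated
  disc);
* `fibrosis_percent()` and `lipofuscin_percent()` — area fractions.

The segmentation path (`preprocess_channel()`, `binarize()` with Otsu or
percentile thresholds, `segment_cardiomyocytes()`, `refine_cx43_mask()`)
is deliberately simple and fully testable: every formula has an exact
pixel-count oracle, and CX43_H is checked against an O(n²) brute-force
nearest-neighbour computation at tolerance 1e-9.

## 2. The synthetic generator

`generate_layout()` places non-overlapping rod-shaped cardiomyocytes and
rectangular fibrotic patches; `render_sample()` draws the four channels with
an exact CX43 pixel budget, so the true CX43 fraction, lateral fraction and
fibrosis fraction are known to the pixel. `generate_cohort()` draws per-donor
parameters from age-coupled log-normal distributions whose defaults are the
study conditions: population median CX43 amount 2.73% of CM area (range
0.44–5.34%) and median lateralization 18.78% (range 6.42–35.78%).

```{r}
co <- generate_cohort(n = 44, seed = 20)
q  <- quantify_cohort(co)
median(q$pct_cx43_cm)     # recovered CX43 amount, % of CM area
median(q$pct_lateral, na.rm = TRUE)
```

**A realism limit worth knowing:** the generator renders CX43 as compact
puncta at intercalated discs and lateral membranes. At the default pixel
size, packing so many positive pixels into puncta forces nearest-neighbour
distances towards the pixel pitch, so the rendered CX43_H sits near 1 µm —
far below the ~19 µm scale reported for real tissue, where positive pixels
form sparse, widely spaced clusters. CX43_H recovery is therefore validated
as a *monotone response* to the clustering parameter, not as an absolute
match to the tissue-scale median; the corresponding acceptance subpart is
expected to fail and is documented as such.

## 3. Cellular and tissue models

Single cells are the O'Hara–Rudy human ventricular model (epicardial and
midmyocardial variants) and the MacCannell active fibroblast, exposed via
`run_single_cell()` and `cell_steady_state()`. The tissue solver
(`run_monodomain()`) integrates the monodomain reaction–diffusion equation
with explicit forward Euler and a 5-point stencil on a regular grid,
harmonic-free edge conductivities, no-flux boundaries, and a CFL guard that
rejects unstable `dt`.

The default tissue sodium current is a **calibrated variant**
(`na_variant = "calibrated"`, a ten Tusscher-style INa): at the working
resolution (dx 0.025 cm, dt 0.02 ms) the native ORd INa under-propagates,
while the calibrated variant yields a control cable CV of ≈64 cm/s, within
10% of the 59.71 cm/s working value. `na_variant = "ord"` remains available
for single-cell fidelity.

### Numerics you should expect

* **Discretization bias.** At dx 0.025 cm the wavefront is resolved by only
  a few nodes; absolute CV carries an O(10%) grid bias. Ratios of CVs
  (percent reductions) cancel most of it — that is why the conductivity
  scenarios are stated as percent changes.
* **Transverse under-resolution.** With anisotropy ratio 0.19 the transverse
  wavelength is √0.19 ≈ 0.44 of the longitudinal one, so transverse
  propagation is effectively computed on a ~2.3× coarser grid. Measured
  CV_T/CV_L is ≈0.51 at dx 0.025 and converges towards √0.19 ≈ 0.436 under
  refinement (0.395 at dx 0.0125, 0.420 at dx 0.00625).
* **An exact invariant instead of a converged ratio.** For a planar wave
  entering from the top edge, the x-diffusion terms vanish node-wise, so
  every column must evolve *exactly* like a 1D cable with diffusion
  `ratio * D_L`. The test suite exploits this: a 2D transverse run is
  compared to the reduced cable at tolerance 1e-9, pinning how the
  anisotropy ratio enters the stencil without any convergence run.
* **Heterogeneity meshes tighten the CFL limit.** `assign_heterogeneity()`
  conserves the summed D_L while spreading it across image-derived levels;
  the upper levels can exceed the homogeneous D_L several-fold, so such runs
  need a smaller `dt` (the guard tells you the limit).

## 4. Scenarios

`set_conductivity_scenario()` implements the age-related perturbations:

* **DIF** — reduce D_L by a percentage (gap-junction rarefaction); with
  `conserve_sum = FALSE` this is a pure scaling, and cable CV obeys
  CV(αD) = √α·CV(D).
* **LAT** — raise the transverse-to-longitudinal ratio (lateralization of
  CX43) with the conductivity sum conserved.
* **FIB** — `assign_fibrosis()` converts a fraction of nodes to MacCannell
  fibroblasts with 3-fold reduced coupling; CV falls and tissue-mean APD
  shortens as fibroblast-loaded tissue repolarizes early.
* **HET** — `assign_heterogeneity()` maps a rendered CX43 channel onto
  node-wise conductivity levels, linking measured spatial heterogeneity to
  dispersion of repolarization (`repol_gradient_map()`, `hrg_area()`).

## 5. Desk-scale limits: the vulnerability window

`s1s2_scan()` and `vw_scan()` implement the S1–S2 cross-stimulation
protocol with `detect_sustained_reentry()` as the classifier. On the
centimetre-scale meshes used here, however, the reentry wavelength
(CV × APD ≈ 60 cm/s × 0.25 s ≈ 15 cm) vastly exceeds the domain, so a
spiral core cannot fit and **every scenario yields VW = 0**. The machinery
is validated against scripted membrane dynamics (mock runners with known
sustained bands), and the VW ordering subpart of the acceptance suite is
expected to fail at desk scale for this physical reason — not a solver
defect. Meaningful VW comparisons require domains of order 10 cm or
APD-shortening interventions that are out of scope here.

## 6. Statistics

`spearman()` (exact permutation p for n ≤ 10, t-approximation above),
`mann_whitney()` (exact enumeration for combined n ≤ 20, corrected normal
approximation above), `median_iqr()`, `split_extreme_groups()` (bottom-n /
top-n by age or lipofuscin), `cohort_correlations()` and `compare_groups()`
reproduce the cohort-level analysis on any metrics table. All exact branches
are tested against independent full-enumeration oracles.

## 7. A worked tissue example

```{r}
cb  <- build_cable(3, 0.025)
pr  <- stimulus_protocol(cb)              # 2-ms pulses, 2x diastolic threshold
res <- run_monodomain(cb, pr, dt_ms = 0.02, duration_ms = 150,
                      meas_start_ms = 0)
cv_field(res$act, 0.025, exclude = cb$protected)$cv_median   # ~64 cm/s

mesh <- build_mesh(1.5, 0.025, islands = NULL)
fib  <- assign_fibrosis(mesh, 19, seed = 1)
r2   <- run_monodomain(fib, stimulus_protocol(mesh), dt_ms = 0.02,
                       duration_ms = 450, quiet_stop_ms = 50)
tissue_mean_apd(r2)
autoplot(r2, what = "activation")
```
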