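---
title: "Mapping task-related cortical networks from MEG: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping task-related cortical networks from MEG: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meghubs)
```

## The problem

Expressive language engages a distributed frontal–temporal network whose
regional membership — especially in children — is not well captured by
looking at focal activation alone. A whole-brain alternative is to estimate
source activity at every voxel of a grid covering the brain, quantify
pairwise functional coupling, and summarize the resulting graph with hub
(centrality) statistics and a hemispheric laterality index. `meghubs`
implements that pipeline end to end for MEG, together with a fully seeded
synthetic-data generator whose ground truth (which voxels desynchronize,
which voxel pairs couple, which hemisphere hosts the network) is known by
construction, so every stage can be validated without access to recordings.

## Pipeline overview

A subject-level run (`run_subject()`) executes a fixed stage order:

1. **Sensor-space cleaning** — baseline correction over $[-0.9, 0)$ s,
   line-noise attenuation at 60/120/180 Hz, a 0.1–100 Hz zero-phase
   band-pass, and jump-artifact trial rejection.
2. **Window extraction** — a $[-0.4, 0)$ s baseline and a $[0.6, 1.0)$ s
   active window (equal length; half-open sample selection throughout).
3. **Source inversion** — a scalar LCMV beamformer from a "common-filter"
   covariance pooled over both windows, applied per trial.
4. **ERD mapping** — relative low-beta (13–23 Hz) band-power change per
   voxel, with sign-flip permutation inference and Benjamini–Hochberg FDR.
5. **Connectivity** — broadband (3–30 Hz) phase-locking value (PLV) per
   voxel pair in each window; the stored adjacency is active minus baseline.
6. **Network analysis** — proportional binarization at 70% of the maximum,
   degree / eigenvector / betweenness centrality, parcel aggregation and the
   laterality index $\mathrm{LI} = (L - R)/(L + R)$ with a $\pm 0.25$
   cutoff.

`run_group()` adds per-label mean parcel maps (rescaled to $[0,1]$), a
parcel-wise independent-samples contrast with FDR correction, and a
laterality category table.

## Models and key choices

### Forward model

Sources are current dipoles inside a homogeneous conducting sphere,
evaluated with the closed-form field expression for that geometry. This
analytic model shares the property that matters for MEG beamforming —
radially oriented dipoles produce no external magnetic field — while being
exact, fast and free of anatomical inputs. Realistic single-shell models fit
to segmented MRI are out of scope; consequently the geometry here is a
sphere and "cortex" is operationalized as the outer radial shell of the
source grid. Source orientations are fixed tangential unit vectors (a
radial component would be silent anyway).

The source grid is an axis-aligned lattice staggered by half a spacing, so
no point falls on the midline plane (hemisphere membership is unambiguous)
or at the sphere center (which would be an exactly silent source).

### Beamformer

The LCMV filter for voxel $v$ with leadfield column $l_v$ is
$w_v = C_r^{-1} l_v / (l_v^\top C_r^{-1} l_v)$ with
$C_r = C + \lambda\,\overline{\mathrm{diag}(C)}\, I$ and $\lambda = 0.001$
(the conventional reading of "0.1% regularization"). The covariance $C$
pools the baseline and active windows (each demeaned separately), so both
windows are projected through identical weights and their power difference
reflects the sources rather than filter differences. The scalar orientation
per voxel is the tangential direction maximizing estimated output power —
the eigenvector of the *smallest* eigenvalue of
$L_v^\top C_r^{-1} L_v$ restricted to the tangential plane. The filter is
constructed to have unit gain at its own voxel, which the test suite
asserts to $10^{-9}$ at every non-silent voxel.

### Spectral estimation and PLV

Band power and spectral phases use a Hann-tapered DFT on each analysis
window. With 400 ms windows the frequency resolution is 2.5 Hz; bins are
retained for PLV when they carry at least `min_cycles = 2` oscillation
cycles per window, i.e. 5–30 Hz by default. The 3–5 Hz edge of the nominal
3–30 Hz band is not resolvable in a 400 ms window and is excluded by
default (`min_cycles = 1` restores it). The broadband PLV is the unweighted
mean of bin-wise PLV. Expected null PLV at $N$ trials is
$\sqrt{\pi/(4N)}$ — about 0.089 at $N = 100$ — and the planted-coupling
tests check observed values against an independent Monte-Carlo oracle.

### Statistics

The ERD contrast uses trial-level sign-flip permutations (the exact
exchangeability structure for paired windows), with add-one p-values
$p = (1 + \#\{|t^\ast| \ge |t|\})/(1 + n_\mathrm{rand})$ so $p$ is never
zero and the test is valid at any $n_\mathrm{rand}$. FDR control is
Benjamini–Hochberg step-up. The group contrast is Welch's t by default
(selectable pooled-variance), FDR-corrected across parcels.

### Graph analysis

The adjacency is binarized at a fraction (default 0.7) of its maximum
positive entry; task-related *decreases* never create edges under the
default `edge_sign = "positive"`. Eigenvector centrality is computed on the
largest connected component (zeros elsewhere; size ties broken toward the
component containing the lowest-index node) and scaled to max 1;
betweenness is unnormalized shortest-path betweenness with each unordered
pair counted once. Degree, EVC and betweenness are cross-checked in the
test suite against brute-force enumeration, a dense eigensolver and
exhaustive shortest-path enumeration. The laterality index aggregates
parcel-mean EVC by summation over frontotemporal parcels per hemisphere
(mean aggregation is selectable; the two agree when hemispheres have equal
parcel counts, which the mirrored synthetic atlas guarantees).

## The synthetic-data generator

`meg_scenario()` + `simulate_meg_dataset()` emulate one subject of a covert
verb-generation experiment: 71 stimulus-locked trials at 1200 Hz, epochs of
$-0.9$ to $1.8$ s, an instrumented helmet of radially oriented
magnetometers on the upper hemisphere of a shell, and ~10 fT sensor noise.
Three kinds of ground truth can be planted:

* **ERD voxels** carry a 13–23 Hz stochastic oscillation (band-limited
  filtered noise, not a deterministic sinusoid, so permutation statistics
  see realistic trial-to-trial variability) whose envelope drops to
  $\sqrt{1-d}$ across the active window: active-window band power is
  $(1-d)\times$ baseline power by construction.
* **Coupled pairs** share per-bin spectral phases in the active window with
  independent trial-wise jitter scaled by $(1 - c)$, so expected PLV grows
  monotonically with the planted strength $c$ (jitter of width
  $(1-c)\pi$ gives per-bin PLV $\mathrm{sinc}((1-c)\pi)$; $c=1$ is exact
  locking). Three design details matter:
  * Each voxel adds a *constant* per-bin phase lag, fixed across trials.
    PLV is invariant to a constant lag, but the lag decorrelates the
    time-domain waveforms — without it, near-perfectly correlated sources
    are partially cancelled by the minimum-variance beamformer (the
    classical correlated-source failure) and planted couplings vanish from
    the source estimates.
  * Coupled voxels are equally active in *both* windows: the baseline
    window carries the same spectral construction with independent phases.
    The task contrast is therefore a pure phase reorganization with no
    power confound, and leakage-induced "ghost" PLV between voxels near a
    planted source — which is window-symmetric — cancels in the
    active-minus-baseline adjacency.
  * Phase locking is transitive: two partners locked to one hub are locked
    to each other. The generator offers two answers. With `split_bins`
    (default) pairs sharing a hub divide the retained bins round-robin, so
    partners share no locked bins and the planted star is exact. The
    `hub_network_scenario()` preset instead locks every pair on the full
    band at moderate strength (c = 0.5): the transitive partner–partner
    locking then sits at the squared jitter spread
    (`sinc²((1-c)π)/sinc((1-c)π) ≈ 0.64` of the direct strength) and falls
    below a proportional edge threshold of 0.7, while the direct edges
    stay strong.
* **Amplitudes**: background voxels carry 1/f-like activity at 10 nA·m RMS;
  task-active sources are stronger (3× for ERD oscillations; 5× for
  coupled sources in the hub preset). Strong coupled sources matter twice:
  they raise the own-signal fraction of each voxel's estimate, and the
  minimum-variance filter *adaptively nulls* strong sources in neighboring
  voxels' estimates, so strong sources carry no leakage "halo" and the
  recovered graph is the planted star rather than a blur of near-clones.
  The hub preset also uses a coarser grid (2.5 cm) with a denser helmet
  (128 sensors) so that neighboring voxel estimates are spatially
  distinct at this channel count.

`build_synthetic_atlas()` partitions the grid into mirrored parcels: the
left hemisphere is grown into spatially contiguous parcels by multi-source
breadth-first search on the 6-neighbor lattice graph and mirrored exactly
onto the right (the staggered lattice maps onto itself under
$x \to -x$), with frontal/temporal annotations assigned by
anterior–posterior centroid and matched across hemispheres.

### What the generator does not emulate

Real anatomy and realistic noise covariance (environmental and
physiological artifacts other than step-like jumps), head movement,
inter-subject anatomical variability, and volume-conduction profiles of a
non-spherical head. Passing tests demonstrate that the pipeline's
estimators are correct and well calibrated under the stated generative
model — not that any particular real dataset would yield the same network
maps.

## Numerical conventions and degenerate inputs

* Half-open $[t_0, t_1)$ sample selection for every analysis window; the
  epoching step itself uses the inclusive convention
  (`round(2.7 * sfreq) + 1` samples for the default epoch).
* The band-pass is a windowed-sinc (Hamming) FIR of order
  `round(sfreq / 3)` by default, applied by reflection-padded FFT
  convolution with group-delay compensation — exactly zero phase, which the
  downstream phase estimates require. With a 0.1 Hz lower edge the filter's
  nominal high-pass transition is only realized on epochs much longer than
  desk scale; on 2.7 s epochs it behaves as a low-pass with DC blocking.
* Line noise is removed by least-squares projection onto sine/cosine pairs
  at each target frequency and its two neighboring DFT frequencies: exact
  for off-bin tones, local in frequency.
* Jump artifacts are scored per trial/channel as the largest single-sample
  step of the 9-sample running-median smooth; the robust z (median/MAD
  across trials, per channel) must exceed 20 — deliberately permissive,
  rejecting only gross steps.
* Zero-variance paired differences give $t = \pm\infty$ (sign of the mean);
  voxels with zero baseline power get `NA` relative change and are excluded
  from inference; an edgeless graph yields all-zero centralities with a
  warning; a parcel with no voxels propagates `NA`.
* All randomness is seeded; stage seeds are derived by hashing the stage
  name with the master seed, so inserting a stage never perturbs later
  stages' streams. Two runs with the same config and data produce
  byte-identical TSV exports.

## Problem sizes used in the tests

The suite validates on desk-scale geometries chosen to keep the full run
inside a few minutes while preserving the physics: 32–128 sensors,
conductor radii of 5.2–7 cm, 2–3 cm grids (45–160 voxels) for end-to-end
runs, and a 1 cm grid (~550 voxels) for the beamformer localization
checks; 24–100 trials at 300–400 Hz sampling. Permutation counts are
reduced (200–2000) where the add-one rule keeps the test valid at any
count. The acceptance script reports, among other quantities, median
localization error over 20 single-source scenarios, the planted-ERD
recovery and its empirical type-I error, null-PLV calibration, hub-parcel
recovery over 20 seeded runs, and the laterality classification of
left- and right-lateralized scenarios.

## Known limitations

* PLV is computed on raw beamformer outputs; no leakage correction
  (orthogonalization, imaginary coherence) is applied, matching the
  method being implemented. Leakage therefore inflates short-range
  coupling; the generator's window-symmetric design cancels it in the
  *difference* adjacency, but real data carry no such guarantee.
* The spherical forward model makes deep (central) voxels nearly silent;
  scenarios plant effects in the outer shell, as cortex would be.
* Group-level maps are rescaled after parcel aggregation (the alternative
  order is a documented choice, not exposed).
* The 10 mm grid of the original design is only used at reduced head
  radius; at 9 cm radius it would produce ~2600 voxels and a dense
  voxel-pair PLV at that size is outside desk-scale budgets.
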