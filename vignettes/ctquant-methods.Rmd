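---
title: "Methods: chromosome-territory quantification and the synthetic embryo field"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chromosome-territory quantification and the synthetic embryo field}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ctquant)
```

`ctquant` quantifies chromosome territories (CTs), chromosome arms and
homolog pairing in single nuclei of multichannel 3D fluorescence stacks.
This vignette explains the models and procedures the package implements,
the parameters that matter, what the bundled simulator does and does not
emulate, and the numerical choices behind the defaults.

## Conventions

Arrays are indexed `[z, y, x]`; voxel indices are 0-based internally, voxel
centres sit at `(index) * voxel_size` per axis, and every distance, area
and volume is in micrometres (µm, µm², µm³) using the per-axis voxel size —
anisotropic confocal grids (z-step > xy pixel) are handled everywhere
without resampling. Connectivity is 26-neighbour in 3D, stated once and
used by all components.

## Segmentation

Nuclei are segmented from the DNA counterstain: Gaussian smoothing in
physical units (`smooth_sigma_um`, default 0.15 µm), a global Otsu
threshold over a 256-bin histogram, then a seeded watershed on the
Euclidean distance transform (EDT) of the foreground. Seeds are the
regional maxima of the EDT after smoothing with `seed_smooth_um` (default
0.3 µm); maxima closer than `seed_min_sep_um` (default 2 µm, about one
nuclear radius) within one component are merged to suppress
plateau-induced oversegmentation. The EDT is an exact anisotropic
lower-envelope transform, so watershed splitting respects physical
geometry. Components below `min_volume_um3` (default 20 µm³, well under a
blastoderm nucleus) are discarded; border-touching nuclei are flagged and,
by default, excluded from analysis because their volumes are truncated by
the stack — the flag is exposed because either convention is defensible.

FISH signals are thresholded per nucleus (Otsu on within-nucleus
intensities), so each nucleus gets its own cutoff regardless of staining
variability across the field. The same watershed split is applied with a
smaller merge radius (default 1.2 µm): one territory signal is never split,
while two homolog signals bridged by PSF blur are. Each component is
assigned to the nucleus containing its centroid — simpler than majority
voting and tie-free. Foreground voxels outside every nucleus are discarded
and counted in a diagnostic.

## Morphometrics

Volume is exactly voxel count × voxel volume. Surface area comes from an
indexed marching-tetrahedra iso-surface (each grid cell split into six
tetrahedra, linear interpolation at level 0.5, physical spacing). A binary
mask meshes into a voxel staircase whose facets overestimate the area of
oblique surfaces by ~25%, so the mask is lightly Gaussian-blurred
(`pre_smooth_sigma_vox`, default 0.7 voxels) before meshing; objects too
small to survive the blur fall back to the raw binary mesh.

Sphericity is π^⅓(6V)^⅔ / A with V and A both taken from the mesh
(mesh-enclosed volume via the divergence theorem over the oriented
triangles). This self-consistency matters: mixing the voxel-count volume
with the mesh area leaves a resolution-dependent bias, whereas the
mesh-intrinsic ratio converges to the true sphericity as resolution grows.
Against closed forms, a digital ball of radius 20 voxels measures 0.978, a
60-voxel cube 0.820 versus (π/6)^⅓ ≈ 0.806, and balls from radius 5 to 40
voxels rise monotonically toward 1. The smoothing sigma trades staircase
suppression (favouring larger sigma) against corner rounding on polyhedral
shapes (favouring smaller); 0.7 voxels keeps both within ~2% at the object
sizes the pipeline measures. Absolute sphericities from other estimators
may differ by a small constant; comparisons between conditions are the
supported use.

Territory intermixing is the voxelwise intersection of two channels'
signals within a nucleus, reported as a percent of each channel's own
volume. Normalized volume is the plain ratio to the host nuclear volume;
for paired-versus-unpaired comparisons the unpaired side uses the combined
volume of the two homolog signals before normalizing, so both sides carry
the same chromatin content. Focus analysis (e.g. histone-locus-body
volume, or polymerase intensity excluding its dominant foci) thresholds at
the larger of a within-nucleus Otsu cutoff and a high intensity quantile
(default 0.9), keeps the `k_foci` largest components (defaults follow
ploidy: 2 for diploid, 1 for haploid runs), and averages the remaining
nucleoplasmic intensity.

## Homolog pairing

A nucleus × target is *paired* when the two signal centroids are at most
0.8 µm apart in 3D (inclusive, exactly as the rule is stated) or when only
one signal is present — fully merged homologs. Centroids of segmented
signals replace manually picked points: they are the reproducible
surrogate. Zero signals (dropout) or more than two (S-phase doublets,
splits) are `ambiguous` and excluded from percentages rather than guessed.
Arm and centromere calls use the same rule on their own channels; the two
arm states and the centromere state cross into six conformation classes.
Percent paired is computed per replicate over non-ambiguous calls and
summarized as mean ± SD across replicates (the replicate, not the nucleus,
is the error-bar unit); summaries with fewer than 300 total nuclei or 3
replicates are returned but flagged non-reportable.

## Statistics

Group comparisons are the field's standard nonparametrics, with exact
small-sample paths: Mann-Whitney two-sided U (exact U distribution for
n ≤ 12 without ties; full enumeration of group assignments with midranks
when ties are present; tie-corrected, continuity-corrected normal
approximation otherwise), Fisher's two-tailed exact test (sum of
hypergeometric probabilities not exceeding the observed table's), and
Levene's test as a one-way ANOVA on absolute deviations from the group
centre — median-centred by default (Brown-Forsythe), because the robust
variant is the safer default when the centre is unstated, with
mean-centring available. No multiple-testing correction is applied;
comparisons are reported per test.

Bimodality of normalized paired-arm volumes is operationalized as: Gaussian
KDE; modes are interior local maxima with density at least 5% of the global
maximum (a prominence floor, configurable); bimodal means two or more
qualifying modes; the antimode is the interior minimum between the two
highest. The default bandwidth is the normal-reference rule with Scott's
1.06 factor: at the n ≈ 500 scale of per-arm populations, the tighter 0.9
factor undersmooths enough to admit spurious tail modes in ~11% of
unimodal samples, while the 1.06 factor brings that to ~2% with unchanged
sensitivity on well-separated mixtures. Samples below n = 20 and constant
samples return unimodal with a flag.

## The synthetic embryo field

The simulator generates what the pipeline is designed to measure, with
exact ground truth:

- **Nuclei** — non-overlapping, axis-aligned ellipsoids,
  radius 2.5 µm ± 10% per-axis jitter (a blastoderm-like diploid regime),
  rejection-sampled with a border margin of one maximal radius so nuclei
  clear the stack edge (override the margin to exercise border handling).
  Infeasible requests fail with a "field too crowded" error after a bounded
  number of attempts.
- **Territories** — per channel, a fraction of nuclear volume (default
  0.06) rendered as a scaled ellipsoid with optional irregularity: a
  smooth random radial modulation (star-shaped by construction, hence
  always connected, volume preserved within ~10% at irregularity 1).
- **Pairing** — each nucleus × channel draws its true state at the
  configured `pairing_fraction`. Paired pairs render as one merged signal
  (probability `paired_mode_merged_prob`, default 0.5, the
  "single FISH signal" case) or as two signals with centre distance
  uniform in (0, 0.8] µm. Unpaired distances are uniform between
  max(1.5 × threshold, blob diameter + 0.5 µm) and 3 × threshold: the
  lower bound both avoids decision-boundary ambiguity and guarantees the
  two signals remain resolvable after PSF blur — without the clearance
  term the blobs would physically overlap and "two signals" would not be a
  meaningful ground truth. The default territory fraction is sized so this
  window is non-empty inside a 2.5 µm nucleus.
- **Foci** — optional bright spheres (radius 0.5 µm, two per nucleus by
  default) over a uniform nucleoplasmic level in an intensity channel,
  emulating dominant nuclear bodies.
- **Optics** — anisotropic Gaussian PSF (default σ = 0.3 µm axial,
  0.12 µm lateral, a high-NA confocal regime), then per-voxel Poisson shot
  noise at `photon_scale` photons per intensity unit and additive Gaussian
  read noise. Real confocal stacks of this kind come with no published
  intensity statistics, so the default photon scale is a free choice set to
  yield SNR ≈ 10 on the DNA channel at its default intensity of 100.

Identical configuration and seed give bit-identical stacks and truth
tables; the caller's RNG state is restored afterwards.

What the simulator does **not** emulate — and hence what passing tests do
not show about real data: realistic PSFs (no Gibson–Lanni model or
depth-dependent aberration), chromatin texture within territories,
cross-channel bleed-through, mitotic figures, embryo-scale tissue curvature,
and segmentation-adversarial staining gradients. Recovery results on
simulated fields certify the algorithms, not the biology of any particular
stack.

## Problem sizes

The test-suite and acceptance computations run at deliberately chosen
scales: geometry oracles on ~40–60-voxel objects; segmentation recovery on
a 50-nucleus field at (0.35, 0.22, 0.22) µm voxels; pairing recovery as
3 replicates × 300 nuclei at each generating fraction (0.2, 0.5, 0.8) on
(0.4, 0.25, 0.25) µm grids — coarser than the default simulation grid,
which the pairing geometry tolerates because all placement gaps are several
voxels wide; statistical calibration with 2000 null replicates of n = 50
per group and 200 mixture replicates of n = 500. These sizes reproduce the
study's per-replicate nucleus counts while keeping a full run in minutes on
one CPU.

## Known limitations

- Absolute surface areas (and hence sphericities) carry an estimator
  constant of up to ~2–4% depending on object size and anisotropy.
- Signal-count ground truth is undefined when two paired homolog blobs are
  rendered overlapping; count-recovery checks therefore use the merged
  paired mode.
- Pairing calls treat signal dropout as `ambiguous`; no correction is
  applied for the bias this may induce when dropout correlates with state.
- The per-nucleus Otsu threshold assumes each nucleus contains both signal
  and background voxels in its FISH channel; a channel that is uniformly
  bright across a nucleus will not segment sensibly.
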