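---
title: "Quantifying nuclear condensates: methods and design notes"
author: "condensateR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying nuclear condensates: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(condensateR)
```

# Scope

condensateR quantifies nuclear biomolecular condensates — the bright puncta
formed by fusion oncoproteins such as ZFTA–RELA — from multichannel 3D
fluorescence z-stacks, together with the three companion assays that
commonly accompany such imaging studies: locus-centered colocalization
profiling against an in-nucleus random null, FRAP (fluorescence recovery
after photobleaching) with double normalization, and CSI/SELEX k-mer
enrichment for DNA-binding-site discovery. Every stage has a synthetic-data
generator with known ground truth, so the whole pipeline is testable
end-to-end without microscope data.

# Coordinate and intensity conventions

All voxel coordinates are `(z, y, x)`, 1-based as is natural in R, and all
bounding boxes are half-open: a box `(z0, z1)` covers slices `z0` to
`z1 - 1`, so `z_extent = z1 - z0`. The default voxel size is
`(0.2, 0.11, 0.11)` µm, matching spinning-disk acquisition with 110-nm
pixels and 0.2-µm plane spacing. `rescale16bit()` maps a channel linearly
onto 0–65535 with round-half-even; a constant channel maps to all zeros,
and the same degenerate min==max rule is used wherever intensities are
min–max normalized. Rescaling is applied per stack; per-plane rescaling
would make planes with different dynamic ranges incomparable along z.

# Segmentation

Nuclei are segmented from the DAPI channel by Gaussian smoothing (default
sigma `(1, 2, 2)` voxels), Otsu thresholding on a 256-bin histogram, 3D
hole filling, 26-connectivity connected components, and a minimum-volume
filter (default 2000 voxels ≈ 5 µm³). Labels are ordered by descending
volume with ties broken by first-voxel raster order. Touching nuclei are
not split (no watershed); fields should be sparse enough that nuclei are
separable, which is a documented limitation.

Puncta detection offers two routes with one downstream representation:

* the built-in detector thresholds each nucleus at a per-nucleus intensity
  quantile (default 0.995) and keeps 26-connected components of at least
  `minSpotVox = 5` voxels. Because the threshold is a rank statistic, the
  result is invariant under monotone intensity transforms. The defaults
  were chosen so that well-separated, high-SNR synthetic spots are
  recovered with recall and precision 1; both are configurable.
* `importPunctaMask()` accepts externally produced label or probability
  volumes (e.g. from an interactively trained pixel classifier, whose
  training is inherently irreproducible and therefore outside this
  package); probability volumes are cut at 0.5 by default and relabeled.

Per-punctum geometry uses intensity-weighted centroids by default
(binary-mask centroids by flag — the choice matters little for compact
spots but weighted centroids are less sensitive to ragged mask edges).
"Cell volume" is implemented as nucleus volume: the DAPI mask is the only
compartment the data define; no whole-cell marker is assumed.

# Puncta density and QC

The per-cell statistic is puncta per 100 µm³:
`density = 100 * n_puncta / nucleus_volume`. Two exclusion rules are
applied before any cross-condition comparison, in this order:

1. cells with nucleus volume strictly below 200 µm³ are flagged as
   mis-segmented or out-of-frame;
2. among the remaining cells of each condition, the `floor(n/3)` cells
   with the lowest mean reporter intensity are flagged (rank-based, ties
   broken by input order). An optional expression floor can first remove
   cells that are not expressing at all; by default every cell that
   survives the volume cut counts as expressing, since a cell with zero
   puncta but clear reporter signal is biologically "expressing, not
   condensed" and must stay in the denominator.

The fraction and the rounding rule (`floor`, input-order ties) are
declared conventions: a rank-based bottom third has no unique definition
at ties, and declaring one keeps the filter reproducible and invariant
under monotone intensity transforms.

# Locus-centered box profiles and the random null

For each punctum, a 61×61-pixel box is centered laterally on the rounded
centroid. For every z-slice of the punctum's bounding box the box patch is
gathered from the channel of interest; the gathered block is min–max
normalized to [0, 1] *per locus* and then averaged over z, giving one
matrix per locus; matrices are averaged over loci. Per-locus normalization
makes each locus contribute equally regardless of local brightness and
renders the profile exactly invariant under affine intensity transforms of
the profiled channel; it is also the only order of operations under which
"normalize, then average" is well defined locus by locus. Loci closer than
30 pixels to the lateral image border are skipped and counted rather than
padded — padding would distort the per-locus normalization.

The null model re-runs the *same* gathering code at random in-nucleus
loci: per cell, exactly as many unique random locations as the cell has
puncta, each accepted only if the full 61×61 footprint lies inside the 2D
projection of the nucleus mask over the locus's z-window. The z-window
length is an integer drawn uniformly between the smallest and largest
punctum z-extent of that cell; the window is centered on the nucleus
mid-plane of the sampled column (the length is specified by the matching
rule; the placement is a declared choice, and integer lengths are used
because z-extents are slice counts). Sampling is rejection-based with a
deterministic per-cell seed derived from the master seed and the cell id,
so adding or removing cells never perturbs other cells' draws.

`enrichmentSummary()` reduces a profile to the mean over the central
11×11 patch, the mean over the outermost 1-pixel ring, and their ratio;
a ratio of 1 means no center enrichment. The RNA-FISH mode swaps roles:
boxes are centered on FISH loci and intensities are gathered from the
reporter channel, with the identical matched null.

# FRAP double normalization

Raw traces are per-frame means of the bleach ROI (1-µm radius disc), the
whole nucleus (2D mask of the imaged plane — FRAP movies are single
plane), and a background region, on a uniform grid (default 1 s). The
normalized trace is

$$v(t) = \frac{(ROI - bg)(t) / (nuc - bg)(t)}
             {\langle (ROI - bg)/(nuc - bg) \rangle_{pre}}$$

Division by the whole-nucleus signal per frame cancels any multiplicative
whole-field decay exactly (acquisition photobleaching hits both numerator
and denominator); division by the prebleach mean — the mean over *all*
prebleach frames — fixes the prebleach level at exactly 1. Ensembles are
pointwise means ± s.d. across cells on a shared grid (no resampling), with
a LOESS curve (default span 0.3, a smoothing choice) through the
postbleach means; the prebleach segment is carried as-is because a single
LOESS across the bleach step would smear the discontinuity. The optional
single-exponential fit
$v(t') = v_b + (plateau - v_b)(1 - e^{-kt'})$ reports
`mobile_fraction = (plateau - v_b)/(1 - v_b)` and `halftime = ln 2 / k`;
an exactly flat postbleach curve returns the zero-amplitude solution
(mobile fraction 0) rather than failing.

# CSI/SELEX k-mer enrichment

Reads are assigned by barcode prefix (exact by default; a mismatch
tolerance exists but the prefix set must stay unambiguous), the 20-bp
randomized region is cut out between the constant flanks (at most one
substitution per flank by default), and k-mers are counted in sliding
windows of step 1, so a region of length L contributes L − k + 1 windows.
The default k = 6 matches the length of the GGCCCC binding sequence the
assay is designed to find; reverse-complement counting is off by default
because binding sequences are reported single-strandedly, with a flag for
double-stranded counting.

Enrichment of the selected pool over the fusion-negative pool is a
frequency ratio with a symmetric pseudofrequency added to both sides
(default one window's worth, `1/totalPositions`): a ratio is scale-free
across sequencing depths, and the pseudofrequency keeps k-mers absent from
the negative pool finite while leaving k-mers absent from both at exactly
1. Ranking is by descending enrichment with a stable lexicographic
tie-break. Both a final-round table and per-round trajectories (with a
strict-monotone-increase flag) are produced, since selection assays are
read both ways; the exact normalization arithmetic against the negative
pool is a declared convention of this package, not a reconstruction of
any particular original script.

# The synthetic-data generators

The generators define the study conditions the tests run under:

* **Images** — ellipsoidal nuclei (default semi-axes `(9, 75, 75)` voxels
  in a `24×220×220` stack, i.e. a ≈16.5 µm × 3.6 µm nucleus) with
  isotropic-in-pixels 3D Gaussian spots (σ = 1.5 voxels, truncated at
  4σ, peak 12000 over background 300, Gaussian read noise σ = 50, clipped
  to 16 bits). Puncta centers are sampled uniformly within 90% of each
  semi-axis at ≥ 10-voxel separation. The lateral nucleus size is chosen
  so that every feasible 61×61 random-null footprint lies in a region
  where the planted spot density is uniform (the z-window caps the column
  depth), making the random null unbiased by construction — on a much
  smaller nucleus the null boxes would correlate with the nucleus center
  and inherit its spot density gradient. A partner channel places a
  chosen fraction of its spots exactly at reporter centers and the rest
  uniformly in the nucleus. Not emulated: a real PSF, Poisson noise,
  camera gain, chromatic shift, stage drift, nucleoli, or touching
  nuclei — so passing tests demonstrate the correctness of the
  *computation*, not robustness to every imaging artifact.
* **FRAP** — closed-form single-exponential recovery with known bleach
  depth, mobile fraction, rate, optional whole-field photobleaching and
  additive Gaussian noise; the normalized plateau is analytically
  `(1 - d) + d·m`.
* **SELEX** — barcoded reads `barcode + flank + N20 + flank` with the
  motif embedded at a uniform offset in a per-round fraction of reads
  (default 0.05/0.15/0.40 over three rounds for the positive sample, 0
  everywhere for the fusion-negative control) and constant Q37 qualities.

Every generator is a pure function of its parameter list including the
seed.

# Numerical and reproducibility choices

* All randomness is drawn under seeds derived from a master seed by
  stage-name hashing (kept below 2³¹), so adding a stage never changes
  another stage's draws; user RNG state is saved and restored.
* Connected components use 26-connectivity in 3D throughout; equal-volume
  label ties are broken by first-voxel raster order.
* TIFF stacks are written as multi-page 16-bit with a JSON sidecar
  carrying layout, voxel size and channel labels; integer-valued arrays
  round-trip bit-identically. Probability masks on the 16-bit scale are
  mapped back to [0, 1] on import.
* Degenerate inputs follow one rule: constant blocks normalize to zero;
  an all-background segmentation is a warning, not an error; a profile
  with zero edge mean reports an infinite ratio with a flag; a punctum
  straddling two nuclei is assigned by centroid and flagged.

# Problem sizes

The shipped tests and the acceptance script run entirely on synthetic
data at desk scale: 8–11 cells per colocalization condition (≥ 80 loci
per condition), 19-cell FRAP ensembles (matching the ensemble size such
experiments typically average), 10,000 reads per SELEX round, and
3-stack pipeline runs. These sizes were chosen as the smallest at which
the Monte-Carlo error of each statistic is comfortably below the margins
being tested.

# Known limitations

* No watershed splitting of touching nuclei and no cell tracking.
* The built-in puncta detector is a quantile thresholder; it is the
  reference path, not a reimplementation of any trained classifier.
* FRAP fitting is single-exponential; reaction–diffusion models and
  bleach-spot geometry corrections are out of scope.
* Pixel-wise correlation statistics (Pearson/Manders) are deliberately
  absent: the box-profile/null machinery answers a different question.
* Motif naming against databases (e.g. calling GGCCCC "Plagl-type") is
  outside the package; it reports ranked k-mers only.
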