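# condensateR

Quantitative analysis of nuclear biomolecular condensates from
multichannel 3D fluorescence imaging, with the companion assays that
usually travel with such studies.

Fusion oncoproteins such as ZFTA–RELA form liquid-like nuclear
condensates that appear as bright puncta in a fluorescent reporter
channel. Asking whether those condensates matter requires a small family
of quantitative procedures, and this package implements them as one
tested toolkit:

* **Puncta detection and density** — nucleus segmentation from DAPI,
  puncta segmentation (built-in quantile detector or imported
  classifier masks), per-punctum 3D geometry, and the per-cell statistic
  *density = 100 · n<sub>puncta</sub> / V<sub>nucleus</sub>* (puncta per
  100 µm³), with the two standard QC exclusions: cells with nucleus
  volume < 200 µm³, and the bottom ⅓ of expressing cells by mean
  reporter intensity per condition.
* **Colocalization box profiles** — for each condensate, a 61×61-pixel
  box centered on its centroid; target-channel intensities are gathered
  over the punctum's z-extent, min–max normalized per locus, z-averaged
  and then averaged over loci. The null model repeats the identical
  computation at an equal number of unique random in-nucleus loci whose
  box footprints fit entirely inside the nucleus and whose z-windows are
  drawn between the smallest and largest condensate z-extent of the
  cell. An RNA-FISH mode centers boxes on FISH loci and profiles the
  reporter instead. The scalar summary is the central-patch mean over
  the edge-ring mean ("enrichment ratio"; 1 = no center enrichment).
* **FRAP** — double normalization
  *v(t) = [(ROI−bg)/(nuc−bg)](t) / ⟨same⟩<sub>prebleach</sub>*, which
  cancels whole-field acquisition photobleaching exactly and pins the
  prebleach level at 1; ensemble mean ± s.d. across cells with a LOESS
  curve through the postbleach means; optional single-exponential fit
  reporting mobile fraction and recovery halftime.
* **CSI/SELEX motif ranking** — FASTQ demultiplexing by barcode,
  extraction of the 20-bp randomized region between constant flanks,
  sliding-window k-mer counts (k = 6 by default), and enrichment =
  pseudofrequency-stabilized frequency ratio against the fusion-negative
  control pool, ranked; per-round trajectories flag monotonically
  enriching k-mers.
* **Synthetic data with ground truth** for every stage: 3D stacks with
  planted nuclei/puncta and a tunable colocalized fraction, FRAP traces
  with known bleach depth/mobile fraction/rate, and barcoded SELEX pools
  with a planted motif growing over rounds.

The package is written Bioconductor-style: S4 classes (`ImageStack`,
`LabelMask`, `PunctaSet`, `BoxProfile`, `FrapTrace`, `FrapEnsemble`,
`KmerTable`, `EnrichmentTable`) with validity checks, accessors and
`show()` methods.

## Worked example

```r
library(condensateR)

## synthetic ground-truth stack: 1 nucleus, 10 puncta, all partner
## spots placed at reporter punctum centers
sim <- simulateStack(syntheticImageParams(seed = 1, colocFraction = 1))
st  <- sim$stack
st
#> ImageStack [czyx]: 3 x 24 x 220 x 220; voxel size (z,y,x) = 0.2 x 0.11 x 0.11 um
#>   channels: reporter, partner, dapi

nuc  <- segmentNuclei(getChannel(st, "dapi"), voxelSize = voxelSize(st))
rep_ <- getChannel(st, "reporter")
sets <- extractPuncta(segmentPuncta(rescale16bit(rep_), nuc), nuc, rep_,
                      stack = st, condition = "demo")
sets[[1]]
#> PunctaSet 'cell001' (condition demo): 10 puncta; nucleus 512.6 um^3

computeCellMetrics(sets)[, c("cell_id", "nucleus_volume", "n_puncta",
                             "puncta_density")]
#>   cell_id nucleus_volume n_puncta puncta_density
#> 1 cell001       512.5971       10        1.95085

## condensate-centered partner-channel profile vs matched random null
target <- getChannel(st, "partner")
prof  <- profilePuncta(sets, target)
nullp <- profileRandomNull(target, nuc, sets, seed = 2)
enrichmentSummary(prof)$ratio    # 5.15  : strong center enrichment
enrichmentSummary(nullp)$ratio   # 1.10  : null is flat

## FRAP: bleach depth 0.8, mobile fraction 0.5 -> plateau 0.6
nt <- normalizeFrap(simulateFrap(syntheticFrapParams(
  bleachDepth = 0.8, mobileFraction = 0.5, noiseSd = 0,
  nPost = 150))$trace)
tail(nt@value, 1)
#> [1] 0.6
```

The density (1.95 per 100 µm³) is 10 puncta in a 513-µm³ nucleus. The
enrichment ratio of ~5 at condensates against ~1 at random loci is the
signature of genuine colocalization; with `colocFraction = 0` both sit
near 1. The FRAP plateau 0.6 equals (1 − 0.8) + 0.8 · 0.5, the analytic
value for that bleach depth and mobile fraction.

An end-to-end run with every stage (synthetic data → segmentation → QC →
colocalization → FISH mode → FRAP → motif ranking), writing CSV/TIFF/TSV
artifacts plus a checksummed manifest:

```r
runPipeline("myrun", config = defaultPipelineConfig(masterSeed = 1))
```

or from a shell: `Rscript inst/scripts/condensate-pipeline.R --out myrun
--seed 1`.

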