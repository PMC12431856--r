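#' @useDynLib condensateR, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' ImageStack: a multichannel 3D (or 2D time-lapse) intensity stack
#'
#' Container for fluorescence image data with physical voxel sizes and
#' channel labels. The array layout is declared explicitly:
#' \code{"zyx"} for a single-channel z-stack, \code{"czyx"} for a
#' multichannel z-stack, \code{"tyx"} for a single-plane time-lapse and
#' \code{"yx"} for a single plane (stored with \code{nz = 1}).
#'
#' Coordinates throughout the package are voxel-indexed in \code{(z, y, x)}
#' order and bounding boxes are half-open on 1-based R indices:
#' a box \code{(z0, z1)} covers slices \code{z0} to \code{z1 - 1}.
#'
#' @slot data numeric array, indexed \code{(z, y, x)}, \code{(c, z, y, x)}
#'   or \code{(t, y, x)} according to \code{layout}.
#' @slot layout character, one of \code{"zyx"}, \code{"czyx"}, \code{"tyx"}.
#' @slot voxelSize numeric length-3, micrometres per voxel along
#'   \code{(z, y, x)} (for \code{"tyx"} the first entry is seconds per frame).
#' @slot channelLabels character, one label per channel (length 1 for
#'   single-channel layouts).
#' @slot bitDepth integer, bit width of the source data (16 for the
#'   acquisition emulated here).
#'
#' @exportClass ImageStack
setClass("ImageStack",
  representation(
    data = "array",
    layout = "character",
    voxelSize = "numeric",
    channelLabels = "character",
    bitDepth = "integer"
  ),
  prototype(
    layout = "zyx",
    voxelSize = c(0.2, 0.11, 0.11),
    channelLabels = "channel1",
    bitDepth = 16L
  )
)

setValidity("ImageStack", function(object) {
  msg <- character()
  lay <- object@layout
  if (!lay %in% c("zyx", "czyx", "tyx"))
    msg <- c(msg, "layout must be one of 'zyx', 'czyx', 'tyx'")
  nd <- length(dim(object@data))
  if (lay == "czyx" && nd != 4L)
    msg <- c(msg, "'czyx' layout requires a 4D array")
  if (lay %in% c("zyx", "tyx") && nd != 3L)
    msg <- c(msg, sprintf("'%s' layout requires a 3D array", lay))
  if (any(dim(object@data) < 1L))
    msg <- c(msg, "all dimensions must be >= 1")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    msg <- c(msg, "voxelSize must be 3 positive numbers (z, y, x)")
  nchan <- if (lay == "czyx") dim(object@data)[1L] else 1L
  if (length(object@channelLabels) != nchan)
    msg <- c(msg, "channel count must equal channel label count")
  if (length(msg)) msg else TRUE
})

#' LabelMask: an integer label volume
#'
#' Integer array of the same spatial shape as its parent
#' \linkS4class{ImageStack}; 0 is background and positive integers
#' identify objects (nuclei or puncta).
#'
#' @slot labels integer array, dim \code{(nz, ny, nx)}.
#' @slot voxelSize numeric length-3, micrometres per voxel (z, y, x).
#'
#' @exportClass LabelMask
setClass("LabelMask",
  representation(labels = "array", voxelSize = "numeric"),
  prototype(voxelSize = c(0.2, 0.11, 0.11))
)

setValidity("LabelMask", function(object) {
  msg <- character()
  if (length(dim(object@labels)) != 3L)
    msg <- c(msg, "labels must be a 3D array")
  if (any(object@labels < 0L))
    msg <- c(msg, "labels must be non-negative")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    msg <- c(msg, "voxelSize must be 3 positive numbers")
  if (length(msg)) msg else TRUE
})

#' PunctaSet: detected condensates of one cell
#'
#' Per-nucleus collection of detected puncta with geometry and intensity
#' statistics, plus the summary metrics of the parent nucleus that the
#' density and QC computations need.
#'
#' The \code{puncta} data frame has one row per punctum with columns
#' \code{punctum_id}, \code{z}, \code{y}, \code{x} (intensity-weighted
#' centroid, voxels), \code{z0, z1, y0, y1, x0, x1} (half-open bounding
#' box), \code{z_extent} (\code{z1 - z0}, slices), \code{volume_um3},
#' \code{mean_intensity}, \code{max_intensity} and \code{straddles}
#' (TRUE when the punctum touched more than one nucleus and was assigned
#' by centroid).
#'
#' @slot cellId character cell identifier.
#' @slot nucleusId integer label of the nucleus in its LabelMask.
#' @slot condition character condition tag.
#' @slot nucleusVolume numeric, nucleus volume in cubic micrometres.
#' @slot nucleusVoxels integer, nucleus voxel count.
#' @slot meanIntensity named numeric, mean intensity over the nucleus mask
#'   per channel label.
#' @slot voxelSize numeric length-3 (z, y, x) micrometres.
#' @slot puncta data.frame as described above.
#'
#' @exportClass PunctaSet
setClass("PunctaSet",
  representation(
    cellId = "character",
    nucleusId = "integer",
    condition = "character",
    nucleusVolume = "numeric",
    nucleusVoxels = "integer",
    meanIntensity = "numeric",
    voxelSize = "numeric",
    puncta = "data.frame"
  ),
  prototype(condition = "unknown")
)

setValidity("PunctaSet", function(object) {
  msg <- character()
  p <- object@puncta
  need <- c("punctum_id", "z", "y", "x", "z0", "z1", "y0", "y1", "x0", "x1",
            "z_extent", "volume_um3", "mean_intensity", "max_intensity")
  if (!all(need %in% names(p)))
    msg <- c(msg, "puncta data frame is missing required columns")
  if (nrow(p)) {
    if (any(p$z_extent < 1L)) msg <- c(msg, "z_extent must be >= 1")
    if (any(p$volume_um3 <= 0)) msg <- c(msg, "punctum volume must be > 0")
    inside <- p$z >= p$z0 - 0.5 & p$z <= p$z1 - 0.5 &
      p$y >= p$y0 - 0.5 & p$y <= p$y1 - 0.5 &
      p$x >= p$x0 - 0.5 & p$x <= p$x1 - 0.5
    if (!all(inside)) msg <- c(msg, "centroid must lie inside its bbox")
  }
  if (object@nucleusVolume <= 0) msg <- c(msg, "nucleus volume must be > 0")
  if (length(msg)) msg else TRUE
})

#' BoxProfile: an averaged, normalized locus-centered intensity box
#'
#' The 61x61 (by default) matrix of mean per-locus min-max-normalized
#' intensities around a set of loci: condensate centroids, matched
#' in-nucleus random loci, or RNA-FISH loci.
#'
#' @slot matrix numeric boxSize x boxSize matrix with entries in [0, 1].
#' @slot nLoci integer, number of loci contributing to the average.
#' @slot nSkipped integer, loci skipped for falling within boxSize %/% 2
#'   pixels of the lateral image border.
#' @slot channel character, label of the profiled channel.
#' @slot mode character, one of \code{"condensate-centered"},
#'   \code{"random-null"}, \code{"fish-centered"}.
#'
#' @exportClass BoxProfile
setClass("BoxProfile",
  representation(
    matrix = "matrix",
    nLoci = "integer",
    nSkipped = "integer",
    channel = "character",
    mode = "character"
  ),
  prototype(nSkipped = 0L, mode = "condensate-centered", channel = "target")
)

setValidity("BoxProfile", function(object) {
  msg <- character()
  m <- object@matrix
  if (nrow(m) != ncol(m)) msg <- c(msg, "profile matrix must be square")
  if (any(m < -1e-9 | m > 1 + 1e-9))
    msg <- c(msg, "profile entries must lie in [0, 1]")
  if (object@nLoci < 1L) msg <- c(msg, "nLoci must be >= 1")
  if (!object@mode %in% c("condensate-centered", "random-null", "fish-centered"))
    msg <- c(msg, "unknown profile mode")
  if (length(msg)) msg else TRUE
})

#' FrapTrace: raw FRAP ROI measurements for one cell
#'
#' Per-frame mean intensities of the bleach ROI, the whole nucleus and a
#' background region, on a uniform time grid, with the bleach frame index.
#'
#' @slot time numeric, seconds per frame (uniform grid).
#' @slot roiMean,nucleusMean,backgroundMean numeric, per-frame means.
#' @slot bleachIndex integer, first postbleach frame (>= 2, so at least
#'   one prebleach frame exists).
#' @slot roiRadiusUm numeric, bleach ROI radius in micrometres (default 1).
#' @slot cellId character.
#'
#' @exportClass FrapTrace
setClass("FrapTrace",
  representation(
    time = "numeric",
    roiMean = "numeric",
    nucleusMean = "numeric",
    backgroundMean = "numeric",
    bleachIndex = "integer",
    roiRadiusUm = "numeric",
    cellId = "character"
  ),
  prototype(roiRadiusUm = 1, cellId = "cell1")
)

setValidity("FrapTrace", function(object) {
  msg <- character()
  n <- length(object@time)
  if (length(object@roiMean) != n || length(object@nucleusMean) != n ||
      length(object@backgroundMean) != n)
    msg <- c(msg, "time, roiMean, nucleusMean, backgroundMean must have equal length")
  if (object@bleachIndex < 2L || object@bleachIndex > n)
    msg <- c(msg, "bleachIndex must leave at least one prebleach frame")
  if (length(msg)) msg else TRUE
})

#' NormalizedTrace: a double-normalized FRAP recovery trace
#'
#' Background-subtracted ROI signal divided per frame by the
#' background-subtracted whole-nucleus signal, then divided by the mean of
#' that ratio over the prebleach frames; the prebleach mean is 1 by
#' construction.
#'
#' @slot time numeric seconds.
#' @slot value numeric dimensionless normalized intensity.
#' @slot bleachIndex integer first postbleach frame.
#' @slot cellId character.
#'
#' @exportClass NormalizedTrace
setClass("NormalizedTrace",
  representation(
    time = "numeric",
    value = "numeric",
    bleachIndex = "integer",
    cellId = "character"
  )
)

setValidity("NormalizedTrace", function(object) {
  msg <- character()
  if (length(object@time) != length(object@value))
    msg <- c(msg, "time and value must have equal length")
  pre <- mean(object@value[seq_len(object@bleachIndex - 1L)])
  if (abs(pre - 1) > 1e-6)
    msg <- c(msg, "prebleach mean must equal 1 by construction")
  if (length(msg)) msg else TRUE
})

#' FrapEnsemble: averaged FRAP recovery across cells
#'
#' Pointwise mean and standard deviation of per-cell normalized traces on a
#' shared time grid, with a locally weighted (LOESS) regression through the
#' mean values.
#'
#' @slot traces list of \linkS4class{NormalizedTrace}.
#' @slot time numeric shared grid.
#' @slot meanCurve,sdCurve,smoothCurve numeric per-frame summaries.
#' @slot nCells integer.
#' @slot span numeric LOESS span used for \code{smoothCurve}.
#'
#' @exportClass FrapEnsemble
setClass("FrapEnsemble",
  representation(
    traces = "list",
    time = "numeric",
    meanCurve = "numeric",
    sdCurve = "numeric",
    smoothCurve = "numeric",
    nCells = "integer",
    bleachIndex = "integer",
    span = "numeric"
  )
)

#' KmerTable: k-mer counts from one sequenced selection pool
#'
#' Sliding-window counts of all length-k DNA words over the extracted
#' variable regions of one (sample, round) pool.
#'
#' @slot sample,round character labels.
#' @slot k integer word length.
#' @slot counts named numeric vector over all 4^k k-mers.
#' @slot totalPositions numeric, number of scored windows
#'   (sum of \code{length - k + 1} over accepted regions).
#'
#' @exportClass KmerTable
setClass("KmerTable",
  representation(
    sample = "character",
    round = "character",
    k = "integer",
    counts = "numeric",
    totalPositions = "numeric"
  )
)

setValidity("KmerTable", function(object) {
  msg <- character()
  if (length(object@counts) != 4^object@k)
    msg <- c(msg, "counts must cover all 4^k k-mers")
  if (abs(sum(object@counts) - object@totalPositions) > 1e-6 &&
      object@totalPositions > 0)
    msg <- c(msg, "sum of counts must equal totalPositions")
  if (length(msg)) msg else TRUE
})

#' EnrichmentTable: ranked k-mer enrichment, positive vs negative pool
#'
#' Per-k-mer frequencies in the selected (positive) and fusion-negative
#' pools and their pseudofrequency-stabilized ratio, sorted by descending
#' enrichment with lexicographic tie-break.
#'
#' @slot table data.frame with columns \code{kmer}, \code{freq_pos},
#'   \code{freq_neg}, \code{enrichment}, \code{rank}.
#' @slot k integer word length.
#' @slot pseudofrequency numeric, added to both frequencies before the ratio.
#'
#' @exportClass EnrichmentTable
setClass("EnrichmentTable",
  representation(
    table = "data.frame",
    k = "integer",
    pseudofrequency = "numeric"
  )
)

setValidity("EnrichmentTable", function(object) {
  msg <- character()
  tab <- object@table
  need <- c("kmer", "freq_pos", "freq_neg", "enrichment", "rank")
  if (!all(need %in% names(tab)))
    msg <- c(msg, "table is missing required columns")
  else {
    if (is.unsorted(rev(tab$enrichment)))
      msg <- c(msg, "table must be sorted by descending enrichment")
    if (!identical(sort(tab$rank), seq_len(nrow(tab))))
      msg <- c(msg, "ranks must be a permutation of 1..nrow")
  }
  if (length(msg)) msg else TRUE
})
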