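#' @rdname ImageStack-class
#' @param object,x an object
#' @export
setGeneric("imageData", function(x) standardGeneric("imageData"))

#' @rdname ImageStack-class
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname ImageStack-class
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))

#' @rdname ImageStack-class
#' @param label channel label to extract
#' @export
setGeneric("getChannel", function(x, label) standardGeneric("getChannel"))

#' @rdname LabelMask-class
#' @export
setGeneric("maskData", function(x) standardGeneric("maskData"))

#' @rdname PunctaSet-class
#' @export
setGeneric("puncta", function(x) standardGeneric("puncta"))

#' @rdname PunctaSet-class
#' @export
setGeneric("nucleusVolume", function(x) standardGeneric("nucleusVolume"))

#' @rdname PunctaSet-class
#' @export
setGeneric("cellId", function(x) standardGeneric("cellId"))

#' @rdname BoxProfile-class
#' @export
setGeneric("profileMatrix", function(x) standardGeneric("profileMatrix"))

#' @rdname BoxProfile-class
#' @export
setGeneric("nLoci", function(x) standardGeneric("nLoci"))

#' @rdname BoxProfile-class
#' @export
setGeneric("profileMode", function(x) standardGeneric("profileMode"))

#' @rdname KmerTable-class
#' @export
setGeneric("kmerCounts", function(x) standardGeneric("kmerCounts"))

#' @rdname EnrichmentTable-class
#' @export
setGeneric("enrichment", function(x) standardGeneric("enrichment"))

# ---- accessors ----

#' @rdname ImageStack-class
#' @export
setMethod("imageData", "ImageStack", function(x) x@data)

#' @rdname ImageStack-class
#' @export
setMethod("voxelSize", "ImageStack", function(x) x@voxelSize)

#' @rdname LabelMask-class
#' @export
setMethod("voxelSize", "LabelMask", function(x) x@voxelSize)

#' @rdname ImageStack-class
#' @export
setMethod("channelLabels", "ImageStack", function(x) x@channelLabels)

#' @rdname ImageStack-class
#' @export
setMethod("getChannel", "ImageStack", function(x, label) {
  if (x@layout == "czyx") {
    i <- match(label, x@channelLabels)
    if (is.na(i))
      stop("no channel labelled '", label, "'; available: ",
           paste(x@channelLabels, collapse = ", "))
    arr <- x@data[i, , , , drop = TRUE]
    dim(arr) <- dim(x@data)[-1L]
    arr
  } else {
    if (!identical(label, x@channelLabels))
      stop("no channel labelled '", label, "'")
    x@data
  }
})

#' @rdname LabelMask-class
#' @export
setMethod("maskData", "LabelMask", function(x) x@labels)

#' @rdname PunctaSet-class
#' @export
setMethod("puncta", "PunctaSet", function(x) x@puncta)

#' @rdname PunctaSet-class
#' @export
setMethod("nucleusVolume", "PunctaSet", function(x) x@nucleusVolume)

#' @rdname PunctaSet-class
#' @export
setMethod("cellId", "PunctaSet", function(x) x@cellId)

#' @rdname BoxProfile-class
#' @export
setMethod("profileMatrix", "BoxProfile", function(x) x@matrix)

#' @rdname BoxProfile-class
#' @export
setMethod("nLoci", "BoxProfile", function(x) x@nLoci)

#' @rdname BoxProfile-class
#' @export
setMethod("profileMode", "BoxProfile", function(x) x@mode)

#' @rdname KmerTable-class
#' @export
setMethod("kmerCounts", "KmerTable", function(x) x@counts)

#' @rdname EnrichmentTable-class
#' @export
setMethod("enrichment", "EnrichmentTable", function(x) x@table)

# ---- show methods ----

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@data)
  cat(sprintf("ImageStack [%s]: %s; voxel size (z,y,x) = %s um\n",
              object@layout, paste(d, collapse = " x "),
              paste(signif(object@voxelSize, 3), collapse = " x ")))
  cat("  channels:", paste(object@channelLabels, collapse = ", "), "\n")
})

setMethod("show", "LabelMask", function(object) {
  lab <- object@labels
  cat(sprintf("LabelMask: %s; %d object(s)\n",
              paste(dim(lab), collapse = " x "),
              length(setdiff(unique(as.vector(lab)), 0L))))
})

setMethod("show", "PunctaSet", function(object) {
  cat(sprintf(
    "PunctaSet '%s' (condition %s): %d puncta; nucleus %.1f um^3\n",
    object@cellId, object@condition, nrow(object@puncta),
    object@nucleusVolume))
})

setMethod("show", "BoxProfile", function(object) {
  cat(sprintf("BoxProfile [%s, channel %s]: %dx%d, %d loci (%d skipped)\n",
              object@mode, object@channel, nrow(object@matrix),
              ncol(object@matrix), object@nLoci, object@nSkipped))
})

setMethod("show", "FrapTrace", function(object) {
  cat(sprintf("FrapTrace '%s': %d frames, bleach at frame %d\n",
              object@cellId, length(object@time), object@bleachIndex))
})

setMethod("show", "FrapEnsemble", function(object) {
  cat(sprintf("FrapEnsemble: %d cells, %d frames, LOESS span %.2f\n",
              object@nCells, length(object@time), object@span))
})

setMethod("show", "KmerTable", function(object) {
  top <- head(sort(object@counts, decreasing = TRUE), 3L)
  cat(sprintf("KmerTable %s/%s k=%d: %.0f windows; top: %s\n",
              object@sample, object@round, object@k, object@totalPositions,
              paste(names(top), top, sep = "=", collapse = ", ")))
})

setMethod("show", "EnrichmentTable", function(object) {
  cat(sprintf("EnrichmentTable k=%d (%d k-mers); top: %s (%.2f)\n",
              object@k, nrow(object@table), object@table$kmer[1L],
              object@table$enrichment[1L]))
})
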