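#' Segment nuclei from the DAPI channel
#'
#' Gaussian smoothing, Otsu thresholding, 3D hole filling and
#' 26-connectivity connected components, followed by a minimum-volume
#' filter. Labels are numbered by descending component volume; equal
#' volumes keep ascending first-voxel raster order.
#'
#' @param dapi numeric 3D array (z, y, x), the DAPI channel.
#' @param minVolumeVox integer, components smaller than this many voxels
#'   are removed.
#' @param smoothingSigma Gaussian sigma in voxels, scalar or length-3
#'   (z, y, x).
#' @param voxelSize numeric length-3 (z, y, x) micrometres, stored on the
#'   returned mask.
#' @return a \linkS4class{LabelMask}; an all-background result gives an
#'   empty mask with a warning rather than an error.
#' @export
segmentNuclei <- function(dapi, minVolumeVox = 2000L,
                          smoothingSigma = c(1, 2, 2),
                          voxelSize = c(0.2, 0.11, 0.11)) {
  stopifnot(length(dim(dapi)) == 3L)
  if (length(smoothingSigma) == 1L) smoothingSigma <- rep(smoothingSigma, 3L)
  sm <- gaussian_blur3d(dapi, smoothingSigma)
  thr <- otsu_threshold(sm)
  fg <- sm > thr
  fg <- array(.fillholes3d_cpp(as.logical(fg), as.integer(dim(fg))),
              dim = dim(fg))
  labels <- label_components(fg)
  labels <- filter_small(labels, minVolumeVox)
  if (max(labels) == 0L)
    warning("nucleus segmentation found no objects")
  new("LabelMask", labels = labels, voxelSize = voxelSize)
}

#' Detect puncta inside nuclei by per-nucleus quantile thresholding
#'
#' Within each nucleus, voxels whose reporter intensity exceeds that
#' nucleus's \code{thresholdQuantile} intensity quantile form candidate
#' spots; candidates are joined by 26-connectivity connected components
#' and components smaller than \code{minSpotVox} voxels are removed.
#' Voxels outside every nucleus are never labeled. Because the threshold
#' is a per-nucleus rank statistic, the label set is invariant under any
#' monotone intensity transform, including constant offsets.
#'
#' This detector is the built-in reference path standing where an
#' interactively trained pixel classifier would sit in a microscope-room
#' workflow; externally produced masks enter via
#' \code{\link{importPunctaMask}}.
#'
#' @param reporter numeric 3D array (z, y, x), typically first rescaled
#'   with \code{\link{rescale16bit}}.
#' @param nucleusMask a \linkS4class{LabelMask} from
#'   \code{\link{segmentNuclei}}.
#' @param thresholdQuantile per-nucleus intensity quantile (default 0.995).
#' @param minSpotVox minimum component size in voxels (default 5).
#' @return a \linkS4class{LabelMask} of puncta.
#' @export
segmentPuncta <- function(reporter, nucleusMask, thresholdQuantile = 0.995,
                          minSpotVox = 5L) {
  stopifnot(is(nucleusMask, "LabelMask"))
  nm <- nucleusMask@labels
  if (!identical(dim(reporter), dim(nm)))
    stop("nucleus mask shape ", paste(dim(nm), collapse = "x"),
         " does not match reporter shape ",
         paste(dim(reporter), collapse = "x"))
  cand <- array(FALSE, dim = dim(reporter))
  for (id in setdiff(sort(unique(as.vector(nm))), 0L)) {
    in_nuc <- nm == id
    vals <- reporter[in_nuc]
    thr <- stats::quantile(vals, thresholdQuantile, names = FALSE)
    cand[in_nuc & reporter > thr] <- TRUE
  }
  labels <- label_components(cand)
  labels <- filter_small(labels, minSpotVox)
  new("LabelMask", labels = labels, voxelSize = nucleusMask@voxelSize)
}

#' Import an externally generated puncta mask
#'
#' Accepts a label volume or a probability volume (e.g. exported by a
#' pixel-classification tool), as a TIFF path or an in-memory array.
#' Probability volumes are thresholded at \code{probabilityCutoff} and
#' relabeled by 26-connectivity connected components; label volumes keep
#' their object identity and only pass through the size filter. Both are
#' cropped to the nuclei as in the built-in detector.
#'
#' @param x file path (TIFF written by \code{\link{writeMask}} /
#'   \code{\link{writeStack}}) or a 3D array.
#' @param nucleusMask a \linkS4class{LabelMask}.
#' @param probabilityCutoff threshold for probability volumes.
#' @param minSpotVox minimum component size in voxels.
#' @param type \code{"labels"}, \code{"probability"}, or \code{"auto"}
#'   (probability iff all finite values lie in [0, 1] and any is
#'   fractional).
#' @return a \linkS4class{LabelMask}.
#' @export
importPunctaMask <- function(x, nucleusMask, probabilityCutoff = 0.5,
                             minSpotVox = 5L,
                             type = c("auto", "labels", "probability")) {
  type <- match.arg(type)
  stopifnot(is(nucleusMask, "LabelMask"))
  arr <- if (is.character(x)) {
    stk <- readStack(x, layout = "zyx")
    a <- stk@data
    # probability volumes stored on the 16-bit scale map back to [0, 1]
    if (type == "probability" && max(a) > 1) a <- a / 65535
    a
  } else x
  nm <- nucleusMask@labels
  if (!identical(dim(arr), dim(nm)))
    stop("mask shape ", paste(dim(arr), collapse = "x"),
         " does not match nucleus mask shape ",
         paste(dim(nm), collapse = "x"))
  if (type == "auto") {
    type <- if (max(arr) <= 1 && min(arr) >= 0 && any(arr != floor(arr)))
      "probability" else "labels"
  }
  if (type == "probability") {
    if (min(arr) < 0 || max(arr) > 1)
      stop("declared probability volume has values outside [0, 1]")
    cand <- arr > probabilityCutoff & nm > 0L
    labels <- label_components(cand)
  } else {
    labels <- arr
    storage.mode(labels) <- "integer"
    labels[nm == 0L] <- 0L
    # compact renumbering, preserving ascending original label order
    ids <- setdiff(sort(unique(as.vector(labels))), 0L)
    re <- integer(max(c(0L, ids)))
    re[ids] <- seq_along(ids)
    labels[labels > 0L] <- re[labels[labels > 0L]]
  }
  labels <- filter_small(labels, minSpotVox)
  new("LabelMask", labels = labels, voxelSize = nucleusMask@voxelSize)
}

#' Extract per-punctum geometry and per-cell summaries
#'
#' Builds one \linkS4class{PunctaSet} per nucleus. Punctum centroids are
#' intensity-weighted centers of mass by default (binary-mask centroids by
#' flag); bounding boxes are tight and half-open; \code{z_extent = z1 - z0}
#' is the axial size used by the colocalization z-averaging. A punctum
#' whose voxels touch more than one nucleus is assigned to the nucleus
#' holding its (rounded) centroid and flagged \code{straddles}.
#'
#' @param punctaMask a \linkS4class{LabelMask} of puncta.
#' @param nucleusMask a \linkS4class{LabelMask} of nuclei.
#' @param reporter numeric 3D array, intensities for centroid weighting
#'   and per-punctum statistics.
#' @param stack optional \linkS4class{ImageStack} (layout \code{"czyx"});
#'   when given, per-nucleus mean intensities are recorded for every
#'   channel, otherwise for the reporter only.
#' @param condition condition tag stored on each set.
#' @param weightedCentroid logical; FALSE gives binary-mask centroids.
#' @return a list of \linkS4class{PunctaSet}, one per nucleus label.
#' @export
extractPuncta <- function(punctaMask, nucleusMask, reporter, stack = NULL,
                          condition = "unknown", weightedCentroid = TRUE) {
  stopifnot(is(punctaMask, "LabelMask"), is(nucleusMask, "LabelMask"))
  pm <- punctaMask@labels
  nm <- nucleusMask@labels
  if (!identical(dim(pm), dim(nm)) || !identical(dim(pm), dim(reporter)))
    stop("puncta mask, nucleus mask and reporter must share one shape")
  vs <- nucleusMask@voxelSize
  vox_vol <- prod(vs)
  empty_puncta <- data.frame(
    punctum_id = integer(), z = numeric(), y = numeric(), x = numeric(),
    z0 = integer(), z1 = integer(), y0 = integer(), y1 = integer(),
    x0 = integer(), x1 = integer(), z_extent = integer(),
    volume_um3 = numeric(), mean_intensity = numeric(),
    max_intensity = numeric(), straddles = logical())
  nuc_ids <- setdiff(sort(unique(as.vector(nm))), 0L)
  rows_by_nuc <- stats::setNames(
    replicate(length(nuc_ids), list(), simplify = FALSE), nuc_ids)
  n_puncta <- max(pm)
  if (n_puncta > 0L) {
    flat <- which(pm > 0L)
    coords <- arrayInd(flat, dim(pm))
    lab <- pm[flat]
    for (pid in seq_len(n_puncta)) {
      sel <- lab == pid
      if (!any(sel)) next
      cz <- coords[sel, 1L]; cy <- coords[sel, 2L]; cx <- coords[sel, 3L]
      ints <- reporter[flat[sel]]
      w <- if (weightedCentroid && sum(ints) > 0) ints else rep(1, length(ints))
      cen <- c(sum(w * cz), sum(w * cy), sum(w * cx)) / sum(w)
      nuc_at <- nm[flat[sel]]
      touched <- setdiff(unique(nuc_at), 0L)
      straddles <- length(touched) > 1L
      rc <- pmin(pmax(round(cen), 1L), dim(nm))
      assigned <- nm[rc[1L], rc[2L], rc[3L]]
      if (assigned == 0L)
        assigned <- if (length(touched)) touched[which.max(
          tabulate(match(nuc_at, touched)))] else 0L
      if (assigned == 0L) next  # punctum outside every nucleus
      row <- data.frame(
        punctum_id = pid, z = cen[1L], y = cen[2L], x = cen[3L],
        z0 = min(cz), z1 = max(cz) + 1L, y0 = min(cy), y1 = max(cy) + 1L,
        x0 = min(cx), x1 = max(cx) + 1L, z_extent = max(cz) - min(cz) + 1L,
        volume_um3 = length(ints) * vox_vol,
        mean_intensity = mean(ints), max_intensity = max(ints),
        straddles = straddles)
      key <- as.character(assigned)
      rows_by_nuc[[key]][[length(rows_by_nuc[[key]]) + 1L]] <- row
    }
  }
  out <- vector("list", length(nuc_ids))
  for (i in seq_along(nuc_ids)) {
    id <- nuc_ids[i]
    in_nuc <- which(nm == id)
    mean_int <- if (is(stack, "ImageStack") && stack@layout == "czyx") {
      vapply(stack@channelLabels, function(lb) {
        mean(getChannel(stack, lb)[in_nuc])
      }, numeric(1))
    } else c(reporter = mean(reporter[in_nuc]))
    plist <- rows_by_nuc[[as.character(id)]]
    pdf <- if (length(plist)) do.call(rbind, plist) else empty_puncta
    rownames(pdf) <- NULL
    out[[i]] <- new("PunctaSet",
                    cellId = sprintf("cell%03d", id), nucleusId = as.integer(id),
                    condition = condition,
                    nucleusVolume = length(in_nuc) * vox_vol,
                    nucleusVoxels = length(in_nuc),
                    meanIntensity = mean_int, voxelSize = vs, puncta = pdf)
  }
  out
}
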