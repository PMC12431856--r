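# Locus-centered box-profile machinery: condensate-centered profiles, the
# matched in-nucleus random-locus null, and the FISH-centered variant all
# go through gather_locus_matrix(), so the null is computed by exactly the
# same code path as the signal.

# Gather the boxSize^2 patch around (yc, xc) for z-slices z0..z1-1,
# min-max normalize the whole gathered block to [0, 1] (per locus, per
# channel; constant block -> zeros), and average over z.
# Returns NULL when the lateral footprint leaves the image.
gather_locus_matrix <- function(channel, yc, xc, z0, z1, box_size) {
  d <- dim(channel)
  h <- box_size %/% 2L
  if (yc - h < 1L || yc + h > d[2L] || xc - h < 1L || xc + h > d[3L])
    return(NULL)
  zs <- max(1L, z0):min(d[1L], z1 - 1L)
  block <- channel[zs, (yc - h):(yc + h), (xc - h):(xc + h), drop = FALSE]
  block <- minmax01(block)
  m <- apply(block, c(2L, 3L), mean)
  dim(m) <- c(box_size, box_size)
  m
}

#' Extract the normalized box profile of a single punctum
#'
#' Takes the \code{boxSize} x \code{boxSize} patch centered laterally on
#' the punctum centroid (rounded to the nearest voxel) for every z-slice
#' of the punctum's bounding box, normalizes the gathered values to
#' [0, 1] (per locus; a constant patch maps to all zeros), and averages
#' across the z-slices.
#'
#' @param channel numeric 3D array (z, y, x): the channel whose
#'   intensities are gathered (staining target, partner, or reporter).
#' @param punctum a one-row data frame (or list) with fields \code{y},
#'   \code{x}, \code{z0}, \code{z1}, \code{z_extent} as produced by
#'   \code{\link{extractPuncta}}.
#' @param boxSize odd box side in pixels (default 61).
#' @return a \code{boxSize} x \code{boxSize} matrix, or \code{NULL} when
#'   the centroid lies within \code{boxSize \%/\% 2} pixels of the lateral
#'   image border (the locus is skipped and should be counted by the
#'   caller).
#' @export
extractBoxProfile <- function(channel, punctum, boxSize = 61L) {
  stopifnot(length(dim(channel)) == 3L, boxSize %% 2L == 1L)
  if (punctum$z_extent < 1L || punctum$z1 <= punctum$z0)
    stop("punctum has zero z extent")
  gather_locus_matrix(channel, round(punctum$y), round(punctum$x),
                      punctum$z0, punctum$z1, as.integer(boxSize))
}

#' Average per-locus box matrices into a BoxProfile
#'
#' @param matrices list of equal-shape numeric matrices (per-locus
#'   normalized profiles).
#' @param mode profile mode: \code{"condensate-centered"},
#'   \code{"random-null"} or \code{"fish-centered"}.
#' @param channel channel label recorded on the profile.
#' @param nSkipped count of loci skipped at the lateral border.
#' @return a \linkS4class{BoxProfile} holding the element-wise mean.
#' @export
averageProfiles <- function(matrices, mode = "condensate-centered",
                            channel = "target", nSkipped = 0L) {
  matrices <- Filter(Negate(is.null), matrices)
  if (!length(matrices)) stop("no contributing loci")
  d1 <- dim(matrices[[1L]])
  if (!all(vapply(matrices, function(m) identical(dim(m), d1), logical(1))))
    stop("profile matrices have mismatched shapes")
  acc <- Reduce(`+`, matrices) / length(matrices)
  new("BoxProfile", matrix = acc, nLoci = length(matrices),
      nSkipped = as.integer(nSkipped), channel = channel, mode = mode)
}

#' Condensate-centered box profile of a set of cells
#'
#' Convenience wrapper: extracts per-punctum profiles for every punctum of
#' every cell and averages them.
#'
#' @param punctaSets list of \linkS4class{PunctaSet} (or a single one).
#' @param channel numeric 3D array to gather intensities from.
#' @param boxSize odd box side (default 61).
#' @param channelLabel label recorded on the profile.
#' @param mode recorded mode (default condensate-centered; used with
#'   \code{"fish-centered"} by \code{\link{fishLocusProfiles}}).
#' @return a \linkS4class{BoxProfile}.
#' @export
profilePuncta <- function(punctaSets, channel, boxSize = 61L,
                          channelLabel = "target",
                          mode = "condensate-centered") {
  if (is(punctaSets, "PunctaSet")) punctaSets <- list(punctaSets)
  mats <- list()
  skipped <- 0L
  for (ps in punctaSets) {
    p <- ps@puncta
    for (i in seq_len(nrow(p))) {
      m <- extractBoxProfile(channel, p[i, ], boxSize)
      if (is.null(m)) skipped <- skipped + 1L
      else mats[[length(mats) + 1L]] <- m
    }
  }
  averageProfiles(mats, mode = mode, channel = channelLabel,
                  nSkipped = skipped)
}

#' Sample matched in-nucleus random loci for one cell
#'
#' Draws exactly as many unique random locations as the cell has puncta.
#' Each locus gets an integer z-window length drawn uniformly between the
#' smallest and largest punctum z-extent of that cell, centered on the
#' nucleus-mask mid-plane of the sampled (y, x) column (shifted to stay
#' inside the stack), and is accepted only when the whole
#' \code{boxSize}^2 footprint lies inside the 2D projection of the
#' nucleus mask over that z-window. Sampling is rejection-based with a
#' deterministic generator seeded per cell from \code{seed} and the cell
#' id, so adding cells never perturbs another cell's draws.
#'
#' @param nucleusMask a \linkS4class{LabelMask}.
#' @param punctaSet the cell's \linkS4class{PunctaSet} (>= 1 punctum).
#' @param boxSize odd box side (default 61).
#' @param seed integer master seed.
#' @param maxRejections bound on rejected draws before reporting the
#'   nucleus too small for the box.
#' @return data frame: \code{cell_id}, \code{y}, \code{x}, \code{z0},
#'   \code{z1} (half-open z-window), \code{z_len}.
#' @export
sampleRandomLoci <- function(nucleusMask, punctaSet, boxSize = 61L,
                             seed = 1L, maxRejections = 10000L) {
  stopifnot(is(nucleusMask, "LabelMask"), is(punctaSet, "PunctaSet"),
            boxSize %% 2L == 1L)
  p <- punctaSet@puncta
  if (!nrow(p)) stop("cell ", punctaSet@cellId, " has no puncta")
  nm <- nucleusMask@labels == punctaSet@nucleusId
  d <- dim(nm)
  h <- boxSize %/% 2L
  proj_all <- apply(nm, c(2L, 3L), any)
  ys <- range(which(rowSums(proj_all) > 0))
  xs <- range(which(colSums(proj_all) > 0))
  if (diff(ys) + 1L < boxSize || diff(xs) + 1L < boxSize)
    stop("nucleus ", punctaSet@cellId, " 2D extent (",
         diff(ys) + 1L, "x", diff(xs) + 1L,
         ") is smaller than the ", boxSize, "x", boxSize, " box")
  cand <- which(proj_all, arr.ind = TRUE)
  cand <- cand[cand[, 1L] >= h + 1L & cand[, 1L] <= d[2L] - h &
                 cand[, 2L] >= h + 1L & cand[, 2L] <= d[3L] - h, ,
               drop = FALSE]
  if (!nrow(cand))
    stop("cell ", punctaSet@cellId,
         ": no in-nucleus center admits a ", boxSize, "-pixel box")
  ext <- range(p$z_extent)
  n_want <- nrow(p)
  out <- matrix(0L, nrow = 0L, ncol = 4L)
  rejections <- 0L
  with_seed(derive_seed(seed, punctaSet@cellId), {
    while (nrow(out) < n_want) {
      if (rejections >= maxRejections)
        stop("cell ", punctaSet@cellId, ": no valid random locus after ",
             maxRejections, " rejections (nucleus too small for the box)")
      yx <- cand[sample.int(nrow(cand), 1L), ]
      yc <- yx[[1L]]; xc <- yx[[2L]]
      if (nrow(out) && any(out[, 1L] == yc & out[, 2L] == xc)) {
        rejections <- rejections + 1L
        next
      }
      L <- if (ext[1L] == ext[2L]) ext[1L] else
        sample(seq(ext[1L], ext[2L]), 1L)
      zcol <- which(nm[, yc, xc])
      zmid <- if (length(zcol)) round((min(zcol) + max(zcol)) / 2) else
        round(d[1L] / 2)
      z0 <- zmid - (L - 1L) %/% 2L
      z0 <- min(max(z0, 1L), d[1L] - L + 1L)
      z1 <- z0 + L
      # footprint-only 2D projection of the mask over the z-window
      sub <- nm[z0:(z1 - 1L), (yc - h):(yc + h), (xc - h):(xc + h),
                drop = FALSE]
      ok <- !any(colSums(array(sub, dim = c(L, boxSize * boxSize))) == 0L)
      if (ok) out <- rbind(out, c(yc, xc, z0, z1))
      else rejections <- rejections + 1L
    }
  })
  data.frame(cell_id = punctaSet@cellId, y = out[, 1L], x = out[, 2L],
             z0 = out[, 3L], z1 = out[, 4L], z_len = out[, 4L] - out[, 3L],
             stringsAsFactors = FALSE)
}

#' Random-locus null box profile for a set of cells
#'
#' Samples matched random loci per cell (\code{\link{sampleRandomLoci}})
#' and gathers, normalizes and averages their boxes through the same code
#' path as the condensate-centered profile.
#'
#' @param channel numeric 3D array to gather intensities from.
#' @param nucleusMask a \linkS4class{LabelMask}.
#' @param punctaSets list of \linkS4class{PunctaSet} (cells without
#'   puncta contribute nothing).
#' @param boxSize odd box side (default 61).
#' @param seed integer master seed (per-cell seeds derived from it).
#' @param channelLabel label recorded on the profile.
#' @return a \linkS4class{BoxProfile} with \code{mode = "random-null"}.
#' @export
profileRandomNull <- function(channel, nucleusMask, punctaSets,
                              boxSize = 61L, seed = 1L,
                              channelLabel = "target") {
  if (is(punctaSets, "PunctaSet")) punctaSets <- list(punctaSets)
  mats <- list()
  skipped <- 0L
  for (ps in punctaSets) {
    if (!nrow(ps@puncta)) next
    loci <- sampleRandomLoci(nucleusMask, ps, boxSize, seed)
    for (i in seq_len(nrow(loci))) {
      m <- gather_locus_matrix(channel, loci$y[i], loci$x[i],
                               loci$z0[i], loci$z1[i], as.integer(boxSize))
      if (is.null(m)) skipped <- skipped + 1L
      else mats[[length(mats) + 1L]] <- m
    }
  }
  averageProfiles(mats, mode = "random-null", channel = channelLabel,
                  nSkipped = skipped)
}

#' RNA-FISH locus-centered reporter profiles with matched null
#'
#' The same machinery with the roles swapped: boxes are centered on FISH
#' loci (detected by the segmentation module on the FISH channel) and
#' intensities are gathered from the reporter channel; the matched
#' random-locus null is sampled exactly as for condensates.
#'
#' @param fishPunctaSets list of \linkS4class{PunctaSet} of FISH loci.
#' @param reporter numeric 3D array, the reporter channel.
#' @param nucleusMask a \linkS4class{LabelMask}.
#' @param boxSize odd box side (default 61).
#' @param seed integer master seed for the null.
#' @return list with \code{profile} (mode \code{"fish-centered"}) and
#'   \code{null} (mode \code{"random-null"}), both
#'   \linkS4class{BoxProfile}s.
#' @export
fishLocusProfiles <- function(fishPunctaSets, reporter, nucleusMask,
                              boxSize = 61L, seed = 1L) {
  if (is(fishPunctaSets, "PunctaSet")) fishPunctaSets <- list(fishPunctaSets)
  with_puncta <- Filter(function(ps) nrow(ps@puncta) > 0L, fishPunctaSets)
  if (!length(with_puncta)) stop("no FISH loci in any cell")
  list(profile = profilePuncta(with_puncta, reporter, boxSize,
                               channelLabel = "reporter",
                               mode = "fish-centered"),
       null = profileRandomNull(reporter, nucleusMask, with_puncta,
                                boxSize, seed, channelLabel = "reporter"))
}

#' Center-vs-edge enrichment summary of a box profile
#'
#' Scalar summary of a profile heatmap: the mean over the centered
#' \code{centralSize} x \code{centralSize} patch, the mean over the
#' 1-pixel outermost ring, and their ratio. A zero edge mean yields an
#' infinite ratio with \code{infinite = TRUE}.
#'
#' @param profile a \linkS4class{BoxProfile} or plain square matrix.
#' @param centralSize odd central patch side, smaller than the box.
#' @return list: \code{central_mean}, \code{edge_mean}, \code{ratio},
#'   \code{infinite}.
#' @export
enrichmentSummary <- function(profile, centralSize = 11L) {
  m <- if (is(profile, "BoxProfile")) profile@matrix else profile
  n <- nrow(m)
  stopifnot(centralSize %% 2L == 1L, centralSize < n)
  c0 <- (n + 1L) %/% 2L
  hc <- centralSize %/% 2L
  central <- mean(m[(c0 - hc):(c0 + hc), (c0 - hc):(c0 + hc)])
  ring <- c(m[1L, ], m[n, ], m[2:(n - 1L), 1L], m[2:(n - 1L), n])
  edge <- mean(ring)
  if (edge == 0)
    list(central_mean = central, edge_mean = 0, ratio = Inf, infinite = TRUE)
  else
    list(central_mean = central, edge_mean = edge, ratio = central / edge,
         infinite = FALSE)
}
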