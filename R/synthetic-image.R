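#' Parameters for the synthetic condensate image generator
#'
#' Describes a multichannel 3D stack containing ellipsoidal nuclei (DAPI
#' channel) with diffraction-limited puncta in a reporter channel and a
#' partner ("staining target") channel whose spot mass is split between
#' reporter punctum centers and uniform random in-nucleus positions.
#'
#' Default voxel size is (0.2, 0.11, 0.11) micrometres (z, y, x), mirroring
#' spinning-disk acquisition with 110-nm pixels and 0.2-micrometre z spacing.
#'
#' @param stackShape integer (nz, ny, nx) voxels.
#' @param voxelSize numeric (dz, dy, dx) micrometres per voxel.
#' @param nuclei list of nuclei, each \code{list(center = c(z, y, x),
#'   semiAxes = c(az, ay, ax), dapiLevel = <intensity>)}; semi-axes in
#'   voxels, all >= 2.
#' @param nPunctaPerNucleus integer, Gaussian spots planted per nucleus in
#'   the reporter channel.
#' @param spotSigma numeric, Gaussian spot sigma in voxels; scalar
#'   (isotropic in pixels) or length 3 per axis. Spots are truncated at
#'   4 sigma.
#' @param spotAmplitude numeric peak intensity above background.
#' @param colocFraction fraction in [0, 1] of partner-channel spots placed
#'   exactly at reporter punctum centers; the remainder go to uniform
#'   random in-nucleus positions.
#' @param backgroundLevel additive background intensity.
#' @param noiseSd standard deviation of additive Gaussian noise (clipped to
#'   the unsigned 16-bit range).
#' @param punctaMargin fraction of each semi-axis within which punctum
#'   centers are sampled (keeps spots strictly interior to the nucleus).
#' @param minSeparation minimum pairwise center distance in voxels within
#'   a nucleus (rejection-sampled; keeps planted spots resolvable).
#' @param seed integer; fully determines the output.
#' @return a validated parameter list of class \code{SyntheticImageParams}.
#' @export
syntheticImageParams <- function(stackShape = c(24L, 220L, 220L),
                                 voxelSize = c(0.2, 0.11, 0.11),
                                 nuclei = list(list(
                                   center = c(12, 110, 110),
                                   semiAxes = c(9, 75, 75),
                                   dapiLevel = 8000)),
                                 nPunctaPerNucleus = 10L,
                                 spotSigma = 1.5,
                                 spotAmplitude = 12000,
                                 colocFraction = 0.5,
                                 backgroundLevel = 300,
                                 noiseSd = 50,
                                 punctaMargin = 0.9,
                                 minSeparation = 10,
                                 seed = 1L) {
  if (length(spotSigma) == 1L) spotSigma <- rep(spotSigma, 3L)
  p <- list(stackShape = as.integer(stackShape), voxelSize = voxelSize,
            nuclei = nuclei, nPunctaPerNucleus = as.integer(nPunctaPerNucleus),
            spotSigma = spotSigma, spotAmplitude = spotAmplitude,
            colocFraction = colocFraction, backgroundLevel = backgroundLevel,
            noiseSd = noiseSd, punctaMargin = punctaMargin,
            minSeparation = minSeparation, seed = as.integer(seed))
  stopifnot(length(p$stackShape) == 3L, all(p$stackShape >= 1L),
            length(p$voxelSize) == 3L, all(p$voxelSize > 0),
            p$colocFraction >= 0, p$colocFraction <= 1,
            p$nPunctaPerNucleus >= 0L, p$noiseSd >= 0,
            p$punctaMargin > 0, p$punctaMargin < 1)
  for (i in seq_along(p$nuclei)) {
    nuc <- p$nuclei[[i]]
    if (any(nuc$semiAxes < 2))
      stop("nucleus ", i, ": all semi-axes must be >= 2 voxels")
    lo <- nuc$center - nuc$semiAxes
    hi <- nuc$center + nuc$semiAxes
    if (any(lo < 1) || any(hi > p$stackShape))
      stop("nucleus ", i, ": ellipsoid extends outside the stack (center ",
           paste(nuc$center, collapse = ","), ", semi-axes ",
           paste(nuc$semiAxes, collapse = ","), ")")
  }
  class(p) <- "SyntheticImageParams"
  p
}

# voxel-center coordinates inside an ellipsoid, optionally shrunk
ellipsoid_voxels <- function(center, semi_axes, shape, shrink = 1) {
  ax <- semi_axes * shrink
  zr <- max(1L, floor(center[1] - ax[1])):min(shape[1], ceiling(center[1] + ax[1]))
  yr <- max(1L, floor(center[2] - ax[2])):min(shape[2], ceiling(center[2] + ax[2]))
  xr <- max(1L, floor(center[3] - ax[3])):min(shape[3], ceiling(center[3] + ax[3]))
  g <- expand.grid(z = zr, y = yr, x = xr)
  d2 <- ((g$z - center[1]) / ax[1])^2 + ((g$y - center[2]) / ax[2])^2 +
    ((g$x - center[3]) / ax[3])^2
  g[d2 < 1, , drop = FALSE]
}

# add a truncated Gaussian spot (peak `amp` at integer center) in place
add_spot <- function(arr, center, sigma, amp, trunc = 4) {
  d <- dim(arr)
  r <- ceiling(trunc * sigma)
  zr <- max(1L, center[1] - r[1]):min(d[1], center[1] + r[1])
  yr <- max(1L, center[2] - r[2]):min(d[2], center[2] + r[2])
  xr <- max(1L, center[3] - r[3]):min(d[3], center[3] + r[3])
  ez <- exp(-0.5 * ((zr - center[1]) / sigma[1])^2)
  ey <- exp(-0.5 * ((yr - center[2]) / sigma[2])^2)
  ex <- exp(-0.5 * ((xr - center[3]) / sigma[3])^2)
  spot <- amp * outer(ez, outer(ey, ex))
  arr[zr, yr, xr] <- arr[zr, yr, xr] + array(spot, dim = c(length(zr), length(yr), length(xr)))
  arr
}

sample_centers_in_nucleus <- function(nuc, shape, margin, n, min_sep) {
  vox <- ellipsoid_voxels(nuc$center, nuc$semiAxes, shape, shrink = margin)
  if (nrow(vox) < n) stop("nucleus too small for requested punctum count")
  picked <- matrix(numeric(0), ncol = 3)
  tries <- 0L
  while (nrow(picked) < n && tries < 5000L) {
    cand <- as.numeric(vox[sample.int(nrow(vox), 1L), ])
    ok <- TRUE
    if (nrow(picked) > 0 && min_sep > 0) {
      dd <- sqrt(colSums((t(picked) - cand)^2))
      ok <- all(dd >= min_sep)
    }
    if (ok) picked <- rbind(picked, cand)
    tries <- tries + 1L
  }
  if (nrow(picked) < n)
    stop("could not place ", n, " puncta at separation >= ", min_sep)
  colnames(picked) <- c("z", "y", "x")
  picked
}

#' Generate a synthetic multichannel condensate stack with ground truth
#'
#' Renders the DAPI, reporter and partner channels described by
#' \code{\link{syntheticImageParams}}. The reporter channel contains exactly
#' \code{nPunctaPerNucleus} truncated-Gaussian spots per nucleus;
#' \code{round(colocFraction * n)} of the partner channel's spots sit at
#' reporter centers and the rest at uniform random in-nucleus voxels.
#' Identical parameters (including seed) give bit-identical stacks.
#'
#' @param params a \code{SyntheticImageParams} list.
#' @return a list with elements \code{stack} (an \linkS4class{ImageStack},
#'   layout \code{"czyx"}, channels reporter/partner/dapi), and
#'   \code{truth}: \code{nucleusMask} (\linkS4class{LabelMask}, labels in
#'   nucleus list order), \code{centers} (data frame of planted reporter
#'   centers with half-open ground-truth z-extents \code{z0, z1} bounding
#'   voxels where the spot exceeds background + 3 noiseSd),
#'   \code{partnerCenters} (data frame with \code{at_punctum} flag) and
#'   \code{params}.
#' @export
simulateStack <- function(params) {
  stopifnot(inherits(params, "SyntheticImageParams"))
  p <- params
  shape <- p$stackShape
  with_seed(p$seed, {
    dapi <- array(0, dim = shape)
    reporter <- array(0, dim = shape)
    partner <- array(0, dim = shape)
    nuc_mask <- array(0L, dim = shape)
    centers_list <- list()
    partner_list <- list()
    for (i in seq_along(p$nuclei)) {
      nuc <- p$nuclei[[i]]
      vox <- ellipsoid_voxels(nuc$center, nuc$semiAxes, shape)
      idx <- cbind(vox$z, vox$y, vox$x)
      dapi[idx] <- dapi[idx] + nuc$dapiLevel
      nuc_mask[idx] <- i
      if (p$nPunctaPerNucleus > 0L) {
        ctr <- sample_centers_in_nucleus(nuc, shape, p$punctaMargin,
                                         p$nPunctaPerNucleus, p$minSeparation)
        ctr <- round(ctr)
        for (j in seq_len(nrow(ctr)))
          reporter <- add_spot(reporter, ctr[j, ], p$spotSigma, p$spotAmplitude)
        # ground-truth z extent: where the axial Gaussian exceeds 3*noiseSd
        if (p$noiseSd > 0 && p$spotAmplitude > 3 * p$noiseSd) {
          dz <- p$spotSigma[1] * sqrt(2 * log(p$spotAmplitude / (3 * p$noiseSd)))
        } else {
          dz <- 4 * p$spotSigma[1]
        }
        centers_list[[i]] <- data.frame(
          nucleus_id = i, z = ctr[, "z"], y = ctr[, "y"], x = ctr[, "x"],
          z0 = pmax(1, floor(ctr[, "z"] - dz)),
          z1 = pmin(shape[1] + 1, ceiling(ctr[, "z"] + dz) + 1))
        # partner spots: coloc at reporter centers, remainder random
        n_co <- round(p$colocFraction * p$nPunctaPerNucleus)
        co_idx <- if (n_co > 0) sample.int(nrow(ctr), n_co) else integer()
        pc <- ctr[co_idx, , drop = FALSE]
        n_rand <- p$nPunctaPerNucleus - n_co
        if (n_rand > 0) {
          rnd <- sample_centers_in_nucleus(nuc, shape, p$punctaMargin,
                                           n_rand, 0)
          rnd <- round(rnd)
          pc <- rbind(pc, rnd)
        }
        for (j in seq_len(nrow(pc)))
          partner <- add_spot(partner, pc[j, ], p$spotSigma, p$spotAmplitude)
        partner_list[[i]] <- data.frame(
          nucleus_id = i, z = pc[, "z"], y = pc[, "y"], x = pc[, "x"],
          at_punctum = rep(c(TRUE, FALSE), c(n_co, n_rand)))
      }
    }
    noise <- function(a) {
      a <- a + p$backgroundLevel
      if (p$noiseSd > 0)
        a <- a + array(stats::rnorm(length(a), 0, p$noiseSd), dim = shape)
      pmin(pmax(a, 0), 65535)
    }
    dat <- array(0, dim = c(3L, shape))
    dat[1L, , , ] <- noise(reporter)
    dat[2L, , , ] <- noise(partner)
    dat[3L, , , ] <- noise(dapi)
    stack <- new("ImageStack", data = dat, layout = "czyx",
                 voxelSize = p$voxelSize,
                 channelLabels = c("reporter", "partner", "dapi"),
                 bitDepth = 16L)
    centers <- if (length(centers_list)) do.call(rbind, centers_list) else
      data.frame(nucleus_id = integer(), z = numeric(), y = numeric(),
                 x = numeric(), z0 = numeric(), z1 = numeric())
    partner_centers <- if (length(partner_list)) do.call(rbind, partner_list) else
      data.frame(nucleus_id = integer(), z = numeric(), y = numeric(),
                 x = numeric(), at_punctum = logical())
    list(stack = stack,
         truth = list(
           nucleusMask = new("LabelMask", labels = nuc_mask,
                             voxelSize = p$voxelSize),
           centers = centers,
           partnerCenters = partner_centers,
           params = p))
  })
}
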