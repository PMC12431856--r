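# Shared fixtures and independent oracles used across test files.

# Small, fast synthetic-image parameters for tests that do not exercise the
# random-locus null (whose geometry needs the full-size default nucleus).
small_image_params <- function(seed = 1L, nPunctaPerNucleus = 6L, ...) {
  syntheticImageParams(
    stackShape = c(20L, 96L, 96L),
    nuclei = list(list(center = c(10, 48, 48), semiAxes = c(7, 32, 32),
                       dapiLevel = 8000)),
    nPunctaPerNucleus = nPunctaPerNucleus, minSeparation = 10,
    seed = seed, ...)
}

# Build a PunctaSet directly from a table of punctum centroids; geometry
# fields derived as 1-voxel objects unless sizes are given.
make_puncta_set <- function(centers, cell_id = "cellA", nucleus_id = 1L,
                            nucleus_volume = 500, condition = "test",
                            z_extent = NULL, mean_reporter = 1000,
                            voxel_size = c(0.2, 0.11, 0.11)) {
  n <- nrow(centers)
  ze <- if (is.null(z_extent)) rep(1L, n) else as.integer(z_extent)
  pdf <- data.frame(
    punctum_id = seq_len(n),
    z = centers$z, y = centers$y, x = centers$x,
    z0 = as.integer(centers$z - (ze - 1) %/% 2),
    z1 = as.integer(centers$z - (ze - 1) %/% 2 + ze),
    y0 = as.integer(centers$y), y1 = as.integer(centers$y + 1L),
    x0 = as.integer(centers$x), x1 = as.integer(centers$x + 1L),
    z_extent = ze,
    volume_um3 = ze * prod(voxel_size),
    mean_intensity = rep(1, n), max_intensity = rep(1, n),
    straddles = rep(FALSE, n))
  new("PunctaSet", cellId = cell_id, nucleusId = as.integer(nucleus_id),
      condition = condition, nucleusVolume = nucleus_volume,
      nucleusVoxels = as.integer(round(nucleus_volume / prod(voxel_size))),
      meanIntensity = c(reporter = mean_reporter), voxelSize = voxel_size,
      puncta = pdf)
}

# Independent triple-loop reference for the box-profile extraction:
# gather, min-max normalize the gathered block, average over z.
naive_box_profile <- function(channel, yc, xc, z0, z1, box_size = 61L) {
  d <- dim(channel)
  h <- box_size %/% 2L
  if (yc - h < 1L || yc + h > d[2L] || xc - h < 1L || xc + h > d[3L])
    return(NULL)
  zs <- max(1L, z0):min(d[1L], z1 - 1L)
  block <- array(0, dim = c(length(zs), box_size, box_size))
  for (zi in seq_along(zs))
    for (iy in seq_len(box_size))
      for (ix in seq_len(box_size))
        block[zi, iy, ix] <- channel[zs[zi], yc - h - 1L + iy, xc - h - 1L + ix]
  lo <- min(block); hi <- max(block)
  block <- if (hi == lo) block * 0 else (block - lo) / (hi - lo)
  out <- matrix(0, box_size, box_size)
  for (iy in seq_len(box_size))
    for (ix in seq_len(box_size))
      out[iy, ix] <- mean(block[, iy, ix])
  out
}

# Dictionary-based k-mer counting oracle (substring loop).
naive_kmer_counts <- function(regions, k) {
  counts <- new.env(parent = emptyenv())
  for (r in regions) {
    for (i in seq_len(nchar(r) - k + 1L)) {
      w <- substr(r, i, i + k - 1L)
      counts[[w]] <- (if (is.null(counts[[w]])) 0 else counts[[w]]) + 1
    }
  }
  out <- unlist(as.list(counts))
  out[order(names(out))]
}

# Brute-force QC-filter oracle: volume rule then per-condition bottom
# floor(n/3) of mean intensity among the survivors.
naive_qc_oracle <- function(records, cutoff = 200, frac = 1 / 3) {
  small <- records$nucleus_volume < cutoff
  low <- rep(FALSE, nrow(records))
  for (cond in unique(records$condition)) {
    i <- which(records$condition == cond & !small)
    n_excl <- floor(length(i) * frac)
    if (n_excl >= 1) {
      ord <- i[order(records$mean_reporter_intensity[i])]
      low[ord[seq_len(n_excl)]] <- TRUE
    }
  }
  list(small = small, low = low, flagged = small | low)
}

# One segmented synthetic stack bundle used by several tests.
segmented_stack <- function(params) {
  sim <- simulateStack(params)
  st <- sim$stack
  nuc <- segmentNuclei(getChannel(st, "dapi"), voxelSize = voxelSize(st))
  rep_ <- getChannel(st, "reporter")
  pm <- segmentPuncta(rescale16bit(rep_), nuc)
  sets <- extractPuncta(pm, nuc, rep_, stack = st, condition = "synthetic")
  list(sim = sim, stack = st, nuc = nuc, pm = pm, sets = sets,
       reporter = rep_, target = getChannel(st, "partner"))
}
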