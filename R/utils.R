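# Internal helpers shared across modules.

# Evaluate expr with a temporarily seeded RNG, restoring the caller's
# .Random.seed afterwards so package randomness never perturbs user code.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_seed) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

# Derive a per-stage (or per-cell) seed from a master seed by hashing the
# stage name, so adding a stage never perturbs another stage's draws.
# Kept below 2^31 - 1.
derive_seed <- function(master, name) {
  h <- 0
  for (b in utf8ToInt(as.character(name))) h <- (h * 131 + b) %% 2147480009
  as.integer((as.numeric(master) * 2654435761 + h) %% 2147480009)
}

# Otsu threshold on an intensity vector: maximizes between-class variance
# over a 256-bin histogram of the observed range.
otsu_threshold <- function(v, n_bins = 256L) {
  v <- as.numeric(v)
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1L])
  h <- tabulate(pmin(
    as.integer((v - rng[1L]) / diff(rng) * n_bins) + 1L, n_bins), n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- rng[1L] + (seq_len(n_bins) - 0.5) / n_bins * diff(rng)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  mids[which.max(sigma_b)]
}

# Separable 3D Gaussian blur with edge replication; sigma per axis (z, y, x)
# in voxels, truncated at 3 sigma. sigma of 0 skips that axis.
gaussian_blur3d <- function(arr, sigma) {
  stopifnot(length(dim(arr)) == 3L, length(sigma) == 3L)
  blur_axis <- function(a, axis, s) {
    if (s <= 0) return(a)
    r <- max(1L, ceiling(3 * s))
    k <- exp(-((-r:r)^2) / (2 * s^2))
    k <- k / sum(k)
    n <- dim(a)[axis]
    idx <- outer(seq_len(n), -r:r, "+")
    idx[idx < 1L] <- 1L
    idx[idx > n] <- n
    # weight matrix W: out[i] = sum_j k[j] * a[idx[i, j]]
    apply_along <- function(vmat) {
      # vmat: n x m matrix of series along the axis; returns blurred n x m
      out <- matrix(0, nrow(vmat), ncol(vmat))
      for (j in seq_along(k)) out <- out + k[j] * vmat[idx[, j], , drop = FALSE]
      out
    }
    d <- dim(a)
    perm <- c(axis, setdiff(1:3, axis))
    ap <- aperm(a, perm)
    m <- matrix(ap, nrow = d[axis])
    m <- apply_along(m)
    ap <- array(m, dim = d[perm])
    aperm(ap, order(perm))
  }
  arr <- blur_axis(arr, 1L, sigma[1L])
  arr <- blur_axis(arr, 2L, sigma[2L])
  blur_axis(arr, 3L, sigma[3L])
}

# 26-connectivity connected components of a logical 3D array, labels
# renumbered by descending component volume; ties broken by ascending
# first-voxel raster order (the native order of the flood fill).
label_components <- function(mask) {
  stopifnot(is.logical(mask) || all(mask %in% c(0, 1)))
  d <- dim(mask)
  raw <- .label3d_cpp(as.logical(mask), as.integer(d))
  nlab <- max(raw)
  if (nlab == 0L) return(raw)
  sizes <- tabulate(raw[raw > 0L], nlab)
  # order(-sizes) is stable, so equal volumes keep first-voxel raster order
  new_id <- integer(nlab)
  new_id[order(-sizes)] <- seq_len(nlab)
  out <- raw
  out[raw > 0L] <- new_id[raw[raw > 0L]]
  out
}

# remove labeled components smaller than min_vox voxels, relabel compactly
filter_small <- function(labels, min_vox) {
  nlab <- max(labels)
  if (nlab == 0L || min_vox <= 1L) return(labels)
  sizes <- tabulate(labels[labels > 0L], nlab)
  keep <- which(sizes >= min_vox)
  new_id <- integer(nlab)
  new_id[keep] <- seq_along(keep)
  out <- labels
  out[labels > 0L] <- new_id[labels[labels > 0L]]
  out
}

# min-max normalize to [0, 1]; constant input maps to all zeros
# (the same degenerate rule as rescale16bit)
minmax01 <- function(x) {
  rng <- range(x)
  if (diff(rng) == 0) return(x * 0)
  (x - rng[1L]) / diff(rng)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
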