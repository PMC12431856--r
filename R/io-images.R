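#' Read an image stack from a multi-page TIFF
#'
#' Reads a stack written by \code{\link{writeStack}} (or any plain
#' multi-page TIFF). Stacks written by this package carry a JSON sidecar
#' (\code{<path>.meta.json}) recording layout, dimensions, voxel size,
#' channel labels and bit depth; when present it is authoritative. Without
#' a sidecar the axis order of a multi-page file is ambiguous and
#' \code{layout} must be supplied.
#'
#' @param path TIFF file path.
#' @param layout one of \code{"zyx"}, \code{"czyx"}, \code{"tyx"},
#'   \code{"yx"} (single plane, stored as \code{"zyx"} with nz = 1).
#'   Overridden by a sidecar if one exists.
#' @param voxelSize numeric length-3 (z, y, x) micrometres; used when no
#'   sidecar provides one.
#' @param channelLabels labels for \code{"czyx"} stacks without a sidecar.
#' @param nChannels channel count for \code{"czyx"} stacks without a
#'   sidecar (pages are channel-major: all z of channel 1, then channel 2, ...).
#' @return an \linkS4class{ImageStack}.
#' @export
readStack <- function(path, layout = NULL, voxelSize = NULL,
                      channelLabels = NULL, nChannels = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path))
    jsonlite::read_json(meta_path, simplifyVector = TRUE) else NULL
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  ny <- nrow(pages[[1L]]); nx <- ncol(pages[[1L]])
  n_pages <- length(pages)
  lay <- meta$layout %||% layout
  if (is.null(lay)) {
    if (n_pages == 1L) lay <- "yx"
    else stop("axis order of a ", n_pages, "-page TIFF is ambiguous; ",
              "supply layout = one of 'zyx', 'czyx', 'tyx'")
  }
  vs <- as.numeric(meta$voxelSize %||% voxelSize %||% c(0.2, 0.11, 0.11))
  flat <- array(unlist(pages, use.names = FALSE), dim = c(ny, nx, n_pages))
  storage.mode(flat) <- "double"
  if (lay == "yx") {
    dat <- aperm(flat, c(3L, 1L, 2L))  # nz = 1
    lab <- as.character(meta$channelLabels %||% channelLabels %||% "channel1")
    stk <- new("ImageStack", data = dat, layout = "zyx", voxelSize = vs,
               channelLabels = lab,
               bitDepth = as.integer(meta$bitDepth %||% 16L))
    return(stk)
  }
  if (lay %in% c("zyx", "tyx")) {
    dat <- aperm(flat, c(3L, 1L, 2L))
    lab <- as.character(meta$channelLabels %||% channelLabels %||% "channel1")
    return(new("ImageStack", data = dat, layout = lay, voxelSize = vs,
               channelLabels = lab,
               bitDepth = as.integer(meta$bitDepth %||% 16L)))
  }
  if (lay == "czyx") {
    nc <- as.integer(meta$nChannels %||% nChannels %||%
                       length(meta$channelLabels %||% channelLabels))
    if (!length(nc) || is.na(nc) || nc < 1L)
      stop("'czyx' without a sidecar needs nChannels or channelLabels")
    if (n_pages %% nc != 0L)
      stop("page count ", n_pages, " not divisible by ", nc, " channels")
    nz <- n_pages %/% nc
    dat <- array(0, dim = c(nc, nz, ny, nx))
    for (ci in seq_len(nc)) {
      sub <- flat[, , (ci - 1L) * nz + seq_len(nz), drop = FALSE]
      dat[ci, , , ] <- aperm(sub, c(3L, 1L, 2L))
    }
    lab <- as.character(meta$channelLabels %||% channelLabels %||%
                          paste0("channel", seq_len(nc)))
    return(new("ImageStack", data = dat, layout = "czyx", voxelSize = vs,
               channelLabels = lab,
               bitDepth = as.integer(meta$bitDepth %||% 16L)))
  }
  stop("unknown layout '", lay, "'; candidates: yx, zyx, tyx, czyx")
}

#' Write an image stack as multi-page 16-bit TIFF with a JSON sidecar
#'
#' Intensities are rounded to integers and clipped to [0, 65535]
#' (integer-valued stacks round-trip bit-identically). Pages are
#' channel-major for \code{"czyx"} layouts. Voxel size, layout, channel
#' labels and bit depth go to \code{<path>.meta.json}.
#'
#' @param stack an \linkS4class{ImageStack}.
#' @param path output TIFF path.
#' @return \code{path}, invisibly.
#' @export
writeStack <- function(stack, path) {
  stopifnot(is(stack, "ImageStack"))
  arr <- round(stack@data)
  arr <- pmin(pmax(arr, 0), 65535)
  pages <- list()
  if (stack@layout == "czyx") {
    d <- dim(arr)
    for (ci in seq_len(d[1L])) for (zi in seq_len(d[2L]))
      pages[[length(pages) + 1L]] <- arr[ci, zi, , ] / 65535
    meta_dim <- d
  } else {
    d <- dim(arr)
    for (zi in seq_len(d[1L]))
      pages[[length(pages) + 1L]] <- arr[zi, , ] / 65535
    meta_dim <- d
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "deflate",
                  reduce = FALSE)
  meta <- list(layout = stack@layout, dim = meta_dim,
               voxelSize = stack@voxelSize,
               channelLabels = stack@channelLabels,
               nChannels = if (stack@layout == "czyx") dim(arr)[1L] else 1L,
               bitDepth = stack@bitDepth)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write a label mask as 16-bit label TIFF
#'
#' @param mask a \linkS4class{LabelMask} (labels must not exceed 65535).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeMask <- function(mask, path) {
  stopifnot(is(mask, "LabelMask"), max(mask@labels) <= 65535)
  stk <- new("ImageStack", data = mask@labels * 1.0, layout = "zyx",
             voxelSize = mask@voxelSize, channelLabels = "labels",
             bitDepth = 16L)
  writeStack(stk, path)
}

#' Read a label mask written by \code{writeMask}
#'
#' @param path TIFF path.
#' @param voxelSize fallback voxel size when no sidecar is present.
#' @return a \linkS4class{LabelMask}.
#' @export
readMask <- function(path, voxelSize = NULL) {
  stk <- readStack(path, layout = "zyx", voxelSize = voxelSize)
  lab <- stk@data
  storage.mode(lab) <- "integer"
  new("LabelMask", labels = lab, voxelSize = stk@voxelSize)
}

#' Rescale a channel linearly onto the 16-bit range
#'
#' Maps the channel minimum to 0 and maximum to 65535, linearly in
#' between, rounding to integers with round-half-even (base R
#' \code{round}). A constant channel maps to all zeros (the degenerate
#' min == max rule used throughout the package). The operation is
#' monotone non-decreasing and idempotent up to quantization (at most
#' \code{(max - min) / 65535} per value).
#'
#' @param channel numeric array or vector.
#' @return array of the same shape with values in 0..65535.
#' @export
rescale16bit <- function(channel) {
  if (!length(channel)) stop("empty channel")
  rng <- range(channel)
  if (diff(rng) == 0) return(channel * 0)
  round((channel - rng[1L]) / diff(rng) * 65535)
}
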