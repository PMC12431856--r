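#' Measure FRAP region means from a single-plane time-lapse
#'
#' Per-frame mean intensities of the circular bleach ROI, the whole
#' nucleus (2D mask of the imaged plane) and a rectangular background
#' region. The bleach frame is detected as the frame with the maximal
#' one-step drop in the ROI mean, unless supplied.
#'
#' @param stack an \linkS4class{ImageStack} with layout \code{"tyx"};
#'   \code{voxelSize} is read as (dt seconds, dy, dx micrometres).
#' @param roiCenter numeric (y, x) pixel center of the bleach ROI.
#' @param roiRadiusUm ROI radius in micrometres (default 1, converted to
#'   pixels with the lateral pixel size).
#' @param nucleusMask2d logical ny x nx matrix of the nucleus.
#' @param backgroundBox integer (y0, y1, x0, x1), half-open background
#'   rectangle.
#' @param bleachIndex optional known first postbleach frame.
#' @param cellId identifier stored on the trace.
#' @return a \linkS4class{FrapTrace}.
#' @export
measureFrap <- function(stack, roiCenter, roiRadiusUm = 1,
                        nucleusMask2d, backgroundBox,
                        bleachIndex = NULL, cellId = "cell1") {
  stopifnot(is(stack, "ImageStack"), stack@layout == "tyx")
  arr <- stack@data
  d <- dim(arr)
  dt <- stack@voxelSize[1L]
  px <- stack@voxelSize[3L]
  r_px <- roiRadiusUm / px
  yy <- matrix(seq_len(d[2L]), d[2L], d[3L])
  xx <- matrix(seq_len(d[3L]), d[2L], d[3L], byrow = TRUE)
  roi <- (yy - roiCenter[1L])^2 + (xx - roiCenter[2L])^2 <= r_px^2
  if (roiCenter[1L] - r_px < 1 || roiCenter[1L] + r_px > d[2L] ||
      roiCenter[2L] - r_px < 1 || roiCenter[2L] + r_px > d[3L])
    stop("bleach ROI extends outside the image")
  stopifnot(identical(dim(nucleusMask2d), d[2:3]))
  bb <- backgroundBox
  bg <- matrix(FALSE, d[2L], d[3L])
  bg[bb[1L]:(bb[2L] - 1L), bb[3L]:(bb[4L] - 1L)] <- TRUE
  series <- function(mask2d) {
    vapply(seq_len(d[1L]), function(ti) {
      pl <- arr[ti, , ]
      mean(pl[mask2d])
    }, numeric(1))
  }
  roi_mean <- series(roi)
  nuc_mean <- series(nucleusMask2d)
  bg_mean <- series(bg)
  if (is.null(bleachIndex)) {
    drops <- -diff(roi_mean)
    if (max(drops) <= 0)
      stop("no bleach found: ROI mean never drops; supply bleachIndex")
    bleachIndex <- which.max(drops) + 1L
  }
  new("FrapTrace", time = (seq_len(d[1L]) - 1) * dt, roiMean = roi_mean,
      nucleusMean = nuc_mean, backgroundMean = bg_mean,
      bleachIndex = as.integer(bleachIndex), roiRadiusUm = roiRadiusUm,
      cellId = cellId)
}

#' Double-normalize a FRAP trace
#'
#' Background values are subtracted from the ROI and whole-nucleus values;
#' the corrected ROI is divided per frame by the corrected whole-nucleus
#' signal (cancelling acquisition photobleaching, which hits both
#' multiplicatively), and that ratio is divided by its mean over the
#' prebleach frames, so the prebleach mean is exactly 1. The whole
#' operation is invariant under any shared affine rescaling of the three
#' measured series.
#'
#' @param trace a \linkS4class{FrapTrace}.
#' @return a \linkS4class{NormalizedTrace}.
#' @export
normalizeFrap <- function(trace) {
  stopifnot(is(trace, "FrapTrace"))
  nuc <- trace@nucleusMean - trace@backgroundMean
  bad <- which(nuc <= 0)
  if (length(bad))
    stop("corrected whole-nucleus signal is not positive at frame ",
         bad[1L])
  ratio <- (trace@roiMean - trace@backgroundMean) / nuc
  pre <- seq_len(trace@bleachIndex - 1L)
  v <- ratio / mean(ratio[pre])
  new("NormalizedTrace", time = trace@time, value = v,
      bleachIndex = trace@bleachIndex, cellId = trace@cellId)
}

#' Ensemble-average normalized FRAP traces
#'
#' Pointwise mean and standard deviation across cells on the shared time
#' grid, plus a locally weighted (LOESS) regression through the mean
#' values. The span default of 0.3 is a documented smoothing choice.
#'
#' @param traces list of \linkS4class{NormalizedTrace} (>= 2) on one grid.
#' @param loessSpan LOESS span for the smooth curve.
#' @return a \linkS4class{FrapEnsemble}.
#' @export
aggregateFrap <- function(traces, loessSpan = 0.3) {
  stopifnot(length(traces) >= 2L,
            all(vapply(traces, is, logical(1), "NormalizedTrace")))
  tm <- traces[[1L]]@time
  for (tr in traces)
    if (!isTRUE(all.equal(tr@time, tm)))
      stop("traces are not on a common time grid (no resampling)")
  vals <- vapply(traces, function(tr) tr@value, numeric(length(tm)))
  mean_curve <- rowMeans(vals)
  sd_curve <- apply(vals, 1L, stats::sd)
  # smooth the postbleach segment only: a single LOESS across the bleach
  # step would smear the discontinuity into the prebleach frames
  bi <- traces[[1L]]@bleachIndex
  pre <- seq_len(bi - 1L)
  post <- seq(bi, length(tm))
  smooth_curve <- mean_curve
  if (length(post) >= 10L) {
    tp <- tm[post]; vp <- mean_curve[post]
    fit <- stats::loess(vp ~ tp, span = loessSpan, degree = 2L)
    smooth_curve[post] <- stats::predict(fit)
  }
  new("FrapEnsemble", traces = traces, time = tm, meanCurve = mean_curve,
      sdCurve = sd_curve, smoothCurve = smooth_curve,
      nCells = length(traces), bleachIndex = bi,
      span = loessSpan)
}

#' Fit a single-exponential recovery to an ensemble mean curve
#'
#' Least-squares fit of
#' \deqn{v(t') = v_{bleach} + (plateau - v_{bleach})(1 - e^{-k t'})}
#' to the postbleach mean curve (\eqn{t'} measured from the bleach
#' frame); the mobile fraction is
#' \eqn{(plateau - v_{bleach}) / (1 - v_{bleach})} and the recovery
#' halftime is \eqn{\ln 2 / k}.
#'
#' @param ensemble a \linkS4class{FrapEnsemble} with >= 5 postbleach
#'   frames.
#' @return list: \code{mobile_fraction}, \code{halftime}, \code{rate},
#'   \code{plateau}, \code{v_bleach}.
#' @export
fitRecovery <- function(ensemble) {
  stopifnot(is(ensemble, "FrapEnsemble"))
  bi <- ensemble@bleachIndex
  post <- seq(bi, length(ensemble@time))
  if (length(post) < 5L) stop("need at least 5 postbleach frames")
  tp <- ensemble@time[post] - ensemble@time[bi]
  v <- ensemble@meanCurve[post]
  v0 <- v[1L]
  if (diff(range(v)) < 1e-10) {
    # flat postbleach curve: the zero-amplitude model is the exact
    # least-squares solution (no recovery, immobile)
    return(list(mobile_fraction = 0, halftime = Inf, rate = 0,
                plateau = mean(v), v_bleach = mean(v)))
  }
  plateau0 <- mean(utils::tail(v, max(3L, length(v) %/% 5L)))
  k0 <- 0.1 / (ensemble@time[2L] - ensemble@time[1L])
  fit <- tryCatch(
    minpack.lm::nlsLM(
      v ~ vb + (pl - vb) * (1 - exp(-k * tp)),
      start = list(vb = v0, pl = max(plateau0, v0 + 1e-3), k = k0),
      lower = c(vb = -Inf, pl = -Inf, k = 1e-8),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error"))
    stop("recovery fit did not converge: ", conditionMessage(fit),
         "; residual range of flat model ",
         paste(signif(range(v - mean(v)), 3), collapse = " .. "))
  co <- stats::coef(fit)
  mobile <- if (abs(1 - co[["vb"]]) < 1e-12) 0 else
    (co[["pl"]] - co[["vb"]]) / (1 - co[["vb"]])
  list(mobile_fraction = unname(mobile),
       halftime = unname(log(2) / co[["k"]]),
       rate = unname(co[["k"]]),
       plateau = unname(co[["pl"]]),
       v_bleach = unname(co[["vb"]]))
}
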