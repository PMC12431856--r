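#' Parameters for the synthetic FRAP trace generator
#'
#' Describes a fluorescence-recovery-after-photobleaching experiment with a
#' known bleach depth, mobile fraction, single-exponential recovery rate,
#' and an optional whole-field acquisition photobleaching decay applied to
#' both the ROI and the whole-nucleus signal (which double normalization
#' must cancel).
#'
#' @param nPre prebleach frames (>= 1).
#' @param nPost postbleach frames.
#' @param dt seconds per frame (default 1 s acquisition interval).
#' @param bleachDepth fraction in [0, 1] of ROI signal removed at bleach
#'   (0 gives an unbleached control trace proportional to the
#'   whole-nucleus signal).
#' @param mobileFraction fraction in [0, 1] of bleached signal that recovers.
#' @param recoveryRate recovery rate constant, 1/seconds.
#' @param photobleachRate whole-field acquisition photobleaching rate,
#'   1/seconds, applied multiplicatively to ROI and nucleus signal.
#' @param backgroundLevel additive background intensity.
#' @param signalLevel prebleach signal scale above background.
#' @param noiseSd additive Gaussian noise s.d. on every measured series.
#' @param seed integer.
#' @return a validated list of class \code{SyntheticFrapParams}.
#' @export
syntheticFrapParams <- function(nPre = 5L, nPost = 60L, dt = 1,
                                bleachDepth = 0.8, mobileFraction = 0.5,
                                recoveryRate = 0.2, photobleachRate = 0,
                                backgroundLevel = 100, signalLevel = 1000,
                                noiseSd = 0, seed = 1L) {
  p <- list(nPre = as.integer(nPre), nPost = as.integer(nPost), dt = dt,
            bleachDepth = bleachDepth, mobileFraction = mobileFraction,
            recoveryRate = recoveryRate, photobleachRate = photobleachRate,
            backgroundLevel = backgroundLevel, signalLevel = signalLevel,
            noiseSd = noiseSd, seed = as.integer(seed))
  if (p$nPre < 1L)
    stop("nPre must be >= 1: prebleach normalization is undefined without prebleach frames")
  stopifnot(p$nPost >= 1L, p$dt > 0,
            p$bleachDepth >= 0, p$bleachDepth <= 1,
            p$mobileFraction >= 0, p$mobileFraction <= 1,
            p$recoveryRate >= 0, p$photobleachRate >= 0, p$noiseSd >= 0)
  class(p) <- "SyntheticFrapParams"
  p
}

#' Generate a synthetic FRAP trace with known ground truth
#'
#' The noiseless ROI mean is
#' \deqn{bg + S e^{-p t} [1_{pre}; (1-d) + d m (1 - e^{-k (t - t_b)})]}
#' and the whole-nucleus mean is \eqn{bg + S e^{-p t}}, where \eqn{d} is
#' the bleach depth, \eqn{m} the mobile fraction, \eqn{k} the recovery
#' rate and \eqn{p} the whole-field photobleaching rate. The normalized
#' recovery plateau is therefore \eqn{(1-d) + d m}.
#'
#' @param params a \code{SyntheticFrapParams} list.
#' @param cellId identifier stored on the trace.
#' @return list with \code{trace} (a \linkS4class{FrapTrace}) and
#'   \code{truth} (mobile fraction, recovery rate, bleach depth, and the
#'   normalized plateau \code{(1 - d) + d * m}).
#' @export
simulateFrap <- function(params, cellId = "cell1") {
  stopifnot(inherits(params, "SyntheticFrapParams"))
  p <- params
  n <- p$nPre + p$nPost
  tm <- (seq_len(n) - 1) * p$dt
  bleach_index <- p$nPre + 1L
  t_b <- tm[bleach_index]
  rec <- rep(1, n)
  post <- seq(bleach_index, n)
  rec[post] <- (1 - p$bleachDepth) +
    p$bleachDepth * p$mobileFraction *
      (1 - exp(-p$recoveryRate * (tm[post] - t_b)))
  field <- p$signalLevel * exp(-p$photobleachRate * tm)
  with_seed(p$seed, {
    nz <- function() if (p$noiseSd > 0) stats::rnorm(n, 0, p$noiseSd) else
      numeric(n)
    roi <- p$backgroundLevel + field * rec + nz()
    nucleus <- p$backgroundLevel + field + nz()
    background <- rep(p$backgroundLevel, n) + nz()
    trace <- new("FrapTrace", time = tm, roiMean = roi,
                 nucleusMean = nucleus, backgroundMean = background,
                 bleachIndex = bleach_index, roiRadiusUm = 1,
                 cellId = cellId)
    list(trace = trace,
         truth = list(mobileFraction = p$mobileFraction,
                      recoveryRate = p$recoveryRate,
                      bleachDepth = p$bleachDepth,
                      plateau = (1 - p$bleachDepth) +
                        p$bleachDepth * p$mobileFraction))
  })
}
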