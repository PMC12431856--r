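# Render a generator trace into a 2D+time movie: nucleus pixels carry the
# whole-nucleus series, a small disc inside carries the ROI series, and a
# corner box carries the background series.
render_frap_movie <- function(trace, ny = 120L, nx = 120L, roi_r_px = 5L) {
  n <- length(trace@time)
  arr <- array(0, dim = c(n, ny, nx))
  yy <- matrix(seq_len(ny), ny, nx)
  xx <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  nuc <- (yy - 60)^2 + (xx - 60)^2 <= 45^2
  roi <- (yy - 60)^2 + (xx - 60)^2 <= roi_r_px^2
  bg_box <- yy <= 15 & xx <= 15
  for (ti in seq_len(n)) {
    pl <- matrix(0, ny, nx)
    pl[nuc] <- trace@nucleusMean[ti]
    pl[roi] <- trace@roiMean[ti]
    pl[bg_box] <- trace@backgroundMean[ti]
    arr[ti, , ] <- pl
  }
  stk <- new("ImageStack", data = arr, layout = "tyx",
             voxelSize = c(1, 0.11, 0.11), channelLabels = "gfp")
  list(stack = stk, nucleus = nuc, roi_center = c(60, 60),
       roi_radius_um = roi_r_px * 0.11,
       background_box = c(1L, 16L, 1L, 16L))
}

test_that("movie measurements recover the generator's analytic series", {
  fs <- simulateFrap(syntheticFrapParams(noiseSd = 0, photobleachRate = 0.01))
  mv <- render_frap_movie(fs$trace)
  tr <- measureFrap(mv$stack, mv$roi_center, mv$roi_radius_um,
                    mv$nucleus, mv$background_box)
  expect_identical(tr@bleachIndex, fs$trace@bleachIndex)
  expect_equal(tr@roiMean, fs$trace@roiMean, tolerance = 1e-12)
  expect_equal(tr@backgroundMean, fs$trace@backgroundMean, tolerance = 1e-12)
  # whole-nucleus mean mixes in the ROI disc; small-disc contamination only
  expect_equal(tr@nucleusMean, fs$trace@nucleusMean, tolerance = 0.02)
})

test_that("a constant movie raises an explicit no-bleach error", {
  arr <- array(100, dim = c(10, 40, 40))
  stk <- new("ImageStack", data = arr, layout = "tyx",
             voxelSize = c(1, 0.11, 0.11), channelLabels = "gfp")
  nuc <- matrix(TRUE, 40, 40)
  expect_error(measureFrap(stk, c(20, 20), 0.5, nuc, c(1L, 5L, 1L, 5L)),
               "no bleach found")
})

test_that("a zero background region measures zero background", {
  fs <- simulateFrap(syntheticFrapParams(noiseSd = 0, backgroundLevel = 0))
  mv <- render_frap_movie(fs$trace)
  tr <- measureFrap(mv$stack, mv$roi_center, mv$roi_radius_um,
                    mv$nucleus, mv$background_box)
  expect_identical(unique(tr@backgroundMean), 0)
})

test_that("double normalization cancels whole-field photobleaching exactly", {
  p <- syntheticFrapParams(bleachDepth = 0, photobleachRate = 0.05,
                           noiseSd = 0)
  nt <- normalizeFrap(simulateFrap(p)$trace)
  expect_equal(nt@value, rep(1, length(nt@value)), tolerance = 1e-12)
})

test_that("normalization is invariant under shared affine intensity rescaling", {
  fs <- simulateFrap(syntheticFrapParams(noiseSd = 3, seed = 6L))
  tr <- fs$trace
  tr2 <- new("FrapTrace", time = tr@time, roiMean = 2.5 * tr@roiMean + 40,
             nucleusMean = 2.5 * tr@nucleusMean + 40,
             backgroundMean = 2.5 * tr@backgroundMean + 40,
             bleachIndex = tr@bleachIndex, roiRadiusUm = 1, cellId = "c")
  expect_equal(normalizeFrap(tr2)@value, normalizeFrap(tr)@value,
               tolerance = 1e-12)
})

test_that("prebleach-only data normalizes to exactly one", {
  n <- 10L
  tr <- new("FrapTrace", time = 0:(n - 1), roiMean = rep(500, n),
            nucleusMean = rep(800, n), backgroundMean = rep(100, n),
            bleachIndex = n, roiRadiusUm = 1, cellId = "c")
  expect_identical(normalizeFrap(tr)@value, rep(1, n))
})

test_that("a nonpositive corrected nucleus signal is reported by frame", {
  tr <- new("FrapTrace", time = 0:4, roiMean = rep(50, 5),
            nucleusMean = c(200, 200, 90, 200, 200),
            backgroundMean = rep(100, 5), bleachIndex = 2L,
            roiRadiusUm = 1, cellId = "c")
  expect_error(normalizeFrap(tr), "frame 3")
})

test_that("ensemble of identical traces has zero spread and unit prebleach smooth", {
  nt <- normalizeFrap(simulateFrap(syntheticFrapParams(noiseSd = 0))$trace)
  ens <- aggregateFrap(list(nt, nt, nt))
  expect_identical(ens@sdCurve, rep(0, length(ens@time)))
  expect_equal(ens@meanCurve, nt@value)
  pre <- seq_len(ens@bleachIndex - 1L)
  expect_lt(max(abs(ens@smoothCurve[pre] - 1)), 0.05)
  expect_error(aggregateFrap(list(nt, new("NormalizedTrace",
    time = nt@time + 0.5, value = nt@value, bleachIndex = nt@bleachIndex,
    cellId = "x"))), "common time grid")
})

test_that("a 19-cell noisy ensemble recovers the planted plateau within 2 se", {
  m <- 0.6; d <- 0.8
  traces <- lapply(1:19, function(i) normalizeFrap(simulateFrap(
    syntheticFrapParams(bleachDepth = d, mobileFraction = m,
                        recoveryRate = 0.25, noiseSd = 10, nPost = 80,
                        seed = 100 + i), cellId = paste0("c", i))$trace))
  ens <- aggregateFrap(traces)
  tail_frames <- seq(length(ens@time) - 19L, length(ens@time))
  per_cell <- vapply(traces, function(tr) mean(tr@value[tail_frames]),
                     numeric(1))
  se <- stats::sd(per_cell) / sqrt(length(per_cell))
  plateau_truth <- (1 - d) + d * m
  expect_lt(abs(mean(per_cell) - plateau_truth), 2 * se + 1e-3)
})

test_that("recovery fitting is exact on noiseless data and bounded on noisy data", {
  p <- syntheticFrapParams(bleachDepth = 0.8, mobileFraction = 0.7,
                           recoveryRate = 0.2, noiseSd = 0, nPost = 100)
  nt <- normalizeFrap(simulateFrap(p)$trace)
  fit <- fitRecovery(aggregateFrap(list(nt, nt)))
  expect_lt(abs(fit$mobile_fraction - 0.7), 1e-6)
  expect_lt(abs(fit$rate - 0.2), 1e-6)
  expect_equal(fit$halftime, log(2) / fit$rate)
  # immobile: flat postbleach, mobile fraction ~ 0
  p0 <- syntheticFrapParams(bleachDepth = 0.8, mobileFraction = 0,
                            noiseSd = 0, nPost = 40)
  nt0 <- normalizeFrap(simulateFrap(p0)$trace)
  fit0 <- fitRecovery(aggregateFrap(list(nt0, nt0)))
  expect_lt(abs(fit0$mobile_fraction), 0.02)
  # 19 noisy cells at 2% noise: parameters within 10% relative error
  traces <- lapply(1:19, function(i) normalizeFrap(simulateFrap(
    syntheticFrapParams(bleachDepth = 0.8, mobileFraction = 0.7,
                        recoveryRate = 0.2, noiseSd = 20, nPost = 100,
                        seed = 300 + i), cellId = paste0("c", i))$trace))
  fitn <- fitRecovery(aggregateFrap(traces))
  expect_lt(abs(fitn$mobile_fraction - 0.7) / 0.7, 0.10)
  expect_lt(abs(fitn$rate - 0.2) / 0.2, 0.10)
})
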