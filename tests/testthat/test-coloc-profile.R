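rect_nucleus_mask <- function(dims, z = NULL, y, x) {
  m <- array(FALSE, dim = dims)
  if (is.null(z)) z <- seq_len(dims[1])
  m[z, y, x] <- TRUE
  new("LabelMask", labels = array(as.integer(m), dim = dims))
}

test_that("a constant patch maps to the all-zero profile", {
  ch <- array(42, dim = c(6, 80, 80))
  pun <- data.frame(y = 40, x = 40, z0 = 2L, z1 = 5L, z_extent = 3L)
  m <- extractBoxProfile(ch, pun)
  expect_identical(m, matrix(0, 61, 61))
})

test_that("a bright voxel at the centroid lands at the matrix center", {
  ch <- array(0, dim = c(6, 80, 80))
  ch[3, 40, 40] <- 100
  pun <- data.frame(y = 40, x = 40, z0 = 3L, z1 = 4L, z_extent = 1L)
  m <- extractBoxProfile(ch, pun)
  expect_identical(which(m == max(m), arr.ind = TRUE)[1, ],
                   c(row = 31L, col = 31L))
})

test_that("box extraction matches the naive triple-loop reference bit-exactly", {
  set.seed(55)
  for (rep in 1:10) {
    nz <- sample(4:9, 1)
    ch <- array(runif(nz * 90 * 90, 0, 4000), dim = c(nz, 90, 90))
    yc <- sample(31:60, 1); xc <- sample(31:60, 1)
    pick <- function(v) v[sample.int(length(v), 1)]
    z0 <- pick(1:(nz - 1)); z1 <- pick((z0 + 1):nz) + 1L
    pun <- data.frame(y = yc, x = xc, z0 = z0, z1 = z1,
                      z_extent = z1 - z0)
    expect_identical(extractBoxProfile(ch, pun),
                     naive_box_profile(ch, yc, xc, z0, z1))
  }
})

test_that("loci at the lateral border are skipped, not padded", {
  ch <- array(runif(5 * 70 * 70), dim = c(5, 70, 70))
  pun <- data.frame(y = 10, x = 35, z0 = 1L, z1 = 3L, z_extent = 2L)
  expect_null(extractBoxProfile(ch, pun))
})

test_that("profile averaging is an element-wise mean", {
  m <- matrix(runif(61 * 61), 61, 61)
  bp <- averageProfiles(list(m, m, m))
  expect_equal(profileMatrix(bp), m)
  expect_identical(nLoci(bp), 3L)
  bp2 <- averageProfiles(list(m, 1 - m))
  expect_equal(profileMatrix(bp2), matrix(0.5, 61, 61))
  expect_error(averageProfiles(list(m, matrix(0.1, 31, 31))), "mismatch")
})

test_that("profiles are invariant under affine intensity transforms", {
  set.seed(66)
  ch <- array(runif(6 * 80 * 80, 100, 900), dim = c(6, 80, 80))
  pun <- data.frame(y = 40, x = 41, z0 = 2L, z1 = 6L, z_extent = 4L)
  m1 <- extractBoxProfile(ch, pun)
  m2 <- extractBoxProfile(3.7 * ch + 250, pun)
  expect_equal(m2, m1, tolerance = 1e-12)
})

test_that("random loci are matched in number, unique, and inside the nucleus", {
  dims <- c(8L, 140L, 140L)
  nm <- rect_nucleus_mask(dims, y = 6:134, x = 6:134)
  centers <- data.frame(z = rep(4, 7), y = 40 + 1:7 * 5, x = 40 + 1:7 * 5)
  ps <- make_puncta_set(centers, z_extent = c(1, 2, 2, 3, 3, 4, 5))
  loci <- sampleRandomLoci(nm, ps, seed = 9L)
  expect_identical(nrow(loci), 7L)
  expect_identical(anyDuplicated(loci[, c("y", "x")]), 0L)
  expect_true(all(loci$z_len >= 1 & loci$z_len <= 5))
  # exhaustive footprint check against the mask projection
  labs <- maskData(nm)
  for (i in seq_len(nrow(loci))) {
    proj <- apply(labs[loci$z0[i]:(loci$z1[i] - 1), , , drop = FALSE] > 0,
                  c(2, 3), any)
    foot <- proj[(loci$y[i] - 30):(loci$y[i] + 30),
                 (loci$x[i] - 30):(loci$x[i] + 30)]
    expect_true(all(foot))
  }
})

test_that("a nucleus narrower than the box is reported as infeasible", {
  nm <- rect_nucleus_mask(c(6L, 80L, 80L), y = 20:60, x = 20:60)
  ps <- make_puncta_set(data.frame(z = 3, y = 40, x = 40))
  expect_error(sampleRandomLoci(nm, ps), "smaller than the 61")
})

test_that("random locus centers are uniform over the feasible region", {
  dims <- c(6L, 160L, 160L)
  nm <- rect_nucleus_mask(dims, y = 3:158, x = 3:158)
  # feasible centers: y, x in 33..128 (border margin 30 within the 3..158 mask)
  n_loci <- 3000L
  centers <- data.frame(z = rep(3, n_loci),
                        y = rep(80, n_loci), x = rep(80, n_loci))
  ps <- make_puncta_set(centers, z_extent = rep(2L, n_loci))
  loci <- sampleRandomLoci(nm, ps, seed = 12L, maxRejections = 1e6)
  cut4 <- function(v, lo, hi) pmin(4L, 1L + (v - lo) %/% ((hi - lo + 1) / 4))
  tab <- table(cut4(loci$y, 33, 128), cut4(loci$x, 33, 128))
  chi <- sum((tab - n_loci / 16)^2 / (n_loci / 16))
  expect_gt(stats::pchisq(chi, df = 15, lower.tail = FALSE), 0.01)
})

test_that("a pure-noise channel gives a flat null profile", {
  set.seed(77)
  dims <- c(8L, 150L, 150L)
  ch <- array(rnorm(prod(dims), 500, 40), dim = dims)
  nm <- rect_nucleus_mask(dims, y = 5:145, x = 5:145)
  centers <- data.frame(z = rep(4, 40), y = rep(75, 40), x = rep(75, 40))
  ps <- make_puncta_set(centers, z_extent = rep(3L, 40))
  null1 <- profileRandomNull(ch, nm, ps, seed = 21L)
  es <- enrichmentSummary(null1)
  # 3-standard-error band from the spread of per-pixel means
  se <- stats::sd(profileMatrix(null1)) / sqrt(11^2)
  expect_lt(abs(es$central_mean - es$edge_mean), 3 * se)
  # determinism: same seed, same profile
  null2 <- profileRandomNull(ch, nm, ps, seed = 21L)
  expect_identical(profileMatrix(null1), profileMatrix(null2))
})

test_that("fish-centered profiles peak at colocalized loci and stay flat far away", {
  b <- segmented_stack(syntheticImageParams(seed = 88, colocFraction = 1))
  # FISH-like loci: detect the partner channel and profile the reporter
  fish_pm <- segmentPuncta(rescale16bit(b$target), b$nuc)
  fish_sets <- extractPuncta(fish_pm, b$nuc, b$target)
  fp <- fishLocusProfiles(fish_sets, b$reporter, b$nuc, seed = 5L)
  expect_identical(profileMode(fp$profile), "fish-centered")
  expect_gt(enrichmentSummary(fp$profile)$ratio,
            enrichmentSummary(fp$null)$ratio)
  expect_gt(enrichmentSummary(fp$profile)$ratio, 2)
  # loci placed >= 40 px from every reporter punctum: ratio near 1
  set.seed(89)
  dims <- dim(b$reporter)
  truth <- b$sim$truth$centers
  far <- data.frame(z = integer(), y = integer(), x = integer())
  while (nrow(far) < 20) {
    yc <- sample(45:175, 1); xc <- sample(45:175, 1)
    if (all(sqrt((truth$y - yc)^2 + (truth$x - xc)^2) >= 40) &&
        maskData(b$nuc)[12, yc, xc] > 0)
      far <- rbind(far, data.frame(z = 12, y = yc, x = xc))
  }
  far_sets <- make_puncta_set(far, z_extent = rep(5L, nrow(far)))
  far_prof <- profilePuncta(far_sets, b$reporter, mode = "fish-centered")
  expect_lt(abs(enrichmentSummary(far_prof)$ratio - 1), 0.5)
})

test_that("cells without FISH loci contribute nothing without error", {
  b <- segmented_stack(small_image_params(seed = 90, nPunctaPerNucleus = 3L))
  empty <- make_puncta_set(data.frame(z = numeric(), y = numeric(),
                                      x = numeric()))
  fp <- profilePuncta(c(b$sets, list(empty)), b$reporter, boxSize = 31L)
  expect_identical(nLoci(fp), 3L)
})

test_that("enrichment summaries match brute force and handle degenerate cases", {
  expect_equal(enrichmentSummary(matrix(0.5, 61, 61))$ratio, 1.0)
  delta <- matrix(0, 61, 61); delta[31, 31] <- 1
  es <- enrichmentSummary(delta)
  expect_true(is.infinite(es$ratio) && es$infinite)
  set.seed(91)
  m <- matrix(runif(61 * 61), 61, 61)
  es2 <- enrichmentSummary(m, centralSize = 11L)
  central_bf <- mean(m[26:36, 26:36])
  ring_bf <- mean(c(m[1, ], m[61, ], m[2:60, 1], m[2:60, 61]))
  expect_equal(es2$central_mean, central_bf)
  expect_equal(es2$edge_mean, ring_bf)
  expect_equal(es2$ratio, central_bf / ring_bf)
})
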