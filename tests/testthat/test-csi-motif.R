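toy_design <- function() {
  libraryDesign(barcodes = c(s1 = "AAACCC", s2 = "GGGTTT", s3 = "CCAAGG"),
                leftFlank = "ACGTACGT", rightFlank = "TTGGCCAA",
                variableLength = 20L, rounds = c("R1", "R2", "R3"))
}

test_that("reads are assigned by exact barcode prefix", {
  d <- toy_design()
  fq <- withr::local_tempfile(fileext = ".fastq")
  reads <- c(paste0("AAACCC", "ACGTACGT", strrep("A", 20), "TTGGCCAA"),
             paste0("GGGTTT", "ACGTACGT", strrep("C", 20), "TTGGCCAA"),
             paste0("TTTTTT", "ACGTACGT", strrep("G", 20), "TTGGCCAA"))
  dna <- Biostrings::DNAStringSet(reads)
  names(dna) <- paste0("r", 1:3)
  Biostrings::writeXStringSet(dna, fq, format = "fastq",
    qualities = Biostrings::BStringSet(strrep("F", nchar(reads))))
  dm <- demultiplex(fq, d)
  expect_identical(lengths(dm$reads), c(s1 = 1L, s2 = 1L, s3 = 0L))
  expect_identical(unname(dm$counts[["unassigned"]]), 1L)
})

test_that("demultiplexed counts equal the generator's on a synthetic pool", {
  p <- syntheticSelexParams(
    barcodes = c(a = "ACGTAC", b = "TGCATG", c = "CCTTAA"),
    motifFractions = list(a = c(0.1, 0.2, 0.3), b = c(0, 0, 0),
                          c = c(0, 0, 0)),
    nReadsPerRound = 2000L, seed = 14L)
  out <- simulateSelex(p, withr::local_tempdir())
  d <- designFromParams(p)
  dm <- demultiplex(out$files$path[out$files$round == "R2"], d)
  expect_identical(unname(lengths(dm$reads)), rep(2000L, 3))
  expect_identical(unname(dm$counts[["unassigned"]]), 0L)
})

test_that("variable regions are recovered exactly from well-formed reads", {
  d <- toy_design()
  region <- "ACGTACGTACGTACGTACGT"
  read <- paste0("AAACCC", d$leftFlank, region, d$rightFlank)
  ex <- extractVariableRegion(read, "s1", d)
  expect_identical(ex$regions, region)
  # two mismatches in the left flank at tolerance 1: rejected
  bad <- paste0("AAACCC", "TTGTACGT", region, d$rightFlank)
  ex2 <- extractVariableRegion(bad, "s1", d, maxFlankMismatch = 1L)
  expect_length(ex2$regions, 0)
  expect_identical(unname(ex2$tallies[["rejected_left_flank"]]), 1L)
  # too-short read lands in the short tally
  ex3 <- extractVariableRegion("AAACCCACG", "s1", d)
  expect_identical(unname(ex3$tallies[["rejected_short"]]), 1L)
})

test_that("extraction inverts the generator for a whole pool", {
  p <- syntheticSelexParams(nReadsPerRound = 3000L, rounds = "R1",
                            motifFractions = list(pos = 0.3, neg = 0),
                            seed = 19L)
  out <- simulateSelex(p, withr::local_tempdir())
  d <- designFromParams(p)
  path <- out$files$path[out$files$sample == "pos"]
  dm <- demultiplex(path, d)
  ex <- extractVariableRegion(dm$reads$pos, "pos", d)
  expect_identical(unname(ex$tallies[["accepted"]]), 3000L)
  # independent recovery of the planted regions by fixed-offset substring
  raw <- as.character(Biostrings::readDNAStringSet(path, format = "fastq"))
  off <- nchar(p$barcodes[["pos"]]) + nchar(p$leftFlank)
  planted <- substr(raw, off + 1L, off + p$variableLength)
  expect_identical(sort(ex$regions), sort(unname(planted)))
})

test_that("k-mer counting matches hand counts and the window formula", {
  kt <- countKmers("CGGCCCCG", k = 6L)
  cn <- kmerCounts(kt)
  expect_identical(cn[["CGGCCC"]], 1)
  expect_identical(cn[["GGCCCC"]], 1)
  expect_identical(cn[["GCCCCG"]], 1)
  expect_identical(sum(cn), 3)
  kt20 <- countKmers(strrep("A", 20), k = 6L)
  expect_identical(kt20@totalPositions, 15)
})

test_that("k-mer counting agrees with a dictionary oracle on random regions", {
  set.seed(23)
  regions <- vapply(1:300, function(i)
    paste0(sample(c("A", "C", "G", "T"), 20, TRUE), collapse = ""),
    character(1))
  kt <- countKmers(regions, k = 6L)
  oracle <- naive_kmer_counts(regions, 6L)
  counts <- kmerCounts(kt)
  expect_identical(counts[names(oracle)], oracle)
  expect_identical(sum(counts), 300 * 15)
  expect_true(all(counts[setdiff(names(counts), names(oracle))] == 0))
})

test_that("reverse-complement counting doubles the scored windows", {
  kt <- countKmers("GGCCCCAA", k = 6L, countReverseComplement = TRUE)
  cn <- kmerCounts(kt)
  expect_identical(cn[["GGCCCC"]], 1)
  expect_identical(cn[["GGGGCC"]], 1)  # revcomp of GGCCCC
  expect_identical(kt@totalPositions, 6)
})

test_that("enrichment is exactly one under identical pools and for absent k-mers", {
  set.seed(27)
  regions <- vapply(1:200, function(i)
    paste0(sample(c("A", "C", "G", "T"), 20, TRUE), collapse = ""),
    character(1))
  kt <- countKmers(regions, k = 4L)
  et <- computeEnrichment(kt, kt)
  expect_true(all(abs(enrichment(et)$enrichment - 1) < 1e-12))
  # absent from both pools: pseudofrequency ratio = 1
  pos <- countKmers("AAAAAAAAAA", k = 6L)
  neg <- countKmers("AAAAAAAAAA", k = 6L)
  et2 <- computeEnrichment(pos, neg)
  tab <- enrichment(et2)
  expect_equal(tab$enrichment[tab$kmer == "GGCCCC"], 1)
  expect_error(computeEnrichment(countKmers(character(), k = 6L), neg),
               "empty")
})

test_that("the ranking is deterministic for fixed FASTQ inputs", {
  p <- syntheticSelexParams(nReadsPerRound = 1500L, rounds = "R1",
                            motifFractions = list(pos = 0.2, neg = 0),
                            seed = 29L)
  out <- simulateSelex(p, withr::local_tempdir())
  d <- designFromParams(p)
  rank_once <- function() {
    tabs <- lapply(c("pos", "neg"), function(s) {
      dm <- demultiplex(out$files$path[out$files$sample == s], d)
      ex <- extractVariableRegion(dm$reads[[s]], s, d)
      countKmers(ex$regions, 6L, sample = s, round = "R1")
    })
    enrichment(computeEnrichment(tabs[[1]], tabs[[2]]))
  }
  expect_identical(rank_once(), rank_once())
})

test_that("round trajectories flag the planted motif and only chance-level others", {
  p <- syntheticSelexParams(nReadsPerRound = 4000L, seed = 37L)
  out <- simulateSelex(p, withr::local_tempdir())
  d <- designFromParams(p)
  tabs <- list()
  for (r in d$rounds) for (s in c("pos", "neg")) {
    dm <- demultiplex(out$files$path[out$files$round == r &
                                       out$files$sample == s], d)
    ex <- extractVariableRegion(dm$reads[[s]], s, d)
    tabs[[paste(s, r)]] <- countKmers(ex$regions, 6L, sample = s, round = r)
  }
  traj <- roundTrajectory(lapply(d$rounds, function(r) tabs[[paste("pos", r)]]),
                          lapply(d$rounds, function(r) tabs[[paste("neg", r)]]))
  expect_identical(nrow(traj), 4096L)
  expect_true(traj$monotone[traj$kmer == "GGCCCC"])
  expect_gt(traj$enrichment_R3[traj$kmer == "GGCCCC"],
            traj$enrichment_R1[traj$kmer == "GGCCCC"])
  expect_error(roundTrajectory(list(tabs[["pos R1"]]), list(tabs[["neg R1"]])),
               "at least 2")
  # negative against negative: monotone count consistent with chance (1/6)
  p2 <- syntheticSelexParams(nReadsPerRound = 4000L, seed = 38L,
                             motifFractions = list(pos = c(0, 0, 0),
                                                   neg = c(0, 0, 0)))
  out2 <- simulateSelex(p2, withr::local_tempdir())
  tabs2 <- list()
  for (r in d$rounds) for (s in c("pos", "neg")) {
    dm <- demultiplex(out2$files$path[out2$files$round == r &
                                        out2$files$sample == s], d)
    ex <- extractVariableRegion(dm$reads[[s]], s, d)
    tabs2[[paste(s, r)]] <- countKmers(ex$regions, 6L, sample = s, round = r)
  }
  traj2 <- roundTrajectory(
    lapply(d$rounds, function(r) tabs2[[paste("pos", r)]]),
    lapply(d$rounds, function(r) tabs2[[paste("neg", r)]]))
  n_mono <- sum(traj2$monotone)
  expected <- 4096 / 6
  sd_mono <- sqrt(4096 * (1 / 6) * (5 / 6))
  expect_lt(abs(n_mono - expected), 4 * sd_mono)
})

test_that("counting conservation holds over accepted regions", {
  p <- syntheticSelexParams(nReadsPerRound = 1000L, rounds = "R1",
                            motifFractions = list(pos = 0.1, neg = 0),
                            seed = 41L)
  out <- simulateSelex(p, withr::local_tempdir())
  d <- designFromParams(p)
  dm <- demultiplex(out$files$path[out$files$sample == "pos"], d)
  ex <- extractVariableRegion(dm$reads$pos, "pos", d)
  kt <- countKmers(ex$regions, 6L)
  expect_identical(sum(kmerCounts(kt)),
                   sum(nchar(ex$regions) - 6 + 1))
})
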