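#' Parameters for the synthetic CSI/SELEX read-pool generator
#'
#' Describes a barcoded amplicon library with a randomized central region
#' (20 bp by default) flanked by constant primer-complementary sequences,
#' selected over rounds: in the positive sample a planted motif is embedded
#' in a growing fraction of reads per round; the fusion-negative control
#' sample carries the motif in no reads at any round.
#'
#' @param motif DNA string planted in motif-carrying reads.
#' @param variableLength length of the randomized central region (bases).
#' @param leftFlank,rightFlank constant flanking sequences.
#' @param barcodes named character vector, sample name -> barcode sequence.
#'   Barcodes must be prefix-free (no barcode a prefix of another).
#' @param rounds character labels of the selection rounds.
#' @param nReadsPerRound reads generated per (sample, round).
#' @param motifFractions named list, sample -> numeric vector (one fraction
#'   per round) of reads carrying the motif. The default plants the motif
#'   at (0.05, 0.15, 0.4) across three rounds in the positive sample and
#'   at 0 everywhere in the negative sample.
#' @param seed integer.
#' @return validated list of class \code{SyntheticSelexParams}.
#' @export
syntheticSelexParams <- function(motif = "GGCCCC",
                                 variableLength = 20L,
                                 leftFlank = "ACACGACGCT",
                                 rightFlank = "AGATCGGAAG",
                                 barcodes = c(pos = "ACGTAC", neg = "TGCATG"),
                                 rounds = c("R1", "R2", "R3"),
                                 nReadsPerRound = 10000L,
                                 motifFractions = list(
                                   pos = c(0.05, 0.15, 0.4),
                                   neg = c(0, 0, 0)),
                                 seed = 1L) {
  p <- list(motif = toupper(motif), variableLength = as.integer(variableLength),
            leftFlank = toupper(leftFlank), rightFlank = toupper(rightFlank),
            barcodes = toupper(barcodes), rounds = rounds,
            nReadsPerRound = as.integer(nReadsPerRound),
            motifFractions = motifFractions, seed = as.integer(seed))
  ok_dna <- function(s) all(strsplit(s, "")[[1]] %in% c("A", "C", "G", "T"))
  stopifnot(nchar(p$motif) <= p$variableLength,
            ok_dna(p$motif), ok_dna(p$leftFlank), ok_dna(p$rightFlank),
            all(vapply(p$barcodes, ok_dna, logical(1))),
            !is.null(names(p$barcodes)),
            setequal(names(p$motifFractions), names(p$barcodes)))
  bc <- p$barcodes
  for (i in seq_along(bc)) for (j in seq_along(bc)) {
    if (i != j && startsWith(bc[[j]], bc[[i]]))
      stop("barcode collision: '", bc[[i]], "' (", names(bc)[i],
           ") is a prefix of '", bc[[j]], "' (", names(bc)[j], ")")
  }
  for (s in names(p$motifFractions)) {
    f <- p$motifFractions[[s]]
    if (length(f) != length(p$rounds))
      stop("motifFractions[['", s, "']] must have one fraction per round")
    if (any(f < 0 | f > 1)) stop("motif fractions must lie in [0, 1]")
  }
  class(p) <- "SyntheticSelexParams"
  p
}

# n random variable regions of length L, the first n_motif carrying `motif`
# at a uniform random offset; returns a character vector (order shuffled)
random_regions <- function(n, L, motif, n_motif) {
  bases <- c("A", "C", "G", "T")
  mat <- matrix(sample(bases, n * L, replace = TRUE), nrow = n)
  if (n_motif > 0) {
    mlen <- nchar(motif)
    mchars <- strsplit(motif, "")[[1]]
    offs <- sample.int(L - mlen + 1L, n_motif, replace = TRUE)
    for (j in seq_len(mlen))
      mat[cbind(seq_len(n_motif), offs + j - 1L)] <- mchars[j]
  }
  regions <- do.call(paste0, as.data.frame(mat, stringsAsFactors = FALSE))
  regions[sample.int(n)]
}

#' Generate synthetic SELEX read pools as gzipped FASTQ
#'
#' Each read is \code{barcode + leftFlank + variable region + rightFlank}
#' with constant Phred-33 quality Q37. Exactly
#' \code{round(fraction * nReadsPerRound)} reads per (sample, round) carry
#' the motif, embedded at a uniform random offset within the variable
#' region; all other variable-region bases are i.i.d. uniform over ACGT.
#'
#' @param params a \code{SyntheticSelexParams} list.
#' @param dir output directory (created if needed).
#' @return list with \code{files} (data frame: sample, round, path,
#'   n_reads, n_motif) and \code{truth} (motif and per-sample fractions).
#' @export
simulateSelex <- function(params, dir = tempfile("selex")) {
  stopifnot(inherits(params, "SyntheticSelexParams"))
  p <- params
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  with_seed(p$seed, {
    for (s in names(p$barcodes)) {
      for (r in seq_along(p$rounds)) {
        frac <- p$motifFractions[[s]][r]
        n <- p$nReadsPerRound
        n_motif <- round(frac * n)
        regions <- random_regions(n, p$variableLength, p$motif, n_motif)
        reads <- paste0(p$barcodes[[s]], p$leftFlank, regions, p$rightFlank)
        path <- file.path(dir, sprintf("%s_%s.fastq.gz", s, p$rounds[r]))
        dna <- Biostrings::DNAStringSet(reads)
        names(dna) <- sprintf("%s_%s_read%d", s, p$rounds[r], seq_len(n))
        qual <- Biostrings::BStringSet(strrep("F", nchar(reads)))
        Biostrings::writeXStringSet(dna, path, format = "fastq",
                                    compress = TRUE, qualities = qual)
        rows[[length(rows) + 1L]] <- data.frame(
          sample = s, round = p$rounds[r], path = path,
          n_reads = n, n_motif = n_motif, stringsAsFactors = FALSE)
      }
    }
  })
  list(files = do.call(rbind, rows),
       truth = list(motif = p$motif, fractions = p$motifFractions,
                    params = p))
}
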