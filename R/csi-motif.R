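#' Describe a CSI/SELEX amplicon library
#'
#' Layout of every read: \code{barcode + leftFlank + variable region +
#' rightFlank}, with a randomized central region of 20 bp by default.
#'
#' @param barcodes named character vector, sample -> barcode (prefix-free).
#' @param leftFlank,rightFlank constant flanking sequences.
#' @param variableLength randomized region length (bases).
#' @param rounds character labels of the selection rounds.
#' @return a list of class \code{LibraryDesign}.
#' @export
libraryDesign <- function(barcodes, leftFlank, rightFlank,
                          variableLength = 20L,
                          rounds = c("R1", "R2", "R3")) {
  stopifnot(!is.null(names(barcodes)), nchar(leftFlank) > 0,
            nchar(rightFlank) > 0, variableLength > 0)
  d <- list(barcodes = toupper(barcodes), leftFlank = toupper(leftFlank),
            rightFlank = toupper(rightFlank),
            variableLength = as.integer(variableLength), rounds = rounds)
  class(d) <- "LibraryDesign"
  d
}

#' @rdname libraryDesign
#' @param params a \code{SyntheticSelexParams} list.
#' @export
designFromParams <- function(params) {
  libraryDesign(params$barcodes, params$leftFlank, params$rightFlank,
                params$variableLength, params$rounds)
}

#' Demultiplex FASTQ reads by barcode prefix
#'
#' Assigns each read to the sample whose barcode matches the read prefix
#' with at most \code{maxBarcodeMismatch} substitutions. Reads matching no
#' barcode go to the unassigned tally; reads matching more than one
#' barcode under mismatches are dropped and counted as ambiguous.
#'
#' @param fastqPaths character vector of FASTQ(.gz) paths.
#' @param design a \code{LibraryDesign}.
#' @param maxBarcodeMismatch allowed substitutions (default 0, exact).
#' @return list: \code{reads} (named list of character vectors per
#'   sample), \code{counts} (assigned per sample, \code{unassigned},
#'   \code{ambiguous}).
#' @export
demultiplex <- function(fastqPaths, design, maxBarcodeMismatch = 0L) {
  stopifnot(inherits(design, "LibraryDesign"))
  reads <- unlist(lapply(fastqPaths, function(p)
    as.character(Biostrings::readDNAStringSet(p, format = "fastq"))),
    use.names = FALSE)
  dna <- Biostrings::DNAStringSet(reads)
  bc <- design$barcodes
  dist <- vapply(bc, function(b)
    Biostrings::neditStartingAt(Biostrings::DNAString(b), dna,
                                starting.at = 1L),
    integer(length(reads)))
  if (length(reads) == 1L) dist <- matrix(dist, nrow = 1L)
  hits <- dist <= maxBarcodeMismatch
  n_hits <- rowSums(hits)
  assigned <- lapply(seq_along(bc), function(j)
    reads[hits[, j] & n_hits == 1L])
  names(assigned) <- names(bc)
  counts <- c(vapply(assigned, length, integer(1)),
              unassigned = sum(n_hits == 0L),
              ambiguous = sum(n_hits > 1L))
  list(reads = assigned, counts = counts)
}

#' Extract the randomized variable region from demultiplexed reads
#'
#' Verifies the left flank directly after the barcode (at most
#' \code{maxFlankMismatch} substitutions), takes the next
#' \code{variableLength} bases, and verifies the right flank after them.
#' Reads failing any check, too short for the full layout, or yielding a
#' region containing non-ACGT bases are rejected and tallied; rejection
#' is a return state, not an error.
#'
#' @param reads character vector of reads from one sample (barcode still
#'   attached).
#' @param sample sample name (selects the barcode length).
#' @param design a \code{LibraryDesign}.
#' @param maxFlankMismatch allowed substitutions per flank (default 1).
#' @return list: \code{regions} (character vector of accepted
#'   variable-length regions) and \code{tallies} (accepted,
#'   rejected_short, rejected_left_flank, rejected_right_flank,
#'   rejected_alphabet).
#' @export
extractVariableRegion <- function(reads, sample, design,
                                  maxFlankMismatch = 1L) {
  stopifnot(inherits(design, "LibraryDesign"),
            sample %in% names(design$barcodes))
  bl <- nchar(design$barcodes[[sample]])
  fl <- nchar(design$leftFlank)
  fr <- nchar(design$rightFlank)
  vl <- design$variableLength
  need <- bl + fl + vl + fr
  tallies <- c(accepted = 0L, rejected_short = 0L, rejected_left_flank = 0L,
               rejected_right_flank = 0L, rejected_alphabet = 0L)
  long_enough <- nchar(reads) >= need
  tallies[["rejected_short"]] <- sum(!long_enough)
  reads <- reads[long_enough]
  if (!length(reads))
    return(list(regions = character(), tallies = tallies))
  dna <- Biostrings::DNAStringSet(reads)
  dl <- Biostrings::neditStartingAt(
    Biostrings::DNAString(design$leftFlank), dna, starting.at = bl + 1L)
  ok_left <- dl <= maxFlankMismatch
  tallies[["rejected_left_flank"]] <- sum(!ok_left)
  dr <- Biostrings::neditStartingAt(
    Biostrings::DNAString(design$rightFlank), dna,
    starting.at = bl + fl + vl + 1L)
  ok_right <- dr <= maxFlankMismatch
  tallies[["rejected_right_flank"]] <- sum(ok_left & !ok_right)
  keep <- ok_left & ok_right
  regions <- substr(reads[keep], bl + fl + 1L, bl + fl + vl)
  clean <- !grepl("[^ACGT]", regions)
  tallies[["rejected_alphabet"]] <- sum(!clean)
  regions <- regions[clean]
  tallies[["accepted"]] <- length(regions)
  list(regions = regions, tallies = tallies)
}

#' Count k-mers over variable regions with a sliding window
#'
#' Every region contributes \code{nchar - k + 1} windows at step 1. With
#' \code{countReverseComplement}, each window also increments its reverse
#' complement (off by default: the selection uses double-stranded DNA but
#' binding sequences are reported single-strandedly).
#'
#' @param regions character vector of ACGT regions.
#' @param k word length (default 6, the length of the identified binding
#'   sequence; sensible range 4-10).
#' @param countReverseComplement logical flag.
#' @param sample,round labels stored on the table.
#' @return a \linkS4class{KmerTable} covering all 4^k k-mers.
#' @export
countKmers <- function(regions, k = 6L, countReverseComplement = FALSE,
                       sample = "sample", round = "round") {
  stopifnot(k >= 1L)
  if (length(regions) && any(nchar(regions) < k))
    stop("k exceeds the length of some regions")
  if (!length(regions)) {
    kmers <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), k)
    counts <- stats::setNames(numeric(4^k), sort(kmers))
    return(new("KmerTable", sample = sample, round = round, k = as.integer(k),
               counts = counts, totalPositions = 0))
  }
  dna <- Biostrings::DNAStringSet(regions)
  counts <- Biostrings::oligonucleotideFrequency(
    dna, width = k, step = 1L, simplify.as = "collapse")
  if (countReverseComplement) {
    rc <- Biostrings::oligonucleotideFrequency(
      Biostrings::reverseComplement(dna), width = k, step = 1L,
      simplify.as = "collapse")
    counts <- counts + rc
  }
  counts <- stats::setNames(as.numeric(counts), names(counts))
  new("KmerTable", sample = sample, round = round, k = as.integer(k),
      counts = counts, totalPositions = sum(counts))
}

#' k-mer enrichment of a selected pool over the fusion-negative pool
#'
#' Per-k-mer frequencies (count / total windows) in the positive and
#' negative tables, stabilized by adding \code{pseudofrequency} to both,
#' and ranked by descending ratio with a stable lexicographic tie-break.
#' The pseudofrequency default is one window's worth of frequency in the
#' positive pool, \code{1 / totalPositions}.
#'
#' @param pos,neg \linkS4class{KmerTable}s with the same k.
#' @param pseudofrequency numeric added to both frequencies.
#' @return an \linkS4class{EnrichmentTable}.
#' @export
computeEnrichment <- function(pos, neg, pseudofrequency = NULL) {
  stopifnot(is(pos, "KmerTable"), is(neg, "KmerTable"))
  if (pos@k != neg@k) stop("positive and negative tables have different k")
  if (pos@totalPositions == 0) stop("positive table is empty")
  p <- pseudofrequency %||% (1 / pos@totalPositions)
  fp <- pos@counts / pos@totalPositions
  fn <- if (neg@totalPositions > 0) neg@counts / neg@totalPositions else
    neg@counts * 0
  enr <- (fp + p) / (fn + p)
  kmers <- names(pos@counts)
  ord <- order(-enr, kmers)
  tab <- data.frame(kmer = kmers[ord], freq_pos = unname(fp[ord]),
                    freq_neg = unname(fn[ord]), enrichment = unname(enr[ord]),
                    rank = seq_along(ord), stringsAsFactors = FALSE)
  new("EnrichmentTable", table = tab, k = pos@k, pseudofrequency = p)
}

#' Per-round enrichment trajectories
#'
#' Enrichment of every k-mer per round against the matched negative
#' round, with a flag for k-mers whose enrichment increases strictly
#' across all rounds.
#'
#' @param posTables,negTables lists of \linkS4class{KmerTable}, one per
#'   round, in round order (>= 2 rounds; same rounds in both).
#' @param pseudofrequency passed to \code{\link{computeEnrichment}}.
#' @return data frame: \code{kmer}, one \code{enrichment_<round>} column
#'   per round, \code{monotone}.
#' @export
roundTrajectory <- function(posTables, negTables, pseudofrequency = NULL) {
  if (length(posTables) < 2L) stop("need at least 2 rounds")
  if (length(posTables) != length(negTables))
    stop("missing round: positive and negative round lists differ in length")
  kmers <- names(posTables[[1L]]@counts)
  mat <- matrix(0, nrow = length(kmers), ncol = length(posTables))
  round_names <- character(length(posTables))
  for (r in seq_along(posTables)) {
    et <- computeEnrichment(posTables[[r]], negTables[[r]], pseudofrequency)
    tab <- et@table
    mat[, r] <- tab$enrichment[match(kmers, tab$kmer)]
    round_names[r] <- posTables[[r]]@round
  }
  monotone <- apply(mat, 1L, function(e) all(diff(e) > 0))
  out <- data.frame(kmer = kmers, mat, monotone = monotone,
                    stringsAsFactors = FALSE)
  names(out)[1L + seq_along(round_names)] <-
    paste0("enrichment_", round_names)
  rownames(out) <- NULL
  out
}

#' One-line top-motif summary of an enrichment table
#'
#' @param et an \linkS4class{EnrichmentTable}.
#' @return character scalar naming the top-ranked k-mer and its
#'   enrichment.
#' @export
topMotif <- function(et) {
  stopifnot(is(et, "EnrichmentTable"))
  sprintf("top %d-mer: %s (enrichment %.3f, pos freq %.2e, neg freq %.2e)",
          et@k, et@table$kmer[1L], et@table$enrichment[1L],
          et@table$freq_pos[1L], et@table$freq_neg[1L])
}
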