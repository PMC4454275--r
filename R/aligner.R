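# Internal alignment machinery: candidate-read filtering (k-mer and
# min-hash indexes), semi-global edit-distance alignment for short accurate
# reads, and seed-chain guide alignment with banded forward scoring for
# long noisy reads.  Coordinates are 0-based half-open on the forward
# strand of the target; reverse-strand hits store forward coordinates.

#' Build a k-mer candidate index over reads
#'
#' Maps every distinct canonical k-mer of every read to the read's id, for
#' retrieving the reads likely to align to a target sequence.
#'
#' @param reads [Biostrings::DNAStringSet] or character vector of reads.
#' @param k k-mer length (default 13).
#' @return A [ReadIndex-class] of type `"kmer"`.
#' @export
readKmerIndex <- function(reads, k = 13L) {
  reads <- as.character(reads)
  new("ReadIndex", ptr = cppBuildKmerIndex(reads, as.integer(k)),
      k = as.integer(k), type = "kmer", numHashes = 0L, seeds = integer())
}

#' Build a min-hash candidate index over reads
#'
#' For each read and each of `numHashes` independent hash functions, stores
#' the read id once under the minimum hash value of the read's canonical
#' k-mer set.  The collision probability of two k-mer sets under one
#' function equals their Jaccard similarity, so reads with small edit
#' distance to the target are retrieved with high probability while the
#' index stores each read only `numHashes` times.
#'
#' @param reads [Biostrings::DNAStringSet] or character vector of reads.
#' @param k k-mer length.
#' @param numHashes number of hash functions.
#' @param seed integer seed from which the per-function 64-bit xor masks are
#'   derived.
#' @return A [ReadIndex-class] of type `"minhash"`.
#' @export
readMinHashIndex <- function(reads, k = 13L, numHashes = 3L, seed = 1L) {
  reads <- as.character(reads)
  seeds <- as.integer(seed) * 1000L + seq_len(numHashes)
  new("ReadIndex", ptr = cppBuildMinHashIndex(reads, as.integer(k), seeds),
      k = as.integer(k), type = "minhash", numHashes = as.integer(numHashes),
      seeds = seeds)
}

#' Min-hash of a k-mer set
#'
#' The minimum hash value of a set of k-mers, for each hash function: each
#' k-mer is 2-bit packed, xor-ed with a per-function 64-bit mask derived
#' from the seed, and passed through the Murmur3 64-bit finalizer (values
#' are truncated to 53 bits so they are exact doubles).
#'
#' @param kmers character vector of equal-length k-mers (ACGT only, k <= 26).
#' @param seeds integer vector of hash-function seeds.
#' @return Numeric vector of min-hash values, one per seed.
#' @export
minHash <- function(kmers, seeds) {
  if (length(kmers) == 0L) stop("empty k-mer set")
  cppMinHashKmers(as.character(kmers), as.integer(seeds))
}

#' Canonical k-mer set of a sequence
#'
#' @param seq a sequence (character or DNAString); k-mers containing
#'   non-ACGT bases are skipped.
#' @param k k-mer length.
#' @param canonical collapse each k-mer with its reverse complement.
#' @return Character vector of distinct k-mers.
#' @export
kmerSet <- function(seq, k, canonical = TRUE) {
  res <- cppCountKmers(as.character(seq), as.integer(k), canonical)
  res$kmer
}

#' Candidate reads for a target sequence
#'
#' Retrieves the reads likely to align within the target: for a k-mer
#' index, all reads sharing at least one canonical k-mer with the target;
#' for a min-hash index, all reads whose min-hash under any function equals
#' the min-hash of some length-`readLength` substring of the target.
#'
#' @param target target sequence (character or DNAString).
#' @param index a [ReadIndex-class].
#' @param readLength substring length for min-hash queries (usually the
#'   read length); ignored for k-mer indexes.
#' @return Integer vector of read ids (1-based, sorted).
#' @export
candidateReads <- function(target, index, readLength = 0L) {
  target <- as.character(target)
  if (nchar(target) < index@k) return(integer())
  cppQueryIndex(index@ptr, target, as.integer(readLength))
}

# Order hits canonically (edit distance, position, strand) and keep at most
# maxHits per read.
.capHits <- function(hits, maxHits) {
  if (nrow(hits) == 0L || is.infinite(maxHits)) return(hits)
  o <- order(hits$read, hits$s, hits$start, hits$strand)
  hits <- hits[o, , drop = FALSE]
  keep <- stats::ave(seq_len(nrow(hits)), hits$read,
                     FUN = seq_along) <= maxHits
  hits[keep, , drop = FALSE]
}

# Shared backend: align a set of candidate reads against a target.
# mode "seeded" uses shared-13-mer seeding with windowed DP; "exhaustive"
# aligns every read over the full target.  Returns 0-based hits.
.scanReads <- function(target, readSeqs, readIds, maxEditFraction,
                       seedK = 13L, mode = c("seeded", "exhaustive")) {
  mode <- match.arg(mode)
  lens <- nchar(readSeqs)
  kmax <- as.integer(ceiling(maxEditFraction * lens))
  hits <- if (mode == "seeded")
    cppScanShort(target, readSeqs, kmax, as.integer(seedK))
  else
    cppScanExhaustive(target, readSeqs, kmax)
  data.frame(read = readIds[hits$idx], start = hits$start, end = hits$end,
             strand = hits$strand, s = hits$s, m = hits$m)
}

#' Align a short accurate read against a target sequence
#'
#' Semi-global alignment (whole read, local in the target) on both strands,
#' reporting all placements with edit distance at most
#' `ceil(maxEditFraction * length)`: qualifying alignment end positions are
#' grouped into maximal consecutive runs and the positions achieving each
#' run's minimum are kept, so distinct (including exactly tandem)
#' occurrences each yield a hit.  At most `maxHits` best hits are returned,
#' tie-broken by (edit distance, position, strand).
#'
#' @param read the read (character or DNAString).
#' @param target the target sequence.
#' @param maxEditFraction maximum edit distance as a fraction of read
#'   length.
#' @param maxHits cap on reported hits (`Inf` for all).
#' @param seedK seeding k-mer length; alignment windows are restricted to
#'   diagonals sharing a seed.  Set `exhaustive = TRUE` to scan every
#'   placement instead (required when reads are shorter than `seedK`).
#' @param exhaustive disable seeding.
#' @return data.frame with columns `read`, `start`, `end` (0-based
#'   half-open), `strand` (+1/-1), `s` (errors), `m` (matches).
#' @export
alignShortRead <- function(read, target, maxEditFraction = 0.1,
                           maxHits = 10L, seedK = 13L, exhaustive = FALSE) {
  read <- as.character(read)
  target <- as.character(target)
  if (nchar(read) == 0L || nchar(target) == 0L)
    stop("read and target must be nonempty")
  mode <- if (exhaustive || nchar(read) < seedK) "exhaustive" else "seeded"
  hits <- .scanReads(target, read, 1L, maxEditFraction, seedK, mode)
  .capHits(hits, maxHits)
}

#' Banded forward probability mass around a guide alignment
#'
#' Sums the alignment weights \eqn{R(s,m) = \epsilon^s(1-\epsilon)^m} over
#' all alignment paths within `band` diagonals of a guide alignment path --
#' the banded forward algorithm used to score long noisy reads, where many
#' near-optimal alignments contribute materially to the read probability.
#' With `band = 0` the mass equals exactly the guide path's own
#' \eqn{R(s,m)}; the mass is nondecreasing in the band width.
#'
#' @param read the read.
#' @param target the target sequence.
#' @param guide two-column integer matrix of guide path cells
#'   `(readPrefix, targetPrefix)`, monotone from `(0, j0)` to
#'   `(length(read), j1)` (as produced by [longReadGuide()]).
#' @param band band half-width in diagonals (default 3).
#' @param errorRate per-base error rate \eqn{\epsilon}.
#' @return Log of the summed probability mass.
#' @export
bandedForward <- function(read, target, guide, band = 3L, errorRate) {
  read <- as.character(read)
  target <- as.character(target)
  guide <- as.matrix(guide)
  cppBandedForwardPath(read, target, as.integer(guide[, 1L]),
                       as.integer(guide[, 2L]), as.integer(band),
                       as.numeric(errorRate))
}

#' Guide alignment of a long read by seed-and-extend
#'
#' Finds exact `seedK`-mer matches between read and target, clusters them
#' by diagonal, and computes a corridor-banded edit-distance alignment for
#' each cluster; the traceback path is the guide around which
#' [bandedForward()] sums near-optimal alignments.
#'
#' @param read the long read.
#' @param target the target sequence.
#' @param seedK seed k-mer length (default 11).
#' @param maxEditFraction maximum edit fraction for a reportable guide.
#' @param band band half-width used when also computing the forward mass.
#' @param errorRate error rate for the forward mass.
#' @param minSeeds minimum seeds per cluster.
#' @return data.frame with one row per guide: `start`, `end`, `strand`,
#'   `s`, `m`, `logmass`.
#' @export
longReadGuide <- function(read, target, seedK = 11L, maxEditFraction = 0.35,
                          band = 3L, errorRate = 0.15, minSeeds = 3L) {
  h <- cppScanLong(as.character(target), as.character(read),
                   as.integer(seedK), maxEditFraction, as.integer(band),
                   errorRate, as.integer(minSeeds))
  data.frame(start = h$start, end = h$end, strand = h$strand, s = h$s,
             m = h$m, logmass = h$logmass)
}

#' Contig/long-read overlap candidates
#'
#' Reports which (contig, read) pairs share a seed-supported overlap:
#' contigs of at least `minContig` bases are matched against each long read
#' by exact `seedK`-mer seeds, and a pair is reported when a diagonal
#' cluster of at least `minSeeds` seeds spans at least `minSpan` bases.
#' Used to restrict which long reads are rescored when a region of the
#' assembly changes.
#'
#' @param contigs [Biostrings::DNAStringSet] of contigs.
#' @param longReads [Biostrings::DNAStringSet] of long reads.
#' @param minContig minimum contig length considered (default 100).
#' @param seedK seed k-mer length.
#' @param minSeeds minimum seeds in a cluster.
#' @param minSpan minimum read span of the cluster in bases (about the
#'   minimum usable overlap).
#' @return data.frame with columns `contig`, `read` (1-based ids).
#' @export
longReadCandidates <- function(contigs, longReads, minContig = 100L,
                               seedK = 11L, minSeeds = 3L, minSpan = 80L) {
  keep <- which(nchar(as.character(contigs)) >= minContig)
  if (!length(keep))
    return(data.frame(contig = integer(), read = integer()))
  pairs <- cppSeedOverlapPairs(as.character(contigs)[keep],
                               as.character(longReads), as.integer(seedK),
                               as.integer(minSeeds), as.integer(minSpan))
  data.frame(contig = keep[pairs$contig], read = pairs$read)
}
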