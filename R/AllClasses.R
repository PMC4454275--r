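#' @import methods
#' @importFrom Rcpp sourceCpp
#' @importClassesFrom Biostrings DNAStringSet
#' @importFrom stats runif rnorm rlnorm dnorm median setNames ave
#' @importFrom utils write.table adist head
#' @useDynLib lapasm, .registration = TRUE
NULL

#' Per-dataset model parameters
#'
#' Holds the probabilistic model parameters of one sequencing dataset: the
#' per-base error rate \eqn{\epsilon} used in the alignment weight
#' \eqn{R(s,m) = \epsilon^s (1-\epsilon)^m}, the normal insert-size model
#' \eqn{(\mu, \sigma)} for paired sets, the dataset weight \eqn{w} in the
#' combined score, the no-alignment floor constants \eqn{c} and \eqn{k}
#' (floor \eqn{e^{c + k\ell}} for a read of length \eqn{\ell}), and the
#' connectivity-penalty constants (window \eqn{k} and per-base \eqn{\alpha}).
#'
#' @slot errorRate per-base sequencing error rate \eqn{\epsilon}, in [0, 1).
#' @slot insertMean insert-size mean \eqn{\mu} in bases (paired sets; `NA`
#'   otherwise).
#' @slot insertSd insert-size standard deviation \eqn{\sigma} (paired sets).
#' @slot weight nonnegative dataset weight in the combined LAP.
#' @slot noalignOffset floor constant \eqn{c} (log space).
#' @slot noalignScale floor constant \eqn{k} (log space, per base; negative
#'   so longer reads get lower floors).
#' @slot connWindow connectivity window: a base \eqn{j} is connected if some
#'   read (or pair span) covers it and starts at least this many bases
#'   before it.
#' @slot penaltyAlpha per-disconnected-base penalty \eqn{\alpha}.
#' @slot orientation expected relative strand of mates: `"fr"`
#'   (forward-reverse, fragment libraries) or `"rf"` (reverse-forward,
#'   jumping libraries).
#' @exportClass ModelParams
setClass("ModelParams", representation(
  errorRate = "numeric",
  insertMean = "numeric",
  insertSd = "numeric",
  weight = "numeric",
  noalignOffset = "numeric",
  noalignScale = "numeric",
  connWindow = "integer",
  penaltyAlpha = "numeric",
  orientation = "character"
))

setValidity("ModelParams", function(object) {
  msg <- character()
  if (object@errorRate < 0 || object@errorRate >= 1)
    msg <- c(msg, "errorRate must be in [0, 1)")
  if (!is.na(object@insertSd) && object@insertSd <= 0)
    msg <- c(msg, "insertSd must be positive")
  if (object@weight < 0) msg <- c(msg, "weight must be nonnegative")
  if (object@penaltyAlpha < 0) msg <- c(msg, "penaltyAlpha must be nonnegative")
  if (!is.na(object@connWindow) && object@connWindow < 1L)
    msg <- c(msg, "connWindow must be >= 1")
  if (!object@orientation %in% c("fr", "rf"))
    msg <- c(msg, "orientation must be 'fr' or 'rf'")
  if (length(msg)) msg else TRUE
})

#' Construct model parameters for a read set
#'
#' @param errorRate per-base error rate \eqn{\epsilon}.
#' @param insertMean,insertSd insert-size model (paired sets only).
#' @param weight dataset weight in the combined LAP (see [combinedLap()]).
#' @param noalignOffset,noalignScale no-alignment floor constants \eqn{c}
#'   and \eqn{k}: reads without a good alignment score
#'   \eqn{e^{c+k\ell}} instead of their (near-zero) probability.
#' @param connWindow connectivity window in bases; `NA` lets the pipeline
#'   derive it from the read length (read length for paired sets, half the
#'   read length for single-end and long-read sets).
#' @param penaltyAlpha per-disconnected-base penalty \eqn{\alpha}.
#' @param orientation `"fr"` or `"rf"`.
#' @return A [ModelParams-class] object.
#' @export
ModelParams <- function(errorRate = 0.01, insertMean = NA_real_,
                        insertSd = NA_real_, weight = 1,
                        noalignOffset = -15, noalignScale = -0.2,
                        connWindow = NA_integer_, penaltyAlpha = 3,
                        orientation = "fr") {
  new("ModelParams", errorRate = as.numeric(errorRate),
      insertMean = as.numeric(insertMean), insertSd = as.numeric(insertSd),
      weight = as.numeric(weight), noalignOffset = as.numeric(noalignOffset),
      noalignScale = as.numeric(noalignScale),
      connWindow = as.integer(connWindow),
      penaltyAlpha = as.numeric(penaltyAlpha), orientation = orientation)
}

#' A read set with its model parameters
#'
#' A collection of reads (plus mate reads if paired) and the
#' [ModelParams-class] describing how the set is scored.  The technology
#' class selects the alignment backend: `"short"` (accurate reads, seeded
#' edit-distance alignment) or `"long"` (noisy reads, seed-chain guide
#' alignment scored by a banded forward algorithm).
#'
#' @slot name dataset label.
#' @slot reads a [Biostrings::DNAStringSet] of reads (first mates if paired).
#' @slot mates second mates (empty set if unpaired).
#' @slot paired logical flag.
#' @slot technology `"short"` or `"long"`.
#' @slot params a [ModelParams-class].
#' @exportClass ReadSet
setClass("ReadSet", representation(
  name = "character",
  reads = "DNAStringSet",
  mates = "DNAStringSet",
  paired = "logical",
  technology = "character",
  params = "ModelParams"
))

setValidity("ReadSet", function(object) {
  msg <- character()
  if (object@paired && length(object@mates) != length(object@reads))
    msg <- c(msg, "paired set must have one mate per read")
  if (!object@paired && length(object@mates) != 0L)
    msg <- c(msg, "unpaired set must not carry mates")
  if (length(object@reads) > 0L && min(Biostrings::width(object@reads)) < 1L)
    msg <- c(msg, "read lengths must be >= 1")
  if (object@paired && length(object@mates) > 0L &&
      min(Biostrings::width(object@mates)) < 1L)
    msg <- c(msg, "mate lengths must be >= 1")
  if (!object@technology %in% c("short", "long"))
    msg <- c(msg, "technology must be 'short' or 'long'")
  if (object@paired && (is.na(object@params@insertMean) ||
                        is.na(object@params@insertSd)))
    msg <- c(msg, "paired set requires insertMean and insertSd")
  if (length(msg)) msg else TRUE
})

#' Construct a read set
#'
#' @param reads a [Biostrings::DNAStringSet] (or character vector) of reads.
#' @param mates second mates for paired sets, `NULL` otherwise.
#' @param params a [ModelParams-class] object.
#' @param technology `"short"` or `"long"`.
#' @param name dataset label.
#' @return A [ReadSet-class].
#' @export
ReadSet <- function(reads, mates = NULL, params = ModelParams(),
                    technology = "short", name = "reads") {
  if (!methods::is(reads, "DNAStringSet")) reads <- Biostrings::DNAStringSet(reads)
  paired <- !is.null(mates)
  if (paired && !methods::is(mates, "DNAStringSet"))
    mates <- Biostrings::DNAStringSet(mates)
  if (!paired) mates <- Biostrings::DNAStringSet()
  new("ReadSet", name = name, reads = reads, mates = mates, paired = paired,
      technology = technology, params = params)
}

setMethod("show", "ReadSet", function(object) {
  cat("ReadSet '", object@name, "': ", length(object@reads),
      if (object@paired) " pairs" else " reads",
      ", technology ", object@technology,
      ", eps ", object@params@errorRate, sep = "")
  if (object@paired)
    cat(", insert ", object@params@insertMean, "+/-",
        object@params@insertSd, sep = "")
  cat("\n")
})

#' Number of reads (or read pairs) in a set
#' @param x a [ReadSet-class].
#' @export
setMethod("length", "ReadSet", function(x) length(x@reads))

#' Conservative assembly graph
#'
#' Contig nodes produced by unambiguous concatenation of de Bruijn k-mers,
#' with directed overlap edges.  Each contig is stored once on an arbitrary
#' representative strand; an oriented contig is a (node, strand) pair and
#' edges connect oriented contigs whose sequences overlap by exactly
#' \eqn{k-1} bases.  The edge table contains both mirror images of each
#' physical adjacency, so `edges` restricted to a (from, fromStrand) pair
#' lists all extensions of that oriented contig.
#'
#' @slot contigs a [Biostrings::DNAStringSet] of contig sequences.
#' @slot edges data.frame with columns `from`, `fromStrand`, `to`,
#'   `toStrand` (strands +1/-1).
#' @slot k k-mer size used in construction.
#' @slot coverage mean k-mer coverage per contig.
#' @exportClass AssemblyGraph
setClass("AssemblyGraph", representation(
  contigs = "DNAStringSet",
  edges = "data.frame",
  k = "integer",
  coverage = "numeric"
))

setValidity("AssemblyGraph", function(object) {
  msg <- character()
  e <- object@edges
  need <- c("from", "fromStrand", "to", "toStrand")
  if (!all(need %in% names(e))) {
    msg <- c(msg, "edges must have columns from, fromStrand, to, toStrand")
  } else if (nrow(e) > 0L) {
    if (any(e$from < 1L | e$from > length(object@contigs)) ||
        any(e$to < 1L | e$to > length(object@contigs)))
      msg <- c(msg, "edge endpoints out of range")
    if (!all(abs(e$fromStrand) == 1L) || !all(abs(e$toStrand) == 1L))
      msg <- c(msg, "strands must be +1/-1")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "AssemblyGraph", function(object) {
  w <- Biostrings::width(object@contigs)
  cat("AssemblyGraph: ", length(object@contigs), " contigs (",
      sum(w), " bp, longest ", if (length(w)) max(w) else 0, "), ",
      nrow(object@edges), " oriented edges, k = ", object@k, "\n", sep = "")
})

#' Contig sequences of an assembly graph
#' @param graph an [AssemblyGraph-class].
#' @return A [Biostrings::DNAStringSet].
#' @export
contigSeqs <- function(graph) graph@contigs

#' Edge table of an assembly graph
#' @param graph an [AssemblyGraph-class].
#' @return data.frame with columns from, fromStrand, to, toStrand.
#' @export
edgeTable <- function(graph) graph@edges

#' A walk through the assembly graph
#'
#' An ordered, oriented traversal of contig nodes, optionally containing
#' N-gap segments.  Steps are parallel vectors: `nodes[i]` is a contig id or
#' `NA` for a gap step, `strands[i]` is +1/-1 (`NA` for gaps), `gapLens[i]`
#' is the gap length (`NA` for contig steps).
#'
#' @slot nodes integer vector of contig ids (`NA` = gap).
#' @slot strands integer vector of orientations.
#' @slot gapLens integer vector of gap lengths.
#' @exportClass Walk
setClass("Walk", representation(
  nodes = "integer", strands = "integer", gapLens = "integer"
))

setValidity("Walk", function(object) {
  msg <- character()
  n <- length(object@nodes)
  if (length(object@strands) != n || length(object@gapLens) != n)
    msg <- c(msg, "nodes, strands, gapLens must have equal length")
  if (n == 0L) msg <- c(msg, "walk must have at least one step")
  gap <- is.na(object@nodes)
  if (any(!gap & is.na(object@strands)))
    msg <- c(msg, "contig steps need a strand")
  if (any(gap & (is.na(object@gapLens) | object@gapLens < 1L)))
    msg <- c(msg, "gap steps need a positive length")
  if (any(gap[c(1L, n)])) msg <- c(msg, "walk cannot start or end with a gap")
  if (n > 1L && any(gap[-1L] & gap[-n]))
    msg <- c(msg, "adjacent gap steps must be merged")
  if (length(msg)) msg else TRUE
})

#' Construct a walk
#'
#' @param nodes contig ids (`NA` for an N-gap step).
#' @param strands orientations (+1/-1), `NA` on gap steps.
#' @param gapLens gap lengths, `NA` on contig steps.
#' @return A [Walk-class].
#' @export
Walk <- function(nodes, strands = rep(1L, length(nodes)), gapLens = NULL) {
  nodes <- as.integer(nodes)
  strands <- as.integer(strands)
  strands[is.na(nodes)] <- NA_integer_
  if (is.null(gapLens)) gapLens <- rep(NA_integer_, length(nodes))
  new("Walk", nodes = nodes, strands = strands, gapLens = as.integer(gapLens))
}

setMethod("show", "Walk", function(object) {
  lab <- ifelse(is.na(object@nodes),
                paste0("N", object@gapLens),
                paste0(object@nodes, ifelse(object@strands == 1L, "+", "-")))
  cat("Walk:", paste(lab, collapse = " -> "), "\n")
})

#' An assembly: a set of walks
#'
#' The state evolved by the annealer.  Walk list names, when present, are
#' the cache ids of the walks.
#'
#' @slot walks list of [Walk-class] objects.
#' @exportClass Assembly
setClass("Assembly", representation(walks = "list"))

setValidity("Assembly", function(object) {
  if (!all(vapply(object@walks, methods::is, logical(1), class2 = "Walk")))
    return("walks must all be Walk objects")
  TRUE
})

#' Construct an assembly from walks
#' @param walks list of [Walk-class] objects.
#' @return An [Assembly-class].
#' @export
Assembly <- function(walks) new("Assembly", walks = walks)

#' Walks of an assembly
#' @param assembly an [Assembly-class].
#' @export
walks <- function(assembly) assembly@walks

setMethod("show", "Assembly", function(object) {
  cat("Assembly of", length(object@walks), "walk(s)\n")
  for (w in object@walks) show(w)
})

#' LAP score breakdown
#'
#' The combined assembly score and its per-dataset components: the log
#' average probability LAP(A|R_i) of each read set, the disconnected-base
#' counts and penalties, the dataset weights, and the weighted penalized
#' total.
#'
#' @slot setNames dataset labels.
#' @slot perSetLap unpenalized LAP(A|R_i), natural log.
#' @slot disconnected disconnected-base count d_i per set.
#' @slot penalty alpha_i * d_i per set.
#' @slot weights dataset weights w_i.
#' @slot total sum_i w_i * (LAP_i - alpha_i d_i).
#' @exportClass LapBreakdown
setClass("LapBreakdown", representation(
  setNames = "character", perSetLap = "numeric", disconnected = "integer",
  penalty = "numeric", weights = "numeric", total = "numeric"
))

setMethod("show", "LapBreakdown", function(object) {
  for (i in seq_along(object@perSetLap)) {
    cat(sprintf("  %-12s LAP %8.2f  disconnected %6d  penalty %10.2f  weight %g\n",
                object@setNames[i], object@perSetLap[i],
                object@disconnected[i], object@penalty[i], object@weights[i]))
  }
  cat(sprintf("  total %.2f\n", object@total))
})

#' Total combined score of a breakdown
#' @param x a [LapBreakdown-class].
#' @export
lapTotal <- function(x) x@total

#' Per-set unpenalized LAP values
#' @param x a [LapBreakdown-class].
#' @export
lapPerSet <- function(x) stats::setNames(x@perSetLap, x@setNames)

#' Assembly summary statistics
#'
#' @slot scaffoldCount number of scaffolds.
#' @slot longest longest scaffold length.
#' @slot n50 N50 length (see [computeStats()] for the basis).
#' @slot totalLength summed scaffold length.
#' @slot nGapTotal total number of N bases.
#' @slot basis `"truth"` when N50 used a supplied genome size, else
#'   `"assembly"`.
#' @exportClass AssemblyStats
setClass("AssemblyStats", representation(
  scaffoldCount = "integer", longest = "integer", n50 = "integer",
  totalLength = "integer", nGapTotal = "integer", basis = "character"
))

setMethod("show", "AssemblyStats", function(object) {
  cat(sprintf(
    "AssemblyStats: %d scaffold(s), longest %d, N50 %d (%s basis), total %d, N bases %d\n",
    object@scaffoldCount, object@longest, object@n50, object@basis,
    object@totalLength, object@nGapTotal))
})

#' Candidate-read index over a read set
#'
#' Either a plain k-mer index (every read listed under each of its distinct
#' canonical k-mers) or a min-hash index (each read listed once per hash
#' function, under its min-hash value).
#'
#' @slot ptr external pointer to the native index.
#' @slot k k-mer length.
#' @slot type `"kmer"` or `"minhash"`.
#' @slot numHashes number of hash functions (min-hash only).
#' @slot seeds integer seeds of the hash functions (min-hash only).
#' @exportClass ReadIndex
setClass("ReadIndex", representation(
  ptr = "externalptr", k = "integer", type = "character",
  numHashes = "integer", seeds = "integer"
))

setMethod("show", "ReadIndex", function(object) {
  cat("ReadIndex (", object@type, "), k = ", object@k, sep = "")
  if (object@type == "minhash") cat(", ", object@numHashes, " hash functions",
                                    sep = "")
  cat("\n")
})
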