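# Synthetic data generator: random genomes with planted repeat families and
# read sets matching each technology model (paired/single short accurate
# reads, long noisy reads), so every stage of the pipeline can be exercised
# end to end with no external data.

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.randomBases <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.mutateSubstitutions <- function(seq, rate) {
  ch <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(ch)) < rate)
  for (i in hit) {
    ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
  }
  paste(ch, collapse = "")
}

#' Generate a random genome with planted repeats
#'
#' Produces a uniform-random sequence and overwrites it with copies of
#' random repeat units at the requested (or randomly chosen,
#' non-overlapping) placements, each copy diverged from the unit by the
#' given per-base substitution rate.  The truth annotation of the planted
#' copies is returned as a [GenomicRanges::GRanges].
#'
#' @param length genome length in bases.
#' @param repeats `NULL`, or a list of repeat-family specs, each a list with
#'   `length` (unit length), `copies`, `divergence` (per-base substitution
#'   rate in [0, 1)), and optionally `positions` (0-based start of each
#'   copy).
#' @param seed RNG seed; identical seeds reproduce identical output.
#' @return list with `genome` (a [Biostrings::DNAString]) and `repeats`
#'   (GRanges with metadata columns `family` and `copy`).
#' @export
randomGenome <- function(length, repeats = NULL, seed = 1L) {
  withSeed(seed, {
    genome <- strsplit(.randomBases(length), "")[[1]]
    ann <- list()
    for (fi in seq_along(repeats)) {
      spec <- repeats[[fi]]
      ulen <- spec$length
      copies <- spec$copies
      div <- if (is.null(spec$divergence)) 0 else spec$divergence
      if (div < 0 || div >= 1) stop("divergence must be in [0, 1)")
      unit <- .randomBases(ulen)
      pos <- spec$positions
      if (is.null(pos)) {
        # random non-overlapping placements with a margin between copies
        margin <- 200L
        for (tries in 1:200) {
          pos <- sort(sample.int(length - ulen, copies))
          if (copies == 1L || all(diff(pos) >= ulen + margin)) break
          pos <- NULL
        }
        if (is.null(pos)) stop("could not place repeat copies")
      }
      if (any(pos < 0L | pos + ulen > length))
        stop("repeat placement out of genome bounds")
      for (ci in seq_len(copies)) {
        copy <- if (div > 0) .mutateSubstitutions(unit, div) else unit
        genome[(pos[ci] + 1L):(pos[ci] + ulen)] <- strsplit(copy, "")[[1]]
        ann[[base::length(ann) + 1L]] <- data.frame(
          start = pos[ci], end = pos[ci] + ulen, family = fi, copy = ci)
      }
    }
    anndf <- if (base::length(ann)) do.call(rbind, ann)
             else data.frame(start = integer(), end = integer(),
                             family = integer(), copy = integer())
    gr <- GenomicRanges::GRanges(
      seqnames = rep("genome", nrow(anndf)),
      ranges = IRanges::IRanges(start = anndf$start + 1L, end = anndf$end),
      family = anndf$family, copy = anndf$copy)
    list(genome = Biostrings::DNAString(paste(genome, collapse = "")),
         repeats = gr)
  })
}

# Apply the per-base error model to one read: substitutions only for the
# short-accurate model; for long reads 1/3 substitutions, 1/3 insertions,
# 1/3 deletions.
.applyErrors <- function(seq, errorRate, indels = FALSE) {
  if (errorRate == 0) return(seq)
  ch <- strsplit(seq, "")[[1]]
  out <- character(0)
  bases <- c("A", "C", "G", "T")
  for (i in seq_along(ch)) {
    if (stats::runif(1) < errorRate) {
      kind <- if (indels) sample(c("sub", "ins", "del"), 1L) else "sub"
      if (kind == "sub") {
        out <- c(out, sample(setdiff(bases, ch[i]), 1L))
      } else if (kind == "ins") {
        out <- c(out, sample(bases, 1L), ch[i])
      } # del: emit nothing
    } else {
      out <- c(out, ch[i])
    }
  }
  paste(out, collapse = "")
}

.rcChar <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Simulate a read set from a genome
#'
#' Draws reads uniformly from both strands with per-base errors at rate
#' `errorRate`.  Paired sets sample insert lengths from
#' `Normal(insertMean, insertSd)` and emit mates in the requested
#' orientation (`"fr"`: mates face inward; `"rf"`: outward, as in jumping
#' libraries).  Long-read sets draw lengths from a log-normal with the
#' given median and apply an error model with 1/3 substitutions and 2/3
#' indels.  Short-accurate reads receive substitution errors only.
#'
#' @param genome [Biostrings::DNAString] (or character) truth sequence.
#' @param technology `"short"` or `"long"`.
#' @param coverage mean sequencing depth.
#' @param readLength read length (short sets).
#' @param errorRate per-base error rate.
#' @param paired emit mate pairs (short sets only).
#' @param insertMean,insertSd insert-length model (paired).
#' @param orientation `"fr"` or `"rf"`.
#' @param longReadMedian median long-read length.
#' @param longReadSdlog log-normal sdlog of long-read lengths.
#' @param weight dataset weight for the combined LAP.
#' @param connWindow connectivity window override (`NA` = derived).
#' @param name dataset label.
#' @param seed RNG seed.
#' @return A [ReadSet-class] with populated [ModelParams-class].
#' @export
simulateReads <- function(genome, technology = c("short", "long"),
                          coverage = 40, readLength = 100L,
                          errorRate = 0.01, paired = FALSE,
                          insertMean = NA, insertSd = NA,
                          orientation = "fr", longReadMedian = 2000L,
                          longReadSdlog = 0.25, weight = 1,
                          connWindow = NA_integer_, name = "sim",
                          seed = 1L) {
  technology <- match.arg(technology)
  genome <- as.character(genome)
  L <- nchar(genome)
  withSeed(seed, {
    if (technology == "long") {
      nreads <- max(1L, round(coverage * L / longReadMedian))
      lens <- pmax(200L, round(stats::rlnorm(nreads,
                                             meanlog = log(longReadMedian),
                                             sdlog = longReadSdlog)))
      lens <- pmin(lens, L)
      starts <- vapply(lens, function(l) sample.int(L - l + 1L, 1L), integer(1))
      strands <- sample(c(1L, -1L), nreads, replace = TRUE)
      seqs <- character(nreads)
      for (i in seq_len(nreads)) {
        raw <- substr(genome, starts[i], starts[i] + lens[i] - 1L)
        if (strands[i] == -1L) raw <- .rcChar(raw)
        seqs[i] <- .applyErrors(raw, errorRate, indels = TRUE)
      }
      params <- ModelParams(errorRate = errorRate, weight = weight,
                            connWindow = connWindow)
      rs <- ReadSet(Biostrings::DNAStringSet(stats::setNames(
        seqs, paste0(name, "_", seq_len(nreads)))),
        params = params, technology = "long", name = name)
      return(rs)
    }
    if (paired) {
      if (is.na(insertMean) || is.na(insertSd))
        stop("paired simulation requires insertMean and insertSd")
      if (L <= insertMean + 6 * insertSd)
        stop("genome too short for the requested insert distribution")
      npairs <- max(1L, round(coverage * L / (2 * readLength)))
      r1 <- character(npairs); r2 <- character(npairs)
      for (i in seq_len(npairs)) {
        D <- max(2L * readLength,
                 round(stats::rnorm(1, insertMean, insertSd)))
        D <- min(D, L)
        f <- sample.int(L - D + 1L, 1L) # fragment [f, f+D) 1-based start f
        left <- substr(genome, f, f + readLength - 1L)
        rightRc <- .rcChar(substr(genome, f + D - readLength, f + D - 1L))
        if (orientation == "fr") { a <- left; b <- rightRc }
        else { a <- .rcChar(left); b <- .rcChar(rightRc) }
        # the physical strand sequenced first is random: swap mates
        if (stats::runif(1) < 0.5) { tmp <- a; a <- b; b <- tmp }
        r1[i] <- .applyErrors(a, errorRate)
        r2[i] <- .applyErrors(b, errorRate)
      }
      params <- ModelParams(errorRate = errorRate, insertMean = insertMean,
                            insertSd = insertSd, weight = weight,
                            connWindow = connWindow,
                            orientation = orientation)
      nm <- paste0(name, "_", seq_len(npairs))
      return(ReadSet(Biostrings::DNAStringSet(stats::setNames(r1, nm)),
                     mates = Biostrings::DNAStringSet(stats::setNames(r2, nm)),
                     params = params, technology = "short", name = name))
    }
    nreads <- max(1L, round(coverage * L / readLength))
    starts <- sample.int(L - readLength + 1L, nreads, replace = TRUE)
    strands <- sample(c(1L, -1L), nreads, replace = TRUE)
    seqs <- character(nreads)
    for (i in seq_len(nreads)) {
      raw <- substr(genome, starts[i], starts[i] + readLength - 1L)
      if (strands[i] == -1L) raw <- .rcChar(raw)
      seqs[i] <- .applyErrors(raw, errorRate)
    }
    params <- ModelParams(errorRate = errorRate, weight = weight,
                          connWindow = connWindow)
    ReadSet(Biostrings::DNAStringSet(stats::setNames(
      seqs, paste0(name, "_", seq_len(nreads)))),
      params = params, technology = "short", name = name)
  })
}
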