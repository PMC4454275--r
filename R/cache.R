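# Incremental likelihood evaluation.  Walks are partitioned into
# overlapping windows; alignments to interiors of contigs are cached per
# contig and reused, and only window spans around junctions (the masked
# realign spans) are realigned when a walk appears.  Per-walk hit tables,
# per-unit (read or pair) probability contributions, and per-walk
# disconnected-base counts recombine into the total score without double
# counting, so that the incremental total equals a full recomputation.

#' Evaluation configuration
#'
#' Tunables of the alignment and scoring machinery shared by the full and
#' incremental evaluation paths.
#'
#' @param seedK seeding k-mer length for short-read alignment (default 13).
#' @param maxEditFraction maximum edit distance of a short-read hit as a
#'   fraction of read length.
#' @param maxHits best alignments kept per read and walk.
#' @param longThreshold contigs longer than this are "long" (bp).
#' @param filter candidate filter for short sets: `"kmer"` or `"minhash"`.
#' @param numHashes hash functions for the min-hash filter.
#' @param indexSeed seed for the min-hash functions.
#' @param longSeedK seed length for long-read guide alignment.
#' @param longMaxEditFraction maximum edit fraction for long-read guides.
#' @param band band half-width (diagonals) of the banded forward algorithm.
#' @param minSeeds minimum seeds per long-read cluster.
#' @param paranoid force full recomputation at every evaluation (debugging).
#' @return list of settings.
#' @export
lapConfig <- function(seedK = 13L, maxEditFraction = 0.1, maxHits = 10L,
                      longThreshold = 500L, filter = "kmer",
                      numHashes = 3L, indexSeed = 1L, longSeedK = 11L,
                      longMaxEditFraction = 0.35, band = 3L, minSeeds = 3L,
                      paranoid = FALSE) {
  list(seedK = as.integer(seedK), maxEditFraction = maxEditFraction,
       maxHits = maxHits, longThreshold = as.integer(longThreshold),
       filter = filter, numHashes = as.integer(numHashes),
       indexSeed = as.integer(indexSeed), longSeedK = as.integer(longSeedK),
       longMaxEditFraction = longMaxEditFraction, band = as.integer(band),
       minSeeds = as.integer(minSeeds), paranoid = isTRUE(paranoid))
}

# Derived per-set constants: read strings, lengths, floors, connectivity
# window, effective longest-read length (read length plus edit budget, so
# indel-extended alignments stay inside windows and margins).
.setMeta <- function(rs, cfg) {
  params <- rs@params
  if (rs@technology == "long") {
    lens <- Biostrings::width(rs@reads)
    if (is.na(params@connWindow))
      params@connWindow <- as.integer(max(1, floor(stats::median(lens) / 2)))
    return(list(tech = "long", reads = as.character(rs@reads),
                lens = lens, nUnits = length(rs@reads), params = params,
                floors = exp(params@noalignOffset +
                             params@noalignScale * lens),
                unitLens = lens))
  }
  paired <- rs@paired
  readsAll <- c(as.character(rs@reads), as.character(rs@mates))
  lens <- nchar(readsAll)
  maxLen <- max(lens)
  if (is.na(params@connWindow))
    params@connWindow <- as.integer(if (paired) maxLen
                                    else max(1, floor(maxLen / 2)))
  nUnits <- length(rs@reads)
  unitLens <- if (paired) lens[seq_len(nUnits)] + lens[nUnits + seq_len(nUnits)]
              else lens
  kmaxv <- as.integer(ceiling(cfg$maxEditFraction * lens))
  list(tech = "short", paired = paired, reads = readsAll, lens = lens,
       kmax = kmaxv, nReads1 = nUnits, nUnits = nUnits, params = params,
       effLr = maxLen + max(kmaxv) + 4L,
       exhaustive = maxLen < 2L * cfg$seedK,
       floors = exp(params@noalignOffset + params@noalignScale * unitLens),
       unitLens = unitLens)
}

#' Create a likelihood cache
#'
#' Builds the per-set candidate indexes and empty per-contig and per-walk
#' alignment stores over which assemblies are scored incrementally.
#'
#' @param graph an [AssemblyGraph-class].
#' @param readsets list of [ReadSet-class] objects.
#' @param config a [lapConfig()] list.
#' @return An environment (the mutable cache).
#' @export
newLikelihoodCache <- function(graph, readsets, config = lapConfig()) {
  cache <- new.env(parent = emptyenv())
  cache$graph <- graph
  cache$readsets <- readsets
  cache$cfg <- config
  cache$meta <- lapply(readsets, .setMeta, cfg = config)
  cache$indexes <- lapply(seq_along(readsets), function(i) {
    mt <- cache$meta[[i]]
    if (mt$tech == "long" || mt$exhaustive) return(NULL)
    if (config$filter == "minhash")
      readMinHashIndex(mt$reads, k = config$seedK,
                       numHashes = config$numHashes,
                       seed = config$indexSeed)
    else readKmerIndex(mt$reads, k = config$seedK)
  })
  cache$ctgStr <- as.character(graph@contigs)
  cache$ctgStrRc <- .rcStrings(cache$ctgStr)
  cache$contigHits <- lapply(readsets, function(...) list())
  # realignment results keyed by the scanned sequence itself: identical
  # junction spans recur across proposals and yield identical local hits
  cache$spanMemo <- lapply(readsets, function(...) new.env(parent = emptyenv()))
  # per-walk alignment summaries keyed by walk content: rejected proposals
  # recur across iterations
  cache$walkMemo <- new.env(parent = emptyenv())
  cache$nodeBudget <- .nodeBudgets(graph, config$longThreshold)
  cache$walks <- list()
  cache$walkSeq <- list()
  cache$walkLen <- numeric()
  cache$walkData <- lapply(readsets, function(...) list())
  cache$current <- character()
  cache$counter <- 0L
  cache
}

# Candidate ids for a target under one set's configured filter.
.candidates <- function(cache, si, target) {
  mt <- cache$meta[[si]]
  if (mt$exhaustive) return(seq_along(mt$reads))
  idx <- cache$indexes[[si]]
  candidateReads(target, idx, readLength = max(mt$lens))
}

# Hits of one read set against one oriented contig sequence (memoized per
# orientation, so canonical hit selection matches an in-walk scan exactly).
.contigHitsFor <- function(cache, si, node, strand) {
  key <- paste0(node, ":", strand)
  got <- cache$contigHits[[si]][[key]]
  if (!is.null(got)) return(got)
  mt <- cache$meta[[si]]
  target <- if (strand == 1L) cache$ctgStr[node] else cache$ctgStrRc[node]
  cand <- .candidates(cache, si, target)
  hits <- if (length(cand))
    .scanReads(target, mt$reads[cand], cand, cache$cfg$maxEditFraction,
               cache$cfg$seedK, if (mt$exhaustive) "exhaustive" else "seeded")
  else .emptyHits()
  cache$contigHits[[si]][[key]] <- hits
  hits
}

# Copy-number budgets per contig from k-mer coverage: the single-copy
# depth is the length-weighted median coverage of long contigs, and a long
# contig may be traversed at most round(cov / singleCopy) times across the
# assembly.  Short contigs are unconstrained (they fill gaps).  The
# likelihood itself cannot see exact content duplication (occurrence
# counts and assembly length scale together), so the budget supplies the
# copy-number information the k-mer spectrum carries.
.nodeBudgets <- function(graph, longThreshold) {
  w <- Biostrings::width(graph@contigs)
  cov <- graph@coverage
  budget <- rep(Inf, length(w))
  long <- which(w > longThreshold & is.finite(cov) & cov > 0)
  if (!length(long)) return(budget)
  covSingle <- stats::median(rep(cov[long],
                                 times = pmax(1L, w[long] %/% 100L)))
  if (!is.finite(covSingle) || covSingle <= 0) return(budget)
  budget[long] <- pmax(1, round(cov[long] / covSingle))
  budget
}

# Does the proposed walk set respect the per-contig traversal budgets?
.withinBudget <- function(cache, removeIds, addWalks) {
  counts <- integer(length(cache$graph@contigs))
  tally <- function(wk) {
    nd <- wk@nodes[!is.na(wk@nodes)]
    for (u in nd) counts[u] <<- counts[u] + 1L
  }
  for (id in setdiff(cache$current, removeIds)) tally(cache$walks[[id]])
  for (wk in addWalks) tally(wk)
  all(counts <= cache$nodeBudget)
}

.emptyHits <- function() {
  data.frame(read = integer(), start = integer(), end = integer(),
             strand = integer(), s = integer(), m = integer())
}

#' Partition a walk into overlapping alignment windows
#'
#' Greedy left-to-right window layout: the first window starts at the first
#' contig and extends at least `2 * readLengthMax` bases beyond that
#' contig's end; each subsequent window starts at the latest contig
#' boundary that preserves an overlap of at least `2 * readLengthMax` with
#' the previous window and extends at least that far beyond the previous
#' window's end.  Every alignment not longer than `readLengthMax` is fully
#' contained in at least one window.
#'
#' @param walk a [Walk-class].
#' @param graph an [AssemblyGraph-class].
#' @param readLengthMax the longest read length \eqn{\ell_r} (inflate by
#'   the edit budget to also contain indel-extended alignments).
#' @return data.frame with columns `start`, `end` (walk coordinates,
#'   0-based half-open) and `firstStep`, `lastStep` (step indexes).
#' @export
partitionWindows <- function(walk, graph, readLengthMax) {
  lay <- .walkLayout(walk, graph, validate = FALSE)
  .windowsFromLayout(lay, 2L * as.integer(readLengthMax))
}

.windowsFromLayout <- function(lay, lr2) {
  stepStart <- lay$offset
  stepEnd <- lay$offset + lay$len
  wlen <- stepEnd[nrow(lay)]
  out <- list()
  startStep <- 1L
  prevEnd <- -Inf
  repeat {
    firstEnd <- stepEnd[startStep]
    targetEnd <- min(wlen, max(firstEnd + lr2, prevEnd + lr2))
    lastStep <- which(stepEnd >= targetEnd)[1L]
    if (is.na(lastStep)) lastStep <- nrow(lay)
    lastStep <- max(lastStep, startStep)
    wEnd <- stepEnd[lastStep]
    out[[length(out) + 1L]] <- data.frame(
      start = stepStart[startStep], end = wEnd,
      firstStep = startStep, lastStep = lastStep)
    if (wEnd >= wlen) break
    prevEnd <- wEnd
    cand <- which(stepStart <= wEnd - lr2)
    startStep <- if (length(cand)) max(cand) else startStep
  }
  do.call(rbind, out)
}

#' Masked realignment span of a window
#'
#' Interiors of long contigs never change between iterations, so when a
#' window begins (ends) with a long contig only its last (first)
#' `2 * readLengthMax` bases are realigned; everything between the margins
#' is realigned in full.
#'
#' @param window one row of [partitionWindows()] output.
#' @param walk,graph the walk and graph the window belongs to.
#' @param readLengthMax the longest read length \eqn{\ell_r}.
#' @param longThreshold long-contig threshold (bp).
#' @return Numeric vector `c(start, end)`; `start >= end` means nothing
#'   needs realignment.
#' @export
maskedRealignSpan <- function(window, walk, graph, readLengthMax,
                              longThreshold = 500L) {
  lay <- .walkLayout(walk, graph, validate = FALSE)
  .maskedSpanFromLayout(window, lay, 2L * as.integer(readLengthMax),
                        longThreshold)
}

.maskedSpanFromLayout <- function(window, lay, lr2, longThreshold) {
  a <- window$start
  b <- window$end
  fs <- window$firstStep
  ls <- window$lastStep
  if (!lay$gap[fs] && lay$len[fs] > longThreshold)
    a <- max(a, lay$offset[fs] + lay$len[fs] - lr2)
  if (!lay$gap[ls] && lay$len[ls] > longThreshold)
    b <- min(b, lay$offset[ls] + lr2)
  c(start = a, end = b)
}

# Assemble the hit table of one short read set against one walk:
# contig-cache interior hits mapped into walk coordinates plus masked-span
# realignment, deduplicated and capped.
.walkHitsShort <- function(cache, si, walk, lay, wseq) {
  mt <- cache$meta[[si]]
  cfg <- cache$cfg
  eff <- mt$effLr
  parts <- list()
  n <- nrow(lay)
  for (j in seq_len(n)) {
    if (lay$gap[j]) next
    ch <- .contigHitsFor(cache, si, lay$node[j], lay$strand[j])
    if (nrow(ch) == 0L) next
    clen <- lay$len[j]
    mL <- if (j > 1L) eff else 0L
    mR <- if (j < n) eff else 0L
    keep <- ch$start >= mL & ch$end <= clen - mR
    if (!any(keep)) next
    ch <- ch[keep, , drop = FALSE]
    ch$start <- ch$start + lay$offset[j]
    ch$end <- ch$end + lay$offset[j]
    parts[[length(parts) + 1L]] <- ch
  }
  win <- .windowsFromLayout(lay, 2L * eff)
  wlen <- nchar(wseq)
  for (r in seq_len(nrow(win))) {
    span <- .maskedSpanFromLayout(win[r, ], lay, 2L * eff, cfg$longThreshold)
    if (span[1] >= span[2]) next
    # scan with a one-read-length pad of context so hits at the span edges
    # are computed exactly as a whole-walk scan would; keep interior hits
    a <- max(0L, span[1] - eff)
    b <- min(wlen, span[2] + eff)
    spanSeq <- substr(wseq, a + 1L, b)
    memo <- cache$spanMemo[[si]]
    sh <- memo[[spanSeq]]
    if (is.null(sh)) {
      cand <- .candidates(cache, si, spanSeq)
      sh <- if (length(cand))
        .scanReads(spanSeq, mt$reads[cand], cand, cfg$maxEditFraction,
                   cfg$seedK, if (mt$exhaustive) "exhaustive" else "seeded")
      else .emptyHits()
      memo[[spanSeq]] <- sh
    }
    if (nrow(sh) == 0L) next
    sh$start <- sh$start + a
    sh$end <- sh$end + a
    lo <- if (span[1] == 0L) 0L else span[1]
    hi <- if (span[2] == wlen) wlen else span[2]
    sh <- sh[sh$start >= lo & sh$end <= hi, , drop = FALSE]
    parts[[length(parts) + 1L]] <- sh
  }
  if (!length(parts)) return(.emptyHits())
  hits <- do.call(rbind, parts)
  hits <- hits[!duplicated(paste(hits$read, hits$start, hits$strand)), ,
               drop = FALSE]
  .capHits(hits, cfg$maxHits)
}

# Hits of a long-read set against one walk (whole-walk seed-chain scan).
.walkHitsLong <- function(cache, si, wseq) {
  mt <- cache$meta[[si]]
  cfg <- cache$cfg
  h <- cppScanLong(wseq, mt$reads, cfg$longSeedK, cfg$longMaxEditFraction,
                   cfg$band, mt$params@errorRate, cfg$minSeeds)
  data.frame(read = h$idx, start = h$start, end = h$end, strand = h$strand,
             s = h$s, m = h$m, logmass = h$logmass)
}

# Consistent mate combinations within one walk's hit table (hits of mate 1
# have read <= n, mate 2 read > n, aligned by pair id).
.walkPairCombos <- function(hits, n, params) {
  h1 <- hits[hits$read <= n, , drop = FALSE]
  h2 <- hits[hits$read > n, , drop = FALSE]
  if (nrow(h1) == 0L || nrow(h2) == 0L)
    return(data.frame(pair = integer(), d = numeric(), w = numeric(),
                      start = integer(), end = integer()))
  p1 <- h1$read
  p2 <- h2$read - n
  # expand all within-pair combinations without a data.frame merge
  s1 <- split(seq_len(nrow(h1)), p1)
  s2 <- split(seq_len(nrow(h2)), p2)
  common <- intersect(names(s1), names(s2))
  if (!length(common))
    return(data.frame(pair = integer(), d = numeric(), w = numeric(),
                      start = integer(), end = integer()))
  n1 <- lengths(s1[common])
  n2 <- lengths(s2[common])
  i1 <- unlist(mapply(function(a, b) rep(a, each = b), s1[common], n2,
                      SIMPLIFY = FALSE), use.names = FALSE)
  i2 <- unlist(mapply(function(a, b) rep(a, times = b), s2[common], n1,
                      SIMPLIFY = FALSE), use.names = FALSE)
  str1 <- h1$strand[i1]; str2 <- h2$strand[i2]
  st1 <- h1$start[i1]; st2 <- h2$start[i2]
  opp <- str1 != str2
  plusStart <- ifelse(str1 == 1L, st1, st2)
  minusStart <- ifelse(str1 == 1L, st2, st1)
  ok <- opp & if (params@orientation == "fr") plusStart <= minusStart
              else minusStart <= plusStart
  i1 <- i1[ok]; i2 <- i2[ok]
  if (!length(i1))
    return(data.frame(pair = integer(), d = numeric(), w = numeric(),
                      start = integer(), end = integer()))
  eps <- params@errorRate
  st <- pmin(h1$start[i1], h2$start[i2])
  en <- pmax(h1$end[i1], h2$end[i2])
  data.frame(pair = p1[i1], d = en - st,
             w = alignmentWeight(h1$s[i1], h1$m[i1], eps) *
                 alignmentWeight(h2$s[i2], h2$m[i2], eps),
             start = st, end = en)
}

# Summarize one walk's hits for one set: per-unit probability-weight
# contributions, covering spans, and the disconnected-base count.
.summarizeWalk <- function(hits, mt, walkLen) {
  params <- mt$params
  if (mt$tech == "long") {
    w <- exp(hits$logmass)
    unitW <- if (nrow(hits))
      data.frame(unit = as.integer(rownames(rowsum(w, hits$read))),
                 w = as.numeric(rowsum(w, hits$read)))
    else data.frame(unit = integer(), w = numeric())
    spans <- hits[c("start", "end")]
  } else if (isTRUE(mt$paired)) {
    cm <- .walkPairCombos(hits, mt$nReads1, params)
    pw <- cm$w * stats::dnorm(cm$d, params@insertMean, params@insertSd)
    unitW <- if (nrow(cm))
      data.frame(unit = as.integer(rownames(rowsum(pw, cm$pair))),
                 w = as.numeric(rowsum(pw, cm$pair)))
    else data.frame(unit = integer(), w = numeric())
    unitW <- unitW[unitW$w > 0, , drop = FALSE]
    # only properly sized pairs act as one long read for connectivity
    proper <- abs(cm$d - params@insertMean) <= 6 * params@insertSd
    spans <- rbind(cm[proper, c("start", "end")], hits[c("start", "end")])
  } else {
    w <- alignmentWeight(hits$s, hits$m, params@errorRate)
    unitW <- if (nrow(hits))
      data.frame(unit = as.integer(rownames(rowsum(w, hits$read))),
                 w = as.numeric(rowsum(w, hits$read)))
    else data.frame(unit = integer(), w = numeric())
    spans <- hits[c("start", "end")]
  }
  d <- .disconnectedBases(walkLen, spans$start, spans$end,
                          params@connWindow, TRUE)
  list(hits = hits, unitW = unitW, d = d)
}

# Register a walk in the cache (compute sequence and per-set data) and
# return its id.
.walkSeqFast <- function(cache, walk, lay) {
  k <- cache$graph@k
  n <- nrow(lay)
  pieces <- character(n)
  for (i in seq_len(n)) {
    if (lay$gap[i]) {
      pieces[i] <- strrep("N", lay$len[i])
    } else {
      s <- if (lay$strand[i] == 1L) cache$ctgStr[lay$node[i]]
           else cache$ctgStrRc[lay$node[i]]
      if (i > 1L && !lay$gap[i - 1L]) s <- substr(s, k, nchar(s))
      pieces[i] <- s
    }
  }
  paste(pieces, collapse = "")
}

.registerWalk <- function(cache, walk) {
  cache$counter <- cache$counter + 1L
  id <- paste0("w", cache$counter)
  key <- paste(walk@nodes, walk@strands, walk@gapLens, collapse = ";")
  memo <- cache$walkMemo[[key]]
  if (is.null(memo)) {
    lay <- .walkLayout(walk, cache$graph, validate = TRUE)
    wseq <- .walkSeqFast(cache, walk, lay)
    wlen <- nchar(wseq)
    data <- lapply(seq_along(cache$readsets), function(si) {
      mt <- cache$meta[[si]]
      hits <- if (mt$tech == "long") .walkHitsLong(cache, si, wseq)
              else .walkHitsShort(cache, si, walk, lay, wseq)
      .summarizeWalk(hits, mt, wlen)
    })
    memo <- list(wseq = wseq, wlen = wlen, data = data)
    if (length(ls(cache$walkMemo)) > 400L)
      cache$walkMemo <- new.env(parent = emptyenv())
    cache$walkMemo[[key]] <- memo
  }
  cache$walks[[id]] <- walk
  cache$walkSeq[[id]] <- memo$wseq
  cache$walkLen[id] <- memo$wlen
  for (si in seq_along(cache$readsets))
    cache$walkData[[si]][[id]] <- memo$data[[si]]
  id
}

.dropWalks <- function(cache, ids) {
  for (id in ids) {
    cache$walks[[id]] <- NULL
    cache$walkSeq[[id]] <- NULL
    cache$walkLen <- cache$walkLen[setdiff(names(cache$walkLen), id)]
    for (si in seq_along(cache$readsets)) cache$walkData[[si]][[id]] <- NULL
  }
}

# Score a set of registered walk ids from their cached per-walk data.
.scoreIds <- function(cache, ids) {
  L <- sum(cache$walkLen[ids])
  if (L < 1) stop("assembly has zero length")
  nsets <- length(cache$readsets)
  laps <- numeric(nsets)
  ds <- integer(nsets)
  for (si in seq_len(nsets)) {
    mt <- cache$meta[[si]]
    acc <- numeric(mt$nUnits)
    d <- 0L
    for (id in ids) {
      wd <- cache$walkData[[si]][[id]]
      if (nrow(wd$unitW))
        acc[wd$unitW$unit] <- acc[wd$unitW$unit] + wd$unitW$w
      d <- d + wd$d
    }
    pr <- pmax(acc / (2 * L), mt$floors)
    laps[si] <- mean(log(pr))
    ds[si] <- d
  }
  combinedLap(laps, ds, lapply(cache$meta, `[[`, "params"),
              vapply(cache$readsets, function(r) r@name, character(1)))
}

#' Install an assembly as the cache's current state
#'
#' Registers every walk (aligning reads as needed) and returns the
#' resulting score.
#'
#' @param cache a likelihood cache.
#' @param assembly an [Assembly-class].
#' @return The [LapBreakdown-class] of the assembly.
#' @export
setAssembly <- function(cache, assembly) {
  .dropWalks(cache, cache$current)
  cache$current <- vapply(assembly@walks, function(w)
    .registerWalk(cache, w), character(1))
  .scoreIds(cache, cache$current)
}

#' Current assembly held by a cache
#' @param cache a likelihood cache.
#' @return An [Assembly-class] (walk list names are the cache ids).
#' @export
currentAssembly <- function(cache) {
  Assembly(stats::setNames(cache$walks[cache$current], cache$current))
}

#' Score of the cache's current assembly
#' @param cache a likelihood cache.
#' @return A [LapBreakdown-class].
#' @export
currentScore <- function(cache) .scoreIds(cache, cache$current)

#' Evaluate a proposed move incrementally
#'
#' Computes alignments only for the added walks (reusing contig-interior
#' caches and realigning masked window spans), then recombines per-walk
#' contributions -- subtracting removed walks and adding new ones -- into
#' the proposed total.  The proposal is not applied until
#' [commitProposal()].
#'
#' @param cache a likelihood cache.
#' @param removeIds ids of walks removed by the move.
#' @param addWalks list of new [Walk-class] objects.
#' @return list with `ids` (proposed walk-id set), `newIds`, and
#'   `breakdown` (a [LapBreakdown-class]).
#' @export
evalProposal <- function(cache, removeIds, addWalks) {
  if (!all(removeIds %in% cache$current))
    stop("proposal removes walks not in the current assembly")
  newIds <- vapply(addWalks, function(w) .registerWalk(cache, w),
                   character(1))
  ids <- c(setdiff(cache$current, removeIds), newIds)
  if (!length(ids)) stop("proposal would empty the assembly")
  breakdown <- .scoreIds(cache, ids)
  if (isTRUE(cache$cfg$paranoid)) {
    full <- scoreAssemblyFull(Assembly(cache$walks[ids]), cache$graph,
                              cache$readsets, cache$cfg)
    if (abs(full@total - breakdown@total) > 1e-6)
      stop("paranoid check failed: incremental ", breakdown@total,
           " vs full ", full@total)
  }
  list(ids = ids, newIds = newIds, breakdown = breakdown)
}

#' Commit a proposal evaluated by [evalProposal()]
#' @param cache a likelihood cache.
#' @param proposal the list returned by [evalProposal()].
#' @param removeIds the ids that were removed.
#' @export
commitProposal <- function(cache, proposal, removeIds) {
  .dropWalks(cache, removeIds)
  cache$current <- proposal$ids
  invisible(NULL)
}

#' Discard a proposal evaluated by [evalProposal()]
#' @param cache a likelihood cache.
#' @param proposal the list returned by [evalProposal()].
#' @export
rejectProposal <- function(cache, proposal) {
  .dropWalks(cache, proposal$newIds)
  invisible(NULL)
}

#' Changed windows between two assemblies
#'
#' Identifies the walks removed and added between two assemblies (walks
#' with identical step content are reused verbatim) and returns the
#' windows of the changed walks; overlapping windows of a walk are glued
#' into maximal realignment regions.
#'
#' @param old,new [Assembly-class] objects over the same graph.
#' @param graph the [AssemblyGraph-class].
#' @param readLengthMax the longest read length.
#' @return list with `removed` and `added`: each a list of per-walk window
#'   tables with an extra `region` column labelling glued overlapping
#'   windows.
#' @export
changedRegions <- function(old, new, graph, readLengthMax) {
  key <- function(w) paste(w@nodes, w@strands, w@gapLens, collapse = ";")
  ko <- vapply(old@walks, key, character(1))
  kn <- vapply(new@walks, key, character(1))
  glue <- function(win) {
    if (is.null(win) || nrow(win) == 0L) return(win)
    reg <- cumsum(c(1L, as.integer(win$start[-1L] > win$end[-nrow(win)])))
    win$region <- reg
    win
  }
  winsOf <- function(ws) lapply(ws, function(w)
    glue(partitionWindows(w, graph, readLengthMax)))
  list(removed = winsOf(old@walks[!(ko %in% kn)]),
       added = winsOf(new@walks[!(kn %in% ko)]))
}

#' Score an assembly by full realignment
#'
#' The independent evaluation path: every read set is aligned against every
#' walk sequence in full (no windows, no contig caches, no reuse), and the
#' score assembled from scratch.  Used by the `paranoid` mode and as the
#' reference the incremental path is checked against.
#'
#' @param assembly an [Assembly-class].
#' @param graph an [AssemblyGraph-class].
#' @param readsets list of [ReadSet-class] objects.
#' @param config a [lapConfig()] list.
#' @return A [LapBreakdown-class].
#' @export
scoreAssemblyFull <- function(assembly, graph, readsets,
                              config = lapConfig()) {
  meta <- lapply(readsets, .setMeta, cfg = config)
  indexes <- lapply(seq_along(readsets), function(i) {
    mt <- meta[[i]]
    if (mt$tech == "long" || mt$exhaustive) return(NULL)
    if (config$filter == "minhash")
      readMinHashIndex(mt$reads, k = config$seedK,
                       numHashes = config$numHashes,
                       seed = config$indexSeed)
    else readKmerIndex(mt$reads, k = config$seedK)
  })
  seqs <- vapply(assembly@walks, walkSequence, character(1), graph = graph)
  lens <- nchar(seqs)
  L <- sum(lens)
  nsets <- length(readsets)
  laps <- numeric(nsets)
  ds <- integer(nsets)
  for (si in seq_len(nsets)) {
    mt <- meta[[si]]
    acc <- numeric(mt$nUnits)
    d <- 0L
    for (wi in seq_along(seqs)) {
      if (mt$tech == "long") {
        hits <- .walkHitsLongSeq(seqs[wi], mt, config)
      } else {
        cand <- if (mt$exhaustive) seq_along(mt$reads)
                else candidateReads(seqs[wi], indexes[[si]],
                                    readLength = max(mt$lens))
        hits <- if (length(cand))
          .scanReads(seqs[wi], mt$reads[cand], cand, config$maxEditFraction,
                     config$seedK,
                     if (mt$exhaustive) "exhaustive" else "seeded")
        else .emptyHits()
        hits <- .capHits(hits, config$maxHits)
      }
      sm <- .summarizeWalk(hits, mt, lens[wi])
      if (nrow(sm$unitW))
        acc[sm$unitW$unit] <- acc[sm$unitW$unit] + sm$unitW$w
      d <- d + sm$d
    }
    pr <- pmax(acc / (2 * L), mt$floors)
    laps[si] <- mean(log(pr))
    ds[si] <- d
  }
  combinedLap(laps, ds, lapply(meta, `[[`, "params"),
              vapply(readsets, function(r) r@name, character(1)))
}

.walkHitsLongSeq <- function(wseq, mt, cfg) {
  h <- cppScanLong(wseq, mt$reads, cfg$longSeedK, cfg$longMaxEditFraction,
                   cfg$band, mt$params@errorRate, cfg$minSeeds)
  data.frame(read = h$idx, start = h$start, end = h$end, strand = h$strand,
             s = h$s, m = h$m, logmass = h$logmass)
}
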