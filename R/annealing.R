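# Simulated-annealing search over assemblies: proposal moves on walks,
# Metropolis acceptance, logarithmic cooling, patience-based stopping, and
# best-assembly tracking.  All moves return either NULL (no-op) or a list
# with `remove` (walk ids) and `add` (new Walk objects); unaffected walks
# are never touched.

#' Annealing configuration
#'
#' @param T0 initial temperature; `NULL` derives `0.01 * |initial score|`
#'   so that early moderately worse moves are occasionally accepted.
#' @param moveProbs named probabilities of the six move types
#'   (`extension`, `local`, `repeat_opt`, `advice`, `disconnect`,
#'   `interchange`); normalized to sum to one.
#' @param patience iterations without improvement of the best score before
#'   stopping.
#' @param maxIter hard iteration cap.
#' @param sampleCount random paths sampled by the local-improvement move.
#' @param greedyChunk extension chunk length (bp) for the greedy gap-filling
#'   strategy.
#' @param maxGap gap length (bp) above which local improvement switches to
#'   greedy chunk extension.
#' @param maxSteps step cap of the walk-extension random walk.
#' @return list of settings.
#' @export
annealConfig <- function(T0 = NULL,
                         moveProbs = c(extension = 0.25, local = 0.20,
                                       repeat_opt = 0.15, advice = 0.15,
                                       disconnect = 0.10, interchange = 0.15),
                         patience = 500L, maxIter = 5000L,
                         sampleCount = 10L, greedyChunk = 200L,
                         maxGap = 5000L, maxSteps = 30L) {
  stopifnot(patience >= 1L, all(moveProbs >= 0), sum(moveProbs) > 0)
  list(T0 = T0, moveProbs = moveProbs / sum(moveProbs),
       patience = as.integer(patience), maxIter = as.integer(maxIter),
       sampleCount = as.integer(sampleCount),
       greedyChunk = as.integer(greedyChunk), maxGap = as.integer(maxGap),
       maxSteps = as.integer(maxSteps))
}

#' Cooling schedule
#'
#' Logarithmic cooling \eqn{T = T_0 / \ln(i + 1)} (shifted by one so the
#' first iteration has a finite temperature).
#'
#' @param iteration iteration number (>= 1).
#' @param T0 initial temperature.
#' @return The temperature.
#' @export
temperatureSchedule <- function(iteration, T0) {
  if (any(iteration < 1)) stop("iteration must be >= 1")
  T0 / log(iteration + 1)
}

#' Metropolis acceptance rule
#'
#' A proposal with score change `delta` is always accepted when
#' `delta >= 0`, and with probability \eqn{e^{\Delta/T}} otherwise.
#'
#' @param delta score change (proposed minus current).
#' @param temperature current temperature (> 0).
#' @return logical.
#' @export
metropolisAccept <- function(delta, temperature) {
  if (temperature <= 0) stop("temperature must be positive")
  delta >= 0 || stats::runif(1) < exp(delta / temperature)
}

# ---------------------------------------------------------------------------
# walk manipulation helpers
# ---------------------------------------------------------------------------

.revWalk <- function(walk) {
  n <- length(walk@nodes)
  Walk(rev(walk@nodes), -rev(walk@strands), rev(walk@gapLens))
}

.walkSteps <- function(walk) {
  data.frame(node = walk@nodes, strand = walk@strands, gap = walk@gapLens)
}

.walkFromSteps <- function(steps) {
  Walk(steps$node, steps$strand, steps$gap)
}

.lastStep <- function(walk) {
  n <- length(walk@nodes)
  list(node = walk@nodes[n], strand = walk@strands[n])
}

.firstStep <- function(walk) {
  list(node = walk@nodes[1L], strand = walk@strands[1L])
}

.nodeLengths <- function(cache) Biostrings::width(cache$graph@contigs)

.longSteps <- function(cache, walk) {
  lens <- .nodeLengths(cache)
  which(!is.na(walk@nodes) & lens[ifelse(is.na(walk@nodes), 1L,
                                         walk@nodes)] >
          cache$cfg$longThreshold)
}

# Oriented-node igraph of the assembly graph, memoized in the cache.
.orientedGraph <- function(cache) {
  if (!is.null(cache$ig)) return(cache$ig)
  e <- cache$graph@edges
  n <- length(cache$graph@contigs)
  vid <- function(node, strand) node + n * (strand == -1L)
  g <- igraph::make_empty_graph(n = 2L * n, directed = TRUE)
  if (nrow(e))
    g <- igraph::add_edges(g, rbind(vid(e$from, e$fromStrand),
                                    vid(e$to, e$toStrand)))
  cache$ig <- g
  g
}

.reachSet <- function(cache, node, strand) {
  n <- length(cache$graph@contigs)
  g <- .orientedGraph(cache)
  vid <- node + n * (strand == -1L)
  vs <- as.integer(igraph::subcomponent(g, vid, mode = "in"))
  data.frame(node = ifelse(vs > n, vs - n, vs),
             strand = ifelse(vs > n, -1L, 1L))
}

# Sample one random path between oriented contigs, restricted to nodes from
# which the target is reachable.  Returns the intermediate steps (possibly
# zero rows) or NULL if the walk failed to reach the target.
.samplePath <- function(cache, from, to, maxDepth = 30L) {
  reach <- .reachSet(cache, to$node, to$strand)
  rkey <- paste(reach$node, reach$strand)
  cur <- from
  nodes <- integer(); strands <- integer()
  for (d in seq_len(maxDepth)) {
    outs <- outEdges(cache$graph, cur$node, cur$strand)
    if (!nrow(outs)) return(NULL)
    direct <- outs$to == to$node & outs$toStrand == to$strand
    keep <- direct | paste(outs$to, outs$toStrand) %in% rkey
    outs <- outs[keep, , drop = FALSE]
    if (!nrow(outs)) return(NULL)
    r <- outs[sample(nrow(outs), 1L), ]
    if (r$to == to$node & r$toStrand == to$strand)
      return(data.frame(node = nodes, strand = strands,
                        gap = rep(NA_integer_, length(nodes))))
    nodes <- c(nodes, r$to); strands <- c(strands, r$toStrand)
    cur <- list(node = r$to, strand = r$toStrand)
  }
  NULL
}

# ---------------------------------------------------------------------------
# proposal moves
# ---------------------------------------------------------------------------

#' Walk-extension move
#'
#' Starts from a random end of a random walk and extends it by uniformly
#' chosen outgoing edges.  Whenever the extension reaches the end of
#' another walk, it uniformly decides between joining the two walks,
#' stopping, and continuing.
#'
#' @param cache a likelihood cache holding the current assembly.
#' @param config an [annealConfig()] list.
#' @return A proposal (list with `remove`, `add`) or `NULL` for a no-op.
#' @export
moveWalkExtension <- function(cache, config = annealConfig()) {
  ids <- cache$current
  id <- sample(ids, 1L)
  w <- cache$walks[[id]]
  if (stats::runif(1) < 0.5) w <- .revWalk(w)
  other <- setdiff(ids, id)
  steps <- .walkSteps(w)
  cur <- .lastStep(w)
  added <- 0L
  for (k in seq_len(config$maxSteps)) {
    outs <- outEdges(cache$graph, cur$node, cur$strand)
    if (!nrow(outs)) break
    r <- outs[sample(nrow(outs), 1L), ]
    steps <- rbind(steps, data.frame(node = r$to, strand = r$toStrand,
                                     gap = NA_integer_))
    added <- added + 1L
    cur <- list(node = r$to, strand = r$toStrand)
    # did we land on the end of another walk?
    for (id2 in other) {
      w2 <- cache$walks[[id2]]
      f <- .firstStep(w2); l <- .lastStep(w2)
      if (f$node == cur$node && f$strand == cur$strand) {
        w2o <- w2
      } else if (l$node == cur$node && -l$strand == cur$strand) {
        w2o <- .revWalk(w2)
      } else next
      choice <- sample(c("join", "stop", "continue"), 1L)
      if (choice == "join") {
        rest <- .walkSteps(w2o)[-1L, , drop = FALSE]
        return(list(remove = c(id, id2),
                    add = list(.walkFromSteps(rbind(steps, rest))),
                    type = "extension"))
      }
      if (choice == "stop") {
        return(list(remove = id, add = list(.walkFromSteps(steps)),
                    type = "extension"))
      }
      break # continue walking; stop checking other walks for this node
    }
  }
  if (added == 0L) return(NULL)
  list(remove = id, add = list(.walkFromSteps(steps)), type = "extension")
}

# Candidate replacement walks for the segment between long-step indexes i
# and j of a walk (steps i and j kept, interior replaced).
.segmentVariants <- function(cache, walk, i, j, config) {
  steps <- .walkSteps(walk)
  from <- list(node = steps$node[i], strand = steps$strand[i])
  to <- list(node = steps$node[j], strand = steps$strand[j])
  paths <- list()
  for (t in seq_len(config$sampleCount)) {
    p <- .samplePath(cache, from, to)
    if (is.null(p)) next
    key <- paste(p$node, p$strand, collapse = ";")
    paths[[key]] <- p
  }
  lapply(paths, function(p) {
    .walkFromSteps(rbind(steps[seq_len(i), , drop = FALSE], p,
                         steps[j:nrow(steps), , drop = FALSE]))
  })
}

#' Local-improvement move
#'
#' Re-optimizes the connection between two consecutive long contigs s and t
#' of one walk: samples several random graph paths from s (restricted to
#' nodes from which t is reachable), scores each candidate replacement, and
#' proposes the best.  For gaps longer than `maxGap` a greedy strategy
#' extends the path in chunks of about `greedyChunk` bases, keeping the
#' best-scoring extension at each step.
#'
#' @inheritParams moveWalkExtension
#' @return A proposal or `NULL`.
#' @export
moveLocalImprovement <- function(cache, config = annealConfig()) {
  ids <- cache$current
  id <- sample(ids, 1L)
  w <- cache$walks[[id]]
  long <- .longSteps(cache, w)
  if (length(long) < 2L) return(NULL)
  pick <- sample(length(long) - 1L, 1L)
  i <- long[pick]; j <- long[pick + 1L]
  lay <- .walkLayout(w, cache$graph, validate = FALSE)
  gapLen <- lay$offset[j] - (lay$offset[i] + lay$len[i])
  if (gapLen > config$maxGap)
    return(.greedySegment(cache, id, w, i, j, config))
  variants <- .segmentVariants(cache, w, i, j, config)
  if (!length(variants)) return(NULL)
  curKey <- paste(w@nodes, w@strands, collapse = ";")
  best <- NULL; bestScore <- -Inf
  for (v in variants) {
    if (paste(v@nodes, v@strands, collapse = ";") == curKey) next
    ev <- evalProposal(cache, id, list(v))
    sc <- lapTotal(ev$breakdown)
    rejectProposal(cache, ev)
    if (sc > bestScore) { bestScore <- sc; best <- v }
  }
  if (is.null(best)) return(NULL)
  list(remove = id, add = list(best), type = "local")
}

# Greedy chunked gap filling: grow the replacement path toward t in
# ~greedyChunk-base extensions, scoring each candidate extension with the
# remaining gap represented as Ns, and keeping the best.
.greedySegment <- function(cache, id, walk, i, j, config) {
  steps <- .walkSteps(walk)
  lens <- .nodeLengths(cache)
  to <- list(node = steps$node[j], strand = steps$strand[j])
  lay <- .walkLayout(walk, cache$graph, validate = FALSE)
  gapTotal <- lay$offset[j] - (lay$offset[i] + lay$len[i])
  prefix <- steps[seq_len(i), , drop = FALSE]
  suffix <- steps[j:nrow(steps), , drop = FALSE]
  built <- 0L
  for (round in 1:50) {
    cur <- list(node = prefix$node[nrow(prefix)],
                strand = prefix$strand[nrow(prefix)])
    if (.hasEdge(cache$graph, cur$node, cur$strand, to$node, to$strand)) {
      cand <- .walkFromSteps(rbind(prefix, suffix))
      return(list(remove = id, add = list(cand), type = "local"))
    }
    exts <- list()
    for (t in seq_len(max(3L, config$sampleCount %/% 2L))) {
      p <- .sampleChunk(cache, cur, to, config$greedyChunk, lens)
      if (is.null(p) || !nrow(p)) next
      exts[[paste(p$node, p$strand, collapse = ";")]] <- p
    }
    if (!length(exts)) return(NULL)
    best <- NULL; bestScore <- -Inf
    for (p in exts) {
      rest <- max(1L, gapTotal - built - sum(lens[p$node] -
                                             (cache$graph@k - 1L)))
      gapStep <- data.frame(node = NA_integer_, strand = NA_integer_,
                            gap = rest)
      cand <- .walkFromSteps(rbind(prefix, p, gapStep, suffix))
      ev <- evalProposal(cache, id, list(cand))
      sc <- lapTotal(ev$breakdown)
      rejectProposal(cache, ev)
      if (sc > bestScore) { bestScore <- sc; best <- p }
    }
    prefix <- rbind(prefix, best)
    built <- built + sum(lens[best$node] - (cache$graph@k - 1L))
    if (built > gapTotal + 2L * config$greedyChunk) break
  }
  NULL
}

# Random path chunk of about chunkLen bases toward `to`, reachability-pruned.
.sampleChunk <- function(cache, from, to, chunkLen, lens) {
  reach <- .reachSet(cache, to$node, to$strand)
  rkey <- paste(reach$node, reach$strand)
  cur <- from
  nodes <- integer(); strands <- integer()
  total <- 0L
  while (total < chunkLen) {
    outs <- outEdges(cache$graph, cur$node, cur$strand)
    keep <- paste(outs$to, outs$toStrand) %in% rkey
    outs <- outs[keep, , drop = FALSE]
    if (!nrow(outs)) break
    r <- outs[sample(nrow(outs), 1L), ]
    if (r$to == to$node && r$toStrand == to$strand) break
    nodes <- c(nodes, r$to); strands <- c(strands, r$toStrand)
    total <- total + lens[r$to] - (cache$graph@k - 1L)
    cur <- list(node = r$to, strand = r$toStrand)
  }
  if (!length(nodes)) return(NULL)
  data.frame(node = nodes, strand = strands,
             gap = rep(NA_integer_, length(nodes)))
}

#' Repeat-optimization move
#'
#' Changes the copy number of a short tandem loop in one walk by one:
#' either splices a precomputed loop (at most five nodes) into a walk at a
#' node the loop passes through, or excises one occurrence of such a loop.
#'
#' @inheritParams moveWalkExtension
#' @param loops loop catalogue from [enumerateShortLoops()].
#' @return A proposal or `NULL`.
#' @export
moveRepeatOptimization <- function(cache, loops, config = annealConfig()) {
  if (!length(loops)) return(NULL)
  ids <- cache$current
  id <- sample(ids, 1L)
  w <- cache$walks[[id]]
  steps <- .walkSteps(w)
  key <- paste(steps$node, steps$strand)
  # loop occurrences usable at this walk
  addable <- list(); removable <- list()
  for (lp in loops) {
    lkey <- paste(lp$node, lp$strand)
    for (pos in which(key %in% lkey)) {
      rot <- match(key[pos], lkey)
      # rotate the loop to start right after the matched node
      ord <- c(seq_len(nrow(lp)), seq_len(nrow(lp)))[rot + seq_len(nrow(lp))]
      splice <- lp[ord, , drop = FALSE]
      addable[[length(addable) + 1L]] <- list(pos = pos, splice = splice)
      # removable if the walk already continues with exactly this loop
      after <- pos + seq_len(nrow(lp))
      if (max(after) <= nrow(steps) &&
          identical(paste(steps$node[after], steps$strand[after]),
                    paste(splice$node, splice$strand)))
        removable[[length(removable) + 1L]] <- list(pos = pos, n = nrow(lp))
    }
  }
  doAdd <- if (length(addable) && length(removable)) stats::runif(1) < 0.5
           else length(addable) > 0L
  if (doAdd && length(addable)) {
    a <- addable[[sample(length(addable), 1L)]]
    splice <- a$splice
    splice$gap <- NA_integer_
    newSteps <- rbind(steps[seq_len(a$pos), , drop = FALSE],
                      splice[, c("node", "strand", "gap")],
                      if (a$pos < nrow(steps))
                        steps[(a$pos + 1L):nrow(steps), , drop = FALSE])
    return(list(remove = id, add = list(.walkFromSteps(newSteps)),
                type = "repeat_opt"))
  }
  if (length(removable)) {
    r <- removable[[sample(length(removable), 1L)]]
    drop <- r$pos + seq_len(r$n)
    newSteps <- steps[-drop, , drop = FALSE]
    return(list(remove = id, add = list(.walkFromSteps(newSteps)),
                type = "repeat_opt"))
  }
  NULL
}

#' Joining-with-advice move
#'
#' Uses long-range evidence -- read pairs with long inserts whose mates lie
#' on different walks, or long reads overlapping contigs of different
#' walks -- to propose joining the two walks, filling the gap with a graph
#' path when one is found and with Ns otherwise.
#'
#' @inheritParams moveWalkExtension
#' @return A proposal or `NULL`.
#' @export
moveJoiningWithAdvice <- function(cache, config = annealConfig()) {
  ids <- cache$current
  if (length(ids) < 2L) return(NULL)
  eligible <- which(vapply(cache$meta, function(mt)
    mt$tech == "long" ||
      (isTRUE(mt$paired) &&
         !is.na(mt$params@insertMean) &&
         mt$params@insertMean > 3 * max(mt$lens)), logical(1)))
  # any paired set can serve as advice when nothing longer exists
  if (!length(eligible))
    eligible <- which(vapply(cache$meta, function(mt)
      isTRUE(mt$paired), logical(1)))
  if (!length(eligible)) return(NULL)
  si <- if (length(eligible) == 1L) eligible else sample(eligible, 1L)
  mt <- cache$meta[[si]]
  if (mt$tech == "long") return(.adviceLong(cache, si, config))
  .advicePaired(cache, si, config)
}

.advicePaired <- function(cache, si, config) {
  ids <- cache$current
  mt <- cache$meta[[si]]
  n <- mt$nReads1
  # best hit of every read on every walk
  tabs <- lapply(ids, function(id) {
    h <- cache$walkData[[si]][[id]]$hits
    if (!nrow(h)) return(NULL)
    cbind(h, id = id)
  })
  hits <- do.call(rbind, tabs)
  if (is.null(hits) || !nrow(hits)) return(NULL)
  hits <- hits[order(hits$read, hits$s), ]
  hits <- hits[!duplicated(hits$read), ] # best placement per read
  m1 <- hits[hits$read <= n, ]
  m2 <- hits[hits$read > n, ]
  m2$pair <- m2$read - n
  m1$pair <- m1$read
  common <- intersect(m1$pair, m2$pair)
  if (!length(common)) return(NULL)
  m1 <- m1[match(common, m1$pair), ]
  m2 <- m2[match(common, m2$pair), ]
  split <- m1$id != m2$id
  if (!any(split)) return(NULL)
  k <- sample(which(split), 1L)
  h1 <- m1[k, ]; h2 <- m2[k, ]
  wA <- cache$walks[[h1$id]]; wB <- cache$walks[[h2$id]]
  lenA <- cache$walkLen[[h1$id]]; lenB <- cache$walkLen[[h2$id]]
  # orient A so the mate-1 hit is on the + strand (fragment extends right)
  if (h1$strand == -1L) {
    wA <- .revWalk(wA)
    h1s <- lenA - h1$end
  } else h1s <- h1$start
  # orient B so the mate-2 hit is on the - strand (fragment enters from left)
  if (h2$strand == 1L) {
    wB <- .revWalk(wB)
    h2e <- lenB - h2$start
  } else h2e <- h2$end
  gap <- round(mt$params@insertMean - (lenA - h1s) - h2e)
  sA <- .walkSteps(wA); sB <- .walkSteps(wB)
  from <- list(node = sA$node[nrow(sA)], strand = sA$strand[nrow(sA)])
  to <- list(node = sB$node[1L], strand = sB$strand[1L])
  joined <- NULL
  if (.hasEdge(cache$graph, from$node, from$strand, to$node, to$strand)) {
    joined <- rbind(sA, sB)
  } else {
    p <- .samplePath(cache, from, to, maxDepth = 15L)
    if (!is.null(p)) joined <- rbind(sA, p, sB)
  }
  if (is.null(joined)) {
    gapStep <- data.frame(node = NA_integer_, strand = NA_integer_,
                          gap = max(1L, as.integer(gap)))
    joined <- rbind(sA, gapStep, sB)
  }
  list(remove = c(h1$id, h2$id), add = list(.walkFromSteps(joined)),
       type = "advice")
}

.adviceLong <- function(cache, si, config) {
  ids <- cache$current
  mt <- cache$meta[[si]]
  tabs <- lapply(ids, function(id) {
    h <- cache$walkData[[si]][[id]]$hits
    if (!nrow(h)) return(NULL)
    cbind(h, id = id)
  })
  hits <- do.call(rbind, tabs)
  if (is.null(hits) || !nrow(hits)) return(NULL)
  # long reads with hits on two walks
  byRead <- split(hits, hits$read)
  cand <- Filter(function(h) length(unique(h$id)) >= 2L, byRead)
  if (!length(cand)) return(NULL)
  h <- cand[[sample(length(cand), 1L)]]
  h <- h[order(h$s), ][1:2, ]
  wA <- cache$walks[[h$id[1L]]]; wB <- cache$walks[[h$id[2L]]]
  if (h$strand[1L] == -1L) wA <- .revWalk(wA)
  if (h$strand[2L] == -1L) wB <- .revWalk(wB)
  sA <- .walkSteps(wA); sB <- .walkSteps(wB)
  from <- list(node = sA$node[nrow(sA)], strand = sA$strand[nrow(sA)])
  to <- list(node = sB$node[1L], strand = sB$strand[1L])
  joined <- NULL
  if (.hasEdge(cache$graph, from$node, from$strand, to$node, to$strand)) {
    joined <- rbind(sA, sB)
  } else {
    p <- .samplePath(cache, from, to, maxDepth = 15L)
    if (!is.null(p)) joined <- rbind(sA, p, sB)
  }
  if (is.null(joined)) {
    gapStep <- data.frame(node = NA_integer_, strand = NA_integer_,
                          gap = 100L)
    joined <- rbind(sA, gapStep, sB)
  }
  list(remove = unique(h$id), add = list(.walkFromSteps(joined)),
       type = "advice")
}

#' Disconnecting move
#'
#' Removes a path of short contigs (or an N-gap) connecting two long
#' contigs of one walk, splitting it into two walks.
#'
#' @inheritParams moveWalkExtension
#' @return A proposal or `NULL`.
#' @export
moveDisconnecting <- function(cache, config = annealConfig()) {
  ids <- cache$current
  id <- sample(ids, 1L)
  w <- cache$walks[[id]]
  long <- .longSteps(cache, w)
  if (length(long) < 2L) return(NULL)
  gaps <- which(diff(long) > 1L)
  if (!length(gaps)) return(NULL)
  pick <- if (length(gaps) == 1L) gaps else sample(gaps, 1L)
  i <- long[pick]; j <- long[pick + 1L]
  steps <- .walkSteps(w)
  w1 <- .walkFromSteps(steps[seq_len(i), , drop = FALSE])
  w2 <- .walkFromSteps(steps[j:nrow(steps), , drop = FALSE])
  list(remove = id, add = list(w1, w2), type = "disconnect")
}

# Traversals of a node across the current walks, oriented so the node
# appears on the + strand.  Same-walk double traversals are excluded (their
# copy number is the repeat-optimization move's job).
.nodeTraversals <- function(cache, node) {
  out <- list()
  for (id in cache$current) {
    w <- cache$walks[[id]]
    at <- which(!is.na(w@nodes) & w@nodes == node)
    if (length(at) != 1L) next
    wo <- if (w@strands[at] == 1L) w else .revWalk(w)
    at2 <- which(!is.na(wo@nodes) & wo@nodes == node &
                   wo@strands == 1L)[1L]
    out[[length(out) + 1L]] <- list(id = id, walk = wo, pos = at2)
  }
  out
}

#' Repeat-interchange move
#'
#' At a long contig traversed by several walks, re-pairs the incoming and
#' outgoing walk parts: all exchanges of the parts of two walks through the
#' contig are evaluated, the best improving exchange applied, and the step
#' repeated until no exchange at this contig improves the score.
#'
#' @inheritParams moveWalkExtension
#' @param node optional contig id to optimize (default: random eligible).
#' @return A proposal (with `delta >= 0` by construction) or `NULL`.
#' @export
moveRepeatInterchange <- function(cache, config = annealConfig(),
                                  node = NULL) {
  lens <- .nodeLengths(cache)
  counts <- integer(length(lens))
  for (id in cache$current) {
    w <- cache$walks[[id]]
    nd <- w@nodes[!is.na(w@nodes)]
    counts[unique(nd)] <- counts[unique(nd)] +
      as.integer(table(nd)[as.character(unique(nd))])
  }
  long <- lens > cache$cfg$longThreshold
  eligible <- which(long & (counts >= 2L |
                              (counts >= 1L & cache$nodeBudget >= 2)))
  if (is.null(node)) {
    if (!length(eligible)) return(NULL)
    node <- if (length(eligible) == 1L) eligible else sample(eligible, 1L)
  }
  trav <- .nodeTraversals(cache, node)
  if (length(trav) < 1L) return(NULL)
  removeIds <- vapply(trav, `[[`, character(1), "id")
  current <- lapply(trav, function(t) {
    s <- .walkSteps(t$walk)
    list(pre = s[seq_len(t$pos), , drop = FALSE],
         post = if (t$pos < nrow(s)) s[(t$pos + 1L):nrow(s), , drop = FALSE]
                else s[0L, , drop = FALSE])
  })
  assemble <- function(pairing) {
    lapply(seq_along(pairing), function(q)
      .walkFromSteps(rbind(current[[q]]$pre, current[[pairing[q]]]$post)))
  }
  scoreOf <- function(rem, walksList) {
    ev <- evalProposal(cache, rem, walksList)
    sc <- lapTotal(ev$breakdown)
    rejectProposal(cache, ev)
    sc
  }
  m <- length(current)
  pairing <- seq_len(m)
  curScore <- scoreOf(removeIds, assemble(pairing))
  improved <- FALSE
  if (m >= 2L) repeat {
    bestSwap <- NULL; bestScore <- curScore + 1e-9
    for (a in seq_len(m - 1L)) for (b in (a + 1L):m) {
      p2 <- pairing
      tmp <- p2[a]; p2[a] <- p2[b]; p2[b] <- tmp
      sc <- scoreOf(removeIds, assemble(p2))
      if (sc > bestScore) { bestScore <- sc; bestSwap <- p2 }
    }
    if (is.null(bestSwap)) break
    pairing <- bestSwap
    curScore <- bestScore
    improved <- TRUE
  }
  if (improved)
    return(list(remove = removeIds, add = assemble(pairing),
                type = "interchange"))
  # threading: when the contig's copy-number budget allows another
  # traversal, try routing a whole other walk through it -- replacing
  # pre [node] post by pre [node] W2 [node] post -- which rescues the
  # pairs spanning both of W2's ends in one step
  .bestThreading(cache, node, trav, assemble(pairing), removeIds,
                 counts, curScore, scoreOf)
}

.bestThreading <- function(cache, node, trav, baseWalks, removeIds, counts,
                           curScore, scoreOf) {
  if (counts[node] + 1L > cache$nodeBudget[node]) return(NULL)
  nodeStep <- data.frame(node = node, strand = 1L, gap = NA_integer_)
  best <- NULL; bestScore <- curScore + 1e-9
  for (ti in seq_along(trav)) {
    t <- trav[[ti]]
    s <- .walkSteps(t$walk)
    pre <- s[seq_len(t$pos), , drop = FALSE]
    post <- if (t$pos < nrow(s)) s[(t$pos + 1L):nrow(s), , drop = FALSE]
            else s[0L, , drop = FALSE]
    for (id2 in setdiff(cache$current, removeIds)) {
      w2 <- cache$walks[[id2]]
      for (orient in 1:2) {
        w2o <- if (orient == 1L) w2 else .revWalk(w2)
        f <- .firstStep(w2o); l <- .lastStep(w2o)
        if (!.hasEdge(cache$graph, node, 1L, f$node, f$strand)) next
        if (!.hasEdge(cache$graph, l$node, l$strand, node, 1L)) next
        cand <- .walkFromSteps(rbind(pre, .walkSteps(w2o), nodeStep, post))
        others <- baseWalks[-ti]
        sc <- scoreOf(c(removeIds, id2), c(list(cand), others))
        if (sc > bestScore) {
          bestScore <- sc
          best <- list(remove = c(removeIds, id2),
                       add = c(list(cand), others), type = "interchange")
        }
      }
    }
  }
  best
}

# ---------------------------------------------------------------------------
# the annealing loop
# ---------------------------------------------------------------------------

#' Find a high-likelihood assembly by simulated annealing
#'
#' Starting from an initial assembly, repeatedly proposes a random move
#' (with per-type probabilities), evaluates the proposed assembly
#' incrementally, and accepts by the Metropolis rule under a logarithmic
#' cooling schedule.  Stops after `patience` iterations without an
#' improvement of the best score (or at `maxIter`), and returns the
#' best-scoring assembly ever visited.
#'
#' @param initial an [Assembly-class] to start from.
#' @param graph the [AssemblyGraph-class].
#' @param readsets list of [ReadSet-class] objects.
#' @param config an [annealConfig()] list.
#' @param evalConfig a [lapConfig()] list.
#' @param cache optional pre-built likelihood cache (rebuilt otherwise).
#' @param verbose print progress every 100 iterations.
#' @return list with `assembly` (best [Assembly-class]), `breakdown` (its
#'   [LapBreakdown-class]), `trajectory` (per-iteration log: iteration,
#'   move, delta, accepted, temperature, total, best), and `cache`.
#' @export
anneal <- function(initial, graph, readsets, config = annealConfig(),
                   evalConfig = lapConfig(), cache = NULL,
                   verbose = FALSE) {
  if (is.null(cache)) cache <- newLikelihoodCache(graph, readsets, evalConfig)
  cur <- setAssembly(cache, initial)
  curTotal <- lapTotal(cur)
  if (is.null(config$T0)) {
    # scale from the unpenalized weighted LAP: the penalty term can dwarf
    # the LAP magnitude and would set an uninformatively hot start
    config$T0 <- 0.01 * abs(sum(cur@weights * cur@perSetLap))
  }
  loops <- enumerateShortLoops(graph)
  best <- currentAssembly(cache)
  bestTotal <- curTotal
  bestBreakdown <- cur
  stall <- 0L
  log <- vector("list", config$maxIter)
  moves <- names(config$moveProbs)
  for (i in seq_len(config$maxIter)) {
    temp <- temperatureSchedule(i, config$T0)
    mv <- sample(moves, 1L, prob = config$moveProbs)
    prop <- switch(mv,
      extension = moveWalkExtension(cache, config),
      local = moveLocalImprovement(cache, config),
      repeat_opt = moveRepeatOptimization(cache, loops, config),
      advice = moveJoiningWithAdvice(cache, config),
      disconnect = moveDisconnecting(cache, config),
      interchange = moveRepeatInterchange(cache, config))
    if (!is.null(prop) &&
        !.withinBudget(cache, prop$remove, prop$add)) {
      # the proposal would exceed a contig's coverage-derived copy-number
      # budget; content duplication is invisible to the likelihood, so
      # such states are excluded from the search space
      prop <- NULL
    }
    if (is.null(prop)) {
      # a degenerate proposal carries no information about convergence
      log[[i]] <- data.frame(iteration = i, move = mv, delta = NA_real_,
                             accepted = NA, temperature = temp,
                             total = curTotal, best = bestTotal)
      next
    }
    ev <- evalProposal(cache, prop$remove, prop$add)
    delta <- lapTotal(ev$breakdown) - curTotal
    acc <- metropolisAccept(delta, temp)
    if (acc) {
      commitProposal(cache, ev, prop$remove)
      curTotal <- lapTotal(ev$breakdown)
      better <- curTotal > bestTotal + 1e-9
      # exact duplication of assembly content is score-neutral (read counts
      # and length scale together); break ties toward the shorter assembly
      tie <- !better && curTotal > bestTotal - 1e-9 &&
        sum(cache$walkLen[cache$current]) < .assemblyLen(best, cache)
      if (better || tie) {
        bestTotal <- max(bestTotal, curTotal)
        best <- currentAssembly(cache)
        bestBreakdown <- ev$breakdown
        if (better) stall <- 0L else stall <- stall + 1L
      } else stall <- stall + 1L
    } else {
      rejectProposal(cache, ev)
      stall <- stall + 1L
    }
    log[[i]] <- data.frame(iteration = i, move = mv, delta = delta,
                           accepted = acc, temperature = temp,
                           total = curTotal, best = bestTotal)
    if (verbose && i %% 100L == 0L)
      message(sprintf("iter %d: total %.3f best %.3f (T=%.4f)",
                      i, curTotal, bestTotal, temp))
    if (stall >= config$patience) break
  }
  trajectory <- do.call(rbind, log[!vapply(log, is.null, logical(1))])
  # leave the cache holding the best assembly, with score-neutral
  # redundant (duplicate-content) walks removed
  fin <- setAssembly(cache, best)
  fin <- .pruneRedundantWalks(cache, fin)
  list(assembly = currentAssembly(cache), breakdown = fin,
       trajectory = trajectory, cache = cache)
}

.assemblyLen <- function(assembly, cache) {
  sum(vapply(assembly@walks, function(w)
    nchar(.walkSeqFast(cache, w, .walkLayout(w, cache$graph,
                                             validate = FALSE))),
    numeric(1)))
}

# Duplicated assembly content (a walk repeating another walk's sequence,
# in either orientation, wholly or in part) is near likelihood-neutral:
# occurrence counts and assembly length scale together.  Remove any walk
# whose removal does not lower the score -- walks with unique content are
# always kept, because their reads would fall to the no-alignment floor.
.pruneRedundantWalks <- function(cache, breakdown) {
  repeat {
    improved <- FALSE
    for (id in cache$current) {
      if (length(cache$current) <= 1L) break
      ev <- evalProposal(cache, id, list())
      if (lapTotal(ev$breakdown) >= lapTotal(breakdown) - 1e-9) {
        commitProposal(cache, ev, id)
        breakdown <- ev$breakdown
        improved <- TRUE
      } else {
        rejectProposal(cache, ev)
      }
    }
    if (!improved) return(breakdown)
  }
}
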