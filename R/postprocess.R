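# Ambiguity-breaking postprocessing: wherever alternative repeat
# resolutions are indistinguishable by likelihood, walks are cut at the
# ambiguous contig so that no arbitrary resolution is emitted.

.trimGapSteps <- function(steps) {
  while (nrow(steps) && is.na(steps$node[1L]))
    steps <- steps[-1L, , drop = FALSE]
  while (nrow(steps) && is.na(steps$node[nrow(steps)]))
    steps <- steps[-nrow(steps), , drop = FALSE]
  if (!nrow(steps)) return(NULL)
  steps
}

# Split the walks traversing `node` at the node's boundaries; the node
# itself is emitted once as a standalone walk.
.breakAtNode <- function(cache, node) {
  removeIds <- character()
  pieces <- list()
  for (id in cache$current) {
    w <- cache$walks[[id]]
    at <- which(!is.na(w@nodes) & w@nodes == node)
    if (!length(at)) next
    removeIds <- c(removeIds, id)
    steps <- .walkSteps(w)
    bounds <- c(0L, at, nrow(steps) + 1L)
    for (b in seq_len(length(bounds) - 1L)) {
      lo <- bounds[b] + 1L; hi <- bounds[b + 1L] - 1L
      if (lo > hi) next
      piece <- .trimGapSteps(steps[lo:hi, , drop = FALSE])
      if (!is.null(piece)) pieces[[length(pieces) + 1L]] <- piece
    }
  }
  pieces[[length(pieces) + 1L]] <- data.frame(node = node, strand = 1L,
                                              gap = NA_integer_)
  list(remove = removeIds, add = lapply(pieces, .walkFromSteps))
}

#' Break walks at ambiguously resolved repeats
#'
#' Applies the repeat-interchange evaluation at every contig traversed more
#' than once: improving exchanges are applied first; where the best
#' alternative resolution changes the score by no more than `tolerance`
#' (for example when a repeat is longer than the span of the longest paired
#' read, so all resolutions look alike to the reads), the traversing walks
#' are cut at the contig's boundaries and the contig emitted once as a
#' standalone walk.  Breaking never introduces new sequence.
#'
#' @param assembly an [Assembly-class] (typically the annealing result).
#' @param graph the [AssemblyGraph-class].
#' @param readsets list of [ReadSet-class] objects.
#' @param tolerance LAP change below which resolutions count as
#'   indistinguishable (default 1e-3).
#' @param evalConfig a [lapConfig()] list.
#' @param cache optional likelihood cache to reuse.
#' @return list with `assembly` (the broken [Assembly-class]), `breakdown`
#'   (its score), and `report` (data.frame: node, delta of the best
#'   alternative, broken flag).
#' @export
breakAmbiguous <- function(assembly, graph, readsets, tolerance = 1e-3,
                           evalConfig = lapConfig(), cache = NULL) {
  if (is.null(cache)) cache <- newLikelihoodCache(graph, readsets, evalConfig)
  cur <- setAssembly(cache, assembly)
  report <- list()
  repeat {
    # recompute multi-traversed contigs against the current state
    counts <- integer(length(graph@contigs))
    for (id in cache$current) {
      nd <- cache$walks[[id]]@nodes
      nd <- nd[!is.na(nd)]
      for (u in unique(nd)) counts[u] <- counts[u] + sum(nd == u)
    }
    done <- vapply(report, `[[`, numeric(1), "node")
    lens <- Biostrings::width(graph@contigs)
    multiCopy <- is.finite(cache$nodeBudget) & cache$nodeBudget >= 2 &
      lens > cache$cfg$longThreshold
    cand <- setdiff(which(counts >= 2L | (counts >= 1L & multiCopy)), done)
    if (!length(cand)) break
    node <- cand[1L]
    curTotal <- lapTotal(.scoreIds(cache, cache$current))
    # apply improving exchanges first
    prop <- moveRepeatInterchange(cache, annealConfig(), node = node)
    if (!is.null(prop)) {
      ev <- evalProposal(cache, prop$remove, prop$add)
      if (lapTotal(ev$breakdown) > curTotal) {
        commitProposal(cache, ev, prop$remove)
        curTotal <- lapTotal(ev$breakdown)
      } else rejectProposal(cache, ev)
    }
    trav <- .nodeTraversals(cache, node)
    if (length(trav) >= 2L) {
      # distinct walks: the tail exchange is content-preserving, so the
      # likelihood comparison is clean
      delta <- .bestAlternativeDelta(cache, node, curTotal)
      broken <- !is.na(delta) && abs(delta) <= tolerance
    } else {
      # traversals within one walk (double traversal, or a single
      # traversal of a multi-copy contig): every content-preserving
      # re-pairing must cut a junction, which biases the likelihood
      # comparison; test the underlying condition directly instead --
      # does a properly sized pair (or long read) span each occurrence?
      delta <- NA_real_
      broken <- !.allOccurrencesSpanned(cache, node)
    }
    if (broken) {
      br <- .breakAtNode(cache, node)
      ev <- evalProposal(cache, br$remove, br$add)
      commitProposal(cache, ev, br$remove)
    }
    report[[length(report) + 1L]] <-
      data.frame(node = node, delta = delta, broken = broken)
  }
  report <- if (length(report)) do.call(rbind, report)
            else data.frame(node = integer(), delta = numeric(),
                            broken = logical())
  list(assembly = currentAssembly(cache),
       breakdown = .scoreIds(cache, cache$current), report = report)
}

# Is every through-traversal of `node` spanned end to end by at least one
# covering span (properly sized pair, long-read alignment, or single
# read)?  Walks consisting of the node alone are not traversals and are
# skipped.
.allOccurrencesSpanned <- function(cache, node) {
  for (id in cache$current) {
    w <- cache$walks[[id]]
    at <- which(!is.na(w@nodes) & w@nodes == node)
    if (!length(at) || length(w@nodes) == 1L) next
    lay <- .walkLayout(w, cache$graph, validate = FALSE)
    occ <- which(!is.na(lay$node) & lay$node == node)
    # terminal occurrences connect only one flank: there is no pairing
    # choice to support, so they are not tested
    occ <- occ[occ > 1L & occ < nrow(lay)]
    for (o in occ) {
      rs <- lay$offset[o]
      re <- rs + lay$len[o]
      spanned <- FALSE
      for (si in seq_along(cache$readsets)) {
        mt <- cache$meta[[si]]
        hits <- cache$walkData[[si]][[id]]$hits
        if (!nrow(hits)) next
        spans <- if (mt$tech == "long" || !isTRUE(mt$paired)) {
          hits[c("start", "end")]
        } else {
          cm <- .walkPairCombos(hits, mt$nReads1, mt$params)
          proper <- abs(cm$d - mt$params@insertMean) <=
            6 * mt$params@insertSd
          cm[proper, c("start", "end"), drop = FALSE]
        }
        if (nrow(spans) && any(spans$start < rs & spans$end > re)) {
          spanned <- TRUE
          break
        }
      }
      if (!spanned) return(FALSE)
    }
  }
  TRUE
}

# Score change of the best alternative resolution at `node`: re-pairings
# across distinct walks, or the pull-apart variant for a double traversal
# within one walk.  NA when no alternative exists.
.bestAlternativeDelta <- function(cache, node, curTotal) {
  trav <- .nodeTraversals(cache, node)
  if (length(trav) >= 2L) {
    current <- lapply(trav, function(t) {
      s <- .walkSteps(t$walk)
      list(pre = s[seq_len(t$pos), , drop = FALSE],
           post = if (t$pos < nrow(s))
                    s[(t$pos + 1L):nrow(s), , drop = FALSE]
                  else s[0L, , drop = FALSE])
    })
    removeIds <- vapply(trav, `[[`, character(1), "id")
    m <- length(current)
    best <- NA_real_
    for (a in seq_len(m - 1L)) for (b in (a + 1L):m) {
      pairing <- seq_len(m)
      pairing[c(a, b)] <- pairing[c(b, a)]
      walksList <- lapply(seq_len(m), function(q)
        .walkFromSteps(rbind(current[[q]]$pre, current[[pairing[q]]]$post)))
      ev <- evalProposal(cache, removeIds, walksList)
      d <- lapTotal(ev$breakdown) - curTotal
      rejectProposal(cache, ev)
      if (is.na(best) || d > best) best <- d
    }
    return(best)
  }
  # double traversal within one walk
  for (id in cache$current) {
    w <- cache$walks[[id]]
    at <- which(!is.na(w@nodes) & w@nodes == node)
    if (length(at) < 2L) next
    if (w@strands[at[1L]] != w@strands[at[2L]]) next # inverted; no swap
    wo <- if (w@strands[at[1L]] == 1L) w else .revWalk(w)
    at <- which(!is.na(wo@nodes) & wo@nodes == node)
    steps <- .walkSteps(wo)
    i <- at[1L]; j <- at[2L]
    post <- if (j < nrow(steps)) steps[(j + 1L):nrow(steps), , drop = FALSE]
            else steps[0L, , drop = FALSE]
    outer <- .walkFromSteps(rbind(steps[seq_len(i), , drop = FALSE], post))
    midSteps <- if (j - i >= 2L)
      .trimGapSteps(steps[(i + 1L):(j - 1L), , drop = FALSE]) else NULL
    walksList <- c(list(outer), if (!is.null(midSteps))
      list(.walkFromSteps(midSteps)))
    ev <- evalProposal(cache, id, walksList)
    d <- lapTotal(ev$breakdown) - curTotal
    rejectProposal(cache, ev)
    return(d)
  }
  NA_real_
}
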