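# Conservative assembly graph: de Bruijn construction with basic error
# correction (low-coverage k-mer dropping, tip clipping) and unambiguous
# condensation into contig nodes; walks through the graph; short-loop
# enumeration; mapping of external assemblies onto the graph.

.rcStrings <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

.canonical <- function(x) {
  rc <- .rcStrings(x)
  ifelse(x <= rc, x, rc)
}

# Condense a retained k-mer set (canonical representatives) into unitigs
# using only edges whose connecting (k+1)-mer is in the support set.
# Returns contig sequences (canonical representative strand) or NULL.
.condenseKmers <- function(kmers, support, k) {
  if (!length(kmers)) return(NULL)
  ori <- unique(c(kmers, .rcStrings(kmers)))
  n <- length(ori)
  suf <- substr(ori, 2L, k)
  pre <- substr(ori, 1L, k - 1L)
  succMat <- matrix(NA_integer_, nrow = 4L, ncol = n)
  bases <- c("A", "C", "G", "T")
  for (b in 1:4) {
    cand <- paste0(suf, bases[b])
    idx <- match(cand, ori)
    # edge requires read support for the connecting (k+1)-mer
    supp <- .canonical(paste0(ori, bases[b])) %in% support
    idx[!supp] <- NA_integer_
    succMat[b, ] <- idx
  }
  outdeg <- colSums(!is.na(succMat))
  indeg <- integer(n)
  tgt <- succMat[!is.na(succMat)]
  tb <- tabulate(tgt, nbins = n)
  indeg <- tb
  uniqueSucc <- function(i) {
    s <- succMat[, i]
    s <- s[!is.na(s)]
    if (length(s) == 1L) s else NA_integer_
  }
  # a node is chain-internal iff it has a unique predecessor whose
  # out-degree is one; chains start at all other nodes
  predOf <- rep(NA_integer_, n)
  for (b in 1:4) {
    s <- succMat[b, ]
    ok <- which(!is.na(s))
    one <- ok[indeg[s[ok]] == 1L]
    predOf[s[one]] <- one
  }
  internal <- !is.na(predOf)
  internal[internal] <- outdeg[predOf[internal]] == 1L
  visited <- logical(n)
  chains <- list()
  order1 <- c(which(!internal), which(internal)) # starts first, then cycle rest
  for (i in order1) {
    if (visited[i]) next
    path <- i
    visited[i] <- TRUE
    cur <- i
    repeat {
      if (outdeg[cur] != 1L) break
      nxt <- uniqueSucc(cur)
      if (is.na(nxt) || indeg[nxt] != 1L || visited[nxt]) break
      path <- c(path, nxt)
      visited[nxt] <- TRUE
      cur <- nxt
    }
    chains[[length(chains) + 1L]] <- path
  }
  seqs <- vapply(chains, function(p) {
    paste0(ori[p[1L]], paste(substr(ori[p[-1L]], k, k), collapse = ""))
  }, character(1))
  # each unitig also appears as its reverse complement; keep one strand
  canon <- .canonical(seqs)
  unique(canon)
}

# Edge table between contigs: oriented overlap of k-1 bases with read
# support for the connecting (k+1)-mer.
.contigEdges <- function(seqs, support, k) {
  n <- length(seqs)
  if (!n) return(data.frame(from = integer(), fromStrand = integer(),
                            to = integer(), toStrand = integer()))
  oriSeq <- c(seqs, .rcStrings(seqs))
  oriNode <- c(seq_len(n), seq_len(n))
  oriStrand <- c(rep(1L, n), rep(-1L, n))
  lastK <- substr(oriSeq, nchar(oriSeq) - k + 1L, nchar(oriSeq))
  firstK <- substr(oriSeq, 1L, k)
  sufK1 <- substr(lastK, 2L, k) # k-1 suffix
  preK1 <- substr(firstK, 1L, k - 1L)
  out <- list()
  for (i in seq_along(oriSeq)) {
    js <- which(preK1 == sufK1[i])
    if (!length(js)) next
    supp <- .canonical(paste0(lastK[i], substr(firstK[js], k, k))) %in% support
    js <- js[supp]
    if (!length(js)) next
    out[[length(out) + 1L]] <- data.frame(
      from = oriNode[i], fromStrand = oriStrand[i],
      to = oriNode[js], toStrand = oriStrand[js])
  }
  if (!length(out)) return(data.frame(from = integer(), fromStrand = integer(),
                                      to = integer(), toStrand = integer()))
  e <- do.call(rbind, out)
  e[order(e$from, e$fromStrand, e$to, e$toStrand), , drop = FALSE]
}

#' Build a conservative de Bruijn assembly graph from reads
#'
#' Counts canonical k-mers across all short accurate read sets, drops
#' low-coverage k-mers (basic error correction), condenses unambiguous
#' chains into contig nodes, and clips short dead-end tips, iterating until
#' stable.  The goal is not contiguity but avoiding errors inside contigs:
#' the resulting short, high-confidence contigs are the vertices over which
#' assemblies are expressed as walks.
#'
#' @param readsets a [ReadSet-class], a list of them (long-read sets are
#'   ignored), or a [Biostrings::DNAStringSet] of sequences.
#' @param kmerSize k-mer length (default 21).
#' @param minCount coverage threshold; `NULL` derives
#'   `max(2, ceiling(0.1 * median(count)))` from the k-mer spectrum.
#' @param tipLength tips shorter than this are clipped (default `2 *
#'   kmerSize`).
#' @param maxRounds maximum tip-clipping rounds.
#' @return An [AssemblyGraph-class].
#' @export
buildConservativeGraph <- function(readsets, kmerSize = 21L, minCount = NULL,
                                   tipLength = NULL, maxRounds = 5L) {
  k <- as.integer(kmerSize)
  if (is.null(tipLength)) tipLength <- 2L * k
  seqs <- if (methods::is(readsets, "DNAStringSet")) {
    as.character(readsets)
  } else {
    if (methods::is(readsets, "ReadSet")) readsets <- list(readsets)
    unlist(lapply(readsets, function(rs) {
      if (rs@technology != "short") return(character())
      c(as.character(rs@reads), as.character(rs@mates))
    }), use.names = FALSE)
  }
  if (!length(seqs)) stop("no short-read sequences to build the graph from")
  tab <- cppCountKmers(seqs, k, canonical = TRUE)
  if (!length(tab$kmer)) stop("no k-mers found; reads shorter than k?")
  if (is.null(minCount)) {
    # error k-mers are dominated by singletons; estimate the true coverage
    # from the non-singleton part of the spectrum
    solid <- tab$count[tab$count >= 2L]
    est <- if (length(solid)) stats::median(solid) else 1
    minCount <- max(2, ceiling(0.1 * est))
  }
  keepK <- tab$kmer[tab$count >= minCount]
  covTab <- stats::setNames(tab$count, tab$kmer)
  e1 <- cppCountKmers(seqs, k + 1L, canonical = TRUE)
  support <- e1$kmer[e1$count >= minCount]
  if (!length(keepK))
    stop("coverage too low: no k-mer passes the threshold (", minCount, ")")
  for (round in seq_len(maxRounds)) {
    seqsC <- .condenseKmers(keepK, support, k)
    if (is.null(seqsC) || !length(seqsC))
      stop("coverage too low to form any contig")
    edges <- .contigEdges(seqsC, support, k)
    # tip detection in + orientation (the - orientation is its mirror)
    nC <- length(seqsC)
    outd <- tabulate(edges$from[edges$fromStrand == 1L], nbins = nC)
    ind <- tabulate(edges$to[edges$toStrand == 1L], nbins = nC)
    lens <- nchar(seqsC)
    tip <- lens < tipLength &
      ((ind == 0L & outd >= 1L) | (outd == 0L & ind >= 1L))
    if (!any(tip) || round == maxRounds) break
    # drop the tips' k-mers and recondense
    dropK <- unique(unlist(lapply(seqsC[tip], function(s)
      kmerSet(s, k, canonical = TRUE))))
    keepK <- setdiff(keepK, dropK)
    if (!length(keepK)) stop("tip clipping removed all k-mers")
  }
  cov <- vapply(seqsC, function(s) {
    km <- .canonical(kmerSet(s, k, canonical = TRUE))
    mean(covTab[km], na.rm = TRUE)
  }, numeric(1))
  new("AssemblyGraph",
      contigs = Biostrings::DNAStringSet(stats::setNames(
        seqsC, paste0("c", seq_along(seqsC)))),
      edges = edges, k = k, coverage = unname(cov))
}

#' Outgoing edges of an oriented contig
#' @param graph an [AssemblyGraph-class].
#' @param node contig id.
#' @param strand +1 or -1.
#' @return data.frame rows of `edgeTable(graph)`.
#' @export
outEdges <- function(graph, node, strand) {
  e <- graph@edges
  e[e$from == node & e$fromStrand == strand, , drop = FALSE]
}

.hasEdge <- function(graph, from, fs, to, ts) {
  e <- graph@edges
  any(e$from == from & e$fromStrand == fs & e$to == to & e$toStrand == ts)
}

# Per-step layout of a walk: offsets and lengths in walk coordinates,
# with k-1 overlaps merged between edge-joined contig steps.
.walkLayout <- function(walk, graph, validate = TRUE) {
  k <- graph@k
  n <- length(walk@nodes)
  lens <- integer(n)
  gap <- is.na(walk@nodes)
  lens[gap] <- walk@gapLens[gap]
  lens[!gap] <- Biostrings::width(graph@contigs)[walk@nodes[!gap]]
  off <- integer(n)
  if (n > 1L) {
    for (i in 2:n) {
      overlap <- if (!gap[i] && !gap[i - 1L]) k - 1L else 0L
      if (validate && !gap[i] && !gap[i - 1L] &&
          !.hasEdge(graph, walk@nodes[i - 1L], walk@strands[i - 1L],
                    walk@nodes[i], walk@strands[i]))
        stop("walk step ", i - 1L, " -> ", i, " is not a graph edge")
      off[i] <- off[i - 1L] + lens[i - 1L] - overlap
    }
  }
  data.frame(node = walk@nodes, strand = walk@strands, gap = gap,
             offset = off, len = lens)
}

#' Sequence spelled by a walk
#'
#' Concatenates the oriented contig sequences of the walk, merging the
#' \eqn{k-1}-base overlap of each graph edge once; N-gap steps are emitted
#' as runs of `N`.
#'
#' @param walk a [Walk-class].
#' @param graph the [AssemblyGraph-class] the walk lives in.
#' @return A character string.
#' @export
walkSequence <- function(walk, graph) {
  lay <- .walkLayout(walk, graph)
  k <- graph@k
  pieces <- character(nrow(lay))
  for (i in seq_len(nrow(lay))) {
    if (lay$gap[i]) {
      pieces[i] <- strrep("N", lay$len[i])
    } else {
      s <- as.character(graph@contigs[[lay$node[i]]])
      if (lay$strand[i] == -1L) s <- .rcStrings(s)
      if (i > 1L && !lay$gap[i] && !lay$gap[i - 1L])
        s <- substr(s, k, nchar(s))
      pieces[i] <- s
    }
  }
  paste(pieces, collapse = "")
}

#' Length of a walk's sequence
#' @param walk a [Walk-class].
#' @param graph an [AssemblyGraph-class].
#' @export
walkLength <- function(walk, graph) {
  lay <- .walkLayout(walk, graph, validate = FALSE)
  n <- nrow(lay)
  lay$offset[n] + lay$len[n]
}

#' Initial assembly: one walk per long contig
#'
#' Contigs longer than `longThreshold` each become a single-node walk;
#' short contigs start unplaced and are pulled into walks by the annealing
#' moves.
#'
#' @param graph an [AssemblyGraph-class].
#' @param longThreshold contigs longer than this (bp) are "long"
#'   (default 500).
#' @return An [Assembly-class].
#' @export
initialAssembly <- function(graph, longThreshold = 500L) {
  w <- Biostrings::width(graph@contigs)
  long <- which(w > longThreshold)
  if (!length(long))
    stop("no contig exceeds the long threshold (", longThreshold,
         "); cannot seed the assembly")
  Assembly(lapply(long, function(i) Walk(i, 1L)))
}

#' Enumerate short loops of the assembly graph
#'
#' All directed cycles of at most `maxNodes` oriented contigs, used by the
#' repeat-optimization move to adjust tandem-repeat copy numbers.
#'
#' @param graph an [AssemblyGraph-class].
#' @param maxNodes maximum cycle length in nodes (default 5).
#' @return list of data.frames with columns `node`, `strand` (the cycle in
#'   order; the edge from the last row back to the first closes it).
#' @export
enumerateShortLoops <- function(graph, maxNodes = 5L) {
  e <- graph@edges
  if (!nrow(e)) return(list())
  n <- length(graph@contigs)
  vid <- function(node, strand) node + n * (strand == -1L)
  nv <- 2L * n
  adj <- vector("list", nv)
  ef <- vid(e$from, e$fromStrand)
  et <- vid(e$to, e$toStrand)
  for (i in seq_along(ef)) adj[[ef[i]]] <- c(adj[[ef[i]]], et[i])
  # enumerate simple directed cycles of <= maxNodes vertices; each cycle is
  # generated once, anchored at its smallest vertex id
  cycles <- list()
  dfs <- function(start, v, path) {
    for (w in adj[[v]]) {
      if (w == start) {
        cycles[[length(cycles) + 1L]] <<- path
      } else if (w > start && !(w %in% path) &&
                 length(path) < maxNodes) {
        dfs(start, w, c(path, w))
      }
    }
  }
  for (v in seq_len(nv)) if (length(adj[[v]])) dfs(v, v, v)
  lapply(cycles, function(vs) {
    data.frame(node = ifelse(vs > n, vs - n, vs),
               strand = ifelse(vs > n, -1L, 1L))
  })
}

# Bounded DFS over graph paths from oriented contig (from, fs) to (to, ts),
# minimizing the edit distance between the spelled intermediate sequence
# and gapSeq; abandons branches once no completion within maxEdit is
# possible.  Returns list(nodes, strands) of intermediates, or NULL.
.bridgePath <- function(graph, from, fs, to, ts, gapSeq, maxEdit = 10L,
                        maxDepth = 25L, maxVisits = 2000L) {
  k <- graph@k
  target <- gapSeq
  tl <- nchar(target)
  best <- NULL
  bestEdit <- maxEdit + 1L
  visits <- 0L
  rec <- function(cur, cs, piece, nodes, strands) {
    visits <<- visits + 1L
    if (visits > maxVisits || length(nodes) > maxDepth) return()
    if (nchar(piece) > tl + maxEdit) return()
    if (.hasEdge(graph, cur, cs, to, ts)) {
      ed <- utils::adist(piece, target)[1, 1]
      if (ed < bestEdit) {
        bestEdit <<- ed
        best <<- list(nodes = nodes, strands = strands)
      }
    }
    outs <- outEdges(graph, cur, cs)
    for (r in seq_len(nrow(outs))) {
      nn <- outs$to[r]; ns <- outs$toStrand[r]
      if (nn == to && ns == ts) next # handled above via direct edge check
      s <- as.character(graph@contigs[[nn]])
      if (ns == -1L) s <- .rcStrings(s)
      add <- substr(s, k, nchar(s))
      rec(nn, ns, paste0(piece, add), c(nodes, nn), c(strands, ns))
    }
  }
  rec(from, fs, "", integer(), integer())
  if (bestEdit <= maxEdit) best else NULL
}

#' Map an external assembly onto the graph
#'
#' Each external contig becomes a walk: graph contigs fully covered by
#' high-identity alignments to it are chained in order; gaps between
#' consecutive mapped contigs are bridged by a bounded search over graph
#' paths minimizing the edit distance to the spanned external sequence,
#' abandoning at edit distance greater than `maxEdit` and inserting an
#' N-gap of the spanned length instead.
#'
#' @param external [Biostrings::DNAStringSet] (or character vector) of
#'   external contigs.
#' @param graph an [AssemblyGraph-class].
#' @param maxEdit edit-distance budget for gap bridging (default 10).
#' @param minIdentity minimum identity for a graph contig to count as
#'   mapped (alignment must cover the entire graph contig).
#' @param seedK seeding k-mer length for the contig-to-external alignment.
#' @return list with `assembly` (an [Assembly-class]; walks for mapped
#'   external contigs) and `mapped` (logical per external contig).  When no
#'   external contig maps at all, `assembly` is `NULL` (callers fall back
#'   to building a graph from the external assembly itself).
#' @export
mapExternalAssembly <- function(external, graph, maxEdit = 10L,
                                minIdentity = 0.95, seedK = 13L) {
  external <- as.character(external)
  contigs <- as.character(graph@contigs)
  clens <- nchar(contigs)
  k <- graph@k
  walksOut <- list()
  mapped <- logical(length(external))
  for (ei in seq_along(external)) {
    E <- external[ei]
    hits <- .scanReads(E, contigs, seq_along(contigs),
                       maxEditFraction = 1 - minIdentity, seedK = seedK,
                       mode = "seeded")
    if (nrow(hits) == 0L) next
    hits <- hits[order(hits$start, hits$s, -clens[hits$read]), , drop = FALSE]
    # greedy chain of non-overlapping (beyond the k-1 edge overlap) hits
    chain <- list()
    prevEnd <- -Inf
    for (r in seq_len(nrow(hits))) {
      if (hits$start[r] >= prevEnd - (k - 1L) - 2L) {
        chain[[length(chain) + 1L]] <- hits[r, ]
        prevEnd <- hits$end[r]
      }
    }
    chain <- do.call(rbind, chain)
    nodes <- integer(); strands <- integer(); gaps <- integer()
    addStep <- function(n, s, g = NA_integer_) {
      nodes <<- c(nodes, n); strands <<- c(strands, s)
      gaps <<- c(gaps, g)
    }
    addStep(chain$read[1L], chain$strand[1L])
    ok <- TRUE
    if (nrow(chain) > 1L) for (r in 2:nrow(chain)) {
      a <- chain[r - 1L, ]; b <- chain[r, ]
      direct <- .hasEdge(graph, a$read, a$strand, b$read, b$strand) &&
        abs(b$start - (a$end - (k - 1L))) <= 2L
      if (direct) {
        addStep(b$read, b$strand)
        next
      }
      gapSeq <- substr(E, a$end - (k - 1L) + 1L, b$start)
      br <- .bridgePath(graph, a$read, a$strand, b$read, b$strand, gapSeq,
                       maxEdit = maxEdit)
      if (!is.null(br)) {
        for (t in seq_along(br$nodes)) addStep(br$nodes[t], br$strands[t])
        addStep(b$read, b$strand)
      } else {
        glen <- max(1L, b$start - a$end)
        addStep(NA_integer_, NA_integer_, glen)
        addStep(b$read, b$strand)
      }
    }
    if (ok) {
      walksOut[[length(walksOut) + 1L]] <-
        Walk(nodes, strands, gaps)
      mapped[ei] <- TRUE
    }
  }
  if (!any(mapped)) return(list(assembly = NULL, mapped = mapped))
  list(assembly = Assembly(walksOut), mapped = mapped)
}

#' Export the assembly graph as GFA
#'
#' Writes segments (contigs) and links (oriented overlap edges, CIGAR
#' `(k-1)M`) in GFA 1 format for inspection in standard graph viewers.
#'
#' @param graph an [AssemblyGraph-class].
#' @param file output path.
#' @export
writeGFA <- function(graph, file) {
  con <- base::file(file, "w")
  on.exit(close(con))
  writeLines("H\tVN:Z:1.0", con)
  nm <- names(graph@contigs)
  for (i in seq_along(graph@contigs)) {
    writeLines(paste("S", nm[i], as.character(graph@contigs[[i]]),
                     sep = "\t"), con)
  }
  e <- graph@edges
  ov <- paste0(graph@k - 1L, "M")
  sym <- function(s) ifelse(s == 1L, "+", "-")
  for (r in seq_len(nrow(e))) {
    writeLines(paste("L", nm[e$from[r]], sym(e$fromStrand[r]),
                     nm[e$to[r]], sym(e$toStrand[r]), ov, sep = "\t"), con)
  }
  invisible(file)
}
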