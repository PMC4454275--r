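# Independent pure-R oracles used to check the compiled alignment and
# scoring machinery, plus small fixture builders.  These re-implement the
# declared canonical definitions from scratch (full DP matrices, per-base
# loops) without touching the package's scanning code paths.

randomSeq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rcSeq <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

mutateSeq <- function(x, nsub = 0) {
  ch <- strsplit(x, "")[[1]]
  pos <- sample(length(ch), nsub)
  for (i in pos) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  paste(ch, collapse = "")
}

# Full semi-global DP of one oriented read against the target: edit
# distance e(j) for every end column j.
oracleEndDistances <- function(read, target) {
  r <- strsplit(read, "")[[1]]
  t <- strsplit(target, "")[[1]]
  len <- length(r); n <- length(t)
  D <- matrix(0L, nrow = len + 1, ncol = n + 1)
  D[, 1] <- 0:len
  for (i in 1:len) {
    for (j in 1:n) {
      sub <- if (r[i] %in% c("A","C","G","T") && r[i] == t[j]) 0L else 1L
      D[i + 1, j + 1] <- min(D[i, j] + sub, D[i, j + 1] + 1L,
                             D[i + 1, j] + 1L)
    }
  }
  D
}

# Traceback from (len, j) with the canonical move priority (diagonal, then
# horizontal, then vertical); returns list(start, m).
oracleTraceback <- function(D, read, target, je) {
  r <- strsplit(read, "")[[1]]
  t <- strsplit(target, "")[[1]]
  i <- length(r); j <- je; m <- 0L
  while (i > 0) {
    stepped <- FALSE
    if (j > 0) {
      sub <- if (r[i] %in% c("A","C","G","T") && r[i] == t[j]) 0L else 1L
      if (D[i + 1, j + 1] == D[i, j] + sub) {
        if (sub == 0L) m <- m + 1L
        i <- i - 1L; j <- j - 1L; stepped <- TRUE
      } else if (D[i + 1, j + 1] == D[i + 1, j] + 1L) {
        j <- j - 1L; stepped <- TRUE
      }
    }
    if (!stepped) i <- i - 1L
  }
  list(start = j, m = m)
}

# Canonical hit set of a read against a target, both strands, by the
# declared rule: qualifying end positions (edit distance <= kmax) grouped
# into maximal consecutive runs, positions achieving the run minimum kept,
# then one hit per (strand, start): max matches, then shortest span.
oracleHits <- function(read, target, kmax) {
  out <- list()
  for (strand in c(1L, -1L)) {
    rd <- if (strand == 1L) read else rcSeq(read)
    D <- oracleEndDistances(rd, target)
    e <- D[nchar(rd) + 1, ]
    qual <- which(e[-1] <= kmax) # end positions 1..n (exclusive end coord)
    # also allow the zero-length end (all-insertion) like the scanner
    qual0 <- e[1] <= kmax
    ends <- sort(unique(c(if (qual0) 0L else integer(), qual)))
    if (!length(ends)) next
    runs <- split(ends, cumsum(c(1L, diff(ends) != 1L)))
    for (run in runs) {
      best <- min(e[run + 1L])
      for (je in run[e[run + 1L] == best]) {
        tb <- oracleTraceback(D, rd, target, je)
        out[[length(out) + 1L]] <- data.frame(
          start = tb$start, end = je, strand = strand, s = best, m = tb$m)
      }
    }
  }
  if (!length(out))
    return(data.frame(start = integer(), end = integer(),
                      strand = integer(), s = integer(), m = integer()))
  h <- do.call(rbind, out)
  h <- h[order(-h$strand, h$start, h$s, -h$m, h$end), ]
  h <- h[!duplicated(h[c("strand", "start")]), ]
  rownames(h) <- NULL
  h
}

# Eq.-style probability from an oracle hit set.
oracleSingleProb <- function(hits, L, eps) {
  if (!nrow(hits)) return(0)
  w <- if (eps == 0) ifelse(hits$s == 0, 1, 0) * (1 - eps)^hits$m
       else eps^hits$s * (1 - eps)^hits$m
  sum(w) / (2 * L)
}

# Full (unbanded) forward algorithm over one strand: sum over all
# alignment paths of eps^s (1-eps)^m with free start and end columns.
oracleForwardLog <- function(read, target, eps) {
  r <- strsplit(read, "")[[1]]
  t <- strsplit(target, "")[[1]]
  len <- length(r); n <- length(t)
  F <- matrix(0, nrow = len + 1, ncol = n + 1)
  F[1, ] <- 1
  for (i in 1:len) {
    F[i + 1, 1] <- F[i, 1] * eps
    for (j in 1:n) {
      pm <- if (r[i] == t[j]) 1 - eps else eps
      F[i + 1, j + 1] <- F[i, j] * pm + F[i, j + 1] * eps +
        F[i + 1, j] * eps
    }
  }
  log(sum(F[len + 1, ]))
}

# Per-base brute force of the connectivity definition.
oracleDisconnected <- function(len, starts, ends, k, exemptStart = TRUE) {
  d <- 0L
  for (j in 0:(len - 1L)) {
    if (exemptStart && j < k) next
    covered <- any(starts <= j - k & ends > j)
    if (!covered) d <- d + 1L
  }
  d
}

# Jaccard similarity of the canonical k-mer sets of two sequences.
oracleJaccard <- function(a, b, k) {
  ka <- kmerSet(a, k); kb <- kmerSet(b, k)
  length(intersect(ka, kb)) / length(union(ka, kb))
}

# Small paired-read fixture around a known genome; memoized so repeated
# use across test files costs one construction.
.fixtureCache <- new.env()

makeFixture <- function(genomeLen = 20000, repeatLen = 1000, copies = 2,
                        coverage = 40, readLen = 100, eps = 0.01,
                        insertMean = 1500, insertSd = 150, seed = 42,
                        readSeed = 7) {
  key <- paste("fx", genomeLen, repeatLen, copies, coverage, readLen, eps,
               insertMean, insertSd, seed, readSeed, sep = "_")
  got <- .fixtureCache[[key]]
  if (!is.null(got)) return(got)
  g <- randomGenome(genomeLen,
                    repeats = if (repeatLen > 0)
                      list(list(length = repeatLen, copies = copies,
                                divergence = 0)) else NULL,
                    seed = seed)
  rs <- simulateReads(g$genome, coverage = coverage, readLength = readLen,
                      errorRate = eps, paired = TRUE,
                      insertMean = insertMean, insertSd = insertSd,
                      name = "pe", seed = readSeed)
  res <- list(genome = g$genome, repeats = g$repeats, readset = rs, key = key)
  .fixtureCache[[key]] <- res
  res
}

# Memoized conservative graph of a fixture.
fixtureGraph <- function(fx, kmerSize = 21) {
  key <- paste0(fx$key, "_graph", kmerSize)
  got <- .fixtureCache[[key]]
  if (!is.null(got)) return(got)
  g <- buildConservativeGraph(fx$readset, kmerSize = kmerSize)
  .fixtureCache[[key]] <- g
  g
}
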