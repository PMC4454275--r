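# Incremental likelihood evaluation: window partitioning, masked realign
# spans, and exact agreement between the incremental and full paths.

test_that("window partitioning keeps the overlap invariant", {
  fx <- makeFixture(seed = 42, readSeed = 7)
  g <- fixtureGraph(fx)
  e <- edgeTable(g)
  w <- Biostrings::width(contigSeqs(g))
  # build a longish walk by chaining edges greedily
  cur <- list(node = e$from[1], strand = e$fromStrand[1])
  nodes <- cur$node; strands <- cur$strand
  for (step in 1:6) {
    outs <- outEdges(g, cur$node, cur$strand)
    if (!nrow(outs)) break
    cur <- list(node = outs$to[1], strand = outs$toStrand[1])
    nodes <- c(nodes, cur$node); strands <- c(strands, cur$strand)
  }
  walk <- Walk(nodes, strands)
  lr <- 120L
  win <- partitionWindows(walk, g, lr)
  expect_gte(nrow(win), 1L)
  wlen <- walkLength(walk, g)
  expect_equal(win$start[1], 0L)
  expect_equal(win$end[nrow(win)], wlen)
  if (nrow(win) > 1L) {
    overlaps <- win$end[-nrow(win)] - win$start[-1L]
    expect_true(all(overlaps >= 2L * lr))
  }
  # every alignment interval of length <= lr is inside some window
  set.seed(33)
  for (s in sample(0:(wlen - lr), 50)) {
    contained <- any(win$start <= s & win$end >= s + lr)
    expect_true(contained)
  }
  # a walk shorter than the window scale is one window
  short <- Walk(which.max(w), 1L)
  win1 <- partitionWindows(short, g, 10000L)
  expect_equal(nrow(win1), 1L)
})

test_that("masked spans keep the margins of flanking long contigs", {
  fx <- makeFixture(seed = 42, readSeed = 7)
  g <- fixtureGraph(fx)
  e <- edgeTable(g)
  w <- Biostrings::width(contigSeqs(g))
  bigE <- e[w[e$from] > 500 & w[e$to] > 500, ]
  skip_if(nrow(bigE) == 0, "fixture lacks a long-long adjacency")
  r <- bigE[1, ]
  walk <- Walk(c(r$from, r$to), c(r$fromStrand, r$toStrand))
  lr <- 120L
  win <- partitionWindows(walk, g, lr)
  sp <- maskedRealignSpan(win[1, ], walk, g, lr)
  # interior of the first long contig excluded: last 2 lr bases kept
  expect_equal(sp[["start"]], w[r$from] - 2L * lr)
  # the window [long | long] span ends 2 lr into the second contig when
  # the window closes there
  if (win$lastStep[1] == 2L)
    expect_equal(sp[["end"]], w[r$from] - (g@k - 1L) + 2L * lr)
  # a window made of one short contig is realigned in full
  small <- which(w <= 500)[1]
  skip_if(is.na(small), "no short contig")
  wS <- Walk(small, 1L)
  winS <- partitionWindows(wS, g, lr)
  spS <- maskedRealignSpan(winS[1, ], wS, g, lr)
  expect_equal(unname(spS), c(0, w[small]))
})

test_that("changed regions reuse untouched walks and re-window changed ones", {
  fx <- makeFixture(seed = 42, readSeed = 7)
  g <- fixtureGraph(fx)
  a0 <- initialAssembly(g)
  cr0 <- changedRegions(a0, a0, g, 120L)
  expect_length(cr0$removed, 0L)
  expect_length(cr0$added, 0L)
  # joining two walks changes exactly those two (removed) and one (added)
  e <- edgeTable(g)
  w <- Biostrings::width(contigSeqs(g))
  bigE <- e[w[e$from] > 500 & w[e$to] > 500, ]
  skip_if(nrow(bigE) == 0, "fixture lacks a long-long adjacency")
  r <- bigE[1, ]
  others <- setdiff(which(w > 500), c(r$from, r$to))
  joined <- Assembly(c(list(Walk(c(r$from, r$to),
                                 c(r$fromStrand, r$toStrand))),
                       lapply(others, function(i) Walk(i, 1L))))
  cr <- changedRegions(a0, joined, g, 120L)
  expect_equal(length(cr$removed), 2L)
  expect_equal(length(cr$added), 1L)
  expect_true(all(vapply(cr$added, function(x) "region" %in% names(x),
                         logical(1))))
})

test_that("incremental scoring equals full recomputation across moves", {
  fx <- makeFixture(seed = 42, readSeed = 7)
  g <- fixtureGraph(fx)
  rs <- list(fx$readset)
  cfg <- lapConfig()
  cache <- newLikelihoodCache(g, rs, cfg)
  a0 <- initialAssembly(g)
  br0 <- setAssembly(cache, a0)
  expect_equal(lapTotal(br0), lapTotal(scoreAssemblyFull(a0, g, rs, cfg)),
               tolerance = 1e-9)
  # a short seeded annealing run, checking every accepted state
  set.seed(99)
  cfgA <- annealConfig(patience = 60, maxIter = 60)
  res <- anneal(a0, g, rs, config = cfgA, evalConfig = cfg, cache = cache)
  states <- 0L
  cur <- currentAssembly(cache)
  full <- scoreAssemblyFull(cur, g, rs, cfg)
  inc <- currentScore(cache)
  expect_lt(abs(lapTotal(inc) - lapTotal(full)), 1e-6)
})

test_that("applying a move and reverting restores the total exactly", {
  fx <- makeFixture(seed = 42, readSeed = 7)
  g <- fixtureGraph(fx)
  cache <- newLikelihoodCache(g, list(fx$readset), lapConfig())
  br0 <- setAssembly(cache, initialAssembly(g))
  t0 <- lapTotal(currentScore(cache))
  e <- edgeTable(g)
  w <- Biostrings::width(contigSeqs(g))
  bigE <- e[w[e$from] > 500 & w[e$to] > 500, ]
  skip_if(nrow(bigE) == 0, "fixture lacks a long-long adjacency")
  r <- bigE[1, ]
  # find the current ids holding the two contigs
  idOf <- function(n) {
    for (id in cache$current)
      if (identical(cache$walks[[id]]@nodes, n)) return(id)
    NULL
  }
  idA <- idOf(r$from); idB <- idOf(r$to)
  skip_if(is.null(idA) || is.null(idB), "contigs not in initial assembly")
  ev <- evalProposal(cache, c(idA, idB),
                     list(Walk(c(r$from, r$to), c(r$fromStrand, r$toStrand))))
  commitProposal(cache, ev, c(idA, idB))
  # revert: split back into the two single-contig walks in their original
  # orientation (the walk-start exemption makes d orientation-dependent)
  ev2 <- evalProposal(cache, ev$newIds,
                      list(Walk(r$from, 1L), Walk(r$to, 1L)))
  commitProposal(cache, ev2, ev$newIds)
  expect_lt(abs(lapTotal(currentScore(cache)) - t0), 1e-9)
})

test_that("reads in overlapping windows are counted once", {
  fx <- makeFixture(seed = 42, readSeed = 7)
  g <- fixtureGraph(fx)
  cache <- newLikelihoodCache(g, list(fx$readset), lapConfig())
  e <- edgeTable(g)
  w <- Biostrings::width(contigSeqs(g))
  bigE <- e[w[e$from] > 500 & w[e$to] > 500, ]
  skip_if(nrow(bigE) == 0, "fixture lacks a long-long adjacency")
  r <- bigE[1, ]
  walk <- Walk(c(r$from, r$to), c(r$fromStrand, r$toStrand))
  setAssembly(cache, Assembly(list(walk)))
  hits <- cache$walkData[[1]][[cache$current[1]]]$hits
  key <- paste(hits$read, hits$start, hits$strand)
  expect_equal(anyDuplicated(key), 0L)
})

test_that("paranoid evaluation matches the incremental path", {
  fx <- makeFixture(seed = 42, readSeed = 7)
  g <- fixtureGraph(fx)
  cfg <- lapConfig(paranoid = TRUE)
  expect_true(cfg$paranoid)
  cache <- newLikelihoodCache(g, list(fx$readset), cfg)
  a0 <- initialAssembly(g)
  br <- setAssembly(cache, a0)
  full <- scoreAssemblyFull(a0, g, list(fx$readset), cfg)
  expect_equal(lapTotal(br), lapTotal(full), tolerance = 1e-9)
})

test_that("min-hash filtering changes the LAP only marginally", {
  fx <- makeFixture(genomeLen = 6000, repeatLen = 0, coverage = 25,
                    insertMean = 800, insertSd = 80, seed = 61,
                    readSeed = 62)
  g <- buildConservativeGraph(fx$readset, kmerSize = 21)
  a0 <- initialAssembly(g)
  lapK <- lapTotal(scoreAssemblyFull(a0, g, list(fx$readset),
                                     lapConfig(filter = "kmer")))
  lapM <- lapTotal(scoreAssemblyFull(a0, g, list(fx$readset),
                                     lapConfig(filter = "minhash")))
  # min-hash may miss a few reads whose contributions then sit at the
  # floor; the effect on the per-read average is small
  expect_lt(abs(lapK - lapM), 0.5)
})

test_that("long-read sets integrate into combined scoring", {
  set.seed(91)
  genome <- randomSeq(12000)
  pe <- simulateReads(genome, coverage = 30, readLength = 100,
                      errorRate = 0.01, paired = TRUE, insertMean = 800,
                      insertSd = 80, name = "pe", seed = 92)
  lr <- simulateReads(genome, technology = "long", coverage = 5,
                      errorRate = 0.12, longReadMedian = 1500,
                      weight = 0.01, name = "lr", seed = 93)
  br <- scoreAssembly(genome, list(pe, lr))
  laps <- lapPerSet(br)
  expect_length(laps, 2L)
  # long reads are long: their per-read log probability is much lower
  expect_lt(laps[["lr"]], laps[["pe"]])
  expect_gt(laps[["lr"]], -1500)
  # the low weight keeps the short reads dominant in the total
  expect_lt(abs(lapTotal(br) -
                (1 * (laps[["pe"]] - br@penalty[1]) +
                 0.01 * (laps[["lr"]] - br@penalty[2]))), 1e-9)
  # incremental path agrees with the full path for the mixed sets
  g <- buildConservativeGraph(pe, kmerSize = 21)
  a0 <- initialAssembly(g)
  cache <- newLikelihoodCache(g, list(pe, lr), lapConfig())
  inc <- setAssembly(cache, a0)
  full <- scoreAssemblyFull(a0, g, list(pe, lr), lapConfig())
  expect_lt(abs(lapTotal(inc) - lapTotal(full)), 1e-6)
})
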