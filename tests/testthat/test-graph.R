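# Conservative de Bruijn graph construction, walks, loop enumeration, and
# external-assembly mapping.

test_that("error-free reads of a repeat-free genome condense to one contig", {
  set.seed(21)
  genome <- randomSeq(2000)
  rs <- simulateReads(genome, coverage = 30, readLength = 100,
                      errorRate = 0, seed = 2)
  g <- buildConservativeGraph(rs, kmerSize = 21)
  w <- Biostrings::width(contigSeqs(g))
  main <- as.character(contigSeqs(g)[[which.max(w)]])
  expect_true(main == genome || main == rcSeq(genome) ||
              grepl(main, genome, fixed = TRUE) ||
              grepl(rcSeq(main), genome, fixed = TRUE))
  expect_gte(max(w), 1900)
})

test_that("an exact repeat longer than k collapses to one branching node", {
  set.seed(22)
  unit <- randomSeq(300)
  genome <- paste0(randomSeq(800), unit, randomSeq(900), unit, randomSeq(700))
  rs <- simulateReads(genome, coverage = 30, readLength = 100,
                      errorRate = 0, seed = 3)
  g <- buildConservativeGraph(rs, kmerSize = 21)
  ctg <- as.character(contigSeqs(g))
  # exactly one contig carries the repeat interior
  inner <- substr(unit, 11, 290)
  core <- vapply(ctg, function(s)
    grepl(inner, s, fixed = TRUE) || grepl(inner, rcSeq(s), fixed = TRUE),
    logical(1))
  expect_equal(sum(core), 1L)
  rep_id <- which(core)
  e <- edgeTable(g)
  expect_gte(sum(e$from == rep_id & e$fromStrand == 1L), 2L)
  expect_gte(sum(e$to == rep_id & e$toStrand == 1L), 2L)
})

test_that("1%-error reads give contigs covering the genome without misjoins", {
  fx <- makeFixture(genomeLen = 20000, seed = 42, readSeed = 7)
  g <- fixtureGraph(fx)
  ctg <- contigSeqs(g)
  big <- ctg[Biostrings::width(ctg) >= 100]
  covered <- sum(Biostrings::width(big))
  # the repeat is collapsed, so contig bases cover >= 99% of the
  # non-redundant genome (20 kb minus one 1 kb repeat copy)
  expect_gte(covered, 0.99 * (20000 - 1000))
  mj <- misjoinCount(big, fx$genome)
  expect_equal(mj$misjoins, 0L)
})

test_that("graph construction is strand-symmetric", {
  set.seed(23)
  genome <- randomSeq(1500)
  rs <- simulateReads(genome, coverage = 25, readLength = 80,
                      errorRate = 0, seed = 4)
  g1 <- buildConservativeGraph(rs, kmerSize = 21)
  rcReads <- ReadSet(Biostrings::reverseComplement(rs@reads),
                     params = rs@params, name = "rc")
  g2 <- buildConservativeGraph(rcReads, kmerSize = 21)
  canon <- function(g) sort(pmin(as.character(contigSeqs(g)),
                                 vapply(as.character(contigSeqs(g)), rcSeq,
                                        character(1))))
  expect_equal(canon(g1), canon(g2))
  expect_equal(nrow(edgeTable(g1)), nrow(edgeTable(g2)))
})

test_that("condensation preserves the retained k-mer spectrum", {
  set.seed(24)
  genome <- randomSeq(1200)
  rs <- simulateReads(genome, coverage = 30, readLength = 80,
                      errorRate = 0, seed = 5)
  g <- buildConservativeGraph(rs, kmerSize = 21)
  ctgK <- unlist(lapply(as.character(contigSeqs(g)), kmerSet, k = 21))
  readK <- kmerSet(paste(as.character(rs@reads), collapse = "NN"), 21)
  # every contig k-mer was observed in the reads
  expect_true(all(ctgK %in% readK))
  # contig k-mers are not duplicated across nodes
  expect_equal(anyDuplicated(ctgK), 0L)
})

test_that("coverage threshold failure gives a clear diagnostic", {
  expect_error(buildConservativeGraph(
    ReadSet(Biostrings::DNAStringSet(c(a = randomSeq(50))),
            params = ModelParams(), name = "x"), kmerSize = 21),
    "coverage|contig")
})

test_that("initial assembly takes one walk per long contig", {
  fx <- makeFixture(seed = 42, readSeed = 7)
  g <- fixtureGraph(fx)
  w <- Biostrings::width(contigSeqs(g))
  asm <- initialAssembly(g)
  expect_equal(length(walks(asm)), sum(w > 500))
  # a lower threshold yields at least as many walks
  asm2 <- initialAssembly(g, longThreshold = 22L)
  expect_gte(length(walks(asm2)), length(walks(asm)))
  # all contigs short: degenerate input rejected
  tiny <- new("AssemblyGraph",
              contigs = Biostrings::DNAStringSet(c(a = randomSeq(40))),
              edges = data.frame(from = integer(), fromStrand = integer(),
                                 to = integer(), toStrand = integer()),
              k = 21L, coverage = 1)
  expect_error(initialAssembly(tiny), "long")
})

test_that("walk sequences merge overlaps and emit N-gaps", {
  fx <- makeFixture(seed = 42, readSeed = 7)
  g <- fixtureGraph(fx)
  e <- edgeTable(g)
  r <- e[1, ]
  w2 <- Walk(c(r$from, r$to), c(r$fromStrand, r$toStrand))
  lens <- Biostrings::width(contigSeqs(g))
  expect_equal(nchar(walkSequence(w2, g)),
               lens[r$from] + lens[r$to] - (g@k - 1L))
  # single node
  w1 <- Walk(r$from, 1L)
  expect_equal(walkSequence(w1, g), as.character(contigSeqs(g)[[r$from]]))
  # gap steps emit N runs and suppress the overlap merge
  wg <- Walk(c(r$from, NA, r$to), c(r$fromStrand, NA, r$toStrand),
             c(NA, 25L, NA))
  expect_equal(nchar(walkSequence(wg, g)), lens[r$from] + 25L + lens[r$to])
  expect_true(grepl(strrep("N", 25), walkSequence(wg, g), fixed = TRUE))
  # an invalid edge is rejected
  bad <- Walk(c(r$from, r$from), c(1L, 1L))
  if (!lapasm:::.hasEdge(g, r$from, 1L, r$from, 1L))
    expect_error(walkSequence(bad, g), "edge")
})

test_that("a walk visiting a node twice emits the repeat twice", {
  fx <- makeFixture(seed = 42, readSeed = 7)
  g <- fixtureGraph(fx)
  # locate the collapsed repeat contig: ~1 kb with 2 in- and out-edges
  w <- Biostrings::width(contigSeqs(g))
  e <- edgeTable(g)
  rep_id <- which(w > 900 & w < 1100)[1]
  expect_false(is.na(rep_id))
  repseq <- as.character(contigSeqs(g)[[rep_id]])
  truth <- as.character(fx$genome)
  # the repeat occurs twice in the genome
  n_occ <- length(gregexpr(substr(repseq, 50, nchar(repseq) - 50), truth,
                           fixed = TRUE)[[1]])
  n_occ_rc <- length(gregexpr(rcSeq(substr(repseq, 50, nchar(repseq) - 50)),
                              truth, fixed = TRUE)[[1]])
  expect_equal(max(n_occ, n_occ_rc), 2L)
})

test_that("short loops are enumerated exhaustively", {
  # hand-built graph: a tandem repeat A -> B -> A plus a linear tail
  contigs <- Biostrings::DNAStringSet(c(a = randomSeq(60), b = randomSeq(40),
                                        c = randomSeq(50)))
  edges <- data.frame(
    from = c(1L, 2L, 1L, 2L, 1L, 3L),
    fromStrand = c(1L, 1L, -1L, -1L, 1L, -1L),
    to = c(2L, 1L, 2L, 1L, 3L, 1L),
    toStrand = c(1L, 1L, -1L, -1L, 1L, -1L))
  g <- new("AssemblyGraph", contigs = contigs, edges = edges, k = 21L,
           coverage = c(1, 1, 1))
  loops <- enumerateShortLoops(g)
  expect_gte(length(loops), 2L) # the 2-node loop in both orientations
  sizes <- vapply(loops, nrow, integer(1))
  expect_true(all(sizes <= 5L))
  has2 <- any(vapply(loops, function(l)
    nrow(l) == 2L && setequal(l$node, c(1L, 2L)), logical(1)))
  expect_true(has2)
  # an acyclic graph has no loops
  g2 <- new("AssemblyGraph", contigs = contigs,
            edges = edges[c(1, 5), ], k = 21L, coverage = c(1, 1, 1))
  expect_length(enumerateShortLoops(g2), 0L)
})

test_that("external contigs map back to walks on the graph", {
  fx <- makeFixture(seed = 42, readSeed = 7)
  g <- fixtureGraph(fx)
  w <- Biostrings::width(contigSeqs(g))
  big <- which(w > 500)
  # a contig of the graph itself maps to a single-node walk
  ext1 <- contigSeqs(g)[big[1]]
  mp <- mapExternalAssembly(ext1, g)
  expect_false(is.null(mp$assembly))
  wk <- walks(mp$assembly)[[1]]
  expect_equal(wk@nodes[!is.na(wk@nodes)], big[1])
  # a two-contig concatenation maps to the two-node walk with its edge
  e <- edgeTable(g)
  bigE <- e[w[e$from] > 500 & w[e$to] > 500, ]
  if (nrow(bigE)) {
    r <- bigE[1, ]
    w2 <- Walk(c(r$from, r$to), c(r$fromStrand, r$toStrand))
    ext2 <- Biostrings::DNAStringSet(c(joined = walkSequence(w2, g)))
    mp2 <- mapExternalAssembly(ext2, g)
    wk2 <- walks(mp2$assembly)[[1]]
    expect_equal(sum(!is.na(wk2@nodes)), 2L)
  }
  # a novel insert beyond the edit budget becomes an N-gap
  wA <- as.character(contigSeqs(g)[[big[1]]])
  wB <- as.character(contigSeqs(g)[[big[2]]])
  ext3 <- Biostrings::DNAStringSet(c(ins = paste0(wA, randomSeq(25), wB)))
  mp3 <- mapExternalAssembly(ext3, g)
  wk3 <- walks(mp3$assembly)[[1]]
  expect_true(any(is.na(wk3@nodes)))
  gl <- wk3@gapLens[is.na(wk3@nodes)]
  expect_true(any(abs(gl - 25L) <= 25L))
  # mapping an unrelated sequence reports failure for the fallback path
  set.seed(31)
  mp4 <- mapExternalAssembly(Biostrings::DNAStringSet(c(x = randomSeq(800))),
                             g)
  expect_true(is.null(mp4$assembly))
})

test_that("GFA export writes segments and links", {
  fx <- makeFixture(seed = 42, readSeed = 7)
  g <- fixtureGraph(fx)
  path <- tempfile(fileext = ".gfa")
  writeGFA(g, path)
  lines <- readLines(path)
  expect_equal(sum(startsWith(lines, "S")), length(contigSeqs(g)))
  expect_equal(sum(startsWith(lines, "L")), nrow(edgeTable(g)))
  unlink(path)
})
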