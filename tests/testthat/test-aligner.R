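# Alignment machinery: canonical hit extraction against the independent
# R oracle, candidate filtering by k-mer and min-hash indexes, and the
# banded forward algorithm for long noisy reads.

test_that("exact and near-exact reads produce the expected hits", {
  set.seed(5)
  tgt <- randomSeq(400)
  rd <- substr(tgt, 101, 200)
  h <- alignShortRead(rd, tgt)
  expect_equal(nrow(h), 1L)
  expect_equal(h$start, 100L)
  expect_equal(h$end, 200L)
  expect_equal(h$s, 0L)
  expect_equal(h$m, 100L)
  expect_equal(h$strand, 1L)
  # reverse-complement read maps to the minus strand, same coordinates
  hrc <- alignShortRead(rcSeq(rd), tgt)
  expect_equal(hrc$start, 100L)
  expect_equal(hrc$strand, -1L)
  # one substitution
  h1 <- alignShortRead(mutateSeq(rd, 1), tgt)
  expect_equal(h1$s, 1L)
  expect_equal(h1$m, 99L)
})

test_that("reads from a two-copy repeat hit both copies", {
  set.seed(6)
  unit <- randomSeq(150)
  tgt <- paste0(randomSeq(100), unit, randomSeq(120), unit, randomSeq(80))
  rd <- substr(unit, 21, 120)
  h <- alignShortRead(rd, tgt)
  expect_equal(nrow(h), 2L)
  expect_setequal(h$start, c(120L, 390L))
  # agreement with an exhaustive scan of all offsets
  ho <- oracleHits(rd, tgt, 10L)
  expect_setequal(h$start, ho$start[ho$s == 0])
})

test_that("seeded hits match the exhaustive R oracle on random instances", {
  set.seed(7)
  for (trial in 1:15) {
    tgt <- randomSeq(sample(150:400, 1))
    src <- sample(nchar(tgt) - 60, 1)
    rd <- mutateSeq(substr(tgt, src, src + 59), sample(0:3, 1))
    kmax <- as.integer(ceiling(0.1 * nchar(rd)))
    got <- alignShortRead(rd, tgt, maxHits = Inf)
    want <- oracleHits(rd, tgt, kmax)
    key <- function(h) sort(paste(h$start, h$strand, h$s, h$m))
    expect_equal(key(got), key(want), info = paste("trial", trial))
  }
})

test_that("tiny reads fall back to exhaustive scanning", {
  tgt <- "ACGTACGTTAGCCGATCGA"
  rd <- "TAGCCGA"
  h <- alignShortRead(rd, tgt, maxEditFraction = 0)
  expect_equal(h$start, 8L)
  expect_equal(h$s, 0L)
})

test_that("min-hash of identical k-mer sets always collides", {
  set.seed(8)
  x <- randomSeq(60)
  seeds <- 1:25
  expect_equal(minHash(kmerSet(x, 13), seeds), minHash(kmerSet(x, 13), seeds))
  # disjoint k-mer sets collide essentially never
  y <- randomSeq(60)
  expect_lt(mean(minHash(kmerSet(x, 13), 1:200) ==
                 minHash(kmerSet(y, 13), 1:200)), 0.05)
  expect_error(minHash(character(), 1), "empty")
})

test_that("min-hash collision frequency estimates Jaccard similarity", {
  set.seed(9)
  base <- randomSeq(200)
  other <- mutateSeq(base, 6)
  J <- oracleJaccard(base, other, 13)
  expect_gt(J, 0.1); expect_lt(J, 0.95)
  seeds <- 1:800
  coll <- mean(minHash(kmerSet(base, 13), seeds) ==
               minHash(kmerSet(other, 13), seeds))
  sigma <- sqrt(J * (1 - J) / length(seeds))
  expect_lt(abs(coll - J), 3 * sigma + 1e-9)
})

test_that("candidate filtering retrieves the right reads", {
  set.seed(10)
  genome <- randomSeq(3000)
  rs <- simulateReads(genome, coverage = 15, readLength = 80,
                      errorRate = 0.01, seed = 3)
  reads <- as.character(rs@reads)
  target <- substr(genome, 1001, 1600)
  kidx <- readKmerIndex(reads)
  midx <- readMinHashIndex(reads, numHashes = 3)
  ck <- candidateReads(target, kidx)
  cm <- candidateReads(target, midx, readLength = 80L)
  # ground truth: reads whose error-free source lies inside the target
  hits <- lapply(seq_along(reads), function(i)
    lapasm:::.scanReads(target, reads[i], i, 0.1, 13L, "seeded"))
  inTarget <- which(vapply(hits, nrow, integer(1)) > 0)
  recallK <- mean(inTarget %in% ck)
  recallM <- mean(inTarget %in% cm)
  expect_gte(recallK, 0.99)
  expect_gte(recallM, 0.8)
  # min-hash retrieves far fewer candidates than the k-mer index relative
  # to its yield (higher specificity), at slightly lower sensitivity
  precK <- length(intersect(ck, inTarget)) / length(ck)
  precM <- length(intersect(cm, inTarget)) / length(cm)
  expect_gt(precM, precK)
  # a target sharing no k-mer with any read returns nothing
  expect_length(candidateReads(strrep("A", 300), kidx), 0)
})

test_that("banded forward mass behaves around a guide alignment", {
  set.seed(11)
  tgt <- randomSeq(200)
  rd <- substr(tgt, 51, 80) # 30 bp perfect read
  guide <- cbind(0:30, 50:80) # exact diagonal path
  eps <- 1e-4
  # band 0 equals exactly the guide path weight R(s, m)
  expect_equal(bandedForward(rd, tgt, guide, band = 0, errorRate = eps),
               30 * log(1 - eps), tolerance = 1e-9)
  # mass is nondecreasing in band width
  m0 <- bandedForward(rd, tgt, guide, band = 0, errorRate = 0.1)
  m1 <- bandedForward(rd, tgt, guide, band = 1, errorRate = 0.1)
  m3 <- bandedForward(rd, tgt, guide, band = 3, errorRate = 0.1)
  expect_lte(m0, m1)
  expect_lte(m1, m3)
  # a noisy 30 bp read: banded mass within a factor 2 of the full forward
  noisy <- mutateSeq(rd, 3)
  mb <- bandedForward(noisy, tgt, guide, band = 3, errorRate = 0.1)
  mf <- oracleForwardLog(noisy, tgt, 0.1)
  expect_lt(abs(mb - mf), log(2))
  # with a wide band it converges to the unbanded value
  mwide <- bandedForward(noisy, tgt, guide, band = 200, errorRate = 0.1)
  expect_equal(mwide, mf, tolerance = 1e-6)
})

test_that("long-read guide alignment finds noisy placements", {
  set.seed(12)
  genome <- randomSeq(4000)
  rs <- simulateReads(genome, technology = "long", coverage = 3,
                      errorRate = 0.12, longReadMedian = 800, seed = 4)
  found <- 0L
  for (i in seq_along(rs@reads)) {
    g <- longReadGuide(as.character(rs@reads[[i]]), genome,
                       errorRate = 0.12)
    if (nrow(g)) found <- found + 1L
  }
  expect_gte(found / length(rs@reads), 0.9)
})

test_that("contig/long-read overlap candidates respect the length floor", {
  set.seed(13)
  genome <- randomSeq(3000)
  contigs <- Biostrings::DNAStringSet(c(
    big = substr(genome, 501, 1500),
    small = substr(genome, 2000, 2049))) # 50 bp: below the floor
  rs <- simulateReads(genome, technology = "long", coverage = 2,
                      errorRate = 0.15, longReadMedian = 900, seed = 5)
  pairs <- longReadCandidates(contigs, rs@reads)
  expect_true(all(pairs$contig == 1L))
  # a 15%-error read overlapping the big contig is reported
  expect_gt(nrow(pairs), 0)
})
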