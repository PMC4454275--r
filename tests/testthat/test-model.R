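# The read-probability model: alignment weights, single and paired read
# probabilities, no-alignment floors, LAP averaging, the connectivity
# penalty, and the weighted combination.

hitRow <- function(start, s, m, strand = 1L, walk = 1L) {
  data.frame(read = 1L, start = start, end = start + m + s, strand = strand,
             s = s, m = m, walk = walk)
}

test_that("single-read probability follows the alignment-weight sum", {
  p <- ModelParams(errorRate = 0)
  # error-free single occurrence reduces to n_r / (2L)
  expect_equal(singleReadProbability(hitRow(0, 0L, 10L), 100, p), 1 / 200)
  hits <- do.call(rbind, lapply(c(0, 30, 60), hitRow, s = 0L, m = 10L))
  expect_equal(singleReadProbability(hits, 100, p), 3 / 200)
  # one imperfect hit at eps = 0.01
  p2 <- ModelParams(errorRate = 0.01)
  expect_equal(singleReadProbability(hitRow(5, 1L, 9L), 50, p2),
               0.01 * 0.99^9 / 100)
  # empty hit set yields 0 (floor applied by the caller)
  expect_equal(singleReadProbability(hitRow(0, 0L, 5L)[0, ], 50, p2), 0)
  expect_error(singleReadProbability(hitRow(0, 0L, 5L), 0, p2),
               "genomeLength")
})

test_that("perfect hits with nonzero error rate are weighted (1-eps)^m", {
  p <- ModelParams(errorRate = 0.05)
  expect_equal(singleReadProbability(hitRow(0, 0L, 20L), 1000, p),
               0.95^20 / 2000)
})

test_that("paired probability multiplies weights by the insert density", {
  p <- ModelParams(errorRate = 0, insertMean = 200, insertSd = 20)
  h1 <- hitRow(0, 0L, 50L, strand = 1L)
  # mate aligned so the outer span is exactly mu
  h2 <- data.frame(read = 1L, start = 150, end = 200, strand = -1L,
                   s = 0L, m = 50L, walk = 1L)
  expect_equal(pairedReadProbability(h1, h2, 1000, p),
               dnorm(200, 200, 20) / 2000)
  # different walks contribute zero
  h2b <- h2; h2b$walk <- 2L
  expect_equal(pairedReadProbability(h1, h2b, 1000, p), 0)
  # same strand is inconsistent
  h2c <- h2; h2c$strand <- 1L
  expect_equal(pairedReadProbability(h1, h2c, 1000, p), 0)
  expect_error(pairedReadProbability(h1, h2, 1000, ModelParams()),
               "insert")
})

test_that("paired probability sums over all consistent placements", {
  p <- ModelParams(errorRate = 0, insertMean = 200, insertSd = 20)
  h1 <- hitRow(0, 0L, 50L, strand = 1L)
  h2 <- data.frame(read = c(1L, 1L), start = c(150, 210), end = c(200, 260),
                   strand = c(-1L, -1L), s = c(0L, 0L), m = c(50L, 50L),
                   walk = c(1L, 1L))
  # brute-force the double sum over the placements
  want <- (dnorm(200, 200, 20) + dnorm(260, 200, 20)) / 2000
  expect_equal(pairedReadProbability(h1, h2, 1000, p), want)
  # the term at distance mu dominates the one 3 sigma away
  expect_gt(dnorm(200, 200, 20), 10 * dnorm(260, 200, 20))
})

test_that("no-alignment floor is exp(c + k * total length)", {
  p <- ModelParams(noalignOffset = -10, noalignScale = -0.1)
  expect_equal(noAlignmentFloor(100, p), exp(-20))
  # a pair's floor is strictly below the single-read floor when k < 0
  expect_lt(noAlignmentFloor(c(100, 100), p), noAlignmentFloor(100, p))
  expect_equal(noAlignmentFloor(c(100, 100), p), exp(-10 - 0.1 * 200))
  expect_error(noAlignmentFloor(0, p))
})

test_that("floors keep unaligned reads from zeroing the likelihood", {
  p <- ModelParams(errorRate = 0.01)
  pr <- singleReadProbability(hitRow(0, 0L, 5L)[0, ], 100, p)
  floor <- noAlignmentFloor(100, p)
  expect_equal(max(pr, floor), floor)
  expect_gt(floor, 0)
})

test_that("readSetLap averages natural-log probabilities", {
  expect_equal(readSetLap(rep(0.01, 5)), log(0.01))
  expect_equal(readSetLap(c(0.1, 0.001)), (log(0.1) + log(0.001)) / 2)
  expect_error(readSetLap(numeric()), "empty")
  expect_error(readSetLap(c(0.1, 0)), "floor")
})

test_that("connectivity penalty matches the per-base brute force", {
  p <- ModelParams(penaltyAlpha = 3, connWindow = 10L)
  # nothing aligned: every base disconnected (no walk-start exemption)
  none <- data.frame(walk = character(), start = integer(), end = integer())
  r <- connectivityPenalty(c(w1 = 50L), none, p, exemptWalkStart = FALSE)
  expect_equal(r$d, 50L)
  expect_equal(r$penalty, 150)
  # fully tiled 50 bp walk: overlapping long spans starting every 5 bases
  spans <- data.frame(walk = "w1", start = seq(0L, 30L, by = 5L),
                      end = pmin(seq(0L, 30L, by = 5L) + 25L, 50L))
  for (ex in c(TRUE, FALSE)) {
    got <- connectivityPenalty(c(w1 = 50L), spans, p, exemptWalkStart = ex)
    want <- oracleDisconnected(50L, spans$start, spans$end, 10L, ex)
    expect_equal(got$d, want)
  }
  # without the exemption the first k-1+1 bases can never be connected
  got <- connectivityPenalty(c(w1 = 50L), spans, p, exemptWalkStart = FALSE)
  expect_equal(got$d, 10L)
  expect_equal(
    connectivityPenalty(c(w1 = 50L), spans, p, exemptWalkStart = TRUE)$d, 0L)
})

test_that("a coverage gap increases the disconnected count by its size", {
  p <- ModelParams(penaltyAlpha = 1, connWindow = 10L)
  tiled <- data.frame(walk = "w1",
                      start = seq(0L, 80L, by = 5L),
                      end = seq(0L, 80L, by = 5L) + 20L)
  # removing the spans starting in [30, 60) leaves bases [45, 60) covered
  # by no span at all: a true coverage gap of 15 bases
  gappy <- tiled[tiled$start < 30 | tiled$start >= 60, ]
  d0 <- connectivityPenalty(c(w1 = 100L), tiled, p)$d
  d1 <- connectivityPenalty(c(w1 = 100L), gappy, p)$d
  expect_gte(d1 - d0, 15L)
  # brute-force agreement on the gappy case
  expect_equal(d1, oracleDisconnected(100L, gappy$start, gappy$end, 10L))
})

test_that("random span layouts agree with the brute-force definition", {
  set.seed(11)
  p <- ModelParams(penaltyAlpha = 2, connWindow = 7L)
  for (trial in 1:20) {
    len <- sample(30:80, 1)
    ns <- sample(0:8, 1)
    starts <- if (ns) sort(sample(0:(len - 5), ns, replace = TRUE)) else integer()
    ends <- pmin(starts + sample(5:30, max(ns, 1), replace = TRUE)[seq_len(ns)],
                 len)
    spans <- data.frame(walk = rep("w", length(starts)), start = starts,
                        end = ends)
    for (ex in c(TRUE, FALSE)) {
      got <- connectivityPenalty(stats::setNames(len, "w"), spans, p,
                                 exemptWalkStart = ex)$d
      expect_equal(got, oracleDisconnected(len, starts, ends, 7L, ex))
    }
  }
})

test_that("combinedLap weights per-set terms with their own penalties", {
  p1 <- ModelParams(weight = 1, penaltyAlpha = 3)
  p2 <- ModelParams(weight = 0.01, penaltyAlpha = 2)
  br <- combinedLap(c(-20, -30), c(0L, 5L), list(p1, p2))
  expect_equal(lapTotal(br), 1 * (-20) + 0.01 * (-30 - 10))
  # single set, unit weight, no penalty: identity
  expect_equal(lapTotal(combinedLap(-25, 0L, list(p1))), -25)
  # a zero-weight set contributes nothing at all
  p0 <- ModelParams(weight = 0, penaltyAlpha = 100)
  expect_equal(lapTotal(combinedLap(c(-20, -999), c(0L, 999L),
                                    list(p1, p0))), -20)
  # permuting sets with their weights leaves the total unchanged
  expect_equal(lapTotal(combinedLap(c(-30, -20), c(5L, 0L), list(p2, p1))),
               lapTotal(br))
  # linear in weights
  p2b <- ModelParams(weight = 0.02, penaltyAlpha = 2)
  br2 <- combinedLap(c(-20, -30), c(0L, 5L), list(p1, p2b))
  expect_equal(lapTotal(br2) - lapTotal(br), 0.01 * (-30 - 10))
  expect_error(combinedLap(c(-1, -2), 0L, list(p1)), "align")
})

test_that("model parameter validity is enforced", {
  expect_error(ModelParams(errorRate = 1.2), "errorRate")
  expect_error(ModelParams(weight = -1), "weight")
  expect_error(ModelParams(insertMean = 100, insertSd = -5), "insertSd")
  expect_error(ModelParams(orientation = "xx"), "orientation")
})
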