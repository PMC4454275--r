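# The assembly likelihood model: per-read and paired-read probabilities
# estimated from a set of best alignments, no-alignment floors, the
# connectivity penalty for spurious joins, and the weighted combination of
# per-dataset log average probabilities (LAP).

#' Alignment weights R(s, m)
#'
#' The probability weight of a single alignment with `m` matching positions
#' and `s` errors (substitutions and indels share one error rate):
#' \eqn{R(s,m) = \epsilon^s (1-\epsilon)^m}.
#'
#' @param s integer vector of error counts.
#' @param m integer vector of match counts.
#' @param errorRate per-base error rate \eqn{\epsilon}.
#' @return Numeric vector of weights.
#' @export
alignmentWeight <- function(s, m, errorRate) {
  if (errorRate == 0) ifelse(s == 0, 1, 0) * (1 - errorRate)^m
  else errorRate^s * (1 - errorRate)^m
}

.checkHits <- function(hits) {
  need <- c("start", "strand", "s", "m")
  if (!all(need %in% names(hits)))
    stop("hit table needs columns ", paste(need, collapse = ", "))
  invisible(hits)
}

#' Probability of observing a single read
#'
#' Estimates \eqn{\Pr(r|A) \approx \sum_{j \in S_r} R(s_j, m_j) / (2L)} from
#' a set of best alignments, where \eqn{L} is the assembly length (2L is the
#' length of the two strands combined).  An empty hit set yields 0; the
#' caller substitutes the no-alignment floor (see [noAlignmentFloor()]).
#'
#' @param hits data.frame of alignments with columns `start`, `strand`, `s`
#'   (errors), `m` (matches); may have zero rows.
#' @param genomeLength assembly length \eqn{L} in bases.
#' @param params a [ModelParams-class] supplying \eqn{\epsilon}.
#' @return A probability (0 for an empty hit set).
#' @export
singleReadProbability <- function(hits, genomeLength, params) {
  if (genomeLength < 1) stop("genomeLength must be >= 1")
  if (nrow(hits) == 0L) return(0)
  .checkHits(hits)
  sum(alignmentWeight(hits$s, hits$m, params@errorRate)) / (2 * genomeLength)
}

# Consistent mate combinations of two per-walk hit tables.  Mates must lie
# on the same walk on opposite strands; for "fr" libraries the plus-strand
# mate must be the leftmost, for "rf" the minus-strand mate.  Returns one
# row per consistent combination: the insert length d (outermost span) and
# the combined alignment weight R1*R2.
.pairCombos <- function(hits1, hits2, params) {
  if (nrow(hits1) == 0L || nrow(hits2) == 0L)
    return(data.frame(walk = integer(), d = integer(), w = numeric(),
                      start = integer(), end = integer()))
  byWalk1 <- if ("walk" %in% names(hits1)) hits1$walk else rep(1L, nrow(hits1))
  byWalk2 <- if ("walk" %in% names(hits2)) hits2$walk else rep(1L, nrow(hits2))
  i <- rep(seq_len(nrow(hits1)), times = nrow(hits2))
  j <- rep(seq_len(nrow(hits2)), each = nrow(hits1))
  same <- byWalk1[i] == byWalk2[j]
  opp <- hits1$strand[i] != hits2$strand[j]
  keep <- same & opp
  i <- i[keep]; j <- j[keep]
  if (!length(i))
    return(data.frame(walk = integer(), d = integer(), w = numeric(),
                      start = integer(), end = integer()))
  plusStart <- ifelse(hits1$strand[i] == 1L, hits1$start[i], hits2$start[j])
  minusStart <- ifelse(hits1$strand[i] == 1L, hits2$start[j], hits1$start[i])
  ok <- if (params@orientation == "fr") plusStart <= minusStart
        else minusStart <= plusStart
  i <- i[ok]; j <- j[ok]
  if (!length(i))
    return(data.frame(walk = integer(), d = integer(), w = numeric(),
                      start = integer(), end = integer()))
  st <- pmin(hits1$start[i], hits2$start[j])
  en <- pmax(hits1$end[i], hits2$end[j])
  eps <- params@errorRate
  w <- alignmentWeight(hits1$s[i], hits1$m[i], eps) *
       alignmentWeight(hits2$s[j], hits2$m[j], eps)
  data.frame(walk = byWalk1[i], d = en - st, w = w, start = st, end = en)
}

#' Probability of observing a read pair
#'
#' Estimates
#' \eqn{\Pr(r_1, r_2|A) \approx \frac{1}{2L}\sum_{j_1}\sum_{j_2}
#' R(s_{j_1}, m_{j_1}) R(s_{j_2}, m_{j_2}) \Pr(d(j_1,j_2)|\mu,\sigma)},
#' where the insert length \eqn{d} is the span between the outermost aligned
#' bases and its distribution is normal with the set's \eqn{(\mu, \sigma)}.
#' Alignment combinations on different walks or on inconsistent strands
#' contribute zero.
#'
#' @param hits1,hits2 hit tables of the two mates, with a `walk` column
#'   identifying the walk of each alignment (plus `start`, `end`, `strand`,
#'   `s`, `m`).
#' @param genomeLength assembly length \eqn{L}.
#' @param params a [ModelParams-class]; must carry `insertMean` and
#'   `insertSd`.
#' @return A probability (0 if no consistent combination exists).
#' @export
pairedReadProbability <- function(hits1, hits2, genomeLength, params) {
  if (genomeLength < 1) stop("genomeLength must be >= 1")
  if (is.na(params@insertMean) || is.na(params@insertSd))
    stop("paired probability requires insertMean and insertSd")
  combos <- .pairCombos(hits1, hits2, params)
  if (nrow(combos) == 0L) return(0)
  sum(combos$w * stats::dnorm(combos$d, params@insertMean, params@insertSd)) /
    (2 * genomeLength)
}

#' No-alignment floor score
#'
#' The probability-like score \eqn{e^{c + k \sum \ell}} assigned to a read
#' (or read pair) in place of its probability whenever the probability falls
#' below it -- approximating the situation where the read would be added to
#' the assembly as a new contig.  With `noalignScale` \eqn{k < 0}, longer
#' reads get lower floors.
#'
#' @param readLengths one length (single read) or two (pair).
#' @param params a [ModelParams-class] supplying \eqn{c} and \eqn{k}.
#' @return The floor score.
#' @export
noAlignmentFloor <- function(readLengths, params) {
  if (any(readLengths < 1)) stop("read lengths must be >= 1")
  exp(params@noalignOffset + params@noalignScale * sum(readLengths))
}

#' Log average probability of a read set
#'
#' \eqn{\mathrm{LAP}(A|R) = \frac{1}{|R|} \sum_{r \in R} \log \Pr(r|A)}
#' (natural log).  Probabilities must already have floors applied; a zero
#' probability reaching this point is an internal error.
#'
#' @param probabilities per-read (or per-pair) probabilities, all positive.
#' @return The LAP value.
#' @export
readSetLap <- function(probabilities) {
  if (length(probabilities) == 0L)
    stop("empty read set: LAP is undefined")
  if (any(probabilities <= 0))
    stop("nonpositive probability: the no-alignment floor was not applied")
  mean(log(probabilities))
}

#' Disconnected bases and connectivity penalty
#'
#' A base \eqn{j} of the assembly is connected with respect to a read set if
#' some read covers \eqn{j} and starts at least `connWindow` bases before
#' \eqn{j} (a properly oriented pair is treated as one long read spanning
#' its outermost aligned bases).  The penalty \eqn{\alpha d} for the
#' \eqn{d} disconnected bases is subtracted from the set's LAP.  The first
#' `connWindow` bases of each walk can never satisfy the definition; by
#' default they are exempted so that the penalty measures joins, not the
#' number of walks (set `exemptWalkStart = FALSE` for the literal count).
#'
#' @param walkLengths named integer vector: length of each walk.
#' @param spans data.frame of covering intervals with columns `walk`
#'   (matching `names(walkLengths)`), `start`, `end` (0-based half-open).
#' @param params a [ModelParams-class] supplying `connWindow` and
#'   `penaltyAlpha`.
#' @param exemptWalkStart exempt the first `connWindow` bases of each walk.
#' @return list with `d` (disconnected bases), `penalty` (alpha * d), and
#'   `perWalk` (named vector of per-walk counts).
#' @export
connectivityPenalty <- function(walkLengths, spans, params,
                                exemptWalkStart = TRUE) {
  k <- params@connWindow
  if (is.na(k)) stop("connWindow is not set")
  ids <- names(walkLengths)
  if (is.null(ids)) ids <- as.character(seq_along(walkLengths))
  perWalk <- stats::setNames(integer(length(walkLengths)), ids)
  for (w in seq_along(walkLengths)) {
    len <- walkLengths[[w]]
    sel <- spans$walk == ids[w]
    perWalk[w] <- .disconnectedBases(len, spans$start[sel], spans$end[sel],
                                     k, exemptWalkStart)
  }
  d <- sum(perWalk)
  list(d = d, penalty = params@penaltyAlpha * d, perWalk = perWalk)
}

# Count of bases j in [0, len) with no covering interval starting at least
# k bases before j.  Interval [s, e) connects bases [s + k, e).
.disconnectedBases <- function(len, starts, ends, k, exemptWalkStart = TRUE) {
  if (len < 1L) return(0L)
  cs <- pmin(starts + k, len)
  ce <- pmin(ends, len)
  if (exemptWalkStart) { cs <- c(cs, 0L); ce <- c(ce, min(k, len)) }
  keep <- cs < ce
  if (!any(keep)) return(as.integer(len))
  covered <- IRanges::reduce(IRanges::IRanges(start = cs[keep] + 1L,
                                              end = ce[keep]))
  as.integer(len - sum(IRanges::width(covered)))
}

#' Combine per-dataset LAP values into the assembly score
#'
#' \eqn{\mathrm{LAP}(A|R_1,\dots,R_k) = \sum_i w_i\,
#' (\mathrm{LAP}(A|R_i) - \alpha_i d_i)}: each set's connectivity penalty is
#' applied to its own LAP term before weighting, so a zero-weight set
#' contributes nothing at all.
#'
#' @param perSetLap numeric vector of unpenalized LAP values.
#' @param disconnected integer vector of disconnected-base counts.
#' @param paramsList list of [ModelParams-class], one per set (supplying
#'   weights and alphas).
#' @param setNames optional labels.
#' @return A [LapBreakdown-class].
#' @export
combinedLap <- function(perSetLap, disconnected, paramsList,
                        setNames = NULL) {
  n <- length(perSetLap)
  if (length(disconnected) != n || length(paramsList) != n)
    stop("per-set LAP, disconnected counts, and params must align")
  if (is.null(setNames)) setNames <- paste0("set", seq_len(n))
  w <- vapply(paramsList, function(p) p@weight, numeric(1))
  a <- vapply(paramsList, function(p) p@penaltyAlpha, numeric(1))
  pen <- a * disconnected
  new("LapBreakdown", setNames = setNames, perSetLap = as.numeric(perSetLap),
      disconnected = as.integer(disconnected), penalty = pen, weights = w,
      total = sum(w * (perSetLap - pen)))
}
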