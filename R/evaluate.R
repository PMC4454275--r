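# Truth-based evaluation of assemblies on synthetic fixtures: anchor-based
# misjoin counting against the known genome.

#' Count misjoins of scaffolds against a truth sequence
#'
#' Splits each scaffold into chunks, maps every chunk against the truth
#' genome, and keeps chunks with a unique placement as anchors (chunks
#' inside repeats map multiply and are skipped).  Adjacent anchors of a
#' scaffold must lie on the same strand, in the right order, and at a
#' spacing matching their distance in the scaffold; every violation counts
#' as one misjoin.
#'
#' @param scaffolds [Biostrings::DNAStringSet] or character vector.
#' @param truth the true genome sequence.
#' @param chunk anchor chunk length in bases (default 300).
#' @param slack tolerated spacing deviation in bases (default 50).
#' @param maxEditFraction chunk mapping stringency.
#' @return list with `misjoins` (total count), `anchored` (scaffolds with
#'   at least two anchors), and `perScaffold` (integer vector).
#' @export
misjoinCount <- function(scaffolds, truth, chunk = 300L, slack = 50L,
                         maxEditFraction = 0.05) {
  seqs <- as.character(scaffolds)
  truth <- as.character(truth)
  per <- integer(length(seqs))
  anchored <- 0L
  for (si in seq_along(seqs)) {
    s <- seqs[si]
    n <- nchar(s)
    if (n < chunk) next
    starts <- seq(1L, n - chunk + 1L, by = chunk)
    pieces <- substring(s, starts, starts + chunk - 1L)
    keep <- !grepl("N", pieces, fixed = TRUE)
    if (!any(keep)) next
    hits <- .scanReads(truth, pieces[keep], which(keep),
                       maxEditFraction = maxEditFraction, seedK = 13L,
                       mode = "seeded")
    tab <- table(hits$read)
    uni <- as.integer(names(tab)[tab == 1L])
    hits <- hits[hits$read %in% uni, , drop = FALSE]
    if (nrow(hits) < 2L) next
    anchored <- anchored + 1L
    hits <- hits[order(hits$read), , drop = FALSE]
    mis <- 0L
    for (r in 2:nrow(hits)) {
      a <- hits[r - 1L, ]; b <- hits[r, ]
      expDelta <- (starts[b$read] - starts[a$read])
      ok <- a$strand == b$strand &&
        (if (a$strand == 1L) abs((b$start - a$start) - expDelta) <= slack
         else abs((a$start - b$start) - expDelta) <= slack)
      if (!ok) mis <- mis + 1L
    }
    per[si] <- mis
  }
  list(misjoins = sum(per), anchored = anchored, perScaffold = per)
}
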