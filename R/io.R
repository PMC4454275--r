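# Standard-format I/O and run configuration: FASTA/FASTQ via Biostrings,
# BED truth annotations, YAML run configs, JSON-lines run summaries, and
# assembly summary statistics.

#' Read a read set from FASTQ/FASTA files
#'
#' @param path path of the reads (first mates if paired).
#' @param matePath path of the second mates, or `NULL` for single-end.
#' @param format `"fastq"` or `"fasta"` (guessed from the extension by
#'   default).  FASTQ qualities are read but ignored by the model.
#' @param params a [ModelParams-class]; paired inputs must carry
#'   `insertMean` and `insertSd` (there are no silent defaults).
#' @param technology `"short"` or `"long"`.
#' @param name dataset label (defaults to the file name).
#' @return A [ReadSet-class].
#' @export
readReadSet <- function(path, matePath = NULL, format = NULL,
                        params = ModelParams(), technology = "short",
                        name = NULL) {
  guess <- function(p) {
    if (grepl("\\.(fq|fastq)(\\.gz)?$", p, ignore.case = TRUE)) "fastq"
    else "fasta"
  }
  if (is.null(format)) format <- guess(path)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  reads <- Biostrings::readDNAStringSet(path, format = format)
  mates <- if (!is.null(matePath))
    Biostrings::readDNAStringSet(matePath, format = guess(matePath))
  ReadSet(reads, mates = mates, params = params, technology = technology,
          name = name)
}

#' Write a read set as FASTQ
#'
#' Paired sets produce `<prefix>_1.fastq` and `<prefix>_2.fastq`; unpaired
#' sets produce `<prefix>.fastq`.  Constant qualities are emitted (the
#' model carries no quality term).
#'
#' @param readset a [ReadSet-class].
#' @param prefix output path prefix.
#' @return The written file paths, invisibly.
#' @export
writeReadSetFastq <- function(readset, prefix) {
  wr <- function(seqs, path) {
    q <- Biostrings::BStringSet(vapply(Biostrings::width(seqs),
                                       function(w) strrep("I", w),
                                       character(1)))
    Biostrings::writeXStringSet(seqs, path, format = "fastq", qualities = q)
    path
  }
  if (readset@paired) {
    paths <- c(wr(readset@reads, paste0(prefix, "_1.fastq")),
               wr(readset@mates, paste0(prefix, "_2.fastq")))
  } else {
    paths <- wr(readset@reads, paste0(prefix, ".fastq"))
  }
  invisible(paths)
}

#' Write scaffolds as FASTA
#'
#' @param scaffolds a [Biostrings::DNAStringSet] (N-gaps as literal N runs).
#' @param path output path.
#' @export
writeScaffolds <- function(scaffolds, path) {
  Biostrings::writeXStringSet(scaffolds, path)
  invisible(path)
}

#' Write repeat truth annotations as BED
#'
#' @param repeats a [GenomicRanges::GRanges] as produced by
#'   [randomGenome()].
#' @param path output path.
#' @export
writeRepeatBed <- function(repeats, path) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(repeats)),
    start = GenomicRanges::start(repeats) - 1L,
    end = GenomicRanges::end(repeats),
    name = paste0("family", repeats$family, "_copy", repeats$copy))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Assembly summary statistics
#'
#' N50 is the largest length x such that scaffolds of length at least x
#' cover half of the reference total: the supplied genome size when
#' `truthLength` is given, the assembly length otherwise.
#'
#' @param scaffolds a [Biostrings::DNAStringSet] or character vector.
#' @param truthLength optional true genome size for the N50 basis.
#' @return An [AssemblyStats-class].
#' @export
computeStats <- function(scaffolds, truthLength = NULL) {
  seqs <- as.character(scaffolds)
  if (!length(seqs)) stop("no scaffolds")
  lens <- nchar(seqs)
  total <- sum(lens)
  half <- (if (is.null(truthLength)) total else truthLength) / 2
  srt <- sort(lens, decreasing = TRUE)
  cum <- cumsum(srt)
  n50 <- if (any(cum >= half)) srt[which(cum >= half)[1L]] else min(srt)
  nGaps <- sum(vapply(gregexpr("N", seqs, fixed = TRUE), function(g)
    sum(g > 0L), numeric(1)))
  new("AssemblyStats", scaffoldCount = length(seqs),
      longest = max(lens), n50 = as.integer(n50),
      totalLength = as.integer(total), nGapTotal = as.integer(nGaps),
      basis = if (is.null(truthLength)) "assembly" else "truth")
}

#' Load a run configuration from YAML
#'
#' The file holds one block per read set (paths, paired flag, error rate,
#' insert mean/sd, weight, orientation, technology) plus optional global
#' sections `model` (floor constants `c` and `k`, `alpha`, `connWindow`),
#' `graph` (`kmerSize`), `anneal`, and `eval` overrides.  Missing
#' `errorRate` for any set, or missing insert parameters for a paired set,
#' is an error: there are no silent defaults for these.
#'
#' @param path YAML file path.
#' @param baseDir directory read paths are resolved against (defaults to
#'   the config file's directory).
#' @return list with `readsets`, `kmerSize`, `annealArgs`, `evalArgs`,
#'   `seed`.
#' @export
loadRunConfig <- function(path, baseDir = dirname(path)) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$readsets) || !length(cfg$readsets))
    stop("config must declare at least one read set")
  model <- cfg$model
  getm <- function(block, key, default) {
    if (!is.null(block[[key]])) block[[key]]
    else if (!is.null(model[[key]])) model[[key]]
    else default
  }
  readsets <- lapply(cfg$readsets, function(b) {
    if (is.null(b$path)) stop("read set without a path")
    if (is.null(b$errorRate))
      stop("read set '", b$path, "': errorRate must be given explicitly")
    paired <- isTRUE(b$paired)
    if (paired && (is.null(b$insertMean) || is.null(b$insertSd)))
      stop("paired read set '", b$path,
           "': insertMean and insertSd must be given explicitly")
    params <- ModelParams(
      errorRate = b$errorRate,
      insertMean = if (paired) b$insertMean else NA,
      insertSd = if (paired) b$insertSd else NA,
      weight = if (is.null(b$weight)) 1 else b$weight,
      noalignOffset = getm(b, "noalignOffset", -15),
      noalignScale = getm(b, "noalignScale", -0.2),
      connWindow = getm(b, "connWindow", NA_integer_),
      penaltyAlpha = getm(b, "alpha", 3),
      orientation = if (is.null(b$orientation)) "fr" else b$orientation)
    resolve <- function(p) if (file.exists(p)) p else file.path(baseDir, p)
    readReadSet(resolve(b$path),
                matePath = if (paired) resolve(b$matePath) else NULL,
                params = params,
                technology = if (is.null(b$technology)) "short"
                             else b$technology,
                name = b$name)
  })
  list(readsets = readsets,
       kmerSize = if (is.null(cfg$graph$kmerSize)) 21L
                  else as.integer(cfg$graph$kmerSize),
       annealArgs = if (is.null(cfg$anneal)) list() else cfg$anneal,
       evalArgs = if (is.null(cfg$eval)) list() else cfg$eval,
       seed = if (is.null(cfg$seed)) 1L else as.integer(cfg$seed))
}

#' Append a machine-readable run summary (JSON lines)
#'
#' @param path output file (appended to).
#' @param breakdown a [LapBreakdown-class].
#' @param stats an [AssemblyStats-class] or `NULL`.
#' @param extra named list of extra fields.
#' @export
writeRunSummary <- function(path, breakdown, stats = NULL, extra = list()) {
  rec <- c(list(
    total = breakdown@total,
    perSetLap = as.list(stats::setNames(breakdown@perSetLap,
                                        breakdown@setNames)),
    disconnected = as.list(stats::setNames(breakdown@disconnected,
                                           breakdown@setNames))),
    if (!is.null(stats)) list(
      scaffolds = stats@scaffoldCount, longest = stats@longest,
      n50 = stats@n50, totalLength = stats@totalLength,
      nGapTotal = stats@nGapTotal, n50Basis = stats@basis),
    extra)
  con <- base::file(path, "a")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  invisible(path)
}

#' Format a LAP breakdown for printing
#'
#' Two decimals per set and total, as assembly LAP scores are commonly
#' reported.
#'
#' @param breakdown a [LapBreakdown-class].
#' @return character vector of lines.
#' @export
formatLap <- function(breakdown) {
  c(vapply(seq_along(breakdown@perSetLap), function(i)
    sprintf("LAP(%s) = %.2f  (disconnected %d, weight %g)",
            breakdown@setNames[i], breakdown@perSetLap[i],
            breakdown@disconnected[i], breakdown@weights[i]),
    character(1)),
    sprintf("total = %.2f", breakdown@total))
}
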