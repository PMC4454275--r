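# End-to-end drivers: assemble from reads, score an existing assembly, and
# improve an externally produced assembly.

#' Assemble a genome from read sets
#'
#' The full pipeline: build the conservative de Bruijn assembly graph from
#' the short accurate read sets, seed the assembly with one walk per long
#' contig, optimize the combined LAP by simulated annealing, break
#' ambiguously resolved repeats, and emit scaffolds.
#'
#' @param readsets a [ReadSet-class] or list of them.
#' @param kmerSize de Bruijn k-mer size.
#' @param evalConfig a [lapConfig()] list.
#' @param annealCfg an [annealConfig()] list.
#' @param tolerance postprocessing ambiguity tolerance (LAP units).
#' @param seed RNG seed; identical seeds give identical assemblies.
#' @param verbose print annealing progress.
#' @return list with `scaffolds` ([Biostrings::DNAStringSet]), `assembly`,
#'   `graph`, `breakdown`, `stats`, `trajectory`, and `breakReport`.
#' @export
assembleGenome <- function(readsets, kmerSize = 21L,
                           evalConfig = lapConfig(),
                           annealCfg = annealConfig(), tolerance = 1e-3,
                           seed = 1L, verbose = FALSE) {
  if (methods::is(readsets, "ReadSet")) readsets <- list(readsets)
  withSeed(seed, {
    graph <- buildConservativeGraph(readsets, kmerSize = kmerSize)
    initial <- initialAssembly(graph, evalConfig$longThreshold)
    res <- anneal(initial, graph, readsets, config = annealCfg,
                  evalConfig = evalConfig, verbose = verbose)
    post <- breakAmbiguous(res$assembly, graph, readsets,
                           tolerance = tolerance, cache = res$cache)
    scaffolds <- .assemblySeqs(post$assembly, graph)
    list(scaffolds = scaffolds, assembly = post$assembly, graph = graph,
         breakdown = post$breakdown, stats = computeStats(scaffolds),
         trajectory = res$trajectory, breakReport = post$report)
  })
}

.assemblySeqs <- function(assembly, graph) {
  seqs <- vapply(assembly@walks, walkSequence, character(1), graph = graph)
  Biostrings::DNAStringSet(stats::setNames(
    seqs, paste0("scaffold", seq_along(seqs))))
}

#' Score an existing assembly against read sets
#'
#' Evaluates the combined LAP of a given set of scaffolds (the probabilistic
#' model standalone): every scaffold is treated as a single-contig walk and
#' all read sets are aligned and scored in full.
#'
#' @param scaffolds a [Biostrings::DNAStringSet], character vector, or
#'   FASTA path.
#' @param readsets a [ReadSet-class] or list of them.
#' @param evalConfig a [lapConfig()] list.
#' @return A [LapBreakdown-class].
#' @export
scoreAssembly <- function(scaffolds, readsets, evalConfig = lapConfig()) {
  if (methods::is(readsets, "ReadSet")) readsets <- list(readsets)
  if (is.character(scaffolds) && length(scaffolds) == 1L &&
      file.exists(scaffolds))
    scaffolds <- Biostrings::readDNAStringSet(scaffolds)
  if (!methods::is(scaffolds, "DNAStringSet"))
    scaffolds <- Biostrings::DNAStringSet(scaffolds)
  graph <- new("AssemblyGraph", contigs = scaffolds,
               edges = data.frame(from = integer(), fromStrand = integer(),
                                  to = integer(), toStrand = integer()),
               k = 21L, coverage = numeric(length(scaffolds)))
  assembly <- Assembly(lapply(seq_along(scaffolds), function(i)
    Walk(i, 1L)))
  scoreAssemblyFull(assembly, graph, readsets, evalConfig)
}

#' Improve an existing assembly
#'
#' Maps an externally produced assembly onto the conservative assembly
#' graph built from the reads (each external contig becomes a walk; when
#' nothing maps, the graph is instead built from the external assembly
#' itself), then optimizes the walks by simulated annealing and breaks
#' ambiguous repeats.  Unsupported joins are penalized apart
#' (penalty-driven breaks) while read evidence drives new joins.
#'
#' @param external external contigs ([Biostrings::DNAStringSet], character
#'   vector, or FASTA path).
#' @inheritParams assembleGenome
#' @return As [assembleGenome()], plus `mapped` (logical per external
#'   contig) and `usedFallback`.
#' @export
improveAssembly <- function(external, readsets, kmerSize = 21L,
                            evalConfig = lapConfig(),
                            annealCfg = annealConfig(), tolerance = 1e-3,
                            seed = 1L, verbose = FALSE) {
  if (methods::is(readsets, "ReadSet")) readsets <- list(readsets)
  if (is.character(external) && length(external) == 1L &&
      file.exists(external))
    external <- Biostrings::readDNAStringSet(external)
  external <- Biostrings::DNAStringSet(external)
  withSeed(seed, {
    graph <- buildConservativeGraph(readsets, kmerSize = kmerSize)
    mp <- mapExternalAssembly(external, graph)
    usedFallback <- is.null(mp$assembly)
    if (usedFallback) {
      # build the graph from the input assembly itself and re-map
      graph <- buildConservativeGraph(external, kmerSize = kmerSize,
                                      minCount = 1L)
      mp <- mapExternalAssembly(external, graph)
      if (is.null(mp$assembly))
        stop("external assembly could not be mapped onto any graph")
    }
    res <- anneal(mp$assembly, graph, readsets, config = annealCfg,
                  evalConfig = evalConfig, verbose = verbose)
    post <- breakAmbiguous(res$assembly, graph, readsets,
                           tolerance = tolerance, cache = res$cache)
    scaffolds <- .assemblySeqs(post$assembly, graph)
    list(scaffolds = scaffolds, assembly = post$assembly, graph = graph,
         breakdown = post$breakdown, stats = computeStats(scaffolds),
         trajectory = res$trajectory, breakReport = post$report,
         mapped = mp$mapped, usedFallback = usedFallback)
  })
}
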