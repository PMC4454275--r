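---
title: "Maximum-likelihood genome assembly with lapasm: model, search, and design notes"
author: "lapasm authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Maximum-likelihood genome assembly with lapasm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`lapasm` treats genome assembly as likelihood maximization. Given read sets
$R_1, \dots, R_k$ and a candidate assembly $A$ of total length $L$, each
read set contributes its *log average probability*

$$\mathrm{LAP}(A \mid R) = \frac{1}{|R|} \sum_{r \in R} \log \Pr(r \mid A),$$

and the objective combines the sets with user weights $w_i$, each term
carrying its own spurious-join penalty:

$$\mathrm{score}(A) = \sum_i w_i \left( \mathrm{LAP}(A \mid R_i) - \alpha_i d_i \right).$$

Per-read probabilities marginalize over a set $S_r$ of best alignments. A
single alignment with $m$ matches and $s$ errors (substitutions and indels
share one per-base rate $\epsilon$) has weight
$R(s,m) = \epsilon^s (1-\epsilon)^m$, and

$$\Pr(r \mid A) \approx \frac{1}{2L} \sum_{j \in S_r} R(s_j, m_j),$$

with $2L$ the length of the two strands combined. For a mate pair, every
consistent combination of placements (same walk, opposite strands, correct
mate order for the library's orientation) contributes the product of the two
alignment weights times a normal density $\mathcal{N}(d; \mu, \sigma)$ on
the implied insert length $d$ (outermost-base span); combinations on
different walks contribute zero. Reads (or pairs) whose probability falls
below the floor $e^{c + k\ell}$ (total read length $\ell$) are scored at
the floor instead -- the score a read would get if it were added to the
assembly as its own contig -- so unalignable reads cannot drive the log
likelihood to $-\infty$.

**Connectivity penalty.** A base $j$ is *connected* with respect to a read
set if some read covers $j$ and starts at least $k_{\mathrm{conn}}$ bases
before it; a properly sized mate pair acts as one long read spanning its
outermost aligned bases. Each disconnected base costs $\alpha$. Two details
are deliberate choices:

* The first $k_{\mathrm{conn}}$ bases of a walk can never satisfy the
  definition, so they are exempt by default (`exemptWalkStart = TRUE` in
  [connectivityPenalty()]); otherwise every walk would pay a constant
  penalty that simply re-counts the number of walks.
* Only pairs whose implied insert lies within $6\sigma$ of $\mu$ act as
  connecting spans. Without this, a pair of multi-mapping reads placed at
  two repeat copies 10 kb apart would "connect" everything between them
  while its near-zero insert density contributes nothing to the likelihood.

Defaults: $c = -15$, $k = -0.2$ per base, $\alpha = 3$,
$k_{\mathrm{conn}}$ = read length for paired sets and half the (median)
read length for single-end and long-read sets. A single-end read of length
$\ell$ can never cover a base while starting $\ell$ bases before it, so the
paired-set default would disconnect every base of a single-end-only
assembly; halving it restores the intended semantics. All constants are
per-set configurable; the floor must simply sit well below any genuine
alignment's log probability, and $\alpha$ must exceed the per-base gain a
spurious join can harvest.

# Alignment machinery

Short accurate reads are aligned semi-globally (whole read, local target)
by a banded edit-distance DP restricted to diagonals around shared 13-mer
seeds. The canonical hit set is defined as: alignment end positions with
edit distance at most $\lceil 0.1 \ell \rceil$, grouped into maximal
consecutive runs, keeping positions that achieve each run's minimum, then
one alignment per (strand, start) -- most matches, then shortest span.
Distinct (including exactly tandem) occurrences each yield a hit, while
indel "wobble" variants of one placement collapse to a single
representative. At most `maxHits = 10` best alignments per read and walk
enter the probability (ties broken by edit distance, position, strand);
the estimate is monotone in the alignment set, so a richer set can only
raise it.

Candidate reads for a target are found either through a k-mer index
(read id stored under each of its distinct canonical 13-mers; near-perfect
recall, low precision) or a min-hash index (one entry per read per hash
function; collision probability between two k-mer sets equals their Jaccard
similarity). Hashing 2-bit-packs the k-mer, xors a per-function 64-bit
mask, and applies the Murmur3 finalizer, truncated to 53 bits so values are
exact doubles in R.

Long noisy reads get a different backend: exact 11-mer seeds are clustered
by diagonal, a corridor-banded DP produces a guide alignment, and a banded
forward algorithm sums $R(s,m)$ over all alignment paths within $\pm 3$
diagonals of the guide path ("band of size three" is interpreted as
diagonals). With band 0 the mass equals the guide's own $R(s,m)$, and it
grows monotonically toward the full forward value as the band widens.

# Search

The assembly graph is a conservative de Bruijn graph: canonical 21-mers
(default) counted across the short accurate sets; k-mers below
$\max(2, 0.1 \cdot \mathrm{cov})$ dropped, where coverage is estimated as
the median count among non-singleton k-mers (singleton error k-mers would
otherwise drag the estimate to 1); unambiguous chains condensed into
contigs; dead-end tips shorter than $2k$ clipped and the graph
recondensed. Edges additionally require read support for the connecting
$(k{+}1)$-mer. The initial assembly takes each contig longer than 500 bp as
its own walk.

Simulated annealing then proposes changes: walk extension (random graph
walk from a walk end; joining, stopping, or continuing with equal
probability upon meeting another walk's end), local improvement (sampled
reachability-pruned paths between consecutive long contigs, greedy ~200 bp
chunks for gaps over 5 kb), repeat optimization (adding/removing
pre-enumerated loops of up to five nodes), joining with advice (mate pairs
or long reads whose other end lies on a different walk; gaps filled by a
graph path or Ns), disconnecting (removing a short-contig bridge), and
repeat interchange (re-pairing walk parts through a multiply-traversed
contig, applied greedily while it improves). Default move probabilities
are 0.25 / 0.20 / 0.15 / 0.15 / 0.10 / 0.15. Worse proposals are accepted
with probability $e^{\Delta/T}$ under $T = T_0 / \ln(i + 1)$ (shifted so
iteration 1 is defined); $T_0$ defaults to 1% of the magnitude of the
*unpenalized* weighted LAP -- the penalty term can dominate the total and
would otherwise set a far-too-hot start. The run stops after `patience`
(default 500) evaluated proposals without improvement of the best score;
degenerate no-op proposals are not counted, and `maxIter` caps the loop.
The best assembly ever visited is returned.

**Duplication neutrality.** The likelihood cannot distinguish an assembly
from a duplicate of its own content (read occurrence counts and $L$ scale
together), and accepting equal-score proposals lets the annealer drift
into states that spell out a walk's reverse complement as a second walk --
which then makes every repeat resolution look ambiguous downstream. Three
mechanisms keep the search honest. First, per-contig copy-number budgets:
the k-mer coverage of each long contig, divided by the length-weighted
median coverage of long contigs (the single-copy depth), estimates how
many times it occurs in the genome, and proposals that would traverse a
long contig more often than that are discarded -- this supplies exactly
the copy-number information the likelihood is blind to, and it is why the
two-copy repeat in the standard fixture may be traversed twice but a
unique contig only once. Second, ties in best-assembly tracking are
broken toward the shorter assembly. Third, after annealing, any walk
whose removal does not lower the score is pruned (walks with unique
content are always kept, because their reads would fall to the floor).

# Incremental evaluation

Each walk is partitioned into windows that overlap by at least $2\ell_r$
(with $\ell_r$ the longest read length inflated by the edit budget, so
indel-extended alignments stay inside windows). Alignments to contig
interiors are cached per oriented contig -- per orientation, because
canonical hit selection is not invariant under strand flip -- and only the
masked window spans around junctions (the last/first $2\ell_r$ bases of
flanking long contigs plus everything between) are realigned when a walk
appears, with one read length of sequence context padded on each side and
only interior hits kept, so hits near span edges are computed exactly as a
whole-walk scan would. Hits are deduplicated by (read, start, strand) and
capped per read and walk; per-unit weight contributions, pair matching,
and disconnected-base counts are stored per walk and recombined into the
total score, so evaluating a move costs alignment work only around the
changed junctions. Span-scan results and per-walk summaries are further
memoized by sequence content (pure functions of the scanned sequence).
A `paranoid` mode recomputes every proposal from scratch through the
independent full path ([scoreAssemblyFull()]) and fails loudly on any
deviation above $10^{-6}$.

# Postprocessing

After annealing, the repeat-interchange evaluation is applied at every
multiply-traversed contig. Improving exchanges are applied; where the best
alternative changes the score by no more than `tolerance` ($10^{-3}$ LAP
units by default -- "negligible" quantified as far below any single-read
contribution), the traversing walks are cut at the contig's boundaries and
the contig emitted once as a standalone walk, so that no arbitrary repeat
resolution is reported. This is what happens, for example, when a repeat
is longer than the span of the longest insert: all resolutions then look
alike to the reads. Cutting at the boundaries (rather than duplicating the
repeat into every scaffold) avoids emitting ambiguous sequence twice.

One case needs a different test. When both traversals of a repeat lie in
the *same* walk, every content-preserving re-pairing must cut one walk
junction (the swapped-out middle becomes a circular piece that has to be
linearized), so the likelihood comparison is biased by that cut --
typically a few hundredths of a LAP unit -- rather than by genuine
evidence. For such double traversals the trigger is tested directly: the
walk is broken at the contig unless some properly sized pair span (or
long-read alignment) bridges each occurrence end to end, which is exactly
the "repeat longer than the span of the longest paired read" condition.

# The simulator, and what passing tests show

`randomGenome()` and `simulateReads()` generate the study conditions:
uniform-random genomes of 18--20 kb with planted repeat families (defaults
scaled down from megabase bacterial genomes, keeping repeat length vs
insert length the binding ratio), paired 100 bp reads at 40x with 1%
substitution errors and normal inserts (1500 +/- 150 in the standard
fixture, so mates span the 1 kb repeat), and log-normal long reads at
10--15% error with 1/3 substitutions and 2/3 indels. Short-read errors are
substitutions only -- adequate for Illumina-like data; indel robustness is
exercised by the long-read model and by the aligner tests directly. The
simulator does not model GC bias, chimeras, position-dependent error
rates, or quality scores (the model has no quality term), so passing tests
demonstrate correctness of the machinery and the model's discriminative
behaviour under idealized noise, not performance on real libraries.

Problem sizes used by the test suite and the acceptance script: 18--20 kb
genomes, 40x paired coverage, one repeat family, annealing capped at
~1500 iterations with patience 250 -- sizes at which a full run takes
tens of seconds and the whole suite stays comfortably repeatable.

# Known limitations

* The model is duplication-neutral (see above); parsimony enters only
  through tie-breaking, not through the likelihood itself.
* The connectivity count is mildly orientation-dependent (the walk-start
  exemption has no mirror at walk ends), so a walk and its reverse
  complement can differ by a few penalty units.
* Same-walk repeat interchange is limited to the pull-apart comparison
  used by postprocessing; tandem copy number is the repeat-optimization
  move's job.
* Long reads are scored against whole walks; reads overhanging walk ends
  are forced into semi-global alignments and may fall to the floor.
* The canonical alignment-set definition collapses run ties locally;
  in extremely repetitive (low-complexity) sequence the incremental and
  full paths could in principle disagree at the boundary of a cached
  contig interior. The paranoid mode exists to surface such cases.
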