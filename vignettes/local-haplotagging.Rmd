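---
title: "Local read haplotagging: model, algorithm and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local read haplotagging: model, algorithm and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(localtag)
```

## The problem

Long reads (PacBio HiFi, ONT) span many heterozygous sites, so each read
carries substantial phase information. Genotypers and many downstream tools
benefit from knowing which of the two parental haplotypes a read came from.
Classical haplotagging (e.g. WhatsHap) needs a variant call set first, which
forces a call–phase–recall loop. `localtag` implements the alternative:
*approximate local haplotagging directly from the pileup*, with no variant
calls. The genome is cut into independent windows (25 kb by default); within
each window, putative heterozygous SNPs are detected heuristically, their
alleles are partitioned into two haplotypes by a dynamic program over an
allele graph, and each read is tagged 1, 2 or 0 by majority vote over the
alleles it supports. Labels are only meaningful within a phase segment;
nothing global is inferred.

## Candidate generation and the heterozygous-SNP filter

A pileup column becomes a candidate when some non-reference base is carried
by at least `min_alt_support` reads (default 2) making up at least
`min_alt_fraction` (default 0.12) of the quality-passing reads at that
column. Bases below `min_base_quality` (10), reads below
`min_mapping_quality` (5), `N` bases, and bases inside deletions support
nothing. Candidates then pass the heterozygosity filter:

* every alternate allele must be a single-base substitution (indel alleles
  never enter the graph), and
* a candidate with exactly one alternate allele is dropped when its
  reference allele is supported by fewer than `min_ref_support` (3) reads —
  such sites are most likely homozygous-alternate and carry no phase
  information. Multi-alternate candidates are kept regardless, because two
  alternates can themselves be the two haplotypes.

The count floor alone cannot reject recurrent sequencing errors: at 30x
coverage and a 1% substitution error rate, two identical errors in one
column occur at roughly 1.4% of positions, an order of magnitude more often
than true heterozygous sites at typical human diversity. The allele-fraction
floor is what separates the two regimes (error doubletons sit near 0.07 of
the column, true heterozygous alleles near 0.5); production candidate
callers use the same combination, and 0.12 is the conventional SNP value.
All five thresholds are exposed in `candidate_filter_config()`.

## The allele graph

Each retained candidate position contributes one vertex per alternate
allele, plus a vertex for the reference allele when it has at least
`min_ref_support` reads. Within a position, the reference vertex comes
first and alternates follow lexicographically; this fixed order defines
pair enumeration and therefore every tie-break. Consecutive candidate
positions are connected by an edge wherever a read supports a vertex at
both; the edge stores that read set. Two repairs keep the chain usable:

* **Artificial edges.** If some vertex at a position has an incoming edge
  but another has none, the orphan is connected to *every* vertex of the
  previous position by support-free edges. They only license extension;
  their empty read sets add no score.
* **Segmentation.** If *no* vertex at a position has an incoming edge, the
  chain genuinely breaks: the window is split into segments, each solved
  and phase-labelled independently (`split_segments()`). The phase-set
  label of a segment is the leftmost 1-based reference position of its
  first candidate.

## The pair-score dynamic program

A state is an ordered pair of vertices at one position: the first element
is the haplotype-1 allele, the second the haplotype-2 allele; a pair may
repeat one vertex (`i == j`), modelling a column that behaves
homozygously. At the first position of a segment,

$$S(V_{1,i}, V_{1,j}) = \lvert R(V_{1,i}) \cup R(V_{1,j}) \rvert,$$

the number of distinct reads supporting either allele. At each later
position,

$$S(V_{n,i}, V_{n,j}) = \max_{(k,l)} \Big\{ S(V_{n-1,k}, V_{n-1,l}) +
\lvert R(V_{n-1,k}, V_{n,i}) \cup R(V_{n-1,l}, V_{n,j}) \cup
R^{*}(V_{n,i}) \cup R^{*}(V_{n,j}) \rvert \Big\},$$

where the maximum ranges over previous pairs whose edges
$E(V_{n-1,k},V_{n,i})$ and $E(V_{n-1,l},V_{n,j})$ exist,
$R(V_{n-1,k},V_{n,i})$ is the read set of that edge, and $R^{*}$ collects
reads that start after position $n-1$ (so reads entering the graph are
counted once). The score is a pure set cardinality; there is no floating
point anywhere in the program. Backtracking from the best final pair
assigns haplotype 1 to the first vertex and haplotype 2 to the second
vertex of every pair on the path.

### Canonical versus symmetric pair state

Because haplotype labels are arbitrary, the states $(i,j)$ and $(j,i)$
describe the same partition. The package's default (`pair_mode =
"canonical"`) exploits this: all ordered pairs are *evaluated* at each
position, but the backward state keeps one entry per unordered pair — the
better-scoring orientation, ties favouring $i \le j$ — and predecessors
attach role-preservingly ($k$ extends the haplotype-1 chain, $l$ the
haplotype-2 chain). This halving is lossless: flipping the labels of an
entire assignment path maps initialization terms and every transition term
onto themselves, so the best path ending in $(j,i)$ has exactly the score
of a best path ending in $(i,j)$. By induction the collapsed state carries
the same maxima as the full ordered state, and the final best score equals
that of `pair_mode = "symmetric"`, which keeps every ordered pair as a
predecessor. What *does* differ between the modes is the intermediate
per-pair table (canonical entries are orientation-dependent), which is why
both are exposed. `brute_force_best_score()` enumerates the complete
ordered path space and is used in the tests as a single independent oracle
for both modes; `selftest()` verifies the built-in two-site worked example
end to end.

An early version of the canonical mode kept only the literal $i \le j$ rows
as backward state. That is subtly wrong: when reference and alternate
alleles alternate orientation between positions (which happens constantly
in real pileups), the best pair at a position can exist only in its
non-canonical orientation, the chain loses it, and the program collapses to
homozygous-like paths. The orientation-max state above is the correct
reading.

### Tie-breaking and degenerate inputs

All ties — among predecessor pairs and among final pairs — resolve to the
first candidate in the fixed enumeration order, making results
deterministic for identical input. An empty window yields a graph with
zero positions and every read tagged 0. A pair with no admissible
predecessor simply gets no table entry; after artificial edges and
segmentation at least the diagonal pairs always survive, so a segment
never dead-ends.

## From allele labels to read tags

A read votes once for every haplotagged allele it supports (its base at
the position equals the vertex allele — spanning a position without
supporting a vertex contributes nothing). Majority wins; equal votes give
tag 0, including reads on the best path's `i == j` vertices, which add one
vote to each side and thus stay neutral. A read supporting alleles in more
than one segment is voted within each and tagged by the segment where it
has most votes (segment tie: tag 0). Windows are merged by assigning each
read to the single window containing its alignment start; a read fetched
by overlap into a neighbouring window is dropped from that window's
result. `HP`/`PS` tags are emitted for tagged reads only.

## The diploid simulator

`simulate_diploid()` emulates exactly the structure the algorithm assumes:
a uniform-random reference, heterozygous SNPs at `het_snp_rate` (default
1/1000, a typical human heterozygosity) with the alternate on a fairly
chosen haplotype, homozygous SNPs at `hom_snp_rate` (default 1/2000, which
must be *rejected* by the het filter), reads of truncated-normal length
(default 15 kb ± 3 kb, minimum 500 b, the accurate-long-read regime) drawn
evenly from both haplotypes to a combined depth of 30x, and i.i.d.
substitution errors (default 1%). Reads are emitted pre-aligned at their
true coordinates with full-match CIGARs, so the pipeline runs without an
aligner, and every read carries a truth haplotype.

What it deliberately does **not** model: indel errors (the algorithm
discards non-SNP alleles anyway, but real indel noise perturbs candidate
columns), homopolymer-context error clustering, coverage waves, mapping
artifacts, chimeric or supplementary alignments, and structural variation.
Passing tests on this generator therefore demonstrate the algorithm's
correctness under its own model assumptions, not performance on any
particular sequencing platform.

## Evaluation

`switch_aware_accuracy()` scores a tagging against truth per phase block:
within each block the better of the two label mappings (identity or swap)
is chosen, matches are aggregated across blocks, and haplotag-0 reads are
excluded from accuracy but reported through `tagged_fraction`. The
per-block permutation is the right granularity here because labels are
segment-local by construction. Mid-block switch points are *not* separated
out (no switch/flip error taxonomy); a within-block label switch simply
costs matches.

## Problem sizes used by the test suite

The suite checks the dynamic program against exhaustive enumeration on 200+
random segments (up to 5 positions, 3 vertices per position, ~30 reads),
and runs the full pipeline on 50 kb simulated genomes at 30x with 15 kb
reads — about 100 reads and 25–55 heterozygous sites per genome — once
error-free (where switch-aware accuracy is exactly 1 for reads covering at
least two heterozygous sites) and once at a 1% error rate (accuracy above
0.99, tagged fraction above 0.8). These sizes exercise every code path,
including segmentation and window merging, while keeping the whole suite
in well under a minute.

## Known limitations

* Haplotype labels never extend past a segment, and no attempt is made to
  stitch blocks across windows; the output is intentionally local.
* The heterozygosity heuristic can admit recurrent errors in badly behaved
  regions and will reject true heterozygous sites with skewed allele
  balance (fraction below 0.12 or reference support below 3).
* A read is tagged by its alignment-start window only; its bases in the
  next window do not influence that window's phasing of it.
* Indels neither form candidates nor votes, so phase-informative indels
  are ignored.
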