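---
title: "Dissecting a heterozygous octoploid genome with a collapsed virtual reference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting a heterozygous octoploid genome with a collapsed virtual reference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polydissect)
```

## The problem

Cultivated strawberry is an allo-octoploid: each nucleus carries eight haploid
complements organised as two homoeologous subgenome pairs per progenitor
lineage (AA A'A' BB B'B'), and outcrossing keeps the two haplotypes of every
subgenome allelically heterozygous. Up to eight slightly different copies of
every locus therefore coexist, which defeats conventional assembly: de Bruijn
assemblers emit several-fold the monoploid length in short, redundant contigs.
One workable strategy is to *embrace* the redundancy: collapse homoeologous
and allelic variants into a single consensus per locus — a *virtual reference
genome* — and then map each species' (or each subgenome proxy's) sequences
back onto it to read off copy number and progenitor contributions.

`polydissect` implements that workflow end to end, together with a synthetic
allo-octoploid generator so every stage can be validated against known truth
without any external data.

## The simulator defines the study conditions

`simulate_octoploid()` builds an ancestral monoploid sequence and diverges it
hierarchically: lineage-private, subgenome-private and haplotype-private
substitution events. The three rates are parameterised by their *observable*
pairwise divergences:

* `d_prog = 0.08` — total expected divergence between subgenomes of different
  progenitor lineages (A vs B ~ 92% identity),
* `d_sub = 0.02` — divergence between homoeologs within a lineage
  (A vs A' ~ 98%),
* `h_allelic = 0.005` — allelic heterozygosity between the two haplotypes of
  one subgenome.

These defaults are chosen so that within-lineage homoeologs collapse
comfortably at the 90% overlap-identity threshold while cross-lineage copies
sit near it — the regime in which the real reference was observed to
over-integrate. The lineage-private rate is therefore `(d_prog - d_sub)/2`
per lineage, which makes the *realized* cross-lineage divergence equal
`d_prog` rather than `d_prog + d_sub`; both the within- and cross-lineage
identities then match their nominal values, which we consider the only
self-consistent reading of the three parameters. No quantitative allelic
heterozygosity rate is available for the sequenced cultivar, so `h_allelic`
is a stated assumption, not a measured value.

Divergence is i.i.d. substitutions plus optional short (1–10 bp) indels;
`indel_rate` defaults to 0 because no structural changes were needed to
explain the real data, and substitution-dominated divergence keeps offsets
between window fragments exact. SSR tracts (motif lengths 1–6, density 16 per
100 kb, inside the observed 12.7–16.8 range) are seeded into the ancestor so
all copies share them. Reads are uniform over both strands with substitution
errors at `error_rate` and phred qualities of `-10 log10(error_rate)` plus a
small per-read jitter. Fragmented "assemblies" cut each haplotype into
contigs around a target N50 and record the true origin in each contig name.

What the generator deliberately does *not* emulate: repeat families and
transposable elements, GC-coverage bias, PCR duplicates, mate-pair libraries,
chimeric contigs and structural rearrangements. Passing recovery tests on
this generator therefore demonstrates the correctness of the algorithms under
substitution-style divergence, not robustness to every artefact of real
short-read assemblies.

## Genome size from the k-mer spectrum

`count_kmer_spectrum()` counts canonical 17-mers (strand-collapsed, N-free)
and `estimate_genome_size()` divides the k-mer mass above the error region by
the depth of the highest-multiplicity peak. Heterozygous material produces a
second peak at half the homozygous depth, which is reported but excluded from
the division. Numerical choices the sources leave open, fixed here once:

* smoothing: centred moving average, window 3 — minimal smoothing that does
  not merge het/hom peaks;
* error region: first local minimum after multiplicity 1, capped at 10;
* the mass in the error region is excluded from the numerator, since error
  k-mers otherwise inflate the estimate;
* local maxima below 5% of the tallest post-cutoff peak are ignored — they
  come from the doubled-multiplicity tail of chance repeats, not coverage.

At 30x coverage with 100-bp reads and 0.5% error the estimator recovers a
1-Mb genome with a median absolute relative error well under 10%.

## The windowed overlap-layout-consensus collapse

The heart of the package. Sequences are split into 300-bp windows every
100 bp (200-bp overlaps), with the final window right-anchored so fragments
always reproduce the parent exactly. `find_overlaps()` generates candidate
fragment pairs from shared 11-mers on both strands, estimates the relative
offset by diagonal voting, and reports overlaps of at least 100 bp at >= 90%
identity (exactly 0.90 passes). `layout_consensus()` then builds contigs and
`merge_unjoined()` concatenates consensus contigs whose ends still overlap.

Two design decisions deserve emphasis because the sources do not specify the
assembler internals:

1. **Cluster-verified agglomeration.** Overlap edges are processed strongest
   first, and a merge of two growing fragment clusters is accepted only if
   the *aggregate* identity over all member columns (under the placement the
   edge implies) still clears the threshold. A single 100-bp window pair
   between 15%-diverged copies will occasionally reach 90% identity by
   binomial chance (about one pair in fifteen); cluster-level verification
   rejects exactly these, so two copies collapse when their overall
   divergence is within the threshold and remain separate when it is not.
   Edges are additionally required to be transitively supported by a third
   fragment unless an endpoint has no other overlap.
2. **Consensus calling.** Per column, the depth-weighted majority base wins;
   ties break by the fixed order A < C < G < T for determinism; a column is
   N only if every member is N. Columns where members disagree are counted
   as `het_sites_collapsed` — the heterozygous bases the collapse
   eliminated.

Offsets are propagated exactly (substitution-only divergence leaves window
offsets integral); placement disagreements above 5 bp are counted as
conflicts and the offending edge ignored. With the default simulation the
eight 100-kb haplotypes collapse into a single 100-kb consensus — between 1x
and 2x the monoploid length, mirroring the over-integration regime observed
with real data (where the collapsed reference came out *below* the monoploid
size; sub-monoploid over-collapse depends on repeat content we do not
simulate, so it is bracketed rather than asserted).

## Comparative mapping

`align_sequences()` is one seed-and-extend local aligner (11-mer seeds,
diagonal chaining, banded DP, X-drop extension) with two presets standing in
for the engines used on real data: `blat_like` (min identity 95, min score
100) and `megablast_like` (min identity 90, E <= 1e-50). E-values use a
Karlin–Altschul statistic with blastn-like scoring (+1/-2, lambda = 1.33,
K = 0.621). Records carry PSL semantics: 0-based half-open spans, matches,
mismatches, gap counts and gap bases, score = matches - mismatches -
q_gap_count - t_gap_count.

`apply_hit_filters()` implements the four selection inequalities, in percent
of query length: (matches + gap bases in query) >= 80, query span >= 80,
matches >= 25, and target span within [80, 120]. Two readings left open by
the terse published wording are fixed as: the gap term counts gap *bases* on
the query side (keeping c1 commensurate with percent-of-length units), and
the match-score criterion is a percentage (a raw ratio >= 25 is impossible).
`select_best_alignment()` keeps the best-scoring record per query at >= 0.20
query coverage, ties broken by matches, then target name — a deterministic
replacement for the manual curation step used on the real data.

Downstream accounting mirrors the published analyses: targets binned by how
many queries best-hit them (single/double/triple/quadruple/five-plus),
per-species top-hit attribution with deterministic tie handling,
non-homologous length ratios, and greedy CD-HIT-style clustering (join the
first representative at >= 80% identity covering >= 10% of the shorter
sequence).

## SSR census and marker phylogenetics

`find_ssrs()` reports all maximal perfect tandem repeats of unit length 1–6
meeting the minimum repeat counts 12/6/7/5/5/5, counting whole units only,
under the smallest primitive unit; motif classes are canonicalized over
rotations and reverse complements so (AT)n and (TA)n are one class. Compound
or interrupted microsatellites are out of scope — only unit lengths and
minimum counts are specified by the method being reproduced.

`jaccard_distance()` on allelic-peak presence/absence, `ward_cluster()`
(ward.D2 by default, switchable to ward.D) and `bootstrap_support()`
(resampling peak columns; optional multiscale scales with approximately
unbiased values from the usual qnorm(1 - BP) = v sqrt(r) + c/sqrt(r) fit)
reproduce the marker-based phylogenetics. "Genetic distance" is equated with
Jaccard distance (1 - similarity); the software originally used for the real
data does not document its formula, so this choice is explicit and the Ward
variant configurable.

## Problem sizes and reproducibility

The test-suite and acceptance runs use monoploid lengths of 10–100 kb,
1-Mb genomes for k-mer estimation, 20 accessions x ~500 peaks with 1000
bootstrap replications — sizes chosen so every recovery property is decided
by a comfortable statistical margin while a full run stays in the minutes
range on a single core. Every stochastic step takes an explicit integer
seed, and `run_pipeline()` writes a manifest with parameters and md5
checksums of every artifact; reruns under the same seed are byte-identical.

## Known limitations

* The aligner is banded around seed diagonals; alignments whose true indel
  offset exceeds the band (default 16 bp plus chain spread) are truncated or
  split. With the default substitution-only simulations this never occurs.
* The collapse assumes offsets compose additively along overlap chains,
  which holds for substitution-dominated divergence; dense indels would
  smear consensus columns rather than produce gapped alignments.
* Peak detection is heuristic (no mixture-model fitting by design); very low
  coverage (< ~12x) pushes the homozygous peak into the error region cap.
* The backbone assembly itself is accepted as input, not reconstructed from
  long reads; the contribution reproduced here is the windowed collapse of
  assembler output, not the assembler.
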