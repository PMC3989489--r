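# polydissect

Tools for dissecting heterozygous allopolyploid genomes by comparative
sequence analysis, in R.

Allo-octoploid plant genomes (the motivating case is cultivated strawberry,
with subgenome composition AA A'A' BB B'B') carry up to eight diverged copies
of every locus: two progenitor lineages, two homoeologous subgenomes per
lineage, two allelic haplotypes per subgenome. Conventional assembly of such
material yields several-fold the monoploid length in redundant fragments.
`polydissect` implements the alternative strategy of building a
*heterozygosity-collapsed virtual reference* — one consensus per locus — and
reading the polyploid structure off comparative mappings against it:

* **Synthetic truth** — `simulate_octoploid()` generates an allo-octoploid
  genome with configurable lineage (`d_prog`), homoeolog (`d_sub`) and
  allelic (`h_allelic`) divergence, seeded SSR tracts, fragmented assemblies
  (`fragment_assembly()`) and error-injected reads (`simulate_reads()`), all
  with recorded per-base truth, so every downstream stage is testable with
  no external data.
* **Genome size** — `count_kmer_spectrum()` / `estimate_genome_size()`:
  canonical k-mer (default k = 17) multiplicity spectrum; the k-mer mass
  above the error region divided by the homozygous coverage-peak depth;
  heterozygous material shows a second peak at half depth, reported
  separately.
* **QC and statistics** — `qc_reads()` (N removal, 3' quality < 10 trimming,
  3' adaptor trimming beyond 5 bases), `filter_by_length()` (>= 300 bp),
  `screen_contamination()` (E <= 1e-10 and >= 10% query coverage),
  `compute_assembly_stats()` (N50, GC% over ATGC).
* **Heterozygosity collapse** — `split_windows()` (300-bp windows, 200-bp
  overlaps), `find_overlaps()` (seed-voted overlaps >= 100 bp at >= 90%
  identity), `layout_consensus()` (cluster-verified agglomerative layout;
  depth-weighted majority consensus; eliminated heterozygous sites counted),
  `merge_unjoined()`, `build_virtual_reference()`.
* **Comparative mapping** — `align_sequences()` (seed-and-extend local
  alignment with PSL record semantics; BLAT-like and MEGABLAST-like
  presets), `apply_hit_filters()` (the four selection inequalities: c1 >= 80,
  c2 >= 80, c3 >= 25, 80 <= c4 <= 120, in percent of query length),
  `select_best_alignment()` (minCover 0.20), `classify_multiplicity()`
  (single/double/triple/quadruple/five-plus), `attribute_top_hits()`
  (progenitor shares), `compute_nonhomologous()`, `greedy_cluster()`
  (c = 0.8, aS = 0.1).
* **SSR census** — `find_ssrs()` (maximal perfect repeats, unit lengths 1–6
  at minimum counts 12/6/7/5/5/5, canonical motif classes),
  `summarize_ssrs()`.
* **Marker phylogenetics** — `jaccard_distance()`, `ward_cluster()`
  (ward.D2), `bootstrap_support()` (1000 column-resampling replications;
  optional multiscale scales with AU values), `summarize_group_distances()`.
* **Orchestration** — `run_pipeline()` runs simulate → QC → genome size →
  collapse → map/attribute → SSR → phylogenetics, writes every artifact in
  standard formats and a manifest with parameters and md5 checksums;
  identical seeds give byte-identical runs.

## Worked example

```r
library(polydissect)

cfg   <- sim_config(monoploid_length = 5e4, seed = 20)  # AAA'A'BBB'B', 8 x 50 kb
truth <- simulate_octoploid(cfg)

collapsed <- collapse_assembly(truth$haplotypes)
#> collapsed contigs: 1 | total length: 50000 | het sites eliminated: 5706

reads <- simulate_reads(truth$haplotypes, coverage = 20, read_length = 100,
                        error_rate = 0.005, seed = 21)
estimate_genome_size(count_kmer_spectrum(reads, k = 17))
#> Genome size estimate: 49,411 bp
#>   homozygous peak depth: 125
#>   heterozygous peak depth: 31
#>   error cutoff: m <= 5

loci <- find_ssrs(c(ancestor = truth$ancestor))
summarize_ssrs(loci, nchar(truth$ancestor))$density_per_100kb
#> [1] 16
```

The eight haplotypes (400 kb of sequence) collapse into a single 50-kb
consensus — the monoploid length — with every allelic and homoeologous
variant eliminated into a counted consensus column. The k-mer estimate
recovers the monoploid size because the deepest coverage peak aggregates all
eight copies of the shared sequence; the lower peak at roughly half depth is
the heterozygous fraction. The SSR density matches the seeded 16 loci per
100 kb.

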