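# End-to-end orchestration: simulate -> QC -> genome size -> collapse ->
# map/attribute -> SSR -> phylogenetics, with a reproducible run manifest.

#' Pipeline configuration
#'
#' Defaults mirror the standard analysis parameters: 300-bp windows with
#' 200-bp overlaps at 90% identity, 300-bp length filter, E-value cutoffs
#' 1e-10 (similarity) and 1e-50 (megablast-like), minIdentity 95 / minScore
#' 100, minCover 0.20, k = 17, 1000 bootstrap replications.
#'
#' @param sim A [sim_config()] describing the simulated octoploid.
#' @param genotype_sim A [genotype_sim_config()] for the marker stage.
#' @param stages Character vector of stages to run, in dependency order;
#'   subset of c("simulate", "qc", "gsize", "collapse", "map", "ssr", "phylo").
#' @param k k-mer size for genome-size estimation.
#' @param window,step,olc_identity Collapse parameters.
#' @param min_len Assembly length filter (inclusive).
#' @param min_identity,min_score BLAT-like mapping thresholds.
#' @param min_cover Best-hit minimum query coverage.
#' @param evalue_similarity,evalue_megablast E-value cutoffs.
#' @param bootstrap_reps Bootstrap replications for the phylo stage.
#' @param seed Global seed; stage seeds derive from it.
#' @param out_dir Output directory (created); NULL for a tempdir.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            genotype_sim = genotype_sim_config(),
                            stages = c("simulate", "qc", "gsize", "collapse",
                                       "map", "ssr", "phylo"),
                            k = 17, window = 300, step = 100,
                            olc_identity = 0.90, min_len = 300,
                            min_identity = 95, min_score = 100,
                            min_cover = 0.20,
                            evalue_similarity = 1e-10,
                            evalue_megablast = 1e-50,
                            bootstrap_reps = 1000,
                            seed = 1, out_dir = NULL) {
  stages <- match.arg(stages, c("simulate", "qc", "gsize", "collapse", "map",
                                "ssr", "phylo"), several.ok = TRUE)
  structure(as.list(environment()), class = "pipeline_config")
}

stage_seed <- function(seed, i) (seed * 101 + i * 7919) %% .Machine$integer.max

#' Run the dissection pipeline
#'
#' Executes the enabled stages in dependency order, writes every artifact to
#' `out_dir` in standard formats (FASTA/FASTQ/TSV/Newick/JSON), and records a
#' manifest with parameters, per-stage summaries and md5 checksums of every
#' artifact. Reruns with the same configuration are byte-identical.
#'
#' @param config A [pipeline_config()].
#' @return List of class `pipeline_run`: `manifest` (also written as JSON),
#'   `out_dir`, and in-memory stage results.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  if (is.null(out_dir)) out_dir <- tempfile("polydissect_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "polydissect",
                   version = as.character(utils::packageVersion("polydissect")),
                   seed = config$seed,
                   parameters = config[setdiff(names(config),
                                               c("sim", "genotype_sim",
                                                 "out_dir"))],
                   sim = unclass(config$sim),
                   genotype_sim = unclass(config$genotype_sim),
                   stages = list())
  results <- list()
  artifacts <- character(0)
  emit <- function(path) artifacts <<- c(artifacts, path)
  run_stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    res
  }

  sim <- config$sim
  sim$seed <- as.integer(stage_seed(config$seed, 1))
  truth <- run_stage("simulate", function() simulate_octoploid(sim))
  contigs <- fragment_assembly(truth, seed = stage_seed(config$seed, 2))
  reads <- simulate_reads(truth$haplotypes, coverage = sim$read_coverage,
                          read_length = sim$read_length,
                          error_rate = sim$error_rate,
                          seed = stage_seed(config$seed, 3))
  if ("simulate" %in% config$stages) {
    write_fasta(truth$haplotypes, file.path(out_dir, "haplotypes.fasta"))
    write_fasta(contigs, file.path(out_dir, "contigs.fasta"))
    write_fastq(reads, file.path(out_dir, "reads.fastq"))
    emit(file.path(out_dir, "haplotypes.fasta"))
    emit(file.path(out_dir, "contigs.fasta"))
    emit(file.path(out_dir, "reads.fastq"))
    manifest$stages$simulate <- list(
      n_haplotypes = length(truth$haplotypes),
      total_length = sum(nchar(truth$haplotypes)),
      n_contigs = length(contigs), n_reads = nrow(reads))
  }
  results$truth <- truth; results$contigs <- contigs

  if ("qc" %in% config$stages) {
    qc <- run_stage("qc", function() qc_reads(reads, qc_rules()))
    reads <- qc$reads
    lf <- filter_by_length(contigs, config$min_len)
    contigs <- lf$kept
    write_tsv(data.frame(cause = names(qc$log), count = as.integer(qc$log)),
              file.path(out_dir, "qc_log.tsv"))
    emit(file.path(out_dir, "qc_log.tsv"))
    manifest$stages$qc <- list(read_log = as.list(qc$log),
                               contigs_kept = length(contigs),
                               dropped_length = lf$dropped_total_length)
    stats <- compute_assembly_stats(contigs)
    write_tsv(assembly_stats_table(stats),
              file.path(out_dir, "assembly_stats.tsv"))
    emit(file.path(out_dir, "assembly_stats.tsv"))
    manifest$stages$qc$assembly_n50 <- unname(stats$n50)
    results$assembly_stats <- stats
  }

  if ("gsize" %in% config$stages) {
    gs <- run_stage("gsize", function() {
      sp <- count_kmer_spectrum(reads, k = config$k)
      list(spectrum = sp, estimate = estimate_genome_size(sp))
    })
    write_tsv(gs$spectrum$counts, file.path(out_dir, "kmer_histogram.tsv"))
    emit(file.path(out_dir, "kmer_histogram.tsv"))
    manifest$stages$gsize <- list(
      estimated_size = gs$estimate$estimated_size,
      homozygous_peak_depth = gs$estimate$homozygous_peak_depth,
      heterozygous_peak_depth = gs$estimate$heterozygous_peak_depth)
    results$genome_size <- gs$estimate
  }

  if ("collapse" %in% config$stages) {
    col <- run_stage("collapse", function()
      collapse_assembly(truth$haplotypes, window = config$window,
                        step = config$step,
                        min_identity = config$olc_identity))
    write_fasta(col$contigs, file.path(out_dir, "collapsed_reference.fasta"))
    emit(file.path(out_dir, "collapsed_reference.fasta"))
    manifest$stages$collapse <- list(
      n_contigs = length(col$contigs),
      total_length = sum(nchar(col$contigs)),
      het_sites_collapsed = sum(col$info$het_sites_collapsed),
      monoploid_length = truth$config$monoploid_length)
    results$collapsed <- col
  }

  if ("map" %in% config$stages) {
    stopifnot("collapse" %in% config$stages)
    map <- run_stage("map", function() {
      reference <- results$collapsed$contigs
      rec <- align_sequences(contigs, reference, mode = "blat_like",
                             min_identity = config$min_identity,
                             min_score = config$min_score)
      best <- select_best_alignment(apply_hit_filters(rec),
                                    min_cover = config$min_cover)
      mult <- classify_multiplicity(best)
      info <- parse_contig_id(best$q_name)
      lineage <- unname(truth$progenitor[info$subgenome])
      by_lineage <- split(best, lineage)
      attribution <- attribute_top_hits(by_lineage)
      list(records = rec, best = best, multiplicity = mult,
           attribution = attribution)
    })
    write_tsv(map$best, file.path(out_dir, "best_hits.psl.tsv"))
    write_tsv(map$multiplicity$by_class,
              file.path(out_dir, "multiplicity.tsv"))
    write_tsv(map$attribution$by_species,
              file.path(out_dir, "attribution.tsv"))
    emit(file.path(out_dir, "best_hits.psl.tsv"))
    emit(file.path(out_dir, "multiplicity.tsv"))
    emit(file.path(out_dir, "attribution.tsv"))
    manifest$stages$map <- list(
      n_records = nrow(map$records), n_mapped = nrow(map$best),
      multiplicity = stats::setNames(as.list(map$multiplicity$by_class$n_targets),
                                     map$multiplicity$by_class$class),
      attribution = stats::setNames(as.list(map$attribution$by_species$percent),
                                    map$attribution$by_species$species))
    results$map <- map
  }

  if ("ssr" %in% config$stages) {
    ssr <- run_stage("ssr", function() {
      loci <- find_ssrs(truth$haplotypes)
      list(loci = loci,
           summary = summarize_ssrs(loci, sum(nchar(truth$haplotypes))))
    })
    write_tsv(ssr$loci, file.path(out_dir, "ssr_loci.bed.tsv"))
    emit(file.path(out_dir, "ssr_loci.bed.tsv"))
    manifest$stages$ssr <- list(
      n_loci = ssr$summary$n_loci,
      n_di_to_hexa = ssr$summary$n_loci_di_to_hexa,
      density_per_100kb = ssr$summary$density_per_100kb)
    results$ssr <- ssr
  }

  if ("phylo" %in% config$stages) {
    phy <- run_stage("phylo", function() {
      gconf <- config$genotype_sim
      gconf$seed <- as.integer(stage_seed(config$seed, 4))
      gm <- simulate_marker_genotypes(gconf)
      bt <- bootstrap_support(gm, replications = config$bootstrap_reps,
                              seed = stage_seed(config$seed, 5))
      list(genotypes = gm, tree = bt)
    })
    gm_df <- as.data.frame(phy$genotypes)
    gm_df <- cbind(accession = rownames(phy$genotypes), gm_df)
    write_tsv(gm_df, file.path(out_dir, "genotypes.tsv"))
    tree_to_newick(phy$tree, file.path(out_dir, "tree.nwk"))
    emit(file.path(out_dir, "genotypes.tsv"))
    emit(file.path(out_dir, "tree.nwk"))
    manifest$stages$phylo <- list(
      n_accessions = nrow(phy$genotypes), n_peaks = ncol(phy$genotypes),
      median_bp = stats::median(phy$tree$node_support$bp))
    results$phylo <- phy
  }

  manifest$artifacts <- lapply(stats::setNames(artifacts, basename(artifacts)),
                               function(p) unname(tools::md5sum(p)))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  structure(list(manifest = manifest, out_dir = out_dir, results = results),
            class = "pipeline_run")
}
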