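# End-to-end orchestration: fixture generation, the full
# preprocess -> map -> cluster -> mobility -> annotate -> compare ->
# target-scan pipeline, and the report tables (per-sample cluster
# summary, mobile size-class summary, common/specific comparison). All
# percentage fields are recomputable from the printed counts; counts are
# never rounded; percentages are rounded half-up to one decimal place.

#' Per-sample cluster summary (report table)
#'
#' Derives every ratio printed alongside the raw counts of a cluster
#' prediction run: percent of reads in clusters, siRNA cluster count
#' (total minus miRNA), mean reads per cluster and mean cluster length.
#'
#' @param total_reads Total mapped reads in the sample.
#' @param reads_in_clusters Reads assigned to clusters.
#' @param n_clusters Total cluster count.
#' @param n_mirna miRNA-matched cluster count.
#' @param mean_cluster_length Mean cluster length (bp), passed through.
#' @return List of counts and derived fields (`pct_reads_in_clusters` at
#'   1 d.p., `n_sirna`, `mean_reads_per_cluster` rounded to integer).
#' @export
cluster_table_summary <- function(total_reads, reads_in_clusters,
                                  n_clusters, n_mirna,
                                  mean_cluster_length = NA_real_) {
  list(
    total_reads = total_reads,
    reads_in_clusters = reads_in_clusters,
    pct_reads_in_clusters_raw = pct_of(reads_in_clusters, total_reads),
    pct_reads_in_clusters = round_half_up(pct_of(reads_in_clusters,
                                                 total_reads), 1),
    n_clusters = n_clusters,
    n_mirna = n_mirna,
    n_sirna = n_clusters - n_mirna,
    mean_reads_per_cluster = round_half_up(
      if (n_clusters > 0) reads_in_clusters / n_clusters else 0, 0),
    mean_cluster_length = mean_cluster_length
  )
}

#' Write a synthetic heterograft fixture to disk
#'
#' A self-contained scenario: two SNP-diverged genomes (FASTA), gene and
#' repeat annotations (GFF3), contaminant references (FASTA), hairpin
#' database (FASTA), a term-annotation map (TSV), per-replicate FASTQ
#' libraries for both compartments, and the truth tables (TSV). The
#' `"medium"` scale is the package's reference study condition: two
#' 200-kb genomes at SNP rate 0.005, 3 replicates x 50,000 reads per
#' compartment, mobile fraction 0.05, no sequencing error, 40%
#' rRNA/tRNA-like contaminant admixture. `"small"` shrinks sizes for
#' fast end-to-end runs.
#'
#' @param outdir Output directory (created).
#' @param scale `"small"` or `"medium"`.
#' @param seed Integer seed; the fixture is byte-identical per seed.
#' @param error_rate Per-base substitution rate (default 0).
#' @param mobile_fraction Mobile read fraction (default 0.05).
#' @param snp_rate Genome divergence rate (default 0.005).
#' @return Invisibly, a named list of the file paths plus the in-memory
#'   objects (`pair`, `loci`, `annotation`, truth tables).
#' @export
make_fixture <- function(outdir, scale = c("small", "medium"), seed = 1,
                         error_rate = 0, mobile_fraction = 0.05,
                         snp_rate = 0.005) {
  scale <- match.arg(scale)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  dims <- if (scale == "medium") {
    list(n_chrom = 2L, chrom_len = 100000L, n_genes = 40L, n_repeats = 30L,
         n_s21 = 20L, n_s24 = 30L, n_mi = 6L, reads = 150000L)
  } else {
    list(n_chrom = 2L, chrom_len = 20000L, n_genes = 10L, n_repeats = 8L,
         n_s21 = 5L, n_s24 = 7L, n_mi = 2L, reads = 4500L)
  }
  pair <- simulate_genome_pair(dims$n_chrom, dims$chrom_len, snp_rate,
                               seed = derive_seed(seed, 1))
  annotation <- plant_annotations(pair, dims$n_genes, dims$n_repeats,
                                  seed = derive_seed(seed, 2))
  loci <- plant_loci(pair, annotation, dims$n_s21, dims$n_s24, dims$n_mi,
                     seed = derive_seed(seed, 3))
  contam <- simulate_contaminants(5, 2000, seed = derive_seed(seed, 4))
  sim_rec <- simulate_reads(pair, loci, "receptor", dims$reads,
                            mobile_fraction = mobile_fraction,
                            error_rate = error_rate, n_replicates = 3,
                            contaminant_fraction = 0.4,
                            contaminants = contam,
                            seed = derive_seed(seed, 5))
  sim_don <- simulate_reads(pair, loci, "donor", dims$reads,
                            mobile_fraction = mobile_fraction,
                            error_rate = error_rate, n_replicates = 3,
                            contaminant_fraction = 0.4,
                            contaminants = contam,
                            seed = derive_seed(seed, 6))
  # term map: every gene gets 1-3 of 12 generic terms
  set.seed(derive_seed(seed, 7))
  terms <- sprintf("TERM:%04d", 1:12)
  tm <- do.call(rbind, lapply(annotation$genes$id, function(g) {
    data.frame(gene_id = g,
               term_id = sample(terms, sample(1:3, 1)),
               stringsAsFactors = FALSE)
  }))
  paths <- list(
    donor_genome = file.path(outdir, "donor_genome.fa"),
    receptor_genome = file.path(outdir, "receptor_genome.fa"),
    annotation = file.path(outdir, "annotation.gff3"),
    contaminants = file.path(outdir, "contaminants.fa"),
    hairpins = file.path(outdir, "hairpins.fa"),
    snp_table = file.path(outdir, "snp_table.tsv"),
    loci = file.path(outdir, "loci.tsv"),
    term_map = file.path(outdir, "term_map.tsv"),
    truth_receptor = file.path(outdir, "truth_receptor.tsv"),
    truth_donor = file.path(outdir, "truth_donor.tsv")
  )
  write_fasta(pair$donor, paths$donor_genome)
  write_fasta(pair$receptor, paths$receptor_genome)
  write_gff3(annotation, paths$annotation)
  write_fasta(contam, paths$contaminants)
  hp <- hairpin_sequences(pair, loci, "receptor")
  if (length(hp)) write_fasta(hp, paths$hairpins)
  write_tsv(pair$snp_table, paths$snp_table)
  write_tsv(as.data.frame(loci), paths$loci)
  write_tsv(tm, paths$term_map)
  write_tsv(sim_rec$truth, paths$truth_receptor)
  write_tsv(sim_don$truth, paths$truth_donor)
  fq <- list()
  for (side in c("receptor", "donor")) {
    sim <- if (side == "receptor") sim_rec else sim_don
    for (r in unique(sim$reads$replicate)) {
      f <- file.path(outdir, sprintf("%s_%s.fastq", side, r))
      write_fastq(sim$reads[sim$reads$replicate == r, ], f)
      fq[[sprintf("%s_%s", side, r)]] <- f
    }
  }
  invisible(list(paths = c(paths, list(fastq = fq)), pair = pair,
                 loci = loci, annotation = annotation, term_map = tm,
                 truth_receptor = sim_rec$truth,
                 truth_donor = sim_don$truth,
                 contaminants = contam, hairpins = hp, seed = seed))
}

#' Run the full pipeline on a fixture directory
#'
#' Preprocesses each compartment's replicates, maps them to their own
#' genome, calls and dicer-scores clusters, classifies reads in both
#' mobility directions, calls mobile clusters on the donor genome of
#' each direction, annotates cluster sets, and compares mobile clusters
#' with the donor compartment's native clusters. Deterministic per seed.
#'
#' @param fixture_dir Directory written by [make_fixture()].
#' @param params A `cluster_params`.
#' @param seed Seed for multimapper resolution.
#' @param outdir Optional directory for TSV/JSON report files.
#' @return List of class `pipeline_report`: per-compartment summaries,
#'   mobility summaries (both directions), annotation tables,
#'   co-localization report, stage counts.
#' @export
run_pipeline <- function(fixture_dir, params = cluster_params(), seed = 1,
                         outdir = NULL) {
  need <- c("donor_genome.fa", "receptor_genome.fa", "annotation.gff3",
            "contaminants.fa")
  for (f in need) {
    if (!file.exists(file.path(fixture_dir, f))) {
      stop_arg("missing pipeline input: ", file.path(fixture_dir, f))
    }
  }
  donor_g <- read_fasta(file.path(fixture_dir, "donor_genome.fa"))
  receptor_g <- read_fasta(file.path(fixture_dir, "receptor_genome.fa"))
  annotation <- read_gff3(file.path(fixture_dir, "annotation.gff3"))
  contam <- read_fasta(file.path(fixture_dir, "contaminants.fa"))
  hp_path <- file.path(fixture_dir, "hairpins.fa")
  hairpins <- if (file.exists(hp_path)) read_fasta(hp_path) else NULL
  chrom_lengths <- setNames(nchar(receptor_g), names(receptor_g))

  idx <- list(donor = build_index(donor_g), receptor = build_index(receptor_g))
  compartments <- list()
  for (side in c("receptor", "donor")) {
    files <- sort(list.files(fixture_dir,
                             pattern = sprintf("^%s_rep\\d+\\.fastq(\\.gz)?$", side),
                             full.names = TRUE))
    if (!length(files)) stop_arg("no FASTQ files for compartment ", side)
    reads <- do.call(rbind, lapply(files, function(f) {
      read_fastq(f, replicate = sub("\\.fastq(\\.gz)?$", "",
                                    sub(sprintf("^%s_", side), "", basename(f))))
    }))
    pp <- preprocess_reads(reads, contaminant_refs = contam)
    mp <- map_readset(idx[[side]], pp$reads,
                      map_params("random_one", derive_seed(seed, 10)))
    cs <- build_clusters(mp$placements, params)
    cs <- call_dicer(cs)
    if (!is.null(hairpins) && nrow(cs$clusters)) {
      cs <- match_known_mirna(cs, pp$reads, hairpins)
    }
    cl <- cs$clusters
    summary <- cluster_table_summary(
      total_reads = length(mp$mapped_ids),
      reads_in_clusters = nrow(cs$assignments),
      n_clusters = nrow(cl),
      n_mirna = sum(!is.na(cl$mirna_match)),
      mean_cluster_length = if (nrow(cl)) round_half_up(mean(cl$end - cl$start), 0)
        else NA_real_)
    compartments[[side]] <- list(
      reads = pp$reads, stage_counts = pp$stage_counts,
      mapped_fraction = mp$mapped_fraction, clusters = cs,
      summary = summary,
      annotation = annotate_clusters(cs, annotation, chrom_lengths),
      depth = depth_categories(cs))
  }

  mobility <- list()
  for (dir_ in c("scion_to_rootstock", "rootstock_to_scion")) {
    # receptor compartment of SC->RT is the rootstock ("receptor" side);
    # of RT->SC, the scion ("donor" side)
    rec_side <- if (dir_ == "scion_to_rootstock") "receptor" else "donor"
    don_side <- setdiff(c("receptor", "donor"), rec_side)
    rep_ <- classify_reads(compartments[[rec_side]]$reads,
                           idx[[rec_side]], idx[[don_side]], dir_)
    mob_cs <- call_mobile_clusters(
      compartments[[rec_side]]$reads, rep_, idx[[don_side]], params,
      map_params("random_one", derive_seed(seed, 11)), hairpins)
    mobility[[dir_]] <- list(
      report = rep_,
      summary = summarize_mobility(rep_, mob_cs),
      clusters = mob_cs,
      annotation = annotate_clusters(mob_cs, annotation, chrom_lengths))
  }

  coloc <- co_localize(mobility$scion_to_rootstock$clusters,
                       compartments$donor$clusters,
                       labels = c("mobile_sc_to_rt", "donor_native"))

  report <- structure(list(compartments = compartments,
                           mobility = mobility, co_localization = coloc,
                           params = params, seed = seed),
                      class = "pipeline_report")
  if (!is.null(outdir)) write_pipeline_report(report, outdir)
  report
}

#' Write the report tables of a pipeline run
#'
#' @param report A `pipeline_report`.
#' @param outdir Output directory (created).
#' @export
write_pipeline_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (side in names(report$compartments)) {
    comp <- report$compartments[[side]]
    write_tsv(comp$stage_counts,
              file.path(outdir, sprintf("%s_stage_counts.tsv", side)))
    export_clusters(comp$clusters,
                    tsv_path = file.path(outdir, sprintf("%s_clusters.tsv", side)),
                    bed_path = file.path(outdir, sprintf("%s_clusters.bed", side)))
    s <- comp$summary
    write_tsv(data.frame(field = names(unlist(s)), value = unlist(s)),
              file.path(outdir, sprintf("%s_summary.tsv", side)))
  }
  for (dir_ in names(report$mobility)) {
    m <- report$mobility[[dir_]]
    u <- unlist(m$summary[!vapply(m$summary, is.list, logical(1))])
    write_tsv(data.frame(field = names(u), value = u),
              file.path(outdir, sprintf("%s_mobility.tsv", dir_)))
    export_clusters(m$clusters,
                    tsv_path = file.path(outdir,
                                         sprintf("%s_mobile_clusters.tsv", dir_)))
  }
  invisible(outdir)
}
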