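# Pipeline orchestration: one config drives simulate -> filter -> bin ->
# presence -> karyotype -> rearrangement -> phasing, and one report object
# collects every stage's output.

#' Default pipeline configuration
#'
#' All tunable parameters of every stage with their default values. The
#' defaults describe a synthetic 46,XY experiment on the 1/100-scale genome
#' with 8 tubes; set `simulate = NULL` and fill `tubes` (per-tube alignment
#' files) and `bulk_vcf` to run on real alignments instead.
#'
#' @return Nested list of parameters; round-trips losslessly through
#'   [write_config()]/[read_config()].
#' @export
default_config <- function() {
  list(
    seed = 1L,
    output_dir = "scs_output",
    simulate = list(
      genome_scale = 100L,
      chromosomes = NULL,          # NULL = all 24
      copy_numbers = NULL,         # e.g. list(chr21 = 3)
      translocations = NULL,       # list of list(chrom_a, pos_a, chrom_b, pos_b, junction_loss_b)
      snp_density = 2e-4,
      k_tubes = 8L,
      loss_prob = 0,
      fixed_partition = NULL,      # named list copy_id -> tube
      model = list(target_fraction = NA, amplicon_length_mean = 300,
                   read_length = 100, mean_depth_on_covered = 4,
                   noise_read_fraction = 0, epsilon = 0,
                   low_mapq_fraction = 0, chimeric_noise_rate = 0),
      bulk_depth = 30),
    tubes = NULL,                  # real mode: character vector of SAM/TSV paths
    bulk_vcf = NULL,               # real mode: bulk VCF path
    mapq_cutoff = 30,
    window_size = 1e4,
    fine_window = 500,
    presence = list(min_reads = 50, min_covered_fraction = 0.02,
                    whole_fraction_min = 0.8, gap_merge_windows = 3),
    rearrangement = list(min_support = 3, merge_tol = 0),
    phasing = list(min_depth = 10, min_qual = 30, common_only = TRUE,
                   min_site_depth = 2, allow_complement = TRUE),
    expected_copies = NULL)
}

merge_config <- function(base, override) {
  for (k in names(override)) {
    if (is.list(base[[k]]) && is.list(override[[k]]) &&
        !is.null(names(base[[k]])))
      base[[k]] <- merge_config(base[[k]], override[[k]])
    else base[k] <- override[k]
  }
  base
}

#' Build a run configuration
#'
#' Starts from [default_config()] and overrides nested fields.
#'
#' @param ... Named overrides, e.g.
#'   `scs_config(seed = 7, simulate = list(k_tubes = 16))`.
#' @return Config list.
#' @export
scs_config <- function(...) merge_config(default_config(), list(...))

#' Write / read a pipeline configuration file (YAML)
#'
#' @param config Config list.
#' @param path File path.
#' @return `path` / the config list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) merge_config(default_config(),
                                           yaml::read_yaml(path))

sim_from_config <- function(cfg, seed) {
  sim <- cfg$simulate
  genome <- mini_genome(sim$genome_scale,
                        chromosomes = unlist(sim$chromosomes))
  trs <- lapply(sim$translocations, function(tr)
    translocation(tr$chrom_a, tr$pos_a, tr$chrom_b, tr$pos_b,
                  if (is.null(tr$junction_loss_b)) 0 else tr$junction_loss_b))
  spec <- karyotype_spec(genome, copy_numbers = unlist(sim$copy_numbers),
                         translocations = trs,
                         snp_density = sim$snp_density)
  copies <- build_karyotype(spec)
  partition <- if (!is.null(sim$fixed_partition)) {
    manual_partition(unlist(sim$fixed_partition), sim$k_tubes)
  } else {
    partition_copies(copies, sim$k_tubes, sim$loss_prob, seed = seed)
  }
  truth <- plant_snps(copies, sim$snp_density, seed = seed + 1L)
  model <- do.call(coverage_model, sim$model)
  simulated <- simulate_reads(copies, partition, truth, model,
                              seed = seed + 2L)
  list(genome = genome, copies = copies, partition = partition,
       truth = truth, model = model, reads = simulated$reads,
       observations = simulated$observations)
}

#' Run the full SCS analysis pipeline
#'
#' Executes MAPQ filtering, window binning, presence calling, karyotype
#' summary, translocation detection (when complementary fragments exist)
#' and haplotype phasing (when bulk variants are available), in order. In
#' synthetic mode (`config$simulate` set) the inputs are generated with the
#' configured seeds and the truth is kept for scoring; in real mode the
#' per-tube alignment files and bulk VCF named in the config are read.
#'
#' @param config Config list from [scs_config()] / [read_config()].
#' @return A `run_report`: list with `config`, `qc` (per-tube read counts
#'   in/out), `window_counts`, `presence`, `karyotype`, `candidates`,
#'   `breakpoints`, `phased`, `phasing_metrics` (synthetic mode), `truth`
#'   objects (synthetic mode).
#' @export
run_pipeline <- function(config) {
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  truth <- NULL; partition <- NULL; observations <- NULL
  if (!is.null(config$simulate)) {
    sim <- sim_from_config(config, seed)
    genome <- sim$genome
    reads <- sim$reads
    observations <- sim$observations
    truth <- sim$truth
    partition <- sim$partition
    bulk <- data.frame(chrom = truth$chrom, pos = truth$pos, ref = truth$ref,
                       alt = truth$alt, depth = config$simulate$bulk_depth,
                       quality = 60, is_common = TRUE, genotype = "0|1")
  } else {
    if (is.null(config$tubes)) stop("config needs either simulate or tubes")
    reads <- do.call(rbind, lapply(seq_along(config$tubes), function(i)
      read_alignments(config$tubes[[i]], tube = i)))
    genome <- NULL
    if (!is.null(config$genome_lengths)) genome <- unlist(config$genome_lengths)
    if (is.null(genome)) {
      sp <- read_spans(reads)
      genome <- tapply(sp$end, sp$chrom, max)
      genome <- stats::setNames(as.numeric(genome), names(genome))
    }
    bulk <- if (!is.null(config$bulk_vcf)) read_bulk_vcf(config$bulk_vcf)
            else NULL
  }
  qc_in <- table(factor(reads$tube, levels = sort(unique(reads$tube))))
  reads <- filter_reads(reads, config$mapq_cutoff)
  qc_out <- table(factor(reads$tube, levels = names(qc_in)))
  qc <- data.frame(tube = as.integer(names(qc_in)),
                   reads_in = as.integer(qc_in),
                   reads_pass_mapq = as.integer(qc_out))
  wcm <- bin_reads(reads, config$window_size, genome,
                   n_tubes = if (!is.null(config$simulate))
                     config$simulate$k_tubes else length(config$tubes))
  presence <- do.call(call_presence, c(list(wcm), config$presence))
  karyotype <- summarize_karyotype(presence, unlist(config$expected_copies))
  candidates <- pair_fragments(presence)
  breakpoints <- list()
  for (cand in candidates) {
    cand <- narrow_region(reads, cand, config$fine_window)
    chim <- collect_chimeric(reads, cand)
    bp <- refine_breakpoint(chim, config$rearrangement$min_support,
                            config$rearrangement$merge_tol)
    bp$candidate <- cand
    breakpoints[[length(breakpoints) + 1L]] <- bp
  }
  phased <- list(); phasing_metrics <- NULL
  if (!is.null(bulk)) {
    snps <- do.call(filter_bulk_snps,
                    c(list(bulk), config$phasing[c("min_depth", "min_qual",
                                                   "common_only")]))
    tubes_of <- separated_chromosome_tubes(presence)
    counts <- if (!is.null(observations)) count_alleles(observations, snps)
              else NULL
    if (!is.null(counts)) {
      for (chrom in names(tubes_of)) {
        het <- snps[snps$chrom == chrom, , drop = FALSE]
        if (nrow(het) == 0) next
        phased[[chrom]] <- phase_chromosome(
          het, counts, tubes_of[[chrom]],
          min_site_depth = config$phasing$min_site_depth,
          allow_complement = config$phasing$allow_complement)
      }
    }
    if (!is.null(truth) && length(phased) > 0)
      phasing_metrics <- evaluate_phasing(phased, truth)
  }
  structure(list(config = config, qc = qc, window_counts = wcm,
                 presence = presence, karyotype = karyotype,
                 candidates = candidates, breakpoints = breakpoints,
                 phased = phased, phasing_metrics = phasing_metrics,
                 truth = truth, partition = partition),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  called <- sum(vapply(x$breakpoints, function(b) b$status == "CALLED",
                       logical(1)))
  cat(sprintf("<run_report: %d tubes, %d reads pass MAPQ; %s; %d translocation call(s); %d chromosome(s) phased>\n",
              nrow(x$qc), sum(x$qc$reads_pass_mapq),
              sprintf("%d separated pairs", x$karyotype$separated_pairs),
              called, length(x$phased)))
  invisible(x)
}

#' Write all pipeline outputs to a directory
#'
#' Emits `report.json` (QC, karyotype, breakpoint calls, phasing metrics,
#' provenance), `window_counts.tsv` (Circos-ring table),
#' `presence_matrix.tsv` and `presence_calls.tsv`, `edge_regions.bed`,
#' `breakpoints.vcf` (BND) and `phased.vcf`.
#'
#' @param report A `run_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir))
    if (!dir.create(dir, recursive = TRUE))
      stop("cannot create output directory ", dir)
  genome <- report$window_counts$chrom_lengths
  write_window_counts_tsv(report$window_counts,
                          file.path(dir, "window_counts.tsv"))
  write_presence_tsv(report$presence, file.path(dir, "presence_matrix.tsv"))
  utils::write.table(report$presence$calls,
                     file.path(dir, "presence_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(report$candidates) > 0) {
    regions <- do.call(rbind, lapply(report$candidates, function(cand)
      data.frame(chrom = c(cand$chrom_a, cand$chrom_b),
                 start = c(cand$edge_region_a[["start"]],
                           cand$edge_region_b[["start"]]),
                 end = c(cand$edge_region_a[["end"]],
                         cand$edge_region_b[["end"]]),
                 name = sprintf("t(%s;%s)_edge_%s",
                                sub("^chr", "", cand$chrom_a),
                                sub("^chr", "", cand$chrom_b),
                                c("a", "b")))))
    write_bed(regions, file.path(dir, "edge_regions.bed"))
  }
  for (bp in report$breakpoints)
    if (bp$status == "CALLED")
      write_bnd_vcf(bp, file.path(dir, "breakpoints.vcf"), genome)
  if (length(report$phased) > 0)
    write_phased_vcf(report$phased, file.path(dir, "phased.vcf"), genome)
  cfg_file <- file.path(dir, "config.yaml")
  write_config(report$config, cfg_file)
  bp_json <- lapply(report$breakpoints, function(bp)
    if (bp$status == "CALLED")
      list(status = bp$status, chrom_a = bp$chrom_a, pos_a = bp$pos_a,
           chrom_b = bp$chrom_b, pos_b = bp$pos_b,
           junction_gap_b = bp$junction_gap_b, n_support = bp$n_support,
           consensus_fraction = bp$consensus_fraction)
    else list(status = bp$status, reason = bp$reason))
  json <- list(
    qc = report$qc,
    karyotype = list(
      separated_pairs = report$karyotype$separated_pairs,
      missing = report$karyotype$missing,
      anomalies = report$karyotype$anomalies,
      per_chromosome = report$karyotype$per_chromosome),
    breakpoints = bp_json,
    phasing = if (!is.null(report$phasing_metrics)) list(
      accuracy = report$phasing_metrics$accuracy,
      phased_fraction_separated =
        report$phasing_metrics$phased_fraction_separated,
      phased_fraction_all = report$phasing_metrics$phased_fraction_all,
      conflicts = report$phasing_metrics$conflicts) else NULL,
    provenance = list(seed = report$config$seed,
                      package_version =
                        as.character(utils::packageVersion("scskit")),
                      config_md5 = unname(tools::md5sum(cfg_file))))
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       na = "null")
  invisible(dir)
}
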