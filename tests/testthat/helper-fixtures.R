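# Shared simulation fixtures.
#
# Two families: a two-chromosome balanced-translocation cell (chrA/chrB at
# a few hundred kb, junction chrA:148,560 | chrB:73,601 with one base of
# chrB lost) and a reduced 46,XY cell on a subset of the 1/100-scale
# genome. Sizes are chosen so a full simulate->call cycle takes well under
# a second.

two_chrom_genome <- c(chrA = 3e5, chrB = 2.5e5)

t35_event <- function(loss = 1) {
  translocation("chrA", 148560, "chrB", 73601, loss)
}

t35_copies <- function(snp_density = 0, loss = 1) {
  build_karyotype(karyotype_spec(two_chrom_genome,
                                 translocations = list(t35_event(loss)),
                                 snp_density = snp_density))
}

# intact homologs in tubes 1/2, derivatives in tubes 3/4
t35_partition <- function() {
  manual_partition(c(chrA.1 = 1, chrB.1 = 2,
                     `der(A)t(A;B)` = 3, `der(B)t(A;B)` = 4), 4)
}

deep_model <- function(...) {
  coverage_model(target_fraction = 0.98, mean_depth_on_covered = 40, ...)
}

sim_t35 <- function(seed, model = deep_model(), copies = t35_copies(),
                    truth = plant_snps(copies, 0)) {
  simulate_reads(copies, t35_partition(), truth, model, seed = seed)
}

t35_presence <- function(reads, window = 1e4) {
  call_presence(bin_reads(filter_reads(reads), window, two_chrom_genome,
                          n_tubes = 4))
}

# reduced 46,XY genome: a spread of sizes including the smallest chromosome
small_genome <- function() {
  mini_genome(chromosomes = c("chr1", "chr8", "chr13", "chr16", "chr19",
                              "chr21", "chrX", "chrY"))
}

sim_small_xy <- function(seed, model = coverage_model(), snp_density = 2e-4,
                         k = 8, loss_prob = 0) {
  copies <- build_karyotype(karyotype_spec(small_genome(),
                                           snp_density = snp_density))
  partition <- partition_copies(copies, k, loss_prob, seed = seed)
  truth <- plant_snps(copies, snp_density, seed = seed + 1L)
  sim <- simulate_reads(copies, partition, truth, model, seed = seed + 2L)
  list(genome = small_genome(), copies = copies, partition = partition,
       truth = truth, reads = sim$reads, observations = sim$observations)
}

# truth presence set: which chromosomes have >= 1 copy in which tube
truth_presence <- function(copies, partition) {
  tube <- partition$assignment
  chrom <- vapply(copies, `[[`, character(1), "chrom")
  keep <- !is.na(tube)
  unique(data.frame(tube = unname(tube[keep]), chrom = chrom[keep]))
}

# does the called presence equal the truth partition exactly (all present
# (tube, chrom) pairs WHOLE, everything else ABSENT)?
presence_matches_truth <- function(presence, copies, partition) {
  tp <- truth_presence(copies, partition)
  called <- presence$calls[presence$calls$status == "WHOLE",
                           c("tube", "chrom")]
  nrow(called) == nrow(tp) &&
    nrow(merge(tp, called)) == nrow(tp) &&
    !any(presence$calls$status == "FRAGMENT")
}
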