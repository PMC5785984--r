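bulk_fixture <- function() {
  data.frame(chrom = "chr16", pos = c(10, 20, 30, 40, 50),
             ref = "G", alt = "A",
             depth = c(30, 10, 11, 30, 30),
             quality = c(60, 60, 60, 30, 31),
             is_common = c(TRUE, TRUE, TRUE, TRUE, FALSE),
             genotype = c("0/1", "0/1", "0/1", "0/1", "0/1"))
}

test_that("bulk SNP filters use strict depth/quality thresholds", {
  v <- bulk_fixture()
  kept <- filter_bulk_snps(v)
  expect_equal(kept$pos, c(10, 30))   # depth 10 and qual 30 are excluded
  all_snps <- filter_bulk_snps(v, common_only = FALSE)
  expect_true(all(kept$pos %in% all_snps$pos))
  expect_equal(all_snps$pos, c(10, 30, 50))

  hom <- transform(v, genotype = "1/1")
  expect_equal(nrow(filter_bulk_snps(hom)), 0)

  bad <- v; bad$depth[1] <- NA
  expect_warning(out <- filter_bulk_snps(bad), "malformed")
  expect_false(10 %in% out$pos)
})

test_that("allele-ratio classes follow the 20/80 thresholds", {
  g <- classify_allele_ratio(c(1, 5, 9, 0, 4, 1, 0), c(9, 5, 1, 0, 1, 4, 1))
  expect_equal(g$class,
               c("HOM_ALT", "HET", "REF", "NO_CALL", "HET", "HET", "NO_CALL"))
  # boundaries 20% and 80% are heterozygous (inclusive)
  expect_equal(classify_allele_ratio(8, 2)$class, "HET")
  expect_equal(classify_allele_ratio(2, 8)$class, "HET")
  expect_equal(classify_allele_ratio(1, 9)$class, "HOM_ALT")
  expect_true(is.na(classify_allele_ratio(0, 0)$alt_ratio))
})

test_that("three distant loci phase into complementary haplotypes", {
  # bulk genotypes G/A, G/C, G/A; one copy reads A, G, A; the other G, C, G
  het <- data.frame(chrom = "chr16", pos = c(587948, 52021811, 89176878),
                    ref = c("G", "G", "G"), alt = c("A", "C", "A"))
  counts <- data.frame(
    tube = c(1, 1, 1, 2, 2, 2), chrom = "chr16",
    pos = rep(het$pos, 2),
    ref_count = c(0, 5, 0, 6, 0, 4),
    alt_count = c(4, 0, 5, 0, 7, 0))
  ph <- phase_chromosome(het, counts, c(1, 2))
  expect_equal(ph$snps$allele0, c("A", "G", "A"))
  expect_equal(ph$snps$allele1, c("G", "C", "G"))
  expect_true(all(ph$snps$evidence == "both_tubes"))

  expect_error(phase_chromosome(het, counts, c(2, 2)), "distinct tubes")
})

test_that("single-tube sites phase by complement, conflicts stay unphased", {
  het <- data.frame(chrom = "chr1", pos = c(100, 200, 300, 400),
                    ref = "G", alt = "A")
  counts <- data.frame(
    tube = c(1, 1, 2, 1, 2), chrom = "chr1",
    pos = c(100, 200, 200, 300, 300),
    ref_count = c(0, 5, 5, 3, 0),
    alt_count = c(4, 0, 0, 3, 4))
  ph <- phase_chromosome(het, counts, c(1, 2))
  expect_equal(ph$snps$evidence,
               c("single_tube_complement", "conflict_unphased",
                 "conflict_unphased", "uncovered"))
  expect_equal(ph$snps$allele0[1], "A")
  expect_equal(ph$snps$allele1[1], "G")
  off <- phase_chromosome(het, counts, c(1, 2), allow_complement = FALSE)
  expect_true(is.na(off$snps$allele0[1]))
})

test_that("noiseless simulation phases without conflicts at accuracy 1", {
  copies <- build_karyotype(karyotype_spec(c(chr16 = 9e5)))
  part <- manual_partition(c(chr16.0 = 1, chr16.1 = 2), 2)
  truth <- plant_snps(copies, 5e-4, seed = 8)
  sim <- simulate_reads(copies, part, truth,
                        coverage_model(target_fraction = 0.2,
                                       mean_depth_on_covered = 6), seed = 9)
  counts <- count_alleles(sim$observations, truth)
  ph <- phase_chromosome(truth[, c("chrom", "pos", "ref", "alt")], counts,
                         c(1, 2))
  m <- evaluate_phasing(list(ph), truth)
  expect_equal(m$accuracy, 1)
  expect_equal(m$conflicts, 0)
  # both phasing routes are scored separately and both are perfect here
  expect_equal(m$by_evidence$n,
               c(sum(ph$snps$evidence == "both_tubes"),
                 sum(ph$snps$evidence == "single_tube_complement")))
  expect_true(all(m$by_evidence$accuracy[m$by_evidence$n > 0] == 1))
  expect_gt(m$phased_fraction_separated, 0)
  expect_true(all(stats::na.omit(ph$snps$allele0 != ph$snps$allele1)))

  # copy labels are arbitrary: swapping them leaves accuracy unchanged
  swapped <- ph
  swapped$snps$allele0 <- ph$snps$allele1
  swapped$snps$allele1 <- ph$snps$allele0
  expect_equal(evaluate_phasing(list(swapped), truth)$accuracy, 1)
})

test_that("phased fraction grows with sequencing depth", {
  frac_at_depth <- function(depth) {
    mean(vapply(1:10, function(s) {
      copies <- build_karyotype(karyotype_spec(c(chr16 = 4e5)))
      part <- manual_partition(c(chr16.0 = 1, chr16.1 = 2), 2)
      truth <- plant_snps(copies, 5e-4, seed = s)
      sim <- simulate_reads(copies, part, truth,
                            coverage_model(target_fraction = 0.15,
                                           mean_depth_on_covered = depth),
                            seed = s + 50)
      counts <- count_alleles(sim$observations, truth)
      ph <- phase_chromosome(truth[, c("chrom", "pos", "ref", "alt")],
                             counts, c(1, 2))
      evaluate_phasing(list(ph), truth)$phased_fraction_separated
    }, numeric(1)))
  }
  f <- vapply(c(2, 6, 18), frac_at_depth, numeric(1))
  expect_true(all(diff(f) > 0))
})
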