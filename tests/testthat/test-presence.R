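test_that("MAPQ filtering is a strict threshold", {
  reads <- data.frame(tube = 1L, chrom = "chrA", pos = c(1, 2, 3),
                      length = 100, mapq = c(29L, 30L, 60L),
                      chrom2 = NA_character_, pos2 = NA_real_,
                      length2 = NA_real_, source_copy = NA_character_)
  expect_equal(filter_reads(reads, 30)$mapq, c(30L, 60L))
  expect_identical(filter_reads(reads, 0), reads)
  all60 <- transform(reads, mapq = 60L)
  expect_equal(nrow(filter_reads(all60, 30)), 3)
})

test_that("reads land in the window containing their leftmost base", {
  genome <- c(chrA = 3e6)
  reads <- data.frame(tube = 1L, chrom = "chrA",
                      pos = c(1, 1e6, 1e6 + 1, 1500000, 2999999),
                      length = 100, mapq = 60L, chrom2 = NA_character_,
                      pos2 = NA_real_, length2 = NA_real_,
                      source_copy = NA_character_)
  wcm <- bin_reads(reads, 1e6, genome)
  expect_equal(as.integer(wcm$counts$chrA), c(2L, 2L, 1L))
  expect_equal(sum(wcm$counts$chrA), nrow(reads))

  empty <- bin_reads(reads[0, ], 1e6, genome, n_tubes = 2)
  expect_true(all(empty$counts$chrA == 0))
  expect_equal(dim(empty$counts$chrA), c(2L, 3L))

  bad <- transform(reads, pos = 4e6)
  expect_error(bin_reads(bad, 1e6, genome), "beyond chromosome end")
  expect_error(bin_reads(transform(reads, chrom = "chrZ"), 1e6, genome),
               "unknown")

  # bases mode splits boundary-straddling reads across their windows:
  # the read starting at 1e6 leaves one base in window 0 and 99 in window
  # 1; the read at 2,999,999 keeps only its 2 in-chromosome bases
  wb <- bin_reads(reads, 1e6, genome, mode = "bases")
  expect_equal(as.numeric(wb$counts$chrA),
               c(100 + 1, 99 + 100 + 100, 2))
})

test_that("presence status reflects coverage on simulated data", {
  copies <- build_karyotype(karyotype_spec(c(chrA = 1e6),
                                           copy_numbers = c(chrA = 1)))
  part <- manual_partition(c(chrA.0 = 1), 1)
  sim <- simulate_reads(copies, part, plant_snps(copies, 0),
                        coverage_model(target_fraction = 0.15), seed = 3)
  wcm <- bin_reads(sim$reads, 1e4, c(chrA = 1e6))
  pres <- call_presence(wcm)
  expect_equal(pres$calls$status, "WHOLE")

  zero <- call_presence(bin_reads(sim$reads[0, ], 1e4, c(chrA = 1e6)))
  expect_equal(zero$calls$status, "ABSENT")
})

test_that("derivative-donor tubes yield complementary fragments at the junction", {
  sim <- sim_t35(4)
  pres <- t35_presence(sim$reads)
  calls <- pres$calls
  get <- function(tb, ch) calls$status[calls$tube == tb & calls$chrom == ch]
  expect_equal(get(1, "chrA"), "WHOLE")
  expect_equal(get(2, "chrB"), "WHOLE")
  expect_equal(get(3, "chrA"), "FRAGMENT")
  expect_equal(get(3, "chrB"), "FRAGMENT")
  expect_equal(get(4, "chrA"), "FRAGMENT")
  expect_equal(get(4, "chrB"), "FRAGMENT")
  # the A fragment in the der(A) tube ends in the window containing pos_a
  iv <- pres$intervals[["3:chrA"]]
  expect_equal(max(iv$win_to), (148560 - 1) %/% 1e4)
  # and the A fragment in the der(B) tube starts there too
  iv2 <- pres$intervals[["4:chrA"]]
  expect_equal(min(iv2$win_from), (148561 - 1) %/% 1e4)
})

test_that("noiseless presence recovers the truth partition", {
  ok <- 0
  for (s in 1:10) {
    run <- sim_small_xy(seed = 100 + s)
    pres <- call_presence(bin_reads(filter_reads(run$reads), 1e4,
                                    run$genome, n_tubes = 8))
    if (presence_matches_truth(pres, run$copies, run$partition)) ok <- ok + 1
  }
  expect_gte(ok, 9)
})

test_that("karyotype summaries flag trisomy and XXY and count separation", {
  # trisomy 21 with the three copies in distinct tubes
  genome <- mini_genome(chromosomes = c("chr1", "chr21"))
  copies <- build_karyotype(karyotype_spec(genome,
                                           copy_numbers = c(chr21 = 3)))
  part <- manual_partition(c(chr1.0 = 2, chr1.1 = 4,
                             chr21.0 = 1, chr21.1 = 6, chr21.2 = 8), 8)
  sim <- simulate_reads(copies, part, plant_snps(copies, 0),
                        coverage_model(target_fraction = 0.15), seed = 9)
  pres <- call_presence(bin_reads(sim$reads, 1e4, genome, n_tubes = 8))
  ks <- summarize_karyotype(pres, expected_copies = c(chr1 = 2, chr21 = 2))
  row21 <- ks$per_chromosome[ks$per_chromosome$chrom == "chr21", ]
  expect_equal(row21$observed_whole, 3)
  expect_equal(row21$tubes, "1,6,8")
  expect_match(ks$anomalies, "chr21.*trisomy", all = FALSE)

  # XXY: two X in tubes 5 and 8, Y in tube 3
  genome <- mini_genome(chromosomes = c("chrX", "chrY"))
  copies <- build_karyotype(karyotype_spec(genome,
                                           copy_numbers = c(chrX = 2,
                                                            chrY = 1)))
  part <- manual_partition(c(chrX.0 = 5, chrX.1 = 8, chrY.0 = 3), 8)
  sim <- simulate_reads(copies, part, plant_snps(copies, 0),
                        coverage_model(target_fraction = 0.15), seed = 10)
  pres <- call_presence(bin_reads(sim$reads, 1e4, genome, n_tubes = 8))
  ks <- summarize_karyotype(pres, expected_copies = c(chrX = 1, chrY = 1))
  pc <- ks$per_chromosome
  expect_equal(pc$observed_whole[pc$chrom == "chrX"], 2)
  expect_equal(pc$tubes[pc$chrom == "chrX"], "5,8")
  expect_equal(pc$observed_whole[pc$chrom == "chrY"], 1)
  expect_match(ks$anomalies, "chrX", all = FALSE)
})

test_that("perfect separation of a 46,XY cell is reported as 22 pairs", {
  run <- sim_small_xy(seed = 55)
  copies <- run$copies
  chrom <- vapply(copies, `[[`, character(1), "chrom")
  # force every pair into distinct tubes
  asg <- integer(length(copies))
  tube_a <- rep(1:8, length.out = sum(!duplicated(chrom)))
  for (i in seq_along(unique(chrom))) {
    ch <- unique(chrom)[i]
    idx <- which(chrom == ch)
    asg[idx] <- c(tube_a[i], tube_a[i] %% 8 + 1)[seq_along(idx)]
  }
  part <- manual_partition(stats::setNames(asg, vapply(copies, `[[`,
                                                       character(1),
                                                       "copy_id")), 8)
  sim <- simulate_reads(copies, part, run$truth, coverage_model(), seed = 77)
  pres <- call_presence(bin_reads(sim$reads, 1e4, run$genome, n_tubes = 8))
  ks <- summarize_karyotype(pres)
  autosomes <- setdiff(names(run$genome), c("chrX", "chrY"))
  expect_equal(ks$separated_pairs, length(autosomes))
  expect_equal(ks$missing, 0)
  expect_length(ks$anomalies, 0)
})
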