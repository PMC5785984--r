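one_mb_copy <- function() {
  build_karyotype(karyotype_spec(c(chrA = 1e6), copy_numbers = c(chrA = 1),
                                 snp_density = 0))
}

test_that("planted SNPs are heterozygous, unique and Poisson-distributed", {
  copies <- build_karyotype(karyotype_spec(small_genome()))
  expect_equal(nrow(plant_snps(copies, 0)), 0)

  truth <- plant_snps(copies, 2e-4, seed = 1)
  expect_true(all(truth$allele0 != truth$allele1))
  expect_true(all(truth$allele0 == truth$ref | truth$allele0 == truth$alt))
  expect_false(any(duplicated(paste(truth$chrom, truth$pos))))
  expect_identical(truth, plant_snps(copies, 2e-4, seed = 1))

  # Poisson mean: density 1e-3 on a 1 Mb chromosome ~ 1000 per seed
  mb <- one_mb_copy()
  counts <- vapply(1:100, function(s) nrow(plant_snps(mb, 1e-3, seed = s)),
                   numeric(1))
  se <- sqrt(1000 / 100)
  expect_lt(abs(mean(counts) - 1000), 3 * se)
})

test_that("dilution loses and separates copies at the expected rates", {
  copies <- build_karyotype(karyotype_spec())
  part <- partition_copies(copies, 1, 0, seed = 1)
  expect_true(all(part$assignment == 1))

  # E[lost] = 46 * 6/46 = 6 over many seeds
  lost <- vapply(1:1000, function(s)
    sum(is.na(partition_copies(copies, 8, 6 / 46, seed = s)$assignment)),
    numeric(1))
  se <- sd(lost) / sqrt(length(lost))
  expect_lt(abs(mean(lost) - 6), 3 * se)

  # mean separated pairs matches the analytic n(k-1)/k of the design module
  chrom <- vapply(copies, `[[`, character(1), "chrom")
  pairs <- names(which(table(chrom) == 2))
  sep <- vapply(1:3000, function(s) {
    a <- partition_copies(copies, 8, 0, seed = 10000 + s)$assignment
    sum(vapply(pairs, function(ch) {
      t2 <- a[chrom == ch]
      t2[1] != t2[2]
    }, logical(1)))
  }, numeric(1))
  se <- sd(sep) / sqrt(length(sep))
  expect_lt(abs(mean(sep) - expected_separated_pairs(length(pairs), 8)),
            3 * se)
})

test_that("noiseless reads stay inside their source copy's segments", {
  copies <- one_mb_copy()
  part <- manual_partition(c(chrA.0 = 1), 1)
  sim <- simulate_reads(copies, part, plant_snps(copies, 0),
                        coverage_model(target_fraction = 0.1), seed = 2)
  expect_gt(nrow(sim$reads), 0)
  expect_true(all(sim$reads$chrom == "chrA"))
  expect_true(all(sim$reads$pos >= 1 &
                    sim$reads$pos + sim$reads$length - 1 <= 1e6))
  expect_true(all(is.na(sim$reads$chrom2)))
  expect_true(all(sim$reads$mapq == 60))
  expect_identical(sim, simulate_reads(copies, part, plant_snps(copies, 0),
                                       coverage_model(target_fraction = 0.1),
                                       seed = 2))
})

test_that("base coverage approximates the target fraction", {
  copies <- one_mb_copy()
  part <- manual_partition(c(chrA.0 = 1), 1)
  for (tf in c(0.05, 0.12, 0.22)) {
    sim <- simulate_reads(copies, part, plant_snps(copies, 0),
                          coverage_model(target_fraction = tf), seed = 7)
    cov <- logical(1e6)
    for (i in seq_len(nrow(sim$reads)))
      cov[sim$reads$pos[i]:(sim$reads$pos[i] + sim$reads$length[i] - 1)] <- TRUE
    expect_lt(abs(mean(cov) - tf), 0.03)
  }
})

test_that("junction-spanning reads carry the split segment", {
  found <- FALSE
  for (s in 1:5) {
    sim <- sim_t35(s)
    split <- sim$reads[!is.na(sim$reads$chrom2), ]
    if (nrow(split) == 0) next
    found <- TRUE
    # every split read implies one of the two planted junction pairs:
    # der(A): chrA:148560 | chrB:73601; der(B): chrB:73599 | chrA:148561
    j1 <- split$pos + split$length - 1
    j2 <- split$pos2
    der_a <- split$chrom == "chrA" & j1 == 148560 &
      split$chrom2 == "chrB" & j2 == 73601
    der_b <- split$chrom == "chrB" & j1 == 73599 &
      split$chrom2 == "chrA" & j2 == 148561
    expect_true(all(der_a | der_b))
    # split reads come only from derivative-bearing tubes
    expect_true(all(split$tube %in% c(3, 4)))
  }
  expect_true(found)
})

test_that("allele observations are error-free truth at epsilon 0", {
  copies <- build_karyotype(karyotype_spec(c(chrA = 5e5)))
  part <- manual_partition(c(chrA.0 = 1, chrA.1 = 2), 2)
  truth <- plant_snps(copies, 1e-3, seed = 5)
  sim <- simulate_reads(copies, part, truth,
                        coverage_model(target_fraction = 0.2), seed = 6)
  obs <- sim$observations
  expect_gt(nrow(obs), 0)
  i <- match(obs$pos, truth$pos)
  h <- ifelse(obs$source_copy == "chrA.0", 0, 1)
  expected <- ifelse(h == 0, truth$allele0[i], truth$allele1[i])
  expect_equal(obs$base, expected)
})

test_that("per-tube read totals grow with the chromosomes present", {
  run <- sim_small_xy(seed = 30)
  per_tube_reads <- table(factor(run$reads$tube, levels = 1:8))
  chrom <- vapply(run$copies, `[[`, character(1), "chrom")
  a <- run$partition$assignment
  per_tube_copies <- vapply(1:8, function(tb) sum(!is.na(a) & a == tb),
                            numeric(1))
  expect_gt(cor(as.numeric(per_tube_reads), per_tube_copies,
                method = "spearman"), 0)
})
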