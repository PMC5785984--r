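test_that("complementary fragments nominate exactly one candidate", {
  sim <- sim_t35(4)
  pres <- t35_presence(sim$reads)
  cands <- pair_fragments(pres)
  expect_length(cands, 1)
  cand <- cands[[1]]
  expect_equal(cand$chrom_a, "chrA")
  expect_equal(cand$chrom_b, "chrB")
  expect_equal(cand$tube_der_a, 3)
  expect_equal(cand$tube_der_b, 4)
  # edge regions bracket the planted junction bases
  expect_true(cand$edge_region_a[["start"]] <= 148560 &&
                148560 <= cand$edge_region_a[["end"]])
  expect_true(cand$edge_region_b[["start"]] <= 73601 &&
                73601 <= cand$edge_region_b[["end"]])
})

test_that("no candidates arise without a translocation", {
  run <- sim_small_xy(seed = 61)
  pres <- call_presence(bin_reads(filter_reads(run$reads), 1e4, run$genome,
                                  n_tubes = 8))
  expect_length(pair_fragments(pres), 0)
})

test_that("fragments of one chromosome alone are not a candidate", {
  # chrA split over tubes 1/2 (a broken chromosome), chrB whole in tube 1:
  # no complementary partner fragments, so no translocation pattern
  genome <- c(chrA = 2e5, chrB = 2e5)
  half1 <- data.frame(tube = 1L, chrom = "chrA",
                      pos = seq(1, 1e5 - 100, by = 150), length = 100,
                      mapq = 60L, chrom2 = NA_character_, pos2 = NA_real_,
                      length2 = NA_real_, source_copy = NA_character_)
  half2 <- transform(half1, tube = 2L, pos = pos + 1e5)
  whole_b <- data.frame(tube = 1L, chrom = "chrB",
                        pos = seq(1, 2e5 - 100, by = 150), length = 100,
                        mapq = 60L, chrom2 = NA_character_, pos2 = NA_real_,
                        length2 = NA_real_, source_copy = NA_character_)
  pres <- call_presence(bin_reads(rbind(half1, half2, whole_b), 1e4, genome,
                                  n_tubes = 2))
  expect_equal(sum(pres$calls$status == "FRAGMENT"), 2)
  expect_length(pair_fragments(pres), 0)
})

test_that("fine-window narrowing shrinks but never leaves the edge region", {
  for (s in c(4, 8, 15)) {
    sim <- sim_t35(s)
    reads <- filter_reads(sim$reads)
    cands <- pair_fragments(t35_presence(reads))
    if (length(cands) == 0) next
    cand <- cands[[1]]
    fine <- narrow_region(reads, cand, 500)
    for (side in c("edge_region_a", "edge_region_b")) {
      expect_gte(fine[[side]][["start"]], cand[[side]][["start"]])
      expect_lte(fine[[side]][["end"]], cand[[side]][["end"]])
    }
    # refined regions still contain the planted junction
    expect_true(fine$edge_region_a[["start"]] <= 148560 &&
                  148560 <= fine$edge_region_a[["end"]])
    expect_true(fine$edge_region_b[["start"]] <= 73601 &&
                  73601 <= fine$edge_region_b[["end"]])
    # at deep coverage the region shrinks to a few fine windows
    expect_lte(diff(fine$edge_region_a) + 1, 15000)

    # fine window equal to the coarse window is a no-op
    noop <- narrow_region(reads, cand, cand$window_size)
    expect_equal(noop$edge_region_a, cand$edge_region_a)
    expect_equal(noop$edge_region_b, cand$edge_region_b)

    # a region without reads is returned unchanged with a warning flag
    starved <- narrow_region(reads[reads$chrom != "chrA", ], cand, 500)
    expect_true(starved$narrow_warning[["a"]])
    expect_equal(starved$edge_region_a, cand$edge_region_a)
  }
})

test_that("chimeric reads are collected only across the two edge regions", {
  sim <- sim_t35(4)
  reads <- filter_reads(sim$reads)
  cand <- pair_fragments(t35_presence(reads))[[1]]
  chim <- collect_chimeric(reads, cand)
  expect_gt(nrow(chim), 0)
  # A-leading reads imply the der(A) junction, B-leading the reciprocal
  a_side <- chim[chim$a_leading, ]
  expect_true(all(a_side$junc1 == 148560 & a_side$junc2 == 73601))
  b_side <- chim[!chim$a_leading, ]
  if (nrow(b_side) > 0)
    expect_true(all(b_side$junc1 == 73599 & b_side$junc2 == 148561))

  expect_equal(nrow(collect_chimeric(reads[is.na(reads$chrom2), ], cand)), 0)

  # a split read with both segments on chromosome A is excluded
  intra <- reads[1, ]
  intra$chrom <- "chrA"; intra$pos <- 148500; intra$length <- 50
  intra$chrom2 <- "chrA"; intra$pos2 <- 148561; intra$length2 <- 50
  intra$tube <- cand$tube_der_a
  expect_equal(nrow(collect_chimeric(intra, cand)), 0)
})

test_that("breakpoint voting calls the modal pair with consensus", {
  mk <- function(n, junc1 = 148560, junc2 = 73601, a_leading = TRUE)
    data.frame(tube = 3L, chrom1 = if (a_leading) "chrA" else "chrB",
               pos1 = junc1 - 49, len1 = 50,
               chrom2 = if (a_leading) "chrB" else "chrA",
               pos2 = junc2, len2 = 50, a_leading = a_leading,
               junc1 = junc1, junc2 = junc2)[rep(1, n), ]
  five <- mk(5)
  bp <- refine_breakpoint(five, min_support = 3)
  expect_equal(bp$status, "CALLED")
  expect_equal(bp$pos_a, 148560)
  expect_equal(bp$pos_b, 73601)
  expect_equal(bp$n_support, 5)
  expect_equal(bp$consensus_fraction, 1)
  expect_equal(bp$junction_gap_b, 0)  # reciprocal junction unobserved

  # with both derivatives observed the lost base surfaces as the gap
  both <- rbind(mk(5), mk(2, junc1 = 73599, junc2 = 148561,
                          a_leading = FALSE))
  bp2 <- refine_breakpoint(both, min_support = 3)
  expect_equal(bp2$junction_gap_b, 1)
  expect_equal(bp2$n_reciprocal, 2)

  expect_equal(refine_breakpoint(mk(2), min_support = 3)$status, "NO_CALL")

  tie <- rbind(mk(3), mk(3, junc1 = 148561, junc2 = 73602))
  bp3 <- refine_breakpoint(tie, min_support = 3)
  expect_equal(bp3$status, "NO_CALL")
  expect_equal(nrow(bp3$tied_candidates), 2)
  expect_setequal(bp3$tied_candidates$pos_a, c(148560, 148561))

  # merge tolerance counts near-modal votes as support
  jitter <- rbind(mk(3), mk(2, junc1 = 148559, junc2 = 73600))
  expect_equal(refine_breakpoint(jitter, min_support = 3,
                                 merge_tol = 2)$n_support, 5)
})

test_that("simulated junction loss is recovered from both derivatives", {
  recovered <- FALSE
  for (s in 1:10) {
    sim <- sim_t35(s)
    reads <- filter_reads(sim$reads)
    cands <- pair_fragments(t35_presence(reads))
    if (length(cands) == 0) next
    chim <- collect_chimeric(reads, cands[[1]])
    if (sum(chim$a_leading) < 3 || sum(!chim$a_leading) < 1) next
    bp <- refine_breakpoint(chim, min_support = 3)
    expect_equal(bp$status, "CALLED")
    expect_equal(bp$pos_a, 148560)
    expect_equal(bp$pos_b, 73601)
    expect_equal(bp$junction_gap_b, 1)
    recovered <- TRUE
    break
  }
  expect_true(recovered)
})
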