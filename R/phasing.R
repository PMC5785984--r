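# Whole-chromosome haplotype phasing by physical separation.
#
# When the two homologs of a chromosome land in different tubes, each tube
# sequences a single haplotype: at a bulk-heterozygous site each tube should
# look homozygous for one of the two alleles, which assigns the alleles to
# their physical copies and yields one phase block per chromosome.

#' Filter bulk-sample variants to the phasable reference set
#'
#' Keeps heterozygous records with depth strictly greater than `min_depth`,
#' quality strictly greater than `min_qual`, and (optionally) flagged as
#' common population SNPs (>= 1% minor allele frequency). Malformed records
#' (missing fields) are skipped with a warning.
#'
#' @param variants data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `depth`, `quality`, `is_common`, `genotype` (e.g. from
#'   [read_bulk_vcf()]).
#' @param min_depth Depth must exceed this (default 10).
#' @param min_qual Quality must exceed this (default 30).
#' @param common_only Keep only common SNPs (default TRUE).
#' @return The retained rows.
#' @export
filter_bulk_snps <- function(variants, min_depth = 10, min_qual = 30,
                             common_only = TRUE) {
  stopifnot(min_depth >= 0, min_qual >= 0)
  bad <- is.na(variants$chrom) | is.na(variants$pos) | is.na(variants$ref) |
    is.na(variants$alt) | is.na(variants$depth) | is.na(variants$quality) |
    is.na(variants$genotype)
  if (any(bad)) {
    warning(sum(bad), " malformed bulk variant record(s) skipped")
    variants <- variants[!bad, , drop = FALSE]
  }
  het <- variants$genotype %in% c("0/1", "1/0", "0|1", "1|0")
  keep <- het & variants$depth > min_depth & variants$quality > min_qual
  if (common_only) keep <- keep & variants$is_common
  variants[keep, , drop = FALSE]
}

#' Count ref/alt allele observations per tube and site
#'
#' @param observations data.frame from [simulate_reads()] (or assembled from
#'   real per-tube pileups): `tube`, `chrom`, `pos`, `base`.
#' @param sites data.frame with `chrom`, `pos`, `ref`, `alt` defining the
#'   sites and alleles to count. Observed bases matching neither allele are
#'   ignored.
#' @return data.frame: `tube`, `chrom`, `pos`, `ref_count`, `alt_count`.
#' @export
count_alleles <- function(observations, sites) {
  if (nrow(observations) == 0)
    return(data.frame(tube = integer(), chrom = character(), pos = numeric(),
                      ref_count = integer(), alt_count = integer()))
  m <- match(paste(observations$chrom, observations$pos),
             paste(sites$chrom, sites$pos))
  ok <- !is.na(m)
  obs <- observations[ok, , drop = FALSE]
  m <- m[ok]
  is_ref <- obs$base == sites$ref[m]
  is_alt <- obs$base == sites$alt[m]
  key <- paste(obs$tube, obs$chrom, obs$pos)
  agg <- rowsum(cbind(ref_count = as.integer(is_ref),
                      alt_count = as.integer(is_alt)), key)
  first <- !duplicated(key)
  info <- data.frame(key = key[first], tube = obs$tube[first],
                     chrom = obs$chrom[first], pos = obs$pos[first])
  info <- info[order(info$tube, info$chrom, info$pos), ]
  out <- data.frame(tube = info$tube, chrom = info$chrom, pos = info$pos,
                    ref_count = agg[info$key, "ref_count"],
                    alt_count = agg[info$key, "alt_count"])
  rownames(out) <- NULL
  out
}

#' Classify a site from its alternative allele ratio
#'
#' The alternative allele ratio alt/(ref+alt) classifies a site as
#' homozygous-alternative (> 80%), heterozygous (20--80%, boundaries
#' inclusive) or reference (< 20%); sites below `min_site_depth` are
#' `NO_CALL`.
#'
#' @param ref_count,alt_count Non-negative allele counts (vectorised).
#' @param min_site_depth Minimum ref+alt depth for a call (default 2).
#' @return data.frame with `class` (`HOM_ALT`/`HET`/`REF`/`NO_CALL`),
#'   `alt_ratio` (NA when depth 0) and `depth`.
#' @examples
#' classify_allele_ratio(c(1, 5, 9, 0), c(9, 5, 1, 0))$class
#' @export
classify_allele_ratio <- function(ref_count, alt_count, min_site_depth = 2) {
  stopifnot(all(ref_count >= 0), all(alt_count >= 0), min_site_depth >= 1)
  depth <- ref_count + alt_count
  ratio <- ifelse(depth > 0, alt_count / depth, NA_real_)
  cls <- ifelse(depth < min_site_depth, "NO_CALL",
                ifelse(ratio > 0.8, "HOM_ALT",
                       ifelse(ratio >= 0.2, "HET", "REF")))
  data.frame(class = cls, alt_ratio = ratio, depth = depth)
}

#' Phase the heterozygous SNPs of one chromosome
#'
#' Requires the chromosome's two copies to sit in distinct tubes
#' (`copy_tubes`). Each site is classified in each tube from its allele
#' counts: opposite homozygous-like calls phase the site directly
#' (`both_tubes`); a site covered in only one tube is phased by assigning
#' the observed allele to that copy and the complementary bulk allele to the
#' other (`single_tube_complement`, controlled by `allow_complement`);
#' agreeing or heterozygous-looking calls conflict (`conflict_unphased`);
#' sites covered in neither tube are `uncovered`.
#'
#' @param het_snps data.frame of bulk het SNPs on this chromosome: `chrom`,
#'   `pos`, `ref`, `alt` (see [filter_bulk_snps()]).
#' @param allele_counts data.frame from [count_alleles()].
#' @param copy_tubes Length-2 vector of distinct tubes holding the two
#'   copies (e.g. from [separated_chromosome_tubes()]).
#' @param min_site_depth Per-tube depth below which a site is uncalled.
#' @param allow_complement Enable single-tube complement phasing (default
#'   TRUE, reflecting low per-tube coverage).
#' @return A `phased_chromosome`: list with `chrom`, `tube_of_copy0`,
#'   `tube_of_copy1` and `snps` (data.frame: pos, ref, alt, allele0,
#'   allele1, evidence).
#' @export
phase_chromosome <- function(het_snps, allele_counts, copy_tubes,
                             min_site_depth = 2, allow_complement = TRUE) {
  if (length(copy_tubes) != 2 || copy_tubes[1] == copy_tubes[2])
    stop("copy_tubes must name two distinct tubes; homologs in one tube ",
         "cannot be phased by physical separation")
  stopifnot(nrow(het_snps) == 0 || length(unique(het_snps$chrom)) == 1)
  chrom <- if (nrow(het_snps) > 0) het_snps$chrom[1] else NA_character_
  counts_for <- function(tube) {
    ac <- allele_counts[allele_counts$tube == tube &
                          allele_counts$chrom == chrom, , drop = FALSE]
    i <- match(het_snps$pos, ac$pos)
    list(ref = ifelse(is.na(i), 0L, ac$ref_count[i]),
         alt = ifelse(is.na(i), 0L, ac$alt_count[i]))
  }
  c0 <- counts_for(copy_tubes[1])
  c1 <- counts_for(copy_tubes[2])
  g0 <- classify_allele_ratio(c0$ref, c0$alt, min_site_depth)$class
  g1 <- classify_allele_ratio(c1$ref, c1$alt, min_site_depth)$class
  n <- nrow(het_snps)
  allele0 <- rep(NA_character_, n)
  allele1 <- rep(NA_character_, n)
  evidence <- rep("uncovered", n)
  hom <- c("REF", "HOM_ALT")
  allele_of <- function(cls, ref, alt) ifelse(cls == "HOM_ALT", alt, ref)
  both <- g0 %in% hom & g1 %in% hom & g0 != g1
  allele0[both] <- allele_of(g0[both], het_snps$ref[both], het_snps$alt[both])
  allele1[both] <- allele_of(g1[both], het_snps$ref[both], het_snps$alt[both])
  evidence[both] <- "both_tubes"
  conflict <- (g0 %in% hom & g1 %in% hom & g0 == g1) |
    g0 == "HET" | g1 == "HET"
  conflict <- conflict & !both
  evidence[conflict] <- "conflict_unphased"
  if (allow_complement) {
    other <- function(a, ref, alt) ifelse(a == ref, alt, ref)
    only0 <- g0 %in% hom & g1 == "NO_CALL" & !conflict
    allele0[only0] <- allele_of(g0[only0], het_snps$ref[only0],
                                het_snps$alt[only0])
    allele1[only0] <- other(allele0[only0], het_snps$ref[only0],
                            het_snps$alt[only0])
    evidence[only0] <- "single_tube_complement"
    only1 <- g1 %in% hom & g0 == "NO_CALL" & !conflict
    allele1[only1] <- allele_of(g1[only1], het_snps$ref[only1],
                                het_snps$alt[only1])
    allele0[only1] <- other(allele1[only1], het_snps$ref[only1],
                            het_snps$alt[only1])
    evidence[only1] <- "single_tube_complement"
  }
  structure(list(chrom = chrom,
                 tube_of_copy0 = copy_tubes[1], tube_of_copy1 = copy_tubes[2],
                 snps = data.frame(pos = het_snps$pos, ref = het_snps$ref,
                                   alt = het_snps$alt, allele0 = allele0,
                                   allele1 = allele1, evidence = evidence)),
            class = "phased_chromosome")
}

#' Tubes hosting the two separated copies of each chromosome
#'
#' @param presence A `presence_matrix`.
#' @return Named list: chromosome -> the two tubes with `WHOLE` calls, for
#'   chromosomes with exactly two whole copies in distinct tubes (the
#'   phasable chromosomes).
#' @export
separated_chromosome_tubes <- function(presence) {
  stopifnot(inherits(presence, "presence_matrix"))
  calls <- presence$calls[presence$calls$status == "WHOLE", ]
  out <- list()
  for (chrom in unique(calls$chrom)) {
    tubes <- sort(calls$tube[calls$chrom == chrom])
    if (length(tubes) == 2) out[[chrom]] <- tubes
  }
  out
}

#' Score phasing against the simulated truth
#'
#' Copy labels are arbitrary, so each chromosome's labeling is aligned to
#' the truth by majority vote before scoring. `phased_fraction_separated`
#' uses only truth SNPs on the chromosomes that were phased (physically
#' separated); `phased_fraction_all` uses all truth het SNPs.
#'
#' @param phased List of `phased_chromosome` objects.
#' @param truth `snp_truth` table from [plant_snps()].
#' @return A `phasing_metrics` list: `per_chromosome` data.frame (chrom,
#'   n_truth, n_phased, per-evidence counts, n_conflict, accuracy),
#'   `accuracy` (overall, phased sites), `phased_fraction_separated`,
#'   `phased_fraction_all`, `by_evidence` (accuracy split by phasing
#'   route), `conflicts`.
#' @export
evaluate_phasing <- function(phased, truth) {
  rows <- lapply(phased, function(ph) {
    tr <- truth[truth$chrom == ph$chrom, ]
    ok <- !is.na(ph$snps$allele0)
    sn <- ph$snps[ok, , drop = FALSE]
    i <- match(sn$pos, tr$pos)
    direct <- sn$allele0 == tr$allele0[i] & sn$allele1 == tr$allele1[i]
    swapped <- sn$allele0 == tr$allele1[i] & sn$allele1 == tr$allele0[i]
    correct <- if (sum(swapped) > sum(direct)) swapped else direct
    acc <- if (nrow(sn) > 0) sum(correct) / nrow(sn) else NA_real_
    data.frame(chrom = ph$chrom, n_truth = nrow(tr), n_phased = nrow(sn),
               n_correct = sum(correct),
               n_both = sum(sn$evidence == "both_tubes"),
               n_both_correct = sum(correct[sn$evidence == "both_tubes"]),
               n_compl = sum(sn$evidence == "single_tube_complement"),
               n_compl_correct =
                 sum(correct[sn$evidence == "single_tube_complement"]),
               n_conflict = sum(ph$snps$evidence == "conflict_unphased"),
               accuracy = acc)
  })
  per_chrom <- do.call(rbind, rows)
  n_phased <- sum(per_chrom$n_phased)
  # the two evidence routes scored separately (their relative reliability
  # differs: complement phasing leans on a single tube's reads)
  by_evidence <- data.frame(
    evidence = c("both_tubes", "single_tube_complement"),
    n = c(sum(per_chrom$n_both), sum(per_chrom$n_compl)),
    accuracy = c(
      if (sum(per_chrom$n_both) > 0)
        sum(per_chrom$n_both_correct) / sum(per_chrom$n_both) else NA_real_,
      if (sum(per_chrom$n_compl) > 0)
        sum(per_chrom$n_compl_correct) / sum(per_chrom$n_compl)
      else NA_real_))
  structure(list(
    per_chromosome = per_chrom,
    accuracy = if (n_phased > 0) sum(per_chrom$n_correct) / n_phased
               else NA_real_,
    phased_fraction_separated = if (sum(per_chrom$n_truth) > 0)
      n_phased / sum(per_chrom$n_truth) else NA_real_,
    phased_fraction_all = if (nrow(truth) > 0) n_phased / nrow(truth)
                          else NA_real_,
    by_evidence = by_evidence,
    conflicts = sum(per_chrom$n_conflict)),
    class = "phasing_metrics")
}

#' @export
print.phasing_metrics <- function(x, ...) {
  cat(sprintf("<phasing_metrics: accuracy %.4f, phased %.2f%% of SNPs on separated chromosomes (%.2f%% of all), %d conflicts>\n",
              x$accuracy, 100 * x$phased_fraction_separated,
              100 * x$phased_fraction_all, x$conflicts))
  invisible(x)
}
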