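# Synthetic single-chromosome-sequencing experiments with known truth.
#
# The simulator emulates what the wet-lab workflow hands to the analyst:
# chromosomes of one metaphase cell diluted into k tubes (with per-copy
# loss), each present copy amplified patchily (clustered amplicons, not
# per-base thinning) and sequenced to a modest depth, plus background noise
# reads. Reads are emitted as mapped records (alignment is upstream); no
# nucleotide-level sequence is synthesised.

#' Coverage/error model for the read simulator
#'
#' @param target_fraction Fraction of each present copy covered by amplicons.
#'   `NA` (default) draws a per-copy value uniformly in `[0.05, 0.22]`, the
#'   range observed for single amplified chromosomes.
#' @param amplicon_length_mean Mean amplicon (cluster) length in bp; cluster
#'   lengths are read_length plus a geometric excess, so coverage is patchy
#'   with contiguous gaps.
#' @param read_length Read length in bp.
#' @param mean_depth_on_covered Mean fold depth over amplified bases.
#' @param noise_read_fraction Background reads scattered genome-wide, as a
#'   fraction of real reads per tube.
#' @param epsilon Per-base allele error rate for allele observations.
#' @param low_mapq_fraction Fraction of reads assigned a mapping quality
#'   below 30 (removed by the default MAPQ filter).
#' @param chimeric_noise_rate Probability a read gains a spurious split
#'   alignment (tests breakpoint-caller specificity). Default 0.
#' @return A `coverage_model` object.
#' @export
coverage_model <- function(target_fraction = NA, amplicon_length_mean = 300,
                           read_length = 100, mean_depth_on_covered = 4,
                           noise_read_fraction = 0, epsilon = 0,
                           low_mapq_fraction = 0, chimeric_noise_rate = 0) {
  stopifnot(is.na(target_fraction) ||
              (target_fraction > 0 && target_fraction <= 1),
            amplicon_length_mean >= read_length, read_length >= 1,
            mean_depth_on_covered > 0, noise_read_fraction >= 0,
            epsilon >= 0, epsilon <= 1,
            low_mapq_fraction >= 0, low_mapq_fraction <= 1,
            chimeric_noise_rate >= 0, chimeric_noise_rate <= 1)
  structure(list(target_fraction = target_fraction,
                 amplicon_length_mean = amplicon_length_mean,
                 read_length = read_length,
                 mean_depth_on_covered = mean_depth_on_covered,
                 noise_read_fraction = noise_read_fraction,
                 epsilon = epsilon,
                 low_mapq_fraction = low_mapq_fraction,
                 chimeric_noise_rate = chimeric_noise_rate),
            class = "coverage_model")
}

#' Plant heterozygous truth SNPs on the simulated genome
#'
#' SNP count per chromosome is Poisson(`density` x length); positions are
#' unique per chromosome; the two homolog alleles always differ, with the
#' ref/alt assignment to homolog 0/1 uniform at random.
#'
#' @param copies List of `chromosome_copy` (defines the chromosomes present).
#' @param density Expected het SNPs per bp.
#' @param seed RNG seed.
#' @return data.frame of class `snp_truth` with columns `chrom`, `pos`,
#'   `ref`, `alt`, `allele0`, `allele1` (alleles carried by homolog 0 and 1).
#' @export
plant_snps <- function(copies, density, seed = 1L) {
  stopifnot(density >= 0)
  set.seed(seed)
  segs <- do.call(rbind, lapply(copies, `[[`, "segments"))
  lens <- tapply(segs$end, segs$chrom, max)
  bases <- c("A", "C", "G", "T")
  out <- lapply(sort(names(lens)), function(chrom) {
    len <- lens[[chrom]]
    n <- stats::rpois(1, density * len)
    if (n == 0) return(NULL)
    pos <- sort(sample.int(len, min(n, len)))
    ref <- sample(bases, length(pos), replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
    alt0 <- stats::runif(length(pos)) < 0.5  # does homolog 0 carry alt?
    data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
               allele0 = ifelse(alt0, alt, ref),
               allele1 = ifelse(alt0, ref, alt),
               row.names = NULL)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(chrom = character(), pos = numeric(), ref = character(),
                      alt = character(), allele0 = character(),
                      allele1 = character())
  class(out) <- c("snp_truth", "data.frame")
  out
}

#' Dilute chromosome copies into tubes
#'
#' Each copy is independently lost with probability `loss_prob` (binding to
#' tube or tip), otherwise assigned uniformly to one of `k` tubes.
#'
#' @param copies List of `chromosome_copy`.
#' @param k Number of tubes (>= 1).
#' @param loss_prob Per-copy loss probability in `[0, 1)`.
#' @param seed RNG seed.
#' @return A `tube_partition`: list with `assignment` (named vector,
#'   copy_id -> tube in 1..k, `NA` = lost) and `k`.
#' @export
partition_copies <- function(copies, k, loss_prob = 0, seed = 1L) {
  stopifnot(k >= 1, loss_prob >= 0, loss_prob < 1)
  set.seed(seed)
  ids <- vapply(copies, `[[`, character(1), "copy_id")
  tube <- sample.int(k, length(ids), replace = TRUE)
  tube[stats::runif(length(ids)) < loss_prob] <- NA_integer_
  structure(list(assignment = stats::setNames(tube, ids), k = as.integer(k)),
            class = "tube_partition")
}

#' Fix a partition by hand
#'
#' Builds a `tube_partition` from an explicit copy -> tube map, e.g. to
#' reproduce a specific dilution outcome.
#'
#' @param assignment Named vector (copy_id -> tube index, `NA` = lost).
#' @param k Number of tubes.
#' @return A `tube_partition`.
#' @export
manual_partition <- function(assignment, k) {
  stopifnot(k >= 1, !is.null(names(assignment)),
            all(is.na(assignment) | (assignment >= 1 & assignment <= k)))
  structure(list(assignment = assignment, k = as.integer(k)),
            class = "tube_partition")
}

empty_reads <- function() {
  data.frame(tube = integer(), chrom = character(), pos = numeric(),
             length = numeric(), mapq = integer(), chrom2 = character(),
             pos2 = numeric(), length2 = numeric(), source_copy = character())
}

empty_observations <- function() {
  data.frame(tube = integer(), chrom = character(), pos = numeric(),
             base = character(), source_copy = character())
}

# Place amplicons over one copy (coordinates on the copy's own axis).
# One amplicon per stratum of width ~amp_mean/target_fraction, uniformly
# jittered within its stratum: patchy contiguous coverage with geometric
# cluster lengths, and amplicon spacing well below the binning window at
# default settings (as kb-scale amplicons are dense within Mb windows at
# real scale).
place_amplicons <- function(copy_len, target_fraction, amp_mean, read_length) {
  n_amp <- max(1L, round(target_fraction * copy_len / amp_mean))
  stride <- copy_len / n_amp
  excess_mean <- max(amp_mean - read_length, 1)
  len <- read_length + stats::rgeom(n_amp, 1 / (excess_mean + 1))
  len <- pmin(len, copy_len)
  lo <- floor((seq_len(n_amp) - 1) * stride) + 1
  hi <- floor(seq_len(n_amp) * stride)
  start <- lo + floor(stats::runif(n_amp) * (hi - lo + 1))
  start <- pmax(pmin(start, copy_len - len + 1), 1)
  data.frame(start = start, end = start + len - 1)
}

# Map read spans on the copy axis back to reference coordinates, splitting
# reads that straddle a derivative-chromosome junction.
map_reads_to_reference <- function(starts, lengths, segments) {
  seg_len <- segments$end - segments$start + 1
  offsets <- cumsum(c(0, seg_len))
  ends <- starts + lengths - 1
  i1 <- findInterval(starts - 1, offsets, rightmost.closed = FALSE)
  i2 <- findInterval(ends - 1, offsets, rightmost.closed = FALSE)
  i1 <- pmin(i1, length(seg_len)); i2 <- pmin(i2, length(seg_len))
  pos1 <- segments$start[i1] + (starts - offsets[i1]) - 1
  split <- i2 > i1
  len1 <- ifelse(split, offsets[i1 + 1] - starts + 1, lengths)
  data.frame(chrom = segments$chrom[i1], pos = pos1, length = len1,
             chrom2 = ifelse(split, segments$chrom[i2], NA_character_),
             pos2 = ifelse(split, segments$start[i2], NA_real_),
             length2 = ifelse(split, lengths - len1, NA_real_))
}

# Allele observations for read spans overlapping truth-SNP sites.
observe_alleles <- function(spans, truth, homolog, epsilon) {
  if (nrow(spans) == 0 || nrow(truth) == 0) return(NULL)
  allele_col <- if (homolog == 0) "allele0" else "allele1"
  out <- lapply(split(spans, spans$chrom), function(sp) {
    tr <- truth[truth$chrom == sp$chrom[1], ]
    if (nrow(tr) == 0) return(NULL)
    lo <- findInterval(sp$pos - 1, tr$pos) + 1
    hi <- findInterval(sp$pos + sp$length - 1, tr$pos)
    n <- pmax(hi - lo + 1, 0)
    keep <- n > 0
    if (!any(keep)) return(NULL)
    snp_idx <- sequence(n[keep]) + rep(lo[keep] - 1, n[keep])
    data.frame(tube = rep(sp$tube[keep], n[keep]),
               chrom = tr$chrom[snp_idx], pos = tr$pos[snp_idx],
               base = tr[[allele_col]][snp_idx],
               source_copy = rep(sp$source_copy[keep], n[keep]))
  })
  out <- do.call(rbind, out)
  if (!is.null(out) && epsilon > 0 && nrow(out) > 0) {
    err <- stats::runif(nrow(out)) < epsilon
    if (any(err)) {
      bases <- c("A", "C", "G", "T")
      out$base[err] <- vapply(out$base[err],
                              function(b) sample(setdiff(bases, b), 1),
                              character(1))
    }
  }
  out
}

#' Simulate per-tube mapped reads and allele observations
#'
#' For each chromosome copy present in a tube, amplicons are placed to cover
#' approximately `target_fraction` of its bases in contiguous clusters, and
#' reads are sampled from the amplicons at `mean_depth_on_covered`. Reads
#' straddling a derivative-chromosome junction are emitted with
#' `chrom2`/`pos2`/`length2` populated (the split alignment on the partner
#' chromosome). Reads overlapping truth-SNP sites yield allele observations
#' carrying the source homolog's allele, corrupted at rate `epsilon`.
#' Background noise reads are scattered uniformly over the reference and
#' carry no allele information.
#'
#' @param copies List of `chromosome_copy` from [build_karyotype()].
#' @param partition A `tube_partition`.
#' @param truth `snp_truth` table from [plant_snps()] (may have zero rows).
#' @param model A [coverage_model()].
#' @param seed RNG seed.
#' @return List with `reads` (data.frame: tube, chrom, pos, length, mapq,
#'   chrom2, pos2, length2, source_copy) and `observations` (data.frame:
#'   tube, chrom, pos, base, source_copy).
#' @export
simulate_reads <- function(copies, partition, truth, model, seed = 1L) {
  stopifnot(inherits(model, "coverage_model"),
            inherits(partition, "tube_partition"),
            is.data.frame(truth), is.list(copies))
  set.seed(seed)
  rl <- model$read_length
  read_parts <- list()
  obs_parts <- list()
  for (copy in copies) {
    tube <- partition$assignment[[copy$copy_id]]
    if (is.na(tube)) next
    len <- copy_length(copy)
    tf <- if (is.na(model$target_fraction))
      stats::runif(1, 0.05, 0.22) else model$target_fraction
    amps <- place_amplicons(len, tf, model$amplicon_length_mean, rl)
    n_reads <- stats::rpois(nrow(amps),
                            model$mean_depth_on_covered *
                              (amps$end - amps$start + 1) / rl)
    amp_idx <- rep(seq_len(nrow(amps)), n_reads)
    if (length(amp_idx) == 0) next
    span <- amps$end[amp_idx] - amps$start[amp_idx] + 1
    this_rl <- pmin(rl, span)
    s <- amps$start[amp_idx] +
      floor(stats::runif(length(amp_idx)) * (span - this_rl + 1))
    mapped <- map_reads_to_reference(s, this_rl, copy$segments)
    mapped$tube <- tube
    mapped$source_copy <- copy$copy_id
    read_parts[[copy$copy_id]] <- mapped
    spans <- rbind(
      data.frame(tube = tube, chrom = mapped$chrom, pos = mapped$pos,
                 length = mapped$length, source_copy = copy$copy_id),
      {
        sp2 <- mapped[!is.na(mapped$chrom2), ]
        if (nrow(sp2) > 0)
          data.frame(tube = tube, chrom = sp2$chrom2, pos = sp2$pos2,
                     length = sp2$length2, source_copy = copy$copy_id)
        else NULL
      })
    obs <- observe_alleles(spans, truth, copy$homolog_index, model$epsilon)
    if (!is.null(obs)) obs_parts[[copy$copy_id]] <- obs
  }
  reads <- if (length(read_parts) > 0) do.call(rbind, read_parts) else NULL
  if (is.null(reads)) {
    reads <- empty_reads()
  } else {
    reads <- reads[c("tube", "chrom", "pos", "length", "chrom2", "pos2",
                     "length2", "source_copy")]
    reads$mapq <- 60L
    # background reads scattered genome-wide, proportional to tube yield
    if (model$noise_read_fraction > 0) {
      segs <- do.call(rbind, lapply(copies, `[[`, "segments"))
      lens <- tapply(segs$end, segs$chrom, max)
      chroms <- names(lens)
      noise <- lapply(sort(unique(reads$tube)), function(tb) {
        n <- stats::rpois(1, model$noise_read_fraction * sum(reads$tube == tb))
        if (n == 0) return(NULL)
        ch <- sample(chroms, n, replace = TRUE, prob = as.numeric(lens))
        data.frame(tube = tb, chrom = ch,
                   pos = floor(stats::runif(n) *
                                 pmax(as.numeric(lens[ch]) - rl, 1)) + 1,
                   length = rl, chrom2 = NA_character_, pos2 = NA_real_,
                   length2 = NA_real_, source_copy = NA_character_,
                   mapq = 60L)
      })
      noise <- do.call(rbind, noise)
      if (!is.null(noise)) reads <- rbind(reads, noise)
    }
    if (model$chimeric_noise_rate > 0) {
      segs <- do.call(rbind, lapply(copies, `[[`, "segments"))
      lens <- tapply(segs$end, segs$chrom, max)
      cand <- which(is.na(reads$chrom2))
      hit <- cand[stats::runif(length(cand)) < model$chimeric_noise_rate]
      if (length(hit) > 0) {
        ch <- sample(names(lens), length(hit), replace = TRUE)
        cut <- pmax(1, floor(reads$length[hit] / 2))
        reads$chrom2[hit] <- ch
        reads$pos2[hit] <- floor(stats::runif(length(hit)) *
                                   pmax(as.numeric(lens[ch]) - rl, 1)) + 1
        reads$length2[hit] <- reads$length[hit] - cut
        reads$length[hit] <- cut
      }
    }
    if (model$low_mapq_fraction > 0) {
      low <- stats::runif(nrow(reads)) < model$low_mapq_fraction
      reads$mapq[low] <- sample(0:29, sum(low), replace = TRUE)
    }
    reads <- reads[order(reads$tube, reads$chrom, reads$pos,
                         method = "radix"), ]
    rownames(reads) <- NULL
  }
  observations <- if (length(obs_parts) > 0)
    do.call(rbind, obs_parts) else empty_observations()
  if (nrow(observations) > 0) {
    observations <- observations[order(observations$tube, observations$chrom,
                                       observations$pos, method = "radix"), ]
    rownames(observations) <- NULL
  }
  list(reads = reads, observations = observations)
}

#' Simulate bulk-sample allele counts at truth-SNP sites
#'
#' Emulates deep whole-genome sequencing of the bulk sample: at each
#' heterozygous truth site the alternative allele is drawn binomially at
#' ratio 0.5 from a Poisson site depth, with error rate `epsilon` moving
#' reads across alleles.
#'
#' @param truth `snp_truth` table.
#' @param mean_depth Mean site depth.
#' @param epsilon Per-read allele error rate.
#' @param seed RNG seed.
#' @return data.frame with `chrom`, `pos`, `ref_count`, `alt_count`.
#' @export
simulate_bulk_counts <- function(truth, mean_depth = 30, epsilon = 0,
                                 seed = 1L) {
  stopifnot(mean_depth > 0, epsilon >= 0, epsilon <= 1)
  set.seed(seed)
  n <- nrow(truth)
  depth <- stats::rpois(n, mean_depth)
  p_alt <- 0.5 * (1 - epsilon) + 0.5 * epsilon / 3
  alt <- stats::rbinom(n, depth, p_alt)
  data.frame(chrom = truth$chrom, pos = truth$pos,
             ref_count = depth - alt, alt_count = alt)
}
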