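# Per-tube chromosome presence calling from binned read counts.
#
# The central object mirrors the Circos-ring data of an SCS run: read counts
# per (tube, chromosome, window). A chromosome is called present in a tube
# when enough reads cover enough of its windows; a partial chromosome
# (derivative-donor fragment) is reported with its covered intervals.

#' Filter reads on mapping quality
#'
#' @param reads Read data.frame (see [simulate_reads()] / [read_alignments()]).
#' @param mapq_cutoff Minimum MAPQ kept (default 30; raising the cutoff from
#'   5 to 30 removes ambiguous mappings while most genuine reads sit at 60).
#' @return The reads with `mapq >= mapq_cutoff`, order preserved.
#' @export
filter_reads <- function(reads, mapq_cutoff = 30) {
  stopifnot(mapq_cutoff >= 0, mapq_cutoff <= 60)
  reads[reads$mapq >= mapq_cutoff, , drop = FALSE]
}

n_windows <- function(len, window_size) as.integer(ceiling(len / window_size))

#' Bin reads into fixed-size genomic windows
#'
#' Windows are `[i*w, (i+1)*w)` in 0-based half-open coordinates (the last
#' window of a chromosome may be short); a read is assigned to the window
#' containing its leftmost mapped base, `floor((pos - 1) / w)`.
#'
#' @param reads Read data.frame.
#' @param window_size Window size in bp (1e6 at hg19 scale; 1e4 on the
#'   default 1/100 fixture keeps the window count per chromosome identical).
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param n_tubes Number of tubes (defaults to the max tube index seen).
#' @param mode `"reads"` (default) counts each read once in the window of
#'   its leftmost base; `"bases"` counts mapped bases, splitting reads
#'   across the windows they overlap.
#' @return A `window_count_matrix`: list with `window_size`, `chrom_lengths`,
#'   `n_tubes` and `counts`, a per-chromosome list of `n_tubes x n_windows`
#'   matrices.
#' @export
bin_reads <- function(reads, window_size, chrom_lengths,
                      n_tubes = max(reads$tube, 1),
                      mode = c("reads", "bases")) {
  mode <- match.arg(mode)
  stopifnot(window_size > 0, all(chrom_lengths > 0))
  unknown <- setdiff(unique(reads$chrom), names(chrom_lengths))
  if (length(unknown) > 0)
    stop("reads on unknown chromosome(s): ", paste(unknown, collapse = ", "))
  beyond <- reads$pos > chrom_lengths[reads$chrom]
  if (any(beyond))
    stop(sum(beyond), " read(s) start beyond chromosome end (first: ",
         reads$chrom[which(beyond)[1]], ":", reads$pos[which(beyond)[1]], ")")
  counts <- lapply(names(chrom_lengths), function(chrom) {
    nw <- n_windows(chrom_lengths[[chrom]], window_size)
    m <- matrix(0, nrow = n_tubes, ncol = nw)
    sel <- reads$chrom == chrom
    if (any(sel)) {
      pos <- reads$pos[sel]
      win <- (pos - 1) %/% window_size  # 0-based window index
      idx <- win * n_tubes + reads$tube[sel]
      if (mode == "reads") {
        m[] <- tabulate(idx, nbins = n_tubes * nw)
      } else {
        # mapped bases; a read straddling a window boundary contributes to
        # both windows (read length << window, so at most two)
        end <- pos + reads$length[sel] - 1
        len1 <- pmin(end, (win + 1) * window_size) - pos + 1
        len2 <- reads$length[sel] - len1
        spill <- len2 > 0 & win + 1 < nw
        w <- c(len1, len2[spill])
        i <- c(idx, idx[spill] + n_tubes)
        acc <- rowsum(w, i)
        m[as.integer(rownames(acc))] <- acc
      }
    }
    m
  })
  structure(list(window_size = window_size, chrom_lengths = chrom_lengths,
                 n_tubes = as.integer(n_tubes),
                 counts = stats::setNames(counts, names(chrom_lengths))),
            class = "window_count_matrix")
}

#' @export
print.window_count_matrix <- function(x, ...) {
  cat(sprintf("<window_count_matrix: %d tubes x %d chromosomes, %s-bp windows, %s reads>\n",
              x$n_tubes, length(x$counts),
              format(x$window_size, big.mark = ","),
              format(sum(vapply(x$counts, sum, numeric(1))), big.mark = ",")))
  invisible(x)
}

# Merge runs of covered windows, bridging gaps of <= gap windows.
# Returns a data.frame of 0-based window index ranges [from, to].
merge_covered_windows <- function(covered, gap) {
  idx <- which(covered)
  if (length(idx) == 0)
    return(data.frame(from = integer(), to = integer()))
  brk <- which(diff(idx) > gap + 1)
  from <- idx[c(1, brk + 1)] - 1L
  to <- idx[c(brk, length(idx))] - 1L
  data.frame(from = from, to = to)
}

#' Call chromosome presence per tube
#'
#' For each (tube, chromosome): windows with at least one read are covered;
#' runs of covered windows separated by at most `gap_merge_windows`
#' uncovered windows (amplification gaps) are merged into intervals. The
#' call is `ABSENT` when the read count or covered fraction is below
#' threshold, `WHOLE` when the merged intervals span at least
#' `whole_fraction_min` of the chromosome's windows, else `FRAGMENT`.
#'
#' @param wcm A `window_count_matrix` from [bin_reads()].
#' @param min_reads Minimum reads for a chromosome to be considered present
#'   in a tube.
#' @param min_covered_fraction Minimum fraction of windows covered.
#' @param whole_fraction_min Span fraction at or above which a chromosome is
#'   called whole.
#' @param gap_merge_windows Maximum uncovered gap (in windows) merged into
#'   an interval.
#' @return A `presence_matrix`: list with `calls` (data.frame: tube, chrom,
#'   status, read_count, covered_window_fraction), `intervals` (named list
#'   `"tube:chrom"` -> data.frame of bp intervals `start`,`end` and window
#'   ranges `win_from`,`win_to`), plus the thresholds and window geometry.
#' @export
call_presence <- function(wcm, min_reads = 50, min_covered_fraction = 0.02,
                          whole_fraction_min = 0.8, gap_merge_windows = 3) {
  stopifnot(inherits(wcm, "window_count_matrix"), min_reads > 0,
            min_covered_fraction > 0, whole_fraction_min > 0,
            gap_merge_windows >= 0)
  w <- wcm$window_size
  rows <- list()
  intervals <- list()
  for (chrom in names(wcm$counts)) {
    m <- wcm$counts[[chrom]]
    nw <- ncol(m)
    chrom_len <- wcm$chrom_lengths[[chrom]]
    for (tube in seq_len(wcm$n_tubes)) {
      cnt <- m[tube, ]
      total <- sum(cnt)
      covered <- cnt > 0
      frac_cov <- mean(covered)
      iv <- merge_covered_windows(covered, gap_merge_windows)
      span <- sum(iv$to - iv$from + 1)
      status <- if (total < min_reads || frac_cov < min_covered_fraction)
        "ABSENT"
      else if (span >= whole_fraction_min * nw) "WHOLE"
      else "FRAGMENT"
      rows[[length(rows) + 1L]] <-
        data.frame(tube = tube, chrom = chrom, status = status,
                   read_count = total, covered_window_fraction = frac_cov)
      if (status != "ABSENT" && nrow(iv) > 0) {
        iv$start <- iv$from * w + 1
        iv$end <- pmin((iv$to + 1) * w, chrom_len)
        intervals[[paste0(tube, ":", chrom)]] <-
          data.frame(start = iv$start, end = iv$end,
                     win_from = iv$from, win_to = iv$to)
      }
    }
  }
  calls <- do.call(rbind, rows)
  rownames(calls) <- NULL
  structure(list(calls = calls, intervals = intervals,
                 window_size = w, chrom_lengths = wcm$chrom_lengths,
                 n_tubes = wcm$n_tubes,
                 params = list(min_reads = min_reads,
                               min_covered_fraction = min_covered_fraction,
                               whole_fraction_min = whole_fraction_min,
                               gap_merge_windows = gap_merge_windows)),
            class = "presence_matrix")
}

#' @export
print.presence_matrix <- function(x, ...) {
  tab <- table(x$calls$status)
  cat(sprintf("<presence_matrix: %d tubes x %d chromosomes (%s)>\n",
              x$n_tubes, length(unique(x$calls$chrom)),
              paste(names(tab), tab, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Summarise the karyotype implied by a presence matrix
#'
#' Counts observed copies per chromosome (`WHOLE` calls across tubes;
#' two copies of the same chromosome in one tube are indistinguishable, so
#' the deficit shows up in `missing` rather than being guessed), lists
#' hosting tubes, flags copy-number anomalies relative to `expected_copies`,
#' and counts separated homologous pairs. `FRAGMENT` calls are reported as
#' annotations (they are typically claimed by a translocation).
#'
#' @param presence A `presence_matrix`.
#' @param expected_copies Named vector of expected copy numbers (defaults to
#'   2 everywhere except chrY = 1 when present).
#' @return A `karyotype_summary`: list with `per_chromosome` (data.frame:
#'   chrom, expected, observed_whole, fragment_tubes, tubes, separated),
#'   `separated_pairs`, `missing`, `anomalies` (character vector).
#' @export
summarize_karyotype <- function(presence, expected_copies = NULL) {
  stopifnot(inherits(presence, "presence_matrix"))
  chroms <- names(presence$chrom_lengths)
  if (is.null(expected_copies)) {
    # default to 46,XY when a Y is in the genome, 46,XX otherwise
    expected_copies <- stats::setNames(rep(2, length(chroms)), chroms)
    if ("chrY" %in% chroms) {
      expected_copies[["chrY"]] <- 1
      if ("chrX" %in% chroms) expected_copies[["chrX"]] <- 1
    }
  }
  calls <- presence$calls
  rows <- lapply(chroms, function(chrom) {
    sub <- calls[calls$chrom == chrom, ]
    whole_tubes <- sub$tube[sub$status == "WHOLE"]
    frag_tubes <- sub$tube[sub$status == "FRAGMENT"]
    expected <- if (chrom %in% names(expected_copies))
      expected_copies[[chrom]] else 2
    data.frame(chrom = chrom, expected = expected,
               observed_whole = length(whole_tubes),
               fragment_tubes = paste(frag_tubes, collapse = ","),
               tubes = paste(whole_tubes, collapse = ","),
               separated = length(whole_tubes) >= 2)
  })
  per_chrom <- do.call(rbind, rows)
  anomalies <- character()
  for (i in seq_len(nrow(per_chrom))) {
    ch <- per_chrom$chrom[i]; obs <- per_chrom$observed_whole[i]
    exp_n <- per_chrom$expected[i]
    if (obs > exp_n)
      anomalies <- c(anomalies, sprintf(
        "%s: %d copies observed, %d expected (%s)", ch, obs, exp_n,
        if (obs == 3 && exp_n == 2) "trisomy" else "gain"))
  }
  missing <- sum(pmax(per_chrom$expected - per_chrom$observed_whole, 0))
  structure(list(per_chromosome = per_chrom,
                 separated_pairs = sum(per_chrom$separated),
                 missing = missing,
                 anomalies = anomalies),
            class = "karyotype_summary")
}

#' @export
print.karyotype_summary <- function(x, ...) {
  cat(sprintf("<karyotype_summary: %d separated pairs, %d missing copies%s>\n",
              x$separated_pairs, x$missing,
              if (length(x$anomalies) > 0)
                paste0("; ", paste(x$anomalies, collapse = "; ")) else ""))
  invisible(x)
}
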