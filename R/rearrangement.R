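# Balanced-translocation detection: complementary chromosome fragments
# across two tubes nominate a candidate; chimeric (split) reads refine the
# junction to base resolution.
#
# Convention for a reciprocal t(A;B): pos_a is the last retained base of A
# on der(A), pos_b the first retained base of B on der(A). Reads from
# der(B) see the reciprocal junction (end of B head, first base of the A
# tail); comparing the two junctions exposes bases of B lost at the join.

frag_span <- function(presence, tube, chrom) {
  iv <- presence$intervals[[paste0(tube, ":", chrom)]]
  if (is.null(iv)) return(NULL)
  c(from = min(iv$win_from), to = max(iv$win_to))
}

#' Nominate translocation candidates from complementary fragments
#'
#' For every unordered chromosome pair (A, B) and tube pair (t1, t2), a
#' candidate is emitted when both tubes hold `FRAGMENT` calls of both
#' chromosomes, the two A-fragments are complementary (union spans at least
#' `whole_fraction_min` of A with window overlap at most
#' `gap_merge_windows`), likewise for B, the head/tail orientation is
#' consistent with two derivative chromosomes, and A and B appear only as
#' `WHOLE`/`ABSENT` elsewhere. The edge regions are the window-resolution
#' uncertainty intervals bracketing each fragment boundary.
#'
#' @param presence A `presence_matrix` from [call_presence()].
#' @return List of `translocation_candidate` objects, each with `chrom_a`,
#'   `chrom_b`, `tube_der_a` (tube holding A-head + B-tail), `tube_der_b`,
#'   `edge_region_a`/`edge_region_b` (bp start/end), `window_size`.
#' @export
pair_fragments <- function(presence) {
  stopifnot(inherits(presence, "presence_matrix"))
  calls <- presence$calls
  w <- presence$window_size
  p <- presence$params
  frag <- calls[calls$status == "FRAGMENT", ]
  out <- list()
  chroms <- sort(unique(frag$chrom))
  if (length(chroms) < 2) return(out)
  for (ia in seq_len(length(chroms) - 1)) for (ib in (ia + 1):length(chroms)) {
    a <- chroms[ia]; b <- chroms[ib]
    tubes <- intersect(frag$tube[frag$chrom == a], frag$tube[frag$chrom == b])
    if (length(tubes) != 2) next
    # elsewhere, A and B must be WHOLE or ABSENT
    other <- calls[calls$chrom %in% c(a, b) & !(calls$tube %in% tubes), ]
    if (any(other$status == "FRAGMENT")) next
    sa1 <- frag_span(presence, tubes[1], a); sa2 <- frag_span(presence, tubes[2], a)
    sb1 <- frag_span(presence, tubes[1], b); sb2 <- frag_span(presence, tubes[2], b)
    if (is.null(sa1) || is.null(sa2) || is.null(sb1) || is.null(sb2)) next
    nwa <- n_windows(presence$chrom_lengths[[a]], w)
    nwb <- n_windows(presence$chrom_lengths[[b]], w)
    complementary <- function(s1, s2, nw) {
      overlap <- max(0, min(s1[["to"]], s2[["to"]]) -
                       max(s1[["from"]], s2[["from"]]) + 1)
      span1 <- s1[["to"]] - s1[["from"]] + 1
      span2 <- s2[["to"]] - s2[["from"]] + 1
      (span1 + span2 - overlap) >= p$whole_fraction_min * nw &&
        overlap <= p$gap_merge_windows
    }
    if (!complementary(sa1, sa2, nwa) || !complementary(sb1, sb2, nwb)) next
    # orientation: der(A) carries the head (low-coordinate part) of A and
    # the tail of B; der(B) the converse
    a_head_tube <- if (sa1[["from"]] <= sa2[["from"]]) tubes[1] else tubes[2]
    b_head_tube <- if (sb1[["from"]] <= sb2[["from"]]) tubes[1] else tubes[2]
    if (a_head_tube == b_head_tube) next
    edge_region <- function(head_span, tail_span, chrom_len) {
      lo_win <- min(head_span[["to"]], tail_span[["from"]])
      hi_win <- max(head_span[["to"]], tail_span[["from"]])
      c(start = lo_win * w + 1, end = min((hi_win + 1) * w, chrom_len))
    }
    a_head <- if (a_head_tube == tubes[1]) sa1 else sa2
    a_tail <- if (a_head_tube == tubes[1]) sa2 else sa1
    b_head <- if (b_head_tube == tubes[1]) sb1 else sb2
    b_tail <- if (b_head_tube == tubes[1]) sb2 else sb1
    out[[length(out) + 1L]] <- structure(
      list(chrom_a = a, chrom_b = b,
           tube_der_a = a_head_tube, tube_der_b = b_head_tube,
           edge_region_a = edge_region(a_head, a_tail,
                                       presence$chrom_lengths[[a]]),
           edge_region_b = edge_region(b_head, b_tail,
                                       presence$chrom_lengths[[b]]),
           window_size = w),
      class = "translocation_candidate")
  }
  out
}

#' @export
print.translocation_candidate <- function(x, ...) {
  cat(sprintf("<translocation_candidate t(%s;%s): tubes %d/%d, edges %s:%s-%s | %s:%s-%s>\n",
              sub("^chr", "", x$chrom_a), sub("^chr", "", x$chrom_b),
              x$tube_der_a, x$tube_der_b,
              x$chrom_a, format(x$edge_region_a[["start"]], big.mark = ","),
              format(x$edge_region_a[["end"]], big.mark = ","),
              x$chrom_b, format(x$edge_region_b[["start"]], big.mark = ","),
              format(x$edge_region_b[["end"]], big.mark = ",")))
  invisible(x)
}

# all mapped segments (primary + split) as (tube, chrom, pos, end) spans
read_spans <- function(reads) {
  prim <- data.frame(tube = reads$tube, chrom = reads$chrom,
                     pos = reads$pos, end = reads$pos + reads$length - 1)
  sec <- reads[!is.na(reads$chrom2), , drop = FALSE]
  if (nrow(sec) > 0)
    prim <- rbind(prim, data.frame(tube = sec$tube, chrom = sec$chrom2,
                                   pos = sec$pos2,
                                   end = sec$pos2 + sec$length2 - 1))
  prim
}

#' Narrow candidate edge regions by fine-window re-binning
#'
#' Re-bins the reads inside each edge region at `fine_window` and moves the
#' fragment boundary to the interval between the last fine window covered by
#' the head-side derivative's reads and the first fine window covered by the
#' tail-side derivative's reads. The refined region is always contained in
#' the input region; if either side has no reads in the region, that region
#' is returned unchanged with a warning flag.
#'
#' @param reads Read data.frame (MAPQ-filtered).
#' @param candidate A `translocation_candidate`.
#' @param fine_window Fine window size in bp (< the coarse window; equal to
#'   the coarse window is a no-op).
#' @return The candidate with refined `edge_region_a`/`edge_region_b` and a
#'   logical `narrow_warning` vector (one flag per side).
#' @export
narrow_region <- function(reads, candidate, fine_window) {
  stopifnot(inherits(candidate, "translocation_candidate"), fine_window > 0)
  if (fine_window >= candidate$window_size) {
    candidate$narrow_warning <- c(a = FALSE, b = FALSE)
    return(candidate)
  }
  spans <- read_spans(reads)
  refine_side <- function(region, chrom, head_tube, tail_tube) {
    sel <- spans$chrom == chrom & spans$end >= region[["start"]] &
      spans$pos <= region[["end"]]
    left <- spans[sel & spans$tube == head_tube, ]
    right <- spans[sel & spans$tube == tail_tube, ]
    if (nrow(left) == 0 || nrow(right) == 0)
      return(list(region = region, warn = TRUE))
    fw_of <- function(p) (pmax(pmin(p, region[["end"]]), region[["start"]]) -
                            region[["start"]]) %/% fine_window
    last_left <- max(fw_of(left$end))
    first_right <- min(fw_of(right$pos))
    lo <- min(last_left, first_right); hi <- max(last_left, first_right)
    list(region = c(start = region[["start"]] + lo * fine_window,
                    end = min(region[["start"]] + (hi + 1) * fine_window - 1,
                              region[["end"]])),
         warn = FALSE)
  }
  # head of A sits on der(A); head of B sits on der(B)
  ra <- refine_side(candidate$edge_region_a, candidate$chrom_a,
                    candidate$tube_der_a, candidate$tube_der_b)
  rb <- refine_side(candidate$edge_region_b, candidate$chrom_b,
                    candidate$tube_der_b, candidate$tube_der_a)
  candidate$edge_region_a <- ra$region
  candidate$edge_region_b <- rb$region
  candidate$narrow_warning <- c(a = ra$warn, b = rb$warn)
  candidate
}

#' Collect chimeric reads supporting a candidate junction
#'
#' Returns split-aligned reads from the two derivative-bearing tubes with
#' one segment overlapping the candidate's edge region on chromosome A and
#' the other overlapping the edge region on chromosome B. `a_leading`
#' records whether the A segment is the first (upstream) part of the read:
#' der(A)-junction reads lead with A, der(B)-junction reads lead with B.
#'
#' @param reads Read data.frame.
#' @param candidate A `translocation_candidate` (possibly narrowed).
#' @return data.frame of chimeric reads: tube, chrom1, pos1, len1, chrom2,
#'   pos2, len2, a_leading, plus the implied junction bases `junc1` (last
#'   reference base of the leading segment) and `junc2` (first reference
#'   base of the trailing segment).
#' @export
collect_chimeric <- function(reads, candidate) {
  stopifnot(inherits(candidate, "translocation_candidate"))
  split <- reads[!is.na(reads$chrom2) &
                   reads$tube %in% c(candidate$tube_der_a,
                                     candidate$tube_der_b), , drop = FALSE]
  if (nrow(split) == 0)
    return(data.frame(tube = integer(), chrom1 = character(),
                      pos1 = numeric(), len1 = numeric(),
                      chrom2 = character(), pos2 = numeric(),
                      len2 = numeric(), a_leading = logical(),
                      junc1 = numeric(), junc2 = numeric()))
  overlaps <- function(chrom, s, e, target_chrom, region)
    chrom == target_chrom & e >= region[["start"]] & s <= region[["end"]]
  e1 <- split$pos + split$length - 1
  e2 <- split$pos2 + split$length2 - 1
  in_a1 <- overlaps(split$chrom, split$pos, e1, candidate$chrom_a,
                    candidate$edge_region_a)
  in_b1 <- overlaps(split$chrom, split$pos, e1, candidate$chrom_b,
                    candidate$edge_region_b)
  in_a2 <- overlaps(split$chrom2, split$pos2, e2, candidate$chrom_a,
                    candidate$edge_region_a)
  in_b2 <- overlaps(split$chrom2, split$pos2, e2, candidate$chrom_b,
                    candidate$edge_region_b)
  keep <- (in_a1 & in_b2) | (in_b1 & in_a2)
  split <- split[keep, , drop = FALSE]
  a_leading <- (in_a1 & in_b2)[keep]
  data.frame(tube = split$tube, chrom1 = split$chrom, pos1 = split$pos,
             len1 = split$length, chrom2 = split$chrom2, pos2 = split$pos2,
             len2 = split$length2, a_leading = a_leading,
             junc1 = split$pos + split$length - 1, junc2 = split$pos2,
             row.names = NULL)
}

#' Call the breakpoint at base resolution from chimeric reads
#'
#' Each A-leading chimeric read votes a `(pos_a, pos_b)` pair (last
#' reference base of its A segment, first reference base of its B segment);
#' the modal pair wins. B-leading reads vote the reciprocal junction; when
#' both derivatives are observed, the called `pos_b` minus the reciprocal
#' B-head end minus one gives the bases of B lost at the junction
#' (`junction_gap_b`), else 0 is reported.
#'
#' @param chimeric data.frame from [collect_chimeric()].
#' @param min_support Minimum reads agreeing on the modal pair (default 3).
#' @param merge_tol Merge tolerance in bp: votes within `merge_tol` of the
#'   modal pair count as support (0 = exact voting; amplification does not
#'   shift alignment ends in the simulator, but real aligners may).
#' @return A `breakpoint_call` with `status` `"CALLED"` (fields `pos_a`,
#'   `pos_b`, `junction_gap_b`, `n_support`, `consensus_fraction`,
#'   `n_reciprocal`) or `"NO_CALL"` (field `reason`, and `tied_candidates`
#'   when two modal pairs tie).
#' @export
refine_breakpoint <- function(chimeric, min_support = 3, merge_tol = 0) {
  stopifnot(min_support >= 1, merge_tol >= 0)
  no_call <- function(reason, tied = NULL)
    structure(list(status = "NO_CALL", reason = reason,
                   tied_candidates = tied),
              class = "breakpoint_call")
  prim <- chimeric[chimeric$a_leading, , drop = FALSE]
  if (nrow(prim) < min_support)
    return(no_call(sprintf("%d A-leading chimeric read(s) < min_support %d",
                           nrow(prim), min_support)))
  key <- paste(prim$junc1, prim$junc2)
  tab <- sort(table(key), decreasing = TRUE)
  if (length(tab) > 1 && tab[1] == tab[2]) {
    tied <- do.call(rbind, lapply(names(tab)[tab == tab[1]], function(k) {
      v <- as.numeric(strsplit(k, " ")[[1]])
      data.frame(pos_a = v[1], pos_b = v[2], votes = as.integer(tab[1]))
    }))
    return(no_call("tie between modal junction pairs", tied))
  }
  modal <- as.numeric(strsplit(names(tab)[1], " ")[[1]])
  pos_a <- modal[1]; pos_b <- modal[2]
  support <- abs(prim$junc1 - pos_a) <= merge_tol &
    abs(prim$junc2 - pos_b) <= merge_tol
  n_support <- sum(support)
  if (n_support < min_support)
    return(no_call(sprintf("modal support %d < min_support %d",
                           n_support, min_support)))
  recip <- chimeric[!chimeric$a_leading, , drop = FALSE]
  gap <- 0
  if (nrow(recip) > 0) {
    b_head_end <- as.numeric(names(sort(table(recip$junc1),
                                        decreasing = TRUE))[1])
    gap <- pos_b - b_head_end - 1
  }
  structure(list(status = "CALLED",
                 chrom_a = if (nrow(prim) > 0) prim$chrom1[1] else NA,
                 chrom_b = if (nrow(prim) > 0) prim$chrom2[1] else NA,
                 pos_a = pos_a, pos_b = pos_b, junction_gap_b = gap,
                 n_support = n_support,
                 consensus_fraction = n_support / nrow(prim),
                 n_reciprocal = nrow(recip)),
            class = "breakpoint_call")
}

#' @export
print.breakpoint_call <- function(x, ...) {
  if (x$status == "CALLED")
    cat(sprintf("<breakpoint_call %s:%s | %s:%s (gap %d bp, %d supporting reads, consensus %.2f)>\n",
                x$chrom_a, format(x$pos_a, big.mark = ","),
                x$chrom_b, format(x$pos_b, big.mark = ","),
                x$junction_gap_b, x$n_support, x$consensus_fraction))
  else
    cat(sprintf("<breakpoint_call NO_CALL: %s>\n", x$reason))
  invisible(x)
}
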