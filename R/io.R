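# Standard-format I/O: minimal SAM and alignment TSV, VCF (truth, phased,
# breakend), BED, and the per-window count table.
#
# Coordinates: 1-based inclusive internally and in SAM/VCF; BED and the
# window table are 0-based half-open.

cigar_ref_len <- function(cigar) {
  ops <- gregexpr("\\d+[MIDNSHP=X]", cigar)
  vapply(regmatches(cigar, ops), function(parts) {
    n <- as.numeric(sub("[MIDNSHP=X]", "", parts))
    op <- sub("\\d+", "", parts)
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, numeric(1))
}

#' Write reads as a minimal SAM file
#'
#' One file per tube. Header carries `@SQ` lines; split reads carry an
#' `SA:Z:` auxiliary field with the partner segment. Sequences and
#' qualities are omitted (`*`): the simulator models mapped records, not
#' nucleotides.
#'
#' @param reads Read data.frame.
#' @param path Output file.
#' @param chrom_lengths Named vector of reference lengths for the header.
#' @param tube If given, write only this tube's reads.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, path, chrom_lengths, tube = NULL) {
  if (!is.null(tube)) reads <- reads[reads$tube == tube, , drop = FALSE]
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                   as.integer(chrom_lengths)))
  lines <- hdr
  if (nrow(reads) > 0) {
    reads <- reads[order(match(reads$chrom, names(chrom_lengths)),
                         reads$pos, method = "radix"), ]
    sa <- ifelse(is.na(reads$chrom2), "",
                 sprintf("\tSA:Z:%s,%d,+,%dM,%d,0;", reads$chrom2,
                         as.integer(reads$pos2), as.integer(reads$length2),
                         as.integer(reads$mapq)))
    rec <- sprintf("r%06d\t0\t%s\t%d\t%d\t%dM\t*\t0\t0\t*\t*%s",
                   seq_len(nrow(reads)), reads$chrom, as.integer(reads$pos),
                   as.integer(reads$mapq), as.integer(reads$length), sa)
    lines <- c(lines, rec)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write reads as an alignment TSV
#'
#' Tab-separated with columns `tube`, `chrom`, `pos` (1-based), `length`,
#' `mapq`, `chrom2`, `pos2`, `length2` (split segment, empty if none),
#' `source_copy` (truth label, synthetic data only).
#'
#' @inheritParams write_sam
#' @return `path`, invisibly.
#' @export
write_alignment_tsv <- function(reads, path) {
  utils::write.table(reads, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read aligned reads from SAM or alignment TSV
#'
#' SAM files are parsed through Rsamtools (conversion to BAM, then
#' `scanBam`), with the first `SA:Z:` entry populating the split segment.
#' TSV files must carry the columns written by [write_alignment_tsv()].
#'
#' @param path Input file.
#' @param format `"auto"` (by extension), `"sam"` or `"tsv"`.
#' @param tube Tube index assigned to SAM records (SAM has one file per
#'   tube; TSV carries its own `tube` column).
#' @param chrom_lengths Optional named vector; when given, records on
#'   unknown chromosomes are rejected with the known names listed.
#' @return Read data.frame (see [simulate_reads()]).
#' @export
read_alignments <- function(path, format = c("auto", "sam", "tsv"),
                            tube = 1L, chrom_lengths = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.sam$", path, ignore.case = TRUE)) "sam" else "tsv"
  reads <- if (format == "sam")
    read_sam_file(path, tube) else read_tsv_alignments(path)
  if (!is.null(chrom_lengths)) {
    unknown <- setdiff(stats::na.omit(unique(c(reads$chrom, reads$chrom2))),
                       names(chrom_lengths))
    if (length(unknown) > 0)
      stop("unknown reference name(s): ", paste(unknown, collapse = ", "),
           "; known: ", paste(names(chrom_lengths), collapse = ", "))
  }
  reads
}

read_sam_file <- function(path, tube) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("reading SAM requires the Rsamtools package")
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(bam), add = TRUE)
  param <- Rsamtools::ScanBamParam(
    what = c("rname", "pos", "mapq", "cigar"), tag = "SA")
  x <- Rsamtools::scanBam(bam, param = param)[[1]]
  n <- length(x$pos)
  sa <- x$tag$SA
  if (is.null(sa)) sa <- rep(NA_character_, n)
  chrom2 <- rep(NA_character_, n); pos2 <- rep(NA_real_, n)
  length2 <- rep(NA_real_, n)
  has_sa <- !is.na(sa)
  if (any(has_sa)) {
    first <- sub(";.*$", "", sa[has_sa])
    parts <- strsplit(first, ",", fixed = TRUE)
    chrom2[has_sa] <- vapply(parts, `[`, character(1), 1)
    pos2[has_sa] <- as.numeric(vapply(parts, `[`, character(1), 2))
    length2[has_sa] <- cigar_ref_len(vapply(parts, `[`, character(1), 4))
  }
  out <- data.frame(tube = rep(as.integer(tube), n),
                    chrom = as.character(x$rname),
                    pos = as.numeric(x$pos),
                    length = if (n > 0) cigar_ref_len(x$cigar) else numeric(),
                    mapq = as.integer(x$mapq),
                    chrom2 = chrom2, pos2 = pos2, length2 = length2,
                    source_copy = rep(NA_character_, n))
  out[order(out$chrom, out$pos, method = "radix"), , drop = FALSE]
}

read_tsv_alignments <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "")
  required <- c("tube", "chrom", "pos", "length", "mapq")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0)
    stop("alignment TSV ", path, " lacks column(s): ",
         paste(missing, collapse = ", "))
  for (col in c("chrom2", "pos2", "length2", "source_copy"))
    if (is.null(x[[col]])) x[[col]] <- NA
  bad <- which(is.na(x$tube) | is.na(x$chrom) | is.na(x$pos) |
                 is.na(x$length) | is.na(x$mapq))
  if (length(bad) > 0)
    stop("malformed alignment record at line ", bad[1] + 1L, " of ", path)
  x$chrom <- as.character(x$chrom)
  x$chrom2 <- as.character(x$chrom2)
  x$tube <- as.integer(x$tube); x$mapq <- as.integer(x$mapq)
  for (col in c("pos", "length", "pos2", "length2"))
    x[[col]] <- as.numeric(x[[col]])
  x$source_copy <- as.character(x$source_copy)
  x[c("tube", "chrom", "pos", "length", "mapq", "chrom2", "pos2", "length2",
      "source_copy")]
}

vcf_header <- function(chrom_lengths, extra = character()) {
  c("##fileformat=VCFv4.2",
    "##source=scskit",
    sprintf("##contig=<ID=%s,length=%d>", names(chrom_lengths),
            as.integer(chrom_lengths)),
    extra)
}

#' Write the simulated truth SNPs as a phased VCF
#'
#' Heterozygous truth genotypes are written phased (`1|0` when homolog 0
#' carries the alternative allele, else `0|1`), with constant depth and
#' quality fields and a `COMMON` flag so the bulk-variant filters retain
#' them. This is the synthetic stand-in for a bulk-sample VCF.
#'
#' @param truth `snp_truth` table.
#' @param path Output file.
#' @param chrom_lengths Named vector of reference lengths.
#' @param depth,qual Depth and quality written on every record.
#' @return `path`, invisibly.
#' @export
write_truth_vcf <- function(truth, path, chrom_lengths, depth = 30,
                            qual = 60) {
  hdr <- vcf_header(chrom_lengths, c(
    '##INFO=<ID=DP,Number=1,Type=Integer,Description="Total depth">',
    '##INFO=<ID=COMMON,Number=0,Type=Flag,Description="Common population SNP (>=1% MAF)">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ttruth"))
  lines <- hdr
  if (nrow(truth) > 0) {
    gt <- ifelse(truth$allele0 == truth$alt, "1|0", "0|1")
    lines <- c(lines, sprintf("%s\t%d\t.\t%s\t%s\t%d\t.\tDP=%d;COMMON\tGT\t%s",
                              truth$chrom, as.integer(truth$pos), truth$ref,
                              truth$alt, as.integer(qual), as.integer(depth),
                              gt))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a bulk-sample VCF of candidate SNPs
#'
#' Parsed with vcfR. Depth is taken from the INFO `DP` field (falling back
#' to the first sample's FORMAT `DP`), the common-SNP flag from an INFO
#' `COMMON` flag (or `CAF`/`COMMON=1` styles), and the genotype from the
#' first sample.
#'
#' @param path VCF file.
#' @return data.frame with `chrom`, `pos`, `ref`, `alt`, `depth`,
#'   `quality`, `is_common`, `genotype` (input for [filter_bulk_snps()]).
#' @export
read_bulk_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v, getINFO = TRUE),
                       stringsAsFactors = FALSE)
  info <- fix$INFO
  dp <- suppressWarnings(as.numeric(sub(".*DP=([0-9]+).*", "\\1",
                                        paste0(";", info, ";"))))
  gt <- if (ncol(v@gt) >= 2)
    sub(":.*$", "", v@gt[, 2]) else rep(NA_character_, nrow(fix))
  if (ncol(v@gt) >= 2 && any(is.na(dp))) {
    fmt <- strsplit(v@gt[, 1], ":", fixed = TRUE)
    smp <- strsplit(v@gt[, 2], ":", fixed = TRUE)
    dp_fmt <- mapply(function(f, s) {
      i <- match("DP", f)
      if (is.na(i) || i > length(s)) NA_real_ else as.numeric(s[i])
    }, fmt, smp)
    dp[is.na(dp)] <- dp_fmt[is.na(dp)]
  }
  data.frame(chrom = fix$CHROM, pos = as.numeric(fix$POS), ref = fix$REF,
             alt = fix$ALT, depth = dp,
             quality = suppressWarnings(as.numeric(fix$QUAL)),
             is_common = grepl("(^|;)COMMON(;|=|$)", info),
             genotype = gt)
}

#' Write phased chromosomes as a VCF with phase sets
#'
#' Phased genotypes use pipe notation (`0|1` = copy 0 carries the reference
#' allele) with one `PS` phase-set identifier per chromosome (the position
#' of its first phased site): physical separation yields a single phase
#' block per chromosome.
#'
#' @param phased List of `phased_chromosome` objects.
#' @param path Output file.
#' @param chrom_lengths Named vector of reference lengths.
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(phased, path, chrom_lengths) {
  hdr <- vcf_header(chrom_lengths, c(
    '##INFO=<ID=EV,Number=1,Type=String,Description="Phasing evidence">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=PS,Number=1,Type=Integer,Description="Phase set">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tscs"))
  lines <- hdr
  for (ph in phased) {
    sn <- ph$snps[!is.na(ph$snps$allele0), , drop = FALSE]
    if (nrow(sn) == 0) next
    ps <- as.integer(min(sn$pos))
    gt <- ifelse(sn$allele0 == sn$alt, "1|0", "0|1")
    lines <- c(lines, sprintf("%s\t%d\t.\t%s\t%s\t.\t.\tEV=%s\tGT:PS\t%s:%d",
                              ph$chrom, as.integer(sn$pos), sn$ref, sn$alt,
                              sn$evidence, gt, ps))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a breakpoint call as paired VCF breakend (BND) records
#'
#' Emits the der(A) junction as two mated BND records in standard breakend
#' notation: the segment right of `pos_b` on chromosome B is joined after
#' `pos_a` on chromosome A.
#'
#' @param call A `breakpoint_call` with status `"CALLED"`.
#' @param path Output file.
#' @param chrom_lengths Named vector of reference lengths.
#' @return `path`, invisibly.
#' @export
write_bnd_vcf <- function(call, path, chrom_lengths) {
  stopifnot(inherits(call, "breakpoint_call"), call$status == "CALLED")
  hdr <- vcf_header(chrom_lengths, c(
    '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="SV type">',
    '##INFO=<ID=MATEID,Number=1,Type=String,Description="Mate breakend">',
    '##INFO=<ID=SUPPORT,Number=1,Type=Integer,Description="Supporting chimeric reads">',
    '##INFO=<ID=JUNCGAP,Number=1,Type=Integer,Description="Bases of partner chromosome lost at the junction">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"))
  rec <- c(
    sprintf("%s\t%d\tbnd_a\tN\tN[%s:%d[\t.\t.\tSVTYPE=BND;MATEID=bnd_b;SUPPORT=%d;JUNCGAP=%d",
            call$chrom_a, as.integer(call$pos_a), call$chrom_b,
            as.integer(call$pos_b), call$n_support,
            as.integer(call$junction_gap_b)),
    sprintf("%s\t%d\tbnd_b\tN\t]%s:%d]N\t.\t.\tSVTYPE=BND;MATEID=bnd_a;SUPPORT=%d;JUNCGAP=%d",
            call$chrom_b, as.integer(call$pos_b), call$chrom_a,
            as.integer(call$pos_a), call$n_support,
            as.integer(call$junction_gap_b)))
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Write intervals as BED (0-based half-open)
#'
#' @param regions data.frame with `chrom`, `start`, `end` (1-based
#'   inclusive) and optional `name`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  name <- if (!is.null(regions$name)) regions$name else "."
  lines <- sprintf("%s\t%d\t%d\t%s", regions$chrom,
                   as.integer(regions$start - 1), as.integer(regions$end),
                   name)
  writeLines(lines, path)
  invisible(path)
}

#' Export window counts as a long-form TSV (Circos-ring table)
#'
#' One row per (tube, chromosome, window) with 0-based half-open window
#' bounds -- the table behind a per-tube Circos ring plot.
#'
#' @param wcm A `window_count_matrix`.
#' @param path Output file.
#' @param drop_zero Omit zero-count windows (default TRUE).
#' @return `path`, invisibly.
#' @export
write_window_counts_tsv <- function(wcm, path, drop_zero = TRUE) {
  rows <- list()
  for (chrom in names(wcm$counts)) {
    m <- wcm$counts[[chrom]]
    len <- wcm$chrom_lengths[[chrom]]
    for (tube in seq_len(nrow(m))) {
      win <- which(if (drop_zero) m[tube, ] > 0 else rep(TRUE, ncol(m)))
      if (length(win) == 0) next
      rows[[paste(chrom, tube)]] <- data.frame(
        tube = tube, chrom = chrom,
        window_start = (win - 1) * wcm$window_size,
        window_end = pmin(win * wcm$window_size, len),
        count = m[tube, win])
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(tube = integer(), chrom = character(),
                      window_start = numeric(), window_end = numeric(),
                      count = integer())
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export the presence matrix as a tube-by-chromosome TSV
#'
#' Wide layout (chromosome rows, tube columns) mirroring the per-tube
#' chromosome table of an SCS run: `whole`, `fragment(start-end,...)` or
#' empty.
#'
#' @param presence A `presence_matrix`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_presence_tsv <- function(presence, path) {
  chroms <- names(presence$chrom_lengths)
  m <- matrix("", nrow = length(chroms), ncol = presence$n_tubes,
              dimnames = list(chroms, paste0("tube", seq_len(presence$n_tubes))))
  for (i in seq_len(nrow(presence$calls))) {
    row <- presence$calls[i, ]
    if (row$status == "ABSENT") next
    val <- if (row$status == "WHOLE") "whole" else {
      iv <- presence$intervals[[paste0(row$tube, ":", row$chrom)]]
      sprintf("fragment(%s)",
              paste(sprintf("%d-%d", as.integer(iv$start),
                            as.integer(iv$end)), collapse = ","))
    }
    m[row$chrom, row$tube] <- val
  }
  out <- data.frame(chrom = chroms, m, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
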