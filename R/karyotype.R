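# Karyotype specification and physical chromosome copies.
#
# A "copy" is one physical homolog (or derivative chromosome after a
# balanced translocation), represented as an ordered list of reference
# segments in 1-based inclusive coordinates. A normal copy has exactly one
# segment spanning its whole chromosome.

#' Describe a balanced translocation
#'
#' A reciprocal translocation t(A;B) produces two derivative chromosomes:
#' `der(A) = A[1..pos_a] + B[pos_b..end]` and
#' `der(B) = B[1..pos_b - 1 - junction_loss_b] + A[pos_a + 1..end]`.
#' `pos_a` is the last base of A retained on der(A) and `pos_b` the first
#' base of B retained on der(A); `junction_loss_b` bases of B immediately
#' before `pos_b` are lost at the junction (a one-base loss is seen in real
#' junctions). Total bases across both derivatives equal
#' `len(A) + len(B) - junction_loss_b`.
#'
#' @param chrom_a,chrom_b Chromosome labels.
#' @param pos_a 1-based last base of `chrom_a` retained on der(A).
#' @param pos_b 1-based first base of `chrom_b` retained on der(A).
#' @param junction_loss_b Bases of `chrom_b` lost at the junction (>= 0).
#' @return A `translocation` object.
#' @export
translocation <- function(chrom_a, pos_a, chrom_b, pos_b, junction_loss_b = 0L) {
  stopifnot(is.character(chrom_a), is.character(chrom_b),
            chrom_a != chrom_b,
            pos_a >= 1, pos_b >= 1, junction_loss_b >= 0,
            pos_b - 1 - junction_loss_b >= 0)
  structure(list(chrom_a = chrom_a, pos_a = as.numeric(pos_a),
                 chrom_b = chrom_b, pos_b = as.numeric(pos_b),
                 junction_loss_b = as.numeric(junction_loss_b)),
            class = "translocation")
}

#' Specify the karyotype of a simulated cell
#'
#' @param genome Named vector of chromosome lengths in bp (default the
#'   1/100-scale [mini_genome()]).
#' @param copy_numbers Named integer vector of copies per chromosome.
#'   Unnamed autosomes default to 2; when a `chrY` is in the genome the sex
#'   chromosomes default to X=1, Y=1 (a 46,XY cell). Use `c(chr21 = 3)` for
#'   trisomy 21 or `c(chrX = 2, chrY = 1)` for XXY.
#' @param translocations List of [translocation()] events. Each consumes one
#'   copy of its two partner chromosomes and replaces them with der(A) and
#'   der(B).
#' @param snp_density Expected heterozygous SNPs per bp (used by
#'   [plant_snps()]).
#' @return A `karyotype_spec` object.
#' @examples
#' spec <- karyotype_spec(mini_genome(chromosomes = c("chr3", "chr5")))
#' @export
karyotype_spec <- function(genome = mini_genome(), copy_numbers = NULL,
                           translocations = list(), snp_density = 2e-4) {
  stopifnot(is.numeric(genome), length(genome) > 0, all(genome > 0),
            !is.null(names(genome)), snp_density >= 0)
  cn <- stats::setNames(rep(2L, length(genome)), names(genome))
  if ("chrY" %in% names(genome)) {
    cn[["chrY"]] <- 1L
    if ("chrX" %in% names(genome)) cn[["chrX"]] <- 1L
  }
  if (!is.null(copy_numbers)) {
    unknown <- setdiff(names(copy_numbers), names(genome))
    if (length(unknown) > 0)
      stop("copy_numbers names not in genome: ", paste(unknown, collapse = ", "))
    cn[names(copy_numbers)] <- as.integer(copy_numbers)
  }
  if (any(cn < 0)) stop("copy_numbers must be >= 0")
  if (length(translocations) > 0 &&
      !all(vapply(translocations, inherits, logical(1), "translocation")))
    stop("translocations must be a list of translocation() objects")
  for (tr in translocations) {
    for (side in c("a", "b")) {
      chrom <- tr[[paste0("chrom_", side)]]
      pos <- tr[[paste0("pos_", side)]]
      if (!chrom %in% names(genome))
        stop("translocation chromosome ", chrom, " not in genome")
      if (pos > genome[[chrom]])
        stop("translocation position ", pos, " outside ", chrom,
             " (length ", genome[[chrom]], ")")
    }
  }
  structure(list(genome = genome, copy_numbers = cn,
                 translocations = translocations, snp_density = snp_density),
            class = "karyotype_spec")
}

new_copy <- function(copy_id, chrom, segments, homolog_index) {
  stopifnot(nrow(segments) >= 1, all(segments$start <= segments$end))
  structure(list(copy_id = copy_id, chrom = chrom,
                 segments = segments, homolog_index = homolog_index),
            class = "chromosome_copy")
}

#' @export
print.chromosome_copy <- function(x, ...) {
  seg <- paste(sprintf("%s:%s-%s", x$segments$chrom,
                       format(x$segments$start, big.mark = ",", trim = TRUE),
                       format(x$segments$end, big.mark = ",", trim = TRUE)),
               collapse = " + ")
  cat(sprintf("<chromosome_copy %s (homolog %d): %s>\n",
              x$copy_id, x$homolog_index, seg))
  invisible(x)
}

#' Total length of a chromosome copy
#' @param copy A `chromosome_copy`.
#' @return Length in bp (sum of its segments).
#' @export
copy_length <- function(copy) sum(copy$segments$end - copy$segments$start + 1)

#' Build the physical chromosome copies of a karyotype
#'
#' Expands a [karyotype_spec()] into one `chromosome_copy` per physical
#' homolog. Each translocation removes one intact copy of each partner
#' chromosome (homolog index 0) and adds the two derivative chromosomes.
#' Deterministic: the same spec always yields the same copies.
#'
#' @param spec A `karyotype_spec`.
#' @return List of `chromosome_copy` objects.
#' @examples
#' copies <- build_karyotype(karyotype_spec())
#' length(copies)  # 46 for the default 46,XY spec
#' @export
build_karyotype <- function(spec) {
  stopifnot(inherits(spec, "karyotype_spec"))
  genome <- spec$genome
  copies <- list()
  for (chrom in names(genome)) {
    n <- spec$copy_numbers[[chrom]]
    if (n < 1) next
    for (i in seq_len(n)) {
      h <- (i - 1L) %% 2L  # third copy of a trisomy reuses homolog 0 alleles
      id <- sprintf("%s.%d", chrom, i - 1L)
      seg <- data.frame(chrom = chrom, start = 1, end = genome[[chrom]])
      copies[[id]] <- new_copy(id, chrom, seg, h)
    }
  }
  for (tr in spec$translocations) {
    a <- tr$chrom_a; b <- tr$chrom_b
    ida <- sprintf("%s.0", a); idb <- sprintf("%s.0", b)
    if (is.null(copies[[ida]]) || is.null(copies[[idb]]))
      stop("translocation partners ", a, "/", b, " have no intact copy to rearrange")
    la <- genome[[a]]; lb <- genome[[b]]
    b_keep_end <- tr$pos_b - 1 - tr$junction_loss_b
    der_a_seg <- data.frame(chrom = c(a, b),
                            start = c(1, tr$pos_b),
                            end = c(tr$pos_a, lb))
    der_b_head <- if (b_keep_end >= 1)
      data.frame(chrom = b, start = 1, end = b_keep_end) else NULL
    der_b_tail <- if (tr$pos_a + 1 <= la)
      data.frame(chrom = a, start = tr$pos_a + 1, end = la) else NULL
    der_b_seg <- rbind(der_b_head, der_b_tail)
    copies[[ida]] <- NULL
    copies[[idb]] <- NULL
    der_a_id <- sprintf("der(%s)t(%s;%s)", sub("^chr", "", a),
                        sub("^chr", "", a), sub("^chr", "", b))
    der_b_id <- sprintf("der(%s)t(%s;%s)", sub("^chr", "", b),
                        sub("^chr", "", a), sub("^chr", "", b))
    copies[[der_a_id]] <- new_copy(der_a_id, a, der_a_seg, 0L)
    copies[[der_b_id]] <- new_copy(der_b_id, b, der_b_seg, 0L)
  }
  unname(copies)
}
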