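#' hg19 main-assembly chromosome lengths
#'
#' Lengths in base pairs of the 24 nuclear chromosomes of the GRCh37/hg19
#' reference (chr1..chr22, chrX, chrY; no unplaced scaffolds).
#'
#' @return Named integer-valued numeric vector of chromosome lengths (bp).
#' @examples
#' sum(hg19_chrom_lengths())  # ~3.10 Gb
#' @export
hg19_chrom_lengths <- function() {
  c(chr1  = 249250621, chr2  = 243199373, chr3  = 198022430,
    chr4  = 191154276, chr5  = 180915260, chr6  = 171115067,
    chr7  = 159138663, chr8  = 146364022, chr9  = 141213431,
    chr10 = 135534747, chr11 = 135006516, chr12 = 133851895,
    chr13 = 115169878, chr14 = 107349540, chr15 = 102531392,
    chr16 =  90354753, chr17 =  81195210, chr18 =  78077248,
    chr19 =  59128983, chr20 =  63025520, chr21 =  48129895,
    chr22 =  51304566, chrX  = 155270560, chrY  =  59373566)
}

#' Scaled-down human genome for fast simulation
#'
#' A miniature genome with the 24 hg19 chromosomes scaled down by a constant
#' factor (default 1/100: chr1 ~2.49 Mb ... chr21 ~0.48 Mb). All window logic
#' in the package takes the window size as a parameter, so full-scale hg19
#' with 1-Mb windows and this fixture with 10-kb windows run the same code.
#'
#' @param scale Integer divisor applied to each hg19 length.
#' @param chromosomes Optional character vector to subset (e.g.
#'   `c("chr3", "chr5")`).
#' @return Named numeric vector of chromosome lengths (bp).
#' @examples
#' mini_genome()[c("chr1", "chr21")]
#' @export
mini_genome <- function(scale = 100, chromosomes = NULL) {
  stopifnot(scale >= 1)
  g <- round(hg19_chrom_lengths() / scale)
  if (!is.null(chromosomes)) {
    missing <- setdiff(chromosomes, names(g))
    if (length(missing) > 0)
      stop("unknown chromosome(s): ", paste(missing, collapse = ", "),
           "; known: ", paste(names(g), collapse = ", "))
    g <- g[chromosomes]
  }
  g
}

#' Mean sequencing depth implied by a base total
#'
#' Fold coverage obtained by dividing the total number of sequenced bases by
#' the genome length, e.g. a 33.4-Gb run over hg19 is ~11-fold.
#'
#' @param total_bases Total sequenced (or mapped) bases.
#' @param genome_lengths Named vector of chromosome lengths; defaults to hg19.
#' @return Depth of coverage (fold).
#' @export
sequencing_depth <- function(total_bases, genome_lengths = hg19_chrom_lengths()) {
  stopifnot(total_bases >= 0, all(genome_lengths > 0))
  total_bases / sum(genome_lengths)
}
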