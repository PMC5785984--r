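Package: scskit
Title: Single-Chromosome Sequencing Analysis by Dilution of a Metaphase Cell
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for single-chromosome sequencing (SCS)
    experiments, in which the chromosomes of one metaphase cell are diluted
    into multiple tubes, amplified and sequenced per tube. Provides analytic
    and Monte-Carlo dilution-design calculations (how many tubes separate
    homologous pairs), a synthetic-data generator with known truth (patchy
    whole-genome-amplification coverage, derivative chromosomes from a
    balanced translocation, aneuploid karyotypes), read binning into genomic
    windows and per-tube chromosome presence calling, detection of balanced
    translocations from complementary chromosome fragments with
    base-resolution breakpoint refinement from chimeric reads, and
    whole-chromosome haplotype phasing of heterozygous SNPs by physical
    separation of homologs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    Rsamtools,
    vcfR
Config/testthat/edition: 3
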