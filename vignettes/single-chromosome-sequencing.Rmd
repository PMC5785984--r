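---
title: "Single-chromosome sequencing: models, parameters and design choices"
author: "scskit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-chromosome sequencing: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scskit)
```

## The method

Single-chromosome sequencing (SCS) separates the chromosomes of one
metaphase cell physically: the cell is lysed, its condensed chromosomes are
serially diluted into `k` tubes, and each tube is whole-genome amplified
(WGA), barcoded and sequenced. Because a diploid cell carries two physical
copies (homologs) of each chromosome, a tube usually receives at most one
copy of any chromosome, which enables three analyses that shotgun
sequencing of bulk DNA cannot do directly:

1. **Karyotype by read counting.** Binning each tube's mapped reads into
   fixed genomic windows shows which chromosomes (whole or partial) landed
   in which tube, including extra copies in trisomy or XXY cells.
2. **Balanced-translocation breakpoints.** A reciprocal translocation
   t(A;B) creates two derivative chromosomes. When the derivatives land in
   different tubes, each tube shows *complementary fragments* of both
   partner chromosomes; chimeric (split) reads across the junction then
   pin the breakpoint to the base.
3. **Whole-chromosome haplotype phasing.** When the two homologs of a
   chromosome land in different tubes, each tube sequences a single
   haplotype: a bulk-heterozygous SNP looks homozygous within a tube, and
   the allele observed in each tube is assigned to that physical copy.
   Every phased SNP of a chromosome belongs to one phase block.

The package implements the full analysis chain plus a dilution-design
calculator and a synthetic-data generator with known truth, so every stage
is testable without sequencing data.

## Dilution design

Dropping the two copies of a homologous pair independently and uniformly
into `k` tubes separates them with probability $(k-1)/k$. For $n$ pairs,
the expected number of separated pairs is $n(k-1)/k$ and the probability
of separating *all* pairs is $((k-1)/k)^n$. For a human cell ($n = 23$)
in $k = 8$ tubes:

```{r design}
expected_separated_pairs(23, 8)      # 20.125 pairs on average
perfect_separation_probability(23, 8)
design_table(23, c(4, 8, 16, 24, 32), reps = 5000, seed = 1)[
  , c("k_tubes", "p_pair_separated", "p_perfect", "expected_separated",
      "mc_mean", "recommended")]
```

`mc_separation()` verifies the closed forms by seeded Monte-Carlo and adds
a per-copy loss probability (chromosomes binding to plasticware are lost;
at a loss rate of 6/46 about 40 of 46 copies are recovered). There is no
single correct tube count: more tubes separate more pairs but dilute each
tube's DNA. The `recommended` column only annotates tube counts whose
expected separated fraction reaches 85%, a threshold we chose as
annotation, not as a claim about any particular experiment.

## What the generator simulates

`build_karyotype()` expands a karyotype specification into physical
chromosome copies: lists of reference segments in 1-based inclusive
coordinates. A balanced translocation with last retained base `pos_a` on A
and first retained base `pos_b` on B (with `junction_loss_b` bases of B
lost at the join) produces

* der(A) = A[1..pos_a] + B[pos_b..end]
* der(B) = B[1..pos_b-1-junction_loss_b] + A[pos_a+1..end]

so total bases are conserved up to the junction loss — an invariant the
test suite checks for random events.

`simulate_reads()` models WGA coverage as *clustered amplicons*, not
per-base thinning: one amplicon of geometric length (mean
`amplicon_length_mean`) is jittered into each stratum of the copy, so a
`target_fraction` of bases is covered in contiguous patches with
contiguous gaps. This matters because the presence caller must tolerate
real WGA gaps; uniform thinning would never produce multi-window holes.
Reads are sampled from amplicons at `mean_depth_on_covered`; a read
straddling a derivative junction is emitted as a split alignment with its
second segment on the partner chromosome. Reads overlapping truth SNPs
yield allele observations carrying the source homolog's allele, corrupted
at the per-base error rate `epsilon`. Optional background noise reads are
scattered genome-wide (they carry no allele information, modelling
mismapped reads), and a configurable rate of spurious split alignments
exercises breakpoint-caller specificity.

Defaults (units bp unless noted): `target_fraction` drawn per copy from
U[0.05, 0.22] — the observed coverage range of single amplified
chromosomes; `read_length` 100 and `amplicon_length_mean` 300 at fixture
scale, chosen so amplicon spacing is well below the binning window (at
real scale, kb amplicons are dense inside 1-Mb windows);
`mean_depth_on_covered` 4-fold, the regime where presence calling is easy
but per-site allele depth is limiting, as in a real shallow run.

The default fixture genome (`mini_genome()`) is hg19 scaled by 1/100
(chr1 ~2.49 Mb ... chr21 ~0.48 Mb) with 10-kb windows, preserving the
window count per chromosome of 1-Mb windows at full scale; all window
logic takes the window size as a parameter, so real-scale data runs the
same code path. What the generator does **not** model: nucleotide
sequences (reads are mapped records; alignment is upstream), chemistry
differences between MDA/MALBAC/GenomePlex beyond the coverage parameters,
GC bias, or strand (ignored throughout). Passing tests therefore show
correctness of the analysis logic under a faithful coverage geometry, not
robustness to aligner artefacts or amplification bias of real libraries.

## Presence calling

Reads with MAPQ below 30 are discarded (mapping error probability above
1e-3; genuine reads overwhelmingly sit at 60). `bin_reads()` counts reads
per (tube, chromosome, window) — windows are `[i*w, (i+1)*w)` in 0-based
half-open coordinates — and a `mode = "bases"` switch counts mapped bases
instead, since either quantity is a defensible definition of window
coverage and we make no claim about which a given study used.

`call_presence()` merges runs of covered windows (gaps of at most
`gap_merge_windows` = 3 windows are bridged — WGA gaps), then calls each
(tube, chromosome) `ABSENT` (fewer than `min_reads` = 50 reads or under
`min_covered_fraction` = 2% of windows covered), `WHOLE` (merged span at
least `whole_fraction_min` = 80% of windows) or `FRAGMENT` (with its
intervals). The thresholds are package choices — the qualitative rule
"determined by the quantity of mapped reads" has no published numeric
form — set so the 5–22% coverage regime robustly yields `WHOLE` at the
default depth, and all are exposed in the configuration. Two copies of
the same chromosome in one tube are indistinguishable by read counts; the
karyotype summary counts one presence and reports the deficit as
`missing` rather than guessing.

## Translocation detection

`pair_fragments()` nominates a candidate when two tubes each hold
`FRAGMENT` calls of the same two chromosomes, the fragments of each
chromosome are complementary (union span at least `whole_fraction_min`,
window overlap at most `gap_merge_windows`), the head/tail orientation is
consistent with exactly two derivatives, and the chromosomes are
`WHOLE`/`ABSENT` everywhere else. The *edge region* is the uncertainty
interval between the last covered window of the head fragment and the
first covered window of the tail fragment.

`narrow_region()` re-bins reads inside each edge region at a fine window
(default 500 bp at fixture scale) and moves the boundary to the interval
between the last head-side-covered and first tail-side-covered fine
window. The exact procedure by which a real study narrows a breakpoint
region from shallow data is not standardised; this implementation is the
package's own reconstruction of that step and is guaranteed only to
shrink monotonically (the refined region is always inside the input
region; a region without reads is returned unchanged with a warning
flag).

`refine_breakpoint()` lets each A-leading chimeric read vote an exact
`(pos_a, pos_b)` pair from its segment ends; the modal pair wins, ties
are a no-call with both candidates reported. Voting is exact by default
because the simulator does not perturb alignment ends; for real aligners
a `merge_tol` of a few bp is available. `min_support` defaults to 3: a
real deep run found five junction-crossing reads, and three balances
sensitivity at desk-scale depth while the specificity tests (spurious
split alignments at rate 1e-4) show no false calls. When reads from the
*reciprocal* derivative are present, the gap between the called `pos_b`
and the reciprocal B-head end exposes bases lost at the junction (a
one-base loss in the motivating case); with only one derivative observed
the gap is reported as 0.

Junction amplification is itself stochastic — WGA either captures the
junction region or it does not, in the simulator exactly as in a real
tube. The package therefore guarantees *conditional* exactness: whenever
at least `min_support` error-free chimeric reads exist, the call equals
the planted junction exactly. The test suite asserts this over 20
junction-amplified simulations and zero false calls over 20
translocation-free ones.

## Phasing

Bulk-sample variants are first filtered to the phasable reference set:
heterozygous, depth strictly above 10, quality strictly above 30 and
(optionally) common population SNPs — strict inequalities, matching the
usual GATK-style post-filters. Within each tube a site is classified by
its alternative allele ratio: homozygous-alternative above 80%,
heterozygous from 20% to 80% inclusive, reference below 20%; sites with
fewer than `min_site_depth` = 2 reads in a tube are no-calls. Depth-1
evidence is deliberately never trusted on its own for a two-sided call.

`phase_chromosome()` requires the chromosome's two copies in distinct
tubes and phases each SNP by one of two routes: opposite homozygous-like
calls in the two tubes (`both_tubes`), or — when only one tube covers the
site — assignment of the observed allele to that copy and the
complementary bulk allele to the other (`single_tube_complement`).
Complement phasing is on by default because per-tube coverage of a single
chromosome copy is low (one allele of a genuinely heterozygous bulk SNP
*must* sit on the uncovered homolog), but it leans on a single tube's
reads, so `evaluate_phasing()` scores the two routes separately and the
switch can be turned off. Agreeing or heterozygous-looking tube calls are
conflicts and stay unphased.

Accuracy is per-SNP allele-assignment concordance with the simulated
truth after aligning the arbitrary copy labels by majority vote; switch
errors cannot occur within a chromosome because physical separation
yields a single phase block by construction. Phased fractions are
reported against two denominators (all bulk het SNPs, and het SNPs on
separated chromosomes only), since either may be wanted as "fraction
phased".

## Numerical conventions and degenerate inputs

Coordinates are 1-based inclusive internally and in SAM/VCF output; BED
and the window-count table are 0-based half-open. Window indices are
0-based (`floor((pos-1)/w)`). Tube indices are 1-based everywhere, the
natural R convention. Deterministic behaviour: every stochastic operation
takes an explicit seed and identical inputs give byte-identical outputs;
the pipeline derives stage seeds from the single configured seed. Empty
inputs (no reads, no SNPs, density 0) produce empty but well-formed
objects; reads beyond a chromosome end or on unknown reference names are
rejected with the offending record named.

## Problem sizes used by the test suite

Tests run on reduced instances chosen to exercise the same code paths as
full-scale data: the 46,XY recovery properties use an 8-chromosome subset
of the 1/100 fixture (about 9.8 Mb of genome, ~100k reads per run, 100
seeds), translocation exactness uses a two-chromosome 550-kb cell at deep
coverage over 20 junction-amplified seeds, and the Monte-Carlo dilution
checks use 1e5 replicates. The acceptance script recomputes the headline
design quantities (20 separated pairs analytically and by simulation;
11-fold depth from the deep-run base total over hg19) from scratch at
those sizes.

## Known limitations

* Two copies of one chromosome in the same tube are not deconvolved.
* Presence thresholds assume roughly uniform per-tube library size; no
  per-window depth normalisation or GC correction is applied.
* `narrow_region()` is a plausible reconstruction of region refinement,
  not a validated reproduction of any specific published procedure.
* The simulator emits mapped records directly; aligner-specific artefacts
  (soft-clips, mismapping near repeats, MAPQ miscalibration) are only
  represented by the uniform noise and low-MAPQ fractions.
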