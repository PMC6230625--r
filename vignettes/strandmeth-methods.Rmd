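---
title: "Strand-resolved bisulfite clone methylation analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strand-resolved bisulfite clone methylation analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strandmeth)
```

## The assay this package models

Bisulfite treatment deaminates unmethylated cytosine to uracil (read as T
after PCR) while 5-methylcytosine is protected and still reads C. Because
conversion destroys the complementarity of the two DNA strands, each PCR
primer set amplifies exactly one strand of the converted DNA: the reverse
primer anneals to the chosen target strand and the amplified product serves
as the template for the forward primer. Cloning the amplicon and
Sanger-sequencing ~20 individual plasmid clones then reads out the
methylation state of every CpG on one *strand* of one *molecule* from one
cell: a read C at a CpG means methylated, a read T means unmethylated, and
the fraction of methylated calls across clones is the per-CpG percent
methylation of the cell population.

The package implements that entire workflow in silico and in analysis:

1. **bisulfite core** — reference amplicons with CpG discovery, strand
   handling, an explicit conversion model, and primer-design validation;
2. **synthetic data** — a clone-library generator with known per-CpG,
   per-strand methylation probabilities, incomplete conversion, sequencing
   error, and optional X-inactivation mosaicism;
3. **clone calling** — conversion-aware global alignment, per-CpG state
   calls, conversion-efficiency QC, and methylation matrices;
4. **statistics** — paired mixed-effects comparisons with Bonferroni
   correction, a donor-level sign-flip permutation companion, strand-bias
   (hemimethylation) analysis, and complete-linkage clustering of cell
   subtypes.

The scientific motivation is the observation that at some loci — notably
the Treg-specific demethylated region (TSDR) and promoter of *FOXP3* — the
two strands can carry *different* methylation states (hemimethylation), so
that an assay reading only one strand can misclassify a cell population.
The strand-bias layer quantifies exactly that: per-CpG
`|top% − bottom%|` indices and a region-level paired test of the
top-minus-bottom differences.

## Conversion model and chemistry defaults

The conversion model has two probabilities: `conversion_rate` (an
unmethylated C reads T) and `protection_rate` (a methylated C stays C).
Both default to 0.995, the performance floor specified for commercial
lightning-conversion kits. Setting both to 1 gives the exact chemistry
used by the deterministic unit tests; real-data analysis never needs them —
they only drive simulation.

Conversion-efficiency QC exploits the fact that non-CpG cytosines carry no
methylation in this assay, so after complete conversion they must all read
T. Per clone, efficiency = (non-CpG reference-C positions read as T) /
(those read as C or T). Clones below the QC threshold (default **0.95**)
are excluded with a recorded reason. The threshold is deliberately looser
than the kit specification (0.995) to tolerate Sanger-type read errors
in short amplicons with few assessable cytosines; it is a declared,
configurable decision, not an inference about how any particular laboratory
handled partially converted clones.

## Coordinates and strand conventions

Internally every position is a 1-based index on the assayed strand written
5'→3' — the idiomatic R convention; the BED export converts to 0-based
half-open coordinates. Bottom-strand assays are represented by
reverse-complementing the genomic sequence once at load, after which all
downstream logic is strand-agnostic. CpG ordinals (CpG 1, CpG 2, …) count
5'→3' on the assayed strand, matching the numbering convention of clone
methylation figures; note the two strands of the same region therefore
number the same physical CpG dinucleotides in opposite orders.

## Alignment: a conversion-aware Needleman–Wunsch

Clone sequences are aligned globally (affine gaps, Gotoh algorithm,
implemented in C++) against the *untreated* reference with an asymmetric
substitution rule: a reference C accepts either C or T in the read as a
match. At non-CpG Cs the T is the expected conversion product; at CpG Cs
the C/T outcome is the methylation signal and must not bias the alignment;
every other mismatch is penalised. Parameters are pinned for
reproducibility: match 2, mismatch −3, gap open −5, gap extend −2 (a gap of
length L costs −5 − 2(L−1)); identity floor 0.8, below which a clone is
flagged unalignable and excluded with a logged reason. Both the clone and
its reverse complement are scored and the better orientation kept, because
cloned inserts can be recovered in either direction even under directional
cloning. The implementation is verified against an independent
quadratic-time dynamic-programming oracle on hundreds of random pairs.

Percentages follow the clone-counting rule: per CpG,
`100 · methylated / (methylated + unmethylated)`, with ambiguous calls
(gap, N, non-C/T base) excluded from numerator and denominator and the
reduced denominators recorded. With 20 callable clones, 2 methylated calls
give exactly 10%.

## The synthetic-data generator

Each simulated clone draws its per-CpG methylation state from a
`methylation_profile`, applies the conversion model, then sprinkles uniform
substitution errors (default rate 0.001, Sanger-like). Two correlation
modes are offered because clone-sequencing data does not identify the
within-molecule correlation structure: `independent` (per-CpG Bernoulli
draws; the default for statistical tests) and `clone_level` (one epiallele
pattern per clone, all-methylated with probability `mean(p_meth)`,
reproducing the bimodal all-dark/all-light rows seen in lollipop plots of
mixed populations). Neither mode is asserted to be the biological truth.

Defaults are the assay's study conditions: 20 clones per
(donor × population × region × strand) group, five cell populations
(CD34, CD45RA+CD15s−, CD45RA−CD15s−, CD45RA−CD15s+, Tcon), and a
15-CpG TSDR-like synthetic region whose coding strand is the genomic
bottom strand (as for an X-linked gene encoded on the reverse strand).
The canned scenarios encode the patterns the analysis is designed to
distinguish, with per-population methylation levels anchored to reported
population averages for this assay family:

* `conventional_male` — Treg subsets demethylated (0.7–48.7%), Tcon
  methylated (85.7%), identically on both strands;
* `hemimethylated_donor` — coding (bottom) strand fully methylated in every
  population while the top strand follows the conventional pattern;
* `xi_female` — a 50:50 clone-level mosaic of an active-X profile and a
  fully methylated inactive-X profile, the pattern expected from
  X-inactivation at an X-linked locus in female donors (marginal ≈ 50%
  methylation in demethylated populations);
* `null_pair` — two populations with identical profiles, for calibration.

Reproducibility uses one master seed with per-group child streams derived
by stable FNV-1a hashing of the (donor, population, region, strand) key, so
adding or reordering groups never changes another group's draws and the
whole dataset is byte-reproducible from `(config, seed)`.

What the generator does **not** emulate: chromatogram noise and quality
scores, PCR duplicates or cloning bias beyond the epiallele option, indel
sequencing errors, or realistic within-region correlation of methylation.
Passing tests on synthetic data therefore demonstrate that the pipeline
recovers what the generator encodes — calling, QC, strand logic and the
statistical layer — not that it is robust to every artefact of real Sanger
data.

## Statistical layer

**Paired comparison.** For two populations of the same donors, the unit of
analysis is the per-(donor, CpG) difference in percent methylation. The
test fits `diff ~ 1 + (1 | donor) + (1 | cpg)` by REML (lme4) — crossed
random intercepts for donor and CpG position — and Wald-tests the intercept
(z reference distribution). The Wald choice and the degrees-of-freedom
question are declared decisions: clone-sequencing designs of this size (a
handful of donors, 10–40 CpGs) give 60+ difference observations, where the
normal reference is adequate. Degenerate inputs are handled explicitly:
all-zero differences return p = 1; a degenerate or unfittable model (e.g.
zero residual variance under a constant offset) falls back to the
permutation test with a note.

**Permutation companion.** Donor-level sign flips: under the null each
donor's whole difference vector is exchangeable with its negation. Flipping
at the donor level (never per CpG) respects within-donor correlation. With
D donors and `2^D` within the permutation budget the test enumerates all
sign patterns and is exact; otherwise Monte-Carlo with add-one correction.

**Multiplicity.** Comparing three Treg populations against the same Tcon
reference gives a family of three tests; the threshold is α = 0.05/3,
*reported* floored to three decimals (0.016) while decisions use the raw
quotient. Calibration under the study conditions (6 donors × 10 CpGs × 20
clones, null profile fixed at a constant p = 0.5 so the model's
homoscedasticity assumption holds) is checked by simulation in the test
suite: the measured type-I error sits near 0.03 — mildly conservative,
which is the expected behaviour of Wald intervals when the true random-
effect variances are on the boundary (zero) — and power for a 40-point
shift is ≈ 1.

**Strand bias.** The hemimethylation index is the absolute per-CpG
difference between strand percentages (a signed top-minus-bottom variant is
kept for directionality); the region-level test is the same paired
mixed-effects machinery applied to top-minus-bottom differences. The
strand-bias cohorts in the tests use 4 donors — the size of a typical
strand-expansion panel in this assay family.

**Clustering.** Cell subtypes are clustered by complete linkage on
Euclidean distances between subtype-average per-CpG methylation vectors
(averaged across donors). Rows are sorted by label before clustering so the
result is invariant to input order; remaining ties break deterministically
by label order. Trees are exported as Newick with merge heights as branch
lengths. Missing per-CpG averages are mean-imputed with a warning.

Female-donor percentages are analysed raw — no X-inactivation correction is
applied anywhere in the pipeline; the `xi_female` mosaic generator exists
for sensitivity analysis only.

## Problem sizes used by the checks

The test suite and the acceptance script run everything at the design's
own scale: 20 clones per group (200 for recovery checks, where the
binomial 3σ band at n = 200 is the stated tolerance), 2,000 null and 500
shifted simulations for calibration, 500 random sequence pairs (≤ 200 nt)
for the alignment oracle, full 2⁶ enumeration for the permutation oracle,
and 50 random point sets for the clustering oracle. One caveat worth
stating honestly: a conjunction of ~500 per-CpG 3σ checks has an
appreciable probability of one boundary exceedance even for a perfectly
calibrated estimator (per-CpG coverage ≈ 99.7%, worst case ≈ 98.6% at
p = 0.007); the acceptance script therefore also reports the *fraction*
of CpGs inside the band.

## Known limitations

* No AB1 chromatogram parsing; input clones are plain FASTA sequences.
* No 5hmC/5mC discrimination — both read as protected C after conversion.
* The aligner assumes amplicon-scale sequences (hundreds of nt); it is
  quadratic and not meant for genome-scale reads.
* Primer validation checks conversion-specificity and CpG overlap, not
  melting temperature or secondary structure.
* The mixed model treats per-CpG percentages as continuous; at very small
  clone counts a binomial GLMM would be more faithful, but percentages are
  the unit this assay family reports and compares.
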