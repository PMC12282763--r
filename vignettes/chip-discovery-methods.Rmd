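---
title: "Methods: sensitive CHIP discovery by meta-calling and three-class classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sensitive CHIP discovery by meta-calling and three-class classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(chipmeta)
```

## The problem

Clonal hematopoiesis of indeterminate potential (CHIP) is the presence of
somatic mutations in leukemia-associated genes, at variant allele
fractions (VAF) of a few percent, in the blood of people without a
hematologic malignancy. At the 30-100x coverage typical of whole-genome
and whole-exome sequencing, a 2-5% clone is supported by only a handful of
reads, and conventional somatic callers -- tuned for specificity -- miss
most of these mutations. `chipmeta` approaches the problem from the
opposite end: call *everything* with any alternative-read evidence, then
let a trained classifier and rule-based refinement separate real clones
from germline variants and artifacts.

## Pipeline model

The pipeline has five stages, each exposed as ordinary functions and
orchestrated by `run_pipeline()`:

1. **Permissive tracking** (`pileup_sites()`, `genotype_candidates()`).
   A single-pass pileup engine scans coordinate-sorted alignments and
   reports every position where at least one counted read carries a
   non-reference base or an indel, together with the evidence attributes
   the classifier will consume (depth, alt and strand counts, mean
   mapping/base quality of alt reads, relative read position, proximity to
   indels). Bases below phred 13 are not counted; at most 1000 reads are
   tallied per position, first-come in coordinate order; duplicate,
   secondary, supplementary and QC-fail reads are excluded. A single
   supporting read is enough to report a candidate -- this permissiveness
   is the source of the ensemble's sensitivity, and its false positives
   are the classifier's job to remove. At multiallelic sites the allele
   with the most supporting reads wins; exact ties are broken by a seeded
   uniform draw so runs are reproducible.

   Comparable permissive-tracking workflows obtain this behavior by
   chaining two external tools (a pileup caller and a genotyper); a
   single engine computing the same candidate sites and attributes in
   one pass is behaviorally equivalent and removes a dependency.

2. **Meta-calling** (`merge_callsets()`). Call sets from the tracker and
   any external callers (VCFs read through `vcfR`, multiallelic rows
   decomposed) are normalized -- multi-nucleotide substitutions split
   into SNVs, indels made parsimonious and left-aligned -- and grouped by
   the canonical variant key. Each merged record carries a *calling
   status*: the number of callers supporting it (1-3 with the default
   two external profiles). Status is consistently the strongest single
   predictor of variant class.

3. **Annotation and featurization** (`classify_consequence()`,
   `build_feature_table()`). A minimal codon-based annotator over a
   transcript table assigns consequences (synonymous through frameshift;
   positions within 2 bp of an intron boundary are essential-splice);
   only function-altering calls are retained. Each retained call becomes
   a fixed-length numeric vector -- 26 features for SNVs, 24 for indels
   (the indel schema drops the substitution-specific features and adds
   the signed indel length). The schema is this package's own
   reconstruction of the feature families known to drive CHIP
   classification -- calling status, per-caller flags, quality metrics,
   genomic context, database overlap -- with the counts pinned at
   26/24. The order is frozen in `inst/extdata/feature_schema.json` and a schema hash is
   embedded in every trained model; prediction refuses mismatched input.

4. **Three-class classification** (`train_classifier()`, `predict()`).
   Gradient-boosted trees (xgboost) or a random forest predict
   CHIP / GERMLINE / ARTIFACT probabilities per variant. Defaults are
   pinned (gbt: 300 trees, depth 6, learning rate 0.1; rf: 500 trees,
   sqrt-features) because tuning was reported to give negligible gains;
   a small k = 5 cross-validated grid is available behind `tune = TRUE`.
   Training deterministically splits 80/20 stratified by class, with
   membership decided by a per-row content hash mixed with the seed, so
   the split is invariant to input row order. Models are trained
   separately per data type (WES / WGS / combined) and variant type, and
   the model bundle records both tags.

5. **Refinement, cohort filtering, credible intervals**
   (`rescue_rules()`, `cohort_filter()`, `chip_posterior()`). Two rescue
   rules recover likely misclassifications: a known-CHIP variant
   detected by at least two callers is flagged `putative_chip_rescued`
   even if predicted non-CHIP; calls above 30% VAF default to germline
   unless they fall in DNMT3A, ASXL1, TET2, PPM1D or JAK2 (where
   germline variation is vanishingly rare), in which case they are
   flagged for review. Cohort-level filtering then removes, in a fixed,
   tallied order: common variants (MAF >= 0.3% in any of four germline
   databases), single-caller calls inside low-complexity regions,
   variants recurring in >= 8% of subjects, sub-2%-VAF calls, and
   non-catalogue variants, with an optional driver-mutation restriction.
   "Low-confidence" in the low-complexity rule is operationalized as
   calling status 1; the recurrence rule counts subjects with *any*
   call. Both choices are configuration-exposed.

## The hierarchical background model

The credible-interval model is this package's committed design, honoring
two stated ingredients -- a hierarchical error model and the CHIP
incidence of a young, healthy reference population as background prior --
and chosen to be verifiable by coverage simulation:

* Per-site sequencing-error Beta(α, β) distributions are fit by the
  method of moments to alt-read fractions across the reference panel,
  with both shapes floored at 0.5 and the mean floored at half a
  pseudocount over the pooled panel depth; sites with fewer than two
  panel observations fall back to a gene-level fit, then a global fit
  (`fit_background()`).
* For an observed site with k alt reads of n, the error component is
  Beta-Binomial(n, α, β); the clone component is Binomial(n, θ) with
  θ ~ Beta(a₀ = 1, b₀ = 1) truncated to (0.005, 0.5) -- uniform over
  detectable clone sizes. The posterior clone probability weighs the two
  marginal likelihoods by the panel incidence π (fraction of panel
  subjects with a retained CHIP call, floored at 1/(2·n_panel)).
* The 95% credible interval for θ is the 2.5/97.5% quantile pair of the
  conjugate truncated Beta(a₀ + k, b₀ + n − k) posterior.

At θ = 0.05 and n = 1000, simulated coverage of the interval is 95-96%
(500 replicates; the test suite asserts 95% ± 2.5%). Alternative
formulations could stratify the incidence prior by gene; all constants
here are exposed in the function signatures.

## What the simulator emulates — and what it does not

`make_reference()` builds a contig of compact single-exon ORFs (plus one
two-exon gene for splice annotation) separated by intergenic sequence
with planted homopolymer and short-tandem-repeat tracts.
`simulate_reads()` emits pre-aligned single-end reads with uniform
starts, i.i.d. substitution errors and high, narrow base qualities;
germline variants are planted by per-read conversion at VAF 0.5/1.0.
`spike_in()` converts each read overlapping a spec independently with
probability equal to the target VAF -- per-read Bernoulli conversion,
not exact count targeting -- so realized VAFs scatter below the target
at low depth, the same behavior reported for read-level spike-in
tooling; sites with depth below m = 2 are skipped and recorded, and a
draw converting zero reads is recorded as a failure so the truth table
always satisfies attempted = spiked + skipped + failed. CHIP-specific
target VAFs are drawn log-normal, calibrated so the median matches the
known-mutation spectrum (12.5% SNVs, 14.8% indels). Mock external
callers are explicit sensitivity curves by VAF bin with an alt-read
floor of 2 and a per-megabase false-positive rate, shaped like real
somatic callers that lose most sub-10%-VAF clones.

The simulator deliberately omits: platform-specific error profiles and
quality-score correlation, PCR duplicates, capture/GC bias, mapping
ambiguity from paralogs, and long repetitive context beyond the planted
tracts. Passing tests therefore demonstrate the *machinery* -- counting,
merging, feature flow, learning, filtering, interval calibration -- not
performance on real cohort data, where artifact structure is richer and
class boundaries are blurrier.

## Study conditions used by the checks

The test suite and `scripts/acceptance.R` run at desk scale, chosen once
as the package's own benchmark conditions: a 1-2 kb reference with 3-4
genes, 20-25 spiked somatic variants and 10-15 germline variants shared
across subjects, 100x depth for calling benchmarks (200x for the
realized-VAF check, 50x for the VAF-spectrum summary), three training
subjects, and the full 13-level uniform VAF series (0.5%, 1-10%, 20%,
30%) plus the CHIP-specific configuration. The batch-arithmetic check
reproduces the 14-configurations-by-21-inputs bookkeeping (294 outputs)
on miniature alignment sets. End-to-end recall of spiked CHIP at
VAF >= 5% and 100x is required to reach 0.8 with recall non-decreasing
across the series within Monte-Carlo tolerance; in practice the small
study sits at 1.0 for every level at or above 2%.

## Numerical and design choices

* Coordinates are 1-based inclusive everywhere in memory (VCF
  convention); BED files convert at the I/O boundary.
* Normalization trims shared suffixes, re-pads through left extension,
  then reduces the shared prefix to a single anchor base; SNVs are fixed
  points; symbolic alleles are rejected. Normalization happens *after*
  multiallelic resolution: the tracker first chooses the winning allele
  at a site, then canonicalizes it, so allele choice is made on raw
  pileup evidence.
* Merging is by exact normalized key (allele-aware); spike-in truth
  matching is position-only, deliberately a different equivalence
  relation, following the spike-in benchmarking convention that a
  recovered position counts regardless of the alternative base.
* The consequence ordinal encoding (noncoding = 0 ... nonsense = 8) is
  arbitrary but frozen; tree models only need determinism. Nine classes
  are distinguished, so the code range runs to 8.
* In-frame indels count as function-altering, as does essential-splice;
  synonymous and noncoding calls are dropped before featurization.
* Catalogue lookups are exact normalized-key matches for SNVs; for
  indels a position + type + length match is required; no fuzzy
  matching is attempted.
* The depth cap selects the first reads in stream order -- deterministic,
  unlike random subsampling.
* Ties in class probability resolve to the first class in the fixed
  CHIP, GERMLINE, ARTIFACT order.
* The feature-schema hash is a 32-bit FNV-1a checksum -- it guards
  against accidental train/predict drift, not adversaries.
* Indel spike-in into an already-gapped read is skipped rather than
  re-gapped twice; at desk scale specs are spaced so this is rare, and
  the truth table records realized conversions either way.

## Known limitations

* The annotator handles one transcript per locus, no UTRs, and does not
  produce HGVS names; multi-transcript consequence ranking is out of
  scope.
* The tracker performs no local reassembly or base-quality
  recalibration, so complex indels in repeats inherit alignment errors.
* Classifier performance numbers on synthetic data are upper bounds; the
  synthetic class structure is cleaner than real cohort data.
* The background model pools strand and context; a real panel-of-normals
  would stratify further.
* CRAM input, structural variants, phasing and star alleles are
  unsupported.
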