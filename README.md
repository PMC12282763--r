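# chipmeta

Sensitive discovery of clonal-hematopoiesis (CHIP) mutations from
standard-depth WES/WGS alignments, in R.

## The problem

CHIP — clonal hematopoiesis of indeterminate potential — is the presence
of somatic mutations in leukemia-associated genes (DNMT3A, TET2, ASXL1,
TP53, …) at ≥ 2% variant allele fraction (VAF) in the blood of people
without hematologic malignancy. At 30–100× coverage a 2–5% clone leaves
only a few supporting reads, and specificity-tuned somatic callers miss
most of them. `chipmeta` inverts the trade-off:

1. a **permissive tracker** reports every position with any
   alternative-read evidence (down to a single read), with pileup
   evidence attributes;
2. a **meta-caller** merges the tracker with external caller VCFs and
   assigns each variant a *calling status* — the number of supporting
   callers;
3. functional variants are **featurized** (26 features for SNVs, 24 for
   indels: status, quality metrics, sequence context, database overlap)
   and classified into **CHIP / GERMLINE / ARTIFACT** by gradient-boosted
   trees or a random forest;
4. **rescue rules** recover known-CHIP variants supported by ≥ 2 callers
   and resolve the 30%-VAF germline boundary (privileged driver genes are
   flagged for review instead);
5. a **hierarchical Bayesian model** — Beta-Binomial sequencing error fit
   from a healthy reference panel vs. a Binomial clone with a truncated
   Beta prior on clone VAF θ ∈ (0.005, 0.5), mixed by the panel's CHIP
   incidence π — yields a posterior clone probability
   P(clone | k, n) = π·L₁ / (π·L₁ + (1−π)·L₀) and a 95% credible interval
   for θ from the truncated Beta(1 + k, 1 + n − k) posterior.

A spike-in read simulator (reference + gene models, reads, per-read
Bernoulli spike-in at target VAFs, mock external callers, truth tables)
makes every stage benchmarkable without external data.

## Worked example

```r
library(chipmeta)

rb    <- make_reference(n_genes = 3, gene_len = 210,
                        intergenic_len = 100, seed = 21)
specs <- make_variant_specs(rb, n_chip = 20, n_germline = 10, seed = 22)
rt    <- make_study_resources(rb, specs$somatic, specs$germline, seed = 23)

# train SNV and indel classifiers on three simulated, truth-labeled
# subjects
models <- lapply(c(SNV = "SNV", INDEL = "INDEL"), function(vt) {
  tr <- build_training_table(rb, rt, specs, n_subjects = 3,
                             variant_type = vt, seed = 30)
  train_classifier(tr, train_config("gbt", "WGS", vt, seed = 1))
})

# a fresh subject spiked at 10% VAF, run end to end
sub <- simulate_subject(rb, specs, chip_vaf = 0.10, mean_depth = 100,
                        seed = 77)
res <- run_pipeline(sub$aln, rb$reference, rb$genes, rt,
                    models = models, seed = 4)
#> [chipmeta] track         228 records
#> [chipmeta] merge         228 records
#> [chipmeta] featurize     133 records
#> [chipmeta] predict       133 records
#> [chipmeta] refine         19 records

spikein_recall_precision(res$chip, sub$chip_truth, rb$reference)
#> $recall            [1] 1
#> $precision         [1] 0.7894737
#> $n_truth           [1] 15
#> $n_recovered       [1] 15
#> $n_false_positive  [1] 4
```

The stage log reads: the tracker reported 228 candidate positions
(mostly sequencing-error artifacts — by design), 133 survived the
functional-consequence filter, and 19 calls remained after
classification and refinement. All 15 successfully spiked somatic
variants were recovered (recall 1) alongside 4 extra calls
(precision 0.79) — at desk scale the classifier removes essentially all
error-driven candidates. Counts are deterministic given the seeds shown;
the acceptance script below recomputes comparable quantities under any
seed.

Classifier evaluation follows the standard one-vs-rest reductions:

```r
cm <- confusion(predict(m, test_set)$label, test_set$label)
metrics_from_confusion(cm, "CHIP")   # precision, recall, specificity,
                                     # F1 = 2PR/(P+R), accuracy
```

## Layout

```
R/                  variant model, tracker, meta-caller, annotation,
                    classifier, refinement + CI, simulator, pipeline
inst/extdata/       frozen feature schema (JSON)
tests/testthat/     unit, property and acceptance suites
scripts/acceptance.R
vignettes/chip-discovery-methods.Rmd   the methods notes
exec/chipmeta       command-line front end
```
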