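#' Run the full CHIP-discovery pipeline on one subject
#'
#' Stage order: permissive tracking, merging with external call sets,
#' consequence annotation and functional filtering, feature extraction,
#' three-class prediction, rule-based rescue, and (when a background model
#' is supplied) credible-interval estimation for the CHIP set. Per-stage
#' record counts are reported via `message()` and returned; identical
#' inputs, configuration and seeds give identical output.
#'
#' @param aln alignment data.frame, or a path to a SAM/BAM file.
#' @param reference named list of contig sequences, or a FASTA path.
#' @param genes gene-model data.frame, or a TSV path.
#' @param rt a [resource_tables()].
#' @param models named list with `SNV` and/or `INDEL` [train_classifier()]
#'   models.
#' @param external named list of external call sets (call-record
#'   data.frames, or VCF paths).
#' @param region optional `list(chrom=, start=, end=)`.
#' @param pileup_cfg a [pileup_config()].
#' @param refine_cfg a [refinement_config()].
#' @param background optional `background_model` from [fit_background()].
#' @param min_alt_reads tracker alt-read floor.
#' @param seed integer seed (multiallelic tie-breaks).
#' @param out_vcf optional path for the final VCF.
#' @return list: `calls` (annotated, predicted, refined data.frame),
#'   `chip` (the final CHIP subset), `merged`, `stage_counts`.
#' @export
run_pipeline <- function(aln, reference, genes, rt, models,
                         external = list(), region = NULL,
                         pileup_cfg = pileup_config(),
                         refine_cfg = refinement_config(),
                         background = NULL, min_alt_reads = 1L, seed = 1L,
                         out_vcf = NULL) {
  if (is.character(aln)) aln <- read_alignments(aln)
  if (is.character(reference)) reference <- read_reference_fasta(reference)
  if (is.character(genes)) genes <- read_gene_model(genes)
  external <- lapply(external, function(x)
    if (is.character(x)) read_caller_vcf(x, "EXTERNAL") else x)
  counts <- c()
  note <- function(stage, n) {
    message(sprintf("[chipmeta] %-10s %6d records", stage, n))
    counts[[stage]] <<- n
  }

  tracked <- track_variants(aln, reference, region, pileup_cfg,
                            min_alt_reads, seed)
  note("track", nrow(tracked))
  callsets <- c(list(TRACKER = tracked), external)
  merged <- merge_callsets(callsets, reference)
  note("merge", nrow(merged))
  caller_ids <- unique(c("TRACKER", names(external),
                         c("CALLER_A", "CALLER_B")))[1:3]
  ft <- build_feature_table(merged, reference, genes, rt, aln = aln,
                            cfg = pileup_cfg, caller_ids = caller_ids)
  note("featurize", nrow(ft$calls))

  calls <- ft$calls
  calls$label <- rep(NA_character_, nrow(calls))
  calls$prob_chip <- calls$prob_germline <- calls$prob_artifact <-
    rep(NA_real_, nrow(calls))
  for (vt in c("SNV", "INDEL")) {
    idx <- which(calls$variant_class == vt)
    if (!length(idx)) next
    model <- models[[vt]]
    if (is.null(model)) {
      calls$label[idx] <- "ARTIFACT"   # no model for this type: do not call
      next
    }
    fm <- if (vt == "SNV") ft$snv else ft$indel
    pr <- predict(model, as.data.frame(fm))
    calls$label[idx] <- pr$label
    calls$prob_chip[idx] <- pr$prob_chip
    calls$prob_germline[idx] <- pr$prob_germline
    calls$prob_artifact[idx] <- pr$prob_artifact
  }
  note("predict", nrow(calls))

  calls <- rescue_rules(calls, rt, refine_cfg)
  chip <- chip_set(calls)
  note("refine", nrow(chip))

  calls$posterior_chip <- rep(NA_real_, nrow(calls))
  calls$ci95_lo <- calls$ci95_hi <- rep(NA_real_, nrow(calls))
  if (!is.null(background) && nrow(chip)) {
    for (i in which(rownames(calls) %in% rownames(chip))) {
      bgab <- background_at(background, calls$chrom[i], calls$pos[i],
                            calls$gene[i])
      cp <- chip_posterior(calls$alt_count[i], calls$depth[i], bgab,
                           background$pi)
      calls$posterior_chip[i] <- cp$posterior_chip
      calls$ci95_lo[i] <- cp$ci95[1]; calls$ci95_hi[i] <- cp$ci95[2]
    }
    chip <- chip_set(calls)
    note("ci", nrow(chip))
  }

  if (!is.null(out_vcf)) {
    calls$pprob <- sprintf("%.4g,%.4g,%.4g", calls$prob_chip,
                           calls$prob_germline, calls$prob_artifact)
    write_calls_vcf(calls, vapply(reference, nchar, integer(1)), out_vcf)
  }
  list(calls = calls, chip = chip, merged = merged,
       stage_counts = unlist(counts))
}

#' The final CHIP subset of refined predictions
#'
#' CHIP-labelled calls not reassigned to germline by the VAF rule, plus
#' calls rescued or flagged for VAF review by the refinement rules.
#'
#' @param calls data.frame with `label` and `refined_flag`.
#' @export
chip_set <- function(calls) {
  keep <- (calls$label == "CHIP" & calls$refined_flag == "none") |
    calls$refined_flag %in% c("putative_chip_rescued",
                              "putative_chip_vaf_review")
  calls[keep, , drop = FALSE]
}

#' Load a pipeline configuration file
#'
#' YAML key-value file naming the input paths (`alignments`, `reference`,
#' `genes`, resource tables, `model_snv`, `model_indel`), thresholds
#' (pileup, refinement, cohort-filter sections) and `seed`. Referenced
#' files must exist.
#'
#' @param path YAML file.
#' @return validated configuration list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (k in intersect(c("alignments", "reference", "genes", "model_snv",
                        "model_indel"), names(cfg))) {
    if (!file.exists(cfg[[k]]))
      stopf("config %s: file not found: %s", k, cfg[[k]])
  }
  if (is.null(cfg$seed)) cfg$seed <- 1L
  cfg
}
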