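#' Draw the study-level variant specifications
#'
#' One fixed set of somatic (CHIP-like, function-altering, placed inside
#' coding exons) and germline variant specs shared by every simulated
#' subject -- mirroring a spike-in benchmark where the same known
#' mutations are inserted into each input alignment set.
#'
#' @param rb a [make_reference()] bundle.
#' @param n_chip number of somatic spike-in specs.
#' @param indel_fraction fraction of somatic specs that are indels.
#' @param n_germline number of germline variants.
#' @param read_len read length (germline placement margin).
#' @param seed integer seed.
#' @return list: `somatic` (`chrom,pos,ref,alt`), `germline` (plus
#'   `zygosity`).
#' @export
make_variant_specs <- function(rb, n_chip = 25L, indel_fraction = 0.25,
                               n_germline = 15L, read_len = 80L,
                               seed = 1L) {
  ref <- rb$reference
  contig <- names(ref)[1]
  L <- nchar(ref[[contig]])
  with_seed(seed, {
    # coding positions, away from exon edges so indels stay inside
    cds_pos <- unlist(lapply(seq_len(nrow(rb$genes)), function(i) {
      ex <- exon_list(rb$genes[i, , drop = FALSE])
      unlist(mapply(function(s, e) seq(s + 3L, e - 6L), ex$start, ex$end,
                    SIMPLIFY = FALSE))
    }))
    somatic_pos <- sort(sample(cds_pos, n_chip))
    # enforce spacing so specs do not collide on the same reads' alleles
    keep <- c(TRUE, diff(somatic_pos) >= 10L)
    somatic_pos <- somatic_pos[keep]
    germ_cand <- setdiff(seq(read_len, L - read_len),
                         outer(somatic_pos, -8:8, `+`))
    germ_pos <- sort(sample(germ_cand, n_germline))
    base_at <- function(p) substring(ref[[contig]], p, p)
    mk_spec <- function(pos, indel_frac) {
      do.call(rbind, lapply(pos, function(p) {
        rb1 <- base_at(p)
        if (runif(1) < indel_frac) {
          if (runif(1) < 0.5) {        # insertion
            ins <- paste(sample(c("A", "C", "G", "T"),
                                sample(1:3, 1), replace = TRUE),
                         collapse = "")
            data.frame(chrom = contig, pos = p, ref = rb1,
                       alt = paste0(rb1, ins), stringsAsFactors = FALSE)
          } else {                      # deletion of 1-3 bp
            dl <- sample(1:3, 1)
            data.frame(chrom = contig, pos = p,
                       ref = substring(ref[[contig]], p, p + dl),
                       alt = rb1, stringsAsFactors = FALSE)
          }
        } else {
          data.frame(chrom = contig, pos = p, ref = rb1,
                     alt = sample(setdiff(c("A", "C", "G", "T"), rb1), 1),
                     stringsAsFactors = FALSE)
        }
      }))
    }
    somatic <- mk_spec(somatic_pos, indel_fraction)
    # known CHIP mutations are function-altering; swap any synonymous SNV
    # for a missense/nonsense alternative at or next to the same site
    # (four-fold degenerate third codon positions admit none in place)
    for (i in seq_len(nrow(somatic))) {
      if (nchar(somatic$ref[i]) != 1L || nchar(somatic$alt[i]) != 1L) next
      cons <- classify_consequence(
        gvariant(somatic$chrom[i], somatic$pos[i], somatic$ref[i],
                 somatic$alt[i]), rb$genes, ref)
      if (cons %in% functional_classes()) next
      found <- FALSE
      for (off in c(0L, -1L, -2L, 1L, 2L)) {
        p <- somatic$pos[i] + off
        rb1 <- base_at(p)
        for (b in setdiff(c("A", "C", "G", "T"), rb1)) {
          if (classify_consequence(gvariant(contig, p, rb1, b),
                                   rb$genes, ref) %in%
              functional_classes()) {
            somatic$pos[i] <- p; somatic$ref[i] <- rb1; somatic$alt[i] <- b
            found <- TRUE
            break
          }
        }
        if (found) break
      }
    }
    germline <- mk_spec(germ_pos, 0)
    germline$zygosity <- sample(c("het", "hom"), nrow(germline),
                                replace = TRUE, prob = c(0.6, 0.4))
    list(somatic = somatic, germline = germline)
  })
}

#' Simulate one subject's alignments with somatic and germline variants
#'
#' Plants the study's germline variants, then spikes its somatic specs at
#' the requested target VAFs. This is the substrate every benchmark in the
#' package runs on.
#'
#' @param rb a [make_reference()] bundle.
#' @param specs a [make_variant_specs()] result.
#' @param chip_vaf `"chip"` for CHIP-like log-normal targets (drawn per
#'   subject), or a single numeric target VAF applied to all specs.
#' @param mean_depth,read_len,err_rate read-simulation parameters.
#' @param seed integer seed.
#' @return list: `aln`, `chip_truth`, `germline_truth`, `specs`.
#' @export
simulate_subject <- function(rb, specs, chip_vaf = "chip",
                             mean_depth = 100, read_len = 80L,
                             err_rate = 0.002, seed = 1L) {
  ref <- rb$reference
  somatic <- specs$somatic
  somatic$target_vaf <- if (identical(chip_vaf, "chip"))
    chip_vaf_targets(nrow(somatic), "SNV", seed = seed + 7L)
  else as.numeric(chip_vaf)
  sim <- simulate_reads(ref, mean_depth = mean_depth,
                        read_len = read_len, err_rate = err_rate,
                        seed = seed + 13L, germline = specs$germline)
  sp <- spike_in(sim$aln, somatic, ref, m = 2L, seed = seed + 29L)
  list(aln = sp$aln, chip_truth = sp$truth,
       germline_truth = sim$germline, specs = somatic)
}

#' Build resource tables for a simulated study
#'
#' The germline databases carry the planted germline variants (population
#' MAFs above the common-variant cutoff), the somatic catalogue and
#' known-CHIP list carry the spiked variants, the driver list covers the
#' reference's genes, and the low-complexity/STR intervals cover the
#' planted repeat tracts.
#'
#' @param rb a [make_reference()] bundle.
#' @param chip_specs data.frame of somatic specs (`chrom,pos,ref,alt`).
#' @param germline_specs data.frame of germline specs.
#' @param seed integer seed (MAF and catalogue-count draws).
#' @return a [resource_tables()].
#' @export
make_study_resources <- function(rb, chip_specs, germline_specs,
                                 seed = 1L) {
  # store all variant-keyed resources under normalized representations so
  # lookups collide with normalized call keys
  chip_specs <- normalize_call_frame(
    chip_specs[, c("chrom", "pos", "ref", "alt")], rb$reference)
  with_seed(seed, {
    gvars <- normalize_call_frame(
      germline_specs[, c("chrom", "pos", "ref", "alt")], rb$reference)
    gdbs <- lapply(1:4, function(j) {
      df <- gvars
      df$maf <- round(runif(nrow(df), 0.01, 0.45), 4)
      # each database observes most, not all, variants
      df[runif(nrow(df)) < 0.9, , drop = FALSE]
    })
    cosmic <- chip_specs[, c("chrom", "pos", "ref", "alt")]
    cosmic$sample_count <- 1L + rpois(nrow(cosmic), 10)
    lc <- rb$repeats[, c("chrom", "start", "end")]
    resource_tables(
      germline = gdbs, cosmic = cosmic,
      known_chip = chip_specs[, c("chrom", "pos", "ref", "alt")],
      driver_genes = rb$genes$gene,
      driver_mutations = chip_specs[, c("chrom", "pos", "ref", "alt")],
      low_complexity = lc,
      str_regions = rb$repeats[rb$repeats$kind == "str",
                               c("chrom", "start", "end")])
  })
}

#' Default mock external-caller profiles
#'
#' Two profiles shaped like real somatic callers: both require two or more
#' supporting reads; caller A is conservative (misses most sub-10% VAF
#' clones, few false calls), caller B is moderately sensitive with more
#' false calls.
#'
#' @return named list of two [mock_caller_profile()]s.
#' @export
default_caller_profiles <- function() {
  list(
    CALLER_A = mock_caller_profile(
      "CALLER_A",
      sens = data.frame(vaf_max = c(0.05, 0.10, 1.00),
                        p = c(0.10, 0.35, 0.92)),
      fp_rate = 50, min_alt_reads = 2L),
    CALLER_B = mock_caller_profile(
      "CALLER_B",
      sens = data.frame(vaf_max = c(0.05, 0.10, 1.00),
                        p = c(0.30, 0.60, 0.95)),
      fp_rate = 150, min_alt_reads = 2L))
}

#' Track, merge, featurize and truth-label one simulated subject
#'
#' Runs the calling front half of the pipeline (tracker plus mock external
#' callers), featurizes the merged calls, and attaches actual class labels
#' by position against the spike-in and germline truth tables (position
#' matching, as ground-truth benchmarking prescribes): spiked positions
#' are CHIP, planted germline positions GERMLINE, everything else
#' ARTIFACT.
#'
#' @param sub a [simulate_subject()] result.
#' @param rb the [make_reference()] bundle used to simulate it.
#' @param rt a [resource_tables()].
#' @param profiles list of [mock_caller_profile()]s.
#' @param seed integer seed.
#' @param functional_only apply the functional-effect filter.
#' @return list: `calls` (with `label` column), `snv`/`indel` feature
#'   matrices, `snv_labels`/`indel_labels`, `callsets`, `merged`.
#' @export
labeled_call_table <- function(sub, rb, rt,
                               profiles = default_caller_profiles(),
                               seed = 1L, functional_only = TRUE) {
  ref <- rb$reference
  truth_all <- rbind(sub$chip_truth[, c("chrom", "pos", "ref", "alt",
                                        "target_vaf", "vtype", "status",
                                        "reason", "depth",
                                        "reads_converted", "realized_vaf")],
                     sub$germline_truth[, c("chrom", "pos", "ref", "alt",
                                            "target_vaf", "vtype", "status",
                                            "reason", "depth",
                                            "reads_converted",
                                            "realized_vaf")])
  tracked <- track_variants(sub$aln, ref, seed = seed)
  callsets <- c(list(TRACKER = tracked),
                lapply(seq_along(profiles), function(i)
                  mock_caller(truth_all, profiles[[i]], sub$aln, ref,
                              seed = seed + 17L * i)))
  names(callsets) <- c("TRACKER", names(profiles))
  merged <- merge_callsets(callsets, ref)
  ft <- build_feature_table(merged, ref, rb$genes, rt, aln = sub$aln,
                            functional_only = functional_only,
                            caller_ids = c("TRACKER", names(profiles)))
  calls <- ft$calls
  # match on normalized anchors: indel truth positions can shift under
  # left-alignment
  norm_pos <- function(tt) {
    n <- suppressWarnings(
      normalize_call_frame(tt[, c("chrom", "pos", "ref", "alt")], ref))
    unique(c(paste(tt$chrom, tt$pos), paste(n$chrom, n$pos)))
  }
  chip_pos <- norm_pos(sub$chip_truth)
  germ_pos <- norm_pos(sub$germline_truth)
  callpos <- paste(calls$chrom, calls$pos)
  calls$label_truth <- ifelse(callpos %in% chip_pos, "CHIP",
                              ifelse(callpos %in% germ_pos, "GERMLINE",
                                     "ARTIFACT"))
  list(calls = calls, snv = ft$snv, indel = ft$indel,
       snv_labels = calls$label_truth[calls$variant_class == "SNV"],
       indel_labels = calls$label_truth[calls$variant_class == "INDEL"],
       callsets = callsets, merged = merged)
}

#' Assemble a labeled training table from simulated subjects
#'
#' Concatenates [labeled_call_table()] features across subjects into the
#' data.frame [train_classifier()] consumes.
#'
#' @param rb reference bundle.
#' @param rt resource tables.
#' @param specs a [make_variant_specs()] result (shared across subjects).
#' @param n_subjects number of simulated subjects.
#' @param variant_type `"SNV"` or `"INDEL"`.
#' @param seed integer seed.
#' @param ... passed to [simulate_subject()].
#' @return data.frame with `label` plus the [feature_schema()] columns.
#' @export
build_training_table <- function(rb, rt, specs, n_subjects = 3L,
                                 variant_type = c("SNV", "INDEL"),
                                 seed = 1L, ...) {
  variant_type <- match.arg(variant_type)
  rows <- list()
  for (s in seq_len(n_subjects)) {
    sub <- simulate_subject(rb, specs, seed = seed + 1000L * s, ...)
    lab <- labeled_call_table(sub, rb, rt, seed = seed + 1000L * s + 1L)
    m <- if (variant_type == "SNV") lab$snv else lab$indel
    y <- if (variant_type == "SNV") lab$snv_labels else lab$indel_labels
    if (nrow(m)) {
      df <- as.data.frame(m)
      df$label <- factor(y, levels = chip_classes())
      rows[[s]] <- df
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, c("label", feature_schema(variant_type))]
}
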