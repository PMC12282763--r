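# Reference generation, read simulation, spike-in, mock callers and
# benchmark metrics.

test_that("reference generation is deterministic and plants valid ORFs", {
  r1 <- make_reference(seed = 17)
  r2 <- make_reference(seed = 17)
  expect_identical(r1$reference$chr1, r2$reference$chr1)
  expect_false(identical(r1$reference$chr1,
                         make_reference(seed = 18)$reference$chr1))
  # every CDS translates start-to-stop without internal stops
  for (i in seq_len(nrow(r1$genes))) {
    ex <- chipmeta:::exon_list(r1$genes[i, , drop = FALSE])
    cds <- paste(substring(r1$reference$chr1, ex$start, ex$end),
                 collapse = "")
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
    expect_identical(substr(aa, 1, 1), "M")
    expect_identical(substr(aa, nchar(aa), nchar(aa)), "*")
    expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1)))
  }
  # planted repeat tracts are present
  expect_identical(substr(r1$reference$chr1, 11, 18), "AAAAAAAA")
  expect_identical(substr(r1$reference$chr1, 31, 42), "ACACACACACAC")
})

test_that("intergenic GC tracks the requested content on a long contig", {
  rb <- make_reference(n_genes = 1L, gene_len = 300L,
                       intergenic_len = 50000L, gc = 0.5, seed = 3)
  bases <- strsplit(rb$reference$chr1, "")[[1]]
  gc <- mean(bases %in% c("G", "C"))
  expect_lt(abs(gc - 0.5), 0.02)
  rb2 <- make_reference(n_genes = 1L, gene_len = 300L,
                        intergenic_len = 20000L, gc = 0.7, seed = 3)
  gc2 <- mean(strsplit(rb2$reference$chr1, "")[[1]] %in% c("G", "C"))
  expect_gt(gc2, 0.6)
})

test_that("error-free reads match the reference and coverage tracks the target", {
  rb <- fixture_ref()
  sim <- simulate_reads(rb$reference, mean_depth = 100, read_len = 100L,
                        err_rate = 0, seed = 6)
  aln <- sim$aln
  expect_false(is.unsorted(aln$pos))
  for (i in sample.int(nrow(aln), 40)) {
    expect_identical(aln$seq[i],
                     substr(rb$reference$chr1, aln$pos[i],
                            aln$pos[i] + nchar(aln$seq[i]) - 1L))
  }
  L <- nchar(rb$reference$chr1)
  mean_cov <- nrow(aln) * 100 / L
  expect_lt(abs(mean_cov - 100), 5)
  # with errors, the tracker sees mismatches at roughly the error rate
  sim2 <- simulate_reads(rb$reference, mean_depth = 50, read_len = 100L,
                         err_rate = 0.01, seed = 6)
  sites <- pileup_sites(sim2$aln, rb$reference)
  expect_gt(nrow(sites), 0L)
})

test_that("planted heterozygous variants read out near 50% VAF", {
  rb <- fixture_ref()
  g <- data.frame(chrom = "chr1", pos = c(300L, 900L),
                  ref = substring(rb$reference$chr1, c(300, 900), c(300, 900)),
                  alt = NA, zygosity = c("het", "hom"))
  g$alt <- vapply(g$ref, function(b)
    setdiff(c("A", "C", "G", "T"), b)[1], character(1))
  sim <- simulate_reads(rb$reference, mean_depth = 120, read_len = 80L,
                        err_rate = 0, seed = 19, germline = g)
  tr <- sim$germline
  expect_identical(tr$status, c("spiked", "spiked"))
  het <- tr[tr$zygosity == "het", ]
  bounds <- qbinom(c(0.005, 0.995), het$depth, 0.5) / het$depth
  expect_gte(het$realized_vaf, bounds[1])
  expect_lte(het$realized_vaf, bounds[2])
  expect_identical(tr$realized_vaf[tr$zygosity == "hom"], 1)
})

test_that("the uniform VAF series is exactly the 13 prescribed levels", {
  v <- vaf_series()
  expect_length(v, 13L)
  expect_identical(v[1], 0.005)
  expect_identical(v[13], 0.30)
  expect_identical(v[2:11], seq(0.01, 0.10, by = 0.01))
  expect_true(all(diff(v) > 0))
})

test_that("CHIP-like VAF draws center on the known-mutation medians", {
  v_snv <- chip_vaf_targets(20000, "SNV", seed = 2)
  v_ind <- chip_vaf_targets(20000, "INDEL", seed = 2)
  expect_lt(abs(median(v_snv) - 0.125), 0.01)
  expect_lt(abs(median(v_ind) - 0.148), 0.012)
  expect_true(all(v_snv >= 0.005 & v_snv <= 0.6))
})

test_that("spike-in respects the minimum-depth rule and records skips", {
  rb <- fixture_ref(); ref <- rb$reference
  aln <- mk_read(100L, substr(ref$chr1, 100L, 149L))   # single read
  spec <- data.frame(chrom = "chr1", pos = 120L,
                     ref = substr(ref$chr1, 120L, 120L),
                     alt = setdiff(c("A", "C", "G", "T"),
                                   substr(ref$chr1, 120L, 120L))[1],
                     target_vaf = 1.0)
  sp <- spike_in(aln, spec, ref, m = 2L, seed = 1)
  expect_identical(sp$truth$status, "skipped")
  expect_identical(sp$truth$reason, "depth < m")
  expect_identical(sp$aln$seq, aln$seq)     # untouched
  # m = 1 converts the lone read at target 1.0
  sp1 <- spike_in(aln, spec, ref, m = 1L, seed = 1)
  expect_identical(sp1$truth$status, "spiked")
  expect_identical(sp1$truth$realized_vaf, 1)
})

test_that("a REF mismatch fails the spec but the run continues", {
  rb <- fixture_ref(); ref <- rb$reference
  sim <- simulate_reads(ref, mean_depth = 30, read_len = 60L,
                        err_rate = 0, seed = 2)
  b <- substr(ref$chr1, 500L, 500L)
  wrong <- setdiff(c("A", "C", "G", "T"), b)[1]
  specs <- data.frame(chrom = "chr1", pos = c(500L, 700L),
                      ref = c(wrong, substr(ref$chr1, 700L, 700L)),
                      alt = c(b, setdiff(c("A", "C", "G", "T"),
                                         substr(ref$chr1, 700L, 700L))[1]),
                      target_vaf = 1.0)
  sp <- spike_in(sim$aln, specs, ref, seed = 3)
  expect_identical(sp$truth$status, c("failed", "spiked"))
  expect_match(sp$truth$reason[1], "REF mismatch")
})

test_that("target VAF 1.0 converts every overlapping read", {
  rb <- fixture_ref(); ref <- rb$reference
  sim <- simulate_reads(ref, mean_depth = 40, read_len = 60L,
                        err_rate = 0, seed = 4)
  p <- 650L
  b <- substr(ref$chr1, p, p)
  spec <- data.frame(chrom = "chr1", pos = p, ref = b,
                     alt = setdiff(c("A", "C", "G", "T"), b)[1],
                     target_vaf = 1.0)
  sp <- spike_in(sim$aln, spec, ref, seed = 5)
  expect_identical(sp$truth$reads_converted, sp$truth$depth)
  expect_identical(sp$truth$realized_vaf, 1)
})

test_that("truth bookkeeping conserves attempted = spiked + skipped + failed", {
  rb <- fixture_ref(); ref <- rb$reference
  sim <- simulate_reads(ref, mean_depth = 20, read_len = 60L,
                        err_rate = 0, seed = 7)
  specs <- fixture_specs()$somatic
  specs$target_vaf <- 0.02                  # low: zero-conversion failures
  sp <- spike_in(sim$aln, specs, ref, seed = 8)
  tt <- table(factor(sp$truth$status,
                     levels = c("spiked", "skipped", "failed")))
  expect_identical(sum(tt), nrow(specs))
  expect_true(all(sp$truth$reads_converted[sp$truth$status == "spiked"] >= 1L))
  expect_true(all(sp$truth$reason[sp$truth$status != "spiked"] != ""))
})

test_that("realized VAFs sit within binomial bounds of the target", {
  rb <- fixture_ref(); ref <- rb$reference
  sim <- simulate_reads(ref, mean_depth = 200, read_len = 80L,
                        err_rate = 0, seed = 9)
  specs <- fixture_specs()$somatic
  specs$target_vaf <- 0.10
  sp <- spike_in(sim$aln, specs, ref, seed = 10)
  spk <- sp$truth[sp$truth$status == "spiked", ]
  expect_gt(nrow(spk), 15L)
  lo <- qbinom(0.005, spk$depth, 0.10); hi <- qbinom(0.995, spk$depth, 0.10)
  expect_true(all(spk$reads_converted >= lo & spk$reads_converted <= hi))
})

test_that("verification recounts every spiked variant and flags none as defects", {
  sub <- fixture_subject()
  rb <- fixture_ref()
  ver <- verify_spikein(sub$aln, sub$chip_truth, rb$reference)
  expect_identical(nrow(ver), sum(sub$chip_truth$status == "spiked"))
  expect_false(any(ver$defect))
  expect_true(all(ver$observed_alt >= 1L))
  # observation equals the conversion record at error-free base quality
  expect_true(all(abs(ver$observed_vaf - ver$realized_vaf) < 0.15))
})

test_that("a perfect mock caller reproduces the observable truth and respects its floor", {
  sub <- fixture_subject(); rb <- fixture_ref()
  perfect <- mock_caller_profile("P", sens = data.frame(vaf_max = 1, p = 1),
                                 fp_rate = 0, min_alt_reads = 1L)
  calls <- mock_caller(sub$chip_truth, perfect, sub$aln, rb$reference,
                       seed = 2)
  spk <- sub$chip_truth[sub$chip_truth$status == "spiked", ]
  expect_identical(nrow(calls), nrow(spk))
  expect_setequal(calls$pos, spk$pos)
  floor2 <- mock_caller_profile("P2", sens = data.frame(vaf_max = 1, p = 1),
                                fp_rate = 0, min_alt_reads = 2L)
  calls2 <- mock_caller(sub$chip_truth, floor2, sub$aln, rb$reference,
                        seed = 2)
  expect_identical(nrow(calls2), sum(spk$reads_converted >= 2L))
})

test_that("mock-caller sensitivity shapes recall by VAF bin", {
  rb <- fixture_ref(); ref <- rb$reference
  # synthetic truth: 400 low-VAF and 400 high-VAF spiked records
  truth <- data.frame(chrom = "chr1", pos = seq_len(800), ref = "A",
                      alt = "T", target_vaf = 0.1, vtype = "SNV",
                      status = "spiked", reason = "",
                      depth = 100L, reads_converted = rep(c(3L, 20L), 400),
                      realized_vaf = rep(c(0.03, 0.20), 400))
  prof <- mock_caller_profile("M", sens = data.frame(
    vaf_max = c(0.05, 0.10, 1), p = c(0.1, 0.5, 0.9)), fp_rate = 0)
  aln <- mk_read(1L, strrep("A", 50))
  calls <- mock_caller(truth, prof, aln, list(chr1 = strrep("A", 900)),
                       seed = 3)
  lo <- mean(truth$pos[truth$realized_vaf < 0.1] %in% calls$pos)
  hi <- mean(truth$pos[truth$realized_vaf >= 0.1] %in% calls$pos)
  expect_lt(lo, hi)
  expect_lt(abs(lo - 0.1), 0.06)            # binomial bounds, n = 400
  expect_lt(abs(hi - 0.9), 0.06)
})

test_that("recall and precision follow the position-only ground-truth rule", {
  truth <- data.frame(chrom = "chr1", pos = 1:10 * 100L, ref = "A",
                      alt = "T", status = c(rep("spiked", 10)))
  calls <- data.frame(chrom = "chr1",
                      pos = c(1:8 * 100L, 55L, 66L, 77L),
                      ref = "A", alt = c(rep("G", 8), "T", "T", "T"))
  rp <- spikein_recall_precision(calls, truth)
  expect_equal(rp$recall, 0.8)
  expect_equal(rp$precision, 8 / 11)
  # a call with a different alt at a truth position still counts (row 1-8
  # carry alt G against truth T above)
  expect_identical(rp$n_recovered, 8L)
  # perfect recovery
  perfect <- data.frame(chrom = "chr1", pos = 1:10 * 100L, ref = "A",
                        alt = "C")
  expect_equal(spikein_recall_precision(perfect, truth)$recall, 1)
  # skipped truths leave the denominator
  truth2 <- truth; truth2$status[1:5] <- "skipped"
  rp2 <- spikein_recall_precision(perfect, truth2)
  expect_identical(rp2$n_truth, 5L)
  expect_equal(rp2$recall, 1)
})

test_that("synthetic feature tables honor class fractions and the schema", {
  tab <- synthetic_feature_table(1000, class_fractions = c(CHIP = 0.2,
                                                           GERMLINE = 0.3,
                                                           ARTIFACT = 0.5),
                                 separation = 1, seed = 5)
  cnt <- table(tab$label)
  expect_lte(abs(cnt[["CHIP"]] - 200L), 1L)
  expect_lte(abs(cnt[["GERMLINE"]] - 300L), 1L)
  expect_identical(names(tab)[-1], feature_schema("SNV"))
  expect_true(all(abs(tab$vaf - tab$alt_count / tab$depth) < 1e-12))
  ti <- synthetic_feature_table(200, separation = 1, seed = 5,
                                variant_type = "INDEL")
  expect_identical(names(ti)[-1], feature_schema("INDEL"))
})
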