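# Consequence annotation, sequence context, and feature-vector assembly.

# toy single-gene reference with a hand-written CDS:
#   ATG GAT CAG TTC CCA TAA  (M D Q F P *)
toy_gene <- function() {
  cds <- "ATGGATCAGTTCCCATAA"
  ref <- list(chr1 = paste0(strrep("T", 10), cds, strrep("G", 10)))
  genes <- data.frame(transcript = "T1", gene = "G1", chrom = "chr1",
                      strand = "+", exon_starts = "11", exon_ends = "28",
                      canonical = 1L, stringsAsFactors = FALSE)
  list(ref = ref, genes = validate_gene_model(genes))
}

test_that("codon translation classifies SNV consequences", {
  tg <- toy_gene()
  # GAT -> GAC is still Asp: third position, synonymous (pos 16)
  expect_identical(classify_consequence(gvariant("chr1", 16, "T", "C"),
                                        tg$genes, tg$ref), "synonymous")
  # CAG -> TAG introduces a stop (pos 17)
  expect_identical(classify_consequence(gvariant("chr1", 17, "C", "T"),
                                        tg$genes, tg$ref), "nonsense")
  # CAG -> CGG Gln->Arg (pos 18)
  expect_identical(classify_consequence(gvariant("chr1", 18, "A", "G"),
                                        tg$genes, tg$ref), "missense")
  # TAA stop -> CAA Gln (pos 26)
  expect_identical(classify_consequence(gvariant("chr1", 26, "T", "C"),
                                        tg$genes, tg$ref), "stop_loss")
  # ATG start -> GTG (pos 11)
  expect_identical(classify_consequence(gvariant("chr1", 11, "A", "G"),
                                        tg$genes, tg$ref), "start_loss")
  # outside the transcript
  expect_identical(classify_consequence(gvariant("chr1", 3, "T", "A"),
                                        tg$genes, tg$ref), "noncoding")
})

test_that("indel length mod 3 separates frameshift from in-frame", {
  tg <- toy_gene()
  r2 <- substr(tg$ref$chr1, 17, 19)
  expect_identical(classify_consequence(
    gvariant("chr1", 17, r2, substr(r2, 1, 1)), tg$genes, tg$ref),
    "frameshift")                          # 2-bp deletion
  r3 <- substr(tg$ref$chr1, 17, 20)
  expect_identical(classify_consequence(
    gvariant("chr1", 17, r3, substr(r3, 1, 1)), tg$genes, tg$ref),
    "inframe_indel")                       # 3-bp deletion
})

test_that("positions within 2 bp of an intron boundary are essential splice", {
  rb <- fixture_ref()
  two_exon <- rb$genes[lengths(gregexpr(",", rb$genes$exon_starts)) == 1 &
                         grepl(",", rb$genes$exon_starts), ]
  ex <- chipmeta:::exon_list(two_exon[1, ])
  donor <- ex$end[1] + 1L                  # first intronic base
  b <- substr(rb$reference$chr1, donor, donor)
  expect_identical(classify_consequence(
    gvariant("chr1", donor, b, setdiff(c("A", "C", "G", "T"), b)[1]),
    rb$genes, rb$reference), "essential_splice")
  mid <- ex$end[1] + 45L                   # deep intron
  bm <- substr(rb$reference$chr1, mid, mid)
  expect_identical(classify_consequence(
    gvariant("chr1", mid, bm, setdiff(c("A", "C", "G", "T"), bm)[1]),
    rb$genes, rb$reference), "noncoding")
})

test_that("the functional filter keeps impactful classes in input order", {
  df <- data.frame(id = 1:6,
                   consequence = c("missense", "synonymous", "frameshift",
                                   "noncoding", "nonsense",
                                   "essential_splice"))
  out <- functional_filter(df)
  expect_identical(out$id, c(1L, 3L, 5L, 6L))
  expect_identical(out$consequence,
                   c("missense", "frameshift", "nonsense",
                     "essential_splice"))
})

test_that("gene models with malformed exons or broken CDS are rejected", {
  bad <- data.frame(transcript = "T1", gene = "G1", chrom = "chr1",
                    strand = "+", exon_starts = "10,5", exon_ends = "20,8",
                    canonical = 1L)
  expect_error(validate_gene_model(bad), "overlap|unordered")
  bad2 <- data.frame(transcript = "T1", gene = "G1", chrom = "chr1",
                     strand = "+", exon_starts = "11", exon_ends = "27",
                     canonical = 1L)
  expect_error(validate_gene_model(bad2), "divisible by 3")
})

test_that("context features report planted repeats and GC boundary cases", {
  rb <- fixture_ref()
  hp <- context_features("chr1", 14L, rb$reference)
  expect_gte(hp$homopolymer_len, 8L)
  expect_false(hp$in_str)
  st <- context_features("chr1", 35L, rb$reference,
                         str_regions = rb$repeats[rb$repeats$kind == "str",
                                                  c("chrom", "start", "end")])
  expect_true(st$in_str)
  # detected tandem without a configured interval
  st2 <- context_features("chr1", 35L, rb$reference)
  expect_true(st2$in_str)
  # all-GC window
  gg <- context_features("chr1", 50L, list(chr1 = strrep("GC", 100)))
  expect_identical(gg$gc_content_101bp, 1.0)
  # non-repetitive context
  nr <- context_features("chr1", 5L, list(chr1 = "ACGTACGATCGGATCCTAG"))
  expect_identical(nr$homopolymer_len, 1L)
  expect_true(nr$clipped)
})

test_that("strand-bias phred matches a brute-force hypergeometric oracle", {
  cases <- list(c(8L, 0L, 10L, 12L), c(3L, 3L, 20L, 20L),
                c(10L, 1L, 5L, 14L), c(0L, 4L, 9L, 9L))
  for (cs in cases) {
    # two-sided Fisher p by enumerating the hypergeometric tail mass
    m <- cs[1] + cs[2]; n <- cs[3] + cs[4]; k <- cs[1] + cs[3]
    probs <- dhyper(max(0, k - n):min(m, k), m, n, k)
    p0 <- dhyper(cs[1], m, n, k)
    p <- sum(probs[probs <= p0 * (1 + 1e-7)])
    expect_equal(strand_bias_phred(cs[1], cs[2], cs[3], cs[4]),
                 max(0, -10 * log10(p)), tolerance = 1e-6)
  }
})

test_that("the feature schema is frozen at 26 SNV / 24 indel entries", {
  expect_length(feature_schema("SNV"), 26L)
  expect_length(feature_schema("INDEL"), 24L)
  expect_identical(setdiff(feature_schema("SNV"), feature_schema("INDEL")),
                   c("mean_read_pos_fraction", "is_transition",
                     "base_change_class"))
  expect_identical(setdiff(feature_schema("INDEL"), feature_schema("SNV")),
                   "indel_length")
  # schema also shipped as a machine-readable file
  sf <- system.file("extdata", "feature_schema.json", package = "chipmeta")
  sj <- jsonlite::read_json(sf, simplifyVector = TRUE)
  expect_identical(sj$snv, feature_schema("SNV"))
  expect_identical(sj$indel, feature_schema("INDEL"))
})

test_that("feature vectors encode calling status, ratios and absent resources as zero", {
  rb <- fixture_ref()
  rt0 <- resource_tables()                    # everything empty
  p <- as.integer(rb$genes$exon_starts[1]) + 7L
  b <- substr(rb$reference$chr1, p, p)
  alt <- setdiff(c("A", "C", "G", "T"), b)[1]
  mc <- data.frame(chrom = "chr1", pos = p, ref = b, alt = alt,
                   key = paste("chr1", p, b, alt, sep = ":"),
                   status = 3L, callers = "CALLER_A,CALLER_B,TRACKER",
                   alt_count = 5L, depth = 100L, vaf = 0.05,
                   alt_fwd = 3L, ref_count = 95L, ref_fwd = 48L,
                   mean_mapq_alt = 60, mean_baseq_alt = 35,
                   mean_read_pos_fraction = 0.5, spans_indel = FALSE,
                   stringsAsFactors = FALSE)
  fv <- build_feature_vector(mc, "missense", rt0, rb$reference)
  expect_length(fv, 26L)
  expect_identical(unname(fv["status_meta"]), 3)
  expect_identical(unname(fv[c("called_by_tracker", "called_by_caller_a",
                               "called_by_caller_b")]), c(1, 1, 1))
  expect_identical(unname(fv["vaf"]), 0.05)
  expect_identical(unname(fv[c("maf_db1", "maf_db2", "maf_db3", "maf_db4",
                               "max_germline_maf", "cosmic_match",
                               "cosmic_freq")]), rep(0, 7))
  expect_identical(unname(fv["consequence_class"]),
                   as.numeric(consequence_levels()[["missense"]]))
  # indel schema: 24 entries with signed length
  mci <- mc
  mci$ref <- substr(rb$reference$chr1, p, p + 2L); mci$alt <- b
  fvi <- build_feature_vector(mci, "frameshift", rt0, rb$reference)
  expect_length(fvi, 24L)
  expect_identical(unname(fvi["indel_length"]), -2)
})

test_that("max_germline_maf is the maximum over the four database slots", {
  rb <- fixture_ref()
  key_df <- data.frame(chrom = "chr1", pos = 500L, ref = "A", alt = "T")
  rt <- resource_tables(germline = list(
    within(key_df, maf <- 0.01), within(key_df, maf <- 0.20),
    within(key_df, maf <- 0.05), within(key_df, maf <- 0.002)))
  mc <- data.frame(chrom = "chr1", pos = 500L, ref = "A", alt = "T",
                   key = "chr1:500:A:T", status = 1L, callers = "TRACKER",
                   alt_count = 3L, depth = 10L, vaf = 0.3, alt_fwd = 2L,
                   ref_count = 7L, ref_fwd = 4L, mean_mapq_alt = 60,
                   mean_baseq_alt = 35, mean_read_pos_fraction = 0.5,
                   spans_indel = FALSE, stringsAsFactors = FALSE)
  fv <- build_feature_vector(mc, "missense", rt, rb$reference)
  expect_identical(unname(fv["max_germline_maf"]), 0.20)
  expect_identical(unname(fv[c("maf_db1", "maf_db2", "maf_db3", "maf_db4")]),
                   c(0.01, 0.20, 0.05, 0.002))
})
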