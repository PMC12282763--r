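# Shared fixtures, built in code and memoized across test files.

.fixtures <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

fixture_ref <- function() fx("rb", function() {
  make_reference(n_genes = 4L, gene_len = 300L, seed = 42L)
})

fixture_specs <- function() fx("specs", function() {
  make_variant_specs(fixture_ref(), n_chip = 25L, n_germline = 15L,
                     seed = 5L)
})

fixture_rt <- function() fx("rt", function() {
  sp <- fixture_specs()
  make_study_resources(fixture_ref(), sp$somatic, sp$germline, seed = 2L)
})

# one simulated subject at CHIP-like VAFs (shared by tracker/merge tests)
fixture_subject <- function() fx("subject", function() {
  simulate_subject(fixture_ref(), fixture_specs(), chip_vaf = "chip",
                   mean_depth = 100, seed = 1L)
})

# classifiers trained on pipeline-derived labeled calls from 3 subjects
fixture_models <- function() fx("models", function() {
  rb <- fixture_ref(); rt <- fixture_rt(); sp <- fixture_specs()
  tr_snv <- build_training_table(rb, rt, sp, n_subjects = 3L,
                                 variant_type = "SNV", seed = 10L)
  tr_ind <- build_training_table(rb, rt, sp, n_subjects = 3L,
                                 variant_type = "INDEL", seed = 10L)
  list(SNV = train_classifier(tr_snv, train_config("gbt", "WGS", "SNV",
                                                   seed = 1L)),
       INDEL = train_classifier(tr_ind, train_config("gbt", "WGS", "INDEL",
                                                     seed = 1L)))
})

# hand-built read row for constructed pileup cases
mk_read <- function(pos, seq, qual = NULL, flag = 0L, cigar = NULL,
                    chrom = "chr1", mapq = 60L, qname = NULL) {
  if (is.null(qual)) qual <- strrep("I", nchar(seq))      # phred 40
  if (is.null(cigar)) cigar <- sprintf("%dM", nchar(seq))
  data.frame(qname = qname %||% sprintf("r%d_%d", pos, sample.int(1e6, 1)),
             flag = flag, chrom = chrom, pos = pos, mapq = mapq,
             cigar = cigar, seq = seq, qual = qual,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force alt recount at one position straight off the read rows,
# mirroring the tracker's documented counting rules but written
# independently (plain loops, no shared code path)
brute_force_alt_count <- function(aln, reference, chrom, pos, allele,
                                  min_bq = 13L) {
  n <- 0L
  for (i in seq_len(nrow(aln))) {
    if (aln$chrom[i] != chrom) next
    fl <- as.integer(aln$flag[i])
    if (bitwAnd(fl, 4L) || bitwAnd(fl, 256L) || bitwAnd(fl, 512L) ||
        bitwAnd(fl, 1024L) || bitwAnd(fl, 2048L)) next
    lens <- as.integer(regmatches(aln$cigar[i],
                                  gregexpr("[0-9]+", aln$cigar[i]))[[1]])
    ops <- regmatches(aln$cigar[i], gregexpr("[A-Z=]", aln$cigar[i]))[[1]]
    rp <- aln$pos[i]; qp <- 1L
    for (j in seq_along(ops)) {
      if (ops[j] %in% c("M", "=", "X")) {
        if (pos >= rp && pos < rp + lens[j]) {
          q <- qp + (pos - rp)
          b <- substr(aln$seq[i], q, q)
          bq <- utf8ToInt(substr(aln$qual[i], q, q)) - 33L
          if (nchar(allele) == 1L && b == allele && bq >= min_bq)
            n <- n + 1L
        }
        rp <- rp + lens[j]; qp <- qp + lens[j]
      } else if (ops[j] == "I") {
        if (rp - 1L == pos && identical(allele, paste0("I:",
            substr(aln$seq[i], qp, qp + lens[j] - 1L))))
          n <- n + 1L
        qp <- qp + lens[j]
      } else if (ops[j] == "D") {
        if (rp - 1L == pos && identical(allele, paste0("D:", lens[j])))
          n <- n + 1L
        rp <- rp + lens[j]
      } else if (ops[j] == "S") {
        qp <- qp + lens[j]
      }
    }
  }
  n
}
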