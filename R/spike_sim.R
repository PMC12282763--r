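#' Build a synthetic reference with gene models
#'
#' Generates one contig carrying `n_genes` open reading frames (ATG start,
#' no internal stop, terminal stop, length divisible by 3) separated by
#' intergenic sequence at the requested GC content. The first intergenic
#' block carries a planted homopolymer run (8 bp) and a short tandem repeat
#' (6 x "AC") so context features are exercised; when `n_genes >= 2` the
#' last gene is split into two exons by a 90-bp intron so splice-site
#' annotation is exercised. Gene names default to leukemia driver symbols
#' so refinement rules keyed on privileged genes can be tested end to end.
#'
#' @param n_genes number of genes.
#' @param gene_len CDS length per gene (divisible by 3).
#' @param gc target GC fraction for intergenic sequence.
#' @param intergenic_len intergenic block length (>= 60).
#' @param seed integer seed; output is deterministic given it.
#' @param gene_names optional character vector of gene symbols.
#' @return list: `reference` (named list of contig strings), `genes`
#'   (gene-model data.frame), `regions` (interval data.frame), `repeats`
#'   (positions of the planted homopolymer/STR).
#' @export
make_reference <- function(n_genes = 4L, gene_len = 300L, gc = 0.5,
                           intergenic_len = 150L, seed = 1L,
                           gene_names = NULL) {
  stopifnot(n_genes >= 1, gene_len %% 3 == 0, gene_len >= 30,
            intergenic_len >= 60, gc > 0, gc < 1)
  if (is.null(gene_names))
    gene_names <- c("DNMT3A", "TET2", "ASXL1", "PPM1D", "JAK2", "TP53",
                    "SF3B1", "CREBBP", "SRSF2", "GNB1", "IDH2", "CBL")
  if (n_genes > length(gene_names))
    gene_names <- c(gene_names,
                    sprintf("GENE%02d", seq_len(n_genes - length(gene_names))))
  gene_names <- gene_names[seq_len(n_genes)]
  with_seed(seed, {
    rand_seq <- function(L) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE,
                   prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
            collapse = "")
    }
    stops <- c("TAA", "TAG", "TGA")
    rand_orf <- function(L) {
      n_codon <- L / 3L
      body <- character(n_codon - 2L)
      for (i in seq_along(body)) {
        repeat {
          cd <- rand_seq(3L)
          if (!cd %in% stops) break
        }
        body[i] <- cd
      }
      paste0("ATG", paste(body, collapse = ""), sample(stops, 1L))
    }
    inter0 <- rand_seq(intergenic_len)
    # plant a homopolymer and an STR in the first intergenic block
    substr(inter0, 11L, 18L) <- "AAAAAAAA"
    substr(inter0, 31L, 42L) <- "ACACACACACAC"
    pieces <- inter0
    gene_rows <- list()
    cursor <- nchar(inter0)
    for (k in seq_len(n_genes)) {
      orf <- rand_orf(gene_len)
      if (k == n_genes && n_genes >= 2L) {
        half <- (gene_len %/% 2L)
        intron <- rand_seq(90L)
        substr(intron, 1L, 2L) <- "GT"
        substr(intron, 89L, 90L) <- "AG"
        ex1 <- substr(orf, 1L, half)
        ex2 <- substr(orf, half + 1L, gene_len)
        e1s <- cursor + 1L; e1e <- cursor + half
        e2s <- e1e + 90L + 1L; e2e <- e2s + nchar(ex2) - 1L
        pieces <- c(pieces, ex1, intron, ex2)
        cursor <- e2e
        gene_rows[[k]] <- data.frame(
          transcript = paste0(gene_names[k], "_t1"), gene = gene_names[k],
          chrom = "chr1", strand = "+",
          exon_starts = paste(e1s, e2s, sep = ","),
          exon_ends = paste(e1e, e2e, sep = ","), canonical = 1L,
          stringsAsFactors = FALSE)
      } else {
        gs <- cursor + 1L; ge <- cursor + gene_len
        pieces <- c(pieces, orf)
        cursor <- ge
        gene_rows[[k]] <- data.frame(
          transcript = paste0(gene_names[k], "_t1"), gene = gene_names[k],
          chrom = "chr1", strand = "+",
          exon_starts = as.character(gs), exon_ends = as.character(ge),
          canonical = 1L, stringsAsFactors = FALSE)
      }
      inter <- rand_seq(intergenic_len)
      pieces <- c(pieces, inter)
      cursor <- cursor + intergenic_len
    }
    genes <- validate_gene_model(do.call(rbind, gene_rows))
    regions <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
      ex <- exon_list(genes[i, , drop = FALSE])
      data.frame(chrom = "chr1", start = min(ex$start), end = max(ex$end),
                 name = genes$gene[i], stringsAsFactors = FALSE)
    }))
    list(reference = list(chr1 = paste(pieces, collapse = "")),
         genes = genes, regions = regions,
         repeats = data.frame(chrom = "chr1",
                              start = c(11L, 31L), end = c(18L, 42L),
                              kind = c("homopolymer", "str"),
                              stringsAsFactors = FALSE))
  })
}

#' Simulate aligned reads over a reference
#'
#' Emits pre-aligned single-end reads (the simulator knows provenance, so
#' no aligner is involved): uniform start positions, fixed read length,
#' per-base substitution error at `err_rate`, phred qualities drawn from a
#' high-quality alphabet with an occasional low-quality base. Optional
#' germline variants are planted by per-read conversion at VAF 0.5
#' (heterozygous) or 1.0 (homozygous). Output is coordinate-sorted.
#'
#' @param reference named list of contig sequences.
#' @param mean_depth target mean coverage.
#' @param read_len read length.
#' @param err_rate per-base substitution error rate.
#' @param seed integer seed.
#' @param germline optional data.frame `chrom,pos,ref,alt,zygosity`
#'   (`"het"` or `"hom"`).
#' @return list: `aln` (alignment data.frame, see [alignments]),
#'   `germline` (truth table for the planted germline variants, see
#'   [spike_in()]).
#' @export
simulate_reads <- function(reference, mean_depth = 30, read_len = 100L,
                           err_rate = 0.001, seed = 1L, germline = NULL) {
  reference <- as.list(reference)
  alphabet <- c("A", "C", "G", "T")
  aln <- with_seed(seed, {
    pieces <- lapply(names(reference), function(ct) {
      L <- nchar(reference[[ct]])
      n <- max(1L, round(mean_depth * L / read_len))
      starts <- sort(sample.int(max(1L, L - read_len + 1L), n,
                                replace = TRUE))
      seqs <- substring(reference[[ct]], starts, starts + read_len - 1L)
      big <- strsplit(paste(seqs, collapse = ""), "")[[1]]
      nerr <- rbinom(1L, length(big), err_rate)
      if (nerr > 0L) {
        at <- sample.int(length(big), nerr)
        big[at] <- vapply(big[at], function(b)
          sample(setdiff(alphabet, b), 1L), character(1))
      }
      qual_int <- sample(c(8L, 30:40), length(big), replace = TRUE,
                         prob = c(0.02, rep(0.98 / 11, 11)))
      seqs <- substring(paste(big, collapse = ""),
                        (seq_len(n) - 1L) * read_len + 1L,
                        seq_len(n) * read_len)
      quals <- substring(rawToChar(as.raw(qual_int + 33L)),
                         (seq_len(n) - 1L) * read_len + 1L,
                         seq_len(n) * read_len)
      data.frame(qname = sprintf("%s_r%06d", ct, seq_len(n)),
                 flag = ifelse(runif(n) < 0.5, 0L, 16L),
                 chrom = ct, pos = starts, mapq = 60L,
                 cigar = sprintf("%dM", read_len),
                 seq = seqs, qual = quals, stringsAsFactors = FALSE)
    })
    do.call(rbind, pieces)
  })
  g_truth <- NULL
  if (!is.null(germline) && nrow(germline)) {
    specs <- germline
    specs$target_vaf <- ifelse(specs$zygosity == "hom", 1.0, 0.5)
    sp <- spike_in(aln, specs, reference, m = 1L, seed = seed + 101L)
    aln <- sp$aln
    g_truth <- sp$truth
    g_truth$zygosity <- germline$zygosity
  }
  list(aln = aln, germline = g_truth)
}

#' The uniform spike-in VAF series
#'
#' Thirteen target allele fractions: 0.5%, 1% to 10% in 1% steps, 20%
#' and 30%.
#'
#' @return numeric vector of length 13, strictly increasing.
#' @export
vaf_series <- function() {
  c(0.005, seq(0.01, 0.10, by = 0.01), 0.20, 0.30)
}

#' Draw CHIP-like target VAFs
#'
#' Log-normal targets calibrated so the median matches the known-CHIP
#' spectrum (12.5% for SNVs, 14.8% for indels), truncated to (0.005, 0.6).
#'
#' @param n number of draws.
#' @param variant_type `"SNV"` or `"INDEL"`.
#' @param seed integer seed.
#' @param sdlog log-scale spread.
#' @return numeric vector of target VAFs.
#' @export
chip_vaf_targets <- function(n, variant_type = c("SNV", "INDEL"), seed = 1L,
                             sdlog = 0.6) {
  variant_type <- match.arg(variant_type)
  med <- if (variant_type == "SNV") 0.125 else 0.148
  with_seed(seed, pmin(0.6, pmax(0.005, exp(rnorm(n, log(med), sdlog)))))
}

# map a reference position to the query offset of a read; NA when the
# position is not aligned to a query base
query_offset <- function(read_pos, cigar, pos) {
  co <- cigar_ops(cigar)
  rp <- read_pos; qp <- 1L
  for (j in seq_along(co$op)) {
    len <- co$len[j]; op <- co$op[j]
    if (op %in% c("M", "=", "X")) {
      if (pos >= rp && pos <= rp + len - 1L) return(qp + (pos - rp))
      rp <- rp + len; qp <- qp + len
    } else if (op == "I") qp <- qp + len
    else if (op %in% c("D", "N")) {
      if (op == "D" && pos >= rp && pos <= rp + len - 1L) return(NA_integer_)
      rp <- rp + len
    } else if (op == "S") qp <- qp + len
  }
  NA_integer_
}

aligned_end <- function(read_pos, cigar) {
  co <- cigar_ops(cigar)
  read_pos + sum(co$len[co$op %in% c("M", "=", "X", "D", "N")]) - 1L
}

#' Spike variants into alignments at target allele fractions
#'
#' BAMSurgeon-style: at each spec, every overlapping read is converted to
#' the alternate allele independently with probability `target_vaf`
#' (per-read Bernoulli conversion, so realized VAFs scatter below the
#' target at low depth, as real spike-in does). Base qualities are
#' preserved; indels re-gap the read while keeping its length. A site whose
#' depth is below `m` (default 2, the minimum read depth to make a
#' mutation) is skipped and recorded; a REF mismatch, or a draw converting
#' zero reads, is recorded as a failure and the run continues.
#'
#' @param aln alignment data.frame.
#' @param specs data.frame `chrom,pos,ref,alt,target_vaf`.
#' @param reference named list of contig sequences.
#' @param m minimum read depth to make a mutation.
#' @param seed integer seed.
#' @return list: `aln` (mutated alignments), `truth` (truth table:
#'   `chrom,pos,ref,alt,vtype,target_vaf,status` in
#'   spiked/skipped/failed, `reason`, `depth`, `reads_converted`,
#'   `realized_vaf`).
#' @export
spike_in <- function(aln, specs, reference, m = 2L, seed = 1L) {
  reference <- as.list(reference)
  truth <- specs[, c("chrom", "pos", "ref", "alt", "target_vaf")]
  truth$vtype <- variant_type(truth$ref, truth$alt)
  truth$status <- "failed"; truth$reason <- ""
  truth$depth <- 0L; truth$reads_converted <- 0L
  truth$realized_vaf <- NA_real_
  with_seed(seed, {
    ends <- mapply(aligned_end, aln$pos, aln$cigar)
    for (i in seq_len(nrow(truth))) {
      chrom <- truth$chrom[i]; pos <- truth$pos[i]
      ref <- toupper(truth$ref[i]); alt <- toupper(truth$alt[i])
      rl <- nchar(ref)
      obs <- substr(reference[[chrom]], pos, pos + rl - 1L)
      if (is.null(reference[[chrom]]) || obs != ref) {
        truth$reason[i] <- sprintf("REF mismatch (reference has %s)", obs)
        next
      }
      cover <- which(aln$chrom == chrom & aln$pos <= pos & ends >= pos)
      depth <- length(cover)
      truth$depth[i] <- depth
      if (depth < m) {
        truth$status[i] <- "skipped"
        truth$reason[i] <- "depth < m"
        next
      }
      vt <- truth$vtype[i]
      conv <- 0L
      for (r in cover) {
        if (runif(1) >= truth$target_vaf[i]) next
        new_read <- convert_read(aln[r, , drop = FALSE], pos, ref, alt, vt,
                                 reference)
        if (is.null(new_read)) next
        aln[r, c("seq", "qual", "cigar")] <-
          new_read[c("seq", "qual", "cigar")]
        conv <- conv + 1L
      }
      if (conv == 0L) {
        truth$reason[i] <- "no reads converted"
        next
      }
      truth$status[i] <- "spiked"
      truth$reads_converted[i] <- conv
      truth$realized_vaf[i] <- conv / depth
      if (vt == "DEL") ends <- mapply(aligned_end, aln$pos, aln$cigar)
    }
  })
  list(aln = aln, truth = truth)
}

# rewrite one read to carry the alt allele; NULL when the read cannot be
# converted (position unaligned, indel into an already-gapped read, or no
# room at the read end)
convert_read <- function(read, pos, ref, alt, vt, reference) {
  read_len <- nchar(read$seq)
  q0 <- query_offset(read$pos, read$cigar, pos)
  if (is.na(q0)) return(NULL)
  if (vt %in% c("SNV", "MNP")) {
    offs <- vapply(seq_len(nchar(ref)), function(k)
      query_offset(read$pos, read$cigar, pos + k - 1L), integer(1))
    if (any(is.na(offs))) return(NULL)
    s <- read$seq
    for (k in seq_along(offs))
      substr(s, offs[k], offs[k]) <- substr(alt, k, k)
    read$seq <- s
    return(read)
  }
  simple <- read$cigar == sprintf("%dM", read_len)
  if (!simple) return(NULL)
  if (vt == "INS") {
    ins <- substr(alt, 2L, nchar(alt))
    il <- nchar(ins)
    if (q0 < 1L || q0 > read_len - il - 1L) return(NULL)
    read$seq <- paste0(substr(read$seq, 1L, q0), ins,
                       substr(read$seq, q0 + 1L, read_len - il))
    aq <- substr(read$qual, q0, q0)
    read$qual <- paste0(substr(read$qual, 1L, q0),
                        strrep(aq, il),
                        substr(read$qual, q0 + 1L, read_len - il))
    read$cigar <- sprintf("%dM%dI%dM", q0, il, read_len - q0 - il)
  } else {                                    # DEL
    dl <- nchar(ref) - 1L
    if (q0 < 1L || q0 > read_len - dl - 1L) return(NULL)
    re <- read$pos + read_len - 1L
    ext <- substr(reference[[read$chrom]], re + 1L, re + dl)
    if (nchar(ext) < dl) return(NULL)        # runs off the contig
    read$seq <- paste0(substr(read$seq, 1L, q0),
                       substr(read$seq, q0 + dl + 1L, read_len), ext)
    lq <- substr(read$qual, read_len, read_len)
    read$qual <- paste0(substr(read$qual, 1L, q0),
                        substr(read$qual, q0 + dl + 1L, read_len),
                        strrep(lq, dl))
    read$cigar <- sprintf("%dM%dD%dM", q0, dl, read_len - q0)
  }
  read
}

#' Verify spiked variants by pileup recount
#'
#' Re-tallies the mutated alignments at every successfully spiked site and
#' reports the observed alt count and VAF; a spiked record with zero
#' observable alt reads is flagged as a simulator defect.
#'
#' @param aln mutated alignments.
#' @param truth truth table from [spike_in()].
#' @param reference named list of contig sequences.
#' @param cfg [pileup_config()].
#' @return data.frame of spiked records with `observed_alt`, `observed_vaf`
#'   and `defect` columns.
#' @export
verify_spikein <- function(aln, truth, reference, cfg = pileup_config()) {
  sp <- truth[truth$status == "spiked", , drop = FALSE]
  if (nrow(sp) == 0L) {
    sp$observed_alt <- integer(0); sp$observed_vaf <- numeric(0)
    sp$defect <- logical(0)
    return(sp)
  }
  sp$observed_alt <- 0L; sp$observed_vaf <- 0
  max_span <- max(nchar(aln$seq)) + 10L
  for (i in seq_len(nrow(sp))) {
    reg <- list(chrom = sp$chrom[i], start = sp$pos[i], end = sp$pos[i])
    near <- aln[aln$chrom == sp$chrom[i] & aln$pos <= sp$pos[i] &
                  aln$pos >= sp$pos[i] - max_span, , drop = FALSE]
    sites <- pileup_sites(near, reference, reg, cfg)
    code <- switch(sp$vtype[i],
                   SNV = sp$alt[i],
                   MNP = substr(sp$alt[i], 1L, 1L),
                   INS = paste0("I:", substr(sp$alt[i], 2L, nchar(sp$alt[i]))),
                   DEL = paste0("D:", nchar(sp$ref[i]) - 1L))
    hit <- sites[sites$allele == code, , drop = FALSE]
    if (nrow(hit)) {
      sp$observed_alt[i] <- hit$count[1]
      sp$observed_vaf[i] <- hit$count[1] / hit$depth[1]
    }
  }
  sp$defect <- sp$observed_alt == 0L
  sp
}

#' Mock external caller profile
#'
#' A stand-in for an external variant caller, characterized by a VAF-binned
#' sensitivity curve, a false-positive rate per megabase, and a minimum
#' alt-read threshold (real somatic callers typically require >= 2
#' supporting reads and lose most sensitivity below 10% VAF).
#'
#' @param name caller id.
#' @param sens data.frame `vaf_max,p`: detection probability for realized
#'   VAF up to each bin bound (last bound should be 1).
#' @param fp_rate expected false calls per megabase of covered sequence.
#' @param min_alt_reads minimum supporting reads to report.
#' @export
mock_caller_profile <- function(name,
                                sens = data.frame(
                                  vaf_max = c(0.05, 0.10, 1.00),
                                  p = c(0.15, 0.45, 0.90)),
                                fp_rate = 0, min_alt_reads = 2L) {
  stopifnot(all(sens$p >= 0 & sens$p <= 1))
  structure(list(name = name, sens = sens, fp_rate = fp_rate,
                 min_alt_reads = as.integer(min_alt_reads)),
            class = "mock_caller_profile")
}

#' Run a mock external caller over spiked alignments
#'
#' Each successfully spiked truth variant is reported with the probability
#' its realized VAF bin prescribes, provided its converted-read count meets
#' the profile's alt-read floor; false positives are placed uniformly at
#' covered non-truth positions at the profile's per-megabase rate.
#'
#' @param truth truth table from [spike_in()].
#' @param profile a [mock_caller_profile()].
#' @param aln alignments (for the covered span and false-positive placement).
#' @param reference named list of contig sequences.
#' @param seed integer seed.
#' @return call-record data.frame.
#' @export
mock_caller <- function(truth, profile, aln, reference, seed = 1L) {
  reference <- as.list(reference)
  with_seed(seed, {
    sp <- truth[truth$status == "spiked", , drop = FALSE]
    rows <- list()
    if (nrow(sp)) {
      pdet <- vapply(sp$realized_vaf, function(v)
        profile$sens$p[which(v <= profile$sens$vaf_max)[1]], numeric(1))
      det <- runif(nrow(sp)) < pdet & sp$reads_converted >= profile$min_alt_reads
      if (any(det))
        rows[["tp"]] <- data.frame(
          chrom = sp$chrom[det], pos = sp$pos[det], ref = sp$ref[det],
          alt = sp$alt[det], caller = profile$name,
          alt_count = sp$reads_converted[det], depth = sp$depth[det],
          vaf = sp$realized_vaf[det], stringsAsFactors = FALSE)
    }
    if (profile$fp_rate > 0 && nrow(aln)) {
      for (ct in unique(aln$chrom)) {
        sub <- aln$chrom == ct
        lo <- min(aln$pos[sub])
        hi <- max(mapply(aligned_end, aln$pos[sub], aln$cigar[sub]))
        span <- hi - lo + 1L
        nfp <- rbinom(1L, span, min(1, profile$fp_rate / 1e6))
        if (nfp == 0L) next
        cand <- setdiff(seq(lo, hi), truth$pos[truth$chrom == ct])
        ppos <- sample(cand, min(nfp, length(cand)))
        mean_depth <- round(sum(sub) * mean(nchar(aln$seq[sub])) / span)
        fp <- lapply(ppos, function(p) {
          rb <- substr(reference[[ct]], p, p)
          ab <- sample(setdiff(c("A", "C", "G", "T"), rb), 1L)
          data.frame(chrom = ct, pos = p, ref = rb, alt = ab,
                     caller = profile$name,
                     alt_count = profile$min_alt_reads,
                     depth = max(mean_depth, profile$min_alt_reads),
                     vaf = profile$min_alt_reads /
                       max(mean_depth, profile$min_alt_reads),
                     stringsAsFactors = FALSE)
        })
        rows[[paste0("fp_", ct)]] <- do.call(rbind, fp)
      }
    }
    out <- do.call(rbind, rows)
    if (is.null(out))
      out <- data.frame(chrom = character(), pos = integer(),
                        ref = character(), alt = character(),
                        caller = character(), alt_count = integer(),
                        depth = integer(), vaf = numeric(),
                        stringsAsFactors = FALSE)
    out <- out[order(out$chrom, out$pos), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Spike-in recall and precision
#'
#' Ground-truth matching is position-only: a spiked truth variant counts as
#' recovered if any call occupies its position, regardless of the
#' alternative allele; calls at positions that belong to no truth record
#' count as false positives. Only successfully spiked truths enter the
#' recall denominator.
#'
#' @param calls call-record data.frame.
#' @param truth truth table from [spike_in()].
#' @param reference optional named list of contig sequences; when given,
#'   a truth variant also matches calls at its left-normalized anchor
#'   (indel representations can shift under normalization).
#' @return list with `recall`, `precision`, `n_truth`, `n_recovered`,
#'   `n_false_positive`.
#' @export
spikein_recall_precision <- function(calls, truth, reference = NULL) {
  sp <- truth[truth$status == "spiked", , drop = FALSE]
  pos_aliases <- function(tt) {
    out <- lapply(seq_len(nrow(tt)), function(i) paste(tt$chrom[i], tt$pos[i]))
    if (!is.null(reference)) {
      n <- suppressWarnings(normalize_call_frame(
        tt[, c("chrom", "pos", "ref", "alt")], reference))
      # one spec can normalize to several SNV rows (MNP split); group back
      for (i in seq_len(nrow(tt))) {
        k <- n$chrom == tt$chrom[i] & abs(n$pos - tt$pos[i]) <= 60L
        out[[i]] <- unique(c(out[[i]], paste(n$chrom[k], n$pos[k])))
      }
    }
    out
  }
  sp_alias <- pos_aliases(sp)
  truth_pos <- unique(c(paste(truth$chrom, truth$pos),
                        unlist(pos_aliases(truth))))
  call_pos <- unique(paste(calls$chrom, calls$pos))
  recovered <- sum(vapply(sp_alias, function(a) any(a %in% call_pos),
                          logical(1)))
  n_fp <- sum(!call_pos %in% truth_pos)
  list(recall = if (nrow(sp)) recovered / nrow(sp) else NA_real_,
       precision = if (recovered + n_fp > 0)
         recovered / (recovered + n_fp) else NA_real_,
       n_truth = nrow(sp), n_recovered = recovered,
       n_false_positive = n_fp)
}

#' Apply the full spike-in batch to a set of alignment inputs
#'
#' The 13 uniform VAF levels plus one CHIP-specific-VAF configuration are
#' each applied to every input alignment set, yielding `14 * B` mutated
#' outputs.
#'
#' @param aln_sets list of alignment data.frames.
#' @param specs data.frame `chrom,pos,ref,alt` of variants to spike (the
#'   `target_vaf` column is set per configuration).
#' @param reference named list of contig sequences.
#' @param m minimum depth to make a mutation.
#' @param seed integer seed.
#' @return list of length `14 * length(aln_sets)`; each element is a
#'   [spike_in()] result plus `input` (index) and `vaf_config` (the level,
#'   or `"chip"`).
#' @export
run_spikein_batch <- function(aln_sets, specs, reference, m = 2L,
                              seed = 1L) {
  configs <- c(as.list(vaf_series()), list("chip"))
  out <- list()
  for (b in seq_along(aln_sets)) {
    for (ci in seq_along(configs)) {
      cfg <- configs[[ci]]
      sp <- specs
      if (identical(cfg, "chip")) {
        sp$target_vaf <- chip_vaf_targets(nrow(sp), "SNV",
                                          seed = seed + 1000L * b + ci)
      } else {
        sp$target_vaf <- cfg
      }
      res <- spike_in(aln_sets[[b]], sp, reference, m = m,
                      seed = seed + 37L * b + ci)
      res$input <- b
      res$vaf_config <- if (identical(cfg, "chip")) "chip" else cfg
      out[[length(out) + 1L]] <- res
    }
  }
  out
}

#' Generate a labeled synthetic feature table
#'
#' Desk-scale stand-in for classifier training data: CHIP rows carry low
#' VAFs and high calling status; GERMLINE rows sit near 50%/100% VAF with
#' nonzero germline MAFs; ARTIFACT rows show single-caller status, low
#' mapping/base quality and repeat-context flags. `separation` in [0, 1]
#' blends each class's distribution with a common baseline: at 0 the
#' classes are statistically indistinguishable, at 1 they are fully
#' separated as described.
#'
#' @param n number of rows.
#' @param class_fractions named fractions for CHIP/GERMLINE/ARTIFACT
#'   (sum 1).
#' @param separation blend weight in [0, 1].
#' @param seed integer seed.
#' @param variant_type `"SNV"` or `"INDEL"` schema.
#' @return data.frame: `label` factor plus the [feature_schema()] columns.
#' @export
synthetic_feature_table <- function(n,
                                    class_fractions = c(CHIP = 1 / 3,
                                                        GERMLINE = 1 / 3,
                                                        ARTIFACT = 1 / 3),
                                    separation = 1, seed = 1L,
                                    variant_type = c("SNV", "INDEL")) {
  variant_type <- match.arg(variant_type)
  stopifnot(abs(sum(class_fractions) - 1) < 1e-8,
            separation >= 0, separation <= 1)
  classes <- c("CHIP", "GERMLINE", "ARTIFACT")
  counts <- round(n * class_fractions[classes])
  counts[1] <- n - sum(counts[-1])
  w <- separation
  with_seed(seed, {
    label <- factor(rep(classes, counts), levels = classes)
    nn <- length(label)
    blend <- function(base_draw, class_draw) (1 - w) * base_draw + w * class_draw
    pblend <- function(pbase, pclass) (1 - w) * pbase + w * pclass
    # per-row class parameter selectors
    pick <- function(chip, germ, art)
      ifelse(label == "CHIP", chip, ifelse(label == "GERMLINE", germ, art))
    # calling status
    status_p <- rbind(CHIP = c(0.10, 0.30, 0.60),
                      GERMLINE = c(0.05, 0.15, 0.80),
                      ARTIFACT = c(0.85, 0.12, 0.03))
    base_p <- c(0.6, 0.25, 0.15)
    status <- vapply(seq_len(nn), function(i) {
      p <- pblend(base_p, status_p[as.character(label[i]), ])
      sample(1:3, 1L, prob = p)
    }, integer(1))
    flags <- t(vapply(status, function(s) {
      called <- sample(1:3, s, prob = c(0.55, 0.25, 0.20))
      as.numeric(1:3 %in% called)
    }, numeric(3)))
    depth <- pmax(10L, rpois(nn, 100))
    vaf_class <- pick(rbeta(nn, 2.5, 15),
                      ifelse(runif(nn) < 0.8, rbeta(nn, 40, 40),
                             rbeta(nn, 60, 1.5)),
                      rbeta(nn, 1.2, 25))
    vaf <- blend(rbeta(nn, 1.5, 8), vaf_class)
    alt <- pmax(1L, round(depth * vaf))
    vaf <- alt / depth
    mapq <- pmin(60, blend(rnorm(nn, 50, 8),
                           pick(rnorm(nn, 59, 1.5), rnorm(nn, 59, 1.5),
                                rnorm(nn, 38, 8))))
    baseq <- pmin(41, blend(rnorm(nn, 32, 3),
                            pick(rnorm(nn, 36, 1.5), rnorm(nn, 36, 1.5),
                                 rnorm(nn, 26, 4))))
    sb <- pmax(0, blend(rexp(nn, 1 / 6),
                        pick(rexp(nn, 1 / 3), rexp(nn, 1 / 3),
                             rexp(nn, 1 / 25))))
    spans <- rbinom(nn, 1L, pblend(0.10, pick(0.05, 0.05, 0.45)))
    rpf <- pmin(1, pmax(0, blend(rnorm(nn, 0.5, 0.12),
                                 pick(rnorm(nn, 0.5, 0.12),
                                      rnorm(nn, 0.5, 0.12),
                                      rbeta(nn, 0.6, 0.6)))))
    hp <- 1L + rpois(nn, pblend(0.4, pick(0.3, 0.3, 2.5)))
    in_str <- rbinom(nn, 1L, pblend(0.03, pick(0.02, 0.02, 0.35)))
    in_lc <- rbinom(nn, 1L, pblend(0.04, pick(0.03, 0.03, 0.40)))
    gcw <- pmin(1, pmax(0, rnorm(nn, 0.5, 0.07)))
    maf_present <- function() rbinom(nn, 1L, pblend(0.30, pick(0.01, 0.85, 0.01)))
    maf_value <- function() 0.4 * rbeta(nn, 0.8, 3)
    mafs <- sapply(1:4, function(j) maf_present() * maf_value())
    colnames(mafs) <- paste0("maf_db", 1:4)
    cosmic <- rbinom(nn, 1L, pblend(0.20, pick(0.70, 0.03, 0.03)))
    cfreq <- cosmic * (1L + rpois(nn, 6))
    trans <- rbinom(nn, 1L, pblend(0.50, pick(0.65, 0.60, 0.50)))
    func_codes <- unname(consequence_levels()[functional_classes()])
    cons <- vapply(seq_len(nn), function(i) {
      pc <- switch(as.character(label[i]),
                   CHIP = c(0.40, 0.02, 0.02, 0.02, 0.05, 0.25, 0.24),
                   GERMLINE = c(0.70, 0.05, 0.02, 0.02, 0.05, 0.08, 0.08),
                   ARTIFACT = c(0.40, 0.05, 0.03, 0.03, 0.06, 0.25, 0.18))
      p <- pblend(rep(1 / 7, 7), pc)
      sample(func_codes, 1L, prob = p)
    }, integer(1))
    bcc <- vapply(seq_len(nn), function(i) {
      pc <- switch(as.character(label[i]),
                   CHIP = c(0.12, 0.06, 0.50, 0.06, 0.16, 0.10),
                   GERMLINE = c(0.15, 0.10, 0.35, 0.10, 0.20, 0.10),
                   ARTIFACT = c(0.20, 0.15, 0.20, 0.15, 0.15, 0.15))
      p <- pblend(rep(1 / 6, 6), pc)
      sample(0:5, 1L, prob = p)
    }, integer(1))
    df <- data.frame(
      label = label,
      status_meta = as.numeric(status),
      called_by_tracker = flags[, 1], called_by_caller_a = flags[, 2],
      called_by_caller_b = flags[, 3],
      depth = as.numeric(depth), alt_count = as.numeric(alt), vaf = vaf,
      mean_mapq_alt = mapq, mean_baseq_alt = baseq,
      strand_bias_phred = sb, spans_indel = as.numeric(spans),
      mean_read_pos_fraction = rpf, homopolymer_len = as.numeric(hp),
      in_str = as.numeric(in_str), in_low_complexity = as.numeric(in_lc),
      gc_content_101bp = gcw,
      maf_db1 = mafs[, 1], maf_db2 = mafs[, 2], maf_db3 = mafs[, 3],
      maf_db4 = mafs[, 4],
      max_germline_maf = apply(mafs, 1, max),
      cosmic_match = as.numeric(cosmic), cosmic_freq = as.numeric(cfreq),
      is_transition = as.numeric(trans),
      consequence_class = as.numeric(cons),
      base_change_class = as.numeric(bcc))
    if (variant_type == "INDEL") {
      mag <- 1L + rpois(nn, pblend(1.2, pick(1.5, 1.5, 0.2)))
      sign <- ifelse(runif(nn) < 0.5, -1L, 1L)
      df$indel_length <- as.numeric(sign * mag)
      df <- df[, c("label", feature_schema("INDEL"))]
    } else {
      df <- df[, c("label", feature_schema("SNV"))]
    }
    df
  })
}
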