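#' Write call records to a VCF v4.2 file
#'
#' Sites-only single-sample VCF with the package's INFO keys (`DP`, `AC`,
#' `VAF`, and when present `MQALT`, `BQALT`, `SPANIND`, `STATUS`,
#' `CALLERS`, `PRED`, `PPROB`, `REFINE`, `PCHIP`, `CI95LO`, `CI95HI`) and a
#' fixed `GT 0/1` sample column. vcfR reads these files back; the writer is
#' in-package because the installed VCF libraries either gzip
#' unconditionally or require a heavyweight object model for custom INFO
#' keys.
#'
#' @param calls data.frame with at least `chrom,pos,ref,alt`; recognized
#'   extra columns become INFO fields.
#' @param ref_lengths named integer vector of contig lengths.
#' @param path output path.
#' @param sample_name sample column name.
#' @return `path`, invisibly.
#' @export
write_calls_vcf <- function(calls, ref_lengths, path,
                            sample_name = "SAMPLE") {
  info_defs <- c(
    DP = "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    AC = "##INFO=<ID=AC,Number=1,Type=Integer,Description=\"Alt-supporting reads\">",
    VAF = "##INFO=<ID=VAF,Number=1,Type=Float,Description=\"Variant allele fraction\">",
    MQALT = "##INFO=<ID=MQALT,Number=1,Type=Float,Description=\"Mean mapping quality of alt reads\">",
    BQALT = "##INFO=<ID=BQALT,Number=1,Type=Float,Description=\"Mean base quality of alt bases\">",
    SPANIND = "##INFO=<ID=SPANIND,Number=0,Type=Flag,Description=\"Read spans an indel within 5 bp\">",
    STATUS = "##INFO=<ID=STATUS,Number=1,Type=Integer,Description=\"Number of callers identifying the variant\">",
    CALLERS = "##INFO=<ID=CALLERS,Number=.,Type=String,Description=\"Callers identifying the variant\">",
    PRED = "##INFO=<ID=PRED,Number=1,Type=String,Description=\"Predicted class\">",
    PPROB = "##INFO=<ID=PPROB,Number=3,Type=Float,Description=\"Class probabilities CHIP,GERMLINE,ARTIFACT\">",
    REFINE = "##INFO=<ID=REFINE,Number=1,Type=String,Description=\"Refinement flag\">",
    PCHIP = "##INFO=<ID=PCHIP,Number=1,Type=Float,Description=\"Posterior probability of a true clone\">",
    CI95LO = "##INFO=<ID=CI95LO,Number=1,Type=Float,Description=\"Lower 95 percent credible bound for clone VAF\">",
    CI95HI = "##INFO=<ID=CI95HI,Number=1,Type=Float,Description=\"Upper 95 percent credible bound for clone VAF\">")
  colmap <- c(DP = "depth", AC = "alt_count", VAF = "vaf",
              MQALT = "mean_mapq_alt", BQALT = "mean_baseq_alt",
              SPANIND = "spans_indel", STATUS = "status",
              CALLERS = "callers", PRED = "label", PPROB = "pprob",
              REFINE = "refined_flag", PCHIP = "posterior_chip",
              CI95LO = "ci95_lo", CI95HI = "ci95_hi")
  used <- names(colmap)[colmap %in% names(calls)]
  hdr <- c("##fileformat=VCFv4.2",
           "##source=chipmeta",
           sprintf("##contig=<ID=%s,length=%d>", names(ref_lengths),
                   as.integer(ref_lengths)),
           info_defs[used],
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", sample_name, sep = "\t"))
  fmt_val <- function(v) {
    if (is.numeric(v) && !is.integer(v)) sprintf("%.6g", v)
    else as.character(v)
  }
  body <- character(0)
  if (nrow(calls)) {
    calls <- calls[order(match(calls$chrom, names(ref_lengths)),
                         calls$pos), , drop = FALSE]
    info <- vapply(seq_len(nrow(calls)), function(i) {
      parts <- character(0)
      for (k in used) {
        v <- calls[[colmap[[k]]]][i]
        if (k == "SPANIND") {
          if (isTRUE(v)) parts <- c(parts, "SPANIND")
        } else if (!is.na(v)) {
          parts <- c(parts, paste0(k, "=", fmt_val(v)))
        }
      }
      if (length(parts)) paste(parts, collapse = ";") else "."
    }, character(1))
    body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t%s\tGT\t0/1",
                    calls$chrom, as.integer(calls$pos), calls$ref,
                    calls$alt, info)
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an external caller's VCF into a call-record frame
#'
#' Reads VCF v4.2 through vcfR; multiallelic rows are decomposed into one
#' record per ALT allele. `DP`/`AC`/`VAF` INFO keys populate the evidence
#' columns when present (per-record `AC` falls back to `AD`-style FORMAT
#' fields is not attempted; absent values stay `NA` and are recomputed by a
#' targeted pileup downstream).
#'
#' @param path VCF file.
#' @param caller_id identifier recorded in the `caller` column.
#' @return call-record data.frame.
#' @export
read_caller_vcf <- function(path, caller_id) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(fix)      # single-row VCFs drop to vector
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L)
    return(data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      caller = character(), alt_count = integer(),
                      depth = integer(), vaf = numeric(),
                      stringsAsFactors = FALSE))
  info <- v@fix[, "INFO"]
  get_info <- function(key) {
    m <- regmatches(info, regexpr(paste0("(?:^|;)", key, "=([^;]+)"),
                                  info, perl = TRUE))
    out <- rep(NA_character_, length(info))
    hit <- grepl(paste0("(?:^|;)", key, "="), info, perl = TRUE)
    out[hit] <- sub(paste0("^.*?", key, "="), "", m)
    out
  }
  dp <- suppressWarnings(as.integer(get_info("DP")))
  ac <- suppressWarnings(as.integer(get_info("AC")))
  vaf <- suppressWarnings(as.numeric(get_info("VAF")))
  rows <- lapply(seq_len(nrow(fix)), function(i) {
    alts <- strsplit(fix$ALT[i], ",")[[1]]
    data.frame(chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
               ref = fix$REF[i], alt = alts, caller = caller_id,
               alt_count = ac[i], depth = dp[i], vaf = vaf[i],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write intervals as BED (0-based half-open)
#'
#' @param iv data.frame `chrom,start,end` (1-based inclusive in memory).
#' @param path output path.
#' @export
write_bed <- function(iv, path) {
  writeLines(sprintf("%s\t%d\t%d", iv$chrom, as.integer(iv$start) - 1L,
                     as.integer(iv$end)), path)
  invisible(path)
}

#' Read a BED file into 1-based inclusive intervals
#'
#' @param path BED file.
#' @export
read_bed <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  data.frame(chrom = df[[1]], start = as.integer(df[[2]]) + 1L,
             end = as.integer(df[[3]]), stringsAsFactors = FALSE)
}

#' Write/read a reference as FASTA
#'
#' Thin wrappers over Biostrings.
#' @param reference named list of contig sequences.
#' @param path FASTA path.
#' @export
write_reference_fasta <- function(reference, path) {
  x <- Biostrings::DNAStringSet(unlist(reference))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_reference_fasta
#' @export
read_reference_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.list(as.character(x)), sub("\\s.*$", "", names(x)))
}
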