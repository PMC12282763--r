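#' Alignment sets
#'
#' Alignments travel through the package as a plain data.frame with one row
#' per read: `qname`, `flag`, `chrom`, `pos` (1-based leftmost aligned
#' position), `mapq`, `cigar`, `seq`, `qual` (phred+33 string). This is the
#' object the simulator emits and the tracker consumes; [write_sam()] and
#' [read_alignments()] move it through the standard SAM/BAM formats.
#'
#' @name alignments
NULL

#' Write alignments to a SAM file
#'
#' @param aln alignment data.frame (see [alignments]).
#' @param ref_lengths named integer vector of contig lengths (for `@SQ`).
#' @param path output path (`.sam`).
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, ref_lengths, path) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(ref_lengths),
                   as.integer(ref_lengths)))
  ord <- order(match(aln$chrom, names(ref_lengths)), aln$pos)
  aln <- aln[ord, , drop = FALSE]
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                  aln$qname, as.integer(aln$flag), aln$chrom,
                  as.integer(aln$pos), as.integer(aln$mapq), aln$cigar,
                  aln$seq, aln$qual)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read alignments from SAM or BAM
#'
#' SAM input is converted to BAM through Rsamtools and scanned back into the
#' package's alignment data.frame.
#'
#' @param path a `.sam` or `.bam` file.
#' @return alignment data.frame (see [alignments]).
#' @export
read_alignments <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, destination = dest,
                             overwrite = TRUE, indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq", "qual"))
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  data.frame(qname = b$qname, flag = b$flag, chrom = as.character(b$rname),
             pos = b$pos, mapq = b$mapq, cigar = b$cigar,
             seq = as.character(b$seq), qual = as.character(b$qual),
             stringsAsFactors = FALSE)
}

# parse a CIGAR string into (len, op) pairs
cigar_ops <- function(cigar) {
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1]]
  list(len = lens, op = ops)
}

# flag predicates
flag_has <- function(flag, bit) bitwAnd(as.integer(flag), bit) != 0L
is_reverse <- function(flag) flag_has(flag, 16L)
fails_filters <- function(flag) {
  flag_has(flag, 4L) | flag_has(flag, 256L) | flag_has(flag, 512L) |
    flag_has(flag, 1024L) | flag_has(flag, 2048L)
}
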