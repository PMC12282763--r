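#' Genomic variant objects
#'
#' A `gvariant` is the package's currency for a single small variant: contig,
#' 1-based position of the first REF base (VCF convention), REF and ALT allele
#' strings, a derived variant type, and a flag recording whether the allele
#' pair has been normalized (parsimonious and left-aligned).
#'
#' @param chrom contig name.
#' @param pos 1-based position of the first REF base.
#' @param ref reference allele (A/C/G/T string).
#' @param alt alternate allele (A/C/G/T string).
#' @param normalized logical; set by [left_normalize()], not by the user.
#' @return an object of class `gvariant` with fields `chrom`, `pos`, `ref`,
#'   `alt`, `vtype` (one of `"SNV"`, `"MNP"`, `"INS"`, `"DEL"`) and
#'   `normalized`.
#' @examples
#' gvariant("chr1", 100, "C", "T")
#' gvariant("chr1", 100, "CA", "C")   # 1-bp deletion
#' @export
gvariant <- function(chrom, pos, ref, alt, normalized = FALSE) {
  ref <- toupper(as.character(ref))
  alt <- toupper(as.character(alt))
  if (!nzchar(ref) || !nzchar(alt))
    stopf("ref and alt must be non-empty (%s:%s)", chrom, pos)
  if (grepl("[^ACGT]", ref) || grepl("[^ACGT]", alt))
    stopf("symbolic or non-ACGT alleles are not supported (%s:%s %s>%s)",
          chrom, pos, ref, alt)
  if (identical(ref, alt))
    stopf("ref and alt are identical at %s:%s", chrom, pos)
  structure(
    list(chrom = as.character(chrom), pos = as.integer(pos),
         ref = ref, alt = alt,
         vtype = variant_type(ref, alt), normalized = isTRUE(normalized)),
    class = "gvariant")
}

#' @export
print.gvariant <- function(x, ...) {
  cat(sprintf("<gvariant> %s:%d %s>%s [%s]%s\n", x$chrom, x$pos, x$ref,
              x$alt, x$vtype, if (x$normalized) " normalized" else ""))
  invisible(x)
}

#' Derive the variant type from an allele pair
#'
#' @param ref,alt allele strings (vectorized).
#' @return character vector: `"SNV"`, `"MNP"`, `"INS"` or `"DEL"`.
#' @export
variant_type <- function(ref, alt) {
  lr <- nchar(ref); la <- nchar(alt)
  ifelse(lr == la, ifelse(lr == 1L, "SNV", "MNP"),
         ifelse(lr < la, "INS", "DEL"))
}

#' Reference window
#'
#' A slice of reference sequence with its 1-based start coordinate, the
#' minimal context normalization needs.
#'
#' @param seq character scalar of reference bases.
#' @param start 1-based coordinate of the first base of `seq`.
#' @param chrom contig name (optional, for error messages).
#' @export
ref_window <- function(seq, start = 1L, chrom = NA_character_) {
  list(seq = toupper(as.character(seq)), start = as.integer(start),
       chrom = chrom)
}

win_base <- function(w, pos, len = 1L) {
  i <- pos - w$start + 1L
  if (i < 1L || i + len - 1L > nchar(w$seq))
    stopf("reference window (start %d, %d bp) does not cover %d..%d: window truncated",
          w$start, nchar(w$seq), pos, pos + len - 1L)
  substr(w$seq, i, i + len - 1L)
}

#' Left-normalize a variant
#'
#' Produces the parsimonious, left-aligned representation of a variant
#' (standard VCF normalization): shared suffix bases are trimmed, empty
#' alleles are re-padded by extending left along the reference, and the
#' shared prefix is reduced to the single anchor base for indels. SNVs are
#' fixed points. Re-applying is a no-op.
#'
#' @param v a [gvariant()].
#' @param window a [ref_window()] covering the variant and sufficient
#'   upstream context (50 bp upstream, or to the contig start, suffices for
#'   ordinary indels).
#' @return a normalized `gvariant`.
#' @export
left_normalize <- function(v, window) {
  stopifnot(inherits(v, "gvariant"))
  obs <- win_base(window, v$pos, nchar(v$ref))
  if (obs != v$ref)
    stopf("REF allele %s does not match reference %s at %s:%d",
          v$ref, obs, v$chrom, v$pos)
  pos <- v$pos; ref <- v$ref; alt <- v$alt
  repeat {
    lr <- nchar(ref); la <- nchar(alt)
    if (lr > 0L && la > 0L &&
        substr(ref, lr, lr) == substr(alt, la, la) &&
        !(lr == 1L && la == 1L)) {
      ref <- substr(ref, 1L, lr - 1L)
      alt <- substr(alt, 1L, la - 1L)
      if (nzchar(ref) && nzchar(alt)) next
    }
    if (!nzchar(ref) || !nzchar(alt)) {
      if (pos == 1L && window$start == 1L)
        stopf("variant at %s:%d cannot be left-extended past the contig start",
              v$chrom, v$pos)
      pos <- pos - 1L
      b <- win_base(window, pos)
      ref <- paste0(b, ref)
      alt <- paste0(b, alt)
      next
    }
    break
  }
  # trim shared prefix down to a single anchor base
  while (nchar(ref) >= 2L && nchar(alt) >= 2L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  gvariant(v$chrom, pos, ref, alt, normalized = TRUE)
}

#' Split a multi-nucleotide polymorphism into SNVs
#'
#' Emits one SNV per position at which the REF and ALT bases differ,
#' positions ascending; internally matching bases emit nothing. An SNV
#' passes through as a singleton list.
#'
#' @param v a [gvariant()] of type SNV or MNP.
#' @return list of `gvariant` SNVs.
#' @export
split_mnp <- function(v) {
  stopifnot(inherits(v, "gvariant"))
  if (v$vtype %in% c("INS", "DEL"))
    stopf("split_mnp() accepts SNV/MNP input, got %s at %s:%d",
          v$vtype, v$chrom, v$pos)
  if (v$vtype == "SNV") return(list(v))
  rb <- strsplit(v$ref, "")[[1]]
  ab <- strsplit(v$alt, "")[[1]]
  idx <- which(rb != ab)
  lapply(idx, function(i)
    gvariant(v$chrom, v$pos + i - 1L, rb[i], ab[i], normalized = TRUE))
}

#' Canonical variant key
#'
#' Normalizes a variant and returns the string key
#' `chrom:pos:ref:alt` under which equivalent representations of the same
#' mutation collide. MNPs must be split with [split_mnp()] first.
#'
#' @inheritParams left_normalize
#' @return character scalar key.
#' @export
variant_key <- function(v, window) {
  stopifnot(inherits(v, "gvariant"))
  if (v$vtype == "MNP")
    stopf("variant_key() does not accept MNPs; split with split_mnp() first (%s:%d)",
          v$chrom, v$pos)
  n <- if (v$normalized) v else left_normalize(v, window)
  paste(n$chrom, n$pos, n$ref, n$alt, sep = ":")
}

#' Apply a variant to a reference window
#'
#' Returns the mutated sequence of the window; used as the semantic oracle
#' that normalization preserves the encoded mutation.
#'
#' @inheritParams left_normalize
#' @return character scalar, the window sequence with the variant applied.
#' @export
apply_variant <- function(v, window) {
  i <- v$pos - window$start + 1L
  stopifnot(i >= 1L, i + nchar(v$ref) - 1L <= nchar(window$seq))
  paste0(substr(window$seq, 1L, i - 1L), v$alt,
         substr(window$seq, i + nchar(v$ref), nchar(window$seq)))
}

# Normalize a (chrom,pos,ref,alt) data.frame against a reference (named list
# of contig sequences); rows whose REF does not match are dropped with a
# warning tally. Returns the frame with normalized alleles plus a `key`
# column. MNPs are split into SNV rows first.
normalize_call_frame <- function(df, reference, upstream = 60L) {
  if (nrow(df) == 0L) {
    df$key <- character(0)
    return(df)
  }
  out <- vector("list", nrow(df))
  dropped <- 0L
  for (i in seq_len(nrow(df))) {
    row <- df[i, , drop = FALSE]
    seqc <- reference[[row$chrom]]
    if (is.null(seqc)) { dropped <- dropped + 1L; next }
    v <- tryCatch(gvariant(row$chrom, row$pos, row$ref, row$alt),
                  error = function(e) NULL)
    if (is.null(v)) { dropped <- dropped + 1L; next }
    ws <- max(1L, v$pos - upstream)
    we <- min(nchar(seqc), v$pos + nchar(v$ref) + 5L)
    w <- ref_window(substr(seqc, ws, we), ws, row$chrom)
    parts <- tryCatch({
      vs <- if (v$vtype %in% c("SNV", "MNP")) split_mnp(v) else list(v)
      lapply(vs, function(x) {
        n <- left_normalize(x, w)
        cbind(row[setdiff(names(row), c("chrom", "pos", "ref", "alt"))],
              data.frame(chrom = n$chrom, pos = n$pos, ref = n$ref,
                         alt = n$alt,
                         key = paste(n$chrom, n$pos, n$ref, n$alt, sep = ":"),
                         stringsAsFactors = FALSE))
      })
    }, error = function(e) NULL)
    if (is.null(parts)) { dropped <- dropped + 1L; next }
    out[[i]] <- do.call(rbind, parts)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (dropped > 0L)
    warnf("%d record(s) failed normalization (reference mismatch or invalid alleles) and were skipped", dropped)
  if (is.null(res)) {
    res <- df[0, , drop = FALSE]
    res$key <- character(0)
  }
  attr(res, "n_dropped") <- dropped
  rownames(res) <- NULL
  res
}
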