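#' Pileup configuration
#'
#' Thresholds for the permissive pileup engine: bases below
#' `min_base_quality` (default phred 13) are not counted toward alleles, at
#' most `depth_cap` reads (default 1000) are tallied per position in stream
#' order, and reads below `min_mapq` are excluded entirely.
#'
#' @param min_base_quality phred floor for counted bases.
#' @param depth_cap maximum reads tallied per position.
#' @param min_mapq mapping-quality floor for counted reads.
#' @export
pileup_config <- function(min_base_quality = 13L, depth_cap = 1000L,
                          min_mapq = 0L) {
  stopifnot(min_base_quality >= 0, depth_cap >= 1)
  structure(list(min_base_quality = as.integer(min_base_quality),
                 depth_cap = as.integer(depth_cap),
                 min_mapq = as.integer(min_mapq)),
            class = "pileup_config")
}

# Expand alignments into per-base / per-indel events.
# Returns a data.table: rid, pos, kind (B base, I insertion anchor,
# D deletion anchor, S deletion-spanned position), base, qual, fwd, mapq, rpf.
read_events <- function(aln) {
  n <- nrow(aln)
  if (n == 0L)
    return(data.table::data.table(rid = integer(), chrom = character(),
                                  pos = integer(), kind = character(),
                                  base = character(), qual = integer(),
                                  fwd = logical(), mapq = integer(),
                                  rpf = numeric()))
  simple <- aln$cigar == sprintf("%dM", nchar(aln$seq))
  pieces <- list()
  if (any(simple)) {
    s <- aln[simple, , drop = FALSE]
    rid_s <- which(simple)
    L <- nchar(s$seq)
    rid <- rep(rid_s, L)
    off <- sequence(L)                       # 1..L per read
    pieces[[1]] <- data.table::data.table(
      rid = rid,
      chrom = rep(s$chrom, L),
      pos = rep(s$pos, L) + off - 1L,
      kind = "B",
      base = unlist(strsplit(s$seq, ""), use.names = FALSE),
      qual = as.integer(charToRaw(paste(s$qual, collapse = ""))) - 33L,
      fwd = rep(!is_reverse(s$flag), L),
      mapq = rep(s$mapq, L),
      rpf = (off - 0.5) / rep(L, L))
  }
  cx <- which(!simple)
  for (i in cx) {
    co <- cigar_ops(aln$cigar[i])
    qlen <- nchar(aln$seq[i])
    quals <- as.integer(charToRaw(aln$qual[i])) - 33L
    bases <- strsplit(aln$seq[i], "")[[1]]
    fwd <- !is_reverse(aln$flag[i])
    rp <- aln$pos[i]; qp <- 1L
    ev <- list()
    for (j in seq_along(co$op)) {
      len <- co$len[j]; op <- co$op[j]
      if (op %in% c("M", "=", "X")) {
        ev[[length(ev) + 1L]] <- data.table::data.table(
          pos = rp + seq_len(len) - 1L, kind = "B",
          base = bases[qp + seq_len(len) - 1L],
          qual = quals[qp + seq_len(len) - 1L],
          rpf = (qp + seq_len(len) - 1.5) / qlen)
        rp <- rp + len; qp <- qp + len
      } else if (op == "I") {
        ev[[length(ev) + 1L]] <- data.table::data.table(
          pos = rp - 1L, kind = "I",
          base = paste(bases[qp + seq_len(len) - 1L], collapse = ""),
          qual = quals[qp - 1L], rpf = (qp - 1.5) / qlen)
        qp <- qp + len
      } else if (op == "D") {
        ev[[length(ev) + 1L]] <- data.table::data.table(
          pos = rp - 1L, kind = "D", base = as.character(len),
          qual = quals[qp - 1L], rpf = (qp - 1.5) / qlen)
        if (len > 0L)
          ev[[length(ev) + 1L]] <- data.table::data.table(
            pos = rp + seq_len(len) - 1L, kind = "S", base = "*",
            qual = NA_integer_, rpf = NA_real_)
        rp <- rp + len
      } else if (op == "S") {
        qp <- qp + len
      } else if (op == "N") {
        rp <- rp + len
      }                                       # H/P consume nothing tracked
    }
    if (length(ev)) {
      e <- data.table::rbindlist(ev)
      e[, `:=`(rid = i, chrom = aln$chrom[i], fwd = fwd,
               mapq = aln$mapq[i])]
      pieces[[length(pieces) + 1L]] <- e
    }
  }
  ev <- data.table::rbindlist(pieces, use.names = TRUE, fill = TRUE)
  data.table::setorder(ev, chrom, pos, rid)
  ev
}

#' Scan alignments for positions with alternative-allele evidence
#'
#' The permissive tracking pass: every position where at least one counted
#' read carries a non-reference base or an indel is reported, together with
#' the evidence attributes the downstream classifier consumes. Bases below
#' the quality floor, and unmapped / secondary / duplicate / QC-fail /
#' supplementary reads, are excluded; at most `depth_cap` reads are tallied
#' per position, first-come in coordinate order.
#'
#' @param aln alignment data.frame (see [alignments]), coordinate-sorted.
#' @param reference named list (or character vector) of contig sequences.
#' @param region optional `list(chrom=, start=, end=)` restricting the scan.
#' @param cfg a [pileup_config()].
#' @return a data.frame with one row per (position, alternative allele):
#'   `chrom`, `pos`, `ref_base`, `depth`, `allele` (base, `I:SEQ` or `D:L`),
#'   `count`, `fwd_count`, `ref_count`, `ref_fwd_count`, `mean_mapq_alt`,
#'   `mean_baseq_alt`, `mean_read_pos_fraction`, `spans_indel`.
#' @export
pileup_sites <- function(aln, reference, region = NULL,
                         cfg = pileup_config()) {
  reference <- as.list(reference)
  empty <- data.frame(chrom = character(), pos = integer(),
                      ref_base = character(), depth = integer(),
                      allele = character(), count = integer(),
                      fwd_count = integer(), ref_count = integer(),
                      ref_fwd_count = integer(), mean_mapq_alt = numeric(),
                      mean_baseq_alt = numeric(),
                      mean_read_pos_fraction = numeric(),
                      spans_indel = logical(), stringsAsFactors = FALSE)
  if (nrow(aln) == 0L) return(empty)
  # sortedness check within contig, in input order
  for (ct in unique(aln$chrom)) {
    p <- aln$pos[aln$chrom == ct]
    if (is.unsorted(p)) stopf("alignments are not coordinate-sorted (contig %s)", ct)
  }
  if (!is.null(region)) {
    if (!region$chrom %in% names(reference))
      stopf("region contig %s not present in the reference", region$chrom)
    clen <- nchar(reference[[region$chrom]])
    if (region$start < 1L || region$end > clen || region$start > region$end)
      stopf("region %s:%d-%d outside contig bounds (1-%d)",
            region$chrom, region$start, region$end, clen)
  }
  keep <- !fails_filters(aln$flag) & aln$mapq >= cfg$min_mapq
  aln <- aln[keep, , drop = FALSE]
  if (nrow(aln) == 0L) return(empty)
  ev <- read_events(aln)
  if (!is.null(region))
    ev <- ev[ev$chrom == region$chrom & ev$pos >= region$start &
               ev$pos <= region$end, ]
  if (nrow(ev) == 0L) return(empty)

  pos <- kind <- rid <- qual <- base <- covered <- counted <- NULL # NSE
  # depth-cap per position in stream (rid) order, over coverage events
  ev[, covered := kind %in% c("B", "S")]
  ev[covered == TRUE, counted := {
    r <- sort(unique(rid))
    rid %in% r[seq_len(min(length(r), cfg$depth_cap))]
  }, by = c("chrom", "pos")]
  ev[covered == FALSE, counted := TRUE]      # indel anchors ride their read
  cov <- ev[covered == TRUE & counted == TRUE]
  depth_tab <- cov[, list(depth = .N), by = c("chrom", "pos")]

  bq <- cfg$min_base_quality
  ref_base <- allele <- NULL # NSE
  bev <- ev[kind == "B" & counted == TRUE & qual >= bq]
  bev[, ref_base := substring(reference[[chrom[1]]], pos, pos), by = chrom]
  alt_b <- bev[base != ref_base & base %in% c("A", "C", "G", "T")]
  ref_tab <- bev[base == ref_base,
                 list(ref_count = .N, ref_fwd_count = sum(fwd)),
                 by = c("chrom", "pos")]
  iev <- ev[kind %in% c("I", "D") & counted == TRUE]
  if (nrow(iev)) {
    iev[, allele := paste0(kind, ":", base)]
    iev[, ref_base := substring(reference[[chrom[1]]], pos, pos), by = chrom]
  }
  if (nrow(alt_b)) alt_b[, allele := base]
  sel <- c("chrom", "pos", "ref_base", "allele", "fwd", "mapq", "qual", "rpf")
  alleles <- data.table::rbindlist(list(
    if (nrow(alt_b)) alt_b[, sel, with = FALSE],
    if (nrow(iev)) iev[, sel, with = FALSE]),
    use.names = TRUE)
  if (is.null(alleles) || nrow(alleles) == 0L) return(empty)
  agg <- alleles[, list(count = .N, fwd_count = sum(fwd),
                        mean_mapq_alt = mean(mapq),
                        mean_baseq_alt = mean(qual),
                        mean_read_pos_fraction = mean(rpf)),
                 by = c("chrom", "pos", "ref_base", "allele")]
  agg <- merge(agg, depth_tab, by = c("chrom", "pos"), all.x = TRUE)
  agg <- merge(agg, ref_tab, by = c("chrom", "pos"), all.x = TRUE)
  agg$ref_count[is.na(agg$ref_count)] <- 0L
  agg$ref_fwd_count[is.na(agg$ref_fwd_count)] <- 0L
  agg$depth[is.na(agg$depth)] <- agg$count[is.na(agg$depth)]
  # spans_indel: any tallied read carries an indel anchored within +/- 5 bp
  anchors <- unique(ev[kind %in% c("I", "D") & counted == TRUE,
                       c("chrom", "pos")])
  agg$spans_indel <- FALSE
  if (nrow(anchors)) {
    for (ct in unique(anchors$chrom)) {
      ap <- anchors$pos[anchors$chrom == ct]
      sel <- agg$chrom == ct
      agg$spans_indel[sel] <- vapply(agg$pos[sel], function(p)
        any(abs(ap - p) <= 5L), logical(1))
    }
  }
  data.table::setorder(agg, chrom, pos, allele)
  out <- as.data.frame(agg)
  out[, c("chrom", "pos", "ref_base", "depth", "allele", "count",
          "fwd_count", "ref_count", "ref_fwd_count", "mean_mapq_alt",
          "mean_baseq_alt", "mean_read_pos_fraction", "spans_indel")]
}

#' Pick the alternative allele at a multiallelic site
#'
#' Returns the allele with the most supporting reads; exact ties are broken
#' by a seeded uniform draw among the tied set, so the choice is
#' reproducible given the seed.
#'
#' @param counts named integer vector of supporting-read counts per allele.
#' @param seed integer seed for tie-breaking.
#' @return name of the chosen allele.
#' @export
resolve_multiallelic <- function(counts, seed = 1L) {
  if (length(counts) == 0L)
    stopf("resolve_multiallelic() requires at least one alternative allele")
  if (length(counts) == 1L) return(names(counts))
  top <- names(counts)[counts == max(counts)]
  if (length(top) == 1L) return(top)
  with_seed(seed, sample(top, 1L))
}

# allele code at a pileup row -> normalized-ready (ref, alt) pair
allele_to_variant <- function(chrom, pos, ref_base, allele, reference) {
  if (startsWith(allele, "I:")) {
    list(ref = ref_base, alt = paste0(ref_base, sub("^I:", "", allele)))
  } else if (startsWith(allele, "D:")) {
    L <- as.integer(sub("^D:", "", allele))
    list(ref = substr(reference[[chrom]], pos, pos + L), alt = ref_base)
  } else {
    list(ref = ref_base, alt = allele)
  }
}

#' Genotype candidate sites into tracker call records
#'
#' Resolves multiallelic sites (most supporting reads, seeded tie-break),
#' applies the minimum alt-read threshold (default 1: the tracker is
#' deliberately permissive and reports single-read evidence), and emits one
#' call record per retained site with its evidence attributes.
#'
#' @param sites output of [pileup_sites()].
#' @param reference named list of contig sequences.
#' @param min_alt_reads minimum supporting reads (default 1).
#' @param seed seed for multiallelic tie-breaking.
#' @return a call-record data.frame: `chrom`, `pos`, `ref`, `alt`, `caller`,
#'   `alt_count`, `depth`, `vaf`, plus the pileup evidence columns.
#' @export
genotype_candidates <- function(sites, reference, min_alt_reads = 1L,
                                seed = 1L) {
  reference <- as.list(reference)
  cols <- c("chrom", "pos", "ref", "alt", "caller", "alt_count", "depth",
            "vaf", "alt_fwd", "ref_count", "ref_fwd", "mean_mapq_alt",
            "mean_baseq_alt", "mean_read_pos_fraction", "spans_indel")
  if (nrow(sites) == 0L) {
    out <- data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), caller = character(),
                      alt_count = integer(), depth = integer(),
                      vaf = numeric(), alt_fwd = integer(),
                      ref_count = integer(), ref_fwd = integer(),
                      mean_mapq_alt = numeric(), mean_baseq_alt = numeric(),
                      mean_read_pos_fraction = numeric(),
                      spans_indel = logical(), stringsAsFactors = FALSE)
    return(out)
  }
  keys <- paste(sites$chrom, sites$pos)
  rows <- lapply(split(seq_len(nrow(sites)), keys), function(idx) {
    s <- sites[idx, , drop = FALSE]
    counts <- setNames(s$count, s$allele)
    chosen <- resolve_multiallelic(counts, seed = seed + s$pos[1])
    s[s$allele == chosen, , drop = FALSE]
  })
  g <- do.call(rbind, rows)
  g <- g[g$count >= min_alt_reads, , drop = FALSE]
  if (nrow(g) == 0L) return(genotype_candidates(sites[0, ], reference))
  va <- mapply(allele_to_variant, g$chrom, g$pos, g$ref_base, g$allele,
               MoreArgs = list(reference = reference), SIMPLIFY = FALSE)
  out <- data.frame(
    chrom = g$chrom, pos = g$pos,
    ref = vapply(va, `[[`, character(1), "ref"),
    alt = vapply(va, `[[`, character(1), "alt"),
    caller = "TRACKER",
    alt_count = g$count, depth = g$depth, vaf = g$count / g$depth,
    alt_fwd = g$fwd_count, ref_count = g$ref_count,
    ref_fwd = g$ref_fwd_count, mean_mapq_alt = g$mean_mapq_alt,
    mean_baseq_alt = g$mean_baseq_alt,
    mean_read_pos_fraction = g$mean_read_pos_fraction,
    spans_indel = g$spans_indel, stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Track variants in one pass
#'
#' Convenience wrapper: [pileup_sites()] followed by
#' [genotype_candidates()].
#'
#' @inheritParams pileup_sites
#' @inheritParams genotype_candidates
#' @return call-record data.frame (see [genotype_candidates()]).
#' @export
track_variants <- function(aln, reference, region = NULL,
                           cfg = pileup_config(), min_alt_reads = 1L,
                           seed = 1L) {
  genotype_candidates(pileup_sites(aln, reference, region, cfg),
                      reference, min_alt_reads, seed)
}
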