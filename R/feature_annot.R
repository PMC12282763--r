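#' Consequence classes and their ordinal encoding
#'
#' Fixed, documented ordering used wherever a consequence becomes a numeric
#' feature. Tree models are insensitive to the ordering itself; it only has
#' to be deterministic and frozen.
#'
#' @return named integer vector mapping class name to code.
#' @export
consequence_levels <- function() {
  c(noncoding = 0L, synonymous = 1L, missense = 2L, inframe_indel = 3L,
    stop_loss = 4L, start_loss = 5L, essential_splice = 6L,
    frameshift = 7L, nonsense = 8L)
}

functional_classes <- function() {
  c("missense", "nonsense", "stop_loss", "start_loss", "inframe_indel",
    "frameshift", "essential_splice")
}

#' Read a transcript/gene model table
#'
#' Tab-separated with header columns `transcript`, `gene`, `chrom`,
#' `strand`, `exon_starts`, `exon_ends` (comma-separated 1-based inclusive
#' intervals), `canonical` (0/1). The CDS is taken to span the exons end to
#' end (toy transcripts carry no UTRs). Validates exon ordering and that the
#' CDS length is divisible by 3.
#'
#' @param path TSV file.
#' @return validated gene-model data.frame.
#' @export
read_gene_model <- function(path) {
  gm <- read.delim(path, stringsAsFactors = FALSE)
  validate_gene_model(gm)
}

#' @rdname read_gene_model
#' @param gm in-memory gene-model data.frame with the same columns.
#' @export
validate_gene_model <- function(gm) {
  need <- c("transcript", "gene", "chrom", "strand", "exon_starts",
            "exon_ends", "canonical")
  miss <- setdiff(need, names(gm))
  if (length(miss)) stopf("gene model lacks column(s): %s",
                          paste(miss, collapse = ", "))
  for (i in seq_len(nrow(gm))) {
    st <- as.integer(strsplit(as.character(gm$exon_starts[i]), ",")[[1]])
    en <- as.integer(strsplit(as.character(gm$exon_ends[i]), ",")[[1]])
    if (length(st) != length(en) || any(en < st))
      stopf("transcript %s: malformed exon intervals", gm$transcript[i])
    if (is.unsorted(st, strictly = TRUE) || any(st[-1] <= en[-length(en)]))
      stopf("transcript %s: exons overlap or are unordered", gm$transcript[i])
    if (sum(en - st + 1L) %% 3L != 0L)
      stopf("transcript %s: CDS length not divisible by 3", gm$transcript[i])
  }
  gm
}

exon_list <- function(gm_row) {
  data.frame(
    start = as.integer(strsplit(as.character(gm_row$exon_starts), ",")[[1]]),
    end = as.integer(strsplit(as.character(gm_row$exon_ends), ",")[[1]]))
}

# CDS sequence (already on transcript strand) and the CDS offset of a
# genomic position
cds_context <- function(gm_row, reference) {
  ex <- exon_list(gm_row)
  seqs <- vapply(seq_len(nrow(ex)), function(i)
    substr(reference[[gm_row$chrom]], ex$start[i], ex$end[i]), character(1))
  cds <- paste(seqs, collapse = "")
  if (identical(gm_row$strand, "-"))
    cds <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
  list(exons = ex, cds = cds)
}

genomic_to_cds <- function(gm_row, ex, pos) {
  if (!any(pos >= ex$start & pos <= ex$end)) return(NA_integer_)
  cum <- cumsum(c(0L, ex$end - ex$start + 1L))
  i <- which(pos >= ex$start & pos <= ex$end)[1]
  fwd <- cum[i] + (pos - ex$start[i] + 1L)
  if (identical(gm_row$strand, "-")) sum(ex$end - ex$start + 1L) - fwd + 1L
  else fwd
}

translate1 <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  unname(gc[codon])
}

#' Classify the protein-level consequence of a variant
#'
#' A minimal codon-based annotator over the package's transcript model:
#' translation on the transcript strand decides synonymous / missense /
#' nonsense / stop-loss / start-loss for SNVs; indel length mod 3 decides
#' frameshift vs in-frame; positions within 2 bp of an intron boundary are
#' essential-splice; positions outside every transcript are noncoding.
#' MNPs must be split first.
#'
#' @param v a normalized [gvariant()] (SNV, INS or DEL).
#' @param genes gene-model data.frame (see [read_gene_model()]).
#' @param reference named list of contig sequences.
#' @return character scalar, one of `names(consequence_levels())`.
#' @export
classify_consequence <- function(v, genes, reference) {
  stopifnot(inherits(v, "gvariant"))
  if (v$vtype == "MNP")
    stopf("classify_consequence() expects split SNVs, not MNPs")
  g <- genes[genes$chrom == v$chrom, , drop = FALSE]
  # indels occupy pos+1 .. pos+len(ref)-1 (pos is the anchor base)
  span <- if (v$vtype == "SNV") c(v$pos, v$pos)
          else c(v$pos + 1L, max(v$pos + 1L, v$pos + nchar(v$ref) - 1L))
  for (i in seq_len(nrow(g))) {
    row <- g[i, , drop = FALSE]
    ex <- exon_list(row)
    tx_start <- min(ex$start); tx_end <- max(ex$end)
    if (span[2] < tx_start || span[1] > tx_end) next
    # essential splice: first/last 2 intronic bases at each internal boundary
    if (nrow(ex) > 1L) {
      donor <- c(outer(ex$end[-nrow(ex)], 1:2, `+`),
                 outer(ex$start[-1], 1:2, `-`))
      if (any(donor >= span[1] & donor <= span[2]))
        return("essential_splice")
    }
    in_exon <- any(span[1] >= ex$start & span[2] <= ex$end &
                     (span[1] >= ex$start & span[2] <= ex$end))
    hit_exon <- any(!(span[2] < ex$start | span[1] > ex$end))
    if (!hit_exon) next                      # intronic, away from boundaries
    if (v$vtype %in% c("INS", "DEL")) {
      delta <- nchar(v$alt) - nchar(v$ref)
      return(if (abs(delta) %% 3L == 0L) "inframe_indel" else "frameshift")
    }
    ctx <- cds_context(row, reference)
    cpos <- genomic_to_cds(row, ctx$exons, v$pos)
    if (is.na(cpos)) next
    base <- v$alt
    if (identical(row$strand, "-"))
      base <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(base)))
    codon_i <- (cpos - 1L) %/% 3L
    off <- (cpos - 1L) %% 3L
    ref_codon <- substr(ctx$cds, codon_i * 3L + 1L, codon_i * 3L + 3L)
    alt_codon <- ref_codon
    substr(alt_codon, off + 1L, off + 1L) <- base
    aa_ref <- translate1(ref_codon); aa_alt <- translate1(alt_codon)
    if (codon_i == 0L && aa_alt != "M") return("start_loss")
    if (aa_ref == aa_alt) return("synonymous")
    if (aa_alt == "*") return("nonsense")
    if (aa_ref == "*") return("stop_loss")
    return("missense")
  }
  "noncoding"
}

#' Keep only variants with predicted functional effect
#'
#' Retains missense, nonsense, stop-loss, start-loss, in-frame indel,
#' frameshift and essential-splice calls; drops synonymous and noncoding
#' ones. Input order is preserved.
#'
#' @param df data.frame with a `consequence` column.
#' @return the retained subset.
#' @export
functional_filter <- function(df) {
  df[df$consequence %in% functional_classes(), , drop = FALSE]
}

#' Sequence-context features at a position
#'
#' Homopolymer length (longest single-base run containing or immediately
#' adjacent to the position), short-tandem-repeat membership (configured
#' interval, or a detected exact tandem of >= 3 copies of a 2-6 bp unit
#' overlapping the position), low-complexity interval membership, and GC
#' fraction of the 101-bp window (clipped at contig edges).
#'
#' @param chrom,pos position.
#' @param reference named list of contig sequences.
#' @param str_regions,low_complexity optional interval data.frames
#'   (`chrom`, `start`, `end`, 1-based inclusive).
#' @return list with `homopolymer_len`, `in_str`, `in_low_complexity`,
#'   `gc_content_101bp`, `clipped`.
#' @export
context_features <- function(chrom, pos, reference, str_regions = NULL,
                             low_complexity = NULL) {
  seqc <- reference[[chrom]]
  if (is.null(seqc)) stopf("contig %s not in reference", chrom)
  L <- nchar(seqc)
  ws <- max(1L, pos - 50L); we <- min(L, pos + 50L)
  win <- substr(seqc, ws, we)
  clipped <- (we - ws + 1L) < 101L
  bases <- strsplit(win, "")[[1]]
  r <- rle(bases)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  p_in_win <- pos - ws + 1L
  # runs containing or immediately adjacent to the position
  touch <- starts <= p_in_win + 1L & ends >= p_in_win - 1L
  hp <- max(r$lengths[touch])
  gc <- mean(bases %in% c("G", "C"))
  in_interval <- function(iv) {
    if (is.null(iv) || nrow(iv) == 0L) return(FALSE)
    any(iv$chrom == chrom & iv$start <= pos & iv$end >= pos)
  }
  in_str <- in_interval(str_regions) || detect_str(win, p_in_win)
  list(homopolymer_len = as.integer(hp), in_str = in_str,
       in_low_complexity = in_interval(low_complexity),
       gc_content_101bp = gc, clipped = clipped)
}

# exact tandem of >=3 copies, unit 2-6 bp, overlapping the focal offset
detect_str <- function(win, p) {
  n <- nchar(win)
  for (u in 2:6) {
    for (s in max(1L, p - 3L * u + 1L):p) {
      if (s + 3L * u - 1L > n) next
      unit <- substr(win, s, s + u - 1L)
      if (length(unique(strsplit(unit, "")[[1]])) == 1L) next # homopolymer
      k <- 1L
      while (s + (k + 1L) * u - 1L <= n &&
             substr(win, s + k * u, s + (k + 1L) * u - 1L) == unit)
        k <- k + 1L
      if (k >= 3L && s + k * u - 1L >= p) return(TRUE)
    }
  }
  FALSE
}

#' Phred-scaled strand-bias score
#'
#' Fisher's exact test on the 2x2 table of forward/reverse counts for alt
#' vs reference reads, reported as -10*log10(p).
#'
#' @param alt_fwd,alt_rev,ref_fwd,ref_rev integer counts.
#' @return non-negative numeric.
#' @export
strand_bias_phred <- function(alt_fwd, alt_rev, ref_fwd, ref_rev) {
  m <- matrix(c(alt_fwd, alt_rev, ref_fwd, ref_rev), nrow = 2)
  p <- fisher.test(m)$p.value
  max(0, -10 * log10(max(p, 1e-300)))
}

# 6-level collapsed substitution class keyed on the pyrimidine strand:
# C>A=0, C>G=1, C>T=2, T>A=3, T>C=4, T>G=5
base_change_class <- function(ref, alt) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  if (ref %in% c("A", "G")) { ref <- comp[[ref]]; alt <- comp[[alt]] }
  idx <- c("C>A" = 0L, "C>G" = 1L, "C>T" = 2L,
           "T>A" = 3L, "T>C" = 4L, "T>G" = 5L)
  idx[[paste0(ref, ">", alt)]]
}

is_transition <- function(ref, alt) {
  paste0(ref, alt) %in% c("AG", "GA", "CT", "TC")
}

#' Resource tables for database-derived features
#'
#' Bundles the germline-frequency tables (four named slots), a somatic
#' catalogue with per-variant sample counts, the known-CHIP key set, driver
#' genes and driver mutations, and low-complexity / STR intervals. All
#' variant-keyed lookups are exact normalized-key matches; missing entries
#' read as 0 / FALSE.
#'
#' @param germline named list of up to 4 data.frames with columns
#'   `chrom,pos,ref,alt,maf`.
#' @param cosmic data.frame `chrom,pos,ref,alt,sample_count`.
#' @param known_chip data.frame `chrom,pos,ref,alt`.
#' @param driver_genes character vector of gene symbols.
#' @param driver_mutations data.frame `chrom,pos,ref,alt`.
#' @param low_complexity,str_regions interval data.frames
#'   (`chrom,start,end`, 1-based inclusive).
#' @return object of class `resource_tables`.
#' @export
resource_tables <- function(germline = list(), cosmic = NULL,
                            known_chip = NULL, driver_genes = character(),
                            driver_mutations = NULL, low_complexity = NULL,
                            str_regions = NULL) {
  keyify <- function(df) {
    if (is.null(df) || nrow(df) == 0L) return(character(0))
    paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
  }
  g <- vector("list", 4L)
  for (i in seq_len(4L)) {
    df <- if (i <= length(germline)) germline[[i]] else NULL
    g[[i]] <- if (is.null(df) || nrow(df) == 0L) setNames(numeric(0), character(0))
              else {
                stopifnot(all(df$maf >= 0 & df$maf <= 1))
                setNames(df$maf, keyify(df))
              }
  }
  names(g) <- paste0("db", seq_len(4L))
  cz <- if (is.null(cosmic) || nrow(cosmic) == 0L) setNames(numeric(0), character(0))
        else {
          stopifnot(all(cosmic$sample_count >= 1))
          setNames(cosmic$sample_count, keyify(cosmic))
        }
  structure(list(
    germline = g,
    cosmic = cz,
    known_chip = keyify(known_chip),
    driver_genes = driver_genes,
    driver_mutations = keyify(driver_mutations),
    low_complexity = low_complexity,
    str_regions = str_regions), class = "resource_tables")
}

lookup0 <- function(tab, key) {
  v <- unname(tab[key])
  ifelse(is.na(v), 0, v)
}

#' Feature schema
#'
#' The fixed, ordered predictor list consumed by the classifiers: 26
#' features for SNVs, 24 for indels (the indel schema drops the
#' substitution-specific features and adds the signed indel length). The
#' same schema is written to `inst/extdata/feature_schema.json`.
#'
#' @param variant_type `"SNV"` or `"INDEL"`.
#' @return character vector of feature names, in order.
#' @export
feature_schema <- function(variant_type = c("SNV", "INDEL")) {
  variant_type <- match.arg(variant_type)
  base <- c("status_meta", "called_by_tracker", "called_by_caller_a",
            "called_by_caller_b", "depth", "alt_count", "vaf",
            "mean_mapq_alt", "mean_baseq_alt", "strand_bias_phred",
            "spans_indel", "mean_read_pos_fraction", "homopolymer_len",
            "in_str", "in_low_complexity", "gc_content_101bp",
            "maf_db1", "maf_db2", "maf_db3", "maf_db4", "max_germline_maf",
            "cosmic_match", "cosmic_freq", "is_transition",
            "consequence_class", "base_change_class")
  if (variant_type == "SNV") return(base)
  c(setdiff(base, c("is_transition", "base_change_class",
                    "mean_read_pos_fraction")), "indel_length")
}

#' Assemble the feature vector for one merged call
#'
#' @param mc one row of a merged-call data.frame (see [merge_callsets()]):
#'   needs `chrom,pos,ref,alt,key,status,callers,alt_count,depth,vaf` and
#'   the pileup evidence columns (`alt_fwd`, `ref_count`, `ref_fwd`,
#'   `mean_mapq_alt`, `mean_baseq_alt`, `mean_read_pos_fraction`,
#'   `spans_indel`).
#' @param consequence consequence class string.
#' @param rt a [resource_tables()].
#' @param reference named list of contig sequences.
#' @param caller_ids character vector `c(tracker, caller_a, caller_b)` of
#'   the caller identifiers behind the three per-caller flags.
#' @return named numeric vector following [feature_schema()].
#' @export
build_feature_vector <- function(mc, consequence, rt, reference,
                                 caller_ids = c("TRACKER", "CALLER_A",
                                                "CALLER_B")) {
  vt <- variant_type(mc$ref, mc$alt)
  schema_type <- if (vt == "SNV") "SNV" else "INDEL"
  callers <- strsplit(mc$callers, ",")[[1]]
  ctx <- context_features(mc$chrom, mc$pos, reference,
                          str_regions = rt$str_regions,
                          low_complexity = rt$low_complexity)
  mafs <- vapply(rt$germline, lookup0, numeric(1), key = mc$key)
  sb <- strand_bias_phred(mc$alt_fwd, mc$alt_count - mc$alt_fwd,
                          mc$ref_fwd, mc$ref_count - mc$ref_fwd)
  fv <- c(
    status_meta = as.numeric(mc$status),
    called_by_tracker = as.numeric(caller_ids[1] %in% callers),
    called_by_caller_a = as.numeric(caller_ids[2] %in% callers),
    called_by_caller_b = as.numeric(caller_ids[3] %in% callers),
    depth = as.numeric(mc$depth),
    alt_count = as.numeric(mc$alt_count),
    vaf = mc$alt_count / mc$depth,
    mean_mapq_alt = as.numeric(mc$mean_mapq_alt),
    mean_baseq_alt = as.numeric(mc$mean_baseq_alt),
    strand_bias_phred = sb,
    spans_indel = as.numeric(mc$spans_indel),
    mean_read_pos_fraction = as.numeric(mc$mean_read_pos_fraction),
    homopolymer_len = as.numeric(ctx$homopolymer_len),
    in_str = as.numeric(ctx$in_str),
    in_low_complexity = as.numeric(ctx$in_low_complexity),
    gc_content_101bp = ctx$gc_content_101bp,
    maf_db1 = mafs[[1]], maf_db2 = mafs[[2]], maf_db3 = mafs[[3]],
    maf_db4 = mafs[[4]],
    max_germline_maf = max(mafs),
    cosmic_match = as.numeric(cosmic_hit(rt, mc$chrom, mc$pos, mc$ref,
                                         mc$alt, mc$key) > 0),
    cosmic_freq = cosmic_hit(rt, mc$chrom, mc$pos, mc$ref, mc$alt, mc$key),
    is_transition = if (vt == "SNV") as.numeric(is_transition(mc$ref, mc$alt)) else NA_real_,
    consequence_class = as.numeric(consequence_levels()[[consequence]]),
    base_change_class = if (vt == "SNV") as.numeric(base_change_class(mc$ref, mc$alt)) else NA_real_)
  if (schema_type == "INDEL")
    fv <- c(fv[setdiff(names(fv), c("is_transition", "base_change_class",
                                    "mean_read_pos_fraction"))],
            indel_length = nchar(mc$alt) - nchar(mc$ref))
  fv <- fv[feature_schema(schema_type)]
  stopifnot(length(fv) == if (schema_type == "SNV") 26L else 24L)
  fv
}

# SNVs: exact key match. Indels: position + type match, length-tolerant +/-0
# (i.e. the catalogue entry must be the same indel length and type at the
# same anchor).
cosmic_hit <- function(rt, chrom, pos, ref, alt, key) {
  if (length(rt$cosmic) == 0L) return(0)
  vt <- variant_type(ref, alt)
  if (vt %in% c("SNV", "MNP")) return(lookup0(rt$cosmic, key))
  parts <- strsplit(names(rt$cosmic), ":")
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (p[1] == chrom && as.integer(p[2]) == pos &&
        variant_type(p[3], p[4]) == vt &&
        (nchar(p[4]) - nchar(p[3])) == (nchar(alt) - nchar(ref)))
      return(unname(rt$cosmic[i]))
  }
  0
}

#' Featurize merged calls
#'
#' Annotates each merged call with its consequence, applies the
#' functional-effect filter, and assembles the feature matrix. Calls whose
#' evidence attributes are missing (external-only calls the tracker did not
#' see) get them recomputed by a targeted pileup of the alignments.
#'
#' @param merged merged-call data.frame from [merge_callsets()].
#' @param reference named list of contig sequences.
#' @param genes gene-model data.frame.
#' @param rt a [resource_tables()].
#' @param aln optional alignments for targeted re-pileup of external-only
#'   calls.
#' @param cfg [pileup_config()] for the targeted pileup.
#' @param functional_only drop synonymous/noncoding calls (default TRUE).
#' @return list with `calls` (annotated, filtered data.frame) and two
#'   numeric feature matrices `snv` and `indel` (rows aligned to the calls
#'   of that type, columns per [feature_schema()]).
#' @export
build_feature_table <- function(merged, reference, genes, rt, aln = NULL,
                                cfg = pileup_config(),
                                functional_only = TRUE,
                                caller_ids = c("TRACKER", "CALLER_A",
                                               "CALLER_B")) {
  if (nrow(merged) == 0L)
    return(list(calls = merged,
                snv = matrix(numeric(0), 0, 26,
                             dimnames = list(NULL, feature_schema("SNV"))),
                indel = matrix(numeric(0), 0, 24,
                               dimnames = list(NULL, feature_schema("INDEL")))))
  evid_cols <- c("alt_fwd", "ref_count", "ref_fwd", "mean_mapq_alt",
                 "mean_baseq_alt", "mean_read_pos_fraction", "spans_indel")
  for (cc in evid_cols) if (is.null(merged[[cc]])) merged[[cc]] <- NA
  need <- which(is.na(merged$mean_mapq_alt) | is.na(merged$alt_fwd))
  if (length(need) && !is.null(aln)) {
    max_span <- max(nchar(aln$seq)) + 10L
    for (i in need) {
      reg <- list(chrom = merged$chrom[i], start = merged$pos[i],
                  end = merged$pos[i])
      near <- aln[aln$chrom == merged$chrom[i] &
                    aln$pos <= merged$pos[i] &
                    aln$pos >= merged$pos[i] - max_span, , drop = FALSE]
      s <- tryCatch(pileup_sites(near, reference, reg, cfg),
                    error = function(e) NULL)
      if (!is.null(s) && nrow(s)) {
        s <- s[which.max(s$count), , drop = FALSE]
        merged$alt_fwd[i] <- s$fwd_count
        merged$ref_count[i] <- s$ref_count
        merged$ref_fwd[i] <- s$ref_fwd_count
        merged$mean_mapq_alt[i] <- s$mean_mapq_alt
        merged$mean_baseq_alt[i] <- s$mean_baseq_alt
        merged$mean_read_pos_fraction[i] <- s$mean_read_pos_fraction
        merged$spans_indel[i] <- s$spans_indel
        if (is.na(merged$depth[i])) merged$depth[i] <- s$depth
        if (is.na(merged$alt_count[i])) merged$alt_count[i] <- s$count
      }
    }
  }
  # conservative defaults for anything still unmeasured
  merged$alt_fwd[is.na(merged$alt_fwd)] <- 0L
  merged$ref_count[is.na(merged$ref_count)] <- 0L
  merged$ref_fwd[is.na(merged$ref_fwd)] <- 0L
  merged$mean_mapq_alt[is.na(merged$mean_mapq_alt)] <- 0
  merged$mean_baseq_alt[is.na(merged$mean_baseq_alt)] <- 0
  merged$mean_read_pos_fraction[is.na(merged$mean_read_pos_fraction)] <- 0.5
  merged$spans_indel[is.na(merged$spans_indel)] <- FALSE

  merged$consequence <- vapply(seq_len(nrow(merged)), function(i)
    classify_consequence(gvariant(merged$chrom[i], merged$pos[i],
                                  merged$ref[i], merged$alt[i],
                                  normalized = TRUE),
                         genes, reference), character(1))
  merged$gene <- vapply(seq_len(nrow(merged)), function(i)
    gene_at(genes, merged$chrom[i], merged$pos[i]), character(1))
  calls <- if (functional_only) functional_filter(merged) else merged
  vt <- variant_type(calls$ref, calls$alt)
  calls$variant_class <- ifelse(vt == "SNV", "SNV", "INDEL")
  fv_rows <- function(idx, type) {
    m <- matrix(NA_real_, length(idx), length(feature_schema(type)),
                dimnames = list(NULL, feature_schema(type)))
    for (j in seq_along(idx)) {
      i <- idx[j]
      m[j, ] <- build_feature_vector(calls[i, , drop = FALSE],
                                     calls$consequence[i], rt, reference,
                                     caller_ids = caller_ids)
    }
    m
  }
  list(calls = calls,
       snv = fv_rows(which(calls$variant_class == "SNV"), "SNV"),
       indel = fv_rows(which(calls$variant_class == "INDEL"), "INDEL"))
}

gene_at <- function(genes, chrom, pos) {
  g <- genes[genes$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(g))) {
    ex <- exon_list(g[i, , drop = FALSE])
    if (pos >= min(ex$start) && pos <= max(ex$end)) return(g$gene[i])
  }
  NA_character_
}
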