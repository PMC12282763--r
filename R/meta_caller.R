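#' Merge call sets from multiple callers
#'
#' Every input record is normalized (MNPs split into SNVs, indels
#' left-aligned) and grouped by its canonical variant key; each merged call
#' carries the set of callers supporting it and a calling status equal to
#' the number of callers -- the ensemble's central signal. Within one
#' caller, duplicate keys collapse to the record with the most supporting
#' reads before merging. Records whose REF does not match the reference are
#' skipped with a warning and counted.
#'
#' @param callsets named list of call-record data.frames (names are the
#'   caller ids; see [genotype_candidates()] for the column contract --
#'   external callers may omit the evidence columns).
#' @param reference named list of contig sequences.
#' @return merged-call data.frame sorted by (chrom, pos): `chrom`, `pos`,
#'   `ref`, `alt`, `key`, `status` (number of callers), `callers`
#'   (comma-separated ids), best-evidence `alt_count`, `depth`, `vaf` and
#'   any evidence columns provided by the best record; attribute
#'   `per_caller` holds the full long table, attribute `n_skipped` the
#'   normalization-failure count.
#' @export
merge_callsets <- function(callsets, reference) {
  if (length(callsets) == 0L) stopf("at least one callset is required")
  ids <- names(callsets)
  if (is.null(ids) || any(!nzchar(ids)) || anyDuplicated(ids))
    stopf("callsets must be uniquely named by caller id")
  reference <- as.list(reference)
  evid_cols <- c("alt_fwd", "ref_count", "ref_fwd", "mean_mapq_alt",
                 "mean_baseq_alt", "mean_read_pos_fraction", "spans_indel")
  long <- list()
  n_skipped <- 0L
  for (id in ids) {
    cs <- callsets[[id]]
    if (is.null(cs) || nrow(cs) == 0L) next
    cs$caller <- id
    for (cc in evid_cols) if (is.null(cs[[cc]])) cs[[cc]] <- NA
    norm <- normalize_call_frame(
      cs[, c("chrom", "pos", "ref", "alt", "caller", "alt_count", "depth",
             "vaf", evid_cols)], reference)
    n_skipped <- n_skipped + (attr(norm, "n_dropped") %||% 0L)
    if (nrow(norm) == 0L) next
    # within-caller duplicates collapse to the max-alt_count record
    norm <- norm[order(norm$key, -ifelse(is.na(norm$alt_count), 0,
                                         norm$alt_count)), , drop = FALSE]
    norm <- norm[!duplicated(norm$key), , drop = FALSE]
    long[[id]] <- norm
  }
  long <- do.call(rbind, long)
  if (is.null(long) || nrow(long) == 0L) {
    out <- data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      key = character(), status = integer(),
                      callers = character(), alt_count = integer(),
                      depth = integer(), vaf = numeric(),
                      stringsAsFactors = FALSE)
    attr(out, "per_caller") <- long
    attr(out, "n_skipped") <- n_skipped
    return(out)
  }
  rownames(long) <- NULL
  groups <- split(seq_len(nrow(long)), long$key)
  rows <- lapply(groups, function(idx) {
    g <- long[idx, , drop = FALSE]
    best <- g[which.max(ifelse(is.na(g$alt_count), -1, g$alt_count)), ,
              drop = FALSE]
    callers <- sort(unique(g$caller))
    data.frame(chrom = best$chrom, pos = best$pos, ref = best$ref,
               alt = best$alt, key = best$key,
               status = length(callers),
               callers = paste(callers, collapse = ","),
               alt_count = best$alt_count, depth = best$depth,
               vaf = best$vaf,
               best[, evid_cols, drop = FALSE],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$pos, out$ref, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "per_caller") <- long
  attr(out, "n_skipped") <- n_skipped
  out
}
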