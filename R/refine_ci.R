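#' Refinement configuration
#'
#' CHIP clones rarely exceed 30% VAF, so higher-VAF calls default to
#' germline -- except in the five genes where germline variation is
#' essentially absent (DNMT3A, ASXL1, TET2, PPM1D, JAK2), which are flagged
#' for review instead. Known-CHIP rescue requires support from at least
#' `rescue_min_callers` callers.
#'
#' @param vaf_germline_default VAF above which a call defaults to germline.
#' @param rescue_min_callers minimum calling status for known-CHIP rescue.
#' @param privileged_genes genes exempt from the VAF-germline rule.
#' @export
refinement_config <- function(vaf_germline_default = 0.30,
                              rescue_min_callers = 2L,
                              privileged_genes = c("DNMT3A", "ASXL1",
                                                   "TET2", "PPM1D",
                                                   "JAK2")) {
  stopifnot(vaf_germline_default > 0, vaf_germline_default <= 1)
  structure(list(vaf_germline_default = vaf_germline_default,
                 rescue_min_callers = as.integer(rescue_min_callers),
                 privileged_genes = privileged_genes),
            class = "refinement_config")
}

#' Rule-based rescue of CHIP predictions
#'
#' Two refinement rules applied after classification: (a) a non-CHIP
#' prediction whose variant is a known CHIP mutation and was detected by at
#' least two callers is flagged `putative_chip_rescued`; (b) a call above
#' the germline VAF threshold is flagged `germline_by_vaf` unless it falls
#' in a privileged gene, in which case it is `putative_chip_vaf_review`.
#' CHIP predictions at or below the threshold pass through unchanged; the
#' rules never demote them.
#'
#' @param pred data.frame with `label`, `key`, `vaf`, `status`, `gene`
#'   columns (one row per call).
#' @param rt a [resource_tables()].
#' @param cfg a [refinement_config()].
#' @return `pred` with a `refined_flag` column (`none`,
#'   `putative_chip_rescued`, `putative_chip_vaf_review`,
#'   `germline_by_vaf`).
#' @export
rescue_rules <- function(pred, rt, cfg = refinement_config()) {
  flag <- rep("none", nrow(pred))
  known <- pred$key %in% rt$known_chip
  rescued <- pred$label != "CHIP" & known & pred$status >= cfg$rescue_min_callers
  flag[rescued] <- "putative_chip_rescued"
  high <- !is.na(pred$vaf) & pred$vaf > cfg$vaf_germline_default
  priv <- !is.na(pred$gene) & pred$gene %in% cfg$privileged_genes
  flag[high & priv] <- "putative_chip_vaf_review"
  flag[high & !priv] <- "germline_by_vaf"
  pred$refined_flag <- flag
  pred
}

#' Cohort-filter configuration
#'
#' @param max_germline_maf remove calls at or above this MAF in any
#'   germline database (default 0.3%).
#' @param max_subject_fraction remove variants found in at least this
#'   fraction of subjects (default 8%) -- recurrent technical artifacts.
#' @param min_vaf retain only calls at or above this VAF (default 2%).
#' @param require_catalogue retain only somatic-catalogue members.
#' @param driver_restrict additionally restrict to the driver-mutation
#'   list.
#' @export
cohort_filter_config <- function(max_germline_maf = 0.003,
                                 max_subject_fraction = 0.08,
                                 min_vaf = 0.02, require_catalogue = TRUE,
                                 driver_restrict = FALSE) {
  stopifnot(max_germline_maf > 0, max_germline_maf < 1,
            max_subject_fraction > 0, max_subject_fraction < 1,
            min_vaf > 0, min_vaf < 1)
  structure(list(max_germline_maf = max_germline_maf,
                 max_subject_fraction = max_subject_fraction,
                 min_vaf = min_vaf,
                 require_catalogue = isTRUE(require_catalogue),
                 driver_restrict = isTRUE(driver_restrict)),
            class = "cohort_filter_config")
}

#' Cohort-level filtering of predicted CHIP mutations
#'
#' Applies the fixed removal cascade to per-subject CHIP predictions:
#' (1) germline-database MAF at or above the threshold; (2) low-confidence
#' calls (single-caller status) inside low-complexity regions; (3) variants
#' recurring in at least `max_subject_fraction` of subjects; then retains
#' only calls with VAF at or above `min_vaf` (and at most the germline
#' threshold unless in a privileged gene) that are catalogue members, with
#' an optional driver-mutation restriction. Per-rule removal tallies are
#' returned and conserve the input count.
#'
#' @param preds data.frame of per-subject CHIP predictions with columns
#'   `subject`, `key`, `chrom`, `pos`, `ref`, `alt`, `gene`, `vaf`,
#'   `status`, `in_low_complexity`.
#' @param rt a [resource_tables()].
#' @param cfg a [cohort_filter_config()].
#' @param refine_cfg a [refinement_config()] (for the privileged-gene VAF
#'   exemption).
#' @param n_subjects cohort size for the recurrence rule; defaults to the
#'   number of distinct subjects appearing in `preds` (pass the full
#'   cohort size when subjects without CHIP calls exist).
#' @return list: `retained` (data.frame), `tallies` (named removal counts),
#'   `n_input`.
#' @export
cohort_filter <- function(preds, rt, cfg = cohort_filter_config(),
                          refine_cfg = refinement_config(),
                          n_subjects = length(unique(preds$subject))) {
  if (n_subjects < 1L)
    stopf("cohort_filter() needs at least one subject")
  n_input <- nrow(preds)
  tal <- c(germline_maf = 0L, low_complexity = 0L, recurrence = 0L,
           min_vaf = 0L, vaf_above_germline = 0L, not_in_catalogue = 0L,
           not_driver_mutation = 0L)
  cur <- preds
  # (1) common in any germline database
  maxmaf <- vapply(cur$key, function(k)
    max(vapply(rt$germline, lookup0, numeric(1), key = k)), numeric(1))
  rm1 <- maxmaf >= cfg$max_germline_maf
  tal["germline_maf"] <- sum(rm1); cur <- cur[!rm1, , drop = FALSE]
  # (2) low-confidence (single caller) in low-complexity regions
  rm2 <- cur$status == 1L & cur$in_low_complexity
  tal["low_complexity"] <- sum(rm2); cur <- cur[!rm2, , drop = FALSE]
  # (3) cohort recurrence
  n_subj <- n_subjects
  per_var <- tapply(cur$subject, cur$key, function(s) length(unique(s)))
  recur_keys <- names(per_var)[per_var / n_subj >= cfg$max_subject_fraction]
  rm3 <- cur$key %in% recur_keys
  tal["recurrence"] <- sum(rm3); cur <- cur[!rm3, , drop = FALSE]
  # retain: VAF floor
  rm4 <- cur$vaf < cfg$min_vaf
  tal["min_vaf"] <- sum(rm4); cur <- cur[!rm4, , drop = FALSE]
  # retain: VAF ceiling unless privileged gene
  priv <- !is.na(cur$gene) & cur$gene %in% refine_cfg$privileged_genes
  rm5 <- cur$vaf > refine_cfg$vaf_germline_default & !priv
  tal["vaf_above_germline"] <- sum(rm5); cur <- cur[!rm5, , drop = FALSE]
  # retain: catalogue membership
  if (cfg$require_catalogue) {
    hit <- vapply(seq_len(nrow(cur)), function(i)
      cosmic_hit(rt, cur$chrom[i], cur$pos[i], cur$ref[i], cur$alt[i],
                 cur$key[i]) > 0, logical(1))
    rm6 <- !hit
    tal["not_in_catalogue"] <- sum(rm6); cur <- cur[!rm6, , drop = FALSE]
  }
  if (cfg$driver_restrict) {
    rm7 <- !cur$key %in% rt$driver_mutations
    tal["not_driver_mutation"] <- sum(rm7); cur <- cur[!rm7, , drop = FALSE]
  }
  stopifnot(nrow(cur) + sum(tal) == n_input)
  list(retained = cur, tallies = tal, n_input = n_input)
}

#' Fit the background error model from a reference panel
#'
#' Per-site alt-read fractions across the reference panel (healthy, young
#' subjects) are fit to a Beta distribution by the method of moments with
#' pseudocounts, flooring both shape parameters at 0.5; sites without panel
#' coverage fall back to a gene-level, then a global, fit. The baseline
#' CHIP incidence `pi` is the fraction of panel subjects carrying a
#' retained CHIP call, floored at `1 / (2 * n_panel)`.
#'
#' @param panel data.frame of panel pileup observations: `subject`,
#'   `chrom`, `pos`, `gene`, `alt_count`, `depth`.
#' @param panel_chip_subjects character vector of panel subjects with a
#'   retained CHIP call (may be empty).
#' @return object of class `background_model`: per-site, per-gene and
#'   global `(alpha, beta)` plus `pi`.
#' @export
fit_background <- function(panel, panel_chip_subjects = character()) {
  if (is.null(panel) || nrow(panel) == 0L)
    stopf("fit_background() needs a non-empty reference panel")
  n_panel <- length(unique(panel$subject))
  if (n_panel < 2L)
    stopf("fit_background() needs >= 2 panel subjects")
  # method of moments on raw alt fractions; the mean is floored at half a
  # pseudocount over the pooled panel depth, and both shapes at 0.5
  mom <- function(idx) {
    r <- panel$alt_count[idx] / panel$depth[idx]
    m <- max(mean(r), 0.5 / (sum(panel$depth[idx]) + 1))
    v <- if (length(r) > 1L) var(r) else 0
    if (v > 0 && v < m * (1 - m)) {
      c0 <- m * (1 - m) / v - 1
      a <- m * c0; b <- (1 - m) * c0
    } else {
      a <- 0.5; b <- a * (1 - m) / m
    }
    if (a < 0.5) { a <- 0.5; b <- a * (1 - m) / m }
    c(alpha = a, beta = max(b, 0.5))
  }
  site_key <- paste(panel$chrom, panel$pos)
  sites <- lapply(split(seq_len(nrow(panel)), site_key), mom)
  n_obs <- vapply(split(seq_len(nrow(panel)), site_key), length, integer(1))
  genes <- lapply(split(seq_len(nrow(panel)), panel$gene), mom)
  glob <- mom(seq_len(nrow(panel)))
  site_gene <- tapply(panel$gene, site_key, function(g) g[1])
  pi_hat <- max(length(unique(panel_chip_subjects)) / n_panel,
                1 / (2 * n_panel))
  structure(list(sites = sites, site_n = n_obs,
                 site_gene = as.list(site_gene), genes = genes,
                 global = glob, pi = pi_hat, n_panel = n_panel),
            class = "background_model")
}

#' Look up the background Beta for a site
#'
#' Site-level fit when at least two panel subjects covered the site;
#' otherwise the gene-level fit; otherwise the global fit.
#'
#' @param bg a `background_model`.
#' @param chrom,pos site.
#' @param gene gene symbol (optional).
#' @return `c(alpha =, beta =)`.
#' @export
background_at <- function(bg, chrom, pos, gene = NA_character_) {
  k <- paste(chrom, pos)
  if (!is.null(bg$sites[[k]]) && bg$site_n[[k]] >= 2L) return(bg$sites[[k]])
  g <- if (!is.na(gene) && !is.null(bg$genes[[gene]])) gene
       else if (!is.null(bg$site_gene[[k]]) && !is.null(bg$genes[[bg$site_gene[[k]]]]))
         bg$site_gene[[k]]
       else NA_character_
  if (!is.na(g)) return(bg$genes[[g]])
  bg$global
}

# log Beta-Binomial pmf
lbetabinom <- function(k, n, a, b) {
  lchoose(n, k) + lbeta(k + a, n - k + b) - lbeta(a, b)
}

#' Posterior probability of a clone and credible interval for its VAF
#'
#' Two-component hierarchical mixture: under the error component the alt
#' count is Beta-Binomial with the site's background error Beta; under the
#' clone component it is Binomial with clone VAF `theta` drawn from a
#' Beta(a0, b0) prior truncated to `theta_bounds` (default uniform on
#' 0.5%-50%, spanning detectable clone sizes). The posterior clone
#' probability weighs the two marginal likelihoods by the baseline
#' incidence `pi`; the 95% credible interval is the 2.5/97.5% quantile
#' pair of the conjugate truncated Beta(a0 + k, b0 + n - k) posterior.
#'
#' @param k alt-supporting reads.
#' @param n depth (> 0).
#' @param background `c(alpha =, beta =)` from [background_at()].
#' @param pi baseline clone incidence.
#' @param a0,b0 clone-VAF prior shapes.
#' @param theta_bounds truncation interval for the clone VAF.
#' @return list: `posterior_chip`, `ci95` (length-2), log marginal
#'   likelihoods `logL_error`, `logL_clone`.
#' @export
chip_posterior <- function(k, n, background, pi, a0 = 1, b0 = 1,
                           theta_bounds = c(0.005, 0.5)) {
  stopifnot(n > 0, k >= 0, pi > 0, pi < 1)
  if (k > n) stopf("alt count k = %d exceeds depth n = %d", k, n)
  l <- theta_bounds[1]; u <- theta_bounds[2]
  a <- unname(background["alpha"]); b <- unname(background["beta"])
  logL0 <- lbetabinom(k, n, a, b)
  # clone marginal: integral of Binom(k | n, theta) over truncated Beta
  ak <- a0 + k; bk <- b0 + n - k
  mass_post <- pbeta(u, ak, bk) - pbeta(l, ak, bk)
  mass_prior <- pbeta(u, a0, b0) - pbeta(l, a0, b0)
  logL1 <- lchoose(n, k) + lbeta(ak, bk) - lbeta(a0, b0) +
    log(max(mass_post, 1e-300)) - log(mass_prior)
  m <- max(logL0, logL1)
  w1 <- pi * exp(logL1 - m); w0 <- (1 - pi) * exp(logL0 - m)
  post <- w1 / (w1 + w0)
  # credible interval from the truncated conjugate posterior
  pl <- pbeta(l, ak, bk); pu <- pbeta(u, ak, bk)
  qs <- qbeta(pl + c(0.025, 0.975) * (pu - pl), ak, bk)
  list(posterior_chip = post, ci95 = qs, logL_error = logL0,
       logL_clone = logL1)
}
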