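# Compact end-to-end study bundle (small genome, shared specs, trained
# models), memoized for the acceptance suite.

fixture_e2e <- function() fx("e2e", function() {
  rb <- make_reference(n_genes = 3L, gene_len = 210L,
                       intergenic_len = 100L, seed = 21L)
  specs <- make_variant_specs(rb, n_chip = 20L, n_germline = 10L,
                              seed = 22L)
  rt <- make_study_resources(rb, specs$somatic, specs$germline, seed = 23L)
  tr_snv <- build_training_table(rb, rt, specs, n_subjects = 3L,
                                 variant_type = "SNV", seed = 30L)
  tr_ind <- build_training_table(rb, rt, specs, n_subjects = 3L,
                                 variant_type = "INDEL", seed = 30L)
  models <- list(
    SNV = train_classifier(tr_snv, train_config("gbt", "WGS", "SNV",
                                                seed = 1L)),
    INDEL = train_classifier(tr_ind, train_config("gbt", "WGS", "INDEL",
                                                  seed = 1L)))
  list(rb = rb, specs = specs, rt = rt, models = models)
})

# run the full pipeline on one subject spiked at a uniform VAF and score
# recall of the spiked set from the final CHIP calls
e2e_recall_at <- function(bundle, vaf, seed) {
  rb <- bundle$rb
  sub <- simulate_subject(rb, bundle$specs, chip_vaf = vaf,
                          mean_depth = 100, seed = seed)
  truth_all <- rbind(sub$chip_truth[, 1:11], sub$germline_truth[, 1:11])
  profs <- default_caller_profiles()
  ext <- lapply(seq_along(profs), function(i)
    mock_caller(truth_all, profs[[i]], sub$aln, rb$reference,
                seed = seed * 13L + i))
  names(ext) <- names(profs)
  res <- suppressMessages(
    run_pipeline(sub$aln, rb$reference, rb$genes, bundle$rt,
                 bundle$models, external = ext, seed = 4L))
  rp <- spikein_recall_precision(res$chip, sub$chip_truth, rb$reference)
  c(recovered = rp$n_recovered, spiked = rp$n_truth)
}
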