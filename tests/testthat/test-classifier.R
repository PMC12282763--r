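# Training, prediction, evaluation metrics and feature importance.

test_that("the stratified split is deterministic, order-invariant and proportioned", {
  tab <- synthetic_feature_table(1000, separation = 1, seed = 4)
  cfg <- train_config("gbt", "WGS", "SNV", seed = 9)
  s1 <- split_train_test(tab, cfg)
  expect_lte(abs(nrow(s1$train) - 800L), 2L)   # per-class rounding
  expect_identical(nrow(s1$train) + nrow(s1$test), 1000L)
  # class proportions preserved within one row per class
  for (cl in levels(tab$label)) {
    expect_lte(abs(sum(s1$train$label == cl) - 0.8 * sum(tab$label == cl)),
               1)
  }
  s2 <- split_train_test(tab, cfg)
  expect_identical(s1$train, s2$train)
  shuf <- tab[sample.int(nrow(tab)), ]
  s3 <- split_train_test(shuf, cfg)
  key <- function(df) sort(apply(df, 1, paste, collapse = "|"))
  expect_identical(key(s1$train), key(s3$train))
  # a different seed changes membership
  s4 <- split_train_test(tab, train_config("gbt", "WGS", "SNV", seed = 10))
  expect_false(identical(key(s1$train), key(s4$train)))
})

test_that("an absent class warns and a single-class set trains a degenerate model", {
  tab <- synthetic_feature_table(60, class_fractions = c(CHIP = 0.5,
                                                         GERMLINE = 0.5,
                                                         ARTIFACT = 0),
                                 separation = 1, seed = 4)
  cfg <- train_config("gbt", "WGS", "SNV", seed = 1)
  expect_warning(split_train_test(tab, cfg), "ARTIFACT")
  one <- tab[tab$label == "CHIP", ]
  m <- suppressWarnings(train_classifier(one, cfg))
  pr <- predict(m, synthetic_feature_table(20, separation = 0, seed = 5))
  expect_true(all(pr$label == "CHIP"))
  expect_true(all(pr$prob_chip == 1))
})

test_that("well-separated synthetic classes are learned almost perfectly by both backends", {
  tab <- synthetic_feature_table(1500, separation = 1, seed = 1)
  for (kind in c("gbt", "rf")) {
    cfg <- train_config(kind, "WGS", "SNV", seed = 1)
    sp <- split_train_test(tab, cfg)
    m <- train_classifier(sp$train, cfg)
    pr <- predict(m, sp$test)
    expect_true(all(abs(pr$prob_chip + pr$prob_germline +
                          pr$prob_artifact - 1) < 1e-6))
    cm <- confusion(pr$label, as.character(sp$test$label))
    expect_gte(chipmeta:::macro_f1(cm), 0.9)
  }
})

test_that("models round-trip through the bundle file with identical predictions", {
  tab <- synthetic_feature_table(400, separation = 1, seed = 2)
  cfg <- train_config("gbt", "WES", "SNV", seed = 3)
  m <- train_classifier(tab, cfg)
  f <- tempfile(fileext = ".rds")
  save_model(m, f)
  m2 <- load_model(f)
  expect_identical(m2$schema_hash, m$schema_hash)
  expect_identical(m2$cfg$data_type, "WES")
  expect_identical(predict(m2, tab), predict(m, tab))
})

test_that("schema mismatches and NaN features are rejected by name", {
  tab <- synthetic_feature_table(200, separation = 1, seed = 2)
  cfg <- train_config("gbt", "WGS", "SNV", seed = 1)
  m <- train_classifier(tab, cfg)
  expect_error(predict(m, tab[, 1:10]), "schema mismatch")
  bad <- tab
  bad$vaf[3] <- NaN
  expect_error(train_classifier(bad, cfg), "vaf")
  expect_error(predict(m, bad), "vaf")
  # INDEL-schema data against an SNV model
  ti <- synthetic_feature_table(50, separation = 1, seed = 2,
                                variant_type = "INDEL")
  expect_error(predict(m, ti), "schema mismatch")
})

test_that("the confusion matrix recounts a hand-built 9-cell case", {
  actual <- c(rep("CHIP", 6), rep("GERMLINE", 5), rep("ARTIFACT", 7))
  predicted <- c("CHIP", "CHIP", "GERMLINE", "ARTIFACT", "CHIP", "ARTIFACT",
                 "GERMLINE", "GERMLINE", "CHIP", "ARTIFACT", "GERMLINE",
                 rep("ARTIFACT", 6), "CHIP")
  cm <- confusion(predicted, actual)
  # independent tally
  for (a in rownames(cm)) for (p in colnames(cm))
    expect_identical(cm[a, p], sum(actual == a & predicted == p))
  expect_identical(sum(cm), 18L)
  # perfect prediction is diagonal; empty input is a zero matrix
  cmp <- confusion(actual, actual)
  expect_identical(sum(cmp), sum(diag(cmp)))
  expect_identical(sum(confusion(character(0), character(0))), 0L)
  expect_error(confusion("CHIP", c("CHIP", "GERMLINE")), "length")
})

test_that("one-vs-rest metrics evaluate the defining ratios", {
  # TP=8, FN=2, FP=1, TN=9
  cm <- matrix(c(8L, 1L, 0L, 2L, 9L, 0L, 0L, 0L, 0L), 3, 3, byrow = TRUE,
               dimnames = list(actual = chipmeta:::chip_classes(),
                               predicted = chipmeta:::chip_classes()))
  cm["GERMLINE", "GERMLINE"] <- 9L; cm["GERMLINE", "CHIP"] <- 1L
  cm["CHIP", "CHIP"] <- 8L; cm["CHIP", "GERMLINE"] <- 2L
  cm["CHIP", "ARTIFACT"] <- 0L; cm["GERMLINE", "ARTIFACT"] <- 0L
  cm["ARTIFACT", ] <- 0L
  mt <- metrics_from_confusion(cm, "CHIP")
  expect_equal(mt$recall, 0.8)
  expect_equal(mt$precision, 8 / 9)
  expect_equal(mt$accuracy, 0.85)
  expect_equal(mt$specificity, 9 / 10)
  expect_equal(mt$f1, f1_score(8 / 9, 0.8))
  # perfect prediction
  cmp <- confusion(rep(chipmeta:::chip_classes(), 4),
                   rep(chipmeta:::chip_classes(), 4))
  mp <- metrics_from_confusion(cmp, "CHIP")
  expect_true(all(unlist(mp[c("precision", "recall", "specificity", "f1",
                              "accuracy")]) == 1))
  # class never predicted nor present: undefined ratios flagged
  cm0 <- confusion(rep("GERMLINE", 5), rep("GERMLINE", 5))
  m0 <- metrics_from_confusion(cm0, "CHIP")
  expect_true(m0$undefined)
  expect_true(is.nan(m0$precision))
})

test_that("F1 from the harmonic-mean identity agrees with direct computation on random matrices", {
  set.seed(77)
  for (i in 1:25) {
    cm <- matrix(rpois(9, 20) + 1L, 3, 3,
                 dimnames = list(actual = chipmeta:::chip_classes(),
                                 predicted = chipmeta:::chip_classes()))
    for (cl in chipmeta:::chip_classes()) {
      mt <- metrics_from_confusion(cm, cl)
      expect_equal(mt$f1, 2 * mt$precision * mt$recall /
                     (mt$precision + mt$recall))
    }
  }
})

test_that("a label copied from one binary feature dominates the gain ranking", {
  tab <- synthetic_feature_table(2000, separation = 0, seed = 1)
  tab$cosmic_match <- as.numeric(tab$label == "CHIP")
  tab$max_germline_maf <- as.numeric(tab$label == "GERMLINE") * 0.2
  cfg <- train_config("gbt", "WGS", "SNV", seed = 1,
                      hyperparameters = list(nrounds = 50L))
  m <- train_classifier(tab, cfg)
  g <- feature_gain(m)
  expect_equal(sum(g), 1, tolerance = 1e-9)
  expect_true(all(g >= 0))
  expect_identical(names(g)[1], "cosmic_match")
  expect_gt(g[["cosmic_match"]], max(g[setdiff(names(g),
                                               c("cosmic_match",
                                                 "max_germline_maf"))]))
  # unused features report zero gain
  expect_true(any(g == 0))
  # the degenerate model has no trees to report on
  one <- synthetic_feature_table(30, class_fractions = c(CHIP = 1,
                                                         GERMLINE = 0,
                                                         ARTIFACT = 0),
                                 separation = 1, seed = 2)
  expect_error(feature_gain(suppressWarnings(train_classifier(one, cfg))),
               "tree-ensemble")
})

test_that("recall for CHIP rises with class separation", {
  recalls <- vapply(c(0.15, 0.5, 1), function(s) {
    tab <- synthetic_feature_table(900, separation = s, seed = 6)
    cfg <- train_config("gbt", "WGS", "SNV", seed = 1,
                        hyperparameters = list(nrounds = 60L))
    sp <- split_train_test(tab, cfg)
    m <- train_classifier(sp$train, cfg)
    cm <- confusion(predict(m, sp$test)$label, as.character(sp$test$label))
    metrics_from_confusion(cm, "CHIP")$recall
  }, numeric(1))
  expect_true(all(diff(recalls) > -0.02))   # monotone within noise
  expect_gt(recalls[3], recalls[1])
})

test_that("hyperparameter tuning returns a model honoring the pinned contract", {
  tab <- synthetic_feature_table(300, separation = 1, seed = 8)
  cfg <- train_config("gbt", "WGS", "SNV", seed = 1, cv_folds = 3L,
                      hyperparameters = list(nrounds = 40L))
  m <- train_classifier(tab, cfg, tune = TRUE)
  expect_s3_class(m, "chip_model")
  expect_true(m$hyperparameters$max_depth %in% c(4L, 6L))
  pr <- predict(m, tab)
  expect_identical(nrow(pr), nrow(tab))
})
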