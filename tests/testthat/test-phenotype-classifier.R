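test_that("training matrix partitions drugs by assignment", {
  drugs <- c(diazepam = "AA", fluoxetine = "AA", imipramine = "AA",
             LiCl = "AA", ketamine = "other", MK801 = "other",
             drugX = "AA", drugY = "other")
  norm <- toy_norm_table(drugs, n_fish = 5, seed = 8)
  assignment <- c(default_assignment(), drugX = "test", drugY = "test")
  lm <- build_training_matrix(norm, assignment, "SRB")
  expect_setequal(unique(lm$train$treatment), names(default_assignment()))
  expect_setequal(unique(lm$test$treatment), c("drugX", "drugY"))
  expect_equal(nrow(lm$train), 6 * 5)   # one SRB row per fish
  expect_equal(nrow(lm$test), 2 * 5)
  expect_true(all(c(phenoscreen:::.feature_cols, "dose_level") %in%
                    lm$feature_cols))
  # unassigned or doubly assigned drugs are rejected
  expect_error(build_training_matrix(norm, assignment[-7], "SRB"), "drugX")
  expect_error(build_training_matrix(norm, assignment[c(1:8, 7)], "SRB"),
               "more than once")
  # empty test partition is valid
  lm2 <- build_training_matrix(toy_norm_table(default_assignment(),
                                              n_fish = 4, seed = 9),
                               default_assignment(), "PSRB")
  expect_equal(nrow(lm2$test), 0)
})

test_that("all three model kinds separate linearly separable classes", {
  norm <- toy_norm_table(default_assignment(), n_fish = 15, shift = 60,
                         seed = 10)
  lm <- build_training_matrix(norm, default_assignment(), "SRB")
  models <- train_models(lm, seed = 1)
  for (m in models) {
    expect_equal(m$train_acc, 1)
    sc <- aa_score(m, lm$train)
    expect_true(min(sc[lm$train$class == "AA"]) >
                  max(sc[lm$train$class == "other"]))
  }
})

test_that("scoring is deterministic and rejects column mismatches", {
  norm <- toy_norm_table(default_assignment(), n_fish = 10, seed = 12)
  lm <- build_training_matrix(norm, default_assignment(), "SRB")
  models <- suppressWarnings(train_models(lm, seed = 3))
  two <- lm$train[c(1, 1), ]      # duplicated row
  for (m in models) {
    sc <- aa_score(m, two)
    expect_equal(sc[1], sc[2])
  }
  expect_error(aa_score(models$glmnet, lm$train[, 1:4]), "missing model column")
  models2 <- suppressWarnings(train_models(lm, seed = 3))
  expect_equal(aa_score(models2$rf, lm$train), aa_score(models$rf, lm$train))
})

test_that("label shuffling destroys cross-validated accuracy", {
  set.seed(31)
  norm <- toy_norm_table(default_assignment(), n_fish = 20, shift = 40,
                         seed = 14)
  lm <- build_training_matrix(norm, default_assignment(), "SRB")
  # shuffle class labels at the fish level
  fish <- unique(lm$train$fish_id)
  newcl <- setNames(sample(lm$train$class[match(fish, lm$train$fish_id)]),
                    fish)
  lm$train$class <- unname(newcl[lm$train$fish_id])
  m <- train_models(lm, seed = 5, kinds = "glmnet")$glmnet
  expect_gt(m$cv_acc, 0.25)
  expect_lt(m$cv_acc, 0.75)
  # single-class input is an error
  lm$train$class <- "AA"
  expect_error(train_models(lm, seed = 1), "both classes")
})

test_that("ROC/AUC equals brute-force pair counting and pROC", {
  set.seed(19)
  for (i in 1:8) {
    n <- sample(10:40, 1)
    scores <- sample(seq(0, 1, 0.05), n, replace = TRUE)  # forces ties
    labels <- runif(n) < 0.5
    if (!any(labels) || all(labels)) next
    rc <- roc_curve(scores, labels)
    expect_equal(rc$auc, oracle_auc(scores, labels), tolerance = 1e-9)
    expect_true(all(rc$curve$fpr >= 0 & rc$curve$fpr <= 1))
    expect_equal(rc$curve$tpr[nrow(rc$curve)], 1)
    if (requireNamespace("pROC", quietly = TRUE))
      expect_equal(rc$auc,
                   as.numeric(pROC::auc(pROC::roc(as.numeric(labels), scores,
                                                  quiet = TRUE,
                                                  direction = "<"))),
                   tolerance = 1e-9)
  }
})

test_that("paired ROC follows the positive/negative control scheme", {
  r <- paired_roc(rep(0.9, 5), "AA", rep(0.1, 5), "other")
  expect_equal(r$auc, 1)
  expect_equal(r$call, "AA")
  # brute-force rank example: {0.8, 0.6} vs {0.7}
  r2 <- paired_roc(c(0.8, 0.6), "AA", 0.7, "other")
  expect_equal(r2$auc, 0.5)
  expect_error(paired_roc(1, "AA", 0, "AA"), "opposite class")
  # same-distribution scores centre near 0.5
  set.seed(27)
  aucs <- replicate(200, paired_roc(runif(30), "AA", runif(30), "other")$auc)
  expect_lt(abs(mean(aucs) - 0.5), 0.02)
})

test_that("glmnet scores are monotone in a planted graded effect", {
  norm <- toy_norm_table(default_assignment(), n_fish = 15, shift = 40,
                         seed = 22)
  lm <- build_training_matrix(norm, default_assignment(), "SRB")
  m <- train_models(lm, seed = 2, kinds = "glmnet")$glmnet
  probe <- lm$train[rep(1, 5), ]
  probe$dose_level <- 2
  grades <- seq(0, -60, length.out = 5)   # increasingly AA-like distance
  for (f in phenoscreen:::.feature_cols) probe[[f]] <- 0
  probe$distance_mm <- grades
  probe$turning_rel <- -grades
  probe$pause_s <- grades
  probe$spurt_mms <- grades
  sc <- aa_score(m, probe)
  expect_true(all(diff(sc) >= -1e-9))
})

test_that("auc summary reports one row per drug, model and window", {
  drugs <- c(default_assignment(), drugX = "AA", drugY = "other")
  norm <- toy_norm_table(drugs, n_fish = 12, shift = 40, seed = 25)
  assignment <- c(default_assignment(), drugX = "test", drugY = "test")
  mats <- lapply(c(SRB = "SRB", PSRB = "PSRB"), function(w)
    build_training_matrix(norm, assignment, w))
  models <- lapply(mats, train_models, seed = 4, kinds = c("glmnet", "rf"))
  tab <- auc_summary(models, mats, c(drugX = "AA", drugY = "other"))
  expect_equal(nrow(tab), 2 * 2 * 2)
  expect_setequal(unique(tab$drug), c("drugX", "drugY"))
  # phenocopying test drugs against opposite-class controls score high
  expect_true(all(tab$auc > 0.8))
})
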