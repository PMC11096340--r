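#' Build the labelled classifier matrix
#'
#' Rows are fish x cycle observations of one window label (SRB or PSRB);
#' predictors are the six control-normalized features (missing values
#' imputed as 0% change, with companion missingness indicator columns)
#' plus the ordinal dose level.  Training rows come only from drugs
#' assigned to the "AA" (antidepressant/anxiolytic) or "other" class;
#' drugs assigned "test" form the unlabelled test partition.  Control
#' (dose 0) fish are excluded from both partitions.
#'
#' @param norm normalized feature table ([normalize_to_controls()]).
#' @param assignment named character vector mapping treatment ->
#'   `"AA"`, `"other"` or `"test"`; default is the standard panel
#'   (diazepam, fluoxetine, imipramine, LiCl = AA; ketamine, MK801 =
#'   other).
#' @param window_label `"SRB"` or `"PSRB"`.
#' @return Object of class `labelled_matrix`: list with `train` (data
#'   frame with `class` factor), `test` (unlabelled, with `treatment`),
#'   `feature_cols`, `window_label`.
#' @export
build_training_matrix <- function(norm, assignment = default_assignment(),
                                  window_label = c("SRB", "PSRB")) {
  window_label <- match.arg(window_label)
  if (anyDuplicated(names(assignment)))
    stop("a drug appears more than once in the assignment")
  bad <- setdiff(unique(norm$treatment[norm$dose_level > 0]),
                 names(assignment))
  if (length(bad))
    stop("treatment(s) without class assignment: ", paste(bad, collapse = ", "))
  d <- norm[norm$label == window_label & norm$dose_level > 0, , drop = FALSE]
  d$class <- unname(assignment[d$treatment])
  # impute missing features as 0% change; add an indicator column only for
  # features that are actually ever missing (constant columns upset the
  # kernel scaling and carry no information)
  ind <- character()
  for (f in .feature_cols) {
    if (anyNA(d[[f]])) {
      ind <- c(ind, paste0(f, "_na"))
      d[[paste0(f, "_na")]] <- as.integer(is.na(d[[f]]))
      d[[f]][is.na(d[[f]])] <- 0
    }
  }
  fcols <- c(.feature_cols, ind, "dose_level")
  structure(list(
    train = d[d$class %in% c("AA", "other"), , drop = FALSE],
    test = d[d$class == "test", , drop = FALSE],
    feature_cols = fcols, window_label = window_label),
    class = "labelled_matrix")
}

#' Default drug-class assignment of the training panel
#' @return Named character vector.
#' @export
default_assignment <- function() {
  c(diazepam = "AA", fluoxetine = "AA", imipramine = "AA", LiCl = "AA",
    ketamine = "other", MK801 = "other")
}

.as_x <- function(d, fcols) as.matrix(d[, fcols, drop = FALSE])

# grouped stratified fold ids: all cycles of one fish share a fold
.group_folds <- function(fish_id, k = 5) {
  fish <- unique(fish_id)
  fold_of <- stats::setNames(rep_len(seq_len(k), length(fish)),
                             sample(fish))
  unname(fold_of[fish_id])
}

#' Train the three phenotype classifiers
#'
#' Fits a penalized logistic regression (glmnet, lambda by internal
#' cross-validation), a polynomial-kernel SVM and a random forest on the
#' training partition, with class weighting for imbalance.  Reports both
#' resubstitution accuracy and 5-fold cross-validated accuracy with folds
#' grouped by fish (all cycles of a fish stay in one fold).
#'
#' @param lm a `labelled_matrix` from [build_training_matrix()].
#' @param seed integer seed; every stochastic step is governed by it.
#' @param kinds subset of `c("glmnet", "svm", "rf")`.
#' @return Named list of `trained_model` objects with fields `kind`,
#'   `fit`, `window_label`, `feature_cols`, `train_acc`, `cv_acc`.
#' @export
train_models <- function(lm, seed = 1,
                         kinds = c("glmnet", "svm", "rf")) {
  stopifnot(inherits(lm, "labelled_matrix"))
  y <- factor(lm$train$class, levels = c("other", "AA"))
  if (nlevels(droplevels(y)) < 2)
    stop("training data must contain both classes")
  x <- .as_x(lm$train, lm$feature_cols)
  w <- as.numeric(1 / (table(y)[y] / length(y))) / 2
  fit_one <- function(kind, x, y, w) {
    switch(kind,
      glmnet = glmnet::cv.glmnet(x, y, family = "binomial", weights = w,
                                 nfolds = 5, alpha = 1),
      svm = e1071::svm(x, y, kernel = "polynomial", degree = 3,
                       probability = TRUE, scale = TRUE,
                       class.weights = c(other = sum(y == "AA") / length(y),
                                         AA = sum(y == "other") / length(y))),
      rf = randomForest::randomForest(x, y))
  }
  pred_one <- function(kind, fit, x) {
    switch(kind,
      glmnet = as.numeric(stats::predict(fit, x, s = "lambda.min",
                                         type = "response")),
      svm = {
        p <- stats::predict(fit, x, probability = TRUE)
        attr(p, "probabilities")[, "AA"]
      },
      rf = stats::predict(fit, x, type = "prob")[, "AA"])
  }
  out <- lapply(kinds, function(kind) {
    set.seed(seed)
    fit <- fit_one(kind, x, y, w)
    sc <- pred_one(kind, fit, x)
    train_acc <- mean((sc > 0.5) == (y == "AA"))
    set.seed(seed + 1)
    folds <- .group_folds(lm$train$fish_id, 5)
    cv_hit <- rep(NA, length(y))
    for (k in sort(unique(folds))) {
      tr <- folds != k
      if (nlevels(droplevels(y[tr])) < 2) next
      f <- fit_one(kind, x[tr, , drop = FALSE], y[tr], w[tr])
      sck <- pred_one(kind, f, x[!tr, , drop = FALSE])
      cv_hit[!tr] <- (sck > 0.5) == (y[!tr] == "AA")
    }
    structure(list(kind = kind, fit = fit, window_label = lm$window_label,
                   feature_cols = lm$feature_cols,
                   train_acc = train_acc,
                   cv_acc = mean(cv_hit, na.rm = TRUE)),
              class = "trained_model")
  })
  stats::setNames(out, kinds)
}

#' Score observations with a trained model
#'
#' Returns a continuous AA-score per row (the model's probability of the
#' AA class); higher means more AA-like.
#'
#' @param model a `trained_model` from [train_models()].
#' @param rows data frame containing the model's feature columns.
#' @return Numeric vector of scores in [0, 1].
#' @export
aa_score <- function(model, rows) {
  stopifnot(inherits(model, "trained_model"))
  miss <- setdiff(model$feature_cols, names(rows))
  if (length(miss))
    stop("rows are missing model column(s): ", paste(miss, collapse = ", "))
  x <- .as_x(rows, model$feature_cols)
  switch(model$kind,
    glmnet = as.numeric(stats::predict(model$fit, x, s = "lambda.min",
                                       type = "response")),
    svm = {
      p <- stats::predict(model$fit, x, probability = TRUE)
      as.numeric(attr(p, "probabilities")[, "AA"])
    },
    rf = as.numeric(stats::predict(model$fit, x, type = "prob")[, "AA"]))
}

#' ROC curve and AUC from scores and binary labels
#'
#' The curve sweeps all score thresholds; the AUC is computed as the
#' rank (concordance) statistic, ties counted half, and therefore equals
#' the trapezoidal area under the empirical curve.
#'
#' @param scores numeric scores, higher = more positive-like.
#' @param labels logical or 0/1 vector, `TRUE` = positive class.
#' @return List with `curve` (data frame `fpr`, `tpr`) and `auc`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), any(labels), any(!labels))
  n1 <- sum(labels); n0 <- sum(!labels)
  r <- rank(scores)
  auc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(labels[ord]); fp <- cumsum(!labels[ord])
  keep <- !duplicated(scores[ord][seq_along(ord)], fromLast = TRUE)
  curve <- data.frame(fpr = c(0, fp[keep] / n0), tpr = c(0, tp[keep] / n1))
  list(curve = curve, auc = auc)
}

#' Paired-control ROC for one test drug
#'
#' The test drug's scored observations (carrying its putative class) are
#' pooled with the observations of a paired control drug of the opposite
#' class -- AA-putative drugs against the negative control (ketamine),
#' "other"-putative drugs against the positive control (fluoxetine) --
#' and the ROC of the AA-score against these labels is computed.
#'
#' @param test_scores scores of the test drug's rows.
#' @param putative_class `"AA"` or `"other"`: the test drug's putative class.
#' @param control_scores scores of the paired control drug's rows.
#' @param control_class class label of the paired control; must differ
#'   from `putative_class`.
#' @param test_drug,control_drug optional names carried into the result.
#' @return Object of class `roc_result`: `test_drug`, `control_drug`,
#'   `curve`, `auc`, `call` (the supported class when AUC >= 0.5, the
#'   opposite otherwise).
#' @export
paired_roc <- function(test_scores, putative_class, control_scores,
                       control_class, test_drug = "test",
                       control_drug = "control") {
  stopifnot(putative_class %in% c("AA", "other"),
            control_class %in% c("AA", "other"))
  if (putative_class == control_class)
    stop("paired control must have the opposite class of the test drug")
  scores <- c(test_scores, control_scores)
  lab <- c(rep(putative_class, length(test_scores)),
           rep(control_class, length(control_scores)))
  rc <- roc_curve(scores, lab == "AA")
  call <- if (rc$auc >= 0.5) putative_class else
    setdiff(c("AA", "other"), putative_class)
  structure(list(test_drug = test_drug, control_drug = control_drug,
                 putative_class = putative_class, curve = rc$curve,
                 auc = rc$auc, call = call),
            class = "roc_result")
}

#' @exportS3Method base::print
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> %s (putative %s) vs %s: AUC %.3f, call %s\n",
              x$test_drug, x$putative_class, x$control_drug, x$auc, x$call))
  invisible(x)
}

#' AUC summary over test drugs, models and windows
#'
#' Scores every test drug with every trained model and computes the
#' paired-control ROC, pairing AA-putative drugs with the negative
#' control and other-putative drugs with the positive control.
#'
#' @param models_by_window named list (`SRB`, `PSRB`) of model lists from
#'   [train_models()].
#' @param matrices_by_window matching named list of `labelled_matrix`.
#' @param putative named character vector: putative class per test drug.
#' @param positive_control,negative_control treatment names of the paired
#'   controls (default fluoxetine / ketamine).
#' @return Data frame `drug`, `model`, `window`, `auc`, `call`.
#' @export
auc_summary <- function(models_by_window, matrices_by_window, putative,
                        positive_control = "fluoxetine",
                        negative_control = "ketamine") {
  out <- list()
  for (w in names(models_by_window)) {
    lm <- matrices_by_window[[w]]
    for (m in names(models_by_window[[w]])) {
      model <- models_by_window[[w]][[m]]
      for (drug in unique(lm$test$treatment)) {
        pc <- putative[[drug]]
        ctrl_drug <- if (pc == "AA") negative_control else positive_control
        ctrl_class <- if (pc == "AA") "other" else "AA"
        ctrl_rows <- lm$train[lm$train$treatment == ctrl_drug, , drop = FALSE]
        if (!nrow(ctrl_rows))
          stop("paired control drug '", ctrl_drug, "' absent from training data")
        rr <- paired_roc(
          aa_score(model, lm$test[lm$test$treatment == drug, , drop = FALSE]),
          pc, aa_score(model, ctrl_rows), ctrl_class,
          test_drug = drug, control_drug = ctrl_drug)
        out[[length(out) + 1]] <- data.frame(
          drug = drug, model = m, window = w, auc = rr$auc, call = rr$call)
      }
    }
  }
  do.call(rbind, out)
}
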