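#' Cross-validation configuration
#'
#' Settings for the two-step cross-validation: outer folds partition the
#' healthy pool into candidate control groups (2 folds when fewer than 50
#' healthy samples, otherwise 4 — applied automatically when
#' `control_folds = NULL`); the inner loop is stratified 10-fold
#' cross-validation of the classifier.
#'
#' @param control_folds 2 or 4, or `NULL` for the automatic rule.
#' @param inner_folds inner stratified folds; default 10.
#' @param classifier `"rf"` (random forest, 500 trees) or `"svm"`
#'   (RBF kernel on standardized features).
#' @param seed integer driving every random choice (fold splits, forests).
#' @param ntree random-forest size.
#' @param svm_cost SVM cost parameter.
#' @param edge_to_length path-length semantics for topology features.
#' @param ridge diagonal loading for the Mahalanobis kernel.
#' @param auc also report a rank-based AUC pooled over folds.  Off by
#'   default: held-out healthy samples are scarce (often one or two per
#'   inner fold), so fold-wise ROC summaries are rarely well defined.
#' @return list of class `cv_config`.
#' @export
cv_config <- function(control_folds = NULL, inner_folds = 10,
                      classifier = c("rf", "svm"), seed = 1L,
                      ntree = 500, svm_cost = 1,
                      edge_to_length = "direct", ridge = 1e-8,
                      auc = FALSE) {
  classifier <- match.arg(classifier)
  if (!is.null(control_folds) && !control_folds %in% c(2L, 4L))
    stop_pn("`control_folds` must be 2 or 4 (or NULL for the automatic rule)")
  if (inner_folds < 2) stop_pn("`inner_folds` must be at least 2")
  structure(list(control_folds = control_folds, inner_folds = inner_folds,
                 classifier = classifier, seed = as.integer(seed),
                 ntree = ntree, svm_cost = svm_cost,
                 edge_to_length = edge_to_length, ridge = ridge,
                 auc = isTRUE(auc)),
            class = "cv_config")
}

auto_control_folds <- function(n_healthy) if (n_healthy < 50) 2L else 4L

#' Partition the healthy pool into candidate control groups
#'
#' Healthy samples are shuffled (seeded) and split into `n_folds` near-equal
#' disjoint folds; each fold in turn serves as the control group (used only
#' for model fitting) while the remaining healthy samples join the
#' classification set as negatives.  The fold count follows the automatic
#' rule (2 if fewer than 50 healthy samples, else 4) unless given.
#'
#' @param healthy_ids character vector of healthy sample ids.
#' @param n_folds 2 or 4; `NULL` for the automatic rule.
#' @param seed integer seed for the shuffle.
#' @return list with one element per fold, each a list
#'   `control` / `heldout_healthy`.
#' @export
split_control <- function(healthy_ids, n_folds = NULL, seed = 1L) {
  n <- length(healthy_ids)
  if (is.null(n_folds)) n_folds <- auto_control_folds(n)
  if (n < n_folds)
    stop_pn("fewer healthy samples (", n, ") than control folds (", n_folds, ")")
  shuffled <- healthy_ids[with_seed(derive_seed(seed, 1L), sample(n))]
  fold_seq <- rep(seq_len(n_folds), length.out = n)
  lapply(seq_len(n_folds), function(f)
    list(control = shuffled[fold_seq == f],
         heldout_healthy = shuffled[fold_seq != f]))
}

stratified_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    idx <- with_seed(derive_seed(seed, match(cl, levels(y))),
                     sample(idx, length(idx)))
    fold[idx] <- rep(seq_len(k), length.out = length(idx))
  }
  fold
}

standardize_train_test <- function(xtr, xte) {
  mu <- colMeans(xtr)
  sdv <- apply(xtr, 2, sd)
  sdv[sdv == 0] <- 1
  list(train = scale(xtr, center = mu, scale = sdv),
       test = scale(xte, center = mu, scale = sdv))
}

## returns class predictions; with scores = TRUE also a disease score
## (class probability / decision value) for AUC
fit_predict <- function(xtr, ytr, xte, config, seed, scores = FALSE) {
  if (config$classifier == "rf") {
    fit <- with_seed(seed, randomForest::randomForest(
      x = xtr, y = ytr, ntree = config$ntree))
    pred <- predict(fit, xte)
    if (scores) list(pred = pred,
                     score = predict(fit, xte, type = "prob")[, "disease"])
    else pred
  } else {
    sc <- standardize_train_test(xtr, xte)
    fit <- with_seed(seed, e1071::svm(
      x = sc$train, y = ytr, kernel = "radial", cost = config$svm_cost,
      scale = FALSE, probability = scores))
    pred <- predict(fit, sc$test, probability = scores)
    if (scores) {
      pr <- attr(pred, "probabilities")
      list(pred = factor(as.character(pred), levels(ytr)),
           score = pr[, "disease"])
    } else pred
  }
}

## rank-based (Mann-Whitney) AUC of disease scores
rank_auc <- function(score, truth) {
  pos <- score[truth == "disease"]; neg <- score[truth == "healthy"]
  if (!length(pos) || !length(neg)) return(NA_real_)
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

confusion_counts <- function(truth, pred) {
  c(tp = sum(truth == "disease" & pred == "disease"),
    tn = sum(truth == "healthy" & pred == "healthy"),
    fp = sum(truth == "healthy" & pred == "disease"),
    fn = sum(truth == "disease" & pred == "healthy"))
}

#' Two-step cross-validated classification
#'
#' Step one partitions the healthy pool into control folds
#' ([split_control()]); for each fold the pairwise control model is fitted
#' on that fold alone, and every remaining sample (held-out healthy =
#' negatives, disease = positives) is represented either by its 12 network
#' topology indices (`feature_mode = "topology"`) or by its raw gene-level
#' methylation values (`"raw"`, the baseline).  Step two is stratified
#' k-fold cross-validation of the classifier on those features.  Confusion
#' counts are pooled over inner and outer folds (folds differ in size, so
#' pooling counts rather than averaging rates).
#'
#' Any label other than `"disease"` counts as healthy.  Specificity is the
#' fraction of healthy samples classified negative; sensitivity the fraction
#' of disease samples classified positive.
#'
#' @param m a [methylation_matrix()] with labels.
#' @param config a [cv_config()].
#' @param kernel `"mahalanobis"` or `"regression"`.
#' @param feature_mode `"topology"` or `"raw"`.
#' @return an object of class `cv_result`: accuracy / specificity /
#'   sensitivity, pooled confusion counts, per-fold structure (control ids,
#'   classified ids, per-inner-fold counts) and the configuration echo.
#' @export
run_two_step_cv <- function(m, config = cv_config(),
                            kernel = c("mahalanobis", "regression"),
                            feature_mode = c("topology", "raw")) {
  stopifnot(inherits(m, "methylation_matrix"))
  kernel <- match.arg(kernel)
  feature_mode <- match.arg(feature_mode)
  if (is.null(m$labels)) stop_pn("sample labels are required for classification")
  labels <- m$labels
  healthy_ids <- names(labels)[labels != "disease"]
  folds <- split_control(healthy_ids, config$control_folds, config$seed)

  per_fold <- vector("list", length(folds))
  total <- c(tp = 0L, tn = 0L, fp = 0L, fn = 0L)
  for (f in seq_along(folds)) {
    control <- folds[[f]]$control
    class_ids <- setdiff(colnames(m$values), control)
    y <- factor(ifelse(labels[class_ids] == "disease", "disease", "healthy"),
                levels = c("healthy", "disease"))
    if (nlevels(droplevels(y)) < 2)
      stop_pn("only one class present outside the control group")

    X <- if (feature_mode == "topology") {
      model <- suppressWarnings(
        if (kernel == "regression") fit_regression(m$values[, control, drop = FALSE])
        else fit_mahalanobis(m$values[, control, drop = FALSE], ridge = config$ridge))
      ft <- topology_feature_table(m, model, sample_ids = class_ids,
                                   edge_to_length = config$edge_to_length)
      as.matrix(ft[, FEATURE_NAMES])
    } else {
      t(m$values[, class_ids, drop = FALSE])
    }
    rownames(X) <- class_ids

    fold_id <- stratified_folds(y, config$inner_folds,
                                derive_seed(config$seed, 100L + f))
    inner_counts <- vector("list", config$inner_folds)
    fold_scores <- fold_truth <- NULL
    for (g in seq_len(config$inner_folds)) {
      te <- fold_id == g
      if (length(unique(y[te])) < 2 || length(unique(y[!te])) < 2)
        stop_pn("inner fold ", g, " has a single class; use fewer inner folds ",
                "or a different stratification seed")
      out <- fit_predict(X[!te, , drop = FALSE], y[!te],
                         X[te, , drop = FALSE], config,
                         derive_seed(config$seed, 100L + f, g),
                         scores = config$auc)
      pred <- if (config$auc) out$pred else out
      if (config$auc) {
        fold_scores <- c(fold_scores, out$score)
        fold_truth <- c(fold_truth, as.character(y[te]))
      }
      inner_counts[[g]] <- confusion_counts(y[te], pred)
    }
    fold_total <- Reduce(`+`, inner_counts)
    total <- total + fold_total
    per_fold[[f]] <- list(control_ids = control, classified_ids = class_ids,
                          inner_counts = inner_counts, counts = fold_total,
                          auc = if (config$auc) rank_auc(fold_scores, fold_truth))
  }

  acc <- (total["tp"] + total["tn"]) / sum(total)
  spec <- total["tn"] / (total["tn"] + total["fp"])
  sens <- total["tp"] / (total["tp"] + total["fn"])
  structure(list(accuracy = unname(acc), specificity = unname(spec),
                 sensitivity = unname(sens), confusion = total,
                 auc = if (config$auc)
                   mean(unlist(lapply(per_fold, `[[`, "auc")), na.rm = TRUE),
                 per_fold = per_fold, kernel = kernel,
                 feature_mode = feature_mode, config = config),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s features, %s kernel, %s classifier\n",
              x$feature_mode, x$kernel, x$config$classifier))
  cat(sprintf("  accuracy %.4f | specificity %.4f | sensitivity %.4f  (tp=%d tn=%d fp=%d fn=%d)\n",
              x$accuracy, x$specificity, x$sensitivity,
              x$confusion["tp"], x$confusion["tn"],
              x$confusion["fp"], x$confusion["fn"]))
  invisible(x)
}

#' Serialize a cross-validation result to JSON
#'
#' @param result a `cv_result`.
#' @param path output file.
#' @export
write_cv_result <- function(result, path) {
  doc <- list(accuracy = result$accuracy, specificity = result$specificity,
              sensitivity = result$sensitivity,
              confusion = as.list(result$confusion),
              kernel = result$kernel, feature_mode = result$feature_mode,
              classifier = result$config$classifier,
              inner_folds = result$config$inner_folds,
              control_folds = length(result$per_fold),
              seed = result$config$seed,
              per_fold = lapply(result$per_fold, function(f)
                list(control_ids = f$control_ids,
                     counts = as.list(f$counts))))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
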