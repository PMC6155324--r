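# Gradient-boosted tree classifier and evaluation metrics.

#' Train the gradient-boosted hot-spot classifier
#'
#' Boosted regression trees on the second-order logistic objective
#' (XGBoost-style: exact greedy splits, L2 leaf regularization `lambda`,
#' minimum split gain `gamma`, shrinkage `eta`). Defaults follow the tuned
#' configuration: 2000 trees, maximum depth 5, gamma 0.005, remaining
#' parameters at library defaults (eta 0.3, lambda 1, min_child_weight 1).
#' Training is fully deterministic (no row/column subsampling; split ties
#' break on the lowest feature index), so `seed` only tags the model.
#'
#' @param table Feature matrix (numeric) or `hs_feature_table`.
#' @param labels Binary 0/1 vector (1 = hot spot); taken from the table's
#'   `label` column when NULL.
#' @param params Named list overriding n_trees, max_depth, eta, gamma,
#'   lambda, min_child_weight.
#' @param seed Integer recorded in the model (training is deterministic).
#' @return An `hs_model` with a predict-probability interface.
#' @export
train_model <- function(table, labels = NULL, params = list(), seed = 1) {
  if (is.data.frame(table)) {
    if (is.null(labels)) labels <- table$label
    table <- feature_matrix(table)
  }
  stopifnot(length(labels) == nrow(table))
  if (length(unique(labels)) < 2) stop("single-class training set")
  p <- modifyList(list(n_trees = 2000, max_depth = 5, eta = 0.3,
                       gamma = 0.005, lambda = 1, min_child_weight = 1),
                  params)
  means <- colMeans(table, na.rm = TRUE)
  X <- impute_features(table, means = means)
  fit <- gbm_train_cpp(X, as.numeric(labels), as.integer(p$n_trees),
                       as.integer(p$max_depth), p$eta, p$gamma, p$lambda,
                       p$min_child_weight, 0.0)
  structure(list(fit = fit, params = p, feature_names = colnames(table),
                 train_means = means, seed = seed,
                 engine = paste0("hotspotr-gbt ",
                                 as.character(utils::packageVersion("hotspotr")))),
            class = "hs_model")
}

#' @export
print.hs_model <- function(x, ...) {
  cat("<hs_model> ", x$params$n_trees, " trees, depth ", x$params$max_depth,
      ", gamma ", x$params$gamma, ", ", length(x$feature_names),
      " features\n", sep = "")
  invisible(x)
}

#' Predict hot-spot probabilities
#'
#' @param object An `hs_model`.
#' @param newdata Feature matrix or `hs_feature_table` containing the model's
#'   feature columns.
#' @param type `"prob"` or `"class"` (threshold `threshold`).
#' @param threshold Probability cutoff for class calls.
#' @param ... Ignored.
#' @return Numeric probabilities or integer 0/1 classes.
#' @export
predict.hs_model <- function(object, newdata, type = c("prob", "class"),
                             threshold = 0.5, ...) {
  type <- match.arg(type)
  if (is.data.frame(newdata)) newdata <- feature_matrix(newdata)
  newdata <- newdata[, object$feature_names, drop = FALSE]
  newdata <- impute_features(newdata, means = object$train_means)
  m <- gbm_margin_cpp(object$fit$trees, object$fit$base_margin, newdata)
  pr <- 1 / (1 + exp(-m))
  if (type == "prob") pr else as.integer(pr >= threshold)
}

#' Gain-based feature importance of a fitted model
#' @param model An `hs_model`.
#' @return Named numeric vector (total split gain per feature).
#' @export
model_importance <- function(model) {
  setNames(as.numeric(model$fit$importance), model$feature_names)
}

#' Confusion-count evaluation metrics
#'
#' Exact metric arithmetic from TP/TN/FP/FN: specificity TN/(TN+FP),
#' precision TP/(TP+FP), sensitivity TP/(TP+FN), accuracy
#' (TP+TN)/total, F1 = 2*PRE*SEN/(PRE+SEN), and Matthews correlation
#' (TP*TN - FP*FN)/sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)). A metric whose
#' denominator is zero is reported as NA (undefined sentinel), never
#' substituted by 0.
#'
#' @param counts Named list/vector with TP, TN, FP, FN.
#' @return Named numeric vector: ACC, SPE, PRE, SEN, F1, MCC.
#' @export
confusion_metrics <- function(counts) {
  tp <- as.numeric(counts[["TP"]]); tn <- as.numeric(counts[["TN"]])
  fp <- as.numeric(counts[["FP"]]); fn <- as.numeric(counts[["FN"]])
  if (any(c(tp, tn, fp, fn) < 0)) stop("negative counts")
  total <- tp + tn + fp + fn
  if (total == 0) stop("all-zero counts")
  div <- function(num, den) if (den == 0) NA_real_ else num / den
  spe <- div(tn, tn + fp)
  pre <- div(tp, tp + fp)
  sen <- div(tp, tp + fn)
  acc <- (tp + tn) / total
  f1 <- if (is.na(pre) || is.na(sen) || pre + sen == 0) NA_real_ else
    2 * pre * sen / (pre + sen)
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (mcc_den == 0) NA_real_ else (tp * tn - fp * fn) / mcc_den
  c(ACC = acc, SPE = spe, PRE = pre, SEN = sen, F1 = f1, MCC = mcc)
}

#' ROC and precision-recall curves with areas
#'
#' Trapezoidal ROC AUC over all score thresholds and step-interpolated
#' precision-recall AUC.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Binary 0/1 labels.
#' @return List: roc (data.frame fpr, tpr), pr (data.frame recall,
#'   precision), roc_auc, pr_auc.
#' @export
roc_pr_curves <- function(scores, labels) {
  labels <- as.integer(labels)
  np <- sum(labels == 1)
  nn <- sum(labels == 0)
  if (np == 0 || nn == 0) stop("need both classes")
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  s <- scores[ord]
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  # one operating point per distinct threshold
  keep <- c(diff(s) != 0, TRUE)
  tp <- tp[keep]; fp <- fp[keep]
  tpr <- c(0, tp / np)
  fpr <- c(0, fp / nn)
  roc_auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  rec <- tp / np
  prec <- tp / (tp + fp)
  # step interpolation: area = sum precision * delta recall
  pr_auc <- sum(prec * diff(c(0, rec)))
  list(roc = data.frame(fpr = fpr, tpr = tpr),
       pr = data.frame(recall = rec, precision = prec),
       roc_auc = roc_auc, pr_auc = pr_auc)
}

# deterministic stratified fold assignment
stratified_folds <- function(labels, folds, seed) {
  n <- length(labels)
  fold <- integer(n)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else if (exists(".Random.seed", .GlobalEnv))
            rm(".Random.seed", envir = .GlobalEnv))
  set.seed(seed)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    idx <- sample(idx)
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

#' Repeated stratified cross-validation report
#'
#' Pools out-of-fold predicted probabilities within each repeat, scores them
#' with [confusion_metrics()] at `threshold` plus ROC/PR AUC, and averages
#' over repeats. Fully reproducible given `seed`.
#'
#' @param table Feature matrix or `hs_feature_table`.
#' @param labels Binary labels (from the table when NULL).
#' @param folds Number of folds (default 10).
#' @param repeats Number of repeats (default 1).
#' @param seed Integer seed for fold assignment.
#' @param params Classifier parameters (see [train_model()]).
#' @param threshold Probability cutoff for class calls.
#' @return An `hs_eval_report`: list with counts, metrics, roc_auc, pr_auc
#'   (repeat means), per_repeat data.frame, oof probabilities of the first
#'   repeat, and the engine/params/seed provenance.
#' @export
cross_validate <- function(table, labels = NULL, folds = 10, repeats = 1,
                           seed = 1, params = list(), threshold = 0.5) {
  if (is.data.frame(table)) {
    if (is.null(labels)) labels <- table$label
    table <- feature_matrix(table)
  }
  labels <- as.integer(labels)
  n <- nrow(table)
  if (n < folds) stop("fewer samples than folds")
  if (min(table(labels)) < folds)
    stop("a class has fewer members than folds; cannot stratify")
  X <- impute_features(table)
  per <- vector("list", repeats)
  oof1 <- NULL
  for (r in seq_len(repeats)) {
    fold <- stratified_folds(labels, folds, seed + 1000L * (r - 1L))
    prob <- numeric(n)
    for (f in seq_len(folds)) {
      tr <- fold != f
      fit <- train_model(X[tr, , drop = FALSE], labels[tr], params = params,
                         seed = seed)
      prob[!tr] <- predict(fit, X[!tr, , drop = FALSE])
    }
    if (r == 1L) oof1 <- prob
    cls <- as.integer(prob >= threshold)
    cnt <- c(TP = sum(cls == 1 & labels == 1), TN = sum(cls == 0 & labels == 0),
             FP = sum(cls == 1 & labels == 0), FN = sum(cls == 0 & labels == 1))
    curves <- roc_pr_curves(prob, labels)
    per[[r]] <- c(cnt, confusion_metrics(cnt), AUC = curves$roc_auc,
                  PRAUC = curves$pr_auc)
  }
  per_df <- as.data.frame(do.call(rbind, per))
  means <- colMeans(per_df)
  structure(list(
    counts = as.list(per_df[1, c("TP", "TN", "FP", "FN")]),
    metrics = means[c("ACC", "SPE", "PRE", "SEN", "F1", "MCC")],
    roc_auc = unname(means["AUC"]), pr_auc = unname(means["PRAUC"]),
    per_repeat = per_df, oof_prob = oof1, folds = folds, repeats = repeats,
    seed = seed, threshold = threshold,
    params = modifyList(list(n_trees = 2000, max_depth = 5, eta = 0.3,
                             gamma = 0.005, lambda = 1,
                             min_child_weight = 1), params),
    engine = paste0("hotspotr-gbt ",
                    as.character(utils::packageVersion("hotspotr")))),
    class = "hs_eval_report")
}

#' @export
print.hs_eval_report <- function(x, ...) {
  cat("<hs_eval_report> ", x$folds, "-fold x ", x$repeats, " repeat(s)\n",
      sep = "")
  print(round(c(x$metrics, AUC = x$roc_auc, PRAUC = x$pr_auc), 4))
  invisible(x)
}

#' Serialize an evaluation report (or any list) as canonical JSON
#' @param report List-like object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  obj <- unclass(report)
  obj$oof_prob <- NULL
  if (!is.null(obj$metrics)) obj$metrics <- as.list(obj$metrics)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}

#' Grid search over boosting hyperparameters
#'
#' Optional helper replicating the tuning protocol: exhaustive grid over
#' n_trees, max_depth and gamma scored by repeated cross-validated Rc.
#'
#' @param table,labels Training data.
#' @param grid data.frame of candidate parameter rows (columns n_trees,
#'   max_depth, gamma).
#' @param folds,repeats,seed Cross-validation control.
#' @return The grid with an `Rc` column, sorted best-first.
#' @export
grid_search <- function(table, labels = NULL, grid = expand.grid(
                          n_trees = c(500, 2000), max_depth = c(3, 5),
                          gamma = c(0, 0.005)),
                        folds = 10, repeats = 1, seed = 1) {
  if (is.data.frame(table)) {
    if (is.null(labels)) labels <- table$label
    table <- feature_matrix(table)
  }
  grid$Rc <- vapply(seq_len(nrow(grid)), function(k) {
    rc_score(colnames(table), table, labels, n_repeats = repeats, seed = seed,
             folds = folds, params = as.list(grid[k, c("n_trees", "max_depth",
                                                       "gamma")]))
  }, numeric(1))
  grid[order(-grid$Rc), , drop = FALSE]
}
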