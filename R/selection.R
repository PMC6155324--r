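# Two-step feature selection: mRMR ranking, greedy triple initialization,
# sequential forward selection under the cross-validated Rc criterion, plus
# F-score and permutation-importance diagnostics.

# classic mRMR discretization: 3 bins at mean +/- sd
discretize_feature <- function(x, n_bins = 3) {
  if (length(unique(x)) <= 1) return(rep(0L, length(x)))
  if (n_bins == 3) {
    mu <- mean(x); s <- sd(x)
    if (s == 0) return(rep(0L, length(x)))
    as.integer(cut(x, c(-Inf, mu - s, mu + s, Inf), labels = FALSE)) - 1L
  } else {
    br <- unique(quantile(x, probs = seq(0, 1, length.out = n_bins + 1)))
    if (length(br) < 2) return(rep(0L, length(x)))
    as.integer(cut(x, br, labels = FALSE, include.lowest = TRUE)) - 1L
  }
}

#' Mutual information between a feature and a label
#'
#' Plug-in histogram estimate (bits) on the discretized joint distribution.
#' Continuous features are discretized into `n_bins` bins (3 bins split at
#' mean +/- sd, the classic mRMR practice); integer-valued inputs with few
#' levels are used as-is. A constant feature has MI 0.
#'
#' @param x Numeric feature vector.
#' @param y Binary label vector (or second feature, discretized the same
#'   way).
#' @param n_bins Number of discretization bins (>= 2).
#' @return Non-negative MI estimate in bits.
#' @export
mutual_information <- function(x, y, n_bins = 3) {
  stopifnot(n_bins >= 2)
  dx <- if (is.integer(x) && length(unique(x)) <= n_bins)
    as.integer(factor(x)) - 1L else discretize_feature(as.numeric(x), n_bins)
  dy <- if (length(unique(y)) <= max(n_bins, 2))
    as.integer(factor(y)) - 1L else discretize_feature(as.numeric(y), n_bins)
  mi_disc_cpp(dx, dy, max(dx) + 1L, max(dy) + 1L)
}

#' Minimum-redundancy maximum-relevance feature ranking
#'
#' Greedy incremental ranking: the first feature maximizes MI with the label;
#' each next feature maximizes MI(feature, label) minus the mean MI with the
#' already selected features (the MID difference form).
#'
#' @param table Feature matrix or `hs_feature_table`.
#' @param labels Binary labels (from the table when NULL).
#' @param k Number of features to rank (defaults to all).
#' @param n_bins Discretization bins.
#' @return Character vector of the top-k feature names in rank order.
#' @export
mrmr_rank <- function(table, labels = NULL, k = NULL, n_bins = 3) {
  if (is.data.frame(table)) {
    if (is.null(labels)) labels <- table$label
    table <- feature_matrix(table)
  }
  p <- ncol(table)
  if (is.null(k)) k <- p
  if (k <= 0) stop("k must be positive")
  k <- min(k, p)
  disc <- vector("list", p)
  for (j in seq_len(p)) disc[[j]] <- discretize_feature(as.numeric(table[, j]))
  dy <- as.integer(factor(labels)) - 1L
  nl <- function(v) max(v) + 1L
  rel <- vapply(seq_len(p), function(j)
    mi_disc_cpp(disc[[j]], dy, nl(disc[[j]]), nl(dy)), numeric(1))
  selected <- integer(0)
  remaining <- seq_len(p)
  red_sum <- numeric(p)
  for (step in seq_len(k)) {
    crit <- if (!length(selected)) rel[remaining] else
      rel[remaining] - red_sum[remaining] / length(selected)
    pick <- remaining[which.max(crit)]
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
    if (length(remaining))
      red_sum[remaining] <- red_sum[remaining] +
        vapply(remaining, function(j)
          mi_disc_cpp(disc[[j]], disc[[pick]], nl(disc[[j]]), nl(disc[[pick]])),
          numeric(1))
  }
  colnames(table)[selected]
}

#' Composite ranking criterion Rc of a feature subset
#'
#' Mean over `n_repeats` repeats of stratified 10-fold cross-validation of
#' ACC + SEN + SPE + AUC, evaluated with the boosted-tree classifier on the
#' given feature subset. Range `[0, 4]`; deterministic given `seed`.
#'
#' @param feature_subset Character vector of feature names.
#' @param table Feature matrix or `hs_feature_table`.
#' @param labels Binary labels.
#' @param n_repeats Repeats of the 10-fold cross-validation (default 5).
#' @param seed Integer seed.
#' @param folds Number of folds (default 10).
#' @param params Classifier parameters; the selection default is a
#'   scaled-down learner (100 trees, depth 3) for tractability.
#' @return Rc value.
#' @export
rc_score <- function(feature_subset, table, labels = NULL, n_repeats = 5,
                     seed = 1, folds = 10,
                     params = list(n_trees = 100, max_depth = 3)) {
  if (is.data.frame(table)) {
    if (is.null(labels)) labels <- table$label
    table <- feature_matrix(table)
  }
  if (!length(feature_subset)) stop("empty feature subset")
  X <- table[, feature_subset, drop = FALSE]
  rep <- cross_validate(X, labels, folds = folds, repeats = n_repeats,
                        seed = seed, params = params)
  mean(rep$per_repeat$ACC + rep$per_repeat$SEN + rep$per_repeat$SPE +
         rep$per_repeat$AUC)
}

#' Greedy initial feature triple from the mRMR top-m features
#'
#' Forward-selects three features: the best single feature by Rc, then the
#' best pair extension, then the best triple extension. Ties break by mRMR
#' rank (earlier wins).
#'
#' @param top50 Candidate feature names (mRMR order).
#' @param table,labels Data.
#' @param n_repeats,seed,folds,params Passed to [rc_score()].
#' @return List: features (length 3), rc (Rc of the triple).
#' @export
select_initial_triple <- function(top50, table, labels = NULL, n_repeats = 5,
                                  seed = 1, folds = 10,
                                  params = list(n_trees = 100, max_depth = 3)) {
  if (length(top50) < 3) stop("need at least 3 candidate features")
  if (is.data.frame(table)) {
    if (is.null(labels)) labels <- table$label
    table <- feature_matrix(table)
  }
  current <- character(0)
  best_rc <- NA_real_
  for (step in 1:3) {
    cand <- setdiff(top50, current)
    rcs <- vapply(cand, function(f)
      rc_score(c(current, f), table, labels, n_repeats, seed, folds, params),
      numeric(1))
    pick <- cand[which.max(rcs)]   # first max = earlier mRMR rank
    best_rc <- max(rcs)
    current <- c(current, pick)
  }
  list(features = current, rc = best_rc)
}

#' Sequential forward selection under the Rc criterion
#'
#' Starting from the initial subset, repeatedly adds the pool feature whose
#' addition maximizes Rc, stopping when no candidate strictly increases Rc
#' (or after `max_steps` additions). The recorded trajectory of Rc values is
#' non-decreasing by construction.
#'
#' @param initial Starting feature names (e.g. the greedy triple).
#' @param top500 Candidate pool (mRMR order).
#' @param table,labels Data.
#' @param n_repeats,seed,folds,params Passed to [rc_score()].
#' @param max_steps Safety cap on the number of additions.
#' @return An `hs_selection`: list with mrmr_pool, initial, trajectory
#'   (data.frame feature, rc), final_subset, final_rc.
#' @export
sequential_forward_selection <- function(initial, top500, table, labels = NULL,
                                         n_repeats = 5, seed = 1, folds = 10,
                                         params = list(n_trees = 100,
                                                       max_depth = 3),
                                         max_steps = 30) {
  if (is.data.frame(table)) {
    if (is.null(labels)) labels <- table$label
    table <- feature_matrix(table)
  }
  current <- initial
  rc_now <- rc_score(current, table, labels, n_repeats, seed, folds, params)
  traj <- data.frame(feature = paste(initial, collapse = "+"), rc = rc_now,
                     stringsAsFactors = FALSE)
  for (step in seq_len(max_steps)) {
    cand <- setdiff(top500, current)
    if (!length(cand)) break
    rcs <- vapply(cand, function(f)
      rc_score(c(current, f), table, labels, n_repeats, seed, folds, params),
      numeric(1))
    best <- which.max(rcs)
    if (rcs[best] <= rc_now) break   # no strict increase: stop
    current <- c(current, cand[best])
    rc_now <- rcs[best]
    traj <- rbind(traj, data.frame(feature = cand[best], rc = rc_now,
                                   stringsAsFactors = FALSE))
  }
  structure(list(mrmr_pool = top500, initial = initial, trajectory = traj,
                 final_subset = current, final_rc = rc_now),
            class = "hs_selection")
}

#' @export
print.hs_selection <- function(x, ...) {
  cat("<hs_selection> ", length(x$final_subset), " features, Rc = ",
      round(x$final_rc, 4), "\n", sep = "")
  invisible(x)
}

#' Run the complete two-step feature selection
#'
#' mRMR ranking, top-m / pool extraction, greedy triple initialization and
#' sequential forward selection.
#'
#' @param table,labels Data.
#' @param top_m Size of the initial-triple candidate list (default 50).
#' @param pool Size of the SFS candidate pool (default 500).
#' @param n_repeats,seed,folds,params,max_steps Selection control.
#' @return An `hs_selection` with additional elements mrmr_ranking and
#'   initial_rc.
#' @export
two_step_selection <- function(table, labels = NULL, top_m = 50, pool = 500,
                               n_repeats = 5, seed = 1, folds = 10,
                               params = list(n_trees = 100, max_depth = 3),
                               max_steps = 30) {
  if (is.data.frame(table)) {
    if (is.null(labels)) labels <- table$label
    table <- feature_matrix(table)
  }
  ranking <- mrmr_rank(table, labels, k = min(pool, ncol(table)))
  top50 <- head(ranking, top_m)
  init <- select_initial_triple(top50, table, labels, n_repeats, seed, folds,
                                params)
  sel <- sequential_forward_selection(init$features, ranking, table, labels,
                                      n_repeats, seed, folds, params,
                                      max_steps)
  sel$mrmr_ranking <- ranking
  sel$top50 <- top50
  sel$initial_rc <- init$rc
  sel
}

#' Serialize a selection result as JSON
#' @param selection An `hs_selection`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_selection_json <- function(selection, path) {
  jsonlite::write_json(unclass(selection), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "columns", pretty = TRUE)
  invisible(path)
}

#' Two-class F-score of a feature
#'
#' Between-class over within-class variance ratio:
#' `((m+ - m)^2 + (m- - m)^2) / (s+^2 + s-^2)` with unbiased class
#' variances; 0 when both classes share mean and variance structure.
#'
#' @param feature Numeric vector.
#' @param labels Binary labels.
#' @return Non-negative F-score (Inf if within-class variance is 0 but the
#'   means differ).
#' @export
f_score <- function(feature, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("single-class labels")
  xp <- feature[labels == 1]; xn <- feature[labels == 0]
  m <- mean(feature)
  num <- (mean(xp) - m)^2 + (mean(xn) - m)^2
  den <- var(xp) + var(xn)
  if (den == 0) {
    if (num == 0) return(0)
    return(Inf)
  }
  num / den
}

#' Permutation importance p-values (PIMP)
#'
#' Re-trains the model on label permutations and reports, per feature, the
#' fraction of permuted-label importances at least as large as the observed
#' importance (add-one corrected): small p-values mark features whose
#' importance is unlikely under the no-association null.
#'
#' @param model A fitted `hs_model`.
#' @param table,labels The training data.
#' @param n_perm Number of label permutations.
#' @param seed Integer seed.
#' @return data.frame: feature, importance, p_value.
#' @export
permutation_importance <- function(model, table, labels = NULL, n_perm = 50,
                                   seed = 1) {
  if (is.data.frame(table)) {
    if (is.null(labels)) labels <- table$label
    table <- feature_matrix(table)
  }
  obs <- model_importance(model)
  exceed <- numeric(length(obs))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  for (b in seq_len(n_perm)) {
    yp <- sample(labels)
    fitp <- train_model(table, yp, params = model$params, seed = seed)
    exceed <- exceed + as.numeric(model_importance(fitp) >= obs)
  }
  data.frame(feature = names(obs), importance = unname(obs),
             p_value = unname((exceed + 1) / (n_perm + 1)),
             stringsAsFactors = FALSE)
}
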