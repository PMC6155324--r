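test_that("mutual information: closed forms and histogram oracle", {
  y <- rep(c(0L, 1L), each = 100)
  expect_equal(mutual_information(rep(1, 200), y), 0)
  expect_equal(mutual_information(as.integer(y), y), 1)   # identity channel
  # Gaussian mixture against the brute-force plug-in oracle
  set.seed(13)
  x <- rnorm(200) + 1.2 * y
  dx <- hotspotr:::discretize_feature(x)
  expect_equal(mutual_information(x, y), brute_mi(dx, y), tolerance = 1e-12)
  expect_error(mutual_information(x, y, n_bins = 1), "n_bins")
})

test_that("mRMR ranking: step-1 relevance, redundancy, brute-force oracle", {
  m <- make_feature_matrix(n_samples = 150, n_features = 8, n_informative = 2,
                           effect_size = 2, n_duplicate = 1, seed = 6)
  X <- feature_matrix(m)
  y <- m$label
  r <- mrmr_rank(X, y, k = ncol(X))
  # first selected = argmax MI with the label
  rel <- vapply(seq_len(ncol(X)), function(j) mutual_information(X[, j], y),
                numeric(1))
  expect_equal(r[1], colnames(X)[which.max(rel)])
  # exact duplicate of the first pick is maximally redundant: never 2nd
  first <- r[1]
  dup_of_first <- if (first == "F0001") "Dup1" else if (first == "Dup1") "F0001" else NA
  if (!is.na(dup_of_first)) expect_false(r[2] == dup_of_first)
  # equals the independent brute-force greedy on the full matrix
  expect_identical(r, brute_mrmr(X, y, ncol(X)))
  expect_error(mrmr_rank(X, y, k = 0), "positive")
})

test_that("Rc: bounds, determinism, separable maximum", {
  m <- make_feature_matrix(n_samples = 100, n_features = 6, n_informative = 2,
                           effect_size = 6, class_balance = 0.5, seed = 7)
  rc1 <- rc_score(c("F0001", "F0002"), m, n_repeats = 2, seed = 3,
                  params = list(n_trees = 60, max_depth = 3))
  rc2 <- rc_score(c("F0001", "F0002"), m, n_repeats = 2, seed = 3,
                  params = list(n_trees = 60, max_depth = 3))
  expect_identical(rc1, rc2)
  expect_gt(rc1, 3.8)          # nearly separable: Rc approaches 4
  expect_lte(rc1, 4)
  expect_error(rc_score(character(0), m), "empty")
})

test_that("initial triple recovers planted orthogonal signals", {
  m <- make_feature_matrix(n_samples = 200, n_features = 12, n_informative = 3,
                           effect_size = 1.8, seed = 8)
  top <- mrmr_rank(m, k = 8)
  tri <- select_initial_triple(top, m, n_repeats = 2, seed = 4,
                               params = list(n_trees = 50, max_depth = 3))
  expect_length(tri$features, 3)
  expect_gte(length(intersect(tri$features, c("F0001", "F0002", "F0003"))), 2)
  tri2 <- select_initial_triple(top, m, n_repeats = 2, seed = 4,
                                params = list(n_trees = 50, max_depth = 3))
  expect_identical(tri$features, tri2$features)
  expect_error(select_initial_triple(top[1:2], m), "at least 3")
})

test_that("SFS: non-decreasing trajectory, stops, shuns constant features", {
  m <- make_feature_matrix(n_samples = 150, n_features = 10, n_informative = 2,
                           effect_size = 2.5, seed = 9)
  m$Const <- 0   # constant feature can never increase Rc
  pool <- c(mrmr_rank(feature_matrix(m), m$label, k = 10), "Const")
  sel <- sequential_forward_selection(pool[1:2], pool, m, n_repeats = 2,
                                      seed = 5,
                                      params = list(n_trees = 50, max_depth = 3),
                                      max_steps = 6)
  expect_true(all(diff(sel$trajectory$rc) >= 0))
  expect_false("Const" %in% sel$final_subset)
  expect_true(all(sel$final_subset %in% pool))
  # two planted signals: selection does not balloon
  expect_lte(length(sel$final_subset), 8)
})

test_that("F-score: null, separation and ranking behavior", {
  y <- rep(c(0, 1), each = 50)
  x_null <- rep(c(1, 2), 50)           # identical distribution in both classes
  expect_equal(f_score(x_null, y), 0)
  x_sep <- c(rnorm(50, -5, 0.3), rnorm(50, 5, 0.3))  # disjoint supports
  x_noise <- rnorm(100)
  expect_gt(f_score(x_sep, y), f_score(x_noise, y))
  expect_gt(f_score(x_sep, y), 50)
  expect_error(f_score(x_noise, rep(1, 100)), "single-class")
})

test_that("permutation importance gives null features large p-values", {
  m <- make_feature_matrix(n_samples = 120, n_features = 5, n_informative = 1,
                           effect_size = 3, seed = 10)
  fit <- train_model(m, params = list(n_trees = 60, max_depth = 3))
  pim <- permutation_importance(fit, m, n_perm = 30, seed = 11)
  expect_equal(nrow(pim), 5)    # one row per feature
  expect_lt(pim$p_value[pim$feature == "F0001"], 0.1)   # planted: significant
  expect_gt(max(pim$p_value[pim$feature != "F0001"]), 0.05)  # noise: not all small
  expect_true(all(pim$p_value > 0 & pim$p_value <= 1))
})

test_that("two-step selection plumbing and JSON serialization", {
  m <- make_feature_matrix(n_samples = 120, n_features = 15, n_informative = 2,
                           effect_size = 2.5, seed = 12)
  sel <- two_step_selection(m, top_m = 6, pool = 10, n_repeats = 1, seed = 6,
                            params = list(n_trees = 40, max_depth = 3),
                            max_steps = 3)
  expect_true(all(sel$final_subset %in% sel$mrmr_ranking))
  expect_true(all(sel$initial %in% sel$top50))
  f <- withr::local_tempfile(fileext = ".json")
  write_selection_json(sel, f)
  js <- jsonlite::read_json(f)
  expect_equal(unlist(js$final_subset), sel$final_subset)
})
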