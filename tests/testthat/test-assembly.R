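test_that("neighborhood aggregation is center + neighbor sum", {
  # two mutual neighbours with site values 1 and 2
  vals <- matrix(c(1, 2), 2, 1, dimnames = list(c("A:1", "A:2"), "f"))
  g <- hotspotr:::new_neighbor_graph("euclidean", cbind(i = 1L, j = 2L), 2,
                                     c("A:1", "A:2"))
  expect_equal(unname(aggregate_neighborhood(vals, g)[, 1]), c(3, 3))
  # residue with no neighbours: context equals its own site vector
  g0 <- hotspotr:::new_neighbor_graph("euclidean",
                                      matrix(integer(0), 0, 2), 2,
                                      c("A:1", "A:2"))
  expect_equal(aggregate_neighborhood(vals, g0), vals)
  expect_equal(unname(aggregate_neighborhood(vals, g, include_center = FALSE)[, 1]),
               c(2, 1))
})

test_that("aggregation equals brute-force summation on a real graph", {
  st <- cached_dimer(8, 4, 1)
  g <- euclidean_neighbors(st, 5)
  set.seed(8)
  vals <- matrix(rnorm(nrow(st$residues) * 3), ncol = 3,
                 dimnames = list(st$residues$res_id, c("a", "b", "c")))
  agg <- aggregate_neighborhood(vals, g)
  for (i in seq_len(nrow(vals))) {
    nb <- c(i, g$edges[g$edges[, 1] == i, 2], g$edges[g$edges[, 2] == i, 1])
    expect_equal(agg[i, ], colSums(vals[nb, , drop = FALSE]))
  }
})

test_that("W_FB weighting semantics and order of operations", {
  st <- cached_dimer(10, 4, 1)
  sp <- surface_profile(st)
  iface <- sp$res_id[sp$is_interface]
  v <- rep(1, 5)
  expect_equal(apply_weighting(v, sp, iface[1]),
               v * sp$W_FB[match(iface[1], sp$res_id)])
  non <- sp$res_id[!sp$is_interface][1]
  expect_error(apply_weighting(v, sp, non), "non-interface")
  expect_error(apply_weighting(v, sp, "Z:999"), "unknown residue")

  # weighted-then-aggregated equals aggregation of per-residue products
  g <- euclidean_neighbors(st, 5)
  set.seed(2)
  vals <- matrix(rnorm(nrow(sp) * 2), ncol = 2,
                 dimnames = list(sp$res_id, c("x", "y")))
  full <- hotspotr:::expand_feature_blocks(vals, sp, g, g)
  wfb <- sp$W_FB
  manual <- aggregate_neighborhood(vals * wfb, g)
  expect_equal(unname(full[, c("W_x_EN", "W_y_EN")]), unname(manual))
  # W_FB = 0 residues have all-zero weighted site features
  zero <- which(wfb == 0)
  expect_true(all(full[zero, c("W_x", "W_y")] == 0))
})

test_that("feature table assembly: shape, labels, exclusions, determinism", {
  st1 <- cached_dimer(8, 4, 1)
  st2 <- cached_dimer(8, 4, 7)
  dir <- withr::local_tempdir()
  tr1 <- make_tracks(st1, file.path(dir, "c1"), seed = 1)
  tr2 <- make_tracks(st2, file.path(dir, "c2"), seed = 2)
  labels <- data.frame(
    complex_id = c("c1", "c1", "c1", "c2", "c2"),
    chain = c("A", "B", "A", "A", "B"),
    resnum = c(4, 5, 3, 5, 4),
    ddG = c(2.5, 0.3, 2.0, 1.9, 4.0))
  ft <- build_feature_table(list(c1 = st1, c2 = st2), labels,
                            tracks = list(c1 = tr1$tracks, c2 = tr2$tracks))
  expect_s3_class(ft, "hs_feature_table")
  expect_equal(nrow(ft), 5)
  expect_equal(ncol(feature_matrix(ft)), 6 * length(site_feature_names()))
  expect_equal(ft$label, as.integer(ft$ddG >= 2.0))

  # complex input order does not change the (sorted) rows
  ft2 <- build_feature_table(list(c2 = st2, c1 = st1), labels,
                             tracks = list(c1 = tr1$tracks, c2 = tr2$tracks))
  expect_identical(as.data.frame(ft), as.data.frame(ft2))

  # unmapped labeled residue lands in the exclusion report
  labels_bad <- rbind(labels,
                      data.frame(complex_id = "c1", chain = "A", resnum = 99,
                                 ddG = 3))
  ft3 <- build_feature_table(list(c1 = st1, c2 = st2), labels_bad,
                             tracks = list(c1 = tr1$tracks, c2 = tr2$tracks))
  expect_equal(attr(ft3, "exclusions")$c1, "A:99")
  expect_equal(nrow(ft3), 5)

  # empty label set: empty table with the full header
  ft0 <- build_feature_table(list(c1 = st1),
                             labels[labels$complex_id == "none", ])
  expect_equal(nrow(ft0), 0)
  expect_true(all(feature_table_names() %in% names(ft0)))

  # BID-style annotation labels
  lab_ann <- data.frame(complex_id = "c1", chain = c("A", "B"),
                        resnum = c(4, 5),
                        annotation = c("strong", "intermediate"))
  ft4 <- build_feature_table(list(c1 = st1), lab_ann,
                             tracks = list(c1 = tr1$tracks))
  expect_equal(ft4$label, c(1L, 0L))
})

test_that("feature table TSV serialization is lossless and byte-stable", {
  m <- make_feature_matrix(n_samples = 40, n_features = 6, seed = 3)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(m, f1)
  back <- read_feature_table(f1)
  expect_equal(feature_matrix(back), feature_matrix(m), ignore_attr = TRUE)
  write_feature_table(back, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("imputation fills NA with column means and records them", {
  X <- cbind(a = c(1, 2, NA, 3), b = c(1, 1, 1, 1))
  Xi <- impute_features(X)
  expect_equal(unname(Xi[3, "a"]), 2)
  expect_equal(attr(Xi, "imputed"), "a")
  Xr <- impute_features(X, means = c(a = 10, b = 0))
  expect_equal(unname(Xr[3, "a"]), 10)
})
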