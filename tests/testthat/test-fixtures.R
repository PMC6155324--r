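test_that("dimer generator: gap control, interface guarantee, determinism", {
  d1 <- make_dimer(n_res = 8, gap = 4, seed = 3)
  d2 <- make_dimer(n_res = 8, gap = 4, seed = 3)
  expect_identical(d1$atoms, d2$atoms)
  d3 <- make_dimer(n_res = 8, gap = 4, seed = 4)
  expect_false(identical(d1$atoms$x, d3$atoms$x))
  expect_error(make_dimer(gap = 0), "positive")
  expect_error(make_dimer(n_res = 3), "n_res")

  # realized minimum inter-chain distance is close to the requested gap
  a <- d1$atoms[d1$atoms$chain == "A", c("x", "y", "z")]
  b <- d1$atoms[d1$atoms$chain == "B", c("x", "y", "z")]
  dmin <- min(sqrt(outer(rowSums(a^2), rowSums(b^2), "+") -
                     2 * as.matrix(a) %*% t(as.matrix(b))))
  expect_lt(abs(dmin - 4), 0.1)

  # close packing yields interface on both sides; far packing yields none
  sp <- surface_profile(cached_dimer(8, 4, 3))
  expect_true(any(sp$is_interface[sp$side == "a"]))
  expect_true(any(sp$is_interface[sp$side == "b"]))
  far <- make_dimer(n_res = 8, gap = 30, seed = 3)
  expect_error(surface_profile(far), "no interface")
})

test_that("planted feature matrices have the stated statistical structure", {
  m <- make_feature_matrix(n_samples = 300, n_features = 50, n_informative = 3,
                           effect_size = 1.5, class_balance = 0.45, seed = 5)
  X <- feature_matrix(m)
  y <- m$label
  expect_equal(dim(X), c(300, 50))
  expect_equal(sum(y), round(300 * 0.45))
  expect_identical(attr(m, "informative"), c("F0001", "F0002", "F0003"))
  shift <- colMeans(X[y == 1, ]) - colMeans(X[y == 0, ])
  expect_true(all(shift[1:3] > 1.0))            # planted effects present
  expect_true(all(abs(shift[10:50]) < 0.6))     # noise columns unshifted
  expect_identical(feature_matrix(make_feature_matrix(seed = 9,
                                                      n_samples = 40,
                                                      n_features = 5)),
                   feature_matrix(make_feature_matrix(seed = 9,
                                                      n_samples = 40,
                                                      n_features = 5)))
  # zero effect: informative columns indistinguishable from noise by rank
  m0 <- make_feature_matrix(n_samples = 200, n_features = 40,
                            n_informative = 3, effect_size = 0, seed = 6)
  rel <- vapply(seq_len(40), function(j)
    mutual_information(feature_matrix(m0)[, j], m0$label), numeric(1))
  expect_gt(mean(rank(-rel)[1:3]), 5)   # not systematically top-ranked
})

test_that("track generator ties to reader dialects and closed forms", {
  st <- cached_dimer(6, 4, 1)
  dir <- withr::local_tempdir()
  tr <- make_tracks(st, dir, seed = 7, pssm_mode = "uniform", ss_letter = "H")
  # uniform PSSM: conservation = log2(20) everywhere
  s <- site_descriptors(st, pssm = tr$tracks$pssm, dssp = tr$tracks$dssp,
                        disopred = tr$tracks$disopred,
                        disembl = tr$tracks$disembl)
  expect_true(all(abs(s[, "Cons"] - log2(20)) < 1e-9))
  # all-helix DSSP: one-hot (1,0,0) everywhere
  expect_true(all(s[, "SS1"] == 1))
  # write-then-read returns the source values
  d1 <- read_disopred(tr$files$diso_A)
  expect_equal(nrow(d1), 6)
  ps <- read_pssm(tr$files$pssm_B)
  expect_equal(ps$sequence, rep("A", 6))
  dssp <- read_dssp(tr$files$dssp)
  expect_equal(sort(unique(dssp$chain)), c("A", "B"))
  expect_true(all(dssp$ss == "H"))
})

test_that("CLI round-trip: fixtures, extraction and cross-validation", {
  dir <- withr::local_tempdir()
  pdb <- file.path(dir, "d.pdb")
  tsv <- file.path(dir, "m.tsv")
  js <- file.path(dir, "cv.json")
  expect_message(run_cli(c("make-dimer", "--n-res", "8", "--gap", "4",
                           "--seed", "2", "--out", pdb)), "wrote")
  st <- read_pdb(pdb, "A:B")
  expect_equal(nrow(st$residues), 16)
  run_cli(c("make-matrix", "--n", "60", "--p", "8", "--informative", "2",
            "--effect", "2", "--seed", "3", "--out", tsv))
  run_cli(c("crossval", "--table", tsv, "--folds", "5", "--seed", "1",
            "--out", js))
  rep <- jsonlite::read_json(js)
  expect_true(rep$metrics$ACC > 0.5)
  expect_error(run_cli(c("bogus")), "unknown command")
})
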