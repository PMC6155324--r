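make_pssm <- function(freq) {
  colnames(freq) <- aa_alphabet()
  structure(list(sequence = rep("A", nrow(freq)),
                 scores = freq * 0, freq = freq), class = "hs_pssm")
}

test_that("physicochemical lookups are consistent tables", {
  expect_identical(physicochemical("W"), physicochemical("W"))
  pol <- vapply(aa_alphabet(), function(a) physicochemical(a)[["polarity"]],
                numeric(1))
  expect_gt(length(unique(pol)), 15)   # near-distinct scale values
  expect_lt(physicochemical("G")[["Natoms"]], physicochemical("W")[["Natoms"]])
  expect_true(all(is.na(physicochemical(NA))))
  expect_false(anyNA(.subset2(as.data.frame(hotspotr:::.pka), "pKa1")))
})

test_that("conservation score hits entropy closed forms", {
  p0 <- matrix(0, 3, 20)
  p0[1, 1] <- 1                        # fully conserved
  p0[2, ] <- 1 / 20                    # maximum entropy
  p0[3, 1:2] <- 0.5                    # binary entropy
  ps <- make_pssm(p0)
  expect_equal(conservation_score(ps, 1), 0)
  expect_equal(conservation_score(ps, 2), log2(20))
  expect_equal(conservation_score(ps, 3), 1)
  expect_error(conservation_score(ps, 9), "out of range")
  expect_error(conservation_score(make_pssm(matrix(0, 1, 20)), 1), "all-zero")
})

test_that("BLOSUM62 rows: W diagonal 11, symmetry, fixed ordering", {
  expect_equal(unname(blosum_row("W")[["W"]]), 11)
  expect_equal(blosum_row("A")[["T"]], blosum_row("T")[["A"]])
  expect_identical(names(blosum_row("C")), aa_alphabet())
  expect_error(blosum_row("Z"), "unknown")
})

test_that("PSSM reader round-trips generated files", {
  st <- cached_dimer(6, 4, 1)
  dir <- withr::local_tempdir()
  tr <- make_tracks(st, dir, seed = 2, pssm_mode = "uniform")
  ps <- tr$tracks$pssm[["A"]]
  expect_s3_class(ps, "hs_pssm")
  expect_equal(nrow(ps$freq), 6)
  expect_true(all(abs(ps$freq - 1 / 20) < 1e-9))
  expect_equal(unname(pssm_row(ps, 1)), unname(ps$scores[1, ]))
  expect_error(pssm_row(ps, 99), "out of range")
  # frequencies are proper: [0,1], row sums about 1
  tr2 <- make_tracks(st, dir, seed = 3, pssm_mode = "random")
  fr <- tr2$tracks$pssm[["B"]]$freq
  expect_true(all(fr >= 0 & fr <= 1))
  expect_true(all(abs(rowSums(fr) - 1) < 0.15))   # percent rounding slack
})

test_that("secondary structure: DSSP mapping and phi/psi fallback", {
  st <- cached_dimer(8, 4, 1)
  res <- st$residues
  for (letter in c("H", "G", "E", "B", "T", " ")) {
    track <- data.frame(chain = res$chain, resseq = res$resseq, icode = "",
                        aa = res$aa, ss = letter, acc = 50,
                        res_id = res$res_id, stringsAsFactors = FALSE)
    m <- secondary_structure(st, track)
    expect_true(all(rowSums(m) == 1))
    expected <- if (letter %in% c("H", "G")) 1 else if (letter %in% c("E", "B")) 2 else 3
    expect_true(all(m[, expected] == 1))
  }
  # fallback on the ideal helix: interior residues all helix, termini coil
  m <- secondary_structure(st)
  interior <- !(res$resseq %in% c(1, 8))
  expect_true(all(m[interior, "SS1"] == 1))
  expect_true(all(rowSums(m) == 1))
})

test_that("disorder tracks attach by residue id, order-independent", {
  st <- cached_dimer(6, 4, 1)
  dir <- withr::local_tempdir()
  tr <- make_tracks(st, dir, seed = 1, disorder_value = 0.5)
  d <- disorder_scores(st, tr$tracks$disopred, tr$tracks$disembl)
  expect_true(all(d[, "Disorder1"] == 0.5))
  expect_true(all(d[, "Disorder6"] == 0.5))
  # shuffled file order gives identical values
  ord <- read_disopred(tr$files$diso_A)
  shuf <- ord[rev(seq_len(nrow(ord))), ]
  f <- withr::local_tempfile(fileext = ".diso")
  hotspotr:::write_disopred_file(shuf$resnum, shuf$aa, shuf$score, f)
  d2 <- disorder_scores(st, list(A = read_disopred(f),
                                 B = tr$tracks$disopred$B))
  expect_equal(d2[, "Disorder1"], d[, "Disorder1"])
  # track shorter than the chain warns and leaves NA
  short <- ord[1:3, ]
  f2 <- withr::local_tempfile(fileext = ".diso")
  hotspotr:::write_disopred_file(short$resnum, short$aa, short$score, f2)
  expect_warning(d3 <- disorder_scores(st, list(A = read_disopred(f2))),
                 "not covered")
  expect_true(anyNA(d3[st$residues$chain == "A", "Disorder1"]))
})

test_that("pair potentials: zeros, monomer identity, hand-summed oracle", {
  iso <- toy_structure(list(list(chain = "A", resseq = 1,
                                 atoms = list(CA = c(0, 0, 0)))))
  pp0 <- pair_potential(iso)
  expect_equal(unlist(pp0[1, c("Ppm", "Ppc", "Delpp")]),
               c(Ppm = 0, Ppc = 0, Delpp = 0))

  st <- cached_dimer(6, 4, 4)
  pot <- default_pair_potential_matrix()
  pp <- pair_potential(st, pot, residue_cutoff = 6.5)
  # independent hand summation over the anchor-distance edge list
  anchor <- hotspotr:::.anchor_coords(st)
  aa <- st$residues$aa
  for (i in c(1, 3, 8)) {
    d <- sqrt(rowSums((anchor - matrix(anchor[i, ], nrow(anchor), 3,
                                       byrow = TRUE))^2))
    nb <- which(d <= 6.5 & seq_along(d) != i)
    expect_equal(pp$Ppc[i], sum(pot[aa[i], aa[nb]]))
  }
  # residues whose contact set is intra-chain only: Delpp = 0
  expect_true(any(abs(pp$Delpp) < 1e-12))
})

test_that("site descriptor block has the documented shape and determinism", {
  st <- cached_dimer(6, 4, 1)
  dir <- withr::local_tempdir()
  tr <- make_tracks(st, dir, seed = 5)
  s1 <- site_descriptors(st, pssm = tr$tracks$pssm, dssp = tr$tracks$dssp,
                         disopred = tr$tracks$disopred,
                         disembl = tr$tracks$disembl)
  expect_identical(colnames(s1), site_feature_names())
  expect_equal(length(site_feature_names()), 102)
  s2 <- site_descriptors(st, pssm = tr$tracks$pssm, dssp = tr$tracks$dssp,
                         disopred = tr$tracks$disopred,
                         disembl = tr$tracks$disembl)
  expect_identical(s1[, ], s2[, ])     # bit-identical extraction
  # missing externals are flagged, not silently zeroed
  expect_true(all(c("Cscore", "TOP") %in% attr(s1, "missing_features")))
  expect_true(all(is.na(s1[, "Cscore"])))
  # pluggable columns attach by residue id
  plug <- data.frame(res_id = st$residues$res_id,
                     Cscore = seq_len(nrow(st$residues)) / 10)
  s3 <- site_descriptors(st, pssm = tr$tracks$pssm, pluggable = plug)
  expect_equal(unname(s3[, "Cscore"]), plug$Cscore)
})
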