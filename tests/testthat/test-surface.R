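single_atom <- function(x = 0, y = 0, z = 0, chain = "A", resseq = 1) {
  list(chain = chain, resseq = resseq, resname = "ALA",
       atoms = list(CA = c(x, y, z)))
}

test_that("Shrake-Rupley matches closed forms for isolated spheres", {
  st <- toy_structure(list(single_atom()))
  s <- shrake_rupley_sasa(st, probe_radius = 1.4, n_sphere_points = 960)
  expect_equal(unname(s$residue_area), 4 * pi * 3.1^2, tolerance = 1e-12)

  # two atoms farther apart than 2*(r + probe): both isolated
  st2 <- toy_structure(list(single_atom(), single_atom(x = 10, resseq = 2)))
  s2 <- shrake_rupley_sasa(st2, 1.4, 960)
  expect_equal(unname(s2$atom_area), rep(4 * pi * 3.1^2, 2), tolerance = 1e-12)
  expect_error(shrake_rupley_sasa(st, probe_radius = -1), "probe_radius")
})

test_that("960-point lattice agrees with a 10000-point oracle within 2%", {
  set.seed(11)
  res <- lapply(1:5, function(i)
    single_atom(runif(1, 0, 4), runif(1, 0, 4), runif(1, 0, 4), resseq = i))
  st <- toy_structure(res)
  lo <- shrake_rupley_sasa(st, 1.4, 960)$atom_area
  hi <- shrake_rupley_sasa(st, 1.4, 10000)$atom_area
  expect_true(all(abs(lo - hi) / pmax(hi, 1) < 0.02))
})

test_that("surface profile: burial, weights and interface detection", {
  st <- cached_dimer(10, 4, 1)
  sp <- surface_profile(st)
  expect_equal(sum(sp$W), 1, tolerance = 1e-9)
  expect_true(all(sp$delta_asa >= -1e-6))
  expect_true(all(sp$W_FB[sp$delta_asa == 0] == 0))
  expect_true(any(sp$is_interface[sp$side == "a"]) &&
                any(sp$is_interface[sp$side == "b"]))
  # W_FB arithmetic: W(i) * dASA / ASA_monomer
  k <- which(sp$is_interface)[1]
  expect_equal(sp$W_FB[k], sp$W[k] * sp$delta_asa[k] / sp$asa_monomer[k])

  # symmetric two-single-residue complex: each side is the whole interface
  st2 <- toy_structure(list(single_atom(), single_atom(x = 4, chain = "B")),
                       partition = list(a = "A", b = "B"))
  sp2 <- surface_profile(st2)
  expect_equal(sp2$W, c(0.5, 0.5), tolerance = 0.02)  # lattice asymmetry
  expect_equal(sum(sp2$W), 1, tolerance = 1e-12)

  # far-apart chains: no interface
  st3 <- toy_structure(list(single_atom(), single_atom(x = 40, chain = "B")),
                       partition = list(a = "A", b = "B"))
  expect_error(surface_profile(st3), "no interface")
})

test_that("residue depth separates buried from exposed atoms", {
  st <- toy_structure(list(single_atom()))
  rd <- residue_depth(st)
  expect_equal(rd$RD, 1.4)   # exposed atom: probe offset only
  # two-shell cluster: center atom fully occluded by a dense spherical shell
  shell <- lapply(1:40, function(i) {
    z <- 1 - 2 * (i - 0.5) / 40
    r <- sqrt(1 - z^2)
    phi <- pi * (3 - sqrt(5)) * i
    v <- 3.0 * c(r * cos(phi), r * sin(phi), z)
    single_atom(v[1], v[2], v[3], resseq = i + 1)
  })
  st2 <- toy_structure(c(list(single_atom()), shell))
  rd2 <- residue_depth(st2)
  expect_gt(rd2$RD[1], min(rd2$RD[-1]))   # inner deeper than outer
})

test_that("half-sphere exposure counts and identities", {
  # isolated residue
  st <- toy_structure(list(list(chain = "A", resseq = 1, resname = "ALA",
                                atoms = list(N = c(-1.458, 0, 0), CA = c(0, 0, 0),
                                             C = c(0.8, 1.3, 0), CB = c(0, -1, 1.1)))))
  h <- half_sphere_exposure(st)
  expect_equal(unlist(h[1, c("HSEAU", "HSEAD", "CN")]), c(HSEAU = 0, HSEAD = 0, CN = 0))

  # one neighbour C-alpha along the CA->CB direction at 5 A
  dir <- c(0, -1, 1.1) / sqrt(sum(c(0, -1, 1.1)^2))
  st2 <- toy_structure(list(
    list(chain = "A", resseq = 1, resname = "ALA",
         atoms = list(N = c(-1.458, 0, 0), CA = c(0, 0, 0),
                      C = c(0.8, 1.3, 0), CB = c(0, -1, 1.1))),
    list(chain = "B", resseq = 50, resname = "ALA",
         atoms = list(CA = 5 * dir))))
  h2 <- half_sphere_exposure(st2, radius = 13)
  expect_equal(h2$HSEAU[1], 1)
  expect_equal(h2$HSEAD[1], 0)

  # helix dimer: HSEBU + HSEBD == CN, and CN equals a brute-force scan
  st3 <- cached_dimer(10, 4, 1)
  h3 <- half_sphere_exposure(st3, radius = 13)
  expect_true(all(h3$HSEBU + h3$HSEBD == h3$CN))
  a <- st3$atoms[st3$atoms$atom == "CA", ]
  for (i in seq_len(nrow(a))) {
    d <- sqrt((a$x - a$x[i])^2 + (a$y - a$y[i])^2 + (a$z - a$z[i])^2)
    expect_equal(h3$CN[i], sum(d <= 13) - 1)
  }
  # removing an atom never increases exposure counts
  keep <- st3$atoms$res_index != 5 | st3$atoms$atom != "CB"
  atoms2 <- st3$atoms[keep, ]
  atoms2$res_index <- NULL; atoms2$res_id <- NULL
  st4 <- hotspotr:::new_structure(atoms2, st3$partition)
  h4 <- half_sphere_exposure(st4, radius = 13)
  expect_true(all(h4$CN <= h3$CN))
})

test_that("contacts match exhaustive enumeration and monomer identities", {
  st <- cached_dimer(8, 4, 2)
  ct <- contacts(st, atom_cutoff = 4.5, residue_cutoff = 6.5)
  # brute-force atom-contact oracle
  a <- st$atoms[st$atoms$is_heavy, ]
  for (i in sample(seq_len(max(a$res_index)), 4)) {
    own <- a[a$res_index == i, ]
    oth <- a[a$res_index != i, ]
    cnt <- 0
    for (k in seq_len(nrow(own)))
      cnt <- cnt + sum(sqrt((oth$x - own$x[k])^2 + (oth$y - own$y[k])^2 +
                              (oth$z - own$z[k])^2) <= 4.5)
    expect_equal(ct$atom_contacts_complex[i], cnt)
  }
  # residues far from the interface: identical environment in both states
  same <- ct$atom_contacts_complex == ct$atom_contacts_monomer &
    ct$res_contacts_complex == ct$res_contacts_monomer
  expect_true(any(same))
  expect_true(all(abs(ct$Delncr[same]) < 1e-12))
  # isolated residue: all zero
  st0 <- toy_structure(list(single_atom()))
  ct0 <- contacts(st0)
  expect_equal(ct0$atom_contacts_complex, 0)
  expect_equal(ct0$Ncrc, 0)
})

test_that("hydrogen bonds: distance and angle criteria", {
  # two residues 20 A apart: no bonds
  far <- toy_structure(list(
    list(chain = "A", resseq = 1, resname = "ALA",
         atoms = list(N = c(0, 0, 0), CA = c(1.4, 0, 0), C = c(2, 1.2, 0),
                      O = c(1.6, 2.3, 0))),
    list(chain = "B", resseq = 1, resname = "ALA",
         atoms = list(N = c(20, 0, 0), CA = c(21.4, 0, 0), C = c(22, 1.2, 0),
                      O = c(21.6, 2.3, 0)))))
  expect_equal(sum(hydrogen_bonds(far)$hbond_count), 0)

  # backbone N...O at 2.9 A with a valid angle: exactly one bond
  near <- toy_structure(list(
    list(chain = "A", resseq = 1, resname = "ALA",
         atoms = list(N = c(0, 0, 0), CA = c(1.458, 0, 0))),
    list(chain = "B", resseq = 1, resname = "ALA",
         atoms = list(O = c(-2.9, 0, 0), C = c(-3.8, 1, 0)))))
  hb <- hydrogen_bonds(near)
  expect_equal(hb$hbond_count, c(1, 1))

  # same geometry but acceptor on the antecedent side: angle < 90, no bond
  bad <- toy_structure(list(
    list(chain = "A", resseq = 1, resname = "ALA",
         atoms = list(N = c(0, 0, 0), CA = c(1.458, 0, 0))),
    list(chain = "B", resseq = 1, resname = "ALA",
         atoms = list(O = c(2.9, 0.3, 0), C = c(3.8, 1.2, 0)))))
  expect_equal(sum(hydrogen_bonds(bad)$hbond_count), 0)
})
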