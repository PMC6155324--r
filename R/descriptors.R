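# Per-residue site descriptors: the 102-column site feature block.

#' Canonical site feature names
#'
#' The fixed, documented ordering of the per-residue site feature block. The
#' enumerated blocks total 102 columns (physicochemical 12, pKa 2, PSSM 20,
#' conservation C-score 1, ASA 6, contacts 6, pair potentials 3,
#' topographical 1, four-body 1, side-chain energy 6, local structural
#' entropy 3, nearby-interface 1, Voronoi contacts 2, secondary structure 3,
#' disorder 6, BLOSUM62 20, solvent exposure 7, PSSM entropy 1, hydrogen
#' bonds 1).
#'
#' @return Character vector of length 102.
#' @export
site_feature_names <- function() {
  c(colnames(.physchem),
    c("Pka1", "Pka2"),
    paste0("Pssm", aa_alphabet()),
    "Cscore",
    c("Asac", "Asam", "Dasa", "Rasac", "Rasam", "Wfb"),
    c("Nacc", "Nacm", "Delnac", "Ncrc", "Ncrm", "Delncr"),
    c("Ppm", "Ppc", "Delpp"),
    "TOP", "FourBody",
    paste0("SCE", 1:6),
    paste0("LSE", 1:3),
    "NearItf",
    c("VoroSame", "VoroCross"),
    paste0("SS", 1:3),
    paste0("Disorder", 1:6),
    paste0("Blosum", aa_alphabet()),
    c("HSEAU", "HSEAD", "HSEBU", "HSEBD", "CN", "RD", "RDa"),
    "Cons", "Hb")
}

# names of columns consumed from external files rather than computed
pluggable_feature_names <- function() {
  c("Cscore", "TOP", "FourBody", paste0("SCE", 1:6), paste0("LSE", 1:3),
    "NearItf")
}

#' Physicochemical property vector of an amino acid
#'
#' Twelve scales: hydrophobicity, hydrophilicity, polarity, polarizability,
#' helix propensity, mean accessible surface area, heavy-atom count, number
#' of electrostatic charges, number of potential hydrogen bonds, mass,
#' electron-ion interaction pseudopotential, and pseudo hydrophobicity.
#'
#' @param aa_type One-letter code.
#' @return Named numeric 12-vector; all-NA for nonstandard types.
#' @export
physicochemical <- function(aa_type) {
  if (is.na(aa_type) || !aa_type %in% rownames(.physchem))
    return(setNames(rep(NA_real_, ncol(.physchem)), colnames(.physchem)))
  .physchem[aa_type, ]
}

#' Conservation score (frequency entropy) at a PSSM position
#'
#' `Score_i = -sum_j p_ij log2 p_ij` over the 20 amino-acid frequencies;
#' lower means more conserved. Bounded in `[0, log2 20]`; `0 log 0` is 0.
#'
#' @param pssm An `hs_pssm`.
#' @param position 1-based position.
#' @return Entropy in bits.
#' @export
conservation_score <- function(pssm, position) {
  if (position < 1 || position > nrow(pssm$freq)) stop("position out of range")
  p <- pssm$freq[position, ]
  if (all(p == 0)) stop("all-zero frequency row at position ", position)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# torsion angle (degrees) of points p1-p2-p3-p4
.torsion <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- pracma_cross(b1, b2); n2 <- pracma_cross(b2, b3)
  m1 <- pracma_cross(n1, .unit(b2))
  x <- sum(n1 * n2); y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

#' Secondary-structure one-hot encoding
#'
#' With a DSSP track, letters G/H/I map to helix (1,0,0), B/E to sheet
#' (0,1,0) and everything else (T, S, blank) to coil (0,0,1). Without a
#' track, an internal phi/psi-based assignment is used: helix for phi in
#' (-120, -30) and psi in (-80, -5); sheet for phi < -45 with psi > 90 or
#' psi < -150; otherwise coil (chain termini are coil).
#'
#' @param structure An `hs_structure`.
#' @param dssp_track Optional data.frame from [read_dssp()].
#' @return Matrix n x 3 (columns SS1 helix, SS2 sheet, SS3 coil), one row per
#'   residue, rows summing to 1.
#' @export
secondary_structure <- function(structure, dssp_track = NULL) {
  res <- structure$residues
  n <- nrow(res)
  cls <- rep("C", n)
  if (!is.null(dssp_track)) {
    idx <- match(res$res_id, dssp_track$res_id)
    letter <- ifelse(is.na(idx), " ", dssp_track$ss[idx])
    cls[letter %in% c("G", "H", "I")] <- "H"
    cls[letter %in% c("B", "E")] <- "E"
  } else {
    a <- structure$atoms
    coord_of <- function(i, name) {
      hit <- which(a$res_index == i & a$atom == name)
      if (length(hit) != 1) return(NULL)
      c(a$x[hit], a$y[hit], a$z[hit])
    }
    for (i in seq_len(n)) {
      prev <- which(res$chain == res$chain[i] & res$resseq == res$resseq[i] - 1)
      nxt <- which(res$chain == res$chain[i] & res$resseq == res$resseq[i] + 1)
      if (length(prev) != 1 || length(nxt) != 1) next
      pts <- list(coord_of(prev, "C"), coord_of(i, "N"), coord_of(i, "CA"),
                  coord_of(i, "C"), coord_of(nxt, "N"))
      if (any(vapply(pts, is.null, logical(1)))) next
      phi <- .torsion(pts[[1]], pts[[2]], pts[[3]], pts[[4]])
      psi <- .torsion(pts[[2]], pts[[3]], pts[[4]], pts[[5]])
      if (phi > -120 && phi < -30 && psi > -80 && psi < -5) cls[i] <- "H"
      else if (phi < -45 && (psi > 90 || psi < -150)) cls[i] <- "E"
    }
  }
  m <- cbind(SS1 = as.numeric(cls == "H"), SS2 = as.numeric(cls == "E"),
             SS3 = as.numeric(cls == "C"))
  rownames(m) <- res$res_id
  m
}

#' Disorder score block from predictor tracks
#'
#' Six columns per residue: DISOPRED score, DISOPRED binary state, DisEMBL
#' coils / rem465 / hotloops scores, and a consensus mean of the four
#' continuous scores. Tracks are keyed by residue number; residues not
#' covered get NA with a warning.
#'
#' @param structure An `hs_structure`.
#' @param disopred Named list (by chain) of [read_disopred()] tables, or NULL.
#' @param disembl Named list (by chain) of [read_disembl()] tables, or NULL.
#' @return Matrix n x 6 (Disorder1..Disorder6).
#' @export
disorder_scores <- function(structure, disopred = NULL, disembl = NULL) {
  res <- structure$residues
  n <- nrow(res)
  m <- matrix(NA_real_, n, 6,
              dimnames = list(res$res_id, paste0("Disorder", 1:6)))
  for (i in seq_len(n)) {
    ch <- res$chain[i]
    if (!is.null(disopred[[ch]])) {
      k <- match(res$resseq[i], disopred[[ch]]$resnum)
      if (!is.na(k)) {
        m[i, 1] <- disopred[[ch]]$score[k]
        m[i, 2] <- disopred[[ch]]$state[k]
      }
    }
    if (!is.null(disembl[[ch]])) {
      k <- match(res$resseq[i], disembl[[ch]]$resnum)
      if (!is.na(k)) {
        m[i, 3] <- disembl[[ch]]$coils[k]
        m[i, 4] <- disembl[[ch]]$rem465[k]
        m[i, 5] <- disembl[[ch]]$hotloops[k]
      }
    }
    sc <- m[i, c(1, 3, 4, 5)]
    if (any(!is.na(sc))) m[i, 6] <- mean(sc, na.rm = TRUE)
  }
  if ((!is.null(disopred) || !is.null(disembl)) && anyNA(m[, 6]))
    warning(sum(is.na(m[, 6])), " residue(s) not covered by disorder tracks")
  m
}

#' Residue-contact pair potentials
#'
#' Sums a 20x20 statistical contact potential over a residue's contacting
#' residues (anchor atoms within `residue_cutoff`), in the residue's own
#' monomer (Ppm), in the complex (Ppc), and their difference
#' (Delpp = Ppc - Ppm). Contacts with nonstandard residues contribute 0.
#'
#' @param structure An `hs_structure`.
#' @param potential 20x20 matrix in [aa_alphabet()] order.
#' @param residue_cutoff Contact distance on anchor atoms, Angstrom.
#' @return data.frame: res_id, Ppm, Ppc, Delpp.
#' @export
pair_potential <- function(structure, potential = default_pair_potential_matrix(),
                           residue_cutoff = 6.5) {
  res <- structure$residues
  n <- nrow(res)
  sum_pot <- function(st) {
    anchor <- .anchor_coords(st)
    out <- setNames(rep(0, nrow(st$residues)), st$residues$res_id)
    if (nrow(anchor) < 2) return(out)
    d <- as.matrix(stats::dist(anchor))
    diag(d) <- Inf
    aa <- st$residues$aa
    for (i in seq_len(nrow(anchor))) {
      nb <- which(d[i, ] <= residue_cutoff)
      if (!length(nb) || is.na(aa[i])) next
      vals <- potential[aa[i], aa[nb]]
      out[i] <- sum(vals, na.rm = TRUE)
    }
    out
  }
  ppc <- sum_pot(structure)
  ppm <- ppc
  if (!is.null(structure$partition)) {
    ppm <- setNames(rep(NA_real_, n), res$res_id)
    for (s in c("a", "b")) {
      v <- sum_pot(extract_monomer(structure, s))
      ppm[names(v)] <- v
    }
  }
  data.frame(res_id = res$res_id, Ppm = unname(ppm[res$res_id]),
             Ppc = unname(ppc[res$res_id]),
             Delpp = unname(ppc[res$res_id] - ppm[res$res_id]),
             stringsAsFactors = FALSE)
}

#' Assemble the full site descriptor block for every residue
#'
#' Computes/collects all 102 site features (see [site_feature_names()]).
#' External tracks are optional; pluggable energy columns (C-score, TOP,
#' four-body, SCE, LSE, nearby-interface) come from `pluggable`, a
#' data.frame keyed by `res_id` (see [read_residue_tsv()]); missing external
#' values are NA and recorded in the `missing_features` attribute, never
#' silently zero.
#'
#' @param structure An `hs_structure` with a partition.
#' @param surface Optional precomputed [surface_profile()] result.
#' @param pssm Named list (by chain) of `hs_pssm` objects; positions are
#'   matched to residues by rank of residue number within the chain.
#' @param dssp Optional [read_dssp()] table.
#' @param disopred,disembl Optional named lists of disorder tracks.
#' @param pluggable Optional data.frame of pre-computed columns.
#' @param config Named list of geometry parameters: probe_radius,
#'   n_sphere_points, hse_radius, atom_contact_cutoff, residue_contact_cutoff,
#'   interface_dasa_min, pair_potential (matrix), contact_reference.
#' @return Numeric matrix n x 102, rownames = res_id, with attribute
#'   `missing_features` (character vector of all-NA external columns).
#' @export
site_descriptors <- function(structure, surface = NULL, pssm = NULL,
                             dssp = NULL, disopred = NULL, disembl = NULL,
                             pluggable = NULL, config = list()) {
  cfg <- modifyList(list(probe_radius = 1.4, n_sphere_points = 960,
                         hse_radius = 13, atom_contact_cutoff = 4.5,
                         residue_contact_cutoff = 6.5,
                         interface_dasa_min = 0.1,
                         pair_potential = default_pair_potential_matrix(),
                         contact_reference = default_contact_reference()),
                    config)
  res <- structure$residues
  n <- nrow(res)
  feats <- matrix(NA_real_, n, length(site_feature_names()),
                  dimnames = list(res$res_id, site_feature_names()))

  # sequence-derived
  pc <- t(vapply(res$aa, physicochemical, numeric(ncol(.physchem))))
  feats[, colnames(.physchem)] <- pc
  known <- !is.na(res$aa) & res$aa %in% rownames(.pka)
  feats[known, c("Pka1", "Pka2")] <- .pka[res$aa[known], ]
  bl <- matrix(NA_real_, n, 20)
  bl[known, ] <- blosum62_matrix()[res$aa[known], ]
  feats[, paste0("Blosum", aa_alphabet())] <- bl

  if (!is.null(pssm)) {
    for (ch in unique(res$chain)) {
      track <- pssm[[ch]]
      if (is.null(track)) next
      rows <- which(res$chain == ch)
      pos <- rank(res$resseq[rows], ties.method = "first")
      ok <- pos <= nrow(track$scores)
      feats[rows[ok], paste0("Pssm", aa_alphabet())] <-
        track$scores[pos[ok], , drop = FALSE]
      feats[rows[ok], "Cons"] <- vapply(pos[ok], function(p)
        conservation_score(track, p), numeric(1))
    }
  }

  # structure-derived
  if (is.null(surface))
    surface <- surface_profile(structure, cfg$probe_radius,
                               cfg$n_sphere_points, cfg$interface_dasa_min)
  feats[, "Asac"] <- surface$asa_complex
  feats[, "Asam"] <- surface$asa_monomer
  feats[, "Dasa"] <- surface$delta_asa
  feats[, "Rasac"] <- surface$rel_asa_complex
  feats[, "Rasam"] <- surface$rel_asa_monomer
  feats[, "Wfb"] <- surface$W_FB

  ct <- contacts(structure, cfg$atom_contact_cutoff,
                 cfg$residue_contact_cutoff, cfg$contact_reference)
  feats[, "Nacc"] <- ct$Nacc
  feats[, "Nacm"] <- ct$Nacm
  feats[, "Delnac"] <- ct$Nacc - ct$Nacm
  feats[, "Ncrc"] <- ct$Ncrc
  feats[, "Ncrm"] <- ct$Ncrm
  feats[, "Delncr"] <- ct$Delncr

  pp <- pair_potential(structure, cfg$pair_potential,
                       cfg$residue_contact_cutoff)
  feats[, c("Ppm", "Ppc", "Delpp")] <- as.matrix(pp[, c("Ppm", "Ppc", "Delpp")])

  vg <- voronoi_neighbors(structure)
  vc <- voronoi_contacts(structure, vg)
  feats[, "VoroSame"] <- vc$voro_same_side
  feats[, "VoroCross"] <- vc$voro_cross_side

  feats[, c("SS1", "SS2", "SS3")] <- secondary_structure(structure, dssp)
  feats[, paste0("Disorder", 1:6)] <-
    suppressWarnings(disorder_scores(structure, disopred, disembl))

  hse <- half_sphere_exposure(structure, cfg$hse_radius)
  feats[, c("HSEAU", "HSEAD", "HSEBU", "HSEBD", "CN")] <-
    as.matrix(hse[, c("HSEAU", "HSEAD", "HSEBU", "HSEBD", "CN")])
  rd <- residue_depth(structure, cfg$probe_radius, cfg$n_sphere_points)
  feats[, "RD"] <- rd$RD
  feats[, "RDa"] <- rd$RDa

  hb <- hydrogen_bonds(structure)
  feats[, "Hb"] <- hb$hbond_count

  if (!is.null(pluggable)) {
    idx <- match(res$res_id, pluggable$res_id)
    for (col in intersect(pluggable_feature_names(), names(pluggable)))
      feats[, col] <- pluggable[[col]][idx]
  }
  missing_cols <- colnames(feats)[colSums(!is.na(feats)) == 0]
  attr(feats, "missing_features") <- missing_cols
  attr(feats, "voronoi_graph") <- vg
  feats
}
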