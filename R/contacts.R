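# Atom/residue contact counts, normalization, and geometric hydrogen bonds.

# residue "anchor" coordinates for residue-level contacts: C-beta, falling
# back to C-alpha (glycine / missing side chain)
.anchor_coords <- function(structure) {
  res <- structure$residues
  a <- structure$atoms
  m <- matrix(NA_real_, nrow(res), 3)
  for (nm in c("CA", "CB")) {   # CB overwrites CA when present
    hit <- a$atom == nm & a$is_heavy
    m[a$res_index[hit], ] <- cbind(a$x[hit], a$y[hit], a$z[hit])
  }
  m
}

.residue_contact_counts <- function(anchor, cutoff) {
  n <- nrow(anchor)
  cnt <- integer(n)
  if (n < 2) return(cnt)
  d <- as.matrix(stats::dist(anchor))
  diag(d) <- Inf
  rowSums(d <= cutoff, na.rm = TRUE)
}

#' Atom and residue contact profile
#'
#' Counts, for every residue, inter-residue heavy-atom contact pairs (any
#' heavy atom within `atom_cutoff`) and residue contacts (C-beta/C-alpha
#' anchor within `residue_cutoff`), both in the complex and in the residue's
#' own monomer. Counts are normalized by a per-amino-acid reference mean
#' (`reference`), and Delncr = Ncrc - Ncrm is the binding-induced change in
#' normalized residue contacts.
#'
#' @param structure An `hs_structure` with a partition (monomer columns are
#'   computed per side); a monomer is also accepted (complex == monomer).
#' @param atom_cutoff Heavy-atom contact distance, Angstrom (default 4.5).
#' @param residue_cutoff Anchor-atom contact distance, Angstrom (default 6.5).
#' @param reference Named 20-vector of reference mean residue-contact counts
#'   used for normalization; defaults to a neutral constant table.
#' @return data.frame: res_id, atom_contacts_complex, atom_contacts_monomer,
#'   res_contacts_complex, res_contacts_monomer, Nacc, Nacm, Ncrc, Ncrm,
#'   Delncr.
#' @export
contacts <- function(structure, atom_cutoff = 4.5, residue_cutoff = 6.5,
                     reference = default_contact_reference()) {
  stopifnot(atom_cutoff > 0, residue_cutoff > 0)
  res <- structure$residues
  nres <- nrow(res)
  hv <- heavy_view(structure)
  st <- residue_dist_stats_cpp(hv$coords, hv$res_index, nres, atom_cutoff)
  ac_complex <- as.numeric(st$atom_contacts)
  rc_complex <- .residue_contact_counts(.anchor_coords(structure), residue_cutoff)

  ac_mono <- ac_complex
  rc_mono <- rc_complex
  if (!is.null(structure$partition)) {
    ac_mono <- rep(NA_real_, nres)
    rc_mono <- rep(NA_real_, nres)
    for (s in c("a", "b")) {
      mono <- extract_monomer(structure, s)
      mhv <- heavy_view(mono)
      mst <- residue_dist_stats_cpp(mhv$coords, mhv$res_index,
                                    nrow(mono$residues), atom_cutoff)
      mrc <- .residue_contact_counts(.anchor_coords(mono), residue_cutoff)
      idx <- match(mono$residues$res_id, res$res_id)
      ac_mono[idx] <- as.numeric(mst$atom_contacts)
      rc_mono[idx] <- mrc
    }
  }

  ref <- unname(reference[res$aa])
  ref[is.na(ref) | ref == 0] <- mean(reference)
  data.frame(res_id = res$res_id,
             atom_contacts_complex = ac_complex,
             atom_contacts_monomer = ac_mono,
             res_contacts_complex = rc_complex,
             res_contacts_monomer = rc_mono,
             Nacc = ac_complex / ref, Nacm = ac_mono / ref,
             Ncrc = rc_complex / ref, Ncrm = rc_mono / ref,
             Delncr = (rc_complex - rc_mono) / ref,
             stringsAsFactors = FALSE)
}

#' Geometric hydrogen bond counts
#'
#' Counts donor-acceptor pairs with D-A distance <= `dist_max` and, when the
#' donor's antecedent atom is present, antecedent-D-A angle >= `angle_min`
#' degrees. Donor/acceptor typing covers backbone N/O and standard polar side
#' chains. Each bond increments the count of both participating residues;
#' intra-residue pairs are ignored. An HBPLUS `.hb2` file can be supplied
#' instead via [read_hb2()].
#'
#' @param structure An `hs_structure`.
#' @param dist_max Donor-acceptor distance cutoff, Angstrom.
#' @param angle_min Minimum antecedent-donor-acceptor angle, degrees.
#' @return data.frame: res_id, hbond_count.
#' @export
hydrogen_bonds <- function(structure, dist_max = 3.5, angle_min = 90) {
  a <- structure$atoms[structure$atoms$is_heavy, , drop = FALSE]
  res <- structure$residues
  don <- list()
  acc <- list()
  for (i in seq_len(nrow(a))) {
    aa1 <- a$aa[i]
    nm <- a$atom[i]
    d_tab <- c(.hb_donors[["*"]],
               if (!is.na(aa1) && !is.null(.hb_donors[[aa1]])) .hb_donors[[aa1]])
    a_tab <- c(.hb_acceptors[["*"]],
               if (!is.na(aa1) && !is.null(.hb_acceptors[[aa1]])) .hb_acceptors[[aa1]])
    if (nm %in% names(d_tab))
      don[[length(don) + 1]] <- list(row = i, ante = unname(d_tab[[nm]]))
    if (nm %in% a_tab)
      acc[[length(acc) + 1]] <- i
  }
  cnt <- setNames(rep(0L, nrow(res)), res$res_id)
  if (!length(don) || !length(acc)) {
    return(data.frame(res_id = res$res_id, hbond_count = as.integer(cnt),
                      stringsAsFactors = FALSE))
  }
  coords <- cbind(a$x, a$y, a$z)
  acc_idx <- unlist(acc)
  cos_min <- cos(angle_min * pi / 180)
  for (d in don) {
    i <- d$row
    ante_row <- which(a$res_index == a$res_index[i] & a$atom == d$ante)
    dv <- coords[acc_idx, , drop = FALSE] -
      matrix(coords[i, ], length(acc_idx), 3, byrow = TRUE)
    dist <- sqrt(rowSums(dv^2))
    ok <- dist <= dist_max & a$res_index[acc_idx] != a$res_index[i]
    if (length(ante_row) == 1) {
      u_ante <- .unit(coords[ante_row, ] - coords[i, ])
      cosang <- (dv / pmax(dist, 1e-9)) %*% u_ante
      # angle(antecedent-D-A) >= angle_min  <=>  cos(angle) <= cos(angle_min)
      ok <- ok & (cosang <= cos_min + 1e-12)
    }
    for (j in acc_idx[ok]) {
      cnt[a$res_index[i]] <- cnt[a$res_index[i]] + 1L
      cnt[a$res_index[j]] <- cnt[a$res_index[j]] + 1L
    }
  }
  data.frame(res_id = res$res_id, hbond_count = as.integer(cnt),
             stringsAsFactors = FALSE)
}
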