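# Solvent-accessible surface area and the interface burial profile.

#' Shrake-Rupley solvent accessible surface area
#'
#' Numerical SASA on the heavy atoms of a structure using a deterministic
#' golden-section spiral sphere lattice, so results are bit-reproducible.
#'
#' @param structure An `hs_structure`.
#' @param probe_radius Solvent probe radius in Angstrom (water: 1.4).
#' @param n_sphere_points Number of lattice points per atom (>= 50).
#' @return List with `atom_area` (per heavy atom, Angstrom^2) and
#'   `residue_area` (named by residue id).
#' @export
shrake_rupley_sasa <- function(structure, probe_radius = 1.4,
                               n_sphere_points = 960) {
  stopifnot(probe_radius > 0, n_sphere_points >= 50)
  hv <- heavy_view(structure)
  if (nrow(hv$coords) == 0) stop("empty structure")
  area <- sasa_cpp(hv$coords, hv$radius, probe_radius, as.integer(n_sphere_points))
  res_area <- tapply(area, hv$res_index, sum)
  out <- setNames(as.numeric(res_area),
                  structure$residues$res_id[as.integer(names(res_area))])
  list(atom_area = area, residue_area = out)
}

#' Interface burial profile of a two-sided complex
#'
#' Computes per-residue SASA in the complex and in the residue's own unbound
#' monomer, the burial dASA = ASA(monomer) - ASA(complex), interface
#' membership, the fractional interface weight
#' W(i) = dASA_i / sum_j dASA_j (over interface residues, summing to 1), and
#' the weighted fraction buried W_FB(i) = W(i) * dASA_i / ASA_monomer_i.
#' Non-interface residues carry W = W_FB = 0.
#'
#' @inheritParams shrake_rupley_sasa
#' @param interface_dasa_min Burial (Angstrom^2) above which a residue counts
#'   as interface; small positive floor against numerical noise.
#' @return data.frame with one row per residue: res_id, side, asa_complex,
#'   asa_monomer, delta_asa, rel_asa_complex, rel_asa_monomer, is_interface,
#'   W, W_FB.
#' @export
surface_profile <- function(structure, probe_radius = 1.4,
                            n_sphere_points = 960,
                            interface_dasa_min = 0.1) {
  if (is.null(structure$partition)) stop("structure has no side partition")
  cx <- shrake_rupley_sasa(structure, probe_radius, n_sphere_points)
  res <- structure$residues
  asa_complex <- unname(cx$residue_area[res$res_id])

  asa_monomer <- rep(NA_real_, nrow(res))
  side <- rep(NA_character_, nrow(res))
  for (s in c("a", "b")) {
    mono <- extract_monomer(structure, s)
    ms <- shrake_rupley_sasa(mono, probe_radius, n_sphere_points)
    hit <- res$res_id %in% names(ms$residue_area)
    asa_monomer[hit] <- ms$residue_area[res$res_id[hit]]
    side[res$chain %in% structure$partition[[s]]] <- s
  }

  delta_asa <- asa_monomer - asa_complex
  delta_asa[delta_asa < 0 & delta_asa > -1e-6] <- 0
  is_interface <- delta_asa > interface_dasa_min
  if (!any(is_interface)) stop("no interface: no residue buries more than ",
                               interface_dasa_min, " A^2 on binding")
  W <- rep(0, nrow(res))
  W[is_interface] <- delta_asa[is_interface] / sum(delta_asa[is_interface])
  W_FB <- rep(0, nrow(res))
  W_FB[is_interface] <- W[is_interface] * delta_asa[is_interface] /
    asa_monomer[is_interface]

  mean_asa <- .physchem[, "meanASA"]
  ref <- unname(mean_asa[res$aa])
  data.frame(res_id = res$res_id, side = side,
             asa_complex = asa_complex, asa_monomer = asa_monomer,
             delta_asa = delta_asa,
             rel_asa_complex = asa_complex / ref,
             rel_asa_monomer = asa_monomer / ref,
             is_interface = is_interface, W = W, W_FB = W_FB,
             stringsAsFactors = FALSE)
}

#' Residue depth from the solvent-exposed surface
#'
#' Depth is approximated as the distance to the nearest solvent-exposed atom
#' (per-atom SASA > 0) plus the probe radius; RD averages over a residue's
#' heavy atoms and RDa uses the C-alpha atom only.
#'
#' @inheritParams shrake_rupley_sasa
#' @return data.frame: res_id, RD, RDa (NA when the residue lacks C-alpha).
#' @export
residue_depth <- function(structure, probe_radius = 1.4,
                          n_sphere_points = 960) {
  hv <- heavy_view(structure)
  area <- sasa_cpp(hv$coords, hv$radius, probe_radius,
                   as.integer(n_sphere_points))
  exposed <- area > 0
  if (!any(exposed)) stop("no solvent-exposed atom found")
  ex <- hv$coords[exposed, , drop = FALSE]
  depth <- vapply(seq_len(nrow(hv$coords)), function(i) {
    d2 <- (ex[, 1] - hv$coords[i, 1])^2 + (ex[, 2] - hv$coords[i, 2])^2 +
      (ex[, 3] - hv$coords[i, 3])^2
    sqrt(min(d2)) + probe_radius
  }, numeric(1))
  rd <- tapply(depth, hv$res_index, mean)
  res <- structure$residues
  is_ca <- hv$atoms$atom == "CA"
  rda <- rep(NA_real_, nrow(res))
  rda[hv$res_index[is_ca]] <- depth[is_ca]
  data.frame(res_id = res$res_id,
             RD = as.numeric(rd[as.character(seq_len(nrow(res)))]),
             RDa = rda, stringsAsFactors = FALSE)
}
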