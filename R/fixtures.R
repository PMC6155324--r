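# Synthetic desk-scale fixtures: toy helix dimers with a real interface,
# PSSM/disorder/DSSP tracks in the readers' dialects, and labeled feature
# matrices with planted class structure. Everything is generated in code;
# the test suite requires zero downloads.

# natural-extension-reference-frame atom placement: position D with
# |CD| = bond, angle(B,C,D) = angle_deg, torsion(A,B,C,D) = torsion_deg
nerf_place <- function(a, b, c, bond, angle_deg, torsion_deg) {
  th <- angle_deg * pi / 180
  chi <- torsion_deg * pi / 180
  bc <- .unit(c - b)
  n <- .unit(pracma_cross(b - a, bc))
  m <- pracma_cross(n, bc)
  d_local <- bond * c(-cos(th), sin(th) * cos(chi), -sin(th) * sin(chi))
  c + d_local[1] * bc + d_local[2] * m + d_local[3] * n
}

# ideal poly-alanine helix backbone (N, CA, C, O, CB) from internal
# coordinates: phi = -57, psi = -47, omega = 180 by default
build_helix_chain <- function(n_res, chain_id, phi = -57, psi = -47) {
  atoms <- list()
  prev <- NULL
  for (i in seq_len(n_res)) {
    if (i == 1) {
      n_at <- c(0, 0, 0)
      ca <- c(1.458, 0, 0)
      th <- 111.2 * pi / 180
      cc <- ca + 1.525 * c(cos(pi - th), sin(pi - th), 0)
    } else {
      n_at <- nerf_place(prev$n, prev$ca, prev$c, 1.329, 116.2, psi)
      ca <- nerf_place(prev$ca, prev$c, n_at, 1.458, 121.7, 180)
      cc <- nerf_place(prev$c, n_at, ca, 1.525, 111.2, phi)
    }
    o <- nerf_place(n_at, ca, cc, 1.231, 120.5, psi + 180)
    cb <- pseudo_cb(n_at, ca, cc)
    for (nm in c("N", "CA", "C", "O", "CB")) {
      xyz <- switch(nm, N = n_at, CA = ca, C = cc, O = o, CB = cb)
      atoms[[length(atoms) + 1]] <- data.frame(
        chain = chain_id, resseq = i, icode = "", resname = "ALA", aa = "A",
        atom = nm, element = substr(nm, 1, 1), x = xyz[1], y = xyz[2],
        z = xyz[3], occupancy = 1, stringsAsFactors = FALSE)
    }
    prev <- list(n = n_at, ca = ca, c = cc)
  }
  do.call(rbind, atoms)
}

#' Generate a synthetic two-chain helix dimer
#'
#' Two ideal poly-alanine alpha-helices (standard backbone geometry built
#' from internal coordinates, phi = -57, psi = -47) packed side by side so
#' that the minimum inter-chain heavy-atom distance equals `gap`. A gap of
#' <= 5 Angstrom guarantees a nonempty burial (delta-ASA) interface. A small
#' seeded coordinate jitter (0.02 Angstrom) makes geometry generic (avoids
#' cospherical degeneracies) while staying byte-reproducible per seed.
#'
#' @param n_res Residues per chain (>= 4).
#' @param gap Target minimum inter-chain heavy-atom distance, Angstrom (> 0).
#' @param seed Integer seed.
#' @param path Optional path to also write the structure as a PDB file.
#' @return An `hs_structure` with partition A | B.
#' @export
make_dimer <- function(n_res = 12, gap = 4, seed = 1, path = NULL) {
  stopifnot(n_res >= 4)
  if (gap <= 0) stop("gap must be positive")
  a <- build_helix_chain(n_res, "A")
  b <- build_helix_chain(n_res, "B")
  # translate B perpendicular to the helix axis until min distance == gap
  ca_rows <- a$atom == "CA"
  axis <- .unit(unlist(a[ca_rows, c("x", "y", "z")][sum(ca_rows), ]) -
                  unlist(a[ca_rows, c("x", "y", "z")][1, ]))
  u <- .unit(pracma_cross(axis, c(0, 0, 1)))
  if (anyNA(u)) u <- .unit(pracma_cross(axis, c(0, 1, 0)))
  pa <- as.matrix(a[, c("x", "y", "z")])
  pb0 <- as.matrix(b[, c("x", "y", "z")])
  mind <- function(t) {
    pb <- sweep(pb0, 2, t * u, "+")
    min(sqrt(pmax(outer(rowSums(pa^2), rowSums(pb^2), "+") -
                    2 * pa %*% t(pb), 0)))
  }
  t_star <- stats::uniroot(function(t) mind(t) - gap, c(0.5, 200),
                           tol = 1e-8)$root
  b[, c("x", "y", "z")] <- sweep(pb0, 2, t_star * u, "+")
  atoms <- rbind(a, b)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  jit <- matrix(runif(3 * nrow(atoms), -0.01, 0.01), ncol = 3)
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  atoms[, c("x", "y", "z")] <- round(atoms[, c("x", "y", "z")] + jit, 3)
  atoms$is_heavy <- TRUE
  atoms$radius <- vdw_radius(atoms$element)
  st <- new_structure(atoms, partition = list(a = "A", b = "B"))
  if (!is.null(path)) write_pdb(st, path)
  st
}

#' Generate a labeled feature matrix with planted class structure
#'
#' Standard-normal noise features with `n_informative` columns whose class
#' means differ by `effect_size` standard deviations (emulating the shifted
#' hot-spot feature distributions the selection and classifier stages
#' assume). Optional exact duplicate columns of the first informative
#' features exercise mRMR redundancy handling.
#'
#' @param n_samples Number of rows (>= 40).
#' @param n_features Total feature count.
#' @param n_informative Number of class-shifted columns.
#' @param effect_size Class mean shift in units of sigma.
#' @param class_balance Fraction of positive (hot spot) samples.
#' @param n_duplicate Number of duplicated informative columns appended as
#'   copies (named `Dup...`).
#' @param seed Integer seed.
#' @return An `hs_feature_table` with columns complex_id, res_id, ddG (NA),
#'   label, and features `F0001...`; attribute `informative` names the
#'   planted columns.
#' @export
make_feature_matrix <- function(n_samples = 300, n_features = 600,
                                n_informative = 4, effect_size = 1.5,
                                class_balance = 0.45, n_duplicate = 0,
                                seed = 1) {
  stopifnot(n_samples >= 40, n_informative <= n_features)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  n_pos <- round(n_samples * class_balance)
  y <- sample(c(rep(1L, n_pos), rep(0L, n_samples - n_pos)))
  X <- matrix(rnorm(n_samples * n_features), n_samples, n_features)
  info <- seq_len(n_informative)
  for (j in info) X[, j] <- X[, j] + y * effect_size
  colnames(X) <- sprintf("F%04d", seq_len(n_features))
  if (n_duplicate > 0) {
    dup <- X[, seq_len(min(n_duplicate, n_informative)), drop = FALSE]
    colnames(dup) <- paste0("Dup", seq_len(ncol(dup)))
    X <- cbind(X, dup)
  }
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  out <- cbind(data.frame(complex_id = "synthetic",
                          res_id = sprintf("S:%d", seq_len(n_samples)),
                          ddG = NA_real_, label = y,
                          stringsAsFactors = FALSE),
               as.data.frame(X, optional = TRUE))
  attr(out, "informative") <- sprintf("F%04d", info)
  class(out) <- c("hs_feature_table", class(out))
  out
}

# ---- track writers (dialects matched to the readers) ----

write_pssm_file <- function(freq, seqv, path) {
  psi_order <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  freq <- freq[, psi_order, drop = FALSE]
  scores <- round(2 * log2(pmax(freq, 1e-4) / 0.05))
  hdr <- paste0("            ", paste(rep(sprintf("%3s", psi_order), 2),
                                      collapse = " "))
  lines <- c("", "Last position-specific scoring matrix computed", hdr)
  for (i in seq_len(nrow(freq))) {
    lines <- c(lines, paste0(
      sprintf("%5d %s ", i, seqv[i]),
      paste(sprintf("%3d", scores[i, ]), collapse = " "), "  ",
      paste(sprintf("%3d", round(freq[i, ] * 100)), collapse = " "),
      sprintf("  %5.2f %9.2f", 0.5, 1.0)))
  }
  writeLines(lines, path)
  invisible(path)
}

write_disopred_file <- function(resnum, aa, score, path, threshold = 0.5) {
  writeLines(c("#         ----- DISOPRED-style disorder track -----", "",
               sprintf("%5d %s %s %5.2f", resnum, aa,
                       ifelse(score >= threshold, "*", "."), score)), path)
  invisible(path)
}

write_disembl_file <- function(resnum, aa, coils, rem465, hotloops, path) {
  df <- data.frame(resnum = resnum, aa = aa, coils = coils, rem465 = rem465,
                   hotloops = hotloops)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_dssp_file <- function(chain, resseq, aa, ss, acc, path) {
  hdr <- c("==== Secondary Structure Definition (synthetic DSSP-style) ====",
           "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC")
  body <- sprintf("%5d%5d %s %s  %s%17s%4d", seq_along(resseq), resseq,
                  chain, aa, ss, "", round(acc))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Generate synthetic per-chain tracks for a structure
#'
#' Writes syntactically valid PSSM, DISOPRED-style, DisEMBL-style and
#' DSSP-style files for every chain of `structure`, with controllable values,
#' and returns both the file paths and the parsed track list ready for
#' [site_descriptors()].
#'
#' @param structure An `hs_structure`.
#' @param dir Output directory (created if needed).
#' @param seed Integer seed for the random PSSM/disorder values.
#' @param pssm_mode `"random"` (Dirichlet-like frequencies) or `"uniform"`
#'   (all 1/20, maximum entropy at every position).
#' @param disorder_value Optional constant for every disorder score.
#' @param ss_letter Optional constant DSSP letter (e.g. `"H"`); default
#'   assigns helix everywhere, matching the helix fixture geometry.
#' @return List: `files` (paths by type/chain) and `tracks` (pssm, dssp,
#'   disopred, disembl) for [build_feature_table()].
#' @export
make_tracks <- function(structure, dir, seed = 1, pssm_mode = "random",
                        disorder_value = NULL, ss_letter = "H") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  res <- structure$residues
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  files <- list()
  pssm <- list(); disopred <- list(); disembl <- list()
  dssp_rows <- list()
  for (ch in unique(res$chain)) {
    rs <- res[res$chain == ch, , drop = FALSE]
    n <- nrow(rs)
    aa <- ifelse(is.na(rs$aa), "X", rs$aa)
    if (identical(pssm_mode, "uniform")) {
      freq <- matrix(1 / 20, n, 20)
    } else {
      g <- matrix(rexp(n * 20), n, 20)
      # sharpen toward the native residue
      g[cbind(seq_len(n), match(aa, aa_alphabet()))] <-
        g[cbind(seq_len(n), match(aa, aa_alphabet()))] + 5
      freq <- g / rowSums(g)
    }
    colnames(freq) <- aa_alphabet()
    fp <- file.path(dir, paste0("chain_", ch, ".pssm"))
    write_pssm_file(freq, aa, fp)
    pssm[[ch]] <- read_pssm(fp)
    files[[paste0("pssm_", ch)]] <- fp

    sc <- if (!is.null(disorder_value)) rep(disorder_value, n) else
      round(runif(n), 2)
    fd <- file.path(dir, paste0("chain_", ch, ".diso"))
    write_disopred_file(rs$resseq, aa, sc, fd)
    disopred[[ch]] <- read_disopred(fd)
    files[[paste0("diso_", ch)]] <- fd

    de <- if (!is.null(disorder_value))
      matrix(disorder_value, n, 3) else matrix(round(runif(3 * n), 2), n, 3)
    fe <- file.path(dir, paste0("chain_", ch, ".disembl.tsv"))
    write_disembl_file(rs$resseq, aa, de[, 1], de[, 2], de[, 3], fe)
    disembl[[ch]] <- read_disembl(fe)
    files[[paste0("disembl_", ch)]] <- fe

    dssp_rows[[ch]] <- data.frame(chain = ch, resseq = rs$resseq, aa = aa,
                                  ss = ss_letter, stringsAsFactors = FALSE)
  }
  dd <- do.call(rbind, dssp_rows)
  fs <- file.path(dir, "structure.dssp")
  write_dssp_file(dd$chain, dd$resseq, dd$aa, dd$ss, rep(50, nrow(dd)), fs)
  files$dssp <- fs
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  list(files = files,
       tracks = list(pssm = pssm, dssp = read_dssp(fs), disopred = disopred,
                     disembl = disembl))
}
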