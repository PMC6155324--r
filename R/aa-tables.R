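# Amino-acid constant tables. Canonical one-letter ordering used for every
# 20-vector feature block (alphabetical by one-letter code).

#' Canonical amino-acid ordering
#'
#' One-letter codes of the 20 standard amino acids in the fixed alphabetical
#' order used for all per-amino-acid feature blocks (PSSM, BLOSUM rows, ...).
#' @return Character vector of length 20.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# three-letter -> one-letter, plus common nonstandard parents (MSE etc.)
.aa3to1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q", GLU = "E",
  GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K", MET = "M", PHE = "F",
  PRO = "P", SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
  # nonstandard residues with a standard parent
  MSE = "M", SEP = "S", TPO = "T", PTR = "Y", CSO = "C", HYP = "P",
  CME = "C", KCX = "K", MLY = "K", LLP = "K", PCA = "E"
)

aa_three_to_one <- function(resname) {
  out <- .aa3to1[toupper(resname)]
  unname(out)
}

# van der Waals radii (Angstrom) keyed by element; configurable via options
.vdw_default <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
                  SE = 1.90, H = 1.20)

vdw_radius <- function(element, table = NULL) {
  tab <- if (is.null(table)) .vdw_default else table
  r <- tab[toupper(element)]
  r[is.na(r)] <- 1.70
  unname(r)
}

# 12 physicochemical scales (rows = aa in aa_alphabet() order):
# hydrophobicity (Kyte-Doolittle), hydrophilicity (Hopp-Woods), polarity
# (Grantham), polarizability (Charton), helix propensity (Chou-Fasman),
# mean accessible surface area, heavy-atom count, number of electrostatic
# charges, number of potential H-bonds, residue mass, electron-ion
# interaction pseudopotential, pseudo hydrophobicity (KD rescaled to [0,1]).
.physchem <- local({
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  kd <- c(1.8, 2.5, -3.5, -3.5, 2.8, -0.4, -3.2, 4.5, -3.9, 3.8,
          1.9, -3.5, -1.6, -3.5, -4.5, -0.8, -0.7, 4.2, -0.9, -1.3)
  hw <- c(-0.5, -1.0, 3.0, 3.0, -2.5, 0.0, -0.5, -1.8, 3.0, -1.8,
          -1.3, 0.2, 0.0, 0.2, 3.0, 0.3, -0.4, -1.5, -3.4, -2.3)
  pol <- c(8.1, 5.5, 13.0, 12.3, 5.2, 9.0, 10.4, 5.2, 11.3, 4.9,
           5.7, 11.6, 8.0, 10.5, 10.5, 9.2, 8.6, 5.9, 5.4, 6.2)
  plz <- c(0.046, 0.128, 0.105, 0.151, 0.290, 0.000, 0.230, 0.186, 0.219,
           0.186, 0.221, 0.134, 0.131, 0.180, 0.291, 0.062, 0.108, 0.140,
           0.409, 0.298)
  helx <- c(1.42, 0.70, 1.01, 1.51, 1.13, 0.57, 1.00, 1.08, 1.16, 1.21,
            1.45, 0.67, 0.57, 1.11, 0.98, 0.77, 0.83, 1.06, 1.08, 0.69)
  masa <- c(118.1, 146.1, 158.7, 186.2, 222.8, 88.1, 202.5, 181.0, 225.8,
            193.1, 203.4, 165.5, 146.8, 193.2, 256.0, 129.8, 152.5, 164.5,
            266.3, 236.8)
  natm <- c(5, 6, 8, 9, 11, 4, 10, 8, 9, 8, 8, 8, 7, 9, 11, 6, 7, 7, 14, 12)
  nec <- c(0, 0, 1, 1, 0, 0, 1, 0, 1, 0, 0, 0, 0, 0, 1, 0, 0, 0, 0, 0)
  nphb <- c(0, 1, 4, 4, 0, 0, 2, 0, 2, 0, 0, 4, 0, 4, 5, 3, 3, 0, 1, 2)
  mass <- c(71.08, 103.14, 115.09, 129.12, 147.18, 57.05, 137.14, 113.16,
            128.17, 113.16, 131.19, 114.10, 97.12, 128.13, 156.19, 87.08,
            101.10, 99.13, 186.21, 163.18)
  eiip <- c(0.0373, 0.0829, 0.1263, 0.0058, 0.0946, 0.0050, 0.0242, 0.0000,
            0.0371, 0.0000, 0.0823, 0.0036, 0.0198, 0.0761, 0.0959, 0.0829,
            0.0941, 0.0057, 0.0548, 0.0516)
  pshp <- (kd + 4.5) / 9
  m <- cbind(Hphob = kd, Hphil = hw, polarity = pol, polariz = plz,
             propens = helx, meanASA = masa, Natoms = natm, NEC = nec,
             NPHB = nphb, mass = mass, EIIP = eiip, PSHP = pshp)
  rownames(m) <- aa
  m
})

# alpha-carboxyl (pKa1) and alpha-amino (pKa2) dissociation constants
.pka <- local({
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  pka1 <- c(2.34, 1.96, 1.88, 2.19, 1.83, 2.34, 1.82, 2.36, 2.18, 2.36,
            2.28, 2.02, 1.99, 2.17, 2.17, 2.21, 2.11, 2.32, 2.38, 2.20)
  pka2 <- c(9.69, 10.28, 9.60, 9.67, 9.13, 9.60, 9.17, 9.68, 8.95, 9.60,
            9.21, 8.80, 10.96, 9.13, 9.04, 9.15, 9.62, 9.62, 9.39, 9.11)
  m <- cbind(pKa1 = pka1, pKa2 = pka2)
  rownames(m) <- aa
  m
})

#' Default residue-contact statistical potential
#'
#' A synthetic stand-in 20x20 contact potential: the negated outer product of
#' Kyte-Doolittle hydrophobicities rescaled to `[0, 1]`, so that
#' hydrophobic-hydrophobic contacts score favourably (negative). The matrix is
#' a configuration point of [pair_potential()]; any published residue-contact
#' statistical potential with the same 20x20 layout can be substituted.
#'
#' @return Symmetric 20x20 numeric matrix in [aa_alphabet()] order.
#' @export
default_pair_potential_matrix <- function() {
  h <- .physchem[, "PSHP"]
  m <- -outer(h, h)
  dimnames(m) <- list(aa_alphabet(), aa_alphabet())
  m
}

# mean reference contact counts used to normalize residue/atom contacts.
# Neutral constant across types (packaged fixtures are poly-alanine backbones,
# so per-type means are not estimable from them); user-overridable.
default_contact_reference <- function() {
  setNames(rep(6.0, 20), aa_alphabet())
}

# hydrogen-bond donor / acceptor atom typing: residue -> atom names.
# "*" applies to every residue (backbone). Antecedent atoms give the angle.
.hb_donors <- list(
  "*"  = c(N = "CA"),
  R = c(NE = "CD", NH1 = "CZ", NH2 = "CZ"),
  K = c(NZ = "CE"), H = c(ND1 = "CG", NE2 = "CD2"),
  W = c(NE1 = "CD1"), N = c(ND2 = "CG"), Q = c(NE2 = "CD"),
  S = c(OG = "CB"), T = c(OG1 = "CB"), Y = c(OH = "CZ"), C = c(SG = "CB")
)
.hb_acceptors <- list(
  "*" = c("O", "OXT"),
  D = c("OD1", "OD2"), E = c("OE1", "OE2"), N = c("OD1"), Q = c("OE1"),
  S = c("OG"), T = c("OG1"), Y = c("OH"), H = c("ND1", "NE2"), M = c("SD")
)

#' BLOSUM62 substitution row for an amino acid
#'
#' @param aa_type One-letter amino-acid code.
#' @return Named numeric 20-vector in [aa_alphabet()] order.
#' @export
blosum_row <- function(aa_type) {
  m <- blosum62_matrix()
  if (!aa_type %in% rownames(m)) stop("unknown amino acid: ", aa_type)
  m[aa_type, aa_alphabet()]
}

blosum62_matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <- e$BLOSUM62[aa_alphabet(), aa_alphabet()]
      cache <<- m
    }
    cache
  }
})
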