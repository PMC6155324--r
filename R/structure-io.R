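# PDB-format structure input/output and the in-memory structure model.
#
# A structure is a list with class "hs_structure":
#   $atoms     data.frame: chain, resseq, icode, resname, aa, res_index,
#              res_id, atom, element, x, y, z, occupancy, radius, is_heavy
#   $residues  data.frame: res_index, res_id, chain, resseq, icode,
#              resname, aa
#   $partition list(a = chains, b = chains) or NULL for a monomer

new_structure <- function(atoms, partition = NULL) {
  key <- paste(atoms$chain, atoms$resseq, atoms$icode, sep = "\r")
  idx <- match(key, unique(key))
  atoms$res_index <- idx
  atoms$res_id <- paste0(atoms$chain, ":", atoms$resseq,
                         ifelse(atoms$icode == "", "", atoms$icode))
  first <- !duplicated(idx)
  residues <- data.frame(
    res_index = idx[first], res_id = atoms$res_id[first],
    chain = atoms$chain[first], resseq = atoms$resseq[first],
    icode = atoms$icode[first], resname = atoms$resname[first],
    aa = atoms$aa[first], stringsAsFactors = FALSE)
  structure(list(atoms = atoms, residues = residues, partition = partition),
            class = "hs_structure")
}

#' @export
print.hs_structure <- function(x, ...) {
  cat("<hs_structure> ", nrow(x$residues), " residues, ",
      sum(x$atoms$is_heavy), " heavy atoms, chains: ",
      paste(unique(x$residues$chain), collapse = ","), "\n", sep = "")
  if (!is.null(x$partition))
    cat("  partition: ", paste(x$partition$a, collapse = ","), " | ",
        paste(x$partition$b, collapse = ","), "\n", sep = "")
  invisible(x)
}

parse_partition <- function(partition_spec) {
  if (is.list(partition_spec)) {
    stopifnot(length(partition_spec) == 2)
    sides <- lapply(partition_spec, as.character)
  } else {
    parts <- strsplit(partition_spec, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2) stop("partition must name two chain groups, e.g. \"A:C\"")
    sides <- lapply(parts, function(p) strsplit(p, ",", fixed = TRUE)[[1]])
  }
  names(sides) <- c("a", "b")
  if (!length(sides$a) || !length(sides$b)) stop("each side needs >= 1 chain")
  if (length(intersect(sides$a, sides$b))) stop("partition sides must be disjoint")
  sides
}

.element_from_name <- function(name) {
  nm <- gsub("[0-9' ]", "", name)
  two <- toupper(substr(nm, 1, 2))
  ifelse(two %in% c("SE", "FE", "ZN", "MG", "MN", "CL", "BR", "NA", "CA") &
           nchar(nm) >= 2 & two == toupper(nm),
         two, toupper(substr(nm, 1, 1)))
}

#' Read a protein complex from a PDB file
#'
#' Parses ATOM records (plus HETATM records of residues with a standard
#' parent, e.g. selenomethionine) from the first MODEL. Alternate locations
#' are resolved to the highest occupancy, waters and hetero ligands are
#' excluded, and hydrogens are kept but flagged so that heavy-atom views can
#' drop them.
#'
#' @param path PDB file path.
#' @param partition_spec Two chain groups defining the binding sides, either
#'   a string like `"A:C"` / `"A,B:C"` or `list(c("A"), c("C"))`.
#' @param vdw_table Optional named vector of van der Waals radii by element.
#' @return An `hs_structure` restricted to the partition chains.
#' @export
read_pdb <- function(path, partition_spec, vdw_table = NULL) {
  lines <- readLines(path, warn = FALSE)
  end_model <- grep("^ENDMDL", lines)
  if (length(end_model)) lines <- lines[seq_len(end_model[1] - 1)]
  rec <- substr(lines, 1, 6)
  keep <- rec == "ATOM  " | rec == "HETATM"
  lines <- lines[keep]
  rec <- rec[keep]
  if (!length(lines)) stop("no ATOM records in ", path)

  resname <- trimws(substr(lines, 18, 20))
  is_water <- resname %in% c("HOH", "WAT", "DOD", "H2O")
  aa <- aa_three_to_one(resname)
  drop_het <- rec == "HETATM" & is.na(aa)   # ligands
  keep <- !is_water & !drop_het
  lines <- lines[keep]
  resname <- resname[keep]
  aa <- aa[keep]
  if (!length(lines)) stop("no protein atoms in ", path)

  name <- trimws(substr(lines, 13, 16))
  altloc <- substr(lines, 17, 17)
  chain <- substr(lines, 22, 22)
  resseq <- as.integer(substr(lines, 23, 26))
  icode <- trimws(substr(lines, 27, 27))
  x <- as.numeric(substr(lines, 31, 38))
  y <- as.numeric(substr(lines, 39, 46))
  z <- as.numeric(substr(lines, 47, 54))
  occ <- suppressWarnings(as.numeric(substr(lines, 55, 60)))
  occ[is.na(occ)] <- 1.0
  element <- toupper(trimws(substr(lines, 77, 78)))
  miss <- element == "" | is.na(element)
  element[miss] <- .element_from_name(name[miss])

  atoms <- data.frame(chain = chain, resseq = resseq, icode = icode,
                      resname = resname, aa = aa, atom = name,
                      element = element, x = x, y = y, z = z,
                      occupancy = occ, stringsAsFactors = FALSE)
  # altloc: keep highest occupancy per (residue, atom name)
  if (any(altloc != " ")) {
    key <- paste(chain, resseq, icode, name, sep = "\r")
    ord <- order(key, -occ)
    atoms <- atoms[ord, , drop = FALSE]
    atoms <- atoms[!duplicated(key[ord]), , drop = FALSE]
    atoms <- atoms[order(as.integer(rownames(atoms))), , drop = FALSE]
  }
  atoms$is_heavy <- !(atoms$element %in% c("H", "D"))
  atoms$radius <- vdw_radius(atoms$element, vdw_table)

  sides <- parse_partition(partition_spec)
  present <- unique(atoms$chain)
  missing_chains <- setdiff(c(sides$a, sides$b), present)
  if (length(missing_chains))
    stop("chain(s) not found in file: ", paste(missing_chains, collapse = ","))
  atoms <- atoms[atoms$chain %in% c(sides$a, sides$b), , drop = FALSE]

  # drop residues without heavy atoms
  key <- paste(atoms$chain, atoms$resseq, atoms$icode, sep = "\r")
  n_heavy <- tapply(atoms$is_heavy, key, sum)
  bad <- names(n_heavy)[n_heavy < 1]
  if (length(bad)) {
    warning(length(bad), " residue(s) without heavy atoms skipped")
    atoms <- atoms[!key %in% bad, , drop = FALSE]
  }
  rownames(atoms) <- NULL
  new_structure(atoms, sides)
}

#' Extract one binding side as a monomer
#'
#' @param structure An `hs_structure` with a two-side partition (or already a
#'   monomer, in which case it is returned unchanged).
#' @param side `"a"` or `"b"`.
#' @return An `hs_structure` containing only that side's chains; residue
#'   identities are preserved.
#' @export
extract_monomer <- function(structure, side = c("a", "b")) {
  side <- match.arg(side)
  if (is.null(structure$partition)) return(structure)
  chains <- structure$partition[[side]]
  atoms <- structure$atoms[structure$atoms$chain %in% chains, , drop = FALSE]
  atoms$res_index <- NULL
  atoms$res_id <- NULL
  rownames(atoms) <- NULL
  st <- new_structure(atoms, partition = NULL)
  st$side <- side
  st
}

#' Write a structure to a PDB file
#'
#' @param structure An `hs_structure`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path) {
  a <- structure$atoms
  lines <- sprintf(
    "ATOM  %5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(a)),
    ifelse(nchar(a$atom) >= 4, a$atom, paste0(" ", a$atom)),
    " ", a$resname, a$chain, a$resseq, ifelse(a$icode == "", " ", a$icode),
    a$x, a$y, a$z, a$occupancy, 0, a$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

# heavy-atom coordinate matrix + residue index for geometry kernels
heavy_view <- function(structure) {
  a <- structure$atoms[structure$atoms$is_heavy, , drop = FALSE]
  list(coords = cbind(a$x, a$y, a$z), res_index = a$res_index,
       radius = a$radius, atoms = a)
}
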