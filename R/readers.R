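# Readers for externally computed per-residue tracks: PSI-BLAST ASCII PSSM,
# DSSP, disorder predictors, HBPLUS, and a generic per-residue TSV.

#' Read a PSI-BLAST ASCII PSSM (-out_ascii_pssm layout)
#'
#' @param path File path.
#' @return An object of class `hs_pssm`: list with `sequence` (one-letter
#'   vector), `scores` (n x 20 log-odds, [aa_alphabet()] column order) and
#'   `freq` (n x 20 observed frequencies in `[0, 1]`).
#' @export
read_pssm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  psi_order <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  hdr <- grep("^\\s*A\\s+R\\s+N\\s+D\\s+C", lines)
  if (!length(hdr)) stop("not a PSI-BLAST ASCII PSSM: ", path)
  body <- lines[(hdr[1] + 1):length(lines)]
  body <- body[grepl("^\\s*\\d+\\s+[A-Z]", body)]
  if (!length(body)) stop("empty PSSM body in ", path)
  toks <- strsplit(trimws(body), "\\s+")
  n <- length(toks)
  seqv <- character(n)
  scores <- matrix(NA_real_, n, 20)
  freq <- matrix(NA_real_, n, 20)
  for (i in seq_len(n)) {
    tk <- toks[[i]]
    if (length(tk) < 42) stop("malformed PSSM row ", i)
    seqv[i] <- tk[2]
    scores[i, ] <- as.numeric(tk[3:22])
    freq[i, ] <- as.numeric(tk[23:42]) / 100
  }
  ord <- match(aa_alphabet(), psi_order)
  scores <- scores[, ord, drop = FALSE]
  freq <- freq[, ord, drop = FALSE]
  colnames(scores) <- colnames(freq) <- aa_alphabet()
  structure(list(sequence = seqv, scores = scores, freq = freq),
            class = "hs_pssm")
}

#' Log-odds PSSM row at a position
#' @param pssm An `hs_pssm`.
#' @param position 1-based sequence position.
#' @return Named numeric 20-vector.
#' @export
pssm_row <- function(pssm, position) {
  if (position < 1 || position > nrow(pssm$scores))
    stop("position out of range")
  pssm$scores[position, ]
}

#' Read a DSSP output file
#'
#' Extracts chain, residue number, insertion code, one-letter amino acid,
#' secondary-structure letter and accessibility from the fixed-column data
#' block.
#'
#' @param path File path.
#' @return data.frame: chain, resseq, icode, aa, ss, acc, res_id.
#' @export
read_dssp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  start <- grep("^  #  RESIDUE", lines)
  if (!length(start)) stop("not a DSSP file: ", path)
  body <- lines[(start[1] + 1):length(lines)]
  body <- body[nchar(body) >= 38 & substr(body, 14, 14) != "!"]
  resseq <- as.integer(substr(body, 6, 10))
  icode <- trimws(substr(body, 11, 11))
  chain <- substr(body, 12, 12)
  aa <- substr(body, 14, 14)
  ss <- substr(body, 17, 17)
  acc <- as.numeric(substr(body, 35, 38))
  data.frame(chain = chain, resseq = resseq, icode = icode, aa = aa,
             ss = ss, acc = acc,
             res_id = paste0(chain, ":", resseq, ifelse(icode == "", "", icode)),
             stringsAsFactors = FALSE)
}

#' Read a DISOPRED-style disorder track (.diso)
#'
#' Data lines: residue number, amino acid, state mark (`*` disordered, `.`
#' ordered), score.
#'
#' @param path File path.
#' @return data.frame: resnum, aa, state (0/1), score.
#' @export
read_disopred <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- lines[grepl("^\\s*\\d+\\s+\\S\\s+[.*]\\s+", lines)]
  toks <- strsplit(trimws(body), "\\s+")
  data.frame(resnum = vapply(toks, function(t) as.integer(t[1]), integer(1)),
             aa = vapply(toks, function(t) t[2], character(1)),
             state = vapply(toks, function(t) as.integer(t[3] == "*"), integer(1)),
             score = vapply(toks, function(t) as.numeric(t[4]), numeric(1)),
             stringsAsFactors = FALSE)
}

#' Read a DisEMBL-style disorder track
#'
#' Tab-separated with header `resnum aa coils rem465 hotloops`.
#'
#' @param path File path.
#' @return data.frame with those columns.
#' @export
read_disembl <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("resnum", "aa", "coils", "rem465", "hotloops")
  if (!all(need %in% names(df))) stop("missing DisEMBL columns in ", path)
  df[need]
}

#' Read an HBPLUS .hb2 hydrogen-bond listing
#'
#' Body lines are parsed by whitespace: donor `<chain><num>-<res>`, donor
#' atom, acceptor `<chain><num>-<res>`, acceptor atom, distance. Returns
#' per-residue bond counts (each bond counted for donor and acceptor
#' residue).
#'
#' @param path File path.
#' @return data.frame: res_id (chain:resnum), hbond_count.
#' @export
read_hb2 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  pat <- "^[A-Za-z0-9][0-9]{4}[-][A-Z]{3}\\s"
  body <- lines[grepl(pat, lines)]
  parse_res <- function(tok) {
    chain <- substr(tok, 1, 1)
    num <- as.integer(substr(tok, 2, 5))
    paste0(chain, ":", num)
  }
  ids <- character(0)
  for (ln in body) {
    tk <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(tk) < 5) next
    ids <- c(ids, parse_res(tk[1]), parse_res(tk[3]))
  }
  tab <- table(ids)
  data.frame(res_id = names(tab), hbond_count = as.integer(tab),
             stringsAsFactors = FALSE)
}

#' Read a generic per-residue value TSV
#'
#' Header columns: `chain`, `resnum`, `icode` (may be empty), then one or
#' more named value columns; used for pluggable pre-computed features.
#'
#' @param path File path.
#' @return data.frame keyed by res_id with the value columns.
#' @export
read_residue_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   na.strings = c("NA", ""))
  if (!all(c("chain", "resnum") %in% names(df)))
    stop("residue TSV needs chain and resnum columns: ", path)
  icode <- if ("icode" %in% names(df)) ifelse(is.na(df$icode), "", df$icode) else ""
  vals <- df[setdiff(names(df), c("chain", "resnum", "icode"))]
  cbind(data.frame(res_id = paste0(df$chain, ":", df$resnum, icode),
                   stringsAsFactors = FALSE), vals)
}
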