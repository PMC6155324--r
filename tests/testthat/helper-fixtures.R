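# Shared fixture builders. Everything is generated in code at test time.

# build an hs_structure from a compact atom spec:
# list(list(chain, resseq, resname, atoms = list(NAME = c(x, y, z)), ...))
toy_structure <- function(res_spec, partition = NULL) {
  rows <- list()
  for (r in res_spec) {
    for (nm in names(r$atoms)) {
      xyz <- r$atoms[[nm]]
      el <- substr(gsub("[0-9]", "", nm), 1, 1)
      rows[[length(rows) + 1]] <- data.frame(
        chain = r$chain, resseq = r$resseq, icode = "",
        resname = r$resname %||% "ALA",
        aa = hotspotr:::aa_three_to_one(r$resname %||% "ALA"),
        atom = nm, element = el, x = xyz[1], y = xyz[2], z = xyz[3],
        occupancy = 1, stringsAsFactors = FALSE)
    }
  }
  atoms <- do.call(rbind, rows)
  atoms$is_heavy <- !(atoms$element %in% c("H", "D"))
  atoms$radius <- hotspotr:::vdw_radius(atoms$element)
  hotspotr:::new_structure(atoms, partition = partition)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# cached small dimer (expensive pieces reused across tests)
.fixture_env <- new.env(parent = emptyenv())
cached_dimer <- function(n_res = 10, gap = 4, seed = 1) {
  key <- paste0("d", n_res, "_", gap, "_", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- make_dimer(n_res, gap, seed)
  .fixture_env[[key]]
}

# brute-force residue adjacency by minimum heavy-atom distance
brute_euclidean_edges <- function(st, cutoff) {
  a <- st$atoms[st$atoms$is_heavy, ]
  n <- max(a$res_index)
  edges <- matrix(0L, 0, 2)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ai <- a[a$res_index == i, c("x", "y", "z")]
    aj <- a[a$res_index == j, c("x", "y", "z")]
    dmin <- Inf
    for (k in seq_len(nrow(ai))) {
      d <- sqrt((aj$x - ai$x[k])^2 + (aj$y - ai$y[k])^2 + (aj$z - ai$z[k])^2)
      dmin <- min(dmin, min(d))
    }
    if (dmin <= cutoff) edges <- rbind(edges, c(i, j))
  }
  edges
}

# independent empty-circumsphere check of a tetrahedron against all points
circumsphere_ok <- function(pts, v, tol = 1e-6) {
  A <- pts[v, , drop = FALSE]
  M <- 2 * (A[2:4, ] - matrix(A[1, ], 3, 3, byrow = TRUE))
  rhs <- rowSums(A[2:4, ]^2) - sum(A[1, ]^2)
  cc <- tryCatch(solve(M, rhs), error = function(e) return(NULL))
  if (is.null(cc)) return(NA)
  r2 <- sum((cc - A[1, ])^2)
  d2 <- rowSums((pts - matrix(cc, nrow(pts), 3, byrow = TRUE))^2)
  inside <- which(d2 < r2 - tol * (1 + r2))
  length(setdiff(inside, v)) == 0
}

# plug-in histogram MI oracle by direct summation over the contingency table
brute_mi <- function(dx, dy) {
  tab <- table(dx, dy)
  n <- sum(tab)
  mi <- 0
  for (a in rownames(tab)) for (b in colnames(tab)) {
    pj <- tab[a, b] / n
    if (pj > 0) mi <- mi + pj * log2(pj * n * n / (sum(tab[a, ]) * sum(tab[, b])))
  }
  mi
}

# independent brute-force greedy mRMR (difference form) on a small matrix
brute_mrmr <- function(X, y, k) {
  p <- ncol(X)
  disc <- lapply(seq_len(p), function(j) hotspotr:::discretize_feature(X[, j]))
  dy <- as.integer(factor(y)) - 1L
  mi <- function(a, b) brute_mi(a, b)
  rel <- vapply(disc, function(d) mi(d, dy), numeric(1))
  sel <- integer(0)
  for (s in seq_len(k)) {
    rest <- setdiff(seq_len(p), sel)
    crit <- vapply(rest, function(j) {
      red <- if (!length(sel)) 0 else
        mean(vapply(sel, function(i2) mi(disc[[j]], disc[[i2]]), numeric(1)))
      rel[j] - red
    }, numeric(1))
    sel <- c(sel, rest[which.max(crit)])
  }
  colnames(X)[sel]
}
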