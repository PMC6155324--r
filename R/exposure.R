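# Half-sphere exposure and coordination number.

# unit vector helper
.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-9) return(c(NA_real_, NA_real_, NA_real_))
  v / n
}

# pseudo C-beta direction from backbone N, CA, C by ideal tetrahedral
# geometry (used for glycine and residues missing C-beta)
pseudo_cb <- function(n, ca, c) {
  u1 <- .unit(n - ca)
  u2 <- .unit(c - ca)
  if (anyNA(u1) || anyNA(u2)) return(c(NA_real_, NA_real_, NA_real_))
  b <- .unit(u1 + u2)
  perp <- .unit(pracma_cross(u1, u2))
  if (anyNA(b) || anyNA(perp)) return(c(NA_real_, NA_real_, NA_real_))
  d <- .unit(-0.604 * b + 0.797 * perp)
  ca + 1.521 * d
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Half-sphere exposure and coordination number
#'
#' For every residue with a C-alpha atom, counts neighbouring C-alpha atoms
#' within `radius`, split by the plane through the C-alpha normal to an
#' up-vector: HSEA uses the C-alpha-trace approximation of the side-chain
#' direction, `-(CA(i-1)-CA(i)) - (CA(i+1)-CA(i))` (falling back to the
#' real or pseudo C-beta when chain neighbours are missing), while HSEB uses
#' the real C-beta vector (pseudo C-beta for glycine). CN is the total number
#' of C-alpha neighbours within `radius`, so HSEBU + HSEBD = CN.
#'
#' @param structure An `hs_structure`.
#' @param radius Neighbour sphere radius in Angstrom (default 13).
#' @return data.frame: res_id, HSEAU, HSEAD, HSEBU, HSEBD, CN (NA rows for
#'   residues without C-alpha).
#' @export
half_sphere_exposure <- function(structure, radius = 13) {
  res <- structure$residues
  nres <- nrow(res)
  a <- structure$atoms
  get_atom <- function(name) {
    m <- matrix(NA_real_, nres, 3)
    hit <- a$atom == name & a$is_heavy
    m[a$res_index[hit], ] <- cbind(a$x[hit], a$y[hit], a$z[hit])
    m
  }
  ca <- get_atom("CA")
  cb <- get_atom("CB")
  nn <- get_atom("N")
  cc <- get_atom("C")
  # fill missing C-beta by ideal construction
  for (i in seq_len(nres)) {
    if (anyNA(cb[i, ]) && !anyNA(ca[i, ]) && !anyNA(nn[i, ]) && !anyNA(cc[i, ]))
      cb[i, ] <- pseudo_cb(nn[i, ], ca[i, ], cc[i, ])
  }
  # C-alpha-trace up-vector per residue (same chain, consecutive resseq)
  up_a <- matrix(NA_real_, nres, 3)
  for (i in seq_len(nres)) {
    if (anyNA(ca[i, ])) next
    prev <- which(res$chain == res$chain[i] & res$resseq == res$resseq[i] - 1)
    nxt <- which(res$chain == res$chain[i] & res$resseq == res$resseq[i] + 1)
    if (length(prev) == 1 && length(nxt) == 1 &&
        !anyNA(ca[prev, ]) && !anyNA(ca[nxt, ])) {
      up_a[i, ] <- .unit(-(ca[prev, ] - ca[i, ]) - (ca[nxt, ] - ca[i, ]))
    } else if (!anyNA(cb[i, ])) {
      up_a[i, ] <- .unit(cb[i, ] - ca[i, ])
    }
  }

  out <- data.frame(res_id = res$res_id, HSEAU = NA_real_, HSEAD = NA_real_,
                    HSEBU = NA_real_, HSEBD = NA_real_, CN = NA_real_,
                    stringsAsFactors = FALSE)
  r2 <- radius^2
  for (i in seq_len(nres)) {
    if (anyNA(ca[i, ])) next
    d2 <- (ca[, 1] - ca[i, 1])^2 + (ca[, 2] - ca[i, 2])^2 +
      (ca[, 3] - ca[i, 3])^2
    nb <- which(d2 <= r2 & seq_len(nres) != i & !is.na(d2))
    out$CN[i] <- length(nb)
    if (!length(nb)) {
      out$HSEAU[i] <- out$HSEAD[i] <- out$HSEBU[i] <- out$HSEBD[i] <- 0
      next
    }
    dv <- ca[nb, , drop = FALSE] - matrix(ca[i, ], length(nb), 3, byrow = TRUE)
    if (!anyNA(up_a[i, ])) {
      s <- dv %*% up_a[i, ]
      out$HSEAU[i] <- sum(s > 0)
      out$HSEAD[i] <- sum(s <= 0)
    }
    if (!anyNA(cb[i, ])) {
      ub <- .unit(cb[i, ] - ca[i, ])
      s <- dv %*% ub
      out$HSEBU[i] <- sum(s > 0)
      out$HSEBD[i] <- sum(s <= 0)
    }
  }
  out
}
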