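# Structural neighborhood graphs: Euclidean (min heavy-atom distance) and
# Voronoi (shared Delaunay tetrahedron) residue adjacency.

new_neighbor_graph <- function(kind, edges, nres, res_ids) {
  adj <- vector("list", nres)
  for (k in seq_len(nres)) adj[[k]] <- integer(0)
  if (nrow(edges)) {
    for (k in seq_len(nrow(edges))) {
      i <- edges[k, 1]; j <- edges[k, 2]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
    adj <- lapply(adj, function(v) sort(unique(v)))
  }
  structure(list(kind = kind, edges = edges, adjacency = adj,
                 res_ids = res_ids),
            class = "hs_neighbor_graph")
}

#' @export
print.hs_neighbor_graph <- function(x, ...) {
  cat("<hs_neighbor_graph> kind=", x$kind, ", ", length(x$res_ids),
      " residues, ", nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Euclidean residue neighborhood graph
#'
#' Residues are adjacent when the minimum distance over all heavy-atom pairs
#' is at most `cutoff` (default 5 Angstrom).
#'
#' @param structure An `hs_structure`.
#' @param cutoff Distance threshold, Angstrom.
#' @return An `hs_neighbor_graph` (symmetric, irreflexive).
#' @export
euclidean_neighbors <- function(structure, cutoff = 5) {
  res <- structure$residues
  hv <- heavy_view(structure)
  st <- residue_dist_stats_cpp(hv$coords, hv$res_index, nrow(res), cutoff)
  md <- st$min_dist
  idx <- which(upper.tri(md) & md <= cutoff, arr.ind = TRUE)
  edges <- cbind(i = idx[, 1], j = idx[, 2])
  new_neighbor_graph("euclidean", edges, nrow(res), res$res_id)
}

#' Voronoi (Delaunay) residue neighborhood graph
#'
#' Tessellates all heavy atoms of the structure (both sides of the complex,
#' so neighborhoods cross the interface) and links two residues when some
#' Delaunay tetrahedron contains a heavy atom of each. Outer-hull artifacts
#' are suppressed by dropping adjacencies whose minimum heavy-atom distance
#' exceeds `max_edge`. Near-degenerate (cospherical) inputs are retried with
#' a deterministic 1e-6 Angstrom jitter; truly coplanar inputs are an error.
#'
#' @param structure An `hs_structure`.
#' @param max_edge Maximum allowed minimum heavy-atom distance for a retained
#'   Voronoi adjacency, Angstrom (default 8).
#' @return An `hs_neighbor_graph`.
#' @export
voronoi_neighbors <- function(structure, max_edge = 8) {
  res <- structure$residues
  hv <- heavy_view(structure)
  n <- nrow(hv$coords)
  if (n < 4) stop("need at least 4 heavy atoms for a tessellation")
  coords <- sweep(hv$coords, 2, colMeans(hv$coords))
  sv <- svd(coords, nu = 0, nv = 0)$d
  if (sv[3] < 1e-6 * max(sv[1], 1))
    stop("degenerate point configuration (coplanar atoms); ",
         "jitter the input coordinates")
  tess <- delaunay_cpp(coords)
  if (tess$degenerate) {
    # deterministic jitter (fixed linear-congruential stream, not user RNG)
    jit <- .lcg_runif(3L * n, seed = 987654321L)
    coords_j <- coords + matrix((jit - 0.5) * 2e-6, n, 3)
    tess <- delaunay_cpp(coords_j)
    if (tess$degenerate)
      stop("degenerate point configuration (coplanar/cospherical); ",
           "jitter the input coordinates")
  }
  tets <- tess$tets
  # residue pairs sharing a tetrahedron
  pairs <- matrix(integer(0), 0, 2)
  if (nrow(tets)) {
    rr <- matrix(hv$res_index[tets], nrow(tets), 4)
    combs <- utils::combn(4, 2)
    plist <- lapply(seq_len(ncol(combs)), function(k) {
      cbind(rr[, combs[1, k]], rr[, combs[2, k]])
    })
    pairs <- do.call(rbind, plist)
    pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
    pairs <- cbind(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
    pairs <- unique(pairs)
  }
  if (nrow(pairs)) {
    st <- residue_dist_stats_cpp(hv$coords, hv$res_index, nrow(res), 4.5)
    keep <- st$min_dist[pairs] <= max_edge
    pairs <- pairs[keep, , drop = FALSE]
  }
  colnames(pairs) <- c("i", "j")
  new_neighbor_graph("voronoi", pairs, nrow(res), res$res_id)
}

# small deterministic uniform stream independent of the user's RNG
# (warm-up discards mix small seeds into the state)
.lcg_runif <- function(n, seed) {
  out <- numeric(n)
  state <- (as.double(seed %% 2147483647L) * 69069 + 1) %% 2147483647
  if (state == 0) state <- 1
  for (k in 1:10) state <- (16807 * state) %% 2147483647
  for (k in seq_len(n)) {
    state <- (16807 * state) %% 2147483647
    out[k] <- state / 2147483647
  }
  out
}

#' Same-side / cross-side Voronoi contact counts
#'
#' Splits each residue's Voronoi degree by the complex partition: the number
#' of Voronoi-neighbour residues on its own binding side and on the opposite
#' side.
#'
#' @param structure An `hs_structure` with a partition.
#' @param graph A Voronoi `hs_neighbor_graph` built on the same structure.
#' @return data.frame: res_id, voro_same_side, voro_cross_side.
#' @export
voronoi_contacts <- function(structure, graph) {
  if (is.null(structure$partition)) stop("structure has no side partition")
  res <- structure$residues
  side <- ifelse(res$chain %in% structure$partition$a, "a", "b")
  same <- integer(nrow(res))
  cross <- integer(nrow(res))
  for (i in seq_len(nrow(res))) {
    nb <- graph$adjacency[[i]]
    same[i] <- sum(side[nb] == side[i])
    cross[i] <- sum(side[nb] != side[i])
  }
  data.frame(res_id = res$res_id, voro_same_side = same,
             voro_cross_side = cross, stringsAsFactors = FALSE)
}

#' Export a neighborhood graph as an edge-list text file
#'
#' Tab-separated lines: residue id, residue id, graph kind.
#' @param graph An `hs_neighbor_graph`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  e <- graph$edges
  df <- data.frame(a = graph$res_ids[e[, 1]], b = graph$res_ids[e[, 2]],
                   kind = graph$kind)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
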