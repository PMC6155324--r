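# Expansion of site descriptors into the full feature table:
# {site, Euclidean neighborhood, Voronoi neighborhood} x {raw, W_FB-weighted}.

#' Aggregate site values over a structural neighborhood
#'
#' The context value of a residue is the sum of the site values of the
#' residue itself (when `include_center`) and its graph neighbours. A residue
#' absent from the graph is treated as having no neighbours.
#'
#' @param site_values Numeric matrix (residues x features), rows aligned with
#'   the graph's residue order.
#' @param graph An `hs_neighbor_graph`.
#' @param include_center Include the central residue's own value (default
#'   TRUE).
#' @return Matrix of the same shape.
#' @export
aggregate_neighborhood <- function(site_values, graph, include_center = TRUE) {
  n <- nrow(site_values)
  out <- matrix(NA_real_, n, ncol(site_values),
                dimnames = dimnames(site_values))
  for (i in seq_len(n)) {
    nb <- if (i <= length(graph$adjacency)) graph$adjacency[[i]] else integer(0)
    rows <- if (include_center) c(i, nb) else nb
    if (!length(rows)) {
      out[i, ] <- 0
    } else {
      block <- site_values[rows, , drop = FALSE]
      out[i, ] <- colSums(block)
    }
  }
  out
}

#' Weight a residue's site values by its weighted fraction buried
#'
#' Multiplies a feature vector by the residue's W_FB from a surface profile.
#' Defined only for interface residues (W_FB of a non-interface residue is
#' not meaningful as a center weight).
#'
#' @param values Numeric vector of site feature values.
#' @param surface_profile A [surface_profile()] data.frame.
#' @param residue Residue id (e.g. `"A:93"`).
#' @return Weighted numeric vector.
#' @export
apply_weighting <- function(values, surface_profile, residue) {
  k <- match(residue, surface_profile$res_id)
  if (is.na(k)) stop("unknown residue: ", residue)
  if (!surface_profile$is_interface[k])
    stop("W_FB undefined for non-interface residue ", residue)
  values * surface_profile$W_FB[k]
}

# full 6-block expansion for every residue of one complex.
# W_ blocks multiply each residue's own site values by its own W_FB *before*
# neighborhood aggregation (non-interface residues carry W_FB = 0).
expand_feature_blocks <- function(site_values, surface, en_graph, vn_graph) {
  wfb <- surface$W_FB[match(rownames(site_values), surface$res_id)]
  wsite <- site_values * wfb
  blocks <- list(
    site = site_values,
    W_site = wsite,
    EN = aggregate_neighborhood(site_values, en_graph),
    W_EN = aggregate_neighborhood(wsite, en_graph),
    VN = aggregate_neighborhood(site_values, vn_graph),
    W_VN = aggregate_neighborhood(wsite, vn_graph))
  nm <- colnames(site_values)
  out <- cbind(blocks$site, blocks$W_site, blocks$EN, blocks$W_EN,
               blocks$VN, blocks$W_VN)
  colnames(out) <- c(nm, paste0("W_", nm), paste0(nm, "_EN"),
                     paste0("W_", nm, "_EN"), paste0(nm, "_VN"),
                     paste0("W_", nm, "_VN"))
  out
}

#' Full feature-name vector (6 x site block)
#' @return Character vector of length `6 * length(site_feature_names())`.
#' @export
feature_table_names <- function() {
  nm <- site_feature_names()
  c(nm, paste0("W_", nm), paste0(nm, "_EN"), paste0("W_", nm, "_EN"),
    paste0(nm, "_VN"), paste0("W_", nm, "_VN"))
}

#' Build the labeled feature table over a set of complexes
#'
#' For every labeled interface residue, assembles the full expanded feature
#' vector. Hot-spot labels follow the training convention ddG >= `ddg_hot`
#' kcal/mol when the label table has a `ddG` column, or `annotation ==
#' "strong"` otherwise. Labeled residues that cannot be mapped to a parsed
#' residue are collected in the `exclusions` attribute, not dropped silently.
#'
#' @param complexes Named list of `hs_structure` objects (names are complex
#'   ids).
#' @param labels data.frame: complex_id, chain, resnum, optional icode, and
#'   ddG (numeric) or annotation (character).
#' @param tracks Optional named list (by complex id) of per-complex track
#'   lists with elements pssm, dssp, disopred, disembl, pluggable.
#' @param config Geometry configuration passed to [site_descriptors()].
#' @param ddg_hot Hot-spot threshold, kcal/mol (default 2.0).
#' @param euclidean_cutoff,voronoi_max_edge Neighborhood parameters.
#' @return An `hs_feature_table`: data.frame with columns complex_id, res_id,
#'   ddG, label and all feature columns, sorted by (complex_id, res_id).
#' @export
build_feature_table <- function(complexes, labels, tracks = NULL,
                                config = list(), ddg_hot = 2.0,
                                euclidean_cutoff = 5, voronoi_max_edge = 8) {
  stopifnot(length(names(complexes)) == length(complexes))
  rows <- list()
  exclusions <- list()
  for (cid in sort(names(complexes))) {
    st <- complexes[[cid]]
    lab <- labels[labels$complex_id == cid, , drop = FALSE]
    if (!nrow(lab)) next
    icode <- if ("icode" %in% names(lab)) ifelse(is.na(lab$icode), "", lab$icode) else ""
    lab$res_id <- paste0(lab$chain, ":", lab$resnum, icode)
    tr <- if (!is.null(tracks)) tracks[[cid]] else NULL
    cfg <- config
    surface <- surface_profile(st,
                               probe_radius = cfg$probe_radius %||% 1.4,
                               n_sphere_points = cfg$n_sphere_points %||% 960,
                               interface_dasa_min = cfg$interface_dasa_min %||% 0.1)
    site <- site_descriptors(st, surface = surface, pssm = tr$pssm,
                             dssp = tr$dssp, disopred = tr$disopred,
                             disembl = tr$disembl, pluggable = tr$pluggable,
                             config = config)
    en <- euclidean_neighbors(st, euclidean_cutoff)
    vn <- attr(site, "voronoi_graph")
    if (is.null(vn)) vn <- voronoi_neighbors(st, voronoi_max_edge)
    full <- expand_feature_blocks(site, surface, en, vn)

    hit <- match(lab$res_id, rownames(full))
    bad <- is.na(hit)
    if (any(bad))
      exclusions[[cid]] <- lab$res_id[bad]
    lab <- lab[!bad, , drop = FALSE]
    hit <- hit[!bad]
    if (!nrow(lab)) next
    if ("ddG" %in% names(lab)) {
      ddg <- lab$ddG
      y <- as.integer(ddg >= ddg_hot)
    } else {
      ddg <- rep(NA_real_, nrow(lab))
      y <- as.integer(lab$annotation == "strong")
    }
    rows[[cid]] <- cbind(
      data.frame(complex_id = cid, res_id = lab$res_id, ddG = ddg,
                 label = y, stringsAsFactors = FALSE),
      as.data.frame(full[hit, , drop = FALSE], optional = TRUE))
  }
  if (!length(rows)) {
    out <- cbind(data.frame(complex_id = character(0), res_id = character(0),
                            ddG = numeric(0), label = integer(0)),
                 as.data.frame(matrix(numeric(0), 0,
                                      length(feature_table_names()),
                                      dimnames = list(NULL, feature_table_names())),
                               optional = TRUE))
  } else {
    out <- do.call(rbind, rows)
    out <- out[order(out$complex_id, out$res_id), , drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "exclusions") <- exclusions
  class(out) <- c("hs_feature_table", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract the numeric feature matrix from a feature table
#' @param table An `hs_feature_table` (or plain data.frame with metadata
#'   columns complex_id, res_id, ddG, label).
#' @return Numeric matrix (samples x features).
#' @export
feature_matrix <- function(table) {
  meta <- intersect(c("complex_id", "res_id", "ddG", "label"), names(table))
  as.matrix(table[setdiff(names(table), meta)])
}

#' Fill missing feature values with column means
#'
#' Missing external (pluggable) columns are imputed with the mean of the
#' observed values of that column at model time; columns with no observed
#' value fall back to 0. The imputed column names are recorded in the
#' `imputed` attribute.
#'
#' @param X Numeric feature matrix.
#' @param means Optional named vector of training means to reuse (for test
#'   data).
#' @return Matrix without NA values.
#' @export
impute_features <- function(X, means = NULL) {
  nas <- colSums(is.na(X)) > 0
  if (!any(nas)) {
    attr(X, "imputed") <- character(0)
    return(X)
  }
  for (j in which(nas)) {
    m <- if (!is.null(means)) means[colnames(X)[j]] else mean(X[, j], na.rm = TRUE)
    if (!is.finite(m)) m <- 0
    X[is.na(X[, j]), j] <- m
  }
  attr(X, "imputed") <- colnames(X)[nas]
  X
}

#' Write / read a feature table as TSV
#'
#' Deterministic tab-separated serialization with a full header line; numeric
#' values at full precision (17 significant digits) so that identical tables
#' are byte-identical.
#'
#' @param table An `hs_feature_table`.
#' @param path File path.
#' @return `path` invisibly / the table.
#' @export
write_feature_table <- function(table, path) {
  df <- as.data.frame(table)
  num <- vapply(df, is.numeric, logical(1))
  for (j in which(num)) df[[j]] <- sprintf("%.17g", df[[j]])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  out <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
  class(out) <- c("hs_feature_table", class(out))
  out
}
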