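# Residue graphs and geometric features.
#
# Each protein becomes a directed k-nearest-neighbour graph over its
# residues. Nearest neighbours are determined by the mean inter-atomic
# distance between residue pairs (heavy atoms only); each directed edge
# j -> i carries a 2-vector of features: the mean distance D_ij (Angstrom)
# and the relative orientation theta_ij (radians), the absolute angle
# between the backbone-plane normals of the two residues.

.residue_xyz <- function(r, atom_filter = c("heavy", "all", "ca")) {
  atom_filter <- match.arg(atom_filter)
  keep <- switch(atom_filter,
    heavy = !r$is_hydrogen,
    all   = rep(TRUE, nrow(r$xyz)),
    ca    = r$atom_names == "CA"
  )
  r$xyz[keep, , drop = FALSE]
}

.cross_dist <- function(A, B) {
  # Euclidean distances between rows of A (n x 3) and rows of B (m x 3)
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
  sqrt(pmax(d2, 0))
}

#' Mean inter-atomic distance between two residues
#'
#' Arithmetic mean of the Euclidean distances over the full cross-product of
#' selected atom pairs. Symmetric in its arguments. Heavy (non-hydrogen)
#' atoms are used by default; hydrogens are usually absent from X-ray
#' structures, so excluding them keeps the metric comparable across files.
#'
#' @param r1,r2 [residue_record()] objects
#' @param atom_filter `"heavy"` (default), `"all"`, or `"ca"`
#' @return distance in Angstrom
#' @export
mean_residue_distance <- function(r1, r2, atom_filter = "heavy") {
  A <- .residue_xyz(r1, atom_filter)
  B <- .residue_xyz(r2, atom_filter)
  if (nrow(A) == 0 || nrow(B) == 0)
    stop(sprintf("no atoms pass filter '%s' for residue %s%s",
                 atom_filter,
                 if (nrow(A) == 0) r1$chain else r2$chain,
                 if (nrow(A) == 0) r1$resno else r2$resno), call. = FALSE)
  mean(.cross_dist(A, B))
}

#' Unit normal of a residue's backbone plane
#'
#' The plane passes through the amide nitrogen (N), the alpha carbon (CA)
#' and the carbonyl carbon (C); the normal is the normalized cross product
#' of (N - CA) and (C - CA). Returns `NULL` when a backbone atom is missing
#' or the three points are collinear (degenerate geometry); callers impute
#' the orientation feature for such residues.
#'
#' @param r a [residue_record()]
#' @return unit 3-vector, or `NULL` on degenerate geometry
#' @export
residue_plane_normal <- function(r) {
  idx <- match(c("N", "CA", "C"), r$atom_names)
  if (anyNA(idx)) return(NULL)
  n_at <- r$xyz[idx[1], ]; ca <- r$xyz[idx[2], ]; c_at <- r$xyz[idx[3], ]
  v1 <- n_at - ca
  v2 <- c_at - ca
  cr <- c(v1[2] * v2[3] - v1[3] * v2[2],
          v1[3] * v2[1] - v1[1] * v2[3],
          v1[1] * v2[2] - v1[2] * v2[1])
  nrm <- sqrt(sum(cr^2))
  if (nrm < 1e-8) return(NULL)
  cr / nrm
}

#' Relative orientation of two residues' backbone planes
#'
#' `theta = acos(|n1 . n2|)` in `[0, pi/2]`: plane normals carry a sign
#' ambiguity, so the absolute dot product makes the angle well defined and
#' symmetric (anti-parallel normals give 0).
#'
#' @param r1,r2 [residue_record()] objects
#' @return angle in radians, or `NA_real_` if either backbone is degenerate
#' @export
relative_orientation <- function(r1, r2) {
  n1 <- residue_plane_normal(r1)
  n2 <- residue_plane_normal(r2)
  if (is.null(n1) || is.null(n2)) return(NA_real_)
  d <- abs(sum(n1 * n2))
  acos(min(1, d))
}

#' Mean-distance matrix over all residue pairs of a structure
#' @noRd
.mean_distance_matrix <- function(structure, atom_filter = "heavy") {
  res <- structure$residues
  n <- length(res)
  coords <- lapply(res, .residue_xyz, atom_filter = atom_filter)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <- mean(.cross_dist(coords[[i]], coords[[j]]))
    }
  }
  D
}

#' Build a directed k-nearest-neighbour residue graph
#'
#' Each residue i receives directed edges from its `min(k, N-1)` nearest
#' residues by [mean_residue_distance()] (distance ties broken by lower
#' sequence index). Edge features are `(D, theta)`; residues with degenerate
#' backbone geometry get `theta` imputed with the mean over valid edges and
#' the edge is flagged.
#'
#' @param structure a [protein_structure()] with at least 2 residues
#' @param k neighbour count (>= 1)
#' @param atom_filter atom policy for the distance metric
#' @return a `residue_graph`: list with `n_nodes`, `edges` (m x 2 integer
#'   matrix, columns `src`, `tgt`, 1-based), `edge_features` (m x 2 matrix,
#'   columns `D`, `theta`), `k`, and `degenerate` (logical per edge)
#' @export
build_knn_graph <- function(structure, k, atom_filter = "heavy") {
  .assert(inherits(structure, "protein_structure"), "not a protein_structure")
  n <- length(structure$residues)
  .assert(n >= 2, "k-NN graph needs at least 2 residues")
  .assert(k >= 1, "k must be >= 1")
  D <- .mean_distance_matrix(structure, atom_filter)
  normals <- lapply(structure$residues, residue_plane_normal)
  kk <- min(k, n - 1)
  m <- n * kk
  src <- integer(m); tgt <- integer(m)
  pos <- 0L
  for (i in seq_len(n)) {
    cand <- setdiff(seq_len(n), i)
    ord <- cand[order(D[cand, i], cand)] # ties -> lower seq index
    nb <- ord[seq_len(kk)]
    src[pos + seq_len(kk)] <- nb
    tgt[pos + seq_len(kk)] <- i
    pos <- pos + kk
  }
  dist_f <- D[cbind(src, tgt)]
  theta <- vapply(seq_len(m), function(e) {
    n1 <- normals[[src[e]]]; n2 <- normals[[tgt[e]]]
    if (is.null(n1) || is.null(n2)) return(NA_real_)
    acos(min(1, abs(sum(n1 * n2))))
  }, 0)
  degen <- is.na(theta)
  if (any(degen)) {
    fill <- if (all(degen)) 0 else mean(theta[!degen])
    theta[degen] <- fill
  }
  structure(list(
    n_nodes = n,
    edges = cbind(src = src, tgt = tgt),
    edge_features = cbind(D = dist_f, theta = theta),
    k = k,
    degenerate = degen
  ), class = "residue_graph")
}

#' @export
print.residue_graph <- function(x, ...) {
  cat(sprintf("<residue_graph> %d nodes, %d directed edges (k=%d)\n",
              x$n_nodes, nrow(x$edges), x$k))
  invisible(x)
}

#' Ground-truth interaction labels for a complex
#'
#' Two residues interact when any pair of their non-hydrogen atoms lies
#' within `cutoff` Angstrom (inclusive). Residues with no heavy atoms are
#' labelled non-interacting with a warning.
#'
#' @param ligand,receptor [protein_structure()] objects (bound forms)
#' @param cutoff distance threshold in Angstrom (default 6.0)
#' @return a `pair_labels` object: list with `matrix` (binary N_l x N_r,
#'   ligand rows) and `cutoff`
#' @export
label_interactions <- function(ligand, receptor, cutoff = 6.0) {
  .assert(cutoff > 0, "cutoff must be positive")
  lres <- ligand$residues; rres <- receptor$residues
  .assert(length(lres) >= 1 && length(rres) >= 1, "empty structure")
  rxyz <- lapply(rres, .residue_xyz, atom_filter = "heavy")
  rcnt <- vapply(rxyz, nrow, 0L)
  if (any(rcnt == 0))
    warning("receptor residue(s) with no heavy atoms labelled 0")
  rall <- do.call(rbind, rxyz[rcnt > 0])
  ridx <- rep(which(rcnt > 0), rcnt[rcnt > 0])
  M <- matrix(0L, length(lres), length(rres))
  warned <- FALSE
  for (i in seq_along(lres)) {
    A <- .residue_xyz(lres[[i]], "heavy")
    if (nrow(A) == 0) {
      if (!warned) warning("ligand residue(s) with no heavy atoms labelled 0")
      warned <- TRUE
      next
    }
    d <- .cross_dist(A, rall)
    mind <- vapply(split(seq_along(ridx), ridx),
                   function(cols) min(d[, cols]), 0)
    hit <- as.integer(names(mind))[mind <= cutoff]
    M[i, hit] <- 1L
  }
  structure(list(matrix = M, cutoff = cutoff), class = "pair_labels")
}

#' Interface-region labels derived from pairwise labels
#'
#' A residue belongs to the interface when it interacts with at least one
#' residue of the partner protein.
#'
#' @param labels a `pair_labels` object from [label_interactions()]
#' @return list with binary integer vectors `ligand` (length N_l) and
#'   `receptor` (length N_r)
#' @export
interface_labels <- function(labels) {
  .assert(inherits(labels, "pair_labels"), "not a pair_labels object")
  M <- labels$matrix
  list(ligand = as.integer(rowSums(M) > 0),
       receptor = as.integer(colSums(M) > 0))
}

#' Standardize edge features across a collection of graphs
#'
#' Centers and scales each edge-feature channel by statistics computed over
#' all edges of `graphs` (training-set statistics), or applies precomputed
#' `stats`. A zero-variance channel gets scale 1 with a warning. Applying
#' stored stats is an affine map, so re-standardizing already-standardized
#' graphs with the same stats does not return them unchanged; recompute
#' stats from raw features when needed.
#'
#' @param graphs list of `residue_graph` objects
#' @param stats optional list with `mean` and `sd` (length-2 numeric each)
#' @return list with `graphs` (standardized) and `stats`
#' @export
standardize_edge_features <- function(graphs, stats = NULL) {
  if (inherits(graphs, "residue_graph")) graphs <- list(graphs)
  all_feats <- do.call(rbind, lapply(graphs, function(g) g$edge_features))
  .assert(nrow(all_feats) >= 1, "no edges to standardize")
  if (is.null(stats)) {
    mu <- colMeans(all_feats)
    sc <- apply(all_feats, 2, stats::sd)
    flat <- is.na(sc) | sc < 1e-12
    if (any(flat)) {
      sc[flat] <- 1
      warning("zero-variance edge feature channel; scale set to 1")
    }
    stats <- list(mean = mu, sd = sc)
  }
  graphs <- lapply(graphs, function(g) {
    g$edge_features <- sweep(sweep(g$edge_features, 2, stats$mean, `-`),
                             2, stats$sd, `/`)
    g
  })
  list(graphs = graphs, stats = stats)
}

#' Export a residue graph as a TSV edge list
#'
#' Columns: `src`, `tgt` (1-based node indices), `D`, `theta`.
#'
#' @param graph a `residue_graph`
#' @param path output TSV path
#' @export
write_graph_tsv <- function(graph, path) {
  df <- data.frame(src = graph$edges[, "src"], tgt = graph$edges[, "tgt"],
                   D = graph$edge_features[, 1],
                   theta = graph$edge_features[, 2])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a residue graph from a TSV edge list written by [write_graph_tsv()]
#'
#' @param path TSV path
#' @param n_nodes node count (defaults to the max index present)
#' @param k neighbour count recorded on the graph object
#' @return a `residue_graph`
#' @export
read_graph_tsv <- function(path, n_nodes = NULL, k = NA_integer_) {
  df <- utils::read.table(path, sep = "\t", header = TRUE)
  n <- n_nodes %||% max(df$src, df$tgt)
  structure(list(
    n_nodes = n,
    edges = cbind(src = as.integer(df$src), tgt = as.integer(df$tgt)),
    edge_features = cbind(D = df$D, theta = df$theta),
    k = k, degenerate = rep(FALSE, nrow(df))
  ), class = "residue_graph")
}
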