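# Node features: per-residue sequence embeddings (pluggable provider)
# concatenated with 16 physicochemical descriptors.
#
# Descriptor layout (fixed column order, d_phychem = 16):
#   1-12  sequence-level scale lookups (see inst/extdata/aa_scales_v1.tsv):
#         hydrophilicity, flexibility, accessibility, turn propensity,
#         exposed surface, antigenicity, net charge index, polarizability,
#         hydrophobicity on two scales (H11a/H12a), polarity on two scales
#         (P11a/P12a)
#   13    side-chain volume (table lookup)
#   14-16 structure-derived: SASA, relative SASA, residue depth

.PHYCHEM_COLS <- c(
  "hydrophilicity", "flexibility", "accessibility", "turn_propensity",
  "exposed_surface", "antigenicity", "net_charge_index", "polarizability",
  "hydrophobicity_h11a", "hydrophobicity_h12a",
  "polarity_p11a", "polarity_p12a",
  "side_chain_volume", "sasa", "rel_sasa", "residue_depth"
)

.load_scales <- function() {
  if (!is.null(.pairsite_env$scales)) return(.pairsite_env$scales)
  path <- system.file("extdata", "aa_scales_v1.tsv", package = "pairsite")
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           comment.char = "#", stringsAsFactors = FALSE)
  rownames(tab) <- tab$aa
  tab$aa <- NULL
  sasa_path <- system.file("extdata", "max_sasa_v1.tsv", package = "pairsite")
  ms <- utils::read.table(sasa_path, sep = "\t", header = TRUE,
                          comment.char = "#", stringsAsFactors = FALSE)
  max_sasa <- stats::setNames(ms$max_sasa, ms$aa)
  scales <- list(table = as.matrix(tab), max_sasa = max_sasa,
                 neutral = colMeans(as.matrix(tab)),
                 neutral_max_sasa = mean(max_sasa))
  .pairsite_env$scales <- scales
  scales
}

# --- embedding providers ------------------------------------------------

#' Construct an embedding provider
#'
#' An embedding provider deterministically maps an amino-acid sequence to an
#' N x dim matrix of per-residue embedding vectors. The shipped providers
#' are [file_embedding_provider()] (precomputed matrices, e.g. from an
#' external 1024-dimensional protein language model) and the test surrogate
#' [surrogate_embedder()].
#'
#' @param name identifier string
#' @param dim embedding dimensionality
#' @param fun function `(sequence, id)` returning an N x dim numeric matrix
#' @return an `embedding_provider`
#' @export
embedding_provider <- function(name, dim, fun) {
  .assert(dim >= 1, "embedding dim must be >= 1")
  structure(list(name = name, dim = as.integer(dim), fun = fun),
            class = "embedding_provider")
}

#' Provider that loads precomputed embedding matrices from TSV files
#'
#' Embeddings produced offline (for instance by a 1024-dimensional protein
#' language model) are read from `<dir>/<id>.tsv`, one residue per row, no
#' header. The matrix must have `dim` columns and one row per residue of the
#' query sequence.
#'
#' @param dir directory holding `<id>.tsv` matrices
#' @param dim expected embedding dimensionality (1024 for the usual
#'   transformer embedder)
#' @return an `embedding_provider`
#' @export
file_embedding_provider <- function(dir, dim = 1024L) {
  force(dir); force(dim)
  embedding_provider(
    name = sprintf("file:%s", dir), dim = dim,
    fun = function(sequence, id) {
      .assert(!is.null(id), "file embedding provider requires a structure id")
      path <- file.path(dir, paste0(id, ".tsv"))
      .assert(file.exists(path),
              sprintf("no precomputed embedding for id '%s' at %s", id, path))
      m <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
      .assert(ncol(m) == dim,
              sprintf("embedding for '%s' has %d columns, expected %d",
                      id, ncol(m), dim))
      .assert(nrow(m) == nchar(sequence),
              sprintf("embedding for '%s' has %d rows, sequence has %d",
                      id, nrow(m), nchar(sequence)))
      unname(m)
    }
  )
}

#' Embed an amino-acid sequence
#'
#' @param sequence one-letter amino-acid string (non-empty)
#' @param provider an [embedding_provider()]
#' @param id optional structure id (required by file-backed providers)
#' @return N x dim numeric matrix, row i the embedding of residue i
#' @export
embed_sequence <- function(sequence, provider, id = NULL) {
  .assert(inherits(provider, "embedding_provider"), "not an embedding_provider")
  .assert(is.character(sequence) && nchar(sequence) >= 1,
          "sequence must be a non-empty string")
  m <- tryCatch(provider$fun(sequence, id),
                error = function(e) stop(sprintf(
                  "embedding provider '%s' failed: %s",
                  provider$name, conditionMessage(e)), call. = FALSE))
  .assert(is.matrix(m) && nrow(m) == nchar(sequence) &&
            ncol(m) == provider$dim,
          sprintf("provider '%s' returned a malformed matrix", provider$name))
  m
}

# --- solvent-accessible surface area ------------------------------------

.VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80,
                SE = 1.90)

# near-uniform points on the unit sphere (golden-spiral lattice)
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area of every atom of a structure
#'
#' Rolling-ball (Shrake-Rupley) SASA: each atom is sampled with a
#' golden-spiral point lattice at radius `r_vdw + probe`; a point is
#' accessible if it lies outside every neighbouring atom's probe-expanded
#' sphere. Hydrogens are ignored.
#'
#' @param structure a [protein_structure()]
#' @param probe probe radius in Angstrom (water, 1.4)
#' @param n_points sphere sample points per atom
#' @return list with `atom_sasa` (per heavy atom, A^2), `atom_residue`
#'   (1-based residue index per heavy atom), and `xyz` (heavy-atom coords)
#' @export
shrake_rupley_sasa <- function(structure, probe = 1.4, n_points = 92L) {
  res <- structure$residues
  xyz_l <- lapply(res, .residue_xyz, atom_filter = "heavy")
  elem_l <- lapply(res, function(r) r$elements[!r$is_hydrogen])
  cnt <- vapply(xyz_l, nrow, 0L)
  .assert(sum(cnt) >= 1, "structure has no heavy atoms")
  xyz <- do.call(rbind, xyz_l)
  elem <- unlist(elem_l)
  radii <- .VDW_RADII[elem]
  radii[is.na(radii)] <- 1.70
  rp <- radii + probe
  n <- nrow(xyz)
  sp <- .sphere_points(n_points)
  sasa <- numeric(n)
  d2 <- outer(rowSums(xyz^2), rowSums(xyz^2), `+`) - 2 * tcrossprod(xyz)
  for (a in seq_len(n)) {
    nb <- which(d2[a, ] < (rp[a] + rp)^2 & seq_len(n) != a)
    pts <- sweep(sp * rp[a], 2, xyz[a, ], `+`)
    if (length(nb) > 0) {
      acc <- rep(TRUE, n_points)
      for (b in nb) {
        db2 <- rowSums(sweep(pts, 2, xyz[b, ], `-`)^2)
        acc <- acc & (db2 > rp[b]^2)
        if (!any(acc)) break
      }
      frac <- mean(acc)
    } else frac <- 1
    sasa[a] <- frac * 4 * pi * rp[a]^2
  }
  list(atom_sasa = sasa,
       atom_residue = factor(rep(seq_along(res), cnt),
                             levels = seq_along(res)),
       xyz = xyz)
}

#' Per-residue physicochemical descriptor matrix
#'
#' Assembles the 16 descriptors per residue: 12 sequence-level scale lookups
#' plus side-chain volume from the shipped scale table, and three
#' structure-derived values (SASA, relative SASA = SASA divided by a
#' per-residue-type reference maximum, and residue depth = mean distance of
#' the residue's atoms to the nearest solvent-exposed atom). Unknown
#' residues ("X") take each scale's neutral value (mean over the 20 standard
#' amino acids) with a warning.
#'
#' @param structure a [protein_structure()]
#' @param probe SASA probe radius in Angstrom
#' @param n_points SASA sphere sample points per atom
#' @param exposed_threshold atom SASA (A^2) above which an atom counts as
#'   solvent-exposed for the residue-depth calculation
#' @return N x 16 numeric matrix with columns as documented in
#'   `.PHYCHEM_COLS`
#' @export
physicochemical_features <- function(structure, probe = 1.4, n_points = 92L,
                                     exposed_threshold = 2.0) {
  .assert(inherits(structure, "protein_structure"), "not a protein_structure")
  sc <- .load_scales()
  res <- structure$residues
  n <- length(res)
  aas <- vapply(res, function(r) r$aa, "")
  unknown <- !(aas %in% rownames(sc$table))
  if (any(unknown))
    warning(sprintf("%d residue(s) with unknown type use neutral scale values",
                    sum(unknown)))
  seq_feats <- matrix(0, n, ncol(sc$table),
                      dimnames = list(NULL, colnames(sc$table)))
  seq_feats[!unknown, ] <- sc$table[aas[!unknown], , drop = FALSE]
  if (any(unknown))
    seq_feats[unknown, ] <- matrix(sc$neutral, sum(unknown),
                                   ncol(sc$table), byrow = TRUE)

  sasa <- shrake_rupley_sasa(structure, probe = probe, n_points = n_points)
  res_sasa <- as.numeric(tapply(sasa$atom_sasa, sasa$atom_residue, sum))
  res_sasa[is.na(res_sasa)] <- 0 # residues with no heavy atoms
  max_ref <- ifelse(unknown, sc$neutral_max_sasa, sc$max_sasa[aas])
  rel_sasa <- res_sasa / max_ref

  exposed <- sasa$atom_sasa > exposed_threshold
  depth <- numeric(n)
  if (any(exposed)) {
    exp_xyz <- sasa$xyz[exposed, , drop = FALSE]
    dmin <- apply(.cross_dist(sasa$xyz, exp_xyz), 1, min)
    depth <- as.numeric(tapply(dmin, sasa$atom_residue, mean))
    depth[is.na(depth)] <- 0
  }

  out <- cbind(seq_feats[, .PHYCHEM_COLS[1:12], drop = FALSE],
               side_chain_volume = seq_feats[, "side_chain_volume"],
               sasa = res_sasa, rel_sasa = rel_sasa, residue_depth = depth)
  dimnames(out) <- list(NULL, .PHYCHEM_COLS)
  out
}

#' Concatenate embedding and physicochemical features into node features
#'
#' Embedding columns come first; the node dimensionality is the embedding
#' dimensionality plus 16 (1040 with a 1024-dimensional embedder).
#'
#' @param embedding N x dim embedding matrix
#' @param phychem N x 16 physicochemical matrix
#' @return N x (dim + 16) node-feature matrix
#' @export
assemble_node_features <- function(embedding, phychem) {
  .assert(is.matrix(embedding) && is.matrix(phychem), "matrix inputs required")
  .assert(nrow(embedding) == nrow(phychem),
          sprintf("row mismatch: embedding %d vs physicochemical %d",
                  nrow(embedding), nrow(phychem)))
  .assert(ncol(phychem) == 16,
          sprintf("physicochemical matrix must have 16 columns, got %d",
                  ncol(phychem)))
  out <- cbind(embedding, phychem)
  dimnames(out) <- NULL
  out
}

#' Standardize node-feature matrices across a collection
#'
#' Centers and scales each channel by training-set statistics (or applies
#' precomputed `stats`). Zero-variance channels get scale 1.
#'
#' @param features list of N x d matrices (or a single matrix)
#' @param stats optional list with `mean` and `sd`
#' @return list with `features` (standardized, same shape) and `stats`
#' @export
standardize_node_features <- function(features, stats = NULL) {
  single <- is.matrix(features)
  if (single) features <- list(features)
  allf <- do.call(rbind, features)
  if (is.null(stats)) {
    mu <- colMeans(allf)
    scl <- apply(allf, 2, stats::sd)
    scl[is.na(scl) | scl < 1e-12] <- 1
    stats <- list(mean = mu, sd = scl)
  }
  features <- lapply(features, function(m)
    sweep(sweep(m, 2, stats$mean, `-`), 2, stats$sd, `/`))
  list(features = if (single) features[[1]] else features, stats = stats)
}
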