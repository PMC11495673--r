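# Deterministic synthetic two-chain complexes with planted interfaces.
#
# Each protein is an idealized alpha-helical backbone (N, CA, C, O per
# residue, non-collinear by construction). The two helices are separated by
# a wide gap; a chosen subset of residues on each side is paired one-to-one
# and given a side-chain pseudo-atom reaching into per-pair contact sites in
# the gap, so exactly the planted residue pairs fall within the interaction
# cutoff and every other cross-pair is at least `separation` apart. Planted
# interface residues are drawn from an aromatic/hydrophobic "sticky" residue
# pool so a sequence-level surrogate embedder can carry the planted signal;
# everything is deterministic per seed.

.STICKY_POOL <- c("W", "F", "Y", "M")
.NONSTICKY_POOL <- setdiff(unname(.AA321), .STICKY_POOL)

#' Specification of a synthetic complex
#'
#' @param n_ligand,n_receptor residue counts (each >= interface_size)
#' @param interface_size planted interacting residues per side (>= 1)
#' @param contact_distance Angstrom between planted partner pseudo-atoms
#'   (must be below `cutoff`)
#' @param separation minimum Angstrom between all non-planted cross-pairs
#'   (must exceed `cutoff`)
#' @param jitter Gaussian coordinate noise scale in Angstrom
#' @param seed integer seed
#' @param cutoff interaction cutoff the labels are planted against
#' @return a `synthetic_spec`
#' @export
synthetic_spec <- function(n_ligand = 12L, n_receptor = 15L,
                           interface_size = 3L, contact_distance = 4.5,
                           separation = 20, jitter = 0.2, seed = 1L,
                           cutoff = 6.0) {
  .assert(interface_size >= 1 && n_ligand >= interface_size &&
            n_receptor >= interface_size,
          "counts must satisfy n >= interface_size >= 1")
  .assert(contact_distance < cutoff && cutoff < separation,
          "need contact_distance < cutoff < separation")
  .assert(jitter >= 0, "jitter must be non-negative")
  if (contact_distance + 4 * jitter >= cutoff ||
      separation - 4 * jitter <= cutoff)
    stop("jitter too large for the contact/separation margins", call. = FALSE)
  structure(list(n_ligand = as.integer(n_ligand),
                 n_receptor = as.integer(n_receptor),
                 interface_size = as.integer(interface_size),
                 contact_distance = contact_distance,
                 separation = separation, jitter = jitter,
                 seed = as.integer(seed), cutoff = cutoff),
            class = "synthetic_spec")
}

# idealized helical backbone: residue t gets CA on a helix plus N/C/O at
# fixed non-collinear local offsets
.helix_backbone <- function(n, origin = c(0, 0, 0)) {
  radius <- 2.3; rise <- 1.5; turn <- 100 * pi / 180
  t <- seq_len(n) - 1
  ang <- t * turn
  u <- cbind(cos(ang), sin(ang), 0)         # radial
  v <- cbind(-sin(ang), cos(ang), 0)        # tangential
  ez <- matrix(rep(c(0, 0, 1), each = n), n, 3)
  ca <- cbind(radius * cos(ang), radius * sin(ang), rise * t)
  ca <- sweep(ca, 2, origin, `+`)
  w1 <- 0.35 * u + 0.75 * v - 0.55 * ez
  w1 <- w1 / sqrt(rowSums(w1^2))
  w2 <- 0.35 * u - 0.75 * v + 0.55 * ez
  w2 <- w2 / sqrt(rowSums(w2^2))
  list(N = ca + 1.46 * w1, CA = ca, C = ca + 1.53 * w2,
       O = ca + 1.53 * w2 + 1.23 * u)
}

.build_chain <- function(n, origin, chain_id, aas, pseudo, jitter) {
  bb <- .helix_backbone(n, origin)
  residues <- vector("list", n)
  for (t in seq_len(n)) {
    xyz <- rbind(bb$N[t, ], bb$CA[t, ], bb$C[t, ], bb$O[t, ])
    names_ <- c("N", "CA", "C", "O")
    elems <- c("N", "C", "C", "O")
    if (!is.null(pseudo[[t]])) {
      xyz <- rbind(xyz, pseudo[[t]])
      names_ <- c(names_, "CB")
      elems <- c(elems, "C")
    }
    if (jitter > 0) xyz <- xyz + matrix(rnorm(length(xyz), sd = jitter),
                                        nrow(xyz), 3)
    residues[[t]] <- residue_record(aas[t], chain_id, t - 1L,
                                    names_, elems, xyz, resno = t)
  }
  residues
}

#' Generate a synthetic two-chain complex with a planted interface
#'
#' Returns the two structures and the analytically expected pair-label
#' matrix: entry (i, j) is 1 exactly for the planted one-to-one pairs.
#' Recomputing labels geometrically with [label_interactions()] at
#' `spec$cutoff` reproduces this matrix (a tested invariant).
#'
#' @param spec a [synthetic_spec()]
#' @return list with `ligand`, `receptor` ([protein_structure()]s),
#'   `labels` (a `pair_labels`), and `interface` (planted index lists)
#' @export
make_complex <- function(spec) {
  .assert(inherits(spec, "synthetic_spec"), "not a synthetic_spec")
  .with_seed(spec$seed, {
    nl <- spec$n_ligand; nr <- spec$n_receptor; ni <- spec$interface_size
    idx_l <- sort(sample(nl, ni))
    idx_r <- sort(sample(nr, ni))
    aas_l <- sample(.NONSTICKY_POOL, nl, replace = TRUE)
    aas_r <- sample(.NONSTICKY_POOL, nr, replace = TRUE)
    aas_l[idx_l] <- sample(.STICKY_POOL, ni, replace = TRUE)
    aas_r[idx_r] <- sample(.STICKY_POOL, ni, replace = TRUE)

    helix_extent <- 2.3 + 3 # radius + local offsets margin
    gap <- 2 * spec$separation + 2 * helix_extent + spec$contact_distance
    site_spacing <- spec$separation + spec$contact_distance + 2
    pseudo_l <- vector("list", nl); pseudo_r <- vector("list", nr)
    for (t in seq_len(ni)) {
      site <- c(gap / 2, 0, t * site_spacing)
      pseudo_l[[idx_l[t]]] <- site - c(spec$contact_distance / 2, 0, 0)
      pseudo_r[[idx_r[t]]] <- site + c(spec$contact_distance / 2, 0, 0)
    }
    lig <- protein_structure(
      .build_chain(nl, c(0, 0, 0), "A", aas_l, pseudo_l, spec$jitter),
      source_id = sprintf("synthL%d", spec$seed))
    rec <- protein_structure(
      .build_chain(nr, c(gap, 0, 0), "B", aas_r, pseudo_r, spec$jitter),
      source_id = sprintf("synthR%d", spec$seed))
    M <- matrix(0L, nl, nr)
    M[cbind(idx_l, idx_r)] <- 1L
    labels <- structure(list(matrix = M, cutoff = spec$cutoff),
                        class = "pair_labels")
    list(ligand = lig, receptor = rec, labels = labels,
         interface = list(ligand = idx_l, receptor = idx_r))
  })
}

#' Write a synthetic complex as PDB + expected-label TSV fixtures
#'
#' @param cx output of [make_complex()]
#' @param dir output directory
#' @param prefix file-name prefix
#' @return invisibly, the written paths
#' @export
write_complex_fixture <- function(cx, dir, prefix = "complex") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pl <- file.path(dir, paste0(prefix, "_ligand.pdb"))
  pr <- file.path(dir, paste0(prefix, "_receptor.pdb"))
  pt <- file.path(dir, paste0(prefix, "_labels.tsv"))
  write_pdb(cx$ligand, pl)
  write_pdb(cx$receptor, pr)
  utils::write.table(cx$labels$matrix, pt, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(c(pl, pr, pt))
}

# deterministic 31-bit string hash
.hash_string <- function(s, seed = 0L) {
  h <- as.numeric(seed) + 17
  for (v in utf8ToInt(s)) h <- (h * 31 + v) %% 2147483587
  as.integer(h)
}

#' Deterministic surrogate embedding provider
#'
#' A test stand-in for an external protein language model: each residue's
#' vector comes from a seeded hash of its identity and a +/-2 sequence
#' window, so identical sequences give bitwise-identical matrices. When
#' `spec_aware = TRUE`, the first channel carries a learnable signal that
#' correlates with planted-interface membership in [make_complex()] output
#' (interface residues are drawn from the aromatic/hydrophobic pool W/F/Y/M,
#' which this channel indicates). This is a test-only device standing in for
#' the information a real embedder extracts from sequence context.
#'
#' @param spec_aware plant the interface-correlated channel
#' @param dim embedding dimensionality (>= 2)
#' @param seed integer seed
#' @param signal_strength magnitude of the spec-aware channel
#' @return an [embedding_provider()]
#' @export
surrogate_embedder <- function(spec_aware = FALSE, dim = 8L, seed = 1L,
                               signal_strength = 2.0) {
  .assert(dim >= 2, "surrogate embedder needs dim >= 2")
  force(spec_aware); force(seed); force(signal_strength)
  embedding_provider(
    name = sprintf("surrogate(dim=%d,seed=%d%s)", dim, seed,
                   if (spec_aware) ",spec_aware" else ""),
    dim = dim,
    fun = function(sequence, id) {
      aas <- strsplit(sequence, "")[[1]]
      n <- length(aas)
      out <- matrix(0, n, dim)
      for (i in seq_len(n)) {
        win <- paste(aas[max(1, i - 2):min(n, i + 2)], collapse = "")
        h <- .hash_string(paste0(aas[i], "|", win), seed)
        out[i, ] <- .with_seed(h, rnorm(dim, sd = 0.5))
        if (spec_aware) {
          out[i, 1] <- signal_strength *
            (if (aas[i] %in% .STICKY_POOL) 1 else -1) + 0.2 * out[i, 1]
        }
      }
      out
    }
  )
}

#' Featurize a two-structure complex into a model-ready sample
#'
#' Builds the k-NN residue graphs, embeds the sequences with `provider`,
#' optionally appends the 16 physicochemical descriptors, and attaches
#' interaction labels (computed geometrically unless supplied).
#'
#' @param ligand,receptor [protein_structure()] objects
#' @param provider an [embedding_provider()]
#' @param k neighbour count for the graphs
#' @param cutoff label cutoff in Angstrom
#' @param labels optional precomputed `pair_labels`
#' @param use_phychem include the physicochemical block
#' @param complex_id identifier
#' @return a `complex_sample`
#' @export
make_complex_sample <- function(ligand, receptor, provider, k = 10L,
                                cutoff = 6.0, labels = NULL,
                                use_phychem = TRUE,
                                complex_id = "complex") {
  g_l <- build_knn_graph(ligand, k)
  g_r <- build_knn_graph(receptor, k)
  e_l <- embed_sequence(extract_sequence(ligand), provider, ligand$source_id)
  e_r <- embed_sequence(extract_sequence(receptor), provider,
                        receptor$source_id)
  if (use_phychem) {
    f_l <- assemble_node_features(e_l, physicochemical_features(ligand))
    f_r <- assemble_node_features(e_r, physicochemical_features(receptor))
  } else {
    f_l <- e_l; f_r <- e_r
  }
  labels <- labels %||% label_interactions(ligand, receptor, cutoff)
  structure(list(
    ligand = list(structure = ligand, graph = g_l, features = f_l),
    receptor = list(structure = receptor, graph = g_r, features = f_r),
    pair_labels = labels,
    iface = interface_labels(labels),
    complex_id = complex_id
  ), class = "complex_sample")
}

#' Generate a synthetic train/validation/test dataset
#'
#' Per-complex seeds derive from the master seed, so the same master seed
#' reproduces identical splits. Downsampling never touches these samples:
#' validation and test keep the constructed class ratio.
#'
#' @param n_complexes total complexes (>= 3)
#' @param spec a [synthetic_spec()] template (its seed is overridden per
#'   complex)
#' @param seed master seed
#' @param split fractions for train/validation/test (sums to 1)
#' @param provider embedding provider (default: spec-aware surrogate)
#' @param k neighbour count for the graphs
#' @param use_phychem include physicochemical node features
#' @return list with `train`, `val`, `test` lists of `complex_sample`s
#' @export
make_dataset <- function(n_complexes, spec = synthetic_spec(), seed = 1L,
                         split = c(0.6, 0.2, 0.2),
                         provider = surrogate_embedder(spec_aware = TRUE,
                                                       seed = seed),
                         k = 4L, use_phychem = TRUE) {
  .assert(n_complexes >= 3, "need at least 3 complexes")
  .assert(abs(sum(split) - 1) < 1e-8 && length(split) == 3,
          "split must be 3 fractions summing to 1")
  samples <- vector("list", n_complexes)
  for (ci in seq_len(n_complexes)) {
    sp <- spec
    sp$seed <- .derive_seed(seed, ci)
    cx <- make_complex(sp)
    samples[[ci]] <- make_complex_sample(
      cx$ligand, cx$receptor, provider, k = k, cutoff = spec$cutoff,
      labels = cx$labels, use_phychem = use_phychem,
      complex_id = sprintf("synth_%03d", ci))
  }
  n_tr <- round(split[1] * n_complexes)
  n_va <- round(split[2] * n_complexes)
  n_te <- n_complexes - n_tr - n_va
  .assert(n_te >= 1 && n_tr >= 1, "split leaves an empty partition")
  list(train = samples[seq_len(n_tr)],
       val = samples[n_tr + seq_len(n_va)],
       test = samples[n_tr + n_va + seq_len(n_te)])
}
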