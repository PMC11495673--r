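# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (double loops, full enumeration) so they cannot share a
# defect with the vectorized implementations they check.

# single-atom residue at a point
point_residue <- function(x, y = 0, z = 0, aa = "G", chain = "A", idx = 0,
                          name = "CA", element = "C") {
  residue_record(aa, chain, idx, name, element, matrix(c(x, y, z), 1, 3))
}

# residue from an explicit atom table
atoms_residue <- function(xyz, names_, elements, aa = "A", chain = "A",
                          idx = 0) {
  residue_record(aa, chain, idx, names_, elements, xyz)
}

# brute-force mean inter-atomic distance over all atom pairs
oracle_mean_distance <- function(r1, r2) {
  A <- r1$xyz[!r1$is_hydrogen, , drop = FALSE]
  B <- r2$xyz[!r2$is_hydrogen, , drop = FALSE]
  tot <- 0
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B)))
    tot <- tot + sqrt(sum((A[i, ] - B[j, ])^2))
  tot / (nrow(A) * nrow(B))
}

# brute-force interaction labels: double loop over residues and atoms
oracle_labels <- function(lig, rec, cutoff = 6.0) {
  M <- matrix(0L, length(lig$residues), length(rec$residues))
  for (i in seq_along(lig$residues)) {
    A <- lig$residues[[i]]$xyz[!lig$residues[[i]]$is_hydrogen, , drop = FALSE]
    for (j in seq_along(rec$residues)) {
      B <- rec$residues[[j]]$xyz[!rec$residues[[j]]$is_hydrogen, ,
                                 drop = FALSE]
      hit <- FALSE
      for (a in seq_len(nrow(A))) {
        for (b in seq_len(nrow(B))) {
          if (sqrt(sum((A[a, ] - B[b, ])^2)) <= cutoff) { hit <- TRUE; break }
        }
        if (hit) break
      }
      M[i, j] <- as.integer(hit)
    }
  }
  M
}

# brute-force k-NN neighbour sets by mean distance with seq-index tie-break
oracle_knn_sets <- function(structure, k) {
  n <- length(structure$residues)
  lapply(seq_len(n), function(i) {
    d <- vapply(seq_len(n), function(j) {
      if (j == i) Inf else oracle_mean_distance(structure$residues[[j]],
                                                structure$residues[[i]])
    }, 0)
    ord <- order(d, seq_len(n))
    sort(ord[seq_len(min(k, n - 1))])
  })
}

# pairwise-comparison AUROC (Mann-Whitney, ties one half)
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# threshold-enumeration AUPRC (step-wise, no interpolation)
oracle_auprc <- function(scores, labels) {
  P <- sum(labels == 1)
  thr <- sort(unique(scores), decreasing = TRUE)
  area <- 0; prev_rec <- 0
  for (t in thr) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1)
    prec <- tp / sum(pred)
    rec <- tp / P
    area <- area + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  area
}

# full-sort precision@N with column-major index tie-break
oracle_prec_at_n <- function(scores, labels, N) {
  ord <- order(-scores, seq_along(scores))
  mean(labels[ord[seq_len(N)]])
}

# dense node-only graph attention layer (no edge features), one layer:
# logit(j->i) = lrelu(a_t.Wh_i + a_s.Wh_j), softmax over in-neighbours,
# out_i = elu(sum alpha Wh_j) + h_i
oracle_node_gat <- function(H, edges, Wg, a_t, a_s, slope = 0.2) {
  lrelu <- function(x) ifelse(x > 0, x, slope * x)
  elu <- function(x) ifelse(x > 0, x, exp(x) - 1)
  Wh <- H %*% Wg
  n <- nrow(H)
  out <- H
  for (i in seq_len(n)) {
    nb <- edges[edges[, 2] == i, 1]
    if (length(nb) == 0) { out[i, ] <- elu(Wh[i, ]) + H[i, ]; next }
    z <- vapply(nb, function(j)
      lrelu(sum(a_t * Wh[i, ]) + sum(a_s * Wh[j, ])), 0)
    al <- exp(z - max(z)); al <- al / sum(al)
    msg <- colSums(al * Wh[nb, , drop = FALSE])
    out[i, ] <- elu(msg) + H[i, ]
  }
  out
}

# small ready-made complex sample for model tests
tiny_sample <- function(seed = 11, n_l = 8, n_r = 9, dim = 4, k = 3) {
  cx <- make_complex(synthetic_spec(n_ligand = n_l, n_receptor = n_r,
                                    interface_size = 2, seed = seed))
  prov <- surrogate_embedder(spec_aware = TRUE, dim = dim, seed = seed)
  make_complex_sample(cx$ligand, cx$receptor, prov, k = k, labels = cx$labels,
                      complex_id = sprintf("tiny%d", seed))
}

swap_sample <- function(s) {
  structure(list(ligand = s$receptor, receptor = s$ligand,
                 pair_labels = structure(list(matrix = t(s$pair_labels$matrix),
                                              cutoff = s$pair_labels$cutoff),
                                         class = "pair_labels"),
                 iface = list(ligand = s$iface$receptor,
                              receptor = s$iface$ligand),
                 complex_id = s$complex_id), class = "complex_sample")
}
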