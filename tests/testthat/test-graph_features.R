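# geometric features, k-NN graphs, interaction labels

test_that("mean residue distance matches hand-computed and brute-force values", {
  r1 <- point_residue(0); r2 <- point_residue(3)
  expect_equal(mean_residue_distance(r1, r2), 3.0)
  expect_equal(mean_residue_distance(r1, r1), 0.0)
  ra <- atoms_residue(rbind(c(0, 0, 0), c(0, 0, 2)), c("CA", "CB"),
                      c("C", "C"))
  rb <- atoms_residue(rbind(c(4, 0, 0), c(4, 0, 2)), c("CA", "CB"),
                      c("C", "C"))
  expect_equal(mean_residue_distance(ra, rb), (4 + sqrt(20) + sqrt(20) + 4) / 4)
  expect_equal(mean_residue_distance(ra, rb), oracle_mean_distance(ra, rb))
  # symmetry
  expect_equal(mean_residue_distance(ra, rb), mean_residue_distance(rb, ra))
})

test_that("hydrogens are excluded by the default atom filter", {
  rh <- atoms_residue(rbind(c(0, 0, 0), c(100, 0, 0)), c("CA", "H"),
                      c("C", "H"))
  r2 <- point_residue(3)
  expect_equal(mean_residue_distance(rh, r2), 3.0)
  ronly_h <- atoms_residue(matrix(c(0, 0, 0), 1, 3), "H", "H")
  expect_error(mean_residue_distance(ronly_h, r2), "no atoms pass filter")
})

test_that("backbone plane normals are unit vectors with the right direction", {
  r <- atoms_residue(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)),
                     c("N", "CA", "C"), c("N", "C", "C"))
  n <- residue_plane_normal(r)
  expect_equal(abs(n), c(0, 0, 1))
  expect_equal(sqrt(sum(n^2)), 1)
  # collinear backbone -> degenerate signal
  rc <- atoms_residue(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
                      c("N", "CA", "C"), c("N", "C", "C"))
  expect_null(residue_plane_normal(rc))
  # missing backbone atom -> degenerate signal
  expect_null(residue_plane_normal(point_residue(0)))
  # any valid synthetic backbone has a unit normal
  cx <- make_complex(synthetic_spec(seed = 2))
  for (r in cx$ligand$residues)
    expect_equal(sqrt(sum(residue_plane_normal(r)^2)), 1, tolerance = 1e-12)
})

test_that("relative orientation uses the absolute-angle convention", {
  mk <- function(n_vec) {
    # residue whose plane normal is n_vec: N-CA and C-CA orthogonal to n
    b1 <- c(n_vec[2] - n_vec[3], n_vec[3] - n_vec[1], n_vec[1] - n_vec[2])
    if (sum(b1^2) < 1e-8) b1 <- c(1, -1, 0)
    b1 <- b1 / sqrt(sum(b1^2))
    b2 <- c(n_vec[2] * b1[3] - n_vec[3] * b1[2],
            n_vec[3] * b1[1] - n_vec[1] * b1[3],
            n_vec[1] * b1[2] - n_vec[2] * b1[1])
    atoms_residue(rbind(b1, c(0, 0, 0), b2), c("N", "CA", "C"),
                  c("N", "C", "C"))
  }
  expect_equal(relative_orientation(mk(c(0, 0, 1)), mk(c(0, 0, 1))), 0)
  expect_equal(relative_orientation(mk(c(0, 0, 1)), mk(c(1, 0, 0))), pi / 2)
  # anti-parallel normals give 0 under the |dot| convention
  expect_equal(relative_orientation(mk(c(0, 0, 1)), mk(c(0, 0, -1))), 0,
               tolerance = 1e-12)
  # symmetry and range on synthetic residues
  cx <- make_complex(synthetic_spec(seed = 9))
  res <- cx$ligand$residues
  for (i in 1:4) {
    th <- relative_orientation(res[[i]], res[[i + 1]])
    expect_identical(th, relative_orientation(res[[i + 1]], res[[i]]))
    expect_gte(th, 0); expect_lte(th, pi / 2 + 1e-12)
  }
})

test_that("k-NN graphs match brute-force neighbour enumeration", {
  # 4 single-atom residues on a line: node at x=0 receives x=1 and x=2
  st <- protein_structure(lapply(0:3, function(x) point_residue(x, idx = x)))
  g <- build_knn_graph(st, k = 2)
  nb1 <- sort(g$edges[g$edges[, "tgt"] == 1, "src"])
  expect_identical(nb1, c(2L, 3L))
  expect_true(all(g$edges[, "src"] != g$edges[, "tgt"]))
  # out-degree rule: every node receives min(k, N-1) edges
  expect_identical(as.integer(table(g$edges[, "tgt"])), rep(2L, 4))
  # k >= N-1 -> complete digraph
  gc <- build_knn_graph(st, k = 10)
  expect_identical(nrow(gc$edges), 4L * 3L)
  # brute-force neighbour sets on a jittered synthetic protein
  cx <- make_complex(synthetic_spec(seed = 13))
  for (k in c(1, 3)) {
    g <- build_knn_graph(cx$ligand, k)
    sets <- oracle_knn_sets(cx$ligand, k)
    for (i in seq_along(sets))
      expect_identical(unname(sort(g$edges[g$edges[, "tgt"] == i, "src"])),
                       sets[[i]])
  }
  expect_error(build_knn_graph(protein_structure(list(point_residue(0))), 1),
               "at least 2")
})

test_that("k-NN distance ties break toward the lower sequence index", {
  st <- protein_structure(list(point_residue(0, idx = 0),
                               point_residue(1, idx = 1),
                               point_residue(-1, idx = 2)))
  g <- build_knn_graph(st, k = 1)
  expect_identical(unname(g$edges[g$edges[, "tgt"] == 1, "src"]), 2L)
})

test_that("edge features are the (D, theta) pair with theta in [0, pi/2]", {
  cx <- make_complex(synthetic_spec(seed = 4))
  g <- build_knn_graph(cx$receptor, k = 3)
  expect_identical(colnames(g$edge_features), c("D", "theta"))
  expect_identical(ncol(g$edge_features), 2L)
  expect_true(all(is.finite(g$edge_features)))
  expect_true(all(g$edge_features[, "D"] > 0))
  expect_true(all(g$edge_features[, "theta"] >= 0 &
                    g$edge_features[, "theta"] <= pi / 2 + 1e-12))
  # D column equals the brute-force mean distance per edge
  for (e in sample(nrow(g$edges), 5)) {
    expect_equal(as.numeric(g$edge_features[e, "D"]),
                 oracle_mean_distance(
                   cx$receptor$residues[[g$edges[e, "src"]]],
                   cx$receptor$residues[[g$edges[e, "tgt"]]]),
                 tolerance = 1e-12)
  }
})

test_that("interaction labels flip at the cutoff and ignore hydrogens", {
  near <- protein_structure(list(point_residue(0)))
  for (d in c(5.9, 6.0, 6.1)) {
    far <- protein_structure(list(point_residue(d)))
    lab <- label_interactions(near, far, 6.0)
    expect_identical(lab$matrix[1, 1], as.integer(d <= 6.0))
  }
  # only hydrogens within the cutoff, nearest heavy atom at 8 A -> 0
  hres <- atoms_residue(rbind(c(2, 0, 0), c(8, 0, 0)), c("H", "CA"),
                        c("H", "C"))
  lab <- label_interactions(near, protein_structure(list(hres)), 6.0)
  expect_identical(lab$matrix[1, 1], 0L)
})

test_that("labels agree with the brute-force double loop on fixtures", {
  for (seed in c(1, 8)) {
    cx <- make_complex(synthetic_spec(seed = seed, jitter = 0.15))
    lab <- label_interactions(cx$ligand, cx$receptor, 6.0)
    expect_identical(lab$matrix, oracle_labels(cx$ligand, cx$receptor, 6.0))
    expect_identical(lab$matrix, cx$labels$matrix)
  }
})

test_that("interface labels are the row-wise and column-wise any", {
  M <- matrix(0L, 4, 7)
  lab <- structure(list(matrix = M, cutoff = 6), class = "pair_labels")
  iv <- interface_labels(lab)
  expect_identical(iv$ligand, rep(0L, 4))
  expect_identical(iv$receptor, rep(0L, 7))
  M[3, 6] <- 1L
  iv <- interface_labels(structure(list(matrix = M, cutoff = 6),
                                   class = "pair_labels"))
  expect_identical(which(iv$ligand == 1), 3L)
  expect_identical(which(iv$receptor == 1), 6L)
  expect_lte(sum(iv$ligand), sum(M > 0))
})

test_that("edge standardization centers channels on the fitting set", {
  cx <- make_complex(synthetic_spec(seed = 6))
  gs <- list(build_knn_graph(cx$ligand, 3), build_knn_graph(cx$receptor, 3))
  std <- standardize_edge_features(gs)
  feats <- do.call(rbind, lapply(std$graphs, `[[`, "edge_features"))
  expect_lt(max(abs(colMeans(feats))), 1e-10)
  expect_equal(unname(apply(feats, 2, sd)), c(1, 1), tolerance = 1e-10)
  # stored stats reproduce the same transform on new data
  std2 <- standardize_edge_features(gs[1], stats = std$stats)
  expect_equal(std2$graphs[[1]]$edge_features, std$graphs[[1]]$edge_features)
  # single-edge input collapses to 0 with a zero-variance warning
  g1 <- gs[[1]]
  g1$edges <- g1$edges[1, , drop = FALSE]
  g1$edge_features <- g1$edge_features[1, , drop = FALSE]
  expect_warning(s1 <- standardize_edge_features(list(g1)), "zero-variance")
  expect_equal(unname(s1$graphs[[1]]$edge_features[1, ]), c(0, 0))
})

test_that("graphs round-trip through the TSV edge-list format", {
  cx <- make_complex(synthetic_spec(seed = 3))
  g <- build_knn_graph(cx$ligand, 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_graph_tsv(g, path)
  g2 <- read_graph_tsv(path, n_nodes = g$n_nodes, k = g$k)
  expect_identical(g2$edges, g$edges)
  expect_equal(unname(g2$edge_features), unname(g$edge_features),
               tolerance = 1e-12)
})
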