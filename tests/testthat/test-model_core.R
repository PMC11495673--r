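# network blocks: shapes, normalization, symmetry, gradients

cfg_small <- model_config(d_model = 8, n_heads = 2, d_k = 4,
                          n_conv_layers = 2, n_gat_layers = 2,
                          ffn_hidden = c(6, 4), seed = 7)

test_that("positional encoding matches the closed form", {
  PE <- positional_encoding(5, 8)
  expect_true(all(PE >= -1 & PE <= 1))
  # position 0: even dimensions sin(0)=0, odd dimensions cos(0)=1
  expect_equal(unname(PE[1, c(2, 4, 6, 8)]), rep(0, 4))
  expect_equal(unname(PE[1, c(1, 3, 5, 7)]), rep(1, 4))
  # pos=1, i=2, d_model=4: sin(1 / 10000^(2/4)) = sin(0.01)
  PE4 <- positional_encoding(2, 4)
  expect_equal(PE4[2, 2], sin(1 / 100), tolerance = 1e-12)
  expect_equal(PE4[2, 2], 0.0099998, tolerance = 1e-4)
  # the paired convention differs but keeps the same range
  PEp <- positional_encoding(5, 8, convention = "paired")
  expect_true(all(PEp >= -1 & PEp <= 1))
  expect_false(isTRUE(all.equal(PE, PEp)))
})

test_that("positional addition is elementwise with strict shape checks", {
  H <- matrix(rnorm(40), 5, 8)
  PE <- positional_encoding(5, 8)
  expect_equal(add_positional(H, matrix(0, 5, 8)), H)
  expect_equal(add_positional(H, PE) - H, PE)
  expect_error(add_positional(matrix(0, 5, 8), matrix(0, 4, 8)),
               "shape mismatch")
})

test_that("local feature extractor preserves length down to N = 1", {
  m <- init_model(cfg_small, d_node = 10)
  for (n in c(1, 2, 7)) {
    X <- matrix(rnorm(n * 10), n, 10)
    H <- local_feature_extractor(X, m)
    expect_identical(dim(H), c(as.integer(n), 8L))
    expect_identical(H, local_feature_extractor(X, m)) # deterministic
  }
})

test_that("graph attention normalizes over each in-neighbourhood", {
  s <- tiny_sample(seed = 19)
  m <- init_model(cfg_small, d_node = ncol(s$ligand$features))
  r <- egret_layer(s$ligand$graph, matrix(rnorm(8 * 8), 8, 8), m,
                   return_attention = TRUE)
  sums <- tapply(r$alpha, s$ligand$graph$edges[, "tgt"], sum)
  expect_true(all(abs(sums - 1) < 1e-6))
  expect_true(all(is.finite(r$out)))
})

test_that("a single-node graph passes through its own transformed features", {
  g1 <- structure(list(n_nodes = 1L,
                       edges = matrix(integer(0), 0, 2,
                                      dimnames = list(NULL, c("src", "tgt"))),
                       edge_features = matrix(numeric(0), 0, 2),
                       k = 1L, degenerate = logical(0)),
                  class = "residue_graph")
  m <- init_model(cfg_small, d_node = 8)
  out <- egret_layer(g1, matrix(rnorm(8), 1, 8), m)
  expect_identical(dim(out), c(1L, 8L))
  expect_true(all(is.finite(out)))
})

test_that("node-only attention matches an independent dense oracle", {
  cfg_ne <- model_config(d_model = 6, n_heads = 1, n_conv_layers = 1,
                         n_gat_layers = 1, seed = 3,
                         use_edge_features = FALSE)
  m <- init_model(cfg_ne, d_node = 6)
  # 5-node toy graph
  edges <- cbind(src = c(2L, 3L, 1L, 4L, 5L, 1L, 2L, 3L),
                 tgt = c(1L, 1L, 2L, 2L, 3L, 4L, 5L, 5L))
  g <- structure(list(n_nodes = 5L, edges = edges,
                      edge_features = matrix(rnorm(16), 8, 2),
                      k = 2L, degenerate = logical(8)),
                 class = "residue_graph")
  H <- matrix(rnorm(30), 5, 6)
  got <- egret_layer(g, H, m)
  want <- oracle_node_gat(H, edges, m$params$Wg1, m$params$at1, m$params$as1,
                          slope = cfg_ne$leaky_slope)
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("the Siamese encoder shares weights across the two proteins", {
  s <- tiny_sample(seed = 23)
  m <- init_model(cfg_small, d_node = ncol(s$ligand$features))
  enc <- siamese_encode(receptor = s$receptor, ligand = s$ligand, m)
  enc_sw <- siamese_encode(receptor = s$ligand, ligand = s$receptor, m)
  expect_identical(enc$H_r, enc_sw$H_l)
  expect_identical(enc$H_l, enc_sw$H_r)
  # same protein on both inputs encodes identically
  same <- siamese_encode(receptor = s$ligand, ligand = s$ligand, m)
  expect_identical(same$H_r, same$H_l)
})

test_that("cross-attention rows are stochastic and handle length-1 partners", {
  m <- init_model(cfg_small, d_node = 8)
  set.seed(5)
  P_l <- matrix(rnorm(6 * 8), 6, 8); P_r <- matrix(rnorm(9 * 8), 9, 8)
  ca <- cross_attention_block(P_l, P_r, m)
  for (A in c(ca$attention$ligand_to_receptor, ca$attention$receptor_to_ligand))
    expect_true(all(abs(rowSums(A) - 1) < 1e-6))
  expect_identical(dim(ca$M_l), dim(P_l))
  # partner of length 1: every weight is 1
  ca1 <- cross_attention_block(P_l, P_r[1, , drop = FALSE], m)
  expect_true(all(ca1$attention$ligand_to_receptor[[1]] == 1))
  # identical key rows give uniform attention
  P_const <- matrix(1, 4, 8)
  cac <- cross_attention_block(P_l, P_const, m)
  expect_true(all(abs(cac$attention$ligand_to_receptor[[1]] - 0.25) < 1e-12))
})

test_that("output heads emit proper probabilities with the right shapes", {
  s <- tiny_sample(seed = 29)
  m <- init_model(cfg_small, d_node = ncol(s$ligand$features))
  enc <- siamese_encode(s$receptor, s$ligand, m)
  ca <- cross_attention_block(enc$H_l, enc$H_r, m)
  P <- pairwise_scores(ca$M_l, ca$M_r, m)
  expect_identical(dim(P), c(8L, 9L))
  expect_true(all(P > 0 & P < 1))
  v <- interface_scores(ca$M_l, m)
  expect_length(v, 8)
  expect_true(all(v > 0 & v < 1))
  # row-wise function: equal features give equal probabilities
  M2 <- ca$M_l[c(1, 1), ]
  expect_identical(interface_scores(M2, m)[1], interface_scores(M2, m)[2])
})

test_that("the full forward pass is order invariant and deterministic", {
  for (seed in c(31, 37)) {
    s <- tiny_sample(seed = seed)
    m <- init_model(cfg_small, d_node = ncol(s$ligand$features))
    p1 <- predict_complex(m, s)
    p2 <- predict_complex(m, s)
    expect_identical(p1$pair_probs, p2$pair_probs)
    ps <- predict_complex(m, swap_sample(s))
    expect_equal(ps$pair_probs, t(p1$pair_probs), tolerance = 1e-5)
    expect_equal(ps$interface_probs_l, p1$interface_probs_r, tolerance = 1e-5)
    expect_equal(ps$interface_probs_r, p1$interface_probs_l, tolerance = 1e-5)
  }
})

test_that("feature switches reduce the model as documented", {
  cx <- make_complex(synthetic_spec(seed = 41))
  prov <- surrogate_embedder(spec_aware = TRUE, dim = 4, seed = 1)
  s_plain <- make_complex_sample(cx$ligand, cx$receptor, prov, k = 3,
                                 labels = cx$labels, use_phychem = FALSE)
  expect_identical(ncol(s_plain$ligand$features), 4L)
  cfg_off <- model_config(d_model = 8, n_heads = 2, seed = 7,
                          use_edge_features = FALSE, use_positional = FALSE)
  m <- init_model(cfg_off, d_node = 4)
  p <- predict_complex(m, s_plain)
  expect_true(all(is.finite(p$pair_probs)))
  # with positional encoding off, P = H: the encoder output feeds the
  # cross-attention block directly
  enc <- siamese_encode(s_plain$receptor, s_plain$ligand, m)
  ca <- cross_attention_block(enc$H_l, enc$H_r, m)
  expect_equal(matrix(pairwise_scores(ca$M_l, ca$M_r, m),
                      nrow(p$pair_probs), ncol(p$pair_probs)),
               p$pair_probs, tolerance = 1e-12)
})

test_that("analytic gradients match central finite differences", {
  s <- tiny_sample(seed = 43, n_l = 6, n_r = 7, dim = 3, k = 2)
  cfg <- model_config(d_model = 6, n_heads = 2, d_k = 3, n_conv_layers = 2,
                      n_gat_layers = 2, ffn_hidden = c(5, 4), seed = 9)
  m <- init_model(cfg, d_node = ncol(s$ligand$features))
  y <- as.numeric(s$pair_labels$matrix)
  kept <- sort(c(which(y == 1), which(y == 0)[1:8]))
  pi_ <- (kept - 1) %% 6 + 1
  pj <- (kept - 1) %/% 6 + 1
  f <- function(p) pairsite:::.loss_and_grads(
    p, cfg, s, list(i = pi_, j = pj), y[kept],
    s$iface$ligand, s$iface$receptor, training = FALSE)$loss
  res <- pairsite:::.loss_and_grads(
    m$params, cfg, s, list(i = pi_, j = pj), y[kept],
    s$iface$ligand, s$iface$receptor, training = FALSE)
  expect_true(is.finite(res$loss))
  eps <- 1e-6
  set.seed(1)
  for (nm in names(m$params)) {
    ix <- sample(length(m$params[[nm]]), 1)
    p1 <- m$params; p1[[nm]][ix] <- p1[[nm]][ix] + eps
    p2 <- m$params; p2[[nm]][ix] <- p2[[nm]][ix] - eps
    num <- (f(p1) - f(p2)) / (2 * eps)
    ana <- res$grads[[nm]][ix]
    if (abs(num) + abs(ana) > 1e-7)
      expect_lt(abs(num - ana) / (abs(num) + abs(ana)), 1e-4,
                label = sprintf("gradient of %s", nm))
  }
})

test_that("one gradient step on one complex strictly decreases the loss", {
  s <- tiny_sample(seed = 47)
  cfg <- model_config(d_model = 8, n_heads = 2, seed = 13)
  m <- init_model(cfg, d_node = ncol(s$ligand$features))
  y <- as.numeric(s$pair_labels$matrix)
  kept <- seq_along(y)
  pi_ <- (kept - 1) %% nrow(s$pair_labels$matrix) + 1
  pj <- (kept - 1) %/% nrow(s$pair_labels$matrix) + 1
  args <- list(pair_idx = list(i = pi_, j = pj), pair_y = y,
               iface_y_l = s$iface$ligand, iface_y_r = s$iface$receptor)
  r0 <- pairsite:::.loss_and_grads(m$params, cfg, s, args$pair_idx,
                                   args$pair_y, args$iface_y_l,
                                   args$iface_y_r, training = FALSE)
  lr <- 1e-3
  p1 <- m$params
  for (nm in names(p1)) p1[[nm]] <- p1[[nm]] - lr * r0$grads[[nm]]
  r1 <- pairsite:::.loss_and_grads(p1, cfg, s, args$pair_idx, args$pair_y,
                                   args$iface_y_l, args$iface_y_r,
                                   training = FALSE)
  expect_lt(r1$loss, r0$loss)
})

test_that("model initialization is seed reproducible", {
  cfg <- model_config(seed = 99)
  m1 <- init_model(cfg, d_node = 24)
  m2 <- init_model(cfg, d_node = 24)
  expect_identical(m1$params, m2$params)
  m3 <- init_model(cfg, d_node = 24, seed = 100)
  expect_false(identical(m1$params, m3$params))
})
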