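# Forward pass of the network.
#
# Pipeline per complex: each protein's node features go through a stack of
# same-padded 1-D convolutions along the sequence (local feature extractor),
# then stacked edge-aggregated graph attention layers with residual
# connections (the Siamese halves share all weights). Sinusoidal positional
# encodings are added, then a multi-head cross-attention block exchanges
# information between the two proteins (queries from one protein, keys and
# values from the other, shared projection weights, residual + layer
# normalization). Two heads read the result: an order-averaged pairwise
# classifier and a per-residue interface classifier.
#
# Every forward helper can retain the intermediate tensors needed by the
# hand-written backward pass in model_grad.R.

.lrelu <- function(x, slope) ifelse(x > 0, x, slope * x)
.lrelu_grad <- function(x, slope) ifelse(x > 0, 1, slope)
.relu <- function(x) pmax(x, 0)
.elu <- function(x) ifelse(x > 0, x, exp(pmin(x, 0)) - 1)
.elu_grad <- function(x) ifelse(x > 0, 1, exp(pmin(x, 0)))
.sigmoid <- function(x) 1 / (1 + exp(-x))

.row_softmax <- function(S) {
  m <- apply(S, 1, max)
  E <- exp(S - m)
  E / rowSums(E)
}

# unfold a sequence matrix X (N x d) into N x (kw*d) windows, zero padded
.unfold_seq <- function(X, kw) {
  n <- nrow(X); d <- ncol(X); half <- (kw - 1L) %/% 2L
  out <- matrix(0, n, kw * d)
  for (o in seq_len(kw)) {
    shift <- o - 1L - half
    src <- seq_len(n) + shift
    ok <- src >= 1 & src <= n
    out[ok, (o - 1L) * d + seq_len(d)] <- X[src[ok], , drop = FALSE]
  }
  out
}

# fold gradient of unfolded windows back onto the sequence matrix
.fold_seq_grad <- function(dU, n, d, kw) {
  half <- (kw - 1L) %/% 2L
  dX <- matrix(0, n, d)
  for (o in seq_len(kw)) {
    shift <- o - 1L - half
    src <- seq_len(n) + shift
    ok <- src >= 1 & src <= n
    dX[src[ok], ] <- dX[src[ok], , drop = FALSE] +
      dU[ok, (o - 1L) * d + seq_len(d), drop = FALSE]
  }
  dX
}

# --- local feature extractor --------------------------------------------

.conv_stack <- function(X, params, cfg, training = FALSE, keep = FALSE) {
  caches <- if (keep) vector("list", cfg$n_conv_layers) else NULL
  for (l in seq_len(cfg$n_conv_layers)) {
    U <- .unfold_seq(X, cfg$conv_kernel)
    Z <- sweep(U %*% params[[paste0("Wc", l)]], 2,
               params[[paste0("bc", l)]], `+`)
    A <- .lrelu(Z, cfg$leaky_slope)
    mask <- NULL
    if (training && cfg$dropout > 0) {
      mask <- matrix(runif(length(A)) >= cfg$dropout, nrow(A), ncol(A)) /
        (1 - cfg$dropout)
      A <- A * mask
    }
    if (keep) caches[[l]] <- list(U = U, Z = Z, mask = mask,
                                  n = nrow(X), d_in = ncol(X))
    X <- A
  }
  list(H = X, caches = caches)
}

#' Local feature extractor (stack of same-padded 1-D convolutions)
#'
#' Convolves the node-feature matrix along the residue order with
#' `n_conv_layers` layers (leaky-ReLU activations, zero same-padding), so
#' sequence length is preserved for any N, including N = 1.
#'
#' @param features N x d_node node-feature matrix
#' @param model a `pairsite_model`
#' @return N x d_model matrix
#' @export
local_feature_extractor <- function(features, model) {
  .assert(is.matrix(features) && nrow(features) >= 1, "non-empty matrix needed")
  .conv_stack(features, model$params, model$config)$H
}

# --- edge-aggregated graph attention ------------------------------------

# one edge-aggregated graph attention layer with residual connection.
# logit(j->i) = leakyrelu( a_t . W h_i + a_s . W h_j + a_e . W_e xi_ji )
# alpha = softmax over the in-neighbourhood of i
# message_i = sum_j alpha_ji (W h_j + W_e xi_ji); out = elu(message) + h
# isolated nodes pass through their own transformed features.
.egret_forward <- function(H, graph, params, cfg, layer, training = FALSE,
                           keep = FALSE) {
  Wg <- params[[paste0("Wg", layer)]]
  We <- params[[paste0("We", layer)]]
  a_t <- params[[paste0("at", layer)]]
  a_s <- params[[paste0("as", layer)]]
  a_e <- params[[paste0("ae", layer)]]
  n <- nrow(H); d <- ncol(H)
  Wh <- H %*% Wg
  m <- nrow(graph$edges)
  if (m > 0) {
    src <- graph$edges[, "src"]; tgt <- graph$edges[, "tgt"]
    Ep <- if (cfg$use_edge_features) graph$edge_features %*% We
          else matrix(0, m, d)
    raw <- as.numeric(Wh[tgt, , drop = FALSE] %*% a_t +
                      Wh[src, , drop = FALSE] %*% a_s +
                      Ep %*% a_e)
    z <- .lrelu(raw, cfg$leaky_slope)
    # grouped softmax over each node's in-neighbourhood
    alpha <- numeric(m)
    groups <- split(seq_len(m), tgt)
    for (g in groups) {
      zz <- z[g]
      e <- exp(zz - max(zz))
      alpha[g] <- e / sum(e)
    }
    Msg_edges <- Wh[src, , drop = FALSE] + Ep
    msg <- rowsum(alpha * Msg_edges, tgt)
    msg_full <- matrix(0, n, d)
    msg_full[as.integer(rownames(msg)), ] <- msg
    iso <- setdiff(seq_len(n), unique(tgt))
  } else {
    Ep <- matrix(0, 0, d); raw <- numeric(0); z <- numeric(0)
    alpha <- numeric(0); groups <- list(); Msg_edges <- matrix(0, 0, d)
    msg_full <- matrix(0, n, d)
    iso <- seq_len(n)
    src <- integer(0); tgt <- integer(0)
  }
  if (length(iso) > 0) msg_full[iso, ] <- Wh[iso, , drop = FALSE]
  out <- .elu(msg_full) + H
  mask <- NULL
  if (training && cfg$dropout > 0) {
    mask <- matrix(runif(length(out)) >= cfg$dropout, n, d) / (1 - cfg$dropout)
    out <- out * mask
  }
  cache <- if (keep) list(H = H, Wh = Wh, Ep = Ep, raw = raw, alpha = alpha,
                          groups = groups, Msg_edges = Msg_edges,
                          msg_full = msg_full, iso = iso, src = src,
                          tgt = tgt, mask = mask) else NULL
  list(out = out, alpha = alpha, cache = cache)
}

#' Edge-aggregated graph attention layer
#'
#' Applies one graph attention layer in which both node and edge features
#' enter the attention logits and the aggregated messages. Attention
#' coefficients are softmax-normalized over each node's in-neighbourhood;
#' the layer output adds a residual connection. Isolated nodes (no in-edges)
#' pass through their own transformed features.
#'
#' @param graph a `residue_graph`
#' @param node_feats N x d_model matrix
#' @param model a `pairsite_model`
#' @param layer which GAT layer's weights to use (default 1)
#' @param return_attention also return the per-edge attention coefficients
#' @return N x d_model matrix, or a list with `out` and `alpha` when
#'   `return_attention = TRUE`
#' @export
egret_layer <- function(graph, node_feats, model, layer = 1L,
                        return_attention = FALSE) {
  .assert(graph$n_nodes == nrow(node_feats),
          "graph and feature matrix disagree on N")
  r <- .egret_forward(node_feats, graph, model$params, model$config, layer)
  if (return_attention) list(out = r$out, alpha = r$alpha) else r$out
}

# encode one protein: conv stack then GAT stack
.encode_side <- function(graph, X, params, cfg, training = FALSE,
                         keep = FALSE) {
  conv <- .conv_stack(X, params, cfg, training = training, keep = keep)
  H <- conv$H
  gat_caches <- if (keep) vector("list", cfg$n_gat_layers) else NULL
  for (l in seq_len(cfg$n_gat_layers)) {
    r <- .egret_forward(H, graph, params, cfg, l, training = training,
                        keep = keep)
    if (keep) gat_caches[[l]] <- r$cache
    H <- r$out
  }
  list(H = H, conv = conv$caches, gat = gat_caches)
}

#' Siamese encoding of the two proteins of a complex
#'
#' Applies the identical (weight-shared) local feature extractor and graph
#' attention stack to both proteins; swapping the inputs exactly swaps the
#' outputs.
#'
#' @param receptor,ligand lists with elements `graph` (a `residue_graph`)
#'   and `features` (node-feature matrix)
#' @param model a `pairsite_model`
#' @return list with `H_r` and `H_l`
#' @export
siamese_encode <- function(receptor, ligand, model) {
  list(H_r = .encode_side(receptor$graph, receptor$features, model$params,
                          model$config)$H,
       H_l = .encode_side(ligand$graph, ligand$features, model$params,
                          model$config)$H)
}

# --- positional encoding -------------------------------------------------

#' Sinusoidal positional encoding
#'
#' With the default `"as_printed"` convention the dimension index i runs
#' from 1 to d_model and `PE(pos, i) = sin(pos / 10000^(i/d_model))` for
#' even i, `cos(pos / 10000^((i-1)/d_model))` for odd i; positions are
#' 0-based. The `"paired"` convention is the common sin/cos-paired variant
#' with exponent `2i/d_model`.
#'
#' @param length sequence length N (>= 1)
#' @param d_model encoding dimensionality
#' @param convention `"as_printed"` or `"paired"`
#' @return N x d_model matrix with entries in `[-1, 1]`
#' @export
positional_encoding <- function(length, d_model,
                                convention = c("as_printed", "paired")) {
  convention <- match.arg(convention)
  .assert(length >= 1 && d_model >= 1, "length and d_model must be >= 1")
  pos <- 0:(length - 1)
  PE <- matrix(0, length, d_model)
  for (i in seq_len(d_model)) {
    if (convention == "as_printed") {
      expo <- if (i %% 2 == 0) i / d_model else (i - 1) / d_model
      f <- if (i %% 2 == 0) sin else cos
      # i even -> sin, i odd -> cos (cos(0)=1 at pos 0 on odd dims)
      if (i %% 2 == 0) PE[, i] <- sin(pos / 10000^expo)
      else PE[, i] <- cos(pos / 10000^expo)
    } else {
      j <- i - 1
      expo <- (j - j %% 2) / d_model
      if (j %% 2 == 0) PE[, i] <- sin(pos / 10000^expo)
      else PE[, i] <- cos(pos / 10000^expo)
    }
  }
  PE
}

#' Add positional encodings to a hidden matrix
#'
#' @param H N x d_model hidden matrix
#' @param PE N x d_model positional matrix from [positional_encoding()]
#' @return elementwise sum
#' @export
add_positional <- function(H, PE) {
  .assert(all(dim(H) == dim(PE)),
          sprintf("shape mismatch: H is %dx%d, PE is %dx%d",
                  nrow(H), ncol(H), nrow(PE), ncol(PE)))
  H + PE
}

# --- cross-attention -----------------------------------------------------

.layernorm_forward <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc^2)
  invstd <- 1 / sqrt(v + eps)
  xhat <- xc * invstd
  Y <- sweep(xhat, 2, g, `*`)
  Y <- sweep(Y, 2, b, `+`)
  list(Y = Y, xhat = xhat, invstd = invstd)
}

.cross_attention_forward <- function(P_l, P_r, params, cfg, keep = FALSE) {
  nh <- cfg$n_heads; dk <- cfg$d_k
  heads_l <- vector("list", nh); heads_r <- vector("list", nh)
  att_l <- vector("list", nh); att_r <- vector("list", nh)
  hcache <- if (keep) vector("list", nh) else NULL
  for (h in seq_len(nh)) {
    Wq <- params[[paste0("Wq", h)]]
    Wk <- params[[paste0("Wk", h)]]
    Wv <- params[[paste0("Wv", h)]]
    Ql <- P_l %*% Wq; Kl <- P_l %*% Wk; Vl <- P_l %*% Wv
    Qr <- P_r %*% Wq; Kr <- P_r %*% Wk; Vr <- P_r %*% Wv
    Al <- .row_softmax(Ql %*% t(Kr) / sqrt(dk)) # ligand attends to receptor
    Ar <- .row_softmax(Qr %*% t(Kl) / sqrt(dk)) # receptor attends to ligand
    heads_l[[h]] <- Al %*% Vr
    heads_r[[h]] <- Ar %*% Vl
    att_l[[h]] <- Al; att_r[[h]] <- Ar
    if (keep) hcache[[h]] <- list(Ql = Ql, Kl = Kl, Vl = Vl,
                                  Qr = Qr, Kr = Kr, Vr = Vr,
                                  Al = Al, Ar = Ar)
  }
  C_l <- do.call(cbind, heads_l)
  C_r <- do.call(cbind, heads_r)
  pre_l <- C_l %*% params$Wo
  pre_r <- C_r %*% params$Wo
  ln_l <- .layernorm_forward(P_l + pre_l, params$ln_g, params$ln_b)
  ln_r <- .layernorm_forward(P_r + pre_r, params$ln_g, params$ln_b)
  list(M_l = ln_l$Y, M_r = ln_r$Y,
       attention = list(ligand_to_receptor = att_l,
                        receptor_to_ligand = att_r),
       cache = if (keep) list(heads = hcache, C_l = C_l, C_r = C_r,
                              ln_l = ln_l, ln_r = ln_r,
                              P_l = P_l, P_r = P_r) else NULL)
}

#' Multi-head cross-attention block over a protein pair
#'
#' Each head projects both proteins with shared query/key/value weights;
#' the ligand attends over the receptor (`softmax(Q_l K_r^T / sqrt(d_k)) V_r`)
#' and vice versa. Heads are concatenated, projected back to d_model, added
#' to the input (residual) and layer-normalized.
#'
#' @param P_l,P_r N_l x d_model and N_r x d_model matrices
#' @param model a `pairsite_model`
#' @return list with `M_l`, `M_r`, and `attention` (per-head row-stochastic
#'   matrices for both directions)
#' @export
cross_attention_block <- function(P_l, P_r, model) {
  .assert(nrow(P_l) >= 1 && nrow(P_r) >= 1, "both inputs must be non-empty")
  r <- .cross_attention_forward(P_l, P_r, model$params, model$config)
  r[c("M_l", "M_r", "attention")]
}

# --- output heads --------------------------------------------------------

.ffn_forward <- function(X, W1, b1, W2, b2, w3, b3, slope, keep = FALSE) {
  Z1 <- sweep(X %*% W1, 2, b1, `+`)
  A1 <- .relu(Z1)
  Z2 <- sweep(A1 %*% W2, 2, b2, `+`)
  A2 <- .lrelu(Z2, slope)
  z3 <- as.numeric(A2 %*% w3) + b3
  p <- .sigmoid(z3)
  if (keep) list(p = p, z3 = z3, A2 = A2, Z2 = Z2, A1 = A1, Z1 = Z1, X = X)
  else list(p = p)
}

.pair_head <- function(M_l, M_r, pair_i, pair_j, params, cfg, keep = FALSE) {
  X_rl <- cbind(M_r[pair_j, , drop = FALSE], M_l[pair_i, , drop = FALSE])
  X_lr <- cbind(M_l[pair_i, , drop = FALSE], M_r[pair_j, , drop = FALSE])
  f_rl <- .ffn_forward(X_rl, params$Pw1, params$Pb1, params$Pw2, params$Pb2,
                       params$Pw3, params$Pb3, cfg$leaky_slope, keep)
  f_lr <- .ffn_forward(X_lr, params$Pw1, params$Pb1, params$Pw2, params$Pb2,
                       params$Pw3, params$Pb3, cfg$leaky_slope, keep)
  list(p = (f_rl$p + f_lr$p) / 2, f_rl = f_rl, f_lr = f_lr,
       pair_i = pair_i, pair_j = pair_j)
}

.iface_head <- function(M, params, cfg, keep = FALSE) {
  .ffn_forward(M, params$Iw1, params$Ib1, params$Iw2, params$Ib2,
               params$Iw3, params$Ib3, cfg$leaky_slope, keep)
}

#' Pairwise interaction probabilities for all residue pairs
#'
#' For each (ligand residue i, receptor residue j) the features are
#' concatenated in both orders, passed through the shared feed-forward
#' classifier, and the two sigmoid outputs are averaged, making the score
#' invariant to the receptor/ligand ordering.
#'
#' @param M_l,M_r cross-attended hidden matrices
#' @param model a `pairsite_model`
#' @return N_l x N_r matrix of probabilities in (0, 1)
#' @export
pairwise_scores <- function(M_l, M_r, model) {
  nl <- nrow(M_l); nr <- nrow(M_r)
  grid_i <- rep(seq_len(nl), times = nr)
  grid_j <- rep(seq_len(nr), each = nl)
  ph <- .pair_head(M_l, M_r, grid_i, grid_j, model$params, model$config)
  matrix(ph$p, nl, nr)
}

#' Per-residue interface probabilities
#'
#' Applies the shared interface feed-forward head row-wise.
#'
#' @param M hidden matrix (either protein)
#' @param model a `pairsite_model`
#' @return numeric vector of probabilities in (0, 1), length `nrow(M)`
#' @export
interface_scores <- function(M, model) {
  .assert(nrow(M) >= 1, "M must be non-empty")
  .iface_head(M, model$params, model$config)$p
}

# --- full forward --------------------------------------------------------

# full forward pass; pair_idx = list(i=, j=) restricts the pairwise head to
# selected pairs (training); NULL scores all pairs.
.forward_full <- function(params, cfg, sample, pair_idx = NULL,
                          training = FALSE, keep = FALSE) {
  enc_l <- .encode_side(sample$ligand$graph, sample$ligand$features,
                        params, cfg, training, keep)
  enc_r <- .encode_side(sample$receptor$graph, sample$receptor$features,
                        params, cfg, training, keep)
  nl <- nrow(enc_l$H); nr <- nrow(enc_r$H)
  if (cfg$use_positional) {
    PE_l <- positional_encoding(nl, cfg$d_model, cfg$pe_convention)
    PE_r <- positional_encoding(nr, cfg$d_model, cfg$pe_convention)
    P_l <- enc_l$H + PE_l
    P_r <- enc_r$H + PE_r
  } else {
    P_l <- enc_l$H; P_r <- enc_r$H
  }
  ca <- .cross_attention_forward(P_l, P_r, params, cfg, keep)
  if (is.null(pair_idx)) {
    pair_i <- rep(seq_len(nl), times = nr)
    pair_j <- rep(seq_len(nr), each = nl)
  } else {
    pair_i <- pair_idx$i; pair_j <- pair_idx$j
  }
  ph <- .pair_head(ca$M_l, ca$M_r, pair_i, pair_j, params, cfg, keep)
  if_l <- .iface_head(ca$M_l, params, cfg, keep)
  if_r <- .iface_head(ca$M_r, params, cfg, keep)
  pair_probs <- if (is.null(pair_idx)) matrix(ph$p, nl, nr) else ph$p
  res <- list(pair_probs = pair_probs,
              interface_probs_l = if_l$p,
              interface_probs_r = if_r$p,
              attention = ca$attention)
  class(res) <- "prediction_result"
  if (keep) {
    attr(res, "cache") <- list(enc_l = enc_l, enc_r = enc_r, ca = ca,
                               ph = ph, if_l = if_l, if_r = if_r,
                               pair_i = pair_i, pair_j = pair_j)
  }
  res
}

#' Run the full network on a complex
#'
#' Composes the Siamese encoder, positional encoding, cross-attention block
#' and both output heads. Deterministic in evaluation mode: repeated calls
#' give identical results, and swapping receptor and ligand transposes the
#' pairwise matrix and exchanges the interface vectors.
#'
#' @param model a `pairsite_model`
#' @param sample a complex sample: list with `ligand` and `receptor`, each a
#'   list holding `graph` and `features`
#' @return a `prediction_result`: `pair_probs` (N_l x N_r), two interface
#'   probability vectors, and the per-head cross-attention matrices
#' @export
predict_complex <- function(model, sample) {
  .forward_full(model$params, model$config, sample)
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf(paste0("<prediction_result> %d x %d pair probabilities, ",
                     "%d + %d interface probabilities, %d attention heads\n"),
              nrow(x$pair_probs), ncol(x$pair_probs),
              length(x$interface_probs_l), length(x$interface_probs_r),
              length(x$attention$ligand_to_receptor)))
  invisible(x)
}

#' Export cross-attention matrices to TSV files
#'
#' Writes one TSV per head and direction
#' (`<prefix>_<direction>_head<h>.tsv`), rows indexed by the query protein's
#' residues. Row sums are 1 by construction, so the files can be inspected
#' directly for interpretability analysis of which partner residues each
#' residue attends to.
#'
#' @param prediction a `prediction_result`
#' @param prefix output path prefix
#' @return invisibly, the written file paths
#' @export
export_attention <- function(prediction, prefix) {
  paths <- character(0)
  for (dir in names(prediction$attention)) {
    mats <- prediction$attention[[dir]]
    for (h in seq_along(mats)) {
      p <- sprintf("%s_%s_head%d.tsv", prefix, dir, h)
      utils::write.table(mats[[h]], p, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}
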