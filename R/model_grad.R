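# Hand-written backpropagation through the full network.
#
# The forward pass (model_forward.R) caches every intermediate tensor;
# .loss_and_grads() replays the chain rule through the output heads, layer
# normalization, multi-head cross-attention, the graph attention stack
# (grouped softmax over in-neighbourhoods) and the convolution stack.
# A numerical-gradient test validates the analytic gradients.

.zero_like <- function(params) lapply(params, function(x) x * 0)

.scatter_add <- function(M, idx, values) {
  rs <- rowsum(values, idx)
  rows <- as.integer(rownames(rs))
  M[rows, ] <- M[rows, , drop = FALSE] + rs
  M
}

.bce <- function(p, y, eps = 1e-12) {
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

.bce_grad <- function(p, y, eps = 1e-12) {
  p <- pmin(pmax(p, eps), 1 - eps)
  (-(y / p) + (1 - y) / (1 - p)) / length(p)
}

#' Binary cross-entropy loss
#'
#' Mean binary cross-entropy between predicted probabilities and binary
#' labels. Used for both tasks: over the (downsampled) residue pairs for
#' pairwise prediction, over all residues for interface prediction.
#'
#' @param probs numeric vector of probabilities
#' @param labels binary vector of the same length
#' @return non-negative scalar
#' @export
bce_loss <- function(probs, labels) {
  .assert(length(probs) == length(labels), "probs/labels length mismatch")
  .bce(as.numeric(probs), as.numeric(labels))
}

# backward through one classifier FFN; returns dX and accumulates grads
.ffn_backward <- function(dz3, f, W1n, b1n, W2n, b2n, w3n, b3n,
                          params, grads, slope) {
  dA2 <- outer(dz3, as.numeric(params[[w3n]]))
  grads[[w3n]] <- grads[[w3n]] + crossprod(f$A2, dz3)
  grads[[b3n]] <- grads[[b3n]] + sum(dz3)
  dZ2 <- dA2 * .lrelu_grad(f$Z2, slope)
  grads[[W2n]] <- grads[[W2n]] + crossprod(f$A1, dZ2)
  grads[[b2n]] <- grads[[b2n]] + colSums(dZ2)
  dA1 <- dZ2 %*% t(params[[W2n]])
  dZ1 <- dA1 * (f$Z1 > 0)
  grads[[W1n]] <- grads[[W1n]] + crossprod(f$X, dZ1)
  grads[[b1n]] <- grads[[b1n]] + colSums(dZ1)
  list(dX = dZ1 %*% t(params[[W1n]]), grads = grads)
}

.layernorm_backward <- function(dY, ln, params, grads) {
  grads$ln_g <- grads$ln_g + colSums(dY * ln$xhat)
  grads$ln_b <- grads$ln_b + colSums(dY)
  dxhat <- sweep(dY, 2, params$ln_g, `*`)
  # length-n vectors recycle down columns, i.e. per row, as intended
  dX <- ln$invstd * (dxhat - rowMeans(dxhat) -
                       ln$xhat * rowMeans(dxhat * ln$xhat))
  list(dX = dX, grads = grads)
}

# backward through the GAT stack of one protein; returns gradient w.r.t.
# the conv-stack output and accumulates parameter grads
.gat_stack_backward <- function(dH, gat_caches, graph, params, grads, cfg) {
  for (l in rev(seq_len(cfg$n_gat_layers))) {
    cc <- gat_caches[[l]]
    if (!is.null(cc$mask)) dH <- dH * cc$mask
    dH_in <- dH # residual
    dMsg <- dH * .elu_grad(cc$msg_full)
    n <- nrow(cc$H); d <- ncol(cc$H)
    dWh <- matrix(0, n, d)
    if (length(cc$iso) > 0)
      dWh[cc$iso, ] <- dWh[cc$iso, , drop = FALSE] +
        dMsg[cc$iso, , drop = FALSE]
    m <- length(cc$alpha)
    if (m > 0) {
      src <- cc$src; tgt <- cc$tgt
      dMsg_t <- dMsg[tgt, , drop = FALSE]
      dalpha <- rowSums(dMsg_t * cc$Msg_edges)
      dMe <- cc$alpha * dMsg_t
      dz <- numeric(m)
      for (g in cc$groups) {
        s <- sum(cc$alpha[g] * dalpha[g])
        dz[g] <- cc$alpha[g] * (dalpha[g] - s)
      }
      draw <- dz * .lrelu_grad(cc$raw, cfg$leaky_slope)
      Wh_t <- cc$Wh[tgt, , drop = FALSE]
      Wh_s <- cc$Wh[src, , drop = FALSE]
      at_n <- paste0("at", l); as_n <- paste0("as", l); ae_n <- paste0("ae", l)
      grads[[at_n]] <- grads[[at_n]] + as.numeric(crossprod(Wh_t, draw))
      grads[[as_n]] <- grads[[as_n]] + as.numeric(crossprod(Wh_s, draw))
      if (cfg$use_edge_features)
        grads[[ae_n]] <- grads[[ae_n]] + as.numeric(crossprod(cc$Ep, draw))
      a_t <- params[[at_n]]; a_s <- params[[as_n]]; a_e <- params[[ae_n]]
      dWh <- .scatter_add(dWh, tgt, outer(draw, a_t))
      dWh <- .scatter_add(dWh, src, outer(draw, a_s) + dMe)
      if (cfg$use_edge_features) {
        dEp <- outer(draw, a_e) + dMe
        we_n <- paste0("We", l)
        grads[[we_n]] <- grads[[we_n]] +
          crossprod(graph$edge_features, dEp)
      }
    }
    wg_n <- paste0("Wg", l)
    grads[[wg_n]] <- grads[[wg_n]] + crossprod(cc$H, dWh)
    dH <- dH_in + dWh %*% t(params[[wg_n]])
  }
  list(dH = dH, grads = grads)
}

.conv_stack_backward <- function(dA, conv_caches, params, grads, cfg) {
  for (l in rev(seq_len(cfg$n_conv_layers))) {
    cc <- conv_caches[[l]]
    if (!is.null(cc$mask)) dA <- dA * cc$mask
    dZ <- dA * .lrelu_grad(cc$Z, cfg$leaky_slope)
    wc_n <- paste0("Wc", l); bc_n <- paste0("bc", l)
    grads[[wc_n]] <- grads[[wc_n]] + crossprod(cc$U, dZ)
    grads[[bc_n]] <- grads[[bc_n]] + colSums(dZ)
    dU <- dZ %*% t(params[[wc_n]])
    dA <- .fold_seq_grad(dU, cc$n, cc$d_in, cfg$conv_kernel)
  }
  grads
}

# full loss + analytic gradients for one complex.
# pair_idx: list(i=, j=) of sampled pairs; pair_y: their binary labels.
.loss_and_grads <- function(params, cfg, sample, pair_idx, pair_y,
                            iface_y_l, iface_y_r,
                            w_pair = 1, w_iface = 1, training = TRUE) {
  fwd <- .forward_full(params, cfg, sample, pair_idx = pair_idx,
                       training = training, keep = TRUE)
  cache <- attr(fwd, "cache")
  p_pair <- as.numeric(fwd$pair_probs)
  p_ifl <- fwd$interface_probs_l
  p_ifr <- fwd$interface_probs_r
  loss_pair <- .bce(p_pair, pair_y)
  p_if <- c(p_ifl, p_ifr)
  y_if <- c(iface_y_l, iface_y_r)
  loss_iface <- .bce(p_if, y_if)
  loss <- w_pair * loss_pair + w_iface * loss_iface

  grads <- .zero_like(params)
  d <- cfg$d_model
  nl <- length(p_ifl); nr <- length(p_ifr)
  dM_l <- matrix(0, nl, d); dM_r <- matrix(0, nr, d)

  # pairwise head (order-averaged)
  dO <- w_pair * .bce_grad(p_pair, pair_y)
  ph <- cache$ph
  for (order in c("rl", "lr")) {
    f <- if (order == "rl") ph$f_rl else ph$f_lr
    dz3 <- (dO / 2) * f$p * (1 - f$p)
    bk <- .ffn_backward(dz3, f, "Pw1", "Pb1", "Pw2", "Pb2", "Pw3", "Pb3",
                        params, grads, cfg$leaky_slope)
    grads <- bk$grads
    dX <- bk$dX
    if (order == "rl") {
      dM_r <- .scatter_add(dM_r, cache$pair_j, dX[, 1:d, drop = FALSE])
      dM_l <- .scatter_add(dM_l, cache$pair_i, dX[, d + 1:d, drop = FALSE])
    } else {
      dM_l <- .scatter_add(dM_l, cache$pair_i, dX[, 1:d, drop = FALSE])
      dM_r <- .scatter_add(dM_r, cache$pair_j, dX[, d + 1:d, drop = FALSE])
    }
  }

  # interface head (shared weights, applied to both proteins; the BCE mean
  # runs over the nl + nr concatenated residues)
  dp_if <- w_iface * .bce_grad(p_if, y_if)
  dz3_l <- dp_if[seq_len(nl)] * p_ifl * (1 - p_ifl)
  dz3_r <- dp_if[nl + seq_len(nr)] * p_ifr * (1 - p_ifr)
  bk <- .ffn_backward(dz3_l, cache$if_l, "Iw1", "Ib1", "Iw2", "Ib2",
                      "Iw3", "Ib3", params, grads, cfg$leaky_slope)
  grads <- bk$grads; dM_l <- dM_l + bk$dX
  bk <- .ffn_backward(dz3_r, cache$if_r, "Iw1", "Ib1", "Iw2", "Ib2",
                      "Iw3", "Ib3", params, grads, cfg$leaky_slope)
  grads <- bk$grads; dM_r <- dM_r + bk$dX

  # layer normalization
  ca <- cache$ca$cache
  lnb <- .layernorm_backward(dM_l, ca$ln_l, params, grads)
  grads <- lnb$grads; dsum_l <- lnb$dX
  lnb <- .layernorm_backward(dM_r, ca$ln_r, params, grads)
  grads <- lnb$grads; dsum_r <- lnb$dX

  dP_l <- dsum_l; dP_r <- dsum_r # residual branch
  grads$Wo <- grads$Wo + crossprod(ca$C_l, dsum_l) + crossprod(ca$C_r, dsum_r)
  dC_l <- dsum_l %*% t(params$Wo)
  dC_r <- dsum_r %*% t(params$Wo)

  dk <- cfg$d_k
  for (h in seq_len(cfg$n_heads)) {
    hc <- ca$heads[[h]]
    cols <- (h - 1) * dk + seq_len(dk)
    dhead_l <- dC_l[, cols, drop = FALSE]
    dhead_r <- dC_r[, cols, drop = FALSE]
    # ligand attends to receptor
    dAl <- dhead_l %*% t(hc$Vr)
    dVr <- crossprod(hc$Al, dhead_l)
    dSl <- hc$Al * (dAl - rowSums(dAl * hc$Al))
    dQl <- dSl %*% hc$Kr / sqrt(dk)
    dKr <- crossprod(dSl, hc$Ql) / sqrt(dk)
    # receptor attends to ligand
    dAr <- dhead_r %*% t(hc$Vl)
    dVl <- crossprod(hc$Ar, dhead_r)
    dSr <- hc$Ar * (dAr - rowSums(dAr * hc$Ar))
    dQr <- dSr %*% hc$Kl / sqrt(dk)
    dKl <- crossprod(dSr, hc$Qr) / sqrt(dk)

    qn <- paste0("Wq", h); kn <- paste0("Wk", h); vn <- paste0("Wv", h)
    grads[[qn]] <- grads[[qn]] + crossprod(ca$P_l, dQl) + crossprod(ca$P_r, dQr)
    grads[[kn]] <- grads[[kn]] + crossprod(ca$P_r, dKr) + crossprod(ca$P_l, dKl)
    grads[[vn]] <- grads[[vn]] + crossprod(ca$P_r, dVr) + crossprod(ca$P_l, dVl)
    dP_l <- dP_l + dQl %*% t(params[[qn]]) + dKl %*% t(params[[kn]]) +
      dVl %*% t(params[[vn]])
    dP_r <- dP_r + dQr %*% t(params[[qn]]) + dKr %*% t(params[[kn]]) +
      dVr %*% t(params[[vn]])
  }

  # positional encoding is additive, so gradients pass through unchanged
  gb <- .gat_stack_backward(dP_l, cache$enc_l$gat, sample$ligand$graph,
                            params, grads, cfg)
  grads <- gb$grads
  grads <- .conv_stack_backward(gb$dH, cache$enc_l$conv, params, grads, cfg)
  gb <- .gat_stack_backward(dP_r, cache$enc_r$gat, sample$receptor$graph,
                            params, grads, cfg)
  grads <- gb$grads
  grads <- .conv_stack_backward(gb$dH, cache$enc_r$conv, params, grads, cfg)

  list(loss = loss, loss_pair = loss_pair, loss_iface = loss_iface,
       grads = grads, prediction = fwd)
}
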