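# Model configuration and parameter initialization.
#
# All learnable parameters live in a flat named list of numeric
# matrices/vectors; the same list is mirrored by the gradient container, so
# the optimizer is a simple elementwise update. One parameter set serves
# both proteins (Siamese weight sharing) by construction.

#' Model configuration
#'
#' @param k neighbour count for the residue k-NN graphs
#' @param d_model hidden width shared by all blocks
#' @param n_heads number of cross-attention heads
#' @param d_k per-head projection dimension (default `d_model / n_heads`)
#' @param n_conv_layers 1-D convolution layers in the local feature extractor
#' @param n_gat_layers stacked edge-aggregated graph attention layers
#' @param conv_kernel convolution kernel width (odd, same-padding)
#' @param ffn_hidden integer vector of the two hidden widths of the
#'   classifier feed-forward networks
#' @param dropout dropout rate applied after each encoder layer during
#'   training (0 disables)
#' @param leaky_slope negative slope of leaky-ReLU activations
#' @param seed integer seed fixing weight initialization
#' @param use_phychem include the 16 physicochemical channels in node features
#' @param use_edge_features include edge features in graph attention
#' @param use_positional add sinusoidal positional encodings
#' @param pe_convention `"as_printed"` (dimension index i in 1..d_model with
#'   exponent i/d_model) or `"paired"` (the common 2i/d variant)
#' @param cutoff interaction-label distance cutoff in Angstrom
#' @return a `model_config` list
#' @export
model_config <- function(k = 10L, d_model = 16L, n_heads = 2L,
                         d_k = NULL, n_conv_layers = 2L, n_gat_layers = 2L,
                         conv_kernel = 3L, ffn_hidden = c(16L, 8L),
                         dropout = 0.0, leaky_slope = 0.2, seed = 1L,
                         use_phychem = TRUE, use_edge_features = TRUE,
                         use_positional = TRUE,
                         pe_convention = c("as_printed", "paired"),
                         cutoff = 6.0) {
  pe_convention <- match.arg(pe_convention)
  d_k <- as.integer(d_k %||% max(1L, d_model %/% n_heads))
  cfg <- list(k = as.integer(k), d_model = as.integer(d_model),
              n_heads = as.integer(n_heads), d_k = d_k,
              n_conv_layers = as.integer(n_conv_layers),
              n_gat_layers = as.integer(n_gat_layers),
              conv_kernel = as.integer(conv_kernel),
              ffn_hidden = as.integer(ffn_hidden),
              dropout = dropout, leaky_slope = leaky_slope,
              seed = as.integer(seed),
              use_phychem = isTRUE(use_phychem),
              use_edge_features = isTRUE(use_edge_features),
              use_positional = isTRUE(use_positional),
              pe_convention = pe_convention, cutoff = cutoff)
  .assert(cfg$d_model >= 1 && cfg$d_k >= 1 && cfg$n_heads >= 1,
          "model dimensions must be >= 1")
  .assert(cfg$conv_kernel %% 2 == 1, "conv_kernel must be odd")
  .assert(length(cfg$ffn_hidden) == 2, "ffn_hidden must give two widths")
  .assert(dropout >= 0 && dropout < 1, "dropout must be in [0, 1)")
  class(cfg) <- "model_config"
  cfg
}

# run expr with a local RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

.glorot <- function(nin, nout) {
  s <- sqrt(2 / (nin + nout))
  matrix(rnorm(nin * nout, sd = s), nin, nout)
}

#' Initialize a model
#'
#' Creates all learnable parameters (seeded) for a given node-feature
#' dimensionality. The parameter count covers a single encoder: the Siamese
#' halves share every weight.
#'
#' @param config a [model_config()]
#' @param d_node input node-feature dimensionality
#' @param seed optional override of `config$seed`
#' @return a `pairsite_model`: list with `params`, `config`, `d_node`
#' @export
init_model <- function(config, d_node, seed = NULL) {
  .assert(inherits(config, "model_config"), "config must be a model_config")
  seed <- seed %||% config$seed
  d <- config$d_model
  kw <- config$conv_kernel
  p <- .with_seed(seed, {
    p <- list()
    din <- d_node
    for (l in seq_len(config$n_conv_layers)) {
      p[[paste0("Wc", l)]] <- .glorot(kw * din, d)
      p[[paste0("bc", l)]] <- numeric(d)
      din <- d
    }
    for (l in seq_len(config$n_gat_layers)) {
      p[[paste0("Wg", l)]] <- .glorot(d, d)
      p[[paste0("We", l)]] <- .glorot(2, d)
      p[[paste0("at", l)]] <- rnorm(d, sd = sqrt(1 / d))
      p[[paste0("as", l)]] <- rnorm(d, sd = sqrt(1 / d))
      p[[paste0("ae", l)]] <- rnorm(d, sd = sqrt(1 / d))
    }
    for (h in seq_len(config$n_heads)) {
      p[[paste0("Wq", h)]] <- .glorot(d, config$d_k)
      p[[paste0("Wk", h)]] <- .glorot(d, config$d_k)
      p[[paste0("Wv", h)]] <- .glorot(d, config$d_k)
    }
    p$Wo <- .glorot(config$n_heads * config$d_k, d)
    p$ln_g <- rep(1, d)
    p$ln_b <- numeric(d)
    h1 <- config$ffn_hidden[1]; h2 <- config$ffn_hidden[2]
    p$Pw1 <- .glorot(2 * d, h1); p$Pb1 <- numeric(h1)
    p$Pw2 <- .glorot(h1, h2);    p$Pb2 <- numeric(h2)
    p$Pw3 <- .glorot(h2, 1);     p$Pb3 <- 0
    p$Iw1 <- .glorot(d, h1);     p$Ib1 <- numeric(h1)
    p$Iw2 <- .glorot(h1, h2);    p$Ib2 <- numeric(h2)
    p$Iw3 <- .glorot(h2, 1);     p$Ib3 <- 0
    p
  })
  structure(list(params = p, config = config, d_node = as.integer(d_node)),
            class = "pairsite_model")
}

#' @export
print.pairsite_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, 0L))
  cat(sprintf(paste0("<pairsite_model> d_node=%d d_model=%d heads=%d ",
                     "conv=%d gat=%d (%d parameters, one shared encoder)\n"),
              x$d_node, x$config$d_model, x$config$n_heads,
              x$config$n_conv_layers, x$config$n_gat_layers, np))
  invisible(x)
}

#' Total learnable parameter count of a model
#' @param model a `pairsite_model`
#' @return integer
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, length, 0L))
}
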