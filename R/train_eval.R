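# Training protocol and evaluation metrics.
#
# Training follows the highly imbalanced-data protocol: negatives among the
# residue pairs are downsampled to a fixed positive:negative ratio (1:10 by
# default) per complex and per epoch, while validation and test keep the
# original class ratio. Both tasks are evaluated per complex with AUROC
# (Mann-Whitney form, ties counting one half), step-wise AUPRC, and a
# precision-at-top-N table for the pairwise task; complexes whose split has
# a single class are excluded from medians and counted.

#' Downsample negative residue pairs
#'
#' Retains every positive pair and a uniform without-replacement sample of
#' `min(ratio * n_pos, n_neg)` negatives, reproducible per seed.
#'
#' @param labels a `pair_labels` object
#' @param ratio negatives retained per positive (default 10)
#' @param rng_seed integer seed
#' @return sorted integer vector of retained linear (column-major) indices
#'   into the label matrix
#' @export
downsample_negatives <- function(labels, ratio = 10, rng_seed = 1L) {
  .assert(inherits(labels, "pair_labels"), "not a pair_labels object")
  .assert(ratio >= 1, "ratio must be >= 1")
  y <- as.numeric(labels$matrix)
  pos <- which(y == 1)
  neg <- which(y == 0)
  if (length(pos) == 0)
    stop("no positive pairs: complex cannot be downsampled", call. = FALSE)
  n_keep <- min(round(ratio * length(pos)), length(neg))
  kept_neg <- .with_seed(rng_seed, sort(sample(neg, n_keep)))
  sort(c(pos, kept_neg))
}

#' Area under the ROC curve
#'
#' Computed as the normalized Mann-Whitney U statistic; tied scores
#' contribute one half. Returns `NA_real_` when only one class is present
#' (the caller excludes and counts such complexes).
#'
#' @param scores numeric vector
#' @param labels binary vector
#' @return value in `[0, 1]`, or `NA_real_` for single-class input
#' @export
auroc <- function(scores, labels) {
  .assert(length(scores) == length(labels), "length mismatch")
  labels <- as.numeric(labels)
  np <- sum(labels == 1); nn <- sum(labels == 0)
  if (np == 0 || nn == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nn)
}

#' Area under the precision-recall curve
#'
#' Step-wise sweep over distinct score thresholds in descending order (no
#' linear precision interpolation): the area adds
#' `(recall_t - recall_{t-1}) * precision_t` at each threshold. Returns
#' `NA_real_` when no positives are present.
#'
#' @param scores numeric vector
#' @param labels binary vector
#' @return value in `[0, 1]`, or `NA_real_` without positives
#' @export
auprc <- function(scores, labels) {
  .assert(length(scores) == length(labels), "length mismatch")
  labels <- as.numeric(labels)
  P <- sum(labels == 1)
  if (P == 0) return(NA_real_)
  ord <- order(-scores)
  s <- scores[ord]; y <- labels[ord]
  n <- length(s)
  boundary <- c(s[-n] != s[-1], TRUE) # last index of each distinct threshold
  tp <- cumsum(y)[boundary]
  k <- seq_len(n)[boundary]
  recall <- tp / P
  precision <- tp / k
  sum(diff(c(0, recall)) * precision)
}

#' Precision and recall at a probability threshold
#'
#' Predictions are `scores >= threshold`. With zero predicted positives the
#' precision is undefined and reported as `NA` (flagged, not 0).
#'
#' @param scores numeric vector
#' @param labels binary vector
#' @param threshold value in `[0, 1]`
#' @return list with `precision`, `recall`, `n_predicted`
#' @export
precision_recall_at_threshold <- function(scores, labels, threshold) {
  .assert(threshold >= 0 && threshold <= 1, "threshold must be in [0,1]")
  labels <- as.numeric(labels)
  pred <- scores >= threshold
  tp <- sum(pred & labels == 1)
  list(precision = if (sum(pred) == 0) NA_real_ else tp / sum(pred),
       recall = if (sum(labels == 1) == 0) NA_real_ else tp / sum(labels == 1),
       n_predicted = sum(pred))
}

#' Precision among the N highest-scoring residue pairs
#'
#' Ties at the boundary are broken by deterministic (column-major) index
#' order. `N` larger than the number of pairs is truncated with a warning.
#'
#' @param pair_scores numeric matrix (or vector) of pair scores
#' @param labels a `pair_labels` object or a binary vector/matrix matching
#'   `pair_scores`
#' @param N number of top pairs
#' @return fraction of the top N that are true interactions
#' @export
precision_at_top_n <- function(pair_scores, labels, N) {
  .assert(N >= 1, "N must be >= 1")
  y <- if (inherits(labels, "pair_labels")) as.numeric(labels$matrix)
       else as.numeric(labels)
  s <- as.numeric(pair_scores)
  .assert(length(s) == length(y), "scores/labels shape mismatch")
  if (N > length(s)) {
    warning(sprintf("N=%d exceeds %d pairs; truncated", N, length(s)))
    N <- length(s)
  }
  ord <- order(-s, seq_along(s))
  mean(y[ord[seq_len(N)]])
}

# standardize one sample's features/graphs with stored training statistics
.apply_stats <- function(sample, node_stats, edge_stats) {
  for (side in c("ligand", "receptor")) {
    sample[[side]]$features <-
      standardize_node_features(sample[[side]]$features, node_stats)$features
    sample[[side]]$graph <-
      standardize_edge_features(sample[[side]]$graph, edge_stats)$graphs[[1]]
  }
  sample
}

.fit_stats <- function(samples) {
  feats <- unlist(lapply(samples, function(s)
    list(s$ligand$features, s$receptor$features)), recursive = FALSE)
  graphs <- unlist(lapply(samples, function(s)
    list(s$ligand$graph, s$receptor$graph)), recursive = FALSE)
  list(node = standardize_node_features(feats)$stats,
       edge = standardize_edge_features(graphs)$stats)
}

# derived seed kept under 2^31
.derive_seed <- function(seed, a, b = 0L) {
  as.integer((as.numeric(seed) * 48271 + a * 7919 + b * 104729) %% 2147483587)
}

#' Train the model on a set of complexes
#'
#' Seeded Adam loop with binary cross-entropy over both heads (joint, equal
#' weights by default). Negative pairs are re-sampled each epoch from a seed
#' schedule at `ratio` negatives per positive; complexes without positive
#' pairs are skipped with a warning. Validation complexes are scored at
#' their original class ratio after every epoch, and the checkpoint with the
#' best validation median pairwise AUROC is kept (training-loss minimum when
#' no validation set is given). Node and edge features are standardized with
#' statistics fitted on the training split and stored in the checkpoint.
#'
#' @param train_set list of complex samples (from [make_dataset()] or
#'   [make_complex_sample()])
#' @param config a [model_config()]
#' @param val_set optional validation list
#' @param epochs training epochs
#' @param lr Adam learning rate
#' @param ratio negatives per positive during training
#' @param w_pair,w_iface loss weights of the two heads
#' @param verbose print per-epoch progress
#' @return a `pairsite_checkpoint`: list with `model`, `node_stats`,
#'   `edge_stats`, `history` (per-epoch losses and validation medians),
#'   `best_epoch`
#' @export
train_model <- function(train_set, config, val_set = NULL, epochs = 60L,
                        lr = 0.01, ratio = 10, w_pair = 1, w_iface = 1,
                        verbose = FALSE) {
  .assert(length(train_set) >= 1, "empty training set")
  stats <- .fit_stats(train_set)
  tr <- lapply(train_set, .apply_stats, stats$node, stats$edge)
  va <- if (!is.null(val_set))
    lapply(val_set, .apply_stats, stats$node, stats$edge) else NULL
  d_node <- ncol(tr[[1]]$ligand$features)
  model <- init_model(config, d_node)
  params <- model$params
  mom <- .zero_like(params); vel <- .zero_like(params)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; t_step <- 0

  # precompute per-complex positive/negative pools
  pools <- lapply(tr, function(s) {
    y <- as.numeric(s$pair_labels$matrix)
    list(pos = which(y == 1), neg = which(y == 0), y = y,
         nl = nrow(s$pair_labels$matrix))
  })
  no_pos <- vapply(pools, function(p) length(p$pos) == 0, TRUE)
  if (any(no_pos))
    warning(sprintf("%d training complex(es) without positive pairs skipped",
                    sum(no_pos)))

  history <- list(epoch = integer(0), train_loss = numeric(0),
                  val_median_auroc = numeric(0))
  best <- list(metric = -Inf, params = params, epoch = 0L)

  for (ep in seq_len(epochs)) {
    ep_loss <- 0; n_used <- 0
    for (ci in seq_along(tr)) {
      if (no_pos[ci]) next
      s <- tr[[ci]]
      pool <- pools[[ci]]
      sseed <- .derive_seed(config$seed, ep, ci)
      n_keep <- min(round(ratio * length(pool$pos)), length(pool$neg))
      kept <- .with_seed(sseed, c(pool$pos, sample(pool$neg, n_keep)))
      pair_i <- (kept - 1L) %% pool$nl + 1L
      pair_j <- (kept - 1L) %/% pool$nl + 1L
      lg <- .loss_and_grads(params, config, s,
                            pair_idx = list(i = pair_i, j = pair_j),
                            pair_y = pool$y[kept],
                            iface_y_l = s$iface$ligand,
                            iface_y_r = s$iface$receptor,
                            w_pair = w_pair, w_iface = w_iface,
                            training = TRUE)
      if (!is.finite(lg$loss))
        stop(sprintf("training diverged at epoch %d complex %d (loss=%g)",
                     ep, ci, lg$loss), call. = FALSE)
      t_step <- t_step + 1
      corr1 <- 1 - b1^t_step; corr2 <- 1 - b2^t_step
      for (nm in names(params)) {
        g <- lg$grads[[nm]]
        mom[[nm]] <- b1 * mom[[nm]] + (1 - b1) * g
        vel[[nm]] <- b2 * vel[[nm]] + (1 - b2) * g * g
        params[[nm]] <- params[[nm]] -
          lr * (mom[[nm]] / corr1) / (sqrt(vel[[nm]] / corr2) + eps)
      }
      ep_loss <- ep_loss + lg$loss; n_used <- n_used + 1
    }
    ep_loss <- ep_loss / max(n_used, 1)

    val_med <- NA_real_
    if (!is.null(va)) {
      model$params <- params
      aucs <- vapply(va, function(s) {
        pred <- predict_complex(model, s)
        auroc(as.numeric(pred$pair_probs), as.numeric(s$pair_labels$matrix))
      }, 0)
      val_med <- stats::median(aucs, na.rm = TRUE)
      metric <- val_med
    } else {
      metric <- -ep_loss
    }
    history$epoch <- c(history$epoch, ep)
    history$train_loss <- c(history$train_loss, ep_loss)
    history$val_median_auroc <- c(history$val_median_auroc, val_med)
    if (metric > best$metric) {
      best <- list(metric = metric, params = params, epoch = ep)
    }
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  val median AUROC %s",
                      ep, ep_loss,
                      if (is.na(val_med)) "-" else sprintf("%.3f", val_med)))
  }
  model$params <- best$params
  structure(list(model = model, node_stats = stats$node,
                 edge_stats = stats$edge, history = history,
                 best_epoch = best$epoch),
            class = "pairsite_checkpoint")
}

#' @export
print.pairsite_checkpoint <- function(x, ...) {
  cat(sprintf("<pairsite_checkpoint> best epoch %d of %d\n",
              x$best_epoch, length(x$history$epoch)))
  invisible(x)
}

#' Save / load a model checkpoint (parameters + config + feature statistics)
#'
#' @param checkpoint a `pairsite_checkpoint`
#' @param path file path (RDS archive)
#' @export
save_checkpoint <- function(checkpoint, path) {
  saveRDS(checkpoint, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  .assert(inherits(ck, "pairsite_checkpoint"), "not a pairsite checkpoint")
  ck
}

#' Predict a complex with a trained checkpoint
#'
#' Applies the stored feature standardization, then the network.
#'
#' @param checkpoint a `pairsite_checkpoint`
#' @param sample a complex sample (raw, unstandardized features)
#' @return a `prediction_result`
#' @export
predict_with_checkpoint <- function(checkpoint, sample) {
  s <- .apply_stats(sample, checkpoint$node_stats, checkpoint$edge_stats)
  predict_complex(checkpoint$model, s)
}

#' Evaluate a checkpoint on a dataset
#'
#' Scores every complex at its original class ratio and reports per-complex
#' AUROC (median as the headline number), AUPRC both pooled over all
#' predictions and as a per-complex median, and for the pairwise task the
#' precision among the top N highest-confidence pairs (N = 10, 20, ..., 100,
#' averaged over complexes). Complexes whose labels contain a single class
#' are excluded from per-complex summaries and counted in `n_excluded`.
#'
#' @param checkpoint a `pairsite_checkpoint`
#' @param dataset list of complex samples
#' @param task `"pairwise"` or `"interface"`
#' @return a `metrics_report` list
#' @export
evaluate_model <- function(checkpoint, dataset,
                           task = c("pairwise", "interface")) {
  task <- match.arg(task)
  .assert(length(dataset) >= 1, "empty dataset")
  per_auroc <- numeric(0); per_auprc <- numeric(0)
  pooled_scores <- numeric(0); pooled_labels <- numeric(0)
  prec_n <- seq(10L, 100L, by = 10L)
  prec_tab <- matrix(NA_real_, length(dataset), length(prec_n),
                     dimnames = list(NULL, paste0("top", prec_n)))
  n_excluded <- 0L
  for (ci in seq_along(dataset)) {
    s <- dataset[[ci]]
    pred <- predict_with_checkpoint(checkpoint, s)
    if (task == "pairwise") {
      scores <- as.numeric(pred$pair_probs)
      labels <- as.numeric(s$pair_labels$matrix)
      for (ni in seq_along(prec_n)) {
        if (prec_n[ni] <= length(scores))
          prec_tab[ci, ni] <- precision_at_top_n(scores, labels, prec_n[ni])
      }
    } else {
      scores <- c(pred$interface_probs_l, pred$interface_probs_r)
      labels <- c(s$iface$ligand, s$iface$receptor)
    }
    a <- auroc(scores, labels)
    if (is.na(a)) {
      n_excluded <- n_excluded + 1L
    } else {
      per_auroc <- c(per_auroc, a)
      per_auprc <- c(per_auprc, auprc(scores, labels))
    }
    pooled_scores <- c(pooled_scores, scores)
    pooled_labels <- c(pooled_labels, labels)
  }
  pr <- precision_recall_at_threshold(pooled_scores, pooled_labels, 0.5)
  structure(list(
    task = task,
    per_complex_auroc = per_auroc,
    median_auroc = stats::median(per_auroc),
    median_auprc = stats::median(per_auprc),
    pooled_auprc = auprc(pooled_scores, pooled_labels),
    precision = pr$precision, recall = pr$recall,
    precision_at_n = if (task == "pairwise")
      colMeans(prec_tab, na.rm = TRUE) else NULL,
    n_complexes = length(dataset), n_excluded = n_excluded
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> task=%s complexes=%d (excluded %d)\n",
              x$task, x$n_complexes, x$n_excluded))
  cat(sprintf("  median AUROC %.4f | median AUPRC %.4f | pooled AUPRC %.4f\n",
              x$median_auroc, x$median_auprc, x$pooled_auprc))
  if (!is.null(x$precision_at_n)) {
    cat("  precision@N:",
        paste(sprintf("%s=%.2f", names(x$precision_at_n), x$precision_at_n),
              collapse = " "), "\n")
  }
  invisible(x)
}
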