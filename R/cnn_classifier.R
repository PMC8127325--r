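# Convolutional intron-sequence classifier:
#   f(s) = net(pool(rect(conv(s))))
# A single convolutional layer of motif-detecting filters, a rectifier, an
# average-pooling layer that collapses each filter's response across sequence
# positions into one value (the cumulative presence of the motif), and a
# fully connected softmax head. The convolution is computed as an im2col
# matrix product over the integer-coded sequences, with ambiguity/padding
# positions contributing a uniform 0.25 over the four bases.

#' Configuration of the convolutional intron classifier
#'
#' Defaults are the selected hyperparameters of the reference architecture:
#' 128 filters of window 24, a 128-unit fully connected layer, dropout 0.2,
#' L2 strength 1e-6, rectifier activation, 30 epochs with batch size 64.
#'
#' @param n_filters Number of convolutional filters.
#' @param window Filter window size in bp.
#' @param fc_units Units in the fully connected layer.
#' @param dropout Dropout rate in \[0, 1) on the fully connected layer.
#' @param l2 L2 weight-penalty strength.
#' @param l1 L1 weight-penalty strength (default 0).
#' @param activation "relu" or "elu".
#' @param epochs Training epochs.
#' @param batch Batch size.
#' @param lr Adam learning rate.
#' @param seed Integer seed controlling initialisation and batch order.
#' @return A list of class `cnn_config`.
#' @export
cnn_config <- function(n_filters = 128L, window = 24L, fc_units = 128L,
                       dropout = 0.2, l2 = 1e-6, l1 = 0,
                       activation = "relu", epochs = 30L, batch = 64L,
                       lr = 1e-3, seed = 1L) {
  stopifnot(n_filters >= 1L, window >= 1L, fc_units >= 1L,
            dropout >= 0, dropout < 1, l2 >= 0, l1 >= 0,
            epochs >= 0L, batch >= 2L)
  structure(list(n_filters = as.integer(n_filters),
                 window = as.integer(window),
                 fc_units = as.integer(fc_units),
                 dropout = dropout, l2 = l2, l1 = l1,
                 activation = match.arg(activation, c("relu", "elu")),
                 epochs = as.integer(epochs), batch = as.integer(batch),
                 lr = lr, seed = as.integer(seed)),
            class = "cnn_config")
}

#' Build an (untrained) convolutional intron classifier
#'
#' @param config A [cnn_config()].
#' @param input_len Window length of the encoded input sequences (bp).
#' @param init "he" for random initialisation, "zero" for all-zero weights
#'   (useful to verify the uninformative 0.5/0.5 output).
#' @param input_kind Which intron window the model consumes ("first_window"
#'   or "last_window"); metadata only.
#' @return A list of class `cnn_model`.
#' @export
build_cnn <- function(config, input_len, init = c("he", "zero"),
                      input_kind = c("first_window", "last_window")) {
  init <- match.arg(init)
  input_kind <- match.arg(input_kind)
  if (config$window > input_len) {
    stop("filter window (", config$window, ") exceeds input length (",
         input_len, ")")
  }
  old <- local_rng(config$seed)
  on.exit(restore_rng(old))
  fan_in <- 4L * config$window
  params <- if (init == "he") {
    list(Wc = he_init(fan_in, config$n_filters),
         bc = rep(0, config$n_filters),
         W1 = he_init(config$n_filters, config$fc_units),
         b1 = rep(0, config$fc_units),
         W2 = he_init(config$fc_units, 2L),
         b2 = rep(0, 2L))
  } else {
    list(Wc = matrix(0, fan_in, config$n_filters),
         bc = rep(0, config$n_filters),
         W1 = matrix(0, config$n_filters, config$fc_units),
         b1 = rep(0, config$fc_units),
         W2 = matrix(0, config$fc_units, 2L),
         b2 = rep(0, 2L))
  }
  structure(list(config = config, params = params,
                 input_len = as.integer(input_len),
                 input_kind = input_kind, trained = FALSE),
            class = "cnn_model")
}

#' Number of trainable parameters of a CNN
#'
#' @param model A `cnn_model`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

# im2col for a batch of integer-coded sequences: returns the
# (B*P) x (4*window) design matrix where P = L - window + 1 and row
# r = (p-1)*B + b holds window p of sequence b.
cnn_im2col <- function(codes, window) {
  B <- nrow(codes); L <- ncol(codes)
  P <- L - window + 1L
  X <- matrix(0, B * P, 4L * window)
  for (j in seq_len(window)) {
    block <- .onehot_rows[codes[, j:(j + P - 1L), drop = FALSE], ,
                          drop = FALSE]
    X[, (4L * j - 3L):(4L * j)] <- block
  }
  X
}

cnn_forward <- function(model, codes, train = FALSE) {
  cfg <- model$config
  p <- model$params
  B <- nrow(codes)
  P <- ncol(codes) - cfg$window + 1L
  X <- cnn_im2col(codes, cfg$window)
  Z <- sweep(X %*% p$Wc, 2, p$bc, "+")
  A <- act_forward(Z, cfg$activation)
  grp <- rep_len(seq_len(B), B * P)
  pooled <- rowsum(A, grp, reorder = TRUE) / P
  Z1 <- sweep(pooled %*% p$W1, 2, p$b1, "+")
  H <- act_forward(Z1, cfg$activation)
  mask <- NULL
  if (train && cfg$dropout > 0) {
    mask <- matrix(stats::runif(length(H)) >= cfg$dropout,
                   nrow(H), ncol(H)) / (1 - cfg$dropout)
    H <- H * mask
  }
  logits <- sweep(H %*% p$W2, 2, p$b2, "+")
  probs <- softmax_rows(logits)
  list(probs = probs, X = X, Z = Z, pooled = pooled, Z1 = Z1, H = H,
       mask = mask, B = B, P = P)
}

cnn_backward <- function(model, cache, Y) {
  cfg <- model$config
  p <- model$params
  B <- cache$B; P <- cache$P
  delta <- (cache$probs - Y) / B
  gW2 <- crossprod(cache$H, delta) + 2 * cfg$l2 * p$W2 + cfg$l1 * sign(p$W2)
  gb2 <- colSums(delta)
  dH <- delta %*% t(p$W2)
  if (!is.null(cache$mask)) dH <- dH * cache$mask
  dZ1 <- dH * act_grad(cache$Z1, cfg$activation)
  gW1 <- crossprod(cache$pooled, dZ1) + 2 * cfg$l2 * p$W1 +
    cfg$l1 * sign(p$W1)
  gb1 <- colSums(dZ1)
  dpooled <- dZ1 %*% t(p$W1)
  dZ <- dpooled[rep_len(seq_len(B), B * P), , drop = FALSE] / P
  dZ <- dZ * act_grad(cache$Z, cfg$activation)
  gWc <- crossprod(cache$X, dZ) + 2 * cfg$l2 * p$Wc + cfg$l1 * sign(p$Wc)
  gbc <- colSums(dZ)
  list(Wc = gWc, bc = gbc, W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
}

#' Gene-grouped train/validation/test split
#'
#' Assigns whole genes (and therefore all their introns) to the held-out test
#' set or to one of `n_folds` cross-validation folds, stratified by binary
#' label, so that no gene contributes introns to more than one partition.
#'
#' @param gene_ids Character vector of gene ids.
#' @param labels Binary labels ("essential"/"nonessential"), parallel to
#'   `gene_ids`.
#' @param test_fraction Fraction of genes held out for the test set.
#' @param n_folds Number of cross-validation folds over the remainder.
#' @param seed Integer seed; the plan is deterministic given the seed.
#' @return A data.frame of class `split_plan` with columns `gene_id`,
#'   `label`, `role` (one of "test", "fold1".."foldK").
#' @export
grouped_split <- function(gene_ids, labels, test_fraction = 0.2,
                          n_folds = 3L, seed = 1L) {
  stopifnot(length(gene_ids) == length(labels),
            !anyDuplicated(gene_ids),
            test_fraction > 0, test_fraction < 1)
  counts <- table(labels)
  if (any(counts < n_folds + 1L)) {
    stop("need at least n_folds + 1 genes per class; got ",
         paste(names(counts), counts, sep = "=", collapse = ", "))
  }
  old <- local_rng(seed)
  on.exit(restore_rng(old))
  role <- character(length(gene_ids))
  for (lab in names(counts)) {
    idx <- which(labels == lab)
    idx <- idx[sample.int(length(idx))]
    n_test <- max(1L, round(test_fraction * length(idx)))
    role[idx[seq_len(n_test)]] <- "test"
    rest <- idx[-seq_len(n_test)]
    role[rest] <- paste0("fold", rep_len(seq_len(n_folds), length(rest)))
  }
  structure(data.frame(gene_id = gene_ids, label = labels, role = role,
                       stringsAsFactors = FALSE),
            class = c("split_plan", "data.frame"))
}

#' Genes in the training partition of a split plan
#'
#' @param plan A `split_plan`.
#' @param val_fold Optional fold name (e.g. "fold1") to hold out for
#'   validation; its genes are excluded from the returned training set.
#' @return Character vector of gene ids.
#' @export
train_genes <- function(plan, val_fold = NULL) {
  keep <- plan$role != "test"
  if (!is.null(val_fold)) keep <- keep & plan$role != val_fold
  plan$gene_id[keep]
}

#' Genes in one partition of a split plan
#'
#' @param plan A `split_plan`.
#' @param role "test" or a fold name.
#' @return Character vector of gene ids.
#' @export
split_genes <- function(plan, role) {
  plan$gene_id[plan$role == role]
}

#' Class-balanced epoch batches
#'
#' Builds one epoch of batch index sets in which the two classes are equally
#' represented: the majority class is shuffled without replacement and the
#' minority class oversampled with replacement to the majority size, then the
#' classes are interleaved so each batch is 50/50 within one example.
#'
#' @param labels Binary labels ("essential"/"nonessential") for the pool of
#'   training introns.
#' @param batch Batch size.
#' @param seed Integer seed; the batch sequence is deterministic given it.
#' @return A list of integer index vectors into `labels`, each of length
#'   `batch` (the final batch may be shorter).
#' @export
balanced_batches <- function(labels, batch, seed = 1L) {
  classes <- unique(labels)
  if (length(classes) != 2L) stop("need exactly two classes")
  old <- local_rng(seed)
  on.exit(restore_rng(old))
  idx1 <- which(labels == classes[1])
  idx2 <- which(labels == classes[2])
  n <- max(length(idx1), length(idx2))
  draw <- function(idx) {
    if (length(idx) == n) idx[sample.int(n)]
    else idx[sample.int(length(idx), n, replace = TRUE)]
  }
  e1 <- draw(idx1); e2 <- draw(idx2)
  interleaved <- as.vector(rbind(e1, e2))
  split(interleaved, ceiling(seq_along(interleaved) / batch))
}

#' Train the convolutional intron classifier
#'
#' Minimises cross-entropy with Adam over class-balanced batches for the
#' configured number of epochs, recording training loss and validation AUC
#' per epoch. With zero epochs the model is returned unchanged.
#'
#' @param model An untrained `cnn_model` from [build_cnn()].
#' @param x_train Integer code matrix of training windows
#'   (see [encode_codes()]).
#' @param y_train Binary labels parallel to `x_train` rows.
#' @param x_val,y_val Optional validation windows/labels for per-epoch AUC.
#' @param verbose Print per-epoch progress.
#' @return The trained `cnn_model`, with a `history` data.frame
#'   (epoch, loss, val_auc) attached.
#' @export
train_cnn <- function(model, x_train, y_train, x_val = NULL, y_val = NULL,
                      verbose = FALSE) {
  cfg <- model$config
  stopifnot(nrow(x_train) == length(y_train))
  Yfull <- label_matrix(y_train)
  opt <- adam_new(model$params, lr = cfg$lr)
  history <- data.frame(epoch = integer(), loss = numeric(),
                        val_auc = numeric())
  if (cfg$epochs == 0L) {
    model$history <- history
    return(model)
  }
  old <- local_rng(cfg$seed)
  on.exit(restore_rng(old))
  for (epoch in seq_len(cfg$epochs)) {
    batches <- balanced_batches(y_train, cfg$batch,
                                seed = cfg$seed + 1000L * epoch)
    epoch_loss <- 0
    for (bi in seq_along(batches)) {
      idx <- batches[[bi]]
      cache <- cnn_forward(model, x_train[idx, , drop = FALSE], train = TRUE)
      loss <- cross_entropy(cache$probs, Yfull[idx, , drop = FALSE])
      if (!is.finite(loss)) {
        stop("non-finite training loss at epoch ", epoch, ", batch ", bi)
      }
      epoch_loss <- epoch_loss + loss
      grads <- cnn_backward(model, cache, Yfull[idx, , drop = FALSE])
      upd <- adam_step(opt, model$params, grads)
      opt <- upd$state
      model$params <- upd$params
    }
    val_auc <- NA_real_
    if (!is.null(x_val) && length(unique(y_val)) == 2L) {
      val_auc <- roc_auc(score_introns(model, x_val), y_val)$auc
    }
    history <- rbind(history,
                     data.frame(epoch = epoch,
                                loss = epoch_loss / length(batches),
                                val_auc = val_auc))
    if (verbose) {
      message(sprintf("epoch %d/%d loss %.4f val_auc %s", epoch, cfg$epochs,
                      epoch_loss / length(batches),
                      ifelse(is.na(val_auc), "-", sprintf("%.3f", val_auc))))
    }
  }
  model$trained <- TRUE
  model$history <- history
  model
}

#' Score introns with a trained classifier
#'
#' @param model A `cnn_model`.
#' @param codes Integer code matrix of encoded windows.
#' @param batch Scoring batch size (memory knob only; results are identical
#'   to one-by-one scoring).
#' @return Numeric vector of essentiality scores in \[0, 1\] (softmax
#'   probability of the essential class).
#' @export
score_introns <- function(model, codes, batch = 256L) {
  n <- nrow(codes)
  out <- numeric(n)
  for (start in seq(1L, n, by = batch)) {
    idx <- start:min(start + batch - 1L, n)
    out[idx] <- cnn_forward(model, codes[idx, , drop = FALSE])$probs[, 2]
  }
  out
}

#' The default 36-model hyperparameter grid
#'
#' Cartesian product over the four searched axes — dropout rate,
#' convolutional window size, activation function and L2 strength — sized to
#' enumerate exactly 36 candidate models and to include the winning
#' combination (dropout 0.2, window 24, rectifier, L2 1e-6).
#'
#' @return A data.frame with columns `dropout`, `window`, `activation`, `l2`
#'   and 36 rows.
#' @export
default_cnn_grid <- function() {
  expand.grid(dropout = c(0, 0.2, 0.5),
              window = c(16L, 24L),
              activation = c("relu", "elu"),
              l2 = c(1e-4, 1e-6, 0),
              stringsAsFactors = FALSE)
}

#' Grid search by k-fold cross-validated AUC
#'
#' Evaluates every hyperparameter combination on each cross-validation fold
#' through a user-supplied evaluator and returns the combination with the
#' highest mean validation AUC. Ties are broken toward smaller L2, then
#' smaller dropout.
#'
#' @param grid Data.frame of hyperparameter combinations (one per row).
#' @param evaluator `function(params, fold)` returning a validation AUC,
#'   where `params` is a one-row slice of `grid` and `fold` runs over
#'   `1:n_folds`.
#' @param n_folds Number of folds (default 3).
#' @return A list with `best` (the winning one-row data.frame), `mean_auc`
#'   and the full `results` table.
#' @export
grid_search <- function(grid, evaluator, n_folds = 3L) {
  if (is.null(grid) || nrow(grid) == 0L) stop("empty hyperparameter grid")
  mean_auc <- numeric(nrow(grid))
  fold_auc <- matrix(NA_real_, nrow(grid), n_folds)
  for (i in seq_len(nrow(grid))) {
    for (f in seq_len(n_folds)) {
      fold_auc[i, f] <- evaluator(grid[i, , drop = FALSE], f)
    }
    mean_auc[i] <- mean(fold_auc[i, ])
  }
  l2 <- if ("l2" %in% names(grid)) grid$l2 else rep(0, nrow(grid))
  dropout <- if ("dropout" %in% names(grid)) grid$dropout else
    rep(0, nrow(grid))
  best <- order(-mean_auc, l2, dropout)[1]
  list(best = grid[best, , drop = FALSE],
       mean_auc = mean_auc[best],
       results = cbind(grid, mean_auc = mean_auc))
}
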