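# Seven-feature gene-essentiality network: z-score normalisation learned on
# training data, a grid-searched fully connected softmax network, and a
# 10-model ensemble whose members differ by initialisation seed and
# bootstrap-resampled training sets.

# Column order of the seven features within the model matrix.
feature_columns <- c("avg_intron_size", "n_introns", "total_intronic_bp",
                     "gc_density_first", "gc_density_later",
                     "gc_excl_first", "gc_excl_later")

#' Configuration of the seven-feature network
#'
#' @param hidden_layers Integer vector of hidden-layer sizes.
#' @param dropout Dropout rate on hidden layers.
#' @param l2 L2 weight-penalty strength.
#' @param activation "relu" or "elu".
#' @param epochs Training epochs (default 30).
#' @param batch Batch size (default 64).
#' @param lr Adam learning rate.
#' @param n_ensemble Number of ensemble members (default 10).
#' @param seed Integer seed.
#' @return A list of class `feature_net_config`.
#' @export
feature_net_config <- function(hidden_layers = c(32L), dropout = 0.2,
                               l2 = 1e-4, activation = "relu",
                               epochs = 30L, batch = 64L, lr = 1e-3,
                               n_ensemble = 10L, seed = 1L) {
  stopifnot(n_ensemble >= 1L, dropout >= 0, dropout < 1, l2 >= 0,
            epochs >= 0L, batch >= 2L)
  structure(list(hidden_layers = as.integer(hidden_layers),
                 dropout = dropout, l2 = l2,
                 activation = match.arg(activation, c("relu", "elu")),
                 epochs = as.integer(epochs), batch = as.integer(batch),
                 lr = lr, n_ensemble = as.integer(n_ensemble),
                 seed = as.integer(seed)),
            class = "feature_net_config")
}

#' Fit a feature normalizer on training data
#'
#' Later-intron features are missing for single-intron genes; they are
#' imputed with the training median and a missingness indicator column is
#' appended. Every feature is then z-scored with training statistics only;
#' constant features map to 0.
#'
#' @param features Per-gene feature data.frame (see [gene_feature_table()]).
#' @return A list of class `feature_normalizer`.
#' @export
fit_normalizer <- function(features) {
  X <- as.matrix(features[, feature_columns])
  medians <- apply(X, 2, stats::median, na.rm = TRUE)
  for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- medians[j]
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[!is.finite(sd) | sd == 0] <- Inf  # constant feature -> output 0
  structure(list(medians = medians, mu = mu, sd = sd),
            class = "feature_normalizer")
}

#' Transform a feature table with a fitted normalizer
#'
#' @param normalizer A `feature_normalizer` from [fit_normalizer()].
#' @param features Per-gene feature data.frame.
#' @return A numeric matrix: the seven z-scored features plus a
#'   `later_missing` indicator column.
#' @export
transform_features <- function(normalizer, features) {
  X <- as.matrix(features[, feature_columns])
  missing_later <- as.numeric(is.na(X[, "gc_density_later"]))
  for (j in seq_len(ncol(X))) {
    X[is.na(X[, j]), j] <- normalizer$medians[j]
  }
  X <- sweep(X, 2, normalizer$mu, "-")
  X <- sweep(X, 2, normalizer$sd, "/")
  cbind(X, later_missing = missing_later)
}

# Train a single MLP on a normalised matrix with class-balanced batches.
fit_mlp <- function(X, labels, config, seed) {
  model <- mlp_build(ncol(X), config$hidden_layers, config$activation,
                     seed = seed)
  if (config$epochs == 0L) return(model)
  Y <- label_matrix(labels)
  opt <- adam_new(model$params, lr = config$lr)
  old <- local_rng(seed)
  on.exit(restore_rng(old))
  for (epoch in seq_len(config$epochs)) {
    batches <- balanced_batches(labels, config$batch,
                                seed = seed + 1000L * epoch)
    for (idx in batches) {
      cache <- mlp_forward(model, X[idx, , drop = FALSE], train = TRUE,
                           dropout = config$dropout)
      loss <- cross_entropy(cache$probs, Y[idx, , drop = FALSE])
      if (!is.finite(loss)) stop("non-finite loss in feature net, epoch ",
                                 epoch)
      grads <- mlp_backward(model, cache, Y[idx, , drop = FALSE],
                            l2 = config$l2)
      upd <- adam_step(opt, model$params, grads)
      opt <- upd$state
      model$params <- upd$params
    }
  }
  model
}

#' Default hyperparameter grid for the feature network
#'
#' Hidden depth 1-2, width 32 or 128, dropout 0 or 0.2, L2 0 or 1e-4.
#'
#' @return A data.frame with columns `n_hidden`, `units`, `dropout`, `l2`.
#' @export
default_feature_grid <- function() {
  expand.grid(n_hidden = c(1L, 2L), units = c(32L, 128L),
              dropout = c(0, 0.2), l2 = c(0, 1e-4))
}

#' Train the seven-feature gene classifier
#'
#' Fits the normalizer on the training genes, optionally grid-searches the
#' architecture by threefold cross-validated AUC (gene-grouped trivially,
#' since each gene contributes one vector), then fits the final network on
#' all training data.
#'
#' @param features Per-gene feature data.frame for the training genes.
#' @param labels Binary labels parallel to `features` rows.
#' @param config A [feature_net_config()].
#' @param grid Optional hyperparameter grid (see [default_feature_grid()]);
#'   NULL skips the search and uses `config` as-is.
#' @return A list of class `feature_net` with the fitted normalizer, model
#'   and config.
#' @export
train_feature_net <- function(features, labels, config = feature_net_config(),
                              grid = NULL) {
  stopifnot(nrow(features) == length(labels))
  normalizer <- fit_normalizer(features)
  X <- transform_features(normalizer, features)
  if (!is.null(grid)) {
    folds <- rep_len(1:3, nrow(X))
    old <- local_rng(config$seed)
    folds <- folds[sample.int(length(folds))]
    restore_rng(old)
    evaluator <- function(params, fold) {
      cfg <- config
      cfg$hidden_layers <- rep(params$units, params$n_hidden)
      cfg$dropout <- params$dropout
      cfg$l2 <- params$l2
      tr <- folds != fold
      m <- fit_mlp(X[tr, , drop = FALSE], labels[tr], cfg, seed = config$seed)
      roc_auc(mlp_predict(m, X[!tr, , drop = FALSE]), labels[!tr])$auc
    }
    found <- grid_search(grid, evaluator, n_folds = 3L)
    config$hidden_layers <- rep(found$best$units, found$best$n_hidden)
    config$dropout <- found$best$dropout
    config$l2 <- found$best$l2
  }
  model <- fit_mlp(X, labels, config, seed = config$seed)
  structure(list(normalizer = normalizer, model = model, config = config),
            class = "feature_net")
}

#' Predict gene essentiality scores from a feature network
#'
#' @param net A `feature_net`.
#' @param features Per-gene feature data.frame.
#' @return Numeric vector of essentiality scores in \[0, 1\].
#' @export
feature_net_predict <- function(net, features) {
  mlp_predict(net$model, transform_features(net$normalizer, features))
}

#' Train the 10-model feature-network ensemble
#'
#' Members share the architecture but differ by initialisation seed and by a
#' bootstrap resample of the training genes; the ensemble score is the
#' unweighted mean of member scores, which reduces variance relative to a
#' single fit.
#'
#' @inheritParams train_feature_net
#' @return A list of class `feature_ensemble`.
#' @export
train_feature_ensemble <- function(features, labels,
                                   config = feature_net_config(),
                                   grid = NULL) {
  members <- vector("list", config$n_ensemble)
  old <- local_rng(config$seed)
  boots <- lapply(seq_len(config$n_ensemble), function(i)
    sample.int(nrow(features), replace = TRUE))
  restore_rng(old)
  for (i in seq_len(config$n_ensemble)) {
    idx <- boots[[i]]
    # ensure both classes survive the bootstrap
    if (length(unique(labels[idx])) < 2L) {
      idx <- c(idx, which(labels == setdiff(unique(labels), labels[idx]))[1])
    }
    cfg_i <- config
    cfg_i$seed <- config$seed + i
    members[[i]] <- train_feature_net(features[idx, , drop = FALSE],
                                      labels[idx], cfg_i,
                                      grid = if (i == 1L) grid else NULL)
    if (i == 1L && !is.null(grid)) {
      # reuse the searched architecture for the remaining members
      config$hidden_layers <- members[[1]]$config$hidden_layers
      config$dropout <- members[[1]]$config$dropout
      config$l2 <- members[[1]]$config$l2
      grid <- NULL
    }
  }
  structure(list(members = members, config = config),
            class = "feature_ensemble")
}

#' Ensemble prediction
#'
#' The unweighted mean of member scores; invariant to member order.
#'
#' @param ensemble A `feature_ensemble` (or list of `feature_net`s).
#' @param features Per-gene feature data.frame.
#' @return Numeric vector of ensemble essentiality scores.
#' @export
ensemble_predict <- function(ensemble, features) {
  members <- if (inherits(ensemble, "feature_ensemble")) ensemble$members
             else ensemble
  scores <- vapply(members, feature_net_predict, numeric(nrow(features)),
                   features = features)
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1L)
  rowMeans(scores)
}
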