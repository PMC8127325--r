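# Shared neural-network machinery: activations, Adam, and a small
# fully-connected softmax network used both as the CNN head and as the
# seven-feature gene classifier. Everything is plain matrix algebra so that
# runs are deterministic given a seed (up to BLAS summation order).

act_forward <- function(z, activation) {
  switch(activation,
    relu = pmax(z, 0),
    elu = ifelse(z > 0, z, exp(pmin(z, 0)) - 1),
    stop("unknown activation: ", activation))
}

# gradient of the activation as a function of the pre-activation z
act_grad <- function(z, activation) {
  switch(activation,
    relu = (z > 0) * 1,
    elu = ifelse(z > 0, 1, exp(pmin(z, 0))),
    stop("unknown activation: ", activation))
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

adam_new <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0,
       m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))
}

adam_step <- function(state, params, grads) {
  state$t <- state$t + 1
  bc1 <- 1 - state$beta1^state$t
  bc2 <- 1 - state$beta2^state$t
  for (k in names(params)) {
    g <- grads[[k]]
    state$m[[k]] <- state$beta1 * state$m[[k]] + (1 - state$beta1) * g
    state$v[[k]] <- state$beta2 * state$v[[k]] + (1 - state$beta2) * g * g
    mhat <- state$m[[k]] / bc1
    vhat <- state$v[[k]] / bc2
    params[[k]] <- params[[k]] - state$lr * mhat / (sqrt(vhat) + state$eps)
  }
  list(state = state, params = params)
}

# He-normal initialisation for a fan_in x fan_out weight matrix
he_init <- function(fan_in, fan_out) {
  matrix(stats::rnorm(fan_in * fan_out, sd = sqrt(2 / fan_in)),
         fan_in, fan_out)
}

#' Build a fully connected softmax network
#'
#' A small multi-layer perceptron with a two-unit softmax output, used as the
#' seven-feature gene classifier. Hidden layers use the configured activation
#' and (in training) inverted dropout.
#'
#' @param n_input Number of input features.
#' @param hidden_layers Integer vector of hidden-layer sizes.
#' @param activation "relu" or "elu".
#' @param seed Integer seed for weight initialisation.
#' @param init "he" (default) or "zero".
#' @return A list of class `mlp_model`.
#' @export
mlp_build <- function(n_input, hidden_layers = c(32L), activation = "relu",
                      seed = 1L, init = c("he", "zero")) {
  init <- match.arg(init)
  sizes <- c(n_input, hidden_layers, 2L)
  params <- list()
  old <- local_rng(seed)
  on.exit(restore_rng(old))
  for (i in seq_len(length(sizes) - 1L)) {
    params[[paste0("W", i)]] <-
      if (init == "he") he_init(sizes[i], sizes[i + 1]) else
        matrix(0, sizes[i], sizes[i + 1])
    params[[paste0("b", i)]] <- rep(0, sizes[i + 1])
  }
  structure(list(params = params, sizes = sizes, activation = activation,
                 n_layers = length(sizes) - 1L),
            class = "mlp_model")
}

# Forward pass; when train=TRUE applies inverted dropout with the supplied
# rate using the current RNG stream, and returns the caches needed for
# backprop.
mlp_forward <- function(model, X, train = FALSE, dropout = 0) {
  p <- model$params
  L <- model$n_layers
  a <- X
  zs <- list(); as_ <- list(X); masks <- list()
  for (i in seq_len(L)) {
    z <- sweep(a %*% p[[paste0("W", i)]], 2, p[[paste0("b", i)]], "+")
    if (i < L) {
      a <- act_forward(z, model$activation)
      if (train && dropout > 0) {
        mask <- matrix(stats::runif(length(a)) >= dropout,
                       nrow(a), ncol(a)) / (1 - dropout)
        a <- a * mask
        masks[[i]] <- mask
      }
    } else {
      a <- softmax_rows(z)
    }
    zs[[i]] <- z; as_[[i + 1]] <- a
  }
  list(probs = a, zs = zs, as_ = as_, masks = masks)
}

# Backward pass: cross-entropy + softmax gradient, plus L2/L1 weight decay.
mlp_backward <- function(model, cache, Y, l2 = 0, l1 = 0) {
  p <- model$params
  L <- model$n_layers
  B <- nrow(Y)
  grads <- list()
  delta <- (cache$probs - Y) / B
  for (i in rev(seq_len(L))) {
    Wk <- paste0("W", i); bk <- paste0("b", i)
    grads[[Wk]] <- crossprod(cache$as_[[i]], delta) +
      2 * l2 * p[[Wk]] + l1 * sign(p[[Wk]])
    grads[[bk]] <- colSums(delta)
    if (i > 1L) {
      delta <- delta %*% t(p[[Wk]])
      if (length(cache$masks) >= i - 1L && !is.null(cache$masks[[i - 1L]])) {
        delta <- delta * cache$masks[[i - 1L]]
      }
      delta <- delta * act_grad(cache$zs[[i - 1L]], model$activation)
    }
  }
  grads
}

#' Predict class probabilities from an MLP
#'
#' @param model An `mlp_model`.
#' @param X Feature matrix (rows = genes).
#' @return Numeric vector of probabilities for the essential class (column 2
#'   of the softmax output).
#' @export
mlp_predict <- function(model, X) {
  mlp_forward(model, as.matrix(X))$probs[, 2]
}

# One-hot label matrix: column 1 = nonessential, column 2 = essential.
label_matrix <- function(labels) {
  y <- as.integer(labels == "essential")
  cbind(1 - y, y)
}

cross_entropy <- function(probs, Y) {
  -mean(log(pmax(rowSums(probs * Y), 1e-12)))
}

# Seed handling that never clobbers the caller's RNG stream.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
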