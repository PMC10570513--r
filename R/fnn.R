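# Small feedforward neural network for vGRF regression, implemented in base
# R: 5 hidden ReLU layers of 10 units, Adam optimizer, RMSE loss, inverted
# dropout after each hidden layer and a max-norm constraint on the incoming
# weight vector of every hidden unit.

#' Feedforward-network configuration
#'
#' @param hidden_layers number of hidden layers.
#' @param neurons units per hidden layer.
#' @param dropout dropout rate applied after each hidden layer in training.
#' @param max_norm maximum Euclidean norm of any unit's incoming weights.
#' @param epochs maximum training epochs.
#' @param batch_size minibatch size.
#' @param learning_rate Adam step size.
#' @param patience early-stopping patience (epochs without validation
#'   improvement) when validation data is supplied.
#' @param seed integer seed (initialization, shuffling, dropout masks).
#' @return list of class `fnn_config`.
#' @export
fnn_config <- function(hidden_layers = 5, neurons = 10, dropout = 0.2,
                       max_norm = 4, epochs = 200, batch_size = 128,
                       learning_rate = 3e-3, patience = 30, seed = 1) {
  stopifnot(hidden_layers >= 1, neurons >= 1, dropout >= 0, dropout < 1,
            max_norm > 0, epochs >= 1, batch_size >= 1)
  structure(list(hidden_layers = hidden_layers, neurons = neurons,
                 dropout = dropout, max_norm = max_norm, epochs = epochs,
                 batch_size = batch_size, learning_rate = learning_rate,
                 patience = patience, seed = seed),
            class = "fnn_config")
}

# forward pass; returns output and (optionally) the per-layer activations
fnn_forward <- function(net, X, keep = FALSE, masks = NULL) {
  a <- X
  acts <- if (keep) vector("list", length(net$W)) else NULL
  for (l in seq_along(net$W)) {
    z <- a %*% net$W[[l]] + matrix(net$b[[l]], nrow(a), length(net$b[[l]]),
                                   byrow = TRUE)
    if (l < length(net$W)) {
      z[z < 0] <- 0                       # ReLU
      if (!is.null(masks)) z <- z * masks[[l]]
    }
    if (keep) acts[[l]] <- z
    a <- z
  }
  list(output = a, acts = acts)
}

# column-wise max-norm constraint (incoming weights of each unit)
apply_max_norm <- function(W, max_norm) {
  nrm <- sqrt(colSums(W^2))
  over <- nrm > max_norm
  if (any(over)) W[, over] <- sweep(W[, over, drop = FALSE], 2,
                                    max_norm / nrm[over], "*")
  W
}

#' Train the feedforward-network vGRF regressor
#'
#' Minimizes the root-mean-square error with Adam. When validation data is
#' given, training stops after `patience` epochs without improvement and the
#' best weights are restored.
#'
#' @param X scaled training features; `y` vGRF labels (BW).
#' @param y numeric label vector.
#' @param config an [fnn_config()].
#' @param X_val,y_val optional validation data for early stopping.
#' @param verbose print the loss every 10 epochs.
#' @return object of class `grf_model` (kind `"fnn"`).
#' @export
train_grf_fnn <- function(X, y, config = fnn_config(), X_val = NULL,
                          y_val = NULL, verbose = FALSE) {
  if (anyNA(X) || anyNA(y)) stop("NaN/NA in training data")
  if (length(y) == 0) stop("empty training data")
  set.seed(config$seed)
  sizes <- c(ncol(X), rep(config$neurons, config$hidden_layers), 1L)
  L <- length(sizes) - 1
  he_init <- function(nin, nout)
    matrix(stats::runif(nin * nout, -1, 1) * sqrt(6 / nin), nin, nout)
  net <- list(W = lapply(seq_len(L), function(l) he_init(sizes[l], sizes[l + 1])),
              b = lapply(seq_len(L), function(l) numeric(sizes[l + 1])))
  mW <- lapply(net$W, function(w) w * 0); vW <- mW
  mb <- lapply(net$b, function(b) b * 0); vb <- mb
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; lr <- config$learning_rate
  step <- 0L
  n <- nrow(X)
  best <- list(loss = Inf, net = net, epoch = 0L)
  wait <- 0L
  epochs_run <- 0L
  history <- numeric(0)

  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    for (start in seq(1, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1, n)]
      xb <- X[idx, , drop = FALSE]; yb <- y[idx]
      m <- length(idx)
      masks <- NULL
      if (config$dropout > 0) {
        masks <- lapply(seq_len(L - 1), function(l)
          matrix(stats::rbinom(m * sizes[l + 1], 1, 1 - config$dropout) /
                   (1 - config$dropout), m, sizes[l + 1]))
      }
      fw <- fnn_forward(net, xb, keep = TRUE, masks = masks)
      err <- drop(fw$output) - yb
      rmse <- sqrt(mean(err^2))
      if (rmse < 1e-12) next
      # dL/dyhat for L = sqrt(mean(err^2))
      delta <- matrix(err / (m * rmse), m, 1)
      gW <- vector("list", L); gb <- vector("list", L)
      for (l in L:1) {
        a_prev <- if (l == 1) xb else fw$acts[[l - 1]]
        gW[[l]] <- crossprod(a_prev, delta)
        gb[[l]] <- colSums(delta)
        if (l > 1) {
          delta <- delta %*% t(net$W[[l]])
          delta[fw$acts[[l - 1]] <= 0] <- 0
          if (!is.null(masks)) delta <- delta * masks[[l - 1]]
        }
      }
      step <- step + 1L
      corr <- sqrt(1 - b2^step) / (1 - b1^step)
      for (l in seq_len(L)) {
        mW[[l]] <- b1 * mW[[l]] + (1 - b1) * gW[[l]]
        vW[[l]] <- b2 * vW[[l]] + (1 - b2) * gW[[l]]^2
        net$W[[l]] <- net$W[[l]] - lr * corr * mW[[l]] / (sqrt(vW[[l]]) + eps)
        mb[[l]] <- b1 * mb[[l]] + (1 - b1) * gb[[l]]
        vb[[l]] <- b2 * vb[[l]] + (1 - b2) * gb[[l]]^2
        net$b[[l]] <- net$b[[l]] - lr * corr * mb[[l]] / (sqrt(vb[[l]]) + eps)
        if (l < L) net$W[[l]] <- apply_max_norm(net$W[[l]], config$max_norm)
      }
    }
    epochs_run <- ep
    if (!is.null(X_val)) {
      pv <- drop(fnn_forward(net, X_val)$output)
      vloss <- sqrt(mean((pv - y_val)^2))
      history <- c(history, vloss)
      if (verbose && ep %% 10 == 0)
        message(sprintf("epoch %d: val RMSE %.4f", ep, vloss))
      if (vloss < best$loss - 1e-6) {
        best <- list(loss = vloss, net = net, epoch = ep)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    }
  }
  if (!is.null(X_val) && is.finite(best$loss)) net <- best$net
  structure(list(kind = "fnn", fit = net, config = config,
                 features = colnames(X), epochs_run = epochs_run,
                 val_history = history, best_epoch = best$epoch),
            class = "grf_model")
}
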